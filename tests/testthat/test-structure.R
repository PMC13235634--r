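test_that("chain order hits its analytic limits", {
  up <- make_bond_frame(c(0, 0, 0.4))
  expect_equal(chain_order(up$frame, up$topo)$S_chain, 1)
  flat <- make_bond_frame(c(0.4, 0, 0))
  expect_equal(chain_order(flat$frame, flat$topo)$S_chain, -0.5)
})

test_that("isotropic bonds average to zero order", {
  set.seed(72)
  n_chains <- 5e4
  u <- matrix(rnorm(3 * n_chains), n_chains, 3)
  u <- u / sqrt(rowSums(u^2)) * 0.4
  pos <- matrix(0, 2 * n_chains, 3)
  pos[seq(1, 2 * n_chains, 2), ] <- 5
  pos[seq(2, 2 * n_chains, 2), ] <- 5 + u
  topo <- new_topology(rep(c("C1", "C2"), n_chains), rep("DPPC", 2 * n_chains),
                       rep(seq_len(n_chains), each = 2),
                       chains = lapply(seq_len(n_chains), function(i) c(2 * i - 1, 2 * i)))
  S <- chain_order(new_frame(pos, c(12, 12, 12)), topo)$S_chain
  expect_lt(abs(S), 0.01)
})

test_that("chain order is invariant under rigid rotation about z", {
  base <- make_bond_frame(c(0.2, 0.1, 0.3))
  S0 <- chain_order(base$frame, base$topo)$S_chain
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  rot <- new_frame(base$frame$positions %*% R + 5, c(20, 20, 20))
  expect_equal(chain_order(rot, base$topo)$S_chain, S0, tolerance = 1e-9)
  expect_error(chain_order(base$frame, simple_chol_topology()), "chain")
})

test_that("area per lipid is bare lateral area over leaflet PC count", {
  n_po4 <- 200
  topo <- new_topology(rep("PO4", n_po4), rep("DPPC", n_po4), seq_len(n_po4))
  z <- rep(c(7, 3), each = 100)
  fr <- new_frame(cbind(runif(n_po4, 0, 8), runif(n_po4, 0, 8), z), c(8, 8, 10))
  apl <- area_per_lipid(fr, topo)
  expect_equal(apl$a_pc, 0.64)        # 8*8/100
  expect_equal(apl$n_pc_leaflet, 100)
})

test_that("area per lipid tracks a fluctuating box exactly", {
  n_po4 <- 40
  topo <- new_topology(rep("PO4", n_po4), rep("DPPC", n_po4), seq_len(n_po4))
  z <- rep(c(7, 3), each = 20)
  Ls <- c(7.8, 8.0, 8.2, 8.1)
  frames <- lapply(seq_along(Ls), function(i)
    new_frame(cbind(runif(n_po4, 0, Ls[i]), runif(n_po4, 0, Ls[i]), z),
              c(Ls[i], Ls[i], 10), time = i))
  apl <- area_per_lipid(frames, topo)
  expect_equal(apl$series, Ls^2 / 20)
  # a fixture built to the gel-phase area is recovered exactly
  L <- sqrt(0.478 * 20)
  fr <- new_frame(cbind(runif(n_po4, 0, L), runif(n_po4, 0, L), z), c(L, L, 10))
  expect_equal(area_per_lipid(fr, topo)$a_pc, 0.478, tolerance = 1e-12)
})

test_that("unequal leaflet occupancy warns and averages", {
  n_po4 <- 30
  topo <- new_topology(rep("PO4", n_po4), rep("DPPC", n_po4), seq_len(n_po4))
  z <- c(rep(7, 20), rep(3, 10))
  fr <- new_frame(cbind(runif(n_po4, 0, 6), runif(n_po4, 0, 6), z), c(6, 6, 10))
  expect_warning(apl <- area_per_lipid(fr, topo), "unequal")
  expect_equal(apl$n_pc_leaflet, 15)
})

test_that("ideal-gas placement gives a flat 2-D RDF", {
  set.seed(73)
  n <- 1500
  pos <- cbind(runif(n, 0, 12), runif(n, 0, 12), rep(7, n))
  topo <- new_topology(rep("PO4", n), rep("DPPC", n), seq_len(n))
  fr <- new_frame(pos, c(12, 12, 10))
  g <- rdf_2d(fr, topo, seq_len(n), r_max = 3, dr = 0.1, per_leaflet = FALSE)
  sigma <- 1 / sqrt(pmax(g$counts, 1))
  expect_true(all(abs(g$g_r - 1) < 4 * pmax(sigma, 0.02)))
  # integral check: expected neighbours within r_max
  rho <- n / 144
  n_nb <- sum(g$g_r * rho * 2 * pi * g$r_nm * 0.1)
  expect_lt(abs(n_nb / (rho * pi * 3^2) - 1), 0.02)
})

test_that("a hexagonal lattice puts the first RDF peak at its spacing", {
  a <- 0.8
  v1 <- c(a, 0); v2 <- c(a / 2, a * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(0:11, function(i) t(sapply(0:11, function(j) i * v1 + j * v2))))
  pts <- pts %% (12 * a)
  n <- nrow(pts)
  topo <- new_topology(rep("PO4", n), rep("DPPC", n), seq_len(n))
  fr <- new_frame(cbind(pts, 5), c(12 * a, 12 * a, 10))
  g <- rdf_2d(fr, topo, seq_len(n), r_max = 2, dr = 0.05, per_leaflet = FALSE)
  first_peak <- g$r_nm[which(g$counts > 0)[1]]
  expect_lt(abs(first_peak - a), 0.05)
  expect_error(rdf_2d(fr, topo, seq_len(n), r_max = 6), "half")
})

test_that("self-pairs are excluded from same-group RDFs", {
  pos <- cbind(c(1, 2), c(1, 1), c(5, 5))
  topo <- new_topology(rep("PO4", 2), rep("DPPC", 2), 1:2)
  fr <- new_frame(pos, c(8, 8, 10))
  g <- rdf_2d(fr, topo, 1:2, r_max = 3, dr = 0.5, per_leaflet = FALSE)
  expect_equal(sum(g$counts), 2)   # the (1,2) and (2,1) pair only
  expect_true(all(is.finite(g$g_r[g$counts > 0])))
})

test_that("melting temperature is the analytic midpoint on noiseless scans", {
  sc <- gen_hysteresis_scan(310, 302, noise = 0)
  tm <- estimate_tm(sc$heating, sc$cooling)
  expect_equal(tm$Tm, 306)
  expect_equal(tm$Tm_heating, 310)
  expect_equal(tm$Tm_cooling, 302)
  # degenerate hysteresis: identical midpoints
  sc2 <- gen_hysteresis_scan(306, 306, noise = 0)
  tm2 <- estimate_tm(sc2$heating, sc2$cooling)
  expect_equal(tm2$Tm, 306)
  expect_equal(tm2$hysteresis, 0)
})

test_that("flat scans report no transition", {
  flat_h <- new_scan_table(seq(280, 340, 0.5), rep(0.5, 121), "heating")
  flat_c <- new_scan_table(seq(340, 280, -0.5), rep(0.5, 121), "cooling")
  tm <- estimate_tm(flat_h, flat_c)
  expect_true(is.na(tm$Tm))
  expect_match(tm$method, "no transition")
})

test_that("swapping heating and cooling labels negates the width, keeps Tm", {
  sc <- gen_hysteresis_scan(312, 304, noise = 0)
  a <- estimate_tm(sc$heating, sc$cooling)
  h2 <- sc$cooling; h2$direction <- "heating"
  c2 <- sc$heating; c2$direction <- "cooling"
  b <- estimate_tm(h2, c2)
  expect_equal(b$Tm, a$Tm)
  expect_equal(b$hysteresis, -a$hysteresis)
})

test_that("Tm recovery under 1% noise stays within 0.5 K median", {
  errs <- vapply(1:50, function(s) {
    sc <- gen_hysteresis_scan(310, 302, noise = 0.01 * (0.634 - 0.478),
                              seed = 800 + s)
    abs(estimate_tm(sc$heating, sc$cooling)$Tm - 306)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})
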