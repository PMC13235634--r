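test_that("tilt angle hits the canonical orientations exactly", {
  topo <- simple_chol_topology(n_chol = 1, n_po4 = 8)
  # upright in the upper leaflet: director along +z = outward normal
  fr <- simple_chol_frame(z_roh = 6.5)
  expect_equal(tilt_angle(fr, topo, 1)$theta, 0)
  # upright in the lower leaflet: director -z, outward normal -z -> 0 again
  fr2 <- simple_chol_frame(z_roh = 3.5)
  expect_equal(tilt_angle(fr2, topo, 1)$theta, 0)
  # in-plane director -> 90 degrees
  pos <- fr$positions
  pos[2, ] <- pos[1, ] + c(0.9, 0, 0)   # tail bead beside the ROH bead
  expect_equal(tilt_angle(new_frame(pos, fr$box), topo, 1)$theta, 90)
  # inverted: ROH toward midplane, tail toward water -> 180
  pos2 <- fr$positions
  pos2[1, 3] <- 5.6; pos2[2, 3] <- 6.5
  expect_equal(tilt_angle(new_frame(pos2, fr$box), topo, 1)$theta, 180)
  # zero-length director errors
  pos3 <- fr$positions; pos3[2, ] <- pos3[1, ]
  expect_error(tilt_angle(new_frame(pos3, fr$box), topo, 1), "zero-length")
})

test_that("a director and its negation have supplementary tilt angles", {
  topo <- simple_chol_topology(n_chol = 1, n_po4 = 8)
  set.seed(61)
  for (i in 1:20) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2)) * 0.9
    pos <- simple_chol_frame(6.2)$positions
    pos[2, ] <- pos[1, ] - d
    t1 <- tilt_angle(new_frame(pos, c(8, 8, 10)), topo, 1)$theta
    pos[2, ] <- pos[1, ] + d
    t2 <- tilt_angle(new_frame(pos, c(8, 8, 10)), topo, 1)$theta
    expect_equal(t1 + t2, 180, tolerance = 1e-9)
  }
})

test_that("surfaces are normalized with zero-minimum free energy", {
  set.seed(62)
  s <- data.frame(z = rnorm(5000, 0, 0.5), theta = runif(5000, 0, 180))
  surf <- build_surface(s, seq(-2, 2, 0.1), seq(0, 180, 2))
  expect_equal(sum(surf$P), 1, tolerance = 1e-12)
  expect_equal(min(surf$F, na.rm = TRUE), 0)
  expect_true(all(surf$F >= 0, na.rm = TRUE))
  expect_true(all(is.na(surf$F[surf$counts == 0])))
})

test_that("all samples in one bin leave the rest masked", {
  s <- data.frame(z = rep(0.55, 10), theta = rep(45.5, 10))
  surf <- build_surface(s, seq(0, 1, 0.1), seq(0, 180, 2))
  expect_equal(sum(!is.na(surf$F)), 1)
  expect_equal(surf$F[6, 23], 0)
  expect_error(build_surface(s[0, ]), "no samples")
})

test_that("free energy depends only on relative frequencies", {
  set.seed(63)
  s <- data.frame(z = rnorm(4000, 0, 0.4), theta = 90 + rnorm(4000, 0, 20))
  s2 <- rbind(s, s)   # doubled sample count
  a <- build_surface(s, seq(-2, 2, 0.2), seq(0, 180, 5))
  b <- build_surface(s2, seq(-2, 2, 0.2), seq(0, 180, 5))
  expect_equal(a$F, b$F)
})

test_that("sampling then rebuilding recovers the generating surface", {
  fw <- fes_five_well()
  s <- sample_fes(fw$F, fw$z_edges, fw$theta_edges, 2e5, seed = 64)
  surf <- build_surface(s, fw$z_edges, fw$theta_edges)
  sel <- surf$counts >= 100
  rms <- sqrt(mean((surf$F[sel] - fw$F[sel])^2))
  expect_lt(rms, 0.1)
})

test_that("1-D projections take the minimum over the other axis", {
  # surface constant in theta: the z-projection equals any fixed-theta slice
  fw <- fes_five_well()
  Fm <- matrix(rep(abs(seq(-2.45, 2.45, by = 0.1)), 90), ncol = 90)
  surf <- list(F = Fm, z_mid = seq(-2.45, 2.45, by = 0.1),
               theta_mid = seq(1, 179, by = 2))
  class(surf) <- "fes_surface"
  pz <- project_1d(surf, "z")
  expect_equal(pz$F, Fm[, 1])
  pt <- project_1d(surf, "theta")
  expect_equal(pt$F, rep(min(Fm), 90))
  # masked column propagates
  Fm2 <- Fm; Fm2[3, ] <- NA
  surf$F <- Fm2
  expect_true(is.na(project_1d(surf, "z")$F[3]))
})

test_that("projection of a single-well surface peaks at the generating well", {
  fw <- fes_five_well()
  s <- sample_fes(fw$F, fw$z_edges, fw$theta_edges, 2e5, seed = 65)
  surf <- build_surface(s, fw$z_edges, fw$theta_edges)
  pz <- project_1d(surf, "z")
  expect_lt(abs(pz$z_nm[which.min(pz$F)] - 1.45), 0.1 + 1e-9)  # state A
  expect_equal(min(pz$F, na.rm = TRUE), 0)
})

test_that("minima detection labels the five canonical states within one bin", {
  fw <- fes_five_well()
  s <- sample_fes(fw$F, fw$z_edges, fw$theta_edges, 1e6, seed = 66)
  surf <- build_surface(s, fw$z_edges, fw$theta_edges)
  m <- find_minima(surf)
  expect_equal(nrow(m), 5)
  expect_equal(sort(m$label), c("A", "B", "C", "D", "E"))
  m <- m[order(m$label), ]
  truth <- fw$minima[order(fw$minima$label), ]
  expect_true(all(abs(m$z_nm - truth$z) <= 0.1 + 1e-9))
  expect_true(all(abs(m$theta_deg - truth$theta) <= 2 + 1e-9))
  expect_equal(m$F[m$label == "A"], 0)
})

test_that("flat and single-well surfaces give the expected minima sets", {
  # exactly flat surface: zero relief, no prominent minima
  grid <- expand.grid(z = seq(-0.95, 0.95, 0.1), theta = seq(5, 175, 10))
  surf <- build_surface(grid[rep(seq_len(nrow(grid)), 120), ],
                        seq(-1, 1, 0.1), seq(0, 180, 10))
  expect_equal(nrow(find_minima(surf)), 0)
  # single well in the cold leaflet: exactly one minimum labeled A
  s2 <- data.frame(z = rnorm(1e5, 1.45, 0.2),
                   theta = pmax(0, pmin(180, rnorm(1e5, 13, 5))))
  surf2 <- build_surface(s2, seq(-2.5, 2.5, 0.1), seq(0, 180, 2))
  m2 <- find_minima(surf2)
  expect_equal(m2$label[1], "A")
  expect_equal(nrow(m2), 1)
})

test_that("surfaces built from membrane trajectories see upright cholesterol", {
  mem <- gen_membrane_frames(n_pc_per_leaflet = 32, n_chol = 16,
                             n_frames = 30, seed = 68)
  coords <- cholesterol_order_coords(mem$frames, mem$topology)
  # schematic cholesterol is upright in both leaflets (half-normal tilt,
  # sd 10 degrees), hydroxyl at |z| = 1.7 nm
  expect_true(all(coords$theta < 50))
  expect_lt(mean(coords$theta), 20)
  expect_true(all(abs(abs(coords$z) - 1.7) < 0.4))
})
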