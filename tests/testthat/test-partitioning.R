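test_that("leaflet assignment follows the midplane and the hysteresis tie rule", {
  topo <- simple_chol_topology(n_chol = 3, n_po4 = 8)
  # midplane at z = 5; cold side up
  fr <- simple_chol_frame(z_roh = c(6, 4, 5))
  lab <- assign_leaflets(fr, topo, cold_side = +1)
  expect_equal(unname(lab), c("cold", "hot", "cold"))   # first frame tie -> cold
  # with a previous-frame label the tie keeps it
  prev <- c("1" = "cold", "2" = "hot", "3" = "hot")
  lab2 <- assign_leaflets(fr, topo, cold_side = +1, prev = prev)
  expect_equal(unname(lab2["3"]), "hot")
  # hot side up flips non-tied labels
  lab3 <- assign_leaflets(fr, topo, cold_side = -1)
  expect_equal(unname(lab3[1:2]), c("hot", "cold"))
})

test_that("a scripted trajectory with three planted crossings changes labels three times", {
  topo <- simple_chol_topology(n_chol = 1, n_po4 = 8)
  # molecule: cold, cold, hot, hot, cold, hot  => 3 changes
  zs <- c(6, 6, 4, 4, 6, 4)
  frames <- lapply(seq_along(zs), function(i)
    simple_chol_frame(zs[i], time = (i - 1) * 1000))
  fs <- fraction_series(frames, topo)
  changes <- sum(diff(fs$x_cold) != 0)
  expect_equal(changes, 3)
})

test_that("fraction series obey the complement identity and the symmetric start", {
  topo <- simple_chol_topology(n_chol = 4, n_po4 = 8)
  frames <- list(simple_chol_frame(c(6, 6, 4, 4), time = 0),
                 simple_chol_frame(c(6, 6, 6, 4), time = 1000),
                 simple_chol_frame(c(6, 6, 6, 6), time = 2000))
  fs <- fraction_series(frames, topo)
  expect_equal(fs$x_cold[1], 0.5)              # symmetric initial configuration
  expect_equal(fs$x_cold + fs$x_hot, rep(1, 3))
  expect_equal(fs$x_cold[3], 1)                # all cholesterol cold
  topo_nochol <- new_topology(rep("PO4", 4), rep("DPPC", 4), 1:4)
  expect_error(fraction_series(frames[1], topo_nochol), "cholesterol")
})

test_that("kinetic fit recovers noiseless parameters to 1e-6 relative", {
  s <- gen_kinetic_series(x0 = 0.5, xs = 0.56, tau = 16.1,
                          times = seq(0, 100, by = 0.1))
  f <- fit_kinetics(s)
  expect_lt(abs(f$tau / 16.1 - 1), 1e-6)
  expect_lt(abs(f$xs / 0.56 - 1), 1e-6)
  # two-state bookkeeping identities hold exactly
  expect_equal(f$k_ch + f$k_hc, 1 / f$tau, tolerance = 1e-12)
  expect_equal(f$k_hc / (f$k_ch + f$k_hc), f$xs, tolerance = 1e-12)
})

test_that("a constant series is flagged degenerate rather than fitted", {
  s <- new_fraction_series(seq(0, 50, by = 1), rep(0.5, 51))
  f <- fit_kinetics(s)
  expect_true(f$degenerate)
  expect_equal(f$xs, 0.5)
  expect_true(is.na(f$tau))
})

test_that("tau recovery under noise stays within 10% median relative error", {
  errs <- vapply(1:100, function(s) {
    ser <- gen_kinetic_series(0.5, 0.56, 16.1, times = seq(0, 100, length.out = 1000),
                              noise_sd = 0.01, seed = 700 + s)
    abs(fit_kinetics(ser)$tau / 16.1 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("steady asymmetry is the fitted plateau offset, antisymmetric by leaflet", {
  s <- gen_kinetic_series(0.5, 0.56, 16.1)
  f <- fit_kinetics(s)
  a <- steady_asymmetry(s, f)
  expect_equal(a$dx_cold, 0.06, tolerance = 1e-6)
  expect_equal(a$dx_hot, -a$dx_cold)
  expect_equal(steady_asymmetry(xs = 0.5, x0 = 0.5)$dx_cold, 0)
})

test_that("Soret arithmetic matches the hand oracle to 1e-12", {
  # x_o = 0.5/0.5, dx' = -0.0131, dT = 10 K -> S_T = 5.24e-3 1/K
  # counts engineered so x'_hot - x'_cold = -0.0131 exactly:
  # with N_PC = 100 per leaflet, x' = n/(n + 100)
  xp_cold <- 0.5 + 0.0131 / 2
  xp_hot <- 0.5 - 0.0131 / 2
  n_cold <- 100 * xp_cold / (1 - xp_cold)
  n_hot <- 100 * xp_hot / (1 - xp_hot)
  r <- soret_from_counts(c(hot = n_hot, cold = n_cold),
                         c(hot = 100, cold = 100), T_hot = 310, T_cold = 300)
  x_o_chol <- (n_hot + n_cold) / (n_hot + n_cold + 200)
  hand <- -(1 / (x_o_chol * (1 - x_o_chol))) * (-0.0131 / 10)
  expect_equal(r$S_T, hand, tolerance = 1e-12)
  expect_equal(r$dx_prime, -0.0131, tolerance = 1e-12)
  # with exactly balanced overall fractions the classic value appears
  expect_equal(-(1 / 0.25) * (-0.0131 / 10), 5.24e-3, tolerance = 1e-12)
})

test_that("Soret sign conventions: zero asymmetry and thermophobic enrichment", {
  r0 <- soret_from_counts(c(hot = 50, cold = 50), c(hot = 50, cold = 50), 320, 300)
  expect_equal(r0$S_T, 0)
  r1 <- soret_from_counts(c(hot = 40, cold = 60), c(hot = 50, cold = 50), 320, 300)
  expect_gt(r1$S_T, 0)   # cold enrichment with dT > 0 => thermophobic
  expect_error(soret_from_counts(c(hot = 1, cold = 1), c(hot = 1, cold = 1), 300, 300),
               "undefined")
})

test_that("trajectory-route Soret agrees with the counts route", {
  s <- gen_kinetic_series(0.5, 0.56, 10, times = seq(0, 200, by = 0.2),
                          n_chol_total = 64,
                          n_pc_leaflet = c(hot = 64, cold = 64))
  f <- fit_kinetics(s)
  r <- soret_coefficient(s, T_hot = 320, T_cold = 300, fit = f)
  direct <- soret_from_counts(c(hot = (1 - 0.56) * 64, cold = 0.56 * 64),
                              c(hot = 64, cold = 64), 320, 300)
  expect_equal(r$S_T, direct$S_T, tolerance = 5e-3)
  expect_equal(r$x_o_chol + r$x_o_pc, 1)
})

test_that("Langevin trajectory fractions match the simulator's own occupancy", {
  cfg <- langevin_config(n_steps = 5e4L, seed = 77, stride = 10L)
  r <- simulate_langevin_flipflop(cfg)
  # fraction of stored particle-steps above the boundary vs internal tally
  frac_stored <- mean(r$z > 0)
  expect_lt(abs(frac_stored - r$occupancy_hot), 0.02)
})
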