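test_that("uniform beads give a flat density profile within Poisson bounds", {
  set.seed(31)
  n <- 1e5; box <- c(5, 5, 10); n_bins <- 50
  fr <- new_frame(matrix(runif(3 * n) * rep(box, each = n), n, 3), box)
  prof <- density_profile(fr, seq_len(n), n_bins)
  expect_df <- n / n_bins
  sigma <- sqrt(expect_df)
  expect_true(all(abs(prof$counts - expect_df) < 4 * sigma))
  expect_equal(mean(prof$value), n / prod(box), tolerance = 1e-9)
})

test_that("a delta layer occupies exactly one bin", {
  n <- 100
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 10), rep(5.0, n))
  prof <- density_profile(new_frame(pos, c(10, 10, 10)), seq_len(n), 10)
  expect_equal(which(prof$counts > 0), 6L)   # bin [5, 6)
  expect_error(density_profile(new_frame(pos, c(10, 10, 10)), integer(0), 10),
               "empty")
})

test_that("density integrates back to the group size", {
  set.seed(32)
  frames <- lapply(1:4, function(i)
    new_frame(matrix(runif(300, 0, 8), 100, 3), c(8, 8, 8), time = i))
  prof <- density_profile(frames, 1:100, 20)
  dz <- 8 / 20
  total <- sum(prof$value * dz * 8 * 8)
  expect_equal(total, 100, tolerance = 1e-9)
})

test_that("two-Gaussian headgroup placement puts profile maxima at the planes", {
  set.seed(33)
  n <- 2e4
  z <- c(rnorm(n / 2, 3, 0.3), rnorm(n / 2, 7, 0.3))   # planes at 5 +/- 2
  pos <- cbind(runif(n, 0, 8), runif(n, 0, 8), z)
  prof <- density_profile(new_frame(pos, c(8, 8, 10)), seq_len(n), 100)
  pk <- membrane_window(prof)
  expect_lt(abs(pk[1] - 3), 0.1 + 1e-9)
  expect_lt(abs(pk[2] - 7), 0.1 + 1e-9)
})

test_that("zero velocities give zero temperature in every occupied bin", {
  n <- 1000
  pos <- matrix(runif(3 * n, 0, 10), n, 3)
  fr <- new_frame(pos, c(10, 10, 10), velocities = matrix(0, n, 3))
  topo <- new_topology(rep("W", n), rep("W", n), seq_len(n))
  prof <- temperature_profile(fr, topo, 10, subtract_streaming = FALSE)
  expect_true(all(prof$value[prof$counts > 0] == 0))
  fr2 <- new_frame(pos, c(10, 10, 10))
  expect_error(temperature_profile(fr2, topo, 10), "velocities")
})

test_that("temperature estimator is chi-square accurate at uniform 300 K", {
  spec <- slab_spec(T_cold = 300, T_hot = 300)
  mb <- gen_mb_frame(spec, 1e5, seed = 34)
  prof <- temperature_profile(mb$frame, mb$topology, n_bins = 20,
                              subtract_streaming = FALSE)
  se <- 300 * sqrt(2 / (3 * prof$counts))
  expect_true(all(abs(prof$value - 300) < 3 * se))
})

test_that("an imposed linear gradient is recovered within the fit CI", {
  spec <- slab_spec(T_knots = c(0, 20), T_values = c(300, 500))  # 10 K/nm
  mb <- gen_mb_frame(spec, 1e5, seed = 35)
  prof <- temperature_profile(mb$frame, mb$topology, n_bins = 20)
  g <- fit_gradient(prof)
  expect_true(g$ci[1] <= 10e9 && 10e9 <= g$ci[2])
  expect_lt(abs(g$gradT_nm - 10), 0.25)
})

test_that("streaming-velocity subtraction restores boost invariance", {
  spec <- slab_spec(T_cold = 300, T_hot = 300)
  mb <- gen_mb_frame(spec, 2e4, seed = 36)
  boosted <- mb$frame
  boosted$velocities <- boosted$velocities + matrix(rep(c(0.5, 0, 0), each = 2e4), 2e4, 3)
  p0 <- temperature_profile(mb$frame, mb$topology, 10, subtract_streaming = TRUE)
  p1 <- temperature_profile(boosted, mb$topology, 10, subtract_streaming = TRUE)
  expect_equal(p1$value, p0$value, tolerance = 1e-6)
  # without subtraction the boost inflates the estimate
  p2 <- temperature_profile(boosted, mb$topology, 10, subtract_streaming = FALSE)
  expect_gt(mean(p2$value), mean(p0$value) + 100)
})

test_that("center-of-mass drift detects constructed trends and none in static frames", {
  n <- 50
  topo <- new_topology(rep("C1", n), rep("DPPC", n), seq_len(n))
  pos <- matrix(runif(3 * n, 0, 8), n, 3)
  static <- lapply(0:9, function(i) new_frame(pos, c(8, 8, 8), time = i))
  expect_equal(com_drift(static, topo)$slope, 0)
  drifting <- lapply(0:9, function(i)
    new_frame(pos + matrix(rep(c(0, 0, 0.001 * i), each = n), n, 3),
              c(8, 8, 8), time = i))
  expect_equal(com_drift(drifting, topo)$slope, 0.001, tolerance = 1e-12)
})

test_that("drift CI covers zero for trendless jitter in most seeds", {
  n <- 20
  topo <- new_topology(rep("C1", n), rep("DPPC", n), seq_len(n))
  hits <- 0
  for (s in 1:100) {
    set.seed(400 + s)
    frames <- lapply(0:19, function(i)
      new_frame(matrix(c(runif(2 * n, 0, 8), rnorm(n, 4, 0.05)), n, 3),
                c(8, 8, 8), time = i))
    ci <- com_drift(frames, topo)$slope_ci
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
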