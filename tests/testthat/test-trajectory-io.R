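test_that("a hand-written coordinate file parses to the expected frame", {
  p <- write_gro3()
  out <- read_gro(p)
  expect_equal(nrow(out$frame$positions), 3)
  expect_equal(out$frame$box, c(10, 10, 10))
  expect_equal(out$frame$positions[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(out$frame$positions[3, ], c(7.25, 8.25, 9.25), ignore_attr = TRUE)
  expect_null(out$frame$velocities)
  expect_equal(out$topology$bead_names, c("PO4", "ROH", "W"))
  expect_equal(out$topology$residue_names, c("DPPC", "CHOL", "W"))
  expect_equal(out$topology$groups$ROH, 2L)
  expect_equal(out$topology$groups$PO4, 1L)
  expect_equal(out$topology$groups$water, 3L)
})

test_that("velocity columns are captured and round-trip bit-identically in values", {
  p <- write_gro3(velocities = TRUE)
  out <- read_gro(p)
  expect_equal(out$frame$velocities[2, ], c(-0.4, 0.5, -0.6), ignore_attr = TRUE)
  p2 <- tempfile(fileext = ".gro")
  write_gro(out$frame, out$topology, p2)
  out2 <- read_gro(p2)
  expect_identical(out2$frame$positions, out$frame$positions)
  expect_identical(unname(out2$frame$velocities), unname(out$frame$velocities))
  expect_identical(out2$frame$box, out$frame$box)
})

test_that("malformed coordinate files raise parse errors naming the problem", {
  lines <- gro3_text()
  lines[2] <- "    5"   # header count disagrees with records
  p <- tempfile(); writeLines(lines, p)
  expect_error(read_gro(p), "5 atoms")
  lines2 <- gro3_text()[1:5]   # box line missing
  p2 <- tempfile(); writeLines(lines2, p2)
  expect_error(read_gro(p2), "box")
  lines3 <- gro3_text()
  lines3[4] <- "garbage"
  p3 <- tempfile(); writeLines(lines3, p3)
  expect_error(read_gro(p3), "line 4")
  expect_error(read_gro(tempfile()), "no such file")
})

test_that("triclinic box lines are rejected as unsupported", {
  lines <- gro3_text()
  lines[6] <- "  10.0  10.0  10.0  0.0  0.0  5.0  0.0  0.0  0.0"
  p <- tempfile(); writeLines(lines, p)
  expect_error(read_gro(p), "triclinic")
})

test_that("write/read round-trip preserves positions to format precision", {
  set.seed(7)
  n <- 50
  topo <- new_topology(rep("C1", n), rep("DPPC", n), seq_len(n))
  pos <- matrix(runif(3 * n, 0, 10), n, 3)
  fr <- new_frame(pos, c(10, 10, 10), time = 3.5)
  p <- tempfile(fileext = ".gro")
  write_gro(fr, topo, p)
  back <- read_gro(p)$frame
  # equality to 3 decimals: the format's precision
  expect_true(all(abs(back$positions - round(pos, 3)) < 1e-9))
  expect_equal(back$time, 3.5)
})

test_that("multi-frame trajectories stream lazily and match eager collection", {
  set.seed(8)
  n <- 10
  topo <- new_topology(rep("C1", n), rep("DPPC", n), seq_len(n))
  frames <- lapply(0:99, function(i)
    new_frame(matrix(round(runif(3 * n, 0, 10), 3), n, 3), c(10, 10, 10),
              time = i))
  p <- tempfile(fileext = ".gro")
  write_gro(frames, topo, p)
  got <- collect_frames(read_trajectory(p, topo))
  expect_length(got, 100)
  expect_equal(vapply(got, `[[`, numeric(1), "time"), as.numeric(0:99))
  for (i in c(1, 50, 100))
    expect_equal(got[[i]]$positions, frames[[i]]$positions, ignore_attr = TRUE)
  # one-at-a-time streaming yields the same sequence
  st <- read_trajectory(p, topo)
  f1 <- st$next_frame()
  expect_equal(f1$positions, frames[[1]]$positions, ignore_attr = TRUE)
})

test_that("trajectory atom-count mismatch, truncation and empty files behave", {
  n <- 12
  topo12 <- new_topology(rep("C1", n), rep("DPPC", n), seq_len(n))
  topo10 <- new_topology(rep("C1", 10), rep("DPPC", 10), 1:10)
  fr <- new_frame(matrix(1, n, 3), c(10, 10, 10))
  p <- tempfile(); write_gro(list(fr, fr), topo12, p)
  st <- read_trajectory(p, topo10)
  expect_error(st$next_frame(), "12 beads")
  # truncated: drop the tail of the second frame
  lines <- readLines(p)
  writeLines(lines[1:(length(lines) - 5)], p)
  st2 <- read_trajectory(p, topo12)
  expect_s3_class(st2$next_frame(), "md_frame")
  expect_warning(res <- st2$next_frame(), "truncated")
  expect_null(res)
  # empty file: zero frames, no crash
  p3 <- tempfile(); writeLines(character(0), p3)
  expect_length(collect_frames(read_trajectory(p3, topo12)), 0)
})

test_that("ledger CSV round trip validates columns and monotone time", {
  led <- new_ledger(c(0, 1, 2), c(0, 5, 10), c(0, 5, 10), area = 36)
  p <- tempfile(fileext = ".csv")
  write_ledger(led, p)
  back <- read_ledger(p, area = 36)
  expect_equal(back$times, led$times)
  expect_equal(back$E_hot, led$E_hot)
  expect_error(new_ledger(c(0, 2, 1), 1:3, 1:3, 36), "increasing")
  df <- data.frame(time_ps = 0:2, E_hot_kJmol = 0:2)
  p2 <- tempfile(); write.csv(df, p2, row.names = FALSE)
  expect_error(read_ledger(p2, 36), "E_cold_kJmol")
})

test_that("ledger slope recovers the generating energy rate", {
  # rate 100 kJ/mol/ns = 0.1 kJ/mol/ps, recovered by least squares
  g <- gen_ledger(lambda_target = 0.1, gradT = -2e9, area = 36)
  rate_target <- 0.1 * 2e9 * 2 * 36 / (1e33 / 6.02214076e23)
  t <- g$ledger$times
  slope <- coef(lm(g$ledger$E_hot ~ t))[2]
  expect_equal(unname(slope), rate_target, tolerance = 1e-9)
})

test_that("scan tables validate direction and monotonicity", {
  s <- new_scan_table(280:285, rep(0.5, 6), "heating", 1L)
  expect_s3_class(s, "scan_table")
  expect_error(new_scan_table(1:3, 1:3, "up"), "heating")
  expect_error(new_scan_table(c(280, 284, 282), 1:3, "heating"), "monotone")
  p <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(s), p, row.names = FALSE)
  expect_equal(read_scan_table(p)$T_K, s$T_K)
})

test_that("frame and topology invariants are enforced", {
  expect_error(new_frame(matrix(1, 2, 3), c(10, 10, -1)), "box")
  expect_error(new_frame(matrix(c(1, 2, NA), 1, 3), c(10, 10, 10)),
               "finite")
  expect_error(new_frame(matrix(1, 2, 3), c(10, 10, 10),
                         velocities = matrix(1, 3, 3)), "shape")
  expect_error(new_topology("A", c("X", "Y"), 1), "equal length")
  expect_error(new_topology(c("A", "B"), c("X", "Y"), c(1, 2),
                            masses = c(-1, 1)), "positive")
  expect_error(new_topology(c("A", "B"), c("X", "Y"), c(1, 2),
                            groups = list(bad = 5L)), "outside")
})
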