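# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to a tempfile.

kB <- 0.0083144621

# A hand-written 3-bead coordinate file (fixed-width GRO layout): one DPPC
# phosphate, one cholesterol hydroxyl, one water bead, box 10x10x10 nm.
gro3_text <- function(velocities = FALSE) {
  recs <- if (velocities) c(
    "    1DPPC   PO4    1   1.000   2.000   3.000  0.1000 -0.2000  0.3000",
    "    2CHOL   ROH    2   4.500   5.500   6.500 -0.4000  0.5000 -0.6000",
    "    3W        W    3   7.250   8.250   9.250  0.7000 -0.8000  0.9000"
  ) else c(
    "    1DPPC   PO4    1   1.000   2.000   3.000",
    "    2CHOL   ROH    2   4.500   5.500   6.500",
    "    3W        W    3   7.250   8.250   9.250"
  )
  c("hand-built fixture t= 0.0", "    3", recs,
    "  10.00000  10.00000  10.00000")
}

write_gro3 <- function(path = tempfile(fileext = ".gro"), velocities = FALSE) {
  writeLines(gro3_text(velocities), path)
  path
}

# Minimal membrane topology: n_chol cholesterols (ROH + tail bead) and
# n_po4 bare phosphate beads, everything else omitted.
simple_chol_topology <- function(n_chol = 4, n_po4 = 8) {
  bead <- c(rep(c("ROH", "C2"), n_chol), rep("PO4", n_po4))
  res <- c(rep("CHOL", 2 * n_chol), rep("DPPC", n_po4))
  rid <- c(rep(seq_len(n_chol), each = 2), n_chol + seq_len(n_po4))
  new_topology(bead, res, rid)
}

# Frame for simple_chol_topology: cholesterol ROH at given z (tail 0.9 nm
# toward the midplane at zmid = 5), phosphates split half at zmid +/- 2.
simple_chol_frame <- function(z_roh, n_po4 = 8, box = c(8, 8, 10), time = 0) {
  n_chol <- length(z_roh)
  zmid <- box[3] / 2
  pos <- matrix(0, 2 * n_chol + n_po4, 3)
  for (j in seq_len(n_chol)) {
    s <- if (z_roh[j] >= zmid) 1 else -1
    pos[2 * j - 1, ] <- c(1 + j * 0.3, 1, z_roh[j])
    pos[2 * j, ] <- c(1 + j * 0.3, 1, z_roh[j] - s * 0.9)
  }
  zpo4 <- rep(c(zmid + 2, zmid - 2), length.out = n_po4)
  for (k in seq_len(n_po4))
    pos[2 * n_chol + k, ] <- c(0.5 * k, 6, zpo4[k])
  new_frame(pos, box, time = time)
}

# Chains of 2 beads sharing one bond vector; for order-parameter limits.
make_bond_frame <- function(bond_vec, n_chains = 50, box = c(10, 10, 10)) {
  n <- 2 * n_chains
  pos <- matrix(0, n, 3)
  set.seed(71)
  for (i in seq_len(n_chains)) {
    a <- runif(3, 2, 8)
    pos[2 * i - 1, ] <- a
    pos[2 * i, ] <- a + bond_vec
  }
  topo <- new_topology(rep(c("C1", "C2"), n_chains), rep("DPPC", n),
                       rep(seq_len(n_chains), each = 2),
                       chains = lapply(seq_len(n_chains),
                                       function(i) c(2 * i - 1, 2 * i)))
  list(frame = new_frame(pos, box), topo = topo)
}
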