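# Cholesterol position/orientation order parameters, 2-D probability
# surfaces P(z, theta), free-energy maps -ln(P/P_ref), 1-D projections and
# minima detection.
#
# Conventions: z is midplane-relative (z = 0 at the bilayer center). The
# tilt angle is measured against the outward normal of the leaflet holding
# the hydroxyl bead (from the midplane toward that leaflet's water), so the
# canonical upright orientation scores small theta in both leaflets and
# inverted configurations score near 180 degrees. No angular Jacobian is
# applied: the map is of raw populations. F is dimensionless (-ln P units,
# i.e. local kB*T).

#' Cholesterol tilt angle and midplane-relative hydroxyl position
#'
#' The molecular director is the unit vector from the terminal tail bead to
#' the hydroxyl (ROH) bead. `theta` is the angle between the director and
#' the outward normal of the leaflet containing the ROH bead; an ROH bead
#' exactly at the midplane uses the cold side's outward normal (tie rule).
#'
#' @param frame `md_frame`.
#' @param topology `md_topology`.
#' @param residue_id cholesterol residue id.
#' @param midplane bilayer midplane z, nm (default: mean of the `PO4`
#'   group).
#' @param cold_side `+1` if the cold leaflet is at larger z.
#' @param axis_mode `"leaflet"` (outward normal, default) or `"fixed"`
#'   (always the `+z` axis).
#' @return list: `theta` (degrees, in `[0, 180]`), `z` (nm, ROH relative to
#'   midplane).
#' @export
tilt_angle <- function(frame, topology, residue_id, midplane = NULL,
                       cold_side = +1, axis_mode = c("leaflet", "fixed")) {
  axis_mode <- match.arg(axis_mode)
  in_res <- which(topology$residue_ids == residue_id)
  roh <- in_res[topology$bead_names[in_res] == "ROH"]
  if (length(roh) != 1L) stop("residue must have exactly one ROH bead")
  tail_candidates <- setdiff(in_res, roh)
  if (!length(tail_candidates)) stop("residue has no tail bead")
  tail <- tail_candidates[length(tail_candidates)]   # terminal tail bead
  if (is.null(midplane)) {
    po4 <- topology$groups$PO4
    if (!length(po4)) stop("midplane not given and no PO4 group")
    midplane <- mean(frame$positions[po4, 3])
  }
  d <- frame$positions[roh, ] - frame$positions[tail, ]
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("zero-length director")
  d <- d / nd
  zrel <- frame$positions[roh, 3] - midplane
  normal_sign <- if (axis_mode == "fixed") 1
                 else if (zrel > 0) 1 else if (zrel < 0) -1 else cold_side
  ct <- max(-1, min(1, d[3] * normal_sign))
  list(theta = acos(ct) * 180 / pi, z = zrel)
}

#' (z, theta) order parameters for all cholesterols over a trajectory
#'
#' Vectorized collection of the inputs of [build_surface()]: for every
#' cholesterol in every frame, the midplane-relative ROH z and the tilt
#' angle (per-frame phosphate midplane, same convention as
#' [tilt_angle()]).
#'
#' @param frames frames or a `frame_stream`.
#' @param topology `md_topology`.
#' @param cold_side `+1` if the cold leaflet is at larger z.
#' @param axis_mode see [tilt_angle()].
#' @return data.frame with columns `z` (nm), `theta` (deg).
#' @export
cholesterol_order_coords <- function(frames, topology, cold_side = +1,
                                     axis_mode = "leaflet") {
  roh <- topology$groups$ROH
  if (!length(roh)) stop("no cholesterol in topology")
  chol_res <- topology$residue_ids[roh]
  tails <- vapply(chol_res, function(rid) {
    in_res <- which(topology$residue_ids == rid)
    in_res <- setdiff(in_res, in_res[topology$bead_names[in_res] == "ROH"])
    in_res[length(in_res)]
  }, integer(1))
  po4 <- topology$groups$PO4
  zs <- c(); ths <- c()
  .each_frame(frames, function(fr) {
    mid <- mean(fr$positions[po4, 3])
    d <- fr$positions[roh, , drop = FALSE] - fr$positions[tails, , drop = FALSE]
    nd <- sqrt(rowSums(d^2))
    zrel <- fr$positions[roh, 3] - mid
    sgn <- ifelse(zrel > 0, 1, ifelse(zrel < 0, -1, cold_side))
    if (axis_mode == "fixed") sgn <- 1
    ct <- pmax(-1, pmin(1, d[, 3] / nd * sgn))
    zs <<- c(zs, zrel); ths <<- c(ths, acos(ct) * 180 / pi)
  })
  data.frame(z = zs, theta = ths)
}

#' Build a free-energy surface from (z, theta) samples
#'
#' 2-D histogram on the given grid, normalized to a probability `P`
#' (`sum(P) = 1`); the free energy is `F = -ln(P / P_ref)` with
#' `P_ref = max(P)`, so the global minimum is exactly 0 and `F >= 0`.
#' Zero-count bins are masked (`NA` in `F`); the display ceiling `clip`
#' applies at export only, the raw `F` is retained.
#'
#' @param samples data.frame with columns `z`, `theta` (from
#'   [cholesterol_order_coords()] or [sample_fes()]).
#' @param z_edges,theta_edges bin edges; defaults 0.1 nm and 2 degree bins
#'   spanning the samples (resolving the ~13 vs ~20 degree upright-state
#'   split).
#' @param clip export ceiling in `-ln P` units.
#' @return list of class `fes_surface`: `z_edges`, `theta_edges`, `z_mid`,
#'   `theta_mid`, `counts`, `P`, `F`, `P_ref`, `clip`, `n_samples`.
#' @export
build_surface <- function(samples, z_edges = NULL, theta_edges = NULL,
                          clip = 10) {
  if (nrow(samples) < 1L) stop("no samples")
  if (is.null(z_edges)) {
    lo <- floor(min(samples$z) * 10) / 10
    hi <- ceiling(max(samples$z) * 10) / 10
    z_edges <- seq(lo, hi + 1e-9, by = 0.1)
  }
  if (is.null(theta_edges)) theta_edges <- seq(0, 180, by = 2)
  nz <- length(z_edges) - 1L; nt <- length(theta_edges) - 1L
  iz <- findInterval(samples$z, z_edges, rightmost.closed = TRUE)
  it <- findInterval(samples$theta, theta_edges, rightmost.closed = TRUE)
  keep <- iz >= 1L & iz <= nz & it >= 1L & it <= nt
  counts <- matrix(0, nz, nt)
  tab <- table(factor(iz[keep], levels = seq_len(nz)),
               factor(it[keep], levels = seq_len(nt)))
  counts[] <- as.numeric(tab)
  P <- counts / sum(counts)
  P_ref <- max(P)
  F <- -log(P / P_ref)
  F[counts == 0] <- NA_real_
  structure(list(z_edges = z_edges, theta_edges = theta_edges,
                 z_mid = (z_edges[-1] + z_edges[-(nz + 1)]) / 2,
                 theta_mid = (theta_edges[-1] + theta_edges[-(nt + 1)]) / 2,
                 counts = counts, P = P, F = F, P_ref = P_ref, clip = clip,
                 n_samples = sum(counts)),
            class = "fes_surface")
}

#' @export
print.fes_surface <- function(x, ...) {
  cat(sprintf("<fes_surface> %d x %d bins (z %.2f..%.2f nm, theta %.0f..%.0f deg), %d samples, %d masked bins\n",
              length(x$z_mid), length(x$theta_mid),
              min(x$z_edges), max(x$z_edges),
              min(x$theta_edges), max(x$theta_edges),
              x$n_samples, sum(is.na(x$F))))
  invisible(x)
}

#' Long-format export of a free-energy surface
#' @param surface `fes_surface`.
#' @param apply_clip clip `F` at the surface's display ceiling.
#' @return data.frame `z_nm, theta_deg, P, F, masked`.
#' @export
as_fes_df <- function(surface, apply_clip = TRUE) {
  F <- surface$F
  if (apply_clip) F <- pmin(F, surface$clip)
  data.frame(z_nm = rep(surface$z_mid, times = length(surface$theta_mid)),
             theta_deg = rep(surface$theta_mid, each = length(surface$z_mid)),
             P = as.numeric(surface$P), F = as.numeric(F),
             masked = as.numeric(is.na(surface$F)))
}

#' Project a surface to one axis by minimizing over the other
#'
#' For each bin of the kept axis, the minimum `F` over the unmasked bins of
#' the other axis: the lowest free-energy cost of the most favorable
#' configuration at that coordinate. Fully masked columns stay masked. The
#' global minimum of the projection is 0 (inherited from the surface).
#'
#' @param surface `fes_surface`.
#' @param axis `"z"` or `"theta"`.
#' @return data.frame with the kept coordinate and `F`.
#' @export
project_1d <- function(surface, axis = c("z", "theta")) {
  axis <- match.arg(axis)
  F <- surface$F
  minf <- function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  if (axis == "z")
    data.frame(z_nm = surface$z_mid, F = apply(F, 1, minf))
  else
    data.frame(theta_deg = surface$theta_mid, F = apply(F, 2, minf))
}

#' Locate and label free-energy minima
#'
#' Local minima are unmasked bins strictly lower than their unmasked
#' 8-neighborhood, filtered by topographic prominence (persistence: the
#' height one must climb from the minimum before reaching a deeper one)
#' `>= depth_threshold`. Labels follow the five canonical cholesterol
#' states: `A`/`B` = upright minima (theta < 45 deg) in the cold/hot
#' leaflet, `C` = midplane band (|z| < 0.5 nm), `D`/`E` = inverted minima
#' (theta > 135 deg) in the cold/hot leaflet; anything else (or a duplicate
#' label, keeping the deeper one) becomes `X1, X2, ...`.
#'
#' A minimum must sit in a bin with at least `min_counts` samples: the
#' statistical uncertainty of `-ln P` in a bin with `c` counts is about
#' `1/sqrt(c)`, so the default floor of 100 counts keeps that noise at or
#' below 0.1 and makes the default prominence threshold a five-sigma
#' requirement; sparser bins cannot support a credible minimum.
#'
#' @param surface `fes_surface` with at least 9 unmasked bins.
#' @param depth_threshold prominence threshold in `-ln P` units.
#' @param cold_side `+1` if positive z is the cold leaflet.
#' @param min_counts minimum bin occupancy for a minimum (ignored when the
#'   surface was built from an analytic `F`, i.e. counts are absent).
#' @return data.frame of class `state_minima`: `label`, `z_nm`,
#'   `theta_deg`, `F`, `prominence`, ordered by `F`. Zero rows when no
#'   minimum is prominent enough (not an error).
#' @export
find_minima <- function(surface, depth_threshold = 0.5, cold_side = +1,
                        min_counts = 100) {
  F <- surface$F
  nz <- nrow(F); nt <- ncol(F)
  ok <- which(!is.na(F))
  if (length(ok) < 9L) stop("surface has fewer than 9 unmasked bins")
  ord <- ok[order(F[ok])]
  comp <- integer(nz * nt)              # 0 = unprocessed
  comp_min_val <- c(); comp_min_bin <- c(); comp_prom <- c()
  find_root <- function(c0) {
    while (comp_parent[c0] != c0) c0 <- comp_parent[c0]
    c0
  }
  comp_parent <- integer(0)
  neighbors <- function(idx) {
    i <- ((idx - 1L) %% nz) + 1L
    j <- ((idx - 1L) %/% nz) + 1L
    ii <- pmax(1L, i - 1L):pmin(nz, i + 1L)
    jj <- pmax(1L, j - 1L):pmin(nt, j + 1L)
    g <- as.matrix(expand.grid(ii, jj))
    n <- (g[, 2] - 1L) * nz + g[, 1]
    n[n != idx]
  }
  for (idx in ord) {
    nb <- neighbors(idx)
    nbc <- unique(comp[nb][comp[nb] > 0L])
    nbc <- unique(vapply(nbc, find_root, integer(1)))
    if (!length(nbc)) {
      comp_parent <- c(comp_parent, length(comp_parent) + 1L)
      cid <- length(comp_parent)
      comp_min_val[cid] <- F[idx]; comp_min_bin[cid] <- idx
      comp_prom[cid] <- NA_real_
      comp[idx] <- cid
    } else if (length(nbc) == 1L) {
      comp[idx] <- nbc
    } else {
      keep <- nbc[which.min(comp_min_val[nbc])]
      for (cother in setdiff(nbc, keep)) {
        comp_prom[cother] <- F[idx] - comp_min_val[cother]
        comp_parent[cother] <- keep
      }
      comp[idx] <- keep
    }
  }
  roots <- which(comp_parent == seq_along(comp_parent))
  # the global basin never merges away; its prominence is the full relief
  comp_prom[roots] <- max(F[ok]) - comp_min_val[roots]
  cand <- which(!is.na(comp_prom) & comp_prom >= depth_threshold)
  if (!is.null(surface$counts) && any(surface$counts > 0))
    cand <- cand[surface$counts[comp_min_bin[cand]] >= min_counts]
  if (!length(cand))
    return(structure(data.frame(label = character(0), z_nm = numeric(0),
                                theta_deg = numeric(0), F = numeric(0),
                                prominence = numeric(0)),
                     class = c("state_minima", "data.frame")))
  bins <- comp_min_bin[cand]
  # enforce 8-neighborhood minimality (masked neighbors count as +Inf);
  # exact ties (a minimum spanning two equal bins) break lexicographically,
  # keeping the lower linear index as the representative
  strict <- vapply(bins, function(idx) {
    nb <- neighbors(idx)
    nbv <- F[nb]
    all(is.na(nbv) | nbv > F[idx] | (nbv == F[idx] & nb > idx))
  }, logical(1))
  cand <- cand[strict]; bins <- bins[strict]
  i <- ((bins - 1L) %% nz) + 1L
  j <- ((bins - 1L) %/% nz) + 1L
  df <- data.frame(z_nm = surface$z_mid[i], theta_deg = surface$theta_mid[j],
                   F = F[bins], prominence = comp_prom[cand])
  df <- df[order(df$F), , drop = FALSE]
  lab <- character(nrow(df))
  for (r in seq_len(nrow(df))) {
    zc <- df$z_nm[r] * cold_side
    th <- df$theta_deg[r]
    want <- if (th < 45) { if (zc > 0) "A" else "B" }
            else if (th > 135) { if (zc > 0) "D" else "E" }
            else if (abs(df$z_nm[r]) < 0.5) "C"
            else NA_character_
    if (!is.na(want) && !(want %in% lab)) lab[r] <- want else lab[r] <- NA
  }
  nx <- sum(is.na(lab))
  lab[is.na(lab)] <- paste0("X", seq_len(nx))
  df <- cbind(label = lab, df)
  rownames(df) <- NULL
  structure(df, class = c("state_minima", "data.frame"))
}

#' Analytic five-state reference surface
#'
#' A synthetic free-energy surface with the canonical five-minimum topology
#' of cholesterol in a saturated bilayer: upright states in each leaflet
#' (A cold, slightly tilted; B hot, more tilted), a midplane in-plane state
#' C, and two inverted states D/E. Used as ground truth for landscape
#' round-trip tests.
#'
#' @param z_edges,theta_edges grid edges (defaults: 0.1 nm over -2.5..2.5,
#'   2 deg over 0..180).
#' @param base plateau free energy far from any state, `-ln P` units.
#' @param cold_side `+1` if positive z is the cold leaflet.
#' @return list: `F` (matrix), `z_edges`, `theta_edges`, `minima`
#'   (data.frame of the generating states: label, z, theta, F).
#' @export
fes_five_well <- function(z_edges = seq(-2.5, 2.5, by = 0.1),
                          theta_edges = seq(0, 180, by = 2),
                          base = 8, cold_side = +1) {
  zm <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  tm <- (theta_edges[-1] + theta_edges[-length(theta_edges)]) / 2
  s <- cold_side
  # generating states sit exactly on bin centers of the default grid so
  # "within one bin" recovery is well defined (z centers at x.x5 nm, theta
  # centers at odd degrees)
  wells <- data.frame(
    label = c("A", "B", "C", "D", "E"),
    z = s * c(1.45, -1.45, 0.05, 0.65, -0.65),
    theta = c(13, 21, 91, 159, 159),
    F = c(0, 0.6, 2.2, 3.6, 4.2),
    sig_z = c(0.25, 0.25, 0.2, 0.18, 0.18),
    sig_t = c(8, 8, 12, 9, 9))
  Fm <- matrix(base, length(zm), length(tm))
  for (w in seq_len(nrow(wells))) {
    g <- outer(zm, tm, function(z, t)
      exp(-((z - wells$z[w])^2 / (2 * wells$sig_z[w]^2) +
              (t - wells$theta[w])^2 / (2 * wells$sig_t[w]^2))))
    Fm <- pmin(Fm, wells$F[w] + (base - wells$F[w]) * (1 - g))
  }
  list(F = Fm, z_edges = z_edges, theta_edges = theta_edges,
       minima = wells[, c("label", "z", "theta", "F")])
}
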