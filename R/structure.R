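# Equilibrium-side membrane structure metrics: acyl chain order parameter,
# area per PC molecule, lateral (2-D) radial distribution functions, and
# melting-temperature extraction from annealing hysteresis cycles.

#' Acyl chain order parameter
#'
#' `S = <(3 cos^2 beta - 1)/2>` over consecutive tail-bead bond vectors,
#' with `beta` the angle between the bond and the bilayer normal (+z),
#' averaged over bonds, chains and frames. Ranges from 1 (bonds along the
#' normal) through 0 (isotropic) to -0.5 (bonds in the membrane plane).
#' With `per_leaflet`, chains are split at the phosphate midplane by the z
#' of their first bead.
#'
#' @param frames frames or a `frame_stream`.
#' @param topology `md_topology` with `chains` defined.
#' @param per_leaflet also report per-leaflet values.
#' @return list of class `order_result`: `S_chain`, `per_bond` (mean per
#'   bond rank along the chain), `per_leaflet` (named upper/lower, or
#'   `NULL`), `n_frames`.
#' @export
chain_order <- function(frames, topology, per_leaflet = FALSE) {
  chains <- topology$chains
  if (is.null(chains) || !length(chains)) stop("topology has no chain bond lists")
  nb <- vapply(chains, length, integer(1)) - 1L
  if (any(nb < 1L)) stop("each chain needs at least one bond")
  max_rank <- max(nb)
  s_sum <- 0; s_n <- 0
  rank_sum <- numeric(max_rank); rank_n <- numeric(max_rank)
  up_sum <- 0; up_n <- 0; lo_sum <- 0; lo_n <- 0
  n_frames <- 0L
  po4 <- topology$groups$PO4
  .each_frame(frames, function(fr) {
    n_frames <<- n_frames + 1L
    mid <- if (length(po4)) mean(fr$positions[po4, 3]) else mean(fr$positions[, 3])
    for (ch in chains) {
      b <- fr$positions[ch[-1], , drop = FALSE] - fr$positions[ch[-length(ch)], , drop = FALSE]
      cb <- b[, 3] / sqrt(rowSums(b^2))
      p2 <- (3 * cb^2 - 1) / 2
      s_sum <<- s_sum + sum(p2); s_n <<- s_n + length(p2)
      rk <- seq_along(p2)
      rank_sum[rk] <<- rank_sum[rk] + p2
      rank_n[rk] <<- rank_n[rk] + 1
      if (per_leaflet) {
        if (fr$positions[ch[1], 3] >= mid) { up_sum <<- up_sum + sum(p2); up_n <<- up_n + length(p2) }
        else { lo_sum <<- lo_sum + sum(p2); lo_n <<- lo_n + length(p2) }
      }
    }
  })
  if (n_frames == 0L) stop("no frames")
  structure(list(
    S_chain = s_sum / s_n,
    per_bond = rank_sum / rank_n,
    per_leaflet = if (per_leaflet)
      c(upper = if (up_n) up_sum / up_n else NA_real_,
        lower = if (lo_n) lo_sum / lo_n else NA_real_) else NULL,
    n_frames = n_frames), class = "order_result")
}

#' Area per PC molecule
#'
#' `a_PC = Lx*Ly / N_PC,leaflet` per frame (cholesterol is not counted in
#' the denominator). Leaflet PC counts come from the phosphate z against
#' the midplane on the first frame; unequal counts give a warning and the
#' mean count is used.
#'
#' @param frames frames or a `frame_stream`.
#' @param topology `md_topology` with a `PO4` group.
#' @return list: `a_pc` (mean, nm^2), `a_pc_se`, `series` (per frame),
#'   `times` (ps), `n_pc_leaflet`.
#' @export
area_per_lipid <- function(frames, topology) {
  po4 <- topology$groups$PO4
  if (!length(po4)) stop("no phosphate beads: cannot count PC per leaflet")
  series <- c(); times <- c(); n_leaf <- NULL
  .each_frame(frames, function(fr) {
    if (is.null(n_leaf)) {
      z <- fr$positions[po4, 3]
      n_up <- sum(z >= mean(z)); n_lo <- length(z) - n_up
      if (n_up != n_lo)
        warning(sprintf("unequal leaflet PC counts (%d vs %d); using their mean", n_up, n_lo))
      n_leaf <<- (n_up + n_lo) / 2
    }
    series <<- c(series, fr$box[1] * fr$box[2] / n_leaf)
    times <<- c(times, fr$time)
  })
  if (!length(series)) stop("no frames")
  list(a_pc = mean(series),
       a_pc_se = if (length(series) > 1) stats::sd(series) / sqrt(length(series)) else 0,
       series = series, times = times, n_pc_leaflet = n_leaf)
}

#' Lateral (2-D) radial distribution function
#'
#' Pair distances in the membrane plane (x, y) with minimum-image wrapping,
#' normalized by the ideal-gas annulus expectation
#' `n_pairs * 2 pi r dr / A`. With `per_leaflet` (default) only pairs
#' within the same leaflet are counted, leaflets split by each bead's z
#' against the group midplane. Self-pairs are excluded when the two groups
#' are identical.
#'
#' @param frames frames or a `frame_stream`.
#' @param topology `md_topology`.
#' @param group_a,group_b integer bead index sets.
#' @param r_max maximum distance, nm (must be at most `min(Lx, Ly)/2`).
#' @param dr bin width, nm.
#' @param per_leaflet restrict pairs to the same leaflet.
#' @return data.frame: `r_nm` (bin centers), `g_r`, `counts`.
#' @export
rdf_2d <- function(frames, topology, group_a, group_b = group_a,
                   r_max = 2, dr = 0.05, per_leaflet = TRUE) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  n_bins <- as.integer(ceiling(r_max / dr))
  counts <- numeric(n_bins); expected <- numeric(n_bins)
  same <- identical(sort(group_a), sort(group_b))
  edges <- (0:n_bins) * dr
  ann <- pi * (edges[-1]^2 - edges[-(n_bins + 1)]^2)
  .each_frame(frames, function(fr) {
    if (r_max > min(fr$box[1], fr$box[2]) / 2)
      stop("r_max exceeds half the smallest lateral box length")
    A <- fr$box[1] * fr$box[2]
    pa <- fr$positions[group_a, , drop = FALSE]
    pb <- fr$positions[group_b, , drop = FALSE]
    la <- lb <- NULL
    if (per_leaflet) {
      allz <- c(pa[, 3], pb[, 3])
      mid <- mean(allz)
      la <- pa[, 3] >= mid; lb <- pb[, 3] >= mid
    }
    for (leaf in if (per_leaflet) c(TRUE, FALSE) else NA) {
      if (per_leaflet) {
        qa <- pa[la == leaf, 1:2, drop = FALSE]
        qb <- pb[lb == leaf, 1:2, drop = FALSE]
      } else { qa <- pa[, 1:2, drop = FALSE]; qb <- pb[, 1:2, drop = FALSE] }
      na <- nrow(qa); nbq <- nrow(qb)
      if (na == 0 || nbq == 0) next
      dx <- outer(qa[, 1], qb[, 1], "-"); dx <- dx - fr$box[1] * round(dx / fr$box[1])
      dy <- outer(qa[, 2], qb[, 2], "-"); dy <- dy - fr$box[2] * round(dy / fr$box[2])
      d <- sqrt(dx^2 + dy^2)
      if (same) d[cbind(seq_len(na), seq_len(na))] <- NA
      d <- d[!is.na(d) & d < r_max]
      i <- pmin.int(floor(d / dr) + 1L, n_bins)
      counts <<- counts + tabulate(i, nbins = n_bins)
      n_pairs <- if (same) na * (na - 1) else na * nbq
      expected <<- expected + n_pairs * ann / A
    }
  })
  if (all(expected == 0)) stop("no frames or no pairs")
  data.frame(r_nm = (edges[-1] + edges[-(n_bins + 1)]) / 2,
             g_r = ifelse(expected > 0, counts / expected, NA_real_),
             counts = counts)
}

#' Melting temperature from hysteresis cycles
#'
#' Per direction and replica, the transition temperature is where the
#' smoothed finite-difference derivative `|d value / dT|` peaks (moving
#' average over `smooth` temperature points, parabolic sub-grid refinement
#' of the peak), with a fallback to the temperature where the value crosses
#' the mid-level `(lo + hi)/2`. The melting temperature is the midpoint
#' `Tm = (Tm_heating + Tm_cooling)/2`, replicas averaged. The midpoint rule
#' is a documented estimator choice and is flagged in the result metadata.
#'
#' @param heating,cooling `scan_table`s (possibly multiple replicas each).
#' @param smooth moving-average width (temperature points, odd).
#' @param min_span minimum value range, as a multiple of the residual
#'   noise scale, below which "no transition" is declared.
#' @return list of class `hysteresis_result`: `Tm`, `Tm_heating`,
#'   `Tm_cooling`, `hysteresis` (K), `per_replica`, `method`. `Tm` is `NA`
#'   with `method = "no transition detected"` for flat scans.
#' @export
estimate_tm <- function(heating, cooling, smooth = 5L, min_span = 6) {
  one_dir <- function(tab) {
    out <- c()
    for (rep_df in split(tab, tab$replica)) {
      o <- order(rep_df$T_K)
      T <- rep_df$T_K[o]; v <- rep_df$value[o]
      n <- length(v)
      if (n < max(5L, smooth)) stop("scan too short")
      # smoothed value
      k <- smooth %/% 2L
      vs <- stats::filter(v, rep(1 / smooth, smooth), sides = 2)
      vs[is.na(vs)] <- v[is.na(vs)]
      # transition present? span must beat the local noise scale
      noise <- stats::sd(diff(v)) / sqrt(2)
      if (diff(range(vs)) < min_span * max(noise, 1e-12)) { out <- c(out, NA_real_); next }
      dv <- (vs[3:n] - vs[1:(n - 2)]) / (T[3:n] - T[1:(n - 2)])
      Ti <- T[2:(n - 1)]
      pk <- which.max(abs(dv))
      Tm <- Ti[pk]
      if (pk > 1 && pk < length(dv)) {
        # parabolic refinement on |dv|
        y1 <- abs(dv[pk - 1]); y2 <- abs(dv[pk]); y3 <- abs(dv[pk + 1])
        den <- y1 - 2 * y2 + y3
        if (den < 0) Tm <- Ti[pk] + 0.5 * (y1 - y3) / den * (Ti[pk + 1] - Ti[pk])
      }
      if (!is.finite(Tm)) {
        # fallback: mid-level crossing
        lo <- min(vs); hi <- max(vs)
        cross <- which(diff(sign(vs - (lo + hi) / 2)) != 0)[1]
        Tm <- if (is.na(cross)) NA_real_ else mean(T[cross + 0:1])
      }
      out <- c(out, Tm)
    }
    out
  }
  th <- one_dir(heating); tc <- one_dir(cooling)
  per <- data.frame(replica = seq_along(th), Tm_heating = th,
                    Tm_cooling = tc[seq_along(th)],
                    Tm = (th + tc[seq_along(th)]) / 2)
  if (all(is.na(per$Tm)))
    return(structure(list(Tm = NA_real_, Tm_heating = NA_real_,
                          Tm_cooling = NA_real_, hysteresis = NA_real_,
                          per_replica = per,
                          method = "no transition detected"),
                     class = "hysteresis_result"))
  structure(list(Tm = mean(per$Tm, na.rm = TRUE),
                 Tm_heating = mean(per$Tm_heating, na.rm = TRUE),
                 Tm_cooling = mean(per$Tm_cooling, na.rm = TRUE),
                 hysteresis = mean(per$Tm_heating - per$Tm_cooling, na.rm = TRUE),
                 per_replica = per,
                 method = "midpoint of heating/cooling derivative peaks"),
            class = "hysteresis_result")
}
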