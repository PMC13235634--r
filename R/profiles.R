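# Slab-binned profiles along the box normal z, and a center-of-mass drift QC.
# Binning is on the fractional coordinate z/Lz so constant-pressure box
# fluctuations do not smear bins; bins are half-open [low, high) and equal
# width in fraction.

#' Construct a binned z-profile
#'
#' @param bin_centers nm (midpoints of equal-width bins covering `[0, Lz)`).
#' @param values profile values (K or beads/nm^3); `NA` where masked.
#' @param counts beads per bin (summed over frames).
#' @param value_sd per-bin standard deviation (same units as `values`).
#' @param axis,group axis and group labels.
#' @return data.frame of class `binned_profile` with attributes `axis`,
#'   `group`.
#' @export
new_profile <- function(bin_centers, values, counts = NA_real_,
                        value_sd = NA_real_, axis = "z", group = "") {
  df <- data.frame(z_nm = as.numeric(bin_centers), value = as.numeric(values),
                   counts = as.numeric(counts), sd = as.numeric(value_sd))
  attr(df, "axis") <- axis
  attr(df, "group") <- group
  class(df) <- c("binned_profile", "data.frame")
  df
}

.bin_index <- function(z, Lz, n_bins) {
  f <- (z / Lz) %% 1            # wrap into the primary box
  i <- floor(f * n_bins) + 1L
  pmin.int(i, n_bins)           # guard f == 1 after rounding
}

#' Time-averaged bead density profile along z
#'
#' Counts per bin divided by the bin volume `Lx*Ly*dz`, averaged over frames
#' with the per-frame box (constant-pressure safe).
#'
#' @param frames `frame_stream`, list of frames, or one `md_frame`.
#' @param group integer bead indices to profile.
#' @param n_bins number of equal-width z bins (>= 2).
#' @return `binned_profile` with values in beads/nm^3.
#' @export
density_profile <- function(frames, group, n_bins = 100L) {
  if (!length(group)) stop("empty group")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  counts <- numeric(n_bins)
  dens <- numeric(n_bins)        # sum over frames of per-frame density
  n_frames <- 0L
  Lz_mean <- 0
  .each_frame(frames, function(fr) {
    z <- fr$positions[group, 3]
    i <- .bin_index(z, fr$box[3], n_bins)
    tab <- tabulate(i, nbins = n_bins)
    counts <<- counts + tab
    dens <<- dens + tab / (fr$box[1] * fr$box[2] * fr$box[3] / n_bins)
    n_frames <<- n_frames + 1L
    Lz_mean <<- Lz_mean + fr$box[3]
  })
  if (n_frames == 0L) stop("no frames")
  Lz_mean <- Lz_mean / n_frames
  centers <- (seq_len(n_bins) - 0.5) * Lz_mean / n_bins
  new_profile(centers, dens / n_frames, counts = counts, group = "density")
}

#' Kinetic temperature profile along z
#'
#' Per bin, `T = sum(m_i |v_i - u_bin|^2) / (3 N_bin kB)` where `u_bin` is
#' the bin's mass-weighted mean velocity (the local streaming velocity) if
#' `subtract_streaming` is on, else zero. Frames are pooled weighting each
#' bin by its per-frame occupancy; bins never occupied are masked (`NA`).
#'
#' @param frames frames with velocities.
#' @param topology `md_topology` providing masses.
#' @param n_bins number of z bins.
#' @param subtract_streaming subtract the per-bin streaming velocity
#'   (default `TRUE`; removes advective bias near the thermostats).
#' @param group optional bead subset (default all beads).
#' @return `binned_profile` with values in K and per-bin sd of the
#'   single-bead temperature estimate.
#' @export
temperature_profile <- function(frames, topology, n_bins = 100L,
                                subtract_streaming = TRUE, group = NULL) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (is.null(group)) group <- seq_len(topology$n_beads)
  m <- topology$masses[group]
  S1 <- numeric(n_bins)   # sum of m|v-u|^2 over beads and frames
  S2 <- numeric(n_bins)   # sum of (m|v-u|^2)^2 for a spread estimate
  N  <- numeric(n_bins)
  Lz_mean <- 0; n_frames <- 0L
  .each_frame(frames, function(fr) {
    if (is.null(fr$velocities)) stop("temperature profile requires velocities")
    z <- fr$positions[group, 3]
    v <- fr$velocities[group, , drop = FALSE]
    i <- .bin_index(z, fr$box[3], n_bins)
    if (subtract_streaming) {
      msum <- rowsum(m, i)
      for (k in 1:3) {
        u <- rowsum(m * v[, k], i) / msum
        v[, k] <- v[, k] - u[match(i, as.integer(rownames(msum)))]
      }
    }
    e <- m * rowSums(v * v)
    add_binned <- function(acc, x) {
      agg <- rowsum(x, i)
      acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] + agg
      acc
    }
    S1 <<- add_binned(S1, e)
    S2 <<- add_binned(S2, e^2)
    N  <<- N + tabulate(i, nbins = n_bins)
    Lz_mean <<- Lz_mean + fr$box[3]; n_frames <<- n_frames + 1L
  })
  if (n_frames == 0L) stop("no frames")
  Lz_mean <- Lz_mean / n_frames
  Tb <- ifelse(N > 0, S1 / (3 * N * .kB), NA_real_)
  # sd of the per-bead kinetic energy, mapped to temperature units
  e_var <- ifelse(N > 1, pmax(S2 / N - (S1 / N)^2, 0), NA_real_)
  Tsd <- sqrt(e_var) / (3 * .kB)
  centers <- (seq_len(n_bins) - 0.5) * Lz_mean / n_bins
  new_profile(centers, Tb, counts = N, value_sd = Tsd, group = "temperature")
}

#' Bilayer center-of-mass drift QC
#'
#' Mass-weighted z center of mass of a group per frame, with the linear
#' trend and its 95% confidence interval. Used to verify the bilayers do
#' not drift systematically during the nonequilibrium run.
#'
#' @param frames frames.
#' @param topology `md_topology` (masses).
#' @param group integer bead indices (default: all non-water beads).
#' @return list with `times` (ps), `z_com` (nm), `slope` (nm/ps),
#'   `slope_ci` (length-2), `fit` (the `lm`).
#' @export
com_drift <- function(frames, topology, group = NULL) {
  if (is.null(group)) {
    w <- topology$groups$water
    group <- setdiff(seq_len(topology$n_beads), w)
  }
  if (!length(group)) stop("empty group")
  m <- topology$masses[group]
  times <- c(); zc <- c()
  .each_frame(frames, function(fr) {
    times <<- c(times, fr$time)
    zc <<- c(zc, sum(m * fr$positions[group, 3]) / sum(m))
  })
  if (length(times) < 2L)
    return(list(times = times, z_com = zc, slope = 0, slope_ci = c(0, 0), fit = NULL))
  fit <- stats::lm(zc ~ times)
  ci <- tryCatch(suppressWarnings(stats::confint(fit)["times", ]),
                 error = function(e) c(NA, NA))
  if (stats::var(zc) == 0) ci <- c(0, 0)  # static frames: exact zero slope
  list(times = times, z_com = zc,
       slope = unname(stats::coef(fit)[2]), slope_ci = unname(ci), fit = fit)
}

#' Write a profile to CSV (`z_nm,value,counts,sd`)
#' @param profile `binned_profile`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("z_nm", "value", "counts", "sd")],
                   path, row.names = FALSE)
  invisible(path)
}
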