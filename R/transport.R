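# Steady-state heat transport: flux from thermostat ledgers, temperature
# gradient by regression of the bilayer temperature profile, Fourier-law
# conductivity and interfacial conductance.
#
# Sign convention: `gradT` is dT/dz across the analyzed membrane region
# (negative when temperature falls along +z) and `J_q` is the flux component
# along +z, so lambda = -J_q / gradT is positive whenever heat flows from
# hot to cold. A negative lambda indicates inconsistent inputs, not a result.

# kJ/mol/ps/nm^2 -> W/m^2 (see thermolip-package.R)
.jq_si <- function(rate_kJmol_ps, area_nm2, paths = 2L)
  rate_kJmol_ps / (paths * area_nm2) * .flux_si

#' Steady-state heat flux from a thermostat ledger
#'
#' The energy rate is the least-squares slope of the cumulative hot-thermostat
#' energy over the steady-state window, cross-checked against the cold
#' thermostat; if the two disagree by more than 5% a warning is emitted. The
#' mean of the two rates defines the flux. In the periodic two-bilayer
#' geometry heat leaves the hot slab both ways, hence the default factor
#' `paths = 2` in `J_q = (dE/dt) / (paths * A)`.
#'
#' @param ledger `thermostat_ledger`.
#' @param steady_window `c(t_lo, t_hi)` in ps; default discards the first
#'   1e5 ps (the approach to the stationary state) and keeps the rest.
#' @param paths number of heat paths from the hot slab (2 for the periodic
#'   two-bilayer slab, 1 for a single-path setup).
#' @return list: `J_q` (W/m^2, positive = flux along each path away from the
#'   hot slab), `J_q_se`, `rate` (kJ/mol/ps), `rate_hot`, `rate_cold`,
#'   `window`.
#' @export
heat_flux <- function(ledger, steady_window = NULL, paths = 2L) {
  if (is.null(steady_window))
    steady_window <- c(min(1e5, max(ledger$times) / 2), max(ledger$times))
  sel <- ledger$times >= steady_window[1] & ledger$times <= steady_window[2]
  if (sum(sel) < 10L) stop("steady-state window holds fewer than 10 ledger samples")
  t <- ledger$times[sel]
  slope <- function(E) {
    f <- stats::lm(E ~ t)
    # noiseless ledgers fit exactly; the SE is then 0, not unreliable
    c(unname(stats::coef(f)[2]), suppressWarnings(summary(f)$coefficients[2, 2]))
  }
  sh <- slope(ledger$E_hot[sel])
  sc <- slope(ledger$E_cold[sel])
  r_hot <- sh[1]; r_cold <- sc[1]
  if (r_hot != 0 || r_cold != 0) {
    rel <- abs(r_hot - r_cold) / max(abs(r_hot), abs(r_cold))
    if (rel > 0.05)
      warning(sprintf(
        "hot/cold thermostat rates disagree by %.1f%% (hot %.4g, cold %.4g kJ/mol/ps); using their mean",
        100 * rel, r_hot, r_cold))
  }
  rate <- (r_hot + r_cold) / 2
  rate_se <- sqrt(sh[2]^2 + sc[2]^2) / 2
  list(J_q = .jq_si(rate, ledger$area, paths),
       J_q_se = .jq_si(rate_se, ledger$area, paths),
       rate = rate, rate_hot = r_hot, rate_cold = r_cold,
       window = steady_window)
}

#' Fit the temperature gradient across a z-window
#'
#' Ordinary least squares of the binned temperature profile over the window
#' (the membrane region for Fourier's law).
#'
#' @param profile `binned_profile` of temperature (K vs nm).
#' @param window `c(z_lo, z_hi)` in nm; default the full unmasked range.
#' @return list: `gradT` (K/m), `gradT_nm` (K/nm), `se` (K/m), `ci` (K/m,
#'   95%), `n_bins`, `fit`.
#' @export
fit_gradient <- function(profile, window = NULL) {
  z <- profile$z_nm; v <- profile$value
  ok <- is.finite(v)
  if (is.null(window)) window <- range(z[ok])
  sel <- ok & z >= window[1] & z <= window[2]
  if (sum(sel) < 3L) stop("gradient fit needs at least 3 unmasked bins in the window")
  zz <- z[sel]; vv <- v[sel]
  fit <- stats::lm(vv ~ zz)
  slope_nm <- unname(stats::coef(fit)[2])
  se_nm <- suppressWarnings(summary(fit)$coefficients[2, 2])
  ci_nm <- if (stats::var(vv - stats::fitted(fit)) == 0) c(slope_nm, slope_nm)
           else suppressWarnings(unname(stats::confint(fit)["zz", ]))
  list(gradT = slope_nm * 1e9, gradT_nm = slope_nm,
       se = se_nm * 1e9, ci = ci_nm * 1e9, n_bins = sum(sel), fit = fit,
       window = window)
}

#' Bilayer thickness from phosphate positions
#'
#' Mean separation between the phosphate headgroup planes of the two
#' leaflets, time-averaged. Leaflets are split at the bilayer midplane (the
#' mean phosphate z).
#'
#' @param frames frames.
#' @param topology `md_topology` with a non-empty `PO4` group.
#' @param po4 optional explicit phosphate index set (default the `PO4`
#'   group restricted by `bilayer_range`).
#' @param bilayer_range optional `c(z_lo, z_hi)` in nm selecting one
#'   bilayer of a two-bilayer stack.
#' @return list: `delta` (nm), `delta_se` (nm, over frames), `per_frame`.
#' @export
bilayer_thickness <- function(frames, topology, po4 = NULL, bilayer_range = NULL) {
  if (is.null(po4)) po4 <- topology$groups$PO4
  if (!length(po4)) stop("no phosphate beads in topology")
  per_frame <- c()
  .each_frame(frames, function(fr) {
    z <- fr$positions[po4, 3]
    if (!is.null(bilayer_range)) z <- z[z >= bilayer_range[1] & z <= bilayer_range[2]]
    mid <- mean(z)
    up <- z[z >= mid]; lo <- z[z < mid]
    if (!length(up) || !length(lo)) stop("one leaflet has no phosphates")
    per_frame <<- c(per_frame, mean(up) - mean(lo))
  })
  if (!length(per_frame)) stop("no frames")
  list(delta = mean(per_frame),
       delta_se = if (length(per_frame) > 1) stats::sd(per_frame) / sqrt(length(per_frame)) else 0,
       per_frame = per_frame)
}

#' Thermal conductivity from Fourier's law
#'
#' `lambda = -J_q / gradT`, with first-order uncertainty propagation.
#'
#' @param J_q heat flux, W/m^2 (or the list from [heat_flux()]).
#' @param gradT temperature gradient dT/dz, K/m (or the list from
#'   [fit_gradient()]).
#' @param J_q_se,gradT_se optional standard errors (taken from the lists if
#'   given).
#' @return list: `lambda` (W/(K m)), `lambda_se`.
#' @export
conductivity <- function(J_q, gradT, J_q_se = 0, gradT_se = 0) {
  if (is.list(J_q)) { J_q_se <- J_q$J_q_se; J_q <- J_q$J_q }
  if (is.list(gradT)) { gradT_se <- gradT$se; gradT <- gradT$gradT }
  if (gradT == 0) stop("gradT is zero: conductivity undefined")
  lambda <- -J_q / gradT
  if (J_q != 0 && lambda < 0)
    warning("negative conductivity: flux and gradient have inconsistent signs")
  se <- abs(lambda) * sqrt((if (J_q != 0) (J_q_se / J_q)^2 else 0) + (gradT_se / gradT)^2)
  list(lambda = lambda, lambda_se = se)
}

#' Interfacial thermal conductance
#'
#' `G = lambda / delta` with the thickness converted to metres; reported in
#' MW/(K m^2).
#'
#' @param lambda W/(K m) (or the list from [conductivity()]).
#' @param delta bilayer thickness, nm (or the list from
#'   [bilayer_thickness()]).
#' @param lambda_se,delta_se optional standard errors.
#' @return list: `G` (MW/(K m^2)), `G_se`.
#' @export
conductance <- function(lambda, delta, lambda_se = 0, delta_se = 0) {
  if (is.list(lambda)) { lambda_se <- lambda$lambda_se; lambda <- lambda$lambda }
  if (is.list(delta)) { delta_se <- delta$delta_se; delta <- delta$delta }
  if (delta <= 0) stop("thickness must be positive")
  G <- lambda / (delta * 1e-9) / 1e6
  se <- abs(G) * sqrt((if (lambda != 0) (lambda_se / lambda)^2 else 0) + (delta_se / delta)^2)
  list(G = G, G_se = se)
}

#' Assemble a full transport result
#'
#' Convenience wrapper enforcing the identities `lambda = -J_q/gradT` and
#' `G = lambda/delta`.
#'
#' @param flux list from [heat_flux()].
#' @param grad list from [fit_gradient()].
#' @param thickness list from [bilayer_thickness()].
#' @return list of class `transport_result` with fields `J_q`, `gradT`,
#'   `lambda`, `delta`, `G`, their uncertainties, and the windows used.
#' @export
transport_result <- function(flux, grad, thickness) {
  lam <- conductivity(flux, grad)
  G <- conductance(lam, thickness)
  structure(list(J_q = flux$J_q, J_q_se = flux$J_q_se,
                 gradT = grad$gradT, gradT_se = grad$se,
                 lambda = lam$lambda, lambda_se = lam$lambda_se,
                 delta = thickness$delta, delta_se = thickness$delta_se,
                 G = G$G, G_se = G$G_se,
                 steady_window = flux$window, fit_window = grad$window),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(paste0("<transport_result>\n",
                     "  J_q    = %.4g +/- %.2g W/m^2\n",
                     "  gradT  = %.4g +/- %.2g K/m\n",
                     "  lambda = %.4g +/- %.2g W/(K m)\n",
                     "  delta  = %.4g +/- %.2g nm\n",
                     "  G      = %.4g +/- %.2g MW/(K m^2)\n"),
              x$J_q, x$J_q_se, x$gradT, x$gradT_se, x$lambda, x$lambda_se,
              x$delta, x$delta_se, x$G, x$G_se))
  invisible(x)
}

#' Membrane-region fit window from a phosphate density profile
#'
#' The Fourier-law gradient is fitted between the two phosphate headgroup
#' density maxima of the analyzed bilayer (the membrane region). This
#' auto-detects that window: the two highest local maxima of the profile,
#' returned in z order.
#'
#' @param po4_profile `binned_profile` of phosphate density.
#' @return `c(z_lo, z_hi)` in nm.
#' @export
membrane_window <- function(po4_profile) {
  v <- po4_profile$value; z <- po4_profile$z_nm
  v[!is.finite(v)] <- 0
  n <- length(v)
  if (n < 3L) stop("profile too short")
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  pk <- which(is_peak)
  if (length(pk) < 2L) stop("fewer than two phosphate density peaks found")
  top2 <- pk[order(v[pk], decreasing = TRUE)][1:2]
  sort(z[top2])
}
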