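# Leaflet assignment, cholesterol fraction time series, two-state kinetic
# relaxation fit, steady-state asymmetry and the Soret coefficient.

#' Construct a cholesterol fraction time series
#'
#' Per-leaflet cholesterol fraction `x_alpha(t) = N_CHOL,alpha(t)/N_CHOL,T`
#' with the complement identity `x_cold + x_hot = 1` at every time (the
#' midplane tie rule resolves every molecule to exactly one leaflet).
#' Phospholipids do not flip-flop on these time scales, so the per-leaflet
#' PC counts are constants carried alongside.
#'
#' @param times_ns times, ns.
#' @param x_cold cold-leaflet fraction.
#' @param n_chol_total total cholesterol count (may be `NA` for purely
#'   fractional series).
#' @param n_pc_leaflet named numeric `c(hot=, cold=)` PC counts.
#' @return data.frame of class `fraction_series` with columns `time_ns`,
#'   `x_cold`, `x_hot` and attributes `n_chol_total`, `n_pc_leaflet`.
#' @export
new_fraction_series <- function(times_ns, x_cold, n_chol_total = NA_real_,
                                n_pc_leaflet = c(hot = NA_real_, cold = NA_real_)) {
  if (any(x_cold < -0.5 | x_cold > 1.5, na.rm = TRUE))
    stop("fractions far outside [0, 1]; wrong column or units?")
  df <- data.frame(time_ns = as.numeric(times_ns),
                   x_cold = as.numeric(x_cold),
                   x_hot = 1 - as.numeric(x_cold))
  attr(df, "n_chol_total") <- n_chol_total
  attr(df, "n_pc_leaflet") <- n_pc_leaflet
  class(df) <- c("fraction_series", "data.frame")
  df
}

#' Assign cholesterol molecules to leaflets
#'
#' The bilayer midplane is the mean z of its phosphate beads (robust to the
#' cholesterol asymmetry being measured); each cholesterol is assigned by
#' its hydroxyl (ROH) bead z against the midplane. Hot/cold identity comes
#' from which side faces the hot thermostat slab. A molecule exactly at the
#' midplane keeps its previous label (hysteresis tie rule); on the first
#' frame it goes to the cold leaflet.
#'
#' @param frame `md_frame`.
#' @param topology `md_topology` with `ROH` and `PO4` groups.
#' @param cold_side `+1` if the cold leaflet is at larger z than the
#'   midplane, `-1` otherwise.
#' @param prev previous frame's labels (character vector, for the tie
#'   rule), or `NULL` for the first frame.
#' @param bilayer_range optional `c(z_lo, z_hi)` restricting to one bilayer
#'   of a stack; molecules farther than half the box from the midplane are
#'   an error (ambiguous membership).
#' @return character vector (`"hot"`/`"cold"`), one per cholesterol
#'   molecule, named by residue id.
#' @export
assign_leaflets <- function(frame, topology, cold_side = +1, prev = NULL,
                            bilayer_range = NULL) {
  roh <- topology$groups$ROH
  po4 <- topology$groups$PO4
  if (!length(roh) || !length(po4)) stop("ROH and PO4 groups must be non-empty")
  zpo4 <- frame$positions[po4, 3]
  zroh <- frame$positions[roh, 3]
  if (!is.null(bilayer_range)) {
    zpo4 <- zpo4[zpo4 >= bilayer_range[1] & zpo4 <= bilayer_range[2]]
    keep <- zroh >= bilayer_range[1] & zroh <= bilayer_range[2]
    roh <- roh[keep]; zroh <- zroh[keep]
  }
  z_mid <- mean(zpo4)
  if (any(abs(zroh - z_mid) > frame$box[3] / 2))
    stop("ambiguous bilayer membership: cholesterol farther than half a box from the midplane")
  d <- (zroh - z_mid) * cold_side
  lab <- ifelse(d > 0, "cold", ifelse(d < 0, "hot", NA))
  ids <- as.character(topology$residue_ids[roh])
  if (anyNA(lab)) {
    tie <- which(is.na(lab))
    if (!is.null(prev)) lab[tie] <- prev[ids[tie]]
    lab[is.na(lab)] <- "cold"   # first-frame tie rule
  }
  names(lab) <- ids
  lab
}

#' Cholesterol fraction time series from a trajectory
#'
#' Applies [assign_leaflets()] frame by frame (carrying labels for the
#' midplane tie rule) and forms `x_alpha(t) = N_alpha(t)/N_total`.
#'
#' @param frames frames or a `frame_stream`.
#' @param topology `md_topology`.
#' @param cold_side see [assign_leaflets()].
#' @param bilayer_range see [assign_leaflets()].
#' @return `fraction_series` (times converted to ns).
#' @export
fraction_series <- function(frames, topology, cold_side = +1,
                            bilayer_range = NULL) {
  if (!length(topology$groups$ROH)) stop("no cholesterol in topology")
  n_pc <- length(topology$groups$PO4)
  times <- c(); xc <- c()
  prev <- NULL
  n_tot <- NULL
  .each_frame(frames, function(fr) {
    lab <- assign_leaflets(fr, topology, cold_side, prev, bilayer_range)
    prev <<- lab
    if (is.null(n_tot)) n_tot <<- length(lab)
    times <<- c(times, fr$time)
    xc <<- c(xc, mean(lab == "cold"))
  })
  if (!length(times)) stop("no frames")
  new_fraction_series(times / 1000, xc, n_chol_total = n_tot,
                      n_pc_leaflet = c(hot = n_pc / 2, cold = n_pc / 2))
}

#' Fit the two-state kinetic relaxation model
#'
#' Nonlinear least squares of
#' `x(t) = x0 + (xs - x0) * (1 - exp(-t/tau))`
#' to a leaflet fraction series. By convention the initial fraction is fixed
#' at `x0 = 0.5` (symmetric start) and `(xs, tau)` are free; set
#' `fix_x0 = FALSE` to free all three. Initialization: `xs` from the mean of
#' the final 20% of the series, `tau` from the first time the series covers
#' `1 - 1/e` of the `x0 -> xs` span. The fitted `(xs, tau)` map onto the
#' microscopic exchange rates via `k_ch + k_hc = 1/tau` and detailed
#' balance `xs = k_hc / (k_ch + k_hc)` (for the cold leaflet: `k_hc` is the
#' hot-to-cold rate).
#'
#' @param series `fraction_series` (or data.frame with `time_ns` and the
#'   chosen leaflet column).
#' @param leaflet `"cold"` or `"hot"`.
#' @param x0 initial fraction (default 0.5).
#' @param fix_x0 keep `x0` fixed (default `TRUE`).
#' @return list of class `kinetic_fit`: `x0`, `xs`, `tau` (ns), `k` (1/ns),
#'   `k_ch`, `k_hc`, `cov`, `rss`, `n`, `degenerate` flag.
#' @export
fit_kinetics <- function(series, leaflet = c("cold", "hot"), x0 = 0.5,
                         fix_x0 = TRUE) {
  leaflet <- match.arg(leaflet)
  t <- series$time_ns
  x <- if (leaflet == "cold") series$x_cold else series$x_hot
  if (length(t) < 10L) stop("need at least 10 time points")
  xs0 <- mean(x[t >= stats::quantile(t, 0.8)])
  span <- xs0 - x0
  degenerate <- FALSE
  if (abs(span) < 1e-12 && stats::sd(x) < 1e-12) {
    # constant series: xs identified, tau is not
    return(structure(list(x0 = x0, xs = xs0, tau = NA_real_, k = NA_real_,
                          k_ch = NA_real_, k_hc = NA_real_, cov = NULL,
                          rss = 0, n = length(t), degenerate = TRUE),
                     class = "kinetic_fit"))
  }
  thresh <- x0 + (1 - exp(-1)) * span
  tau0 <- if (span > 0) t[which(x >= thresh)[1]] else t[which(x <= thresh)[1]]
  if (is.na(tau0) || tau0 <= 0) tau0 <- max(t) / 3
  df <- data.frame(t = t, x = x)
  fit <- tryCatch({
    if (fix_x0)
      minpack.lm::nlsLM(x ~ x0 + (xs - x0) * (1 - exp(-t / tau)), data = df,
                        start = list(xs = xs0, tau = tau0),
                        lower = c(-Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(x ~ a0 + (xs - a0) * (1 - exp(-t / tau)), data = df,
                        start = list(a0 = x0, xs = xs0, tau = tau0),
                        lower = c(-Inf, -Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e)
    stop(sprintf("kinetic fit did not converge (start: xs = %.4g, tau = %.4g ns): %s",
                 xs0, tau0, conditionMessage(e))))
  co <- stats::coef(fit)
  xs <- unname(co["xs"]); tau <- unname(co["tau"])
  if (!fix_x0) x0 <- unname(co["a0"])
  k <- 1 / tau
  # two-state decomposition for this leaflet's steady state
  k_in <- xs / tau        # rate into this leaflet (e.g. k_hc for cold)
  k_out <- (1 - xs) / tau
  structure(list(x0 = x0, xs = xs, tau = tau, k = k,
                 k_ch = if (leaflet == "cold") k_out else k_in,
                 k_hc = if (leaflet == "cold") k_in else k_out,
                 cov = stats::vcov(fit), rss = sum(stats::resid(fit)^2),
                 n = length(t), degenerate = degenerate),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> x0 = %.4g, xs = %.4g, tau = %.4g ns (k_ch = %.4g, k_hc = %.4g 1/ns)%s\n",
              x$x0, x$xs, x$tau, x$k_ch, x$k_hc,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Steady-state cholesterol asymmetry
#'
#' `dx = xs - x(0)` for the cold leaflet (the hot leaflet's value is its
#' exact negative, by the complement identity).
#'
#' @param series `fraction_series` (used for `x(0)` unless `x0` given).
#' @param fit `kinetic_fit` providing `xs`; alternatively pass `xs`.
#' @param xs,x0 optional explicit values.
#' @return list: `dx_cold`, `dx_hot`.
#' @export
steady_asymmetry <- function(series = NULL, fit = NULL, xs = NULL, x0 = NULL) {
  if (is.null(xs)) xs <- fit$xs
  if (is.null(x0)) x0 <- if (!is.null(fit)) fit$x0 else series$x_cold[1]
  dx <- xs - x0
  list(dx_cold = dx, dx_hot = -dx)
}

#' Soret coefficient of cholesterol partitioning
#'
#' Finite-difference Soret coefficient
#' `S_T = -(1 / (x_o_CHOL * x_o_PC)) * (dx_prime / dT)`
#' where `dx_prime = x'_CHOL,hot - x'_CHOL,cold` is the steady-state
#' difference of per-leaflet cholesterol mole fractions
#' `x'_alpha = N_CHOL,alpha / (N_CHOL,alpha + N_PC,alpha)`, `dT = T_hot -
#' T_cold` is the leaflet temperature difference, and `x_o` are the overall
#' mole fractions. Cold enrichment with `dT > 0` gives `S_T > 0`
#' (thermophobic solute).
#'
#' Steady-state counts are averaged over `t > 5 tau` from the kinetic fit
#' (or the final 20% of the series if no fit is supplied).
#'
#' @param series `fraction_series` carrying `n_chol_total` and
#'   `n_pc_leaflet` attributes.
#' @param T_hot,T_cold leaflet temperatures, K (by convention read off the
#'   fitted temperature profile at the leaflet phosphate-peak positions).
#' @param fit optional `kinetic_fit` fixing the steady-state window.
#' @return list of class `soret_result`: `S_T` (1/K), `S_T_se`, `x_o_chol`,
#'   `x_o_pc`, `dx_prime`, `dT`, `x_prime` (named hot/cold), window used.
#' @export
soret_coefficient <- function(series, T_hot, T_cold, fit = NULL) {
  if (T_hot == T_cold) stop("T_hot = T_cold: Soret coefficient undefined")
  n_tot <- attr(series, "n_chol_total")
  n_pc <- attr(series, "n_pc_leaflet")
  if (is.na(n_tot) || any(is.na(n_pc)))
    stop("series must carry cholesterol and PC counts for mole fractions")
  t <- series$time_ns
  t_lo <- if (!is.null(fit) && is.finite(fit$tau)) 5 * fit$tau
          else stats::quantile(t, 0.8)
  if (t_lo >= max(t)) {
    warning("series shorter than 5 relaxation times; using its final 20% as the steady state")
    t_lo <- stats::quantile(t, 0.8)
  }
  sel <- t >= t_lo
  if (!any(sel)) stop("steady-state window is empty")
  xc <- mean(series$x_cold[sel])
  n_cold <- xc * n_tot
  n_hot <- (1 - xc) * n_tot
  xp_cold <- n_cold / (n_cold + n_pc[["cold"]])
  xp_hot <- n_hot / (n_hot + n_pc[["hot"]])
  dxp <- xp_hot - xp_cold
  x_o_chol <- n_tot / (n_tot + sum(n_pc))
  x_o_pc <- 1 - x_o_chol
  dT <- T_hot - T_cold
  S_T <- -(1 / (x_o_chol * x_o_pc)) * (dxp / dT)
  # uncertainty from the scatter of x_cold over the steady window,
  # propagated through the mole-fraction map
  xc_se <- stats::sd(series$x_cold[sel]) / sqrt(sum(sel))
  eps <- 1e-6
  f <- function(x) {
    nc <- x * n_tot; nh <- (1 - x) * n_tot
    (nh / (nh + n_pc[["hot"]]) - nc / (nc + n_pc[["cold"]]))
  }
  dfdx <- (f(xc + eps) - f(xc - eps)) / (2 * eps)
  S_T_se <- abs(dfdx * xc_se / (x_o_chol * x_o_pc * dT))
  structure(list(S_T = S_T, S_T_se = S_T_se,
                 x_o_chol = x_o_chol, x_o_pc = x_o_pc,
                 dx_prime = dxp, dT = dT,
                 x_prime = c(hot = xp_hot, cold = xp_cold),
                 steady_from_ns = as.numeric(t_lo)),
            class = "soret_result")
}

#' Soret coefficient from explicit counts (arithmetic core)
#'
#' The bare finite-difference Soret formula on given steady-state leaflet
#' compositions; used directly by the trajectory route above.
#'
#' @param n_chol named `c(hot=, cold=)` steady cholesterol counts.
#' @param n_pc named `c(hot=, cold=)` PC counts.
#' @param T_hot,T_cold leaflet temperatures, K.
#' @return list: `S_T`, `x_o_chol`, `x_o_pc`, `dx_prime`, `dT`.
#' @export
soret_from_counts <- function(n_chol, n_pc, T_hot, T_cold) {
  if (T_hot == T_cold) stop("T_hot = T_cold: Soret coefficient undefined")
  xp <- n_chol / (n_chol + n_pc)
  dxp <- xp[["hot"]] - xp[["cold"]]
  x_o_chol <- sum(n_chol) / (sum(n_chol) + sum(n_pc))
  x_o_pc <- 1 - x_o_chol
  dT <- T_hot - T_cold
  list(S_T = -(1 / (x_o_chol * x_o_pc)) * (dxp / dT),
       x_o_chol = x_o_chol, x_o_pc = x_o_pc, dx_prime = dxp, dT = dT)
}
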