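# End-to-end orchestration: profiles -> transport -> partitioning ->
# landscape -> structure, per replica, then cross-replica aggregation.
# Deterministic given the config; every window and parameter actually used
# is recorded in the run manifest.

#' Validate a pipeline run configuration
#'
#' A config is a list (or YAML file) with:
#' \describe{
#'   \item{replicas}{list, one entry per replica, each with `coordinates`
#'     (GRO file), `trajectory` (multi-frame GRO), `ledger` (CSV),
#'     `area` (nm^2), optional `profile` (temperature-profile CSV with
#'     columns `z_nm,value,counts,sd`).}
#'   \item{T_cold, T_hot}{thermostat set points, K (defaults 300 / 350; the
#'     protocol uses cold 300 K and hot 325-425 K).}
#'   \item{cold_side}{+1 if the cold leaflet is the upper one.}
#'   \item{n_bins, steady_window, fit_window}{analysis windows; `NULL`
#'     means auto.}
#'   \item{seed}{explicit RNG seed (mandatory).}
#'   \item{out_dir}{optional output directory.}
#' }
#'
#' @param config list or path to a YAML file.
#' @return the validated config (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$replicas) || !length(config$replicas))
    stop("config needs at least one replica")
  if (is.null(config$seed)) stop("config must set an explicit seed")
  defaults <- list(T_cold = 300, T_hot = 350, cold_side = 1, n_bins = 50L,
                   steady_window = NULL, fit_window = NULL, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (i in seq_along(config$replicas)) {
    r <- config$replicas[[i]]
    for (f in c("coordinates", "trajectory", "ledger")) {
      if (is.null(r[[f]])) stop(sprintf("replica %d: missing '%s'", i, f))
      if (!file.exists(r[[f]]))
        stop(sprintf("replica %d: file not found: %s", i, r[[f]]))
    }
    if (!is.null(r$profile) && !file.exists(r$profile))
      stop(sprintf("replica %d: file not found: %s", i, r$profile))
    if (is.null(r$area)) stop(sprintf("replica %d: missing 'area'", i))
  }
  config
}

.read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("z_nm", "value") %in% names(df)))
    stop("profile CSV needs columns z_nm,value")
  new_profile(df$z_nm, df$value,
              counts = if ("counts" %in% names(df)) df$counts else NA,
              value_sd = if ("sd" %in% names(df)) df$sd else NA)
}

#' Run the full analysis pipeline
#'
#' Per replica: temperature profile (from the supplied profile CSV, or
#' computed from trajectory velocities), heat flux from the ledger,
#' gradient fit over the membrane window, thickness, conductivity and
#' conductance; cholesterol fraction series, kinetic fit, steady
#' asymmetry and Soret coefficient; (z, theta) landscape and minima; chain
#' order and area per lipid. Scalars are then aggregated across replicas
#' (mean and standard error of the mean, the replica convention of the
#' NEMD protocol).
#'
#' @param config see [validate_config()].
#' @return list of class `pipeline_report`: `replicas` (per-replica
#'   results), `summary` (aggregated scalars), `manifest` (parameters
#'   actually used). If `config$out_dir` is set, writes `report.json`,
#'   `summary.csv` and per-replica fraction-series CSVs there.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed)
  rep_results <- list()
  for (i in seq_along(config$replicas)) {
    r <- config$replicas[[i]]
    res <- tryCatch(
      .run_replica(r, config),
      error = function(e) stop(sprintf("replica %d failed in stage [%s]: %s",
                                       i, attr(e, "stage") %||% "unknown",
                                       conditionMessage(e)), call. = FALSE))
    rep_results[[i]] <- res
  }
  scalars <- lapply(rep_results, `[[`, "scalars")
  summary <- aggregate_replicas(scalars)
  manifest <- list(
    package = "thermolip",
    version = as.character(utils::packageVersion("thermolip")),
    seed = config$seed,
    T_cold = config$T_cold, T_hot = config$T_hot,
    cold_side = config$cold_side, n_bins = config$n_bins,
    steady_window = rep_results[[1]]$transport$steady_window,
    fit_window = rep_results[[1]]$transport$fit_window,
    n_replicas = length(rep_results),
    inputs = lapply(config$replicas, function(r)
      r[intersect(names(r), c("coordinates", "trajectory", "ledger", "profile"))])
  )
  report <- structure(list(replicas = rep_results, summary = summary,
                           manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    for (i in seq_along(rep_results))
      utils::write.csv(rep_results[[i]]$fractions,
                       file.path(config$out_dir, sprintf("fractions_rep%d.csv", i)),
                       row.names = FALSE)
    json <- list(summary = summary, manifest = manifest,
                 replicas = lapply(rep_results, `[[`, "scalars"))
    jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "stage") <- name
    stop(e)
  })
}

.run_replica <- function(r, config) {
  gro <- .stage("read", read_gro(r$coordinates))
  topo <- gro$topology
  frames <- .stage("read", collect_frames(read_trajectory(r$trajectory, topo)))
  ledger <- .stage("read", read_ledger(r$ledger, area = r$area))

  profile <- .stage("profiles",
    if (!is.null(r$profile)) .read_profile_csv(r$profile)
    else temperature_profile(frames, topo, n_bins = config$n_bins))
  dens_po4 <- .stage("profiles",
    density_profile(frames, topo$groups$PO4, n_bins = config$n_bins))
  drift <- .stage("profiles", com_drift(frames, topo))

  flux <- .stage("transport", heat_flux(ledger, config$steady_window))
  fit_window <- config$fit_window %||%
    tryCatch(membrane_window(dens_po4), error = function(e) NULL)
  grad <- .stage("transport", fit_gradient(profile, fit_window))
  thick <- .stage("transport", bilayer_thickness(frames, topo))
  tr <- .stage("transport", transport_result(flux, grad, thick))

  fs <- .stage("partitioning", fraction_series(frames, topo, config$cold_side))
  kf <- .stage("partitioning", fit_kinetics(fs))
  asym <- .stage("partitioning", steady_asymmetry(fs, kf))
  # leaflet temperatures: profile evaluated at the phosphate peak z of each
  # leaflet when the profile spans them, else the thermostat set points
  T_leaf <- .stage("partitioning", {
    w <- tryCatch(membrane_window(dens_po4), error = function(e) NULL)
    if (!is.null(w) && min(profile$z_nm) <= w[1] && max(profile$z_nm) >= w[2]) {
      Tv <- stats::approx(profile$z_nm, profile$value, xout = w)$y
      hot_at_low_z <- config$cold_side > 0
      if (hot_at_low_z) c(hot = Tv[1], cold = Tv[2]) else c(hot = Tv[2], cold = Tv[1])
    } else c(hot = config$T_hot, cold = config$T_cold)
  })
  soret <- .stage("partitioning",
    if (!is.na(T_leaf[["hot"]]) && T_leaf[["hot"]] != T_leaf[["cold"]])
      soret_coefficient(fs, T_leaf[["hot"]], T_leaf[["cold"]], kf)
    else soret_coefficient(fs, config$T_hot, config$T_cold, kf))

  coords <- .stage("landscape", cholesterol_order_coords(frames, topo, config$cold_side))
  surf <- .stage("landscape", build_surface(coords))
  minima <- .stage("landscape",
    if (sum(!is.na(surf$F)) >= 9) find_minima(surf, cold_side = config$cold_side)
    else NULL)

  ord <- .stage("structure",
    if (!is.null(topo$chains)) chain_order(frames, topo, per_leaflet = TRUE)
    else NULL)
  apl <- .stage("structure", area_per_lipid(frames, topo))

  scalars <- c(J_q = tr$J_q, gradT = tr$gradT, lambda = tr$lambda,
               delta = tr$delta, G = tr$G,
               tau_ns = kf$tau, xs = kf$xs, dx_cold = asym$dx_cold,
               S_T = soret$S_T,
               S_chain = if (!is.null(ord)) ord$S_chain else NA_real_,
               a_pc = apl$a_pc,
               com_drift_slope = drift$slope,
               n_minima = if (!is.null(minima)) nrow(minima) else NA_real_)
  list(transport = tr, kinetics = kf, asymmetry = asym, soret = soret,
       fractions = as.data.frame(fs), surface = surf, minima = minima,
       order = ord, area = apl, drift = drift, profile = profile,
       scalars = scalars)
}

#' Aggregate per-replica scalar metrics
#'
#' Mean and standard error of the mean (`sd/sqrt(n)`) per metric across
#' replicas; with a single replica the SEM is reported as `NA`
#' (unavailable), not zero.
#'
#' @param results list of named numeric vectors (one per replica).
#' @return data.frame: `metric`, `mean`, `sem`, `n`.
#' @export
aggregate_replicas <- function(results) {
  if (!length(results)) stop("no replica results")
  mat <- do.call(rbind, lapply(results, function(x) x[names(results[[1]])]))
  n <- nrow(mat)
  data.frame(
    metric = colnames(mat),
    mean = colMeans(mat, na.rm = TRUE),
    sem = if (n >= 2) apply(mat, 2, function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
          else rep(NA_real_, ncol(mat)),
    n = n, row.names = NULL)
}
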