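# Synthetic generators for every input the analysis consumes, with known
# ground truth. Each generator has a forward-analysis inverse elsewhere in
# the package; the round-trip identities are the core test surface.
#
# All generators are deterministic given (parameters, seed).

#' Specify a thermostatted slab geometry
#'
#' Defines the periodic two-bilayer NEMD geometry: an orthorhombic box, the
#' z positions of the bilayer midplanes, hot/cold thermostat slabs (hot at
#' the box center, cold at the edges, 0.2 nm thick by default) and an
#' imposed piecewise-linear temperature profile T(z), which defaults to a
#' tent between the thermostat set points (cold 300 K at the edges, hot at
#' the center).
#'
#' @param box length-3 box, nm.
#' @param bilayer_centers z of the bilayer midplanes, nm.
#' @param T_cold,T_hot thermostat set points, K (protocol range: cold 300 K,
#'   hot 325-425 K).
#' @param slab_thickness thermostat slab thickness, nm.
#' @param T_knots,T_values optional explicit piecewise-linear T(z) knots
#'   overriding the tent profile.
#' @return list of class `slab_spec`; `t_of_z(spec)` gives T(z) as a
#'   function.
#' @export
slab_spec <- function(box = c(6, 6, 20), bilayer_centers = c(5, 15),
                      T_cold = 300, T_hot = 350, slab_thickness = 0.2,
                      T_knots = NULL, T_values = NULL) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (is.null(T_knots)) {
    T_knots <- c(0, box[3] / 2, box[3])
    T_values <- c(T_cold, T_hot, T_cold)
  }
  if (any(T_values <= 0)) stop("imposed temperature must be positive everywhere")
  hot_slab <- box[3] / 2 + c(-0.5, 0.5) * slab_thickness
  for (bc in bilayer_centers)
    if (bc > hot_slab[1] - 1 && bc < hot_slab[2] + 1)
      warning("bilayer center close to the hot thermostat slab")
  structure(list(box = box, bilayer_centers = bilayer_centers,
                 T_cold = T_cold, T_hot = T_hot,
                 slab_thickness = slab_thickness,
                 T_knots = T_knots, T_values = T_values),
            class = "slab_spec")
}

#' Imposed temperature profile of a slab spec
#' @param spec `slab_spec`.
#' @return function of z (nm) returning K (piecewise linear, clamped at the
#'   ends).
#' @export
t_of_z <- function(spec) {
  knots <- spec$T_knots; vals <- spec$T_values
  function(z) stats::approx(knots, vals, xout = z, rule = 2)$y
}

#' Generate a Maxwell-Boltzmann frame under an imposed T(z)
#'
#' Beads are placed uniformly in the box; each velocity component is drawn
#' from the Maxwell-Boltzmann distribution at the bead's local temperature,
#' with per-component variance `kB T(z)/m` (in (nm/ps)^2 with masses in
#' amu). The stationary NEMD state is locally Maxwellian to leading order,
#' which is what this emulates; no cross-bin correlation is imposed.
#'
#' @param spec `slab_spec`.
#' @param n_beads number of beads.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param mass bead mass, amu (default 72, a 4-to-1 coarse-grained bead).
#' @return `list(frame, topology)`.
#' @export
gen_mb_frame <- function(spec, n_beads, seed, mass = 72) {
  if (n_beads < 1) stop("n_beads must be positive")
  Tz_f <- t_of_z(spec)
  if (any(Tz_f(seq(0, spec$box[3], length.out = 2001)) <= 0))
    stop("imposed temperature must be positive everywhere")
  set.seed(seed)
  pos <- cbind(runif(n_beads, 0, spec$box[1]),
               runif(n_beads, 0, spec$box[2]),
               runif(n_beads, 0, spec$box[3]))
  Tz <- Tz_f(pos[, 3])
  sdv <- sqrt(.kB * Tz / mass)
  vel <- cbind(rnorm(n_beads, 0, sdv), rnorm(n_beads, 0, sdv),
               rnorm(n_beads, 0, sdv))
  frame <- new_frame(pos, spec$box, vel, time = 0)
  topo <- new_topology(rep("W", n_beads), rep("W", n_beads), seq_len(n_beads),
                       masses = rep(mass, n_beads))
  list(frame = frame, topology = topo)
}

#' Generate a thermostat ledger with prescribed conductivity
#'
#' Inverse of the Fourier-law analysis: given a target conductivity and a
#' membrane temperature gradient, emits (a) a cumulative-energy ledger whose
#' steady-state flux is `J_q = lambda_target * |gradT|` under the factor-2
#' two-path periodic-geometry convention of [heat_flux()], and (b) a matching
#' linear temperature profile over the membrane window. Noiseless output is
#' exact, so `gen_ledger` then [heat_flux()] + [fit_gradient()] +
#' [conductivity()] is the identity on `lambda_target`.
#'
#' Noise model (the reference data give replica scatter but no noise model,
#' so it is fixed here once): energy increments get i.i.d. relative Gaussian
#' noise of sd `noise_sd`; profile bins get additive Gaussian noise of sd
#' `noise_sd * |temperature span across the window|`.
#'
#' @param lambda_target W/(K m), > 0.
#' @param gradT membrane temperature gradient dT/dz in K/m (negative:
#'   temperature falls along +z). Must be nonzero.
#' @param area lateral area Lx*Ly, nm^2.
#' @param duration ledger length, ps.
#' @param dt ledger sampling interval, ps.
#' @param noise_sd fractional noise level (0 = exact).
#' @param seed RNG seed.
#' @param T_mid membrane mid-temperature, K.
#' @param window membrane z-window `c(z_lo, z_hi)`, nm.
#' @param n_bins profile bins across the window.
#' @return list: `ledger` (`thermostat_ledger`), `profile`
#'   (`binned_profile`), `window`, `lambda_target`, `gradT`.
#' @export
gen_ledger <- function(lambda_target, gradT = -2e9, area = 36,
                       duration = 6e5, dt = 100, noise_sd = 0, seed = 1,
                       T_mid = 347, window = c(2, 6), n_bins = 51) {
  if (lambda_target <= 0) stop("lambda_target must be positive")
  if (gradT == 0) stop("gradT = 0: target flux undefined")
  set.seed(seed)
  J_q <- lambda_target * abs(gradT)                   # W/m^2
  rate <- J_q * 2 * area / .flux_si                   # kJ/mol/ps (both paths)
  times <- seq(0, duration, by = dt)
  n <- length(times) - 1L
  inc_hot <- rate * dt * (1 + if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n))
  inc_cold <- rate * dt * (1 + if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n))
  ledger <- new_ledger(times, c(0, cumsum(inc_hot)), c(0, cumsum(inc_cold)), area)
  dz <- diff(window) / n_bins
  centers <- window[1] + (seq_len(n_bins) - 0.5) * dz
  slope_nm <- gradT / 1e9
  Tv <- T_mid + slope_nm * (centers - mean(window))
  if (noise_sd > 0)
    Tv <- Tv + rnorm(n_bins, 0, noise_sd * abs(slope_nm) * diff(window))
  prof <- new_profile(centers, Tv, counts = 1, group = "temperature")
  list(ledger = ledger, profile = prof, window = window,
       lambda_target = lambda_target, gradT = gradT)
}

#' Generate an exponential leaflet-relaxation time series
#'
#' The two-state kinetic model of cholesterol interleaflet exchange:
#' `x_cold(t) = x0 + (xs - x0) * (1 - exp(-t/tau))`, plus optional i.i.d.
#' Gaussian noise; `x_hot = 1 - x_cold`.
#'
#' @param x0 initial cold-leaflet fraction (0.5 for a symmetric start).
#' @param xs steady-state cold-leaflet fraction.
#' @param tau relaxation time, ns.
#' @param times sample times, ns.
#' @param noise_sd additive noise sd on the fraction (0 = exact).
#' @param seed RNG seed.
#' @param n_chol_total,n_pc_leaflet bookkeeping counts carried into the
#'   series (used by the Soret analysis).
#' @return `fraction_series`.
#' @export
gen_kinetic_series <- function(x0 = 0.5, xs = 0.56, tau = 16.1,
                               times = seq(0, 100, by = 0.1),
                               noise_sd = 0, seed = 1,
                               n_chol_total = NA_real_,
                               n_pc_leaflet = c(hot = NA_real_, cold = NA_real_)) {
  if (x0 < 0 || x0 > 1 || xs < 0 || xs > 1) stop("fractions must lie in [0, 1]")
  if (tau <= 0) stop("tau must be positive")
  x <- x0 + (xs - x0) * (1 - exp(-times / tau))
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(times), 0, noise_sd)
  }
  new_fraction_series(times, x, n_chol_total = n_chol_total,
                      n_pc_leaflet = n_pc_leaflet)
}

#' Draw (z, theta) samples from a tabulated free-energy surface
#'
#' Samples bins with probability proportional to `exp(-F)` (dimensionless
#' F, units of kB*T) or `exp(-F/(kB*T))` when `temperature` is given, then
#' jitters uniformly within the bin. No angular Jacobian is applied: the
#' samples target the binned histogram density exactly as
#' [build_surface()] bins it, so the round trip is the identity.
#'
#' @param F matrix `nz x ntheta` of free energies on the grid (finite or
#'   `Inf` for excluded bins).
#' @param z_edges,theta_edges bin edges (length `nz+1`, `ntheta+1`).
#' @param n number of samples.
#' @param seed RNG seed.
#' @param temperature optional K, with `F` in kJ/mol.
#' @return data.frame with columns `z`, `theta`.
#' @export
sample_fes <- function(F, z_edges, theta_edges, n, seed, temperature = NULL) {
  F <- as.matrix(F)
  nz <- length(z_edges) - 1L; nt <- length(theta_edges) - 1L
  if (!all(dim(F) == c(nz, nt))) stop("F must be (length(z_edges)-1) x (length(theta_edges)-1)")
  beta_F <- if (is.null(temperature)) F else F / (.kB * temperature)
  w <- exp(-beta_F)
  w[!is.finite(w)] <- 0
  if (sum(w) == 0) stop("free-energy surface is infinite everywhere")
  set.seed(seed)
  idx <- sample.int(nz * nt, n, replace = TRUE, prob = as.numeric(w))
  iz <- ((idx - 1L) %% nz) + 1L
  it <- ((idx - 1L) %/% nz) + 1L
  data.frame(
    z = z_edges[iz] + runif(n) * (z_edges[iz + 1L] - z_edges[iz]),
    theta = theta_edges[it] + runif(n) * (theta_edges[it + 1L] - theta_edges[it])
  )
}

#' Generate a hysteretic melting scan pair
#'
#' Sigmoidal area-per-lipid annealing curves,
#' `value(T) = lo + (hi-lo)/(1 + exp(-(T - Tm_dir)/width))`, with the
#' heating transition at `Tm_heat` and the cooling one at `Tm_cool`
#' (`Tm_cool <= Tm_heat`: a first-order transition shows hysteresis).
#' Defaults emulate a saturated-PC annealing study: gel-phase area 0.478
#' nm^2, fluid 0.634 nm^2, scans over 280-340 K.
#'
#' @param Tm_heat,Tm_cool transition midpoints, K.
#' @param width sigmoid width, K.
#' @param lo,hi low/high-temperature plateau values, nm^2.
#' @param T_range scan range, K.
#' @param step temperature step, K.
#' @param noise additive value noise sd (absolute; 0 = exact).
#' @param seed RNG seed.
#' @param replica replica id recorded in the tables.
#' @return list: `heating`, `cooling` (both `scan_table`).
#' @export
gen_hysteresis_scan <- function(Tm_heat = 310, Tm_cool = 303, width = 2,
                                lo = 0.478, hi = 0.634,
                                T_range = c(280, 340), step = 0.5,
                                noise = 0, seed = 1, replica = 1L) {
  if (Tm_cool > Tm_heat) stop("Tm_cool must not exceed Tm_heat (hysteresis)")
  set.seed(seed)
  Th <- seq(T_range[1], T_range[2], by = step)
  Tc <- rev(Th)
  sig <- function(T, Tm) lo + (hi - lo) / (1 + exp(-(T - Tm) / width))
  vh <- sig(Th, Tm_heat); vc <- sig(Tc, Tm_cool)
  if (noise > 0) {
    vh <- vh + rnorm(length(vh), 0, noise)
    vc <- vc + rnorm(length(vc), 0, noise)
  }
  list(heating = new_scan_table(Th, vh, "heating", replica),
       cooling = new_scan_table(Tc, vc, "cooling", replica))
}

# ---- Langevin thermophoresis simulator -------------------------------------

#' Configure the overdamped Langevin flip-flop simulator
#'
#' A desk-scale stand-in for cholesterol translocation under a thermal
#' gradient: particles move in a 1-D potential `F(z)` (kJ/mol) under
#' position-dependent temperature `T(z)` by the Ito Euler-Maruyama update
#' `z <- z - F'(z)/gamma dt + sqrt(2 kB T(z) dt / gamma) xi`. The tilt angle
#' is evolved as an independent Ornstein-Uhlenbeck angle around a
#' leaflet-dependent mean; only the z dynamics carry the thermophoresis
#' physics.
#'
#' @param F function of z returning kJ/mol (default: symmetric double well
#'   `barrier * ((z/z_well)^2 - 1)^2` with `z_well = 1` nm).
#' @param T_z function of z returning K, or a single temperature.
#' @param gamma friction, kJ/mol ps/nm^2 (diffusivity `D = kB T / gamma`).
#' @param n_particles particles simulated in parallel.
#' @param dt timestep, ps.
#' @param n_steps steps.
#' @param seed RNG seed (mandatory).
#' @param z_star leaflet boundary, nm (occupancy is measured against it).
#' @param z_range simulation domain; leaving it is treated as divergence.
#' @param z_init initial positions (default alternating wells at +/-1 nm).
#' @param z_commit commitment threshold for counting well-to-well crossings
#'   (a crossing is a change of committed side, with hysteresis, so
#'   diffusive jitter at the barrier top is not counted).
#' @param theta_mean_up,theta_mean_down,theta_tau,theta_sd OU parameters of
#'   the decorative tilt coordinate (degrees, ps).
#' @param stride store every `stride`-th step in the returned trajectory
#'   (occupancies and crossings always use every step).
#' @param barrier,z_well parameters of the default double well, kJ/mol and
#'   nm.
#' @return list of class `langevin_config`.
#' @export
langevin_config <- function(F = NULL, T_z = 300, gamma = 5,
                            n_particles = 32L, dt = 0.005, n_steps = 1e5L,
                            seed = 1L, z_star = 0, z_range = c(-2.5, 2.5),
                            z_init = NULL, z_commit = 0.5,
                            theta_mean_up = 15, theta_mean_down = 165,
                            theta_tau = 5, theta_sd = 10,
                            stride = NULL, barrier = 2.5 * 0.0083144621 * 300,
                            z_well = 1) {
  if (is.null(F)) {
    force(barrier); force(z_well)
    F <- function(z) barrier * ((z / z_well)^2 - 1)^2
  }
  if (!is.function(T_z)) { T0 <- T_z; T_z <- function(z) rep(T0, length(z)) }
  if (is.null(z_init)) {
    z_init <- rep(c(-z_well, z_well), length.out = n_particles)
  }
  if (is.null(stride)) stride <- max(1L, as.integer(n_steps %/% 2000L))
  cfg <- list(F = F, T_z = T_z, gamma = gamma,
              n_particles = as.integer(n_particles), dt = dt,
              n_steps = as.integer(n_steps), seed = as.integer(seed),
              z_star = z_star, z_range = z_range, z_init = z_init,
              z_commit = z_commit,
              theta_mean_up = theta_mean_up, theta_mean_down = theta_mean_down,
              theta_tau = theta_tau, theta_sd = theta_sd,
              stride = as.integer(stride))
  class(cfg) <- "langevin_config"
  cfg
}

#' Run the Langevin thermophoresis simulator
#'
#' See [langevin_config()]. Before running, a stability check requires the
#' largest drift step `dt * max|F'|/gamma` to be small against the domain
#' (< 5% of the z range) and `dt * max|F''|/gamma < 0.5`, both evaluated
#' over the thermally accessible region (`F` within 15 kB*T of its minimum;
#' the hard domain walls are excursions the dynamics cannot reach, and a
#' divergence there is still a runtime error). Failing either check is an
#' error, not a warning, because an unstable integrator silently biases
#' occupancies.
#'
#' @param cfg `langevin_config`.
#' @return list: `times` (ps, thinned by `stride`), `z`, `theta` (matrices
#'   `n_stored x n_particles`), `crossings` (data.frame step/particle/
#'   direction), `occupancy_hot` (pooled fraction of particle-steps with
#'   `z > z_star`), `occupancy_by_particle`, `dt`, `n_steps`.
#' @export
simulate_langevin_flipflop <- function(cfg) {
  stopifnot(inherits(cfg, "langevin_config"))
  ngrid <- 4001L
  zg <- seq(cfg$z_range[1], cfg$z_range[2], length.out = ngrid)
  Fg <- cfg$F(zg)
  if (any(!is.finite(Fg))) stop("F(z) must be finite on the simulation domain")
  Tg <- cfg$T_z(zg)
  if (any(Tg <= 0)) stop("T(z) must be positive")
  h <- zg[2] - zg[1]
  dF <- c(diff(Fg)[1], (Fg[-(1:2)] - Fg[1:(ngrid - 2)]) / (2 * h), diff(Fg)[ngrid - 1] / h)
  dF[1] <- (Fg[2] - Fg[1]) / h
  kT_max <- .kB * max(Tg)
  acc <- Fg <= min(Fg) + 15 * kT_max    # thermally accessible region
  drift_max <- cfg$dt * max(abs(dF[acc])) / cfg$gamma
  if (drift_max > 0.05 * diff(cfg$z_range))
    stop(sprintf("unstable timestep: drift step %.3g nm vs domain %.3g nm", drift_max, diff(cfg$z_range)))
  d2F <- max(abs(diff(dF[acc]) / h))
  if (cfg$dt * d2F / cfg$gamma > 0.5)
    stop(sprintf("unstable timestep: dt*max|F''|/gamma = %.3g > 0.5", cfg$dt * d2F / cfg$gamma))
  set.seed(cfg$seed)
  res <- langevin_step_cpp(cfg$z_init,
                           rep(c(cfg$theta_mean_down, cfg$theta_mean_up),
                               length.out = cfg$n_particles),
                           zg, dF, Tg, cfg$gamma, cfg$dt, cfg$n_steps,
                           .kB, cfg$z_star, cfg$z_range[1], cfg$z_range[2],
                           cfg$z_commit,
                           cfg$theta_tau, cfg$theta_sd,
                           cfg$theta_mean_up, cfg$theta_mean_down,
                           cfg$stride)
  res$times <- res$stored_steps * cfg$dt
  res$dt <- cfg$dt
  res$n_steps <- cfg$n_steps
  res$crossings <- data.frame(step = res$crossing_step,
                              particle = res$crossing_particle,
                              direction = res$crossing_direction)
  res$crossing_step <- res$crossing_particle <- res$crossing_direction <- NULL
  res
}

# ---- synthetic membrane frames ---------------------------------------------

#' Generate synthetic membrane trajectory frames
#'
#' Builds a schematic single bilayer in a box: phosphatidylcholine residues
#' (one PO4 headgroup bead plus a 4-bead acyl chain pointing toward the
#' midplane) in both leaflets, cholesterol residues (ROH headgroup bead plus
#' a tail bead), and a time-dependent cholesterol leaflet occupancy given by
#' `x_cold_of_t`. Geometry is idealized (beads jittered around leaflet
#' planes); this emulates the bookkeeping structure of a membrane
#' trajectory, not its energetics.
#'
#' @param n_pc_per_leaflet PC molecules per leaflet.
#' @param n_chol cholesterol molecules in the bilayer (split per
#'   `x_cold_of_t`).
#' @param box box, nm; bilayer midplane at `box[3]/2`.
#' @param thickness PO4 plane separation, nm.
#' @param cold_side `+1` if the cold leaflet is the upper one (larger z).
#' @param x_cold_of_t function of time (ps) giving the cold-leaflet
#'   cholesterol fraction (default constant 0.5).
#' @param x_noise_sd per-frame Gaussian jitter on the occupancy fraction
#'   (replica-to-replica scatter; 0 gives the schedule exactly).
#' @param n_frames,dt_ps frames and spacing.
#' @param jitter_sd z jitter of headgroup beads, nm.
#' @param chain_tilt_sd_deg half-normal tilt of each acyl chain off the
#'   normal (liquid-ordered-like disorder; 20 degrees gives a chain order
#'   parameter around 0.8).
#' @param chol_tilt_sd_deg half-normal tilt of each cholesterol director
#'   (upright states sit at 10-20 degrees in ordered bilayers).
#' @param seed RNG seed.
#' @return list: `frames` (list of `md_frame`), `topology` (with `chains`
#'   set to the PC acyl chains), `cold_side`.
#' @export
gen_membrane_frames <- function(n_pc_per_leaflet = 100, n_chol = 100,
                                box = c(8, 8, 10), thickness = 4,
                                cold_side = +1,
                                x_cold_of_t = function(t) rep(0.5, length(t)),
                                x_noise_sd = 0.02,
                                n_frames = 20, dt_ps = 1000,
                                jitter_sd = 0.05,
                                chain_tilt_sd_deg = 20,
                                chol_tilt_sd_deg = 10, seed = 1) {
  set.seed(seed)
  zmid <- box[3] / 2
  n_pc <- 2L * n_pc_per_leaflet
  pc_beads <- 5L   # PO4 + C1..C4
  ch_beads <- 2L   # ROH + tail
  n_beads <- n_pc * pc_beads + n_chol * ch_beads
  bead_names <- character(n_beads); res_names <- character(n_beads)
  res_ids <- integer(n_beads)
  chains <- vector("list", n_pc)
  k <- 0L
  pc_leaflet <- rep(c(1, -1), each = n_pc_per_leaflet)  # +1 upper, -1 lower
  for (i in seq_len(n_pc)) {
    idx <- k + seq_len(pc_beads)
    bead_names[idx] <- c("PO4", "C1", "C2", "C3", "C4")
    res_names[idx] <- "DPPC"
    res_ids[idx] <- i
    chains[[i]] <- idx[2:5]
    k <- k + pc_beads
  }
  chol_first <- k + 1L
  for (j in seq_len(n_chol)) {
    idx <- k + seq_len(ch_beads)
    bead_names[idx] <- c("ROH", "C2")
    res_names[idx] <- "CHOL"
    res_ids[idx] <- n_pc + j
    k <- k + ch_beads
  }
  topo <- new_topology(bead_names, res_names, res_ids, chains = chains)
  xy <- function(n) cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
  pc_xy <- xy(n_pc); ch_xy <- xy(n_chol)
  frames <- vector("list", n_frames)
  times <- (seq_len(n_frames) - 1) * dt_ps
  xc <- x_cold_of_t(times)
  if (x_noise_sd > 0)
    xc <- pmin(1, pmax(0, xc + rnorm(n_frames, 0, x_noise_sd)))
  tilted <- function(s, sd_deg) {
    # unit vector pointing inward (toward the midplane) tilted off the
    # normal by a half-normal polar angle with uniform azimuth
    beta <- abs(rnorm(1, 0, sd_deg)) * pi / 180
    phi <- runif(1, 0, 2 * pi)
    c(sin(beta) * cos(phi), sin(beta) * sin(phi), -s * cos(beta))
  }
  for (f in seq_len(n_frames)) {
    pos <- matrix(0, n_beads, 3)
    # PC lipids: PO4 at +/- thickness/2, chain beads step 0.35 nm inward
    # along a tilted director
    for (i in seq_len(n_pc)) {
      s <- pc_leaflet[i]
      idx <- (i - 1L) * pc_beads + seq_len(pc_beads)
      zhead <- zmid + s * thickness / 2 + rnorm(1, 0, jitter_sd)
      d <- tilted(s, chain_tilt_sd_deg)
      steps <- 0.35 * (0:(pc_beads - 1L))
      pos[idx, 1] <- pc_xy[i, 1] + d[1] * steps
      pos[idx, 2] <- pc_xy[i, 2] + d[2] * steps
      pos[idx, 3] <- zhead + d[3] * steps
    }
    # cholesterol: first n_cold molecules in the cold leaflet, rest hot
    n_cold <- round(xc[f] * n_chol)
    for (j in seq_len(n_chol)) {
      s <- if (j <= n_cold) cold_side else -cold_side
      idx <- chol_first - 1L + (j - 1L) * ch_beads + seq_len(ch_beads)
      zroh <- zmid + s * (thickness / 2 - 0.3) + rnorm(1, 0, jitter_sd)
      d <- tilted(s, chol_tilt_sd_deg)
      pos[idx, 1] <- c(ch_xy[j, 1], ch_xy[j, 1] + d[1] * 0.9)
      pos[idx, 2] <- c(ch_xy[j, 2], ch_xy[j, 2] + d[2] * 0.9)
      pos[idx, 3] <- c(zroh, zroh + d[3] * 0.9)
    }
    frames[[f]] <- new_frame(pos, box, time = times[f])
  }
  list(frames = frames, topology = topo, cold_side = cold_side)
}
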