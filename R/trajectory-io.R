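# Data model and readers/writers for trajectory frames, topologies,
# thermostat energy ledgers and annealing scan tables. All downstream
# analyses consume only these types.
#
# Conventions: orthorhombic boxes only; lengths nm, times ps, masses amu;
# bead indices are 1-based R indices (file serials are 1-based too, so the
# GRO round trip is the identity).

#' Construct a trajectory frame
#'
#' A frame is one snapshot: an `N x 3` position matrix (nm), an optional
#' `N x 3` velocity matrix (nm/ps), an orthorhombic box `(Lx, Ly, Lz)` (nm)
#' and a time stamp (ps).
#'
#' @param positions numeric `N x 3` matrix of bead coordinates, nm.
#' @param box numeric length-3 vector, box edge lengths in nm (all > 0).
#' @param velocities optional `N x 3` matrix of bead velocities, nm/ps.
#' @param time time stamp in ps.
#' @return An object of class `md_frame`.
#' @export
new_frame <- function(positions, box, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L || ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix with N > 0")
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stop("box must be three positive finite lengths (orthorhombic)")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(positions)))
      stop("velocities must match positions in shape")
    if (!all(is.finite(velocities))) stop("non-finite velocities")
  }
  structure(list(positions = positions, velocities = velocities,
                 box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> %d beads, box %.3f x %.3f x %.3f nm, t = %g ps, %s\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3], x$time,
              if (is.null(x$velocities)) "no velocities" else "with velocities"))
  invisible(x)
}

#' Construct a topology
#'
#' Per-bead labels, residue assignment and masses, plus named index groups
#' (e.g. `CHOL`, `PO4`, `ROH`, `water`) and per-chain bead index lists used
#' by the chain order parameter. Groups not supplied are derived from the
#' bead/residue names by [standard_groups()].
#'
#' @param bead_names,residue_names character length-N labels.
#' @param residue_ids integer length-N residue numbers (a bead belongs to
#'   exactly one residue).
#' @param masses numeric length-N masses in amu; default 72 (a typical
#'   coarse-grained 4-to-1 bead).
#' @param groups named list of integer index vectors, each within `1..N`.
#' @param chains list of integer vectors, each a bonded bead path along one
#'   acyl chain (consecutive pairs are the bonds).
#' @return An object of class `md_topology`.
#' @export
new_topology <- function(bead_names, residue_names, residue_ids,
                         masses = NULL, groups = NULL, chains = NULL) {
  n <- length(bead_names)
  if (n < 1L) stop("empty topology")
  if (length(residue_names) != n || length(residue_ids) != n)
    stop("bead_names, residue_names, residue_ids must have equal length")
  if (is.null(masses)) masses <- rep(72, n)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be length-N and positive")
  auto <- standard_groups(bead_names, residue_names)
  if (is.null(groups)) groups <- auto
  else groups <- utils::modifyList(auto, groups)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      stop(sprintf("group '%s' has indices outside 1..N", g))
  }
  if (!is.null(chains)) {
    for (ch in chains)
      if (any(ch < 1L) || any(ch > n)) stop("chain index outside 1..N")
  }
  structure(list(bead_names = as.character(bead_names),
                 residue_names = as.character(residue_names),
                 residue_ids = as.integer(residue_ids),
                 masses = as.numeric(masses),
                 groups = groups, chains = chains,
                 n_beads = n),
            class = "md_topology")
}

#' Derive the standard named bead groups from labels
#'
#' `CHOL` = cholesterol residues, `PC` = phosphatidylcholine residues
#' (residue name ending in "PC"), `ROH` = cholesterol hydroxyl beads,
#' `PO4` = phosphate beads, `water` = water residues (`W`, `SOL`, `WATER`).
#'
#' @param bead_names,residue_names character vectors of equal length.
#' @return Named list of integer index vectors.
#' @export
standard_groups <- function(bead_names, residue_names) {
  list(
    CHOL  = which(residue_names == "CHOL"),
    PC    = which(grepl("PC$", residue_names) & residue_names != "CHOL"),
    ROH   = which(bead_names == "ROH"),
    PO4   = which(bead_names == "PO4"),
    water = which(residue_names %in% c("W", "SOL", "WATER"))
  )
}

# ---- GRO-class fixed-width coordinate files --------------------------------

.parse_gro_model <- function(lines, offset) {
  # Parse one model starting at lines[offset]; returns list(frame fields,
  # labels, next offset) or NULL if offset beyond input.
  if (offset > length(lines)) return(NULL)
  title <- lines[offset]
  if (offset + 1L > length(lines)) stop(sprintf("truncated file at line %d", offset + 1L))
  nat <- suppressWarnings(as.integer(trimws(lines[offset + 1L])))
  if (is.na(nat) || nat < 1L)
    stop(sprintf("bad atom count at line %d", offset + 1L))
  last <- offset + 1L + nat + 1L
  if (last > length(lines)) {
    if (length(lines) == last - 1L)
      stop(sprintf("missing box line after %d atom records", nat))
    stop(sprintf("header declares %d atoms but file ends at line %d", nat, length(lines)))
  }
  rec <- lines[(offset + 2L):(offset + 1L + nat)]
  bad <- which(nchar(rec) < 44L)
  if (length(bad))
    stop(sprintf("malformed coordinate record at line %d", offset + 1L + bad[1]))
  resid <- as.integer(substr(rec, 1, 5))
  resnm <- trimws(substr(rec, 6, 10))
  atnm  <- trimws(substr(rec, 11, 15))
  num <- function(a, b) suppressWarnings(as.numeric(substr(rec, a, b)))
  x <- num(21, 28); y <- num(29, 36); z <- num(37, 44)
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    ln <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop(sprintf("malformed coordinate record at line %d", offset + 1L + ln))
  }
  has_vel <- all(nchar(rec) >= 68L)
  vel <- NULL
  if (has_vel) {
    vx <- num(45, 52); vy <- num(53, 60); vz <- num(61, 68)
    if (!(anyNA(vx) || anyNA(vy) || anyNA(vz))) vel <- cbind(vx, vy, vz)
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]]))
  if (!length(boxv) || anyNA(boxv))
    stop(sprintf("missing or malformed box line at line %d", last))
  if (length(boxv) > 3L && any(boxv[4:length(boxv)] != 0))
    stop("triclinic boxes are not supported (orthorhombic slab geometry only)")
  tm <- 0
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m))
  list(positions = cbind(x, y, z), velocities = vel, box = boxv[1:3], time = tm,
       resid = resid, resnm = resnm, atnm = atnm, nxt = last + 1L)
}

#' Read a GRO-class coordinate file
#'
#' Fixed-width coordinate file: title, atom count, one record per bead
#' (residue id/name, bead name, serial, x y z in nm to 3 decimals, optional
#' velocities in nm/ps to 4 decimals), then the box line. Only the first
#' model is read; see [read_trajectory()] for multi-frame files.
#'
#' @param path file path.
#' @param masses optional per-bead masses (amu) for the topology.
#' @return `list(frame = md_frame, topology = md_topology)`.
#' @export
read_gro <- function(path, masses = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  p <- .parse_gro_model(lines, 1L)
  if (is.null(p)) stop("empty file")
  frame <- new_frame(p$positions, p$box, p$velocities, p$time)
  topo <- new_topology(p$atnm, p$resnm, p$resid, masses = masses)
  list(frame = frame, topology = topo)
}

#' Write one or more frames as a GRO-class file
#'
#' Positions to 3 decimals (nm), velocities to 4 (nm/ps); multiple frames are
#' concatenated models with `t=` stamps, the multi-frame text trajectory
#' format consumed by [read_trajectory()].
#'
#' @param frames an `md_frame` or list of them.
#' @param topology matching `md_topology`.
#' @param path output path.
#' @param title title prefix for each model.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, topology, path, title = "thermolip frame") {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    if (n != topology$n_beads) stop("frame/topology bead count mismatch")
    writeLines(sprintf("%s t= %.4f", title, fr$time), con)
    writeLines(sprintf("%5d", n), con)
    serial <- ((seq_len(n) - 1L) %% 100000L) + 0L
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    topology$residue_ids %% 100000L,
                    substr(topology$residue_names, 1, 5),
                    substr(topology$bead_names, 1, 5),
                    seq_len(n) %% 100000L,
                    fr$positions[, 1], fr$positions[, 2], fr$positions[, 3])
    if (!is.null(fr$velocities))
      base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                   fr$velocities[, 1], fr$velocities[, 2],
                                   fr$velocities[, 3]))
    writeLines(base, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

# ---- trajectory streaming ---------------------------------------------------

#' Open a multi-frame trajectory as a lazy frame stream
#'
#' Frames are parsed on demand in time order; the whole file is never held as
#' frames at once. Each frame's bead count is checked against the topology.
#' A trailing partial frame yields a warning and the stream ends after the
#' last whole frame.
#'
#' @param path multi-frame GRO-class text trajectory.
#' @param topology `md_topology` the frames must match.
#' @return A `frame_stream`: call `x$next_frame()` for the next `md_frame`
#'   (or `NULL` when exhausted); [collect_frames()] reads all remaining.
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  env <- new.env(parent = emptyenv())
  env$offset <- 1L
  env$done <- length(lines) == 0L ||
    all(!nzchar(trimws(lines)))
  env$next_frame <- function() {
    if (env$done) return(NULL)
    p <- tryCatch(.parse_gro_model(lines, env$offset), error = function(e) e)
    if (is.null(p)) { env$done <- TRUE; return(NULL) }
    if (inherits(p, "error")) {
      env$done <- TRUE
      warning(sprintf("truncated trajectory: %s; stopping after last whole frame",
                      conditionMessage(p)))
      return(NULL)
    }
    if (nrow(p$positions) != topology$n_beads)
      stop(sprintf("trajectory frame has %d beads but topology has %d",
                   nrow(p$positions), topology$n_beads))
    env$offset <- p$nxt
    if (env$offset > length(lines)) env$done <- TRUE
    new_frame(p$positions, p$box, p$velocities, p$time)
  }
  class(env) <- "frame_stream"
  env
}

#' Collect all frames of a stream (eager read)
#' @param x a `frame_stream` from [read_trajectory()], or a list of frames
#'   (returned unchanged), or a single `md_frame`.
#' @return list of `md_frame`.
#' @export
collect_frames <- function(x) {
  if (inherits(x, "md_frame")) return(list(x))
  if (is.list(x) && !inherits(x, "frame_stream")) return(x)
  out <- list()
  repeat {
    fr <- x$next_frame()
    if (is.null(fr)) break
    out[[length(out) + 1L]] <- fr
  }
  out
}

# Apply f(frame) over frames given either a list or a stream.
.each_frame <- function(frames, f) {
  if (inherits(frames, "frame_stream")) {
    repeat {
      fr <- frames$next_frame()
      if (is.null(fr)) break
      f(fr)
    }
  } else {
    for (fr in collect_frames(frames)) f(fr)
  }
  invisible(NULL)
}

# ---- thermostat ledgers and scan tables ------------------------------------

#' Construct a thermostat energy ledger
#'
#' Cumulative energy injected by the hot thermostat and removed by the cold
#' one, against time, plus the lateral cross-section `Lx*Ly` through which
#' the heat flows. Derivatives are taken downstream by regression, so the
#' ledger itself stores cumulative energies (robust to uneven sampling).
#'
#' @param times ps, strictly increasing.
#' @param E_hot,E_cold cumulative energies, kJ/mol.
#' @param area lateral box area, nm^2.
#' @return An object of class `thermostat_ledger`.
#' @export
new_ledger <- function(times, E_hot, E_cold, area) {
  if (length(times) != length(E_hot) || length(times) != length(E_cold))
    stop("times, E_hot, E_cold must have equal length")
  if (any(diff(times) <= 0)) stop("ledger times must be strictly increasing")
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  structure(list(times = as.numeric(times), E_hot = as.numeric(E_hot),
                 E_cold = as.numeric(E_cold), area = as.numeric(area)),
            class = "thermostat_ledger")
}

#' Read a thermostat ledger from CSV
#'
#' Expects the header `time_ps,E_hot_kJmol,E_cold_kJmol`.
#'
#' @param path CSV file.
#' @param area lateral box area in nm^2 (not stored in the CSV).
#' @return `thermostat_ledger`.
#' @export
read_ledger <- function(path, area) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  need <- c("time_ps", "E_hot_kJmol", "E_cold_kJmol")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("ledger is missing column(s): %s", paste(missing, collapse = ", ")))
  new_ledger(df$time_ps, df$E_hot_kJmol, df$E_cold_kJmol, area)
}

#' Write a thermostat ledger to CSV
#' @param ledger `thermostat_ledger`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(data.frame(time_ps = ledger$times,
                              E_hot_kJmol = ledger$E_hot,
                              E_cold_kJmol = ledger$E_cold),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an annealing scan table from CSV
#'
#' Expects the header `T_K,value,direction,replica`; direction is
#' `heating` or `cooling`, temperatures monotone within one
#' direction/replica.
#'
#' @param path CSV file.
#' @return data.frame of class `scan_table`.
#' @export
read_scan_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  need <- c("T_K", "value", "direction", "replica")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("scan table is missing column(s): %s", paste(missing, collapse = ", ")))
  new_scan_table(df$T_K, df$value, df$direction, df$replica)
}

#' Construct a scan table
#' @param temperatures K; `values` the observable (e.g. area per lipid, nm^2);
#'   `direction` "heating" or "cooling"; `replica` integer id.
#' @param values,direction,replica see above.
#' @return data.frame of class `scan_table`.
#' @export
new_scan_table <- function(temperatures, values, direction, replica = 1L) {
  df <- data.frame(T_K = as.numeric(temperatures), value = as.numeric(values),
                   direction = as.character(direction),
                   replica = as.integer(replica))
  if (!all(df$direction %in% c("heating", "cooling")))
    stop("direction must be 'heating' or 'cooling'")
  if (!all(is.finite(df$value))) stop("non-finite scan values")
  for (key in split(df, list(df$direction, df$replica), drop = TRUE)) {
    d <- diff(key$T_K)
    if (length(d) && !(all(d > 0) || all(d < 0)))
      stop("temperatures must be monotone within one direction/replica")
  }
  class(df) <- c("scan_table", "data.frame")
  df
}

#' Infer acyl-chain bond lists from bead names
#'
#' Coordinate files carry no bonds, so chain bead paths are reconstructed
#' by name: within each residue, beads matching `pattern` (default the
#' tail beads `C1, C2, ...`) in file order form one chain. Residues with
#' fewer than two matching beads contribute none.
#'
#' @param topology `md_topology`.
#' @param pattern regular expression selecting chain beads.
#' @return the topology with its `chains` field set.
#' @export
infer_chains <- function(topology, pattern = "^C[0-9]+$") {
  chains <- list()
  for (rid in unique(topology$residue_ids)) {
    in_res <- which(topology$residue_ids == rid)
    ch <- in_res[grepl(pattern, topology$bead_names[in_res])]
    if (length(ch) >= 2L) chains[[length(chains) + 1L]] <- ch
  }
  topology$chains <- chains
  topology
}
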