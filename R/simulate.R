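## Scenario suite: the simulation experiments of the analysis — TKI
## dose-response at several pump expression levels, mechanism knockouts
## (NBD-only / SBD-only inhibition), ATP sweeps with transition-point
## detection, and hypothetical 10-fold parameter improvements.

.MECHANISMS <- c("BOTH", "NBD_ONLY", "SBD_ONLY")
.SWEEP_AXES <- c("tki_ext", "atp", "pgp_total", "sub_ext")
.IMPROVABLE <- c("Kd_nbd", "Kd_sbd", "PC")

#' Define a simulation scenario
#'
#' A scenario fixes the drug pair, the clamped set-point concentrations, the
#' inhibition mechanism in force, and optionally a sweep axis, a readout
#' time and a hypothetical parameter improvement.
#'
#' @param substrate,tki Compound names, looked up in the drug table at run
#'   time.
#' @param sub_ext Extracellular substrate concentration, molar.
#' @param tki_ext Extracellular TKI concentration, molar.
#' @param atp Cytosolic ATP, molar.
#' @param pgp_total Total pump concentration (membrane-volume basis), molar.
#' @param mechanism `"BOTH"` (default), `"NBD_ONLY"` (TKI cannot bind the
#'   substrate site: its membrane SBD Kd is set to infinity) or
#'   `"SBD_ONLY"` (TKI cannot bind the nucleotide site: Kd_nbd set to
#'   infinity). Knockouts remove the corresponding binding fluxes exactly.
#' @param sweep Optional `list(axis =, values =)` with `axis` one of
#'   `"tki_ext"`, `"atp"`, `"pgp_total"`, `"sub_ext"` and positive sorted
#'   `values` (molar).
#' @param readout_time `"steady_state"` (default) or a time in seconds at
#'   which the cytosolic substrate concentration is read out.
#' @param improvement Optional `list(parameter =, fold =)` with `parameter`
#'   one of `"Kd_nbd"`, `"Kd_sbd"`, `"PC"`; affinity improvements divide the
#'   Kd by `fold`, the PC improvement multiplies the partition coefficient.
#' @return An object of class `pgp_scenario`.
#' @export
scenario <- function(substrate = "paclitaxel", tki = "nilotinib",
                     sub_ext = 3e-6, tki_ext = 0, atp = 3e-3,
                     pgp_total = 10e-6, mechanism = "BOTH", sweep = NULL,
                     readout_time = "steady_state", improvement = NULL) {
  mechanism <- match.arg(mechanism, .MECHANISMS)
  stopifnot(sub_ext >= 0, tki_ext >= 0, atp >= 0, pgp_total >= 0)
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), !is.null(sweep$axis), !is.null(sweep$values))
    sweep$axis <- match.arg(sweep$axis, .SWEEP_AXES)
    v <- sweep$values
    if (!is.numeric(v) || length(v) < 1L || any(v < 0) || is.unsorted(v)) {
      stop("sweep values must be non-negative and sorted", call. = FALSE)
    }
  }
  if (!identical(readout_time, "steady_state")) {
    stopifnot(is.numeric(readout_time), length(readout_time) == 1L,
              readout_time > 0)
  }
  if (!is.null(improvement)) {
    stopifnot(is.list(improvement), !is.null(improvement$parameter))
    improvement$parameter <- match.arg(improvement$parameter, .IMPROVABLE)
    if (is.null(improvement$fold)) improvement$fold <- 10
    stopifnot(improvement$fold > 0)
  }
  structure(
    list(substrate = substrate, tki = tki, sub_ext = sub_ext,
         tki_ext = tki_ext, atp = atp, pgp_total = pgp_total,
         mechanism = mechanism, sweep = sweep, readout_time = readout_time,
         improvement = improvement),
    class = "pgp_scenario"
  )
}

#' @export
print.pgp_scenario <- function(x, ...) {
  cat(sprintf("<pgp_scenario> %s + %s | sub %.3g M, tki %.3g M, ATP %.3g M, P-gp %.3g M | %s%s\n",
              x$substrate, x$tki, x$sub_ext, x$tki_ext, x$atp, x$pgp_total,
              x$mechanism,
              if (!is.null(x$sweep)) paste0(" | sweep ", x$sweep$axis,
                                            " (", length(x$sweep$values), ")")
              else ""))
  invisible(x)
}

## Apply mechanism knockout / hypothetical improvement to a TKI's parameters.
.effective_tki <- function(tki, mechanism, improvement = NULL) {
  if (!is.null(improvement)) {
    tki <- switch(improvement$parameter,
      Kd_nbd = { tki$Kd_nbd <- tki$Kd_nbd / improvement$fold; tki },
      Kd_sbd = { tki$Kd_sbd_membrane <- tki$Kd_sbd_membrane / improvement$fold; tki },
      PC = { tki$partition_coefficient <- tki$partition_coefficient *
               improvement$fold; tki })
  }
  if (mechanism == "NBD_ONLY") tki$Kd_sbd_membrane <- Inf
  if (mechanism == "SBD_ONLY") tki$Kd_nbd <- Inf
  tki
}

.lookup_drug <- function(drugs, name) {
  d <- drugs[[name]]
  if (is.null(d)) stop("unknown drug name: ", name, call. = FALSE)
  d
}

#' Run a scenario
#'
#' Builds the kinetic model for the scenario's (possibly knocked-out or
#' improved) parameters and integrates each sweep point to its readout —
#' cytosolic substrate concentration at steady state (default) or at a fixed
#' time. Deterministic given its inputs.
#'
#' @param s A [scenario()].
#' @param params A [kinetic_parameters()].
#' @param drugs Named list of [drug_params()], e.g. from [pgp_drug_table()].
#' @param scheme Model scheme, see [pgp_model()].
#' @return An object of class `sweep_result`: a list with `axis`, `values`,
#'   `readout` (cytosolic substrate, molar, one per sweep value) and
#'   `states` (matrix of endpoint states, one row per sweep value).
#' @export
run_scenario <- function(s, params = kinetic_parameters(),
                         drugs = pgp_drug_table(), scheme = "competitive") {
  stopifnot(inherits(s, "pgp_scenario"))
  sub <- .lookup_drug(drugs, s$substrate)
  tki <- .effective_tki(.lookup_drug(drugs, s$tki), s$mechanism, s$improvement)
  model <- pgp_model(sub, tki, params, scheme = scheme)
  sweep <- s$sweep
  if (is.null(sweep)) sweep <- list(axis = "tki_ext", values = s$tki_ext)
  set_points <- list(sub_ext = s$sub_ext, tki_ext = s$tki_ext, atp = s$atp,
                     pgp_total = s$pgp_total)
  readout <- numeric(length(sweep$values))
  states <- matrix(NA_real_, length(sweep$values), model$n,
                   dimnames = list(NULL, model$vars))
  for (i in seq_along(sweep$values)) {
    sp <- set_points
    sp[[if (sweep$axis == "atp") "atp" else sweep$axis]] <- sweep$values[i]
    y0 <- initial_state(model, sub_ext = sp$sub_ext, tki_ext = sp$tki_ext,
                        atp = sp$atp, pgp_total = sp$pgp_total)
    y <- tryCatch({
      if (identical(s$readout_time, "steady_state")) {
        pgp_steady_state(model, y0)$y
      } else {
        tr <- simulate_trajectory(model, y0, c(0, s$readout_time))
        tr[nrow(tr), -1L]
      }
    }, error = function(e) {
      stop(sprintf("integration failed at sweep value %g (%s): %s",
                   sweep$values[i], sweep$axis, conditionMessage(e)),
           call. = FALSE)
    })
    readout[i] <- y[["sub_cyt"]]
    states[i, ] <- y
  }
  structure(list(axis = sweep$axis, values = sweep$values, readout = readout,
                 states = states, scenario = s),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %d values; cytosolic substrate %.3g..%.3g M\n",
              x$axis, length(x$values), min(x$readout), max(x$readout)))
  invisible(x)
}

#' Cytosolic accumulation in the absence of the pump
#'
#' Reference readout for normalisation: the same scenario with
#' `pgp_total = 0` (and no TKI), i.e. the passive partition equilibrium.
#'
#' @inheritParams run_scenario
#' @return Cytosolic substrate concentration, molar.
#' @export
no_pump_reference <- function(s, params = kinetic_parameters(),
                              drugs = pgp_drug_table(), scheme = "competitive") {
  s0 <- s
  s0$pgp_total <- 0
  s0$tki_ext <- 0
  s0$sweep <- NULL
  run_scenario(s0, params, drugs, scheme)$readout
}

#' TKI dose-response curves across pump expression levels
#'
#' For each P-gp level, sweeps the extracellular TKI dose and records
#' steady-state cytosolic substrate accumulation — the dose-response
#' analysis at pump levels spanning drug-sensitive (0.1 uM) to maximally
#' resistant (100 uM) cells.
#'
#' @param tki TKI name.
#' @param doses Positive sorted TKI doses, molar.
#' @param pgp_levels Pump concentrations, molar.
#' @param base A [scenario()] providing the remaining set points.
#' @inheritParams run_scenario
#' @return Named list of `sweep_result`, one per pump level (names are the
#'   levels in molar).
#' @export
dose_response <- function(tki, doses, pgp_levels = c(0.1, 1, 10, 100) * 1e-6,
                          base = scenario(), params = kinetic_parameters(),
                          drugs = pgp_drug_table(), scheme = "competitive") {
  stopifnot(all(doses > 0), !is.unsorted(doses))
  out <- lapply(pgp_levels, function(lev) {
    s <- base
    s$tki <- tki
    s$pgp_total <- lev
    s$sweep <- list(axis = "tki_ext", values = doses)
    run_scenario(s, params, drugs, scheme)
  })
  names(out) <- format(pgp_levels, scientific = TRUE)
  out
}

#' Log-spaced sweep grid
#'
#' @param from,to Positive range endpoints.
#' @param n Number of grid points across the swept decade range (default 25,
#'   matching logarithmic figure axes).
#' @return Sorted numeric vector of length `n`.
#' @export
log_grid <- function(from, to, n = 25) {
  stopifnot(from > 0, to > from, n >= 2)
  10^seq(log10(from), log10(to), length.out = n)
}

#' ATP concentration at which SBD competition overtakes NBD competition
#'
#' Computes the NBD-only and SBD-only inhibition curves over an ATP range
#' and locates their crossing: below the transition point displacement of
#' ATP from the nucleotide site dominates the inhibition; above it, direct
#' substrate-site competition does. The crossing is bracketed on a
#' logarithmic ATP grid and refined by bisection on log-ATP to 1% relative
#' tolerance.
#'
#' @param tki TKI name.
#' @param atp_range Length-2 positive range, molar.
#' @param base A [scenario()]; its `tki_ext` is the fixed TKI dose (1 uM in
#'   the published sweeps).
#' @param n_grid Number of initial grid points.
#' @inheritParams run_scenario
#' @return `list(transition = molar or NA, ambiguous = logical,
#'   n_crossings = integer, grid = data.frame(atp, nbd_only, sbd_only))`.
#'   If the curves do not cross in range, `transition` is `NA`. With
#'   multiple crossings the lowest is returned and `ambiguous` is `TRUE`.
#' @export
transition_point <- function(tki, atp_range = c(1e-6, 1e-2),
                             base = scenario(tki_ext = 1e-6),
                             n_grid = 25, params = kinetic_parameters(),
                             drugs = pgp_drug_table(), scheme = "competitive") {
  stopifnot(length(atp_range) == 2L, all(atp_range > 0),
            atp_range[2] > atp_range[1])
  atps <- 10^seq(log10(atp_range[1]), log10(atp_range[2]),
                 length.out = n_grid)
  curve <- function(mech, values) {
    s <- base
    s$tki <- tki
    s$mechanism <- mech
    s$sweep <- list(axis = "atp", values = values)
    run_scenario(s, params, drugs, scheme)$readout
  }
  nbd <- curve("NBD_ONLY", atps)
  sbd <- curve("SBD_ONLY", atps)
  d <- nbd - sbd
  grid <- data.frame(atp = atps, nbd_only = nbd, sbd_only = sbd)
  sgn <- sign(d)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (any(sgn == 0)) {
    z <- which(sgn == 0)
    return(list(transition = atps[z[1]], ambiguous = length(z) > 1 || length(flips) > 0,
                n_crossings = length(z) + length(flips), grid = grid))
  }
  if (length(flips) == 0L) {
    return(list(transition = NA_real_, ambiguous = FALSE, n_crossings = 0L,
                grid = grid))
  }
  lo <- atps[flips[1]]; hi <- atps[flips[1] + 1L]
  dlo <- d[flips[1]]
  while (hi / lo > 1.01) {
    mid <- sqrt(lo * hi)
    dm <- curve("NBD_ONLY", mid) - curve("SBD_ONLY", mid)
    if (dm == 0) { lo <- hi <- mid; break }
    if (sign(dm) == sign(dlo)) { lo <- mid; dlo <- dm } else hi <- mid
  }
  list(transition = sqrt(lo * hi), ambiguous = length(flips) > 1L,
       n_crossings = length(flips), grid = grid)
}

#' Hypothetical single-parameter improvement screen
#'
#' Re-simulates a TKI dose-response with each of the three tunable TKI
#' parameters improved separately — NBD affinity (Kd / fold), SBD affinity
#' (membrane Kd / fold), partition coefficient (PC x fold) — alongside the
#' baseline, to ask which property most limits the inhibitor.
#'
#' @param tki TKI name.
#' @param base A [scenario()] whose sweep (default a log dose grid
#'   1e-8..1e-4 M) is reused for all four curves.
#' @param fold Improvement factor (default 10).
#' @inheritParams run_scenario
#' @return Named list of `sweep_result`: `baseline`, `Kd_nbd`, `Kd_sbd`,
#'   `PC`.
#' @export
improvement_screen <- function(tki, base = scenario(), fold = 10,
                               params = kinetic_parameters(),
                               drugs = pgp_drug_table(),
                               scheme = "competitive") {
  s <- base
  s$tki <- tki
  if (is.null(s$sweep)) {
    s$sweep <- list(axis = "tki_ext", values = log_grid(1e-8, 1e-4, 13))
  }
  out <- list(baseline = run_scenario(s, params, drugs, scheme))
  for (p in .IMPROVABLE) {
    si <- s
    si$improvement <- list(parameter = p, fold = fold)
    out[[p]] <- run_scenario(si, params, drugs, scheme)
  }
  out
}

#' Write a sweep result as tidy CSV
#'
#' Long format: one row per (sweep value, variable), with the readout
#' flagged as `sub_cyt`.
#'
#' @param res A `sweep_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(res, path) {
  stopifnot(inherits(res, "sweep_result"))
  long <- do.call(rbind, lapply(seq_along(res$values), function(i) {
    data.frame(axis = res$axis, sweep_value = res$values[i],
               variable = colnames(res$states), value_M = res$states[i, ],
               row.names = NULL)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
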