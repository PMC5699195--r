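## The pump-cycle model.
##
## Compartments: extracellular aqueous, plasma membrane (a thin shell of
## volume V_mem), cytosolic aqueous. Drugs exchange passively between each
## aqueous face and the membrane; the substrate and the TKI bind the P-gp
## substrate-binding domain (SBD) from the membrane pool, while ATP and the
## TKI bind the nucleotide-binding domain (NBD) from the cytosol. Only states
## with ATP at the NBD and a drug at the SBD turn over: the SBD occupant is
## ejected to the extracellular pool, the bound ATP is consumed, and the pump
## resets to the apo state.
##
## The right-hand side is assembled once per model as
##   dy = L y + S_b (k_on * y[lig] * y[from])
## where L holds every linear term (passive exchange, dissociations, efflux)
## and the bilinear association fluxes are scattered through S_b. The
## Jacobian is then available analytically, which the stiff integrator and
## the Newton steady-state polish both exploit.

.SBD_ALPHABET <- list(competitive = c("EMPTY", "SUBSTRATE", "TKI"),
                      noncompetitive = c("EMPTY", "SUBSTRATE", "TKI", "BOTH"))
.NBD_ALPHABET <- c("EMPTY", "ATP", "TKI")

#' Enumerate the pump binding configurations
#'
#' Returns the fixed, documented ordering of P-gp binding states: the
#' Cartesian product of the SBD occupancy alphabet and the NBD occupancy
#' alphabet, row-major in SBD (all NBD states for the first SBD occupant,
#' then the next). The competitive scheme has the canonical nine states
#' (SBD in EMPTY/SUBSTRATE/TKI, NBD in EMPTY/ATP/TKI); the noncompetitive
#' scheme models the SBD as two independent sub-sites so its alphabet gains
#' a BOTH occupant, giving twelve states.
#'
#' @param scheme `"competitive"` (default, 9 states) or `"noncompetitive"`
#'   (12 states).
#' @return A data frame with columns `sbd`, `nbd` and `label` (e.g.
#'   `"pgp_EMPTY.EMPTY"`); the first row is always the apo pump.
#' @export
pgp_states <- function(scheme = c("competitive", "noncompetitive")) {
  scheme <- match.arg(scheme)
  sbd <- .SBD_ALPHABET[[scheme]]
  df <- expand.grid(nbd = .NBD_ALPHABET, sbd = sbd,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("sbd", "nbd")]
  df$label <- paste0("pgp_", abbreviate_state(df$sbd), ".",
                     abbreviate_state(df$nbd))
  df
}

abbreviate_state <- function(x) {
  c(EMPTY = "E", SUBSTRATE = "S", TKI = "T", ATP = "A", BOTH = "B")[x]
}

#' Global kinetic parameters
#'
#' Rate constants and bookkeeping shared by all compounds. Dissociation
#' constants are thermodynamic anchors (printed or fitted values); the
#' association rates are not printed anywhere, so a common diffusion-limited
#' k_on of 1e6 M^-1 s^-1 is used for both sites and every off-rate follows
#' from k_off = Kd * k_on. Steady-state readouts depend only on the Kd's,
#' not on the absolute rates.
#'
#' @param Kd_A ATP dissociation constant at the NBD, molar (docked value
#'   11.6 uM).
#' @param k_on_sbd,k_on_nbd Association rate constants, M^-1 s^-1.
#' @param k_cat Transport/hydrolysis turnover of the loaded, ATP-bound pump,
#'   s^-1. A single irreversible lumped step (hydrolysis, release, reset).
#' @param extracellular_clamped Hold both extracellular drug pools at their
#'   initial values (dose as a set-point).
#' @param atp_clamped Hold cytosolic ATP at its initial value.
#' @param geometry A [cell_geometry()]; sets the membrane and cytosol
#'   volumes.
#' @param V_ext Extracellular volume in liters; default 1000 x cytosol
#'   volume (irrelevant while the extracellular pools are clamped).
#' @param rtol,atol Local error tolerances for trajectory integration.
#' @param drive_rtol Relaxed relative tolerance used only while driving the
#'   system towards steady state; the terminal Newton polish determines the
#'   accuracy of the steady state itself, so the drive tolerance affects the
#'   path but not the answer (verified to ~1e-12 relative in the tests).
#' @param ss_rtol Steady-state threshold on the relative derivative, s^-1.
#' @param t_max Hard cap on simulated time, seconds.
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(Kd_A = 1.16e-5, k_on_sbd = 1e6, k_on_nbd = 1e6,
                               k_cat = 1, extracellular_clamped = TRUE,
                               atp_clamped = TRUE, geometry = cell_geometry(),
                               V_ext = NULL, rtol = 1e-8, atol = 1e-12,
                               drive_rtol = 1e-3, ss_rtol = 1e-8, t_max = 1e6) {
  stopifnot(Kd_A > 0, k_on_sbd > 0, k_on_nbd > 0, k_cat >= 0,
            rtol > 0, atol > 0, drive_rtol > 0, ss_rtol > 0, t_max > 0)
  V_mem <- membrane_volume(geometry)
  V_cyt <- cytosol_volume(geometry)
  if (is.null(V_ext)) V_ext <- 1000 * V_cyt
  stopifnot(V_ext > 0)
  structure(
    list(Kd_A = Kd_A, k_on_sbd = k_on_sbd, k_on_nbd = k_on_nbd, k_cat = k_cat,
         extracellular_clamped = isTRUE(extracellular_clamped),
         atp_clamped = isTRUE(atp_clamped),
         V_mem = V_mem, V_cyt = V_cyt, V_ext = V_ext,
         rtol = rtol, atol = atol, drive_rtol = drive_rtol,
         ss_rtol = ss_rtol, t_max = t_max),
    class = "kinetic_parameters"
  )
}

## Variable layout: 1 sub_ext, 2 sub_mem, 3 sub_cyt, 4 tki_ext, 5 tki_mem,
## 6 tki_cyt, 7 atp_cyt, then the pump states in pgp_states() order.
.VAR_DRUGS <- c("sub_ext", "sub_mem", "sub_cyt", "tki_ext", "tki_mem",
                "tki_cyt", "atp_cyt")

#' Build a pump-cycle kinetic model
#'
#' Assembles the full ODE system for one substrate / TKI pair: variable
#' layout, linear operator, bilinear association fluxes, clamping and the
#' pump conservation law. Setting a dissociation constant to `Inf`
#' (`Kd_sbd_membrane` or `Kd_nbd` on a [drug_params()]) removes the
#' corresponding binding edges from the model exactly — this is how
#' mechanism knockouts are realised.
#'
#' @param substrate [drug_params()] for the transported substrate
#'   (paclitaxel, calcein). Its `Kd_nbd` is ignored (substrates do not bind
#'   the nucleotide site in this scheme).
#' @param tki [drug_params()] for the inhibitor.
#' @param params [kinetic_parameters()].
#' @param scheme `"competitive"`: substrate and TKI compete for a single
#'   SBD site (nine pump states). `"noncompetitive"`: the SBD carries two
#'   independent sub-sites, one per compound, which may be occupied
#'   simultaneously (twelve states); one turnover ejects every SBD occupant
#'   and consumes one ATP.
#' @return An object of class `pgp_model`.
#' @export
pgp_model <- function(substrate, tki, params = kinetic_parameters(),
                      scheme = c("competitive", "noncompetitive")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(substrate, "drug_params"), inherits(tki, "drug_params"),
            inherits(params, "kinetic_parameters"))
  states <- pgp_states(scheme)
  ns <- nrow(states)
  n <- 7L + ns
  vars <- c(.VAR_DRUGS, states$label)
  pump_idx <- 8:n
  sidx <- function(sbd, nbd) 7L + which(states$sbd == sbd & states$nbd == nbd)

  vm_ve <- params$V_mem / params$V_ext
  vm_vc <- params$V_mem / params$V_cyt

  L <- matrix(0, n, n, dimnames = list(vars, vars))
  ## passive exchange, both faces, membrane-volume basis
  add_passive <- function(ext, mem, cyt, kp, pc) {
    kpo <- kp / pc
    L[mem, ext] <<- L[mem, ext] + kp
    L[mem, cyt] <<- L[mem, cyt] + kp
    L[mem, mem] <<- L[mem, mem] - 2 * kpo
    L[ext, ext] <<- L[ext, ext] - kp * vm_ve
    L[ext, mem] <<- L[ext, mem] + kpo * vm_ve
    L[cyt, cyt] <<- L[cyt, cyt] - kp * vm_vc
    L[cyt, mem] <<- L[cyt, mem] + kpo * vm_vc
  }
  add_passive(1L, 2L, 3L, substrate$passive_rate, substrate$partition_coefficient)
  add_passive(4L, 5L, 6L, tki$passive_rate, tki$partition_coefficient)

  ## binding edges: bilinear on-flux (k_on * [lig] * [from]) and linear
  ## off-flux (k_off * [to]); ligvol converts the ligand bookkeeping to the
  ## ligand pool's own volume basis
  edges <- list()
  add_edge <- function(from, to, lig, kon, kd, ligvol) {
    if (!is.finite(kd)) return(invisible())
    koff <- kon * kd
    L[from, to] <<- L[from, to] + koff
    L[to, to] <<- L[to, to] - koff
    L[lig, to] <<- L[lig, to] + koff * ligvol
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, lig = lig,
                                         kon = kon, ligvol = ligvol)
  }
  ## competitive: one SBD site, EMPTY -> SUBSTRATE or EMPTY -> TKI.
  ## noncompetitive: two independent SBD sub-sites; the substrate sub-site
  ## fills EMPTY -> SUBSTRATE and TKI -> BOTH, the TKI sub-site fills
  ## EMPTY -> TKI and SUBSTRATE -> BOTH, with the same two Kds.
  for (nbd in .NBD_ALPHABET) {
    add_edge(sidx("EMPTY", nbd), sidx("SUBSTRATE", nbd), 2L,
             params$k_on_sbd, substrate$Kd_sbd_membrane, 1)
    add_edge(sidx("EMPTY", nbd), sidx("TKI", nbd), 5L,
             params$k_on_sbd, tki$Kd_sbd_membrane, 1)
    if (scheme == "noncompetitive") {
      add_edge(sidx("TKI", nbd), sidx("BOTH", nbd), 2L,
               params$k_on_sbd, substrate$Kd_sbd_membrane, 1)
      add_edge(sidx("SUBSTRATE", nbd), sidx("BOTH", nbd), 5L,
               params$k_on_sbd, tki$Kd_sbd_membrane, 1)
    }
  }
  for (sbd in .SBD_ALPHABET[[scheme]]) {
    add_edge(sidx(sbd, "EMPTY"), sidx(sbd, "ATP"), 7L,
             params$k_on_nbd, params$Kd_A, vm_vc)
    add_edge(sidx(sbd, "EMPTY"), sidx(sbd, "TKI"), 6L,
             params$k_on_nbd, tki$Kd_nbd, vm_vc)
  }

  ## efflux: loaded + ATP-bound states turn over irreversibly; the SBD
  ## occupant(s) go to the extracellular pool, the bound ATP is consumed
  ## (it left the cytosol pool at association), the pump resets to apo
  apo <- sidx("EMPTY", "EMPTY")
  add_efflux <- function(from, eject_pools) {
    kc <- params$k_cat
    if (kc == 0) return(invisible())
    L[from, from] <<- L[from, from] - kc
    L[apo, from] <<- L[apo, from] + kc
    for (pool in eject_pools) L[pool, from] <<- L[pool, from] + kc * vm_ve
  }
  add_efflux(sidx("SUBSTRATE", "ATP"), 1L)
  add_efflux(sidx("TKI", "ATP"), 4L)
  if (scheme == "noncompetitive") add_efflux(sidx("BOTH", "ATP"), c(1L, 4L))

  clamped <- integer(0)
  if (params$extracellular_clamped) clamped <- c(clamped, 1L, 4L)
  if (params$atp_clamped) clamped <- c(clamped, 7L)

  ne <- length(edges)
  Sb <- matrix(0, n, max(ne, 1L))
  lig <- from <- integer(ne)
  kon <- numeric(ne)
  for (k in seq_len(ne)) {
    e <- edges[[k]]
    Sb[e$from, k] <- Sb[e$from, k] - 1
    Sb[e$to, k] <- Sb[e$to, k] + 1
    Sb[e$lig, k] <- Sb[e$lig, k] - e$ligvol
    lig[k] <- e$lig; from[k] <- e$from; kon[k] <- e$kon
  }
  ## clamped variables have identically zero derivative
  L[clamped, ] <- 0
  Sb[clamped, ] <- 0

  structure(
    list(n = n, vars = vars, states = states, scheme = scheme,
         pump_idx = pump_idx, apo_idx = apo, clamped = clamped,
         L = L, Sb = Sb, ne = ne, lig = lig, from = from, kon = kon,
         substrate = substrate, tki = tki, params = params),
    class = "pgp_model"
  )
}

#' @export
print.pgp_model <- function(x, ...) {
  cat(sprintf("<pgp_model> %s scheme: %d variables (%d pump states), substrate %s, TKI %s\n",
              x$scheme, x$n, nrow(x$states), x$substrate$name, x$tki$name))
  invisible(x)
}

.model_rhs <- function(m) {
  if (m$ne == 0L) {
    function(y) as.vector(m$L %*% y)
  } else {
    function(y) {
      as.vector(m$L %*% y) +
        as.vector(m$Sb %*% (m$kon * y[m$lig] * y[m$from]))
    }
  }
}

.model_jac <- function(m) {
  if (m$ne == 0L) {
    function(y) m$L
  } else {
    ij_lig <- cbind(seq_len(m$ne), m$lig)
    ij_from <- cbind(seq_len(m$ne), m$from)
    function(y) {
      D <- matrix(0, m$ne, m$n)
      D[ij_lig] <- m$kon * y[m$from]
      D[ij_from] <- m$kon * y[m$lig]
      m$L + m$Sb %*% D
    }
  }
}

#' Time derivative of the system state
#'
#' The validated, user-facing right-hand side. Checks that the state vector
#' has the model's length and layout and contains no negative
#' concentrations, then returns the mass-action derivative. Clamped
#' variables have exactly zero derivative and the pump-state derivatives sum
#' to zero identically (the pump is neither created nor destroyed).
#'
#' @param state Named or unnamed numeric vector in the model's variable
#'   order (see `model$vars`).
#' @param model A [pgp_model()].
#' @return Named derivative vector, molar per second.
#' @export
pgp_rhs <- function(state, model) {
  stopifnot(inherits(model, "pgp_model"))
  if (length(state) != model$n) {
    stop(sprintf("state must have %d entries (got %d)", model$n, length(state)),
         call. = FALSE)
  }
  if (!is.null(names(state)) && !identical(names(state), model$vars)) {
    state <- state[model$vars]
    if (any(is.na(state))) stop("state names do not match model variables",
                                call. = FALSE)
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state contains negative or non-finite concentrations", call. = FALSE)
  }
  out <- .model_rhs(model)(as.numeric(state))
  names(out) <- model$vars
  out
}

#' Default initial condition
#'
#' Drugs entirely extracellular, the pump entirely in its apo
#' (EMPTY, EMPTY) configuration, ATP at its cytosolic set point.
#'
#' @param model A [pgp_model()].
#' @param sub_ext,tki_ext Extracellular drug concentrations, molar.
#' @param atp Cytosolic ATP, molar.
#' @param pgp_total Total pump concentration on the membrane-volume basis,
#'   molar.
#' @return Named state vector.
#' @export
initial_state <- function(model, sub_ext = 0, tki_ext = 0, atp = 3e-3,
                          pgp_total = 10e-6) {
  stopifnot(sub_ext >= 0, tki_ext >= 0, atp >= 0, pgp_total >= 0)
  y <- stats::setNames(numeric(model$n), model$vars)
  y["sub_ext"] <- sub_ext
  y["tki_ext"] <- tki_ext
  y["atp_cyt"] <- atp
  y[model$apo_idx] <- pgp_total
  y
}

#' Integrate a model trajectory
#'
#' @param model A [pgp_model()].
#' @param y0 Initial state (see [initial_state()]).
#' @param times Increasing output times in seconds, starting at the initial
#'   time.
#' @return Matrix with a `time` column and one column per state variable.
#' @export
simulate_trajectory <- function(model, y0, times) {
  y0 <- stats::setNames(as.numeric(y0[model$vars]), model$vars)
  ode_integrate(.model_rhs(model), .model_jac(model), y0, times,
                rtol = model$params$rtol, atol = model$params$atol)
}

#' Steady state of a model
#'
#' Integrates until the maximum relative derivative over unclamped variables
#' drops below the declared threshold (default 1e-8 s^-1, capped at 1e6 s
#' simulated), then polishes the stationary point with a Newton iteration in
#' which the pump conservation law replaces the redundant apo-state
#' equation.
#'
#' @param model A [pgp_model()].
#' @param y0 Initial state.
#' @return `list(y, t, converged, newton)`; `y` is the named steady state.
#' @export
pgp_steady_state <- function(model, y0) {
  y0 <- y0[model$vars]
  cons <- list(row = model$apo_idx, idx = model$pump_idx,
               total = sum(y0[model$pump_idx]))
  res <- ode_steady_state(.model_rhs(model), .model_jac(model),
                          as.numeric(y0), clamped = model$clamped,
                          conservation = cons,
                          ss_rtol = model$params$ss_rtol,
                          t_max = model$params$t_max,
                          rtol = model$params$drive_rtol,
                          atol = model$params$atol)
  names(res$y) <- model$vars
  res
}

#' Closed-form equilibrium occupancy of the pump lattice
#'
#' With turnover switched off (`k_cat = 0`) and fixed free ligand
#' concentrations, the binding lattice is a pair of independent sites (or,
#' noncompetitively, three independent sub-sites) and its stationary
#' distribution is the product of single-site competitive isotherms, e.g.
#' P(SBD = SUBSTRATE) = (s/Kd_P) / (1 + s/Kd_P + t_mem/Kd_N). This provides
#' a closed-form check target for the ODE core.
#'
#' @param model A [pgp_model()] built with `k_cat = 0`.
#' @param free Named list of free ligand concentrations, molar:
#'   `sub_mem`, `tki_mem`, `atp_cyt`, `tki_cyt` (missing entries default
#'   to 0).
#' @return Named vector of state fractions, in [pgp_states()] order, summing
#'   to 1.
#' @export
equilibrium_occupancy <- function(model, free = list()) {
  stopifnot(inherits(model, "pgp_model"))
  if (model$params$k_cat != 0) {
    stop("equilibrium_occupancy requires a model with k_cat = 0", call. = FALSE)
  }
  g <- function(nm) if (!is.null(free[[nm]])) free[[nm]] else 0
  ratio <- function(conc, kd) if (is.finite(kd)) conc / kd else 0
  rs <- ratio(g("sub_mem"), model$substrate$Kd_sbd_membrane)
  rt <- ratio(g("tki_mem"), model$tki$Kd_sbd_membrane)
  ra <- ratio(g("atp_cyt"), model$params$Kd_A)
  ri <- ratio(g("tki_cyt"), model$tki$Kd_nbd)
  p_nbd <- c(EMPTY = 1, ATP = ra, TKI = ri) / (1 + ra + ri)
  if (model$scheme == "competitive") {
    p_sbd <- c(EMPTY = 1, SUBSTRATE = rs, TKI = rt) / (1 + rs + rt)
  } else {
    ps <- rs / (1 + rs)
    pt <- rt / (1 + rt)
    p_sbd <- c(EMPTY = (1 - ps) * (1 - pt), SUBSTRATE = ps * (1 - pt),
               TKI = (1 - ps) * pt, BOTH = ps * pt)
  }
  st <- model$states
  out <- p_sbd[st$sbd] * p_nbd[st$nbd]
  names(out) <- st$label
  out
}

#' Total moles of a drug across compartments and bound states
#'
#' Bookkeeping helper: moles of the substrate (or TKI) free in the three
#' compartments plus bound at the SBD, each scaled by its compartment
#' volume. With turnover off and clamps released this quantity is conserved
#' along trajectories.
#'
#' @param y Named state vector.
#' @param model A [pgp_model()].
#' @param which `"substrate"` or `"tki"`.
#' @return Moles.
#' @export
drug_moles <- function(y, model, which = c("substrate", "tki")) {
  which <- match.arg(which)
  p <- model$params
  st <- model$states
  if (which == "substrate") {
    bound <- st$sbd %in% c("SUBSTRATE", "BOTH")
    free <- y["sub_ext"] * p$V_ext + y["sub_mem"] * p$V_mem +
      y["sub_cyt"] * p$V_cyt
  } else {
    bound_sbd <- st$sbd %in% c("TKI", "BOTH")
    bound_nbd <- st$nbd == "TKI"
    bound <- bound_sbd | bound_nbd
    ## a TKI in state (TKI, TKI) counts twice: one at each site
    free <- y["tki_ext"] * p$V_ext + y["tki_mem"] * p$V_mem +
      y["tki_cyt"] * p$V_cyt
    return(unname(free + p$V_mem * sum(y[model$pump_idx] *
                                         (bound_sbd + bound_nbd))))
  }
  unname(free + p$V_mem * sum(y[model$pump_idx][bound]))
}
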