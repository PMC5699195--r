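## Shared fixtures. Loaded once per test run; everything here is cheap —
## expensive objects are built (and documented) inside the tests that need
## them.

td_ctx <- thermo_context()
td_drugs <- pgp_drug_table()
td_params <- kinetic_parameters()

## a TKI that binds nothing: useful for degenerate-scenario checks
inert_tki <- drug_params("inert", partition_coefficient = 100,
                         Kd_nbd = Inf, Kd_sbd_membrane = Inf)

## random valid system state for property tests (concentrations in
## plausible ranges, pump mass spread over the lattice)
random_state <- function(model, rng_scale = 1e-6) {
  y <- stats::runif(model$n, 0, rng_scale)
  y[7] <- stats::runif(1, 1e-4, 5e-3)           # ATP
  pump <- stats::runif(length(model$pump_idx))
  y[model$pump_idx] <- 1e-5 * pump / sum(pump)  # total pump 10 uM
  names(y) <- model$vars
  y
}

## linear interpolation of the dose at which a readout reaches `target`
dose_at <- function(doses, readout, target) {
  stats::approx(readout, log10(doses), xout = target, ties = "ordered")$y
}
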