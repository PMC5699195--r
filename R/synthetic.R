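## Synthetic-data generator. The original efflux-inhibition measurements
## (TKI-mediated inhibition of calcein efflux in P-gp-overexpressing cells)
## are external and not deposited; this module generates datasets with the
## same statistical structure — normalized accumulation vs dose, additive
## Gaussian fluorescence noise, known ground-truth NBD Kd — so the entire
## fitting pipeline is testable end to end.

#' Specification for a synthetic efflux-inhibition dataset
#'
#' @param true_Kd_nbd Ground-truth NBD dissociation constant, molar.
#' @param tki TKI name (SBD affinity and partition coefficient come from the
#'   drug table).
#' @param doses Positive dose grid, molar.
#' @param noise_sd Additive Gaussian noise SD on the normalized readout
#'   (default 0.02, a fluorescence-assay noise proxy).
#' @param n_replicates Replicates per dose.
#' @param seed Integer RNG seed, recorded in the output.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(true_Kd_nbd, tki = "nilotinib",
                           doses = 10^seq(-8, -4, length.out = 9),
                           noise_sd = 0.02, n_replicates = 1L, seed = 1L) {
  stopifnot(true_Kd_nbd > 0, all(doses > 0), noise_sd >= 0,
            n_replicates >= 1L, is.numeric(seed), length(seed) == 1L)
  structure(
    list(true_Kd_nbd = true_Kd_nbd, tki = tki, doses = as.numeric(doses),
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

## run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic calcein efflux-inhibition dataset
#'
#' Readouts are the model's own predicted normalized accumulation at the
#' ground-truth Kd plus additive Gaussian noise, clipped at zero. The same
#' seed always yields the same dataset; the RNG algorithm and seed are
#' recorded on the result.
#'
#' @param spec A [generator_spec()].
#' @param scheme Substrate-site assumption passed to
#'   [predict_accumulation()].
#' @param assay A [calcein_assay()].
#' @param params A [kinetic_parameters()].
#' @param drugs Drug table.
#' @param predictions Optional precomputed noiseless curve for `spec$doses`
#'   (one value per dose), to skip re-simulation.
#' @return A [dose_response_dataset()] with `ground_truth_Kd` set and
#'   attributes `spec`, `rng_kind`.
#' @export
generate_calcein_dataset <- function(spec,
                                     scheme = c("noncompetitive", "competitive"),
                                     assay = calcein_assay(),
                                     params = kinetic_parameters(),
                                     drugs = pgp_drug_table(),
                                     predictions = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "generator_spec"))
  tki <- .lookup_drug(drugs, spec$tki)
  if (is.null(predictions)) {
    predictions <- predict_accumulation(spec$true_Kd_nbd, spec$doses, tki,
                                        scheme, assay, params)
  }
  stopifnot(length(predictions) == length(spec$doses))
  doses <- rep(spec$doses, times = spec$n_replicates)
  pred <- rep(predictions, times = spec$n_replicates)
  replicate <- rep(seq_len(spec$n_replicates), each = length(spec$doses))
  noise <- .with_seed(spec$seed,
                      stats::rnorm(length(pred), 0, spec$noise_sd))
  readouts <- pmax(pred + noise, 0)
  ds <- dose_response_dataset(spec$tki, doses, readouts, replicate,
                              substrate = assay$substrate,
                              ground_truth_Kd = spec$true_Kd_nbd)
  attr(ds, "spec") <- spec
  attr(ds, "rng_kind") <- RNGkind()[1]
  ds
}

#' Write / read a dose-response dataset as CSV with a JSON sidecar
#'
#' The CSV carries `dose_M, readout, replicate`; the sidecar
#' (`<path>.json`) records the TKI, the reporter parameters, the ground
#' truth and (for synthetic data) the generator spec and RNG algorithm.
#'
#' @param ds A [dose_response_dataset()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(ds, path) {
  stopifnot(inherits(ds, "dose_response_dataset"))
  utils::write.csv(
    data.frame(dose_M = ds$doses, readout = ds$readouts,
               replicate = ds$replicate),
    path, row.names = FALSE)
  sub <- unclass(ds$substrate)
  ## JSON has no Inf literal; serialise non-finite Kds as strings
  sub$Kd_nbd <- if (is.finite(sub$Kd_nbd)) sub$Kd_nbd else "Inf"
  sub$Kd_sbd_membrane <- if (is.finite(sub$Kd_sbd_membrane))
    sub$Kd_sbd_membrane else "Inf"
  side <- list(tki = ds$tki, substrate = sub,
               ground_truth_Kd_M = ds$ground_truth_Kd)
  spec <- attr(ds, "spec")
  if (!is.null(spec)) {
    side$generator_spec <- unclass(spec)
    side$rng_kind <- attr(ds, "rng_kind")
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  tab <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("missing JSON sidecar: ", side_path, call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  ss <- side$substrate
  sub <- drug_params(name = ss$name,
                     partition_coefficient = as.numeric(ss$partition_coefficient),
                     Kd_nbd = as.numeric(ss$Kd_nbd),
                     Kd_sbd_membrane = as.numeric(ss$Kd_sbd_membrane),
                     passive_rate = as.numeric(ss$passive_rate))
  dose_response_dataset(side$tki, tab$dose_M, tab$readout, tab$replicate,
                        substrate = sub,
                        ground_truth_Kd = side$ground_truth_Kd_M)
}

#' The published scenario grid
#'
#' Emits the full scenario suite of the analysis as [scenario()] objects:
#' TKI dose sweeps at extracellular paclitaxel 0.03 / 0.3 / 3 uM and pump
#' levels 0.1 / 1 / 10 / 100 uM, and ATP sweeps (1 uM - 10 mM) at the
#' effective pump level of 10 uM with a fixed 1 uM TKI dose, for each of the
#' three TKIs.
#'
#' @param dose_grid TKI dose sweep values, molar.
#' @param atp_grid ATP sweep values, molar.
#' @return List of `pgp_scenario`.
#' @export
paper_fixture_scenarios <- function(dose_grid = log_grid(1e-8, 1e-4, 25),
                                    atp_grid = log_grid(1e-6, 1e-2, 25)) {
  tkis <- c("nilotinib", "imatinib", "dasatinib")
  out <- list()
  for (tki in tkis) {
    for (pac in c(0.03, 0.3, 3) * 1e-6) {
      for (pgp in c(0.1, 1, 10, 100) * 1e-6) {
        out[[length(out) + 1L]] <- scenario(
          substrate = "paclitaxel", tki = tki, sub_ext = pac, atp = 3e-3,
          pgp_total = pgp, sweep = list(axis = "tki_ext", values = dose_grid))
      }
    }
    out[[length(out) + 1L]] <- scenario(
      substrate = "paclitaxel", tki = tki, sub_ext = 3e-6, tki_ext = 1e-6,
      pgp_total = 10e-6, sweep = list(axis = "atp", values = atp_grid))
  }
  out
}
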