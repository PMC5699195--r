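## NBD-affinity estimation. The nucleotide-site dissociation constants of
## the TKIs are not measurable by docking (the fitted quantities of the
## analysis); they are estimated one at a time by exhaustive grid search
## against efflux-inhibition dose-response data — normalized intracellular
## accumulation of a reporter substrate (calcein) versus TKI dose — under a
## competitive or noncompetitive substrate-site assumption.

#' Calcein reporter parameters
#'
#' Surrogate substrate for the efflux-inhibition assay. The assay reports
#' calcein accumulation in cells overexpressing P-gp; the reporter's own
#' membrane-basis SBD Kd (1 uM) and partition coefficient (100) are fixture
#' defaults documented as reconstructions — the published analysis does not
#' print them.
#'
#' @param Kd_sbd_membrane Membrane-basis SBD Kd, molar.
#' @param pc Partition coefficient.
#' @return A [drug_params()] for the reporter (no NBD binding).
#' @export
calcein_params <- function(Kd_sbd_membrane = 1e-6, pc = 100) {
  drug_params("calcein", partition_coefficient = pc, Kd_nbd = Inf,
              Kd_sbd_membrane = Kd_sbd_membrane)
}

#' Efflux-inhibition assay set points
#'
#' Conditions under which [predict_accumulation()] simulates the reporter
#' assay: P-gp-overexpressing cells, physiological ATP (3 mM), 1 uM
#' extracellular reporter. The default pump level (1 uM, ten-fold above the
#' drug-sensitive baseline) is a reconstruction chosen so that the
#' normalized readout spans its full dynamic range across physiological
#' inhibitor doses — the regime in which the experimental inhibition curves
#' were measured; at much higher pump levels the readout saturates near
#' zero and carries no dose information.
#'
#' @param substrate Reporter [drug_params()].
#' @param sub_ext Extracellular reporter concentration, molar.
#' @param pgp_total Pump concentration, molar.
#' @param atp Cytosolic ATP, molar.
#' @return A list with class `calcein_assay`.
#' @export
calcein_assay <- function(substrate = calcein_params(), sub_ext = 1e-6,
                          pgp_total = 1e-6, atp = 3e-3) {
  stopifnot(inherits(substrate, "drug_params"), sub_ext > 0, pgp_total >= 0,
            atp >= 0)
  structure(list(substrate = substrate, sub_ext = sub_ext,
                 pgp_total = pgp_total, atp = atp),
            class = "calcein_assay")
}

#' Dose-response dataset
#'
#' Inhibitor dose versus normalized intracellular reporter accumulation
#' (1 = no-pump level, 0 = fully effluxed), with optional replicates and
#' known ground truth (for synthetic data).
#'
#' @param tki TKI name (looked up in the drug table when predicting).
#' @param doses Positive doses, molar; one per readout.
#' @param readouts Normalized accumulation values, same length as `doses`.
#' @param replicate Integer replicate labels (default all 1).
#' @param substrate Reporter [drug_params()] used in the assay.
#' @param ground_truth_Kd Optional known NBD Kd, molar.
#' @return An object of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(tki, doses, readouts, replicate = NULL,
                                  substrate = calcein_params(),
                                  ground_truth_Kd = NULL) {
  if (length(doses) == 0L) stop("dataset has no doses", call. = FALSE)
  if (length(doses) != length(readouts)) {
    stop("doses and readouts must have equal length", call. = FALSE)
  }
  stopifnot(all(doses > 0), all(is.finite(readouts)))
  if (any(readouts < 0) || any(readouts > 1.5)) {
    stop("readouts must lie in [0, 1] up to noise allowance", call. = FALSE)
  }
  if (is.null(replicate)) replicate <- rep(1L, length(doses))
  stopifnot(length(replicate) == length(doses))
  structure(
    list(tki = tki, doses = as.numeric(doses), readouts = as.numeric(readouts),
         replicate = as.integer(replicate), substrate = substrate,
         ground_truth_Kd = ground_truth_Kd),
    class = "dose_response_dataset"
  )
}

#' @export
print.dose_response_dataset <- function(x, ...) {
  cat(sprintf("<dose_response_dataset> %s: %d points (%d doses)%s\n",
              x$tki, length(x$doses), length(unique(x$doses)),
              if (!is.null(x$ground_truth_Kd))
                sprintf(", ground truth Kd = %.3g M", x$ground_truth_Kd)
              else ""))
  invisible(x)
}

#' Root-mean-square error
#'
#' sqrt(mean((predicted - observed)^2)); the error function minimised by the
#' grid search over all available data points.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Non-negative scalar; zero iff the vectors are identical.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L) {
    stop("predicted and observed must be non-empty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Predicted normalized accumulation at a candidate NBD Kd
#'
#' Simulates the reporter assay at each dose with the TKI's NBD dissociation
#' constant set to the candidate value, and normalizes the steady-state
#' cytosolic reporter concentration to its no-pump level.
#'
#' @param Kd_candidate Candidate NBD Kd, molar (`Inf` = no NBD binding).
#' @param doses TKI doses, molar.
#' @param tki TKI [drug_params()] (SBD affinity and PC are taken from here).
#' @param scheme `"noncompetitive"` (default; reporter and TKI occupy
#'   independent SBD sub-sites) or `"competitive"` (single shared site).
#' @param assay A [calcein_assay()].
#' @param params A [kinetic_parameters()].
#' @return Normalized accumulation, one value per dose.
#' @export
predict_accumulation <- function(Kd_candidate, doses, tki,
                                 scheme = c("noncompetitive", "competitive"),
                                 assay = calcein_assay(),
                                 params = kinetic_parameters()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(tki, "drug_params"), all(doses > 0),
            Kd_candidate > 0)
  tki$Kd_nbd <- Kd_candidate
  model <- pgp_model(assay$substrate, tki, params, scheme = scheme)
  ## no-pump reference for normalisation
  model0 <- pgp_model(assay$substrate, tki,
                      kinetic_parameters(
                        Kd_A = params$Kd_A, k_on_sbd = params$k_on_sbd,
                        k_on_nbd = params$k_on_nbd, k_cat = params$k_cat,
                        extracellular_clamped = params$extracellular_clamped,
                        atp_clamped = params$atp_clamped),
                      scheme = scheme)
  ref <- pgp_steady_state(
    model0, initial_state(model0, sub_ext = assay$sub_ext, tki_ext = 0,
                          atp = assay$atp, pgp_total = 0))$y[["sub_cyt"]]
  vapply(doses, function(d) {
    y <- pgp_steady_state(
      model, initial_state(model, sub_ext = assay$sub_ext, tki_ext = d,
                           atp = assay$atp, pgp_total = assay$pgp_total))$y
    y[["sub_cyt"]] / ref
  }, numeric(1))
}

#' Default Kd search grid
#'
#' Log-spaced grid over 1e-10 to 1e-4 M with 13 points per decade
#' (79 points).
#'
#' @param from,to Grid range, molar.
#' @param points_per_decade Grid density.
#' @return Sorted numeric vector.
#' @export
kd_default_grid <- function(from = 1e-10, to = 1e-4, points_per_decade = 13) {
  10^seq(log10(from), log10(to), by = 1 / points_per_decade)
}

#' Precompute predicted curves over a Kd grid
#'
#' The predicted dose-response depends only on the grid point and the assay,
#' not on the observed data, so fits of many datasets sharing doses and
#' assay conditions (e.g. noisy replicates) can reuse one prediction matrix.
#'
#' @param grid Candidate Kd values, molar.
#' @param doses TKI doses, molar.
#' @inheritParams predict_accumulation
#' @return Matrix `length(grid) x length(doses)` of normalized accumulation,
#'   with the grid as `rownames` attribute input.
#' @export
kd_grid_predictions <- function(grid, doses, tki,
                                scheme = c("noncompetitive", "competitive"),
                                assay = calcein_assay(),
                                params = kinetic_parameters()) {
  scheme <- match.arg(scheme)
  out <- t(vapply(grid, function(kd) {
    predict_accumulation(kd, doses, tki, scheme, assay, params)
  }, numeric(length(doses))))
  attr(out, "grid") <- grid
  attr(out, "doses") <- doses
  out
}

#' Grid-search estimate of a TKI's NBD dissociation constant
#'
#' Evaluates the RMSE between observed and predicted normalized accumulation
#' at every grid point and selects the minimiser. One parameter is fitted at
#' a time. Ties are broken toward the smaller Kd and flagged.
#'
#' @param dataset A [dose_response_dataset()].
#' @param scheme Substrate-site assumption, see [predict_accumulation()].
#' @param grid Candidate Kd values (default [kd_default_grid()]).
#' @param drugs Drug table for the TKI's SBD parameters.
#' @param predictions Optional precomputed matrix from
#'   [kd_grid_predictions()] for this grid and the dataset's unique doses.
#' @inheritParams predict_accumulation
#' @return An object of class `kd_fit`: `best_Kd`, `grid`
#'   (data.frame Kd/error, sorted by Kd), `scheme`, `tie`.
#' @export
grid_search_kd <- function(dataset, scheme = c("noncompetitive", "competitive"),
                           grid = kd_default_grid(),
                           assay = calcein_assay(),
                           params = kinetic_parameters(),
                           drugs = pgp_drug_table(), predictions = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "dose_response_dataset"))
  if (length(grid) == 0L) stop("empty Kd grid", call. = FALSE)
  grid <- sort(grid)
  udoses <- sort(unique(dataset$doses))
  if (is.null(predictions)) {
    tki <- .lookup_drug(drugs, dataset$tki)
    assay <- calcein_assay(substrate = dataset$substrate,
                           sub_ext = assay$sub_ext,
                           pgp_total = assay$pgp_total, atp = assay$atp)
    predictions <- kd_grid_predictions(grid, udoses, tki, scheme, assay, params)
  } else {
    stopifnot(nrow(predictions) == length(grid),
              ncol(predictions) == length(udoses))
  }
  di <- match(dataset$doses, udoses)
  errors <- vapply(seq_along(grid), function(i) {
    rmse(predictions[i, di], dataset$readouts)
  }, numeric(1))
  best <- which.min(errors)
  tie <- sum(abs(errors - errors[best]) < 1e-12) > 1L
  structure(
    list(best_Kd = grid[best],
         grid = data.frame(Kd = grid, error = errors),
         scheme = scheme, tie = tie),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> best Kd = %.3g M (%s scheme, %d grid points%s)\n",
              x$best_Kd, x$scheme, nrow(x$grid),
              if (x$tie) ", tied" else ""))
  invisible(x)
}

#' Write a fit result as JSON
#'
#' Serialises the best estimate plus the full error landscape for audit.
#'
#' @param fit A `kd_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "kd_fit"))
  jsonlite::write_json(
    list(best_Kd_M = fit$best_Kd, scheme = fit$scheme, tie = fit$tie,
         grid = fit$grid),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
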