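## Physical constants. The gas constant is fixed at its physical value in
## kcal/(mol K); Avogadro's number in 1/mol.
.R_KCAL <- 1.9872e-3
.N_AVOGADRO <- 6.02214076e23

#' Thermodynamic context
#'
#' Bundles the temperature and gas constant used for every free-energy to
#' dissociation-constant conversion in the package. The default temperature is
#' physiological (310 K); all docking-derived affinities are converted at this
#' temperature.
#'
#' @param temperature Absolute temperature in kelvin. Must be positive.
#' @return An object of class `thermo_context` with fields `temperature` and
#'   `gas_constant` (kcal mol^-1 K^-1).
#' @examples
#' ctx <- thermo_context()
#' affinity_to_kd(-7.0, ctx) # ~11.6 uM
#' @export
thermo_context <- function(temperature = 310) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive finite number (kelvin)",
         call. = FALSE)
  }
  structure(
    list(temperature = as.numeric(temperature), gas_constant = .R_KCAL),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %g K, R = %g kcal/(mol K), RT = %g kcal/mol\n",
              x$temperature, x$gas_constant, x$gas_constant * x$temperature))
  invisible(x)
}

.rt <- function(ctx) ctx$gas_constant * ctx$temperature

#' Cell geometry
#'
#' Spherical-cell geometry used to convert transporter copy numbers to
#' membrane-phase molarities and to compute compartment volumes. Defaults are
#' the measured dimensions of K562-type cells: radius ~7 um, membrane
#' thickness ~8 nm.
#'
#' @param radius Cell radius in meters.
#' @param membrane_thickness Plasma-membrane thickness in meters. Must satisfy
#'   `0 < membrane_thickness < radius`.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(radius = 7e-6, membrane_thickness = 8e-9) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(membrane_thickness), length(membrane_thickness) == 1L,
            is.finite(membrane_thickness))
  if (!(radius > membrane_thickness && membrane_thickness > 0)) {
    stop("require radius > membrane_thickness > 0", call. = FALSE)
  }
  structure(list(radius = radius, membrane_thickness = membrane_thickness),
            class = "cell_geometry")
}

#' Convert a binding free energy to a dissociation constant
#'
#' Kd = exp(dG / RT) with a 1 M standard state, so dG = -7.0 kcal/mol at
#' 310 K corresponds to Kd = 11.6 uM.
#'
#' @param dG Binding free energy in kcal/mol (negative = favourable).
#' @param ctx A [thermo_context()].
#' @return Dissociation constant in molar.
#' @seealso [kd_to_affinity()] for the inverse.
#' @export
affinity_to_kd <- function(dG, ctx = thermo_context()) {
  if (!is.numeric(dG) || any(!is.finite(dG))) {
    stop("`dG` must be finite (kcal/mol)", call. = FALSE)
  }
  exp(dG / .rt(ctx))
}

#' Convert a dissociation constant to a binding free energy
#'
#' Inverse of [affinity_to_kd()]: dG = RT * log(Kd) with Kd in molar.
#'
#' @param kd Dissociation constant in molar; must be positive (Inf allowed,
#'   mapping to +Inf free energy, i.e. no binding).
#' @param ctx A [thermo_context()].
#' @return Free energy in kcal/mol.
#' @export
kd_to_affinity <- function(kd, ctx = thermo_context()) {
  if (!is.numeric(kd) || any(is.na(kd)) || any(kd <= 0)) {
    stop("`kd` must be positive (molar)", call. = FALSE)
  }
  .rt(ctx) * log(kd)
}

#' Correct an aqueous binding affinity for membrane partitioning
#'
#' Substrates reach the P-gp substrate-binding domain from within the lipid
#' bilayer, where their chemical potential is raised by partitioning:
#' dG_membrane = dG_aqueous + RT * log(PC). For lipophilic compounds
#' (PC > 1) the membrane-phase affinity is therefore weaker (less negative)
#' than the aqueous docking affinity.
#'
#' @param dG_aqueous Docking (aqueous-phase) affinity, kcal/mol.
#' @param pc Octanol/water partition coefficient (dimensionless, > 0).
#' @param ctx A [thermo_context()].
#' @return Membrane-phase binding free energy in kcal/mol.
#' @export
membrane_affinity <- function(dG_aqueous, pc, ctx = thermo_context()) {
  if (!is.numeric(dG_aqueous) || any(!is.finite(dG_aqueous))) {
    stop("`dG_aqueous` must be finite (kcal/mol)", call. = FALSE)
  }
  if (!is.numeric(pc) || any(is.na(pc)) || any(pc <= 0)) {
    stop("`pc` must be positive", call. = FALSE)
  }
  dG_aqueous + .rt(ctx) * log(pc)
}

## Membrane shell volume in liters, thin-shell approximation 4 pi r^2 t.
## At r = 7 um, t = 8 nm the exact shell differs by < 0.2%.
membrane_volume <- function(geom = cell_geometry()) {
  4 * pi * geom$radius^2 * geom$membrane_thickness * 1000
}

#' Cytosol volume of a spherical cell
#'
#' Volume of the sphere enclosed by the membrane, (4/3) pi (r - t)^3,
#' in liters.
#'
#' @param geom A [cell_geometry()].
#' @return Volume in liters.
#' @export
cytosol_volume <- function(geom = cell_geometry()) {
  (4 / 3) * pi * (geom$radius - geom$membrane_thickness)^3 * 1000
}

#' Convert transporter copy number to membrane molarity
#'
#' Treats the plasma membrane as a thin spherical shell of volume
#' 4 pi r^2 t and returns n / (N_A * V_shell). 300 copies in a 7 um cell
#' give ~0.1 uM (drug-sensitive K562); 300,000 give ~100 uM (resistant
#' K562-ADR).
#'
#' @param n_copies Number of transporter molecules per cell (>= 0).
#' @param geom A [cell_geometry()].
#' @return Concentration in molar on the membrane-volume basis.
#' @export
copies_to_membrane_molarity <- function(n_copies, geom = cell_geometry()) {
  if (!is.numeric(n_copies) || any(is.na(n_copies)) || any(n_copies < 0)) {
    stop("`n_copies` must be a non-negative count", call. = FALSE)
  }
  n_copies / (.N_AVOGADRO * membrane_volume(geom))
}

#' Per-compound thermodynamic and transport parameters
#'
#' Collects everything the kinetic model needs to know about one compound:
#' its substrate-site affinity (given either as an aqueous docking free
#' energy, from which the membrane-basis dissociation constant is derived via
#' [membrane_affinity()], or directly as a membrane-basis Kd), its membrane
#' partition coefficient, its nucleotide-binding-domain dissociation constant
#' (Inf = does not bind the NBD), and the first-order passive
#' aqueous-to-membrane exchange rate constant.
#'
#' @param name Compound identifier.
#' @param dG_sbd_aqueous Aqueous docking affinity to the substrate site,
#'   kcal/mol, or `NA` if `Kd_sbd_membrane` is given directly.
#' @param partition_coefficient Octanol/water partition coefficient (> 0).
#' @param Kd_nbd NBD dissociation constant in molar (`Inf` = no NBD binding).
#' @param Kd_sbd_membrane Optional direct membrane-basis SBD Kd in molar;
#'   when `NULL` it is derived from `dG_sbd_aqueous` and
#'   `partition_coefficient`. `Inf` means no SBD binding.
#' @param passive_rate Aqueous-to-membrane exchange rate constant, s^-1.
#' @param ctx A [thermo_context()].
#' @return An object of class `drug_params`.
#' @examples
#' nilo <- drug_params("nilotinib", -11.1, 25704, Kd_nbd = 2e-9)
#' nilo$Kd_sbd_membrane # ~3.8e-4 M
#' @export
drug_params <- function(name, dG_sbd_aqueous = NA_real_, partition_coefficient,
                        Kd_nbd = Inf, Kd_sbd_membrane = NULL,
                        passive_rate = 1, ctx = thermo_context()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(partition_coefficient) || length(partition_coefficient) != 1L ||
      is.na(partition_coefficient) || partition_coefficient <= 0) {
    stop("`partition_coefficient` must be positive", call. = FALSE)
  }
  if (!is.numeric(Kd_nbd) || length(Kd_nbd) != 1L || is.na(Kd_nbd) || Kd_nbd <= 0) {
    stop("`Kd_nbd` must be > 0 (molar) or Inf", call. = FALSE)
  }
  if (is.null(Kd_sbd_membrane)) {
    if (is.na(dG_sbd_aqueous)) {
      stop("give either `dG_sbd_aqueous` or `Kd_sbd_membrane`", call. = FALSE)
    }
    dG_mem <- membrane_affinity(dG_sbd_aqueous, partition_coefficient, ctx)
    Kd_sbd_membrane <- affinity_to_kd(dG_mem, ctx)
  } else {
    if (!is.numeric(Kd_sbd_membrane) || length(Kd_sbd_membrane) != 1L ||
        is.na(Kd_sbd_membrane) || Kd_sbd_membrane <= 0) {
      stop("`Kd_sbd_membrane` must be > 0 (molar) or Inf", call. = FALSE)
    }
  }
  if (!is.numeric(passive_rate) || length(passive_rate) != 1L ||
      !is.finite(passive_rate) || passive_rate <= 0) {
    stop("`passive_rate` must be a positive rate (s^-1)", call. = FALSE)
  }
  structure(
    list(name = name,
         dG_sbd_aqueous = as.numeric(dG_sbd_aqueous),
         partition_coefficient = as.numeric(partition_coefficient),
         Kd_nbd = as.numeric(Kd_nbd),
         Kd_sbd_membrane = as.numeric(Kd_sbd_membrane),
         passive_rate = as.numeric(passive_rate)),
    class = "drug_params"
  )
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s: Kd_sbd(mem) = %.3g M, Kd_nbd = %.3g M, PC = %g\n",
              x$name, x$Kd_sbd_membrane, x$Kd_nbd, x$partition_coefficient))
  invisible(x)
}

#' Read a drug parameter table
#'
#' Reads a CSV with columns `name`, `dG_sbd_aqueous_kcal_mol`,
#' `partition_coefficient`, `Kd_nbd_M` (and optionally `pc_source`) and
#' returns a named list of [drug_params()] objects. `Kd_nbd_M` may be the
#' string `"Inf"` for compounds that do not bind the NBD. A row named
#' `"atp"` is allowed to omit the partition coefficient; it only contributes
#' its NBD (nucleotide-site) dissociation constant.
#'
#' @param path Path to the CSV file.
#' @param ctx A [thermo_context()].
#' @param passive_rate Passive exchange rate constant applied to every
#'   compound, s^-1.
#' @return Named list of `drug_params`, plus attribute `Kd_atp` (molar) if an
#'   `atp` row is present.
#' @export
read_drug_table <- function(path, ctx = thermo_context(), passive_rate = 1) {
  if (!file.exists(path)) stop("drug table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "dG_sbd_aqueous_kcal_mol", "partition_coefficient",
                "Kd_nbd_M")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("drug table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drugs <- list()
  kd_atp <- NULL
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    kd_nbd <- suppressWarnings(as.numeric(row$Kd_nbd_M))
    if (is.na(kd_nbd)) kd_nbd <- Inf
    if (identical(tolower(row$name), "atp")) {
      kd_atp <- kd_nbd
      next
    }
    drugs[[row$name]] <- drug_params(
      name = row$name,
      dG_sbd_aqueous = as.numeric(row$dG_sbd_aqueous_kcal_mol),
      partition_coefficient = as.numeric(row$partition_coefficient),
      Kd_nbd = kd_nbd,
      passive_rate = passive_rate,
      ctx = ctx
    )
  }
  if (!is.null(kd_atp)) attr(drugs, "Kd_atp") <- kd_atp
  drugs
}

#' Bundled drug parameter table
#'
#' Returns the parameters used throughout the published analysis: docking
#' affinities and partition coefficients for nilotinib, imatinib, dasatinib
#' and paclitaxel, fitted NBD dissociation constants (2 nM / 200 nM /
#' 250 nM), and the docked ATP nucleotide-site Kd (11.6 uM).
#'
#' @param ctx A [thermo_context()].
#' @param passive_rate Passive exchange rate constant, s^-1.
#' @return As [read_drug_table()].
#' @export
pgp_drug_table <- function(ctx = thermo_context(), passive_rate = 1) {
  path <- system.file("extdata", "drug_params.csv", package = "pgpflux",
                      mustWork = TRUE)
  read_drug_table(path, ctx = ctx, passive_rate = passive_rate)
}
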