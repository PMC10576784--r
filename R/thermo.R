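#' Thermodynamic constants for affinity-to-free-energy conversion
#'
#' Bundles the Boltzmann constant (in kcal mol^-1 K^-1) and the assay
#' temperature used by every conversion in the package. All binding
#' free energies are reported in kcal mol^-1 at this temperature.
#'
#' @param temperature Assay temperature in kelvin. Defaults to 300 K, the
#'   temperature at which affinity ratios are conventionally converted to
#'   free energies in benchmarking studies.
#' @param boltzmann Boltzmann constant in kcal mol^-1 K^-1. Fixed at
#'   1.9872e-3; exposed only so the unit system is explicit.
#'
#' @return An object of class `thermo_constants`: a list with elements
#'   `boltzmann_kcal`, `temperature`, and the derived product `kT`
#'   (kcal mol^-1).
#' @examples
#' tc <- thermo_constants()
#' tc$kT # 0.59616 kcal/mol at 300 K
#' @export
thermo_constants <- function(temperature = 300, boltzmann = 1.9872e-3) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)", call. = FALSE)
  }
  structure(
    list(
      boltzmann_kcal = boltzmann,
      temperature = temperature,
      kT = boltzmann * temperature
    ),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat(sprintf(
    "<thermo_constants> T = %g K, kB = %g kcal/mol/K, kT = %.5f kcal/mol\n",
    x$temperature, x$boltzmann_kcal, x$kT
  ))
  invisible(x)
}

valid_measure_types <- c("Kd", "Ki", "IC50")
valid_qualifiers <- c("eq", "lt", "gt")

#' Absolute binding free energy from a measured affinity
#'
#' Converts a molar affinity (Kd, Ki or IC50) to an absolute binding free
#' energy dG = kT * ln(X). For IC50 measurements the result is known only
#' up to an assay-specific additive constant; rank and relative metrics are
#' unaffected, but absolute-scale comparisons across assays should not be
#' made from IC50-derived dG values.
#'
#' @param value Numeric vector of affinities in molar units; strictly
#'   positive.
#' @param constants A [thermo_constants()] object.
#' @return Numeric vector of free energies in kcal mol^-1.
#' @examples
#' abs_dg(1e-9) # a 1 nM binder, about -12.35 kcal/mol
#' @seealso [rel_ddg()] for ligand-pair differences.
#' @export
abs_dg <- function(value, constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  if (length(value) == 0L) return(numeric(0))
  if (anyNA(value) || !is.numeric(value) || any(value <= 0)) {
    stop("affinity `value` must be strictly positive (molar)", call. = FALSE)
  }
  constants$kT * log(value)
}

#' Relative binding free energy between two ligands
#'
#' Computes ddG_ab = -kT * ln(X_b / X_a) from two affinities measured in the
#' same assay. Under this sign convention ddG_ab = dG_a - dG_b, where
#' dG = kT ln(X). The ratio assumption (IC50, Ki and Kd ratios agree) makes
#' the result independent of the measure type when both measurements share
#' one; mixed measure types are refused unless `allow_mixed = TRUE`.
#'
#' @param value_a,value_b Positive molar affinities for ligands a and b.
#' @param constants A [thermo_constants()] object.
#' @param measure_type_a,measure_type_b Optional measure types
#'   (`"Kd"`, `"Ki"`, `"IC50"`) used to enforce same-type ratios.
#' @param allow_mixed Set `TRUE` to permit a ratio across measure types
#'   (admissible for many, but not all, inhibitory mechanisms).
#' @return ddG_ab in kcal mol^-1; antisymmetric in its arguments.
#' @examples
#' rel_ddg(10e-9, 100e-9) # 10x weaker b: -1.37 kcal/mol
#' @export
rel_ddg <- function(value_a, value_b, constants = thermo_constants(),
                    measure_type_a = NULL, measure_type_b = NULL,
                    allow_mixed = FALSE) {
  if (!is.null(measure_type_a) || !is.null(measure_type_b)) {
    if (is.null(measure_type_a) || is.null(measure_type_b)) {
      stop("provide both measure types or neither", call. = FALSE)
    }
    if (!allow_mixed && any(measure_type_a != measure_type_b)) {
      stop(
        "mixed measure types in an affinity ratio; set `allow_mixed = TRUE` ",
        "to opt in to the cross-type ratio assumption",
        call. = FALSE
      )
    }
  }
  abs_dg(value_a, constants) - abs_dg(value_b, constants)
}

#' Convert a pKi-scale quantity to kcal/mol
#'
#' One pKi unit is a tenfold change in affinity, worth ln(10) * kT in free
#' energy. Used to translate literature error estimates quoted in pKi units
#' (e.g. repeatability standard deviations) into kcal mol^-1.
#'
#' @param p Non-negative numeric vector in pKi units.
#' @param constants A [thermo_constants()] object.
#' @return Free-energy magnitudes in kcal mol^-1, linear in `p`.
#' @examples
#' pki_to_kcal(0.3) # ~0.41 kcal/mol
#' @export
pki_to_kcal <- function(p, constants = thermo_constants()) {
  if (anyNA(p) || !is.numeric(p) || any(p < 0)) {
    stop("`p` must be non-negative (pKi units)", call. = FALSE)
  }
  log(10) * constants$kT * p
}

#' Propagate an absolute-dG RMSE to a pairwise-ddG RMSE
#'
#' If per-compound dG errors are unbiased, Gaussian and independent, the
#' error of a difference of two dG values has standard deviation sqrt(2)
#' times the per-compound value. This converts absolute-scale reproducibility
#' estimates into the pairwise RMSE scale used for ddG benchmarking.
#'
#' @param sigma Non-negative RMSE of absolute binding free energies
#'   (kcal mol^-1).
#' @return `sqrt(2) * sigma`, the implied pairwise RMSE.
#' @examples
#' abs_rmse_to_pairwise_rmse(0.95) # ~1.34
#' @export
abs_rmse_to_pairwise_rmse <- function(sigma) {
  if (anyNA(sigma) || !is.numeric(sigma) || any(sigma < 0)) {
    stop("`sigma` must be non-negative (kcal/mol)", call. = FALSE)
  }
  sqrt(2) * sigma
}
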