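#' Conversion constants for radiolabel quantification
#'
#' Bundles the tracer specific activity and the carbon-mass conventions used
#' to turn scintillation counts into carbon amounts and pool masses. Carbon
#' is assumed to make up 40% of the weight of starch and 80% of the weight of
#' triacylglycerol (TAG); both fractions are overridable.
#'
#' @param specific_activity Tracer specific activity in dpm per micromole of
#'   labeled substrate. Must be a single positive number.
#' @param carbon_mass_fraction_starch Mass fraction of carbon in starch
#'   (dimensionless, in (0, 1]). Default 0.40.
#' @param carbon_mass_fraction_tag Mass fraction of carbon in TAG
#'   (dimensionless, in (0, 1]). Default 0.80.
#' @param carbon_atomic_mass Mass of one mole of tracer carbon in g/mol.
#'   Default 12.0: the tracer bookkeeping counts carbon atoms, and 12.0
#'   reproduces published starch/TAG mass conversions at their printed
#'   precision (12.011 does not; see the methods vignette).
#'
#' @return An object of class `conversion_constants`.
#' @examples
#' cc <- conversion_constants(specific_activity = 2220)
#' counts_to_carbon(4440, cc)  # 2000 nmol C per 1e6 cells
#' @export
conversion_constants <- function(specific_activity,
                                 carbon_mass_fraction_starch = 0.40,
                                 carbon_mass_fraction_tag = 0.80,
                                 carbon_atomic_mass = 12.0) {
  if (!is.numeric(specific_activity) || length(specific_activity) != 1L ||
      !is.finite(specific_activity) || specific_activity <= 0) {
    stop_config("specific_activity must be a single finite number > 0 (got %s)",
                format(specific_activity))
  }
  for (nm in c("carbon_mass_fraction_starch", "carbon_mass_fraction_tag")) {
    f <- get(nm)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f > 1) {
      stop_config("%s must lie in (0, 1] (got %s)", nm, format(f))
    }
  }
  if (!is.numeric(carbon_atomic_mass) || carbon_atomic_mass <= 0) {
    stop_config("carbon_atomic_mass must be > 0")
  }
  structure(
    list(specific_activity = specific_activity,
         carbon_mass_fraction_starch = carbon_mass_fraction_starch,
         carbon_mass_fraction_tag = carbon_mass_fraction_tag,
         carbon_atomic_mass = carbon_atomic_mass),
    class = "conversion_constants"
  )
}

#' @export
print.conversion_constants <- function(x, ...) {
  cat("Conversion constants\n")
  cat(sprintf("  specific activity : %g dpm/umol\n", x$specific_activity))
  cat(sprintf("  carbon fraction   : starch %.2f, TAG %.2f\n",
              x$carbon_mass_fraction_starch, x$carbon_mass_fraction_tag))
  cat(sprintf("  carbon mass       : %g g/mol\n", x$carbon_atomic_mass))
  invisible(x)
}

#' Convert scintillation counts to carbon amounts
#'
#' Divides counts by the tracer specific activity to obtain micromoles of
#' labeled carbon, reported as nmol C per 10^6 cells. The conversion is
#' linear in `dpm`.
#'
#' @param dpm Counts in dpm per 10^6 cells; non-negative, may be a vector.
#' @param constants A [conversion_constants()] object.
#' @return Carbon amount(s) in nmol C per 10^6 cells.
#' @export
counts_to_carbon <- function(dpm, constants) {
  stopifnot(inherits(constants, "conversion_constants"))
  if (!is.numeric(dpm) || any(!is.finite(dpm)) || any(dpm < 0)) {
    stop_input("dpm must be finite and >= 0")
  }
  dpm / constants$specific_activity * 1000
}

#' Convert a carbon amount to a pool mass
#'
#' `mass = carbon * atomic_mass * 1e-3 / fraction`, giving micrograms per
#' 10^6 cells from nmol C per 10^6 cells. Exact inverse of
#' [mass_to_carbon()].
#'
#' @param carbon Carbon amount in nmol C per 10^6 cells (non-negative).
#' @param fraction Carbon mass fraction of the pool, in (0, 1] (0.40 for
#'   starch, 0.80 for TAG).
#' @param atomic_mass Carbon atomic mass in g/mol (default 12.0).
#' @return Mass in micrograms per 10^6 cells.
#' @examples
#' carbon_to_mass(765, 0.40)   # ~23 ug starch
#' carbon_to_mass(1850, 0.40)  # 55.5 ug starch
#' @export
carbon_to_mass <- function(carbon, fraction, atomic_mass = 12.0) {
  check_fraction(fraction)
  if (!is.numeric(carbon) || any(!is.finite(carbon)) || any(carbon < 0)) {
    stop_input("carbon must be finite and >= 0")
  }
  carbon * atomic_mass * 1e-3 / fraction
}

#' Convert a pool mass to a carbon amount
#'
#' Inverse of [carbon_to_mass()]: nmol C per 10^6 cells from micrograms per
#' 10^6 cells.
#'
#' @param mass Mass in micrograms per 10^6 cells (non-negative).
#' @inheritParams carbon_to_mass
#' @return Carbon amount in nmol C per 10^6 cells.
#' @export
mass_to_carbon <- function(mass, fraction, atomic_mass = 12.0) {
  check_fraction(fraction)
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass < 0)) {
    stop_input("mass must be finite and >= 0")
  }
  mass * fraction / (atomic_mass * 1e-3)
}

check_fraction <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop_config("fraction must lie in (0, 1] (got %s)", format(fraction))
  }
  invisible(fraction)
}

#' Round for reporting, half away from zero
#'
#' Reported tables use one-decimal rounding with ties going away from zero
#' (base `round()` rounds half to even). Used only at the reporting layer;
#' computations are carried at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
report_round <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
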