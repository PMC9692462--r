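#' Energy units and conversion
#'
#' All internal arithmetic in radaudit is carried out in kJ/mol; unit
#' conversion happens only at input/output boundaries.  The conversion
#' constants are fixed to the values conventionally used in computational
#' thermochemistry: 1 hartree = 2625.49964 kJ/mol, 1 kcal = 4.184 kJ
#' (thermochemical calorie), 1 eV = 96.48533 kJ/mol.
#'
#' @name units
NULL

#' Physical constants used throughout the package
#'
#' @return Named list with `hartree_in_kJ_per_mol`, `kcal_in_kJ`,
#'   `eV_in_kJ_per_mol`, `temperature_K` (fixed at 298.15) and
#'   `h_atom_thermal_correction_hartree` (0.002361, the translational +
#'   pV thermal correction added to the electronic energy of the H atom
#'   at 298.15 K).
#' @export
energy_constants <- function() {
  list(
    hartree_in_kJ_per_mol = 2625.49964,
    kcal_in_kJ = 4.184,
    eV_in_kJ_per_mol = 96.48533,
    temperature_K = 298.15,
    h_atom_thermal_correction_hartree = 0.002361
  )
}

#' Recognized energy units
#' @return Character vector of the closed unit enumeration.
#' @export
energy_units <- function() c("hartree", "kJ/mol", "kcal/mol", "eV")

# kJ/mol per one unit of each member of the enumeration
.unit_in_kj <- function(unit) {
  cc <- energy_constants()
  switch(unit,
    "hartree"  = cc$hartree_in_kJ_per_mol,
    "kJ/mol"   = 1,
    "kcal/mol" = cc$kcal_in_kJ,
    "eV"       = cc$eV_in_kJ_per_mol,
    stop("unknown energy unit: '", unit, "' (expected one of ",
         paste(energy_units(), collapse = ", "), ")", call. = FALSE)
  )
}

.check_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1 || !(unit %in% energy_units()))
    stop("unknown energy unit: '", paste(unit, collapse = ","),
         "' (expected one of ", paste(energy_units(), collapse = ", "), ")",
         call. = FALSE)
  unit
}

#' Create an energy value with an explicit unit
#'
#' @param magnitude Finite numeric scalar (or vector).
#' @param unit One of `energy_units()`.
#' @return An object of class `energy_value`: numeric with a `unit` attribute.
#' @examples
#' x <- energy_value(1, "hartree")
#' convert_energy(x, "kJ/mol")
#' @export
energy_value <- function(magnitude, unit) {
  .check_unit(unit)
  if (!is.numeric(magnitude) || any(!is.finite(magnitude)))
    stop("energy magnitude must be finite numeric", call. = FALSE)
  structure(as.numeric(magnitude), unit = unit, class = "energy_value")
}

#' @export
print.energy_value <- function(x, ...) {
  cat(format(unclass(x)), attr(x, "unit"), "\n")
  invisible(x)
}

#' Convert an energy value between units
#'
#' Conversion is exact (a single multiplicative factor through kJ/mol);
#' converting to the same unit is the identity.
#'
#' @param value An `energy_value`, or a plain numeric (then `from` is
#'   required).
#' @param to Target unit.
#' @param from Source unit when `value` is a plain numeric.
#' @return An `energy_value` in `to`.
#' @export
convert_energy <- function(value, to, from = NULL) {
  if (inherits(value, "energy_value")) {
    from <- attr(value, "unit")
    value <- unclass(value)
  }
  if (is.null(from)) stop("'from' unit required for plain numeric input", call. = FALSE)
  .check_unit(from); .check_unit(to)
  if (any(!is.finite(value)))
    stop("cannot convert non-finite energy value", call. = FALSE)
  if (identical(from, to)) return(energy_value(value, to))
  energy_value(value * .unit_in_kj(from) / .unit_in_kj(to), to)
}

#' H-atom enthalpy at 298.15 K from its electronic energy
#'
#' Adds the standard thermal correction of 0.002361 hartree (identical for
#' all model chemistries at 298.15 K) to the electronic energy.
#'
#' @param electronic_energy_hartree Finite numeric scalar, in hartree.
#' @return `energy_value` in hartree.
#' @export
h_atom_enthalpy <- function(electronic_energy_hartree) {
  if (!is.numeric(electronic_energy_hartree) ||
      any(!is.finite(electronic_energy_hartree)))
    stop("electronic energy must be finite numeric", call. = FALSE)
  energy_value(electronic_energy_hartree +
                 energy_constants()$h_atom_thermal_correction_hartree, "hartree")
}

#' Round the way thermochemistry tables print
#'
#' Rounds half away from zero (not banker's rounding) with a relative
#' epsilon guard of 1e-9 applied before rounding, so that values such as
#' 164.84999999999997 (a binary artifact of 164.85) round up as a human
#' transcribing the table would round them.
#'
#' @param value Numeric.
#' @param decimals Non-negative integer count of printed decimals.
#' @return Numeric rounded to `decimals`.
#' @export
round_printed <- function(value, decimals) {
  if (length(decimals) != 1 || decimals < 0)
    stop("decimals must be a single non-negative integer", call. = FALSE)
  guarded <- abs(value) * (1 + 1e-9)
  sign(value) * floor(guarded * 10^decimals + 0.5) / 10^decimals
}
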