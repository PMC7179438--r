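#' Convert EC50 (nM) to pEC50
#'
#' pEC50 is the negative decadic logarithm of the half-maximal effective
#' concentration expressed in mol/L. With EC50 given in nanomolar this is
#' `9 - log10(ec50_nM)`; larger pEC50 means a more potent agonist.
#'
#' @param ec50_nM Positive EC50 values in nanomolar (vectorised).
#' @return pEC50 values (dimensionless, molar scale).
#' @examples
#' ec50_to_pec50(c(0.66, 1, 2242))
#' @export
ec50_to_pec50 <- function(ec50_nM) {
  if (any(is.na(ec50_nM)) || any(ec50_nM <= 0)) {
    abort("ec50_nM must be positive and non-missing")
  }
  9 - log10(ec50_nM)
}

#' Convert pEC50 back to EC50 (nM)
#'
#' Exact inverse of [ec50_to_pec50()]: `10^(9 - pec50)`.
#'
#' @param pec50 pEC50 values (vectorised).
#' @return EC50 in nanomolar.
#' @export
pec50_to_ec50 <- function(pec50) {
  10^(9 - pec50)
}

#' Convert an inhibition constant Ki (nM) to binding free energy
#'
#' Computes `deltaG = R * T * ln(Ki)` with Ki expressed in mol/L, the
#' standard relation between an equilibrium inhibition constant and the
#' binding free energy. Negative for sub-molar Ki; more negative means
#' tighter binding.
#'
#' @param ki_nM Positive Ki values in nanomolar (vectorised).
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @param gas_constant Gas constant in kcal mol^-1 K^-1 (default
#'   1.987e-3).
#' @return Binding free energy in kcal/mol.
#' @examples
#' ki_to_delta_g(4.75) # approx -11.35 kcal/mol
#' @export
ki_to_delta_g <- function(ki_nM, temperature = 298.15, gas_constant = 1.987e-3) {
  if (any(is.na(ki_nM)) || any(ki_nM <= 0)) abort("ki_nM must be positive")
  if (temperature <= 0) abort("temperature must be positive (kelvin)")
  gas_constant * temperature * log(ki_nM * 1e-9)
}

#' Fill in pEC50 from measured EC50 in a compound table
#'
#' Adds (or completes) the `pec50` column from `ec50_nM` using
#' [ec50_to_pec50()]. Rows without an EC50 keep their existing `pec50`
#' (or `NA`). Existing pEC50 values are never overwritten.
#'
#' @param table A compound tibble with an `ec50_nM` column.
#' @return The table with a complete-as-possible `pec50` column.
#' @examples
#' a2a_training() %>% convert_activity()
#' @export
convert_activity <- function(table) {
  if (!"ec50_nM" %in% names(table)) abort("table has no 'ec50_nM' column")
  if (!"pec50" %in% names(table)) table$pec50 <- NA_real_
  fill <- is.na(table$pec50) & !is.na(table$ec50_nM)
  table$pec50[fill] <- ec50_to_pec50(table$ec50_nM[fill])
  table
}
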