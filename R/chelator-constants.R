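#' Load a metal-ligand stability-constant table
#'
#' Reads a TSV of chelator stability constants. Each row is one
#' (ligand, metal) pair carrying: `logK_ML`, the stability constant of the
#' unprotonated complex (M + L = ML); `logK_MHL`, the constant of the
#' monoprotonated complex formed from the monoprotonated ligand
#' (M + HL = MHL); the ligand protonation `pKas` (semicolon-separated,
#' strictly decreasing, most basic first); an optional reaction enthalpy
#' `dH_ML_kJmol` for van't Hoff temperature correction; and the reference
#' ionic strength and temperature at which the constants are stated.
#'
#' The packaged table covers EGTA with Ca2+, Mg2+ and Ba2+, transcribed from
#' the NIST-derived values used throughout the calcium-buffer literature
#' (reference conditions 0.1 M ionic strength, 20 degrees C).
#'
#' @param file path to a TSV; default is the packaged table.
#' @return a data.frame of class `binding_constants`.
#' @export
binding_constants <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "stability_constants.tsv", package = "shieldfit")
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  needed <- c("ligand", "metal", "logK_ML", "logK_MHL", "pKas",
              "ref_ionic_strength", "ref_temperature_C")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stop("constants table missing columns: ", paste(miss, collapse = ", "))
  if (!"dH_ML_kJmol" %in% names(tab)) tab$dH_ML_kJmol <- NA_real_
  for (i in seq_len(nrow(tab))) {
    pk <- pka_list(tab$pKas[i])
    if (any(!is.finite(pk)) || any(diff(pk) >= 0))
      stop("pKa list must be finite and strictly decreasing for ",
           tab$metal[i], "-", tab$ligand[i])
    if (!is.finite(tab$logK_ML[i]))
      stop("non-finite logK_ML for ", tab$metal[i], "-", tab$ligand[i])
  }
  class(tab) <- c("binding_constants", "data.frame")
  tab
}

pka_list <- function(s) as.numeric(strsplit(s, ";")[[1]])

# Davies-type single-ion activity function F(I) = A(T) (sqrt(I)/(1+sqrt(I)) - 0.3 I),
# with the Debye-Huckel limiting slope A as a quadratic in Celsius temperature.
davies_f <- function(ionic_strength, temperature) {
  tC <- temperature - 273.15
  A <- 0.4918 + 6.6098e-4 * tC + 5.0231e-6 * tC^2
  A * (sqrt(ionic_strength) / (1 + sqrt(ionic_strength)) - 0.3 * ionic_strength)
}

# Shift an association logK from reference to target ionic strength.
# dz2 = sum of squared charges of reactants minus product.
adjust_logK_I <- function(logK, dz2, I, I_ref, temperature) {
  logK - dz2 * (davies_f(I, temperature) - davies_f(I_ref, temperature))
}

# van't Hoff shift of logK from T_ref to T given reaction enthalpy (kJ/mol).
adjust_logK_T <- function(logK, dH_kJmol, temperature, t_ref) {
  if (is.na(dH_kJmol)) return(logK)
  logK - dH_kJmol * 1000 / (.Rgas * log(10)) * (1 / temperature - 1 / t_ref)
}

# Ligand charge is inferred from the number of acidic protons (EGTA: 4 -> L^4-).
# Squared-charge sums for the Davies shift of each association step:
#   M2+ + L(n-)  -> ML(n-2)-    : 4 + n^2 - (n-2)^2 = 4n
#   M2+ + HL(n-1)- -> MHL(n-3)- : 4 + (n-1)^2 - (n-3)^2 = 4n - 4
#   H+ + H_(k-1)L -> H_k L      : 1 + (n-k+1)^2 - (n-k)^2 = 2(n-k) + 2
corrected_record <- function(rec, ionic_strength, temperature) {
  pk <- pka_list(rec$pKas)
  n <- length(pk)
  I_ref <- rec$ref_ionic_strength
  t_ref <- rec$ref_temperature_C + 273.15
  pk_adj <- vapply(seq_len(n), function(k) {
    adjust_logK_I(pk[k], 2 * (n - k) + 2, ionic_strength, I_ref, temperature)
  }, numeric(1))
  logK_ML <- adjust_logK_I(rec$logK_ML, 4 * n, ionic_strength, I_ref, temperature)
  logK_ML <- adjust_logK_T(logK_ML, rec$dH_ML_kJmol, temperature, t_ref)
  logK_MHL <- if (is.finite(rec$logK_MHL))
    adjust_logK_I(rec$logK_MHL, 4 * n - 4, ionic_strength, I_ref, temperature)
  else -Inf
  list(pKa = pk_adj, logK_ML = logK_ML, logK_MHL = logK_MHL)
}

#' Apparent (conditional) association constant of a metal-ligand pair
#'
#' Computes the pH-conditional association constant K_app between a metal and
#' the pool of unbound ligand (all protonation states), after adjusting the
#' tabulated constants to the requested ionic strength (Davies-type
#' correction) and temperature (van't Hoff, when an enthalpy is tabulated):
#'
#'   K_app = (K_ML + K_MHL * h1) / alpha_H
#'
#' with h1 = \[HL\]/\[L\] and alpha_H the ligand protonation polynomial at the
#' given pH. K_app is monotone increasing in pH below the top pKa, and tends
#' to K_ML when no protons compete.
#'
#' @param record one row of a [binding_constants()] table (or the table plus
#'   `metal`/`ligand` names to select the row).
#' @param pH solution pH.
#' @param ionic_strength molar-scale ionic strength (e.g. 0.073).
#' @param temperature kelvin (accepts `"20C"` style tags).
#' @param metal,ligand optional row selectors when `record` is a full table.
#' @return apparent association constant, per molar.
#' @export
apparent_constant <- function(record, pH, ionic_strength, temperature,
                              metal = NULL, ligand = NULL) {
  if (!is.null(metal) || !is.null(ligand)) {
    i <- which(record$metal == metal & record$ligand == ligand)
    if (length(i) != 1)
      stop("no stability-constant record for (", metal, ", ", ligand, ")")
    record <- record[i, , drop = FALSE]
  }
  if (nrow(record) != 1) stop("record must be a single row")
  if (pH <= 0 || pH >= 14) stop("pH out of range (0, 14)")
  if (ionic_strength <= 0) stop("ionic strength must be positive")
  temperature <- parse_temp(temperature)
  if (temperature < 273 || temperature > 320)
    stop("temperature out of supported range [273, 320] K")
  cr <- corrected_record(record, ionic_strength, temperature)
  H <- 10^(-pH)
  cum_pk <- cumsum(cr$pKa)
  alpha_H <- 1 + sum(10^(seq_along(cum_pk) * (-pH) + cum_pk))
  h1 <- H * 10^cr$pKa[1]
  (10^cr$logK_ML + 10^cr$logK_MHL * h1) / alpha_H
}
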