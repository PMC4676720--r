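#' Parse a concentration with an explicit unit tag
#'
#' Accepts numbers tagged with one of `M`, `mM`, `uM` (or `µM`), `nM`,
#' `pM`, e.g. `"3mM"` or `"16.4 uM"`. Bare numerics are taken to already be
#' molar. Vectorized.
#'
#' @param x character or numeric vector.
#' @return numeric vector of concentrations in molar.
#' @examples
#' parse_conc(c("3mM", "50 uM", "1e-7"))
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  scales <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)
  out <- vapply(as.character(x), function(s) {
    s0 <- trimws(s)
    m <- regmatches(s0, regexec("^([-+0-9.eE]+)\\s*([A-Za-zµ]*)$", s0))[[1]]
    if (length(m) == 0 || m[2] == "")
      stop("cannot parse concentration '", s, "'", call. = FALSE)
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) stop("cannot parse concentration '", s, "'", call. = FALSE)
    unit <- m[3]
    if (unit == "") return(val)
    if (!unit %in% names(scales))
      stop("unknown concentration unit '", unit, "' in '", s, "'", call. = FALSE)
    val * scales[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Parse a temperature with an explicit unit tag
#'
#' Accepts `"20C"`, `"293.15K"`, or a bare numeric (kelvin).
#'
#' @param x character or numeric scalar/vector.
#' @return numeric vector of temperatures in kelvin.
#' @export
parse_temp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    s0 <- trimws(s)
    m <- regmatches(s0, regexec("^([-+0-9.eE]+)\\s*([CcKk]?)$", s0))[[1]]
    if (length(m) == 0) stop("cannot parse temperature '", s, "'", call. = FALSE)
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) stop("cannot parse temperature '", s, "'", call. = FALSE)
    if (m[3] %in% c("C", "c")) val + 273.15 else val
  }, numeric(1), USE.NAMES = FALSE)
}

# CODATA physical constants used by the Boltzmann accumulation factor.
.kB <- 1.380649e-23    # J/K
.qe <- 1.602176634e-19 # C
.Rgas <- 8.31446261815324 # J/mol/K

#' Thermal voltage kB*T/q
#' @param temperature kelvin.
#' @return volts.
#' @keywords internal
thermal_voltage <- function(temperature) .kB * temperature / .qe
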