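#' Describe a shielding cation
#'
#' A cation is characterized by its valence `z`, a size/charge-separation
#' factor `Y` (1 for small inorganic ions; < 1 for bulky organic polycations
#' whose accumulation is limited by crowding and by charge spread across the
#' molecule), and an association constant `K` describing chemical binding to
#' the substrate on the effective-concentration scale.
#'
#' @param name cation name.
#' @param z positive integer valence.
#' @param Y dimensionless factor in (0, 1].
#' @param K association constant, per molar (>= 0).
#' @param plateau_capable logical; whether a residual unshieldable-substrate
#'   plateau (`W`) applies to this cation (neomycin in the default set).
#' @return an object of class `cation_spec`.
#' @examples
#' cation_spec("Mg", z = 2, Y = 1, K = 1)
#' @export
cation_spec <- function(name, z, Y = 1, K = 0, plateau_capable = FALSE) {
  if (!(is.numeric(z) && length(z) == 1 && z >= 1 && z == round(z)))
    stop("z must be a positive integer valence")
  if (!(Y > 0 && Y <= 1)) stop("Y must lie in (0, 1]")
  if (K < 0) stop("K must be non-negative")
  structure(list(name = name, z = as.integer(z), Y = Y, K = K,
                 plateau_capable = isTRUE(plateau_capable)),
            class = "cation_spec")
}

#' @export
print.cation_spec <- function(x, ...) {
  cat(sprintf("Cation %s: z = %d, Y = %g, K = %g /M%s\n", x$name, x$z, x$Y,
              x$K, if (x$plateau_capable) " (plateau-capable)" else ""))
  invisible(x)
}

#' Shielding-model parameter set
#'
#' Houses the fixed quantities of the charge-shielding model: the local
#' electrostatic potential `psi` at the substrate (volts, negative),
#' temperature, the reference half-maximal effective cation concentration
#' `L_ref` anchored at valence `z_ref`, the total substrate concentration,
#' the unshieldable residual substrate `W`, and the effective
#' enzyme-substrate dissociation constant `Kd`.
#'
#' For a cation of valence z the half-maximal constant is scaled as
#' L_z = L_ref * z_ref / z (valence-proportional, using nominal z). A
#' different rule can be plugged in through `L_scale`.
#'
#' @param psi local potential in volts (default -0.025).
#' @param temperature kelvin (default 295.15, room temperature).
#' @param L_ref reference half-maximal effective concentration, molar.
#' @param z_ref valence anchor for `L_ref` (default 2).
#' @param pip2_total total substrate concentration, molar.
#' @param W unshieldable residual substrate, molar (0 <= W < pip2_total).
#' @param Kd effective enzyme-substrate dissociation constant, molar.
#' @param L_scale function(L_ref, z_ref, z) returning the valence-scaled L;
#'   default is valence-proportional reduction.
#' @return an object of class `shielding_params`.
#' @export
shielding_params <- function(psi = -0.025, temperature = 295.15,
                             L_ref = 32e-3, z_ref = 2,
                             pip2_total = 30e-6, W = 0, Kd = 50e-6,
                             L_scale = NULL) {
  if (psi > 0) stop("psi must be <= 0 for a polyanionic substrate")
  if (temperature <= 0) stop("temperature must be positive")
  if (L_ref <= 0) stop("L_ref must be positive")
  if (!(W >= 0 && W < pip2_total)) stop("W must lie in [0, pip2_total)")
  if (Kd <= 0) stop("Kd must be positive")
  if (is.null(L_scale)) L_scale <- function(L_ref, z_ref, z) L_ref * z_ref / z
  structure(list(psi = psi, temperature = temperature, L_ref = L_ref,
                 z_ref = z_ref, pip2_total = pip2_total, W = W, Kd = Kd,
                 L_scale = L_scale),
            class = "shielding_params")
}

#' @export
print.shielding_params <- function(x, ...) {
  cat(sprintf(paste0("Shielding parameters: psi = %g mV, T = %g K, ",
                     "L_ref = %g mM (z_ref = %d)\n  pip2_total = %g uM, ",
                     "W = %g uM, Kd = %g uM\n"),
              x$psi * 1e3, x$temperature, x$L_ref * 1e3, x$z_ref,
              x$pip2_total * 1e6, x$W * 1e6, x$Kd * 1e6))
  invisible(x)
}

#' Load the packaged default parameter set and cation table
#'
#' The packaged YAML carries the model defaults (psi = -25 mV, L_ref = 32 mM
#' anchored at z = 2, total substrate 30 uM, Kd = 50 uM) and per-cation
#' (z, Y, K) values for Mg2+, Ca2+, Ba2+, putrescine2+, spermidine3+,
#' spermine4+ and neomycin6+ (whose entry also carries W = 4.1 uM).
#'
#' @param file optional path to a YAML parameter file of the same layout.
#' @return `default_params()`: a [shielding_params()] object.
#' @export
default_params <- function(file = NULL) {
  y <- read_defaults_yaml(file)
  p <- y$params
  shielding_params(psi = p$psi_mV * 1e-3, temperature = p$temperature_K,
                   L_ref = p$L_ref_mM * 1e-3, z_ref = p$z_ref,
                   pip2_total = p$pip2_total_uM * 1e-6,
                   W = p$W_uM * 1e-6, Kd = p$Kd_uM * 1e-6)
}

#' @rdname default_params
#' @return `default_cations()`: a named list of [cation_spec()] objects,
#'   with a `W` attribute (molar) on plateau-capable entries.
#' @export
default_cations <- function(file = NULL) {
  y <- read_defaults_yaml(file)
  out <- lapply(names(y$cations), function(nm) {
    c0 <- y$cations[[nm]]
    sp <- cation_spec(nm, z = c0$z, Y = c0$Y, K = c0$K_per_M,
                      plateau_capable = isTRUE(c0$plateau_capable))
    if (!is.null(c0$W_uM)) attr(sp, "W") <- c0$W_uM * 1e-6
    sp
  })
  names(out) <- names(y$cations)
  out
}

read_defaults_yaml <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "paper_defaults.yaml", package = "shieldfit")
  yaml::read_yaml(file)
}

#' Boltzmann accumulation factor of a cation at the substrate
#'
#' The enhancement of the local over the bulk cation concentration,
#' exp(-(z Y) q psi / (kB T)). Greater than 1 whenever psi < 0, and strictly
#' increasing in z and in Y.
#'
#' @param cation a [cation_spec()].
#' @param params a [shielding_params()].
#' @return dimensionless enhancement factor.
#' @examples
#' boltzmann_factor(cation_spec("Mg", 2), shielding_params())
#' @export
boltzmann_factor <- function(cation, params) {
  stopifnot(inherits(cation, "cation_spec"), inherits(params, "shielding_params"))
  exp(-cation$z * cation$Y * params$psi / thermal_voltage(params$temperature))
}

scaled_L <- function(cation, params) params$L_scale(params$L_ref, params$z_ref, cation$z)

#' Free (unshielded) substrate concentration
#'
#' Free substrate under electrostatic accumulation and chemical binding of a
#' cation, with an optional unshieldable residue W:
#'
#'   free = (total - W) * L_z/(L_z + C_eff) * 1/(1 + K C_eff) + W
#'
#' where C_eff = bulk * Boltzmann factor and L_z the valence-scaled
#' half-maximal constant. Nonincreasing in `bulk`, bounded in
#' \[W, total\].
#'
#' @param bulk bulk cation concentration(s), molar (vectorized).
#' @param cation a [cation_spec()].
#' @param params a [shielding_params()]; its `W` applies only when the
#'   cation is plateau-capable (otherwise 0 is used) unless `force_W = TRUE`.
#' @param force_W apply `params$W` regardless of the cation's plateau flag.
#' @return free substrate concentration(s), molar.
#' @export
free_pip2 <- function(bulk, cation, params, force_W = FALSE) {
  if (any(bulk < 0)) stop("bulk concentration must be non-negative")
  W <- if (cation$plateau_capable || force_W) params$W else 0
  f <- boltzmann_factor(cation, params)
  Lz <- scaled_L(cation, params)
  ceff <- bulk * f
  (params$pip2_total - W) * (Lz / (Lz + ceff)) / (1 + cation$K * ceff) + W
}

#' Normalized enzyme activity at a bulk cation concentration
#'
#' Activity relative to the cation-free condition,
#' A(bulk) = v(bulk)/v(0) with v(x) = free(x) / (free(x) + Kd). Equals 1 at
#' bulk = 0, is nonincreasing in bulk, and with W > 0 tends to a strictly
#' positive plateau.
#'
#' @inheritParams free_pip2
#' @return normalized activity in (0, 1] (vectorized over `bulk`).
#' @examples
#' p <- default_params()
#' normalized_activity(c(0, 0.01, 0.1), cation_spec("Mg", 2, K = 1), p)
#' @export
normalized_activity <- function(bulk, cation, params, force_W = FALSE) {
  v <- function(x) {
    fp <- free_pip2(x, cation, params, force_W = force_W)
    fp / (fp + params$Kd)
  }
  v(bulk) / v(0)
}

#' Half-inhibitory bulk concentration (IC50)
#'
#' The bulk cation concentration at which normalized activity drops to 0.5,
#' located by bracketing on a log scale and bisection to 1e-6 relative
#' accuracy. When the activity plateau stays above 0.5 (large W), no such
#' concentration exists and `NA` is returned.
#'
#' @inheritParams free_pip2
#' @param lower,upper bracket for the search, molar.
#' @return the IC50 in molar, or `NA_real_` when unreachable.
#' @export
ic50 <- function(cation, params, force_W = FALSE, lower = 1e-12, upper = 1e2) {
  a <- function(x) normalized_activity(x, cation, params, force_W = force_W)
  # asymptotic activity as bulk -> Inf
  W <- if (cation$plateau_capable || force_W) params$W else 0
  P <- params$pip2_total
  a_inf <- (W / (W + params$Kd)) / (P / (P + params$Kd))
  if (a_inf >= 0.5) return(NA_real_)
  if (a(upper) > 0.5) return(NA_real_)
  r <- stats::uniroot(function(lx) a(10^lx) - 0.5, c(log10(lower), log10(upper)),
                      tol = 1e-10)
  x <- 10^r$root
  # polish to the stated relative accuracy on the linear scale
  stats::uniroot(function(b) a(b) - 0.5, c(x * 0.9, x * 1.1),
                 tol = 1e-6 * x)$root
}

#' Multiplicative multi-cation suppression mode
#'
#' Optional mode combining several cations at once by multiplying each
#' cation's suppression term (L_z/(L_z + C_eff)) * 1/(1 + K C_eff) on the
#' shieldable substrate pool. With a single cation this reduces exactly to
#' [normalized_activity()]. The single-cation model is canonical: dose-response
#' experiments add one cation at a time over a fixed background.
#'
#' @param bulks named numeric vector of bulk concentrations (molar), one per
#'   entry of `cations`.
#' @param cations list of [cation_spec()] matching `bulks` by name.
#' @param params a [shielding_params()].
#' @param W residual unshieldable substrate (molar) for the combined curve.
#' @return normalized activity relative to the all-zero condition.
#' @export
multi_cation_activity <- function(bulks, cations, params, W = 0) {
  stopifnot(all(names(bulks) %in% names(cations)))
  supp <- 1
  for (nm in names(bulks)) {
    ct <- cations[[nm]]
    f <- boltzmann_factor(ct, params)
    Lz <- scaled_L(ct, params)
    ceff <- bulks[[nm]] * f
    supp <- supp * (Lz / (Lz + ceff)) / (1 + ct$K * ceff)
  }
  fp <- (params$pip2_total - W) * supp + W
  v <- fp / (fp + params$Kd)
  v0 <- params$pip2_total / (params$pip2_total + params$Kd)
  v / v0
}
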