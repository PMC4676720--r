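#' Replicate noise model for synthetic dose-response data
#'
#' Additive Gaussian noise on normalized activity, i.i.d. across replicates
#' and doses, clipped below at -0.05 (normalized activities can dip slightly
#' below zero by measurement noise but not arbitrarily). Emulates assay
#' replication with n = 4-8 per condition.
#'
#' @param n_rep replicates per dose (>= 1).
#' @param sd Gaussian SD of normalized activity (>= 0); default 0.05.
#' @param seed integer seed; all generator randomness flows through it.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(n_rep = 4, sd = 0.05, seed = 1L) {
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n_rep = as.integer(n_rep), sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dose-response dataset
#'
#' Draws `n_rep` noisy replicates of the model activity at each dose; the
#' replicate mean equals [normalized_activity()] exactly before noise.
#' Provenance (seed and generating parameters) is recorded in attributes,
#' and the full replicate matrix is kept for case-resampling bootstrap.
#'
#' @param cation a [cation_spec()].
#' @param params a [shielding_params()].
#' @param doses bulk doses in molar, strictly increasing, >= 4 levels.
#' @param noise a [noise_model()]; `sd = 0` gives the exact model curve.
#' @param enzyme enzyme label carried in the dataset.
#' @return a data.frame of class `dose_response` with columns `enzyme`,
#'   `cation`, `dose` (molar), `activity` (replicate mean), `replicate_sd`,
#'   `n_rep`; attributes `replicates` (dose x replicate matrix),
#'   `provenance` (list with seed, generating parameter values).
#' @examples
#' ds <- generate_dose_response(cation_spec("Mg", 2, K = 1), default_params(),
#'                              doses = 10^seq(-4, -0.5, length.out = 8),
#'                              noise = noise_model(sd = 0))
#' @export
generate_dose_response <- function(cation, params, doses,
                                   noise = noise_model(), enzyme = "PLC") {
  if (any(doses < 0) || any(diff(doses) <= 0))
    stop("doses must be non-negative and strictly increasing")
  if (length(doses) < 4) stop("at least 4 dose levels are required")
  mu <- normalized_activity(doses, cation, params)
  reps <- with_local_seed(noise$seed, {
    m <- matrix(stats::rnorm(length(doses) * noise$n_rep, mean = rep(mu, noise$n_rep),
                             sd = noise$sd),
                nrow = length(doses))
    pmax(m, -0.05)
  })
  out <- data.frame(enzyme = enzyme, cation = cation$name, dose = doses,
                    activity = rowMeans(reps),
                    replicate_sd = apply(reps, 1, stats::sd),
                    n_rep = noise$n_rep, stringsAsFactors = FALSE)
  attr(out, "replicates") <- reps
  attr(out, "provenance") <- list(source = if (noise$sd > 0) "synthetic" else
                                    "synthetic-noiseless",
                                  seed = noise$seed, sd = noise$sd,
                                  cation = unclass(cation),
                                  params = unclass(params)[c("psi", "temperature",
                                    "L_ref", "z_ref", "pip2_total", "W", "Kd")])
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Specification of a fluorogenic progress-curve experiment
#'
#' Parameters of a Michaelis-Menten progress curve read out by a fluorogenic
#' substrate and a linear standard curve. Vmax is enzyme amount times
#' specific activity divided by reaction volume.
#'
#' @param enzyme_ng enzyme amount per reaction, nanograms.
#' @param specific_activity mol product per minute per mg enzyme.
#' @param substrate_total total substrate, molar (default 30 uM).
#' @param Km Michaelis constant, molar.
#' @param times sampling times in minutes, strictly increasing.
#' @param volume reaction volume in liters (default 20 uL).
#' @param slope standard-curve slope, fluorescence AU per molar product.
#' @param intercept standard-curve intercept, AU.
#' @return an object of class `time_course_spec`.
#' @export
time_course_spec <- function(enzyme_ng, specific_activity,
                             substrate_total = 30e-6, Km = 50e-6,
                             times = seq(0, 90, by = 2), volume = 20e-6,
                             slope = 1e7, intercept = 0) {
  if (enzyme_ng < 0 || specific_activity < 0)
    stop("enzyme amount and specific activity must be non-negative")
  if (substrate_total <= 0 || Km <= 0 || volume <= 0 || slope <= 0)
    stop("substrate_total, Km, volume and slope must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(enzyme_ng = enzyme_ng, specific_activity = specific_activity,
                 substrate_total = substrate_total, Km = Km, times = times,
                 volume = volume, slope = slope, intercept = intercept),
            class = "time_course_spec")
}

#' Closed-form Michaelis-Menten progress curve
#'
#' Remaining substrate of dS/dt = -Vmax S/(Km + S) in Lambert-W form:
#' S(t) = Km W0( (S0/Km) exp((S0 - Vmax t)/Km) ).
#'
#' @param t time(s), minutes.
#' @param S0 initial substrate, molar.
#' @param Vmax maximal rate, molar per minute.
#' @param Km Michaelis constant, molar.
#' @return substrate concentration(s), molar.
#' @export
mm_progress_substrate <- function(t, S0, Vmax, Km) {
  if (Vmax == 0) return(rep(S0, length(t)))
  # evaluate the W0 argument in log space to avoid overflow for S0 >> Km
  la <- log(S0 / Km) + (S0 - Vmax * t) / Km
  vapply(la, function(l) {
    if (l > 700) {
      # asymptotic W0(e^l) ~ l - log(l) + log(l)/l for large l
      w <- l - log(l) + log(l) / l
    } else {
      w <- pracma::lambertWp(exp(l))
    }
    Km * w
  }, numeric(1))
}

#' Generate a synthetic fluorescence time course
#'
#' Product formation follows the closed-form Michaelis-Menten progress
#' curve; fluorescence is `slope * product + intercept` plus optional
#' Gaussian noise. Product is monotone nondecreasing and bounded by the
#' total substrate.
#'
#' @param spec a [time_course_spec()].
#' @param noise_sd Gaussian fluorescence noise SD, AU (default 0).
#' @param seed seed used when `noise_sd > 0`.
#' @return a data.frame of class `time_course` with columns `time_min`,
#'   `fluorescence_au`; attributes record the spec and the noiseless product
#'   trace (molar).
#' @export
generate_time_course <- function(spec, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "time_course_spec"))
  mass_mg <- spec$enzyme_ng * 1e-6
  Vmax <- spec$specific_activity * mass_mg / spec$volume  # M/min
  S <- mm_progress_substrate(spec$times, spec$substrate_total, Vmax, spec$Km)
  P <- spec$substrate_total - S
  F0 <- spec$slope * P + spec$intercept
  if (noise_sd > 0)
    F0 <- with_local_seed(seed, F0 + stats::rnorm(length(F0), sd = noise_sd))
  out <- data.frame(time_min = spec$times, fluorescence_au = F0)
  attr(out, "spec") <- spec
  attr(out, "product_M") <- P
  class(out) <- c("time_course", "data.frame")
  out
}
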