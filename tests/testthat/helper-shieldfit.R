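# Shared fixtures: packaged defaults and standard dose grids.
pk_params <- default_params()
pk_cations <- default_cations()

divalent_grid <- 10^seq(log10(1e-5), log10(0.1), length.out = 12)
mg_grid <- 10^seq(log10(1e-4), log10(0.3), length.out = 12)
neomycin_grid <- 10^seq(log10(1e-7), log10(1e-2), length.out = 14)

noiseless <- function(cation, params = pk_params, doses = divalent_grid,
                      enzyme = "PLCb1") {
  generate_dose_response(cation, params, doses, noise_model(1, 0, 1),
                         enzyme = enzyme)
}

# Neomycin parameter set: defaults plus its W plateau.
neo_params <- local({
  p <- pk_params
  p$W <- attr(pk_cations$neomycin, "W")
  p
})

# Brute-force 1-metal/1-ligand speciation oracle: scan the free-metal
# mass-balance residual on successively refined log grids, independent of
# the package solver's iteration scheme.
scan_speciation_oracle <- function(Mtot, Ltot, K_app) {
  resid <- function(x) {
    B <- Mtot - x
    Lp <- Ltot - B
    B - K_app * x * Lp
  }
  lo <- log10(Mtot) - 15
  hi <- log10(Mtot)
  for (pass in 1:6) {
    g <- 10^seq(lo, hi, length.out = 400)
    r <- vapply(g, resid, numeric(1))
    i <- which(r[-1] * r[-length(r)] <= 0)[1]
    if (is.na(i)) i <- which.min(abs(r))
    lo <- log10(g[max(i - 1, 1)])
    hi <- log10(g[min(i + 2, length(g))])
  }
  10^((lo + hi) / 2)
}
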