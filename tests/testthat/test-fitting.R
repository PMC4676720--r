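test_that("noiseless staged round-trip recovers the generating defaults", {
  mg_sets <- lapply(c("PLCb1", "PLCg1", "PLCd1"), function(e)
    noiseless(pk_cations$Mg, doses = mg_grid, enzyme = e))
  fL <- fit_stage_L(mg_sets, pk_params)
  expect_equal(fL$value, pk_params$L_ref, tolerance = 1e-3)
  expect_true(fL$converged)

  ba <- noiseless(pk_cations$Ba)
  fK <- fit_stage_K(ba, pk_params, cation_spec("Ba", 2), L = fL$value)
  expect_equal(fK$value, pk_cations$Ba$K, tolerance = 1e-3)

  put <- noiseless(pk_cations$putrescine)
  fY <- fit_stage_Y(put, NULL, pk_params, L = fL$value)
  expect_equal(fY$estimates$Y, pk_cations$putrescine$Y, tolerance = 1e-3)
  expect_equal(fY$estimates$K, pk_cations$putrescine$K, tolerance = 1e-2)

  neo <- noiseless(pk_cations$neomycin, params = neo_params,
                   doses = neomycin_grid)
  fW <- fit_stage_W(neo, pk_params, pk_cations$neomycin, L = fL$value)
  expect_equal(fW$value, neo_params$W, tolerance = 1e-3)
})

test_that("full pipeline on generated defaults reproduces them and reports IC50s", {
  datasets <- list(
    noiseless(pk_cations$Mg, doses = mg_grid, enzyme = "PLCb1"),
    noiseless(pk_cations$Mg, doses = mg_grid, enzyme = "PLCg1"),
    noiseless(pk_cations$Ba),
    noiseless(pk_cations$Ca),
    noiseless(pk_cations$putrescine),
    noiseless(pk_cations$neomycin, params = neo_params, doses = neomycin_grid))
  fit <- fit_staged(datasets, pk_cations, pk_params)
  expect_equal(fit$params$L_ref, pk_params$L_ref, tolerance = 1e-3)
  expect_equal(fit$cations$Ba$K, 460, tolerance = 1e-3)
  expect_equal(fit$cations$Ca$K, 190, tolerance = 1e-3)
  expect_equal(fit$cations$putrescine$Y, 0.12, tolerance = 1e-3)
  expect_equal(fit$params$W, 4.1e-6, tolerance = 1e-2)
  expect_true(all(fit$rss < 1e-10))
  expect_true(all(is.finite(fit$ic50)))
})

test_that("flat data yields a flagged non-estimate, not a silent number", {
  flat <- noiseless(pk_cations$Mg)
  flat$activity <- rep(1, nrow(flat))
  fL <- fit_stage_L(flat, pk_params)
  expect_false(fL$converged)
  expect_true(is.na(fL$value))
  expect_match(paste(fL$diagnostics$notes, collapse = " "), "no_signal")
})

test_that("sparse transition-region sampling is reported as ill-conditioned", {
  ds <- noiseless(pk_cations$Mg, doses = c(1e-5, 2e-5, 1, 2))
  fL <- fit_stage_L(ds, pk_params)
  expect_match(paste(fL$diagnostics$notes, collapse = " "), "ill_conditioned")
})

test_that("boundary cases land on their bounds with a flag", {
  # K = 0 generating curve
  ct0 <- cation_spec("Ba", 2, K = 0)
  ds0 <- noiseless(ct0, doses = mg_grid)
  fK <- fit_stage_K(ds0, pk_params, cation_spec("Ba", 2))
  expect_lt(fK$value, 1e-6)
  expect_true(any(unlist(fK$boundary)))
  # putrescine behaving exactly like Mg implies Y at the upper bound 1
  ds1 <- noiseless(cation_spec("putrescine", 2, Y = 1, K = 1), doses = mg_grid)
  fY <- fit_stage_Y(ds1, NULL, pk_params, L = pk_params$L_ref)
  expect_equal(fY$estimates$Y, 1, tolerance = 1e-6)
  # W = 0 generating curve
  ctn <- pk_cations$neomycin
  dsn <- noiseless(ctn, params = pk_params, doses = neomycin_grid)
  dsn2 <- dsn
  attr(dsn2, "provenance") <- NULL
  fW <- fit_stage_W(dsn2, pk_params, ctn)
  expect_lt(fW$value, 1e-9)
})

test_that("recovered W matches the closed-form plateau inversion within 2 percent", {
  neo <- noiseless(pk_cations$neomycin, params = neo_params,
                   doses = neomycin_grid)
  fW <- fit_stage_W(neo, pk_params, pk_cations$neomycin)
  # independent back-calculation from the asymptotic activity
  a_inf <- normalized_activity(10, pk_cations$neomycin, neo_params)
  P <- pk_params$pip2_total; Kd <- pk_params$Kd
  a <- a_inf * P / (P + Kd)
  W_back <- Kd * a / (1 - a)
  expect_equal(fW$value, W_back, tolerance = 0.02)
})

test_that("round-trip recovery holds across 50 random parameter draws", {
  set.seed(101)
  for (i in 1:50) {
    L_true <- 10^runif(1, -2.3, -0.7)
    K_true <- 10^runif(1, 0, 3.3)
    p <- shielding_params(L_ref = L_true)
    ds_mg <- generate_dose_response(cation_spec("Mg", 2, K = 1), p,
                                    mg_grid, noise_model(1, 0, 1))
    fL <- fit_stage_L(ds_mg, shielding_params())
    expect_equal(fL$value, L_true, tolerance = 1e-3)
    ds_k <- generate_dose_response(cation_spec("Ba", 2, K = K_true), p,
                                   divalent_grid, noise_model(1, 0, 1))
    fK <- fit_stage_K(ds_k, shielding_params(L_ref = fL$value),
                      cation_spec("Ba", 2))
    expect_equal(fK$value, K_true, tolerance = 1e-3)
  }
})

test_that("fits are invariant to row order and to concentration unit tags", {
  ds <- noiseless(pk_cations$Ba)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dose_response(ds, f1)  # written in mM
  tab <- utils::read.csv(f1)
  tab$dose <- tab$dose * 1e-3  # same doses retagged in molar
  tab$dose_unit <- "M"
  tab <- tab[sample(nrow(tab)), ]  # and shuffled
  utils::write.csv(tab, f2, row.names = FALSE)
  k1 <- fit_stage_K(read_dose_response(f1)[[1]], pk_params,
                    cation_spec("Ba", 2))$value
  k2 <- fit_stage_K(read_dose_response(f2)[[1]], pk_params,
                    cation_spec("Ba", 2))$value
  expect_equal(k1, k2, tolerance = 1e-6)
})

test_that("bootstrap is reproducible, degenerate on noiseless data, and validates n_boot", {
  ds <- generate_dose_response(pk_cations$Mg, pk_params, mg_grid,
                               noise_model(n_rep = 6, sd = 0.05, seed = 3))
  fitL <- function(d) fit_stage_L(d, pk_params)$value
  expect_error(bootstrap_ci(fitL, ds, n_boot = 50, seed = 1), "n_boot")
  ci_a <- bootstrap_ci(fitL, ds, n_boot = 120, seed = 9)
  ci_b <- bootstrap_ci(fitL, ds, n_boot = 120, seed = 9)
  expect_identical(ci_a, ci_b)
  expect_lt(ci_a$lower, ci_a$upper)
  ds0 <- generate_dose_response(pk_cations$Mg, pk_params, mg_grid,
                                noise_model(n_rep = 4, sd = 0, seed = 1))
  ci0 <- bootstrap_ci(fitL, ds0, n_boot = 100, seed = 1)
  expect_equal(ci0$lower, ci0$upper, tolerance = 1e-8)
})

test_that("Y recovery is nearly unbiased at realistic noise", {
  # 100 seeded repeats at replicate SD 0.05: |mean(Yhat) - Y| < 0.02
  yhats <- vapply(1:100, function(s) {
    ds <- generate_dose_response(pk_cations$putrescine, pk_params,
                                 divalent_grid,
                                 noise_model(n_rep = 6, sd = 0.05, seed = s))
    fit_stage_Y(ds, NULL, pk_params, L = pk_params$L_ref)$estimates$Y
  }, numeric(1))
  expect_lt(abs(mean(yhats) - 0.12), 0.02)
})
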