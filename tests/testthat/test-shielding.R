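test_that("Boltzmann factor matches the closed form and its monotonicities", {
  p0 <- shielding_params(psi = 0)
  for (ct in pk_cations)
    expect_identical(boltzmann_factor(ct, p0), 1)
  # z = 2, Y = 1, psi = -25 mV, T = 295.15 K; hand-evaluated closed form
  expect_equal(boltzmann_factor(cation_spec("Mg", 2), pk_params), 7.14111,
               tolerance = 1e-5)
  # smaller Y accumulates less
  expect_lt(boltzmann_factor(cation_spec("put", 2, Y = 0.12), pk_params),
            boltzmann_factor(cation_spec("Mg", 2), pk_params))
  # strictly increasing in z and Y
  fz <- vapply(1:6, function(z)
    boltzmann_factor(cation_spec("x", z), pk_params), numeric(1))
  expect_true(all(diff(fz) > 0))
  fy <- vapply(seq(0.1, 1, 0.1), function(y)
    boltzmann_factor(cation_spec("x", 3, Y = y), pk_params), numeric(1))
  expect_true(all(diff(fy) > 0))
})

test_that("free substrate honours its limits and half-maximal definition", {
  mg <- pk_cations$Mg
  expect_equal(free_pip2(0, mg, pk_params), pk_params$pip2_total)
  # C_eff = L_z with K = 0, W = 0 gives exactly half the total
  ct <- cation_spec("x", 2, K = 0)
  Lz <- pk_params$L_ref  # z = z_ref
  bulk_half <- Lz / boltzmann_factor(ct, pk_params)
  expect_equal(free_pip2(bulk_half, ct, pk_params), pk_params$pip2_total / 2)
  # saturating neomycin leaves exactly W
  expect_equal(free_pip2(1e3, pk_cations$neomycin, neo_params), neo_params$W,
               tolerance = 1e-4)
  expect_error(free_pip2(-1e-3, mg, pk_params), "non-negative")
  # bounded in [W, total] and nonincreasing
  fp <- free_pip2(10^seq(-8, 0, length.out = 50), pk_cations$neomycin, neo_params)
  expect_true(all(diff(fp) <= 0))
  expect_true(all(fp >= neo_params$W - 1e-18 & fp <= neo_params$pip2_total))
})

test_that("normalized activity is 1 at zero dose and plateaus per the closed form", {
  for (nm in names(pk_cations)) {
    ct <- pk_cations[[nm]]
    p <- if (ct$plateau_capable) neo_params else pk_params
    expect_identical(normalized_activity(0, ct, p), 1)
  }
  # neomycin asymptote (W/(W+Kd)) / (P/(P+Kd))
  W <- neo_params$W; Kd <- neo_params$Kd; P <- neo_params$pip2_total
  a_inf <- (W / (W + Kd)) / (P / (P + Kd))
  expect_equal(normalized_activity(10, pk_cations$neomycin, neo_params), a_inf,
               tolerance = 1e-3)
  # stronger binder suppresses at least as much at equal bulk
  b <- 10^seq(-5, -1, length.out = 20)
  expect_true(all(normalized_activity(b, pk_cations$Ba, pk_params) <=
                    normalized_activity(b, pk_cations$Mg, pk_params)))
})

test_that("normalized activity is nonincreasing in dose for random valid parameters", {
  set.seed(11)
  b <- 10^seq(-7, 0, length.out = 60)
  for (i in 1:50) {
    ct <- cation_spec("x", sample(1:6, 1), Y = runif(1, 0.05, 1),
                      K = 10^runif(1, -2, 4),
                      plateau_capable = runif(1) < 0.3)
    p <- shielding_params(psi = -runif(1, 0.005, 0.06),
                          temperature = runif(1, 280, 310),
                          L_ref = 10^runif(1, -3, -0.5),
                          pip2_total = 30e-6,
                          W = if (ct$plateau_capable) runif(1, 0, 25e-6) else 0,
                          Kd = 10^runif(1, -5.5, -3.5))
    a <- normalized_activity(b, ct, p)
    expect_true(all(diff(a) <= 1e-12))
    expect_true(all(a > 0 & a <= 1))
  }
})

test_that("the (psi, L, K) rescaling leaves every curve unchanged", {
  # doubling psi while rescaling L by f'/f and K by f/f' is unobservable
  b <- 10^seq(-6, -0.5, length.out = 40)
  for (nm in c("Mg", "Ba", "spermine", "neomycin")) {
    ct <- pk_cations[[nm]]
    p1 <- if (ct$plateau_capable) neo_params else pk_params
    p2 <- p1
    p2$psi <- 2 * p1$psi
    f1 <- boltzmann_factor(ct, p1)
    f2 <- boltzmann_factor(ct, p2)
    p2$L_ref <- p1$L_ref * f2 / f1
    ct2 <- ct
    ct2$K <- ct$K * f1 / f2
    expect_equal(normalized_activity(b, ct2, p2),
                 normalized_activity(b, ct, p1), tolerance = 1e-12)
  }
})

test_that("with Y = 1, W = 0, K = 0 the model reduces to the pure electrostatic Hill form", {
  ct <- cation_spec("x", 3, Y = 1, K = 0)
  b <- 10^seq(-6, -1, length.out = 30)
  f <- boltzmann_factor(ct, pk_params)
  Lz <- pk_params$L_ref * pk_params$z_ref / 3
  hill <- pk_params$pip2_total * Lz / (Lz + b * f)
  expect_equal(free_pip2(b, ct, pk_params), hill, tolerance = 1e-12)
})

test_that("IC50 satisfies its defining property and matches a dense log-grid scan", {
  grid_oracle <- function(ct, p) {
    lg <- seq(-9, 0, length.out = 1e4)
    a <- normalized_activity(10^lg, ct, p)
    10^lg[which.min(abs(a - 0.5))]
  }
  for (nm in c("Mg", "Ca", "Ba", "spermine", "neomycin")) {
    ct <- pk_cations[[nm]]
    p <- if (ct$plateau_capable) neo_params else pk_params
    x <- ic50(ct, p)
    expect_false(is.na(x))
    expect_equal(normalized_activity(x, ct, p), 0.5, tolerance = 1e-6)
    expect_equal(x, grid_oracle(ct, p), tolerance = 3e-3, info = nm)
  }
  # unreachable half-inhibition when the plateau stays above 0.5
  p_highW <- shielding_params(W = 25e-6)
  ct <- cation_spec("neo", 6, Y = 0.12, K = 1000, plateau_capable = TRUE)
  expect_true(is.na(ic50(ct, p_highW)))
})

test_that("larger z*Y strictly lowers IC50 at fixed L_z and W = 0", {
  p <- shielding_params(L_scale = function(L, zr, z) L)  # L_z held constant
  ics <- vapply(2:5, function(z)
    ic50(cation_spec("x", z, Y = 1, K = 10), p), numeric(1))
  expect_true(all(diff(ics) < 0))
  icy <- vapply(c(0.2, 0.5, 1), function(y)
    ic50(cation_spec("x", 4, Y = y, K = 10), p), numeric(1))
  expect_true(all(diff(icy) < 0))
})

test_that("suppression at equal bulk orders the cations as the binding constants imply", {
  b <- 3e-3
  a <- vapply(c("Mg", "Ca", "Ba", "putrescine", "spermidine", "spermine",
                "neomycin"), function(nm) {
    ct <- pk_cations[[nm]]
    p <- if (ct$plateau_capable) neo_params else pk_params
    normalized_activity(b, ct, p)
  }, numeric(1))
  expect_lt(a[["Ba"]], a[["Mg"]])
  expect_lt(a[["Ca"]], a[["Mg"]])
  expect_lt(abs(a[["Ba"]] - a[["Ca"]]), 0.12)  # Ba ~ Ca
  expect_true(a[["neomycin"]] < a[["spermine"]] &&
                a[["spermine"]] < a[["spermidine"]] &&
                a[["spermidine"]] < a[["putrescine"]])
})

test_that("multi-cation mode reduces to the single-cation model for one cation", {
  b <- c(1e-4, 1e-3, 1e-2)
  one <- normalized_activity(b, pk_cations$Ba, pk_params)
  multi <- vapply(b, function(x)
    multi_cation_activity(c(Ba = x), pk_cations, pk_params), numeric(1))
  expect_equal(multi, one, tolerance = 1e-12)
  # adding a second cation only suppresses further
  both <- vapply(b, function(x)
    multi_cation_activity(c(Ba = x, Mg = 5e-3), pk_cations, pk_params),
    numeric(1))
  expect_true(all(both <= multi))
})
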