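#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Model activity with stage-specific parameter overrides.
# overrides: named list possibly holding L_ref, K, Y, W (molar / per-molar).
model_activity <- function(dose, cation, params, overrides = list()) {
  if (!is.null(overrides$L_ref)) params$L_ref <- overrides$L_ref
  if (!is.null(overrides$K)) cation$K <- overrides$K
  if (!is.null(overrides$Y)) cation$Y <- overrides$Y
  force_W <- FALSE
  if (!is.null(overrides$W)) { params$W <- overrides$W; force_W <- TRUE }
  normalized_activity(dose, cation, params, force_W = force_W)
}

# Bounded Levenberg-Marquardt least squares with coarse grid-scan start.
# par_grid: list of candidate start vectors. Returns list(par, rss, info,
# iterations, boundary).
lm_fit <- function(resid_fn, par_grid, lower, upper) {
  best <- NULL
  for (p0 in par_grid) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ptol = 1e-10, ftol = 1e-12, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(par = fit$par, rss = rss, info = fit$info,
                   iterations = fit$niter)
  }
  if (is.null(best)) stop("least-squares optimisation failed for all starts")
  tolb <- 1e-6
  best$boundary <- mapply(function(p, lo, hi) {
    (is.finite(lo) && abs(p - lo) <= tolb * max(abs(lo), 1e-12)) ||
      (is.finite(hi) && abs(p - hi) <= tolb * max(abs(hi), 1)) ||
      (lo == 0 && p <= 1e-9)
  }, best$par, lower, upper)
  best
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "dose_response")) list(datasets) else datasets
}

dataset_weights <- function(ds, weighted) {
  if (!weighted) return(rep(1, nrow(ds)))
  w <- 1 / pmax(ds$replicate_sd, 1e-6)^2
  w / mean(w)
}

check_signal <- function(ds) {
  notes <- character(0)
  if (max(ds$activity) - min(ds$activity) < 0.02)
    notes <- c(notes, "no_signal: activity range < 0.02, no estimate reported")
  trans <- sum(ds$activity > 0.2 & ds$activity < 0.8)
  if (trans < 2)
    notes <- c(notes, "ill_conditioned: fewer than 2 doses in the transition region")
  notes
}

new_fit_stage <- function(stage, estimates, value, per_dataset, params,
                          boundary, converged, diagnostics) {
  structure(list(stage = stage, estimates = estimates, value = value,
                 per_dataset = per_dataset,
                 fixed = unclass(params)[c("psi", "temperature", "z_ref",
                                           "pip2_total", "Kd")],
                 boundary = boundary, converged = converged,
                 diagnostics = diagnostics),
            class = "fit_stage")
}

#' @export
print.fit_stage <- function(x, ...) {
  cat("Stage", x$stage, "fit:",
      paste(names(x$estimates), signif(unlist(x$estimates), 5), collapse = ", "),
      "\n")
  if (!is.null(x$value)) cat("  stage value:", signif(x$value, 5), "\n")
  if (any(unlist(x$boundary))) cat("  note: estimate at a bound\n")
  if (length(x$diagnostics$notes))
    cat("  diagnostics:", paste(x$diagnostics$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Stage 1: estimate the electrostatic half-maximal constant L
#'
#' Fits L to one or more reference-divalent (Mg2+) dose-response datasets,
#' one L per enzyme, with the binding constant fixed at its small reference
#' value, then averages across enzymes. L is optimised on a log scale within
#' `L_bounds`.
#'
#' @param datasets a `dose_response` or list of them (reference divalent,
#'   typically one per enzyme).
#' @param params a [shielding_params()] skeleton (psi, Kd, pip2_total fixed).
#' @param cation the reference divalent [cation_spec()]; default Mg2+ with
#'   K = 1 per molar.
#' @param K_ref binding constant held fixed during the L fit.
#' @param L_bounds search bounds for L, molar.
#' @param weighted use 1/SD^2 weights (default unweighted).
#' @return a `fit_stage` object; `value` is the averaged L (molar),
#'   `estimates` the per-dataset values.
#' @export
fit_stage_L <- function(datasets, params, cation = NULL, K_ref = 1,
                        L_bounds = c(1e-5, 10), weighted = FALSE) {
  datasets <- as_dataset_list(datasets)
  if (is.null(cation)) cation <- cation_spec("Mg", z = 2, Y = 1, K = K_ref)
  cation$K <- K_ref
  ests <- list(); per <- list(); bnds <- list(); notes <- character(0)
  conv <- TRUE
  for (ds in datasets) {
    nm <- paste0(ds$enzyme[1], ":", ds$cation[1])
    dn <- check_signal(ds)
    if (length(dn)) notes <- c(notes, paste0(nm, " ", dn))
    if (any(grepl("^no_signal", dn))) {
      ests[[nm]] <- NA_real_; per[[nm]] <- list(rss = NA_real_)
      bnds[[nm]] <- FALSE; conv <- FALSE
      next
    }
    w <- sqrt(dataset_weights(ds, weighted))
    resid_fn <- function(p) {
      w * (model_activity(ds$dose, cation, params,
                          list(L_ref = 10^p[1])) - ds$activity)
    }
    grid <- lapply(seq(log10(L_bounds[1]) + 0.5, log10(L_bounds[2]) - 0.5,
                       length.out = 5), function(g) c(logL = g))
    fit <- lm_fit(resid_fn, grid, lower = log10(L_bounds[1]),
                  upper = log10(L_bounds[2]))
    ests[[nm]] <- 10^fit$par[[1]]
    per[[nm]] <- list(rss = fit$rss, iterations = fit$iterations)
    bnds[[nm]] <- any(fit$boundary)
  }
  vals <- unlist(ests)
  new_fit_stage("L", ests, value = mean(vals, na.rm = TRUE), per_dataset = per,
                params = params, boundary = bnds, converged = conv,
                diagnostics = list(notes = notes))
}

#' Stage 2: estimate a cation's binding constant K
#'
#' Fits the association constant K (>= 0) for one cation dataset with L
#' fixed from stage 1 and Y, W fixed for the cation class.
#'
#' @param dataset a `dose_response` for a single cation.
#' @param params a [shielding_params()] with `L_ref` set to the stage-1
#'   value (or pass `L`).
#' @param cation the [cation_spec()] of the measured cation; its `K` field
#'   is ignored (it is the fit target).
#' @param L optional explicit L (molar) overriding `params$L_ref`.
#' @param weighted use 1/SD^2 weights.
#' @return a `fit_stage` object; `value` is K (per molar).
#' @export
fit_stage_K <- function(dataset, params, cation, L = NULL, weighted = FALSE) {
  stopifnot(inherits(dataset, "dose_response"))
  if (!is.null(L)) params$L_ref <- L
  notes <- check_signal(dataset)
  w <- sqrt(dataset_weights(dataset, weighted))
  resid_fn <- function(p) {
    w * (model_activity(dataset$dose, cation, params, list(K = p[1])) -
           dataset$activity)
  }
  grid <- c(list(c(K = 0)), lapply(10^seq(-2, 5), function(k) c(K = k)))
  fit <- lm_fit(resid_fn, grid, lower = 0, upper = Inf)
  nm <- paste0(dataset$enzyme[1], ":", dataset$cation[1])
  new_fit_stage("K", stats::setNames(list(fit$par[[1]]), nm),
                value = fit$par[[1]],
                per_dataset = stats::setNames(
                  list(list(rss = fit$rss, iterations = fit$iterations)), nm),
                params = params, boundary = list(any(fit$boundary)),
                converged = TRUE, diagnostics = list(notes = notes))
}

#' Stage 3: estimate the size/charge-separation factor Y
#'
#' Compares a bulky organic divalent (putrescine) with the small reference
#' divalent on the same enzyme: with L fixed (from the reference dataset or
#' stage 1), Y in (0, 1] and the organic cation's K >= 0 are fitted jointly
#' on the organic-cation dataset. The recovered Y is then frozen for all
#' organic polyvalents.
#'
#' @param putrescine_dataset `dose_response` of the organic divalent.
#' @param reference_dataset optional `dose_response` of the reference
#'   divalent used to (re)estimate L when `L` is not given.
#' @param params a [shielding_params()].
#' @param cation [cation_spec()] of the organic cation; `Y` and `K` fields
#'   are ignored (fit targets).
#' @param L explicit L (molar); default `params$L_ref` or a stage-1 fit of
#'   `reference_dataset`.
#' @param weighted use 1/SD^2 weights.
#' @return a `fit_stage` object; `value` is Y, `estimates` holds Y and K.
#' @export
fit_stage_Y <- function(putrescine_dataset, reference_dataset = NULL, params,
                        cation = NULL, L = NULL, weighted = FALSE) {
  stopifnot(inherits(putrescine_dataset, "dose_response"))
  if (is.null(cation))
    cation <- cation_spec(putrescine_dataset$cation[1], z = 2, Y = 0.5, K = 0)
  if (is.null(L)) {
    L <- if (!is.null(reference_dataset))
      fit_stage_L(reference_dataset, params)$value else params$L_ref
  }
  params$L_ref <- L
  ds <- putrescine_dataset
  notes <- check_signal(ds)
  w <- sqrt(dataset_weights(ds, weighted))
  resid_fn <- function(p) {
    w * (model_activity(ds$dose, cation, params, list(Y = p[1], K = p[2])) -
           ds$activity)
  }
  grid <- list()
  for (y0 in c(0.05, 0.12, 0.3, 0.6, 0.9))
    for (k0 in c(0, 1, 100)) grid <- c(grid, list(c(Y = y0, K = k0)))
  fit <- lm_fit(resid_fn, grid, lower = c(1e-4, 0), upper = c(1, Inf))
  nm <- paste0(ds$enzyme[1], ":", ds$cation[1])
  new_fit_stage("Y", list(Y = fit$par[[1]], K = fit$par[[2]]),
                value = fit$par[[1]],
                per_dataset = stats::setNames(
                  list(list(rss = fit$rss, iterations = fit$iterations)), nm),
                params = params,
                boundary = list(Y = fit$boundary[1], K = fit$boundary[2]),
                converged = TRUE, diagnostics = list(notes = notes))
}

#' Stage 4: estimate the unshieldable-substrate plateau W
#'
#' Fits W in \[0, total substrate) to a plateau-capable cation's dataset
#' (neomycin), with L, Y and K handled as in the earlier stages. Set
#' `fit_K = TRUE` to co-estimate K with W (used by the full pipeline when no
#' K stage preceded for this cation).
#'
#' @param dataset `dose_response` of the plateau-capable cation.
#' @param params a [shielding_params()].
#' @param cation [cation_spec()] flagged `plateau_capable`.
#' @param L explicit L (molar); default `params$L_ref`.
#' @param fit_K also estimate K jointly with W.
#' @param weighted use 1/SD^2 weights.
#' @return a `fit_stage` object; `value` is W (molar).
#' @export
fit_stage_W <- function(dataset, params, cation, L = NULL, fit_K = FALSE,
                        weighted = FALSE) {
  stopifnot(inherits(dataset, "dose_response"))
  if (!cation$plateau_capable)
    stop("cation '", cation$name, "' is not flagged plateau-capable")
  if (!is.null(L)) params$L_ref <- L
  ds <- dataset
  notes <- check_signal(ds)
  w <- sqrt(dataset_weights(ds, weighted))
  Wmax <- params$pip2_total * (1 - 1e-9)
  if (fit_K) {
    resid_fn <- function(p) {
      w * (model_activity(ds$dose, cation, params,
                          list(W = p[1], K = p[2])) - ds$activity)
    }
    grid <- list()
    for (w0 in c(0, 2e-6, 5e-6, 15e-6))
      for (k0 in c(10, 1000, 1e5)) grid <- c(grid, list(c(W = w0, K = k0)))
    fit <- lm_fit(resid_fn, grid, lower = c(0, 0), upper = c(Wmax, Inf))
    ests <- list(W = fit$par[[1]], K = fit$par[[2]])
  } else {
    resid_fn <- function(p) {
      w * (model_activity(ds$dose, cation, params, list(W = p[1])) -
             ds$activity)
    }
    grid <- lapply(c(0, 1e-6, 4e-6, 1e-5, 2e-5), function(w0) c(W = w0))
    fit <- lm_fit(resid_fn, grid, lower = 0, upper = Wmax)
    ests <- list(W = fit$par[[1]])
  }
  nm <- paste0(ds$enzyme[1], ":", ds$cation[1])
  new_fit_stage("W", ests, value = fit$par[[1]],
                per_dataset = stats::setNames(
                  list(list(rss = fit$rss, iterations = fit$iterations)), nm),
                params = params,
                boundary = as.list(fit$boundary),
                converged = TRUE, diagnostics = list(notes = notes))
}

#' Full staged fitting pipeline (L then K then Y then W)
#'
#' Orchestrates the four stages over a collection of dose-response datasets:
#' stage 1 estimates L from the reference divalent (Mg2+) across enzymes;
#' stage 2 estimates each remaining small cation's K; stage 3 estimates Y
#' (with the organic divalent's K) from the putrescine/reference pair;
#' stage 4 estimates W (with K) for plateau-capable cations. A per-curve
#' IC50 is computed from the fitted parameters.
#'
#' @param datasets list of `dose_response` objects.
#' @param cations named list of [cation_spec()]s covering every cation in
#'   `datasets`; the reference divalent is taken to be `"Mg"`, the organic
#'   divalent `"putrescine"`.
#' @param params a [shielding_params()] skeleton.
#' @param weighted use 1/SD^2 weights.
#' @return an object of class `shield_fit`: stage fragments, the assembled
#'   parameter table, per-dataset RSS and IC50s.
#' @export
fit_staged <- function(datasets, cations, params, weighted = FALSE) {
  datasets <- as_dataset_list(datasets)
  key <- vapply(datasets, function(d) d$cation[1], character(1))
  stages <- list()
  ref <- datasets[key == "Mg"]
  if (length(ref) == 0) stop("staged fit requires reference divalent (Mg) datasets")
  stages$L <- fit_stage_L(ref, params, cation = cations[["Mg"]],
                          K_ref = cations[["Mg"]]$K, weighted = weighted)
  params$L_ref <- stages$L$value
  fitted_cations <- cations
  stages$K <- list()
  for (i in which(!key %in% c("Mg", "putrescine"))) {
    ct <- cations[[key[i]]]
    if (ct$plateau_capable) next
    fr <- fit_stage_K(datasets[[i]], params, ct, weighted = weighted)
    fitted_cations[[key[i]]]$K <- fr$value
    stages$K[[paste0(datasets[[i]]$enzyme[1], ":", key[i])]] <- fr
  }
  if ("putrescine" %in% key) {
    i <- which(key == "putrescine")[1]
    fr <- fit_stage_Y(datasets[[i]], reference_dataset = NULL, params,
                      cation = cations[["putrescine"]], L = params$L_ref,
                      weighted = weighted)
    stages$Y <- fr
    yhat <- fr$estimates$Y
    fitted_cations[["putrescine"]]$Y <- yhat
    fitted_cations[["putrescine"]]$K <- fr$estimates$K
    for (nm in names(fitted_cations))
      if (fitted_cations[[nm]]$Y < 1) fitted_cations[[nm]]$Y <- yhat
  }
  stages$W <- list()
  for (i in which(vapply(key, function(k) cations[[k]]$plateau_capable,
                         logical(1)))) {
    ct <- fitted_cations[[key[i]]]
    fr <- fit_stage_W(datasets[[i]], params, ct, fit_K = TRUE,
                      weighted = weighted)
    stages$W[[paste0(datasets[[i]]$enzyme[1], ":", key[i])]] <- fr
    fitted_cations[[key[i]]]$K <- fr$estimates$K
    params$W <- fr$value
  }
  ic <- rss <- stats::setNames(numeric(length(datasets)),
                               vapply(datasets, function(d)
                                 paste0(d$enzyme[1], ":", d$cation[1]),
                                 character(1)))
  for (j in seq_along(datasets)) {
    ds <- datasets[[j]]
    ct <- fitted_cations[[ds$cation[1]]]
    pred <- normalized_activity(ds$dose, ct, params,
                                force_W = ct$plateau_capable)
    rss[j] <- sum((pred - ds$activity)^2)
    ic[j] <- ic50(ct, params)
  }
  structure(list(stages = stages, params = params, cations = fitted_cations,
                 rss = rss, ic50 = ic),
            class = "shield_fit")
}

#' @export
print.shield_fit <- function(x, ...) {
  cat("Staged shielding fit\n")
  cat("  L =", signif(x$params$L_ref * 1e3, 5), "mM\n")
  for (nm in names(x$cations))
    cat(sprintf("  %-11s z=%d Y=%.3g K=%.4g /M\n", nm, x$cations[[nm]]$z,
                x$cations[[nm]]$Y, x$cations[[nm]]$K))
  if (x$params$W > 0) cat("  W =", signif(x$params$W * 1e6, 4), "uM\n")
  cat("  per-curve IC50 (M):\n")
  for (nm in names(x$ic50))
    cat(sprintf("    %-18s %s\n", nm,
                if (is.na(x$ic50[nm])) "none" else signif(x$ic50[nm], 4)))
  invisible(x)
}

#' Case-resampling bootstrap percentile interval for a fitted quantity
#'
#' Resamples the replicate measurements within each dose level (with
#' replacement), recomputes the per-dose means, refits with `fit_fun`, and
#' returns the percentile interval of the refitted scalar. Reproducible
#' under a fixed seed.
#'
#' @param fit_fun function taking a `dose_response` and returning a numeric
#'   scalar (e.g. `function(d) fit_stage_L(d, params)$value`).
#' @param dataset a `dose_response` carrying its replicate matrix.
#' @param n_boot number of bootstrap draws (>= 100).
#' @param seed integer seed.
#' @param level interval level (default 0.95).
#' @return list with `lower`, `upper`, `level`, `estimates` (all bootstrap
#'   refits).
#' @export
bootstrap_ci <- function(fit_fun, dataset, n_boot = 200, seed = 1L,
                         level = 0.95) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  reps <- attr(dataset, "replicates")
  if (is.null(reps))
    stop("dataset carries no replicate matrix; bootstrap needs replicates")
  ests <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- matrix(sample.int(ncol(reps), length(reps), replace = TRUE),
                    nrow = nrow(reps))
      m <- reps[cbind(rep(seq_len(nrow(reps)), ncol(reps)), as.vector(idx))]
      m <- matrix(m, nrow = nrow(reps))
      d2 <- dataset
      d2$activity <- rowMeans(m)
      d2$replicate_sd <- apply(m, 1, stats::sd)
      attr(d2, "replicates") <- m
      fit_fun(d2)
    }, numeric(1))
  })
  qs <- stats::quantile(ests, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], level = level, estimates = ests)
}
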