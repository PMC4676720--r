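#' Read dose-response curves from CSV
#'
#' Expected columns: `enzyme`, `cation`, `dose`, `dose_unit` (M/mM/uM/nM),
#' `activity_norm`, and optionally `replicate_sd`, `n_rep`. Rows are split
#' into one `dose_response` per enzyme x cation, doses converted to molar
#' and sorted increasing.
#'
#' @param file CSV path.
#' @return named list of `dose_response` objects (`"enzyme:cation"`).
#' @export
read_dose_response <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("enzyme", "cation", "dose", "dose_unit", "activity_norm")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stop("dose-response CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"replicate_sd" %in% names(tab)) tab$replicate_sd <- 0
  if (!"n_rep" %in% names(tab)) tab$n_rep <- 1L
  dose_M <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    dose_M[i] <- tryCatch(parse_conc(paste0(tab$dose[i], tab$dose_unit[i])),
                          error = function(e) verr(
                            "row ", i, ", column dose_unit: ",
                            conditionMessage(e)))
  }
  tab$dose_M <- dose_M
  out <- list()
  for (grp in split(tab, paste0(tab$enzyme, ":", tab$cation))) {
    grp <- grp[order(grp$dose_M), ]
    if (any(duplicated(grp$dose_M)))
      stop("duplicate dose levels for ", grp$enzyme[1], ":", grp$cation[1])
    ds <- data.frame(enzyme = grp$enzyme, cation = grp$cation,
                     dose = grp$dose_M, activity = grp$activity_norm,
                     replicate_sd = grp$replicate_sd, n_rep = grp$n_rep,
                     stringsAsFactors = FALSE)
    attr(ds, "provenance") <- list(source = "measured", file = file)
    class(ds) <- c("dose_response", "data.frame")
    out[[paste0(grp$enzyme[1], ":", grp$cation[1])]] <- ds
  }
  out
}

#' Write dose-response curves to CSV
#'
#' Inverse of [read_dose_response()]; doses are written in mM.
#'
#' @param datasets a `dose_response` or list of them.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
write_dose_response <- function(datasets, file) {
  datasets <- as_dataset_list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(enzyme = d$enzyme, cation = d$cation, dose = d$dose * 1e3,
               dose_unit = "mM", activity_norm = d$activity,
               replicate_sd = d$replicate_sd, n_rep = d$n_rep,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Serialize a staged fit to JSON
#'
#' @param fit a `shield_fit` from [fit_staged()].
#' @param file output path.
#' @param extra optional named list merged into the output (e.g. seed,
#'   config hash).
#' @return the file path, invisibly.
#' @export
write_fit_json <- function(fit, file, extra = list()) {
  stopifnot(inherits(fit, "shield_fit"))
  obj <- c(list(
    L_ref_M = fit$params$L_ref,
    W_M = fit$params$W,
    fixed = fit$stages$L$fixed,
    cations = lapply(fit$cations, function(ct)
      list(z = ct$z, Y = ct$Y, K_per_M = ct$K)),
    rss = as.list(fit$rss),
    ic50_M = lapply(as.list(fit$ic50), function(x)
      if (is.na(x)) "none" else x)), extra)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
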