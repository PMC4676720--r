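#' Construct an assay solution
#'
#' Totals for metals and chelating ligands, plus pH, ionic strength and
#' temperature. Buffer components that only set the ionic strength (HEPES,
#' KCl, DTT, BSA) are not listed explicitly: their contribution enters
#' through `ionic_strength`, mirroring standard free-ion calculator usage.
#'
#' @param metals named vector of total metal concentrations (molar, or unit
#'   tagged strings such as `"3mM"`).
#' @param ligands named vector of total ligand concentrations (same forms).
#' @param pH solution pH (0, 14).
#' @param ionic_strength molar-scale ionic strength, e.g. `0.073`.
#' @param temperature kelvin, or a tag such as `"20C"`; must lie in
#'   \[273, 320\] K.
#' @return an object of class `assay_solution`.
#' @examples
#' assay_solution(c(Ca = "3mM"), c(EGTA = "3mM"), pH = 7.3,
#'                ionic_strength = 0.073, temperature = "20C")
#' @export
assay_solution <- function(metals, ligands = NULL, pH = 7.3,
                           ionic_strength = 0.073, temperature = "20C") {
  metals <- vapply(metals, parse_conc, numeric(1))
  ligands <- if (is.null(ligands) || length(ligands) == 0) numeric(0)
             else vapply(ligands, parse_conc, numeric(1))
  if (is.null(names(metals)) || any(names(metals) == ""))
    stop("metals must be a named vector")
  if (length(ligands) && (is.null(names(ligands)) || any(names(ligands) == "")))
    stop("ligands must be a named vector")
  if (any(metals < 0) || any(ligands < 0))
    stop("total concentrations must be non-negative")
  if (pH <= 0 || pH >= 14) stop("pH out of range (0, 14)")
  if (ionic_strength <= 0) stop("ionic strength must be positive")
  temperature <- parse_temp(temperature)
  if (temperature < 273 || temperature > 320)
    stop("temperature out of supported range [273, 320] K")
  structure(list(metals = metals, ligands = ligands, pH = pH,
                 ionic_strength = ionic_strength, temperature = temperature),
            class = "assay_solution")
}

#' @export
print.assay_solution <- function(x, ...) {
  cat("Assay solution: pH", x$pH, " I =", x$ionic_strength,
      " T =", sprintf("%.2f K", x$temperature), "\n")
  if (length(x$metals))
    cat("  metals (total, M): ",
        paste(names(x$metals), signif(x$metals, 4), collapse = ", "), "\n")
  if (length(x$ligands))
    cat("  ligands (total, M):",
        paste(names(x$ligands), signif(x$ligands, 4), collapse = ", "), "\n")
  invisible(x)
}

# Per-(metal, ligand) conditional binding polynomial pieces at the solution's
# pH/I/T. Returns list with, per ligand: alpha_H and per-metal effective
# association constant to the free unprotonated ligand,
# K_eff = K_ML + K_MHL * [HL]/[L].
speciation_system <- function(solution, constants) {
  mets <- names(solution$metals)
  ligs <- names(solution$ligands)
  H <- 10^(-solution$pH)
  sys <- list()
  for (lg in ligs) {
    rows <- constants[constants$ligand == lg, , drop = FALSE]
    if (nrow(rows) == 0) stop("no stability-constant records for ligand ", lg)
    cr0 <- corrected_record(rows[1, , drop = FALSE],
                            solution$ionic_strength, solution$temperature)
    cum_pk <- cumsum(cr0$pKa)
    alpha_H <- 1 + sum(10^(seq_along(cum_pk) * (-solution$pH) + cum_pk))
    h1 <- H * 10^cr0$pKa[1]
    K_eff <- vapply(mets, function(m) {
      i <- which(rows$metal == m)
      if (length(i) == 0)
        stop("no stability-constant record for (", m, ", ", lg, ")")
      cr <- corrected_record(rows[i[1], , drop = FALSE],
                             solution$ionic_strength, solution$temperature)
      10^cr$logK_ML + 10^cr$logK_MHL * h1
    }, numeric(1))
    sys[[lg]] <- list(alpha_H = alpha_H, K_eff = K_eff)
  }
  sys
}

#' Solve the free-ion speciation of an assay solution
#'
#' Solves the simultaneous mass-action / mass-balance system for all metals
#' and ligands in the solution, using constants adjusted to the solution's
#' pH, ionic strength and temperature. Free metal concentrations are
#' eliminated analytically given the free ligand concentrations; each
#' ligand's scalar balance is then solved by bracketed root finding on a log
#' grid, iterated Gauss-Seidel style across ligands until the joint residual
#' falls below `tol` (relative). The solve is deterministic.
#'
#' @param solution an [assay_solution()].
#' @param constants a [binding_constants()] table; every (metal, ligand)
#'   pair present must have a record. Metals with no ligand records at all
#'   are treated as inert only if the solution has no ligands.
#' @param tol relative residual tolerance (default 1e-12).
#' @param max_iter iteration cap (default 200).
#' @return an object of class `speciation_result` with elements
#'   `free_metal` (named, molar), `bound` (metal x ligand matrix of total
#'   complexed metal, molar), `free_ligand` (named, molar; all unbound
#'   protonation states pooled), `converged`, `residual`, `iterations`, and
#'   the input `solution`.
#' @examples
#' sol <- assay_solution(c(Ca = "3mM"), c(EGTA = "3mM"))
#' res <- solve_speciation(sol)
#' res$free_metal[["Ca"]] * 1e6  # free Ca2+ in uM
#' @export
solve_speciation <- function(solution, constants = binding_constants(),
                             tol = 1e-12, max_iter = 200) {
  stopifnot(inherits(solution, "assay_solution"))
  mets <- names(solution$metals)
  ligs <- names(solution$ligands)
  Mtot <- solution$metals
  Ltot <- solution$ligands

  if (length(ligs) == 0 || all(Ltot == 0) || all(Mtot == 0)) {
    bound <- matrix(0, length(mets), length(ligs),
                    dimnames = list(mets, ligs))
    return(structure(list(free_metal = Mtot, bound = bound,
                          free_ligand = Ltot, converged = TRUE,
                          residual = 0, iterations = 0L, solution = solution),
                     class = "speciation_result"))
  }

  sys <- speciation_system(solution, constants)

  free_metal <- function(L) { # L: named free unprotonated ligand concentrations
    denom <- rep(1, length(mets)); names(denom) <- mets
    for (lg in ligs) denom <- denom + sys[[lg]]$K_eff[mets] * L[[lg]]
    Mtot / denom
  }
  ligand_balance <- function(lg, L) {
    M <- free_metal(L)
    L[[lg]] * sys[[lg]]$alpha_H + sum(M * sys[[lg]]$K_eff[mets] * L[[lg]]) - Ltot[[lg]]
  }

  # Gauss-Seidel over ligands; each scalar balance is monotone in log10 L,
  # solved with uniroot to machine precision.
  L <- Ltot / vapply(ligs, function(lg) sys[[lg]]$alpha_H, numeric(1))
  names(L) <- ligs
  L <- pmax(L, 1e-30)
  residual <- Inf
  it <- 0L
  scale <- pmax(c(Mtot, Ltot), 1e-30)
  while (it < max_iter && residual > tol) {
    it <- it + 1L
    for (lg in ligs) {
      if (Ltot[[lg]] == 0) { L[[lg]] <- 0; next }
      f <- function(logL) { L2 <- L; L2[[lg]] <- 10^logL; ligand_balance(lg, L2) }
      hi <- log10(Ltot[[lg]])
      lo <- -30
      r <- stats::uniroot(f, c(lo, hi), tol = 1e-15)
      L[[lg]] <- 10^r$root
    }
    M <- free_metal(L)
    res_m <- abs(M + vapply(mets, function(m)
      sum(vapply(ligs, function(lg) sys[[lg]]$K_eff[[m]] * M[[m]] * L[[lg]],
                 numeric(1))), numeric(1)) - Mtot)
    res_l <- abs(vapply(ligs, function(lg) ligand_balance(lg, L), numeric(1)))
    residual <- max(c(res_m / pmax(Mtot, 1e-30), res_l / pmax(Ltot, 1e-30)))
  }
  converged <- residual <= tol
  if (!converged)
    stop("speciation solver did not converge in ", max_iter,
         " iterations; last relative residual ", signif(residual, 3))
  M <- free_metal(L)
  bound <- matrix(0, length(mets), length(ligs), dimnames = list(mets, ligs))
  for (m in mets) for (lg in ligs)
    bound[m, lg] <- sys[[lg]]$K_eff[[m]] * M[[m]] * L[[lg]]
  free_ligand <- vapply(ligs, function(lg) L[[lg]] * sys[[lg]]$alpha_H, numeric(1))
  structure(list(free_metal = M, bound = bound, free_ligand = free_ligand,
                 converged = converged, residual = residual, iterations = it,
                 solution = solution),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Speciation result (", if (x$converged) "converged" else "NOT converged",
      ", residual ", format(x$residual, digits = 3), ")\n", sep = "")
  for (m in names(x$free_metal))
    cat(sprintf("  free %-4s %12.6g M\n", m, x$free_metal[[m]]))
  for (lg in names(x$free_ligand))
    cat(sprintf("  free %-4s %12.6g M (unbound, all protonation states)\n",
                lg, x$free_ligand[[lg]]))
  if (length(x$bound))
    for (m in rownames(x$bound)) for (lg in colnames(x$bound))
      cat(sprintf("  %s-%s    %12.6g M bound\n", m, lg, x$bound[m, lg]))
  invisible(x)
}
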