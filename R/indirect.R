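# Indirect GEBV prediction for genotyped selection candidates from a
# previous evaluation's solutions: SNP-effect backsolving, residual
# polygenic (RPG) effects, and the PA / DGV / REG / GRV predictors.

#' Backsolve SNP effects from genotyped-animal GEBV
#'
#' g-hat = K^{-1} Z' C^{-1} u-hat_g via two triangular solves against the
#' Cholesky factor of K; algebraically equal to B Z' G_C^{-1} u-hat_g.
#'
#' @param factor the evaluation's [GenomicFactor-class].
#' @param uG GEBV solutions of the genotyped animals, factor order.
#' @return numeric vector of marker effects.
#' @export
backsolveSnpEffects <- function(factor, uG) {
  if (length(uG) != nrow(factor@geno@counts))
    stop("uG must have one entry per genotyped animal")
  kinvTimes(factor, ztTimes(factor@geno, factor@p, cinvTimes(factor, uG)))
}

#' Residual polygenic effects of the genotyped animals
#'
#' d-hat_g = u-hat_g - Z g-hat: the part of each genotyped animal's GEBV
#' not captured by the markers.
#'
#' @param factor the evaluation's [GenomicFactor-class].
#' @param uG genotyped-animal GEBV solutions.
#' @param gHat backsolved SNP effects (recomputed when omitted).
#' @return numeric vector d-hat_g.
#' @export
rpgGenotyped <- function(factor, uG, gHat = NULL) {
  if (is.null(gHat)) gHat <- backsolveSnpEffects(factor, uG)
  uG - zTimes(factor@geno, factor@p, gHat)
}

#' Residual polygenic effects for selection candidates
#'
#' Computes d-hat_c = A_cg A_gg^{-1} d-hat_g for genotyped selection
#' candidates by one of three routes:
#' * `"exact"` — two steps: x = A_gg^{-1} d-hat_g by dense Cholesky
#'   solve, then A_cg x read off a single Colleau full-pedigree product
#'   with zero padding;
#' * `"ancestor"` — solves the sparse inverse-A system for the
#'   non-genotyped ancestors of the genotyped set, then propagates parent
#'   averages down the pedigree, oldest to youngest;
#' * `"regression"` — the approximation used by the REG predictor: a
#'   parent average where genotyped parents contribute d-hat_g and
#'   non-genotyped parents the fitted regression
#'   d-tilde = a-hat + b-hat * u-hat (unknown ancestors contribute 0).
#'
#' `"exact"` and `"ancestor"` agree to numerical precision; both need the
#' candidates to be absent from the genotyped set.
#'
#' @param ped a [Pedigree-class] covering candidates and evaluation
#'   animals.
#' @param gidx pedigree indices of the evaluation's genotyped animals.
#' @param candIdx pedigree indices of the candidates.
#' @param dG residual polygenic effects of the genotyped animals.
#' @param method `"exact"`, `"ancestor"` or `"regression"`.
#' @param aggChol upper Cholesky of A_gg (exact method; computed when
#'   omitted).
#' @param uHat full vector of GEBV per pedigree animal (regression
#'   method only).
#' @return numeric d-hat_c per candidate (named by candidate id); for
#'   `"regression"` also carries attributes `a` and `b`.
#' @export
rpgCandidates <- function(ped, gidx, candIdx, dG,
                          method = c("exact", "ancestor", "regression"),
                          aggChol = NULL, uHat = NULL) {
  method <- match.arg(method)
  n <- length(ped@id)
  gidx <- as.integer(gidx); candIdx <- as.integer(candIdx)
  if (any(candIdx %in% gidx))
    stop("candidates must be disjoint from the evaluation's genotyped set")
  if (any(candIdx < 1L | candIdx > n)) stop("candidate not in pedigree")
  out <- switch(method,
    exact = {
      if (is.null(aggChol)) aggChol <- chol(aSubmatrix(ped, gidx))
      x <- backsolve(aggChol, backsolve(aggChol, dG, transpose = TRUE))
      padded <- numeric(n)
      padded[gidx] <- x
      aTimesVector(ped, padded)[candIdx]
    },
    ancestor = rpgAncestorRoute(ped, gidx, candIdx, dG),
    regression = rpgRegressionRoute(ped, gidx, candIdx, dG, uHat)
  )
  names(out) <- ped@id[candIdx]
  out
}

# ancestor route: solve -(A^{anc,anc})^{-1} A^{anc,g} dG on the pruned
# ancestor pedigree of the genotyped animals, then run the parent-average
# recursion down the full pedigree.
rpgAncestorRoute <- function(ped, gidx, candIdx, dG) {
  n <- length(ped@id)
  pr <- pruneToAncestors(ped, gidx)
  sub <- pr$ped; map <- pr$map
  gSub <- match(gidx, map)
  ancSub <- setdiff(seq_along(map), gSub)
  d <- numeric(n)
  d[gidx] <- dG
  if (length(ancSub)) {
    AinvSub <- buildAInverse(sub)
    rhsAnc <- -as.numeric(AinvSub[ancSub, gSub, drop = FALSE] %*% dG)
    dAnc <- as.numeric(Matrix::solve(AinvSub[ancSub, ancSub, drop = FALSE],
                                     rhsAnc))
    d[map[ancSub]] <- dAnc
  }
  known <- logical(n)
  known[map] <- TRUE
  for (i in seq_len(n)) {
    if (known[i]) next
    acc <- 0
    if (ped@sire[i] > 0L) acc <- acc + 0.5 * d[ped@sire[i]]
    if (ped@dam[i] > 0L) acc <- acc + 0.5 * d[ped@dam[i]]
    d[i] <- acc
    known[i] <- TRUE
  }
  d[candIdx]
}

# regression route: OLS of dG on uG, applied to non-genotyped relatives,
# then a parent average per candidate; unknown ancestors contribute 0.
rpgRegressionRoute <- function(ped, gidx, candIdx, dG, uHat) {
  if (is.null(uHat))
    stop("uHat (GEBV per pedigree animal) is required for the regression route")
  n <- length(ped@id)
  uG <- uHat[gidx]
  if (length(uG) < 2 || sd(uG) == 0) {
    warning("degenerate regression (constant GEBV among genotyped animals); ",
            "falling back to a = mean(dG), b = 0")
    a <- mean(dG); b <- 0
  } else {
    fit <- lm(dG ~ uG)
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  }
  isG <- logical(n); isG[gidx] <- TRUE
  d <- numeric(n)
  d[gidx] <- dG
  d[!isG] <- a + b * uHat[!isG]
  parentAvg <- function(i) {
    acc <- 0
    if (ped@sire[i] > 0L) acc <- acc + 0.5 * d[ped@sire[i]]
    if (ped@dam[i] > 0L) acc <- acc + 0.5 * d[ped@dam[i]]
    acc
  }
  out <- vapply(candIdx, parentAvg, numeric(1))
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Parent genotype status of candidates
#'
#' Partitions candidates into GG (both parents genotyped), NG (exactly
#' one) and NN (none); an unknown parent counts as not genotyped.
#'
#' @param ped a [Pedigree-class].
#' @param candIdx candidate pedigree indices.
#' @param gidx genotyped-animal pedigree indices.
#' @return factor with levels GG, NG, NN, one per candidate.
#' @export
parentStatus <- function(ped, candIdx, gidx) {
  isG <- logical(length(ped@id)); isG[gidx] <- TRUE
  k <- vapply(as.integer(candIdx), function(i) {
    sum(c(ped@sire[i] > 0L && isG[ped@sire[i]],
          ped@dam[i] > 0L && isG[ped@dam[i]]))
  }, numeric(1))
  factor(c("NN", "NG", "GG")[k + 1], levels = c("GG", "NG", "NN"))
}

#' Indirect GEBV prediction for genotyped selection candidates
#'
#' The four predictors computed from a previous evaluation's solutions:
#' * `PA` — mean of parent GEBV (an unknown parent contributes 0, the
#'   base mean);
#' * `DGV` — direct genomic value Z_c g-hat, candidate genotypes
#'   centered with the evaluation's allele frequencies;
#' * `REG` — -mu-hat + Z_c g-hat + d-tilde_c with the
#'   regression-approximated RPG parent average;
#' * `GRV` — -mu-hat + Z_c g-hat + A_cg A_gg^{-1} d-hat_g, the exact
#'   decomposition.
#'
#' @param fit a [SingleStepFit-class] from the previous (reduced)
#'   evaluation.
#' @param ped the [Pedigree-class] covering evaluation animals and
#'   candidates.
#' @param candGeno [GenotypeMatrix-class] of the candidates (same marker
#'   set and order as the evaluation's).
#' @param methods subset of `c("PA", "DGV", "REG", "GRV")`.
#' @param rpgMethod route for the exact RPG term of GRV: `"exact"` or
#'   `"ancestor"`.
#' @return data frame: `candidate`, `method`, `gebv`, `dgv_component`,
#'   `rpg_component`, `j_component`, `parent_status`.
#' @export
predictIndirect <- function(fit, ped, candGeno,
                            methods = c("PA", "DGV", "REG", "GRV"),
                            rpgMethod = "exact") {
  methods <- match.arg(methods, several.ok = TRUE)
  factor <- fit@factor
  if (!identical(candGeno@markerIds, factor@geno@markerIds))
    stop("candidate markers must match the evaluation's marker set")
  candIdx <- match(candGeno@animalIds, ped@id)
  if (anyNA(candIdx)) stop("candidate not in pedigree")
  gidx <- match(factor@geno@animalIds, ped@id)
  if (anyNA(gidx)) stop("evaluation's genotyped animals not in pedigree")
  mu <- fit@jfactorMu
  gHat <- fit@snpEffects
  dG <- fit@rpg
  # candidate DGV on the evaluation's centering scale
  dgv <- as.numeric(candGeno@counts %*% gHat) - 2 * sum(factor@p * gHat)
  status <- parentStatus(ped, candIdx, gidx)
  rows <- list()
  gebvByIdx <- fit@gebv[match(ped@id, names(fit@gebv))]
  for (method in methods) {
    if (method == "PA") {
      pa <- vapply(candIdx, function(i) {
        acc <- 0
        if (ped@sire[i] > 0L) acc <- acc + 0.5 * gebvByIdx[ped@sire[i]]
        if (ped@dam[i] > 0L) acc <- acc + 0.5 * gebvByIdx[ped@dam[i]]
        acc
      }, numeric(1))
      rows[[method]] <- data.frame(
        candidate = candGeno@animalIds, method = method, gebv = pa,
        dgv_component = NA_real_, rpg_component = NA_real_,
        j_component = NA_real_, parent_status = as.character(status))
    } else if (method == "DGV") {
      rows[[method]] <- data.frame(
        candidate = candGeno@animalIds, method = method, gebv = dgv,
        dgv_component = dgv, rpg_component = 0, j_component = 0,
        parent_status = as.character(status))
    } else {
      dC <- if (method == "GRV")
        rpgCandidates(ped, gidx, candIdx, dG, method = rpgMethod,
                      aggChol = if (nrow(factor@aggChol)) factor@aggChol
                                else NULL)
      else
        rpgCandidates(ped, gidx, candIdx, dG, method = "regression",
                      uHat = fit@uHat[match(ped@id, names(fit@uHat))])
      rows[[method]] <- data.frame(
        candidate = candGeno@animalIds, method = method,
        gebv = -mu + dgv + as.numeric(dC),
        dgv_component = dgv, rpg_component = as.numeric(dC),
        j_component = -mu, parent_status = as.character(status))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
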