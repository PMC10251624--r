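# High-level driver: assemble, precondition, solve, and post-process one
# single-step evaluation into a SingleStepFit.

#' Run one single-step genomic evaluation
#'
#' Assembles the MME in the requested formulation, solves by PCG to the
#' requested tolerance, backsolves SNP effects (for ssGTBLUP; for
#' ssSNPBLUP they are part of the solution vector), computes residual
#' polygenic effects of the genotyped animals, and returns
#' J-factor-adjusted GEBV for every pedigree animal.
#'
#' The reported GEBV are u-hat + J_i * mu-hat when the J-factor is
#' fitted, so genotyped and non-genotyped animals are on a common base.
#'
#' @param ped a [Pedigree-class].
#' @param geno [GenotypeMatrix-class] of the genotyped animals.
#' @param phenotypes phenotype data frame (`animal`, fixed columns,
#'   `trait`).
#' @param model an [ssModel()].
#' @param tol,maxit PCG controls (see [pcgSolve()]).
#' @param snpDiagMode preconditioner SNP-diagonal mode
#'   (see [buildPreconditioner()]).
#' @param factor optional prebuilt [GenomicFactor-class].
#' @return a [SingleStepFit-class].
#' @export
singleStepSolve <- function(ped, geno, phenotypes, model = ssModel(h2 = 0.3),
                            tol = 1e-7, maxit = 5000L,
                            snpDiagMode = "exact", factor = NULL) {
  system <- assembleSystem(model, ped, geno, phenotypes, factor = factor)
  precond <- buildPreconditioner(system, snpDiagMode = snpDiagMode)
  res <- pcgSolve(system, precond, tol = tol, maxit = maxit)
  map <- system@map
  sol <- res$solutions
  fixed <- sol[map$fixed]
  names(fixed) <- map$fixedNames
  uHat <- sol[map$animal]
  factor <- map$factor
  uG <- uHat[map$gidx]
  gHat <- if (length(map$snp)) sol[map$snp]
          else backsolveSnpEffects(factor, uG)
  dG <- rpgGenotyped(factor, uG, gHat)
  mu <- if (model$jfactor) unname(fixed["jfactor"]) else 0
  gebvAll <- uHat + if (model$jfactor) map$jCov * mu else 0
  new("SingleStepFit",
      gebv = setNames(gebvAll, ped@id),
      uHat = setNames(uHat, ped@id),
      fixedEffects = fixed,
      jfactorMu = mu,
      jCovariate = if (model$jfactor) map$jCov else numeric(0),
      snpEffects = setNames(gHat, geno@markerIds),
      rpg = setNames(dG, geno@animalIds),
      genotyped = map$genotyped,
      factor = factor,
      pcg = list(iterations = res$iterations, converged = res$converged,
                 crHistory = res$crHistory, eigMin = res$eigMin,
                 eigMax = res$eigMax))
}
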