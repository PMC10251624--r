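# End-to-end orchestration of the two-evaluation study design:
# simulate -> solve full and reduced -> indirect predictions from the
# reduced solutions -> comparison report against the full evaluation.

#' Run the full/reduced indirect-prediction study end to end
#'
#' Simulates a breeding population, solves the full-data evaluation
#' (candidate genotypes included) and the reduced-data evaluation
#' (candidate genotypes excluded) in the requested formulation, computes
#' the four indirect candidate predictions from the reduced solutions,
#' and compares them with the full-data candidate GEBV.
#'
#' @param config a [simConfig()].
#' @param seed RNG seed for the simulation.
#' @param formulation `"ssgtblup"` (default) or `"sssnpblup"`.
#' @param tol,maxit PCG controls.
#' @param methods indirect methods to compute.
#' @param verbose print progress lines.
#' @return list: `study`, `fitFull`, `fitReduced`, `indirect`, `report`
#'   (from [compareIndirect()]), `commonCor` (full-vs-reduced GEBV
#'   correlation over all animals).
#' @export
runStudy <- function(config = simConfig(), seed = 1L,
                     formulation = c("ssgtblup", "sssnpblup"),
                     tol = 1e-7, maxit = 5000L,
                     methods = c("PA", "DGV", "REG", "GRV"),
                     verbose = interactive()) {
  formulation <- match.arg(formulation)
  say <- function(...) if (verbose) message(...)
  say("simulating study (seed ", seed, ") ...")
  study <- simulateStudy(config, seed = seed)
  model <- ssModel(h2 = config$h2, w = config$w, formulation = formulation,
                   sigmaU2 = config$sigmaU2)
  say("solving full evaluation (", length(study$gidxFull), " genotypes) ...")
  fitFull <- singleStepSolve(study$ped, study$genoFull, study$phenotypes,
                             model, tol = tol, maxit = maxit)
  say("solving reduced evaluation (", length(study$gidxReduced),
      " genotypes) ...")
  fitReduced <- singleStepSolve(study$ped, study$genoReduced,
                                study$phenotypes, model, tol = tol,
                                maxit = maxit)
  say("computing indirect predictions ...")
  indirect <- predictIndirect(fitReduced, study$ped, study$genoCandidates,
                              methods = methods)
  fullCand <- setNames(fitFull@gebv[study$candIdx],
                       study$ped@id[study$candIdx])
  report <- compareIndirect(indirect, fullCand,
                            sigmaU = sqrt(config$sigmaU2))
  # animals present in both evaluations: the reduced evaluation's data
  # extraction drops the candidates (no record, no genotype, no progeny
  # there), so the common set is every non-candidate animal
  common <- setdiff(seq_along(study$ped@id), study$candIdx)
  commonCor <- cor(fitFull@gebv[common], fitReduced@gebv[common])
  list(study = study, fitFull = fitFull, fitReduced = fitReduced,
       indirect = indirect, report = report, commonCor = commonCor)
}
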