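#' @import methods
#' @importFrom Matrix sparseMatrix crossprod t diag solve
#' @importFrom stats rnorm runif rbinom coef lm sd cor var setNames
#' @importFrom utils read.csv write.csv read.table write.table
NULL

#' Pedigree of a breeding population
#'
#' An S4 container for a topologically ordered pedigree: every animal's
#' parents precede it. Parent index 0 means unknown; unknown parents are
#' treated as unrelated base-population animals. Inbreeding coefficients
#' (diagonal of the numerator relationship matrix A minus one) are computed
#' on construction with the Meuwissen-Luo recursion.
#'
#' @slot id character vector of external animal labels (unique).
#' @slot sire integer vector, row index of each animal's sire (0 = unknown).
#' @slot dam integer vector, row index of each animal's dam (0 = unknown).
#' @slot inbreeding numeric vector of pedigree inbreeding coefficients F.
#' @slot generation integer vector of generation numbers (NA when unknown);
#'   carried through from input files or the simulator, not used in algebra.
#'
#' @seealso [readPedigree()], [computeInbreeding()], [buildAInverse()],
#'   [aTimesVector()], [aSubmatrix()], [pruneToAncestors()]
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    sire = "integer",
    dam = "integer",
    inbreeding = "numeric",
    generation = "integer"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msg <- character()
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@inbreeding) != n || length(object@generation) != n)
    msg <- c(msg, "slot lengths differ")
  if (anyDuplicated(object@id))
    msg <- c(msg, "duplicated animal ids")
  idx <- seq_len(n)
  if (n && (any(object@sire < 0L) || any(object@dam < 0L) ||
            any(object@sire > n) || any(object@dam > n)))
    msg <- c(msg, "parent indices out of range")
  if (n && (any(object@sire >= idx) || any(object@dam >= idx)))
    msg <- c(msg, "parents must precede offspring (topological order)")
  if (n && (any(object@inbreeding < 0) || any(object@inbreeding >= 1)))
    msg <- c(msg, "inbreeding coefficients must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn Pedigree number of animals
#' @param x a `Pedigree`
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

setMethod("show", "Pedigree", function(object) {
  n <- length(object)
  founders <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", n, "animals (", founders, "founders )\n")
  if (n) cat("  mean inbreeding:", format(mean(object@inbreeding), digits = 4),
             " max:", format(max(object@inbreeding), digits = 4), "\n")
})

#' Accessors for Pedigree
#'
#' `animalIds()` returns external labels; `sireOf()`/`damOf()` the internal
#' parent indices (0 = unknown); `inbreeding()` the coefficients F.
#'
#' @param ped a [Pedigree-class] object
#' @return vectors parallel to the pedigree order.
#' @export
animalIds <- function(ped) ped@id

#' @rdname animalIds
#' @export
sireOf <- function(ped) ped@sire

#' @rdname animalIds
#' @export
damOf <- function(ped) ped@dam

#' @rdname animalIds
#' @export
inbreeding <- function(ped) ped@inbreeding

#' Genotype matrix of allele counts
#'
#' Counts of the first (A1) allele per animal and marker, values in
#' \{0, 1, 2\}, with no missing codes (missingness is resolved at read
#' time). Monomorphic markers are expected to be removed before
#' construction of genomic factors.
#'
#' @slot counts integer matrix, animals in rows, markers in columns.
#' @slot animalIds character, row labels.
#' @slot markerIds character, column labels.
#'
#' @seealso [readPlink()], [writePlink()], [alleleFrequencies()]
#' @export
setClass("GenotypeMatrix",
  representation(
    counts = "matrix",
    animalIds = "character",
    markerIds = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@animalIds))
    msg <- c(msg, "animalIds length != nrow(counts)")
  if (ncol(object@counts) != length(object@markerIds))
    msg <- c(msg, "markerIds length != ncol(counts)")
  if (anyNA(object@counts))
    msg <- c(msg, "missing genotype codes present")
  else if (length(object@counts) &&
           !all(object@counts %in% c(0, 1, 2)))
    msg <- c(msg, "genotype counts must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@counts), "animals x",
      ncol(object@counts), "markers\n")
})

#' @describeIn GenotypeMatrix animals x markers
#' @param x a `GenotypeMatrix`
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@counts))

#' Genomic factor for Woodbury-form inverse relationship products
#'
#' Holds everything needed to apply the inverse of the regularized genomic
#' relationship matrix G_C = ZBZ' + C to a vector without forming G_C:
#' the centered-genotype semantics (allele frequencies p, VanRaden scaling
#' constant k, diagonal of B), the regularization C (either epsilon*I or
#' w*A_gg with a cached dense Cholesky factor of A_gg), the m x m matrix
#' K = Z'C^{-1}Z + B^{-1} with its lower Cholesky factor L, and optionally
#' the matrix T = L^{-1} Z' C^{-1} used by the original product strategy.
#'
#' @slot geno the [GenotypeMatrix-class] of the evaluation's genotyped set.
#' @slot p numeric, allele frequencies used for centering.
#' @slot k numeric(1), VanRaden scaling constant 2*sum p(1-p).
#' @slot w numeric(1), residual polygenic proportion (0 when C = eps*I).
#' @slot bDiag numeric, diagonal of the marker scaling matrix B.
#' @slot regKind character(1), `"epsilon_identity"` or `"w_agg"`.
#' @slot epsilon numeric(1), ridge for the identity regularization.
#' @slot aggChol matrix, upper Cholesky factor of A_gg (w_agg only).
#' @slot aggDiagInv numeric, diagonal of A_gg^{-1} (w_agg only).
#' @slot K matrix, m x m.
#' @slot L matrix, lower Cholesky factor of K.
#' @slot Tmat matrix, m x n matrix T (may have zero extent when unused).
#'
#' @seealso [buildGenomicFactor()], [gcinvTimes()], [denseGC()]
#' @export
setClass("GenomicFactor",
  representation(
    geno = "GenotypeMatrix",
    p = "numeric",
    k = "numeric",
    w = "numeric",
    bDiag = "numeric",
    regKind = "character",
    epsilon = "numeric",
    aggChol = "matrix",
    aggDiagInv = "numeric",
    K = "matrix",
    L = "matrix",
    Tmat = "matrix"
  )
)

setValidity("GenomicFactor", function(object) {
  msg <- character()
  m <- ncol(object@geno@counts)
  if (!object@regKind %in% c("epsilon_identity", "w_agg"))
    msg <- c(msg, "regKind must be 'epsilon_identity' or 'w_agg'")
  if (length(object@p) != m || length(object@bDiag) != m)
    msg <- c(msg, "p and bDiag must have one entry per marker")
  if (nrow(object@K) != m || ncol(object@K) != m)
    msg <- c(msg, "K must be m x m")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomicFactor", function(object) {
  d <- dim(object@geno)
  cat("GenomicFactor:", d[1], "genotyped animals,", d[2], "markers\n")
  cat("  regularization:",
      if (object@regKind == "w_agg")
        sprintf("C = w * A_gg (w = %g)", object@w)
      else sprintf("C = eps * I (eps = %g)", object@epsilon), "\n")
  cat("  strategies:", if (nrow(object@Tmat)) "component_wise, original_T"
      else "component_wise", "\n")
})

#' Matrix-free single-step mixed model equations
#'
#' The assembled coefficient-matrix action, right-hand side, exact (or
#' approximated) diagonal and the equation layout of a single-step system
#' in either the Woodbury (ssGTBLUP) or explicit-SNP (ssSNPBLUP)
#' formulation.
#'
#' @slot matvec function(v) returning the coefficient matrix times v.
#' @slot rhs numeric right-hand side.
#' @slot diagonal numeric, diagonal of the coefficient matrix.
#' @slot map list with blocks: `fixed` (indices), `animal` (indices over
#'   all animals in pedigree order), `snp` (indices, empty for ssGTBLUP),
#'   `genotyped` (logical per animal), plus model metadata (`lambda`,
#'   `formulation`, `jfactor` column index in X or 0).
#'
#' @seealso [assembleSystem()], [pcgSolve()]
#' @export
setClass("SingleStepSystem",
  representation(
    matvec = "function",
    rhs = "numeric",
    diagonal = "numeric",
    map = "list"
  )
)

setMethod("show", "SingleStepSystem", function(object) {
  m <- object@map
  cat("SingleStepSystem (", m$formulation, "):",
      length(object@rhs), "equations\n")
  cat("  fixed:", length(m$fixed), " animal:", length(m$animal),
      " snp:", length(m$snp), "\n")
})

#' Solutions of a converged single-step evaluation
#'
#' Everything a later indirect prediction needs from one evaluation:
#' J-factor-adjusted GEBV for all animals, raw animal-effect solutions,
#' fixed effects, the fitted J-factor mean, backsolved SNP effects,
#' residual polygenic effects of the genotyped animals, and the genomic
#' factor (carrying the allele frequencies and scaling the SNP effects
#' were estimated under).
#'
#' @slot gebv numeric, J-adjusted GEBV, one per pedigree animal.
#' @slot uHat numeric, raw additive-effect solutions per animal.
#' @slot fixedEffects numeric, named fixed-effect solutions.
#' @slot jfactorMu numeric(1), fitted J-factor covariate (0 if not fitted).
#' @slot jCovariate numeric, J covariate value per animal (0-length if not fitted).
#' @slot snpEffects numeric, backsolved marker effects g-hat.
#' @slot rpg numeric, residual polygenic effects d-hat of genotyped animals.
#' @slot genotyped logical per pedigree animal.
#' @slot factor the [GenomicFactor-class] of the evaluation.
#' @slot pcg list: iterations, converged, crHistory, eigMin, eigMax.
#'
#' @seealso [singleStepSolve()], [predictIndirect()]
#' @export
setClass("SingleStepFit",
  representation(
    gebv = "numeric",
    uHat = "numeric",
    fixedEffects = "numeric",
    jfactorMu = "numeric",
    jCovariate = "numeric",
    snpEffects = "numeric",
    rpg = "numeric",
    genotyped = "logical",
    factor = "GenomicFactor",
    pcg = "list"
  )
)

setMethod("show", "SingleStepFit", function(object) {
  cat("SingleStepFit:", length(object@gebv), "animals,",
      sum(object@genotyped), "genotyped,",
      length(object@snpEffects), "markers\n")
  cat("  PCG:", object@pcg$iterations, "iterations, converged:",
      object@pcg$converged, "\n")
  if (length(object@jCovariate))
    cat("  J-factor mu-hat:", format(object@jfactorMu, digits = 4), "\n")
})

#' @describeIn SingleStepFit J-adjusted GEBV in pedigree order
#' @param object a `SingleStepFit`
#' @export
gebv <- function(object) object@gebv

#' @describeIn SingleStepFit backsolved SNP effect solutions
#' @export
snpEffects <- function(object) object@snpEffects
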