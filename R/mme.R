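# Matrix-free assembly of the univariate single-step mixed model
# equations, in the Woodbury (ssGTBLUP) and explicit-SNP (ssSNPBLUP)
# formulations. Equation layout: [fixed | animal (pedigree order) | snp].

#' Specify a single-step model
#'
#' @param fixedTerms character vector of phenotype-table column names to
#'   fit as fixed effects; character/factor columns become cross-classified
#'   effects (sorted levels, first level absorbed into the intercept),
#'   numeric columns become covariates. The intercept is always fitted.
#' @param sigmaU2,sigmaE2 additive genetic and residual variances; their
#'   ratio lambda = sigmaE2/sigmaU2 enters the MME.
#' @param h2 alternative to `sigmaE2`: narrow-sense heritability, from
#'   which sigmaE2 = sigmaU2 (1 - h2)/h2.
#' @param w residual polygenic proportion in (0, 1) for the w*A_gg
#'   regularization; ignored for `regKind = "epsilon_identity"`.
#' @param epsilon ridge for the identity regularization.
#' @param regKind `"w_agg"` (default) or `"epsilon_identity"`.
#' @param formulation `"ssgtblup"` or `"sssnpblup"`.
#' @param strategy `"component_wise"` or `"original_T"` product strategy
#'   (ssGTBLUP only).
#' @param jfactor fit the pedigree-to-genomic base-difference covariate
#'   (default `TRUE`).
#' @return a list of class `ssModel`.
#' @export
ssModel <- function(fixedTerms = character(), sigmaU2 = 1, sigmaE2 = NULL,
                    w = 0.20, epsilon = 0.01,
                    regKind = c("w_agg", "epsilon_identity"),
                    formulation = c("ssgtblup", "sssnpblup"),
                    strategy = c("component_wise", "original_T"),
                    jfactor = TRUE, h2 = NULL) {
  regKind <- match.arg(regKind)
  formulation <- match.arg(formulation)
  strategy <- match.arg(strategy)
  if (is.null(sigmaE2)) {
    if (is.null(h2)) stop("supply sigmaE2 or h2")
    sigmaE2 <- sigmaU2 * (1 - h2) / h2
  }
  stopifnot(sigmaU2 > 0, sigmaE2 > 0)
  if (regKind == "w_agg") stopifnot(w > 0, w < 1)
  if (formulation == "sssnpblup" && strategy == "original_T")
    stop("strategy 'original_T' applies to the ssgtblup formulation only")
  structure(list(fixedTerms = fixedTerms, sigmaU2 = sigmaU2,
                 sigmaE2 = sigmaE2, lambda = sigmaE2 / sigmaU2, w = w,
                 epsilon = epsilon, regKind = regKind,
                 formulation = formulation, strategy = strategy,
                 jfactor = jfactor),
            class = "ssModel")
}

#' Fixed-effect and animal incidence structures
#'
#' Builds the sparse fixed-effect design X (intercept, class dummies in
#' sorted-label order with the first level absorbed, covariates) and the
#' record-to-animal incidence W from a phenotype table.
#'
#' @param phenotypes data frame with columns `animal`, `trait` and any
#'   fixed-effect columns.
#' @param ped a [Pedigree-class]; every record's animal must be present.
#' @param fixedTerms character vector of fixed-effect column names.
#' @return list with sparse `X`, sparse `W` (records x animals), numeric
#'   `y`, integer `recAnimal`, character `colnames`.
#' @export
buildDesign <- function(phenotypes, ped, fixedTerms = character()) {
  recAnimal <- match(as.character(phenotypes$animal), ped@id)
  if (anyNA(recAnimal))
    stop("phenotype record on animal absent from pedigree: ",
         phenotypes$animal[which(is.na(recAnimal))[1]])
  nrec <- nrow(phenotypes)
  cols <- list("(Intercept)" = rep(1, nrec))
  for (term in fixedTerms) {
    x <- phenotypes[[term]]
    if (is.null(x)) stop("fixed term not in phenotype table: ", term)
    if (is.numeric(x)) {
      cols[[term]] <- x
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2)
        stop("fixed effect '", term, "' has a single level")
      for (l in lev[-1])
        cols[[paste0(term, ":", l)]] <- as.numeric(x == l)
    }
  }
  X <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  colnames(X) <- names(cols)
  W <- Matrix::sparseMatrix(i = seq_len(nrec), j = recAnimal, x = 1,
                            dims = c(nrec, length(ped@id)))
  list(X = X, W = W, y = as.numeric(phenotypes$trait),
       recAnimal = recAnimal, colnames = names(cols))
}

#' J-factor covariate over all animals
#'
#' The covariate that absorbs the mean difference between the pedigree
#' base and the genomic base: -1 for genotyped animals and
#' -(A_ng A_gg^{-1} 1)_i for non-genotyped animals, computed as a single
#' A_gg solve followed by one Colleau product with zero padding.
#'
#' @param ped a [Pedigree-class].
#' @param gidx integer indices of the genotyped animals.
#' @param aggChol upper Cholesky factor of A_gg (order matching `gidx`).
#' @return numeric covariate per pedigree animal.
#' @export
buildJFactorCovariate <- function(ped, gidx, aggChol) {
  n <- length(ped@id)
  tvec <- backsolve(aggChol, backsolve(aggChol, rep(1, length(gidx)),
                                       transpose = TRUE))
  padded <- numeric(n)
  padded[gidx] <- tvec
  j <- -aTimesVector(ped, padded)
  j[gidx] <- -1
  j
}

#' Assemble the single-step mixed model equations
#'
#' Builds the matrix-free coefficient operator, right-hand side, exact
#' diagonal and equation map for either formulation. The ssGTBLUP
#' operator applies lambda * A^{-1} plus the genotyped-block correction
#' lambda * (G_C^{-1} - A_gg^{-1}); the ssSNPBLUP operator carries the
#' SNP block explicitly, applying K as Z'(C^{-1}(Z v)) + B^{-1} v so that
#' no m x m product is needed inside an iteration.
#'
#' @param model an [ssModel()].
#' @param ped a [Pedigree-class].
#' @param geno [GenotypeMatrix-class] of the genotyped animals (ids must
#'   be pedigree animals), or `NULL` for plain pedigree BLUP (no genomic
#'   term; requires `jfactor = FALSE`).
#' @param phenotypes phenotype data frame (see [buildDesign()]).
#' @param factor optional prebuilt [GenomicFactor-class]; built from
#'   `geno` and the model regularization when omitted.
#' @param omitCorrectionDiag drop the Woodbury low-rank term from the
#'   stored diagonal (mirrors production component-wise preconditioners
#'   that skip it); default `FALSE` (exact diagonal).
#' @return a [SingleStepSystem-class].
#' @export
assembleSystem <- function(model, ped, geno, phenotypes, factor = NULL,
                           omitCorrectionDiag = FALSE) {
  stopifnot(inherits(model, "ssModel"))
  n <- length(ped@id)
  if (is.null(geno)) {
    # no genomic information: the system is plain pedigree BLUP
    if (model$jfactor)
      stop("the J-factor needs a genotyped set; use jfactor = FALSE")
    des <- buildDesign(phenotypes, ped, model$fixedTerms)
    X <- des$X; W <- des$W; y <- des$y
    nf <- ncol(X)
    lambda <- model$lambda
    Ainv <- buildAInverse(ped)
    fixedIdx <- seq_len(nf)
    animalIdx <- nf + seq_len(n)
    matvec <- function(v) {
      vf <- v[fixedIdx]; va <- v[animalIdx]
      rec <- as.numeric(X %*% vf) + va[des$recAnimal]
      c(as.numeric(Matrix::crossprod(X, rec)),
        as.numeric(Matrix::crossprod(W, rec)) +
          lambda * as.numeric(Ainv %*% va))
    }
    rhs <- c(as.numeric(Matrix::crossprod(X, y)),
             as.numeric(Matrix::crossprod(W, y)))
    diagonal <- c(as.numeric(Matrix::colSums(X^2)),
                  as.numeric(Matrix::colSums(W)) + lambda * Matrix::diag(Ainv))
    map <- list(fixed = fixedIdx, animal = animalIdx, snp = integer(0),
                gidx = integer(0), genotyped = rep(FALSE, n),
                lambda = lambda, formulation = "pedigree_blup",
                strategy = model$strategy, jCov = NULL, X = X, W = W, y = y,
                recAnimal = des$recAnimal, Ainv = Ainv, model = model,
                nAnimals = n, fixedNames = colnames(X))
    return(new("SingleStepSystem", matvec = matvec, rhs = rhs,
               diagonal = diagonal, map = map))
  }
  gidx <- match(geno@animalIds, ped@id)
  if (anyNA(gidx)) stop("genotyped animal absent from pedigree")
  if (is.null(factor)) {
    agg <- if (model$regKind == "w_agg") aSubmatrix(ped, gidx) else NULL
    factor <- buildGenomicFactor(
      geno, regKind = model$regKind, w = model$w, epsilon = model$epsilon,
      agg = agg, withT = (model$strategy == "original_T"))
  }
  # A_gg Cholesky for the -A_gg^{-1} correction (independent of C kind)
  aggChol <- if (factor@regKind == "w_agg") factor@aggChol
             else chol(aSubmatrix(ped, gidx))
  aggInvDiag <- if (factor@regKind == "w_agg") factor@aggDiagInv
                else diag(chol2inv(aggChol))
  des <- buildDesign(phenotypes, ped, model$fixedTerms)
  X <- des$X; W <- des$W; y <- des$y
  jCov <- NULL
  if (model$jfactor) {
    jCov <- buildJFactorCovariate(ped, gidx, aggChol)
    X <- cbind(X, Matrix::Matrix(jCov[des$recAnimal], ncol = 1, sparse = TRUE))
    colnames(X) <- c(des$colnames, "jfactor")
  }
  nf <- ncol(X)
  m <- ncol(geno@counts)
  lambda <- model$lambda
  Ainv <- buildAInverse(ped)
  snpBlock <- model$formulation == "sssnpblup"
  fixedIdx <- seq_len(nf)
  animalIdx <- nf + seq_len(n)
  snpIdx <- if (snpBlock) nf + n + seq_len(m) else integer(0)
  aggSolve <- function(v)
    backsolve(aggChol, backsolve(aggChol, v, transpose = TRUE))
  strategy <- model$strategy

  if (!snpBlock) {
    matvec <- function(v) {
      vf <- v[fixedIdx]; va <- v[animalIdx]
      rec <- as.numeric(X %*% vf) + va[des$recAnimal]
      rf <- as.numeric(Matrix::crossprod(X, rec))
      ra <- as.numeric(Matrix::crossprod(W, rec)) +
        lambda * as.numeric(Ainv %*% va)
      vg <- va[gidx]
      ra[gidx] <- ra[gidx] +
        lambda * (gcinvTimes(factor, vg, strategy) - aggSolve(vg))
      c(rf, ra)
    }
  } else {
    matvec <- function(v) {
      vf <- v[fixedIdx]; va <- v[animalIdx]; g <- v[snpIdx]
      rec <- as.numeric(X %*% vf) + va[des$recAnimal]
      rf <- as.numeric(Matrix::crossprod(X, rec))
      ra <- as.numeric(Matrix::crossprod(W, rec)) +
        lambda * as.numeric(Ainv %*% va)
      vg <- va[gidx]
      civg <- cinvTimes(factor, vg)
      Zg <- zTimes(geno, factor@p, g)
      ra[gidx] <- ra[gidx] + lambda *
        (civg - aggSolve(vg) - cinvTimes(factor, Zg))
      rg <- lambda * (-ztTimes(geno, factor@p, civg) +
                      ztTimes(geno, factor@p, cinvTimes(factor, Zg)) +
                      g / factor@bDiag)
      c(rf, ra, rg)
    }
  }

  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(W, y)),
           if (snpBlock) numeric(m))

  # exact diagonal
  dFixed <- as.numeric(Matrix::colSums(X^2))
  dAnimal <- as.numeric(Matrix::colSums(W)) + lambda * Matrix::diag(Ainv)
  corr <- gcinvCorrectionDiag(factor)
  ciDiag <- if (factor@regKind == "epsilon_identity")
    rep(1 / factor@epsilon, length(gidx)) else factor@aggDiagInv / factor@w
  if (!snpBlock) {
    gDiag <- if (omitCorrectionDiag) ciDiag - aggInvDiag
             else corr$gcinvDiag - aggInvDiag
    dAnimal[gidx] <- dAnimal[gidx] + lambda * gDiag
    dSnp <- numeric(0)
  } else {
    dAnimal[gidx] <- dAnimal[gidx] + lambda * (ciDiag - aggInvDiag)
    dSnp <- lambda * diag(factor@K)
  }
  diagonal <- c(dFixed, dAnimal, dSnp)

  map <- list(fixed = fixedIdx, animal = animalIdx, snp = snpIdx,
              gidx = gidx, genotyped = seq_len(n) %in% gidx,
              lambda = lambda, formulation = model$formulation,
              strategy = strategy, jCov = jCov, X = X, W = W, y = y,
              recAnimal = des$recAnimal, Ainv = Ainv, aggChol = aggChol,
              factor = factor, model = model, nAnimals = n,
              fixedNames = colnames(X))
  new("SingleStepSystem", matvec = matvec, rhs = rhs, diagonal = diagonal,
      map = map)
}

#' Dense coefficient matrix and right-hand side (oracle helper)
#'
#' Explicitly assembles the coefficient matrix of a
#' [SingleStepSystem-class] for direct solving and cross-checks. Refuses
#' beyond 5000 equations.
#'
#' @param system a [SingleStepSystem-class].
#' @return list with dense `C` and `rhs`.
#' @export
denseReference <- function(system) {
  map <- system@map
  neq <- length(system@rhs)
  if (neq > 5000) stop("refusing to densify a system with > 5000 equations")
  X <- as.matrix(map$X); W <- as.matrix(map$W)
  Ainv <- as.matrix(map$Ainv)
  factor <- map$factor
  lambda <- map$lambda
  n <- map$nAnimals
  gidx <- map$gidx
  nf <- ncol(X)
  if (map$formulation == "pedigree_blup") {
    C <- rbind(cbind(crossprod(X), crossprod(X, W)),
               cbind(crossprod(W, X), crossprod(W) + lambda * Ainv))
    return(list(C = as.matrix(C), rhs = system@rhs))
  }
  agg <- crossprod(map$aggChol)
  aggInv <- chol2inv(map$aggChol)
  XtX <- crossprod(X)
  XtW <- crossprod(X, W)
  WtW <- crossprod(W)
  if (map$formulation == "ssgtblup") {
    GCinv <- solve(denseGC(factor, agg = if (factor@regKind == "w_agg") agg
                                          else NULL))
    Huu <- Ainv * lambda
    Huu[gidx, gidx] <- Huu[gidx, gidx] + lambda * (GCinv - aggInv)
    C <- rbind(cbind(XtX, XtW),
               cbind(t(XtW), WtW + Huu))
  } else {
    m <- ncol(factor@geno@counts)
    Z <- sweep(factor@geno@counts, 2, 2 * factor@p)
    Cinv <- if (factor@regKind == "w_agg") aggInv / factor@w
            else diag(1 / factor@epsilon, length(gidx))
    CiZ <- Cinv %*% Z
    Huu <- Ainv * lambda
    Huu[gidx, gidx] <- Huu[gidx, gidx] + lambda * (Cinv - aggInv)
    Cug <- matrix(0, n, m)
    Cug[gidx, ] <- -lambda * CiZ
    C <- rbind(
      cbind(XtX, XtW, matrix(0, nf, m)),
      cbind(t(XtW), WtW + Huu, Cug),
      cbind(matrix(0, m, nf), t(Cug), lambda * factor@K))
  }
  list(C = as.matrix(C), rhs = system@rhs)
}
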