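# Preconditioned conjugate gradient for the single-step MME, with the
# block preconditioner used in large evaluations: a dense Cholesky of
# P_ff = X'X + diag(X'X) * 1e-4 on the fixed block and the (exact or
# approximated) coefficient-matrix diagonal on the random blocks.

#' Build the PCG preconditioner
#'
#' @param system a [SingleStepSystem-class].
#' @param snpDiagMode `"exact"` (default; uses the stored diagonal, i.e.
#'   lambda * diag(K)) or `"approx_2pqn"` (replaces the SNP diagonal by
#'   lambda * (c * 2 p_i (1-p_i) n + 1/b_i) with c = 1/w or 1/epsilon,
#'   the approximation used when K is never formed).
#' @return list with `apply(v)` (the preconditioner solve), `pffChol`,
#'   `randomDiag`.
#' @export
buildPreconditioner <- function(system, snpDiagMode = c("exact", "approx_2pqn")) {
  snpDiagMode <- match.arg(snpDiagMode)
  map <- system@map
  fixedIdx <- map$fixed
  XtX <- as.matrix(Matrix::crossprod(map$X))
  Pff <- XtX + diag(diag(XtX) * 1e-4, nrow(XtX))
  pffChol <- chol(Pff)
  randomDiag <- system@diagonal[-fixedIdx]
  if (snpDiagMode == "approx_2pqn" && length(map$snp)) {
    factor <- map$factor
    ng <- nrow(factor@geno@counts)
    cScale <- if (factor@regKind == "w_agg") 1 / factor@w else 1 / factor@epsilon
    approx <- map$lambda *
      (cScale * 2 * factor@p * (1 - factor@p) * ng + 1 / factor@bDiag)
    randomDiag[length(map$animal) + seq_along(map$snp)] <- approx
  }
  if (any(randomDiag <= 0))
    stop("nonpositive preconditioner diagonal at random equation ",
         which(randomDiag <= 0)[1])
  applyP <- function(v) {
    out <- numeric(length(v))
    out[fixedIdx] <- backsolve(pffChol,
                               backsolve(pffChol, v[fixedIdx],
                                         transpose = TRUE))
    out[-fixedIdx] <- v[-fixedIdx] / randomDiag
    out
  }
  list(apply = applyP, pffChol = pffChol, randomDiag = randomDiag)
}

#' Relative left-minus-right convergence criterion
#'
#' C_r = ||C s - r|| / ||r|| in 2-norms for the current solution vector.
#'
#' @param system a [SingleStepSystem-class].
#' @param s solution vector.
#' @return numeric(1).
#' @export
convergenceCriterion <- function(system, s) {
  rn <- sqrt(sum(system@rhs^2))
  if (rn == 0) stop("zero right-hand side; criterion undefined")
  sqrt(sum((system@matvec(s) - system@rhs)^2)) / rn
}

#' Solve a single-step system by preconditioned conjugate gradient
#'
#' Standard PCG recurrences from a zero start vector, evaluating the
#' relative residual criterion every iteration (the maintained residual
#' r_k = rhs - C s_k makes this free). Also records the alpha/beta
#' scalars for the Lanczos effective-eigenvalue estimates.
#'
#' @param system a [SingleStepSystem-class].
#' @param precond a preconditioner from [buildPreconditioner()]; built
#'   with defaults when omitted.
#' @param tol convergence tolerance on C_r (default 1e-7).
#' @param maxit iteration cap (default 5000).
#' @param start optional start vector (default zero).
#' @return a list of class `pcgResult`: `solutions`, `crHistory`,
#'   `iterations`, `converged`, `eigMin`, `eigMax`.
#' @export
pcgSolve <- function(system, precond = NULL, tol = 1e-7, maxit = 5000L,
                     start = NULL) {
  if (is.null(precond)) precond <- buildPreconditioner(system)
  b <- system@rhs
  bn <- sqrt(sum(b^2))
  if (bn == 0) stop("zero right-hand side")
  x <- if (is.null(start)) numeric(length(b)) else start
  r <- b - system@matvec(x)
  z <- precond$apply(r)
  p <- z
  rz <- sum(r * z)
  crHistory <- numeric(0)
  alphas <- numeric(0); betas <- numeric(0)
  converged <- FALSE
  it <- 0L
  cr <- sqrt(sum(r^2)) / bn
  if (cr < tol) converged <- TRUE
  while (!converged && it < maxit) {
    it <- it + 1L
    Ap <- system@matvec(p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0)
      stop("PCG breakdown (non-positive curvature) at iteration ", it)
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (any(!is.finite(r)))
      stop("NaN in PCG recurrence at iteration ", it)
    z <- precond$apply(r)
    rzNew <- sum(r * z)
    beta <- rzNew / rz
    p <- z + beta * p
    rz <- rzNew
    cr <- sqrt(sum(r^2)) / bn
    crHistory <- c(crHistory, cr)
    alphas <- c(alphas, alpha); betas <- c(betas, beta)
    if (cr < tol) converged <- TRUE
  }
  eig <- effectiveEigenvalues(list(alphas = alphas, betas = betas))
  structure(list(solutions = x, crHistory = crHistory, iterations = it,
                 converged = converged, eigMin = eig[1], eigMax = eig[2],
                 alphas = alphas, betas = betas),
            class = "pcgResult")
}

#' Effective extreme eigenvalues from PCG scalars
#'
#' Builds the Lanczos tridiagonal implied by the PCG alpha/beta sequence
#' and returns its extreme eigenvalues — estimates of the smallest and
#' largest effective eigenvalues of the preconditioned coefficient
#' matrix. Diagnostic only.
#'
#' @param scalars list with `alphas` and `betas` from a PCG run.
#' @return numeric(2): `c(eigMin, eigMax)`; `NA` when fewer than 3
#'   iterations were recorded.
#' @export
effectiveEigenvalues <- function(scalars) {
  a <- scalars$alphas; be <- scalars$betas
  k <- length(a)
  if (k < 3) return(c(NA_real_, NA_real_))
  dg <- numeric(k)
  dg[1] <- 1 / a[1]
  for (j in 2:k) dg[j] <- 1 / a[j] + be[j - 1] / a[j - 1]
  off <- sqrt(pmax(be[seq_len(k - 1)], 0)) / a[seq_len(k - 1)]
  Tm <- diag(dg)
  for (j in seq_len(k - 1)) {
    Tm[j, j + 1] <- off[j]
    Tm[j + 1, j] <- off[j]
  }
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  c(min(ev), max(ev))
}
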