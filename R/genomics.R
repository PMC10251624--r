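# Genotype I/O and the genomic side of the single-step algebra.
#
# PLINK 1 binary layout: .bed starts with magic bytes 0x6C 0x1B, then a
# mode byte (0x01 = variant-major, the only mode supported), then one
# byte block of ceil(n/4) bytes per variant, 2 bits per genotype packed
# little-endian within a byte: 00 = homozygous A1 (count 2),
# 10 = heterozygous (1), 11 = homozygous A2 (0), 01 = missing.

#' Read genotypes from PLINK 1 binary files
#'
#' Decodes `prefix.bed`/`.bim`/`.fam` into allele counts of the A1
#' allele. Monomorphic markers (after missing handling) are dropped with
#' a message. Only the variant-major .bed mode is supported.
#'
#' @param prefix path prefix (without extension).
#' @param missingPolicy `"fail"` (default) errors on any missing code;
#'   `"mean_impute"` replaces missing cells with the column mean of
#'   observed counts, with a warning.
#' @param dropMonomorphic drop markers with allele frequency 0 or 1
#'   (default `TRUE`).
#' @return a [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix, missingPolicy = c("fail", "mean_impute"),
                      dropMonomorphic = TRUE) {
  missingPolicy <- match.arg(missingPolicy)
  bim <- read.table(paste0(prefix, ".bim"), colClasses = "character")
  fam <- read.table(paste0(prefix, ".fam"), colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bedPath <- paste0(prefix, ".bed")
  raw <- readBin(bedPath, "raw", n = file.info(bedPath)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (bad magic bytes): ", bedPath)
  if (raw[3] != as.raw(0x01))
    stop("sample-major .bed files are not supported")
  bpv <- ceiling(n / 4)
  expected <- 3 + bpv * m
  if (length(raw) != expected)
    stop("truncated .bed file: expected ", expected, " bytes, found ",
         length(raw))
  payload <- raw[-(1:3)]
  # unpack all 2-bit codes at once
  bits <- matrix(as.integer(rawToBits(payload)), nrow = 8)
  codes <- bits[seq(1, 8, by = 2), , drop = FALSE] +
    2L * bits[seq(2, 8, by = 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4 * bpv)[seq_len(n), , drop = FALSE]
  # map 2-bit code -> count of A1: 0->2, 2->1, 3->0, 1->NA (missing)
  lut <- c(2L, NA_integer_, 1L, 0L)
  counts <- matrix(lut[codes + 1L], n, m)
  if (anyNA(counts)) {
    if (missingPolicy == "fail")
      stop("missing genotype codes present; use missingPolicy = 'mean_impute'")
    warning("mean-imputing ", sum(is.na(counts)), " missing genotype calls")
    for (j in which(colSums(is.na(counts)) > 0)) {
      mu <- mean(counts[, j], na.rm = TRUE)
      counts[is.na(counts[, j]), j] <- mu
    }
  }
  geno <- new("GenotypeMatrix", counts = counts,
              animalIds = fam[[2]], markerIds = bim[[2]])
  if (dropMonomorphic) {
    p <- colSums(geno@counts) / (2 * n)
    mono <- p <= 0 | p >= 1
    if (any(mono)) {
      message("dropping ", sum(mono), " monomorphic markers")
      geno <- new("GenotypeMatrix", counts = geno@counts[, !mono, drop = FALSE],
                  animalIds = geno@animalIds, markerIds = geno@markerIds[!mono])
    }
  }
  geno
}

#' Write genotypes to PLINK 1 binary files
#'
#' Inverse of [readPlink()]: writes variant-major `.bed` plus minimal
#' `.bim`/`.fam` sidecars. Counts must be integral (0/1/2).
#'
#' @param geno a [GenotypeMatrix-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(geno, prefix) {
  counts <- geno@counts
  if (any(counts != round(counts)))
    stop("cannot write imputed (non-integer) genotypes to PLINK binary")
  n <- nrow(counts); m <- ncol(counts)
  # count -> 2-bit code: 2->0, 1->2, 0->3
  codeOf <- c(3L, 2L, 0L)
  codes <- matrix(codeOf[counts + 1L], n, m)
  bpv <- ceiling(n / 4)
  pad <- matrix(0L, 4 * bpv - n, m)
  codes <- rbind(codes, pad)
  b1 <- codes %% 2L
  b2 <- codes %/% 2L
  bits <- matrix(0L, 8, bpv * m)
  bits[seq(1, 8, by = 2), ] <- matrix(as.vector(b1), nrow = 4)
  bits[seq(2, 8, by = 2), ] <- matrix(as.vector(b2), nrow = 4)
  payload <- packBits(as.logical(bits), "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(payload, con)
  close(con)
  write.table(data.frame(1, geno@markerIds, 0, seq_len(m), "A", "B"),
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(1, geno@animalIds, 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Observed allele frequencies
#'
#' @param geno a [GenotypeMatrix-class].
#' @return numeric vector p, column sums over 2n.
#' @export
alleleFrequencies <- function(geno) {
  colSums(geno@counts) / (2 * nrow(geno@counts))
}

#' VanRaden scaling constant
#'
#' k = 2 * sum p_i (1 - p_i), the Method-1 normalizer that puts the
#' marker-based relationship matrix on the scale of A.
#'
#' @param p allele frequencies in (0, 1).
#' @return numeric(1).
#' @export
scalingConstant <- function(p) {
  stopifnot(all(p > 0), all(p < 1))
  2 * sum(p * (1 - p))
}

#' Centered genotype products Z v and Z' v
#'
#' Applies the centered marker matrix Z = M - 2 1 p' (or its transpose)
#' without materializing Z: `zTimes` maps a length-m vector to animals,
#' `ztTimes` a length-n vector to markers.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param p centering allele frequencies (fixed at evaluation build).
#' @param v numeric vector.
#' @return numeric vector.
#' @export
zTimes <- function(geno, p, v) {
  if (length(v) != ncol(geno@counts)) stop("v must have one entry per marker")
  as.numeric(geno@counts %*% v) - 2 * sum(p * v)
}

#' @rdname zTimes
#' @export
ztTimes <- function(geno, p, v) {
  if (length(v) != nrow(geno@counts)) stop("v must have one entry per animal")
  as.numeric(crossprod(geno@counts, v)) - 2 * p * sum(v)
}

# C^{-1} v for the two regularization kinds
cinvTimes <- function(factor, v) {
  if (factor@regKind == "epsilon_identity") {
    v / factor@epsilon
  } else {
    backsolve(factor@aggChol,
              backsolve(factor@aggChol, v, transpose = TRUE)) / factor@w
  }
}

#' Build the genomic factor
#'
#' Assembles K = Z'C^{-1}Z + B^{-1} for the chosen regularization,
#' factors it (lower Cholesky L), and optionally precomputes
#' T = L^{-1} Z' C^{-1} for the original product strategy. For
#' C = w A_gg, B = (1-w)/k I and solves against A_gg go through a cached
#' dense Cholesky factor; for C = eps I, B = 1/k I.
#'
#' @param geno [GenotypeMatrix-class] of the genotyped set, in the order
#'   matching `agg` when supplied.
#' @param regKind `"w_agg"` or `"epsilon_identity"`.
#' @param w residual polygenic proportion in (0, 1) (w_agg).
#' @param epsilon ridge constant > 0 (epsilon_identity).
#' @param agg dense A_gg relationship matrix among the genotyped animals
#'   (required for w_agg; see [aSubmatrix()]).
#' @param p centering allele frequencies; default observed frequencies of
#'   `geno`.
#' @param withT also compute and store T (default `FALSE`).
#' @return a [GenomicFactor-class].
#' @export
buildGenomicFactor <- function(geno, regKind = c("w_agg", "epsilon_identity"),
                               w = 0.20, epsilon = 0.01, agg = NULL,
                               p = alleleFrequencies(geno), withT = FALSE) {
  regKind <- match.arg(regKind)
  n <- nrow(geno@counts); m <- ncol(geno@counts)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic markers present; drop them before building the factor")
  k <- scalingConstant(p)
  Z <- sweep(geno@counts, 2, 2 * p)
  if (regKind == "w_agg") {
    if (is.null(agg)) stop("agg (dense A_gg) is required for regKind 'w_agg'")
    stopifnot(nrow(agg) == n)
    aggChol <- chol(agg)
    aggInv <- chol2inv(aggChol)
    CiZ <- backsolve(aggChol, backsolve(aggChol, Z, transpose = TRUE)) / w
    bDiag <- rep((1 - w) / k, m)
    aggDiagInv <- diag(aggInv)
  } else {
    aggChol <- matrix(numeric(0), 0, 0)
    aggDiagInv <- numeric(0)
    CiZ <- Z / epsilon
    bDiag <- rep(1 / k, m)
    w <- 0
  }
  K <- crossprod(Z, CiZ)
  diag(K) <- diag(K) + 1 / bDiag
  K <- (K + t(K)) / 2
  L <- tryCatch(t(chol(K)), error = function(e)
    stop("K is not positive definite; increase epsilon or check for ",
         "duplicated genotypes (", conditionMessage(e), ")"))
  Tmat <- if (withT) forwardsolve(L, t(CiZ)) else matrix(numeric(0), 0, 0)
  new("GenomicFactor", geno = geno, p = p, k = k, w = w, bDiag = bDiag,
      regKind = regKind, epsilon = if (regKind == "w_agg") 0 else epsilon,
      aggChol = aggChol, aggDiagInv = aggDiagInv, K = K, L = L, Tmat = Tmat)
}

kinvTimes <- function(factor, v) {
  # K^{-1} v = L'^{-1} (L^{-1} v): forward solve with L, back solve with L'
  backsolve(t(factor@L), forwardsolve(factor@L, v))
}

#' Inverse regularized genomic relationship times a vector
#'
#' Applies G_C^{-1} = (ZBZ' + C)^{-1} via the Woodbury identity
#' G_C^{-1} = C^{-1} - C^{-1} Z K^{-1} Z' C^{-1}. The `component_wise`
#' strategy nests the products with two triangular solves against L; the
#' `original_T` strategy uses the precomputed T as (C^{-1} - T'T) v.
#'
#' @param factor a [GenomicFactor-class].
#' @param v numeric vector over genotyped animals.
#' @param strategy `"component_wise"` (default) or `"original_T"`.
#' @return numeric vector G_C^{-1} v.
#' @export
gcinvTimes <- function(factor, v, strategy = c("component_wise", "original_T")) {
  strategy <- match.arg(strategy)
  if (length(v) != nrow(factor@geno@counts))
    stop("v must have one entry per genotyped animal")
  civ <- cinvTimes(factor, v)
  if (strategy == "original_T") {
    if (!nrow(factor@Tmat))
      stop("factor was built without T; rebuild with withT = TRUE")
    civ - as.numeric(crossprod(factor@Tmat, factor@Tmat %*% v))
  } else {
    s <- ztTimes(factor@geno, factor@p, civ)
    civ - cinvTimes(factor, zTimes(factor@geno, factor@p, kinvTimes(factor, s)))
  }
}

#' Dense regularized genomic relationship matrix (oracle helper)
#'
#' Materializes G_C = ZBZ' + C. Intended for validation at small n; the
#' solver path never forms it.
#'
#' @param factor a [GenomicFactor-class].
#' @param agg dense A_gg (required when regularization is w_agg).
#' @return dense n x n matrix.
#' @export
denseGC <- function(factor, agg = NULL) {
  n <- nrow(factor@geno@counts)
  if (n > 2000) stop("refusing to materialize G_C for n > 2000")
  Z <- sweep(factor@geno@counts, 2, 2 * factor@p)
  G <- Z %*% (factor@bDiag * t(Z))
  if (factor@regKind == "w_agg") {
    if (is.null(agg)) agg <- crossprod(factor@aggChol)
    G + factor@w * agg
  } else {
    G + diag(factor@epsilon, n)
  }
}

# exact diagonal of (G_C^{-1} - A_gg^{-1}); used by the preconditioner
gcinvCorrectionDiag <- function(factor) {
  n <- nrow(factor@geno@counts)
  Z <- sweep(factor@geno@counts, 2, 2 * factor@p)
  CiZ <- cinvTimes(factor, Z)
  Wm <- forwardsolve(factor@L, t(CiZ))   # m x n
  lowRank <- colSums(Wm^2)
  ciDiag <- if (factor@regKind == "epsilon_identity")
    rep(1 / factor@epsilon, n)
  else factor@aggDiagInv / factor@w
  aggInvDiag <- if (factor@regKind == "epsilon_identity")
    rep(0, n) else factor@aggDiagInv
  # for eps*I there is no A_gg^{-1} to subtract unless the system does;
  # the caller passes the A_gg^{-1} diagonal separately in that case
  list(gcinvDiag = ciDiag - lowRank, aggInvDiag = aggInvDiag)
}
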