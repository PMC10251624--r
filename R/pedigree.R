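# Pedigree relationship algebra. All of it works on the triangular
# factorization A = T D T', where T is the (I - 0.5 * parent-incidence)
# inverse and D holds the Mendelian-sampling variances
# d_i = 0.5 - 0.25 (F_s + F_d), with an unknown parent entering as a
# base animal (F = -1 convention folded into the per-parent terms).

newPedigree <- function(id, sire, dam, generation = NULL, inbreeding = NULL) {
  n <- length(id)
  if (is.null(generation)) generation <- rep(NA_integer_, n)
  if (is.null(inbreeding)) {
    obj <- new("Pedigree", id = as.character(id), sire = as.integer(sire),
               dam = as.integer(dam), inbreeding = numeric(n),
               generation = as.integer(generation))
    obj@inbreeding <- computeInbreeding(obj)
    validObject(obj)
    obj
  } else {
    new("Pedigree", id = as.character(id), sire = as.integer(sire),
        dam = as.integer(dam), inbreeding = as.numeric(inbreeding),
        generation = as.integer(generation))
  }
}

#' Read a pedigree from CSV
#'
#' Expects columns `animal`, `sire`, `dam` (other names via `idColumns`);
#' unknown parents are coded `0`, `NA` or the empty string. Rows are
#' topologically sorted so parents precede offspring; a cycle (an animal
#' among its own ancestors) is an error naming an offending animal.
#'
#' @param path CSV file path.
#' @param idColumns length-3 character: animal, sire, dam column names.
#' @param addMissingParents if `TRUE` (default) a parent id that has no
#'   own row is added as a founder; if `FALSE` this is an error.
#' @return a [Pedigree-class] with inbreeding computed.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(animal = c("a", "b", "c"), sire = c(0, 0, "a"),
#'                      dam = c(0, 0, "b")), f, row.names = FALSE)
#' readPedigree(f)
#' @export
readPedigree <- function(path, idColumns = c("animal", "sire", "dam"),
                         addMissingParents = TRUE) {
  df <- read.csv(path, colClasses = "character")
  if (!all(idColumns %in% names(df)))
    stop("pedigree file must have columns: ", paste(idColumns, collapse = ", "))
  gen <- if ("generation" %in% names(df)) suppressWarnings(as.integer(df$generation)) else NULL
  makePedigree(df[[idColumns[1]]], df[[idColumns[2]]], df[[idColumns[3]]],
               generation = gen, addMissingParents = addMissingParents)
}

#' Build a Pedigree from animal/sire/dam label vectors
#'
#' @param animal,sire,dam character vectors; `0`, `NA` or `""` = unknown
#'   parent.
#' @param generation optional integer vector parallel to `animal`.
#' @inheritParams readPedigree
#' @return a [Pedigree-class].
#' @export
makePedigree <- function(animal, sire, dam, generation = NULL,
                         addMissingParents = TRUE) {
  animal <- as.character(animal)
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  sire <- norm(sire); dam <- norm(dam)
  if (anyDuplicated(animal))
    stop("duplicated animal id: ", animal[duplicated(animal)][1])
  missing <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(missing)) {
    if (!addMissingParents)
      stop("parent id not in file: ", missing[1])
    animal <- c(missing, animal)
    sire <- c(rep(NA_character_, length(missing)), sire)
    dam <- c(rep(NA_character_, length(missing)), dam)
    if (!is.null(generation))
      generation <- c(rep(NA_integer_, length(missing)), generation)
  }
  n <- length(animal)
  idx <- seq_len(n); names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  ord <- topoOrder(si, di, animal)
  rank <- integer(n); rank[ord] <- seq_len(n)
  remap <- function(p) c(0L, rank)[p + 1L]
  newPedigree(animal[ord], remap(si)[ord], remap(di)[ord],
              generation = if (is.null(generation)) NULL else generation[ord])
}

# Kahn topological sort over the parent -> offspring DAG.
topoOrder <- function(sire, dam, labels) {
  n <- length(sire)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(sire[i], dam[i]))) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    # take the earliest-listed available animal so an already-sorted
    # file keeps its order exactly
    k <- which.min(queue)
    v <- queue[k]; queue <- queue[-k]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- setdiff(seq_len(n), ord)
    stop("pedigree cycle detected involving animal: ", labels[bad[1]])
  }
  ord
}

#' Pedigree inbreeding coefficients
#'
#' Meuwissen-Luo recursion over each animal's ancestor list: cost scales
#' with pedigree depth, not quadratically with pedigree size. Returns
#' F_i = A_ii - 1.
#'
#' @param ped a [Pedigree-class].
#' @return numeric vector of inbreeding coefficients.
#' @export
computeInbreeding <- function(ped) {
  n <- length(ped@id)
  s <- ped@sire; d <- ped@dam
  FF <- numeric(n)
  # Mendelian sampling variance term per animal, filled as we go
  dvec <- numeric(n)
  fOf <- function(p) if (p == 0L) -1 else FF[p]
  for (i in seq_len(n)) {
    dvec[i] <- 0.5 - 0.25 * (fOf(s[i]) + fOf(d[i]))
    if (s[i] == 0L || d[i] == 0L) { FF[i] <- 0; next }
    # A_ii = sum_j L_ij^2 d_j over the animal and its ancestors, with L
    # the pedigree's triangular factor (Meuwissen & Luo working vector);
    # F_i = A_ii - 1.
    AN <- numeric(i)        # coefficient per ancestor
    AN[i] <- 1
    f <- 0
    for (j in seq(i, 1L)) {
      if (AN[j] == 0) next
      f <- f + AN[j]^2 * dvec[j]
      if (s[j] > 0L) AN[s[j]] <- AN[s[j]] + 0.5 * AN[j]
      if (d[j] > 0L) AN[d[j]] <- AN[d[j]] + 0.5 * AN[j]
    }
    FF[i] <- f - 1
  }
  FF
}

mendelianD <- function(ped) {
  fOf <- function(p) if (p == 0L) -1 else ped@inbreeding[p]
  vapply(seq_along(ped@id), function(i)
    0.5 - 0.25 * (fOf(ped@sire[i]) + fOf(ped@dam[i])), numeric(1))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' b_i = 1/d_i at (i,i), -b_i/2 to the animal-parent cells and b_i/4
#' among its known parents, where d_i = 0.5 - 0.25(F_s + F_d) and an
#' unknown parent enters as an unrelated, non-inbred base animal.
#'
#' @param ped a [Pedigree-class].
#' @return a symmetric [Matrix::sparseMatrix()] (class `dsCMatrix`).
#' @export
buildAInverse <- function(ped) {
  n <- length(ped@id)
  b <- 1 / mendelianD(ped)
  s <- ped@sire; d <- ped@dam
  tri_i <- seq_len(n); tri_j <- seq_len(n); tri_x <- b
  par <- rbind(
    data.frame(i = tri_i[s > 0L], j = s[s > 0L], x = -0.5 * b[s > 0L]),
    data.frame(i = tri_i[d > 0L], j = d[d > 0L], x = -0.5 * b[d > 0L])
  )
  both <- which(s > 0L & d > 0L)
  pp <- rbind(
    data.frame(i = s, j = s, x = 0.25 * b)[s > 0L, ],
    data.frame(i = d, j = d, x = 0.25 * b)[d > 0L, ],
    data.frame(i = pmax(s, d)[both], j = pmin(s, d)[both], x = 0.25 * b[both])
  )
  lower <- rbind(data.frame(i = tri_i, j = tri_j, x = tri_x),
                 data.frame(i = par$i, j = par$j, x = par$x),
                 pp)
  Matrix::sparseMatrix(i = lower$i, j = lower$j, x = lower$x,
                       dims = c(n, n), symmetric = TRUE)
}

#' A times a vector without forming A
#'
#' Colleau's indirect algorithm: with A = T D T', computes u = T'v
#' (youngest to oldest), scales by the Mendelian-sampling variances D,
#' then solves the offspring recursion t_i = w_i + (t_s + t_d)/2 oldest
#' to youngest. O(N) per product.
#'
#' @param ped a [Pedigree-class].
#' @param v numeric vector over all animals, pedigree order.
#' @return numeric vector A v.
#' @export
aTimesVector <- function(ped, v) {
  n <- length(ped@id)
  if (length(v) != n) stop("v must have one entry per pedigree animal")
  s <- ped@sire; d <- ped@dam
  u <- as.numeric(v)
  if (n > 1) for (i in seq(n, 2L)) {
    if (s[i] > 0L) u[s[i]] <- u[s[i]] + 0.5 * u[i]
    if (d[i] > 0L) u[d[i]] <- u[d[i]] + 0.5 * u[i]
  }
  w <- u * mendelianD(ped)
  t <- w
  for (i in seq_len(n)) {
    acc <- 0
    if (s[i] > 0L) acc <- acc + 0.5 * t[s[i]]
    if (d[i] > 0L) acc <- acc + 0.5 * t[d[i]]
    t[i] <- w[i] + acc
  }
  t
}

# Colleau product applied to the columns of a matrix simultaneously;
# the pedigree sweep is shared, each row update is vectorized.
aTimesMatrix <- function(ped, V) {
  n <- length(ped@id)
  stopifnot(nrow(V) == n)
  s <- ped@sire; d <- ped@dam
  dvec <- mendelianD(ped)
  U <- V
  if (n > 1) for (i in seq(n, 2L)) {
    if (s[i] > 0L) U[s[i], ] <- U[s[i], ] + 0.5 * U[i, ]
    if (d[i] > 0L) U[d[i], ] <- U[d[i], ] + 0.5 * U[i, ]
  }
  W <- U * dvec
  for (i in seq_len(n)) {
    if (s[i] > 0L) W[i, ] <- W[i, ] + 0.5 * W[s[i], ]
    if (d[i] > 0L) W[i, ] <- W[i, ] + 0.5 * W[d[i], ]
  }
  W
}

#' Dense relationship submatrix among a subset of animals
#'
#' Computes A restricted to `subset` with one Colleau product per subset
#' member (run as a single multi-column sweep), suitable for desk-scale
#' subsets such as the genotyped animals.
#'
#' @param ped a [Pedigree-class].
#' @param subset integer indices into the pedigree.
#' @return dense symmetric matrix `length(subset)` square.
#' @export
aSubmatrix <- function(ped, subset) {
  n <- length(ped@id)
  subset <- as.integer(subset)
  if (any(subset < 1L | subset > n)) stop("subset index out of range")
  ns <- length(subset)
  E <- matrix(0, n, ns)
  E[cbind(subset, seq_len(ns))] <- 1
  out <- aTimesMatrix(ped, E)[subset, , drop = FALSE]
  out <- (out + t(out)) / 2
  dimnames(out) <- list(ped@id[subset], ped@id[subset])
  out
}

#' Prune a pedigree to a kept set and its ancestors
#'
#' @param ped a [Pedigree-class].
#' @param keep integer indices of animals to keep.
#' @return list with `ped` (re-indexed [Pedigree-class]) and `map`
#'   (integer: new index -> original index).
#' @export
pruneToAncestors <- function(ped, keep) {
  n <- length(ped@id)
  keepL <- logical(n)
  keepL[as.integer(keep)] <- TRUE
  for (i in seq(n, 1L)) {
    if (keepL[i]) {
      if (ped@sire[i] > 0L) keepL[ped@sire[i]] <- TRUE
      if (ped@dam[i] > 0L) keepL[ped@dam[i]] <- TRUE
    }
  }
  map <- which(keepL)
  rank <- integer(n); rank[map] <- seq_along(map)
  remap <- function(p) c(0L, rank)[p + 1L]
  sub <- newPedigree(ped@id[map], remap(ped@sire[map]), remap(ped@dam[map]),
                     generation = ped@generation[map],
                     inbreeding = ped@inbreeding[map])
  list(ped = sub, map = map)
}
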