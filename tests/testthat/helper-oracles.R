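# Independent oracles and fixture builders. The tabular relationship
# matrix below is the classical recursive definition, kept deliberately
# separate from the package's Henderson/Colleau code paths.

tabularAOracle <- function(ped) {
  n <- length(animalIds(ped))
  s <- sireOf(ped); d <- damOf(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (s[i] > 0 && d[i] > 0) 0.5 * A[s[i], d[i]] else 0
    if (i > 1) for (j in seq_len(i - 1)) {
      aij <- 0
      if (s[i] > 0) aij <- aij + 0.5 * A[j, s[i]]
      if (d[i] > 0) aij <- aij + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

randomPedigree <- function(n, nFounders = max(3L, n %/% 5L)) {
  s <- d <- integer(n)
  for (i in (nFounders + 1):n) {
    pr <- sample(seq_len(i - 1L), 2L)
    s[i] <- pr[1]; d[i] <- pr[2]
  }
  makePedigree(as.character(seq_len(n)), as.character(s), as.character(d))
}

# random polymorphic genotype matrix
randomGeno <- function(n, m, ids = paste0("a", seq_len(n))) {
  repeat {
    counts <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    p <- colSums(counts) / (2 * n)
    if (all(p > 0 & p < 1)) break
  }
  new("GenotypeMatrix", counts = counts, animalIds = ids,
      markerIds = paste0("m", seq_len(m)))
}

# a small but complete single-step fixture: pedigree, genotyped subset,
# phenotypes; suitable for dense-oracle comparisons
smallSingleStepFixture <- function(n = 40, nGeno = 15, m = 8,
                                   nFounders = 6) {
  ped <- randomPedigree(n, nFounders)
  gidx <- sort(sample((nFounders + 1):n, nGeno))
  geno <- randomGeno(nGeno, m, ids = animalIds(ped)[gidx])
  recIdx <- setdiff(seq(nFounders + 1, n), integer(0))
  phen <- data.frame(animal = animalIds(ped)[recIdx],
                     trait = rnorm(length(recIdx), mean = 1))
  list(ped = ped, geno = geno, gidx = gidx, phen = phen)
}

# the standard simulated study solved once and cached for the session
.studyCache <- new.env(parent = emptyenv())
standardStudyResults <- function() {
  if (is.null(.studyCache$res)) {
    res <- runStudy(seed = 1, formulation = "ssgtblup", verbose = FALSE)
    model3 <- ssModel(h2 = res$study$config$h2, w = res$study$config$w,
                      formulation = "sssnpblup")
    fitSnp <- singleStepSolve(res$study$ped, res$study$genoFull,
                              res$study$phenotypes, model3)
    res$fitSnp <- fitSnp
    .studyCache$res <- res
  }
  .studyCache$res
}
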