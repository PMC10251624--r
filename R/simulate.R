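# Gene-dropping breeding-population simulator: discrete generations,
# unlinked biallelic markers, marker-based breeding values plus a
# pedigree-correlated residual polygenic component, phenotypes at a
# stated heritability, partial genotyping of parent generations, and a
# final cohort of genotyped selection candidates without records or
# progeny. Produces the full and reduced genotype sets of the
# two-evaluation study design.

#' Simulation configuration
#'
#' Defaults realise the standard study: ~3,100 animals over 6 discrete
#' generations, 1,000 unlinked markers, narrow-sense heritability 0.3,
#' residual polygenic proportion 0.20, 70% of the three pre-candidate
#' generations genotyped, and a final candidate cohort (all genotyped,
#' no records, no progeny) that makes up roughly a fifth of the genotype
#' set, so the reduced evaluation keeps about four fifths of the
#' genotypes, mirroring routine full/reduced evaluation proportions.
#'
#' @param nFounders founder count (generation 1).
#' @param nGenerations total generations including founders.
#' @param offspringPerMating full-sib family size; each generation pairs
#'   the previous one into floor(size/2) matings.
#' @param candidatesPerMating family size of the final (candidate)
#'   generation; the default 1 keeps the candidate cohort a minority of
#'   the genotyped set, as in routine evaluations where newly genotyped
#'   selection candidates are a fraction of the reference.
#' @param genotypedGenerations how many generations immediately before
#'   the candidates are eligible for parent genotyping.
#' @param mMarkers number of unlinked biallelic markers.
#' @param founderFreqRange founder allele-frequency range (uniform draw).
#' @param h2 narrow-sense heritability of the single trait.
#' @param w residual polygenic proportion of additive variance.
#' @param genotypingRateParents probability that a non-candidate animal
#'   in the two generations before the candidates is genotyped.
#' @param jfactorShift additive true-value shift, in genetic-SD units,
#'   applied to descendants of a designated founder half to create a
#'   pedigree-vs-genomic base difference for the J-factor to absorb.
#' @param sigmaU2 additive genetic variance (1 keeps level bias readable
#'   in genetic-SD units).
#' @param mu0 phenotype intercept.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(nFounders = 560L, nGenerations = 6L,
                      offspringPerMating = 2L, candidatesPerMating = 1L,
                      genotypedGenerations = 3L, mMarkers = 1000L,
                      founderFreqRange = c(0.05, 0.95), h2 = 0.3, w = 0.20,
                      genotypingRateParents = 0.7, jfactorShift = 0.3,
                      sigmaU2 = 1, mu0 = 1) {
  stopifnot(h2 > 0, h2 < 1, w > 0, w < 1,
            genotypingRateParents >= 0, genotypingRateParents <= 1,
            founderFreqRange[1] > 0, founderFreqRange[2] < 1)
  structure(as.list(environment()), class = "simConfig")
}

#' Simulate a discrete-generation pedigree
#'
#' Random pairing within the previous generation, `offspringPerMating`
#' full sibs per mating. Deterministic for a given RNG state.
#'
#' @param config a [simConfig()].
#' @return a [Pedigree-class] with the `generation` slot filled.
#' @export
simulatePedigree <- function(config) {
  id <- paste0("G1_", seq_len(config$nFounders))
  sire <- rep(0L, config$nFounders)
  dam <- rep(0L, config$nFounders)
  gen <- rep(1L, config$nFounders)
  prevIdx <- seq_len(config$nFounders)
  total <- config$nFounders
  if (config$nGenerations > 1) for (g in 2:config$nGenerations) {
    perm <- sample(prevIdx)
    nMat <- length(perm) %/% 2
    if (nMat == 0) stop("previous generation too small to mate")
    sires <- perm[seq_len(nMat)]
    dams <- perm[nMat + seq_len(nMat)]
    fam <- if (g == config$nGenerations) config$candidatesPerMating
           else config$offspringPerMating
    newIdx <- integer(0)
    for (j in seq_len(nMat)) {
      for (k in seq_len(fam)) {
        total <- total + 1L
        id <- c(id, paste0("G", g, "_", length(newIdx) + 1L))
        newIdx <- c(newIdx, total)
        sire <- c(sire, sires[j])
        dam <- c(dam, dams[j])
        gen <- c(gen, g)
      }
    }
    prevIdx <- newIdx
  }
  newPedigree(id, sire, dam, generation = gen)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotype alleles are Bernoulli(p_i) with p_i drawn uniformly
#' from the configured range; each descendant inherits one uniformly
#' chosen allele per parent per marker (no linkage). An unknown parent
#' contributes a fresh base-population haplotype.
#'
#' @param ped a [Pedigree-class].
#' @param config a [simConfig()].
#' @return list with integer `counts` (all animals x markers) and the
#'   drawn founder frequencies `p`.
#' @export
simulateGenotypes <- function(ped, config) {
  n <- length(ped@id); m <- config$mMarkers
  p <- runif(m, config$founderFreqRange[1], config$founderFreqRange[2])
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  baseHap <- function() rbinom(m, 1L, p)
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    h1[i, ] <- if (s > 0L) {
      pick <- runif(m) < 0.5
      ifelse(pick, h1[s, ], h2[s, ])
    } else baseHap()
    h2[i, ] <- if (d > 0L) {
      pick <- runif(m) < 0.5
      ifelse(pick, h1[d, ], h2[d, ])
    } else baseHap()
  }
  list(counts = h1 + h2, p = p)
}

#' Simulate true breeding values
#'
#' u = Z a + d: i.i.d. marker effects a ~ N(0, (1-w) sigmaU2 / k) with k
#' the VanRaden constant at the drawn founder frequencies, plus a
#' gene-dropped infinitesimal residual polygenic component d (founders
#' N(0, w sigmaU2); offspring parent average plus Mendelian sampling with
#' inbreeding-adjusted variance). Z is centered at the founder
#' frequencies. The configured `jfactorShift` (in genetic-SD units) is
#' then added to every descendant of a designated founder half, creating
#' the pedigree-vs-genomic base difference the J-factor absorbs.
#'
#' @param ped a [Pedigree-class].
#' @param genoTrue output of [simulateGenotypes()].
#' @param config a [simConfig()].
#' @return list with `u` (true total), `a` (marker effects), `d` (RPG
#'   deviations), `shifted` (logical per animal).
#' @export
simulateTrueValues <- function(ped, genoTrue, config) {
  n <- length(ped@id)
  p <- genoTrue$p
  k <- scalingConstant(p)
  a <- rnorm(config$mMarkers, 0, sqrt((1 - config$w) * config$sigmaU2 / k))
  za <- as.numeric(genoTrue$counts %*% a) - 2 * sum(p * a)
  d <- numeric(n)
  fOf <- function(pp) if (pp == 0L) 0 else ped@inbreeding[pp]
  for (i in seq_len(n)) {
    s <- ped@sire[i]; dd <- ped@dam[i]
    if (s == 0L && dd == 0L) {
      d[i] <- rnorm(1, 0, sqrt(config$w * config$sigmaU2))
    } else {
      pa <- 0.5 * (if (s > 0L) d[s] else 0) + 0.5 * (if (dd > 0L) d[dd] else 0)
      # Mendelian sampling variance; an unknown parent contributes as a
      # base animal (its F enters as 0 with full base variance share)
      msVar <- config$w * config$sigmaU2 *
        (if (s > 0L && dd > 0L) 0.5 * (1 - (fOf(s) + fOf(dd)) / 2)
         else 0.75 - 0.25 * (if (s > 0L) fOf(s) else fOf(dd)))
      d[i] <- pa + rnorm(1, 0, sqrt(msVar))
    }
  }
  designated <- logical(n)
  founders <- which(ped@sire == 0L & ped@dam == 0L)
  designated[founders[seq_len(ceiling(length(founders) / 2))]] <- TRUE
  shifted <- designated
  for (i in seq_len(n)) {
    s <- ped@sire[i]; dd <- ped@dam[i]
    if ((s > 0L && shifted[s]) || (dd > 0L && shifted[dd])) shifted[i] <- TRUE
  }
  u <- za + d + config$jfactorShift * sqrt(config$sigmaU2) *
    as.numeric(shifted & !designated)
  list(u = u, a = a, d = d, za = za, shifted = shifted)
}

#' Simulate phenotypes
#'
#' One record y = mu0 + u + e per non-candidate animal in generations 2
#' and later, e ~ N(0, sigmaE2) with sigmaE2 = sigmaU2 (1 - h2)/h2.
#' Candidates (final generation) get no records.
#'
#' @param ped a [Pedigree-class].
#' @param u true breeding values.
#' @param config a [simConfig()].
#' @return data frame `animal`, `trait`.
#' @export
simulatePhenotypes <- function(ped, u, config) {
  sigmaE2 <- config$sigmaU2 * (1 - config$h2) / config$h2
  recorded <- which(ped@generation >= 2L &
                    ped@generation < config$nGenerations)
  data.frame(animal = ped@id[recorded],
             trait = config$mu0 + u[recorded] +
               rnorm(length(recorded), 0, sqrt(sigmaE2)))
}

#' Simulate a complete study
#'
#' Runs pedigree, genotypes, true values and phenotypes under one seed,
#' labels the final generation as selection candidates, draws the
#' genotyped set (all candidates; non-candidates of the two preceding
#' generations with probability `genotypingRateParents`), and defines
#' the full and reduced genotype sets of the study design: the reduced
#' set is the full set minus the candidates.
#'
#' @param config a [simConfig()].
#' @param seed integer RNG seed; the whole study is reproducible from it.
#' @return a list of class `simStudy`: `ped`, `config`, `seed`, `truth`
#'   (u, a, d, p), `phenotypes`, `candIdx`, `gidxFull`, `gidxReduced`,
#'   `genoFull`, `genoReduced`, `genoCandidates`.
#' @export
simulateStudy <- function(config = simConfig(), seed = 1L) {
  set.seed(seed)
  ped <- simulatePedigree(config)
  genoTrue <- simulateGenotypes(ped, config)
  truth <- simulateTrueValues(ped, genoTrue, config)
  phenotypes <- simulatePhenotypes(ped, truth$u, config)
  candIdx <- which(ped@generation == config$nGenerations)
  eligible <- which(ped@generation >= config$nGenerations -
                      config$genotypedGenerations &
                    ped@generation < config$nGenerations)
  genotypedParents <- eligible[runif(length(eligible)) <
                                 config$genotypingRateParents]
  gidxFull <- sort(c(genotypedParents, candIdx))
  gidxReduced <- sort(genotypedParents)
  markerIds <- sprintf("snp%04d", seq_len(config$mMarkers))
  subGeno <- function(idx) {
    new("GenotypeMatrix",
        counts = genoTrue$counts[idx, , drop = FALSE],
        animalIds = ped@id[idx], markerIds = markerIds)
  }
  structure(list(
    ped = ped, config = config, seed = seed,
    truth = list(u = truth$u, a = truth$a, d = truth$d, za = truth$za,
                 p = genoTrue$p, shifted = truth$shifted),
    phenotypes = phenotypes,
    candIdx = candIdx, gidxFull = gidxFull, gidxReduced = gidxReduced,
    genoFull = subGeno(gidxFull), genoReduced = subGeno(gidxReduced),
    genoCandidates = subGeno(candIdx)),
    class = "simStudy")
}

#' Write a simulated study to plain-text and PLINK fixtures
#'
#' Writes pedigree CSV, phenotype CSV, truth TSV, full/reduced/candidate
#' PLINK trios and a JSON-like manifest of the configuration and seed.
#'
#' @param study a `simStudy` from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- study$ped
  pedDf <- data.frame(
    animal = ped@id,
    sire = ifelse(ped@sire == 0L, "0", ped@id[pmax(ped@sire, 1L)]),
    dam = ifelse(ped@dam == 0L, "0", ped@id[pmax(ped@dam, 1L)]),
    generation = ped@generation)
  write.csv(pedDf, file.path(dir, "pedigree.csv"), row.names = FALSE)
  write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  write.table(data.frame(animal = ped@id, true_u = study$truth$u,
                         true_d = study$truth$d),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writePlink(study$genoFull, file.path(dir, "geno_full"))
  writePlink(study$genoReduced, file.path(dir, "geno_reduced"))
  writePlink(study$genoCandidates, file.path(dir, "geno_candidates"))
  cfg <- study$config
  manifest <- paste0(
    "{", paste(sprintf('"%s": %s', c(names(cfg), "seed"),
                       c(vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)), study$seed)),
               collapse = ", "), "}")
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
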