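test_that("simulation is deterministic and structurally correct", {
  cfg <- simConfig(nFounders = 20L, nGenerations = 5L,
                   offspringPerMating = 2L, candidatesPerMating = 2L,
                   mMarkers = 30L)
  s1 <- simulateStudy(cfg, seed = 99)
  s2 <- simulateStudy(cfg, seed = 99)
  expect_identical(animalIds(s1$ped), animalIds(s2$ped))
  expect_identical(s1$genoFull@counts, s2$genoFull@counts)
  expect_identical(s1$phenotypes, s2$phenotypes)

  # closed-form animal count: each generation pairs the previous one
  sizes <- 20
  for (g in 2:5) sizes <- c(sizes, (tail(sizes, 1) %/% 2) * 2)
  expect_identical(length(s1$ped), as.integer(sum(sizes)))

  # founders only
  set.seed(1)
  pedF <- simulatePedigree(simConfig(nFounders = 7L, nGenerations = 1L))
  expect_identical(length(pedF), 7L)
  expect_true(all(sireOf(pedF) == 0L))
})

test_that("gene dropping respects Mendelian transmission", {
  set.seed(61)
  cfg <- simConfig(nFounders = 30L, nGenerations = 4L, mMarkers = 40L)
  ped <- simulatePedigree(cfg)
  gt <- simulateGenotypes(ped, cfg)
  expect_true(all(gt$counts %in% 0:2))
  both <- which(sireOf(ped) > 0 & damOf(ped) > 0)
  for (i in sample(both, 10)) {
    s <- gt$counts[sireOf(ped)[i], ]; d <- gt$counts[damOf(ped)[i], ]
    kid <- gt$counts[i, ]
    # each parent passes at least one allele it owns
    expect_true(all(kid <= (s > 0) + (d > 0)  + 0))
    expect_true(all(kid >= (s == 2) + (d == 2)))
  }
})

test_that("founder allele frequencies match the drawn probabilities", {
  set.seed(62)
  cfg <- simConfig(nFounders = 2000L, nGenerations = 1L, mMarkers = 25L)
  ped <- simulatePedigree(cfg)
  gt <- simulateGenotypes(ped, cfg)
  obs <- colMeans(gt$counts) / 2
  se <- sqrt(gt$p * (1 - gt$p) / (2 * 2000))
  expect_true(all(abs(obs - gt$p) < 3.9 * se))
})

test_that("true values realize the configured variance split", {
  set.seed(63)
  # near-total RPG: marker share of variance vanishes
  cfgW <- simConfig(nFounders = 400L, nGenerations = 3L, mMarkers = 50L,
                    w = 0.999)
  pedW <- simulatePedigree(cfgW)
  gtW <- simulateGenotypes(pedW, cfgW)
  tvW <- simulateTrueValues(pedW, gtW, cfgW)
  expect_lt(var(tvW$za) / var(tvW$u - mean(tvW$u)), 0.01)

  # default split: marker share near 1 - w
  cfg <- simConfig(nFounders = 500L, nGenerations = 3L, mMarkers = 200L,
                   jfactorShift = 0)
  ped <- simulatePedigree(cfg)
  gt <- simulateGenotypes(ped, cfg)
  tv <- simulateTrueValues(ped, gt, cfg)
  share <- var(tv$za) / (var(tv$za) + var(tv$d))
  expect_equal(share, 0.8, tolerance = 0.1)

  # RPG deviations of a repeated trio have covariance w sigmaU2 A
  cfgT <- simConfig(nFounders = 2L, nGenerations = 2L, mMarkers = 2L,
                    offspringPerMating = 1L, candidatesPerMating = 1L)
  set.seed(64)
  pedT <- simulatePedigree(cfgT)
  gtT <- simulateGenotypes(pedT, cfgT)
  reps <- replicate(4000, simulateTrueValues(pedT, gtT, cfgT)$d)
  covHat <- cov(t(reps))
  expect_equal(covHat, 0.2 * tabularAOracle(pedT), tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("phenotypes carry the configured heritability and exclusions", {
  set.seed(65)
  cfgH <- simConfig(nFounders = 300L, nGenerations = 4L, mMarkers = 50L,
                    h2 = 0.999)
  pedH <- simulatePedigree(cfgH)
  gtH <- simulateGenotypes(pedH, cfgH)
  tvH <- simulateTrueValues(pedH, gtH, cfgH)
  phenH <- simulatePhenotypes(pedH, tvH$u, cfgH)
  idx <- match(phenH$animal, animalIds(pedH))
  expect_gt(cor(phenH$trait, tvH$u[idx]), 0.99)

  # moment check on the realized heritability at the default h2
  cfg <- simConfig(nFounders = 1200L, nGenerations = 3L, mMarkers = 60L)
  ped <- simulatePedigree(cfg)
  gt <- simulateGenotypes(ped, cfg)
  tv <- simulateTrueValues(ped, gt, cfg)
  phen <- simulatePhenotypes(ped, tv$u, cfg)
  idx <- match(phen$animal, animalIds(ped))
  e <- phen$trait - cfg$mu0 - tv$u[idx]
  h2hat <- var(tv$u[idx]) / (var(tv$u[idx]) + var(e))
  expect_equal(h2hat, 0.3, tolerance = 0.1)

  # candidates have no records
  study <- simulateStudy(simConfig(nFounders = 60L, nGenerations = 4L,
                                   mMarkers = 30L), seed = 3)
  expect_false(any(study$phenotypes$animal %in%
                     animalIds(study$ped)[study$candIdx]))
})

test_that("the full and reduced genotype sets follow the study design", {
  study <- simulateStudy(simConfig(nFounders = 80L, nGenerations = 5L,
                                   mMarkers = 40L), seed = 4)
  expect_identical(nrow(study$genoFull) - nrow(study$genoReduced),
                   length(study$candIdx))
  expect_identical(setdiff(study$genoFull@animalIds,
                           study$genoReduced@animalIds),
                   study$genoCandidates@animalIds)
  # reduced-set animals all have their own records
  expect_true(all(study$genoReduced@animalIds %in% study$phenotypes$animal))
  # all three parent-status groups occur at the default genotyping rate
  st <- parentStatus(study$ped, study$candIdx, study$gidxReduced)
  expect_true(all(c("GG", "NG", "NN") %in% as.character(st)))
  # candidates have no progeny
  expect_false(any(sireOf(study$ped) %in% study$candIdx |
                     damOf(study$ped) %in% study$candIdx))
})

test_that("study fixtures round trip through the plain-text writers", {
  study <- simulateStudy(simConfig(nFounders = 30L, nGenerations = 3L,
                                   mMarkers = 12L), seed = 5)
  dir <- withr::local_tempdir()
  writeStudy(study, dir)
  ped2 <- readPedigree(file.path(dir, "pedigree.csv"))
  expect_identical(animalIds(ped2), animalIds(study$ped))
  geno2 <- readPlink(file.path(dir, "geno_full"), dropMonomorphic = FALSE)
  expect_identical(geno2@counts, study$genoFull@counts)
})

test_that("genomic information improves over pedigree BLUP", {
  res <- standardStudyResults()
  study <- res$study
  model0 <- ssModel(h2 = study$config$h2, jfactor = FALSE)
  sys0 <- assembleSystem(model0, study$ped, NULL, study$phenotypes)
  fit0 <- pcgSolve(sys0, tol = 1e-7)
  u0 <- fit0$solutions[sys0@map$animal]
  phenotyped <- intersect(study$gidxReduced,
                          match(study$phenotypes$animal,
                                animalIds(study$ped)))
  corPed <- cor(u0[phenotyped], study$truth$u[phenotyped])
  corSS <- cor(res$fitFull@uHat[phenotyped], study$truth$u[phenotyped])
  expect_gt(corSS, corPed)
})
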