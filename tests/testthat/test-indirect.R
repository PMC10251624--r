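test_that("SNP backsolving equals the dense B Z' G_C^{-1} route", {
  set.seed(51)
  for (rep in 1:3) {
    n <- 12; m <- 6
    ped <- randomPedigree(n + 8)
    gidx <- sort(sample(seq_len(n + 8), n))
    geno <- randomGeno(n, m, ids = animalIds(ped)[gidx])
    agg <- aSubmatrix(ped, gidx)
    f <- buildGenomicFactor(geno, "w_agg", w = 0.2, agg = agg)
    uG <- rnorm(n)
    gHat <- backsolveSnpEffects(f, uG)
    Z <- sweep(geno@counts, 2, 2 * f@p)
    dense <- f@bDiag * as.numeric(crossprod(Z, solve(denseGC(f, agg), uG)))
    expect_equal(gHat, dense, tolerance = 1e-8)
    expect_equal(backsolveSnpEffects(f, numeric(n)), numeric(m))

    # d-hat_g = u-hat_g - Z g-hat also equals w A_gg G_C^{-1} u-hat_g
    dG <- rpgGenotyped(f, uG)
    expect_equal(dG, as.numeric(0.2 * agg %*% solve(denseGC(f, agg), uG)),
                 tolerance = 1e-8)
    expect_equal(rpgGenotyped(f, numeric(n)), numeric(n))
  }
})

test_that("the RPG term degenerates to a base constant as w goes to zero", {
  # with observed-frequency centering Z'1 = 0, so the marker term can
  # never carry the common mean: as w -> 0 the RPG effects collapse to a
  # constant base shift while their animal-to-animal variation vanishes
  # (the markers need to span the genotyped set, m >= n)
  set.seed(52)
  n <- 10; m <- 30
  ped <- randomPedigree(n + 5)
  gidx <- sort(sample(seq_len(n + 5), n))
  geno <- randomGeno(n, m, ids = animalIds(ped)[gidx])
  agg <- aSubmatrix(ped, gidx)
  uG <- rnorm(n)
  one <- rep(1, n)
  # derived limit: d-hat -> A_gg 1 (1' u-hat) / (1' A_gg 1), linearly in w
  dLimit <- as.numeric(agg %*% one) * sum(uG) /
    as.numeric(t(one) %*% agg %*% one)
  for (w in c(1e-3, 1e-4)) {
    f <- buildGenomicFactor(geno, "w_agg", w = w, agg = agg)
    d <- rpgGenotyped(f, uG)
    expect_lt(sqrt(sum((d - dLimit)^2)) / sqrt(sum(dLimit^2)), 10 * w)
  }
})

test_that("candidate RPG routes agree with each other and the dense blocks", {
  set.seed(53)
  for (rep in 1:3) {
    ped <- randomPedigree(60, nFounders = 10)
    candIdx <- sort(sample(40:60, 8))
    gpool <- setdiff(15:60, candIdx)
    gidx <- sort(sample(gpool, 20))
    dG <- rnorm(20)
    A <- tabularAOracle(ped)
    dense <- as.numeric(A[candIdx, gidx] %*% solve(A[gidx, gidx], dG))
    exact <- rpgCandidates(ped, gidx, candIdx, dG, method = "exact")
    anc <- rpgCandidates(ped, gidx, candIdx, dG, method = "ancestor")
    expect_equal(as.numeric(exact), dense, tolerance = 1e-8)
    expect_equal(as.numeric(anc), as.numeric(exact), tolerance = 1e-8)
  }
  # a candidate with both parents genotyped gets the parent average
  ped <- makePedigree(c("s", "d", "c"), c("0", "0", "s"), c("0", "0", "d"))
  dG <- c(0.4, -0.2)
  out <- rpgCandidates(ped, 1:2, 3L, dG, method = "exact")
  expect_equal(as.numeric(out), mean(dG), tolerance = 1e-12)
  # a founder candidate unrelated to the genotyped set gets zero
  ped2 <- makePedigree(c("g1", "g2", "x"), c("0", "0", "0"),
                       c("0", "0", "0"))
  expect_equal(as.numeric(rpgCandidates(ped2, 1:2, 3L, c(1, 2),
                                        method = "exact")), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(rpgCandidates(ped2, 1:2, 3L, c(1, 2),
                                        method = "ancestor")), 0,
               tolerance = 1e-12)
  # overlap between candidates and genotyped set is rejected
  expect_error(rpgCandidates(ped, 1:2, 2L, dG, method = "exact"),
               "disjoint")
})

test_that("the regression route fits OLS and falls back when degenerate", {
  set.seed(54)
  ped <- randomPedigree(40, nFounders = 8)
  candIdx <- sort(sample(30:40, 5))
  gidx <- sort(sample(setdiff(10:40, candIdx), 12))
  uHat <- rnorm(40)
  dG <- 0.1 + 0.3 * uHat[gidx] + rnorm(12, 0, 0.05)
  out <- rpgCandidates(ped, gidx, candIdx, dG, method = "regression",
                       uHat = uHat)
  # closed-form least squares oracle
  x <- uHat[gidx]
  bOracle <- sum((x - mean(x)) * (dG - mean(dG))) / sum((x - mean(x))^2)
  aOracle <- mean(dG) - bOracle * mean(x)
  expect_equal(attr(out, "a"), aOracle, tolerance = 1e-10)
  expect_equal(attr(out, "b"), bOracle, tolerance = 1e-10)

  # perfect proportionality: d-tilde = c * u for non-genotyped parents
  dProp <- 0.25 * uHat[gidx]
  outP <- rpgCandidates(ped, gidx, candIdx, dProp, method = "regression",
                        uHat = uHat)
  expect_equal(attr(outP, "a"), 0, tolerance = 1e-10)
  expect_equal(attr(outP, "b"), 0.25, tolerance = 1e-10)

  # constant GEBV among genotyped animals: warned fallback
  uFlat <- uHat; uFlat[gidx] <- 1
  expect_warning(
    outF <- rpgCandidates(ped, gidx, candIdx, dG, method = "regression",
                          uHat = uFlat),
    "degenerate")
  expect_equal(attr(outF, "a"), mean(dG))
  expect_equal(attr(outF, "b"), 0)
})

test_that("parent status partitions candidates exhaustively", {
  ped <- makePedigree(c("g1", "g2", "n1", "cGG", "cNG", "cNN", "cOrph"),
                      c("0", "0", "0", "g1", "g2", "n1", "0"),
                      c("0", "0", "0", "g2", "0", "0", "0"))
  st <- parentStatus(ped, match(c("cGG", "cNG", "cNN", "cOrph"),
                                animalIds(ped)),
                     match(c("g1", "g2"), animalIds(ped)))
  expect_identical(as.character(st), c("GG", "NG", "NN", "NN"))
})

test_that("the four predictors decompose and specialize as required", {
  # a miniature study guarantees candidates in all parent-status groups
  study <- simulateStudy(simConfig(nFounders = 60L, nGenerations = 4L,
                                   mMarkers = 40L), seed = 6)
  ped <- study$ped
  fit <- singleStepSolve(ped, study$genoReduced, study$phenotypes,
                         ssModel(h2 = 0.3, w = 0.2), tol = 1e-9)
  genoCand <- study$genoCandidates
  nCand <- nrow(genoCand)
  pred <- predictIndirect(fit, ped, genoCand)
  expect_identical(nrow(pred), 4L * nCand)

  # additive decomposition of GRV holds to machine precision
  grv <- pred[pred$method == "GRV", ]
  expect_equal(grv$gebv,
               grv$j_component + grv$dgv_component + grv$rpg_component,
               tolerance = 1e-14)

  # REG equals GRV exactly for GG candidates
  reg <- pred[pred$method == "REG", ]
  gg <- grv$parent_status == "GG"
  expect_true(any(gg))
  expect_equal(reg$gebv[gg], grv$gebv[gg], tolerance = 1e-12)

  # PA is the mean of parent GEBV
  pa <- pred[pred$method == "PA", ]
  i1 <- match(pa$candidate[1], animalIds(ped))
  expected <- 0.5 * (if (sireOf(ped)[i1] > 0)
    gebv(fit)[sireOf(ped)[i1]] else 0) +
    0.5 * (if (damOf(ped)[i1] > 0) gebv(fit)[damOf(ped)[i1]] else 0)
  expect_equal(pa$gebv[1], unname(expected), tolerance = 1e-12)

  # DGV with zero SNP effects is zero
  fit0 <- fit
  fit0@snpEffects[] <- 0
  fit0@jfactorMu <- 0
  pred0 <- predictIndirect(fit0, ped, genoCand, methods = "DGV")
  expect_equal(pred0$gebv, rep(0, nCand))
})

test_that("indirect reconstruction matches evaluated animals exactly", {
  # the decomposition -mu + Z g-hat + d-hat reproduces the J-adjusted
  # GEBV of every genotyped animal in the evaluation itself
  set.seed(56)
  fx <- smallSingleStepFixture(n = 50, nGeno = 18, m = 9)
  fit <- singleStepSolve(fx$ped, fx$geno, fx$phen,
                         ssModel(h2 = 0.3, w = 0.2), tol = 1e-9)
  f <- fit@factor
  recon <- -fit@jfactorMu + zTimes(f@geno, f@p, fit@snpEffects) +
    as.numeric(fit@rpg)
  expect_equal(unname(fit@gebv[fx$gidx]), recon, tolerance = 1e-12)
})
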