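test_that("PLINK 1 binary decoding matches a hand-built fixture", {
  # 4 animals x 2 markers; per-variant codes packed by hand:
  # marker 1 counts (2,1,0,1) -> codes (00,10,11,10) -> byte 10 11 10 00
  # (little-endian pairs: animal 1 in lowest bits) = 0b10111000 = 0xB8
  # marker 2 counts (0,0,2,2) -> codes (11,11,00,00) = 0b00001111 = 0x0F
  pre <- withr::local_tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xB8, 0x0F)), paste0(pre, ".bed"))
  writeLines(c("1\tsnpA\t0\t1\tA\tB", "1\tsnpB\t0\t2\tA\tB"),
        paste0(pre, ".bim"))
  write(paste(1, paste0("an", 1:4), 0, 0, 0, -9, sep = "\t"),
        paste0(pre, ".fam"))
  geno <- readPlink(pre)
  expect_equal(unname(geno@counts), cbind(c(2, 1, 0, 1), c(0, 0, 2, 2)))
  expect_identical(geno@markerIds, c("snpA", "snpB"))

  # mode byte 0x00 (sample-major) and truncation both rejected
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0xB8, 0x0F)), paste0(pre, ".bed"))
  expect_error(readPlink(pre), "sample-major")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xB8)), paste0(pre, ".bed"))
  expect_error(readPlink(pre), "expected 5 bytes")
})

test_that("PLINK round trip is bit-exact on the .bed payload", {
  set.seed(21)
  geno <- randomGeno(11, 7)
  pre <- withr::local_tempfile()
  writePlink(geno, pre)
  back <- readPlink(pre, dropMonomorphic = FALSE)
  expect_identical(back@counts, geno@counts)
  expect_identical(back@animalIds, geno@animalIds)
  # writing the decoded matrix again reproduces the same bytes
  pre2 <- withr::local_tempfile()
  writePlink(back, pre2)
  expect_identical(readBin(paste0(pre, ".bed"), "raw", 1e4),
                   readBin(paste0(pre2, ".bed"), "raw", 1e4))
})

test_that("missing genotypes follow the chosen policy", {
  pre <- withr::local_tempfile()
  # 3 animals, 1 marker: codes (00, 01, 11) -> counts (2, NA, 0)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x34)), paste0(pre, ".bed"))
  write("1\tsnpA\t0\t1\tA\tB", paste0(pre, ".bim"))
  write(paste(1, paste0("an", 1:3), 0, 0, 0, -9, sep = "\t"),
        paste0(pre, ".fam"))
  expect_error(readPlink(pre, missingPolicy = "fail"), "missing")
  expect_warning(geno <- readPlink(pre, missingPolicy = "mean_impute",
                                   dropMonomorphic = FALSE),
                 "imputing")
  expect_equal(unname(geno@counts[2, 1]), 1)  # mean of observed 2 and 0
})

test_that("allele frequencies and the scaling constant follow their definitions", {
  geno <- new("GenotypeMatrix",
              counts = cbind(c(0, 1, 2, 1), c(1, 1, 1, 1)),
              animalIds = paste0("a", 1:4), markerIds = c("m1", "m2"))
  expect_equal(alleleFrequencies(geno), c(m1 = 0.5, m2 = 0.5),
               ignore_attr = TRUE)
  expect_equal(scalingConstant(rep(0.5, 100)), 50)
  expect_equal(scalingConstant(0.1), 0.18)
  set.seed(22)
  p <- runif(37, 0.05, 0.95)
  expect_equal(scalingConstant(p), sum(2 * p * (1 - p)), tolerance = 1e-14)
})

test_that("implicit centered products match the dense Z", {
  set.seed(23)
  geno <- randomGeno(10, 8)
  p <- alleleFrequencies(geno)
  Z <- sweep(geno@counts, 2, 2 * p)
  v <- rnorm(8); u <- rnorm(10)
  expect_equal(zTimes(geno, p, v), as.numeric(Z %*% v), tolerance = 1e-12)
  expect_equal(ztTimes(geno, p, u), as.numeric(crossprod(Z, u)),
               tolerance = 1e-12)
  expect_equal(zTimes(geno, p, numeric(8)), numeric(10))
  # a perfectly average animal has a zero Z row
  avg <- new("GenotypeMatrix", counts = matrix(c(1, 1), 1, 2),
             animalIds = "avg", markerIds = c("m1", "m2"))
  expect_equal(zTimes(avg, c(0.5, 0.5), rnorm(2)), 0)
  expect_error(zTimes(geno, p, numeric(3)), "per marker")
})

test_that("the genomic factor satisfies its defining identities", {
  set.seed(24)
  geno <- randomGeno(6, 4)
  f <- buildGenomicFactor(geno, "epsilon_identity", epsilon = 1, withT = TRUE)
  p <- f@p
  Z <- sweep(geno@counts, 2, 2 * p)
  expect_equal(f@K, crossprod(Z) + diag(1 / f@bDiag), tolerance = 1e-10)
  expect_equal(f@L %*% t(f@L), f@K, tolerance = 1e-10)
  # T'T = C^{-1} Z K^{-1} Z' C^{-1}
  expect_equal(crossprod(f@Tmat), Z %*% solve(f@K, t(Z)), tolerance = 1e-8)
  # duplicated genotypes with a vanishing ridge are flagged as non-PD
  dup <- new("GenotypeMatrix",
             counts = rbind(c(0, 1, 2, 1), c(2, 1, 0, 1))[c(1, 2, 1, 2, 1, 2), ],
             animalIds = paste0("d", 1:6), markerIds = geno@markerIds)
  expect_error(
    buildGenomicFactor(dup, "epsilon_identity", epsilon = 1e-300),
    "positive definite")
})

test_that("Woodbury products invert the dense G_C for both regularizations", {
  set.seed(25)
  for (rep in 1:25) {
    n <- sample(5:50, 1); m <- sample(3:40, 1)
    geno <- randomGeno(n, m)
    v <- rnorm(n)
    fe <- buildGenomicFactor(geno, "epsilon_identity",
                             epsilon = runif(1, 0.05, 1), withT = TRUE)
    err <- gcinvTimes(fe, v) - solve(denseGC(fe), v)
    expect_lt(sqrt(sum(err^2)) / sqrt(sum(v^2)), 1e-7)
    expect_equal(gcinvTimes(fe, v), gcinvTimes(fe, v, "original_T"),
                 tolerance = 1e-8)

    ped <- randomPedigree(n + 10)
    gidx <- sort(sample(seq_len(n + 10), n))
    agg <- aSubmatrix(ped, gidx)
    fw <- buildGenomicFactor(geno, "w_agg", w = 0.2, agg = agg, withT = TRUE)
    errW <- gcinvTimes(fw, v) - solve(denseGC(fw), v)
    expect_lt(sqrt(sum(errW^2)) / sqrt(sum(v^2)), 1e-7)
    expect_equal(gcinvTimes(fw, v), gcinvTimes(fw, v, "original_T"),
                 tolerance = 1e-8)
  }
})

test_that("dense G_C is symmetric and consistent with its inverse action", {
  set.seed(26)
  geno <- randomGeno(12, 6)
  f <- buildGenomicFactor(geno, "epsilon_identity", epsilon = 0.3)
  G <- denseGC(f)
  expect_lt(max(abs(G - t(G))), 1e-12)
  v <- rnorm(12)
  expect_equal(gcinvTimes(f, as.numeric(G %*% v)), v, tolerance = 1e-7)
  expect_equal(gcinvTimes(f, numeric(12)), numeric(12))
  expect_error(gcinvTimes(f, v, "original_T"), "without T")
})
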