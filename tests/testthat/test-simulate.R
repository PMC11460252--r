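test_that("synthetic references are deterministic and carry the homology design", {
  a <- buildSyntheticReferences(seed = 42)
  b <- buildSyntheticReferences(seed = 42)
  expect_identical(as.character(a), as.character(b))
  c <- buildSyntheticReferences(seed = 43)
  expect_false(identical(as.character(a), as.character(c)))
  # the 800 bp arm appears verbatim in both rAAV genome and producer record
  raav <- as.character(a[["rAAV_genome"]])
  arm <- substr(raav, 146, 945)
  expect_true(grepl(arm, as.character(a[["producer_genome"]]), fixed = TRUE))
  # both ITRs flank the backbone
  itr <- substr(raav, 1, 145)
  bb <- as.character(a[["plasmid_backbone"]])
  expect_identical(substr(bb, 1, 145), itr)
  # the homology search finds at least the two ITR and two arm regions
  masks <- findSharedRegions(panelRecords(a))
  expect_gte(nrow(masks), 3)
  expect_setequal(unique(masks$target_ref),
                  c("plasmid_backbone", "producer_genome"))
  expect_error(buildSyntheticReferences(seed = 1,
    sizes = c(defaultSpeciesSizes()[-2], rAAV_genome = 1000)),
    "rAAV genome length")
})

test_that("effective fractions follow the encapsidation/DNase model", {
  prep <- PrepSpec("p", c(rAAV_genome = 0.5, producer_genome = 0.3,
                          helper_plasmid = 0.2),
                   encapsidated = c(rAAV_genome = 1, producer_genome = 0,
                                    helper_plasmid = 0.5),
                   dnaseEfficiency = 0.9)
  expect_identical(effectiveFractions(prep, dnase = FALSE),
                   prepFractions(prep))
  w <- c(0.5 * 1, 0.3 * 0.1, 0.2 * (0.5 + 0.5 * 0.1))
  expect_equal(unname(effectiveFractions(prep, dnase = TRUE)), w / sum(w))
  # complete digestion of a fully extra-capsid species
  prep2 <- PrepSpec("p2", c(rAAV_genome = 0.7, producer_genome = 0.3),
                    encapsidated = c(rAAV_genome = 1, producer_genome = 0),
                    dnaseEfficiency = 1)
  refs <- fixtureSmallRefs()
  sim <- simulatePrepReads(refs, prep2, dnase = TRUE, nPairs = 500, seed = 3)
  expect_false("producer_genome" %in% sim$truth$species)
  # all weights zero errors
  prep3 <- PrepSpec("p3", c(producer_genome = 1),
                    encapsidated = c(producer_genome = 0),
                    dnaseEfficiency = 1)
  expect_error(simulatePrepReads(refs, prep3, dnase = TRUE, nPairs = 10),
               "effective")
})

test_that("DNase monotonicity: unprotected species shrink relative to rAAV", {
  fr <- c(rAAV_genome = 0.6, producer_genome = 0.4)
  prev <- Inf
  for (eff in c(0, 0.3, 0.6, 0.9, 1)) {
    prep <- PrepSpec("p", fr, encapsidated = c(rAAV_genome = 1,
                                               producer_genome = 0.2),
                     dnaseEfficiency = eff)
    w <- effectiveFractions(prep, dnase = TRUE)
    rel <- w[["producer_genome"]] / w[["rAAV_genome"]]
    expect_lte(rel, prev + 1e-12)
    prev <- rel
  }
})

test_that("truth species counts follow the multinomial model (3-sigma)", {
  refs <- fixtureRefs()
  prep <- PrepSpec("AAV2", compositionFractions("AAV2", FALSE))
  n <- 50000
  sim <- simulatePrepReads(refs, prep, dnase = FALSE, nPairs = n, seed = 9,
                           umiDupRate = 0)
  counts <- table(factor(sim$truth$species,
                         levels = names(prepFractions(prep))))
  p <- prepFractions(prep)
  for (s in names(p)) {
    expected <- n * p[[s]]
    sigma <- sqrt(n * p[[s]] * (1 - p[[s]]))
    expect_lte(abs(counts[[s]] - expected), 3 * sigma + 1)
  }
  # determinism: same seed, same bytes
  sim2 <- simulatePrepReads(refs, prep, dnase = FALSE, nPairs = 1000, seed = 5)
  sim3 <- simulatePrepReads(refs, prep, dnase = FALSE, nPairs = 1000, seed = 5)
  expect_identical(as.character(sim2$r1), as.character(sim3$r1))
  expect_identical(sim2$umi, sim3$umi)
})

test_that("read pairs are drawn from the stated fragment model", {
  refs <- fixtureSmallRefs()
  prep <- PrepSpec("p", c(rAAV_genome = 1))
  sim <- simulatePrepReads(refs, prep, nPairs = 2000, seed = 4,
                           errRate = 0, umiDupRate = 0)
  expect_true(all(nchar(as.character(sim$r1)) <= 150))
  # error-free long-fragment mate 1 is a verbatim substring of the genome
  # (either strand)
  raav <- as.character(refs[["rAAV_genome"]])
  raavRc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(raav)))
  r1 <- as.character(sim$r1)
  full <- r1[nchar(r1) == 150][1:50]
  hitsFwd <- vapply(full, function(s) grepl(s, raav, fixed = TRUE) ||
                      grepl(s, raavRc, fixed = TRUE), logical(1))
  expect_true(all(hitsFwd))
  # short fragments run into the adapter
  prepShort <- PrepSpec("p", c(rAAV_genome = 1))
  simS <- simulatePrepReads(refs, prepShort, nPairs = 3000, seed = 6,
                            fragMean = 100, fragSd = 10, errRate = 0,
                            umiDupRate = 0)
  shortIdx <- which(nchar(as.character(simS$r1)) == 150)
  expect_gt(length(shortIdx), 0)
  withAdapter <- vapply(as.character(simS$r1), function(s)
    grepl(substr(defaultAdapter(), 1, 12), s, fixed = TRUE), logical(1))
  expect_gt(mean(withAdapter), 0.9)
})

test_that("spike-in control survival is binomial in the DNase efficiency", {
  refs <- fixtureSmallRefs()
  minus <- simulateSpikeControl(refs, withDnase = FALSE, n = 5000, seed = 8)
  expect_true(all(minus$truth$species == "lambda_spike"))
  expect_equal(sum(!minus$truth$duplicate), 5000)
  plus <- simulateSpikeControl(refs, withDnase = TRUE, n = 10000,
                               dnaseEfficiency = 0.999, seed = 8)
  # binomial 3-sigma bound around 10 surviving molecules
  expect_lte(sum(!plus$truth$duplicate), 10 + 3 * sqrt(10) + 1)
  none <- simulateSpikeControl(refs, withDnase = TRUE, n = 10000,
                               dnaseEfficiency = 1, seed = 8)
  expect_equal(length(none$r1), 0L)
})

test_that("read pairs round-trip through FASTQ with UMIs and truth table", {
  refs <- fixtureSmallRefs()
  prep <- PrepSpec("p", c(rAAV_genome = 0.5, ecoli_genome = 0.5))
  sim <- simulatePrepReads(refs, prep, nPairs = 200, seed = 10)
  dir <- tempfile("reads")
  writeReadPairs(sim, dir)
  back <- readReadPairs(dir)
  expect_identical(as.character(back$r1), as.character(sim$r1))
  expect_identical(as.character(back$r2), as.character(sim$r2))
  expect_identical(back$umi, sim$umi)
  expect_identical(back$truth$species, sim$truth$species)
  expect_true(all(nchar(back$umi) == 8))
  # truth covers every read id exactly once
  expect_false(anyDuplicated(back$truth$read_id) > 0)
  expect_setequal(back$truth$read_id, names(sim$r1))
})

test_that("simulated phenotypes embody the stated clonogenicity model", {
  # noise 0, slope 0: identical expected %CFU everywhere
  m <- defaultEffectModel()
  m$noiseSd <- 0; m$slope <- 0; m$intercept <- 10
  ph <- simulatePhenotypes(c(a = 10, b = 90), m, seed = 1)
  expect_setequal(unique(ph$cfu$condition_id), c("a", "b"))
  # slope 0.2, intercept 5, purity 95 -> expected 72 colonies per 300 cells
  m2 <- defaultEffectModel()
  m2$noiseSd <- 0; m2$nDonors <- 200L
  ph2 <- simulatePhenotypes(c(x = 95), m2, seed = 2)
  plates300 <- ph2$cfu[ph2$cfu$cells_plated == 300, ]
  totals <- rowSums(plates300[, morphologyClasses()])
  expect_lt(abs(mean(totals) - 72), 3 * sqrt(72 / nrow(plates300)) + 0.5)
  # beta-actin is present for every sample and invariant in expectation
  actb <- ph2$ct[ph2$ct$gene == "ACTB", ]
  expect_setequal(unique(ph2$ct$sample_id), unique(actb$sample_id))
  expect_lt(abs(mean(actb$ct) - m2$actbCt), 0.05)
})
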