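test_that("adapter trimming matches the local-alignment contract", {
  set.seed(21)
  adapter <- defaultAdapter()
  clean <- rdna(150)
  # no adapter occurrence: unchanged (use a read with no spurious hit)
  trimmedClean <- trimReads(clean, adapter)
  expect_true(nchar(trimmedClean) == 150 || nchar(trimmedClean) > 100)
  # exact adapter in the last 30 nt: 120 nt survive
  read <- paste0(rdna(120), substr(adapter, 1, 30))
  expect_equal(nchar(trimReads(read, adapter)), 120L)
  # adapter embedded with 2 mismatches at position 100 (0-based): cut at 100
  adMut <- mutateAt(adapter, c(5, 20))
  read2 <- paste0(rdna(100), adMut, rdna(150 - 100 - nchar(adMut)))
  expect_equal(nchar(trimReads(read2, adapter)), 100L)
  # oracle: exhaustive local alignment finds the same adapter start
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(adapter), Biostrings::DNAString(read2),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  expect_equal(Biostrings::start(Biostrings::subject(aln)) - 1L, 100L)
})

test_that("pairs failing length or quality thresholds are rejected, not dropped silently", {
  set.seed(22)
  r1 <- c(rdna(150), rdna(20), rdna(150))
  r2 <- c(rdna(150), rdna(150), rdna(150))
  lowQ <- strrep("#", 150) # phred 2
  okQ <- strrep("?", 150)  # phred 30
  tf <- trimAndFilter(r1, r2, qual1 = c(okQ, okQ, lowQ),
                      qual2 = rep(okQ, 3), adapter = NULL)
  expect_equal(tf$keep, c(TRUE, FALSE, FALSE))
  expect_equal(tf$nRejected, 2L)
})

test_that("exact reads align uniquely at their source position", {
  panel <- fixturePanel()
  rseq <- as.character(refSequences(panel)[["rAAV_genome"]])
  read <- substr(rseq, 2001, 2150)
  h <- alignReads(read, panel)
  expect_equal(nrow(h), 1L)
  expect_equal(h$species, "rAAV_genome")
  expect_equal(h$pos, 2000L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$score, 150L)
  # reverse-complement read maps to the same locus on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h2 <- alignReads(rc, panel)
  expect_equal(h2$pos[h2$species == "rAAV_genome"], 2000L)
  expect_equal(h2$strand[h2$species == "rAAV_genome"], "-")
  # a read shorter than k yields no hits
  expect_equal(nrow(alignReads(substr(rseq, 1, 15), panel)), 0L)
})

test_that("reads from a masked region hit only the unmasked owner", {
  refs <- fixtureRefs()
  panel <- fixturePanel()
  # ITR region of the backbone is masked there; owner is the rAAV genome
  bbUnmasked <- as.character(refs[["plasmid_backbone"]])
  read <- substr(bbUnmasked, 11, 130) # inside the 145 bp ITR
  h <- alignReads(read, panel, minAlnLen = 50)
  expect_true(nrow(h) > 0)
  expect_true(all(h$species == "rAAV_genome"))
})

test_that("aligner positions agree with a brute-force Smith-Waterman scan", {
  panel <- fixtureSmallPanel()
  refs <- refSequences(panel)
  set.seed(23)
  nReads <- 1000
  refIdx <- sample(length(refs), nReads, replace = TRUE)
  reads <- character(nReads)
  truePos <- integer(nReads)
  for (i in seq_len(nReads)) {
    s <- as.character(refs[[refIdx[i]]])
    # draw from unmasked stretches so the true owner is the source record
    repeat {
      p <- sample(nchar(s) - 150, 1)
      sub <- substr(s, p, p + 149)
      if (!grepl("N", sub, fixed = TRUE)) break
    }
    reads[i] <- sub
    truePos[i] <- p - 1L
  }
  hits <- alignReads(reads, panel)
  best <- hits[!duplicated(hits$read), ] # sorted by score within read
  agree <- 0L
  for (i in seq_len(nReads)) {
    hrow <- best[best$read == i, ]
    if (nrow(hrow) != 1) next
    sw <- ssvseqr:::cpp_sw_local(as.character(refs[[hrow$ref_id]]),
                                 reads[i], 1L, -4L, -6L, -1L)
    if (abs(hrow$pos - sw$start) <= 2 && hrow$score == sw$score) {
      agree <- agree + 1L
    }
  }
  expect_gte(agree / nReads, 0.99)
})

test_that("the brute-force SW oracle itself matches pairwiseAlignment", {
  set.seed(24)
  for (i in 1:5) {
    ref <- rdna(800)
    p <- sample(600, 1)
    read <- mutateAt(substr(ref, p, p + 99), sample(100, 3))
    sw <- ssvseqr:::cpp_sw_local(ref, read, 1L, -4L, -6L, -1L)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(ref),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -4),
      gapOpening = 6, gapExtension = 1)
    expect_equal(sw$score, Biostrings::score(aln))
    expect_equal(sw$start, Biostrings::start(Biostrings::subject(aln)) - 1L)
  }
})

test_that("pair assignment follows the score-margin rule", {
  panel <- fixtureSmallPanel()
  ids <- names(refSequences(panel))
  mkHits <- function(read, ref_id, score, pos = 100L) {
    data.frame(read = read, ref_id = ref_id,
               species = unname(refSpecies(panel)[ref_id]),
               pos = rep(pos, length(read)),
               strand = rep("+", length(read)),
               score = score, aln_len = rep(100L, length(read)),
               identity = rep(0.99, length(read)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  # both mates hit only the producer genome
  a <- assignPairs(mkHits(1L, "producer_genome", 100L),
                   mkHits(1L, "producer_genome", 90L), panel, nPairs = 1)
  expect_equal(a$category, "producer_genome")
  expect_equal(a$pos, 100L)
  # no hits at all -> unmapped
  empty <- mkHits(integer(), character(), integer())
  b <- assignPairs(empty, empty, panel, nPairs = 1)
  expect_equal(b$category, "unmapped")
  # mate1 ties between helper and repcap, mate2 unaligned -> ambiguous
  h1 <- rbind(mkHits(1L, "helper_plasmid", 80L),
              mkHits(1L, "repcap_plasmid", 80L))
  c1 <- assignPairs(h1, empty, panel, nPairs = 1)
  expect_equal(c1$category, "ambiguous")
  # a clear margin wins
  h2 <- rbind(mkHits(1L, "helper_plasmid", 85L),
              mkHits(1L, "repcap_plasmid", 80L))
  c2 <- assignPairs(h2, empty, panel, nPairs = 1, scoreMargin = 5)
  expect_equal(c2$category, "helper_plasmid")
})

test_that("UMI deduplication collapses duplicates and preserves distinct molecules", {
  asg <- data.frame(
    pair = 1:5,
    category = c("rAAV_genome", "rAAV_genome", "rAAV_genome",
                 "rAAV_genome", "rAAV_genome"),
    ref_id = "rAAV_genome",
    pos = c(100L, 100L, 1100L, 100L, 101L),
    score = 150, stringsAsFactors = FALSE)
  umi <- c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "AAAAAAAT")
  keep <- dedupUmi(asg, umi)
  # same UMI+pos collapses (1,2); distant position survives (3); different
  # UMI survives (4); Hamming-1 UMI at same position collapses only at
  # dp = 0 -- record 5 is at pos 101 so it survives
  expect_equal(keep, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  umi2 <- c("AAAAAAAA", "AAAAAAAT", "AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
  asg2 <- asg; asg2$pos <- c(100L, 100L, 1100L, 100L, 100L)
  expect_equal(dedupUmi(asg2, umi2), c(TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("dedup recovers the true molecule count within 1% at 5% duplication", {
  refs <- fixtureRefs()
  panel <- fixturePanel()
  prep <- fixturePrep()
  sim <- simulatePrepReads(refs, prep, dnase = FALSE, nPairs = 20000,
                           seed = 31, umiDupRate = 0.05)
  res <- classifyReads(sim$r1, sim$r2, sim$umi, panel, prepId = "AAV2",
                       dnase = FALSE, adapter = NULL)
  trueMolecules <- sum(!sim$truth$duplicate)
  expect_lte(abs(res$qc$nDedup - trueMolecules) / trueMolecules, 0.01)
})

test_that("profiles conserve reads and sum to 100", {
  panel <- fixtureSmallPanel()
  asg <- data.frame(pair = 1:4,
                    category = c("rAAV_genome", "rAAV_genome",
                                 "ambiguous", "unmapped"),
                    ref_id = c("rAAV_genome", "rAAV_genome", NA, NA),
                    pos = c(1L, 5L, NA, NA), score = c(300, 300, NA, NA),
                    stringsAsFactors = FALSE)
  prof <- speciesProfile(asg, panel, "p", FALSE)
  p <- percentages(prof)
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_equal(p[["rAAV_genome"]], 50)
  expect_equal(p[["unmapped"]], 50) # ambiguous folded into unmapped
  expect_equal(nAmbiguous(prof), 1L)
  expect_error(speciesProfile(asg[0, ], panel, "p", FALSE), "zero")
  # two categories, one read each -> 50/50
  asg2 <- data.frame(pair = 1:2,
                     category = c("rAAV_genome", "ecoli_genome"),
                     ref_id = c("rAAV_genome", "ecoli_genome"),
                     pos = c(1L, 1L), score = c(1, 1),
                     stringsAsFactors = FALSE)
  p2 <- percentages(speciesProfile(asg2, panel, "p", FALSE))
  expect_equal(unname(p2[c("rAAV_genome", "ecoli_genome")]), c(50, 50))
})

test_that("every input pair lands in exactly one outcome bucket", {
  refs <- fixtureRefs()
  panel <- fixturePanel()
  prep <- fixturePrep()
  sim <- simulatePrepReads(refs, prep, dnase = FALSE, nPairs = 3000,
                           seed = 32)
  res <- classifyReads(sim$r1, sim$r2, sim$umi, panel, prepId = "AAV2",
                       dnase = FALSE)
  expect_equal(res$qc$nRejected + res$qc$nPairs, res$qc$nInput)
  expect_equal(nrow(res$assignments), res$qc$nPairs)
  cats <- res$assignments$category
  known <- c(unique(refSpecies(panel)), "ambiguous", "unmapped")
  expect_true(all(cats %in% known))
  expect_equal(sum(table(cats)), res$qc$nPairs)
})

test_that("unmapped triage reports secondary hits without altering profiles", {
  set.seed(25)
  secondary <- Biostrings::DNAStringSet(c(mystery_plasmid = rdna(4000)))
  reads <- vapply(1:20, function(i) {
    p <- sample(3800, 1)
    substr(as.character(secondary[[1]]), p, p + 149)
  }, character(1))
  tri <- triageUnmapped(reads, secondary)
  expect_gte(length(unique(tri$read)), 19)
  expect_true(all(tri$ref_id == "mystery_plasmid"))
})
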