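# Synthetic-data generator: reference construction with deliberate
# cross-species homology, prep composition, encapsidation/DNase model and
# read simulation with UMIs and substitution errors.

#' Default synthetic reference lengths (bases)
#'
#' A producer-genome segment stands in for the full producer cell genome;
#' the lambda segment matches the length of the phage genome used as the
#' DNase spike-in control.
#'
#' @return named numeric vector of sequence lengths per species.
#' @export
defaultSpeciesSizes <- function() {
  c(producer_genome = 200000, rAAV_genome = 4700, plasmid_backbone = 3000,
    helper_plasmid = 10000, repcap_plasmid = 7000, ecoli_genome = 50000,
    baculovirus = 20000, lambda_spike = 48500, foreign = 20000)
}

#' Standard 3' sequencing adapter used by the simulator and trimmer
#' @return adapter sequence as a character scalar.
#' @export
defaultAdapter <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Build synthetic reference records with deliberate cross-species homology
#'
#' Emulates the homology structure that makes competitive classification of
#' real rAAV preparations hard: the vector genome is
#' `ITR + left homology arm + cassette + right arm + ITR` where both
#' 800-bp arms are copied verbatim from random loci of the producer-genome
#' record and the 145-bp ITRs (the right one inverted) also flank the
#' vector-plasmid backbone. All other records are i.i.d. uniform DNA.
#' Output is byte-deterministic under `seed`.
#'
#' @param seed integer RNG seed.
#' @param sizes named lengths per species; see [defaultSpeciesSizes()].
#' @param itrLen inverted terminal repeat length (145 bp).
#' @param armLen homology arm length copied from the producer genome.
#' @return a [referenceSet()]: named `DNAStringSet` with `species` and
#'   `priority` mcols. The `foreign` record carries priority `NA` and must
#'   not be placed in a panel.
#' @export
buildSyntheticReferences <- function(seed, sizes = defaultSpeciesSizes(),
                                     itrLen = 145, armLen = 800) {
  set.seed(seed)
  sizes <- sizes[order(match(names(sizes), names(defaultSpeciesSizes())))]
  if (sizes[["rAAV_genome"]] < 2 * itrLen + 2 * armLen)
    stop("rAAV genome length must be at least 2*itrLen + 2*armLen")
  producer <- randomDna(sizes[["producer_genome"]])
  itr <- randomDna(itrLen)
  # two non-overlapping arm loci on the producer segment
  L <- sizes[["producer_genome"]]
  lociOk <- FALSE
  while (!lociOk) {
    locs <- sort(sample.int(L - armLen, 2) - 1L)
    lociOk <- locs[2] - locs[1] >= armLen
  }
  armL <- substr(producer, locs[1] + 1, locs[1] + armLen)
  armR <- substr(producer, locs[2] + 1, locs[2] + armLen)
  cassette <- randomDna(sizes[["rAAV_genome"]] - 2 * itrLen - 2 * armLen)
  raav <- paste0(itr, armL, cassette, armR, revcompChar(itr))
  bbMid <- randomDna(sizes[["plasmid_backbone"]] - 2 * itrLen)
  backbone <- paste0(itr, bbMid, revcompChar(itr))
  seqs <- c(
    rAAV_genome = raav,
    producer_genome = producer,
    plasmid_backbone = backbone,
    helper_plasmid = randomDna(sizes[["helper_plasmid"]]),
    repcap_plasmid = randomDna(sizes[["repcap_plasmid"]]),
    ecoli_genome = randomDna(sizes[["ecoli_genome"]]),
    baculovirus = randomDna(sizes[["baculovirus"]]),
    lambda_spike = randomDna(sizes[["lambda_spike"]]),
    foreign = randomDna(sizes[["foreign"]])
  )
  species <- names(seqs)
  priority <- unname(DEFAULT_PRIORITY[species])
  out <- DNAStringSet(seqs)
  mcols(out) <- DataFrame(species = species, priority = as.integer(priority))
  attr(out, "arm_loci") <- locs
  out
}

#' Effective species fractions under the encapsidation/DNase model
#'
#' Without DNase the effective fractions equal the prep's molecule
#' fractions. With DNase, each species' weight is
#' `f * (enc + (1 - enc) * (1 - efficiency))`: encapsidated molecules are
#' protected, a `(1 - efficiency)` remnant of extra-capsid molecules
#' survives, and the weights are renormalized.
#'
#' @param prep a [PrepSpec].
#' @param dnase logical, apply the DNase model.
#' @return named numeric fractions summing to 1.
#' @export
effectiveFractions <- function(prep, dnase) {
  f <- prepFractions(prep)
  if (!dnase) return(f)
  enc <- prepEncapsidated(prep)[names(f)]
  eff <- prepDnaseEfficiency(prep)
  w <- f * (enc + (1 - enc) * (1 - eff))
  if (sum(w) <= 0) stop("all effective species weights are zero under DNase")
  w / sum(w)
}

injectErrors <- function(reads, errRate) {
  if (errRate <= 0) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), errRate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  reads
}

#' Simulate paired-end SSV-seq reads from a prep specification
#'
#' Molecules are drawn multinomially from the prep's effective fractions
#' (see [effectiveFractions()]), fragmented at ~300 bp (sonication-scale
#' fragments), sequenced from both ends with i.i.d. substitution errors,
#' tagged with random 8-nt UMIs, and a configurable fraction of molecules
#' is emitted twice to exercise UMI deduplication. When a fragment is
#' shorter than the read length the read runs into the 3' adapter. The
#' ground-truth species of every read pair (pre-error) is recorded in the
#' `truth` table, never in the reads themselves.
#'
#' @param refs a [referenceSet()] including a `foreign` record.
#' @param prep a [PrepSpec].
#' @param dnase logical, simulate the DNase-treated aliquot.
#' @param nPairs number of molecules (deduplicated read pairs) to draw.
#' @param fragMean,fragSd sonication fragment length model (normal,
#'   truncated to `[50, 2*readLen + 200]`).
#' @param readLen read length per mate.
#' @param errRate per-base substitution error rate.
#' @param umiDupRate fraction of molecules emitted as PCR duplicates.
#' @param adapter 3' adapter appended on fragment read-through.
#' @param seed integer RNG seed.
#' @return list with `r1`, `r2` (named [Biostrings::DNAStringSet]), `umi`
#'   (character per read pair), and `truth` (data.frame: `read_id`,
#'   `molecule_id`, `species`, `duplicate`).
#' @export
simulatePrepReads <- function(refs, prep, dnase = FALSE, nPairs,
                              fragMean = 300, fragSd = 60, readLen = 150,
                              errRate = 0.001, umiDupRate = 0.05,
                              adapter = defaultAdapter(), seed = 1) {
  stopifnot(nPairs >= 1)
  set.seed(seed)
  w <- effectiveFractions(prep, dnase)
  w <- w[w > 0]
  refChars <- setNames(as.character(refs), mcols(refs)$species)
  missing <- setdiff(names(w), names(refChars))
  if (length(missing))
    stop("no reference record for species: ", paste(missing, collapse = ", "))
  counts <- as.vector(rmultinom(1, nPairs, w))
  species <- rep(names(w), counts)
  species <- sample(species) # shuffle molecule order
  n <- length(species)
  refLen <- nchar(refChars)[species]
  maxFrag <- 2 * readLen + 200
  fragLen <- pmin(pmax(round(rnorm(n, fragMean, fragSd)), 50), maxFrag)
  fragLen <- pmin(fragLen, refLen)
  start <- floor(runif(n) * (refLen - fragLen + 1)) # 0-based
  frag <- substr(refChars[species], start + 1, start + fragLen)
  minus <- runif(n) < 0.5
  frag[minus] <- revcompChar(frag[minus])
  umi <- do.call(paste0, as.data.frame(
    matrix(sample(c("A", "C", "G", "T"), 8 * n, replace = TRUE), nrow = n),
    stringsAsFactors = FALSE
  ))
  moleculeId <- sprintf("%s_m%06d", prepId(prep), seq_len(n))

  makeMates <- function(frag) {
    short <- nchar(frag) < readLen
    r1 <- substr(frag, 1, readLen)
    r2 <- revcompChar(substr(frag, pmax(nchar(frag) - readLen + 1, 1),
                             nchar(frag)))
    if (any(short)) {
      pad <- readLen - nchar(frag[short])
      tail3 <- substr(strrep(adapter, ceiling(readLen / nchar(adapter))),
                      1, max(pad))
      r1[short] <- paste0(r1[short], substring(tail3, 1, pad))
      r2[short] <- paste0(r2[short], substring(tail3, 1, pad))
    }
    list(r1 = r1, r2 = r2)
  }
  mates <- makeMates(frag)
  dup <- runif(n) < umiDupRate
  idx <- c(seq_len(n), which(dup))
  readId <- c(sprintf("%s_r%06d", prepId(prep), seq_len(n)),
              sprintf("%s_r%06d_dup", prepId(prep), which(dup)))
  r1 <- injectErrors(mates$r1[idx], errRate)
  r2 <- injectErrors(mates$r2[idx], errRate)
  truth <- data.frame(
    read_id = readId,
    molecule_id = moleculeId[idx],
    species = species[idx],
    duplicate = c(rep(FALSE, n), rep(TRUE, sum(dup))),
    stringsAsFactors = FALSE
  )
  r1 <- DNAStringSet(r1); names(r1) <- readId
  r2 <- DNAStringSet(r2); names(r2) <- readId
  list(r1 = r1, r2 = r2, umi = umi[idx], truth = truth)
}

#' Simulate the lambda spike-in DNase control
#'
#' The spike-in is naked (never encapsidated) lambda DNA: without DNase all
#' molecules survive; with DNase each molecule survives independently with
#' probability `1 - dnaseEfficiency`, so the surviving count is binomial
#' and complete digestion yields an empty read set.
#'
#' @param refs a [referenceSet()] containing a `lambda_spike` record.
#' @param withDnase logical.
#' @param n number of spike molecules in the reaction.
#' @param dnaseEfficiency fraction of (extra-capsid) molecules destroyed.
#' @param seed integer RNG seed.
#' @param ... passed on to [simulatePrepReads()].
#' @return as [simulatePrepReads()]; all components empty when every
#'   molecule is digested.
#' @export
simulateSpikeControl <- function(refs, withDnase, n = 10000,
                                 dnaseEfficiency = 0.999, seed = 1, ...) {
  set.seed(seed)
  nSurv <- if (withDnase) rbinom(1, n, 1 - dnaseEfficiency) else n
  if (nSurv == 0) {
    empty <- DNAStringSet()
    return(list(r1 = empty, r2 = empty, umi = character(),
                truth = data.frame(read_id = character(),
                                   molecule_id = character(),
                                   species = character(),
                                   duplicate = logical())))
  }
  prep <- PrepSpec(if (withDnase) "spike_plus" else "spike_minus",
                   fractions = c(lambda_spike = 1),
                   encapsidated = c(lambda_spike = 0),
                   dnaseEfficiency = dnaseEfficiency)
  simulatePrepReads(refs, prep, dnase = FALSE, nPairs = nSurv,
                    seed = seed + 1L, ...)
}

#' Write / read simulated read pairs as FASTQ plus a truth table
#'
#' Reads go to `R1.fastq` / `R2.fastq` (flat Q30 qualities; the UMI is
#' carried in the read name as `<id> UMI=<seq>`), the ground truth to
#' `truth.tsv`.
#'
#' @param reads a read set from [simulatePrepReads()].
#' @param dir output directory.
#' @return `writeReadPairs` returns `dir` invisibly; `readReadPairs`
#'   returns the same structure as [simulatePrepReads()] (plus `qual1`,
#'   `qual2`).
#' @export
writeReadPairs <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMate <- function(x, path) {
    q <- PhredQuality(strrep("?", BiocGenerics::width(x))) # Q30
    xs <- QualityScaledDNAStringSet(x, q)
    names(xs) <- sprintf("%s UMI=%s", names(x), reads$umi)
    writeQualityScaledXStringSet(xs, path)
  }
  writeMate(reads$r1, file.path(dir, "R1.fastq"))
  writeMate(reads$r2, file.path(dir, "R2.fastq"))
  write.table(reads$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeReadPairs
#' @param dir directory written by `writeReadPairs`.
#' @export
readReadPairs <- function(dir) {
  rd <- function(path) {
    # Biostrings warns about dropping (empty) mcols during its internal
    # coercion; nothing of ours is lost
    suppressWarnings(readQualityScaledDNAStringSet(path))
  }
  r1 <- rd(file.path(dir, "R1.fastq"))
  r2 <- rd(file.path(dir, "R2.fastq"))
  parse <- function(x) {
    nm <- names(x)
    id <- sub(" .*", "", nm)
    umi <- sub(".*UMI=", "", nm)
    names(x) <- id
    list(x = x, umi = umi)
  }
  p1 <- parse(r1); p2 <- parse(r2)
  truth <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  mcols(p1$x) <- NULL
  mcols(p2$x) <- NULL
  list(r1 = DNAStringSet(p1$x), r2 = DNAStringSet(p2$x), umi = p1$umi,
       qual1 = as.character(p1$x@quality), qual2 = as.character(p2$x@quality),
       truth = truth)
}
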