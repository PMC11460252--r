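# Per-base coverage over the rAAV genome with depth normalization, and
# SNV aggregation with the combined-alternative-allele rule.

#' Per-base coverage track over the vector genome
#'
#' `raw[i]` is the number of deduplicated read alignments whose aligned
#' span covers base `i`; `normalized` scales the track to a total of
#' 1,000 so preps are comparable regardless of sequencing depth
#' (`1000 * raw / sum(raw)`).
#'
#' @param pos 0-based leftmost alignment positions.
#' @param alnLen aligned span lengths.
#' @param refLen reference length in bases.
#' @param refId reference identifier stored on the track.
#' @return a [CoverageTrack]. With zero total coverage the normalized
#'   track is all zero, with a warning.
#' @export
coverageTrack <- function(pos, alnLen, refLen, refId = "rAAV_genome") {
  stopifnot(length(pos) == length(alnLen))
  if (length(pos)) {
    ir <- IRanges(start = pos + 1L, width = alnLen)
    raw <- as.numeric(coverage(ir, width = refLen))
  } else {
    raw <- numeric(refLen)
  }
  tot <- sum(raw)
  if (tot > 0) {
    normalized <- 1000 * raw / tot
  } else {
    warning("zero total coverage; normalized track is all zero")
    normalized <- numeric(refLen)
  }
  new("CoverageTrack", refId = refId, raw = raw, normalized = normalized)
}

#' Per-base nucleotide counts for one sample
#'
#' Projects reference-oriented, ungapped read alignments onto the
#' reference and counts A/C/G/T per position.
#'
#' @param pos 0-based leftmost alignment positions.
#' @param seqs aligned read sequences, reference-oriented.
#' @param refSeq reference sequence (character or `DNAString`).
#' @return list with `counts` (4 x L integer matrix, rows A,C,G,T) and
#'   `ref` (reference base per position).
#' @export
pileupCounts <- function(pos, seqs, refSeq) {
  refSeq <- as.character(refSeq)
  L <- nchar(refSeq)
  counts <- cpp_pileup(as.integer(L), as.integer(pos), as.character(seqs))
  rownames(counts) <- c("A", "C", "G", "T")
  list(counts = counts, ref = strsplit(refSeq, "")[[1]])
}

#' Aggregate SNVs across samples with combined alternative alleles
#'
#' Per sample and position with depth at least `minDepth`, the alternative
#' fraction is `(depth - reference-base count) / depth`: all alternative
#' alleles at a position are combined into one variant contribution. A
#' position is "present" in a sample when its alternative fraction reaches
#' `minAltFraction`, and is reported only when present in at least half of
#' all samples (`ceiling(S / 2)`). The reported fraction is the mean over
#' the samples where the variant is present.
#'
#' @param pileups list of per-sample pileups from [pileupCounts()]; all
#'   must share the same reference bases.
#' @param minDepth minimum per-sample depth to evaluate a position.
#' @param minAltFraction presence threshold on the combined alternative
#'   fraction.
#' @return data.frame with `pos` (0-based), `ref_base`,
#'   `alt_fraction_combined`, `n_samples_present`; the per-sample presence
#'   matrix is attached as attribute `present`.
#' @export
callSnvs <- function(pileups, minDepth = 20, minAltFraction = 0.01) {
  S <- length(pileups)
  stopifnot(S >= 1)
  ref <- pileups[[1]]$ref
  for (p in pileups) {
    if (!identical(p$ref, ref))
      stop("inconsistent reference bases across samples")
  }
  L <- length(ref)
  refIdx <- match(ref, c("A", "C", "G", "T"))
  altFrac <- matrix(NA_real_, nrow = S, ncol = L)
  for (s in seq_len(S)) {
    cnt <- pileups[[s]]$counts
    depth <- colSums(cnt)
    refCnt <- ifelse(is.na(refIdx), 0L, cnt[cbind(refIdx, seq_len(L))])
    af <- (depth - refCnt) / depth
    af[depth < minDepth] <- NA_real_
    altFrac[s, ] <- af
  }
  present <- !is.na(altFrac) & altFrac >= minAltFraction
  nPresent <- colSums(present)
  report <- which(nPresent >= ceiling(S / 2))
  combined <- vapply(report, function(j) {
    mean(altFrac[present[, j], j])
  }, numeric(1))
  out <- data.frame(pos = report - 1L, ref_base = ref[report],
                    alt_fraction_combined = combined,
                    n_samples_present = nPresent[report],
                    stringsAsFactors = FALSE)
  attr(out, "present") <- present[, report, drop = FALSE]
  out
}

#' Write a coverage track / SNV table as TSV
#'
#' @param track a [CoverageTrack].
#' @param snvs data.frame from [callSnvs()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
writeCoverage <- function(track, path) {
  df <- data.frame(pos = seq_along(rawCoverage(track)) - 1L,
                   raw = rawCoverage(track),
                   normalized = normalizedCoverage(track))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCoverage
#' @export
writeSnvs <- function(snvs, path) {
  write.table(snvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
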