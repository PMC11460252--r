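# Read QC, adapter trimming, competitive alignment against the masked
# panel, pair assignment, UMI deduplication and species profiling.

asCharReads <- function(x) {
  if (is(x, "XStringSet")) as.character(x) else as.character(x)
}

#' Locate and trim a 3' adapter by local alignment
#'
#' The adapter is located within each read by Smith-Waterman local
#' alignment (match 1, mismatch -1, gap -2); when the best alignment
#' reaches `minScore` the read is cut at the alignment start and everything
#' downstream removed.
#'
#' @param reads character vector or `DNAStringSet`.
#' @param adapter adapter sequence.
#' @param minScore minimum local-alignment score to accept an adapter hit.
#' @return character vector of trimmed reads.
#' @export
trimReads <- function(reads, adapter = defaultAdapter(), minScore = 10) {
  stopifnot(nchar(adapter) > 0)
  r <- asCharReads(reads)
  pos <- cpp_trim_positions(r, adapter, 1L, -1L, -2L, as.integer(minScore))
  trimmed <- ifelse(pos >= 0, substr(r, 1, pos), r)
  names(trimmed) <- names(r)
  trimmed
}

meanPhred <- function(qual) {
  vapply(qual, function(q) {
    if (nchar(q) == 0) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Trim adapters and quality-filter read pairs
#'
#' Both mates are adapter-trimmed with [trimReads()]; a pair is rejected
#' (a counted outcome, not an error) when either trimmed mate is shorter
#' than `minLen` or has mean base quality below `minMeanQ`.
#'
#' @param r1,r2 mate sequences (character or `DNAStringSet`).
#' @param qual1,qual2 optional phred quality strings (trimmed alongside
#'   the reads); when `NULL` all bases are assumed Q30.
#' @param adapter 3' adapter sequence; `NULL` skips trimming.
#' @param minLen minimum surviving mate length.
#' @param minMeanQ minimum mean phred quality per mate.
#' @return list with trimmed `r1`, `r2`, logical `keep` per pair and the
#'   count `nRejected`.
#' @export
trimAndFilter <- function(r1, r2, qual1 = NULL, qual2 = NULL,
                          adapter = defaultAdapter(), minLen = 30,
                          minMeanQ = 20) {
  r1 <- asCharReads(r1); r2 <- asCharReads(r2)
  stopifnot(length(r1) == length(r2))
  if (!is.null(adapter)) {
    t1 <- trimReads(r1, adapter); t2 <- trimReads(r2, adapter)
  } else {
    t1 <- r1; t2 <- r2
  }
  if (!is.null(qual1)) qual1 <- substr(qual1, 1, nchar(t1))
  if (!is.null(qual2)) qual2 <- substr(qual2, 1, nchar(t2))
  q1 <- if (is.null(qual1)) rep(30, length(t1)) else meanPhred(qual1)
  q2 <- if (is.null(qual2)) rep(30, length(t2)) else meanPhred(qual2)
  keep <- nchar(t1) >= minLen & nchar(t2) >= minLen &
    q1 >= minMeanQ & q2 >= minMeanQ
  list(r1 = t1, r2 = t2, keep = keep, nRejected = sum(!keep))
}

#' Competitively align reads against a masked reference panel
#'
#' Seed-and-extend local alignment: exact k-mer seeds against the unmasked
#' panel bases, diagonal chaining, banded extension with affine gaps
#' (match 1, mismatch -4, gap open -6, extend -1). At most the best hit
#' per reference is kept for each read; hits below `minIdentity` or
#' `minAlnLen` are discarded. Reads shorter than `k` yield no hits.
#'
#' @param reads character vector or `DNAStringSet`.
#' @param panel a [ReferencePanel].
#' @param k seed length.
#' @param minIdentity,minAlnLen hit acceptance thresholds.
#' @param band half-width of the extension band (max indel drift).
#' @param maxOcc seeds occurring more often than this in the panel are
#'   ignored as repetitive.
#' @param maxChains diagonal clusters extended per read and strand.
#' @return data.frame with columns `read` (input index), `ref_id`,
#'   `species`, `pos` (0-based leftmost), `strand`, `score`, `aln_len`,
#'   `identity`, sorted by read then score descending.
#' @export
alignReads <- function(reads, panel, k = 21, minIdentity = 0.90,
                       minAlnLen = 50, band = 4, maxOcc = 32,
                       maxChains = 4) {
  r <- asCharReads(reads)
  refs <- as.character(refSequences(panel))
  hits <- cpp_align_reads(refs, r, as.integer(k), as.integer(band),
                          1L, -4L, -6L, -1L, minIdentity,
                          as.integer(minAlnLen), as.integer(maxOcc),
                          as.integer(maxChains))
  df <- data.frame(
    read = hits$read,
    ref_id = names(refSequences(panel))[hits$ref],
    species = panel@species[hits$ref],
    pos = hits$pos,
    strand = ifelse(hits$strand == 0L, "+", "-"),
    score = hits$score,
    aln_len = hits$aln_len,
    identity = hits$identity,
    stringsAsFactors = FALSE
  )
  df[order(df$read, -df$score), , drop = FALSE]
}

#' Assign read pairs to species by competitive pair score
#'
#' The pair score for a reference is the best hit score of mate 1 plus the
#' best of mate 2 (0 for a mate without a hit on that reference); species
#' scores are the maximum over the species' references. A pair is assigned
#' to the top species when it beats the runner-up species by at least
#' `scoreMargin`, is `ambiguous` when within the margin, and `unmapped`
#' when neither mate has any hit.
#'
#' @param hits1,hits2 per-mate hit tables from [alignReads()].
#' @param panel a [ReferencePanel].
#' @param nPairs number of read pairs the hits refer to.
#' @param scoreMargin minimum winning margin between species scores.
#' @return data.frame with one row per pair: `pair`, `category`, `ref_id`,
#'   `pos` (best-hit position of mate 1 on the winning reference, mate 2's
#'   when mate 1 has none; `NA` for unmapped/ambiguous), `score`.
#' @export
assignPairs <- function(hits1, hits2, panel, nPairs, scoreMargin = 5) {
  ids <- names(refSequences(panel))
  nref <- length(ids)
  scoreMat <- matrix(0, nrow = nPairs, ncol = nref,
                     dimnames = list(NULL, ids))
  hitMat <- matrix(FALSE, nrow = nPairs, ncol = nref)
  addMate <- function(h) {
    if (nrow(h) == 0) return()
    j <- match(h$ref_id, ids)
    idx <- cbind(h$read, j)
    scoreMat[idx] <<- scoreMat[idx] + h$score
    hitMat[idx] <<- TRUE
  }
  addMate(hits1); addMate(hits2)
  speciesOf <- panel@species
  uspecies <- unique(speciesOf)
  spMat <- matrix(-Inf, nrow = nPairs, ncol = length(uspecies),
                  dimnames = list(NULL, uspecies))
  spHit <- matrix(FALSE, nrow = nPairs, ncol = length(uspecies),
                  dimnames = list(NULL, uspecies))
  for (s in uspecies) {
    cols <- which(speciesOf == s)
    sub <- scoreMat[, cols, drop = FALSE]
    sub[!hitMat[, cols, drop = FALSE]] <- -Inf
    spMat[, s] <- do.call(pmax, c(as.data.frame(sub), list(-Inf)))
    spHit[, s] <- rowSums(hitMat[, cols, drop = FALSE]) > 0
  }
  anyHit <- rowSums(spHit) > 0
  category <- rep("unmapped", nPairs)
  refId <- rep(NA_character_, nPairs)
  pos <- rep(NA_integer_, nPairs)
  score <- rep(NA_real_, nPairs)
  if (any(anyHit)) {
    ord <- t(apply(spMat[anyHit, , drop = FALSE], 1, function(r) {
      o <- order(r, decreasing = TRUE)
      c(o[1], r[o[1]], if (length(r) > 1) r[o[2]] else -Inf)
    }))
    top <- uspecies[ord[, 1]]
    margin <- ord[, 2] - ord[, 3]
    won <- is.infinite(ord[, 3]) | margin >= scoreMargin
    category[anyHit] <- ifelse(won, top, "ambiguous")
    score[anyHit] <- ord[, 2]
    # winning reference: best-scoring ref of the winning species
    winIdx <- which(anyHit)[won]
    if (length(winIdx)) {
      winSpecies <- top[won]
      refPick <- vapply(seq_along(winIdx), function(t) {
        cols <- which(speciesOf == winSpecies[t])
        sc <- scoreMat[winIdx[t], cols]
        sc[!hitMat[winIdx[t], cols]] <- -Inf
        cols[which.max(sc)]
      }, integer(1))
      refId[winIdx] <- ids[refPick]
      # position: mate1's best hit on that ref, else mate2's
      key <- paste(winIdx, ids[refPick])
      p1 <- hits1$pos[match(key, paste(hits1$read, hits1$ref_id))]
      p2 <- hits2$pos[match(key, paste(hits2$read, hits2$ref_id))]
      pos[winIdx] <- ifelse(!is.na(p1), p1, p2)
    }
  }
  data.frame(pair = seq_len(nPairs), category = category, ref_id = refId,
             pos = pos, score = score, stringsAsFactors = FALSE)
}

#' Collapse PCR duplicates by UMI
#'
#' Mapped records identical in (UMI, category, position within `posTol`
#' bases) collapse to one; at the same position, UMIs within Hamming
#' distance 1 also collapse (sequencing errors in the UMI itself).
#' Unmapped and ambiguous records deduplicate on (UMI, first 30 nt of
#' mate 1).
#'
#' @param assignments data.frame from [assignPairs()].
#' @param umi UMI per pair.
#' @param r1 mate-1 sequences (used for unmapped dedup); optional.
#' @param posTol positional tolerance in bases.
#' @return logical vector, `TRUE` for the retained representative of each
#'   molecule.
#' @export
dedupUmi <- function(assignments, umi, r1 = NULL, posTol = 2) {
  n <- nrow(assignments)
  stopifnot(length(umi) == n)
  keep <- rep(TRUE, n)
  mapped <- !is.na(assignments$pos)
  if (any(mapped)) {
    mi <- which(mapped)
    cat_id <- as.integer(factor(paste(assignments$category[mi],
                                      assignments$ref_id[mi])))
    o <- order(cat_id, assignments$pos[mi])
    k <- cpp_dedup_keep(cat_id[o], as.integer(assignments$pos[mi][o]),
                        umi[mi][o], as.integer(posTol))
    keep[mi[o]] <- k
  }
  if (any(!mapped)) {
    ui <- which(!mapped)
    sig <- if (is.null(r1)) umi[ui]
           else paste(umi[ui], substr(asCharReads(r1)[ui], 1, 30))
    keep[ui] <- !duplicated(sig)
  }
  keep
}

#' Build a species percentage profile from deduplicated assignments
#'
#' Percentages are deduplicated read-pair fractions per category over all
#' panel species plus `unmapped`. Ambiguous pairs count inside `unmapped`
#' for the headline percentages; their number is retained separately.
#'
#' @param assignments deduplicated assignment table ([assignPairs()] rows
#'   after [dedupUmi()]).
#' @param panel a [ReferencePanel].
#' @param prepId,dnase profile identity.
#' @param nQcRejected pairs removed before mapping (kept out of the
#'   denominator).
#' @return a [SpeciesProfile].
#' @export
speciesProfile <- function(assignments, panel, prepId, dnase,
                           nQcRejected = 0L) {
  n <- nrow(assignments)
  if (n == 0) stop("cannot profile zero assignments")
  cats <- unique(panel@species)
  counts <- setNames(numeric(length(cats) + 1), c(cats, "unmapped"))
  tab <- table(assignments$category)
  for (s in names(tab)) {
    if (s %in% cats) counts[s] <- tab[[s]]
    else counts["unmapped"] <- counts["unmapped"] + tab[[s]]
  }
  nAmb <- if ("ambiguous" %in% names(tab)) tab[["ambiguous"]] else 0L
  new("SpeciesProfile", prepId = prepId, dnase = dnase,
      percentages = 100 * counts / n, nTotalDedup = as.integer(n),
      nAmbiguous = as.integer(nAmb), nQcRejected = as.integer(nQcRejected))
}

#' Classify read pairs end to end
#'
#' Runs adapter trimming and QC, competitive alignment of both mates,
#' pair assignment, UMI deduplication and profiling.
#'
#' @param r1,r2 mate sequences (character or `DNAStringSet`).
#' @param umi UMI per pair.
#' @param panel a [ReferencePanel].
#' @param prepId,dnase profile identity.
#' @param qual1,qual2 optional phred strings.
#' @param adapter 3' adapter (`NULL` skips trimming).
#' @param scoreMargin winning margin for [assignPairs()].
#' @param ... further arguments to [alignReads()].
#' @return list with the [SpeciesProfile] (`profile`), the per-pair
#'   `assignments` (with `kept` flag for dedup survivors), `qc` counters,
#'   and `raavAlignments`: deduplicated mate alignments on the rAAV
#'   record (`pos`, `aln_len`, `strand`, `seq` reference-oriented) for
#'   coverage and SNV analysis.
#' @export
classifyReads <- function(r1, r2, umi, panel, prepId = "prep",
                          dnase = FALSE, qual1 = NULL, qual2 = NULL,
                          adapter = defaultAdapter(), scoreMargin = 5, ...) {
  tf <- trimAndFilter(r1, r2, qual1, qual2, adapter = adapter)
  keepIdx <- which(tf$keep)
  if (length(keepIdx) == 0) stop("no read pairs survive QC")
  t1 <- tf$r1[keepIdx]; t2 <- tf$r2[keepIdx]
  h1 <- alignReads(t1, panel, ...)
  h2 <- alignReads(t2, panel, ...)
  asg <- assignPairs(h1, h2, panel, nPairs = length(keepIdx),
                     scoreMargin = scoreMargin)
  kept <- dedupUmi(asg, umi[keepIdx], r1 = t1)
  prof <- speciesProfile(asg[kept, , drop = FALSE], panel, prepId, dnase,
                         nQcRejected = tf$nRejected)
  # reference-oriented alignments on the rAAV record from kept pairs
  raavId <- names(refSequences(panel))[panel@species == "rAAV_genome"]
  collectMate <- function(h, seqs) {
    sel <- h$ref_id == raavId & h$read %in% which(kept) &
      asg$category[h$read] == "rAAV_genome"
    hh <- h[sel, , drop = FALSE]
    s <- seqs[hh$read]
    s[hh$strand == "-"] <- revcompChar(s[hh$strand == "-"])
    data.frame(pos = hh$pos, aln_len = hh$aln_len, strand = hh$strand,
               seq = s, stringsAsFactors = FALSE)
  }
  raav <- rbind(collectMate(h1, t1), collectMate(h2, t2))
  list(profile = prof,
       assignments = cbind(asg, kept = kept),
       qc = list(nInput = length(tf$keep), nRejected = tf$nRejected,
                 nPairs = length(keepIdx), nDedup = sum(kept),
                 nAmbiguous = nAmbiguous(prof)),
       raavAlignments = raav)
}

#' Triage unmapped reads against a secondary reference set
#'
#' Re-searches reads that mapped to no panel reference against a
#' user-supplied secondary FASTA panel (for example bacterial genomes
#' suspected as carryover). Hits are reported as an annex table and never
#' change the headline profile categories.
#'
#' @param reads unmapped mate-1 sequences.
#' @param secondary named `DNAStringSet` (or FASTA path) of candidate
#'   contaminant references.
#' @param k,minIdentity,minAlnLen,band aligner settings (laxer defaults
#'   than the panel aligner: the question is "what might this be", not a
#'   competitive assignment).
#' @return data.frame `read`, `ref_id`, `score`, `identity`.
#' @export
triageUnmapped <- function(reads, secondary, k = 21, minIdentity = 0.80,
                           minAlnLen = 40, band = 4) {
  if (is.character(secondary) && length(secondary) == 1 &&
      file.exists(secondary)) {
    secondary <- readDNAStringSet(secondary)
  }
  r <- asCharReads(reads)
  hits <- cpp_align_reads(as.character(secondary), r, as.integer(k),
                          as.integer(band), 1L, -4L, -6L, -1L, minIdentity,
                          as.integer(minAlnLen), 64L, 4L)
  data.frame(read = hits$read,
             ref_id = names(secondary)[hits$ref],
             score = hits$score, identity = hits$identity,
             stringsAsFactors = FALSE)
}

#' Write a species profile as a TSV table
#'
#' @param profile a [SpeciesProfile].
#' @param path output file.
#' @return `path` invisibly.
#' @export
writeProfile <- function(profile, path) {
  p <- percentages(profile)
  counts <- round(p * nTotalDedup(profile) / 100)
  df <- data.frame(category = names(p), count = counts, percent = p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##prep_id=%s\tdnase=%s\tn_total_dedup=%d\tn_ambiguous=%d",
                     profilePrepId(profile), profileDnase(profile),
                     nTotalDedup(profile), nAmbiguous(profile)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
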