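#' Assemble an unmasked reference record set
#'
#' Bundles reference sequences with their species labels and competitive
#' priorities into the input expected by [findSharedRegions()] and
#' [applyMasks()]. Records are a named [Biostrings::DNAStringSet] whose
#' `mcols` carry `species` and `priority`.
#'
#' @param sequences named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences.
#' @param species character vector of species labels, one per record, from
#'   [speciesLevels()].
#' @param priority integer ranks (1 = highest); defaults to
#'   [defaultPriorities()] looked up by species.
#' @return a [Biostrings::DNAStringSet] with `species` and `priority` mcols.
#' @export
referenceSet <- function(sequences, species, priority = NULL) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("reference sequences must carry unique names")
  if (length(species) != length(sequences))
    stop("one species label per record required")
  if (!all(species %in% SPECIES_LEVELS))
    stop("unknown species label: ",
         paste(setdiff(species, SPECIES_LEVELS), collapse = ", "))
  if (is.null(priority)) {
    priority <- unname(DEFAULT_PRIORITY[species])
    if (anyNA(priority))
      stop("no default priority for species: ",
           paste(species[is.na(priority)], collapse = ", "))
  }
  mcols(sequences) <- DataFrame(species = species,
                                priority = as.integer(priority))
  sequences
}

emptyMaskTable <- function() {
  DataFrame(target_ref = character(), start = integer(), end = integer(),
            source_ref = character(), identity = numeric(),
            length = integer())
}

#' Find homologous regions shared between reference records
#'
#' Detects local sequence homology between every pair of records by shared
#' k-mer seeding and ungapped x-drop extension, on both strands. Each
#' detected region is reported as an interval on the lower-priority record
#' of the pair (the record that will be masked), with overlapping intervals
#' from the same source merged.
#'
#' @param records a [referenceSet()] (named `DNAStringSet` with `species`
#'   and `priority` mcols).
#' @param maskMinLen minimum aligned length (bases) for a region to be
#'   reported; must be at least `kmerSize`.
#' @param maskMinIdentity minimum identity fraction over the aligned region.
#' @param kmerSize exact seed length for the homology search.
#' @param xdrop extension stops when the running score falls this far below
#'   its maximum (match +1 / mismatch -2).
#' @return [S4Vectors::DataFrame] with columns `target_ref`, `start`, `end`
#'   (0-based half-open on the target), `source_ref`, `identity`, `length`.
#' @export
findSharedRegions <- function(records, maskMinLen = 50,
                              maskMinIdentity = 0.90, kmerSize = 15,
                              xdrop = 16) {
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stop("duplicate or missing reference ids")
  if (maskMinLen < kmerSize)
    stop("maskMinLen must be at least the seed size kmerSize")
  prio <- mcols(records)$priority
  if (is.null(prio)) stop("records must carry a priority mcol; see referenceSet()")
  w <- BiocGenerics::width(records)
  usable <- w >= maskMinLen
  if (any(!usable))
    warning("skipping records shorter than maskMinLen: ",
            paste(ids[!usable], collapse = ", "))
  use <- which(usable)
  if (length(use) < 2) return(emptyMaskTable())
  out <- list()
  for (a in seq_along(use)) {
    for (b in seq_along(use)) {
      if (a >= b) next
      i <- use[a]; j <- use[b]
      # source = higher-priority member (smaller rank); ties broken by id
      # order so the masked member never depends on input permutation
      if (prio[i] < prio[j] || (prio[i] == prio[j] && ids[i] < ids[j])) {
        src <- i; tgt <- j
      } else {
        src <- j; tgt <- i
      }
      hits <- cpp_homology_pair(
        as.character(records[[src]]), as.character(records[[tgt]]),
        as.integer(kmerSize), as.integer(xdrop), as.integer(maskMinLen),
        maskMinIdentity
      )
      if (nrow(hits) == 0) next
      ir <- IRanges(start = hits$b_start + 1L, end = hits$b_end)
      red <- reduce(ir, with.revmap = TRUE)
      ident <- vapply(S4Vectors::mcols(red)$revmap, function(k) {
        max(hits$identity[k])
      }, numeric(1))
      keep <- BiocGenerics::width(red) >= maskMinLen
      if (!any(keep)) next
      out[[length(out) + 1L]] <- DataFrame(
        target_ref = ids[tgt],
        start = BiocGenerics::start(red)[keep] - 1L,
        end = BiocGenerics::end(red)[keep],
        source_ref = ids[src],
        identity = ident[keep],
        length = BiocGenerics::width(red)[keep]
      )
    }
  }
  if (length(out) == 0) return(emptyMaskTable())
  res <- do.call(rbind, out)
  res[order(res$target_ref, res$start), , drop = FALSE]
}

#' Apply mask intervals to reference records
#'
#' Replaces every masked position with `N` on the target record only;
#' source records are untouched and all other bases are byte-identical to
#' the input. Masking is idempotent.
#'
#' @param records a [referenceSet()].
#' @param masks mask intervals as produced by [findSharedRegions()].
#' @param kmerSize homology seed size recorded on the panel.
#' @return a [ReferencePanel].
#' @export
applyMasks <- function(records, masks, kmerSize = 15) {
  ids <- names(records)
  chars <- as.character(records)
  if (nrow(masks) > 0) {
    idx <- match(masks$target_ref, ids)
    if (anyNA(idx)) stop("mask target_ref not found among records")
    for (i in seq_len(nrow(masks))) {
      s <- masks$start[i]; e <- masks$end[i]
      if (s < 0 || s >= e || e > nchar(chars[idx[i]]))
        stop(sprintf("mask interval %d out of bounds on '%s'",
                     i, masks$target_ref[i]))
      substr(chars[idx[i]], s + 1L, e) <- strrep("N", e - s)
    }
  }
  seqs <- DNAStringSet(chars)
  names(seqs) <- ids
  new("ReferencePanel",
      sequences = seqs,
      species = mcols(records)$species,
      priority = mcols(records)$priority,
      masks = masks,
      kmerSize = as.integer(kmerSize))
}

#' Build a masked reference panel in one step
#'
#' Runs [findSharedRegions()] followed by [applyMasks()].
#'
#' @inheritParams findSharedRegions
#' @return a [ReferencePanel].
#' @export
buildReferencePanel <- function(records, maskMinLen = 50,
                                maskMinIdentity = 0.90, kmerSize = 15) {
  masks <- findSharedRegions(records, maskMinLen = maskMinLen,
                             maskMinIdentity = maskMinIdentity,
                             kmerSize = kmerSize)
  applyMasks(records, masks, kmerSize = kmerSize)
}

#' Write / read a reference panel
#'
#' `writePanel` stores the panel as `panel.fasta` (headers carry
#' `species=` and `priority=` tags) plus `masks.bed`, a 0-based half-open
#' BED-like TSV whose name field is `mask_from=<source>;id=<identity>`.
#' `readPanel` is its inverse; `readPanel(writePanel(p))` reproduces the
#' panel.
#'
#' @param panel a [ReferencePanel].
#' @param dir directory to write into (created if needed).
#' @return `writePanel` returns `dir` invisibly; `readPanel` returns a
#'   [ReferencePanel].
#' @export
writePanel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seqs <- refSequences(panel)
  hdr <- sprintf("%s species=%s priority=%d", names(seqs),
                 panel@species, panel@priority)
  tmp <- seqs
  names(tmp) <- hdr
  writeXStringSet(tmp, file.path(dir, "panel.fasta"))
  m <- as.data.frame(maskTable(panel))
  con <- file(file.path(dir, "masks.bed"), "w")
  on.exit(close(con))
  writeLines(sprintf("##kmer_size=%d", panelKmerSize(panel)), con)
  writeLines("#target\tstart\tend\tinfo", con)
  if (nrow(m) > 0) {
    writeLines(sprintf("%s\t%d\t%d\tmask_from=%s;id=%.4f",
                       m$target_ref, m$start, m$end, m$source_ref,
                       m$identity), con)
  }
  invisible(dir)
}

#' Parse one BED-like mask line
#'
#' @param line a single line `target<TAB>start<TAB>end<TAB>info` with
#'   `info` of the form `mask_from=<source>;id=<identity>`.
#' @param lineNo line number used in error messages.
#' @return list with `target_ref`, `start`, `end`, `source_ref`,
#'   `identity`.
#' @export
parseMaskLine <- function(line, lineNo = NA) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 4)
    stop(sprintf("malformed mask line %s: expected 4 tab-separated fields",
                 lineNo))
  start <- suppressWarnings(as.integer(f[2]))
  end <- suppressWarnings(as.integer(f[3]))
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop(sprintf("malformed mask line %s: bad coordinates", lineNo))
  kv <- strsplit(strsplit(f[4], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  tags <- setNames(
    vapply(kv, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1)),
    vapply(kv, `[`, character(1), 1)
  )
  if (!"mask_from" %in% names(tags) || is.na(tags[["mask_from"]]))
    stop(sprintf("malformed mask line %s: missing mask_from tag", lineNo))
  ident <- suppressWarnings(as.numeric(tags[["id"]]))
  if (is.na(ident))
    stop(sprintf("malformed mask line %s: missing or bad id tag", lineNo))
  list(target_ref = f[1], start = start, end = end,
       source_ref = tags[["mask_from"]], identity = ident)
}

#' @rdname writePanel
#' @export
readPanel <- function(dir) {
  fa <- file.path(dir, "panel.fasta")
  bed <- file.path(dir, "masks.bed")
  if (!file.exists(fa) || !file.exists(bed))
    stop("panel directory must contain panel.fasta and masks.bed")
  seqs <- readDNAStringSet(fa)
  hdr <- names(seqs)
  parts <- strsplit(hdr, " +")
  ids <- vapply(parts, `[`, character(1), 1)
  getTag <- function(p, tag) {
    hit <- grep(paste0("^", tag, "="), p, value = TRUE)
    if (length(hit) != 1)
      stop("malformed FASTA header (missing ", tag, "= tag): ",
           paste(p, collapse = " "))
    sub(paste0("^", tag, "="), "", hit)
  }
  species <- vapply(parts, getTag, character(1), tag = "species")
  priority <- as.integer(vapply(parts, getTag, character(1), tag = "priority"))
  names(seqs) <- ids
  lines <- readLines(bed)
  k <- 15L
  kline <- grep("^##kmer_size=", lines)
  if (length(kline)) k <- as.integer(sub("^##kmer_size=", "", lines[kline[1]]))
  body <- which(!startsWith(lines, "#"))
  masks <- emptyMaskTable()
  if (length(body)) {
    parsed <- lapply(body, function(i) parseMaskLine(lines[i], lineNo = i))
    masks <- DataFrame(
      target_ref = vapply(parsed, `[[`, character(1), "target_ref"),
      start = vapply(parsed, `[[`, integer(1), "start"),
      end = vapply(parsed, `[[`, integer(1), "end"),
      source_ref = vapply(parsed, `[[`, character(1), "source_ref"),
      identity = vapply(parsed, `[[`, numeric(1), "identity"),
      length = vapply(parsed, function(p) p$end - p$start, integer(1))
    )
  }
  new("ReferencePanel", sequences = seqs, species = species,
      priority = priority, masks = masks, kmerSize = k)
}
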