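#' ReferencePanel: a homology-masked, priority-ordered reference set
#'
#' Container for the multi-species reference sequences that reads are
#' competitively classified against. Homologous segments shared between two
#' records (ITRs, homology arms) have been replaced by `N` on the
#' lower-priority record, so every read from a shared region has a single,
#' deterministic owner.
#'
#' @slot sequences [Biostrings::DNAStringSet] of post-masking records; masked
#'   bases are `N`.
#' @slot species character vector, one of [speciesLevels()] per record.
#' @slot priority integer rank per record, 1 = highest.
#' @slot masks [S4Vectors::DataFrame] with columns `target_ref`, `start`,
#'   `end` (0-based half-open), `source_ref`, `identity`, `length`.
#' @slot kmerSize integer seed size used for the homology search.
#'
#' @export
setClass("ReferencePanel",
  slots = c(
    sequences = "DNAStringSet",
    species = "character",
    priority = "integer",
    masks = "DataFrame",
    kmerSize = "integer"
  )
)

setValidity("ReferencePanel", function(object) {
  msg <- character()
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "reference ids must be present and unique")
  if (length(object@species) != n || length(object@priority) != n)
    msg <- c(msg, "species and priority must have one entry per record")
  if (!all(object@species %in% SPECIES_LEVELS))
    msg <- c(msg, "unknown species label")
  if (sum(object@species == "rAAV_genome") != 1L)
    msg <- c(msg, "exactly one record must be the rAAV genome")
  if (any(BiocGenerics::width(object@sequences) < 1L))
    msg <- c(msg, "all sequences must have length >= 1")
  m <- object@masks
  if (nrow(m) > 0) {
    idx <- match(m$target_ref, ids)
    if (anyNA(idx)) {
      msg <- c(msg, "mask target_ref not found in panel")
    } else {
      for (i in seq_len(nrow(m))) {
        w <- BiocGenerics::width(object@sequences)[idx[i]]
        if (m$start[i] < 0 || m$start[i] >= m$end[i] || m$end[i] > w) {
          msg <- c(msg, sprintf("mask %d out of bounds", i))
          next
        }
        seg <- substr(as.character(object@sequences[[idx[i]]]),
                      m$start[i] + 1L, m$end[i])
        if (gsub("N", "", seg) != "")
          msg <- c(msg, sprintf("mask %d covers non-N bases", i))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferencePanel number of reference records
#' @param x,object a `ReferencePanel`
#' @export
setMethod("length", "ReferencePanel", function(x) length(x@sequences))

#' Accessors for ReferencePanel
#'
#' @param x a [ReferencePanel]
#' @return `refSequences` the masked [Biostrings::DNAStringSet];
#'   `refSpecies` named character vector of species labels; `refPriority`
#'   named integer priorities; `maskTable` the mask intervals as a
#'   [S4Vectors::DataFrame]; `panelKmerSize` the homology seed size.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
refSequences <- function(x) x@sequences

#' @rdname panel-accessors
#' @export
refSpecies <- function(x) setNames(x@species, names(x@sequences))

#' @rdname panel-accessors
#' @export
refPriority <- function(x) setNames(x@priority, names(x@sequences))

#' @rdname panel-accessors
#' @export
maskTable <- function(x) x@masks

#' @rdname panel-accessors
#' @export
panelKmerSize <- function(x) x@kmerSize

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf(
    "ReferencePanel with %d records, %d mask interval(s), k = %d\n",
    length(object), nrow(object@masks), object@kmerSize
  ))
  w <- BiocGenerics::width(object@sequences)
  for (i in seq_along(object@sequences)) {
    cat(sprintf(
      "  %-20s %-16s priority %d  %6d bp\n",
      names(object@sequences)[i], object@species[i], object@priority[i], w[i]
    ))
  }
})

#' PrepSpec: simulation ground truth for one rAAV preparation
#'
#' Describes a preparation as a mixture of DNA species together with the
#' fraction of each species that is packaged inside capsids (and therefore
#' protected from DNase) and the efficiency with which DNase destroys
#' extra-capsid molecules.
#'
#' @slot prepId character identifier.
#' @slot fractions named numeric, fraction of DNA molecules per species
#'   (including `foreign` for the unmapped bucket); sums to 1.
#' @slot encapsidated named numeric in `[0, 1]`, fraction of each species
#'   inside capsids. Species not named default to 0; the rAAV genome
#'   defaults to 1.
#' @slot dnaseEfficiency numeric in `[0, 1]`, fraction of extra-capsid
#'   molecules destroyed by DNase.
#'
#' @export
setClass("PrepSpec",
  slots = c(
    prepId = "character",
    fractions = "numeric",
    encapsidated = "numeric",
    dnaseEfficiency = "numeric"
  )
)

setValidity("PrepSpec", function(object) {
  msg <- character()
  f <- object@fractions
  if (is.null(names(f)) || !all(names(f) %in% SPECIES_LEVELS))
    msg <- c(msg, "fractions must be named with known species labels")
  if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1 (tolerance 1e-9)")
  if (any(f < 0)) msg <- c(msg, "fractions must be non-negative")
  e <- object@encapsidated
  if (length(e) && (is.null(names(e)) || !all(names(e) %in% SPECIES_LEVELS)))
    msg <- c(msg, "encapsidated must be named with known species labels")
  if (any(e < 0 | e > 1)) msg <- c(msg, "encapsidated must lie in [0, 1]")
  d <- object@dnaseEfficiency
  if (length(d) != 1 || d < 0 || d > 1)
    msg <- c(msg, "dnaseEfficiency must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a PrepSpec
#'
#' @param prepId character identifier for the preparation.
#' @param fractions named numeric vector of molecule fractions per species;
#'   must sum to 1.
#' @param encapsidated named numeric vector, fraction of each species inside
#'   capsids. Unnamed species default to 0 except the rAAV genome, which
#'   defaults to 1 (the vector genome is packaged).
#' @param dnaseEfficiency fraction of extra-capsid molecules destroyed by
#'   DNase treatment.
#' @return a [PrepSpec] object.
#' @export
PrepSpec <- function(prepId, fractions, encapsidated = numeric(),
                     dnaseEfficiency = 0.99) {
  full <- setNames(numeric(length(fractions)), names(fractions))
  full[] <- 0
  if ("rAAV_genome" %in% names(fractions)) full["rAAV_genome"] <- 1
  full[names(encapsidated)] <- encapsidated
  new("PrepSpec", prepId = prepId, fractions = fractions,
      encapsidated = full, dnaseEfficiency = dnaseEfficiency)
}

#' @rdname PrepSpec-class
#' @param x a `PrepSpec`
#' @export
prepFractions <- function(x) x@fractions

#' @rdname PrepSpec-class
#' @export
prepEncapsidated <- function(x) x@encapsidated

#' @rdname PrepSpec-class
#' @export
prepDnaseEfficiency <- function(x) x@dnaseEfficiency

#' @rdname PrepSpec-class
#' @export
prepId <- function(x) x@prepId

setMethod("show", "PrepSpec", function(object) {
  cat(sprintf("PrepSpec '%s' (DNase efficiency %.3g)\n",
              object@prepId, object@dnaseEfficiency))
  for (s in names(object@fractions)) {
    cat(sprintf("  %-18s %7.3f%%  encapsidated %.2f\n", s,
                100 * object@fractions[s], object@encapsidated[s]))
  }
})

#' SpeciesProfile: percentage decomposition of one sequenced prep
#'
#' The per-species percentages of deduplicated read pairs for one
#' preparation under one DNase condition -- the row set of a published
#' decomposition table. Ambiguous pairs (two species within the score
#' margin) are folded into `unmapped` for the headline percentages and
#' retained in `nAmbiguous`.
#'
#' @slot prepId character.
#' @slot dnase logical, whether the prep was DNase treated.
#' @slot percentages named numeric over all panel species plus `unmapped`;
#'   sums to 100.
#' @slot nTotalDedup integer, deduplicated pairs in the denominator.
#' @slot nAmbiguous integer, pairs ambiguous between species.
#' @slot nQcRejected integer, pairs removed before mapping (not in the
#'   denominator).
#'
#' @export
setClass("SpeciesProfile",
  slots = c(
    prepId = "character",
    dnase = "logical",
    percentages = "numeric",
    nTotalDedup = "integer",
    nAmbiguous = "integer",
    nQcRejected = "integer"
  )
)

setValidity("SpeciesProfile", function(object) {
  msg <- character()
  p <- object@percentages
  if (is.null(names(p)) || !"unmapped" %in% names(p))
    msg <- c(msg, "percentages must be named and include 'unmapped'")
  if (abs(sum(p) - 100) > 0.01)
    msg <- c(msg, "percentages must sum to 100 (tolerance 0.01)")
  if (any(p < 0)) msg <- c(msg, "percentages must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname SpeciesProfile-class
#' @param x a `SpeciesProfile`
#' @export
percentages <- function(x) x@percentages

#' @rdname SpeciesProfile-class
#' @export
profileDnase <- function(x) x@dnase

#' @rdname SpeciesProfile-class
#' @export
profilePrepId <- function(x) x@prepId

#' @rdname SpeciesProfile-class
#' @export
nTotalDedup <- function(x) x@nTotalDedup

#' @rdname SpeciesProfile-class
#' @export
nAmbiguous <- function(x) x@nAmbiguous

setMethod("show", "SpeciesProfile", function(object) {
  cat(sprintf("SpeciesProfile '%s' %sDNase (%d deduplicated pairs, %d ambiguous)\n",
              object@prepId, if (object@dnase) "+" else "-",
              object@nTotalDedup, object@nAmbiguous))
  p <- object@percentages
  for (s in names(p)) cat(sprintf("  %-18s %7.2f%%\n", s, p[s]))
})

#' CoverageTrack: per-base coverage over the vector genome
#'
#' Raw per-base counts of deduplicated read alignments and the
#' depth-normalized track: each base's count scaled so that the whole track
#' sums to 1,000, making preps comparable regardless of sequencing depth.
#'
#' @slot refId character, reference the track is computed on.
#' @slot raw numeric per-base alignment counts.
#' @slot normalized numeric, `1000 * raw / sum(raw)` (all zero when no read
#'   maps).
#'
#' @export
setClass("CoverageTrack",
  slots = c(refId = "character", raw = "numeric", normalized = "numeric")
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@raw) != length(object@normalized))
    msg <- c(msg, "raw and normalized must have equal length")
  tot <- sum(object@raw)
  if (tot > 0) {
    if (abs(sum(object@normalized) - 1000) > 1e-6)
      msg <- c(msg, "normalized track must sum to 1000 (tolerance 1e-6)")
    if (max(abs(object@normalized - 1000 * object@raw / tot)) > 1e-6)
      msg <- c(msg, "normalized must equal 1000 * raw / sum(raw)")
  } else if (any(object@normalized != 0)) {
    msg <- c(msg, "normalized must be all zero when raw coverage is zero")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CoverageTrack-class
#' @param x a `CoverageTrack`
#' @export
rawCoverage <- function(x) x@raw

#' @rdname CoverageTrack-class
#' @export
normalizedCoverage <- function(x) x@normalized

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack on '%s': %d bases, total raw %g, mean depth %.2f\n",
              object@refId, length(object@raw), sum(object@raw),
              mean(object@raw)))
})
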