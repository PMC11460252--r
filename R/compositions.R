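# Published percentage decompositions of rAAV preparations characterized
# by SSV-seq, used as realistic simulation presets and as direct inputs to
# the DNase localization analysis.

#' Reference prep compositions (published SSV-seq decompositions)
#'
#' Percentage decompositions of six rAAV6 preparations -- four packaged by
#' triple transfection of HEK293T cells and two by baculovirus infection
#' of Sf9 insect cells -- each sequenced with and without DNase
#' pretreatment. The producer-cell genome row (human or Sf9) is labelled
#' `producer_genome`; the unmapped row is labelled `foreign` so the table
#' can be used directly as simulation ground truth.
#'
#' @return data.frame in long format: `prep_id`, `system`, `dnase`
#'   (logical), `species`, `percent`. Columns of one prep/condition sum to
#'   ~100 (printed rounding).
#' @export
prepCompositions <- function() {
  hek <- list(
    # prep      -DNase                                         +DNase
    AAV1 = list(m = c(1.08, 86.41, 1.55, 0.21, 0.33, 1.06, 9.56),
                p = c(1.18, 85.36, 1.25, 0.21, 0.35, 0.97, 10.38)),
    AAV2 = list(m = c(45.02, 26.42, 1.24, 0.65, 0.24, 2.13, 24.40),
                p = c(83.91, 8.64, 1.17, 0.83, 0.16, 0.87, 4.43)),
    AAV5 = list(m = c(69.26, 0.47, 3.27, 0.47, 0.17, 1.79, 24.58),
                p = c(84.15, 0.48, 3.64, 0.52, 0.18, 1.47, 9.57)),
    AAV6 = list(m = c(68.22, 1.97, 3.01, 2.77, 0.16, 2.33, 21.54),
                p = c(88.11, 0.39, 4.28, 3.94, 0.25, 0.67, 2.36))
  )
  hekSpecies <- c("rAAV_genome", "producer_genome", "helper_plasmid",
                  "plasmid_backbone", "repcap_plasmid", "ecoli_genome",
                  "foreign")
  sf9 <- list(
    AAV3 = list(m = c(80.75, 0.07, 0.20, 0.77, 0.005, 0.73, 17.48),
                p = c(91.99, 0.052, 0.15, 0.68, 0.002, 0.61, 6.51)),
    AAV4 = list(m = c(95.67, 0.22, 0.29, 0.13, 0.0052, 0.83, 2.85),
                p = c(94.85, 0.20, 0.42, 0.16, 0.0066, 0.47, 3.89))
  )
  sf9Species <- c("rAAV_genome", "producer_genome", "baculovirus",
                  "plasmid_backbone", "repcap_plasmid", "ecoli_genome",
                  "foreign")
  rows <- list()
  addSystem <- function(tbl, species, system) {
    for (prep in names(tbl)) {
      for (cond in c("m", "p")) {
        rows[[length(rows) + 1L]] <<- data.frame(
          prep_id = prep, system = system, dnase = cond == "p",
          species = species, percent = tbl[[prep]][[cond]],
          stringsAsFactors = FALSE)
      }
    }
  }
  addSystem(hek, hekSpecies, "HEK293T")
  addSystem(sf9, sf9Species, "Sf9")
  do.call(rbind, rows)
}

#' Molecule fractions for one published prep/condition
#'
#' Extracts one prep x DNase column of [prepCompositions()] and rescales
#' it to sum exactly to 1, for use as [PrepSpec] fractions.
#'
#' @param prep prep identifier (`"AAV1"` ... `"AAV6"`).
#' @param dnase logical, the DNase-treated column.
#' @return named numeric fractions summing to 1.
#' @export
compositionFractions <- function(prep, dnase = FALSE) {
  tbl <- prepCompositions()
  sel <- tbl[tbl$prep_id == prep & tbl$dnase == dnase, ]
  if (nrow(sel) == 0) stop("unknown prep: ", prep)
  setNames(sel$percent / sum(sel$percent), sel$species)
}
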