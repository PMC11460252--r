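# Differential +/-DNase analysis: per-species susceptibility relative to
# the protected vector genome, and intra- vs extra-capsid verdicts.

#' Localize contaminants inside or outside the capsid from a +/-DNase pair
#'
#' DNase destroys DNA outside capsids, so removing extra-capsid species
#' mechanically inflates every surviving species' raw percentage. Ratios
#' are therefore taken relative to the rAAV genome share (which is fully
#' protected): `ratio = species% / rAAV%` in each condition, and
#' `log2_change = log2(ratio_plus / ratio_minus)`. A species whose
#' rAAV-normalized share drops at least two-fold (`log2_change <= -1`) is
#' called `extra_capsid`; a change within two-fold (`|log2_change| < 1`)
#' is `intra_capsid`; anything else -- either share below `floor` in
#' either condition, or a relative increase of two-fold or more -- is
#' `indeterminate`.
#'
#' @param profileMinus,profilePlus the two conditions of one prep, as
#'   [SpeciesProfile] objects or plain named percentage vectors (for
#'   example columns of a published decomposition table; the ratios cancel
#'   any global renormalization, so the vectors need not sum to exactly
#'   100).
#' @param floor percentage below which a species share is treated as
#'   unobserved (ratio undefined).
#' @return data.frame with `species`, `ratio_minus`, `ratio_plus`,
#'   `log2_change`, `verdict`.
#' @export
localize <- function(profileMinus, profilePlus, floor = 0.01) {
  pm <- asPercentages(profileMinus)
  pp <- asPercentages(profilePlus)
  if (is(profileMinus, "SpeciesProfile") && is(profilePlus, "SpeciesProfile")) {
    if (profilePrepId(profileMinus) != profilePrepId(profilePlus))
      stop("profiles must come from the same prep")
    if (profileDnase(profileMinus) || !profileDnase(profilePlus))
      stop("expected a -DNase profile and a +DNase profile, in that order")
  }
  species <- union(names(pm), names(pp))
  species <- setdiff(species, "rAAV_genome")
  pm <- pm[species]; pp <- pp[species]
  pm[is.na(pm)] <- 0; pp[is.na(pp)] <- 0
  pmFull <- asPercentages(profileMinus)
  ppFull <- asPercentages(profilePlus)
  if (!"rAAV_genome" %in% names(pmFull) || !"rAAV_genome" %in% names(ppFull))
    stop("both profiles must report an rAAV_genome percentage")
  rm0 <- pmFull[["rAAV_genome"]]
  rp0 <- ppFull[["rAAV_genome"]]
  if (rm0 == 0 || rp0 == 0)
    stop("rAAV genome percentage must be non-zero in both profiles")
  ratioMinus <- pm / rm0
  ratioPlus <- pp / rp0
  log2Change <- log2(ratioPlus / ratioMinus)
  verdict <- ifelse(pm < floor | pp < floor, "indeterminate",
             ifelse(log2Change <= -1, "extra_capsid",
             ifelse(abs(log2Change) < 1, "intra_capsid", "indeterminate")))
  log2Change[pm < floor | pp < floor] <- NA_real_
  data.frame(species = species,
             ratio_minus = unname(ratioMinus),
             ratio_plus = unname(ratioPlus),
             log2_change = unname(log2Change),
             verdict = unname(verdict),
             stringsAsFactors = FALSE)
}

asPercentages <- function(x) {
  if (is(x, "SpeciesProfile")) percentages(x)
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("expected a SpeciesProfile or a named numeric percentage vector")
}

#' Verify the lambda spike-in digestion control
#'
#' The spike-in is naked DNA added to both reaction conditions; a working
#' DNase reaction leaves at most `maxSurvival` of the untreated molecule
#' count in the treated aliquot.
#'
#' @param countMinus,countPlus lambda molecule counts in the -DNase and
#'   +DNase control runs.
#' @param maxSurvival maximum surviving fraction for a pass.
#' @return `"pass"` or `"fail"`.
#' @export
spikeQC <- function(countMinus, countPlus, maxSurvival = 0.01) {
  if (countMinus == 0) stop("-DNase lambda count is zero; control invalid")
  if (countPlus <= maxSurvival * countMinus) "pass" else "fail"
}

#' Write localization calls as TSV
#' @param calls data.frame from [localize()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
writeLocalization <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
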