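# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

panelRecords <- function(refs) {
  refs[S4Vectors::mcols(refs)$species != "foreign"]
}

# view a masked panel as a record set usable by findSharedRegions()
refSequencesAsRecords <- function(panel) {
  s <- refSequences(panel)
  S4Vectors::mcols(s) <- S4Vectors::DataFrame(
    species = unname(refSpecies(panel)),
    priority = unname(refPriority(panel)))
  s
}

# full-size synthetic reference set + masked panel (the study conditions)
fixtureRefs <- function() memo("refs", buildSyntheticReferences(seed = 101))
fixturePanel <- function() {
  memo("panel", buildReferencePanel(panelRecords(fixtureRefs())))
}

# scaled-down reference set for exhaustive-alignment oracle comparisons
smallSizes <- function() {
  c(producer_genome = 4000, rAAV_genome = 4700, plasmid_backbone = 3000,
    helper_plasmid = 1500, repcap_plasmid = 1500, ecoli_genome = 2000,
    baculovirus = 1500, lambda_spike = 1500, foreign = 1500)
}
fixtureSmallRefs <- function() {
  memo("smallRefs", buildSyntheticReferences(seed = 202, sizes = smallSizes()))
}
fixtureSmallPanel <- function() {
  memo("smallPanel", buildReferencePanel(panelRecords(fixtureSmallRefs())))
}

# a prep with the mixed composition of a characteristic "dirty" prep
fixturePrep <- function() {
  PrepSpec("AAV2", compositionFractions("AAV2", dnase = FALSE),
           encapsidated = c(rAAV_genome = 1, helper_plasmid = 0.9,
                            plasmid_backbone = 0.9, repcap_plasmid = 0.9,
                            producer_genome = 0.05, ecoli_genome = 0.1,
                            foreign = 0.05),
           dnaseEfficiency = 0.99)
}

# random DNA string helper for ad-hoc cases
rdna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence by substitution at given 1-based positions
mutateAt <- function(seq, pos) {
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seq
}

# percentages of a printed prep/condition column, named by species
printedColumn <- function(prep, dnase) {
  tbl <- prepCompositions()
  sel <- tbl[tbl$prep_id == prep & tbl$dnase == dnase, ]
  stats::setNames(sel$percent, sel$species)
}

# expected percentages after classification: printed fractions adjusted for
# reads that cross mask boundaries is not modelled; plain renormalized truth
expectedPercents <- function(prep, dnase) {
  100 * compositionFractions(prep, dnase)
}
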