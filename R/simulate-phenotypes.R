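# Synthetic phenotype generator: CFU plates, viability trajectories and
# qPCR Ct tables with known ground truth, for validating the downstream
# phenotype analysis.

#' Default effect model for phenotype simulation
#'
#' The clonogenicity model is linear: expected %CFU per plated cell is
#' `intercept + slope * purity` (purity = %rAAV genome of the prep), with
#' Gaussian condition-by-donor noise. Plates follow the dilution series
#' 300/100/25 cells in duplicate; colony counts are Poisson around the
#' expected colony number and are split across morphology classes
#' multinomially. Ct values are Gaussian around
#' `baseCt - log2(fold change)` with an invariant beta-actin reference.
#'
#' @return list of model parameters (see source for fields).
#' @export
defaultEffectModel <- function() {
  list(
    slope = 0.2,           # %CFU gained per %rAAV purity
    intercept = 5,         # %CFU at zero purity
    noiseSd = 2,           # sd of condition x donor %CFU noise
    platedCells = c(300L, 100L, 25L),
    nReplicates = 2L,      # duplicate plates per dilution
    nDonors = 3L,
    classProbs = c(BFU_E = 0.25, CFU_E = 0.30, CFU_GM = 0.25,
                   CFU_G = 0.10, CFU_M = 0.07, CFU_GEMM = 0.03),
    genes = c("FAS", "CDKN1A", "BAX", "TNFA", "TP53", "IFNB1", "IL6",
              "CASP3", "CCND1", "OAS1", "MKI67"),
    baseCt = 24,           # mean target-gene Ct in the mock condition
    actbCt = 18,           # beta-actin Ct, invariant across conditions
    ctSd = 0.1,            # technical Ct noise sd
    nTechReps = 3L,
    # per-gene sensitivity: log2 fold change per percentage point of
    # contamination (100 - purity); stress/apoptosis genes respond most
    geneSensitivity = c(FAS = 0.02, CDKN1A = 0.02, BAX = 0.015,
                        TNFA = 0.015, TP53 = 0.01, IFNB1 = 0.02,
                        IL6 = 0.015, CASP3 = 0.01, CCND1 = -0.005,
                        OAS1 = 0.015, MKI67 = -0.01),
    viability = list(mockBase = 90, contaminantEffect = 30,
                     dayRecovery = 2, sd = 3, days = c(1L, 3L, 5L))
  )
}

#' Colony morphology classes of the CFU assay
#'
#' Erythroid (BFU-E, CFU-E), myeloid (CFU-GM, CFU-G, CFU-M) and mixed
#' (CFU-GEMM) colony classes, as column names used in CFU plate tables.
#'
#' @return character vector of class column names.
#' @export
morphologyClasses <- function() {
  c("BFU_E", "CFU_E", "CFU_GM", "CFU_G", "CFU_M", "CFU_GEMM")
}

#' Simulate CFU, viability and qPCR tables with known ground truth
#'
#' @param purityByPrep named numeric: %rAAV genome purity per condition
#'   (condition names become `condition_id`). A `mock` condition (purity
#'   irrelevant, fold changes 1) is added automatically for the qPCR table.
#' @param effectModel list as produced by [defaultEffectModel()].
#' @param seed integer RNG seed.
#' @return list with data.frames `cfu` (condition_id, donor, cells_plated,
#'   replicate, one column per morphology class), `viability`
#'   (condition_id, donor, day, viability), `ct` (sample_id, condition_id,
#'   gene, rep, ct), and `truth` (the generating parameters, including the
#'   per-gene, per-condition fold-change matrix).
#' @export
simulatePhenotypes <- function(purityByPrep, effectModel = defaultEffectModel(),
                               seed = 1) {
  set.seed(seed)
  m <- effectModel
  conds <- names(purityByPrep)
  stopifnot(length(conds) > 0)
  cls <- names(m$classProbs)

  # --- CFU plates -----------------------------------------------------
  cfu <- list()
  clipped <- FALSE
  for (cond in conds) {
    for (donor in seq_len(m$nDonors)) {
      expPct <- m$intercept + m$slope * purityByPrep[[cond]] +
        rnorm(1, 0, m$noiseSd)
      if (expPct < 0) { expPct <- 0; clipped <- TRUE }
      for (cells in m$platedCells) {
        for (rep in seq_len(m$nReplicates)) {
          total <- rpois(1, cells * expPct / 100)
          split <- as.vector(rmultinom(1, total, m$classProbs))
          row <- data.frame(condition_id = cond, donor = donor,
                            cells_plated = cells, replicate = rep,
                            stringsAsFactors = FALSE)
          row[cls] <- as.list(split)
          cfu[[length(cfu) + 1L]] <- row
        }
      }
    }
  }
  if (clipped) warning("negative expected colony numbers clipped at 0")
  cfu <- do.call(rbind, cfu)

  # --- viability trajectories ----------------------------------------
  v <- m$viability
  viability <- expand.grid(condition_id = conds,
                           donor = seq_len(m$nDonors), day = v$days,
                           stringsAsFactors = FALSE)
  contam <- (100 - unlist(purityByPrep)[viability$condition_id]) / 100
  viability$viability <- pmin(pmax(
    v$mockBase - v$contaminantEffect * contam +
      v$dayRecovery * (viability$day - 1) + rnorm(nrow(viability), 0, v$sd),
    0), 100)

  # --- qPCR Ct values -------------------------------------------------
  ctConds <- c("mock", conds)
  fold <- matrix(1, nrow = length(m$genes), ncol = length(ctConds),
                 dimnames = list(m$genes, ctConds))
  for (cond in conds) {
    contamPct <- 100 - purityByPrep[[cond]]
    fold[, cond] <- 2^(m$geneSensitivity[m$genes] * contamPct)
  }
  ct <- list()
  for (cond in ctConds) {
    for (donor in seq_len(m$nDonors)) {
      sid <- sprintf("%s_d%d", cond, donor)
      for (g in m$genes) {
        ct[[length(ct) + 1L]] <- data.frame(
          sample_id = sid, condition_id = cond, gene = g,
          rep = seq_len(m$nTechReps),
          ct = m$baseCt - log2(fold[g, cond]) +
            rnorm(m$nTechReps, 0, m$ctSd),
          stringsAsFactors = FALSE)
      }
      ct[[length(ct) + 1L]] <- data.frame(
        sample_id = sid, condition_id = cond, gene = "ACTB",
        rep = seq_len(m$nTechReps),
        ct = m$actbCt + rnorm(m$nTechReps, 0, m$ctSd),
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, ct)

  list(cfu = cfu, viability = viability, ct = ct,
       truth = list(slope = m$slope, intercept = m$intercept,
                    noiseSd = m$noiseSd, foldChanges = fold,
                    purity = unlist(purityByPrep)))
}
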