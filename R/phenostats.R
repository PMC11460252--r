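# Downstream phenotype analysis: CFU clonogenicity, lineage proportions,
# purity-clonogenicity regression, delta-delta-Ct fold changes and group
# comparisons with significance stars.

#' Percent CFUs per plated cell
#'
#' Per plate, `100 * total colonies / cells plated`; the condition value
#' is the mean over its plates.
#'
#' @param plates data.frame with columns `condition_id`, `cells_plated`,
#'   `replicate` and one column per morphology class (`BFU_E`, `CFU_E`,
#'   `CFU_GM`, `CFU_G`, `CFU_M`, `CFU_GEMM`).
#' @return data.frame with `condition_id`, `pct_cfu` (condition mean) and
#'   `n_plates`; the per-plate values are attached as attribute
#'   `per_plate`.
#' @export
cfuPercent <- function(plates) {
  stopifnot(nrow(plates) >= 1)
  cls <- intersect(morphologyClasses(), colnames(plates))
  if (length(cls) == 0) stop("no morphology class columns found")
  total <- rowSums(plates[, cls, drop = FALSE])
  perPlate <- data.frame(condition_id = plates$condition_id,
                         replicate = plates$replicate,
                         cells_plated = plates$cells_plated,
                         pct_cfu = 100 * total / plates$cells_plated,
                         stringsAsFactors = FALSE)
  agg <- aggregate(pct_cfu ~ condition_id, data = perPlate, FUN = mean)
  agg$n_plates <- as.vector(table(perPlate$condition_id)[agg$condition_id])
  attr(agg, "per_plate") <- perPlate
  agg
}

#' Erythroid versus myeloid progenitor proportions
#'
#' Erythroid = BFU-E + CFU-E; myeloid = CFU-GM + CFU-G + CFU-M. Mixed
#' CFU-GEMM colonies belong to neither lineage and are reported
#' separately; percentages are taken over erythroid + myeloid only.
#'
#' @inheritParams cfuPercent
#' @return data.frame with `condition_id`, `erythroid_pct`,
#'   `myeloid_pct`, `gemm_count`.
#' @export
lineageProportions <- function(plates) {
  need <- c("BFU_E", "CFU_E", "CFU_GM", "CFU_G", "CFU_M")
  missing <- setdiff(need, colnames(plates))
  if (length(missing))
    stop("missing class columns: ", paste(missing, collapse = ", "))
  gemmCol <- if ("CFU_GEMM" %in% colnames(plates)) plates$CFU_GEMM else 0
  df <- data.frame(condition_id = plates$condition_id,
                   ery = plates$BFU_E + plates$CFU_E,
                   mye = plates$CFU_GM + plates$CFU_G + plates$CFU_M,
                   gemm = gemmCol, stringsAsFactors = FALSE)
  agg <- aggregate(cbind(ery, mye, gemm) ~ condition_id, data = df,
                   FUN = sum)
  tot <- agg$ery + agg$mye
  if (any(tot == 0)) stop("zero classified colonies for condition(s): ",
                          paste(agg$condition_id[tot == 0], collapse = ", "))
  data.frame(condition_id = agg$condition_id,
             erythroid_pct = 100 * agg$ery / tot,
             myeloid_pct = 100 * agg$mye / tot,
             gemm_count = agg$gemm,
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression of clonogenicity on vector purity
#'
#' Fits `%CFU ~ %rAAV genome` by OLS; the p value is the two-sided t test
#' on the slope.
#'
#' @param purity percent rAAV genome per point.
#' @param pctCfu percent CFUs per plated cell per point.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   and `ci` (95% confidence interval of the slope).
#' @export
purityCfuRegression <- function(purity, pctCfu) {
  stopifnot(length(purity) == length(pctCfu))
  n <- length(purity)
  if (n < 3) stop("at least 3 points required")
  if (length(unique(purity)) < 2) stop("purity values are constant")
  fit <- lm(pctCfu ~ purity)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = n,
       ci = unname(confint(fit, "purity", level = 0.95))[1, ])
}

#' Delta-delta-Ct relative expression fold change
#'
#' Technical replicate Cts are averaged first; then
#' `dCt = Ct_target - Ct_reference` per condition,
#' `ddCt = dCt_condition - dCt_mock`, fold change `2^(-ddCt)`, i.e.
#' expression normalized to the housekeeping reference gene and to a mock
#' control.
#'
#' @param targetCt,refCt Ct replicates of the target and reference
#'   (beta-actin) gene in the condition of interest.
#' @param mockTargetCt,mockRefCt the same two genes in the mock control.
#' @return fold change (numeric scalar).
#' @export
ddctFoldChange <- function(targetCt, refCt, mockTargetCt, mockRefCt) {
  for (v in list(targetCt, refCt, mockTargetCt, mockRefCt)) {
    if (length(v) == 0 || anyNA(v))
      stop("all four Ct records must be present and complete")
  }
  dct <- mean(targetCt) - mean(refCt)
  dctMock <- mean(mockTargetCt) - mean(mockRefCt)
  2^(-(dct - dctMock))
}

#' Fold changes per gene x condition from a long Ct table
#'
#' Applies [ddctFoldChange()] per (gene, condition, donor) against the
#' matching donor's mock sample and averages over donors.
#'
#' @param ct data.frame with columns `sample_id`, `condition_id`, `gene`,
#'   `ct` (one row per technical replicate).
#' @param mockCondition name of the mock condition.
#' @param refGene housekeeping reference gene.
#' @return matrix of mean fold changes, genes x non-mock conditions.
#' @export
foldChangeMatrix <- function(ct, mockCondition = "mock", refGene = "ACTB") {
  if (!refGene %in% ct$gene)
    stop("reference gene '", refGene, "' missing from Ct table")
  conds <- setdiff(unique(ct$condition_id), mockCondition)
  genes <- setdiff(unique(ct$gene), refGene)
  donorOf <- function(sid) sub(".*_d", "", sid)
  ct$donor <- donorOf(ct$sample_id)
  get <- function(cond, gene, donor) {
    ct$ct[ct$condition_id == cond & ct$gene == gene & ct$donor == donor]
  }
  out <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
  for (cond in conds) {
    for (g in genes) {
      donors <- unique(ct$donor[ct$condition_id == cond])
      folds <- vapply(donors, function(d) {
        tc <- get(cond, g, d); rc <- get(cond, refGene, d)
        mt <- get(mockCondition, g, d); mr <- get(mockCondition, refGene, d)
        if (!length(rc) || !length(mr))
          stop("missing beta-actin record for condition ", cond,
               " donor ", d)
        if (!length(tc) || !length(mt)) return(NA_real_)
        ddctFoldChange(tc, rc, mt, mr)
      }, numeric(1))
      out[g, cond] <- mean(folds)
    }
  }
  out
}

#' Welch two-sample comparison with significance stars
#'
#' Welch's unequal-variance t test; stars follow the thresholds
#' `* p < 0.05`, `** p < 0.01`, `*** p < 0.0005`, `**** p < 0.0001`.
#' Two groups with zero variance and equal means compare at `p = 1`.
#'
#' @param a,b numeric vectors, each of length at least 2.
#' @return list with `p_value`, `stars`, `mean_a`, `mean_b`.
#' @export
groupCompare <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    p <- t.test(a, b, var.equal = FALSE)$p.value
  }
  stars <- if (p < 0.0001) "****" else if (p < 0.0005) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(p_value = p, stars = stars, mean_a = mean(a), mean_b = mean(b))
}

#' Log2 fold-change matrix for heatmap rendering
#'
#' @param folds complete fold-change matrix (genes x conditions), e.g.
#'   from [foldChangeMatrix()].
#' @return log2-transformed matrix with the input dimnames.
#' @export
expressionHeatmapTable <- function(folds) {
  if (anyNA(folds)) {
    bad <- which(is.na(folds), arr.ind = TRUE)
    stop("missing fold-change cells: ",
         paste(sprintf("%s x %s", rownames(folds)[bad[, 1]],
                       colnames(folds)[bad[, 2]]), collapse = ", "))
  }
  log2(folds)
}

#' Write / read a labelled numeric matrix as TSV
#'
#' @param m matrix with row and column names.
#' @param path file path.
#' @return `writeMatrixTsv` returns `path` invisibly; `readMatrixTsv`
#'   returns the matrix.
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Viability summary (descriptive)
#'
#' Means and standard deviations per condition and day; the +/-DNase
#' viability contrast is reported descriptively, without a significance
#' test.
#'
#' @param viability data.frame with `condition_id`, `donor`, `day`,
#'   `viability`.
#' @return data.frame with `condition_id`, `day`, `mean`, `sd`, `n`.
#' @export
viabilitySummary <- function(viability) {
  agg <- aggregate(viability ~ condition_id + day, data = viability,
                   FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                       n = length(x)))
  data.frame(condition_id = agg$condition_id, day = agg$day,
             mean = agg$viability[, "mean"], sd = agg$viability[, "sd"],
             n = agg$viability[, "n"], stringsAsFactors = FALSE)
}
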