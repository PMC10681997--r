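# Niche-resolved statistics on fragment pseudobulks: zonated-gene
# detection with an ordered-factor covariate, two-group differential
# expression, cell-type abundance testing, and bias/robustness helpers.
#
# Models are negative-binomial generalized log-linear fits with
# quasi-likelihood F-tests (edgeR); sample identity always enters as a
# fixed-effect blocking factor.

de_table <- function(fit_test, extra = NULL) {
  tt <- edgeR::topTags(fit_test, n = Inf, sort.by = "none")$table
  out <- data.frame(gene = rownames(tt), coef = tt$logFC, p = tt$PValue,
                    fdr = stats::p.adjust(tt$PValue, method = "BH"),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra[out$gene, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("DEResult", "data.frame")
  out
}

group_means_cpm <- function(counts, groups) {
  cpm <- edgeR::cpm(counts, log = FALSE)
  sapply(levels(groups), function(g)
    rowMeans(cpm[, groups == g, drop = FALSE]))
}

#' Remove lowly expressed genes from a pseudobulk
#'
#' Keeps genes with at least `min_count` counts in at least `min_prop` of
#' the smallest design group's samples (edgeR's `filterByExpr` heuristic).
#'
#' @param pseudobulk Fragments x genes count matrix (sum mode).
#' @param groups Per-fragment design groups driving the smallest-group
#'   size.
#' @param min_count,min_prop Filter parameters (defaults 10 and 0.7).
#' @return The pseudobulk restricted to kept genes (warning when empty).
#' @export
filter_low_expression <- function(pseudobulk, groups,
                                  min_count = 10, min_prop = 0.7) {
  keep <- edgeR::filterByExpr(t(pseudobulk), group = groups,
                              min.count = min_count, min.prop = min_prop)
  if (!any(keep)) warning("filter_low_expression: no gene passes the filter")
  pseudobulk[, keep, drop = FALSE]
}

ql_de <- function(counts, design, coef_name, groups_for_means) {
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qt <- edgeR::glmQLFTest(fit, coef = coef_name)
  de_table(qt, extra = group_means_cpm(counts, groups_for_means))
}

#' Detect zonated genes with an ordered lobule-layer covariate
#'
#' Fits a negative-binomial log-linear model per gene with the lobule
#' layer as an ordered factor encoded as equally spaced numeric scores
#' (L1-L3 < L4 < L5 < L6 < L7 < L8-L10 when extremes are merged) and the
#' sample as a blocking factor, then tests the layer coefficient with a
#' quasi-likelihood F-test. Genes are significant at a
#' Benjamini-Hochberg adjusted p below 0.05.
#'
#' @param pseudobulk Fragments x genes sum-mode pseudobulk (fragments with
#'   at least 5 cells of the type of interest).
#' @param layers Ordered factor (or character coercible to one) of layer
#'   labels per fragment.
#' @param sample_ids Sample id per fragment.
#' @param filter Apply [filter_low_expression()] first (default `TRUE`).
#' @return A `DEResult` data frame: `gene`, `coef` (log2 change per layer
#'   step), `p`, `fdr`, and mean counts-per-million per layer level.
#' @export
zonated_de <- function(pseudobulk, layers, sample_ids, filter = TRUE) {
  if (any(pseudobulk != floor(pseudobulk)))
    stop("zonated_de: pseudobulk must hold raw summed counts")
  layers <- if (is.ordered(layers)) droplevels(layers) else
    factor(layers, levels = unique(sort(as.character(layers))),
           ordered = TRUE)
  if (nlevels(layers) < 2)
    stop("zonated_de: need at least 2 layer levels")
  score <- as.numeric(layers)          # equally spaced 1..K
  sample_f <- factor(sample_ids)
  design <- if (nlevels(sample_f) > 1)
    stats::model.matrix(~ sample_f + score) else
      stats::model.matrix(~ score)
  if (filter)
    pseudobulk <- filter_low_expression(pseudobulk, layers)
  ql_de(t(pseudobulk), design, "score", layers)
}

#' Two-group differential expression on fragment pseudobulks
#'
#' Same model as [zonated_de()] with a binary group covariate instead of
#' the layer scores. Positive coefficients mean higher expression in the
#' second-listed group.
#'
#' @param pseudobulk Fragments x genes sum-mode pseudobulk (fragments with
#'   at least 2 cells of the type of interest).
#' @param groups Two-level factor (or character) per fragment; the factor
#'   level order fixes the sign convention.
#' @param sample_ids Sample id per fragment.
#' @param filter Apply [filter_low_expression()] first.
#' @return A `DEResult` data frame with per-group mean counts-per-million.
#' @export
twogroup_de <- function(pseudobulk, groups, sample_ids, filter = TRUE) {
  groups <- if (is.factor(groups)) droplevels(groups) else
    factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2)
    stop("twogroup_de: need exactly two non-empty groups")
  sample_f <- factor(sample_ids)
  design <- if (nlevels(sample_f) > 1)
    stats::model.matrix(~ sample_f + groups) else
      stats::model.matrix(~ groups)
  coef_name <- colnames(design)[ncol(design)]
  if (filter)
    pseudobulk <- filter_low_expression(pseudobulk, groups)
  ql_de(t(pseudobulk), design, coef_name, groups)
}

#' Test cell-type abundance shifts between two niche groups
#'
#' Per sample-by-group unit, cell-type counts are assembled and modeled
#' per cell type with a negative-binomial log-linear model (library size =
#' total cells of the unit, so normalized log abundances account for the
#' total number of cells per sample), group as covariate and sample as
#' blocking factor; dispersion is estimated without an abundance trend and
#' the group coefficient is tested with a robust quasi-likelihood F-test.
#' BH adjustment runs across cell types.
#'
#' @param annotation Cell annotation with fragment assignments and types.
#' @param groups Named character (or factor) vector: niche group per
#'   fragment. With a character vector levels are taken in sorted order,
#'   so for distal/proximal contrasts positive coefficients mean
#'   proximal-enriched; pass a factor to fix another order.
#' @return An `AbundanceResult` data frame: `type`, `coef` (log2
#'   difference, positive = more abundant in the second-level group),
#'   `p`, `fdr`, and mean counts-per-million per group.
#' @export
abundance_test <- function(annotation, groups) {
  ann <- annotation[!is_sentinel(annotation$fragment), , drop = FALSE]
  ann <- ann[ann$fragment %in% names(groups), , drop = FALSE]
  ann$group <- as.character(groups[ann$fragment])
  glev <- if (is.factor(groups)) levels(droplevels(groups)) else
    sort(unique(as.character(groups)))
  if (length(glev) != 2) stop("abundance_test: need exactly two groups")
  ann$unit <- paste(ann$sample, ann$group, sep = "|")
  units <- unique(ann$unit)
  if (length(unique(ann$sample)) < 2)
    stop("abundance_test: need at least 2 samples")
  types <- sort(unique(ann$type))
  counts <- sapply(units, function(u)
    table(factor(ann$type[ann$unit == u], levels = types)))
  counts <- matrix(as.integer(counts), nrow = length(types),
                   dimnames = list(types, units))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("abundance_test: skipping cell type(s) absent everywhere: ",
            paste(types[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  meta <- do.call(rbind, strsplit(units, "|", fixed = TRUE))
  sample_f <- factor(meta[, 1])
  group_f <- factor(meta[, 2], levels = glev)
  design <- if (nlevels(sample_f) > 1)
    stats::model.matrix(~ sample_f + group_f) else
      stats::model.matrix(~ group_f)
  y <- edgeR::DGEList(counts = counts, lib.size = colSums(counts))
  y <- edgeR::estimateDisp(y, design, trend.method = "none")
  fit <- edgeR::glmQLFit(y, design, robust = TRUE, abundance.trend = FALSE)
  qt <- edgeR::glmQLFTest(fit, coef = colnames(design)[ncol(design)])
  tt <- edgeR::topTags(qt, n = Inf, sort.by = "none")$table
  cpm <- edgeR::cpm(y)
  out <- data.frame(type = rownames(tt), coef = tt$logFC, p = tt$PValue,
                    fdr = stats::p.adjust(tt$PValue, method = "BH"),
                    stringsAsFactors = FALSE)
  for (g in glev)
    out[[paste0("cpm_", g)]] <- rowMeans(cpm[out$type, group_f == g,
                                             drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("AbundanceResult", "data.frame")
  out
}

#' Compare fragment covariates between two groups
#'
#' Two-sided Wilcoxon rank test per covariate, with group means and SDs.
#'
#' @param table Fragment table.
#' @param groups Named character vector: group per fragment (two levels).
#' @param covariates Columns to compare (default size and cell count).
#' @return Data frame: `covariate`, `p`, and per-group mean/sd columns.
#' @export
compare_fragment_covariates <- function(table, groups,
                                        covariates = c("size", "n_cells")) {
  tab <- table[table$fragment %in% names(groups), , drop = FALSE]
  g <- factor(groups[tab$fragment])
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("compare_fragment_covariates: need two non-empty groups")
  lv <- levels(g)
  out <- lapply(covariates, function(cv) {
    x <- tab[[cv]][g == lv[1]]
    y <- tab[[cv]][g == lv[2]]
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    stats::setNames(
      data.frame(cv, p, mean(x), stats::sd(x), mean(y), stats::sd(y),
                 stringsAsFactors = FALSE),
      c("covariate", "p", paste0("mean_", lv[1]), paste0("sd_", lv[1]),
        paste0("mean_", lv[2]), paste0("sd_", lv[2])))
  })
  do.call(rbind, out)
}

#' Uniformly downsample cells of an experiment
#'
#' Samples `target_n` cells without replacement and recomputes fragment
#' cell counts; used to separate fragment-size effects from undersampling.
#'
#' @param exp A `FragmentExperiment`.
#' @param target_n Number of cells to keep (must not exceed the current
#'   count).
#' @param seed Integer seed.
#' @return The downsampled experiment.
#' @export
downsample_cells <- function(exp, target_n, seed = 1) {
  n <- nrow(exp$cells)
  if (target_n > n) stop("downsample_cells: target_n exceeds cell count")
  set.seed(seed)
  keep <- sort(sample.int(n, target_n))
  exp$cells <- exp$cells[keep, , drop = FALSE]
  exp$counts <- exp$counts[, exp$cells$cell, drop = FALSE]
  recount_fragments(exp)
}

#' Write a differential-expression or abundance result to CSV
#' @param result A `DEResult` or `AbundanceResult`.
#' @param path Output path.
#' @export
write_de_result <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
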