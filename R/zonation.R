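# Spatial niche reconstruction: lobule layer from landmark-gene zonation
# coordinates, metastasis proximity from landmark cell types, and
# data-driven niche clusters from landmark gene panels.

#' Construct a landmark reference panel
#'
#' Per-gene reference profiles (mean and SEM per lobule layer) with a zone
#' tag. The reference may carry 9 or 10 layers; pole-based filters use the
#' first and last available layer.
#'
#' @param gene Gene identifiers.
#' @param zone `"central"` or `"portal"` per gene.
#' @param means,sems Numeric matrices, genes x layers, non-negative.
#' @return A `LandmarkPanel`.
#' @export
landmark_panel <- function(gene, zone, means, sems) {
  gene <- as.character(gene)
  zone <- as.character(zone)
  means <- as.matrix(means); sems <- as.matrix(sems)
  if (!all(zone %in% c("central", "portal")))
    stop("landmark_panel: zone must be 'central' or 'portal'")
  if (length(gene) != nrow(means) || !all(dim(means) == dim(sems)))
    stop("landmark_panel: dimension mismatch")
  if (any(means < 0) || any(sems < 0))
    stop("landmark_panel: reference profiles must be non-negative")
  rownames(means) <- rownames(sems) <- gene
  structure(list(gene = gene, zone = zone, means = means, sems = sems),
            class = "LandmarkPanel")
}

#' Read / write a landmark panel as TSV
#'
#' Columns: `gene`, `zone`, `mean_L1..`, `sem_L1..`.
#' @param path TSV path.
#' @export
read_landmark_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mcols <- grep("^mean_L", names(df), value = TRUE)
  scols <- grep("^sem_L", names(df), value = TRUE)
  landmark_panel(df$gene, df$zone, df[, mcols, drop = FALSE],
                 df[, scols, drop = FALSE])
}

#' @rdname read_landmark_panel
#' @param panel A `LandmarkPanel`.
#' @export
write_landmark_panel <- function(panel, path) {
  nl <- ncol(panel$means)
  df <- data.frame(gene = panel$gene, zone = panel$zone,
                   panel$means, panel$sems)
  names(df) <- c("gene", "zone", paste0("mean_L", seq_len(nl)),
                 paste0("sem_L", seq_len(nl)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter landmark genes by expression, polarity and stability
#'
#' Keeps genes satisfying all three reference-profile predicates:
#' (i) maximum layer mean above `min_expr`; (ii) fold change between the
#' first and last layer of at least `min_fold` (a zero mean at one pole
#' with a positive other pole counts as infinite fold change and passes,
#' flagged); (iii) mean over layers of SEM/mean below `max_cv`, discarding
#' highly varying genes.
#'
#' @param panel A `LandmarkPanel`.
#' @param min_expr Expression floor (default 1e-5, normalized fraction
#'   units).
#' @param min_fold Minimum pole fold change (default 1.1, i.e. 10%).
#' @param max_cv Maximum mean SEM/mean ratio (default 0.2).
#' @return The filtered panel; attribute `flagged` lists genes passing via
#'   an infinite pole fold change.
#' @export
filter_landmarks <- function(panel, min_expr = 1e-5, min_fold = 1.1,
                             max_cv = 0.2) {
  m <- panel$means; s <- panel$sems
  p1 <- apply(m, 1, max) > min_expr
  lo <- m[, 1]; hi <- m[, ncol(m)]
  poles_mx <- pmax(lo, hi); poles_mn <- pmin(lo, hi)
  fold <- ifelse(poles_mn > 0, poles_mx / poles_mn,
                 ifelse(poles_mx > 0, Inf, 1))
  p2 <- fold >= min_fold
  # CV is undefined where a layer mean is 0; average over expressed layers
  ratio <- ifelse(m > 0, s / m, NA_real_)
  p3 <- rowMeans(ratio, na.rm = TRUE) < max_cv
  p3[is.na(p3)] <- FALSE
  keep <- p1 & p2 & p3
  out <- landmark_panel(panel$gene[keep], panel$zone[keep],
                        m[keep, , drop = FALSE], s[keep, , drop = FALSE])
  attr(out, "flagged") <- panel$gene[keep & is.infinite(fold)]
  out
}

# library-size normalize to counts per `scale` and log1p
lognorm <- function(counts, scale = 1e4) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  log1p(Matrix::t(Matrix::t(counts) * (scale / libs)))
}

#' Per-fragment pseudobulk of one cell type
#'
#' Only fragments with at least `min_cells` cells of the type are emitted.
#' `sum` mode adds raw counts (input for count models); `mean` mode
#' averages log-normalized expression (input for clustering and zonation
#' coordinates).
#'
#' @param exp A `FragmentExperiment`.
#' @param cell_type Cell type of interest (`NULL` = all cells).
#' @param min_cells Minimum cells of the type per fragment (default 5).
#' @param mode `"sum"` or `"mean"`.
#' @return Fragments x genes matrix (rownames = fragment ids); attribute
#'   `n_cells` gives per-fragment cell counts used.
#' @export
fragment_pseudobulk <- function(exp, cell_type = NULL, min_cells = 5,
                                mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  ann <- exp$cells
  keep <- !is_sentinel(ann$fragment)
  if (!is.null(cell_type)) keep <- keep & ann$type %in% cell_type
  ann <- ann[keep, , drop = FALSE]
  cnt <- table(ann$fragment)
  frags <- names(cnt)[cnt >= min_cells]
  if (!length(frags)) {
    warning("fragment_pseudobulk: no fragment passes the cell cutoff")
    return(matrix(0, 0, nrow(exp$counts),
                  dimnames = list(NULL, rownames(exp$counts))))
  }
  ann <- ann[ann$fragment %in% frags, , drop = FALSE]
  mat <- exp$counts[, ann$cell, drop = FALSE]
  if (mode == "mean") mat <- lognorm(mat)
  grp <- factor(ann$fragment, levels = frags)
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp),
                              x = 1, dims = c(length(grp), length(frags)))
  pb <- Matrix::t(ind) %*% Matrix::t(mat)    # fragments x genes
  pb <- as.matrix(pb)
  if (mode == "mean") pb <- pb / as.vector(cnt[frags])
  dimnames(pb) <- list(frags, rownames(exp$counts))
  attr(pb, "n_cells") <- as.integer(cnt[frags])
  pb
}

#' Compute per-fragment zonation coordinates
#'
#' Genes in the pseudobulk are max-normalized over fragments (each gene
#' divided by its maximum) so all landmarks contribute equally; the portal
#' and central landmark sums (pLM, cLM) then give the raw coordinate
#' ZC = pLM / (pLM + cLM), which is min-max rescaled over retained
#' fragments so 0 is the most central and 1 the most portal fragment.
#' Fragments with pLM + cLM = 0 (no landmark expression) are dropped and
#' listed in the `dropped` attribute.
#'
#' @param pseudobulk Fragments x genes matrix (mean-mode LEC pseudobulk).
#' @param panel A filtered `LandmarkPanel`.
#' @return A `ZonationResult` data frame: `fragment`, `plm_sum`,
#'   `clm_sum`, `zc_raw`, `zc_rescaled`.
#' @export
compute_zc <- function(pseudobulk, panel) {
  if (nrow(pseudobulk) < 2)
    stop("compute_zc: need at least 2 fragments")
  genes <- intersect(panel$gene, colnames(pseudobulk))
  zone <- panel$zone[match(genes, panel$gene)]
  if (!any(zone == "central") || !any(zone == "portal"))
    stop("compute_zc: need measured landmarks in both zones")
  m <- pseudobulk[, genes, drop = FALSE]
  mx <- apply(m, 2, max)
  ok <- mx > 0
  m <- sweep(m[, ok, drop = FALSE], 2, mx[ok], "/")
  zone <- zone[ok]
  plm <- rowSums(m[, zone == "portal", drop = FALSE])
  clm <- rowSums(m[, zone == "central", drop = FALSE])
  denom <- plm + clm
  dropped <- rownames(pseudobulk)[denom == 0]
  keep <- denom > 0
  zc_raw <- plm[keep] / denom[keep]
  rng <- range(zc_raw)
  if (diff(rng) == 0)
    stop("compute_zc: degenerate rescale, all fragments have identical ZC")
  res <- data.frame(fragment = rownames(pseudobulk)[keep],
                    plm_sum = unname(plm[keep]), clm_sum = unname(clm[keep]),
                    zc_raw = unname(zc_raw),
                    zc_rescaled = unname((zc_raw - rng[1]) / diff(rng)),
                    stringsAsFactors = FALSE)
  attr(res, "dropped") <- dropped
  class(res) <- c("ZonationResult", "data.frame")
  res
}

#' Bin zonation coordinates into lobule layers L1-L10
#'
#' Decile bins of the rescaled coordinate: layer k covers
#' \[0.1(k-1), 0.1k) for k = 1..9 and L10 covers \[0.9, 1\] (the upper bin
#' is closed at both ends so binning is total on \[0,1\]). Optionally the
#' sparsely populated extremes are merged into L1-L3 and L8-L10.
#'
#' @param result A `ZonationResult`.
#' @param merge_extremes Merge L1..L3 and L8..L10 into single labels.
#' @return The result with a `layer` column (ordered factor).
#' @export
bin_layers <- function(result, merge_extremes = FALSE) {
  zc <- result$zc_rescaled
  if (any(zc < 0 | zc > 1))
    stop("bin_layers: zonation coordinates must lie in [0,1]")
  k <- pmin(floor(zc * 10 + 1e-9) + 1L, 10L)
  if (merge_extremes) {
    lab <- ifelse(k <= 3, "L1-L3", ifelse(k >= 8, "L8-L10",
                                          paste0("L", k)))
    levs <- c("L1-L3", "L4", "L5", "L6", "L7", "L8-L10")
  } else {
    lab <- paste0("L", k)
    levs <- paste0("L", 1:10)
  }
  result$layer <- factor(lab, levels = levs, ordered = TRUE)
  result
}

#' Group lobule layers into central and portal zones
#'
#' L1-L5 become `central` (pericentral), L6-L10 `portal` (periportal).
#'
#' @param result A `ZonationResult` with `layer` set by [bin_layers()]
#'   (unmerged layers).
#' @return The result with a `zone` column.
#' @export
group_zone <- function(result) {
  if (is.null(result$layer) || any(is.na(result$layer)))
    stop("group_zone: bin layers first")
  k <- as.integer(sub("^L", "", sub("-.*$", "", as.character(result$layer))))
  result$zone <- ifelse(k <= 5, "central", "portal")
  result
}

#' Label fragments by metastasis proximity
#'
#' Samples with fewer than `min_landmark_cells_per_sample` landmark cells
#' overall are excluded entirely; fragments with fewer than
#' `min_cells_per_fragment` cells are excluded; remaining fragments are
#' `proximal` iff they contain at least one landmark cell (e.g. a
#' metastatic cell), else `distal`.
#'
#' @param exp A `FragmentExperiment` with cell types annotated.
#' @param landmark_type Cell type defining the niche (default
#'   `"metastatic"`).
#' @param min_cells_per_fragment Fragment cell cutoff (default 5).
#' @param min_landmark_cells_per_sample Sample-level landmark cutoff
#'   (default 20).
#' @return Data frame (`fragment`, `sample`, `proximity`); attribute
#'   `excluded_samples` lists dropped samples.
#' @export
assign_proximity <- function(exp, landmark_type = "metastatic",
                             min_cells_per_fragment = 5,
                             min_landmark_cells_per_sample = 20) {
  ann <- exp$cells[!is_sentinel(exp$cells$fragment), , drop = FALSE]
  per_sample <- tapply(ann$type == landmark_type, ann$sample, sum)
  good_samples <- names(per_sample)[per_sample >=
                                      min_landmark_cells_per_sample]
  excluded <- setdiff(names(per_sample), good_samples)
  ann <- ann[ann$sample %in% good_samples, , drop = FALSE]
  cnt <- table(ann$fragment)
  frags <- names(cnt)[cnt >= min_cells_per_fragment]
  has_lm <- tapply(ann$type == landmark_type, ann$fragment, any)[frags]
  out <- data.frame(fragment = frags,
                    sample = ann$sample[match(frags, ann$fragment)],
                    proximity = ifelse(has_lm, "proximal", "distal"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_samples") <- excluded
  out
}

#' Cluster fragments on a landmark gene panel
#'
#' Mean-mode pseudobulk over the landmark genes is scaled to unit
#' variance, projected onto principal components, and partitioned with a
#' shared-nearest-neighbor graph and Louvain modularity communities (the
#' resolution parameter maps onto the Louvain resolution).
#'
#' @param exp A `FragmentExperiment`.
#' @param landmark_genes Character vector of marker genes (e.g. top 10 per
#'   niche).
#' @param n_pcs Principal components to keep (default 10; truncated with a
#'   warning when fewer fragments are available).
#' @param resolution Louvain resolution (default 0.4).
#' @param k_snn Neighbors for the SNN graph (default 10).
#' @param min_cells Fragment cell cutoff for the pseudobulk.
#' @param seed Integer seed (community detection is randomized).
#' @return Data frame (`fragment`, `cluster`).
#' @export
landmark_cluster_fragments <- function(exp, landmark_genes, n_pcs = 10,
                                       resolution = 0.4, k_snn = 10,
                                       min_cells = 5, seed = 1) {
  pb <- fragment_pseudobulk(exp, cell_type = NULL, min_cells = min_cells,
                            mode = "mean")
  genes <- intersect(landmark_genes, colnames(pb))
  if (length(genes) < 2)
    stop("landmark_cluster_fragments: fewer than 2 landmark genes measured")
  x <- pb[, genes, drop = FALSE]
  if (nrow(x) < 2)
    stop("landmark_cluster_fragments: need at least 2 fragments")
  sdv <- apply(x, 2, stats::sd)
  if (!any(sdv > 0))
    return(data.frame(fragment = rownames(x), cluster = "1",
                      stringsAsFactors = FALSE))
  x <- scale(x[, sdv > 0, drop = FALSE])
  npc <- min(n_pcs, nrow(x) - 1, ncol(x))
  if (npc < n_pcs)
    warning("landmark_cluster_fragments: components truncated to ", npc)
  pcs <- stats::prcomp(x, center = FALSE, scale. = FALSE)$x[, seq_len(npc),
                                                            drop = FALSE]
  if (all(stats::dist(pcs) < 1e-10)) {
    return(data.frame(fragment = rownames(x),
                      cluster = "1", stringsAsFactors = FALSE))
  }
  k <- min(k_snn, nrow(pcs) - 1)
  d <- as.matrix(stats::dist(pcs))
  nn <- apply(d, 1, function(r) order(r)[2:(k + 1)])  # k x n
  # SNN edge weight: Jaccard overlap of neighbor sets
  n <- nrow(pcs)
  edges <- list(); wts <- list(); e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(nn[, i], nn[, j]))
    if (shared > 0 || j %in% nn[, i] || i %in% nn[, j]) {
      jac <- shared / (2 * k - shared)
      if (jac > 1 / 15 || j %in% nn[, i] || i %in% nn[, j]) {
        e <- e + 1
        edges[[e]] <- c(i, j)
        wts[[e]] <- max(jac, 1 / (2 * k))
      }
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = unlist(wts))
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  data.frame(fragment = rownames(x),
             cluster = as.character(igraph::membership(comm)),
             stringsAsFactors = FALSE)
}

#' Allocate deconvolved spots to cell types
#'
#' A spot is labelled with its top cell type when that type's fraction
#' reaches `threshold` (default 0.75), else `"mixed"`. Ties at the top are
#' broken by the first-listed type and flagged.
#'
#' @param weights Spots x cell-types matrix of deconvolution fractions
#'   (rows must sum to 1 within 1%).
#' @param threshold Allocation threshold (default 0.75).
#' @return Data frame (`spot`, `label`, `top_fraction`, `tied`).
#' @export
allocate_spot_celltype <- function(weights, threshold = 0.75) {
  weights <- as.matrix(weights)
  rs <- rowSums(weights)
  if (any(abs(rs - 1) > 0.01))
    stop("allocate_spot_celltype: rows must sum to 1 (within 1%)")
  top <- apply(weights, 1, which.max)
  topfrac <- weights[cbind(seq_len(nrow(weights)), top)]
  tied <- rowSums(weights == topfrac) > 1
  lab <- ifelse(topfrac >= threshold, colnames(weights)[top], "mixed")
  data.frame(spot = if (is.null(rownames(weights)))
    as.character(seq_len(nrow(weights))) else rownames(weights),
    label = lab, top_fraction = unname(topfrac), tied = unname(tied),
    stringsAsFactors = FALSE)
}
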