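# Ligand-receptor interaction scoring within niche groups via
# cluster-label permutation, supporting multi-subunit complexes.
#
# Scoring follows the mean-of-means convention: an interaction score is
# the average of the ligand's mean normalized expression in the sender
# cluster and the receptor's in the receiver cluster; complexes are
# summarized by the minimum over subunits; significance comes from an
# upper-tail permutation of cluster labels over the pooled cells
# (enrichment, unadjusted).

cluster_gene_stats <- function(norm, cols) {
  sub <- norm[, cols, drop = FALSE]
  list(mean = Matrix::rowMeans(sub),
       frac = Matrix::rowMeans(sub > 0))
}

complex_expr <- function(means, components) {
  vapply(components, function(cmp) min(means[cmp]), 0)
}

#' Score ligand-receptor interactions between two clusters
#'
#' Input cells should already be restricted to one niche group (e.g.
#' pericentral fragments). An interaction is tested only when every ligand
#' component is expressed in more than `min_frac_expressing` of sender
#' cells and every receptor component likewise in receiver cells.
#' Normalized expression is log1p of library-size-scaled counts. The
#' permutation null redraws sender/receiver membership over the pooled
#' cells of the two clusters (optionally within sample).
#'
#' @param exp A `FragmentExperiment` subset to one group.
#' @param db Interaction database from [lr_database()].
#' @param sender,receiver Cell type labels.
#' @param min_frac_expressing Expression-fraction gate (default 0.1).
#' @param n_perm Permutations (default 1000, minimum 10).
#' @param seed Integer seed.
#' @param within_sample Permute labels within each sample rather than over
#'   the pool.
#' @return An `InteractionScore` data frame: `id`, `sender`, `receiver`,
#'   `tested`, `score`, `p`, `skipped_reason`.
#' @export
score_interactions <- function(exp, db, sender, receiver,
                               min_frac_expressing = 0.1, n_perm = 1000,
                               seed = 1, within_sample = FALSE) {
  if (n_perm < 10) stop("score_interactions: n_perm must be >= 10")
  ann <- exp$cells
  s_cells <- ann$cell[ann$type == sender]
  r_cells <- ann$cell[ann$type == receiver]
  if (!length(s_cells) || !length(r_cells))
    stop("score_interactions: empty sender or receiver cluster")
  genes_needed <- unique(c(unlist(db$ligand), unlist(db$receptor)))
  present <- genes_needed %in% rownames(exp$counts)
  have <- genes_needed[present]

  pool <- c(s_cells, r_cells)
  norm <- lognorm(exp$counts[, pool, drop = FALSE])
  norm <- norm[rownames(norm) %in% have, , drop = FALSE]
  ns <- length(s_cells)
  st_s <- cluster_gene_stats(norm, seq_len(ns))
  st_r <- cluster_gene_stats(norm, ns + seq_along(r_cells))

  n_int <- nrow(db)
  tested <- logical(n_int); obs <- rep(NA_real_, n_int)
  reason <- rep("", n_int)
  for (i in seq_len(n_int)) {
    lg <- db$ligand[[i]]; rc <- db$receptor[[i]]
    if (!all(c(lg, rc) %in% rownames(norm))) {
      reason[i] <- "missing gene"
      next
    }
    if (!all(st_s$frac[lg] > min_frac_expressing) ||
        !all(st_r$frac[rc] > min_frac_expressing)) {
      reason[i] <- "below expression fraction"
      next
    }
    tested[i] <- TRUE
    obs[i] <- (min(st_s$mean[lg]) + min(st_r$mean[rc])) / 2
  }

  p <- rep(NA_real_, n_int)
  if (any(tested)) {
    set.seed(seed)
    idx_t <- which(tested)
    lg_list <- db$ligand[idx_t]; rc_list <- db$receptor[idx_t]
    exceed <- integer(length(idx_t))
    npool <- length(pool)
    samp_of <- ann$sample[match(pool, ann$cell)]
    for (b in seq_len(n_perm)) {
      perm <- if (within_sample) {
        o <- seq_len(npool)
        for (s in unique(samp_of)) {
          w <- which(samp_of == s)
          o[w] <- w[sample.int(length(w))]
        }
        o
      } else sample.int(npool)
      si <- perm[seq_len(ns)]
      ri <- perm[(ns + 1):npool]
      ms <- Matrix::rowMeans(norm[, si, drop = FALSE])
      mr <- Matrix::rowMeans(norm[, ri, drop = FALSE])
      null_sc <- (vapply(lg_list, function(g) min(ms[g]), 0) +
                    vapply(rc_list, function(g) min(mr[g]), 0)) / 2
      exceed <- exceed + (null_sc >= obs[idx_t])
    }
    p[idx_t] <- (exceed + 1) / (n_perm + 1)
  }
  out <- data.frame(id = db$id, sender = sender, receiver = receiver,
                    tested = tested, score = obs, p = p,
                    skipped_reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("InteractionScore", "data.frame")
  out
}

#' Compare interaction scores between two niche groups
#'
#' Interactions untested in one group enter with score 0 and an
#' `untested_in` flag. The table is ordered decreasing by
#' `difference = score_A - score_B`; swapping the groups negates every
#' difference.
#'
#' @param scores_a,scores_b `InteractionScore` tables over the same
#'   interaction universe.
#' @return Data frame: `id`, `sender`, `receiver`, `score_a`, `score_b`,
#'   `difference`, `p_a`, `p_b`, `untested_in`.
#' @export
compare_groups <- function(scores_a, scores_b) {
  key <- function(s) paste(s$id, s$sender, s$receiver)
  if (!setequal(key(scores_a), key(scores_b)))
    stop("compare_groups: interaction universes differ")
  b <- scores_b[match(key(scores_a), key(scores_b)), ]
  a <- scores_a
  sa <- ifelse(a$tested, a$score, 0)
  sb <- ifelse(b$tested, b$score, 0)
  out <- data.frame(id = a$id, sender = a$sender, receiver = a$receiver,
                    score_a = sa, score_b = sb, difference = sa - sb,
                    p_a = a$p, p_b = b$p,
                    untested_in = paste0(ifelse(a$tested, "", "A"),
                                         ifelse(b$tested, "", "B")),
                    stringsAsFactors = FALSE)
  out[order(-out$difference), ]
}

#' Rank of a planted interaction in a group comparison
#'
#' Reports where a known enriched ligand-receptor pair falls when
#' interactions are ordered by group score difference, and whether it
#' makes the top `k`.
#'
#' @param comparison Output of [compare_groups()].
#' @param planted_id Interaction id of the planted pair.
#' @param k Top-set size (default 3).
#' @return List with `rank`, `top_k` (logical), `difference`.
#' @export
recover_planted_interaction <- function(comparison, planted_id, k = 3) {
  pos <- which(comparison$id == planted_id)
  if (!length(pos))
    stop("recover_planted_interaction: planted id not in comparison")
  list(rank = pos[1], top_k = pos[1] <= k,
       difference = comparison$difference[pos[1]])
}

#' Write interaction scores or a group comparison to CSV
#' @param x An `InteractionScore` or comparison data frame.
#' @param path Output path.
#' @export
write_interactions <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
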