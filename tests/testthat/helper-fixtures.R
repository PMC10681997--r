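# Shared fixture builders; everything is generated in code.

toy_experiment <- function() {
  counts <- matrix(c(5, 0, 2, 1,
                     0, 3, 0, 4,
                     2, 2, 1, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("c1", "c2", "c3", "c4")))
  cells <- cell_annotation(c("c1", "c2", "c3", "c4"),
                           sample = c("S1", "S1", "S2", "S2"),
                           fragment = c("F1", "F1", "F2", "DOUBLET"),
                           type = c("LEC", "KC", "LEC", "LEC"))
  fragments <- fragment_table(c("F1", "F2"), sample = c("S1", "S2"),
                              tof = c(500, 700))
  fragment_experiment(count_matrix(counts), cells, fragments)
}

random_sparse_counts <- function(n_genes = 12, n_cells = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 0.8), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  count_matrix(m)
}

# Adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force nearest-segment label expansion oracle
expand_oracle <- function(m, d) {
  out <- m
  lab <- which(m > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] > 0) next
    dd <- sqrt((lab[, 1] - i)^2 + (lab[, 2] - j)^2)
    k <- which(dd == min(dd))
    k <- k[which.min(m[lab[k, , drop = FALSE]])]
    if (min(dd) <= d) out[i, j] <- m[lab[k, 1], lab[k, 2]]
  }
  out
}

# Benjamini-Hochberg by direct sort (independent of stats::p.adjust)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
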