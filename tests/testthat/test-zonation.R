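make_panel <- function(n_layers = 10) {
  simulate_landmark_panel(lobule_sim_config(n_landmarks = 3),
                          n_layers = n_layers)
}

test_that("landmark filtering applies all three reference predicates", {
  # flat profile fails the pole fold change; noisy profile fails the CV
  means <- rbind(flat = rep(1, 10),
                 good = seq(0.1, 2, length.out = 10),
                 noisy = seq(0.1, 2, length.out = 10),
                 silent = rep(1e-6, 10))
  sems <- rbind(flat = rep(0.01, 10), good = rep(0.01, 10),
                noisy = seq(0.1, 2, length.out = 10),  # SEM = mean
                silent = rep(0, 10))
  panel <- landmark_panel(rownames(means), rep("portal", 4), means, sems)
  kept <- filter_landmarks(panel)
  expect_equal(kept$gene, "good")

  # a zero pole with a positive other pole passes (infinite fold), flagged
  pz <- landmark_panel("zeropole", "central",
                       matrix(c(0, rep(0.5, 9)), 1), matrix(0.01, 1, 10))
  kz <- filter_landmarks(pz)
  expect_equal(kz$gene, "zeropole")
  expect_equal(attr(kz, "flagged"), "zeropole")
})

test_that("landmark filtering equals an independent three-predicate oracle", {
  set.seed(14)
  n <- 50
  means <- matrix(rexp(n * 10, 2), n)
  means[sample(n, 10), ] <- rep(runif(10, 0, 2e-5), each = 10)  # near floor
  sems <- means * matrix(runif(n * 10, 0, 0.5), n)
  genes <- sprintf("g%02d", 1:n)
  panel <- landmark_panel(genes, sample(c("central", "portal"), n, TRUE),
                          means, sems)
  kept <- filter_landmarks(panel)$gene
  oracle <- genes[vapply(seq_len(n), function(i) {
    m <- means[i, ]; s <- sems[i, ]
    p1 <- max(m) > 1e-5
    p2 <- max(m[1], m[10]) / min(m[1], m[10]) >= 1.1
    p3 <- mean(s / m) < 0.2
    isTRUE(p1 && p2 && p3)
  }, TRUE)]
  expect_setequal(kept, oracle)
})

test_that("fragment pseudobulk aggregates per fragment and cell type", {
  exp <- toy_experiment()
  pb <- fragment_pseudobulk(exp, "LEC", min_cells = 1, mode = "sum")
  # F1 has one LEC (c1), F2 one LEC (c3); doublet cell c4 excluded
  expect_equal(pb["F1", c("g1", "g2", "g3")], c(g1 = 5, g2 = 0, g3 = 2))
  expect_equal(unname(pb["F2", "g1"]), 2)
  # min_cells excludes under-populated fragments
  expect_warning(empty <- fragment_pseudobulk(exp, "LEC", min_cells = 5),
                 "cutoff")
  expect_equal(nrow(empty), 0)

  # random experiment: sum mode equals a group-by aggregate oracle
  sim <- simulate_lobule_experiment(lobule_sim_config(n_fragments = 10),
                                    seed = 30)
  e <- sim$experiment
  pbs <- fragment_pseudobulk(e, "LEC", min_cells = 2, mode = "sum")
  m <- as.matrix(e$counts)
  for (f in rownames(pbs)) {
    lecs <- e$cells$cell[e$cells$fragment == f & e$cells$type == "LEC"]
    expect_equal(pbs[f, ], rowSums(m[, lecs, drop = FALSE]))
  }
})

test_that("zonation coordinates follow the landmark-sum formula", {
  panel <- landmark_panel(c("c1", "c2", "p1", "p2"),
                          c("central", "central", "portal", "portal"),
                          matrix(1, 4, 10), matrix(0.01, 4, 10))
  pb <- rbind(FA = c(c1 = 2, c2 = 2, p1 = 0, p2 = 0),
              FB = c(c1 = 1, c2 = 1, p1 = 1, p2 = 1),
              FC = c(c1 = 0, c2 = 0, p1 = 2, p2 = 2))
  zc <- compute_zc(pb, panel)
  # pure central -> 0; balanced -> 0.5 raw
  expect_equal(zc$zc_raw[zc$fragment == "FA"], 0)
  expect_equal(zc$zc_raw[zc$fragment == "FB"], 0.5)
  expect_equal(zc$zc_rescaled, c(0, 0.5, 1))

  # rescale arithmetic on planted raw coordinates (0.2, 0.4, 0.8)
  pb2 <- rbind(F1 = c(c1 = 0.8, c2 = 0, p1 = 0.2, p2 = 0),
               F2 = c(c1 = 0.6, c2 = 0, p1 = 0.4, p2 = 0),
               F3 = c(c1 = 0.2, c2 = 0, p1 = 0.8, p2 = 0))
  zc2 <- compute_zc(pb2, panel)
  expect_equal(zc2$zc_raw, c(0.2, 0.4, 0.8))
  expect_equal(zc2$zc_rescaled, c(0, 1/3, 1))

  # zero-denominator fragments are dropped and reported
  pb3 <- rbind(pb2, F4 = c(c1 = 0, c2 = 0, p1 = 0, p2 = 0))
  zc3 <- compute_zc(pb3, panel)
  expect_equal(attr(zc3, "dropped"), "F4")
  expect_equal(nrow(zc3), 3)

  # scaling one gene's column is absorbed by max-normalization
  pb4 <- pb2
  pb4[, "p1"] <- pb4[, "p1"] * 37
  expect_equal(compute_zc(pb4, panel)$zc_rescaled, zc2$zc_rescaled)

  expect_error(compute_zc(pb2[, 1:2] * 0 + 1,
                          landmark_panel("c1", "central",
                                         matrix(1, 1, 10),
                                         matrix(0, 1, 10))),
               "both zones")
})

test_that("layer binning is total, disjoint and matches the decile rule", {
  z <- data.frame(fragment = sprintf("F%02d", 1:10),
                  zc_rescaled = seq(0.05, 0.95, by = 0.1))
  b <- bin_layers(z)
  expect_equal(as.character(b$layer), paste0("L", 1:10))
  edge <- bin_layers(data.frame(fragment = c("a", "b", "c", "d"),
                                zc_rescaled = c(0, 0.9, 1, 0.7)))
  expect_equal(as.character(edge$layer), c("L1", "L10", "L10", "L8"))
  expect_error(bin_layers(data.frame(fragment = "x", zc_rescaled = 1.2)),
               "\\[0,1\\]")
  # every coordinate lands in exactly one bin
  grid <- data.frame(fragment = as.character(1:1001),
                     zc_rescaled = seq(0, 1, length.out = 1001))
  bg <- bin_layers(grid)
  expect_false(any(is.na(bg$layer)))
  expect_equal(nlevels(droplevels(bg$layer)), 10)
  # merged extremes
  bm <- bin_layers(z, merge_extremes = TRUE)
  expect_equal(levels(bm$layer),
               c("L1-L3", "L4", "L5", "L6", "L7", "L8-L10"))
  expect_equal(sum(bm$layer == "L1-L3"), 3)
})

test_that("zone grouping splits layers at L5/L6 and preserves counts", {
  z <- bin_layers(data.frame(fragment = sprintf("F%02d", 1:10),
                             zc_rescaled = seq(0.05, 0.95, by = 0.1)))
  g <- group_zone(z)
  expect_equal(g$zone[g$layer == "L5"], "central")
  expect_equal(g$zone[g$layer == "L6"], "portal")
  expect_false(any(is.na(g$zone)))
  expect_equal(sum(g$zone == "central"),
               sum(table(g$layer)[paste0("L", 1:5)]))
})

test_that("proximity labels follow presence of the landmark cell type", {
  cells <- cell_annotation(
    sprintf("c%03d", 1:60),
    sample = rep(c("S1", "S2"), each = 30),
    fragment = rep(sprintf("F%d", 1:6), each = 10),
    type = c(rep("hepatocyte", 9), "metastatic",      # F1: 1 met
             rep(c("hepatocyte", "metastatic"), 5),   # F2: 5 met
             rep("hepatocyte", 10),                   # F3: none
             rep("metastatic", 30)))                  # F4-6 (S2)
  frag <- fragment_table(sprintf("F%d", 1:6),
                         sample = rep(c("S1", "S2"), each = 3))
  exp <- fragment_experiment(
    count_matrix(matrix(1, 1, 60, dimnames = list("g", cells$cell))),
    cells, frag)
  # S1 has 6 metastatic cells -> excluded at the 20-cell sample cutoff
  lab <- assign_proximity(exp, min_landmark_cells_per_sample = 20)
  expect_equal(attr(lab, "excluded_samples"), "S1")
  expect_true(all(lab$proximity == "proximal"))
  # with the sample cutoff lowered, presence/absence decides
  lab2 <- assign_proximity(exp, min_landmark_cells_per_sample = 1)
  expect_equal(lab2$proximity[lab2$fragment == "F1"], "proximal")
  expect_equal(lab2$proximity[lab2$fragment == "F3"], "distal")
  # set-membership oracle on a random experiment
  sim <- simulate_lobule_experiment(lobule_sim_config(n_fragments = 30),
                                    seed = 19)
  lab3 <- assign_proximity(sim$experiment,
                           min_landmark_cells_per_sample = 0)
  ann <- sim$experiment$cells
  for (i in seq_len(nrow(lab3))) {
    has <- any(ann$type[ann$fragment == lab3$fragment[i]] == "metastatic")
    expect_equal(lab3$proximity[i] == "proximal", has)
  }
})

test_that("landmark clustering recovers planted niche signatures", {
  # two planted expression programs over 12 marker genes
  set.seed(77)
  nf <- 40
  ncell_per <- 8
  genes <- c(sprintf("mkA%02d", 1:6), sprintf("mkB%02d", 1:6))
  truth <- rep(c("nicheA", "nicheB"), each = nf / 2)
  frag_ids <- sprintf("F%02d", seq_len(nf))
  cellfr <- rep(frag_ids, each = ncell_per)
  mu <- matrix(0.2, length(genes), length(cellfr),
               dimnames = list(genes,
                               sprintf("c%04d", seq_along(cellfr))))
  isA <- truth[match(cellfr, frag_ids)] == "nicheA"
  mu[1:6, isA] <- 6
  mu[7:12, !isA] <- 6
  counts <- matrix(rpois(length(mu), mu), nrow = nrow(mu),
                   dimnames = dimnames(mu))
  exp <- fragment_experiment(count_matrix(counts),
                             cell_annotation(colnames(counts),
                                             fragment = cellfr,
                                             type = "any"),
                             fragment_table(frag_ids))
  cl <- landmark_cluster_fragments(exp, genes, min_cells = 2, seed = 4)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_gte(adjusted_rand(cl$cluster, truth[match(cl$fragment,
                                                   frag_ids)]), 0.9)
  # same seed gives identical labels
  cl2 <- landmark_cluster_fragments(exp, genes, min_cells = 2, seed = 4)
  expect_identical(cl, cl2)
  # identical fragments collapse to one cluster
  cid <- matrix(5L, length(genes), length(cellfr), dimnames = dimnames(mu))
  expi <- fragment_experiment(count_matrix(cid), exp$cells, exp$fragments)
  expect_equal(unique(landmark_cluster_fragments(expi, genes,
                                                 min_cells = 2)$cluster),
               "1")
})

test_that("spot allocation applies the 75% rule with tie flagging", {
  w <- rbind(s1 = c(t1 = 0.8, t2 = 0.2),
             s2 = c(t1 = 0.5, t2 = 0.5),
             s3 = c(t1 = 0.74, t2 = 0.26))
  out <- allocate_spot_celltype(w)
  expect_equal(out$label, c("t1", "mixed", "mixed"))
  # threshold 0 always takes the argmax; ties break to the first index
  out0 <- allocate_spot_celltype(w, threshold = 0)
  expect_equal(out0$label, c("t1", "t1", "t1"))
  expect_true(out0$tied[2])
  expect_error(allocate_spot_celltype(rbind(c(0.6, 0.2))), "sum to 1")
})
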