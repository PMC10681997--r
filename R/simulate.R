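# Synthetic fragment-seq and spatial data with known ground truth.
#
# The generator emulates the statistical structure of the real assay --
# zonated expression gradients along a 0-1 lobule axis, niche-dependent
# cell-type composition, hashing counts with doublet/negative contamination,
# TOF proportional to size with noise, and 2-D point patterns with planted
# type-type attraction -- so that every downstream stage has a
# parameter-recovery test without external data. Hashing noise levels are
# order-of-magnitude defaults (no quantitative values are published for this
# chemistry); treat them as plausible, not measured.

#' Configuration for the lobule fragment simulator
#'
#' Defaults describe a mid-sized metastatic-liver run: 200 fragments across
#' 3 samples, ~30 cells per fragment, 20 central + 20 portal landmark genes
#' expressed in liver endothelial cells (LECs), and a hashing chemistry with
#' strong signal over background.
#'
#' @param n_fragments Number of sorted fragments.
#' @param n_samples Samples the fragments are spread over (round-robin).
#' @param cells_mean,cells_dispersion Negative-binomial parameters of the
#'   cells-per-fragment distribution (mean, size); floored at 5 cells.
#' @param cell_types Cell-type labels in the panel.
#' @param composition Baseline type proportions (same length/order as
#'   `cell_types`; normalized internally).
#' @param proximal_frac Fraction of fragments near a metastasis.
#' @param proximal_shift Named multipliers applied to `composition` in
#'   proximal fragments (direction: more metastatic cells and
#'   macrophages/monocytes, fewer KCs and LECs).
#' @param n_landmarks Landmark genes per pole (central and portal), LEC
#'   expressed.
#' @param landmark_slope Log-scale slope of landmark means versus the true
#'   zonation coordinate (portal +, central -).
#' @param landmark_base Mean landmark expression in LECs at coordinate 0.5.
#' @param zonated_genes Data frame (`gene`, `type`, `slope`) of additional
#'   planted zonated genes, or `NULL`.
#' @param n_null_genes Unzonated filler genes expressed in all types.
#' @param null_base Mean expression of filler genes.
#' @param nb_size Negative-binomial size (dispersion) of expression counts.
#' @param sample_effect Multiplicative per-sample depth factors (recycled).
#' @param hash_signal,hash_background Poisson means of the assigned barcode
#'   and of every other barcode.
#' @param doublet_rate,negative_rate Fractions of cells carrying two signal
#'   barcodes / background only.
#' @param size_range Fragment diameter range (micrometres).
#' @param tof_slope,tof_intercept,tof_noise_sd Linear TOF model
#'   (sorter units per micrometre; units; units).
#' @param zc_distribution `"uniform"` or `"truncnorm"` (mean 0.5, sd 0.2,
#'   truncated to \[0,1\]; mimics sparsely sampled extreme layers).
#' @return A validated list of class `LobuleSimConfig`.
#' @export
lobule_sim_config <- function(n_fragments = 200, n_samples = 3,
                              cells_mean = 30, cells_dispersion = 5,
                              cell_types = c("LEC", "hepatocyte", "KC",
                                             "T", "B", "macrophage",
                                             "metastatic"),
                              composition = c(0.25, 0.2, 0.2, 0.12, 0.08,
                                              0.1, 0.05),
                              proximal_frac = 0.3,
                              proximal_shift = c(metastatic = 4,
                                                 macrophage = 2,
                                                 KC = 0.5, LEC = 0.7),
                              n_landmarks = 20, landmark_slope = 2,
                              landmark_base = 5,
                              zonated_genes = NULL, n_null_genes = 60,
                              null_base = 2, nb_size = 2,
                              sample_effect = c(1, 1.25, 0.8),
                              hash_signal = 500, hash_background = 5,
                              doublet_rate = 0.05, negative_rate = 0.05,
                              size_range = c(200, 450), tof_slope = 2,
                              tof_intercept = 20, tof_noise_sd = 10,
                              zc_distribution = c("uniform", "truncnorm")) {
  cfg <- list(n_fragments = n_fragments, n_samples = n_samples,
              cells_mean = cells_mean, cells_dispersion = cells_dispersion,
              cell_types = cell_types,
              composition = composition / sum(composition),
              proximal_frac = proximal_frac, proximal_shift = proximal_shift,
              n_landmarks = n_landmarks, landmark_slope = landmark_slope,
              landmark_base = landmark_base, zonated_genes = zonated_genes,
              n_null_genes = n_null_genes, null_base = null_base,
              nb_size = nb_size, sample_effect = sample_effect,
              hash_signal = hash_signal, hash_background = hash_background,
              doublet_rate = doublet_rate, negative_rate = negative_rate,
              size_range = size_range, tof_slope = tof_slope,
              tof_intercept = tof_intercept, tof_noise_sd = tof_noise_sd,
              zc_distribution = match.arg(zc_distribution))
  if (n_fragments < 1) stop("lobule_sim_config: need at least 1 fragment")
  if (length(cell_types) != length(composition))
    stop("lobule_sim_config: composition length mismatch")
  rates <- c(proximal_frac, doublet_rate, negative_rate)
  if (any(rates < 0 | rates > 1))
    stop("lobule_sim_config: rates must lie in [0,1]")
  if (any(c(cells_mean, landmark_base, null_base, hash_signal) <= 0))
    stop("lobule_sim_config: means must be positive")
  if (size_range[1] <= 0 || size_range[2] > 1000 ||
      size_range[1] >= size_range[2])
    stop("lobule_sim_config: size range must be within (0, 1000) um")
  class(cfg) <- "LobuleSimConfig"
  cfg
}

landmark_gene_names <- function(cfg) {
  list(central = sprintf("cLM%02d", seq_len(cfg$n_landmarks)),
       portal = sprintf("pLM%02d", seq_len(cfg$n_landmarks)))
}

#' Simulate a fragment experiment over a liver lobule axis
#'
#' Draws a true zonation coordinate per fragment, assigns a proximity label
#' and a per-fragment cell population, and generates negative-binomial UMI
#' counts whose log-mean is linear in the true coordinate for landmark and
#' planted zonated genes (restricted to their carrier cell type). Landmark
#' genes form two monotone opposed gradients in LECs.
#'
#' @param cfg A [lobule_sim_config()].
#' @param seed Integer seed; the run is fully reproducible under it.
#' @return `list(experiment = FragmentExperiment, truth = list(...))` where
#'   `truth` carries `zc` (true coordinate per fragment), `proximity`,
#'   per-cell `fragment`/`type`, and the planted zonated-gene table.
#' @export
simulate_lobule_experiment <- function(cfg = lobule_sim_config(), seed = 1) {
  if (cfg$n_fragments < 1) stop("simulate_lobule_experiment: 0 fragments")
  set.seed(seed)
  nf <- cfg$n_fragments
  frag_ids <- sprintf("F%03d", seq_len(nf))
  samples <- paste0("S", rep_len(seq_len(cfg$n_samples), nf))

  zc <- if (cfg$zc_distribution == "uniform") stats::runif(nf) else {
    z <- stats::rnorm(nf, 0.5, 0.2)
    while (any(z < 0 | z > 1)) {
      bad <- z < 0 | z > 1
      z[bad] <- stats::rnorm(sum(bad), 0.5, 0.2)
    }
    z
  }
  proximity <- ifelse(stats::runif(nf) < cfg$proximal_frac,
                      "proximal", "distal")

  n_cells <- pmax(5L, stats::rnbinom(nf, mu = cfg$cells_mean,
                                     size = cfg$cells_dispersion))
  cell_frag <- rep(frag_ids, n_cells)
  cell_sample <- rep(samples, n_cells)
  ncell <- length(cell_frag)
  cell_ids <- sprintf("C%05d", seq_len(ncell))

  # per-cell type draw, proximity-shifted composition
  comp <- matrix(rep(cfg$composition, nf), nrow = nf, byrow = TRUE,
                 dimnames = list(frag_ids, cfg$cell_types))
  shift <- cfg$proximal_shift[names(cfg$proximal_shift) %in% cfg$cell_types]
  prox_rows <- proximity == "proximal"
  for (ty in names(shift)) comp[prox_rows, ty] <- comp[prox_rows, ty] * shift[[ty]]
  comp <- comp / rowSums(comp)
  cell_type <- character(ncell)
  for (f in seq_len(nf)) {
    idx <- which(cell_frag == frag_ids[f])
    cell_type[idx] <- sample(cfg$cell_types, length(idx), replace = TRUE,
                             prob = comp[f, ])
  }

  lm <- landmark_gene_names(cfg)
  planted <- cfg$zonated_genes
  if (!is.null(planted) &&
      !all(c("gene", "type", "slope") %in% names(planted)))
    stop("simulate_lobule_experiment: zonated_genes needs gene/type/slope")
  null_genes <- if (cfg$n_null_genes > 0)
    sprintf("G%03d", seq_len(cfg$n_null_genes)) else character()
  genes <- c(lm$central, lm$portal,
             if (!is.null(planted)) planted$gene, null_genes)
  if (!length(genes)) stop("simulate_lobule_experiment: empty gene panel")
  if (anyDuplicated(genes))
    stop("simulate_lobule_experiment: duplicate gene names in panel")

  # per-gene slope and carrier type (NA carrier = all types)
  slope <- c(rep(-cfg$landmark_slope, length(lm$central)),
             rep(cfg$landmark_slope, length(lm$portal)),
             if (!is.null(planted)) planted$slope,
             rep(0, length(null_genes)))
  carrier <- c(rep("LEC", 2 * cfg$n_landmarks),
               if (!is.null(planted)) planted$type,
               rep(NA_character_, length(null_genes)))
  base <- c(rep(cfg$landmark_base, 2 * cfg$n_landmarks),
            if (!is.null(planted)) rep(cfg$null_base, nrow(planted)),
            rep(cfg$null_base, length(null_genes)))

  zc_cell <- zc[match(cell_frag, frag_ids)]
  depth <- rep_len(cfg$sample_effect, cfg$n_samples)[
    as.integer(sub("^S", "", cell_sample))]
  counts <- matrix(0L, nrow = length(genes), ncol = ncell,
                   dimnames = list(genes, cell_ids))
  for (g in seq_along(genes)) {
    mu <- rep(0.02, ncell)  # off-carrier leak
    on <- if (is.na(carrier[g])) rep(TRUE, ncell) else cell_type == carrier[g]
    mu[on] <- base[g] * exp(slope[g] * (zc_cell[on] - 0.5))
    mu <- mu * depth
    counts[g, ] <- stats::rnbinom(ncell, mu = mu, size = cfg$nb_size)
  }

  fragments <- fragment_table(frag_ids, well = frag_ids, sample = samples)
  size <- stats::runif(nf, cfg$size_range[1], cfg$size_range[2])
  fragments$tof <- cfg$tof_slope * size + cfg$tof_intercept +
    stats::rnorm(nf, 0, cfg$tof_noise_sd)
  fragments$extinction <- 0.5 * size + stats::rnorm(nf, 0, 5)
  cells <- cell_annotation(cell_ids, sample = cell_sample,
                           fragment = cell_frag, type = cell_type)
  exp <- fragment_experiment(count_matrix(counts), cells, fragments)

  truth <- list(zc = stats::setNames(zc, frag_ids),
                proximity = stats::setNames(proximity, frag_ids),
                size = stats::setNames(size, frag_ids),
                cell_fragment = stats::setNames(cell_frag, cell_ids),
                cell_type = stats::setNames(cell_type, cell_ids),
                zonated_genes = data.frame(
                  gene = c(lm$central, lm$portal,
                           if (!is.null(planted)) planted$gene),
                  type = c(rep("LEC", 2 * cfg$n_landmarks),
                           if (!is.null(planted)) planted$type),
                  slope = c(rep(-cfg$landmark_slope, cfg$n_landmarks),
                            rep(cfg$landmark_slope, cfg$n_landmarks),
                            if (!is.null(planted)) planted$slope)))
  list(experiment = exp, truth = truth)
}

#' Build a landmark reference panel matching the simulator's gradients
#'
#' Layer means follow the simulator's log-linear model evaluated at the
#' layer midpoints; SEMs are a stated fraction of the mean, so the panel
#' passes the landmark quality filter by construction.
#'
#' @param cfg A [lobule_sim_config()].
#' @param n_layers Number of reference lobule layers (9 or 10).
#' @param sem_frac SEM as a fraction of the layer mean.
#' @return A landmark panel (see [landmark_panel()]).
#' @export
simulate_landmark_panel <- function(cfg = lobule_sim_config(), n_layers = 10,
                                    sem_frac = 0.1) {
  lm <- landmark_gene_names(cfg)
  genes <- c(lm$central, lm$portal)
  zone <- rep(c("central", "portal"), each = cfg$n_landmarks)
  mids <- (seq_len(n_layers) - 0.5) / n_layers
  sl <- ifelse(zone == "portal", cfg$landmark_slope, -cfg$landmark_slope)
  means <- outer(sl, mids - 0.5, function(s, z) cfg$landmark_base * exp(s * z))
  landmark_panel(genes, zone, means, means * sem_frac)
}

#' Simulate hashing-barcode UMI counts for classified cells
#'
#' One barcode per fragment. A cell's assigned barcode is Poisson with the
#' signal mean; every other barcode is Poisson with the background mean.
#' Doublet cells receive a second signal barcode from another fragment;
#' negative cells receive background everywhere.
#'
#' @param cell_fragment Named character vector (names = cell ids, values =
#'   true fragment id), e.g. `truth$cell_fragment` from the simulator.
#' @param cfg A [lobule_sim_config()] supplying the hashing parameters.
#' @param seed Integer seed.
#' @return `list(counts = barcode-by-cell count matrix, truth = data.frame
#'   (cell, fragment, call))` with `call` in POSITIVE/DOUBLET/NEGATIVE,
#'   plus `barcode_of` mapping fragment to barcode id.
#' @export
simulate_hashing_counts <- function(cell_fragment,
                                    cfg = lobule_sim_config(), seed = 1) {
  set.seed(seed)
  frags <- sort(unique(cell_fragment))
  if (!length(frags)) stop("simulate_hashing_counts: no fragments")
  barcodes <- sprintf("BC%03d", seq_along(frags))
  names(barcodes) <- frags
  ncell <- length(cell_fragment)
  cells <- names(cell_fragment)
  u <- stats::runif(ncell)
  call <- ifelse(u < cfg$negative_rate, "NEGATIVE",
                 ifelse(u < cfg$negative_rate + cfg$doublet_rate,
                        "DOUBLET", "POSITIVE"))
  if (length(frags) < 2) call[call == "DOUBLET"] <- "POSITIVE"
  counts <- matrix(stats::rpois(length(frags) * ncell,
                                cfg$hash_background),
                   nrow = length(frags), ncol = ncell,
                   dimnames = list(barcodes, cells))
  own <- match(cell_fragment, frags)
  pos <- call != "NEGATIVE"
  counts[cbind(own[pos], which(pos))] <-
    stats::rpois(sum(pos), cfg$hash_signal)
  dbl <- which(call == "DOUBLET")
  if (length(dbl)) {
    other <- vapply(own[dbl], function(o)
      sample(setdiff(seq_along(frags), o), 1L), 1L)
    counts[cbind(other, dbl)] <- stats::rpois(length(dbl), cfg$hash_signal)
  }
  list(counts = count_matrix(counts),
       truth = data.frame(cell = cells, fragment = unname(cell_fragment),
                          call = call, stringsAsFactors = FALSE),
       barcode_of = barcodes)
}

#' Simulate a two-species organoid mixing experiment
#'
#' Each fragment (well) carries one species; each cell's observed species
#' flips with probability `mismatch_rate`, emulating sorting or assignment
#' errors.
#'
#' @param n_fragments,cells_per_fragment Experiment scale.
#' @param mismatch_rate Per-cell flip probability in \[0, 1\].
#' @param seed Integer seed.
#' @return `list(cells = CellAnnotation with species, fragments =
#'   fragment table with a `well_species` column)`.
#' @export
simulate_species_mixing <- function(n_fragments = 50,
                                    cells_per_fragment = 20,
                                    mismatch_rate = 0.05, seed = 1) {
  if (mismatch_rate < 0 || mismatch_rate > 1)
    stop("simulate_species_mixing: mismatch_rate must be in [0,1]")
  set.seed(seed)
  frag_ids <- sprintf("W%03d", seq_len(n_fragments))
  well_species <- rep_len(c("mouse", "human"), n_fragments)
  cell_frag <- rep(frag_ids, each = cells_per_fragment)
  ncell <- length(cell_frag)
  truth_species <- well_species[match(cell_frag, frag_ids)]
  flip <- stats::runif(ncell) < mismatch_rate
  obs <- ifelse(flip, ifelse(truth_species == "mouse", "human", "mouse"),
                truth_species)
  cells <- cell_annotation(sprintf("C%05d", seq_len(ncell)),
                           fragment = cell_frag, species = obs)
  fragments <- fragment_table(frag_ids)
  fragments$well_species <- well_species
  fragments$n_cells <- as.integer(table(cell_frag)[fragments$fragment])
  list(cells = cells, fragments = fragments)
}

#' Simulate a segmented 2-D point pattern with planted attraction
#'
#' Cells are dropped uniformly into rectangular regions of interest (ROIs);
#' for each attraction pair, a stated fraction of B-type cells is placed
#' within `pair_distance` of a random A-type cell, planting colocalization.
#'
#' @param n_cells_per_type Named integer vector: cells of each type per ROI.
#' @param roi_size ROI width/height in micrometres (square ROI).
#' @param attraction `NULL` or data frame with columns `type_a`, `type_b`,
#'   `fraction_paired`, `pair_distance` and optionally `group` (label the
#'   attraction is restricted to; `NA` = all groups).
#' @param n_rois ROIs per group per slide.
#' @param group_labels Labels of the two ROI groups.
#' @param n_slides Number of slides.
#' @param seed Integer seed.
#' @return A `SpatialCellMap` data frame: `x`, `y` (um), `type`, `roi`,
#'   `group`, `slide`.
#' @export
simulate_point_pattern <- function(n_cells_per_type = c(A = 100, B = 100),
                                   roi_size = 200, attraction = NULL,
                                   n_rois = 4,
                                   group_labels = c("distal", "proximal"),
                                   n_slides = 1, seed = 1) {
  if (!is.null(attraction) &&
      any(attraction$pair_distance >= roi_size))
    stop("simulate_point_pattern: pair_distance must be below ROI extent")
  set.seed(seed)
  out <- list()
  for (sl in seq_len(n_slides)) for (g in group_labels)
    for (r in seq_len(n_rois)) {
      roi_id <- sprintf("slide%d_%s_roi%d", sl, g, r)
      pts <- lapply(names(n_cells_per_type), function(ty) {
        n <- n_cells_per_type[[ty]]
        data.frame(x = stats::runif(n, 0, roi_size),
                   y = stats::runif(n, 0, roi_size),
                   type = rep(ty, n), stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, pts)
      if (!is.null(attraction)) for (i in seq_len(nrow(attraction))) {
        a <- attraction[i, ]
        if (!is.null(a$group) && !is.na(a$group) && a$group != g) next
        ia <- which(df$type == a$type_a)
        ib <- which(df$type == a$type_b)
        if (!length(ia) || !length(ib)) next
        nb <- round(a$fraction_paired * length(ib))
        if (nb < 1) next
        move <- sample(ib, nb)
        # spread pairs over distinct anchors where possible
        anchor <- sample(ia, nb, replace = nb > length(ia))
        ang <- stats::runif(nb, 0, 2 * pi)
        rad <- stats::runif(nb, 0, a$pair_distance)
        df$x[move] <- pmin(pmax(df$x[anchor] + rad * cos(ang), 0), roi_size)
        df$y[move] <- pmin(pmax(df$y[anchor] + rad * sin(ang), 0), roi_size)
      }
      df$roi <- roi_id
      df$group <- g
      df$slide <- paste0("slide", sl)
      out[[roi_id]] <- df
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
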