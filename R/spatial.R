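# Post-segmentation operators for imaging-based validation data: label
# expansion, transcript-to-cell assignment, segment-size filtering, area
# annotation, radius neighbor graphs, and the colocalization permutation
# test.

#' Construct a label image
#'
#' Integer matrix where 0 is background and k > 0 marks segment k, with a
#' physical pixel size.
#'
#' @param mat Integer matrix of labels.
#' @param pixel_size Micrometres per pixel (> 0).
#' @return A `LabelImage` (matrix with a `pixel_size` attribute).
#' @export
label_image <- function(mat, pixel_size = 1) {
  mat <- as.matrix(mat)
  if (any(mat < 0) || any(mat != floor(mat)))
    stop("label_image: labels must be non-negative integers")
  if (pixel_size <= 0) stop("label_image: pixel size must be positive")
  structure(mat, pixel_size = pixel_size, class = c("LabelImage", "matrix"))
}

#' Read / write a label image as a plain integer text grid
#' @param path Whitespace-delimited text file, one image row per line.
#' @param pixel_size Micrometres per pixel.
#' @export
read_label_image <- function(path, pixel_size = 1) {
  label_image(as.matrix(utils::read.table(path)), pixel_size)
}

#' @rdname read_label_image
#' @param img A `LabelImage`.
#' @export
write_label_image <- function(img, path) {
  utils::write.table(unclass(img), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Expand segment labels into surrounding background
#'
#' Every background pixel whose Euclidean distance to the nearest labelled
#' pixel is at most `distance` adopts that pixel's label; original labels
#' never change and segments never merge. Distance ties go to the smaller
#' label id.
#'
#' @param img A `LabelImage`.
#' @param distance Expansion radius; in pixels by default, in micrometres
#'   with `units = "um"`.
#' @param units `"pixels"` or `"um"`.
#' @return The expanded `LabelImage`.
#' @export
expand_labels <- function(img, distance, units = c("pixels", "um")) {
  units <- match.arg(units)
  if (distance < 0) stop("expand_labels: distance must be >= 0")
  ps <- attr(img, "pixel_size")
  d_px <- if (units == "um") distance / ps else distance
  m <- unclass(img)
  if (d_px == 0 || !any(m > 0) || !any(m == 0)) return(img)
  lab_idx <- which(m > 0)
  nr <- nrow(m)
  lab_rc <- cbind((lab_idx - 1) %% nr + 1, (lab_idx - 1) %/% nr + 1)
  lab_val <- m[lab_idx]
  o <- order(lab_val)          # smaller label wins distance ties
  lab_rc <- lab_rc[o, , drop = FALSE]
  lab_val <- lab_val[o]
  bg_idx <- which(m == 0)
  bg_rc <- cbind((bg_idx - 1) %% nr + 1, (bg_idx - 1) %/% nr + 1)
  out <- m
  chunk <- max(1L, floor(4e6 / nrow(lab_rc)))
  for (s in seq(1, length(bg_idx), by = chunk)) {
    e <- min(s + chunk - 1, length(bg_idx))
    dr <- outer(bg_rc[s:e, 1], lab_rc[, 1], "-")
    dc <- outer(bg_rc[s:e, 2], lab_rc[, 2], "-")
    d2 <- dr * dr + dc * dc
    nearest <- max.col(-d2, ties.method = "first")
    dist <- sqrt(d2[cbind(seq_len(e - s + 1), nearest)])
    hit <- dist <= d_px
    out[bg_idx[s:e][hit]] <- lab_val[nearest[hit]]
  }
  label_image(out, ps)
}

#' Assign transcripts to (expanded) segments
#'
#' Each transcript is assigned the label of its containing pixel; label 0
#' means unassigned. Coordinates are in micrometres with the origin at the
#' image corner; pixel (r, c) covers y in \[(r-1), r) and x in \[(c-1), c)
#' pixel sizes.
#'
#' @param img A `LabelImage` (typically after [expand_labels()]).
#' @param transcripts Data frame with `x`, `y` (um) and `gene`.
#' @return A gene-by-segment count matrix (segments as columns named by
#'   label); attributes `n_unassigned` (background hits) and
#'   `n_out_of_bounds` (dropped) conserve totals.
#' @export
assign_transcripts <- function(img, transcripts) {
  ps <- attr(img, "pixel_size")
  m <- unclass(img)
  if (any(!is.finite(transcripts$x)) || any(!is.finite(transcripts$y)))
    stop("assign_transcripts: coordinates must be finite")
  col <- floor(transcripts$x / ps) + 1L
  row <- floor(transcripts$y / ps) + 1L
  inb <- row >= 1 & row <= nrow(m) & col >= 1 & col <= ncol(m)
  lab <- rep(NA_integer_, nrow(transcripts))
  lab[inb] <- m[cbind(row[inb], col[inb])]
  segs <- sort(unique(m[m > 0]))
  assigned <- inb & lab > 0
  cm <- table(factor(transcripts$gene[assigned],
                     levels = sort(unique(transcripts$gene))),
              factor(lab[assigned], levels = segs))
  out <- count_matrix(matrix(as.integer(cm), nrow = nrow(cm),
                             dimnames = list(rownames(cm),
                                             as.character(segs))))
  attr(out, "n_unassigned") <- sum(inb & lab == 0)
  attr(out, "n_out_of_bounds") <- sum(!inb)
  out
}

#' Remove oversized segments by a MAD rule
#'
#' Segments whose pixel area exceeds `median + k_mad * MAD` of the segment
#' areas are removed (set to background). The MAD is the raw median
#' absolute deviation (no normal-consistency scaling).
#'
#' @param img A `LabelImage` with at least one segment.
#' @param k_mad MAD multiplier (default 4).
#' @return The filtered `LabelImage`; attribute `removed` lists removed
#'   segment ids.
#' @export
filter_segments_by_area <- function(img, k_mad = 4) {
  m <- unclass(img)
  if (!any(m > 0)) stop("filter_segments_by_area: no segments")
  areas <- table(m[m > 0])
  a <- as.numeric(areas)
  cutoff <- stats::median(a) + k_mad * stats::mad(a, constant = 1)
  removed <- as.integer(names(areas)[a > cutoff])
  if (length(removed) == length(areas))
    warning("filter_segments_by_area: all segments removed")
  m[m %in% removed] <- 0L
  out <- label_image(m, attr(img, "pixel_size"))
  attr(out, "removed") <- removed
  out
}

# crossing-free point-in-polygon via pracma; closed boundary convention
in_polygon <- function(x, y, poly_x, poly_y) {
  pracma::inpolygon(x, y, poly_x, poly_y, boundary = TRUE)
}

#' Annotate cells by manually drawn feature areas
#'
#' Point-in-polygon assignment of cell centroids to named areas (closed
#' boundary: a cell exactly on an edge counts as inside). Cells inside
#' several polygons take the first-listed one (warned); cells outside all
#' polygons keep `NA`.
#'
#' @param cells `SpatialCellMap` data frame with `x`, `y`.
#' @param polygons Data frame of vertices in draw order: `area`, `group`,
#'   `x`, `y`.
#' @return `cells` with `roi` and `group` columns set from the areas.
#' @export
annotate_areas <- function(cells, polygons) {
  areas <- unique(polygons$area)
  cells$roi <- NA_character_
  cells$group <- NA_character_
  overlap <- FALSE
  for (a in areas) {
    pv <- polygons[polygons$area == a, , drop = FALSE]
    if (nrow(pv) < 3)
      stop("annotate_areas: polygon '", a, "' has fewer than 3 vertices")
    inside <- in_polygon(cells$x, cells$y, pv$x, pv$y)
    overlap <- overlap || any(inside & !is.na(cells$roi))
    take <- inside & is.na(cells$roi)
    cells$roi[take] <- a
    cells$group[take] <- pv$group[1]
  }
  if (overlap)
    warning("annotate_areas: overlapping polygons, first-listed area wins")
  cells
}

#' Radius neighbor graph of cell centroids
#'
#' Undirected simple graph with an edge between two cells iff their
#' Euclidean distance is strictly below `radius`. Built with a
#' grid-bucket radius search (no full distance matrix). Per-vertex
#' neighbor lists are truncated at the `k_cap - 1` nearest neighbors; a
#' warning recommends a larger cap when any vertex saturates, since a
#' saturated cap silently drops edges.
#'
#' @param cells Data frame with `x`, `y` in micrometres.
#' @param radius Connection radius (um), default 10.
#' @param k_cap Neighbor cap including self (default 41, i.e. at most 40
#'   neighbors per vertex).
#' @return Two-column integer matrix of edges (i < j, row indices into
#'   `cells`).
#' @export
build_neighbor_graph <- function(cells, radius = 10, k_cap = 41) {
  if (radius <= 0) stop("build_neighbor_graph: radius must be positive")
  n <- nrow(cells)
  if (n < 2) return(matrix(integer(), 0, 2))
  gx <- floor(cells$x / radius)
  gy <- floor(cells$y / radius)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  bx <- as.numeric(sub(" .*", "", names(buckets)))
  by <- as.numeric(sub(".* ", "", names(buckets)))
  bkey <- stats::setNames(seq_along(buckets), names(buckets))
  ei <- integer(); ej <- integer(); ed <- numeric()
  for (b in seq_along(buckets)) {
    pts <- buckets[[b]]
    for (dx in -1:1) for (dy in -1:1) {
      nb <- bkey[paste(bx[b] + dx, by[b] + dy)]
      if (is.na(nb) || nb < b) next
      qts <- buckets[[nb]]
      dmat <- sqrt(outer(cells$x[pts], cells$x[qts], "-")^2 +
                     outer(cells$y[pts], cells$y[qts], "-")^2)
      hit <- which(dmat < radius, arr.ind = TRUE)
      a <- pts[hit[, 1]]; b2 <- qts[hit[, 2]]
      keep <- if (nb == b) a < b2 else a != b2
      ei <- c(ei, pmin(a, b2)[keep]); ej <- c(ej, pmax(a, b2)[keep])
      ed <- c(ed, dmat[hit][keep])
    }
  }
  if (!length(ei)) return(matrix(integer(), 0, 2))
  deg <- tabulate(ei, n) + tabulate(ej, n)
  if (any(deg > k_cap - 1)) {
    warning("build_neighbor_graph: ", sum(deg > k_cap - 1),
            " vertex/vertices exceed the neighbor cap (k_cap = ", k_cap,
            "); increase k_cap to keep all edges")
    ord <- order(ed)
    keepq <- logical(length(ei))
    cnt <- integer(n)
    for (e in ord) {
      a <- ei[e]; b2 <- ej[e]
      if (cnt[a] < k_cap - 1 && cnt[b2] < k_cap - 1) {
        keepq[e] <- TRUE
        cnt[a] <- cnt[a] + 1L
        cnt[b2] <- cnt[b2] + 1L
      }
    }
    ei <- ei[keepq]; ej <- ej[keepq]
  }
  cbind(i = ei, j = ej)
}

# Normalized edge counts per unordered type pair for one ROI.
# edges: local index pairs; tt: integer type per local cell; K: n types.
# Returns a vector over pair slots (a <= b): E / (n_a + n_b), with
# denominator 2 n_a for same-type pairs; NA when both types absent.
pair_slots <- function(K) {
  idx <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

roi_pair_counts <- function(edges, tt, K, slots) {
  nt <- tabulate(tt, K)
  if (nrow(edges)) {
    a <- pmin(tt[edges[, 1]], tt[edges[, 2]])
    b <- pmax(tt[edges[, 1]], tt[edges[, 2]])
    cnt <- tabulate((a - 1) * K + b, K * K)
  } else cnt <- integer(K * K)
  e <- cnt[(slots[, 1] - 1) * K + slots[, 2]]
  denom <- ifelse(slots[, 1] == slots[, 2], 2 * nt[slots[, 1]],
                  nt[slots[, 1]] + nt[slots[, 2]])
  out <- ifelse(denom > 0, e / pmax(denom, 1), NA_real_)
  out[denom == 0] <- NA_real_
  out
}

#' Colocalization permutation test between two ROI groups
#'
#' Per ROI, the number of neighbor-graph edges between each cell-type pair
#' is divided by the summed cell counts of the pair; per slide, the
#' difference of the per-group ROI means (`group2 - group1`) is compared
#' to a null built by permuting the type labels over the slide's vertices
#' (graph fixed), giving p = (b + 1)/(m + 1). The cross-slide score is the
#' signed fraction of slides in which the pair is significant.
#'
#' @param cells `SpatialCellMap` data frame: `x`, `y`, `type`, `roi`,
#'   `group`, `slide`.
#' @param radius Neighbor radius in micrometres (default 10).
#' @param contrast Length-2 character: the two group labels (difference is
#'   second minus first).
#' @param m Permutations per slide (default 1000).
#' @param seed Integer seed.
#' @param tail `"abs"` (default): b counts null |difference| >= observed
#'   |difference|, the sign carried into the score; `"upper"`: literal
#'   one-tail count (null >= observed).
#' @param k_cap Neighbor cap passed to [build_neighbor_graph()].
#' @param alpha Per-slide significance level entering the score (0.05).
#' @return A `ColocalizationTestResult`: list with `per_slide` (data
#'   frame: slide, type_a, type_b, observed, b, m, p) and `score` (data
#'   frame: type_a, type_b, score in \[-1, 1\]).
#' @export
colocalization_test <- function(cells, radius = 10,
                                contrast = c("distal", "proximal"),
                                m = 1000, seed = 1,
                                tail = c("abs", "upper"), k_cap = 41,
                                alpha = 0.05) {
  tail <- match.arg(tail)
  types <- sort(unique(cells$type))
  K <- length(types)
  slots <- pair_slots(K)
  res <- list()
  set.seed(seed)
  for (sl in unique(cells$slide)) {
    sc <- cells[cells$slide == sl, , drop = FALSE]
    rois <- unique(sc$roi)
    grp <- sc$group[match(rois, sc$roi)]
    if (!all(contrast %in% grp))
      stop("colocalization_test: slide ", sl,
           " lacks ROIs of both contrast groups")
    roi_edges <- list(); roi_cells <- list()
    for (r in rois) {
      w <- which(sc$roi == r)
      roi_cells[[r]] <- w
      roi_edges[[r]] <- build_neighbor_graph(sc[w, , drop = FALSE],
                                             radius, k_cap)
    }
    tt0 <- match(sc$type, types)
    stat <- function(tt) {
      per_roi <- vapply(rois, function(r)
        roi_pair_counts(roi_edges[[r]], tt[roi_cells[[r]]], K, slots),
        numeric(nrow(slots)))
      if (is.null(dim(per_roi)))
        per_roi <- matrix(per_roi, nrow = nrow(slots))
      g1 <- rowMeans(per_roi[, grp == contrast[1], drop = FALSE],
                     na.rm = TRUE)
      g2 <- rowMeans(per_roi[, grp == contrast[2], drop = FALSE],
                     na.rm = TRUE)
      g2 - g1
    }
    obs <- stat(tt0)
    b <- integer(nrow(slots))
    for (p in seq_len(m)) {
      nullv <- stat(tt0[sample.int(length(tt0))])
      b <- b + if (tail == "abs") (abs(nullv) >= abs(obs)) else
        (nullv >= obs)
    }
    res[[sl]] <- data.frame(slide = sl, type_a = types[slots[, 1]],
                            type_b = types[slots[, 2]],
                            observed = obs, b = b, m = m,
                            p = (b + 1) / (m + 1),
                            stringsAsFactors = FALSE)
  }
  per_slide <- do.call(rbind, res)
  rownames(per_slide) <- NULL
  key <- paste(per_slide$type_a, per_slide$type_b)
  score <- vapply(split(per_slide, key), function(d)
    sum(sign(d$observed) * (d$p < alpha), na.rm = TRUE) / nrow(d), 0)
  sc_df <- data.frame(
    type_a = sub(" .*", "", names(score)),
    type_b = sub(".* ", "", names(score)),
    score = unname(score), stringsAsFactors = FALSE)
  structure(list(per_slide = per_slide, score = sc_df),
            class = "ColocalizationTestResult")
}
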