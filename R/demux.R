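# Hashing-barcode design, cell-to-fragment classification and
# species-mixing scoring.

#' Design a DNA hashing-barcode set with a minimum Hamming distance
#'
#' Seeded random-candidate generation with greedy rejection: candidates are
#' drawn uniformly over \{A,C,G,T\}^length and accepted only when at least
#' `min_distance` substitutions away from every accepted barcode. The run
#' fails with a capacity error once the try budget is exhausted, so an
#' infeasible request terminates.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nucleotides (default 8 nt, typical for
#'   lipid-hashing oligos).
#' @param min_distance Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed.
#' @param max_tries Candidate budget before declaring the request
#'   infeasible.
#' @return A `BarcodeSet`: list with `sequences`, `length`, `min_distance`.
#' @export
design_barcodes <- function(n, length = 8, min_distance = 3, seed = 1,
                            max_tries = 2000 * n) {
  if (n < 1) stop("design_barcodes: n must be >= 1")
  if (min_distance < 1 || min_distance > length)
    stop("design_barcodes: need 1 <= min_distance <= length")
  if (n > 4^length)
    stop("design_barcodes: capacity error, n exceeds 4^length")
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  accepted <- matrix(0L, nrow = n, ncol = length)
  n_acc <- 0L
  tries <- 0L
  while (n_acc < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("design_barcodes: capacity error, could not place ", n,
           " barcodes of length ", length, " at distance ", min_distance,
           " within ", max_tries, " tries")
    cand <- sample.int(4L, length, replace = TRUE)
    ok <- if (n_acc == 0L) TRUE else {
      d <- rowSums(accepted[seq_len(n_acc), , drop = FALSE] !=
                     matrix(cand, n_acc, length, byrow = TRUE))
      all(d >= min_distance)
    }
    if (ok) {
      n_acc <- n_acc + 1L
      accepted[n_acc, ] <- cand
    }
  }
  seqs <- apply(accepted, 1, function(r) paste(alphabet[r], collapse = ""))
  structure(list(sequences = seqs, length = length,
                 min_distance = min_distance),
            class = "BarcodeSet")
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' Exhaustive O(n^2 L) check, used to verify designed sets post hoc.
#'
#' @param sequences Character vector of equal-length DNA strings, or a
#'   `BarcodeSet`.
#' @return The minimum Hamming distance over all pairs (Inf for < 2
#'   sequences).
#' @export
min_pairwise_hamming <- function(sequences) {
  if (inherits(sequences, "BarcodeSet")) sequences <- sequences$sequences
  n <- length(sequences)
  if (n < 2) return(Inf)
  L <- unique(nchar(sequences))
  if (length(L) != 1)
    stop("min_pairwise_hamming: sequences differ in length")
  m <- matrix(unlist(strsplit(sequences, "")), nrow = n, byrow = TRUE)
  best <- L
  for (i in seq_len(n - 1)) {
    d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, L, byrow = TRUE))
    best <- min(best, d)
    if (best == 0) break
  }
  best
}

#' Write a barcode set as FASTA and TSV
#' @param set A `BarcodeSet`.
#' @param fasta_path,tsv_path Output paths (either may be `NULL`).
#' @export
write_barcode_set <- function(set, fasta_path = NULL, tsv_path = NULL) {
  ids <- sprintf("BC%03d", seq_along(set$sequences))
  if (!is.null(fasta_path))
    writeLines(as.vector(rbind(paste0(">", ids), set$sequences)), fasta_path)
  if (!is.null(tsv_path))
    utils::write.table(data.frame(id = ids, sequence = set$sequences),
                       tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(set)
}

# Per-barcode threshold at sweep position q: the log1p count density of a
# barcode across cells is bimodal (background mode low, signal mode high);
# the threshold interpolates the interval between the two modes. Returns NA
# (no positive calls) for barcodes without two separated modes.
barcode_threshold <- function(x, q) {
  if (length(unique(x)) < 2) return(NA_real_)
  d <- tryCatch(stats::density(x, n = 256), error = function(e) NULL)
  if (is.null(d)) return(NA_real_)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) < 0) + 1L
  locmax <- union(locmax, c(if (y[1] > y[2]) 1L,
                            if (y[length(y)] > y[length(y) - 1]) length(y)))
  if (length(locmax) < 2) return(NA_real_)
  lo <- d$x[locmax[which.max(y[locmax])]]   # background mode: largest mass
  hi <- d$x[max(locmax)]                    # signal mode: right-most maximum
  if (hi <= lo) {
    hi <- d$x[max(setdiff(locmax, locmax[which.max(y[locmax])]))]
    if (hi <= lo) return(NA_real_)
  }
  lo + q * (hi - lo)
}

#' Classify cells to fragments from hashing-barcode counts
#'
#' Per-barcode thresholds on log1p counts are placed along the interval
#' between the background and signal modes of each barcode's count
#' distribution; a single sweep position `q` is chosen from `q_grid` as the
#' one maximizing the singlet fraction across all cells. A cell is then
#' NEGATIVE (0 barcodes above threshold), POSITIVE (exactly 1; assigned that
#' barcode's fragment), or DOUBLET (2 or more).
#'
#' @param barcode_counts Barcode-by-cell count matrix.
#' @param q_grid Sweep positions (default 0.10 to 0.90 step 0.05).
#' @param thresholds Optional fixed per-barcode thresholds on the log1p
#'   scale, bypassing the sweep (recycled).
#' @return A `ClassificationResult`: data frame (`cell`, `call`,
#'   `fragment`) with attributes `thresholds` and `q`. `fragment` holds the
#'   barcode id for POSITIVE cells and a sentinel otherwise.
#' @export
classify_cells <- function(barcode_counts,
                           q_grid = seq(0.1, 0.9, by = 0.05),
                           thresholds = NULL) {
  if (nrow(barcode_counts) < 1 || ncol(barcode_counts) < 1)
    stop("classify_cells: need at least one barcode and one cell")
  lg <- log1p(as.matrix(barcode_counts))
  if (all(lg == 0)) {
    warning("classify_cells: all-zero barcode matrix, all cells NEGATIVE")
    thresholds <- rep(Inf, nrow(lg))
  }
  q_used <- NA_real_
  if (is.null(thresholds)) {
    best <- -1
    for (q in q_grid) {
      thr <- apply(lg, 1, barcode_threshold, q = q)
      thr[is.na(thr)] <- Inf
      nab <- colSums(lg > thr)
      singlet <- mean(nab == 1)
      if (singlet > best) {
        best <- singlet
        thresholds <- thr
        q_used <- q
      }
    }
  } else {
    thresholds <- rep_len(thresholds, nrow(lg))
  }
  nab <- colSums(lg > thresholds)
  top <- rownames(lg)[apply(lg, 2, which.max)]
  call <- ifelse(nab == 0, "NEGATIVE", ifelse(nab == 1, "POSITIVE",
                                              "DOUBLET"))
  fragment <- ifelse(call == "POSITIVE",
                     top, FRAGMENT_SENTINELS[match(call, names(
                       FRAGMENT_SENTINELS))])
  # for positives the barcode above threshold is by construction the max
  res <- data.frame(cell = colnames(lg), call = call, fragment = fragment,
                    stringsAsFactors = FALSE)
  attr(res, "thresholds") <- thresholds
  attr(res, "q") <- q_used
  class(res) <- c("ClassificationResult", "data.frame")
  res
}

#' Write a classification result to CSV
#' @param result A `ClassificationResult`.
#' @param path Output path.
#' @export
write_classification <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Attach classified fragments to a whole-transcriptome experiment
#'
#' Matches classified cell barcodes with the cell barcodes of the count
#' matrix: POSITIVE cells get their fragment, NEGATIVE/DOUBLET cells their
#' sentinel, and cells absent from the hashing matrix become UNASSIGNED.
#' Per-fragment cell counts are recomputed.
#'
#' @param result A `ClassificationResult` (fragment column must reference
#'   fragment ids of `exp`, e.g. after mapping barcodes to wells).
#' @param exp A `FragmentExperiment`.
#' @param barcode_map Optional named vector translating barcode ids in
#'   `result$fragment` to fragment ids.
#' @return The experiment with updated cell annotation.
#' @export
attach_fragments <- function(result, exp, barcode_map = NULL) {
  fr <- result$fragment
  if (!is.null(barcode_map)) {
    hit <- fr %in% names(barcode_map)
    fr[hit] <- barcode_map[fr[hit]]
  }
  idx <- match(exp$cells$cell, result$cell)
  newfr <- ifelse(is.na(idx), FRAGMENT_SENTINELS[["UNASSIGNED"]], fr[idx])
  unknown <- !is_sentinel(newfr) & !(newfr %in% exp$fragments$fragment)
  if (any(unknown)) {
    warning("attach_fragments: ", sum(unknown),
            " cell(s) classified to unknown fragments; marked UNASSIGNED")
    newfr[unknown] <- FRAGMENT_SENTINELS[["UNASSIGNED"]]
  }
  exp$cells$fragment <- newfr
  recount_fragments(exp)
}

#' Score species-mixing assignment accuracy
#'
#' Applies the flip rule first: any fragment whose cells are 100%
#' mismatched has its well species flipped (such wells are attributed to a
#' fluorescence sorting error), then computes accuracy as matched /
#' assigned cells.
#'
#' @param cells Cell annotation with a `species` column and fragment
#'   assignments.
#' @param well_species Named character vector: expected species per
#'   fragment.
#' @param flip_threshold Mismatch fraction at which a well is flipped
#'   (default exactly 1).
#' @return List with `accuracy`, per-fragment data frame `per_fragment`
#'   (`fragment`, `n`, `mismatch_frac`, `flipped`), and `well_species`
#'   after flipping.
#' @export
score_species_mixing <- function(cells, well_species, flip_threshold = 1) {
  assigned <- cells[!is_sentinel(cells$fragment), , drop = FALSE]
  if (any(is.na(assigned$species)))
    stop("score_species_mixing: assigned cells must carry a species label")
  frs <- intersect(names(well_species), unique(assigned$fragment))
  mism <- vapply(frs, function(f) {
    sp <- assigned$species[assigned$fragment == f]
    mean(sp != well_species[[f]])
  }, 0)
  n <- vapply(frs, function(f) sum(assigned$fragment == f), 0L)
  keep <- n > 0
  frs <- frs[keep]; mism <- mism[keep]; n <- n[keep]
  flipped <- mism >= flip_threshold
  ws <- well_species
  ws[frs[flipped]] <- ifelse(ws[frs[flipped]] == "mouse", "human", "mouse")
  mism2 <- vapply(frs, function(f) {
    sp <- assigned$species[assigned$fragment == f]
    mean(sp != ws[[f]])
  }, 0)
  acc <- 1 - sum(mism2 * n) / sum(n)
  list(accuracy = acc,
       per_fragment = data.frame(fragment = frs, n = as.integer(n),
                                 mismatch_frac = unname(mism2),
                                 flipped = unname(flipped),
                                 stringsAsFactors = FALSE),
       well_species = ws)
}

#' Normalize a fluorescence channel by fragment size
#'
#' Divides the raw channel by the estimated fragment diameter to correct
#' for size-dependent autofluorescence.
#'
#' @param table Fragment table with `size` set for all fragments.
#' @param channel Column name of the raw channel (default
#'   `"fluorescence"`).
#' @return The table with an added `<channel>_per_um` column.
#' @export
normalize_fluorescence <- function(table, channel = "fluorescence") {
  if (!channel %in% names(table))
    stop("normalize_fluorescence: no such channel: ", channel)
  if (any(is.na(table$size) | table$size <= 0))
    stop("normalize_fluorescence: size must be set and positive")
  table[[paste0(channel, "_per_um")]] <- table[[channel]] / table$size
  table
}
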