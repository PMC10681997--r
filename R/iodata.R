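# Shared domain containers and readers/writers.
#
# Conventions: cell and fragment identifiers are opaque strings; sample id is
# its own column and is never parsed out of a cell id. MatrixMarket files are
# 1-based on disk (per the standard); everything in memory uses R's native
# 1-based indexing on named dimensions.

#' Reserved fragment-id sentinels
#'
#' Cells that could not be assigned to a fragment carry one of these reserved
#' strings in their `fragment` column. Sentinel-labelled cells are excluded
#' from every per-fragment statistic.
#'
#' @format Character vector of length 3: `NEGATIVE`, `DOUBLET`, `UNASSIGNED`.
#' @export
FRAGMENT_SENTINELS <- c(NEGATIVE = "NEGATIVE", DOUBLET = "DOUBLET",
                        UNASSIGNED = "UNASSIGNED")

is_sentinel <- function(x) x %in% FRAGMENT_SENTINELS

#' Construct a sparse gene-by-cell count matrix
#'
#' Validates and returns a `dgCMatrix` with gene rownames and cell colnames.
#' Entries must be non-negative integers (UMI counts).
#'
#' @param counts Matrix-like object (dense or sparse), genes in rows.
#' @param genes,cells Optional identifier vectors overriding dimnames.
#' @return A `dgCMatrix` satisfying the count-matrix invariants.
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         cells = colnames(counts)) {
  m <- if (is.matrix(counts))
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  else
    methods::as(methods::as(methods::as(counts, "dMatrix"),
                            "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(cells))
    stop("count_matrix: gene and cell identifiers are required")
  if (length(genes) != nrow(m) || length(cells) != ncol(m))
    stop("count_matrix: identifier lengths do not match matrix dimensions")
  dimnames(m) <- list(as.character(genes), as.character(cells))
  validate_count_matrix(m)
  m
}

validate_count_matrix <- function(m) {
  if (anyDuplicated(rownames(m)))
    stop("count matrix: duplicate gene identifiers")
  if (anyDuplicated(colnames(m)))
    stop("count matrix: duplicate cell identifiers")
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop("count matrix: entries must be non-negative integers")
  invisible(m)
}

#' Read a sparse count matrix from a MatrixMarket triplet
#'
#' @param mtx_path Path to the `.mtx` coordinate file.
#' @param genes_path Path to a headerless TSV whose first column holds gene
#'   identifiers, one per matrix row.
#' @param cells_path Same for cell identifiers (matrix columns).
#' @return A gene-by-cell `dgCMatrix`.
#' @export
read_count_matrix <- function(mtx_path, genes_path, cells_path) {
  for (p in c(mtx_path, genes_path, cells_path))
    if (!file.exists(p)) stop("read_count_matrix: no such file: ", p)
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.table(genes_path, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_path, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  if (length(genes) != nrow(m))
    stop("read_count_matrix: row count of ", mtx_path,
         " does not match ", genes_path)
  if (length(cells) != ncol(m))
    stop("read_count_matrix: column count of ", mtx_path,
         " does not match ", cells_path)
  count_matrix(m, genes, cells)
}

#' Write a count matrix as a MatrixMarket triplet with TSV sidecars
#'
#' Round-trips bit-exactly with [read_count_matrix()].
#'
#' @param m Count matrix (`dgCMatrix` with dimnames).
#' @param mtx_path,genes_path,cells_path Output paths.
#' @export
write_count_matrix <- function(m, mtx_path, genes_path, cells_path) {
  validate_count_matrix(m)
  Matrix::writeMM(m, mtx_path)
  writeLines(rownames(m), genes_path)
  writeLines(colnames(m), cells_path)
  invisible(c(mtx_path, genes_path, cells_path))
}

#' Construct a per-fragment metadata table
#'
#' One row per fragment with sorter readouts and (initially unset) derived
#' columns: estimated `size` in micrometres diameter, `n_cells`, and the
#' niche labels `layer`, `zone`, `proximity`, `cluster`.
#'
#' @param fragment Fragment identifiers (unique, no sentinels).
#' @param well,sample Well and sample identifiers.
#' @param tof Time-of-flight in sorter units.
#' @param extinction,fluorescence Optional sorter channels.
#' @return A `data.frame` with the canonical fragment-table columns.
#' @export
fragment_table <- function(fragment, well = fragment,
                           sample = "S1", tof = NA_real_,
                           extinction = NA_real_, fluorescence = NA_real_) {
  fragment <- as.character(fragment)
  if (anyDuplicated(fragment))
    stop("fragment_table: duplicate fragment identifiers")
  if (any(is_sentinel(fragment)))
    stop("fragment_table: reserved sentinel used as fragment id")
  data.frame(fragment = fragment, well = as.character(well),
             sample = as.character(sample), tof = as.numeric(tof),
             extinction = as.numeric(extinction),
             fluorescence = as.numeric(fluorescence),
             size = NA_real_, n_cells = NA_integer_,
             layer = NA_character_, zone = NA_character_,
             proximity = NA_character_, cluster = NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a biosorter well export
#'
#' Expects a CSV with one row per sorted well carrying at least the columns
#' named in `columns` (defaults: `well`, `TOF`, `extinction`; a fluorescence
#' column is optional). Size and niche fields are left unset.
#'
#' @param path CSV path.
#' @param columns Named character vector mapping the canonical quantities
#'   (`well`, `tof`, `extinction`, `fluorescence`) to the file's headers.
#' @param sample Sample identifier stored for all wells.
#' @return A fragment table (fragment id = well id).
#' @export
read_biosorter_export <- function(path,
                                  columns = c(well = "well", tof = "TOF",
                                              extinction = "extinction",
                                              fluorescence = "fluorescence"),
                                  sample = "S1") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (need in c("well", "tof", "extinction")) {
    if (!columns[[need]] %in% names(df))
      stop("read_biosorter_export: missing mandatory column '",
           columns[[need]], "' in ", path)
  }
  if (anyDuplicated(df[[columns[["well"]]]]))
    stop("read_biosorter_export: duplicate well id in ", path)
  fluo <- if (!is.na(columns["fluorescence"]) &&
              columns[["fluorescence"]] %in% names(df))
    df[[columns[["fluorescence"]]]] else NA_real_
  fragment_table(fragment = df[[columns[["well"]]]],
                 well = df[[columns[["well"]]]], sample = sample,
                 tof = df[[columns[["tof"]]]],
                 extinction = df[[columns[["extinction"]]]],
                 fluorescence = fluo)
}

#' Write a fragment table to CSV
#' @param table Fragment table.
#' @param path Output CSV path.
#' @export
write_fragment_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a fragment table written by [write_fragment_table()]
#' @param path CSV path.
#' @export
read_fragment_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fragment = "character",
                                       well = "character",
                                       sample = "character"))
  for (col in c("layer", "zone", "proximity", "cluster"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("tof", "extinction", "fluorescence", "size"))
    df[[col]] <- as.numeric(df[[col]])
  df$n_cells <- as.integer(df$n_cells)
  df
}

#' Construct a per-cell annotation table
#'
#' @param cell Unique cell identifiers.
#' @param sample Sample id per cell.
#' @param fragment Fragment id per cell, or a sentinel
#'   (`NEGATIVE`/`DOUBLET`/`UNASSIGNED`).
#' @param type Cell type label.
#' @param species Optional species label.
#' @return A `data.frame` with columns cell, sample, fragment, type, species.
#' @export
cell_annotation <- function(cell, sample = "S1",
                            fragment = FRAGMENT_SENTINELS[["UNASSIGNED"]],
                            type = NA_character_, species = NA_character_) {
  cell <- as.character(cell)
  if (anyDuplicated(cell)) stop("cell_annotation: duplicate cell identifiers")
  data.frame(cell = cell, sample = as.character(sample),
             fragment = as.character(fragment), type = as.character(type),
             species = as.character(species), stringsAsFactors = FALSE)
}

#' Bundle counts, cell annotation and fragment table into one experiment
#'
#' The central container consumed by every downstream stage.
#'
#' @param counts Gene-by-cell count matrix (see [count_matrix()]).
#' @param cells Cell annotation (see [cell_annotation()]).
#' @param fragments Fragment table (see [fragment_table()]).
#' @param recount If `TRUE` (default) recompute `n_cells` from the
#'   annotation.
#' @return An object of class `FragmentExperiment`.
#' @export
fragment_experiment <- function(counts, cells, fragments, recount = TRUE) {
  x <- structure(list(counts = counts, cells = cells, fragments = fragments),
                 class = "FragmentExperiment")
  if (recount) x <- recount_fragments(x)
  v <- validate_experiment(x)
  if (length(v)) stop("fragment_experiment: ", paste(v, collapse = "; "))
  x
}

#' Recompute per-fragment cell counts from the annotation
#' @param exp A `FragmentExperiment`.
#' @export
recount_fragments <- function(exp) {
  tab <- table(exp$cells$fragment[!is_sentinel(exp$cells$fragment)])
  n <- as.integer(tab[exp$fragments$fragment])
  n[is.na(n)] <- 0L
  exp$fragments$n_cells <- n
  exp
}

#' List cross-reference violations of an experiment
#'
#' Reports (never throws) every violated invariant: annotated cells missing
#' from the matrix, unknown fragment references, and stale `n_cells`.
#'
#' @param exp A `FragmentExperiment`.
#' @return Character vector of violation descriptions; empty if consistent.
#' @export
validate_experiment <- function(exp) {
  out <- character()
  bad <- setdiff(exp$cells$cell, colnames(exp$counts))
  if (length(bad))
    out <- c(out, paste0(length(bad), " annotated cell(s) not in count matrix"))
  if (anyDuplicated(exp$cells$cell))
    out <- c(out, "duplicate cell identifiers in annotation")
  fr <- exp$cells$fragment
  unknown <- setdiff(fr[!is_sentinel(fr)], exp$fragments$fragment)
  if (length(unknown))
    out <- c(out, paste0("cell(s) reference unknown fragment(s): ",
                         paste(utils::head(unknown, 5), collapse = ", ")))
  if (anyDuplicated(exp$fragments$fragment))
    out <- c(out, "duplicate fragment identifiers")
  sz <- exp$fragments$size
  if (any(!is.na(sz) & sz <= 0)) out <- c(out, "non-positive fragment size")
  tab <- table(fr[!is_sentinel(fr)])
  expected <- as.integer(tab[exp$fragments$fragment])
  expected[is.na(expected)] <- 0L
  got <- exp$fragments$n_cells
  mismatch <- !is.na(got) & got != expected
  if (any(mismatch))
    out <- c(out, paste0("n_cells stale for ", sum(mismatch), " fragment(s)"))
  out
}

#' @export
print.FragmentExperiment <- function(x, ...) {
  cat("FragmentExperiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", nrow(x$fragments), "fragments\n")
  calls <- table(factor(ifelse(is_sentinel(x$cells$fragment),
                               x$cells$fragment, "assigned"),
                        levels = c("assigned", FRAGMENT_SENTINELS)))
  cat("  cells:", paste(names(calls), as.integer(calls), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset an experiment to a set of cells
#' @param exp A `FragmentExperiment`.
#' @param cell_ids Cells to keep.
#' @export
subset_cells <- function(exp, cell_ids) {
  keep <- exp$cells$cell %in% cell_ids
  exp$cells <- exp$cells[keep, , drop = FALSE]
  exp$counts <- exp$counts[, exp$cells$cell, drop = FALSE]
  recount_fragments(exp)
}

#' Read a ligand-receptor interaction database
#'
#' CSV with columns `id`, `ligand`, `receptor`; multi-subunit complexes are
#' semicolon-joined gene lists. Component order is preserved.
#'
#' @param path CSV path.
#' @return A `data.frame` with list-columns `ligand` and `receptor`.
#' @export
read_lr_database <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (need in c("id", "ligand", "receptor"))
    if (!need %in% names(df))
      stop("read_lr_database: missing column '", need, "' in ", path)
  lr_database(df$id, df$ligand, df$receptor)
}

#' Construct a ligand-receptor database from component strings
#' @param id Interaction identifiers.
#' @param ligand,receptor Semicolon-joined component gene names (or lists).
#' @export
lr_database <- function(id, ligand, receptor) {
  split1 <- function(x, what) {
    parts <- if (is.list(x)) x else strsplit(as.character(x), ";", fixed = TRUE)
    lapply(seq_along(parts), function(i) {
      p <- trimws(parts[[i]])
      if (!length(p) || any(!nzchar(p)))
        stop("lr_database: empty ", what, " component in interaction '",
             id[i], "'")
      p
    })
  }
  out <- data.frame(id = as.character(id), stringsAsFactors = FALSE)
  out$ligand <- split1(ligand, "ligand")
  out$receptor <- split1(receptor, "receptor")
  out
}

#' Write a ligand-receptor database to CSV
#' @param db Database from [lr_database()].
#' @param path Output path.
#' @export
write_lr_database <- function(db, path) {
  flat <- data.frame(id = db$id,
                     ligand = vapply(db$ligand, paste, "", collapse = ";"),
                     receptor = vapply(db$receptor, paste, "", collapse = ";"))
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
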