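# Configuration-driven orchestration of the pipeline stages with a hashed
# output manifest, so identical configuration and inputs give identical
# manifests.

run_config_defaults <- function() {
  list(seed = 1, outdir = "fragseq_out", n_fragments = 100,
       n_samples = 3, cells_mean = 30,
       stage_demux = TRUE, stage_sorter = TRUE, stage_zonation = TRUE,
       stage_stats = TRUE, stage_interactions = FALSE,
       min_cells = 5, radius = 10, n_perm = 1000)
}

#' Read a flat key=value run configuration
#'
#' One `key=value` per line; `#` starts a comment. Unknown keys are
#' rejected. Every stochastic stage draws from the single `seed`.
#'
#' @param path Configuration file path.
#' @return A named list (class `RunConfig`) merging the file over the
#'   defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("read_run_config: malformed line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  cfg <- run_config_defaults()
  unknown <- setdiff(keys, names(cfg))
  if (length(unknown))
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  for (i in seq_along(keys)) {
    old <- cfg[[keys[i]]]
    cfg[[keys[i]]] <- if (is.logical(old)) as.logical(vals[i]) else
      if (is.numeric(old)) as.numeric(vals[i]) else vals[i]
  }
  structure(cfg, class = "RunConfig")
}

#' Run the pipeline end to end from a configuration
#'
#' Simulates a fragment experiment (the package's input source when no
#' external data is given), then runs the enabled stages in order --
#' demultiplexing, sorter size annotation, zonation, zonated-gene
#' statistics, ligand-receptor scoring -- writing every output under
#' `outdir` and a manifest of file content hashes. A stage failure aborts
#' with the stage name and cause.
#'
#' @param config A `RunConfig` list (see [read_run_config()]) or a path to
#'   a configuration file.
#' @return Invisibly, the manifest data frame (`file`, `md5`); also
#'   written to `manifest.csv` in `outdir`, with a `run.log` recording
#'   every parameter actually used.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(run_config_defaults(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  log <- c(paste0("fragseq run, ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           paste0(names(cfg), " = ", vapply(cfg, paste, "", collapse = ",")))
  emit <- function(name, writer) {
    p <- file.path(cfg$outdir, name)
    writer(p)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("run_pipeline: stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  sim_cfg <- lobule_sim_config(n_fragments = cfg$n_fragments,
                               n_samples = cfg$n_samples,
                               cells_mean = cfg$cells_mean)
  sim <- stage("simulate", function()
    simulate_lobule_experiment(sim_cfg, seed = cfg$seed))
  exp <- sim$experiment
  emit("counts.mtx", function(p)
    write_count_matrix(exp$counts, p, file.path(cfg$outdir, "genes.tsv"),
                       file.path(cfg$outdir, "cells_ids.tsv")))
  outputs <- c(outputs, file.path(cfg$outdir, c("genes.tsv",
                                                "cells_ids.tsv")))

  if (isTRUE(cfg$stage_demux)) {
    hs <- stage("demux", function() {
      h <- simulate_hashing_counts(sim$truth$cell_fragment, sim_cfg,
                                   seed = cfg$seed + 1)
      cl <- classify_cells(h$counts)
      list(result = cl,
           exp = attach_fragments(cl, exp, barcode_map = stats::setNames(
             names(h$barcode_of), h$barcode_of)))
    })
    exp <- hs$exp
    emit("classification.csv", function(p) write_classification(hs$result, p))
  }

  if (isTRUE(cfg$stage_sorter)) {
    exp$fragments <- stage("sorter", function() {
      beads <- rep(c(60, 125, 175), each = 5)
      set.seed(cfg$seed + 2)
      tof <- sim_cfg$tof_slope * beads + sim_cfg$tof_intercept +
        stats::rnorm(length(beads), 0, sim_cfg$tof_noise_sd)
      suppressWarnings(size_from_tof(fit_calibration(beads, tof),
                                     exp$fragments))
    })
  }

  zon <- NULL
  if (isTRUE(cfg$stage_zonation)) {
    zon <- stage("zonation", function() {
      panel <- filter_landmarks(simulate_landmark_panel(sim_cfg))
      pb <- fragment_pseudobulk(exp, "LEC", min_cells = cfg$min_cells,
                                mode = "mean")
      group_zone(bin_layers(compute_zc(pb, panel)))
    })
    emit("zonation.csv", function(p)
      utils::write.csv(as.data.frame(zon), p, row.names = FALSE))
  }

  if (isTRUE(cfg$stage_stats) && !is.null(zon)) {
    de <- stage("stats", function() {
      pb <- fragment_pseudobulk(exp, "LEC", min_cells = cfg$min_cells,
                                mode = "sum")
      zl <- bin_layers(zon, merge_extremes = TRUE)
      common <- intersect(rownames(pb), zl$fragment)
      i <- match(common, zl$fragment)
      zonated_de(pb[common, , drop = FALSE], zl$layer[i],
                 exp$fragments$sample[match(common,
                                            exp$fragments$fragment)])
    })
    emit("zonated_de.csv", function(p) write_de_result(de, p))
  }

  if (isTRUE(cfg$stage_interactions) && !is.null(zon)) {
    lr <- stage("interactions", function() {
      db <- lr_database("pLM01_cLM01", "pLM01", "cLM01")
      zone_of <- stats::setNames(zon$zone, zon$fragment)
      res <- lapply(c("central", "portal"), function(z) {
        frs <- names(zone_of)[zone_of == z]
        sub <- subset_cells(exp, exp$cells$cell[exp$cells$fragment %in% frs])
        score_interactions(sub, db, "LEC", "LEC", n_perm = cfg$n_perm,
                           seed = cfg$seed + 3)
      })
      compare_groups(res[[1]], res[[2]])
    })
    emit("lr_comparison.csv", function(p) write_interactions(lr, p))
  }

  emit("fragments.csv", function(p) write_fragment_table(exp$fragments, p))
  emit("cells.csv", function(p)
    utils::write.csv(exp$cells, p, row.names = FALSE))
  writeLines(log, file.path(cfg$outdir, "run.log"))

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(cfg$outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
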