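#' Run configuration for the pipeline commands
#'
#' Collects stage parameters and input/output paths for [run_pipeline()].
#' Unknown keys are rejected so a configuration file cannot silently
#' misspell a parameter, and a configuration round-trips losslessly through
#' YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param seed root RNG seed for all randomized stages; when absent one is
#'   drawn, logged and embedded in outputs.
#' @param simulate,sticr,trackerseq,coupling,mapping,collide named lists of
#'   per-stage overrides (see Details in the pipeline help).
#' @param inputs named list of input paths (`reads`, `pools`,
#'   `annotation`, `embryonic`, `postnatal`, `genes`, `clone_table`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = NULL,
                       simulate = list(), sticr = list(),
                       trackerseq = list(), coupling = list(),
                       mapping = list(), collide = list(),
                       inputs = list()) {
  defaults <- list(
    seed = seed,
    simulate = list(n_clones = 100L, clone_size_mean = 3, clone_size_max = 30,
                    n_states = 4L, mode = "STICR",
                    pool_sizes = c(50L, 50L, 50L),
                    umi_per_molecule = 12L, pcr_dups = 2L,
                    umi_error_rate = 0, fragment_error_rate = 0),
    sticr = list(max_fragment_mismatch = 2L, umi_collapse_mismatch = 1L,
                 min_umi_candidate = 5L, dominance_factor = 5,
                 min_umi_final = 9L, tier_policy = "tier1_only",
                 dataset_id = "D1"),
    trackerseq = list(min_reads_per_triple = 10L, min_umi_per_pair = 6L,
                      cut_height = 0.999, min_barcode_length = 37L,
                      dataset_id = "D1"),
    coupling = list(n_perm = 10000L),
    mapping = list(n_perm = 100L, fdr_threshold = 0.1,
                   perm_scheme = "within_cell"),
    collide = list(library_size = 1e6, population_sizes = 10^(1:6),
                   n_reps = 20000L),
    inputs = list()
  )
  user <- list(simulate = simulate, sticr = sticr, trackerseq = trackerseq,
               coupling = coupling, mapping = mapping, collide = collide,
               inputs = inputs)
  cfg <- defaults
  for (section in names(user)) {
    extra <- setdiff(names(user[[section]]),
                     c(names(defaults[[section]]),
                       if (section == "inputs")
                         c("reads", "pools", "viral_indices", "annotation",
                           "embryonic", "postnatal", "genes",
                           "clone_table")))
    if (length(extra) > 0L) {
      abort(sprintf("unknown key(s) in config section '%s': %s",
                    section, paste(extra, collapse = ", ")))
    }
    cfg[[section]] <- modifyList(defaults[[section]], user[[section]])
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("seed", "simulate", "sticr", "trackerseq", "coupling",
             "mapping", "collide", "inputs")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  do.call(run_config, c(list(seed = raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a pipeline command
#'
#' Chains the package's stages into the analyses the package automates.
#' Commands:
#'
#' * `"simulate"` — generate a synthetic library, clonal population and read
#'   set; writes reads (TSV), fragment pools and ground truth.
#' * `"sticr"` — STICR clone calling on a read table; writes barcode calls
#'   and the clone table.
#' * `"trackerseq"` — integration filtering and Jaccard clone calling;
#'   writes the sparse integration matrix and clone table.
#' * `"coupling"` — lineage coupling z-scores/correlations from a clone
#'   table plus state annotation; writes the matrices.
#' * `"mapping"` — correlation-based mapping of embryonic cells onto
#'   postnatal model vectors; writes per-cell results and fractions.
#' * `"collide"` — barcode collision curve; writes the curve CSV.
#'
#' Every output directory receives a `run_metadata.yaml` with the resolved
#' parameters, seed and package version; per-stage record counts are logged.
#' Outputs are removed again if the command fails partway.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @param command one of the commands above.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "sticr", "trackerseq",
                                     "coupling", "mapping", "collide"),
                         out_dir, quiet = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) {
    config$seed <- sample.int(1e6, 1L)
    if (!quiet) message("no seed supplied; drew seed ", config$seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(obj, p)
    written <<- c(written, p)
    p
  }

  artifacts <- switch(command,
    simulate = {
      sim <- config$simulate
      lib <- gen_barcode_library(pool_sizes = sim$pool_sizes,
                                 seed = config$seed)
      states <- paste0("S", seq_len(sim$n_states))
      pop <- gen_clonal_population(
        n_clones = sim$n_clones,
        clone_size = dist_truncgeom(sim$clone_size_mean, sim$clone_size_max),
        states = states, mode = sim$mode, library = lib,
        seed = config$seed + 1L
      )
      reads <- gen_reads(pop, lib,
                         umi_per_molecule = dist_constant(sim$umi_per_molecule),
                         pcr_dups = dist_constant(sim$pcr_dups),
                         umi_error_rate = sim$umi_error_rate,
                         fragment_error_rate = sim$fragment_error_rate,
                         seed = config$seed + 2L)
      log("simulate: %d cells, %d clones, %d read records",
          nrow(pop$cells), sim$n_clones, nrow(reads))
      reads_path <- file.path(out_dir, "reads.tsv")
      write_reads(reads, reads_path)
      written <- c(written, reads_path)
      pool_paths <- vapply(seq_along(lib$pools), function(i) {
        p <- file.path(out_dir, sprintf("pool%d.txt", i))
        writeLines(paste(names(lib$pools[[i]]), lib$pools[[i]], sep = "\t"),
                   p)
        p
      }, character(1))
      written <- c(written, pool_paths)
      idx_path <- file.path(out_dir, "viral_indices.txt")
      writeLines(lib$viral_index, idx_path)
      written <- c(written, idx_path)
      truth <- emit(pop$cells[, c("cell_id", "clone_id", "state", "class")],
                    "ground_truth.csv")
      list(reads = reads_path, pools = pool_paths,
           viral_indices = idx_path, ground_truth = truth)
    },
    sticr = {
      reads <- load_reads_input(config, mode = "STICR")
      reference <- read_fragment_pools(
        require_input(config, "pools"),
        viral_indices = readLines(require_input(config, "viral_indices"))
      )
      p <- config$sticr
      params <- sticr_params(p$max_fragment_mismatch, p$umi_collapse_mismatch,
                             p$min_umi_candidate, p$dominance_factor,
                             p$min_umi_final)
      res <- call_sticr_clones(reads, reference, params,
                               dataset_id = p$dataset_id,
                               tier_policy = p$tier_policy)
      for (i in seq_len(nrow(res$funnel))) {
        log("sticr: %s = %d", res$funnel$stage[i], res$funnel$n[i])
      }
      list(calls = emit(res$calls, "barcode_calls.csv"),
           clone_table = emit(res$clone_table, "clone_table.csv"),
           funnel = emit(res$funnel, "funnel.csv"))
    },
    trackerseq = {
      records <- load_reads_input(config, mode = "TrackerSeq")
      p <- config$trackerseq
      params <- tracker_params(p$min_reads_per_triple, p$min_umi_per_pair,
                               p$cut_height, p$min_barcode_length)
      im <- filter_integrations(records, params)
      for (i in seq_len(nrow(im$funnel))) {
        log("trackerseq: %s = %d", im$funnel$stage[i], im$funnel$n[i])
      }
      clone_table <- call_clones_jaccard(im, params,
                                         dataset_id = p$dataset_id)
      list(matrix = emit(as_tibble(im), "integration_matrix.csv"),
           clone_table = emit(clone_table, "clone_table.csv"),
           funnel = emit(im$funnel, "funnel.csv"))
    },
    coupling = {
      clone_table <- readr::read_csv(require_input(config, "clone_table"),
                                     show_col_types = FALSE)
      ann <- read_annotation(require_input(config, "annotation"))
      res <- coupling_zscores(clone_table, ann,
                              n_perm = config$coupling$n_perm,
                              seed = config$seed)
      log("coupling: %d cells, %d clones, %d states, %d permutations",
          res$n_cells, res$n_clones, length(res$states), res$n_perm)
      list(z = emit(matrix_to_tibble(res$z), "coupling_z.csv"),
           observed = emit(matrix_to_tibble(res$observed),
                           "coupling_observed.csv"),
           corr = emit(matrix_to_tibble(res$corr), "coupling_corr.csv"))
    },
    mapping = {
      post <- read_expression_matrix(require_input(config, "postnatal"))
      emb <- read_expression_matrix(require_input(config, "embryonic"))
      ann <- read_annotation(require_input(config, "annotation"))
      genes_path <- config$inputs$genes
      genes <- if (is.null(genes_path)) rownames(post)
               else readLines(genes_path)
      post_labels <- dplyr::filter(ann, .data$cell_id %in% colnames(post))
      emb_labels <- dplyr::filter(ann, .data$cell_id %in% colnames(emb))
      models <- build_model_vectors(post, post_labels, genes)
      res <- map_embryonic_cells(emb, models,
                                 n_perm = config$mapping$n_perm,
                                 fdr_threshold = config$mapping$fdr_threshold,
                                 scheme = config$mapping$perm_scheme,
                                 seed = config$seed)
      log("mapping: %d cells, %d mapped (FDR < %g)",
          nrow(res), sum(res$mapped), config$mapping$fdr_threshold)
      fractions <- mapping_fractions(res, emb_labels)
      list(cells = emit(as_tibble(res), "mapping_cells.csv"),
           fractions = emit(fractions, "mapping_fractions.csv"))
    },
    collide = {
      p <- config$collide
      curve <- simulate_collisions(p$library_size,
                                   population_sizes = p$population_sizes,
                                   n_reps = p$n_reps, seed = config$seed)
      log("collide: %d population sizes, library size %g",
          nrow(curve), p$library_size)
      list(curve = emit(as_tibble(curve), "collision_curve.csv"))
    }
  )

  meta <- list(command = command, seed = config$seed,
               parameters = unclass(config)[[
                 if (command == "simulate") "simulate" else command
               ]] %||% list(),
               package_version = as.character(packageVersion("clonecall")),
               written = as.character(unlist(artifacts)))
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  written <- c(written, meta_path)
  ok <- TRUE
  invisible(c(artifacts, list(metadata = meta_path)))
}

require_input <- function(config, key) {
  path <- config$inputs[[key]]
  if (is.null(path)) abort(sprintf("config inputs lack '%s'", key))
  for (p in path) {
    if (!file.exists(p)) abort(sprintf("missing input: %s", p))
  }
  path
}

load_reads_input <- function(config, mode) {
  path <- require_input(config, "reads")
  format <- if (grepl("\\.(fastq|fq)$", path)) "fastq" else "tsv"
  read_reads(path, format = format, mode = mode)
}

matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble(state = rownames(m)),
                   as_tibble(as.data.frame(m)))
}
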