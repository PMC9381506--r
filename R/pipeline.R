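# Pipeline orchestration: validated config, staged run, run manifest.

RUN_CONFIG_KEYS <- c("manifest", "markers", "out_dir", "factors",
                     "databases_dir", "samples", "screen", "stats",
                     "allow_missing_stages")
SCREEN_KEYS <- c("min_identity_pct", "min_aln_length_aa")
STATS_KEYS <- c("seed", "n_permutations", "group_by", "log_base",
                "regression_genes")

#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration, checks it against a strict schema
#' (unknown keys error, with a nearest-key suggestion), verifies that all
#' referenced paths exist, and fills in defaults. All validation failures
#' are collected and reported together, not just the first.
#'
#' @param path YAML config path, or an equivalent named list.
#' @return list of class `RunConfig`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    stop("config must be a YAML path or a named list")
  }
  errors <- character(0L)

  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  for (key in unknown) {
    dist <- utils::adist(key, RUN_CONFIG_KEYS)
    near <- RUN_CONFIG_KEYS[which.min(dist)]
    errors <- c(errors, sprintf("unknown config key '%s' (did you mean '%s'?)",
                                key, near))
  }
  for (key in c("manifest", "markers", "out_dir")) {
    if (is.null(cfg[[key]])) {
      errors <- c(errors, sprintf("missing required key '%s'", key))
    }
  }
  for (key in c("manifest", "markers", "factors", "samples",
                "databases_dir")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      errors <- c(errors, sprintf("path for '%s' does not exist: %s",
                                  key, cfg[[key]]))
    }
  }
  if (is.null(cfg$factors) && is.null(cfg$databases_dir)) {
    errors <- c(errors,
                "supply 'factors' (TSV) or 'databases_dir' (FASTA+TSV pairs)")
  }
  if (!is.null(cfg$screen)) {
    bad <- setdiff(names(cfg$screen), SCREEN_KEYS)
    if (length(bad) > 0L) {
      errors <- c(errors, sprintf("unknown screen key(s): %s",
                                  paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$stats)) {
    bad <- setdiff(names(cfg$stats), STATS_KEYS)
    if (length(bad) > 0L) {
      errors <- c(errors, sprintf("unknown stats key(s): %s",
                                  paste(bad, collapse = ", ")))
    }
    if (!is.null(cfg$stats$group_by) && is.null(cfg$stats$seed)) {
      errors <- c(errors, "stats.seed is required when ANOSIM is requested")
    }
    if (!is.null(cfg$stats$group_by) && is.null(cfg$samples)) {
      errors <- c(errors, "stats.group_by requires sample metadata ('samples')")
    }
  }
  if (length(errors) > 0L) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  if (is.null(cfg$allow_missing_stages)) cfg$allow_missing_stages <- FALSE
  if (!is.null(cfg$stats) && is.null(cfg$stats$n_permutations)) {
    cfg$stats$n_permutations <- 999L
  }
  structure(cfg, class = "RunConfig")
}

read_marker_lengths <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("marker", "length_aa") %in% names(tab))) {
    stop("marker length file needs columns 'marker' and 'length_aa'")
  }
  marker_lengths(stats::setNames(tab$length_aa, tab$marker))
}

factors_from_database_dir <- function(dir, threshold = 0.99) {
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(fastas) == 0L) stop("no .fasta databases in ", dir)
  nr_dbs <- list()
  for (fa in fastas) {
    gene <- sub("\\.fasta$", "", basename(fa))
    meta <- file.path(dir, paste0(gene, ".tsv"))
    db <- load_database(fa, meta, gene = gene)
    nr_dbs[[gene]] <- dereplicate(db, threshold)$nr
  }
  compute_normalization_factors(nr_dbs)
}

#' Run the survey pipeline
#'
#' Executes the configured stages in order: normalization factors (read, or
#' computed from a database directory by dereplicating each family), hit
#' screening over the manifest, relative abundance, and the optional
#' statistics stage (Bray-Curtis distance matrix, seeded ANOSIM on a
#' metadata grouping, per-gene log-log phosphate regressions). Every output
#' is written under `out_dir` and checksummed; a machine-readable JSON run
#' manifest records inputs, package version, seeds and checksums. A rerun
#' with identical config and inputs is byte-identical for all deterministic
#' outputs.
#'
#' @param config a `RunConfig` from [validate_config()], or a path/list
#'   accepted by it.
#' @param verbose log per-stage progress.
#' @return Invisibly, the run manifest list.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0L)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  factors <- stage("factors", {
    f <- if (!is.null(config$factors)) {
      read_factors(config$factors)
    } else {
      factors_from_database_dir(config$databases_dir)
    }
    p <- file.path(out_dir, "factors.tsv")
    write_factors(f, p)
    outputs <- c(outputs, p)
    f
  })
  outputs <- c(outputs, file.path(out_dir, "factors.tsv"))

  scfg <- NULL
  if (!is.null(config$screen)) {
    overrides <- config$screen$min_identity_pct
    scfg <- screen_config(
      min_identity_pct = if (!is.null(overrides)) unlist(overrides),
      min_aln_length_aa = config$screen$min_aln_length_aa)
  }
  counts <- stage("screen", {
    ct <- screen_samples(config$manifest, config = scfg, verbose = verbose)
    p <- file.path(out_dir, "counts.tsv")
    utils::write.table(ct, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
    ct
  })
  outputs <- c(outputs, file.path(out_dir, "counts.tsv"))

  metadata <- if (!is.null(config$samples)) {
    utils::read.delim(config$samples, sep = "\t", stringsAsFactors = FALSE)
  }
  abundance <- stage("abundance", {
    lengths <- read_marker_lengths(config$markers)
    ab <- relative_abundance_table(counts, factors, lengths,
                                   metadata = metadata)
    p <- file.path(out_dir, "abundance.tsv")
    utils::write.table(ab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
    ab
  })
  outputs <- c(outputs, file.path(out_dir, "abundance.tsv"))

  stats_out <- NULL
  if (!is.null(config$stats)) {
    stats_out <- stage("stats", {
      mat <- abundance_matrix(abundance)
      d <- bray_curtis_matrix(mat)
      dp <- file.path(out_dir, "bray_curtis.tsv")
      write_distance_matrix(d, dp)
      outputs <- c(outputs, dp)
      res <- list(distance_path = dp)
      if (!is.null(config$stats$group_by)) {
        g <- metadata[[config$stats$group_by]][
          match(rownames(mat), metadata$sample_id)]
        an <- anosim_test(d, g,
                          n_permutations = config$stats$n_permutations,
                          seed = config$stats$seed)
        ap <- file.path(out_dir, "anosim.json")
        jsonlite::write_json(an[c("R", "p", "n_permutations", "seed")],
                             ap, auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, ap)
        res$anosim <- an
      }
      if (!is.null(metadata$phosphate_umol_L)) {
        genes <- config$stats$regression_genes
        if (is.null(genes)) genes <- intersect(colnames(mat), factors$gene)
        rows <- lapply(genes, function(gene) {
          pi_vals <- metadata$phosphate_umol_L[
            match(rownames(mat), metadata$sample_id)]
          fit <- tryCatch(loglog_pi_regression(mat[, gene], pi_vals),
                          error = function(e) NULL)
          if (is.null(fit)) return(NULL)
          data.frame(gene = gene, slope = fit$slope, p = fit$slope_p,
                     r2 = fit$r_squared, n = fit$n, stringsAsFactors = FALSE)
        })
        reg <- do.call(rbind, rows)
        if (!is.null(reg)) {
          rp <- file.path(out_dir, "regression.tsv")
          utils::write.table(reg, rp, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          outputs <- c(outputs, rp)
          res$regression <- reg
        }
      }
      res
    })
  }

  outputs <- unique(outputs[file.exists(outputs)])
  manifest <- list(
    package = "phoscycle",
    version = as.character(utils::packageVersion("phoscycle")),
    config = unclass(config),
    seed = config$stats$seed,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
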