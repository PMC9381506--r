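# Parsing and screening of 12-column tabular translated-search hits (m8).

M8_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_length_aa",
                "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "evalue", "bitscore")

#' Default per-gene screening thresholds
#'
#' Minimum percent identity per gene family (50% for pepM, aepY, phnA,
#' phnW, phnX, phnZ, phnI; 55% for phnM; 60% for phpC, mpnS, hepD, palA,
#' phnJ; 65% for phnY) and the minimum alignment length in amino acids
#' selected by read length: 32 aa for 100 bp reads, 40 aa for 125 bp
#' reads. Marker genes default to 50% identity. All thresholds are
#' inclusive (`>=`).
#'
#' @param read_length_bp read length in bp (100 or 125) used to pick the
#'   default minimum alignment length.
#' @param min_identity_pct optional named overrides, gene -> percent.
#' @param min_aln_length_aa optional override of the alignment-length
#'   threshold.
#' @return list of class `ScreenConfig` with elements `min_identity_pct`
#'   (named numeric) and `min_aln_length_aa` (integer).
#' @export
screen_config <- function(read_length_bp = 100L, min_identity_pct = NULL,
                          min_aln_length_aa = NULL) {
  identity <- c(
    pepM = 50, aepY = 50, phnA = 50, phnW = 50, phnX = 50, phnZ = 50,
    phnI = 50, phnM = 55, phpC = 60, mpnS = 60, hepD = 60, palA = 60,
    phnJ = 60, phnY = 65,
    recA = 50, atpD = 50, tufA = 50, gyrB = 50, hsp70 = 50)
  if (!is.null(min_identity_pct)) {
    stopifnot(!is.null(names(min_identity_pct)))
    identity[names(min_identity_pct)] <- min_identity_pct
  }
  if (is.null(min_aln_length_aa)) {
    min_aln_length_aa <- min_aln_for_read_length(read_length_bp)
  }
  structure(list(min_identity_pct = identity,
                 min_aln_length_aa = as.integer(min_aln_length_aa)),
            class = "ScreenConfig")
}

#' @rdname screen_config
#' @export
min_aln_for_read_length <- function(read_length_bp) {
  read_length_bp <- as.integer(read_length_bp)
  ifelse(read_length_bp >= 125L, 40L, 32L)
}

#' Parse a 12-column tabular hit file
#'
#' Reads BLAST/DIAMOND `outfmt 6` ("m8") output: one hit per row, 12
#' tab-separated columns. Lines starting with `#` are skipped. Optionally
#' gzip-compressed.
#'
#' @param path file path (or a connection).
#' @param strict if `TRUE` (default) a malformed row raises an error with
#'   its line number; if `FALSE` malformed rows are skipped and their count
#'   reported as attribute `n_skipped` (with a warning).
#' @return data.frame of hits with columns
#'   `query_id, subject_id, pct_identity, aln_length_aa, mismatches,
#'   gap_opens, q_start, q_end, s_start, s_end, evalue, bitscore`.
#' @export
parse_tabular_hits <- function(path, strict = TRUE) {
  lines <- if (inherits(path, "connection")) {
    readLines(path)
  } else {
    if (!file.exists(path)) stop("hit file not found: ", path)
    readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  }
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  empty_hits <- function(n_skipped = 0L) {
    out <- data.frame(query_id = character(0L), subject_id = character(0L),
                      pct_identity = numeric(0L), aln_length_aa = integer(0L),
                      mismatches = integer(0L), gap_opens = integer(0L),
                      q_start = integer(0L), q_end = integer(0L),
                      s_start = integer(0L), s_end = integer(0L),
                      evalue = numeric(0L), bitscore = numeric(0L))
    attr(out, "n_skipped") <- n_skipped
    out
  }
  if (length(data_idx) == 0L) return(empty_hits())

  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    if (strict) {
      stop(sprintf("malformed hit row at line %d: expected 12 fields, got %d",
                   data_idx[bad[1L]], nf[bad[1L]]))
    }
    warning(sprintf("skipped %d malformed row(s)", length(bad)))
    fields <- fields[-bad]
    if (length(fields) == 0L) return(empty_hits(length(bad)))
  }
  mat <- do.call(rbind, fields)
  out <- data.frame(
    query_id = mat[, 1L], subject_id = mat[, 2L],
    pct_identity = as.numeric(mat[, 3L]),
    aln_length_aa = as.integer(mat[, 4L]),
    mismatches = as.integer(mat[, 5L]),
    gap_opens = as.integer(mat[, 6L]),
    q_start = as.integer(mat[, 7L]), q_end = as.integer(mat[, 8L]),
    s_start = as.integer(mat[, 9L]), s_end = as.integer(mat[, 10L]),
    evalue = as.numeric(mat[, 11L]), bitscore = as.numeric(mat[, 12L]),
    stringsAsFactors = FALSE)
  nonnum <- which(is.na(out$pct_identity) | is.na(out$aln_length_aa) |
                    is.na(out$evalue) | is.na(out$bitscore))
  if (length(nonnum) > 0L) {
    if (strict) {
      stop("non-numeric value in hit row at line ", data_idx[nonnum[1L]])
    }
    warning(sprintf("skipped %d row(s) with non-numeric fields",
                    length(nonnum)))
    out <- out[-nonnum, , drop = FALSE]
  }
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("pct_identity outside [0, 100]")
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(bad) + length(nonnum)
  out
}

#' Reduce hits to the best hit per query
#'
#' For each query keeps the row with the maximum bitscore; ties are broken
#' by minimum e-value, remaining ties by input order. Idempotent. Mirrors a
#' translated search run with a best-hit-only option.
#'
#' @param hits data.frame from [parse_tabular_hits()].
#' @return data.frame with at most one row per `query_id`, in first-seen
#'   query order.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  # order: query, bitscore desc, evalue asc, input order; stable radix sort
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue,
               seq_len(nrow(hits)), method = "radix")
  sorted <- hits[ord, , drop = FALSE]
  best <- sorted[!duplicated(sorted$query_id), , drop = FALSE]
  # restore first-appearance order of queries
  best <- best[order(match(best$query_id, hits$query_id)), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Filter hits by per-gene identity and alignment-length thresholds
#'
#' A hit passes iff `pct_identity >= min_identity_pct[gene]` and
#' `aln_length_aa >= min_aln_length_aa`; both thresholds inclusive. Input
#' order is preserved.
#'
#' @param hits data.frame of hits.
#' @param gene gene name whose threshold applies.
#' @param config a `ScreenConfig` from [screen_config()].
#' @return The passing subset of `hits`.
#' @export
filter_hits <- function(hits, gene, config = screen_config()) {
  stopifnot(inherits(config, "ScreenConfig"))
  if (!gene %in% names(config$min_identity_pct)) {
    stop("no identity threshold configured for gene '", gene,
         "'; configured genes: ",
         paste(names(config$min_identity_pct), collapse = ", "))
  }
  keep <- hits$pct_identity >= config$min_identity_pct[[gene]] &
    hits$aln_length_aa >= config$min_aln_length_aa
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count unique passing hits per sample and gene
#'
#' Every unique query with a passing hit counts once; forward and reverse
#' mates carry distinct query ids and both count. A read may count toward
#' several genes because screens are run per gene database.
#'
#' @param hits_by_sample_gene nested list: `[[sample_id]][[gene]]` ->
#'   data.frame of filtered best hits.
#' @param total_reads optional named vector of per-sample read totals.
#' @return data.frame of class `GeneCountTable` with columns `sample_id`,
#'   `gene`, `raw_count` and (when supplied) `total_reads`.
#' @export
count_hits <- function(hits_by_sample_gene, total_reads = NULL) {
  rows <- list()
  for (sample_id in names(hits_by_sample_gene)) {
    per_gene <- hits_by_sample_gene[[sample_id]]
    for (gene in names(per_gene)) {
      h <- per_gene[[gene]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, gene = gene,
        raw_count = length(unique(h$query_id)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(sample_id = character(0L), gene = character(0L),
               raw_count = integer(0L))
  if (!is.null(total_reads)) {
    out$total_reads <- unname(total_reads[out$sample_id])
  }
  class(out) <- c("GeneCountTable", class(out))
  out
}

#' Screen a manifest of per-sample per-gene hit files
#'
#' Drives [parse_tabular_hits()], [best_hit_per_query()], [filter_hits()]
#' and [count_hits()] over a manifest TSV with columns
#' `sample_id  gene  path  read_length  total_reads`. The alignment-length
#' threshold is chosen per sample from `read_length` (100 bp -> 32 aa,
#' 125 bp -> 40 aa) unless overridden in `config`.
#'
#' @param manifest data.frame or path to the manifest TSV.
#' @param config optional `ScreenConfig`; when `NULL`, per-sample defaults
#'   from `read_length` are used.
#' @param strict parsing mode passed to [parse_tabular_hits()].
#' @param verbose log kept/dropped counts per file.
#' @return A `GeneCountTable` (see [count_hits()]).
#' @export
screen_samples <- function(manifest, config = NULL, strict = TRUE,
                           verbose = FALSE) {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  required <- c("sample_id", "gene", "path", "read_length")
  if (!all(required %in% names(manifest))) {
    stop("manifest must have columns: ", paste(required, collapse = ", "))
  }
  missing_files <- manifest$path[!file.exists(manifest$path)]
  if (length(missing_files) > 0L) {
    bad <- manifest[!file.exists(manifest$path), , drop = FALSE]
    stop("manifest references missing hit file(s) for sample(s) ",
         paste(unique(bad$sample_id), collapse = ", "), ": ",
         paste(utils::head(missing_files, 5L), collapse = ", "))
  }
  nested <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    cfg <- if (is.null(config)) screen_config(row$read_length) else config
    hits <- parse_tabular_hits(row$path, strict = strict)
    best <- best_hit_per_query(hits)
    passed <- filter_hits(best, row$gene, cfg)
    if (verbose) {
      message(sprintf("%s/%s: %d hits, %d best, %d passed",
                      row$sample_id, row$gene, nrow(hits), nrow(best),
                      nrow(passed)))
    }
    nested[[row$sample_id]][[row$gene]] <- passed
  }
  totals <- NULL
  if ("total_reads" %in% names(manifest)) {
    tr <- manifest[!duplicated(manifest$sample_id), ]
    totals <- stats::setNames(tr$total_reads, tr$sample_id)
  }
  count_hits(nested, total_reads = totals)
}
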