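# Copy-number and length normalization factors; genome presence matrix.

#' Compute per-gene normalization factors
#'
#' For each non-redundant phosphonate database the copy-number normalizing
#' factor is (number of genomes)/(number of sequences) — 1 for a strictly
#' single-copy family, smaller when genomes carry multiple copies. The
#' length normalizing factor is (mean sequence length over all sequences in
#' all supplied phosphonate databases)/(mean length of the given database),
#' correcting the hit-count bias toward longer genes. The study-wide mean
#' is taken over the phosphonate databases only, not the single-copy
#' markers.
#'
#' @param nr_dbs named list of non-redundant `GeneDatabase` objects (names
#'   are gene names; all must be nonempty).
#' @return data.frame with columns `gene`, `n_sequences`, `n_genomes`,
#'   `mean_length_aa`, `cn_factor`, `len_factor`; the study-wide mean
#'   length is attached as attribute `study_mean_length_aa`.
#' @export
compute_normalization_factors <- function(nr_dbs) {
  stopifnot(is.list(nr_dbs), length(nr_dbs) > 0L)
  if (is.null(names(nr_dbs)) || any(!nzchar(names(nr_dbs)))) {
    names(nr_dbs) <- vapply(nr_dbs, function(d) d$gene, character(1L))
  }
  empty <- names(nr_dbs)[vapply(nr_dbs, n_sequences, integer(1L)) == 0L]
  if (length(empty) > 0L) {
    stop("empty database(s): ", paste(empty, collapse = ", "))
  }
  n_seq <- vapply(nr_dbs, n_sequences, integer(1L))
  n_gen <- vapply(nr_dbs, n_genomes, integer(1L))
  mean_len <- vapply(nr_dbs, mean_length_aa, numeric(1L))
  # mean over the union of all sequences = sequence-count-weighted mean
  study_mean <- sum(n_seq * mean_len) / sum(n_seq)
  out <- data.frame(
    gene = names(nr_dbs),
    n_sequences = n_seq,
    n_genomes = n_gen,
    mean_length_aa = mean_len,
    cn_factor = n_gen / n_seq,
    len_factor = study_mean / mean_len,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "study_mean_length_aa") <- study_mean
  out
}

#' Write / read normalization factors as TSV
#'
#' @param factors data.frame from [compute_normalization_factors()].
#' @param path TSV path.
#' @export
write_factors <- function(factors, path) {
  out <- factors
  out$study_mean_length_aa <- attr(factors, "study_mean_length_aa")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_factors
#' @export
read_factors <- function(path) {
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  sm <- unique(out$study_mean_length_aa)
  out$study_mean_length_aa <- NULL
  attr(out, "study_mean_length_aa") <- sm
  out
}

#' Genome-by-gene presence matrix
#'
#' Boolean matrix over the union of genome ids of the supplied redundant
#' databases: a cell is `TRUE` iff the genome contributes at least one
#' sequence to that gene's database. Column sums therefore equal per-gene
#' genome counts. Computed from the redundant (pre-dereplication)
#' databases, which retain every genome's own sequences.
#'
#' @param redundant_dbs list of `GeneDatabase` objects.
#' @return Logical matrix, rows = genomes, columns = genes.
#' @export
presence_matrix <- function(redundant_dbs) {
  stopifnot(is.list(redundant_dbs))
  if (length(redundant_dbs) == 0L) {
    return(matrix(logical(0L), nrow = 0L, ncol = 0L))
  }
  genes <- vapply(redundant_dbs, function(d) d$gene, character(1L))
  genomes <- sort(unique(unlist(lapply(redundant_dbs,
                                       function(d) d$member_genomes))))
  mat <- matrix(FALSE, nrow = length(genomes), ncol = length(genes),
                dimnames = list(genomes, genes))
  for (j in seq_along(redundant_dbs)) {
    mat[redundant_dbs[[j]]$member_genomes, j] <- TRUE
  }
  mat
}
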