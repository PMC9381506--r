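#' Construct a gene-family reference database
#'
#' A `GeneDatabase` bundles the protein records of one enzyme family with
#' their per-sequence metadata (source genome, ranked taxonomy, marine
#' flag, length). Databases are either redundant (as collected) or
#' non-redundant (after [dereplicate()]); the non-redundant form keeps the
#' full set of member genomes of each cluster so genome accounting for the
#' copy-number factor is unaffected by dereplication.
#'
#' @param records data.frame with columns `seq_id`, `gene`, `genome_id`,
#'   the ranked taxonomy (`domain` ... `species`, any subset), `marine`
#'   (logical or NA), `length_aa`, `sequence`. `length_aa` and `sequence`
#'   may be derived from each other; ungapped length must equal
#'   `length_aa`.
#' @param gene gene name; defaults to the unique value of `records$gene`.
#' @param redundant logical; `TRUE` for an as-collected database.
#' @param member_genomes optional character vector of all genome ids
#'   represented by the database including cluster members collapsed by
#'   dereplication. Defaults to `records$genome_id`.
#' @return An object of class `GeneDatabase`.
#' @export
gene_database <- function(records, gene = NULL, redundant = TRUE,
                          member_genomes = NULL) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0L) {
    required <- c("seq_id", "genome_id")
    missing_cols <- setdiff(required, names(records))
    if (length(missing_cols) > 0L) {
      stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
    }
    if (anyDuplicated(records$seq_id)) {
      dup <- unique(records$seq_id[duplicated(records$seq_id)])
      stop("duplicate seq_id in database: ", paste(dup, collapse = ", "))
    }
    if (is.null(records$sequence) && is.null(records$length_aa)) {
      stop("records need a 'sequence' or 'length_aa' column")
    }
    if (is.null(records$length_aa)) {
      records$length_aa <- ungapped_length(records$sequence)
    }
    if (!is.null(records$sequence)) {
      ul <- ungapped_length(records$sequence)
      bad <- which(ul != records$length_aa)
      if (length(bad) > 0L) {
        stop("length_aa disagrees with ungapped sequence length for: ",
             paste(records$seq_id[bad], collapse = ", "))
      }
    }
    if (any(records$length_aa <= 0L)) stop("length_aa must be positive")
  }
  if (is.null(gene)) {
    gene <- if (nrow(records) > 0L && !is.null(records$gene)) {
      unique(as.character(records$gene))
    } else {
      NA_character_
    }
    if (length(gene) != 1L) {
      stop("records span multiple genes; supply `gene` explicitly")
    }
  }
  if (is.null(member_genomes)) member_genomes <- unique(records$genome_id)
  structure(
    list(gene = gene, records = records, redundant = isTRUE(redundant),
         member_genomes = unique(as.character(member_genomes))),
    class = "GeneDatabase"
  )
}

#' @rdname gene_database
#' @param db,x a `GeneDatabase`.
#' @export
n_sequences <- function(db) nrow(db$records)

#' @rdname gene_database
#' @export
n_genomes <- function(db) length(db$member_genomes)

#' @rdname gene_database
#' @export
mean_length_aa <- function(db) {
  if (nrow(db$records) == 0L) return(NA_real_)
  mean(db$records$length_aa)
}

#' @export
print.GeneDatabase <- function(x, ...) {
  cat(sprintf("GeneDatabase '%s' (%s): %d sequences, %d genomes, mean length %.1f aa\n",
              x$gene, if (x$redundant) "redundant" else "non-redundant",
              n_sequences(x), n_genomes(x),
              if (n_sequences(x) > 0L) mean_length_aa(x) else NA_real_))
  invisible(x)
}

# ungapped length of (possibly gapped) sequences
ungapped_length <- function(sequence) {
  nchar(gsub("[-.]", "", sequence))
}

#' Load a gene-family database from FASTA plus metadata TSV
#'
#' Reads protein sequences (optionally gapped/aligned FASTA) and joins them
#' to a tab-separated metadata table keyed by `seq_id`. Records present in
#' the FASTA but absent from the metadata (or vice versa) are reported; if
#' their fraction exceeds `max_mismatch_frac` loading fails.
#'
#' @param fasta_path path to a protein FASTA file.
#' @param metadata_path path to a TSV with header including `seq_id`,
#'   `gene`, `genome_id` and optionally taxonomy ranks, `marine`,
#'   `length_aa`.
#' @param gene gene name override (default: from metadata).
#' @param redundant logical, passed to [gene_database()].
#' @param max_mismatch_frac maximum tolerated fraction of FASTA/metadata id
#'   mismatches before a hard error; default 0 (strict).
#' @return A `GeneDatabase`.
#' @export
load_database <- function(fasta_path, metadata_path, gene = NULL,
                          redundant = TRUE, max_mismatch_frac = 0) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate seq_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("seq_id", "gene", "genome_id") %in% names(meta))) {
    stop("metadata must have columns seq_id, gene, genome_id")
  }
  if (anyDuplicated(meta$seq_id)) stop("duplicate seq_id in metadata")

  only_fasta <- setdiff(ids, meta$seq_id)
  only_meta <- setdiff(meta$seq_id, ids)
  n_mismatch <- length(only_fasta) + length(only_meta)
  if (n_mismatch > 0L) {
    frac <- n_mismatch / max(length(ids), nrow(meta))
    msg <- sprintf(
      "%d FASTA/metadata id mismatches (%.1f%%): %s",
      n_mismatch, 100 * frac,
      paste(utils::head(c(only_fasta, only_meta), 10L), collapse = ", "))
    if (frac > max_mismatch_frac) stop(msg) else warning(msg)
  }
  keep <- intersect(ids, meta$seq_id)
  meta <- meta[match(keep, meta$seq_id), , drop = FALSE]
  meta$sequence <- as.character(seqs[match(keep, ids)])
  meta$length_aa <- ungapped_length(meta$sequence)
  rownames(meta) <- NULL
  gene_database(meta, gene = gene, redundant = redundant)
}

#' Write a gene database to FASTA + metadata TSV
#'
#' @param db a `GeneDatabase`.
#' @param fasta_path,metadata_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_database <- function(db, fasta_path, metadata_path) {
  stopifnot(inherits(db, "GeneDatabase"))
  seqs <- Biostrings::AAStringSet(db$records$sequence)
  names(seqs) <- db$records$seq_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- db$records[, setdiff(names(db$records), "sequence"), drop = FALSE]
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, metadata = metadata_path))
}
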