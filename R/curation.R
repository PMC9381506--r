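# Alignment handling and conserved-residue curation.
#
# Alignments are named character vectors of equal-length gapped sequences
# ('-' or '.' as gap). Anything coercible (AAStringSet, AAMultipleAlignment,
# GeneDatabase with gapped sequences) is accepted.

as_alignment <- function(x) {
  if (inherits(x, "GeneDatabase")) {
    aln <- x$records$sequence
    names(aln) <- x$records$seq_id
  } else if (inherits(x, c("AAStringSet", "AAMultipleAlignment"))) {
    aln <- as.character(x)
  } else if (is.character(x)) {
    aln <- x
  } else {
    stop("cannot interpret object of class ", class(x)[1L], " as an alignment")
  }
  if (length(aln) == 0L) stop("empty alignment")
  if (is.null(names(aln)) || any(!nzchar(names(aln)))) {
    stop("alignment sequences must be named by seq_id")
  }
  if (length(unique(nchar(aln))) != 1L) {
    stop("aligned sequences must all have the same number of columns")
  }
  aln
}

#' Map ungapped reference positions to alignment columns
#'
#' Conserved-residue rules are stated as 1-based positions on an ungapped
#' anchor sequence (typically a crystallized reference enzyme). This maps
#' each such position to the 1-based column of the alignment in which the
#' anchor's residue sits.
#'
#' @param alignment named character vector (or `AAStringSet`) of equal
#'   length gapped sequences.
#' @param ref_seq_id name of the anchor sequence in the alignment.
#' @param positions integer vector of 1-based ungapped positions on the
#'   anchor.
#' @return Integer vector of alignment columns, in input order.
#' @export
map_reference_positions <- function(alignment, ref_seq_id, positions) {
  aln <- as_alignment(alignment)
  if (!ref_seq_id %in% names(aln)) {
    stop("anchor sequence not in alignment: ", ref_seq_id)
  }
  chars <- strsplit(aln[[ref_seq_id]], "", fixed = TRUE)[[1L]]
  nongap_cols <- which(!chars %in% c("-", "."))
  positions <- as.integer(positions)
  if (any(positions < 1L) || any(positions > length(nongap_cols))) {
    stop(sprintf("position out of range for anchor %s (ungapped length %d)",
                 ref_seq_id, length(nongap_cols)))
  }
  nongap_cols[positions]
}

#' Read a residue-rule TSV
#'
#' Columns: `gene`, `ref_seq_id`, `ref_position` (1-based ungapped on the
#' anchor), `allowed` (amino-acid symbols, optionally comma/pipe separated),
#' `role` (free text).
#'
#' @param path rule TSV path.
#' @return data.frame of rules.
#' @export
read_residue_rules <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  rules <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("gene", "ref_seq_id", "ref_position", "allowed")
  if (!all(required %in% names(rules))) {
    stop("rule file must have columns: ", paste(required, collapse = ", "))
  }
  if (is.null(rules$role)) rules$role <- NA_character_
  validate_residue_rules(rules)
  rules
}

validate_residue_rules <- function(rules) {
  stopifnot(is.data.frame(rules))
  if (nrow(rules) == 0L) return(invisible(rules))
  allowed_sets <- parse_allowed(rules$allowed)
  bad <- which(!vapply(allowed_sets,
                       function(a) length(a) > 0L && all(a %in% AA_ALPHABET20),
                       logical(1L)))
  if (length(bad) > 0L) {
    stop("invalid allowed-residue set in rule row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(rules$ref_position < 1L)) stop("ref_position must be >= 1")
  invisible(rules)
}

parse_allowed <- function(allowed) {
  lapply(strsplit(toupper(gsub("[,;| ]", "", allowed)), "", fixed = TRUE),
         unique)
}

#' Verify sequences by conserved catalytic residues
#'
#' Applies per-gene residue rules to a multiple alignment: each rule names
#' an anchor sequence, an ungapped anchor position and the allowed amino
#' acids there. A sequence is kept iff it passes every rule; a rule passes
#' iff the sequence's character at the mapped alignment column is one of
#' the allowed residues. A gap at a rule column counts as absence of the
#' conserved residue, hence failure. Anchor sequences always pass their own
#' rules.
#'
#' @param alignment named character vector (or coercible) of gapped
#'   sequences.
#' @param rules data.frame of rules as in [read_residue_rules()].
#' @param pass_through if `TRUE` an empty rule set keeps everything instead
#'   of erroring.
#' @return list with `kept`, `removed` (character vectors of seq_ids, a
#'   partition of the alignment) and `report` (long data.frame with one row
#'   per sequence per rule: `seq_id`, `gene`, `rule_column`, `observed`,
#'   `pass`).
#' @export
apply_residue_rules <- function(alignment, rules, pass_through = FALSE) {
  aln <- as_alignment(alignment)
  if (is.null(rules) || nrow(rules) == 0L) {
    if (pass_through) {
      return(list(kept = names(aln), removed = character(0L),
                  report = data.frame()))
    }
    stop("no residue rules supplied; refusing to verify without criteria ",
         "(set pass_through = TRUE to keep all sequences)")
  }
  validate_residue_rules(rules)
  missing_anchor <- setdiff(unique(rules$ref_seq_id), names(aln))
  if (length(missing_anchor) > 0L) {
    stop("rule anchor(s) absent from alignment: ",
         paste(missing_anchor, collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(mat) <- names(aln)
  allowed_sets <- parse_allowed(rules$allowed)

  reports <- vector("list", nrow(rules))
  pass_all <- rep(TRUE, length(aln))
  names(pass_all) <- names(aln)
  for (i in seq_len(nrow(rules))) {
    col <- map_reference_positions(aln, rules$ref_seq_id[i],
                                   rules$ref_position[i])
    observed <- toupper(mat[, col])
    pass <- observed %in% allowed_sets[[i]]
    pass[names(aln) == rules$ref_seq_id[i]] <- TRUE  # anchor passes its own rule
    pass_all <- pass_all & pass
    reports[[i]] <- data.frame(
      seq_id = names(aln),
      gene = rules$gene[i],
      rule_column = col,
      observed = observed,
      pass = pass,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(kept = names(aln)[pass_all],
       removed = names(aln)[!pass_all],
       report = do.call(rbind, reports))
}

#' Rescue candidate sequences by genome-neighbourhood synteny
#'
#' Some gene families (phpC, phnY) cannot be identified reliably by
#' annotation alone because they resemble common protein superfamilies.
#' A candidate is accepted only when another phosphonate-cycling gene lies
#' on the same contig within `window` locus ranks of it.
#'
#' @param loci data.frame with columns `genome_id`, `contig_id`,
#'   `locus_index` (integer rank along the contig), `gene_label`, `seq_id`.
#' @param candidates seq_ids of the target-gene candidates to verify.
#' @param companion_genes character vector of companion gene labels.
#' @param window maximum locus-rank distance (default 10).
#' @return Character vector of kept candidate seq_ids. Candidates absent
#'   from `loci` are reported via a warning and excluded.
#' @export
verify_by_neighborhood <- function(loci, candidates, companion_genes,
                                   window = 10L) {
  stopifnot(is.data.frame(loci), window >= 1L)
  required <- c("genome_id", "contig_id", "locus_index", "gene_label", "seq_id")
  if (!all(required %in% names(loci))) {
    stop("loci must have columns: ", paste(required, collapse = ", "))
  }
  unknown <- setdiff(candidates, loci$seq_id)
  if (length(unknown) > 0L) {
    warning("candidates absent from locus table (unverifiable, excluded): ",
            paste(unknown, collapse = ", "))
    candidates <- setdiff(candidates, unknown)
  }
  kept <- vapply(candidates, function(sid) {
    row <- loci[loci$seq_id == sid, , drop = FALSE][1L, ]
    mates <- loci[loci$genome_id == row$genome_id &
                    loci$contig_id == row$contig_id &
                    loci$gene_label %in% companion_genes &
                    loci$seq_id != sid, , drop = FALSE]
    any(abs(mates$locus_index - row$locus_index) <= window)
  }, logical(1L))
  candidates[kept]
}
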