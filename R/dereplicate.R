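# Greedy identity dereplication (CD-HIT-style), deterministic.

#' Pairwise global-alignment identity
#'
#' Fraction of identically aligned residues over the length of the shorter
#' sequence, under Needleman-Wunsch global alignment (the convention of
#' greedy clustering tools). Gaps are stripped before aligning.
#'
#' @param a,b amino-acid strings.
#' @return Identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  a <- gsub("[-.]", "", a)
  b <- gsub("[-.]", "", b)
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = identity_submat(),
    gapOpening = 6, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# match-reward substitution matrix so the alignment maximizes identities
identity_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- c(AA_ALPHABET20, "B", "J", "O", "U", "X", "Z", "*")
      m <- matrix(-1, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 2
      mat <<- m
    }
    mat
  }
})

#' Dereplicate a gene database by greedy identity clustering
#'
#' Deterministic greedy incremental clustering: sequences are processed
#' longest-first (ties broken by lexicographic seq_id); each sequence joins
#' the first existing cluster (in representative-creation order) whose
#' representative it matches at `>= threshold` identity, otherwise it
#' founds a new cluster. Identity is identical aligned residues divided by
#' the length of the shorter sequence under global alignment
#' ([seq_identity()]). The non-redundant database consists of the cluster
#' representatives but retains every member's genome id, so genome counts
#' (and hence copy-number factors) are computed over the full membership.
#'
#' @param db a redundant `GeneDatabase` (ungapped sequences).
#' @param threshold identity threshold in `(0, 1]`; default 0.99.
#' @return list with `nr` (non-redundant `GeneDatabase`) and `clusters`
#'   (data.frame `representative`, `member`, one row per input sequence).
#' @export
dereplicate <- function(db, threshold = 0.99) {
  stopifnot(inherits(db, "GeneDatabase"),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  recs <- db$records
  if (nrow(recs) == 0L) {
    warning("empty database: nothing to dereplicate")
    return(list(nr = gene_database(recs, gene = db$gene, redundant = FALSE),
                clusters = data.frame(representative = character(0L),
                                      member = character(0L))))
  }
  seqs <- gsub("[-.]", "", recs$sequence)
  names(seqs) <- recs$seq_id
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  assignment <- greedy_cluster(seqs[ord], threshold)

  reps <- unique(assignment)
  clusters <- data.frame(representative = assignment,
                         member = names(assignment),
                         row.names = NULL, stringsAsFactors = FALSE)
  nr_records <- recs[match(reps, recs$seq_id), , drop = FALSE]
  rownames(nr_records) <- NULL
  nr <- gene_database(nr_records, gene = db$gene, redundant = FALSE,
                      member_genomes = recs$genome_id)
  list(nr = nr, clusters = clusters)
}

# seqs: named, already in processing order; returns representative per member
greedy_cluster <- function(seqs, threshold) {
  reps <- character(0L)
  assignment <- character(length(seqs))
  names(assignment) <- names(seqs)
  for (i in seq_along(seqs)) {
    hit <- NA_character_
    for (r in reps) {  # representative-creation order
      if (seq_identity(seqs[[i]], seqs[[r]]) >= threshold) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, names(seqs)[i])
      hit <- names(seqs)[i]
    }
    assignment[i] <- hit
  }
  assignment
}

#' Write cluster membership to TSV
#'
#' @param clusters data.frame from [dereplicate()].
#' @param path output TSV (`representative\tmember`).
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
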