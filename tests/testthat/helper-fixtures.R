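# Shared fixtures and independent oracles, built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# mutate exactly k positions (to a different residue)
mutate_k <- function(s, k, at = NULL) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (is.null(at)) at <- sample(length(chars), k)
  for (p in at) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

# small in-memory database
make_db <- function(sequences, genome_ids = NULL, gene = "pepM",
                    classes = NULL, redundant = TRUE) {
  n <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("%s_s%02d", gene, seq_len(n))
  if (is.null(genome_ids)) genome_ids <- sprintf("%s_g%02d", gene, seq_len(n))
  if (is.null(classes)) classes <- rep("Alphaproteobacteria", n)
  gene_database(data.frame(
    seq_id = ids, gene = rep(gene, n), genome_id = genome_ids,
    domain = rep("Bacteria", n), class = classes, marine = rep(TRUE, n),
    length_aa = nchar(gsub("[-.]", "", sequences)),
    sequence = unname(sequences), stringsAsFactors = FALSE),
    gene = gene, redundant = redundant)
}

# write a database to temp FASTA + TSV, return the two paths
write_temp_db <- function(db, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, paste0(db$gene, ".fasta"))
  tsv <- file.path(dir, paste0(db$gene, ".tsv"))
  write_database(db, fa, tsv)
  c(fasta = fa, metadata = tsv)
}

# independent brute-force oracle for greedy dereplication: identities are
# computed exhaustively for all pairs first, then the greedy rule is applied
# in plain loops (longest-first, lexicographic ties, first-qualifying rep)
greedy_oracle <- function(seqs, threshold) {
  ids <- names(seqs)
  id_mat <- matrix(1, length(seqs), length(seqs), dimnames = list(ids, ids))
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i < j) {
        id_mat[i, j] <- id_mat[j, i] <- seq_identity(seqs[[i]], seqs[[j]])
      }
    }
  }
  ord <- ids[order(-nchar(seqs), ids, method = "radix")]
  reps <- character(0L)
  assignment <- character(0L)
  for (sid in ord) {
    assigned <- NA_character_
    for (r in reps) {
      if (id_mat[sid, r] >= threshold) { assigned <- r; break }
    }
    if (is.na(assigned)) { reps <- c(reps, sid); assigned <- sid }
    assignment[sid] <- assigned
  }
  assignment
}

# write m8 lines for given fields (defaults produce a passing pepM hit)
m8_line <- function(query = "r1", subject = "s1", ident = 75, alen = 40,
                    mism = 10, gaps = 0, qs = 1, qe = 120, ss = 5, se = 44,
                    evalue = 1e-10, bits = 80.1) {
  sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g",
          query, subject, format(ident), alen, mism, gaps, qs, qe, ss, se,
          evalue, bits)
}

write_m8 <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "hits.m8")
  writeLines(lines, path)
  path
}

# hits data.frame straight from fields (already parsed)
hits_df <- function(query_id, pct_identity, aln_length_aa,
                    bitscore = 50, evalue = 1e-10) {
  n <- length(query_id)
  data.frame(query_id = query_id, subject_id = rep("ref", n),
             pct_identity = rep(pct_identity, length.out = n),
             aln_length_aa = rep(aln_length_aa, length.out = n),
             mismatches = rep(0L, n), gap_opens = rep(0L, n),
             q_start = rep(1L, n), q_end = rep(100L, n),
             s_start = rep(1L, n), s_end = rep(40L, n),
             evalue = rep(evalue, length.out = n),
             bitscore = rep(bitscore, length.out = n),
             stringsAsFactors = FALSE)
}
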