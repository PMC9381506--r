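# Reference-database construction, curation, dereplication, factors.

test_that("load_database round-trips FASTA + metadata and counts genomes", {
  set.seed(11)
  db <- make_db(replicate(3, rand_protein(60)),
                genome_ids = c("gA", "gA", "gB"))
  paths <- write_temp_db(db)
  loaded <- load_database(paths["fasta"], paths["metadata"])
  expect_equal(n_sequences(loaded), 3L)
  expect_equal(n_genomes(loaded), 2L)   # two records share genome gA
  expect_equal(sort(loaded$records$seq_id), sort(db$records$seq_id))
  expect_equal(loaded$records$length_aa, nchar(loaded$records$sequence))
})

test_that("load_database rejects duplicate ids and unmatched ids", {
  set.seed(12)
  db <- make_db(replicate(3, rand_protein(50)))
  paths <- write_temp_db(db)
  # duplicate FASTA id
  dir <- withr::local_tempdir()
  dup_fa <- file.path(dir, "dup.fasta")
  writeLines(c(">x1", "ACDEF", ">x1", "ACDEY"), dup_fa)
  expect_error(load_database(dup_fa, paths["metadata"]), "duplicate seq_id")
  # id mismatch: strict default errors, tolerance reports and drops
  meta <- read.delim(paths["metadata"])
  meta$seq_id[1] <- "not_in_fasta"
  mis <- file.path(dir, "mismatch.tsv")
  write.table(meta, mis, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_database(paths["fasta"], mis), "mismatch")
  expect_warning(
    loaded <- load_database(paths["fasta"], mis, max_mismatch_frac = 0.9),
    "mismatch")
  expect_equal(n_sequences(loaded), 2L)
})

test_that("gene_database enforces its invariants", {
  expect_error(make_db(c(a = "ACD", b = "ACE")[c(1, 1)]), "duplicate")
  rec <- data.frame(seq_id = "s1", gene = "pepM", genome_id = "g1",
                    length_aa = 5L, sequence = "ACD")
  expect_error(gene_database(rec), "length_aa disagrees")
  # gapped sequence: length counts non-gap characters only
  db <- make_db(c(s1 = "AC-DE"))
  expect_equal(db$records$length_aa, 4L)
})

test_that("reference positions map through gaps to alignment columns", {
  aln <- c(anchor = "AC-DE", other = "ACQDE")
  expect_equal(map_reference_positions(aln, "anchor", 3), 4L)
  expect_equal(map_reference_positions(c(a = "ACDE"), "a", 1:4), 1:4)
  expect_equal(map_reference_positions(c(a = "-A-C", b = "QAQC"), "a", c(1, 2)),
               c(2L, 4L))
  expect_error(map_reference_positions(aln, "anchor", 5), "out of range")
  expect_error(map_reference_positions(aln, "absent", 1), "not in alignment")
})

test_that("residue rules keep matches, remove mismatches and gaps", {
  aln <- c(anchor = "ACDDE",  # rule column 4, D
           match_ = "GGGDG",
           glu___ = "GGGEG",  # E also allowed
           miss__ = "GGGNG",
           gap___ = "GGG-G")
  rules <- data.frame(gene = "pepM", ref_seq_id = "anchor",
                      ref_position = 4, allowed = "DE", role = "catalytic")
  res <- apply_residue_rules(aln, rules)
  expect_setequal(res$kept, c("anchor", "match_", "glu___"))
  expect_setequal(res$removed, c("miss__", "gap___"))
  expect_false(res$report$pass[res$report$seq_id == "miss__"])
  # kept and removed partition the alignment
  expect_setequal(c(res$kept, res$removed), names(aln))
  expect_length(intersect(res$kept, res$removed), 0)
})

test_that("anchors pass their own rules; empty rule sets refuse to verify", {
  # anchor's own residue is not in `allowed`, yet the anchor is kept
  aln <- c(anchor = "AAXAA", member = "AADAA")
  aln <- gsub("X", "C", aln)
  rules <- data.frame(gene = "pepM", ref_seq_id = "anchor",
                      ref_position = 3, allowed = "D", role = "catalytic")
  res <- apply_residue_rules(aln, rules)
  expect_true("anchor" %in% res$kept)
  expect_error(apply_residue_rules(aln, rules[0, ]), "refusing to verify")
  expect_setequal(apply_residue_rules(aln, NULL, pass_through = TRUE)$kept,
                  names(aln))
})

test_that("multi-rule verification requires passing every rule", {
  set.seed(13)
  sim <- simulate_reference_databases(
    sim_config(seed = 13, genes = c("pepM", "phpC")),
    n_seq_per_gene = 20, violator_fraction = 0.2)
  for (gene in c("pepM", "phpC")) {
    res <- apply_residue_rules(sim$alignments[[gene]],
                               sim$rules[sim$rules$gene == gene, ])
    expect_setequal(res$removed, sim$violators[[gene]])
  }
})

test_that("synteny verification respects window and contig boundaries", {
  loci <- data.frame(
    genome_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    contig_id = c("c1", "c1", "c2", "c2", "c3", "c4"),
    locus_index = c(10L, 12L, 10L, 30L, 10L, 11L),
    gene_label = c("phpC", "phnW", "phpC", "phnW", "phpC", "phnW"),
    seq_id = c("p1", "w1", "p2", "w2", "p3", "w3"))
  kept <- verify_by_neighborhood(loci, c("p1", "p2", "p3"), "phnW",
                                 window = 5)
  expect_equal(kept, "p1")  # p2 outside window, p3 companion on other contig
  expect_equal(verify_by_neighborhood(loci, "p2", "phnW", window = 20), "p2")
  expect_warning(res <- verify_by_neighborhood(loci, c("p1", "ghost"), "phnW",
                                               window = 5),
                 "unverifiable")
  expect_equal(res, "p1")
})

test_that("dereplication merges duplicates and splits below-threshold pairs", {
  set.seed(21)
  s <- rand_protein(100)
  dup <- make_db(c(a = s, b = s), genome_ids = c("g1", "g2"))
  res <- dereplicate(dup, 0.99)
  expect_equal(n_sequences(res$nr), 1L)
  expect_equal(n_genomes(res$nr), 2L)  # member genomes survive dereplication
  expect_equal(nrow(res$clusters), 2L)
  expect_length(unique(res$clusters$representative), 1L)

  s2 <- mutate_k(s, 2)                 # 0.98 identity
  pair <- make_db(c(a = s, b = s2))
  expect_equal(seq_identity(s, s2), 0.98)
  expect_equal(n_sequences(dereplicate(pair, 0.99)$nr), 2L)
  # threshold 1 merges only exact duplicates
  expect_equal(n_sequences(dereplicate(pair, 1)$nr), 2L)
  expect_equal(n_sequences(dereplicate(dup, 1)$nr), 1L)
  # threshold near zero collapses everything
  expect_equal(n_sequences(dereplicate(pair, 1e-6)$nr), 1L)
  expect_warning(dereplicate(make_db(character(0))), "empty")
})

test_that("dereplication equals the brute-force greedy oracle", {
  set.seed(22)
  # mixed family structure: 5 ancestors, members at varied identities/lengths
  seqs <- character(0)
  for (f in 1:5) {
    anc <- rand_protein(sample(60:90, 1))
    for (m in 1:6) {
      seqs[sprintf("f%d_m%d", f, m)] <- mutate_k(anc, sample(0:4, 1))
    }
  }
  db <- make_db(seqs)
  for (threshold in c(0.99, 0.97, 0.90)) {
    res <- dereplicate(db, threshold)
    got <- with(res$clusters, setNames(representative, member))
    oracle <- greedy_oracle(seqs, threshold)
    expect_identical(got[names(oracle)], oracle)
  }
})

test_that("normalization factors follow the genome/sequence and length formulas", {
  set.seed(23)
  # 6 genomes x 1 copy -> cn 1; 5 genomes x 2 copies -> cn 0.5
  single <- make_db(replicate(6, rand_protein(300)), gene = "pepM")
  double <- make_db(replicate(10, rand_protein(600)),
                    genome_ids = rep(sprintf("g%d", 1:5), each = 2),
                    gene = "phnM")
  fac <- compute_normalization_factors(list(pepM = single, phnM = double))
  expect_equal(fac$cn_factor[fac$gene == "pepM"], 1)
  expect_equal(fac$cn_factor[fac$gene == "phnM"], 0.5)
  # study mean over 6x300 + 10x600 sequences
  study <- (6 * 300 + 10 * 600) / 16
  expect_equal(attr(fac, "study_mean_length_aa"), study)
  expect_equal(fac$len_factor, study / c(300, 600))
  expect_error(compute_normalization_factors(
    list(pepM = single, phnX = make_db(character(0), gene = "phnX"))),
    "phnX")
})

test_that("equal-size databases with lengths 300 and 600 give factors 1.5 and 0.75", {
  set.seed(24)
  a <- make_db(replicate(10, rand_protein(300)), gene = "pepM")
  b <- make_db(replicate(10, rand_protein(600)), gene = "aepY")
  fac <- compute_normalization_factors(list(pepM = a, aepY = b))
  expect_equal(attr(fac, "study_mean_length_aa"), 450)
  expect_equal(fac$len_factor, c(1.5, 0.75))
})

test_that("sequence-weighted mean of len_factor-corrected lengths is the study mean", {
  set.seed(25)
  dbs <- lapply(1:4, function(i)
    make_db(replicate(sample(3:8, 1), rand_protein(sample(c(200, 350, 500), 1))),
            gene = PHOSPHONATE_GENES[i]))
  names(dbs) <- PHOSPHONATE_GENES[1:4]
  fac <- compute_normalization_factors(dbs)
  lhs <- sum(fac$n_sequences * fac$mean_length_aa * fac$len_factor) /
    sum(fac$n_sequences)
  expect_equal(lhs, attr(fac, "study_mean_length_aa"))
})

test_that("duplicating sequences without genomes halves the copy-number factor", {
  set.seed(26)
  db <- make_db(replicate(4, rand_protein(100)), gene = "pepM")
  rec2 <- db$records
  rec2$seq_id <- paste0(rec2$seq_id, "_dup")
  dupl <- gene_database(rbind(db$records, rec2), gene = "pepM")
  fac1 <- compute_normalization_factors(list(pepM = db))
  fac2 <- compute_normalization_factors(list(pepM = dupl))
  expect_equal(fac2$cn_factor, fac1$cn_factor / 2)
  # duplicating genomes alongside restores the factor
  rec3 <- db$records
  rec3$seq_id <- paste0(rec3$seq_id, "_dup")
  rec3$genome_id <- paste0(rec3$genome_id, "_dup")
  both <- gene_database(rbind(db$records, rec3), gene = "pepM")
  expect_equal(compute_normalization_factors(list(pepM = both))$cn_factor,
               fac1$cn_factor)
})

test_that("presence matrix marks contributing genomes; column sums match", {
  set.seed(27)
  dbs <- list(
    make_db(replicate(2, rand_protein(50)), genome_ids = c("gA", "gB"),
            gene = "pepM"),
    make_db(replicate(3, rand_protein(50)), genome_ids = c("gA", "gA", "gC"),
            gene = "aepY"))
  P <- presence_matrix(dbs)
  expect_equal(dim(P), c(3L, 2L))
  expect_true(P["gA", "pepM"] && P["gA", "aepY"])
  expect_false(P["gC", "pepM"])
  expect_equal(unname(colSums(P)),
               vapply(dbs, n_genomes, integer(1)), ignore_attr = TRUE)
  expect_equal(dim(presence_matrix(list())), c(0L, 0L))
})
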