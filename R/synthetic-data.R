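# Synthetic reference databases, communities, and hit tables with known
# ground truth, so every pipeline stage is testable without downloads.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic generator: community
#' composition, per-gene carrier probabilities (marine-survey-like
#' prevalences), copy numbers, sequence lengths, the sequencing model and
#' the identity model for true hits and planted decoys.
#'
#' The hit-count model is Poisson with rate proportional to
#' (genome abundance) x (copies) x (gene length): the minimal model under
#' which the copy-number and length corrections are exactly the right
#' inverse transforms. All genes and markers default to the same mean
#' length (350 aa), the identifiability condition under which the planted
#' carrier fraction is the analytic expectation of relative abundance;
#' unequal lengths are exercised explicitly in length-bias checks.
#'
#' @param seed global integer seed; a hierarchical seed tree (per sample,
#'   per gene) is derived from it so subsets rerun reproducibly.
#' @param n_genomes community size (genomes).
#' @param genes phosphonate genes to simulate.
#' @param class_pool taxonomic class names; relative frequencies are drawn
#'   from a Dirichlet with concentration `class_concentration`.
#' @param class_concentration Dirichlet concentration parameter.
#' @param carrier_prob named per-gene carrier probabilities.
#' @param cooccurrence conditional overrides, a named list
#'   `list(co_gene = c(src_gene = prob))` meaning P(co | src) = prob for
#'   genomes carrying src (non-carriers of src fall back to
#'   `carrier_prob[co]`).
#' @param copy_number named per-gene copies per carrier genome (constant;
#'   default 1).
#' @param gene_length_aa named per-gene mean sequence length (aa); any
#'   gene or marker not named uses `default_length_aa`.
#' @param default_length_aa default mean length, 350 aa.
#' @param abundance_meanlog,abundance_sdlog log-normal genome abundance
#'   model (normalized to sum to 1).
#' @param n_samples number of sequenced samples (replicate draws).
#' @param total_reads reads per sample (Poisson rate scale).
#' @param read_length_bp 100 (TARA-like) or 125 (MOTS-like).
#' @param l_norm fixed rate constant: expected hits for a gene of length L
#'   carried by the whole community are `total_reads * L / l_norm`.
#' @param decoy_rate expected planted decoys per true hit; decoys carry
#'   identities strictly below the gene's threshold so filter correctness
#'   is testable exactly.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 500L,
                       genes = PHOSPHONATE_GENES,
                       class_pool = c(
                         "Alphaproteobacteria", "Gammaproteobacteria",
                         "Betaproteobacteria", "Deltaproteobacteria",
                         "Actinomycetia", "Bacilli", "Clostridia",
                         "Cyanobacteriia", "Bacteroidia", "Planctomycetia",
                         "Verrucomicrobiae", "Nitrososphaeria",
                         "Thermoplasmata", "Halobacteria", "Acidimicrobiia"),
                       class_concentration = 1,
                       carrier_prob = NULL,
                       cooccurrence = list(aepY = c(pepM = 0.86)),
                       copy_number = NULL,
                       gene_length_aa = NULL,
                       default_length_aa = 350,
                       abundance_meanlog = 0,
                       abundance_sdlog = 1,
                       n_samples = 6L,
                       total_reads = 1e6,
                       read_length_bp = 100L,
                       l_norm = 1e5,
                       decoy_rate = 0.2) {
  default_carrier <- c(
    pepM = 0.20, aepY = 0.18, phpC = 0.12, mpnS = 0.03, hepD = 0.01,
    palA = 0.02, phnA = 0.08, phnW = 0.30, phnX = 0.05, phnY = 0.08,
    phnZ = 0.20, phnI = 0.03, phnJ = 0.04, phnM = 0.03)
  cp <- default_carrier[genes]
  names(cp) <- genes
  cp[is.na(cp)] <- 0.1
  if (!is.null(carrier_prob)) cp[names(carrier_prob)] <- carrier_prob
  stopifnot(all(cp >= 0 & cp <= 1), total_reads > 0, n_genomes >= 1L)
  cn <- stats::setNames(rep(1L, length(genes)), genes)
  if (!is.null(copy_number)) cn[names(copy_number)] <- copy_number
  len <- stats::setNames(rep(default_length_aa, length(c(genes, MARKER_GENES))),
                         c(genes, MARKER_GENES))
  if (!is.null(gene_length_aa)) len[names(gene_length_aa)] <- gene_length_aa
  stopifnot(all(len > 0))
  for (co in names(cooccurrence)) {
    stopifnot(all(cooccurrence[[co]] >= 0 & cooccurrence[[co]] <= 1))
  }
  # keep only overrides whose genes are actually simulated
  cooccurrence <- cooccurrence[names(cooccurrence) %in% genes]
  cooccurrence <- Filter(function(ov) all(names(ov) %in% genes), cooccurrence)
  structure(list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    genes = genes, class_pool = class_pool,
    class_concentration = class_concentration,
    carrier_prob = cp, cooccurrence = cooccurrence, copy_number = cn,
    gene_length_aa = len,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    n_samples = as.integer(n_samples), total_reads = total_reads,
    read_length_bp = as.integer(read_length_bp), l_norm = l_norm,
    decoy_rate = decoy_rate),
    class = "SimConfig")
}

# deterministic child seeds below 2^31
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  ints <- utf8ToInt(key)
  h <- 0
  for (v in ints) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

mutate_at <- function(sequence, positions) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate gene-family reference databases with planted structure
#'
#' Per gene family, generates members from a random ancestor by point
#' mutation at a specified identity (no indels, so the family is its own
#' ungapped alignment), plants three conserved residues that satisfy the
#' emitted rule file, optionally plants a fraction of rule violators, and
#' emits a locus table in which a configurable fraction of phpC candidates
#' lack companion genes (for synteny-verification tests). Deterministic
#' given the config seed.
#'
#' @param config a `SimConfig`.
#' @param n_seq_per_gene members per family (distributed over genomes
#'   according to the gene's copy number).
#' @param member_identity target identity of each member to the ancestor,
#'   in `(0, 1]`; mutations avoid rule columns.
#' @param violator_fraction fraction of members given a disallowed residue
#'   at one rule position.
#' @param orphan_fraction fraction of phpC locus entries placed without a
#'   companion gene within reach.
#' @param synteny_window locus-rank window used when placing companions.
#' @return list with `databases` (named list of redundant `GeneDatabase`),
#'   `alignments` (named character vectors), `rules` (data.frame),
#'   `loci` (data.frame), `violators` (named list of planted violator
#'   seq_ids).
#' @export
simulate_reference_databases <- function(config = sim_config(),
                                         n_seq_per_gene = 12L,
                                         member_identity = 0.90,
                                         violator_fraction = 0,
                                         orphan_fraction = 0,
                                         synteny_window = 10L) {
  stopifnot(inherits(config, "SimConfig"),
            member_identity > 0, member_identity <= 1)
  databases <- list()
  alignments <- list()
  rules <- list()
  loci <- list()
  violators <- list()
  genes <- config$genes
  for (gene in genes) {
    set.seed(child_seed(config$seed, "refdb", gene))
    L <- round(config$gene_length_aa[[gene]])
    if (L * (1 - member_identity) > L - 3L) {
      stop("infeasible identity target for gene ", gene)
    }
    ancestor <- random_aa(L)
    rule_pos <- sort(sample(seq_len(L), 3L))
    anchor_chars <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
    copies <- config$copy_number[[gene]]
    n_gen <- max(1L, ceiling(n_seq_per_gene / copies))
    genome_ids <- sprintf("%s_g%03d", gene, seq_len(n_gen))
    seq_genomes <- rep(genome_ids, each = copies)[seq_len(n_seq_per_gene)]
    n_mut <- round((1 - member_identity) * L)
    mutable <- setdiff(seq_len(L), rule_pos)
    n_violators <- round(violator_fraction * n_seq_per_gene)
    # anchor (first member) is never a violator
    violator_idx <- if (n_violators > 0L)
      1L + sample(n_seq_per_gene - 1L, n_violators) else integer(0L)
    seqs <- character(n_seq_per_gene)
    ids <- sprintf("%s_s%03d", gene, seq_len(n_seq_per_gene))
    for (i in seq_len(n_seq_per_gene)) {
      # the anchor (first member) is the unmutated ancestor, so members at
      # identity >= threshold to it join its cluster deterministically
      s <- if (i > 1L && n_mut > 0L) {
        mutate_at(ancestor, sample(mutable, min(n_mut, length(mutable))))
      } else ancestor
      if (i %in% violator_idx) {
        s <- mutate_at(s, sample(rule_pos, 1L))
      }
      seqs[i] <- s
    }
    classes <- sample(config$class_pool, n_gen, replace = TRUE)
    records <- data.frame(
      seq_id = ids, gene = gene, genome_id = seq_genomes,
      domain = "Bacteria",
      class = classes[match(seq_genomes, genome_ids)],
      marine = TRUE, length_aa = nchar(seqs), sequence = seqs,
      stringsAsFactors = FALSE)
    databases[[gene]] <- gene_database(records, gene = gene, redundant = TRUE)
    alignments[[gene]] <- stats::setNames(seqs, ids)
    rules[[gene]] <- data.frame(
      gene = gene, ref_seq_id = ids[1L], ref_position = rule_pos,
      allowed = anchor_chars[rule_pos], role = "catalytic",
      stringsAsFactors = FALSE)
    violators[[gene]] <- ids[violator_idx]

    # locus table: one contig per genome; companion phnW placed within the
    # window except for a planted orphan fraction (phpC only)
    first_idx <- !duplicated(seq_genomes)
    orphan <- rep(FALSE, sum(first_idx))
    if (gene == "phpC" && orphan_fraction > 0) {
      orphan[sample(length(orphan),
                    round(orphan_fraction * length(orphan)))] <- TRUE
    }
    gi <- 0L
    for (g_idx in which(first_idx)) {
      gi <- gi + 1L
      genome <- seq_genomes[g_idx]
      contig <- paste0(genome, "_c1")
      base <- 10L
      loci[[length(loci) + 1L]] <- data.frame(
        genome_id = genome, contig_id = contig, locus_index = base,
        gene_label = gene, seq_id = ids[g_idx], stringsAsFactors = FALSE)
      companion_offset <- if (orphan[gi]) synteny_window + 15L else 2L
      loci[[length(loci) + 1L]] <- data.frame(
        genome_id = genome,
        contig_id = if (orphan[gi]) paste0(genome, "_c2") else contig,
        locus_index = base + companion_offset,
        gene_label = "phnW",
        seq_id = paste0(genome, "_phnW"), stringsAsFactors = FALSE)
    }
  }
  list(databases = databases, alignments = alignments,
       rules = do.call(rbind, unname(rules)),
       loci = do.call(rbind, loci), violators = violators)
}

#' Simulate a community with known gene content and abundances
#'
#' Draws genome classes from a Dirichlet-weighted pool, per-gene carrier
#' status from `carrier_prob` with conditional co-occurrence overrides,
#' constant per-gene copy numbers for carriers, and log-normal genome
#' abundances normalized to sum to one. The truth table is computed
#' analytically from the realized community.
#'
#' @param config a `SimConfig`.
#' @return list of class `SyntheticCommunity`: `genomes` (data.frame with
#'   `genome_id`, `class`, `abundance`), `content` (genome-by-gene copy
#'   matrix), `truth` (data.frame `gene`, `carrier_fraction`,
#'   `weighted_copies` = abundance-weighted copies per community member),
#'   `config`.
#' @export
simulate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(child_seed(config$seed, "community"))
  n <- config$n_genomes
  genes <- config$genes
  class_w <- stats::rgamma(length(config$class_pool),
                           shape = config$class_concentration)
  class_w <- class_w / sum(class_w)
  classes <- sample(config$class_pool, n, replace = TRUE, prob = class_w)
  abundance <- stats::rlnorm(n, config$abundance_meanlog,
                             config$abundance_sdlog)
  abundance <- abundance / sum(abundance)

  content <- matrix(0L, nrow = n, ncol = length(genes),
                    dimnames = list(sprintf("genome_%04d", seq_len(n)), genes))
  # source genes (unconditioned) first, then conditional overrides
  conditioned <- names(config$cooccurrence)
  for (gene in setdiff(genes, conditioned)) {
    content[, gene] <- stats::rbinom(n, 1L, config$carrier_prob[[gene]])
  }
  for (co in conditioned) {
    overrides <- config$cooccurrence[[co]]
    src <- names(overrides)[1L]
    if (!src %in% genes) stop("co-occurrence source gene not simulated: ", src)
    has_src <- content[, src] == 1L
    p <- ifelse(has_src, overrides[[1L]], config$carrier_prob[[co]])
    content[, co] <- stats::rbinom(n, 1L, p)
  }
  for (gene in genes) {
    content[, gene] <- content[, gene] * config$copy_number[[gene]]
  }
  carrier_fraction <- vapply(genes, function(g)
    sum(abundance[content[, g] > 0L]), numeric(1L))
  weighted_copies <- vapply(genes, function(g)
    sum(abundance * content[, g]), numeric(1L))
  truth <- data.frame(gene = genes,
                      carrier_fraction = carrier_fraction,
                      weighted_copies = weighted_copies,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    genomes = data.frame(genome_id = rownames(content), class = classes,
                         abundance = abundance, stringsAsFactors = FALSE),
    content = content, truth = truth, config = config),
    class = "SyntheticCommunity")
}

#' Expected relative abundance implied by the truth table
#'
#' For single-copy genes at the default equal-length conditions this is
#' simply 100 x carrier fraction; in general it is the carrier fraction
#' adjusted by the realized copies and the copy-number and length factors
#' of the reference databases used for normalization.
#'
#' @param truth truth data.frame from [simulate_community()].
#' @param factors normalization factors (default: identity factors, i.e.
#'   single-copy equal-length databases).
#' @param gene_length_aa named gene lengths used by the sequencing model.
#' @param recA_length_aa recA baseline length of the marker normalization.
#' @return data.frame `gene`, `expected_relative_abundance_pct`.
#' @export
expected_relative_abundance <- function(truth, factors = NULL,
                                        gene_length_aa = NULL,
                                        recA_length_aa = 350) {
  cn <- lenf <- stats::setNames(rep(1, nrow(truth)), truth$gene)
  if (!is.null(factors)) {
    i <- match(truth$gene, factors$gene)
    if (anyNA(i)) stop("factors missing gene(s): ",
                       paste(truth$gene[is.na(i)], collapse = ", "))
    cn <- factors$cn_factor[i]
    lenf <- factors$len_factor[i]
  }
  len <- if (is.null(gene_length_aa)) rep(recA_length_aa, nrow(truth)) else
    gene_length_aa[truth$gene]
  data.frame(
    gene = truth$gene,
    expected_relative_abundance_pct =
      100 * truth$weighted_copies * cn * lenf * len / recA_length_aa,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate per-sample tabular hit files from a community
#'
#' For each sample, gene (phosphonate families plus the five single-copy
#' markers) and genome, the passing-hit count is Poisson with rate
#' `total_reads * abundance * copies * length / l_norm`. Rows carry
#' identities drawn uniformly at or above the gene's threshold, alignment
#' lengths at or above the read-length profile's minimum, and distinct
#' query ids with `/1` and `/2` mates. Decoys with identities strictly
#' below threshold are appended at `decoy_rate` per true hit. Deterministic
#' given the config seed: identical seeds produce byte-identical files.
#'
#' @param community a `SyntheticCommunity`.
#' @param out_dir output directory; created if needed.
#' @param config defaults to the community's config.
#' @return list: `manifest` (data.frame `sample_id, gene, path,
#'   read_length, total_reads`), `samples` (metadata data.frame), paths
#'   `manifest_path`, `samples_path`, `truth_path`, `markers_path`, and
#'   `true_counts` (data.frame of planted passing-hit counts per sample
#'   and gene).
#' @export
simulate_hit_tables <- function(community, out_dir,
                                config = community$config) {
  stopifnot(inherits(community, "SyntheticCommunity"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- screen_config(config$read_length_bp)
  min_aln <- scfg$min_aln_length_aa
  genes <- c(config$genes, MARKER_GENES)
  abundance <- community$genomes$abundance
  content <- community$content

  depth_zones <- rep(c("SUR", "DCM", "MES"), length.out = config$n_samples)
  seasons <- rep(c("summer", "winter"), length.out = config$n_samples)
  sample_ids <- sprintf("sim%02d", seq_len(config$n_samples))
  set.seed(child_seed(config$seed, "phosphate"))
  phosphate <- round(stats::rlnorm(config$n_samples, log(0.3), 1), 3)

  manifest <- list()
  true_counts <- list()
  for (s in seq_along(sample_ids)) {
    sid <- sample_ids[s]
    for (gene in genes) {
      set.seed(child_seed(config$seed, "hits", sid, gene))
      L <- config$gene_length_aa[[gene]]
      copies <- if (gene %in% MARKER_GENES) rep(1L, nrow(content)) else
        content[, gene]
      lambda <- config$total_reads * abundance * copies * L / config$l_norm
      n_true <- sum(stats::rpois(length(lambda), lambda))
      thr <- scfg$min_identity_pct[[gene]]
      n_decoy <- stats::rpois(1L, config$decoy_rate * n_true)
      n_rows <- n_true + n_decoy
      path <- file.path(out_dir, sprintf("%s_%s.m8", sid, gene))
      if (n_rows > 0L) {
        mate <- rep(c("1", "2"), length.out = n_rows)
        qid <- sprintf("%s_%s_r%06d/%s", sid, gene, seq_len(n_rows), mate)
        ident <- c(round(stats::runif(n_true, thr, 100), 1),
                   round(stats::runif(n_decoy, 20, thr - 0.5), 1))
        alen <- min_aln + sample(0:1, n_rows, replace = TRUE)
        lines <- sprintf(
          "%s\t%s_ref\t%.1f\t%d\t%d\t0\t1\t%d\t1\t%d\t%.1e\t%.1f",
          qid, gene, ident, alen, pmax(0L, round(alen * (1 - ident / 100))),
          alen * 3L, alen, 1e-20, ident * alen / 25)
      } else {
        lines <- character(0L)
      }
      writeLines(lines, path)
      manifest[[length(manifest) + 1L]] <- data.frame(
        sample_id = sid, gene = gene, path = path,
        read_length = config$read_length_bp,
        total_reads = config$total_reads, stringsAsFactors = FALSE)
      true_counts[[length(true_counts) + 1L]] <- data.frame(
        sample_id = sid, gene = gene, true_hits = n_true,
        decoys = n_decoy, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  true_counts <- do.call(rbind, true_counts)
  samples <- data.frame(
    sample_id = sample_ids, dataset = "synthetic",
    depth_zone = depth_zones, region = "synthetic_basin", season = seasons,
    phosphate_umol_L = phosphate,
    read_length_bp = config$read_length_bp,
    total_reads = config$total_reads, stringsAsFactors = FALSE)

  manifest_path <- file.path(out_dir, "manifest.tsv")
  samples_path <- file.path(out_dir, "samples.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  markers_path <- file.path(out_dir, "markers.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(community$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(marker = MARKER_GENES,
               length_aa = config$gene_length_aa[MARKER_GENES]),
    markers_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(manifest = manifest, samples = samples, true_counts = true_counts,
       manifest_path = manifest_path, samples_path = samples_path,
       truth_path = truth_path, markers_path = markers_path)
}

#' Simulate samples for phosphate-regression recovery
#'
#' Generates per-sample phosphate concentrations (log-normal) and relative
#' abundances following a power law in (Pi + pseudocount) with log-normal
#' noise, so [loglog_pi_regression()] should recover the planted slope.
#'
#' @param n samples.
#' @param slope,intercept planted power-law parameters on the log scale.
#' @param noise_sd standard deviation of the Gaussian log-noise.
#' @param pseudocount phosphate pseudocount (default 0.01).
#' @param seed integer seed.
#' @param missing_frac fraction of samples with missing phosphate.
#' @return data.frame `phosphate_umol_L`, `abundance`.
#' @export
simulate_regression_samples <- function(n = 50L, slope = -0.8,
                                        intercept = 1, noise_sd = 0.3,
                                        pseudocount = 0.01, seed = 1L,
                                        missing_frac = 0) {
  set.seed(as.integer(seed))
  pi_vals <- stats::rlnorm(n, log(0.3), 1)
  log_ab <- intercept + slope * log(pi_vals + pseudocount) +
    stats::rnorm(n, 0, noise_sd)
  if (missing_frac > 0) {
    pi_vals[sample(n, round(missing_frac * n))] <- NA_real_
  }
  data.frame(phosphate_umol_L = pi_vals, abundance = exp(log_ab))
}
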