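# Normalized counts, marker-based community size, relative abundance.

#' Default single-copy marker reference lengths
#'
#' Mean reference protein lengths (aa) for the five conserved single-copy
#' genes used as the community-size proxy. recA is the shortest and is the
#' base of the marker length normalization. Values are configurable inputs;
#' any named numeric vector over the five markers may be supplied instead.
#'
#' @param length_aa optional named overrides.
#' @return named numeric vector over `recA, atpD, tufA, gyrB, hsp70`.
#' @export
marker_lengths <- function(length_aa = NULL) {
  lengths <- c(recA = 350, atpD = 460, tufA = 396, gyrB = 640, hsp70 = 620)
  if (!is.null(length_aa)) {
    stopifnot(!is.null(names(length_aa)))
    lengths[names(length_aa)] <- length_aa
  }
  if (!all(MARKER_GENES %in% names(lengths))) {
    stop("marker lengths must cover: ", paste(MARKER_GENES, collapse = ", "))
  }
  lengths <- lengths[MARKER_GENES]
  if (any(lengths <= 0)) stop("marker lengths must be positive")
  if (lengths[["recA"]] > min(lengths)) {
    warning("recA is not the shortest marker; community size may be ",
            "over-estimated relative to the recA baseline")
  }
  lengths
}

#' Normalize a raw gene hit count
#'
#' Applies the copy-number and gene-length corrections:
#' raw count x cn_factor x len_factor.
#'
#' @param raw_count non-negative raw hit count.
#' @param gene gene name.
#' @param factors data.frame from [compute_normalization_factors()].
#' @return Normalized count (real, >= 0).
#' @export
normalized_gene_count <- function(raw_count, gene, factors) {
  stopifnot(all(raw_count >= 0))
  i <- match(gene, factors$gene)
  if (anyNA(i)) {
    stop("no normalization factors for gene(s): ",
         paste(gene[is.na(i)], collapse = ", "))
  }
  raw_count * factors$cn_factor[i] * factors$len_factor[i]
}

#' Marker-based community size proxy
#'
#' Mean of the length-normalized counts of the five conserved single-copy
#' genes; each marker count is scaled by (length of recA)/(length of the
#' marker) so longer markers do not inflate the community-size estimate.
#'
#' @param marker_counts named numeric vector of raw counts for the five
#'   markers.
#' @param lengths named marker lengths, see [marker_lengths()].
#' @param missing how to handle absent markers: `"error"` (default) or
#'   `"mean_available"` (mean over present markers, with a warning).
#' @return Community size (real >= 0). Zero community size is returned
#'   with a warning since downstream relative abundance is undefined.
#' @export
marker_community_size <- function(marker_counts, lengths = marker_lengths(),
                                  missing = c("error", "mean_available")) {
  missing <- match.arg(missing)
  absent <- setdiff(MARKER_GENES, names(marker_counts))
  if (length(absent) > 0L) {
    if (missing == "error") {
      stop("missing marker count(s): ", paste(absent, collapse = ", "))
    }
    warning("missing marker count(s), averaging over available: ",
            paste(absent, collapse = ", "))
  }
  use <- intersect(MARKER_GENES, names(marker_counts))
  normalized <- marker_counts[use] * lengths[["recA"]] / lengths[use]
  size <- mean(normalized)
  if (size == 0) warning("community size is zero; relative abundance undefined")
  size
}

#' Per-sample per-gene relative abundance table
#'
#' Divides the copy-number- and length-normalized phosphonate gene count by
#' the marker-based community size and reports the result as a percentage
#' of community members. Samples with zero community size are excluded and
#' listed in attribute `excluded_samples`. Values above 100% are permitted
#' (a gene can out-count the marker average) and flagged with a warning.
#'
#' @param counts `GeneCountTable` from [count_hits()] or
#'   [screen_samples()], containing both phosphonate genes and the five
#'   markers.
#' @param factors normalization factors for the phosphonate genes.
#' @param lengths marker lengths, see [marker_lengths()].
#' @param metadata optional sample metadata data.frame (keyed `sample_id`)
#'   merged onto the output.
#' @return data.frame of class `AbundanceTable` with columns `sample_id`,
#'   `gene`, `raw_count`, `normalized_count`, `community_size`,
#'   `relative_abundance_pct` and, when `total_reads` is present in
#'   `counts`, `rate_per_100k`.
#' @export
relative_abundance_table <- function(counts, factors,
                                     lengths = marker_lengths(),
                                     metadata = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("sample_id", "gene", "raw_count") %in% names(counts)))
  samples <- unique(counts$sample_id)
  sizes <- vapply(samples, function(s) {
    sub <- counts[counts$sample_id == s & counts$gene %in% MARKER_GENES, ]
    mc <- stats::setNames(sub$raw_count, sub$gene)
    suppressWarnings(marker_community_size(mc, lengths))
  }, numeric(1L))
  zero <- samples[sizes == 0 | is.na(sizes)]
  if (length(zero) > 0L) {
    warning("excluding sample(s) with zero community size: ",
            paste(zero, collapse = ", "))
  }
  keep_samples <- setdiff(samples, zero)
  out <- counts[counts$sample_id %in% keep_samples &
                  counts$gene %in% factors$gene, , drop = FALSE]
  out <- as.data.frame(out)
  out$normalized_count <- normalized_gene_count(out$raw_count, out$gene,
                                                factors)
  out$community_size <- sizes[out$sample_id]
  out$relative_abundance_pct <-
    100 * out$normalized_count / out$community_size
  if (any(out$relative_abundance_pct > 100)) {
    warning(sum(out$relative_abundance_pct > 100),
            " relative abundance value(s) exceed 100%")
  }
  if ("total_reads" %in% names(out)) {
    out$rate_per_100k <- rate_per_100k(out$raw_count, out$total_reads)
  }
  if (!is.null(metadata)) {
    out <- merge(out, metadata, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "excluded_samples") <- zero
  class(out) <- c("AbundanceTable", class(out))
  out
}

#' Hits per 100,000 reads
#'
#' @param raw_count raw hit count(s).
#' @param total_reads sequencing depth (> 0).
#' @return `raw_count * 1e5 / total_reads`.
#' @export
rate_per_100k <- function(raw_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  raw_count * 1e5 / total_reads
}

#' Reshape an abundance table to a samples-by-genes matrix
#'
#' @param abundance an `AbundanceTable`.
#' @param value which column to spread (default `relative_abundance_pct`).
#' @return numeric matrix, rows = samples, columns = genes.
#' @export
abundance_matrix <- function(abundance, value = "relative_abundance_pct") {
  stopifnot(value %in% names(abundance))
  samples <- unique(abundance$sample_id)
  genes <- unique(abundance$gene)
  mat <- matrix(0, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  mat[cbind(match(abundance$sample_id, samples),
            match(abundance$gene, genes))] <- abundance[[value]]
  mat
}
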