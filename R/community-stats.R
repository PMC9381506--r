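# Co-occurrence fractions, diversity, ANOVA/Tukey, regression, Bray-Curtis.

#' Genome co-occurrence fractions
#'
#' For each (source gene, co-occurring gene) pair, the fraction of genomes
#' carrying the source gene that also carry the co-occurring gene. The
#' matrix is generally asymmetric because each column conditions on a
#' different genome subset; the diagonal is 1 wherever the source gene has
#' at least one genome.
#'
#' @param presence logical genome-by-gene matrix from [presence_matrix()].
#' @return list of class `CooccurrenceMatrix` with `fraction` (source gene
#'   x co-gene matrix; columns with zero source genomes are `NA` and
#'   reported via attribute `undefined_genes`) and `n_source_genomes`
#'   (named integer vector).
#' @export
cooccurrence_matrix <- function(presence) {
  stopifnot(is.matrix(presence))
  if (nrow(presence) == 0L || ncol(presence) == 0L) stop("empty presence matrix")
  storage.mode(presence) <- "logical"
  p <- presence * 1L
  joint <- t(p) %*% p                     # co-carrier genome counts
  n_source <- diag(joint)
  frac <- joint / n_source                # row = source gene (divides rowwise)
  frac[n_source == 0L, ] <- NA_real_
  undefined <- colnames(presence)[n_source == 0L]
  if (length(undefined) > 0L) {
    warning("gene(s) with zero source genomes: ",
            paste(undefined, collapse = ", "))
  }
  structure(list(fraction = frac,
                 n_source_genomes = stats::setNames(as.integer(n_source),
                                                    colnames(presence))),
            class = "CooccurrenceMatrix", undefined_genes = undefined)
}

#' @export
print.CooccurrenceMatrix <- function(x, digits = 2, ...) {
  cat("Genome co-occurrence fractions (rows = source gene):\n")
  print(round(x$fraction, digits))
  invisible(x)
}

#' Write a co-occurrence matrix in long format
#'
#' @param cooc a `CooccurrenceMatrix`.
#' @param path TSV path (`source_gene  co_gene  fraction  n_source`).
#' @export
write_cooccurrence <- function(cooc, path) {
  long <- expand.grid(source_gene = rownames(cooc$fraction),
                      co_gene = colnames(cooc$fraction),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$fraction <- cooc$fraction[cbind(long$source_gene, long$co_gene)]
  long$n_source <- cooc$n_source_genomes[long$source_gene]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shannon index and Pielou evenness of a label tally
#'
#' H = -sum p_i log p_i over label frequencies (natural log by default);
#' evenness J = H / log(S) for S > 1 classes, undefined (NA) for a single
#' class. Used for the taxonomic-class diversity of each gene database.
#'
#' @param labels character vector of class labels (one per sequence), or a
#'   named tally of counts.
#' @param base logarithm base (default `exp(1)`).
#' @return list of class `DiversitySummary`: `H`, `S`, `J`,
#'   `class_fractions`.
#' @export
shannon_evenness <- function(labels, base = exp(1)) {
  if (length(labels) == 0L) stop("no labels supplied")
  counts <- if (!is.null(names(labels)) && is.numeric(labels)) {
    labels[labels > 0]
  } else {
    table(as.character(labels))
  }
  p <- as.numeric(counts) / sum(counts)
  H <- -sum(p * log(p, base = base))
  S <- length(p)
  structure(list(H = H, S = S,
                 J = if (S > 1L) H / log(S, base = base) else NA_real_,
                 class_fractions = stats::setNames(p, names(counts))),
            class = "DiversitySummary")
}

#' @export
print.DiversitySummary <- function(x, ...) {
  cat(sprintf("Shannon H = %.3f over S = %d classes (evenness J = %.3f)\n",
              x$H, x$S, x$J))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Standard between/within sums-of-squares decomposition with
#' F = MS_between / MS_within and the upper-tail p-value from the F
#' distribution.
#'
#' @param groups list (>= 2 elements, each with n >= 2) of numeric vectors,
#'   or a numeric vector with `g` giving group labels.
#' @param g optional group factor when `groups` is a single vector.
#' @return list of class `AnovaResult`: `F`, `df_between`, `df_within`,
#'   `p`, `group_means`, `ms_within`, `group_n`.
#' @export
one_way_anova <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need at least two groups")
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("each group needs n >= 2")
  x <- unlist(groups, use.names = FALSE)
  if (stats::var(x) == 0) stop("degenerate input: zero total variance")
  means <- vapply(groups, mean, numeric(1L))
  grand <- mean(x)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1L)))
  df_b <- length(groups) - 1L
  df_w <- sum(n_i) - length(groups)
  ms_w <- ss_within / df_w
  if (ms_w == 0) stop("degenerate input: zero within-group variance")
  Fstat <- (ss_between / df_b) / ms_w
  structure(list(F = Fstat, df_between = df_b, df_within = df_w,
                 p = stats::pf(Fstat, df_b, df_w, lower.tail = FALSE),
                 group_means = means, ms_within = ms_w, group_n = n_i),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey honestly-significant-difference test
#'
#' All pairwise group comparisons after a one-way ANOVA. For groups i, j:
#' q = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j)), with the
#' adjusted p-value from the studentized-range distribution with k groups
#' and the ANOVA's within df (`stats::ptukey`, numerically integrated).
#'
#' @inheritParams one_way_anova
#' @return data.frame of class `TukeyResult`: one row per unordered pair
#'   with `group_1`, `group_2`, `mean_diff` (mean_1 - mean_2), `q`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  fit <- one_way_anova(groups)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(names(groups), 2L)
  rows <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt(fit$ms_within / 2 * (1 / fit$group_n[[i]] + 1 / fit$group_n[[j]]))
    diff <- fit$group_means[[i]] - fit$group_means[[j]]
    q <- abs(diff) / se
    data.frame(group_1 = i, group_2 = j, mean_diff = diff, q = q,
               p_adj = stats::ptukey(q, nmeans = k, df = fit$df_within,
                                     lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("TukeyResult", class(out))
  out
}

#' Log-log regression of relative abundance on phosphate
#'
#' Ordinary least squares of log(abundance) on log(Pi + pseudocount). The
#' pseudocount (default 0.01 umol/L) permits samples with phosphate below
#' the detection limit (Pi = 0) to enter the regression. Samples with
#' missing phosphate are excluded and counted; zero abundances are
#' excluded and counted (the pseudocount applies to phosphate only).
#'
#' @param abundance per-sample relative abundance of one gene (> 0 to be
#'   included).
#' @param phosphate_umol_L per-sample phosphate, NA = missing metadata.
#' @param pseudocount added to phosphate before the log (default 0.01).
#' @param base log base; natural log by default. Significance is
#'   base-invariant; the slope is not.
#' @return list of class `RegressionResult`: `slope`, `intercept`,
#'   `slope_p`, `r_squared`, `n`, `pseudocount`, `n_excluded_missing_pi`,
#'   `n_excluded_zero_abundance`.
#' @export
loglog_pi_regression <- function(abundance, phosphate_umol_L,
                                 pseudocount = 0.01, base = exp(1)) {
  stopifnot(length(abundance) == length(phosphate_umol_L))
  if (all(is.na(phosphate_umol_L))) stop("all phosphate values missing")
  miss <- is.na(phosphate_umol_L) | is.na(abundance)
  zero <- !miss & abundance <= 0
  keep <- !miss & !zero
  n <- sum(keep)
  if (n < 3L) stop("need at least 3 usable samples, got ", n)
  y <- log(abundance[keep], base = base)
  x <- log(phosphate_umol_L[keep] + pseudocount, base = base)
  fit <- stats::lm(y ~ x)
  coefs <- summary(fit)$coefficients
  structure(list(
    slope = unname(coefs["x", "Estimate"]),
    intercept = unname(coefs["(Intercept)", "Estimate"]),
    slope_p = unname(coefs["x", "Pr(>|t|)"]),
    r_squared = summary(fit)$r.squared,
    n = n, pseudocount = pseudocount,
    n_excluded_missing_pi = sum(is.na(phosphate_umol_L)),
    n_excluded_zero_abundance = sum(zero)),
    class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf(
    "log-log Pi regression: slope = %.4g (p = %.3g), r^2 = %.3f, n = %d\n",
    x$slope, x$slope_p, x$r_squared, x$n))
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between non-negative abundance
#' vectors; zero for identical samples, one for samples with disjoint
#' support.
#'
#' @param mat samples-by-genes non-negative matrix (e.g. from
#'   [abundance_matrix()]).
#' @return symmetric `dist`-compatible numeric matrix in `[0, 1]` with zero
#'   diagonal.
#' @export
bray_curtis_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  zero_rows <- rownames(mat)[rowSums(mat) == 0]
  if (is.null(rownames(mat))) zero_rows <- which(rowSums(mat) == 0)
  if (length(zero_rows) > 0L) {
    stop("all-zero abundance row(s): ", paste(zero_rows, collapse = ", "))
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d[i, j] <- d[j, i] <-
        sum(abs(mat[i, ] - mat[j, ])) / sum(mat[i, ] + mat[j, ])
    }
  }
  d
}

#' Write a square distance matrix as TSV
#'
#' @param d square matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(as.matrix(d), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
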