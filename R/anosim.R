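# Analysis of similarities (ANOSIM), rank-based permutation test.

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test for separation of predefined groups in a distance
#' matrix. All pairwise distances are ranked (mid-ranks for ties) and
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2 total pairs, so R lies in [-1, 1] and equals 1 when every
#' within-group distance ranks below every between-group distance.
#' Significance comes from permuting group
#' labels: p = (1 + #\{permuted R >= observed R\}) / (1 + n_permutations).
#' With `exact = TRUE` all distinct label permutations are enumerated and
#' p is the exact proportion of permutations (identity included) with
#' R >= observed.
#'
#' @param d distance matrix (`dist` or square symmetric matrix).
#' @param groups group labels, one per sample; every group needs >= 2
#'   members and at least 2 groups are required.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed; required for sampled permutations so pipeline
#'   runs are reproducible.
#' @param exact enumerate all distinct permutations instead of sampling
#'   (feasible for small n).
#' @return list of class `AnosimResult`: `R`, `p`, `n_permutations`,
#'   `seed`, `exact`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999L, seed = NULL,
                        exact = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("group(s) with a single member: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  if (!exact && is.null(seed)) {
    stop("supply a seed for sampled permutations (or set exact = TRUE)")
  }

  lower <- lower.tri(d)
  ranks <- rank(d[lower])                      # mid-ranks for ties
  M <- n * (n - 1L) / 2
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]
  r_stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
  }
  R_obs <- r_stat(groups)

  if (exact) {
    perms <- all_label_permutations(groups)
    R_perm <- vapply(perms, r_stat, numeric(1L))
    p <- mean(R_perm >= R_obs - 1e-12)         # identity permutation included
    n_perm_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    R_perm <- vapply(seq_len(n_permutations),
                     function(i) r_stat(sample(groups)), numeric(1L))
    p <- (1 + sum(R_perm >= R_obs - 1e-12)) / (1 + n_permutations)
    n_perm_used <- as.integer(n_permutations)
  }
  structure(list(R = R_obs, p = p, n_permutations = n_perm_used,
                 seed = seed, exact = exact),
            class = "AnosimResult")
}

#' @export
print.AnosimResult <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s%d permutations)\n",
              x$R, x$p, if (x$exact) "exact, " else "", x$n_permutations))
  invisible(x)
}

# all distinct arrangements of a label multiset (small n only)
all_label_permutations <- function(groups, max_n = 10L) {
  n <- length(groups)
  if (n > max_n) {
    stop("exact enumeration limited to n <= ", max_n, " samples")
  }
  perms <- permutations_of(seq_len(n))
  arrangements <- unique(lapply(perms, function(p) groups[p]))
  arrangements
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}
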