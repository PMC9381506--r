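# Co-occurrence, diversity, ANOVA/Tukey, regression, Bray-Curtis, ANOSIM.

test_that("co-occurrence fractions condition on the source-gene genomes", {
  P <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE,   # pepM
                TRUE, TRUE, FALSE, FALSE, FALSE,  # aepY
                FALSE, TRUE, FALSE, TRUE, FALSE), # phpC
              nrow = 5, dimnames = list(sprintf("g%d", 1:5),
                                        c("pepM", "aepY", "phpC")))
  cooc <- cooccurrence_matrix(P)
  # brute-force oracle by exhaustive pairwise counting
  for (src in colnames(P)) {
    for (co in colnames(P)) {
      carriers <- which(P[, src])
      expect_equal(cooc$fraction[src, co],
                   sum(P[carriers, co]) / length(carriers),
                   info = paste(src, co))
    }
  }
  expect_equal(unname(diag(cooc$fraction)), rep(1, 3))
  expect_equal(unname(cooc$n_source_genomes), unname(colSums(P)))
  # asymmetry: P(aepY|pepM) = 2/3 but P(pepM|aepY) = 1
  expect_equal(cooc$fraction["pepM", "aepY"], 2 / 3)
  expect_equal(cooc$fraction["aepY", "pepM"], 1)
  # fraction x source count is an integer co-carrier count
  nco <- cooc$fraction * cooc$n_source_genomes
  expect_equal(nco, round(nco))
})

test_that("identical gene sets give all-ones co-occurrence; empty columns flagged", {
  P <- matrix(TRUE, 2, 2, dimnames = list(c("g1", "g2"), c("pepM", "aepY")))
  expect_equal(unname(cooccurrence_matrix(P)$fraction), matrix(1, 2, 2))
  P2 <- cbind(P, phnZ = c(FALSE, FALSE))
  expect_warning(cooc <- cooccurrence_matrix(P2), "phnZ")
  expect_true(all(is.na(cooc$fraction["phnZ", ])))
})

test_that("Shannon index and evenness follow the entropy definitions", {
  four <- shannon_evenness(rep(c("a", "b", "c", "d"), 25))
  expect_equal(four$H, log(4))
  expect_equal(four$J, 1)
  one <- shannon_evenness(rep("a", 10))
  expect_equal(one$H, 0)
  expect_true(is.na(one$J))
  # named tally input matches label input
  expect_equal(shannon_evenness(c(a = 5, b = 3, c = 2))$H,
               shannon_evenness(rep(c("a", "b", "c"), c(5, 3, 2)))$H)
  expect_error(shannon_evenness(character(0)), "no labels")
})

test_that("Shannon is permutation-invariant, bounded, and grows on class splits", {
  set.seed(51)
  for (i in 1:5) {
    labels <- sample(letters[1:6], 60, replace = TRUE)
    a <- shannon_evenness(labels)
    b <- shannon_evenness(sample(labels))
    expect_equal(a$H, b$H)
    expect_lte(a$H, log(a$S) + 1e-12)
    expect_gte(a$H, 0)
  }
  # splitting one class into two equal halves increases H
  tall <- c(a = 40, b = 20)
  split <- c(a1 = 20, a2 = 20, b = 20)
  expect_gt(shannon_evenness(split)$H, shannon_evenness(tall)$H)
  # cross-check against vegan's diversity on the same tally
  skip_if_not_installed("vegan")
  tally <- c(a = 12, b = 7, c = 30, d = 1)
  expect_equal(shannon_evenness(tally)$H,
               unname(vegan::diversity(tally, index = "shannon")))
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  fit <- one_way_anova(groups)
  # oracle: SS_between = 3[(2-3)^2+(3-3)^2+(4-3)^2] = 6 over df 2;
  # SS_within = 2+2+2 = 6 over df 6; F = 3/1 = 3
  expect_equal(fit$F, 3)
  expect_equal(fit$df_between, 2L)
  expect_equal(fit$df_within, 6L)
  expect_equal(fit$p, pf(3, 2, 6, lower.tail = FALSE))
  # cross-check against stats::aov on random data
  set.seed(52)
  x <- rnorm(30)
  g <- factor(rep(1:3, 10))
  ours <- one_way_anova(x, g)
  ref <- summary(stats::aov(x ~ g))[[1]]
  expect_equal(ours$F, ref[["F value"]][1])
  expect_equal(ours$p, ref[["Pr(>F)"]][1])
})

test_that("ANOVA F is zero for equal means and shift-invariant", {
  equal <- list(c(1, 3), c(2, 2), c(0, 4))
  expect_equal(one_way_anova(equal)$F, 0)
  set.seed(53)
  groups <- replicate(3, rnorm(8), simplify = FALSE)
  expect_equal(one_way_anova(groups)$F,
               one_way_anova(lapply(groups, `+`, 100))$F)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "n >= 2")
})

test_that("Tukey HSD with two balanced groups equals the pooled t-test", {
  set.seed(54)
  g1 <- rnorm(8, 0, 1)
  g2 <- rnorm(8, 1, 1)
  tk <- tukey_hsd(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$q, sqrt(2) * abs(tt$statistic), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("Tukey HSD is null-calibrated, symmetric-in-pairs and conservative", {
  eq <- list(a = c(5, 5, 6, 6), b = c(5, 6, 5, 6), c = c(6, 5, 6, 5))
  expect_true(all(tukey_hsd(eq)$p_adj > 0.999))
  set.seed(55)
  groups <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(6, 1))
  tk <- tukey_hsd(groups)
  expect_equal(nrow(tk), 3L)
  # adjusted p >= unadjusted pairwise pooled t p for k > 2
  for (i in seq_len(nrow(tk))) {
    tt <- t.test(groups[[tk$group_1[i]]], groups[[tk$group_2[i]]],
                 var.equal = TRUE)
    expect_gte(tk$p_adj[i] + 1e-12, tt$p.value * 0.999)
  }
  # cross-check against stats::TukeyHSD
  x <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  ref <- TukeyHSD(aov(x ~ g))$g
  expect_equal(sort(tk$p_adj), sort(unname(ref[, "p adj"])), tolerance = 1e-8)
})

test_that("studentized-range tail matches a Monte-Carlo oracle", {
  # q upper 5% point at k = 3, df = 10 vs simulation of the range statistic
  set.seed(56)
  n_sim <- 20000
  q_sim <- replicate(n_sim, {
    means <- rnorm(3)
    s <- sqrt(rchisq(1, 10) / 10)
    (max(means) - min(means)) / s
  })
  expect_lt(abs(mean(q_sim >= qtukey(0.95, 3, 10)) - 0.05), 0.02)
})

test_that("log-log Pi regression recovers an exact power law", {
  pi_vals <- c(0, 0.02, 0.05, 0.1, 0.5, 1, 2)
  abundance <- 2 * (pi_vals + 0.01)^(-0.5)
  # exact fit: lm warns that the summary may be unreliable, which is the point
  fit <- suppressWarnings(loglog_pi_regression(abundance, pi_vals))
  expect_equal(fit$slope, -0.5)
  expect_equal(fit$intercept, log(2))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 7L)                     # Pi = 0 included via pseudocount
  expect_equal(fit$n_excluded_missing_pi, 0L)
})

test_that("regression exclusions are counted; degenerate inputs error", {
  pi_vals <- c(NA, 0.1, 0.2, 0.5, 1)
  abundance <- c(5, 0, 2, 1, 0.5)
  fit <- loglog_pi_regression(abundance, pi_vals)
  expect_equal(fit$n, 3L)
  expect_equal(fit$n_excluded_missing_pi, 1L)
  expect_equal(fit$n_excluded_zero_abundance, 1L)
  expect_error(loglog_pi_regression(1:3, rep(NA_real_, 3)), "missing")
  expect_error(loglog_pi_regression(c(1, 2), c(0.1, 0.2, 0.3)), "length")
  expect_error(loglog_pi_regression(c(1, 2, 0), c(0.1, 0.2, 0.3)), "3 usable")
})

test_that("regression recovers a planted slope within Monte-Carlo error", {
  slopes <- vapply(1:20, function(r) {
    d <- simulate_regression_samples(n = 50, slope = -0.8, noise_sd = 0.3,
                                     seed = 5600 + r)
    loglog_pi_regression(d$abundance, d$phosphate_umol_L)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) + 0.8), 3 * se)
})

test_that("Bray-Curtis follows the sum-difference formula", {
  mat <- rbind(s1 = c(2, 2), s2 = c(1, 1), s3 = c(1, 0), s4 = c(0, 1))
  d <- bray_curtis_matrix(mat)
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(d["s3", "s4"], 1)               # disjoint support
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(bray_curtis_matrix(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  expect_error(bray_curtis_matrix(rbind(ok = c(1, 1), bad = c(0, 0))), "bad")
  expect_error(bray_curtis_matrix(rbind(c(1, -1), c(1, 1))), "non-negative")
})

test_that("Bray-Curtis is symmetric and bounded on random inputs", {
  set.seed(57)
  for (i in 1:5) {
    mat <- matrix(rexp(6 * 4), nrow = 6)
    d <- bray_curtis_matrix(mat)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
  }
  skip_if_not_installed("vegan")
  mat <- matrix(rexp(5 * 3), nrow = 5,
                dimnames = list(paste0("s", 1:5), NULL))
  expect_equal(bray_curtis_matrix(mat),
               as.matrix(vegan::vegdist(mat, "bray")), tolerance = 1e-12)
})

test_that("ANOSIM gives R = 1 under perfect group separation", {
  # within-group distances all smaller than between-group distances
  n <- 8
  g <- rep(c("A", "B"), each = 4)
  d <- matrix(0.9, n, n)
  d[1:4, 1:4] <- 0.1
  d[5:8, 5:8] <- 0.1
  diag(d) <- 0
  res <- anosim_test(d, g, exact = TRUE)
  expect_equal(res$R, 1)
  # only the 2 group-preserving labelings of the 70 reach R = 1
  expect_equal(res$p, 2 / 70)
})

test_that("exhaustive ANOSIM at n = 6 matches a brute-force oracle", {
  set.seed(58)
  d <- as.matrix(dist(matrix(rnorm(12), nrow = 6)))
  g <- rep(c("A", "B"), each = 3)
  res <- anosim_test(d, g, exact = TRUE)
  # oracle: enumerate the 20 distinct half-splits directly
  lower <- lower.tri(d)
  ranks <- rank(d[lower])
  pi_ <- row(d)[lower]; pj <- col(d)[lower]
  M <- 15
  r_of <- function(lab) {
    w <- lab[pi_] == lab[pj]
    (mean(ranks[!w]) - mean(ranks[w])) / (M / 2)
  }
  splits <- combn(6, 3)
  R_all <- apply(splits, 2, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"; r_of(lab)
  })
  expect_equal(res$R, r_of(g))
  expect_equal(res$p, mean(R_all >= res$R - 1e-12))
  expect_equal(res$n_permutations, 20L)
})

test_that("ANOSIM is invariant to relabeling and monotone distance transforms", {
  set.seed(59)
  d <- as.matrix(dist(matrix(rnorm(20), nrow = 10)))
  g <- rep(c("A", "B"), 5)
  r1 <- anosim_test(d, g, n_permutations = 99, seed = 7)$R
  r2 <- anosim_test(d, ifelse(g == "A", "x", "y"),
                    n_permutations = 99, seed = 7)$R
  expect_equal(r1, r2)
  r3 <- anosim_test(sqrt(d), g, n_permutations = 99, seed = 7)$R
  expect_equal(r1, r3)                         # rank-based
  skip_if_not_installed("vegan")
  ref <- vegan::anosim(as.dist(d), grouping = factor(g), permutations = 9)
  expect_equal(r1, unname(ref$statistic))
})

test_that("ANOSIM validates groups and requires a seed for sampling", {
  d <- as.matrix(dist(1:5))
  expect_error(anosim_test(d, c("A", "A", "B", "B", "C"), seed = 1),
               "single member")
  expect_error(anosim_test(d, rep("A", 5), seed = 1), "two groups")
  expect_error(anosim_test(d, c("A", "A", "A", "B", "B"),
                           n_permutations = 9), "seed")
  r1 <- anosim_test(d, c("A", "A", "A", "B", "B"), n_permutations = 49,
                    seed = 3)
  r2 <- anosim_test(d, c("A", "A", "A", "B", "B"), n_permutations = 49,
                    seed = 3)
  expect_identical(r1$p, r2$p)                 # seeded, reproducible
})
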