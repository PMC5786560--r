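sim_vec <- function(labels, r, reference = "dream_high", D = 20L) {
  structure(data.frame(label = labels, r = r, stringsAsFactors = FALSE),
            class = c("similarity_vector", "data.frame"),
            reference = reference, D = D)
}

test_that("ranking assigns 1 to the most similar and flags lexicographic tie-breaks", {
  rk <- rank_documents(sim_vec(c("a", "b", "c"), c(0.5, 0.9, 0.1)))
  expect_equal(rk$label, c("b", "a", "c"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$rank_inv, 3:1)
  expect_false(any(rk$tie))
  expect_warning(
    rk2 <- rank_documents(sim_vec(c("zeta", "alpha", "mid"), c(0.4, 0.4, 0.6))),
    "tie")
  expect_equal(rk2$label, c("mid", "alpha", "zeta"))
  expect_equal(rk2$tie, c(FALSE, TRUE, TRUE))
})

test_that("ranks are a permutation of 1..n and invariant to monotone transforms", {
  set.seed(21)
  n <- 165L
  r <- runif(n, -1, 1)
  labs <- sprintf("s%03d", seq_len(n))
  rk <- rank_documents(sim_vec(labs, r))
  expect_setequal(rk$rank, seq_len(n))
  for (f in list(function(x) tanh(3 * x), function(x) exp(x),
                 function(x) x^3 + 2 * x)) {
    rk2 <- rank_documents(sim_vec(labs, f(r)))
    expect_identical(rk2$label, rk$label)
  }
})

test_that("undefined similarities are excluded with a warning; empty is fatal", {
  expect_warning(rk <- rank_documents(sim_vec(c("a", "b"), c(0.2, NA))),
                 "undefined")
  expect_equal(rk$label, "a")
  expect_error(suppressWarnings(
    rank_documents(sim_vec("a", NA_real_))), "no defined")
})

test_that("category summaries match quantiles and honor the exclusion threshold", {
  labs <- sprintf("s%02d", 1:4)
  rk <- rank_documents(sim_vec(labs, c(0.9, 0.8, 0.7, 0.6)))
  scheme <- category_scheme(labs, c("serotonergic", "serotonergic",
                                    "stimulant", "stimulant"))
  out <- suppressMessages(category_rank_summary(rk, scheme, min_n = 0))
  expect_equal(out$median[out$category == "serotonergic"], 1.5)
  expect_equal(out$median[out$category == "stimulant"], 3.5)
  # default threshold excludes sparse categories
  out2 <- suppressMessages(category_rank_summary(rk, scheme, min_n = 6))
  expect_equal(nrow(out2), 0L)
  expect_setequal(attr(out2, "excluded"), c("serotonergic", "stimulant"))
  expect_error(category_rank_summary(rk, category_scheme("s01", "other")),
               "missing from")
})

test_that("two-way ANOVA matches the closed-form balanced decomposition", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 9)
  a <- rep(c("cat1", "cat2"), each = 4)
  b <- rep(c("high", "low", "high", "low"), each = 2)
  want <- balanced_anova_oracle(y, a, b)
  got <- two_way_anova(y, a, b)
  expect_equal(got$F[got$effect == "category"], want$F_a, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "lucidity"], want$F_b, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "interaction"], want$F_ab, tolerance = 1e-10)
  set.seed(22)
  for (i in 1:10) {
    y <- rnorm(24)
    a <- rep(c("c1", "c2", "c3"), each = 8)
    b <- rep(rep(c("high", "low"), each = 4), 3)
    want <- balanced_anova_oracle(y, a, b)
    got <- two_way_anova(y, a, b)
    expect_equal(got$F[got$effect == "category"], want$F_a, tolerance = 1e-10)
    expect_equal(got$F[got$effect == "lucidity"], want$F_b, tolerance = 1e-10)
    expect_equal(got$F[got$effect == "interaction"], want$F_ab,
                 tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate designs behave as symmetry dictates", {
  # duplicating the data across lucidity levels forces lucidity F = 0
  y0 <- c(3, 5, 8, 1, 9, 2, 7, 4)
  a0 <- rep(c("c1", "c2"), each = 4)
  got <- two_way_anova(c(y0, y0), rep(a0, 2),
                       rep(c("high", "low"), each = 8))
  expect_equal(got$F[got$effect == "lucidity"], 0, tolerance = 1e-12)
  expect_equal(got$F[got$effect == "interaction"], 0, tolerance = 1e-12)
  # equal cell means with residual noise: all F = 0, p = 1
  y1 <- c(1, 3, 1, 3, 1, 3, 1, 3)
  got1 <- two_way_anova(y1, rep(c("c1", "c2"), each = 4),
                        rep(c("high", "low", "high", "low"), each = 2))
  expect_true(all(abs(got1$F[got1$effect != "residuals"]) < 1e-12))
  expect_true(all(got1$p[got1$effect != "residuals"] > 0.999))
  # singleton categories are fatal
  expect_error(two_way_anova(1:3, c("c1", "c1", "c2"), c("h", "l", "h")),
               "single observation")
  expect_error(two_way_anova(1:4, rep("c1", 4), rep(c("h", "l"), 2)),
               "at least 2 categories")
})

test_that("exact rank-sum p-values match exhaustive enumeration for all sizes <= 7", {
  set.seed(23)
  for (n1 in 2:7) for (n2 in n1:7) {
    x <- sample(seq_len(100), n1)
    y <- sample(setdiff(seq_len(100), x), n2)
    res <- pairwise_category_tests(c(x, y),
                                   rep(c("g1", "g2"), c(n1, n2)))
    expect_equal(res$p["g1", "g2"], enum_ranksum_p(x, y), tolerance = 1e-12,
                 label = sprintf("sizes %d vs %d", n1, n2))
  }
  # fully separated 5 vs 5: two-sided p = 2 / C(10, 5)
  res <- pairwise_category_tests(c(1:5, 6:10), rep(c("lo", "hi"), each = 5))
  expect_equal(res$p["lo", "hi"], 2 / 252, tolerance = 1e-12)
})

test_that("pairwise test output is a symmetric matrix with the declared contracts", {
  set.seed(24)
  vals <- c(rnorm(5), rnorm(6, 2), rnorm(7, 4))
  cats <- rep(c("a", "b", "c"), c(5, 6, 7))
  res <- pairwise_category_tests(vals, cats)
  expect_equal(res$p, t(res$p))
  expect_equal(sum(!is.na(res$p[upper.tri(res$p)])), 3L)
  expect_true(all(res$p[upper.tri(res$p)] >= 0 &
                    res$p[upper.tri(res$p)] <= 1))
  # identical groups give the maximal attainable p
  res2 <- pairwise_category_tests(c(1, 2, 3, 1, 2, 3),
                                  rep(c("a", "b"), each = 3))
  expect_gt(res2$p["a", "b"], 0.99)
  # signed-rank without pairing must error, not silently fall back
  expect_error(pairwise_category_tests(vals, cats, method = "signed_rank"),
               "pairing")
  # BH correction only reorders significance, never breaks symmetry
  res3 <- pairwise_category_tests(vals, cats, correct = TRUE)
  expect_equal(res3$p, t(res3$p))
  expect_true(all(res3$p[upper.tri(res3$p)] >= res$p[upper.tri(res$p)] - 1e-12))
})

test_that("signed-rank variant works on explicitly paired equal-size groups", {
  set.seed(25)
  base <- rnorm(8)
  vals <- c(base, base + 1 + rnorm(8, sd = 0.1))
  cats <- rep(c("a", "b"), each = 8)
  ids <- rep(sprintf("p%d", 1:8), 2)
  res <- pairwise_category_tests(vals, cats, method = "signed_rank",
                                 pair_id = ids)
  want <- wilcox.test(vals[1:8], vals[9:16], paired = TRUE,
                      exact = TRUE)$p.value
  expect_equal(res$p["a", "b"], want, tolerance = 1e-12)
})

test_that("lucidity deltas follow the declared convention and ordering", {
  labs <- c("mel", "sil", "calea", "benzo")
  high <- rank_documents(sim_vec(labs, c(0.9, 0.8, 0.7, 0.1)))
  low <- rank_documents(sim_vec(labs, c(0.1, 0.7, 0.8, 0.9)))
  d <- lucidity_delta_ranking(high, low)
  # mel: rank 1 high, rank 4 low -> delta +3, most lucidity-specific
  expect_equal(d$label[1], "mel")
  expect_equal(d$delta[1], 3L)
  expect_equal(d$delta[d$label == "benzo"], -3L)
  # identical rankings: all deltas zero
  d0 <- lucidity_delta_ranking(high, high)
  expect_true(all(d0$delta == 0L))
  # label mismatch is fatal and names the difference
  low2 <- low[low$label != "mel", , drop = FALSE]
  class(low2) <- class(low)
  expect_error(lucidity_delta_ranking(high, low2), "mel")
})

test_that("cross-similarity prediction equals the hand-rolled Spearman oracle", {
  set.seed(26)
  n_terms <- 30; labs <- c(sprintf("s%02d", 1:12), "dream_high")
  W <- matrix(rexp(n_terms * 13), n_terms)
  sp <- make_space(W, doc_labels = labs)
  out <- cross_similarity_prediction(sp, "s01", "dream_high")
  ok <- !is.na(out$profile$to_probe)
  want <- spearman_oracle(out$profile$to_probe[ok], out$profile$to_reference[ok])
  expect_equal(out$rho, want, tolerance = 1e-12)
  expect_equal(out$n, 11L)   # probe excluded
  # probe column identical to the reference: profiles coincide, rho = 1
  W2 <- W; W2[, 1] <- W[, 13]
  sp2 <- make_space(W2, doc_labels = labs)
  expect_equal(cross_similarity_prediction(sp2, "s01", "dream_high")$rho, 1,
               tolerance = 1e-12)
  # fewer than 3 usable substances: undefined and flagged
  sp3 <- make_space(W[, c(1, 2, 13)], doc_labels = c("s01", "s02", "dream_high"))
  expect_warning(out3 <- cross_similarity_prediction(sp3, "s01", "dream_high"),
                 "fewer than 3")
  expect_true(is.na(out3$rho))
})

test_that("stability matrices are symmetric, unit-diagonal, grid-order invariant", {
  # one-element grid
  set.seed(27)
  W <- matrix(rexp(40 * 8), 40, 8)
  tdm <- make_tdm(W, doc_labels = c(sprintf("s%d", 1:7), "dream_high"))
  sm1 <- stability_analysis(tdm, D_grid = 3L)
  expect_equal(unclass(sm1), matrix(1, 1, 1, dimnames = list("3", "3")),
               ignore_attr = TRUE)
  # low-rank matrix: every D >= rank gives identical reconstructions
  L <- matrix(rnorm(40 * 3), 40, 3); R <- matrix(rnorm(3 * 8), 3, 8)
  tdm2 <- make_tdm(L %*% R, doc_labels = c(sprintf("s%d", 1:7), "dream_high"))
  sm2 <- stability_analysis(tdm2, D_grid = c(3L, 4L, 5L, 6L))
  expect_true(all(abs(unclass(sm2) - 1) < 1e-12))
  # grid trimming warns; order of the grid does not matter
  sm3 <- suppressWarnings(stability_analysis(tdm, D_grid = c(5L, 3L, 99L)))
  expect_equal(attr(sm3, "D_grid"), c(3L, 5L))
  expect_warning(stability_analysis(tdm, D_grid = c(3L, 99L)), "trimming")
  sm4 <- stability_analysis(tdm, D_grid = c(3L, 5L))
  expect_equal(unclass(sm3), unclass(sm4))
  expect_equal(unclass(sm3), t(unclass(sm3)))
  expect_true(all(diag(unclass(sm3)) == 1))
})
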