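#' Rank substances by similarity to a reference document
#'
#' Rank 1 is the most similar substance (highest Pearson r), matching the
#' convention of the ranking tables; the inverted "ascending-score"
#' convention used by some box-plot displays (n = most similar) is available
#' as `rank_inv = n + 1 - rank`. Exact ties are broken by lexicographic
#' label order and flagged.
#'
#' @param sim A `similarity_vector` from [similarity_to_reference()].
#' @return A `similarity_ranking`: data frame with columns `label`, `r`,
#'   `rank`, `rank_inv`, `tie`; attributes `reference` and `D`.
#' @export
rank_documents <- function(sim) {
  stopifnot(inherits(sim, "similarity_vector") ||
            (is.data.frame(sim) && all(c("label", "r") %in% names(sim))))
  x <- as.data.frame(sim)
  if (anyNA(x$r)) {
    warning("rank_documents: excluding ", sum(is.na(x$r)),
            " target(s) with undefined similarity")
    x <- x[!is.na(x$r), , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no defined similarities to rank")
  ord <- order(-x$r, x$label)
  x <- x[ord, , drop = FALSE]
  n <- nrow(x)
  x$rank <- seq_len(n)
  x$rank_inv <- n + 1L - x$rank
  dup <- duplicated(x$r) | duplicated(x$r, fromLast = TRUE)
  x$tie <- dup
  if (any(dup)) {
    warning("rank_documents: ", sum(dup),
            " tied similarity value(s); lexicographic tie-break applied")
  }
  rownames(x) <- NULL
  structure(x, class = c("similarity_ranking", "data.frame"),
            reference = attr(sim, "reference"), D = attr(sim, "D"))
}

#' Per-category summary of substance ranks
#'
#' Box-plot style summary (n, median, quartiles, outliers by the 1.5 IQR
#' rule) of the ranks falling in each primary (or secondary) category.
#' Categories with `n <= min_n` substances are excluded and reported, so
#' sparsely populated categories do not produce unstable summaries.
#'
#' @param ranking A `similarity_ranking`.
#' @param scheme A `category_scheme`.
#' @param use_secondary Summarize by secondary instead of primary category.
#' @param min_n Exclusion threshold: categories with `n <= min_n` are
#'   dropped (default 6).
#' @param use_inverted Summarize `rank_inv` (n = most similar) instead of
#'   `rank`; the two conventions are never mixed in one table.
#' @return Data frame with columns `category`, `n`, `median`, `q25`, `q75`,
#'   `outliers` (comma-joined labels); excluded categories in the
#'   `"excluded"` attribute.
#' @export
category_rank_summary <- function(ranking, scheme, use_secondary = FALSE,
                                  min_n = 6L, use_inverted = FALSE) {
  stopifnot(inherits(ranking, "similarity_ranking"))
  idx <- match(ranking$label, scheme$label)
  if (anyNA(idx)) {
    stop("labels missing from category scheme: ",
         paste(ranking$label[is.na(idx)], collapse = ", "))
  }
  cat_col <- if (use_secondary) "secondary" else "primary"
  cats <- scheme[[cat_col]][idx]
  val <- if (use_inverted) ranking$rank_inv else ranking$rank
  tab <- table(cats)
  excluded <- names(tab)[tab <= min_n]
  keep_cat <- setdiff(names(tab), excluded)
  if (length(excluded) > 0L) {
    message("category_rank_summary: excluded ", length(excluded),
            " categor(ies) with n <= ", min_n, ": ",
            paste(excluded, collapse = ", "))
  }
  rows <- lapply(keep_cat, function(cc) {
    v <- val[cats == cc]
    q <- stats::quantile(v, c(.25, .5, .75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    out <- ranking$label[cats == cc][v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    data.frame(category = cc, n = length(v), median = q[2],
               q25 = q[1], q75 = q[3],
               outliers = paste(out, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(category = character(0), n = integer(0),
                      median = numeric(0), q25 = numeric(0),
                      q75 = numeric(0), outliers = character(0))
  } else {
    res <- res[order(res$median), , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Two-factor analysis of variance on substance ranks
#'
#' Fixed-effects ANOVA with interaction, rank as the dependent variable and
#' drug category and dream lucidity (high/low reference) as crossed factors.
#' Each substance contributes two observations: its rank against the
#' high-lucidity and against the low-lucidity dream document. The design is
#' unbalanced (categories differ in size), so Type II sums of squares are
#' the default; Type I and III are available.
#'
#' @param rank_values Numeric vector of ranks (or similarities).
#' @param factor_category Factor/character of drug categories.
#' @param factor_lucidity Factor/character of lucidity levels.
#' @param ss_type Sums-of-squares type: 2 (default), 1 or 3.
#' @return Data frame with columns `effect`, `df`, `sum_sq`, `F`, `p` for
#'   the two main effects, the interaction and residuals.
#' @export
two_way_anova <- function(rank_values, factor_category, factor_lucidity,
                          ss_type = 2) {
  stopifnot(length(rank_values) == length(factor_category),
            length(rank_values) == length(factor_lucidity))
  category <- factor(factor_category)
  lucidity <- factor(factor_lucidity)
  if (nlevels(category) < 2L) stop("need at least 2 categories")
  singletons <- names(table(category))[table(category) < 2L]
  if (length(singletons) > 0L) {
    stop("category with a single observation cannot enter the ANOVA: ",
         paste(singletons, collapse = ", "))
  }
  d <- data.frame(y = rank_values, category = category, lucidity = lucidity)
  fit <- stats::lm(y ~ category * lucidity, data = d,
                   contrasts = list(category = "contr.sum",
                                    lucidity = "contr.sum"))
  if (ss_type == 1) {
    a <- stats::anova(fit)
    tab <- data.frame(effect = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                      F = a$`F value`, p = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = ss_type)
    tab <- data.frame(effect = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                      F = a$`F value`, p = a$`Pr(>F)`)
  }
  tab$effect <- sub("^category:lucidity$", "interaction", tab$effect)
  tab$effect <- sub("^Residuals$", "residuals", tab$effect)
  rownames(tab) <- NULL
  tab
}

#' Pairwise nonparametric tests between drug categories
#'
#' For every pair of categories, tests whether their rank (or similarity)
#' distributions differ. The default is the two-sample Wilcoxon rank-sum
#' (Mann-Whitney) test, appropriate for the unequal category sizes of a real
#' corpus; the paired Wilcoxon signed-rank variant is available for
#' explicitly paired inputs of equal size and errors out otherwise rather
#' than silently falling back. Exact p-values are used when both groups have
#' at most `exact_n` observations (and no ties force the normal
#' approximation); uncorrected significance at `alpha` is reported by
#' default, with optional Benjamini-Hochberg correction.
#'
#' @param rank_values Numeric vector.
#' @param factor_category Factor/character of categories.
#' @param method `"ranksum"` (default) or `"signed_rank"`.
#' @param alpha Significance level (default 0.05).
#' @param pair_id Pairing key, required for `method = "signed_rank"`.
#' @param correct Apply Benjamini-Hochberg correction to the p-values.
#' @param exact_n Exact-test size threshold (default 25).
#' @return A `category_test_result`: list with symmetric matrices `p` and
#'   `significant`, plus `method`, `alpha`, `corrected`.
#' @export
pairwise_category_tests <- function(rank_values, factor_category,
                                    method = c("ranksum", "signed_rank"),
                                    alpha = 0.05, pair_id = NULL,
                                    correct = FALSE, exact_n = 25L) {
  method <- match.arg(method)
  category <- factor(factor_category)
  lev <- levels(category)
  if (length(lev) < 2L) stop("need at least 2 categories")
  p <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  diag(p) <- NA_real_
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    xi <- rank_values[category == lev[i]]
    xj <- rank_values[category == lev[j]]
    if (method == "signed_rank") {
      if (is.null(pair_id)) {
        stop("signed_rank requires a pairing key (pair_id)")
      }
      pi_ <- pair_id[category == lev[i]]
      pj_ <- pair_id[category == lev[j]]
      if (length(xi) != length(xj) || !setequal(pi_, pj_)) {
        stop("signed_rank requires equal-size groups paired by pair_id; ",
             "use method = 'ranksum' for unpaired categories")
      }
      xi <- xi[order(pi_)]; xj <- xj[order(pj_)]
      use_exact <- length(xi) <= exact_n
      pv <- suppressWarnings(
        stats::wilcox.test(xi, xj, paired = TRUE, exact = use_exact,
                           correct = FALSE)$p.value)
    } else {
      use_exact <- max(length(xi), length(xj)) <= exact_n
      pv <- suppressWarnings(
        stats::wilcox.test(xi, xj, exact = use_exact,
                           correct = FALSE)$p.value)
    }
    p[i, j] <- p[j, i] <- pv
  }
  if (correct) {
    ut <- upper.tri(p)
    adj <- stats::p.adjust(p[ut], method = "BH")
    p[ut] <- adj
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(p = p, significant = p < alpha, method = method,
                 alpha = alpha, corrected = correct),
            class = "category_test_result")
}

#' @export
print.category_test_result <- function(x, ...) {
  cat("pairwise category tests (", x$method,
      if (x$corrected) ", BH-corrected" else ", uncorrected",
      "), alpha = ", x$alpha, "\n", sep = "")
  print(round(x$p, 4))
  invisible(x)
}

#' Rank substances by their lucidity difference
#'
#' For each substance, the difference between its rank against the
#' low-lucidity and the high-lucidity dream document. Positive deltas mean
#' the substance's reports are more similar to high-lucidity dreams (its
#' rank against `dream_high` is better, i.e. numerically smaller, than
#' against `dream_low`); oneirogen-like substances are expected at the top.
#'
#' @param ranking_high,ranking_low `similarity_ranking`s against the high-
#'   and low-lucidity dream documents, over the same label set.
#' @return Data frame with columns `label`, `rank_high`, `rank_low`,
#'   `delta`, sorted by descending delta (ties lexicographic).
#' @export
lucidity_delta_ranking <- function(ranking_high, ranking_low) {
  if (!setequal(ranking_high$label, ranking_low$label)) {
    extra_h <- setdiff(ranking_high$label, ranking_low$label)
    extra_l <- setdiff(ranking_low$label, ranking_high$label)
    stop("label sets differ; only-high: {",
         paste(extra_h, collapse = ", "), "}, only-low: {",
         paste(extra_l, collapse = ", "), "}")
  }
  m <- match(ranking_high$label, ranking_low$label)
  d <- data.frame(label = ranking_high$label,
                  rank_high = ranking_high$rank,
                  rank_low = ranking_low$rank[m],
                  stringsAsFactors = FALSE)
  d$delta <- d$rank_low - d$rank_high
  d <- d[order(-d$delta, d$label), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Predict dream similarity from similarity to a probe substance
#'
#' Spearman rank correlation between two similarity profiles over all
#' substances: similarity to a probe substance (x) and similarity to a dream
#' reference (y). High coefficients mean that knowing how much each
#' substance resembles the probe predicts how much it resembles dreaming.
#' The probe itself is excluded from the profile.
#'
#' @param space A `semantic_space`.
#' @param probe Substance document label.
#' @param reference Dream document label.
#' @return List with `rho` (Spearman, `NA` if fewer than 3 substances
#'   remain), `n`, and the underlying profile data frame.
#' @export
cross_similarity_prediction <- function(space, probe, reference) {
  stopifnot(inherits(space, "semantic_space"))
  subs <- space$doc_labels[space$doc_source == "substance"]
  subs <- setdiff(subs, probe)
  x <- vapply(subs, function(s)
    suppressWarnings(document_similarity(space, s, probe)), numeric(1))
  y <- vapply(subs, function(s)
    suppressWarnings(document_similarity(space, s, reference)), numeric(1))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    warning("cross_similarity_prediction: fewer than 3 usable substances")
    return(list(rho = NA_real_, n = sum(ok),
                profile = data.frame(label = subs, to_probe = x,
                                     to_reference = y)))
  }
  rho <- stats::cor(x[ok], y[ok], method = "spearman")
  list(rho = rho, n = sum(ok),
       profile = data.frame(label = subs, to_probe = unname(x),
                            to_reference = unname(y),
                            stringsAsFactors = FALSE))
}

#' Stability of the substance ranking across retained ranks
#'
#' Recomputes the full LSA + ranking pipeline for every retained-rank value
#' in `D_grid` (one SVD truncation each) and returns the matrix of Spearman
#' correlations between every pair of resulting substance rankings. Grid
#' values exceeding `min(n_terms, n_docs)` are trimmed with a warning.
#'
#' @param M A `term_document_matrix`.
#' @param D_grid Integer vector of retained ranks (default 20 to 70 by 5).
#' @param reference Dream document label to rank against.
#' @return A `stability_matrix`: symmetric matrix of Spearman rho with the
#'   (possibly trimmed) grid as dimnames and a `D_grid` attribute.
#' @export
stability_analysis <- function(M, D_grid = seq(20L, 70L, by = 5L),
                               reference = "dream_high") {
  stopifnot(inherits(M, "term_document_matrix"))
  kmax <- min(dim(M$W))
  bad <- D_grid > kmax
  if (any(bad)) {
    warning("stability_analysis: trimming D values above min(n_terms, n_docs) = ",
            kmax, ": ", paste(D_grid[bad], collapse = ", "))
    D_grid <- D_grid[!bad]
  }
  if (length(D_grid) == 0L) stop("no admissible D values in the grid")
  D_grid <- sort(unique(as.integer(D_grid)))
  ranks <- lapply(D_grid, function(D) {
    sp <- truncate_svd(M, D = D)
    rk <- rank_documents(similarity_to_reference(sp, reference))
    stats::setNames(rk$rank, rk$label)
  })
  labs <- names(ranks[[1]])
  n <- length(D_grid)
  rho <- matrix(1, n, n, dimnames = list(D_grid, D_grid))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    rho[i, j] <- rho[j, i] <-
      stats::cor(ranks[[i]][labs], ranks[[j]][labs], method = "spearman")
  }
  structure(rho, class = c("stability_matrix", "matrix"),
            D_grid = D_grid, reference = reference)
}
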