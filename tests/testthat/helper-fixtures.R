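# Shared fixtures and independent oracles. Everything is built in code; no
# fixture files on disk.

# Reports data frame from parallel vectors (substance reports unless a
# lucidity is given).
make_reports <- function(labels, texts, lucidity = NULL) {
  n <- length(labels)
  if (is.null(lucidity)) lucidity <- rep(NA_integer_, n)
  data.frame(report_id = sprintf("r%03d", seq_len(n)), label = labels,
             source = ifelse(is.na(lucidity), "substance", "dream"),
             lucidity = lucidity, text = texts, stringsAsFactors = FALSE)
}

# The 3-document toy corpus used for the hand-checked tf-idf cells.
toy_collection <- function() {
  reps <- make_reports(c("d1", "d2", "d3"),
                       c("cat cat dog", "dog fish", "fish fish fish"))
  docs <- suppressMessages(assemble_documents(reps, min_reports = 1L))
  preprocess_collection(docs)
}

# Wrap an arbitrary dense matrix as a term_document_matrix so the SVD layer
# can be tested on matrices with known spectra.
make_tdm <- function(W, doc_labels = NULL, doc_source = NULL) {
  if (is.null(doc_labels)) doc_labels <- sprintf("doc%02d", seq_len(ncol(W)))
  if (is.null(rownames(W))) rownames(W) <- sprintf("t%03d", seq_len(nrow(W)))
  colnames(W) <- doc_labels
  if (is.null(doc_source)) {
    doc_source <- ifelse(startsWith(doc_labels, "dream"), "dream", "substance")
  }
  structure(list(W = W, vocabulary = rownames(W), doc_labels = doc_labels,
                 doc_source = doc_source, df = rep(0.5, nrow(W)),
                 n_docs = ncol(W), df_all = rep(0.5, nrow(W)),
                 idf_dialect = "plain", df_min = 0, df_max = 1),
            class = "term_document_matrix")
}

# Wrap a reconstructed matrix directly as a semantic_space so the similarity
# definition can be tested against hand-picked columns.
make_space <- function(W_D, doc_labels = NULL, doc_source = NULL, D = 2L) {
  if (is.null(doc_labels)) doc_labels <- sprintf("doc%02d", seq_len(ncol(W_D)))
  if (is.null(rownames(W_D))) rownames(W_D) <- sprintf("t%03d", seq_len(nrow(W_D)))
  colnames(W_D) <- doc_labels
  if (is.null(doc_source)) {
    doc_source <- ifelse(startsWith(doc_labels, "dream"), "dream", "substance")
  }
  structure(list(U = NULL, S_star = NULL, V = NULL, D = D, W_D = W_D,
                 sigma = NULL, doc_labels = doc_labels,
                 doc_source = doc_source, vocabulary = rownames(W_D)),
            class = "semantic_space")
}

# Small topic-model spec: 3 topics on disjoint 20-word blocks, four
# substance classes (two sharing the dream_high mixture direction) and the
# two dream classes.
small_spec <- function(seed = 42L, n_reports = 12L, length_mean = 60) {
  V <- 60L; K <- 3L
  topic_word <- matrix(0, K, V)
  for (k in 1:K) {
    idx <- ((k - 1L) * 20L + 1L):(k * 20L)
    w <- seq_len(20L)
    topic_word[k, idx] <- w / sum(w)
  }
  mixtures <- rbind(
    subA = c(0.8, 0.1, 0.1), subB = c(0.7, 0.2, 0.1),
    subC = c(0.1, 0.8, 0.1), subD = c(0.1, 0.1, 0.8),
    dream_high = c(0.8, 0.1, 0.1), dream_low = c(0.1, 0.2, 0.7))
  classes <- data.frame(
    label = rownames(mixtures),
    source = c(rep("substance", 4), "dream", "dream"),
    lucidity = c(rep(NA_integer_, 4), 5L, 1L),
    n_reports = n_reports, length_mean = length_mean,
    length_dispersion = 10, stringsAsFactors = FALSE)
  topic_model_spec(V = V, K = K, topic_word = topic_word, classes = classes,
                   mixtures = mixtures,
                   contaminant_terms = list(subA = c("druga1", "druga2"),
                                            subB = "drugb1",
                                            subC = "drugc1",
                                            subD = "drugd1"),
                   contaminant_rate = 0.03, seed = seed)
}

# Exhaustive-enumeration oracle for the two-sided exact rank-sum test:
# every C(n1 + n2, n1) relabeling, two-sided p = 2 * min(tail masses),
# capped at 1. Independent of stats::wilcox.test.
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Closed-form balanced two-way ANOVA decomposition (textbook sums of
# squares), independent of lm()/car.
balanced_anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  g <- mean(y)
  n <- length(y)
  la <- levels(a); lb <- levels(b)
  r <- n / (length(la) * length(lb))   # replicates per cell
  ssa <- r * length(lb) * sum((tapply(y, a, mean) - g)^2)
  ssb <- r * length(la) * sum((tapply(y, b, mean) - g)^2)
  cell <- tapply(y, list(a, b), mean)
  ssab <- r * sum((sweep(sweep(cell, 1, tapply(y, a, mean)), 2,
                         tapply(y, b, mean)) + g)^2)
  sse <- sum((y - cell[cbind(a, b)])^2)
  dfa <- length(la) - 1; dfb <- length(lb) - 1
  dfab <- dfa * dfb; dfe <- n - length(la) * length(lb)
  mse <- sse / dfe
  list(F_a = (ssa / dfa) / mse, F_b = (ssb / dfb) / mse,
       F_ab = (ssab / dfab) / mse,
       ss = c(a = ssa, b = ssb, ab = ssab, e = sse))
}

# Spearman oracle: average-rank transform then the Pearson formula, written
# out by hand.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Full pipeline on a generated corpus: returns the ranking against a dream
# reference plus the matrix/space, for recovery checks.
run_pipeline_on <- function(corpus, reference = "dream_high", D = 20L,
                            df_min = 0.05, df_max = 0.95) {
  docs <- suppressMessages(assemble_documents(corpus$reports))
  docs <- preprocess_collection(docs, censor = corpus$censor)
  tdm <- build_term_document_matrix(docs, df_min = df_min, df_max = df_max)
  D <- min(D, min(dim(tdm$W)))
  space <- truncate_svd(tdm, D = D)
  list(docs = docs, tdm = tdm, space = space,
       ranking = rank_documents(similarity_to_reference(space, reference)))
}
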