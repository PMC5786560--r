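#' Build the tf-idf term-document matrix
#'
#' Rows are unique lemmas, columns are documents (one per substance, one per
#' dream-lucidity class). The entry for term t in document d is
#' `count(t in d) * idf(t)` where the inverse document frequency is the
#' logarithmically scaled inverse fraction of documents containing the term:
#' `idf(t) = ln(N / n_t)` (`dialect = "plain"`, the default) or the common
#' library variant `ln((1 + N) / (1 + n_t)) + 1` (`dialect = "smoothed"`,
#' never used silently). Terms whose document frequency falls outside the
#' open band `(df_min, df_max)` are removed before weighting; the vocabulary
#' is sorted lexicographically for determinism.
#'
#' @param docs A preprocessed `document_collection` (see
#'   [preprocess_collection()]).
#' @param df_min,df_max Document-frequency retention band as fractions of the
#'   document count; strict inequalities (defaults 0.05 and 0.95).
#' @param idf_dialect `"plain"` or `"smoothed"`.
#' @return A `term_document_matrix`: list with `W` (terms x documents dense
#'   weight matrix), `vocabulary`, `doc_labels`, `doc_source`, `df`
#'   (per-retained-term document-frequency fraction), `n_docs`, and the
#'   pre-filter df distribution `df_all` for diagnostics.
#' @export
build_term_document_matrix <- function(docs, df_min = 0.05, df_max = 0.95,
                                       idf_dialect = c("plain", "smoothed")) {
  stopifnot(inherits(docs, "document_collection"))
  idf_dialect <- match.arg(idf_dialect)
  if (is.null(docs$tokens)) {
    stop("collection is not preprocessed; run preprocess_collection() first")
  }
  n_docs <- length(docs$label)
  if (n_docs < 2L) stop("need at least 2 documents")
  if (!(df_min < df_max)) stop("need df_min < df_max")

  all_terms <- sort(unique(unlist(docs$tokens, use.names = FALSE)))
  if (length(all_terms) == 0L) stop("no tokens in any document")
  # document frequency: number of documents containing each term
  df_count <- integer(length(all_terms))
  per_doc_unique <- lapply(docs$tokens, unique)
  for (u in per_doc_unique) {
    idx <- match(u, all_terms)
    df_count[idx] <- df_count[idx] + 1L
  }
  df_frac_all <- df_count / n_docs
  keep <- df_frac_all > df_min & df_frac_all < df_max
  if (!any(keep)) {
    qs <- stats::quantile(df_frac_all, c(0, .25, .5, .75, 1))
    stop("empty vocabulary after document-frequency filtering (band ",
         df_min, " < df < ", df_max, "); df distribution: ",
         paste(sprintf("%s=%.3f", names(qs), qs), collapse = ", "))
  }
  vocab <- all_terms[keep]
  counts <- matrix(0, nrow = length(vocab), ncol = n_docs,
                   dimnames = list(vocab, docs$label))
  for (j in seq_len(n_docs)) {
    tb <- table(factor(docs$tokens[[j]], levels = vocab))
    counts[, j] <- as.integer(tb)
  }
  n_t <- df_count[keep]
  idf <- if (idf_dialect == "plain") log(n_docs / n_t)
         else log((1 + n_docs) / (1 + n_t)) + 1
  W <- counts * idf
  structure(list(W = W, vocabulary = vocab, doc_labels = docs$label,
                 doc_source = docs$source, df = n_t / n_docs,
                 n_docs = n_docs, df_all = df_frac_all,
                 idf_dialect = idf_dialect,
                 df_min = df_min, df_max = df_max),
            class = "term_document_matrix")
}

#' @export
print.term_document_matrix <- function(x, ...) {
  cat("term_document_matrix:", length(x$vocabulary), "terms x",
      x$n_docs, "documents (idf:", x$idf_dialect, ")\n")
  invisible(x)
}

#' Latent semantic analysis by truncated SVD
#'
#' Decomposes the weight matrix `W = U S V'` with a deterministic full
#' (LAPACK) SVD, keeps the `D` largest singular values, and stores the
#' rank-`D` reconstruction `W_D = U S* V'` whose columns carry the
#' context-sensitive document profiles used for similarity.
#'
#' @param M A `term_document_matrix`.
#' @param D Number of retained singular values (default 20). Values above
#'   the matrix rank are allowed (the reconstruction then equals `W`).
#' @return A `semantic_space`: list with `U`, `S_star`, `V`, `D`, `W_D`,
#'   the full spectrum `sigma` (for diagnostics), and the document
#'   labels/sources and vocabulary of the source matrix.
#' @export
truncate_svd <- function(M, D = 20L) {
  stopifnot(inherits(M, "term_document_matrix"))
  D <- as.integer(D)
  if (is.na(D) || D < 1L) stop("D must be a positive integer")
  kmax <- min(dim(M$W))
  if (D > kmax) {
    stop("D = ", D, " exceeds min(n_terms, n_docs) = ", kmax)
  }
  sv <- svd(M$W)
  keep <- seq_len(D)
  W_D <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  dimnames(W_D) <- dimnames(M$W)
  structure(list(U = sv$u[, keep, drop = FALSE], S_star = sv$d[keep],
                 V = sv$v[, keep, drop = FALSE], D = D, W_D = W_D,
                 sigma = sv$d, doc_labels = M$doc_labels,
                 doc_source = M$doc_source, vocabulary = M$vocabulary),
            class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("semantic_space: rank-", x$D, " LSA over ", length(x$vocabulary),
      " terms x ", length(x$doc_labels), " documents\n", sep = "")
  invisible(x)
}

.space_column <- function(space, label) {
  j <- match(label, space$doc_labels)
  if (is.na(j)) stop("unknown document label: ", label)
  space$W_D[, j]
}

#' Semantic similarity between two documents
#'
#' Pearson linear correlation between the rank-reduced term-space columns of
#' the two documents. A zero-variance (constant) reconstructed column makes
#' the coefficient undefined; `NA` is returned with a warning rather than a
#' silent zero.
#'
#' @param space A `semantic_space`.
#' @param a,b Document labels.
#' @return Pearson r in `[-1, 1]`, or `NA` if undefined.
#' @export
document_similarity <- function(space, a, b) {
  stopifnot(inherits(space, "semantic_space"))
  ca <- .space_column(space, a)
  cb <- .space_column(space, b)
  if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
    warning("similarity undefined: constant reconstructed column for '",
            if (stats::sd(ca) == 0) a else b, "'")
    return(NA_real_)
  }
  stats::cor(ca, cb)
}

#' Similarity of every substance document to a reference document
#'
#' @param space A `semantic_space`.
#' @param reference Reference document label (normally `"dream_high"` or
#'   `"dream_low"`).
#' @param targets Target document labels; defaults to all substance
#'   documents. The reference itself is always excluded.
#' @return A `similarity_vector`: data frame with columns `label` and `r`
#'   (in collection order), attributes `reference` and `D`.
#' @export
similarity_to_reference <- function(space, reference, targets = NULL) {
  stopifnot(inherits(space, "semantic_space"))
  if (!reference %in% space$doc_labels) {
    stop("reference '", reference, "' is not a document label")
  }
  if (is.null(targets)) {
    targets <- space$doc_labels[space$doc_source == "substance"]
  }
  targets <- targets[targets != reference]
  r <- vapply(targets, function(t) {
    suppressWarnings(document_similarity(space, reference, t))
  }, numeric(1))
  if (anyNA(r)) {
    warning("similarity undefined for: ",
            paste(targets[is.na(r)], collapse = ", "))
  }
  structure(data.frame(label = targets, r = unname(r),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("similarity_vector", "data.frame"),
            reference = reference, D = space$D)
}
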