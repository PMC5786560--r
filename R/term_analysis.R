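#' Top terms of a document, by tf-idf or reduced-matrix weight
#'
#' The table behind a word cloud: the `n` heaviest terms of one document
#' under one weighting scheme. `"reduced-matrix"` (default) ranks terms by
#' their value in the rank-reduced LSA reconstruction `W_D`;
#' `"raw-frequency"` ranks by the un-reduced tf-idf weight in `W`. Ties are
#' broken lexicographically.
#'
#' @param source A `semantic_space` (either scheme) or a
#'   `term_document_matrix` (`"raw-frequency"` only).
#' @param doc Document label.
#' @param n Number of terms to return (default 40); truncated with a warning
#'   if it exceeds the vocabulary.
#' @param scheme `"reduced-matrix"` or `"raw-frequency"`.
#' @return Data frame (`term_rank_table`) with columns `term`, `weight`,
#'   `rank`, `scheme`, `document`.
#' @export
top_terms <- function(source, doc, n = 40L,
                      scheme = c("reduced-matrix", "raw-frequency")) {
  scheme <- match.arg(scheme)
  if (inherits(source, "semantic_space")) {
    M <- if (scheme == "reduced-matrix") source$W_D else {
      stop("raw-frequency scheme needs the term_document_matrix, ",
           "not the semantic_space")
    }
    labs <- source$doc_labels
  } else if (inherits(source, "term_document_matrix")) {
    if (scheme != "raw-frequency") {
      stop("reduced-matrix scheme needs a semantic_space")
    }
    M <- source$W
    labs <- source$doc_labels
  } else {
    stop("source must be a semantic_space or term_document_matrix")
  }
  j <- match(doc, labs)
  if (is.na(j)) stop("unknown document label: ", doc)
  w <- M[, j]
  terms <- rownames(M)
  if (n > length(terms)) {
    warning("top_terms: n = ", n, " exceeds vocabulary size ",
            length(terms), "; truncated")
    n <- length(terms)
  }
  ord <- order(-w, terms)
  out <- data.frame(term = terms[ord][seq_len(n)],
                    weight = unname(w[ord][seq_len(n)]),
                    rank = seq_len(n), scheme = scheme, document = doc,
                    stringsAsFactors = FALSE)
  structure(out, class = c("term_rank_table", "data.frame"))
}

#' Jointly weighted terms across substance and dream vocabularies
#'
#' Ranks every term twice in the reduced matrix: once on the substance side
#' (by default the rank of its mean `W_D` weight across the given substance
#' documents) and once in the dream document; the joint score is the
#' arithmetic mean of the two ranks, so terms prominent in both vocabularies
#' float to the top (smaller joint score = larger prominence).
#'
#' @param space A `semantic_space`.
#' @param substance_docs Substance document labels (>= 1).
#' @param dream_doc Dream document label.
#' @param n Number of terms returned (default 40).
#' @param combine `"rank_of_mean"` (default: rank the mean weight) or
#'   `"mean_of_ranks"` (rank each substance document separately and average
#'   the ranks) for the substance side.
#' @return Data frame with columns `term`, `rank_substance`, `rank_dream`,
#'   `joint_score`, `rank`, ascending joint score, ties lexicographic.
#' @export
joint_rank_weights <- function(space, substance_docs, dream_doc, n = 40L,
                               combine = c("rank_of_mean", "mean_of_ranks")) {
  stopifnot(inherits(space, "semantic_space"), length(substance_docs) >= 1L)
  combine <- match.arg(combine)
  terms <- rownames(space$W_D)
  rank_desc <- function(w) {
    # rank 1 = heaviest; lexicographic tie-break
    ord <- order(-w, terms)
    r <- integer(length(w)); r[ord] <- seq_along(w)
    r
  }
  cols <- function(doc) {
    j <- match(doc, space$doc_labels)
    if (is.na(j)) stop("unknown document label: ", doc)
    space$W_D[, j]
  }
  if (combine == "rank_of_mean") {
    mw <- rowMeans(sapply(substance_docs, cols))
    r_sub <- rank_desc(mw)
  } else {
    r_sub <- rowMeans(sapply(substance_docs, function(d) rank_desc(cols(d))))
  }
  r_dream <- rank_desc(cols(dream_doc))
  joint <- (r_sub + r_dream) / 2
  if (n > length(terms)) {
    warning("joint_rank_weights: n truncated to vocabulary size")
    n <- length(terms)
  }
  ord <- order(joint, terms)
  out <- data.frame(term = terms[ord][seq_len(n)],
                    rank_substance = r_sub[ord][seq_len(n)],
                    rank_dream = r_dream[ord][seq_len(n)],
                    joint_score = joint[ord][seq_len(n)],
                    rank = seq_len(n), stringsAsFactors = FALSE)
  structure(out, class = c("term_rank_table", "data.frame"),
            combine = combine, substance_docs = substance_docs,
            dream_doc = dream_doc)
}
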