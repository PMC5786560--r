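#' Specify a synthetic topic-model corpus
#'
#' Defines a corpus of report classes (substances plus two dream-lucidity
#' classes) with known statistical structure: each class is a mixture over
#' `K` topics, each topic a probability vector over a vocabulary of `V`
#' synthetic word types. Reports are bags of words drawn i.i.d. from the
#' class's mixed term distribution, so the expected term distribution of
#' every class — and hence the ground-truth similarity structure the
#' pipeline should recover — is known exactly. Substance classes carry
#' class-specific contaminant "drug-name" tokens injected at a fixed rate,
#' which the censor list must remove.
#'
#' @param V Vocabulary size.
#' @param K Topic count.
#' @param topic_word `K x V` matrix; each row a probability vector.
#' @param classes Data frame with columns `label`, `source`
#'   (`substance`/`dream`), `lucidity` (`NA` for substances), `n_reports`,
#'   `length_mean`, `length_dispersion` (negative-binomial report lengths).
#' @param mixtures `n_classes x K` matrix of topic mixtures (rows sum to 1),
#'   rownames = class labels.
#' @param contaminant_terms Named list: substance label -> character vector
#'   of contaminant tokens.
#' @param contaminant_rate Expected fraction of contaminant tokens injected
#'   into substance reports.
#' @param categories Optional [category_scheme()] over the substance labels.
#' @param seed Integer seed; all sampling is deterministic given it.
#' @param vocab Optional vocabulary strings (default `w0001`...).
#' @return A validated `topic_model_spec` list.
#' @export
topic_model_spec <- function(V, K, topic_word, classes, mixtures,
                             contaminant_terms = list(),
                             contaminant_rate = 0, categories = NULL,
                             seed = 1L, vocab = NULL) {
  if (is.null(vocab)) vocab <- sprintf("w%04d", seq_len(V))
  spec <- structure(list(V = as.integer(V), K = as.integer(K),
                         topic_word = topic_word, classes = classes,
                         mixtures = mixtures,
                         contaminant_terms = contaminant_terms,
                         contaminant_rate = contaminant_rate,
                         categories = categories, seed = as.integer(seed),
                         vocab = vocab),
                    class = "topic_model_spec")
  validate_topic_model_spec(spec)
  spec
}

#' Validate a topic-model corpus specification
#'
#' @param spec A `topic_model_spec`.
#' @param min_reports Minimum reports per substance class (default 10).
#' @return `spec`, invisibly; errors on any violated invariant.
#' @export
validate_topic_model_spec <- function(spec, min_reports = 10L) {
  stopifnot(inherits(spec, "topic_model_spec"))
  tol <- 1e-8
  if (!is.matrix(spec$topic_word) ||
      nrow(spec$topic_word) != spec$K || ncol(spec$topic_word) != spec$V) {
    stop("topic_word must be a K x V matrix")
  }
  if (any(spec$topic_word < 0) ||
      any(abs(rowSums(spec$topic_word) - 1) > tol)) {
    stop("topic_word rows must be probability vectors")
  }
  cl <- spec$classes
  need <- c("label", "source", "lucidity", "n_reports",
            "length_mean", "length_dispersion")
  if (!all(need %in% names(cl))) {
    stop("classes must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(cl$label)) stop("duplicate class labels")
  if (!is.matrix(spec$mixtures) || nrow(spec$mixtures) != nrow(cl) ||
      ncol(spec$mixtures) != spec$K) {
    stop("mixtures must be an n_classes x K matrix")
  }
  if (is.null(rownames(spec$mixtures)) ||
      !identical(rownames(spec$mixtures), cl$label)) {
    stop("mixtures rownames must equal class labels, in order")
  }
  if (any(spec$mixtures < 0) || any(abs(rowSums(spec$mixtures) - 1) > tol)) {
    stop("mixture rows must be probability vectors")
  }
  is_sub <- cl$source == "substance"
  if (any(cl$n_reports[is_sub] < min_reports)) {
    stop("substance classes need n_reports >= ", min_reports)
  }
  dr <- cl[cl$source == "dream", , drop = FALSE]
  if (nrow(dr) == 0L || !any(dr$lucidity == 5L) || !any(dr$lucidity == 1L)) {
    stop("need at least one dream class per lucidity extreme (1 and 5)")
  }
  if (spec$contaminant_rate < 0 || spec$contaminant_rate >= 1) {
    stop("contaminant_rate must be in [0, 1)")
  }
  bad <- setdiff(names(spec$contaminant_terms), cl$label[is_sub])
  if (length(bad) > 0L) {
    stop("contaminant terms for unknown substance classes: ",
         paste(bad, collapse = ", "))
  }
  if (length(spec$vocab) != spec$V || anyDuplicated(spec$vocab)) {
    stop("vocab must hold V distinct word types")
  }
  invisible(spec)
}

#' Expected term distribution of each class
#' @param spec A `topic_model_spec`.
#' @return `n_classes x V` matrix of class term distributions
#'   (`mixtures %*% topic_word`), rownames = class labels.
#' @export
class_term_distributions <- function(spec) {
  P <- spec$mixtures %*% spec$topic_word
  colnames(P) <- spec$vocab
  P
}

#' Sample a synthetic report corpus
#'
#' Draws every report of every class: a negative-binomial length, then that
#' many word types i.i.d. from the class's mixed term distribution;
#' substance reports additionally receive contaminant tokens (binomial count
#' at the configured rate). Token-identical across runs with the same spec.
#'
#' @param spec A `topic_model_spec`.
#' @return List with `reports` (data frame in [load_reports()] layout),
#'   `censor` (a [censor_list()] of every injected contaminant), and the
#'   `spec` itself.
#' @export
generate_corpus <- function(spec) {
  validate_topic_model_spec(spec, min_reports = 1L)
  P <- class_term_distributions(spec)
  cl <- spec$classes
  set.seed(spec$seed)
  pieces <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    n <- cl$n_reports[i]
    len <- pmax(1L, stats::rnbinom(n, size = cl$length_dispersion[i],
                                   mu = cl$length_mean[i]))
    words <- sample(spec$vocab, sum(len), replace = TRUE, prob = P[i, ])
    grp <- rep.int(seq_len(n), len)
    texts <- vapply(split(words, grp), paste, character(1), collapse = " ")
    if (cl$source[i] == "substance" && spec$contaminant_rate > 0 &&
        !is.null(spec$contaminant_terms[[cl$label[i]]])) {
      cont <- spec$contaminant_terms[[cl$label[i]]]
      n_inj <- stats::rbinom(n, size = len, prob = spec$contaminant_rate)
      for (k in which(n_inj > 0L)) {
        extra <- sample(cont, n_inj[k], replace = TRUE)
        texts[k] <- paste(texts[k], paste(extra, collapse = " "))
      }
    }
    lab <- if (cl$source[i] == "dream") "dream" else cl$label[i]
    pieces[[i]] <- data.frame(
      report_id = sprintf("%s_r%05d", cl$label[i], seq_len(n)),
      label = lab, source = cl$source[i],
      lucidity = if (cl$source[i] == "dream") cl$lucidity[i] else NA_integer_,
      text = unname(texts), stringsAsFactors = FALSE)
  }
  reports <- do.call(rbind, pieces)
  rownames(reports) <- NULL
  censor <- censor_list(unlist(spec$contaminant_terms, use.names = FALSE),
                        provenance = "synthetic contaminant terms")
  list(reports = reports, censor = censor, spec = spec)
}

#' Exact ground-truth similarity structure of a corpus specification
#'
#' No sampling: the expected term distribution of each class is
#' `mixture %*% topic_word`, pairwise class similarity is the Pearson
#' correlation between expected distributions (paralleling the pipeline's
#' statistic), and the implied substance ranking against each dream class is
#' the descending sort of its similarity column. Jensen-Shannon divergence
#' is included as a diagnostic alternative.
#'
#' @param spec A `topic_model_spec`.
#' @return List with `expected` (class term distributions), `similarity`
#'   (symmetric correlation matrix), `jsd` (Jensen-Shannon divergence
#'   matrix), and `ranking_vs` (per dream class: data frame `label`,
#'   `similarity`, `rank` over substance classes).
#' @export
ground_truth_similarity <- function(spec) {
  validate_topic_model_spec(spec, min_reports = 1L)
  P <- class_term_distributions(spec)
  sim <- stats::cor(t(P))
  n <- nrow(P)
  jsd <- matrix(0, n, n, dimnames = dimnames(sim))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    m <- (P[i, ] + P[j, ]) / 2
    kl <- function(p, q) {
      nz <- p > 0
      sum(p[nz] * log(p[nz] / q[nz]))
    }
    jsd[i, j] <- jsd[j, i] <- 0.5 * kl(P[i, ], m) + 0.5 * kl(P[j, ], m)
  }
  is_sub <- spec$classes$source == "substance"
  sub_labs <- spec$classes$label[is_sub]
  dream_labs <- spec$classes$label[!is_sub]
  ranking_vs <- lapply(stats::setNames(dream_labs, dream_labs), function(dl) {
    s <- sim[sub_labs, dl]
    ord <- order(-s, sub_labs)
    data.frame(label = sub_labs[ord], similarity = unname(s[ord]),
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  list(expected = P, similarity = sim, jsd = jsd, ranking_vs = ranking_vs)
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' The frozen benchmark corpus specification
#'
#' The standing acceptance benchmark emulating the scale and structure the
#' pipeline targets: vocabulary of 2,000 word types partitioned into 10
#' topics (one 200-word support block each, within-block Dirichlet(0.5)
#' weights); 30 substance classes plus two dream classes (lucidity 1 and 5);
#' topic mixtures drawn from Dirichlet(0.3), with six substance classes
#' ("class01"-"class06") deliberately sharing at least half their mixture
#' mass with the high-lucidity dream class (mixture = 0.6 x dream_high
#' mixture + 0.4 x own draw); 200 reports per class; report lengths
#' negative-binomial with mean 120 (dispersion 10); three class-specific
#' contaminant tokens per substance injected at rate 0.02. Substance classes
#' carry categories from the closed vocabulary (six categories of size 3-6)
#' so the statistical layer is exercisable end to end.
#'
#' @param seed Integer seed (default 20180122); both the specification
#'   draws and later corpus sampling flow from it.
#' @return A `topic_model_spec` with extra fields `overlap_labels` (the six
#'   dream-sharing classes) and `categories`.
#' @export
benchmark_config <- function(seed = 20180122L) {
  V <- 2000L; K <- 10L
  n_sub <- 30L; n_overlap <- 6L
  set.seed(seed)
  block <- 200L
  topic_word <- matrix(0, K, V)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * block + 1L):(k * block)
    topic_word[k, idx] <- .rdirichlet(1L, rep(0.5, block))
  }
  mix_dream_high <- .rdirichlet(1L, rep(0.3, K))
  mix_dream_low <- .rdirichlet(1L, rep(0.3, K))
  mix_background <- .rdirichlet(n_sub - n_overlap, rep(0.3, K))
  mix_overlap <- 0.6 * matrix(mix_dream_high, n_overlap, K, byrow = TRUE) +
    0.4 * .rdirichlet(n_overlap, rep(0.3, K))
  sub_labels <- sprintf("class%02d", seq_len(n_sub))
  overlap_labels <- sub_labels[seq_len(n_overlap)]
  mixtures <- rbind(mix_overlap, mix_background, mix_dream_high, mix_dream_low)
  rownames(mixtures) <- c(sub_labels, "dream_high", "dream_low")
  classes <- data.frame(
    label = rownames(mixtures),
    source = c(rep("substance", n_sub), "dream", "dream"),
    lucidity = c(rep(NA_integer_, n_sub), 5L, 1L),
    n_reports = 200L, length_mean = 120, length_dispersion = 10,
    stringsAsFactors = FALSE)
  contaminants <- stats::setNames(
    lapply(seq_len(n_sub), function(i) sprintf("drug%02dv%d", i, 1:3)),
    sub_labels)
  cats <- rep(c("serotonergic", "dissociative", "entactogen", "stimulant",
                "depressant/sedative", "antipsychotic/antidepressant"),
              times = c(3, 3, 6, 6, 6, 6))
  scheme <- category_scheme(sub_labels, cats)
  spec <- topic_model_spec(V = V, K = K, topic_word = topic_word,
                           classes = classes, mixtures = mixtures,
                           contaminant_terms = contaminants,
                           contaminant_rate = 0.02, categories = scheme,
                           seed = seed)
  spec$overlap_labels <- overlap_labels
  spec
}
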