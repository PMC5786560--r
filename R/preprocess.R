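#' Split raw narrative text into word tokens
#'
#' All Unicode punctuation is removed before splitting on whitespace, so
#' intra-word punctuation fuses compounds ("well-known" becomes "wellknown").
#' Word repetitions are preserved and digits are kept inside tokens.
#'
#' @param text Character scalar (or vector, tokenized elementwise and
#'   concatenated).
#' @param punctuation `"strip"` (default) deletes punctuation characters;
#'   `"space"` replaces them with a space so hyphenated compounds split.
#' @return Character vector of raw tokens (possibly empty).
#' @export
tokenize <- function(text, punctuation = c("strip", "space")) {
  punctuation <- match.arg(punctuation)
  repl <- if (punctuation == "strip") "" else " "
  text <- gsub("\\p{P}+", repl, paste(text, collapse = " "), perl = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Irregular noun plurals the suffix rules cannot reach.
.lemma_exceptions <- c(
  men = "man", women = "woman", children = "child", feet = "foot",
  teeth = "tooth", mice = "mouse", geese = "goose", people = "person",
  lives = "life", knives = "knife", wives = "wife", leaves = "leaf",
  selves = "self", wolves = "wolf", halves = "half", shelves = "shelf",
  buses = "bus", gases = "gas"
)

#' Reduce word tokens to dictionary roots
#'
#' A light rule-based lemmatizer for English nouns (the pipeline's default
#' part of speech): irregular plurals via a small exception table, then
#' ordered suffix-detachment rules (`-ies` to `-y`, `-es` after sibilants,
#' plain `-s`). Tokens already in root form, and tokens containing digits,
#' pass through unchanged, which makes the function idempotent. The rule-set
#' identifier is exposed as [lemmatizer_id()] so runs record which lemma
#' dialect produced their vocabulary.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of lemmas, same length.
#' @export
lemmatize <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  u <- unique(tokens)
  out <- u
  exc <- .lemma_exceptions[u]
  hit <- !is.na(exc)
  out[hit] <- exc[hit]
  todo <- !hit & !grepl("[0-9]", u)
  x <- out[todo]
  n <- nchar(x)
  res <- x
  # -ies -> -y (cities -> city), only when long enough to be a real plural
  r1 <- n > 4L & endsWith(x, "ies")
  res[r1] <- paste0(substr(x[r1], 1L, n[r1] - 3L), "y")
  # -es after a sibilant (boxes -> box, dishes -> dish, glasses -> glass);
  # a single s before -es is left to the plain -s rule so roses -> rose
  r2 <- !r1 & n > 3L & grepl("(ss|x|z|ch|sh)es$", x)
  res[r2] <- substr(x[r2], 1L, n[r2] - 2L)
  # plain -s, but never -ss, -us, -is (roses -> rose, glass stays glass)
  r3 <- !r1 & !r2 & n > 3L & endsWith(x, "s") &
    !grepl("(ss|us|is)$", x)
  res[r3] <- substr(x[r3], 1L, n[r3] - 1L)
  out[todo] <- res
  out[match(tokens, u)]
}

#' Identifier of the active lemmatizer rule-set
#'
#' Lemma dialects change vocabularies, so every results bundle records which
#' lemmatizer produced it.
#'
#' @return Character scalar naming the rule-set and its version.
#' @export
lemmatizer_id <- function() "dreamlsa-suffix-noun/1"

#' Normalize one raw token to a lemma, or drop it
#'
#' Lowercases, lemmatizes, and drops lemmas shorter than `min_token_len`
#' characters.
#'
#' @param token Character vector of raw tokens.
#' @param min_token_len Minimum lemma length retained (default 3).
#' @return Character vector of surviving lemmas (shorter than the input when
#'   tokens are dropped).
#' @export
normalize_token <- function(token, min_token_len = 3L) {
  lem <- lemmatize(tolower(token))
  lem[nchar(lem) >= min_token_len]
}

#' Preprocess one document into a bag of lemmas
#'
#' Tokenize, lowercase, lemmatize, drop short lemmas, and (for substance
#' documents) remove every lemma found in the lemmatized censor set. The
#' censor list is passed through the same lemmatizer before matching so that
#' both sides live in the same lemma dialect.
#'
#' @param text Raw narrative text.
#' @param censor A [censor_list()] (may be empty).
#' @param apply_censor Censor removal is applied only when `TRUE`
#'   (substance documents); dream documents keep their full vocabulary.
#' @param min_token_len Minimum lemma length (default 3).
#' @param drop_numeric Drop all-digit tokens when `TRUE` (default `FALSE`:
#'   numerals of length >= `min_token_len` are kept).
#' @param punctuation Passed to [tokenize()].
#' @return Character vector: the document's token stream (ordered multiset of
#'   lemmas).
#' @export
preprocess_document <- function(text, censor = censor_list(character(0)),
                                apply_censor = TRUE, min_token_len = 3L,
                                drop_numeric = FALSE,
                                punctuation = c("strip", "space")) {
  toks <- tokenize(text, punctuation = match.arg(punctuation))
  lem <- normalize_token(toks, min_token_len = min_token_len)
  if (drop_numeric && length(lem) > 0L) lem <- lem[!grepl("^[0-9]+$", lem)]
  if (apply_censor && length(censor) > 0L && length(lem) > 0L) {
    censor_lem <- unique(lemmatize(tolower(as.character(censor))))
    lem <- lem[!(lem %in% censor_lem)]
  }
  if (length(lem) == 0L) {
    warning("preprocess_document: document reduced to an empty token stream")
  }
  lem
}

#' Preprocess every document of a collection
#'
#' Fills the `tokens` slot of a [assemble_documents()] result. Censoring is
#' applied to substance documents only.
#'
#' @param docs A `document_collection`.
#' @param censor A [censor_list()].
#' @inheritParams preprocess_document
#' @return The collection with `tokens` filled (one lemma bag per document)
#'   and a `preprocess_stats` data frame (tokens before/after filters and
#'   censor removals per document) attached.
#' @export
preprocess_collection <- function(docs, censor = censor_list(character(0)),
                                  min_token_len = 3L, drop_numeric = FALSE,
                                  punctuation = c("strip", "space")) {
  stopifnot(inherits(docs, "document_collection"))
  punctuation <- match.arg(punctuation)
  censor_lem <- unique(lemmatize(tolower(as.character(censor))))
  toks <- vector("list", length(docs$label))
  stats <- data.frame(label = docs$label, raw = 0L, normalized = 0L,
                      censored_out = 0L, final = 0L)
  for (i in seq_along(docs$label)) {
    raw <- tokenize(docs$text[[i]], punctuation = punctuation)
    lem <- normalize_token(raw, min_token_len = min_token_len)
    if (drop_numeric && length(lem) > 0L) lem <- lem[!grepl("^[0-9]+$", lem)]
    n_norm <- length(lem)
    if (docs$source[i] == "substance" && length(censor_lem) > 0L && n_norm > 0L) {
      lem <- lem[!(lem %in% censor_lem)]
    }
    stats$raw[i] <- length(raw)
    stats$normalized[i] <- n_norm
    stats$censored_out[i] <- n_norm - length(lem)
    stats$final[i] <- length(lem)
    toks[[i]] <- lem
  }
  docs$tokens <- toks
  docs$preprocess_stats <- stats
  docs$lemmatizer <- lemmatizer_id()
  docs
}
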