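#' Read subjective reports from JSON Lines or TSV
#'
#' Each record is one free-text report of a psychoactive-substance experience
#' or a dream, with fields `id`, `label`, `source` (`"substance"` or
#' `"dream"`), `lucidity` (integer 1-5, dream reports only) and `text`.
#' Records with empty text are dropped (the drop count is reported via a
#' message and the `"n_dropped"` attribute); records with structural problems
#' (missing label, lucidity out of range or on the wrong source) are collected
#' and reported together rather than aborting on the first one.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line, UTF-8) or `"tsv"`
#'   (tab-separated with a header carrying the same column names).
#' @return A data frame with columns `report_id`, `label`, `source`,
#'   `lucidity`, `text`, in file order, with attributes `n_dropped` (empty
#'   texts removed) and `record_errors` (character vector of per-record
#'   problems, possibly empty).
#' @export
load_reports <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read reports file: ", path)
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE),
               error = function(e) structure(list(msg = conditionMessage(e)),
                                             class = "jsonl_parse_error"))
    })
  } else {
    tab <- utils::read.delim(path, colClasses = "character",
                             na.strings = character(0), quote = "",
                             fileEncoding = "UTF-8", check.names = FALSE)
    recs <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, , drop = FALSE]))
  }
  if (length(recs) == 0L) stop("no records found in ", path)

  field <- function(r, key) {
    v <- r[[key]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !nzchar(as.character(v))) NA_character_
    else as.character(v)
  }
  errors <- character(0)
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (inherits(r, "jsonl_parse_error")) {
      errors <- c(errors, sprintf("record %d: unparseable JSON (%s)", i, r$msg))
      next
    }
    lab <- field(r, "label")
    src <- field(r, "source")
    luc <- field(r, "lucidity")
    txt <- r[["text"]]
    txt <- if (is.null(txt) || length(txt) != 1L || is.na(txt)) "" else as.character(txt)
    if (is.na(lab)) {
      errors <- c(errors, sprintf("record %d: missing label", i))
      next
    }
    if (is.na(src)) src <- "substance"
    if (!src %in% c("substance", "dream")) {
      errors <- c(errors, sprintf("record %d: unknown source '%s'", i, src))
      next
    }
    luc_i <- NA_integer_
    if (!is.na(luc)) {
      luc_i <- suppressWarnings(as.integer(luc))
      if (is.na(luc_i) || luc_i < 1L || luc_i > 5L) {
        errors <- c(errors,
                    sprintf("record %d: lucidity '%s' outside 1-5", i, luc))
        next
      }
    }
    if (src == "dream" && is.na(luc_i)) {
      errors <- c(errors, sprintf("record %d: dream report without lucidity", i))
      next
    }
    if (src == "substance" && !is.na(luc_i)) {
      errors <- c(errors, sprintf("record %d: substance report carries lucidity", i))
      next
    }
    rows[[i]] <- data.frame(
      report_id = if (!is.na(field(r, "id"))) field(r, "id") else sprintf("rec%06d", i),
      label = lab, source = src, lucidity = luc_i, text = txt,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("all records invalid in ", path, ":\n  ",
         paste(utils::head(errors, 10L), collapse = "\n  "))
  }
  out <- do.call(rbind, rows)
  empty <- !nzchar(trimws(out$text))
  n_dropped <- sum(empty)
  if (n_dropped > 0L) {
    message("load_reports: dropped ", n_dropped, " record(s) with empty text")
    out <- out[!empty, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("all records had empty text in ", path)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "record_errors") <- errors
  if (length(errors) > 0L) {
    message("load_reports: ", length(errors), " invalid record(s) skipped")
  }
  out
}

#' Read a censor word-list
#'
#' The censor list holds substance names, slang variants and
#' route-of-administration words that are removed from substance documents so
#' that similarity reflects the experienced effects rather than the identity
#' of the drug. One term per line; `#` lines are comments; terms are
#' lowercased and deduplicated.
#'
#' @param path Plain-text file, one term per line.
#' @return Character vector of class `censor_list` (lowercase, unique, no
#'   blanks), with a `provenance` attribute recording the source path.
#' @export
load_censor_list <- function(path) {
  if (!file.exists(path)) stop("cannot read censor list: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  terms <- unique(tolower(lines))
  if (length(terms) == 0L) {
    warning("censor list at ", path, " is empty; censoring will be a no-op")
  }
  message("load_censor_list: ", length(terms), " distinct term(s)")
  censor_list(terms, provenance = path)
}

#' Construct a censor list from a character vector
#'
#' @param terms Character vector of censor terms.
#' @param provenance Free-text note on where the list came from.
#' @return Character vector of class `censor_list`.
#' @export
censor_list <- function(terms, provenance = "in-memory") {
  terms <- unique(tolower(trimws(as.character(terms))))
  terms <- terms[nzchar(terms)]
  structure(terms, class = "censor_list", provenance = provenance)
}

#' Read a substance category scheme
#'
#' TSV with columns `label`, `primary`, `secondary`; categories must come
#' from the closed vocabulary used throughout the pipeline.
#'
#' @param path TSV file path.
#' @return Data frame of class `category_scheme` with columns `label`,
#'   `primary`, `secondary`.
#' @export
load_category_scheme <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  need <- c("label", "primary", "secondary")
  if (!all(need %in% names(tab))) {
    stop("category scheme must have columns: ", paste(need, collapse = ", "))
  }
  category_scheme(tab$label, tab$primary, tab$secondary)
}

#' The closed category vocabulary
#' @return Character vector of admissible category names.
#' @export
category_vocabulary <- function() {
  c("serotonergic", "dissociative", "deliriant", "entactogen", "stimulant",
    "depressant/sedative", "antipsychotic/antidepressant", "MAOI",
    "oneirogen", "other")
}

#' Construct a category scheme
#'
#' @param label Substance labels.
#' @param primary,secondary Categories from [category_vocabulary()].
#' @return Data frame of class `category_scheme`.
#' @export
category_scheme <- function(label, primary, secondary = primary) {
  if (anyDuplicated(label)) {
    stop("duplicate labels in category scheme: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  bad <- setdiff(unique(c(primary, secondary)), category_vocabulary())
  if (length(bad) > 0L) {
    stop("categories outside the closed vocabulary: ",
         paste(bad, collapse = ", "))
  }
  structure(data.frame(label = label, primary = primary,
                       secondary = secondary, stringsAsFactors = FALSE),
            class = c("category_scheme", "data.frame"))
}

#' Assemble per-class documents from individual reports
#'
#' Substance reports are pooled into one document per substance label,
#' keeping only substances with at least `min_reports` reports. Dream reports
#' at the two lucidity extremes are pooled into exactly two documents,
#' `dream_low` and `dream_high`; dreams at intermediate lucidity are
#' discarded. Within a document, reports are ordered by `report_id` so the
#' result is invariant to the input order.
#'
#' @param reports Data frame as returned by [load_reports()].
#' @param min_reports Minimum reports for a substance to be included
#'   (default 10).
#' @param lucidity_low,lucidity_high Lucidity scores defining the low/high
#'   dream documents (defaults 1 and 5).
#' @return A `document_collection`: list with parallel vectors `label`,
#'   `source`, `report_count`, `word_count` (raw whitespace token counts) and
#'   list column `text` (one concatenated raw text per document). Token bags
#'   are filled later by [preprocess_collection()].
#' @export
assemble_documents <- function(reports, min_reports = 10L,
                               lucidity_low = 1L, lucidity_high = 5L) {
  stopifnot(min_reports >= 1L)
  if (!(lucidity_low >= 1L && lucidity_low < lucidity_high && lucidity_high <= 5L)) {
    stop("need 1 <= lucidity_low < lucidity_high <= 5")
  }
  subs <- reports[reports$source == "substance", , drop = FALSE]
  drms <- reports[reports$source == "dream", , drop = FALSE]

  labels <- character(0); srcs <- character(0)
  texts <- list(); n_rep <- integer(0); n_word <- integer(0)
  excluded <- list()

  if (nrow(subs) > 0L) {
    for (lab in sort(unique(subs$label))) {
      grp <- subs[subs$label == lab, , drop = FALSE]
      if (nrow(grp) < min_reports) {
        excluded[[lab]] <- nrow(grp)
        next
      }
      grp <- grp[order(grp$report_id), , drop = FALSE]
      txt <- paste(grp$text, collapse = "\n")
      labels <- c(labels, lab); srcs <- c(srcs, "substance")
      texts[[length(texts) + 1L]] <- txt
      n_rep <- c(n_rep, nrow(grp))
      n_word <- c(n_word, length(strsplit(trimws(txt), "\\s+")[[1]]))
    }
  }
  if (length(excluded) > 0L) {
    message("assemble_documents: excluded ", length(excluded),
            " substance(s) with fewer than ", min_reports, " reports (",
            paste(sprintf("%s: %d", names(excluded), unlist(excluded)),
                  collapse = ", "), ")")
  }

  n_discarded_dreams <- 0L
  if (nrow(drms) > 0L) {
    lowg <- drms[drms$lucidity == lucidity_low, , drop = FALSE]
    higg <- drms[drms$lucidity == lucidity_high, , drop = FALSE]
    n_discarded_dreams <- nrow(drms) - nrow(lowg) - nrow(higg)
    if (nrow(lowg) == 0L && nrow(higg) == 0L) {
      stop("dream reports present but none at lucidity ",
           lucidity_low, " or ", lucidity_high)
    }
    for (side in list(list(lab = "dream_high", grp = higg),
                      list(lab = "dream_low", grp = lowg))) {
      if (nrow(side$grp) == 0L) next
      grp <- side$grp[order(side$grp$report_id), , drop = FALSE]
      txt <- paste(grp$text, collapse = "\n")
      labels <- c(labels, side$lab); srcs <- c(srcs, "dream")
      texts[[length(texts) + 1L]] <- txt
      n_rep <- c(n_rep, nrow(grp))
      n_word <- c(n_word, length(strsplit(trimws(txt), "\\s+")[[1]]))
    }
    if (n_discarded_dreams > 0L) {
      message("assemble_documents: discarded ", n_discarded_dreams,
              " dream report(s) at intermediate lucidity")
    }
  }
  if (length(labels) == 0L) stop("no documents survived assembly")
  structure(list(label = labels, source = srcs, text = texts,
                 report_count = n_rep, word_count = n_word,
                 tokens = NULL,
                 excluded = unlist(excluded),
                 n_discarded_dreams = n_discarded_dreams),
            class = "document_collection")
}

#' @export
print.document_collection <- function(x, ...) {
  cat("document_collection:", length(x$label), "document(s)\n")
  cat("  substances:", sum(x$source == "substance"),
      " dream docs:", sum(x$source == "dream"), "\n")
  if (!is.null(x$tokens)) {
    cat("  preprocessed: yes (",
        format(sum(lengths(x$tokens)), big.mark = ","), " tokens )\n", sep = "")
  } else {
    cat("  preprocessed: no\n")
  }
  invisible(x)
}

#' Write reports to JSON Lines
#'
#' Inverse of [load_reports()]; used by the synthetic-corpus generator to
#' emit corpora in the same record format the reader consumes.
#'
#' @param reports Report data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports_jsonl <- function(reports, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    rec <- list(id = reports$report_id[i], label = reports$label[i],
                source = reports$source[i], text = reports$text[i])
    if (!is.na(reports$lucidity[i])) rec$lucidity <- reports$lucidity[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
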