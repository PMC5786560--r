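.config_defaults <- function() {
  list(
    reports_path = NULL, reports_format = "jsonl",
    censor_path = NULL, scheme_path = NULL,
    synthetic = FALSE,
    min_reports = 10L, lucidity_low = 1L, lucidity_high = 5L,
    min_token_len = 3L, drop_numeric = FALSE, punctuation = "strip",
    idf_dialect = "plain", df_min = 0.05, df_max = 0.95,
    D = 20L, D_grid = seq(20L, 70L, by = 5L),
    test_method = "ranksum", alpha = 0.05, correction = FALSE,
    category_min_n = 6L, n_top_terms = 40L, probes = NULL,
    output_dir = "results", seed = 20180122L
  )
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration, fills in the pipeline defaults (minimum 10
#' reports per substance, 3-character token floor, 5%/95% document-frequency
#' band, D = 20 with a 20-70 stability grid, alpha = 0.05, plain-log idf)
#' and validates every constraint. Unknown keys are rejected rather than
#' ignored. An empty file yields the full default configuration.
#'
#' @param path YAML file path, or `NULL`/a named list for in-memory configs.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path = NULL) {
  defaults <- .config_defaults()
  user <- list()
  if (is.list(path)) {
    user <- path
  } else if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$min_reports >= 1, "min_reports: must be >= 1")
  chk(cfg$lucidity_low >= 1 && cfg$lucidity_low < cfg$lucidity_high &&
        cfg$lucidity_high <= 5,
      "lucidity_low/lucidity_high: need 1 <= low < high <= 5")
  chk(cfg$min_token_len >= 1, "min_token_len: must be >= 1")
  chk(cfg$df_min >= 0 && cfg$df_max <= 1 && cfg$df_min < cfg$df_max,
      "df_min/df_max: need 0 <= df_min < df_max <= 1")
  chk(cfg$D >= 1, "D: must be >= 1")
  chk(all(cfg$D_grid >= 1), "D_grid: all values must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha: must be in (0, 1)")
  chk(cfg$idf_dialect %in% c("plain", "smoothed"),
      "idf_dialect: must be 'plain' or 'smoothed'")
  chk(cfg$test_method %in% c("ranksum", "signed_rank"),
      "test_method: must be 'ranksum' or 'signed_rank'")
  chk(cfg$punctuation %in% c("strip", "space"),
      "punctuation: must be 'strip' or 'space'")
  chk(isTRUE(cfg$synthetic) || !is.null(cfg$reports_path),
      "reports_path: required unless synthetic = true")
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  structure(cfg, class = "run_config")
}

.write_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative-phenomenology pipeline
#'
#' Ingest (or synthesize) the report corpus, preprocess and censor, build the
#' tf-idf matrix, reduce by truncated SVD, rank every substance by similarity
#' to the high- and low-lucidity dream documents, and produce the statistical
#' layer: per-category summaries, the two-factor ANOVA, pairwise category
#' tests, the lucidity-difference ranking, cross-similarity predictions for
#' the probe substances, term-rank tables, and the retained-rank stability
#' matrix. All tables are written as TSV under `config$output_dir` together
#' with a reproducibility manifest; outputs are byte-identical across runs
#' with the same configuration and inputs.
#'
#' @param config A `run_config` from [validate_config()] (or a named list,
#'   validated on entry).
#' @return Invisibly, a list with every intermediate object (`collection`,
#'   `tdm`, `space`, `ranking_high`, `ranking_low`, `anova`, `pairwise`,
#'   `delta`, `cross`, `terms`, `stability`, `manifest`, `paths`).
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  checksums <- list()
  if (isTRUE(config$synthetic)) {
    spec <- benchmark_config(seed = config$seed)
    corpus <- generate_corpus(spec)
    reports <- corpus$reports
    censor <- corpus$censor
    scheme <- spec$categories
  } else {
    reports <- load_reports(config$reports_path, config$reports_format)
    checksums$reports <- unname(tools::md5sum(config$reports_path))
    censor <- if (!is.null(config$censor_path)) {
      checksums$censor <- unname(tools::md5sum(config$censor_path))
      load_censor_list(config$censor_path)
    } else censor_list(character(0))
    scheme <- if (!is.null(config$scheme_path)) {
      checksums$scheme <- unname(tools::md5sum(config$scheme_path))
      load_category_scheme(config$scheme_path)
    } else NULL
  }

  docs <- assemble_documents(reports, min_reports = config$min_reports,
                             lucidity_low = config$lucidity_low,
                             lucidity_high = config$lucidity_high)
  docs <- preprocess_collection(docs, censor = censor,
                                min_token_len = config$min_token_len,
                                drop_numeric = config$drop_numeric,
                                punctuation = config$punctuation)
  tdm <- build_term_document_matrix(docs, df_min = config$df_min,
                                    df_max = config$df_max,
                                    idf_dialect = config$idf_dialect)
  space <- truncate_svd(tdm, D = config$D)

  meta <- list(D = config$D, df_band = c(config$df_min, config$df_max),
               idf_dialect = config$idf_dialect,
               lemmatizer = lemmatizer_id(), seed = config$seed,
               reference = NA)
  paths <- list()
  res <- list(collection = docs, tdm = tdm, space = space)

  dreams <- intersect(c("dream_high", "dream_low"), tdm$doc_labels)
  rankings <- list()
  for (ref in dreams) {
    rk <- rank_documents(similarity_to_reference(space, ref))
    rankings[[ref]] <- rk
    meta$reference <- ref
    out <- rk
    if (!is.null(scheme)) {
      idx <- match(out$label, scheme$label)
      out$primary <- scheme$primary[idx]
      out$secondary <- scheme$secondary[idx]
    }
    paths[[paste0("ranking_", ref)]] <-
      .write_tsv(out, file.path(config$output_dir,
                                paste0("ranking_", ref, ".tsv")), meta)
  }
  res$ranking_high <- rankings[["dream_high"]]
  res$ranking_low <- rankings[["dream_low"]]

  if (length(rankings) == 2L && !is.null(scheme)) {
    rk_h <- rankings$dream_high; rk_l <- rankings$dream_low
    idx <- match(rk_h$label, scheme$label)
    cats <- scheme$primary[idx]
    vals <- c(rk_h$rank, rk_l$rank[match(rk_h$label, rk_l$label)])
    fcat <- rep(cats, 2L)
    fluc <- rep(c("high", "low"), each = nrow(rk_h))
    res$anova <- two_way_anova(vals, fcat, fluc)
    meta$reference <- "both"
    paths$anova <- .write_tsv(res$anova,
                              file.path(config$output_dir, "anova.tsv"), meta)
    res$pairwise <- pairwise_category_tests(vals, fcat,
                                            method = config$test_method,
                                            alpha = config$alpha,
                                            correct = config$correction)
    pw <- as.data.frame(res$pairwise$p)
    pw <- cbind(category = rownames(pw), pw)
    paths$pairwise <- .write_tsv(pw,
                                 file.path(config$output_dir, "pairwise_p.tsv"),
                                 meta)
    res$category_summary <- lapply(rankings, category_rank_summary,
                                   scheme = scheme,
                                   min_n = config$category_min_n)
    for (ref in names(res$category_summary)) {
      meta$reference <- ref
      paths[[paste0("category_summary_", ref)]] <-
        .write_tsv(res$category_summary[[ref]],
                   file.path(config$output_dir,
                             paste0("category_summary_", ref, ".tsv")), meta)
    }
    res$delta <- lucidity_delta_ranking(rk_h, rk_l)
    meta$reference <- "both"
    paths$delta <- .write_tsv(res$delta,
                              file.path(config$output_dir, "lucidity_delta.tsv"),
                              meta)
  }

  if (length(rankings) > 0L) {
    ref_main <- dreams[1]
    probes <- config$probes
    if (is.null(probes)) {
      probes <- utils::head(rankings[[ref_main]]$label, 4L)
    }
    res$cross <- do.call(rbind, lapply(dreams, function(ref) {
      do.call(rbind, lapply(probes, function(pb) {
        cs <- cross_similarity_prediction(space, pb, ref)
        data.frame(probe = pb, reference = ref, rho = cs$rho, n = cs$n,
                   stringsAsFactors = FALSE)
      }))
    }))
    meta$reference <- "per-row"
    paths$cross <- .write_tsv(res$cross,
                              file.path(config$output_dir,
                                        "cross_similarity.tsv"), meta)

    res$terms <- list()
    for (ref in dreams) {
      tt <- top_terms(space, ref, n = config$n_top_terms)
      res$terms[[paste0("top_", ref)]] <- tt
      meta$reference <- ref
      paths[[paste0("terms_", ref)]] <-
        .write_tsv(tt, file.path(config$output_dir,
                                 paste0("top_terms_", ref, ".tsv")), meta)
      jt <- joint_rank_weights(space, probes, ref, n = config$n_top_terms)
      res$terms[[paste0("joint_", ref)]] <- jt
      paths[[paste0("joint_terms_", ref)]] <-
        .write_tsv(jt, file.path(config$output_dir,
                                 paste0("joint_terms_", ref, ".tsv")), meta)
    }

    res$stability <- lapply(stats::setNames(dreams, dreams), function(ref) {
      suppressWarnings(stability_analysis(tdm, D_grid = config$D_grid,
                                          reference = ref))
    })
    for (ref in dreams) {
      sm <- res$stability[[ref]]
      smd <- as.data.frame(unclass(sm))
      smd <- cbind(D = rownames(smd), smd)
      meta$reference <- ref
      paths[[paste0("stability_", ref)]] <-
        .write_tsv(smd, file.path(config$output_dir,
                                  paste0("stability_", ref, ".tsv")), meta)
    }
  }

  manifest <- list(
    package = "dreamlsa",
    version = as.character(utils::packageVersion("dreamlsa")),
    parameters = unclass(config)[setdiff(names(config), "probes")],
    probes = if (exists("probes")) probes else NULL,
    lemmatizer = lemmatizer_id(),
    input_checksums = checksums,
    n_documents = length(docs$label),
    n_terms = length(tdm$vocabulary),
    documents = docs$label,
    report_counts = docs$report_count
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$manifest <- manifest_path
  res$manifest <- manifest
  res$paths <- paths
  invisible(res)
}
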