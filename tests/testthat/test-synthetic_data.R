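test_that("spec validation catches broken probability structures", {
  spec <- small_spec()
  expect_silent(validate_topic_model_spec(spec))
  bad <- spec; bad$mixtures[1, ] <- c(0.5, 0.2, 0.2)
  expect_error(validate_topic_model_spec(bad), "probability")
  bad2 <- spec; bad2$topic_word[1, 1] <- -0.1
  expect_error(validate_topic_model_spec(bad2), "probability")
  bad3 <- spec; bad3$classes$lucidity[5] <- 4L
  expect_error(validate_topic_model_spec(bad3), "extreme")
  bad4 <- spec; bad4$classes$n_reports[1] <- 5L
  expect_error(validate_topic_model_spec(bad4), "n_reports")
})

test_that("corpus generation is token-identical under a fixed seed", {
  spec <- small_spec(seed = 77)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$reports, c2$reports)
  c3 <- generate_corpus(small_spec(seed = 78))
  expect_false(identical(c1$reports$text, c3$reports$text))
})

test_that("a single shared topic collapses all ground-truth similarities to 1", {
  spec <- small_spec()
  one <- topic_model_spec(
    V = spec$V, K = 1L,
    topic_word = matrix(spec$topic_word[1, ], 1),
    classes = spec$classes,
    mixtures = matrix(1, nrow(spec$classes), 1,
                      dimnames = list(spec$classes$label, NULL)),
    seed = 5L)
  gt <- ground_truth_similarity(one)
  expect_true(all(abs(gt$similarity - 1) < 1e-12))
})

test_that("disjoint single-topic classes attain the minimal pairwise similarity", {
  classes <- data.frame(
    label = c("pure1", "pure2", "blend", "dream_high", "dream_low"),
    source = c("substance", "substance", "substance", "dream", "dream"),
    lucidity = c(NA, NA, NA, 5L, 1L),
    n_reports = 10L, length_mean = 30, length_dispersion = 5,
    stringsAsFactors = FALSE)
  tw <- rbind(c(rep(0.25, 4), rep(0, 4)), c(rep(0, 4), rep(0.25, 4)))
  mixtures <- rbind(pure1 = c(1, 0), pure2 = c(0, 1), blend = c(0.6, 0.4),
                    dream_high = c(0.9, 0.1), dream_low = c(0.1, 0.9))
  spec <- topic_model_spec(V = 8L, K = 2L, topic_word = tw, classes = classes,
                           mixtures = mixtures, seed = 9L)
  gt <- ground_truth_similarity(spec)
  off <- gt$similarity[upper.tri(gt$similarity)]
  expect_equal(gt$similarity["pure1", "pure2"], min(off), tolerance = 1e-12)
})

test_that("ground truth matches hand-computed mixture correlations", {
  # 2 topics on 4 words each; 3 classes with simple mixtures
  tw <- rbind(c(0.4, 0.3, 0.2, 0.1, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0.1, 0.2, 0.3, 0.4))
  mixtures <- rbind(ca = c(1, 0), cb = c(0.5, 0.5), dream_high = c(0.2, 0.8),
                    dream_low = c(0.8, 0.2))
  classes <- data.frame(label = rownames(mixtures),
                        source = c("substance", "substance", "dream", "dream"),
                        lucidity = c(NA, NA, 5L, 1L),
                        n_reports = 10L, length_mean = 30,
                        length_dispersion = 5, stringsAsFactors = FALSE)
  spec <- topic_model_spec(V = 8L, K = 2L, topic_word = tw, classes = classes,
                           mixtures = mixtures, seed = 3L)
  gt <- ground_truth_similarity(spec)
  # hand mixture arithmetic, then the Pearson formula via cor()
  p_ca <- tw[1, ]
  p_cb <- 0.5 * tw[1, ] + 0.5 * tw[2, ]
  p_dh <- 0.2 * tw[1, ] + 0.8 * tw[2, ]
  expect_equal(gt$similarity["ca", "cb"], cor(p_ca, p_cb), tolerance = 1e-12)
  expect_equal(gt$similarity["ca", "dream_high"], cor(p_ca, p_dh),
               tolerance = 1e-12)
  # ranking vs a dream class is the descending sort of its similarity column
  rk <- gt$ranking_vs$dream_high
  expect_equal(rk$label,
               names(sort(gt$similarity[c("ca", "cb"), "dream_high"],
                          decreasing = TRUE)))
  expect_equal(rk$rank, seq_len(nrow(rk)))
})

test_that("empirical class term frequencies converge to the expected distribution", {
  tv_dream_high <- function(spec) {
    corpus <- generate_corpus(spec)
    P <- class_term_distributions(spec)
    dh <- corpus$reports[corpus$reports$source == "dream" &
                           corpus$reports$lucidity == 5L, ]
    toks <- unlist(strsplit(dh$text, " ", fixed = TRUE), use.names = FALSE)
    emp <- table(factor(toks, levels = spec$vocab)) / length(toks)
    0.5 * sum(abs(as.numeric(emp) - P["dream_high", ]))
  }
  spec <- benchmark_config()
  tv200 <- tv_dream_high(spec)   # 200 reports x ~120 words
  expect_lt(tv200, 0.1)
  # quadrupling the report count must shrink the distance (~1/2 in theory)
  spec4 <- spec
  spec4$classes$n_reports <- 800L
  tv800 <- tv_dream_high(spec4)
  expect_lt(tv800, tv200 * 0.75)
})

test_that("the frozen benchmark spec has the planted ground-truth structure", {
  spec <- benchmark_config()
  expect_silent(validate_topic_model_spec(spec))
  expect_equal(spec$seed, 20180122L)
  expect_equal(sum(spec$classes$source == "substance"), 30L)
  expect_setequal(spec$classes$lucidity[spec$classes$source == "dream"],
                  c(1L, 5L))
  # overlap classes share at least half their mixture mass with dream_high
  mh <- spec$mixtures["dream_high", ]
  for (lab in spec$overlap_labels) {
    expect_gte(sum(pmin(spec$mixtures[lab, ], mh)), 0.5)
  }
  gt <- ground_truth_similarity(spec)
  top8 <- head(gt$ranking_vs$dream_high$label, 8)
  expect_equal(sum(top8 %in% spec$overlap_labels), 6L)
  # categories cover every substance class with n >= 2 for the ANOVA layer
  expect_setequal(spec$categories$label,
                  spec$classes$label[spec$classes$source == "substance"])
  expect_true(all(table(spec$categories$primary) >= 2L))
})

test_that("injected contaminants are confined to substance reports and censorable", {
  spec <- small_spec(seed = 55)
  corpus <- generate_corpus(spec)
  cens <- as.character(corpus$censor)
  expect_setequal(cens, unlist(spec$contaminant_terms, use.names = FALSE))
  dream_text <- paste(corpus$reports$text[corpus$reports$source == "dream"],
                      collapse = " ")
  expect_false(any(vapply(cens, grepl, logical(1), x = dream_text,
                          fixed = TRUE)))
  sub_text <- paste(corpus$reports$text[corpus$reports$label == "subA"],
                    collapse = " ")
  expect_true(any(vapply(c("druga1", "druga2"), grepl, logical(1),
                         x = sub_text, fixed = TRUE)))
})
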