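test_that("the registry holds exactly 32 basic feature types", {
  reg <- feature_registry()
  expect_length(reg, 32L)
  expect_false(any(duplicated(reg)))
})

test_that("every exemplar surface fires its named feature", {
  exemplars <- list(
    INITCAPS = "Albumin", ALLCAPS = "SGPT", ENDCAPS = "IgA",
    `UPPER-LOWER` = "Serum", TWOCAPS = "LH", THREECAPS = "HMG",
    MORECAPS = "GGTP", MIXEDCAPS = "EcoRI", LOWERCASE = "calcitonin",
    ENDDIGIT = "cna1", ALPHANUMERIC = "p53", SINGLECHAR = "R",
    NUMBERS_LETTERS = "UR2", HASDIGIT = "E6", GREEK = "Alpha",
    ROMAN = "II", HAS_QUOTE = "gstC'", HAS_SLASH = "P42/44",
    END_PLUS = "HexA+", END_QUOTE = "C'", HASDASH = "Ap-2",
    INITDASH = "-beta", ENDDASH = "CD45-", HASGREEK = "TNF-alpha",
    HASROMAN = "factor II", PUNCTUATION = "("
  )
  for (feat in names(exemplars)) {
    expect_true(feat %in% basic_features(exemplars[[feat]]),
                label = sprintf("%s fires on '%s'", feat, exemplars[[feat]]))
  }
  affix <- basic_features("fibrin")
  expect_true(all(c("2PREFIX=fi", "3PREFIX=fib", "4PREFIX=fibr",
                    "2SUFFIX=in", "3SUFFIX=rin", "4SUFFIX=brin") %in% affix))
})

test_that("predicates co-fire and are pure functions of the surface", {
  f <- basic_features("p53")
  expect_true(all(c("ALPHANUMERIC", "HASDIGIT", "ENDDIGIT",
                    "NUMBERS_LETTERS") %in% f))
  expect_false(any(c("INITCAPS", "ALLCAPS", "LOWERCASE") %in% f))
  f2 <- basic_features("TNF-alpha")
  expect_true(all(c("HASGREEK", "HASDASH", "THREECAPS") %in% f2))
  # determinism
  for (s in c("p53", "EcoRI", "(", "-beta", "P42/44")) {
    expect_identical(basic_features(s), basic_features(s))
  }
})

test_that("character N-grams slide a width-4 window over the surface", {
  expect_setequal(char_ngrams("fibrin"),
                  c("NGRAM=fibr", "NGRAM=ibri", "NGRAM=brin"))
  expect_equal(char_ngrams("p53"), "NGRAM=p53")
  expect_equal(char_ngrams("abcd"), "NGRAM=abcd")
  expect_equal(char_ngrams("("), character())
  # n - 3 windows for distinct-character tokens of length n >= 4
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    tokstr <- paste(sample(letters, n), collapse = "")
    expect_length(char_ngrams(tokstr), n - 3L)
  }
  # prefix-mode alternative reading
  expect_setequal(char_ngrams("fibrin", mode = "prefixes"),
                  c("NGRAM=f", "NGRAM=fi", "NGRAM=fib", "NGRAM=fibr"))
})

test_that("the corpus-frequency table counts full mention surfaces", {
  mentions <- data.frame(
    sentence_id = c("S1", "S2", "S2"),
    start = c(0L, 0L, 4L), end = c(2L, 2L, 9L),
    text = c("COR", "COR", "factor II"),
    stringsAsFactors = FALSE
  )
  tab <- build_frequency_table(mentions)
  expect_equal(corpus_frequency(tab, "COR"), 2L)
  expect_equal(corpus_frequency(tab, "factor II"), 1L)
  expect_equal(corpus_frequency(tab, "unseen"), 0L)
  expect_equal(tab$theta_freq, 10L)
  empty <- build_frequency_table(bitagger:::empty_mentions())
  expect_length(empty$counts, 0L)
})

test_that("the frequency feature fires only for nouns inside the band", {
  mentions <- data.frame(sentence_id = c("S1", "S2"), start = 0L, end = 2L,
                         text = "COR", stringsAsFactors = FALSE)
  tab <- build_frequency_table(mentions, theta_freq = 10L)
  expect_equal(corpus_frequency_feature("COR", "NNP", tab), "CORPUS_FREQ")
  expect_equal(corpus_frequency_feature("COR", "VB", tab), character())
  expect_equal(corpus_frequency_feature("unseen", "NN", tab), character())
  # above the threshold the indicator goes silent (rare-name band)
  many <- build_frequency_table(
    data.frame(sentence_id = sprintf("S%d", 1:11), start = 0L, end = 2L,
               text = "ABC", stringsAsFactors = FALSE))
  expect_equal(corpus_frequency_feature("ABC", "NN", many), character())
  expect_equal(corpus_frequency_feature("ABC", "NN", many, invert = TRUE),
               "CORPUS_FREQ")
})

test_that("offset conjunctions copy neighbor features with positional prefixes", {
  basics <- lapply(c("Albumin", "binds", "p53", "in", "cells"),
                   basic_features)
  mid <- offset_conjunction(basics, 3L)
  expect_true("@-2:INITCAPS" %in% mid)
  expect_true(any(startsWith(mid, "@-1:")))
  expect_true(any(startsWith(mid, "@+1:")))
  expect_true(any(startsWith(mid, "@+2:")))
  left <- offset_conjunction(basics, 1L)
  expect_true(all(c("@-1:__EDGE__", "@-2:__EDGE__") %in% left))
  expect_false(any(grepl("^@-[12]:[^_]", left)))
  single <- offset_conjunction(list(basic_features("p53")), 1L)
  expect_setequal(single, c("@-1:__EDGE__", "@-2:__EDGE__",
                            "@+1:__EDGE__", "@+2:__EDGE__"))
})

test_that("full extraction is deterministic and dumps one token per line", {
  ts <- toy_sentence(c("Albumin", "binds", "p53"))
  f1 <- extract_features(ts)
  f2 <- extract_features(ts)
  expect_identical(f1, f2)
  dump <- format_feature_dump(ts, f1)
  expect_length(dump, 3L)
  expect_true(startsWith(dump[1], "Albumin\t"))
})

test_that("PCA selection matches a dense eigendecomposition oracle", {
  # fixed small integer matrix: eigenvalues match the covariance eigenvalues
  x0 <- matrix(c(1, 0, 2, 1,
                 0, 1, 1, 3,
                 2, 2, 0, 1), nrow = 4,
               dimnames = list(NULL, c("A", "B", "C")))
  got0 <- pca_select(x0, 2L, 3L)
  eg0 <- eigen(stats::cov(x0), symmetric = TRUE)
  expect_lt(max(abs(got0$eigenvalues - eg0$values)), 1e-8)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    p <- sample(3:10, 1)
    x <- matrix(stats::runif(n * p), n, p,
                dimnames = list(NULL, sprintf("F%d", 1:p)))
    L <- sample(1:min(n - 1, p), 1)
    K <- sample(1:p, 1)
    got <- pca_select(x, L, K)
    # oracle: eigendecomposition of the feature covariance matrix
    eg <- eigen(stats::cov(x), symmetric = TRUE)
    r <- min(sum(eg$values > 1e-12), length(got$eigenvalues))
    expect_lt(max(abs(got$eigenvalues[1:r] - eg$values[1:r])), 1e-8)
    expect_true(all(diff(got$eigenvalues) <= 1e-12))
    expect_true(all(got$eigenvalues >= -1e-12))
    Lr <- min(L, r)
    scores <- stats::setNames(
      apply(abs(eg$vectors[, 1:Lr, drop = FALSE]), 1, max), colnames(x))
    expect_lt(max(abs(got$scores - scores)), 1e-8)
    # every retained feature outscores every dropped one
    dropped <- setdiff(colnames(x), got$selected)
    if (length(dropped) > 0L) {
      expect_gte(min(scores[got$selected]), max(scores[dropped]) - 1e-10)
    }
  }
})

test_that("PCA selection ranks constant features last and respects K", {
  x <- cbind(const = rep(1, 6), varies = c(1, 0, 1, 0, 1, 0))
  sel <- pca_select(x, n_components = 1L, n_keep = 1L)
  expect_equal(sel$selected, "varies")
  x2 <- matrix(stats::rnorm(30), 6, 5,
               dimnames = list(NULL, sprintf("F%d", 1:5)))
  expect_setequal(pca_select(x2, 2L, 5L)$selected, colnames(x2))
  expect_error(pca_select(matrix(1, 4, 3), 1L, 1L), "degenerate")
})

test_that("PCA selection is invariant to row permutation", {
  set.seed(13)
  x <- matrix(sample(0:1, 80, replace = TRUE), 10, 8,
              dimnames = list(NULL, sprintf("F%d", 1:8)))
  a <- pca_select(x, 3L, 4L)
  b <- pca_select(x[sample(nrow(x)), ], 3L, 4L)
  expect_equal(a$selected, b$selected)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-10)
})
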