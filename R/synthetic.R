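# Vocabulary pools for the toy corpus.  Filler words are plain lowercase
# common words, disjoint from gene surfaces, so that orthography and
# context carry the label signal.
SYN_FILLER <- c(
  "the", "expression", "of", "was", "measured", "in", "cells", "we",
  "observed", "that", "levels", "increased", "during", "treatment",
  "samples", "from", "patients", "showed", "significant", "changes",
  "analysis", "revealed", "a", "role", "for", "this", "pathway",
  "response", "to", "stress", "conditions", "tissue", "normal",
  "compared", "with", "control", "groups", "after", "exposure")

SYN_VERBS <- c("encodes", "produces", "contains", "shows", "remains")

# long-form word pool: initials are combinable into plausible short forms
SYN_LF_WORDS <- c(
  "brown", "adipose", "white", "nuclear", "growth", "tumor", "necrosis",
  "receptor", "kinase", "transfer", "serum", "plasma", "hepatic",
  "epidermal", "vascular", "neural", "cardiac", "muscle", "fetal",
  "adult")

SYN_RELATION_WORDS <- c("binds", "activates", "phosphorylates",
                        "inhibits", "regulates", "interacts")

SYN_GREEK <- c("alpha", "beta", "gamma", "kappa")

#' Toy corpus configuration
#'
#' Generation parameters for the deterministic synthetic BC2GM-format
#' corpus.  Output is a pure function of the configuration.
#'
#' @param seed Integer RNG seed.
#' @param n_sentences Number of sentences.
#' @param gene_lexicon_size Number of distinct gene surfaces to draw on.
#' @param p_abbreviation Fraction of sentences built around an
#'   `Long Form ( SF )` construct.
#' @param p_parenthesized Fraction with a parenthesized synonym mention.
#' @param p_relation_keyword Fraction with a relation-keyword context.
#' @param p_connective Fraction with a connective "and/or" gene pair.
#' @param unseen_fraction When generating a held-out companion lexicon,
#'   the fraction of fresh (never trained on) gene surfaces; defaults to
#'   0.2 so that orthographic generalization, not memorization, is
#'   exercised.
#' @return A `bt_syn_config` list.
#' @export
toy_corpus_config <- function(seed = 1L, n_sentences = 100L,
                              gene_lexicon_size = 200L,
                              p_abbreviation = 0.2,
                              p_parenthesized = 0.15,
                              p_relation_keyword = 0.25,
                              p_connective = 0.2,
                              unseen_fraction = 0.2) {
  probs <- c(p_abbreviation, p_parenthesized, p_relation_keyword,
             p_connective, unseen_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1), n_sentences >= 1L,
            gene_lexicon_size >= 1L)
  structure(list(seed = as.integer(seed),
                 n_sentences = as.integer(n_sentences),
                 gene_lexicon_size = as.integer(gene_lexicon_size),
                 p_abbreviation = p_abbreviation,
                 p_parenthesized = p_parenthesized,
                 p_relation_keyword = p_relation_keyword,
                 p_connective = p_connective,
                 unseen_fraction = unseen_fraction),
            class = "bt_syn_config")
}

syn_syllable <- function() {
  cons <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r",
            "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(sample(cons, 1L), sample(vow, 1L),
         sample(c(cons, ""), 1L))
}

syn_caps <- function(nmin = 2L, nmax = 5L) {
  paste(sample(LETTERS, sample(nmin:nmax, 1L), replace = TRUE),
        collapse = "")
}

#' Generate a gene-surface lexicon
#'
#' Surfaces follow the orthographic shapes the feature registry keys on:
#' all-caps symbols, lowercase+digit names, letter/digit compounds,
#' mixed-case restriction-enzyme style names, Greek-suffixed compounds,
#' slash/plus/quote variants and multi-token roman-numeral factors.
#'
#' @param n Number of surfaces.
#' @return Character vector of `n` distinct gene surfaces.
#' @export
generate_gene_lexicon <- function(n) {
  stopifnot(n >= 1L)
  gens <- list(
    function() syn_caps(3L, 5L),                                  # SGPT
    function() paste0(sample(letters, 1L), sample(10:99, 1L)),    # p53
    function() {                                                  # Albumin
      s <- paste0(syn_syllable(), syn_syllable())
      paste0(toupper(substr(s, 1L, 1L)), substring(s, 2L))
    },
    function() paste0(toupper(substr(syn_syllable(), 1L, 1L)),    # EcoRI
                      syn_syllable(), syn_caps(2L, 2L)),
    function() paste0(syn_caps(2L, 3L), "-",                      # TNF-alpha
                      sample(SYN_GREEK, 1L)),
    function() paste0("CD", sample(10:99, 1L)),                   # CD45
    function() paste0("I", syn_syllable(), syn_caps(1L, 1L)),     # IgA
    function() paste0(syn_caps(2L, 2L), sample(1:9, 1L)),         # UR2
    function() paste0(syn_caps(1L, 1L), sample(10:60, 1L), "/",   # P42/44
                      sample(10:60, 1L)),
    function() paste0(syn_caps(1L, 1L), syn_syllable(),           # HexA+
                      syn_caps(1L, 1L), "+"),
    function() paste0(syn_syllable(), syn_caps(1L, 1L), "'"),     # gstC'
    function() paste0(syn_syllable(), sample(1:9, 1L)),           # cna1
    function() syn_syllable(),                                    # src
    function() paste0("factor ", sample(c("II", "IV", "IX", "XI"), 1L)),
    function() sample(SYN_GREEK, 1L)                               # kappa
  )
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    g <- gens[[(guard %% length(gens)) + 1L]]
    out <- unique(c(out, g()))
    guard <- guard + 1L
  }
  out[seq_len(min(n, length(out)))]
}

# ns-offset arithmetic: items are words (may contain internal spaces);
# returns mention rows for flagged items
assemble_sentence <- function(sid, items, is_gene) {
  ns <- 0L
  starts <- integer(length(items))
  ends <- integer(length(items))
  for (i in seq_along(items)) {
    starts[i] <- ns
    ns <- ns + nchar(gsub("[[:space:]]", "", items[i]))
    ends[i] <- ns - 1L
  }
  text <- paste(items, collapse = " ")
  mentions <- if (any(is_gene)) {
    data.frame(sentence_id = sid, start = starts[is_gene],
               end = ends[is_gene], text = items[is_gene],
               stringsAsFactors = FALSE)
  } else {
    empty_mentions()
  }
  list(text = text, mentions = mentions)
}

syn_filler <- function(k) sample(SYN_FILLER, k, replace = TRUE)

# one sentence as (items, is_gene); lexicon is the gene surface pool
syn_sentence_items <- function(config, lexicon) {
  u <- stats::runif(1L)
  gene <- function() sample(lexicon, 1L)
  if (u < config$p_abbreviation) {
    k <- sample(2:3, 1L)
    lf_words <- sample(SYN_LF_WORDS, k)
    lf <- paste(lf_words, collapse = " ")
    sf <- toupper(paste(substr(lf_words, 1L, 1L), collapse = ""))
    items <- c(syn_filler(2L), lf, "(", sf, ")", syn_filler(3L))
    is_gene <- rep(FALSE, length(items))
    is_gene[3L] <- TRUE   # long form
    is_gene[5L] <- TRUE   # short form
  } else if (u < config$p_abbreviation + config$p_parenthesized) {
    items <- c(syn_filler(1L), gene(), "(", gene(), ")", syn_filler(3L))
    is_gene <- rep(FALSE, length(items))
    is_gene[c(2L, 4L)] <- TRUE
  } else if (u < config$p_abbreviation + config$p_parenthesized +
             config$p_relation_keyword) {
    items <- c(syn_filler(1L), gene(), sample(SYN_RELATION_WORDS, 1L),
               gene(), syn_filler(3L))
    is_gene <- rep(FALSE, length(items))
    is_gene[c(2L, 4L)] <- TRUE
  } else if (u < config$p_abbreviation + config$p_parenthesized +
             config$p_relation_keyword + config$p_connective) {
    items <- c(syn_filler(2L), gene(), sample(c("and", "or"), 1L),
               gene(), syn_filler(2L))
    is_gene <- rep(FALSE, length(items))
    is_gene[c(3L, 5L)] <- TRUE
  } else {
    items <- c(syn_filler(2L), gene(), SYN_VERBS[sample.int(5L, 1L)],
               syn_filler(3L))
    is_gene <- rep(FALSE, length(items))
    is_gene[3L] <- TRUE
  }
  list(items = items, is_gene = is_gene)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy BC2GM-format corpus
#'
#' Deterministic in the configuration: identical configs give byte-identical
#' output.  Gene surfaces carry the orthographic shapes the feature
#' registry targets; a configurable fraction of sentences contain
#' `Long Form ( SF )` constructs, parenthesized synonym mentions,
#' relation-keyword and connective contexts.  Gold annotations are emitted
#' in the `id|start end|text` format with non-space offsets.
#'
#' @param config A [toy_corpus_config()].
#' @param lexicon Optional pre-built gene lexicon (for held-out corpora
#'   sharing surfaces with a training corpus).
#' @param id_prefix Sentence-id prefix (default `"SYN"`).
#' @return A list with `sentences` and `mentions` data.frames, the
#'   `lexicon` used, and preformatted file content vectors
#'   `sentence_lines` / `annotation_lines`.
#' @export
generate_corpus <- function(config, lexicon = NULL, id_prefix = "SYN") {
  stopifnot(inherits(config, "bt_syn_config"))
  with_seed(config$seed, {
    if (is.null(lexicon)) {
      lexicon <- generate_gene_lexicon(config$gene_lexicon_size)
    }
    if (length(lexicon) == 0L) stop("empty gene lexicon")
    sent_rows <- vector("list", config$n_sentences)
    men_rows <- vector("list", config$n_sentences)
    for (i in seq_len(config$n_sentences)) {
      sid <- sprintf("%s%05d", id_prefix, i)
      si <- syn_sentence_items(config, lexicon)
      asm <- assemble_sentence(sid, si$items, si$is_gene)
      sent_rows[[i]] <- data.frame(sentence_id = sid, text = asm$text,
                                   stringsAsFactors = FALSE)
      men_rows[[i]] <- asm$mentions
    }
    sentences <- do.call(rbind, sent_rows)
    mentions <- do.call(rbind, men_rows)
    list(
      sentences = sentences,
      mentions = mentions,
      lexicon = lexicon,
      sentence_lines = paste(sentences$sentence_id, sentences$text),
      annotation_lines = sprintf("%s|%d %d|%s", mentions$sentence_id,
                                 mentions$start, mentions$end,
                                 mentions$text)
    )
  })
}

#' Generate matched train and held-out toy corpora
#'
#' The held-out corpus draws `1 - unseen_fraction` of its gene surfaces
#' from the training lexicon and the rest from fresh surfaces, so held-out
#' performance reflects orthographic generalization as well as recall of
#' seen names.
#'
#' @param config A [toy_corpus_config()] describing the training corpus.
#' @param n_test Number of held-out sentences.
#' @return List with `train` and `test` corpora (as from
#'   [generate_corpus()]).
#' @export
generate_train_test <- function(config, n_test = 100L) {
  train <- generate_corpus(config, id_prefix = "TRN")
  test_cfg <- config
  test_cfg$seed <- config$seed + 104729L  # distinct stream, still derived
  test_cfg$n_sentences <- as.integer(n_test)
  test_lex <- with_seed(test_cfg$seed, {
    n_seen <- round((1 - config$unseen_fraction) * length(train$lexicon))
    fresh <- generate_gene_lexicon(2L * config$gene_lexicon_size)
    fresh <- setdiff(fresh, train$lexicon)
    c(sample(train$lexicon, n_seen),
      fresh[seq_len(min(length(fresh),
                        length(train$lexicon) - n_seen))])
  })
  test <- generate_corpus(test_cfg, lexicon = test_lex, id_prefix = "TST")
  list(train = train, test = test)
}
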