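#' Pipeline configuration
#'
#' Collects every tunable of the tagging pipeline with its default:
#' corpus-frequency threshold `theta_freq = 10`, post-keyword list minimum
#' count 3, conjunction half-width 2 (preceding/following two tokens),
#' character N-gram window 4, optional PCA selection (off unless `pca_keep`
#' is set), L2-regularized CRF training, 5 MIRA epochs, and the
#' combination mode.
#'
#' @param theta_freq Corpus-frequency upper threshold.
#' @param freq_invert Use the complementary frequency band (see
#'   [corpus_frequency_feature()]).
#' @param pkl_min_count Minimum training count for pkl matchability.
#' @param conj_window Offset-conjunction half-width.
#' @param ngram_window Character N-gram width.
#' @param ngram_mode `"windows"` or `"prefixes"` (see [char_ngrams()]).
#' @param pca_components Number of leading components scored when PCA
#'   selection is enabled.
#' @param pca_keep Number of features to keep; `NULL` disables selection.
#' @param crf_lambda L2 regularization strength.
#' @param crf_maxit Maximum optimizer iterations.
#' @param mira_epochs MIRA refinement passes.
#' @param mode Combination mode: `"forward"`, `"backward"`, `"union"`,
#'   `"intersection"` or `"mira"`.
#' @param rules_contextual,rules_parentheses,rules_abbreviation
#'   Post-processing rule toggles.
#' @param max_sf_chars Maximum abbreviation short-form length.
#' @param seed Random seed recorded with the config.
#' @return A `bt_config` list.
#' @export
pipeline_config <- function(theta_freq = 10L,
                            freq_invert = FALSE,
                            pkl_min_count = 3L,
                            conj_window = 2L,
                            ngram_window = 4L,
                            ngram_mode = "windows",
                            pca_components = 50L,
                            pca_keep = NULL,
                            crf_lambda = 1.0,
                            crf_maxit = 200L,
                            mira_epochs = 5L,
                            mode = c("mira", "forward", "backward",
                                     "union", "intersection"),
                            rules_contextual = TRUE,
                            rules_parentheses = TRUE,
                            rules_abbreviation = TRUE,
                            max_sf_chars = 10L,
                            seed = 1L) {
  mode <- match.arg(mode)
  structure(list(
    theta_freq = as.integer(theta_freq),
    freq_invert = isTRUE(freq_invert),
    pkl_min_count = as.integer(pkl_min_count),
    conj_window = as.integer(conj_window),
    ngram_window = as.integer(ngram_window),
    ngram_mode = ngram_mode,
    pca_components = as.integer(pca_components),
    pca_keep = if (is.null(pca_keep)) NULL else as.integer(pca_keep),
    crf_lambda = crf_lambda,
    crf_maxit = as.integer(crf_maxit),
    mira_epochs = as.integer(mira_epochs),
    mode = mode,
    rules_contextual = isTRUE(rules_contextual),
    rules_parentheses = isTRUE(rules_parentheses),
    rules_abbreviation = isTRUE(rules_abbreviation),
    max_sf_chars = as.integer(max_sf_chars),
    seed = as.integer(seed)
  ), class = "bt_config")
}

# training sequences (string features + BIO labels) for a tokenized corpus
build_sequences <- function(tok_sents, mentions, freq_table, config) {
  lapply(tok_sents, function(ts) {
    list(features = extract_features(ts, freq_table, config),
         labels = mentions_to_bio(ts, mentions))
  })
}

restrict_features <- function(sequences, keep) {
  lapply(sequences, function(s) {
    s$features <- lapply(s$features, function(f) f[f %in% keep])
    s
  })
}

#' Train the full tagger
#'
#' Tokenizes and annotates the training corpus, builds the
#' corpus-frequency table and the post-keyword list from the gold
#' mentions, extracts features, optionally applies PCA feature selection,
#' trains forward and backward second-order CRFs and combines them
#' according to `config$mode`.
#'
#' @param sentences Sentence data.frame (`sentence_id`, `text`).
#' @param mentions Gold mention data.frame.
#' @param config A [pipeline_config()].
#' @param backend Annotation backend (default [default_backend()]).
#' @param lexicon Keyword lexicon for post-processing (default bundled).
#' @param verbose Log per-stage progress.
#' @return A `bt_tagger` bundling the models, frequency table, pkl,
#'   lexicon and config.
#' @export
train_tagger <- function(sentences, mentions, config = pipeline_config(),
                         backend = default_backend(),
                         lexicon = keyword_lexicon(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  tok_sents <- tokenize_corpus(sentences, backend)
  say("tokenized %d sentences [%.1fs]", length(tok_sents),
      proc.time()[["elapsed"]] - t0)
  freq_table <- build_frequency_table(mentions, config$theta_freq)
  pkl <- build_pkl(mentions, config$pkl_min_count)
  sequences <- build_sequences(tok_sents, mentions, freq_table, config)
  say("extracted features for %d sequences", length(sequences))
  if (!is.null(config$pca_keep)) {
    fm <- feature_matrix(lapply(sequences, `[[`, "features"))
    sel <- pca_select(fm, config$pca_components, config$pca_keep)
    sequences <- restrict_features(sequences, sel$selected)
    say("PCA selection kept %d of %d features",
        length(sel$selected), ncol(fm))
  }
  forward <- backward <- combined <- NULL
  if (config$mode %in% c("forward", "union", "intersection", "mira")) {
    forward <- train_crf(sequences, "forward", lambda = config$crf_lambda,
                         maxit = config$crf_maxit)
    say("forward model: nll %.2f -> %.2f", forward$nll_initial,
        forward$nll_final)
  }
  if (config$mode %in% c("backward", "union", "intersection", "mira")) {
    backward <- train_crf(sequences, "backward", lambda = config$crf_lambda,
                          maxit = config$crf_maxit)
    say("backward model: nll %.2f -> %.2f", backward$nll_initial,
        backward$nll_final)
  }
  if (config$mode == "mira") {
    combined <- mira_combine(forward, backward, sequences,
                             epochs = config$mira_epochs)
    say("MIRA updates per epoch: %s",
        paste(combined$mira_updates, collapse = " "))
  }
  say("training done [%.1fs]", proc.time()[["elapsed"]] - t0)
  structure(list(
    forward = forward, backward = backward, combined = combined,
    freq_table = freq_table, pkl = pkl, lexicon = lexicon,
    config = config
  ), class = "bt_tagger")
}

#' @export
print.bt_tagger <- function(x, ...) {
  cat(sprintf("<bt_tagger mode=%s: %s>\n", x$config$mode,
              paste(names(Filter(Negate(is.null),
                                 x[c("forward", "backward", "combined")])),
                    collapse = "+")))
  invisible(x)
}

# decode one tokenized sentence with one directional model
decode_sentence <- function(model, features) {
  if (model$direction == "backward") {
    enc <- encode_direction(features, NULL, "backward")
    lab_rev <- viterbi(model, enc$features)
    # map labels back to the forward orientation
    n <- length(lab_rev)
    out <- rep("O", n)
    for (sp in bio_spans(lab_rev)) {
      fs <- n + 1L - sp[2L]
      fe <- n + 1L - sp[1L]
      out[fs] <- "B"
      if (fe > fs) out[(fs + 1L):fe] <- "I"
    }
    out
  } else {
    viterbi(model, features)
  }
}

#' Tag a corpus of sentences
#'
#' Decodes each sentence with the configured model(s), applies the
#' post-processing rules in their fixed order and converts the label
#' sequences to mention spans.
#'
#' @param tagger A trained `bt_tagger`.
#' @param sentences Sentence data.frame.
#' @param postprocess Apply the rule-based post-processing (default TRUE).
#' @param mode Override the tagger's combination mode.
#' @param backend Annotation backend (must match training).
#' @return A mention data.frame.
#' @export
tag_corpus <- function(tagger, sentences, postprocess = TRUE,
                       mode = tagger$config$mode,
                       backend = default_backend()) {
  config <- tagger$config
  out <- list()
  for (i in seq_len(nrow(sentences))) {
    ts <- annotate(tokenize(sentences$text[i], sentences$sentence_id[i]),
                   backend)
    feats <- extract_features(ts, tagger$freq_table, config)
    labels <- switch(mode,
      forward = decode_sentence(tagger$forward, feats),
      backward = decode_sentence(tagger$backward, feats),
      mira = decode_sentence(tagger$combined, feats),
      union = ,
      intersection = {
        lf <- decode_sentence(tagger$forward, feats)
        lb <- decode_sentence(tagger$backward, feats)
        mf <- bio_to_mentions(ts, lf)
        mb2 <- bio_to_mentions(ts, lb)
        m <- if (mode == "union") union_mentions(mf, mb2)
             else intersect_mentions(mf, mb2)
        mentions_to_bio(ts, m)
      }
    )
    if (postprocess) {
      labels <- postprocess_labels(ts, labels, tagger$lexicon, tagger$pkl,
                                   config)
    }
    out[[i]] <- bio_to_mentions(ts, labels)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_mentions() else res
}
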