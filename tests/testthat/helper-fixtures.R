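# Shared fixtures built in code.

# random CRF model over an arbitrary feature vocabulary
random_model <- function(nfeat = 5L, direction = "forward") {
  vocab <- sprintf("f%02d", seq_len(nfeat))
  W <- matrix(stats::rnorm(nfeat * 3L), nfeat, 3L,
              dimnames = list(vocab, c("B", "I", "O")))
  bitagger:::new_crf_model(vocab, W, stats::rnorm(48L), direction)
}

random_features <- function(model, n_tokens, per_token = 3L) {
  lapply(seq_len(n_tokens), function(i) {
    sample(model$vocab, min(per_token, length(model$vocab)))
  })
}

# every BIO label sequence of length n (columns B < I < O, first position
# most significant)
all_label_sequences <- function(n) {
  grid <- expand.grid(rep(list(c("B", "I", "O")), n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_len(n)), drop = FALSE]  # first position varies last
  lapply(seq_len(nrow(grid)), function(r) as.character(grid[r, ]))
}

# brute-force log partition and argmax by enumeration
brute_force_crf <- function(model, feats) {
  seqs <- all_label_sequences(length(feats))
  scores <- vapply(seqs, function(y) sequence_score(model, feats, y),
                   numeric(1))
  m <- max(scores)
  list(logZ = m + log(sum(exp(scores - m))),
       argmax = seqs[[which.max(scores)]],
       scores = scores, seqs = seqs)
}

# random valid BIO sequence (B I* runs separated by O's)
random_bio <- function(n, p_mention = 0.3) {
  labels <- rep("O", n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < p_mention) {
      len <- sample(1:min(3L, n - i + 1L), 1L)
      labels[i] <- "B"
      if (len > 1L) labels[(i + 1L):(i + len - 1L)] <- "I"
      i <- i + len + 1L
    } else {
      i <- i + 1L
    }
  }
  labels
}

# a tokenized sentence from explicit word surfaces (single spaces)
toy_sentence <- function(surfaces, sid = "S1") {
  annotate(tokenize(paste(surfaces, collapse = " "), sid))
}

# Toy separable tagging language: the surface fully determines the label.
# GENE tokens are gene mentions, everything else is filler.
separable_sequences <- function(n_sentences = 8L, len = 6L) {
  lapply(seq_len(n_sentences), function(s) {
    is_gene <- stats::runif(len) < 0.35
    surfaces <- ifelse(is_gene, "GENE", "filler")
    feats <- lapply(surfaces, function(w) paste0("W=", w))
    labels <- ifelse(is_gene, "B", "O")
    list(features = feats, labels = labels,
         surfaces = surfaces)
  })
}

# random mention data.frame over a universe of sentences
random_mentions <- function(n, sids = sprintf("S%d", 1:5)) {
  if (n == 0L) return(bitagger:::empty_mentions())
  start <- sample(0:30, n, replace = TRUE)
  data.frame(
    sentence_id = sample(sids, n, replace = TRUE),
    start = start,
    end = start + sample(0:5, n, replace = TRUE),
    text = replicate(n, paste(sample(letters, 4), collapse = "")),
    stringsAsFactors = FALSE
  )
}

# cached end-to-end run: train on 300 generated sentences, tag 100 held out
.e2e_cache <- new.env(parent = emptyenv())
e2e_fixture <- function() {
  if (is.null(.e2e_cache$result)) {
    cfg <- toy_corpus_config(seed = 1L, n_sentences = 300L)
    tt <- generate_train_test(cfg, n_test = 100L)
    pc <- pipeline_config(mode = "mira", crf_maxit = 150L)
    t0 <- proc.time()[["elapsed"]]
    tagger <- train_tagger(tt$train$sentences, tt$train$mentions, pc)
    pred <- tag_corpus(tagger, tt$test$sentences)
    elapsed <- proc.time()[["elapsed"]] - t0
    .e2e_cache$result <- list(
      corpora = tt, tagger = tagger, pred = pred,
      eval = evaluate_mentions(tt$test$mentions, pred),
      elapsed = elapsed
    )
  }
  .e2e_cache$result
}

# brackets inside a mention must pair up inside the same mention
mention_brackets_balanced <- function(surfaces, labels) {
  for (sp in bitagger:::bio_spans(labels)) {
    seg <- surfaces[sp[1L]:sp[2L]]
    for (k in seq_along(c("(", "[", "{"))) {
      op <- c("(", "[", "{")[k]
      cl <- c(")", "]", "}")[k]
      depth <- 0L
      for (s in seg) {
        if (s == op) depth <- depth + 1L
        if (s == cl) {
          depth <- depth - 1L
          if (depth < 0L) return(FALSE)
        }
      }
      if (depth != 0L) return(FALSE)
    }
  }
  TRUE
}
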