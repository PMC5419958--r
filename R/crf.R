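BIO_LABELS <- c("B", "I", "O")

# number of trigram transition parameters: (B,I,O,BOS) x (B,I,O,BOS) x (B,I,O)
N_TRANS <- 48L

new_crf_model <- function(vocab, W, Tr, direction) {
  structure(list(direction = direction, order = 2L, labels = BIO_LABELS,
                 vocab = vocab, W = W, Tr = Tr),
            class = "bt_crf")
}

#' @export
print.bt_crf <- function(x, ...) {
  cat(sprintf("<bt_crf %s: order %d, %d features, %d transition weights>\n",
              x$direction, x$order, length(x$vocab), length(x$Tr)))
  invisible(x)
}

labels_to_int <- function(labels) match(labels, BIO_LABELS)
int_to_labels <- function(ints) BIO_LABELS[ints]

# Index string features against a vocabulary; unknown features are dropped.
index_features <- function(feature_strings, vocab) {
  lapply(feature_strings, function(f) {
    idx <- match(f, vocab)
    idx[!is.na(idx)]
  })
}

# swap @-k and @+k positional prefixes in feature identifier strings
mirror_conjunction_prefixes <- function(feats) {
  swapped <- gsub("^@-", "@\001", feats)
  swapped <- gsub("^@\\+", "@-", swapped)
  gsub("^@\001", "@+", swapped)
}

#' Re-encode a feature/label sequence for a parsing direction
#'
#' Forward parsing is the identity.  Backward parsing reverses the token
#' order, mirrors the positional conjunction prefixes (`@-k` <-> `@+k`,
#' the left neighbor in reading order), and re-encodes the labels so that
#' each mention's first token in the reversed reading order carries `B`
#' (reversed verbatim labels would violate the BIO grammar).  Applying the
#' backward encoding twice restores the original sequence.
#'
#' @param features List of per-token feature string vectors.
#' @param labels Character BIO labels (may be `NULL` at decode time).
#' @param direction `"forward"` or `"backward"`.
#' @return List with re-encoded `features` and `labels`.
#' @export
encode_direction <- function(features, labels = NULL,
                             direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    return(list(features = features, labels = labels))
  }
  n <- length(features)
  rev_feats <- lapply(rev(features), mirror_conjunction_prefixes)
  rev_labels <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    rev_labels <- rep("O", n)
    spans <- bio_spans(labels)
    for (sp in spans) {
      rs <- n + 1L - sp[2L]
      re <- n + 1L - sp[1L]
      rev_labels[rs] <- "B"
      if (re > rs) rev_labels[(rs + 1L):re] <- "I"
    }
  }
  list(features = rev_feats, labels = rev_labels)
}

# mention spans (start, end token indices) of a BIO sequence, orphan-I healed
bio_spans <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(list())
  prev <- c("O", labels[-n])
  labels[labels == "I" & prev == "O"] <- "B"
  spans <- list()
  i <- 1L
  while (i <= n) {
    if (labels[i] == "B") {
      j <- i
      while (j < n && labels[j + 1L] == "I") j <- j + 1L
      spans[[length(spans) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  spans
}

#' Train a second-order linear-chain CRF
#'
#' Maximizes the L2-regularized conditional log-likelihood of the BIO
#' label sequences by batch L-BFGS.  The parameterization uses
#' (feature, label) state weights plus label-trigram transition weights
#' (with a begin-of-sentence context); single-token sentences contribute
#' state terms only.  Training is deterministic for a fixed input order.
#'
#' @param sequences List of training sequences; each is a list with
#'   `features` (list of per-token feature string vectors) and `labels`
#'   (character BIO vector).
#' @param direction `"forward"` or `"backward"`; backward sequences are
#'   re-encoded via [encode_direction()].
#' @param lambda L2 regularization strength (default 1).
#' @param maxit Maximum L-BFGS iterations.
#' @param vocab Optional fixed feature vocabulary; defaults to all features
#'   observed in `sequences` (after direction encoding).
#' @return A `bt_crf` model.
#' @export
train_crf <- function(sequences, direction = c("forward", "backward"),
                      lambda = 1.0, maxit = 200L, vocab = NULL) {
  direction <- match.arg(direction)
  if (length(sequences) == 0L) stop("empty training set")
  enc <- lapply(sequences, function(s) {
    encode_direction(s$features, s$labels, direction)
  })
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(lapply(enc, function(s) unlist(s$features)))))
  }
  feats_idx <- lapply(enc, function(s) index_features(s$features, vocab))
  labels_int <- lapply(enc, function(s) labels_to_int(s$labels))
  keep <- vapply(feats_idx, length, integer(1)) > 0L
  feats_idx <- feats_idx[keep]
  labels_int <- labels_int[keep]
  if (length(feats_idx) == 0L) stop("no non-empty training sequences")

  nfeat <- length(vocab)
  npar <- nfeat * 3L + N_TRANS
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    W <- matrix(par[seq_len(nfeat * 3L)], nrow = nfeat, ncol = 3L)
    Tr <- par[nfeat * 3L + seq_len(N_TRANS)]
    res <- .crf_corpus_nll_grad(feats_idx, labels_int, W, Tr)
    val <- list(
      nll = res$nll + 0.5 * lambda * sum(par^2),
      grad = c(as.numeric(res$gradW), res$gradTr) + lambda * par
    )
    cache$par <- par
    cache$val <- val
    val
  }
  par0 <- numeric(npar)
  nll0 <- evaluate(par0)$nll
  opt <- stats::optim(par0,
                      fn = function(p) evaluate(p)$nll,
                      gr = function(p) evaluate(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  W <- matrix(opt$par[seq_len(nfeat * 3L)], nrow = nfeat, ncol = 3L,
              dimnames = list(vocab, BIO_LABELS))
  Tr <- opt$par[nfeat * 3L + seq_len(N_TRANS)]
  model <- new_crf_model(vocab, W, Tr, direction)
  model$nll_initial <- nll0
  model$nll_final <- opt$value
  model$lambda <- lambda
  model$convergence <- opt$convergence
  model
}

#' Viterbi decoding
#'
#' Returns the highest-scoring BIO label sequence under the model's
#' second-order dynamics; ties are broken deterministically toward the
#' fixed label order B < I < O.
#'
#' @param model A `bt_crf` (or combined) model.
#' @param features List of per-token feature string vectors in the model's
#'   own orientation.
#' @return Character vector of BIO labels (empty for an empty sentence).
#' @export
viterbi <- function(model, features) {
  if (length(features) == 0L) return(character())
  idx <- index_features(features, model$vocab)
  int_to_labels(.crf_viterbi(idx, model$W, model$Tr))
}

#' Log-partition function log Z(B)
#'
#' Computed by the forward recursion over second-order label contexts in
#' log space.
#'
#' @inheritParams viterbi
#' @return The log normalizer of the conditional distribution.
#' @export
log_partition <- function(model, features) {
  if (length(features) == 0L) return(0.0)
  idx <- index_features(features, model$vocab)
  .crf_logZ(idx, model$W, model$Tr)
}

#' Unnormalized score of a label sequence
#'
#' Sum of state weights for the active (feature, label) pairs plus the
#' trigram transition weights along the sequence; single-token sentences
#' use state terms only.
#'
#' @inheritParams viterbi
#' @param labels Character BIO labels, same length as `features`.
#' @return Numeric score.
#' @export
sequence_score <- function(model, features, labels) {
  stopifnot(length(features) == length(labels))
  n <- length(features)
  if (n == 0L) return(0.0)
  idx <- index_features(features, model$vocab)
  y <- labels_to_int(labels)
  sc <- 0.0
  for (i in seq_len(n)) {
    if (length(idx[[i]]) > 0L) sc <- sc + sum(model$W[idx[[i]], y[i]])
  }
  if (n >= 2L) {
    sc <- sc + model$Tr[tri_index(4L, 4L, y[1L])]
    for (i in 2:n) {
      a <- if (i >= 3L) y[i - 2L] else 4L
      sc <- sc + model$Tr[tri_index(a, y[i - 1L], y[i])]
    }
  }
  sc
}

# 1-based flat index into the 4 x 4 x 3 trigram array (a, b in 1..4 with
# 4 = BOS context; c in 1..3)
tri_index <- function(a, b, c) {
  (a - 1L) * 12L + (b - 1L) * 3L + c
}

#' Conditional probability of a label sequence
#'
#' @inheritParams sequence_score
#' @return `exp(score - logZ)`, a probability in `[0, 1]`.
#' @export
sequence_probability <- function(model, features, labels) {
  exp(sequence_score(model, features, labels) - log_partition(model, features))
}

#' Serialize a CRF or combined model to a text (JSON) dump
#'
#' The dump records direction, order, labels, feature vocabulary and all
#' weights at full precision; [read_crf_model()] restores it bit-exactly.
#'
#' @param model A `bt_crf` model.
#' @param path Output path.
#' @export
write_crf_model <- function(model, path) {
  payload <- list(
    direction = model$direction,
    order = model$order,
    labels = model$labels,
    vocab = model$vocab,
    # %.17g guarantees an exact IEEE-754 round trip through text
    W = sprintf("%.17g", as.numeric(model$W)),
    Tr = sprintf("%.17g", as.numeric(model$Tr)),
    lambda = model$lambda,
    mira_epochs = model$mira_epochs,
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a model written by [write_crf_model()]
#' @param path Path to the JSON dump.
#' @return A `bt_crf` model.
#' @export
read_crf_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- as.character(p$vocab)
  W <- matrix(as.numeric(p$W), nrow = length(vocab), ncol = 3L,
              dimnames = list(vocab, BIO_LABELS))
  m <- new_crf_model(vocab, W, as.numeric(p$Tr), p$direction)
  m$lambda <- p$lambda
  if (!is.null(p$mira_epochs)) m$mira_epochs <- p$mira_epochs
  if (!is.null(p$provenance)) m$provenance <- as.character(p$provenance)
  m
}
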