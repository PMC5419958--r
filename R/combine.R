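mention_key <- function(m) {
  paste(m$sentence_id, m$start, m$end, sep = "\r")
}

#' Union of two mention sets
#'
#' Set union by exact span `(sentence_id, start, end)`.  Unioning the
#' outputs of the forward and backward taggers trades precision for
#' recall.
#'
#' @param a,b Mention data.frames.
#' @return Mention data.frame.
#' @export
union_mentions <- function(a, b) {
  out <- rbind(a, b)
  out <- out[!duplicated(mention_key(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection of two mention sets
#'
#' Exact-span set intersection; keeps only mentions proposed by both
#' models, trading recall for precision.
#'
#' @inheritParams union_mentions
#' @return Mention data.frame.
#' @export
intersect_mentions <- function(a, b) {
  out <- a[mention_key(a) %in% mention_key(b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mirror a model's weights between reading orientations: state weights are
# direction-invariant (modulo conjunction-prefix mirroring of their feature
# names); in-sentence transition trigrams reverse, (a,b,c) -> (c,b,a);
# boundary-context trigrams (BOS in the conditioning labels) stay boundary
# weights.  An involution.
mirror_weights <- function(model) {
  vocab2 <- mirror_conjunction_prefixes(model$vocab)
  ord <- order(vocab2)
  W2 <- model$W[ord, , drop = FALSE]
  vocab2 <- vocab2[ord]
  rownames(W2) <- vocab2
  Tr2 <- model$Tr
  for (a in 1:3) for (b in 1:3) for (c in 1:3) {
    Tr2[tri_index(a, b, c)] <- model$Tr[tri_index(c, b, a)]
  }
  out <- new_crf_model(vocab2, W2, Tr2,
                       if (model$direction == "backward") "forward"
                       else "backward")
  out$lambda <- model$lambda
  out
}

#' Map a backward model's weights into the forward orientation
#'
#' State feature weights carry over unchanged (with positional conjunction
#' prefixes mirrored, `@-k` <-> `@+k`); transition trigram contexts are
#' reversed (`(a,b,c)` becomes `(c,b,a)`).  Required before summing the
#' two directional models into one weight vector.
#'
#' @param model A `bt_crf` with `direction == "backward"`.
#' @return A forward-oriented `bt_crf`.
#' @export
map_backward_weights <- function(model) {
  if (!identical(model$direction, "backward")) {
    stop("map_backward_weights() expects a backward-direction model")
  }
  mirror_weights(model)
}

# omega0: forward weights + mapped backward weights over the union space
sum_models <- function(forward, backward_mapped) {
  vocab <- sort(unique(c(forward$vocab, backward_mapped$vocab)))
  W <- matrix(0, nrow = length(vocab), ncol = 3L,
              dimnames = list(vocab, BIO_LABELS))
  W[forward$vocab, ] <- W[forward$vocab, ] + forward$W
  W[backward_mapped$vocab, ] <- W[backward_mapped$vocab, ] +
    backward_mapped$W
  Tr <- forward$Tr + backward_mapped$Tr
  new_crf_model(vocab, W, Tr, "combined")
}

#' Global feature vector of a label sequence
#'
#' Counts, over the whole sentence, every active (feature, label) state
#' pair and every transition trigram of a candidate label sequence — the
#' sufficient statistics whose inner product with the weight vector is the
#' sequence score.
#'
#' @param model Model providing the feature vocabulary.
#' @param features Per-token feature string vectors.
#' @param labels Candidate BIO labels.
#' @return List with `state` (named count vector keyed by flat state-weight
#'   index) and `trans` (length-48 trigram count vector).
#' @export
global_feature_vector <- function(model, features, labels) {
  n <- length(features)
  stopifnot(length(labels) == n)
  nfeat <- length(model$vocab)
  idx <- index_features(features, model$vocab)
  y <- labels_to_int(labels)
  keys <- integer()
  for (i in seq_len(n)) {
    if (length(idx[[i]]) > 0L) {
      # column-major flat index into W
      keys <- c(keys, idx[[i]] + (y[i] - 1L) * nfeat)
    }
  }
  state <- if (length(keys)) {
    tab <- table(keys)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    stats::setNames(numeric(), character())
  }
  trans <- numeric(N_TRANS)
  if (n >= 2L) {
    k <- tri_index(4L, 4L, y[1L])
    trans[k] <- trans[k] + 1
    for (i in 2:n) {
      a <- if (i >= 3L) y[i - 2L] else 4L
      k <- tri_index(a, y[i - 1L], y[i])
      trans[k] <- trans[k] + 1
    }
  }
  list(state = state, trans = trans)
}

# sparse difference of two global feature vectors
gfv_diff <- function(phi_y, phi_yhat) {
  keys <- union(names(phi_y$state), names(phi_yhat$state))
  d <- stats::setNames(numeric(length(keys)), keys)
  d[names(phi_y$state)] <- phi_y$state
  d[names(phi_yhat$state)] <- d[names(phi_yhat$state)] - phi_yhat$state
  d <- d[d != 0]
  list(state = d, trans = phi_y$trans - phi_yhat$trans)
}

#' Combine forward and backward CRFs with MIRA refinement
#'
#' Initializes a single forward-oriented weight vector as the sum of the
#' forward weights and the mapped backward weights, then refines it with
#' single-best MIRA passes over the training data: each sentence is
#' decoded; a correct decode triggers no update; otherwise the minimal
#' weight change is applied that scores the gold sequence above the
#' prediction by at least the Hamming label loss,
#' `tau = max(0, (L - margin) / ||dPhi||^2)`, `omega <- omega + tau * dPhi`.
#'
#' @param forward Forward-direction `bt_crf`.
#' @param backward Backward-direction `bt_crf`.
#' @param sequences Training sequences in forward orientation (as for
#'   [train_crf()]).
#' @param epochs Number of passes over the training data (default 5);
#'   instances are visited in corpus order, unshuffled, so the result is
#'   deterministic.
#' @return A combined `bt_crf` (direction `"combined"`) with
#'   `mira_epochs`, `provenance` and per-epoch update counts attached.
#' @export
mira_combine <- function(forward, backward, sequences, epochs = 5L) {
  stopifnot(identical(forward$direction, "forward"))
  omega <- sum_models(forward, map_backward_weights(backward))
  nfeat <- length(omega$vocab)
  updates <- integer(epochs)
  for (ep in seq_len(epochs)) {
    for (s in sequences) {
      y <- s$labels
      if (length(y) == 0L) next
      yhat <- viterbi(omega, s$features)
      if (identical(yhat, y)) next
      phi_y <- global_feature_vector(omega, s$features, y)
      phi_yhat <- global_feature_vector(omega, s$features, yhat)
      d <- gfv_diff(phi_y, phi_yhat)
      nrm2 <- sum(d$state^2) + sum(d$trans^2)
      if (nrm2 == 0) {
        warning("MIRA: identical feature vectors for differing sequences; skipping")
        next
      }
      loss <- sum(y != yhat)
      margin <- mira_score(omega, d)
      tau <- max(0, (loss - margin) / nrm2)
      if (tau > 0) {
        keys <- as.integer(names(d$state))
        omega$W[keys] <- omega$W[keys] + tau * d$state
        omega$Tr <- omega$Tr + tau * d$trans
        updates[ep] <- updates[ep] + 1L
      }
    }
  }
  omega$mira_epochs <- as.integer(epochs)
  omega$mira_updates <- updates
  omega$provenance <- c(forward = "forward", backward = "backward")
  omega
}

# inner product of omega with a sparse feature-vector difference:
# score(x, y) - score(x, yhat)
mira_score <- function(omega, d) {
  keys <- as.integer(names(d$state))
  sum(omega$W[keys] * d$state) + sum(omega$Tr * d$trans)
}
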