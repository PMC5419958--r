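test_that("direction encoding reverses tokens and re-heads mentions", {
  feats <- lapply(c("a", "b", "c", "d"), function(w) paste0("W=", w))
  enc <- encode_direction(feats, c("O", "B", "I", "O"), "backward")
  expect_equal(enc$labels, c("O", "B", "I", "O"))
  expect_equal(enc$features[[1]], "W=d")

  enc2 <- encode_direction(feats, rep("O", 4), "backward")
  expect_equal(enc2$labels, rep("O", 4))

  # involution, including conjunction-prefix mirroring
  feats3 <- list(c("W=a", "@-1:INITCAPS"), c("W=b", "@+2:HASDIGIT"))
  labs3 <- c("B", "I")
  once <- encode_direction(feats3, labs3, "backward")
  expect_equal(once$features[[2]], c("W=a", "@+1:INITCAPS"))
  twice <- encode_direction(once$features, once$labels, "backward")
  expect_identical(twice$features, feats3)
  expect_identical(twice$labels, labs3)

  # forward encoding is the identity
  fwd <- encode_direction(feats3, labs3, "forward")
  expect_identical(fwd$features, feats3)
})

test_that("the analytic gradient matches finite differences", {
  set.seed(71)
  vocab <- sprintf("f%d", 1:4)
  feats <- list(list(1:2, 2:3, c(1L, 4L)), list(2L, c(3L, 4L)))
  labels <- list(c(1L, 2L, 3L), c(3L, 1L))
  par <- stats::rnorm(4 * 3 + 48) * 0.5
  obj <- function(p) {
    W <- matrix(p[1:12], 4, 3)
    Tr <- p[13:60]
    bitagger:::.crf_corpus_nll_grad(feats, labels, W, Tr)$nll
  }
  res <- bitagger:::.crf_corpus_nll_grad(
    feats, labels, matrix(par[1:12], 4, 3), par[13:60])
  grad <- c(as.numeric(res$gradW), res$gradTr)
  eps <- 1e-6
  num <- vapply(seq_along(par), function(k) {
    pp <- par; pp[k] <- pp[k] + eps
    pm <- par; pm[k] <- pm[k] - eps
    (obj(pp) - obj(pm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(grad - num)), 1e-5)
})

test_that("training separates a toy language and reduces the objective", {
  set.seed(3)
  seqs <- separable_sequences(8L, 6L)
  model <- train_crf(seqs, "forward", lambda = 0.01, maxit = 100L)
  for (s in seqs) {
    expect_equal(viterbi(model, s$features), s$labels)
  }
  expect_lt(model$nll_final, model$nll_initial)
})

test_that("plain gradient descent on the objective is monotone", {
  set.seed(9)
  seqs <- separable_sequences(4L, 5L)
  vocab <- sort(unique(unlist(lapply(seqs, function(s) unlist(s$features)))))
  feats_idx <- lapply(seqs, function(s)
    bitagger:::index_features(s$features, vocab))
  labels_int <- lapply(seqs, function(s) match(s$labels, c("B", "I", "O")))
  nfeat <- length(vocab)
  par <- numeric(nfeat * 3 + 48)
  lambda <- 1.0
  value <- function(p) {
    r <- bitagger:::.crf_corpus_nll_grad(
      feats_idx, labels_int, matrix(p[1:(nfeat * 3)], nfeat, 3),
      p[nfeat * 3 + 1:48])
    list(nll = r$nll + 0.5 * lambda * sum(p^2),
         grad = c(as.numeric(r$gradW), r$gradTr) + lambda * p)
  }
  vals <- numeric(15)
  cur <- value(par)
  for (it in 1:15) {
    step <- 0.5
    repeat {  # backtracking line search
      cand <- par - step * cur$grad
      nxt <- value(cand)
      if (nxt$nll <= cur$nll || step < 1e-8) break
      step <- step / 2
    }
    par <- cand
    cur <- nxt
    vals[it] <- cur$nll
  }
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("training is deterministic and rejects empty input", {
  set.seed(4)
  seqs <- separable_sequences(5L, 5L)
  m1 <- train_crf(seqs, "forward", lambda = 0.1, maxit = 50L)
  m2 <- train_crf(seqs, "forward", lambda = 0.1, maxit = 50L)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$Tr, m2$Tr)
  expect_error(train_crf(list(), "forward"), "empty")
})

test_that("viterbi equals exhaustive enumeration and respects constraints", {
  set.seed(17)
  for (rep in 1:100) {
    model <- random_model(sample(3:6, 1))
    n <- sample(1:5, 1)
    feats <- random_features(model, n)
    bf <- brute_force_crf(model, feats)
    expect_equal(viterbi(model, feats), bf$argmax)
    expect_lt(abs(log_partition(model, feats) - bf$logZ), 1e-8)
  }
  # single token with state weights favoring O
  model <- random_model(2L)
  model$W[, ] <- 0
  model$W[1, "O"] <- 5
  expect_equal(viterbi(model, list("f01")), "O")
  expect_equal(viterbi(model, list()), character())

  # a huge penalty on I-after-O (and initial I) bans the bigram
  set.seed(18)
  for (rep in 1:20) {
    model <- random_model(4L)
    for (a in 1:4) model$Tr[bitagger:::tri_index(a, 3L, 2L)] <- -1e6
    model$Tr[bitagger:::tri_index(4L, 4L, 2L)] <- -1e6
    out <- paste(viterbi(model, random_features(model, 5L)), collapse = "")
    expect_false(grepl("OI", out))
    expect_false(startsWith(out, "I"))
  }
})

test_that("the conditional distribution normalizes and favors the viterbi path", {
  set.seed(19)
  model <- random_model(5L)
  for (n in 1:5) {
    feats <- random_features(model, n)
    bf <- brute_force_crf(model, feats)
    probs <- exp(bf$scores - log_partition(model, feats))
    expect_equal(sum(probs), 1, tolerance = 1e-10)
    vp <- sequence_probability(model, feats, viterbi(model, feats))
    for (rep in 1:100) {
      alt <- sample(c("B", "I", "O"), n, replace = TRUE)
      expect_gte(vp, sequence_probability(model, feats, alt))
    }
  }
  # single-token closed form: log-sum-exp of the three state scores
  feats1 <- random_features(model, 1L)
  idx <- match(feats1[[1]], model$vocab)
  expect_equal(log_partition(model, feats1),
               log(sum(exp(colSums(model$W[idx, , drop = FALSE])))),
               tolerance = 1e-12)
})

test_that("adding a constant to one position's state scores shifts logZ by it", {
  set.seed(20)
  model <- random_model(6L)
  # disjoint features per position so the shift hits one position only
  feats <- list("f01", "f02", "f03")
  base <- log_partition(model, feats)
  shifted <- model
  shifted$W["f02", ] <- shifted$W["f02", ] + 1.75
  expect_equal(log_partition(shifted, feats), base + 1.75,
               tolerance = 1e-10)
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(21)
  model <- train_crf(separable_sequences(3L, 4L), "backward",
                     lambda = 0.5, maxit = 30L)
  f <- withr::local_tempfile(fileext = ".json")
  write_crf_model(model, f)
  back <- read_crf_model(f)
  expect_identical(back$W, model$W)
  expect_identical(back$Tr, model$Tr)
  expect_identical(back$vocab, model$vocab)
  expect_identical(back$direction, "backward")
  expect_identical(back$order, 2L)
})
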