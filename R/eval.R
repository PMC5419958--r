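#' Match predicted against gold mentions
#'
#' Exact-span matching on non-space offsets.  A prediction is a true
#' positive when it matches a gold span or, if an alternates table is
#' supplied, any acceptable alternate span of a gold mention; each gold
#' mention is credited at most once, and each prediction consumed at most
#' once.
#'
#' @param gold Gold mention data.frame.
#' @param predicted Predicted mention data.frame.
#' @param alternates Optional data.frame of acceptable alternate spans in
#'   the same format; an alternate belongs to whichever gold mention of
#'   the same sentence its span overlaps (BC2GM ALTGENE convention:
#'   alternates are listed per sentence).
#' @return Named integer vector `c(TP, FP, FN)`.
#' @export
match_mentions <- function(gold, predicted, alternates = NULL) {
  gold_keys <- mention_key(gold)
  pred_keys <- mention_key(predicted)
  gold_used <- rep(FALSE, nrow(gold))
  pred_used <- rep(FALSE, nrow(predicted))

  # exact matches first
  for (g in seq_len(nrow(gold))) {
    hit <- which(!pred_used & pred_keys == gold_keys[g])
    if (length(hit) > 0L) {
      gold_used[g] <- TRUE
      pred_used[hit[1L]] <- TRUE
    }
  }
  # alternate-span credit for still-unmatched gold mentions
  if (!is.null(alternates) && nrow(alternates) > 0L &&
      any(!gold_used) && any(!pred_used)) {
    alt_keys <- mention_key(alternates)
    for (g in which(!gold_used)) {
      alts <- which(alternates$sentence_id == gold$sentence_id[g] &
                    alternates$start <= gold$end[g] &
                    alternates$end >= gold$start[g])
      if (length(alts) == 0L) next
      hit <- which(!pred_used & pred_keys %in% alt_keys[alts])
      if (length(hit) > 0L) {
        gold_used[g] <- TRUE
        pred_used[hit[1L]] <- TRUE
      }
    }
  }
  c(TP = sum(gold_used), FP = sum(!pred_used), FN = sum(!gold_used))
}

#' Precision, recall and F-score from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`, each defined as 0
#' when its denominator is 0.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return Named numeric vector `c(precision, recall, f_score)`.
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_score = f)
}

#' Evaluate predicted mentions against gold
#'
#' @inheritParams match_mentions
#' @return A `bt_eval` list with TP/FP/FN and precision/recall/F-score,
#'   plus a per-sentence breakdown.
#' @export
evaluate_mentions <- function(gold, predicted, alternates = NULL) {
  counts <- match_mentions(gold, predicted, alternates)
  scores <- prf(counts[["TP"]], counts[["FP"]], counts[["FN"]])
  sids <- sort(unique(c(gold$sentence_id, predicted$sentence_id)))
  per_sentence <- do.call(rbind, lapply(sids, function(sid) {
    ct <- match_mentions(gold[gold$sentence_id == sid, , drop = FALSE],
                         predicted[predicted$sentence_id == sid, ,
                                   drop = FALSE],
                         alternates)
    sc <- prf(ct[["TP"]], ct[["FP"]], ct[["FN"]])
    data.frame(sentence_id = sid, TP = ct[["TP"]], FP = ct[["FP"]],
               FN = ct[["FN"]], precision = sc[["precision"]],
               recall = sc[["recall"]], f_score = sc[["f_score"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(TP = counts[["TP"]], FP = counts[["FP"]],
                 FN = counts[["FN"]],
                 precision = scores[["precision"]],
                 recall = scores[["recall"]],
                 f_score = scores[["f_score"]],
                 per_sentence = per_sentence),
            class = "bt_eval")
}

#' @export
print.bt_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$TP, x$FP, x$FN))
  cat(sprintf("precision %.4f  recall %.4f  F-score %.4f\n",
              x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Write an evaluation report
#'
#' Plain-text summary plus a tab-delimited per-sentence table.
#'
#' @param result A `bt_eval` from [evaluate_mentions()].
#' @param path Output path for the plain-text report; the per-sentence
#'   table goes to `<path>.tsv`.
#' @export
write_eval_report <- function(result, path) {
  lines <- c(
    sprintf("TP\t%d", result$TP),
    sprintf("FP\t%d", result$FP),
    sprintf("FN\t%d", result$FN),
    sprintf("precision\t%.6f", result$precision),
    sprintf("recall\t%.6f", result$recall),
    sprintf("f_score\t%.6f", result$f_score)
  )
  writeLines(lines, path)
  utils::write.table(result$per_sentence, paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
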