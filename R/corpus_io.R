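#' Read a BioCreative II GM style sentence file
#'
#' Each non-blank line holds a whitespace-free sentence identifier, a single
#' space, and the raw sentence text.  Sentence order is preserved.
#'
#' @param path Path to the sentence file (UTF-8).
#' @return A data.frame with columns `sentence_id` and `text`.
#' @export
read_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(sentence_id = character(), text = character(),
                      stringsAsFactors = FALSE))
  }
  sep <- regexpr(" ", lines, fixed = TRUE)
  bad <- which(sep < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("sentence file '%s': line %d has no id/text separator",
                 path, which(keep)[bad[1L]]))
  }
  data.frame(
    sentence_id = substr(lines, 1L, sep - 1L),
    text        = substring(lines, sep + 1L),
    stringsAsFactors = FALSE
  )
}

#' Write a sentence file
#'
#' @param sentences data.frame with `sentence_id` and `text` columns.
#' @param path Output path.
#' @export
write_sentences <- function(sentences, path) {
  writeLines(paste(sentences$sentence_id, sentences$text), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a GENE/ALTGENE style annotation file
#'
#' Lines have the form `id|start end|text`; `start` and `end` are 0-based
#' inclusive indices into the sentence's non-whitespace characters.
#'
#' @param path Path to the annotation file.
#' @return A data.frame with columns `sentence_id`, `start`, `end`, `text`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_mentions())
  p1 <- regexpr("|", lines, fixed = TRUE)
  if (any(p1 < 0L)) {
    stop(sprintf("annotation file '%s': line %d lacks '|' separators",
                 path, which(p1 < 0L)[1L]))
  }
  rest <- substring(lines, p1 + 1L)
  p2 <- regexpr("|", rest, fixed = TRUE)
  if (any(p2 < 0L)) {
    stop(sprintf("annotation file '%s': line %d lacks a second '|'",
                 path, which(p2 < 0L)[1L]))
  }
  span <- substr(rest, 1L, p2 - 1L)
  se <- strsplit(trimws(span), "[[:space:]]+")
  if (any(lengths(se) != 2L)) {
    stop(sprintf("annotation file '%s': line %d span is not 'start end'",
                 path, which(lengths(se) != 2L)[1L]))
  }
  se <- do.call(rbind, se)
  start <- suppressWarnings(as.integer(se[, 1L]))
  end   <- suppressWarnings(as.integer(se[, 2L]))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("annotation file '%s': non-integer offsets (line %d)",
                 path, which(is.na(start) | is.na(end))[1L]))
  }
  if (any(start < 0L) || any(start > end)) {
    stop(sprintf("annotation file '%s': invalid span start > end (line %d)",
                 path, which(start < 0L | start > end)[1L]))
  }
  data.frame(
    sentence_id = substr(lines, 1L, p1 - 1L),
    start = start,
    end = end,
    text = substring(rest, p2 + 1L),
    stringsAsFactors = FALSE
  )
}

#' Write an annotation file
#'
#' Inverse of [read_annotations()]: writes `id|start end|text` lines.
#'
#' @param mentions data.frame with `sentence_id`, `start`, `end`, `text`.
#' @param path Output path.
#' @export
write_annotations <- function(mentions, path) {
  writeLines(sprintf("%s|%d %d|%s", mentions$sentence_id,
                     mentions$start, mentions$end, mentions$text),
             path, useBytes = TRUE)
  invisible(path)
}

empty_mentions <- function() {
  data.frame(sentence_id = character(), start = integer(), end = integer(),
             text = character(), stringsAsFactors = FALSE)
}

#' Map between raw and non-space character positions
#'
#' BC2GM annotation offsets count only non-whitespace characters.  This
#' builds the bijection between the two coordinate systems for one string.
#' All positions are 0-based.
#'
#' @param text A single string.
#' @return A list with `ns_to_raw` (integer vector: element `k + 1` is the
#'   raw position of non-space character `k`) and `raw_to_ns` (integer
#'   vector over raw positions, `NA` at whitespace).
#' @export
nonspace_index_map <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) {
    return(list(ns_to_raw = integer(), raw_to_ns = integer()))
  }
  is_ns <- !grepl("[[:space:]]", chars)
  raw_to_ns <- rep(NA_integer_, length(chars))
  raw_to_ns[is_ns] <- seq_len(sum(is_ns)) - 1L
  list(ns_to_raw = which(is_ns) - 1L, raw_to_ns = raw_to_ns)
}

#' Convert mention spans to a BIO label sequence
#'
#' The first token of each mention is labeled `B`, later tokens `I`, and all
#' remaining tokens `O`.  Mentions must start and end exactly on token
#' boundaries of `sentence`.
#'
#' @param sentence A tokenized sentence (see [tokenize()]).
#' @param mentions data.frame of mentions; rows whose `sentence_id` differs
#'   from the sentence's are ignored.
#' @return Character vector of labels, one of `"B"`, `"I"`, `"O"` per token.
#' @export
mentions_to_bio <- function(sentence, mentions) {
  stopifnot(inherits(sentence, "bt_tokens"))
  tok <- sentence$tokens
  labels <- rep("O", nrow(tok))
  if (is.null(mentions) || nrow(mentions) == 0L) return(labels)
  mentions <- mentions[mentions$sentence_id == sentence$sentence_id, ,
                       drop = FALSE]
  for (r in seq_len(nrow(mentions))) {
    s <- mentions$start[r]
    e <- mentions$end[r]
    first <- which(tok$ns_start == s)
    last  <- which(tok$ns_end == e)
    if (length(first) != 1L || length(last) != 1L || first > last) {
      stop(sprintf(
        "mention '%s' [%d,%d] in sentence %s does not align with token boundaries",
        mentions$text[r], s, e, sentence$sentence_id))
    }
    labels[first] <- "B"
    if (last > first) labels[(first + 1L):last] <- "I"
  }
  labels
}

#' Convert a BIO label sequence back to mention spans
#'
#' Maximal `B I*` runs become mentions.  An orphan `I` (following `O` or at
#' the sentence start) is healed to `B` so every label sequence decodes;
#' rule-based label edits can otherwise leave such orphans behind.
#'
#' @param sentence A tokenized sentence.
#' @param labels Character vector of BIO labels, one per token.
#' @return A mention data.frame (`sentence_id`, `start`, `end`, `text`).
#' @export
bio_to_mentions <- function(sentence, labels) {
  stopifnot(inherits(sentence, "bt_tokens"))
  tok <- sentence$tokens
  if (length(labels) != nrow(tok)) {
    stop(sprintf("sentence %s: %d labels for %d tokens",
                 sentence$sentence_id, length(labels), nrow(tok)))
  }
  if (nrow(tok) == 0L) return(empty_mentions())
  # heal orphan I's, then cut runs
  prev <- c("O", labels[-length(labels)])
  labels[labels == "I" & prev == "O"] <- "B"
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] == "B") {
      j <- i
      while (j < n && labels[j + 1L] == "I") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        sentence_id = sentence$sentence_id,
        start = tok$ns_start[i],
        end = tok$ns_end[j],
        text = substr(sentence$text, tok$raw_start[i] + 1L, tok$raw_end[j]),
        stringsAsFactors = FALSE
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  do.call(rbind, out)
}
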