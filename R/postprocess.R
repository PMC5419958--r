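#' Relation/connective keyword lexicon
#'
#' The contextual-clue rules trigger on interaction ("relation") keywords
#' and on connective words.  The full interaction list is corpus-specific
#' and user-extensible; a seed list of common interaction verbs ships with
#' the package (see `system.file("extdata", "relation_keywords.txt",
#' package = "bitagger")`).
#'
#' @param relation_words Character vector of relation keywords; defaults to
#'   the bundled seed list.
#' @param connective_words Connectives (default `and`, `or`).
#' @return A `bt_lexicon` list with lowercase-normalized word sets.
#' @export
keyword_lexicon <- function(relation_words = NULL,
                            connective_words = c("and", "or")) {
  if (is.null(relation_words)) {
    path <- system.file("extdata", "relation_keywords.txt",
                        package = "bitagger")
    relation_words <- readLines(path, warn = FALSE)
  }
  structure(list(
    relation_words = unique(tolower(trimws(relation_words))),
    connective_words = unique(tolower(trimws(connective_words)))
  ), class = "bt_lexicon")
}

#' Load a keyword lexicon file
#'
#' One keyword per line, UTF-8; used to supply a full interaction-keyword
#' list in place of the bundled seed.
#'
#' @param path File path.
#' @param connective_words Connectives to pair with the loaded relation
#'   words.
#' @return A `bt_lexicon`.
#' @export
read_keyword_lexicon <- function(path, connective_words = c("and", "or")) {
  keyword_lexicon(readLines(path, encoding = "UTF-8", warn = FALSE),
                  connective_words)
}

#' Build the post-keyword list (pkl)
#'
#' Counts gold mention surfaces over the training corpus; surfaces
#' annotated three or more times (configurable) become matchable by the
#' contextual-clue rules.
#'
#' @param mentions Gold mention data.frame.
#' @param min_count Minimum occurrence count for matchability (default 3).
#' @return A `bt_pkl` list with `counts` and the `matchable` surface set.
#' @export
build_pkl <- function(mentions, min_count = 3L) {
  counts <- if (is.null(mentions) || nrow(mentions) == 0L) {
    integer()
  } else {
    tab <- table(mentions$text)
    stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(counts = counts,
                 matchable = names(counts)[counts >= min_count],
                 min_count = as.integer(min_count)),
            class = "bt_pkl")
}

nearest_nonpunct <- function(surfaces, i, step) {
  j <- i + step
  while (j >= 1L && j <= length(surfaces) &&
         grepl("^[[:punct:]]+$", surfaces[j])) {
    j <- j + step
  }
  if (j < 1L || j > length(surfaces)) NA_integer_ else j
}

#' Contextual-clue relabeling around connective and relation keywords
#'
#' Two passes over the sentence: first connective words ("and", "or"),
#' then relation keywords.  For each keyword token, the nearest
#' non-punctuation neighbor on either side is checked against the
#' post-keyword list; a neighbor currently labeled `O` whose surface is
#' matchable becomes a single-token `B` mention.  Existing mentions are
#' never removed.
#'
#' @param sentence A `bt_tokens` object.
#' @param labels BIO labels aligned to the tokens.
#' @param lexicon A [keyword_lexicon()].
#' @param pkl A [build_pkl()] result.
#' @return Updated label vector.
#' @export
apply_contextual_rules <- function(sentence, labels, lexicon, pkl) {
  surfaces <- sentence$tokens$surface
  stopifnot(length(labels) == length(surfaces))
  low <- tolower(surfaces)
  for (wordset in list(lexicon$connective_words, lexicon$relation_words)) {
    hits <- which(low %in% wordset)
    for (i in hits) {
      for (j in c(nearest_nonpunct(surfaces, i, -1L),
                  nearest_nonpunct(surfaces, i, +1L))) {
        if (!is.na(j) && labels[j] == "O" &&
            surfaces[j] %in% pkl$matchable) {
          labels[j] <- "B"
        }
      }
    }
  }
  labels
}

BRACKET_OPEN <- c("(", "[", "{")
BRACKET_CLOSE <- c(")", "]", "}")

# match brackets in a surface vector; returns list(pairs = 2-col matrix of
# open/close indices, unmatched = integer vector)
match_brackets <- function(surfaces) {
  stacks <- list(`(` = integer(), `[` = integer(), `{` = integer())
  pairs <- NULL
  unmatched <- integer()
  for (i in seq_along(surfaces)) {
    s <- surfaces[i]
    if (s %in% BRACKET_OPEN) {
      stacks[[s]] <- c(stacks[[s]], i)
    } else if (s %in% BRACKET_CLOSE) {
      op <- BRACKET_OPEN[match(s, BRACKET_CLOSE)]
      if (length(stacks[[op]]) > 0L) {
        j <- stacks[[op]][length(stacks[[op]])]
        stacks[[op]] <- stacks[[op]][-length(stacks[[op]])]
        pairs <- rbind(pairs, c(j, i))
      } else {
        unmatched <- c(unmatched, i)
      }
    }
  }
  list(pairs = pairs, unmatched = c(unmatched, unlist(stacks)))
}

#' Repair parenthesis mismatches in a BIO labeling
#'
#' A mention should not contain one member of a bracket pair without the
#' other.  For every matched pair, if both members sit inside the same
#' mention the labeling is kept; if exactly one member lies inside a
#' mention (or the two members lie in different mentions, or a bracket has
#' no partner in the sentence), the offending bracket token is ejected:
#' relabeled `O`, with the following token re-headed to `B` when the
#' ejected bracket led the mention.  The repair iterates to a fixed point,
#' so the output never contains a mention with an unbalanced bracket.
#'
#' @inheritParams apply_contextual_rules
#' @return Updated label vector.
#' @export
fix_parentheses <- function(sentence, labels) {
  surfaces <- sentence$tokens$surface
  stopifnot(length(labels) == length(surfaces))
  n <- length(labels)
  repeat {
    spans <- bio_spans(labels)
    run_of <- rep(NA_integer_, n)
    for (k in seq_along(spans)) {
      run_of[spans[[k]][1L]:spans[[k]][2L]] <- k
    }
    mb <- match_brackets(surfaces)
    eject <- integer()
    if (!is.null(mb$pairs)) {
      for (r in seq_len(nrow(mb$pairs))) {
        o <- mb$pairs[r, 1L]
        cl <- mb$pairs[r, 2L]
        ro <- run_of[o]
        rc <- run_of[cl]
        if (is.na(ro) && is.na(rc)) next
        if (!is.na(ro) && !is.na(rc) && ro == rc) next  # balanced in mention
        if (!is.na(ro)) eject <- c(eject, o)
        if (!is.na(rc)) eject <- c(eject, cl)
      }
    }
    for (u in mb$unmatched) {
      if (!is.na(run_of[u])) eject <- c(eject, u)
    }
    if (length(eject) == 0L) break
    for (i in sort(unique(eject))) {
      was_head <- labels[i] == "B"
      labels[i] <- "O"
      if (i < n && labels[i + 1L] == "I") labels[i + 1L] <- "B"
    }
  }
  labels
}

#' Extract long-form/short-form abbreviation pairs from a sentence
#'
#' Finds parenthesized short-form candidates (at most `max_sf_chars`
#' non-space characters, at least one letter) and validates them against
#' the text before the opening parenthesis with the classical
#' right-to-left character pairing test: every short-form character must
#' appear, in order, in the long-form window, and the first character must
#' match the initial character of a word.  The long-form window is capped
#' at `min(|SF| + 5, |SF| * 2)` words.
#'
#' @param sentence A `bt_tokens` object.
#' @param max_sf_chars Maximum short-form length in non-space characters
#'   (default 10).
#' @return A data.frame with one row per pair: token spans
#'   (`sf_start`/`sf_end` for the tokens inside the parentheses,
#'   `lf_start`/`lf_end`), surfaces `short_form` and `long_form`, and
#'   `sentence_id`.
#' @export
extract_abbreviation_pairs <- function(sentence, max_sf_chars = 10L) {
  surfaces <- sentence$tokens$surface
  out <- list()
  mb <- match_brackets(surfaces)
  if (!is.null(mb$pairs)) {
    for (r in seq_len(nrow(mb$pairs))) {
      o <- mb$pairs[r, 1L]
      cl <- mb$pairs[r, 2L]
      if (surfaces[o] != "(" || cl - o < 2L || o == 1L) next
      sf_tokens <- surfaces[(o + 1L):(cl - 1L)]
      sf <- paste(sf_tokens, collapse = " ")
      sf_ns <- gsub("[[:space:]]", "", sf)
      if (nchar(sf_ns) > max_sf_chars || !grepl("[A-Za-z]", sf_ns)) next
      if (!grepl("^[A-Za-z0-9]", sf)) next
      max_words <- min(nchar(sf_ns) + 5L, nchar(sf_ns) * 2L)
      win_start <- max(1L, o - max_words)
      # the long form never crosses another bracket token
      brackets <- which(surfaces %in% c(BRACKET_OPEN, BRACKET_CLOSE))
      brackets <- brackets[brackets >= win_start & brackets < o]
      if (length(brackets) > 0L) win_start <- max(brackets) + 1L
      if (win_start > o - 1L) next
      window <- surfaces[win_start:(o - 1L)]
      lf_str <- paste(window, collapse = " ")
      hit <- find_best_long_form(sf, lf_str)
      if (is.null(hit)) next
      # map the matched suffix of the window string back to tokens
      prefix <- substr(lf_str, 1L, hit$start - 1L)
      n_before <- if (nzchar(trimws(prefix))) {
        length(strsplit(trimws(prefix), "[ ]+")[[1L]])
      } else 0L
      lf_start <- win_start + n_before
      lf_end <- o - 1L
      if (lf_start > lf_end) next
      long_form <- paste(surfaces[lf_start:lf_end], collapse = " ")
      if (toupper(long_form) == toupper(sf)) next
      out[[length(out) + 1L]] <- data.frame(
        sentence_id = sentence$sentence_id,
        sf_start = o + 1L, sf_end = cl - 1L,
        lf_start = lf_start, lf_end = lf_end,
        short_form = sf, long_form = long_form,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sentence_id = character(), sf_start = integer(),
                      sf_end = integer(), lf_start = integer(),
                      lf_end = integer(), short_form = character(),
                      long_form = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Classical right-to-left abbreviation pairing: walk the short form from its
# last alphanumeric character, locating each in the candidate long form from
# the right; the first short-form character must align with the start of a
# word.  Returns the 1-based start position of the long form within lf (the
# match is then trimmed left to the containing word) or NULL.
find_best_long_form <- function(sf, lf) {
  s_chars <- strsplit(tolower(sf), "")[[1L]]
  l_chars <- strsplit(tolower(lf), "")[[1L]]
  si <- length(s_chars)
  li <- length(l_chars)
  while (si >= 1L) {
    ch <- s_chars[si]
    if (!grepl("[a-z0-9]", ch)) {
      si <- si - 1L
      next
    }
    repeat {
      if (li < 1L) return(NULL)
      ok <- l_chars[li] == ch
      if (ok && si == 1L) {
        # first SF char must start a word
        ok <- li == 1L || !grepl("[a-z0-9]", l_chars[li - 1L])
      }
      if (ok) break
      li <- li - 1L
    }
    si <- si - 1L
    li <- li - 1L
  }
  start <- li + 1L
  # trim to the start of the containing word
  while (start > 1L && grepl("[a-z0-9]", l_chars[start - 1L])) {
    start <- start - 1L
  }
  list(start = start)
}

#' Propagate mention labels between abbreviation long and short forms
#'
#' The sequence model frequently tags only one member of an
#' `Long Form (SF)` pair.  For each extracted pair: if the short-form span
#' overlaps a mention while the long-form span carries no `B`/`I`, the
#' long form becomes a `B I...I` mention, and symmetrically for a tagged
#' long form with an untagged short form.  The rule only propagates; it
#' never creates a mention when neither side is tagged, and it never
#' removes one.
#'
#' @inheritParams apply_contextual_rules
#' @param pairs Output of [extract_abbreviation_pairs()] for the same
#'   sentence.
#' @return Updated label vector.
#' @export
propagate_abbreviation_labels <- function(labels, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(labels)
  for (r in seq_len(nrow(pairs))) {
    sf_idx <- pairs$sf_start[r]:pairs$sf_end[r]
    lf_idx <- pairs$lf_start[r]:pairs$lf_end[r]
    sf_tagged <- any(labels[sf_idx] %in% c("B", "I"))
    lf_tagged <- any(labels[lf_idx] %in% c("B", "I"))
    if (sf_tagged && !lf_tagged) {
      labels[lf_idx] <- c("B", rep("I", length(lf_idx) - 1L))
    } else if (lf_tagged && !sf_tagged) {
      labels[sf_idx] <- c("B", rep("I", length(sf_idx) - 1L))
    }
  }
  labels
}

#' Read a sense inventory file
#'
#' Tab-separated, one sense per line:
#' `SF<TAB>sense_id<TAB>long form<TAB>context terms (comma-separated)`.
#'
#' @param path File path.
#' @return A `bt_senses` data.frame.
#' @export
read_sense_inventory <- function(path) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L)) {
    stop("sense inventory lines must have 4 tab-separated fields")
  }
  out <- data.frame(
    sf = vapply(parts, `[[`, "", 1L),
    sense_id = vapply(parts, `[[`, "", 2L),
    long_form = vapply(parts, `[[`, "", 3L),
    context_terms = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bt_senses", class(out))
  out
}

DISAMBIG_STOPWORDS <- c(
  "the", "a", "an", "of", "in", "on", "and", "or", "to", "for", "with",
  "by", "is", "are", "was", "were", "be", "this", "that", "we", "it"
)

#' Disambiguate an ambiguous short form
#'
#' Chooses among the inventory senses of `short_form` by bag-of-words
#' overlap between the sentence context and each sense's context terms
#' (case-insensitive, stop-words removed).  If the sentence itself
#' contains a sense's long form, that sense wins outright.  Ties go to the
#' earlier inventory row.
#'
#' @param short_form The ambiguous abbreviation.
#' @param context Character vector of token surfaces around the short form
#'   (typically the whole sentence).
#' @param inventory A [read_sense_inventory()] data.frame.
#' @return The winning `sense_id`, or `NA_character_` when the short form
#'   is absent from the inventory.
#' @export
disambiguate <- function(short_form, context, inventory) {
  rows <- inventory[inventory$sf == short_form, , drop = FALSE]
  if (nrow(rows) == 0L) return(NA_character_)
  ctx_text <- paste(tolower(context), collapse = " ")
  for (r in seq_len(nrow(rows))) {
    lf <- tolower(trimws(rows$long_form[r]))
    if (nzchar(lf) && grepl(lf, ctx_text, fixed = TRUE)) {
      return(rows$sense_id[r])
    }
  }
  ctx <- setdiff(unique(tolower(context)), DISAMBIG_STOPWORDS)
  overlap <- vapply(seq_len(nrow(rows)), function(r) {
    terms <- tolower(trimws(strsplit(rows$context_terms[r], ",")[[1L]]))
    length(intersect(ctx, terms))
  }, integer(1))
  rows$sense_id[which.max(overlap)]
}

#' Apply the full post-processing pipeline to one sentence
#'
#' Fixed order: contextual keyword rules, then parenthesis repair, then
#' abbreviation label propagation.  (Sense disambiguation via
#' [disambiguate()] selects senses but does not alter labels.)
#'
#' @inheritParams apply_contextual_rules
#' @param config A [pipeline_config()]; rule toggles
#'   `rules_contextual`, `rules_parentheses`, `rules_abbreviation`.
#' @return Updated label vector.
#' @export
postprocess_labels <- function(sentence, labels, lexicon, pkl,
                               config = pipeline_config()) {
  if (isTRUE(config$rules_contextual)) {
    labels <- apply_contextual_rules(sentence, labels, lexicon, pkl)
  }
  if (isTRUE(config$rules_parentheses)) {
    labels <- fix_parentheses(sentence, labels)
  }
  if (isTRUE(config$rules_abbreviation)) {
    pairs <- extract_abbreviation_pairs(sentence,
                                        max_sf_chars = config$max_sf_chars)
    labels <- propagate_abbreviation_labels(labels, pairs)
  }
  labels
}
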