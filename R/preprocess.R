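#' @useDynLib bitagger, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim
#' @importFrom utils head tail
"_PACKAGE"

# Greek-letter lexicon shared by the tokenizer and the feature extractor.
GREEK_WORDS <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
  "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
  "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"
)
GREEK_CHARS <- c(
  "α", "β", "γ", "δ", "ε", "ζ", "η",
  "θ", "ι", "κ", "λ", "μ", "ν", "ξ",
  "ο", "π", "ρ", "σ", "τ", "υ", "φ",
  "χ", "ψ", "ω"
)

SENTENCE_ABBREV_STOPLIST <- c(
  "e.g", "i.e", "etc", "cf", "vs", "al", "fig", "figs", "dr", "prof",
  "no", "st", "ca", "approx"
)

#' Split a document into sentences
#'
#' Splits at sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and an upper-case letter or opening parenthesis, unless the
#' token before the period is on a small abbreviation stop-list
#' (e.g. "e.g.", "Fig.").  Concatenating the returned pieces reproduces the
#' input exactly.
#'
#' @param document A single string.
#' @return Character vector of sentences.
#' @export
split_sentences <- function(document) {
  if (!nzchar(document)) return(character())
  m <- gregexpr("[.!?][])\"']*[ \t\r\n]+[A-Z(]", document, perl = TRUE)[[1L]]
  if (m[1L] < 0L) return(document)
  cuts <- integer()
  for (k in seq_along(m)) {
    pos <- m[k]  # position of the terminator
    # word immediately before the terminator
    before <- sub(".*?([A-Za-z.]*)$", "\\1",
                  substr(document, max(1L, pos - 12L), pos - 1L))
    word <- tolower(sub("\\.+$", "", before))
    if (substr(document, pos, pos) == "." &&
        word %in% SENTENCE_ABBREV_STOPLIST) next
    # cut after the trailing whitespace run
    tail_txt <- substring(document, pos + 1L)
    ws <- regexpr("^[])\"']*[ \t\r\n]+", tail_txt)
    cuts <- c(cuts, pos + attr(ws, "match.length"))
  }
  if (length(cuts) == 0L) return(document)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(document))
  substring(document, starts, ends)
}

# Split one whitespace-delimited chunk into sub-token surfaces.
# Parentheses/brackets, double quotes, commas, semicolons, colons, hyphens
# and slashes are isolated; a trailing period is cut off; apostrophes and
# '+' stay attached (they are token-internal cues).  Slash compounds of two
# alphanumeric halves containing a digit ("P42/44") are kept whole.
split_chunk <- function(chunk) {
  if (grepl("^[A-Za-z0-9]+(/[A-Za-z0-9]+)+$", chunk) && grepl("[0-9]", chunk)) {
    return(chunk)
  }
  s <- gsub("([][(){}<>,;:!?\"=/])", " \\1 ", chunk)
  s <- gsub("-", " - ", s, fixed = TRUE)
  pieces <- strsplit(trimws(s), "[ ]+")[[1L]]
  out <- character()
  for (p in pieces) {
    # peel trailing periods; internal periods ("0.05", "e.g") survive
    peeled <- character()
    while (nchar(p) > 1L && endsWith(p, ".")) {
      p <- substr(p, 1L, nchar(p) - 1L)
      peeled <- c(".", peeled)
    }
    out <- c(out, p, peeled)
  }
  out[nzchar(out)]
}

#' Tokenize a sentence
#'
#' Splits on whitespace, then isolates bracket characters, double quotes,
#' commas, semicolons, colons, slashes, hyphens and trailing periods as
#' their own tokens; digits stay attached to letters ("p53" is one token)
#' and alphanumeric slash compounds with a digit ("P42/44") are kept whole.
#' Hyphenated names therefore span several tokens ("HNF-3" becomes
#' `HNF`, `-`, `3`).
#'
#' @param sentence Either a single string, or a list/one-row data.frame with
#'   `sentence_id` and `text`.
#' @param sentence_id Identifier used when `sentence` is a bare string.
#' @return An object of class `bt_tokens`: list with `sentence_id`, `text`
#'   and a `tokens` data.frame holding `surface`, raw offsets
#'   (`raw_start`/`raw_end`, 0-based half-open), non-space offsets
#'   (`ns_start`/`ns_end`, 0-based inclusive) and `pos`/`lemma`/`chunk`
#'   slots filled by [annotate()].
#' @export
tokenize <- function(sentence, sentence_id = "S0") {
  if (is.character(sentence) && length(sentence) == 1L) {
    text <- sentence
    sid <- sentence_id
  } else {
    text <- sentence$text[[1L]]
    sid <- sentence$sentence_id[[1L]]
  }
  map <- nonspace_index_map(text)
  surfaces <- character()
  raw_start <- integer()
  chunks <- gregexpr("[^[:space:]]+", text)[[1L]]
  if (chunks[1L] > 0L) {
    for (k in seq_along(chunks)) {
      ch_start <- chunks[k]                       # 1-based raw
      ch <- substr(text, ch_start,
                   ch_start + attr(chunks, "match.length")[k] - 1L)
      subs <- split_chunk(ch)
      cursor <- 1L
      for (sb in subs) {
        at <- regexpr(sb, substring(ch, cursor), fixed = TRUE)
        stopifnot(at > 0L)
        surfaces <- c(surfaces, sb)
        raw_start <- c(raw_start, ch_start + cursor + at - 3L)  # 0-based
        cursor <- cursor + at + nchar(sb) - 1L
      }
    }
  }
  n <- length(surfaces)
  raw_end <- raw_start + nchar(surfaces)  # half-open
  ns_start <- if (n) map$raw_to_ns[raw_start + 1L] else integer()
  ns_end <- if (n) map$raw_to_ns[raw_end] else integer()
  structure(list(
    sentence_id = sid,
    text = text,
    tokens = data.frame(
      surface = surfaces,
      raw_start = raw_start, raw_end = raw_end,
      ns_start = ns_start, ns_end = ns_end,
      pos = rep("", n), lemma = rep("", n), chunk = rep("", n),
      stringsAsFactors = FALSE
    )
  ), class = "bt_tokens")
}

#' @export
print.bt_tokens <- function(x, ...) {
  cat(sprintf("<bt_tokens %s: %d tokens>\n", x$sentence_id, nrow(x$tokens)))
  cat(" ", paste(x$tokens$surface, collapse = " "), "\n")
  invisible(x)
}

#' Built-in naive annotation backend
#'
#' Returns a backend function mapping a character vector of token surfaces
#' to a list with equal-length `pos`, `lemma` and `chunk` vectors.  POS uses
#' suffix rules (-ed/-ing/-ate/-ize and friends are verbs) plus small
#' closed-class lists; everything else is a noun (`NNP` when capitalised).
#' Lemmatisation is identity plus plural stripping.  This is deliberately
#' approximate; swap in a real NLP toolchain via the backend contract for
#' serious use.
#'
#' @return A backend function.
#' @export
default_backend <- function() {
  dets <- c("the", "a", "an", "this", "that", "these", "those")
  preps <- c("of", "in", "on", "for", "with", "by", "to", "from", "at",
             "into", "between", "during", "after", "before", "through")
  conj <- c("and", "or", "but", "nor")
  aux <- c("is", "are", "was", "were", "be", "been", "being", "can",
           "could", "may", "might", "will", "would", "shall", "should",
           "do", "does", "did", "have", "has", "had")
  pron <- c("we", "it", "they", "he", "she", "i", "you")
  verb_suffix <- "(ed|ing|ate|ates|ated|ize|izes|ized|ise|ises|ised|yze|yzes|yzed|ify|ifies|ified)$"
  function(surfaces) {
    n <- length(surfaces)
    pos <- character(n)
    lemma <- surfaces
    low <- tolower(surfaces)
    for (i in seq_len(n)) {
      s <- surfaces[i]
      pos[i] <- if (grepl("^[[:punct:]]+$", s)) "PUNCT"
        else if (grepl("^[0-9.]+$", s)) "CD"
        else if (low[i] %in% dets) "DT"
        else if (low[i] %in% preps) "IN"
        else if (low[i] %in% conj) "CC"
        else if (low[i] %in% aux) "VB"
        else if (low[i] %in% pron) "PRP"
        else if (grepl(verb_suffix, low[i]) && nchar(s) > 4L) "VB"
        else if (grepl("^[A-Z]", s)) "NNP"
        else "NN"
      if (pos[i] %in% c("NN", "NNP")) {
        if (grepl("ies$", s) && nchar(s) > 4L) {
          lemma[i] <- sub("ies$", "y", s)
        } else if (grepl("(?<!s)s$", s, perl = TRUE) && nchar(s) > 3L &&
                   !grepl("[0-9]s$", s)) {
          lemma[i] <- sub("s$", "", s)
        }
      }
    }
    chunk <- ifelse(pos %in% c("NN", "NNP", "CD"), "B-NP", "O")
    list(pos = pos, lemma = lemma, chunk = chunk)
  }
}

#' Fill POS, lemma and chunk slots of a tokenized sentence
#'
#' @param sentence A `bt_tokens` object.
#' @param backend A function taking a character vector of surfaces and
#'   returning a list of equal-length `pos`, `lemma`, `chunk` vectors.
#'   Defaults to [default_backend()].
#' @return The sentence with annotation slots filled.
#' @export
annotate <- function(sentence, backend = default_backend()) {
  stopifnot(inherits(sentence, "bt_tokens"))
  n <- nrow(sentence$tokens)
  if (n == 0L) return(sentence)
  ann <- tryCatch(backend(sentence$tokens$surface), error = function(e) {
    stop(sprintf("annotation backend failed on sentence %s: %s",
                 sentence$sentence_id, conditionMessage(e)))
  })
  if (length(ann$pos) != n || length(ann$lemma) != n ||
      length(ann$chunk) != n) {
    stop(sprintf("annotation backend returned wrong lengths for sentence %s",
                 sentence$sentence_id))
  }
  sentence$tokens$pos <- ann$pos
  sentence$tokens$lemma <- ann$lemma
  sentence$tokens$chunk <- ann$chunk
  sentence
}

# Tokenize + annotate a whole sentence data.frame -> list of bt_tokens.
tokenize_corpus <- function(sentences, backend = default_backend()) {
  out <- vector("list", nrow(sentences))
  for (i in seq_len(nrow(sentences))) {
    out[[i]] <- annotate(tokenize(sentences$text[i],
                                  sentences$sentence_id[i]), backend)
  }
  names(out) <- sentences$sentence_id
  out
}
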