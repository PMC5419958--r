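#' The basic feature registry
#'
#' The 32 orthographic, morphologic and affix feature types.  Predicates
#' are pure functions of the token surface and are not mutually exclusive.
#'
#' @return Character vector of the 32 feature type names.
#' @export
feature_registry <- function() {
  c("INITCAPS", "ALLCAPS", "ENDCAPS", "UPPER-LOWER", "TWOCAPS",
    "THREECAPS", "MORECAPS", "MIXEDCAPS", "LOWERCASE", "ENDDIGIT",
    "ALPHANUMERIC", "SINGLECHAR", "NUMBERS_LETTERS", "HASDIGIT", "GREEK",
    "ROMAN", "HAS_QUOTE", "HAS_SLASH", "END_PLUS", "END_QUOTE", "HASDASH",
    "INITDASH", "ENDDASH", "2PREFIX", "3PREFIX", "4PREFIX", "2SUFFIX",
    "3SUFFIX", "4SUFFIX", "HASGREEK", "HASROMAN", "PUNCTUATION")
}

is_greek_word <- function(s) {
  tolower(s) %in% GREEK_WORDS | s %in% GREEK_CHARS
}

is_roman_numeral <- function(s) {
  nzchar(s) &
    grepl("^M{0,3}(CM|CD|D?C{0,3})(XC|XL|L?X{0,3})(IX|IV|V?I{0,3})$", s) &
    grepl("[IVXLCDM]", s)
}

#' Extract the basic orthographic/morphologic/affix features of one token
#'
#' Every registry predicate true of the surface contributes its name;
#' prefix/suffix types contribute value-bearing identifiers such as
#' `3PREFIX=fib`.
#'
#' @param surface Token surface string (or a one-row token data.frame).
#' @return Character vector of feature identifiers.
#' @export
basic_features <- function(surface) {
  if (is.list(surface)) surface <- surface$surface[[1L]]
  s <- surface
  f <- character()
  n_upper <- nchar(gsub("[^A-Z]", "", s))
  has_alpha <- grepl("[A-Za-z]", s)
  alpha_only <- gsub("[^A-Za-z]", "", s)
  if (grepl("^[A-Z]", s) &&
      !(nchar(alpha_only) >= 2L && alpha_only == toupper(alpha_only)) &&
      grepl("[a-z]", s)) f <- c(f, "INITCAPS")
  if (nchar(alpha_only) >= 2L && has_alpha &&
      alpha_only == toupper(alpha_only)) f <- c(f, "ALLCAPS")
  if (grepl("[a-z][A-Z]+$", s)) f <- c(f, "ENDCAPS")
  if (grepl("^[A-Z][a-z]+$", s)) f <- c(f, "UPPER-LOWER")
  if (n_upper == 2L) f <- c(f, "TWOCAPS")
  if (n_upper == 3L) f <- c(f, "THREECAPS")
  if (n_upper >= 4L) f <- c(f, "MORECAPS")
  if (grepl("[A-Z][a-z]", s) && grepl("[a-z][A-Z]", s)) f <- c(f, "MIXEDCAPS")
  if (grepl("^[a-z]+$", s)) f <- c(f, "LOWERCASE")
  if (grepl("[0-9]$", s)) f <- c(f, "ENDDIGIT")
  if (grepl("^[A-Za-z0-9]+$", s) && grepl("[A-Za-z]", s) && grepl("[0-9]", s))
    f <- c(f, "ALPHANUMERIC")
  if (nchar(s) == 1L && grepl("^[A-Za-z]$", s)) f <- c(f, "SINGLECHAR")
  if (grepl("[0-9][A-Za-z]|[A-Za-z][0-9]", s)) f <- c(f, "NUMBERS_LETTERS")
  if (grepl("[0-9]", s)) f <- c(f, "HASDIGIT")
  if (is_greek_word(s)) f <- c(f, "GREEK")
  if (is_roman_numeral(s)) f <- c(f, "ROMAN")
  if (grepl("['’\"`]", s)) f <- c(f, "HAS_QUOTE")
  if (grepl("/", s, fixed = TRUE)) f <- c(f, "HAS_SLASH")
  if (grepl("\\+$", s)) f <- c(f, "END_PLUS")
  if (grepl("['’\"`]$", s)) f <- c(f, "END_QUOTE")
  if (grepl("-", s, fixed = TRUE)) f <- c(f, "HASDASH")
  if (grepl("^-", s)) f <- c(f, "INITDASH")
  if (grepl("-$", s)) f <- c(f, "ENDDASH")
  nc <- nchar(s)
  for (k in 2:4) {
    if (nc >= k) {
      f <- c(f,
             sprintf("%dPREFIX=%s", k, substr(s, 1L, k)),
             sprintf("%dSUFFIX=%s", k, substr(s, nc - k + 1L, nc)))
    }
  }
  parts <- strsplit(s, "[- ]")[[1L]]
  parts <- parts[nzchar(parts)]
  if (any(is_greek_word(parts))) f <- c(f, "HASGREEK")
  if (any(is_roman_numeral(parts))) f <- c(f, "HASROMAN")
  if (grepl("^[[:punct:]]+$", s)) f <- c(f, "PUNCTUATION")
  f
}

#' Character N-gram features of a token
#'
#' All contiguous substrings of `window` characters, emitted as
#' `NGRAM=<substring>`; tokens shorter than the window emit the whole
#' surface once.  Pure-punctuation and single-character tokens emit
#' nothing (noise control).  `mode = "prefixes"` switches to the
#' alternative reading of a window "from the beginning to four
#' characters": prefixes of length 1 to `window`.
#'
#' @param surface Token surface string.
#' @param window Window width (default 4).
#' @param mode `"windows"` (default) or `"prefixes"`.
#' @return Character vector of N-gram feature identifiers.
#' @export
char_ngrams <- function(surface, window = 4L, mode = c("windows", "prefixes")) {
  mode <- match.arg(mode)
  if (is.list(surface)) surface <- surface$surface[[1L]]
  s <- surface
  nc <- nchar(s)
  if (nc < 2L || grepl("^[[:punct:]]+$", s)) return(character())
  if (mode == "prefixes") {
    return(unique(sprintf("NGRAM=%s", substr(rep(s, min(window, nc)),
                                             1L, seq_len(min(window, nc))))))
  }
  if (nc <= window) return(sprintf("NGRAM=%s", s))
  starts <- seq_len(nc - window + 1L)
  unique(sprintf("NGRAM=%s", substring(s, starts, starts + window - 1L)))
}

#' Build the corpus-frequency table from gold mentions
#'
#' Counts how often each mention surface (the full word or word sequence,
#' case-sensitive) is annotated across the training corpus.
#'
#' @param mentions Gold mention data.frame.
#' @param theta_freq Upper count threshold for the frequency feature
#'   (default 10).
#' @return A list with `counts` (named integer vector) and `theta_freq`.
#' @export
build_frequency_table <- function(mentions, theta_freq = 10L) {
  counts <- if (is.null(mentions) || nrow(mentions) == 0L) {
    integer()
  } else {
    tab <- table(mentions$text)
    stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(counts = counts, theta_freq = as.integer(theta_freq)),
            class = "bt_freq_table")
}

#' Corpus frequency of a phrase
#' @param table A frequency table from [build_frequency_table()].
#' @param phrase Phrase to look up.
#' @return Integer count (0 for unseen phrases).
#' @export
corpus_frequency <- function(table, phrase) {
  out <- table$counts[phrase]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Corpus-frequency feature for one token
#'
#' Fires `CORPUS_FREQ` for noun tokens whose surface was annotated as a
#' mention between 1 and `theta_freq` times in the training corpus; rare
#' names thus receive a shared indicator that supports tagging them
#' consistently across sentences.
#'
#' @param surface Token surface.
#' @param pos Token POS tag; only noun tags (`NN*`) qualify.
#' @param table Frequency table.
#' @param invert If `TRUE`, fire for counts above `theta_freq` instead
#'   (the complementary band).
#' @return `"CORPUS_FREQ"` or `character(0)`.
#' @export
corpus_frequency_feature <- function(surface, pos, table, invert = FALSE) {
  if (!startsWith(pos, "NN")) return(character())
  cf <- corpus_frequency(table, surface)
  hit <- if (invert) cf > table$theta_freq
         else cf >= 1L && cf <= table$theta_freq
  if (hit) "CORPUS_FREQ" else character()
}

#' Add offset-conjunction copies of neighboring tokens' basic features
#'
#' The basic features of the tokens at relative offsets -2, -1, +1, +2 are
#' added with positional prefixes (`@-1:INITCAPS`, ...); offsets that fall
#' outside the sentence add a boundary marker instead.
#'
#' @param basic_list List of per-token basic feature vectors for the whole
#'   sentence.
#' @param position Token index (1-based).
#' @param window Conjunction half-width (default 2).
#' @return Character vector of prefixed neighbor features and boundary
#'   markers for `position`.
#' @export
offset_conjunction <- function(basic_list, position, window = 2L) {
  n <- length(basic_list)
  stopifnot(position >= 1L, position <= n)
  out <- character()
  for (d in c(-seq_len(window), seq_len(window))) {
    j <- position + d
    pre <- sprintf("@%+d:", d)
    if (j < 1L || j > n) {
      out <- c(out, paste0(pre, "__EDGE__"))
    } else {
      out <- c(out, paste0(pre, basic_list[[j]]))
    }
  }
  out
}

#' Extract the full feature set for a tokenized sentence
#'
#' Per token: basic registry features, character N-grams, the
#' corpus-frequency feature (when a frequency table is supplied), and
#' offset-conjunction copies of the neighbors' basic features.
#'
#' @param sentence An annotated `bt_tokens` object.
#' @param freq_table Optional frequency table for the corpus-frequency
#'   feature.
#' @param config Pipeline configuration, see [pipeline_config()].
#' @return List of character vectors, one per token.
#' @export
extract_features <- function(sentence, freq_table = NULL,
                             config = pipeline_config()) {
  tok <- sentence$tokens
  n <- nrow(tok)
  if (n == 0L) return(list())
  basic <- lapply(tok$surface, basic_features)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fi <- c(basic[[i]],
            char_ngrams(tok$surface[i], window = config$ngram_window,
                        mode = config$ngram_mode))
    if (!is.null(freq_table)) {
      fi <- c(fi, corpus_frequency_feature(tok$surface[i], tok$pos[i],
                                           freq_table,
                                           invert = config$freq_invert))
    }
    fi <- c(fi, offset_conjunction(basic, i, window = config$conj_window))
    out[[i]] <- unique(fi)
  }
  out
}

#' Dump per-token features in a flat debugging format
#'
#' One token per line: surface, then tab-separated feature identifiers.
#'
#' @param sentence A `bt_tokens` object.
#' @param features Output of [extract_features()].
#' @return Character vector of lines.
#' @export
format_feature_dump <- function(sentence, features) {
  vapply(seq_along(features), function(i) {
    paste(c(sentence$tokens$surface[i], features[[i]]), collapse = "\t")
  }, character(1))
}

#' PCA-based selection of sparse indicator features
#'
#' Builds principal components of the mean-centered sentence-by-feature
#' occurrence matrix, scores every original feature by its maximum
#' absolute loading over the first `n_components` components, and keeps
#' the `n_keep` highest-scoring features.  Selection operates on the
#' original sparse indicators (the sequence model needs them); the dense
#' projection is only used to rank them.
#'
#' @param x Numeric matrix (rows = sentences, columns = features); column
#'   names identify the features.
#' @param n_components Number of leading components (L) used for scoring.
#' @param n_keep Number of features (K) to retain.
#' @return List with `selected` (feature names, in original column order),
#'   `scores` (per-feature loading scores), and `eigenvalues`
#'   (non-increasing variances of the components).
#' @export
pca_select <- function(x, n_components, n_keep) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 1L)
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%d", seq_len(ncol(x)))
  vars <- apply(x, 2L, stats::var)
  if (all(vars == 0)) {
    stop("degenerate feature matrix: every column has zero variance")
  }
  n_keep <- min(n_keep, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$rotation))
  load <- abs(pc$rotation[, seq_len(n_components), drop = FALSE])
  scores <- apply(load, 1L, max)
  keep <- sort(order(scores, decreasing = TRUE)[seq_len(n_keep)])
  list(selected = colnames(x)[keep],
       scores = scores,
       eigenvalues = pc$sdev^2)
}

#' Build the sentence-by-feature occurrence matrix for [pca_select()]
#'
#' @param feature_lists List (one element per sentence) of per-token
#'   feature lists, as returned by [extract_features()].
#' @return Binary matrix, rows = sentences, columns = distinct features.
#' @export
feature_matrix <- function(feature_lists) {
  per_sentence <- lapply(feature_lists, function(fl) unique(unlist(fl)))
  vocab <- sort(unique(unlist(per_sentence)))
  m <- matrix(0, nrow = length(per_sentence), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(per_sentence)) {
    m[i, match(per_sentence[[i]], vocab)] <- 1
  }
  m
}
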