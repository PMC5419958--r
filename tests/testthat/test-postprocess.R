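test_that("the post-keyword list admits surfaces seen three or more times", {
  mk <- function(times, text) {
    if (times == 0) return(bitagger:::empty_mentions())
    data.frame(sentence_id = sprintf("S%d", seq_len(times)), start = 0L,
               end = nchar(text) - 1L, text = text,
               stringsAsFactors = FALSE)
  }
  expect_true("C4" %in% build_pkl(mk(3L, "C4"))$matchable)
  expect_false("C4" %in% build_pkl(mk(2L, "C4"))$matchable)
  expect_length(build_pkl(mk(0L, ""))$matchable, 0L)
})

test_that("contextual clues tag pkl neighbors of connective and relation words", {
  ts <- toy_sentence(c("Early", "complement", "components", ",", "C1q",
                       "and", "C4", ",", "and", "IgA", "secretory",
                       "piece", "were", "absent"))
  labels <- rep("O", 14)
  labels[5] <- "B"  # C1q already tagged
  pkl <- build_pkl(data.frame(sentence_id = c("T1", "T2", "T3"),
                              start = 0L, end = 1L, text = "C4",
                              stringsAsFactors = FALSE))
  lex <- keyword_lexicon()
  out <- apply_contextual_rules(ts, labels, lex, pkl)
  expect_equal(out[7], "B")     # C4 tagged via the connective "and"
  expect_equal(out[5], "B")     # existing mention untouched
  expect_equal(out[-c(5, 7)], labels[-c(5, 7)])

  # no lexicon words in the sentence: unchanged
  ts2 <- toy_sentence(c("C4", "levels", "rose"))
  expect_equal(apply_contextual_rules(ts2, rep("O", 3), lex, pkl),
               rep("O", 3))
  # neighbor not in the pkl: unchanged
  ts3 <- toy_sentence(c("X9", "and", "Y8"))
  expect_equal(apply_contextual_rules(ts3, rep("O", 3), lex, pkl),
               rep("O", 3))
  # relation keywords work like connectives
  ts4 <- toy_sentence(c("C4", "binds", "C4"))
  expect_equal(apply_contextual_rules(ts4, rep("O", 3), lex, pkl),
               c("B", "O", "B"))
})

test_that("parenthesis repair ejects the unbalanced bracket and re-heads", {
  ts <- toy_sentence(c("(", "HNF", "-", "3", ")"))
  expect_equal(fix_parentheses(ts, c("B", "I", "I", "I", "O")),
               c("O", "B", "I", "I", "O"))
  # fully enclosed pair stays
  ts2 <- toy_sentence(c("tissue", "(", "BAT", ")", "works"))
  lab2 <- c("O", "B", "I", "I", "O")
  expect_equal(fix_parentheses(ts2, lab2), lab2)
  # all-O unchanged
  expect_equal(fix_parentheses(ts, rep("O", 5)), rep("O", 5))
  # trailing bracket inside the mention, partner outside
  ts3 <- toy_sentence(c("(", "BAT", ")", "x"))
  expect_equal(fix_parentheses(ts3, c("O", "B", "I", "O")),
               c("O", "B", "O", "O"))
})

test_that("repaired labelings never leave an unbalanced bracket in a mention", {
  set.seed(67)
  pool <- c("(", ")", "[", "]", "Aa1", "bb", "CDE", "x")
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    surfaces <- sample(pool, n, replace = TRUE)
    ts <- toy_sentence(surfaces)
    labels <- random_bio(n, p_mention = 0.5)
    out <- fix_parentheses(ts, labels)
    expect_true(mention_brackets_balanced(surfaces, out))
    # never invents a mention where none existed
    expect_true(all(out[labels == "O"] == "O"))
  }
})

test_that("abbreviation pairs are extracted by the character pairing test", {
  ts <- toy_sentence(c("Brown", "adipose", "tissue", "(", "BAT", ")"))
  p <- extract_abbreviation_pairs(ts)
  expect_equal(nrow(p), 1L)
  expect_equal(p$short_form, "BAT")
  expect_equal(p$long_form, "Brown adipose tissue")
  expect_equal(p$lf_start, 1L)
  expect_equal(p$lf_end, 3L)
  expect_equal(p$sf_start, 5L)

  ts2 <- toy_sentence(c("in", "white", "adipose", "tissue", "(", "WAT",
                        ")", "today"))
  p2 <- extract_abbreviation_pairs(ts2)
  expect_equal(p2$long_form, "white adipose tissue")

  # numeric parenthetical: no letter-initial match, no pair
  ts3 <- toy_sentence(c("measured", "(", "p", "<", "0.05", ")"))
  expect_equal(nrow(extract_abbreviation_pairs(ts3)), 0L)
  # over-long parenthetical is not a short-form candidate
  ts4 <- toy_sentence(c("measured", "(", "averylongparenthetical", ")"))
  expect_equal(nrow(extract_abbreviation_pairs(ts4)), 0L)
})

test_that("labels propagate between long and short forms but are never invented", {
  ts <- toy_sentence(c("Brown", "adipose", "tissue", "(", "BAT", ")"))
  pairs <- extract_abbreviation_pairs(ts)
  # SF tagged only -> LF becomes B I I
  lab_sf <- c("O", "O", "O", "B", "I", "I")
  out <- propagate_abbreviation_labels(lab_sf, pairs)
  expect_equal(out[1:3], c("B", "I", "I"))
  expect_equal(out[4:6], lab_sf[4:6])
  # LF tagged only -> SF tokens become a mention
  lab_lf <- c("B", "I", "I", "O", "O", "O")
  out2 <- propagate_abbreviation_labels(lab_lf, pairs)
  expect_equal(out2[5], "B")
  # both tagged: unchanged; neither tagged: unchanged
  both <- c("B", "I", "I", "O", "B", "O")
  expect_equal(propagate_abbreviation_labels(both, pairs), both)
  none <- rep("O", 6)
  expect_equal(propagate_abbreviation_labels(none, pairs), none)
})

test_that("sense disambiguation prefers in-sentence long forms then context overlap", {
  inv <- data.frame(
    sf = c("ACE", "ACE", "BP"),
    sense_id = c("ace1", "ace2", "bp1"),
    long_form = c("angiotensin converting enzyme", "acetylcholinesterase",
                  "binding protein"),
    context_terms = c("blood,pressure,renin", "nerve,synapse,neural",
                      "complex"),
    stringsAsFactors = FALSE
  )
  ctx_lf <- c("the", "angiotensin", "converting", "enzyme", "(", "ACE", ")")
  expect_equal(disambiguate("ACE", ctx_lf, inv), "ace1")
  ctx_nerve <- c("nerve", "terminals", "contain", "ACE")
  expect_equal(disambiguate("ACE", ctx_nerve, inv), "ace2")
  # single-sense short form wins regardless of context
  expect_equal(disambiguate("BP", c("unrelated", "words"), inv), "bp1")
  # tie on zero overlap: first inventory row
  expect_equal(disambiguate("ACE", c("unrelated"), inv), "ace1")
  # unknown short form: no sense
  expect_true(is.na(disambiguate("XYZ", c("a"), inv)))
})

test_that("sense inventories load from tab-separated files", {
  f <- withr::local_tempfile()
  writeLines("ACE\tace1\tangiotensin converting enzyme\tblood,renin", f)
  inv <- read_sense_inventory(f)
  expect_equal(inv$sense_id, "ace1")
  writeLines("ACE\tonly-two", f)
  expect_error(read_sense_inventory(f), "4 tab-separated")
})

test_that("every post-processing operation is idempotent", {
  set.seed(71)
  lex <- keyword_lexicon()
  pkl <- build_pkl(data.frame(sentence_id = c("A", "B", "C"), start = 0L,
                              end = 2L, text = "Aa1",
                              stringsAsFactors = FALSE))
  pool <- c("(", ")", "Aa1", "and", "binds", "bb", "Brown", "adipose",
            "tissue", "BAT")
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    ts <- toy_sentence(sample(pool, n, replace = TRUE))
    labels <- random_bio(n, p_mention = 0.4)
    c1 <- apply_contextual_rules(ts, labels, lex, pkl)
    expect_identical(apply_contextual_rules(ts, c1, lex, pkl), c1)
    p1 <- fix_parentheses(ts, labels)
    expect_identical(fix_parentheses(ts, p1), p1)
    pairs <- extract_abbreviation_pairs(ts)
    a1 <- propagate_abbreviation_labels(labels, pairs)
    expect_identical(propagate_abbreviation_labels(a1, pairs), a1)
    full <- postprocess_labels(ts, labels, lex, pkl)
    expect_identical(postprocess_labels(ts, full, lex, pkl), full)
  }
})
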