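test_that("normalize_tokens lowercases, strips punctuation and splits", {
  expect_equal(normalize_tokens("Neck Pain, revisited!"), c("neck", "pain", "revisited"))
  expect_equal(normalize_tokens(""), character(0))
  expect_equal(normalize_tokens("...!!!"), character(0))
  expect_equal(normalize_tokens("self-reported pain"), c("self", "reported", "pain"))
  expect_equal(normalize_tokens(NA_character_), character(0))
})

test_that("normalize_tokens agrees with a character-walk oracle on random ASCII", {
  set.seed(11)
  alphabet <- c(letters, LETTERS, 0:9, strsplit(" .,;:!?-_()[]/'\"", "")[[1]])
  for (i in 1:200) {
    text <- paste(sample(alphabet, sample(0:60, 1), replace = TRUE), collapse = "")
    expect_equal(normalize_tokens(text), oracle_tokenize(text), info = text)
  }
})

test_that("key_phrase validates its fields", {
  expect_error(key_phrase("pain"), "two words")
  expect_error(key_phrase(c("neck pain", "x")), "whitespace")
  expect_error(key_phrase(c("neck", "pain"), max_gap = -1), "max_gap")
  expect_equal(length(default_phrases()), 5L)
})

test_that("phrase_match handles adjacency, gap boundary and miss", {
  np <- key_phrase(c("neck", "pain"))
  res <- phrase_match(c("chronic", "neck", "pain"), np)
  expect_true(res$matched)
  expect_equal(res$gap, 0L)
  expect_equal(res$positions, c(2L, 3L))

  cp <- key_phrase(c("cervical", "pain"))
  expect_true(phrase_match(c("cervical", "a", "b", "c", "pain"), cp)$matched) # gap 3
  expect_false(phrase_match(c("cervical", "a", "b", "c", "d", "pain"), cp)$matched) # gap 4
  expect_false(phrase_match(c("pain", "cervical"), cp)$matched) # order matters
  expect_false(phrase_match(character(0), cp)$matched)
})

test_that("the published guideline title matches 'cervical pain' with gap 2", {
  title <- paste(
    "Consensus practice guidelines on interventions for cervical spine",
    "joint pain from a multispecialty international working group"
  )
  res <- phrase_match(normalize_tokens(title), key_phrase(c("cervical", "pain")))
  expect_true(res$matched)
  expect_equal(res$gap, 2L)
})

test_that("backtracking finds matches that greedy next-position search misses", {
  # the earliest admissible "b" (position 2) cannot reach "c"; the match
  # needs the later "b" at position 3
  ph <- key_phrase(c("a", "b", "c"), max_gap = 1L)
  res <- phrase_match(c("a", "b", "b", "x", "c"), ph)
  expect_true(res$matched)
  expect_equal(res$positions, c(1L, 3L, 5L))
  expect_equal(res$gap, 2L)
})

test_that("phrase_match equals the exhaustive index-pair oracle, exhaustively", {
  # every token list over a two-symbol alphabet up to length 12
  ph <- key_phrase(c("neck", "pain"))
  for (len in 1:12) {
    grid <- expand.grid(rep(list(c("neck", "pain")), len), stringsAsFactors = FALSE)
    for (row in seq_len(nrow(grid))) {
      tokens <- unlist(grid[row, ], use.names = FALSE)
      got <- phrase_match(tokens, ph)
      want <- oracle_phrase_match(tokens, ph$words, ph$max_gap)
      expect_equal(got$matched, want$matched)
      expect_equal(got$gap, want$gap)
    }
  }
})

test_that("phrase_match equals the oracle on random longer token lists", {
  set.seed(21)
  vocab <- c("neck", "pain", "cervical", "x", "y")
  phrases <- list(
    key_phrase(c("neck", "pain")),
    key_phrase(c("cervical", "pain"), max_gap = 2L),
    key_phrase(c("neck", "x", "pain"), max_gap = 1L)
  )
  for (i in 1:2000) {
    tokens <- sample(vocab, sample(13:30, 1), replace = TRUE)
    ph <- phrases[[sample(3, 1)]]
    got <- phrase_match(tokens, ph)
    want <- oracle_phrase_match(tokens, ph$words, ph$max_gap)
    expect_equal(got$matched, want$matched)
    expect_equal(got$gap, want$gap)
    if (got$matched) expect_equal(got$positions, want$positions)
  }
})

test_that("matched positions are strictly increasing and respect the gap bound", {
  set.seed(31)
  vocab <- c("back", "pain", "z")
  ph <- key_phrase(c("back", "pain"))
  for (i in 1:300) {
    tokens <- sample(vocab, sample(2:15, 1), replace = TRUE)
    res <- phrase_match(tokens, ph)
    if (res$matched) {
      expect_true(all(diff(res$positions) > 0))
      expect_true(all(diff(res$positions) - 1L <= ph$max_gap))
      expect_true(res$gap <= ph$max_gap)
    }
  }
})

test_that("screen_record is the OR of per-field phrase matches", {
  arts <- make_tiny_articles()
  expect_true(screen_record(list(
    title = "Consensus practice guidelines on interventions for cervical spine joint pain",
    abstract = ""
  )))
  expect_false(screen_record(list(title = "knee surgery trial", abstract = "no phrase")))

  set.seed(41)
  vocab <- c("neck", "pain", "back", "cervical", "w", "v")
  phrases <- default_phrases()
  for (i in 1:300) {
    rec <- list(
      title = paste(sample(vocab, sample(1:10, 1), replace = TRUE), collapse = " "),
      abstract = paste(sample(vocab, sample(0:20, 1), replace = TRUE), collapse = " ")
    )
    want <- any(vapply(phrases, function(ph) {
      oracle_phrase_match(normalize_tokens(rec$title), ph$words, ph$max_gap)$matched ||
        oracle_phrase_match(normalize_tokens(rec$abstract), ph$words, ph$max_gap)$matched
    }, logical(1)))
    expect_equal(screen_record(rec, phrases), want)
  }
})

test_that("screening is monotone in the phrase list", {
  arts <- make_tiny_articles()
  base <- default_phrases()
  kept_base <- screen_records(arts, base)
  more <- c(base, list(key_phrase(c("knee", "surgery"), max_gap = 0L)))
  kept_more <- screen_records(arts, more)
  expect_true(all(kept_base$id %in% kept_more$id))
})

test_that("deduplicate keeps first occurrences by id then normalized title", {
  arts <- make_tiny_articles()
  expect_equal(deduplicate(arts), arts) # all distinct

  dup_id <- rbind(arts, transform(arts[1, ], title = "something else"))
  expect_equal(nrow(deduplicate(dup_id)), nrow(arts))

  dup_title <- rbind(arts, transform(arts[2, ], id = "A99", title = "Low BACK pain: outcomes!"))
  out <- deduplicate(dup_title)
  expect_equal(nrow(out), nrow(arts))
  expect_false("A99" %in% out$id)

  set.seed(51)
  for (i in 1:20) {
    n_dup <- sample(0:5, 1)
    shuffled <- arts[sample(nrow(arts)), , drop = FALSE]
    extra <- shuffled[sample(nrow(arts), n_dup, replace = TRUE), , drop = FALSE]
    mixed <- rbind(shuffled, extra)
    expect_equal(nrow(deduplicate(mixed)), nrow(arts))
  }
})

test_that("filter_journal_info keeps exactly resolvable journals", {
  arts <- make_tiny_articles()
  jt <- make_tiny_journals()
  expect_equal(filter_journal_info(arts, jt), arts)
  expect_equal(nrow(filter_journal_info(arts, jt[0, ])), 0L)
  partial <- jt[jt$journal_id %in% c("J01", "J03"), ]
  out <- filter_journal_info(arts, partial)
  expect_equal(nrow(out), sum(arts$journal_id %in% c("J01", "J03")))
})

test_that("assign_labels partitions records into positives and negatives", {
  arts <- make_tiny_articles()
  all_pos <- assign_labels(arts, arts$id)
  expect_true(all(all_pos$label == 1L))
  none <- assign_labels(arts, character(0))
  expect_true(all(none$label == 0L))
  some <- assign_labels(arts, c("A01", "A03"))
  expect_equal(sum(some$label), 2L)
  expect_equal(sum(some$label == 1L) + sum(some$label == 0L), nrow(arts))
  expect_warning(assign_labels(arts, "NOT-THERE"), "not found")
})

test_that("labelling a corpus with the published set sizes preserves the partition", {
  # synthetic stand-in with the published counts: 27,406 articles of which
  # 1,005 are guideline-cited
  n_total <- 27406L
  n_pos <- 1005L
  ids <- sprintf("S%05d", seq_len(n_total))
  records <- data.frame(id = ids, stringsAsFactors = FALSE)
  labelled <- assign_labels(records, ids[seq_len(n_pos)])
  expect_equal(sum(labelled$label == 1L), 1005L)
  expect_equal(sum(labelled$label == 0L), 26401L)
  expect_equal(sum(labelled$label == 1L) + sum(labelled$label == 0L), n_total)
})

test_that("downsample_negatives draws the exact count, reproducibly", {
  # smallest exact 3:7 case
  arts <- data.frame(
    id = sprintf("A%02d", 1:20),
    label = c(rep(1L, 3), rep(0L, 17)),
    stringsAsFactors = FALSE
  )
  out <- downsample_negatives(arts, 0.3, seed = 5)
  expect_equal(sum(out$label == 1L), 3L)
  expect_equal(sum(out$label == 0L), 7L)

  # determinism and containment
  out2 <- downsample_negatives(arts, 0.3, seed = 5)
  expect_identical(out, out2)
  out3 <- downsample_negatives(arts, 0.3, seed = 6)
  expect_true(all(out3$id %in% arts$id))
  expect_false(anyDuplicated(out3$id) > 0)
  diff_seen <- any(!(out3$id %in% out$id)) || any(!(out$id %in% out3$id))
  expect_true(diff_seen || identical(out$id, out3$id)) # subsets either way

  # error names required vs available counts
  few <- arts[1:6, ]
  expect_error(downsample_negatives(few, 0.3, seed = 1), "available")
})

test_that("downsampling arithmetic reproduces the published 3:7 draw size", {
  n_pos <- 1005L
  arts <- data.frame(
    id = sprintf("B%05d", 1:27406),
    label = c(rep(1L, n_pos), rep(0L, 26401L)),
    stringsAsFactors = FALSE
  )
  out <- downsample_negatives(arts, 0.3, seed = 1)
  expect_equal(sum(out$label == 0L), 2345L)
  expect_equal(sum(out$label == 1L), 1005L)
  expect_equal(nrow(out), 3350L)
})

test_that("word_frequencies counts tokens with deterministic tie-breaks", {
  one <- data.frame(id = "x", title = "neck pain neck", abstract = "", stringsAsFactors = FALSE)
  wf <- word_frequencies(one, k = 10)
  expect_equal(wf$word, c("neck", "pain"))
  expect_equal(wf$count, c(2L, 1L))

  arts <- make_tiny_articles()
  full <- word_frequencies(arts, k = 10000)
  tokens <- unlist(lapply(seq_len(nrow(arts)), function(i) {
    c(oracle_tokenize(arts$title[i]), oracle_tokenize(arts$abstract[i]))
  }))
  expect_equal(nrow(full), length(unique(tokens)))
  expect_equal(sum(full$count), length(tokens))
  counts <- table(tokens)
  for (i in seq_len(nrow(full))) {
    expect_equal(full$count[i], as.integer(counts[[full$word[i]]]))
  }
  expect_true(all(diff(full$count) <= 0))
})

test_that("build_corpus composes the pipeline and preserves counts", {
  synth <- generate_corpus(synth_config(n_pos = 30, n_neg = 90, seed = 2))
  built <- build_corpus(synth$records, synth$journals, synth$positive_ids, seed = 2)
  cnt <- built$counts
  expect_true(cnt["screened"] >= cnt["deduplicated"])
  expect_true(cnt["deduplicated"] >= cnt["journal_filtered"])
  expect_equal(unname(cnt["journal_filtered"]), unname(cnt["positive"] + cnt["negative"]))
  expect_equal(unname(cnt["downsampled"]), nrow(built$corpus))
  expect_equal(sum(built$corpus$label == 1L), 30L)
  expect_equal(sum(built$corpus$label == 0L), 70L)
})
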