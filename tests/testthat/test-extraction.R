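test_that("tokenizer splits on whitespace and punctuation with exact offsets", {
  toks <- tokenize("EBL 500 cc")
  expect_equal(toks$token, c("EBL", "500", "cc"))
  expect_equal(toks$start, c(1L, 5L, 9L))
  expect_equal(nrow(tokenize("")), 0)
  expect_equal(tokenize("d&c")$token, c("d", "&", "c"))
  # offsets round-trip on random strings (character-scan oracle)
  set.seed(5)
  alphabet <- c(letters, "0", "9", " ", " ", ".", ",", "/", "&", "-", "\n")
  for (i in 1:50) {
    s <- paste(sample(alphabet, sample(0:80, 1), TRUE), collapse = "")
    toks <- tokenize(s)
    if (nrow(toks) > 0) {
      expect_identical(substring(s, toks$start, toks$end), toks$token)
    }
  }
})

test_that("chunking follows the stated step arithmetic", {
  cfg <- extraction_config(window_tokens = 512, overlap_tokens = 128)
  long <- make_note(text = paste(rep("tok", 1000), collapse = " "))
  chunks <- chunk_note(long, cfg)
  expect_length(chunks, 3)
  expect_equal(vapply(chunks, `[[`, integer(1), "token_start") /
                 1L, c(0, 384, 768))
  expect_equal(chunks[[3]]$token_end, 1000)
  # n = window -> exactly one chunk covering [0, 512)
  exact <- make_note(text = paste(rep("tok", 512), collapse = " "))
  one <- chunk_note(exact, cfg)
  expect_length(one, 1)
  expect_equal(c(one[[1]]$token_start, one[[1]]$token_end), c(0, 512))
  # empty note -> no chunks (not one empty chunk)
  expect_length(chunk_note(make_note(text = ""), cfg), 0)
})

test_that("chunk coverage and width hold by enumeration across window shapes", {
  set.seed(17)
  for (wo in list(c(512L, 128L), c(8L, 3L), c(5L, 0L))) {
    cfg <- extraction_config(window_tokens = wo[1], overlap_tokens = wo[2])
    for (n in sample(0:2000, 25)) {
      note <- make_note(text = paste(rep("w", n), collapse = " "))
      chunks <- chunk_note(note, cfg)
      if (n == 0) { expect_length(chunks, 0); next }
      covered <- sort(unique(unlist(lapply(chunks, function(ch)
        seq(ch$token_start, ch$token_end - 1L)))))
      expect_identical(covered, 0:(n - 1L))
      widths <- vapply(chunks, function(ch) ch$token_end - ch$token_start, integer(1))
      expect_true(all(widths <= wo[1]))
      starts <- vapply(chunks, `[[`, integer(1), "token_start")
      expect_equal(starts, (seq_along(starts) - 1L) * (wo[1] - wo[2]))
    }
  }
  expect_error(extraction_config(window_tokens = 8, overlap_tokens = 8), "smaller")
})

test_that("yes/no parsing strips leading junk and falls back to unparseable", {
  expect_equal(parse_yes_no("Yes"), "positive")
  expect_equal(parse_yes_no(" no."), "negative")
  expect_equal(parse_yes_no("\"YES, she did\""), "positive")
  expect_equal(parse_yes_no("maybe"), "unparseable")
  expect_equal(parse_yes_no(""), "unparseable")
})

test_that("binary aggregation is OR over chunks and over chained prompts", {
  cfg <- extraction_config(window_tokens = 5, overlap_tokens = 0)
  reg <- builtin_registry()
  # note with atony phrase in the final chunk only
  text <- paste(c(rep("word", 11), "uterine atony was noted"), collapse = " ")
  note <- make_note(text = text)
  call <- run_binary_concept(note, reg$uterine_atony, pattern_backend(reg), cfg)
  expect_true(call$label)
  expect_gt(nrow(call$per_chunk), 1)
  expect_true(any(call$per_chunk$outcome == "positive"))
  # aggregation equivalence: label equals brute-force OR over per-chunk labels
  per_chunk_or <- any(vapply(chunk_note(note, cfg), function(ch) {
    any(vapply(reg$uterine_atony$patterns, function(p)
      grepl(p, ch$text, perl = TRUE, ignore.case = TRUE), logical(1)))
  }, logical(1)))
  expect_equal(call$label, per_chunk_or)
  # chained prompts: only the third accreta prompt's pattern present
  note2 <- make_note(text = "findings were consistent with placenta accreta today")
  call2 <- run_binary_concept(note2, reg$accreta_spectrum, pattern_backend(reg),
                              extraction_config())
  expect_true(call2$label)
  expect_equal(nrow(call2$per_chunk), 3)  # one chunk x three chained prompts
  # all negative -> false
  call3 <- run_binary_concept(make_note(text = "unremarkable stay"),
                              reg$accreta_spectrum, pattern_backend(reg))
  expect_false(call3$label)
})

test_that("pattern backend is position-invariant near chunk boundaries", {
  cfg <- extraction_config(window_tokens = 8, overlap_tokens = 3)
  reg <- builtin_registry()
  # plant a 2-token phrase at every offset; overlap (3) exceeds phrase length
  for (offset in 0:20) {
    words <- rep("filler", 24)
    words[offset + 1] <- "uterine"
    words[offset + 2] <- "atony"
    note <- make_note(text = paste(words, collapse = " "))
    call <- run_binary_concept(note, reg$uterine_atony, pattern_backend(reg), cfg)
    expect_true(call$label, info = paste("offset", offset))
  }
})

test_that("measurement extraction unions segments and drops the fallback token", {
  reg <- builtin_registry()
  truth <- data.frame(note_id = "n1", concept_id = "estimated_blood_loss",
                      segment = "800 cc", stringsAsFactors = FALSE)
  note <- make_note("n1", text = paste(rep("w", 900), collapse = " "))
  call <- run_extraction_concept(note, reg$estimated_blood_loss,
                                 mock_backend(truth), extraction_config())
  expect_equal(call$segments, "800 cc")  # identical chunk answers collapse
  expect_gt(nrow(call$per_chunk), 1)
  # all unanswerable -> empty set
  truth$segment <- NA_character_
  call2 <- run_extraction_concept(note, reg$estimated_blood_loss,
                                  mock_backend(truth), extraction_config())
  expect_length(call2$segments, 0)
})

test_that("pattern backend answers from patterns and extracts numeric spans", {
  reg <- builtin_registry()
  be <- pattern_backend(reg)
  ctx <- function(cid, text) list(note_id = "n", concept = reg[[cid]],
                                  chunk_text = text, chunk_index = 0L,
                                  prompt_index = 1L)
  expect_equal(be$respond("", ctx("uterine_atony", "pt with uterine atony")), "yes")
  expect_equal(be$respond("", ctx("uterine_atony", "normal delivery")), "no")
  expect_equal(be$respond("", ctx("estimated_blood_loss", "EBL: 800cc today")), "800cc")
  expect_equal(be$respond("", ctx("estimated_blood_loss", "no loss recorded")),
               "unanswerable")
  # construction fails on a pattern-less concept
  broken <- reg
  broken$laceration$patterns <- character(0)
  expect_error(pattern_backend(broken), "laceration")
})

test_that("mock backend replays truth, flips at the configured rate, and is seed-stable", {
  truth <- make_mock_truth(1000, "uterine_atony", positive_rate = 1)
  reg <- builtin_registry()
  ctx <- function(id) list(note_id = id, concept = reg$uterine_atony,
                           chunk_text = "x", chunk_index = 0L, prompt_index = 1L)
  # flip_rate 0 -> exact replay
  be0 <- mock_backend(truth, flip_rate = 0)
  expect_true(all(vapply(truth$note_id[1:50], function(id)
    be0$respond("", ctx(id)) == "yes", logical(1))))
  # flip fraction within 3 binomial SD of 0.2 over 1000 calls
  be <- mock_backend(truth, flip_rate = 0.2, seed = 7)
  ans <- vapply(truth$note_id, function(id) be$respond("", ctx(id)), character(1))
  flipped <- mean(ans == "no")
  expect_lt(abs(flipped - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))
  # same seed -> identical call-by-call outcomes
  be2 <- mock_backend(truth, flip_rate = 0.2, seed = 7)
  ans2 <- vapply(truth$note_id, function(id) be2$respond("", ctx(id)), character(1))
  expect_identical(ans, ans2)
  # unknown pair is an error
  expect_error(be0$respond("", ctx("nope")), "no planted truth")
})

test_that("backend failures surface as hard errors carrying the chunk index", {
  reg <- builtin_registry()
  failing <- structure(list(id = "boom", respond = function(prompt, context)
    stop("connection lost")), class = "pph_backend")
  expect_error(run_binary_concept(make_note(text = "some text"),
                                  reg$uterine_atony, failing),
               "chunk 0")
})

test_that("generative backend enforces its adapter contract", {
  expect_error(generative_backend(), "generate_fn")
  seen <- NULL
  be <- generative_backend(list(model = "t2t", max_context_tokens = 10),
                           extraction_config(),
                           generate_fn = function(prompt, params) {
                             seen <<- params
                             "yes"
                           })
  short_ctx <- list(note_id = "n", concept = builtin_registry()$uterine_atony,
                    chunk_text = "x", chunk_index = 0L, prompt_index = 1L)
  expect_equal(be$respond("short prompt", short_ctx), "yes")
  expect_equal(seen$max_new_tokens, 5L)
  expect_equal(seen$temperature, 1.0)
  expect_equal(seen$decode_mode, "greedy")
  long_prompt <- paste(rep("w", 40), collapse = " ")
  expect_error(be$respond(long_prompt, short_ctx), "context")
})

test_that("single-chunk sensitivity under a flipping mock converges to 1 - flip_rate", {
  reg <- builtin_registry()
  n <- 1000
  truth <- make_mock_truth(n, "uterine_atony", positive_rate = 1)
  be <- mock_backend(truth, flip_rate = 0.1, seed = 3)
  notes <- lapply(truth$note_id, function(id) make_note(id, text = "short note"))
  labels <- vapply(notes, function(note)
    run_binary_concept(note, reg$uterine_atony, be)$label, logical(1))
  sens <- mean(labels)
  expect_lt(abs(sens - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})
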