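test_that("binary metrics reproduce the arithmetic and flag degenerate denominators", {
  m <- binary_metrics(list(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$binary_f1, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$specificity, 5 / 6)
  expect_length(m$undefined, 0)
  # perfect predictor
  p <- binary_metrics(list(tp = 4, fp = 0, fn = 0, tn = 6))
  expect_true(all(unlist(p[c("sensitivity", "specificity", "ppv",
                             "binary_f1", "accuracy")]) == 1))
  # no predicted positives: PPV flagged NA, never coerced to 0
  d <- binary_metrics(list(tp = 0, fp = 0, fn = 2, tn = 8))
  expect_true(is.na(d$ppv))
  expect_true("ppv" %in% d$undefined)
  expect_false(identical(d$ppv, 0))
})

test_that("binary metrics agree with brute-force recounts on random fixtures", {
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    pred <- runif(n) < 0.5
    truth <- runif(n) < 0.5
    m <- binary_metrics(confusion_counts(pred, truth))
    # recount oracle straight from the raw pairs
    sens <- if (sum(truth) > 0) sum(pred & truth) / sum(truth) else NA_real_
    ppv <- if (sum(pred) > 0) sum(pred & truth) / sum(pred) else NA_real_
    spec <- if (sum(!truth) > 0) sum(!pred & !truth) / sum(!truth) else NA_real_
    expect_equal(m$sensitivity, sens)
    expect_equal(m$ppv, ppv)
    expect_equal(m$specificity, spec)
    expect_equal(m$accuracy, mean(pred == truth))
  }
})

test_that("extraction metrics pool values and score note-level set equality", {
  m <- extraction_metrics(list(n1 = 500), list(n1 = 500))
  expect_equal(unlist(m[c("sensitivity", "ppv", "note_accuracy")]),
               c(sensitivity = 1, ppv = 1, note_accuracy = 1))
  # empty vs empty counts toward accuracy but not the pooled ratios
  m2 <- extraction_metrics(list(n1 = numeric(0), n2 = 500),
                           list(n1 = numeric(0), n2 = 500))
  expect_equal(m2$note_accuracy, 1)
  expect_equal(m2$sensitivity, 1)
  # over-extraction: sens 1, ppv 0.5, note incorrect
  m3 <- extraction_metrics(list(n1 = c(500, 800)), list(n1 = 500))
  expect_equal(m3$sensitivity, 1)
  expect_equal(m3$ppv, 0.5)
  expect_equal(m3$note_accuracy, 0)
  # all-empty gold: sensitivity undefined, flagged
  m4 <- extraction_metrics(list(n1 = numeric(0)), list(n1 = numeric(0)))
  expect_true(is.na(m4$sensitivity))
  expect_true("sensitivity" %in% m4$undefined)
  expect_error(extraction_metrics(list(a = 1), list(b = 1)), "universe")
})

test_that("extraction metrics agree with pooled recounts on random fixtures", {
  set.seed(29)
  vals <- c(300, 500, 800, 1000, 1500)
  for (i in 1:1000) {
    n <- sample(1:10, 1)
    ids <- sprintf("n%d", seq_len(n))
    pred <- lapply(ids, function(i) sample(vals, sample(0:3, 1)))
    gold <- lapply(ids, function(i) sample(vals, sample(0:3, 1)))
    names(pred) <- names(gold) <- ids
    m <- extraction_metrics(pred, gold)
    tp <- sum(mapply(function(p, g) length(intersect(p, g)), pred, gold))
    ng <- sum(lengths(lapply(gold, unique)))
    np <- sum(lengths(lapply(pred, unique)))
    expect_equal(m$sensitivity, if (ng > 0) tp / ng else NA_real_)
    expect_equal(m$ppv, if (np > 0) tp / np else NA_real_)
    expect_equal(m$note_accuracy, mean(mapply(setequal, pred, gold)))
  }
})

test_that("exact McNemar equals the binomial tail oracle exhaustively to b + c = 20", {
  for (bc in 1:20) {
    for (b in 0:bc) {
      c_ <- bc - b
      got <- mcnemar(list(n10 = b, n01 = c_), mode = "exact")$p_value
      # two-sided binomial tail: sum of P(X = k) over k with P(k) <= P(b)
      probs <- stats::dbinom(0:bc, bc, 0.5)
      oracle <- min(1, sum(probs[probs <= probs[b + 1] * (1 + 1e-7)]))
      expect_equal(got, oracle, tolerance = 1e-10)
    }
  }
  # the closed-form spot checks
  expect_equal(mcnemar(list(n10 = 10, n01 = 0), mode = "exact")$p_value,
               2 * 0.5^10)
  expect_equal(mcnemar(list(n10 = 3, n01 = 3), mode = "exact")$p_value, 1.0)
})

test_that("chi-square McNemar matches the continuity-corrected closed form and stats oracle", {
  r <- mcnemar(list(n10 = 40, n01 = 20), mode = "chi2cc")
  expect_equal(r$statistic, (abs(40 - 20) - 1)^2 / 60)
  expect_equal(r$statistic, 6.0167, tolerance = 1e-4)
  # independent oracle: stats::mcnemar.test on the paired table
  tab <- matrix(c(30, 40, 20, 10), nrow = 2)
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  # auto switches on the discordant count
  expect_equal(mcnemar(list(n10 = 12, n01 = 12), mode = "auto")$mode_used, "exact")
  expect_equal(mcnemar(list(n10 = 13, n01 = 12), mode = "auto")$mode_used, "chi2cc")
  # no discordance -> p = 1
  expect_equal(mcnemar(list(n10 = 0, n01 = 0))$p_value, 1.0)
})

test_that("McNemar is symmetric under swapping the two methods", {
  set.seed(43)
  for (i in 1:50) {
    b <- sample(0:50, 1); c_ <- sample(0:50, 1)
    if (b + c_ == 0) next
    for (mode in c("exact", "chi2cc")) {
      ab <- mcnemar(list(n10 = b, n01 = c_), mode = mode)
      ba <- mcnemar(list(n10 = c_, n01 = b), mode = mode)
      expect_equal(ab$p_value, ba$p_value)
      expect_equal(ab$statistic, ba$statistic)
    }
  }
  p <- paired_outcomes(c(TRUE, TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(unlist(p[c("n11", "n10", "n01", "n00")]),
               c(n11 = 2, n10 = 1, n01 = 1, n00 = 0))
})

test_that("concept report matches a per-note tally on a 20-note fixture", {
  syn <- clean_synth(20, seed = 301)
  reg <- builtin_registry()
  calls <- extract_corpus(syn$notes, reg, pattern_backend(reg))
  rep <- suppressWarnings(concept_report(calls, syn$gold, reg))
  # n column equals the gold positive count, recounted by hand
  for (cid in setdiff(rep$concept_id, "estimated_blood_loss")) {
    gold_pos <- sum(vapply(syn$gold, function(a)
      a$concept_id == cid && isTRUE(a$label), logical(1)))
    expect_equal(rep$n[rep$concept_id == cid], gold_pos)
    # brute-force confusion from raw labels
    notes_gold <- Filter(function(a) a$concept_id == cid, syn$gold)
    truth <- vapply(notes_gold, `[[`, logical(1), "label")
    ids <- vapply(notes_gold, `[[`, character(1), "note_id")
    sub <- calls[calls$concept_id == cid, ]
    pred <- sub$label[match(ids, sub$note_id)]
    cc <- confusion_counts(pred, truth)
    want <- binary_metrics(cc)
    expect_equal(rep$binary_f1[rep$concept_id == cid], want$binary_f1)
  }
  # clean corpus: every evaluable concept is perfect
  evaluable <- !is.na(rep$sensitivity)
  expect_true(all(rep$sensitivity[evaluable] == 1))
  expect_true(all(rep$ppv[!is.na(rep$ppv)] == 1))
  # concept missing from gold is omitted with a warning
  gold_partial <- Filter(function(a) a$concept_id != "laceration", syn$gold)
  expect_warning(rep2 <- concept_report(calls, gold_partial, reg), "laceration")
  expect_false("laceration" %in% rep2$concept_id)
})

test_that("EBL-by-ICD crosstab matches a brute-force recount", {
  set.seed(53)
  n <- 40
  ass <- tibble::tibble(
    delivery_id = sprintf("d%d", 1:n), patient_id = sprintf("p%d", 1:n),
    note_ids = replicate(n, "x", simplify = FALSE), n_notes = 1L,
    total_ebl_ml = sample(c(0, 300, 700, 1200, 1800, 2500), n, TRUE),
    mode = "vaginal", pph = FALSE, concept_flags = replicate(n, list(), simplify = FALSE))
  ass$ebl_values <- lapply(ass$total_ebl_ml, function(v) if (v == 0) numeric(0) else v)
  coded <- sample(n, 15)
  icd <- lapply(coded, function(i) icd_record(sprintf("p%d", i), "666.12",
                                              "2010-01-01", "ICD9"))
  tab <- ebl_icd_crosstab(ass, icd, bin_edges = c(0, 500, 1000, 1500, 2000))
  expect_equal(sum(tab$n), n)
  is_coded <- ass$patient_id %in% sprintf("p%d", coded)
  # recount each bin by hand
  no_ebl <- lengths(ass$ebl_values) == 0
  expect_equal(tab$n[tab$bin == "no EBL extracted"], sum(no_ebl))
  expect_equal(tab$n_coded[tab$bin == "no EBL extracted"], sum(is_coded & no_ebl))
  in_bin <- !no_ebl & ass$total_ebl_ml > 500 & ass$total_ebl_ml <= 1000
  expect_equal(tab$n[tab$bin == "(500, 1000]"], sum(in_bin))
  expect_equal(tab$proportion[tab$bin == "(500, 1000]"],
               sum(is_coded & in_bin) / sum(in_bin))
  # all coded -> proportion 1 in every non-empty bin; no codes -> 0
  all_icd <- lapply(1:n, function(i) icd_record(sprintf("p%d", i), "666.02",
                                                "2010-01-01", "ICD9"))
  t1 <- ebl_icd_crosstab(ass, all_icd)
  expect_true(all(t1$proportion[t1$n > 0] == 1))
  t0 <- ebl_icd_crosstab(ass, list())
  expect_true(all(t0$proportion[t0$n > 0] == 0))
})
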