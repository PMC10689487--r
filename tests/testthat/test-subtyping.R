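all_flag_combos <- function(ids) {
  n <- length(ids)
  lapply(0:(2^n - 1), function(m) {
    stats::setNames(as.logical(bitwAnd(m, 2^(seq_len(n) - 1))), ids)
  })
}

test_that("NLP subtype rule matches the truth-table oracle exhaustively", {
  ids15 <- setdiff(subtype_concepts(), "fresh_frozen_plasma")
  mismatches <- 0L
  for (flags in all_flag_combos(ids15)) {
    flags <- c(flags, fresh_frozen_plasma = FALSE)
    got <- nlp_subtype(flags)
    want <- oracle_subtype(flags)
    if (!identical(list(tone = got$tone, tissue = got$tissue,
                        trauma = got$trauma, thrombin = got$thrombin), want)) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("subtype evidence and the laceration guard behave per the composite rules", {
  base <- stats::setNames(rep(FALSE, 16), subtype_concepts())
  one <- function(...) { f <- base; f[c(...)] <- TRUE; f }
  r <- nlp_subtype(one("uterine_atony"))
  expect_true(r$tone); expect_false(r$trauma)
  expect_equal(r$evidence$tone, "uterine_atony")
  # laceration alone -> trauma only
  r2 <- nlp_subtype(one("laceration"))
  expect_true(r2$trauma); expect_false(any(r2$tone, r2$tissue, r2$thrombin))
  expect_equal(r2$evidence$trauma, "laceration")
  # laceration + atony -> tone only, guard suppresses trauma
  r3 <- nlp_subtype(one("laceration", "uterine_atony"))
  expect_true(r3$tone); expect_false(r3$trauma)
  # laceration + uterine rupture -> trauma via rupture, laceration not listed
  r4 <- nlp_subtype(one("laceration", "uterine_rupture"))
  expect_true(r4$trauma)
  expect_equal(r4$evidence$trauma, "uterine_rupture")
  expect_error(nlp_subtype(list(uterine_atony = TRUE)), "missing required")
})

test_that("FFP triggers thrombin only with a ratio above 1:1:1 or in permissive mode", {
  base <- stats::setNames(rep(FALSE, 16), subtype_concepts())
  ffp <- base; ffp["fresh_frozen_plasma"] <- TRUE
  # no counts: not thrombin, but the skipped check is recorded
  r <- nlp_subtype(ffp)
  expect_false(r$thrombin)
  expect_match(r$notes, "ratio", all = FALSE)
  # counts with ffp > rbc: thrombin
  r2 <- nlp_subtype(ffp, transfusion_counts = list(ffp_units = 3, rbc_units = 2))
  expect_true(r2$thrombin)
  expect_true("fresh_frozen_plasma" %in% r2$evidence$thrombin)
  # counts at parity: not thrombin (ratio must exceed 1:1:1)
  r3 <- nlp_subtype(ffp, transfusion_counts = list(ffp_units = 2, rbc_units = 2))
  expect_false(r3$thrombin)
  # permissive switch
  r4 <- nlp_subtype(ffp, ffp_alone_qualifies = TRUE)
  expect_true(r4$thrombin)
  # FFP-triggered thrombin also engages the laceration guard
  both <- ffp; both["laceration"] <- TRUE
  expect_true(nlp_subtype(both)$trauma)                      # no counts: guard sees no thrombin
  expect_false(nlp_subtype(both, transfusion_counts = list(ffp_units = 3, rbc_units = 1))$trauma)
})

test_that("subtype monotonicity: triggers only add, the guard only removes laceration", {
  set.seed(61)
  ids <- subtype_concepts()
  non_lac <- setdiff(ids, "laceration")
  labels <- c("tone", "tissue", "trauma", "thrombin")
  for (i in 1:200) {
    flags <- stats::setNames(runif(16) < 0.3, ids)
    before <- nlp_subtype(flags, ffp_alone_qualifies = TRUE)
    cand <- non_lac[!flags[non_lac]]
    if (length(cand) == 0L) next
    add <- if (length(cand) == 1L) cand else sample(cand, 1)
    flags2 <- flags; flags2[add] <- TRUE
    after <- nlp_subtype(flags2, ffp_alone_qualifies = TRUE)
    for (lb in labels) {
      lost <- before[[lb]] && !after[[lb]]
      if (lb == "trauma") {
        # only the guarded laceration route may be lost
        expect_true(!lost || identical(before$evidence$trauma, "laceration"))
      } else {
        expect_false(lost)
      }
    }
  }
})

test_that("ICD code wildcard matching follows the dotted-prefix semantics", {
  expect_true(code_matches("666.14", "666.1x"))
  expect_false(code_matches("666.24", "666.1x"))
  expect_true(code_matches("664.3", "664.x"))
  expect_true(code_matches("666.14", "666.x"))
  expect_false(code_matches("666.1", "666.1x"))   # wildcard needs a digit
  expect_true(code_matches("666.145", "666.1x"))  # extension through trailing x
  expect_false(code_matches("66.14", "666.1x"))
  expect_false(code_matches("666.1a", "666.1x"))
  expect_true(code_matches("650", "650"))         # no wildcard: exact only
  expect_false(code_matches("650.1", "650"))
  expect_error(code_matches("666.14", "6x6.1"), "malformed")
})

test_that("ICD subtyping matches a brute-force oracle over a 10-code universe", {
  universe <- c("666.04", "666.12", "666.14", "666.32", "665.5", "665.11",
                "664.1", "664.31", "650.0", "999.9")
  for (m in 0:(2^10 - 1)) {
    codes <- universe[as.logical(bitwAnd(m, 2^(0:9)))]
    got <- icd_subtype(codes)
    want <- oracle_icd_subtype(codes)
    expect_identical(list(tone = got$tone, tissue = got$tissue,
                          trauma = got$trauma, thrombin = got$thrombin),
                     want)
  }
  # the printed guard cases
  expect_true(icd_subtype("664.1")$trauma)
  r <- icd_subtype(c("664.1", "666.14"))
  expect_true(r$tone); expect_false(r$trauma)
  # 665.x trauma holds regardless of 666 codes
  expect_true(icd_subtype(c("665.5", "666.14"))$trauma)
})

test_that("subtype prevalence fractions agree with a recount", {
  set.seed(71)
  results <- tibble::tibble(tone = runif(10) < 0.5, tissue = runif(10) < 0.5,
                            trauma = runif(10) < 0.5, thrombin = runif(10) < 0.5)
  results$tone[1:3] <- TRUE
  tab <- subtype_prevalence(results)
  for (lb in tab$subtype) {
    expect_equal(tab$fraction[tab$subtype == lb], mean(results[[lb]]))
  }
  expect_warning(subtype_prevalence(list()), "empty")
  all_false <- tibble::tibble(tone = rep(FALSE, 4), tissue = FALSE,
                              trauma = FALSE, thrombin = FALSE)
  expect_true(all(subtype_prevalence(all_false)$fraction == 0))
})
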