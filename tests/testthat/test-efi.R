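test_that("lf_side is the minimum of the three organ ratings", {
  expect_identical(lf_side(4, 4, 4), 4L)
  expect_identical(lf_side(4, 3, 1), 1L)
  expect_identical(lf_side(0, 4, 4), 0L)
  expect_error(lf_side(5, 4, 4), class = "efindex_validation_error")
  expect_error(lf_side(-1, 4, 4), class = "efindex_validation_error")
})

test_that("lf_total sums sides and doubles when one ovary is absent", {
  both4 <- function_scores(left = c(tube = 4, fimbria = 4, ovary = 4),
                           right = c(tube = 4, fimbria = 4, ovary = 4))
  expect_identical(lf_total(both4), 8L)

  # right ovary absent, left side score 3 -> doubled to 6
  one_absent <- function_scores(
    left = c(tube = 3, fimbria = 4, ovary = 3),
    right = c(tube = 4, fimbria = 4, ovary = 0),
    ovary_present = c(left = TRUE, right = FALSE))
  expect_identical(lf_total(one_absent), 6L)

  zeros <- function_scores(left = c(tube = 0, fimbria = 2, ovary = 1),
                           right = c(tube = 1, fimbria = 0, ovary = 4))
  expect_identical(lf_total(zeros), 0L)

  expect_error(function_scores(
    left = c(tube = 4, fimbria = 4, ovary = 0),
    right = c(tube = 4, fimbria = 4, ovary = 0),
    ovary_present = c(left = FALSE, right = FALSE)),
    class = "efindex_validation_error")
})

test_that("efi_score matches the rubric on the two hand-applied cases", {
  h <- clinical_history(32, 2, TRUE)
  r <- efi_score(h, 8, list(lesion_score = 10, total_score = 30))
  expect_identical(r$total, 10L)
  expect_identical(r$historical_points, 5L)
  expect_identical(r$surgical_points, 5L)
  expect_true(r$high_group)

  h2 <- clinical_history(41, 8, FALSE)
  r2 <- efi_score(h2, 2, list(lesion_score = 20, total_score = 75))
  expect_identical(r2$total, 0L)
  expect_false(r2$high_group)
})

test_that("band edges are inclusive toward the higher-scoring band", {
  afs <- list(lesion_score = 0, total_score = 10)
  expect_identical(efi_score(clinical_history(35, 5, FALSE), 0, afs)$total,
                   efi_score(clinical_history(30, 5, FALSE), 0, afs)$total)
  expect_identical(efi_score(clinical_history(45, 3, FALSE), 0, afs)$total,
                   efi_score(clinical_history(45, 1, FALSE), 0, afs)$total)
  # and just past the edge the score drops
  expect_lt(efi_score(clinical_history(36, 5, FALSE), 0, afs)$total,
            efi_score(clinical_history(35, 5, FALSE), 0, afs)$total)
  expect_lt(efi_score(clinical_history(45, 3.1, FALSE), 0, afs)$total,
            efi_score(clinical_history(45, 3, FALSE), 0, afs)$total)
})

test_that("efi_score equals the literal band oracle exhaustively", {
  ages <- c(25, 35, 36, 39, 40, 47)
  durations <- c(0, 3, 3.5, 9)
  lfs <- 0:8
  lesions <- c(0, 15, 16, 50)
  totals <- c(1, 70, 71, 120)
  for (age in ages) for (dur in durations) for (preg in c(TRUE, FALSE)) {
    h <- clinical_history(age, dur, preg)
    for (lf in lfs) for (les in lesions) for (tot in totals) {
      got <- efi_score(h, lf, list(lesion_score = les, total_score = tot))
      expect_identical(got$total,
                       as.integer(oracle_efi(age, dur, preg, lf, les, tot)))
      expect_true(got$total >= 0L && got$total <= 10L)
      expect_true(got$historical_points <= 5L && got$surgical_points <= 5L)
    }
  }
})

test_that("improving any single input never decreases the EFI", {
  set.seed(7)
  for (i in 1:100) {
    age <- runif(1, 25, 45); dur <- runif(1, 0, 10)
    preg <- runif(1) < 0.5; lf <- sample(0:8, 1)
    les <- sample(0:40, 1); tot <- sample(1:100, 1)
    base <- efi_score(clinical_history(age, dur, preg), lf,
                      list(lesion_score = les, total_score = tot))$total
    better <- list(
      efi_score(clinical_history(max(age - 6, 16), dur, preg), lf,
                list(lesion_score = les, total_score = tot))$total,
      efi_score(clinical_history(age, max(dur - 4, 0), preg), lf,
                list(lesion_score = les, total_score = tot))$total,
      efi_score(clinical_history(age, dur, TRUE), lf,
                list(lesion_score = les, total_score = tot))$total,
      efi_score(clinical_history(age, dur, preg), min(lf + 2, 8),
                list(lesion_score = les, total_score = tot))$total,
      efi_score(clinical_history(age, dur, preg), lf,
                list(lesion_score = 0, total_score = tot))$total,
      efi_score(clinical_history(age, dur, preg), lf,
                list(lesion_score = les, total_score = 1))$total)
    for (b in better) expect_gte(b, base)
  }
})

test_that("function_scores feeds efi_score with per-side LF detail", {
  fs <- function_scores(left = c(tube = 4, fimbria = 3, ovary = 4),
                        right = c(tube = 2, fimbria = 4, ovary = 3))
  r <- efi_score(clinical_history(30, 2, FALSE), fs,
                 list(lesion_score = 4, total_score = 12))
  expect_identical(r$lf_left, 3L)
  expect_identical(r$lf_right, 2L)
  expect_identical(r$lf_total, 5L)
  expect_identical(r$surgical_points, 2L + 1L + 1L)
})

test_that("suggested ratings are valid and respond to adhesions", {
  clean <- suggest_function_ratings(surgical_findings())
  expect_identical(lf_total(clean), 8L)
  scarred <- suggest_function_ratings(surgical_findings(
    adhesions = data.frame(organ = "tube", side = "left", kind = "dense",
                           enclosure = "gt_two_thirds",
                           fimbria_enclosed = TRUE)))
  expect_lt(lf_total(scarred), 8L)
  expect_identical(lf_side(scarred$left[["tube"]], scarred$left[["fimbria"]],
                           scarred$left[["ovary"]]), 1L)
})

test_that("clinical_history validates and warns on implausible age", {
  expect_warning(clinical_history(60, 1, FALSE), "reproductive range")
  expect_error(clinical_history(-1, 1, FALSE),
               class = "efindex_validation_error")
  expect_error(clinical_history(30, -2, FALSE),
               class = "efindex_validation_error")
})
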