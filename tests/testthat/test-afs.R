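test_that("lesion scoring matches hand lookups on the 1985 form", {
  expect_identical(score_lesions(surgical_findings()), 0L)

  f <- surgical_findings(
    lesions = data.frame(site = "ovary_left", depth = "deep", size_cm = 2.5),
    culdesac = "partial")
  expect_identical(score_lesions(f), 20L)  # 16 + 4

  f <- surgical_findings(
    lesions = data.frame(site = c("peritoneum", "peritoneum"),
                         depth = c("superficial", "deep"),
                         size_cm = c(0.5, 4)))
  expect_identical(score_lesions(f), 7L)   # 1 + 6
})

test_that("adhesion scoring matches hand lookups incl. fimbria override", {
  expect_identical(score_adhesions(surgical_findings()), 0L)

  f <- surgical_findings(adhesions = data.frame(
    organ = c("ovary", "tube"), side = "right",
    kind = c("dense", "filmy"),
    enclosure = c("gt_two_thirds", "lt_one_third")))
  expect_identical(score_adhesions(f), 17L)  # 16 + 1

  f <- surgical_findings(adhesions = data.frame(
    organ = "tube", side = "left", kind = "dense",
    enclosure = "one_to_two_thirds", fimbria_enclosed = TRUE))
  expect_identical(score_adhesions(f), 16L)  # override, not 8
})

test_that("stage is a step function with breakpoints 5/6, 15/16, 40/41", {
  expect_identical(afs_stage(c(5, 6, 16, 41)), c("I", "II", "III", "IV"))
  totals <- 1:60
  stages <- afs_stage(totals)
  expect_identical(stages, ifelse(totals > 40, "IV",
                           ifelse(totals > 15, "III",
                           ifelse(totals > 5, "II", "I"))))
  expect_warning(s0 <- afs_stage(0), "no endometriosis")
  expect_true(is.na(s0))
})

test_that("afs_score assembles components and the stage correctly", {
  f <- surgical_findings(
    lesions = data.frame(site = "ovary_left", depth = "deep", size_cm = 2.5),
    adhesions = data.frame(
      organ = c("ovary", "tube"), side = "right",
      kind = c("dense", "filmy"),
      enclosure = c("gt_two_thirds", "lt_one_third")),
    culdesac = "partial")
  res <- afs_score(f)
  expect_identical(res$lesion_score, 20L)
  expect_identical(res$adhesion_score, 17L)
  expect_identical(res$total_score, 37L)
  expect_identical(res$stage, "III")
  expect_true(res$advanced)
  # convention switch: lesion score without cul-de-sac points
  res2 <- afs_score(f, lesion_score_includes_culdesac = FALSE)
  expect_identical(res2$lesion_score, 16L)
  expect_identical(res2$total_score, 37L)  # total always includes them
})

test_that("scores equal the brute-force oracle over the literal table", {
  set.seed(41)
  for (i in 1:200) {
    r <- random_findings()
    f <- surgical_findings(r$lesions, r$adhesions, r$culdesac)
    o <- oracle_afs(r$lesions, r$adhesions, r$culdesac)
    # an empty random record legitimately warns about stage 0
    res <- suppressWarnings(afs_score(f))
    expect_equal(res$implant_points + res$culdesac_points, o$implant + o$culdesac)
    expect_equal(res$adhesion_score, o$adhesion)
    expect_equal(res$total_score, o$total)
  }
})

test_that("every single-category finding matches the oracle table exactly", {
  for (site in c("peritoneum", "ovary_left", "ovary_right")) {
    for (depth in c("superficial", "deep")) {
      for (cm in c(0.5, 2, 5)) {
        f <- surgical_findings(data.frame(site = site, depth = depth,
                                          size_cm = cm))
        g <- if (site == "peritoneum") "peritoneum" else "ovary"
        expect_identical(score_lesions(f),
                         as.integer(oracle_implant_points[[
                           paste(g, depth, oracle_size_band(cm))]]))
      }
    }
  }
  for (organ in c("ovary", "tube")) {
    for (kind in c("filmy", "dense")) {
      for (enc in c("lt_one_third", "one_to_two_thirds", "gt_two_thirds")) {
        f <- surgical_findings(adhesions = data.frame(
          organ = organ, side = "left", kind = kind, enclosure = enc))
        expect_identical(score_adhesions(f),
                         as.integer(oracle_adhesion_points[[
                           paste(organ, kind, enc)]]))
      }
    }
  }
})

test_that("adding a finding never decreases any score", {
  set.seed(42)
  for (i in 1:60) {
    r <- random_findings()
    f1 <- surgical_findings(r$lesions, r$adhesions, r$culdesac)
    extra_les <- data.frame(site = sample(c("peritoneum", "ovary_left"), 1),
                            depth = sample(c("superficial", "deep"), 1),
                            size_cm = round(runif(1, 0.2, 5), 2))
    f2 <- surgical_findings(rbind(r$lesions, extra_les), r$adhesions,
                            r$culdesac)
    expect_gte(score_lesions(f2), score_lesions(f1))
    extra_adh <- data.frame(organ = "tube", side = "left", kind = "dense",
                            enclosure = "lt_one_third",
                            fimbria_enclosed = FALSE)
    f3 <- surgical_findings(r$lesions, rbind(r$adhesions, extra_adh),
                            r$culdesac)
    expect_gte(score_adhesions(f3), score_adhesions(f1))
  }
})

test_that("multiple lesions in one category score the largest only", {
  f <- surgical_findings(data.frame(
    site = "peritoneum", depth = "deep", size_cm = c(0.5, 2, 4)))
  expect_identical(score_lesions(f), 6L)  # worst band only, not 2+4+6
})

test_that("validation rejects inconsistent records", {
  expect_error(surgical_findings(
    data.frame(site = "ovary_left", depth = "deep", size_cm = 2),
    ovary_present = c(left = FALSE, right = TRUE)),
    class = "efindex_validation_error")
  expect_error(surgical_findings(adhesions = data.frame(
    organ = "ovary", side = "right", kind = "dense",
    enclosure = "lt_one_third"),
    ovary_present = c(left = TRUE, right = FALSE)),
    class = "efindex_validation_error")
  expect_error(surgical_findings(adhesions = data.frame(
    organ = "ovary", side = "left", kind = "dense",
    enclosure = "lt_one_third", fimbria_enclosed = TRUE)),
    class = "efindex_validation_error")
  expect_error(surgical_findings(
    data.frame(site = "peritoneum", depth = "deep", size_cm = -1)),
    class = "efindex_validation_error")
  expect_error(surgical_findings(ovary_present = c(left = FALSE, right = FALSE)),
    class = "efindex_validation_error")
})

test_that("duplicate adhesions canonicalize to the single worst", {
  f <- surgical_findings(adhesions = data.frame(
    organ = "ovary", side = "left", kind = "dense",
    enclosure = c("lt_one_third", "gt_two_thirds")))
  expect_identical(nrow(f$adhesions), 1L)
  expect_identical(score_adhesions(f), 16L)
})
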