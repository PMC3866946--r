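#' Per-side organ function ratings
#'
#' Surgeon-assigned function ratings for the fallopian tube, tubal fimbria
#' and ovary on each side, on the 0--4 scale of the least-function rubric
#' (4 = normal, 3 = mild dysfunction, 2 = moderate, 1 = severe,
#' 0 = absent or nonfunctional). Ratings are required inputs: they are
#' rated directly at surgery, never inferred from lesion/adhesion records
#' (see [suggest_function_ratings()] for an explicit, opt-in helper).
#'
#' @param left,right Numeric vectors `c(tube = , fimbria = , ovary = )`
#'   with integer ratings in 0--4.
#' @param ovary_present Named logical `c(left = , right = )`; an absent
#'   ovary triggers the contralateral doubling rule in [lf_total()].
#' @return An object of class `function_scores`.
#' @export
#' @examples
#' fs <- function_scores(left = c(tube = 4, fimbria = 3, ovary = 4),
#'                       right = c(tube = 2, fimbria = 2, ovary = 3))
#' lf_total(fs)
function_scores <- function(left, right,
                            ovary_present = c(left = TRUE, right = TRUE)) {
  check_side <- function(x, nm) {
    if (!all(c("tube", "fimbria", "ovary") %in% names(x))) {
      stop_validation(sprintf("`%s` needs named ratings tube/fimbria/ovary", nm))
    }
    x <- x[c("tube", "fimbria", "ovary")]
    if (any(!is.finite(x)) || any(x < 0) || any(x > 4) || any(x != round(x))) {
      stop_validation(sprintf("`%s` ratings must be integers in 0..4", nm))
    }
    x
  }
  left <- check_side(left, "left")
  right <- check_side(right, "right")
  ovary_present <- ovary_present[c("left", "right")]
  if (!any(ovary_present)) {
    stop_validation("both ovaries absent: least-function score undefined")
  }
  structure(list(left = left, right = right,
                 ovary_present = as.logical(ovary_present) |>
                   stats::setNames(c("left", "right"))),
            class = "function_scores")
}

#' Least-function score of one side
#'
#' The side score is the minimum of the tube, fimbria and ovary ratings.
#'
#' @param tube,fimbria,ovary Integer ratings in 0--4 (vectorised).
#' @return Integer vector in 0--4.
#' @export
lf_side <- function(tube, fimbria, ovary) {
  r <- cbind(tube, fimbria, ovary)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 4)) {
    stop_validation("function ratings must lie in 0..4")
  }
  as.integer(pmin(tube, fimbria, ovary))
}

#' Total least-function (LF) score
#'
#' LF = left side score + right side score, where each side score is the
#' minimum of that side's tube, fimbria and ovary ratings. If one ovary is
#' absent, the LF score is twice the contralateral side score; if both are
#' absent the LF score is undefined (error).
#'
#' @param scores A [function_scores()] object.
#' @return Integer in 0--8.
#' @export
lf_total <- function(scores) {
  stopifnot(inherits(scores, "function_scores"))
  op <- scores$ovary_present
  sides <- vapply(c("left", "right"), function(s) {
    x <- scores[[s]]
    lf_side(x[["tube"]], x[["fimbria"]], x[["ovary"]])
  }, integer(1))
  if (all(op)) {
    sides[["left"]] + sides[["right"]]
  } else if (op[["left"]]) {
    2L * sides[["left"]]
  } else {
    2L * sides[["right"]]
  }
}

#' Clinical history record
#'
#' @param age_years Age at cycle start (years).
#' @param infertility_years Duration of infertility (years).
#' @param prior_pregnancy Any prior pregnancy (gravidity > 0, counting
#'   ectopics, miscarriages and abortions), logical.
#' @return An object of class `clinical_history`.
#' @export
clinical_history <- function(age_years, infertility_years, prior_pregnancy) {
  if (!is.finite(age_years) || age_years <= 0) {
    stop_validation("`age_years` must be a positive number")
  }
  if (age_years < 15 || age_years > 55) {
    warning("age outside the plausible reproductive range 15-55", call. = FALSE)
  }
  if (!is.finite(infertility_years) || infertility_years < 0) {
    stop_validation("`infertility_years` must be non-negative")
  }
  structure(list(age_years = age_years,
                 infertility_years = infertility_years,
                 prior_pregnancy = isTRUE(as.logical(prior_pregnancy))),
            class = "clinical_history")
}

# EFI rubric bands (vectorised). Band edges are inclusive on the
# higher-scoring side: age exactly 35 scores 2, duration exactly 3 y
# scores 2, matching the form's "<=35" / "<=3" wording.
efi_age_points      <- function(age) ifelse(age <= 35, 2L, ifelse(age < 40, 1L, 0L))
efi_duration_points <- function(years) ifelse(years <= 3, 2L, 0L)
efi_pregnancy_points <- function(prior) ifelse(prior, 1L, 0L)
efi_lf_points       <- function(lf) ifelse(lf >= 7, 3L, ifelse(lf >= 4, 2L, 0L))
efi_lesion_points   <- function(lesion_score) ifelse(lesion_score < 16, 1L, 0L)
efi_total_afs_points <- function(total_score) ifelse(total_score < 71, 1L, 0L)

#' Endometriosis Fertility Index
#'
#' Combines historical factors (age, duration of infertility, prior
#' pregnancy; up to 5 points) with surgical factors (least-function score,
#' r-AFS lesion-score band, r-AFS total-score band; up to 5 points) into
#' the 0--10 EFI. Higher scores predict better fecundity.
#'
#' Rubric: age \eqn{\le} 35 scores 2, 36--39 scores 1, \eqn{\ge} 40 scores
#' 0; infertility \eqn{\le} 3 years scores 2, longer 0; any prior
#' pregnancy 1; LF 7--8 scores 3, 4--6 scores 2, 0--3 scores 0; r-AFS
#' lesion score < 16 scores 1; r-AFS total score < 71 scores 1.
#'
#' @param history A [clinical_history()] object.
#' @param lf Either a [function_scores()] object or an integer LF total in
#'   0--8.
#' @param afs An [afs_score()] result (or a list with `lesion_score` and
#'   `total_score`).
#' @return An `efi_result` list with per-side LF scores, `lf_total`,
#'   `historical_points`, `surgical_points`, `total` (0--10) and the
#'   dichotomized `high_group` flag (EFI \eqn{\ge} 6).
#' @export
#' @examples
#' h <- clinical_history(32, 2, TRUE)
#' efi_score(h, lf = 8, afs = list(lesion_score = 10, total_score = 30))
efi_score <- function(history, lf, afs) {
  stopifnot(inherits(history, "clinical_history"))
  lf_l <- lf_r <- NA_integer_
  if (inherits(lf, "function_scores")) {
    lf_l <- lf_side(lf$left[["tube"]], lf$left[["fimbria"]], lf$left[["ovary"]])
    lf_r <- lf_side(lf$right[["tube"]], lf$right[["fimbria"]], lf$right[["ovary"]])
    lf <- lf_total(lf)
  }
  if (!is.finite(lf) || lf < 0 || lf > 8 || lf != round(lf)) {
    stop_validation("LF total must be an integer in 0..8")
  }
  if (!all(c("lesion_score", "total_score") %in% names(afs))) {
    stop_validation("`afs` must carry lesion_score and total_score")
  }
  hist_pts <- efi_age_points(history$age_years) +
    efi_duration_points(history$infertility_years) +
    efi_pregnancy_points(history$prior_pregnancy)
  surg_pts <- efi_lf_points(lf) +
    efi_lesion_points(afs$lesion_score) +
    efi_total_afs_points(afs$total_score)
  total <- as.integer(hist_pts + surg_pts)
  structure(list(lf_left = lf_l, lf_right = lf_r, lf_total = as.integer(lf),
                 historical_points = as.integer(hist_pts),
                 surgical_points = as.integer(surg_pts),
                 total = total, high_group = total >= 6L),
            class = "efi_result")
}

#' @export
print.efi_result <- function(x, ...) {
  cat(sprintf("EFI = %d (historical %d + surgical %d), LF total %d; group %s\n",
              x$total, x$historical_points, x$surgical_points, x$lf_total,
              if (x$high_group) ">=6" else "<=5"))
  invisible(x)
}

#' Suggest function ratings from surgical findings (opt-in helper)
#'
#' Heuristic mapping from recorded adhesions to candidate 0--4 function
#' ratings: no adhesion suggests 4 (normal); a filmy adhesion lowers the
#' suggestion by its enclosure band (to 3/3/2); a dense adhesion lowers it
#' to 3/2/1; a tubal adhesion with completely enclosed fimbria suggests 1
#' for tube and fimbria. The suggestion is never applied automatically --
#' ratings are surgeon-assigned inputs; this exists only to draft ratings
#' for records that lack them, for the user to review.
#'
#' @param findings A [surgical_findings()] object.
#' @return A [function_scores()] object with the suggested ratings.
#' @export
suggest_function_ratings <- function(findings) {
  stopifnot(inherits(findings, "surgical_findings"))
  adh <- findings$adhesions
  drop_for <- function(organ, side) {
    rows <- adh[adh$organ == organ & adh$side == side, , drop = FALSE]
    if (!nrow(rows)) return(0L)
    band <- match(rows$enclosure, .afs_enclosures)
    max(ifelse(rows$kind == "dense", band, c(1L, 1L, 2L)[band]))
  }
  one_side <- function(side) {
    t_drop <- drop_for("tube", side)
    o_drop <- drop_for("ovary", side)
    fimb_enc <- any(adh$organ == "tube" & adh$side == side & adh$fimbria_enclosed)
    tube <- max(4L - t_drop, if (fimb_enc) 1L else 1L)
    tube <- if (fimb_enc) min(tube, 1L) else tube
    fimbria <- if (fimb_enc) 1L else max(4L - t_drop, 1L)
    ovary <- if (!findings$ovary_present[[side]]) 0L else max(4L - o_drop, 1L)
    c(tube = max(tube, 1L), fimbria = fimbria, ovary = ovary)
  }
  function_scores(left = one_side("left"), right = one_side("right"),
                  ovary_present = findings$ovary_present)
}
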