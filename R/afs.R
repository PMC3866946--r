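#' r-AFS point tables
#'
#' Literal point tables of the revised American Fertility Society (1985)
#' endometriosis classification form, stored as plain data frames so the
#' values themselves are reviewable. Implant points depend on site
#' (peritoneum vs ovary), depth (superficial vs deep) and the size band of
#' the largest implant in that category; adhesion points depend on organ
#' (ovary vs tube), type (filmy vs dense) and the enclosure band. Size
#' bands are `< 1` cm, `1--3` cm and `> 3` cm (band edges 1 and 3 cm fall
#' in the middle band); enclosure bands are `< 1/3`, `1/3--2/3` and
#' `> 2/3` of the organ enclosed. A tubal adhesion whose fimbriated end is
#' completely enclosed is re-assigned 16 points regardless of its band.
#' Cul-de-sac obliteration scores 4 (partial) or 40 (complete).
#'
#' @return A data frame of point values.
#' @seealso [afs_score()]
#' @export
#' @examples
#' afs_implant_points()
afs_implant_points <- function() {
  data.frame(
    site      = rep(c("peritoneum", "ovary"), each = 6L),
    depth     = rep(rep(c("superficial", "deep"), each = 3L), 2L),
    size_band = rep(c("lt_1cm", "1_to_3cm", "gt_3cm"), 4L),
    points    = c(1L, 2L, 4L,   2L, 4L, 6L,    # peritoneum
                  1L, 2L, 4L,   4L, 16L, 20L), # each ovary
    stringsAsFactors = FALSE
  )
}

#' @rdname afs_implant_points
#' @export
afs_adhesion_points <- function() {
  data.frame(
    organ     = rep(c("ovary", "tube"), each = 6L),
    kind      = rep(rep(c("filmy", "dense"), each = 3L), 2L),
    enclosure = rep(c("lt_one_third", "one_to_two_thirds", "gt_two_thirds"), 4L),
    points    = c(1L, 2L, 4L,   4L, 8L, 16L,   # each ovary
                  1L, 2L, 4L,   4L, 8L, 16L),  # each tube
    stringsAsFactors = FALSE
  )
}

#' @rdname afs_implant_points
#' @export
afs_culdesac_points <- function() {
  data.frame(culdesac = c("none", "partial", "complete"),
             points = c(0L, 4L, 40L), stringsAsFactors = FALSE)
}

.afs_sites       <- c("peritoneum", "ovary_left", "ovary_right")
.afs_depths      <- c("superficial", "deep")
.afs_organs      <- c("ovary", "tube")
.afs_sides       <- c("left", "right")
.afs_kinds       <- c("filmy", "dense")
.afs_enclosures  <- c("lt_one_third", "one_to_two_thirds", "gt_two_thirds")
.afs_culdesacs   <- c("none", "partial", "complete")

# size in cm -> band label of the 1985 form (1 and 3 cm sit in the middle band)
.afs_size_band <- function(size_cm) {
  ifelse(size_cm < 1, "lt_1cm", ifelse(size_cm <= 3, "1_to_3cm", "gt_3cm"))
}

# vectorised implant-point lookup; site may be peritoneum/ovary_left/ovary_right
.afs_implant_lookup <- function(site, depth, size_cm) {
  tab <- afs_implant_points()
  generic_site <- ifelse(site == "peritoneum", "peritoneum", "ovary")
  key <- paste(generic_site, depth, .afs_size_band(size_cm))
  tab_key <- paste(tab$site, tab$depth, tab$size_band)
  tab$points[match(key, tab_key)]
}

# vectorised adhesion-point lookup with the fimbria override
.afs_adhesion_lookup <- function(organ, kind, enclosure, fimbria_enclosed) {
  tab <- afs_adhesion_points()
  key <- paste(organ, kind, enclosure)
  pts <- tab$points[match(key, paste(tab$organ, tab$kind, tab$enclosure))]
  ifelse(organ == "tube" & fimbria_enclosed %in% TRUE, 16L, pts)
}

#' Assemble and validate one patient's laparoscopic findings
#'
#' @param lesions `NULL` or a data frame with columns `site` (one of
#'   `"peritoneum"`, `"ovary_left"`, `"ovary_right"`), `depth`
#'   (`"superficial"` or `"deep"`) and `size_cm` (largest diameter, cm,
#'   strictly positive).
#' @param adhesions `NULL` or a data frame with columns `organ` (`"ovary"`
#'   or `"tube"`), `side` (`"left"`/`"right"`), `kind` (`"filmy"`/`"dense"`),
#'   `enclosure` (`"lt_one_third"`, `"one_to_two_thirds"`,
#'   `"gt_two_thirds"`) and optionally `fimbria_enclosed` (logical;
#'   meaningful for tubes only). Duplicate rows per (organ, side, kind) are
#'   canonicalized to the single worst (highest-scoring) one.
#' @param culdesac Cul-de-sac obliteration: `"none"`, `"partial"` or
#'   `"complete"`.
#' @param ovary_present Named logical `c(left = , right = )`. A lesion or
#'   adhesion recorded on an absent ovary is a validation error.
#'
#' @return An object of class `surgical_findings`.
#' @export
#' @examples
#' f <- surgical_findings(
#'   lesions = data.frame(site = "ovary_left", depth = "deep", size_cm = 2.5),
#'   culdesac = "partial"
#' )
#' afs_score(f)
surgical_findings <- function(lesions = NULL, adhesions = NULL,
                              culdesac = "none",
                              ovary_present = c(left = TRUE, right = TRUE)) {
  empty_lesions <- data.frame(site = character(), depth = character(),
                              size_cm = numeric(), stringsAsFactors = FALSE)
  empty_adh <- data.frame(organ = character(), side = character(),
                          kind = character(), enclosure = character(),
                          fimbria_enclosed = logical(),
                          stringsAsFactors = FALSE)
  if (is.null(lesions) || nrow(lesions) == 0L) lesions <- empty_lesions
  if (is.null(adhesions) || nrow(adhesions) == 0L) adhesions <- empty_adh
  lesions <- as.data.frame(lesions, stringsAsFactors = FALSE)
  adhesions <- as.data.frame(adhesions, stringsAsFactors = FALSE)
  if (is.null(adhesions$fimbria_enclosed)) {
    adhesions$fimbria_enclosed <- rep(FALSE, nrow(adhesions))
  }
  adhesions$fimbria_enclosed[is.na(adhesions$fimbria_enclosed)] <- FALSE

  if (!all(c("left", "right") %in% names(ovary_present))) {
    stop_validation("`ovary_present` must be a named logical c(left=, right=)")
  }
  ovary_present <- ovary_present[c("left", "right")]
  if (!any(ovary_present)) {
    stop_validation("both ovaries absent: findings invalid for this cohort")
  }
  if (length(culdesac) != 1L || !culdesac %in% .afs_culdesacs) {
    stop_validation(sprintf("`culdesac` must be one of %s",
                            paste(.afs_culdesacs, collapse = ", ")))
  }

  bad <- function(what, i) {
    stop_validation(sprintf("%s in %s row(s) %s", what,
                            if (grepl("ovary|site|depth|size", what)) "lesions" else "adhesions",
                            paste(i, collapse = ", ")))
  }
  if (nrow(lesions)) {
    i <- which(!lesions$site %in% .afs_sites)
    if (length(i)) bad("invalid lesion site", i)
    i <- which(!lesions$depth %in% .afs_depths)
    if (length(i)) bad("invalid lesion depth", i)
    i <- which(!is.finite(lesions$size_cm) | lesions$size_cm <= 0)
    if (length(i)) bad("non-positive lesion size_cm", i)
    for (s in c("left", "right")) {
      if (!ovary_present[[s]]) {
        i <- which(lesions$site == paste0("ovary_", s))
        if (length(i)) bad(sprintf("lesion on absent %s ovary", s), i)
      }
    }
  }
  if (nrow(adhesions)) {
    chk <- list(organ = .afs_organs, side = .afs_sides, kind = .afs_kinds,
                enclosure = .afs_enclosures)
    for (col in names(chk)) {
      i <- which(!adhesions[[col]] %in% chk[[col]])
      if (length(i)) {
        stop_validation(sprintf("invalid adhesion %s in row(s) %s",
                                col, paste(i, collapse = ", ")))
      }
    }
    i <- which(adhesions$organ == "ovary" & adhesions$fimbria_enclosed)
    if (length(i)) {
      stop_validation(sprintf(
        "fimbria_enclosed set on ovarian adhesion row(s) %s (tube only)",
        paste(i, collapse = ", ")))
    }
    for (s in c("left", "right")) {
      if (!ovary_present[[s]]) {
        i <- which(adhesions$organ == "ovary" & adhesions$side == s)
        if (length(i)) {
          stop_validation(sprintf("adhesion on absent %s ovary in row(s) %s",
                                  s, paste(i, collapse = ", ")))
        }
      }
    }
    # canonicalize: keep the worst adhesion per (organ, side, kind)
    pts <- .afs_adhesion_lookup(adhesions$organ, adhesions$kind,
                                adhesions$enclosure,
                                adhesions$fimbria_enclosed)
    ord <- order(adhesions$organ, adhesions$side, adhesions$kind, -pts)
    adhesions <- adhesions[ord, , drop = FALSE]
    keep <- !duplicated(adhesions[c("organ", "side", "kind")])
    adhesions <- adhesions[keep, , drop = FALSE]
    rownames(adhesions) <- NULL
  }

  structure(list(lesions = lesions, adhesions = adhesions,
                 culdesac = culdesac,
                 ovary_present = as.logical(ovary_present) |>
                   stats::setNames(c("left", "right"))),
            class = "surgical_findings")
}

#' r-AFS implant (lesion) points
#'
#' Sums implant points over site-by-depth categories, scoring in each
#' category only the single largest implant (the form scores disease
#' extent per category, not per lesion), plus cul-de-sac obliteration
#' points (partial 4, complete 40).
#'
#' @param findings A [surgical_findings()] object.
#' @param include_culdesac Add cul-de-sac points (default `TRUE`). The
#'   total r-AFS score always includes them; this switch only matters when
#'   extracting the "lesion score" fed to the EFI band.
#' @return Non-negative integer points.
#' @export
score_lesions <- function(findings, include_culdesac = TRUE) {
  stopifnot(inherits(findings, "surgical_findings"))
  les <- findings$lesions
  implant <- 0L
  if (nrow(les)) {
    pts <- .afs_implant_lookup(les$site, les$depth, les$size_cm)
    implant <- sum(tapply(pts, paste(les$site, les$depth), max))
  }
  cds <- afs_culdesac_points()
  cd <- cds$points[match(findings$culdesac, cds$culdesac)]
  as.integer(implant + if (include_culdesac) cd else 0L)
}

#' r-AFS adhesion points
#'
#' Sums adhesion points over (organ, side): filmy 1/2/4 and dense 4/8/16
#' by enclosure band for each ovary and each tube; a tubal adhesion with
#' completely enclosed fimbria scores 16 regardless of band.
#'
#' @inheritParams score_lesions
#' @return Non-negative integer points.
#' @export
score_adhesions <- function(findings) {
  stopifnot(inherits(findings, "surgical_findings"))
  adh <- findings$adhesions
  if (!nrow(adh)) return(0L)
  as.integer(sum(.afs_adhesion_lookup(adh$organ, adh$kind, adh$enclosure,
                                      adh$fimbria_enclosed)))
}

#' Map an r-AFS total score to stage I--IV
#'
#' Step function with breakpoints 5/6, 15/16 and 40/41: stage I = 1--5,
#' II = 6--15, III = 16--40, IV = > 40. A total of 0 ("no endometriosis
#' scored") has undefined stage and returns `NA` with a warning; for this
#' cohort it signals inconsistent input.
#'
#' @param total_score Non-negative integer vector.
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"` or `NA`.
#' @export
afs_stage <- function(total_score) {
  if (any(total_score < 0)) stop_validation("negative r-AFS total score")
  out <- ifelse(total_score > 40, "IV",
         ifelse(total_score >= 16, "III",
         ifelse(total_score >= 6, "II",
         ifelse(total_score >= 1, "I", NA_character_))))
  if (anyNA(out)) {
    warning("total_score = 0: no endometriosis scored, stage undefined",
            call. = FALSE)
  }
  out
}

#' Full r-AFS scoring of one patient
#'
#' @inheritParams score_lesions
#' @param lesion_score_includes_culdesac Convention switch for the lesion
#'   score reported to the EFI: whether cul-de-sac obliteration points are
#'   part of it (default `TRUE`). The total score always includes them.
#' @return An `afs_result` list with `implant_points`, `culdesac_points`,
#'   `lesion_score`, `adhesion_score`, `total_score`, `stage` and the
#'   dichotomized `advanced` flag (stage III--IV).
#' @export
#' @examples
#' f <- surgical_findings(
#'   lesions = data.frame(site = c("peritoneum", "peritoneum"),
#'                        depth = c("superficial", "deep"),
#'                        size_cm = c(0.5, 4)))
#' afs_score(f)
afs_score <- function(findings, lesion_score_includes_culdesac = TRUE) {
  implant <- score_lesions(findings, include_culdesac = FALSE)
  cds <- afs_culdesac_points()
  culdesac <- cds$points[match(findings$culdesac, cds$culdesac)]
  adhesion <- score_adhesions(findings)
  total <- as.integer(implant + culdesac + adhesion)
  stage <- if (total == 0L) {
    warning("total_score = 0: no endometriosis scored, stage undefined",
            call. = FALSE)
    NA_character_
  } else afs_stage(total)
  structure(list(
    implant_points = implant,
    culdesac_points = as.integer(culdesac),
    lesion_score = as.integer(implant +
      if (lesion_score_includes_culdesac) culdesac else 0L),
    adhesion_score = adhesion,
    total_score = total,
    stage = stage,
    advanced = isTRUE(stage %in% c("III", "IV"))
  ), class = "afs_result")
}

#' @export
print.afs_result <- function(x, ...) {
  cat("r-AFS score\n")
  cat(sprintf("  implants %d + cul-de-sac %d + adhesions %d = total %d\n",
              x$implant_points, x$culdesac_points, x$adhesion_score,
              x$total_score))
  cat(sprintf("  lesion score (for EFI band): %d\n", x$lesion_score))
  cat(sprintf("  stage: %s%s\n", if (is.na(x$stage)) "undefined" else x$stage,
              if (x$advanced) " (advanced, III-IV)" else ""))
  invisible(x)
}
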