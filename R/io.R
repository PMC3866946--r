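# ---- schema-validated CSV readers -------------------------------------
#
# All patient tables are plain CSV with documented headers. The surgical
# table is long format, one row per finding:
#   patient_id, record_type (lesion | adhesion | culdesac), site, side,
#   depth_or_kind, size_or_enclosure, fimbria_enclosed
# where for a lesion row `site` is peritoneum/ovary_left/ovary_right,
# `depth_or_kind` is superficial/deep and `size_or_enclosure` is the size
# in cm; for an adhesion row `site` is the organ (ovary/tube), `side` is
# left/right, `depth_or_kind` is filmy/dense and `size_or_enclosure` is
# the enclosure band; for a culdesac row `size_or_enclosure` is
# none/partial/complete and the other detail columns are empty.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_validation(sprintf("%s: missing column(s) %s", basename(path),
                            paste(missing_cols, collapse = ", ")))
  }
  df
}

.offenders <- function(path, what, rows) {
  if (!length(rows)) return(invisible())
  stop_validation(sprintf("%s: %s in row(s) %s", basename(path), what,
                          paste(utils::head(rows, 10), collapse = ", ")))
}

#' Read and validate pipeline CSV tables
#'
#' Each reader checks the header, types and value ranges and rejects
#' malformed rows with line-numbered messages (row numbers refer to data
#' rows, header excluded).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @name cohort_io
#' @export
read_clinical_csv <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "age_years",
                                  "infertility_years", "prior_pregnancy"))
  .offenders(path, "duplicate patient_id",
             which(duplicated(df$patient_id)))
  .offenders(path, "non-positive age_years",
             which(!is.finite(df$age_years) | df$age_years <= 0))
  .offenders(path, "negative infertility_years",
             which(!is.finite(df$infertility_years) | df$infertility_years < 0))
  .offenders(path, "prior_pregnancy not 0/1",
             which(!df$prior_pregnancy %in% c(0, 1)))
  if (any(df$age_years < 15 | df$age_years > 55)) {
    warning("age outside the plausible reproductive range 15-55",
            call. = FALSE)
  }
  df
}

#' @rdname cohort_io
#' @export
read_surgical_csv <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "record_type", "site", "side",
                                  "depth_or_kind", "size_or_enclosure",
                                  "fimbria_enclosed"))
  df$size_or_enclosure <- as.character(df$size_or_enclosure)
  .offenders(path, "invalid record_type",
             which(!df$record_type %in% c("lesion", "adhesion", "culdesac")))
  les <- df$record_type == "lesion"
  adh <- df$record_type == "adhesion"
  cds <- df$record_type == "culdesac"
  size <- suppressWarnings(as.numeric(df$size_or_enclosure))
  .offenders(path, "invalid lesion site",
             which(les & !df$site %in% .afs_sites))
  .offenders(path, "invalid lesion depth",
             which(les & !df$depth_or_kind %in% .afs_depths))
  .offenders(path, "non-positive lesion size_cm",
             which(les & (!is.finite(size) | size <= 0)))
  .offenders(path, "invalid adhesion organ",
             which(adh & !df$site %in% .afs_organs))
  .offenders(path, "invalid adhesion side",
             which(adh & !df$side %in% .afs_sides))
  .offenders(path, "invalid adhesion kind",
             which(adh & !df$depth_or_kind %in% .afs_kinds))
  .offenders(path, "invalid adhesion enclosure",
             which(adh & !df$size_or_enclosure %in% .afs_enclosures))
  .offenders(path, "fimbria_enclosed set on non-tube adhesion",
             which(adh & df$site != "tube" &
                     df$fimbria_enclosed %in% c("TRUE", "true", "1")))
  .offenders(path, "invalid culdesac status",
             which(cds & !df$size_or_enclosure %in% .afs_culdesacs))
  cds_rows <- which(cds)
  .offenders(path, "more than one culdesac row per patient",
             cds_rows[duplicated(df$patient_id[cds_rows])])
  df
}

#' @rdname cohort_io
#' @export
read_ratings_csv <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "side", "tube", "fimbria",
                                  "ovary", "ovary_present"))
  .offenders(path, "invalid side", which(!df$side %in% .afs_sides))
  .offenders(path, "duplicate (patient_id, side)",
             which(duplicated(df[c("patient_id", "side")])))
  for (col in c("tube", "fimbria", "ovary")) {
    .offenders(path, sprintf("%s rating outside 0..4", col),
               which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 4 |
                       df[[col]] != round(df[[col]])))
  }
  .offenders(path, "ovary_present not logical/0-1",
             which(!df$ovary_present %in% c(TRUE, FALSE, 0, 1,
                                            "TRUE", "FALSE", "true", "false")))
  df$ovary_present <- df$ovary_present %in% c(TRUE, 1, "TRUE", "true")
  bad_pid <- setdiff(unique(df$patient_id),
                     df$patient_id[df$side == "left"])
  bad_pid <- union(bad_pid, setdiff(unique(df$patient_id),
                                    df$patient_id[df$side == "right"]))
  if (length(bad_pid)) {
    stop_validation(sprintf("%s: patient(s) %s lack one side's ratings",
                            basename(path),
                            paste(utils::head(bad_pid, 10), collapse = ", ")))
  }
  df
}

#' @rdname cohort_io
#' @export
read_cycles_csv <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "oocytes", "fert_2pn",
                                  "cleaved", "transferred", "implanted",
                                  "clinical_pregnancy",
                                  "cumulative_pregnancy"))
  .offenders(path, "duplicate patient_id", which(duplicated(df$patient_id)))
  for (col in c("oocytes", "fert_2pn", "cleaved", "transferred", "implanted")) {
    .offenders(path, sprintf("negative or non-integer %s", col),
               which(!is.finite(df[[col]]) | df[[col]] < 0 |
                       df[[col]] != round(df[[col]])))
  }
  for (col in c("clinical_pregnancy", "cumulative_pregnancy")) {
    .offenders(path, sprintf("%s not 0/1", col),
               which(!df[[col]] %in% c(0, 1)))
  }
  .offenders(path, "implanted exceeds transferred",
             which(df$implanted > df$transferred))
  df
}

# ---- vectorised cohort scoring ----------------------------------------

#' Score a whole cohort (r-AFS and EFI)
#'
#' Vectorised scoring of every patient in the three input tables. The
#' result is identical, patient by patient, to assembling each record
#' with [surgical_findings()] / [function_scores()] and calling
#' [afs_score()] and [efi_score()] (a tested equivalence), but runs in
#' O(rows) for large simulated cohorts.
#'
#' @param clinical Data frame as from [read_clinical_csv()].
#' @param surgical Long-format findings as from [read_surgical_csv()].
#' @param ratings Function ratings as from [read_ratings_csv()].
#' @param lesion_score_includes_culdesac Whether the EFI lesion-score band
#'   uses implant + cul-de-sac points (default) or implant points only.
#' @return Data frame with one row per patient: r-AFS components
#'   (`implant_points`, `culdesac_points`, `lesion_score`,
#'   `adhesion_score`, `total_score`, `stage`, `advanced`), the LF scores
#'   and the EFI decomposition (`efi_historical`, `efi_surgical`, `efi`,
#'   `efi_high`).
#' @export
score_cohort <- function(clinical, surgical, ratings,
                         lesion_score_includes_culdesac = TRUE) {
  pid <- clinical$patient_id
  n <- length(pid)
  if (anyDuplicated(pid)) stop_validation("duplicate patient_id in clinical")

  rat_l <- ratings[ratings$side == "left", ]
  rat_r <- ratings[ratings$side == "right", ]
  il <- match(pid, rat_l$patient_id)
  ir <- match(pid, rat_r$patient_id)
  if (anyNA(il) || anyNA(ir)) {
    stop_validation("every patient needs left and right function ratings")
  }
  ovp_l <- rat_l$ovary_present[il]
  ovp_r <- rat_r$ovary_present[ir]
  if (any(!ovp_l & !ovp_r)) {
    stop_validation(sprintf("both ovaries absent for patient(s) %s",
      paste(utils::head(pid[!ovp_l & !ovp_r], 10), collapse = ", ")))
  }

  les <- surgical[surgical$record_type == "lesion", ]
  adh <- surgical[surgical$record_type == "adhesion", ]
  cds <- surgical[surgical$record_type == "culdesac", ]

  # absent-ovary consistency between the surgical record and the ratings
  for (s in c("left", "right")) {
    absent <- pid[!(if (s == "left") ovp_l else ovp_r)]
    bad <- unique(c(
      les$patient_id[les$site == paste0("ovary_", s) &
                       les$patient_id %in% absent],
      adh$patient_id[adh$site == "ovary" & adh$side == s &
                       adh$patient_id %in% absent]))
    if (length(bad)) {
      stop_validation(sprintf(
        "lesion/adhesion recorded on absent %s ovary for patient(s) %s",
        s, paste(utils::head(bad, 10), collapse = ", ")))
    }
  }

  implant <- stats::setNames(numeric(n), pid)
  if (nrow(les)) {
    size <- as.numeric(les$size_or_enclosure)
    pts <- .afs_implant_lookup(les$site, les$depth_or_kind, size)
    # worst lesion per patient x site x depth category, then sum per patient
    worst <- tapply(pts, paste(les$patient_id, les$site, les$depth_or_kind,
                               sep = "\r"), max)
    worst_pid <- vapply(strsplit(names(worst), "\r", fixed = TRUE),
                        `[[`, character(1), 1L)
    agg <- rowsum(as.numeric(worst), worst_pid)
    implant[rownames(agg)] <- agg[, 1]
  }

  culdesac_status <- stats::setNames(rep("none", n), pid)
  if (nrow(cds)) culdesac_status[as.character(cds$patient_id)] <-
    cds$size_or_enclosure
  cd_tab <- afs_culdesac_points()
  culdesac_pts <- cd_tab$points[match(culdesac_status, cd_tab$culdesac)]

  adhesion <- stats::setNames(numeric(n), pid)
  if (nrow(adh)) {
    fimb <- adh$fimbria_enclosed %in% c(TRUE, "TRUE", "true", 1, "1")
    pts <- .afs_adhesion_lookup(adh$site, adh$depth_or_kind,
                                adh$size_or_enclosure, fimb)
    # canonicalize: worst adhesion per patient x organ x side x kind
    worst <- tapply(pts, paste(adh$patient_id, adh$site, adh$side,
                               adh$depth_or_kind, sep = "\r"), max)
    worst_pid <- vapply(strsplit(names(worst), "\r", fixed = TRUE),
                        `[[`, character(1), 1L)
    agg <- rowsum(as.numeric(worst), worst_pid)
    adhesion[rownames(agg)] <- agg[, 1]
  }

  implant <- as.integer(implant)
  adhesion <- as.integer(adhesion)
  total <- implant + as.integer(culdesac_pts) + adhesion
  lesion_score <- implant +
    if (lesion_score_includes_culdesac) as.integer(culdesac_pts) else 0L
  stage <- suppressWarnings(afs_stage(total))
  if (anyNA(stage)) {
    warning(sprintf("%d patient(s) scored 0 (no endometriosis): stage NA",
                    sum(is.na(stage))), call. = FALSE)
  }

  lf_l <- lf_side(rat_l$tube[il], rat_l$fimbria[il], rat_l$ovary[il])
  lf_r <- lf_side(rat_r$tube[ir], rat_r$fimbria[ir], rat_r$ovary[ir])
  lf <- ifelse(ovp_l & ovp_r, lf_l + lf_r,
               ifelse(ovp_l, 2L * lf_l, 2L * lf_r))

  hist_pts <- efi_age_points(clinical$age_years) +
    efi_duration_points(clinical$infertility_years) +
    efi_pregnancy_points(clinical$prior_pregnancy == 1)
  surg_pts <- efi_lf_points(lf) + efi_lesion_points(lesion_score) +
    efi_total_afs_points(total)
  efi <- as.integer(hist_pts + surg_pts)

  data.frame(patient_id = pid,
             implant_points = implant,
             culdesac_points = as.integer(culdesac_pts),
             lesion_score = as.integer(lesion_score),
             adhesion_score = adhesion,
             total_score = total,
             stage = stage,
             stage_numeric = match(stage, c("I", "II", "III", "IV")),
             advanced = stage %in% c("III", "IV"),
             lf_left = lf_l, lf_right = lf_r, lf_total = as.integer(lf),
             efi_historical = as.integer(hist_pts),
             efi_surgical = as.integer(surg_pts),
             efi = efi, efi_high = efi >= 6L)
}

# ---- cohort bundle read/write ----------------------------------------

#' Write / read a cohort bundle of CSV tables
#'
#' `write_cohort()` emits `clinical.csv`, `surgical.csv`, `ratings.csv`
#' and `cycles.csv` (plus `truth.json` for synthetic cohorts) into a
#' directory; `read_cohort()` loads and re-validates them. A written
#' bundle round-trips through its own reader.
#'
#' @param cohort An `efindex_cohort` (or a plain list with the same
#'   data-frame elements).
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_cohort()` the directory path, invisibly;
#'   `read_cohort()` a list of validated data frames.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("clinical", "surgical", "ratings", "cycles")) {
    utils::write.csv(cohort[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth[c("beta0", "beta1", "seed")]
    truth$achieved_rates <- as.list(cohort$truth$achieved_rates)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(clinical = read_clinical_csv(file.path(dir, "clinical.csv")),
       surgical = read_surgical_csv(file.path(dir, "surgical.csv")),
       ratings = read_ratings_csv(file.path(dir, "ratings.csv")),
       cycles = read_cycles_csv(file.path(dir, "cycles.csv")))
}
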