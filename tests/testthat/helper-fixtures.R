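# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# independent literal r-AFS point tables, re-keyed by hand from the 1985
# form; deliberately NOT derived from the package's own tables
oracle_implant_points <- c(
  "peritoneum superficial lt_1cm"   = 1,
  "peritoneum superficial 1_to_3cm" = 2,
  "peritoneum superficial gt_3cm"   = 4,
  "peritoneum deep lt_1cm"          = 2,
  "peritoneum deep 1_to_3cm"        = 4,
  "peritoneum deep gt_3cm"          = 6,
  "ovary superficial lt_1cm"        = 1,
  "ovary superficial 1_to_3cm"      = 2,
  "ovary superficial gt_3cm"        = 4,
  "ovary deep lt_1cm"               = 4,
  "ovary deep 1_to_3cm"             = 16,
  "ovary deep gt_3cm"               = 20)

oracle_adhesion_points <- c(
  "ovary filmy lt_one_third"      = 1,
  "ovary filmy one_to_two_thirds" = 2,
  "ovary filmy gt_two_thirds"     = 4,
  "ovary dense lt_one_third"      = 4,
  "ovary dense one_to_two_thirds" = 8,
  "ovary dense gt_two_thirds"     = 16,
  "tube filmy lt_one_third"       = 1,
  "tube filmy one_to_two_thirds"  = 2,
  "tube filmy gt_two_thirds"      = 4,
  "tube dense lt_one_third"       = 4,
  "tube dense one_to_two_thirds"  = 8,
  "tube dense gt_two_thirds"      = 16)

oracle_size_band <- function(cm) {
  if (cm < 1) "lt_1cm" else if (cm <= 3) "1_to_3cm" else "gt_3cm"
}

# brute-force scorer over the oracle tables: per (site, depth) keep the
# single worst implant, sum adhesions with fimbria override
oracle_afs <- function(lesions, adhesions, culdesac = "none") {
  implant <- 0
  if (!is.null(lesions) && nrow(lesions)) {
    site_g <- ifelse(lesions$site == "peritoneum", "peritoneum", "ovary")
    pts <- oracle_implant_points[paste(site_g, lesions$depth,
      vapply(lesions$size_cm, oracle_size_band, character(1)))]
    implant <- sum(tapply(pts, paste(lesions$site, lesions$depth), max))
  }
  adhesion <- 0
  if (!is.null(adhesions) && nrow(adhesions)) {
    if (is.null(adhesions$fimbria_enclosed)) {
      adhesions$fimbria_enclosed <- FALSE
    }
    pts <- ifelse(adhesions$organ == "tube" & adhesions$fimbria_enclosed,
                  16,
                  oracle_adhesion_points[paste(adhesions$organ,
                    adhesions$kind, adhesions$enclosure)])
    # worst per organ-side-kind (canonicalization)
    adhesion <- sum(tapply(pts, paste(adhesions$organ, adhesions$side,
                                      adhesions$kind), max))
  }
  cd <- c(none = 0, partial = 4, complete = 40)[[culdesac]]
  list(implant = implant, adhesion = adhesion,
       total = implant + adhesion + cd, culdesac = cd)
}

# random valid findings record (both ovaries present so everything is legal)
random_findings <- function() {
  n_les <- sample(0:4, 1)
  lesions <- if (n_les) data.frame(
    site = sample(c("peritoneum", "ovary_left", "ovary_right"), n_les, TRUE),
    depth = sample(c("superficial", "deep"), n_les, TRUE),
    size_cm = round(stats::runif(n_les, 0.1, 6), 2)) else NULL
  n_adh <- sample(0:4, 1)
  adhesions <- if (n_adh) {
    organ <- sample(c("ovary", "tube"), n_adh, TRUE)
    data.frame(
      organ = organ,
      side = sample(c("left", "right"), n_adh, TRUE),
      kind = sample(c("filmy", "dense"), n_adh, TRUE),
      enclosure = sample(c("lt_one_third", "one_to_two_thirds",
                           "gt_two_thirds"), n_adh, TRUE),
      fimbria_enclosed = organ == "tube" & stats::runif(n_adh) < 0.2)
  } else NULL
  culdesac <- sample(c("none", "partial", "complete"), 1)
  list(lesions = lesions, adhesions = adhesions, culdesac = culdesac)
}

# independent EFI rubric lookup (literal bands, re-keyed by hand)
oracle_efi <- function(age, years, prior, lf, lesion, total) {
  pts_age <- if (age <= 35) 2 else if (age <= 39) 1 else 0
  pts_dur <- if (years <= 3) 2 else 0
  pts_preg <- if (prior) 1 else 0
  pts_lf <- if (lf >= 7) 3 else if (lf >= 4) 2 else 0
  pts_les <- if (lesion < 16) 1 else 0
  pts_tot <- if (total < 71) 1 else 0
  pts_age + pts_dur + pts_preg + pts_lf + pts_les + pts_tot
}

# brute-force AUC by pair counting (concordant + half ties)
oracle_auc_pairs <- function(index, outcome) {
  pos <- index[outcome]; neg <- index[!outcome]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# the printed Table 3 pregnancy 2x2 (index = EFI >= 6, outcome = pregnancy)
paper_pregnancy_table <- function() two_by_two(61, 54, 24, 60)
# the Table 1 pilot 2x2 (EFI >= 6 vs pregnancy, n = 161)
paper_pilot_table <- function() two_by_two(44, 47, 23, 47)
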