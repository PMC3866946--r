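# deterministic substream seed per generation block, so adding draws to one
# block never perturbs another; kept below 2^31 - 1
.substream <- function(seed, k) {
  m <- 2147483629
  # exact in doubles: (m-1) * 69069 + k * 1234567 < 2^53
  as.integer(((as.double(seed) %% m) * 69069 + k * 1234567) %% m)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulation configuration for a synthetic endometriosis IVF cohort
#'
#' The defaults state the world the generator emulates: a post-surgical
#' endometriosis cohort entering a first fresh IVF cycle, with age
#' 32.0 +/- 4.2 years, infertility duration with median 5 years (IQR
#' roughly 3--7, log-normal family), about a third of patients with any
#' prior pregnancy, laparoscopic lesion/adhesion frequencies that yield a
#' majority of advanced (stage III--IV) disease, and a clinical-pregnancy
#' probability increasing in the EFI through
#' `logit P(pregnancy) = beta0 + beta1 * EFI`, calibrated by default so
#' the EFI <= 5 and EFI >= 6 groups have pregnancy rates of about 28.6%
#' and 53.0%.
#'
#' @param n_patients Cohort size (>= 2).
#' @param seed Master seed (mandatory; drives one substream per table).
#' @param age_mean,age_sd Normal age distribution (years).
#' @param infertility_median,infertility_iqr Log-normal duration of
#'   infertility: the median is matched exactly, the IQR ratio sets the
#'   log-scale SD.
#' @param prior_pregnancy_prob P(any prior pregnancy).
#' @param ovary_absent_prob Per-side probability of a surgically absent
#'   ovary (never both; the left is retained if both are drawn absent).
#' @param lesion_probs Named occurrence probabilities
#'   `peritoneum_superficial`, `peritoneum_deep`, `ovary_superficial`,
#'   `ovary_deep` (ovarian entries are per present side).
#' @param culdesac_probs Probabilities of none/partial/complete
#'   cul-de-sac obliteration.
#' @param adhesion_probs Named: `ovary`, `tube` (per-side occurrence),
#'   `dense_ovary`, `dense_tube` (P(dense | adhesion)),
#'   `fimbria_enclosed` (P(completely enclosed fimbria | dense tubal
#'   adhesion)).
#' @param enclosure_probs Probabilities of the three enclosure bands.
#' @param coupling Couple function ratings to adhesion severity (default
#'   `TRUE`), so EFI and r-AFS are realistically correlated.
#' @param rating_noise_prob Probability of one extra rating point lost to
#'   unmodelled dysfunction.
#' @param target_rates Pregnancy rates `c(low, high)` for the EFI <= 5
#'   and >= 6 groups used to calibrate `(beta0, beta1)`.
#' @param efi_cutoff Cut-off defining the two EFI groups (default 6).
#' @param beta Optional `c(beta0, beta1)` override; skips calibration.
#' @param cumulative_boost P(pregnancy in a later freeze-thaw cycle |
#'   fresh cycle failed).
#' @param lesion_score_includes_culdesac Convention switch passed through
#'   to the r-AFS scorer.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 199L, seed,
                       age_mean = 32.0, age_sd = 4.2,
                       infertility_median = 5.0,
                       infertility_iqr = c(3.0, 7.0),
                       prior_pregnancy_prob = 0.32,
                       ovary_absent_prob = 0.02,
                       lesion_probs = c(peritoneum_superficial = 0.75,
                                        peritoneum_deep = 0.30,
                                        ovary_superficial = 0.25,
                                        ovary_deep = 0.28),
                       culdesac_probs = c(none = 0.55, partial = 0.30,
                                          complete = 0.15),
                       adhesion_probs = c(ovary = 0.5, tube = 0.4,
                                          dense_ovary = 0.45,
                                          dense_tube = 0.5,
                                          fimbria_enclosed = 0.15),
                       enclosure_probs = c(0.40, 0.35, 0.25),
                       coupling = TRUE, rating_noise_prob = 0.15,
                       target_rates = c(low = 0.286, high = 0.530),
                       efi_cutoff = 6L, beta = NULL,
                       cumulative_boost = 22 / 114,
                       lesion_score_includes_culdesac = TRUE) {
  if (missing(seed) || !is.finite(seed)) {
    stop_validation("`seed` is mandatory for reproducibility")
  }
  if (!is.finite(n_patients) || n_patients < 2) {
    stop_validation("`n_patients` must be >= 2")
  }
  probs <- c(prior_pregnancy_prob, ovary_absent_prob, lesion_probs,
             culdesac_probs, adhesion_probs, enclosure_probs,
             rating_noise_prob, cumulative_boost)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_validation("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(culdesac_probs) - 1) > 1e-8 ||
      abs(sum(enclosure_probs) - 1) > 1e-8) {
    stop_validation("culdesac_probs and enclosure_probs must each sum to 1")
  }
  if (ovary_absent_prob >= 1) {
    stop_validation("ovary_absent_prob = 1 would remove both ovaries")
  }
  if (!is.null(beta) && length(beta) != 2L) {
    stop_validation("`beta` must be c(beta0, beta1)")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd,
    infertility_median = infertility_median,
    infertility_iqr = infertility_iqr,
    prior_pregnancy_prob = prior_pregnancy_prob,
    ovary_absent_prob = ovary_absent_prob,
    lesion_probs = lesion_probs, culdesac_probs = culdesac_probs,
    adhesion_probs = adhesion_probs, enclosure_probs = enclosure_probs,
    coupling = isTRUE(coupling), rating_noise_prob = rating_noise_prob,
    target_rates = stats::setNames(as.numeric(target_rates), c("low", "high")),
    efi_cutoff = as.integer(efi_cutoff), beta = beta,
    cumulative_boost = cumulative_boost,
    lesion_score_includes_culdesac = isTRUE(lesion_score_includes_culdesac)
  ), class = "sim_config")
}

#' Calibrate the logistic outcome model to target group rates
#'
#' Finds `(beta0, beta1)` such that, over a given EFI distribution, the
#' expected pregnancy rate `mean(plogis(beta0 + beta1 * EFI))` equals the
#' low target in the EFI < cutoff group and the high target in the
#' EFI >= cutoff group. Deterministic damped Newton iteration with
#' analytic Jacobian, to within `tol` on both rates.
#'
#' @param target_rates `c(low, high)` rates in (0, 1); `beta1` is
#'   constrained positive, so `high < low` is an error and
#'   `high == low` returns `beta1 = 0` exactly.
#' @param efi_values Integer vector of EFI scores (the distribution to
#'   calibrate over); both groups must be non-empty.
#' @param cutoff Group cut-off (default 6).
#' @param tol Convergence tolerance on the group rates.
#' @return List with `beta0`, `beta1`, `achieved` (the two fitted rates)
#'   and `iterations`.
#' @export
#' @examples
#' calibrate_outcome_model(c(0.286, 0.530), rep(2:9, times = c(3, 5, 10,
#'   15, 25, 60, 50, 30)))
calibrate_outcome_model <- function(target_rates, efi_values, cutoff = 6L,
                                    tol = 1e-10) {
  t_lo <- target_rates[[1]]; t_hi <- target_rates[[2]]
  if (any(!is.finite(c(t_lo, t_hi))) || t_lo <= 0 || t_lo >= 1 ||
      t_hi <= 0 || t_hi >= 1) {
    stop_validation("target rates must lie strictly in (0, 1)")
  }
  e_lo <- efi_values[efi_values < cutoff]
  e_hi <- efi_values[efi_values >= cutoff]
  if (!length(e_lo) || !length(e_hi)) {
    stop_validation("both EFI groups must be non-empty for calibration")
  }
  if (t_hi < t_lo) {
    stop_validation(paste("non-monotone targets: high-group rate below",
                          "low-group rate with beta1 constrained positive"))
  }
  if (t_hi == t_lo) {
    return(list(beta0 = stats::qlogis(t_lo), beta1 = 0,
                achieved = c(low = t_lo, high = t_hi), iterations = 0L))
  }
  rates <- function(b) {
    c(mean(stats::plogis(b[1] + b[2] * e_lo)),
      mean(stats::plogis(b[1] + b[2] * e_hi)))
  }
  b <- c(stats::qlogis((t_lo + t_hi) / 2) - 0.3 * mean(efi_values), 0.3)
  g <- rates(b) - c(t_lo, t_hi)
  iter <- 0L
  while (max(abs(g)) > tol && iter < 200L) {
    iter <- iter + 1L
    p_lo <- stats::plogis(b[1] + b[2] * e_lo)
    p_hi <- stats::plogis(b[1] + b[2] * e_hi)
    jac <- rbind(c(mean(p_lo * (1 - p_lo)), mean(e_lo * p_lo * (1 - p_lo))),
                 c(mean(p_hi * (1 - p_hi)), mean(e_hi * p_hi * (1 - p_hi))))
    if (abs(det(jac)) < 1e-14) stop("singular Jacobian in calibration")
    step <- solve(jac, g)
    # damped update: halve the step until the residual improves
    lambda <- 1
    repeat {
      b_new <- b - lambda * step
      g_new <- rates(b_new) - c(t_lo, t_hi)
      if (sum(g_new^2) <= sum(g^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    b <- b_new; g <- g_new
  }
  if (max(abs(g)) > 1e-6) stop("calibration failed to converge")
  if (b[2] < 0) {
    stop_validation("calibration produced beta1 < 0 for monotone targets")
  }
  list(beta0 = b[1], beta1 = b[2],
       achieved = stats::setNames(rates(b), c("low", "high")),
       iterations = iter)
}

# severity of the worst adhesion per organ-side: 0 none, filmy 1/1/2 by
# enclosure band, dense 1/2/3; used for the rating coupling
.adhesion_severity <- function(present, dense, band) {
  ifelse(!present, 0L,
         ifelse(dense, band, c(1L, 1L, 2L)[band]))
}

#' Generate a synthetic endometriosis IVF cohort
#'
#' Emits every table the analysis pipeline consumes -- clinical history,
#' long-format surgical findings, per-side function ratings and IVF cycle
#' outcomes -- together with the ground-truth per-patient scores and the
#' outcome-model coefficients, so recovery tests can check every stage.
#' Deterministic given `config$seed`; each table is drawn from its own
#' substream.
#'
#' @param config A [sim_config()].
#' @return An object of class `efindex_cohort`: list with data frames
#'   `clinical`, `surgical`, `ratings`, `cycles`, `scores` and a list
#'   `truth` (`beta0`, `beta1`, achieved calibration rates, seed).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 50, seed = 7))
#' head(cohort$scores)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  pid <- seq_len(n)
  sdlog_inf <- log(config$infertility_iqr[2] / config$infertility_iqr[1]) /
    (2 * stats::qnorm(0.75))

  clinical <- .with_seed(.substream(config$seed, 1L), {
    data.frame(
      patient_id = pid,
      age_years = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
      infertility_years = round(stats::rlnorm(n, log(config$infertility_median),
                                              sdlog_inf), 1),
      prior_pregnancy = stats::rbinom(n, 1, config$prior_pregnancy_prob),
      bmi = round(stats::rlnorm(n, log(20.2), 0.107), 1),
      basal_fsh = round(stats::rlnorm(n, log(8.1), 0.29), 1),
      basal_lh = round(stats::rlnorm(n, log(3.8), 0.53), 1),
      basal_e2 = round(stats::rlnorm(n, log(42.4), 0.61), 1)
    )
  })
  clinical$age_years <- pmin(pmax(clinical$age_years, 20), 47)

  anatomy <- .with_seed(.substream(config$seed, 2L), {
    left <- stats::rbinom(n, 1, 1 - config$ovary_absent_prob) == 1
    right <- stats::rbinom(n, 1, 1 - config$ovary_absent_prob) == 1
    left[!left & !right] <- TRUE  # never both absent
    cbind(left = left, right = right)
  })

  lesions <- .with_seed(.substream(config$seed, 3L), {
    lp <- config$lesion_probs
    blocks <- list()
    add <- function(blocks, site, present, depth, size) {
      if (!any(present)) return(blocks)
      c(blocks, list(data.frame(
        patient_id = pid[present], record_type = "lesion", site = site,
        side = "", depth_or_kind = depth,
        size_or_enclosure = as.character(round(size[present], 2)),
        fimbria_enclosed = "", stringsAsFactors = FALSE)))
    }
    ps <- stats::rbinom(n, 1, lp[["peritoneum_superficial"]]) == 1
    pd <- stats::rbinom(n, 1, lp[["peritoneum_deep"]]) == 1
    os <- od <- list()
    for (s in c("left", "right")) {
      os[[s]] <- stats::rbinom(n, 1, lp[["ovary_superficial"]]) == 1 &
        anatomy[, s]
      od[[s]] <- stats::rbinom(n, 1, lp[["ovary_deep"]]) == 1 & anatomy[, s]
    }
    # histologically confirmed endometriosis: every patient has at least one
    # implant, so a patient drawn with none gets a small superficial
    # peritoneal lesion
    none <- !(ps | pd | os$left | os$right | od$left | od$right)
    ps <- ps | none
    blocks <- add(blocks, "peritoneum", ps, "superficial",
                  pmax(stats::rgamma(n, 1.5, scale = 1), 0.1))
    blocks <- add(blocks, "peritoneum", pd, "deep",
                  pmax(stats::rgamma(n, 2, scale = 1), 0.1))
    for (s in c("left", "right")) {
      blocks <- add(blocks, paste0("ovary_", s), os[[s]], "superficial",
                    stats::runif(n, 0.2, 2))
      blocks <- add(blocks, paste0("ovary_", s), od[[s]], "deep",
                    stats::rlnorm(n, log(3), 0.5))
    }
    do.call(rbind, blocks)
  })

  culdesac <- .with_seed(.substream(config$seed, 4L), {
    status <- sample(names(config$culdesac_probs), n, replace = TRUE,
                     prob = config$culdesac_probs)
    data.frame(patient_id = pid, record_type = "culdesac", site = "",
               side = "", depth_or_kind = "", size_or_enclosure = status,
               fimbria_enclosed = "", stringsAsFactors = FALSE)
  })

  adh <- .with_seed(.substream(config$seed, 5L), {
    ap <- config$adhesion_probs
    out <- list(); sev <- list()
    for (organ in c("ovary", "tube")) {
      for (s in c("left", "right")) {
        present <- stats::rbinom(n, 1, ap[[organ]]) == 1
        if (organ == "ovary") present <- present & anatomy[, s]
        dense <- stats::rbinom(n, 1, ap[[paste0("dense_", organ)]]) == 1
        band <- sample.int(3L, n, replace = TRUE,
                           prob = config$enclosure_probs)
        fimb <- organ == "tube" & dense &
          stats::rbinom(n, 1, ap[["fimbria_enclosed"]]) == 1
        sev[[paste(organ, s)]] <- .adhesion_severity(present, dense, band)
        if (any(present)) {
          out[[paste(organ, s)]] <- data.frame(
            patient_id = pid[present], record_type = "adhesion",
            site = organ, side = s,
            depth_or_kind = ifelse(dense[present], "dense", "filmy"),
            size_or_enclosure = .afs_enclosures[band[present]],
            fimbria_enclosed = ifelse(fimb[present], "TRUE", "FALSE"),
            stringsAsFactors = FALSE)
        }
        sev[[paste(organ, s, "fimb")]] <- ifelse(present & fimb, 3L, 0L)
      }
    }
    list(rows = do.call(rbind, out), severity = sev)
  })

  surgical <- rbind(lesions, adh$rows, culdesac)
  surgical <- surgical[order(surgical$patient_id), , drop = FALSE]
  rownames(surgical) <- NULL

  ratings <- .with_seed(.substream(config$seed, 6L), {
    one_side <- function(s) {
      sev_ov <- if (config$coupling) adh$severity[[paste("ovary", s)]] else 0L
      sev_tb <- if (config$coupling) adh$severity[[paste("tube", s)]] else 0L
      sev_fb <- if (config$coupling) {
        pmax(sev_tb, adh$severity[[paste("tube", s, "fimb")]])
      } else 0L
      noise <- function() stats::rbinom(n, 1, config$rating_noise_prob)
      tube <- pmax(4L - sev_tb - noise(), 1L)
      fimbria <- pmax(4L - sev_fb - noise(), 1L)
      ovary <- ifelse(anatomy[, s], pmax(4L - sev_ov - noise(), 1L), 0L)
      data.frame(patient_id = pid, side = s, tube = tube, fimbria = fimbria,
                 ovary = ovary, ovary_present = anatomy[, s],
                 stringsAsFactors = FALSE)
    }
    out <- rbind(one_side("left"), one_side("right"))
    out[order(out$patient_id, out$side), ]
  })
  rownames(ratings) <- NULL

  scores <- score_cohort(clinical, surgical, ratings,
                         lesion_score_includes_culdesac =
                           config$lesion_score_includes_culdesac)

  if (is.null(config$beta)) {
    cal <- calibrate_outcome_model(config$target_rates, scores$efi,
                                   cutoff = config$efi_cutoff)
    beta0 <- cal$beta0; beta1 <- cal$beta1; achieved <- cal$achieved
  } else {
    beta0 <- config$beta[1]; beta1 <- config$beta[2]
    achieved <- NULL
  }

  outcome <- .with_seed(.substream(config$seed, 7L), {
    p <- stats::plogis(beta0 + beta1 * scores$efi)
    preg <- stats::rbinom(n, 1, p)
    thaw <- stats::rbinom(n, 1, config$cumulative_boost)
    list(pregnant = preg, cumulative = pmax(preg, thaw * (1 - preg) +
                                              preg * 0))
  })
  outcome$cumulative <- as.integer(outcome$pregnant == 1 | outcome$cumulative == 1)

  cycles <- .with_seed(.substream(config$seed, 8L), {
    ov <- matrix(ratings$ovary, ncol = 2, byrow = TRUE)  # left, right per pid
    afc <- pmax(1L, stats::rnbinom(n, size = 8,
                                   mu = pmax(2, 2 + 1.1 * rowSums(ov))))
    gn_start <- ifelse(afc >= 12, 150, ifelse(afc >= 7, 225, 300))
    stim_days <- pmax(7L, pmin(16L, round(stats::rnorm(n, 10.5, 1.6))))
    gn_total <- round(gn_start * stim_days * stats::runif(n, 0.85, 1.15))
    oocytes <- pmax(1L, stats::rnbinom(n, size = 5, mu = 0.85 * afc))
    fert_2pn <- stats::rbinom(n, oocytes, 0.59)
    poly <- stats::rbinom(n, oocytes - fert_2pn, 0.084 / 0.41)
    cleaved <- stats::rbinom(n, fert_2pn, 0.845)
    available <- stats::rbinom(n, cleaved, 0.85)
    transferred <- pmin(pmax(available, 1L),
                        ifelse(clinical$age_years >= 35, 3L, 2L))
    implanted <- ifelse(outcome$pregnant == 1,
                        1L + stats::rbinom(n, pmax(transferred - 1L, 0L), 0.35),
                        0L)
    data.frame(patient_id = pid, afc = afc, gn_start_iu = gn_start,
               gn_total_iu = gn_total, stim_days = stim_days,
               e2_hcg = round(stats::rlnorm(n, log(2000), 0.8), 1),
               oocytes = oocytes, fert_2pn = fert_2pn,
               polypronucleate = poly, cleaved = cleaved,
               available_embryos = available, transferred = transferred,
               implanted = implanted,
               clinical_pregnancy = outcome$pregnant,
               cumulative_pregnancy = outcome$cumulative)
  })

  structure(list(clinical = clinical, surgical = surgical, ratings = ratings,
                 cycles = cycles, scores = scores,
                 truth = list(beta0 = beta0, beta1 = beta1,
                              achieved_rates = achieved,
                              seed = config$seed, config = config)),
            class = "efindex_cohort")
}

#' @export
print.efindex_cohort <- function(x, ...) {
  n <- nrow(x$clinical)
  cat(sprintf("Synthetic endometriosis IVF cohort: %d patients (seed %d)\n",
              n, x$truth$seed))
  cat(sprintf("  outcome model: logit P = %.4f + %.4f * EFI\n",
              x$truth$beta0, x$truth$beta1))
  cat(sprintf("  EFI >= 6: %d, r-AFS III-IV: %d, pregnant (fresh): %d\n",
              sum(x$scores$efi_high), sum(x$scores$advanced),
              sum(x$cycles$clinical_pregnancy)))
  invisible(x)
}
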