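#' Truncated-normal draws
#'
#' Inverse-CDF sampler used for gestational ages and distress scores.
#' Errors when the truncation interval carries essentially no mass under the
#' parent normal (mean far outside the bounds with a tiny sd).
#'
#' @param n Number of draws.
#' @param mean,sd Parent normal parameters.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (any(upper <= lower)) {
    stop("upper bound must exceed lower bound", call. = FALSE)
  }
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  if (any(pu - pl < 1e-12)) {
    stop("impossible truncation: the interval [", lower[1], ", ", upper[1],
         "] carries no mass under N(", mean[1], ", ", sd[1], ")", call. = FALSE)
  }
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

#' Distress scale bounds
#' @return Named list of `c(lower, upper)` per scale.
#' @export
distress_bounds <- function() {
  list(ssai = c(20, 80), stai = c(20, 80), pss = c(0, 40), epds = c(0, 30))
}

brain_outcomes <- function() {
  c(paste0("vol_", c("cgm", "wm", "dgm", "hippocampus", "cerebellum", "brainstem")),
    paste0("area_", lobe_names()), paste0("lgi_", lobe_names()),
    paste0("depth_", lobe_names()))
}

global_outcomes <- function() c("area_global", "lgi_global", "depth_global")

# pre-pandemic reference growth curves (documented in the methods vignette):
# volumes (cm^3) grow exponentially with GA; folding features grow linearly.
# Anchors are cohort-level adjusted means near GA 30.4 weeks; slopes give
# realistic second-half-of-gestation trajectories.
growth_reference <- function() {
  vol_anchor <- c(cgm = 60, wm = 99, dgm = 15.5, hippocampus = 1.14,
                  cerebellum = 8.8, brainstem = 3.99)
  vol_rate <- c(cgm = 0.135, wm = 0.10, dgm = 0.10, hippocampus = 0.09,
                cerebellum = 0.13, brainstem = 0.07)
  lobe_share <- c(frontal = 0.35, parietal = 0.25, temporal = 0.25,
                  occipital = 0.15)
  list(
    vol_a = log(vol_anchor) - vol_rate * 30.4, vol_b = vol_rate,
    area_anchor = 16000, area_slope = 1150,      # mm^2 (global), per week
    lgi_anchor = 1.28, lgi_slope = 0.025,        # per week
    depth_anchor = 1.6, depth_slope = 0.12,      # mm, per week
    lobe_share = lobe_share,
    ga_anchor = 30.4
  )
}

#' Cohort specification
#'
#' The stated world of the simulator: two enrollment epochs with the study's
#' sample structure (137 pre-pandemic / 65 pandemic mothers, 33% / 42%
#' scanned twice), truncated-normal gestational ages on 16.7-39.1 weeks,
#' cohort-shifted distress scores inside the published scale bounds, and
#' additive cohort effects on tissue volumes and folding outcomes. Every
#' scan row records its generating phantom parameters as ground truth.
#'
#' @param n_subjects Named vector `c(pre = ..., pandemic = ...)`.
#' @param repeat_scan_fraction Fraction of subjects scanned twice; scalar or
#'   named per epoch.
#' @param ga_mean,ga_sd,ga_range Truncated-normal GA-at-first-scan parameters
#'   (weeks); second scans follow after a uniform 6-12 week gap capped at the
#'   upper bound.
#' @param sex_ratio Probability of a male fetus.
#' @param distress Named list per scale of `list(mean = c(pre, pandemic), sd)`.
#' @param effects Named list of additive pandemic-cohort effects:
#'   `volumes` (cm^3 per tissue), `area` (mm^2 per lobe), `lgi`, `depth` (mm),
#'   `fold_amplitude`. Zero when omitted.
#' @param resid_sd,subject_sd Named residual / between-subject SDs per outcome
#'   group; see Details in the methods vignette.
#' @param missing_distress_fraction Fraction of mothers with no distress
#'   scores (missing completely at random, all four scales together).
#' @param cortical_missing_fraction Fraction of scans whose surface
#'   reconstruction fails (folding outcomes missing).
#' @param seed Integer seed fixing all draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(pre = 137, pandemic = 65),
                        repeat_scan_fraction = c(pre = 45 / 137, pandemic = 27 / 65),
                        ga_mean = 29.5, ga_sd = 6.5,
                        ga_range = c(16.7, 39.1),
                        sex_ratio = 0.52,
                        distress = list(
                          ssai = list(mean = c(33, 35), sd = 10),
                          stai = list(mean = c(33, 35), sd = 10),
                          pss = list(mean = c(12, 16), sd = 6),
                          epds = list(mean = c(5, 8), sd = 4.5)
                        ),
                        effects = list(),
                        resid_sd = NULL, subject_sd = NULL,
                        missing_distress_fraction = 29 / 202,
                        cortical_missing_fraction = 70 / 274,
                        seed = 1L) {
  # accept list-shaped inputs (e.g. from YAML configs)
  n_subjects <- unlist(n_subjects)
  repeat_scan_fraction <- unlist(repeat_scan_fraction)
  ga_range <- unlist(ga_range)
  distress <- lapply(distress, function(d) {
    list(mean = unlist(d$mean), sd = unlist(d$sd))
  })
  effects <- lapply(effects, unlist)
  resid_sd <- lapply(resid_sd, unlist)
  subject_sd <- lapply(subject_sd, unlist)
  if (length(repeat_scan_fraction) == 1L) {
    repeat_scan_fraction <- c(pre = repeat_scan_fraction[[1]],
                              pandemic = repeat_scan_fraction[[1]])
  }
  eff0 <- list(
    volumes = setNames(numeric(6), c("cgm", "wm", "dgm", "hippocampus",
                                     "cerebellum", "brainstem")),
    area = setNames(numeric(4), lobe_names()),
    lgi = setNames(numeric(4), lobe_names()),
    depth = setNames(numeric(4), lobe_names()),
    fold_amplitude = 0
  )
  for (nm in names(effects)) {
    if (!nm %in% names(eff0)) stop("unknown effect block: ", nm, call. = FALSE)
    if (nm == "fold_amplitude") {
      eff0[[nm]] <- effects[[nm]]
    } else {
      e <- effects[[nm]]
      eff0[[nm]][names(e)] <- e
    }
  }
  resid0 <- list(
    volumes = c(cgm = 7, wm = 11, dgm = 1.8, hippocampus = 0.12,
                cerebellum = 1.1, brainstem = 0.35),
    area = 900, lgi = 0.06, depth = 0.22, global_area = 1800
  )
  subj0 <- list(
    volumes = c(cgm = 4, wm = 6, dgm = 1.0, hippocampus = 0.07,
                cerebellum = 0.6, brainstem = 0.2),
    area = 500, lgi = 0.035, depth = 0.12
  )
  for (nm in names(resid_sd)) resid0[[nm]] <- resid_sd[[nm]]
  for (nm in names(subject_sd)) subj0[[nm]] <- subject_sd[[nm]]

  spec <- list(
    n_subjects = n_subjects, repeat_scan_fraction = repeat_scan_fraction,
    ga_mean = ga_mean, ga_sd = ga_sd, ga_range = ga_range,
    sex_ratio = sex_ratio, distress = distress, effects = eff0,
    resid_sd = resid0, subject_sd = subj0,
    missing_distress_fraction = missing_distress_fraction,
    cortical_missing_fraction = cortical_missing_fraction,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  fr <- c(spec$repeat_scan_fraction, spec$missing_distress_fraction,
          spec$cortical_missing_fraction, spec$sex_ratio)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(spec$n_subjects < 1)) stop("need at least one subject per epoch", call. = FALSE)
  bounds <- distress_bounds()
  for (nm in names(spec$distress)) {
    b <- bounds[[nm]]
    if (is.null(b)) stop("unknown distress scale: ", nm, call. = FALSE)
    dd <- spec$distress[[nm]]
    for (m in dd$mean) {
      pl <- pnorm(b[1], m, dd$sd); pu <- pnorm(b[2], m, dd$sd)
      if (pu - pl < 1e-12) {
        stop("impossible truncation for ", nm, ": mean ", m, " sd ", dd$sd,
             " within [", b[1], ", ", b[2], "]", call. = FALSE)
      }
    }
  }
  spec
}

#' Simulate a two-epoch cohort of fetal MRI scans
#'
#' Draws subjects, repeat scans, gestational ages, fetal sex, distress scores
#' and parental covariates per [cohort_spec()], then generates every brain
#' outcome from the reference growth curves plus a subject-level random
#' intercept, the configured additive cohort effects, and measurement noise.
#' Each scan row also records the generating phantom parameters
#' (`true_wm_radius`, `true_fold_amplitude`, ...) so parameter-recovery tests
#' need no re-derivation, plus the true (noise-free) cohort effect sizes as
#' attributes.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per scan (class `scan_table`); attributes
#'   `effects` (the generating effect sizes) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- growth_reference()
  bounds <- distress_bounds()

  epochs <- c("pre", "pandemic")
  subj <- purrr::map_dfr(seq_along(epochs), function(e) {
    n <- spec$n_subjects[[epochs[e]]]
    tibble::tibble(
      epoch = epochs[e],
      cohort = e - 1L,
      subject_id = sprintf("%s%03d", ifelse(e == 1, "P", "C"), seq_len(n)),
      two_scans = runif(n) < spec$repeat_scan_fraction[[epochs[e]]],
      sex = ifelse(runif(n) < spec$sex_ratio, "male", "female"),
      maternal_age = round(rtruncnorm(n, 34, 4.5, 17, 51), 1),
      edu_maternal = sample(1:5, n, replace = TRUE, prob = c(.05, .1, .2, .4, .25)),
      edu_paternal = sample(1:5, n, replace = TRUE, prob = c(.05, .15, .2, .35, .25)),
      employ_maternal = rbinom(n, 1, 0.8),
      employ_paternal = rbinom(n, 1, 0.9),
      distress_missing = runif(n) < spec$missing_distress_fraction,
      subj_re = rnorm(n)
    )
  })

  # gestational ages: first scan truncated normal; optional second 6-12w later
  ga1_upper <- ifelse(subj$two_scans, spec$ga_range[2] - 6, spec$ga_range[2])
  subj$ga1 <- rtruncnorm(nrow(subj), spec$ga_mean, spec$ga_sd,
                         spec$ga_range[1], ga1_upper)
  gap_hi <- pmin(12, spec$ga_range[2] - subj$ga1)
  gap <- 6 + runif(nrow(subj)) * pmax(gap_hi - 6, 0)
  subj$ga2 <- ifelse(subj$two_scans, subj$ga1 + gap, NA_real_)

  scans <- tidyr::pivot_longer(
    subj, cols = c("ga1", "ga2"), names_to = "timepoint",
    values_to = "ga_mri_weeks", values_drop_na = TRUE
  )
  scans$timepoint <- as.integer(sub("ga", "", scans$timepoint))
  scans$scan_id <- sprintf("%s_t%d", scans$subject_id, scans$timepoint)

  n <- nrow(scans)
  # distress scores: per-scan draws around the epoch mean, missing as a block
  for (nm in names(spec$distress)) {
    dd <- spec$distress[[nm]]
    b <- bounds[[nm]]
    mu <- dd$mean[scans$cohort + 1L]
    val <- round(rtruncnorm(n, mu, dd$sd, b[1], b[2]))
    val[scans$distress_missing] <- NA_real_
    scans[[nm]] <- val
  }

  eff <- spec$effects
  pan <- scans$cohort  # 0/1
  male <- as.integer(scans$sex == "male")
  rsd <- spec$resid_sd
  ssd <- spec$subject_sd

  # tissue volumes (cm^3): exponential growth, sex and cohort shifts,
  # subject intercept shared across timepoints, residual noise; left/right
  # split near 50:50 with a stable subject-level asymmetry
  asym <- 0.5 + 0.02 * scans$subj_re
  for (ti in names(g$vol_b)) {
    base <- exp(g$vol_a[[ti]] + g$vol_b[[ti]] * scans$ga_mri_weeks)
    sexadd <- if (ti == "cgm") 1.5 * male else 0
    v <- base + sexadd + eff$volumes[[ti]] * pan +
      ssd$volumes[[ti]] * scans$subj_re +
      rnorm(n, 0, rsd$volumes[[ti]])
    v <- pmax(v, 0.05 * base)
    scans[[paste0("vol_", ti)]] <- v
    scans[[paste0("vol_", ti, "_left")]] <- v * asym
    scans[[paste0("vol_", ti, "_right")]] <- v * (1 - asym)
  }

  # folding outcomes: linear growth per lobe, area-weighted global values
  cortical_fail <- runif(n) < spec$cortical_missing_fraction
  area_global <- g$area_anchor + g$area_slope * (scans$ga_mri_weeks - g$ga_anchor)
  lobes <- lobe_names()
  area_mat <- matrix(NA_real_, n, 4, dimnames = list(NULL, lobes))
  lgi_mat <- area_mat
  depth_mat <- area_mat
  for (lb in lobes) {
    share <- g$lobe_share[[lb]]
    a <- share * (area_global + 300 * male) + eff$area[[lb]] * pan +
      ssd$area * share * scans$subj_re + rnorm(n, 0, rsd$area * share)
    l <- g$lgi_anchor + g$lgi_slope * (scans$ga_mri_weeks - g$ga_anchor) +
      eff$lgi[[lb]] * pan + ssd$lgi * scans$subj_re + rnorm(n, 0, rsd$lgi)
    dpt <- g$depth_anchor + g$depth_slope * (scans$ga_mri_weeks - g$ga_anchor) +
      eff$depth[[lb]] * pan + ssd$depth * scans$subj_re + rnorm(n, 0, rsd$depth)
    a <- pmax(a, 50)
    l <- pmax(l, 0.9)
    dpt <- pmax(dpt, 0.05)
    area_mat[, lb] <- a
    lgi_mat[, lb] <- l
    depth_mat[, lb] <- dpt
    scans[[paste0("area_", lb)]] <- ifelse(cortical_fail, NA_real_, a)
    scans[[paste0("lgi_", lb)]] <- ifelse(cortical_fail, NA_real_, l)
    scans[[paste0("depth_", lb)]] <- ifelse(cortical_fail, NA_real_, dpt)
    scans[[paste0("area_", lb, "_left")]] <-
      ifelse(cortical_fail, NA_real_, a * asym)
    scans[[paste0("area_", lb, "_right")]] <-
      ifelse(cortical_fail, NA_real_, a * (1 - asym))
    scans[[paste0("lgi_", lb, "_left")]] <-
      ifelse(cortical_fail, NA_real_, l + 0.01 * scans$subj_re)
    scans[[paste0("lgi_", lb, "_right")]] <-
      ifelse(cortical_fail, NA_real_, l - 0.01 * scans$subj_re)
    scans[[paste0("depth_", lb, "_left")]] <-
      ifelse(cortical_fail, NA_real_, dpt + 0.02 * scans$subj_re)
    scans[[paste0("depth_", lb, "_right")]] <-
      ifelse(cortical_fail, NA_real_, dpt - 0.02 * scans$subj_re)
  }
  tot_area <- rowSums(area_mat)
  scans$area_global <- ifelse(cortical_fail, NA_real_, tot_area)
  scans$lgi_global <- ifelse(cortical_fail, NA_real_,
                             rowSums(lgi_mat * area_mat) / tot_area)
  scans$depth_global <- ifelse(cortical_fail, NA_real_,
                               rowSums(depth_mat * area_mat) / tot_area)

  # ground-truth phantom parameters for each scan
  scans$true_wm_radius <- (3 * scans$vol_wm * 1000 / (4 * pi))^(1 / 3)
  lgi_true <- g$lgi_anchor + g$lgi_slope * (scans$ga_mri_weeks - g$ga_anchor) +
    eff$fold_amplitude * pan
  scans$true_fold_amplitude <- pmin(0.25, pmax(0, 0.35 * (lgi_true - 1)))
  r3 <- scans$true_wm_radius^3
  scans$true_cgm_thickness <-
    (r3 + 3 * scans$vol_cgm * 1000 / (4 * pi))^(1 / 3) - scans$true_wm_radius

  scans <- dplyr::select(scans, -dplyr::all_of(c("two_scans", "subj_re",
                                                 "distress_missing")))
  scans <- dplyr::arrange(scans, .data$cohort, .data$subject_id, .data$timepoint)
  attr(scans, "effects") <- eff
  attr(scans, "spec") <- spec
  class(scans) <- c("scan_table", class(scans))
  scans
}

#' Build the phantom specification recorded for one scan row
#'
#' @param record One row of a [simulate_cohort()] table.
#' @param spacing Voxel spacing for rendering, mm.
#' @return A [phantom_spec()] with the scan's ground-truth parameters.
#' @export
phantom_spec_for_scan <- function(record, spacing = c(1.25, 1.25, 2)) {
  stopifnot(nrow(record) == 1L)
  phantom_spec(
    wm_radius = record$true_wm_radius,
    fold_amplitude = record$true_fold_amplitude,
    cgm_thickness = record$true_cgm_thickness,
    spacing = spacing
  )
}
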