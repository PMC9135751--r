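volume_outcomes <- function() {
  paste0("vol_", c("cgm", "wm", "dgm", "hippocampus", "cerebellum", "brainstem"))
}
cortical_outcomes <- function() {
  c(paste0("area_", lobe_names()), paste0("lgi_", lobe_names()),
    paste0("depth_", lobe_names()))
}

outcome_family <- function(outcome) {
  dplyr::case_when(
    grepl("^vol_", outcome) ~ "volumes",
    grepl("^area_.*global|^lgi_.*global|^depth_.*global", outcome) ~ "global",
    grepl("^area_", outcome) ~ "area",
    grepl("^lgi_", outcome) ~ "lgi",
    grepl("^depth_", outcome) ~ "depth",
    TRUE ~ "distress"
  )
}

#' Enumerate the cohort-comparison model battery
#'
#' Expands one analysis step into its full list of GEE specifications,
#' reproducing the printed model counts exactly:
#' \describe{
#'   \item{step1 (12)}{4 distress outcomes vs cohort, in all subjects and in
#'     the low/high stratum of each measure's own threshold.}
#'   \item{step2 (90)}{18 brain outcomes (6 tissue volumes + 3 cortical
#'     features x 4 lobes) vs cohort: 18 base models adjusted for GA and sex,
#'     plus 72 further adjusted for each of the 4 distress measures.}
#'   \item{step3 (36)}{cohort comparisons inside low/high strata of the
#'     step-1-significant measures (explicit input, default PSS and EPDS):
#'     24 volume models + 12 global-feature models.}
#'   \item{distress (72)}{each of the 4 measures as a continuous predictor of
#'     the 18 brain outcomes, all subjects.}
#'   \item{interaction (12)}{GA x cohort interaction on the 12 lobar cortical
#'     features.}
#'   \item{sensitivity (180)}{the step-2 battery under two exclusions:
#'     scans before 28 weeks; mothers older than 40.}
#'   \item{laterality (36)}{the 18 outcomes fitted per hemisphere.}
#'   \item{parental (72)}{4 parental education/employment variables as
#'     predictors of the 18 outcomes.}
#' }
#' Every specification carries its FDR family (6 tissues, 4 lobes per
#' feature, or 3 global features). Enumeration is deterministic and
#' order-stable.
#'
#' @param step One of "step1", "step2", "step3", "distress", "interaction",
#'   "sensitivity", "laterality", "parental".
#' @param step3_measures Measures stratified in step 3 (the measures found
#'   cohort-associated in step 1; an explicit input so counts are stable).
#' @return Tibble of model specifications: `battery`, `model_id`, `outcome`,
#'   `rhs` (formula right side), `term` (coefficient of interest), `subset`
#'   (filter expression or NA), `fdr_family`.
#' @export
enumerate_models <- function(step, step3_measures = c("pss", "epds")) {
  measures <- c("ssai", "stai", "pss", "epds")
  thr <- distress_thresholds()
  base_rhs <- "cohort + ga_mri_weeks + sex"
  vols <- volume_outcomes()
  cort <- cortical_outcomes()
  brain <- c(vols, cort)

  specs <- switch(
    step,
    step1 = purrr::map_dfr(measures, function(m) {
      tibble::tibble(
        outcome = m,
        rhs = base_rhs,
        term = "cohort",
        subset = c(NA_character_,
                   sprintf("%s <= %g", m, thr[[m]]),
                   sprintf("%s > %g", m, thr[[m]])),
        stratum = c("all", "low", "high"),
        fdr_family = paste0("step1_", c("all", "low", "high"))
      )
    }),
    step2 = dplyr::bind_rows(
      tibble::tibble(outcome = brain, rhs = base_rhs, term = "cohort",
                     subset = NA_character_, stratum = "all",
                     fdr_family = paste0("step2_unadj_", outcome_family(brain))),
      purrr::map_dfr(measures, function(m) {
        tibble::tibble(
          outcome = brain,
          rhs = paste(base_rhs, "+", m),
          term = "cohort", subset = NA_character_, stratum = "all",
          fdr_family = paste0("step2_", m, "_", outcome_family(brain))
        )
      })
    ),
    step3 = purrr::map_dfr(step3_measures, function(m) {
      purrr::map_dfr(c("low", "high"), function(s) {
        outc <- c(vols, global_outcomes())
        tibble::tibble(
          outcome = outc, rhs = base_rhs, term = "cohort",
          subset = sprintf("%s %s %g", m, ifelse(s == "low", "<=", ">"), thr[[m]]),
          stratum = paste(s, m),
          fdr_family = paste0("step3_", m, "_", s, "_",
                              ifelse(grepl("^vol_", outc), "volumes", "global"))
        )
      })
    }),
    distress = purrr::map_dfr(measures, function(m) {
      tibble::tibble(
        outcome = brain,
        rhs = paste(m, "+ ga_mri_weeks + sex"),
        term = m, subset = NA_character_, stratum = "all",
        fdr_family = paste0("distress_", m, "_", outcome_family(brain))
      )
    }),
    interaction = tibble::tibble(
      outcome = cort,
      rhs = paste(base_rhs, "+ ga_mri_weeks:cohort"),
      # terms() orders interaction factors by first appearance in the formula
      term = "cohort:ga_mri_weeks", subset = NA_character_, stratum = "all",
      fdr_family = paste0("interaction_", outcome_family(cort))
    ),
    sensitivity = purrr::map_dfr(
      c(ga28 = "ga_mri_weeks >= 28", age40 = "maternal_age <= 40"),
      function(cond) {
        s2 <- enumerate_models("step2")
        s2$subset <- cond
        s2$fdr_family <- paste0("sens_", gsub("[^a-z0-9]", "", cond), "_",
                                s2$fdr_family)
        s2$battery <- NULL
        s2$model_id <- NULL
        s2
      }
    ),
    laterality = purrr::map_dfr(c("left", "right"), function(h) {
      outc <- paste0(brain, "_", h)
      tibble::tibble(
        outcome = outc, rhs = base_rhs, term = "cohort",
        subset = NA_character_, stratum = h,
        fdr_family = paste0("lat_", h, "_", outcome_family(brain))
      )
    }),
    parental = purrr::map_dfr(
      c("edu_maternal", "edu_paternal", "employ_maternal", "employ_paternal"),
      function(v) {
        tibble::tibble(
          outcome = brain,
          rhs = paste(v, "+ ga_mri_weeks + sex"),
          term = v, subset = NA_character_, stratum = "all",
          fdr_family = paste0("parental_", v, "_", outcome_family(brain))
        )
      }
    ),
    stop("unknown step: ", step, call. = FALSE)
  )
  specs$battery <- step
  specs$model_id <- sprintf("%s_%03d", step, seq_len(nrow(specs)))
  dplyr::select(specs, dplyr::all_of(c("battery", "model_id", "outcome", "rhs",
                                       "term", "subset", "stratum", "fdr_family")))
}

#' Fit an enumerated battery of GEE models
#'
#' Fits each specification from [enumerate_models()] on the scan table,
#' extracts the coefficient of interest with its robust standard error and
#' two-sided Wald p, and adjusts p within each declared FDR family
#' (Benjamini-Hochberg). Models whose subset leaves too few clusters, or
#' whose design is rank deficient, are reported with NA estimates rather
#' than aborting the battery.
#'
#' @param data Scan table ([simulate_cohort()] output or a matching CSV).
#' @param models Tibble from [enumerate_models()].
#' @param id Cluster (subject) column.
#' @param corstr Working correlation.
#' @param alpha Significance level for the `sig_p` / `sig_q` flags.
#' @return Tibble: the model list plus `estimate`, `std.error`, `p`, `q`,
#'   `n_obs`, `n_clusters`, `sig_p`, `sig_q`, `error`.
#' @export
run_battery <- function(data, models, id = "subject_id",
                        corstr = "exchangeable", alpha = 0.05) {
  res <- purrr::pmap_dfr(
    models[, c("model_id", "outcome", "rhs", "term", "subset")],
    function(model_id, outcome, rhs, term, subset) {
      df <- data
      if (!is.na(subset)) {
        keep <- rlang::eval_tidy(rlang::parse_expr(subset), data = df)
        df <- df[!is.na(keep) & keep, , drop = FALSE]
      }
      out <- tibble::tibble(model_id = model_id, estimate = NA_real_,
                            std.error = NA_real_, p = NA_real_,
                            n_obs = NA_integer_, n_clusters = NA_integer_,
                            error = NA_character_)
      fit <- tryCatch(
        fit_gee(df, stats::as.formula(paste(outcome, "~", rhs)), id = id,
                corstr = corstr),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        out$error <- conditionMessage(fit)
        return(out)
      }
      td <- tidy.gee_fit(fit)
      row <- td[td$term == term, ]
      if (nrow(row) != 1) {
        out$error <- paste("term not found:", term)
        return(out)
      }
      out$estimate <- row$estimate
      out$std.error <- row$std.error
      out$p <- row$p.value
      out$n_obs <- fit$n_obs
      out$n_clusters <- fit$n_clusters
      out
    }
  )
  res <- dplyr::left_join(models, res, by = "model_id")
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$fdr_family),
    q = bh_fdr(.data$p)$q,
    .after = "p"
  )
  res <- dplyr::ungroup(res)
  res$sig_p <- !is.na(res$p) & res$p < alpha
  res$sig_q <- !is.na(res$q) & res$q < alpha
  class(res) <- c("gee_battery", class(res))
  res
}

#' Least-squares mean tables for stratified cohort comparisons
#'
#' Reproduces the stratified adjusted-mean layout: for each measure and
#' low/high stratum, the cohort LS-means (GA at the stratum mean, sex at the
#' stratum proportion) for the six tissue volumes and/or the three global
#' folding features.
#'
#' @param data Scan table.
#' @param measures Distress measures to stratify on.
#' @param outcomes Outcome columns (default volumes + global features).
#' @param id Cluster column.
#' @return Tibble with `measure`, `stratum`, `outcome`, `lsmean_pre`,
#'   `lsmean_pandemic`, `se_pre`, `se_pandemic`, `p` (cohort Wald p).
#' @export
stratified_ls_means <- function(data, measures = c("pss", "epds"),
                                outcomes = c(volume_outcomes(), global_outcomes()),
                                id = "subject_id") {
  thr <- distress_thresholds()
  purrr::map_dfr(measures, function(m) {
    purrr::map_dfr(c("low", "high"), function(s) {
      keep <- if (s == "low") data[[m]] <= thr[[m]] else data[[m]] > thr[[m]]
      df <- data[!is.na(keep) & keep, , drop = FALSE]
      purrr::map_dfr(outcomes, function(oc) {
        fit <- tryCatch(
          fit_gee(df, stats::as.formula(paste(oc, "~ cohort + ga_mri_weeks + sex")),
                  id = id),
          error = function(e) NULL
        )
        if (is.null(fit)) {
          return(tibble::tibble(measure = m, stratum = s, outcome = oc,
                                lsmean_pre = NA_real_, lsmean_pandemic = NA_real_,
                                se_pre = NA_real_, se_pandemic = NA_real_,
                                p = NA_real_))
        }
        lsm <- ls_means(fit)
        td <- tidy.gee_fit(fit)
        tibble::tibble(
          measure = m, stratum = s, outcome = oc,
          lsmean_pre = lsm$lsmean[lsm$group == 0],
          lsmean_pandemic = lsm$lsmean[lsm$group == 1],
          se_pre = lsm$se[lsm$group == 0],
          se_pandemic = lsm$se[lsm$group == 1],
          p = td$p.value[td$term == "cohort"]
        )
      })
    })
  })
}
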