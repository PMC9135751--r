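#' Pipeline configuration
#'
#' A fully serializable description of one end-to-end run: cohort simulation
#' parameters, phantom rendering resolution, gyrification parameters,
#' distress-threshold overrides, the statistical batteries to fit, and the
#' seed. A run is reproducible from config + seed alone; the config hash is
#' stamped into every CSV the run writes.
#'
#' @param cohort Arguments for [cohort_spec()] (list).
#' @param render_spacing Voxel spacing (mm) for phantom rendering; the
#'   acquisition default is 1.25 x 1.25 x 2 mm.
#' @param n_render How many scans get full phantom rendering + surface
#'   morphometry (the tabular statistics always use the whole cohort).
#' @param lgi Arguments for [lgi_params()] (list).
#' @param thresholds Distress-threshold overrides.
#' @param batteries Which model batteries to fit.
#' @param alpha Significance level.
#' @param seed Integer seed for the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(),
                            render_spacing = c(1.25, 1.25, 2),
                            n_render = 2L,
                            lgi = list(),
                            thresholds = NULL,
                            batteries = c("step1", "step2", "step3"),
                            alpha = 0.05,
                            seed = 1L) {
  cfg <- list(
    cohort = cohort,
    render_spacing = as.numeric(render_spacing),
    n_render = as.integer(n_render),
    lgi = lgi,
    thresholds = thresholds,
    batteries = batteries,
    alpha = alpha,
    seed = as.integer(seed)
  )
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$render_spacing) != 3 || any(cfg$render_spacing <= 0)) {
    stop("config error: render_spacing must be 3 positive mm values", call. = FALSE)
  }
  if (cfg$n_render < 0) stop("config error: n_render must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config error: alpha must be in (0, 1)", call. = FALSE)
  }
  bad <- setdiff(cfg$batteries, c("step1", "step2", "step3", "distress",
                                  "interaction", "sensitivity", "laterality",
                                  "parental"))
  if (length(bad) > 0) {
    stop("config error: unknown batteries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # cohort and lgi blocks are validated by their own constructors
  do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  do.call(lgi_params, cfg$lgi)
  invisible(cfg)
}

#' Read / write pipeline configs as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a validated config;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(yaml_friendly(unclass(config)), path)
  invisible(path)
}

# named atomic vectors become named lists so YAML keeps the names
yaml_friendly <- function(x) {
  if (is.list(x)) {
    lapply(x, yaml_friendly)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else {
    x
  }
}

# hash the canonical YAML form so a config survives a write/read round trip
# with an unchanged hash
config_hash <- function(config) {
  digest::digest(yaml::as.yaml(yaml_friendly(unclass(config))), algo = "sha1")
}

write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fetalfold config_hash=", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the pipeline (skipping the hash comment)
#' @param path CSV path.
#' @return Tibble.
#' @export
read_pipeline_csv <- function(path) {
  tibble::as_tibble(read.csv(path, comment.char = "#"))
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate -> volumes -> surface -> features -> stats -> report
#' into a run directory. Each stage is idempotent: existing outputs are
#' reused unless `overwrite = TRUE`, so an interrupted run resumes. The
#' provenance log records the config hash, seed and package version; every
#' CSV carries the config hash as a comment header, so two runs from the
#' same config + seed produce byte-identical tables.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @param out_dir Run directory (created if needed).
#' @param overwrite Recompute stages whose outputs already exist.
#' @return `out_dir`, invisibly; the directory contains `cohort.csv`,
#'   `measured_features.csv`, per-scan NIfTI/PLY artifacts, `stats_*.csv`,
#'   `lsmeans.csv`, `figures/`, and `provenance.yaml`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  hash <- config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  stage <- function(name, outputs, fun) {
    if (!overwrite && all(file.exists(file.path(out_dir, outputs)))) {
      log_line(log_path, "stage ", name, ": outputs exist, skipping")
      return(invisible(NULL))
    }
    log_line(log_path, "stage ", name, ": start")
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(log_path, "stage ", name, ": done")
  }

  # simulate
  stage("simulate", "cohort.csv", function() {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    scans <- simulate_cohort(spec)
    write_csv_stamped(scans, file.path(out_dir, "cohort.csv"), hash)
  })
  scans <- read_pipeline_csv(file.path(out_dir, "cohort.csv"))

  # volumes + surface + features on rendered phantoms
  n_render <- min(config$n_render, nrow(scans))
  if (n_render > 0) {
    render_ids <- scans$scan_id[seq_len(n_render)]
    stage("render", "measured_features.csv", function() {
      lp <- do.call(lgi_params, config$lgi)
      feats <- purrr::map_dfr(render_ids, function(sid) {
        rec <- scans[scans$scan_id == sid, ]
        spec <- phantom_spec_for_scan(rec, spacing = config$render_spacing)
        ph <- make_phantom(spec)
        write_nifti(ph$segmentation,
                    file.path(out_dir, paste0(sid, "_seg.nii.gz")))
        write_nifti(ph$parcellation,
                    file.path(out_dir, paste0(sid, "_parc.nii.gz")))
        mesh <- extract_junction_mesh(
          ph$segmentation,
          segmentation_labels()[c("wm", "dgm", "hippocampus", "ventricles")]
        )
        mesh <- assign_regions(mesh, ph$parcellation)
        write_ply(mesh, file.path(out_dir, paste0(sid, "_junction.ply")))
        dplyr::bind_cols(tibble::tibble(scan_id = sid),
                         compute_scan_features(ph$segmentation, ph$parcellation,
                                               params = lp))
      })
      write_csv_stamped(feats, file.path(out_dir, "measured_features.csv"), hash)
    })
  }

  # stats on the full simulated cohort table
  stage("stats", c(paste0("stats_", config$batteries, ".csv"), "lsmeans.csv"),
        function() {
          for (b in config$batteries) {
            models <- enumerate_models(b)
            res <- run_battery(scans, models, alpha = config$alpha)
            write_csv_stamped(res, file.path(out_dir, paste0("stats_", b, ".csv")),
                              hash)
          }
          lsm <- stratified_ls_means(scans)
          write_csv_stamped(lsm, file.path(out_dir, "lsmeans.csv"), hash)
        })

  # report
  stage("report", file.path("figures", "volumes_vs_ga.pdf"), function() {
    render_report(out_dir)
  })

  prov <- list(
    config_hash = hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fetalfold")),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Render figures and tables from a completed run directory
#'
#' Produces volume-vs-GA scatter plots with per-cohort exponential fits,
#' folding-feature-vs-GA scatter plots with linear fits (both drawn through
#' [growth_fit()], the same code path reported in the tables), a wide
#' coefficient/p/q grid of the distress-adjusted cohort models, and the
#' stratified LS-means tables.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Invisible list of the ggplot objects.
#' @export
render_report <- function(run_dir) {
  cohort_path <- file.path(run_dir, "cohort.csv")
  if (!file.exists(cohort_path)) {
    stop("missing stats outputs in ", run_dir, ": run the pipeline first",
         call. = FALSE)
  }
  scans <- read_pipeline_csv(cohort_path)
  fig_dir <- file.path(run_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)

  if (nrow(scans) == 0) {
    writeLines("no data: empty cohort", file.path(run_dir, "report.txt"))
    # keep the report stage's contract: an (empty) figure file must exist
    grDevices::pdf(file.path(fig_dir, "volumes_vs_ga.pdf"))
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no data")
    grDevices::dev.off()
    return(invisible(list()))
  }

  p_vol <- plot_growth(scans, volume_outcomes(), form = "exponential") +
    ggplot2::labs(title = "Brain tissue volumes vs gestational age",
                  y = "volume (cm^3)")
  ggplot2::ggsave(file.path(fig_dir, "volumes_vs_ga.pdf"), p_vol,
                  width = 10, height = 7)
  feat_cols <- cortical_outcomes()
  p_feat <- plot_growth(scans, feat_cols, form = "linear") +
    ggplot2::labs(title = "Lobar folding features vs gestational age")
  ggplot2::ggsave(file.path(fig_dir, "features_vs_ga.pdf"), p_feat,
                  width = 12, height = 9)

  # Table-2-style grid from the step-2 battery if present
  s2_path <- file.path(run_dir, "stats_step2.csv")
  if (file.exists(s2_path)) {
    s2 <- read_pipeline_csv(s2_path)
    adj <- s2[grepl("\\+ (ssai|stai|pss|epds)$", s2$rhs), ]
    adj$measure <- sub("^.*\\+ ", "", adj$rhs)
    grid <- tidyr::pivot_wider(
      adj[, c("outcome", "measure", "estimate", "p", "q")],
      names_from = "measure", values_from = c("estimate", "p", "q")
    )
    write.csv(grid, file.path(run_dir, "table2_grid.csv"), row.names = FALSE)
  }
  invisible(list(volumes = p_vol, features = p_feat))
}
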