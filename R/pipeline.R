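# End-to-end orchestration: simulate (or ingest) -> train thresholds ->
# quantify -> evaluate -> combine -> report, each stage writing its
# declared file interface under the run directory so stages can also be
# driven independently from the command line.

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML or JSON document with fields:
#' \describe{
#'   \item{mode}{"simulate" or "ingest".}
#'   \item{seed}{Integer master seed (simulate mode).}
#'   \item{cohort}{Arguments for [cohort_config()] shared by all markers
#'     (simulate mode).}
#'   \item{markers}{List of markers; each has a unique `name` plus, in
#'     simulate mode, `dab_fraction_hr`/`dab_fraction_lr`, or, in ingest
#'     mode, `dir` (a dataset directory with cores.csv and images).}
#'   \item{training}{`n_hr`, `n_lr`, `seed` for the random training
#'     draw, and optionally `grid_step`; mutually exclusive with
#'     `thresholds`.}
#'   \item{thresholds}{Fixed `t_tissue`/`t_signal` applied to every
#'     marker, skipping training.}
#'   \item{pretest_p}{Optional pretest probability for post-test
#'     probabilities.}
#'   \item{combination}{List of marker-name pairs to combine
#'     logistically.}
#'   \item{log_level}{"info" (default) or "quiet".}
#' }
#'
#' @param path Config file (.yaml/.yml/.json), or a list already in that
#'   shape.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$mode)) cfg$mode <- "simulate"
  if (!cfg$mode %in% c("simulate", "ingest")) {
    stop("config: mode must be 'simulate' or 'ingest'", call. = FALSE)
  }
  if (is.null(cfg$markers) || length(cfg$markers) == 0) {
    stop("config: at least one marker is required", call. = FALSE)
  }
  nms <- vapply(cfg$markers, function(m) m$name %||% NA_character_,
                character(1))
  if (anyNA(nms) || anyDuplicated(nms)) {
    stop("config: every marker needs a unique name", call. = FALSE)
  }
  has_thr <- !is.null(cfg$thresholds)
  has_tr <- !is.null(cfg$training)
  if (has_thr == has_tr) {
    stop("config: exactly one of 'thresholds' and 'training' must be given",
         call. = FALSE)
  }
  if (has_tr) {
    cfg$training$n_hr <- cfg$training$n_hr %||% 10
    cfg$training$n_lr <- cfg$training$n_lr %||% 10
    if (is.null(cfg$training$seed)) {
      stop("config: training.seed is required", call. = FALSE)
    }
    cfg$training$grid_step <- cfg$training$grid_step %||% 5
  }
  if (cfg$mode == "simulate" && is.null(cfg$seed)) {
    stop("config: a master seed is required in simulate mode", call. = FALSE)
  }
  cfg$log_level <- cfg$log_level %||% "info"
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, msg))
}

marker_cohort_config <- function(cfg, marker, k) {
  args <- as.list(cfg$cohort %||% list())
  args$dab_fraction_hr <- marker$dab_fraction_hr %||% args$dab_fraction_hr %||%
    formals(cohort_config)$dab_fraction_hr
  args$dab_fraction_lr <- marker$dab_fraction_lr %||% args$dab_fraction_lr %||%
    formals(cohort_config)$dab_fraction_lr
  args$seed <- (as.integer(cfg$seed) + 101L * k) %% .Machine$integer.max
  do.call(cohort_config, args)
}

#' Simulate and write the datasets for every configured marker
#'
#' @param cfg A `run_config` in simulate mode.
#' @param out_dir Run directory; datasets land in
#'   `out_dir/markers/<name>/`.
#' @return Invisibly, the per-marker dataset directories.
#' @export
simulate_datasets <- function(cfg, out_dir) {
  cfg <- validate_run_config(cfg)
  if (cfg$mode != "simulate") {
    stop("simulate_datasets() requires a simulate-mode config",
         call. = FALSE)
  }
  dirs <- character(0)
  for (k in seq_along(cfg$markers)) {
    m <- cfg$markers[[k]]
    ccfg <- marker_cohort_config(cfg, m, k)
    pipe_log(cfg, "simulate",
             sprintf("marker %s: %d pairs x %d cores", m$name,
                     ccfg$n_pairs, ccfg$cores_per_patient))
    cohort <- generate_cohort(ccfg)
    d <- file.path(out_dir, "markers", m$name)
    write_dataset(cohort, d, overwrite = TRUE)
    dirs[m$name] <- d
  }
  invisible(dirs)
}

run_stage <- function(cfg, out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, threshold training (or fixed thresholds),
#' quantification, marker evaluation, logistic combination and reporting
#' in order, writing every stage's outputs under `out_dir`:
#' per-marker dataset directories with `thresholds.json` and
#' `quantification.csv`, `marker_report.csv`/`.json`,
#' `combination_report.csv`/`.json`, mountain and ROC figures under
#' `figures/`, and a `manifest.json` echoing the configuration and
#' seeds. Fully deterministic given the config. A failing stage leaves a
#' `FAILED` sentinel naming the stage.
#'
#' @param config A `run_config`, or a path readable by
#'   [read_run_config()].
#' @param out_dir Run directory (created; must be empty unless
#'   `overwrite`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the marker reports, combination
#'   models, and the summary tables.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  cfg <- read_run_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop(sprintf("run directory '%s' is not empty; set overwrite = TRUE",
                 out_dir), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  marker_dirs <- run_stage(cfg, out_dir, "simulate", {
    if (cfg$mode == "simulate") {
      simulate_datasets(cfg, out_dir)
    } else {
      d <- vapply(cfg$markers, function(m) m$dir, character(1))
      names(d) <- vapply(cfg$markers, function(m) m$name, character(1))
      d
    }
  })

  reports <- list()
  quants <- list()
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)

  for (m in cfg$markers) {
    name <- m$name
    d <- marker_dirs[[name]]
    cohort <- run_stage(cfg, out_dir, paste0("load:", name),
                        read_cohort(d))

    thr <- run_stage(cfg, out_dir, paste0("thresholds:", name), {
      if (!is.null(cfg$thresholds)) {
        tp <- threshold_pair(cfg$thresholds$t_tissue,
                             cfg$thresholds$t_signal)
        write_thresholds(tp, file.path(d, "thresholds.json"))
        tp
      } else {
        ids <- sample_training_set(cohort$metadata,
                                   n_hr = cfg$training$n_hr,
                                   n_lr = cfg$training$n_lr,
                                   seed = cfg$training$seed)
        tr <- train_thresholds(
          cohort$images[ids],
          cohort$metadata$group[match(ids, cohort$metadata$core_id)],
          grid_step = cfg$training$grid_step
        )
        pipe_log(cfg, "thresholds",
                 sprintf("%s: t_tissue=%d t_signal=%d (R2=%.3f)", name,
                         tr$best$t_tissue, tr$best$t_signal, tr$fit_score))
        write_thresholds(tr, file.path(d, "thresholds.json"))
        tr$best
      }
    })

    quant <- run_stage(cfg, out_dir, paste0("quantify:", name), {
      q <- quantify_cohort(cohort$images, cohort$metadata, thr)
      qcsv <- file.path(d, "quantification.csv")
      utils::write.csv(q, qcsv, row.names = FALSE)
      # downstream stages consume the declared file interface, so that a
      # staged CLI run reproduces run_pipeline() byte for byte
      tibble::as_tibble(utils::read.csv(qcsv, stringsAsFactors = FALSE))
    })
    quants[[name]] <- quant

    reports[[name]] <- run_stage(cfg, out_dir, paste0("evaluate:", name), {
      r <- evaluate_marker(quant, name, pretest_p = cfg$pretest_p)
      mountain_plot(quant, name,
                    out_path = file.path(fig_dir,
                                         paste0("mountain_", name, ".png")))
      r
    })
    pipe_log(cfg, "evaluate",
             sprintf("%s: AUC=%.3f±%.3f p=%.3g", name,
                     reports[[name]]$auc$a, reports[[name]]$auc$se_a,
                     reports[[name]]$u_test$p_two_sided))
  }

  combos <- run_stage(cfg, out_dir, "combine",
                      fit_combinations(quants, cfg$combination))

  run_stage(cfg, out_dir, "report", {
    summary_tables(reports, combos, out_dir)
    roc_plot(reports, file.path(fig_dir, "roc.png"))
  })

  manifest <- list(
    config = unclass(cfg),
    package = "tmaquant",
    package_version = as.character(utils::packageVersion("tmaquant")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(reports = reports, combinations = combos,
                 quantifications = quants))
}

#' Fit the configured logistic marker combinations
#'
#' Joins the per-marker ratios on core_id (cores valid under every
#' involved marker) and fits one logistic model per combination.
#'
#' @param quants Named list of quantification tibbles, one per marker.
#' @param combination List of character vectors of marker names (length
#'   >= 1 each); NULL gives an empty result.
#' @return Named list of `logistic_model`s, keyed "m1+m2".
#' @export
fit_combinations <- function(quants, combination) {
  out <- list()
  for (combo in combination %||% list()) {
    combo <- unlist(combo)
    absent <- setdiff(combo, names(quants))
    if (length(absent)) {
      stop("combination references unknown markers: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    base <- quants[[combo[1]]]
    keep <- base$valid
    mat <- data.frame(row.names = base$core_id)
    for (nm in combo) {
      q <- quants[[nm]]
      q <- q[match(base$core_id, q$core_id), ]
      keep <- keep & q$valid & !is.na(q$ratio)
      mat[[nm]] <- q$ratio
    }
    out[[paste(combo, collapse = "+")]] <-
      fit_logistic(as.matrix(mat[keep, , drop = FALSE]),
                   base$group[keep])
  }
  out
}
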