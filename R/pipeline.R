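#' Pipeline run configuration
#'
#' Bundles every stage's settings with pinned defaults. All flags default to
#' the package's documented conventions (plain AEC without leakage
#' correction, raw PSD for matching, diagonal excluded from the
#' differentiability null).
#'
#' @param simulate Named list of [synth_config()] arguments (without
#'   `seed`, which is fanned out from `seed` below).
#' @param feature_types Feature sets to run (`"connectome"`,
#'   `"spectral"`).
#' @param bands Character vector of band names and/or `"broadband"`.
#' @param challenges Challenges to run (subset of `"within"`, `"between"`,
#'   `"within_short"`, `"between_short"`).
#' @param empty_room Also fingerprint an empty-room analog (default
#'   `TRUE`).
#' @param orthogonalize,log_psd,include_self_in_null Pinned analysis flags.
#' @param n_perm,n_boot PLS inference effort.
#' @param run_pls Run the PLS stage (default `TRUE`).
#' @param seed Global seed, fanned out to per-stage child seeds.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate, feature_types = c("connectome", "spectral"),
                       bands = "broadband", challenges = "within",
                       empty_room = TRUE, orthogonalize = FALSE,
                       log_psd = FALSE, include_self_in_null = FALSE,
                       n_perm = 1000, n_boot = 1000, run_pls = TRUE,
                       seed = 1L) {
  cfg <- list(
    simulate = simulate, feature_types = feature_types, bands = bands,
    challenges = challenges, empty_room = empty_room,
    orthogonalize = orthogonalize, log_psd = log_psd,
    include_self_in_null = include_self_in_null,
    n_perm = n_perm, n_boot = n_boot, run_pls = run_pls,
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' Round-trips a [run_config()] through a YAML file losslessly.
#'
#' @param path File path.
#' @param config A `run_config`.
#' @return `read_run_config` returns a `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate$bands)) {
    raw$simulate$bands <- tibble::as_tibble(raw$simulate$bands)
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full fingerprinting pipeline
#'
#' Simulates a cohort (and optionally an empty-room analog), runs every
#' requested challenge for every feature type and band, computes
#' within-session broadband feature reliability, correlates
#' differentiability with artifact confounds, and runs the PLS stage on
#' band-power features versus demographics. Deterministic for a fixed
#' config: the global seed is fanned out to independent per-stage child
#' seeds and the report carries no timestamps.
#'
#' @param config A [run_config()] or path to its YAML form.
#' @param out_dir Optional directory; when given, the JSON report and CSV
#'   tables are written there.
#' @return A `pipeline_report` list with elements `meta`, `accuracies`,
#'   `empty_room`, `reliability`, `confounds`, `pls`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  scfg <- do.call(synth_config,
                  c(config$simulate, list(seed = child_seed(seed, 11))))
  cohort <- simulate_cohort(scfg)

  acc <- list()
  for (ft in config$feature_types) {
    for (bd in config$bands) {
      band_arg <- if (identical(bd, "broadband")) NULL else bd
      for (ch in config$challenges) {
        res <- run_challenge(cohort$recording, challenge = ch, type = ft,
                             band = band_arg,
                             orthogonalize = config$orthogonalize,
                             log_psd = config$log_psd,
                             include_self_in_null = config$include_self_in_null)
        acc[[length(acc) + 1]] <- glance(res)
        if (ch == "within" && identical(bd, config$bands[1])) {
          # keep the headline challenge's per-subject scores for confounds
          attr(acc[[length(acc)]], "d_self") <- res$d_self
        }
      }
    }
  }
  accuracies <- dplyr::bind_rows(acc)

  empty_tbl <- NULL
  if (isTRUE(config$empty_room)) {
    ecfg <- scfg
    ecfg$seed <- child_seed(seed, 13)
    empty <- simulate_empty_room(ecfg)
    erows <- list()
    for (ft in config$feature_types) {
      eres <- run_challenge(empty, challenge = "within", type = ft,
                            band = NULL, log_psd = config$log_psd)
      g <- glance(eres)
      g$challenge <- "empty_room"
      erows[[length(erows) + 1]] <- g
    }
    empty_tbl <- dplyr::bind_rows(erows)
  }

  # reliability + confounds on the broadband within-session challenge
  halves <- segment_recording(cohort$recording, "within_halves")
  ses1 <- cohort$recording$session_ids[1]
  rel_rows <- list()
  conf_rows <- list()
  for (ft in config$feature_types) {
    f1 <- extract_features(halves[[paste0(ses1, "_h1")]], type = ft,
                           log_psd = config$log_psd)
    f2 <- extract_features(halves[[paste0(ses1, "_h2")]], type = ft,
                           log_psd = config$log_psd)
    rel <- feature_reliability(f1, f2)
    rel$feature_type <- ft
    rel_rows[[ft]] <- rel
    sim <- similarity(f1, f2)
    ds <- differentiability(sim,
                            include_self_in_null = config$include_self_in_null)
    cc <- confound_correlations(ds, cohort$artifacts)
    cc$feature_type <- ft
    conf_rows[[ft]] <- cc
  }
  reliability <- dplyr::bind_rows(rel_rows)
  confounds <- dplyr::bind_rows(conf_rows)

  pls_out <- NULL
  if (isTRUE(config$run_pls)) {
    full1 <- roi_dataset(
      array(cohort$recording$data[, 1, , ], dim(cohort$recording$data)[c(1, 3, 4)]),
      cohort$recording$fs, cohort$recording$subject_ids,
      cohort$recording$roi_labels, ses1)
    y <- bandpower_features(full1, bands = scfg$bands)
    x <- encode_demographics(cohort$demographics)
    fit <- pls_fit(x, y)
    fit <- pls_permutation(fit, n_perm = config$n_perm,
                           seed = child_seed(seed, 17))
    fit <- pls_bootstrap(fit, n_boot = config$n_boot,
                         seed = child_seed(seed, 19))
    pls_out <- fit
  }

  report <- list(
    meta = list(
      package = "brainprint",
      seed = seed,
      n_subjects = scfg$n_subjects,
      n_sessions = scfg$n_sessions,
      n_rois = scfg$n_rois,
      fs = scfg$fs,
      duration = scfg$duration
    ),
    accuracies = accuracies,
    empty_room = empty_tbl,
    reliability = reliability,
    confounds = confounds,
    pls = pls_out,
    d_self = dplyr::bind_rows(lapply(acc, function(a) {
      ds <- attr(a, "d_self")
      if (is.null(ds)) return(NULL)
      ds$feature_type <- a$type
      ds
    }))
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$accuracies[, c("challenge", "type", "band", "accuracy_mean")])
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes the JSON report (`report.json`) plus CSV tables (accuracies,
#' differentiability, reliability, confounds, PLS summaries) into a run
#' directory with a `manifest.json` listing every file.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    files <<- c(files, name)
  }
  wr(report$accuracies, "accuracies.csv")
  if (!is.null(report$empty_room)) wr(report$empty_room, "empty_room.csv")
  wr(report$reliability, "reliability.csv")
  wr(report$confounds, "confounds.csv")
  if (nrow(report$d_self %||% tibble()) > 0) wr(report$d_self, "d_self.csv")
  json <- report_json(report)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "report.json")
  jsonlite::write_json(list(files = files), file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

report_json <- function(report) {
  pls <- report$pls
  list(
    meta = report$meta,
    accuracies = as.data.frame(report$accuracies),
    empty_room = if (!is.null(report$empty_room)) {
      as.data.frame(report$empty_room)
    },
    reliability_summary = as.data.frame(
      dplyr::summarise(
        dplyr::group_by(report$reliability, .data$feature_type),
        median_icc = median(.data$icc, na.rm = TRUE),
        median_gc = median(.data$group_consistency, na.rm = TRUE),
        median_dp = median(.data$differential_power, na.rm = TRUE))),
    confounds = as.data.frame(report$confounds),
    pls = if (!is.null(pls)) {
      list(
        singular_values = pls$singular_values,
        p_perm = pls$p_perm,
        n_perm = pls$n_perm,
        n_boot_used = pls$n_boot_used,
        demographic = as.data.frame(tidy(pls, "demographic"))
      )
    }
  )
}

#' Check a serialized report against the shipped schema
#'
#' Structural validation of `report.json` against the JSON schema shipped
#' in `inst/schema/report-schema.json`: required top-level keys and their
#' types.
#'
#' @param path Path to a `report.json` file.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "brainprint"))
  rep <- jsonlite::read_json(path)
  for (key in names(schema$required)) {
    rule <- schema$required[[key]]
    if (isTRUE(rule$mandatory) && is.null(rep[[key]])) {
      abort(sprintf("Report is missing required key '%s'.", key))
    }
    if (!is.null(rep[[key]]) && !is.null(rule$type)) {
      ok <- switch(rule$type,
        object = is.list(rep[[key]]) && !is.null(names(rep[[key]])),
        array = is.list(rep[[key]]),
        TRUE)
      if (!ok) {
        abort(sprintf("Report key '%s' must be of type %s.", key, rule$type))
      }
    }
  }
  invisible(TRUE)
}
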