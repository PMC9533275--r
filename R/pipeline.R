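#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param cohort path to a cohort CSV, or `NULL` to simulate one.
#' @param patients path to a patient CSV, `"simulate"`, or `NULL` to skip
#'   the concordance stage.
#' @param tests test names to process.
#' @param n_cohort simulated healthy-cohort size (when `cohort` is `NULL`).
#' @param alpha_enter,alpha_remove stepwise thresholds.
#' @param quantile_type percentile convention.
#' @param seed global seed; every stage derives a named substream from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = NULL, patients = "simulate",
                            tests = test_catalog()$test, n_cohort = 204,
                            alpha_enter = 0.05, alpha_remove = 0.05,
                            quantile_type = 7, seed = 1L) {
  if (!is.null(cohort) && !file.exists(cohort)) {
    stop("cohort file does not exist: ", cohort)
  }
  if (!is.null(patients) && !identical(patients, "simulate") &&
      !file.exists(patients)) {
    stop("patients file does not exist: ", patients)
  }
  structure(list(out_dir = out_dir, cohort = cohort, patients = patients,
                 tests = tests, n_cohort = n_cohort,
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove,
                 quantile_type = quantile_type, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full norming pipeline
#'
#' Simulate (or load) a healthy cohort, screen descriptives and candidate
#' transformations, fit the adjustment equation per test, tabulate the
#' correction grids, derive tolerance limits / Equivalent Score thresholds /
#' percentile tables from the adjusted scores, and — when a patient cohort is
#' available — compare the fitted norms against the stand-in reference norms.
#' Writes every artifact under `config$out_dir` and a manifest JSON listing
#' each output with its MD5 checksum, the seed, and per-stage status; a
#' failed stage marks later stages skipped.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stages <- list()
  failed <- FALSE

  emit <- function(name) files[[name]] <<- file.path(config$out_dir, name)

  run_stage <- function(name, fn) {
    if (failed) {
      stages[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(fn(), error = function(e) {
      stages[[name]] <<- paste0("failed: ", conditionMessage(e))
      failed <<- TRUE
      NULL
    })
    if (is.null(stages[[name]])) stages[[name]] <<- "ok"
    res
  }

  cohort <- run_stage("cohort", function() {
    if (is.null(config$cohort)) {
      ch <- simulate_healthy_cohort(
        healthy_spec(n = config$n_cohort,
                     seed = substream_seed(config$seed, "healthy")))
      write_cohort_csv(ch, emit("cohort_healthy.csv"))
      ch
    } else {
      read_cohort_csv(config$cohort)
    }
  })

  run_stage("descriptives", function() {
    scr <- descriptive_screen(cohort)
    utils::write.csv(scr$summary, emit("descriptives.csv"), row.names = FALSE)
    utils::write.csv(round(scr$corr, 3), emit("correlations.csv"))
    scr
  })

  fits <- run_stage("norming", function() {
    out <- list()
    for (t in intersect(config$tests, names(cohort))) {
      scr <- screen_transforms(cohort, t)
      eq <- stepwise_fit(cohort, t, scr$best,
                         alpha_enter = config$alpha_enter,
                         alpha_remove = config$alpha_remove)
      write_equation_json(eq, emit(sprintf("equation_%s.json", t)))
      utils::write.csv(build_grid(eq), emit(sprintf("grid_%s.csv", t)),
                       row.names = FALSE)
      adjusted <- adjust_cohort(eq, cohort)
      th <- es_thresholds(adjusted)
      th$test <- t
      write_thresholds_json(th, emit(sprintf("thresholds_%s.json", t)))
      pt <- percentile_table(adjusted, type = config$quantile_type)
      utils::write.csv(pt, emit(sprintf("percentiles_%s.csv", t)),
                       row.names = FALSE)
      out[[t]] <- list(equation = eq, thresholds = th)
    }
    out
  })

  if (is.null(config$patients)) {
    stages[["concordance"]] <- "skipped"
  } else {
    run_stage("concordance", function() {
      patients <- if (identical(config$patients, "simulate")) {
        pp <- simulate_patient_cohort(
          patient_spec(seed = substream_seed(config$seed, "patients")))
        write_cohort_csv(pp, emit("cohort_patients.csv"))
        pp
      } else {
        read_cohort_csv(config$patients)
      }
      systems_new <- lapply(fits, function(f) {
        normative_system(paste0("fitted_", f$equation$test), f$equation,
                         thresholds = f$thresholds)
      })
      cmp <- run_comparison(patients, systems_new, standin_reference_systems(),
                            tests = names(systems_new),
                            seed = substream_seed(config$seed, "concordance"))
      metrics <- do.call(rbind, lapply(names(cmp), function(t) {
        s <- cmp[[t]]$stats
        data.frame(test = t, accuracy = s$accuracy, auc = s$auc,
                   auc_lo = s$auc_ci[1], auc_hi = s$auc_ci[2],
                   kappa = s$kappa, kappa_lo = s$kappa_ci[1],
                   kappa_hi = s$kappa_ci[2],
                   ac1 = s$ac1, ac1_lo = s$ac1_ci[1], ac1_hi = s$ac1_ci[2])
      }))
      utils::write.csv(metrics, emit("concordance_metrics.csv"), row.names = FALSE)
      cms <- do.call(rbind, lapply(names(cmp), function(t) {
        m <- cmp[[t]]$cm
        data.frame(test = t, a = m$a, b = m$b, c = m$c, d = m$d)
      }))
      utils::write.csv(cms, emit("confusion_matrices.csv"), row.names = FALSE)
      roc <- do.call(rbind, lapply(names(cmp), function(t) {
        cbind(test = t, cmp[[t]]$roc)
      }))
      utils::write.csv(roc, emit("roc_points.csv"), row.names = FALSE)
      cmp
    })
  }

  checksums <- if (length(files) > 0) {
    as.list(tools::md5sum(unlist(files)))
  } else {
    list()
  }
  names(checksums) <- names(files)
  manifest <- list(package_version = as.character(utils::packageVersion("memnorms")),
                   seed = config$seed, stages = stages, files = checksums)
  write_json_file(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
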