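# Tabular I/O and the end-to-end analysis pipeline.
#
# Time-course tables are comma-separated UTF-8 files with mandatory
# header `experiment_id,replicate,time_s,signal_nM`.

.tc_columns <- c("experiment_id", "replicate", "time_s", "signal_nM")

#' Read observed time courses from a CSV file
#'
#' Rows are grouped by `(experiment_id, replicate)` and sorted by time
#' within each group. Duplicate `(experiment_id, replicate, time_s)`
#' rows and non-numeric fields are rejected with informative errors.
#'
#' @param path CSV file with header
#'   `experiment_id,replicate,time_s,signal_nM`.
#' @return Named list (by experiment id) of lists of observed time
#'   courses (one per replicate).
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.tc_columns, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("time_s", "signal_nM")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[col]] <- v
  }
  key <- paste(df$experiment_id, df$replicate, df$time_s, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (experiment, replicate, time) at data line(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  out <- list()
  for (ex in unique(df$experiment_id)) {
    sub <- df[df$experiment_id == ex, ]
    out[[ex]] <- lapply(sort(unique(sub$replicate)), function(r) {
      g <- sub[sub$replicate == r, ]
      g <- g[order(g$time_s), ]
      observed_timecourse(g$time_s, g$signal_nM, experiment_id = ex,
                          replicate = r)
    })
  }
  out
}

#' Write observed time courses to a CSV file
#'
#' Inverse of [read_timecourses()]; accepts the nested list layout that
#' function returns, a flat list of time courses, or an
#' `experiment_suite`.
#'
#' @param tcs Time courses to serialize.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tcs, path) {
  if (inherits(tcs, "experiment_suite")) tcs <- tcs$timecourses
  if (inherits(tcs, "polbkin_tc")) tcs <- list(list(tcs))
  if (length(tcs) && inherits(tcs[[1]], "polbkin_tc")) tcs <- list(tcs)
  rows <- list()
  for (ex in names(tcs)) {
    for (tc in tcs[[ex]]) {
      rows[[length(rows) + 1]] <- data.frame(
        experiment_id = if (nzchar(ex)) ex else attr(tc, "experiment_id"),
        replicate = attr(tc, "replicate"),
        time_s = tc$time_s, signal_nM = tc$signal_nM)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an experiment suite to a directory
#'
#' Writes one CSV of time courses plus a JSON manifest carrying the
#' generating ground truth and seed.
#'
#' @param suite An `experiment_suite`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "experiment_suite"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timecourses(suite, file.path(dir, "timecourses.csv"))
  jsonlite::write_json(
    list(seed = suite$seed, mode = suite$mode, design = suite$design,
         truth = suite$truth),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.fit_experiment <- function(tcs, linear = FALSE) {
  fits <- lapply(tcs, if (linear) fit_linear else fit_single_exponential)
  if (linear) {
    list(fits = fits,
         slope = aggregate_replicates(vapply(fits, `[[`, 0, "slope")),
         intercept = aggregate_replicates(
           vapply(fits, `[[`, 0, "intercept")))
  } else {
    list(fits = fits,
         A = aggregate_replicates(vapply(fits, `[[`, 0, "A")),
         k_obs = aggregate_replicates(vapply(fits, `[[`, 0, "k_obs")))
  }
}

#' Run the full analysis pipeline
#'
#' Ingests (or generates) an experiment suite, fits every time course,
#' aggregates replicates, and computes the derived diagnostics: sulfur
#' elemental effects for correct and incorrect incorporation,
#' pulse-quench/pulse-chase amplitude partitioning, Eyring activation
#' parameters with the activation free energy at 37 C, the viscosity
#' flatness slope, and the rate-limiting-step verdict.
#'
#' @param config A list with optional elements:
#'   \describe{
#'     \item{suite}{An `experiment_suite`, or a path to a CSV of time
#'       courses, or a directory written by [write_suite()].}
#'     \item{synthetic}{When no suite is given, a list of arguments for
#'       [generate_suite()] (e.g. `mode`, `seed`, `sd_nM`).}
#'     \item{analyses}{Character vector selecting analyses; default all
#'       applicable. An empty vector yields a provenance-only report.}
#'     \item{out_json}{Optional path; the report is written there as
#'       JSON.}
#'   }
#' @return A list of class `run_report` with `fits`, `diagnostics`,
#'   `verdict`, and `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  t0 <- Sys.time()
  seed <- NA_integer_
  if (!is.null(config$suite)) {
    suite <- config$suite
    if (is.character(suite)) {
      path <- suite
      if (dir.exists(path)) path <- file.path(path, "timecourses.csv")
      suite <- read_timecourses(path)
    }
    tcs <- if (inherits(suite, "experiment_suite")) {
      seed <- suite$seed
      suite$timecourses
    } else {
      suite
    }
  } else {
    syn <- config$synthetic
    if (is.null(syn)) syn <- list()
    seed <- if (!is.null(syn$seed)) as.integer(syn$seed) else 1L
    nm <- noise_model(sd_nM = if (!is.null(syn$sd_nM)) syn$sd_nM else 0,
                      seed = seed)
    suite <- generate_suite(noise = nm,
                            mode = if (!is.null(syn$mode)) syn$mode else
                              "closed_form")
    tcs <- suite$timecourses
  }
  analyses <- config$analyses
  if (is.null(analyses)) {
    analyses <- c("elemental_correct", "elemental_mismatch", "partition",
                  "eyring", "viscosity", "verdict")
  }
  fits <- list()
  for (ex in names(tcs)) {
    fits[[ex]] <- .fit_experiment(tcs[[ex]], linear = (ex == "dGTPaS"))
  }
  diag <- list()
  if ("elemental_correct" %in% analyses &&
      all(c("dCTP", "dCTPaS") %in% names(fits))) {
    kO <- fits$dCTP$k_obs$values
    kS <- fits$dCTPaS$k_obs$values
    diag$elemental_correct <- if (length(kO) == length(kS)) {
      elemental_effect(kO, kS)
    } else {
      elemental_effect(mean(kO), mean(kS))
    }
  }
  if ("elemental_mismatch" %in% analyses &&
      all(c("dGTP", "dGTPaS") %in% names(fits))) {
    k_thio <- kobs_from_slope(fits$dGTPaS$slope$mean, fits$dGTP$A$mean)
    diag$elemental_mismatch <-
      elemental_effect(fits$dGTP$k_obs$mean, k_thio)
    diag$k_thio_from_slope <- k_thio
  }
  if ("partition" %in% analyses &&
      all(c("pulse_quench", "pulse_chase") %in% names(fits))) {
    diag$partition <- partition_analysis(
      fits$pulse_quench$A$mean, fits$pulse_chase$A$mean,
      fits$pulse_chase$k_obs$mean)
  }
  temp_ids <- grep("^temperature_", names(fits), value = TRUE)
  if ("eyring" %in% analyses && length(temp_ids) >= 2) {
    T_K <- as.numeric(sub("^temperature_([0-9.]+)K$", "\\1", temp_ids))
    n_rep <- min(vapply(temp_ids, function(id)
      length(fits[[id]]$k_obs$values), 0L))
    per_rep <- lapply(seq_len(n_rep), function(r) {
      k <- vapply(temp_ids, function(id) fits[[id]]$k_obs$values[r], 0)
      fit_eyring(T_K, k)
    })
    dH <- aggregate_replicates(vapply(per_rep, `[[`, 0, "dH_kcal"))
    dS <- aggregate_replicates(vapply(per_rep, `[[`, 0, "dS_cal"))
    dG <- delta_g(list(dH_kcal = dH$mean, dS_cal = dS$mean,
                       se_dH = dH$sd, se_dS = dS$sd), 310.15)
    diag$eyring <- list(dH = dH, dS = dS, dG_310K = dG,
                        per_replicate = per_rep)
  }
  visc_ids <- grep("^viscosity_", names(fits), value = TRUE)
  if ("viscosity" %in% analyses && length(visc_ids) >= 2) {
    gly <- as.numeric(sub("^viscosity_", "", visc_ids))
    eta <- 1 + gly / 30 * 2
    k <- vapply(visc_ids, function(id) fits[[id]]$k_obs$mean, 0)
    rel <- k / k[which.min(eta)]
    diag$viscosity_slope <- unname(stats::coef(stats::lm(rel ~ eta))[2])
  }
  verdict <- NULL
  if ("verdict" %in% analyses) {
    have <- !vapply(list(diag$elemental_correct, diag$viscosity_slope,
                         diag$partition), is.null, TRUE)
    if (any(have)) {
      verdict <- classify_rate_limiting(
        elemental = diag$elemental_correct,
        viscosity_slope = diag$viscosity_slope,
        amplitude_ratio = if (!is.null(diag$partition))
          diag$partition$amplitude_ratio else NULL)
    }
  }
  report <- structure(
    list(fits = fits, diagnostics = diag, verdict = verdict,
         provenance = list(
           seed = seed,
           n_experiments = length(tcs),
           analyses = analyses,
           package_version = as.character(utils::packageVersion("polbkin")),
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "run_report")
  if (!is.null(config$out_json)) {
    jsonlite::write_json(report_to_list(report), config$out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' Flatten a run report into plain lists for JSON serialization
#'
#' Derived statistics are additionally rounded to two significant
#' figures in a `summary` block; full precision is retained in the body.
#'
#' @param report A `run_report`.
#' @return A plain nested list.
#' @export
report_to_list <- function(report) {
  s2 <- function(x) signif(x, 2)
  summary <- list()
  d <- report$diagnostics
  if (!is.null(d$elemental_correct)) {
    summary$elemental_effect_correct <- s2(d$elemental_correct$ratio)
  }
  if (!is.null(d$elemental_mismatch)) {
    summary$elemental_effect_mismatch <- s2(d$elemental_mismatch$ratio)
  }
  if (!is.null(d$partition)) {
    summary$amplitude_ratio <- s2(d$partition$amplitude_ratio)
    summary$amplitude_difference_nM <- s2(d$partition$amplitude_difference)
    summary$K_int <- s2(d$partition$K_int)
    summary$release_rate_s1 <- s2(d$partition$release_rate)
  }
  if (!is.null(d$eyring)) {
    summary$dH_kcal <- s2(d$eyring$dH$mean)
    summary$dS_cal <- s2(d$eyring$dS$mean)
    summary$dG_310K_kcal <- s2(unname(d$eyring$dG_310K["dG_kcal"]))
  }
  if (!is.null(report$verdict)) summary$verdict <- report$verdict$verdict
  fits <- lapply(report$fits, function(f) {
    out <- list()
    for (p in intersect(names(f), c("A", "k_obs", "slope", "intercept"))) {
      out[[p]] <- list(mean = f[[p]]$mean, sd = f[[p]]$sd, n = f[[p]]$n)
    }
    out
  })
  list(summary = summary, fits = fits,
       diagnostics = lapply(d, function(x) {
         if (is.list(x)) unclass(x)[!vapply(unclass(x), is.list, TRUE)]
         else x
       }),
       provenance = report$provenance)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  s <- report_to_list(x)$summary
  for (nm in names(s)) cat(sprintf("  %s: %s\n", nm, as.character(s[[nm]])))
  cat(sprintf("  (%d experiments, seed %s)\n",
              x$provenance$n_experiments, as.character(x$provenance$seed)))
  invisible(x)
}
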