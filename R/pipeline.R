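#' Default pipeline configuration
#'
#' Central parameter set serialized into every output's provenance header.
#' Defaults: per-link significance level 0.05 (no multiple-testing
#' correction, a Bonferroni switch exists), beat-domain maximum lag 4, raw
#' rate 250 Hz, signal representations at 25 and 2.5 Hz, ADF screen at
#' 0.05, 256 spectral grid points, VAR order caps 20 (25 Hz) and 10
#' (2.5 Hz), TiMINo distance-correlation permutation test with 200
#' permutations at level 0.05.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    alpha = 0.05,
    bonferroni = FALSE,
    max_lag_beats = 4L,
    fs_raw = 250,
    fs_ds1 = 25,
    fs_ds2 = 2.5,
    adf_alpha = 0.05,
    n_freqs = 256L,
    max_order_ds1 = 20L,
    max_order_ds2 = 10L,
    timino_n_perm = 200L,
    timino_alpha_ind = 0.05,
    methods = c("time", "spectral", "extended", "timino"),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fs_raw > 0, cfg$fs_ds1 > 0,
            cfg$fs_ds2 > 0)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a \code{pipeline_config}.
#' @return \code{read_pipeline_config} returns a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Analyze one recording with the configured causality methods
#'
#' Preprocesses a raw recording, builds the 25 Hz and 2.5 Hz signal sets
#' and the beat-by-beat sequence, screens stationarity, and runs the
#' enabled frameworks: time-domain pairwise-conditional Granger causality
#' (25 Hz), spectral Granger causality (2.5 Hz), extended zero-lag Granger
#' causality and TiMINo discovery (beat sequences).
#'
#' @param rec a \code{raw_recording}.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with per-method result data frames (\code{time},
#'   \code{spectral}, \code{extended}, \code{timino}), the
#'   \code{stationarity} screen, and the intermediate representations.
#' @export
analyze_recording <- function(rec, config = pipeline_config()) {
  alpha <- if (isTRUE(config$bonferroni)) config$alpha / 6 else config$alpha
  ss25 <- build_signal_set(rec, fs_out = config$fs_ds1)
  ss2p5 <- downsample_signal_set(ss25, fs_out = config$fs_ds2)
  bs <- build_beat_sequence(ss25$r_peaks, ss25$z_smooth, ss25$phases,
                            ss25$insp_onsets, rec$fs)
  meta <- data.frame(subject = rec$subject_id, posture = rec$posture,
                     group = rec$group, stringsAsFactors = FALSE)
  out <- list(stationarity = cbind(meta, screen_stationarity(ss25)))

  if ("time" %in% config$methods) {
    out$time <- cbind(meta, gc_all_links(ss25$series,
                                         max_order = config$max_order_ds1,
                                         alpha = alpha))
  }
  if ("spectral" %in% config$methods) {
    out$spectral <- cbind(meta, spectral_all_links(ss2p5$series,
                                                   fs = config$fs_ds2,
                                                   n_freqs = config$n_freqs,
                                                   max_order = config$max_order_ds2,
                                                   alpha = alpha))
  }
  if ("extended" %in% config$methods) {
    out$extended <- cbind(meta, extended_all_links(bs,
                                                   max_lag = config$max_lag_beats,
                                                   alpha = alpha))
  }
  if ("timino" %in% config$methods) {
    out$timino <- cbind(meta, timino_all_pairs(bs,
                                               max_lag = config$max_lag_beats,
                                               alpha_ind = config$timino_alpha_ind,
                                               n_perm = config$timino_n_perm,
                                               seed = config$seed))
  }
  out$signal_set <- ss25
  out$beat_sequence <- bs
  out
}

#' Run the end-to-end cohort analysis
#'
#' Orchestrates preprocess, derive, stationarity screening, the enabled
#' causality methods and cohort summarization over either a synthetic
#' cohort (a \code{\link{simulate_cohort}} result, realized one recording
#' at a time) or a directory of signal CSV + JSON sidecar files.
#' Per-recording failures are caught, logged in the manifest and skipped;
#' a series flagged non-stationary is reported but not excluded.
#'
#' @param input a \code{cohort} object or a directory path with signal
#'   CSVs.
#' @param config a \code{\link{pipeline_config}}.
#' @param output_dir optional directory; when given, per-method results,
#'   summaries and the manifest are written as CSVs keyed with the config
#'   hash and seed.
#' @param progress print per-recording progress lines.
#' @return list of class \code{pipeline_result}: \code{results}
#'   (per-method stacked data frames), \code{stationarity},
#'   \code{summaries} (per-link tables: \code{time} and \code{extended}
#'   prediction improvements, \code{spectral} peak amplitude/frequency),
#'   \code{census} (TiMINo link counts), \code{subjects},
#'   \code{manifest}, \code{config}, \code{config_hash}.
#' @export
run_pipeline <- function(input, config = pipeline_config(), output_dir = NULL,
                         progress = FALSE) {
  jobs <- pipeline_jobs(input)
  results <- list(time = list(), spectral = list(), extended = list(),
                  timino = list(), stationarity = list())
  manifest <- list()
  subjects <- list()
  for (i in seq_along(jobs)) {
    job <- jobs[[i]]
    rec <- try(job(), silent = TRUE)
    if (inherits(rec, "try-error")) {
      manifest[[length(manifest) + 1L]] <- data.frame(
        item = names(jobs)[i], error = conditionMessage(attr(rec, "condition")),
        stringsAsFactors = FALSE)
      next
    }
    if (progress) message(sprintf("[%d/%d] %s %s", i, length(jobs),
                                  rec$subject_id, rec$posture))
    ana <- try(analyze_recording(rec, config), silent = TRUE)
    if (inherits(ana, "try-error")) {
      manifest[[length(manifest) + 1L]] <- data.frame(
        item = paste(rec$subject_id, rec$posture),
        error = conditionMessage(attr(ana, "condition")),
        stringsAsFactors = FALSE)
      next
    }
    for (m in c("time", "spectral", "extended", "timino", "stationarity")) {
      if (!is.null(ana[[m]])) results[[m]][[length(results[[m]]) + 1L]] <- ana[[m]]
    }
    subjects[[length(subjects) + 1L]] <- data.frame(
      subject = rec$subject_id, posture = rec$posture, group = rec$group,
      sex = rec$sex, stringsAsFactors = FALSE)
  }
  results <- lapply(results, function(l) if (length(l)) do.call(rbind, l) else NULL)
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(item = character(0), error = character(0))

  summaries <- list()
  if (!is.null(results$time)) summaries$time <- summarize_links(results$time, "pi")
  if (!is.null(results$extended)) {
    summaries$extended <- summarize_links(results$extended, "pi")
  }
  if (!is.null(results$spectral)) {
    summaries$spectral_g <- summarize_links(results$spectral, "peak_g")
    summaries$spectral_f <- summarize_links(results$spectral, "peak_f")
  }
  census <- if (!is.null(results$timino) && nrow(results$timino)) {
    res <- results$timino
    res$group <- ifelse(res$group == "control", "control", "athlete")
    cohort_link_census(res)
  } else NULL

  out <- structure(list(results = results,
                        stationarity = results$stationarity,
                        summaries = summaries, census = census,
                        subjects = if (length(subjects)) do.call(rbind, subjects) else NULL,
                        manifest = manifest, config = config,
                        config_hash = config_hash(config)),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_result(out, output_dir)
  out
}

pipeline_jobs <- function(input) {
  if (inherits(input, "cohort")) {
    jobs <- lapply(input$specs, function(sp) function() simulate_subject(sp))
    names(jobs) <- paste(input$subjects$subject, input$subjects$posture)
    return(jobs)
  }
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!grepl("_(rpeaks|phases)\\.csv$", files)]
    files <- files[file.exists(sidecar_path(files))]
    jobs <- lapply(files, function(f) function() read_recording(f))
    names(jobs) <- basename(files)
    return(jobs)
  }
  stop("input must be a cohort object or an existing directory", call. = FALSE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  n_rec <- if (is.null(x$subjects)) 0L else nrow(x$subjects)
  cat(sprintf("pipeline result: %d recordings analyzed, %d failures\n",
              n_rec, nrow(x$manifest)))
  for (m in c("time", "spectral", "extended", "timino")) {
    if (!is.null(x$results[[m]])) {
      cat(sprintf("  %-9s %d link rows\n", m, nrow(x$results[[m]])))
    }
  }
  invisible(x)
}

write_pipeline_result <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- sprintf("%s_seed%d", substr(res$config_hash, 1, 8), res$config$seed)
  prov <- sprintf("# config_hash=%s seed=%d", res$config_hash, res$config$seed)
  emit <- function(df, stem) {
    if (is.null(df)) return(invisible(NULL))
    path <- file.path(output_dir, sprintf("%s_%s.csv", stem, tag))
    con <- file(path, "w")
    writeLines(prov, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  for (m in names(res$results)) emit(res$results[[m]], paste0("results_", m))
  for (s in names(res$summaries)) emit(res$summaries[[s]], paste0("summary_", s))
  if (!is.null(res$census)) emit(res$census$counts, "timino_census")
  emit(res$manifest, "manifest")
  write_pipeline_config(res$config, file.path(output_dir,
                                              sprintf("config_%s.yaml", tag)))
  invisible(output_dir)
}
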