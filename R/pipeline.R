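# End-to-end pipeline: acquire segments (AlphaPose files + annotations, or
# the synthetic generator), clean, normalize with each method, evaluate,
# and write a provenance-carrying report.

#' Build a synthetic study cohort
#'
#' Emulates the study design the pipeline targets: `n_per_group`
#' participants in each of the three clinical groups (EOA, DCD, CON), each
#' walking towards and away from the camera twice, giving
#' `3 * n_per_group * 4` segments. Walking towards the camera is a rising
#' scale ramp, walking away a falling one; body size varies mildly across
#' participants; every segment's generator seed derives deterministically
#' from `seed`.
#'
#' @param n_per_group participants per group.
#' @param n_frames frames per segment.
#' @param seed master seed.
#' @param ... further arguments passed to [synthetic_gait_config()]
#'   (e.g. `noise_sd`, `dropout_rate`).
#' @return A list with `segments` (list of `gait_segment`), `truths` and
#'   `configs`, in matching order.
#' @export
synthetic_study <- function(n_per_group = 5, n_frames = 100, seed = 1L, ...) {
  segments <- list(); truths <- list(); configs <- list()
  k <- 0L
  for (g in c("EOA", "DCD", "CON")) {
    for (p in seq_len(n_per_group)) {
      pid <- sprintf("%s%02d", g, p)
      size <- 1 + 0.1 * .sub_rnorm(seed, 9000L + k, 1)  # child size spread
      for (dir in c("towards", "away")) {
        for (rep in 1:2) {
          k <- k + 1L
          cfg <- synthetic_gait_config(
            n_frames = n_frames, profile = g,
            seed = (abs(seed) * 1009L + k) %% 2147483647L,
            px_per_unit = 28 * size,
            scale_start = if (dir == "towards") 1 else 2,
            scale_end = if (dir == "towards") 2 else 1,
            ...)
          sim <- simulate_gait(cfg)
          sim$segment$participant_id <- pid
          sim$segment$direction <- dir
          sim$segment$segment_label <- sprintf("%s-%d", dir, rep)
          segments[[k]] <- sim$segment
          truths[[k]] <- sim$truth
          configs[[k]] <- cfg
        }
      }
    }
  }
  list(segments = segments, truths = truths, configs = configs)
}

#' Pipeline run configuration
#'
#' Validated bundle of everything one pipeline run needs. Provide either
#' `input` (AlphaPose result files, named by participant id, plus an
#' `annotations` table or CSV path) or `synthetic` (a list of
#' [synthetic_gait_config()]s, or the output of [synthetic_study()]).
#'
#' @param input character vector of AlphaPose JSON paths, names =
#'   participant ids (optional if `synthetic` given).
#' @param annotations annotation CSV path or data frame (see
#'   [read_annotations()]).
#' @param synthetic synthetic input, see above.
#' @param methods scaling methods to evaluate.
#' @param cleaning a [cleaning_policy()].
#' @param x0,y0 recentering offset.
#' @param on_degenerate degenerate-frame policy.
#' @param output_dir optional directory for the JSON report.
#' @param seed seed recorded for provenance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, annotations = NULL,
                            synthetic = NULL,
                            methods = norm_methods(),
                            cleaning = cleaning_policy(),
                            x0 = 640, y0 = 200,
                            on_degenerate = "skip",
                            output_dir = NULL, seed = 1L) {
  if (is.null(input) && is.null(synthetic))
    stop("provide 'input' files or a 'synthetic' specification",
         call. = FALSE)
  if (!is.null(input)) {
    missing <- input[!file.exists(input)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (is.null(annotations))
      stop("'annotations' are required with file input", call. = FALSE)
    if (is.character(annotations)) annotations <- read_annotations(annotations)
  }
  methods <- vapply(methods, .match_method, character(1))
  stopifnot(inherits(cleaning, "cleaning_policy"))
  structure(list(input = input, annotations = annotations,
                 synthetic = synthetic, methods = methods,
                 cleaning = cleaning, x0 = x0, y0 = y0,
                 on_degenerate = on_degenerate,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: acquire segments, clean frames, summarize prediction likelihood
#' before/after cleaning (with a paired t-test at the segment level),
#' normalize with every configured method and evaluate. The returned report
#' embeds the configuration and per-stage frame counts, so every number is
#' regenerable from it; given the same config (and seed) the result is
#' deterministic.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `report` (a
#'   `gait_eval_report`), `likelihood` (before/after summaries and the
#'   paired test), `counts` (frames read / removed / retained), and
#'   `config`. If `config$output_dir` is set, a JSON rendering is written
#'   to `<output_dir>/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  segments <- .acquire_segments(config)
  if (length(segments) == 0L)
    stop("pipeline stage 'acquire': no segments found", call. = FALSE)

  cleaned <- lapply(segments, function(s)
    tryCatch(filter_frames(s, config$cleaning),
             error = function(e) stop("pipeline stage 'clean': ",
                                      conditionMessage(e), call. = FALSE)))
  clean_segs <- lapply(cleaned, `[[`, "segment")
  removed <- lapply(cleaned, `[[`, "removed")

  lik_before <- likelihood_summary(segments)
  lik_after <- likelihood_summary(clean_segs)
  lik_test <- tryCatch(
    paired_t(lik_after$per_unit_means, lik_before$per_unit_means),
    error = function(e) NULL)

  report <- evaluate_methods(clean_segs, methods = config$methods,
                             x0 = config$x0, y0 = config$y0,
                             on_degenerate = config$on_degenerate)

  counts <- list(segments = length(segments),
                 frames_read = sum(vapply(segments, n_frames, integer(1))),
                 frames_removed = sum(lengths(removed)),
                 frames_retained = sum(vapply(clean_segs, n_frames,
                                              integer(1))))
  out <- structure(list(report = report,
                        likelihood = list(before = lik_before,
                                          after = lik_after,
                                          paired_t = lik_test),
                        counts = counts,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_report_json(out, file.path(config$output_dir, "report.json"))
  }
  out
}

.acquire_segments <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    if (!is.null(syn$segments)) return(syn$segments)  # synthetic_study()
    if (inherits(syn, "synthetic_gait_config")) syn <- list(syn)
    return(lapply(syn, function(cf) simulate_gait(cf)$segment))
  }
  segs <- list()
  ids <- names(config$input)
  if (is.null(ids)) ids <- rep(NA_character_, length(config$input))
  for (i in seq_along(config$input)) {
    dets <- read_alphapose(config$input[i])
    track <- select_track(dets, "auto")
    ann <- config$annotations
    if (!is.na(ids[i])) ann <- ann[ann$participant_id == ids[i], ]
    segs <- c(segs, extract_segments(track, ann))
  }
  segs
}

.write_report_json <- function(result, path) {
  obj <- list(
    format = "gaitnorm-report", version = 1L,
    settings = result$report$settings,
    cleaning = unclass(result$config$cleaning),
    seed = result$config$seed,
    counts = result$counts,
    likelihood = list(
      before = list(mean = result$likelihood$before$grand_mean,
                    sd = result$likelihood$before$grand_sd),
      after = list(mean = result$likelihood$after$grand_mean,
                   sd = result$likelihood$after$grand_sd),
      paired_t = result$likelihood$paired_t),
    angle_error = result$report$angle_error,
    distance_variance = result$report$distance_variance,
    by_group = result$report$by_group,
    tests = result$report$tests)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$counts$segments, "segments,",
      x$counts$frames_read, "frames read,",
      x$counts$frames_removed, "removed by cleaning\n")
  cat(sprintf("Likelihood: %.3f before -> %.3f after cleaning\n",
              x$likelihood$before$grand_mean,
              x$likelihood$after$grand_mean))
  if (!is.null(x$likelihood$paired_t))
    cat(sprintf("  paired t(%d) = %.2f, p = %.3g\n",
                x$likelihood$paired_t$df, x$likelihood$paired_t$t,
                x$likelihood$paired_t$p))
  cat("\n")
  print(x$report)
  invisible(x)
}
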