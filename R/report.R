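# Method comparison across a collection of segments: angle errors,
# distance variances (overall and per group), and group tests.

#' Evaluate normalization methods over a segment collection
#'
#' For every requested scaling method, normalizes each segment and
#' summarizes (1) the mean absolute angle error against the original
#' coordinates — averaged over frames within a segment, then over segments,
#' then over the 12 evaluated angles — and (2) the mean variance of the
#' four bilateral pair distances, overall and per clinical group, with the
#' original (unnormalized) coordinates as the baseline row. Optionally runs
#' Mann-Whitney U tests between groups on the per-segment wrist and ankle
#' distance variances (the sampling unit is the segment).
#'
#' @param segments list of `gait_segment`s (cleaned).
#' @param methods character vector of methods, default all seven.
#' @param x0,y0 recentering offset passed to [normalize_segment()].
#' @param on_degenerate degenerate-frame policy, see [segment_reference()];
#'   the default `"skip"` tolerates the near-zero frame heights the `S` and
#'   `H` methods produce in frontal walking.
#' @param group_tests run between-group Mann-Whitney U tests on wrist and
#'   ankle variances.
#' @param p_adjust `"none"` (default) or `"holm"` for the group tests.
#' @return An object of class `gait_eval_report`: list with `angle_error`
#'   (data frame, one row per method: the 12 per-angle means and `overall`),
#'   `distance_variance` (data frame, rows original + methods, columns the
#'   four pairs), `by_group` (same, split by group), `tests` (data frame of
#'   comparisons) and `settings`.
#' @export
evaluate_methods <- function(segments, methods = norm_methods(),
                             x0 = 640, y0 = 200,
                             on_degenerate = "skip",
                             group_tests = TRUE,
                             p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (inherits(segments, "gait_segment")) segments <- list(segments)
  stopifnot(length(segments) >= 1L)
  methods <- vapply(methods, .match_method, character(1))
  groups <- unique(stats::na.omit(vapply(segments, `[[`, character(1),
                                         "group")))
  pairs <- distance_pairs()$name

  per_seg_var <- function(segs, pair)
    vapply(segs, function(s) stats::var(pair_distance_series(s, pair)),
           numeric(1))

  dv_row <- function(segs)
    vapply(pairs, function(p) mean(per_seg_var(segs, p)), numeric(1))

  angle_tab <- NULL
  dv_tab <- list(original = dv_row(segments))
  by_group <- list()
  raw_var <- list(original = lapply(stats::setNames(pairs, pairs),
                                    function(p) per_seg_var(segments, p)))
  for (g in groups)
    by_group[[length(by_group) + 1L]] <-
      data.frame(method = "original", group = g,
                 t(dv_row(Filter(function(s) identical(s$group, g),
                                 segments))))

  normalized <- list()
  for (m in methods) {
    norm_m <- suppressWarnings(
      lapply(segments, normalize_segment, method = m, x0 = x0, y0 = y0,
             on_degenerate = on_degenerate))
    normalized[[m]] <- norm_m
    errs <- t(vapply(seq_along(segments), function(i) {
      before <- segments[[i]]
      after <- norm_m[[i]]
      if (!identical(before$frame_index, after$frame_index))
        before <- subset_frames(before,
                                before$frame_index %in% after$frame_index)
      angle_error(before, after)$per_angle
    }, numeric(12)))
    per_angle <- colMeans(errs)
    angle_tab <- rbind(angle_tab,
                       data.frame(method = m, t(per_angle),
                                  overall = mean(per_angle)))
    dv_tab[[m]] <- dv_row(norm_m)
    raw_var[[m]] <- lapply(stats::setNames(pairs, pairs),
                           function(p) per_seg_var(norm_m, p))
    for (g in groups)
      by_group[[length(by_group) + 1L]] <-
        data.frame(method = m, group = g,
                   t(dv_row(Filter(function(s) identical(s$group, g),
                                   norm_m))))
  }

  tests <- NULL
  if (group_tests && length(groups) >= 2L) {
    combos <- utils::combn(sort(groups), 2, simplify = FALSE)
    for (m in names(raw_var)) {
      for (p in c("wrists", "ankles")) {
        for (cb in combos) {
          gidx <- function(g) vapply(segments, function(s)
            identical(s$group, g), logical(1))
          smp <- raw_var[[m]][[p]]
          mw <- mann_whitney_u(smp[gidx(cb[1])], smp[gidx(cb[2])])
          tests <- rbind(tests, data.frame(
            method = m, pair = p,
            comparison = paste(cb[1], "vs", cb[2]),
            U = mw$U, p = mw$p, exact = mw$exact))
        }
      }
    }
    if (p_adjust == "holm") tests$p_adj <- stats::p.adjust(tests$p, "holm")
  }

  dv <- data.frame(method = names(dv_tab),
                   do.call(rbind, dv_tab), row.names = NULL)
  structure(list(angle_error = angle_tab,
                 distance_variance = dv,
                 by_group = if (length(by_group))
                   do.call(rbind, by_group) else NULL,
                 tests = tests,
                 settings = list(methods = methods, x0 = x0, y0 = y0,
                                 on_degenerate = on_degenerate,
                                 n_segments = length(segments),
                                 p_adjust = p_adjust,
                                 aggregation =
                                   "frames -> segments -> angle set")),
            class = "gait_eval_report")
}

#' @export
print.gait_eval_report <- function(x, digits = 3, ...) {
  cat("Gait normalization evaluation over", x$settings$n_segments,
      "segment(s)\n\n")
  cat("Mean absolute angle error (degrees):\n")
  ae <- x$angle_error
  print(data.frame(method = ae$method,
                   overall = round(ae$overall, digits)), row.names = FALSE)
  cat("\nMean variance of pair distance (px^2):\n")
  dv <- x$distance_variance
  dv[-1] <- round(dv[-1], digits)
  print(dv, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nGroup comparisons (Mann-Whitney U on per-segment variances):\n")
    tt <- x$tests
    tt$p <- signif(tt$p, 3)
    print(utils::head(tt, 12), row.names = FALSE)
    if (nrow(tt) > 12) cat("  ...", nrow(tt) - 12, "more rows\n")
  }
  invisible(x)
}

#' @export
summary.gait_eval_report <- function(object, ...) print(object, ...)
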