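# Structured analysis report mirroring the study's results layout:
# behavioral descriptives with Wilcoxon tests, P3 latency (paired t) and
# amplitude (load x anterior-posterior x lateral-medial rm-ANOVA), alpha
# latency (load x activity rm-ANOVA plus per-activity paired contrasts,
# and condition-collapsed grand latencies), evoked/induced amplitude
# rm-ANOVAs, and Rayleigh summaries of the phase analysis.

descriptives <- function(df, value, by) {
  agg <- stats::aggregate(df[[value]], list(df[[by]]),
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- lapply(seq_len(nrow(agg)), function(i)
    list(mean = unname(agg$x[i, "mean"]), sd = unname(agg$x[i, "sd"])))
  names(out) <- agg$Group.1
  out
}

paired_by_condition <- function(df, value, conditions = c("ST", "DT")) {
  wide <- stats::reshape(df[c("subject", "condition", value)],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  x <- wide[[paste0(value, ".", conditions[1])]]
  y <- wide[[paste0(value, ".", conditions[2])]]
  list(x = x, y = y)
}

#' Assemble the full statistical report
#'
#' @param latency_table Long data frame: subject, condition, signal_kind
#'   (`P3`, `evoked_alpha`, `induced_alpha`), electrode, latency_ms,
#'   amplitude_uv.
#' @param p3_matrix,evoked_matrix,induced_matrix Long electrode-matrix
#'   amplitude tables from [matrix_amplitudes()] (all subjects, both
#'   conditions).
#' @param behavior Data frame: subject, condition, rt_ms, accuracy_pct; or
#'   `NULL` to omit the behavioral section.
#' @param phase_table Data frame: subject, condition, activity, phase
#'   (radians); or `NULL` to omit the phase section.
#' @param alpha Significance level used by normality gates (default 0.05).
#' @return Nested list of class `tse_report`; see [write_report()].
#' @export
analysis_report <- function(latency_table, p3_matrix, evoked_matrix,
                            induced_matrix, behavior = NULL,
                            phase_table = NULL, alpha = 0.05) {
  need <- function(x, what) if (is.null(x)) stop("missing input: ", what)
  need(latency_table, "latency_table"); need(p3_matrix, "p3_matrix")
  need(evoked_matrix, "evoked_matrix"); need(induced_matrix, "induced_matrix")
  rep_ <- list()

  if (!is.null(behavior)) {
    rt <- paired_by_condition(behavior, "rt_ms")
    ac <- paired_by_condition(behavior, "accuracy_pct")
    rep_$behavioral <- list(
      rt = list(descriptives = descriptives(behavior, "rt_ms", "condition"),
                test = tryCatch(wilcoxon_signed_rank(rt$x, rt$y),
                                error = function(e)
                                  list(error = conditionMessage(e)))),
      accuracy = list(
        descriptives = descriptives(behavior, "accuracy_pct", "condition"),
        test = tryCatch(wilcoxon_signed_rank(ac$x, ac$y),
                        error = function(e) list(error = conditionMessage(e)))))
  }

  lat <- function(kind) latency_table[latency_table$signal_kind == kind, ]
  p3l <- paired_by_condition(lat("P3"), "latency_ms")
  rep_$p3 <- list(
    latency = list(
      descriptives = descriptives(lat("P3"), "latency_ms", "condition"),
      gate = shapiro_wilk(p3l$x - p3l$y),
      test = paired_t(p3l$x, p3l$y)),
    amplitude = list(
      anova = rm_anova(p3_matrix, dv = "amplitude_uv",
                       within = c("condition", "ap", "lm"))))

  alpha_lat <- latency_table[latency_table$signal_kind %in%
                               c("evoked_alpha", "induced_alpha"), ]
  alpha_lat$activity <- sub("_alpha$", "", alpha_lat$signal_kind)
  cond_means <- function(kind)
    vapply(split(lat(kind)$latency_ms, lat(kind)$condition), mean,
           numeric(1))
  ev_means <- cond_means("evoked_alpha")
  in_means <- cond_means("induced_alpha")
  per_activity <- lapply(c(evoked = "evoked_alpha", induced = "induced_alpha"),
                         function(kind) {
    pc <- paired_by_condition(lat(kind), "latency_ms")
    tryCatch(paired_comparison(pc$x, pc$y, alpha = alpha),
             error = function(e) list(error = conditionMessage(e)))
  })
  rep_$alpha_latency <- list(
    descriptives = list(
      evoked = descriptives(lat("evoked_alpha"), "latency_ms", "condition"),
      induced = descriptives(lat("induced_alpha"), "latency_ms", "condition")),
    grand_ms = list(evoked = latency_grand_average(ev_means),
                    induced = latency_grand_average(in_means)),
    anova = rm_anova(alpha_lat, dv = "latency_ms",
                     within = c("condition", "activity")),
    condition_contrasts = per_activity)

  rep_$alpha_amplitude <- list(
    evoked = list(anova = rm_anova(evoked_matrix, dv = "amplitude_uv",
                                   within = c("condition", "ap", "lm"))),
    induced = list(anova = rm_anova(induced_matrix, dv = "amplitude_uv",
                                    within = c("condition", "ap", "lm"))))

  if (!is.null(phase_table)) {
    groups <- split(phase_table,
                    list(phase_table$condition, phase_table$activity))
    rep_$phase <- lapply(groups, function(g)
      if (nrow(g) >= 2) rayleigh_test(g$phase) else NULL)
  }
  rep_$alpha_level <- alpha
  class(rep_) <- "tse_report"
  rep_
}

fmt_test <- function(t) {
  if (!is.null(t$error)) return(paste("  (not computed:", t$error, ")"))
  sprintf("  %s: statistic = %.3f, p = %.4g, n = %d",
          t$test_name, t$statistic, t$p_value, t$n)
}

fmt_anova <- function(a) {
  paste(sprintf(
    "  %-28s F(%g, %g) = %8.3f, eps = %.3f, p_gg = %.4g, pes = %.3f",
    a$name, a$df_num, a$df_den, a$F, a$gg_epsilon, a$p_gg,
    a$partial_eta_sq), collapse = "\n")
}

#' Write a report as JSON and readable text
#'
#' @param rep A `tse_report` from [analysis_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(rep, dir) {
  stopifnot(inherits(rep, "tse_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(rep), jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  tpath <- file.path(dir, "report.txt")
  lines <- c("TSE analysis report", "===================")
  if (!is.null(rep$behavioral)) {
    lines <- c(lines, "", "Behavior",
               sprintf("  RT (ms): ST %.1f +/- %.1f, DT %.1f +/- %.1f",
                       rep$behavioral$rt$descriptives$ST$mean,
                       rep$behavioral$rt$descriptives$ST$sd,
                       rep$behavioral$rt$descriptives$DT$mean,
                       rep$behavioral$rt$descriptives$DT$sd),
               fmt_test(rep$behavioral$rt$test),
               sprintf("  Accuracy (%%): ST %.2f +/- %.2f, DT %.2f +/- %.2f",
                       rep$behavioral$accuracy$descriptives$ST$mean,
                       rep$behavioral$accuracy$descriptives$ST$sd,
                       rep$behavioral$accuracy$descriptives$DT$mean,
                       rep$behavioral$accuracy$descriptives$DT$sd),
               fmt_test(rep$behavioral$accuracy$test))
  }
  lines <- c(lines, "", "P3 latency", fmt_test(rep$p3$latency$test),
             "", "P3 amplitude ANOVA", fmt_anova(rep$p3$amplitude$anova),
             "", sprintf("Alpha latency grand means: evoked %g ms, induced %g ms",
                         rep$alpha_latency$grand_ms$evoked,
                         rep$alpha_latency$grand_ms$induced),
             "Alpha latency ANOVA (load x activity)",
             fmt_anova(rep$alpha_latency$anova),
             "", "Evoked amplitude ANOVA",
             fmt_anova(rep$alpha_amplitude$evoked$anova),
             "", "Induced amplitude ANOVA",
             fmt_anova(rep$alpha_amplitude$induced$anova))
  if (!is.null(rep$phase)) {
    lines <- c(lines, "", "Phase (Rayleigh tests)")
    for (nm in names(rep$phase)) {
      r <- rep$phase[[nm]]
      if (!is.null(r))
        lines <- c(lines, sprintf("  %-18s R = %.3f, Z = %.3f, p = %.4g",
                                  nm, r$resultant_length, r$statistic,
                                  r$p_value))
    }
  }
  writeLines(lines, tpath)
  invisible(c(jpath, tpath))
}
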