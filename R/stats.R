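#' Configuration of the statistical layer
#'
#' @param alpha Significance threshold (default 0.05).
#' @param t_variant `"welch"` (unequal variances, default) or `"student"`
#'   (pooled variance). Welch is the defensible default when cell standard
#'   deviations differ by an order of magnitude, as is common for
#'   pupil-diameter summaries.
#' @return Object of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, t_variant = c("welch", "student")) {
  t_variant <- match.arg(t_variant)
  if (!(alpha > 0 && alpha < 1)) cg_stop("stat_config: alpha must be in (0,1)")
  structure(list(alpha = alpha, t_variant = t_variant), class = "stat_config")
}

#' Two-sample t-test on observer features
#'
#' Computes the two-sided two-sample t statistic from sample moments:
#' Welch's statistic with Welch-Satterthwaite degrees of freedom by
#' default, or the pooled-variance Student variant. Used to compare gaze
#' counts and pupil diameters between two observers (e.g. trail versus
#' lead referee) or two game phases.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param cfg A [stat_config()].
#' @return List of class `t_test_result`: `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`, `significant`.
#' @export
t_test_features <- function(sample_a, sample_b, cfg = stat_config()) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  n_a <- length(sample_a); n_b <- length(sample_b)
  if (n_a < 2L || n_b < 2L) cg_stop("t_test_features: need >= 2 observations per sample")
  v_a <- stats::var(sample_a); v_b <- stats::var(sample_b)
  if (v_a + v_b == 0) cg_stop("t_test_features: zero variance in both samples")
  m_a <- mean(sample_a); m_b <- mean(sample_b)
  if (cfg$t_variant == "welch") {
    se2 <- v_a / n_a + v_b / n_b
    t <- (m_a - m_b) / sqrt(se2)
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
    t <- (m_a - m_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean_a = m_a, mean_b = m_b,
                 sd_a = sqrt(v_a), sd_b = sqrt(v_b), n_a = n_a, n_b = n_b,
                 significant = p <= cfg$alpha),
            class = "t_test_result")
}

#' Two-by-two mixed-design ANOVA
#'
#' Classical sums-of-squares decomposition for a design with one
#' within-subjects factor (`phase`: attack/defense, both levels observed on
#' every subject) and one between-subjects factor (`coach`: two groups).
#' The between effect is tested against subjects-within-groups; the within
#' main effect and the interaction are tested against the
#' phase-by-subjects-within-groups residual. With two groups the error
#' degrees of freedom are `N_subjects - 2` for all three effects.
#'
#' Convention for degenerate data: an effect with zero sum of squares is
#' reported as `F = 0`, `p = 1`; a nonzero effect over a zero error sum of
#' squares is reported as `F = Inf`, `p = 0` and flagged with a message.
#'
#' @param data Data frame in long format with columns `subject_id`,
#'   `coach` (two levels), `phase` (two levels), `value`; each subject must
#'   contribute exactly one value per phase.
#' @return Object of class `mixed_anova`: a data frame with rows
#'   `between`, `within`, `interaction` and columns `ss`, `df_num`,
#'   `df_den`, `ms`, `ms_error`, `F`, `p`.
#' @export
mixed_anova_2x2 <- function(data) {
  need <- c("subject_id", "coach", "phase", "value")
  if (!all(need %in% names(data))) {
    cg_stop("mixed_anova_2x2: data must have columns %s",
            paste(need, collapse = ", "))
  }
  subj <- as.character(data$subject_id)
  coach <- as.character(data$coach)
  phase <- as.character(data$phase)
  y <- data$value
  if (any(is.na(y))) cg_stop("mixed_anova_2x2: missing values not supported")
  phases <- sort(unique(phase)); coaches <- sort(unique(coach))
  if (length(phases) != 2L || length(coaches) != 2L) {
    cg_stop("mixed_anova_2x2: exactly two phases and two coach groups required")
  }
  tab <- table(subj, phase)
  if (!all(tab == 1L)) {
    cg_stop("mixed_anova_2x2: each subject needs exactly one value per phase")
  }
  subj_coach <- tapply(coach, subj, function(g) length(unique(g)))
  if (any(subj_coach != 1L)) {
    cg_stop("mixed_anova_2x2: a subject appears in both coach groups")
  }
  subjects <- sort(unique(subj))
  N <- length(subjects)
  group_of <- tapply(coach, subj, `[[`, 1L)[subjects]
  if (any(table(group_of) < 2L)) {
    cg_stop("mixed_anova_2x2: need >= 2 subjects per coach group")
  }

  b <- 2L  # phase levels
  M <- mean(y)
  S <- tapply(y, subj, mean)[subjects]                 # subject means
  G <- tapply(y, coach, mean)                          # group means
  P <- tapply(y, phase, mean)                          # phase means
  C <- tapply(y, list(coach, phase), mean)             # cell means
  n_g <- table(group_of)[names(G)]                     # subjects per group

  ss_total <- sum((y - M)^2)
  ss_between_subj <- b * sum((S - M)^2)
  ss_coach <- b * sum(n_g * (G - M)^2)
  ss_subj_within <- ss_between_subj - ss_coach
  ss_phase <- N * sum((P - M)^2)
  ss_inter <- sum(outer(as.numeric(n_g), rep(1, 2)) *
                    (C - outer(G, rep(1, 2)) - outer(rep(1, 2), P) + M)^2)
  ss_err_within <- ss_total - ss_coach - ss_subj_within - ss_phase - ss_inter
  ss_err_within <- max(ss_err_within, 0)

  df_subj_w <- N - 2L
  df_err_w <- N - 2L   # (b - 1) * (N - groups), b = 2, groups = 2
  ms_subj_w <- ss_subj_within / df_subj_w
  ms_err_w <- ss_err_within / df_err_w

  eff <- function(name, ss, ms_err, df_den) {
    ms <- ss / 1
    if (ss <= 0) {
      f <- 0; p <- 1
    } else if (ms_err <= 0) {
      cg_warn(sprintf("mixed_anova_2x2: zero error sum of squares for %s effect", name))
      f <- Inf; p <- 0
    } else {
      f <- ms / ms_err
      p <- stats::pf(f, 1, df_den, lower.tail = FALSE)
    }
    data.frame(effect = name, ss = ss, df_num = 1L, df_den = df_den,
               ms = ms, ms_error = ms_err, F = f, p = p)
  }
  out <- rbind(eff("between", ss_coach, ms_subj_w, df_subj_w),
               eff("within", ss_phase, ms_err_w, df_err_w),
               eff("interaction", ss_inter, ms_err_w, df_err_w))
  attr(out, "n_subjects") <- N
  attr(out, "ss_subjects_within") <- ss_subj_within
  attr(out, "ss_error_within") <- ss_err_within
  class(out) <- c("mixed_anova", class(out))
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("2x2 mixed-design ANOVA (%d subjects)\n", attr(x, "n_subjects")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s F(%d,%d) = %.4f, p = %.4g\n", x$effect[i],
                x$df_num[i], x$df_den[i], x$F[i], x$p[i]))
  }
  invisible(x)
}

#' Pull a long per-cell observation table out of feature tables
#'
#' Stacks one feature table per clip/condition into the long format used by
#' [report_tables()]: one row per (measure, team, condition, clip value),
#' with `DIA` rows carrying pupil means and `GAZE` rows carrying gaze-event
#' counts.
#'
#' @param tables Named list of lists of `feature_table`s:
#'   `tables[[condition]][[clip]]`.
#' @return Long data frame: `measure`, `team`, `condition`, `clip`, `value`.
#' @export
feature_tables_long <- function(tables) {
  rows <- list()
  for (cond in names(tables)) {
    for (k in seq_along(tables[[cond]])) {
      ft <- tables[[cond]][[k]]
      agg <- stats::aggregate(cbind(gaze_event_count, n_pupil) ~ team, ft, sum)
      for (tm in agg$team) {
        sel <- ft$team == tm
        dia <- stats::weighted.mean(ft$pupil_mean[sel], ft$n_pupil[sel])
        rows[[length(rows) + 1L]] <- data.frame(
          measure = c("DIA", "GAZE"), team = tm, condition = cond, clip = k,
          value = c(dia, sum(ft$gaze_event_count[sel])))
      }
    }
  }
  do.call(rbind, rows)
}

#' Comparison tables of pupil diameter and gaze count
#'
#' Lays out the standard report: one row per measure (`DIA`, `GAZE`) and
#' observed team (A, B, total), with mean and standard deviation per
#' condition, the two-sided t-test p value, and a significance marker
#' (`*` when `p <= alpha`).
#'
#' @param long Long observation table ([feature_tables_long()]), with
#'   exactly two levels in `condition`.
#' @param cfg A [stat_config()].
#' @return Data frame with one row per measure x team.
#' @export
report_tables <- function(long, cfg = stat_config()) {
  conds <- sort(unique(long$condition))
  if (length(conds) == 0L) {
    return(data.frame(measure = character(0), team = character(0),
                      mean_1 = numeric(0), sd_1 = numeric(0),
                      mean_2 = numeric(0), sd_2 = numeric(0),
                      p = numeric(0), significant = logical(0)))
  }
  if (length(conds) != 2L) cg_stop("report_tables: exactly two conditions required")
  combos <- expand.grid(measure = c("DIA", "GAZE"),
                        team = c("A", "B", "total"),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$measure, combos$team), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- long$measure == combos$measure[i] & long$team == combos$team[i]
    a <- long$value[sel & long$condition == conds[[1]]]
    b <- long$value[sel & long$condition == conds[[2]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    row <- data.frame(measure = combos$measure[i], team = combos$team[i],
                      mean_1 = NA_real_, sd_1 = NA_real_,
                      mean_2 = NA_real_, sd_2 = NA_real_,
                      p = NA_real_, significant = NA)
    if (length(a)) { row$mean_1 <- mean(a); row$sd_1 <- stats::sd(a) }
    if (length(b)) { row$mean_2 <- mean(b); row$sd_2 <- stats::sd(b) }
    tt <- tryCatch(t_test_features(a, b, cfg), error = function(e) NULL)
    if (!is.null(tt)) { row$p <- tt$p; row$significant <- tt$significant }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "conditions") <- conds
  out
}

#' Format a comparison table as aligned plain text
#' @param report Output of [report_tables()].
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  conds <- attr(report, "conditions") %||% c("cond1", "cond2")
  fmt <- function(m, s) ifelse(is.na(m), "-",
                               sprintf("%.3f ± %.3f", m, s))
  lines <- c(sprintf("%-6s %-6s %-18s %-18s %-8s %s",
                     "meas", "team", conds[[1]], conds[[2]], "p", "sig"))
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf("%-6s %-6s %-18s %-18s %-8s %s",
                              r$measure, r$team, fmt(r$mean_1, r$sd_1),
                              fmt(r$mean_2, r$sd_2),
                              ifelse(is.na(r$p), "-", sprintf("%.4f", r$p)),
                              ifelse(isTRUE(r$significant), "*", "")))
  }
  lines
}

#' Write / read a report table as CSV (lossless round trip)
#' @param report Output of [report_tables()].
#' @param path Destination CSV.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
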