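test_that("t-test handles identity, separation, and antisymmetry", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  tt <- t_test_features(a, b)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  shifted <- t_test_features(a, b + 10)
  expect_gt(abs(shifted$t), 10)
  expect_lt(shifted$p, 0.001)
  # closed form: equal variances, equal n -> t = -10 / (s * sqrt(2/3))
  s2 <- stats::var(a)
  expect_equal(shifted$t, -10 / sqrt(s2 * 2 / 3))

  fwd <- t_test_features(c(1, 5, 7, 2), c(4, 4, 9))
  rev <- t_test_features(c(4, 4, 9), c(1, 5, 7, 2))
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$df, rev$df)

  expect_error(t_test_features(c(1), c(1, 2)), ">= 2 observations")
  expect_error(t_test_features(c(2, 2), c(5, 5)), "zero variance")
})

test_that("t statistics match the reference implementation on random data", {
  set.seed(101)
  for (k in 1:50) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    mine <- t_test_features(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    mine_s <- t_test_features(a, b, stat_config(t_variant = "student"))
    ref_s <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine_s$t, unname(ref_s$statistic), tolerance = 1e-10)
    expect_equal(mine_s$p, ref_s$p.value, tolerance = 1e-10)
  }
})

test_that("mixed ANOVA handles constant data with the documented convention", {
  d <- expand.grid(subject_id = 1:8, phase = c("attack", "defense"))
  d$coach <- ifelse(d$subject_id <= 4, "A", "B")
  d$value <- 5
  an <- mixed_anova_2x2(d)
  expect_equal(an$F, c(0, 0, 0))
  expect_equal(an$p, c(1, 1, 1))
})

test_that("a pure interaction shows up in the interaction F with df_den N-2", {
  # opposite phase shifts per coach, no noise: cell-means oracle says the
  # phase main effect is exactly zero and all variance sits in the interaction
  d <- expand.grid(subject_id = 1:16, phase = c("attack", "defense"))
  d$coach <- ifelse(d$subject_id <= 8, "A", "B")
  shift <- ifelse(d$coach == "A", 1, -1) * ifelse(d$phase == "defense", 1, 0)
  set.seed(7)
  d$value <- 4 + shift + rnorm(nrow(d), sd = 0.01)    # tiny residual noise
  an <- mixed_anova_2x2(d)
  expect_equal(an$df_den, c(14L, 14L, 14L))
  i <- an[an$effect == "interaction", ]
  w <- an[an$effect == "within", ]
  expect_gt(i$F, 100 * max(w$F, 1e-12))
  # brute-force cell-means oracle for the interaction SS:
  # n * sum_gp (cell - coach - phase + grand)^2
  cm <- tapply(d$value, list(d$coach, d$phase), mean)
  gm <- mean(d$value); g <- rowMeans(cm); p <- colMeans(cm)
  ss_oracle <- 8 * sum((cm - outer(g, c(1, 1)) - outer(c(1, 1), p) + gm)^2)
  expect_equal(i$ss, ss_oracle, tolerance = 1e-10)
})

test_that("mixed ANOVA matches the aov Error-strata reference to 1e-8", {
  set.seed(29)
  for (k in 1:25) {
    n <- sample(3:10, 1)
    d <- generate_null_and_effect_datasets(
      n_per_cell = n, phase_shift_sd = runif(1, 0, 1.5),
      coach_shift_sd = runif(1, 0, 1.5), interaction_sd = runif(1, 0, 1.5),
      seed = 1000 + k)[[1]]
    mine <- mixed_anova_2x2(d)
    d$subject_id <- factor(d$subject_id)
    fit <- summary(stats::aov(value ~ coach * phase + Error(subject_id),
                              data = d))
    btw <- fit[["Error: subject_id"]][[1]]
    wth <- fit[["Error: Within"]][[1]]
    ref_F <- c(btw["coach", "F value"], wth["phase", "F value"],
               wth["coach:phase", "F value"])
    ref_p <- c(btw["coach", "Pr(>F)"], wth["phase", "Pr(>F)"],
               wth["coach:phase", "Pr(>F)"])
    expect_equal(mine$F, unname(ref_F), tolerance = 1e-8)
    expect_equal(mine$p, unname(ref_p), tolerance = 1e-8)
    expect_equal(mine$df_den, rep(2L * n - 2L, 3))
  }
})

test_that("unbalanced within-subject data is rejected", {
  d <- expand.grid(subject_id = 1:6, phase = c("attack", "defense"))
  d$coach <- ifelse(d$subject_id <= 3, "A", "B")
  d$value <- rnorm(nrow(d))
  expect_error(mixed_anova_2x2(d[-1, ]), "exactly one value per phase")
  d2 <- d; d2$coach[1] <- "B"
  expect_error(mixed_anova_2x2(d2), "both coach groups")
})

test_that("report tables lay out DIA/GAZE x team rows and round trip", {
  set.seed(31)
  long <- expand.grid(measure = c("DIA", "GAZE"), team = c("A", "B", "total"),
                      condition = c("attack", "defense"), clip = 1:6,
                      stringsAsFactors = FALSE)
  long$value <- ifelse(long$measure == "DIA", rnorm(nrow(long), 4, 0.2),
                       rpois(nrow(long), 40))
  rep_tab <- report_tables(long)
  expect_equal(nrow(rep_tab), 6L)        # DIA/GAZE x A/B/Total
  expect_true(all(!is.na(rep_tab$p)))
  expect_true(all(rep_tab$p >= 0 & rep_tab$p <= 1))
  # means/sds agree with direct computation for one row
  sel <- long$measure == "DIA" & long$team == "A" & long$condition == "attack"
  expect_equal(rep_tab$mean_1[rep_tab$measure == "DIA" & rep_tab$team == "A"],
               mean(long$value[sel]))
  p <- tempfile(fileext = ".csv")
  write_report(rep_tab, p)
  back <- read_report(p)
  expect_equal(back$mean_1, rep_tab$mean_1)
  expect_equal(back$p, rep_tab$p)
  expect_equal(back$significant, rep_tab$significant)
  # degenerate: no observations -> header-only table
  expect_equal(nrow(report_tables(long[0, ])), 0L)
  # formatted text has one line per row plus header
  expect_length(format_report(rep_tab), 7L)
})
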