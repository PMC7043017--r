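test_that("pooled t-test matches the textbook formula and conventions", {
  # degenerate conventions
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-12)
  expect_equal(two_sample_t(c(2, 2), c(2, 2)), list(t = 0, df = 2, p = 1))
  expect_error(two_sample_t(c(2, 2), c(3, 3)), "zero pooled variance")
  # extreme separation
  expect_lt(two_sample_t(c(1, 2, 3), c(101, 102, 103))$p, 1e-6)
  # reference oracle: manual pooled-variance formula on random data
  set.seed(20)
  for (k in 1:100) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 0.5)
    got <- two_sample_t(a, b)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(got$t, t_ref, tolerance = 1e-8)
    expect_equal(got$df, na + nb - 2)
    expect_equal(got$p, 2 * pt(-abs(t_ref), na + nb - 2), tolerance = 1e-8)
  }
})

test_that("mixed ANOVA reproduces the split-plot decomposition (manual oracle)", {
  d <- simulate_metric_panel(groups = c("g1", "g2", "g3"),
                             timepoints = paste0("t", 1:4),
                             effects = matrix(rnorm(12, 0, 2), 3, 4),
                             n_per_group = 5, seed = 31)
  an <- mixed_anova(d, gg = FALSE)
  # manual balanced-design sums of squares
  grand <- mean(d$value)
  t_ <- 4
  subj_mean <- tapply(d$value, d$animal_id, mean)
  grp_of <- tapply(as.character(d$group), d$animal_id, `[`, 1)
  grp_mean <- tapply(d$value, d$group, mean)
  time_mean <- tapply(d$value, d$timepoint, mean)
  cell_mean <- tapply(d$value, list(d$group, d$timepoint), mean)
  n_g <- table(grp_of)
  ss_between <- t_ * sum((subj_mean - grand)^2)
  ss_group <- t_ * sum(n_g * (grp_mean[names(n_g)] - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- length(subj_mean) * sum((time_mean - grand)^2)
  ss_gxt <- 0
  for (g in rownames(cell_mean)) for (tp in colnames(cell_mean))
    ss_gxt <- ss_gxt + n_g[g] *
      (cell_mean[g, tp] - grp_mean[g] - time_mean[tp] + grand)^2
  ss_gxt <- unname(ss_gxt)
  ss_total <- sum((d$value - grand)^2)
  expect_equal(unname(an$ss["group"]), ss_group, tolerance = 1e-8)
  expect_equal(unname(an$ss["subjects_error"]), ss_subj, tolerance = 1e-8)
  expect_equal(unname(an$ss["time"]), ss_time, tolerance = 1e-8)
  expect_equal(unname(an$ss["group:time"]), ss_gxt, tolerance = 1e-8)
  # decomposition identity
  expect_equal(sum(an$ss[c("group", "subjects_error", "time", "group:time",
                           "within_error")]),
               unname(an$ss["total"]), tolerance = 1e-8)
  # F ratios from the manual mean squares
  df_subj <- length(subj_mean) - 3
  expect_equal(an$table$F[1], (ss_group / 2) / (ss_subj / df_subj),
               tolerance = 1e-8)
})

test_that("mixed ANOVA agrees with frozen reference values", {
  # frozen oracle: statsmodels/pingouin mixed_anova on this exact panel
  # gives SS (10.876121, 6.875971, 48.226482) and
  # F (2.600282, 1.502053, 10.535053); the Greenhouse-Geisser epsilon of
  # the pooled within-group covariance is 0.9082877777 (numpy).
  d <- simulate_metric_panel(groups = c("g1", "g2"),
                             timepoints = paste0("t", 1:4),
                             effects = matrix(c(0, 1, 0, 2, 1, 0, 2, 0),
                                              2, 4, byrow = TRUE),
                             n_per_group = 6, intercept_sd = 1,
                             noise_sd = 1, seed = 42)
  an <- mixed_anova(d)
  expect_equal(an$table$ss, c(10.876121, 6.875971, 48.226482),
               tolerance = 1e-6)
  expect_equal(an$table$F, c(2.600282, 1.502053, 10.535053),
               tolerance = 1e-6)
  expect_equal(an$table$epsilon[2], 0.9082877777, tolerance = 1e-9)
  # uncorrected p of the time effect (reference 0.234096)
  expect_equal(mixed_anova(d, gg = FALSE)$table$p[2], 0.234096,
               tolerance = 1e-5)
})

test_that("ANOVA conventions: constant data, epsilon bounds, design errors", {
  d <- simulate_metric_panel(effects = 5, intercept_sd = 0, noise_sd = 0,
                             n_per_group = 3, seed = 1)
  an <- mixed_anova(d)
  expect_equal(an$table$F, c(0, 0, 0))
  expect_equal(an$table$p, c(1, 1, 1))
  # epsilon within [1/(t-1), 1]
  d2 <- simulate_metric_panel(n_per_group = 6, seed = 5)
  eps <- mixed_anova(d2)$table$epsilon[2]
  expect_gte(eps, 1 / 3); expect_lte(eps, 1)
  # two timepoints: sphericity trivially holds, epsilon 1
  d3 <- simulate_metric_panel(timepoints = c("t1", "t2"), seed = 6)
  expect_equal(mixed_anova(d3)$table$epsilon, c(1, 1, 1))
  # missing cell is an explicit error
  expect_error(mixed_anova(d2[-1, ]), "unbalanced")
})

test_that("group F equals t squared with two groups and one timepoint", {
  set.seed(33)
  a <- rnorm(8); b <- rnorm(6, 1)
  d <- data.frame(animal_id = sprintf("x%02d", 1:14),
                  group = rep(c("g1", "g2"), c(8, 6)),
                  timepoint = "t1", value = c(a, b))
  an <- mixed_anova(d)
  tt <- two_sample_t(a, b)
  expect_equal(an$table$F, tt$t^2, tolerance = 1e-6)
  expect_equal(an$table$p, tt$p, tolerance = 1e-8)
})

test_that("p values decrease with injected effect size", {
  # effect ladder starts above the chance baseline offset of the fixed
  # seed, where the observed separation grows monotonically with es
  ps <- sapply(c(1, 2, 4, 8), function(es) {
    d <- simulate_metric_panel(groups = c("g1", "g2"),
                               effects = matrix(c(0, 0, 0, 0,
                                                  es, es, es, es),
                                                2, 4, byrow = TRUE),
                               n_per_group = 6, intercept_sd = 0,
                               noise_sd = 0.5, seed = 77)
    mixed_anova(d)$table$p[1]
  })
  expect_true(all(diff(ps) < 0))
})

test_that("Tukey HSD agrees with the reference implementation", {
  expect_equal(tukey_hsd(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))$q,
               0)
  expect_equal(tukey_hsd(c(1, 2, 3, 1, 2, 3),
                         rep(c("A", "B"), each = 3))$p_adj, 1)
  set.seed(34)
  for (k in 1:20) {
    g <- rep(c("A", "B", "C"), times = sample(3:8, 3, replace = TRUE))
    v <- rnorm(length(g), ave(seq_along(g), g))
    got <- tukey_hsd(v, g)
    ref <- TukeyHSD(aov(v ~ gg, data.frame(v = v, gg = factor(g))))$gg
    expect_equal(unname(got$p_adj), unname(ref[, "p adj"]),
                 tolerance = 1e-6)
    expect_equal(unname(abs(got$diff)), unname(abs(ref[, "diff"])),
                 tolerance = 1e-10)
  }
  # symmetry under relabeling
  v <- rnorm(12); g <- rep(c("A", "B", "C"), 4)
  p1 <- tukey_hsd(v, g)$p_adj
  g2 <- c(A = "C", B = "B", C = "A")[g]
  p2 <- tukey_hsd(v, g2)$p_adj
  expect_equal(sort(p1), sort(p2), tolerance = 1e-12)
  expect_error(tukey_hsd(v, g, ms_error = 1, df_error = 0), "domain error")
})
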