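# Inferential statistics of the study design: pooled-variance t-test,
# two-way mixed-design (between-group x repeated-time) ANOVA with
# Greenhouse-Geisser correction, and Tukey HSD post hoc comparisons.

#' Two-sample Student's t-test
#'
#' Pooled-variance, two-tailed, with `df = n_a + n_b - 2`. When the
#' pooled variance is exactly zero the test is degenerate: equal means
#' give `t = 0, p = 1` by convention; unequal means are an error.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the repeated measures (subjects x timepoints matrix Y, residualized on
# group x time cell means).
gg_epsilon <- function(Y, group) {
  t_ <- ncol(Y)
  if (t_ < 3) return(1)
  E <- Y
  for (g in unique(group))
    E[group == g, ] <- sweep(Y[group == g, , drop = FALSE], 2,
                             colMeans(Y[group == g, , drop = FALSE]))
  S <- crossprod(E) / (nrow(Y) - length(unique(group)))
  sbar <- mean(S); di <- mean(diag(S)); ri <- rowMeans(S)
  num <- (t_ * (di - sbar))^2
  den <- (t_ - 1) * (sum(S^2) - 2 * t_ * sum(ri^2) + t_^2 * sbar^2)
  if (den <= 0) return(1)
  min(1, max(1 / (t_ - 1), num / den))
}

#' Mixed-design (split-plot) ANOVA
#'
#' Two-way ANOVA with one between-subjects factor (group) and one
#' within-subjects factor (timepoint): the between-subjects group effect
#' is tested against subjects-within-group error, and the
#' within-subjects time and group-by-time effects against the
#' time-by-subjects-within-group error. The Greenhouse-Geisser
#' sphericity correction (on by default) shrinks the within-subject
#' degrees of freedom by the epsilon estimated from the pooled
#' within-group covariance of the repeated measures; F statistics are
#' unchanged.
#'
#' @param data Long data.frame with columns `animal_id`, `group`,
#'   `timepoint`, `value`; every animal must have exactly one value per
#'   timepoint (missing cells are an error, never imputed).
#' @param gg Apply the Greenhouse-Geisser correction (default `TRUE`).
#' @return An object of class `mixed_anova`: a list with `table` (one
#'   row per effect: `effect`, `ss`, `df_num`, `df_den`, `F`, `epsilon`,
#'   `p`) and `ss` (named vector of all sums of squares, including error
#'   terms and the total).
#' @export
mixed_anova <- function(data, gg = TRUE) {
  need <- c("animal_id", "group", "timepoint", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  data$animal_id <- factor(data$animal_id)
  data$group <- factor(data$group)
  data$timepoint <- factor(data$timepoint)
  tab <- table(data$animal_id, data$timepoint)
  if (any(tab != 1))
    stop("unbalanced design: every animal needs exactly one value per ",
         "timepoint (no silent imputation)")
  if (any(rowSums(table(data$animal_id, data$group) > 0) != 1))
    stop("each animal must belong to exactly one group")
  ng <- nlevels(data$group); nt <- nlevels(data$timepoint)
  if (ng < 2) stop("need at least 2 groups")
  grand <- mean(data$value)
  ss_total <- sum((data$value - grand)^2)
  if (nt == 1) {
    fit <- stats::aov(value ~ group, data = data)
    sm <- stats::anova(fit)
    tab_out <- data.frame(effect = "group", ss = sm$`Sum Sq`[1],
                          df_num = sm$Df[1], df_den = sm$Df[2],
                          F = sm$`F value`[1], epsilon = 1,
                          p = sm$`Pr(>F)`[1])
    ss <- c(group = sm$`Sum Sq`[1], subjects_error = sm$`Sum Sq`[2],
            total = ss_total)
  } else {
    fit <- stats::aov(value ~ group * timepoint + Error(animal_id),
                      data = data)
    sm <- summary(fit)
    btw <- sm$`Error: animal_id`[[1]]
    wth <- sm$`Error: Within`[[1]]
    rownames(btw) <- trimws(rownames(btw))
    rownames(wth) <- trimws(rownames(wth))
    eps <- if (gg) {
      wide <- stats::xtabs(value ~ animal_id + timepoint, data = data)
      grp_of <- data$group[match(rownames(wide), data$animal_id)]
      gg_epsilon(unclass(wide), grp_of)
    } else 1
    eff <- data.frame(
      effect = c("group", "time", "group:time"),
      ss = c(btw["group", "Sum Sq"], wth["timepoint", "Sum Sq"],
             wth["group:timepoint", "Sum Sq"]),
      df_num = c(btw["group", "Df"], wth["timepoint", "Df"],
                 wth["group:timepoint", "Df"]),
      df_den = c(btw["Residuals", "Df"], wth["Residuals", "Df"],
                 wth["Residuals", "Df"]),
      F = c(btw["group", "F value"], wth["timepoint", "F value"],
            wth["group:timepoint", "F value"]),
      epsilon = c(1, eps, eps))
    # no-variance convention: an effect with (numerically) zero SS has
    # F = 0, p = 1, even when the error SS is zero too
    zero <- eff$ss <= 1e-12 * max(ss_total, .Machine$double.eps)
    eff$F[zero] <- 0
    eff$p <- stats::pf(eff$F, eff$epsilon * eff$df_num,
                       eff$epsilon * eff$df_den, lower.tail = FALSE)
    eff$p[zero] <- 1
    tab_out <- eff
    ss <- c(group = eff$ss[1],
            subjects_error = btw["Residuals", "Sum Sq"],
            time = eff$ss[2], `group:time` = eff$ss[3],
            within_error = wth["Residuals", "Sum Sq"],
            total = ss_total)
  }
  rownames(tab_out) <- NULL
  structure(list(table = tab_out, ss = ss), class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed-design ANOVA (group x repeated time)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD post hoc comparisons
#'
#' Pairwise comparisons of group means using the studentized-range
#' distribution, with the Tukey-Kramer allowance for unequal group
#' sizes: `q = |m_i - m_j| / sqrt(ms_error/2 * (1/n_i + 1/n_j))`.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or vector) of group labels, same length.
#' @param ms_error,df_error Error mean square and its degrees of
#'   freedom; defaults to the one-way within-group mean square of the
#'   supplied data. Pass the appropriate error term from a
#'   [mixed_anova()] to post-hoc a split-plot effect.
#' @return Data.frame with one row per pair: `group1`, `group2`,
#'   `diff` (mean of group1 minus group2), `q`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, ms_error = NULL, df_error = NULL) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  m <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  if (is.null(ms_error)) {
    df_error <- length(values) - k
    ms_error <- sum(tapply(values, groups,
                           function(v) sum((v - mean(v))^2))) / df_error
  }
  if (is.null(df_error) || df_error <= 0)
    stop("domain error: df_error must be positive")
  pairs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  out$diff <- as.numeric(m[out$group1] - m[out$group2])
  se <- sqrt(ms_error / 2 * as.numeric(1 / n[out$group1] + 1 / n[out$group2]))
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = df_error,
                             lower.tail = FALSE)
  rownames(out) <- NULL
  out
}
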