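# Replicate-level statistics: the hypothesis tests used for the headline
# comparisons (one-sample t against a ratio of 1, paired and Welch t tests,
# one-way ANOVA with Tukey HSD, simple linear regression with R^2).

.check_variance <- function(...) {
  xs <- list(...)
  if (all(vapply(xs, function(x) stats::var(x) == 0, logical(1)))) {
    .psk_error("zero variance in all groups; test statistic undefined",
               "psk_zero_variance")
  }
}

#' Run a named hypothesis test
#'
#' Thin, uniformly-shaped wrapper around the standard tests used in the
#' replicate-level analysis. `groups` is a list of numeric vectors (one per
#' group) except for `linear_fit`, where it is `list(x, y)`.
#'
#' @param kind one of `"one_sample_t_vs_1"`, `"student_t"`, `"welch_t"`,
#'   `"paired_t"`, `"anova_tukey"`, `"linear_fit"`.
#' @param groups list of numeric vectors.
#' @param mu null value for the one-sample test (default 1, a ratio of
#'   sinking velocities under no change).
#' @return list of class `psk_test` with `test`, `statistic`, `df`,
#'   `p_value` and a test-specific `effect` (mean difference/ratio, Tukey
#'   pairwise table, or regression coefficients with R^2).
#' @export
#' @examples
#' run_test("one_sample_t_vs_1", list(c(3.0, 2.8, 3.2, 3.0)))
run_test <- function(kind = c("one_sample_t_vs_1", "student_t", "welch_t",
                              "paired_t", "anova_tukey", "linear_fit"),
                     groups, mu = 1) {
  kind <- match.arg(kind)
  groups <- lapply(groups, as.numeric)
  out <- switch(kind,
    one_sample_t_vs_1 = {
      x <- groups[[1]]
      if (length(x) < 2) .psk_error("need >= 2 values",
                                    "psk_insufficient_data")
      .check_variance(x)
      tt <- stats::t.test(x, mu = mu)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value,
           effect = list(mean = mean(x),
                         sem = stats::sd(x) / sqrt(length(x))))
    },
    student_t = ,
    welch_t = {
      x <- groups[[1]]; y <- groups[[2]]
      .check_variance(x, y)
      tt <- stats::t.test(x, y, var.equal = (kind == "student_t"))
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value,
           effect = list(mean_difference = mean(x) - mean(y)))
    },
    paired_t = {
      x <- groups[[1]]; y <- groups[[2]]
      if (length(x) != length(y)) .psk_error("paired groups differ in length",
                                             "psk_pairing")
      d <- x - y
      if (stats::var(d) == 0 && all(d == 0)) {
        # identical pairs: difference is exactly zero everywhere
        list(statistic = 0, df = length(d) - 1, p_value = 1,
             effect = list(mean_difference = 0))
      } else {
        if (stats::var(d) == 0) .psk_error("zero variance of differences",
                                           "psk_zero_variance")
        tt <- stats::t.test(x, y, paired = TRUE)
        list(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             effect = list(mean_difference = mean(d)))
      }
    },
    anova_tukey = {
      if (length(groups) < 2) .psk_error("need >= 2 groups",
                                         "psk_insufficient_data")
      values <- unlist(groups, use.names = FALSE)
      if (stats::var(values) == 0) {
        .psk_error("all groups identical; zero variance", "psk_zero_variance")
      }
      labels <- if (!is.null(names(groups))) names(groups) else
        paste0("g", seq_along(groups))
      df <- data.frame(
        value = values,
        group = factor(rep(labels, lengths(groups)), levels = labels))
      fit <- stats::aov(value ~ group, data = df)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$group
      list(statistic = an[["F value"]][1],
           df = an[["Df"]],
           p_value = an[["Pr(>F)"]][1],
           effect = list(tukey = as.data.frame(tk)))
    },
    linear_fit = {
      x <- groups[[1]]; y <- groups[[2]]
      if (stats::var(x) == 0) .psk_error("predictor has zero variance",
                                         "psk_zero_variance")
      fit <- stats::lm(y ~ x)
      sm <- summary(fit)
      fstat <- sm$fstatistic
      p <- if (is.null(fstat)) NA_real_ else
        unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
      list(statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
           df = length(x) - 2,
           p_value = p,
           effect = list(slope = unname(stats::coef(fit)[2]),
                         intercept = unname(stats::coef(fit)[1]),
                         r_squared = sm$r.squared))
    })
  structure(c(list(test = kind), out), class = "psk_test")
}

#' @export
print.psk_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = "/"), x$p_value))
  invisible(x)
}

#' Relative sinking-velocity change between conditions
#'
#' Pairs replicate cultures of the two conditions by replicate id, forms the
#' per-pair velocity ratio low/high, and tests the ratios against 1 with a
#' one-sample t test. A ratio above 1 means the cells sink faster when
#' starved.
#'
#' @param high,low named numeric vectors of per-replicate sinking
#'   velocities (um/s); names are replicate ids. Unnamed vectors of equal
#'   length are paired by position.
#' @return list of class `psk_fold_change`: `ratios`, `mean_ratio`, `sem`,
#'   and the `psk_test` result in `test`.
#' @export
#' @examples
#' relative_sinking_change(c(a = 1, b = 1.1), c(a = 3.0, b = 3.2))
relative_sinking_change <- function(high, low) {
  if (!is.null(names(high)) && !is.null(names(low))) {
    common <- intersect(names(high), names(low))
    high <- high[common]; low <- low[common]
  } else if (length(high) != length(low)) {
    .psk_error("unnamed velocity vectors must have equal length",
               "psk_pairing")
  }
  usable <- is.finite(high) & is.finite(low) & high > 0
  if (any(!usable)) {
    warning(sprintf(
      "relative_sinking_change: excluding %d pair(s) with non-positive or missing high-condition velocity",
      sum(!usable)), call. = FALSE)
  }
  high <- high[usable]; low <- low[usable]
  if (length(high) < 2) {
    .psk_error("fewer than 2 usable replicate pairs", "psk_insufficient_data")
  }
  ratios <- low / high
  tt <- run_test("one_sample_t_vs_1", list(ratios))
  structure(list(ratios = ratios, mean_ratio = mean(ratios),
                 sem = stats::sd(ratios) / sqrt(length(ratios)),
                 n_pairs = length(ratios), test = tt),
            class = "psk_fold_change")
}
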