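# Comparative statistics: one-sided Welch two-sample comparisons (from raw
# samples or from printed summary statistics) and the Poisson mixed count
# model for LCD vs non-LCD buffer use.

#' Welch two-sample test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch–Satterthwaite
#' degrees of freedom. One-sided p-value: for `"less"` the lower tail
#' `P(T <= t)`, for `"greater"` the upper tail. Published comparisons
#' report group means and SDs, so this summary form is the primary entry
#' point; sample SDs use the n-1 denominator.
#'
#' @param m1,s1,n1 mean, sd and size of group 1.
#' @param m2,s2,n2 mean, sd and size of group 2.
#' @param alternative `"less"` (mu1 - mu2 < 0) or `"greater"`.
#' @return object of class `welch_result`: list with `t`, `df`,
#'   `p_one_sided`, `alternative`, and the input summaries.
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2,
                               alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (s1 <= 0 || s2 <= 0) stop_bad_arg("group SDs must be > 0")
  if (n1 < 2 || n2 < 2) stop_bad_arg("group sizes must be >= 2")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- if (alternative == "less") stats::pt(t, df) else
    stats::pt(t, df, lower.tail = FALSE)
  structure(list(t = t, df = df, p_one_sided = p,
                 alternative = alternative,
                 summary = c(m1 = m1, s1 = s1, n1 = n1,
                             m2 = m2, s2 = s2, n2 = n2)),
            class = "welch_result")
}

#' Welch two-sample test from raw samples
#'
#' Computes each group's mean and sample SD (n-1 denominator) and
#' delegates to [welch_from_summary()].
#'
#' @param x1,x2 numeric samples with at least 2 values each.
#' @param alternative `"less"` or `"greater"`.
#' @return a `welch_result`.
#' @export
welch_from_samples <- function(x1, x2,
                               alternative = c("less", "greater")) {
  if (length(x1) < 2L || length(x2) < 2L)
    stop_bad_arg("each sample needs at least 2 values")
  welch_from_summary(mean(x1), stats::sd(x1), length(x1),
                     mean(x2), stats::sd(x2), length(x2),
                     alternative = alternative)
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample test (one-sided, %s)\n", x$alternative))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n", x$t, x$df,
              x$p_one_sided))
  invisible(x)
}

#' Mixed count model for buffer use at LCD vs non-LCD clusters
#'
#' Poisson log-link model of GPS-location counts within a buffer:
#' `count ~ intercept + beta * is_lcd + u_animal`, with animal-level
#' random intercepts `u ~ Normal(0, sd^2)`, fitted by Laplace-approximated
#' maximum likelihood (lme4). A negative-binomial switch is available for
#' overdispersed counts. With `random_effect = FALSE` the random intercept
#' is dropped (its sd fixed at zero) and an ordinary Poisson regression is
#' fitted — mostly useful as a degenerate-case check.
#'
#' @param records buffer-use data.frame from [buffer_use_counts()] or
#'   [simulate_buffer_counts()] (columns animal_id, radius, count,
#'   is_lcd).
#' @param radius which buffer radius to model (meters).
#' @param family `"poisson"` (default) or `"nb"`.
#' @param random_effect logical; include the animal random intercept
#'   (default TRUE).
#' @return object of class `glmm_result`: list with `fixed_effects`
#'   (data.frame term/estimate/se/z), `random_intercept_sd`, `family`,
#'   `n_obs`, `n_animals`, `converged`, and the underlying `fit`.
#' @export
fit_buffer_glmm <- function(records, radius,
                            family = c("poisson", "nb"),
                            random_effect = TRUE) {
  family <- match.arg(family)
  d <- records[records$radius == radius, , drop = FALSE]
  if (nrow(d) == 0L)
    stop_bad_arg("no records at radius ", radius)
  if (length(unique(d$animal_id)) < 2L && random_effect)
    stop_bad_arg("mixed model needs at least 2 animals")
  if (length(unique(d$is_lcd)) < 2L)
    stop_bad_arg("both cluster types (LCD and non-LCD) must be present")
  d$is_lcd <- as.logical(d$is_lcd)
  d$animal_id <- factor(d$animal_id)
  if (random_effect) {
    fit <- if (family == "poisson")
      lme4::glmer(count ~ is_lcd + (1 | animal_id), data = d,
                  family = stats::poisson(link = "log"))
    else
      lme4::glmer.nb(count ~ is_lcd + (1 | animal_id), data = d)
    co <- summary(fit)$coefficients
    re_sd <- sqrt(as.numeric(lme4::VarCorr(fit)$animal_id[1, 1]))
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  } else {
    fit <- stats::glm(count ~ is_lcd, data = d,
                      family = stats::poisson(link = "log"))
    co <- summary(fit)$coefficients
    re_sd <- 0
    conv <- fit$converged
  }
  fixed <- data.frame(term = rownames(co),
                      estimate = co[, 1], se = co[, 2], z = co[, 3],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fixed_effects = fixed,
                 random_intercept_sd = re_sd,
                 family = if (family == "poisson") "POISSON_LOG"
                          else "NEGBIN_LOG",
                 n_obs = nrow(d),
                 n_animals = length(unique(d$animal_id)),
                 converged = conv,
                 fit = fit),
            class = "glmm_result")
}

#' LCD effect row of a fitted buffer-use model
#' @param x a `glmm_result`.
#' @return one-row data.frame (term, estimate, se, z) for the LCD term.
#' @export
lcd_effect <- function(x) {
  stopifnot(inherits(x, "glmm_result"))
  fe <- x$fixed_effects
  fe[grepl("is_lcd", fe$term), , drop = FALSE]
}

#' @export
print.glmm_result <- function(x, ...) {
  cat(sprintf("Buffer-use mixed count model (%s), %d obs, %d animals\n",
              x$family, x$n_obs, x$n_animals))
  print(x$fixed_effects, digits = 4)
  cat(sprintf("  animal random-intercept sd = %.4g\n",
              x$random_intercept_sd))
  invisible(x)
}
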