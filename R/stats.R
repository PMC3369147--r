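## Statistical layer: two-group comparison (pooled-variance t),
## intraclass correlation ICC(2,1) with Landis-Koch interpretation, and
## simple linear regression with the Pearson correlation.

#' Two-sample Student's t-test (pooled variance)
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @param welch use Welch's unequal-variance form instead of the pooled
#'   form.
#' @return object of class `hip_ttest`: list with `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `t`, `df`, `p_two_sided`.
#' @examples
#' student_t(rnorm(18), rnorm(16, 1))
#' @export
student_t <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 finite values")
  ht <- t.test(group_a, group_b, var.equal = !welch)
  structure(list(mean_a = mean(group_a), mean_b = mean(group_b),
                 sd_a = sd(group_a), sd_b = sd(group_b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_two_sided = ht$p.value,
                 welch = welch),
            class = "hip_ttest")
}

#' @export
print.hip_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: %.3f (SD %.3f) vs %.3f (SD %.3f), t = %.3f, df = %.4g, p = %.4g\n",
              if (x$welch) "Welch" else "Student", x$mean_a, x$sd_a,
              x$mean_b, x$sd_b, x$t, x$df, x$p_two_sided))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures: with
#' between-subject, between-rater and residual mean squares MSR, MSC, MSE
#' from the two-way ANOVA of the complete subjects x raters matrix,
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + k (MSC - MSE)/n}.}
#' The Landis-Koch label is attached.
#'
#' @param ratings numeric matrix, subjects in rows (n >= 5), raters in
#'   columns (k >= 2), complete.
#' @return object of class `hip_icc`: list with `icc`, `category`, the
#'   mean squares and variance components.
#' @examples
#' icc(cbind(rnorm(10), rnorm(10)))
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings))) stop("ratings must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 raters")
  if (sd(as.numeric(ratings)) == 0)
    stop("ratings are constant: ICC undefined")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = val, category = interpret_icc(val),
                 ms = c(MSR = msr, MSC = msc, MSE = mse),
                 var_components = c(
                   subject = max((msr - mse) / k, 0),
                   rater = max((msc - mse) / n, 0),
                   residual = mse),
                 n_subjects = n, n_raters = k),
            class = "hip_icc")
}

#' @export
print.hip_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (%s), n = %d subjects x %d raters\n",
              x$icc, x$category, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Landis-Koch interpretation of an ICC
#'
#' slight (< 0.20), fair (0.21-0.40), moderate (0.41-0.60),
#' substantial (0.61-0.80), almost perfect (> 0.80).
#'
#' @param value ICC value (<= 1).
#' @return character label.
#' @examples
#' interpret_icc(0.52)  # "moderate"
#' @export
interpret_icc <- function(value) {
  if (value > 1) stop("ICC cannot exceed 1")
  if (value <= 0.20) "slight"
  else if (value <= 0.40) "fair"
  else if (value <= 0.60) "moderate"
  else if (value <= 0.80) "substantial"
  else "almost perfect"
}

#' Simple linear regression with the Pearson correlation
#'
#' Least-squares slope and intercept of `y ~ x`, the Pearson correlation r,
#' and the two-sided p-value from \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#'
#' @param x,y numeric vectors, n >= 3, x not constant; pairs with missing
#'   values are dropped.
#' @return object of class `hip_regression`: list with `slope`,
#'   `intercept`, `pearson_r`, `p`, `n`.
#' @examples
#' simple_regression(1:10, 2 * (1:10) + rnorm(10))
#' @export
simple_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("x is constant")
  fit <- lm(y ~ x)
  r <- cor(x, y)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = r, p = p, n = n),
            class = "hip_regression")
}

#' @export
print.hip_regression <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x, r = %.3f, p = %.4g (n = %d)\n",
              x$intercept, x$slope, x$pearson_r, x$p, x$n))
  invisible(x)
}

## ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.hip_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_a - x$mean_b,
                 mean_a = x$mean_a, mean_b = x$mean_b,
                 sd_a = x$sd_a, sd_b = x$sd_b,
                 statistic = x$t, df = x$df, p.value = x$p_two_sided)
}

#' @export
glance.hip_ttest <- function(x, ...) tidy(x)

#' @export
tidy.hip_icc <- function(x, ...) {
  tibble::tibble(estimate = x$icc, category = x$category,
                 var_subject = x$var_components["subject"],
                 var_rater = x$var_components["rater"],
                 var_residual = x$var_components["residual"])
}

#' @export
glance.hip_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, category = x$category,
                 n_subjects = x$n_subjects, n_raters = x$n_raters)
}

#' @export
tidy.hip_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.hip_regression <- function(x, ...) {
  tibble::tibble(r = x$pearson_r, slope = x$slope,
                 intercept = x$intercept, p.value = x$p, n = x$n)
}
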