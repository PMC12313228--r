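#' Pearson correlation with best-fit regression line
#'
#' The association analysis applied to every correlation plot: sample
#' Pearson r with its two-sided p-value (t statistic
#' `r * sqrt((n-2)/(1-r^2))` on n-2 df) and the ordinary least-squares
#' best-fit line.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither
#'   constant.
#' @param x_name,y_name Labels carried into the result.
#' @return An `association` object; [tidy()] gives a one-row tibble
#'   `x_name, y_name, n, r, p_value, slope, intercept`.
#' @export
#' @examples
#' fit <- pearson_with_regression(1:5, 2 * (1:5) + 1)
#' tidy(fit)
pearson_with_regression <- function(x, y,
                                    x_name = deparse(substitute(x)),
                                    y_name = deparse(substitute(y))) {
  force(x_name); force(y_name)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("At least 3 points are required for a p-value.")
  if (sd(x) == 0 || sd(y) == 0) abort("Constant vector: Pearson r is undefined.")
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  structure(
    list(
      x_name = x_name, y_name = y_name, n = n,
      r = unname(ct$estimate), p_value = ct$p.value,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      data = tibble(x = x, y = y)
    ),
    class = "association"
  )
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("association: %s vs %s  (n = %d)\n  r = %.4f, p = %.3g, y = %.4g + %.4g x\n",
              x$y_name, x$x_name, x$n, x$r, x$p_value, x$intercept, x$slope))
  invisible(x)
}

#' @describeIn pearson_with_regression One-row tidy summary.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.association <- function(x, ...) {
  tibble(x_name = x$x_name, y_name = x$y_name, n = x$n, r = x$r,
         p_value = x$p_value, slope = x$slope, intercept = x$intercept)
}

#' @describeIn pearson_with_regression Same one-row summary (model-level).
#' @exportS3Method generics::glance
glance.association <- function(x, ...) tidy(x)

#' @describeIn pearson_with_regression Scatter plot with the best-fit line.
#' @param object An `association` object.
#' @exportS3Method ggplot2::autoplot
autoplot.association <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "firebrick") +
    labs(x = object$x_name, y = object$y_name,
         subtitle = sprintf("r = %.3f, p = %.3g", object$r, object$p_value)) +
    theme_minimal()
}

#' Paired two-sided t-test
#'
#' Standard paired t on the differences `a - b` with n - 1 degrees of
#' freedom. Degenerate cases follow a documented convention: all-zero
#' differences give t = 0, p = 1; constant nonzero differences give an
#' infinite t (flagged) with p = 0.
#'
#' @param a,b Paired numeric vectors of equal length, n >= 2.
#' @return Tibble `t, df, p_value, mean_diff, degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 2) abort("At least 2 pairs are required.")
  d <- a - b
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble(t = 0, df = n - 1, p_value = 1, mean_diff = 0,
                    degenerate = TRUE))
    }
    return(tibble(t = sign(m) * Inf, df = n - 1, p_value = 0, mean_diff = m,
                  degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  tibble(t = t, df = n - 1, p_value = 2 * pt(-abs(t), n - 1),
         mean_diff = m, degenerate = FALSE)
}

grubbs_critical <- function(n, alpha) {
  t <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Grubbs outlier flagging
#'
#' Repeatedly tests the single most extreme point with Grubbs'
#' statistic `G = max|x - mean| / sd` against the two-sided critical
#' value at level `alpha`, flags it if exceeded, removes it, and
#' repeats until no point exceeds the critical value or fewer than
#' three points remain. Flags are returned in input order; removal is
#' left to the caller. A simpler documented stand-in for interactive
#' outlier removal tools.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level per step (default 0.05).
#' @return Logical vector of flags, same length and order as `values`.
#' @export
#' @examples
#' identify_outliers(c(1, 1.1, 0.9, 50))
identify_outliers <- function(values, alpha = 0.05) {
  n0 <- length(values)
  if (n0 < 3) abort("At least 3 values are required for outlier identification.")
  flags <- rep(FALSE, n0)
  active <- seq_len(n0)
  repeat {
    v <- values[active]
    n <- length(v)
    if (n < 3 || sd(v) == 0) break
    dev <- abs(v - mean(v))
    g <- max(dev) / sd(v)
    if (g <= grubbs_critical(n, alpha)) break
    worst <- active[which.max(dev)]
    flags[worst] <- TRUE
    active <- setdiff(active, worst)
  }
  flags
}

#' Classify TGF-beta responsiveness from pSMAD3 densitometry
#'
#' A population is TGF-beta-responsive when its pSMAD3 fold change
#' (treated over control densitometry, both relative to GAPDH) reaches
#' the threshold; responsive populations typically show 2- to 4-fold
#' stimulation while non-responders stay near 1.
#'
#' @param densitometry Tibble with columns `population_id,
#'   psmad3_ctrl, psmad3_tgfb`, all densitometry values > 0.
#' @param threshold Responder fold-change cutoff (default 1.5).
#' @return Tibble `population_id, fold_change, responsive, threshold`.
#' @export
classify_tgfb_response <- function(densitometry, threshold = 1.5) {
  d <- as_tibble(densitometry)
  needed <- c("population_id", "psmad3_ctrl", "psmad3_tgfb")
  if (!all(needed %in% names(d))) {
    abort(paste0("`densitometry` must have columns ", paste(needed, collapse = ", "), "."))
  }
  if (any(d$psmad3_ctrl <= 0) || any(d$psmad3_tgfb <= 0)) {
    abort("Densitometry values must be positive.")
  }
  d |>
    mutate(
      fold_change = .data$psmad3_tgfb / .data$psmad3_ctrl,
      responsive = .data$fold_change >= threshold,
      threshold = threshold
    ) |>
    select("population_id", "fold_change", "responsive", "threshold")
}

#' Transcription-factor invasion screen
#'
#' Correlates each transcription factor's expression across populations
#' with an invasion phenotype (invasion index or SPOI), reporting
#' Pearson r, two-sided p, OLS slope/intercept and a Benjamini-Hochberg
#' q-value column (the q-values never alter the ranking, which is by
#' |r| descending). Constant TF columns are reported with `r = NA` and
#' placed last.
#'
#' @param tf_expression Matrix or data frame, populations x TFs, with
#'   column names.
#' @param phenotype Numeric phenotype aligned to the rows (n >= 3).
#' @return Tibble `tf, n, r, p_value, q_value, slope, intercept` sorted
#'   by |r| descending.
#' @export
tf_screen <- function(tf_expression, phenotype) {
  m <- as.matrix(tf_expression)
  if (is.null(colnames(m))) colnames(m) <- paste0("TF", seq_len(ncol(m)))
  if (nrow(m) != length(phenotype)) {
    abort("`phenotype` must have one value per row of `tf_expression`.")
  }
  if (nrow(m) < 3) abort("At least 3 populations are required.")
  rows <- map(colnames(m), function(tf) {
    v <- m[, tf]
    if (sd(v) == 0 || sd(phenotype) == 0) {
      return(tibble(tf = tf, n = length(v), r = NA_real_,
                    p_value = NA_real_, slope = NA_real_,
                    intercept = NA_real_))
    }
    a <- pearson_with_regression(v, phenotype, x_name = tf,
                                 y_name = "phenotype")
    tibble(tf = tf, n = a$n, r = a$r, p_value = a$p_value,
           slope = a$slope, intercept = a$intercept)
  }) |> list_rbind()
  rows$q_value <- p.adjust(rows$p_value, method = "BH")
  rows |>
    arrange(desc(abs(.data$r))) |>
    select("tf", "n", "r", "p_value", "q_value", "slope", "intercept")
}
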