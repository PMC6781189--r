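#' Construct a 2x2 contingency table
#'
#' Rows are exposure levels (reference first), columns are outcomes
#' (accurate, inaccurate).
#'
#' @param a,b Reference-level counts: accurate, inaccurate.
#' @param c,d Comparison-level counts: accurate, inaccurate.
#' @param levels Optional exposure level names (reference first).
#' @return A 2x2 integer matrix with dimnames.
#' @export
table2x2 <- function(a, b, c, d, levels = c("reference", "comparison")) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) == 0) {
    abort("Counts must be non-negative integers with a positive total.",
          class = "lesioncam_input_error")
  }
  matrix(as.integer(counts), 2, 2, byrow = TRUE,
         dimnames = list(levels, c("accurate", "inaccurate")))
}

#' Univariable odds ratio with Wald confidence interval
#'
#' The odds ratio of the "accurate" outcome for the comparison exposure
#' relative to the reference: `OR = (c/d) / (a/b)` for the table laid out as
#' rows (reference: a accurate, b inaccurate; comparison: c accurate,
#' d inaccurate). The 95% interval is Wald on the log scale,
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero a
#' 0.5 continuity correction is applied to all cells when
#' `correct_zero = TRUE`, otherwise a degenerate-table error is raised.
#'
#' @param table A 2x2 matrix as from [table2x2()], or a length-4 numeric
#'   vector `c(a, b, c, d)`.
#' @param conf_level Confidence level (default 0.95).
#' @param correct_zero Apply the Haldane 0.5 correction to zero-cell tables.
#' @return An `odds_ratio_result` tibble row: odds_ratio, ci_low, ci_high,
#'   log_or, se, conf_level, corrected.
#' @export
#' @examples
#' odds_ratio_wald(c(97, 39, 38, 32))
odds_ratio_wald <- function(table, conf_level = 0.95, correct_zero = FALSE) {
  if (is.numeric(table) && length(table) == 4 && is.null(dim(table))) {
    table <- table2x2(table[1], table[2], table[3], table[4])
  }
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  corrected <- FALSE
  if (any(c(a, b, c, d) == 0)) {
    if (!correct_zero) {
      abort("Zero cell in 2x2 table; set `correct_zero = TRUE` for the 0.5 correction.",
            class = "lesioncam_degenerate_table_error")
    }
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  or <- (c / d) / (a / b)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(odds_ratio = or,
                        ci_low = exp(log(or) - z * se),
                        ci_high = exp(log(or) + z * se),
                        log_or = log(or), se = se,
                        conf_level = conf_level, corrected = corrected)
  class(out) <- c("odds_ratio_result", class(out))
  out
}

#' Pearson chi-squared test for a 2 x K contingency table
#'
#' Pearson statistic without continuity correction; degrees of freedom
#' `(2 - 1)(K - 1)`.
#'
#' @param table A 2 x K matrix of counts.
#' @return Tibble: statistic, df, p_value.
#' @export
chi_squared <- function(table) {
  stopifnot(is.matrix(table), nrow(table) == 2)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Chi-squared test requires positive row and column margins.",
          class = "lesioncam_input_error")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum, over all tables with the observed margins, of
#' hypergeometric probabilities no greater than that of the observed table.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)),
            all(table >= 0), all(table == round(table)))
  stats::fisher.test(table)$p.value
}

#' Count as a percentage at one-decimal precision
#'
#' `100 * count / total`, rounded half-up to one decimal — the convention of
#' printed clinical tables.
#'
#' @param count,total Non-negative counts with `count <= total`,
#'   `total > 0`.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' proportion_summary(589, 800)
proportion_summary <- function(count, total) {
  if (any(total <= 0)) {
    abort("`total` must be positive.", class = "lesioncam_input_error")
  }
  if (any(count < 0) || any(count > total)) {
    abort("`count` must lie in [0, total].", class = "lesioncam_input_error")
  }
  round_half_up(100 * count / total, 1)
}
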