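# Observer-study statistics: Welch t, Pearson chi-square, Wilson score
# intervals, truncation display rounding, Fleiss kappa with Landis-Koch
# bands, and the per-rater diagnostic table.

#' Welch two-sample t-test
#'
#' Two-tailed t-test for independent samples with unequal variances (Welch
#' statistic, Satterthwaite degrees of freedom), the comparison applied to
#' the per-class intensity and spread samples. Thin wrapper over
#' [stats::t.test()] with a documented degenerate-case convention: if both
#' samples have zero variance and equal means, `t = 0, p = 1`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))  # t = -2.19, df = 6
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need n >= 2", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both samples are constant with different means; t is undefined",
         call. = FALSE)
  }
  ht <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (df = 1), as appropriate for the large cell
#' counts of the observer study.
#'
#' @param table A 2x2 matrix of nonnegative counts with all row and column
#'   sums positive.
#' @return List with `statistic`, `p`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(20, 10, 10, 20), 2))  # X2 = 6.67
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0))
    stop("a 2x2 matrix of nonnegative counts is required", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginals of the 2x2 table must be positive", call. = FALSE)
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The closed-form score interval; it reproduces the printed confidence
#' bounds of the observer study under truncation display rounding.
#'
#' @param k Successes.
#' @param n Trials (>= 1).
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)` inside `[0, 1]`.
#' @export
#' @examples
#' wilson_ci(8, 10)  # (0.4901, 0.9433)
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1L || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # the closed form gives exactly 0/1 at the boundary counts; keep it exact
  lower <- if (k == 0) 0 else max(0, centre - half)
  upper <- if (k == n) 1 else min(1, centre + half)
  c(lower = lower, upper = upper)
}

#' Truncation display rounding for percentages
#'
#' The display convention of the observer-study tables: proportions are
#' printed as percentages truncated (not rounded) toward zero to one decimal
#' (13/27 = 48.148% prints as 48.1). Raw full-precision values should always
#' be kept alongside.
#'
#' @param p Proportions in `[0, 1]`.
#' @return Percentages with one truncated decimal.
#' @export
#' @examples
#' percent_trunc(26/33)  # 78.7
percent_trunc <- function(p) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  floor(p * 1000 + 1e-9) / 10
}

#' Diagnostic accuracy from 2x2 counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, 95% Wilson score
#' intervals, and display values in the truncation convention
#' ([percent_trunc()]).
#'
#' @param tp,fn,fp,tn Counts (SCC called inhomogeneous, SCC called
#'   homogeneous, benign called inhomogeneous, benign called homogeneous).
#' @param conf Confidence level for the Wilson intervals.
#' @return An object of class `cle_diagnostic_result`: list with the counts,
#'   `sensitivity`, `specificity`, `sens_ci`, `spec_ci` (raw proportions) and
#'   `display` (truncated percentages).
#' @export
#' @examples
#' diagnostic_metrics(189, 42, 26, 163)$display
diagnostic_metrics <- function(tp, fn, fp, tn, conf = 0.95) {
  if (tp + fn < 1L) stop("no positive-class items (tp + fn = 0)", call. = FALSE)
  if (tn + fp < 1L) stop("no negative-class items (tn + fp = 0)", call. = FALSE)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  sens_ci <- wilson_ci(tp, tp + fn, conf)
  spec_ci <- wilson_ci(tn, tn + fp, conf)
  structure(list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = sens, specificity = spec,
    sens_ci = sens_ci, spec_ci = spec_ci,
    display = c(sensitivity = percent_trunc(sens),
                sens_lower = percent_trunc(sens_ci[["lower"]]),
                sens_upper = percent_trunc(sens_ci[["upper"]]),
                specificity = percent_trunc(spec),
                spec_lower = percent_trunc(spec_ci[["lower"]]),
                spec_upper = percent_trunc(spec_ci[["upper"]]))
  ), class = "cle_diagnostic_result")
}

#' @export
print.cle_diagnostic_result <- function(x, ...) {
  d <- x$display
  cat(sprintf(
    "sensitivity %.1f%% (95%%CI: %.1f-%.1f) | specificity %.1f%% (95%%CI: %.1f-%.1f)\n",
    d["sensitivity"], d["sens_lower"], d["sens_upper"],
    d["specificity"], d["spec_lower"], d["spec_upper"]))
  invisible(x)
}

#' Items x raters rating matrix
#'
#' Binary calls (0 = homogeneous, 1 = inhomogeneous) of several raters over
#' the same items, with the per-item histology truth.
#'
#' @param calls Integer matrix, items in rows, raters in columns, cells 0/1,
#'   no missing values.
#' @param truth Character vector of per-item labels (`"benign"`/`"scc"`).
#' @return An object of class `cle_rating_matrix`.
#' @export
rating_matrix <- function(calls, truth) {
  calls <- as.matrix(calls)
  if (anyNA(calls) || !all(calls %in% c(0L, 1L)))
    stop("calls must be a complete 0/1 matrix", call. = FALSE)
  if (length(truth) != nrow(calls))
    stop("one truth label per item (row) is required", call. = FALSE)
  if (!all(truth %in% c("benign", "scc")))
    stop("truth labels must be 'benign' or 'scc'", call. = FALSE)
  storage.mode(calls) <- "integer"
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("rater", seq_len(ncol(calls)))
  structure(list(calls = calls, truth = truth), class = "cle_rating_matrix")
}

#' Fleiss kappa for binary ratings
#'
#' Chance-corrected agreement of >= 2 raters over the two categories
#' homogeneous/inhomogeneous. When every rating falls in a single category
#' the chance-agreement denominator vanishes; by documented convention the
#' function returns kappa = 1 then (observed agreement is necessarily 1).
#'
#' @param m A [rating_matrix()] or a plain 0/1 items x raters matrix.
#' @return An object of class `cle_kappa_result`: list with `kappa`, `band`
#'   (Landis-Koch, see [interpret_kappa()]), `p_obs`, `p_exp`.
#' @export
fleiss_kappa <- function(m) {
  calls <- if (inherits(m, "cle_rating_matrix")) m$calls else as.matrix(m)
  if (anyNA(calls) || !all(calls %in% c(0L, 1L)))
    stop("calls must be a complete 0/1 matrix", call. = FALSE)
  n_items <- nrow(calls)
  n_raters <- ncol(calls)
  if (n_items < 2L || n_raters < 2L)
    stop("Fleiss kappa needs >= 2 items and >= 2 raters", call. = FALSE)
  n1 <- rowSums(calls)
  n0 <- n_raters - n1
  p_obs <- mean((n0 * (n0 - 1) + n1 * (n1 - 1)) / (n_raters * (n_raters - 1)))
  p1 <- sum(n1) / (n_items * n_raters)
  p_exp <- p1^2 + (1 - p1)^2
  if (p_exp >= 1) {
    if (p_obs == 1) {
      kappa <- 1
    } else {
      stop("all ratings in one category with imperfect agreement: kappa undefined",
           call. = FALSE)
    }
  } else {
    kappa <- (p_obs - p_exp) / (1 - p_exp)
  }
  structure(list(kappa = kappa, band = interpret_kappa(kappa),
                 p_obs = p_obs, p_exp = p_exp),
            class = "cle_kappa_result")
}

#' @export
print.cle_kappa_result <- function(x, ...) {
  cat(sprintf("Fleiss kappa = %.3f (%s agreement)\n", x$kappa, x$band))
  invisible(x)
}

#' Landis-Koch interpretation of kappa
#'
#' Bands with inclusive upper bounds: up to 0.20 low, 0.40 fair, 0.60
#' moderate, 0.80 substantial, 1.0 almost perfect. Negative kappas map to
#' `low` with a warning.
#'
#' @param k Kappa in `[-1, 1]`.
#' @return One of `"low"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
#' @examples
#' interpret_kappa(0.53)  # moderate
interpret_kappa <- function(k) {
  if (!is.finite(k) || k < -1 || k > 1)
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  if (k < 0) {
    warning("negative kappa (agreement below chance) mapped to 'low'",
            call. = FALSE)
    return("low")
  }
  if (k <= 0.20) "low"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Per-rater and pooled diagnostic table
#'
#' For each rater, and pooled over all raters ("All"), the inhomogeneity
#' counts among benign and SCC items, sensitivity/specificity with Wilson
#' 95% CIs (raw and truncation-display values) and the chi-square p of the
#' rater's 2x2 table.
#'
#' @param m A [rating_matrix()] with truth labels, or a data.frame of counts
#'   in the shape of [cle_observer_counts()].
#' @return A data.frame with one row per rater plus `"All"`.
#' @export
#' @examples
#' rater_table(cle_observer_counts())[8, c("sensitivity_pct", "specificity_pct")]
rater_table <- function(m) {
  if (inherits(m, "cle_rating_matrix")) {
    scc <- m$truth == "scc"
    counts <- data.frame(
      rater = colnames(m$calls),
      n_benign = sum(!scc),
      benign_inhom = colSums(m$calls[!scc, , drop = FALSE]),
      n_scc = sum(scc),
      scc_inhom = colSums(m$calls[scc, , drop = FALSE])
    )
  } else {
    counts <- as.data.frame(m)
    need <- c("rater", "n_benign", "benign_inhom", "n_scc", "scc_inhom")
    if (!all(need %in% names(counts)))
      stop("count input must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
  }
  pooled <- data.frame(rater = "All",
                       n_benign = sum(counts$n_benign),
                       benign_inhom = sum(counts$benign_inhom),
                       n_scc = sum(counts$n_scc),
                       scc_inhom = sum(counts$scc_inhom))
  counts <- rbind(counts, pooled)

  rows <- lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], {
      dm <- diagnostic_metrics(tp = scc_inhom, fn = n_scc - scc_inhom,
                               fp = benign_inhom, tn = n_benign - benign_inhom)
      chi_p <- tryCatch(
        chi_square_2x2(matrix(c(dm$tp, dm$fp, dm$fn, dm$tn), 2L))$p,
        error = function(e) NA_real_)
      data.frame(rater = rater,
                 n_benign = n_benign, benign_inhom = benign_inhom,
                 n_scc = n_scc, scc_inhom = scc_inhom,
                 sensitivity = dm$sensitivity,
                 specificity = dm$specificity,
                 sens_lower = dm$sens_ci[["lower"]],
                 sens_upper = dm$sens_ci[["upper"]],
                 spec_lower = dm$spec_ci[["lower"]],
                 spec_upper = dm$spec_ci[["upper"]],
                 sensitivity_pct = dm$display[["sensitivity"]],
                 specificity_pct = dm$display[["specificity"]],
                 chisq_p = chi_p)
    })
  })
  do.call(rbind, rows)
}
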