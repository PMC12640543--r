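#' Relative RNA level by the delta-Ct method
#'
#' `2^(ct_reference - ct_target)`: the target's abundance expressed in
#' copies per copy of the reference transcript, assuming equal
#' amplification efficiency.
#'
#' @param ct_target,ct_reference qPCR cycle-threshold values
#'   (vectorised).
#' @return Relative level(s), `> 0`.
#' @export
delta_ct_level <- function(ct_target, ct_reference) {
  if (anyNA(ct_reference) || any(!is.finite(ct_reference))) {
    abort("missing or non-finite reference Ct: normalization impossible")
  }
  if (anyNA(ct_target) || any(!is.finite(ct_target))) {
    abort("missing or non-finite target Ct; record undetected targets as negative instead")
  }
  2^(ct_reference - ct_target)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Tibble `estimate, low, high` (proportions). `k = 0` gives
#'   `low = 0`; `k = n` gives `high = 1`.
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    abort("need integer 0 <= k <= n with n >= 1")
  }
  ci <- binom.test(k, n, conf.level = conf)$conf.int
  tibble(estimate = k / n, low = ci[1], high = ci[2])
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the
#' observed one, as computed by [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != round(table))) {
    abort("need a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warn("a margin of the table is zero: p = 1")
    return(1)
  }
  fisher.test(table)$p.value
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order (via
#'   [stats::p.adjust()] with `method = "holm"`).
#' @export
holm_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact for small tie-free samples (combined n <= 20), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warn("all values identical across groups: p = 1")
    return(1)
  }
  exact <- length(x) + length(y) <= 20 && !any(duplicated(c(x, y)))
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

#' Studentized bootstrap two-sample t test
#'
#' Bootstrap analogue of Welch's t test: each group is centred at its own
#' mean (imposing the null of equal means), resampled with replacement,
#' and the Welch t statistic recomputed; the two-sided p-value is the
#' add-one-corrected fraction of bootstrap statistics at least as extreme
#' as the observed one. Suited to comparing large non-normal
#' distributions such as pairwise-identity sets.
#'
#' @param x,y Numeric samples of size >= 2 with nonzero variance.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed.
#' @return List of class `boot_t_test`: `statistic` (observed Welch t),
#'   `p_value`, `n_boot`, `estimate` (mean difference x - y).
#' @export
bootstrap_t_test <- function(x, y, n_boot = 10000, seed = NULL) {
  if (length(x) < 2 || length(y) < 2) abort("both samples must have size >= 2")
  if (var(x) == 0 || var(y) == 0) abort("zero variance in a sample: t undefined")
  if (!is.null(seed)) set.seed(seed)
  nx <- length(x)
  ny <- length(y)
  welch_t <- function(mx, my, vx, vy) (mx - my) / sqrt(vx / nx + vy / ny)
  t_obs <- welch_t(mean(x), mean(y), var(x), var(y))

  xc <- x - mean(x)
  yc <- y - mean(y)
  # vectorised resampling in blocks to bound memory on large samples
  block <- max(1L, min(n_boot, floor(2e6 / max(nx, ny))))
  n_extreme <- 0L
  done <- 0L
  while (done < n_boot) {
    b <- min(block, n_boot - done)
    bx <- matrix(sample(xc, nx * b, replace = TRUE), nrow = b)
    by <- matrix(sample(yc, ny * b, replace = TRUE), nrow = b)
    mx <- rowMeans(bx)
    my <- rowMeans(by)
    vx <- (rowSums(bx^2) - nx * mx^2) / (nx - 1)
    vy <- (rowSums(by^2) - ny * my^2) / (ny - 1)
    t_star <- welch_t(mx, my, vx, vy)
    # degenerate resamples (both groups constant and equal): no evidence
    t_star[is.nan(t_star)] <- 0
    n_extreme <- n_extreme + sum(abs(t_star) >= abs(t_obs))
    done <- done + b
  }
  p <- (1 + n_extreme) / (1 + n_boot)
  structure(
    list(statistic = t_obs, p_value = p, n_boot = n_boot,
         estimate = mean(x) - mean(y), seed = seed),
    class = "boot_t_test"
  )
}

#' @export
print.boot_t_test <- function(x, ...) {
  cat(sprintf("bootstrap Welch t = %.3f, p = %.4g (%d resamples)\n",
              x$statistic, x$p_value, x$n_boot))
  invisible(x)
}

#' @export
tidy.boot_t_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         estimate = x$estimate, n_boot = x$n_boot)
}

#' Reads per million host-mapping reads
#'
#' @param virus_reads,host_reads Read counts (vectorised);
#'   `host_reads > 0`.
#' @return `virus_reads / host_reads * 1e6`.
#' @export
rpm_normalize <- function(virus_reads, host_reads) {
  if (any(host_reads <= 0)) abort("host_reads must be positive")
  virus_reads / host_reads * 1e6
}

#' Plus/minus strand read ratio
#'
#' @param plus_reads,minus_reads Strand-specific read counts;
#'   `minus_reads > 0`.
#' @return `plus_reads / minus_reads`.
#' @export
strand_ratio <- function(plus_reads, minus_reads) {
  if (any(minus_reads <= 0)) abort("minus_reads must be positive")
  plus_reads / minus_reads
}

#' Log10-log10 linear regression
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`, the standard way
#' to compare two relative-abundance measures spanning orders of
#' magnitude.
#'
#' @param x,y Positive numeric vectors, length >= 3.
#' @return Tibble `slope, intercept, r_squared, n`.
#' @export
loglog_regression <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 points")
  if (any(x <= 0) || any(y <= 0)) abort("values must be positive for log transformation")
  ly <- log10(y)
  fit <- lm(ly ~ log10(x))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = 1 - ss_res / ss_tot,
    n = length(x)
  )
}

#' Prevalence table with exact binomial intervals
#'
#' Prevalence is virus-positive samples over reference-positive samples
#' (the assay-valid denominator), as a percentage, with Clopper-Pearson
#' intervals.
#'
#' @param counts Tibble with columns `n_reference_positive`,
#'   `n_virus_positive` and any grouping columns (e.g. `location`,
#'   `period`).
#' @param conf Confidence level (default 0.95).
#' @return The input with `prevalence`, `ci_low`, `ci_high` appended
#'   (percent).
#' @export
prevalence_table <- function(counts, conf = 0.95) {
  if (any(counts$n_virus_positive > counts$n_reference_positive)) {
    abort("n_virus_positive cannot exceed n_reference_positive")
  }
  cis <- map2(counts$n_virus_positive, counts$n_reference_positive,
              clopper_pearson_ci, conf = conf) |>
    bind_rows()
  counts |>
    mutate(
      prevalence = 100 * cis$estimate,
      ci_low = 100 * cis$low,
      ci_high = 100 * cis$high
    )
}
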