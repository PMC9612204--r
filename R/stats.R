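#' Pearson correlation and root mean squared deviation
#'
#' The two waveform/spectrum agreement metrics used throughout the
#' cap-versus-cap comparison.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `pearson_r()`: the product-moment correlation; `rmsd()`:
#'   `sqrt(mean((x - y)^2))`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' @rdname pearson_r
#' @export
rmsd <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  sqrt(mean((x - y)^2))
}

#' Lilliefors test of normality
#'
#' One-sample Kolmogorov--Smirnov test against a normal distribution with
#' mean and SD *estimated from the sample* (the Lilliefors correction);
#' comparing against a fully specified normal would be anticonservative with
#' estimated moments. Used to justify nonparametric comparison tests.
#'
#' @param sample numeric vector, n >= 8, non-degenerate.
#' @param alpha decision level.
#' @return tibble of class `cap_test_result` with columns `test`,
#'   `statistic`, `p_value`, `alpha`, `decision`.
#' @export
ks_normality <- function(sample, alpha = 0.05) {
  sample <- as.numeric(sample)
  if (length(sample) < 8) {
    stop("Lilliefors test needs n >= 8 (got ", length(sample), ")",
         call. = FALSE)
  }
  if (stats::sd(sample) == 0) {
    stop("degenerate sample (zero SD)", call. = FALSE)
  }
  lt <- nortest::lillie.test(sample)
  new_test_result("ks_normality", unname(lt$statistic), lt$p.value, alpha,
                  reject_means = "non-normal", accept_means = "normal")
}

#' Wilcoxon--Mann--Whitney U test
#'
#' Rank-sum test of two independent samples with midranks for ties. The U
#' statistic is reported for the first sample. The p-value is exact (from
#' the full permutation null of the rank statistic) when `n_a * n_b <= 400`
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param alpha decision level.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact path; the
#'   default `NULL` selects it automatically. Forcing `TRUE` with ties is an
#'   error.
#' @return tibble of class `cap_test_result` with columns `test`,
#'   `statistic` (U of `a`), `p_value`, `alpha`, `decision`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(a, b, alpha = 0.05, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))                     # midranks for ties
  ra <- sum(r[seq_len(na)])
  u_a <- ra - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (isTRUE(exact) && ties) {
    stop("exact Mann-Whitney p-value unavailable with ties", call. = FALSE)
  }
  use_exact <- if (is.null(exact)) !ties && na * nb <= 400 else exact
  if (use_exact) {
    # exact null distribution of U over all C(na+nb, na) rank assignments
    u_low <- min(u_a, na * nb - u_a)
    p <- min(1, 2 * stats::pwilcox(u_low, na, nb))
    method <- "exact"
  } else {
    tie_tab <- table(r)
    n <- na + nb
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1                             # all observations identical
    } else {
      z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)  # continuity corr.
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  out <- new_test_result("mann_whitney_u", u_a, p, alpha,
                         reject_means = "different", accept_means = "equal")
  out$method <- method
  out
}

new_test_result <- function(test, statistic, p_value, alpha,
                            reject_means, accept_means) {
  out <- tibble::tibble(
    test = test, statistic = statistic, p_value = p_value, alpha = alpha,
    decision = ifelse(p_value < alpha, reject_means, accept_means))
  class(out) <- c("cap_test_result", class(out))
  out
}

#' @export
tidy.cap_test_result <- function(x, ...) tibble::as_tibble(x)
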