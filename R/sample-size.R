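#' Asymptotic variance of the intraclass kappa estimate
#'
#' Large-sample variance of the estimated kappa in a reproducibility study
#' with binary outcomes under the common-correlation model, the quantity on
#' which the expected confidence-interval-width method of Giraudeau and
#' Mary rests. For two replicates per subject the closed form is
#' \deqn{var(\hat\kappa) = \frac{1-\kappa}{n}\left[(1-\kappa)(1-2\kappa) +
#'   \frac{\kappa(2-\kappa)}{2\pi(1-\pi)}\right]}
#' with trait prevalence \eqn{\pi} and `n` subjects. For more than two
#' replicates per subject no comparably standard closed form exists; the
#' two-replicate variance is divided by `replicates - 1` as a documented
#' approximation (each added replicate contributing roughly one more
#' quasi-independent comparison), and planning calculations in this package
#' default to the two-replicate design the method is defined for.
#'
#' @param kappa0 Expected kappa, in (0, 1).
#' @param n Number of subjects, at least 2.
#' @param prevalence Probability of the trait, in (0, 1); default 0.5.
#' @param replicates Replicate ratings per subject, at least 2 (default 2).
#' @return The variance (dimensionless), scaling as 1/n.
#' @examples
#' kappa_variance(0.70, n = 50)
#' @export
kappa_variance <- function(kappa0, n, prevalence = 0.5, replicates = 2) {
  .check_ss(kappa0, prevalence, replicates)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2) {
    stop("'n' must be a single number >= 2", call. = FALSE)
  }
  v2 <- (1 - kappa0) / n *
    ((1 - kappa0) * (1 - 2 * kappa0) +
       kappa0 * (2 - kappa0) / (2 * prevalence * (1 - prevalence)))
  v2 / (replicates - 1)
}

.check_ss <- function(kappa0, prevalence, replicates) {
  if (!is.numeric(kappa0) || length(kappa0) != 1L || kappa0 <= 0 ||
      kappa0 >= 1) {
    stop("'kappa0' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("'prevalence' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 2 ||
      replicates != round(replicates)) {
    stop("'replicates' must be an integer >= 2", call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected confidence-interval width for kappa
#'
#' Full width (upper minus lower limit) of the anticipated two-sided
#' normal-approximation confidence interval for kappa at the given sample
#' size: `2 * z * sqrt(kappa_variance(...))`.
#'
#' @inheritParams kappa_variance
#' @param conf Two-sided confidence level (default 0.90).
#' @return Expected CI width (dimensionless).
#' @examples
#' kappa_ci_width(0.70, n = 50, conf = 0.90)
#' @export
kappa_ci_width <- function(kappa0, n, prevalence = 0.5, conf = 0.90,
                           replicates = 2) {
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1) {
    stop("'conf' must lie strictly in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  2 * z * sqrt(kappa_variance(kappa0, n, prevalence, replicates))
}

#' Required number of subjects for an agreement study
#'
#' Smallest number of subjects `n >= 2` such that the expected width of the
#' two-sided confidence interval for kappa does not exceed
#' `max_expected_width`, given the anticipated kappa, trait prevalence and
#' confidence level (the expected-width planning approach of Giraudeau and
#' Mary). Because the variance scales as 1/n, the closed-form candidate is
#' `n = 4 z^2 V1 / width^2` (with `V1` the per-subject variance factor),
#' refined to the exact minimal integer.
#'
#' @inheritParams kappa_ci_width
#' @param max_expected_width Largest acceptable expected CI width, > 0.
#' @param n_max Upper bound on the search (default 1e6); an `n` beyond this
#'   triggers an error describing the unattainable width.
#' @return Integer: the minimal sufficient number of subjects.
#' @examples
#' # anticipated kappa 0.70, 90% confidence, expected width at most 0.35
#' required_n(0.70, max_expected_width = 0.35)
#' @export
required_n <- function(kappa0, max_expected_width, prevalence = 0.5,
                       conf = 0.90, replicates = 2, n_max = 1e6) {
  if (!is.numeric(max_expected_width) || length(max_expected_width) != 1L ||
      max_expected_width <= 0) {
    stop("'max_expected_width' must be > 0", call. = FALSE)
  }
  width <- function(n) kappa_ci_width(kappa0, n, prevalence, conf, replicates)
  # width(n) = c / sqrt(n): invert, then settle the integer boundary exactly
  n0 <- max(2, ceiling((width(1e4) * sqrt(1e4) / max_expected_width)^2))
  if (n0 > n_max) {
    stop(sprintf(paste0("expected width %.4g requires more than n_max = %g ",
                        "subjects under these parameters"),
                 max_expected_width, n_max), call. = FALSE)
  }
  n <- n0
  while (n > 2 && width(n - 1) <= max_expected_width) n <- n - 1
  while (width(n) > max_expected_width) {
    n <- n + 1
    if (n > n_max) {
      stop(sprintf("width target unattainable within n_max = %g", n_max),
           call. = FALSE)
    }
  }
  as.integer(n)
}
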