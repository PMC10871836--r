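#' @title Chance-corrected agreement estimates
#' @description Internal constructor for the classed kappa estimate returned
#'   by all agreement functions in the package.
#' @param kappa,se,conf,p_o,p_e,n_subjects,n_raters,n_categories,method,degenerate
#'   Components of the estimate.
#' @return An object of class `kappa_estimate`.
#' @keywords internal
new_kappa_estimate <- function(kappa, se, conf, p_o, p_e,
                               n_subjects, n_raters, n_categories,
                               method, degenerate = FALSE) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else kappa + c(-1, 1) * z * se
  ci <- pmin(pmax(ci, -1), 1)
  structure(
    list(kappa = kappa, se = se, ci_low = ci[1], ci_high = ci[2], conf = conf,
         p_o = p_o, p_e = p_e,
         n_subjects = as.integer(n_subjects), n_raters = as.integer(n_raters),
         n_categories = as.integer(n_categories),
         interpretation = interpret_kappa(kappa),
         degenerate = degenerate, method = method),
    class = "kappa_estimate"
  )
}

#' @export
print.kappa_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s\n", x$method))
  cat(sprintf("  kappa = %.*f (SE %.*f, %g%% CI %.*f to %.*f) - %s\n",
              digits, x$kappa, digits, x$se, 100 * x$conf,
              digits, x$ci_low, digits, x$ci_high, x$interpretation))
  cat(sprintf("  %d subjects, %d raters, %d categories",
              x$n_subjects, x$n_raters, x$n_categories))
  if (isTRUE(x$degenerate)) cat("  [degenerate: chance agreement = 1]")
  cat("\n")
  invisible(x)
}

#' Interpret a kappa value
#'
#' Maps a kappa coefficient to the conventional qualitative band used in
#' classification-reproducibility studies: values below 0.5 are
#' unsatisfactory, values between 0.5 and 0.75 (inclusive at both ends) are
#' satisfactory, and values above 0.75 are excellent.
#'
#' @param kappa Numeric vector of kappa values in `[-1, 1]`.
#' @return Character vector: `"unsatisfactory"`, `"satisfactory"` or
#'   `"excellent"`.
#' @examples
#' interpret_kappa(c(0.344, 0.595, 0.771))
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || anyNA(kappa)) {
    stop("'kappa' must be numeric without missing values", call. = FALSE)
  }
  if (any(kappa < -1 - 1e-12 | kappa > 1 + 1e-12)) {
    stop("kappa values must lie in [-1, 1]", call. = FALSE)
  }
  ifelse(kappa < 0.5, "unsatisfactory",
         ifelse(kappa <= 0.75, "satisfactory", "excellent"))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two categorical label sequences,
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is the observed proportion
#' of agreement and `p_e` the chance agreement from the product of the
#' marginal label distributions. The standard error is the large-sample
#' (delta-method) estimate of Fleiss, Cohen and Everitt, and the confidence
#' interval is the normal approximation clipped to `[-1, 1]`.
#'
#' When both raters assign one identical constant label, chance agreement is
#' 1 and kappa is undefined as a ratio; the estimate is returned as 1 with
#' zero standard error and flagged `degenerate`.
#'
#' @param labels_a,labels_b Equal-length vectors (character or factor) of
#'   labels for the same subjects; length at least 2.
#' @param categories Optional character vector fixing the label alphabet
#'   (useful so that unused categories are retained); defaults to the union
#'   of observed labels.
#' @param conf Confidence level for the interval (default 0.95).
#' @return A `kappa_estimate` object.
#' @examples
#' a <- c("I", "II", "II", "III", "I")
#' b <- c("I", "II", "III", "III", "I")
#' cohen_kappa(a, b)
#' @export
cohen_kappa <- function(labels_a, labels_b, categories = NULL, conf = 0.95) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(labels_a) || anyNA(labels_b)) {
    stop("label sequences must not contain missing values", call. = FALSE)
  }
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  if (is.null(categories)) {
    categories <- sort(unique(c(labels_a, labels_b)))
  } else if (!all(c(labels_a, labels_b) %in% categories)) {
    stop("labels outside the declared category alphabet", call. = FALSE)
  }
  fa <- factor(labels_a, levels = categories)
  fb <- factor(labels_b, levels = categories)
  tab <- table(fa, fb)
  p <- tab / n
  po <- sum(diag(p))
  prow <- rowSums(p)
  pcol <- colSums(p)
  pe <- sum(prow * pcol)

  if (1 - pe < 1e-12) {
    return(new_kappa_estimate(1, 0, conf, po, pe, n, 2, length(categories),
                              "Cohen's kappa (two raters)", degenerate = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt large-sample variance of kappa-hat
  k <- length(categories)
  A <- 0
  for (i in seq_len(k)) {
    A <- A + p[i, i] * ((1 - pe) - (pcol[i] + prow[i]) * (1 - po))^2
  }
  B <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) B <- B + p[i, j] * (pcol[i] + prow[j])^2
    }
  }
  B <- B * (1 - po)^2
  C <- (po * pe - 2 * pe + po)^2
  v <- (A + B - C) / (n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  new_kappa_estimate(kappa, se, conf, po, pe, n, 2, length(categories),
                     "Cohen's kappa (two raters)")
}

#' Fleiss's kappa for a fixed number of raters per subject
#'
#' Multi-rater chance-corrected agreement from a subjects-by-categories
#' count matrix in which each row records how many of the `m` raters
#' assigned each category to that subject. Per-subject agreement is the
#' proportion of concordant rater pairs; chance agreement is the sum of
#' squared overall category shares. The standard error is Fleiss's
#' large-sample formula.
#'
#' If all rating mass falls in a single category across all subjects,
#' chance agreement is 1; the estimate is returned as 1 with zero standard
#' error and flagged `degenerate`.
#'
#' @param count_matrix Numeric matrix (subjects x categories) of
#'   non-negative integer counts; every row must sum to the same number of
#'   raters `m >= 2`; at least 2 subjects.
#' @param conf Confidence level for the interval (default 0.95).
#' @return A `kappa_estimate` object.
#' @examples
#' counts <- rbind(c(3, 0, 0), c(2, 1, 0), c(0, 3, 0), c(0, 1, 2))
#' fleiss_kappa(counts)
#' @export
fleiss_kappa <- function(count_matrix, conf = 0.95) {
  count_matrix <- as.matrix(count_matrix)
  if (nrow(count_matrix) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(count_matrix) || any(count_matrix < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  m_per_row <- rowSums(count_matrix)
  m <- m_per_row[1]
  if (any(m_per_row != m)) {
    stop("every subject must be rated by the same number of raters",
         call. = FALSE)
  }
  if (m < 2) stop("need at least 2 raters per subject", call. = FALSE)
  n <- nrow(count_matrix)
  k <- ncol(count_matrix)

  p_j <- colSums(count_matrix) / (n * m)
  P_i <- (rowSums(count_matrix^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)

  if (1 - P_e < 1e-12) {
    return(new_kappa_estimate(1, 0, conf, P_bar, P_e, n, m, k,
                              sprintf("Fleiss's kappa (%d raters)", m),
                              degenerate = TRUE))
  }
  kappa <- (P_bar - P_e) / (1 - P_e)

  # Fleiss (1971) large-sample standard error
  q_j <- 1 - p_j
  spq <- sum(p_j * q_j)
  se <- sqrt(2 / (n * m * (m - 1))) *
    sqrt(max(spq^2 - sum(p_j * q_j * (q_j - p_j)), 0)) / spq
  new_kappa_estimate(kappa, se, conf, P_bar, P_e, n, m, k,
                     sprintf("Fleiss's kappa (%d raters)", m))
}
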