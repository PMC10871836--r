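# Independent brute-force oracles, deliberately coded from the defining
# formulas rather than sharing any code path with the package.

# Cohen kappa straight from the cross-tabulation: count agreements and
# marginal label frequencies by explicit loops.
oracle_cohen <- function(a, b, categories = sort(unique(c(a, b)))) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n)) if (a[i] == b[i]) agree <- agree + 1
  po <- agree / n
  pe <- 0
  for (cat in categories) {
    pe <- pe + (sum(a == cat) / n) * (sum(b == cat) / n)
  }
  if (1 - pe < 1e-12) return(NA_real_)  # degenerate, flagged by the package
  (po - pe) / (1 - pe)
}

# Fleiss kappa from per-subject pair counts: P_i as the fraction of
# concordant rater pairs, category shares p_j pooled over all ratings.
oracle_fleiss <- function(counts) {
  n <- nrow(counts)
  m <- sum(counts[1, ])
  P_i <- numeric(n)
  for (i in seq_len(n)) {
    concordant <- 0
    for (j in seq_len(ncol(counts))) {
      concordant <- concordant + counts[i, j] * (counts[i, j] - 1)
    }
    P_i[i] <- concordant / (m * (m - 1))
  }
  p_j <- colSums(counts) / (n * m)
  pe <- sum(p_j^2)
  if (1 - pe < 1e-12) return(NA_real_)
  (mean(P_i) - pe) / (1 - pe)
}

# Textbook one-way ANOVA F from explicit sums of squares.
oracle_oneway_F <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, 1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  (ss_between / df1) / (ss_within / df2)
}

# All non-negative integer k-vectors summing to m (count-matrix rows).
compositions <- function(m, k) {
  g <- as.matrix(expand.grid(rep(list(0:m), k)))
  g[rowSums(g) == m, , drop = FALSE]
}

# All label sequences of length n over an alphabet.
all_sequences <- function(n, categories) {
  as.matrix(expand.grid(rep(list(categories), n),
                        stringsAsFactors = FALSE))
}
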