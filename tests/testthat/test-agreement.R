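# small deterministic rating table builder
make_ratings <- function(labels_by_obs_session, system = "IDEAL",
                         subjects = NULL) {
  rows <- list()
  for (obs in names(labels_by_obs_session)) {
    for (ses in names(labels_by_obs_session[[obs]])) {
      lab <- labels_by_obs_session[[obs]][[ses]]
      subj <- if (is.null(subjects)) sprintf("s%02d", seq_along(lab)) else subjects
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj, observer_id = obs, session = ses,
        system = system, label = lab, stringsAsFactors = FALSE)
    }
  }
  rating_table(do.call(rbind, rows))
}

test_that("rating-table validation flags duplicates, bad labels and gaps", {
  ok <- data.frame(subject_id = rep(c("s1", "s2"), each = 2),
                   observer_id = rep(c("o1", "o2"), 2),
                   session = "T1", system = "Frykman",
                   label = c("I", "II", "VIII", "IV"),
                   stringsAsFactors = FALSE)
  v <- validate_ratings(ok)
  expect_equal(nrow(v$issues), 0L)

  dup <- rbind(ok, ok[2, ])
  vd <- validate_ratings(dup)
  errs <- vd$issues[vd$issues$severity == "error", ]
  expect_equal(nrow(errs), 1L)
  expect_match(errs$message, "duplicate record")
  expect_match(errs$message, "observer o2")
  expect_error(rating_table(dup), "duplicate")

  bad <- ok
  bad$label[3] <- "IX"
  vb <- validate_ratings(bad)
  expect_match(vb$issues$message[vb$issues$severity == "error"],
               "label 'IX' not in Frykman alphabet")
  expect_error(rating_table(bad), "alphabet")

  gap <- ok[-4, ]
  vg <- validate_ratings(gap)
  w <- vg$issues[vg$issues$severity == "warning", ]
  expect_match(w$message, "1 missing \\(subject, observer, session\\)")
  expect_warning(rating_table(gap), "missing")

  expect_error(validate_ratings(ok[, -5]), "missing columns: label")
})

test_that("intraobserver kappa treats sessions as replicate raters", {
  # identical labels in all three sessions -> kappa 1
  lab <- c("I", "II", "III", "II", "I", "III")
  rt <- make_ratings(list(o1 = list(T1 = lab, T2 = lab, T3 = lab)))
  expect_equal(intraobserver_kappa(rt, "o1", "IDEAL")$kappa, 1)

  # three sessions must equal a hand-built Fleiss kappa on the same counts
  l1 <- c("I", "II", "II", "III", "I")
  l2 <- c("I", "II", "III", "III", "I")
  l3 <- c("II", "II", "II", "III", "I")
  rt3 <- make_ratings(list(o1 = list(T1 = l1, T2 = l2, T3 = l3)))
  counts <- t(sapply(1:5, function(i) {
    tabulate(factor(c(l1[i], l2[i], l3[i]), levels = c("I", "II", "III")), 3)
  }))
  est <- intraobserver_kappa(rt3, "o1", "IDEAL")
  expect_equal(est$kappa, fleiss_kappa(counts)$kappa, tolerance = 1e-14)
  expect_equal(est$kappa, oracle_fleiss(counts), tolerance = 1e-12)
  expect_equal(est$n_raters, 3L)

  # two sessions reduce to the 2-replicate Fleiss kappa
  rt2 <- make_ratings(list(o1 = list(T1 = l1, T2 = l2)))
  counts2 <- t(sapply(1:5, function(i) {
    tabulate(factor(c(l1[i], l2[i]), levels = c("I", "II", "III")), 3)
  }))
  expect_equal(intraobserver_kappa(rt2, "o1", "IDEAL")$kappa,
               fleiss_kappa(counts2)$kappa, tolerance = 1e-14)
})

test_that("incomplete session coverage drops subjects with a warning", {
  df <- data.frame(
    subject_id = c("s1", "s1", "s2", "s2", "s3"),
    observer_id = "o1", session = c("T1", "T2", "T1", "T2", "T1"),
    system = "IDEAL", label = c("I", "I", "II", "II", "III"),
    stringsAsFactors = FALSE)
  rt <- suppressWarnings(rating_table(df))
  expect_warning(est <- intraobserver_kappa(rt, "o1", "IDEAL"),
                 "dropped 1 of 3 subjects")
  expect_equal(est$n_subjects, 2L)
  # with a single complete subject the analysis must refuse
  df2 <- df[df$subject_id != "s2" | df$session != "T2", ]
  rt2 <- suppressWarnings(rating_table(df2))
  expect_error(suppressWarnings(intraobserver_kappa(rt2, "o1", "IDEAL")),
               "fewer than 2")
})

test_that("interobserver kappa pools observers at one session", {
  lab <- c("I", "II", "III", "II")
  rt <- make_ratings(list(o1 = list(T1 = lab), o2 = list(T1 = lab),
                          o3 = list(T1 = lab)))
  expect_equal(interobserver_kappa(rt, "T1", "IDEAL")$kappa, 1)

  # two observers: equals the 2-rater Fleiss kappa on the same data
  a <- c("I", "II", "II", "III", "I", "II")
  b <- c("I", "III", "II", "III", "II", "II")
  rt2 <- make_ratings(list(o1 = list(T1 = a), o2 = list(T1 = b)))
  counts <- t(sapply(seq_along(a), function(i) {
    tabulate(factor(c(a[i], b[i]), levels = c("I", "II", "III")), 3)
  }))
  expect_equal(interobserver_kappa(rt2, "T1", "IDEAL")$kappa,
               fleiss_kappa(counts)$kappa, tolerance = 1e-14)
})

test_that("session drift returns consecutive-pair Cohen kappas", {
  l1 <- c("I", "II", "II", "III", "I", "II", "III", "I")
  l2 <- c("I", "II", "III", "III", "I", "II", "III", "II")
  l3 <- l2
  rt <- make_ratings(list(o1 = list(T1 = l1, T2 = l2, T3 = l3)))
  dr <- session_drift(rt, "o1", "IDEAL")
  expect_named(dr, c("T1 vs T2", "T2 vs T3"))
  expect_equal(dr[["T1 vs T2"]]$kappa,
               cohen_kappa(l1, l2, categories = c("I", "II", "III"))$kappa)
  expect_equal(dr[["T2 vs T3"]]$kappa, 1)

  same <- make_ratings(list(o1 = list(T1 = l1, T2 = l1, T3 = l1)))
  dr2 <- session_drift(same, "o1", "IDEAL")
  expect_true(all(vapply(dr2, function(e) e$kappa, 1) == 1))
})

test_that("pairwise mean kappa equals the brute-force mean over pairs", {
  set.seed(31)
  cats <- c("I", "II", "III")
  obs <- paste0("o", 1:6)
  truth <- sample(cats, 25, replace = TRUE)
  labs <- lapply(obs, function(o) {
    ifelse(runif(25) < 0.75, truth, sample(cats, 25, replace = TRUE))
  })
  names(labs) <- obs
  rt <- make_ratings(lapply(labs, function(l) list(T1 = l)))
  pm <- pairwise_mean_kappa(rt, "T1", "IDEAL")
  expect_equal(pm$n_pairs, choose(6, 2))
  # independent enumeration of the 15 pairs
  ref <- mean(apply(combn(obs, 2), 2, function(p) {
    oracle_cohen(labs[[p[1]]], labs[[p[2]]], cats)
  }))
  expect_equal(pm$mean_kappa, ref, tolerance = 1e-12)

  # two observers: the mean is just their Cohen kappa
  rt2 <- make_ratings(list(o1 = list(T1 = labs$o1), o2 = list(T1 = labs$o2)))
  expect_equal(pairwise_mean_kappa(rt2, "T1", "IDEAL")$mean_kappa,
               cohen_kappa(labs$o1, labs$o2, categories = cats)$kappa)

  # all observers identical -> 1
  rt_same <- make_ratings(stats::setNames(rep(list(list(T1 = truth)), 3),
                                          c("a", "b", "c")))
  expect_equal(pairwise_mean_kappa(rt_same, "T1", "IDEAL")$mean_kappa, 1)
})

test_that("degenerate observer pairs are excluded with a warning", {
  rt <- make_ratings(list(o1 = list(T1 = c("I", "I", "I")),
                          o2 = list(T1 = c("I", "I", "I")),
                          o3 = list(T1 = c("I", "II", "I"))))
  expect_warning(pm <- pairwise_mean_kappa(rt, "T1", "IDEAL"),
                 "degenerate")
  expect_equal(pm$n_pairs, 2L)
  expect_equal(pm$excluded, "o1:o2")
})

test_that("cross-system comparison reproduces a sums-of-squares F oracle", {
  groups <- list(IDEAL = c(0.80, 0.90), Frykman = c(0.55, 0.60))
  cmp <- compare_kappa_sets(groups)
  expect_equal(cmp$statistic, oracle_oneway_F(groups), tolerance = 1e-12)
  expect_equal(cmp$df, c(1, 2))
  # p from the F distribution itself
  expect_equal(cmp$p_value, stats::pf(cmp$statistic, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  g4 <- list(a = c(0.7, 0.8, 0.75), b = c(0.5, 0.55, 0.6),
             c = c(0.65, 0.6, 0.7), d = c(0.4, 0.45, 0.5))
  cmp4 <- compare_kappa_sets(g4, permutations = 200, seed = 5)
  expect_equal(cmp4$statistic, oracle_oneway_F(g4), tolerance = 1e-12)
  expect_equal(nrow(cmp4$pairwise), choose(4, 2))
  expect_true(cmp4$permutation_p > 0 && cmp4$permutation_p <= 1)
  # pairwise rows are two-group F tests
  ab <- cmp4$pairwise[cmp4$pairwise$system_a == "a" &
                        cmp4$pairwise$system_b == "b", ]
  expect_equal(ab$F, oracle_oneway_F(g4[c("a", "b")]), tolerance = 1e-12)
})

test_that("identical groups yield a degenerate zero-F comparison", {
  cmp <- compare_kappa_sets(list(x = c(0.6, 0.6), y = c(0.6, 0.6)))
  expect_true(cmp$degenerate)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_kappa_sets(list(x = 0.5, y = c(0.6, 0.7))),
               "at least 2")
  expect_error(compare_kappa_sets(list(c(0.5, 0.6))), "named")
})

test_that("the F comparison holds its nominal type-I error under the null", {
  set.seed(41)
  reps <- 400
  rejections <- 0
  for (r in 1:reps) {
    groups <- list(a = rnorm(6, 0.6, 0.05), b = rnorm(6, 0.6, 0.05),
                   c = rnorm(6, 0.6, 0.05), d = rnorm(6, 0.6, 0.05))
    if (compare_kappa_sets(groups)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / reps
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 3 * mc_se)
})
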