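# case table with externally fixed true labels for one categorical system
fixed_truth_cases <- function(truth, system = "Fernandez") {
  df <- data.frame(case_id = sprintf("c%04d", seq_along(truth)),
                   stringsAsFactors = FALSE)
  df[[paste0("true_", system)]] <- truth
  df
}

perfect_profile <- function(id, rho = 0) {
  observer_profile(
    id,
    noise_sd = c(step = 0, shortening = 0, tilt = 0, inclination = 0),
    flip_prob = c(energy = 0, lesions = 0),
    accuracy = 1, session_correlation = rho)
}

test_that("case generation is deterministic and sized as configured", {
  cfg <- case_config(n_cases = 60, seed = 123)
  c1 <- generate_cases(cfg)
  c2 <- generate_cases(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 60L)
  expect_true(all(c1$true_IDEAL %in% c("I", "II", "III")))
  expect_true(all(c1$true_Frykman %in% study_alphabets()$Frykman))
  expect_true(all(c1$age_years >= 18))
  # the recorded truth is literally the score of the true findings
  rescored <- score_cases(c1[c("case_id", "articular_step_mm",
                               "radial_shortening_mm", "volar_tilt_loss_deg",
                               "radial_inclination_loss_deg", "age_years",
                               "energy", "lesions_present")])
  expect_equal(rescored$fracture_type, c1$true_IDEAL)
  expect_equal(rescored$total, c1$total)
})

test_that("a case mix with no displacement, young ages and low energy is all Type I", {
  cfg <- case_config(
    n_cases = 40, seed = 5, age_mean = 40, age_sd = 5, age_min = 18,
    p_high_energy = 0, p_lesions = 0, p_displaced = 0,
    p_articular = c(displaced = 0, undisplaced = 0),
    undisplaced = list(mean = c(step = 0, shortening = 0, tilt = 0,
                                inclination = 0),
                       sd = c(step = 0, shortening = 0, tilt = 0,
                              inclination = 0)))
  cases <- generate_cases(cfg)
  expect_true(all(cases$age_years < 60))
  expect_true(all(cases$true_IDEAL == "I"))
  expect_true(all(cases$total == 0))
})

test_that("the full study design yields 4320 rating records", {
  cases <- generate_cases(case_config(n_cases = 60, seed = 2))
  panel <- default_observer_panel()
  ratings <- simulate_ratings(cases, panel, n_sessions = 3, seed = 2)
  expect_equal(nrow(ratings), 60L * 6L * 3L * 4L)
  expect_s3_class(ratings, "rating_table")
  # exactly one record per key
  expect_equal(anyDuplicated(ratings[c("subject_id", "observer_id",
                                       "session", "system")]), 0L)
  # deterministic given the seed
  ratings2 <- simulate_ratings(cases, panel, n_sessions = 3, seed = 2)
  expect_identical(as.data.frame(ratings), as.data.frame(ratings2))
})

test_that("error-free observers reproduce the truth and all kappas are 1", {
  cases <- generate_cases(case_config(n_cases = 30, seed = 9))
  panel <- list(perfect_profile("p1"), perfect_profile("p2"),
                perfect_profile("p3"))
  ratings <- simulate_ratings(cases, panel, n_sessions = 3, seed = 9)
  for (s in c("IDEAL", "Frykman", "Fernandez", "AO")) {
    truth <- cases[[paste0("true_", s)]][match(
      ratings$subject_id[ratings$system == s], cases$case_id)]
    expect_true(all(ratings$label[ratings$system == s] == truth))
  }
  expect_equal(interobserver_kappa(ratings, "T1", "IDEAL")$kappa, 1)
  expect_equal(intraobserver_kappa(ratings, "p1", "Frykman")$kappa, 1)
})

test_that("observer substreams are isolated: panels grow without perturbing others", {
  cases <- generate_cases(case_config(n_cases = 20, seed = 4))
  p1 <- default_observer_panel()[[1]]
  p2 <- default_observer_panel()[[2]]
  solo <- simulate_ratings(cases, list(p1), n_sessions = 2, seed = 4)
  duo <- simulate_ratings(cases, list(p1, p2), n_sessions = 2, seed = 4)
  duo_p1 <- duo[duo$observer_id == p1$observer_id, ]
  expect_equal(as.data.frame(solo), as.data.frame(duo_p1),
               ignore_attr = TRUE)
})

test_that("session correlation 1 copies session 1 exactly; 0 decorrelates", {
  truth <- rep(study_alphabets()$Fernandez, 40)  # 200 cases, balanced
  cases <- fixed_truth_cases(truth)
  locked <- observer_profile("locked", accuracy = 0.7,
                             session_correlation = 1)
  r <- simulate_ratings(cases, list(locked), n_sessions = 3,
                        systems = "Fernandez", seed = 6)
  wide <- split(r$label, r$session)
  expect_identical(wide$T1, wide$T2)
  expect_identical(wide$T1, wide$T3)
  expect_equal(intraobserver_kappa(r, "locked", "Fernandez")$kappa, 1)

  free <- observer_profile("free", accuracy = 0.7, session_correlation = 0)
  r0 <- simulate_ratings(cases, list(free), n_sessions = 2,
                         systems = "Fernandez", seed = 6)
  w0 <- split(r0$label, r0$session)
  expect_false(identical(w0$T1, w0$T2))
})

test_that("presentation order is a blinded per-observer-session permutation", {
  ord <- randomize_presentation(60, observers = c("a", "b"), n_sessions = 3,
                                seed = 10)
  expect_equal(nrow(ord), 60 * 2 * 3)
  for (obs in c("a", "b")) {
    for (ses in c("T1", "T2", "T3")) {
      perm <- ord$case[ord$observer_id == obs & ord$session == ses]
      expect_equal(sort(perm), 1:60)
    }
  }
  # determinism and seed sensitivity: 100 seeds, no colliding orders
  perms <- vapply(1:100, function(s) {
    paste(randomize_presentation(60, seed = s)$case, collapse = ",")
  }, "")
  expect_equal(length(unique(perms)), 100L)
  expect_identical(perms[1],
                   paste(randomize_presentation(60, seed = 1)$case,
                         collapse = ","))
  expect_equal(randomize_presentation(1, seed = 3)$case, 1L)
})

test_that("estimated kappas recover the analytic confusion-model values (n = 500)", {
  k <- 5
  truth_probs <- c(0.30, 0.25, 0.20, 0.15, 0.10)
  set.seed(77)
  truth <- sample(study_alphabets()$Fernandez, 500, replace = TRUE,
                  prob = truth_probs)
  cases <- fixed_truth_cases(truth)
  cmA <- uniform_confusion(study_alphabets()$Fernandez, 0.85)
  cmB <- uniform_confusion(study_alphabets()$Fernandez, 0.70)
  pA <- observer_profile("A", confusion = list(Fernandez = cmA),
                         session_correlation = 0)
  pB <- observer_profile("B", confusion = list(Fernandez = cmB),
                         session_correlation = 0)
  r <- simulate_ratings(cases, list(pA, pB), n_sessions = 1,
                        systems = "Fernandez", seed = 77)
  la <- r$label[r$observer_id == "A"][order(r$subject_id[r$observer_id == "A"])]
  lb <- r$label[r$observer_id == "B"][order(r$subject_id[r$observer_id == "B"])]
  est <- cohen_kappa(la, lb, categories = study_alphabets()$Fernandez)
  # population kappa from the empirical truth mix actually simulated
  emp_probs <- as.vector(table(factor(truth,
                                      study_alphabets()$Fernandez))) / 500
  k_star <- analytic_cohen_kappa(emp_probs, cmA, cmB)
  expect_lt(abs(est$kappa - k_star), 3 * est$se)
})

test_that("intraobserver kappa recovers the session-correlation closed form (n = 500)", {
  alphabet <- study_alphabets()$Fernandez
  truth <- rep(alphabet, each = 100)  # fixed balanced truth
  cases <- fixed_truth_cases(truth)
  cm <- uniform_confusion(alphabet, 0.75)
  rho <- 0.4
  prof <- observer_profile("obs", confusion = list(Fernandez = cm),
                           session_correlation = rho)
  r <- simulate_ratings(cases, list(prof), n_sessions = 3,
                        systems = "Fernandez", seed = 42)
  est <- intraobserver_kappa(r, "obs", "Fernandez")
  k_star <- analytic_intraobserver_kappa(rep(0.2, 5), cm, rho, n_sessions = 3)
  expect_lt(abs(est$kappa - k_star), 3 * est$se)
})

test_that("uniform confusion gives chance-level agreement", {
  alphabet <- study_alphabets()$AO
  truth <- rep(alphabet, length.out = 400)
  cases <- fixed_truth_cases(truth, "AO")
  blind <- lapply(c("u1", "u2", "u3"), function(id) {
    observer_profile(id,
                     confusion = list(AO = uniform_confusion(alphabet,
                                                             1 / length(alphabet))),
                     session_correlation = 0)
  })
  r <- simulate_ratings(cases, blind, n_sessions = 1, systems = "AO",
                        seed = 14)
  est <- interobserver_kappa(r, "T1", "AO")
  expect_lt(abs(est$kappa), 3 * est$se)
})

test_that("halving the error at the last session raises late-pair agreement", {
  alphabet <- study_alphabets()$Fernandez
  truth <- rep(alphabet, each = 100)
  cases <- fixed_truth_cases(truth)
  learner <- observer_profile("learner",
                              confusion = list(Fernandez = uniform_confusion(alphabet, 0.65)),
                              session_correlation = 0,
                              session_multiplier = c(1, 1, 0.4))
  r <- simulate_ratings(cases, list(learner), n_sessions = 3,
                        systems = "Fernandez", seed = 21)
  dr <- session_drift(r, "learner", "Fernandez")
  expect_gt(dr[["T2 vs T3"]]$kappa, dr[["T1 vs T2"]]$kappa)

  # without a learning effect (and no session anchoring) the two pairwise
  # kappas agree within Monte-Carlo tolerance
  steady <- observer_profile("steady",
                             confusion = list(Fernandez = uniform_confusion(alphabet, 0.65)),
                             session_correlation = 0)
  r0 <- simulate_ratings(cases, list(steady), n_sessions = 3,
                         systems = "Fernandez", seed = 22)
  dr0 <- session_drift(r0, "steady", "Fernandez")
  tol <- 3 * sqrt(dr0[["T1 vs T2"]]$se^2 + dr0[["T2 vs T3"]]$se^2)
  expect_lt(abs(dr0[["T1 vs T2"]]$kappa - dr0[["T2 vs T3"]]$kappa), tol)
})

test_that("profile and config validation reject malformed inputs", {
  expect_error(observer_profile("x", session_correlation = 1.5), "\\[0, 1\\]")
  bad_cm <- matrix(0.5, 3, 3)
  expect_error(observer_profile("x",
                                confusion = list(Fernandez = bad_cm)),
               "must be 5 x 5")
  expect_error(case_config(n_cases = 0), "positive integer")
  expect_error(case_config(p_high_energy = 1.4), "\\[0, 1\\]")
  expect_error(case_config(label_probs = list(Fernandez = c(0.5, 0.5))),
               "probability vector")
  cm5 <- uniform_confusion(study_alphabets()$Fernandez, 0.8)
  cm5[1, 1] <- 0.9  # rows no longer sum to 1
  expect_error(observer_profile("x", confusion = list(Fernandez = cm5)),
               "sum to 1")
})
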