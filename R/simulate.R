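#' Derive a deterministic substream seed
#'
#' Hashes a base seed together with string/numeric labels into a
#' reproducible seed in `[0, 2^31 - 2]`. The simulator gives each random
#' stream (case generation, each observer-by-system rating stream, each
#' presentation order) its own substream so that, for example, adding an
#' observer never perturbs the generated cases.
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# truncated-at-zero additive Gaussian perturbation
.perturb <- function(x, sd) {
  if (sd <= 0) return(x)
  pmax(0, x + stats::rnorm(length(x), 0, sd))
}

#' Uniform-error confusion matrix
#'
#' Row-stochastic confusion matrix placing probability `accuracy` on the
#' true label and spreading the remaining mass uniformly over the other
#' labels — the simplest observer-error model, chosen because agreement
#' probabilities under it have closed forms (see
#' [analytic_cohen_kappa()]).
#'
#' @param labels Character vector: the system's label alphabet.
#' @param accuracy Probability of reporting the true label, in `[0, 1]`.
#' @return A `length(labels)` square matrix with dimnames `labels`.
#' @examples
#' uniform_confusion(c("I", "II", "III"), accuracy = 0.9)
#' @export
uniform_confusion <- function(labels, accuracy) {
  k <- length(labels)
  stopifnot(k >= 2, accuracy >= 0, accuracy <= 1)
  m <- matrix((1 - accuracy) / (k - 1), k, k,
              dimnames = list(labels, labels))
  diag(m) <- accuracy
  m
}

.check_confusion <- function(m, system, labels) {
  if (!is.matrix(m) || nrow(m) != length(labels) || ncol(m) != length(labels)) {
    stop(sprintf("confusion matrix for %s must be %d x %d", system,
                 length(labels), length(labels)), call. = FALSE)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
    stop(sprintf("confusion rows for %s must be non-negative and sum to 1",
                 system), call. = FALSE)
  }
  invisible(TRUE)
}

# shrink (gamma < 1) or inflate (gamma > 1) off-diagonal error mass
.scale_confusion <- function(m, gamma) {
  if (gamma == 1) return(m)
  out <- diag(nrow(m)) + gamma * (m - diag(nrow(m)))
  out[out < 0] <- 0
  sweep(out, 1, rowSums(out), "/")
}

#' Observer error profile for the rating simulator
#'
#' Describes one synthetic observer: Gaussian measurement noise on each
#' continuous radiographic finding (IDEAL ratings are produced by
#' perturbing the true measurements and re-scoring), flip probabilities for
#' the binary epidemiological items, a row-stochastic confusion matrix per
#' categorical system (Frykman, Fernandez, AO), a within-observer session
#' correlation, and optional per-session error multipliers to model a
#' learning effect.
#'
#' The session correlation `rho` is implemented as: at sessions after the
#' first, with probability `rho` the observer reuses their session-1 latent
#' perception of the case (hence repeats the session-1 label), otherwise
#' they perceive the case afresh. `rho = 1` forces identical labels across
#' sessions; `rho = 0` makes sessions conditionally independent given the
#' truth.
#'
#' @param observer_id Observer identifier string.
#' @param noise_sd Named numeric vector with entries `step`, `shortening`
#'   (mm) and `tilt`, `inclination` (degrees): measurement noise standard
#'   deviations.
#' @param flip_prob Named numeric vector with entries `energy`, `lesions`:
#'   probabilities of misreading each binary item.
#' @param accuracy Convenience shortcut: probability of the true label for
#'   every categorical system, expanded into [uniform_confusion()]
#'   matrices. Ignored when `confusion` is given.
#' @param confusion Named list of confusion matrices keyed by system name;
#'   rows/columns ordered as in `alphabets`.
#' @param session_correlation Within-observer correlation `rho` in `[0, 1]`.
#' @param session_multiplier Numeric vector of per-session error
#'   multipliers (recycled to the number of sessions at simulation time);
#'   values below 1 shrink the error at that session (learning), above 1
#'   inflate it.
#' @param alphabets System alphabets (default [study_alphabets()]); the
#'   categorical systems are all entries except IDEAL.
#' @return An object of class `observer_profile`.
#' @examples
#' observer_profile("specialist", accuracy = 0.92)
#' @export
observer_profile <- function(observer_id,
                             noise_sd = c(step = 0.5, shortening = 0.8,
                                          tilt = 3.5, inclination = 2.0),
                             flip_prob = c(energy = 0.04, lesions = 0.04),
                             accuracy = 0.85,
                             confusion = NULL,
                             session_correlation = 0.3,
                             session_multiplier = 1,
                             alphabets = study_alphabets()) {
  stopifnot(is.character(observer_id), length(observer_id) == 1L)
  for (nm in c("step", "shortening", "tilt", "inclination")) {
    if (is.na(noise_sd[nm]) || noise_sd[nm] < 0) {
      stop(sprintf("noise_sd['%s'] must be a non-negative number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("energy", "lesions")) {
    if (is.na(flip_prob[nm]) || flip_prob[nm] < 0 || flip_prob[nm] > 1) {
      stop(sprintf("flip_prob['%s'] must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (session_correlation < 0 || session_correlation > 1) {
    stop("'session_correlation' must lie in [0, 1]", call. = FALSE)
  }
  if (any(session_multiplier < 0)) {
    stop("'session_multiplier' values must be non-negative", call. = FALSE)
  }
  categorical <- setdiff(names(alphabets), "IDEAL")
  if (is.null(confusion)) {
    confusion <- lapply(alphabets[categorical], uniform_confusion,
                        accuracy = accuracy)
  }
  for (s in names(confusion)) .check_confusion(confusion[[s]], s,
                                               alphabets[[s]])
  structure(
    list(observer_id = observer_id, noise_sd = noise_sd,
         flip_prob = flip_prob, confusion = confusion,
         session_correlation = session_correlation,
         session_multiplier = session_multiplier, alphabets = alphabets),
    class = "observer_profile"
  )
}

#' Default six-observer panel
#'
#' A panel of six synthetic observers with heterogeneous skill, emulating a
#' reading panel that spans a senior hand-surgery specialist, a general
#' orthopedic surgeon, two residents and two medical students: measurement
#' noise and confusion error grow, in that order, from the specialist to
#' the students.
#'
#' @param session_correlation Session correlation shared by all observers
#'   (default 0.3).
#' @param session_multiplier Per-session error multipliers shared by all
#'   observers (default 1: no learning effect).
#' @return List of six [observer_profile()] objects.
#' @export
default_observer_panel <- function(session_correlation = 0.3,
                                   session_multiplier = 1) {
  spec <- list(
    hand_specialist = list(c(0.30, 0.50, 2.0, 1.2), 0.02, 0.92),
    hand_resident = list(c(0.40, 0.70, 3.0, 1.6), 0.03, 0.88),
    general_orthopedist = list(c(0.50, 0.80, 3.5, 2.0), 0.04, 0.85),
    orthopedics_resident = list(c(0.60, 1.00, 4.0, 2.5), 0.05, 0.82),
    medical_student_1 = list(c(1.00, 1.60, 6.0, 4.0), 0.10, 0.68),
    medical_student_2 = list(c(0.90, 1.40, 5.5, 3.5), 0.08, 0.72)
  )
  lapply(names(spec), function(id) {
    p <- spec[[id]]
    observer_profile(
      id,
      noise_sd = stats::setNames(p[[1]],
                                 c("step", "shortening", "tilt",
                                   "inclination")),
      flip_prob = c(energy = p[[2]], lesions = p[[2]]),
      accuracy = p[[3]],
      session_correlation = session_correlation,
      session_multiplier = session_multiplier
    )
  })
}

#' Configuration for the synthetic fracture-case generator
#'
#' Parameters of the simulated case mix: number of cases, the age
#' distribution (truncated normal, adults only), the proportions of
#' high-energy trauma and associated lesions, and a two-component mixture
#' for the displacement measurements (an essentially undisplaced component
#' and a displaced component), with a separate probability of articular
#' involvement in each component. True labels for the categorical systems
#' are drawn from `label_probs` (uniform by default), since those systems'
#' internal morphological logic is out of scope.
#'
#' @param n_cases Number of cases (default 60, the size of a typical
#'   reproducibility-study radiograph sample).
#' @param seed Integer seed; case generation is deterministic given it.
#' @param age_mean,age_sd,age_min Age distribution (years): truncated
#'   normal with lower bound `age_min`.
#' @param p_high_energy Probability of a high-energy mechanism.
#' @param p_lesions Probability of associated lesions.
#' @param p_displaced Mixture weight of the displaced component.
#' @param p_articular Probability of articular involvement (a step/gap)
#'   given each component, named vector `c(displaced =, undisplaced =)`.
#' @param displaced,undisplaced Named lists giving `mean` and `sd` vectors
#'   (entries `step`, `shortening`, `tilt`, `inclination`) for the two
#'   mixture components; draws are truncated at zero.
#' @param label_probs Named list of category probability vectors for the
#'   non-IDEAL systems; defaults to uniform over each alphabet.
#' @param alphabets System alphabets (default [study_alphabets()]).
#' @return An object of class `case_config`.
#' @export
case_config <- function(n_cases = 60, seed = 1,
                        age_mean = 62, age_sd = 18, age_min = 18,
                        p_high_energy = 0.25, p_lesions = 0.15,
                        p_displaced = 0.65,
                        p_articular = c(displaced = 0.5, undisplaced = 0.1),
                        displaced = list(
                          mean = c(step = 3.0, shortening = 5.0, tilt = 15.0,
                                   inclination = 8.0),
                          sd = c(step = 1.2, shortening = 2.0, tilt = 6.0,
                                 inclination = 3.5)),
                        undisplaced = list(
                          mean = c(step = 0.4, shortening = 1.0, tilt = 3.0,
                                   inclination = 1.5),
                          sd = c(step = 0.5, shortening = 0.8, tilt = 2.5,
                                 inclination = 1.2)),
                        label_probs = NULL,
                        alphabets = study_alphabets()) {
  if (!is.numeric(n_cases) || n_cases < 1 || n_cases != round(n_cases)) {
    stop("'n_cases' must be a positive integer", call. = FALSE)
  }
  for (p in c(p_high_energy, p_lesions, p_displaced, p_articular)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  categorical <- setdiff(names(alphabets), "IDEAL")
  if (is.null(label_probs)) {
    label_probs <- lapply(alphabets[categorical],
                          function(a) rep(1 / length(a), length(a)))
  }
  for (s in names(label_probs)) {
    pr <- label_probs[[s]]
    if (length(pr) != length(alphabets[[s]]) || any(pr < 0) ||
        abs(sum(pr) - 1) > 1e-8) {
      stop(sprintf("label_probs for %s must be a probability vector over %d categories",
                   s, length(alphabets[[s]])), call. = FALSE)
    }
  }
  structure(
    list(n_cases = as.integer(n_cases), seed = seed, age_mean = age_mean,
         age_sd = age_sd, age_min = age_min, p_high_energy = p_high_energy,
         p_lesions = p_lesions, p_displaced = p_displaced,
         p_articular = p_articular, displaced = displaced,
         undisplaced = undisplaced, label_probs = label_probs,
         alphabets = alphabets),
    class = "case_config"
  )
}

#' Generate synthetic fracture cases with known truth
#'
#' Draws a case table from a [case_config()]: continuous radiographic
#' findings from the displacement mixture (truncated at zero),
#' epidemiological context, the true IDEAL label derived by actually
#' scoring the true findings with [ideal_classify()], and true labels for
#' the categorical systems sampled from the configured category
#' distributions. Deterministic given `config$seed`.
#'
#' @param config A [case_config()].
#' @return A data frame (one row per case) with the standard case columns
#'   (`case_id`, measurements, `age_years`, `energy`, `lesions_present`)
#'   plus `true_IDEAL`, `true_Frykman`, `true_Fernandez`, `true_AO` and the
#'   IDEAL component scores; the config is attached as attribute `config`.
#' @examples
#' cases <- generate_cases(case_config(n_cases = 10, seed = 42))
#' table(cases$true_IDEAL)
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "case_config"))
  n <- config$n_cases
  cases <- with_seed(substream_seed(config$seed, "cases"), {
    age <- round(pmax(config$age_min,
                      stats::rnorm(n, config$age_mean, config$age_sd)))
    energy <- ifelse(stats::runif(n) < config$p_high_energy, "high", "low")
    lesions <- stats::runif(n) < config$p_lesions
    disp <- stats::runif(n) < config$p_displaced
    comp <- function(displaced, item) {
      src <- if (displaced) config$displaced else config$undisplaced
      pmax(0, stats::rnorm(1, src$mean[item], src$sd[item]))
    }
    art <- stats::runif(n) < ifelse(disp, config$p_articular["displaced"],
                                    config$p_articular["undisplaced"])
    step <- vapply(seq_len(n), function(i) {
      if (art[i]) comp(disp[i], "step") else 0
    }, 1)
    shortening <- vapply(seq_len(n), function(i) comp(disp[i], "shortening"), 1)
    tilt <- vapply(seq_len(n), function(i) comp(disp[i], "tilt"), 1)
    incl <- vapply(seq_len(n), function(i) comp(disp[i], "inclination"), 1)
    data.frame(
      case_id = sprintf("case%03d", seq_len(n)),
      articular_step_mm = step, radial_shortening_mm = shortening,
      volar_tilt_loss_deg = tilt, radial_inclination_loss_deg = incl,
      age_years = age, energy = energy, lesions_present = lesions,
      stringsAsFactors = FALSE
    )
  })
  scored <- score_cases(cases)
  cases$true_IDEAL <- scored$fracture_type
  for (s in names(config$label_probs)) {
    cases[[paste0("true_", s)]] <- with_seed(
      substream_seed(config$seed, "truth", s),
      sample(config$alphabets[[s]], n, replace = TRUE,
             prob = config$label_probs[[s]])
    )
  }
  cases[c("score_I", "score_D", "score_E", "score_A", "score_L", "total")] <-
    scored[c("score_I", "score_D", "score_E", "score_A", "score_L", "total")]
  attr(cases, "config") <- config
  cases
}

# one observer's labels for one system across sessions -> n_cases x n_sessions
.simulate_observer_system <- function(cases, profile, system, n_sessions,
                                      seed) {
  n <- nrow(cases)
  rho <- profile$session_correlation
  gamma <- rep_len(profile$session_multiplier, n_sessions)
  labels <- matrix(NA_character_, n, n_sessions)

  with_seed(substream_seed(seed, "rate", profile$observer_id, system), {
    if (system == "IDEAL") {
      perceive <- function(g) {
        sd <- profile$noise_sd * g
        fp <- pmin(profile$flip_prob * g, 1)
        df <- data.frame(
          articular_step_mm = .perturb(cases$articular_step_mm, sd["step"]),
          radial_shortening_mm = .perturb(cases$radial_shortening_mm,
                                          sd["shortening"]),
          volar_tilt_loss_deg = .perturb(cases$volar_tilt_loss_deg,
                                         sd["tilt"]),
          radial_inclination_loss_deg = .perturb(
            cases$radial_inclination_loss_deg, sd["inclination"]),
          age_years = cases$age_years,
          energy = ifelse(stats::runif(n) < fp["energy"],
                          ifelse(cases$energy == "high", "low", "high"),
                          cases$energy),
          lesions_present = ifelse(stats::runif(n) < fp["lesions"],
                                   !cases$lesions_present,
                                   cases$lesions_present),
          stringsAsFactors = FALSE
        )
        score_cases(df)$fracture_type
      }
      labels[, 1] <- perceive(gamma[1])
      for (s in seq_len(n_sessions)[-1]) {
        reuse <- stats::runif(n) < rho
        fresh <- perceive(gamma[s])
        labels[, s] <- ifelse(reuse, labels[, 1], fresh)
      }
    } else {
      alphabet <- profile$alphabets[[system]]
      truth <- cases[[paste0("true_", system)]]
      if (is.null(truth)) {
        stop(sprintf("cases carry no true labels for system '%s'", system),
             call. = FALSE)
      }
      if (!all(truth %in% alphabet)) {
        stop(sprintf("true labels outside the %s alphabet of the profile",
                     system), call. = FALSE)
      }
      draw <- function(g) {
        cm <- .scale_confusion(profile$confusion[[system]], g)
        out <- character(n)
        for (t in unique(truth)) {
          idx <- which(truth == t)
          out[idx] <- sample(alphabet, length(idx), replace = TRUE,
                             prob = cm[match(t, alphabet), ])
        }
        out
      }
      labels[, 1] <- draw(gamma[1])
      for (s in seq_len(n_sessions)[-1]) {
        reuse <- stats::runif(n) < rho
        fresh <- draw(gamma[s])
        labels[, s] <- ifelse(reuse, labels[, 1], fresh)
      }
    }
  })
  labels
}

#' Simulate a complete multi-observer rating table
#'
#' Produces one label per (case, observer, session, system): IDEAL labels
#' by perturbing the true continuous findings with each observer's
#' measurement noise (and flipping binary items with their flip
#' probabilities) and re-scoring; categorical-system labels through each
#' observer's confusion matrix. Within-observer session correlation and
#' per-session error multipliers are applied as described in
#' [observer_profile()]. The result is deterministic given `seed`, and each
#' (observer, system) pair has its own random substream.
#'
#' @param cases Case table from [generate_cases()].
#' @param profiles List of [observer_profile()] objects.
#' @param n_sessions Number of rating sessions (default 3).
#' @param systems Character vector of systems to rate (default: IDEAL plus
#'   every system with a `true_*` column and a confusion matrix).
#' @param seed Integer seed.
#' @return A `rating_table` with `nrow(cases) * length(profiles) *
#'   n_sessions * length(systems)` rows.
#' @examples
#' cases <- generate_cases(case_config(n_cases = 8, seed = 7))
#' panel <- default_observer_panel()[1:2]
#' ratings <- simulate_ratings(cases, panel, n_sessions = 2, seed = 7)
#' nrow(ratings)
#' @export
simulate_ratings <- function(cases, profiles, n_sessions = 3,
                             systems = NULL, seed = 1) {
  stopifnot(length(profiles) >= 1, n_sessions >= 1)
  if (inherits(profiles, "observer_profile")) profiles <- list(profiles)
  if (is.null(systems)) {
    truth_cols <- sub("^true_", "", grep("^true_", names(cases), value = TRUE))
    systems <- intersect(names(study_alphabets()), truth_cols)
  }
  sessions <- paste0("T", seq_len(n_sessions))
  out <- list()
  alphabets <- profiles[[1]]$alphabets
  for (profile in profiles) {
    stopifnot(inherits(profile, "observer_profile"))
    for (system in systems) {
      lab <- .simulate_observer_system(cases, profile, system, n_sessions,
                                       seed)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = rep(cases$case_id, times = n_sessions),
        observer_id = profile$observer_id,
        session = rep(sessions, each = nrow(cases)),
        system = system,
        label = as.vector(lab),
        stringsAsFactors = FALSE
      )
    }
  }
  rating_table(do.call(rbind, out), alphabets = alphabets)
}

#' Blinded randomized presentation order
#'
#' Independent random permutation of the case indices for every
#' (observer, session) pair, emulating the blinded randomized reading order
#' of a reproducibility study. Deterministic given the seed; each
#' (observer, session) pair has its own substream.
#'
#' @param n_cases Number of cases, at least 1.
#' @param observers Character vector of observer identifiers.
#' @param n_sessions Number of sessions.
#' @param seed Integer seed.
#' @return Long data frame with columns `observer_id`, `session`,
#'   `position` (1..n_cases) and `case` (the case index shown at that
#'   position); within each (observer, session) the `case` column is a
#'   permutation of `1:n_cases`.
#' @export
randomize_presentation <- function(n_cases, observers = "observer1",
                                   n_sessions = 1, seed = 1) {
  stopifnot(n_cases >= 1, n_sessions >= 1, length(observers) >= 1)
  sessions <- paste0("T", seq_len(n_sessions))
  rows <- list()
  for (obs in observers) {
    for (s in sessions) {
      perm <- with_seed(substream_seed(seed, "order", obs, s),
                        sample.int(n_cases))
      rows[[length(rows) + 1L]] <- data.frame(
        observer_id = obs, session = s, position = seq_len(n_cases),
        case = perm, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Analytic Cohen kappa for two confusion-matrix observers
#'
#' Closed-form population kappa between two observers who label cases drawn
#' from a known true-label distribution through known confusion matrices:
#' observed agreement `p_o = sum_t pi_t sum_l A[t,l] B[t,l]`, chance
#' agreement from the product of the observers' marginal label
#' distributions. Estimated Cohen kappas on simulated data converge to this
#' value as the number of cases grows.
#'
#' @param truth_probs Probability vector over the true labels.
#' @param conf_a,conf_b Row-stochastic confusion matrices (rows: true
#'   label, columns: reported label); `conf_b` defaults to `conf_a`.
#' @return The population kappa (numeric scalar).
#' @export
analytic_cohen_kappa <- function(truth_probs, conf_a, conf_b = conf_a) {
  stopifnot(abs(sum(truth_probs) - 1) < 1e-8,
            nrow(conf_a) == length(truth_probs),
            nrow(conf_b) == length(truth_probs))
  po <- sum(truth_probs * rowSums(conf_a * conf_b))
  marg_a <- drop(truth_probs %*% conf_a)
  marg_b <- drop(truth_probs %*% conf_b)
  pe <- sum(marg_a * marg_b)
  (po - pe) / (1 - pe)
}

#' Analytic Fleiss kappa for a panel of confusion-matrix observers
#'
#' Population value of the multi-rater Fleiss kappa for a panel of
#' observers with known confusion matrices rating cases from a known
#' true-label distribution: expected agreement is the average pairwise
#' agreement probability over observer pairs, chance agreement the sum of
#' squared pooled marginal label shares.
#'
#' @param truth_probs Probability vector over the true labels.
#' @param confusions List of row-stochastic confusion matrices, one per
#'   observer (at least 2).
#' @return The population kappa (numeric scalar).
#' @export
analytic_fleiss_kappa <- function(truth_probs, confusions) {
  stopifnot(length(confusions) >= 2)
  m <- length(confusions)
  pairs <- utils::combn(m, 2)
  po <- mean(vapply(seq_len(ncol(pairs)), function(j) {
    sum(truth_probs * rowSums(confusions[[pairs[1, j]]] *
                                confusions[[pairs[2, j]]]))
  }, 1))
  margs <- vapply(confusions, function(cm) drop(truth_probs %*% cm),
                  numeric(ncol(confusions[[1]])))
  p_bar <- rowMeans(margs)
  pe <- sum(p_bar^2)
  (po - pe) / (1 - pe)
}

#' Analytic intraobserver kappa under session correlation
#'
#' Population value of the sessions-as-raters Fleiss kappa for one
#' confusion-matrix observer with session correlation `rho` (reuse of the
#' session-1 perception with probability `rho` at later sessions).
#' Conditional on truth `t`, a later session agrees with session 1 with
#' probability `rho + (1 - rho) S_t` and two later sessions agree with
#' probability `rho^2 + (1 - rho^2) S_t`, where `S_t` is the sum of squared
#' confusion-row entries; chance agreement uses the (session-invariant)
#' marginal label distribution.
#'
#' @param truth_probs Probability vector over the true labels.
#' @param confusion Row-stochastic confusion matrix.
#' @param rho Session correlation in `[0, 1]`.
#' @param n_sessions Number of sessions (default 3).
#' @return The population kappa (numeric scalar).
#' @export
analytic_intraobserver_kappa <- function(truth_probs, confusion, rho,
                                         n_sessions = 3) {
  stopifnot(n_sessions >= 2, rho >= 0, rho <= 1)
  S_t <- rowSums(confusion^2)
  S_bar <- sum(truth_probs * S_t)
  pairs <- utils::combn(n_sessions, 2)
  po <- mean(vapply(seq_len(ncol(pairs)), function(j) {
    if (pairs[1, j] == 1) rho + (1 - rho) * S_bar
    else rho^2 + (1 - rho^2) * S_bar
  }, 1))
  marg <- drop(truth_probs %*% confusion)
  pe <- sum(marg^2)
  (po - pe) / (1 - pe)
}
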