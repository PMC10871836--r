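#' Run a full classification-reproducibility analysis
#'
#' The package's central fitting function: from a long-format
#' [rating_table()] it computes, for every classification system present,
#' the per-observer intraobserver Fleiss kappas (sessions as replicate
#' raters) with two aggregations (arithmetic mean of the per-observer
#' kappas, and a pooled Fleiss kappa over all observers' subject-by-session
#' panels), the per-session interobserver Fleiss kappas with their
#' arithmetic mean over sessions, the mean pairwise Cohen kappa among
#' observers at each session, consecutive-session drift kappas per observer
#' (the learning-effect check), and one-way F comparisons of the
#' intraobserver and interobserver kappa sets across systems. Every kappa
#' carries its interpretation band (unsatisfactory below 0.5, satisfactory
#' from 0.5 to 0.75, excellent above 0.75).
#'
#' Cells with insufficient data (too few complete subjects, a single
#' session, ...) are reported as `NA` and listed in
#' `metadata$skipped`, never as silent zeros.
#'
#' @param ratings A `rating_table` (or data frame / CSV path coercible to
#'   one).
#' @param systems Systems to analyse; default: all systems present, in
#'   [study_alphabets()] order.
#' @param conf Confidence level for all kappa intervals (default 0.95).
#' @param permutations Permutations for the comparison tests' optional
#'   permutation p-value (default 0: parametric only).
#' @param seed Optional seed for the permutation test.
#' @return An object of class `agreement_study` with components
#'   `intraobserver`, `interobserver`, `pairwise`, `drift`, `comparisons`,
#'   `conf` and `metadata`; see [summary.agreement_study()].
#' @seealso [write_study_tables()], [write_study_json()]
#' @examples
#' cases <- generate_cases(case_config(n_cases = 20, seed = 3))
#' panel <- default_observer_panel()[c(1, 3, 5)]
#' ratings <- simulate_ratings(cases, panel, n_sessions = 3, seed = 3)
#' fit <- agreement_study(ratings)
#' fit
#' @export
agreement_study <- function(ratings, systems = NULL, conf = 0.95,
                            permutations = 0, seed = NULL) {
  if (!inherits(ratings, "rating_table")) ratings <- rating_table(ratings)
  all_systems <- unique(ratings$system)
  canon <- names(study_alphabets())
  all_systems <- c(intersect(canon, all_systems),
                   setdiff(all_systems, canon))
  if (is.null(systems)) systems <- all_systems
  observers <- sort(unique(ratings$observer_id))
  sessions <- sort(unique(ratings$session))
  if (length(observers) < 2) stop("need at least 2 observers", call. = FALSE)
  if (length(sessions) < 2) stop("need at least 2 sessions", call. = FALSE)

  skipped <- character()
  try_est <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      skipped <<- c(skipped, sprintf("%s: %s", label, conditionMessage(e)))
      NULL
    })
  }

  # ---- intraobserver (per observer, sessions as raters) ----
  intra_est <- list()
  intra_kappa <- matrix(NA_real_, length(observers), length(systems),
                        dimnames = list(observers, systems))
  for (s in systems) {
    intra_est[[s]] <- list()
    for (o in observers) {
      est <- try_est(sprintf("intraobserver %s/%s", o, s),
                     intraobserver_kappa(ratings, o, s, conf = conf))
      intra_est[[s]][[o]] <- est
      if (!is.null(est)) intra_kappa[o, s] <- est$kappa
    }
  }
  intra_mean <- colMeans(intra_kappa, na.rm = TRUE)
  intra_pooled <- vapply(systems, function(s) {
    counts <- NULL
    for (o in observers) {
      d <- ratings[ratings$observer_id == o & ratings$system == s, ,
                   drop = FALSE]
      if (!nrow(d)) next
      wide <- suppressWarnings(.label_matrix(d, "session", ""))
      if (nrow(wide) && ncol(wide) >= 2) {
        counts <- rbind(counts,
                        .counts_from_labels(wide, .tbl_alphabet(ratings, s)))
      }
    }
    if (is.null(counts) || nrow(counts) < 2) return(NA_real_)
    fleiss_kappa(counts, conf = conf)$kappa
  }, 1)

  # ---- interobserver (per session, observers as raters) ----
  inter_est <- list()
  inter_kappa <- matrix(NA_real_, length(sessions), length(systems),
                        dimnames = list(sessions, systems))
  pairwise <- matrix(NA_real_, length(sessions), length(systems),
                     dimnames = list(sessions, systems))
  for (s in systems) {
    inter_est[[s]] <- list()
    for (tt in sessions) {
      est <- try_est(sprintf("interobserver %s/%s", tt, s),
                     interobserver_kappa(ratings, tt, s, conf = conf))
      inter_est[[s]][[tt]] <- est
      if (!is.null(est)) inter_kappa[tt, s] <- est$kappa
      pw <- try_est(sprintf("pairwise %s/%s", tt, s),
                    pairwise_mean_kappa(ratings, tt, s, conf = conf))
      if (!is.null(pw)) pairwise[tt, s] <- pw$mean_kappa
    }
  }
  inter_mean <- colMeans(inter_kappa, na.rm = TRUE)

  # ---- session drift per (observer, system) ----
  drift_rows <- list()
  for (s in systems) {
    for (o in observers) {
      dr <- try_est(sprintf("drift %s/%s", o, s),
                    session_drift(ratings, o, s, conf = conf))
      if (is.null(dr)) next
      for (nm in names(dr)) {
        drift_rows[[length(drift_rows) + 1L]] <- data.frame(
          observer_id = o, system = s, pair = nm, kappa = dr[[nm]]$kappa,
          stringsAsFactors = FALSE)
      }
    }
  }
  drift <- if (length(drift_rows)) do.call(rbind, drift_rows) else
    data.frame(observer_id = character(), system = character(),
               pair = character(), kappa = numeric())

  # ---- cross-system comparisons ----
  comparisons <- list()
  if (length(systems) >= 2) {
    intra_groups <- lapply(systems,
                           function(s) intra_kappa[, s][!is.na(intra_kappa[, s])])
    names(intra_groups) <- systems
    if (all(vapply(intra_groups, length, 1L) >= 2)) {
      comparisons$intraobserver <- compare_kappa_sets(intra_groups,
                                                      permutations, seed)
    } else skipped <- c(skipped, "comparison intraobserver: too few observers")
    inter_groups <- lapply(systems,
                           function(s) inter_kappa[, s][!is.na(inter_kappa[, s])])
    names(inter_groups) <- systems
    if (all(vapply(inter_groups, length, 1L) >= 2)) {
      comparisons$interobserver <- compare_kappa_sets(inter_groups,
                                                      permutations, seed)
    } else skipped <- c(skipped, "comparison interobserver: too few sessions")
  }

  structure(
    list(
      intraobserver = list(estimates = intra_est, kappa = intra_kappa,
                           mean = intra_mean, pooled = intra_pooled),
      interobserver = list(estimates = inter_est, kappa = inter_kappa,
                           mean = inter_mean),
      pairwise = pairwise,
      drift = drift,
      comparisons = comparisons,
      conf = conf,
      metadata = list(
        systems = systems, observers = observers, sessions = sessions,
        n_subjects = length(unique(ratings$subject_id)),
        n_observers = length(observers), n_sessions = length(sessions),
        n_records = nrow(ratings), skipped = skipped,
        issues = attr(ratings, "issues"))
    ),
    class = "agreement_study"
  )
}

.round3 <- function(x) round(x, 3)  # 3 decimals, half-even (base round)

#' @export
print.agreement_study <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Agreement study: %d subjects, %d observers, %d sessions, %d records\n",
              md$n_subjects, md$n_observers, md$n_sessions, md$n_records))
  band <- function(k) if (is.na(k)) "no data" else interpret_kappa(k)
  for (s in md$systems) {
    cat(sprintf("  %-10s intraobserver mean %.3f (%s), interobserver mean %.3f (%s)\n",
                s, x$intraobserver$mean[s], band(x$intraobserver$mean[s]),
                x$interobserver$mean[s], band(x$interobserver$mean[s])))
  }
  if (length(md$skipped)) {
    cat(sprintf("  (%d analyses skipped for insufficient data)\n",
                length(md$skipped)))
  }
  invisible(x)
}

#' Summarise an agreement study
#'
#' Prints the intraobserver table (per observer by system, with the mean
#' and pooled aggregations), the interobserver table (per session by
#' system with the mean over sessions and the mean pairwise Cohen kappa),
#' and the cross-system comparisons. All kappas rounded to 3 decimals,
#' half-even.
#'
#' @param object An `agreement_study`.
#' @param ... Unused.
#' @export
summary.agreement_study <- function(object, ...) {
  x <- object
  cat("Intraobserver reproducibility (sessions as replicate raters)\n")
  tab3 <- rbind(.round3(x$intraobserver$kappa),
                Mean = .round3(x$intraobserver$mean),
                Pooled = .round3(x$intraobserver$pooled))
  print(tab3)
  cat("\nInterobserver reproducibility (observers as raters, per session)\n")
  tab4 <- rbind(.round3(x$interobserver$kappa),
                Mean = .round3(x$interobserver$mean))
  print(tab4)
  cat("\nMean pairwise Cohen kappa among observers\n")
  print(.round3(x$pairwise))
  for (nm in names(x$comparisons)) {
    cat(sprintf("\nComparison across systems (%s)\n", nm))
    print(x$comparisons[[nm]])
  }
  invisible(x)
}

#' Extract the headline kappas of an agreement study
#'
#' @param object An `agreement_study`.
#' @param ... Unused.
#' @return Matrix with rows `intraobserver` and `interobserver` and one
#'   column per system, holding the per-system mean kappas.
#' @export
coef.agreement_study <- function(object, ...) {
  rbind(intraobserver = object$intraobserver$mean,
        interobserver = object$interobserver$mean)
}

#' Plot interobserver agreement by session
#'
#' Base-graphics dot chart of the per-session interobserver kappas of every
#' system, with the 0.5 and 0.75 interpretation boundaries drawn as
#' horizontal reference lines.
#'
#' @param x An `agreement_study`.
#' @param ... Passed on to [graphics::matplot()].
#' @export
plot.agreement_study <- function(x, ...) {
  k <- x$interobserver$kappa
  graphics::matplot(seq_len(nrow(k)), k, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "Session", ylab = "Fleiss kappa",
                    ylim = c(0, 1),
                    main = "Interobserver agreement by session", ...)
  graphics::axis(1, at = seq_len(nrow(k)), labels = rownames(k))
  graphics::abline(h = c(0.5, 0.75), lty = 3, col = "grey40")
  graphics::legend("bottomleft", legend = colnames(k), col = seq_len(ncol(k)),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}

#' Write the study's report tables as CSV
#'
#' Emits `table3.csv` (per-observer intraobserver kappas, plus the mean and
#' pooled aggregation rows), `table4.csv` (per-session interobserver kappas
#' plus their mean, and the mean pairwise Cohen kappa rows) and
#' `table5.csv` (overall and pairwise cross-system F comparisons) into a
#' directory. Values are rounded to 3 decimals (half-even); the JSON report
#' ([write_study_json()]) keeps full precision.
#'
#' @param study An `agreement_study`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study_tables <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p3 <- file.path(dir, "table3.csv")
  tab3 <- rbind(.round3(study$intraobserver$kappa),
                Mean = .round3(study$intraobserver$mean),
                Pooled = .round3(study$intraobserver$pooled))
  utils::write.csv(data.frame(unit = rownames(tab3), tab3,
                              check.names = FALSE, row.names = NULL), p3,
                   row.names = FALSE)
  p4 <- file.path(dir, "table4.csv")
  tab4 <- rbind(.round3(study$interobserver$kappa),
                Mean = .round3(study$interobserver$mean))
  pw <- .round3(study$pairwise)
  rownames(pw) <- paste0("pairwise_", rownames(pw))
  tab4 <- rbind(tab4, pw)
  utils::write.csv(data.frame(unit = rownames(tab4), tab4,
                              check.names = FALSE, row.names = NULL), p4,
                   row.names = FALSE)
  p5 <- file.path(dir, "table5.csv")
  rows <- list()
  for (nm in names(study$comparisons)) {
    cmp <- study$comparisons[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, systems = paste(cmp$groups, collapse = "+"),
      F = .round3(cmp$statistic), p_value = .round3(cmp$p_value),
      stringsAsFactors = FALSE)
    pwc <- cmp$pairwise
    for (i in seq_len(nrow(pwc))) {
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm,
        systems = paste(pwc$system_a[i], "vs", pwc$system_b[i]),
        F = .round3(pwc$F[i]), p_value = .round3(pwc$p_value[i]),
        stringsAsFactors = FALSE)
    }
  }
  tab5 <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), systems = character(), F = numeric(),
               p_value = numeric())
  utils::write.csv(tab5, p5, row.names = FALSE)
  invisible(c(p3, p4, p5))
}

#' Write the full-precision study report as JSON
#'
#' Machine-readable report: unrounded kappas, standard errors, confidence
#' intervals, interpretation bands, aggregations, drift kappas, comparisons
#' and metadata.
#'
#' @param study An `agreement_study`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_study_json <- function(study, path) {
  est_list <- function(e) {
    if (is.null(e)) return(NULL)
    e[c("kappa", "se", "ci_low", "ci_high", "conf", "p_o", "p_e",
        "n_subjects", "n_raters", "n_categories", "interpretation",
        "degenerate")]
  }
  rep <- list(
    intraobserver = list(
      estimates = lapply(study$intraobserver$estimates,
                         function(sys) lapply(sys, est_list)),
      mean = as.list(study$intraobserver$mean),
      pooled = as.list(study$intraobserver$pooled)),
    interobserver = list(
      estimates = lapply(study$interobserver$estimates,
                         function(sys) lapply(sys, est_list)),
      mean = as.list(study$interobserver$mean)),
    pairwise_mean = apply(study$pairwise, 2, as.list),
    drift = study$drift,
    comparisons = lapply(study$comparisons, function(cmp) {
      list(statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
           method = cmp$method, pairwise = cmp$pairwise,
           permutation_p = cmp$permutation_p)
    }),
    conf = study$conf,
    metadata = study$metadata[c("systems", "observers", "sessions",
                                "n_subjects", "n_observers", "n_sessions",
                                "n_records", "skipped")]
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
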