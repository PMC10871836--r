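#' Label alphabets of the four classification systems
#'
#' The study design covers four distal-radius-fracture classification
#' systems, modelled here purely as label alphabets: IDEAL (three fracture
#' types), Frykman (eight categories), Fernandez (five categories) and AO
#' (the nine main subgroups A1 to C3). The internal morphological logic of
#' the established systems is out of scope; only their label sets matter for
#' agreement statistics.
#'
#' @return Named list of character vectors, one per system.
#' @examples
#' study_alphabets()$AO
#' @export
study_alphabets <- function() {
  list(
    IDEAL = c("I", "II", "III"),
    Frykman = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
    Fernandez = c("1", "2", "3", "4", "5"),
    AO = c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3")
  )
}

#' Validate a long-format rating table
#'
#' Checks a raw rating table (or CSV path) against the required long format
#' `subject_id, observer_id, session, system, label`: required columns
#' present, labels inside each system's declared alphabet, and at most one
#' record per (subject, observer, session, system) key. Missing
#' (subject, observer, session) combinations within each system are
#' inventoried as warnings, not errors, since analyses drop incomplete
#' panels explicitly.
#'
#' @param x Data frame of ratings or path to a ratings CSV.
#' @param alphabets Named list of system label alphabets; defaults to
#'   [study_alphabets()]. Systems appearing in the data must be declared.
#' @return A list with `table` (the typed data frame, columns coerced to
#'   character) and `issues` (data frame with columns `severity`, `row`,
#'   `message`; zero rows when the file is clean apart from completeness
#'   warnings, which carry `severity = "warning"`).
#' @seealso [rating_table()] which applies this validation and stops on
#'   errors.
#' @export
validate_ratings <- function(x, alphabets = study_alphabets()) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.csv(x, stringsAsFactors = FALSE, colClasses = "character")
  }
  issues <- data.frame(severity = character(), row = integer(),
                       message = character(), stringsAsFactors = FALSE)
  add_issue <- function(severity, row, message) {
    rbind(issues, data.frame(severity = severity, row = row,
                             message = message, stringsAsFactors = FALSE))
  }
  needed <- c("subject_id", "observer_id", "session", "system", "label")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("rating table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- x[needed]
  for (nm in needed) df[[nm]] <- as.character(df[[nm]])
  if (anyNA(df) || any(df == "")) {
    bad <- which(apply(is.na(df) | df == "", 1, any))
    for (r in bad) {
      issues <- add_issue("error", r, sprintf("row %d: missing value", r))
    }
  }

  unknown_sys <- setdiff(unique(df$system), names(alphabets))
  if (length(unknown_sys)) {
    for (s in unknown_sys) {
      r <- which(df$system == s)[1]
      issues <- add_issue("error", r,
                          sprintf("row %d: undeclared system '%s'", r, s))
    }
  }
  for (s in intersect(unique(df$system), names(alphabets))) {
    bad <- which(df$system == s & !(df$label %in% alphabets[[s]]))
    for (r in bad) {
      issues <- add_issue("error", r,
                          sprintf("row %d: label '%s' not in %s alphabet",
                                  r, df$label[r], s))
    }
  }

  key <- paste(df$subject_id, df$observer_id, df$session, df$system,
               sep = "\r")
  dup <- which(duplicated(key))
  for (r in dup) {
    issues <- add_issue("error", r,
                        sprintf(paste0("row %d: duplicate record for ",
                                       "(subject %s, observer %s, session %s, ",
                                       "system %s)"),
                                r, df$subject_id[r], df$observer_id[r],
                                df$session[r], df$system[r]))
  }

  # completeness inventory: every (subject, observer, session) per system
  for (s in intersect(unique(df$system), names(alphabets))) {
    d <- df[df$system == s, ]
    full <- expand.grid(subject_id = unique(d$subject_id),
                        observer_id = unique(d$observer_id),
                        session = unique(d$session),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    have <- paste(d$subject_id, d$observer_id, d$session, sep = "\r")
    want <- paste(full$subject_id, full$observer_id, full$session, sep = "\r")
    n_missing <- sum(!(want %in% have))
    if (n_missing > 0) {
      issues <- add_issue("warning", NA_integer_,
                          sprintf("system %s: %d missing (subject, observer, session) combinations",
                                  s, n_missing))
    }
  }
  list(table = df, issues = issues)
}

#' Construct a validated rating table
#'
#' Applies [validate_ratings()] and stops with the collected messages if any
#' hard errors (duplicates, unknown labels or systems, missing values) are
#' present; completeness warnings are emitted as a single R warning and kept
#' as an attribute.
#'
#' @inheritParams validate_ratings
#' @return A data frame of class `rating_table` with attributes `alphabets`
#'   and `issues`.
#' @examples
#' df <- expand.grid(subject_id = c("s1", "s2", "s3"),
#'                   observer_id = c("o1", "o2"), session = c("T1", "T2"),
#'                   stringsAsFactors = FALSE)
#' df$system <- "IDEAL"; df$label <- "II"
#' rt <- rating_table(df)
#' @export
rating_table <- function(x, alphabets = study_alphabets()) {
  v <- validate_ratings(x, alphabets)
  errs <- v$issues[v$issues$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("invalid rating table:\n  ",
         paste(errs$message, collapse = "\n  "), call. = FALSE)
  }
  warns <- v$issues[v$issues$severity == "warning", , drop = FALSE]
  if (nrow(warns)) {
    warning(paste(warns$message, collapse = "; "), call. = FALSE)
  }
  structure(v$table, class = c("rating_table", "data.frame"),
            alphabets = alphabets, issues = v$issues)
}

#' Read a long-format rating CSV
#'
#' @param path Path to a CSV with header
#'   `subject_id,observer_id,session,system,label`.
#' @inheritParams validate_ratings
#' @return A `rating_table`.
#' @export
read_ratings <- function(path, alphabets = study_alphabets()) {
  rating_table(path, alphabets)
}

.tbl_alphabet <- function(table, system) {
  alph <- attr(table, "alphabets")
  if (is.null(alph) || is.null(alph[[system]])) {
    alph <- study_alphabets()
  }
  if (is.null(alph[[system]])) {
    stop(sprintf("no alphabet declared for system '%s'", system),
         call. = FALSE)
  }
  alph[[system]]
}

# Wide matrix subjects x units (sessions or observers) of labels for one
# system; drops subjects missing any unit, with a warning naming the count.
.label_matrix <- function(d, unit_col, context) {
  units <- sort(unique(d[[unit_col]]))
  subjects <- sort(unique(d$subject_id))
  wide <- matrix(NA_character_, length(subjects), length(units),
                 dimnames = list(subjects, units))
  wide[cbind(match(d$subject_id, subjects), match(d[[unit_col]], units))] <-
    d$label
  complete <- !apply(is.na(wide), 1, any)
  if (any(!complete)) {
    warning(sprintf("%s: dropped %d of %d subjects with incomplete ratings",
                    context, sum(!complete), length(subjects)), call. = FALSE)
  }
  wide[complete, , drop = FALSE]
}

.counts_from_labels <- function(wide, categories) {
  t(apply(wide, 1, function(r) tabulate(factor(r, levels = categories),
                                        nbins = length(categories))))
}

#' Intraobserver agreement across repeated sessions
#'
#' Agreement of one observer with themselves across the blinded repeated
#' reading sessions (T1, T2, T3, ...), treating the sessions as
#' interchangeable replicate raters and applying Fleiss's kappa. With
#' exactly two sessions this reduces to the two-replicate Fleiss kappa.
#' Subjects the observer did not rate in every session are dropped with a
#' warning.
#'
#' @param table A `rating_table`.
#' @param observer Observer identifier.
#' @param system Classification system name.
#' @param conf Confidence level (default 0.95).
#' @return A `kappa_estimate`.
#' @export
intraobserver_kappa <- function(table, observer, system, conf = 0.95) {
  d <- table[table$observer_id == observer & table$system == system, ,
             drop = FALSE]
  if (!nrow(d)) {
    stop(sprintf("no ratings for observer '%s', system '%s'", observer,
                 system), call. = FALSE)
  }
  wide <- .label_matrix(d, "session",
                        sprintf("intraobserver %s/%s", observer, system))
  if (nrow(wide) < 2) {
    stop("fewer than 2 subjects with complete session coverage",
         call. = FALSE)
  }
  if (ncol(wide) < 2) stop("need at least 2 sessions", call. = FALSE)
  counts <- .counts_from_labels(wide, .tbl_alphabet(table, system))
  est <- fleiss_kappa(counts, conf = conf)
  est$method <- sprintf("Intraobserver Fleiss kappa (%s, %s; %d sessions)",
                        observer, system, ncol(wide))
  est
}

#' Interobserver agreement at one session
#'
#' Fleiss's kappa across all observers who rated at the given session,
#' with observers as the replicate raters. Subjects lacking a rating from
#' any observer at that session are dropped with a warning.
#'
#' @inheritParams intraobserver_kappa
#' @param session Session identifier (e.g. `"T1"`).
#' @return A `kappa_estimate`.
#' @export
interobserver_kappa <- function(table, session, system, conf = 0.95) {
  d <- table[table$session == session & table$system == system, ,
             drop = FALSE]
  if (!nrow(d)) {
    stop(sprintf("no ratings for session '%s', system '%s'", session,
                 system), call. = FALSE)
  }
  wide <- .label_matrix(d, "observer_id",
                        sprintf("interobserver %s/%s", session, system))
  if (nrow(wide) < 2) {
    stop("fewer than 2 subjects with complete observer coverage",
         call. = FALSE)
  }
  if (ncol(wide) < 2) stop("need at least 2 observers", call. = FALSE)
  counts <- .counts_from_labels(wide, .tbl_alphabet(table, system))
  est <- fleiss_kappa(counts, conf = conf)
  est$method <- sprintf("Interobserver Fleiss kappa (%s, %s; %d observers)",
                        session, system, ncol(wide))
  est
}

#' Session-to-session drift of one observer
#'
#' Pairwise Cohen kappas between consecutive sessions of a single observer
#' (T1 vs T2, T2 vs T3, ...). Comparing the first pair with the last
#' reveals a conditioning/learning effect: if familiarity with the system
#' improves consistency, agreement between later sessions exceeds that
#' between earlier ones.
#'
#' @inheritParams intraobserver_kappa
#' @return A named list of `kappa_estimate` objects, one per consecutive
#'   session pair, named like `"T1 vs T2"`.
#' @export
session_drift <- function(table, observer, system, conf = 0.95) {
  d <- table[table$observer_id == observer & table$system == system, ,
             drop = FALSE]
  if (!nrow(d)) {
    stop(sprintf("no ratings for observer '%s', system '%s'", observer,
                 system), call. = FALSE)
  }
  wide <- .label_matrix(d, "session",
                        sprintf("session drift %s/%s", observer, system))
  if (nrow(wide) < 2) {
    stop("fewer than 2 subjects with complete session coverage",
         call. = FALSE)
  }
  sessions <- colnames(wide)
  if (length(sessions) < 2) stop("need at least 2 sessions", call. = FALSE)
  cats <- .tbl_alphabet(table, system)
  out <- list()
  for (i in seq_len(length(sessions) - 1)) {
    est <- cohen_kappa(wide[, i], wide[, i + 1], categories = cats,
                       conf = conf)
    est$method <- sprintf("Cohen kappa %s vs %s (%s, %s)", sessions[i],
                          sessions[i + 1], observer, system)
    out[[paste(sessions[i], "vs", sessions[i + 1])]] <- est
  }
  out
}

#' Mean pairwise Cohen kappa among observers at one session
#'
#' Unweighted arithmetic mean of the Cohen kappas over all observer pairs
#' rating the same subjects at one session. Degenerate pairs (both
#' observers constant with the same label, so chance agreement is 1) are
#' excluded with a warning.
#'
#' @inheritParams interobserver_kappa
#' @return A list with `mean_kappa`, `n_pairs`, `pairs` (data frame of
#'   per-pair kappas) and `excluded` (character vector of degenerate
#'   pairs).
#' @export
pairwise_mean_kappa <- function(table, session, system, conf = 0.95) {
  d <- table[table$session == session & table$system == system, ,
             drop = FALSE]
  if (!nrow(d)) {
    stop(sprintf("no ratings for session '%s', system '%s'", session,
                 system), call. = FALSE)
  }
  wide <- .label_matrix(d, "observer_id",
                        sprintf("pairwise %s/%s", session, system))
  obs <- colnames(wide)
  if (length(obs) < 2) stop("need at least 2 observers", call. = FALSE)
  cats <- .tbl_alphabet(table, system)
  pairs <- utils::combn(obs, 2)
  rows <- list()
  excluded <- character()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- cohen_kappa(wide[, a], wide[, b], categories = cats, conf = conf)
    if (isTRUE(est$degenerate)) {
      excluded <- c(excluded, paste(a, b, sep = ":"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(observer_a = a, observer_b = b,
                                            kappa = est$kappa,
                                            stringsAsFactors = FALSE)
  }
  if (length(excluded)) {
    warning(sprintf("excluded %d degenerate observer pair(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  }
  pair_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observer_a = character(), observer_b = character(),
               kappa = numeric(), stringsAsFactors = FALSE)
  list(mean_kappa = if (nrow(pair_df)) mean(pair_df$kappa) else NA_real_,
       n_pairs = nrow(pair_df), pairs = pair_df, excluded = excluded)
}

#' Compare kappa values across classification systems
#'
#' One-way F test (analysis of variance) of unit-level kappa values grouped
#' by classification system — the units being observers for intraobserver
#' agreement and sessions for interobserver agreement. All pairwise
#' two-group comparisons are reported alongside the overall test. An
#' optional permutation p-value (permuting group membership of the units)
#' accompanies the parametric one.
#'
#' @param groups Named list of numeric vectors of kappa values, one vector
#'   per system; each of length at least 2.
#' @param permutations Number of permutations for an optional
#'   permutation-based p-value; 0 (default) skips it.
#' @param seed Optional integer seed used only for the permutation test.
#' @return An object of class `kappa_comparison`: list with `statistic`
#'   (the F value), `df` (numerator/denominator degrees of freedom),
#'   `p_value`, `groups`, `method`, `pairwise` (data frame of pairwise F
#'   tests), `permutation_p` (or `NA`) and `degenerate` flag (all values
#'   identical, no variance to test).
#' @examples
#' compare_kappa_sets(list(IDEAL = c(0.79, 0.88, 0.91, 0.76),
#'                         Frykman = c(0.60, 0.68, 0.68, 0.60)))
#' @export
compare_kappa_sets <- function(groups, permutations = 0, seed = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("'groups' must be a fully named list", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least 2 kappa values", call. = FALSE)
  }
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), vapply(groups, length, 1L)),
                  levels = names(groups))
  degenerate <- stats::var(value) < .Machine$double.eps
  if (degenerate) {
    fstat <- 0; p <- 1; df <- c(length(groups) - 1L,
                                length(value) - length(groups))
  } else {
    fit <- stats::anova(stats::lm(value ~ group))
    fstat <- fit$`F value`[1]
    p <- fit$`Pr(>F)`[1]
    df <- c(fit$Df[1], fit$Df[2])
  }

  pair_idx <- utils::combn(names(groups), 2)
  pw <- lapply(seq_len(ncol(pair_idx)), function(j) {
    a <- pair_idx[1, j]; b <- pair_idx[2, j]
    v <- c(groups[[a]], groups[[b]])
    g <- factor(rep(c(a, b), c(length(groups[[a]]), length(groups[[b]]))))
    if (stats::var(v) < .Machine$double.eps) {
      data.frame(system_a = a, system_b = b, F = 0, p_value = 1,
                 stringsAsFactors = FALSE)
    } else {
      f <- stats::anova(stats::lm(v ~ g))
      data.frame(system_a = a, system_b = b, F = f$`F value`[1],
                 p_value = f$`Pr(>F)`[1], stringsAsFactors = FALSE)
    }
  })
  pairwise <- do.call(rbind, pw)

  perm_p <- NA_real_
  if (permutations > 0 && !degenerate) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    fperm <- replicate(permutations, {
      g2 <- sample(group)
      stats::anova(stats::lm(value ~ g2))$`F value`[1]
    })
    perm_p <- (sum(fperm >= fstat) + 1) / (permutations + 1)
  }

  structure(
    list(statistic = fstat, df = df, p_value = p, groups = names(groups),
         method = "one-way F test on unit-level kappas",
         pairwise = pairwise, permutation_p = perm_p,
         degenerate = degenerate),
    class = "kappa_comparison"
  )
}

#' @export
print.kappa_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("%s\n", x$method))
  cat(sprintf("  systems: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  F(%d, %d) = %.*f, p = %.*g%s\n", x$df[1], x$df[2],
              digits, x$statistic, digits, x$p_value,
              if (x$degenerate) "  [degenerate: no variance]" else ""))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p = %.*g\n", digits, x$permutation_p))
  }
  invisible(x)
}
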