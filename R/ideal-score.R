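#' Radiographic findings for IDEAL scoring
#'
#' Bundles the continuous radiographic displacement parameters of a distal
#' radius fracture, measured on posteroanterior and lateral views, into a
#' validated object. All quantities are losses relative to normal alignment
#' and must be non-negative; units are fixed to millimetres and degrees (no
#' unit auto-detection).
#'
#' @param articular_step_mm Articular step or gap (joint incongruity), mm.
#' @param radial_shortening_mm Radial shortening, mm.
#' @param volar_tilt_loss_deg Loss of volar tilt, degrees.
#' @param radial_inclination_loss_deg Loss of radial inclination, degrees.
#' @param requires_reduction Optional logical override for the Displacement
#'   item: when `TRUE`/`FALSE` it is used directly instead of the threshold
#'   rule; `NA` (default) derives displacement from the thresholds.
#' @return An object of class `radiographic_findings`.
#' @seealso [score_displacement()], [ideal_classify()]
#' @examples
#' radiographic_findings(articular_step_mm = 2.5, radial_shortening_mm = 4)
#' @export
radiographic_findings <- function(articular_step_mm = 0,
                                  radial_shortening_mm = 0,
                                  volar_tilt_loss_deg = 0,
                                  radial_inclination_loss_deg = 0,
                                  requires_reduction = NA) {
  f <- list(
    articular_step_mm = articular_step_mm,
    radial_shortening_mm = radial_shortening_mm,
    volar_tilt_loss_deg = volar_tilt_loss_deg,
    radial_inclination_loss_deg = radial_inclination_loss_deg,
    requires_reduction = requires_reduction
  )
  for (nm in names(f)[1:4]) {
    x <- f[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
    if (x < 0) {
      stop(sprintf("'%s' must be non-negative (got %g)", nm, x), call. = FALSE)
    }
  }
  if (!is.logical(requires_reduction) || length(requires_reduction) != 1L) {
    stop("'requires_reduction' must be TRUE, FALSE or NA", call. = FALSE)
  }
  structure(f, class = "radiographic_findings")
}

#' Epidemiological context of a fracture case
#'
#' Patient age, trauma energy and presence of associated lesions
#' (radiocarpal dislocation or subluxation, carpal bone fracture, carpal or
#' distal radioulnar instability, neurovascular injury, open fracture,
#' distal ulnar fracture). Low energy means a fall from standing height;
#' anything else counts as high energy.
#'
#' @param age_years Patient age in whole years, non-negative.
#' @param energy `"low"` or `"high"`.
#' @param lesions_present Logical; any associated lesion present.
#' @return An object of class `case_context`.
#' @examples
#' case_context(age_years = 65, energy = "low", lesions_present = FALSE)
#' @export
case_context <- function(age_years, energy = c("low", "high"),
                         lesions_present = FALSE) {
  if (!is.numeric(age_years) || length(age_years) != 1L || !is.finite(age_years) ||
      age_years < 0) {
    stop("'age_years' must be a single finite non-negative number", call. = FALSE)
  }
  energy <- match.arg(energy)
  if (!is.logical(lesions_present) || length(lesions_present) != 1L ||
      is.na(lesions_present)) {
    stop("'lesions_present' must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(age_years = age_years, energy = energy,
         lesions_present = lesions_present),
    class = "case_context"
  )
}

# Scoring thresholds. The source tables print two variants of two boundaries
# (step "> 2 mm" vs ">= 2 mm"; age ">= 60" vs "> 60 / < 60" leaving 60
# undefined); this implementation fixes step >= 2 mm and age >= 60 and keeps
# the displacement thresholds strict, as documented in ?ideal_thresholds.
.ideal_thresholds <- list(
  step_mm = 2.0,          # scores when >= (inclusive)
  shortening_mm = 3.0,    # scores when >  (strict)
  tilt_deg = 10.0,        # scores when >  (strict)
  inclination_deg = 5.0,  # scores when >  (strict)
  age_years = 60          # scores when >= (inclusive)
)

#' IDEAL scoring thresholds
#'
#' Returns the fixed thresholds of the IDEAL items. The step/gap boundary is
#' inclusive (a step of exactly 2 mm scores) and the age boundary is
#' inclusive (exactly 60 years scores); the three displacement thresholds
#' are strict. The published descriptions of the step and age boundaries are
#' internally inconsistent (inclusive in one place, strict in another); the
#' conventions here are fixed design choices, documented rather than guessed
#' as intent.
#'
#' @return A named list of thresholds (mm, degrees, years).
#' @export
ideal_thresholds <- function() .ideal_thresholds

#' Score the Incongruity item
#'
#' One point when the articular step or gap is at least 2 mm.
#'
#' @param findings A [radiographic_findings()] object.
#' @return Integer 0 or 1.
#' @export
score_incongruity <- function(findings) {
  stopifnot(inherits(findings, "radiographic_findings"))
  as.integer(findings$articular_step_mm >= .ideal_thresholds$step_mm)
}

#' Score the Displacement item
#'
#' One point when the fracture requires reduction. If the
#' `requires_reduction` override is set it is returned directly; otherwise
#' displacement is derived from the radiographic thresholds: radial
#' shortening > 3 mm, loss of volar tilt > 10 degrees, or loss of radial
#' inclination > 5 degrees (all strict).
#'
#' @param findings A [radiographic_findings()] object.
#' @return Integer 0 or 1.
#' @export
score_displacement <- function(findings) {
  stopifnot(inherits(findings, "radiographic_findings"))
  if (!is.na(findings$requires_reduction)) {
    return(as.integer(findings$requires_reduction))
  }
  th <- .ideal_thresholds
  as.integer(
    findings$radial_shortening_mm > th$shortening_mm ||
      findings$volar_tilt_loss_deg > th$tilt_deg ||
      findings$radial_inclination_loss_deg > th$inclination_deg
  )
}

#' Score the Energy, Age and Lesions items
#'
#' Energy scores for high-energy trauma, Age for patients 60 years or
#' older, Lesions for any associated lesion.
#'
#' @param context A [case_context()] object.
#' @return Named integer vector `c(E =, A =, L =)` of 0/1 scores.
#' @export
score_context <- function(context) {
  stopifnot(inherits(context, "case_context"))
  c(E = as.integer(context$energy == "high"),
    A = as.integer(context$age_years >= .ideal_thresholds$age_years),
    L = as.integer(context$lesions_present))
}

# Guidance strings per fracture type (total 0-1 / 2-3 / 4-5).
.ideal_types <- data.frame(
  fracture_type = c("I", "II", "III"),
  min_total = c(0L, 2L, 4L),
  max_total = c(1L, 3L, 5L),
  description = c("Stable", "Potentially unstable", "Complex"),
  treatment = c("Conservative", "Pins/external fixation/plating",
                "Associated methods/bone graft"),
  prognosis = c("Good", "Intermediate", "Poor"),
  stringsAsFactors = FALSE
)

.type_from_total <- function(total) {
  stopifnot(total %in% 0:5)
  .ideal_types$fracture_type[total >= .ideal_types$min_total &
                               total <= .ideal_types$max_total]
}

#' Classify a distal radius fracture with the IDEAL system
#'
#' Computes the five binary IDEAL components (Incongruity, Displacement,
#' Energy, Age, Lesions), their total, the fracture type and the associated
#' treatment/prognosis guidance.
#'
#' Fracture types by total score: 0-1 points Type I (stable, conservative
#' treatment, good prognosis); 2-3 points Type II (potentially unstable,
#' pins/external fixation/plating, intermediate prognosis); 4-5 points Type
#' III (complex, associated methods/bone graft, poor prognosis).
#'
#' @param findings A [radiographic_findings()] object.
#' @param context A [case_context()] object.
#' @return An object of class `ideal_result`: list with integer components
#'   `score_I`, `score_D`, `score_E`, `score_A`, `score_L`, `total`,
#'   and character `fracture_type` (`"I"`, `"II"`, `"III"`),
#'   `description`, `treatment`, `prognosis`.
#' @examples
#' f <- radiographic_findings(radial_shortening_mm = 4)
#' ctx <- case_context(age_years = 65, energy = "low", lesions_present = FALSE)
#' ideal_classify(f, ctx)
#' @export
ideal_classify <- function(findings, context) {
  i <- score_incongruity(findings)
  d <- score_displacement(findings)
  eal <- score_context(context)
  total <- i + d + sum(eal)
  type <- .type_from_total(total)
  row <- .ideal_types[.ideal_types$fracture_type == type, ]
  structure(
    list(score_I = i, score_D = d,
         score_E = unname(eal["E"]), score_A = unname(eal["A"]),
         score_L = unname(eal["L"]),
         total = as.integer(total), fracture_type = type,
         description = row$description, treatment = row$treatment,
         prognosis = row$prognosis),
    class = "ideal_result"
  )
}

#' @export
print.ideal_result <- function(x, ...) {
  cat(sprintf("IDEAL classification: Type %s (%s)\n", x$fracture_type,
              x$description))
  cat(sprintf("  Components I=%d D=%d E=%d A=%d L=%d, total %d/5\n",
              x$score_I, x$score_D, x$score_E, x$score_A, x$score_L, x$total))
  cat(sprintf("  Treatment: %s\n  Prognosis: %s\n", x$treatment, x$prognosis))
  invisible(x)
}

#' Enumerate the complete IDEAL score space
#'
#' Exhaustive table of all 32 component vectors with their total and
#' fracture type; a self-check that the 0-1/2-3/4-5 bands partition the
#' score range and that every component vector maps to exactly one type.
#'
#' @return A data frame with 32 rows and columns `I`, `D`, `E`, `A`, `L`,
#'   `total`, `fracture_type`.
#' @export
ideal_score_space <- function() {
  g <- expand.grid(I = 0:1, D = 0:1, E = 0:1, A = 0:1, L = 0:1,
                   KEEP.OUT.ATTRS = FALSE)
  g$total <- as.integer(rowSums(g))
  g$fracture_type <- vapply(g$total, .type_from_total, character(1))
  g
}

#' Score a table of fracture cases
#'
#' Vectorised IDEAL classification of a per-case measurement table, e.g. one
#' read with [read_cases()]. Each row is validated and classified via
#' [ideal_classify()].
#'
#' @param cases Data frame with columns `articular_step_mm`,
#'   `radial_shortening_mm`, `volar_tilt_loss_deg`,
#'   `radial_inclination_loss_deg`, `age_years`, `energy`,
#'   `lesions_present`, and optionally `case_id` and `requires_reduction`.
#' @return The input data frame with appended columns `score_I` .. `score_L`,
#'   `total`, `fracture_type`, `description`, `treatment`, `prognosis`.
#' @examples
#' cases <- data.frame(articular_step_mm = c(0, 2.5),
#'                     radial_shortening_mm = c(0, 5),
#'                     volar_tilt_loss_deg = 0, radial_inclination_loss_deg = 0,
#'                     age_years = c(30, 72), energy = c("low", "high"),
#'                     lesions_present = c(FALSE, TRUE))
#' score_cases(cases)
#' @export
score_cases <- function(cases) {
  needed <- c("articular_step_mm", "radial_shortening_mm",
              "volar_tilt_loss_deg", "radial_inclination_loss_deg",
              "age_years", "energy", "lesions_present")
  missing_cols <- setdiff(needed, names(cases))
  if (length(missing_cols)) {
    stop("missing case columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_override <- "requires_reduction" %in% names(cases)
  res <- lapply(seq_len(nrow(cases)), function(i) {
    rr <- if (has_override) .as_logical_flag(cases$requires_reduction[i]) else NA
    f <- radiographic_findings(
      articular_step_mm = cases$articular_step_mm[i],
      radial_shortening_mm = cases$radial_shortening_mm[i],
      volar_tilt_loss_deg = cases$volar_tilt_loss_deg[i],
      radial_inclination_loss_deg = cases$radial_inclination_loss_deg[i],
      requires_reduction = rr
    )
    ctx <- case_context(age_years = cases$age_years[i],
                        energy = as.character(cases$energy[i]),
                        lesions_present = .as_logical_flag(cases$lesions_present[i],
                                                           na_ok = FALSE))
    r <- ideal_classify(f, ctx)
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  })
  cbind(cases, do.call(rbind, res))
}

# Accepts 0/1, true/false (any case), TRUE/FALSE, NA/"" -> NA.
.as_logical_flag <- function(x, na_ok = TRUE) {
  if (is.logical(x)) {
    out <- x
  } else if (is.numeric(x)) {
    out <- if (is.na(x)) NA else x != 0
  } else {
    s <- tolower(trimws(as.character(x)))
    out <- if (is.na(x) || s == "" || s == "na") NA
           else if (s %in% c("1", "true", "t", "yes")) TRUE
           else if (s %in% c("0", "false", "f", "no")) FALSE
           else stop(sprintf("cannot interpret '%s' as a logical flag", x),
                     call. = FALSE)
  }
  if (!na_ok && is.na(out)) stop("missing logical flag", call. = FALSE)
  out
}

#' Read a fracture case table from CSV
#'
#' Expects the header `case_id,articular_step_mm,radial_shortening_mm,`
#' `volar_tilt_loss_deg,radial_inclination_loss_deg,requires_reduction,`
#' `age_years,energy,lesions_present` (UTF-8, comma-separated); `energy` is
#' `low`/`high`, logical columns accept `0/1/true/false`, and an empty
#' `requires_reduction` means "derive from thresholds".
#'
#' @param path Path to the CSV file.
#' @return A data frame suitable for [score_cases()].
#' @export
read_cases <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("case_id", "articular_step_mm", "radial_shortening_mm",
              "volar_tilt_loss_deg", "radial_inclination_loss_deg",
              "age_years", "energy", "lesions_present")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("case CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
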