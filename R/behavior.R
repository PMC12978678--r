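# Behavioral scoring and contrast assembly.
#
# Stimulus classes: real_word (200 monosyllabic real words) and three
# pseudoword types distinguished by the number of learned
# orthography-to-phonology (OP) mappings of the orthographic body —
# PW0M (no body neighbors in English), PW1M (one plausible mapping),
# PWMM (multiple plausible mappings), 20 items each.

STIMULUS_CLASSES <- c("real_word", "PW0M", "PW1M", "PWMM")

#' Define a lesion-symptom mapping contrast
#'
#' A contrast names the stimulus class (or class union) whose accuracy is the
#' dependent variable and the class accuracies controlled for. Nuisance
#' covariates (lesion volume, age, education) are always included and are
#' treated identically to the behavioral covariates at residualization time.
#'
#' @param name character identifier.
#' @param target character vector of stimulus classes pooled into the
#'   dependent variable.
#' @param covariates list of character vectors; each element is a class union
#'   whose pooled accuracy enters as one behavioral covariate column.
#' @return Object of class `contrast_spec`.
#' @seealso [reading_contrasts] for the five built-in contrasts.
#' @export
contrast_spec <- function(name, target, covariates = list()) {
  target <- match.arg(target, STIMULUS_CLASSES, several.ok = TRUE)
  covariates <- lapply(covariates, match.arg,
                       choices = STIMULUS_CLASSES, several.ok = TRUE)
  if (any(unlist(covariates) %in% target))
    stopf("contrast '%s': target classes overlap behavioral covariates", name)
  structure(list(name = name, target = target, covariates = covariates,
                 nuisance = c("lesion_volume_cm3", "age", "education")),
            class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cv <- vapply(x$covariates, paste, "", collapse = "+")
  cat(sprintf("<contrast_spec> %s: %s | %s + %s\n", x$name,
              paste(x$target, collapse = "+"),
              if (length(cv)) paste(cv, collapse = ", ") else "(none)",
              paste(x$nuisance, collapse = "+")))
  invisible(x)
}

#' The five built-in covariate-controlled reading contrasts
#'
#' * `pseudoword_lexicality`: all pseudowords controlling for real words —
#'   lesions producing an exaggerated lexicality effect (phonological alexia
#'   pattern).
#' * `realword_lexicality`: the reverse — real words controlling for
#'   pseudowords.
#' * `learned_mappings`: 1M+MM pseudowords controlling for 0M pseudowords
#'   and real words — the use of learned OP body mappings.
#' * `multiple_mappings`: MM pseudowords controlling for 1M pseudowords and
#'   real words — selection among multiple plausible mappings.
#' * `zero_mappings`: 0M pseudowords controlling for 1M+MM pseudowords and
#'   real words — sublexical reading without learned body mappings.
#'
#' @param name optional; if supplied, return that single contrast.
#' @return Named list of [contrast_spec] objects, or one spec.
#' @export
reading_contrasts <- function(name = NULL) {
  specs <- list(
    pseudoword_lexicality = contrast_spec(
      "pseudoword_lexicality", c("PW0M", "PW1M", "PWMM"),
      list("real_word")),
    realword_lexicality = contrast_spec(
      "realword_lexicality", "real_word",
      list(c("PW0M", "PW1M", "PWMM"))),
    learned_mappings = contrast_spec(
      "learned_mappings", c("PW1M", "PWMM"),
      list("PW0M", "real_word")),
    multiple_mappings = contrast_spec(
      "multiple_mappings", "PWMM",
      list("PW1M", "real_word")),
    zero_mappings = contrast_spec(
      "zero_mappings", "PW0M",
      list(c("PW1M", "PWMM"), "real_word"))
  )
  if (is.null(name)) return(specs)
  if (!name %in% names(specs))
    stopf("unknown contrast '%s'; built-ins: %s", name,
          paste(names(specs), collapse = ", "))
  specs[[name]]
}

#' Serialize / deserialize a contrast spec as JSON
#' @param spec a [contrast_spec].
#' @return `contrast_to_json`: JSON string. `contrast_from_json`: the spec.
#' @export
contrast_to_json <- function(spec) {
  jsonlite::toJSON(list(name = spec$name, target = spec$target,
                        covariates = spec$covariates), auto_unbox = FALSE)
}

#' @rdname contrast_to_json
#' @param json JSON string produced by [contrast_to_json].
#' @export
contrast_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyMatrix = FALSE)
  contrast_spec(x$name, unlist(x$target), lapply(x$covariates, unlist))
}

#' Pooled accuracy over a union of stimulus classes
#'
#' Trials are pooled: `sum(n_correct) / sum(n_presented)` over the union.
#' With the equal 20-item pseudoword classes this coincides with averaging
#' class proportions, but stays well-defined for unequal counts. Subjects
#' with zero presented trials in any required class get `NA` (missing-score
#' flag).
#'
#' @param cohort cohort data frame (see [read_cohort_table]).
#' @param classes character vector of stimulus classes to pool.
#' @return Numeric vector in `[0, 1]` (or `NA`), one per cohort row.
#' @examples
#' cohort <- data.frame(PW1M_n = 20, PW1M_correct = 15)
#' score_accuracy(cohort, "PW1M") # 0.75
#' @export
score_accuracy <- function(cohort, classes) {
  classes <- match.arg(classes, STIMULUS_CLASSES, several.ok = TRUE)
  n <- cor <- rep(0, nrow(cohort))
  missing <- rep(FALSE, nrow(cohort))
  for (cl in classes) {
    ncol_ <- paste0(cl, "_n"); ccol <- paste0(cl, "_correct")
    if (!all(c(ncol_, ccol) %in% names(cohort)))
      stopf("cohort table lacks columns for class '%s'", cl)
    missing <- missing | is.na(cohort[[ncol_]]) | cohort[[ncol_]] == 0 |
      is.na(cohort[[ccol]])
    n <- n + ifelse(is.na(cohort[[ncol_]]), 0, cohort[[ncol_]])
    cor <- cor + ifelse(is.na(cohort[[ccol]]), 0, cohort[[ccol]])
  }
  if (any(!missing & cor > n)) stopf("n_correct exceeds n_presented")
  ifelse(missing, NA_real_, cor / n)
}

#' Inverse time-on-item
#'
#' `1 / seconds`, the reading-speed transform used to normalize the skewed
#' per-item duration distribution. Items time out at 10 s, so valid inputs
#' lie in (0, 10].
#'
#' @param seconds positive numeric vector.
#' @return `1/seconds`.
#' @examples
#' inverse_duration(2) # 0.5
#' @export
inverse_duration <- function(seconds) {
  if (any(!is.finite(seconds)) || any(seconds <= 0))
    stopf("durations must be positive and finite")
  if (any(seconds > 10))
    warnf("durations exceed the 10 s timeout cap")
  1 / seconds
}

#' Assemble the dependent variable and covariates for one contrast
#'
#' Restricts the cohort to patients, scores the target and behavioral
#' covariate accuracies, attaches the nuisance covariates (lesion volume,
#' age, education), and drops subjects with any missing value (logged via
#' message). Lesion volume is taken from the `lesion_volume_cm3` column if
#' present, else computed from `masks`.
#'
#' @param cohort cohort data frame.
#' @param spec a [contrast_spec].
#' @param masks optional list of [lesion_mask] whose `subject_id`s cover the
#'   patients; used to compute lesion volumes when the table lacks them.
#' @param min_subjects minimum retained patients (default 10); fewer is an
#'   error because multivariate LSM is meaningless below that.
#' @return Object of class `behavior_target`: `subject_id`, `y`,
#'   `behavioral` (matrix, one column per covariate union), `nuisance`
#'   (matrix), `dropped` (ids).
#' @export
build_contrast_target <- function(cohort, spec, masks = NULL,
                                  min_subjects = 10L) {
  stopifnot(inherits(spec, "contrast_spec"))
  pat <- cohort[cohort$group == "patient", , drop = FALSE]
  if (nrow(pat) == 0L) stopf("no patient rows in cohort table")

  if (!"lesion_volume_cm3" %in% names(pat)) {
    if (is.null(masks))
      stopf("cohort table lacks lesion_volume_cm3 and no masks supplied")
    vols <- vapply(masks, lesion_volume_cm3, 0)
    names(vols) <- vapply(masks, `[[`, "", "subject_id")
    pat$lesion_volume_cm3 <- vols[pat$subject_id]
  }

  y <- score_accuracy(pat, spec$target)
  beh <- vapply(spec$covariates, function(cl) score_accuracy(pat, cl),
                numeric(nrow(pat)))
  beh <- matrix(beh, nrow = nrow(pat),
                dimnames = list(NULL, vapply(spec$covariates, paste, "",
                                             collapse = "+")))
  nui <- cbind(lesion_volume_cm3 = pat$lesion_volume_cm3,
               age = pat$age, education = pat$education)

  keep <- !is.na(y) & stats::complete.cases(beh) & stats::complete.cases(nui)
  dropped <- pat$subject_id[!keep]
  if (length(dropped))
    message(sprintf("build_contrast_target: dropped %d subject(s) with missing scores: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (sum(keep) < min_subjects)
    stopf("only %d subjects retained for contrast '%s' (< %d)",
          sum(keep), spec$name, min_subjects)

  structure(list(subject_id = pat$subject_id[keep], y = y[keep],
                 behavioral = beh[keep, , drop = FALSE],
                 nuisance = nui[keep, , drop = FALSE],
                 dropped = dropped, contrast = spec$name),
            class = "behavior_target")
}

#' @export
print.behavior_target <- function(x, ...) {
  cat(sprintf("<behavior_target> contrast '%s': %d subjects, %d behavioral + %d nuisance covariates\n",
              x$contrast, length(x$y), ncol(x$behavioral), ncol(x$nuisance)))
  invisible(x)
}

#' Full covariate matrix of a behavior target
#'
#' Behavioral and nuisance covariates form a single block; both are regressed
#' out of the lesion/edge features and the dependent variable alike.
#' @param target a `behavior_target`.
#' @return Numeric matrix.
#' @export
covariate_matrix <- function(target) {
  cbind(target$behavioral, target$nuisance)
}
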