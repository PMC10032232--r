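#' Derive case status from raw diagnosis records
#'
#' An individual is a case iff they have at least one malignant diagnosis
#' (prevalent or incident); their assigned cancer is the earliest
#' malignant diagnosis. Individuals whose only diagnoses are in situ are
#' excluded from both cases and controls; individuals with no diagnoses
#' are eligible controls.
#'
#' @param diagnoses data.frame with columns `individual_id`, `cancer_type`,
#'   `age_at_diagnosis`, `malignant` (logical; `FALSE` = in situ).
#' @param individual_ids ids of the full cohort (so diagnosis-free
#'   individuals appear in the output).
#' @return data.frame with one row per individual: `individual_id`,
#'   `status` (`"case"`, `"control"`, `"excluded"`), `case_type`,
#'   `age_at_diagnosis` of the assigned cancer.
#' @export
derive_case_status <- function(diagnoses, individual_ids) {
  if (nrow(diagnoses) > 0 && anyNA(diagnoses$age_at_diagnosis)) {
    bad <- diagnoses$individual_id[which(is.na(diagnoses$age_at_diagnosis))[1]]
    stop("diagnosis without age for individual ", bad)
  }
  out <- data.frame(individual_id = individual_ids,
                    status = "control",
                    case_type = NA_character_,
                    age_at_diagnosis = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(diagnoses) == 0) return(out)
  for (id in unique(diagnoses$individual_id)) {
    dx <- diagnoses[diagnoses$individual_id == id, , drop = FALSE]
    row <- match(id, out$individual_id)
    if (is.na(row)) next
    mal <- dx[dx$malignant, , drop = FALSE]
    if (nrow(mal) > 0) {
      first <- mal[which.min(mal$age_at_diagnosis), ]
      out$status[row] <- "case"
      out$case_type[row] <- first$cancer_type
      out$age_at_diagnosis[row] <- first$age_at_diagnosis
    } else {
      out$status[row] <- "excluded"  # in-situ only: neither case nor control
    }
  }
  out
}

#' Match one control to each case on birth year and sex
#'
#' Greedy 1:1 exact matching: cases are processed in a seed-shuffled
#' order; for each, a control with the same birth year and sex whose age
#' at death or censoring is at least the case's age at diagnosis is drawn
#' uniformly at random from the remaining eligible pool. Each control is
#' used at most once. Cases without an eligible control are reported, not
#' an error.
#'
#' @param cases data.frame: `individual_id`, `birth_year`, `sex`,
#'   `age_at_diagnosis`.
#' @param control_pool data.frame: `individual_id`, `birth_year`, `sex`,
#'   `age_at_death_or_censoring`.
#' @param seed RNG seed for the shuffle and tie-breaking draws.
#' @return a `matched_set` list: `pairs` (data.frame `case_id`,
#'   `control_id`), `unmatched_cases` (character vector).
#' @export
match_controls <- function(cases, control_pool, seed = 1) {
  if (length(intersect(cases$individual_id, control_pool$individual_id))) {
    stop("case and control pools overlap")
  }
  set.seed(seed)
  ord <- sample.int(nrow(cases))
  taken <- rep(FALSE, nrow(control_pool))
  case_id <- character(0)
  control_id <- character(0)
  unmatched <- character(0)
  for (i in ord) {
    elig <- which(!taken &
                    control_pool$birth_year == cases$birth_year[i] &
                    control_pool$sex == cases$sex[i] &
                    control_pool$age_at_death_or_censoring >=
                      cases$age_at_diagnosis[i])
    if (length(elig) == 0) {
      unmatched <- c(unmatched, cases$individual_id[i])
    } else {
      pick <- if (length(elig) == 1) elig else elig[sample.int(length(elig), 1)]
      taken[pick] <- TRUE
      case_id <- c(case_id, cases$individual_id[i])
      control_id <- c(control_id, control_pool$individual_id[pick])
    }
  }
  o <- order(match(case_id, cases$individual_id))
  structure(list(pairs = data.frame(case_id = case_id[o],
                                    control_id = control_id[o],
                                    stringsAsFactors = FALSE),
                 unmatched_cases = unmatched),
            class = "matched_set")
}

#' Restrict a matched set to cases with a family history
#'
#' Keeps only the pairs whose case reports a first-degree family history
#' of the cancer under study; pairs are dropped whole (the matched control
#' leaves with its case).
#'
#' @param matched a [match_controls()] result.
#' @param phenotypes PhenotypeTable with `individual_id` and
#'   `family_history` (logical; `NA` = unavailable).
#' @return a filtered `matched_set`.
#' @export
restrict_family_history <- function(matched, phenotypes) {
  fh <- phenotypes$family_history[match(matched$pairs$case_id,
                                        phenotypes$individual_id)]
  if (anyNA(fh)) {
    stop("family history unavailable for case(s): ",
         paste(matched$pairs$case_id[is.na(fh)], collapse = ", "))
  }
  structure(list(pairs = matched$pairs[fh, , drop = FALSE],
                 unmatched_cases = matched$unmatched_cases),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("matched_set:", nrow(x$pairs), "pairs,",
      length(x$unmatched_cases), "unmatched cases\n")
  invisible(x)
}
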