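#' Disease definition for cohort selection
#'
#' A named family of ICD-9-CM principal-diagnosis prefixes. The two shipped
#' definitions follow the standard claims families: AMI is 410.x; COPD is
#' 490.x, 491.x, 492.x, 494.x and 496.x (asthma, 493.x, is not included).
#'
#' @param name \code{"AMI"}, \code{"COPD"}, or a custom label when
#'   \code{icd9_prefixes} is supplied.
#' @param icd9_prefixes optional custom prefix vector overriding the shipped
#'   family.
#' @return object of class \code{disease_definition}.
#' @export
disease_definition <- function(name, icd9_prefixes = NULL) {
  if (is.null(icd9_prefixes)) {
    icd9_prefixes <- switch(name,
      AMI = "410",
      COPD = c("490", "491", "492", "494", "496"),
      stop("no shipped definition for disease '", name,
           "'; supply icd9_prefixes", call. = FALSE))
  }
  stopifnot(length(icd9_prefixes) >= 1L)
  structure(list(name = name,
                 icd9_prefixes = normalize_icd9(icd9_prefixes)),
            class = "disease_definition")
}

age_completed_years <- function(birth_date, at_date) {
  b <- as.POSIXlt(birth_date); a <- as.POSIXlt(at_date)
  age <- a$year - b$year
  before_bday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  age - as.integer(before_bday)
}

#' Identify index hospitalizations
#'
#' For each patient with at least one admission whose principal diagnosis
#' prefix-matches the disease definition and whose admission date lies in
#' the study window (default calendar year 2002), returns the earliest such
#' admission. Ties on admission date are broken by the longer stay, then the
#' lexicographically smallest principal diagnosis, so selection is
#' deterministic.
#'
#' @param dataset a [claims_dataset()].
#' @param disease a [disease_definition()].
#' @param window length-2 Date (or ISO string) vector, closed interval.
#' @return data.frame of index admissions, one row per patient.
#' @export
find_index_admissions <- function(dataset, disease,
                                  window = c("2002-01-01", "2002-12-31")) {
  stopifnot(inherits(dataset, "claims_dataset"),
            inherits(disease, "disease_definition"))
  window <- as.Date(window)
  stopifnot(length(window) == 2L, !anyNA(window), window[1] <= window[2])
  adm <- dataset$admissions
  canon <- normalize_icd9(adm$principal_dx)
  qual <- icd9_prefix_match(canon, disease$icd9_prefixes) &
    adm$admit_date >= window[1] & adm$admit_date <= window[2]
  adm <- adm[qual, , drop = FALSE]
  if (!nrow(adm)) return(adm)
  los <- as.integer(adm$discharge_date - adm$admit_date)
  ord <- order(adm$patient_id, adm$admit_date, -los, adm$principal_dx)
  adm <- adm[ord, , drop = FALSE]
  adm <- adm[!duplicated(adm$patient_id), , drop = FALSE]
  rownames(adm) <- NULL
  adm
}

#' Apply cohort exclusion rules
#'
#' Removes candidates younger than 18 completed years at the index admission
#' and candidates whose index discharge falls after the study cutoff
#' (default 2002-12-31, i.e. not discharged within the study year). Age
#' exactly 18 is retained. Returns the survivors together with a per-rule
#' exclusion ledger.
#'
#' @param candidates index-admission data.frame from
#'   [find_index_admissions()].
#' @param patients the demographics data.frame of the source dataset.
#' @param cutoff last allowed discharge date.
#' @return list with \code{retained} (data.frame, with an \code{age_years}
#'   column added) and \code{ledger} (named integer vector of per-rule
#'   exclusion counts).
#' @export
apply_exclusions <- function(candidates, patients, cutoff = "2002-12-31") {
  cutoff <- as.Date(cutoff)
  m <- match(candidates$patient_id, patients$patient_id)
  stopifnot(!anyNA(m))
  age <- age_completed_years(patients$birth_date[m], candidates$admit_date)
  too_young <- age < 18L
  late_discharge <- candidates$discharge_date > cutoff
  ledger <- c("age<18" = sum(too_young),
              "not_discharged_by_cutoff" = sum(!too_young & late_discharge))
  keep <- !too_young & !late_discharge
  retained <- candidates[keep, , drop = FALSE]
  retained$age_years <- age[keep]
  rownames(retained) <- NULL
  list(retained = retained, ledger = ledger)
}

#' Derive baseline covariates and mortality outcomes
#'
#' Attaches demographics and both outcomes to each retained index
#' admission. In-hospital death is a registry death date inside the closed
#' admission interval, or a claim discharged dead; either source of evidence
#' counts, and claim/registry disagreements are surfaced as a warning rather
#' than silently reconciled. One-year death is a death
#' date within 365 days of the index admission date (closed window,
#' admission-anchored). Surgery is membership of the index DRG in the
#' surgical-DRG set.
#'
#' @param candidates data.frame from [apply_exclusions()]\code{$retained}.
#' @param patients demographics data.frame.
#' @param surgical_drgs character vector of surgical DRG codes; defaults to
#'   the bundled (synthetic) surgical list.
#' @return cohort data.frame, one row per patient: index-admission fields
#'   plus \code{age_years}, \code{sex}, \code{male}, \code{aborigine},
#'   \code{surgery}, \code{died_in_hospital}, \code{died_within_1yr}.
#' @export
derive_outcomes <- function(candidates, patients, surgical_drgs = NULL) {
  if (is.null(surgical_drgs)) {
    surgical_drgs <- read_ref_tsv("surgical_drgs_synthetic.tsv")$drg
  }
  m <- match(candidates$patient_id, patients$patient_id)
  stopifnot(!anyNA(m))
  death <- patients$death_date[m]

  bad <- which(!is.na(death) & death < candidates$admit_date)
  if (length(bad)) {
    stop("death_date precedes index admission for patient(s): ",
         paste(candidates$patient_id[bad], collapse = ", "), call. = FALSE)
  }

  death_in_stay <- !is.na(death) &
    death >= candidates$admit_date & death <= candidates$discharge_date
  claim_dead <- !candidates$discharge_alive
  conflict <- claim_dead != death_in_stay
  if (any(conflict)) {
    warning("discharge status and death registry disagree for patient(s): ",
            paste(candidates$patient_id[conflict], collapse = ", "),
            call. = FALSE)
  }
  died_in_hospital <- claim_dead | death_in_stay

  died_within_1yr <- !is.na(death) &
    death <= candidates$admit_date + 365L
  # a claim discharged dead counts for the 1-year outcome as well
  died_within_1yr <- died_within_1yr | died_in_hospital

  out <- candidates
  if (is.null(out$age_years)) {
    out$age_years <- age_completed_years(patients$birth_date[m],
                                         out$admit_date)
  }
  out$sex <- patients$sex[m]
  out$male <- out$sex == "male"
  out$aborigine <- patients$aborigine[m]
  out$surgery <- out$drg %in% surgical_drgs
  out$died_in_hospital <- died_in_hospital
  out$died_within_1yr <- died_within_1yr
  rownames(out) <- NULL
  out
}

#' Build an analysis cohort from a claims dataset
#'
#' One call chaining [find_index_admissions()], [apply_exclusions()] and
#' [derive_outcomes()]. The exclusion ledger is attached as the
#' \code{"exclusion_ledger"} attribute.
#'
#' @inheritParams find_index_admissions
#' @inheritParams apply_exclusions
#' @inheritParams derive_outcomes
#' @return cohort data.frame (see [derive_outcomes()]) with attribute
#'   \code{exclusion_ledger}.
#' @export
build_cohort <- function(dataset, disease,
                         window = c("2002-01-01", "2002-12-31"),
                         cutoff = "2002-12-31", surgical_drgs = NULL) {
  cand <- find_index_admissions(dataset, disease, window)
  ex <- apply_exclusions(cand, dataset$patients, cutoff)
  cohort <- derive_outcomes(ex$retained, dataset$patients, surgical_drgs)
  attr(cohort, "exclusion_ledger") <- ex$ledger
  cohort
}
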