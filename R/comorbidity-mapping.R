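#' Comorbidity ascertainment period
#'
#' The claims window from which comorbidity evidence is drawn:
#' \code{"index_only"} uses the index admission's secondary diagnoses only;
#' \code{"index_plus_prior"} additionally uses every diagnosis field
#' (principal and secondary) of admissions in the year before the index
#' admission date (a 365-day lookback, closed on the early end, open at the
#' index date).
#'
#' @param kind \code{"index_only"} or \code{"index_plus_prior"}.
#' @return an object of class \code{data_period}.
#' @export
data_period <- function(kind = c("index_only", "index_plus_prior")) {
  kind <- match.arg(kind)
  structure(list(kind = kind,
                 lookback_days = if (kind == "index_plus_prior") 365L else 0L),
            class = "data_period")
}

as_data_period <- function(x) {
  if (inherits(x, "data_period")) x else data_period(x)
}

#' Load a comorbidity classification method
#'
#' Builds a fully populated method object from the bundled reference tables:
#' the ordered category list, the ICD-9-CM prefix map, the hierarchy rules
#' (e.g. complicated diabetes suppresses uncomplicated diabetes), and, for
#' the Elixhauser method, the per-category DRG screen. Both Charlson
#' adaptations expose exactly 17 categories; the Elixhauser method exposes
#' exactly 30.
#'
#' For the Charlson variants, \code{prior_rule = "complication_prone"}
#' restricts a set of complication-prone categories (congestive heart
#' failure, cerebrovascular disease, myocardial infarction) to prior-admission
#' evidence only, so they can never be flagged from the index admission
#' alone; the default (\code{"none"}) counts every category from index
#' secondary diagnoses as well, which keeps index-only Charlson models
#' non-degenerate.
#'
#' @param name one of \code{"charlson_deyo"}, \code{"charlson_romano"},
#'   \code{"elixhauser"}.
#' @param prior_rule prior-admission rule for the Charlson variants; ignored
#'   for Elixhauser, whose comorbidity-versus-complication distinction is the
#'   DRG screen instead.
#' @return an object of class \code{comorbidity_method}.
#' @export
load_method <- function(name, prior_rule = c("none", "complication_prone")) {
  prior_rule <- match.arg(prior_rule)
  known <- c("charlson_deyo", "charlson_romano", "elixhauser")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    stop("unknown comorbidity method: ", paste(name, collapse = ", "),
         " (expected one of ", paste(known, collapse = ", "), ")",
         call. = FALSE)
  }
  tab <- read_ref_tsv(paste0(name, ".tsv"))
  needed <- c("method", "category", "icd9_prefix")
  if (!all(needed %in% names(tab)) || any(!nzchar(tab$icd9_prefix))) {
    stop("malformed reference table for ", name, call. = FALSE)
  }
  categories <- unique(tab$category)
  code_map <- lapply(split(tab$icd9_prefix, factor(tab$category, categories)),
                     normalize_icd9)

  hier <- read_ref_tsv("hierarchy.tsv")
  hier <- hier[hier$method == name, c("dominant", "suppressed")]
  stopifnot(all(unlist(hier) %in% categories))

  drg_screen <- NULL
  if (name == "elixhauser") {
    scr <- read_ref_tsv("drg_screen_synthetic.tsv")
    stopifnot(all(scr$category %in% categories))
    drg_screen <- split(scr$drg, factor(scr$category, categories))
    drg_screen <- drg_screen[lengths(drg_screen) > 0L]
  }

  prior_only <- character(0)
  if (name != "elixhauser" && prior_rule == "complication_prone") {
    prior_only <- intersect(c("chf", "cvd", "mi"), categories)
  }

  structure(list(name = name,
                 categories = categories,
                 code_map = code_map,
                 drg_screen = drg_screen,
                 prior_only = prior_only,
                 hierarchy = hier),
            class = "comorbidity_method")
}

#' @export
print.comorbidity_method <- function(x, ...) {
  cat("<comorbidity_method>", x$name, "\n")
  cat("  categories:", length(x$categories), "\n")
  cat("  hierarchy rules:", nrow(x$hierarchy), "\n")
  if (!is.null(x$drg_screen)) {
    cat("  DRG screen on", length(x$drg_screen), "categories\n")
  }
  if (length(x$prior_only)) {
    cat("  prior-only categories:", paste(x$prior_only, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Collect the diagnosis codes eligible as comorbidity evidence
#'
#' Projects a patient's admissions onto the (code, source, position) triples
#' that may contribute comorbidity evidence under a given period. The index
#' admission contributes its secondary diagnoses only — its principal
#' diagnosis defines the cohort condition and never counts as a comorbidity
#' for any method. Under \code{index_plus_prior}, admissions with
#' \code{admit_date} in \code{[index - 365 days, index)} contribute all
#' their diagnosis fields, principal included.
#'
#' @param admissions data.frame of the patient's admission rows (claims
#'   schema; may include the index row itself).
#' @param index a single-row data.frame: the patient's index admission.
#' @param period a [data_period()] (or its kind string).
#' @param method a [load_method()] object (kept in the signature for
#'   interface symmetry; eligibility does not depend on it).
#' @return data.frame with columns \code{code} (canonical ICD-9-CM),
#'   \code{source} (\code{"index"}/\code{"prior"}), \code{position}
#'   (\code{"principal"}/\code{"secondary"}).
#' @export
eligible_diagnoses <- function(admissions, index, period, method = NULL) {
  period <- as_data_period(period)
  stopifnot(nrow(index) == 1L)
  codes <- character(0); source <- character(0); position <- character(0)

  sec <- unlist(index[1, DX_COLS], use.names = FALSE)
  sec <- sec[!is.na(sec)]
  if (length(sec)) {
    codes <- c(codes, sec)
    source <- c(source, rep("index", length(sec)))
    position <- c(position, rep("secondary", length(sec)))
  }

  if (period$kind == "index_plus_prior" && nrow(admissions)) {
    lo <- index$admit_date[1] - period$lookback_days
    prior <- admissions[admissions$admit_date >= lo &
                          admissions$admit_date < index$admit_date[1], ,
                        drop = FALSE]
    if (nrow(prior)) {
      pr <- prior$principal_dx
      codes <- c(codes, pr)
      source <- c(source, rep("prior", length(pr)))
      position <- c(position, rep("principal", length(pr)))
      for (col in DX_COLS) {
        v <- prior[[col]]
        v <- v[!is.na(v)]
        if (length(v)) {
          codes <- c(codes, v)
          source <- c(source, rep("prior", length(v)))
          position <- c(position, rep("secondary", length(v)))
        }
      }
    }
  }
  data.frame(code = if (length(codes)) normalize_icd9(codes) else character(0),
             source = source, position = position,
             stringsAsFactors = FALSE)
}

#' Map eligible diagnoses to a binary comorbidity profile
#'
#' Applies one classification method's rules to a patient's eligible codes.
#' A category is flagged when some eligible code prefix-matches its code
#' list, subject to the method's comorbidity-versus-complication rule:
#' for Elixhauser, an index-sourced code is discounted when the index
#' admission's DRG is in that category's screen set (the condition may be a
#' complication of the reason for stay); prior-sourced codes bypass the
#' screen. For the Charlson variants, categories in the method's
#' prior-only set require at least one prior-sourced match. Hierarchy rules
#' then clear the milder category when its dominant partner is flagged.
#'
#' @param eligible output of [eligible_diagnoses()].
#' @param index_drg the index admission's DRG code (string).
#' @param method a [load_method()] object.
#' @param period a [data_period()]; recorded on the profile.
#' @return named logical vector over the method's categories (in method
#'   order), with attributes \code{method} and \code{period}.
#' @export
map_profile <- function(eligible, index_drg, method, period) {
  stopifnot(inherits(method, "comorbidity_method"))
  period <- as_data_period(period)
  flags <- stats::setNames(logical(length(method$categories)),
                           method$categories)
  if (nrow(eligible)) {
    for (cat in method$categories) {
      hit <- icd9_prefix_match(eligible$code, method$code_map[[cat]])
      if (!any(hit)) next
      src <- eligible$source[hit]
      if (!is.null(method$drg_screen) &&
          !is.null(method$drg_screen[[cat]]) &&
          index_drg %in% method$drg_screen[[cat]]) {
        # screened: only prior evidence survives
        if (!any(src == "prior")) next
      }
      if (cat %in% method$prior_only && !any(src == "prior")) next
      flags[[cat]] <- TRUE
    }
  }
  if (nrow(method$hierarchy)) {
    for (i in seq_len(nrow(method$hierarchy))) {
      dom <- method$hierarchy$dominant[i]
      sup <- method$hierarchy$suppressed[i]
      if (flags[[dom]]) flags[[sup]] <- FALSE
    }
  }
  attr(flags, "method") <- method$name
  attr(flags, "period") <- period$kind
  flags
}

#' Comorbidity profile matrix for a cohort
#'
#' Maps every cohort member under one (method, period) pair and stacks the
#' profiles into a binary patients-by-categories matrix, columns fixed to
#' the method's category order.
#'
#' @param cohort a cohort data.frame from [build_cohort()] (or any
#'   data.frame with \code{patient_id}, \code{admit_date},
#'   \code{drg} columns identifying the index admissions).
#' @param dataset the [claims_dataset()] the cohort was built from.
#' @param method a [load_method()] object.
#' @param period a [data_period()].
#' @return integer 0/1 matrix, one row per cohort entry (rownames =
#'   patient_id), one column per category.
#' @export
profile_matrix <- function(cohort, dataset, method, period) {
  stopifnot(inherits(dataset, "claims_dataset"),
            inherits(method, "comorbidity_method"))
  period <- as_data_period(period)
  adm_by_pat <- split(dataset$admissions,
                      dataset$admissions$patient_id)
  out <- matrix(0L, nrow = nrow(cohort), ncol = length(method$categories),
                dimnames = list(cohort$patient_id, method$categories))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    pat_adm <- adm_by_pat[[pid]]
    idx <- pat_adm[pat_adm$admit_date == cohort$admit_date[i] &
                     pat_adm$discharge_date == cohort$discharge_date[i] &
                     pat_adm$principal_dx == cohort$principal_dx[i], ,
                   drop = FALSE][1, , drop = FALSE]
    elig <- eligible_diagnoses(pat_adm, idx, period, method)
    out[i, ] <- as.integer(map_profile(elig, idx$drg[1], method, period))
  }
  out
}
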