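#' Canonicalize ICD-9-CM codes
#'
#' Strips decimal points and whitespace so that reference lists and claims
#' that differ only in decimal usage compare equal: \code{"410.71"} and
#' \code{"41071"} normalize to the same string. All code matching in the
#' package is prefix matching on these canonical forms, mirroring the
#' \code{"410.x"} convention used for disease families.
#'
#' @param code character vector of raw ICD-9-CM diagnosis or procedure codes.
#' @return character vector of decimal-free, upper-case canonical codes.
#' @examples
#' normalize_icd9(c("410.71", "41071", "V45.81"))
#' @export
normalize_icd9 <- function(code) {
  if (length(code) == 0L) return(character(0))
  code <- toupper(trimws(as.character(code)))
  if (any(!nzchar(code))) {
    stop("normalize_icd9: empty code", call. = FALSE)
  }
  out <- gsub(".", "", code, fixed = TRUE)
  bad <- grepl("[^0-9VE]", out)
  if (any(bad)) {
    stop("normalize_icd9: invalid characters in code(s): ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

# Prefix match of canonical codes against canonical reference prefixes.
# A reference entry "4280" matches "4280", "42800", ..., "42809".
icd9_prefix_match <- function(codes, prefixes) {
  if (length(codes) == 0L || length(prefixes) == 0L) {
    return(logical(length(codes)))
  }
  out <- logical(length(codes))
  for (p in prefixes) {
    out <- out | startsWith(codes, p)
  }
  out
}

DX_COLS <- paste0("dx", 1:4)
PROC_COLS <- paste0("proc", 1:3)
ADMISSION_COLS <- c("patient_id", "admit_date", "discharge_date",
                    "principal_dx", DX_COLS, PROC_COLS, "drg",
                    "discharge_alive")
PATIENT_COLS <- c("patient_id", "birth_date", "sex", "aborigine", "death_date")

parse_iso_date <- function(x, what, allow_na = FALSE) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(x)
  if (!allow_na) bad <- bad | is.na(x)
  if (any(bad)) {
    stop(sprintf("unparseable %s in row(s): %s", what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  d
}

#' Assemble and validate a claims dataset
#'
#' Bundles an admissions table and a patients table into a validated
#' \code{claims_dataset}. Every admission must link to exactly one patient;
#' admissions carry at most four secondary diagnoses and three procedures;
#' dates must satisfy \code{admit_date <= discharge_date} and, when present,
#' \code{death_date >= birth_date}. Fully duplicate admission rows are
#' dropped with a warning (claims extracts commonly contain resubmissions).
#'
#' @param admissions data.frame with columns \code{patient_id},
#'   \code{admit_date}, \code{discharge_date}, \code{principal_dx},
#'   \code{dx1..dx4}, \code{proc1..proc3}, \code{drg},
#'   \code{discharge_alive}. Dates may be \code{Date} or ISO-8601 strings.
#' @param patients data.frame with columns \code{patient_id},
#'   \code{birth_date}, \code{sex} (\code{"male"}/\code{"female"}),
#'   \code{aborigine} (logical), \code{death_date} (NA or empty = alive).
#' @return an object of class \code{claims_dataset}: a list with validated
#'   \code{admissions} and \code{patients} data.frames.
#' @seealso [read_claims()], [write_claims()]
#' @export
claims_dataset <- function(admissions, patients) {
  admissions <- as.data.frame(admissions, stringsAsFactors = FALSE)
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)

  missing_a <- setdiff(ADMISSION_COLS, names(admissions))
  if (length(missing_a)) {
    stop("admissions table lacks column(s): ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  extra_dx <- grep("^dx[0-9]+$", names(admissions), value = TRUE)
  extra_dx <- setdiff(extra_dx, DX_COLS)
  if (length(extra_dx)) {
    stop("admissions table has more than 4 secondary diagnosis columns (",
         paste(extra_dx, collapse = ", "),
         "); records carry at most 4 secondary diagnoses", call. = FALSE)
  }
  extra_pr <- setdiff(grep("^proc[0-9]+$", names(admissions), value = TRUE),
                      PROC_COLS)
  if (length(extra_pr)) {
    stop("admissions table has more than 3 procedure columns (",
         paste(extra_pr, collapse = ", "), ")", call. = FALSE)
  }
  missing_p <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing_p)) {
    stop("patients table lacks column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }

  admissions <- admissions[ADMISSION_COLS]
  patients <- patients[PATIENT_COLS]

  admissions$patient_id <- as.character(admissions$patient_id)
  admissions$admit_date <- parse_iso_date(admissions$admit_date, "admit_date")
  admissions$discharge_date <-
    parse_iso_date(admissions$discharge_date, "discharge_date")
  admissions$principal_dx <- as.character(admissions$principal_dx)
  for (col in c(DX_COLS, PROC_COLS)) {
    v <- as.character(admissions[[col]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    admissions[[col]] <- v
  }
  admissions$drg <- as.character(admissions$drg)
  admissions$discharge_alive <- as.logical(admissions$discharge_alive)

  bad <- which(!nzchar(admissions$principal_dx) | is.na(admissions$principal_dx))
  if (length(bad)) {
    stop("admissions with empty principal_dx in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(admissions$admit_date > admissions$discharge_date)
  if (length(bad)) {
    stop("admit_date after discharge_date in admission row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  dup <- duplicated(admissions)
  if (any(dup)) {
    warning(sum(dup), " fully duplicate admission row(s) dropped",
            call. = FALSE)
    admissions <- admissions[!dup, , drop = FALSE]
  }

  patients$patient_id <- as.character(patients$patient_id)
  patients$birth_date <- parse_iso_date(patients$birth_date, "birth_date")
  patients$sex <- as.character(patients$sex)
  if (!all(patients$sex %in% c("male", "female"))) {
    stop("patients$sex must be 'male' or 'female'", call. = FALSE)
  }
  patients$aborigine <- as.logical(patients$aborigine)
  patients$death_date <-
    parse_iso_date(patients$death_date, "death_date", allow_na = TRUE)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(patients$death_date) &
                 patients$death_date < patients$birth_date)
  if (length(bad)) {
    stop("death_date before birth_date for patient(s): ",
         paste(patients$patient_id[bad], collapse = ", "), call. = FALSE)
  }

  orphan <- setdiff(admissions$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop("admissions reference patient_id(s) absent from the patients ",
         "table: ", paste(sort(orphan), collapse = ", "), call. = FALSE)
  }

  rownames(admissions) <- NULL
  rownames(patients) <- NULL
  structure(list(admissions = admissions, patients = patients),
            class = "claims_dataset")
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat("  admissions:", nrow(x$admissions), "rows,",
      length(unique(x$admissions$patient_id)), "patients with claims\n")
  cat("  patients:  ", nrow(x$patients), "demographic records,",
      sum(!is.na(x$patients$death_date)), "deaths registered\n")
  invisible(x)
}

#' Read claims and demographics files
#'
#' Reads the two-CSV representation of a claims extract (admissions +
#' patients) and validates it into a [claims_dataset()]. Rows violating the
#' record invariants abort with a diagnostic naming the offending rows;
#' nothing is silently dropped except fully duplicate admission rows, which
#' are dropped with a warning.
#'
#' @param admissions_path,patients_path paths to the CSV files; see
#'   [claims_dataset()] for the column schema.
#' @return a validated \code{claims_dataset}.
#' @export
read_claims <- function(admissions_path, patients_path) {
  for (p in c(admissions_path, patients_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  adm <- utils::read.csv(admissions_path, colClasses = "character")
  pat <- utils::read.csv(patients_path, colClasses = "character")
  claims_dataset(adm, pat)
}

#' Write a claims dataset as CSV files
#'
#' Serializes a [claims_dataset()] as \code{admissions.csv} and
#' \code{patients.csv} with ISO-8601 dates, such that
#' \code{read_claims()} on the output reproduces the dataset field for
#' field.
#'
#' @param dataset a \code{claims_dataset}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named character vector of the two file paths.
#' @export
write_claims <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "claims_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  adm <- dataset$admissions
  pat <- dataset$patients
  adm$admit_date <- format(adm$admit_date, "%Y-%m-%d")
  adm$discharge_date <- format(adm$discharge_date, "%Y-%m-%d")
  pat$birth_date <- format(pat$birth_date, "%Y-%m-%d")
  pat$death_date <- ifelse(is.na(pat$death_date),
                           "", format(pat$death_date, "%Y-%m-%d"))
  paths <- c(admissions = file.path(out_dir, "admissions.csv"),
             patients = file.path(out_dir, "patients.csv"))
  utils::write.csv(adm, paths[["admissions"]], row.names = FALSE, na = "")
  utils::write.csv(pat, paths[["patients"]], row.names = FALSE, na = "")
  invisible(paths)
}

ref_path <- function(file) {
  p <- system.file("extdata", "comorbidity", file, package = "comorbidikit")
  if (!nzchar(p)) stop("bundled reference table not found: ", file,
                       call. = FALSE)
  p
}

read_ref_tsv <- function(file) {
  utils::read.delim(ref_path(file), colClasses = "character")
}
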