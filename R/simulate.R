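#' Configuration for the synthetic-claims generator
#'
#' Collects and validates every knob of the generator: cohort size, disease
#' family, demographic marginals, per-category latent comorbidity
#' prevalences, the logistic mortality model (coefficients on baseline
#' covariates and latent comorbidities, plus one intercept per outcome),
#' the prior-admission intensity, and the per-admission coding probability
#' (\code{carryover_prob}) that makes lookback periods informative: a latent
#' condition may be absent from the index claim yet present on a prior one.
#'
#' Age enters the mortality model in decades, centred at \code{age_mean},
#' so intercepts are interpretable as (logit) mortality for an average-aged
#' patient with no comorbidities.
#'
#' @param n_patients number of patients to generate.
#' @param disease \code{"AMI"} or \code{"COPD"} (sets the index
#'   principal-diagnosis family and DRG table).
#' @param age_mean,age_sd normal age distribution in years (clamped to
#'   18–110).
#' @param male_frac,aborigine_frac,surgery_frac Bernoulli fractions.
#' @param comorbidity_prevalences named numeric vector of latent
#'   prevalences; names must be categories of the bundled emission table.
#' @param mortality_coefficients named numeric vector of log-odds; names
#'   must be baseline covariates (\code{age}, \code{male},
#'   \code{aborigine}, \code{surgery}) or comorbidity category names.
#' @param mortality_intercepts length-2 numeric, names
#'   \code{in_hospital} and \code{one_year} (log-odds).
#' @param prior_admission_rate expected prior admissions per patient in the
#'   lookback year (Poisson).
#' @param carryover_prob probability a present latent comorbidity is coded
#'   on any given admission.
#' @param seed integer RNG seed.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients,
                              disease = c("AMI", "COPD"),
                              age_mean = 66.31, age_sd = 13.36,
                              male_frac = 0.72,
                              aborigine_frac = 0.018,
                              surgery_frac = 0.145,
                              comorbidity_prevalences = numeric(0),
                              mortality_coefficients = numeric(0),
                              mortality_intercepts =
                                c(in_hospital = -1.9, one_year = -1.1),
                              prior_admission_rate = 0.8,
                              carryover_prob = 0.7,
                              seed = 1L) {
  disease <- match.arg(disease)
  stopifnot(n_patients >= 1, age_sd >= 0)
  probs <- c(male_frac, aborigine_frac, surgery_frac, carryover_prob,
             comorbidity_prevalences)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(prior_admission_rate >= 0)
  emit <- generator_code_table()
  prev <- unlist(comorbidity_prevalences)
  unknown <- setdiff(names(prev), unique(emit$category))
  if (length(unknown)) {
    stop("comorbidity_prevalences name(s) not in the emission table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  coefs <- unlist(mortality_coefficients)
  known_keys <- c("age", "male", "aborigine", "surgery", names(prev))
  unknown <- setdiff(names(coefs), known_keys)
  if (length(unknown)) {
    stop("mortality_coefficients name(s) reference unknown covariates or ",
         "categories: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ic <- unlist(mortality_intercepts)
  stopifnot(all(c("in_hospital", "one_year") %in% names(ic)))
  structure(list(n_patients = as.integer(n_patients), disease = disease,
                 age_mean = age_mean, age_sd = age_sd,
                 male_frac = male_frac, aborigine_frac = aborigine_frac,
                 surgery_frac = surgery_frac,
                 comorbidity_prevalences = prev,
                 mortality_coefficients = coefs,
                 mortality_intercepts = ic[c("in_hospital", "one_year")],
                 prior_admission_rate = prior_admission_rate,
                 carryover_prob = carryover_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

generator_code_table <- function() {
  tab <- read_ref_tsv("generator_codes.tsv")
  tab$weight <- as.numeric(tab$weight)
  tab
}

#' Load a bundled or user simulation scenario
#'
#' Bundled scenarios: \code{"ami"} and \code{"copd"} (calibrated to the
#' demographic and mortality marginals typical of AMI and COPD inpatient
#' cohorts) and \code{"dominance"} (mortality driven in part by categories
#' only the Elixhauser classification observes; used for rank-order
#' checks). Any other string is treated as a path to a YAML file with the
#' same keys as [simulation_config()].
#'
#' @param scenario scenario name or YAML path.
#' @param n_patients,seed optional overrides of the file's values.
#' @return a [simulation_config()].
#' @export
load_scenario <- function(scenario, n_patients = NULL, seed = NULL) {
  bundled <- c("ami", "copd", "dominance")
  path <- if (scenario %in% bundled) {
    system.file("extdata", "scenarios", paste0(scenario, ".yaml"),
                package = "comorbidikit")
  } else scenario
  if (!file.exists(path)) stop("scenario not found: ", scenario, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$comorbidity_prevalences <- unlist(cfg$comorbidity_prevalences)
  cfg$mortality_coefficients <- unlist(cfg$mortality_coefficients)
  cfg$mortality_intercepts <- unlist(cfg$mortality_intercepts)
  if (!is.null(n_patients)) cfg$n_patients <- n_patients
  if (!is.null(seed)) cfg$seed <- seed
  do.call(simulation_config, cfg)
}

# sample a claim code for each (row, category) hit, using emission weights
sample_codes_for <- function(hits, categories, emit) {
  out <- matrix(NA_character_, nrow = nrow(hits), ncol = ncol(hits),
                dimnames = dimnames(hits))
  for (j in seq_along(categories)) {
    rows <- which(hits[, j])
    if (!length(rows)) next
    sub <- emit[emit$category == categories[j], ]
    out[rows, j] <- sample(sub$code, length(rows), replace = TRUE,
                           prob = sub$weight)
  }
  out
}

# collapse a row-wise code matrix into dx1..dx4 columns (cap 4, random keep)
pack_secondary <- function(code_mat, max_slots = 4L) {
  n <- nrow(code_mat)
  dx <- matrix(NA_character_, nrow = n, ncol = max_slots)
  counts <- rowSums(!is.na(code_mat))
  for (i in which(counts > 0L)) {
    v <- code_mat[i, !is.na(code_mat[i, ])]
    if (length(v) > max_slots) v <- sample(v, max_slots)
    dx[i, seq_along(v)] <- v
  }
  colnames(dx) <- paste0("dx", seq_len(max_slots))
  dx
}

#' Simulate a claims population with known ground truth
#'
#' Generates demographics, independent Bernoulli latent comorbidities, an
#' index admission in 2002 with a principal diagnosis from the configured
#' disease family and a DRG from the bundled disease-to-DRG table,
#' Poisson-distributed prior admissions inside the 1-year lookback window,
#' and deaths from the configured logistic model on baseline covariates and
#' latent comorbidities. Each admission's secondary-diagnosis slots (at
#' most 4) are filled by coding each latent condition with probability
#' \code{carryover_prob}; in-hospital deaths get a death date inside the
#' stay, other first-year deaths a date uniform between discharge and 365
#' days after admission. The run is fully determined by
#' \code{config$seed}.
#'
#' @param config a [simulation_config()].
#' @return list with \code{dataset} (a [claims_dataset()]),
#'   \code{ground_truth} (per-patient latent flags, generator covariates
#'   and realized outcome probabilities; generating coefficients in the
#'   \code{coefficients} attribute), and \code{config}.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  emit <- generator_code_table()
  cats <- names(config$comorbidity_prevalences)

  pid <- sprintf("P%06d", seq_len(n))
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18), 110)
  male <- stats::runif(n) < config$male_frac
  aborigine <- stats::runif(n) < config$aborigine_frac
  surgery <- stats::runif(n) < config$surgery_frac

  L <- matrix(FALSE, n, length(cats), dimnames = list(NULL, cats))
  for (j in seq_along(cats)) {
    L[, j] <- stats::runif(n) < config$comorbidity_prevalences[[j]]
  }

  # index admission
  year_start <- as.Date("2002-01-01")
  admit <- year_start + sample(0:333, n, replace = TRUE)  # Jan 1 - Nov 30
  los <- 2L + stats::rpois(n, 5)
  los <- pmin(los, as.integer(as.Date("2002-12-31") - admit))
  discharge <- admit + los

  dx_fams <- switch(config$disease,
    AMI = c("41001", "41041", "41071", "41091"),
    COPD = c("4910", "49121", "4928", "4940", "496"))
  principal <- sample(dx_fams, n, replace = TRUE)

  drg_tab <- read_ref_tsv("disease_drg_synthetic.tsv")
  drg_tab <- drg_tab[drg_tab$disease == config$disease, ]
  drg_tab$surgical <- as.logical(drg_tab$surgical)
  drg <- character(n)
  surg_drgs <- drg_tab$drg[drg_tab$surgical]
  med_drgs <- drg_tab$drg[!drg_tab$surgical]
  drg[surgery] <- sample(surg_drgs, sum(surgery), replace = TRUE)
  drg[!surgery] <- sample(med_drgs, sum(!surgery), replace = TRUE)

  if (length(cats)) {
    coded <- L & matrix(stats::runif(n * length(cats)) < config$carryover_prob,
                        n, length(cats))
    dx_idx <- pack_secondary(sample_codes_for(coded, cats, emit))
  } else {
    dx_idx <- pack_secondary(matrix(NA_character_, n, 0))
  }

  # mortality model: age in decades centred at the configured mean
  lp <- numeric(n)
  cf <- config$mortality_coefficients
  if ("age" %in% names(cf)) lp <- lp + cf[["age"]] * (age - config$age_mean) / 10
  if ("male" %in% names(cf)) lp <- lp + cf[["male"]] * male
  if ("aborigine" %in% names(cf)) lp <- lp + cf[["aborigine"]] * aborigine
  if ("surgery" %in% names(cf)) lp <- lp + cf[["surgery"]] * surgery
  for (cat in intersect(names(cf), cats)) lp <- lp + cf[[cat]] * L[, cat]

  p_ih <- stats::plogis(config$mortality_intercepts[["in_hospital"]] + lp)
  p_1y <- stats::plogis(config$mortality_intercepts[["one_year"]] + lp)
  died_ih <- stats::runif(n) < p_ih
  p_late <- pmax(0, (p_1y - p_ih) / (1 - p_ih))
  died_late <- !died_ih & (stats::runif(n) < p_late)

  death_date <- rep(as.Date(NA), n)
  if (any(died_ih)) {
    death_date[died_ih] <- admit[died_ih] +
      floor(stats::runif(sum(died_ih)) * (los[died_ih] + 1L))
  }
  if (any(died_late)) {
    span <- as.integer(admit[died_late] + 365L - discharge[died_late])
    death_date[died_late] <- discharge[died_late] + 1L +
      floor(stats::runif(sum(died_late)) * span)
  }

  admissions <- data.frame(
    patient_id = pid,
    admit_date = admit, discharge_date = discharge,
    principal_dx = principal, stringsAsFactors = FALSE)
  admissions <- cbind(admissions, as.data.frame(dx_idx,
                                                stringsAsFactors = FALSE))
  admissions$proc1 <- NA_character_
  admissions$proc2 <- NA_character_
  admissions$proc3 <- NA_character_
  admissions$drg <- drg
  admissions$discharge_alive <- !died_ih

  # prior admissions inside the lookback year
  k <- stats::rpois(n, config$prior_admission_rate)
  if (sum(k) > 0L) {
    owner <- rep(seq_len(n), k)
    m <- length(owner)
    p_admit <- admit[owner] - sample(30:365, m, replace = TRUE)
    p_los <- 1L + stats::rpois(m, 3)
    generic <- c("78609", "78900", "4659", "7807")
    p_principal <- sample(generic, m, replace = TRUE)
    if (length(cats)) {
      has_com <- rowSums(L[owner, , drop = FALSE]) > 0L
      use_com <- has_com & stats::runif(m) < 0.5
      for (i in which(use_com)) {
        av <- cats[L[owner[i], ]]
        cat <- if (length(av) == 1L) av else sample(av, 1L)
        sub <- emit[emit$category == cat, ]
        p_principal[i] <- sample(sub$code, 1L, prob = sub$weight)
      }
      p_coded <- L[owner, , drop = FALSE] &
        matrix(stats::runif(m * length(cats)) < config$carryover_prob,
               m, length(cats))
      p_dx <- pack_secondary(sample_codes_for(p_coded, cats, emit))
    } else {
      p_dx <- pack_secondary(matrix(NA_character_, m, 0))
    }
    prior <- data.frame(patient_id = pid[owner],
                        admit_date = p_admit,
                        discharge_date = p_admit + p_los,
                        principal_dx = p_principal,
                        stringsAsFactors = FALSE)
    prior <- cbind(prior, as.data.frame(p_dx, stringsAsFactors = FALSE))
    prior$proc1 <- NA_character_
    prior$proc2 <- NA_character_
    prior$proc3 <- NA_character_
    prior$drg <- "467"
    prior$discharge_alive <- TRUE
    prior <- prior[!duplicated(prior), , drop = FALSE]  # claim collisions
    admissions <- rbind(admissions, prior)
  }

  patients <- data.frame(
    patient_id = pid,
    birth_date = admit - round(age * 365.25),
    sex = ifelse(male, "male", "female"),
    aborigine = aborigine,
    death_date = death_date,
    stringsAsFactors = FALSE)

  gt <- data.frame(patient_id = pid,
                   age_years = age,
                   age_decades_centred = (age - config$age_mean) / 10,
                   male = male, aborigine = aborigine, surgery = surgery,
                   stringsAsFactors = FALSE)
  if (length(cats)) gt <- cbind(gt, as.data.frame(L * 1L))
  gt$p_in_hospital <- p_ih
  gt$p_one_year <- p_1y
  gt$died_in_hospital <- died_ih
  gt$died_within_1yr <- died_ih | died_late
  attr(gt, "coefficients") <- config$mortality_coefficients
  attr(gt, "intercepts") <- config$mortality_intercepts

  list(dataset = claims_dataset(admissions, patients),
       ground_truth = gt,
       config = config)
}

#' Cohort characteristics summary
#'
#' Count-and-percent summary of the cohort in the conventional layout for
#' inpatient study populations: male, aborigines, surgery, in-hospital
#' mortality, 1-year mortality, and mean ± SD age.
#'
#' @param dataset the source [claims_dataset()] (unused beyond interface
#'   symmetry; all fields summarized live on the cohort).
#' @param cohort a cohort data.frame from [build_cohort()].
#' @return data.frame with columns \code{characteristic}, \code{count},
#'   \code{percent} (NA for the age row), \code{mean}, \code{sd} (NA for
#'   count rows).
#' @export
table1_summary <- function(dataset, cohort) {
  n <- nrow(cohort)
  if (n == 0L) {
    warning("empty cohort; summary of zeros", call. = FALSE)
  }
  cnt <- function(x) if (n == 0L) 0L else sum(x)
  pct <- function(x) if (n == 0L) 0 else 100 * sum(x) / n
  rows <- c("male", "aborigines", "surgery",
            "in_hospital_mortality", "one_year_mortality")
  vals <- if (n == 0L) rep(list(logical(0)), 5) else
    list(cohort$male, cohort$aborigine, cohort$surgery,
         cohort$died_in_hospital, cohort$died_within_1yr)
  out <- data.frame(
    characteristic = c("n", rows, "age_years"),
    count = c(n, vapply(vals, cnt, numeric(1)), NA),
    percent = c(NA, vapply(vals, pct, numeric(1)), NA),
    mean = c(rep(NA, 6), if (n) mean(cohort$age_years) else NA),
    sd = c(rep(NA, 6),
           if (n == 0L) NA else if (n == 1L) 0
           else stats::sd(cohort$age_years)),
    stringsAsFactors = FALSE)
  out
}
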