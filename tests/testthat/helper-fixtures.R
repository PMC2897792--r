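# Hand-built claims fixtures and independent oracles used across test files.

adm_row <- function(patient_id, admit, discharge, principal,
                    dx = character(0), drg = "121", alive = TRUE) {
  dx <- c(dx, rep(NA_character_, 4 - length(dx)))
  data.frame(patient_id = patient_id, admit_date = admit,
             discharge_date = discharge, principal_dx = principal,
             dx1 = dx[1], dx2 = dx[2], dx3 = dx[3], dx4 = dx[4],
             proc1 = NA_character_, proc2 = NA_character_,
             proc3 = NA_character_,
             drg = drg, discharge_alive = alive,
             stringsAsFactors = FALSE)
}

pat_row <- function(patient_id, birth, sex = "male", aborigine = FALSE,
                    death = NA_character_) {
  data.frame(patient_id = patient_id, birth_date = birth, sex = sex,
             aborigine = aborigine, death_date = death,
             stringsAsFactors = FALSE)
}

# Three admissions over two patients; P1 has an index AMI stay plus a prior
# admission, P2 a single COPD stay.
toy_dataset <- function() {
  adm <- rbind(
    adm_row("P1", "2002-03-10", "2002-03-18", "41071",
            dx = c("4280", "25000"), drg = "121"),
    adm_row("P1", "2001-11-02", "2001-11-05", "5856", dx = "4019",
            drg = "467"),
    adm_row("P2", "2002-06-01", "2002-06-07", "4912", dx = "4280",
            drg = "88"))
  pat <- rbind(
    pat_row("P1", "1940-01-15", death = "2002-09-01"),
    pat_row("P2", "1935-06-30", sex = "female"))
  claims_dataset(adm, pat)
}

# Exhaustive pairwise concordance: the independent oracle for c_statistic.
brute_force_c <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  ev <- scores[y]; nv <- scores[!y]
  tot <- 0
  for (a in ev) for (b in nv) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ev) * length(nv))
}

# Direct likelihood maximization, independent of glm: the oracle for
# g2_statistic. Returns the maximized log-likelihood.
direct_loglik <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) {
    eta <- drop(X1 %*% b)
    -drop(t(X1) %*% (y - plogis(eta)))
  }
  fit <- optim(rep(0, ncol(X1)), nll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-15))
  -fit$value
}

# Rule-by-rule re-derivation of the mapping logic: the independent oracle
# for map_profile. Enumerates every (code, category) pair and applies the
# DRG screen / prior-only / hierarchy rules literally.
brute_force_profile <- function(eligible, index_drg, method, period) {
  flags <- setNames(rep(FALSE, length(method$categories)),
                    method$categories)
  for (cat in method$categories) {
    for (i in seq_len(nrow(eligible))) {
      code <- eligible$code[i]
      src <- eligible$source[i]
      matched <- FALSE
      for (p in method$code_map[[cat]]) {
        if (substr(code, 1, nchar(p)) == p) matched <- TRUE
      }
      if (!matched) next
      if (method$name == "elixhauser") {
        scr <- method$drg_screen[[cat]]
        if (!is.null(scr) && (index_drg %in% scr) && src == "index") next
      } else if (cat %in% method$prior_only && src == "index") {
        next
      }
      flags[cat] <- TRUE
    }
  }
  for (i in seq_len(nrow(method$hierarchy))) {
    if (flags[[method$hierarchy$dominant[i]]]) {
      flags[[method$hierarchy$suppressed[i]]] <- FALSE
    }
  }
  flags
}

# Random small claims fixture: n patients, each with an index admission and
# 0-2 prior admissions carrying random codes from a mixed pool.
random_small_dataset <- function(n_patients, code_pool, drg_pool) {
  adm <- list(); pat <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("R%02d", i)
    idx_admit <- as.Date("2002-01-01") + sample(0:300, 1)
    n_dx <- sample(0:3, 1)
    adm[[length(adm) + 1L]] <- adm_row(
      pid, format(idx_admit), format(idx_admit + sample(1:10, 1)),
      "41011", dx = sample(code_pool, n_dx), drg = sample(drg_pool, 1))
    for (k in seq_len(sample(0:2, 1))) {
      p_admit <- idx_admit - sample(1:500, 1)
      adm[[length(adm) + 1L]] <- adm_row(
        pid, format(p_admit), format(p_admit + sample(1:5, 1)),
        sample(code_pool, 1), dx = sample(code_pool, sample(0:3, 1)),
        drg = "467")
    }
    pat[[length(pat) + 1L]] <- pat_row(pid, "1940-01-01")
  }
  claims_dataset(do.call(rbind, adm), do.call(rbind, pat))
}

# Code pool mixing codes recognized by all/some/none of the methods.
mixed_code_pool <- c("4280", "4254", "25000", "2504", "5856", "4019",
                     "42731", "2762", "2866", "1970", "1629", "3310",
                     "4400", "78900", "V4581", "496", "2809", "042")
screen_drg_pool <- c("121", "127", "138", "296", "467")
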