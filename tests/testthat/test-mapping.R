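deyo <- load_method("charlson_deyo")
romano <- load_method("charlson_romano")
elix <- load_method("elixhauser")

test_that("the three methods expose 17, 17 and 30 categories", {
  expect_length(deyo$categories, 17L)
  expect_length(romano$categories, 17L)
  expect_length(elix$categories, 30L)
  expect_null(deyo$drg_screen)
  expect_null(romano$drg_screen)
  expect_true(length(elix$drg_screen) > 0L)
  expect_error(load_method("foo"), "unknown comorbidity method")
})

test_that("eligibility projects index secondaries and lookback admissions", {
  adm <- rbind(
    adm_row("P1", "2002-06-01", "2002-06-08", "41071", dx = "4280"),
    adm_row("P1", "2001-09-01", "2001-09-04", "5856", dx = "42731"),
    adm_row("P1", "2001-04-01", "2001-04-04", "4912"))  # 426 days before
  d <- claims_dataset(adm, pat_row("P1", "1940-01-01"))
  idx <- d$admissions[1, ]

  e1 <- eligible_diagnoses(d$admissions, idx, "index_only", deyo)
  expect_equal(e1$code, "4280")
  expect_equal(e1$source, "index")
  expect_equal(e1$position, "secondary")

  e2 <- eligible_diagnoses(d$admissions, idx, "index_plus_prior", deyo)
  # the 426-day-old admission contributes nothing; the index principal never
  # appears as comorbidity evidence
  expect_setequal(e2$code, c("4280", "5856", "42731"))
  expect_false("41071" %in% e2$code)
  expect_equal(sort(unique(e2$source)), c("index", "prior"))
})

test_that("the Elixhauser DRG screen discounts index-sourced codes only", {
  chf_screen_drg <- elix$drg_screen[["chf"]][1]
  e_index <- data.frame(code = "4280", source = "index",
                        position = "secondary")
  e_prior <- data.frame(code = "4280", source = "prior",
                        position = "secondary")
  expect_false(map_profile(e_index, chf_screen_drg, elix, "index_only")[["chf"]])
  expect_true(map_profile(e_prior, chf_screen_drg, elix,
                          "index_plus_prior")[["chf"]])
  # an unrelated index DRG does not screen
  expect_true(map_profile(e_index, "121", elix, "index_only")[["chf"]])
})

test_that("hierarchy clears the milder category when both are present", {
  e <- data.frame(code = c("2504", "2500"), source = "index",
                  position = "secondary")
  f <- map_profile(e, "121", deyo, "index_only")
  expect_true(f[["dm_comp"]])
  expect_false(f[["dm"]])
  f2 <- map_profile(e[2, ], "121", deyo, "index_only")
  expect_true(f2[["dm"]])

  fe <- map_profile(data.frame(code = c("1970", "1629"), source = "index",
                               position = "secondary"), "121", elix,
                    "index_only")
  expect_true(fe[["mets"]])
  expect_false(fe[["solid_tumor"]])
})

test_that("no eligible codes yields an all-false profile with full schema", {
  empty <- data.frame(code = character(0), source = character(0),
                      position = character(0))
  for (m in list(deyo, romano, elix)) {
    f <- map_profile(empty, "121", m, "index_only")
    expect_identical(names(f), m$categories)
    expect_false(any(f))
  }
})

test_that("the complication-prone prior rule needs prior evidence", {
  deyo_strict <- load_method("charlson_deyo",
                             prior_rule = "complication_prone")
  e_index <- data.frame(code = "4280", source = "index",
                        position = "secondary")
  e_prior <- data.frame(code = "4280", source = "prior",
                        position = "secondary")
  expect_false(map_profile(e_index, "121", deyo_strict,
                           "index_only")[["chf"]])
  expect_true(map_profile(e_prior, "121", deyo_strict,
                          "index_plus_prior")[["chf"]])
  # the default rule counts index evidence
  expect_true(map_profile(e_index, "121", deyo, "index_only")[["chf"]])
})

test_that("profile matrices have method-ordered columns and toy shapes", {
  d <- toy_dataset()
  cohort <- build_cohort(d, disease_definition("AMI"))
  m17 <- profile_matrix(cohort, d, romano, "index_only")
  expect_equal(dim(m17), c(1L, 17L))
  expect_identical(colnames(m17), romano$categories)
  m30 <- profile_matrix(cohort, d, elix, "index_only")
  expect_equal(dim(m30), c(1L, 30L))
  # P1 index carries CHF (4280) and uncomplicated diabetes (25000)
  expect_equal(unname(m17[1, c("chf", "dm")]), c(1L, 1L))
})

test_that("an index admission without secondary codes maps to a zero row", {
  adm <- adm_row("P1", "2002-05-01", "2002-05-06", "41001")
  d <- claims_dataset(adm, pat_row("P1", "1940-01-01"))
  cohort <- build_cohort(d, disease_definition("AMI"))
  m <- profile_matrix(cohort, d, elix, "index_only")
  expect_equal(sum(m), 0L)
})

test_that("index-only flags are a subset of index-plus-prior flags", {
  set.seed(77)
  for (rep in 1:6) {
    d <- random_small_dataset(8, mixed_code_pool, screen_drg_pool)
    cohort <- build_cohort(d, disease_definition("AMI"))
    for (m in list(deyo, romano, elix,
                   load_method("charlson_romano",
                               prior_rule = "complication_prone"))) {
      p1 <- profile_matrix(cohort, d, m, "index_only")
      p2 <- profile_matrix(cohort, d, m, "index_plus_prior")
      expect_true(all(p2 - p1 >= 0L))
    }
  }
})

test_that("mapping is deterministic and idempotent", {
  d <- random_small_dataset(5, mixed_code_pool, screen_drg_pool)
  cohort <- build_cohort(d, disease_definition("AMI"))
  a <- profile_matrix(cohort, d, elix, "index_plus_prior")
  b <- profile_matrix(cohort, d, elix, "index_plus_prior")
  expect_identical(a, b)
})

test_that("map_profile agrees with the brute-force rule evaluator", {
  set.seed(101)
  methods <- list(deyo, romano, elix,
                  load_method("charlson_deyo",
                              prior_rule = "complication_prone"))
  for (rep in 1:12) {
    d <- random_small_dataset(5, mixed_code_pool, screen_drg_pool)
    cohort <- build_cohort(d, disease_definition("AMI"))
    adm_by_pat <- split(d$admissions, d$admissions$patient_id)
    for (m in methods) for (p in c("index_only", "index_plus_prior")) {
      for (i in seq_len(nrow(cohort))) {
        pa <- adm_by_pat[[cohort$patient_id[i]]]
        idx <- pa[pa$admit_date == cohort$admit_date[i] &
                    pa$principal_dx == cohort$principal_dx[i], ][1, ]
        e <- eligible_diagnoses(pa, idx, p, m)
        got <- map_profile(e, idx$drg, m, p)
        want <- brute_force_profile(e, idx$drg, m, p)
        expect_identical(names(got), names(want))
        expect_equal(as.logical(got), as.logical(want))
      }
    }
  }
})
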