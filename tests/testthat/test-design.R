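test_that("segmented time-series codings follow the published scheme", {
  # first study year, unexposed: trend origin, exposure block all zero
  t1 <- its_terms(2008, "no_low", 2014, 2008)
  expect_equal(unname(t1), c(0, 0, 0, 0, 0, 0, 0))
  # year after the event, high exposure
  t2 <- its_terms(2015, "high", 2014, 2008)
  expect_equal(t2[["T"]], 7)
  expect_equal(t2[["E_h"]], 1)
  expect_equal(t2[["E_h:I_post"]], 1)
  expect_equal(t2[["E_h:I_post:T_post"]], 1)
  expect_equal(t2[["E_m"]] + t2[["E_m:I_post"]] + t2[["E_m:I_post:T_post"]], 0)
  # last pre-event year, moderate exposure
  t3 <- its_terms(2013, "moderate", 2014, 2008)
  expect_equal(t3[["T"]], 5)
  expect_equal(t3[["E_m"]], 1)
  expect_equal(t3[["E_m:I_post"]], 0)
  expect_equal(t3[["E_m:I_post:T_post"]], 0)
  # event year itself: level shift on, post-trend still zero
  t4 <- its_terms(2014, "moderate", 2014, 2008)
  expect_equal(t4[["E_m:I_post"]], 1)
  expect_equal(t4[["E_m:I_post:T_post"]], 0)
  expect_error(its_terms(2014, "severe", 2014, 2008), "exposure group")
})

test_that("ITS invariants hold across the whole grid", {
  for (year in 2008:2018)
    for (g in c("no_low", "moderate", "high")) {
      v <- its_terms(year, g, 2014, 2008)
      expect_equal(v[["E_m"]] * v[["E_h"]], 0)          # groups exclusive
      if (year < 2014) {                                 # I_post=0 => T_post=0
        expect_equal(v[["E_m:I_post:T_post"]], 0)
        expect_equal(v[["E_h:I_post:T_post"]], 0)
      }
      if (g == "no_low") expect_equal(sum(v) - v[["T"]], 0)
    }
})

make_one_school_tables <- function(group = "no_low") {
  obs <- data.frame(school_id = "S001", domain = "Writing", grade = 3,
                    year = 2008:2018, mean = 0, se = 1, n = 10,
                    centred = TRUE)
  obs$cohort_id <- assign_cohort(obs$year, obs$grade)
  prof <- data.frame(school_id = "S001", year = 2008:2018, icsea = 960,
                     enrolments = 100, prop_girls = 0.49,
                     sector = "government", school_type = "primary",
                     exposure_group = group)
  list(obs = obs, prof = prof)
}

test_that("per-school design rows match the hand-computed ITS block", {
  # one school per exposure group so all seven columns are identifiable
  obs <- do.call(rbind, lapply(c("S001", "S002", "S003"), function(id) {
    o <- make_one_school_tables()$obs
    o$school_id <- id
    o
  }))
  prof <- do.call(rbind, Map(function(id, g) {
    p <- make_one_school_tables(g)$prof
    p$school_id <- id
    p
  }, c("S001", "S002", "S003"), c("no_low", "moderate", "high")))
  d <- build_design(obs, prof, domain = "Writing", event_year = 2014)
  expect_equal(nrow(d$X), 33)
  high_rows <- d$data$school_id == "S003"
  expected <- cbind(
    T = 0:10,
    E_h = rep(1, 11),
    `E_h:I_post` = c(rep(0, 6), rep(1, 5)),
    `E_h:I_post:T_post` = c(rep(0, 7), 1, 2, 3, 4))
  ord <- order(d$data$year[high_rows])
  for (cn in colnames(expected))
    expect_equal(unname(d$X[high_rows, cn][ord]), unname(expected[, cn]))
  mod_rows <- d$data$school_id == "S002"
  expect_equal(unname(d$X[mod_rows, "E_m:I_post"][ord]),
               c(rep(0, 6), rep(1, 5)))
  expect_true(all(d$X[d$data$school_id == "S001",
                      c("E_m", "E_h", "E_m:I_post", "E_h:I_post")] == 0))
})

test_that("all-control studies drop the exposure block entirely", {
  study <- generate_study(
    sim_config(n_schools_by_group = c(no_low = 10, moderate = 1, high = 1),
               domains = "Writing", seed = 31))
  obs <- center_scores(study$observations, study$reference)
  keep_ids <- unique(study$profiles$school_id[
    study$profiles$exposure_group == "no_low"])
  obs <- obs[obs$school_id %in% keep_ids, ]
  d <- build_design(obs, study$profiles, domain = "Writing")
  expect_true(all(c("E_m", "E_h", "E_m:I_post", "E_h:I_post") %in%
                    d$dropped_columns))
  expect_true(all(c("(Intercept)", "T", "icsea") %in% colnames(d$X)))
})

test_that("identical covariates give identical design rows", {
  tabs <- make_one_school_tables()
  obs <- rbind(tabs$obs[1, ], tabs$obs[1, ])
  d <- build_design(obs, tabs$prof, domain = "Writing")
  expect_equal(d$X[1, ], d$X[2, ])
})

test_that("design is invariant to row order up to permutation", {
  study <- generate_study(small_config(seed = 32))
  obs <- center_scores(study$observations, study$reference)
  d1 <- build_design(obs, study$profiles, domain = "Writing")
  set.seed(1)
  perm <- sample(nrow(obs))
  d2 <- build_design(obs[perm, ], study$profiles, domain = "Writing")
  back <- order(perm)
  expect_equal(d2$X[back, ], d1$X)
  expect_equal(d2$y[back], d1$y)
  expect_equal(d2$school_levels[d2$school_index[back]],
               d1$school_levels[d1$school_index])
})

test_that("covariate scaling back-transforms to raw-scale coefficients", {
  study <- generate_study(small_config(seed = 33))
  obs <- center_scores(study$observations, study$reference)
  ds <- build_design(obs, study$profiles, domain = "Writing",
                     scale_covariates = TRUE)
  dr <- build_design(obs, study$profiles, domain = "Writing",
                     scale_covariates = FALSE)
  w <- 1 / ds$se^2
  fs <- lm(ds$y ~ 0 + ds$X, weights = w)
  fr <- lm(dr$y ~ 0 + dr$X, weights = w)
  for (k in seq_len(nrow(ds$scaling))) {
    cn <- ds$scaling$column[k]
    expect_equal(unname(coef(fs)[paste0("ds$X", cn)]) / ds$scaling$scale[k],
                 unname(coef(fr)[paste0("dr$X", cn)]), tolerance = 1e-8)
  }
})

test_that("join failures and collinear columns are reported by name", {
  tabs <- make_one_school_tables()
  expect_error(build_design(tabs$obs, tabs$prof[tabs$prof$year > 2010, ],
                            domain = "Writing"),
               "S001 2008")
  # LOCF: later observation years reuse the last profile row
  d <- build_design(tabs$obs[tabs$obs$year >= 2012, ],
                    tabs$prof[tabs$prof$year <= 2012, ], domain = "Writing")
  expect_equal(nrow(d$X), 7)

  prof2 <- tabs$prof
  prof2$enrolments <- prof2$icsea  # collinear after scaling
  tabs$obs$year <- 2008:2018       # vary icsea so the columns survive
  prof2$icsea <- 900 + seq_len(11)
  prof2$enrolments <- prof2$icsea
  expect_error(build_design(tabs$obs, prof2, domain = "Writing"),
               "collinear")

  expect_error(build_design(tabs$obs, tabs$prof, domain = "Maths"),
               "no observations")
  study <- generate_study(small_config(seed = 34,
                                       domains = c("Writing", "Reading")))
  obs <- center_scores(study$observations, study$reference)
  expect_error(build_design(obs, study$profiles), "2 domains")
})
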