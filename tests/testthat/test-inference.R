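mk_records <- function(n_animal = 8, seasons = c("summer", "winter"),
                       years = 2007:2008, herds = c("h1", "h2"),
                       season_effect = 0, sd = 0.3, kind = "spatial_strength") {
  grid <- expand.grid(
    animal = seq_len(n_animal), season = seasons, year = years,
    stringsAsFactors = FALSE
  )
  herd <- herds[(grid$animal - 1) %% length(herds) + 1]
  tibble::tibble(
    animal_id = sprintf("%s_a%02d", herd, grid$animal),
    herd = herd,
    season = factor(grid$season, levels = c("summer", "winter")),
    year = as.integer(grid$year),
    year_pair = NA_character_,
    kind = kind,
    value = exp(rnorm(nrow(grid), 0, sd) +
                  ifelse(grid$season == "winter", season_effect, 0))
  )
}

test_that("the summer home-range outlier rule removes animals everywhere", {
  rec <- dplyr::bind_rows(
    tibble::tibble(animal_id = "big", herd = "h1",
                   season = factor(c("summer", "winter"), levels = c("summer", "winter")),
                   year = 2007L, year_pair = NA_character_,
                   kind = "hr_area_km2", value = c(5000, 100)),
    tibble::tibble(animal_id = "big", herd = "h1",
                   season = factor("winter", levels = c("summer", "winter")),
                   year = 2007L, year_pair = NA_character_,
                   kind = "spatial_strength", value = 1),
    tibble::tibble(animal_id = "ok", herd = "h1",
                   season = factor("summer", levels = c("summer", "winter")),
                   year = 2007L, year_pair = NA_character_,
                   kind = "hr_area_km2", value = 3000)
  )
  out <- suppressMessages(filter_outliers(rec))
  # every record of the offending animal is gone, other animals untouched
  expect_false("big" %in% out$animal_id)
  expect_true("ok" %in% out$animal_id)
  expect_equal(attr(out, "dropped"), "big")

  # below-threshold data pass through unchanged
  expect_equal(nrow(filter_outliers(rec[rec$animal_id == "ok", ])), 1)

  # a winter-only exceedance is retained: the rule keys on summer ranges
  rec_w <- tibble::tibble(animal_id = "w", herd = "h1",
                          season = factor("winter", levels = c("summer", "winter")),
                          year = 2007L, year_pair = NA_character_,
                          kind = "hr_area_km2", value = 6000)
  expect_equal(nrow(filter_outliers(rec_w)), 1)
})

test_that("the log transform is zero-safe, monotone and errors on negatives", {
  expect_equal(log_transform(1, offset = 0), 0)
  expect_true(is.finite(log_transform(0, offset = 0.01)))
  v <- c(0, 0.2, 1, 5)
  expect_equal(order(log_transform(v)), order(v))
  # default offset: half the minimum positive value
  expect_equal(log_transform(c(0, 4), offset = NULL), log(c(0, 4) + 2))
  expect_error(log_transform(-1), "non-negative")
  expect_error(log_transform(0, offset = 0), "-Inf")
})

test_that("balanced two-season fits reproduce the OLS season contrast", {
  set.seed(17)
  rec <- mk_records(n_animal = 10, season_effect = 0.8, sd = 0.2)
  df <- rec
  df$resp <- log(df$value)
  fit <- suppressMessages(
    fit_lmm(df, resp ~ season + (1 | herd) + (1 | herd:animal_id) + (1 | year)))
  td <- tidy(fit, effects = "fixed")
  beta <- unname(td$estimate[td$term == "seasonwinter"])
  ols <- mean(df$resp[df$season == "winter"]) - mean(df$resp[df$season == "summer"])
  expect_equal(beta, ols, tolerance = 1e-6)
})

test_that("a null season effect is estimated near zero", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    # ten collared animals per herd, the study-scale sampling condition
    rec <- mk_records(n_animal = 10, season_effect = 0, sd = 0.4)
    df <- rec
    df$resp <- log(df$value)
    fit <- suppressMessages(
      fit_lmm(df, resp ~ season + (1 | herd) + (1 | herd:animal_id) + (1 | year)))
    td <- tidy(fit, effects = "fixed")
    b <- td[td$term == "seasonwinter", ]
    if (abs(b$estimate) < 2 * b$std.error) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("adding a constant shifts only the intercept", {
  set.seed(19)
  rec <- mk_records(n_animal = 8, season_effect = 0.5)
  df <- rec
  df$resp <- log(df$value)
  f <- resp ~ season + (1 | herd) + (1 | herd:animal_id) + (1 | year)
  t1 <- tidy(suppressMessages(fit_lmm(df, f)), effects = "fixed")
  df2 <- df
  df2$resp <- df$resp + 5
  t2 <- tidy(suppressMessages(fit_lmm(df2, f)), effects = "fixed")
  expect_equal(t2$estimate[t2$term == "(Intercept)"],
               t1$estimate[t1$term == "(Intercept)"] + 5, tolerance = 1e-6)
  expect_equal(t2$estimate[t2$term == "seasonwinter"],
               t1$estimate[t1$term == "seasonwinter"], tolerance = 1e-6)
})

test_that("variance components are reported and near-zero ones tolerated", {
  set.seed(23)
  rec <- mk_records(n_animal = 10, season_effect = 0.5, sd = 0.2)
  df <- rec
  df$resp <- log(df$value)
  fit <- suppressMessages(
    fit_lmm(df, resp ~ season + (1 | herd) + (1 | herd:animal_id) + (1 | year)))
  vc <- tidy(fit, effects = "ran_pars")
  expect_true(all(vc$estimate >= 0))
  expect_true("Residual" %in% vc$term)
  g <- glance(fit)
  expect_true(is.logical(g$singular))
  expect_equal(g$p_method, "Satterthwaite")
})

test_that("the model suite demands complete responses and valid pairing", {
  rec <- mk_records()
  expect_error(run_model_suite(rec), "missing response kind")

  # unpaired observed/null strengths are rejected
  full <- dplyr::bind_rows(
    mk_records(kind = "spatial_strength"),
    mk_records(kind = "hr_area_km2"),
    mk_records(kind = "social_strength_observed"),
    mk_records(n_animal = 4, kind = "social_strength_null_mean"),
    dplyr::mutate(mk_records(kind = "fidelity_udoi"),
                  year_pair = "2007-2008", year = NA_integer_)
  )
  expect_error(run_model_suite(full), "paired")
})

test_that("the four-model suite runs and recovers planted directions", {
  set.seed(29)
  nul <- mk_records(kind = "social_strength_null_mean", season_effect = 0.3)
  obs <- nul
  obs$kind <- "social_strength_observed"
  # observed exceeds null in winter only (the conspecific-attraction signature)
  obs$value <- obs$value * ifelse(obs$season == "winter", 3, 1)
  full <- dplyr::bind_rows(
    dplyr::mutate(mk_records(kind = "fidelity_udoi", season_effect = -1.5),
                  year_pair = paste0(year, "-", year + 1), year = NA_integer_),
    mk_records(kind = "spatial_strength", season_effect = 1),
    mk_records(kind = "hr_area_km2", season_effect = 0.6),
    obs, nul
  )
  suite <- suppressMessages(run_model_suite(full))
  td <- tidy(suite, effects = "fixed")
  b <- function(model, term) td$estimate[td$model == model & td$term == term]
  expect_lt(b("fidelity", "seasonwinter"), 0)
  expect_gt(b("spatial", "seasonwinter"), 0)
  expect_gt(b("social", "seasonwinter"), 0)
  expect_gt(b("social", "seasonwinter:sourceobserved"), 0)
  expect_gt(b("area", "seasonwinter"), 0)
  g <- glance(suite)
  expect_equal(nrow(g), 4)
  expect_setequal(g$model, c("fidelity", "spatial", "social", "area"))
})
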