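#' Assemble the long analysis-record table
#'
#' Binds the per-animal responses produced by the upstream stages into one
#' long tibble with a `kind` column, the shape consumed by
#' [filter_outliers()] and [run_model_suite()]. Kinds: `fidelity_udoi`
#' (keyed by `year_pair`), `spatial_strength`, `social_strength_observed`,
#' `social_strength_null_mean`, `hr_area_km2`.
#'
#' @param social A `pbsn` object (observed social networks).
#' @param spatial A `spatial_network` object.
#' @param fidelity A tibble from [site_fidelity()].
#' @param areas A tibble from [home_range_areas()].
#' @param ensemble Optionally, a `pbsn_ensemble`; contributes the
#'   per-animal null-mean strengths.
#' @return A long tibble with columns `animal_id`, `herd`, `season`,
#'   `year`, `year_pair`, `kind`, `value`.
#' @export
assemble_records <- function(social = NULL, spatial = NULL, fidelity = NULL,
                             areas = NULL, ensemble = NULL) {
  rec <- list()
  add <- function(df, kind, value_col, year_col = "year") {
    tibble::tibble(
      animal_id = df$animal_id,
      herd = as.character(df$herd),
      season = factor(as.character(df$season), levels = c("summer", "winter")),
      year = if (year_col == "year") as.integer(df$year) else NA_integer_,
      year_pair = if (year_col == "year_pair") as.character(df$year_pair) else NA_character_,
      kind = kind,
      value = as.numeric(df[[value_col]])
    )
  }
  if (!is.null(social)) {
    rec[[length(rec) + 1]] <- add(social$strength, "social_strength_observed", "strength")
  }
  if (!is.null(spatial)) {
    rec[[length(rec) + 1]] <- add(spatial$strength, "spatial_strength", "spatial_strength")
  }
  if (!is.null(fidelity) && nrow(fidelity) > 0) {
    rec[[length(rec) + 1]] <- add(fidelity, "fidelity_udoi", "udoi", year_col = "year_pair")
  }
  if (!is.null(areas)) {
    rec[[length(rec) + 1]] <- add(areas, "hr_area_km2", "area_km2")
  }
  if (!is.null(ensemble)) {
    td <- tidy(ensemble)
    rec[[length(rec) + 1]] <- add(td, "social_strength_null_mean", "null_mean")
  }
  if (length(rec) == 0) rlang::abort("no responses supplied")
  dplyr::bind_rows(rec)
}

#' Remove animals with implausibly large summer home ranges
#'
#' Any animal with a summer home-range area above `threshold` km2 is removed
#' from *all* analyses: every record of that animal, for every response
#' kind, is dropped. Winter-only exceedances are retained; the rule keys on
#' summer areas only.
#'
#' @param records Long record tibble from [assemble_records()].
#' @param threshold Area threshold in km2 (default 4,000).
#' @return The filtered records; dropped animal ids are attached as
#'   `attr(, "dropped")`.
#' @export
filter_outliers <- function(records, threshold = 4000) {
  bad <- records |>
    dplyr::filter(.data$kind == "hr_area_km2",
                  .data$season == "summer",
                  .data$value > threshold) |>
    dplyr::pull(.data$animal_id) |>
    unique()
  out <- dplyr::filter(records, !.data$animal_id %in% bad)
  attr(out, "dropped") <- bad
  if (length(bad) > 0) {
    rlang::inform(glue::glue(
      "filter_outliers: removed {length(bad)} animal(s) with summer home range > {threshold} km2"
    ))
  }
  out
}

#' Zero-safe log transform
#'
#' `log(value + offset)`. The default offset is half the minimum positive
#' value of the input, a scale-respecting choice that keeps exact zeros
#' finite while perturbing positive values by at most a factor of 1.5 at the
#' minimum. Monotone, so record ordering is preserved.
#'
#' @param value Non-negative numeric vector.
#' @param offset Non-negative scalar; `NULL` for the default.
#' @return The transformed vector.
#' @export
log_transform <- function(value, offset = NULL) {
  if (any(value < 0, na.rm = TRUE)) {
    rlang::abort("log_transform requires non-negative values")
  }
  if (is.null(offset)) {
    pos <- value[value > 0 & !is.na(value)]
    offset <- if (length(pos) > 0) min(pos) / 2 else 1
  }
  if (offset == 0 && any(value == 0, na.rm = TRUE)) {
    rlang::abort("offset 0 with zero values would produce -Inf")
  }
  log(value + offset)
}

# Drop random-intercept terms whose grouping factor has a single observed
# level (unidentifiable variance); returns the pruned formula.
prune_random_formula <- function(formula, data) {
  fixed <- deparse1(lme4::nobars(formula))
  bars <- lme4::findbars(formula)
  keep <- character(0)
  dropped <- character(0)
  for (b in bars) {
    gvars <- all.vars(b[[3]])
    f <- do.call(interaction, c(as.list(data[gvars]), drop = TRUE))
    term <- paste0("(", deparse1(b), ")")
    if (nlevels(f) >= 2) keep <- c(keep, term) else dropped <- c(dropped, term)
  }
  if (length(keep) == 0) {
    rlang::abort("all random-effect grouping factors have a single level; cannot fit a mixed model")
  }
  if (length(dropped) > 0) {
    rlang::inform(glue::glue(
      "dropping single-level random term(s): {paste(dropped, collapse = ', ')}"
    ))
  }
  list(
    formula = stats::as.formula(paste(fixed, "+", paste(keep, collapse = " + "))),
    dropped = dropped
  )
}

#' Fit one seasonal linear mixed model
#'
#' REML Gaussian fit via `lmerTest` (Satterthwaite degrees of freedom for
#' p-values). Near-singular variance components are tolerated and flagged
#' rather than treated as failures; random terms whose grouping factor has a
#' single observed level are dropped with a message.
#'
#' @param data A model data frame.
#' @param formula An lmer formula.
#' @return An object of class `pbsn_lmm` wrapping the fit with convergence
#'   and singularity flags.
#' @export
fit_lmm <- function(data, formula) {
  pr <- prune_random_formula(formula, data)
  formula <- pr$formula
  msgs <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(formula, data = data, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  structure(
    list(
      fit = fit,
      formula = formula,
      converged = length(fit@optinfo$conv$lme4$messages) == 0,
      singular = lme4::isSingular(fit),
      dropped_random = pr$dropped,
      messages = msgs,
      p_method = "Satterthwaite"
    ),
    class = "pbsn_lmm"
  )
}

#' @export
print.pbsn_lmm <- function(x, ...) {
  cat(glue::glue(
    "<pbsn_lmm> {deparse(x$formula)}",
    "{if (!x$converged) ' [did not converge]' else ''}",
    "{if (x$singular) ' [singular fit]' else ''}"
  ), "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a mixed-model fit
#'
#' @param x A `pbsn_lmm`.
#' @param effects `"fixed"`, `"ran_pars"`, or both.
#' @param ... Unused.
#' @return Fixed-effect rows carry `estimate`, `std.error`, `statistic`
#'   (t), `df`, `p.value` (Satterthwaite); variance-component rows carry
#'   `estimate` (variance) and `std.dev`.
#' @export
tidy.pbsn_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    co <- stats::coef(summary(x$fit))
    out$fixed <- tibble::tibble(
      effect = "fixed",
      term = rownames(co),
      estimate = co[, "Estimate"],
      std.error = co[, "Std. Error"],
      df = co[, "df"],
      statistic = co[, "t value"],
      p.value = co[, "Pr(>|t|)"]
    )
  }
  if ("ran_pars" %in% effects) {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    vc <- vc[is.na(vc$var2), ]
    out$ran <- tibble::tibble(
      effect = "ran_pars",
      term = ifelse(is.na(vc$var1), vc$grp, paste0(vc$grp, ".", vc$var1)),
      estimate = vc$vcov,
      std.error = NA_real_,
      df = NA_real_,
      statistic = NA_real_,
      p.value = NA_real_,
      std.dev = vc$sdcor
    )
  }
  dplyr::bind_rows(out)
}

#' @export
glance.pbsn_lmm <- function(x, ...) {
  tibble::tibble(
    nobs = stats::nobs(x$fit),
    sigma = stats::sigma(x$fit),
    logLik = as.numeric(stats::logLik(x$fit)),
    REMLcrit = lme4::REMLcrit(x$fit),
    converged = x$converged,
    singular = x$singular,
    p_method = x$p_method
  )
}

suite_random <- "(1 | herd) + (1 | herd:animal_id)"

build_model_df <- function(records, kind, offset = NULL) {
  df <- dplyr::filter(records, .data$kind == !!kind)
  if (nrow(df) == 0) rlang::abort(glue::glue("no records of kind '{kind}'"))
  df$resp <- log_transform(df$value, offset)
  df$season <- factor(as.character(df$season), levels = c("summer", "winter"))
  df$herd <- factor(df$herd)
  df$year <- factor(df$year)
  df$year_pair <- factor(df$year_pair)
  df
}

#' Fit the four seasonal models
#'
#' The model suite contrasting seasons across the four responses, each
#' log-transformed (half-minimum-positive offset per response) and fitted by
#' REML with random intercepts for herd, animal nested in herd, and year:
#'
#' 1. *fidelity*: interannual site-fidelity UDOI ~ season, with the year
#'    random effect replaced by the year *pair* over which fidelity was
#'    measured;
#' 2. *spatial*: spatial graph strength ~ season;
#' 3. *social*: social graph strength ~ season x source, where `source`
#'    contrasts each animal's observed strength with its permutation
#'    null-mean strength, paired within animal-season-year;
#' 4. *area*: home-range area ~ season + log observed social strength.
#'
#' @param records Long record tibble (after [filter_outliers()]) holding all
#'   five response kinds.
#' @return An object of class `pbsn_model_suite`: named list of `pbsn_lmm`
#'   fits (`fidelity`, `spatial`, `social`, `area`) plus the offsets used.
#' @export
run_model_suite <- function(records) {
  needed <- c("fidelity_udoi", "spatial_strength", "social_strength_observed",
              "social_strength_null_mean", "hr_area_km2")
  have <- unique(records$kind)
  missing <- setdiff(needed, have)
  if (length(missing) > 0) {
    rlang::abort(glue::glue(
      "records are missing response kind(s): {paste(missing, collapse = ', ')}"
    ))
  }
  offsets <- list()

  # 1: fidelity ~ season, year-pair random effect
  df1 <- build_model_df(records, "fidelity_udoi")
  offsets$fidelity <- attr_offset(records, "fidelity_udoi")
  m1 <- fit_lmm(df1, stats::as.formula(paste(
    "resp ~ season +", suite_random, "+ (1 | year_pair)")))

  # 2: spatial strength ~ season
  df2 <- build_model_df(records, "spatial_strength")
  offsets$spatial <- attr_offset(records, "spatial_strength")
  m2 <- fit_lmm(df2, stats::as.formula(paste(
    "resp ~ season +", suite_random, "+ (1 | year)")))

  # 3: social strength ~ season x source, observed paired with null mean
  obs <- dplyr::filter(records, .data$kind == "social_strength_observed")
  nul <- dplyr::filter(records, .data$kind == "social_strength_null_mean")
  pair_keys <- c("animal_id", "herd", "season", "year")
  chk <- dplyr::full_join(
    dplyr::count(obs, dplyr::across(dplyr::all_of(pair_keys))),
    dplyr::count(nul, dplyr::across(dplyr::all_of(pair_keys))),
    by = pair_keys
  )
  if (any(is.na(chk$n.x)) || any(is.na(chk$n.y)) ||
      any(chk$n.x != 1) || any(chk$n.y != 1)) {
    rlang::abort("observed and null-mean social strengths are not one-to-one paired per animal-season-year")
  }
  df3 <- dplyr::bind_rows(
    dplyr::mutate(obs, source = "observed"),
    dplyr::mutate(nul, source = "null")
  )
  off3 <- {
    pos <- df3$value[df3$value > 0]
    if (length(pos) > 0) min(pos) / 2 else 1
  }
  offsets$social <- off3
  df3$resp <- log(df3$value + off3)
  df3$source <- factor(df3$source, levels = c("null", "observed"))
  df3$season <- factor(as.character(df3$season), levels = c("summer", "winter"))
  df3$herd <- factor(df3$herd)
  df3$year <- factor(df3$year)
  m3 <- fit_lmm(df3, stats::as.formula(paste(
    "resp ~ season * source +", suite_random, "+ (1 | year)")))

  # 4: home range area ~ season + log observed social strength
  df4 <- build_model_df(records, "hr_area_km2")
  offsets$area <- attr_offset(records, "hr_area_km2")
  social_pred <- obs |>
    dplyr::mutate(social_log = log(.data$value + off3)) |>
    dplyr::select(dplyr::all_of(pair_keys), "social_log")
  df4 <- dplyr::inner_join(
    df4, dplyr::mutate(social_pred,
                       season = factor(as.character(.data$season), levels = c("summer", "winter")),
                       herd = factor(.data$herd),
                       year = factor(.data$year)),
    by = pair_keys
  )
  if (nrow(df4) == 0) rlang::abort("no overlap between home-range and social-strength records")
  m4 <- fit_lmm(df4, stats::as.formula(paste(
    "resp ~ season + social_log +", suite_random, "+ (1 | year)")))

  structure(
    list(fidelity = m1, spatial = m2, social = m3, area = m4,
         offsets = offsets),
    class = "pbsn_model_suite"
  )
}

attr_offset <- function(records, kind) {
  v <- records$value[records$kind == kind]
  pos <- v[v > 0 & !is.na(v)]
  if (length(pos) > 0) min(pos) / 2 else 1
}

#' @export
print.pbsn_model_suite <- function(x, ...) {
  cat("<pbsn_model_suite> four seasonal mixed models\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the model suite into a Table-3-style summary
#'
#' @param x A `pbsn_model_suite`.
#' @param effects Passed to [tidy.pbsn_lmm()].
#' @param ... Unused.
#' @return A tibble with a `model` column binding the four fits' terms.
#' @export
tidy.pbsn_model_suite <- function(x, effects = c("fixed", "ran_pars"), ...) {
  purrr::map_dfr(
    c("fidelity", "spatial", "social", "area"),
    function(m) dplyr::mutate(tidy(x[[m]], effects = effects), model = m,
                              .before = 1)
  )
}

#' @export
glance.pbsn_model_suite <- function(x, ...) {
  purrr::map_dfr(
    c("fidelity", "spatial", "social", "area"),
    function(m) dplyr::mutate(glance(x[[m]]), model = m, .before = 1)
  )
}
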