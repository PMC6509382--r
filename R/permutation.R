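#' Shuffle daily movement trajectories within individuals
#'
#' The data-stream null model: for each animal (independently, within each
#' season-year), the calendar dates of its daily trajectory blocks are
#' permuted uniformly at random while the within-day sequence of fixes and
#' their time-of-day offsets are preserved (a fix at 13:00 stays at 13:00 on
#' its new date). The spatial content of each day is untouched, so each
#' animal's fix multiset modulo date -- and hence its home range -- is
#' invariant; only the simultaneity structure between animals is destroyed.
#'
#' @param fixes Season-tagged fixes (a `round_time` column, if present, is
#'   recomputed consistently).
#' @return The fixes with shuffled timestamps, re-sorted by animal and time.
#' @export
shuffle_days <- function(fixes) {
  check_fixes(fixes)
  if (!all(c("season", "year") %in% names(fixes))) {
    rlang::abort("fixes must be season-tagged (run assign_season())")
  }
  date <- as.Date(fixes$timestamp, tz = "UTC")
  tod <- as.numeric(fixes$timestamp) - as.numeric(as.POSIXct(paste(date), tz = "UTC"))
  key <- paste(fixes$animal_id, fixes$season, fixes$year, sep = "\r")
  new_date <- date
  single_day <- FALSE
  for (k in unique(key)) {
    i <- which(key == k)
    days <- sort(unique(date[i]))
    if (length(days) < 2) {
      single_day <- TRUE
      next
    }
    perm <- days[sample.int(length(days))]
    new_date[i] <- perm[match(date[i], days)]
  }
  if (single_day) {
    rlang::warn("some animal-season-years hold a single day; identity permutation used")
  }
  out <- fixes
  out$timestamp <- as.POSIXct(paste(new_date), tz = "UTC") + tod
  if ("round_time" %in% names(out)) {
    anchor <- round(as.numeric(out$timestamp) / 3600) * 3600
    out$round_time <- as.POSIXct(anchor, origin = "1970-01-01", tz = "UTC")
  }
  dplyr::arrange(out, .data$animal_id, .data$timestamp)
}

# Precompile a network's fixes for repeated shuffling: integer day and
# hour-slot per fix, so each iteration only permutes day labels.
compile_network <- function(fx, tolerance) {
  ids <- sort(unique(fx$animal_id))
  animal <- match(fx$animal_id, ids)
  date <- as.Date(fx$timestamp, tz = "UTC")
  tod <- as.numeric(fx$timestamp) - as.numeric(as.POSIXct(paste(date), tz = "UTC"))
  slot <- round(as.numeric(fx$timestamp) / 3600)
  ok <- abs(as.numeric(fx$timestamp) - slot * 3600) <= tolerance
  day0 <- as.integer(min(date))
  day <- as.integer(date) - day0 + 1L
  # per-animal observed-day blocks, for independent within-animal shuffles
  fix_idx <- split(seq_along(animal), animal)
  days_by_animal <- lapply(fix_idx, function(i) sort(unique(day[i])))
  day_rank <- integer(length(day))
  for (a in seq_along(fix_idx)) {
    i <- fix_idx[[a]]
    day_rank[i] <- match(day[i], days_by_animal[[a]])
  }
  list(
    ids = ids,
    animal = animal,
    day = day,
    fix_idx = fix_idx,
    days_by_animal = days_by_animal,
    day_rank = day_rank,
    slot_in_day = as.integer(round(tod / 3600)),
    ok = ok,
    x = fx$x,
    y = fx$y
  )
}

# one independent uniform day-block permutation per animal
shuffle_day_of <- function(cn) {
  day_of <- cn$day
  for (a in seq_along(cn$fix_idx)) {
    days_a <- cn$days_by_animal[[a]]
    if (length(days_a) < 2) next
    perm <- days_a[sample.int(length(days_a))]
    i <- cn$fix_idx[[a]]
    day_of[i] <- perm[cn$day_rank[i]]
  }
  day_of
}

# strengths for one (possibly day-permuted) network realisation
network_strength <- function(cn, day_of, assoc_dist) {
  keep <- cn$ok
  round_key <- (day_of - 1L) * 24L + cn$slot_in_day
  rk <- round_key[keep]
  rounds <- sort(unique(rk))
  eng <- sri_engine(
    round = match(rk, rounds),
    animal = cn$animal[keep],
    x = cn$x[keep], y = cn$y[keep],
    n_rounds = length(rounds), n_animals = length(cn$ids),
    assoc_dist = assoc_dist
  )
  den <- eng$n_obs[eng$pa] + eng$n_obs[eng$pb] - eng$n_ab
  w <- ifelse(den > 0, eng$x / den, 0)
  s <- numeric(length(cn$ids))
  for (k in seq_along(w)) {
    if (w[k] > 0) {
      s[eng$pa[k]] <- s[eng$pa[k]] + w[k]
      s[eng$pb[k]] <- s[eng$pb[k]] + w[k]
    }
  }
  s
}

#' Run a day-shuffling permutation ensemble
#'
#' Repeats the daily-trajectory shuffle `n_iter` times. In each iteration
#' every animal's day blocks are permuted independently within its
#' season-year, rounds and proximity-based social networks are rebuilt for
#' every herd-season-year, and per-animal graph strength is recorded. The
#' per-animal mean null strength is the value paired with the observed
#' strength in downstream models.
#'
#' @param fixes Round-aligned, season-tagged fixes.
#' @param n_iter Number of shuffles (1,000 for full analyses; scale down for
#'   exploration).
#' @param seed Integer master seed; iteration `i` uses `seed + i` so results
#'   are order-insensitive and reproducible.
#' @param assoc_dist Chain-rule adjacency distance, m.
#' @param tolerance Round simultaneity tolerance, s.
#' @return An object of class `pbsn_ensemble`: list with `key` (tibble:
#'   herd, season, year, animal_id, observed strength), `null` (matrix,
#'   animals x iterations), `n_iter`, `seed`.
#' @export
run_ensemble <- function(fixes, n_iter = 1000, seed = 1, assoc_dist = 50,
                         tolerance = 300) {
  check_fixes(fixes)
  if (!all(c("season", "year") %in% names(fixes))) {
    rlang::abort("fixes must be season-tagged (run assign_season())")
  }
  keys <- intersect(c("herd", "season", "year"), names(fixes))
  groups <- fixes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split()
  key_rows <- fixes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_keys()

  compiled <- lapply(groups, compile_network, tolerance = tolerance)
  key <- purrr::map2_dfr(seq_along(compiled), compiled, function(i, cn) {
    dplyr::bind_cols(key_rows[rep(i, length(cn$ids)), , drop = FALSE],
                     tibble::tibble(animal_id = cn$ids))
  })
  observed <- unlist(lapply(compiled, function(cn) {
    network_strength(cn, day_of = cn$day, assoc_dist = assoc_dist)
  }))

  null <- matrix(NA_real_, nrow(key), n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(seed + it)
    row0 <- 0L
    for (cn in compiled) {
      s <- network_strength(cn, day_of = shuffle_day_of(cn), assoc_dist = assoc_dist)
      null[row0 + seq_along(s), it] <- s
      row0 <- row0 + length(s)
    }
  }
  key$observed <- observed
  structure(
    list(key = key, null = null, n_iter = n_iter, seed = seed,
         assoc_dist = assoc_dist, tolerance = tolerance, keys = keys),
    class = "pbsn_ensemble"
  )
}

#' @export
print.pbsn_ensemble <- function(x, ...) {
  cat(glue::glue(
    "<pbsn_ensemble> {nrow(x$key)} animal-network(s) x {x$n_iter} iteration(s)"
  ), "\n")
  invisible(x)
}

#' Per-animal summary of a permutation ensemble
#'
#' @param x A `pbsn_ensemble`.
#' @param band Central null band mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with the observed strength, null mean, the band's lower
#'   and upper empirical quantiles, and `inside_band`.
#' @export
tidy.pbsn_ensemble <- function(x, band = 0.95, ...) {
  a <- (1 - band) / 2
  lo <- apply(x$null, 1, stats::quantile, probs = a, names = FALSE)
  hi <- apply(x$null, 1, stats::quantile, probs = 1 - a, names = FALSE)
  out <- x$key
  out$null_mean <- rowMeans(x$null)
  out$null_lo <- lo
  out$null_hi <- hi
  out$inside_band <- out$observed >= lo & out$observed <= hi
  out
}

#' @export
glance.pbsn_ensemble <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_animal_networks = nrow(td),
    n_iter = x$n_iter,
    prop_inside_band = mean(td$inside_band),
    mean_observed = mean(td$observed),
    mean_null = mean(td$null_mean)
  )
}

#' Permutation null distribution of seasonal model coefficients
#'
#' Fits the seasonal strength model (log strength ~ season with random
#' intercepts for year and for animal nested in herd) to the observed
#' strengths and then to each permutation iteration's strengths, and
#' compares the observed intercept and season coefficients to the empirical
#' 95\% band of the null coefficient distribution. An observed coefficient
#' outside the band indicates nonrandom seasonal structure in association
#' strength.
#'
#' @param ensemble A `pbsn_ensemble` covering both seasons.
#' @param band Central band mass (default 0.95).
#' @param offset Log-transform offset; default half the minimum positive
#'   observed strength (shared between observed and null fits so
#'   coefficients are commensurable).
#' @return An object of class `pbsn_coefnull`: list with `summary` (tibble:
#'   term, observed, null quantiles, `outside`), `draws` (iterations x
#'   terms), and bookkeeping fields. Iterations whose refit fails are
#'   dropped; an error is raised if fewer than 95\% converge.
#' @export
coefficient_null <- function(ensemble, band = 0.95, offset = NULL) {
  stopifnot(inherits(ensemble, "pbsn_ensemble"))
  key <- ensemble$key
  if (length(unique(key$season)) < 2) {
    rlang::abort("coefficient_null needs networks from both seasons")
  }
  if (is.null(offset)) {
    pos <- key$observed[key$observed > 0]
    if (length(pos) == 0) rlang::abort("all observed strengths are zero; cannot set a log offset")
    offset <- min(pos) / 2
  }
  df <- data.frame(
    resp = log(key$observed + offset),
    season = factor(key$season, levels = c("summer", "winter")),
    herd = factor(key$herd),
    animal = factor(key$animal_id),
    year = factor(key$year)
  )
  pr <- prune_random_formula(
    resp ~ season + (1 | herd) + (1 | herd:animal) + (1 | year), df)
  fit0 <- suppressWarnings(suppressMessages(
    lme4::lmer(pr$formula, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  ))
  obs_coef <- lme4::fixef(fit0)
  terms <- names(obs_coef)
  draws <- matrix(NA_real_, ensemble$n_iter, length(terms),
                  dimnames = list(NULL, terms))
  failed <- 0L
  for (it in seq_len(ensemble$n_iter)) {
    newresp <- log(ensemble$null[, it] + offset)
    fit_it <- tryCatch(
      suppressWarnings(suppressMessages(lme4::refit(fit0, newresp = newresp))),
      error = function(e) NULL
    )
    if (is.null(fit_it)) {
      failed <- failed + 1L
      next
    }
    draws[it, ] <- lme4::fixef(fit_it)
  }
  if (failed > 0.05 * ensemble$n_iter) {
    rlang::abort(glue::glue(
      "{failed}/{ensemble$n_iter} null refits failed (> 5%); ensemble invalid"
    ))
  }
  if (failed > 0) {
    rlang::inform(glue::glue("{failed} null refit(s) failed and were dropped"))
  }
  ok <- stats::complete.cases(draws)
  a <- (1 - band) / 2
  summary <- tibble::tibble(
    term = terms,
    observed = unname(obs_coef),
    null_mean = colMeans(draws[ok, , drop = FALSE]),
    null_lo = apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = a, names = FALSE),
    null_hi = apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = 1 - a, names = FALSE)
  )
  summary$outside <- summary$observed < summary$null_lo |
    summary$observed > summary$null_hi
  structure(
    list(summary = summary, draws = draws[ok, , drop = FALSE],
         band = band, offset = offset, n_failed = failed,
         observed_fit = fit0),
    class = "pbsn_coefnull"
  )
}

#' @export
print.pbsn_coefnull <- function(x, ...) {
  cat(glue::glue("<pbsn_coefnull> {nrow(x$draws)} null draws, band {x$band * 100}%"), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.pbsn_coefnull <- function(x, ...) x$summary
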