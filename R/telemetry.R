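#' Default seasonal windows
#'
#' Two discrete 48-day windows bracketing the seasons used throughout the
#' package: winter (15 January--3 March) and summer (15 July--1 September).
#' Both avoid calving (May--June) and rut (September--October) so that space
#' use within a window reflects foraging, not reproductive behaviour. End
#' dates are inclusive.
#'
#' @return A tibble with columns `season`, `start_month`, `start_day`,
#'   `end_month`, `end_day`.
#' @export
#' @examples
#' season_windows()
season_windows <- function() {
  tibble::tibble(
    season      = c("winter", "summer"),
    start_month = c(1L, 7L),
    start_day   = c(15L, 15L),
    end_month   = c(3L, 9L),
    end_day     = c(3L, 1L)
  )
}

check_fixes <- function(fixes, need = c("animal_id", "herd", "timestamp", "x", "y")) {
  missing <- setdiff(need, names(fixes))
  if (length(missing) > 0) {
    rlang::abort(glue::glue(
      "`fixes` is missing required column(s): {paste(missing, collapse = ', ')}"
    ))
  }
  if (nrow(fixes) > 0 && (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y)))) {
    rlang::abort("fix coordinates must be finite (projected planar meters)")
  }
  invisible(fixes)
}

#' Read a telemetry CSV
#'
#' Reads the canonical telemetry table: one row per GPS fix with columns
#' `animal_id`, `herd`, `timestamp` (ISO-8601, interpreted as UTC), `x`, `y`
#' (projected planar meters, e.g. UTM). Geographic coordinates must be
#' projected upstream; all distances downstream are Euclidean.
#'
#' @param path Path to a CSV file.
#' @return A tibble of fixes sorted by animal and time.
#' @export
read_telemetry <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixes <- tibble::as_tibble(raw)
  check_fixes(fixes)
  fixes$timestamp <- as.POSIXct(
    fixes$timestamp, tz = "UTC",
    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  )
  if (anyNA(fixes$timestamp)) {
    rlang::abort("could not parse some timestamps; use ISO-8601 UTC")
  }
  dplyr::arrange(fixes, .data$animal_id, .data$timestamp)
}

#' Write a telemetry CSV
#'
#' @param fixes A fix tibble (see [read_telemetry()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(fixes, path) {
  check_fixes(fixes)
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Screen out erroneous and outlier fixes
#'
#' Two-rule positional screen applied independently to each animal's
#' time-ordered track. A fix is removed as a *spike* when both the step in
#' and the step out exceed `max_step` (an out-and-back excursion within one
#' fix), and as a *speed violation* when the speed from the last retained fix
#' exceeds `max_speed`. Retained and rejected fixes partition the input, and
#' the screen is idempotent.
#'
#' @param fixes Fix tibble sorted by animal and time.
#' @param max_speed Maximum plausible sustained speed, m/hr.
#' @param max_step Maximum plausible single-step displacement, m.
#' @return The retained fixes; the rejected rows (with a `reason` column) are
#'   attached as `attr(, "rejected")`.
#' @export
screen_fixes <- function(fixes, max_speed = 15000, max_step = 10000) {
  check_fixes(fixes)
  if (nrow(fixes) == 0) {
    out <- fixes
    attr(out, "rejected") <- dplyr::mutate(fixes, reason = character(0))
    return(out)
  }
  screen_one <- function(df, id) {
    o <- order(df$timestamp)
    if (anyDuplicated(df$timestamp[o])) {
      rlang::abort(glue::glue(
        "duplicate timestamps for animal '{id}'; fixes must be strictly increasing in time"
      ))
    }
    df <- df[o, , drop = FALSE]
    n <- nrow(df)
    reason <- rep(NA_character_, n)
    if (n >= 3) {
      din  <- c(NA, sqrt(diff(df$x)^2 + diff(df$y)^2))
      dout <- c(din[-1], NA)
      spike <- !is.na(din) & !is.na(dout) & din > max_step & dout > max_step
      reason[spike] <- "spike"
    }
    # sequential speed rule against the last retained fix
    keep_idx <- which(is.na(reason))
    if (length(keep_idx) >= 2) {
      last <- keep_idx[1]
      for (i in keep_idx[-1]) {
        dt_hr <- as.numeric(difftime(df$timestamp[i], df$timestamp[last], units = "hours"))
        dd <- sqrt((df$x[i] - df$x[last])^2 + (df$y[i] - df$y[last])^2)
        if (dt_hr > 0 && dd / dt_hr > max_speed) {
          reason[i] <- "speed"
        } else {
          last <- i
        }
      }
    }
    df$.reason <- reason
    df
  }
  res <- fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(.x, .y) screen_one(.x, .y$animal_id)) |>
    dplyr::ungroup()
  # group_modify drops the grouping column from .x; restore ordering/columns
  res <- dplyr::relocate(res, dplyr::all_of(names(fixes)))
  kept <- dplyr::select(dplyr::filter(res, is.na(.data$.reason)), -".reason")
  rejected <- dplyr::rename(dplyr::filter(res, !is.na(.data$.reason)), reason = ".reason")
  attr(kept, "rejected") <- rejected
  kept
}

#' Tag fixes with season and year, dropping off-season fixes
#'
#' Fixes whose month-day falls inside a seasonal window (end date inclusive)
#' are tagged with that window's `season` label and the fix's calendar year;
#' all other fixes are dropped. Windows must not wrap the year boundary.
#'
#' @param fixes Fix tibble.
#' @param windows Seasonal windows as returned by [season_windows()].
#' @return The in-season fixes with `season` (factor, summer as the reference
#'   level) and `year` columns appended.
#' @export
assign_season <- function(fixes, windows = season_windows()) {
  check_fixes(fixes)
  wstart <- windows$start_month * 100L + windows$start_day
  wend   <- windows$end_month * 100L + windows$end_day
  if (any(wend < wstart)) {
    rlang::abort("seasonal windows must not wrap the year boundary")
  }
  lt <- as.POSIXlt(fixes$timestamp, tz = "UTC")
  mmdd <- (lt$mon + 1L) * 100L + lt$mday
  season <- rep(NA_character_, nrow(fixes))
  for (w in seq_len(nrow(windows))) {
    season[mmdd >= wstart[w] & mmdd <= wend[w]] <- windows$season[w]
  }
  out <- fixes[!is.na(season), , drop = FALSE]
  out$season <- factor(season[!is.na(season)], levels = c("summer", "winter"))
  out$year <- (lt$year + 1900L)[!is.na(season)]
  out
}

#' Align fixes into simultaneous sampling rounds
#'
#' Fixes are anchored to the hourly schedule: each fix joins the round at its
#' nearest whole hour provided it lies within `tolerance` of it (the
#' simultaneity criterion). Fixes farther than `tolerance` from any whole
#' hour are dropped; when an animal contributes two fixes to one round the
#' nearer one is kept, so each round holds at most one fix per animal.
#'
#' @param fixes Season-tagged fix tibble.
#' @param tolerance Simultaneity tolerance in seconds (default 300 s = 5 min).
#' @return The fixes with a `round_time` (POSIXct) column appended.
#' @export
build_rounds <- function(fixes, tolerance = 300) {
  check_fixes(fixes)
  secs <- as.numeric(fixes$timestamp)
  anchor <- round(secs / 3600) * 3600
  off <- abs(secs - anchor)
  out <- fixes[off <= tolerance, , drop = FALSE]
  out$round_time <- as.POSIXct(anchor[off <= tolerance], origin = "1970-01-01", tz = "UTC")
  out$.off <- off[off <= tolerance]
  out <- out |>
    dplyr::group_by(.data$animal_id, .data$round_time) |>
    dplyr::slice_min(.data$.off, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".off") |>
    dplyr::arrange(.data$animal_id, .data$timestamp)
  n_drop <- nrow(fixes) - sum(off <= tolerance)
  if (n_drop > 0) {
    rlang::inform(glue::glue("build_rounds: dropped {n_drop} fix(es) beyond {tolerance} s of the hourly schedule"))
  }
  out
}
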