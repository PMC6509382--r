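#' Reference bandwidth for a bivariate kernel
#'
#' The reference ("href") smoothing parameter for a bivariate normal kernel:
#' \deqn{h = \sigma \, n^{-1/6}, \qquad
#'       \sigma = \sqrt{(\mathrm{var}(x) + \mathrm{var}(y)) / 2}}
#' with sample variances. Scale-equivariant: doubling the coordinates
#' doubles `h`.
#'
#' @param x,y Fix coordinates in meters.
#' @return Bandwidth in meters.
#' @export
#' @examples
#' # var(x) = var(y) = 1e6, n = 64 -> 1000 * 64^(-1/6) = 500
href_bandwidth <- function(x, y) {
  n <- length(x)
  if (n < 5) {
    rlang::abort("at least 5 fixes are required to estimate a bandwidth")
  }
  sigma <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (!is.finite(sigma) || sigma <= 0) {
    rlang::abort("degenerate bandwidth: fixes have zero spatial variance")
  }
  sigma * n^(-1 / 6)
}

#' Define a shared estimation grid
#'
#' A square-celled grid covering the supplied fixes plus a margin, used so
#' that utilization distributions meant for overlap comparison share cell
#' geometry exactly.
#'
#' @param x,y Coordinates the grid must cover (typically pooled over all
#'   animals of a herd-season-year).
#' @param cell Cell side, m.
#' @param margin Margin added on every side, m (use ~3 bandwidths so kernel
#'   tails are not truncated).
#' @return A list with `x0`, `y0` (lower-left corner), `cell`, `nx`, `ny`,
#'   and cell-center vectors `xc`, `yc`.
#' @export
make_grid <- function(x, y, cell, margin) {
  if (cell <= 0) rlang::abort("grid cell size must be positive")
  x0 <- min(x) - margin
  y0 <- min(y) - margin
  nx <- ceiling((max(x) + margin - x0) / cell)
  ny <- ceiling((max(y) + margin - y0) / cell)
  list(
    x0 = x0, y0 = y0, cell = cell, nx = as.integer(nx), ny = as.integer(ny),
    xc = x0 + (seq_len(nx) - 0.5) * cell,
    yc = y0 + (seq_len(ny) - 0.5) * cell
  )
}

same_grid <- function(g1, g2) {
  isTRUE(all.equal(g1$x0, g2$x0)) && isTRUE(all.equal(g1$y0, g2$y0)) &&
    isTRUE(all.equal(g1$cell, g2$cell)) && g1$nx == g2$nx && g1$ny == g2$ny
}

#' Estimate a kernel utilization distribution
#'
#' Places an isotropic bivariate normal kernel of bandwidth `h` at each fix
#' and integrates the resulting mixture over every grid cell (exact separable
#' Gaussian cell masses, not point evaluations), renormalizing so the masses
#' sum to one. Errors if more than 1\% of kernel mass falls outside the grid,
#' which indicates an under-sized extent.
#'
#' @param fixes A data frame with columns `x`, `y` (one animal's fixes).
#' @param h Bandwidth in m; default [href_bandwidth()] of the fixes.
#' @param grid A grid from [make_grid()]; default a private grid with
#'   `cell = h/4` and a `3h` margin.
#' @return An object of class `ud`: list with `grid`, matrix `mass`
#'   (`nx` x `ny`, sums to 1), `h`, `n_fixes`.
#' @export
estimate_ud <- function(fixes, h = NULL, grid = NULL) {
  x <- fixes$x
  y <- fixes$y
  n <- length(x)
  if (n < 5) rlang::abort("at least 5 fixes are required to estimate a UD")
  if (is.null(h)) h <- href_bandwidth(x, y)
  if (!is.finite(h) || h <= 0) rlang::abort("bandwidth must be positive")
  if (is.null(grid)) grid <- make_grid(x, y, cell = h / 4, margin = 3 * h)

  xe <- grid$x0 + (0:grid$nx) * grid$cell
  ye <- grid$y0 + (0:grid$ny) * grid$cell
  # Mx[i, j] = mass of kernel i in x-slab j (separable, exact cell integrals)
  Px <- outer(x, xe, function(xi, e) stats::pnorm((e - xi) / h))
  Py <- outer(y, ye, function(yi, e) stats::pnorm((e - yi) / h))
  Mx <- Px[, -1, drop = FALSE] - Px[, -(grid$nx + 1), drop = FALSE]
  My <- Py[, -1, drop = FALSE] - Py[, -(grid$ny + 1), drop = FALSE]
  mass <- crossprod(Mx, My) / n
  tot <- sum(mass)
  if (tot < 0.99) {
    rlang::abort(glue::glue(
      "grid truncates {signif((1 - tot) * 100, 3)}% of kernel mass (> 1%); enlarge the grid"
    ))
  }
  structure(
    list(grid = grid, mass = mass / tot, h = h, n_fixes = n),
    class = "ud"
  )
}

#' @export
print.ud <- function(x, ...) {
  cat(glue::glue(
    "<ud> {x$grid$nx} x {x$grid$ny} grid, cell {signif(x$grid$cell, 4)} m, ",
    "h = {signif(x$h, 4)} m, n = {x$n_fixes} fixes"
  ), "\n")
  invisible(x)
}

# logical matrix marking the smallest set of highest-density cells holding
# `level` of the mass
isopleth_cells <- function(ud, level) {
  o <- order(ud$mass, decreasing = TRUE)
  cum <- cumsum(ud$mass[o])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(o)
  inside <- matrix(FALSE, nrow(ud$mass), ncol(ud$mass))
  inside[o[seq_len(k)]] <- TRUE
  inside
}

#' Home-range isopleth
#'
#' The `level` isopleth of a utilization distribution: the smallest set of
#' highest-density cells whose cumulative mass reaches `level`. The area is
#' the summed cell area.
#'
#' @param ud A `ud` object.
#' @param level Cumulative mass level (default 0.95).
#' @return An object of class `home_range`: list with `level`, `area_km2`,
#'   logical cell matrix `cells`, and the `grid`.
#' @export
isopleth <- function(ud, level = 0.95) {
  stopifnot(inherits(ud, "ud"), level > 0, level <= 1)
  cells <- isopleth_cells(ud, level)
  structure(
    list(
      level = level,
      area_km2 = sum(cells) * ud$grid$cell^2 / 1e6,
      cells = cells,
      grid = ud$grid
    ),
    class = "home_range"
  )
}

#' @export
print.home_range <- function(x, ...) {
  cat(glue::glue(
    "<home_range> {x$level * 100}% isopleth, {signif(x$area_km2, 4)} km2 ",
    "({sum(x$cells)} cells)"
  ), "\n")
  invisible(x)
}

#' Utilization distribution overlap index (UDOI)
#'
#' \deqn{UDOI = A_{1,2} \int\int UD_1(x, y)\, UD_2(x, y)\, dx\, dy}
#' where \eqn{A_{1,2}} is the intersection area of the two `level`
#' home ranges. Zero when the home ranges are disjoint, 1 for two identical
#' uniform distributions, and above 1 for strongly concentrated mutual
#' overlap. With `restrict = TRUE` (default) each UD is masked to its own
#' `level` home range and renormalized before the product integral, which is
#' what makes the identical-uniform calibration equal 1 exactly; with
#' `restrict = FALSE` the full-grid densities are used and \eqn{A_{1,2}} is
#' still taken from the `level` isopleths.
#'
#' @param ud1,ud2 `ud` objects on the same grid (see [make_grid()]).
#' @param level Isopleth level defining the home ranges (default 0.95).
#' @param restrict Mask and renormalize UDs to their home ranges first.
#' @return A non-negative scalar; symmetric in its arguments.
#' @export
udoi <- function(ud1, ud2, level = 0.95, restrict = TRUE) {
  stopifnot(inherits(ud1, "ud"), inherits(ud2, "ud"))
  if (!same_grid(ud1$grid, ud2$grid)) {
    rlang::abort("UDs are on different grids; estimate them on a shared make_grid()")
  }
  cellarea <- ud1$grid$cell^2
  in1 <- isopleth_cells(ud1, level)
  in2 <- isopleth_cells(ud2, level)
  a12 <- sum(in1 & in2) * cellarea
  if (a12 == 0) return(0)
  m1 <- ud1$mass
  m2 <- ud2$mass
  if (restrict) {
    m1 <- m1 * in1
    m2 <- m2 * in2
    m1 <- m1 / sum(m1)
    m2 <- m2 / sum(m2)
  }
  # sum of density products times cell area = sum(mass1 * mass2) / cellarea
  a12 * sum(m1 * m2) / cellarea
}

ud_meta_cols <- c("animal_id", "herd", "season", "year")

# Estimate UDs for every animal of every herd-season-year on a grid shared
# within the herd-season-year. Animals with fewer than `min_fixes` fixes are
# skipped (reported via attribute).
estimate_uds <- function(fixes, min_fixes = 5, cell_div = 4, margin_mult = 3) {
  check_fixes(fixes)
  keys <- intersect(c("herd", "season", "year"), names(fixes))
  groups <- fixes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split()
  out <- list()
  skipped <- list()
  for (g in groups) {
    counts <- table(g$animal_id)
    ok_ids <- names(counts)[counts >= min_fixes]
    bad_ids <- setdiff(names(counts), ok_ids)
    key <- g[1, keys, drop = FALSE]
    for (id in bad_ids) {
      skipped[[length(skipped) + 1]] <- dplyr::mutate(key, animal_id = id,
                                                      n_fixes = as.integer(counts[[id]]))
    }
    if (length(ok_ids) == 0) next
    hs <- vapply(ok_ids, function(id) {
      sub <- g[g$animal_id == id, ]
      href_bandwidth(sub$x, sub$y)
    }, numeric(1))
    hmax <- max(hs)
    grid <- make_grid(g$x[g$animal_id %in% ok_ids], g$y[g$animal_id %in% ok_ids],
                      cell = hmax / cell_div, margin = margin_mult * hmax)
    for (id in ok_ids) {
      sub <- g[g$animal_id == id, ]
      entry <- c(as.list(key), list(
        animal_id = id,
        ud = estimate_ud(sub, h = hs[[id]], grid = grid)
      ))
      out[[length(out) + 1]] <- entry
    }
  }
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else NULL
  out
}

#' Home-range areas for every animal-season-year
#'
#' Estimates a kernel UD per animal per herd-season-year (reference
#' bandwidth, shared per-network grid) and returns the area of the `level`
#' isopleth. Animals with fewer than `min_fixes` fixes in a season-year are
#' excluded.
#'
#' @param fixes Season-tagged fixes.
#' @param level Isopleth level (default 0.95).
#' @param min_fixes Minimum fixes per animal-season-year (default 5).
#' @return A tibble with herd/season/year keys, `animal_id`, `n_fixes`, `h`,
#'   `area_km2`.
#' @export
home_range_areas <- function(fixes, level = 0.95, min_fixes = 5) {
  uds <- estimate_uds(fixes, min_fixes = min_fixes)
  purrr::map_dfr(uds, function(e) {
    hr <- isopleth(e$ud, level)
    tibble::tibble(
      herd = e$herd %||% NA_character_,
      season = e$season %||% NA,
      year = e$year %||% NA_integer_,
      animal_id = e$animal_id,
      n_fixes = e$ud$n_fixes,
      h = e$ud$h,
      area_km2 = hr$area_km2
    )
  })
}

#' Build spatial (home-range overlap) networks
#'
#' For each herd-season-year, estimates per-animal kernel UDs on a shared
#' grid and weights every dyadic edge by the utilization distribution
#' overlap index. Spatial graph strength is the sum of incident UDOI values.
#'
#' @inheritParams home_range_areas
#' @param restrict Passed to [udoi()].
#' @return An object of class `spatial_network`: list of tibbles `edges`
#'   (dyadic UDOI) and `strength` (per animal), plus settings.
#' @export
build_spatial_network <- function(fixes, level = 0.95, min_fixes = 5,
                                  restrict = TRUE) {
  uds <- estimate_uds(fixes, min_fixes = min_fixes)
  keys <- intersect(c("herd", "season", "year"), names(fixes))
  key_of <- function(e) paste(unlist(e[keys]), collapse = "\r")
  by_net <- split(seq_along(uds), vapply(uds, key_of, character(1)))
  edges <- list()
  strength <- list()
  for (net_idx in by_net) {
    entries <- uds[net_idx]
    ids <- vapply(entries, function(e) e$animal_id, character(1))
    key <- tibble::as_tibble(entries[[1]][keys])
    svec <- stats::setNames(numeric(length(ids)), ids)
    if (length(ids) >= 2) {
      for (i in seq_len(length(ids) - 1)) {
        for (j in seq.int(i + 1, length(ids))) {
          v <- udoi(entries[[i]]$ud, entries[[j]]$ud, level = level, restrict = restrict)
          edges[[length(edges) + 1]] <- dplyr::bind_cols(
            key,
            tibble::tibble(animal_a = ids[i], animal_b = ids[j], udoi = v)
          )
          svec[i] <- svec[i] + v
          svec[j] <- svec[j] + v
        }
      }
    }
    strength[[length(strength) + 1]] <- dplyr::bind_cols(
      key[rep(1, length(ids)), , drop = FALSE],
      tibble::tibble(animal_id = ids, spatial_strength = unname(svec))
    )
  }
  out <- list(
    edges = if (length(edges)) dplyr::bind_rows(edges) else tibble::tibble(),
    strength = if (length(strength)) dplyr::bind_rows(strength) else tibble::tibble(),
    level = level,
    restrict = restrict,
    keys = keys
  )
  class(out) <- "spatial_network"
  out
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(glue::glue(
    "<spatial_network> {nrow(x$edges)} edge(s), {nrow(x$strength)} ",
    "animal-network(s), {x$level * 100}% home ranges"
  ), "\n")
  invisible(x)
}

#' @export
tidy.spatial_network <- function(x, ...) x$edges

#' @export
glance.spatial_network <- function(x, ...) {
  x$strength |>
    dplyr::group_by(dplyr::across(dplyr::all_of(x$keys))) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      mean_spatial_strength = mean(.data$spatial_strength),
      .groups = "drop"
    )
}

#' Interannual site fidelity
#'
#' Within-individual home-range consistency across years: for each animal
#' and season, the UDOI between its utilization distributions in
#' consecutive years (non-consecutive year pairs are excluded). The two UDs
#' of a pair are estimated on a grid shared across the two years.
#'
#' @param fixes Season-tagged fixes spanning two or more years.
#' @param level Isopleth level for the UDOI home-range restriction.
#' @param min_fixes Minimum fixes per animal-season-year.
#' @param restrict Passed to [udoi()].
#' @return A tibble with `animal_id`, `herd`, `season`, `year_from`,
#'   `year_to`, `year_pair`, `udoi`.
#' @export
site_fidelity <- function(fixes, level = 0.95, min_fixes = 5, restrict = TRUE) {
  check_fixes(fixes)
  if (!all(c("season", "year") %in% names(fixes))) {
    rlang::abort("fixes must be season-tagged (run assign_season())")
  }
  out <- list()
  combos <- fixes |>
    dplyr::distinct(.data$animal_id, .data$herd, .data$season, .data$year) |>
    dplyr::group_by(.data$animal_id, .data$herd, .data$season) |>
    dplyr::summarise(years = list(sort(.data$year)), .groups = "drop")
  for (i in seq_len(nrow(combos))) {
    yrs <- combos$years[[i]]
    yrs_consec <- yrs[which(diff(yrs) == 1)]
    for (y in yrs_consec) {
      sub <- fixes[fixes$animal_id == combos$animal_id[i] &
                     fixes$season == combos$season[i] &
                     fixes$year %in% c(y, y + 1), ]
      n1 <- sum(sub$year == y)
      n2 <- sum(sub$year == y + 1)
      if (n1 < min_fixes || n2 < min_fixes) next
      f1 <- sub[sub$year == y, ]
      f2 <- sub[sub$year == y + 1, ]
      h1 <- href_bandwidth(f1$x, f1$y)
      h2 <- href_bandwidth(f2$x, f2$y)
      hmax <- max(h1, h2)
      grid <- make_grid(sub$x, sub$y, cell = hmax / 4, margin = 3 * hmax)
      v <- udoi(estimate_ud(f1, h = h1, grid = grid),
                estimate_ud(f2, h = h2, grid = grid),
                level = level, restrict = restrict)
      out[[length(out) + 1]] <- tibble::tibble(
        animal_id = combos$animal_id[i],
        herd = combos$herd[i],
        season = combos$season[i],
        year_from = y,
        year_to = y + 1L,
        year_pair = paste0(y, "-", y + 1L),
        udoi = v
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      animal_id = character(0), herd = character(0),
      season = factor(character(0), levels = c("summer", "winter")),
      year_from = integer(0), year_to = integer(0),
      year_pair = character(0), udoi = numeric(0)
    ))
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
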