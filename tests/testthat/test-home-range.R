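test_that("href bandwidth follows the closed form and is scale-equivariant", {
  set.seed(5)
  x0 <- rnorm(64)
  x <- x0 * sqrt(1e6 / var(x0))
  y0 <- rnorm(64)
  y <- y0 * sqrt(1e6 / var(y0))
  # var(x) = var(y) = 1e6 exactly -> h = 1000 * 64^(-1/6) = 500
  expect_equal(href_bandwidth(x, y), 500, tolerance = 1e-10)
  expect_equal(href_bandwidth(2 * x, 2 * y), 1000, tolerance = 1e-10)

  expect_error(href_bandwidth(rep(1, 10), rep(2, 10)), "degenerate")
  expect_error(href_bandwidth(1:4, 1:4), "at least 5")
})

test_that("the UD is a normalized surface with the kernel's shape", {
  fx <- tibble::tibble(x = rep(0, 6), y = rep(0, 6))
  ud <- estimate_ud(fx, h = 100)
  expect_s3_class(ud, "ud")
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
  # single location: mode at the cell nearest the point
  peak <- which(ud$mass == max(ud$mass), arr.ind = TRUE)
  expect_lt(abs(ud$grid$xc[peak[1]]), ud$grid$cell)
  expect_lt(abs(ud$grid$yc[peak[2]]), ud$grid$cell)

  set.seed(9)
  fx2 <- tibble::tibble(x = rnorm(40, 0, 300), y = rnorm(40, 0, 300))
  ud2 <- estimate_ud(fx2)
  expect_equal(sum(ud2$mass), 1, tolerance = 1e-6)
})

test_that("two well-separated clusters split the mass evenly", {
  set.seed(13)
  fx <- tibble::tibble(
    x = c(rnorm(50, 0, 100), rnorm(50, 10000, 100)),
    y = rnorm(100, 0, 100)
  )
  ud <- estimate_ud(fx, h = 200)
  left <- sum(ud$mass[ud$grid$xc < 5000, ])
  expect_equal(left, 0.5, tolerance = 0.01)
})

test_that("an undersized grid is rejected for mass truncation", {
  fx <- tibble::tibble(x = rnorm(20, 0, 500), y = rnorm(20, 0, 500))
  tight <- make_grid(fx$x, fx$y, cell = 50, margin = 0)
  expect_error(estimate_ud(fx, h = 400, grid = tight), "truncates")
})

test_that("isopleths take the highest-density cells to the target mass", {
  grid <- make_grid(c(0, 10000), c(0, 10000), cell = 1000, margin = 0)
  expect_equal(grid$nx * grid$ny, 100)
  ud <- uniform_ud(grid, 1:10, 1:10)
  hr <- isopleth(ud, 0.95)
  expect_equal(hr$area_km2, 95) # 95 of 100 one-km2 cells

  all_cells <- isopleth(ud, 1)
  expect_equal(all_cells$area_km2, 100)

  # nesting
  set.seed(31)
  fx <- tibble::tibble(x = rnorm(60, 0, 400), y = rnorm(60, 0, 400))
  ud2 <- estimate_ud(fx)
  expect_lte(isopleth(ud2, 0.5)$area_km2, isopleth(ud2, 0.95)$area_km2)
})

test_that("UDOI is calibrated: disjoint 0, identical uniform 1, symmetric", {
  grid <- make_grid(c(0, 20000), c(0, 20000), cell = 100, margin = 0)
  u1 <- uniform_ud(grid, 1:60, 1:60)
  u2 <- uniform_ud(grid, 120:180, 120:180)
  expect_identical(udoi(u1, u2), 0)

  u3 <- uniform_ud(grid, 1:60, 1:60)
  expect_equal(udoi(u1, u3), 1, tolerance = 1e-10)

  set.seed(41)
  fa <- tibble::tibble(x = rnorm(40, 0, 300), y = rnorm(40, 0, 300))
  fb <- tibble::tibble(x = rnorm(40, 200, 300), y = rnorm(40, 0, 300))
  g <- make_grid(c(fa$x, fb$x), c(fa$y, fb$y), cell = 50, margin = 1000)
  ua <- estimate_ud(fa, h = 250, grid = g)
  ub <- estimate_ud(fb, h = 250, grid = g)
  expect_equal(udoi(ua, ub), udoi(ub, ua))
  expect_gte(udoi(ua, ub), 0)
  expect_error(udoi(ua, estimate_ud(fb, h = 250)), "different grids")
})

test_that("UDOI is stable under grid refinement on smooth surfaces", {
  set.seed(43)
  fa <- tibble::tibble(x = rnorm(50, 0, 300), y = rnorm(50, 0, 300))
  fb <- tibble::tibble(x = rnorm(50, 300, 300), y = rnorm(50, 100, 300))
  v <- sapply(c(80, 40), function(cell) {
    g <- make_grid(c(fa$x, fb$x), c(fa$y, fb$y), cell = cell, margin = 1200)
    udoi(estimate_ud(fa, h = 250, grid = g), estimate_ud(fb, h = 250, grid = g))
  })
  expect_lt(abs(v[2] - v[1]) / v[1], 0.05)
})

test_that("spatial networks sum UDOI into strength and respect locality", {
  mk <- function(id, cx) {
    set.seed(match(id, c("A", "B", "C")) * 100)
    tibble::tibble(
      animal_id = id, herd = "h1",
      timestamp = as.POSIXct("2010-02-01", tz = "UTC") + (1:40) * 7200,
      x = rnorm(40, cx, 250), y = rnorm(40, 0, 250)
    )
  }
  fx <- dplyr::bind_rows(mk("A", 0), mk("B", 150), mk("C", 50000))
  sn <- build_spatial_network(fx)
  ab <- sn$edges$udoi[sn$edges$animal_a == "A" & sn$edges$animal_b == "B"]
  expect_gt(ab, 0)
  # C's range is disjoint: its edges are 0 and its strength is 0
  sC <- sn$strength$spatial_strength[sn$strength$animal_id == "C"]
  expect_equal(sC, 0)
  # A and B strengths equal their shared edge (C contributes nothing)
  expect_equal(sn$strength$spatial_strength[sn$strength$animal_id == "A"], ab)
  expect_equal(sn$strength$spatial_strength[sn$strength$animal_id == "B"], ab)

  # adding a disjoint animal leaves existing strengths essentially unchanged
  # (UDs share one grid per herd-season-year, so the grid geometry -- and
  # with it the discretized UDOI -- can shift by a fraction of a percent)
  sn2 <- build_spatial_network(dplyr::bind_rows(mk("A", 0), mk("B", 150)))
  expect_equal(
    sn2$strength$spatial_strength[sn2$strength$animal_id %in% c("A", "B")],
    sn$strength$spatial_strength[sn$strength$animal_id %in% c("A", "B")],
    tolerance = 0.02
  )
})

test_that("site fidelity uses consecutive year pairs only", {
  mk_year <- function(yr, cx) {
    tibble::tibble(
      animal_id = "A", herd = "h1",
      timestamp = as.POSIXct(sprintf("%d-02-01", yr), tz = "UTC") + (1:30) * 7200,
      x = rnorm(30, cx, 200), y = rnorm(30, 0, 200)
    )
  }
  set.seed(51)
  fx <- assign_season(dplyr::bind_rows(mk_year(2007, 0), mk_year(2009, 0)))
  expect_equal(nrow(site_fidelity(fx)), 0) # 2007 & 2009 are not consecutive

  fx2 <- assign_season(dplyr::bind_rows(mk_year(2007, 0), mk_year(2008, 0)))
  fid <- site_fidelity(fx2)
  expect_equal(nrow(fid), 1)
  expect_equal(fid$year_pair, "2007-2008")
  expect_gt(fid$udoi, 0.2) # same range in both years overlaps strongly

  # far-moved range in the next year -> essentially no overlap
  fx3 <- assign_season(dplyr::bind_rows(mk_year(2007, 0), mk_year(2008, 1e6)))
  fid3 <- site_fidelity(fx3)
  expect_equal(fid3$udoi, 0)
})

test_that("full-grid UDOI mode is available and lower for identical uniforms", {
  grid <- make_grid(c(0, 10000), c(0, 10000), cell = 100, margin = 0)
  u <- uniform_ud(grid, 1:50, 1:50)
  full <- udoi(u, u, restrict = FALSE)
  # intersection area 0.95 * support times the unmasked uniform integral 1/area
  expect_equal(full, 0.95, tolerance = 1e-10)
})
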