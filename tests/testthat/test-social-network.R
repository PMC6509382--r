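test_that("chain rule groups collinear animals transitively", {
  m <- tibble::tibble(animal_id = c("A", "B", "C"), x = c(0, 40, 80), y = 0)
  g <- chain_group(m, assoc_dist = 50)
  # A-B and B-C are adjacent, A-C is not, yet all three form one group
  expect_equal(g$group, c(1L, 1L, 1L))

  far <- tibble::tibble(animal_id = c("A", "B"), x = c(0, 60), y = 0)
  g2 <- chain_group(far, assoc_dist = 50)
  expect_equal(length(unique(g2$group)), 2)
})

test_that("chain grouping matches the BFS oracle on random instances", {
  set.seed(101)
  for (trial in 1:200) {
    n <- sample(2:25, 1)
    m <- tibble::tibble(
      animal_id = sprintf("a%02d", seq_len(n)),
      x = runif(n, 0, 300), y = runif(n, 0, 300)
    )
    got <- chain_group(m, assoc_dist = 50)$group
    want <- bfs_groups(m$x, m$y, 50)
    # same partition up to label names
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
  }
})

test_that("dyad counts partition the rounds a dyad appears in", {
  # A,B grouped in 2 rounds; both present but apart in 1; A alone 3; B alone 2
  t0 <- as.POSIXct("2012-01-20 00:00:00", tz = "UTC")
  mk <- function(i, ids, xs) {
    tibble::tibble(animal_id = ids, herd = "h1", timestamp = t0 + i * 7200,
                   x = xs, y = 0, round_time = t0 + i * 7200)
  }
  fx <- dplyr::bind_rows(
    mk(1, c("A", "B"), c(0, 30)),
    mk(2, c("A", "B"), c(0, 10)),
    mk(3, c("A", "B"), c(0, 500)),
    mk(4, "A", 0), mk(5, "A", 0), mk(6, "A", 0),
    mk(7, "B", 0), mk(8, "B", 0)
  )
  dc <- dyad_counts(fx)
  expect_equal(nrow(dc), 1)
  expect_equal(dc$x, 2L)
  expect_equal(dc$y_ab, 1L)
  expect_equal(dc$y_a, 3L)
  expect_equal(dc$y_b, 2L)
  expect_equal(sri(dc$x, dc$y_ab, dc$y_a, dc$y_b), 2 / 8)
})

test_that("degenerate dyad histories count correctly", {
  # always together in all 10 rounds
  always <- dyad_counts(dyad_fixture(rep(10, 10)))
  expect_equal(unname(unlist(always[, c("x", "y_ab", "y_a", "y_b")])),
               c(10L, 0L, 0L, 0L))
  expect_equal(sri(always$x, always$y_ab, always$y_a, always$y_b), 1)

  # never co-observed: A in 4 rounds, B in 6 disjoint rounds
  t0 <- as.POSIXct("2012-01-20 00:00:00", tz = "UTC")
  fx <- dplyr::bind_rows(
    tibble::tibble(animal_id = "A", herd = "h1",
                   timestamp = t0 + (0:3) * 7200, x = 0, y = 0),
    tibble::tibble(animal_id = "B", herd = "h1",
                   timestamp = t0 + (10:15) * 7200, x = 0, y = 0)
  )
  fx$round_time <- fx$timestamp
  dc <- dyad_counts(fx)
  expect_equal(unname(unlist(dc[, c("x", "y_ab", "y_a", "y_b")])),
               c(0L, 0L, 4L, 6L))
  # SRI defined (denominator 10) and zero
  expect_equal(sri(dc$x, dc$y_ab, dc$y_a, dc$y_b), 0)
})

test_that("sri follows the printed formula and flags empty denominators", {
  expect_equal(sri(10, 0, 0, 0), 1)
  expect_equal(sri(0, 5, 3, 2), 0)
  expect_equal(sri(2, 1, 3, 2), 0.25)
  expect_true(is.na(sri(0, 0, 0, 0)))
  expect_error(sri(-1, 0, 0, 0), "non-negative")
})

test_that("a two-animal network has one edge and equal strengths", {
  # separations: 2 rounds together, 1 apart; then A-only and B-only rounds
  t0 <- as.POSIXct("2012-01-20 00:00:00", tz = "UTC")
  mk <- function(i, ids, xs) {
    tibble::tibble(animal_id = ids, herd = "h1", timestamp = t0 + i * 7200,
                   x = xs, y = 0, round_time = t0 + i * 7200)
  }
  fx <- dplyr::bind_rows(
    mk(1, c("A", "B"), c(0, 40)), mk(2, c("A", "B"), c(0, 20)),
    mk(3, c("A", "B"), c(0, 1000)),
    mk(4, "A", 0), mk(5, "A", 0), mk(6, "A", 0),
    mk(7, "B", 0), mk(8, "B", 0)
  )
  net <- build_pbsn(fx)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sri, 0.25)
  expect_equal(net$strength$strength, c(0.25, 0.25))
})

test_that("graph strength is additive over incident edges", {
  # V at origin; B within 50 m in some rounds, C in others, B and C never
  # close to each other or co-observed with both -> two edges incident to V
  t0 <- as.POSIXct("2012-01-20 00:00:00", tz = "UTC")
  mk <- function(i, ids, xs, ys) {
    tibble::tibble(animal_id = ids, herd = "h1", timestamp = t0 + i * 7200,
                   x = xs, y = ys, round_time = t0 + i * 7200)
  }
  fx <- dplyr::bind_rows(
    mk(1, c("V", "B"), c(0, 10), c(0, 0)),
    mk(2, c("V", "B"), c(0, 10), c(0, 0)),
    mk(3, c("V", "B"), c(0, 900), c(0, 0)),
    mk(4, c("V", "B"), c(0, 900), c(0, 0)),
    mk(5, c("V", "B"), c(0, 900), c(0, 0)),
    mk(6, c("V", "C"), c(0, 0), c(0, 10)),
    mk(7, c("V", "C"), c(0, 0), c(0, 900)),
    mk(8, c("V", "C"), c(0, 0), c(0, 900)),
    mk(9, c("V", "C"), c(0, 0), c(0, 900)),
    mk(10, c("V", "C"), c(0, 0), c(0, 900))
  )
  net <- build_pbsn(fx)
  ed <- net$edges
  sV <- net$strength$strength[net$strength$animal_id == "V"]
  expect_equal(sV, sum(ed$sri[ed$animal_a == "V" | ed$animal_b == "V"]))
  expect_equal(sV, 2 / 10 + 1 / 10)
})

test_that("network construction is deterministic and order-invariant", {
  set.seed(77)
  fx <- random_round_fixes(n_animals = 6, n_rounds = 12)
  fx <- dplyr::mutate(fx, season = factor("winter", levels = c("summer", "winter")),
                      year = 2010L)
  n1 <- build_pbsn(fx)
  n2 <- build_pbsn(fx[sample(nrow(fx)), ])
  expect_equal(n1$edges, n2$edges)
  expect_equal(n1$strength, n2$strength)
  n3 <- build_pbsn(fx)
  expect_identical(n1$edges, n3$edges)
})

test_that("single-animal networks warn and yield no edges", {
  fx <- steady_walk(n = 6)
  fx$round_time <- fx$timestamp
  expect_warning(net <- build_pbsn(fx), "fewer than 2")
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$strength$strength, 0)
})

test_that("group co-membership, not raw dyadic distance, defines association", {
  # A at 0, B at 40, C at 80: A and C are 80 m apart but share a group, so
  # the A-C dyad counts toward x
  t0 <- as.POSIXct("2012-01-20 00:00:00", tz = "UTC")
  fx <- tibble::tibble(
    animal_id = c("A", "B", "C"), herd = "h1",
    timestamp = t0, x = c(0, 40, 80), y = 0, round_time = t0
  )
  dc <- dyad_counts(fx)
  ac <- dc[dc$animal_a == "A" & dc$animal_b == "C", ]
  expect_equal(ac$x, 1L)
  expect_equal(ac$y_ab, 0L)
})
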