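# Independent oracles and fixture builders shared across tests.

# Connected components of the <= d proximity graph by explicit breadth-first
# search over the pairwise distance matrix (independent of the package's
# label-merging implementation).
bfs_groups <- function(x, y, d) {
  n <- length(x)
  if (n == 0) return(integer(0))
  dm <- as.matrix(stats::dist(cbind(x, y)))
  adj <- dm <= d
  grp <- rep(NA_integer_, n)
  g <- 0L
  for (s in seq_len(n)) {
    if (!is.na(grp[s])) next
    g <- g + 1L
    queue <- s
    grp[s] <- g
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(grp))
      grp[nb] <- g
      queue <- c(queue, nb)
    }
  }
  grp
}

# Brute-force dyadic counts for one dyad over a list of rounds. Each round is
# a data frame with animal_id, x, y. Grouping uses the BFS oracle.
brute_dyad <- function(rounds, a, b, d) {
  x <- 0L; y_ab <- 0L; y_a <- 0L; y_b <- 0L
  for (r in rounds) {
    has_a <- a %in% r$animal_id
    has_b <- b %in% r$animal_id
    if (has_a && has_b) {
      grp <- bfs_groups(r$x, r$y, d)
      if (grp[match(a, r$animal_id)] == grp[match(b, r$animal_id)]) {
        x <- x + 1L
      } else {
        y_ab <- y_ab + 1L
      }
    } else if (has_a) {
      y_a <- y_a + 1L
    } else if (has_b) {
      y_b <- y_b + 1L
    }
  }
  c(x = x, y_ab = y_ab, y_a = y_a, y_b = y_b)
}

# Random multi-round fixture: n_rounds rounds, each with a random subset of
# animals at random positions. Returns a round-aligned fix tibble.
random_round_fixes <- function(n_animals = 5, n_rounds = 8, spread = 120,
                               herd = "h1") {
  ids <- sprintf("a%02d", seq_len(n_animals))
  rows <- list()
  t0 <- as.POSIXct("2010-01-20 00:00:00", tz = "UTC")
  for (r in seq_len(n_rounds)) {
    present <- ids[stats::runif(n_animals) < 0.8]
    if (length(present) == 0) present <- sample(ids, 1)
    rows[[r]] <- tibble::tibble(
      animal_id = present,
      herd = herd,
      timestamp = t0 + (r - 1) * 7200,
      x = stats::runif(length(present), 0, spread),
      y = stats::runif(length(present), 0, spread)
    )
  }
  fx <- dplyr::bind_rows(rows)
  fx$round_time <- fx$timestamp
  fx
}

# round list view of a round-aligned fix tibble (for the brute oracle)
rounds_of <- function(fx) {
  lapply(split(fx, fx$round_time), function(r) r[order(r$animal_id), ])
}

# Hand-built uniform utilization distribution over a rectangular block of
# cells, as a `ud` object on the given grid.
uniform_ud <- function(grid, ix, iy) {
  mass <- matrix(0, grid$nx, grid$ny)
  mass[ix, iy] <- 1 / (length(ix) * length(iy))
  structure(list(grid = grid, mass = mass, h = grid$cell, n_fixes = 10L),
            class = "ud")
}

# Minimal clean movement track for screening tests: constant velocity walk.
steady_walk <- function(n = 10, speed_m_hr = 200, interval_hr = 2,
                        id = "w1", herd = "h1") {
  t0 <- as.POSIXct("2011-01-20 00:00:00", tz = "UTC")
  tibble::tibble(
    animal_id = id,
    herd = herd,
    timestamp = t0 + (seq_len(n) - 1) * interval_hr * 3600,
    x = (seq_len(n) - 1) * speed_m_hr * interval_hr,
    y = 0
  )
}

# Season-tagged two-animal fixture with prescribed per-round separations:
# one round per element of `sep`; animals sit at (0, 0) and (sep, 0).
dyad_fixture <- function(sep, herd = "h1") {
  t0 <- as.POSIXct("2012-01-20 00:00:00", tz = "UTC")
  fx <- dplyr::bind_rows(lapply(seq_along(sep), function(i) {
    tibble::tibble(
      animal_id = c("A", "B"),
      herd = herd,
      timestamp = t0 + (i - 1) * 7200,
      x = c(0, sep[i]),
      y = 0
    )
  }))
  fx$round_time <- fx$timestamp
  fx
}
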