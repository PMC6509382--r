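#' Chain-rule group assignment for one sampling round
#'
#' Partitions the members of a round into social groups by the chain rule:
#' two animals are adjacent when they are within `assoc_dist` of each other,
#' and a group is a connected component of that adjacency graph. Members of a
#' group need not all be mutually within `assoc_dist`; a chain of pairwise
#' proximities suffices.
#'
#' @param members A data frame with one row per animal present in the round
#'   and columns `animal_id`, `x`, `y`.
#' @param assoc_dist Adjacency distance in meters (default 50).
#' @return `members` with an integer `group` column (labels are arbitrary but
#'   consecutive from 1).
#' @export
#' @examples
#' chain_group(tibble::tibble(animal_id = c("a", "b", "c"),
#'                            x = c(0, 40, 80), y = 0))
chain_group <- function(members, assoc_dist = 50) {
  if (!all(c("animal_id", "x", "y") %in% names(members))) {
    rlang::abort("`members` needs columns animal_id, x, y")
  }
  n <- nrow(members)
  if (n == 0) {
    members$group <- integer(0)
    return(members)
  }
  lab <- merge_components(members$x, members$y, assoc_dist)
  members$group <- match(lab, unique(lab))
  members
}

# label-merging connected components under the <= d adjacency; O(n^2) on the
# handful of animals present in one round
merge_components <- function(x, y, d) {
  n <- length(x)
  lab <- seq_len(n)
  if (n < 2) return(lab)
  d2 <- d^2
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= d2) {
        la <- lab[i]; lb <- lab[j]
        if (la != lb) lab[lab == lb] <- la
      }
    }
  }
  lab
}

# Core association engine over many rounds.
#
# round, animal: integer indices (1..n_rounds, 1..n_animals); x, y planar m.
# At most one fix per animal per round (build_rounds guarantees this).
# Returns per-dyad chain-rule co-membership counts x, co-observation counts
# n_ab, per-animal observation counts n_obs, and the number of groups of two
# or more animals summed over rounds.
sri_engine <- function(round, animal, x, y, n_rounds, n_animals, assoc_dist) {
  X <- matrix(NA_real_, n_rounds, n_animals)
  Y <- matrix(NA_real_, n_rounds, n_animals)
  idx <- cbind(round, animal)
  X[idx] <- x
  Y[idx] <- y
  present <- !is.na(X)
  n_obs <- colSums(present)

  if (n_animals < 2) {
    return(list(pa = integer(0), pb = integer(0), x = integer(0),
                n_ab = integer(0), n_obs = n_obs, n_groups = 0L))
  }
  pr <- which(upper.tri(diag(n_animals)), arr.ind = TRUE)
  pa <- pr[, 1]; pb <- pr[, 2]
  co <- present[, pa, drop = FALSE] & present[, pb, drop = FALSE]
  d2 <- (X[, pa, drop = FALSE] - X[, pb, drop = FALSE])^2 +
        (Y[, pa, drop = FALSE] - Y[, pb, drop = FALSE])^2
  adj <- co
  adj[co] <- d2[co] <= assoc_dist^2
  n_ab <- colSums(co)

  xcnt <- integer(length(pa))
  n_groups <- 0L
  edge_rounds <- which(rowSums(adj) > 0)
  for (r in edge_rounds) {
    lab <- seq_len(n_animals)
    for (k in which(adj[r, ])) {
      la <- lab[pa[k]]; lb <- lab[pb[k]]
      if (la != lb) lab[lab == lb] <- la
    }
    same <- co[r, ] & lab[pa] == lab[pb]
    xcnt <- xcnt + same
    tab <- tabulate(lab[present[r, ]], nbins = n_animals)
    n_groups <- n_groups + sum(tab >= 2L)
  }
  list(pa = pa, pb = pb, x = xcnt, n_ab = n_ab, n_obs = n_obs,
       n_groups = n_groups)
}

# shared front door: round-aligned fixes -> engine inputs, per network key
network_keys <- function(fixes) {
  keys <- intersect(c("herd", "season", "year"), names(fixes))
  if (length(keys) == 0) rlang::abort("fixes need at least a `herd` column")
  keys
}

#' Dyadic association counts
#'
#' For every dyad observed in a herd-season-year, counts the sampling rounds
#' in which the two animals were grouped together (`x`, chain-rule
#' co-membership), both observed but in different groups (`y_ab`), and each
#' observed without a simultaneous fix from the other (`y_a`, `y_b`).
#' These four counts partition the rounds in which at least one member of
#' the dyad appears.
#'
#' @param fixes Round-aligned, season-tagged fixes (see [build_rounds()]).
#' @param assoc_dist Chain-rule adjacency distance, m.
#' @return A tibble with one row per dyad per network:
#'   herd/season/year keys, `animal_a`, `animal_b`, `x`, `y_ab`, `y_a`, `y_b`.
#' @export
dyad_counts <- function(fixes, assoc_dist = 50) {
  check_fixes(fixes)
  if (!"round_time" %in% names(fixes)) {
    rlang::abort("fixes must carry `round_time`; run build_rounds() first")
  }
  keys <- network_keys(fixes)
  fixes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(.x, .y) dyad_counts_one(.x, assoc_dist)) |>
    dplyr::ungroup()
}

dyad_counts_one <- function(fx, assoc_dist) {
  ids <- sort(unique(fx$animal_id))
  rounds <- sort(unique(fx$round_time))
  eng <- sri_engine(
    round = match(fx$round_time, rounds),
    animal = match(fx$animal_id, ids),
    x = fx$x, y = fx$y,
    n_rounds = length(rounds), n_animals = length(ids),
    assoc_dist = assoc_dist
  )
  tibble::tibble(
    animal_a = ids[eng$pa],
    animal_b = ids[eng$pb],
    x = as.integer(eng$x),
    y_ab = as.integer(eng$n_ab - eng$x),
    y_a = as.integer(eng$n_obs[eng$pa] - eng$n_ab),
    y_b = as.integer(eng$n_obs[eng$pb] - eng$n_ab)
  )
}

#' Simple ratio index
#'
#' The simple ratio association index
#' \deqn{SRI = x / (x + y_{AB} + y_A + y_B)}
#' where `x` counts rounds in which the dyad was grouped together, `y_ab`
#' rounds in which both were observed but separated, and `y_a`, `y_b` rounds
#' in which only one of the two was observed. All arguments are recycled;
#' dyads never observed (zero denominator) yield `NA`, which downstream
#' network construction treats as "no edge".
#'
#' @param x,y_ab,y_a,y_b Non-negative counts.
#' @return Association weights in \[0, 1\] (or `NA` for empty denominators).
#' @export
#' @examples
#' sri(2, 1, 3, 2) # 0.25
sri <- function(x, y_ab, y_a, y_b) {
  if (any(c(x, y_ab, y_a, y_b) < 0, na.rm = TRUE)) {
    rlang::abort("association counts must be non-negative")
  }
  den <- x + y_ab + y_a + y_b
  ifelse(den > 0, x / den, NA_real_)
}

#' Build proximity-based social networks
#'
#' Constructs one weighted, undirected social network per herd-season-year
#' from round-aligned fixes. Association is chain-rule group co-membership
#' within a round; edges are weighted by the simple ratio index and dyads
#' with an empty denominator contribute no edge. Graph strength is the sum
#' of incident edge weights, zero for observed animals with no edges.
#'
#' @param fixes Round-aligned, season-tagged fixes (see [build_rounds()]).
#' @param assoc_dist Chain-rule adjacency distance, m (default 50).
#' @return An object of class `pbsn`: a list with tibbles `edges`
#'   (herd/season/year, `animal_a`, `animal_b`, counts, `sri`), `strength`
#'   (per animal per network, with `n_obs` rounds observed), and `groups`
#'   (per network, the number of groups of two or more animals summed over
#'   rounds).
#' @export
build_pbsn <- function(fixes, assoc_dist = 50) {
  check_fixes(fixes)
  if (!"round_time" %in% names(fixes)) {
    rlang::abort("fixes must carry `round_time`; run build_rounds() first")
  }
  keys <- network_keys(fixes)
  nets <- fixes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_map(function(.x, .y) {
      res <- pbsn_one(.x, assoc_dist)
      list(key = .y, res = res)
    })

  bind_key <- function(part) {
    purrr::map_dfr(nets, function(nt) dplyr::bind_cols(nt$key, nt$res[[part]]))
  }
  out <- list(
    edges = bind_key("edges"),
    strength = bind_key("strength"),
    groups = bind_key("groups"),
    assoc_dist = assoc_dist,
    keys = keys
  )
  class(out) <- "pbsn"
  out
}

pbsn_one <- function(fx, assoc_dist) {
  ids <- sort(unique(fx$animal_id))
  if (length(ids) < 2) {
    rlang::warn("network with fewer than 2 animals: no edges possible")
  }
  rounds <- sort(unique(fx$round_time))
  eng <- sri_engine(
    round = match(fx$round_time, rounds),
    animal = match(fx$animal_id, ids),
    x = fx$x, y = fx$y,
    n_rounds = length(rounds), n_animals = length(ids),
    assoc_dist = assoc_dist
  )
  edges <- tibble::tibble(
    animal_a = ids[eng$pa],
    animal_b = ids[eng$pb],
    x = as.integer(eng$x),
    y_ab = as.integer(eng$n_ab - eng$x),
    y_a = as.integer(eng$n_obs[eng$pa] - eng$n_ab),
    y_b = as.integer(eng$n_obs[eng$pb] - eng$n_ab)
  )
  edges$sri <- sri(edges$x, edges$y_ab, edges$y_a, edges$y_b)
  edges <- edges[!is.na(edges$sri), , drop = FALSE]
  strength <- vapply(seq_along(ids), function(i) {
    sum(edges$sri[edges$animal_a == ids[i] | edges$animal_b == ids[i]])
  }, numeric(1))
  degree <- vapply(seq_along(ids), function(i) {
    sum((edges$animal_a == ids[i] | edges$animal_b == ids[i]) & edges$sri > 0)
  }, integer(1))
  list(
    edges = edges,
    strength = tibble::tibble(
      animal_id = ids,
      strength = strength,
      degree = as.integer(degree),
      n_obs = as.integer(eng$n_obs)
    ),
    groups = tibble::tibble(n_groups = as.integer(eng$n_groups))
  )
}

#' @export
print.pbsn <- function(x, ...) {
  n_nets <- nrow(x$groups)
  cat(glue::glue(
    "<pbsn> {n_nets} network(s), {nrow(x$edges)} edge(s), ",
    "{nrow(x$strength)} animal-network(s); assoc_dist = {x$assoc_dist} m"
  ), "\n")
  invisible(x)
}

#' Convert a social network to an igraph object
#'
#' @param net A `pbsn` object.
#' @param herd,season,year Keys selecting one network (may be omitted when
#'   the object holds a single network).
#' @return An `igraph` weighted undirected graph with a `sri` edge attribute.
#' @export
pbsn_igraph <- function(net, herd = NULL, season = NULL, year = NULL) {
  stopifnot(inherits(net, "pbsn"))
  ed <- net$edges
  st <- net$strength
  for (k in c("herd", "season", "year")) {
    v <- get(k)
    if (!is.null(v) && k %in% names(ed)) {
      ed <- ed[ed[[k]] == v, , drop = FALSE]
      st <- st[st[[k]] == v, , drop = FALSE]
    }
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = ed$animal_a, to = ed$animal_b, weight = ed$sri, sri = ed$sri),
    directed = FALSE,
    vertices = data.frame(name = st$animal_id)
  )
  g
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a social network into its edge list
#'
#' @param x A `pbsn` object.
#' @param ... Unused.
#' @return The edge tibble (one row per dyad with a defined SRI).
#' @export
tidy.pbsn <- function(x, ...) x$edges

#' One-row-per-network summary of a social network object
#'
#' @param x A `pbsn` object.
#' @param ... Unused.
#' @return A tibble with node/edge counts, mean strength and group counts
#'   per herd-season-year.
#' @export
glance.pbsn <- function(x, ...) {
  keys <- x$keys
  nodes <- x$strength |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      mean_strength = mean(.data$strength),
      .groups = "drop"
    )
  edges <- x$edges |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_edges = dplyr::n(), mean_sri = mean(.data$sri), .groups = "drop")
  nodes |>
    dplyr::left_join(edges, by = keys) |>
    dplyr::left_join(x$groups, by = keys) |>
    dplyr::mutate(
      n_edges = dplyr::coalesce(.data$n_edges, 0L),
      mean_sri = dplyr::coalesce(.data$mean_sri, NA_real_)
    )
}

#' Export a social network as edge-list CSV and GraphML
#'
#' @param net A `pbsn` object.
#' @param edge_csv Path for the weighted edge list CSV.
#' @param strength_csv Path for the per-animal strength CSV.
#' @param graphml Optional path for a GraphML export of the pooled network
#'   (one file; herd-season-year keys become edge attributes).
#' @return Invisibly, the paths written.
#' @export
export_pbsn <- function(net, edge_csv, strength_csv, graphml = NULL) {
  stopifnot(inherits(net, "pbsn"))
  utils::write.csv(net$edges, edge_csv, row.names = FALSE)
  utils::write.csv(net$strength, strength_csv, row.names = FALSE)
  paths <- c(edge_csv, strength_csv)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = net$edges$animal_a, to = net$edges$animal_b,
                     weight = net$edges$sri),
      directed = FALSE
    )
    igraph::write_graph(g, graphml, format = "graphml")
    paths <- c(paths, graphml)
  }
  invisible(paths)
}
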