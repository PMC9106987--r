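#' q-Multiset Multicover instances
#'
#' The emergency-doctor provision model: suppliers (doctors with vehicles)
#' are placed at locations (potential stations); each supplier can serve up
#' to `q` clients in the regions its location is incident to; every region's
#' integral client count must be served. The objective is the minimum total
#' number of suppliers.
#'
#' @param locations character vector of location ids.
#' @param regions character vector of region ids.
#' @param clients named non-negative integer vector per region.
#' @param incidence logical matrix `locations x regions` (TRUE = a supplier
#'   at that location may serve that region).
#' @param q clients servable per supplier (>= 1).
#' @return list of class `cover_instance`.
#' @export
cover_instance <- function(locations, regions, clients, incidence, q) {
  locations <- as.character(locations); regions <- as.character(regions)
  if (q < 1) stop_input("q must be >= 1")
  clients <- clients[regions]
  if (anyNA(clients) || any(clients < 0) || any(!is.finite(clients))) {
    stop_input("clients must be finite, non-negative, and keyed by region")
  }
  incidence <- as.matrix(incidence)
  if (!identical(dim(incidence), c(length(locations), length(regions)))) {
    stop_input("incidence must be a locations x regions matrix")
  }
  dimnames(incidence) <- list(locations, regions)
  structure(list(locations = locations, regions = regions,
                 clients = stats::setNames(as.integer(clients), regions),
                 incidence = incidence, q = as.integer(q)),
            class = "cover_instance")
}

#' Incidence from travel times
#'
#' Derives the location-region incidence of a [cover_instance()] from the
#' street network: a location is incident to a municipality iff the fastest
#' route from the location to the municipality center is within a response
#' threshold under the given (typically blue-light) profile.
#'
#' @param region a [generate_region()] result.
#' @param stations character vector of station nodes (locations).
#' @param profile a [speed_profile()].
#' @param threshold_s response-time threshold in seconds (default 12 min).
#' @param clients named client counts per municipality.
#' @param q clients per supplier.
#' @return A [cover_instance()] with locations = stations and regions =
#'   municipality ids.
#' @export
cover_instance_from_region <- function(region, stations, profile,
                                       threshold_s = 720, clients, q) {
  mun <- region$municipalities
  inc <- matrix(FALSE, length(stations), nrow(mun),
                dimnames = list(stations, mun$id))
  for (s in stations) {
    tt <- nearest_source_times(region$network, profile, s)
    inc[s, ] <- tt[mun$center] <= threshold_s
  }
  cover_instance(stations, mun$id, clients, inc, q)
}

#' Check whether an allocation covers a client vector
#'
#' Feasibility is decided by maximum flow on the bipartite network
#' source -> locations (capacity `q * suppliers`) -> incident regions ->
#' sink (capacity `clients`): the allocation serves all clients iff the
#' maximum flow equals the total client count.
#'
#' @param inst a [cover_instance()].
#' @param suppliers named non-negative integer vector per location.
#' @param clients optional client vector (defaults to the instance's).
#' @return list: `feasible` flag, `uncovered` (region ids whose demand is
#'   not met), `flow` (served clients per region).
#' @export
check_coverage <- function(inst, suppliers, clients = NULL) {
  clients <- if (is.null(clients)) inst$clients else {
    stats::setNames(as.integer(clients[inst$regions]), inst$regions)
  }
  suppliers <- stats::setNames(as.integer(round(suppliers[inst$locations])),
                               inst$locations)
  suppliers[is.na(suppliers)] <- 0L
  total <- sum(clients)
  if (total == 0L) {
    return(list(feasible = TRUE, uncovered = character(0),
                flow = stats::setNames(rep(0L, length(inst$regions)),
                                       inst$regions)))
  }
  nl <- length(inst$locations); nr <- length(inst$regions)
  # vertices: 1 = source, 2..(nl+1) locations, then regions, last = sink
  from <- integer(0); to <- integer(0); cap <- numeric(0)
  for (i in seq_len(nl)) {
    from <- c(from, 1L); to <- c(to, 1L + i)
    cap <- c(cap, inst$q * suppliers[i])
  }
  for (i in seq_len(nl)) for (j in seq_len(nr)) {
    if (inst$incidence[i, j]) {
      from <- c(from, 1L + i); to <- c(to, 1L + nl + j)
      cap <- c(cap, inst$q * suppliers[i])
    }
  }
  for (j in seq_len(nr)) {
    from <- c(from, 1L + nl + j); to <- c(to, 2L + nl + nr)
    cap <- c(cap, clients[j])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(g) < 2L + nl + nr) {
    g <- igraph::add_vertices(g, 2L + nl + nr - igraph::vcount(g))
  }
  mf <- igraph::max_flow(g, source = 1L, target = 2L + nl + nr,
                         capacity = cap)
  region_arc <- seq.int(length(from) - nr + 1L, length(from))
  served <- stats::setNames(as.integer(round(mf$flow[region_arc])),
                            inst$regions)
  uncovered <- inst$regions[served < clients]
  list(feasible = abs(mf$value - total) < 0.5, uncovered = uncovered,
       flow = served)
}

#' Solve q-Multiset Multicover to optimality
#'
#' Exact branch-and-bound over supplier counts per location (depth-first,
#' locations in ascending id order, higher counts tried first so ties favor
#' the lexicographically smallest location ids), with flow-based feasibility
#' at the leaves and combinatorial lower bounds (`ceil(total/q)` overall and
#' `ceil(clients_r / q)` over each region's incident locations) for pruning.
#'
#' @param inst a [cover_instance()].
#' @return list of class `cover_allocation`: `suppliers` (named integer per
#'   location), `cost` (their sum).
#' @export
solve_qmsmc <- function(inst) {
  solve_qmsmc_scenarios(inst, list(inst$clients))
}

#' Robust q-Multiset Multicover
#'
#' Minimum-cost allocation feasible for every client scenario in the
#' uncertainty set (an explicit finite list of client vectors).
#'
#' @param inst a [cover_instance()].
#' @param scenarios non-empty list of named client vectors per region.
#' @return A `cover_allocation` feasible for all scenarios.
#' @export
solve_robust_qmsmc <- function(inst, scenarios) {
  if (!length(scenarios)) stop_input("uncertainty set must be non-empty")
  solve_qmsmc_scenarios(inst, scenarios)
}

solve_qmsmc_scenarios <- function(inst, scenarios) {
  nl <- length(inst$locations)
  scen <- lapply(seq_along(scenarios), function(k) {
    sc <- scenarios[[k]]
    v <- stats::setNames(as.integer(sc[inst$regions]), inst$regions)
    v[is.na(v)] <- 0L
    orphan <- inst$regions[v > 0L & colSums(inst$incidence) == 0L]
    if (length(orphan)) {
      stop_infeasible(sprintf(
        "region(s) with clients but no incident location%s: %s",
        if (length(scenarios) > 1L) sprintf(" in scenario %d", k) else "",
        paste(orphan, collapse = ", ")), detail = orphan)
    }
    v
  })
  q <- inst$q
  lb_total <- max(vapply(scen, function(v) ceiling(sum(v) / q), 0))
  if (max(vapply(scen, sum, 0)) == 0) {
    return(structure(list(suppliers = stats::setNames(rep(0L, nl),
                                                      inst$locations),
                          cost = 0L), class = "cover_allocation"))
  }
  # Feasibility for a fixed allocation is a transportation problem; by
  # max-flow/min-cut it holds iff for every region subset S the q-capacity
  # of locations incident to S covers the demand of S. With few regions the
  # subsets are enumerated directly; otherwise fall back to the flow check.
  nr <- length(inst$regions)
  if (nr <= 12L) {
    subsets <- lapply(seq_len(2^nr - 1L), function(mask) {
      S <- which(bitwAnd(mask, 2^(seq_len(nr) - 1L)) > 0L)
      locs <- which(rowSums(inst$incidence[, S, drop = FALSE]) > 0L)
      list(S = S, locs = locs)
    })
    feasible_one <- function(x, v) {
      for (sb in subsets) {
        if (q * sum(x[sb$locs]) < sum(v[sb$S])) return(FALSE)
      }
      TRUE
    }
  } else {
    feasible_one <- function(x, v) {
      check_coverage(inst, stats::setNames(x, inst$locations), v)$feasible
    }
  }
  feasible_all <- function(x) {
    all(vapply(scen, function(v) feasible_one(x, v), TRUE))
  }
  # guaranteed upper bound: stack each scenario's per-region independent
  # covering (suppliers only help, so the union is feasible for every
  # scenario)
  x_ub <- rep(0L, nl)
  for (v in scen) {
    need <- ceiling(v / q)
    for (j in seq_along(inst$regions)) {
      if (need[j] > 0L) {
        loc <- which(inst$incidence[, j])[1L]
        x_ub[loc] <- x_ub[loc] + need[j]
      }
    }
  }
  stopifnot(feasible_all(x_ub))
  best_cost <- sum(x_ub)
  best_x <- x_ub

  # region lower bound given partial assignment: suppliers incident to each
  # region among undecided locations can still grow, so only check regions
  # whose incident locations are all decided
  x <- rep(0L, nl)
  rec <- function(i, placed) {
    if (placed + max(0L, lb_total - placed) > best_cost) return(invisible(NULL))
    if (placed >= best_cost) return(invisible(NULL))
    if (i > nl) {
      if (feasible_all(x) && placed < best_cost) {
        best_cost <<- placed; best_x <<- x
      }
      return(invisible(NULL))
    }
    # per-scenario bound over regions fully decided after location i-1
    for (v in scen) {
      for (j in seq_along(inst$regions)) {
        inc <- which(inst$incidence[, j])
        if (all(inc < i)) {
          if (q * sum(x[inc]) < v[j]) return(invisible(NULL))
        } else {
          # even with all remaining incident capacity the bound must hold
          # only via best_cost budget
          rem_budget <- best_cost - 1L - placed
          undecided <- inc[inc >= i]
          if (q * (sum(x[inc[inc < i]]) + rem_budget) < v[j] &&
              length(undecided)) return(invisible(NULL))
        }
      }
    }
    for (cnt in (best_cost - 1L - placed):0L) {
      if (cnt < 0L) break
      x[i] <<- cnt
      rec(i + 1L, placed + cnt)
      x[i] <<- 0L
    }
  }
  rec(1L, 0L)
  structure(list(suppliers = stats::setNames(as.integer(best_x),
                                             inst$locations),
                 cost = as.integer(best_cost)),
            class = "cover_allocation")
}

#' @export
print.cover_allocation <- function(x, ...) {
  cat(sprintf("<cover_allocation> %d supplier(s)\n", x$cost))
  nz <- x$suppliers[x$suppliers > 0]
  for (l in names(nz)) cat(sprintf("  %s: %d\n", l, nz[[l]]))
  invisible(x)
}
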