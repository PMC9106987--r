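#' Vaccination-center location instances
#'
#' The strategic siting problem: decide which candidate centers to open, how
#' to assign each municipality to exactly one open center, and how many
#' physicians to staff at each center. Distances are straight-line (Euclidean)
#' between the municipality center coordinate and the site coordinate.
#' Staffing must satisfy `physicians(s) >= ceil(assigned population /
#' throughput)`.
#'
#' @param candidates data.frame: `id`, `x`, `y` of candidate sites.
#' @param municipalities data.frame: `id`, `x`, `y`, `population`.
#' @param throughput persons one physician can vaccinate over the campaign.
#' @param weights numeric length-3 `(w_centers, w_distance, w_physicians)`,
#'   all >= 0, not all zero. The distance term is population-weighted
#'   person-kilometers.
#' @param capacity optional named vector: per-site population cap.
#' @param prefix optional named character vector municipality -> site,
#'   fixing those assignments.
#' @param max_dist_m optional maximum assignment distance in meters.
#' @return list of class `vax_instance`.
#' @export
vax_instance <- function(candidates, municipalities, throughput,
                         weights = c(centers = 1, distance = 1e-4,
                                     physicians = 0.1),
                         capacity = NULL, prefix = NULL, max_dist_m = Inf) {
  if (throughput <= 0) stop_input("throughput must be > 0")
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(weights < 0) || all(weights == 0)) {
    stop_input("weights must be 3 non-negative values, not all zero")
  }
  candidates <- data.frame(id = as.character(candidates$id),
                           x = as.numeric(candidates$x),
                           y = as.numeric(candidates$y),
                           stringsAsFactors = FALSE)
  municipalities <- data.frame(id = as.character(municipalities$id),
                               x = as.numeric(municipalities$x),
                               y = as.numeric(municipalities$y),
                               population = as.numeric(municipalities$population),
                               stringsAsFactors = FALSE)
  if (!is.null(prefix)) {
    bad <- !(names(prefix) %in% municipalities$id) | !(prefix %in% candidates$id)
    if (any(bad)) stop_input("prefix references unknown municipality or site")
  }
  structure(list(candidates = candidates, municipalities = municipalities,
                 throughput = throughput,
                 weights = stats::setNames(weights, c("centers", "distance",
                                                      "physicians")),
                 capacity = capacity, prefix = prefix,
                 max_dist_m = max_dist_m),
            class = "vax_instance")
}

# municipality x site distance matrix in km
vax_dist_km <- function(inst) {
  dx <- outer(inst$municipalities$x, inst$candidates$x, "-")
  dy <- outer(inst$municipalities$y, inst$candidates$y, "-")
  d <- sqrt(dx^2 + dy^2) / 1000
  dimnames(d) <- list(inst$municipalities$id, inst$candidates$id)
  d
}

#' Solve the vaccination-center location problem to optimality
#'
#' Exact branch-and-bound over open-site sets and municipality assignments:
#' minimizes `w_centers * #open + w_distance * sum_m pop_m * dist_km(m,
#' site(m)) + w_physicians * sum_s ceil(load_s / throughput)` subject to
#' single assignment, staffing coverage, and any capacity / prefix /
#' max-distance scenario constraints. `objective = "lexicographic"` instead
#' minimizes the number of open centers first, then the person-distance,
#' then the physician total.
#'
#' @param inst a [vax_instance()].
#' @param objective `"weighted"` (default) or `"lexicographic"`.
#' @return list of class `vax_plan`: `open` (site ids), `assign` (named
#'   vector municipality -> site), `physicians` (named integer per open
#'   site), `objective` value, `weights`.
#' @export
solve_center_location <- function(inst, objective = c("weighted",
                                                      "lexicographic")) {
  objective <- match.arg(objective)
  stopifnot(inherits(inst, "vax_instance"))
  nm <- nrow(inst$municipalities); ns <- nrow(inst$candidates)
  if (ns == 0L) stop_input("no candidate sites")
  if (ns > 16L) stop_input("exact solver limited to 16 candidate sites")
  d <- vax_dist_km(inst)
  pop <- inst$municipalities$population
  mid <- inst$municipalities$id; sid <- inst$candidates$id

  allowed <- d * 1000 <= inst$max_dist_m
  if (!is.null(inst$prefix)) {
    for (m in names(inst$prefix)) {
      i <- match(m, mid)
      allowed[i, ] <- sid == inst$prefix[[m]]
    }
  }
  bad <- which(rowSums(allowed) == 0L)
  if (length(bad)) {
    stop_infeasible(sprintf("no admissible site for municipalit%s %s",
                            if (length(bad) > 1) "ies" else "y",
                            paste(mid[bad], collapse = ", ")),
                    detail = mid[bad])
  }

  cap <- rep(Inf, ns)
  if (!is.null(inst$capacity)) cap[match(names(inst$capacity), sid)] <-
      as.numeric(inst$capacity)

  w <- inst$weights
  # objective as a 3-tuple compared lexicographically; the weighted mode
  # collapses everything into the first component
  tup <- function(open_n, dist_pk, phys) {
    if (objective == "weighted") {
      c(w[["centers"]] * open_n + w[["distance"]] * dist_pk +
          w[["physicians"]] * phys, 0, 0)
    } else c(open_n, dist_pk, phys)
  }
  lex_lt <- function(a, b) {
    for (k in 1:3) {
      if (a[k] < b[k] - 1e-9) return(TRUE)
      if (a[k] > b[k] + 1e-9) return(FALSE)
    }
    FALSE
  }
  best_val <- c(Inf, Inf, Inf)
  best_sol <- NULL

  ord_m <- order(pop, decreasing = TRUE)  # big municipalities first
  for (mask in seq_len(2^ns) - 1L) {
    open <- which(bitwAnd(mask, 2^(seq_len(ns) - 1L)) > 0L)
    if (!length(open)) next
    if (any(rowSums(allowed[, open, drop = FALSE]) == 0L)) next
    if (!lex_lt(tup(length(open), 0, 0), best_val)) next

    # B&B over assignments: partial cost uses ceil monotonicity as a bound
    load <- stats::setNames(rep(0, length(open)), sid[open])
    asg <- rep(NA_integer_, nm)
    # remaining lower bound on the distance term per municipality
    minrow <- vapply(seq_len(nm), function(i) {
      ao <- open[allowed[i, open]]
      if (!length(ao)) Inf else min(d[i, ao]) * pop[i]
    }, 0)
    if (any(!is.finite(minrow))) next

    rec <- function(t, dist_pk) {
      if (t > nm) {
        phys <- sum(ceiling(load / inst$throughput))
        val <- tup(length(open), dist_pk, phys)
        if (lex_lt(val, best_val)) {
          best_val <<- val
          best_sol <<- list(open = open, asg = asg,
                            load = load, dist_pk = dist_pk, phys = phys)
        }
        return(invisible(NULL))
      }
      i <- ord_m[t]
      rest_lb <- if (t < nm) sum(minrow[ord_m[(t + 1):nm]]) else 0
      for (s in open[allowed[i, open]]) {
        si <- sid[s]
        if (load[[si]] + pop[i] > cap[s]) next
        load2 <- load; load2[[si]] <- load2[[si]] + pop[i]
        phys_lb <- sum(ceiling(load2 / inst$throughput))
        lb <- tup(length(open), dist_pk + d[i, s] * pop[i] + rest_lb, phys_lb)
        if (!lex_lt(lb, best_val)) next
        load <<- load2; asg[i] <<- s
        rec(t + 1L, dist_pk + d[i, s] * pop[i])
        load[[si]] <<- load[[si]] - pop[i]; asg[i] <<- NA_integer_
      }
    }
    rec(1L, 0)
  }
  if (is.null(best_sol)) {
    stop_infeasible("no feasible center plan (capacity or distance constraints)",
                    detail = mid)
  }
  phys <- ceiling(best_sol$load / inst$throughput)
  structure(list(open = sid[best_sol$open],
                 assign = stats::setNames(sid[best_sol$asg], mid),
                 physicians = stats::setNames(as.integer(phys), names(phys)),
                 objective = if (objective == "weighted") best_val[1L] else
                   c(centers = best_val[1L], person_km = best_val[2L],
                     physicians = best_val[3L]),
                 mode = objective, weights = w),
            class = "vax_plan")
}

#' @export
print.vax_plan <- function(x, ...) {
  cat(sprintf("<vax_plan> %d open center(s), %d physicians total\n",
              length(x$open), sum(x$physicians)))
  for (s in x$open) {
    cat(sprintf("  %s: %d physician(s), municipalities: %s\n", s,
                x$physicians[[s]],
                paste(names(x$assign)[x$assign == s], collapse = ", ")))
  }
  invisible(x)
}

#' Evaluate a vaccination plan
#'
#' Deterministic decision-support statistics: per-municipality travel
#' distance to the assigned center, the population-weighted median distance
#' (the choropleth statistic), center count and physician total. Optionally
#' re-evaluates staffing needs over a list of demand scenarios and reports
#' the worst case.
#'
#' @param inst a [vax_instance()].
#' @param plan a `vax_plan` (or a list with `open`, `assign`, `physicians`).
#' @param scenarios optional list of named population vectors; the plan's
#'   worst-case physician need over the scenarios is reported.
#' @return list: `distance_km` (named per municipality),
#'   `median_km` (population-weighted), `n_centers`, `physicians_total`,
#'   and `worst_case_physicians` when scenarios are given.
#' @export
evaluate_plan <- function(inst, plan, scenarios = NULL) {
  mid <- inst$municipalities$id
  if (any(!(mid %in% names(plan$assign))) || anyNA(plan$assign[mid])) {
    stop_input("plan leaves municipalities unassigned: %s",
               paste(setdiff(mid, names(plan$assign)[!is.na(plan$assign)]),
                     collapse = ", "))
  }
  if (any(!(plan$assign[mid] %in% plan$open))) {
    stop_input("assignment targets a center that is not open")
  }
  d <- vax_dist_km(inst)
  dist_km <- vapply(mid, function(m) d[m, plan$assign[[m]]], 0)
  med <- weighted_median(dist_km, inst$municipalities$population)
  out <- list(distance_km = dist_km, median_km = med,
              n_centers = length(plan$open),
              physicians_total = sum(plan$physicians))
  if (!is.null(scenarios)) {
    out$worst_case_physicians <- max(vapply(scenarios, function(sc) {
      load <- tapply(sc[mid], plan$assign[mid], sum)
      sum(ceiling(load / inst$throughput))
    }, 0))
  }
  out
}

# Weighted lower median: smallest value whose cumulative weight reaches half
# the total. With equal weights on {1,2,3} this is 2.
weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  unname(x[o][which(cw >= sum(w) / 2)[1L]])
}

#' GeoJSON allocation chart for a vaccination plan
#'
#' Emits site `Point` features (with `physicians`, sized like the paper's
#' allocation-chart markers) and one `LineString` per municipality connecting
#' its center coordinate to the assigned site, plus per-municipality
#' properties `median_km` for choropleth coloring.
#'
#' @param inst a [vax_instance()]; @param plan a `vax_plan`.
#' @return GeoJSON list structure.
#' @export
vax_geojson <- function(inst, plan) {
  ev <- evaluate_plan(inst, plan)
  feats <- list()
  for (s in plan$open) {
    i <- match(s, inst$candidates$id)
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(inst$candidates$x[i], inst$candidates$y[i])),
      properties = list(kind = "site", id = s,
                        physicians = unname(plan$physicians[[s]])))
  }
  for (m in inst$municipalities$id) {
    i <- match(m, inst$municipalities$id)
    s <- plan$assign[[m]]
    j <- match(s, inst$candidates$id)
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = list(
                        c(inst$municipalities$x[i], inst$municipalities$y[i]),
                        c(inst$candidates$x[j], inst$candidates$y[j]))),
      properties = list(kind = "allocation", municipality = m, site = s,
                        median_km = unname(ev$distance_km[[m]])))
  }
  list(type = "FeatureCollection", features = feats)
}
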