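#' Out-of-hours pharmacy rostering instances
#'
#' Annual duty planning: every day a subset of pharmacies serves a 24-hour
#' out-of-hours shift such that every municipality has enough open pharmacies
#' within reach, nearby pharmacies never serve the same day, every pharmacy
#' rests between services, legal minimum annual services are met, and the
#' burden is fair. Robustness against quarantine closures is modeled as
#' surplus coverage: `c + gamma` distinct in-range pharmacies per
#' municipality-day, so that any `gamma` closures still leave `c`.
#'
#' @param pharmacies character vector of pharmacy ids.
#' @param municipalities character vector of municipality ids.
#' @param cov named list municipality -> pharmacy ids within the coverage
#'   radius (street-network distance).
#' @param conflicts list of length-2 character vectors: pharmacy pairs within
#'   the vicinity radius that must not serve the same day.
#' @param horizon number of days T.
#' @param c_cover required open in-range pharmacies per municipality-day.
#' @param gamma quarantine budget (surplus coverage), >= 0.
#' @param rest days of rest after a service (duty on day t forbids duty on
#'   t+1 ... t+rest).
#' @param s_min minimum annual services per pharmacy.
#' @param delta fairness slack for bracket bounds around idealized loads.
#' @param mult named integer multiplicities (aggregated instances; default 1).
#' @param internal_conflict named logical: whether members of an aggregated
#'   class mutually conflict (at most one per day).
#' @param dist_m optional municipality x pharmacy street-distance matrix in
#'   meters (needed by [reachability_stats()]).
#' @param pharmacy_municipality named vector pharmacy -> municipality
#'   (needed for fairness statistics).
#' @param neighbors named list municipality -> neighbor municipality ids.
#' @return list of class `pharmacy_instance`.
#' @export
pharmacy_instance <- function(pharmacies, municipalities, cov, conflicts,
                              horizon, c_cover = 1L, gamma = 0L, rest = 0L,
                              s_min = 0L, delta = 0.2, mult = NULL,
                              internal_conflict = NULL, dist_m = NULL,
                              pharmacy_municipality = NULL, neighbors = NULL) {
  pharmacies <- as.character(pharmacies)
  municipalities <- as.character(municipalities)
  if (horizon < 1L) stop_input("horizon must be >= 1")
  if (c_cover < 1L) stop_input("coverage count must be >= 1")
  if (gamma < 0L || rest < 0L || s_min < 0L) {
    stop_input("gamma, rest and s_min must be >= 0")
  }
  cov <- lapply(cov[municipalities], function(s) {
    s <- intersect(as.character(s), pharmacies)
    sort(s)
  })
  names(cov) <- municipalities
  conflicts <- unique(lapply(conflicts, function(pr) sort(as.character(pr))))
  conflicts <- Filter(function(pr) length(pr) == 2L && pr[1] != pr[2] &&
                        all(pr %in% pharmacies), conflicts)
  if (is.null(mult)) mult <- stats::setNames(rep(1L, length(pharmacies)),
                                             pharmacies)
  if (is.null(internal_conflict)) {
    internal_conflict <- stats::setNames(rep(FALSE, length(pharmacies)),
                                         pharmacies)
  }
  structure(list(pharmacies = pharmacies, municipalities = municipalities,
                 cov = cov, conflicts = conflicts,
                 horizon = as.integer(horizon), c_cover = as.integer(c_cover),
                 gamma = as.integer(gamma), rest = as.integer(rest),
                 s_min = as.integer(s_min), delta = delta,
                 mult = mult[pharmacies],
                 internal_conflict = internal_conflict[pharmacies],
                 dist_m = dist_m,
                 pharmacy_municipality = pharmacy_municipality,
                 neighbors = neighbors),
            class = "pharmacy_instance")
}

#' Build a pharmacy rostering instance from a synthetic region
#'
#' Coverage and vicinity are measured in street-network meters (municipality
#' measured at its center node).
#'
#' @param region a [generate_region()] result.
#' @param horizon days.
#' @param radius_m coverage radius R.
#' @param vicinity_m dispersion radius V (no two open pharmacies within V on
#'   the same day).
#' @inheritParams pharmacy_instance
#' @return A [pharmacy_instance()].
#' @export
pharmacy_instance_from_region <- function(region, horizon, radius_m,
                                          vicinity_m, c_cover = 1L,
                                          gamma = 0L, rest = 1L, s_min = 0L,
                                          delta = 0.2) {
  ph <- region$pharmacies
  mun <- region$municipalities
  dist_m <- matrix(Inf, nrow(mun), nrow(ph),
                   dimnames = list(mun$id, ph$id))
  for (i in seq_len(nrow(mun))) {
    dd <- network_distances(region$network, mun$center[i])
    dist_m[i, ] <- dd[ph$node]
  }
  cov <- lapply(mun$id, function(m) ph$id[dist_m[m, ] <= radius_m])
  names(cov) <- mun$id
  conflicts <- list()
  if (vicinity_m > 0 && nrow(ph) > 1L) {
    for (i in seq_len(nrow(ph) - 1L)) {
      dd <- network_distances(region$network, ph$node[i])
      for (j in (i + 1L):nrow(ph)) {
        if (dd[[ph$node[j]]] <= vicinity_m) {
          conflicts[[length(conflicts) + 1L]] <- c(ph$id[i], ph$id[j])
        }
      }
    }
  }
  pharmacy_instance(ph$id, mun$id, cov, conflicts, horizon, c_cover, gamma,
                    rest, s_min, delta, dist_m = dist_m,
                    pharmacy_municipality = stats::setNames(ph$municipality,
                                                            ph$id),
                    neighbors = region$neighbors)
}

#' Idealized lexicographically fair loads
#'
#' Solves the simplified planning problem (coverage only: no vicinity, no
#' rest, no minimum services) for annual loads that are lexicographically
#' fair: the sorted-descending load vector is minimal — the largest load is
#' as small as possible, then the second largest, and so on. These loads
#' define the service relation between pharmacies in neighboring
#' municipalities for the full model's fairness brackets.
#'
#' On small instances the loads are computed exactly by branch-and-bound
#' over per-day cover patterns (inclusion-minimal patterns only; adding a
#' pharmacy to a day can only worsen the sorted load vector). Larger
#' instances fall back to a balancing greedy: day by day, municipalities in
#' order of scarcity (fewest reachable pharmacies first), skipping those
#' already covered, each assignment picking the eligible pharmacy with the
#' smallest current load (ties: covers more still-uncovered municipalities,
#' then lower id). The greedy seeds the exact search as its incumbent.
#'
#' @param inst a [pharmacy_instance()].
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact search;
#'   default `NULL` decides by instance size.
#' @return named integer vector of class `idealized_loads`.
#' @export
idealized_fair_plan <- function(inst, exact = NULL) {
  P <- inst$pharmacies
  for (m in inst$municipalities) {
    if (length(inst$cov[[m]]) < inst$c_cover) {
      stop_infeasible(sprintf(
        "municipality %s has only %d pharmacies within reach (%d required)",
        m, length(inst$cov[[m]]), inst$c_cover), detail = m)
    }
  }
  load <- fair_greedy_loads(inst)
  tractable <- FALSE
  if (isTRUE(exact) || is.null(exact)) {
    pats <- if (length(P) <= 12L) minimal_cover_patterns(inst) else list()
    # multisets of T patterns: gate the exact search by its worst-case size
    tractable <- length(pats) > 0L &&
      choose(inst$horizon + length(pats) - 1L, length(pats) - 1L) <= 2e5
    if (isTRUE(exact) || tractable) {
      if (length(pats)) load <- fair_exact_loads(inst, pats, load)
    }
  }
  structure(load, class = "idealized_loads")
}

fair_greedy_loads <- function(inst) {
  load <- stats::setNames(rep(0L, length(inst$pharmacies)), inst$pharmacies)
  scarcity <- order(lengths(inst$cov[inst$municipalities]),
                    inst$municipalities)
  munis <- inst$municipalities[scarcity]
  for (d in seq_len(inst$horizon)) {
    open <- character(0)
    for (m in munis) {
      while (length(intersect(open, inst$cov[[m]])) < inst$c_cover) {
        elig <- setdiff(inst$cov[[m]], open)
        gain <- vapply(elig, function(p) {
          sum(vapply(munis, function(mm)
            p %in% inst$cov[[mm]] &&
              length(intersect(open, inst$cov[[mm]])) < inst$c_cover, TRUE))
        }, 0)
        elig <- elig[order(load[elig], -gain, elig)]
        open <- c(open, elig[1L])
        load[[elig[1L]]] <- load[[elig[1L]]] + 1L
      }
    }
  }
  load
}

# All inclusion-minimal pharmacy sets giving every municipality c-coverage.
minimal_cover_patterns <- function(inst) {
  P <- inst$pharmacies
  if (length(P) > 16L) return(list())
  n <- length(P)
  feas <- list()
  for (mask in seq_len(2^n) - 1L) {
    S <- P[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    ok <- all(vapply(inst$municipalities, function(m)
      length(intersect(S, inst$cov[[m]])) >= inst$c_cover, TRUE))
    if (ok) feas[[length(feas) + 1L]] <- S
  }
  sizes <- lengths(feas)
  keep <- vapply(seq_along(feas), function(i) {
    !any(vapply(which(sizes < sizes[i]), function(j)
      all(feas[[j]] %in% feas[[i]]), TRUE))
  }, TRUE)
  feas[keep]
}

fair_exact_loads <- function(inst, pats, incumbent) {
  P <- inst$pharmacies
  T <- inst$horizon
  K <- length(pats)
  pat_ind <- matrix(vapply(pats, function(S) as.numeric(P %in% S),
                           numeric(length(P))), nrow = length(P))
  lex_lt <- function(a, b) {
    # a, b sorted descending
    d <- a - b
    nz <- which(d != 0)
    length(nz) > 0L && d[nz[1L]] < 0
  }
  best_sorted <- sort(incumbent, decreasing = TRUE)
  best_loads <- incumbent
  loads <- stats::setNames(rep(0, length(P)), P)
  rec <- function(t, kmin) {
    cur <- sort(loads, decreasing = TRUE)
    # loads only grow day by day, so the current sorted vector is a
    # lexicographic lower bound on any completion
    if (!lex_lt(cur, best_sorted) && t <= T) return(invisible(NULL))
    if (t > T) {
      if (lex_lt(cur, best_sorted)) {
        best_sorted <<- cur
        best_loads <<- loads
      }
      return(invisible(NULL))
    }
    for (k in kmin:K) {
      loads <<- loads + pat_ind[, k]
      rec(t + 1L, k)
      loads <<- loads - pat_ind[, k]
    }
  }
  rec(1L, 1L)
  stats::setNames(as.integer(best_loads), P)
}

# -------------------------------------------------------------------------
# exact duty-plan solver (multiplicity-aware: counts per pharmacy class)

# All day vectors y (0..mult per class) that are conflict-free and meet
# coverage c+gamma in every municipality; returned as a matrix sorted by
# total then lexicographically. P is capped to keep enumeration exact.
day_candidates <- function(inst) {
  P <- length(inst$pharmacies)
  caps <- ifelse(inst$internal_conflict, pmin(1L, inst$mult), inst$mult)
  need0 <- inst$c_cover + inst$gamma
  short <- inst$municipalities[vapply(inst$municipalities, function(m)
    sum(caps[inst$cov[[m]]]) < need0, TRUE)]
  if (length(short)) {
    stop_infeasible(sprintf(
      "coverage infeasible: municipalities with fewer than %d eligible in-range pharmacies: %s",
      need0, paste(short, collapse = ", ")),
      detail = list(family = "coverage", units = short))
  }
  if (sum(log2(caps + 1)) > 20) {
    stop_input("exact solver limited to ~2^20 day patterns; aggregate first")
  }
  grid <- as.matrix(expand.grid(lapply(caps, function(k) 0:k)))
  colnames(grid) <- inst$pharmacies
  need <- inst$c_cover + inst$gamma
  keep <- rep(TRUE, nrow(grid))
  for (m in inst$municipalities) {
    cm <- inst$cov[[m]]
    keep <- keep & (if (length(cm)) rowSums(grid[, cm, drop = FALSE]) else 0) >= need
  }
  for (pr in inst$conflicts) {
    keep <- keep & !(grid[, pr[1]] > 0 & grid[, pr[2]] > 0)
  }
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) {
    stop_infeasible("no day pattern satisfies coverage and dispersion jointly",
                    detail = "coverage/dispersion")
  }
  o <- do.call(order, c(list(rowSums(grid)),
                        lapply(seq_len(ncol(grid)), function(j) grid[, j])))
  grid[o, , drop = FALSE]
}

#' Solve the duty-plan problem to optimality
#'
#' Minimizes the total number of out-of-hours services subject to coverage
#' (`c + gamma` distinct in-range pharmacies per municipality-day),
#' dispersion (no conflicting pair on the same day), rest (a service on day
#' t forbids days t+1..t+rest), minimum annual services, and, when
#' `fairness` loads are supplied, per-pharmacy totals within
#' `floor((1-delta)*load) ... ceiling((1+delta)*load)`. Exact depth-first
#' search over per-day patterns with lower-bound pruning; proven optimal.
#'
#' @param inst a [pharmacy_instance()].
#' @param fairness optional [idealized_fair_plan()] loads.
#' @param initial_last named integer: last service day per pharmacy before
#'   day 1 (days <= 0; used by the rolling horizon), default none.
#' @param initial_totals named integer: services already performed.
#' @param enforce_lower enforce the lower total bounds (s_min and fairness
#'   lower bracket) at the end of this horizon (default `TRUE`).
#' @param lo_override optional named vector of absolute lower bounds on the
#'   cumulative totals (including `initial_totals`), replacing the bounds
#'   derived from `s_min` and `fairness`; used by the rolling horizon to
#'   prorate annual bounds across windows.
#' @return list of class `duty_plan`: `duty` (pharmacy x day count matrix;
#'   0/1 for unit multiplicities), `totals`, `objective`.
#' @export
solve_duty_plan <- function(inst, fairness = NULL, initial_last = NULL,
                            initial_totals = NULL, enforce_lower = TRUE,
                            lo_override = NULL) {
  P <- length(inst$pharmacies)
  T <- inst$horizon
  r <- inst$rest
  mult <- inst$mult
  cand <- day_candidates(inst)
  sizes <- rowSums(cand)
  minsize <- min(sizes)

  lo <- stats::setNames(rep(inst$s_min, P) * mult, inst$pharmacies)
  hi <- stats::setNames(rep(Inf, P), inst$pharmacies)
  if (!is.null(fairness)) {
    fl <- unclass(fairness)[inst$pharmacies] * 1.0
    lo <- pmax(lo, floor((1 - inst$delta) * fl * mult))
    hi <- ceiling((1 + inst$delta) * fl * mult)
  }
  if (!is.null(lo_override)) {
    lo <- stats::setNames(as.numeric(lo_override[inst$pharmacies]),
                          inst$pharmacies)
    lo[is.na(lo)] <- 0
  }
  tot0 <- stats::setNames(rep(0L, P), inst$pharmacies)
  if (!is.null(initial_totals)) tot0[names(initial_totals)] <-
      as.integer(initial_totals)
  # window history of the last r days (counts per class), oldest first
  hist0 <- matrix(0L, max(r, 1L), P, dimnames = list(NULL, inst$pharmacies))
  if (!is.null(initial_last) && r > 0L) {
    for (p in names(initial_last)) {
      dlast <- initial_last[[p]]
      if (dlast >= 1L - r) {
        # row r corresponds to day 0 (yesterday), row r-1 to day -1, ...
        row <- r + dlast
        if (row >= 1L) hist0[row, p] <- hist0[row, p] + 1L
      }
    }
  }

  # capacity: services class p can still perform in days d..T given the
  # window constraint (each member at most once per r+1 consecutive days)
  cap_rem <- function(d) {
    if (d > T) return(stats::setNames(rep(0, P), inst$pharmacies))
    mult * ceiling((T - d + 1) / (r + 1))
  }

  best_cost <- Inf
  best_plan <- NULL
  duty <- matrix(0L, P, T, dimnames = list(inst$pharmacies, NULL))

  rec <- function(d, hist, tot, cost) {
    if (d > T) {
      if (enforce_lower && any(tot < lo)) return(invisible(NULL))
      if (cost < best_cost) {
        best_cost <<- cost
        best_plan <<- duty
      }
      return(invisible(NULL))
    }
    # bounds
    need <- if (enforce_lower) pmax(0, lo - tot) else rep(0, P)
    if (any(need > cap_rem(d))) return(invisible(NULL))
    lb <- cost + max((T - d + 1L) * minsize, sum(need))
    if (lb >= best_cost) return(invisible(NULL))
    # per-day caps from the rest window
    caps <- if (r > 0L) mult - colSums(hist) else mult
    caps <- pmin(caps, hi - tot)
    ok <- which(sizes + cost + max(0, (T - d) * minsize) < best_cost)
    for (ci in ok) {
      y <- cand[ci, ]
      if (any(y > caps)) next
      duty[, d] <<- y
      hist2 <- if (r > 0L) rbind(hist[-1L, , drop = FALSE], y) else hist
      rec(d + 1L, hist2, tot + y, cost + sizes[ci])
      duty[, d] <<- 0L
    }
  }
  rec(1L, hist0, tot0, 0L)
  if (is.null(best_plan)) {
    diagnose_infeasibility(inst, lo, enforce_lower)
  }
  totals <- rowSums(best_plan)
  structure(list(duty = best_plan, totals = totals,
                 objective = as.integer(best_cost), instance = inst),
            class = "duty_plan")
}

diagnose_infeasibility <- function(inst, lo, enforce_lower) {
  need <- inst$c_cover + inst$gamma
  short <- inst$municipalities[vapply(inst$municipalities, function(m)
    sum(inst$mult[inst$cov[[m]]]) < need, TRUE)]
  if (length(short)) {
    stop_infeasible(sprintf(
      "coverage infeasible: municipalities with fewer than %d in-range pharmacies: %s",
      need, paste(short, collapse = ", ")), detail = list(family = "coverage",
                                                          units = short))
  }
  cap <- inst$mult * ceiling(inst$horizon / (inst$rest + 1))
  over <- inst$pharmacies[enforce_lower & lo > cap]
  if (length(over)) {
    stop_infeasible(sprintf(
      "rest/minimum-services infeasible for pharmacies: %s",
      paste(over, collapse = ", ")), detail = list(family = "rest_smin",
                                                   units = over))
  }
  stop_infeasible("no feasible duty plan (dispersion interacts with coverage or fairness brackets)",
                  detail = list(family = "dispersion_or_fairness",
                                units = character(0)))
}

#' @export
print.duty_plan <- function(x, ...) {
  cat(sprintf("<duty_plan> %d day(s), %d service(s) total\n",
              ncol(x$duty), x$objective))
  cat(sprintf("  services per pharmacy: %s\n",
              paste(sprintf("%s=%d", names(x$totals), x$totals),
                    collapse = ", ")))
  invisible(x)
}

#' Aggregate mathematically equivalent pharmacies
#'
#' Pharmacies are equivalent when they share the same municipality, cover the
#' same municipalities, and have the same vicinity-conflict set apart from
#' one another (with a consistent mutual-conflict relation inside the class).
#' Each class is replaced by one representative with a multiplicity; the
#' rest constraint becomes a sliding-window cap on the class (at most `k`
#' services in any `rest+1` consecutive days), which is exactly the set of
#' class service patterns admitting a round-robin disaggregation. The
#' reduction is exact: the aggregated optimum equals the direct optimum.
#'
#' @param inst a [pharmacy_instance()] with unit multiplicities.
#' @return list: `instance` (aggregated [pharmacy_instance()]), `classes`
#'   (named list representative -> member ids).
#' @export
aggregate_pharmacies <- function(inst) {
  P <- inst$pharmacies
  covered_by <- lapply(P, function(p) {
    sort(inst$municipalities[vapply(inst$municipalities, function(m)
      p %in% inst$cov[[m]], TRUE)])
  })
  names(covered_by) <- P
  confset <- stats::setNames(lapply(P, function(p) character(0)), P)
  for (pr in inst$conflicts) {
    confset[[pr[1]]] <- union(confset[[pr[1]]], pr[2])
    confset[[pr[2]]] <- union(confset[[pr[2]]], pr[1])
  }
  muni_of <- inst$pharmacy_municipality
  if (is.null(muni_of)) {
    # fall back: class key uses the covered set only
    muni_of <- stats::setNames(rep("", length(P)), P)
  }
  classes <- list()        # member id vectors
  cls_internal <- logical(0)  # NA-free: FALSE until a second member decides
  cls_decided <- logical(0)   # whether the internal flag is fixed yet
  for (p in P) {
    placed <- FALSE
    for (k in seq_along(classes)) {
      q <- classes[[k]][1L]
      same <- identical(muni_of[[p]], muni_of[[q]]) &&
        identical(covered_by[[p]], covered_by[[q]]) &&
        identical(sort(setdiff(confset[[p]], classes[[k]])),
                  sort(setdiff(confset[[q]], c(classes[[k]], p))))
      if (!same) next
      # p's conflict relation to every current member must be identical,
      # and must agree with the class's established internal relation
      rels <- vapply(classes[[k]], function(qq) qq %in% confset[[p]], TRUE)
      if (length(unique(rels)) > 1L) next
      inpair <- rels[1L]
      if (cls_decided[k] && inpair != cls_internal[k]) next
      classes[[k]] <- c(classes[[k]], p)
      cls_internal[k] <- inpair
      cls_decided[k] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) {
      classes[[length(classes) + 1L]] <- p
      cls_internal <- c(cls_internal, FALSE)
      cls_decided <- c(cls_decided, FALSE)
    }
  }
  reps <- vapply(classes, `[[`, "", 1L)
  names(classes) <- reps
  mult <- stats::setNames(vapply(classes, length, 0L), reps)
  internal <- stats::setNames(cls_internal & lengths(classes) > 1L, reps)
  rep_of <- stats::setNames(rep(reps, lengths(classes)), unlist(classes))
  cov2 <- lapply(inst$cov, function(s) sort(unique(unname(rep_of[s]))))
  conf2 <- unique(Filter(function(pr) pr[1] != pr[2],
                         lapply(inst$conflicts, function(pr)
                           sort(unname(rep_of[pr])))))
  inst2 <- pharmacy_instance(reps, inst$municipalities, cov2, conf2,
                             inst$horizon, inst$c_cover, inst$gamma,
                             inst$rest, inst$s_min, inst$delta, mult = mult,
                             internal_conflict = internal,
                             dist_m = if (!is.null(inst$dist_m))
                               inst$dist_m[, reps, drop = FALSE] else NULL,
                             pharmacy_municipality =
                               if (!is.null(inst$pharmacy_municipality))
                                 inst$pharmacy_municipality[reps] else NULL,
                             neighbors = inst$neighbors)
  list(instance = inst2, classes = classes)
}

#' Disaggregate an aggregated duty plan
#'
#' Spreads each class's services round-robin across its members in
#' chronological order, which respects the rest constraint whenever the
#' aggregated plan satisfies the class window cap.
#'
#' @param agg result of [aggregate_pharmacies()].
#' @param plan `duty_plan` solved on `agg$instance`.
#' @param inst the original (unit-multiplicity) [pharmacy_instance()].
#' @return A `duty_plan` on the original pharmacies.
#' @export
disaggregate_plan <- function(agg, plan, inst) {
  T <- ncol(plan$duty)
  duty <- matrix(0L, length(inst$pharmacies), T,
                 dimnames = list(inst$pharmacies, NULL))
  for (repid in names(agg$classes)) {
    members <- agg$classes[[repid]]
    ptr <- 0L
    for (d in seq_len(T)) {
      k <- plan$duty[repid, d]
      if (k > 0L) for (j in seq_len(k)) {
        duty[members[ptr %% length(members) + 1L], d] <- 1L
        ptr <- ptr + 1L
      }
    }
  }
  structure(list(duty = duty, totals = rowSums(duty),
                 objective = sum(duty), instance = inst),
            class = "duty_plan")
}

#' Rolling-horizon duty planning
#'
#' Decomposes a long horizon into overlapping windows of `W` days, committing
#' the first `W - O` days of each window and carrying committed duties, rest
#' state and accumulated totals across the boundary. Annual lower total
#' bounds (minimum services, fairness lower brackets) are prorated: by the
#' end of a window covering day `e`, cumulative totals must reach
#' `floor(lo * e / T)`, reaching the full bounds in the final window; upper
#' brackets hold throughout. If a window is infeasible given its commitments
#' it is retried without fairness brackets, else the failure is reported.
#' The committed plan satisfies all full-horizon constraints; its objective
#' is an upper bound on the exact optimum.
#'
#' @param inst a [pharmacy_instance()].
#' @param W window length; @param O overlap (0 <= O < W <= T).
#' @param fairness optional [idealized_fair_plan()] loads.
#' @return A `duty_plan` on the full horizon.
#' @export
rolling_horizon_solve <- function(inst, W = 28L, O = 7L, fairness = NULL) {
  T <- inst$horizon
  if (O < 0L || O >= W) stop_input("need 0 <= O < W")
  if (W > T) W <- T
  duty <- matrix(0L, length(inst$pharmacies), T,
                 dimnames = list(inst$pharmacies, NULL))
  full_lo <- stats::setNames(rep(inst$s_min, length(inst$pharmacies)) *
                               inst$mult, inst$pharmacies)
  if (!is.null(fairness)) {
    fl <- unclass(fairness)[inst$pharmacies] * 1.0
    full_lo <- pmax(full_lo, floor((1 - inst$delta) * fl * inst$mult))
  }
  start <- 1L
  while (start <= T) {
    end <- min(start + W - 1L, T)
    win <- inst
    win$horizon <- end - start + 1L
    last <- last_service_before(duty, start, inst$rest)
    tots <- rowSums(duty[, seq_len(start - 1L), drop = FALSE])
    final <- end == T
    lo_w <- if (final) full_lo else floor(full_lo * end / T)
    sub <- tryCatch(
      solve_duty_plan(win, fairness = fairness,
                      initial_last = last, initial_totals = tots,
                      enforce_lower = TRUE, lo_override = lo_w),
      careops_infeasible = function(e) {
        if (!is.null(fairness)) {
          solve_duty_plan(win, fairness = NULL, initial_last = last,
                          initial_totals = tots, enforce_lower = final)
        } else stop(e)
      })
    commit_end <- if (final) end else min(end, start + (W - O) - 1L)
    duty[, start:commit_end] <-
      sub$duty[, seq_len(commit_end - start + 1L), drop = FALSE]
    start <- commit_end + 1L
  }
  structure(list(duty = duty, totals = rowSums(duty), objective = sum(duty),
                 instance = inst),
            class = "duty_plan")
}

last_service_before <- function(duty, start, r) {
  if (r == 0L || start == 1L) return(NULL)
  lastv <- integer(0)
  for (p in rownames(duty)) {
    days <- which(duty[p, seq_len(start - 1L)] > 0L)
    if (length(days)) {
      # re-zero so that day `start` is day 1 of the window
      lastv[p] <- max(days) - (start - 1L)
    }
  }
  if (length(lastv)) lastv else NULL
}

#' Independent validation of a duty plan
#'
#' Re-checks every constraint family with naive recounting, independent of
#' the solver: coverage (`c + gamma` distinct in-range pharmacies per
#' municipality-day), dispersion, rest, minimum services, and, if loads are
#' given, fairness brackets. Also recomputes the fairness-chart statistics:
#' maximum within-municipality difference of totals and each pharmacy's
#' difference to its municipality average.
#'
#' @param inst a [pharmacy_instance()] (unit multiplicities).
#' @param plan a `duty_plan` or a 0/1 pharmacy x day matrix.
#' @param fairness optional [idealized_fair_plan()] loads.
#' @return list of class `plan_validation`: per-family violation tables,
#'   `n_violations`, `feasible`, and `fairness_stats`.
#' @export
validate_plan <- function(inst, plan, fairness = NULL) {
  duty <- if (inherits(plan, "duty_plan")) plan$duty else as.matrix(plan)
  if (!all(rownames(duty) %in% inst$pharmacies) ||
      ncol(duty) != inst$horizon) {
    stop_input("plan dimensions do not match the instance")
  }
  duty <- duty[inst$pharmacies, , drop = FALSE]
  T <- inst$horizon
  need <- inst$c_cover + inst$gamma

  cover_viol <- list()
  for (m in inst$municipalities) {
    cm <- inst$cov[[m]]
    for (d in seq_len(T)) {
      have <- if (length(cm)) sum(duty[cm, d] > 0L) else 0L
      if (have < need) {
        cover_viol[[length(cover_viol) + 1L]] <-
          data.frame(municipality = m, day = d, have = have, need = need)
      }
    }
  }
  disp_viol <- list()
  for (pr in inst$conflicts) {
    for (d in seq_len(T)) {
      if (duty[pr[1], d] > 0L && duty[pr[2], d] > 0L) {
        disp_viol[[length(disp_viol) + 1L]] <-
          data.frame(p1 = pr[1], p2 = pr[2], day = d)
      }
    }
  }
  rest_viol <- list()
  if (inst$rest > 0L) {
    for (p in inst$pharmacies) {
      days <- which(duty[p, ] > 0L)
      if (length(days) > 1L) {
        gaps <- diff(days)
        bad <- which(gaps <= inst$rest)
        for (b in bad) {
          rest_viol[[length(rest_viol) + 1L]] <-
            data.frame(pharmacy = p, day1 = days[b], day2 = days[b + 1L])
        }
      }
    }
  }
  totals <- rowSums(duty)
  smin_viol <- names(totals)[totals < inst$s_min]
  fair_viol <- character(0)
  if (!is.null(fairness)) {
    fl <- unclass(fairness)[inst$pharmacies]
    lo <- floor((1 - inst$delta) * fl)
    hi <- ceiling((1 + inst$delta) * fl)
    fair_viol <- inst$pharmacies[totals < lo | totals > hi]
  }
  bind0 <- function(l) if (length(l)) do.call(rbind, l) else NULL
  nv <- length(cover_viol) + length(disp_viol) + length(rest_viol) +
    length(smin_viol) + length(fair_viol)

  fairness_stats <- NULL
  if (!is.null(inst$pharmacy_municipality)) {
    pm <- inst$pharmacy_municipality[inst$pharmacies]
    munis <- sort(unique(pm))
    within_max_diff <- vapply(munis, function(m) {
      x <- totals[names(pm)[pm == m]]
      if (length(x) > 1L) max(x) - min(x) else 0
    }, 0)
    diff_to_avg <- totals - ave(totals, pm)[names(totals)]
    fairness_stats <- list(within_municipality_max_diff = within_max_diff,
                           diff_to_municipality_avg = diff_to_avg)
  }
  structure(list(coverage = bind0(cover_viol), dispersion = bind0(disp_viol),
                 rest = bind0(rest_viol), min_services = smin_viol,
                 fairness = fair_viol, n_violations = nv,
                 feasible = nv == 0L, totals = totals,
                 fairness_stats = fairness_stats),
            class = "plan_validation")
}

#' @export
print.plan_validation <- function(x, ...) {
  cat(sprintf("<plan_validation> %s (%d violation(s))\n",
              if (x$feasible) "feasible" else "INFEASIBLE", x$n_violations))
  for (fam in c("coverage", "dispersion", "rest")) {
    v <- x[[fam]]
    if (!is.null(v)) cat(sprintf("  %s: %d\n", fam, nrow(v)))
  }
  if (length(x$min_services)) cat("  min services:",
                                  paste(x$min_services, collapse = ", "), "\n")
  if (length(x$fairness)) cat("  fairness:",
                              paste(x$fairness, collapse = ", "), "\n")
  invisible(x)
}

#' Annual reachability statistics of a duty plan
#'
#' For every day, the street-network distance from each municipality center
#' to the nearest open pharmacy; summarized per municipality as the median
#' (plus min and max) over the days — the annual reachability choropleth. A
#' day with no reachable open pharmacy contributes `Inf` and is flagged.
#'
#' @param inst a [pharmacy_instance()] with a `dist_m` matrix.
#' @param plan a `duty_plan` or 0/1 matrix.
#' @return data.frame: `municipality`, `median_m`, `min_m`, `max_m`,
#'   `days_unreachable`.
#' @export
reachability_stats <- function(inst, plan) {
  if (is.null(inst$dist_m)) stop_input("instance carries no distance matrix")
  duty <- if (inherits(plan, "duty_plan")) plan$duty else as.matrix(plan)
  duty <- duty[colnames(inst$dist_m)[colnames(inst$dist_m) %in% rownames(duty)], ,
               drop = FALSE]
  T <- ncol(duty)
  out <- lapply(inst$municipalities, function(m) {
    dm <- inst$dist_m[m, rownames(duty)]
    daily <- vapply(seq_len(T), function(d) {
      open <- rownames(duty)[duty[, d] > 0L]
      if (!length(open)) return(Inf)
      min(dm[open])
    }, 0)
    data.frame(municipality = m, median_m = stats::median(daily),
               min_m = min(daily), max_m = max(daily),
               days_unreachable = sum(!is.finite(daily)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
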