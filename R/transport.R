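#' Patient-transport requests and vehicles
#'
#' Requests carry a soft requested pickup time (lateness is allowed but
#' penalized; early pickups are forbidden — vehicles wait), service
#' durations, and infection/dialysis flags. Vehicles have hard shift windows,
#' a depot, and a fleet type: `clean` vehicles carry only non-infectious
#' patients, `covid` vehicles only infectious ones, `floater` vehicles carry
#' both at the price of a changeover duration whenever consecutive transports
#' switch category. Infectious transports additionally extend both service
#' legs by a protective-clothing/disinfection add-on.
#'
#' @param df data.frame with columns `id`, `pickup`, `dropoff`, `t_req_s`,
#'   `load_s`, `unload_s`, `covid`, `dialysis`, `release_s` (missing optional
#'   columns are filled with defaults).
#' @return validated data.frame of class `transport_requests`.
#' @export
transport_requests <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("id", "pickup", "dropoff", "t_req_s")) {
    if (!col %in% names(df)) stop_input("requests need column %s", col)
  }
  n <- nrow(df)
  if (!"load_s" %in% names(df)) df$load_s <- rep(300, n)
  if (!"unload_s" %in% names(df)) df$unload_s <- rep(300, n)
  if (!"covid" %in% names(df)) df$covid <- rep(FALSE, n)
  if (!"dialysis" %in% names(df)) df$dialysis <- rep(FALSE, n)
  if (!"release_s" %in% names(df)) df$release_s <- rep(0, n)
  if (!"replaceable" %in% names(df)) df$replaceable <- rep(FALSE, n)
  if (any(df$pickup == df$dropoff)) stop_input("pickup must differ from dropoff")
  if (any(df$load_s < 0 | df$unload_s < 0)) stop_input("service durations must be >= 0")
  if (any(df$release_s > df$t_req_s)) stop_input("release must precede requested time")
  if (anyDuplicated(df$id)) stop_input("duplicate request ids")
  class(df) <- c("transport_requests", "data.frame")
  df
}

#' @param df data.frame with columns `id`, `depot`, `shift_start_s`,
#'   `shift_end_s`, `fleet` and optional `changeover_s`, `covid_addon_s`.
#' @rdname transport_requests
#' @export
transport_vehicles <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("id", "depot", "shift_start_s", "shift_end_s", "fleet")) {
    if (!col %in% names(df)) stop_input("vehicles need column %s", col)
  }
  if (!all(df$fleet %in% c("clean", "covid", "floater"))) {
    stop_input("fleet must be clean, covid or floater")
  }
  if (any(df$shift_start_s >= df$shift_end_s)) {
    stop_input("shift start must precede shift end")
  }
  if (!"covid_addon_s" %in% names(df)) df$covid_addon_s <- 600
  if (!"changeover_s" %in% names(df)) df$changeover_s <- df$covid_addon_s
  class(df) <- c("transport_vehicles", "data.frame")
  df
}

#' Memoized travel-time function on a street network
#'
#' @param net a [street_network()]; @param profile a [speed_profile()].
#' @return function `(from, to) -> seconds`, caching one single-source run
#'   per origin.
#' @export
travel_time_fun <- function(net, profile) {
  idx <- net_index(net)
  w <- indexed_times(net, profile, idx)
  cache <- new.env(parent = emptyenv())
  function(from, to) {
    if (from == to) return(0)
    if (!exists(from, envir = cache, inherits = FALSE)) {
      assign(from, dijkstra_nodes(idx, w, unname(idx$pos[from]))$dist,
             envir = cache)
    }
    unname(get(from, envir = cache)[idx$pos[to]])
  }
}

veh_compatible <- function(veh_fleet, covid) {
  if (covid) veh_fleet %in% c("covid", "floater")
  else veh_fleet %in% c("clean", "floater")
}

# Evaluate one vehicle's route: fixed stop order, earliest-start timing with
# no early pickups. Returns feasibility (shift + compatibility + quota),
# per-stop times and delays.
eval_route <- function(veh, reqs, tt, anchor = NULL, delay_cap_s = Inf,
                       covid_quota = Inf) {
  pos <- anchor$node %||% veh$depot
  t <- anchor$time %||% veh$shift_start_s
  lastcat <- anchor$category %||% NA
  ncov <- anchor$covid_trips %||% 0L
  n <- nrow(reqs)
  arrive <- pickup_start <- dropoff_end <- delay <- numeric(n)
  for (i in seq_len(n)) {
    covid <- isTRUE(reqs$covid[i])
    if (!veh_compatible(veh$fleet, covid)) return(NULL)
    if (covid) {
      ncov <- ncov + 1L
      if (ncov > covid_quota) return(NULL)
    }
    extra <- if (veh$fleet == "floater" && !is.na(lastcat) &&
                 covid != lastcat) veh$changeover_s else 0
    tr1 <- tt(pos, reqs$pickup[i])
    if (!is.finite(tr1)) return(NULL)
    arrive[i] <- t + extra + tr1
    pickup_start[i] <- max(arrive[i], reqs$t_req_s[i])
    delay[i] <- pickup_start[i] - reqs$t_req_s[i]
    if (delay[i] > delay_cap_s) return(NULL)
    addon <- if (covid) veh$covid_addon_s else 0
    tr2 <- tt(reqs$pickup[i], reqs$dropoff[i])
    if (!is.finite(tr2)) return(NULL)
    dropoff_end[i] <- pickup_start[i] + reqs$load_s[i] + addon + tr2 +
      reqs$unload_s[i] + addon
    t <- dropoff_end[i]
    pos <- reqs$dropoff[i]
    lastcat <- covid
  }
  back <- tt(pos, veh$depot)
  if (!is.finite(back) || t + back > veh$shift_end_s) return(NULL)
  list(arrive = arrive, pickup_start = pickup_start,
       dropoff_end = dropoff_end, delay = delay,
       max_delay = if (n) max(delay) else 0,
       sum_delay = sum(delay), end_time = t + back)
}

permutations_of <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Solve the patient-transport routing problem (lexicographic VRPGTW)
#'
#' Exact lexicographic optimization: first minimize the maximum waiting time
#' over all requests, then the total waiting time, where waiting is the
#' one-sided lateness `max(0, pickup start - requested time)` (hard shift
#' windows, soft pickup windows, no early pickups). The search enumerates
#' vehicle assignments, computes each vehicle's Pareto frontier over
#' (max delay, total delay) across stop orders, and combines frontiers; this
#' equals the two-stage min-max then min-sum optimum. Fixed prefixes (already
#' started or finished transports) are immutable: vehicles are anchored at
#' the prefix's end position and time.
#'
#' @param requests a [transport_requests()] table.
#' @param vehicles a [transport_vehicles()] table.
#' @param tt travel-time function from [travel_time_fun()].
#' @param fixed_prefix optional named list vehicle id -> executed stop
#'   data.frame (columns as in the returned `stops`); its rows are copied
#'   verbatim into the result.
#' @param anchors optional named list vehicle id -> list(node, time,
#'   category, covid_trips) overriding the depot start.
#' @param delay_cap_s optional hard cap on any single delay (default `Inf`:
#'   pure soft windows).
#' @param covid_quota optional max infectious transports per vehicle per day.
#' @return list of class `transport_schedule`: `stops` (vehicle, request,
#'   arrive_s, pickup_start_s, dropoff_end_s, delay_s, covid, executed),
#'   `max_delay_s`, `total_delay_s`, `unserved` (ids), `vehicles`.
#' @export
solve_vrpgtw <- function(requests, vehicles, tt, fixed_prefix = NULL,
                         anchors = NULL, delay_cap_s = Inf,
                         covid_quota = Inf) {
  requests <- transport_requests(requests)
  vehicles <- transport_vehicles(vehicles)
  nreq <- nrow(requests); nveh <- nrow(vehicles)
  if (nreq > 9L) stop_input("exact routing solver limited to 9 open requests")
  compat <- lapply(seq_len(nreq), function(i) {
    which(vapply(seq_len(nveh), function(v)
      veh_compatible(vehicles$fleet[v], isTRUE(requests$covid[i])), TRUE))
  })
  if (any(lengths(compat) == 0L)) {
    stop_infeasible(sprintf("request(s) compatible with no vehicle: %s",
                            paste(requests$id[lengths(compat) == 0L],
                                  collapse = ", ")),
                    detail = requests$id[lengths(compat) == 0L])
  }
  anchor_of <- function(v) {
    a <- anchors[[vehicles$id[v]]]
    a
  }
  # per-vehicle route evaluation over all orders of a request subset:
  # Pareto frontier of (max_delay, sum_delay)
  frontier <- function(v, ridx) {
    reqs <- requests[ridx, , drop = FALSE]
    best <- list()
    for (p in permutations_of(length(ridx))) {
      ev <- eval_route(vehicles[v, ], reqs[p, , drop = FALSE], tt,
                       anchor = anchor_of(v), delay_cap_s = delay_cap_s,
                       covid_quota = covid_quota)
      if (is.null(ev)) next
      dominated <- FALSE
      keep <- logical(length(best))
      for (b in seq_along(best)) {
        if (best[[b]]$max_delay <= ev$max_delay + 1e-9 &&
            best[[b]]$sum_delay <= ev$sum_delay + 1e-9) dominated <- TRUE
        keep[b] <- !(ev$max_delay <= best[[b]]$max_delay + 1e-9 &&
                       ev$sum_delay <= best[[b]]$sum_delay + 1e-9)
      }
      if (!dominated) {
        best <- c(best[keep], list(c(ev, list(order = ridx[p]))))
      }
    }
    best
  }

  best_val <- c(Inf, Inf)
  best_routes <- NULL
  assign_vec <- integer(nreq)
  rec <- function(i) {
    if (i > nreq) {
      byv <- lapply(seq_len(nveh), function(v) which(assign_vec == v))
      fronts <- lapply(seq_len(nveh), function(v) frontier(v, byv[[v]]))
      if (any(vapply(fronts, length, 0L) == 0L)) return(invisible(NULL))
      # combine one frontier point per vehicle, lexicographic best
      pick <- integer(nveh)
      comb <- function(v, curmax, cursum) {
        if (curmax > best_val[1] + 1e-9) return(invisible(NULL))
        if (v > nveh) {
          if (curmax < best_val[1] - 1e-9 ||
              (curmax < best_val[1] + 1e-9 && cursum < best_val[2] - 1e-9)) {
            best_val <<- c(curmax, cursum)
            best_routes <<- lapply(seq_len(nveh), function(vv)
              fronts[[vv]][[pick[vv]]])
          }
          return(invisible(NULL))
        }
        for (b in seq_along(fronts[[v]])) {
          pick[v] <<- b
          comb(v + 1L, max(curmax, fronts[[v]][[b]]$max_delay),
               cursum + fronts[[v]][[b]]$sum_delay)
        }
      }
      comb(1L, 0, 0)
      return(invisible(NULL))
    }
    for (v in compat[[i]]) {
      assign_vec[i] <<- v
      rec(i + 1L)
    }
    assign_vec[i] <<- 0L
  }
  rec(1L)
  if (is.null(best_routes)) {
    stop_infeasible("no feasible schedule within the shifts",
                    detail = requests$id)
  }
  stops <- list()
  for (v in seq_len(nveh)) {
    vid <- vehicles$id[v]
    if (!is.null(fixed_prefix[[vid]]) && nrow(fixed_prefix[[vid]])) {
      pf <- fixed_prefix[[vid]]
      pf$executed <- TRUE
      stops[[length(stops) + 1L]] <- pf
    }
    rt <- best_routes[[v]]
    if (length(rt$order)) {
      stops[[length(stops) + 1L]] <- data.frame(
        vehicle = vid, request = requests$id[rt$order],
        arrive_s = rt$arrive, pickup_start_s = rt$pickup_start,
        dropoff_end_s = rt$dropoff_end, delay_s = rt$delay,
        covid = requests$covid[rt$order], executed = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  stops <- if (length(stops)) do.call(rbind, stops) else
    data.frame(vehicle = character(0), request = character(0),
               arrive_s = numeric(0), pickup_start_s = numeric(0),
               dropoff_end_s = numeric(0), delay_s = numeric(0),
               covid = logical(0), executed = logical(0))
  rownames(stops) <- NULL
  structure(list(stops = stops, max_delay_s = best_val[1],
                 total_delay_s = best_val[2], unserved = character(0),
                 vehicles = vehicles),
            class = "transport_schedule")
}

#' @export
print.transport_schedule <- function(x, ...) {
  cat(sprintf("<transport_schedule> %d stop(s), max delay %.1f min, total %.1f min\n",
              nrow(x$stops), x$max_delay_s / 60, x$total_delay_s / 60))
  if (length(x$unserved)) cat("  unserved:", paste(x$unserved, collapse = ", "), "\n")
  invisible(x)
}

#' Day state at a clock time
#'
#' Splits an incumbent schedule at `now`: stops whose pickup has started are
#' executed (immutable); each vehicle is anchored at the end of its last
#' executed stop.
#'
#' @param schedule a `transport_schedule`.
#' @param requests the request table the schedule was built from.
#' @param now clock time (seconds).
#' @return list of class `day_state`: `now`, `executed` (per-vehicle list),
#'   `anchors`, `outstanding` (request ids not yet started).
#' @export
day_state <- function(schedule, requests, now) {
  st <- schedule$stops
  executed <- list(); anchors <- list()
  for (vid in schedule$vehicles$id) {
    rows <- st[st$vehicle == vid, , drop = FALSE]
    rows <- rows[order(rows$pickup_start_s), , drop = FALSE]
    ex <- rows[rows$pickup_start_s <= now, , drop = FALSE]
    executed[[vid]] <- ex
    if (nrow(ex)) {
      last <- ex[nrow(ex), ]
      ri <- match(last$request, requests$id)
      anchors[[vid]] <- list(node = requests$dropoff[ri],
                             time = last$dropoff_end_s,
                             category = isTRUE(requests$covid[ri]),
                             covid_trips = sum(ex$covid))
    }
  }
  started <- unlist(lapply(executed, function(e) e$request))
  outstanding <- setdiff(st$request, started)
  structure(list(now = now, executed = executed, anchors = anchors,
                 outstanding = outstanding),
            class = "day_state")
}

#' Re-optimize a running day
#'
#' Re-solves the routing problem over the outstanding and newly released
#' requests with all started or finished transports fixed and vehicles
#' anchored at their current positions and times. Executed stops are returned
#' byte-identical. A new request that admits no feasible insertion is flagged
#' unserved and the remaining schedule is returned.
#'
#' @param state a [day_state()].
#' @param requests full request table (outstanding requests are looked up
#'   here by id).
#' @param new_requests a [transport_requests()] table (may be empty).
#' @param vehicles a [transport_vehicles()] table.
#' @param tt travel-time function.
#' @param ... passed to [solve_vrpgtw()].
#' @return A `transport_schedule` including the executed prefix.
#' @export
reoptimize <- function(state, requests, new_requests, vehicles, tt, ...) {
  keep <- requests[requests$id %in% state$outstanding, , drop = FALSE]
  pool <- rbind(keep[, names(keep)],
                if (nrow(new_requests)) new_requests[, names(keep)])
  pool <- transport_requests(pool)
  vehicles <- transport_vehicles(vehicles)
  try_ids <- list(pool$id)
  # drop newest requests one at a time if needed
  newids <- if (nrow(new_requests)) rev(new_requests$id) else character(0)
  for (k in seq_along(newids)) {
    try_ids[[k + 1L]] <- setdiff(pool$id, newids[seq_len(k)])
  }
  for (ids in try_ids) {
    sub <- pool[pool$id %in% ids, , drop = FALSE]
    res <- tryCatch(
      solve_vrpgtw(sub, vehicles, tt, fixed_prefix = state$executed,
                   anchors = state$anchors, ...),
      careops_infeasible = function(e) NULL)
    if (!is.null(res)) {
      res$unserved <- setdiff(pool$id, ids)
      return(res)
    }
  }
  stop_infeasible("outstanding requests admit no feasible schedule",
                  detail = pool$id)
}

#' Dummy return transports for dialysis trips
#'
#' For every dialysis request A -> B at time t, emits a replaceable dummy
#' request B -> A at `t + stay(request)`: origin and destination are known
#' from the outward trip, only the time is estimated. When the actual return
#' materializes, replace the dummy and re-optimize.
#'
#' @param requests a [transport_requests()] table.
#' @param stay_s estimated stay duration in seconds, or a function
#'   `request-row -> seconds` (default 4 h).
#' @return A [transport_requests()] table of dummies (possibly empty).
#' @export
make_dummy_returns <- function(requests, stay_s = 14400) {
  di <- which(requests$dialysis)
  if (!length(di)) return(transport_requests(
    data.frame(id = character(0), pickup = character(0),
               dropoff = character(0), t_req_s = numeric(0))))
  stay <- if (is.function(stay_s)) {
    vapply(di, function(i) stay_s(requests[i, ]), 0)
  } else rep(stay_s, length(di))
  d <- data.frame(id = paste0(requests$id[di], "_ret"),
                  pickup = requests$dropoff[di],
                  dropoff = requests$pickup[di],
                  t_req_s = requests$t_req_s[di] + stay,
                  load_s = requests$load_s[di],
                  unload_s = requests$unload_s[di],
                  covid = requests$covid[di], dialysis = FALSE,
                  release_s = requests$release_s[di], replaceable = TRUE,
                  stringsAsFactors = FALSE)
  transport_requests(d)
}

#' Replay a transport day under a dispatch policy
#'
#' Plannable requests are solved once at day start; each ad-hoc request
#' triggers the policy at its release time. Policy `"reoptimize"` re-solves
#' the routing problem with the executed prefix fixed; policy
#' `"nearest_available"` mimics the status-quo dispatching: append the
#' request to the compatible vehicle that reaches the pickup earliest (ties
#' by earlier availability, then vehicle id), never revising earlier
#' decisions. Travel is deterministic, so realized times equal planned times.
#'
#' @param day a [sample_transport_day()] result (or list with `plannable`
#'   and `adhoc` request data.frames).
#' @param vehicles a [transport_vehicles()] table.
#' @param net a [street_network()]; @param profile a [speed_profile()].
#' @param policy `"reoptimize"` or `"nearest_available"`.
#' @param use_dummies create dummy returns for dialysis requests (only with
#'   the reoptimize policy).
#' @param ... passed to [solve_vrpgtw()].
#' @return A `transport_schedule` with realized stops (all `executed`).
#' @export
simulate_transport_day <- function(day, vehicles, net, profile,
                                   policy = c("reoptimize",
                                              "nearest_available"),
                                   use_dummies = FALSE, ...) {
  policy <- match.arg(policy)
  vehicles <- transport_vehicles(vehicles)
  tt <- travel_time_fun(net, profile)
  plannable <- transport_requests(day$plannable)
  adhoc <- transport_requests(day$adhoc)

  if (policy == "nearest_available") {
    return(nearest_available_day(plannable, adhoc, vehicles, tt))
  }

  pool <- plannable
  if (use_dummies && nrow(plannable)) {
    pool <- transport_requests(rbind(pool, make_dummy_returns(pool)))
  }
  sched <- solve_vrpgtw(pool, vehicles, tt, ...)
  if (nrow(adhoc)) {
    for (k in order(adhoc$release_s, adhoc$id)) {
      now <- adhoc$release_s[k]
      st <- day_state(sched, pool, now)
      newreq <- adhoc[k, , drop = FALSE]
      # a materializing return replaces its dummy
      if (use_dummies) {
        dummy_id <- paste0(sub("_act$", "", newreq$id), "_ret")
        st$outstanding <- setdiff(st$outstanding, dummy_id)
      }
      sched2 <- tryCatch(
        reoptimize(st, pool, newreq, vehicles, tt, ...),
        careops_infeasible = function(e) NULL)
      if (!is.null(sched2)) {
        sched <- sched2
        pool <- transport_requests(rbind(pool[, names(pool)],
                                         newreq[, names(pool)]))
      } else {
        sched$unserved <- c(sched$unserved, newreq$id)
      }
    }
  }
  sched$stops$executed <- TRUE
  sched$requests <- pool
  sched
}

nearest_available_day <- function(plannable, adhoc, vehicles, tt) {
  all_req <- rbind(plannable[, names(plannable)], adhoc[, names(plannable)])
  all_req <- all_req[order(pmax(all_req$t_req_s, all_req$release_s),
                           all_req$id), , drop = FALSE]
  nveh <- nrow(vehicles)
  pos <- vehicles$depot
  avail <- vehicles$shift_start_s
  lastcat <- rep(NA, nveh)
  stops <- list()
  unserved <- character(0)
  for (i in seq_len(nrow(all_req))) {
    covid <- isTRUE(all_req$covid[i])
    cand <- which(vapply(seq_len(nveh), function(v)
      veh_compatible(vehicles$fleet[v], covid), TRUE))
    if (!length(cand)) { unserved <- c(unserved, all_req$id[i]); next }
    eta <- vapply(cand, function(v) {
      extra <- if (vehicles$fleet[v] == "floater" && !is.na(lastcat[v]) &&
                   covid != lastcat[v]) vehicles$changeover_s[v] else 0
      tr <- tt(pos[v], all_req$pickup[i])
      if (!is.finite(tr)) return(Inf)
      # dispatch not before release nor before the vehicle frees up
      max(avail[v], all_req$release_s[i]) + extra + tr
    }, 0)
    if (all(!is.finite(eta))) { unserved <- c(unserved, all_req$id[i]); next }
    o <- order(eta, avail[cand], vehicles$id[cand])
    v <- cand[o[1L]]
    arrive <- eta[o[1L]]
    start <- max(arrive, all_req$t_req_s[i])
    addon <- if (covid) vehicles$covid_addon_s[v] else 0
    endt <- start + all_req$load_s[i] + addon +
      tt(all_req$pickup[i], all_req$dropoff[i]) + all_req$unload_s[i] + addon
    stops[[length(stops) + 1L]] <- data.frame(
      vehicle = vehicles$id[v], request = all_req$id[i], arrive_s = arrive,
      pickup_start_s = start, dropoff_end_s = endt,
      delay_s = start - all_req$t_req_s[i], covid = covid, executed = TRUE,
      stringsAsFactors = FALSE)
    pos[v] <- all_req$dropoff[i]
    avail[v] <- endt
    lastcat[v] <- covid
  }
  stops <- if (length(stops)) do.call(rbind, stops) else
    data.frame(vehicle = character(0), request = character(0),
               arrive_s = numeric(0), pickup_start_s = numeric(0),
               dropoff_end_s = numeric(0), delay_s = numeric(0),
               covid = logical(0), executed = logical(0))
  delays <- stops$delay_s
  structure(list(stops = stops,
                 max_delay_s = if (length(delays)) max(delays) else 0,
                 total_delay_s = sum(delays), unserved = unserved,
                 vehicles = vehicles, requests = all_req),
            class = "transport_schedule")
}

#' Schedule metrics and Gantt rows
#'
#' Deterministic recomputation from the stop times: maximum and total delay,
#' per-vehicle busy fraction of the shift, shift-violation count (routes that
#' cannot return to the depot in time are already excluded by the solver;
#' violations can occur in baseline replays), and per-stop Gantt rows.
#'
#' @param schedule a `transport_schedule`.
#' @param tt optional travel-time function (needed for the return-to-depot
#'   leg in shift-violation and busy-time accounting; without it the last
#'   dropoff is used).
#' @param requests optional request table for dropoff lookups.
#' @return list: `max_delay_s`, `total_delay_s`, `n_stops`, `busy_fraction`
#'   (named per vehicle), `shift_violations`, `gantt` (vehicle, request,
#'   start_s, end_s, category, delay_s).
#' @export
schedule_metrics <- function(schedule, tt = NULL, requests = NULL) {
  st <- schedule$stops
  veh <- schedule$vehicles
  if (nrow(st) == 0L) {
    return(list(max_delay_s = 0, total_delay_s = 0, n_stops = 0L,
                busy_fraction = stats::setNames(rep(0, nrow(veh)), veh$id),
                shift_violations = 0L,
                gantt = data.frame(vehicle = character(0),
                                   request = character(0),
                                   start_s = numeric(0), end_s = numeric(0),
                                   category = character(0),
                                   delay_s = numeric(0))))
  }
  busy <- stats::setNames(rep(0, nrow(veh)), veh$id)
  viol <- 0L
  if (is.null(requests)) requests <- schedule$requests
  for (v in veh$id) {
    rows <- st[st$vehicle == v, , drop = FALSE]
    if (!nrow(rows)) next
    rows <- rows[order(rows$pickup_start_s), , drop = FALSE]
    vi <- match(v, veh$id)
    t0 <- veh$shift_start_s[vi]
    end <- max(rows$dropoff_end_s)
    if (!is.null(tt) && !is.null(requests)) {
      lastreq <- rows$request[which.max(rows$dropoff_end_s)]
      ri <- match(lastreq, requests$id)
      if (!is.na(ri)) end <- end + tt(requests$dropoff[ri], veh$depot[vi])
    }
    busy[v] <- (end - t0) / (veh$shift_end_s[vi] - t0)
    if (end > veh$shift_end_s[vi] + 1e-9) viol <- viol + 1L
  }
  gantt <- data.frame(vehicle = st$vehicle, request = st$request,
                      start_s = st$pickup_start_s, end_s = st$dropoff_end_s,
                      category = ifelse(st$covid, "covid", "clean"),
                      delay_s = st$delay_s, stringsAsFactors = FALSE)
  gantt <- gantt[order(gantt$vehicle, gantt$start_s), , drop = FALSE]
  rownames(gantt) <- NULL
  list(max_delay_s = max(st$delay_s), total_delay_s = sum(st$delay_s),
       n_stops = nrow(st), busy_fraction = busy, shift_violations = viol,
       gantt = gantt)
}
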