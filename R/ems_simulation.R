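#' Event-based simulation of emergency-doctor operations
#'
#' Replays an emergency log under a provision plan. Doctors idle at their
#' stations or drive back from a previous mission; returning doctors remain
#' alarmable and are re-dispatched from their current position along the
#' return path. On each alarm the nearest available doctor (by estimated
#' travel time from its current position; ties by earliest-available-since,
#' then doctor id) is dispatched; if none is available the emergency queues
#' FIFO and is served as soon as a doctor finishes its mission. After the
#' on-scene phase (plus an optional transport leg to a hospital) the doctor
#' heads straight back to its home station. A doctor already on a mission is
#' never redirected.
#'
#' @param region a [generate_region()] result (supplies the network).
#' @param stations character vector of station nodes.
#' @param suppliers named integer vector: doctors on duty per station (a
#'   `cover_allocation$suppliers` keyed by station nodes works).
#' @param log an `emergency_log` from [sample_emergencies()] (sorted).
#' @param profile a [speed_profile()] (typically the blue-light profile).
#' @param respect_restrictions honor turn restrictions when routing
#'   (default `FALSE`: emergency vehicles may ignore them).
#' @return data.frame of class `ems_events`, one row per emergency:
#'   `alarm_s`, `dispatch_s`, `doctor`, `arrival_s`, `response_s`
#'   (= arrival - alarm), `queue_wait_s` (= dispatch - alarm), `node`,
#'   `municipality`.
#' @export
simulate_ems <- function(region, stations, suppliers, log, profile,
                         respect_restrictions = FALSE) {
  stopifnot(inherits(region, "synthetic_region"))
  if (inherits(suppliers, "cover_allocation")) suppliers <- suppliers$suppliers
  suppliers <- suppliers[stations]
  suppliers[is.na(suppliers)] <- 0L
  empty <- data.frame(alarm_s = numeric(0), dispatch_s = numeric(0),
                      doctor = character(0), arrival_s = numeric(0),
                      response_s = numeric(0), queue_wait_s = numeric(0),
                      node = character(0), municipality = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ems_events", "data.frame")
  if (nrow(log) == 0L) return(empty)
  if (sum(suppliers) == 0L) stop_input("no suppliers on duty but log is non-empty")
  if (is.unsorted(log$time_s)) stop_input("emergency log must be sorted by time")

  net <- region$network
  idx <- net_index(net)
  w <- indexed_times(net, profile, idx)
  # per-origin cached single-source runs (restriction-free: doctors with
  # sirens may ignore forbidden maneuvers; flag kept for completeness)
  cache <- new.env(parent = emptyenv())
  sssp <- function(origin) {
    if (!exists(origin, envir = cache, inherits = FALSE)) {
      res <- if (respect_restrictions && length(net$restrictions)) {
        st <- search_states(idx, w, restriction_automata(net, idx),
                            unname(idx$pos[origin]))
        list(dist = st$best_node, pred = NULL, states = st)
      } else dijkstra_nodes(idx, w, unname(idx$pos[origin]))
      assign(origin, res, envir = cache)
    }
    get(origin, envir = cache)
  }
  tt <- function(a, b) {
    if (a == b) return(0)
    unname(sssp(a)$dist[idx$pos[b]])
  }
  route_times <- function(a, b) {
    # node sequence and cumulative times a -> b (restriction-free return)
    if (a == b) return(list(nodes = a, at = 0))
    res <- sssp(a)
    if (is.null(res$pred)) res <- dijkstra_nodes(idx, w, unname(idx$pos[a]))
    cur <- unname(idx$pos[b])
    nodes <- idx$node_ids[cur]; at <- res$dist[cur]
    while (!is.na(res$pred[cur])) {
      k <- res$pred[cur]
      cur <- idx$ui[k]
      nodes <- c(idx$node_ids[cur], nodes)
      at <- c(res$dist[cur], at)
    }
    list(nodes = nodes, at = at)
  }

  docs <- data.frame(id = character(0), home = character(0),
                     stringsAsFactors = FALSE)
  for (s in stations) {
    k <- suppliers[[s]]
    if (k > 0L) docs <- rbind(docs, data.frame(
      id = sprintf("%s#%d", s, seq_len(k)), home = s,
      stringsAsFactors = FALSE))
  }
  nd <- nrow(docs)
  # doctor state: "station" | "returning" | "busy"
  state <- rep("station", nd)
  avail_since <- rep(0, nd)        # when current availability began
  busy_until <- rep(0, nd)
  ret_path <- vector("list", nd)   # list(nodes, at = absolute times)
  ret_depart <- rep(0, nd)

  settle <- function(i, now) {
    # returning doctors that have arrived are back at the station
    if (state[i] == "returning") {
      p <- ret_path[[i]]
      if (now >= ret_depart[i] + p$at[length(p$at)] - 1e-9) {
        state[i] <<- "station"
        avail_since[i] <<- ret_depart[i] + p$at[length(p$at)]
      }
    }
  }
  position_eta <- function(i, now, dest) {
    # (travel time from current position to dest, node the doctor heads to)
    if (state[i] == "station") return(tt(docs$home[i], dest))
    p <- ret_path[[i]]
    el <- now - ret_depart[i]
    j <- findInterval(el, p$at)          # last node passed
    if (j >= length(p$nodes)) return(tt(docs$home[i], dest))
    if (abs(p$at[j] - el) < 1e-9) {
      # exactly at a node: free to head anywhere from here
      return(tt(p$nodes[j], dest))
    }
    # mid-edge: finish the current edge to node j+1, then route from there
    (p$at[j + 1L] - el) + tt(p$nodes[j + 1L], dest)
  }

  n <- nrow(log)
  out_dispatch <- rep(NA_real_, n); out_doc <- rep(NA_character_, n)
  out_arr <- rep(NA_real_, n)
  queue <- integer(0)

  dispatch <- function(em, now) {
    # choose nearest available doctor; returns FALSE if none
    for (i in seq_len(nd)) settle(i, now)
    av <- which(state != "busy")
    if (!length(av)) return(FALSE)
    eta <- vapply(av, function(i) position_eta(i, now, log$node[em]), 0)
    fin <- is.finite(eta)
    if (!any(fin)) return(FALSE)
    av <- av[fin]; eta <- eta[fin]
    o <- order(eta, avail_since[av], docs$id[av])
    i <- av[o[1L]]
    arrive <- now + eta[o[1L]]
    out_dispatch[em] <<- now
    out_doc[em] <<- docs$id[i]
    out_arr[em] <<- arrive
    fin_t <- arrive + log$onscene_s[em]
    end_node <- log$node[em]
    if (isTRUE(log$transport[em]) && !is.na(log$hospital[em])) {
      fin_t <- fin_t + tt(log$node[em], log$hospital[em])
      end_node <- log$hospital[em]
    }
    state[i] <<- "busy"
    busy_until[i] <<- fin_t
    ret_path[[i]] <<- route_times(end_node, docs$home[i])
    ret_depart[i] <<- fin_t
    TRUE
  }

  # event loop over alarms and mission completions
  next_free <- function() {
    b <- which(state == "busy")
    if (!length(b)) return(Inf)
    min(busy_until[b])
  }
  ei <- 1L
  repeat {
    tf <- next_free()
    ta <- if (ei <= n) log$time_s[ei] else Inf
    if (!is.finite(tf) && !is.finite(ta)) break
    if (tf <= ta) {
      # a doctor finishes and starts returning; serve the queue
      i <- which(state == "busy" & abs(busy_until - tf) < 1e-9)[1L]
      state[i] <- "returning"
      avail_since[i] <- tf
      while (length(queue)) {
        if (dispatch(queue[1L], tf)) queue <- queue[-1L] else break
      }
    } else {
      if (!dispatch(ei, ta)) queue <- c(queue, ei)
      ei <- ei + 1L
    }
    if (ei > n && !length(queue) && !any(state == "busy")) break
  }

  out <- data.frame(alarm_s = log$time_s, dispatch_s = out_dispatch,
                    doctor = out_doc, arrival_s = out_arr,
                    response_s = out_arr - log$time_s,
                    queue_wait_s = out_dispatch - log$time_s,
                    node = log$node,
                    municipality = if ("municipality" %in% names(log)) {
                      log$municipality
                    } else unname(region$node_municipality[log$node]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ems_events", "data.frame")
  out
}

#' Median response times per geographic unit
#'
#' Aggregates simulated (or historical) emergency events to per-municipality
#' and per-county median response times plus histogram bins, the basis of
#' median-response choropleth maps. Units without events get `NA`, never 0.
#'
#' @param events an `ems_events` data.frame from [simulate_ems()].
#' @param region a [generate_region()] result (supplies county membership).
#' @param breaks_s histogram breaks in seconds (default 0 to 30 min by 2 min,
#'   with an overflow bin).
#' @return list: `municipality` and `county` data.frames (`unit`, `n`,
#'   `median_s`), `histogram` (`from_s`, `to_s`, `count`).
#' @export
response_time_summary <- function(events, region,
                                  breaks_s = seq(0, 1800, by = 120)) {
  mun_ids <- region$municipalities$id
  per_mun <- data.frame(unit = mun_ids,
                        n = vapply(mun_ids, function(m)
                          sum(events$municipality == m), 0L),
                        median_s = vapply(mun_ids, function(m) {
                          x <- events$response_s[events$municipality == m]
                          if (length(x)) stats::median(x) else NA_real_
                        }, 0), stringsAsFactors = FALSE, row.names = NULL)
  cty <- region$municipalities$county[match(events$municipality, mun_ids)]
  cty_ids <- sort(unique(region$municipalities$county))
  per_cty <- data.frame(unit = cty_ids,
                        n = vapply(cty_ids, function(cc)
                          sum(cty == cc, na.rm = TRUE), 0L),
                        median_s = vapply(cty_ids, function(cc) {
                          x <- events$response_s[!is.na(cty) & cty == cc]
                          if (length(x)) stats::median(x) else NA_real_
                        }, 0), stringsAsFactors = FALSE, row.names = NULL)
  br <- c(breaks_s, Inf)
  cnt <- as.integer(table(cut(events$response_s, br, right = FALSE)))
  hist <- data.frame(from_s = br[-length(br)], to_s = br[-1L], count = cnt)
  list(municipality = per_mun, county = per_cty, histogram = hist)
}
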