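#' Speed profiles
#'
#' A speed profile maps each street-class label to an average speed in km/h
#' for one vehicle type; edge traversal time is `length_m / speed`.
#'
#' @param speeds named numeric vector, km/h per street class (all >= 1).
#' @param vehicle_type label, e.g. `"car"` or `"blue_light"`.
#' @return An object of class `speed_profile`.
#' @export
speed_profile <- function(speeds, vehicle_type = "car") {
  speeds <- unlist(speeds)
  if (is.null(names(speeds)) || any(!nzchar(names(speeds)))) {
    stop_input("speeds must be a named vector (street class -> km/h)")
  }
  if (any(!is.finite(speeds)) || any(speeds < 1)) {
    stop_input("all speeds must be finite and >= 1 km/h")
  }
  structure(list(speed = speeds, vehicle_type = as.character(vehicle_type)),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile> vehicle type: %s\n", x$vehicle_type))
  for (cl in names(x$speed)) cat(sprintf("  %-10s %6.1f km/h\n", cl, x$speed[[cl]]))
  invisible(x)
}

# Edge traversal times in seconds; errors if a class has no speed.
edge_times <- function(net, profile) {
  stopifnot(inherits(profile, "speed_profile"))
  miss <- setdiff(unique(net$edges$class), names(profile$speed))
  if (length(miss)) {
    stop_config("speed profile lacks street class(es): %s",
                paste(miss, collapse = ", "))
  }
  net$edges$length_m * 3.6 / unname(profile$speed[net$edges$class])
}

# Node/edge index used by the search routines. Nodes sorted by id so that
# tie-breaking by index equals tie-breaking by ascending node identifier.
net_index <- function(net) {
  ord <- order(net$nodes$id)
  nid <- net$nodes$id[ord]
  pos <- stats::setNames(seq_along(nid), nid)
  ed <- net$edges
  eord <- order(ed$id)
  ed <- ed[eord, , drop = FALSE]
  ui <- unname(pos[ed$u]); vi <- unname(pos[ed$v])
  out <- vector("list", length(nid))
  for (k in seq_along(ui)) out[[ui[k]]] <- c(out[[ui[k]]], k)
  list(node_ids = nid, pos = pos, eid = ed$id, ui = ui, vi = vi,
       len = ed$length_m, class = ed$class, out = out, edge_order = eord)
}

# Edge times aligned with net_index edge ordering.
indexed_times <- function(net, profile, idx) {
  edge_times(net, profile)[idx$edge_order]
}

# Plain Dijkstra from one or more source nodes over the node graph.
# Tie-break: smaller node index (== ascending node id) wins.
# Returns dist (seconds) and predecessor edge index per node.
dijkstra_nodes <- function(idx, w, sources, target = NULL) {
  n <- length(idx$node_ids)
  dist <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[sources] <- 0
  scan <- dist
  repeat {
    u <- which.min(scan)  # first index on ties == ascending node id
    if (!is.finite(scan[u])) break
    done[u] <- TRUE
    scan[u] <- Inf
    if (!is.null(target) && u == target) break
    for (k in idx$out[[u]]) {
      v <- idx$vi[k]
      nd <- dist[u] + w[k]
      if (!done[v] &&
          (nd < dist[v] - 1e-12 ||
           (nd < dist[v] + 1e-12 && !is.na(pred[v]) && k < pred[v]))) {
        dist[v] <- nd; pred[v] <- k; scan[v] <- nd
      }
    }
  }
  list(dist = dist, pred = pred)
}

# KMP prefix automata over restriction edge-id sequences.
restriction_automata <- function(net, idx) {
  seqs <- restriction_edge_seqs(net)
  lapply(seqs, function(s) {
    e <- match(s, idx$eid)
    L <- length(e)
    fail <- integer(L)
    if (L >= 2L) {
      k <- 0L
      for (q in 2:L) {
        while (k > 0L && e[k + 1L] != e[q]) k <- fail[k]
        if (e[k + 1L] == e[q]) k <- k + 1L
        fail[q] <- k
      }
    }
    list(edges = e, fail = fail, L = L)
  })
}

# Advance progress p of automaton a on edge index e; returns new progress
# (== a$L means the forbidden maneuver would be completed).
kmp_step <- function(a, p, e) {
  while (p > 0L && a$edges[p + 1L] != e) p <- a$fail[p]
  if (a$edges[p + 1L] == e) p + 1L else 0L
}

prog_key <- function(p) paste(p, collapse = ",")

# Label-correcting search over (edge, restriction-progress) states.
# sources: integer node indices, all at time 0. Returns, per node, the best
# arrival time and the state that achieved it, plus parent links for paths.
search_states <- function(idx, w, auto, sources, target = NULL) {
  nR <- length(auto)
  dist <- new.env(parent = emptyenv())   # state key -> time
  meta <- new.env(parent = emptyenv())   # state key -> list(edge, prog, parent)
  best_node <- rep(Inf, length(idx$node_ids))
  best_state <- rep(NA_character_, length(idx$node_ids))
  best_node[sources] <- 0

  init_prog <- function(e) {
    if (nR == 0L) return(integer(0))
    vapply(auto, function(a) kmp_step(a, 0L, e), 0L)
  }

  # frontier as a simple pairing of keys and times (small state counts)
  keys <- character(0); times <- numeric(0)
  push <- function(key, tm) {
    i <- match(key, keys)
    if (is.na(i)) { keys[length(keys) + 1L] <<- key; times[length(times) + 1L] <<- tm }
    else if (tm < times[i]) times[i] <<- tm
  }

  for (s in sources) {
    for (k in idx$out[[s]]) {
      p <- init_prog(k)
      if (nR && any(p == vapply(auto, `[[`, 0L, "L"))) next
      key <- paste0(k, "|", prog_key(p))
      tm <- w[k]
      old <- if (exists(key, envir = dist, inherits = FALSE)) get(key, envir = dist) else Inf
      if (tm < old) {
        assign(key, tm, envir = dist)
        assign(key, list(edge = k, prog = p, parent = NA_character_), envir = meta)
        push(key, tm)
      }
    }
  }

  Ls <- if (nR) vapply(auto, `[[`, 0L, "L") else integer(0)
  while (length(keys)) {
    i <- which.min(times)
    # deterministic tie-break on equal times: smallest state key
    tmin <- times[i]
    cand <- which(times <= tmin + 1e-15)
    if (length(cand) > 1L) i <- cand[order(keys[cand])][1L]
    key <- keys[i]; tm <- times[i]
    keys <- keys[-i]; times <- times[-i]
    if (tm > get(key, envir = dist) + 1e-15) next
    st <- get(key, envir = meta)
    v <- idx$vi[st$edge]
    if (tm < best_node[v] - 1e-12) { best_node[v] <- tm; best_state[v] <- key }
    if (!is.null(target) && v == target && tm > best_node[target] + 1e-12) next
    for (k2 in idx$out[[v]]) {
      if (nR) {
        p2 <- vapply(seq_len(nR), function(r) kmp_step(auto[[r]], st$prog[r], k2), 0L)
        if (any(p2 == Ls)) next
      } else p2 <- integer(0)
      key2 <- paste0(k2, "|", prog_key(p2))
      tm2 <- tm + w[k2]
      old <- if (exists(key2, envir = dist, inherits = FALSE)) get(key2, envir = dist) else Inf
      if (tm2 < old - 1e-15) {
        assign(key2, tm2, envir = dist)
        assign(key2, list(edge = k2, prog = p2, parent = key), envir = meta)
        push(key2, tm2)
      }
    }
  }
  list(best_node = best_node, best_state = best_state, meta = meta)
}

state_path <- function(res, node_i, idx) {
  key <- res$best_state[node_i]
  if (is.na(key)) return(character(0))
  path <- integer(0)
  while (!is.na(key)) {
    st <- get(key, envir = res$meta)
    path <- c(st$edge, path)
    key <- st$parent
  }
  idx$eid[path]
}

# Expanded-graph mode: materialize the product graph over
# (edge, restriction-progress) states and run the plain node Dijkstra on it.
expanded_query <- function(idx, w, auto, src, dst) {
  nR <- length(auto)
  Ls <- if (nR) vapply(auto, `[[`, 0L, "L") else integer(0)
  # discover states by BFS from the source's out-edges
  state_id <- new.env(parent = emptyenv())
  states <- list()
  get_state <- function(e, p) {
    key <- paste0(e, "|", prog_key(p))
    if (exists(key, envir = state_id, inherits = FALSE)) {
      return(get(key, envir = state_id))
    }
    id <- length(states) + 1L
    states[[id]] <<- list(edge = e, prog = p)
    assign(key, id, envir = state_id)
    id
  }
  queue <- integer(0)
  for (k in idx$out[[src]]) {
    p <- if (nR) vapply(auto, function(a) kmp_step(a, 0L, k), 0L) else integer(0)
    if (nR && any(p == Ls)) next
    queue <- c(queue, get_state(k, p))
  }
  roots <- queue
  seen <- rep(FALSE, 0)
  arcs_from <- list()
  qi <- 1L
  while (qi <= length(queue)) {
    sid <- queue[qi]; qi <- qi + 1L
    if (sid <= length(seen) && seen[sid]) next
    if (sid > length(seen)) seen <- c(seen, rep(FALSE, sid - length(seen)))
    seen[sid] <- TRUE
    st <- states[[sid]]
    v <- idx$vi[st$edge]
    nbrs <- integer(0)
    for (k2 in idx$out[[v]]) {
      p2 <- if (nR) vapply(seq_len(nR), function(r) kmp_step(auto[[r]], st$prog[r], k2), 0L) else integer(0)
      if (nR && any(p2 == Ls)) next
      nid <- get_state(k2, p2)
      nbrs <- c(nbrs, nid)
      if (nid > length(seen) || !seen[nid]) queue <- c(queue, nid)
    }
    arcs_from[[sid]] <- nbrs
  }
  nS <- length(states)
  if (nS == 0L) return(list(dist = Inf, path = character(0)))
  # Dijkstra over states
  dist <- rep(Inf, nS); pred <- rep(NA_integer_, nS)
  for (sid in roots) dist[sid] <- min(dist[sid], w[states[[sid]]$edge])
  scan <- dist
  repeat {
    u <- which.min(scan)
    if (!is.finite(scan[u])) break
    scan[u] <- Inf
    nb <- if (u <= length(arcs_from)) arcs_from[[u]] else NULL
    for (sid in nb) {
      nd <- dist[u] + w[states[[sid]]$edge]
      if (nd < dist[sid] - 1e-15) { dist[sid] <- nd; pred[sid] <- u; scan[sid] <- nd }
    }
  }
  at_dst <- which(vapply(states, function(st) idx$vi[st$edge] == dst, TRUE))
  if (!length(at_dst) || all(!is.finite(dist[at_dst]))) {
    return(list(dist = Inf, path = character(0)))
  }
  bi <- at_dst[which.min(dist[at_dst])]
  path <- integer(0); cur <- bi
  while (!is.na(cur)) { path <- c(states[[cur]]$edge, path); cur <- pred[cur] }
  list(dist = dist[bi], path = idx$eid[path])
}

#' Fastest route between two nodes
#'
#' Computes the minimum travel time (seconds) between two nodes under a speed
#' profile. Turn restrictions can be respected (no returned path contains a
#' forbidden maneuver) or ignored, e.g. for blue-light routing. Two
#' restriction-aware implementations are available and return identical
#' durations: `"state"` runs a label search over (edge, maneuver-progress)
#' states; `"expanded"` materializes the equivalent product graph and runs a
#' standard search on it.
#'
#' @param net a [street_network()]
#' @param profile a [speed_profile()] covering all street classes in `net`
#' @param origin,dest node ids
#' @param respect_restrictions honor forbidden maneuvers (default `FALSE`)
#' @param mode `"state"` (default) or `"expanded"`; ignored when
#'   restrictions are not respected
#' @return list with `duration` (seconds; `Inf` if unreachable), `path`
#'   (directed edge ids; empty if origin equals dest or unreachable) and
#'   `reached` (logical).
#' @export
shortest_time <- function(net, profile, origin, dest,
                          respect_restrictions = FALSE,
                          mode = c("state", "expanded")) {
  mode <- match.arg(mode)
  idx <- net_index(net)
  if (!(origin %in% idx$node_ids)) stop_input("unknown origin node %s", origin)
  if (!(dest %in% idx$node_ids)) stop_input("unknown dest node %s", dest)
  w <- indexed_times(net, profile, idx)
  src <- unname(idx$pos[origin]); dst <- unname(idx$pos[dest])
  if (src == dst) return(list(duration = 0, path = character(0), reached = TRUE))

  if (!respect_restrictions || length(net$restrictions) == 0L) {
    res <- dijkstra_nodes(idx, w, src, target = dst)
    if (!is.finite(res$dist[dst])) {
      return(list(duration = Inf, path = character(0), reached = FALSE))
    }
    path <- integer(0); cur <- dst
    while (cur != src) { k <- res$pred[cur]; path <- c(k, path); cur <- idx$ui[k] }
    return(list(duration = res$dist[dst], path = idx$eid[path], reached = TRUE))
  }

  auto <- restriction_automata(net, idx)
  if (mode == "state") {
    res <- search_states(idx, w, auto, src, target = NULL)
    if (!is.finite(res$best_node[dst])) {
      return(list(duration = Inf, path = character(0), reached = FALSE))
    }
    list(duration = res$best_node[dst], path = state_path(res, dst, idx),
         reached = TRUE)
  } else {
    res <- expanded_query(idx, w, auto, src, dst)
    if (!is.finite(res$dist)) {
      return(list(duration = Inf, path = character(0), reached = FALSE))
    }
    list(duration = res$dist, path = res$path, reached = TRUE)
  }
}

#' Travel-time field from the nearest of several sources
#'
#' For every node, the minimum travel time from any source (multi-source
#' search); the basis of isochrone maps where each street segment is colored
#' by the larger of its endpoint times. Unreachable nodes get `Inf`.
#'
#' @inheritParams shortest_time
#' @param sources non-empty vector of source node ids
#' @return named numeric vector: node id -> seconds (`Inf` = unreachable).
#' @export
nearest_source_times <- function(net, profile, sources,
                                 respect_restrictions = FALSE) {
  if (length(sources) == 0L) stop_input("sources must be non-empty")
  idx <- net_index(net)
  bad <- setdiff(sources, idx$node_ids)
  if (length(bad)) stop_input("unknown source node(s): %s", paste(bad, collapse = ", "))
  w <- indexed_times(net, profile, idx)
  si <- unname(idx$pos[as.character(sources)])
  if (!respect_restrictions || length(net$restrictions) == 0L) {
    res <- dijkstra_nodes(idx, w, si)
    out <- res$dist
  } else {
    auto <- restriction_automata(net, idx)
    res <- search_states(idx, w, auto, si)
    out <- res$best_node
    out[si] <- 0
  }
  stats::setNames(out, idx$node_ids)
}

# Network *distance* (meters) field / point-to-point, used where regulations
# are written in street-network meters rather than minutes.
network_distances <- function(net, sources) {
  idx <- net_index(net)
  si <- unname(idx$pos[as.character(sources)])
  res <- dijkstra_nodes(idx, idx$len, si)
  stats::setNames(res$dist, idx$node_ids)
}
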