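# Shared fixtures and independent brute-force oracles.

# ---- networks -----------------------------------------------------------

grid_raw <- function(g, spacing = 100) {
  ij <- expand.grid(i = 0:(g - 1), j = 0:(g - 1))
  nodes <- data.frame(id = sprintf("n%d_%d", ij$i, ij$j),
                      x = ij$i * spacing, y = ij$j * spacing)
  ways <- list()
  for (j in 0:(g - 1)) {
    ways[[length(ways) + 1]] <- list(id = sprintf("h%d", j),
                                     nodes = sprintf("n%d_%d", 0:(g - 1), j),
                                     class = "minor")
  }
  for (i in 0:(g - 1)) {
    ways[[length(ways) + 1]] <- list(id = sprintf("v%d", i),
                                     nodes = sprintf("n%d_%d", i, 0:(g - 1)),
                                     class = "minor")
  }
  list(nodes = nodes, ways = ways)
}

line_net <- function(n = 5, len = 1000, class = "minor") {
  nodes <- data.frame(id = letters[1:n], x = (0:(n - 1)) * len, y = 0)
  streets <- data.frame(id = paste0("s", 1:(n - 1)),
                        u = letters[1:(n - 1)], v = letters[2:n],
                        length_m = len, class = class, oneway = FALSE)
  street_network(nodes, streets)
}

random_streets_net <- function(n_nodes, n_extra, seed) {
  set.seed(seed)
  nodes <- data.frame(id = sprintf("x%02d", 1:n_nodes),
                      x = runif(n_nodes, 0, 5000),
                      y = runif(n_nodes, 0, 5000))
  # spanning chain + random extras, so the graph is connected
  u <- nodes$id[1:(n_nodes - 1)]; v <- nodes$id[2:n_nodes]
  for (k in seq_len(n_extra)) {
    pr <- sample(nodes$id, 2)
    u <- c(u, pr[1]); v <- c(v, pr[2])
  }
  keep <- u != v
  u <- u[keep]; v <- v[keep]
  len <- sqrt((nodes$x[match(u, nodes$id)] - nodes$x[match(v, nodes$id)])^2 +
                (nodes$y[match(u, nodes$id)] - nodes$y[match(v, nodes$id)])^2)
  len[len <= 0] <- 1
  streets <- data.frame(id = sprintf("e%03d", seq_along(u)), u = u, v = v,
                        length_m = len,
                        class = sample(c("major", "minor"), length(u),
                                       replace = TRUE),
                        oneway = FALSE)
  street_network(nodes, streets)
}

# Exhaustive restriction-respecting shortest time by simple-path enumeration
# (paths up to max_edges edges, no repeated edges).
enumerate_restricted_time <- function(net, profile, origin, dest,
                                      max_edges = 12) {
  idx <- careops:::net_index(net)
  w <- careops:::indexed_times(net, profile, idx)
  seqs <- lapply(careops:::restriction_edge_seqs(net),
                 function(s) match(s, idx$eid))
  best <- Inf
  if (origin == dest) return(0)
  src <- unname(idx$pos[origin]); dst <- unname(idx$pos[dest])
  contains_banned <- function(edges) {
    for (s in seqs) {
      L <- length(s)
      if (length(edges) >= L) {
        for (st in 1:(length(edges) - L + 1)) {
          if (all(edges[st:(st + L - 1)] == s)) return(TRUE)
        }
      }
    }
    FALSE
  }
  rec <- function(node, edges, tm) {
    if (tm >= best) return(invisible(NULL))
    if (node == dst && length(edges)) { best <<- min(best, tm); return(invisible(NULL)) }
    if (length(edges) >= max_edges) return(invisible(NULL))
    for (k in idx$out[[node]]) {
      if (k %in% edges) next
      e2 <- c(edges, k)
      if (contains_banned(e2)) next
      rec(idx$vi[k], e2, tm + w[k])
    }
  }
  rec(src, integer(0), 0)
  best
}

# ---- q-multiset multicover oracle ---------------------------------------

# Minimum suppliers by iterative deepening over total cost; feasibility by
# region-subset (min-cut) condition; robust over a scenario list.
oracle_qmsmc <- function(inst, scenarios) {
  nl <- length(inst$locations); nr <- length(inst$regions); q <- inst$q
  subsets <- lapply(seq_len(2^nr - 1), function(mask) {
    S <- which(bitwAnd(mask, 2^(seq_len(nr) - 1)) > 0)
    list(S = S, locs = which(rowSums(inst$incidence[, S, drop = FALSE]) > 0))
  })
  feas <- function(x, v) {
    for (sb in subsets) if (q * sum(x[sb$locs]) < sum(v[sb$S])) return(FALSE)
    TRUE
  }
  # stacking each scenario's independent covering is always feasible, so it
  # bounds the iterative-deepening search from above
  ub <- sum(vapply(scenarios, function(v) sum(ceiling(v / q)), 0))
  if (ub == 0) return(0L)
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (first in 0:total) {
      rest <- compositions(total - first, parts - 1)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  for (cost in 0:ub) {
    comp <- compositions(cost, nl)
    for (r in seq_len(nrow(comp))) {
      x <- comp[r, ]
      if (all(vapply(scenarios, function(v) feas(x, v), TRUE))) {
        return(as.integer(cost))
      }
    }
  }
  ub
}

random_cover_instance <- function() {
  nl <- sample(2:5, 1); nr <- sample(2:5, 1); q <- sample(1:3, 1)
  inc <- matrix(runif(nl * nr) < 0.55, nl, nr)
  cl <- sample(0:3, nr, replace = TRUE)
  for (j in which(cl > 0 & colSums(inc) == 0)) inc[sample(nl, 1), j] <- TRUE
  cover_instance(paste0("l", 1:nl), paste0("r", 1:nr),
                 stats::setNames(cl, paste0("r", 1:nr)), inc, q)
}

# ---- duty plan oracle ---------------------------------------------------

# Exhaustive over all 2^(P*T) 0/1 plans (vectorized over plan codes).
# Returns list(opt = minimal services or Inf,
#              fair = lexicographically minimal sorted-descending load
#                     vector of the coverage-only problem, or NULL).
oracle_duty <- function(inst, fairness = NULL) {
  P <- length(inst$pharmacies); T <- inst$horizon
  nb <- P * T
  stopifnot(nb <= 20)
  codes <- 0:(2^nb - 1)
  bits <- matrix(0L, length(codes), nb)
  for (b in seq_len(nb)) bits[, b] <- bitwAnd(codes, 2^(b - 1)) > 0
  # column b = pharmacy ((b-1) %% P) + 1, day ((b-1) %/% P) + 1
  ok <- rep(TRUE, length(codes))
  need <- inst$c_cover + inst$gamma
  colof <- function(p, d) (d - 1) * P + p
  for (m in inst$municipalities) {
    cm <- match(inst$cov[[m]], inst$pharmacies)
    for (d in seq_len(T)) {
      cnt <- if (length(cm)) rowSums(bits[, colof(cm, d), drop = FALSE]) else 0
      ok <- ok & cnt >= need
    }
  }
  ok_cover_only <- ok
  need1 <- inst$c_cover
  if (need1 != need) {
    ok_cover_only <- rep(TRUE, length(codes))
    for (m in inst$municipalities) {
      cm <- match(inst$cov[[m]], inst$pharmacies)
      for (d in seq_len(T)) {
        cnt <- if (length(cm)) rowSums(bits[, colof(cm, d), drop = FALSE]) else 0
        ok_cover_only <- ok_cover_only & cnt >= need1
      }
    }
  }
  for (pr in inst$conflicts) {
    i <- match(pr[1], inst$pharmacies); j <- match(pr[2], inst$pharmacies)
    for (d in seq_len(T)) {
      ok <- ok & !(bits[, colof(i, d)] & bits[, colof(j, d)])
    }
  }
  if (inst$rest > 0) {
    for (p in seq_len(P)) for (d in seq_len(T - 1)) {
      for (dd in (d + 1):min(T, d + inst$rest)) {
        ok <- ok & !(bits[, colof(p, d)] & bits[, colof(p, dd)])
      }
    }
  }
  totals <- sapply(seq_len(P), function(p)
    rowSums(bits[, colof(p, seq_len(T)), drop = FALSE]))
  if (is.null(dim(totals))) totals <- matrix(totals, nrow = 1)
  lo <- rep(inst$s_min, P); hi <- rep(Inf, P)
  if (!is.null(fairness)) {
    fl <- unclass(fairness)[inst$pharmacies]
    lo <- pmax(lo, floor((1 - inst$delta) * fl))
    hi <- ceiling((1 + inst$delta) * fl)
  }
  okb <- ok
  for (p in seq_len(P)) okb <- okb & totals[, p] >= lo[p] & totals[, p] <= hi[p]
  opt <- if (any(okb)) min(rowSums(bits[okb, , drop = FALSE])) else Inf

  fair <- NULL
  if (any(ok_cover_only)) {
    loads <- totals[ok_cover_only, , drop = FALSE]
    sorted <- t(apply(loads, 1, function(x) sort(x, decreasing = TRUE)))
    if (is.null(dim(sorted))) sorted <- matrix(sorted, ncol = P)
    o <- do.call(order, lapply(seq_len(P), function(j) sorted[, j]))
    fair <- sorted[o[1], ]
  }
  list(opt = opt, fair = fair)
}

random_pharmacy_instance <- function(max_bits = 16, gamma_max = 1,
                                     with_conflict = TRUE) {
  repeat {
    P <- sample(2:4, 1); T <- sample(2:5, 1)
    if (P * T <= max_bits) break
  }
  Ps <- paste0("p", 1:P)
  M <- sample(1:2, 1); Ms <- paste0("m", 1:M)
  covl <- lapply(Ms, function(m) sample(Ps, sample(1:P, 1)))
  names(covl) <- Ms
  conf <- if (with_conflict && P >= 2 && runif(1) < 0.4) list(sample(Ps, 2)) else list()
  pharmacy_instance(Ps, Ms, covl, conf, T,
                    c_cover = 1, gamma = sample(0:gamma_max, 1),
                    rest = sample(0:1, 1), s_min = sample(0:1, 1),
                    pharmacy_municipality = stats::setNames(
                      sample(Ms, P, replace = TRUE), Ps))
}

# ---- vrp oracle ---------------------------------------------------------

perms_list <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms_list(v[-i]), function(p) c(v[i], p))))
}

# Lexicographic (max delay, total delay) optimum by full assignment x
# permutation enumeration, sharing only the route-timing arithmetic.
oracle_vrp <- function(requests, vehicles, tt, anchors = NULL) {
  n <- nrow(requests); nv <- nrow(vehicles)
  best <- c(Inf, Inf)
  grid <- expand.grid(rep(list(1:nv), n))
  for (g in seq_len(max(1, nrow(grid)))) {
    a <- if (n) as.integer(grid[g, ]) else integer(0)
    fronts <- list(); ok <- TRUE
    for (v in 1:nv) {
      ridx <- which(a == v); bestv <- list()
      for (p in perms_list(ridx)) {
        ev <- careops:::eval_route(vehicles[v, ],
                                   requests[p, , drop = FALSE], tt,
                                   anchor = anchors[[vehicles$id[v]]])
        if (!is.null(ev)) bestv[[length(bestv) + 1]] <- c(ev$max_delay,
                                                          ev$sum_delay)
      }
      if (!length(bestv)) { ok <- FALSE; break }
      fronts[[v]] <- bestv
    }
    if (!ok) next
    combo <- function(v, cm, cs) {
      if (v > nv) {
        if (cm < best[1] - 1e-9 ||
            (cm < best[1] + 1e-9 && cs < best[2] - 1e-9)) best <<- c(cm, cs)
        return(invisible(NULL))
      }
      for (b in fronts[[v]]) combo(v + 1, max(cm, b[1]), cs + b[2])
    }
    combo(1, 0, 0)
  }
  best
}

random_vrp_case <- function(net_nodes = letters[1:5]) {
  nr <- sample(2:4, 1)
  pk <- sample(net_nodes, nr, replace = TRUE)
  dr <- vapply(pk, function(p) sample(setdiff(net_nodes, p), 1), "")
  transport_requests(data.frame(
    id = paste0("r", 1:nr), pickup = pk, dropoff = unname(dr),
    t_req_s = sort(sample(seq(3600, 20000, by = 600), nr)),
    load_s = 300, unload_s = 300, covid = runif(nr) < 0.3))
}

two_vehicles <- function(depot = "a") {
  transport_vehicles(data.frame(
    id = c("v1", "v2"), depot = depot, shift_start_s = 0,
    shift_end_s = 86400, fleet = c("clean", "floater")))
}

small_region <- function(seed = 7) {
  generate_region(region_config(grid = 6, municipalities = 4,
                                pharmacies = 6, population = 20000,
                                n_restrictions = 1, extra_sites = 2),
                  seed = seed)
}

# Shared travel-time function on the 5-node line for the routing suites.
tt_accept <- local({
  net <- NULL
  fn <- NULL
  function(from, to) {
    if (is.null(fn)) {
      net <<- line_net(5, len = 1000, class = "minor")
      fn <<- travel_time_fun(net, speed_profile(c(minor = 60)))
    }
    fn(from, to)
  }
})
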