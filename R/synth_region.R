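#' Synthetic planning regions
#'
#' Seeded generator of synthetic regions carrying the structure the planning
#' problems assume: a classed street network (grid with diagonal shortcuts and
#' a few turn restrictions), municipalities as Voronoi cells of random seed
#' nodes with Dirichlet-split populations, candidate facility sites,
#' pharmacies placed proportionally to population, hospitals and depots.
#' It replaces the confidential municipal, emergency and transport data the
#' planning methods were developed on; identical `seed` + `config` give
#' byte-identical regions.
#'
#' @param config list of generator settings, see [region_config()].
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_region`: list with `network`
#'   ([street_network()]), `municipalities` (data.frame: id, center node,
#'   population, county), `neighbors` (named list of neighbor-municipality
#'   ids), `node_municipality` (named vector), `candidate_sites`,
#'   `pharmacies` (data.frame: id, node, municipality), `hospitals`,
#'   `depots`, `seed`, `config`.
#' @export
generate_region <- function(config = region_config(), seed = 1L) {
  cfg <- utils::modifyList(region_config(), config)
  if (cfg$municipalities > cfg$grid^2) {
    stop_input("more municipalities (%d) than nodes (%d)",
               cfg$municipalities, cfg$grid^2)
  }
  with_seed(seed, {
    g <- cfg$grid
    sp <- cfg$spacing_m
    ij <- expand.grid(i = seq_len(g) - 1L, j = seq_len(g) - 1L)
    ids <- sprintf("n%03d", seq_len(nrow(ij)))
    jit <- cfg$jitter_m
    nodes <- data.frame(id = ids,
                        x = ij$i * sp + stats::runif(nrow(ij), -jit, jit),
                        y = ij$j * sp + stats::runif(nrow(ij), -jit, jit),
                        stringsAsFactors = FALSE)
    at <- function(i, j) ids[i + j * g + 1L]

    ways <- list()
    wid <- 0L
    add_way <- function(a, b, cl, oneway = FALSE) {
      wid <<- wid + 1L
      ways[[wid]] <<- list(id = sprintf("w%04d", wid), nodes = c(a, b),
                           class = cl, oneway = oneway)
    }
    # class mix: horizontal/vertical streets; a band of major roads
    for (j in 0:(g - 1L)) for (i in 0:(g - 2L)) {
      cl <- if (j %% cfg$major_every == 0L) "major" else "minor"
      add_way(at(i, j), at(i + 1L, j), cl)
    }
    for (i in 0:(g - 1L)) for (j in 0:(g - 2L)) {
      cl <- if (i %% cfg$major_every == 0L) "major" else "minor"
      add_way(at(i, j), at(i, j + 1L), cl)
    }
    # diagonal shortcuts on a random subset of cells
    for (j in 0:(g - 2L)) for (i in 0:(g - 2L)) {
      if (stats::runif(1) < cfg$diagonal_prob) {
        if (stats::runif(1) < 0.5) add_way(at(i, j), at(i + 1L, j + 1L), "minor")
        else add_way(at(i + 1L, j), at(i, j + 1L), "minor")
      }
    }
    net <- build_network(nodes, ways, simplify = FALSE)

    # a few forbidden maneuvers at interior crossings
    restr <- list()
    if (cfg$n_restrictions > 0L) {
      tries <- 0L
      while (length(restr) < cfg$n_restrictions && tries < 200L) {
        tries <- tries + 1L
        i <- sample(seq_len(g - 2L), 1L); j <- sample(seq_len(g - 2L), 1L)
        mid <- at(i, j)
        # straight-through ban west->mid->east
        wv <- find_way(ways, at(i - 1L, j), mid)
        ev <- find_way(ways, mid, at(i + 1L, j))
        if (is.null(wv) || is.null(ev)) next
        cand <- list(via_nodes = c(at(i - 1L, j), mid, at(i + 1L, j)),
                     via_ways = c(wv, ev))
        key <- paste(cand$via_nodes, collapse = "-")
        if (!key %in% vapply(restr, function(r) paste(r$via_nodes, collapse = "-"), "")) {
          restr[[length(restr) + 1L]] <- cand
        }
      }
      net <- build_network(nodes, ways, restr, simplify = FALSE)
    }

    M <- cfg$municipalities
    centers <- sort(sample(ids, M))
    mid <- sprintf("m%02d", seq_len(M))
    cx <- nodes$x[match(centers, nodes$id)]
    cy <- nodes$y[match(centers, nodes$id)]
    d2 <- outer(nodes$x, cx, "-")^2 + outer(nodes$y, cy, "-")^2
    cell <- apply(d2, 1L, which.min)
    node_mun <- stats::setNames(mid[cell], nodes$id)

    # populations: symmetric Dirichlet(alpha = 2) split of the total
    gam <- stats::rgamma(M, shape = 2)
    popfrac <- gam / sum(gam)
    pop <- floor(popfrac * cfg$population)
    rem <- cfg$population - sum(pop)
    if (rem > 0) {
      o <- order(popfrac * cfg$population - pop, decreasing = TRUE)
      pop[o[seq_len(rem)]] <- pop[o[seq_len(rem)]] + 1L
    }
    pop[pop == 0L] <- 1L

    # neighbor sets from street adjacency across cell boundaries
    nb <- stats::setNames(vector("list", M), mid)
    for (k in seq_len(nrow(net$streets))) {
      a <- node_mun[[net$streets$u[k]]]; b <- node_mun[[net$streets$v[k]]]
      if (a != b) {
        nb[[a]] <- union(nb[[a]], b)
        nb[[b]] <- union(nb[[b]], a)
      }
    }
    nb <- lapply(nb, function(s) sort(s %||% character(0)))

    # counties by coordinate quadrant of the municipality center
    county <- paste0("c", 1L + (cx > stats::median(nodes$x)) +
                       2L * (cy > stats::median(nodes$y)))

    municipalities <- data.frame(id = mid, center = centers,
                                 population = as.integer(pop),
                                 county = county, stringsAsFactors = FALSE)

    # candidate facility sites: municipality centers plus random extras
    extra <- sample(setdiff(ids, centers), min(cfg$extra_sites, g^2 - M))
    candidate_sites <- sort(unique(c(centers, extra)))

    # pharmacies placed proportionally to population
    nph <- cfg$pharmacies
    cnt <- pmax(1L, floor(nph * pop / sum(pop)))
    while (sum(cnt) > nph) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
    while (sum(cnt) < nph) cnt[which.max(pop / cnt)] <- cnt[which.max(pop / cnt)] + 1L
    ph_node <- character(0); ph_mun <- character(0)
    for (m in seq_len(M)) {
      pool <- names(node_mun)[node_mun == mid[m]]
      pick <- sample(pool, cnt[m], replace = cnt[m] > length(pool))
      ph_node <- c(ph_node, pick)
      ph_mun <- c(ph_mun, rep(mid[m], cnt[m]))
    }
    pharmacies <- data.frame(id = sprintf("p%03d", seq_along(ph_node)),
                             node = ph_node, municipality = ph_mun,
                             stringsAsFactors = FALSE)

    hospitals <- sort(sample(candidate_sites, max(1L, cfg$hospitals)))
    depots <- sort(sample(ids, max(1L, cfg$depots)))

    structure(list(network = net, municipalities = municipalities,
                   neighbors = nb, node_municipality = node_mun,
                   candidate_sites = candidate_sites,
                   pharmacies = pharmacies, hospitals = hospitals,
                   depots = depots, seed = as.integer(seed), config = cfg),
              class = "synthetic_region")
  })
}

find_way <- function(ways, a, b) {
  for (w in ways) {
    if ((w$nodes[1] == a && w$nodes[2] == b) ||
        (!isTRUE(w$oneway) && w$nodes[1] == b && w$nodes[2] == a)) return(w$id)
  }
  NULL
}

#' Generator settings for [generate_region()]
#'
#' @param grid nodes per grid side (network has `grid^2` nodes).
#' @param spacing_m grid spacing in meters.
#' @param jitter_m coordinate jitter in meters.
#' @param major_every every k-th row/column of streets is class `major`.
#' @param diagonal_prob probability of a diagonal shortcut per grid cell.
#' @param n_restrictions number of forbidden straight-through maneuvers.
#' @param municipalities number of municipalities (Voronoi cells).
#' @param population total region population, Dirichlet(2)-split.
#' @param pharmacies number of pharmacies, placed proportional to population.
#' @param extra_sites candidate facility sites beyond municipality centers.
#' @param hospitals,depots counts of hospital nodes / vehicle depots.
#' @return named list of settings.
#' @export
region_config <- function(grid = 10L, spacing_m = 1500, jitter_m = 150,
                          major_every = 3L, diagonal_prob = 0.25,
                          n_restrictions = 4L, municipalities = 8L,
                          population = 100000L, pharmacies = 18L,
                          extra_sites = 6L, hospitals = 2L, depots = 2L) {
  list(grid = as.integer(grid), spacing_m = spacing_m, jitter_m = jitter_m,
       major_every = as.integer(major_every), diagonal_prob = diagonal_prob,
       n_restrictions = as.integer(n_restrictions),
       municipalities = as.integer(municipalities),
       population = as.integer(population), pharmacies = as.integer(pharmacies),
       extra_sites = as.integer(extra_sites), hospitals = as.integer(hospitals),
       depots = as.integer(depots))
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf("<synthetic_region> seed %d: %d nodes, %d municipalities, %d pharmacies\n",
              x$seed, nrow(x$network$nodes), nrow(x$municipalities),
              nrow(x$pharmacies)))
  cat(sprintf("  population %d, %d candidate sites, %d hospitals, %d depots\n",
              sum(x$municipalities$population), length(x$candidate_sites),
              length(x$hospitals), length(x$depots)))
  invisible(x)
}

#' Sample a synthetic emergency log
#'
#' Homogeneous Poisson arrivals over a horizon of days; scene nodes drawn
#' proportionally to municipality population (uniform node within the
#' municipality); log-normal on-scene durations; Bernoulli
#' transport-to-hospital legs to the nearest hospital.
#'
#' @param region a [generate_region()] result.
#' @param daily_rate mean emergencies per day (>= 0).
#' @param days horizon in days.
#' @param seed RNG seed.
#' @param onscene_median_s,onscene_sdlog log-normal on-scene duration
#'   parameters (median seconds, sigma on the log scale).
#' @param transport_prob probability an emergency needs a hospital leg.
#' @return data.frame of class `emergency_log`: `time_s` (non-decreasing,
#'   seconds from horizon start), `node`, `onscene_s`, `transport`,
#'   `hospital`, `municipality`.
#' @export
sample_emergencies <- function(region, daily_rate, days, seed = 1L,
                               onscene_median_s = 1200, onscene_sdlog = 0.5,
                               transport_prob = 0.5) {
  stopifnot(inherits(region, "synthetic_region"))
  if (daily_rate < 0) stop_input("daily_rate must be >= 0")
  with_seed(seed, {
    n <- stats::rpois(1L, daily_rate * days)
    if (n == 0L) {
      return(structure(data.frame(time_s = numeric(0), node = character(0),
                                  onscene_s = numeric(0), transport = logical(0),
                                  hospital = character(0),
                                  municipality = character(0),
                                  stringsAsFactors = FALSE),
                       class = c("emergency_log", "data.frame")))
    }
    times <- sort(stats::runif(n, 0, days * 86400))
    mun <- region$municipalities
    mpick <- sample(mun$id, n, replace = TRUE, prob = mun$population)
    node <- vapply(mpick, function(m) {
      pool <- names(region$node_municipality)[region$node_municipality == m]
      sample(pool, 1L)
    }, "")
    onscene <- stats::rlnorm(n, meanlog = log(onscene_median_s),
                             sdlog = onscene_sdlog)
    transport <- stats::runif(n) < transport_prob
    hosp <- rep(NA_character_, n)
    if (any(transport)) {
      hd <- vapply(region$hospitals, function(h) {
        network_distances(region$network, h)
      }, numeric(nrow(region$network$nodes)))
      hosp[transport] <- region$hospitals[
        apply(hd[node[transport], , drop = FALSE], 1L, which.min)]
    }
    structure(data.frame(time_s = times, node = unname(node),
                         onscene_s = onscene, transport = transport,
                         hospital = hosp, municipality = unname(mpick),
                         stringsAsFactors = FALSE),
              class = c("emergency_log", "data.frame"))
  })
}

#' Sample a synthetic transport day
#'
#' Plannable requests (known at day start) with pickup times uniform in
#' 06:00-18:00 between random node pairs, plus ad-hoc requests arriving as an
#' in-day Poisson stream with short uniform lead times (release before the
#' requested pickup). Covid flags are Bernoulli; a configured fraction of
#' plannable requests are dialysis outward trips to the nearest hospital.
#'
#' @param region a [generate_region()] result.
#' @param n_plannable number of plannable requests.
#' @param adhoc_rate_per_h ad-hoc arrival rate per hour over 06:00-18:00.
#' @param covid_prob Covid prevalence among requests.
#' @param dialysis_frac fraction of plannable requests tagged dialysis.
#' @param load_s,unload_s service durations (seconds).
#' @param lead_min_s,lead_max_s ad-hoc lead time bounds (seconds).
#' @param seed RNG seed.
#' @return list of class `transport_day` with `plannable` and `adhoc`
#'   request data.frames (`adhoc` carries `release_s` < `t_req_s`).
#' @export
sample_transport_day <- function(region, n_plannable = 20L,
                                 adhoc_rate_per_h = 1, covid_prob = 0.1,
                                 dialysis_frac = 0.3, load_s = 300,
                                 unload_s = 300, lead_min_s = 600,
                                 lead_max_s = 2700, seed = 1L) {
  stopifnot(inherits(region, "synthetic_region"))
  with_seed(seed, {
    ids <- region$network$nodes$id
    mk <- function(n, prefix, t_req, release) {
      if (n == 0L) {
        return(data.frame(id = character(0), pickup = character(0),
                          dropoff = character(0), t_req_s = numeric(0),
                          load_s = numeric(0), unload_s = numeric(0),
                          covid = logical(0), dialysis = logical(0),
                          release_s = numeric(0), stringsAsFactors = FALSE))
      }
      pick <- sample(ids, n, replace = TRUE)
      drop <- vapply(pick, function(p) sample(setdiff(ids, p), 1L), "")
      data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
                 pickup = pick, dropoff = unname(drop), t_req_s = t_req,
                 load_s = load_s, unload_s = unload_s,
                 covid = stats::runif(n) < covid_prob,
                 dialysis = FALSE, release_s = release,
                 stringsAsFactors = FALSE)
    }
    plannable <- mk(n_plannable, "r",
                    t_req = sort(round(stats::runif(n_plannable, 6 * 3600, 18 * 3600))),
                    release = 0)
    if (n_plannable > 0L) {
      ndial <- round(dialysis_frac * n_plannable)
      if (ndial > 0L) {
        di <- sample(seq_len(n_plannable), ndial)
        plannable$dialysis[di] <- TRUE
        # dialysis outward trips end at the nearest hospital (skipping a
        # hospital co-located with the pickup)
        for (i in di) {
          hs <- setdiff(region$hospitals, plannable$pickup[i])
          if (!length(hs)) next
          plannable$dropoff[i] <- hs[
            which.min(vapply(hs, function(h) {
              network_distances(region$network, h)[[plannable$pickup[i]]]
            }, 0))]
        }
      }
    }
    n_adhoc <- stats::rpois(1L, adhoc_rate_per_h * 12)
    adhoc <- mk(n_adhoc, "a",
                t_req = sort(round(stats::runif(n_adhoc, 6 * 3600, 18 * 3600))),
                release = 0)
    if (n_adhoc > 0L) {
      lead <- stats::runif(n_adhoc, lead_min_s, lead_max_s)
      adhoc$release_s <- pmax(0, adhoc$t_req_s - round(lead))
    }
    structure(list(plannable = plannable, adhoc = adhoc, seed = as.integer(seed)),
              class = "transport_day")
  })
}

#' Read or write a synthetic region as JSON
#'
#' Full round-trip serialization: the street network, municipalities,
#' neighbor sets, facility layers, and the generating seed/config.
#'
#' @param region a [generate_region()] result.
#' @param path file path.
#' @return `read_region_json` returns a `synthetic_region`;
#'   `write_region_json` returns `path` invisibly.
#' @export
write_region_json <- function(region, path) {
  doc <- list(
    schema = "careops/region/1",
    seed = region$seed,
    config = region$config,
    nodes = region$network$nodes,
    edges = region$network$streets,
    restrictions = lapply(region$network$restrictions,
                          function(r) list(via = r$via)),
    municipalities = region$municipalities,
    neighbors = region$neighbors,
    node_municipality = as.list(region$node_municipality),
    candidate_sites = region$candidate_sites,
    pharmacies = region$pharmacies,
    hospitals = region$hospitals,
    depots = region$depots)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_region_json
#' @export
read_region_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (!identical(doc$schema, "careops/region/1")) {
    stop_input("unsupported region schema: %s", doc$schema %||% "<missing>")
  }
  restr <- doc$restrictions
  if (is.data.frame(restr)) {
    restr <- lapply(restr$via, function(v) list(via = as.character(v)))
  } else if (is.list(restr) && length(restr)) {
    restr <- lapply(restr, function(r) list(via = as.character(r$via)))
  } else restr <- list()
  net <- street_network(doc$nodes, doc$edges, restr)
  structure(list(network = net,
                 municipalities = doc$municipalities,
                 neighbors = lapply(doc$neighbors, as.character),
                 node_municipality = unlist(doc$node_municipality),
                 candidate_sites = as.character(doc$candidate_sites),
                 pharmacies = doc$pharmacies,
                 hospitals = as.character(doc$hospitals),
                 depots = as.character(doc$depots),
                 seed = as.integer(doc$seed),
                 config = utils::modifyList(region_config(), doc$config)),
            class = "synthetic_region")
}
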