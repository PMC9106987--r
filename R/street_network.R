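#' Street networks with turn restrictions
#'
#' A `street_network` is a directed, classed road graph: planar node
#' coordinates in meters, directed edges carrying a length and a street-class
#' label, and an optional list of forbidden-maneuver turn restrictions. Two-way
#' streets are stored as two directed edges sharing a street identifier
#' (suffixes `:f` and `:b`).
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (planar meters).
#' @param streets data.frame with columns `id`, `u`, `v`, `length_m`, `class`
#'   and logical `oneway`; one row per (undirected) street.
#' @param restrictions list of turn restrictions, each a list with element
#'   `via`: an alternating character vector `node, edge, node, edge, node, ...`
#'   of at least two edges, forming a connected walk of directed edge ids.
#' @return An object of class `street_network` with elements `nodes`,
#'   `edges` (directed), `streets`, and `restrictions`.
#' @export
street_network <- function(nodes, streets, restrictions = list()) {
  nodes <- data.frame(id = as.character(nodes$id),
                      x = as.numeric(nodes$x), y = as.numeric(nodes$y),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop_input("duplicate node ids")
  streets <- data.frame(id = as.character(streets$id),
                        u = as.character(streets$u),
                        v = as.character(streets$v),
                        length_m = as.numeric(streets$length_m),
                        class = as.character(streets$class),
                        oneway = as.logical(streets$oneway),
                        stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes,
                        edges = directed_edges(streets),
                        streets = streets,
                        restrictions = restrictions),
                   class = "street_network")
  validate_network(net)
  net
}

directed_edges <- function(streets) {
  fwd <- data.frame(id = paste0(streets$id, ":f"),
                    u = streets$u, v = streets$v,
                    length_m = streets$length_m, class = streets$class,
                    street = streets$id, stringsAsFactors = FALSE)
  bwd <- streets[!streets$oneway, , drop = FALSE]
  if (nrow(bwd)) {
    bwd <- data.frame(id = paste0(bwd$id, ":b"),
                      u = bwd$v, v = bwd$u,
                      length_m = bwd$length_m, class = bwd$class,
                      street = bwd$id, stringsAsFactors = FALSE)
    fwd <- rbind(fwd, bwd)
  }
  fwd[order(fwd$id), , drop = FALSE]
}

validate_network <- function(net) {
  stopifnot(inherits(net, "street_network"))
  miss <- setdiff(c(net$edges$u, net$edges$v), net$nodes$id)
  if (length(miss)) stop_input("edge endpoint(s) not in nodes: %s",
                               paste(miss, collapse = ", "))
  if (any(!is.finite(net$edges$length_m)) || any(net$edges$length_m <= 0)) {
    stop_input("edge lengths must be positive and finite")
  }
  eid <- net$edges$id
  for (r in net$restrictions) {
    via <- r$via
    if (length(via) < 5L || length(via) %% 2L == 0L) {
      stop_input("restriction via must alternate node,edge,...,node with >= 2 edges")
    }
    rn <- via[seq(1L, length(via), by = 2L)]
    re <- via[seq(2L, length(via), by = 2L)]
    if (!all(re %in% eid)) stop_input("restriction references unknown edge")
    if (!all(rn %in% net$nodes$id)) stop_input("restriction references unknown node")
    for (k in seq_along(re)) {
      e <- net$edges[match(re[k], eid), ]
      if (e$u != rn[k] || e$v != rn[k + 1L]) {
        stop_input("restriction via is not a connected walk at edge %s", re[k])
      }
    }
  }
  invisible(net)
}

# Restriction edge-id sequences (the walk's directed edges, in order).
restriction_edge_seqs <- function(net) {
  lapply(net$restrictions, function(r) r$via[seq(2L, length(r$via), by = 2L)])
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf("<street_network> %d nodes, %d directed edges (%d streets), %d turn restrictions\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$streets), length(x$restrictions)))
  cat(sprintf("  classes: %s\n",
              paste(sort(unique(x$edges$class)), collapse = ", ")))
  cat(sprintf("  total length: %.1f km\n", sum(x$streets$length_m) / 1000))
  invisible(x)
}

#' Build a street network from raw ways
#'
#' Constructs a [street_network()] from raw map primitives: a node table,
#' a list of ways (node sequences with a street class), and raw turn
#' restrictions given as way-level via sequences. Ways are split at crossings
#' (nodes shared by two or more ways and way endpoints). With `simplify`,
#' interior degree-2 nodes joining exactly two streets with identical
#' attribute sets are smoothed away and lengths summed; total network length
#' is preserved and restrictions are remapped onto the surviving edges.
#'
#' @param raw_nodes data.frame with `id`, `x`, `y` (planar meters).
#' @param raw_ways list of ways; each way is a list with `id`, `nodes`
#'   (character vector of node ids, length >= 2), `class`, and optional
#'   logical `oneway` (default `FALSE`, direction = node order).
#' @param raw_restrictions list of forbidden maneuvers; each a list with
#'   `via_nodes` (k+1 node ids) and `via_ways` (k way ids, k >= 2): the walk
#'   enters at `via_nodes[i]`, follows `via_ways[i]` to `via_nodes[i+1]`.
#' @param simplify smooth out interior degree-2 nodes (default `TRUE`).
#' @return A [street_network()].
#' @export
build_network <- function(raw_nodes, raw_ways, raw_restrictions = list(),
                          simplify = TRUE) {
  nodes <- data.frame(id = as.character(raw_nodes$id),
                      x = as.numeric(raw_nodes$x), y = as.numeric(raw_nodes$y),
                      stringsAsFactors = FALSE)
  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  way_ids <- vapply(raw_ways, function(w) as.character(w$id), "")
  if (anyDuplicated(way_ids)) stop_input("duplicate way ids")

  for (w in raw_ways) {
    bad <- setdiff(as.character(w$nodes), nodes$id)
    if (length(bad)) {
      stop_input("way %s references unknown node(s): %s",
                 w$id, paste(bad, collapse = ", "))
    }
    if (length(w$nodes) < 2L) stop_input("way %s has fewer than 2 nodes", w$id)
  }

  # pair-level directed segments: every consecutive node pair of every way
  seg <- list()
  for (w in raw_ways) {
    nd <- as.character(w$nodes)
    ow <- isTRUE(w$oneway)
    for (k in seq_len(length(nd) - 1L)) {
      a <- nd[k]; b <- nd[k + 1L]
      len <- sqrt((nodes$x[pos[a]] - nodes$x[pos[b]])^2 +
                    (nodes$y[pos[a]] - nodes$y[pos[b]])^2)
      if (len <= 0) stop_input("way %s has zero-length segment %s-%s", w$id, a, b)
      seg[[length(seg) + 1L]] <- list(way = as.character(w$id), k = k,
                                      a = a, b = b, len = len,
                                      class = as.character(w$class), oneway = ow)
    }
  }

  # protected nodes: crossings (used by >= 2 ways), way endpoints, and
  # interior junction nodes of raw restrictions (so maneuvers stay mappable)
  use <- list()
  for (w in raw_ways) {
    for (n in unique(as.character(w$nodes))) use[[n]] <- c(use[[n]], w$id)
  }
  protected <- names(use)[vapply(use, function(u) length(unique(u)) >= 2L, TRUE)]
  protected <- union(protected, unlist(lapply(raw_ways, function(w) {
    as.character(w$nodes)[c(1L, length(w$nodes))]
  })))
  for (r in raw_restrictions) {
    vn <- as.character(r$via_nodes)
    if (length(vn) >= 3L) protected <- union(protected, vn[-c(1L, length(vn))])
  }

  # chains: start as the raw pair segments, then merge through unprotected
  # degree-2 nodes with identical attribute sets
  chains <- lapply(seg, function(s) {
    list(nodes = c(s$a, s$b), len = s$len, class = s$class, oneway = s$oneway,
         pairs = list(c(s$a, s$b)))
  })
  if (simplify) chains <- smooth_chains(chains, protected)

  streets <- data.frame(
    id = vapply(seq_along(chains), function(i) sprintf("s%04d", i), ""),
    u = vapply(chains, function(ch) ch$nodes[1L], ""),
    v = vapply(chains, function(ch) ch$nodes[length(ch$nodes)], ""),
    length_m = vapply(chains, function(ch) ch$len, 0),
    class = vapply(chains, function(ch) ch$class, ""),
    oneway = vapply(chains, function(ch) ch$oneway, TRUE),
    stringsAsFactors = FALSE)

  keep_nodes <- unique(c(streets$u, streets$v))
  nodes_out <- nodes[nodes$id %in% keep_nodes, , drop = FALSE]
  rownames(nodes_out) <- NULL

  # map a directed raw pair (a>b) to its final directed edge id
  pair_map <- new.env(parent = emptyenv())
  for (i in seq_along(chains)) {
    sid <- streets$id[i]
    ow <- chains[[i]]$oneway
    for (p in chains[[i]]$pairs) {
      assign(paste0(p[1L], ">", p[2L]), paste0(sid, ":f"), envir = pair_map)
      if (!ow) assign(paste0(p[2L], ">", p[1L]), paste0(sid, ":b"), envir = pair_map)
    }
  }

  restrictions <- lapply(raw_restrictions, function(r) {
    map_raw_restriction(r, raw_ways, way_ids, pair_map, streets)
  })

  street_network(nodes_out, streets, restrictions)
}

# Merge chains sharing an unprotected node of street-degree exactly 2,
# provided both chains have identical (class, oneway) and, for one-ways,
# consistent direction through the node.
smooth_chains <- function(chains, protected) {
  repeat {
    ends <- list()
    for (i in seq_along(chains)) {
      ch <- chains[[i]]
      for (n in c(ch$nodes[1L], ch$nodes[length(ch$nodes)])) {
        ends[[n]] <- c(ends[[n]], i)
      }
    }
    merged <- FALSE
    for (n in names(ends)) {
      if (n %in% protected) next
      inc <- unique(ends[[n]])
      if (length(inc) != 2L) next
      if (length(ends[[n]]) != 2L) next  # loop chain touching n twice
      i <- inc[1L]; j <- inc[2L]
      a <- chains[[i]]; b <- chains[[j]]
      if (a$class != b$class || a$oneway != b$oneway) next
      m <- join_chains(a, b, n)
      if (is.null(m)) next
      chains[[i]] <- m
      chains[[j]] <- NULL
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  chains
}

join_chains <- function(a, b, n) {
  al <- length(a$nodes); bl <- length(b$nodes)
  flip <- function(ch) {
    if (ch$oneway) return(NULL)
    list(nodes = rev(ch$nodes), len = ch$len, class = ch$class,
         oneway = ch$oneway, pairs = lapply(rev(ch$pairs), rev))
  }
  # orient so a ends at n and b starts at n
  if (a$nodes[al] != n) a <- if (a$nodes[1L] == n) flip(a) else NULL
  if (is.null(a)) return(NULL)
  if (b$nodes[1L] != n) b <- if (b$nodes[length(b$nodes)] == n) flip(b) else NULL
  if (is.null(b)) return(NULL)
  out_nodes <- c(a$nodes, b$nodes[-1L])
  # reject merges that would create a self-loop street
  if (out_nodes[1L] == out_nodes[length(out_nodes)]) return(NULL)
  list(nodes = out_nodes, len = a$len + b$len, class = a$class,
       oneway = a$oneway, pairs = c(a$pairs, b$pairs))
}

map_raw_restriction <- function(r, raw_ways, way_ids, pair_map, streets) {
  vn <- as.character(r$via_nodes)
  vw <- as.character(r$via_ways)
  if (length(vn) != length(vw) + 1L || length(vw) < 2L) {
    stop_input("restriction needs k+1 via nodes for k >= 2 via ways")
  }
  edge_seq <- character(0)
  for (k in seq_along(vw)) {
    wi <- match(vw[k], way_ids)
    if (is.na(wi)) stop_input("restriction references unknown way %s", vw[k])
    wn <- as.character(raw_ways[[wi]]$nodes)
    ia <- match(vn[k], wn); ib <- match(vn[k + 1L], wn)
    if (is.na(ia) || is.na(ib) || ia == ib) {
      stop_input("restriction via nodes not on way %s", vw[k])
    }
    idxs <- if (ia < ib) ia:(ib - 1L) else ia:(ib + 1L)
    for (t in idxs) {
      a <- wn[t]; b <- wn[t + sign(ib - ia)]
      key <- paste0(a, ">", b)
      if (!exists(key, envir = pair_map, inherits = FALSE)) {
        stop_input("restriction maneuver along way %s violates one-way direction", vw[k])
      }
      edge_seq <- c(edge_seq, get(key, envir = pair_map))
    }
  }
  edge_seq <- edge_seq[c(TRUE, edge_seq[-1L] != edge_seq[-length(edge_seq)])]
  if (length(edge_seq) < 2L) {
    stop_input("restriction collapsed onto a single edge and cannot be mapped")
  }
  eix <- match(edge_seq, streets_edge_ids(streets))
  ed <- streets_edges_tbl(streets)
  via <- ed$u[eix[1L]]
  for (k in seq_along(eix)) via <- c(via, edge_seq[k], ed$v[eix[k]])
  list(via = via)
}

streets_edge_ids <- function(streets) streets_edges_tbl(streets)$id

streets_edges_tbl <- function(streets) directed_edges(streets)

#' Read or write a street network as JSON
#'
#' The schema stores nodes, undirected streets (with a one-way flag) and
#' restrictions as alternating node/edge via sequences; a written network
#' reads back identically.
#'
#' @param net a [street_network()]
#' @param path file path
#' @return `read_network_json` returns a [street_network()];
#'   `write_network_json` returns `path` invisibly.
#' @export
write_network_json <- function(net, path) {
  doc <- list(
    schema = "careops/street_network/1",
    nodes = net$nodes,
    edges = net$streets,
    restrictions = lapply(net$restrictions, function(r) list(via = r$via))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(doc$schema, "careops/street_network/1")) {
    stop_input("unsupported network schema: %s", doc$schema %||% "<missing>")
  }
  restr <- doc$restrictions
  if (is.data.frame(restr)) {
    restr <- lapply(restr$via, function(v) list(via = as.character(v)))
  } else if (is.list(restr)) {
    restr <- lapply(restr, function(r) list(via = as.character(r$via)))
  } else restr <- list()
  street_network(doc$nodes, doc$edges, restr)
}

#' Export street edges as a GeoJSON FeatureCollection
#'
#' Each directed street becomes a `LineString` feature with properties
#' `class` and, if `times` is supplied, `time_s` (the isochrone value:
#' maximum of the endpoint times, so a segment is colored by the later of
#' its ends).
#'
#' @param net a [street_network()]
#' @param times optional named vector of node travel times (seconds), as
#'   returned by [nearest_source_times()].
#' @return GeoJSON list structure (serialize with [write_geojson()]).
#' @export
network_geojson <- function(net, times = NULL) {
  pos <- stats::setNames(seq_len(nrow(net$nodes)), net$nodes$id)
  feats <- lapply(seq_len(nrow(net$streets)), function(i) {
    s <- net$streets[i, ]
    props <- list(id = s$id, class = s$class)
    if (!is.null(times)) {
      tu <- unname(times[s$u]); tv <- unname(times[s$v])
      props$time_s <- if (is.na(tu) || is.na(tv)) NA else max(tu, tv)
    }
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(
                           c(net$nodes$x[pos[s$u]], net$nodes$y[pos[s$u]]),
                           c(net$nodes$x[pos[s$v]], net$nodes$y[pos[s$v]]))),
         properties = props)
  })
  list(type = "FeatureCollection", features = feats)
}

#' Write a GeoJSON document to disk
#' @param doc GeoJSON list structure
#' @param path file path
#' @export
write_geojson <- function(doc, path) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
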