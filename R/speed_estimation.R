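#' Trip records for speed-profile estimation
#'
#' @param origin,dest node ids (origin != dest, element-wise)
#' @param duration_s observed driving times in seconds (> 0)
#' @return data.frame of class `trip_records`
#' @export
trip_records <- function(origin, dest, duration_s) {
  origin <- as.character(origin); dest <- as.character(dest)
  duration_s <- as.numeric(duration_s)
  if (any(origin == dest)) stop_input("trip origin must differ from destination")
  if (any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop_input("trip durations must be positive")
  }
  structure(data.frame(origin = origin, dest = dest, duration_s = duration_s,
                       stringsAsFactors = FALSE),
            class = c("trip_records", "data.frame"))
}

# Per-class driven distances for each trip under the current profile.
# Routes are grouped by origin: one full single-source run per distinct origin.
trip_class_distances <- function(net, profile, trips, idx = net_index(net)) {
  classes <- sort(unique(net$edges$class))
  w <- indexed_times(net, profile, idx)
  X <- matrix(0, nrow(trips), length(classes), dimnames = list(NULL, classes))
  reach <- rep(TRUE, nrow(trips))
  for (o in unique(trips$origin)) {
    rows <- which(trips$origin == o)
    res <- dijkstra_nodes(idx, w, unname(idx$pos[o]))
    for (i in rows) {
      di <- unname(idx$pos[trips$dest[i]])
      if (!is.finite(res$dist[di])) { reach[i] <- FALSE; next }
      cur <- di
      while (!is.na(res$pred[cur])) {
        k <- res$pred[cur]
        X[i, idx$class[k]] <- X[i, idx$class[k]] + idx$len[k]
        cur <- idx$ui[k]
      }
    }
  }
  list(X = X, reach = reach)
}

#' Estimate a class-speed profile from observed trips
#'
#' Iterates the estimation loop used for blue-light driving profiles: route
#' every trip under the current profile, extract the driven distance on each
#' street class, regress the observed duration on the class distances with a
#' robust loss (Huber M-estimation, the coefficients being inverse speeds,
#' intercept fixed at zero), and update the profile. Stops when the maximum
#' relative speed change drops below `tol` or after `max_iter` rounds.
#' Returned speeds are clamped to at least 1 km/h. Classes never driven by
#' any routed trip keep their current speed (with a warning).
#'
#' @param net a [street_network()]
#' @param initial a [speed_profile()] used for the first routing round
#' @param trips a [trip_records()] table
#' @param tol relative-change convergence tolerance (default `1e-3`)
#' @param max_iter iteration cap (default 20)
#' @param huber_k Huber tuning constant (default 1.345)
#' @return An object of class `speed_fit`: the fitted [speed_profile()]
#'   plus `converged`, `iterations`, and per-iteration maximum relative
#'   change. `coef()` returns the speeds; `print()` summarizes.
#' @export
estimate_speed_profile <- function(net, initial, trips, tol = 1e-3,
                                   max_iter = 20L, huber_k = 1.345) {
  stopifnot(inherits(initial, "speed_profile"))
  idx <- net_index(net)
  classes <- sort(unique(net$edges$class))
  miss <- setdiff(classes, names(initial$speed))
  if (length(miss)) stop_config("initial profile lacks class(es): %s",
                                paste(miss, collapse = ", "))
  cur <- initial$speed[classes]
  history <- numeric(0)
  converged <- FALSE
  warned <- character(0)
  for (it in seq_len(max_iter)) {
    prof <- speed_profile(cur, initial$vehicle_type)
    td <- trip_class_distances(net, prof, trips, idx)
    ok <- td$reach
    if (!any(ok)) stop_input("no trip is routable under the current profile")
    X <- td$X[ok, , drop = FALSE]
    y <- trips$duration_s[ok]
    driven <- colSums(X) > 0
    skip <- classes[!driven]
    if (length(skip) && !length(warned)) {
      warning(sprintf("class(es) never driven, keeping initial speed: %s",
                      paste(skip, collapse = ", ")))
      warned <- skip
    }
    newsp <- cur
    if (any(driven)) {
      Xd <- X[, driven, drop = FALSE]
      # matrix-interface rlm fits without an intercept column
      fit <- suppressWarnings(
        MASS::rlm(Xd, y, psi = MASS::psi.huber, k = huber_k, maxit = 100))
      b <- stats::coef(fit)  # seconds per meter, per class
      sp <- 3.6 / b
      sp[!is.finite(sp) | sp < 1] <- 1
      newsp[colnames(Xd)] <- sp
    }
    delta <- max(abs(newsp - cur) / cur)
    history <- c(history, delta)
    cur <- newsp
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(profile = speed_profile(cur, initial$vehicle_type),
                 converged = converged, iterations = length(history),
                 rel_change = history, skipped_classes = warned),
            class = "speed_fit")
}

#' @export
coef.speed_fit <- function(object, ...) object$profile$speed

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf("<speed_fit> %s after %d iteration(s)\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(x$profile)
  invisible(x)
}
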