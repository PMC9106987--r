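test_that("coverage checking by max-flow matches direct reasoning", {
  inc <- matrix(TRUE, 1, 1)
  inst <- cover_instance("l1", "r1", c(r1 = 0), inc, q = 2)
  res <- check_coverage(inst, c(l1 = 0))
  expect_true(res$feasible)

  inst2 <- cover_instance("l1", "r1", c(r1 = 3), inc, q = 2)
  res2 <- check_coverage(inst2, c(l1 = 1))
  expect_false(res2$feasible)
  expect_identical(res2$uncovered, "r1")
  expect_true(check_coverage(inst2, c(l1 = 2))$feasible)
})

test_that("flow verdicts equal exhaustive client-assignment search on 5x5", {
  set.seed(71)
  # brute force: assign each client unit to an incident location, respect q*x
  assign_search <- function(inst, x, v) {
    units <- rep(seq_along(inst$regions), v)
    caps <- inst$q * x
    rec <- function(i, used) {
      if (i > length(units)) return(TRUE)
      r <- units[i]
      for (l in which(inst$incidence[, r])) {
        if (used[l] < caps[l]) {
          used[l] <- used[l] + 1
          if (rec(i + 1, used)) return(TRUE)
          used[l] <- used[l] - 1
        }
      }
      FALSE
    }
    rec(1, rep(0, length(inst$locations)))
  }
  for (trial in 1:20) {
    inst <- random_cover_instance()
    x <- stats::setNames(sample(0:2, length(inst$locations), replace = TRUE),
                         inst$locations)
    flow <- check_coverage(inst, x)$feasible
    brute <- assign_search(inst, x, inst$clients)
    expect_identical(flow, brute, info = paste("trial", trial))
  }
})

test_that("single-region cost is the ceiling bound and ties go to lower ids", {
  inc <- matrix(TRUE, 1, 1)
  inst <- cover_instance("l1", "r1", c(r1 = 7), inc, q = 3)
  expect_equal(solve_qmsmc(inst)$cost, ceiling(7 / 3))

  inst2 <- cover_instance(c("l1", "l2"), "r1", c(r1 = 2),
                          matrix(TRUE, 2, 1), q = 2)
  a2 <- solve_qmsmc(inst2)
  expect_equal(a2$cost, 1)
  expect_equal(unname(a2$suppliers["l1"]), 1L)
})

test_that("nominal and robust optima equal exhaustive enumeration", {
  set.seed(72)
  for (trial in 1:30) {
    inst <- random_cover_instance()
    a <- solve_qmsmc(inst)
    expect_equal(a$cost, oracle_qmsmc(inst, list(inst$clients)),
                 info = paste("nominal", trial))
    expect_true(check_coverage(inst, a$suppliers)$feasible)

    nr <- length(inst$regions)
    sc2 <- stats::setNames(sample(0:3, nr, replace = TRUE), inst$regions)
    sc2[colSums(inst$incidence) == 0] <- 0L
    U <- list(inst$clients, sc2)
    ar <- solve_robust_qmsmc(inst, U)
    expect_equal(ar$cost, oracle_qmsmc(inst, U),
                 info = paste("robust", trial))
    # robust cost dominates each nominal scenario cost
    expect_gte(ar$cost, a$cost)
  }
})

test_that("degenerate uncertainty sets reduce to the nominal problem", {
  set.seed(73)
  inst <- random_cover_instance()
  expect_equal(solve_robust_qmsmc(inst, list(inst$clients))$cost,
               solve_qmsmc(inst)$cost)
  zero <- stats::setNames(rep(0L, length(inst$regions)), inst$regions)
  expect_equal(solve_robust_qmsmc(inst, list(zero))$cost, 0L)
  expect_error(solve_robust_qmsmc(inst, list()),
               class = "careops_input_error")
})

test_that("orphan regions with demand are reported as infeasible", {
  inc <- matrix(c(TRUE, FALSE), 1, 2)
  inst <- cover_instance("l1", c("r1", "r2"), c(r1 = 1, r2 = 2), inc, q = 1)
  expect_error(solve_qmsmc(inst), "r2", class = "careops_infeasible")
})

test_that("optimal cost is monotone in q and in client counts", {
  set.seed(74)
  for (trial in 1:10) {
    inst <- random_cover_instance()
    c1 <- solve_qmsmc(inst)$cost
    instq <- cover_instance(inst$locations, inst$regions, inst$clients,
                            inst$incidence, inst$q + 1)
    expect_lte(solve_qmsmc(instq)$cost, c1)
    cl2 <- inst$clients
    grow <- inst$regions[colSums(inst$incidence) > 0][1]
    if (!is.na(grow)) {
      cl2[grow] <- cl2[grow] + 1L
      inst2 <- cover_instance(inst$locations, inst$regions, cl2,
                              inst$incidence, inst$q)
      expect_gte(solve_qmsmc(inst2)$cost, c1)
    }
  }
})

test_that("a lone emergency is met in exactly the free-flow travel time", {
  region <- small_region(7)
  prof <- speed_profile(c(major = 100, minor = 50), "blue_light")
  station <- region$candidate_sites[1]
  log <- sample_emergencies(region, 5, 2, seed = 2)[1, ]
  log$time_s <- 500
  ev <- simulate_ems(region, station, stats::setNames(2L, station), log, prof)
  expect_equal(ev$response_s,
               shortest_time(region$network, prof, station, log$node)$duration,
               tolerance = 1e-9)
  expect_equal(ev$queue_wait_s, 0)
})

test_that("queueing follows hand-computed event algebra on a line graph", {
  # stations and scenes on a 3-node line a-b-c, 1000 m edges, 36 km/h = 100 s
  net <- line_net(3, len = 1000, class = "minor")
  prof <- speed_profile(c(minor = 36))
  region <- structure(list(
    network = net,
    municipalities = data.frame(id = "m1", center = "a", population = 1L,
                                county = "c1", stringsAsFactors = FALSE),
    node_municipality = stats::setNames(rep("m1", 3), c("a", "b", "c")),
    candidate_sites = "a", pharmacies = data.frame(), hospitals = "a",
    depots = "a", seed = 1L, config = region_config()),
    class = "synthetic_region")
  log <- data.frame(time_s = c(0, 0), node = c("b", "c"),
                    onscene_s = c(300, 300), transport = FALSE,
                    hospital = NA_character_, municipality = "m1",
                    stringsAsFactors = FALSE)
  ev <- simulate_ems(region, "a", stats::setNames(1L, "a"), log, prof)
  # first: dispatched at 0, arrives b at 100, serves until 400
  expect_equal(ev$response_s[1], 100)
  # second queues until 400, doctor is at b, travels 100 s to c
  expect_equal(ev$dispatch_s[2], 400)
  expect_equal(ev$arrival_s[2], 500)
  expect_equal(ev$queue_wait_s[2], 400)
})

test_that("simulation conserves emergencies and respects physics", {
  region <- small_region(7)
  prof <- speed_profile(c(major = 100, minor = 50), "blue_light")
  stations <- region$candidate_sites[1:2]
  log <- sample_emergencies(region, 15, 3, seed = 9)
  alloc <- stats::setNames(c(1L, 1L), stations)
  ev <- simulate_ems(region, stations, alloc, log, prof)
  expect_equal(nrow(ev), nrow(log))            # served exactly once
  expect_true(all(ev$arrival_s >= ev$dispatch_s - 1e-9))
  expect_true(all(ev$dispatch_s >= ev$alarm_s - 1e-9))
  # no doctor serves two emergencies simultaneously
  for (d in unique(ev$doctor)) {
    rows <- ev[ev$doctor == d, ]
    rows <- rows[order(rows$dispatch_s), ]
    if (nrow(rows) > 1) {
      expect_true(all(diff(rows$dispatch_s) >= 0))
      busy_end <- rows$arrival_s[-nrow(rows)] +
        log$onscene_s[match(rows$alarm_s[-nrow(rows)], log$time_s)]
      expect_true(all(rows$dispatch_s[-1] >= busy_end - 1e-6))
    }
  }
  # a component-wise larger allocation never worsens any queueing delay
  ev2 <- simulate_ems(region, stations, alloc + 1L, log, prof)
  expect_true(all(ev2$queue_wait_s <= ev$queue_wait_s + 1e-9))
  expect_error(simulate_ems(region, stations, alloc * 0L, log, prof),
               class = "careops_input_error")
  expect_equal(nrow(simulate_ems(region, stations, alloc, log[0, ], prof)), 0)
})

test_that("summary medians equal direct quantiles of the event rows", {
  region <- small_region(7)
  prof <- speed_profile(c(major = 100, minor = 50), "blue_light")
  stations <- region$candidate_sites[1:2]
  log <- sample_emergencies(region, 40, 5, seed = 10)
  ev <- simulate_ems(region, stations,
                     stats::setNames(c(2L, 2L), stations), log, prof)
  summ <- response_time_summary(ev, region)
  for (i in seq_len(nrow(summ$municipality))) {
    m <- summ$municipality$unit[i]
    x <- ev$response_s[ev$municipality == m]
    if (length(x)) {
      expect_equal(summ$municipality$median_s[i], stats::median(x))
    } else {
      expect_true(is.na(summ$municipality$median_s[i]))
    }
  }
  expect_equal(sum(summ$histogram$count), nrow(ev))
  # single event: median equals its response
  one <- ev[1, ]
  s1 <- response_time_summary(one, region)
  m1 <- s1$municipality[s1$municipality$unit == one$municipality, ]
  expect_equal(m1$median_s, one$response_s)
})

test_that("travel-time incidence thresholds build the cover instance", {
  region <- small_region(7)
  prof <- speed_profile(c(major = 100, minor = 50), "blue_light")
  stations <- region$candidate_sites[1:3]
  cl <- stats::setNames(rep(1L, nrow(region$municipalities)),
                        region$municipalities$id)
  inst <- cover_instance_from_region(region, stations, prof,
                                     threshold_s = 600, clients = cl, q = 2)
  for (s in stations) {
    tts <- nearest_source_times(region$network, prof, s)
    expect_equal(unname(inst$incidence[s, ]),
                 unname(tts[region$municipalities$center] <= 600))
  }
})
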