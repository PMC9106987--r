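# All cases run on a 5-node line a-b-c-d-e (1000 m edges, 60 km/h): every
# leg is a multiple of 60 s, so expected times are hand-computable.
tt_line <- local({
  net <- line_net(5, len = 1000, class = "minor")
  travel_time_fun(net, speed_profile(c(minor = 60)))
})

test_that("timing contracts: exact starts, forced delays, depot returns", {
  veh <- transport_vehicles(data.frame(id = "v1", depot = "a",
                                       shift_start_s = 0,
                                       shift_end_s = 86400, fleet = "clean"))
  req <- transport_requests(data.frame(id = "r1", pickup = "b",
                                       dropoff = "c", t_req_s = 3600))
  s <- solve_vrpgtw(req, veh, tt_line)
  expect_equal(s$max_delay_s, 0)
  expect_equal(s$stops$pickup_start_s, 3600)  # waits, never early

  veh2 <- transport_vehicles(data.frame(id = "v1", depot = "a",
                                        shift_start_s = 1000,
                                        shift_end_s = 86400,
                                        fleet = "clean"))
  req2 <- transport_requests(data.frame(id = "r1", pickup = "c",
                                        dropoff = "d", t_req_s = 500))
  s2 <- solve_vrpgtw(req2, veh2, tt_line)
  expect_equal(s2$max_delay_s, 1000 + 120 - 500)

  # a shift too short for the return leg is infeasible
  veh3 <- transport_vehicles(data.frame(id = "v1", depot = "a",
                                        shift_start_s = 0,
                                        shift_end_s = 700, fleet = "clean"))
  expect_error(solve_vrpgtw(req, veh3, tt_line),
               class = "careops_infeasible")
})

test_that("lexicographic optimum equals assignment x permutation brute force", {
  set.seed(91)
  veh <- two_vehicles()
  for (trial in 1:20) {
    req <- random_vrp_case()
    got <- tryCatch(solve_vrpgtw(req, veh, tt_line),
                    careops_infeasible = function(e) NULL)
    want <- oracle_vrp(req, veh, tt_line)
    gv <- if (is.null(got)) c(Inf, Inf) else c(got$max_delay_s,
                                               got$total_delay_s)
    expect_equal(gv, want, tolerance = 1e-6, info = paste("trial", trial))
  }
})

test_that("adding a request never decreases the optimal maximum delay", {
  set.seed(92)
  veh <- two_vehicles()
  for (trial in 1:8) {
    req <- random_vrp_case()
    base <- solve_vrpgtw(req, veh, tt_line)
    extra <- random_vrp_case()[1, ]
    extra$id <- "zz"
    grown <- tryCatch(
      solve_vrpgtw(transport_requests(rbind(req, extra)), veh, tt_line),
      careops_infeasible = function(e) NULL)
    if (!is.null(grown)) expect_gte(grown$max_delay_s,
                                    base$max_delay_s - 1e-9)
  }
})

test_that("fleet separation bars infectious patients from clean vehicles", {
  veh <- transport_vehicles(data.frame(
    id = c("v1", "v2"), depot = "a", shift_start_s = 0,
    shift_end_s = 86400, fleet = c("clean", "covid")))
  req <- transport_requests(data.frame(
    id = c("r1", "r2"), pickup = c("b", "c"), dropoff = c("c", "d"),
    t_req_s = c(3600, 3600), covid = c(TRUE, FALSE)))
  s <- solve_vrpgtw(req, veh, tt_line)
  expect_equal(s$stops$vehicle[s$stops$request == "r1"], "v2")
  expect_equal(s$stops$vehicle[s$stops$request == "r2"], "v1")
  # infectious-only demand with no covid-capable vehicle is reported
  vclean <- veh[veh$fleet == "clean", ]
  expect_error(solve_vrpgtw(req[req$covid, ],
                            transport_vehicles(vclean), tt_line),
               class = "careops_infeasible")
})

test_that("a larger covid service add-on never reduces the total delay", {
  set.seed(93)
  for (trial in 1:6) {
    req <- random_vrp_case()
    req$covid[1] <- TRUE
    v1 <- transport_vehicles(data.frame(
      id = c("v1", "v2"), depot = "a", shift_start_s = 0,
      shift_end_s = 86400, fleet = c("clean", "floater"),
      covid_addon_s = 300))
    v2 <- v1; v2$covid_addon_s <- 1200; v2$changeover_s <- 1200
    s1 <- solve_vrpgtw(req, v1, tt_line)
    s2 <- solve_vrpgtw(req, transport_vehicles(v2), tt_line)
    expect_gte(s2$total_delay_s, s1$total_delay_s - 1e-9)
  }
})

test_that("re-optimization is idempotent and never rewrites executed stops", {
  veh <- two_vehicles()
  req <- transport_requests(data.frame(
    id = paste0("r", 1:3), pickup = c("b", "d", "c"),
    dropoff = c("c", "e", "a"), t_req_s = c(3600, 7200, 10800)))
  s <- solve_vrpgtw(req, veh, tt_line)
  st <- day_state(s, req, now = 5000)
  none <- transport_requests(data.frame(id = character(0),
                                        pickup = character(0),
                                        dropoff = character(0),
                                        t_req_s = numeric(0)))
  s2 <- reoptimize(st, req, none, veh, tt_line)
  expect_equal(s2$max_delay_s, s$max_delay_s)
  expect_equal(s2$total_delay_s, s$total_delay_s)
  ex_before <- s$stops[s$stops$pickup_start_s <= 5000, ]
  ex_after <- s2$stops[s2$stops$executed, ]
  o1 <- ex_before[order(ex_before$request),
                  c("vehicle", "request", "pickup_start_s", "dropoff_end_s")]
  o2 <- ex_after[order(ex_after$request),
                 c("vehicle", "request", "pickup_start_s", "dropoff_end_s")]
  expect_equal(o1, o2, ignore_attr = TRUE)

  # an added ad-hoc request is placed optimally among prefix-respecting
  # schedules (constrained brute force)
  set.seed(94)
  for (trial in 1:6) {
    adhoc <- transport_requests(data.frame(
      id = "ax", pickup = sample(letters[2:5], 1), dropoff = "a",
      t_req_s = 12000, release_s = 5000))
    s3 <- reoptimize(st, req, adhoc, veh, tt_line)
    open <- transport_requests(rbind(
      req[req$id %in% st$outstanding, ],
      adhoc[, names(req)]))
    want <- oracle_vrp(open, veh, tt_line, anchors = st$anchors)
    open_ids <- c(st$outstanding, "ax")
    got_delays <- s3$stops$delay_s[s3$stops$request %in% open_ids]
    expect_equal(max(got_delays), want[1], tolerance = 1e-6)
    expect_equal(sum(got_delays), want[2], tolerance = 1e-6)
  }
})

test_that("dialysis trips spawn replaceable dummy returns", {
  req <- transport_requests(data.frame(
    id = c("d1", "r2"), pickup = c("a", "b"), dropoff = c("e", "c"),
    t_req_s = c(8 * 3600, 9 * 3600), dialysis = c(TRUE, FALSE)))
  dum <- make_dummy_returns(req, stay_s = 240 * 60)
  expect_equal(nrow(dum), 1)
  expect_equal(dum$id, "d1_ret")
  expect_equal(dum$pickup, "e")
  expect_equal(dum$dropoff, "a")
  expect_equal(dum$t_req_s, 8 * 3600 + 240 * 60)
  expect_true(dum$replaceable)
  expect_equal(nrow(make_dummy_returns(req[!req$dialysis, ])), 0)
})

test_that("day replay is deterministic and respects fleet separation", {
  region <- small_region(7)
  prof <- speed_profile(c(major = 80, minor = 45))
  veh <- transport_vehicles(data.frame(
    id = c("v1", "v2"), depot = region$depots[1],
    shift_start_s = 5 * 3600, shift_end_s = 22 * 3600,
    fleet = c("clean", "floater")))
  day <- sample_transport_day(region, n_plannable = 4, adhoc_rate_per_h = 0,
                              covid_prob = 0.5, seed = 4)
  s1 <- simulate_transport_day(day, veh, region$network, prof,
                               policy = "reoptimize")
  # no ad-hoc arrivals: the realized schedule is the initial solve
  init <- solve_vrpgtw(transport_requests(day$plannable), veh,
                       travel_time_fun(region$network, prof))
  expect_equal(s1$max_delay_s, init$max_delay_s)
  expect_equal(sort(s1$stops$pickup_start_s), sort(init$stops$pickup_start_s))
  # infectious patients never ride a clean vehicle, under either policy
  for (pol in c("reoptimize", "nearest_available")) {
    s <- simulate_transport_day(day, veh, region$network, prof, policy = pol)
    cov_stops <- s$stops[s$stops$covid, ]
    fleets <- veh$fleet[match(cov_stops$vehicle, veh$id)]
    expect_true(all(fleets %in% c("covid", "floater")))
  }
})

test_that("metrics recount the schedule and handle the empty case", {
  veh <- two_vehicles()
  req <- transport_requests(data.frame(
    id = paste0("r", 1:3), pickup = c("b", "c", "d"),
    dropoff = c("c", "d", "e"),
    t_req_s = c(3600, 3600, 3600)))
  s <- solve_vrpgtw(req, veh, tt_line)
  m <- schedule_metrics(s, tt_line, req)
  expect_equal(m$max_delay_s, max(s$stops$delay_s))
  expect_equal(m$total_delay_s, sum(s$stops$delay_s))
  expect_equal(m$n_stops, 3)
  expect_equal(nrow(m$gantt), 3)
  expect_true(all(m$busy_fraction >= 0 & m$busy_fraction <= 1))

  empty <- solve_vrpgtw(transport_requests(data.frame(
    id = character(0), pickup = character(0), dropoff = character(0),
    t_req_s = numeric(0))), veh, tt_line)
  m0 <- schedule_metrics(empty)
  expect_equal(m0$max_delay_s, 0)
  expect_equal(m0$total_delay_s, 0)
  expect_equal(m0$n_stops, 0L)

  # hand-set delays
  fake <- empty
  fake$stops <- data.frame(vehicle = "v1", request = paste0("r", 1:3),
                           arrive_s = 0, pickup_start_s = c(0, 420, 720),
                           dropoff_end_s = c(100, 800, 1500),
                           delay_s = c(0, 420, 720), covid = FALSE,
                           executed = TRUE)
  mf <- schedule_metrics(fake)
  expect_equal(mf$max_delay_s, 720)
  expect_equal(mf$total_delay_s, 1140)
})
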