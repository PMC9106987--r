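test_that("balanced greedy loads match the forced and balanced cases", {
  i1 <- pharmacy_instance(paste0("p", 1:4), "m1",
                          list(m1 = paste0("p", 1:4)), list(), 8)
  expect_equal(unname(sort(unclass(idealized_fair_plan(i1)))), rep(2L, 4))
  i2 <- pharmacy_instance("p1", "m1", list(m1 = "p1"), list(), 365)
  expect_equal(unname(unclass(idealized_fair_plan(i2))), 365L)
  i3 <- pharmacy_instance("p1", c("m1", "m2"),
                          list(m1 = "p1", m2 = character(0)), list(), 5)
  expect_error(idealized_fair_plan(i3), "m2", class = "careops_infeasible")
})

test_that("greedy loads are lexicographically minimal (exhaustive check)", {
  set.seed(81)
  for (trial in 1:25) {
    inst <- random_pharmacy_instance(max_bits = 14, gamma_max = 0,
                                     with_conflict = FALSE)
    loads <- tryCatch(idealized_fair_plan(inst),
                      careops_infeasible = function(e) NULL)
    o <- oracle_duty(inst)
    if (is.null(loads)) {
      expect_null(o$fair, info = paste("trial", trial))
    } else {
      got <- sort(unclass(loads), decreasing = TRUE)
      expect_equal(unname(got), unname(o$fair), info = paste("trial", trial))
    }
  }
})

test_that("duty-plan optimum equals exhaustive search over all plans", {
  set.seed(82)
  for (trial in 1:25) {
    inst <- random_pharmacy_instance(max_bits = 16)
    o <- oracle_duty(inst)$opt
    got <- tryCatch(solve_duty_plan(inst)$objective,
                    careops_infeasible = function(e) Inf)
    expect_equal(as.numeric(got), as.numeric(o), info = paste("trial", trial))
    if (is.finite(got)) {
      expect_true(validate_plan(inst, solve_duty_plan(inst))$feasible)
    }
  }
})

test_that("counting and surplus-coverage corner cases are exact", {
  i1 <- pharmacy_instance(paste0("p", 1:3), "m1",
                          list(m1 = paste0("p", 1:3)), list(), 6, rest = 1)
  s1 <- solve_duty_plan(i1)
  expect_equal(s1$objective, 6L)
  for (p in rownames(s1$duty)) {
    days <- which(s1$duty[p, ] > 0)
    if (length(days) > 1) expect_true(all(diff(days) > 1))
  }
  # gamma = 1 with exactly two in-range pharmacies forces both on every day
  i2 <- pharmacy_instance(c("p1", "p2"), "m1", list(m1 = c("p1", "p2")),
                          list(), 4, c_cover = 1, gamma = 1)
  s2 <- solve_duty_plan(i2)
  expect_true(all(s2$duty == 1L))
})

test_that("quarantine surplus survives deleting any gamma-subset", {
  set.seed(83)
  for (gamma in 1:2) {
    for (trial in 1:4) {
      P <- 4 + gamma
      Ps <- paste0("p", 1:P)
      inst <- pharmacy_instance(Ps, c("m1", "m2"),
                                list(m1 = sample(Ps, P - 1), m2 = Ps),
                                list(), horizon = 3,
                                c_cover = 1, gamma = gamma, rest = 0)
      plan <- solve_duty_plan(inst)
      subsets <- utils::combn(Ps, gamma, simplify = FALSE)
      for (del in subsets) {
        duty <- plan$duty
        duty[del, ] <- 0L
        for (m in inst$municipalities) {
          cm <- inst$cov[[m]]
          cnt <- colSums(duty[cm, , drop = FALSE] > 0)
          expect_true(all(cnt >= inst$c_cover),
                      info = paste("gamma", gamma, "del",
                                   paste(del, collapse = ",")))
        }
      }
    }
  }
})

test_that("optimum is monotone in the tightening parameters", {
  set.seed(84)
  base <- pharmacy_instance(paste0("p", 1:4), c("m1", "m2"),
                            list(m1 = paste0("p", 1:3),
                                 m2 = paste0("p", 2:4)),
                            list(c("p1", "p2")), horizon = 4,
                            c_cover = 1, gamma = 0, rest = 0, s_min = 0,
                            pharmacy_municipality = stats::setNames(
                              c("m1", "m1", "m2", "m2"), paste0("p", 1:4)))
  obj <- function(inst) tryCatch(solve_duty_plan(inst)$objective,
                                 careops_infeasible = function(e) Inf)
  o0 <- obj(base)
  tweak <- function(field, value) {
    i <- base; i[[field]] <- value; i
  }
  expect_gte(obj(tweak("gamma", 1L)), o0)
  expect_gte(obj(tweak("s_min", 1L)), o0)
  expect_gte(obj(tweak("rest", 1L)), o0)
  more_conf <- base
  more_conf$conflicts <- list(c("p1", "p2"), c("p3", "p4"))
  expect_gte(obj(more_conf), o0)
  tighter_c <- base; tighter_c$c_cover <- 2L
  expect_gte(obj(tighter_c), o0)
})

test_that("aggregation groups equivalent pharmacies and stays exact", {
  # co-located pair: one representative of multiplicity two
  inst <- pharmacy_instance(c("a", "b"), "m1", list(m1 = c("a", "b")),
                            list(), 4,
                            pharmacy_municipality = c(a = "m1", b = "m1"))
  agg <- aggregate_pharmacies(inst)
  expect_length(agg$classes, 1)
  expect_equal(unname(agg$instance$mult), 2L)
  # pairwise distinct coverage: identity mapping
  inst2 <- pharmacy_instance(c("a", "b"), c("m1", "m2"),
                             list(m1 = "a", m2 = "b"), list(), 4,
                             pharmacy_municipality = c(a = "m1", b = "m2"))
  expect_length(aggregate_pharmacies(inst2)$classes, 2)

  # paired solves on random instances: aggregated == direct, and the
  # disaggregated plan validates on the original instance
  set.seed(85)
  for (trial in 1:12) {
    inst <- random_pharmacy_instance(max_bits = 16)
    direct <- tryCatch(solve_duty_plan(inst)$objective,
                       careops_infeasible = function(e) Inf)
    agg <- aggregate_pharmacies(inst)
    via <- tryCatch({
      ap <- solve_duty_plan(agg$instance)
      dp <- disaggregate_plan(agg, ap, inst)
      if (is.finite(direct)) {
        expect_true(validate_plan(inst, dp)$feasible,
                    info = paste("trial", trial))
      }
      ap$objective
    }, careops_infeasible = function(e) Inf)
    expect_equal(as.numeric(via), as.numeric(direct),
                 info = paste("trial", trial))
  }
})

test_that("rolling horizon degenerates to the exact solve and stays feasible", {
  inst <- pharmacy_instance(paste0("p", 1:3), "m1",
                            list(m1 = paste0("p", 1:3)), list(), 6, rest = 1)
  exact <- solve_duty_plan(inst)
  rh <- rolling_horizon_solve(inst, W = 6, O = 0)
  expect_equal(rh$objective, exact$objective)
  rh2 <- rolling_horizon_solve(inst, W = 3, O = 1)
  expect_true(validate_plan(inst, rh2)$feasible)
  expect_gte(rh2$objective, exact$objective)
  expect_error(rolling_horizon_solve(inst, W = 3, O = 3),
               class = "careops_input_error")
})

test_that("fairness brackets with zero slack equalize within a municipality", {
  inst <- pharmacy_instance(paste0("p", 1:3), "m1",
                            list(m1 = paste0("p", 1:3)), list(),
                            horizon = 6, delta = 0,
                            pharmacy_municipality = stats::setNames(
                              rep("m1", 3), paste0("p", 1:3)))
  loads <- idealized_fair_plan(inst)
  plan <- solve_duty_plan(inst, fairness = loads)
  tot <- plan$totals
  expect_lte(max(tot) - min(tot), 1)
  expect_true(validate_plan(inst, plan, fairness = loads)$feasible)
})

test_that("validation recounts violations independently of the solver", {
  inst <- pharmacy_instance(c("p1", "p2"), "m1", list(m1 = c("p1", "p2")),
                            list(c("p1", "p2")), 3, rest = 1)
  # hand-built plan: both vicinal pharmacies open on day 2
  duty <- matrix(0L, 2, 3, dimnames = list(c("p1", "p2"), NULL))
  duty["p1", ] <- c(1L, 1L, 0L)   # also a rest violation (days 1,2)
  duty["p2", 2] <- 1L
  v <- validate_plan(inst, duty)
  expect_equal(nrow(v$dispersion), 1)
  expect_equal(nrow(v$rest), 1)
  expect_false(v$feasible)

  # random plans: counts equal a naive double-loop recount
  set.seed(86)
  for (trial in 1:10) {
    inst <- random_pharmacy_instance(max_bits = 16)
    P <- length(inst$pharmacies); T <- inst$horizon
    duty <- matrix(rbinom(P * T, 1, 0.5), P, T,
                   dimnames = list(inst$pharmacies, NULL))
    v <- validate_plan(inst, duty)
    n_cov <- 0
    for (m in inst$municipalities) for (d in seq_len(T)) {
      cm <- inst$cov[[m]]
      have <- if (length(cm)) sum(duty[cm, d]) else 0
      if (have < inst$c_cover + inst$gamma) n_cov <- n_cov + 1
    }
    n_disp <- 0
    for (pr in inst$conflicts) for (d in seq_len(T)) {
      if (duty[pr[1], d] == 1 && duty[pr[2], d] == 1) n_disp <- n_disp + 1
    }
    n_rest <- 0
    if (inst$rest > 0) for (p in inst$pharmacies) {
      days <- which(duty[p, ] == 1)
      if (length(days) > 1) n_rest <- n_rest + sum(diff(days) <= inst$rest)
    }
    expect_equal(if (is.null(v$coverage)) 0 else nrow(v$coverage), n_cov)
    expect_equal(if (is.null(v$dispersion)) 0 else nrow(v$dispersion), n_disp)
    expect_equal(if (is.null(v$rest)) 0 else nrow(v$rest), n_rest)
  }
})

test_that("annual reachability summarizes daily nearest-open distances", {
  dist_m <- matrix(c(0, 2500), 1, 2, dimnames = list("m1", c("p1", "p2")))
  inst <- pharmacy_instance(c("p1", "p2"), "m1", list(m1 = c("p1", "p2")),
                            list(), 4, dist_m = dist_m)
  # pharmacy at the center open daily -> median 0
  duty <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 2, 4, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), NULL))
  r <- reachability_stats(inst, duty)
  expect_equal(r$median_m, 0)

  # alternating near (1 km) / far (3 km) over an even horizon -> median 2 km
  dist2 <- matrix(c(1000, 3000), 1, 2, dimnames = list("m1", c("p1", "p2")))
  inst2 <- pharmacy_instance(c("p1", "p2"), "m1", list(m1 = c("p1", "p2")),
                             list(), 4, dist_m = dist2)
  duty2 <- matrix(c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L), 2, 4, byrow = TRUE,
                  dimnames = list(c("p1", "p2"), NULL))
  r2 <- reachability_stats(inst2, duty2)
  expect_equal(r2$median_m, 2000)
  expect_equal(r2$min_m, 1000)
  expect_equal(r2$max_m, 3000)

  # random plans match a day-by-day recount; empty days are flagged infinite
  set.seed(87)
  duty3 <- matrix(rbinom(8, 1, 0.4), 2, 4,
                  dimnames = list(c("p1", "p2"), NULL))
  r3 <- reachability_stats(inst2, duty3)
  daily <- vapply(1:4, function(d) {
    open <- c("p1", "p2")[duty3[, d] > 0]
    if (!length(open)) Inf else min(dist2[1, open])
  }, 0)
  expect_equal(r3$median_m, stats::median(daily))
  expect_equal(r3$days_unreachable, sum(!is.finite(daily)))
})
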