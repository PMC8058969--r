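expect_valid_matrix <- function(P) {
  expect_equal(rowSums(P), setNames(rep(1, 7), markov_states()),
               tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_equal(unname(P["DEATH", ]), c(0, 0, 0, 0, 0, 0, 1))
}

test_that("transition matrix encodes the allowed structure", {
  # all probabilities zero: every reportable state holds its mass (the
  # one-cycle tunnels still drain into their post-complication twins,
  # which report as the same state and are unoccupied at zero
  # complication probability anyway)
  zeros <- c(progression = 0, death = 0, complication = 0)
  P0 <- build_transition_matrix(zeros)
  keep <- setdiff(markov_states(), c("TC", "PC"))
  expect_equal(unname(P0[keep, keep]), diag(5), ignore_attr = TRUE)
  expect_equal(unname(P0["TC", "SD_postC"]), 1)
  expect_equal(unname(P0["PC", "PROG_postC"]), 1)
  tr0 <- run_cohort_trace(P0, 4)
  expect_equal(unname(tr0[5, ]), unname(tr0[1, ]))

  sc <- bundled_scenario()
  P <- build_transition_matrix(sc$arms$monotherapy$transitions)
  expect_valid_matrix(P)
  expect_equal(P["SD", "SD"], 1 - 0.55459395 - 0.1126958)
  # death only through progression: no stable-phase state reaches DEATH
  expect_equal(unname(P[c("SD", "SD_postC", "TC"), "DEATH"]), c(0, 0, 0))
  # complication entered at most once: post-complication states cannot
  # re-enter a tunnel
  expect_equal(unname(P["SD_postC", "TC"]), 0)
  expect_equal(unname(P["PROG_postC", "PC"]), 0)
  # tunnels hold for exactly one cycle
  expect_equal(unname(P["TC", "TC"]), 0)
  expect_equal(unname(P["PC", "PC"]), 0)

  expect_error(
    build_transition_matrix(c(progression = 0.95, death = 0.2,
                              complication = 0.11)),
    "SD row.*excess", ignore.case = TRUE)
  # renormalisation rescales exits proportionally and counts the rows
  P <- build_transition_matrix(c(progression = 0.95, death = 0.2,
                                 complication = 0.11),
                               renormalize = TRUE)
  expect_valid_matrix(P)
  expect_equal(attr(P, "renormalized"), 1L)
  expect_equal(P["SD", "PROG"] / P["SD", "TC"], 0.95 / 0.11)
  expect_equal(unname(P["SD", "SD"]), 0)
})

test_that("certain death empties the progressed states", {
  P <- build_transition_matrix(c(progression = 0.3, death = 1,
                                 complication = 0))
  tr <- run_cohort_trace(P, 60)
  expect_equal(unname(tr[61, "DEATH"]), 1, tolerance = 1e-8)
})

test_that("cohort trace follows the closed forms", {
  # identity matrix: nothing moves
  P <- build_transition_matrix(c(progression = 0, death = 0,
                                 complication = 0))
  tr <- run_cohort_trace(P, 5)
  expect_equal(unname(tr[6, ]), c(1, 0, 0, 0, 0, 0, 0))

  # leave-at-rate-1/2: start-state occupancy is 0.5^t
  P <- build_transition_matrix(c(progression = 0.5, death = 0,
                                 complication = 0))
  tr <- run_cohort_trace(P, 10)
  expect_equal(unname(tr[, "SD"]), 0.5^(0:10), tolerance = 1e-12)

  # complication shuffling never changes the stable-phase total
  sc <- bundled_scenario()
  P <- build_transition_matrix(sc$arms$monotherapy$transitions)
  tr <- run_cohort_trace(P, 30)
  stable_phase <- rowSums(tr[, c("SD", "SD_postC", "TC")])
  expect_equal(unname(stable_phase), (1 - 0.55459395)^(0:30),
               tolerance = 1e-12)
})

test_that("trace conserves mass and death is monotone", {
  for (seed in 1:25) {
    sc <- random_scenario(seed)
    for (a in names(sc$arms)) {
      tr <- run_arm(sc, a)$trace
      expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)),
                   tolerance = 1e-10)
      expect_true(all(diff(tr[, "DEATH"]) >= -1e-12))
    }
  }
})

test_that("reported states aggregate the post-complication twins", {
  sc <- bundled_scenario()
  tr <- run_arm(sc, "combination")$trace
  rep_tr <- report_trace(tr)
  expect_equal(colnames(rep_tr), reported_states())
  expect_equal(unname(rep_tr[, "SD"]),
               unname(tr[, "SD"] + tr[, "SD_postC"]))
  expect_equal(unname(rowSums(rep_tr)), rep(1, 31), tolerance = 1e-10)
})

test_that("per-cycle QALY scaling and discounting follow their closed forms", {
  expect_equal(round(cycle_qaly(0.72, 8), 8), 0.11076923)
  expect_equal(round(cycle_qaly(0.59, 8), 8), 0.09076923)
  expect_equal(cycle_qaly(0, 8), 0)
  expect_error(cycle_qaly(1.2, 8), "\\[0, 1\\]")

  expect_equal(discount_factor(0, 0.035, 8, "annualized"), 1)
  expect_equal(discount_factor(0, 0.035, 8, "per_cycle"), 1)
  expect_equal(discount_factor(7, 0, 8, "annualized"), 1)
  # 13 cycles x 8/52 = exactly 2 years
  expect_equal(discount_factor(13, 0.035, 8, "annualized"),
               0.9335107, tolerance = 1e-5)
  expect_equal(discount_factor(3, 0.035, 8, "per_cycle"), 1.035^-3)
  expect_error(discount_factor(1, 0.035, 8, "weekly"), "convention")
})

test_that("accrual reduces to hand-computable totals in simple cases", {
  sc <- toy_scenario()
  # zero values give zero totals
  tr <- run_arm(sc, "a")$trace
  zero_cost <- list(on_treatment = 0, complication_once = 0,
                    progression = 0)
  u0 <- utility_set(stable = 0, progression = 0)
  tot <- accrue_values(tr, zero_cost, u0, annual_discount = 0)
  expect_equal(tot$discounted_cost, 0)
  expect_equal(tot$discounted_qaly, 0)

  # immortal, non-progressing cohort at utility u: QALY = n * u * 8/52
  P <- build_transition_matrix(c(progression = 0, death = 0,
                                 complication = 0))
  tr <- run_cohort_trace(P, 30)
  u <- utility_set(stable = 0.8, progression = 0.5)
  tot <- accrue_values(tr, zero_cost, u, annual_discount = 0,
                       counting = "cycle_start")
  expect_equal(tot$discounted_qaly, 30 * 0.8 * 8 / 52)
  # all three counting conventions agree on a constant cohort
  tot_end <- accrue_values(tr, zero_cost, u, annual_discount = 0,
                           counting = "cycle_end")
  expect_equal(tot$discounted_qaly, tot_end$discounted_qaly)
})

test_that("infinite-horizon stable time approaches 1/p_progression", {
  p <- 0.23
  P <- build_transition_matrix(c(progression = p, death = 0.5,
                                 complication = 0))
  n <- ceiling(log(1e-9) / log(1 - p))  # truncation error < 1e-8 cycles
  tr <- run_cohort_trace(P, n)
  stable_cycles <- sum(rowSums(tr[, c("SD", "SD_postC", "TC")])[1:n])
  expect_equal(stable_cycles, 1 / p, tolerance = 1e-8)
})

test_that("removing complications leaves QALYs unchanged and removes
           exactly the once-only complication cost", {
  sc <- bundled_scenario()
  for (a in names(sc$arms)) {
    base_run <- run_arm(sc, a)
    no_comp <- run_arm(sc, a, prob_overrides = c(complication = 0))
    expect_equal(no_comp$totals$discounted_qaly,
                 base_run$totals$discounted_qaly, tolerance = 1e-12)
    expect_equal(base_run$totals$discounted_cost -
                   no_comp$totals$discounted_cost,
                 base_run$totals$discounted_complication_cost,
                 tolerance = 1e-9)
  }
})

test_that("discounted totals are non-increasing in the discount rate", {
  sc <- bundled_scenario()
  rates <- c(0, 0.02, 0.035, 0.06, 0.1)
  for (a in names(sc$arms)) {
    runs <- lapply(rates, function(r) {
      sc$model$annual_discount <- r
      run_arm(sc, a)$totals
    })
    costs <- vapply(runs, function(t) t$discounted_cost, numeric(1))
    qalys <- vapply(runs, function(t) t$discounted_qaly, numeric(1))
    expect_true(all(diff(costs) <= 1e-9))
    expect_true(all(diff(qalys) <= 1e-12))
  }
})

test_that("microsimulation agrees with the cohort computation", {
  sc <- bundled_scenario()
  for (a in names(sc$arms)) {
    r <- run_arm(sc, a)
    ms <- microsim_oracle(r$matrix, r$cycle_cost, sc$arms[[a]]$utilities,
                          n_cycles = sc$model$n_cycles,
                          n_patients = 50000, seed = 101)
    expect_lt(abs(ms$mean_cost - r$totals$discounted_cost),
              3 * ms$se_cost)
    expect_lt(abs(ms$mean_qaly - r$totals$discounted_qaly),
              3 * ms$se_qaly)
  }
})

test_that("microsimulation is deterministic and exact on a frozen cohort", {
  sc <- bundled_scenario()
  r <- run_arm(sc, "combination")
  a <- microsim_oracle(r$matrix, r$cycle_cost,
                       sc$arms$combination$utilities, n_cycles = 30,
                       n_patients = 500, seed = 9)
  b <- microsim_oracle(r$matrix, r$cycle_cost,
                       sc$arms$combination$utilities, n_cycles = 30,
                       n_patients = 500, seed = 9)
  expect_identical(a, b)

  # identity matrix: zero variance, equal to the cohort value
  P <- build_transition_matrix(c(progression = 0, death = 0,
                                 complication = 0))
  tr <- run_cohort_trace(P, 10)
  u <- bundled_scenario()$arms$monotherapy$utilities
  cc <- list(on_treatment = 100, complication_once = 7, progression = 0)
  cohort <- accrue_values(tr, cc, u)
  ms <- microsim_oracle(P, cc, u, n_cycles = 10, n_patients = 200,
                        seed = 3)
  expect_equal(ms$mean_cost, cohort$discounted_cost)
  expect_equal(ms$mean_qaly, cohort$discounted_qaly)
  expect_equal(ms$se_cost, 0)
})
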