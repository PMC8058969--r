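tot <- function(cost, qaly) list(cost = cost, qaly = qaly)

test_that("ICER computation classifies dominance and applies the threshold", {
  r <- icer(tot(0, 0), tot(100, 1), wtp = 117746)
  expect_equal(r$icer, 100)
  expect_equal(r$dominance, "comparable")
  expect_true(r$cost_effective)

  r <- icer(tot(100, 1), tot(50, 2), wtp = 117746)
  expect_equal(r$dominance, "dominant")
  expect_true(is.na(r$icer))
  expect_true(r$cost_effective)

  r <- icer(tot(100, 2), tot(150, 1), wtp = 117746)
  expect_equal(r$dominance, "dominated")
  expect_false(r$cost_effective)

  # published totals with the unrounded incremental QALY implied by the
  # printed ICER
  r <- icer(tot(3434.834, 0.501), tot(8424.188, 0.501 + 0.231489),
            wtp = 117746)
  expect_equal(r$incremental_cost, 4989.354)
  expect_equal(r$icer, 4989.354 / 0.231489, tolerance = 1e-12)
  expect_equal(r$icer, 21553.31, tolerance = 1e-6)

  # zero incremental QALY: undefined ICER, sign of the cost decides
  r <- icer(tot(100, 1), tot(90, 1), wtp = 117746)
  expect_true(is.na(r$icer))
  expect_equal(r$dominance, "comparable")
  expect_true(r$cost_effective)
  expect_false(icer(tot(100, 1), tot(110, 1), wtp = 1e5)$cost_effective)
})

test_that("net monetary benefit is wtp x QALY - cost", {
  expect_equal(nmb(tot(0, 0), 123), 0)
  expect_equal(nmb(tot(100, 1), 100), 0)
  expect_equal(nmb(tot(8424.188, 0.73), 50000), 28075.812)
  expect_error(nmb(tot(1, 1), -5), "wtp")
})

test_that("at wtp equal to the ICER the two arms' NMBs tie", {
  bc <- base_case(calibrated_scenario())
  n1 <- nmb(bc$arms[[bc$reference]], bc$icer)
  n2 <- nmb(bc$arms[[bc$comparator]], bc$icer)
  expect_equal(n1, n2, tolerance = 1e-6)
})

test_that("identical arms yield zero incrementals through the pipeline", {
  sc <- degenerate_scenarios()$equal_arms
  bc <- base_case(sc)
  expect_equal(bc$incremental_cost, 0)
  expect_equal(bc$incremental_qaly, 0)
  expect_true(is.na(bc$icer))
})

test_that("free comparator drugs make the combination dominant", {
  sc <- calibrated_scenario()
  sc$arms$combination$multiplicities <- numeric(0)
  bc <- base_case(sc)
  expect_equal(bc$dominance, "dominant")
  expect_true(bc$incremental_qaly > 0)
  expect_true(bc$incremental_cost < 0)
})

test_that("ICER is scale equivariant in costs and antisymmetric in arms", {
  sc <- calibrated_scenario()
  bc <- base_case(sc)
  k <- 3.7
  sc_k <- sc
  for (nm in names(sc_k$cost_items)) {
    it <- sc_k$cost_items[[nm]]
    sc_k$cost_items[[nm]] <- cost_item(it$label, k * it$base, k * it$min,
                                       k * it$max)
  }
  bc_k <- base_case(sc_k)
  expect_equal(bc_k$incremental_cost, k * bc$incremental_cost,
               tolerance = 1e-12)
  expect_equal(bc_k$icer, k * bc$icer, tolerance = 1e-12)
  expect_equal(bc_k$incremental_qaly, bc$incremental_qaly,
               tolerance = 1e-15)

  # swapping reference and comparator negates incrementals, keeps |ICER|
  sc_sw <- sc
  sc_sw$model$reference <- "combination"
  bc_sw <- base_case(sc_sw)
  expect_equal(bc_sw$incremental_cost, -bc$incremental_cost)
  expect_equal(bc_sw$incremental_qaly, -bc$incremental_qaly)
  expect_equal(abs(bc_sw$icer), abs(bc$icer), tolerance = 1e-12)
})

test_that("calibration recovers a known configuration exactly", {
  sc <- bundled_scenario()
  known <- sc
  known$model$cost_counting <- "cycle_end"
  known$model$qaly_counting <- "cycle_end"
  known$model$discounting <- "per_cycle"
  known$arms$monotherapy$multiplicities <- c(tas102 = 2)
  known$arms$combination$multiplicities <- c(tas102 = 2, bevacizumab = 3)
  bc <- base_case(known)
  self_targets <- list(
    cost_monotherapy = bc$arms$monotherapy$cost,
    qaly_monotherapy = bc$arms$monotherapy$qaly,
    cost_combination = bc$arms$combination$cost,
    qaly_combination = bc$arms$combination$qaly,
    incremental_cost = bc$incremental_cost,
    incremental_qaly = bc$incremental_qaly)
  grid <- list(monotherapy = expand.grid(tas102 = 1:2),
               combination = expand.grid(tas102 = 1:2, bevacizumab = 2:4))
  cal <- calibrate_conventions(sc, targets = self_targets,
                               multiplicity_grid = grid)
  expect_equal(cal$best$objective, 0, tolerance = 1e-12)
  expect_equal(cal$best$cost_counting, "cycle_end")
  expect_equal(cal$best$qaly_counting, "cycle_end")
  expect_equal(cal$best$discounting, "per_cycle")
  expect_equal(cal$best$multiplicities$monotherapy, c(tas102 = 2))
  expect_equal(cal$best$multiplicities$combination,
               c(tas102 = 2, bevacizumab = 3))
})

test_that("a single-configuration grid is returned regardless of fit", {
  sc <- bundled_scenario()
  grid <- list(monotherapy = expand.grid(tas102 = 1),
               combination = expand.grid(tas102 = 1))
  cal <- calibrate_conventions(
    sc, targets = list(qaly_monotherapy = 0.501),
    counting_grid = "cycle_end", discounting_grid = "per_cycle",
    multiplicity_grid = grid)
  expect_equal(nrow(cal$report), 1L)
  expect_equal(cal$best$cost_counting, "cycle_end")
  expect_equal(cal$best$multiplicities$monotherapy, c(tas102 = 1))
  expect_error(calibrate_conventions(sc, counting_grid = character(0)),
               "empty")
})
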