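test_that("DEALE conversion matches the exponential closed form", {
  # at the median exactly half the cohort transitions
  expect_equal(median_to_transition_prob(3.7, 3.7), 0.5)
  expect_equal(median_to_transition_prob(12, 0), 0)
  # frozen value computed independently as 1 - 0.5^(L/m)
  expect_equal(median_to_transition_prob(3.7, 1.8405), 0.291633658817,
               tolerance = 1e-10)
  # monotone: increasing in cycle length, decreasing in median
  p <- median_to_transition_prob(6, c(1, 2, 4))
  expect_true(all(diff(p) > 0))
  p <- median_to_transition_prob(c(3, 6, 12), 2)
  expect_true(all(diff(p) < 0))
  expect_error(median_to_transition_prob(-1, 2), "positive")
  expect_error(median_to_transition_prob(3, -2), "non-negative")
})

test_that("probability rescaling is the constant-rate change of step", {
  expect_equal(prob_rescale(0.3, 5, 5), 0.3)
  expect_equal(prob_rescale(0, 1, 7), 0)
  expect_equal(prob_rescale(0.75, 2, 1), 0.5)  # (1-0.75)^(1/2) = 0.5
  expect_equal(prob_rescale(1, 2, 1), 1)       # certainty stays certain
  expect_error(prob_rescale(1.2, 1, 1), "\\[0, 1\\]")
  expect_error(prob_rescale(0.5, 0, 1), "positive")
})

test_that("DEALE then rescaling equals direct conversion at the new length", {
  medians <- c(1.9, 3.7, 6.4, 14)
  for (m in medians) for (L1 in c(0.5, 1.84, 4)) for (L2 in c(0.9, 2, 8)) {
    direct <- median_to_transition_prob(m, L2)
    via <- prob_rescale(median_to_transition_prob(m, L1), L1, L2)
    expect_equal(via, direct, tolerance = 1e-12)
  }
})

test_that("parameter constructors enforce orderings and bounds", {
  p <- prob_param(0.4)
  expect_equal(c(p$min, p$max), c(0.3, 0.5))
  expect_equal(prob_param(0.9)$max, 1)  # cap at 1
  expect_error(prob_param(1.4), "\\[0, 1\\]")
  expect_error(prob_param(0.5, min = 0.6), "min <= base")
  expect_error(cost_item("x", -5), "non-negative")
  expect_error(arm_transitions(0.95, 0.2, 0.11), "infeasible")
  u <- utility_set(stable = 0.73, progression = 0.59)
  expect_equal(u$complication$base, 0.73)   # ties to the parent state
  expect_equal(u$prog_complication$base, 0.59)
  expect_equal(u$death$base, 0)
})

test_that("yen conversion uses the 110.05 rate", {
  expect_equal(jpy_to_usd(110.05), 1)
  expect_equal(jpy_to_usd(0), 0)
  expect_equal(jpy_to_usd(793432), 7209.74, tolerance = 0.01 / 7209.74)
})

test_that("cycle cost assembly is additive over multiplicities", {
  sc <- bundled_scenario()
  cc <- assemble_cycle_cost(sc, "monotherapy")
  # 2 x TAS-102 + 2 x monotherapy administration fee
  expect_equal(cc$on_treatment, 2 * 1833.66516 + 2 * 10.4072398)
  expect_equal(cc$progression, 0)
  expect_equal(assemble_cycle_cost(sc, "combination")$complication_once,
               72.0921038)
  # doubling every multiplicity doubles the on-treatment cost exactly
  sc2 <- sc
  for (a in names(sc2$arms))
    sc2$arms[[a]]$multiplicities <- 2 * sc2$arms[[a]]$multiplicities
  expect_equal(assemble_cycle_cost(sc2, "monotherapy")$on_treatment,
               2 * cc$on_treatment)
  # empty multiplicities give zero treatment cost
  sc2$arms$monotherapy$multiplicities <- numeric(0)
  expect_equal(assemble_cycle_cost(sc2, "monotherapy")$on_treatment, 0)
  # unknown labels are named in the error
  sc2$arms$monotherapy$multiplicities <- c(nonexistent_item = 1)
  expect_error(assemble_cycle_cost(sc2, "monotherapy"), "nonexistent_item")
})

test_that("single-item cycle cost reproduces the tabulated TAS-102 price", {
  sc <- bundled_scenario()
  sc$arms$monotherapy$multiplicities <- c(tas102 = 1)
  expect_equal(assemble_cycle_cost(sc, "monotherapy")$on_treatment,
               1833.66516)
})

test_that("every bundled sensitivity band is +/-25% of base", {
  sc <- bundled_scenario()
  chk <- function(p) {
    expect_equal(p$min, 0.75 * p$base, tolerance = 1e-6)
    expect_equal(p$max, 1.25 * p$base, tolerance = 1e-6)
  }
  for (a in names(sc$arms)) {
    for (nm in names(sc$arms[[a]]$transitions))
      chk(sc$arms[[a]]$transitions[[nm]])
    for (nm in c("stable", "complication", "progression",
                 "prog_complication"))
      chk(sc$arms[[a]]$utilities[[nm]])
  }
  for (it in sc$cost_items) chk(it)
})

test_that("PSA samplers are moment matched and respect support", {
  withr::local_seed(11)
  # point mass
  s <- build_psa_distribution(prob_param(0.5, 0.5, 0.5))
  expect_equal(s$draw(5), rep(0.5, 5))
  # gamma: mean within 1% over 1e5 draws
  s <- build_psa_distribution(cost_item("tas", 1833.66516))
  x <- s$draw(1e5)
  expect_equal(mean(x), 1833.66516, tolerance = 0.01)
  expect_true(all(x >= 0))
  # beta: mean matched, support respected
  s <- build_psa_distribution(prob_param(0.38191794))
  x <- s$draw(1e5)
  expect_equal(mean(x), 0.38191794, tolerance = 0.01)
  expect_true(all(x >= 0 & x <= 1))
  # dispersion: central 95% approximately spans [min, max]
  expect_equal(unname(stats::quantile(x, c(0.025, 0.975))),
               c(0.75, 1.25) * 0.38191794, tolerance = 0.03)
  # utility near 1 still bounded
  x <- build_psa_distribution(prob_param(0.9, 0.675, 1))$draw(1e5)
  expect_true(all(x <= 1))
  # gamma with base 0 collapses to a warned point mass
  expect_warning(s <- build_psa_distribution(cost_item("z", 0, 0, 10)),
                 "point mass")
  expect_equal(s$draw(3), c(0, 0, 0))
})
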