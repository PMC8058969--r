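# Bundled and generated scenarios: the TAS-102 comparison shipped with the
# package, random scenarios with the same statistical structure for
# property-based testing, and named degenerate fixtures.

#' The bundled TAS-102 +/- bevacizumab scenario
#'
#' The complete two-arm comparison shipped with the package: TAS-102 plus
#' bevacizumab combination therapy versus TAS-102 monotherapy in
#' chemorefractory metastatic colorectal cancer, Japanese payer
#' perspective — per-cycle transition probabilities, itemised 2019-USD
#' costs, annual health-state utilities (each with +/-25% sensitivity
#' bounds), 8-week cycles over 30 cycles, 3.5% annual discount, and a
#' willingness-to-pay threshold of $117,746/QALY.
#'
#' @return A validated `cea_scenario`; idempotent.
#' @seealso [scenario_file()] for the underlying YAML path.
#' @export
tas102_scenario <- function() {
  read_scenario(scenario_file())
}

#' Path to the bundled scenario file
#'
#' @param name Fixture name; currently only `"tas102_bevacizumab"`.
#' @return Path to the installed YAML file.
#' @export
scenario_file <- function(name = "tas102_bevacizumab") {
  f <- system.file("extdata", paste0(name, ".yaml"), package = "markovcea")
  if (!nzchar(f)) stop("no bundled scenario named '", name, "'")
  f
}

#' Blueprint for random scenario generation
#'
#' Parameter-class ranges from which [random_scenario()] draws a valid
#' two-arm scenario: uniform base-value ranges for transition
#' probabilities, costs and utilities, and the fractional half-width of
#' every min/max sensitivity band.
#'
#' @param progression_range,death_range,complication_range Base-value
#'   ranges for the per-cycle probabilities.
#' @param stable_utility_range Range for the stable-state utility; the
#'   progression utility is drawn below the stable one.
#' @param drug_cost_range,fee_cost_range,complication_cost_range USD
#'   ranges for the cost classes.
#' @param range_fraction Half-width of min/max bands (min/max =
#'   base x (1 -/+ fraction), probabilities capped at 1).
#' @param feasibility_margin Generated rows satisfy
#'   `p_a + p_b <= 1 - margin` so every +/-fraction extreme stays
#'   buildable.
#' @return A `scenario_blueprint` list.
#' @export
scenario_blueprint <- function(progression_range = c(0.15, 0.6),
                               death_range = c(0.1, 0.4),
                               complication_range = c(0.02, 0.2),
                               stable_utility_range = c(0.5, 0.9),
                               drug_cost_range = c(500, 3000),
                               fee_cost_range = c(1, 250),
                               complication_cost_range = c(10, 100),
                               range_fraction = 0.25,
                               feasibility_margin = 0.05) {
  structure(list(progression_range = progression_range,
                 death_range = death_range,
                 complication_range = complication_range,
                 stable_utility_range = stable_utility_range,
                 drug_cost_range = drug_cost_range,
                 fee_cost_range = fee_cost_range,
                 complication_cost_range = complication_cost_range,
                 range_fraction = range_fraction,
                 feasibility_margin = feasibility_margin),
            class = "scenario_blueprint")
}

#' Generate a random valid scenario
#'
#' Draws a two-arm scenario with the same structure as the bundled one:
#' three transition probabilities, tied complication utilities with
#' progression utility below stable, a shared cost table with per-arm
#' integer multiplicities, and +/-`range_fraction` sensitivity bands.
#' Transition rows are drawn with a feasibility margin (bounded rejection)
#' so the scenario always validates and both transition matrices build.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param seed Integer seed.
#' @param blueprint A [scenario_blueprint()].
#' @return A validated `cea_scenario` with arms `a` (reference) and `b`.
#' @export
random_scenario <- function(seed, blueprint = scenario_blueprint()) {
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  bp <- blueprint
  fr <- bp$range_fraction
  pp <- function(base) prob_param(base, base * (1 - fr),
                                  min(base * (1 + fr), 1))
  runi <- function(r) stats::runif(1, r[1], r[2])
  draw_pair <- function(r1, r2) {
    # two probabilities whose +/-fr extremes keep the row feasible
    cap <- (1 - bp$feasibility_margin) / (1 + fr)
    for (i in 1:1000) {
      a <- runi(r1); b <- runi(r2)
      if (a + b <= cap) return(c(a, b))
    }
    stop("could not draw a feasible probability pair; ",
         "blueprint ranges too wide")
  }
  make_arm <- function() {
    pc_pp <- draw_pair(bp$complication_range, bp$progression_range)
    pc_pd <- draw_pair(bp$complication_range, bp$death_range)
    u_sd <- runi(bp$stable_utility_range)
    u_pr <- stats::runif(1, 0.2, u_sd)
    list(transitions = arm_transitions(progression = pp(pc_pp[2]),
                                       death = pp(pc_pd[2]),
                                       complication = pp(pc_pp[1])),
         utilities = utility_set(stable = pp(u_sd), progression = pp(u_pr)))
  }
  arm_a <- make_arm(); arm_b <- make_arm()
  items <- list(
    drug_a = cost_item("drug_a", runi(bp$drug_cost_range),
                       range_fraction = fr),
    drug_b = cost_item("drug_b", runi(bp$drug_cost_range),
                       range_fraction = fr),
    fee = cost_item("fee", runi(bp$fee_cost_range), range_fraction = fr),
    complication_a = cost_item("complication_a",
                               runi(bp$complication_cost_range),
                               range_fraction = fr),
    complication_b = cost_item("complication_b",
                               runi(bp$complication_cost_range),
                               range_fraction = fr))
  arm_a$multiplicities <- c(drug_a = sample(1:3, 1), fee = sample(0:3, 1))
  arm_a$complication_cost <- "complication_a"
  arm_b$multiplicities <- c(drug_a = sample(0:2, 1),
                            drug_b = sample(1:4, 1), fee = sample(0:3, 1))
  arm_b$complication_cost <- "complication_b"
  scenario(arms = list(a = arm_a, b = arm_b), cost_items = items,
           cycle_length_weeks = 8, n_cycles = sample(10:40, 1),
           annual_discount = stats::runif(1, 0, 0.06),
           wtp_threshold = stats::runif(1, 10000, 150000),
           counting = sample(COUNTING_CONVENTIONS, 1),
           discounting = sample(DISCOUNT_CONVENTIONS, 1),
           reference = "a",
           metadata = list(generator = "random_scenario", seed = seed))
}

#' Named degenerate scenario fixtures
#'
#' Edge-case variants of the bundled scenario used by the invariant test
#' suite: `zero_discount`, `immortal` (death probability 0 in both arms),
#' `instant_progression` (progression probability 1, complication 0),
#' `no_complication` (complication probability and cost 0), and
#' `equal_arms` (comparator identical to the reference).
#'
#' @return Named list of `cea_scenario` objects.
#' @export
degenerate_scenarios <- function() {
  base <- tas102_scenario()
  set_prob <- function(sc, which, value) {
    for (a in names(sc$arms))
      sc$arms[[a]]$transitions[[which]] <- prob_param(value, value, value)
    sc
  }
  zero_discount <- base
  zero_discount$model$annual_discount <- 0
  immortal <- set_prob(base, "death", 0)
  instant <- set_prob(set_prob(base, "progression", 1), "complication", 0)
  no_compl <- set_prob(base, "complication", 0)
  for (a in names(no_compl$arms)) no_compl$arms[[a]]$complication_cost <- NULL
  equal_arms <- base
  equal_arms$arms$combination <- equal_arms$arms$monotherapy
  list(zero_discount = zero_discount, immortal = immortal,
       instant_progression = instant, no_complication = no_compl,
       equal_arms = equal_arms)
}
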