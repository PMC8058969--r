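# Shared fixtures, all built in code.

# Memoised bundled scenario and its calibrated counterpart (the sweep is
# deterministic, so computing it once per session is safe).
.cache <- new.env(parent = emptyenv())

bundled_scenario <- function() {
  if (is.null(.cache$sc)) .cache$sc <- tas102_scenario()
  .cache$sc
}

bundled_calibration <- function() {
  if (is.null(.cache$cal))
    .cache$cal <- calibrate_conventions(bundled_scenario())
  .cache$cal
}

calibrated_scenario <- function() {
  if (is.null(.cache$sc_cal))
    .cache$sc_cal <- apply_calibration(bundled_scenario(),
                                       bundled_calibration())
  .cache$sc_cal
}

# A minimal hand-buildable two-arm scenario for unit tests.
toy_scenario <- function(p_prog_a = 0.5, p_prog_b = 0.25,
                         p_death = 0.2, p_comp = 0.1,
                         discount = 0, n_cycles = 10,
                         counting = "cycle_start") {
  mk_arm <- function(p_prog, mult) {
    list(transitions = arm_transitions(progression = p_prog,
                                       death = p_death,
                                       complication = p_comp),
         utilities = utility_set(stable = 0.8, progression = 0.5),
         multiplicities = mult,
         complication_cost = "compl")
  }
  scenario(
    arms = list(a = mk_arm(p_prog_a, c(drug = 1)),
                b = mk_arm(p_prog_b, c(drug = 2, fee = 1))),
    cost_items = list(drug = cost_item("drug", 1000),
                      fee = cost_item("fee", 50),
                      compl = cost_item("compl", 30)),
    cycle_length_weeks = 8, n_cycles = n_cycles,
    annual_discount = discount, wtp_threshold = 50000,
    counting = counting, reference = "a")
}

# Shrink every sensitivity band to +/-fraction around base (PSA
# convergence checks).
shrink_ranges <- function(sc, fraction) {
  sq <- function(p) prob_param(p$base, p$base * (1 - fraction),
                               min(p$base * (1 + fraction), 1),
                               dist = p$dist)
  for (a in names(sc$arms)) {
    for (nm in names(sc$arms[[a]]$transitions))
      sc$arms[[a]]$transitions[[nm]] <- sq(sc$arms[[a]]$transitions[[nm]])
    for (nm in c("stable", "complication", "progression",
                 "prog_complication"))
      sc$arms[[a]]$utilities[[nm]] <- sq(sc$arms[[a]]$utilities[[nm]])
  }
  for (nm in names(sc$cost_items)) {
    it <- sc$cost_items[[nm]]
    sc$cost_items[[nm]] <- cost_item(it$label, it$base,
                                     it$base * (1 - fraction),
                                     it$base * (1 + fraction))
  }
  sc
}
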