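# Markov cohort engine: expanded state space with once-only complication
# tunnel states, trace propagation, and discounted value accrual.

# Expanded state space.  The reported model has five states (SD, TC, PROG,
# PC, DEATH); complication costs must be counted at most once per patient,
# so TC and PC are one-cycle tunnel states with post-complication twins
# (SD_postC, PROG_postC) that can never re-enter a complication state.
STATES <- c("SD", "SD_postC", "TC", "PROG", "PROG_postC", "PC", "DEATH")

# Surjection from expanded onto reported states.
REPORTED_STATES <- c("SD", "TC", "PROG", "PC", "DEATH")
REPORT_MAP <- c(SD = "SD", SD_postC = "SD", TC = "TC", PROG = "PROG",
                PROG_postC = "PROG", PC = "PC", DEATH = "DEATH")

#' Names of the expanded and reported Markov states
#'
#' @return `markov_states()` returns the seven expanded state names;
#'   `reported_states()` the five reported (aggregated) ones.
#' @export
markov_states <- function() STATES

#' @rdname markov_states
#' @export
reported_states <- function() REPORTED_STATES

.arm_probs <- function(arm) {
  if (inherits(arm, "arm_transitions"))
    c(progression = arm$progression$base, death = arm$death$base,
      complication = arm$complication$base)
  else {
    stopifnot(is.numeric(arm),
              all(c("progression", "death", "complication") %in% names(arm)))
    arm[c("progression", "death", "complication")]
  }
}

#' Build the per-cycle transition matrix for one arm
#'
#' Encodes the allowed transitions: stable disease can progress or suffer a
#' complication; death is reached only through progression; complication
#' states last one cycle and fall back to post-complication twins that are
#' structurally barred from a second complication, so the one-time
#' complication cost is counted at most once per patient path.
#'
#' @param arm An [arm_transitions()], or a named numeric vector with
#'   entries `progression`, `death`, `complication`.
#' @param renormalize If `TRUE`, an infeasible row (exit probabilities
#'   summing above 1) is rescaled proportionally with the self-loop set to
#'   0 instead of raising an error; the number of rescaled rows is attached
#'   as attribute `"renormalized"`.  Used by probabilistic sensitivity
#'   analysis, where sampled probabilities can transiently violate row
#'   feasibility.
#' @return A 7x7 row-stochastic matrix over [markov_states()], with the
#'   death row an identity row.
#' @export
build_transition_matrix <- function(arm, renormalize = FALSE) {
  p <- .arm_probs(arm)
  if (any(p < 0) || any(p > 1))
    stop("transition probabilities must be in [0, 1]")
  pp <- p[["progression"]]; pd <- p[["death"]]; pc <- p[["complication"]]
  n_renorm <- 0L
  fix_row <- function(exits, row_name) {
    s <- sum(exits)
    if (s > 1) {
      if (!renormalize)
        stop("infeasible ", row_name, " row: exit probabilities sum to ",
             format(s), " (excess ", format(s - 1), ")")
      n_renorm <<- n_renorm + 1L
      exits <- exits / s
      s <- 1
    }
    c(exits, self = 1 - s)
  }
  P <- matrix(0, 7, 7, dimnames = list(STATES, STATES))
  r <- fix_row(c(TC = pc, PROG = pp), "SD")
  P["SD", c("TC", "PROG", "SD")] <- r
  r <- fix_row(c(PROG = pp), "TC")
  P["TC", c("PROG", "SD_postC")] <- r   # one-cycle tunnel, no self-loop
  r <- fix_row(c(PROG = pp), "SD_postC")
  P["SD_postC", c("PROG", "SD_postC")] <- r
  r <- fix_row(c(PC = pc, DEATH = pd), "PROG")
  P["PROG", c("PC", "DEATH", "PROG")] <- r
  r <- fix_row(c(DEATH = pd), "PC")
  P["PC", c("DEATH", "PROG_postC")] <- r
  r <- fix_row(c(DEATH = pd), "PROG_postC")
  P["PROG_postC", c("DEATH", "PROG_postC")] <- r
  P["DEATH", "DEATH"] <- 1
  structure(P, renormalized = n_renorm)
}

#' Propagate a cohort through the transition matrix
#'
#' @param P Transition matrix from [build_transition_matrix()].
#' @param n_cycles Number of cycles to run.
#' @param init Initial distribution over [markov_states()]; defaults to a
#'   point mass on stable disease.
#' @return A `(n_cycles + 1) x 7` occupancy matrix (class `cohort_trace`)
#'   whose row `t + 1` is the distribution after `t` cycles; every row
#'   sums to 1.
#' @export
run_cohort_trace <- function(P, n_cycles,
                             init = c(1, rep(0, 6))) {
  stopifnot(is.matrix(P), nrow(P) == 7, ncol(P) == 7,
            n_cycles >= 1, length(init) == 7,
            abs(sum(init) - 1) < 1e-12)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12))
    stop("transition matrix rows must sum to 1; worst deviation ",
         format(max(abs(rs - 1))))
  trace <- matrix(0, n_cycles + 1, 7,
                  dimnames = list(cycle = 0:n_cycles, state = STATES))
  trace[1, ] <- init
  for (t in seq_len(n_cycles))
    trace[t + 1, ] <- trace[t, ] %*% P
  structure(trace, class = c("cohort_trace", "matrix", "array"))
}

#' Aggregate an expanded trace onto the five reported states
#'
#' @param trace A `cohort_trace`.
#' @return Occupancy matrix over [reported_states()] (SD includes its
#'   post-complication twin, likewise PROG).
#' @export
report_trace <- function(trace) {
  out <- sapply(REPORTED_STATES, function(s)
    rowSums(trace[, names(REPORT_MAP)[REPORT_MAP == s], drop = FALSE]))
  rownames(out) <- rownames(trace)
  out
}

#' QALYs accrued by one cycle spent at a given annual utility
#'
#' Utilities are annual weights; a cycle contributes
#' `utility * cycle_length_weeks / 52` QALYs.
#'
#' @param utility Annual utility weight in `[0, 1]`.
#' @param cycle_length_weeks Cycle length in weeks.
#' @return QALYs per cycle; vectorised.
#' @export
cycle_qaly <- function(utility, cycle_length_weeks) {
  if (any(utility < 0) || any(utility > 1))
    stop("`utility` must be in [0, 1]")
  utility * cycle_length_weeks / 52
}

#' Discount factor for a given cycle
#'
#' @param cycle_index Cycle number(s), 0-based.
#' @param annual_rate Annual discount rate.
#' @param cycle_length_weeks Cycle length in weeks.
#' @param convention `"annualized"`: `(1+r)^(-t * cycle_length/52)`
#'   (calendar-time discounting); `"per_cycle"`: `(1+r)^(-t)` (each cycle
#'   one compounding period).
#' @return Discount factor(s) in `(0, 1]`; 1 at cycle 0 under both
#'   conventions.
#' @export
discount_factor <- function(cycle_index, annual_rate, cycle_length_weeks,
                            convention = "annualized") {
  stopifnot(all(cycle_index >= 0), annual_rate >= 0)
  switch(convention,
    annualized = (1 + annual_rate)^(-cycle_index * cycle_length_weeks / 52),
    per_cycle = (1 + annual_rate)^(-cycle_index),
    stop("unknown discount convention '", convention, "'")
  )
}

# Per-state values (cost per cycle, QALY per cycle) on the expanded space.
# Treatment cost accrues over the whole stable phase including the TC
# tunnel (a complicated patient stays on treatment); the one-time
# complication-management cost is attached to the TC and PC tunnel states,
# which by construction hold each patient for exactly one cycle.
.state_values <- function(cycle_cost, utilities, cycle_length_weeks) {
  u <- vapply(utilities[c("stable", "complication", "progression",
                          "prog_complication", "death")],
              function(p) p$base, numeric(1))
  cost <- c(SD = cycle_cost$on_treatment,
            SD_postC = cycle_cost$on_treatment,
            TC = cycle_cost$on_treatment + cycle_cost$complication_once,
            PROG = cycle_cost$progression,
            PROG_postC = cycle_cost$progression,
            PC = cycle_cost$progression + cycle_cost$complication_once,
            DEATH = 0)
  qaly <- cycle_qaly(
    c(SD = u[["stable"]], SD_postC = u[["stable"]],
      TC = u[["complication"]], PROG = u[["progression"]],
      PROG_postC = u[["progression"]], PC = u[["prog_complication"]],
      DEATH = 0),
    cycle_length_weeks)
  list(cost = cost[STATES], qaly = qaly[STATES])
}

# Counting weights over trace rows 0..n: which cycles accrue value, and
# with what discount factor.
.accrual_weights <- function(n_cycles, annual_rate, cycle_length_weeks,
                             counting, discounting, discounted = TRUE) {
  d <- if (discounted)
    discount_factor(0:n_cycles, annual_rate, cycle_length_weeks,
                    discounting)
  else rep(1, n_cycles + 1)
  ind_start <- c(rep(1, n_cycles), 0)
  ind_end <- c(0, rep(1, n_cycles))
  ind <- switch(counting,
    cycle_start = ind_start,
    cycle_end = ind_end,
    half_cycle = (ind_start + ind_end) / 2,
    stop("unknown counting convention '", counting, "'")
  )
  ind * d
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Per cycle, each state contributes occupancy times its per-cycle value:
#' the on-treatment cost over the stable phase (stable disease, its
#' post-complication twin, and the complication tunnel), the once-only
#' complication-management cost on the mass passing through a complication
#' tunnel state, and utility-weighted time in every alive state.  Cycles
#' are selected and weighted by the counting convention and discounted per
#' the discounting convention.
#'
#' @param trace A `cohort_trace`.
#' @param cycle_cost Output of [assemble_cycle_cost()].
#' @param utilities A [utility_set()].
#' @param cycle_length_weeks,annual_discount,counting,discounting Model
#'   constants, see [scenario()].
#' @param cost_counting,qaly_counting Optional per-quantity counting
#'   conventions overriding `counting`: costs incurred up front (drugs
#'   bought at the start of each cycle) pair naturally with
#'   `"cycle_start"`, while continuously accruing health outcomes pair
#'   with the `"half_cycle"` (life-table) correction.
#' @return An `arm_totals` object: `discounted_cost`, `discounted_qaly`,
#'   `undiscounted_cost`, `undiscounted_qaly`, and a per-cycle accrual
#'   `ledger` data frame (columns: cycle, cost_weight, qaly_weight, cost,
#'   qaly, complication_cost).
#' @export
accrue_values <- function(trace, cycle_cost, utilities,
                          cycle_length_weeks = 8, annual_discount = 0.035,
                          counting = "cycle_start",
                          discounting = "annualized",
                          cost_counting = counting,
                          qaly_counting = counting) {
  stopifnot(inherits(trace, "cohort_trace"), ncol(trace) == 7)
  n <- nrow(trace) - 1L
  vals <- .state_values(cycle_cost, utilities, cycle_length_weeks)
  cost_t <- as.numeric(trace %*% vals$cost)
  qaly_t <- as.numeric(trace %*% vals$qaly)
  compl_t <- (trace[, "TC"] + trace[, "PC"]) * cycle_cost$complication_once
  wt <- function(cnt, discounted)
    .accrual_weights(n, annual_discount, cycle_length_weeks, cnt,
                     discounting, discounted = discounted)
  wc <- wt(cost_counting, TRUE); wq <- wt(qaly_counting, TRUE)
  wc0 <- wt(cost_counting, FALSE); wq0 <- wt(qaly_counting, FALSE)
  structure(
    list(discounted_cost = sum(wc * cost_t),
         discounted_qaly = sum(wq * qaly_t),
         undiscounted_cost = sum(wc0 * cost_t),
         undiscounted_qaly = sum(wq0 * qaly_t),
         discounted_complication_cost = sum(wc * compl_t),
         ledger = data.frame(cycle = 0:n, cost_weight = wc,
                             qaly_weight = wq, cost = cost_t,
                             qaly = qaly_t, complication_cost = compl_t)),
    class = "arm_totals")
}

#' @export
print.arm_totals <- function(x, ...) {
  cat(sprintf(paste0("<arm_totals> discounted: $%.3f / %.6f QALY",
                     "  (undiscounted: $%.3f / %.6f)\n"),
              x$discounted_cost, x$discounted_qaly,
              x$undiscounted_cost, x$undiscounted_qaly))
  invisible(x)
}

#' Run one arm of a scenario end to end
#'
#' Convenience wrapper: builds the arm's transition matrix, propagates the
#' cohort, assembles cycle costs and accrues values under the scenario's
#' conventions.
#'
#' @param sc A `cea_scenario`.
#' @param arm Arm name.
#' @param prob_overrides Optional named numeric vector (`progression`,
#'   `death`, `complication`) replacing the arm's base probabilities.
#' @param cost_overrides Optional named numeric vector of cost-item base
#'   values, passed to [assemble_cycle_cost()].
#' @param utility_overrides Optional named numeric vector (names among
#'   `stable`, `complication`, `progression`, `prog_complication`)
#'   replacing base utilities.
#' @param renormalize Passed to [build_transition_matrix()].
#' @return A list with `matrix`, `trace`, `cycle_cost`, `totals`, and
#'   `renormalized` (count of rescaled rows).
#' @export
run_arm <- function(sc, arm, prob_overrides = NULL, cost_overrides = NULL,
                    utility_overrides = NULL, renormalize = FALSE) {
  a <- sc$arms[[arm]]
  if (is.null(a)) stop("unknown arm '", arm, "'")
  p <- .arm_probs(a$transitions)
  if (!is.null(prob_overrides)) p[names(prob_overrides)] <- prob_overrides
  P <- build_transition_matrix(p, renormalize = renormalize)
  trace <- run_cohort_trace(P, sc$model$n_cycles)
  cc <- assemble_cycle_cost(sc, arm, overrides = cost_overrides)
  ut <- a$utilities
  if (!is.null(utility_overrides)) {
    for (nm in names(utility_overrides)) {
      stopifnot(nm %in% c("stable", "complication", "progression",
                          "prog_complication"))
      ut[[nm]] <- prob_param(utility_overrides[[nm]],
                             utility_overrides[[nm]],
                             utility_overrides[[nm]])
    }
  }
  cnt <- .counting_of(sc$model)
  totals <- accrue_values(trace, cc, ut,
                          cycle_length_weeks = sc$model$cycle_length_weeks,
                          annual_discount = sc$model$annual_discount,
                          counting = sc$model$counting,
                          discounting = sc$model$discounting,
                          cost_counting = cnt[["cost"]],
                          qaly_counting = cnt[["qaly"]])
  list(matrix = P, trace = trace, cycle_cost = cc, totals = totals,
       renormalized = attr(P, "renormalized"))
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates individual patient paths through the same transition matrix
#' with the same counting, discounting and state values, and reports mean
#' discounted cost and QALYs with Monte-Carlo standard errors.  An
#' independent check on the cohort algebra: the cohort result is the exact
#' expectation the microsimulation estimates.
#'
#' @param P Transition matrix.
#' @param cycle_cost Output of [assemble_cycle_cost()].
#' @param utilities A [utility_set()].
#' @param n_cycles,cycle_length_weeks,annual_discount,counting,discounting
#'   Model constants matching the cohort run.
#' @param cost_counting,qaly_counting Per-quantity counting conventions,
#'   as in [accrue_values()].
#' @param n_patients Number of simulated patients.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return List with `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`,
#'   `n_patients`.
#' @export
microsim_oracle <- function(P, cycle_cost, utilities, n_cycles,
                            cycle_length_weeks = 8, annual_discount = 0.035,
                            counting = "cycle_start",
                            discounting = "annualized",
                            cost_counting = counting,
                            qaly_counting = counting,
                            n_patients = 10000, seed = 1L) {
  stopifnot(n_patients >= 1)
  vals <- .state_values(cycle_cost, utilities, cycle_length_weeks)
  wc <- .accrual_weights(n_cycles, annual_discount, cycle_length_weeks,
                         cost_counting, discounting)
  wq <- .accrual_weights(n_cycles, annual_discount, cycle_length_weeks,
                         qaly_counting, discounting)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  states <- rep(1L, n_patients)            # all start in SD
  cost_acc <- wc[1] * vals$cost[states]
  qaly_acc <- wq[1] * vals$qaly[states]
  for (t in seq_len(n_cycles)) {
    new_states <- states
    for (s in unique(states)) {
      idx <- which(states == s)
      new_states[idx] <- sample.int(7L, length(idx), replace = TRUE,
                                    prob = P[s, ])
    }
    states <- new_states
    cost_acc <- cost_acc + wc[t + 1] * vals$cost[states]
    qaly_acc <- qaly_acc + wq[t + 1] * vals$qaly[states]
  }
  list(mean_cost = mean(cost_acc),
       se_cost = stats::sd(cost_acc) / sqrt(n_patients),
       mean_qaly = mean(qaly_acc),
       se_qaly = stats::sd(qaly_acc) / sqrt(n_patients),
       n_patients = n_patients)
}

# Effective per-quantity counting conventions of a scenario's model block:
# `cost_counting` / `qaly_counting` override the shared `counting`.
.counting_of <- function(model) {
  c(cost = if (!is.null(model$cost_counting)) model$cost_counting
           else model$counting,
    qaly = if (!is.null(model$qaly_counting)) model$qaly_counting
           else model$counting)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
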