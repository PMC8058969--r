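# Scenario container: the complete model specification for a two-arm
# cost-effectiveness comparison, plus YAML (de)serialisation.

COUNTING_CONVENTIONS <- c("cycle_start", "cycle_end", "half_cycle")
DISCOUNT_CONVENTIONS <- c("annualized", "per_cycle")

#' Assemble a cost-effectiveness scenario
#'
#' The full specification of a two-arm Markov cohort comparison: per-arm
#' transition probabilities, utilities and cost multiplicities, a shared
#' cost-item table, and the model constants (cycle length, horizon,
#' discount rate, willingness-to-pay threshold, counting and discounting
#' conventions).
#'
#' Cost items live in one shared table (a drug's price is a single
#' parameter even when both arms use it); each arm selects items through a
#' named integer `multiplicities` vector (doses / fee counts per cycle) and
#' names its once-only complication-management item via
#' `complication_cost`.
#'
#' @param arms Named list of exactly two arms, each a list with components
#'   `transitions` ([arm_transitions()]), `utilities` ([utility_set()]),
#'   `multiplicities` (named non-negative integers keyed by cost-item
#'   name), and `complication_cost` (a cost-item name or `NULL`).
#' @param cost_items Named list of [cost_item()]s.
#' @param cycle_length_weeks Markov cycle length in weeks.
#' @param n_cycles Number of cycles to run.
#' @param annual_discount Annual discount rate applied to costs and QALYs.
#' @param wtp_threshold Willingness-to-pay threshold in USD/QALY.
#' @param counting State-membership counting convention: count occupancy at
#'   `"cycle_start"` (cycles 0..n-1), `"cycle_end"` (1..n) or
#'   `"half_cycle"` (the average of the two; the life-table correction).
#' @param cost_counting,qaly_counting Optional per-quantity counting
#'   conventions overriding `counting`: costs paid up front at each cycle
#'   pair naturally with `"cycle_start"`, continuously accrued health
#'   outcomes with `"half_cycle"`.  `NULL` (default) inherits `counting`.
#' @param discounting `"annualized"` discounts cycle t by
#'   `(1+r)^(-t * cycle_length/52)`; `"per_cycle"` treats each cycle as one
#'   compounding period, `(1+r)^(-t)`.
#' @param reference Name of the reference arm for incremental outcomes.
#' @param metadata Free-form provenance list (exchange rate, body size,
#'   notes); not used in computation.
#' @return An object of class `cea_scenario`.
#' @seealso [tas102_scenario()] for the bundled worked scenario,
#'   [read_scenario()] / [write_scenario()] for file I/O.
#' @export
scenario <- function(arms, cost_items = list(),
                     cycle_length_weeks = 8, n_cycles = 30,
                     annual_discount = 0.035, wtp_threshold = 117746,
                     counting = "cycle_start", discounting = "annualized",
                     cost_counting = NULL, qaly_counting = NULL,
                     reference = names(arms)[1], metadata = list()) {
  if (length(cost_items) && is.null(names(cost_items)))
    names(cost_items) <- vapply(cost_items, function(it) it$label,
                                character(1))
  model <- list(cycle_length_weeks = cycle_length_weeks,
                n_cycles = n_cycles,
                annual_discount = annual_discount,
                wtp_threshold = wtp_threshold,
                counting = counting, discounting = discounting,
                reference = reference)
  if (!is.null(cost_counting)) model$cost_counting <- cost_counting
  if (!is.null(qaly_counting)) model$qaly_counting <- qaly_counting
  sc <- structure(
    list(arms = arms, cost_items = cost_items,
         model = model,
         metadata = metadata),
    class = "cea_scenario")
  errs <- validate_scenario(sc)
  if (length(errs))
    stop("invalid scenario:\n  - ", paste(errs, collapse = "\n  - "))
  sc
}

#' Validate a scenario, returning every violation
#'
#' Checks ranges, orderings and transition-row feasibility and returns the
#' complete list of violations (an empty character vector when valid) —
#' never a partial model.
#'
#' @param sc A `cea_scenario`, or anything shaped like one.
#' @return Character vector of human-readable violations; `character(0)`
#'   if the scenario is valid.
#' @export
validate_scenario <- function(sc) {
  errs <- character(0)
  say <- function(...) errs <<- c(errs, paste0(...))
  if (!is.list(sc) || is.null(sc$arms) || is.null(sc$model)) {
    return("not a scenario: missing `arms` or `model` section")
  }
  m <- sc$model
  chk_num <- function(x, nm, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      say("model.", nm, " must be a finite number")
      FALSE
    } else if (x < lo || x > hi) {
      say("model.", nm, " = ", x, " outside [", lo, ", ", hi, "]")
      FALSE
    } else TRUE
  }
  chk_num(m$cycle_length_weeks, "cycle_length_weeks", lo = 1e-9)
  if (chk_num(m$n_cycles, "n_cycles", lo = 1) &&
      m$n_cycles != round(m$n_cycles))
    say("model.n_cycles must be an integer")
  chk_num(m$annual_discount, "annual_discount", lo = 0, hi = 1 - 1e-12)
  chk_num(m$wtp_threshold, "wtp_threshold", lo = 0)
  if (!isTRUE(m$counting %in% COUNTING_CONVENTIONS))
    say("model.counting must be one of ",
        paste(COUNTING_CONVENTIONS, collapse = ", "))
  for (nm in c("cost_counting", "qaly_counting"))
    if (!is.null(m[[nm]]) && !isTRUE(m[[nm]] %in% COUNTING_CONVENTIONS))
      say("model.", nm, " must be one of ",
          paste(COUNTING_CONVENTIONS, collapse = ", "))
  if (!isTRUE(m$discounting %in% DISCOUNT_CONVENTIONS))
    say("model.discounting must be one of ",
        paste(DISCOUNT_CONVENTIONS, collapse = ", "))
  if (length(sc$arms) != 2L || is.null(names(sc$arms)))
    say("`arms` must be a named list of exactly two arms")
  if (!is.null(names(sc$arms)) && !isTRUE(m$reference %in% names(sc$arms)))
    say("model.reference ('", m$reference, "') is not an arm name")

  chk_pp <- function(p, nm, utility = FALSE) {
    if (!inherits(p, "prob_param")) {
      say(nm, " is not a prob_param"); return(invisible(NULL))
    }
    if (!(0 <= p$min && p$min <= p$base && p$base <= p$max && p$max <= 1))
      say(nm, ": need 0 <= min <= base <= max <= 1, got [",
          p$min, ", ", p$base, ", ", p$max, "]")
  }
  for (arm in names(sc$arms)) {
    a <- sc$arms[[arm]]
    pre <- paste0("arms.", arm, ".")
    tr <- a$transitions
    if (is.null(tr)) { say(pre, "transitions section missing"); next }
    for (nm in c("progression", "death", "complication"))
      chk_pp(tr[[nm]], paste0(pre, "transitions.", nm))
    ok <- all(vapply(tr[c("progression", "death", "complication")],
                     inherits, logical(1), what = "prob_param"))
    if (ok) {
      if (tr$progression$base + tr$complication$base > 1)
        say(pre, "transitions: stable row infeasible, progression + ",
            "complication = ",
            tr$progression$base + tr$complication$base, " > 1")
      if (tr$death$base + tr$complication$base > 1)
        say(pre, "transitions: progression row infeasible, death + ",
            "complication = ",
            tr$death$base + tr$complication$base, " > 1")
    }
    ut <- a$utilities
    if (is.null(ut)) { say(pre, "utilities section missing"); next }
    for (nm in c("stable", "complication", "progression",
                 "prog_complication", "death"))
      chk_pp(ut[[nm]], paste0(pre, "utilities.", nm), utility = TRUE)
    if (inherits(ut$death, "prob_param") && ut$death$base != 0)
      say(pre, "utilities.death must be 0")
    mult <- a$multiplicities
    if (length(mult)) {
      if (is.null(names(mult)) || any(!nzchar(names(mult))))
        say(pre, "multiplicities must be a named vector")
      else {
        unknown <- setdiff(names(mult), names(sc$cost_items))
        if (length(unknown))
          say(pre, "multiplicities name unknown cost item(s): ",
              paste(unknown, collapse = ", "))
      }
      if (any(mult < 0) || any(mult != round(mult)))
        say(pre, "multiplicities must be non-negative integers")
    }
    if (!is.null(a$complication_cost) &&
        !isTRUE(a$complication_cost %in% names(sc$cost_items)))
      say(pre, "complication_cost names unknown item '",
          a$complication_cost, "'")
  }
  for (nm in names(sc$cost_items)) {
    it <- sc$cost_items[[nm]]
    if (!inherits(it, "cost_item")) {
      say("cost_items.", nm, " is not a cost_item"); next
    }
    if (!(0 <= it$min && it$min <= it$base && it$base <= it$max))
      say("cost_items.", nm, ": need 0 <= min <= base <= max")
  }
  errs
}

#' @export
print.cea_scenario <- function(x, ...) {
  m <- x$model
  cat("<cea_scenario> ", paste(names(x$arms), collapse = " vs "), "\n",
      sprintf("  %d cycles of %g weeks, %.1f%% annual discount (%s, %s)\n",
              m$n_cycles, m$cycle_length_weeks, 100 * m$annual_discount,
              m$counting, m$discounting),
      sprintf("  WTP threshold $%s/QALY, reference arm '%s'\n",
              format(m$wtp_threshold, big.mark = ","), m$reference),
      sprintf("  %d cost items\n", length(x$cost_items)), sep = "")
  invisible(x)
}

# ---- YAML serialisation -----------------------------------------------

.pp_to_list <- function(p) list(base = p$base, min = p$min, max = p$max,
                                dist = p$dist)
.pp_from_list <- function(x, what = "parameter") {
  need <- c("base", "min", "max")
  if (!all(need %in% names(x)))
    stop(what, " must have fields base/min/max")
  prob_param(as.numeric(x$base), as.numeric(x$min), as.numeric(x$max),
             dist = if (is.null(x$dist)) "beta_like" else x$dist)
}

#' Write a scenario to a YAML file
#'
#' The file round-trips: [read_scenario()] on the written file recovers a
#' scenario whose every numeric value is identical to the original.
#'
#' @param sc A `cea_scenario`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_scenario <- function(sc, file) {
  arms <- lapply(sc$arms, function(a) {
    list(transitions = lapply(a$transitions, .pp_to_list),
         utilities = lapply(unclass(a$utilities), .pp_to_list),
         multiplicities = as.list(a$multiplicities),
         complication_cost = a$complication_cost)
  })
  items <- lapply(sc$cost_items, function(it)
    list(base = it$base, min = it$min, max = it$max, dist = it$dist))
  doc <- list(model = sc$model, arms = arms, cost_items = items,
              metadata = sc$metadata)
  yaml::write_yaml(doc, file, precision = 15L)
  invisible(file)
}

#' Read and validate a scenario from a YAML file
#'
#' Parses the documented schema (`model`, `arms.<name>.{transitions,
#' utilities, multiplicities, complication_cost}`, `cost_items`,
#' `metadata`) and validates it, reporting every violation at once.
#'
#' @param file Path to a scenario YAML file.
#' @return A validated `cea_scenario`.
#' @export
read_scenario <- function(file) {
  doc <- yaml::read_yaml(file)
  known <- c("model", "arms", "cost_items", "metadata")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown top-level key(s) in scenario file: ",
         paste(unknown, collapse = ", "))
  for (sect in c("model", "arms"))
    if (is.null(doc[[sect]]))
      stop("scenario file is missing required section '", sect, "'")
  arms <- lapply(doc$arms, function(a) {
    tr <- lapply(a$transitions, .pp_from_list, what = "transition")
    ut_raw <- lapply(a$utilities, .pp_from_list, what = "utility")
    ut <- structure(ut_raw[c("stable", "complication", "progression",
                             "prog_complication", "death")],
                    class = "utility_set")
    mult <- unlist(a$multiplicities)
    mult <- if (is.null(mult)) numeric(0)
            else stats::setNames(as.numeric(mult), names(mult))
    list(transitions = structure(tr[c("progression", "death",
                                      "complication")],
                                 class = "arm_transitions"),
         utilities = ut, multiplicities = mult,
         complication_cost = a$complication_cost)
  })
  items <- lapply(names(doc$cost_items), function(nm) {
    it <- doc$cost_items[[nm]]
    cost_item(nm, as.numeric(it$base), as.numeric(it$min),
              as.numeric(it$max),
              dist = if (is.null(it$dist)) "gamma_like" else it$dist)
  })
  names(items) <- names(doc$cost_items)
  m <- doc$model
  for (nm in c("cycle_length_weeks", "n_cycles", "annual_discount",
               "wtp_threshold"))
    if (!is.null(m[[nm]]) && is.numeric(m[[nm]]))
      m[[nm]] <- as.numeric(m[[nm]])
  if (is.null(m$reference)) m$reference <- names(arms)[1]
  if (is.null(m$counting)) m$counting <- "cycle_start"
  if (is.null(m$discounting)) m$discounting <- "annualized"
  sc <- structure(list(arms = arms, cost_items = items, model = m,
                       metadata = doc$metadata),
                  class = "cea_scenario")
  errs <- validate_scenario(sc)
  if (length(errs))
    stop("invalid scenario file '", file, "':\n  - ",
         paste(errs, collapse = "\n  - "))
  sc
}
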