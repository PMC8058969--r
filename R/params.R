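# Parameter containers: probabilities, costs, utilities, and their
# sensitivity ranges / sampling distributions.

#' Probability parameter with a deterministic sensitivity range
#'
#' Bundles a per-cycle probability (or a 0-1 utility weight) with the
#' min/max range used in one-way sensitivity analysis and the distribution
#' family used in probabilistic sensitivity analysis.  When `min`/`max` are
#' omitted they default to `base * (1 - range_fraction)` and
#' `base * (1 + range_fraction)`, the latter capped at 1.
#'
#' @param base Base-case value in `[0, 1]`.
#' @param min,max Deterministic sensitivity bounds; defaults are +/-25%
#'   around `base` (capped at 1).
#' @param dist Sampling family for PSA: `"beta_like"` (the default for
#'   probabilities and utilities) or `"gamma_like"`.
#' @param range_fraction Fractional half-width used when `min`/`max` are
#'   omitted.
#' @return An object of class `prob_param` with fields `base`, `min`,
#'   `max`, `dist`.
#' @seealso [cost_item()], [build_psa_distribution()]
#' @export
prob_param <- function(base, min = NULL, max = NULL,
                       dist = c("beta_like", "gamma_like"),
                       range_fraction = 0.25) {
  dist <- match.arg(dist)
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  if (base < 0 || base > 1)
    stop("`base` must be a probability in [0, 1], got ", base)
  if (is.null(min)) min <- base * (1 - range_fraction)
  if (is.null(max)) max <- base::min(base * (1 + range_fraction), 1)
  if (!(min <= base && base <= max))
    stop("need min <= base <= max, got [", min, ", ", base, ", ", max, "]")
  if (min < 0 || max > 1)
    stop("probability range must stay inside [0, 1]")
  structure(list(base = base, min = min, max = max, dist = dist),
            class = "prob_param")
}

#' Cost item with a deterministic sensitivity range
#'
#' A direct medical cost in USD, with DSA bounds (default +/-25%) and a
#' gamma-family PSA distribution, mirroring a row of a cost input table.
#'
#' @param label Human-readable item label.
#' @param base Base-case cost in USD (non-negative).
#' @param min,max DSA bounds; default `base * (1 -/+ range_fraction)`.
#' @param dist Sampling family; costs are `"gamma_like"`.
#' @param range_fraction Fractional half-width for the default range.
#' @return An object of class `cost_item`.
#' @export
cost_item <- function(label, base, min = NULL, max = NULL,
                      dist = "gamma_like", range_fraction = 0.25) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(base), length(base) == 1L, is.finite(base))
  if (base < 0) stop("cost `base` must be non-negative")
  if (is.null(min)) min <- base * (1 - range_fraction)
  if (is.null(max)) max <- base * (1 + range_fraction)
  if (!(0 <= min && min <= base && base <= max))
    stop("need 0 <= min <= base <= max for cost item '", label, "'")
  structure(list(label = label, base = base, min = min, max = max,
                 dist = dist),
            class = "cost_item")
}

#' Per-arm transition probabilities
#'
#' The three per-cycle probabilities driving one arm of the model:
#' progression (stable -> progressed), death (progressed -> dead) and
#' complication onset.  Death is reachable only through progression, so no
#' direct stable -> death probability exists.
#'
#' @param progression,death,complication Each a [prob_param()] or a bare
#'   numeric (converted with the default +/-25% range).
#' @return An object of class `arm_transitions`.
#' @export
arm_transitions <- function(progression, death, complication) {
  as_pp <- function(x) if (inherits(x, "prob_param")) x else prob_param(x)
  out <- structure(list(progression = as_pp(progression),
                        death = as_pp(death),
                        complication = as_pp(complication)),
                   class = "arm_transitions")
  if (out$progression$base + out$complication$base > 1)
    stop("infeasible stable-state row: progression + complication = ",
         out$progression$base + out$complication$base, " > 1")
  out
}

#' Health-state utilities for one arm
#'
#' Annual utility weights by health state.  Complication-state utilities
#' default to (and are varied in sensitivity analyses tied to) their parent
#' states: treatment-complication follows stable disease, progression-with-
#' complication follows progression.  Death is fixed at 0.
#'
#' @param stable,progression Utilities for the stable-disease and
#'   progression states, as [prob_param()] or bare numerics.
#' @param complication,prog_complication Complication-state utilities;
#'   default to `stable` and `progression` respectively.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(stable, progression,
                        complication = stable,
                        prog_complication = progression) {
  as_pp <- function(x) if (inherits(x, "prob_param")) x else prob_param(x)
  structure(list(stable = as_pp(stable),
                 complication = as_pp(complication),
                 progression = as_pp(progression),
                 prog_complication = as_pp(prog_complication),
                 death = prob_param(0, 0, 0)),
            class = "utility_set")
}

#' Convert a survival median to a per-cycle transition probability
#'
#' Declining Exponential Approximation of Life Expectancy (DEALE): survival
#' is treated as exponential with rate `log(2) / median`, so the
#' probability of transitioning within one cycle is
#' `1 - exp(-log(2) / median * cycle_length)`.  `median` and `cycle_length`
#' must be in the same time unit.
#'
#' @param median Median survival (> 0).
#' @param cycle_length Cycle length in the same unit (> 0).
#' @return Per-cycle transition probability; vectorised.
#' @examples
#' median_to_transition_prob(6.4, 8 / 4.345)  # median OS in months, 8-week cycle
#' @export
median_to_transition_prob <- function(median, cycle_length) {
  if (any(!is.finite(median)) || any(median <= 0))
    stop("`median` must be positive and finite")
  if (any(!is.finite(cycle_length)) || any(cycle_length < 0))
    stop("`cycle_length` must be non-negative and finite")
  1 - exp(-log(2) / median * cycle_length)
}

#' Rescale a per-cycle probability to a different cycle length
#'
#' Constant-rate change of time step: `1 - (1 - p)^(to_len / from_len)`.
#'
#' @param p Per-cycle probability in `[0, 1]`.
#' @param from_len,to_len Old and new cycle lengths (> 0, same unit).
#' @return Probability per `to_len`-long cycle; vectorised over `p`.
#' @export
prob_rescale <- function(p, from_len, to_len) {
  if (any(p < 0) || any(p > 1)) stop("`p` must be in [0, 1]")
  if (any(from_len <= 0) || any(to_len <= 0))
    stop("cycle lengths must be positive")
  1 - (1 - p)^(to_len / from_len)
}

#' Convert Japanese yen to US dollars
#'
#' @param amount Amount in JPY.
#' @param exchange_rate JPY per USD; default 110.05 (2019 rate used by the
#'   bundled scenario).
#' @return Amount in USD.
#' @export
jpy_to_usd <- function(amount, exchange_rate = 110.05) {
  stopifnot(is.numeric(amount), all(is.finite(amount)), exchange_rate > 0)
  amount / exchange_rate
}

#' Assemble per-cycle state costs for one arm
#'
#' Sums the arm's drug and fee costs per cycle (item base value times the
#' arm's per-cycle multiplicity) into the on-treatment cost, and pulls out
#' the once-only complication-management cost.  Post-progression routine
#' care carries no cost: after progression only the one-time complication
#' cost can accrue.
#'
#' @param scenario A `cea_scenario` (see [scenario()]).
#' @param arm Arm name, e.g. `"monotherapy"` or `"combination"`.
#' @param overrides Optional named numeric vector of cost-item base values
#'   (keyed by item name) replacing the scenario's, used by sensitivity
#'   analyses.
#' @return A list with components `on_treatment`, `complication_once`,
#'   `progression` (always 0), all USD per cycle / per event.
#' @export
assemble_cycle_cost <- function(scenario, arm, overrides = NULL) {
  arm_spec <- scenario$arms[[arm]]
  if (is.null(arm_spec)) stop("unknown arm '", arm, "'")
  items <- scenario$cost_items
  bases <- vapply(items, function(it) it$base, numeric(1))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(bases))
    if (length(unknown))
      stop("cost override names not in scenario: ",
           paste(unknown, collapse = ", "))
    bases[names(overrides)] <- overrides
  }
  mult <- arm_spec$multiplicities
  if (length(mult)) {
    unknown <- setdiff(names(mult), names(bases))
    if (length(unknown))
      stop("multiplicity refers to unknown cost item(s): ",
           paste(unknown, collapse = ", "))
    if (any(mult < 0)) stop("multiplicities must be non-negative")
  }
  on_treatment <- if (length(mult)) sum(bases[names(mult)] * mult) else 0
  compl_label <- arm_spec$complication_cost
  complication_once <- 0
  if (!is.null(compl_label)) {
    if (!compl_label %in% names(bases))
      stop("complication cost refers to unknown item '", compl_label, "'")
    complication_once <- bases[[compl_label]]
  }
  list(on_treatment = on_treatment,
       complication_once = complication_once,
       progression = 0)
}

#' Build a PSA sampling distribution for a parameter
#'
#' Moment-matched second-order distribution: the sampler's mean equals the
#' base value and its dispersion is chosen so the central ~95% of the mass
#' spans `[min, max]`, i.e. `sd = (max - min) / (2 * 1.96)`.  Probabilities
#' and utilities use a beta distribution (support `[0, 1]`); costs use a
#' gamma distribution (support `[0, Inf)`).  A degenerate range
#' (`min == max == base`) yields a point mass, as does a gamma item with
#' `base == 0` (with a warning when its range is non-degenerate).
#'
#' @param param A [prob_param()] or [cost_item()].
#' @return An object of class `psa_sampler`: a list with `draw(n)` (uses
#'   the current RNG stream), `dist`, `mean`, `sd`.
#' @export
build_psa_distribution <- function(param) {
  stopifnot(inherits(param, "prob_param") || inherits(param, "cost_item"))
  base <- param$base
  s <- (param$max - param$min) / (2 * 1.96)
  point_mass <- function(v, lab) {
    structure(list(draw = function(n) rep(v, n),
                   dist = lab, mean = v, sd = 0),
              class = "psa_sampler")
  }
  if (s == 0) return(point_mass(base, "point_mass"))
  if (param$dist == "beta_like") {
    v <- s^2
    if (v >= base * (1 - base))
      stop("beta moment matching infeasible: variance ", v,
           " >= mean*(1-mean) for base ", base)
    nu <- base * (1 - base) / v - 1
    a <- base * nu
    b <- (1 - base) * nu
    structure(list(draw = function(n) stats::rbeta(n, a, b),
                   dist = "beta", mean = base, sd = s,
                   shape1 = a, shape2 = b),
              class = "psa_sampler")
  } else {
    if (base == 0) {
      warning("gamma-like parameter with base 0 and positive range: ",
              "using a point mass at 0")
      return(point_mass(0, "point_mass"))
    }
    shape <- (base / s)^2
    rate <- base / s^2
    structure(list(draw = function(n) stats::rgamma(n, shape, rate),
                   dist = "gamma", mean = base, sd = s,
                   shape = shape, rate = rate),
              class = "psa_sampler")
  }
}

#' @export
print.prob_param <- function(x, ...) {
  cat(sprintf("<prob_param> base %.8g [%.8g, %.8g] (%s)\n",
              x$base, x$min, x$max, x$dist))
  invisible(x)
}

#' @export
print.cost_item <- function(x, ...) {
  cat(sprintf("<cost_item> %s: $%.6g [%.6g, %.6g] (%s)\n",
              x$label, x$base, x$min, x$max, x$dist))
  invisible(x)
}
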