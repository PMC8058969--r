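# Sensitivity analyses: one-way deterministic (tornado), probabilistic
# (PSA) with cost-effectiveness acceptability curve and CE-plane export.

# Enumerate the varied parameters of a scenario: per-arm transition
# probabilities, shared cost items, and per-arm stable/progression
# utilities (complication-state utilities move with their parents).
.varied_parameters <- function(sc) {
  out <- list()
  for (arm in names(sc$arms)) {
    tr <- sc$arms[[arm]]$transitions
    for (nm in c("progression", "death", "complication"))
      out[[paste(arm, nm, sep = ".")]] <-
        list(kind = "transition", arm = arm, name = nm, param = tr[[nm]])
    ut <- sc$arms[[arm]]$utilities
    for (nm in c("stable", "progression")) {
      p <- ut[[nm]]
      if (p$base > 0)
        out[[paste(arm, "utility", nm, sep = ".")]] <-
          list(kind = "utility", arm = arm, name = nm, param = p)
    }
  }
  for (nm in names(sc$cost_items))
    out[[paste("cost", nm, sep = ".")]] <-
      list(kind = "cost", name = nm, param = sc$cost_items[[nm]])
  out
}

# Run the base case with a single parameter forced to `value`.
.run_with_parameter <- function(sc, par, value, renormalize = FALSE) {
  arms <- names(sc$arms)
  ref <- sc$model$reference
  cmp <- setdiff(arms, ref)
  ov <- list()
  for (a in arms)
    ov[[a]] <- list(prob = NULL, cost = NULL, util = NULL)
  if (par$kind == "transition") {
    ov[[par$arm]]$prob <- stats::setNames(value, par$name)
  } else if (par$kind == "cost") {
    co <- stats::setNames(value, par$name)
    for (a in arms) ov[[a]]$cost <- co
  } else if (par$kind == "utility") {
    tied <- if (par$name == "stable") c("stable", "complication")
            else c("progression", "prog_complication")
    ov[[par$arm]]$util <- stats::setNames(rep(value, length(tied)), tied)
  } else stop("unknown parameter kind '", par$kind, "'")
  runs <- lapply(stats::setNames(arms, arms), function(a)
    run_arm(sc, a, prob_overrides = ov[[a]]$prob,
            cost_overrides = ov[[a]]$cost,
            utility_overrides = ov[[a]]$util,
            renormalize = renormalize))
  icer(runs[[ref]]$totals, runs[[cmp]]$totals,
       wtp = sc$model$wtp_threshold, arm_names = c(ref, cmp))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full base case twice per parameter — once at its minimum,
#' once at its maximum, all other parameters at base — and records the
#' resulting ICERs.  Entries are sorted by non-increasing width
#' `|icer_at_max - icer_at_min|`.  A parameter extreme that makes a
#' transition row infeasible is flagged rather than silently clipped.
#'
#' @param sc A `cea_scenario`.
#' @param parameters Optional character vector of parameter labels to
#'   vary (defaults to every tabulated probability, cost item and non-zero
#'   utility; structural constants are not varied).
#' @return A data frame of class `tornado` with columns `parameter`,
#'   `icer_at_min`, `icer_at_max`, `width`, `infeasible`.
#' @export
dsa_tornado <- function(sc, parameters = NULL) {
  pars <- .varied_parameters(sc)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, names(pars))
    if (length(missing))
      stop("unknown parameter(s): ", paste(missing, collapse = ", "))
    pars <- pars[parameters]
  }
  rows <- lapply(names(pars), function(lbl) {
    par <- pars[[lbl]]
    at <- function(v) {
      tryCatch(list(icer = .run_with_parameter(sc, par, v)$icer,
                    infeasible = FALSE),
               error = function(e) list(icer = NA_real_, infeasible = TRUE))
    }
    lo <- at(par$param$min)
    hi <- at(par$param$max)
    data.frame(parameter = lbl,
               icer_at_min = lo$icer, icer_at_max = hi$icer,
               width = abs(hi$icer - lo$icer),
               infeasible = lo$infeasible || hi$infeasible,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws every varied parameter independently from its moment-matched
#' distribution ([build_psa_distribution()]), re-runs both arms per draw,
#' and records per-draw costs, QALYs and incrementals.  Shared cost items
#' are sampled once per draw and used in both arms.  Sampled transition
#' rows that turn infeasible are renormalised (self-loop to zero, exits
#' rescaled proportionally) and counted in `renormalized_rows`.
#' Deterministic given `seed`.
#'
#' @param sc A `cea_scenario`.
#' @param n_draws Number of re-samplings.
#' @param seed RNG seed (logged in the result).
#' @return A `psa_result`: `n_draws`, `seed`, `renormalized_rows`, and
#'   `draws` — a data frame with one row per draw holding every sampled
#'   parameter value plus `cost_<ref>`, `qaly_<ref>`, `cost_<cmp>`,
#'   `qaly_<cmp>`, `delta_cost`, `delta_qaly`.
#' @export
psa_run <- function(sc, n_draws = 1000, seed = 20210420) {
  stopifnot(n_draws >= 0)
  arms <- names(sc$arms)
  ref <- sc$model$reference
  cmp <- setdiff(arms, ref)
  pars <- .varied_parameters(sc)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  samples <- vapply(pars, function(p) build_psa_distribution(p$param)$draw(n_draws),
                    numeric(n_draws))
  if (n_draws == 1L) samples <- matrix(samples, nrow = 1,
                                       dimnames = list(NULL, names(pars)))
  n_renorm <- 0L
  res <- matrix(NA_real_, n_draws, 6)
  colnames(res) <- c(paste0(c("cost_", "qaly_"), rep(c(ref, cmp), each = 2)),
                     "delta_cost", "delta_qaly")
  for (i in seq_len(n_draws)) {
    draw <- samples[i, ]
    runs <- lapply(stats::setNames(arms, arms), function(a) {
      pk <- paste(a, c("progression", "death", "complication"), sep = ".")
      prob <- stats::setNames(draw[pk],
                              c("progression", "death", "complication"))
      uo <- c()
      for (nm in c("stable", "progression")) {
        key <- paste(a, "utility", nm, sep = ".")
        if (key %in% names(draw)) {
          tied <- if (nm == "stable") c("stable", "complication")
                  else c("progression", "prog_complication")
          uo <- c(uo, stats::setNames(rep(draw[[key]], length(tied)), tied))
        }
      }
      ck <- grep("^cost\\.", names(draw), value = TRUE)
      co <- stats::setNames(draw[ck], sub("^cost\\.", "", ck))
      run_arm(sc, a, prob_overrides = prob, cost_overrides = co,
              utility_overrides = if (length(uo)) uo else NULL,
              renormalize = TRUE)
    })
    n_renorm <- n_renorm +
      sum(vapply(runs, function(r) r$renormalized, integer(1)))
    res[i, ] <- c(runs[[ref]]$totals$discounted_cost,
                  runs[[ref]]$totals$discounted_qaly,
                  runs[[cmp]]$totals$discounted_cost,
                  runs[[cmp]]$totals$discounted_qaly,
                  runs[[cmp]]$totals$discounted_cost -
                    runs[[ref]]$totals$discounted_cost,
                  runs[[cmp]]$totals$discounted_qaly -
                    runs[[ref]]$totals$discounted_qaly)
  }
  draws <- cbind(data.frame(draw = seq_len(n_draws)),
                 as.data.frame(samples), as.data.frame(res))
  structure(list(n_draws = n_draws, seed = seed,
                 reference = ref, comparator = cmp,
                 renormalized_rows = n_renorm, draws = draws),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %s), %s vs %s\n",
              x$n_draws, format(x$seed), x$comparator, x$reference))
  if (x$n_draws) {
    cat(sprintf("  mean incremental cost $%.1f, mean incremental QALY %.4f\n",
                mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
    if (x$renormalized_rows)
      cat("  renormalized transition rows: ", x$renormalized_rows, "\n",
          sep = "")
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the comparator
#' is cost-effective is the fraction of PSA draws with positive
#' incremental net monetary benefit, `wtp * dQALY - dCost > 0`
#' (ties go to the reference).  The two strategies' probabilities sum
#' to 1 at every grid point.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay grid in USD/QALY; default 0 to
#'   150,000 in steps of 1,000.
#' @return A data frame of class `ceac_curve` with columns `wtp`,
#'   `p_<reference>`, `p_<comparator>`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 150000, by = 1000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (!length(wtp_grid)) stop("empty willingness-to-pay grid")
  if (!psa$n_draws) stop("PSA has no draws")
  dq <- psa$draws$delta_qaly
  dc <- psa$draws$delta_cost
  p_cmp <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, p_ref = 1 - p_cmp, p_cmp = p_cmp)
  names(out) <- c("wtp", paste0("p_", psa$reference),
                  paste0("p_", psa$comparator))
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Cost-effectiveness plane export
#'
#' One `(incremental QALY, incremental cost)` pair per PSA draw, with
#' quadrant counts (NE: more effective and more costly, etc.) attached as
#' attribute `"quadrants"`.
#'
#' @param psa A `psa_result`.
#' @return Data frame with columns `draw`, `delta_qaly`, `delta_cost`.
#' @export
ce_plane <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  d <- psa$draws
  out <- data.frame(draw = d$draw, delta_qaly = d$delta_qaly,
                    delta_cost = d$delta_cost)
  quadrants <- c(
    NE = sum(d$delta_qaly > 0 & d$delta_cost > 0),
    NW = sum(d$delta_qaly < 0 & d$delta_cost > 0),
    SW = sum(d$delta_qaly < 0 & d$delta_cost < 0),
    SE = sum(d$delta_qaly > 0 & d$delta_cost < 0))
  attr(out, "quadrants") <- quadrants
  out
}
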