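# Comparative outcomes: incremental cost, incremental QALY, ICER with
# dominance classification, net monetary benefit, base-case report, and
# the convention/multiplicity calibration sweep.

.cost_qaly <- function(x) {
  if (inherits(x, "arm_totals"))
    c(cost = x$discounted_cost, qaly = x$discounted_qaly)
  else {
    stopifnot(is.list(x) || is.numeric(x))
    c(cost = x[["cost"]], qaly = x[["qaly"]])
  }
}

#' Incremental cost-effectiveness ratio between two arms
#'
#' Computes incremental cost and QALYs of the comparator over the
#' reference, classifies dominance, and reports the ICER where defined.
#' `dominant` means cheaper and more effective (no ICER is reported);
#' `dominated` the reverse; otherwise the arms are `comparable` and
#' ICER = incremental cost / incremental QALY.  With zero incremental
#' QALYs the ICER is undefined and cost-effectiveness is decided by the
#' sign of the incremental cost.
#'
#' @param ref_totals,new_totals Discounted [accrue_values()] results (or
#'   lists with `cost` and `qaly`) for the reference and comparator arm.
#' @param wtp Willingness-to-pay threshold in USD/QALY.
#' @param arm_names Length-2 character vector naming reference and
#'   comparator.
#' @return A `cea_result`: per-arm cost/QALY, `incremental_cost`,
#'   `incremental_qaly`, `icer` (NA when undefined or dominant/dominated),
#'   `dominance` label, `wtp_threshold`, `cost_effective`.
#' @export
icer <- function(ref_totals, new_totals, wtp,
                 arm_names = c("reference", "comparator")) {
  ref <- .cost_qaly(ref_totals)
  new <- .cost_qaly(new_totals)
  d_cost <- new[["cost"]] - ref[["cost"]]
  d_qaly <- new[["qaly"]] - ref[["qaly"]]
  dominance <-
    if (d_cost < 0 && d_qaly > 0) "dominant"
    else if (d_cost > 0 && d_qaly < 0) "dominated"
    else "comparable"
  ratio <- if (d_qaly != 0) d_cost / d_qaly else NA_real_
  icer_val <- if (dominance == "comparable") ratio else NA_real_
  cost_effective <-
    if (dominance == "dominant") TRUE
    else if (dominance == "dominated") FALSE
    else if (d_qaly == 0) d_cost < 0
    else d_qaly > 0 && icer_val <= wtp
  structure(
    list(arms = stats::setNames(
           list(as.list(ref), as.list(new)), arm_names),
         reference = arm_names[1], comparator = arm_names[2],
         incremental_cost = d_cost, incremental_qaly = d_qaly,
         icer = icer_val, dominance = dominance,
         wtp_threshold = wtp, cost_effective = cost_effective),
    class = "cea_result")
}

#' Net monetary benefit
#'
#' `wtp * QALYs - cost`: converts effectiveness to money so strategies can
#' be ranked on one scale; the strategy with the larger NMB at a given
#' willingness-to-pay is the cost-effective one.
#'
#' @param totals An `arm_totals` or a list with `cost` and `qaly`.
#' @param wtp Willingness-to-pay in USD/QALY (>= 0).
#' @return NMB in USD.
#' @export
nmb <- function(totals, wtp) {
  stopifnot(wtp >= 0)
  x <- .cost_qaly(totals)
  wtp * x[["qaly"]] - x[["cost"]]
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> ", x$comparator, " vs ", x$reference, "\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cea_result <- function(x, ...) {
  arms <- names(x$arms)
  data.frame(
    arm = arms,
    cost = vapply(x$arms, function(a) a$cost, numeric(1)),
    qaly = vapply(x$arms, function(a) a$qaly, numeric(1)),
    incremental_cost = c(NA, x$incremental_cost),
    incremental_qaly = c(NA, x$incremental_qaly),
    icer = c(NA, x$icer),
    dominance = c("(reference)", x$dominance),
    row.names = NULL)
}

#' Base-case analysis of a scenario
#'
#' Runs both arms through the Markov engine under the scenario's
#' conventions and compares the comparator against the reference arm.
#'
#' @param sc A `cea_scenario`.
#' @return A `cea_result` with the per-arm `arm_runs` (traces and accrual
#'   ledgers) attached as an attribute.
#' @export
base_case <- function(sc) {
  arms <- names(sc$arms)
  ref <- sc$model$reference
  cmp <- setdiff(arms, ref)
  if (length(cmp) != 1L) stop("scenario must have exactly two arms")
  runs <- lapply(stats::setNames(arms, arms), function(a) run_arm(sc, a))
  res <- icer(runs[[ref]]$totals, runs[[cmp]]$totals,
              wtp = sc$model$wtp_threshold, arm_names = c(ref, cmp))
  attr(res, "arm_runs") <- runs
  res
}

# ---- Convention / multiplicity calibration ----------------------------

#' Printed base-case surface of the bundled comparison
#'
#' The published base-case totals used as default calibration targets:
#' per-arm discounted cost and QALYs, incremental cost and QALYs.
#'
#' @return Named list of target values (USD and QALY).
#' @export
published_base_case <- function() {
  list(cost_monotherapy = 3434.834, qaly_monotherapy = 0.501,
       cost_combination = 8424.188, qaly_combination = 0.73,
       incremental_cost = 4989.354, incremental_qaly = 0.231)
}

.default_multiplicity_grid <- function() {
  list(
    monotherapy = expand.grid(
      tas102 = 1:2,
      admin_fee_monotherapy = 0:2,
      chemo_admin_fee = 0:2,
      outpatient_service_fee = 0:2,
      prescription_fee = 0:2),
    combination = expand.grid(
      tas102 = 1:2,
      bevacizumab = 0:4,
      admin_fee_combination = 0:2,
      iv_drip_fee = 0:2,
      chemo_admin_fee = 0:2,
      outpatient_service_fee = 0:2,
      prescription_fee = 0:2))
}

#' Calibrate counting/discounting conventions and dose multiplicities
#'
#' The source analysis does not document its cycle-counting or discounting
#' convention, nor the per-cycle dose and fee counts behind its cost
#' totals.  This sweep enumerates counting conventions (separately for
#' costs and QALYs — up-front costs pair with cycle-start counting,
#' continuously accrued outcomes with the half-cycle correction) crossed
#' with discounting conventions and a bounded integer grid of per-cycle
#' multiplicities, evaluates the model under each configuration, and
#' returns the configuration minimising the maximum relative deviation
#' from the supplied targets.  Deterministic: ties break to the first
#' configuration in enumeration order.
#'
#' QALY targets depend only on the conventions; cost targets additionally
#' on the multiplicities, so for each convention combination the cohort
#' trace is run once per arm and cost totals are assembled arithmetically
#' over the grid.
#'
#' @param sc A `cea_scenario`.
#' @param targets Named list of target values; any subset of the names in
#'   [published_base_case()] (the default).
#' @param counting_grid,discounting_grid Convention values to sweep; the
#'   counting grid is applied independently to costs and QALYs.
#' @param multiplicity_grid Named list (one entry per arm) of data frames,
#'   one column per cost-item name, one row per candidate multiplicity
#'   assignment; `NULL` freezes each arm at its scenario multiplicities.
#'   The default grid varies drug doses and fee counts over small integer
#'   ranges.
#' @return A `cea_calibration`: `best` (list with `counting`,
#'   `discounting`, per-arm `multiplicities`, `objective`, achieved
#'   `values` and per-target `deviations`), `report` (one row per
#'   convention pair with its best multiplicities and objective), and
#'   `targets`.
#' @seealso [apply_calibration()]
#' @export
calibrate_conventions <- function(sc, targets = published_base_case(),
                                  counting_grid = COUNTING_CONVENTIONS,
                                  discounting_grid = DISCOUNT_CONVENTIONS,
                                  multiplicity_grid =
                                    .default_multiplicity_grid()) {
  if (!length(counting_grid) || !length(discounting_grid))
    stop("empty convention grid")
  arms <- names(sc$arms)
  ref <- sc$model$reference
  cmp <- setdiff(arms, ref)
  tnames <- names(targets)
  tv <- function(nm) if (nm %in% tnames) targets[[nm]] else NULL
  # map target names onto reference/comparator arms
  t_cost <- list(); t_qaly <- list()
  t_cost[[ref]] <- tv(paste0("cost_", ref)); t_qaly[[ref]] <- tv(paste0("qaly_", ref))
  t_cost[[cmp]] <- tv(paste0("cost_", cmp)); t_qaly[[cmp]] <- tv(paste0("qaly_", cmp))
  t_dcost <- tv("incremental_cost"); t_dqaly <- tv("incremental_qaly")
  rel <- function(x, target)
    if (target == 0) abs(x) else abs(x - target) / abs(target)

  bases <- vapply(sc$cost_items, function(it) it$base, numeric(1))
  grid_for <- function(arm) {
    g <- multiplicity_grid[[arm]]
    if (is.null(g)) {
      m <- sc$arms[[arm]]$multiplicities
      g <- as.data.frame(as.list(m))
      names(g) <- names(m)
    }
    unknown <- setdiff(names(g), names(bases))
    if (length(unknown))
      stop("multiplicity grid for arm '", arm,
           "' names unknown cost item(s): ", paste(unknown, collapse = ", "))
    g
  }
  grids <- lapply(stats::setNames(arms, arms), grid_for)
  # per-candidate on-treatment cost per cycle
  cyc_cost <- lapply(grids, function(g)
    as.numeric(as.matrix(g) %*% bases[names(g)]))

  report <- list()
  best <- NULL
  for (cnt_c in counting_grid) for (cnt_q in counting_grid)
  for (dsc in discounting_grid) {
    sc2 <- sc
    sc2$model$counting <- cnt_c
    sc2$model$cost_counting <- cnt_c
    sc2$model$qaly_counting <- cnt_q
    sc2$model$discounting <- dsc
    # one trace per arm; cost totals are linear in the per-cycle cost
    agg <- lapply(stats::setNames(arms, arms), function(a) {
      r <- run_arm(sc2, a)
      w <- r$totals$ledger$cost_weight
      tr <- r$trace
      list(qaly = r$totals$discounted_qaly,
           treat_time = sum(w * rowSums(tr[, c("SD", "SD_postC", "TC")])),
           compl_time = sum(w * (tr[, "TC"] + tr[, "PC"])),
           compl_cost = assemble_cycle_cost(sc2, a)$complication_once)
    })
    qaly_dev <- 0
    for (a in arms)
      if (!is.null(t_qaly[[a]]))
        qaly_dev <- max(qaly_dev, rel(agg[[a]]$qaly, t_qaly[[a]]))
    if (!is.null(t_dqaly))
      qaly_dev <- max(qaly_dev,
                      rel(agg[[cmp]]$qaly - agg[[ref]]$qaly, t_dqaly))
    cost_cand <- lapply(stats::setNames(arms, arms), function(a)
      cyc_cost[[a]] * agg[[a]]$treat_time +
        agg[[a]]$compl_cost * agg[[a]]$compl_time)
    dev_arm <- lapply(stats::setNames(arms, arms), function(a)
      if (is.null(t_cost[[a]])) rep(0, length(cost_cand[[a]]))
      else rel(cost_cand[[a]], t_cost[[a]]))
    # objective over the ref x cmp candidate product
    obj <- outer(dev_arm[[ref]], dev_arm[[cmp]], pmax)
    if (!is.null(t_dcost)) {
      dmat <- outer(cost_cand[[ref]], cost_cand[[cmp]],
                    function(r, c) rel(c - r, t_dcost))
      obj <- pmax(obj, dmat)
    }
    obj <- pmax(obj, qaly_dev)
    # primary: minimise the worst deviation; secondary: among ties,
    # minimise the summed cost deviations (first index on exact ties)
    devsum <- outer(dev_arm[[ref]], dev_arm[[cmp]], "+")
    if (!is.null(t_dcost)) devsum <- devsum + dmat
    cand <- which(obj <= min(obj) + 1e-12)
    k <- arrayInd(cand[which.min(devsum[cand])], dim(obj))
    i_ref <- k[1]; i_cmp <- k[2]
    idx <- stats::setNames(list(i_ref, i_cmp), c(ref, cmp))
    mult <- lapply(stats::setNames(arms, arms), function(a) {
      row <- grids[[a]][idx[[a]], , drop = FALSE]
      v <- as.numeric(row)
      names(v) <- names(row)
      v[v > 0]
    })
    vals <- list()
    vals[[paste0("cost_", ref)]] <- cost_cand[[ref]][i_ref]
    vals[[paste0("qaly_", ref)]] <- agg[[ref]]$qaly
    vals[[paste0("cost_", cmp)]] <- cost_cand[[cmp]][i_cmp]
    vals[[paste0("qaly_", cmp)]] <- agg[[cmp]]$qaly
    vals$incremental_cost <- cost_cand[[cmp]][i_cmp] - cost_cand[[ref]][i_ref]
    vals$incremental_qaly <- agg[[cmp]]$qaly - agg[[ref]]$qaly
    devs <- vapply(tnames, function(nm) rel(vals[[nm]], targets[[nm]]),
                   numeric(1))
    entry <- list(cost_counting = cnt_c, qaly_counting = cnt_q,
                  discounting = dsc,
                  multiplicities = mult, objective = min(obj),
                  values = vals, deviations = devs)
    report[[paste(cnt_c, cnt_q, dsc, sep = "+")]] <- entry
    if (is.null(best) || entry$objective < best$objective) best <- entry
  }
  rep_df <- do.call(rbind, lapply(report, function(e)
    data.frame(cost_counting = e$cost_counting,
               qaly_counting = e$qaly_counting,
               discounting = e$discounting,
               objective = e$objective,
               t(vapply(tnames, function(nm) e$values[[nm]], numeric(1))),
               row.names = NULL)))
  structure(list(best = best, report = rep_df, details = report,
                 targets = targets),
            class = "cea_calibration")
}

#' @export
print.cea_calibration <- function(x, ...) {
  b <- x$best
  cat(sprintf(paste0("<cea_calibration> best: costs %s, QALYs %s, %s ",
                     "(max relative deviation %.4f)\n"),
              b$cost_counting, b$qaly_counting, b$discounting,
              b$objective))
  for (a in names(b$multiplicities)) {
    m <- b$multiplicities[[a]]
    cat("  ", a, ": ",
        paste(sprintf("%s x%d", names(m), as.integer(m)), collapse = ", "),
        "\n", sep = "")
  }
  cat("  deviations: ",
      paste(sprintf("%s %.3f", names(b$deviations), b$deviations),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Apply a calibration result to a scenario
#'
#' @param sc A `cea_scenario`.
#' @param calibration A `cea_calibration` (or its `best` component).
#' @return The scenario with counting/discounting conventions and per-arm
#'   multiplicities replaced by the calibrated configuration.
#' @export
apply_calibration <- function(sc, calibration) {
  b <- if (inherits(calibration, "cea_calibration")) calibration$best
       else calibration
  sc$model$counting <- b$cost_counting
  sc$model$cost_counting <- b$cost_counting
  sc$model$qaly_counting <- b$qaly_counting
  sc$model$discounting <- b$discounting
  for (a in names(b$multiplicities))
    sc$arms[[a]]$multiplicities <- b$multiplicities[[a]]
  sc
}
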