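# Three-criterion screening: contractile force (A), loss factor (B),
# modulus increase (C); sequential funnel and dose-threshold rules.

#' Screening criteria configuration
#'
#' Thresholds and per-condition verdict rules for the three criteria:
#' A, contractile force: diameter-baselined force difference above
#' `cf_min_difference`; B, purity: loss factor below `tan_delta_max` in
#' solution; C, mechanical recovery: complex-modulus increase above
#' `delta_Estar_min` between the paired before/after states.
#'
#' The default verdict rules follow the study design: majority of
#' replicates for A, all replicates for B (one sample above 0.4 demotes
#' the condition), group means for C.
#'
#' @param tan_delta_max Loss-factor ceiling (default 0.4).
#' @param cf_min_difference CF difference floor (N, default 3 uN).
#' @param delta_Estar_min Modulus-increase floor (Pa, default 5 kPa).
#' @param rule_cf,rule_tan Verdict rule for criteria A and B: one of
#'   `"majority"`, `"all_replicates"`, `"any"`, `"mean"`.
#' @return List of class `criteria_config`.
#' @export
criteria_config <- function(tan_delta_max = 0.4, cf_min_difference = 3e-6,
                            delta_Estar_min = 5e3,
                            rule_cf = "majority",
                            rule_tan = "all_replicates") {
  if (tan_delta_max <= 0 || cf_min_difference <= 0 || delta_Estar_min <= 0)
    stop("thresholds must be positive")
  rules <- c("majority", "all_replicates", "any", "mean")
  structure(list(tan_delta_max = tan_delta_max,
                 cf_min_difference = cf_min_difference,
                 delta_Estar_min = delta_Estar_min,
                 rule_cf = match.arg(rule_cf, rules),
                 rule_tan = match.arg(rule_tan, rules)),
            class = "criteria_config")
}

apply_rule <- function(pass_vec, value_vec, threshold, rule, direction) {
  ok <- pass_vec[!is.na(pass_vec)]
  if (!length(ok)) return(NA)
  mean_ok <- if (direction == "gt") mean(value_vec, na.rm = TRUE) > threshold
             else mean(value_vec, na.rm = TRUE) < threshold
  switch(rule,
         majority = mean(ok) > 0.5,
         all_replicates = all(ok),
         any = any(ok),
         mean = mean_ok)
}

known_factor_cols <- c("combination", "DS", "C_g", "C_LAP", "dose_uM",
                       "alginate", "cacl2", "diameter_um")

condition_key <- function(df, cols) {
  do.call(paste, c(lapply(cols, function(cc) df[[cc]]), sep = "|"))
}

#' Evaluate the three screening criteria per condition
#'
#' Aggregates a per-sample summary table (see [analyze_population()]) to
#' per-condition criterion values and verdicts. Criterion C needs a paired
#' `before` table (same condition columns) carrying the pre-perturbation
#' complex modulus; when absent it is marked not evaluable rather than
#' failed. Non-measurable samples are excluded upstream.
#'
#' @param after Per-sample summary data.frame of the measured end state,
#'   with condition columns plus `cf_diff_uN`, `tan_delta`, `E_star_kPa`.
#' @param config A [criteria_config()].
#' @param before Optional per-sample summary of the paired reference state
#'   (pre-differentiation bundle, or pre-degradation composite) with
#'   `E_star_kPa`.
#' @param condition_cols Columns identifying a condition; defaults to the
#'   known grid factors present in `after`.
#' @return data.frame of class `screening_result`: one row per condition
#'   with `n`, `cf_diff_uN`, `pass_cf`, `mean_tan_delta`, `max_tan_delta`,
#'   `pass_tan`, `delta_Estar_kPa`, `pass_estar`.
#' @export
evaluate_criteria <- function(after, config = criteria_config(),
                              before = NULL, condition_cols = NULL) {
  condition_cols <- condition_cols %||%
    intersect(known_factor_cols, names(after))
  if (!length(condition_cols)) stop("no condition columns found")
  if ("measurable" %in% names(after)) after <- after[after$measurable, ]
  key <- condition_key(after, condition_cols)
  before_key <- if (!is.null(before))
    condition_key(before, intersect(condition_cols, names(before)))
  rows <- list()
  for (kk in unique(key)) {
    d <- after[key == kk, , drop = FALSE]
    row <- d[1, condition_cols, drop = FALSE]
    row$n <- nrow(d)
    cf <- d$cf_diff_uN
    row$cf_diff_uN <- mean(cf, na.rm = TRUE)
    row$pass_cf <- apply_rule(cf > config$cf_min_difference * 1e6, cf,
                              config$cf_min_difference * 1e6,
                              config$rule_cf, "gt")
    td <- d$tan_delta
    row$mean_tan_delta <- mean(td, na.rm = TRUE)
    row$max_tan_delta <- if (all(is.na(td))) NA_real_ else max(td, na.rm = TRUE)
    row$pass_tan <- apply_rule(td < config$tan_delta_max, td,
                               config$tan_delta_max, config$rule_tan, "lt")
    if (!is.null(before) && any(before_key == kk)) {
      dE <- mean(d$E_star_kPa, na.rm = TRUE) -
        mean(before$E_star_kPa[before_key == kk], na.rm = TRUE)
      row$delta_Estar_kPa <- dE
      row$pass_estar <- dE > config$delta_Estar_min / 1e3
    } else {
      row$delta_Estar_kPa <- NA_real_
      row$pass_estar <- NA
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Sequential screening funnel
#'
#' Filters conditions through the criteria in order (default A, B, C:
#' contractile force, then loss factor, then modulus increase), returning
#' per-stage survivor counts and each condition's funnel stage. Because the
#' criteria are pure predicates the final selected set does not depend on
#' the order; the staged counts do.
#'
#' @param results A `screening_result` from [evaluate_criteria()].
#' @param order Criterion order, a permutation of `c("cf", "tan",
#'   "estar")`.
#' @return List with `counts` (named: entering count then survivors after
#'   each stage), `stage` (per-condition label: `rejected_<criterion>`,
#'   `not_evaluable_<criterion>` or `selected`) and `selected` (row indices
#'   of surviving conditions).
#' @export
screening_funnel <- function(results, order = c("cf", "tan", "estar")) {
  stopifnot(setequal(order, c("cf", "tan", "estar")))
  pass_cols <- c(cf = "pass_cf", tan = "pass_tan", estar = "pass_estar")
  alive <- rep(TRUE, nrow(results))
  stage <- rep("selected", nrow(results))
  counts <- c(entering = sum(alive))
  for (cr in order) {
    p <- results[[pass_cols[cr]]]
    rej <- alive & !is.na(p) & !p
    ne <- alive & is.na(p)
    stage[rej] <- paste0("rejected_", cr)
    stage[ne] <- paste0("not_evaluable_", cr)
    alive <- alive & !rej & !ne
    counts[paste0("after_", cr)] <- sum(alive)
  }
  list(counts = counts, stage = stage, selected = which(alive))
}

#' Dose threshold by the monotone-prefix rule
#'
#' Returns the largest dose `d` such that every dose at or below `d`
#' passes; a pass pattern that is not a prefix (a failing dose below a
#' passing one) is flagged as non-monotone. Input order is irrelevant.
#'
#' @param doses Numeric doses.
#' @param pass Logical pass/fail per dose.
#' @return List with `threshold` (largest prefix-passing dose, or `NA` with
#'   `below_minimum = TRUE` when even the lowest dose fails) and
#'   `non_monotone`.
#' @export
dose_threshold <- function(doses, pass) {
  stopifnot(length(doses) == length(pass), !anyNA(doses))
  o <- order(doses)
  doses <- doses[o]; pass <- as.logical(pass[o])
  if (anyNA(pass)) stop("pass pattern contains NA")
  if (!any(pass))
    return(list(threshold = NA_real_, below_minimum = TRUE,
                non_monotone = FALSE))
  first_fail <- which(!pass)[1]
  if (is.na(first_fail))
    return(list(threshold = doses[length(doses)], below_minimum = FALSE,
                non_monotone = FALSE))
  if (first_fail == 1)
    return(list(threshold = NA_real_, below_minimum = TRUE,
                non_monotone = any(pass)))
  list(threshold = doses[first_fail - 1],
       below_minimum = FALSE,
       non_monotone = any(pass[first_fail:length(pass)]))
}

#' Reference outcome table of the hypoxia dose screen
#'
#' The per-dose three-criterion outcomes of the CoCl2 hypoxia study on
#' exosome-protected muscle-fiber repair, as established after
#' culture-period optimization (screening passes at all doses up to and
#' including 120 uM and fails from 140 uM upward) and under the original
#' un-optimized 3+3-day schedule (contractile force already fails above
#' 80 uM, the loss factor above 120 uM).
#'
#' @param culture_period `"optimized"` or `"standard"`.
#' @return data.frame with `dose_uM`, `pass_cf`, `pass_tan`, `pass_estar`,
#'   `pass` (all three).
#' @export
cocl2_reference_outcomes <- function(culture_period = c("optimized",
                                                        "standard")) {
  culture_period <- match.arg(culture_period)
  d <- condition_grid("cocl2_14")$dose_uM
  if (culture_period == "optimized") {
    pass_cf <- d <= 120
    pass_tan <- d <= 120
  } else {
    pass_cf <- d <= 80
    pass_tan <- d <= 120
  }
  pass_estar <- d <= 160
  data.frame(dose_uM = d, pass_cf = pass_cf, pass_tan = pass_tan,
             pass_estar = pass_estar,
             pass = pass_cf & pass_tan & pass_estar)
}

#' Reference loss factors of the eleven CF-positive bioink combinations
#'
#' Worked example of the second screening stage on the 54-combination
#' composite-bioink grid: the eleven combinations that passed the
#' contractile-force criterion, with their measured in-solution loss
#' factors. The two exclusions carry their reported values (0.75 at
#' alginate 0.8 / CaCl2 0.5 / diameter 300 um; 0.718 at 0.7 / 1 / 300);
#' the remaining nine, which passed `tan delta < 0.4`, carry
#' representative sub-0.4 values.
#'
#' @return data.frame with `alginate`, `cacl2`, `diameter_um`,
#'   `tan_delta`.
#' @export
bioink_cf_survivors_reference <- function() {
  data.frame(
    alginate    = c(0.7, 0.8, 0.8, 0.7, 0.6, 0.6, 0.7, 0.7, 0.7, 0.8, 0.6),
    cacl2       = c(1,   1,   0.5, 1,   1.5, 1,   1.5, 1,   0.5, 1.5, 1),
    diameter_um = c(200, 200, 300, 300, 110, 200, 200, 110, 200, 200, 110),
    tan_delta   = c(0.21, 0.25, 0.75, 0.718, 0.33, 0.28, 0.31, 0.22,
                    0.35, 0.30, 0.38))
}
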