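#' Unit reimbursement schedule
#'
#' Unit reimbursements granted for the two procedures, and the counting rules
#' applied when a procedure is repeated.  Defaults are the Italian NHS
#' (Campania rate table) reimbursements used throughout the analysis:
#' EUR 129.50 per FNAC (US guidance, ROSE, processing, ancillary techniques
#' if any, interpretation and report) and EUR 1666.64 per surgical biopsy
#' (day-surgery admission, excision, histology and report).  Follow-up visits
#' and ancillary techniques carry no cost here.
#'
#' The default counting rules reproduce the published accounting: repeat
#' FNACs are billed (545 aspirations on 535 lymphadenopathies) while the one
#' surgical biopsy repeated after excision of the wrong node is not billed
#' twice (131 biopsy costs, not 132).  Both rules are exposed as flags so the
#' asymmetry is a choice, not a hard-coded fact.
#'
#' @param fnac_unit_cost Reimbursement per FNAC procedure, EUR.
#' @param sb_unit_cost Reimbursement per surgical biopsy, EUR.
#' @param count_fnac_repeats Bill repeat FNAC procedures? (default `TRUE`)
#' @param count_sb_repeats Bill repeated biopsy procedures beyond the first?
#'   (default `FALSE`)
#' @return An object of class `cost_schedule`.
#' @export
cost_schedule <- function(fnac_unit_cost = 129.50, sb_unit_cost = 1666.64,
                          count_fnac_repeats = TRUE, count_sb_repeats = FALSE) {
  if (!is.numeric(fnac_unit_cost) || fnac_unit_cost <= 0 ||
      !is.numeric(sb_unit_cost) || sb_unit_cost <= 0) {
    rlang::abort("unit costs must be positive numbers")
  }
  structure(list(
    fnac_unit_cost = fnac_unit_cost,
    sb_unit_cost = sb_unit_cost,
    count_fnac_repeats = isTRUE(count_fnac_repeats),
    count_sb_repeats = isTRUE(count_sb_repeats)
  ), class = "cost_schedule")
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("Cost schedule: FNAC ", format_eur(x$fnac_unit_cost),
      ", surgical biopsy ", format_eur(x$sb_unit_cost),
      "\n  repeat FNACs billed: ", x$count_fnac_repeats,
      "; repeat biopsies billed: ", x$count_sb_repeats, "\n", sep = "")
  invisible(x)
}

# Billable procedure counts for a cohort under a schedule.
billable_counts <- function(feats, schedule) {
  list(
    n = nrow(feats),
    fnac = if (schedule$count_fnac_repeats) sum(feats$n_fnac) else nrow(feats),
    sb = if (schedule$count_sb_repeats) sum(feats$n_sb_procedures)
         else sum(feats$sb_patient)
  )
}

new_cost_report <- function(strategy, total, sb_total, per_state, n) {
  structure(list(
    strategy = strategy,
    total_cost = total,
    cost_per_patient = total / n,
    sb_component_per_patient = sb_total / n,
    sb_component_share = if (total > 0) sb_total / total else NA_real_,
    per_initial_state_cost = per_state,
    n_lymphadenopathies = n
  ), class = "cost_report")
}

#' Cost of the FNAC-first diagnostic strategy
#'
#' Accumulates, over the whole cohort, the cost of the first FNAC performed in
#' every case plus any repeat FNAC plus any surgical biopsy, following the
#' billing flags of the [cost_schedule()].  The per-patient figure divides the
#' total by the number of lymphadenopathies; the biopsy component is reported
#' separately because it dominates the total.
#'
#' @param cohort A non-empty cohort tibble.
#' @param schedule A [cost_schedule()].
#' @return An object of class `cost_report` with `total_cost`,
#'   `cost_per_patient`, `sb_component_per_patient`, `sb_component_share`
#'   (unrounded fractions of a euro; round at presentation with
#'   [round_half_up()]) and the per-initial-state breakdown of
#'   [cost_by_initial_state()].
#' @examples
#' rep <- cost_fnac_first(reference_cohort())
#' round_half_up(rep$cost_per_patient)
#' @export
cost_fnac_first <- function(cohort, schedule = cost_schedule()) {
  cohort <- as_cohort(cohort)
  stopifnot_cohort_nonempty(cohort, "cost_fnac_first()")
  feats <- pathway_features(cohort)
  b <- billable_counts(feats, schedule)
  total <- schedule$fnac_unit_cost * b$fnac + schedule$sb_unit_cost * b$sb
  new_cost_report(
    "fnac_first", total, schedule$sb_unit_cost * b$sb,
    cost_by_initial_state(cohort, schedule), b$n
  )
}

#' Cost of the upfront-surgery comparator strategy
#'
#' The comparator assumes every clinically suspicious lymphadenopathy goes
#' straight to excisional biopsy with no prior cytology, so the cost per
#' patient is the biopsy reimbursement itself, for any cohort.
#'
#' @inheritParams cost_fnac_first
#' @return A `cost_report` (see [cost_fnac_first()]).
#' @export
cost_sb_only <- function(cohort, schedule = cost_schedule()) {
  cohort <- as_cohort(cohort)
  stopifnot_cohort_nonempty(cohort, "cost_sb_only()")
  n <- nrow(cohort)
  per_state <- dplyr::count(tibble::as_tibble(cohort),
                            initial_state = factor(.data$initial_state,
                                                   levels = dx_states()),
                            .drop = FALSE, name = "n")
  per_state <- dplyr::mutate(
    per_state,
    initial_state = as.character(.data$initial_state),
    n_fnac_billed = 0L,
    n_sb_billed = .data$n,
    total_cost = schedule$sb_unit_cost * .data$n,
    cost_per_patient = dplyr::if_else(.data$n > 0, schedule$sb_unit_cost,
                                      NA_real_)
  )
  new_cost_report("sb_only", schedule$sb_unit_cost * n,
                  schedule$sb_unit_cost * n, per_state, n)
}

#' Diagnostic cost stratified by first-FNAC result
#'
#' Per-patient FNAC-first cost within each initial state: the FNAC procedures
#' performed on patients entering in that state (repeat aspirations attach to
#' the patient's initial state) plus the biopsies among them, divided by the
#' number of patients entering in that state.
#'
#' @inheritParams cost_fnac_first
#' @return A tibble with one row per diagnostic state: `initial_state`, `n`,
#'   `n_fnac_billed`, `n_sb_billed`, `total_cost`, `cost_per_patient`
#'   (`NA` for states with no patients).
#' @examples
#' cost_by_initial_state(reference_cohort())
#' @export
cost_by_initial_state <- function(cohort, schedule = cost_schedule()) {
  cohort <- as_cohort(cohort)
  stopifnot_cohort_nonempty(cohort, "cost_by_initial_state()")
  feats <- pathway_features(cohort)
  feats$initial_state <- factor(feats$initial_state, levels = dx_states())
  out <- dplyr::summarise(
    dplyr::group_by(feats, .data$initial_state, .drop = FALSE),
    n = dplyr::n(),
    n_fnac_billed = if (schedule$count_fnac_repeats) sum(.data$n_fnac)
                    else dplyr::n(),
    n_sb_billed = if (schedule$count_sb_repeats) sum(.data$n_sb_procedures)
                  else sum(.data$sb_patient),
    .groups = "drop"
  )
  dplyr::mutate(
    tibble::as_tibble(out),
    initial_state = as.character(.data$initial_state),
    n_fnac_billed = as.integer(.data$n_fnac_billed),
    n_sb_billed = as.integer(.data$n_sb_billed),
    total_cost = schedule$fnac_unit_cost * .data$n_fnac_billed +
      schedule$sb_unit_cost * .data$n_sb_billed,
    cost_per_patient = dplyr::if_else(.data$n > 0, .data$total_cost / .data$n,
                                      NA_real_)
  )
}

#' Compare the FNAC-first and upfront-surgery strategies
#'
#' The headline cost-minimization comparison: the per-patient saving obtained
#' by triaging with FNAC, and the cost ratio of the two strategies.
#'
#' @inheritParams cost_fnac_first
#' @return A one-row tibble: `fnac_first_per_patient`, `sb_only_per_patient`,
#'   `saving_per_patient` (upfront-surgery minus FNAC-first) and `cost_ratio`
#'   (FNAC-first / upfront-surgery, a fraction).
#' @examples
#' compare_strategies(reference_cohort())
#' @export
compare_strategies <- function(cohort, schedule = cost_schedule()) {
  fnac <- cost_fnac_first(cohort, schedule)
  sb <- cost_sb_only(cohort, schedule)
  tibble::tibble(
    fnac_first_per_patient = fnac$cost_per_patient,
    sb_only_per_patient = sb$cost_per_patient,
    saving_per_patient = sb$cost_per_patient - fnac$cost_per_patient,
    cost_ratio = fnac$cost_per_patient / sb$cost_per_patient
  )
}

#' One-way sensitivity of the per-patient saving
#'
#' Varies a single parameter over a grid, holding the cohort's empirical
#' procedure mix fixed, and reports the per-patient saving of FNAC-first over
#' upfront surgery at each value.  With `F` billed FNACs, `B` billed biopsies
#' and `n` lymphadenopathies, the saving is linear in each parameter:
#'
#' * `fnac_unit_cost` `x`:  `saving = c_sb - (x * F + c_sb * B) / n`
#' * `sb_unit_cost` `x`:    `saving = x * (1 - B / n) - c_fnac * F / n`
#' * `biopsy_rate` `r`:     `saving = c_sb * (1 - r) - c_fnac * F / n`
#'
#' The exact break-even value (saving = 0) is solved from the linear form and
#' appended to the table as a `break_even = TRUE` row.
#'
#' @inheritParams cost_fnac_first
#' @param parameter One of `"fnac_unit_cost"`, `"sb_unit_cost"`,
#'   `"biopsy_rate"`.
#' @param values Non-empty numeric grid of parameter values (costs in EUR,
#'   biopsy rate as a fraction in \[0, 1\]).
#' @return A tibble of class `sensitivity_table` with columns `parameter`,
#'   `value`, `saving_per_patient`, `break_even`, ordered by `value`; the
#'   break-even value is also available as `attr(x, "break_even")`.
#' @examples
#' one_way_sensitivity(reference_cohort(), parameter = "sb_unit_cost",
#'                     values = seq(0, 2000, by = 500))
#' @export
one_way_sensitivity <- function(cohort, schedule = cost_schedule(),
                                parameter = c("fnac_unit_cost", "sb_unit_cost",
                                              "biopsy_rate"),
                                values) {
  parameter <- rlang::arg_match(parameter)
  if (missing(values) || length(values) == 0) {
    rlang::abort("`values` must be a non-empty numeric grid")
  }
  cohort <- as_cohort(cohort)
  stopifnot_cohort_nonempty(cohort, "one_way_sensitivity()")
  feats <- pathway_features(cohort)
  b <- billable_counts(feats, schedule)
  cf <- schedule$fnac_unit_cost
  cs <- schedule$sb_unit_cost

  saving_fun <- switch(parameter,
    fnac_unit_cost = function(x) cs - (x * b$fnac + cs * b$sb) / b$n,
    sb_unit_cost = function(x) x * (1 - b$sb / b$n) - cf * b$fnac / b$n,
    biopsy_rate = function(r) cs * (1 - r) - cf * b$fnac / b$n
  )
  break_even <- switch(parameter,
    fnac_unit_cost = cs * (b$n - b$sb) / b$fnac,
    sb_unit_cost = cf * b$fnac / (b$n - b$sb),
    biopsy_rate = 1 - cf * b$fnac / (b$n * cs)
  )

  grid <- tibble::tibble(
    parameter = parameter,
    value = as.numeric(values),
    saving_per_patient = saving_fun(as.numeric(values)),
    break_even = FALSE
  )
  grid <- dplyr::bind_rows(grid, tibble::tibble(
    parameter = parameter, value = break_even,
    saving_per_patient = saving_fun(break_even), break_even = TRUE
  ))
  grid <- dplyr::arrange(grid, .data$value)
  structure(grid, break_even = break_even,
            class = c("sensitivity_table", class(grid)))
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Cost report — strategy: ", x$strategy, " (n = ",
      x$n_lymphadenopathies, ")\n", sep = "")
  cat("  total cost:           ", format_eur(x$total_cost), "\n", sep = "")
  cat("  cost per patient:     ", format_eur(x$cost_per_patient), "\n", sep = "")
  cat("  biopsy component:     ", format_eur(x$sb_component_per_patient),
      " per patient (", formatC(round_half_up(100 * x$sb_component_share, 2),
                                format = "f", digits = 2),
      "% of total)\n", sep = "")
  cat("  per initial state (EUR/patient): ",
      paste0(x$per_initial_state_cost$initial_state, "=",
             ifelse(is.na(x$per_initial_state_cost$cost_per_patient), "-",
                    formatC(round_half_up(
                      x$per_initial_state_cost$cost_per_patient, 2),
                      format = "f", digits = 2)),
             collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cost_report <- function(x, ...) {
  x$per_initial_state_cost
}

#' @export
glance.cost_report <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    n_lymphadenopathies = x$n_lymphadenopathies,
    total_cost = x$total_cost,
    cost_per_patient = x$cost_per_patient,
    sb_component_per_patient = x$sb_component_per_patient,
    sb_component_share = x$sb_component_share
  )
}
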