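#' Plot state occupancy at entry and at conclusion
#'
#' Bar chart of the number of lymphadenopathies per diagnostic state, at the
#' first FNAC and after the model has run.
#'
#' @param object A [tally_cohort()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cohort_tally <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tidy(object)[c("initial_state", "n", "n_final")],
    cols = c("n", "n_final"),
    names_to = "when", values_to = "count"
  )
  df$when <- factor(df$when, levels = c("n", "n_final"),
                    labels = c("first FNAC", "model conclusion"))
  df$initial_state <- factor(df$initial_state, levels = dx_states())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$initial_state, y = .data$count,
                                   fill = .data$when)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "diagnostic state", y = "lymphadenopathies",
                  fill = NULL, title = "State occupancy") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' 2x2 tile plot of the cytology call against the reference-standard truth.
#'
#' @param object A [confusion_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tibble::tibble(
    call = factor(c("positive", "positive", "negative", "negative"),
                  levels = c("positive", "negative")),
    truth = factor(c("malignant", "benign", "malignant", "benign"),
                   levels = c("malignant", "benign")),
    count = c(object$tp, object$fp, object$fn, object$tn),
    label = c("TP", "FP", "FN", "TN")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$call,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$label, "\n", .data$count))) +
    ggplot2::scale_fill_gradient(low = "grey92", high = "steelblue") +
    ggplot2::labs(x = "reference standard", y = "FNAC call",
                  title = paste0("Confusion matrix (",
                                 object$reference, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a one-way sensitivity analysis
#'
#' Per-patient saving of the FNAC-first strategy as the varied parameter
#' moves across its grid, with the break-even point marked.
#'
#' @param object A [one_way_sensitivity()] table.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  be <- attr(object, "break_even")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$saving_per_patient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object[object$break_even, ],
                        colour = "firebrick", size = 2) +
    ggplot2::annotate("text", x = be, y = 0, vjust = -1, hjust = 0,
                      colour = "firebrick",
                      label = paste0("break-even: ",
                                     formatC(be, format = "g", digits = 4))) +
    ggplot2::labs(x = object$parameter[1],
                  y = "saving per patient (EUR)",
                  title = "One-way sensitivity of the FNAC-first saving") +
    ggplot2::theme_minimal()
}
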