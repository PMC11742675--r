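#' Plot a step histogram, optionally with a fitted binomial model
#'
#' @param object A `step_histogram`.
#' @param scan Optional `stoich_scan`; the best model's truncated pmf is
#'   overlaid as expected counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.step_histogram <- function(object, scan = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$n)) +
    ggplot2::geom_col(fill = "#6a51a3", width = 0.8) +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "steps / states per particle (k)",
                  y = "particles") +
    ggplot2::theme_minimal()
  if (!is.null(scan)) {
    m <- attr(scan, "best_m"); p_hat <- attr(scan, "best_p_hat")
    n_total <- attr(object, "n_total") %||% sum(object$n)
    model <- tibble::tibble(
      k = seq_len(m),
      n = n_total * binomial_label_pmf(seq_len(m), m, p_hat,
                                       truncated = attr(scan, "truncated")))
    p <- p + ggplot2::geom_line(data = model, colour = "grey30") +
      ggplot2::geom_point(data = model, colour = "grey30")
  }
  p
}

#' Plot a stoichiometry model scan
#'
#' Labeling error and fit residual as a function of the candidate
#' oligomer order; the selected order minimizes both.
#'
#' @param object A `stoich_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stoich_scan <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::filter(is.finite(.data$labeling_error)) |>
    tidyr::pivot_longer(cols = c("labeling_error", "residual"),
                        names_to = "criterion", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::geom_vline(xintercept = attr(object, "best_m"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "monomers per oligomer (m)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a CODEX fit
#'
#' Measured points, the fitted exchange decay, and the fitted plateau
#' (1/N) as a dashed line.
#'
#' @param object A `codex_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codex_fit <- function(object, ...) {
  curve <- object$curve
  tt <- seq(min(curve$mixing_time_s), max(curve$mixing_time_s),
            length.out = 200)
  fit <- tibble::tibble(
    mixing_time_s = tt,
    signal = codex_signal(tt, object$n_continuous, object$rate_per_s))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$mixing_time_s,
                                      y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, colour = "#2171b5") +
    ggplot2::geom_hline(yintercept = object$plateau_hat,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "mixing time (s)", y = "normalized CODEX signal") +
    ggplot2::theme_minimal()
}

#' Plot a CSP profile
#'
#' Per-residue average CSP with the similar/dissimilar cutoff as a dotted
#' line; similar residues in green, dissimilar in pink.
#'
#' @param object A `csp_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csp_profile <- function(object, ...) {
  cutoff <- attr(object, "cutoff_ppm")
  d <- object[!is.na(object$average_csp_ppm), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue_number,
                                  y = .data$average_csp_ppm,
                                  fill = .data$similar)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#41ab5d",
                                          `FALSE` = "#f768a1"),
                               labels = c(`TRUE` = "similar",
                                          `FALSE` = "dissimilar"),
                               name = NULL) +
    ggplot2::labs(x = "residue", y = "average CSP (ppm)") +
    ggplot2::theme_minimal()
}
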