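#' Binomial label-count probability
#'
#' Probability that an m-mer carries k labeled subunits when each subunit
#' is labeled independently with probability p: C(m,k) p^k (1-p)^(m-k).
#' With `truncated = TRUE` the probability is conditioned on k >= 1
#' (at least one label, i.e. the particle is visible), dividing by
#' 1 - (1-p)^m.
#'
#' @param k Label count(s), integer(s) in 0..m (1..m if truncated).
#' @param m Oligomer order (integer >= 1).
#' @param p Labeling fraction.
#' @param truncated Condition on k >= 1.
#' @return Probability vector of the same length as `k`.
#' @examples
#' binomial_label_pmf(2, m = 4, p = 0.25)            # 0.2109375
#' binomial_label_pmf(1, m = 4, p = 0.25, truncated = TRUE)
#' @export
binomial_label_pmf <- function(k, m, p, truncated = FALSE) {
  m <- stopifnot_count(m, "m", min = 1L)
  stopifnot_scalar_prob(p)
  if (any(k != trunc(k)) || any(k < 0) || any(k > m)) {
    abort("`k` must be integer(s) in 0..m.")
  }
  if (!truncated) return(dbinom(k, size = m, prob = p))
  if (p == 0) abort("Truncated pmf is undefined at p = 0.")
  if (any(k < 1)) abort("Truncated pmf requires k >= 1.")
  dbinom(k, size = m, prob = p) / (1 - (1 - p)^m)
}

#' Relative labeling-efficiency error
#'
#' |fitted - experimental| / experimental: the relative deviation of a
#' fitted labeling efficiency from the experimentally set labeling
#' fraction. Used as the model-selection score across candidate oligomer
#' orders.
#'
#' @param p_fit Fitted labeling efficiency.
#' @param p_experimental Experimental labeling fraction (> 0).
#' @return Non-negative ratio.
#' @examples
#' labeling_error(0.27, 0.25) # 0.08
#' @export
labeling_error <- function(p_fit, p_experimental) {
  if (any(p_experimental <= 0)) {
    abort("`p_experimental` must be > 0.")
  }
  abs(p_fit - p_experimental) / p_experimental
}

#' Nominal labeling fraction from a mixing ratio
#'
#' The labeling fraction implied by mixing labeled and unlabeled protein
#' at a given molar ratio: labeled / (labeled + unlabeled). One part
#' labeled to three parts unlabeled gives 0.25.
#'
#' @param labeled_parts,unlabeled_parts Non-negative mixing parts;
#'   `labeled_parts` must be > 0.
#' @return Fraction in (0, 1].
#' @examples
#' nominal_labeling_fraction(1, 3) # 0.25
#' @export
nominal_labeling_fraction <- function(labeled_parts, unlabeled_parts) {
  if (labeled_parts <= 0 || unlabeled_parts < 0) {
    abort("Mixing parts must be positive (labeled) and non-negative.")
  }
  labeled_parts / (labeled_parts + unlabeled_parts)
}

hist_counts_ <- function(hist) {
  if (!is.data.frame(hist) || !all(c("k", "n") %in% names(hist))) {
    abort("A step histogram needs columns `k` and `n`.")
  }
  if (any(hist$n < 0)) abort("Histogram counts must be non-negative.")
  n_zero <- sum(hist$n[hist$k == 0])
  hist <- hist[hist$k >= 1 & hist$n > 0, ]
  if (nrow(hist) == 0) abort("Histogram is empty.")
  attr(hist, "n_zero_bin") <- n_zero
  hist
}

#' Fit the labeling efficiency for one candidate oligomer order
#'
#' Least-squares fit of the binomial label-count model to a step-count
#' histogram: finds the p minimizing the sum of squared differences
#' between observed relative frequencies over k = 1..m and the model pmf
#' (zero-truncated by default, since unlabeled particles are invisible).
#' The minimization is a bounded scalar search on p in (0, 1) with
#' tolerance 1e-9. A maximum-likelihood alternative (multinomial over the
#' observed bins) is available via `method = "ml"`.
#'
#' If the histogram contains counts at k > m the model cannot explain the
#' data; the fit is returned marked infeasible with an infinite residual
#' rather than raising an error.
#'
#' @param hist Step histogram: tibble with columns `k`, `n` (as from
#'   [build_step_histogram()]).
#' @param m Candidate oligomer order.
#' @param truncated Use the zero-truncated pmf (default `TRUE`).
#' @param method `"ls"` (least squares on relative frequencies, default)
#'   or `"ml"` (maximum likelihood).
#' @return A one-row tibble of class `binom_fit`: `m`, `p_hat`,
#'   `residual` (sum of squared frequency differences at `p_hat`),
#'   `feasible`.
#' @export
fit_labeling_efficiency <- function(hist, m, truncated = TRUE,
                                    method = c("ls", "ml")) {
  method <- match.arg(method)
  m <- stopifnot_count(m, "m", min = 1L)
  hist <- hist_counts_(hist)
  # frequencies are relative to all particles the model describes: a k = 0
  # bin (if recorded) counts toward the untruncated total only
  n_total <- sum(hist$n) +
    if (truncated) 0 else attr(hist, "n_zero_bin")
  if (any(hist$k > m)) {
    out <- tibble::tibble(m = m, p_hat = NA_real_, residual = Inf,
                          feasible = FALSE, identifiable = FALSE)
    class(out) <- c("binom_fit", class(out))
    return(out)
  }
  if (truncated && m == 1L) {
    # zero-truncated monomer model: pmf(1) = 1 for every p, so the data
    # carry no information about p; any p is an exact fit
    out <- tibble::tibble(
      m = 1L, p_hat = NA_real_,
      residual = (sum(hist$n[hist$k == 1]) / n_total - 1)^2,
      feasible = TRUE, identifiable = FALSE)
    class(out) <- c("binom_fit", class(out))
    return(out)
  }
  obs <- numeric(m)
  obs[hist$k] <- hist$n / n_total
  kk <- seq_len(m)
  sse <- function(p) {
    sum((obs - binomial_label_pmf(kk, m, p, truncated = truncated))^2)
  }
  objective <- if (method == "ls") sse else function(p) {
    -sum(obs * n_total *
           log(binomial_label_pmf(kk, m, p, truncated = truncated) +
                 .Machine$double.xmin))
  }
  opt <- optimize(objective, interval = c(1e-9, 1 - 1e-9), tol = 1e-9)
  out <- tibble::tibble(m = m, p_hat = opt$minimum,
                        residual = sse(opt$minimum), feasible = TRUE,
                        identifiable = TRUE)
  class(out) <- c("binom_fit", class(out))
  out
}

#' Select the oligomer order from a step histogram
#'
#' Fits the (zero-truncated) binomial labeling model for every candidate
#' oligomer order in `m_range`, scores each fit by its labeling error
#' relative to the experimental labeling fraction and by the fit residual,
#' and ranks candidates lexicographically by (labeling error, residual),
#' ties toward smaller m. The top-ranked m is the selected stoichiometry.
#'
#' @param hist Step histogram (columns `k`, `n`).
#' @param p_experimental Experimental labeling fraction (> 0).
#' @param m_range Candidate oligomer orders (default 1..8).
#' @param truncated Use the zero-truncated model (default `TRUE`).
#' @param method Fit method, see [fit_labeling_efficiency()].
#' @return A tibble of class `stoich_scan`, one row per candidate, sorted
#'   best first, with columns `m`, `p_hat`, `residual`, `labeling_error`,
#'   `feasible`, `rank`. Attributes `best_m`, `best_p_hat`,
#'   `p_experimental` summarize the selection.
#' @examples
#' h <- build_step_histogram(sample_label_counts(
#'   2000, m = 4, p = 0.25, seed = 1, visible_only = TRUE))
#' select_oligomer_order(h, p_experimental = 0.25)
#' @export
select_oligomer_order <- function(hist, p_experimental, m_range = 1:8,
                                  truncated = TRUE,
                                  method = c("ls", "ml")) {
  method <- match.arg(method)
  if (length(m_range) == 0) abort("`m_range` must be non-empty.")
  if (p_experimental <= 0) abort("`p_experimental` must be > 0.")
  fits <- purrr::map(m_range, function(m) {
    fit_labeling_efficiency(hist, m, truncated = truncated, method = method)
  }) |> dplyr::bind_rows()
  if (!any(fits$feasible)) {
    abort("No candidate oligomer order can explain the histogram.")
  }
  fits$labeling_error <- dplyr::case_when(
    !fits$feasible ~ Inf,
    # unidentifiable p (truncated monomer model): every p fits exactly,
    # so the minimal deviation from the experimental value is zero
    !fits$identifiable ~ 0,
    TRUE ~ labeling_error(dplyr::coalesce(fits$p_hat, p_experimental),
                          p_experimental)
  )
  ord <- order(fits$labeling_error, fits$residual, fits$m)
  fits <- fits[ord, c("m", "p_hat", "residual", "labeling_error",
                      "feasible")]
  fits$rank <- seq_len(nrow(fits))
  attr(fits, "best_m") <- fits$m[1]
  attr(fits, "best_p_hat") <- fits$p_hat[1]
  attr(fits, "p_experimental") <- p_experimental
  attr(fits, "truncated") <- truncated
  attr(fits, "hist") <- hist
  class(fits) <- c("stoich_scan", class(fits))
  fits
}

#' @export
print.stoich_scan <- function(x, ...) {
  cat(sprintf(
    "<stoich_scan> best oligomer order m = %d (p_hat = %.3f, experimental p = %.3f)\n",
    attr(x, "best_m"), attr(x, "best_p_hat"), attr(x, "p_experimental")))
  NextMethod()
}

#' @rdname select_oligomer_order
#' @param x A `stoich_scan` object.
#' @param ... Unused.
#' @export
tidy.stoich_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stoich_scan")
  for (a in c("best_m", "best_p_hat", "p_experimental", "truncated",
              "hist")) attr(out, a) <- NULL
  out
}

#' @rdname select_oligomer_order
#' @export
glance.stoich_scan <- function(x, ...) {
  tibble::tibble(
    best_m = attr(x, "best_m"),
    p_hat = attr(x, "best_p_hat"),
    labeling_error = x$labeling_error[1],
    residual = x$residual[1],
    p_experimental = attr(x, "p_experimental"),
    truncated = attr(x, "truncated")
  )
}
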