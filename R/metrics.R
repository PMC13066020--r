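# Frequency post-processing: running averages and the normalized treatment
# effect scores (apoptosis restoration / proliferation inhibition).

#' Trailing running average of a frequency series
#'
#' Causal (trailing) mean over `window` steps; the first `window - 1` entries
#' average over the available prefix, so the output has the same length as
#' the input and stays inside its range.
#'
#' @param series numeric vector of per-step frequencies.
#' @param window window length in steps (>= 1, <= length of series).
#' @return numeric vector of the same length.
#' @export
running_average <- function(series, window = 20L) {
  n <- length(series)
  if (n == 0L) stop("empty series")
  if (window < 1L || window > n) stop("window must lie in [1, length(series)]")
  if (window == 1L) return(series)
  cs <- cumsum(series)
  out <- numeric(n)
  head_idx <- seq_len(window - 1L)
  out[head_idx] <- cs[head_idx] / head_idx
  idx <- window:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  out
}

marginal_of <- function(x, node) {
  m <- if (inherits(x, "scenario_result")) x$result$end_marginals
       else if (inherits(x, "ensemble_result")) x$end_marginals
       else x
  if (!(node %in% names(m))) stop("no marginal for node '", node, "'")
  unname(m[[node]])
}

#' Normalized treatment effect scores
#'
#' Computes the pair of effect scores used to compare interventions across
#' mutation backgrounds:
#' \describe{
#'   \item{apoptosis_restoration}{(treated - untreated) apoptosis frequency,
#'     normalized by the apoptosis frequency of the mutation-free (healthy)
#'     simulation. Can exceed 1 when treatment pushes apoptosis above the
#'     healthy level.}
#'   \item{proliferation_inhibition}{(untreated - treated) proliferation
#'     frequency, normalized by the untreated-mutant proliferation
#'     frequency.}
#' }
#' Positive restoration means treatment increased apoptosis; positive
#' inhibition means it decreased proliferation. A zero reference denominator
#' yields `NA` with a warning rather than a silent 0.
#'
#' @param treated,untreated_mut,healthy `ensemble_result`/`scenario_result`
#'   objects (or named end-marginal vectors) for the treated mutant, the
#'   untreated mutant, and the mutation-free reference.
#' @param apoptosis_node,proliferation_node readout node names.
#' @return list with numeric fields `apoptosis_restoration` and
#'   `proliferation_inhibition`.
#' @export
effect_scores <- function(treated, untreated_mut, healthy,
                          apoptosis_node = "Apoptosis",
                          proliferation_node = "Proliferation") {
  a_tr <- marginal_of(treated, apoptosis_node)
  a_un <- marginal_of(untreated_mut, apoptosis_node)
  a_he <- marginal_of(healthy, apoptosis_node)
  p_tr <- marginal_of(treated, proliferation_node)
  p_un <- marginal_of(untreated_mut, proliferation_node)
  restoration <- if (a_he == 0) {
    warning("healthy apoptosis frequency is zero; restoration undefined")
    NA_real_
  } else (a_tr - a_un) / a_he
  inhibition <- if (p_un == 0) {
    warning("untreated proliferation frequency is zero; inhibition undefined")
    NA_real_
  } else (p_un - p_tr) / p_un
  list(apoptosis_restoration = restoration, proliferation_inhibition = inhibition)
}
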