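#' Net benefit at a threshold probability
#'
#' Decision-analytic net benefit of acting on predictions at threshold
#' probability `t`: patients with predicted probability `>= t` (inclusive)
#' are classified positive, and
#' `NB = TP/n - (FP/n) * t / (1 - t)`.
#' The threshold encodes the harm-benefit trade-off: treating all patients
#' yields `pi - (1 - pi) * t / (1 - t)` at prevalence `pi`, treating none
#' yields 0, and a perfect predictor yields `pi` at every threshold.
#'
#' @param probabilities Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param threshold Threshold probability in (0, 1).
#' @return Net benefit (events prevented per patient, benefit scale).
#' @export
net_benefit <- function(probabilities, outcomes, threshold) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single value in (0, 1)", call. = FALSE)
  y <- .as_binary(outcomes)
  n <- length(y)
  pos <- probabilities >= threshold
  tp <- sum(pos & y == 1L); fp <- sum(pos & y == 0L)
  tp / n - (fp / n) * threshold / (1 - threshold)
}

#' Decision curve analysis
#'
#' Computes net-benefit curves over a grid of threshold probabilities for
#' each supplied prediction strategy, always alongside the treat-all and
#' treat-none references. Regions of net harm (negative net benefit) are
#' flagged per strategy.
#'
#' @param strategies Named list of predicted-probability vectors (e.g.
#'   original and recalibrated models).
#' @param outcomes Binary outcomes shared by all strategies.
#' @param thresholds Threshold grid in (0, 1). Default
#'   `seq(0.005, 0.5, by = 0.005)`.
#' @return Object of class `caki_dca`: long data frame with columns
#'   `threshold`, `strategy`, `net_benefit`; attributes `n`, `prevalence`,
#'   `harm_regions` (per-strategy thresholds where NB < 0).
#' @export
decision_curve <- function(strategies, outcomes,
                           thresholds = seq(0.005, 0.5, by = 0.005)) {
  if (!length(thresholds)) stop("threshold grid is empty", call. = FALSE)
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  y <- .as_binary(outcomes)
  if (is.null(names(strategies)) || any(!nzchar(names(strategies))))
    stop("strategies must be a named list", call. = FALSE)
  for (nm in names(strategies))
    if (length(strategies[[nm]]) != length(y))
      stop("strategy '", nm, "' does not cover the patient set",
           call. = FALSE)
  pi_hat <- mean(y)
  all_strats <- c(strategies,
                  list(treat_all = rep(1, length(y)),
                       treat_none = rep(0, length(y))))
  rows <- lapply(names(all_strats), function(nm) {
    nb <- vapply(thresholds, function(t)
      net_benefit(all_strats[[nm]], y, t), numeric(1))
    data.frame(threshold = thresholds, strategy = nm, net_benefit = nb)
  })
  out <- do.call(rbind, rows)
  harm <- lapply(names(all_strats), function(nm) {
    s <- out[out$strategy == nm, ]
    s$threshold[s$net_benefit < 0]
  })
  names(harm) <- names(all_strats)
  structure(out, n = length(y), prevalence = pi_hat, harm_regions = harm,
            class = c("caki_dca", "data.frame"))
}

#' @export
print.caki_dca <- function(x, ...) {
  cat(sprintf("Decision curve: n = %d, prevalence %.3f, %d thresholds, %d strategies\n",
              attr(x, "n"), attr(x, "prevalence"),
              length(unique(x$threshold)), length(unique(x$strategy))))
  harm <- attr(x, "harm_regions")
  for (nm in setdiff(names(harm), "treat_none"))
    if (length(harm[[nm]]))
      cat(sprintf("  net harm for '%s' at %d threshold(s), first at %.3f\n",
                  nm, length(harm[[nm]]), min(harm[[nm]])))
  invisible(x)
}

#' @export
plot.caki_dca <- function(x, ...) {
  strat <- unique(x$strategy)
  cols <- stats::setNames(seq_along(strat), strat)
  graphics::plot(NULL, xlim = range(x$threshold),
                 ylim = c(min(x$net_benefit, -0.01),
                          max(x$net_benefit) * 1.05),
                 xlab = "Threshold probability", ylab = "Net benefit", ...)
  for (nm in strat) {
    s <- x[x$strategy == nm, ]
    graphics::lines(s$threshold, s$net_benefit, col = cols[nm],
                    lty = if (nm == "treat_none") 3 else 1)
  }
  graphics::legend("topright", legend = strat, col = cols, lty = 1, cex = 0.8)
  invisible(x)
}
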