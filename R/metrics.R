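# Nonparametric metacognitive-accuracy metrics.

.metric_check <- function(trials) {
  y <- trials$outcome
  if (length(unique(y)) < 2L)
    stop(structure(class = c("bim_degenerate", "error", "condition"),
                   list(message = "metric undefined: all outcomes identical",
                        call = sys.call(-1))))
  y
}

#' Goodman-Kruskal gamma
#'
#' Rank association between confidence and accuracy over all
#' (correct, incorrect) trial pairs; pairs tied on confidence are excluded.
#'
#' @param trials Trial table with `outcome` and `confidence` (any scale).
#' @return Gamma in -1..1; errors (class `bim_degenerate`) when all
#'   outcomes are identical, `NaN` if every pair is tied.
#' @export
gamma_stat <- function(trials) {
  y <- .metric_check(trials)
  conf <- trials$confidence
  lev <- sort(unique(conf))
  n1 <- vapply(lev, function(l) sum(conf == l & y == 1), numeric(1))
  n0 <- vapply(lev, function(l) sum(conf == l & y == 0), numeric(1))
  cum0_below <- c(0, cumsum(n0))[seq_along(lev)]
  cum0_above <- rev(c(0, cumsum(rev(n0))))[-1]
  concordant <- sum(n1 * cum0_below)
  discordant <- sum(n1 * cum0_above)
  if (concordant + discordant == 0) return(NaN)
  (concordant - discordant) / (concordant + discordant)
}

#' Type II area under the ROC curve (trapezoidal)
#'
#' Cumulates type II hit and false-alarm rates from the highest confidence
#' level downward, appends the (0,0) and (1,1) endpoints, and applies the
#' trapezoidal rule. Equivalent to P(conf_correct > conf_incorrect) +
#' P(tie)/2 over all cross pairs.
#'
#' @inheritParams gamma_stat
#' @return AUROC in 0..1.
#' @export
auroc2 <- function(trials) {
  y <- .metric_check(trials)
  conf <- trials$confidence
  lev <- sort(unique(conf), decreasing = TRUE)
  n1 <- vapply(lev, function(l) sum(conf == l & y == 1), numeric(1))
  n0 <- vapply(lev, function(l) sum(conf == l & y == 0), numeric(1))
  h <- c(0, cumsum(n1) / sum(n1))
  f <- c(0, cumsum(n0) / sum(n0))
  sum(diff(f) * (head(h, -1) + h[-1]) / 2)
}
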