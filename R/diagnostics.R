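#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of the chain with the mean of a late
#' window: `z = (m1 - m2) / sqrt(s1/n1 + s2/n2)`, where `s1`, `s2` are
#' spectral density estimates at frequency zero (autoregressive estimator),
#' so autocorrelation within each window is accounted for. Under
#' stationarity `z` is approximately standard normal.
#'
#' @param chain numeric vector of draws (length >= 100).
#' @param first,last fractions of the chain used for the early and late
#'   windows (defaults 0.1 and 0.5).
#' @return The z score; defined as 0 when both windows are constant.
#' @export
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for the Geweke diagnostic (< 100)")
  stopifnot(first > 0, last > 0, first + last <= 1)
  x1 <- chain[seq_len(floor(first * n))]
  x2 <- chain[(n - floor(last * n) + 1):n]
  s1 <- .spectrum0(x1); s2 <- .spectrum0(x2)
  if (s1 == 0 && s2 == 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

# spectral density at frequency zero via an AR fit (Yule-Walker);
# for a white chain this reduces to the sample variance
.spectrum0 <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(30, length(x) %/% 4),
              method = "yule-walker"),
    error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (fit$order == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke report for the monitored chains of a run
#'
#' Computes the Geweke z for the standard monitored quantities of a sampler
#' run: residual variance, total genetic variance, and a tracer marker
#' effect (the marker with the highest posterior inclusion frequency).
#'
#' @param run an [ssbc_gibbs()] result.
#' @return Named numeric vector of z scores.
#' @export
geweke_report <- function(run) {
  stopifnot(inherits(run, "ssbc_mcmc"))
  out <- c(sigma_e2 = geweke_z(run$sigma_e2),
           sigma_g2 = geweke_z(run$sigma_g2))
  if (ncol(run$alpha) > 0) {
    k <- which.max(run$inclusion)
    out <- c(out, tracer_alpha = geweke_z(run$alpha[, k]))
  }
  out
}
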