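# Monoexponential decay fitting: y(t) = A * exp(-(t - t0)/tau) + C, offset C
# free. Used for both the per-beat decay and the caffeine-transient efflux.

#' Fit a monoexponential decay with free offset
#'
#' Least-squares fit of \code{y = A exp(-(t - t[1])/tau) + C}. Starting
#' values come from the tail (offset) and a log-linear regression of the
#' offset-corrected signal; the refinement uses Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}).
#'
#' @param t,y numeric vectors (t in seconds).
#' @return A list with \code{A}, \code{tau} (s), \code{C}, \code{rmse},
#'   \code{r2}, \code{converged} (logical) and \code{reason} (character,
#'   non-empty when the fit failed; \code{tau} is then \code{NA}).
#' @export
fitMonoexp <- function(t, y) {
  fail <- function(reason) list(A = NA_real_, tau = NA_real_, C = NA_real_,
                                rmse = NA_real_, r2 = NA_real_,
                                converged = FALSE, reason = reason)
  if (length(t) < 4L) return(fail("fewer than 4 samples in decay window"))
  ts <- t - t[1]
  c0 <- mean(y[seq(max(1L, length(y) - max(3L, length(y) %/% 10L)), length(y))])
  a0 <- y[1] - c0
  if (!is.finite(a0) || a0 <= 0) a0 <- max(y) - min(y)
  if (a0 <= 0) return(fail("no decaying component"))
  span <- diff(range(ts))
  # initial tau: 1/e crossing of the lightly smoothed, offset-corrected decay
  # (robust to noise-dominated tails, unlike a log-linear slope); clamped to
  # the fit span.
  ysm <- movingAverage(y, max(3L, length(y) %/% 100L))
  cross <- which(ysm - c0 < a0 / exp(1))
  tau0 <- if (length(cross)) max(ts[cross[1]], span / 200) else span / 3
  tau0 <- min(tau0, span)
  fit <- NULL
  for (t0try in unique(c(tau0, span / 5, span / 20))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-ts / tau) + C,
                        start = list(A = a0, tau = t0try, C = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fail("non-convergent monoexponential fit"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0)
    return(fail("non-positive fitted tau"))
  res <- y - stats::fitted(fit)
  sst <- sum((y - mean(y))^2)
  list(A = unname(cf[["A"]]), tau = unname(cf[["tau"]]), C = unname(cf[["C"]]),
       rmse = sqrt(mean(res^2)),
       r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
       converged = TRUE, reason = "")
}
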