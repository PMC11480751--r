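## Two-state CTMC over left/right swimming: exact analytics and estimators.
##
## State 1 = "left" swimmer (moving along the field, toward the interface),
## state 2 = "right" swimmer (moving against it).  A left swimmer switches
## out at the basal rate lambda_minus; a right swimmer switches back at the
## increased rate lambda_plus.

#' Two-state switching-rate parameters
#'
#' The pair of reversal rates governing the reduced two-state chain:
#' `lambda_minus` is the basal rate at which an interface-facing ("left")
#' swimmer reverses, `lambda_plus` the increased rate at which an outbound
#' ("right") swimmer reverses back.  Fitted defaults: 0.0413 and
#' 0.4186 s^-1.
#'
#' @param lambda_minus basal rate (s^-1), > 0.
#' @param lambda_plus increased rate (s^-1), > 0.
#' @return an object of class `"ctmc_params"`.
#' @export
ctmc_params <- function(lambda_minus = 0.0413, lambda_plus = 0.4186) {
  stopifnot(is.numeric(lambda_minus), length(lambda_minus) == 1L,
            is.numeric(lambda_plus), length(lambda_plus) == 1L)
  if (!is.finite(lambda_minus) || lambda_minus <= 0)
    stop("lambda_minus must be finite and > 0")
  if (!is.finite(lambda_plus) || lambda_plus <= 0)
    stop("lambda_plus must be finite and > 0")
  structure(list(lambda_minus = lambda_minus, lambda_plus = lambda_plus),
            class = "ctmc_params")
}

#' CTMC generator matrix
#'
#' Returns the 2x2 generator `Q = [[-l-, l-], [l+, -l+]]` of the left/right
#' switching chain; rows sum to zero.
#'
#' @param params a [ctmc_params()] object.
#' @return 2x2 numeric matrix with dimnames `c("left", "right")`.
#' @export
ctmc_generator <- function(params = ctmc_params()) {
  stopifnot(inherits(params, "ctmc_params"))
  lm <- params$lambda_minus; lp <- params$lambda_plus
  matrix(c(-lm, lm, lp, -lp), nrow = 2, byrow = TRUE,
         dimnames = list(c("left", "right"), c("left", "right")))
}

#' Stationary law of the switching chain
#'
#' `pi_left = lambda_plus / (lambda_plus + lambda_minus)` and
#' `pi_right = lambda_minus / (lambda_plus + lambda_minus)`; satisfies
#' `pi %*% Q = 0`.  With the fitted rates this gives roughly 91% left
#' swimmers, i.e. a left:right ratio of `lambda_plus / lambda_minus`.
#'
#' @param params a [ctmc_params()] object.
#' @return named numeric vector `c(pi_left, pi_right)` summing to 1.
#' @export
ctmc_stationary <- function(params = ctmc_params()) {
  stopifnot(inherits(params, "ctmc_params"))
  s <- params$lambda_minus + params$lambda_plus
  c(pi_left = params$lambda_plus / s, pi_right = params$lambda_minus / s)
}

#' Relaxation rate of the switching chain
#'
#' The spectral gap `lambda_plus + lambda_minus`: any initial law relaxes to
#' the stationary law as `exp(-(lambda_plus + lambda_minus) * t)`.
#'
#' @param params a [ctmc_params()] object.
#' @return relaxation rate in s^-1.
#' @export
relaxation_rate <- function(params = ctmc_params()) {
  stopifnot(inherits(params, "ctmc_params"))
  params$lambda_minus + params$lambda_plus
}

#' Transient law of the switching chain
#'
#' Closed-form solution of the master equation `dp/dt = p Q` for the
#' two-state chain: `p(t) = pi + (p0 - pi) * exp(-(l+ + l-) t)`.
#'
#' @param params a [ctmc_params()] object.
#' @param p0 initial law, length-2 non-negative vector summing to 1.
#' @param t_s time(s) at which to evaluate (vectorised).
#' @return matrix with one row per time, columns `left`, `right`.
#' @export
ctmc_transient <- function(params = ctmc_params(), p0 = c(1, 0), t_s = 0) {
  stopifnot(inherits(params, "ctmc_params"), length(p0) == 2L,
            all(p0 >= 0), abs(sum(p0) - 1) < 1e-8)
  pi_ <- ctmc_stationary(params)
  decay <- exp(-relaxation_rate(params) * t_s)
  out <- cbind(left = pi_[[1]] + (p0[1] - pi_[[1]]) * decay,
               right = pi_[[2]] + (p0[2] - pi_[[2]]) * decay)
  out
}

#' Estimate the basal reversal rate from the never-departed fraction
#'
#' The waiting time until a colony first leaves the interface is
#' exponential with the basal rate, `T ~ Exp(lambda_minus)`, so the
#' fraction still resident at the end of a finite observation window
#' estimates `Pr(T >= t_final)` and
#' `lambda_minus_hat = -log(n_stayed / n_total) / t_final`.
#'
#' @param n_stayed number of colonies that never departed, 0 < n_stayed <= n_total
#'   (`n_stayed = 0` gives an infinite rate and is an error;
#'   `n_stayed = n_total` returns 0 with a warning).
#' @param n_total total number of colonies observed.
#' @param t_final_s observation time (s), > 0.
#' @return estimated basal rate (s^-1).
#' @export
estimate_lambda_minus <- function(n_stayed, n_total, t_final_s) {
  stopifnot(length(n_stayed) == 1L, length(n_total) == 1L,
            n_total >= 1, t_final_s > 0)
  if (n_stayed < 0 || n_stayed > n_total)
    stop("need 0 <= n_stayed <= n_total")
  if (n_stayed == 0)
    stop("every colony departed: the survival-based estimate is infinite; ",
         "shorten t_final_s or use more colonies")
  if (n_stayed == n_total) {
    warning("no colony departed: estimate degenerates to 0")
    return(0)
  }
  -log(n_stayed / n_total) / t_final_s
}

#' Estimate the rate ratio from steady-state counts
#'
#' At stationarity the expected left:right swimmer count ratio equals
#' `lambda_plus / lambda_minus`; the estimator is simply
#' `n_left / n_right`, intended to be computed over a window after the
#' chain has converged (relaxation rate `lambda_plus + lambda_minus`;
#' the fitted analysis uses the final 5 s of the record).
#'
#' @param n_left,n_right swimmer counts (possibly pooled over frames).
#' @return estimated ratio `lambda_plus / lambda_minus`.
#' @export
estimate_rate_ratio <- function(n_left, n_right) {
  stopifnot(length(n_left) == 1L, length(n_right) == 1L, n_left >= 0)
  if (n_right <= 0) stop("n_right must be > 0: ratio undefined")
  n_left / n_right
}

#' Simulate the two-state switching chain
#'
#' Exact event-driven simulation (exponential holding times) of the
#' left/right chain, sampled on a regular grid.
#'
#' @param params a [ctmc_params()] object.
#' @param n number of independent chains.
#' @param t_final_s duration (s).
#' @param dt_s sampling interval (s).
#' @param init initial state for all chains: `"left"` or `"right"`.
#' @return integer matrix (`length(times)` x `n`) of states (+1 = left,
#'   -1 = right), with attribute `times`.
#' @export
simulate_ctmc <- function(params = ctmc_params(), n = 1, t_final_s = 17,
                          dt_s = 0.1, init = "left") {
  stopifnot(inherits(params, "ctmc_params"), n >= 1, t_final_s > 0, dt_s > 0)
  times <- seq(0, t_final_s, by = dt_s)
  out <- matrix(NA_integer_, nrow = length(times), ncol = n)
  for (j in seq_len(n)) {
    state <- if (identical(init, "left")) 1L else -1L
    t <- 0; i <- 1L
    while (i <= length(times)) {
      rate <- if (state == 1L) params$lambda_minus else params$lambda_plus
      t_next <- t + rexp(1, rate)
      while (i <= length(times) && times[i] < t_next) {
        out[i, j] <- state
        i <- i + 1L
      }
      state <- -state
      t <- t_next
    }
  }
  attr(out, "times") <- times
  out
}
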