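#' Model rate terms
#'
#' The local (per-node) dynamics of the cell concentration \eqn{\alpha} under
#' an oxygen concentration \eqn{C} are
#' \deqn{\frac{\partial\alpha}{\partial t} =
#'   \frac{(1+s_1)\,\alpha\,(1-\alpha)\,C}{1+s_1 C} -
#'   \frac{(s_2+s_3 C)\,\alpha}{1+s_4 C}.}
#' The first term models proliferation (logistic in \eqn{\alpha}, saturating
#' in \eqn{C}; at \eqn{C=1} the \eqn{s_1} factors cancel exactly), the second
#' models death. `growth_term` and `death_term` evaluate the two right-hand
#' terms, `dalpha_dt` their difference. All three are vectorized over `alpha`
#' and `c`.
#'
#' @param alpha Cell concentration(s) in \[0, 1\].
#' @param c Oxygen concentration(s), >= 0 (1 = medium/far-field level).
#' @param p A [model_params].
#' @return Rate(s) per hour (nondimensional concentration per hour).
#' @examples
#' p <- model_params(s1 = 1)
#' growth_term(0.5, 1, p)   # 0.25, independent of s1 at c = 1
#' @export
growth_term <- function(alpha, c, p) {
  check_alpha_c(alpha, c)
  p <- as_model_params(p)
  # grouped so the s1 factors cancel exactly (x/x == 1) at c = 1
  ((1 + p$s1) * c / (1 + p$s1 * c)) * alpha * (1 - alpha)
}

#' @rdname growth_term
#' @export
death_term <- function(alpha, c, p) {
  check_alpha_c(alpha, c)
  p <- as_model_params(p)
  (p$s2 + p$s3 * c) * alpha / (1 + p$s4 * c)
}

#' @rdname growth_term
#' @export
dalpha_dt <- function(alpha, c, p) {
  growth_term(alpha, c, p) - death_term(alpha, c, p)
}

#' Oxygen consumption rate
#'
#' Local oxygen sink \eqn{Q\,\alpha\,C/(1+Q_1 C)}: consumption is
#' proportional to the cell concentration and saturates in oxygen
#' (Michaelis--Menten-like with saturation constant \eqn{1/Q_1}).
#'
#' @inheritParams growth_term
#' @return Consumption rate(s), >= 0.
#' @export
consumption_term <- function(alpha, c, p) {
  check_alpha_c(alpha, c)
  p <- as_model_params(p)
  p$Q * alpha * c / (1 + p$Q1 * c)
}

check_alpha_c <- function(alpha, c) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop_invalid_input("'alpha' must lie in [0, 1]")
  }
  if (any(!is.finite(c)) || any(c < 0)) {
    stop_invalid_input("'c' must be finite and >= 0")
  }
  invisible(TRUE)
}

# Effective logistic coefficients at fixed oxygen: dalpha/dt = (a-b) alpha - a alpha^2
logistic_coefs <- function(c_const, p) {
  p <- as_model_params(p)
  a <- (1 + p$s1) * c_const / (1 + p$s1 * c_const)
  b <- (p$s2 + p$s3 * c_const) / (1 + p$s4 * c_const)
  list(a = a, b = b)
}

#' Closed-form solution at constant oxygen
#'
#' With the oxygen concentration held constant the concentration equation
#' reduces to the scalar logistic-with-death ODE
#' \eqn{\dot\alpha = (a-b)\alpha - a\alpha^2} with
#' \eqn{a = (1+s_1)c/(1+s_1 c)} and \eqn{b = (s_2+s_3 c)/(1+s_4 c)}.
#' Its exact solution, used throughout the test suite as the solver oracle, is
#' \deqn{\alpha(t) = \frac{r\,\alpha_0 e^{rt}}{r + a\,\alpha_0\,(e^{rt}-1)},
#'   \quad r = a - b \neq 0,}
#' and \eqn{\alpha(t) = \alpha_0/(1 + a\,\alpha_0 t)} when \eqn{r = 0}.
#'
#' @param alpha0 Initial concentration(s) in \[0, 1\].
#' @param c_const Constant oxygen level, >= 0.
#' @param p A [model_params].
#' @param t Time(s) in hours, >= 0 (`Inf` allowed: the long-time limit).
#' @return Concentration(s) in \[0, 1\], vectorized over `alpha0` and `t`.
#' @export
closed_form_alpha <- function(alpha0, c_const, p, t) {
  if (any(!is.finite(alpha0)) || any(alpha0 < 0) || any(alpha0 > 1)) {
    stop_invalid_input("'alpha0' must lie in [0, 1]")
  }
  if (length(c_const) != 1L || !is.finite(c_const) || c_const < 0) {
    stop_invalid_input("'c_const' must be a single finite value >= 0")
  }
  if (any(is.na(t)) || any(t < 0)) stop_invalid_input("'t' must be >= 0")
  co <- logistic_coefs(c_const, p)
  a <- co$a; b <- co$b; r <- a - b
  n <- max(length(alpha0), length(t))
  alpha0 <- rep_len(alpha0, n); t <- rep_len(t, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a0 <- alpha0[i]; ti <- t[i]
    if (ti == 0 || a0 == 0) {
      out[i] <- a0
    } else if (r == 0) {
      out[i] <- if (is.infinite(ti)) 0 * (a > 0) + a0 * (a == 0)
                else a0 / (1 + a * a0 * ti)
    } else if (is.infinite(ti)) {
      out[i] <- if (r > 0) r / a else 0
    } else {
      # e^{-rt} form avoids overflow for large positive r*t
      emrt <- exp(-r * ti)
      out[i] <- r * a0 / (r * emrt + a * a0 * (1 - emrt))
    }
  }
  pmin(1, pmax(0, out))
}

#' Steady state at constant oxygen
#'
#' Long-time limit of [closed_form_alpha]: `max(0, 1 - b/a)` with the
#' effective growth and death rates `a`, `b` of the constant-oxygen
#' reduction; 0 when death dominates (`b >= a`, extinction). In the doubly
#' degenerate case `a = b = 0` every state is stationary and the function
#' returns 1 by convention (the `alpha = 0` fixed point is unstable only when
#' `a > b`).
#'
#' @inheritParams closed_form_alpha
#' @return A single concentration in \[0, 1\].
#' @export
steady_state <- function(c_const, p) {
  co <- logistic_coefs(c_const, p)
  if (co$a == 0) return(if (co$b == 0) 1 else 0)
  max(0, 1 - co$b / co$a)
}
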