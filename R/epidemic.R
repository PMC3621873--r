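#' Basic reproduction number of the SIR model
#'
#' @param beta transmission rate per unit time (> 0).
#' @param gamma recovery rate per unit time (> 0); `1/gamma` is the mean
#'   infectious period.
#' @return `R0 = beta / gamma`.
#' @export
#' @examples
#' r0(0.624, 0.312)  # 2
r0 <- function(beta, gamma) {
  if (!is.numeric(gamma) || any(gamma <= 0))
    stop("'gamma' must be positive")
  if (!is.numeric(beta) || any(beta < 0))
    stop("'beta' must be non-negative")
  beta / gamma
}

#' Herd-immunity vaccination threshold
#'
#' The minimum vaccination coverage at which the effective reproduction
#' number falls to one, so an epidemic cannot grow:
#' `theta_vac = max(0, 1 - 1/R0)`. Below-one reproduction numbers need no
#' vaccination — transmission decays naturally.
#'
#' @param R0 basic reproduction number (> 0); vectorized.
#' @return Threshold coverage in `[0, 1)`.
#' @export
#' @examples
#' vaccination_threshold(2)    # 0.5
#' vaccination_threshold(0.8)  # 0
vaccination_threshold <- function(R0) {
  if (!is.numeric(R0) || any(R0 <= 0))
    stop("'R0' must be positive")
  pmax(0, 1 - 1 / R0)
}

#' SIR parameters
#'
#' @param beta transmission rate (>= 0).
#' @param gamma recovery rate (> 0); default 0.312 (a 3.2-day infectious
#'   period, calibrated to 2009 H1N1 influenza).
#' @param N population size.
#' @param V vaccination coverage in `[0, 1]`; vaccinated individuals are
#'   fully immunized and removed from the susceptible pool before
#'   integration.
#' @param I0 initial infectious count (> 0, among the unvaccinated);
#'   default `1e-4 * N`.
#' @param t_max initial integration horizon (days); extended automatically
#'   until the epidemic has died out.
#' @param dt output grid spacing (days).
#' @return A list of class `sir_params`.
#' @export
sir_params <- function(beta, gamma = 0.312, N = 1, V = 0, I0 = 1e-4 * N,
                       t_max = 500, dt = 0.5) {
  stopifnot(beta >= 0, gamma > 0, N > 0, V >= 0, V <= 1, I0 > 0,
            t_max > 0, dt > 0)
  if (I0 + V * N > N * (1 + 1e-12))
    stop("initial infectious and vaccinated together exceed the population")
  structure(list(beta = beta, gamma = gamma, N = N, V = V, I0 = I0,
                 t_max = t_max, dt = dt), class = "sir_params")
}

#' Integrate the SIR epidemic
#'
#' Solves the homogeneous-mixing SIR equations
#' `dS/dt = -beta * S * I / N`, `dI/dt = beta * S * I / N - gamma * I`,
#' `dR/dt = gamma * I` with `S(0) = N(1 - V) - I0`, `I(0) = I0`, `R(0) = 0`
#' (the force of infection is proportional to the infectious fraction of the
#' whole population, vaccinated included). Integration uses an adaptive
#' solver at relative tolerance 1e-8 and the horizon is extended by doubling
#' until the infectious count has peaked and fallen below `1e-6 * N`, so the
#' reported attack rate is the final epidemic size.
#'
#' @param params an [sir_params()].
#' @return A list of class `epidemic_summary` with `attack_rate` (fraction
#'   of the total population ever infected, `R(end)/N`), `final_R`,
#'   `peak_I`, and `trajectory` (data.frame `t, S, I, R`).
#' @export
#' @examples
#' ep <- integrate_sir(sir_params(beta = 1.6 * 0.312, gamma = 0.312))
#' ep$attack_rate  # ~0.642
integrate_sir <- function(params) {
  stopifnot(inherits(params, "sir_params"))
  N <- params$N
  deriv <- function(t, y, p) {
    lam <- p$beta * y[["I"]] / N
    list(c(S = -lam * y[["S"]],
           I = lam * y[["S"]] - p$gamma * y[["I"]],
           R = p$gamma * y[["I"]]))
  }
  S0 <- N * (1 - params$V) - params$I0
  if (S0 < 0) {
    if (S0 > -1e-9 * N) S0 <- 0  # rounding from V ~ 1 - I0/N
    else stop("initial susceptible count is negative; reduce I0 or V")
  }
  y0 <- c(S = S0, I = params$I0, R = 0)
  pieces <- list()
  t0 <- 0
  horizon <- params$t_max
  total <- sum(y0)
  for (chunk in 1:40) {
    times <- seq(t0, t0 + horizon, by = params$dt)
    sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = params,
                        rtol = 1e-8, atol = 1e-12 * N, method = "lsoda")
    if (any(!is.finite(sol)))
      stop("SIR integration produced non-finite state")
    pieces[[chunk]] <- sol[if (chunk == 1L) TRUE else -1L, , drop = FALSE]
    last <- sol[nrow(sol), ]
    if (max(abs(rowSums(sol[, c("S", "I", "R")]) - total)) > 1e-6 * N)
      stop("SIR integration violated conservation of the unvaccinated population")
    growing <- params$beta * last[["S"]] / N > params$gamma
    if (last[["I"]] < 1e-6 * N && !growing) break
    y0 <- c(S = last[["S"]], I = last[["I"]], R = last[["R"]])
    t0 <- last[["time"]]
    horizon <- horizon * 2
    if (chunk == 40L)
      stop("epidemic failed to die out within the extended horizon")
  }
  tr <- as.data.frame(do.call(rbind, pieces))
  names(tr) <- c("t", "S", "I", "R")
  structure(list(attack_rate = tr$R[nrow(tr)] / N,
                 final_R = tr$R[nrow(tr)],
                 peak_I = max(tr$I),
                 trajectory = tr),
            class = "epidemic_summary")
}

#' @export
print.epidemic_summary <- function(x, ...) {
  cat(sprintf("epidemic summary: attack rate %.4f, peak I %.4g\n",
              x$attack_rate, x$peak_I))
  invisible(x)
}

#' Analytic final epidemic size
#'
#' Closed-form companion to [integrate_sir()] in the small-seed limit. With
#' coverage `V`, the effective reproduction number among the unvaccinated
#' pool is `R0 * (1 - V)`; the fraction `z` of that pool ever infected is
#' the largest root of `z = 1 - exp(-R0 * (1 - V) * z)`, found by damped
#' fixed-point iteration to 1e-10 (`z = 0` when the effective reproduction
#' number is at or below one). The value returned is the attack fraction
#' among the total population, `(1 - V) * z`.
#'
#' @param R0 basic reproduction number (> 0).
#' @param V vaccination coverage in `[0, 1)`.
#' @return Predicted attack rate in `[0, 1)`.
#' @export
#' @examples
#' final_size_fixed_point(2, 0)    # ~0.7968
#' final_size_fixed_point(2, 0.5)  # 0
final_size_fixed_point <- function(R0, V = 0) {
  stopifnot(R0 > 0, V >= 0, V < 1)
  Re <- R0 * (1 - V)
  if (Re <= 1) return(0)
  z <- 1 - 1 / Re  # start above 0, below the root
  damp <- 0.5
  for (k in 1:10000) {
    znew <- (1 - damp) * z + damp * (1 - exp(-Re * z))
    if (abs(znew - z) < 1e-10) { z <- znew; break }
    z <- znew
  }
  (1 - V) * z
}
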