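#' Activated-sludge process parameters
#'
#' Constructs the parameter set of the four-state activated-sludge model
#' (aerator + settler mass balances with double-Monod growth kinetics).
#' Defaults are the standard simulation parameter set for this benchmark.
#' All rates are per hour, all concentrations in mg/l.
#'
#' @param Y biomass yield coefficient (dimensionless, 0 < Y <= 1)
#' @param qr recycled-flow to influent-flow ratio (dimensionless)
#' @param beta waste-flow to influent-flow ratio (dimensionless)
#' @param K0 oxygen-demand constant (dimensionless)
#' @param Cs dissolved-oxygen saturation concentration (mg/l)
#' @param Sin mean influent substrate concentration (mg/l)
#' @param Coin influent dissolved-oxygen concentration (mg/l)
#' @param mumax maximum specific growth rate (1/h)
#' @param Ks substrate affinity constant (mg/l)
#' @param Kc dissolved-oxygen saturation constant (mg/l)
#' @return object of class `asp_parameters` (named list)
#' @export
asp_parameters <- function(Y = 0.65, qr = 0.6, beta = 0.2, K0 = 0.5,
                           Cs = 10, Sin = 200, Coin = 0.5,
                           mumax = 0.15, Ks = 100, Kc = 2) {
  p <- list(Y = Y, qr = qr, beta = beta, K0 = K0, Cs = Cs, Sin = Sin,
            Coin = Coin, mumax = mumax, Ks = Ks, Kc = Kc)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all activated-sludge parameters must be finite and strictly positive")
  }
  if (Y > 1) stop("yield coefficient Y must satisfy 0 < Y <= 1")
  class(p) <- "asp_parameters"
  p
}

#' Activated-sludge state vector
#'
#' State ordering is fixed as (X, Xr, S, Co): biomass, recycled biomass,
#' substrate and dissolved-oxygen concentrations (mg/l).
#'
#' @param X biomass concentration (mg/l)
#' @param Xr recycled biomass concentration (mg/l)
#' @param S substrate concentration (mg/l)
#' @param Co dissolved-oxygen concentration (mg/l)
#' @return named numeric vector of length 4
#' @export
asp_state <- function(X, Xr, S, Co) {
  x <- c(X = X, Xr = Xr, S = S, Co = Co)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("all concentrations must be finite and non-negative")
  }
  x
}

#' Manipulated inputs
#'
#' @param D dilution rate (1/h)
#' @param KLa aeration flow rate (1/h)
#' @return named numeric vector (D, KLa)
#' @export
control_input <- function(D, KLa) {
  u <- c(D = D, KLa = KLa)
  if (any(!is.finite(u))) stop("inputs must be finite")
  u
}

#' Double-Monod specific growth rate
#'
#' mu(S, Co) = mumax * S/(Ks + S) * Co/(Kc + Co): saturating in both the
#' substrate and the dissolved oxygen.
#'
#' @param S substrate concentration (mg/l), non-negative
#' @param Co dissolved-oxygen concentration (mg/l), non-negative
#' @param p [asp_parameters()]
#' @return specific growth rate (1/h), in [0, mumax)
#' @export
growth_rate <- function(S, Co, p) {
  if (any(S < 0) || any(Co < 0)) {
    stop("growth_rate: S and Co must be non-negative")
  }
  p$mumax * S / (p$Ks + S) * Co / (p$Kc + Co)
}

#' Activated-sludge model right-hand side
#'
#' Mass balances of the aerator/settler loop:
#' \deqn{dX/dt   = \mu X - D(1+q_r)X + q_r D X_r}
#' \deqn{dX_r/dt = D(1+q_r)X - D(\beta+q_r)X_r}
#' \deqn{dS/dt   = -\mu X/Y - D(1+q_r)S + D(S_{in} + \Delta S_{in})}
#' \deqn{dC_o/dt = -K_0\mu X/Y - D(1+q_r)C_o + D C_{oin} + K_{La}(C_s - C_o)}
#' The influent-substrate deviation `delta_sin` enters the substrate balance
#' as the additive disturbance d(t) = D * delta_sin.
#'
#' @param x state vector (X, Xr, S, Co), see [asp_state()]
#' @param u input vector (D, KLa), see [control_input()]
#' @param delta_sin influent-substrate deviation from its mean (mg/l)
#' @param p [asp_parameters()]
#' @return derivative vector in state order (X, Xr, S, Co), mg/l/h
#' @export
plant_rhs <- function(x, u, delta_sin = 0, p = asp_parameters()) {
  X <- x[[1]]; Xr <- x[[2]]; S <- x[[3]]; Co <- x[[4]]
  D <- u[[1]]; KLa <- u[[2]]
  mu <- growth_rate(S, Co, p)
  c(X  = mu * X - D * (1 + p$qr) * X + p$qr * D * Xr,
    Xr = D * (1 + p$qr) * X - D * (p$beta + p$qr) * Xr,
    S  = -mu * X / p$Y - (1 + p$qr) * D * S + D * (p$Sin + delta_sin),
    Co = -p$K0 * mu * X / p$Y - D * (1 + p$qr) * Co + D * p$Coin +
         KLa * (p$Cs - Co))
}

#' Steady state of the activated-sludge loop for given controlled values
#'
#' Solves the mass balances at equilibrium for a prescribed substrate and
#' dissolved-oxygen pair: the settler balance pins Xr/X = (1+qr)/(beta+qr),
#' the biomass balance gives D = mu(S, Co) (beta+qr) / ((1+qr) beta), the
#' substrate balance then yields X, and the oxygen balance the aeration
#' rate.
#'
#' @param S substrate concentration at equilibrium (mg/l)
#' @param Co dissolved-oxygen concentration at equilibrium (mg/l)
#' @param p [asp_parameters()]
#' @return list with `x` (state vector X, Xr, S, Co) and `u` (D, KLa)
#' @export
asp_equilibrium <- function(S, Co, p = asp_parameters()) {
  mu <- growth_rate(S, Co, p)
  f <- (1 + p$qr) * p$beta / (p$beta + p$qr)
  D <- mu / f
  X <- p$Y * (p$Sin - (1 + p$qr) * S) / f
  if (X <= 0) stop("no positive-biomass equilibrium at this substrate level")
  Xr <- X * (1 + p$qr) / (p$beta + p$qr)
  KLa <- (p$K0 * mu * X / p$Y + D * (1 + p$qr) * Co - D * p$Coin) /
    (p$Cs - Co)
  list(x = c(X = X, Xr = Xr, S = S, Co = Co),
       u = c(D = D, KLa = KLa))
}

#' Disturbance scenario
#'
#' Describes the influent and kinetic disturbances applied to the plant:
#' a sinusoidal variation of the influent substrate around its daily mean
#' and temporary relative changes of kinetic parameters. Internal time unit
#' is hours; "one day" is 24 h.
#'
#' @param sin_amplitude_fraction amplitude of the influent-substrate sinusoid
#'   as a fraction of `Sin` (0 <= fraction < 1)
#' @param sin_period period of the sinusoid (h)
#' @param kinetic_events list of events, each a list with fields
#'   `param` (`"mumax"` or `"Kc"`), `change` (relative change, e.g. 0.1 for
#'   +10 percent), `start` (h) and `duration` (h). Events step the parameter
#'   to (1+change)*base for the duration, then revert.
#' @return object of class `disturbance_scenario`
#' @export
disturbance_scenario <- function(sin_amplitude_fraction = 0.05,
                                 sin_period = 24,
                                 kinetic_events = list(
                                   list(param = "mumax", change = 0.1,
                                        start = 10 * 24, duration = 2 * 24),
                                   list(param = "Kc", change = 0.1,
                                        start = 50 * 24, duration = 2 * 24))) {
  if (sin_period <= 0) stop("sin_period must be positive")
  if (sin_amplitude_fraction < 0 || sin_amplitude_fraction >= 1) {
    stop("sin_amplitude_fraction must lie in [0, 1)")
  }
  for (ev in kinetic_events) {
    if (!all(c("param", "change", "start", "duration") %in% names(ev))) {
      stop("each kinetic event needs fields param, change, start, duration")
    }
    if (!ev$param %in% c("mumax", "Kc")) {
      stop("unknown kinetic-event parameter: ", ev$param)
    }
    if (ev$duration <= 0) stop("kinetic-event duration must be positive")
  }
  sc <- list(sin_amplitude_fraction = sin_amplitude_fraction,
             sin_period = sin_period, kinetic_events = kinetic_events)
  class(sc) <- "disturbance_scenario"
  sc
}

#' Null disturbance scenario (no influent variation, no kinetic events)
#' @return `disturbance_scenario` with zero amplitude and no events
#' @export
no_disturbance <- function() {
  disturbance_scenario(sin_amplitude_fraction = 0, sin_period = 24,
                       kinetic_events = list())
}

#' Evaluate a disturbance scenario at a time point
#'
#' @param t time (h), non-negative
#' @param sc [disturbance_scenario()]
#' @param base baseline [asp_parameters()]
#' @return list with `delta_sin` (mg/l, the influent-substrate deviation
#'   `amplitude*Sin*sin(2*pi*t/period)`) and `effective` (parameters with any
#'   active kinetic events applied)
#' @export
scenario_eval <- function(t, sc, base = asp_parameters()) {
  if (t < 0) stop("scenario_eval: t must be non-negative")
  delta_sin <- sc$sin_amplitude_fraction * base$Sin *
    sin(2 * pi * t / sc$sin_period)
  eff <- base
  for (ev in sc$kinetic_events) {
    if (t >= ev$start && t < ev$start + ev$duration) {
      eff[[ev$param]] <- eff[[ev$param]] * (1 + ev$change)
    }
  }
  list(delta_sin = delta_sin, effective = eff)
}

#' Analytic time derivative of the influent-substrate deviation
#'
#' d/dt of `delta_sin(t)`; used to form the disturbance-derivative component
#' of the observer's exogenous input (the augmented disturbance state has
#' derivative d/dt of d(t) = D(t)*delta_sin(t)).
#'
#' @inheritParams scenario_eval
#' @return derivative of delta_sin (mg/l/h)
#' @export
delta_sin_deriv <- function(t, sc, base = asp_parameters()) {
  sc$sin_amplitude_fraction * base$Sin * (2 * pi / sc$sin_period) *
    cos(2 * pi * t / sc$sin_period)
}
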