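#' Seasonal site environment
#'
#' A site's ocean temperature is modelled as a pure sinusoid between a winter
#' minimum and a summer maximum, peaking on `peak_day` and bottoming out half
#' a period later. Only the two extremes are specified by field estimates, so
#' no richer seasonal shape is imposed.
#'
#' @param t_winter_min Winter minimum mean temperature, degrees C.
#' @param t_summer_max Summer maximum mean temperature, degrees C. Must be
#'   >= `t_winter_min`.
#' @param peak_day Day of year at which the maximum occurs (0-based,
#'   in `[0, period)`).
#' @param period Length of the seasonal cycle in days (default 365).
#' @return An object of class `site_environment`.
#' @examples
#' env <- site_environment(10, 24, peak_day = 200)
#' temperature_at(200, env) # 24
#' @export
site_environment <- function(t_winter_min, t_summer_max, peak_day = 200,
                             period = 365) {
  stopifnot(is.numeric(t_winter_min), is.numeric(t_summer_max))
  if (t_summer_max < t_winter_min) {
    stop("t_summer_max must be >= t_winter_min")
  }
  if (peak_day < 0 || peak_day >= period) {
    stop("peak_day must lie in [0, period)")
  }
  structure(list(t_winter_min = t_winter_min, t_summer_max = t_summer_max,
                 peak_day = peak_day, period = period),
            class = "site_environment")
}

#' Temperature at a point in time
#'
#' @param t Time in days (vectorised, >= 0).
#' @param env A [site_environment()].
#' @return Temperature in degrees C.
#' @export
temperature_at <- function(t, env) {
  if (any(t < 0)) stop("time must be non-negative")
  mid <- (env$t_winter_min + env$t_summer_max) / 2
  amp <- (env$t_summer_max - env$t_winter_min) / 2
  mid + amp * cos(2 * pi * (t - env$peak_day) / env$period)
}

#' Ontogenetic growth parameters
#'
#' Parameters of the universal ontogenetic growth law
#' `dm/dt = a(T) m^(3/4) (1 - (m/M)^(1/4))`, taking individuals from a newborn
#' mass `m0` to an asymptotic mass `M`. Temperature enters through the growth
#' coefficient as a Q10 factor, `a(T) = a_ref * q10^((T - t_ref)/10)`, the
#' standard ectotherm metabolic scaling; warmer water means faster growth and
#' a younger age at any given mass.
#'
#' @param m0 Newborn mass, g.
#' @param M Asymptotic mass, g (> m0).
#' @param a_ref Growth coefficient at the reference temperature,
#'   g^(1/4) day^(-1).
#' @param t_ref Reference temperature, degrees C.
#' @param q10 Multiplicative change in the growth coefficient per 10 degrees C
#'   (>= 1).
#' @param t_viable Two-element physiological temperature range, degrees C;
#'   temperatures outside it are clamped (with a warning) before computing the
#'   coefficient.
#' @return An object of class `growth_params`.
#' @examples
#' gp <- growth_params()
#' growth_rate(gp$M, 15, gp) # 0 at the asymptote
#' @export
growth_params <- function(m0 = 5300, M = 160800, a_ref = 0.035,
                          t_ref = 15, q10 = 2, t_viable = c(-2, 40)) {
  stopifnot(m0 > 0, M > m0, a_ref > 0, q10 >= 1,
            length(t_viable) == 2, t_viable[1] < t_viable[2])
  structure(list(m0 = m0, M = M, a_ref = a_ref, t_ref = t_ref, q10 = q10,
                 t_viable = t_viable),
            class = "growth_params")
}

#' Temperature-dependent growth coefficient
#'
#' `a(T) = a_ref * q10^((T - t_ref)/10)`, strictly increasing in temperature.
#' Temperatures outside the configured viability range are clamped to it with
#' a warning.
#'
#' @param T_c Temperature, degrees C (vectorised).
#' @param params A [growth_params()] object.
#' @return Growth coefficient in g^(1/4) day^(-1).
#' @export
growth_coefficient <- function(T_c, params = growth_params()) {
  lo <- params$t_viable[1]
  hi <- params$t_viable[2]
  if (any(T_c < lo | T_c > hi)) {
    warning(sprintf("temperature outside viable range [%g, %g] C; clamped",
                    lo, hi))
    T_c <- pmin(pmax(T_c, lo), hi)
  }
  params$a_ref * params$q10^((T_c - params$t_ref) / 10)
}

#' Instantaneous somatic growth rate
#'
#' West-type ontogenetic growth:
#' `dm/dt = a(T) m^(3/4) (1 - (m/M)^(1/4))`. Zero at the asymptotic mass,
#' positive below it.
#'
#' @param m Mass in g (vectorised; must satisfy `0 < m <= M`).
#' @inheritParams growth_coefficient
#' @param T_c Temperature, degrees C.
#' @return Growth rate in g/day.
#' @export
growth_rate <- function(m, T_c, params = growth_params()) {
  if (any(m <= 0) || any(m > params$M)) {
    stop("mass must lie in (0, M]")
  }
  a <- growth_coefficient(T_c, params)
  a * m^0.75 * (1 - (m / params$M)^0.25)
}

#' Mass along the constant-temperature growth trajectory
#'
#' Closed-form solution of the growth law at constant temperature:
#' `1 - (m(t)/M)^(1/4) = (1 - (m0/M)^(1/4)) exp(-a t / (4 M^(1/4)))`.
#'
#' @param t Age in days (vectorised, >= 0).
#' @inheritParams growth_rate
#' @return Mass in g.
#' @export
mass_at_age <- function(t, T_c, params = growth_params()) {
  if (any(t < 0)) stop("age must be non-negative")
  a <- growth_coefficient(T_c, params)
  u0 <- 1 - (params$m0 / params$M)^0.25
  u <- u0 * exp(-a * t / (4 * params$M^0.25))
  params$M * (1 - u)^4
}

#' Age at which a mass is reached at constant temperature
#'
#' Inverts [mass_at_age()]; strictly decreasing in temperature, reflecting
#' faster growth in warm water.
#'
#' @param m_target Target mass in g, strictly between `m0` and `M`.
#' @inheritParams growth_rate
#' @return Age in days.
#' @export
age_at_mass <- function(m_target, T_c, params = growth_params()) {
  if (any(m_target <= params$m0) || any(m_target >= params$M)) {
    stop("target mass must lie strictly between m0 and M")
  }
  a <- growth_coefficient(T_c, params)
  u0 <- 1 - (params$m0 / params$M)^0.25
  u <- 1 - (m_target / params$M)^0.25
  -4 * params$M^0.25 / a * log(u / u0)
}
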