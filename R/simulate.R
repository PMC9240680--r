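#' Demographic rate parameters
#'
#' Per-capita reproduction and mortality rates, in day^-1. Reproduction takes
#' place only at the juvenile (nursery) site and only among females at or
#' above the maturation mass; mortality is constant across size classes and
#' sites. Defaults are the field estimates 0.47e-7 female inds/s and
#' 5.71e-9 inds/s, converted to per-day.
#'
#' @param r Per-capita reproduction rate at the juvenile site, day^-1.
#' @param mu Per-capita mortality rate, day^-1.
#' @return An object of class `demography_params`.
#' @export
demography_params <- function(r = 0.47e-7 * 86400, mu = 5.71e-9 * 86400) {
  stopifnot(r >= 0, mu >= 0)
  structure(list(r = r, mu = mu), class = "demography_params")
}

#' Dispersal parameters
#'
#' Juvenile dispersal is mass-triggered: the per-capita rate of leaving the
#' nursery rises sigmoidally (logistic) from 0 to `k_j_max` around the
#' maturation mass `m_j`, with width `xi_j` (the juvenile dispersal window, in
#' grams; small `xi_j` = strict size threshold). Adult dispersal back to the
#' nursery is time-triggered: an annual wrapped-Gaussian pulse centred on
#' `t_peak` with spread `xi_a` (the adult dispersal window, in days; small
#' `xi_a` = tightly synchronised migration), whose integral over one year is
#' `k_a_annual` expected migrations per adult. Visiting adults return to the
#' adult site after `residence` days.
#'
#' @param m_j Maturation / first-dispersal mass threshold, g.
#' @param xi_j Juvenile dispersal window, g (> 0).
#' @param t_peak Day of year of peak adult migration to the nursery.
#' @param xi_a Adult dispersal window, days (> 0).
#' @param residence Days visiting adults spend at the nursery before
#'   returning (>= 0).
#' @param k_j_max Maximum per-capita juvenile dispersal rate, day^-1.
#' @param k_a_annual Expected adult migrations per year (annual integral of
#'   the dispersal pulse).
#' @return An object of class `dispersal_params`.
#' @export
dispersal_params <- function(m_j = 66000, xi_j = 2000, t_peak = 130,
                             xi_a = 30, residence = 150,
                             k_j_max = 0.05, k_a_annual = 2) {
  stopifnot(m_j > 0, xi_j > 0, xi_a > 0, residence >= 0,
            k_j_max >= 0, k_a_annual >= 0)
  structure(list(m_j = m_j, xi_j = xi_j, t_peak = t_peak, xi_a = xi_a,
                 residence = residence, k_j_max = k_j_max,
                 k_a_annual = k_a_annual),
            class = "dispersal_params")
}

#' Tooth shedding model
#'
#' Living sharks continuously replace and drop teeth; the accumulated
#' dentition at a site therefore mirrors the size structure of the sharks
#' occupying it. The default is a constant per-capita shedding rate; an
#' optional seasonal modulation `1 + amplitude * cos(...)` peaking on
#' `seasonal_peak_day` is available (it has little effect on distribution
#' shapes, but is kept as an explicit variant).
#'
#' @param base_rate Teeth shed per individual per day.
#' @param seasonal_amplitude Relative seasonal modulation, in `[0, 1)`.
#' @param seasonal_peak_day Day of year of peak shedding.
#' @return An object of class `shedding_model`.
#' @export
shedding_model <- function(base_rate = 0.1, seasonal_amplitude = 0,
                           seasonal_peak_day = 200) {
  stopifnot(base_rate > 0, seasonal_amplitude >= 0, seasonal_amplitude < 1)
  structure(list(base_rate = base_rate,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_peak_day = seasonal_peak_day),
            class = "shedding_model")
}

#' Simulation grid settings
#'
#' Mass discretisation and time stepping for the size-class simulation. Mass
#' bins default to 60 log-spaced bins from half the newborn mass to 5% above
#' the asymptotic mass (log spacing resolves the fast early growth phase);
#' teeth are accumulated only after `burn_in_years`, once the population size
#' structure has converged.
#'
#' @param mass_bin_edges Optional explicit bin edges in g (strictly
#'   increasing). If `NULL`, edges are built from the growth parameters at run
#'   time.
#' @param n_bins Number of mass bins when edges are auto-built (>= 30).
#' @param dt Time step, days.
#' @param n_years Total simulated years.
#' @param burn_in_years Years discarded before tooth accumulation
#'   (< `n_years`).
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(mass_bin_edges = NULL, n_bins = 60, dt = 1,
                     n_years = 60, burn_in_years = 40) {
  stopifnot(dt > 0, n_years > 0, burn_in_years >= 0,
            burn_in_years < n_years)
  if (!is.null(mass_bin_edges)) {
    stopifnot(all(diff(mass_bin_edges) > 0))
    n_bins <- length(mass_bin_edges) - 1
  }
  if (n_bins < 30) stop("at least 30 mass bins are required")
  structure(list(mass_bin_edges = mass_bin_edges, n_bins = n_bins, dt = dt,
                 n_years = n_years, burn_in_years = burn_in_years),
            class = "sim_grid")
}

#' Per-capita juvenile dispersal rate as a function of mass
#'
#' `k_j_max * logistic((m - m_j) / xi_j)`: sigmoidal in mass, half-maximal at
#' the maturation mass, approaching a hard step as `xi_j -> 0`.
#'
#' @param m Mass in g (vectorised, > 0).
#' @param disp A [dispersal_params()] object.
#' @return Rate in day^-1, in `(0, k_j_max)`.
#' @export
juvenile_dispersal_rate <- function(m, disp = dispersal_params()) {
  if (any(m <= 0)) stop("mass must be positive")
  disp$k_j_max * stats::plogis((m - disp$m_j) / disp$xi_j)
}

#' Per-capita adult dispersal rate as a function of time
#'
#' An annual wrapped-Gaussian pulse centred on `t_peak` with spread `xi_a`,
#' normalised so its integral over one year equals `k_a_annual` expected
#' migrations per adult. 365-day periodic.
#'
#' @param t Time in days (vectorised, >= 0).
#' @param disp A [dispersal_params()] object.
#' @param period Length of the year in days.
#' @return Rate in day^-1, maximal at `t_peak` (mod `period`).
#' @export
adult_dispersal_rate <- function(t, disp = dispersal_params(), period = 365) {
  if (any(t < 0)) stop("time must be non-negative")
  d <- (t - disp$t_peak) %% period
  dens <- 0
  for (k in -4:4) {
    dens <- dens + stats::dnorm(d + k * period, mean = 0, sd = disp$xi_a)
  }
  disp$k_a_annual * dens
}

#' Create an empty population state
#'
#' The state tracks female abundance per mass bin in three pools: natal
#' juveniles at the nursery, residents of the adult site, and adults
#' currently visiting the nursery (with a fixed-delay return queue).
#'
#' @param mass_bin_edges Strictly increasing mass bin edges, g.
#' @param n_delay Number of time steps a visiting adult stays at the nursery
#'   (`residence / dt`, rounded).
#' @param time Initial time in days.
#' @return An object of class `population_state`.
#' @export
population_state <- function(mass_bin_edges, n_delay = 150, time = 0) {
  stopifnot(all(diff(mass_bin_edges) > 0), n_delay >= 0)
  nb <- length(mass_bin_edges) - 1
  centers <- sqrt(mass_bin_edges[-1] * mass_bin_edges[-(nb + 1)])
  structure(
    list(time = time,
         edges = mass_bin_edges,
         centers = centers,
         widths = diff(mass_bin_edges),
         juv = numeric(nb),
         adult = numeric(nb),
         visit = numeric(nb),
         queue = matrix(0, nrow = max(n_delay, 1), ncol = nb),
         n_delay = n_delay,
         qpos = 1L),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(paste0("Population state at t = %.1f d: juveniles %.4g, ",
                     "adults %.4g, visiting adults %.4g\n"),
              x$time, sum(x$juv), sum(x$adult), sum(x$visit)))
  invisible(x)
}

#' Total abundance in a population state
#'
#' @param state A [population_state()].
#' @return Total female abundance across all pools.
#' @export
total_abundance <- function(state) {
  sum(state$juv) + sum(state$adult) + sum(state$visit)
}

# One integration step. Split-operator update in the order: growth advection
# (upwind), mortality, reproduction, juvenile dispersal, adult dispersal with
# delayed return. a_juv / a_adult are the growth coefficients a(T) at the two
# sites' current temperatures; k_a_rate is the adult dispersal rate at the
# current time. Errors out if any transfer fraction reaches 1 (CFL).
advance_state <- function(state, dt, a_juv, a_adult, k_a_rate, demo, disp,
                          growth) {
  ctr <- state$centers
  nb <- length(ctr)

  # growth advection: upwind transfer toward the next-larger bin; the flux
  # base m^(3/4)(1-(m/M)^(1/4)) is clamped to 0 above the asymptote so the
  # top bin absorbs
  base <- ctr^0.75 * pmax(0, 1 - (ctr / growth$M)^0.25)
  cour_juv <- a_juv * base * dt / state$widths
  cour_adu <- a_adult * base * dt / state$widths
  if (max(cour_juv, cour_adu) >= 1) {
    stop("CFL violation in growth advection: reduce dt or coarsen bins")
  }
  shift_up <- function(n, cour) {
    out <- cour * n
    out[nb] <- 0
    n - out + c(0, out[-nb])
  }
  juv <- shift_up(state$juv, cour_juv)
  adult <- shift_up(state$adult, cour_adu)
  visit <- state$visit # visiting adults sit near M; no advection during visit

  # mortality: exact exponential decay in every pool
  surv <- exp(-demo$mu * dt)
  juv <- juv * surv
  adult <- adult * surv
  visit <- visit * surv

  # reproduction: mature females present at the nursery produce newborns
  # into the m0 bin of the natal pool
  mature <- ctr >= disp$m_j
  m0_bin <- findInterval(growth$m0, state$edges, rightmost.closed = TRUE)
  m0_bin <- min(max(m0_bin, 1L), nb)
  births <- demo$r * dt * (sum(juv[mature]) + sum(visit[mature]))
  juv[m0_bin] <- juv[m0_bin] + births

  # juvenile dispersal: mass-sigmoidal transfer nursery -> adult site
  frac_j <- juvenile_dispersal_rate(ctr, disp) * dt
  if (max(frac_j) >= 1) {
    stop("CFL violation in juvenile dispersal: k_j_max * dt must be < 1")
  }
  moved_j <- frac_j * juv
  juv <- juv - moved_j
  adult <- adult + moved_j

  # adult dispersal: pulsed transfer adult site -> nursery, with return to
  # the adult site after the residence delay (mortality-decayed)
  frac_a <- k_a_rate * dt
  if (frac_a >= 1) {
    stop("CFL violation in adult dispersal: peak rate * dt must be < 1")
  }
  arrivals <- frac_a * adult
  adult <- adult - arrivals
  visit <- visit + arrivals
  if (state$n_delay > 0) {
    dep <- state$queue[state$qpos, ] * exp(-demo$mu * state$n_delay * dt)
    state$queue[state$qpos, ] <- arrivals
    state$qpos <- if (state$qpos == state$n_delay) 1L else state$qpos + 1L
  } else {
    dep <- arrivals
  }
  visit <- pmax(visit - dep, 0)
  adult <- adult + dep

  state$juv <- juv
  state$adult <- adult
  state$visit <- visit
  state$time <- state$time + dt
  state
}

#' Advance the population state by one time step
#'
#' Applies, in order: growth advection across mass bins (upwind, at each
#' site's current temperature), mortality, reproduction at the nursery,
#' mass-triggered juvenile dispersal, and pulsed adult dispersal with a
#' fixed-delay return. Abundances remain non-negative; any per-step transfer
#' fraction reaching 1 raises an error naming the offending rate.
#'
#' @param state A [population_state()].
#' @param dt Time step, days.
#' @param envs List with elements `juvenile` and `adult`, each a
#'   [site_environment()].
#' @param demo A [demography_params()] object.
#' @param disp A [dispersal_params()] object.
#' @param growth A [growth_params()] object.
#' @return The updated `population_state`.
#' @export
step_population <- function(state, dt, envs, demo, disp, growth) {
  if (any(!is.finite(c(state$juv, state$adult, state$visit)))) {
    stop("non-finite abundances in population state")
  }
  a_j <- growth_coefficient(temperature_at(state$time, envs$juvenile), growth)
  a_a <- growth_coefficient(temperature_at(state$time, envs$adult), growth)
  k_a <- adult_dispersal_rate(state$time, disp)
  advance_state(state, dt, a_j, a_a, k_a, demo, disp, growth)
}

#' Create an empty tooth accumulator
#'
#' Holds accumulated shed-tooth counts per site and crown-height bin.
#'
#' @param edges_mm Strictly increasing crown-height bin edges, mm.
#' @return An object of class `tooth_accumulator`.
#' @export
tooth_accumulator <- function(edges_mm) {
  stopifnot(all(diff(edges_mm) > 0))
  counts <- matrix(0, nrow = 2, ncol = length(edges_mm) - 1,
                   dimnames = list(c("juvenile", "adult"), NULL))
  structure(list(edges_mm = edges_mm, counts = counts),
            class = "tooth_accumulator")
}

#' @export
print.tooth_accumulator <- function(x, ...) {
  cat(sprintf("Tooth accumulator: %d crown-height bins (%.1f-%.1f mm)\n",
              ncol(x$counts), min(x$edges_mm), max(x$edges_mm)))
  cat(sprintf("  juvenile site: %.4g teeth; adult site: %.4g teeth\n",
              sum(x$counts["juvenile", ]), sum(x$counts["adult", ])))
  invisible(x)
}

#' Normalised dental distribution of an accumulator
#'
#' @param acc A [tooth_accumulator()].
#' @return Matrix of per-site probabilities (rows sum to 1 when non-empty).
#' @export
normalized_counts <- function(acc) {
  tot <- rowSums(acc$counts)
  sweep(acc$counts, 1, ifelse(tot > 0, tot, 1), "/")
}

#' Accumulate shed teeth for one time step
#'
#' Adds `shed_rate(t) * abundance * dt` for each site and mass bin, mapped to
#' crown-height bins through the allometry. Teeth shed by visiting adults are
#' attributed to the nursery they currently occupy.
#'
#' @param state A [population_state()].
#' @param dt Time step, days.
#' @param shed A [shedding_model()] object.
#' @param allom An [allometry_params()] object.
#' @param acc A [tooth_accumulator()].
#' @param period Length of the year in days.
#' @return The updated accumulator.
#' @export
accumulate_teeth <- function(state, dt, shed, allom, acc, period = 365) {
  rate <- shed$base_rate *
    (1 + shed$seasonal_amplitude *
       cos(2 * pi * (state$time - shed$seasonal_peak_day) / period))
  th <- mass_to_tooth(state$centers, allom)
  idx <- findInterval(th, acc$edges_mm, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= ncol(acc$counts)
  add_site <- function(row, n) {
    inc <- rate * dt * n[keep]
    tab <- rowsum(inc, idx[keep])
    acc$counts[row, as.integer(rownames(tab))] <<-
      acc$counts[row, as.integer(rownames(tab))] + tab[, 1]
  }
  add_site("juvenile", state$juv + state$visit)
  add_site("adult", state$adult)
  acc
}

#' Run the two-site metapopulation simulation
#'
#' Integrates the size-class dynamics for `n_years`, discards the burn-in,
#' and accumulates the dental distributions shed at each site thereafter.
#' Fully deterministic: identical configurations give bit-identical
#' accumulators.
#'
#' @param config A run configuration as produced by [default_config()] /
#'   [load_config()].
#' @return An object of class `sim_result` with elements `accumulator`
#'   (a [tooth_accumulator()]), `trajectory` (data frame of yearly per-pool
#'   totals), `state` (final [population_state()]), `config_hash` and
#'   `diagnostics`.
#' @examples
#' \donttest{
#' cfg <- default_config()
#' cfg$grid$n_years <- 12
#' cfg$grid$burn_in_years <- 8
#' res <- run_simulation(cfg)
#' res$accumulator
#' }
#' @export
run_simulation <- function(config) {
  config <- validate_config(config)
  grd <- config$grid
  growth <- config$growth
  disp <- config$dispersal
  demo <- config$demography
  shed <- config$shedding
  allom <- config$allometry

  edges <- grd$mass_bin_edges
  if (is.null(edges)) {
    edges <- exp(seq(log(0.5 * growth$m0), log(1.05 * growth$M),
                     length.out = grd$n_bins + 1))
  }
  if (edges[1] > growth$m0 || edges[length(edges)] < growth$M) {
    stop("mass bin edges must span [m0, M]")
  }

  dt <- grd$dt
  n_steps <- round(grd$n_years * 365 / dt)
  burn_steps <- round(grd$burn_in_years * 365 / dt)
  n_delay <- round(disp$residence / dt)

  state <- population_state(edges, n_delay = n_delay)
  m0_bin <- findInterval(growth$m0, edges, rightmost.closed = TRUE)
  state$juv[m0_bin] <- 1

  # precompute per-step forcings (temperatures only enter via a(T))
  times <- (seq_len(n_steps) - 1) * dt
  a_juv <- growth_coefficient(temperature_at(times, config$sites$juvenile),
                              growth)
  a_adu <- growth_coefficient(temperature_at(times, config$sites$adult),
                              growth)
  k_a <- adult_dispersal_rate(times, disp)
  shed_rate <- shed$base_rate *
    (1 + shed$seasonal_amplitude *
       cos(2 * pi * (times - shed$seasonal_peak_day) / 365))

  # teeth are accumulated in mass-bin space and mapped to crown-height bins
  # once at the end (the mapping is static, so this is exact)
  nb <- length(edges) - 1
  acc_mass <- matrix(0, nrow = 2, ncol = nb,
                     dimnames = list(c("juvenile", "adult"), NULL))
  yearly <- matrix(0, nrow = grd$n_years, ncol = 3)

  for (k in seq_len(n_steps)) {
    state <- advance_state(state, dt, a_juv[k], a_adu[k], k_a[k], demo, disp,
                           growth)
    if (k > burn_steps) {
      w <- shed_rate[k] * dt
      acc_mass[1, ] <- acc_mass[1, ] + w * (state$juv + state$visit)
      acc_mass[2, ] <- acc_mass[2, ] + w * state$adult
    }
    if (k %% round(365 / dt) == 0) {
      yr <- k %/% round(365 / dt)
      if (yr >= 1 && yr <= grd$n_years) {
        yearly[yr, ] <- c(sum(state$juv), sum(state$adult), sum(state$visit))
      }
      if (any(!is.finite(c(state$juv, state$adult, state$visit)))) {
        stop(sprintf("non-finite state at year %d; check rates and dt", yr))
      }
    }
  }

  th <- mass_to_tooth(state$centers, allom)
  max_mm <- ceiling(max(th)) + 1
  tooth_edges <- seq(0, max_mm, by = 0.5)
  acc <- tooth_accumulator(tooth_edges)
  idx <- findInterval(th, tooth_edges, rightmost.closed = TRUE)
  for (row in 1:2) {
    tab <- rowsum(acc_mass[row, ], idx)
    acc$counts[row, as.integer(rownames(tab))] <- tab[, 1]
  }

  trajectory <- data.frame(year = seq_len(grd$n_years),
                           juvenile = yearly[, 1], adult = yearly[, 2],
                           visiting = yearly[, 3])
  structure(
    list(accumulator = acc,
         trajectory = trajectory,
         state = state,
         config_hash = config_hash(config),
         diagnostics = list(
           n_steps = n_steps,
           max_courant = max(c(a_juv, a_adu)) *
             max(state$centers^0.75 *
                   pmax(0, 1 - (state$centers / growth$M)^0.25) /
                   state$widths) * dt,
           final_total = total_abundance(state))),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Two-site metapopulation simulation\n")
  cat(sprintf("  steps: %d, config hash: %s\n", x$diagnostics$n_steps,
              x$config_hash))
  print(x$accumulator)
  invisible(x)
}

#' Total-variation distance between two normalised histograms
#'
#' @param p,q Non-negative vectors on the same bins; each is normalised to
#'   sum 1 before comparison.
#' @return Total-variation distance in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (sum(p) == 0 || sum(q) == 0) stop("empty histogram")
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}
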