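#' Dental distribution
#'
#' The object being compared throughout the package: a size-frequency
#' distribution of anterior tooth crown heights at one locality, either as a
#' raw sample of measurements or as a histogram (as produced by the
#' simulator's tooth accumulator).
#'
#' @param values Raw crown heights in mm (all > 0), or `NULL` when a
#'   histogram is supplied.
#' @param edges_mm Histogram bin edges in mm (with `counts`).
#' @param counts Histogram bin contents (non-negative; need not be integer —
#'   the simulator accumulates continuous tooth mass).
#' @param site_label Free-text locality label.
#' @return An object of class `dental_distribution`.
#' @examples
#' d <- dental_distribution(values = rlnorm(100, log(15), 0.2))
#' d$n
#' @export
dental_distribution <- function(values = NULL, edges_mm = NULL, counts = NULL,
                                site_label = "") {
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (any(!is.finite(values)) || any(values <= 0)) {
      stop("crown heights must be positive and finite")
    }
    out <- list(kind = "sample", values = values, site_label = site_label,
                n = length(values))
  } else {
    stopifnot(!is.null(edges_mm), !is.null(counts),
              length(counts) == length(edges_mm) - 1)
    if (any(counts < 0) || sum(counts) <= 0) {
      stop("histogram counts must be non-negative with positive total")
    }
    out <- list(kind = "histogram", edges_mm = edges_mm, counts = counts,
                site_label = site_label, n = sum(counts))
  }
  structure(out, class = "dental_distribution")
}

#' Extract one site's dental distribution from a simulation
#'
#' @param x A `sim_result` or [tooth_accumulator()].
#' @param site `"juvenile"` or `"adult"`.
#' @return A histogram-backed [dental_distribution()].
#' @export
site_distribution <- function(x, site = c("juvenile", "adult")) {
  site <- match.arg(site)
  acc <- if (inherits(x, "sim_result")) x$accumulator else x
  stopifnot(inherits(acc, "tooth_accumulator"))
  dental_distribution(edges_mm = acc$edges_mm, counts = acc$counts[site, ],
                      site_label = site)
}

#' @export
print.dental_distribution <- function(x, ...) {
  cat(sprintf("Dental distribution%s (%s, n = %.4g)\n",
              if (nzchar(x$site_label)) paste0(" '", x$site_label, "'") else "",
              x$kind, x$n))
  invisible(x)
}

# weighted Silverman-type bandwidth; nominal n for histogram input because a
# simulated accumulator is a density, not a finite sample
hist_bandwidth <- function(mids, p, nominal_n = 5000) {
  mu <- sum(p * mids)
  sdv <- sqrt(sum(p * (mids - mu)^2))
  cdf <- cumsum(p)
  q <- stats::approx(cdf, mids, xout = c(0.25, 0.75), ties = "ordered",
                     rule = 2)$y
  spread <- min(sdv, diff(q) / 1.34)
  if (spread <= 0) spread <- sdv
  bw <- 0.9 * spread * nominal_n^(-1 / 5)
  max(bw, min(diff(mids)))
}

density_of <- function(dist, n_grid = 512) {
  if (dist$kind == "sample") {
    if (stats::sd(dist$values) == 0) return(NULL)
    stats::density(dist$values, bw = "nrd0", n = n_grid)
  } else {
    mids <- (dist$edges_mm[-1] + dist$edges_mm[-length(dist$edges_mm)]) / 2
    p <- dist$counts / sum(dist$counts)
    keep <- p > 0
    if (sum(keep) < 2) return(NULL)
    stats::density(mids[keep], weights = p[keep] / sum(p[keep]),
                   bw = hist_bandwidth(mids[keep], p[keep] / sum(p[keep])),
                   n = n_grid)
  }
}

degenerate_location <- function(dist) {
  if (dist$kind == "sample") return(dist$values[1])
  mids <- (dist$edges_mm[-1] + dist$edges_mm[-length(dist$edges_mm)]) / 2
  mids[which.max(dist$counts)]
}

# peak prominences as in standard signal practice: on each side of a peak,
# take the minimum until a strictly higher point (or the boundary); the
# prominence is the height above the higher of the two side minima
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    side_min <- function(idx) {
      if (length(idx) == 0) return(min(y[p]))
      higher <- which(y[idx] > y[p])
      if (length(higher) > 0) idx <- idx[seq_len(higher[1])]
      min(y[idx])
    }
    lmin <- side_min(rev(seq_len(p - 1)))
    rmin <- side_min(if (p < length(y)) (p + 1):length(y) else integer(0))
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Estimate the modes of a dental distribution
#'
#' Modes are local maxima of a kernel density estimate (Gaussian kernel,
#' Silverman's rule) whose prominence is at least `prominence_frac` of the
#' global density maximum. A degenerate sample (all values identical) has one
#' mode at that value.
#'
#' @param dist A [dental_distribution()] with at least 20 observations.
#' @param prominence_frac Minimum peak prominence as a fraction of the global
#'   density maximum.
#' @param n_grid Density evaluation grid size.
#' @return An object of class `mode_estimate`: list with `locations` (mm,
#'   ascending) and `prominences` (density units, matched to locations).
#' @export
estimate_modes <- function(dist, prominence_frac = 0.05, n_grid = 512) {
  stopifnot(inherits(dist, "dental_distribution"))
  if (dist$kind == "sample" && dist$n < 20) {
    stop("at least 20 measurements are required for mode estimation")
  }
  den <- density_of(dist, n_grid)
  if (is.null(den)) {
    return(structure(list(locations = degenerate_location(dist),
                          prominences = Inf),
                     class = "mode_estimate"))
  }
  y <- den$y
  ny <- length(y)
  peaks <- which(y > c(-Inf, y[-ny]) & y >= c(y[-1], -Inf))
  prom <- peak_prominences(y, peaks)
  keep <- prom >= prominence_frac * max(y)
  if (!any(keep)) { # extremely flat density: fall back to the global max
    keep <- which.max(prom)
  }
  loc <- den$x[peaks[keep]]
  prm <- prom[keep]
  o <- order(loc)
  structure(list(locations = loc[o], prominences = prm[o]),
            class = "mode_estimate")
}

#' @export
print.mode_estimate <- function(x, ...) {
  cat(sprintf("%d mode(s) at %s mm\n", length(x$locations),
              paste(sprintf("%.2f", x$locations), collapse = ", ")))
  invisible(x)
}

weighted_quantiles <- function(edges, counts, probs) {
  cdf <- c(0, cumsum(counts) / sum(counts))
  stats::approx(cdf, edges, xout = probs, ties = "ordered", rule = 2)$y
}

#' Compute the seven-parameter shape vector of a dental distribution
#'
#' The seven shape parameters summarising a dental distribution: mean (mm),
#' variance (mm^2), 25th/50th/75th percentiles (mm), the number of modes
#' (capped at the `max_modes` most prominent), and the distance between the
#' two most prominent modes (Delta mode, mm; 0 when unimodal). Percentiles of
#' raw samples use the linear-interpolation convention
#' (`quantile(..., type = 7)`); histogram percentiles interpolate the
#' cumulative histogram across bin edges.
#'
#' @inheritParams estimate_modes
#' @param max_modes Cap on the number of modes entering the shape vector.
#' @return An object of class `shape_vector`: named numeric of length 7
#'   (`mean`, `variance`, `p25`, `p50`, `p75`, `n_modes`, `delta_mode`).
#' @export
compute_shape_vector <- function(dist, prominence_frac = 0.05,
                                 max_modes = 2) {
  stopifnot(inherits(dist, "dental_distribution"))
  if (dist$kind == "sample") {
    if (dist$n < 20) stop("at least 20 measurements are required")
    v <- dist$values
    m <- mean(v)
    vv <- stats::var(v)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  } else {
    mids <- (dist$edges_mm[-1] + dist$edges_mm[-length(dist$edges_mm)]) / 2
    p <- dist$counts / sum(dist$counts)
    m <- sum(p * mids)
    vv <- sum(p * (mids - m)^2)
    q <- weighted_quantiles(dist$edges_mm, dist$counts, c(0.25, 0.5, 0.75))
  }
  modes <- estimate_modes(dist, prominence_frac = prominence_frac)
  k <- min(length(modes$locations), max_modes)
  if (length(modes$locations) > max_modes) {
    top <- order(modes$prominences, decreasing = TRUE)[seq_len(max_modes)]
    kept <- sort(modes$locations[top])
  } else {
    kept <- modes$locations
  }
  delta <- if (k >= 2) diff(range(kept)) else 0
  out <- c(mean = m, variance = vv, p25 = q[1], p50 = q[2], p75 = q[3],
           n_modes = k, delta_mode = delta)
  structure(out, class = "shape_vector")
}

#' @export
print.shape_vector <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Relative-error statistic between two shape vectors
#'
#' The fit error between a simulated and an observed dental distribution:
#' `epsilon = sum_k |w_k_sim - w_k_obs| / w_k_obs` over the seven shape
#' parameters. A zero (or near-zero) observed component — typically Delta
#' mode for unimodal data — would make the relative error undefined, so the
#' denominator is floored at `delta_floor` in that parameter's units; the
#' floored components are recorded in the `"floored"` attribute.
#'
#' @param sim,obs [compute_shape_vector()] results (or named numerics of
#'   length 7).
#' @param delta_floor Denominator floor, default 0.1.
#' @return Non-negative scalar epsilon; 0 iff the vectors are equal on their
#'   non-degenerate components.
#' @export
error_epsilon <- function(sim, obs, delta_floor = 0.1) {
  sim <- as.numeric(sim)
  obs <- as.numeric(obs)
  stopifnot(length(sim) == 7, length(obs) == 7, all(is.finite(obs)),
            all(is.finite(sim)))
  den <- pmax(abs(obs), delta_floor)
  eps <- sum(abs(sim - obs) / den)
  attr(eps, "floored") <- which(abs(obs) < delta_floor)
  eps
}

#' Bootstrap uncertainty of the shape parameters
#'
#' Resamples a raw dental distribution with replacement, recomputes the shape
#' vector for each replicate, and reports the spread of each parameter. Used
#' to judge whether a locality's sample size is adequate for shape
#' estimation.
#'
#' @param dist A sample-backed [dental_distribution()] with `n >= 20`.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed for reproducibility.
#' @param conf Confidence level for the percentile intervals.
#' @return A data frame with one row per shape parameter: `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
bootstrap_shape_uncertainty <- function(dist, B = 1000, seed = 1,
                                        conf = 0.95) {
  stopifnot(inherits(dist, "dental_distribution"))
  if (dist$kind != "sample") stop("bootstrap requires a raw sample")
  if (dist$n < 20) stop("at least 20 measurements are required")
  if (B < 100) stop("B must be at least 100")
  set.seed(seed)
  est <- compute_shape_vector(dist)
  reps <- matrix(NA_real_, nrow = B, ncol = 7)
  for (b in seq_len(B)) {
    res <- dental_distribution(values = sample(dist$values, dist$n,
                                               replace = TRUE))
    reps[b, ] <- as.numeric(compute_shape_vector(res))
  }
  alpha <- (1 - conf) / 2
  data.frame(
    parameter = names(unclass(est)),
    estimate = as.numeric(est),
    se = apply(reps, 2, stats::sd),
    lower = apply(reps, 2, stats::quantile, probs = alpha),
    upper = apply(reps, 2, stats::quantile, probs = 1 - alpha),
    row.names = NULL
  )
}
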