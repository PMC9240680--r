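#' Default run configuration
#'
#' Assembles the full parameter set for a simulation run: the two seasonal
#' site environments (a warm nursery and a cooler pelagic adult habitat),
#' demography, dispersal, growth, allometry, numerical grid and tooth
#' shedding. Every block can be overridden piecemeal or from a YAML/JSON file
#' via [load_config()].
#'
#' @return A named list of class `dentdist_config` with blocks `sites`,
#'   `demography`, `dispersal`, `growth`, `allometry`, `grid`, `shedding`.
#' @examples
#' cfg <- default_config()
#' cfg$dispersal$xi_j
#' @export
default_config <- function() {
  structure(
    list(sites = list(juvenile = site_environment(10, 24, peak_day = 200),
                      adult = site_environment(8, 16, peak_day = 200)),
         demography = demography_params(),
         dispersal = dispersal_params(),
         growth = growth_params(),
         allometry = allometry_params(),
         grid = sim_grid(),
         shedding = shedding_model()),
    class = "dentdist_config"
  )
}

block_constructors <- function() {
  list(demography = demography_params,
       dispersal = dispersal_params,
       growth = growth_params,
       allometry = allometry_params,
       grid = sim_grid,
       shedding = shedding_model)
}

rebuild_block <- function(name, fields) {
  ctor <- block_constructors()[[name]]
  ok <- intersect(names(fields), names(formals(ctor)))
  bad <- setdiff(names(fields), names(formals(ctor)))
  if (length(bad)) {
    stop(sprintf("unknown field(s) in '%s' block: %s", name,
                 paste(bad, collapse = ", ")))
  }
  tryCatch(do.call(ctor, fields[ok]),
           error = function(e) {
             stop(sprintf("invalid '%s' block: %s", name, conditionMessage(e)),
                  call. = FALSE)
           })
}

#' Validate (and complete) a run configuration
#'
#' Missing blocks are filled from [default_config()]; present blocks are
#' re-validated against their type invariants. Errors name the offending
#' block.
#'
#' @param config A configuration list.
#' @return A validated `dentdist_config`.
#' @export
validate_config <- function(config) {
  def <- default_config()
  for (nm in names(def)) {
    if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
  }
  stopifnot(is.list(config$sites),
            inherits(config$sites$juvenile, "site_environment"),
            inherits(config$sites$adult, "site_environment"))
  for (nm in names(block_constructors())) {
    blk <- config[[nm]]
    if (!inherits(blk, class(def[[nm]]))) {
      stop(sprintf("'%s' block has wrong type", nm))
    }
    rebuild_block(nm, unclass(blk)) # re-check invariants
  }
  class(config) <- "dentdist_config"
  config
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a (possibly partial) configuration file, converts any printed
#' per-second demographic rates (`r_per_sec`, `mu_per_sec`) to per-day,
#' merges the result over the package defaults and validates every block.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `dentdist_config`; the attribute `"config_hash"` holds
#'   a stable hash of the result.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()

  if (!is.null(raw$sites)) {
    for (s in intersect(names(raw$sites), c("juvenile", "adult"))) {
      fields <- raw$sites[[s]]
      cur <- unclass(cfg$sites[[s]])
      cur[names(fields)] <- fields
      cfg$sites[[s]] <- tryCatch(do.call(site_environment, cur),
                                 error = function(e) {
                                   stop(sprintf("invalid site '%s': %s", s,
                                                conditionMessage(e)),
                                        call. = FALSE)
                                 })
    }
  }
  if (!is.null(raw$demography)) {
    dem <- raw$demography
    if (!is.null(dem$r_per_sec)) {
      dem$r <- dem$r_per_sec * 86400
      dem$r_per_sec <- NULL
    }
    if (!is.null(dem$mu_per_sec)) {
      dem$mu <- dem$mu_per_sec * 86400
      dem$mu_per_sec <- NULL
    }
    raw$demography <- dem
  }
  for (nm in names(block_constructors())) {
    if (!is.null(raw[[nm]])) {
      cur <- unclass(cfg[[nm]])
      cur[names(raw[[nm]])] <- raw[[nm]]
      cfg[[nm]] <- rebuild_block(nm, cur)
    }
  }
  cfg <- validate_config(cfg)
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Stable hash of a configuration
#'
#' @param config A configuration list.
#' @return Character hash, identical for identical configurations.
#' @export
config_hash <- function(config) {
  flat <- lapply(unclass(config), function(b) {
    if (is.list(b)) lapply(b, unclass) else unclass(b)
  })
  rlang::hash(flat)
}

#' @export
print.dentdist_config <- function(x, ...) {
  cat("dentdist run configuration (hash", config_hash(x), ")\n")
  cat(sprintf("  nursery %g-%g C, adult site %g-%g C\n",
              x$sites$juvenile$t_winter_min, x$sites$juvenile$t_summer_max,
              x$sites$adult$t_winter_min, x$sites$adult$t_summer_max))
  cat(sprintf("  xi_j = %g g, xi_a = %g d, m_j = %g g, residence = %g d\n",
              x$dispersal$xi_j, x$dispersal$xi_a, x$dispersal$m_j,
              x$dispersal$residence))
  cat(sprintf("  %d mass bins, dt = %g d, %d years (%d burn-in)\n",
              x$grid$n_bins, x$grid$dt, x$grid$n_years,
              x$grid$burn_in_years))
  invisible(x)
}
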