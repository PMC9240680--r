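anterior_positions <- c("A1", "A2", "a1", "a2")

#' Read a tooth-measurement CSV
#'
#' Reads the tooth schema (`site`, `specimen_id`, `tooth_position`,
#' `crown_height_mm`; external headers can be remapped via `col_map`),
#' optionally keeps only anterior teeth (positions A1-2 / a1-2, the positions
#' whose long narrow crowns make them a reliable body-size proxy), and drops
#' rows with non-numeric or out-of-range heights. Every dropped row is
#' accounted for in the returned filter report.
#'
#' @param path CSV file path.
#' @param anterior_only Keep only anterior tooth positions (default TRUE).
#' @param col_map Optional named character vector mapping the expected column
#'   names to the file's headers, e.g.
#'   `c(crown_height_mm = "CH_mm")`.
#' @return An object of class `tooth_measurement_set`: `site`, `records`
#'   (data frame of kept rows), and `provenance` (path plus a filter report
#'   satisfying `n_input = n_kept + dropped`).
#' @export
read_tooth_csv <- function(path, anterior_only = TRUE, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "specimen_id", "tooth_position", "crown_height_mm")
  if (!is.null(col_map)) {
    for (want in names(col_map)) {
      have <- col_map[[want]]
      if (!have %in% names(df)) stop("mapped column not in file: ", have)
      names(df)[names(df) == have] <- want
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  n_input <- nrow(df)

  heights <- suppressWarnings(as.numeric(df$crown_height_mm))
  bad_height <- !is.finite(heights) | heights <= 0 | heights >= 100
  n_bad_height <- sum(bad_height)
  bad_rows <- which(bad_height)
  df <- df[!bad_height, , drop = FALSE]
  df$crown_height_mm <- heights[!bad_height]

  n_nonanterior <- 0L
  if (anterior_only) {
    keep <- df$tooth_position %in% anterior_positions
    n_nonanterior <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  dup <- duplicated(df[, c("specimen_id", "tooth_position")])

  structure(
    list(site = if (nrow(df)) df$site[1] else NA_character_,
         records = df[, required],
         provenance = list(path = path,
                           n_input = n_input,
                           n_kept = nrow(df),
                           n_dropped_invalid_height = n_bad_height,
                           invalid_rows = bad_rows,
                           n_dropped_position = n_nonanterior,
                           n_duplicate_ids = sum(dup),
                           anterior_only = anterior_only)),
    class = "tooth_measurement_set"
  )
}

#' @export
print.tooth_measurement_set <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Tooth measurements from '%s' (%s)\n", x$site, p$path))
  cat(sprintf("  %d rows read, %d kept (%d invalid heights, %d non-anterior)\n",
              p$n_input, p$n_kept, p$n_dropped_invalid_height,
              p$n_dropped_position))
  invisible(x)
}

#' Convert a tooth-measurement set to a dental distribution
#'
#' @param x A [read_tooth_csv()] result.
#' @return A sample-backed [dental_distribution()].
#' @export
as_dental_distribution <- function(x) {
  stopifnot(inherits(x, "tooth_measurement_set"))
  dental_distribution(values = x$records$crown_height_mm,
                      site_label = as.character(x$site))
}

#' Write a simulated dental histogram to CSV
#'
#' One row per site and crown-height bin, with raw and normalised counts.
#'
#' @param sim A `sim_result` or [tooth_accumulator()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_histogram_csv <- function(sim, path) {
  acc <- if (inherits(sim, "sim_result")) sim$accumulator else sim
  norm <- normalized_counts(acc)
  nb <- ncol(acc$counts)
  df <- data.frame(
    site = rep(rownames(acc$counts), each = nb),
    bin_left_mm = rep(acc$edges_mm[-(nb + 1)], 2),
    bin_right_mm = rep(acc$edges_mm[-1], 2),
    count = c(t(acc$counts)),
    normalized = c(t(norm))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a shape report JSON
#'
#' The seven shape parameters plus mode diagnostics for one dental
#' distribution, with provenance fields.
#'
#' @param dist A [dental_distribution()].
#' @param path Output JSON path.
#' @param extra Named list of extra provenance fields (seed, config hash...).
#' @return The path, invisibly.
#' @export
write_shape_report <- function(dist, path, extra = list()) {
  sv <- compute_shape_vector(dist)
  modes <- estimate_modes(dist)
  report <- c(list(site_label = dist$site_label,
                   n = dist$n,
                   shape = as.list(unclass(sv)),
                   modes = list(locations = modes$locations,
                                prominences = modes$prominences)),
              extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an error surface (with 10% bands) to CSV
#'
#' @param surface An [compute_error_surface()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  bands <- error_contours(surface)
  g <- surface$grid
  df <- expand.grid(xi_a = g$xi_a_values, xi_j = g$xi_j_values)[, 2:1]
  df$eps_j <- c(t(surface$epsilon_j))
  df$eps_a <- c(t(surface$epsilon_a))
  df$band_j <- c(t(bands$band_j))
  df$band_a <- c(t(bands$band_a))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
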