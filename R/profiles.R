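#' Construct a unit-level dissolution profile
#'
#' A dissolution profile holds the cumulative release (%) of every individual
#' tablet unit of one product over a common sampling grid. The canonical
#' representation is a long tibble with columns `product`, `unit`, `time_min`
#' and `release_pct`; this constructor validates the invariants every
#' downstream operation relies on.
#'
#' @param data A data frame with columns `product`, `unit`, `time_min`,
#'   `release_pct` (one row per unit and time point).
#'
#' @details Invariants enforced:
#' * sampling times are positive and, within a unit, strictly increasing;
#' * release values lie in \[0, 120\] (values above 100 are tolerated up to
#'   120 to accommodate assay overshoot; negative values are rejected);
#' * at least one unit, and every unit observed at every time (no ragged
#'   grids).
#'
#' @return A tibble of class `dissolution_profile`, rows ordered by unit
#'   label then ascending time.
#' @export
#' @examples
#' prof <- dissolution_profile(data.frame(
#'   product = "REF", unit = rep(1:2, each = 3),
#'   time_min = rep(c(60, 240, 480), 2),
#'   release_pct = c(30, 60, 80, 32, 61, 79)
#' ))
#' profile_matrix(prof)
dissolution_profile <- function(data) {
  required <- c("product", "unit", "time_min", "release_pct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_format(paste0(
      "dissolution data must have columns product, unit, time_min, release_pct; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- tibble::as_tibble(data[required])
  if (nrow(data) == 0) {
    stop_not_found("no dissolution observations in the selection")
  }
  if (!is.numeric(data$time_min) || any(!is.finite(data$time_min)) ||
      any(data$time_min <= 0)) {
    stop_validation("time_min must be finite and strictly positive (minutes)")
  }
  if (!is.numeric(data$release_pct) || any(!is.finite(data$release_pct))) {
    stop_validation("release_pct must be finite numbers")
  }
  if (any(data$release_pct < 0) || any(data$release_pct > 120)) {
    stop_validation("release_pct must lie in [0, 120] (percent scale)")
  }
  if (length(unique(data$product)) > 1) {
    stop_validation("a dissolution_profile holds exactly one product")
  }

  times <- sort(unique(data$time_min))
  units <- sort(unique(data$unit))
  # complete rectangular grid: every unit at every time, no duplicates
  counts <- table(data$unit, data$time_min)
  if (any(counts != 1L)) {
    stop_validation("ragged unit/time grid: every unit needs exactly one value per time point")
  }

  out <- dplyr::arrange(data, .data$unit, .data$time_min)
  class(out) <- c("dissolution_profile", class(out))
  out
}

#' Read dissolution profiles from CSV
#'
#' Reads per-unit cumulative dissolution data. The canonical layout is long
#' (`product`, `unit`, `time_min`, `release_pct`); a wide layout (`product`,
#' `unit` plus one numeric-named column per sampling time) is detected
#' automatically and pivoted.
#'
#' @param path Path to a UTF-8 CSV file with a header row and `.` decimal
#'   separator.
#' @param product_id Optional product identifier to select when the file
#'   contains several products.
#' @return A [dissolution_profile()] tibble.
#' @export
read_profiles <- function(path, product_id = NULL) {
  if (!file.exists(path)) stop_not_found(paste0("file not found: ", path))
  # base read.csv parses doubles via strtod (correctly rounded), so a write/
  # read cycle reproduces every release value bit-exactly
  raw <- tibble::as_tibble(
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  )

  long_cols <- c("product", "unit", "time_min", "release_pct")
  if (!all(long_cols %in% names(raw))) {
    time_cols <- names(raw)[!is.na(suppressWarnings(as.numeric(names(raw))))]
    if (all(c("product", "unit") %in% names(raw)) && length(time_cols) > 0) {
      raw <- tidyr::pivot_longer(raw, dplyr::all_of(time_cols),
        names_to = "time_min", values_to = "release_pct",
        names_transform = as.numeric
      )
    } else {
      stop_format(paste0(
        "unrecognized dissolution CSV layout in ", path,
        ": expected long columns (product, unit, time_min, release_pct) ",
        "or wide columns (product, unit, <time>...)"
      ))
    }
  }

  if (!is.null(product_id)) {
    raw <- dplyr::filter(raw, .data$product == product_id)
    if (nrow(raw) == 0) {
      stop_not_found(paste0("product '", product_id, "' not present in ", path))
    }
  }
  dissolution_profile(raw)
}

#' Write dissolution profiles to CSV
#'
#' Writes the canonical long layout so that [read_profiles()] round-trips the
#' unit-by-time matrix exactly.
#'
#' @param profile A [dissolution_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profile, path) {
  profile <- dissolution_profile(profile)
  readr::write_csv(profile, path, progress = FALSE)
  invisible(path)
}

#' Unit-by-time release matrix
#'
#' @param profile A [dissolution_profile()].
#' @return A numeric matrix, one row per tablet unit (ordered by unit label),
#'   one column per sampling time (ascending); dimnames are unit labels and
#'   times in minutes.
#' @export
profile_matrix <- function(profile) {
  profile <- dissolution_profile(profile)
  wide <- tidyr::pivot_wider(profile,
    id_cols = "unit", names_from = "time_min",
    values_from = "release_pct", names_sort = TRUE
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$unit)
  m
}

#' Sampling times of a profile
#' @param profile A [dissolution_profile()].
#' @return Ascending numeric vector of sampling times (min).
#' @export
profile_times <- function(profile) {
  sort(unique(profile$time_min))
}

#' Per-time-point summary of a dissolution profile
#'
#' Computes, at each requested time point, the arithmetic mean and the
#' unbiased sample variance (divisor n - 1) of cumulative release across
#' tablet units. These are the per-time summary statistics that the
#' similarity factor and its variance-penalized expectation consume.
#'
#' @param profile A [dissolution_profile()].
#' @param times Times (min) to summarize at; default all sampling times.
#'   Every requested time must be present in the profile.
#' @return A tibble of class `profile_summary` with columns `time_min`,
#'   `mean_release`, `var_release`, `n` (units per product). The number of
#'   rows is the number of time points P used in the similarity-factor sums.
#'   With a single unit the variance is reported as 0 and a warning is
#'   raised.
#' @export
summarize_profile <- function(profile, times = NULL) {
  profile <- dissolution_profile(profile)
  all_times <- profile_times(profile)
  times <- times %||% all_times
  missing_t <- setdiff(times, all_times)
  if (length(missing_t) > 0) {
    stop_validation(paste0(
      "requested time(s) not in the sampling grid: ",
      paste(missing_t, collapse = ", ")
    ))
  }

  out <- profile |>
    dplyr::filter(.data$time_min %in% times) |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      mean_release = mean(.data$release_pct),
      var_release = if (dplyr::n() > 1) stats::var(.data$release_pct) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$time_min, times))

  if (anyNA(out$var_release)) {
    warn("single-unit profile: sample variances reported as 0")
    out$var_release[is.na(out$var_release)] <- 0
  }
  class(out) <- c("profile_summary", class(out))
  out
}

#' @export
print.dissolution_profile <- function(x, ...) {
  m <- profile_matrix(x)
  cat(sprintf(
    "<dissolution_profile> product %s: %d units x %d time points (%s min)\n",
    unique(x$product), nrow(m), ncol(m),
    paste(colnames(m), collapse = ", ")
  ))
  NextMethod()
}
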