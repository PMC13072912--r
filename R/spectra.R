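#' Read ED-XRF spectra from a long-format CSV file
#'
#' The interchange dialect is a plain long-format CSV with one row per energy
#' channel and the metadata columns repeated: `standard_id`, `pellet_id`,
#' `repeat_id`, `energy_keV`, `total_counts`, `background_counts`,
#' `live_time_s`. Each (standard, pellet, repeat) block must lie on a uniform
#' energy grid.
#'
#' @param path Path to the CSV file.
#' @return A spectra tibble (one row per channel per acquisition).
#' @seealso [write_spectra()], [subtract_background()]
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) xrf_abort(paste0("no such file: ", path), "io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_spectra(df)
}

#' Write spectra to the long-format CSV dialect
#'
#' @param spectra A spectra tibble as returned by [read_spectra()] or the
#'   simulator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  spectra <- validate_spectra(spectra)
  readr::write_csv(spectra[, spectra_cols()], path, progress = FALSE)
  invisible(path)
}

spectra_cols <- function() {
  c("standard_id", "pellet_id", "repeat_id", "energy_keV",
    "total_counts", "background_counts", "live_time_s")
}

#' Validate a spectra tibble
#'
#' Checks the column contract, non-negative counts, positive live time and a
#' uniform energy grid within each acquisition.
#'
#' @param spectra A spectra tibble.
#' @param step_tol Tolerance (keV) on energy-step uniformity.
#' @return The validated tibble, ordered by (standard, pellet, repeat, energy).
#' @export
validate_spectra <- function(spectra, step_tol = 1e-9) {
  missing <- setdiff(spectra_cols(), names(spectra))
  if (length(missing)) {
    xrf_abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
              "format_error")
  }
  if (any(spectra$total_counts < 0) || any(spectra$background_counts < 0)) {
    xrf_abort("counts must be non-negative", "validation_error")
  }
  if (any(spectra$live_time_s <= 0)) {
    xrf_abort("live_time_s must be positive", "validation_error")
  }
  spectra <- spectra %>%
    arrange(.data$standard_id, .data$pellet_id, .data$repeat_id, .data$energy_keV)
  # each acquisition must sit on one uniform grid
  split_keys <- interaction(spectra$standard_id, spectra$pellet_id,
                            spectra$repeat_id, drop = TRUE)
  for (e in split(spectra$energy_keV, split_keys)) infer_grid(e, step_tol)
  as_tibble(spectra)
}

#' Subtract the instrument background estimate channelwise
#'
#' Adds a `net_counts` column, `total_counts - background_counts` per channel.
#' Net values may be negative by design: clamping at zero would bias the
#' low-signal channels the calibration model has to learn from. Both original
#' count columns are retained for audit.
#'
#' @param spectra A spectra tibble.
#' @return The tibble with a `net_counts` column.
#' @examples
#' s <- tibble::tibble(
#'   standard_id = "a", pellet_id = 1L, repeat_id = 1L,
#'   energy_keV = c(10.35, 10.36), total_counts = c(100, 50),
#'   background_counts = c(40, 50), live_time_s = 120
#' )
#' subtract_background(s)$net_counts # 60 0
#' @export
subtract_background <- function(spectra) {
  if (!all(c("total_counts", "background_counts") %in% names(spectra))) {
    xrf_abort("total_counts and background_counts are required", "validation_error")
  }
  mutate(spectra, net_counts = .data$total_counts - .data$background_counts)
}

#' Extract the spectral-window feature vector of a single acquisition
#'
#' Concatenates, window by window, the net counts at every grid channel whose
#' centre energy falls in the closed window interval. The feature length
#' depends only on the grid and the windows, never on the counts.
#'
#' @param spectrum A spectra tibble holding exactly one acquisition.
#' @param region A [region_spec()].
#' @return A named numeric vector of net counts (names give channel energies).
#' @export
extract_features <- function(spectrum, region) {
  key <- unique(spectrum[, c("standard_id", "pellet_id", "repeat_id")])
  if (nrow(key) != 1) {
    xrf_abort("`spectrum` must hold exactly one acquisition", "validation_error")
  }
  if (!"net_counts" %in% names(spectrum)) {
    spectrum <- subtract_background(spectrum)
  }
  spectrum <- arrange(spectrum, .data$energy_keV)
  feats <- unlist(lapply(region$windows, function(w) {
    sel <- spectrum$energy_keV >= w[1] - 1e-9 & spectrum$energy_keV <= w[2] + 1e-9
    if (!any(sel)) {
      xrf_abort(sprintf("window [%g, %g] keV contains no grid channel", w[1], w[2]),
                "empty_window_error")
    }
    set_names(spectrum$net_counts[sel], feature_names(spectrum$energy_keV[sel]))
  }))
  feats
}

feature_names <- function(energies) sprintf("ch_%08.4f", energies)

#' Assemble the model-ready feature table from spectra and standards
#'
#' Background-subtracts every acquisition, extracts the windowed feature
#' vector, and joins the known concentrations. One row per spectrum -- the
#' nine replicate spectra of a standard are deliberately left unaveraged so
#' the model trains on within-standard variability. Row order is
#' deterministic: (standard, pellet, repeat).
#'
#' @param spectra A spectra tibble (any number of acquisitions, one shared grid).
#' @param standards A standards tibble with columns `standard_id`, `as_ug_kg`,
#'   `pb_ug_kg` (and optionally `role`).
#' @param region A [region_spec()].
#' @return A feature table: tibble with metadata columns `standard_id`,
#'   `pellet_id`, `repeat_id`, targets `as_ug_kg`, `pb_ug_kg`, and one `ch_*`
#'   column per selected channel.
#' @export
assemble_dataset <- function(spectra, standards, region = region_spec()) {
  spectra <- subtract_background(spectra)
  grids <- unique(spectra$energy_keV)
  split_keys <- interaction(spectra$standard_id, spectra$pellet_id,
                            spectra$repeat_id, drop = TRUE)
  n_per <- table(split_keys)
  if (length(unique(as.integer(n_per))) > 1) {
    xrf_abort("acquisitions do not share one energy grid", "grid_error")
  }
  first <- spectra %>%
    filter(split_keys == levels(split_keys)[1])
  ref_energy <- sort(first$energy_keV)
  mask <- region_mask(ref_energy, region)
  if (!any(mask)) xrf_abort("no window overlaps the grid", "empty_window_error")
  for (w in region$windows) {
    if (!any(ref_energy >= w[1] - 1e-9 & ref_energy <= w[2] + 1e-9)) {
      xrf_abort(sprintf("window [%g, %g] keV contains no grid channel", w[1], w[2]),
                "empty_window_error")
    }
  }

  wide <- spectra %>%
    arrange(.data$standard_id, .data$pellet_id, .data$repeat_id, .data$energy_keV) %>%
    group_by(.data$standard_id, .data$pellet_id, .data$repeat_id) %>%
    summarise(
      feats = list({
        e <- .data$energy_keV
        if (length(e) != length(ref_energy) || max(abs(e - ref_energy)) > 1e-9) {
          xrf_abort("acquisitions do not share one energy grid", "grid_error")
        }
        set_names(.data$net_counts[mask], feature_names(e[mask]))
      }),
      .groups = "drop"
    )
  feats <- do.call(rbind, wide$feats)
  out <- bind_rows(as_tibble(feats))
  meta <- wide %>% select("standard_id", "pellet_id", "repeat_id")
  targ <- standards %>% select("standard_id", "as_ug_kg", "pb_ug_kg")
  res <- meta %>%
    left_join(targ, by = "standard_id") %>%
    dplyr::bind_cols(out)
  if (anyNA(res$as_ug_kg) || anyNA(res$pb_ug_kg)) {
    xrf_abort("some spectra have no matching standard", "validation_error")
  }
  attr(res, "region") <- region
  res
}

# numeric feature matrix of a feature table
feature_matrix <- function(ft) {
  as.matrix(ft[, grepl("^ch_", names(ft)), drop = FALSE])
}

# target matrix (As, Pb) of a feature table
target_matrix <- function(ft) {
  cbind(As = ft$as_ug_kg, Pb = ft$pb_ug_kg)
}

#' Replicate mean and spread
#'
#' Arithmetic mean and sample standard deviation (divisor n - 1) of replicate
#' values; the spread of a single observation is reported as 0.
#'
#' @param values Numeric vector with at least one value.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @examples
#' summarize_replicates(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 10)) # mean 1, sd 3.1623
#' @export
summarize_replicates <- function(values) {
  if (length(values) < 1) xrf_abort("at least one value is required", "validation_error")
  c(mean = mean(values), sd = if (length(values) == 1L) 0 else sd(values))
}

#' Read / write the standards table
#'
#' Columns: `standard_id`, `as_ug_kg`, `pb_ug_kg`, `role`
#' (`train`, `test`, `scenario1`, `scenario2` or `validation`).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_standards <- function(path) {
  if (!file.exists(path)) xrf_abort(paste0("no such file: ", path), "io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("standard_id", "as_ug_kg", "pb_ug_kg"), names(df))
  if (length(missing)) {
    xrf_abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
              "format_error")
  }
  if (any(df$as_ug_kg < 0) || any(df$pb_ug_kg < 0)) {
    xrf_abort("concentrations must be non-negative", "validation_error")
  }
  df
}

#' @rdname read_standards
#' @param standards A standards tibble.
#' @export
write_standards <- function(standards, path) {
  readr::write_csv(standards, path, progress = FALSE)
  invisible(path)
}

#' Overlay plot of (averaged) spectra
#'
#' Plots the background-subtracted, replicate-averaged spectrum of each
#' standard, the usual way calibration sets are inspected around the
#' As K-alpha / Pb L-alpha overlap.
#'
#' @param spectra A spectra tibble.
#' @param region Optional [region_spec()] whose windows are shaded.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, region = NULL) {
  avg <- subtract_background(spectra) %>%
    group_by(.data$standard_id, .data$energy_keV) %>%
    summarise(net = mean(.data$net_counts), .groups = "drop")
  p <- ggplot2::ggplot(avg, ggplot2::aes(.data$energy_keV, .data$net,
                                         colour = .data$standard_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Energy (keV)", y = "Net counts (replicate mean)",
                  colour = "Standard") +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    shade <- do.call(rbind, lapply(region$windows, function(w) {
      data.frame(xmin = w[1], xmax = w[2])
    }))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.08
    )
  }
  p
}
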