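#' Energy grid of an ED-XRF acquisition
#'
#' A uniform grid of channel-centre energies. Channel `i` (1-based) maps to
#' `start_keV + (i - 1) * step_keV`.
#'
#' @param start_keV Energy of the first channel centre (keV).
#' @param step_keV Channel width (keV); must be positive.
#' @param n_channels Number of channels; at least 1.
#'
#' @return An object of class `energy_grid`: a list with fields `start_keV`,
#'   `step_keV` and `n_channels`.
#' @examples
#' g <- energy_grid(10, 0.01, 321)
#' head(grid_energies(g))
#' @export
energy_grid <- function(start_keV, step_keV, n_channels) {
  if (!is.numeric(step_keV) || step_keV <= 0) {
    xrf_abort("`step_keV` must be > 0", "grid_error")
  }
  if (n_channels < 1) xrf_abort("`n_channels` must be >= 1", "grid_error")
  structure(
    list(start_keV = start_keV, step_keV = step_keV,
         n_channels = as.integer(n_channels)),
    class = "energy_grid"
  )
}

#' Channel-centre energies of a grid
#'
#' @param grid An [energy_grid()].
#' @return Numeric vector of channel-centre energies (keV), strictly increasing.
#' @export
grid_energies <- function(grid) {
  stopifnot(inherits(grid, "energy_grid"))
  grid$start_keV + (seq_len(grid$n_channels) - 1) * grid$step_keV
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> %.4f-%.4f keV, step %.4g keV, %d channels\n",
              x$start_keV, x$start_keV + (x$n_channels - 1) * x$step_keV,
              x$step_keV, x$n_channels))
  invisible(x)
}

# infer a uniform grid from an energy column; tolerance on step uniformity
infer_grid <- function(energy, tol = 1e-9) {
  energy <- as.numeric(energy)
  if (length(energy) == 1L) return(energy_grid(energy, 1, 1L))
  steps <- diff(energy)
  if (any(steps <= 0) || (max(steps) - min(steps)) > tol) {
    xrf_abort("energy channels are not a uniform increasing grid", "grid_error")
  }
  energy_grid(energy[1], mean(steps), length(energy))
}

#' Spectral windows used as model inputs
#'
#' A set of closed energy intervals `[lo_keV, hi_keV]`; a grid channel belongs
#' to a window when its centre energy lies inside the closed interval. The
#' default windows cover the As K-alpha / Pb L-alpha overlap region and the
#' Pb L-beta region.
#'
#' @param windows A list of length-2 numeric vectors `c(lo_keV, hi_keV)`.
#' @return An object of class `region_spec`.
#' @examples
#' region_spec() # the default calibration windows
#' @export
region_spec <- function(windows = list(c(10.35, 10.70), c(12.40, 12.85))) {
  windows <- lapply(windows, as.numeric)
  for (w in windows) {
    if (length(w) != 2 || !(w[1] < w[2])) {
      xrf_abort("each window must be c(lo, hi) with lo < hi", "validation_error")
    }
  }
  o <- order(vapply(windows, `[`, numeric(1), 1))
  windows <- windows[o]
  if (length(windows) > 1) {
    lo <- vapply(windows, `[`, numeric(1), 1)
    hi <- vapply(windows, `[`, numeric(1), 2)
    if (any(lo[-1] <= hi[-length(hi)])) {
      xrf_abort("windows must be non-overlapping", "validation_error")
    }
  }
  structure(list(windows = windows), class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec>",
      paste(vapply(x$windows, function(w) sprintf("[%.4g, %.4g]", w[1], w[2]),
                   character(1)), collapse = " "), "keV\n")
  invisible(x)
}

# logical mask of grid channels falling in any window (closed intervals,
# small tolerance absorbs floating-point error in channel energies)
region_mask <- function(energies, region, tol = 1e-9) {
  stopifnot(inherits(region, "region_spec"))
  Reduce(`|`, lapply(region$windows, function(w) {
    energies >= w[1] - tol & energies <= w[2] + tol
  }))
}
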