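#' Regular pressure-measurement grid
#'
#' A regular 3-D grid of hydrophone positions (study layout 17 x 6 x 3 =
#' 306 points) carrying either synchronous pressure time series or
#' pre-computed RMS pressures per point.
#'
#' @param shape Integer grid counts `c(nx, ny, nz)`.
#' @param spacing Grid spacing per axis in metres, `c(dx, dy, dz)`.
#' @param series Optional matrix, points x samples, of pressure time series
#'   (Pa); point order is x-fastest then y then z (column-major over the
#'   grid).
#' @param rms Optional numeric vector of per-point RMS pressures (Pa);
#'   derived from `series` when omitted.
#' @param sample_rate Sampling rate of `series` (Hz).
#' @param rho Water density (kg/m^3, default 1000).
#' @return Object of class `pressure_grid`.
#' @export
pressure_grid <- function(shape, spacing, series = NULL, rms = NULL,
                          sample_rate = NULL, rho = 1000) {
  shape <- as.integer(shape); npt <- prod(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive counts", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  if (!is.null(series)) {
    series <- as.matrix(series)
    if (nrow(series) != npt) stop("series rows must match prod(shape)", call. = FALSE)
    if (is.null(rms)) rms <- sqrt(rowMeans(series^2))
  }
  if (is.null(rms)) stop("need series or rms values", call. = FALSE)
  if (length(rms) != npt) stop("rms length must match prod(shape)", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing), series = series,
                 rms = as.numeric(rms), sample_rate = sample_rate, rho = rho),
            class = "pressure_grid")
}

# internal: linear index of grid point (i, j, k), x-fastest
grid_index <- function(i, j, k, shape) {
  i + (j - 1L) * shape[1] + (k - 1L) * shape[1] * shape[2]
}

#' Per-point signal-to-noise ratio map
#'
#' `20 * log10(P_signal / P_noise)` per grid point, with RMS pressures
#' taken over an optional frequency band (requires time series and a
#' sample rate). Points with zero noise pressure are undefined (`NA`).
#'
#' @param signal_grid,noise_grid [pressure_grid()]s of identical shape.
#' @param band Optional `c(f_lo, f_hi)` (Hz), e.g. [third_octave_band()].
#' @return 3-D array (nx, ny, nz) of SNR in dB; `NA` where undefined.
#' @export
snr_map <- function(signal_grid, noise_grid, band = NULL) {
  stopifnot(inherits(signal_grid, "pressure_grid"),
            inherits(noise_grid, "pressure_grid"))
  if (!identical(signal_grid$shape, noise_grid$shape))
    stop("grid shapes differ", call. = FALSE)
  point_rms <- function(g) {
    if (is.null(band)) return(g$rms)
    if (is.null(g$series) || is.null(g$sample_rate))
      stop("banded SNR needs time series and a sample rate", call. = FALSE)
    apply(g$series, 1, function(x) sqrt(mean(band_filter(x, g$sample_rate, band)^2)))
  }
  ps <- point_rms(signal_grid); pn <- point_rms(noise_grid)
  snr <- ifelse(pn > 0, 20 * log10(ps / pn), NA_real_)
  array(snr, dim = signal_grid$shape)
}

#' Finite-difference particle acceleration map
#'
#' Particle acceleration from the pressure gradient, `a = -grad(P) / rho`.
#' Pressure differences between adjacent grid points are formed per axis,
#' their RMS over time divided by the grid spacing and the water density,
#' and the per-axis RMS accelerations combined as a root sum of squares
#' into the total. Forward differences are attributed to the staggered
#' interior grid, so the total map has shape `(nx-1, ny-1, nz-1)`. An axis
#' with fewer than 2 points has an undefined (NA) component.
#'
#' @param grid A [pressure_grid()] carrying time series.
#' @param db_ref Reference acceleration for the dB map (m/s^2; default
#'   `1e-6` = 1 um/s^2; use `1e-3` for dB re 1 mm/s^2).
#' @return A list of class `accel_map`: `ax`, `ay`, `az` (RMS acceleration
#'   arrays on the staggered grid, m/s^2), `total`, and `db`
#'   (`20*log10(total/db_ref)`, `-Inf` where the field is uniform).
#' @export
particle_acceleration <- function(grid, db_ref = 1e-6) {
  stopifnot(inherits(grid, "pressure_grid"))
  if (is.null(grid$series))
    stop("particle acceleration needs pressure time series", call. = FALSE)
  sh <- grid$shape; sp <- grid$spacing; rho <- grid$rho
  comp <- function(axis) {
    if (sh[axis] < 2L) return(NULL)
    dims <- sh; dims[axis] <- sh[axis] - 1L
    a <- array(NA_real_, dims)
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
      idx <- c(i, j, k); nxt <- idx; nxt[axis] <- nxt[axis] + 1L
      p0 <- grid$series[grid_index(idx[1], idx[2], idx[3], sh), ]
      p1 <- grid$series[grid_index(nxt[1], nxt[2], nxt[3], sh), ]
      a[i, j, k] <- sqrt(mean((p1 - p0)^2)) / (sp[axis] * rho)
    }
    a
  }
  ax <- comp(1); ay <- comp(2); az <- comp(3)
  tot_dim <- pmax(ifelse(sh >= 2L, sh - 1L, 1L), 1L)
  total <- array(0, tot_dim)
  trunc3 <- function(a, dims) a[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
  for (cmp in list(ax, ay, az)) {
    if (is.null(cmp)) next
    total <- total + trunc3(cmp, tot_dim)^2
  }
  total <- sqrt(total)
  db <- ifelse(total > 0, 20 * log10(total / db_ref), -Inf)
  structure(list(ax = ax, ay = ay, az = az, total = total,
                 db = array(db, dim = tot_dim),
                 spacing = sp, rho = rho, db_ref = db_ref),
            class = "accel_map")
}

#' Write / read a pressure grid's RMS values as CSV + YAML header
#'
#' CSV columns: `x_idx, y_idx, z_idx, x_m, y_m, z_m, value` (RMS pressure,
#' Pa). Spacing, density and an optional band annotation go to
#' `<path>.yaml`. Time series are not serialised.
#'
#' @param grid A [pressure_grid()].
#' @param path Output CSV path.
#' @param band Optional band annotation for the header.
#' @return `write_grid_csv()` returns `path` invisibly; `read_grid_csv()` a
#'   [pressure_grid()] with `rms` values only.
#' @export
write_grid_csv <- function(grid, path, band = NULL) {
  stopifnot(inherits(grid, "pressure_grid"))
  sh <- grid$shape
  idx <- expand.grid(x_idx = seq_len(sh[1]), y_idx = seq_len(sh[2]),
                     z_idx = seq_len(sh[3]))
  df <- data.frame(idx,
                   x_m = (idx$x_idx - 1) * grid$spacing[1],
                   y_m = (idx$y_idx - 1) * grid$spacing[2],
                   z_m = (idx$z_idx - 1) * grid$spacing[3],
                   value = grid$rms)
  write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(shape = as.integer(sh), spacing = grid$spacing,
                        rho = grid$rho, band = band),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  sh <- as.integer(meta$shape)
  df <- df[order(df$z_idx, df$y_idx, df$x_idx), ]
  pressure_grid(sh, as.numeric(meta$spacing), rms = df$value, rho = meta$rho)
}
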