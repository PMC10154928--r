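#' Gridded wake velocity-plane time series
#'
#' Container for time-resolved velocity fields measured (or simulated) on a
#' y-z plane perpendicular to the free stream, as produced by tomographic
#' particle image velocimetry behind a flying animal. `u` holds the
#' streamwise *perturbation* relative to the free-stream field, `v` and `w`
#' the in-plane (horizontal and vertical) components.
#'
#' @param y,z Monotone, uniformly spaced grid coordinates in m. For a
#'   half-wake series `y[1]` is the body centre plane.
#' @param t Strictly increasing frame timestamps in s.
#' @param u,v,w Numeric arrays of dimension `c(length(y), length(z),
#'   length(t))` in m s^-1.
#' @param freestream Free-stream speed field \eqn{U_\infty(y,z)}, a
#'   `length(y)` by `length(z)` matrix (a scalar is recycled), strictly
#'   positive.
#' @param wingbeat_freq Wingbeat frequency of the animal in Hz, used to
#'   segment frames into wingbeats.
#' @param half_wake Logical; `TRUE` when only one half of the (assumed
#'   symmetric) wake was measured. Half wakes are mirrored about the centre
#'   plane before power estimation and their vertical force is doubled.
#' @return An object of class `wake_series`.
#' @examples
#' ws <- simulate_vortex_wake(seed = 1)
#' ws
#' @export
wake_series <- function(y, z, t, u, v, w, freestream,
                        wingbeat_freq, half_wake = FALSE) {
  ny <- length(y); nz <- length(z); nt <- length(t)
  if (ny < 3 || nz < 3) stop_invalid("grid must be at least 3 x 3.")
  if (any(diff(t) <= 0)) stop_invalid("timestamps must be strictly increasing.")
  check_uniform_grid(y, "y"); check_uniform_grid(z, "z")
  dims <- c(ny, nz, nt)
  for (nm in c("u", "v", "w")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dims))) {
      stop_data("`%s` must be an array of dimension %s.", nm,
                paste(dims, collapse = " x "))
    }
  }
  if (length(freestream) == 1) freestream <- matrix(freestream, ny, nz)
  if (!identical(dim(freestream), as.integer(c(ny, nz)))) {
    stop_data("`freestream` must be a %d x %d matrix or a scalar.", ny, nz)
  }
  if (any(freestream <= 0)) stop_invalid("freestream must be positive everywhere.")
  check_positive(wingbeat_freq, "wingbeat_freq")
  structure(
    list(y = y, z = z, t = t, u = u, v = v, w = w, freestream = freestream,
         wingbeat_freq = wingbeat_freq, half_wake = isTRUE(half_wake)),
    class = "wake_series"
  )
}

check_uniform_grid <- function(x, name) {
  d <- diff(x)
  if (any(d <= 0)) stop_invalid("`%s` must be strictly increasing.", name)
  if (diff(range(d)) > 1e-8 * mean(d)) {
    stop_invalid("`%s` grid spacing must be uniform.", name)
  }
  invisible(x)
}

#' @export
print.wake_series <- function(x, ...) {
  cat(sprintf(
    "<wake_series> %d x %d grid, %d frames (%.3g s), U_inf ~ %.3g m/s, f = %.3g Hz%s\n",
    length(x$y), length(x$z), length(x$t), diff(range(x$t)),
    mean(x$freestream), x$wingbeat_freq,
    if (x$half_wake) ", half wake" else ""))
  invisible(x)
}

grid_spacing <- function(ws) c(dy = ws$y[2] - ws$y[1], dz = ws$z[2] - ws$z[1])

#' Mirror a half wake about the body centre plane
#'
#' Builds the full symmetric wake from a half-wake series measured for
#' `y >= y[1]` by reflecting about `y[1]`: `u`, `w` and the free stream are
#' even under the reflection, `v` (the y-component) is odd, so streamwise
#' vorticity is odd, as expected of a counter-rotating vortex pair.
#'
#' @param ws A half-wake [wake_series()].
#' @return A full-grid `wake_series` with `half_wake = FALSE`.
#' @examples
#' half <- simulate_vortex_wake(half_wake = TRUE, seed = 1)
#' full <- mirror_wake(half)
#' @export
mirror_wake <- function(ws) {
  stopifnot(inherits(ws, "wake_series"))
  if (!ws$half_wake) {
    warn("mirroring a series not marked half_wake")
  }
  ny <- length(ws$y)
  y_full <- c(2 * ws$y[1] - rev(ws$y[-1]), ws$y)
  refl <- function(a, sign) {
    out <- array(0, c(2 * ny - 1, length(ws$z), length(ws$t)))
    out[ny:(2 * ny - 1), , ] <- a
    out[1:(ny - 1), , ] <- sign * a[ny:2, , , drop = FALSE]
    out
  }
  fs <- rbind(ws$freestream[ny:2, , drop = FALSE], ws$freestream)
  wake_series(y_full, ws$z, ws$t,
              u = refl(ws$u, 1), v = refl(ws$v, -1), w = refl(ws$w, 1),
              freestream = fs, wingbeat_freq = ws$wingbeat_freq,
              half_wake = FALSE)
}

#' Convert a wake series to and from a long tibble
#'
#' Long-format interchange (one row per grid point per frame) used for
#' plain-text storage of wake planes.
#'
#' @param x A `wake_series`.
#' @param ... Unused.
#' @return `as_tibble()`: a tibble with columns `t`, `y`, `z`, `u`, `v`,
#'   `w`, `freestream`, `wingbeat_freq`, `half_wake`.
#' @examples
#' df <- tibble::as_tibble(simulate_vortex_wake(n_wingbeats = 1, seed = 1))
#' ws <- wake_series_from_tibble(df)
#' @export
as_tibble.wake_series <- function(x, ...) {
  ny <- length(x$y); nz <- length(x$z); nt <- length(x$t)
  tibble(
    t = rep(x$t, each = ny * nz),
    y = rep(rep(x$y, times = nz), times = nt),
    z = rep(rep(x$z, each = ny), times = nt),
    u = as.vector(x$u), v = as.vector(x$v), w = as.vector(x$w),
    freestream = rep(as.vector(x$freestream), times = nt),
    wingbeat_freq = x$wingbeat_freq,
    half_wake = x$half_wake
  )
}

#' @rdname as_tibble.wake_series
#' @param df A tibble in the layout produced by `as_tibble()`.
#' @export
wake_series_from_tibble <- function(df) {
  check_columns(df, c("t", "y", "z", "u", "v", "w", "freestream",
                      "wingbeat_freq", "half_wake"), "wake tibble")
  y <- sort(unique(df$y)); z <- sort(unique(df$z)); t <- sort(unique(df$t))
  ny <- length(y); nz <- length(z); nt <- length(t)
  df <- arrange(df, .data$t, .data$z, .data$y)
  shape <- function(col) array(df[[col]], c(ny, nz, nt))
  wake_series(y, z, t, shape("u"), shape("v"), shape("w"),
              freestream = matrix(df$freestream[seq_len(ny * nz)], ny, nz),
              wingbeat_freq = df$wingbeat_freq[1],
              half_wake = df$half_wake[1])
}

#' Read or write a wake series as CSV
#'
#' @param ws A `wake_series`.
#' @param path File path.
#' @return `read_wake_csv()` returns a `wake_series`; `write_wake_csv()`
#'   returns `path` invisibly.
#' @export
write_wake_csv <- function(ws, path) {
  readr::write_csv(as_tibble(ws), path)
  invisible(path)
}

#' @rdname write_wake_csv
#' @export
read_wake_csv <- function(path) {
  wake_series_from_tibble(readr::read_csv(path, show_col_types = FALSE))
}
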