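#' PIV velocity field from a frame pair
#'
#' Windowed cross-correlation between two frames, converted to a
#' velocity in um/h. Defaults: 48 px interrogation windows with 50%
#' overlap and Gaussian 3-point subpixel peak interpolation.
#'
#' @param frame_a,frame_b image matrices (same shape)
#' @param dt_min frame interval, minutes
#' @param window interrogation window, px
#' @param overlap overlap fraction
#' @param pixel_size um per pixel
#' @return object of class `velocity_field`: `x`, `y` (um), `vx`, `vy`
#'   (um/h), `mask`
#' @export
piv_velocity <- function(frame_a, frame_b, dt_min, window = 48L,
                         overlap = 0.5, pixel_size = 1) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frame dimensions differ", call. = FALSE)
  if (dt_min <= 0) stop("dt must be positive", call. = FALSE)
  wd <- window_displacements(frame_a, frame_b, window, overlap)
  f <- pixel_size * 60 / dt_min       # px/frame -> um/h
  structure(list(x = wd$x * pixel_size, y = wd$y * pixel_size,
                 vx = wd$dx * f, vy = wd$dy * f, mask = wd$mask,
                 grid_spacing = wd$step * pixel_size),
            class = "velocity_field")
}

#' Mean migration speed of a velocity field
#'
#' Spatial mean of the speed `|v|` over unmasked grid cells.
#'
#' @param field a [piv_velocity()] field
#' @return scalar mean speed, um/h
#' @export
mean_speed <- function(field) {
  sp <- sqrt(field$vx^2 + field$vy^2)
  ok <- field$mask & is.finite(sp)
  if (!any(ok)) stop("all velocity cells are masked", call. = FALSE)
  mean(sp[ok])
}

#' Kymograph of a scalar map time series
#'
#' Each frame is collapsed along the y axis (column-wise mean over valid
#' pixels); the one-dimensional profiles are stacked so that row `k` of
#' the result is frame `k`.
#'
#' @param stack list of image matrices (or 3D array y-x-frame); NA pixels
#'   are ignored in the average
#' @param pixel_size um per pixel (x calibration)
#' @param dt_min minutes between frames (time calibration)
#' @return object of class `kymograph`: `matrix` (rows = time), `x_um`,
#'   `t_min`
#' @export
kymograph <- function(stack, pixel_size = 1, dt_min = 1) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  if (!length(stack)) stop("empty stack", call. = FALSE)
  rows <- t(vapply(stack, function(fr) colMeans(fr, na.rm = TRUE),
                   numeric(ncol(stack[[1L]]))))
  structure(list(matrix = rows,
                 x_um = (seq_len(ncol(rows)) - 1) * pixel_size,
                 t_min = (seq_len(nrow(rows)) - 1) * dt_min),
            class = "kymograph")
}

#' Pearson correlation between adjacent frames
#'
#' For every adjacent pair of maps, the Pearson correlation over all
#' grid cells; vector maps (lists with two components) have their
#' components concatenated. A pair where either map has zero variance
#' yields `NA` with a flag.
#'
#' @param maps list of matrices, or list of 2-component lists for vector
#'   maps
#' @return data.frame with `frame` (index of the later frame), `r`, and
#'   `degenerate` (zero-variance flag)
#' @export
pearson_adjacent <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 maps", call. = FALSE)
  flat <- lapply(maps, function(mp) {
    if (is.list(mp)) c(as.numeric(mp[[1L]]), as.numeric(mp[[2L]]))
    else as.numeric(mp)
  })
  out <- data.frame(frame = seq_len(length(maps) - 1L) + 1L,
                    r = NA_real_, degenerate = FALSE)
  for (k in seq_len(length(maps) - 1L)) {
    a <- flat[[k]]; b <- flat[[k + 1L]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      out$degenerate[k] <- TRUE
    } else {
      out$r[k] <- stats::cor(a, b)
    }
  }
  out
}

#' Mean traction component versus window size
#'
#' For each requested square window side (um, centred on the field), the
#' absolute value of the mean `Tx` and mean `Ty` inside the window. Over
#' a randomly oriented traction field the component means shrink with
#' window size; a persistent offset reveals an orientation bias.
#'
#' @param traction a [fttc_traction()] field
#' @param sizes window sides, um
#' @return data.frame with `size`, `abs_mean_Tx`, `abs_mean_Ty`
#' @export
component_mean_vs_fieldsize <- function(traction, sizes) {
  ny <- nrow(traction$Tx); nx <- ncol(traction$Tx)
  d <- traction$grid_spacing
  if (any(sizes > min(nx, ny) * d))
    stop("window size exceeds field extent", call. = FALSE)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  res <- lapply(sizes, function(s) {
    half <- s / (2 * d)
    iy <- max(1L, ceiling(cy - half)):min(ny, floor(cy + half))
    ix <- max(1L, ceiling(cx - half)):min(nx, floor(cx + half))
    data.frame(size = s,
               abs_mean_Tx = abs(mean(traction$Tx[iy, ix])),
               abs_mean_Ty = abs(mean(traction$Ty[iy, ix])))
  })
  do.call(rbind, res)
}

#' Linear density-to-thickness calibration
#'
#' Least-squares line mapping cell density (cells/mm^2) to monolayer
#' thickness (um), as used to convert density maps from nuclei counting
#' into thickness maps.
#'
#' @param density cells/mm^2
#' @param thickness um
#' @return object of class `thickness_calibration`: `slope`,
#'   `intercept`, `fit` (the `lm`), and `predict(density)` via
#'   [predict.thickness_calibration()]
#' @export
fit_thickness_calibration <- function(density, thickness) {
  if (length(density) != length(thickness)) stop("length mismatch", call. = FALSE)
  if (length(unique(density)) < 2L)
    stop("degenerate fit: need at least 2 distinct densities", call. = FALSE)
  fit <- stats::lm(thickness ~ density)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 fit = fit),
            class = "thickness_calibration")
}

#' @param object a `thickness_calibration`
#' @param newdata density values, cells/mm^2
#' @param ... unused
#' @rdname fit_thickness_calibration
#' @export
predict.thickness_calibration <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' Cell density map from a nuclei image
#'
#' Counts local intensity maxima (nucleus centres) above a prominence
#' threshold in sliding square windows and converts counts to
#' cells/mm^2. A maximum is a pixel that strictly dominates its 8
#' neighbours and exceeds the image floor by `prominence` times the
#' dynamic range.
#'
#' @param image nuclei image matrix
#' @param window window side, um (>= 10)
#' @param pixel_size um per pixel
#' @param prominence fraction of the dynamic range a peak must rise
#'   above the image floor
#' @return object of class `density_map`: `density` (cells/mm^2 matrix),
#'   `peaks` (n x 2 pixel coordinates), `window_um`
#' @export
density_map <- function(image, window, pixel_size = 1, prominence = 0.1) {
  if (window < 10) stop("window must be >= 10 um", call. = FALSE)
  ny <- nrow(image); nx <- ncol(image)
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("empty image: zero density everywhere")
    return(structure(list(density = matrix(0, 1L, 1L),
                          peaks = matrix(numeric(0), 0L, 2L),
                          window_um = window),
                     class = "density_map"))
  }
  thr <- rng[1L] + prominence * diff(rng)
  inner <- image[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (inner >= image[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  pk <- which(is_max, arr.ind = TRUE)
  peaks <- cbind(y = pk[, 1] + 1L, x = pk[, 2] + 1L)
  wpx <- max(2L, round(window / pixel_size))
  step <- max(1L, floor(wpx / 2))
  ys <- seq(1L, max(1L, ny - wpx + 1L), by = step)
  xs <- seq(1L, max(1L, nx - wpx + 1L), by = step)
  dens <- matrix(0, length(ys), length(xs))
  area_mm2 <- (wpx * pixel_size / 1000)^2
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    cnt <- sum(peaks[, 1] >= ys[i] & peaks[, 1] < ys[i] + wpx &
               peaks[, 2] >= xs[j] & peaks[, 2] < xs[j] + wpx)
    dens[i, j] <- cnt / area_mm2
  }
  structure(list(density = dens, peaks = peaks, window_um = window),
            class = "density_map")
}
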