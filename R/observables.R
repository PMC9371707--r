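#' Radial velocity statistics of a trajectory
#'
#' Computes, per pair of consecutive snapshots, the area-weighted mean
#' inward radial velocity (um/h; positive = toward the disc centre) and
#' the outward-moving area fraction, from finite differences of the
#' Cartesian displacement snapshots.
#'
#' @param traj a [simulate_monolayer()] / [quiescence_run()] trajectory
#' @return object of class `radial_velocity_series`: data.frame with
#'   `time` (nondimensional midpoint), `time_h` (hours),
#'   `mean_radial_velocity` (um/h, inward positive) and `outward_fraction`
#' @export
radial_velocity_series <- function(traj) {
  nf <- length(traj$times)
  if (nf < 2L) stop("need at least 2 snapshots", call. = FALSE)
  nodes <- traj$mesh$nodes
  r <- sqrt(rowSums(nodes^2))
  rhat <- nodes / pmax(r, 1e-12)
  rhat[r < 1e-12, ] <- 0
  w <- traj$mesh$node_areas / sum(traj$mesh$node_areas)
  vscale <- traj$groups$vel_scale_um_h
  mid <- numeric(nf - 1L); v <- numeric(nf - 1L); outf <- numeric(nf - 1L)
  for (k in seq_len(nf - 1L)) {
    dt <- traj$times[k + 1L] - traj$times[k]
    dvr <- (rowSums((traj$u[, , k + 1L] - traj$u[, , k]) * rhat)) / dt
    mid[k] <- (traj$times[k] + traj$times[k + 1L]) / 2
    v[k] <- -sum(w * dvr) * vscale
    outf[k] <- sum(w[dvr > 0])
  }
  out <- data.frame(time = mid,
                    time_h = mid * traj$groups$tau_L / 3600,
                    mean_radial_velocity = v,
                    outward_fraction = outf)
  class(out) <- c("radial_velocity_series", "data.frame")
  out
}

#' Windowed average of the radial velocity
#'
#' Applies the coordinated-migration window: the window opens at the
#' first frame where less than `open_frac` (default 1%) of the monolayer
#' area moves away from the centre, and closes at the first later frame
#' where the mean radial velocity has fallen below `close_frac` (default
#' 20%) of its value at the opening frame; if it never falls that far the
#' window extends to the end of the series. The returned value is the
#' mean of the per-frame mean radial velocities inside the window.
#'
#' If no frame satisfies the opening rule the run never achieves
#' coordinated inward migration and an error of class
#' `activegel_window_error` is thrown; ensemble drivers treat such runs
#' as immobile (velocity 0).
#'
#' @param series a [radial_velocity_series()]
#' @param open_frac outward-area fraction opening the window
#' @param close_frac velocity fraction (of the opening value) closing it
#' @return scalar averaged radial velocity, um/h
#' @export
averaged_radial_velocity <- function(series, open_frac = 0.01,
                                     close_frac = 0.20) {
  if (nrow(series) < 1L) stop("empty series", call. = FALSE)
  i0 <- which(series$outward_fraction < open_frac)[1L]
  if (is.na(i0))
    stop(structure(class = c("activegel_window_error", "error", "condition"),
                   list(message = "no frame satisfies the outward-fraction rule; run is immobile",
                        call = sys.call(-1))))
  v <- series$mean_radial_velocity
  v0 <- v[i0]
  i1 <- which(seq_along(v) > i0 & v < close_frac * v0)[1L]
  if (is.na(i1)) i1 <- length(v)
  mean(v[i0:i1])
}

#' Prestress sweep over seeding prefactors
#'
#' Runs the quiescence-exit protocol for every (prefactor, seed)
#' combination, records the realized prestress `c0` and the windowed
#' averaged radial velocity per run (immobile runs enter as 0), and
#' summarises each prefactor by the ensemble mean and the min/max
#' envelope (plus a conventional SD).
#'
#' @param mesh a [disc_mesh()]
#' @param params a [model_params()]
#' @param stepper a [stepper_spec()]
#' @param prefactors numeric vector of seeding prefactors
#' @param n_seeds ensemble size per prefactor
#' @param base_seed integer; run `(i, j)` uses seed
#'   `base_seed + (i-1)*n_seeds + (j-1)`
#' @param output_times passed to the simulation
#' @return object of class `sweep_result`: list with `runs` (data.frame:
#'   prefactor, seed, c0, v_avg, mobile) and `summary` (data.frame:
#'   prefactor, mean c0, mean/min/max/sd of v_avg)
#' @export
prestress_sweep <- function(mesh, params, stepper = stepper_spec(),
                            prefactors = c(0.01, 0.1, 0.5, 1.0, 2.0, 3.0),
                            n_seeds = 10L, base_seed = 1L,
                            output_times = NULL) {
  stopifnot(n_seeds >= 1L)
  rows <- list()
  for (i in seq_along(prefactors)) {
    for (j in seq_len(n_seeds)) {
      seed <- base_seed + (i - 1L) * n_seeds + (j - 1L)
      sp <- seeding_spec(prefactor = prefactors[i], rng_seed = seed)
      traj <- tryCatch(
        quiescence_run(mesh, params, sp, stepper, output_times),
        error = function(e) {
          stop(sprintf("solver failed at prefactor %g, seed %d: %s",
                       prefactors[i], seed, conditionMessage(e)), call. = FALSE)
        })
      v <- tryCatch(averaged_radial_velocity(radial_velocity_series(traj)),
                    activegel_window_error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        prefactor = prefactors[i], seed = seed, c0 = traj$c0,
        v_avg = ifelse(is.na(v), 0, v), mobile = !is.na(v))
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$prefactor), function(d)
    data.frame(prefactor = d$prefactor[1L], c0 = mean(d$c0),
               v_mean = mean(d$v_avg), v_min = min(d$v_avg),
               v_max = max(d$v_avg), v_sd = stats::sd(d$v_avg))))
  rownames(summ) <- NULL
  summ <- summ[order(summ$prefactor), ]
  structure(list(runs = runs, summary = summ,
                 params = params, stepper = stepper),
            class = "sweep_result")
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat("prestress sweep:", nrow(x$runs), "runs\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Fit a sigmoid velocity response
#'
#' Nonlinear least squares of `v = a0 / (1 + exp(-a1 (x - a2)))` by
#' Levenberg--Marquardt with a deterministic multi-start grid: `a0`
#' starts at `max(v)` and `1.5 max(v)`, `a1` on a log grid from 1 to 100,
#' `a2` on the data quantiles. The best converged start (lowest residual
#' sum of squares) wins; ties and data order do not affect the result.
#'
#' @param x abscissa (excess prestress `c0 - 1` by convention)
#' @param v velocities, um/h
#' @return object of class `sigmoid_fit`: list with `a0`, `a1`, `a2`,
#'   `residual_norm`, `cov` (parameter covariance estimate) and `fitted`
#' @export
fit_sigmoid <- function(x, v) {
  if (length(x) != length(v)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(v)
  x <- x[ok]; v <- v[ok]
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct abscissa values", call. = FALSE)
  if (stats::sd(v) == 0)
    stop("degenerate fit: constant response", call. = FALSE)
  ord <- order(x, v)
  x <- x[ord]; v <- v[ord]
  dat <- data.frame(x = x, v = v)
  starts <- expand.grid(
    a0 = c(max(v), 1.5 * max(v)),
    a1 = c(1, 3, 10, 17, 30, 100),
    a2 = unique(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ a0 / (1 + exp(-a1 * (x - a2))), data = dat,
                        start = as.list(starts[i, ]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("sigmoid fit did not converge from any start", call. = FALSE)
  cf <- stats::coef(best$fit)
  cv <- tryCatch(stats::vcov(best$fit), error = function(e) matrix(NA, 3, 3))
  structure(list(a0 = unname(cf["a0"]), a1 = unname(cf["a1"]),
                 a2 = unname(cf["a2"]),
                 residual_norm = sqrt(best$rss), cov = cv,
                 fitted = stats::fitted(best$fit), x = x, v = v),
            class = "sigmoid_fit")
}

#' @exportS3Method base::print
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: a0 = %.4g um/h, a1 = %.4g, a2 = %.4g (residual %.3g)\n",
              x$a0, x$a1, x$a2, x$residual_norm))
  invisible(x)
}

#' Predict from a sigmoid fit
#' @param object a `sigmoid_fit`
#' @param newdata abscissa values
#' @param ... unused
#' @export
predict.sigmoid_fit <- function(object, newdata, ...) {
  object$a0 / (1 + exp(-object$a1 * (newdata - object$a2)))
}
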