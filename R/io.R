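# Readers/writers for the formats the pipeline touches: flat key=value
# run configs, multi-frame TIFF stacks, and a hierarchical directory
# container for field data.

run_config_keys <- function() {
  c("model.E", "model.h_eq", "model.Gamma", "model.D",
    "model.beta_over_ceq", "model.tau_c", "model.eta", "model.alpha_hat",
    "model.c_eq", "model.R", "model.strain_activation",
    "stepper.dt0", "stepper.growth", "stepper.dt_max", "stepper.t_end",
    "stepper.newton_tol", "stepper.newton_max_iter",
    "seeding.probability", "seeding.prefactor", "seeding.rng_seed",
    "seeding.value_mean", "seeding.value_sd",
    "mesh.spacing",
    "substrate.youngs_modulus", "substrate.poisson_ratio",
    "imaging.pixel_size", "imaging.frame_interval_min",
    "io.out_dir")
}

#' Read a run configuration file
#'
#' Flat `key = value` format with `#` comments; keys are dotted paths
#' (e.g. `model.E`, units documented in the packaged template, see
#' `system.file("extdata", "demo_run.cfg", package = "activegel")`).
#' Unknown keys are rejected; missing required keys are reported with
#' their full path.
#'
#' @param path config file
#' @param required character vector of keys that must be present
#' @return named list of values (numeric where possible), nested by the
#'   first path component
#' @export
read_run_config <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  unknown <- setdiff(keys, run_config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(required, keys)
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- suppressWarnings(as.numeric(vals))
  parsed <- ifelse(is.na(num), vals, num)
  out <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1L]]
    v <- if (is.na(num[i])) vals[i] else num[i]
    out[[parts[1L]]][[parts[2L]]] <- v
  }
  out
}

#' Build model/stepper/seeding objects from a config
#' @param cfg a [read_run_config()] result
#' @return list with `params`, `stepper`, `seeding`, `mesh_spacing`
#' @export
config_objects <- function(cfg) {
  pick <- function(block, name, default) {
    v <- cfg[[block]][[name]]
    if (is.null(v)) default else v
  }
  params <- model_params(
    E = pick("model", "E", 4000), h_eq = pick("model", "h_eq", 8e-6),
    Gamma = pick("model", "Gamma", 2.5e8), D = pick("model", "D", 1e-9),
    beta_over_ceq = pick("model", "beta_over_ceq", 8e-5),
    tau_c = pick("model", "tau_c", 13000), eta = pick("model", "eta", 0),
    alpha_hat = pick("model", "alpha_hat", default_alpha_hat()),
    c_eq = pick("model", "c_eq", 1), R = pick("model", "R", 3.5e-3),
    strain_activation = pick("model", "strain_activation", "compression"))
  stepper <- stepper_spec(
    dt0 = pick("stepper", "dt0", 5e-5), growth = pick("stepper", "growth", 1.05),
    dt_max = pick("stepper", "dt_max", 1e-3), t_end = pick("stepper", "t_end", 3),
    newton_tol = pick("stepper", "newton_tol", 1e-8),
    newton_max_iter = pick("stepper", "newton_max_iter", 25))
  seeding <- seeding_spec(
    probability = pick("seeding", "probability", 0.6),
    prefactor = pick("seeding", "prefactor", 1),
    rng_seed = pick("seeding", "rng_seed", 1),
    value_mean = pick("seeding", "value_mean", 1 / 3),
    value_sd = pick("seeding", "value_sd", 1 / 6))
  list(params = params, stepper = stepper, seeding = seeding,
       mesh_spacing = pick("mesh", "spacing", 0.05))
}

#' Read a multi-frame TIFF stack
#'
#' Frames are returned as float matrices flipped so that the origin is
#' at the lower-left (x right, y up) — image row 1 becomes the bottom
#' row.
#'
#' @param path TIFF file
#' @return list of matrices
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  lapply(fr, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    f[nrow(f):1L, , drop = FALSE]
  })
}

#' Write a multi-frame TIFF stack
#' @param frames list of matrices (package convention, origin lower-left)
#' @param path output file
#' @export
write_image_stack <- function(frames, path) {
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f <- f[nrow(f):1L, , drop = FALSE]
    mx <- max(f)
    if (mx > 1) f <- f / mx
    pmin(pmax(f, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Maximum-intensity projection of a z-stack
#' @param frames list of matrices (z planes)
#' @return single matrix of per-pixel maxima
#' @export
max_projection <- function(frames) {
  Reduce(pmax, frames)
}

container_schema_version <- 1L

#' Write / read a hierarchical field container
#'
#' A container is a directory holding a `meta.json` (schema version plus
#' arbitrary metadata) and one serialized dataset per name. Datasets are
#' read lazily: [read_container()] returns an index; `$get(name)` loads
#' a dataset on demand, so large per-frame collections never sit in
#' memory at once.
#'
#' @param path container directory (created if needed)
#' @param datasets named list of R objects
#' @param meta named list of metadata (stored as JSON)
#' @export
write_container <- function(path, datasets, meta = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta$schema_version <- container_schema_version
  meta$datasets <- names(datasets)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(datasets)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    saveRDS(datasets[[nm]], file.path(path, paste0(safe, ".rds")))
  }
  invisible(path)
}

#' @rdname write_container
#' @return `read_container` returns an object of class `field_container`
#'   with `$meta`, `$names` and `$get(name)`
#' @export
read_container <- function(path) {
  mp <- file.path(path, "meta.json")
  if (!file.exists(mp))
    stop("not a container (missing meta.json): ", path, call. = FALSE)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (is.null(meta$schema_version))
    stop("container schema error: no schema_version in metadata", call. = FALSE)
  if (meta$schema_version > container_schema_version)
    stop(sprintf("container schema version %s is newer than supported (%d)",
                 meta$schema_version, container_schema_version), call. = FALSE)
  nms <- meta$datasets
  structure(list(
    meta = meta, names = nms, path = path,
    get = function(name) {
      if (!name %in% nms) stop("no such dataset: ", name, call. = FALSE)
      safe <- gsub("[^A-Za-z0-9_.-]", "_", name)
      readRDS(file.path(path, paste0(safe, ".rds")))
    }), class = "field_container")
}

#' Save a trajectory as a container
#' @param traj a `gel_trajectory`
#' @param path container directory
#' @export
write_trajectory <- function(traj, path) {
  sets <- list(
    "mesh/nodes" = traj$mesh$nodes,
    "mesh/triangles" = traj$mesh$triangles,
    "times" = traj$times)
  for (k in seq_along(traj$times)) {
    sets[[sprintf("snapshots/%d/u", k)]] <- traj$u[, , k]
    sets[[sprintf("snapshots/%d/c", k)]] <- traj$c[, k]
  }
  meta <- list(kind = "gel_trajectory",
               params = unclass(traj$params),
               stepper = unclass(traj$stepper),
               seeding = if (!is.null(traj$seeding)) unclass(traj$seeding),
               c0 = traj$c0, n_steps = traj$n_steps,
               c_boundary = traj$c_boundary)
  write_container(path, sets, meta)
}
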