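#' Head-motion exclusion rule
#'
#' Flags a subject for exclusion when any realignment parameter exceeds the
#' translation or rotation limit (defaults 3 mm / 3 degrees).
#'
#' @param motion_params numeric matrix, time x 6: three translations (mm)
#'   then three rotations (degrees).
#' @param trans_limit_mm translation limit in mm.
#' @param rot_limit_deg rotation limit in degrees.
#' @return `TRUE` if the subject must be excluded, `FALSE` to keep.
#' @export
qc_motion_exclusion <- function(motion_params, trans_limit_mm = 3,
                                rot_limit_deg = 3) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L)
    stop("motion_params must have 6 columns (3 translations, 3 rotations)")
  any(abs(motion_params[, 1:3]) > trans_limit_mm) ||
    any(abs(motion_params[, 4:6]) > rot_limit_deg)
}

#' Drop initial equilibration frames
#'
#' @param run a `bold_run` (4D array, time first).
#' @param k number of leading frames to drop (default 10).
#' @return The trimmed `bold_run`.
#' @export
trim_initial_volumes <- function(run, k = 10L) {
  tp <- dim(run$data)[1]
  if (k < 0L) stop("k must be non-negative")
  if (tp <= k + 1L)
    stop("cannot trim ", k, " frames from a run of length ", tp)
  if (k > 0L) run$data <- run$data[-seq_len(k), , , , drop = FALSE]
  run
}

#' Remove a least-squares linear trend
#'
#' Projects each series onto the complement of `[1, t]`; the output is
#' orthogonal to both the constant and the linear ramp, and the operation is
#' idempotent.
#'
#' @param series numeric vector, or time x voxels matrix.
#' @return Detrended series of the same shape.
#' @export
detrend_linear <- function(series) {
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  tp <- nrow(x)
  if (tp < 3L) stop("need at least 3 timepoints to detrend")
  design <- cbind(1, seq_len(tp))
  res <- stats::lm.fit(design, x)$residuals
  if (is.matrix(series)) res else drop(res)
}

#' Regress out nuisance signals
#'
#' Ordinary least squares of each series on an intercept plus the nuisance
#' columns (tissue means, global signal, motion parameters); returns the
#' residual, which is orthogonal to every regressor. Rank-deficient designs
#' are handled by dropping aliased columns (the residual is still the unique
#' projection) with a warning.
#'
#' @param series numeric vector or time x voxels matrix.
#' @param regressors numeric matrix, time x q.
#' @return Residual series of the same shape as `series`.
#' @export
regress_nuisance <- function(series, regressors) {
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(x))
    stop("regressor rows (", nrow(regressors),
         ") must match series length (", nrow(x), ")")
  if (any(!is.finite(regressors))) stop("regressors must be finite")
  design <- cbind(intercept = 1, regressors)
  fit <- stats::lm.fit(design, x)
  if (fit$rank < ncol(design))
    warning("rank-deficient nuisance design; aliased columns dropped")
  res <- fit$residuals
  if (is.matrix(series)) res else drop(res)
}

#' Ideal frequency-domain bandpass filter
#'
#' Discrete-Fourier brick-wall filter: frequency bins inside `[low_hz,
#' high_hz]` are kept, all others (including DC, always) are zeroed. This is
#' the resting-state convention for the 0.01--0.08 Hz band.
#'
#' @param series numeric vector or time x voxels matrix.
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.08).
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @return Filtered series of the same shape.
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.08,
                            tr_seconds = 2) {
  nyquist <- 1 / (2 * tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz) stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyquist)
    stop("high_hz (", high_hz, ") must be below the Nyquist frequency (",
         nyquist, ")")
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  tp <- nrow(x)
  k <- 0:(tp - 1)
  freq <- pmin(k, tp - k) / (tp * tr_seconds)
  keep <- freq >= low_hz & freq <= high_hz & k != 0L
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / tp
  if (is.matrix(series)) out else drop(out)
}

# time x voxels matrix of the in-mask voxels of a run, Fortran voxel order
.run_matrix <- function(run) {
  tp <- dim(run$data)[1]
  m <- matrix(run$data, nrow = tp)
  m[, as.vector(run$mask), drop = FALSE]
}

#' Mean time series of the seed region
#'
#' Unweighted mean, per timepoint, over all voxels whose atlas label is one
#' of `seed_labels`.
#'
#' @param run a `bold_run`.
#' @param atlas an `atlas_map` on the same grid.
#' @param seed_labels region ids forming the seed (default: the atlas's).
#' @return Numeric vector of length `T`.
#' @export
seed_mean_series <- function(run, atlas, seed_labels = atlas$seed_labels) {
  if (!identical(dim(run$data)[-1], dim(atlas$labels)))
    stop("run and atlas grids do not match")
  sel <- as.vector(atlas$labels %in% seed_labels & run$mask)
  if (!any(sel)) stop("no in-mask voxels carry a seed label")
  tp <- dim(run$data)[1]
  m <- matrix(run$data, nrow = tp)
  rowMeans(m[, sel, drop = FALSE])
}

.Z_CLAMP <- 1 - 1e-7

#' Seed-to-voxel correlation map with Fisher z transform
#'
#' Pearson correlation of every in-mask voxel with the seed series, and its
#' Fisher z transform `z = atanh(r)` with `|r|` clamped at `1 - 1e-7` so z
#' stays finite. Zero-variance voxels get `r = 0` with a warning.
#'
#' @param run a `bold_run` (already trimmed/detrended/filtered as intended).
#' @param seed_series numeric vector matching the run's time length.
#' @param atlas an `atlas_map` on the run's grid (carried into the map).
#' @return An `fc_map`: list with 3D arrays `r` and `z` (zero outside the
#'   mask), `mask`, and `seed_labels`.
#' @export
seed_correlation_map <- function(run, seed_series, atlas) {
  tp <- dim(run$data)[1]
  if (length(seed_series) != tp)
    stop("seed series length does not match run")
  if (stats::sd(seed_series) == 0)
    stop("degenerate seed: constant seed series")
  m <- matrix(run$data, nrow = tp)
  sel <- as.vector(run$mask)
  v <- m[, sel, drop = FALSE]
  sds <- apply(v, 2L, stats::sd)
  dead <- sds == 0
  r <- numeric(ncol(v))
  if (any(!dead)) {
    r[!dead] <- drop(stats::cor(seed_series, v[, !dead, drop = FALSE]))
  }
  if (any(dead)) {
    warning(sum(dead), " zero-variance voxel(s); correlation set to 0")
    r[dead] <- 0
  }
  rc <- pmin(pmax(r, -.Z_CLAMP), .Z_CLAMP)
  z <- atanh(rc)
  grid <- dim(run$data)[-1]
  rmap <- array(0, dim = grid); rmap[sel] <- r
  zmap <- array(0, dim = grid); zmap[sel] <- z
  structure(list(r = rmap, z = zmap, mask = run$mask,
                 seed_labels = atlas$seed_labels),
            class = "fc_map")
}

#' Voxel registry for a masked atlas
#'
#' Fixed linear ordering of in-mask voxels: ascending linear index with the
#' first axis fastest (column-major, the array's native order). The registry
#' maps each feature-vector position to its grid coordinate and region label.
#' By default the seed region's own voxels are excluded -- the connectivity
#' features are the correlations of the seed with the *remaining* voxels.
#'
#' @param atlas an `atlas_map`.
#' @param mask logical 3D array (default: the atlas mask).
#' @param exclude_seed drop voxels belonging to seed regions (default
#'   `TRUE`).
#' @return data.frame `index, linear, x, y, z, region` (1-based coordinates).
#' @export
voxel_registry <- function(atlas, mask = atlas$mask, exclude_seed = TRUE) {
  if (!identical(dim(mask), dim(atlas$labels)))
    stop("mask does not match atlas grid")
  if (exclude_seed) mask <- mask & !(atlas$labels %in% atlas$seed_labels)
  lin <- which(as.vector(mask))
  co <- arrayInd(lin, dim(mask))
  data.frame(index = seq_along(lin), linear = lin,
             x = co[, 1], y = co[, 2], z = co[, 3],
             region = as.integer(atlas$labels[lin]))
}

#' Vectorize an FC map over a mask
#'
#' @param fcmap an `fc_map`.
#' @param registry a [voxel_registry()]; its mask must match the map grid.
#' @param what `"z"` (default) or `"r"`.
#' @return Numeric feature vector in registry order.
#' @export
vectorize_map <- function(fcmap, registry, what = c("z", "r")) {
  what <- match.arg(what)
  arr <- fcmap[[what]]
  if (max(registry$linear) > length(arr))
    stop("registry does not match map grid")
  arr[registry$linear]
}

#' Restore a feature vector to its 3D grid
#'
#' Inverse of [vectorize_map()]: round-trips bit-exactly.
#'
#' @param values numeric vector in registry order.
#' @param registry a [voxel_registry()].
#' @param grid_shape integer vector of length 3.
#' @return 3D array, zero outside the registry's voxels.
#' @export
devectorize_map <- function(values, registry, grid_shape) {
  if (length(values) != nrow(registry))
    stop("value length does not match registry")
  arr <- array(0, dim = grid_shape)
  arr[registry$linear] <- values
  arr
}

#' Full seed-connectivity chain for one run
#'
#' Applies the fixed processing order -- trim initial frames, linear detrend,
#' optional nuisance regression, ideal bandpass -- then extracts the seed
#' mean series and computes the Fisher z correlation map.
#'
#' @param run a `bold_run`.
#' @param atlas an `atlas_map` on the run's grid.
#' @param seed_labels seed region ids (default: the atlas's).
#' @param trim frames to drop (default 10).
#' @param nuisance optional time x q regressor matrix (rows must match the
#'   *trimmed* length).
#' @param bandpass length-2 numeric passband in Hz, or `NULL` to skip.
#' @param detrend logical, remove linear trend (default `TRUE`).
#' @return An `fc_map`.
#' @export
compute_fc_map <- function(run, atlas, seed_labels = atlas$seed_labels,
                           trim = 10L, nuisance = NULL,
                           bandpass = c(0.01, 0.08), detrend = TRUE) {
  run <- trim_initial_volumes(run, trim)
  tp <- dim(run$data)[1]
  grid <- dim(run$data)[-1]
  m <- matrix(run$data, nrow = tp)
  if (detrend) m <- detrend_linear(m)
  if (!is.null(nuisance)) m <- regress_nuisance(m, nuisance)
  if (!is.null(bandpass))
    m <- bandpass_filter(m, bandpass[1], bandpass[2], run$tr_seconds)
  run$data <- array(m, dim = c(tp, grid))
  seed <- seed_mean_series(run, atlas, seed_labels)
  seed_correlation_map(run, seed, atlas)
}

#' Build a subjects x voxels feature matrix from a cohort
#'
#' Runs [compute_fc_map()] on every subject and stacks the vectorized Fisher
#' z maps in registry order.
#'
#' @param runs list of `bold_run`.
#' @param atlas an `atlas_map`.
#' @param ... passed to [compute_fc_map()].
#' @return List with `values` (subjects x voxels matrix, rownames = subject
#'   ids), `registry`, and `grid_shape`.
#' @export
build_feature_matrix <- function(runs, atlas, ...) {
  registry <- voxel_registry(atlas)
  vals <- t(vapply(runs, function(run) {
    vectorize_map(compute_fc_map(run, atlas, ...), registry)
  }, numeric(nrow(registry))))
  rownames(vals) <- vapply(runs, `[[`, character(1), "subject_id")
  list(values = vals, registry = registry, grid_shape = dim(atlas$labels))
}

#' Write an FC map as paired NIfTI volumes
#'
#' @param fcmap an `fc_map`.
#' @param prefix output path prefix; writes `<prefix>_r.nii.gz` and
#'   `<prefix>_z.nii.gz`.
#' @return Invisibly, the two file paths.
#' @export
write_fc_map <- function(fcmap, prefix) {
  pr <- paste0(prefix, "_r.nii.gz")
  pz <- paste0(prefix, "_z.nii.gz")
  RNifti::writeNifti(fcmap$r, pr)
  RNifti::writeNifti(fcmap$z, pz)
  invisible(c(pr, pz))
}

#' Read six-column motion parameters from whitespace-delimited text
#'
#' @param path text file with 6 numeric columns (translations mm, rotations
#'   degrees).
#' @return time x 6 numeric matrix.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion file must have 6 columns")
  unname(m)
}
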