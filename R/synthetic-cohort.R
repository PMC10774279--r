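#' Cohort specification for the synthetic generator
#'
#' Describes a synthetic resting-state cohort with the statistical structure
#' the seed-connectivity analysis assumes: a small labelled 3D grid with a
#' designated bilateral seed region, group-dependent seed--voxel coupling that
#' is elevated in a planted subset of regions for the bipolar-like groups
#' (emulating the unipolar < bipolar connectivity pattern), independent
#' Gaussian voxel noise, and clinician-scale scores with group-dependent
#' means.
#'
#' A voxel in a region with coupling `c` carries the signal
#' `c * seed + sqrt(1 - c^2) * noise`, so with unit-variance noise
#' (`noise_sd = 1`) its expected correlation with the seed latent series is
#' exactly `c`. Seed-region voxels carry the latent series itself
#' (coupling 1).
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param n_regions number of atlas regions `R` (>= 2).
#' @param seed_region_ids region ids acting as the bilateral seed.
#' @param planted_region_ids region ids carrying the group effect; must be
#'   disjoint from `seed_region_ids`.
#' @param n_per_group named integer vector of subjects per group; names are
#'   group labels from `UD`, `tBD`, `BD`.
#' @param coupling_by_group named numeric vector in `[0, 1)`: seed coupling of
#'   planted-region voxels for each group.
#' @param baseline_coupling coupling of non-planted, non-seed voxels, shared
#'   by all groups.
#' @param noise_sd standard deviation of the voxel noise. With the default 1
#'   the expected seed correlation of a voxel equals its coupling; otherwise
#'   it is `c / sqrt(c^2 + (1 - c^2) * noise_sd^2)`.
#' @param n_timepoints frames per run (default 200, i.e. a 400 s acquisition
#'   at TR 2 s).
#' @param tr_seconds repetition time in seconds.
#' @param rng_seed integer seed governing the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(grid_shape = c(12L, 12L, 8L),
                        n_regions = 12L,
                        seed_region_ids = 1L,
                        planted_region_ids = c(4L, 6L, 9L, 11L),
                        n_per_group = c(UD = 30L, BD = 30L),
                        coupling_by_group = c(UD = 0.2, tBD = 0.6, BD = 0.6),
                        baseline_coupling = 0.2,
                        noise_sd = 1,
                        n_timepoints = 200L,
                        tr_seconds = 2,
                        rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("n_regions must be >= 2")
  if (prod(grid_shape) < n_regions)
    stop("grid too small: ", prod(grid_shape), " voxels < ", n_regions,
         " regions")
  seed_region_ids <- as.integer(seed_region_ids)
  planted_region_ids <- as.integer(planted_region_ids)
  ids <- c(seed_region_ids, planted_region_ids)
  if (any(ids < 1L | ids > n_regions))
    stop("region ids must lie in [1, n_regions]")
  if (length(intersect(seed_region_ids, planted_region_ids)) > 0L)
    stop("planted_region_ids must not overlap seed_region_ids")
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% c("UD", "tBD", "BD")))
    stop("n_per_group must be named with groups among UD, tBD, BD")
  if (any(n_per_group < 1L)) stop("group counts must be positive")
  if (!all(names(n_per_group) %in% names(coupling_by_group)))
    stop("coupling_by_group must cover every group in n_per_group")
  if (any(coupling_by_group < 0 | coupling_by_group >= 1) ||
      baseline_coupling < 0 || baseline_coupling >= 1)
    stop("couplings must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  structure(list(grid_shape = grid_shape, n_regions = n_regions,
                 seed_region_ids = seed_region_ids,
                 planted_region_ids = planted_region_ids,
                 n_per_group = n_per_group,
                 coupling_by_group = coupling_by_group,
                 baseline_coupling = baseline_coupling,
                 noise_sd = noise_sd,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# Recursive bisection of a box into r axis-aligned, contiguous, non-empty
# blocks. ranges: list of length-2 integer vectors per axis.
.split_box <- function(labels, ranges, r, next_id) {
  if (r == 1L) {
    labels[ranges[[1]][1]:ranges[[1]][2],
           ranges[[2]][1]:ranges[[2]][2],
           ranges[[3]][1]:ranges[[3]][2]] <- next_id
    return(list(labels = labels, next_id = next_id + 1L))
  }
  ext <- vapply(ranges, function(rg) rg[2] - rg[1] + 1L, integer(1))
  ax <- which.max(ext)
  e <- ext[ax]
  area <- prod(ext[-ax])
  r1 <- r %/% 2L
  r2 <- r - r1
  lo <- ceiling(r1 / area)
  hi <- e - ceiling(r2 / area)
  s <- as.integer(min(max(round(e * r1 / r), lo), hi))
  left <- ranges
  left[[ax]][2] <- ranges[[ax]][1] + s - 1L
  right <- ranges
  right[[ax]][1] <- ranges[[ax]][1] + s
  out <- .split_box(labels, left, r1, next_id)
  .split_box(out$labels, right, r2, out$next_id)
}

#' Build a miniature atlas of contiguous axis-aligned regions
#'
#' Partitions a small 3D grid into `n_regions` non-empty, spatially
#' contiguous axis-aligned blocks by recursive bisection (the split always
#' follows the longest axis, proportional to the region counts on each side),
#' then applies a seeded permutation of the labels. Serves as a stand-in for
#' an anatomical parcellation with a designated seed region.
#'
#' @param grid_shape integer vector of length 3.
#' @param n_regions number of regions (>= 2, <= number of voxels).
#' @param seed_region_ids region ids designated as the seed (default 1).
#' @param rng_seed seed for the label permutation.
#' @return An `atlas_map`: list with `labels` (3D integer array), `mask`
#'   (all `TRUE` here), `n_regions`, `seed_labels`, and `region_names`
#'   (id -> name; seed regions are named `amygdala_<id>`).
#' @export
build_toy_atlas <- function(grid_shape, n_regions, seed_region_ids = 1L,
                            rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("n_regions must be >= 2")
  if (prod(grid_shape) < n_regions)
    stop("grid too small: ", prod(grid_shape), " voxels < ", n_regions,
         " regions")
  seed_region_ids <- as.integer(seed_region_ids)
  if (any(seed_region_ids < 1L | seed_region_ids > n_regions))
    stop("seed_region_ids must lie in [1, n_regions]")
  labels <- array(0L, dim = grid_shape)
  ranges <- lapply(grid_shape, function(d) c(1L, d))
  labels <- .split_box(labels, ranges, n_regions, 1L)$labels
  # seeded relabelling keeps geometry deterministic while exercising rng_seed
  perm <- withr_seed(rng_seed, sample.int(n_regions))
  labels <- array(perm[labels], dim = grid_shape)
  nm <- sprintf("region_%02d", seq_len(n_regions))
  nm[seed_region_ids] <- sprintf("amygdala_%02d", seed_region_ids)
  structure(list(labels = labels, mask = array(TRUE, dim = grid_shape),
                 n_regions = n_regions, seed_labels = seed_region_ids,
                 region_names = stats::setNames(nm, seq_len(n_regions))),
            class = "atlas_map")
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# coupling of every region for one group
.region_coupling <- function(spec, group) {
  cc <- rep(spec$baseline_coupling, spec$n_regions)
  cc[spec$planted_region_ids] <- spec$coupling_by_group[[group]]
  cc[spec$seed_region_ids] <- 1
  cc
}

#' Simulate one subject's BOLD run
#'
#' Draws a latent seed series `s_t ~ N(0,1)` and gives each voxel in a region
#' with coupling `c` the signal `c*s + sqrt(1-c^2)*e`, `e ~ N(0, noise_sd^2)`
#' independent over voxels and timepoints. Seed-region voxels carry `s`
#' itself, so the seed mean series equals the latent series and the expected
#' seed correlation of a voxel is its coupling (exactly, when `noise_sd = 1`).
#'
#' @param atlas an `atlas_map` on the spec's grid.
#' @param spec a [cohort_spec()].
#' @param group group label; must be present in `spec$n_per_group`.
#' @param rng_stream integer seed for this subject's private stream.
#' @param subject_id subject identifier string.
#' @return A `bold_run`: list with `data` (4D array, time first), `mask`,
#'   `tr_seconds`, `subject_id`.
#' @export
simulate_subject_run <- function(atlas, spec, group, rng_stream,
                                 subject_id = "sub-000") {
  if (!group %in% names(spec$n_per_group))
    stop("unknown group '", group, "' for this cohort spec")
  tp <- spec$n_timepoints
  vox_region <- as.integer(atlas$labels)
  cc <- .region_coupling(spec, group)[vox_region]
  dat <- withr_seed(rng_stream, {
    s <- stats::rnorm(tp)
    noise <- matrix(stats::rnorm(tp * length(cc), sd = spec$noise_sd), nrow = tp)
    outer(s, cc) + sweep(noise, 2L, sqrt(1 - cc^2), `*`)
  })
  structure(list(data = array(dat, dim = c(tp, spec$grid_shape)),
                 mask = atlas$mask, tr_seconds = spec$tr_seconds,
                 subject_id = subject_id),
            class = "bold_run")
}

# group parameters for clinician scales / demographics, approximating the
# printed cohort description (means or medians with SD or IQR/1.349)
.clinical_params <- list(
  hamd17 = list(UD = c(24.6, 8.1), tBD = c(24.3, 6.7), BD = c(15.6, 7.3),
                range = c(0, 52)),
  hama   = list(UD = c(17.0, 8.2), tBD = c(24.0, 9.6), BD = c(11.5, 7.0),
                range = c(0, 56)),
  ymrs   = list(UD = c(0, 1.5), tBD = c(0, 0.5), BD = c(2, 3.7),
                range = c(0, 60)),
  age    = list(UD = c(29.0, 13.0), tBD = c(27.0, 9.6), BD = c(24.5, 8.5),
                range = c(13, 55)),
  p_female = c(UD = 43 / 69, tBD = 14 / 23, BD = 30 / 48)
)

.draw_scale <- function(n, par, integer = TRUE) {
  x <- stats::rnorm(n, par[1], par[2])
  x <- pmin(pmax(x, par[3]), par[4])
  if (integer) round(x) else x
}

#' Simulate a full cohort
#'
#' Builds the atlas, draws per-subject private RNG streams from the cohort
#' seed, simulates one run per subject and a metadata table of clinician
#' scales (truncated-normal draws rounded to integers, clipped to instrument
#' ranges) with group-dependent parameters.
#'
#' @param spec a [cohort_spec()].
#' @param atlas optional pre-built `atlas_map`; built from the spec otherwise.
#' @return List with `runs` (list of `bold_run`), `subjects` (data.frame:
#'   `subject_id, group, hamd17, hama, ymrs, age_years, sex`), and `atlas`.
#' @export
simulate_cohort <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(atlas))
    atlas <- build_toy_atlas(spec$grid_shape, spec$n_regions,
                             spec$seed_region_ids, spec$rng_seed)
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n <- length(groups)
  meta <- withr_seed(spec$rng_seed, {
    streams <- sample.int(.Machine$integer.max - 1L, n)
    df <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = groups,
      stringsAsFactors = FALSE
    )
    for (sc in c("hamd17", "hama", "ymrs")) {
      par <- .clinical_params[[sc]]
      df[[sc]] <- vapply(seq_len(n), function(i) {
        g <- groups[i]
        as.integer(.draw_scale(1L, c(par[[g]], par$range)))
      }, integer(1))
    }
    par <- .clinical_params$age
    df$age_years <- vapply(seq_len(n), function(i)
      .draw_scale(1L, c(par[[groups[i]]], par$range), integer = FALSE),
      numeric(1))
    df$sex <- ifelse(stats::runif(n) < .clinical_params$p_female[groups],
                     "F", "M")
    list(df = df, streams = streams)
  })
  runs <- lapply(seq_len(n), function(i)
    simulate_subject_run(atlas, spec, groups[i], meta$streams[i],
                         meta$df$subject_id[i]))
  list(runs = runs, subjects = meta$df, atlas = atlas)
}

#' Packaged contingency tables and score summaries of the source cohort
#'
#' Returns the demographic/clinical fixture tables for the three diagnostic
#' groups (69 unipolar, 23 converted-bipolar, 48 bipolar): sex and medication
#' 3x2 contingency tables, the 3x3 first-episode table, and the per-group
#' depression-scale summary (n, mean, sd). These are the published counts,
#' shipped as a plain-text fixture.
#'
#' @return A `table1_fixture`: list with `sex_counts`, `medication_counts`,
#'   `first_episode_counts` (integer matrices with named dimensions) and
#'   `hamd_summary` (data.frame `group, n, mean, sd`).
#' @export
load_table1_fixtures <- function() {
  path <- system.file("extdata", "table1.json", package = "limbicscreen",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_counts <- function(x, cols) {
    m <- if (is.matrix(x)) x
         else matrix(as.integer(unlist(x)), nrow = 3, byrow = TRUE)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(c("UD", "tBD", "BD"), cols)
    m
  }
  sex <- as_counts(raw$sex_counts, c("female", "male"))
  med <- as_counts(raw$medication_counts, c("yes", "no"))
  fe <- as_counts(raw$first_episode_counts, c("yes", "no", "unclear"))
  hs <- as.data.frame(raw$hamd_summary)
  gs <- as.integer(rowSums(sex))
  if (!identical(gs, c(69L, 23L, 48L)))
    stop("fixture corrupted: sex row sums must be 69/23/48")
  structure(list(sex_counts = sex, medication_counts = med,
                 first_episode_counts = fe, hamd_summary = hs),
            class = "table1_fixture")
}

#' Write a cohort to disk in standard formats
#'
#' Runs and atlas go out as NIfTI-1 volumes, metadata as TSV, and the spec as
#' JSON, mirroring the layout a real-data analysis would consume.
#'
#' @param cohort result of [simulate_cohort()].
#' @param spec the [cohort_spec()] used.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  RNifti::writeNifti(cohort$atlas$labels, atlas_path, datatype = "int16")
  files <- c(files, atlas_path)
  for (run in cohort$runs) {
    p <- file.path(out_dir, paste0(run$subject_id, "_bold.nii.gz"))
    # store as x,y,z,t per NIfTI convention
    RNifti::writeNifti(aperm(run$data, c(2, 3, 4, 1)), p)
    files <- c(files, p)
  }
  meta_path <- file.path(out_dir, "participants.tsv")
  utils::write.table(cohort$subjects, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  spec_path <- file.path(out_dir, "cohort_spec.json")
  jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, meta_path, spec_path))
}
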