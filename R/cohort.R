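## Synthetic multi-reader cohorts: per-subject hip geometry drawn from
## group-specific parameter distributions (controls anteverted with normal
## coverage, patients retroverted with posterior deficiency), simulated AP
## landmarks per reader and read with landmark-level jitter, and analytic
## ground truth per subject.

#' Specification of a synthetic two-group cohort
#'
#' Parameter distributions emulate the direction of the group differences
#' (anteverted controls vs retroverted, shallower patient cups); they are
#' not calibrated to any particular patient series.
#'
#' @param n_controls,n_patients group sizes.
#' @param n_readers,n_reads readers and repeated reads per radiograph.
#' @param reader_noise_sd SD of the per-landmark reader jitter, mm.
#' @param control_version_mean,control_version_sd,patient_version_mean,patient_version_sd
#'   cup version distributions, degrees (positive anteverted).
#' @param control_depth_mean,control_depth_sd,patient_depth_mean,patient_depth_sd
#'   cup depth-angle distributions, degrees.
#' @param head_radius_mean,head_radius_sd femoral head radius, mm.
#' @param tilt_sd,rotation_sd per-subject pelvic tilt/rotation SD, degrees.
#' @param mesh_resolution femur mesh vertex budget per subject.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   spec.
#' @return a validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 18, n_patients = 16,
                        n_readers = 2, n_reads = 2,
                        reader_noise_sd = 0.5,
                        control_version_mean = 15, control_version_sd = 3,
                        patient_version_mean = -12, patient_version_sd = 4,
                        control_depth_mean = 98, control_depth_sd = 3,
                        patient_depth_mean = 89, patient_depth_sd = 4,
                        head_radius_mean = 25, head_radius_sd = 1.5,
                        tilt_sd = 2, rotation_sd = 2,
                        mesh_resolution = 5000,
                        seed = 1L) {
  spec <- as.list(environment())
  if (spec$n_controls < 0 || spec$n_patients < 0 ||
      spec$n_controls + spec$n_patients < 1)
    stop("cohort must contain at least one subject")
  if (spec$n_readers < 1 || spec$n_reads < 1)
    stop("need n_readers >= 1 and n_reads >= 1")
  sds <- spec[grep("_sd$", names(spec))]
  if (any(unlist(sds) < 0)) stop("all SDs must be >= 0")
  structure(spec, class = "cohort_spec")
}

## per-entity landmark jitter: each named landmark gets its own offset so
## that noise propagates coherently into every measure that uses it.  The
## two wall traces share a common (film-level) offset plus a small
## independent per-wall component: a reader mislocates the wall pair far
## more than the walls relative to each other.
jitter_landmarks <- function(lm, sd) {
  if (sd == 0) return(lm)
  j2 <- function(p) p + rnorm(2, 0, sd)
  lm$head_circle$center <- j2(lm$head_circle$center)
  lm$head_circle$radius <- abs(lm$head_circle$radius + rnorm(1, 0, sd / 2))
  lm$lateral_sourcil <- j2(lm$lateral_sourcil)
  lm$medial_sourcil <- j2(lm$medial_sourcil)
  lm$teardrop <- j2(lm$teardrop)
  lm$teardrop_contralateral <- j2(lm$teardrop_contralateral)
  lm$lateral_rim <- j2(lm$lateral_rim)
  wall_common <- rnorm(2, 0, sd)
  lm$anterior_wall <- sweep(lm$anterior_wall, 2,
                            wall_common + rnorm(2, 0, sd / 4), "+")
  lm$posterior_wall <- sweep(lm$posterior_wall, 2,
                             wall_common + rnorm(2, 0, sd / 4), "+")
  lm$obturator_width_ipsi <- abs(lm$obturator_width_ipsi + rnorm(1, 0, sd / 2))
  lm$obturator_width_contra <- abs(lm$obturator_width_contra + rnorm(1, 0, sd / 2))
  lm
}

#' Generate a synthetic cohort
#'
#' Draws per-subject hip parameters from the group distributions, builds
#' the rim (and optionally the femur mesh), projects noiseless landmarks,
#' and adds per-reader/read landmark jitter.  Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a `cohort_spec`.
#' @param include_mesh build the femur surface mesh per subject (required
#'   for 3D coverage; skip for landmark-only simulations).
#' @return tibble with one row per subject: `subject`, `group`, `params`,
#'   `rim`, `mesh` (or `NULL`), `head_sphere`, `crossover_expected`,
#'   `expected_tc`, `true_version`, and `landmarks` (a tibble of
#'   reader/read/landmark-set rows).
#' @export
generate_cohort <- function(spec, include_mesh = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n_tot <- spec$n_controls + spec$n_patients
  groups <- rep(c("control", "patient"),
                c(spec$n_controls, spec$n_patients))
  rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    g <- groups[i]
    version <- rnorm(1, if (g == "control") spec$control_version_mean
                     else spec$patient_version_mean,
                     if (g == "control") spec$control_version_sd
                     else spec$patient_version_sd)
    depth <- rnorm(1, if (g == "control") spec$control_depth_mean
                   else spec$patient_depth_mean,
                   if (g == "control") spec$control_depth_sd
                   else spec$patient_depth_sd)
    hr <- rnorm(1, spec$head_radius_mean, spec$head_radius_sd)
    tilt <- rnorm(1, 0, spec$tilt_sd)
    rot <- rnorm(1, 0, spec$rotation_sd)
    par_i <- hip_params(head_radius = hr, neck_radius = 0.6 * hr,
                        cup_radius = 1.08 * hr,
                        cup_version = version, cup_depth_angle = depth,
                        mesh_resolution = spec$mesh_resolution)
    rim <- rim_curve(build_rim_points(par_i))
    hs <- list(center = par_i$head_center, radius = par_i$head_radius)
    mesh <- if (include_mesh) build_femur_mesh(par_i) else NULL
    lm0 <- project_to_radiograph(NULL, rim, pelvic_tilt = tilt,
                                 pelvic_rotation = rot, head_sphere = hs)
    reads <- tidyr::expand_grid(reader = seq_len(spec$n_readers),
                                read = seq_len(spec$n_reads))
    reads$landmarks <- lapply(seq_len(nrow(reads)), function(j)
      jitter_landmarks(lm0, spec$reader_noise_sd))
    rows[[i]] <- tibble::tibble(
      subject = i, group = g,
      params = list(par_i), rim = list(rim), mesh = list(mesh),
      head_sphere = list(hs),
      crossover_expected = is.finite(crossover_ratio(lm0)),
      expected_tc = analytic_total_coverage(par_i),
      true_version = version,
      pelvic_tilt = tilt, pelvic_rotation = rot,
      landmarks = list(reads))
  }
  dplyr::bind_rows(rows)
}
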