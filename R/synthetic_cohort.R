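#' Observer perturbation model
#'
#' Parametrises one simulated delineator: a systematic volume bias (signed
#' surface offset in mm, negative = under-contouring), spatially smooth
#' random surface noise, and a small random rigid shift. Defaults for the
#' noise terms (1.5 mm surface noise SD, 0.5 mm shift SD) are chosen to
#' produce Dice/HD95/CV spreads on the scale reported for human observers
#' in nasopharyngeal delineation studies.
#'
#' @param observer_id identifier.
#' @param volume_bias_mm signed systematic surface offset in mm.
#' @param surface_noise_mm SD of the smooth random boundary displacement.
#' @param shift_mm per-axis SD of the random rigid offset.
#' @param seed integer stream seed; the simulation is deterministic given it.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(observer_id, volume_bias_mm = 0,
                           surface_noise_mm = 1.5, shift_mm = 0.5,
                           seed = 1L) {
  if (surface_noise_mm < 0 || shift_mm < 0)
    stop("noise SDs must be nonnegative")
  structure(list(observer_id = observer_id,
                 volume_bias_mm = volume_bias_mm,
                 surface_noise_mm = surface_noise_mm,
                 shift_mm = shift_mm, seed = as.integer(seed)),
            class = "observer_model")
}

#' Conformal dose surrogate model
#'
#' An analytic stand-in for an optimised IMRT dose: full prescription inside
#' each planned target, Gaussian falloff with distance outside it
#' (`rx * exp(-d^2 / (2 sigma^2))`), plus a flat background. It is not a
#' planned dose — it provides the one property the analysis needs: dose
#' conformal to the *planned* target with a finite gradient, so that
#' under-contouring produces cold spots on the gold-standard target.
#'
#' @param prescription_gy named vector of prescriptions per target label
#'   (defaults to the 70/66/60/54 Gy nasopharynx prescription levels for
#'   the PTV hierarchy; only labels present in the planned set are used).
#' @param penumbra_sigma_mm Gaussian falloff scale outside the target (> 0).
#' @param background_gy flat scattered-dose floor.
#' @return An object of class `dose_model`.
#' @export
dose_model <- function(prescription_gy = c(PTVnx = 70, PTVnd = 66,
                                           PTV1 = 60, PTV2 = 54),
                       penumbra_sigma_mm = 3, background_gy = 0) {
  if (any(prescription_gy <= 0)) stop("prescriptions must be positive")
  if (penumbra_sigma_mm <= 0) stop("penumbra sigma must be positive")
  if (background_gy < 0) stop("background dose must be nonnegative")
  structure(list(prescription_gy = prescription_gy,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 background_gy = background_gy),
            class = "dose_model")
}

#' Default phantom grid
#'
#' 128 x 128 x 96 voxels at 1 x 1 x 2.5 mm: in-plane CT-like resolution with
#' the 2.5 mm dose-grid slice scale.
#' @return A [voxel_grid()].
#' @export
default_grid <- function() voxel_grid(c(128L, 128L, 96L), c(1, 1, 2.5))

# On coarse grids a sub-voxel organ can rasterise to nothing; keep at least
# the voxel nearest its centre so every phantom organ exists.
ensure_nonempty <- function(mask, center_mm) {
  if (any(mask$occupancy)) return(mask)
  idx <- pmin(pmax(round((center_mm - mask$grid$origin_mm) /
                           mask$grid$spacing_mm) + 1, 1), mask$grid$shape)
  mask$occupancy[idx[1], idx[2], idx[3]] <- TRUE
  mask
}

ellipsoid_mask <- function(grid, center_mm, semi_mm, label) {
  x <- grid$origin_mm[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing_mm[1]
  y <- grid$origin_mm[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing_mm[2]
  z <- grid$origin_mm[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing_mm[3]
  dx2 <- ((x - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((y - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((z - center_mm[3]) / semi_mm[3])^2
  occ <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  ensure_nonempty(structure_mask(occ, grid, label), center_mm)
}

tube_mask <- function(grid, center_xy_mm, radius_mm, z_range_mm, label) {
  x <- grid$origin_mm[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing_mm[1]
  y <- grid$origin_mm[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing_mm[2]
  z <- grid$origin_mm[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing_mm[3]
  r2 <- outer((x - center_xy_mm[1])^2, (y - center_xy_mm[2])^2, `+`)
  inz <- z >= z_range_mm[1] & z <= z_range_mm[2]
  occ <- outer(r2 <= radius_mm^2, inz, `&`)
  structure_mask(occ, grid, label)
}

#' Gold-standard phantom anatomy
#'
#' A deterministic-given-seed head-and-neck-like anatomy on a regular grid:
#' an ellipsoidal primary target (`GTVnx`, ~30 cc), a tubular serial organ
#' (`SpinalCord`), paired parallel organs (`Parotid_L`/`Parotid_R`,
#' ~20 cc each) and paired small serial organs (`OpticNerve_L`/`_R`,
#' ~0.2 cc — the small-organ scale where observer variability is largest).
#' Organ centres are jittered by up to 2 mm per axis from the seed so
#' different patients differ; the target never overlaps the cord.
#'
#' @param grid a [voxel_grid()]; the default 128 x 128 x 96 at 1 x 1 x 2.5 mm.
#' @param seed integer; the anatomy is a pure function of it.
#' @return A [structure_set()] with `observer_id = "standard"`.
#' @export
make_phantom <- function(grid = default_grid(), seed = 1L) {
  ext <- grid$origin_mm + (grid$shape - 1) * grid$spacing_mm
  if (any(ext - grid$origin_mm < c(100, 100, 180)))
    stop("grid too small for the phantom anatomy (needs >= 100 x 100 x 180 mm)")
  ctr <- (grid$origin_mm + ext) / 2
  with_seed(seed, {
    j <- function() runif(3, -2, 2)
    gtv <- ellipsoid_mask(grid, ctr + c(0, -8, 0) + j(), c(22, 18, 18), "GTVnx")
    cord <- tube_mask(grid, ctr[1:2] + c(0, 38) + runif(2, -1, 1), 4.5,
                      c(grid$origin_mm[3], ext[3]), "SpinalCord")
    par_l <- ellipsoid_mask(grid, ctr + c(-42, 4, 0) + j(), c(14, 17, 17),
                            "Parotid_L")
    par_r <- ellipsoid_mask(grid, ctr + c(42, 4, 0) + j(), c(14, 17, 17),
                            "Parotid_R")
    on_l <- ellipsoid_mask(grid, ctr + c(-15, -22, 52) + j(), c(9, 2.4, 2.4),
                           "OpticNerve_L")
    on_r <- ellipsoid_mask(grid, ctr + c(15, -22, 52) + j(), c(9, 2.4, 2.4),
                           "OpticNerve_R")
    if (any(gtv$occupancy & cord$occupancy))
      stop("phantom target overlaps the spinal cord")
    structure_set(list(gtv, cord, par_l, par_r, on_l, on_r), "standard")
  })
}

# Smooth zero-mean unit-SD Gaussian random field: iid noise on a coarse grid
# (spacing = correlation length), trilinearly upsampled, then standardised.
smooth_noise_field <- function(grid, correlation_mm = 10) {
  cdim <- pmax(2L, as.integer(ceiling((grid$shape - 1) * grid$spacing_mm /
                                        correlation_mm)) + 2L)
  corigin <- grid$origin_mm - correlation_mm
  coarse <- array(rnorm(prod(cdim)), dim = cdim)
  v <- .cv_resample_grid(as.double(coarse), cdim,
                         rep(correlation_mm, 3), corigin,
                         grid$shape, grid$spacing_mm, grid$origin_mm, 0)
  v <- (v - mean(v)) / sd(v)
  array(v, dim = grid$shape)
}

#' Simulate one observer's delineation of a gold-standard set
#'
#' Each mask is perturbed in the signed-distance domain: the signed distance
#' field of the standard structure is rigidly shifted (per-axis normal
#' offsets of SD `shift_mm`), offset by the systematic `volume_bias_mm`,
#' displaced by a spatially smooth noise field (correlation length ~10 mm,
#' SD `surface_noise_mm`), and re-thresholded to a binary mask. This yields
#' anatomically plausible contours rather than per-voxel label flips.
#'
#' Negative (eroding) offsets saturate at half the structure's maximum
#' interior depth: an observer under-contours a thin organ but does not
#' delete it, so a systematic bias larger than a small organ's radius
#' shrinks that organ instead of annihilating it.
#'
#' @param standard a [structure_set()] (the gold standard).
#' @param model an [observer_model()].
#' @param sd_fields optional precomputed signed-distance fields of the
#'   standard masks (named by label), to amortise the distance transforms
#'   across many observers of one anatomy.
#' @return A [structure_set()] with the model's `observer_id`. A
#'   perturbation that annihilates a structure raises an error naming it.
#' @export
simulate_observer <- function(standard, model, sd_fields = NULL) {
  grid <- standard$grid
  masks <- lapply(seq_along(standard$masks), function(i) {
    m <- standard$masks[[i]]
    with_seed(derive_seed(model$seed, i), {
      shift <- rnorm(3, 0, model$shift_mm)
      sd_field <- if (!is.null(sd_fields)) sd_fields[[m$label]]
                  else signed_distance_mm(m)
      if (any(shift != 0)) {
        v <- .cv_resample_grid(as.double(sd_field), grid$shape,
                               grid$spacing_mm, grid$origin_mm,
                               grid$shape, grid$spacing_mm,
                               grid$origin_mm - shift, 1e6)
        sd_field <- array(v, dim = grid$shape)
      }
      offset <- model$volume_bias_mm
      if (model$surface_noise_mm > 0)
        offset <- offset + model$surface_noise_mm * smooth_noise_field(grid)
      # half-voxel surface correction: the continuous boundary lies about
      # half a voxel beyond the last occupied centre, so voxel distances
      # overstate the surface distance by ~h/2 on either side
      h2 <- min(grid$spacing_mm) / 2
      sd_adj <- sd_field + ifelse(sd_field < 0, h2, -h2)
      # erosion floor, from the post-shift field so a core always survives:
      # half the maximum interior depth, or the field minimum itself when
      # interpolation of a very thin structure never dips below zero
      msd <- min(sd_adj)
      floor_mm <- if (msd < 0) 0.5 * msd else msd + 1e-9
      occ <- sd_adj <= pmax(offset, floor_mm)
      if (!any(occ))
        stop("perturbation annihilated structure '", m$label, "'")
      structure_mask(occ, grid, m$label)
    })
  })
  structure_set(masks, model$observer_id)
}

#' Synthesize a conformal dose surrogate for a planned structure set
#'
#' `dose(x) = background + max_t rx_t * exp(-d_t(x)^2 / (2 sigma^2))` where
#' `d_t(x)` is the Euclidean distance from `x` to planned target `t` (zero
#' inside it). By construction the planning observer's own target is fully
#' covered (its PDC is 100%), and coverage of any *other* anatomy — in
#' particular the gold-standard target — degrades with the distance by which
#' the planned target misses it.
#'
#' @param planned_set a [structure_set()] containing every target label of
#'   the model that should be planned (labels of `prescription_gy` absent
#'   from the set are ignored; if none match, an error lists the labels).
#' @param model a [dose_model()].
#' @return A [dose_grid()] on the set's grid.
#' @export
synthesize_dose <- function(planned_set, model) {
  labels <- intersect(names(model$prescription_gy), names(planned_set$masks))
  if (length(labels) == 0)
    stop("planned set contains none of the target labels: ",
         paste(names(model$prescription_gy), collapse = ", "))
  grid <- planned_set$grid
  dose <- array(model$background_gy, dim = grid$shape)
  s2 <- 2 * model$penumbra_sigma_mm^2
  for (lb in labels) {
    d2 <- .cv_edt_sq(as.logical(planned_set$masks[[lb]]$occupancy),
                     grid$shape, grid$spacing_mm)
    field <- model$background_gy +
      model$prescription_gy[[lb]] * exp(-d2 / s2)
    dose <- pmax(dose, array(field, dim = grid$shape))
  }
  dose_grid(dose, grid)
}

#' Generate a synthetic multi-observer cohort
#'
#' Mirrors the study design the pipeline analyses: `n_patients` gold-standard
#' anatomies, each independently delineated by K simulated observers whose
#' systematic biases and noise are fixed across patients; per observer a
#' dose surrogate conformal to that observer's own expanded target, plus the
#' standard plan conformal to the gold-standard target. All randomness
#' derives from the master seed (per-patient and per-observer stream seeds
#' are recorded in the manifest), so regeneration is bit-identical.
#'
#' @param n_patients number of patients (>= 1).
#' @param observers list of >= 2 [observer_model()]s (their `seed` fields
#'   are overridden by the derived per-patient stream seeds).
#' @param dose_mod a [dose_model()].
#' @param seed master integer seed.
#' @param grid phantom grid.
#' @param target_label gold-standard structure expanded into the planning
#'   target.
#' @param margin_mm setup-uncertainty margin applied to the target (GTV ->
#'   PTV expansion; default 3 mm).
#' @param dir if non-NULL, the cohort is also written to disk under
#'   `dir/patient_###/{standard,<observer>}/<label>.nii.gz`, with per-plan
#'   doses `dose_<observer>.nii.gz` and a `manifest.json`.
#' @return An object of class `cohort`: list of patients (each with
#'   `standard`, `ptv_standard`, `dose_standard`, per-observer `sets`,
#'   `ptvs`, `doses`) plus `observers`, `dose_model`, `manifest`.
#' @export
# One patient of the cohort: the gold-standard anatomy, every observer's
# perturbed set, and the conformal dose surrogate for each plan. Stream
# seeds: phantom = derive_seed(seed, p, 0); observer k = derive_seed(seed,
# p, k).
build_patient <- function(p, seed, observers, dose_mod, grid, target_label,
                          margin_mm) {
  obs_ids <- vapply(observers, function(o) o$observer_id, character(1))
  ptv_label <- sub("^GTV", "PTV", target_label)
  plan_target <- function(set) {
    ptv <- expand_margin(set$masks[[target_label]], margin_mm)
    ptv$label <- ptv_label
    ptv
  }
  std <- make_phantom(grid, derive_seed(seed, p, 0))
  sd_fields <- lapply(std$masks, signed_distance_mm)
  ptv_std <- plan_target(std)
  plan_std <- structure_set(c(list(ptv_std), std$masks), "standard")
  dose_std <- synthesize_dose(plan_std, dose_mod)
  sets <- list(); ptvs <- list(); doses <- list()
  for (k in seq_along(observers)) {
    om <- observers[[k]]
    om$seed <- derive_seed(seed, p, k)
    oset <- simulate_observer(std, om, sd_fields = sd_fields)
    optv <- plan_target(oset)
    oplan <- structure_set(c(list(optv), oset$masks), om$observer_id)
    sets[[obs_ids[k]]] <- oset
    ptvs[[obs_ids[k]]] <- optv
    doses[[obs_ids[k]]] <- synthesize_dose(oplan, dose_mod)
  }
  list(patient_id = sprintf("patient_%03d", p), standard = std,
       ptv_standard = ptv_std, dose_standard = dose_std,
       sets = sets, ptvs = ptvs, doses = doses)
}

generate_cohort <- function(n_patients, observers, dose_mod = dose_model(),
                            seed = 1L, grid = default_grid(),
                            target_label = "GTVnx", margin_mm = 3,
                            dir = NULL) {
  if (n_patients < 1) stop("need at least 1 patient")
  if (length(observers) < 2) stop("need at least 2 observers")
  patients <- lapply(seq_len(n_patients), function(p)
    build_patient(p, seed, observers, dose_mod, grid, target_label,
                  margin_mm))
  ptv_label <- sub("^GTV", "PTV", target_label)
  manifest <- list(
    seed = seed, n_patients = n_patients, grid = unclass(grid),
    target_label = target_label, ptv_label = ptv_label,
    margin_mm = margin_mm,
    observers = lapply(seq_along(observers), function(k) {
      om <- observers[[k]]
      c(unclass(om),
        list(patient_seeds = vapply(seq_len(n_patients), function(p)
          derive_seed(seed, p, k), integer(1))))
    }),
    phantom_seeds = vapply(seq_len(n_patients), function(p)
      derive_seed(seed, p, 0), integer(1)),
    dose_model = unclass(dose_mod))
  cohort <- structure(list(patients = patients, observers = observers,
                           dose_model = dose_mod, manifest = manifest),
                      class = "cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort bundle to disk
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pt in cohort$patients) {
    pdir <- file.path(dir, pt$patient_id)
    sdir <- file.path(pdir, "standard")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (m in c(pt$standard$masks, list(pt$ptv_standard)))
      write_mask(m, file.path(sdir, paste0(m$label, ".nii.gz")))
    write_dose(pt$dose_standard, file.path(pdir, "dose_standard.nii.gz"))
    for (oid in names(pt$sets)) {
      odir <- file.path(pdir, oid)
      dir.create(odir, recursive = TRUE, showWarnings = FALSE)
      for (m in c(pt$sets[[oid]]$masks, list(pt$ptvs[[oid]])))
        write_mask(m, file.path(odir, paste0(m$label, ".nii.gz")))
      write_dose(pt$doses[[oid]],
                 file.path(pdir, paste0("dose_", oid, ".nii.gz")))
    }
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
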