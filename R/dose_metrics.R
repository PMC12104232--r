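#' Cumulative dose-volume histogram of a structure
#'
#' The cumulative DVH gives, for each dose level, the fraction of the
#' structure volume receiving at least that dose. The exact per-voxel doses
#' are retained alongside the binned curve so downstream statistics (EUD,
#' D1cc) can avoid bin-width sensitivity.
#'
#' @param dose a [dose_grid()]; resampled (trilinear) to the mask grid if the
#'   geometries differ — structure voxelization defines the integration
#'   domain.
#' @param mask a non-empty [structure_mask()].
#' @param bin_width_gy histogram bin width in Gy (default 0.01).
#' @return An object of class `dvh`: `structure_label`, `dose_edges_gy`,
#'   `cum_volume_frac` (non-increasing from 1 to 0), `total_volume_cc`,
#'   `voxel_doses_gy`.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.01) {
  vox <- structure_doses(dose, mask)
  edges <- seq(0, max(vox, bin_width_gy) + bin_width_gy, by = bin_width_gy)
  n <- length(vox)
  cum <- vapply(edges, function(e) sum(vox >= e) / n, double(1))
  structure(list(structure_label = mask$label, dose_edges_gy = edges,
                 cum_volume_frac = cum, total_volume_cc = volume_cc(mask),
                 voxel_doses_gy = vox),
            class = "dvh")
}

# Per-voxel doses over the occupied voxels, after aligning the dose to the
# mask grid.
structure_doses <- function(dose, mask) {
  if (!any(mask$occupancy)) stop("empty structure mask: ", mask$label)
  dose <- resample_to(dose, mask$grid)
  as.double(dose$dose_gy[mask$occupancy])
}

#' Evaluate a cumulative DVH at given dose levels
#' @param dvh a `dvh` object.
#' @param dose_gy dose level(s) in Gy.
#' @return fraction of the structure volume receiving at least `dose_gy`,
#'   computed from the exact retained voxel doses.
#' @export
dvh_fraction_at <- function(dvh, dose_gy) {
  vapply(dose_gy, function(d) mean(dvh$voxel_doses_gy >= d), double(1))
}

#' Prescription dose coverage of a planning target volume
#'
#' `PDC = 100 x (PTV voxels with dose >= prescription) / (PTV voxels)`.
#' "Receives 100% of the prescribed dose" is read literally as
#' `dose >= prescription` on whole voxels (voxel-centre in/out, no
#' partial-volume weighting), so results are bit-stable.
#'
#' @param dose a [dose_grid()].
#' @param ptv a non-empty [structure_mask()].
#' @param prescription_gy prescribed dose in Gy (> 0).
#' @return coverage percentage in \[0, 100\].
#' @export
pdc <- function(dose, ptv, prescription_gy) {
  if (prescription_gy <= 0) stop("prescription must be positive")
  vox <- structure_doses(dose, ptv)
  100 * mean(vox >= prescription_gy)
}

#' Dose summary of a structure: Dmax, Dmean, D1cc
#'
#' D1cc is the highest dose d such that at least 1 cc of the structure
#' receives >= d, computed from the exactly sorted voxel doses with linear
#' interpolation at the 1 cc boundary (not from a binned DVH). Serial-type
#' organs (spinal cord, brainstem) are summarised by Dmax or D1cc;
#' parallel-type organs (parotid) by Dmean or D1cc.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()].
#' @param organ_class one of `"serial"`, `"parallel"`, `"target"`.
#' @return An object of class `dose_summary` with `structure_label`,
#'   `Dmax_gy`, `Dmean_gy`, `D1cc_gy`, `organ_class`. Structures smaller
#'   than 1 cc report `D1cc = Dmin` with a warning.
#' @export
dose_summary <- function(dose, mask,
                         organ_class = c("serial", "parallel", "target")) {
  organ_class <- match.arg(organ_class)
  vox <- structure_doses(dose, mask)
  vcc <- voxel_volume_mm3(mask$grid) / 1000
  total <- length(vox) * vcc
  srt <- sort(vox, decreasing = TRUE)
  if (total < 1) {
    warning(sprintf("structure '%s' is smaller than 1 cc (%.3f cc); D1cc set to Dmin",
                    mask$label, total))
    d1cc <- min(vox)
  } else {
    cumvol <- seq_along(srt) * vcc
    d1cc <- approx(cumvol, srt, xout = 1, rule = 2)$y
  }
  structure(list(structure_label = mask$label, Dmax_gy = max(vox),
                 Dmean_gy = mean(vox), D1cc_gy = d1cc,
                 organ_class = organ_class),
            class = "dose_summary")
}

#' Relative dose difference versus the gold-standard plan
#'
#' `100 x (dm - ds) / ds` (signed, percent): the magnitude of dose-parameter
#' differences between an observer's plan and the standard plan.
#'
#' @param dm observer-plan dose parameter in Gy.
#' @param ds standard-plan dose parameter in Gy (> 0).
#' @return signed percentage.
#' @export
delta_d_diff <- function(dm, ds) {
  if (ds <= 0) stop("standard dose parameter must be positive")
  100 * (dm - ds) / ds
}

#' Map an observer's dose grid onto the gold-standard structure set
#'
#' Evaluates one observer's planned dose on every gold-standard structure:
#' prescription dose coverage for targets, class-appropriate Dmax/Dmean/D1cc
#' summaries for organs at risk. This is the dosimetric core of the
#' analysis: a plan conformal to the observer's own delineation is judged
#' on the reference anatomy, so under-contouring shows up as cold spots.
#'
#' @param observer_dose a [dose_grid()].
#' @param standard_set a [structure_set()] of gold-standard masks.
#' @param config named list per structure label:
#'   targets `list(class = "target", prescription_gy = <Gy>)`, OARs
#'   `list(class = "serial"|"parallel", summary = "dmax"|"dmean"|"d1cc")`.
#' @param observer_id,patient_id identifiers for the emitted rows.
#' @return data.frame of metric records: one `PDC_pct` row per target, one
#'   summary row per OAR (plus Dmax/Dmean/D1cc detail rows).
#' @export
map_plan_to_standard <- function(observer_dose, standard_set, config,
                                 observer_id = "observer",
                                 patient_id = "patient") {
  rows <- list()
  for (label in names(standard_set$masks)) {
    cfg <- config[[label]]
    if (is.null(cfg)) next
    mask <- standard_set$masks[[label]]
    if (identical(cfg$class, "target")) {
      if (is.null(cfg$prescription_gy))
        stop("missing prescription for target label '", label, "'")
      rows[[length(rows) + 1L]] <-
        metric_record(patient_id, observer_id, label, "PDC_pct",
                      pdc(observer_dose, mask, cfg$prescription_gy))
    } else {
      ds <- dose_summary(observer_dose, mask, cfg$class)
      rows[[length(rows) + 1L]] <-
        metric_record(patient_id, observer_id, label,
                      c("Dmax_gy", "Dmean_gy", "D1cc_gy"),
                      c(ds$Dmax_gy, ds$Dmean_gy, ds$D1cc_gy))
    }
  }
  do.call(rbind, rows)
}

# Which summary metric feeds Delta-D_diff / NTCP for an OAR config entry:
# serial organs default to Dmax, parallel organs to Dmean; "d1cc" selects
# D1cc for either class.
oar_summary_metric <- function(cfg) {
  s <- cfg$summary
  if (is.null(s)) s <- if (identical(cfg$class, "serial")) "dmax" else "dmean"
  switch(s, dmax = "Dmax_gy", dmean = "Dmean_gy", d1cc = "D1cc_gy",
         stop("unknown summary '", s, "'"))
}
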