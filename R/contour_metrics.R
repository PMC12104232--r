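#' Signed volume difference versus the gold standard
#'
#' `delta_v = vm - vs`: positive when the observer over-contours relative to
#' the standard volume, negative when under-contouring.
#'
#' @param vm observer volume in cc (>= 0).
#' @param vs gold-standard volume in cc (>= 0).
#' @return signed difference in cc.
#' @export
delta_v <- function(vm, vs) {
  stopifnot(vm >= 0, vs >= 0)
  vm - vs
}

#' Maximum-to-minimum volume ratio across observers
#'
#' @param volumes numeric vector of >= 2 observer volumes in cc, all > 0.
#' @return `max(volumes) / min(volumes)`, dimensionless, always >= 1.
#' @export
mmr <- function(volumes) {
  if (length(volumes) < 2) stop("mmr needs at least 2 volumes")
  if (any(volumes <= 0)) stop("mmr undefined for non-positive volumes")
  max(volumes) / min(volumes)
}

#' Coefficient of variation of observer volumes
#'
#' Sample standard deviation (n - 1 denominator) over the mean; the
#' small-sample convention appropriate for a handful of observers.
#'
#' @param volumes numeric vector of >= 2 volumes with positive mean.
#' @return dimensionless CV >= 0.
#' @export
cv_volumes <- function(volumes) {
  if (length(volumes) < 2) stop("cv needs at least 2 volumes")
  m <- mean(volumes)
  if (m <= 0) stop("cv undefined for non-positive mean volume")
  sd(volumes) / m
}

#' Dice similarity coefficient between two masks
#'
#' `2|A intersect B| / (|A| + |B|)` by voxel counting on a shared grid.
#'
#' @param a,b [structure_mask()] objects on the same grid.
#' @return DSC in \[0, 1\]. Both masks empty is undefined and raises an error.
#' @export
dsc <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) stop("dsc requires masks on the same grid")
  na <- sum(a$occupancy); nb <- sum(b$occupancy)
  if (na + nb == 0) stop("dsc undefined: both masks are empty")
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

# Boundary voxels: occupied with at least one unoccupied 6-neighbour, or
# occupied and touching the volume edge.
boundary_voxels <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  interior <- array(TRUE, d)
  shift_and <- function(inter, ax, dir) {
    n <- d[ax]
    if (n == 1) return(inter & FALSE)  # singleton axis: all voxels touch edge
    idx_to <- switch(ax, list(2:n, TRUE, TRUE), list(TRUE, 2:n, TRUE),
                     list(TRUE, TRUE, 2:n))
    idx_from <- switch(ax, list(1:(n - 1), TRUE, TRUE),
                       list(TRUE, 1:(n - 1), TRUE),
                       list(TRUE, TRUE, 1:(n - 1)))
    if (dir < 0) { tmp <- idx_to; idx_to <- idx_from; idx_from <- tmp }
    nb <- array(FALSE, d)
    nb <- do.call(`[<-`, c(list(nb), idx_to,
                           list(do.call(`[`, c(list(occ), idx_from)))))
    inter & nb
  }
  for (ax in 1:3) for (dir in c(-1, 1)) interior <- shift_and(interior, ax, dir)
  occ & !interior
}

#' Directed and symmetric 95th-percentile Hausdorff distance
#'
#' Distances are measured between boundary-voxel centres (a voxel is boundary
#' iff occupied with an unoccupied 6-neighbour or touching the volume edge)
#' under anisotropic spacing, via an exact Euclidean distance transform of
#' the opposing boundary. The per-direction value is the 95th percentile of
#' nearest-boundary distances, with linear interpolation between order
#' statistics; `hd95()` reports the symmetric maximum of the two directions.
#'
#' @param a,b non-empty [structure_mask()] objects on the same grid.
#' @param probs percentile in \[0, 1\]; 0.95 gives HD95, 1 the classic
#'   Hausdorff distance.
#' @return `hd95()`: symmetric HD95 in mm, with the two directed values in
#'   attributes `"a_to_b"` and `"b_to_a"`. `hd95_directed()`: the directed
#'   value from `a` to `b`.
#' @export
hd95 <- function(a, b, probs = 0.95) {
  ab <- hd95_directed(a, b, probs)
  ba <- hd95_directed(b, a, probs)
  structure(max(ab, ba), a_to_b = ab, b_to_a = ba)
}

#' @rdname hd95
#' @export
hd95_directed <- function(a, b, probs = 0.95) {
  if (!grids_equal(a$grid, b$grid)) stop("hd95 requires masks on the same grid")
  if (!any(a$occupancy) || !any(b$occupancy))
    stop("hd95 undefined for empty masks")
  bb <- boundary_voxels(b)
  dmap <- distance_mm(structure_mask(bb, b$grid, b$label))
  vals <- dmap[boundary_voxels(a)]
  quantile(vals, probs = probs, type = 7, names = FALSE)
}

#' STAPLE consensus segmentation
#'
#' Simultaneous Truth and Performance Level Estimation: an EM algorithm on
#' the binary performance model. The E-step computes the per-voxel posterior
#' probability of the hidden true label given each observer's sensitivity
#' `p` and specificity `q` and a global foreground prior; the M-step
#' re-estimates `(p, q)` from the posterior weights. The consensus is the
#' voxel set with posterior >= 0.5.
#'
#' @param masks list of >= 2 [structure_mask()] objects on one grid.
#' @param max_iter maximum EM iterations.
#' @param tol convergence: max absolute change in any `p` or `q`.
#' @param prior global foreground prior probability; default is the mean
#'   observer foreground fraction.
#' @param shared if `TRUE`, the "equally reliable observers" model: every
#'   observer is constrained to the same known symmetric performance
#'   `p = q = init` and no performance estimation is done, so the posterior
#'   is a monotone function of the per-voxel vote count — with a uniform
#'   prior the consensus is then exactly the majority vote (ties included
#'   by the `>= 0.5` rule). Default `FALSE` estimates per-observer
#'   performance by EM.
#' @param init initial value for every sensitivity and specificity (and the
#'   fixed performance level in `shared` mode); must exceed 0.5.
#' @return list with `consensus` ([structure_mask()]), `sensitivity`,
#'   `specificity` (per observer, clamped to `[1e-6, 1 - 1e-6]`), `prior`,
#'   `posterior` (voxel array), `iterations`, `converged`.
#' @export
staple <- function(masks, max_iter = 50, tol = 1e-6, prior = NULL,
                   shared = FALSE, init = 0.99) {
  K <- length(masks)
  if (K < 2) stop("staple needs at least 2 observer masks")
  g <- masks[[1]]$grid
  for (m in masks)
    if (!grids_equal(m$grid, g)) stop("staple masks must share one grid")
  D <- vapply(masks, function(m) as.double(m$occupancy),
              double(prod(g$shape)))       # nvox x K
  if (any(colSums(D) == 0))
    warning("an all-empty observer was supplied; its sensitivity is ",
            "undefined and will be clamped")
  if (is.null(prior)) prior <- mean(D)
  eps <- 1e-6
  clamp <- function(x) {
    x[!is.finite(x)] <- eps  # degenerate posterior mass: rate unidentifiable
    pmin(pmax(x, eps), 1 - eps)
  }
  if (shared && init <= 0.5) stop("shared mode needs init > 0.5")
  p <- rep(init, K); q <- rep(init, K)
  converged <- shared
  it <- 0L
  if (!shared) {
    for (it in seq_len(max_iter)) {
      # E-step in log space: posterior odds of true foreground
      la <- log(prior) + D %*% log(p) + (1 - D) %*% log(1 - p)
      lb <- log(1 - prior) + D %*% log(1 - q) + (1 - D) %*% log(q)
      W <- as.vector(1 / (1 + exp(lb - la)))
      # M-step
      sw <- sum(W); swc <- sum(1 - W)
      p_new <- clamp(colSums(D * W) / sw)
      q_new <- clamp(colSums((1 - D) * (1 - W)) / swc)
      delta <- max(abs(p_new - p), abs(q_new - q))
      p <- p_new; q <- q_new
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  # final E-step with converged rates
  la <- log(prior) + D %*% log(p) + (1 - D) %*% log(1 - p)
  lb <- log(1 - prior) + D %*% log(1 - q) + (1 - D) %*% log(q)
  W <- as.vector(1 / (1 + exp(lb - la)))
  consensus <- structure_mask(array(W >= 0.5, dim = g$shape), g,
                              masks[[1]]$label)
  list(consensus = consensus, sensitivity = p, specificity = q,
       prior = prior, posterior = array(W, dim = g$shape),
       iterations = it, converged = converged)
}

## ---- metric records --------------------------------------------------------

metric_units <- c(dV_cc = "cc", MMR = "", CV = "", DSC = "", HD95_mm = "mm",
                  PDC_pct = "%", dPDC_pct = "%", dDdiff_pct = "%",
                  EUD_gy = "Gy", TCP = "", NTCP = "", dTCP = "%",
                  dNTCP = "%", Dmax_gy = "Gy", Dmean_gy = "Gy",
                  D1cc_gy = "Gy")

metric_record <- function(patient_id, observer_id, structure_label,
                          metric_name, value) {
  if (!all(metric_name %in% names(metric_units)))
    stop("unknown metric name(s): ",
         paste(setdiff(metric_name, names(metric_units)), collapse = ", "))
  data.frame(patient_id = patient_id, observer_id = observer_id,
             structure_label = structure_label, metric_name = metric_name,
             value = as.double(value),
             units = unname(metric_units[metric_name]),
             stringsAsFactors = FALSE)
}

#' Per-structure observer-group variability report
#'
#' For one structure delineated by K observers plus a gold-standard
#' reference: per observer the signed volume difference, Dice coefficient
#' and HD95 versus the reference; per group the max-to-min volume ratio and
#' coefficient of variation over the observer volumes (the reference volume
#' is excluded from MMR/CV, mirroring the usual report layout where the
#' standard volume is its own column).
#'
#' @param masks list of >= 2 observer [structure_mask()]s.
#' @param reference the gold-standard [structure_mask()].
#' @param observer_ids character vector, one id per observer mask.
#' @param patient_id patient identifier for the emitted rows.
#' @return data.frame of metric records with `3 K + 2` rows.
#' @export
group_report <- function(masks, reference, observer_ids = NULL,
                         patient_id = "patient") {
  K <- length(masks)
  if (is.null(observer_ids)) observer_ids <- paste0("observer_", seq_len(K))
  vs <- volume_cc(reference)
  # the reference boundary distance map is shared across observers
  ref_bnd <- boundary_voxels(reference)
  ref_dmap <- distance_mm(structure_mask(ref_bnd, reference$grid))
  rows <- lapply(seq_len(K), function(i) {
    m <- masks[[i]]
    obs_bnd <- boundary_voxels(m)
    obs_dmap <- distance_mm(structure_mask(obs_bnd, m$grid))
    to_ref <- quantile(ref_dmap[obs_bnd], 0.95, type = 7, names = FALSE)
    to_obs <- quantile(obs_dmap[ref_bnd], 0.95, type = 7, names = FALSE)
    metric_record(patient_id, observer_ids[i], m$label,
                  c("dV_cc", "DSC", "HD95_mm"),
                  c(delta_v(volume_cc(m), vs), dsc(m, reference),
                    max(to_ref, to_obs)))
  })
  vols <- vapply(masks, volume_cc, double(1))
  rows <- c(rows, list(
    metric_record(patient_id, "group", masks[[1]]$label, c("MMR", "CV"),
                  c(mmr(vols), cv_volumes(vols)))))
  do.call(rbind, rows)
}
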