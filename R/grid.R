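#' Regular 3D voxel lattice
#'
#' The common geometry that masks and dose grids share. Sampling is
#' voxel-centre based with 0-based indices: the physical position of voxel
#' `(i, j, k)` is `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param shape integer triple `(nx, ny, nz)`, each >= 1.
#' @param spacing_mm positive real triple, voxel spacing in mm (anisotropic
#'   spacing, e.g. 1 x 1 x 2.5 mm, is fully supported).
#' @param origin_mm real triple, physical position of voxel (0, 0, 0) in mm.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing_mm <- as.double(spacing_mm)
  origin_mm <- as.double(origin_mm)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be an integer triple with all components >= 1")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be a positive finite triple")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be a finite triple")
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %d x %d x %d, spacing %g x %g x %g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

voxel_volume_mm3 <- function(grid) prod(grid$spacing_mm)

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

#' Binary structure mask on a voxel grid
#'
#' @param occupancy logical (or coercible 0/1) 3D array matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @param label structure name, e.g. `"GTVnx"` or `"Brainstem"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, grid, label = "structure") {
  if (length(occupancy) != prod(grid$shape))
    stop("occupancy dimensions do not match grid shape")
  occ <- array(as.logical(occupancy), dim = grid$shape)
  if (anyNA(occ)) stop("occupancy contains NA")
  structure(list(occupancy = occ, grid = grid, label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s': %d voxels, %.3f cc on ", x$label,
              sum(x$occupancy), volume_cc(x)))
  print(x$grid)
  invisible(x)
}

#' Scalar absorbed-dose grid (Gy)
#'
#' @param dose_gy nonnegative finite numeric 3D array matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose_gy, grid) {
  if (length(dose_gy) != prod(grid$shape))
    stop("dose dimensions do not match grid shape")
  d <- array(as.double(dose_gy), dim = grid$shape)
  if (any(!is.finite(d))) stop("dose contains non-finite values")
  if (any(d < 0)) stop("dose contains negative values")
  structure(list(dose_gy = d, grid = grid), class = "dose_grid")
}

#' Structure set: one observer's masks, all on one grid
#'
#' @param masks list of [structure_mask()]; names default to mask labels.
#' @param observer_id identifier for the delineating observer.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, observer_id = "standard") {
  if (is.null(names(masks)) || any(names(masks) == ""))
    names(masks) <- vapply(masks, function(m) m$label, character(1))
  if (anyDuplicated(names(masks)))
    stop("structure labels must be unique within a set")
  g <- masks[[1]]$grid
  for (m in masks)
    if (!grids_equal(m$grid, g)) stop("all masks in a set must share one grid")
  structure(list(observer_id = observer_id, masks = masks, grid = g),
            class = "structure_set")
}

#' Structure volume in cubic centimetres
#'
#' Occupied-voxel count times the voxel volume (mm^3) / 1000.
#'
#' @param mask a [structure_mask()].
#' @return volume in cc (>= 0; an empty mask gives 0).
#' @export
volume_cc <- function(mask) {
  sum(mask$occupancy) * voxel_volume_mm3(mask$grid) / 1000
}

## ---- NIfTI I/O -------------------------------------------------------------

grid_from_nifti <- function(img) {
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- abs(as.double(pd[seq_len(3)]))
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error")) as.double(xf[1:3, 4]) else c(0, 0, 0)
  list(grid = voxel_grid(dim(arr), spacing, origin), values = arr)
}

nifti_from_grid <- function(values, grid) {
  img <- RNifti::asNifti(array(values, dim = grid$shape))
  RNifti::pixdim(img) <- grid$spacing_mm
  xf <- diag(c(grid$spacing_mm, 1))
  xf[1:3, 4] <- grid$origin_mm
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  img
}

#' Read a binary structure mask from a volumetric image file
#'
#' The file must hold a 3D volume. Values are binarised at half the maximum
#' value (`> 0.5 * max`), so both 0/1 and 0/255 label conventions are read
#' identically. Geometry (shape, spacing, origin) is taken from the header.
#'
#' @param path path to a NIfTI file (`.nii` / `.nii.gz`).
#' @param label structure label; defaults to the file base name.
#' @return A [structure_mask()]. An all-zero volume yields a valid empty mask
#'   with a warning.
#' @export
read_mask <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gv <- grid_from_nifti(RNifti::readNifti(path))
  if (is.null(label))
    label <- sub("\\.nii(\\.gz)?$", "", basename(path))
  mx <- max(gv$values)
  if (mx <= 0) {
    warning("all-zero volume in ", path, ": returning an empty mask")
    occ <- array(FALSE, dim = gv$grid$shape)
  } else {
    occ <- gv$values > 0.5 * mx
  }
  structure_mask(occ, gv$grid, label)
}

#' Write a structure mask as integer 0/1 NIfTI
#' @param mask a [structure_mask()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(nifti_from_grid(as.integer(mask$occupancy), mask$grid),
                     path, datatype = "uint8")
  invisible(path)
}

#' Read a dose grid (float Gy) from a volumetric image file
#' @param path path to a NIfTI file.
#' @return A [dose_grid()].
#' @export
read_dose <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gv <- grid_from_nifti(RNifti::readNifti(path))
  dose_grid(gv$values, gv$grid)
}

#' Write a dose grid as float NIfTI
#' @param dose a [dose_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dose <- function(dose, path) {
  RNifti::writeNifti(nifti_from_grid(dose$dose_gy, dose$grid), path,
                     datatype = "float")
  invisible(path)
}

## ---- resampling & morphology ----------------------------------------------

grid_extent <- function(grid) {
  lo <- grid$origin_mm
  hi <- grid$origin_mm + (grid$shape - 1) * grid$spacing_mm
  rbind(lo, hi)
}

#' Resample a dose grid onto a target geometry (trilinear)
#'
#' Dose is interpolated trilinearly at the target voxel centres; target
#' voxels outside the source extent are set to 0. Masks are deliberately
#' never interpolated this way (binary occupancy under trilinear
#' interpolation would create ambiguous partial volumes).
#'
#' @param dose a [dose_grid()].
#' @param target a [voxel_grid()] with extent overlapping the source.
#' @return A [dose_grid()] on `target`.
#' @export
resample_to <- function(dose, target) {
  if (grids_equal(dose$grid, target)) return(dose)
  es <- grid_extent(dose$grid); et <- grid_extent(target)
  if (any(et[1, ] > es[2, ]) || any(et[2, ] < es[1, ]))
    stop("source and target grids have disjoint physical extents")
  v <- .cv_resample_grid(as.double(dose$dose_gy), dose$grid$shape,
                         dose$grid$spacing_mm, dose$grid$origin_mm,
                         target$shape, target$spacing_mm, target$origin_mm,
                         0)
  dose_grid(array(v, dim = target$shape), target)
}

# Distance (mm) from every voxel centre to the nearest occupied voxel centre,
# exact under anisotropic spacing. Inf everywhere if the mask is empty.
distance_mm <- function(mask) {
  d2 <- .cv_edt_sq(as.logical(mask$occupancy), mask$grid$shape,
                   mask$grid$spacing_mm)
  array(sqrt(d2), dim = mask$grid$shape)
}

# Signed distance: negative inside the structure, positive outside.
signed_distance_mm <- function(mask) {
  dout <- distance_mm(mask)
  din <- distance_mm(structure_mask(!mask$occupancy, mask$grid, mask$label))
  dout[!is.finite(dout)] <- 1e6
  din[!is.finite(din)] <- 1e6
  dout - din
}

#' Expand a structure mask by an isotropic physical margin
#'
#' A voxel is occupied in the result iff the Euclidean distance from its
#' centre to the original occupied set is at most `margin_mm`; the distance
#' respects anisotropic spacing (exact Euclidean distance transform, not a
#' structuring-element dilation). Used to grow GTV/CTV into PTV and OARs
#' into PRV.
#'
#' @param mask a [structure_mask()].
#' @param margin_mm nonnegative margin in mm; 0 returns the mask unchanged.
#' @return A [structure_mask()] with the same label.
#' @export
expand_margin <- function(mask, margin_mm) {
  if (length(margin_mm) != 1L || !is.finite(margin_mm) || margin_mm < 0)
    stop("margin_mm must be a single nonnegative number (erosion is not a margin)")
  if (margin_mm == 0) return(mask)
  d <- distance_mm(mask)
  structure_mask(d <= margin_mm + 1e-9, mask$grid, mask$label)
}
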