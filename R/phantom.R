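# 4D dynamic phantom rendering, VOI/TAC extraction and the image-derived
# input function.

.organ_codes <- c(background = 0L, heart = 1L, liver = 2L,
                  kidney_cortex_l = 3L, kidney_cortex_r = 4L, bladder = 5L)

#' Phantom geometry configuration
#'
#' Describes the voxel grid and the organ shapes of the digital mouse
#' phantom: ellipsoidal heart and liver, half-moon (crescent) renal-cortex
#' shells and a spherical bladder. Centres, semi-axes and radii are in
#' voxel units (0-indexed axes x, y, z with z axial).
#'
#' @param dim integer grid dimensions `c(nx, ny, nz)`.
#' @param voxel_mm voxel size per axis, mm.
#' @param organs named list of shape descriptions; see
#'   [default_phantom_geometry()] for the format.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(dim, voxel_mm, organs) {
  stopifnot(length(dim) == 3L, all(dim >= 4), length(voxel_mm) == 3L,
            all(voxel_mm > 0), is.list(organs), length(organs) >= 1L)
  if (!all(names(organs) %in% setdiff(names(.organ_codes), "background")))
    stop("unknown organ names in geometry", call. = FALSE)
  structure(list(dim = as.integer(dim), voxel_mm = as.numeric(voxel_mm),
                 organs = organs),
            class = "phantom_geometry")
}

#' Default phantom geometry
#'
#' A 64 x 64 x 96 grid at 0.4 mm isotropic voxels (small-animal scanner
#' scale): heart and liver as ellipsoids, kidney cortices as medially
#' opening crescent shells, bladder as a sphere.
#'
#' @param dim grid dimensions, default `c(64, 64, 96)`.
#' @param voxel_mm voxel size, default 0.4 mm isotropic.
#' @return A [phantom_geometry()].
#' @export
default_phantom_geometry <- function(dim = c(64, 64, 96),
                                     voxel_mm = c(0.4, 0.4, 0.4)) {
  s <- dim / c(64, 64, 96)  # proportional rescaling for smaller test grids
  phantom_geometry(dim, voxel_mm, list(
    heart = list(type = "ellipsoid", center = c(32, 32, 75) * s,
                 semi = c(10, 10, 8) * min(s)),
    liver = list(type = "ellipsoid", center = c(32, 34, 52) * s,
                 semi = c(16, 12, 9) * min(s)),
    kidney_cortex_l = list(type = "crescent", center = c(15, 32, 34) * s,
                           r_inner = 5.5 * min(s), r_outer = 8.5 * min(s),
                           open_axis = c(1, 0, 0)),
    kidney_cortex_r = list(type = "crescent", center = c(48, 32, 34) * s,
                           r_inner = 5.5 * min(s), r_outer = 8.5 * min(s),
                           open_axis = c(-1, 0, 0)),
    bladder = list(type = "sphere", center = c(32, 32, 12) * s,
                   r = 6 * min(s))
  ))
}

# logical mask of one organ shape on the grid
.shape_mask <- function(shape, dim) {
  ax <- lapply(dim, function(n) seq_len(n) - 1)
  x <- array(rep(ax[[1L]], times = dim[2L] * dim[3L]), dim)
  y <- array(rep(rep(ax[[2L]], each = dim[1L]), times = dim[3L]), dim)
  z <- array(rep(ax[[3L]], each = dim[1L] * dim[2L]), dim)
  dx <- x - shape$center[1L]; dy <- y - shape$center[2L]
  dz <- z - shape$center[3L]
  switch(shape$type,
    ellipsoid = (dx / shape$semi[1L])^2 + (dy / shape$semi[2L])^2 +
      (dz / shape$semi[3L])^2 <= 1,
    sphere = dx^2 + dy^2 + dz^2 <= shape$r^2,
    crescent = {
      r <- sqrt(dx^2 + dy^2 + dz^2)
      proj <- dx * shape$open_axis[1L] + dy * shape$open_axis[2L] +
        dz * shape$open_axis[3L]
      r >= shape$r_inner & r <= shape$r_outer & proj >= 0
    },
    stop(sprintf("unknown shape type '%s'", shape$type), call. = FALSE))
}

#' Build the 3D organ label map of a geometry
#'
#' @param geometry a [phantom_geometry()].
#' @return integer 3D array with codes 0 = background, 1 = heart,
#'   2 = liver, 3/4 = left/right kidney cortex, 5 = bladder. Overlapping
#'   organs raise an error.
#' @export
make_labels <- function(geometry) {
  if (!inherits(geometry, "phantom_geometry"))
    stop("'geometry' must be a phantom_geometry", call. = FALSE)
  labels <- array(0L, geometry$dim)
  for (organ in names(geometry$organs)) {
    m <- .shape_mask(geometry$organs[[organ]], geometry$dim)
    if (!any(m)) stop(sprintf("organ '%s' contains no voxels", organ), call. = FALSE)
    if (any(labels[m] != 0L))
      stop(sprintf("organ '%s' overlaps another organ", organ), call. = FALSE)
    labels[m] <- .organ_codes[[organ]]
  }
  labels
}

#' Render a 4D dynamic phantom from per-organ TACs
#'
#' Each labelled organ's voxels carry that organ's frame value; background
#' is zero. Optional voxel-level noise reuses the duration-scaled noise
#' model of [add_noise()] independently per voxel (off by default — the
#' TAC-level noise of the cohort generator is the primary regime).
#'
#' @param organ_tacs named list of [tac()]s, names a subset of `heart`,
#'   `liver`, `kidney_cortex_l`, `kidney_cortex_r`, `bladder`; all on one
#'   schedule.
#' @param geometry a [phantom_geometry()].
#' @param noise_scale voxel-level noise magnitude (default 0 = off).
#' @param seed seed for voxel noise.
#' @return An object of class `dynamic_phantom` with fields `voxels`
#'   (4D array x, y, z, frame of kBq/mL), `labels`, `voxel_mm`, `schedule`,
#'   `geometry`.
#' @export
render_phantom <- function(organ_tacs, geometry = default_phantom_geometry(),
                           noise_scale = 0, seed = 1L) {
  if (!is.list(organ_tacs) || is.null(names(organ_tacs)) ||
      !all(vapply(organ_tacs, inherits, logical(1), "tac")))
    stop("'organ_tacs' must be a named list of tac objects", call. = FALSE)
  if (!all(names(organ_tacs) %in% names(geometry$organs)))
    stop("organ_tacs names must match geometry organs", call. = FALSE)
  sch <- organ_tacs[[1L]]$schedule
  for (tt in organ_tacs)
    if (!schedules_equal(tt$schedule, sch))
      stop("all organ TACs must share one schedule", call. = FALSE)
  labels <- make_labels(geometry)
  nvox <- prod(geometry$dim)
  vox <- matrix(0, nvox, sch$count)
  for (organ in names(organ_tacs)) {
    idx <- which(labels == .organ_codes[[organ]])
    vox[idx, ] <- rep(organ_tacs[[organ]]$values, each = length(idx))
  }
  if (noise_scale > 0) {
    dur_min <- sch$duration_s / 60
    vox <- with_seed(seed, {
      sigma <- noise_scale *
        sqrt(pmax(vox, 0.01) / rep(dur_min, each = nvox))
      pmax(vox + stats::rnorm(length(vox), 0, sigma), 0)
    })
  }
  structure(list(voxels = array(vox, c(geometry$dim, sch$count)),
                 labels = labels, voxel_mm = geometry$voxel_mm,
                 schedule = sch, geometry = geometry),
            class = "dynamic_phantom")
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("Dynamic phantom: %s voxels x %d frames, %.3g mm voxels\n",
              paste(dim(x$labels), collapse = " x "), x$schedule$count,
              x$voxel_mm[1L]))
  cat("Organs:", paste(names(x$geometry$organs), collapse = ", "), "\n")
  invisible(x)
}

#' Volume-of-interest mask
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @param label region name.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, label = "voi") {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a logical 3D array", call. = FALSE)
  if (!any(mask)) stop("mask must contain at least one voxel", call. = FALSE)
  structure(list(mask = mask, label = as.character(label)), class = "voi_mask")
}

#' Mask of one labelled organ in a phantom
#'
#' @param phantom a [render_phantom()] result.
#' @param organ organ name.
#' @return A [voi_mask()].
#' @export
organ_mask <- function(phantom, organ) {
  if (!organ %in% names(.organ_codes) || organ == "background")
    stop(sprintf("unknown organ '%s'", organ), call. = FALSE)
  voi_mask(phantom$labels == .organ_codes[[organ]], label = organ)
}

#' Extract a time-activity curve from a phantom
#'
#' Per frame, the arithmetic mean over the masked voxels.
#'
#' @param phantom a [render_phantom()] result.
#' @param voi a [voi_mask()] with dimensions matching the phantom.
#' @return A [tac()] labelled from the mask.
#' @export
extract_tac <- function(phantom, voi) {
  if (!inherits(phantom, "dynamic_phantom"))
    stop("'phantom' must be a dynamic_phantom", call. = FALSE)
  if (!inherits(voi, "voi_mask")) stop("'voi' must be a voi_mask", call. = FALSE)
  if (!identical(dim(voi$mask), dim(phantom$labels)))
    stop("mask dimensions must match the phantom", call. = FALSE)
  nvox <- prod(dim(phantom$labels))
  m <- matrix(phantom$voxels, nvox, phantom$schedule$count)
  vals <- colMeans(m[as.vector(voi$mask), , drop = FALSE])
  tac(phantom$schedule, vals, region_label = voi$label)
}

#' Image-derived input function from the heart region
#'
#' Reproduces the heart-based input-function procedure: (1) average all
#' frames whose full window lies within the first `early_window_s` seconds;
#' (2) rank axial slices by mean early intensity and take the `n_slices`
#' most intense; (3) on each selected slice, centre a filled circle of
#' `circle_diameter_px` pixels on the slice's intensity-weighted centroid
#' (circles clipped at image edges trigger a warning); (4) the union of the
#' circles is the heart VOI, whose [extract_tac()] is returned.
#'
#' @param phantom a [render_phantom()] result.
#' @param circle_diameter_px circle diameter in pixels (default 15).
#' @param n_slices number of axial slices (default 6).
#' @param early_window_s early averaging window, seconds (default 20).
#' @return A [tac()] labelled `"idif"`, with the heart VOI attached as
#'   attribute `voi`.
#' @export
build_idif <- function(phantom, circle_diameter_px = 15, n_slices = 6,
                       early_window_s = 20) {
  if (!inherits(phantom, "dynamic_phantom"))
    stop("'phantom' must be a dynamic_phantom", call. = FALSE)
  .assert_scalar_num(circle_diameter_px, "circle_diameter_px", 0, strict = TRUE)
  .assert_scalar_num(n_slices, "n_slices", 0, strict = TRUE)
  .assert_scalar_num(early_window_s, "early_window_s", 0, strict = TRUE)
  sch <- phantom$schedule
  dims <- dim(phantom$labels)
  if (dims[3L] < n_slices)
    stop("fewer axial slices than n_slices", call. = FALSE)
  early <- which(sch$start_s >= 0 &
                   frame_ends(sch) <= early_window_s + 1e-9)
  if (length(early) == 0L)
    stop("no frame lies fully inside the early window", call. = FALSE)
  # duration-weighted mean of the qualifying frames
  wts <- sch$duration_s[early] / sum(sch$duration_s[early])
  avg <- array(0, dims)
  for (i in seq_along(early))
    avg <- avg + phantom$voxels[, , , early[i]] * wts[i]
  slice_mean <- apply(avg, 3L, mean)
  top <- sort(order(slice_mean, decreasing = TRUE)[seq_len(n_slices)])
  mask <- array(FALSE, dims)
  r <- circle_diameter_px / 2
  xg <- matrix(seq_len(dims[1L]) - 1, dims[1L], dims[2L])
  yg <- matrix(seq_len(dims[2L]) - 1, dims[1L], dims[2L], byrow = TRUE)
  clipped <- FALSE
  for (z in top) {
    sl <- avg[, , z]
    tot <- sum(sl)
    if (tot > 0) {
      cx <- sum(xg * sl) / tot
      cy <- sum(yg * sl) / tot
    } else {
      cx <- (dims[1L] - 1) / 2; cy <- (dims[2L] - 1) / 2
    }
    if (cx - r < 0 || cx + r > dims[1L] - 1 ||
        cy - r < 0 || cy + r > dims[2L] - 1) clipped <- TRUE
    mask[, , z] <- mask[, , z] | ((xg - cx)^2 + (yg - cy)^2 <= r^2)
  }
  if (clipped)
    warning("IDIF circle clipped at the image edge", call. = FALSE)
  voi <- voi_mask(mask, label = "idif")
  out <- extract_tac(phantom, voi)
  attr(out, "voi") <- voi
  attr(out, "slices") <- top
  out
}

#' Write / read a dynamic phantom as NIfTI-1 plus a frame-timing sidecar
#'
#' The 4D volume goes to `<prefix>.nii` (voxel size in the header), the
#' organ label map to `<prefix>_labels.nii`, and the frame timing to
#' `<prefix>_frames.csv` (columns `frame_start_s`, `frame_duration_s`).
#'
#' @param phantom a [render_phantom()] result.
#' @param prefix output path prefix.
#' @return `write_phantom` returns `prefix` invisibly; `read_phantom`
#'   returns a `dynamic_phantom` (geometry not reconstructed).
#' @export
write_phantom <- function(phantom, prefix) {
  img <- RNifti::asNifti(phantom$voxels)
  RNifti::pixdim(img) <- c(phantom$voxel_mm, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii"))
  lab <- RNifti::asNifti(array(as.integer(phantom$labels),
                               dim(phantom$labels)))
  RNifti::pixdim(lab) <- phantom$voxel_mm
  RNifti::writeNifti(lab, paste0(prefix, "_labels.nii"), datatype = "uint8")
  write_frame_schedule(phantom$schedule, paste0(prefix, "_frames.csv"))
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  vox <- as.array(RNifti::readNifti(paste0(prefix, ".nii")))
  lab_img <- RNifti::readNifti(paste0(prefix, "_labels.nii"))
  lab <- array(as.integer(as.array(lab_img)), dim(lab_img))
  sch <- read_frame_schedule(paste0(prefix, "_frames.csv"))
  pd <- RNifti::pixdim(lab_img)
  structure(list(voxels = vox, labels = lab,
                 voxel_mm = as.numeric(pd[seq_len(3L)]),
                 schedule = sch, geometry = NULL),
            class = "dynamic_phantom")
}

#' Write / read a VOI mask as a NIfTI-1 unsigned-int volume
#'
#' @param voi a [voi_mask()].
#' @param path file path (`.nii`).
#' @param label region name attached on read.
#' @return `write_voi` returns `path` invisibly; `read_voi` a [voi_mask()].
#' @export
write_voi <- function(voi, path) {
  img <- RNifti::asNifti(array(as.integer(voi$mask), dim(voi$mask)))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_voi
#' @export
read_voi <- function(path, label = "voi") {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.array(img) > 0, dim(img)), label = label)
}
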