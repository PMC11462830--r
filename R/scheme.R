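#' Convert b-values from s/mm^2 to ms/um^2
#'
#' The package works internally in ms/um^2 (diffusivities in um^2/ms) so that
#' exponents are O(1); acquisition tables in s/mm^2 are converted at the
#' boundary, in this one place only.
#'
#' @param b numeric b-values in s/mm^2
#' @return b-values in ms/um^2
#' @export
b_si_to_internal <- function(b) b / 1000

#' Build a multi-shell gradient scheme
#'
#' Groups measurements into shells by clustering b-values within a tolerance,
#' flags b0 measurements, and renormalizes nonzero-shell directions to unit
#' length. B-tensor shape `beta` is 1 (linear tensor encoding) for every
#' measurement; the acquisition this package targets uses no other encoding.
#'
#' @param bvals numeric vector of b-values, in s/mm^2 by default
#' @param bvecs N x 3 matrix of gradient directions (rows may be unnormalized;
#'   b0 rows may be zero)
#' @param shell_tolerance clustering tolerance in the same units as `bvals`
#' @param units either "s/mm2" or "ms/um2"
#' @return object of class `dwi_scheme`: data frame-like list with `bval`
#'   (ms/um^2), `bvec`, `shell_id`, `b0`, `beta`, plus shell table
#' @export
build_scheme <- function(bvals, bvecs, shell_tolerance = 50, units = c("s/mm2", "ms/um2")) {
  units <- match.arg(units)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  if (length(bvals) != nrow(bvecs)) {
    stop("bvals and bvecs describe different numbers of measurements")
  }
  if (any(bvals < 0)) stop("negative b-values")
  if (units == "s/mm2") {
    b <- b_si_to_internal(bvals)
    tol <- b_si_to_internal(shell_tolerance)
  } else {
    b <- bvals
    tol <- shell_tolerance
  }

  # 1-d clustering: walk sorted b-values, open a new shell when the gap to the
  # running centroid exceeds the tolerance
  ord <- order(b)
  shell_of <- integer(length(b))
  centers <- numeric(0)
  cur_sum <- 0; cur_n <- 0
  for (i in ord) {
    if (cur_n == 0 || abs(b[i] - cur_sum / cur_n) > tol) {
      centers <- c(centers, b[i])
      cur_sum <- b[i]; cur_n <- 1
    } else {
      cur_sum <- cur_sum + b[i]; cur_n <- cur_n + 1
    }
    shell_of[i] <- length(centers)
  }
  centers <- vapply(seq_along(centers), function(k) mean(b[shell_of == k]), 0)
  b0 <- centers[shell_of] <= tol

  nrm <- sqrt(rowSums(bvecs^2))
  if (any(!b0 & nrm < 1e-12)) stop("zero-norm direction on a nonzero shell")
  bvecs[!b0, ] <- bvecs[!b0, , drop = FALSE] / nrm[!b0]
  bvecs[b0 & nrm < 1e-12, ] <- 0

  structure(list(
    bval = b, bvec = bvecs, shell_id = shell_of, b0 = b0,
    beta = rep(1, length(b)),
    shells = data.frame(
      shell_id = seq_along(centers), b = centers,
      n = as.integer(table(factor(shell_of, levels = seq_along(centers))))
    )
  ), class = "dwi_scheme")
}

#' @export
print.dwi_scheme <- function(x, ...) {
  cat("Diffusion gradient scheme:", length(x$bval), "measurements\n")
  sh <- x$shells
  for (i in seq_len(nrow(sh))) {
    cat(sprintf("  shell %d: b = %.4g ms/um^2 (%d dirs)\n", sh$shell_id[i], sh$b[i], sh$n[i]))
  }
  invisible(x)
}

#' @export
length.dwi_scheme <- function(x) length(x$bval)

#' The acquisition protocol used throughout this package
#'
#' Two-shell scheme with b = 0, 1250, 2500 s/mm^2 and 25 near-uniform
#' directions per nonzero shell (51 measurements), matching a clinical DKI
#' protocol.
#'
#' @param n_dirs directions per nonzero shell
#' @return a `dwi_scheme`
#' @export
study_scheme <- function(n_dirs = 25L) {
  dirs <- fibonacci_sphere(n_dirs, hemisphere = TRUE)
  bvals <- c(0, rep(1250, n_dirs), rep(2500, n_dirs))
  bvecs <- rbind(c(0, 0, 0), dirs, dirs)
  build_scheme(bvals, bvecs)
}

#' Read / write FSL-dialect gradient tables
#'
#' `bval` files hold one row of b-values (s/mm^2); `bvec` files hold three rows
#' (x, y, z components, image space, no reorientation applied).
#'
#' @param bval_path,bvec_path file paths
#' @param shell_tolerance passed to [build_scheme()]
#' @return a `dwi_scheme`
#' @export
read_scheme <- function(bval_path, bvec_path, shell_tolerance = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3) stop("bvec file must have 3 rows")
  build_scheme(bvals, t(bv), shell_tolerance = shell_tolerance)
}

#' @rdname read_scheme
#' @param scheme a `dwi_scheme`
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  cat(paste(format(scheme$bval * 1000, trim = TRUE), collapse = " "), "\n",
      file = bval_path, sep = "")
  bv <- t(scheme$bvec)
  utils::write.table(format(bv, digits = 17, trim = TRUE), bvec_path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Load a 4D diffusion-weighted dataset
#'
#' @param image_path NIfTI volume (4th dimension = measurements)
#' @param bval_path,bvec_path FSL gradient tables
#' @return object of class `dwi_dataset`: `signal` (4D array), `scheme`,
#'   `voxel_size` (mm), `affine`
#' @export
load_dwi <- function(image_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(image_path)
  scheme <- read_scheme(bval_path, bvec_path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4) stop("expected a 4D image")
  if (dim(arr)[4] != length(scheme)) {
    stop(sprintf("image has %d volumes but gradient table has %d entries",
                 dim(arr)[4], length(scheme)))
  }
  vs <- RNifti::pixdim(img)[1:3]
  structure(list(signal = arr, scheme = scheme, voxel_size = vs,
                 affine = RNifti::xform(img)),
            class = "dwi_dataset")
}

#' Write a 4D diffusion-weighted dataset with its gradient tables
#'
#' @param dataset a `dwi_dataset`
#' @param image_path,bval_path,bvec_path output paths
#' @export
write_dwi <- function(dataset, image_path, bval_path, bvec_path) {
  img <- RNifti::asNifti(dataset$signal)
  img <- RNifti::`pixdim<-`(img, c(dataset$voxel_size, 1))
  RNifti::writeNifti(img, image_path)
  write_scheme(dataset$scheme, bval_path, bvec_path)
  invisible(NULL)
}

#' Place circular in-plane ROIs of a given physical diameter
#'
#' ROIs are rasterized disks in the axial plane: a voxel belongs to the ROI if
#' its center lies within diameter/2 of the ROI center, in mm.
#'
#' @param mask_shape integer triple, volume dimensions
#' @param centers matrix (n x 3) of voxel-index centers (1-based)
#' @param diameter_mm physical ROI diameter
#' @param voxel_size mm triple
#' @param reference_center optional center for a contralateral reference ROI
#' @return object of class `roi_set`: list of logical 3D masks `tumor_rois`,
#'   optional `reference_roi`, and `diameter_mm`
#' @export
place_circular_rois <- function(mask_shape, centers, diameter_mm = 6,
                                voxel_size = c(1.875, 1.875, 3),
                                reference_center = NULL) {
  centers <- matrix(centers, ncol = 3)
  make_disk <- function(ctr) {
    if (any(ctr < 1) || any(ctr > mask_shape)) stop("ROI center out of bounds")
    m <- array(FALSE, dim = mask_shape)
    r <- diameter_mm / 2
    ri <- max(0, ceiling(r / voxel_size[1]))
    rj <- max(0, ceiling(r / voxel_size[2]))
    ii <- max(1, ctr[1] - ri):min(mask_shape[1], ctr[1] + ri)
    jj <- max(1, ctr[2] - rj):min(mask_shape[2], ctr[2] + rj)
    for (i in ii) for (j in jj) {
      d2 <- ((i - ctr[1]) * voxel_size[1])^2 + ((j - ctr[2]) * voxel_size[2])^2
      if (d2 <= r^2) m[i, j, ctr[3]] <- TRUE
    }
    if (!any(m)) m[ctr[1], ctr[2], ctr[3]] <- TRUE  # sub-voxel diameter
    m
  }
  rois <- apply(centers, 1, make_disk, simplify = FALSE)
  ref <- if (!is.null(reference_center)) make_disk(as.numeric(reference_center)) else NULL
  if (!is.null(ref)) {
    for (m in rois) {
      if (any(m & ref)) stop("tumor ROI overlaps the reference ROI")
    }
  }
  structure(list(tumor_rois = rois, reference_roi = ref, diameter_mm = diameter_mm),
            class = "roi_set")
}
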