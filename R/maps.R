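#' Fit all microstructure models voxel-wise over a mask
#'
#' Runs the seven reconstructions (DTI, DKI + AWF, Watson-NODDI,
#' Bingham-NODDI, SMI, CSD + AFD) on every voxel of `mask` and returns named
#' parameter maps for all 21 derived metrics. The CSD response is estimated
#' from the dataset itself (voxels above `fa_threshold`, falling back to the
#' top-FA voxel when none passes).
#'
#' @param dataset a `dwi_dataset`
#' @param mask logical 3D array (default: all voxels)
#' @param models character subset of c("dti","dki","noddi","bingham","smi","afd")
#' @param fa_threshold response-selection threshold for CSD
#' @param smi_seed seed for the SMI estimator training
#' @return named list of 3D arrays (class `parameter_maps`)
#' @export
fit_parameter_maps <- function(dataset, mask = NULL,
                               models = c("dti", "dki", "noddi", "bingham", "smi", "afd"),
                               fa_threshold = 0.5, smi_seed = 20260919L) {
  dims <- dim(dataset$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(mask, arr.ind = TRUE)
  scheme <- dataset$scheme
  sig_at <- function(r) dataset$signal[r[1], r[2], r[3], ]

  metric_names <- c(
    dti = list(c("FA", "MD", "AD", "RD")),
    dki = list(c("AK", "MK", "RK", "AWF")),
    noddi = list(c("ICVF", "ODI")),
    bingham = list(c("Bin_ICVF", "Bin_ODI", "DAI")),
    smi = list(c("Da", "De_par", "De_perp", "f", "fw")),
    afd = list(c("AFD_max", "AFD_sum", "AFD_total"))
  )
  maps <- list()
  for (m in unlist(metric_names[models])) maps[[m]] <- array(NA_real_, dims)

  response <- NULL
  if ("afd" %in% models) {
    sm <- t(apply(idx, 1, sig_at))
    response <- tryCatch(
      estimate_response(sm, scheme, fa_threshold = fa_threshold),
      error = function(e) {
        fa <- apply(sm, 1, function(s) dti_metrics(fit_dti(s, scheme))$FA)
        estimate_response(sm[which.max(fa), , drop = FALSE], scheme,
                          fa_threshold = 0)
      })
  }
  smi_est <- if ("smi" %in% models) {
    train_smi_estimator(scheme$shells$b[scheme$shells$b > 1e-9], seed = smi_seed)
  } else NULL

  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    s <- sig_at(v)
    set_map <- function(nm, val) maps[[nm]][v[1], v[2], v[3]] <<- val
    if ("dti" %in% models) {
      dm <- dti_metrics(fit_dti(s, scheme))
      for (nm in names(dm)) set_map(nm, dm[[nm]])
    }
    watson <- NULL
    if ("dki" %in% models) {
      kf <- fit_dki(s, scheme)
      km <- dki_metrics(kf)
      set_map("AK", km$AK); set_map("MK", km$MK); set_map("RK", km$RK)
      set_map("AWF", as.numeric(awf_from_kurtosis(kf)))
    }
    if ("noddi" %in% models) {
      watson <- fit_noddi_watson(s, scheme)
      set_map("ICVF", watson$Vic); set_map("ODI", watson$ODI)
    }
    if ("bingham" %in% models) {
      bf <- fit_noddi_bingham(s, scheme, watson = watson)
      set_map("Bin_ICVF", bf$Vic); set_map("Bin_ODI", bf$Bin_ODI)
      set_map("DAI", bf$DAI)
    }
    if ("smi" %in% models) {
      sf <- fit_smi(decompose_invariants(s, scheme), estimator = smi_est)
      for (nm in c("Da", "De_par", "De_perp", "f", "fw")) set_map(nm, sf[[nm]])
    }
    if ("afd" %in% models) {
      am <- afd_metrics(csd_fit(s, scheme, response))
      set_map("AFD_max", am$afd_max); set_map("AFD_sum", am$afd_sum)
      set_map("AFD_total", am$afd_total)
    }
  }
  structure(maps, class = "parameter_maps", voxel_size = dataset$voxel_size)
}

#' Write parameter maps as NIfTI volumes
#'
#' @param maps a `parameter_maps` (named list of 3D arrays)
#' @param dir output directory (created if needed)
#' @param voxel_size mm triple (defaults to the maps' attribute)
#' @return invisibly, the written paths
#' @export
write_parameter_maps <- function(maps, dir, voxel_size = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(voxel_size)) voxel_size <- attr(maps, "voxel_size")
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  paths <- vapply(names(maps), function(nm) {
    img <- RNifti::asNifti(maps[[nm]])
    img <- RNifti::`pixdim<-`(img, voxel_size)
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    p
  }, "")
  invisible(paths)
}
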