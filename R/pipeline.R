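#' Run the full vessel-extraction pipeline
#'
#' Chains denoising, unsharp masking, CLAHE, polarity inversion (dark
#' vessels are inverted so the vesselness filter and the tracker's gray
#' maxima are well defined), multiscale vesselness, Chan-Vese
#' segmentation of the enhanced image, ridge detection with the
#' scattered-point prefilter, random seed selection and adaptive
#' tracking.
#'
#' @param img numeric matrix in [0, 255] (see [readGrayImage()]).
#' @param config a [pipelineConfig()] list.
#' @return list with `preprocessed`, `enhanced`, `vmap`
#'   (a [VesselnessMap-class]), `mask`, `contours`, `ridges`, `seed`
#'   (one-row data.frame) and `skeleton` (a [Skeleton-class]).
#' @examples
#' \donttest{
#' ph <- renderPhantom(yTreePhantom())
#' res <- runPipeline(ph$image, pipelineConfig(vessel_polarity = "bright",
#'                                             denoise_enabled = FALSE,
#'                                             um_enabled = FALSE,
#'                                             clahe_enabled = FALSE))
#' centerlineError(res$skeleton, ph$truth)
#' }
#' @export
runPipeline <- function(img, config = pipelineConfig()) {
  .assertGrayImage(img)
  work <- img
  if (isTRUE(config$denoise_enabled) && config$denoise_sigma > 0) {
    work <- denoiseImage(work, config$denoise_sigma,
                         config$denoise_block_size,
                         config$denoise_search_window,
                         config$denoise_max_group)
    .logStage("denoise", sprintf("sigma=%g range=[%.1f,%.1f]",
                                 config$denoise_sigma, min(work), max(work)))
  }
  if (isTRUE(config$um_enabled)) {
    work <- unsharpMask(work, config$um_k, config$um_kernel_size)
    .logStage("unsharp", sprintf("k=%g kernel=%d range=[%.1f,%.1f]",
                                 config$um_k, config$um_kernel_size,
                                 min(work), max(work)))
  }
  if (isTRUE(config$clahe_enabled)) {
    work <- clahe(work, config$clahe_clip_limit, config$clahe_tile_rows,
                  config$clahe_tile_cols, config$clahe_n_bins)
    .logStage("clahe", sprintf("clip=%g tiles=%dx%d range=[%.1f,%.1f]",
                               config$clahe_clip_limit,
                               config$clahe_tile_rows,
                               config$clahe_tile_cols, min(work), max(work)))
  }
  pre <- work
  vin <- if (config$vessel_polarity == "dark") 255 - pre else pre
  vmap <- vesselnessMultiscale(vin, beta = config$vesselness_beta,
                               c = config$vesselness_c,
                               m = config$vesselness_m,
                               sigma_min = config$vesselness_sigma_min,
                               sigma_max = config$vesselness_sigma_max,
                               n_scales = config$vesselness_n_scales,
                               gamma_norm = config$vesselness_gamma)
  .logStage("vesselness", sprintf("scales=%d polarity=%s max_raw=%.4f",
                                  config$vesselness_n_scales,
                                  config$vessel_polarity, max(vmap@raw)))
  seg <- segmentVessels(responseMap(vmap), init = config$cv_init,
                        u = config$cv_u, v = config$cv_v,
                        lambda0 = config$cv_lambda0,
                        lambdab = config$cv_lambdab,
                        epsilon = config$cv_epsilon, dt = config$cv_dt,
                        max_iter = config$cv_max_iter, tol = config$cv_tol,
                        reinit_every = config$cv_reinit_every,
                        period = config$cv_checker_period,
                        radius = config$cv_circle_radius)
  ridges <- detectRidgePoints(vmap, config$ridge_gray_threshold)
  ridges <- filterScatteredRidges(ridges, config$ridge_tau_R,
                                  config$ridge_radius_R)
  .logStage("ridges", sprintf("kept=%d", nrow(ridges)))
  seed <- .selectWorkingSeed(responseMap(vmap), ridges, config)
  skel <- trackVessels(responseMap(vmap), seg$mask, ridges, seed, config)
  list(preprocessed = pre, enhanced = responseMap(vmap), vmap = vmap,
       mask = seg$mask, contours = seg$contours, ridges = ridges,
       seed = seed, skeleton = skel)
}
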