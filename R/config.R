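#' Pipeline configuration with defaults
#'
#' Builds the flat named list of parameters driving every pipeline stage.
#' Every key has a default, so an empty configuration file is valid.
#' Defaults for the tracker and the vesselness filter follow the reference
#' operating point for coronary angiograms: beta = 0.5, c = 20, scales
#' sigma = 1..10; step radius d = 5 px, forward half-angle 45 deg, fan ring
#' (r1, r2) = (7, 12) px with half-angle 135 deg, intensity floor I0 = 10,
#' angle gaps tau1 = 45 deg, tau2 = 30 deg, loop guard tau_P = 4,
#' bifurcation cap tau_B = 2, ridge prefilter tau_R = 3.
#'
#' @param ... named overrides of any default (unknown names are an error).
#' @return named list of class `coroConfig`.
#' @examples
#' cfg <- pipelineConfig(track_d = 4, rng_seed = 7)
#' cfg$track_d
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    vessel_polarity = "dark",       # dark vessels on bright background
    rng_seed = 1L,
    # -- denoise (collaborative block filter) --
    denoise_enabled = TRUE,
    denoise_sigma = 10,             # assumed additive-noise std, [0,255] scale
    denoise_block_size = 8L,
    denoise_search_window = 16L,
    denoise_max_group = 8L,
    # -- unsharp masking --
    um_enabled = TRUE,
    um_k = 1.5,                     # enlarge coefficient
    um_kernel_size = 9L,            # mean-filter size, odd
    # -- CLAHE --
    clahe_enabled = TRUE,
    clahe_clip_limit = 2.5,         # multiple of the uniform bin height
    clahe_tile_rows = 8L,
    clahe_tile_cols = 8L,
    clahe_n_bins = 256L,
    # -- multiscale vesselness --
    vesselness_beta = 0.5,
    vesselness_c = 20,
    vesselness_m = 0,
    vesselness_sigma_min = 1,
    vesselness_sigma_max = 10,
    vesselness_n_scales = 10L,
    vesselness_gamma = 2,           # scale-normalization exponent
    # -- Chan-Vese --
    cv_u = 0.2 * 255^2,             # length weight
    cv_v = 0,                       # area weight
    cv_lambda0 = 1,                 # outside fit weight
    cv_lambdab = 1,                 # inside fit weight
    cv_epsilon = 1.5,               # Heaviside regularization width, px
    cv_dt = 0.5,
    cv_max_iter = 500L,
    cv_tol = 1e-5,
    cv_reinit_every = 50L,
    cv_init = "circle",             # or "checkerboard"
    cv_checker_period = 16,
    cv_circle_radius = 5,
    # -- ridge detection --
    ridge_gray_threshold = 10,      # screening floor on the enhanced image
    ridge_tau_R = 3L,               # scattered-point prefilter count
    ridge_radius_R = 3.0,           # prefilter neighborhood radius, px
    # -- tracking --
    track_d = 5,                    # step / arc-search radius, px
    track_delta_theta = 45,         # forward arc half-angle, deg
    track_I0 = 10,                  # intensity floor
    track_tau_P = 4L,               # loop-guard count
    track_r1 = 7, track_r2 = 12,    # fan-ring radii, px
    track_delta_theta_prime = 135,  # fan-ring half-angle, deg
    track_tau1 = 45, track_tau2 = 30, # branch angle gaps, deg
    track_tau_B = 2L,               # bifurcation duplication cap
    track_arc_step_deg = 1,
    track_np_radius = 5,            # loop-guard radius (= d)
    track_nb_radius = 12,           # bifurcation-dedup radius (= r2)
    track_max_ray = 20,             # center-adjust ray cap, px
    track_max_shift = 2,            # center-adjust displacement cap, px
    track_max_points = 5000L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad) || is.null(names(ov)) || any(names(ov) == ""))
      stop("unknown config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(ov)] <- ov
  }
  cfg <- .validateConfig(cfg)
  class(cfg) <- c("coroConfig", "list")
  cfg
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$vessel_polarity %in% c("dark", "bright"))
  ang <- c(cfg$track_delta_theta, cfg$track_tau1, cfg$track_tau2,
           cfg$track_arc_step_deg)
  if (any(ang <= 0) || any(ang > 180))
    stop("angle parameters must be in (0, 180] degrees", call. = FALSE)
  if (cfg$track_delta_theta >= 90)
    stop("track_delta_theta must be in (0, 90)", call. = FALSE)
  if (cfg$track_delta_theta_prime <= 0 || cfg$track_delta_theta_prime > 180)
    stop("track_delta_theta_prime must be in (0, 180]", call. = FALSE)
  pos <- c(cfg$track_d, cfg$track_r1, cfg$track_r2, cfg$ridge_radius_R,
           cfg$track_np_radius, cfg$track_nb_radius, cfg$track_max_ray,
           cfg$vesselness_beta, cfg$vesselness_c, cfg$cv_epsilon, cfg$cv_dt,
           cfg$cv_lambda0, cfg$cv_lambdab)
  if (any(pos <= 0))
    stop("radii, thresholds and weights must be strictly positive",
         call. = FALSE)
  if (cfg$track_r2 <= cfg$track_r1)
    stop("track_r2 must exceed track_r1", call. = FALSE)
  if (cfg$vesselness_sigma_min > cfg$vesselness_sigma_max)
    stop("vesselness_sigma_min must not exceed sigma_max", call. = FALSE)
  if (cfg$um_kernel_size %% 2 == 0 || cfg$um_kernel_size < 3)
    stop("um_kernel_size must be odd and >= 3", call. = FALSE)
  if (cfg$clahe_n_bins < 2 || cfg$clahe_tile_rows < 1 ||
      cfg$clahe_tile_cols < 1)
    stop("invalid CLAHE tiling", call. = FALSE)
  if (cfg$clahe_clip_limit < 1)
    stop("clahe_clip_limit is a multiple of the uniform bin height, >= 1",
         call. = FALSE)
  if (cfg$denoise_block_size > cfg$denoise_search_window)
    stop("denoise_block_size must not exceed denoise_search_window",
         call. = FALSE)
  cfg
}

#' Read a configuration file
#'
#' Reads a flat key-value YAML file and merges it over [pipelineConfig()]
#' defaults. An empty or missing-key file is valid.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a `coroConfig` list.
#' @export
readPipelineConfig <- function(path = NULL) {
  if (is.null(path)) return(pipelineConfig())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipelineConfig, vals)
}
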