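#' Simulation configuration for synthetic macroarrays
#'
#' Bundles all parameters of the synthetic-data generator: array geometry
#' (subgrid arrangement, spot pitch and radius), image appearance
#' (background level, gradient, noise, global rotation) and the serum-group
#' structure (group sizes, fraction of differentially reactive antigens,
#' effect size). Intensities live on the 8-bit grey scale, 0--255.
#'
#' The geometry must provide at least `2 * n_antigens` spot positions,
#' because every antigen is spotted in duplicate. Spot positions are
#' enumerated row-major across subgrids and antigen `i` occupies positions
#' `2i - 1` and `2i`, so duplicates sit in adjacent target areas.
#'
#' @param n_antigens Number of distinct antigens on the array.
#' @param n_subgrid_rows,n_subgrid_cols Arrangement of subgrids on the array.
#' @param spots_per_subgrid Spot target areas per subgrid. Internally laid
#'   out on a near-square cell grid.
#' @param spot_pitch Side length in pixels of one square spot target area.
#' @param spot_radius Radius in pixels of the rendered spot disc; must be
#'   smaller than `spot_pitch / 2` so discs stay inside their target area.
#' @param margin Blank border in pixels around the spotted area of the
#'   rendered image (virtually cut away during quantification).
#' @param background_level Membrane background intensity (0--255). Spots are
#'   dark, i.e. rendered *below* this level.
#' @param background_gradient Linear intensity drift per pixel along the
#'   image width, emulating uneven illumination.
#' @param noise_sd Standard deviation of additive Gaussian pixel/intensity
#'   noise on the 0--255 scale.
#' @param rotation_deg Global rotation applied to rendered images, degrees;
#'   small angles (|angle| <= 2 is typical for scanner misalignment).
#' @param n_group1,n_group2 Number of sera per serum group.
#' @param frac_informative Fraction of antigens given a group-1 reactivity
#'   shift (`effect_size`).
#' @param effect_size Mean intensity shift (0--255 scale) added to
#'   informative antigens in group-1 sera.
#' @param baseline_mean_depth Mean of the exponential distribution of
#'   per-antigen baseline spot depths (most antigens weakly reactive, few
#'   strong).
#' @param scale_sd Standard deviation, on the log scale, of the per-serum
#'   multiplicative array effect (log-normal) that quantile normalization
#'   is expected to remove.
#' @param seed Integer seed controlling all randomness of the generator.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_antigens = 60, n_subgrid_rows = 2, n_subgrid_cols = 3,
#'                   spots_per_subgrid = 40)
#' cfg$n_antigens
#' @export
sim_config <- function(n_antigens = 1827,
                       n_subgrid_rows = 8,
                       n_subgrid_cols = 12,
                       spots_per_subgrid = 40,
                       spot_pitch = 12,
                       spot_radius = 3,
                       margin = 24,
                       background_level = 200,
                       background_gradient = 0,
                       noise_sd = 5,
                       rotation_deg = 0,
                       n_group1 = 20,
                       n_group2 = 20,
                       frac_informative = 0.1,
                       effect_size = 30,
                       baseline_mean_depth = 20,
                       scale_sd = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_antigens = as.integer(n_antigens),
    n_subgrid_rows = as.integer(n_subgrid_rows),
    n_subgrid_cols = as.integer(n_subgrid_cols),
    spots_per_subgrid = as.integer(spots_per_subgrid),
    spot_pitch = as.integer(spot_pitch),
    spot_radius = spot_radius,
    margin = as.integer(margin),
    background_level = background_level,
    background_gradient = background_gradient,
    noise_sd = noise_sd,
    rotation_deg = rotation_deg,
    n_group1 = as.integer(n_group1),
    n_group2 = as.integer(n_group2),
    frac_informative = frac_informative,
    effect_size = effect_size,
    baseline_mean_depth = baseline_mean_depth,
    scale_sd = scale_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_antigens >= 1, cfg$n_subgrid_rows >= 1, cfg$n_subgrid_cols >= 1,
    cfg$spots_per_subgrid >= 1, cfg$spot_pitch >= 2,
    cfg$margin >= 0, cfg$noise_sd >= 0, cfg$scale_sd >= 0,
    cfg$frac_informative >= 0, cfg$frac_informative <= 1,
    cfg$baseline_mean_depth >= 0
  )
  if (cfg$spot_radius >= cfg$spot_pitch / 2) {
    stop("'spot_radius' must be smaller than spot_pitch/2 so spots fit ",
         "their target areas", call. = FALSE)
  }
  for (p in c("background_level", "effect_size")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 255) {
      stop("'", p, "' must lie in [0, 255]", call. = FALSE)
    }
  }
  capacity <- subgrid_capacity(cfg)
  if (capacity < 2L * cfg$n_antigens) {
    stop("geometry infeasible: ", cfg$n_antigens, " antigens need ",
         2L * cfg$n_antigens, " spot positions (duplicates) but the grid ",
         "provides only ", capacity, call. = FALSE)
  }
  invisible(cfg)
}

subgrid_capacity <- function(cfg) {
  cfg$n_subgrid_rows * cfg$n_subgrid_cols * cfg$spots_per_subgrid
}

#' @export
print.sim_config <- function(x, ...) {
  cap <- subgrid_capacity(x)
  cat("Synthetic macroarray configuration\n")
  cat(sprintf("  %d antigens in duplicate on %d x %d subgrids (%d spots each, %d positions)\n",
              x$n_antigens, x$n_subgrid_rows, x$n_subgrid_cols,
              x$spots_per_subgrid, cap))
  cat(sprintf("  spot pitch %d px, radius %.1f px, margin %d px\n",
              x$spot_pitch, x$spot_radius, x$margin))
  cat(sprintf("  background %g, gradient %g/px, noise sd %g, rotation %g deg\n",
              x$background_level, x$background_gradient, x$noise_sd,
              x$rotation_deg))
  cat(sprintf("  sera: %d vs %d; %.0f%% informative antigens, effect %g\n",
              x$n_group1, x$n_group2, 100 * x$frac_informative, x$effect_size))
  invisible(x)
}
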