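#' Simulation configuration for synthetic colony-formation experiments
#'
#' Collects every generative parameter of the agent-based colony model.
#' Defaults reproduce the kinetics of sparse bone-marrow-stromal-cell (BMSC)
#' colony-forming-unit assays: 15-min imaging frames, dividing-cell lifetimes
#' with mean 0.83 d and SD 0.27 d, a ~1 d first-generation lag before the
#' founder division, a per-daughter senescence probability tuned so that
#' roughly 16\% of a colony's cells at Day 4 never divide again, spread areas
#' that shrink with generation while senescent cells keep growing, and a
#' twice-weekly media-exchange perturbation starting at the Day-4 frame.
#'
#' @param frame_interval_min minutes between frames (> 0).
#' @param n_frames number of frames simulated (default 1344 = 14 d at 15 min).
#' @param field_width_um,field_height_um imaging field dimensions in microns.
#' @param pixel_size_um microns per pixel for rendered label images
#'   (default 9.7/15, i.e. 15 px = 9.7 um).
#' @param seed_density_cells_per_cm2 seeding density used to derive the
#'   founder count when `n_founders` is `NULL`.
#' @param n_founders explicit founder count; overrides the density when set.
#'   The default simulates a single founding cell (one colony per field).
#' @param lifetime_mean_d,lifetime_sd_d mean and SD (days) of the dividing-cell
#'   lifetime distribution (truncated normal, truncated at one frame).
#' @param founder_lag_mean_d mean lifetime (days) of first-generation cells.
#'   Founders draw from the same truncated normal but centered here: freshly
#'   plated cells show an extended first cycle (~1 d) before their first
#'   division.
#' @param p_senescent_daughter probability that each daughter cell is
#'   senescent (never divides), drawn independently per daughter.
#' @param area_birth_um2 founder spread area at attachment (um^2).
#' @param area_growth_rate_um2_per_d linear spread-area growth rate of
#'   proliferative cells (um^2/day).
#' @param generation_shrink_factor multiplier (< 1 shrinks) applied to the
#'   parent's pre-division area before splitting it between the daughters;
#'   each daughter is born with `parent_area * factor / 2`.
#' @param senescent_growth_rate_um2_per_d linear growth rate of senescent
#'   cells, which keep spreading for the remainder of the experiment.
#' @param migration_step_sd_um per-axis SD (um) of the per-frame migration
#'   step of the persistent random walk.
#' @param migration_persistence AR(1) velocity persistence in [0, 1).
#' @param media_exchange_frames frame indices of media exchanges. `NULL`
#'   (default) uses frame 374 (Day 4) and then every 336 frames (twice
#'   weekly) up to `n_frames`.
#' @param media_perturbation_sd multiplicative noise scale added to lifetime
#'   and birth-area draws for cells born after each media exchange.
#' @param render_aspect_ratio major/minor axis ratio of the ellipses used
#'   when rendering label images.
#' @param rng_seed integer seed; fixing it makes the experiment (and its
#'   exported tracking matrix) bit-reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_colony()]
#' @export
simulation_config <- function(frame_interval_min = 15,
                              n_frames = 1344,
                              field_width_um = 3500,
                              field_height_um = 2600,
                              pixel_size_um = 9.7 / 15,
                              seed_density_cells_per_cm2 = 30,
                              n_founders = 1,
                              lifetime_mean_d = 0.83,
                              lifetime_sd_d = 0.27,
                              founder_lag_mean_d = 1.0,
                              p_senescent_daughter = 0.08,
                              area_birth_um2 = 3800,
                              area_growth_rate_um2_per_d = 2400,
                              generation_shrink_factor = 0.85,
                              senescent_growth_rate_um2_per_d = 1050,
                              migration_step_sd_um = 12,
                              migration_persistence = 0.6,
                              media_exchange_frames = NULL,
                              media_perturbation_sd = 0.2,
                              render_aspect_ratio = 2,
                              rng_seed = 1L) {
  cfg <- list(
    frame_interval_min = frame_interval_min,
    n_frames = as.integer(n_frames),
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    pixel_size_um = pixel_size_um,
    seed_density_cells_per_cm2 = seed_density_cells_per_cm2,
    n_founders = if (is.null(n_founders)) NULL else as.integer(n_founders),
    lifetime_mean_d = lifetime_mean_d,
    lifetime_sd_d = lifetime_sd_d,
    founder_lag_mean_d = founder_lag_mean_d,
    p_senescent_daughter = p_senescent_daughter,
    area_birth_um2 = area_birth_um2,
    area_growth_rate_um2_per_d = area_growth_rate_um2_per_d,
    generation_shrink_factor = generation_shrink_factor,
    senescent_growth_rate_um2_per_d = senescent_growth_rate_um2_per_d,
    migration_step_sd_um = migration_step_sd_um,
    migration_persistence = migration_persistence,
    media_exchange_frames = media_exchange_frames,
    media_perturbation_sd = media_perturbation_sd,
    render_aspect_ratio = render_aspect_ratio,
    rng_seed = as.integer(rng_seed)
  )
  if (is.null(cfg$media_exchange_frames)) {
    cfg$media_exchange_frames <- if (cfg$n_frames >= 374L) {
      seq(374L, cfg$n_frames, by = 336L)
    } else integer(0)
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c("frame_interval_min", "n_frames", "field_width_um",
                  "field_height_um", "pixel_size_um",
                  "seed_density_cells_per_cm2", "lifetime_mean_d",
                  "lifetime_sd_d", "founder_lag_mean_d",
                  "p_senescent_daughter", "area_birth_um2",
                  "area_growth_rate_um2_per_d", "generation_shrink_factor",
                  "senescent_growth_rate_um2_per_d", "migration_step_sd_um",
                  "migration_persistence", "media_perturbation_sd",
                  "render_aspect_ratio")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field '", f, "' must be a single finite number",
           call. = FALSE)
    }
    if (v < 0) stop("config field '", f, "' must be non-negative",
                    call. = FALSE)
  }
  if (cfg$frame_interval_min <= 0) stop("frame_interval_min must be > 0",
                                        call. = FALSE)
  if (cfg$p_senescent_daughter > 1) stop("p_senescent_daughter must be in [0, 1]",
                                         call. = FALSE)
  if (cfg$generation_shrink_factor <= 0) stop("generation_shrink_factor must be > 0",
                                              call. = FALSE)
  if (cfg$migration_persistence >= 1) stop("migration_persistence must be < 1",
                                           call. = FALSE)
  if (!is.null(cfg$n_founders) && cfg$n_founders < 1)
    stop("n_founders must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d frames x %g min (%.2f d), field %g x %g um\n",
              x$n_frames, x$frame_interval_min,
              x$n_frames * x$frame_interval_min / 1440,
              x$field_width_um, x$field_height_um))
  nf <- if (is.null(x$n_founders)) {
    sprintf("density %g cells/cm^2", x$seed_density_cells_per_cm2)
  } else {
    sprintf("%d founder(s)", x$n_founders)
  }
  cat(sprintf("  %s; lifetime %g +/- %g d (founders %g d); P(senescent) = %g\n",
              nf, x$lifetime_mean_d, x$lifetime_sd_d, x$founder_lag_mean_d,
              x$p_senescent_daughter))
  invisible(x)
}

# frames per day for a config
frames_per_day <- function(cfg) 1440 / cfg$frame_interval_min

# truncated-normal sampler (lower truncation only, inverse-CDF method);
# sd = 0 degenerates to max(lower, mean) but still consumes one uniform so
# that the draw sequence does not depend on parameter values.
rtnorm_lower <- function(n, mean, sd, lower) {
  u <- stats::runif(n)
  if (sd <= 0) return(rep(max(lower, mean), n))
  plo <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(plo + u * (1 - plo))
}
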