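#' Simulate a synthetic colony-formation experiment
#'
#' Agent-based generative model of sparse colony formation under time-lapse
#' imaging. Founders attach at random positions (or a supplied count) and
#' divide after a lifetime drawn from a truncated normal; each daughter is
#' independently senescent with a configured probability, in which case it
#' never divides but keeps growing in spread area. Daughter birth area is the
#' parent's pre-division area times a per-generation shrink factor, split
#' between the two daughters, so successive generations are born smaller.
#' Cells migrate as persistent random walks reflected at the field borders.
#' Media exchanges inflate the noise of subsequent lifetime and birth-area
#' draws, emulating the behavioural deviations observed around feeding.
#'
#' Frames are 1-based: frame `f` corresponds to elapsed time
#' `(f - 1) * frame_interval_min`. A cell born at frame `b` with a lifetime of
#' `n` frames occupies frames `b .. b + n - 1`; its daughters appear at frame
#' `b + n`.
#'
#' @param config a [simulation_config()] object.
#' @return An object of class `sim_experiment`: a list with elements
#'   `config`, `cells` (one row per cell: `cell_id`, `parent_id`, `twin_id`,
#'   `generation`, `birth_frame`, `end_frame`, `fate` in
#'   `{"divided", "senescent", "alive_at_end"}`, `birth_area_um2`,
#'   `growth_rate_um2_per_d`, `orientation_rad`), `tracks` (one row per cell
#'   per frame: `cell_id`, `frame`, `x_um`, `y_um`, `area_um2`) and
#'   `founders` (integer ids of first-generation cells).
#' @examples
#' cfg <- simulation_config(n_frames = 200, n_founders = 2, rng_seed = 7)
#' exp <- simulate_colony(cfg)
#' table(exp$cells$fate)
#' @export
simulate_colony <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a simulation_config() object")
  }
  validate_sim_config(config)
  set.seed(config$rng_seed)

  fpd <- frames_per_day(config)
  dt_d <- 1 / fpd
  nf <- config$n_frames
  W <- config$field_width_um
  H <- config$field_height_um
  exch <- config$media_exchange_frames
  sig <- config$migration_step_sd_um
  rho <- config$migration_persistence
  innov_sd <- sig * sqrt(max(0, 1 - rho^2))

  n0 <- config$n_founders
  if (is.null(n0)) {
    area_cm2 <- (W / 1e4) * (H / 1e4)
    n0 <- as.integer(round(config$seed_density_cells_per_cm2 * area_cm2))
    if (n0 < 1) {
      stop(sprintf(
        "field (%.3g cm^2) too small for seeding density %g cells/cm^2",
        area_cm2, config$seed_density_cells_per_cm2))
    }
  }

  # reflect positions into [0, lim] (triangle-wave folding)
  fold <- function(p, lim) {
    q <- p %% (2 * lim)
    ifelse(q <= lim, q, 2 * lim - q)
  }

  cap <- 4L * n0 + 64L
  parent_id <- twin_id <- rep(NA_integer_, cap)
  generation <- birth_frame <- end_frame <- integer(cap)
  senescent <- logical(cap)
  fate <- character(cap)
  birth_area <- grate <- orient <- numeric(cap)
  bx <- by <- v0x <- v0y <- numeric(cap)
  traj <- vector("list", cap)

  grow <- function(newcap) {
    length(parent_id) <<- length(twin_id) <<- newcap
    length(generation) <<- length(birth_frame) <<- length(end_frame) <<- newcap
    length(senescent) <<- length(fate) <<- newcap
    length(birth_area) <<- length(grate) <<- length(orient) <<- newcap
    length(bx) <<- length(by) <<- length(v0x) <<- length(v0y) <<- newcap
    length(traj) <<- newcap
  }

  # founders
  n_cells <- n0
  fx <- stats::runif(n0, 0, W)
  fy <- stats::runif(n0, 0, H)
  for (i in seq_len(n0)) {
    generation[i] <- 1L
    birth_frame[i] <- 1L
    senescent[i] <- FALSE
    birth_area[i] <- config$area_birth_um2
    grate[i] <- config$area_growth_rate_um2_per_d
    bx[i] <- fx[i]; by[i] <- fy[i]
    v0 <- stats::rnorm(2, 0, sig)
    v0x[i] <- v0[1]; v0y[i] <- v0[2]
    orient[i] <- stats::runif(1, 0, pi)
  }

  i <- 1L
  while (i <= n_cells) {
    # lifetime draw (noise inflated after each media exchange before birth)
    k_ex <- sum(exch < birth_frame[i])
    if (senescent[i]) {
      end_frame[i] <- nf
      fate[i] <- "senescent"
      grate[i] <- config$senescent_growth_rate_um2_per_d
    } else {
      lt_mean <- if (generation[i] == 1L) config$founder_lag_mean_d else
        config$lifetime_mean_d
      lt_sd <- config$lifetime_sd_d * (1 + config$media_perturbation_sd)^k_ex
      lt_d <- rtnorm_lower(1, lt_mean, lt_sd, dt_d)
      n_live <- max(1L, as.integer(round(lt_d * fpd)))
      if (birth_frame[i] + n_live - 1L >= nf) {
        end_frame[i] <- nf
        fate[i] <- "alive_at_end"
      } else {
        end_frame[i] <- birth_frame[i] + n_live - 1L
        fate[i] <- "divided"
      }
    }

    # trajectory: AR(1) velocity, positions folded at the borders
    n_fr <- end_frame[i] - birth_frame[i] + 1L
    if (n_fr > 1L) {
      ex <- stats::rnorm(n_fr - 1L, 0, innov_sd)
      ey <- stats::rnorm(n_fr - 1L, 0, innov_sd)
      vx <- as.numeric(stats::filter(ex, rho, "recursive", init = v0x[i]))
      vy <- as.numeric(stats::filter(ey, rho, "recursive", init = v0y[i]))
      px <- fold(bx[i] + cumsum(c(0, vx)), W)
      py <- fold(by[i] + cumsum(c(0, vy)), H)
    } else {
      vx <- v0x[i]; vy <- v0y[i]
      px <- fold(bx[i], W); py <- fold(by[i], H)
    }
    traj[[i]] <- cbind(px, py)

    if (fate[i] == "divided") {
      area_end <- birth_area[i] + grate[i] * (n_fr - 1L) * dt_d
      a_child <- area_end * config$generation_shrink_factor / 2
      theta <- stats::runif(1, 0, 2 * pi)
      sen_child <- stats::runif(2) < config$p_senescent_daughter
      k_child <- sum(exch < end_frame[i] + 1L)
      if (k_child > 0 && config$media_perturbation_sd > 0) {
        s <- config$media_perturbation_sd * sqrt(k_child)
        a_mult <- exp(stats::rnorm(2, 0, s) - s^2 / 2)
      } else {
        a_mult <- c(1, 1)
      }
      r_off <- sqrt(a_child / pi)
      if (n_cells + 2L > length(parent_id)) grow(2L * length(parent_id))
      px_end <- px[n_fr]; py_end <- py[n_fr]
      for (d in 1:2) {
        j <- n_cells + d
        parent_id[j] <- i
        generation[j] <- generation[i] + 1L
        birth_frame[j] <- end_frame[i] + 1L
        senescent[j] <- sen_child[d]
        birth_area[j] <- max(1, a_child * a_mult[d])
        grate[j] <- config$area_growth_rate_um2_per_d
        sgn <- if (d == 1L) 1 else -1
        bx[j] <- fold(px_end + sgn * r_off * cos(theta), W)
        by[j] <- fold(py_end + sgn * r_off * sin(theta), H)
        v0 <- stats::rnorm(2, 0, sig)
        v0x[j] <- v0[1]; v0y[j] <- v0[2]
        orient[j] <- stats::runif(1, 0, pi)
      }
      twin_id[n_cells + 1L] <- n_cells + 2L
      twin_id[n_cells + 2L] <- n_cells + 1L
      n_cells <- n_cells + 2L
    }
    i <- i + 1L
  }

  idx <- seq_len(n_cells)
  cells <- data.frame(
    cell_id = idx,
    parent_id = parent_id[idx],
    twin_id = twin_id[idx],
    generation = generation[idx],
    birth_frame = birth_frame[idx],
    end_frame = end_frame[idx],
    fate = fate[idx],
    birth_area_um2 = birth_area[idx],
    growth_rate_um2_per_d = grate[idx],
    orientation_rad = orient[idx],
    stringsAsFactors = FALSE
  )

  n_fr_cell <- cells$end_frame - cells$birth_frame + 1L
  frames <- unlist(lapply(idx, function(i) birth_frame[i]:end_frame[i]),
                   use.names = FALSE)
  xy <- do.call(rbind, traj[idx])
  tracks <- data.frame(
    cell_id = rep(idx, n_fr_cell),
    frame = frames,
    x_um = xy[, 1],
    y_um = xy[, 2],
    area_um2 = rep(cells$birth_area_um2, n_fr_cell) +
      rep(cells$growth_rate_um2_per_d, n_fr_cell) *
        (frames - rep(cells$birth_frame, n_fr_cell)) * dt_d
  )

  structure(
    list(config = config, cells = cells, tracks = tracks,
         founders = which(cells$generation == 1L)),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment>\n")
  cat(sprintf("  %d cells (%d founders), %d divisions, %d frames\n",
              nrow(x$cells), length(x$founders),
              sum(x$cells$fate == "divided"), x$config$n_frames))
  cat(sprintf("  fates: %s\n",
              paste(names(table(x$cells$fate)), table(x$cells$fate),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cells alive at a given frame of a simulated experiment
#'
#' @param exp a `sim_experiment`.
#' @param frame frame index.
#' @return Integer cell ids, ordered; per-frame object numbers are the ranks
#'   of the living cells in this ordering.
#' @export
living_cells <- function(exp, frame) {
  stopifnot(inherits(exp, "sim_experiment"))
  if (frame < 1L || frame > exp$config$n_frames) {
    stop("frame out of range 1..", exp$config$n_frames)
  }
  with(exp$cells, cell_id[birth_frame <= frame & end_frame >= frame])
}
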