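# Shared fixtures built in code.

# deterministic clockwork colony: divisions at exactly 1, 2, 3, ... days
clockwork_config <- function(n_frames = 400, ...) {
  simulation_config(n_frames = n_frames, n_founders = 1,
                    lifetime_mean_d = 1.0, lifetime_sd_d = 0,
                    founder_lag_mean_d = 1.0, p_senescent_daughter = 0,
                    media_perturbation_sd = 0, rng_seed = 1, ...)
}

# small stochastic default-parameter experiment
small_default_exp <- function(seed = 1, n_frames = 480) {
  simulate_colony(simulation_config(n_frames = n_frames, rng_seed = seed))
}

# toy object matrix: 1 parent (frames 1..10), daughters (11..20)
toy_matrix_3col <- function() {
  v <- matrix(0L, 20, 3)
  v[1:10, 1] <- 1L
  v[11:20, 2] <- 1L
  v[11:20, 3] <- 2L
  object_matrix(v, cell_ids = c("A", "B", "C"))
}

# draw a filled disk into a matrix
disk_image <- function(n = 64, cx = n / 2, cy = n / 2, r = 20, label = 1L) {
  m <- matrix(0L, n, n)
  xy <- as.matrix(expand.grid(row = 1:n, col = 1:n))
  d <- sqrt((xy[, "col"] - cx)^2 + (xy[, "row"] - cy)^2)
  m[xy[d <= r, , drop = FALSE]] <- label
  m
}

# brute-force area/centroid oracle for label images (0-based coords)
brute_regionprops <- function(img) {
  labs <- sort(unique(img[img > 0L]))
  do.call(rbind, lapply(labs, function(L) {
    pix <- which(img == L, arr.ind = TRUE)
    data.frame(label = L, area = nrow(pix),
               x = mean(pix[, 2] - 1), y = mean(pix[, 1] - 1))
  }))
}
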