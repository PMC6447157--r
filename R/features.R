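#' Build the per-cell feature table
#'
#' Aggregates per-frame tracks into one row per cell: lifetime-aggregated
#' spread-area statistics, the early-lifetime average area (over the first
#' 0.83 d of life, the population-average lifetime, so that long-lived or
#' senescent cells do not inflate their own average), migration, neighbor
#' counts, genealogy (generation, lifetime, progeny counts, parent
#' properties) and bookkeeping (colony id, proliferative class of the
#' progeny).
#'
#' Entries that the experimental design cannot measure are `NA` and act as
#' validity masks for the downstream statistics: lifetime-dependent columns
#' are masked for founders and never-dividing cells; parent columns are
#' masked for first- and second-generation cells (their parents' properties
#' are unknown - a founder's own birth was never observed); birth time is
#' masked for founders. The `filters` attribute names the filter family of
#' every column, and is consumed by [correlation_matrix()] and
#' [binary_ttests()].
#'
#' Neighbor counts use a centroid-disc approximation of the edge-to-edge
#' rule: two cells are in contact when their centroid distance is below the
#' sum of their circle-equivalent radii plus `contact_dist_um` (9.7 um, the
#' 15 px rule). The table notes this via the `neighbor_basis` attribute.
#'
#' @param f a `lineage_forest`.
#' @param tracks data.frame `cell_id`, `frame`, `x_um`, `y_um`, `area_um2`.
#' @param fates optional named character vector (by cell id) of fate labels
#'   (`"senescent"` etc.), e.g. simulation truth or [classify_fate()]
#'   output; used for `n_senescent_daughters`.
#' @param day4_frame frame at which progeny proliferative classes are
#'   assessed (default 374); set `NULL` to skip the class column.
#' @param contact_dist_um edge-clearance defining a contact (default 9.7).
#' @param early_window_d early-lifetime averaging window in days
#'   (default 0.83).
#' @return data.frame (class `feature_table`) with attributes `filters` and
#'   `neighbor_basis`.
#' @export
build_feature_table <- function(f, tracks, fates = NULL, day4_frame = 374L,
                                contact_dist_um = 9.7,
                                early_window_d = 0.83) {
  stopifnot(inherits(f, "lineage_forest"))
  r <- f$records
  dt_d <- f$frame_interval_min / 1440
  fpd <- 1 / dt_d
  win_frames <- as.integer(round(early_window_d * fpd))

  tracks <- tracks[order(tracks$cell_id, tracks$frame), ]
  tr_by_cell <- split(tracks, tracks$cell_id)

  # per-frame neighbor counts (centroid-disc contact rule)
  by_frame <- split(tracks, tracks$frame)
  cnt_all <- lapply(by_frame, function(at) {
    n <- nrow(at)
    if (n == 1L) return(0L)
    rad <- sqrt(at$area_um2 / pi)
    d <- as.matrix(stats::dist(cbind(at$x_um, at$y_um)))
    lim <- outer(rad, rad, "+") + contact_dist_um
    as.integer(colSums(d <= lim) - 1L)
  })
  nb_count <- split(unlist(cnt_all, use.names = FALSE),
                    unlist(lapply(by_frame, function(at)
                      as.character(at$cell_id)), use.names = FALSE))

  n_desc <- descendant_counts(f)
  roots <- root_of(f)

  per_cell <- lapply(seq_len(nrow(r)), function(i) {
    id <- r$cell_id[i]
    tc <- tr_by_cell[[id]]
    a <- tc$area_um2
    nfr <- nrow(tc)
    steps <- if (nfr > 1L) {
      sum(sqrt(diff(tc$x_um)^2 + diff(tc$y_um)^2))
    } else 0
    early <- mean(a[seq_len(min(nfr, win_frames))])
    abd <- NA_real_
    if (r$divided[i]) {
      w <- max(1L, nfr - 8L):max(1L, nfr - 4L)
      abd <- mean(a[w])
    }
    nb <- nb_count[[id]]
    data.frame(
      cell_id = id,
      avg_area = mean(a), max_area = max(a), area_at_birth = a[1L],
      area_before_division = abd,
      avg_area_first_083d = early,
      total_distance_traveled = steps,
      avg_n_neighbors = mean(nb), max_n_neighbors = max(nb),
      cum_n_neighbors = sum(nb), n_neighbors_at_birth = nb[1L],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, per_cell)

  tab$birth_time_d <- ifelse(r$generation == 1L, NA_real_,
                             (r$birth_frame - 1L) * dt_d)
  tab$lifetime_d <- r$lifetime_d
  tab$generation <- r$generation
  tab$n_progeny <- as.integer(n_desc[r$cell_id])

  if (!is.null(fates)) {
    sen <- names(fates)[fates == "senescent"]
    tab$n_senescent_daughters <- ifelse(
      r$divided,
      vapply(r$cell_id, function(id) {
        sum(r$parent_id == id & r$cell_id %in% sen, na.rm = TRUE)
      }, numeric(1)),
      NA_real_)
  } else {
    tab$n_senescent_daughters <- NA_real_
  }

  pi_idx <- match(r$parent_id, r$cell_id)
  parent_ok <- r$generation >= 3L & !is.na(pi_idx)
  tab$parent_max_area <- ifelse(parent_ok, tab$max_area[pi_idx], NA_real_)
  tab$parent_lifetime <- ifelse(parent_ok, r$lifetime_d[pi_idx], NA_real_)
  tab$parent_area_before_division <-
    ifelse(parent_ok, tab$area_before_division[pi_idx], NA_real_)

  tab$colony_id <- unname(roots[r$cell_id])
  if (!is.null(day4_frame)) {
    counts <- progeny_counts(f, day4_frame)
    cls <- classify_progeny(counts)
    tab$progeny_class <- cls$class[match(tab$colony_id, cls$founder_id)]
  }

  filters <- c(
    avg_area = "none", max_area = "none", area_at_birth = "none",
    area_before_division = "division", avg_area_first_083d = "none",
    total_distance_traveled = "none", avg_n_neighbors = "none",
    max_n_neighbors = "none", cum_n_neighbors = "none",
    n_neighbors_at_birth = "none", birth_time_d = "birth",
    lifetime_d = "lifetime", generation = "none", n_progeny = "none",
    n_senescent_daughters = "division", parent_max_area = "parent",
    parent_lifetime = "parent", parent_area_before_division = "parent"
  )
  attr(tab, "filters") <- filters
  attr(tab, "neighbor_basis") <- "centroid_disc"
  class(tab) <- c("feature_table", "data.frame")
  rownames(tab) <- NULL
  tab
}

# number of descendants (children, grandchildren, ...) per cell
descendant_counts <- function(f) {
  r <- f$records
  idx <- stats::setNames(seq_len(nrow(r)), r$cell_id)
  n <- rep(0L, nrow(r))
  # process in reverse birth order: children before parents
  for (i in order(r$birth_frame, decreasing = TRUE)) {
    p <- r$parent_id[i]
    if (!is.na(p)) n[idx[p]] <- n[idx[p]] + n[i] + 1L
  }
  stats::setNames(n, r$cell_id)
}
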