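#' Export the object-number tracking matrix of a simulated experiment
#'
#' Produces the canonical tracking exchange format: an integer matrix with
#' one row per frame and one column per unique cell, where entry `(t, c)` is
#' the per-frame object number of cell `c` at frame `t`, and 0 when the cell
#' does not exist at that frame. Object numbers at a frame are the ranks of
#' the living cells' ids, matching the labels drawn by [render_labels()].
#' Per-frame object centroids (in pixels) travel along as the `centroids`
#' element, so that simultaneous divisions can later be disambiguated.
#'
#' @param exp a `sim_experiment`.
#' @param frames frame indices to export (default: all simulated frames).
#'   Cells whose whole support lies outside the window are dropped.
#' @return An [object_matrix()].
#' @export
export_tracking_matrix <- function(exp, frames = NULL) {
  stopifnot(inherits(exp, "sim_experiment"))
  if (is.null(frames)) frames <- seq_len(exp$config$n_frames)
  frames <- as.integer(frames)
  cells <- exp$cells
  keep <- cells$birth_frame <= max(frames) & cells$end_frame >= min(frames)
  cells <- cells[keep, ]
  vals <- matrix(0L, nrow = length(frames), ncol = nrow(cells))
  tr <- exp$tracks[exp$tracks$frame %in% frames &
                     exp$tracks$cell_id %in% cells$cell_id, ]
  # object number = rank of cell id among living cells at the frame
  ord <- order(tr$frame, tr$cell_id)
  tr <- tr[ord, ]
  lab <- stats::ave(tr$cell_id, tr$frame, FUN = seq_along)
  ti <- match(tr$frame, frames)
  ci <- match(tr$cell_id, cells$cell_id)
  vals[cbind(ti, ci)] <- as.integer(lab)
  centroids <- data.frame(
    frame = tr$frame,
    label = as.integer(lab),
    x_px = tr$x_um / exp$config$pixel_size_um,
    y_px = tr$y_um / exp$config$pixel_size_um
  )
  object_matrix(vals, frames = frames,
                cell_ids = as.character(cells$cell_id),
                frame_interval_min = exp$config$frame_interval_min,
                centroids = centroids)
}

#' Inject tracking errors into an object matrix
#'
#' Simulates the error classes that arise in automated tracking of label
#' images and that [validate_matrix()] is designed to surface:
#' \describe{
#'   \item{gap}{a zero inside a column's support (a cell transiently lost).}
#'   \item{merge}{one daughter column of a division deleted (two touching
#'     cells segmented as one, so the division appears to have a single
#'     successor).}
#'   \item{orphan}{a spurious column starting at a division boundary with no
#'     coincident sibling.}
#' }
#'
#' @param m an [object_matrix()].
#' @param gaps,merges,orphans number of errors of each kind to inject.
#' @param rng_seed seed controlling the error placement.
#' @return A corrupted `object_matrix` with an `injected` attribute
#'   (data.frame `kind`, `frame`, `cell`) recording what was planted.
#' @export
corrupt_matrix <- function(m, gaps = 0L, merges = 0L, orphans = 0L,
                           rng_seed = 1L) {
  stopifnot(inherits(m, "object_matrix"))
  set.seed(rng_seed)
  vals <- m$values
  injected <- data.frame(kind = character(), frame = integer(),
                         cell = character(), stringsAsFactors = FALSE)
  sup <- column_supports(vals)

  if (gaps > 0L) {
    elig <- which(sup$last - sup$first >= 3L)  # interior frames exist
    if (length(elig) < gaps) stop("not enough columns with interior support for ", gaps, " gaps")
    cols <- sample(elig, gaps)
    for (cc in cols) {
      f <- sample((sup$first[cc] + 1L):(sup$last[cc] - 1L), 1L)
      vals[f, cc] <- 0L
      injected <- rbind(injected, data.frame(
        kind = "gap", frame = m$frames[f], cell = m$cell_ids[cc],
        stringsAsFactors = FALSE))
    }
  }

  drop_cols <- integer()
  if (merges > 0L || orphans > 0L) {
    # division boundaries: columns ending before the last frame
    enders <- which(sup$last < nrow(vals) & sup$first <= sup$last)
    starters_at <- function(t1) which(sup$first == t1)
    div_bounds <- unique(sup$last[enders])
    div_bounds <- div_bounds[vapply(div_bounds, function(t) {
      length(starters_at(t + 1L)) >= 2L
    }, logical(1))]
    if (merges > 0L) {
      if (length(div_bounds) < merges) stop("not enough divisions to inject ", merges, " merges")
      bsel <- sample(div_bounds, merges)
      for (t in bsel) {
        dcols <- starters_at(t + 1L)
        # prefer a leaf daughter so the deletion stays local
        leaf <- dcols[sup$last[dcols] == nrow(vals)]
        victim <- if (length(leaf)) leaf[1L] else dcols[1L]
        drop_cols <- c(drop_cols, victim)
        injected <- rbind(injected, data.frame(
          kind = "merge", frame = m$frames[t], cell = m$cell_ids[victim],
          stringsAsFactors = FALSE))
      }
      div_bounds <- setdiff(div_bounds, bsel)
    }
    if (orphans > 0L) {
      if (length(div_bounds) < orphans) stop("not enough division boundaries for ", orphans, " orphans")
      bsel <- sample(div_bounds, orphans)
      extra <- matrix(0L, nrow = nrow(vals), ncol = orphans)
      for (j in seq_along(bsel)) {
        t <- bsel[j]
        rows <- (t + 1L):nrow(vals)
        extra[rows, j] <- max(vals[rows, , drop = FALSE]) + j
        injected <- rbind(injected, data.frame(
          kind = "orphan", frame = m$frames[t], cell = paste0("spurious_", j),
          stringsAsFactors = FALSE))
      }
      vals <- cbind(vals, extra)
      m$cell_ids <- c(m$cell_ids, paste0("spurious_", seq_len(orphans)))
    }
  }

  if (length(drop_cols)) {
    keep <- setdiff(seq_len(ncol(vals)), drop_cols)
    vals <- vals[, keep, drop = FALSE]
    m$cell_ids <- m$cell_ids[keep]
  }
  m$values <- vals
  attr(m, "injected") <- injected
  m
}
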