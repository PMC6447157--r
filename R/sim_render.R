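#' Render a label image for one frame of a simulated experiment
#'
#' Draws each living cell as a filled, rotated ellipse of its current spread
#' area, centred at its current position. Pixel labels are the cell's
#' per-frame object number (the rank of its cell id among living cells, the
#' same numbering used by [export_tracking_matrix()]). Where ellipses overlap,
#' contested pixels go to the nearer centroid; every living cell keeps at
#' least one pixel (its centre pixel is forced if the overlap would swallow
#' it).
#'
#' Coordinates are 0-based pixel indices with the origin at the top-left:
#' x is the column index, y the row index, so matrix element `[r, c]` is the
#' pixel at `(x, y) = (c - 1, r - 1)`.
#'
#' @param exp a `sim_experiment`.
#' @param frame frame index to render.
#' @param pixel_size_um microns per pixel (default from the config).
#' @param aspect_ratio ellipse major/minor axis ratio (default from config).
#' @return Integer matrix (rows = y, cols = x) of per-pixel object numbers,
#'   0 for background, with attributes `pixel_size_um` and `frame`.
#' @export
render_labels <- function(exp, frame,
                          pixel_size_um = exp$config$pixel_size_um,
                          aspect_ratio = exp$config$render_aspect_ratio) {
  stopifnot(inherits(exp, "sim_experiment"))
  ids <- living_cells(exp, frame)
  nx <- as.integer(ceiling(exp$config$field_width_um / pixel_size_um))
  ny <- as.integer(ceiling(exp$config$field_height_um / pixel_size_um))
  lab <- matrix(0L, nrow = ny, ncol = nx)
  if (length(ids) == 0L) {
    attr(lab, "pixel_size_um") <- pixel_size_um
    attr(lab, "frame") <- frame
    return(lab)
  }
  tr <- exp$tracks[exp$tracks$frame == frame & exp$tracks$cell_id %in% ids, ]
  tr <- tr[match(ids, tr$cell_id), ]
  bestd <- matrix(Inf, nrow = ny, ncol = nx)

  for (k in seq_along(ids)) {
    cx <- tr$x_um[k] / pixel_size_um
    cy <- tr$y_um[k] / pixel_size_um
    area_px <- tr$area_um2[k] / pixel_size_um^2
    a <- sqrt(area_px * aspect_ratio / pi)   # semi-major, px
    b <- sqrt(area_px / (aspect_ratio * pi)) # semi-minor, px
    th <- exp$cells$orientation_rad[match(ids[k], exp$cells$cell_id)]
    cols <- max(1L, floor(cx - a) + 1L):min(nx, ceiling(cx + a) + 1L)
    rows <- max(1L, floor(cy - a) + 1L):min(ny, ceiling(cy + a) + 1L)
    if (cx < -a || cx > nx - 1 + a || cy < -a || cy > ny - 1 + a) {
      stop(sprintf("cell %d lies fully outside the field at frame %d",
                   ids[k], frame))
    }
    dx <- outer(rep(1, length(rows)), cols - 1 - cx)
    dy <- outer(rows - 1 - cy, rep(1, length(cols)))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) {
      # sub-pixel cell: take the centre pixel
      inside[which.min(dx^2 + dy^2)] <- TRUE
    }
    d2 <- dx^2 + dy^2
    ridx <- rep(rows, times = length(cols))[inside]
    cidx <- rep(cols, each = length(rows))[inside]
    flat <- ridx + (cidx - 1L) * ny
    take <- d2[inside] < bestd[flat]
    lab[flat[take]] <- k
    bestd[flat[take]] <- d2[inside][take]
  }

  # guarantee >= 1 pixel per cell
  counts <- tabulate(lab[lab > 0L], nbins = length(ids))
  for (k in which(counts == 0L)) {
    cc <- min(nx, max(1L, as.integer(round(tr$x_um[k] / pixel_size_um)) + 1L))
    rr <- min(ny, max(1L, as.integer(round(tr$y_um[k] / pixel_size_um)) + 1L))
    lab[rr, cc] <- k
  }
  attr(lab, "pixel_size_um") <- pixel_size_um
  attr(lab, "frame") <- frame
  lab
}

#' Render a stack of label images
#'
#' @param exp a `sim_experiment`.
#' @param frames frame indices (default all simulated frames).
#' @inheritParams render_labels
#' @return List of label matrices, one per frame.
#' @export
render_label_stack <- function(exp, frames = seq_len(exp$config$n_frames),
                               pixel_size_um = exp$config$pixel_size_um,
                               aspect_ratio = exp$config$render_aspect_ratio) {
  lapply(frames, function(f) {
    render_labels(exp, f, pixel_size_um = pixel_size_um,
                  aspect_ratio = aspect_ratio)
  })
}
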