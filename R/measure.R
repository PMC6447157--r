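#' @title Per-frame geometry of labelled objects
#'
#' @description
#' Computes the standard single-cell morphology set from a label image:
#' area, centroid, perimeter, major/minor axis length, eccentricity,
#' orientation, solidity, extent, form factor (`4*pi*area/perimeter^2`) and
#' compactness (`2*pi*MSD/area`, 1 for a filled disk). Lengths and areas are
#' reported both in pixels and in microns.
#'
#' Conventions: coordinates are 0-based with the origin at the top-left
#' (x = column, y = row). The perimeter uses the four-direction
#' Cauchy-Crofton estimator (intercept counts weighted by direction), which
#' is close to unbiased for smooth shapes, so a disk's form factor lands
#' within a few percent of 1. Second
#' moments include the 1/12 per-pixel variance correction, so a single pixel
#' has a finite axis length and eccentricity stays strictly below 1.
#' Solidity divides by the area of the convex hull of the pixel squares
#' (not pixel centres), so a filled rectangle has solidity exactly 1.
#'
#' @param img integer label matrix (0 = background).
#' @param pixel_size_um microns per pixel (default taken from the image
#'   attribute, else 1).
#' @return data.frame with one row per nonzero label, ordered by label.
#' @export
measure_frame <- function(img, pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) {
    pixel_size_um <- attr(img, "pixel_size_um")
    if (is.null(pixel_size_um)) pixel_size_um <- 1
  }
  labs <- sort(unique(img[img > 0L]))
  cols <- c("label", "x_px", "y_px", "x_um", "y_um", "area_px2", "area_um2",
            "perimeter_px", "perimeter_um", "major_axis_px", "major_axis_um",
            "minor_axis_px", "minor_axis_um", "eccentricity",
            "orientation_rad", "solidity", "extent", "form_factor",
            "compactness")
  if (length(labs) == 0L) {
    out <- as.data.frame(stats::setNames(replicate(length(cols),
                                                   numeric(0),
                                                   simplify = FALSE), cols))
    return(out)
  }
  idx <- which(img > 0L, arr.ind = TRUE)
  lab_at <- img[img > 0L]
  res <- lapply(labs, function(L) {
    pix <- idx[lab_at == L, , drop = FALSE]
    x <- pix[, 2] - 1
    y <- pix[, 1] - 1
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    dx <- x - mx; dy <- y - my
    mxx <- mean(dx^2) + 1 / 12
    myy <- mean(dy^2) + 1 / 12
    mxy <- mean(dx * dy)
    common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
    major <- 2 * sqrt(2) * sqrt(mxx + myy + common)
    minor <- 2 * sqrt(2) * sqrt(max(0, mxx + myy - common))
    ecc <- sqrt(max(0, 1 - (minor / major)^2))
    theta <- 0.5 * atan2(2 * mxy, mxx - myy)
    per <- perimeter_crofton(pix, dim(img))
    hull_a <- pixel_hull_area(x, y)
    bbox_a <- (diff(range(x)) + 1) * (diff(range(y)) + 1)
    msd <- mean(dx^2 + dy^2) + 1 / 6
    data.frame(
      label = L, x_px = mx, y_px = my,
      x_um = mx * pixel_size_um, y_um = my * pixel_size_um,
      area_px2 = n, area_um2 = n * pixel_size_um^2,
      perimeter_px = per, perimeter_um = per * pixel_size_um,
      major_axis_px = major, major_axis_um = major * pixel_size_um,
      minor_axis_px = minor, minor_axis_um = minor * pixel_size_um,
      eccentricity = ecc, orientation_rad = theta,
      solidity = min(1, n / hull_a), extent = n / bbox_a,
      form_factor = 4 * pi * n / per^2,
      compactness = 2 * pi * msd / n
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Cauchy-Crofton perimeter (4 directions) of one object's pixel set:
# counts boundary configurations of each pixel with its right and lower
# neighbor and weights them by the Crofton direction coefficients. Nearly
# unbiased for smooth shapes (a digital disk lands within ~3% of 2*pi*r).
perimeter_crofton <- function(pix, imdim) {
  r0 <- min(pix[, 1]); c0 <- min(pix[, 2])
  nr <- max(pix[, 1]) - r0 + 3L
  ncl <- max(pix[, 2]) - c0 + 3L
  M <- matrix(0L, nr, ncl)
  M[cbind(pix[, 1] - r0 + 2L, pix[, 2] - c0 + 2L)] <- 1L
  left <- cbind(0L, M[, -ncl, drop = FALSE])
  above <- rbind(0L, M[-nr, , drop = FALSE])
  above_left <- rbind(0L, left[-nr, , drop = FALSE])
  code <- M + 4L * left + 2L * above + 8L * above_left
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  p <- sum(coefs * h)
  if (p <= 0) p <- max(1, nrow(pix))  # degenerate (isolated pixels)
  p
}

# area of the convex hull of the pixel *squares* for pixels at centres (x, y)
pixel_hull_area <- function(x, y) {
  if (length(x) == 1L) return(1)
  h <- grDevices::chull(x, y)
  vx <- x[h]; vy <- y[h]
  cx <- c(vx - 0.5, vx - 0.5, vx + 0.5, vx + 0.5)
  cy <- c(vy - 0.5, vy + 0.5, vy - 0.5, vy + 0.5)
  h2 <- grDevices::chull(cx, cy)
  shoelace(cx[h2], cy[h2])
}

# polygon area by the shoelace formula (vertices in hull order)
shoelace <- function(px, py) {
  n <- length(px)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(px * py[j] - px[j] * py)) / 2
}

#' Neighbor statistics from a label image
#'
#' A cell's neighbors are the objects whose edge comes within
#' `threshold_px` of its own edge; the paper-standard contact rule is 15 px
#' (9.7 um). Edge-to-edge distance is the minimum Euclidean distance between
#' boundary-pixel centres. The distances to the two nearest objects are
#' reported regardless of the threshold.
#'
#' Distances are clear gaps: two objects occupying adjacent pixels are 0 px
#' apart (boundary-pixel centre distance minus one pixel, floored at 0), so
#' "20 px apart" means 20 empty pixels between the edges.
#'
#' @param img integer label matrix.
#' @param threshold_px neighbor distance threshold in pixels (default 15).
#' @return data.frame with columns `label`, `n_neighbors`,
#'   `first_closest_distance`, `second_closest_distance` (px; `NA` when
#'   there are not enough other objects).
#' @export
neighbor_stats <- function(img, threshold_px = 15) {
  labs <- sort(unique(img[img > 0L]))
  nlab <- length(labs)
  out <- data.frame(label = labs, n_neighbors = rep(0L, nlab),
                    first_closest_distance = rep(NA_real_, nlab),
                    second_closest_distance = rep(NA_real_, nlab))
  if (nlab <= 1L) return(out)

  idx <- which(img > 0L, arr.ind = TRUE)
  lab_at <- img[img > 0L]
  bnd <- lapply(labs, function(L) {
    pix <- idx[lab_at == L, , drop = FALSE]
    boundary_pixels(pix, dim(img))
  })
  cen <- t(vapply(bnd, colMeans, numeric(2)))
  maxr <- vapply(seq_len(nlab), function(i) {
    sqrt(max(rowSums((bnd[[i]] - rep(cen[i, ], each = nrow(bnd[[i]])))^2)))
  }, numeric(1))

  dmin <- matrix(NA_real_, nlab, nlab)
  exact <- function(i, j) {
    if (!is.na(dmin[i, j])) return(dmin[i, j])
    a <- bnd[[i]]; b <- bnd[[j]]
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    d <- max(0, sqrt(min(d2)) - 1)  # clear gap between edges
    dmin[i, j] <<- dmin[j, i] <<- d
    d
  }
  cdist <- as.matrix(stats::dist(cen))
  lb <- pmax(cdist - outer(maxr, maxr, "+") - 1, 0)

  for (i in seq_len(nlab)) {
    ord <- order(lb[i, -i])
    js <- seq_len(nlab)[-i][ord]
    best <- c(Inf, Inf)
    nnb <- 0L
    for (j in js) {
      if (lb[i, j] > threshold_px && lb[i, j] > best[2L]) break
      d <- exact(i, j)
      if (d <= threshold_px) nnb <- nnb + 1L
      if (d < best[1L]) best <- c(d, best[1L])
      else if (d < best[2L]) best[2L] <- d
    }
    out$n_neighbors[i] <- nnb
    out$first_closest_distance[i] <- if (is.finite(best[1L])) best[1L] else NA_real_
    out$second_closest_distance[i] <- if (is.finite(best[2L])) best[2L] else NA_real_
  }
  out
}

# boundary pixels (4-connectivity; image border counts as outside)
boundary_pixels <- function(pix, imdim) {
  keyed <- pix[, 1] + (pix[, 2] - 1) * imdim[1]
  inset <- function(dr, dc) {
    (pix[, 1] + dr + (pix[, 2] + dc - 1) * imdim[1]) %in% keyed &
      pix[, 1] + dr >= 1 & pix[, 1] + dr <= imdim[1] &
      pix[, 2] + dc >= 1 & pix[, 2] + dc <= imdim[2]
  }
  interior <- inset(1, 0) & inset(-1, 0) & inset(0, 1) & inset(0, -1)
  pix[!interior, , drop = FALSE]
}

#' Colony-level convex-hull metrics
#'
#' Measures the footprint of a colony: the area of the convex hull over all
#' member pixels, the area occupied by the cells themselves, their ratio
#' (confluency), the circle-equivalent ("approximate") diameter
#' `2 * sqrt(hull_area / pi)`, and the colony centroid, defined as the
#' unweighted mean of the member objects' centroids.
#'
#' Either a label image or centroid positions can be supplied. With
#' positions only, the hull is taken over the centroids and the occupied
#' area is the sum of the supplied cell areas; the output is flagged
#' `basis = "centroids"` because such a hull slightly underestimates the
#' pixel-true footprint.
#'
#' @param img integer label matrix (preferred input).
#' @param members labels (image mode) or row indices (position mode)
#'   belonging to the colony; default all objects.
#' @param positions data.frame/matrix of centroid `x`, `y` (um) when no
#'   image is given.
#' @param areas_um2 per-cell areas (um^2), required with `positions`.
#' @param pixel_size_um microns per pixel (image mode).
#' @return list of class `colony_metrics`: `hull_area_um2`,
#'   `occupied_area_um2`, `confluency`, `approx_diameter_mm`,
#'   `centroid_x_um`, `centroid_y_um`, `basis`.
#' @export
colony_hull_metrics <- function(img = NULL, members = NULL, positions = NULL,
                                areas_um2 = NULL, pixel_size_um = NULL) {
  if (!is.null(img)) {
    if (is.null(pixel_size_um)) {
      pixel_size_um <- attr(img, "pixel_size_um")
      if (is.null(pixel_size_um)) pixel_size_um <- 1
    }
    labs <- sort(unique(img[img > 0L]))
    if (is.null(members)) members <- labs
    sel <- img %in% members & img > 0L
    if (!any(sel)) stop("no member pixels in image")
    pix <- which(matrix(sel, nrow(img)), arr.ind = TRUE)
    x <- pix[, 2] - 1
    y <- pix[, 1] - 1
    hull_px2 <- pixel_hull_area(x, y)
    occ_px2 <- nrow(pix)
    # centroid of all member objects (unweighted mean over objects)
    mm <- measure_frame(ifelse(matrix(sel, nrow(img)), img, 0L),
                        pixel_size_um = pixel_size_um)
    cen <- c(mean(mm$x_um), mean(mm$y_um))
    hull_um2 <- hull_px2 * pixel_size_um^2
    occ_um2 <- occ_px2 * pixel_size_um^2
    basis <- "pixels"
  } else {
    if (is.null(positions) || is.null(areas_um2)) {
      stop("either img or positions + areas_um2 must be supplied")
    }
    positions <- as.matrix(positions)
    if (is.null(members)) members <- seq_len(nrow(positions))
    positions <- positions[members, , drop = FALSE]
    areas_um2 <- areas_um2[members]
    h <- grDevices::chull(positions[, 1], positions[, 2])
    hull_um2 <- shoelace(positions[h, 1], positions[h, 2])
    occ_um2 <- sum(areas_um2)
    cen <- colMeans(positions)
    basis <- "centroids"
  }
  structure(list(
    hull_area_um2 = hull_um2,
    occupied_area_um2 = occ_um2,
    confluency = if (hull_um2 > 0) occ_um2 / hull_um2 else NA_real_,
    approx_diameter_mm = 2 * sqrt(hull_um2 / pi) / 1000,
    centroid_x_um = cen[[1]], centroid_y_um = cen[[2]],
    basis = basis
  ), class = "colony_metrics")
}

#' @export
print.colony_metrics <- function(x, ...) {
  cat(sprintf(
    "<colony_metrics> hull %.3g mm^2, confluency %.1f%%, diameter %.2f mm (%s)\n",
    x$hull_area_um2 / 1e6, 100 * x$confluency, x$approx_diameter_mm, x$basis))
  invisible(x)
}

#' Map mitotic events onto colony geometry
#'
#' One event per division, located at the parent's centroid at its final
#' frame (the time point just before the daughters appear), with the
#' distance to the colony centroid at that frame - the centroid being the
#' unweighted mean position of all cells alive then - and, when per-frame
#' metrics are supplied, the colony confluency at the event frame.
#'
#' @param f a `lineage_forest`.
#' @param tracks data.frame `cell_id`, `frame`, `x`, `y` (any consistent
#'   length unit; `x_um`/`y_um` columns are also accepted).
#' @param metrics optional data.frame `frame`, `confluency`.
#' @return data.frame `cell_id`, `frame`, `x`, `y`, `distance_from_centroid`,
#'   `confluency`.
#' @export
mitotic_event_map <- function(f, tracks, metrics = NULL) {
  stopifnot(inherits(f, "lineage_forest"))
  if (!"x" %in% names(tracks) && "x_um" %in% names(tracks)) {
    tracks$x <- tracks$x_um
    tracks$y <- tracks$y_um
  }
  r <- f$records
  div <- r[r$divided, , drop = FALSE]
  if (nrow(div) == 0L) {
    return(data.frame(cell_id = character(), frame = integer(), x = numeric(),
                      y = numeric(), distance_from_centroid = numeric(),
                      confluency = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(tracks$cell_id, tracks$frame)
  pos <- tracks[match(paste(div$cell_id, div$last_frame), key), c("x", "y")]
  cen <- do.call(rbind, lapply(div$last_frame, function(fr) {
    alive <- r$cell_id[r$birth_frame <= fr & r$last_frame >= fr]
    at <- tracks[tracks$frame == fr & tracks$cell_id %in% alive, ]
    c(mean(at$x), mean(at$y))
  }))
  conf <- rep(NA_real_, nrow(div))
  if (!is.null(metrics)) {
    conf <- metrics$confluency[match(div$last_frame, metrics$frame)]
  }
  data.frame(
    cell_id = div$cell_id, frame = div$last_frame,
    x = pos$x, y = pos$y,
    distance_from_centroid = sqrt((pos$x - cen[, 1])^2 +
                                    (pos$y - cen[, 2])^2),
    confluency = conf, stringsAsFactors = FALSE
  )
}
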