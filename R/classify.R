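#' Classify cell fate at a reference frame
#'
#' Operational senescence call: every cell alive at `reference_frame` is
#' labelled `proliferative` if it divides by `horizon_frame` (the Day-7
#' frame for a Day-4 reference), `senescent` if it is tracked through the
#' horizon without dividing, and `censored` if its track ends before the
#' horizon without a division (truncated simulation or field exit), in which
#' case its fate cannot be assessed. Censored cells are excluded from
#' senescent-fraction summaries.
#'
#' @param f a `lineage_forest`.
#' @param reference_frame assessment frame (default 374, ~Day 4).
#' @param horizon_frame division deadline (default 672, Day 7).
#' @return data.frame `cell_id`, `fate`, `assessed_at_frame`,
#'   `horizon_frame` - one row per cell alive at the reference frame.
#' @export
classify_fate <- function(f, reference_frame = 374L, horizon_frame = 672L) {
  stopifnot(inherits(f, "lineage_forest"))
  r <- f$records
  if (reference_frame > max(r$last_frame)) {
    stop("reference_frame ", reference_frame, " is beyond the tracked data")
  }
  if (horizon_frame <= reference_frame) {
    stop("horizon_frame must exceed reference_frame")
  }
  alive <- r$birth_frame <= reference_frame & r$last_frame >= reference_frame
  rr <- r[alive, , drop = FALSE]
  divides_by <- rr$divided & rr$last_frame < horizon_frame
  fate <- ifelse(divides_by, "proliferative",
                 ifelse(rr$last_frame >= horizon_frame | rr$divided,
                        "senescent", "censored"))
  data.frame(cell_id = rr$cell_id, fate = fate,
             assessed_at_frame = reference_frame,
             horizon_frame = horizon_frame, stringsAsFactors = FALSE)
}

#' Classify progenies by proliferative capacity
#'
#' A progeny (the descendants of one founding cell) is a `slow` proliferator
#' with fewer than 8 cells at the Day-4 assessment (under three population
#' doublings), `fast` with more than 16 cells (over four doublings), and
#' `moderate` with 8-16 cells inclusive.
#'
#' @param counts named integer vector: cells per founder at the assessment
#'   frame (see [progeny_counts()]).
#' @return data.frame `founder_id`, `n_cells_at_day4`, `class`.
#' @export
classify_progeny <- function(counts) {
  n <- as.integer(counts)
  cls <- ifelse(n < 8L, "slow", ifelse(n > 16L, "fast", "moderate"))
  data.frame(founder_id = if (is.null(names(counts)))
    as.character(seq_along(counts)) else names(counts),
    n_cells_at_day4 = n, class = cls, stringsAsFactors = FALSE)
}

#' Flag asynchronous twin divisions
#'
#' Sibling cells born of the same division are `asynchronous` when their
#' lifetimes differ by strictly more than one dataset-wide standard
#' deviation of dividing-cell lifetime (0.27 d in typical BMSC data). Pairs
#' where either lifetime is undefined (founder or non-divider) are excluded.
#'
#' @param f a `lineage_forest`.
#' @param sd_d the SD threshold in days, or `"auto"` (default) to use the SD
#'   of all defined lifetimes in the forest.
#' @return data.frame `cell_1`, `cell_2`, `lifetime_1`, `lifetime_2`,
#'   `delta_d`, `asynchronous`, with the threshold in the `sd_d` attribute.
#' @export
classify_asynchrony <- function(f, sd_d = "auto") {
  stopifnot(inherits(f, "lineage_forest"))
  lt <- lifetimes(f)
  if (identical(sd_d, "auto")) {
    sd_d <- stats::sd(lt[!is.na(lt)])
    if (is.na(sd_d)) stop("cannot compute lifetime SD: fewer than 2 defined lifetimes")
  }
  tp <- twin_pairs(f)
  l1 <- lt[tp$cell_1]
  l2 <- lt[tp$cell_2]
  keep <- !is.na(l1) & !is.na(l2)
  out <- data.frame(
    cell_1 = tp$cell_1[keep], cell_2 = tp$cell_2[keep],
    lifetime_1 = unname(l1[keep]), lifetime_2 = unname(l2[keep]),
    delta_d = abs(unname(l1[keep]) - unname(l2[keep])),
    stringsAsFactors = FALSE
  )
  out$asynchronous <- out$delta_d > sd_d
  attr(out, "sd_d") <- sd_d
  out
}

#' Classify colony origin (single- vs multi-cell-derived)
#'
#' A colony is single-cell-derived (SCD) when exactly one original founder
#' (a root present from the first frame) has living descendants among the
#' colony members at the assessment frame, and multi-cell-derived (MCD)
#' otherwise. Roots whose track begins mid-experiment are cells that
#' migrated into the field; they set the `infiltrated` flag but do not
#' count as founders.
#'
#' @param f a `lineage_forest`.
#' @param members cell ids belonging to the colony at the assessment frame.
#' @param colony_id identifier carried through to the output.
#' @return data.frame `colony_id`, `n_founders`, `origin`, `infiltrated`.
#' @export
classify_origin <- function(f, members, colony_id = "colony") {
  stopifnot(inherits(f, "lineage_forest"))
  r <- f$records
  miss <- setdiff(members, r$cell_id)
  if (length(miss)) stop("unknown member cell id(s): ",
                         paste(miss, collapse = ", "))
  roots <- unique(unname(root_of(f)[as.character(members)]))
  first_frame <- min(r$birth_frame)
  orig <- roots[r$birth_frame[match(roots, r$cell_id)] == first_frame]
  late <- setdiff(roots, orig)
  n_founders <- length(orig)
  data.frame(
    colony_id = colony_id, n_founders = n_founders,
    origin = if (n_founders == 1L) "SCD" else "MCD",
    infiltrated = length(late) > 0L, stringsAsFactors = FALSE
  )
}

#' Colony predicate
#'
#' Full colony formation is defined as a group of at least 50 cells.
#'
#' @param n_cells cell count(s).
#' @return logical vector.
#' @export
is_colony <- function(n_cells) {
  n_cells >= 50
}

#' Degree-of-isolation score of a developing colony
#'
#' Scores 1-5 describe how long a colony developed before any non-colony
#' cell was observable, under the staged field-of-view (FOV) schedule of a
#' sparse CFU imaging experiment: a 1.7 x 1.3 mm montage from Day 0,
#' expanded to 2.6 x 2.1 mm at Day 2 and to 3.5 x 2.6 mm at Day 6.
#' \describe{
#'   \item{1}{foreign cells present in the initial FOV from the start;}
#'   \item{2}{foreign cells migrated into the initial FOV within two days;}
#'   \item{3}{foreign cells revealed by the Day-2 FOV expansion;}
#'   \item{4}{foreign cells migrated into the expanded FOV in Days 2-6;}
#'   \item{5}{no foreign cell until the Day-6 expansion (or later).}
#' }
#'
#' @param foreign_xy data.frame/matrix with columns `time_d`, `x_um`,
#'   `y_um`: position of the nearest foreign (non-colony) cell over time,
#'   relative to the colony centre. A single static position (one row,
#'   `time_d = 0`) covers the common case of a non-migrating neighbor.
#' @param colony_id identifier carried to the output.
#' @return data.frame `colony_id`, `score`, `first_visible_d` (`NA` when the
#'   foreign cell never becomes visible).
#' @export
isolation_score <- function(foreign_xy, colony_id = "colony") {
  fov <- data.frame(day = c(0, 2, 6),
                    w_um = c(1.7, 2.6, 3.5) * 1000,
                    h_um = c(1.3, 2.1, 2.6) * 1000)
  foreign_xy <- as.data.frame(foreign_xy)
  stopifnot(all(c("time_d", "x_um", "y_um") %in% names(foreign_xy)))
  fov_at <- function(t) fov[max(which(fov$day <= t)), ]
  vis <- vapply(seq_len(nrow(foreign_xy)), function(i) {
    fv <- fov_at(foreign_xy$time_d[i])
    abs(foreign_xy$x_um[i]) <= fv$w_um / 2 &&
      abs(foreign_xy$y_um[i]) <= fv$h_um / 2
  }, logical(1))
  # static positions persist: a point given at t is assumed present onward,
  # so also test it against the later, larger FOVs
  tmax <- max(foreign_xy$time_d)
  extra <- do.call(rbind, lapply(fov$day[fov$day > tmax], function(d) {
    last <- foreign_xy[nrow(foreign_xy), ]
    last$time_d <- d
    last
  }))
  if (!is.null(extra)) {
    vis <- c(vis, vapply(seq_len(nrow(extra)), function(i) {
      fv <- fov_at(extra$time_d[i])
      abs(extra$x_um[i]) <= fv$w_um / 2 && abs(extra$y_um[i]) <= fv$h_um / 2
    }, logical(1)))
    foreign_xy <- rbind(foreign_xy, extra)
  }
  tv <- foreign_xy$time_d[vis]
  if (!any(vis)) {
    score <- 5L
    first <- NA_real_
  } else {
    first <- min(tv)
    score <- if (first == 0) 1L
    else if (first < 2) 2L
    else if (first == 2) 3L
    else if (first < 6) 4L
    else 5L
  }
  data.frame(colony_id = colony_id, score = score, first_visible_d = first,
             stringsAsFactors = FALSE)
}
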