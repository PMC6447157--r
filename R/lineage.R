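#' Object-number tracking matrix
#'
#' The tracking exchange format for single-cell time-lapse analysis: an
#' integer matrix with one row per frame (time point) and one column per
#' unique cell. Entry `(t, c)` is the per-frame segmentation label (object
#' number) of cell `c` at frame `t`, and 0 when the cell does not exist.
#' A valid matrix has contiguous column supports and every mid-experiment
#' column ending matched by exactly two new columns at the next frame (a
#' division).
#'
#' @param values integer matrix (frames x cells), entries >= 0.
#' @param frames frame indices (default `1:nrow(values)`).
#' @param cell_ids unique cell identifiers (default column names or
#'   `1:ncol`).
#' @param frame_interval_min minutes between frames (default 15).
#' @param centroids optional data.frame (`frame`, `label`, `x_px`, `y_px`)
#'   with per-frame object centroids, used to disambiguate simultaneous
#'   divisions.
#' @return An object of class `object_matrix`.
#' @export
object_matrix <- function(values, frames = NULL, cell_ids = NULL,
                          frame_interval_min = 15, centroids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (any(values < 0, na.rm = TRUE)) stop("object numbers must be >= 0")
  if (any(is.na(values))) stop("object matrix entries must not be NA")
  if (is.null(frames)) frames <- seq_len(nrow(values))
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values)
    if (is.null(cell_ids)) cell_ids <- as.character(seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (length(cell_ids) != ncol(values)) stop("cell_ids length != ncol(values)")
  if (length(frames) != nrow(values)) stop("frames length != nrow(values)")
  dimnames(values) <- NULL
  structure(list(values = values, frames = as.integer(frames),
                 cell_ids = cell_ids,
                 frame_interval_min = frame_interval_min,
                 centroids = centroids),
            class = "object_matrix")
}

#' @export
print.object_matrix <- function(x, ...) {
  cat(sprintf("<object_matrix> %d frames x %d cells (%g min/frame)%s\n",
              nrow(x$values), ncol(x$values), x$frame_interval_min,
              if (is.null(x$centroids)) "" else ", with centroids"))
  invisible(x)
}

# first/last nonzero row index per column (NA-free; Inf/-Inf when empty)
column_supports <- function(vals) {
  nz <- vals != 0L
  first <- apply(nz, 2, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  last <- apply(nz, 2, function(z) if (any(z)) max(which(z)) else NA_integer_)
  data.frame(first = as.integer(first), last = as.integer(last))
}

#' Validate an object matrix for tracking errors
#'
#' Checks the two structural rules of the format: every column's support is a
#' contiguous block of frames (no internal zeros), and whenever columns end
#' at a mid-experiment frame `t`, exactly two new columns per ending column
#' begin at `t + 1` (each supposed division yields two daughters). All
#' findings are returned; validation never stops at the first problem.
#'
#' Finding kinds: `gap` (zero inside a support), `merge` (fewer new columns
#' at `t + 1` than divisions require), `orphan` (more new columns than
#' divisions can account for), `late_sibling` (a daughter matched only
#' within `sibling_slack` extra frames). Columns that begin at a frame with
#' no coincident column ending are treated as migrating-in founders, not
#' errors.
#'
#' @param m an [object_matrix()].
#' @param sibling_slack non-negative integer; allow daughters to first appear
#'   up to this many frames late (default 0, strict). Late matches are
#'   reported as `late_sibling` findings but do not count as merge/orphan.
#' @return data.frame with columns `kind`, `frame`, `cells`, `message`;
#'   zero rows when the matrix is clean.
#' @export
validate_matrix <- function(m, sibling_slack = 0L) {
  stopifnot(inherits(m, "object_matrix"))
  vals <- m$values
  sup <- column_supports(vals)
  out <- list()
  add <- function(kind, frame, cells, msg) {
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, frame = frame, cells = paste(cells, collapse = ","),
      message = msg, stringsAsFactors = FALSE)
  }

  empty <- is.na(sup$first)
  for (cc in which(empty)) {
    add("gap", NA_integer_, m$cell_ids[cc], "column has no nonzero entries")
  }

  # gaps: maximal zero runs strictly inside a support
  for (cc in which(!empty)) {
    seg <- vals[sup$first[cc]:sup$last[cc], cc]
    if (any(seg == 0L)) {
      z <- rle(seg == 0L)
      pos <- cumsum(c(0L, z$lengths[-length(z$lengths)])) + sup$first[cc]
      for (k in which(z$values)) {
        add("gap", m$frames[pos[k]], m$cell_ids[cc],
            sprintf("zero run of %d frame(s) inside support", z$lengths[k]))
      }
    }
  }

  n_frames <- nrow(vals)
  ends <- sup$last[!empty]
  boundary_frames <- sort(unique(ends[ends < n_frames]))
  matched_late <- rep(FALSE, ncol(vals))
  for (t in boundary_frames) {
    E <- which(!empty & sup$last == t)
    S <- which(!empty & sup$first == t + 1L)
    need <- 2L * length(E)
    got <- length(S)
    if (got < need && sibling_slack > 0L) {
      for (slack in seq_len(sibling_slack)) {
        late <- which(!empty & sup$first == t + 1L + slack & !matched_late)
        n_take <- min(length(late), need - got)
        if (n_take > 0L) {
          take <- late[seq_len(n_take)]
          matched_late[take] <- TRUE
          got <- got + n_take
          add("late_sibling", m$frames[t + 1L + slack], m$cell_ids[take],
              sprintf("daughter(s) first appear %d frame(s) late", slack))
        }
        if (got >= need) break
      }
    }
    if (got < need) {
      add("merge", m$frames[t], m$cell_ids[c(E, S)],
          sprintf("%d column(s) end but only %d new column(s) start (%d missing sibling(s))",
                  length(E), got, need - got))
    } else if (got > need) {
      add("orphan", m$frames[t + 1L], m$cell_ids[S],
          sprintf("%d new column(s) start but the %d coincident division(s) account for %d",
                  got, length(E), need))
    }
  }

  if (length(out) == 0L) {
    return(data.frame(kind = character(), frame = integer(),
                      cells = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Assign 2k daughters to k parents minimizing summed parent-daughter
# distance. Exact enumeration for k <= 4 parents, greedy otherwise.
assign_daughters <- function(dmat) {
  k <- nrow(dmat)
  nd <- ncol(dmat)
  stopifnot(nd == 2L * k)
  if (k == 1L) return(rep(1L, 2L))
  if (k <= 4L) {
    best <- NULL
    best_cost <- Inf
    recurse <- function(remaining, assign, cost) {
      if (cost >= best_cost) return()
      if (length(remaining) == 0L) {
        best <<- assign
        best_cost <<- cost
        return()
      }
      p <- (2L * k - length(remaining)) / 2L + 1L
      pairs <- utils::combn(remaining, 2L)
      for (j in seq_len(ncol(pairs))) {
        dd <- pairs[, j]
        a2 <- assign
        a2[dd] <- p
        recurse(setdiff(remaining, dd), a2,
                cost + dmat[p, dd[1L]] + dmat[p, dd[2L]])
      }
    }
    recurse(seq_len(nd), integer(nd), 0)
    return(best)
  }
  # greedy: repeatedly take the globally closest (parent, daughter) pair
  assign <- integer(nd)
  capacity <- rep(2L, k)
  dm <- dmat
  for (step in seq_len(nd)) {
    idx <- arrayInd(which.min(dm), dim(dm))
    p <- idx[1L]; d <- idx[2L]
    assign[d] <- p
    dm[, d] <- Inf
    capacity[p] <- capacity[p] - 1L
    if (capacity[p] == 0L) dm[p, ] <- Inf
  }
  assign
}

#' Build a lineage forest from an object matrix
#'
#' Reconstructs parent/daughter/twin relations, generations and birth and
#' division frames from the column structure of a validated tracking matrix.
#' Founders are the columns live at the first frame, plus columns that begin
#' at a frame where no column ends (cells migrating into the field; they
#' become roots with generation 1). When two or more divisions end at the
#' same frame the daughters are attributed to parents by proximity of the
#' parents' final centroids to the daughters' first centroids (an error is
#' raised if the matrix carries no centroids).
#'
#' @param m an [object_matrix()]; must validate cleanly (see
#'   [validate_matrix()]).
#' @param sibling_slack forwarded to [validate_matrix()]; with slack > 0,
#'   daughters first appearing up to that many frames late are linked to
#'   their division.
#' @return An object of class `lineage_forest`: list with `records` (one row
#'   per cell: `cell_id`, `parent_id`, `twin_id`, `generation`,
#'   `birth_frame`, `last_frame`, `divided`, `lifetime_d`), `roots`, and
#'   `frame_interval_min`. `lifetime_d` is `(last - birth + 1) * dt` in days,
#'   defined only for divided cells of generation >= 2 (the birth of a
#'   founder is not observed).
#' @export
build_forest <- function(m, sibling_slack = 0L) {
  stopifnot(inherits(m, "object_matrix"))
  errs <- validate_matrix(m, sibling_slack = sibling_slack)
  errs <- errs[errs$kind != "late_sibling", , drop = FALSE]
  if (nrow(errs) > 0L) {
    stop("object matrix has ", nrow(errs),
         " tracking error(s); run validate_matrix() for details")
  }
  vals <- m$values
  sup <- column_supports(vals)
  nc <- ncol(vals)
  n_frames <- nrow(vals)
  parent <- twin <- rep(NA_integer_, nc)

  centroid_of <- function(col, row) {
    if (is.null(m$centroids)) return(NULL)
    ce <- m$centroids
    hit <- ce$frame == m$frames[row] & ce$label == vals[row, col]
    if (!any(hit)) return(NULL)
    c(ce$x_px[hit][1L], ce$y_px[hit][1L])
  }

  boundary_frames <- sort(unique(sup$last[sup$last < n_frames]))
  for (t in boundary_frames) {
    E <- which(sup$last == t)
    S <- which(sup$first > t & sup$first <= t + 1L + sibling_slack)
    # keep only daughters belonging to this boundary (earliest wins)
    S <- S[order(sup$first[S])][seq_len(min(length(S), 2L * length(E)))]
    if (length(E) == 1L) {
      parent[S] <- E
      twin[S[1L]] <- S[2L]
      twin[S[2L]] <- S[1L]
    } else {
      pc <- lapply(E, function(cc) centroid_of(cc, t))
      dc <- lapply(S, function(cc) centroid_of(cc, sup$first[cc]))
      if (any(vapply(c(pc, dc), is.null, logical(1)))) {
        stop(sprintf(
          "ambiguous simultaneous divisions at frame %d require centroids",
          m$frames[t]))
      }
      dmat <- matrix(0, nrow = length(E), ncol = length(S))
      for (i in seq_along(E)) for (j in seq_along(S)) {
        dmat[i, j] <- sqrt(sum((pc[[i]] - dc[[j]])^2))
      }
      asg <- assign_daughters(dmat)
      for (i in seq_along(E)) {
        dd <- S[asg == i]
        parent[dd] <- E[i]
        twin[dd[1L]] <- dd[2L]
        twin[dd[2L]] <- dd[1L]
      }
    }
  }

  generation <- rep(NA_integer_, nc)
  roots <- which(is.na(parent))
  generation[roots] <- 1L
  # children appear later than parents, so one ordered pass suffices
  ord <- order(sup$first)
  for (cc in ord) {
    if (!is.na(parent[cc])) generation[cc] <- generation[parent[cc]] + 1L
  }

  divided <- vapply(seq_len(nc), function(cc) any(parent == cc, na.rm = TRUE),
                    logical(1))
  dt_d <- m$frame_interval_min / 1440
  lifetime <- ifelse(divided & generation >= 2L,
                     (sup$last - sup$first + 1L) * dt_d, NA_real_)

  records <- data.frame(
    cell_id = m$cell_ids,
    parent_id = ifelse(is.na(parent), NA_character_, m$cell_ids[parent]),
    twin_id = ifelse(is.na(twin), NA_character_, m$cell_ids[twin]),
    generation = generation,
    birth_frame = m$frames[sup$first],
    last_frame = m$frames[sup$last],
    divided = divided,
    lifetime_d = lifetime,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, roots = m$cell_ids[roots],
                 frame_interval_min = m$frame_interval_min),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> %d cells, %d root(s), %d division(s)\n",
              nrow(x$records), length(x$roots), sum(x$records$divided)))
  invisible(x)
}

#' Per-cell lifetimes in days
#'
#' A cell's lifetime is the span from its birth (the parental division) to
#' its own division, counted inclusively: `(last_frame - birth_frame + 1)`
#' frames. It is undefined (`NA`) for founders - whose birth was not
#' observed - and for cells that never divide.
#'
#' @param f a `lineage_forest`.
#' @return Named numeric vector (days), one entry per cell.
#' @export
lifetimes <- function(f) {
  stopifnot(inherits(f, "lineage_forest"))
  stats::setNames(f$records$lifetime_d, f$records$cell_id)
}

#' Twin (sibling) pairs of a forest
#'
#' @param f a `lineage_forest`.
#' @return data.frame with columns `cell_1`, `cell_2`, one unordered pair
#'   per division.
#' @export
twin_pairs <- function(f) {
  stopifnot(inherits(f, "lineage_forest"))
  r <- f$records
  has <- !is.na(r$twin_id)
  a <- r$cell_id[has]
  b <- r$twin_id[has]
  keep <- pmin(a, b) == a  # each unordered pair once
  data.frame(cell_1 = a[keep], cell_2 = b[keep], stringsAsFactors = FALSE)
}

# root ancestor of every cell
root_of <- function(f) {
  r <- f$records
  idx <- stats::setNames(seq_len(nrow(r)), r$cell_id)
  root <- r$cell_id
  repeat {
    p <- r$parent_id[idx[root]]
    done <- is.na(p)
    if (all(done)) break
    root[!done] <- p[!done]
  }
  stats::setNames(root, r$cell_id)
}

#' Living-cell counts per founding cell at a frame
#'
#' @param f a `lineage_forest`.
#' @param frame frame index.
#' @return Named integer vector: for each root (founder), the number of its
#'   descendants (including itself) alive at `frame`.
#' @export
progeny_counts <- function(f, frame) {
  stopifnot(inherits(f, "lineage_forest"))
  r <- f$records
  alive <- r$birth_frame <= frame & r$last_frame >= frame
  roots <- root_of(f)
  counts <- table(factor(roots[alive], levels = f$roots))
  stats::setNames(as.integer(counts), names(counts))
}

#' Censoring-aware summary of dividing-cell lifetimes
#'
#' The naive mean lifetime over the cells observed to divide is biased low:
#' cells born near the end of the tracked window only enter the sample when
#' their lifetime happens to be short (right-censoring of the long-lived).
#' This summary therefore restricts to dividing cells whose birth leaves a
#' full observation margin before the end of tracking, so that essentially
#' any lifetime would have been observed. By default the margin is the
#' longest lifetime observed anywhere in the forest.
#'
#' @param f a `lineage_forest`, or a list of forests pooled together.
#' @param margin_d observation margin in days (default: the maximum
#'   observed lifetime across the input).
#' @return list `mean_d`, `sd_d`, `n`, `margin_d`, `n_censored_excluded`.
#' @export
dividing_lifetime_stats <- function(f, margin_d = NULL) {
  if (inherits(f, "lineage_forest")) f <- list(f)
  stopifnot(all(vapply(f, inherits, logical(1), "lineage_forest")))
  recs <- lapply(f, function(ff) {
    r <- ff$records
    r$end_of_track <- max(r$last_frame)
    r$dt_d <- ff$frame_interval_min / 1440
    r
  })
  r <- do.call(rbind, recs)
  lt <- r$lifetime_d
  if (all(is.na(lt))) return(list(mean_d = NA_real_, sd_d = NA_real_,
                                  n = 0L, margin_d = NA_real_,
                                  n_censored_excluded = 0L))
  if (is.null(margin_d)) margin_d <- max(lt, na.rm = TRUE)
  margin_fr <- margin_d / r$dt_d
  ok <- !is.na(lt) & (r$birth_frame - 1) <= (r$end_of_track - margin_fr)
  list(mean_d = mean(lt[ok]), sd_d = stats::sd(lt[ok]), n = sum(ok),
       margin_d = margin_d,
       n_censored_excluded = sum(!is.na(lt)) - sum(ok))
}
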