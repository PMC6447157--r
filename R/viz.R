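#' Lineage-tree drawing specification
#'
#' Lays out a lineage forest as pure drawing data (no graphics device):
#' each cell is a vertical polyline at a fixed x position spanning its
#' birth-to-last frames, with per-frame line width proportional to the
#' cell's spread area and color index equal to its generation; each
#' division contributes a horizontal connector from the parent to its two
#' daughters. Leaves are placed at consecutive integer x positions
#' (depth-first order within each root), internal cells at the mean of
#' their children, the classic tree layout.
#'
#' @param f a `lineage_forest`.
#' @param tracks optional data.frame `cell_id`, `frame`, `area_um2`; when
#'   given, polylines carry per-frame `width` (sqrt of area, so line area
#'   scales with spread area).
#' @return list of class `tree_spec`: `polylines` (data.frame `cell_id`,
#'   `frame`, `x`, `width`, `generation`), `connectors` (`parent_id`,
#'   `frame`, `x_parent`, `x_child_1`, `x_child_2`), `n_branch_points`.
#' @export
render_tree <- function(f, tracks = NULL) {
  stopifnot(inherits(f, "lineage_forest"))
  r <- f$records
  idx <- stats::setNames(seq_len(nrow(r)), r$cell_id)
  children_of <- split(r$cell_id[!is.na(r$parent_id)],
                       r$parent_id[!is.na(r$parent_id)])
  xpos <- stats::setNames(rep(NA_real_, nrow(r)), r$cell_id)
  leaf_counter <- 0
  assign_x <- function(id) {
    ch <- children_of[[id]]
    if (is.null(ch)) {
      leaf_counter <<- leaf_counter + 1
      xpos[id] <<- leaf_counter
    } else {
      for (c1 in ch) assign_x(c1)
      xpos[id] <<- mean(xpos[ch])
    }
  }
  for (rt in f$roots) assign_x(rt)

  width_of <- function(id, frames) {
    if (is.null(tracks)) return(rep(1, length(frames)))
    tc <- tracks[tracks$cell_id == id, ]
    sqrt(tc$area_um2[match(frames, tc$frame)])
  }
  poly <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    fr <- r$birth_frame[i]:r$last_frame[i]
    data.frame(cell_id = r$cell_id[i], frame = fr,
               x = unname(xpos[r$cell_id[i]]),
               width = width_of(r$cell_id[i], fr),
               generation = r$generation[i], stringsAsFactors = FALSE)
  }))
  div <- r[r$divided, , drop = FALSE]
  connectors <- do.call(rbind, lapply(div$cell_id, function(id) {
    ch <- children_of[[id]]
    data.frame(parent_id = id, frame = r$last_frame[idx[id]] + 1L,
               x_parent = unname(xpos[id]),
               x_child_1 = unname(xpos[ch[1L]]),
               x_child_2 = unname(xpos[ch[2L]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(connectors)) {
    connectors <- data.frame(parent_id = character(), frame = integer(),
                             x_parent = numeric(), x_child_1 = numeric(),
                             x_child_2 = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(polylines = poly, connectors = connectors,
                 n_branch_points = nrow(div)),
            class = "tree_spec")
}

#' Colony glyph drawing specification
#'
#' Encodes a colony snapshot as pure drawing data, the standard colony
#' glyph: one filled circle per living cell at its position, radius
#' proportional to the square root of its spread area (so circle area
#' tracks spread area), fill color indexed by generation, and a `/` mark on
#' senescent cells; around the colony, one ring per originating progeny
#' whose line style encodes proliferative capacity (dashed = slow,
#' dotted = moderate, solid = fast).
#'
#' @param snapshot data.frame of the living cells at the chosen frame:
#'   `cell_id`, `x_um`, `y_um`, `area_um2`, `generation`, and optionally
#'   `colony_id` (progeny membership).
#' @param classes optional data.frame `founder_id`, `class` (see
#'   [classify_progeny()]); one ring per founder.
#' @param fates optional named character vector of fate labels; cells with
#'   `"senescent"` get the mark.
#' @return list of class `glyph_spec`: `circles` (`cell_id`, `x`, `y`,
#'   `radius`, `generation`, `senescent_mark`), `rings` (`progeny_id`,
#'   `class`, `linetype`, `x`, `y`, `radius`).
#' @export
render_glyph <- function(snapshot, classes = NULL, fates = NULL) {
  stopifnot(all(c("cell_id", "x_um", "y_um", "area_um2", "generation")
                %in% names(snapshot)))
  sen <- rep(FALSE, nrow(snapshot))
  if (!is.null(fates)) {
    sen <- unname(fates[as.character(snapshot$cell_id)] == "senescent")
    sen[is.na(sen)] <- FALSE
  }
  circles <- data.frame(
    cell_id = as.character(snapshot$cell_id),
    x = snapshot$x_um, y = snapshot$y_um,
    radius = sqrt(snapshot$area_um2 / pi),
    generation = snapshot$generation,
    senescent_mark = sen, stringsAsFactors = FALSE
  )
  linetype_of <- c(slow = "dashed", moderate = "dotted", fast = "solid")
  rings <- data.frame(progeny_id = character(), class = character(),
                      linetype = character(), x = numeric(), y = numeric(),
                      radius = numeric(), stringsAsFactors = FALSE)
  if (!is.null(classes) && nrow(classes) > 0L) {
    cx <- mean(snapshot$x_um); cy <- mean(snapshot$y_um)
    r0 <- max(sqrt((snapshot$x_um - cx)^2 + (snapshot$y_um - cy)^2) +
                circles$radius)
    rings <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i) {
      data.frame(progeny_id = classes$founder_id[i],
                 class = classes$class[i],
                 linetype = unname(linetype_of[classes$class[i]]),
                 x = cx, y = cy, radius = r0 * (1.05 + 0.08 * (i - 1)),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(circles = circles, rings = rings), class = "glyph_spec")
}
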