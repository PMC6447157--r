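#' @name colonytrack-io
#' @title File formats: tracking matrices, label stacks, forests, tables
#'
#' @description
#' All readers/writers round-trip losslessly. CSV files use comma
#' separators, UTF-8, a header row and `.` decimals; missing or masked
#' values are written as empty fields. Label-image stacks are multi-page
#' 16-bit TIFF, one page per frame.
NULL

#' Write / read an object matrix as CSV
#'
#' The first column is the frame index; the remaining headers are the cell
#' ids. An optional sidecar (`<path>.centroids.csv`) carries per-frame
#' object centroids.
#'
#' @param m an [object_matrix()].
#' @param path output CSV path.
#' @param centroids write the centroid sidecar when the matrix has
#'   centroids (default TRUE).
#' @return `path`, invisibly.
#' @export
write_object_matrix <- function(m, path, centroids = TRUE) {
  stopifnot(inherits(m, "object_matrix"))
  df <- data.frame(frame = m$frames, m$values, check.names = FALSE)
  names(df) <- c("frame", m$cell_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  if (centroids && !is.null(m$centroids)) {
    utils::write.csv(m$centroids, paste0(path, ".centroids.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_object_matrix
#' @param frame_interval_min minutes per frame of the stored matrix.
#' @export
read_object_matrix <- function(path, frame_interval_min = 15) {
  check_rectangular_csv(path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (names(df)[1L] != "frame") stop("first column must be 'frame'")
  cen_path <- paste0(path, ".centroids.csv")
  cen <- if (file.exists(cen_path)) utils::read.csv(cen_path) else NULL
  object_matrix(as.matrix(df[, -1L, drop = FALSE]), frames = df$frame,
                cell_ids = names(df)[-1L],
                frame_interval_min = frame_interval_min, centroids = cen)
}

# error (naming the row) on ragged CSV input
check_rectangular_csv <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("malformed CSV '", path, "': row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  invisible(TRUE)
}

#' Write / read a lineage forest as JSON
#'
#' @param f a `lineage_forest`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(f, path) {
  stopifnot(inherits(f, "lineage_forest"))
  jsonlite::write_json(
    list(frame_interval_min = f$frame_interval_min, roots = f$roots,
         records = f$records),
    path, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest_json
#' @export
read_forest_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- obj$records
  for (col in c("parent_id", "twin_id")) {
    if (!col %in% names(rec)) rec[[col]] <- NA_character_
  }
  if (!"lifetime_d" %in% names(rec)) rec$lifetime_d <- NA_real_
  rec$lifetime_d <- as.numeric(rec$lifetime_d)
  structure(list(records = rec, roots = obj$roots,
                 frame_interval_min = obj$frame_interval_min),
            class = "lineage_forest")
}

#' Write / read a label-image stack as multi-page 16-bit TIFF
#'
#' @param stack list of integer label matrices (labels < 65536).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  if (any(vapply(stack, max, numeric(1)) > 65535)) {
    stop("labels exceed the 16-bit range")
  }
  pages <- lapply(stack, function(m) {
    mm <- m / 65535
    attributes(mm) <- list(dim = dim(m))
    mm
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_stack
#' @export
read_label_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) {
    out <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
    out
  })
}

#' Write / read a feature table (CSV, masked values as empty fields)
#'
#' @param tab a feature table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  check_rectangular_csv(path)
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         na.strings = "")
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Write / read a simulation or pipeline configuration as YAML
#'
#' @param cfg a [simulation_config()] or [pipeline_config()] list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(cfg, path) {
  cls <- class(cfg)
  yaml::write_yaml(c(unclass(cfg), list(.class = cls[1L])), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "sim_config")) {
    do.call(simulation_config, obj)
  } else if (identical(cls, "pipeline_config")) {
    do.call(pipeline_config, obj)
  } else {
    obj
  }
}
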