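#' Binary-group Welch t-tests with per-filter Bonferroni correction
#'
#' Compares every (numeric) property between the two levels of a binary
#' grouping (senescent vs proliferative, fast- vs slow-progeny membership,
#' asynchronous vs synchronous twins, ...) with an unequal-variance
#' two-sample t-test. The significance threshold is Bonferroni-corrected
#' *per filter family*: `alpha` divided by the number of properties sharing
#' that property's validity filter (e.g. the three parent-derived
#' properties are tested against `0.05 / 3`).
#'
#' @param tab a feature table; its `filters` attribute defines the filter
#'   families (absent filters count all tested properties as one family).
#' @param grouping logical/factor with two levels, length `nrow(tab)`;
#'   `NA` rows are dropped.
#' @param properties columns to test (default: all numeric).
#' @param alpha family-wise level per filter (default 0.05).
#' @return data.frame: `property`, `filter_id`, `n_1`, `n_2`, `mean_1`,
#'   `mean_2`, `t`, `p_value`, `threshold`, `significant`.
#' @export
binary_ttests <- function(tab, grouping, properties = NULL, alpha = 0.05) {
  if (is.null(properties)) {
    properties <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  g <- as.factor(grouping)
  if (nlevels(droplevels(g[!is.na(g)])) != 2L) {
    stop("grouping must have exactly two observed levels")
  }
  g <- droplevels(g)
  lev <- levels(g)
  filters <- attr(tab, "filters")
  fid <- if (is.null(filters)) rep("none", length(properties)) else
    unname(ifelse(is.na(filters[properties]), "none", filters[properties]))
  fam_size <- table(fid)

  rows <- lapply(seq_along(properties), function(k) {
    p <- properties[k]
    v <- tab[[p]]
    x1 <- v[g == lev[1L] & !is.na(g)]
    x2 <- v[g == lev[2L] & !is.na(g)]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    thr <- alpha / fam_size[[fid[k]]]
    if (length(x1) < 2L || length(x2) < 2L ||
        (stats::sd(x1) == 0 && stats::sd(x2) == 0)) {
      return(data.frame(property = p, filter_id = fid[k],
                        n_1 = length(x1), n_2 = length(x2),
                        mean_1 = mean(x1), mean_2 = mean(x2),
                        t = NA_real_, p_value = NA_real_, threshold = thr,
                        significant = FALSE, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x1, x2, var.equal = FALSE)
    data.frame(property = p, filter_id = fid[k],
               n_1 = length(x1), n_2 = length(x2),
               mean_1 = mean(x1), mean_2 = mean(x2),
               t = unname(tt$statistic), p_value = tt$p.value,
               threshold = thr,
               significant = tt$p.value < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generation-area trend per progeny
#'
#' For each progeny (descendants of one founder), the Spearman correlation
#' between cell generation and the early-lifetime average spread area
#' (`avg_area_first_083d`). Most progenies produce smaller cells with each
#' generation, so the typical trend is negative.
#'
#' @param tab a feature table with `generation`, `avg_area_first_083d` and
#'   `colony_id` columns.
#' @param by grouping column (default `"colony_id"`).
#' @return data.frame `founder_id`, `r_s`, `p_value`, `n_cells`,
#'   `degenerate` (no variance in either variable).
#' @export
generation_area_trend <- function(tab, by = "colony_id") {
  stopifnot(all(c("generation", "avg_area_first_083d", by) %in% names(tab)))
  groups <- split(seq_len(nrow(tab)), tab[[by]])
  rows <- lapply(names(groups), function(gid) {
    i <- groups[[gid]]
    sp <- spearman_rs(tab$generation[i], tab$avg_area_first_083d[i])
    data.frame(founder_id = gid, r_s = sp$r_s, p_value = sp$p_value,
               n_cells = sp$n,
               degenerate = isTRUE(sp$degenerate), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generation dispersion per colony
#'
#' Sample standard deviation of the generation numbers of the cells alive
#' at a frame, per root (founder). A perfectly synchronous colony scores 0;
#' asynchronous divisions and senescence spread the generations out.
#'
#' @param f a `lineage_forest`.
#' @param frame assessment frame.
#' @return Named numeric vector, one entry per root: the sample SD of the
#'   living cells' generations (0 when they all share one generation,
#'   including a lone cell), `NA` for roots with no living cells.
#' @export
generation_dispersion <- function(f, frame) {
  stopifnot(inherits(f, "lineage_forest"))
  r <- f$records
  alive <- r$birth_frame <= frame & r$last_frame >= frame
  roots <- root_of(f)
  vapply(f$roots, function(rt) {
    gg <- r$generation[alive & roots[r$cell_id] == rt]
    if (length(gg) == 0L) return(NA_real_)
    if (length(gg) == 1L) return(0)
    stats::sd(gg)
  }, numeric(1))
}

#' PCA embedding with k-means clustering of a feature table
#'
#' Drops rows with any masked (NA) value in the selected property set,
#' z-score normalizes each column, and runs principal component analysis.
#' Cluster labels come from k-means with `k = round(sqrt(N / 2))` by
#' default (N retained rows) and a fixed, documented seed with multiple
#' restarts.
#'
#' @param tab feature table / data.frame.
#' @param properties columns to embed (default: all numeric).
#' @param k cluster count, or `"auto"`.
#' @param seed k-means seed (default 1).
#' @param nstart k-means restarts (default 10).
#' @return list of class `embedding_result`: `scores` (rows x PCs),
#'   `loadings`, `explained_variance` (eigenvalues; they sum to the number
#'   of retained columns), `cluster`, `k`, `rows_used`, `properties_used`.
#' @export
pca_embed <- function(tab, properties = NULL, k = "auto", seed = 1L,
                      nstart = 10L) {
  if (is.null(properties)) {
    properties <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  X <- as.matrix(as.data.frame(tab)[, properties, drop = FALSE])
  rows_used <- which(stats::complete.cases(X))
  X <- X[rows_used, , drop = FALSE]
  if (nrow(X) < 3L) stop("fewer than 3 complete rows for PCA")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  N <- nrow(X)
  if (identical(k, "auto")) k <- max(1L, as.integer(round(sqrt(N / 2))))
  k <- min(k, N - 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  structure(list(
    scores = pc$x, loadings = pc$rotation,
    explained_variance = pc$sdev^2,
    cluster = km$cluster, k = k, rows_used = rows_used,
    properties_used = colnames(X)
  ), class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf(
    "<embedding_result> %d cells x %d properties; PC1 %.1f%%, PC2 %.1f%%; k = %d\n",
    nrow(x$scores), length(x$properties_used),
    100 * ev[1] / sum(ev), 100 * ev[2] / sum(ev), x$k))
  invisible(x)
}
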