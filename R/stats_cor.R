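#' Spearman rank correlation with small-sample exact p-value
#'
#' Tie-corrected Spearman coefficient: the Pearson correlation of midranks.
#' The p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom for
#' `n >= 10`, and the exact permutation distribution (all `n!` orderings of
#' one variable, two-sided: `P(|r_perm| >= |r_obs|)`) for `n <= 9`, so that
#' small-progeny screens do not rely on an asymptotic approximation.
#'
#' @param x,y numeric vectors; pairs with `NA` in either are dropped.
#' @return list `r_s`, `p_value`, `n`. `r_s` is `NA` (with `p_value` 1 and
#'   `degenerate = TRUE`) when either variable has no variance.
#' @examples
#' spearman_rs(1:5, c(1, 3, 2, 5, 4))  # r_s = 0.8
#' @export
spearman_rs <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(list(r_s = NA_real_, p_value = NA_real_, n = n,
                degenerate = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(r_s = NA_real_, p_value = 1, n = n, degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  if (n <= 9L) {
    p <- spearman_perm_p(rx, ry)
  } else {
    r_c <- min(1 - 1e-15, max(-1 + 1e-15, r))
    tt <- r_c * sqrt((n - 2) / (1 - r_c^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r_s = r, p_value = p, n = n, degenerate = FALSE)
}

# exact two-sided permutation p for the rank correlation (n <= 9)
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  P <- all_permutations(n)
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  # r for every permutation of y
  num <- matrix(cy[P], nrow = nrow(P)) %*% cx
  r_all <- as.numeric(num) / denom
  r_obs <- sum(cx * cy) / denom
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# matrix of all permutations of 1:n (n! x n), memoized
perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  P <- if (n == 1L) matrix(1L, 1, 1) else {
    sub <- all_permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, ifelse(sub >= k, sub + 1L, sub))
    }))
  }
  storage.mode(P) <- "integer"
  perm_cache[[key]] <- P
  P
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons.
#' @return `alpha / m`; e.g. 276 pairwise comparisons at 0.05 give 1.8e-4.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Filtered pairwise Spearman correlation screen
#'
#' Computes the Spearman coefficient and p-value for every pair of
#' properties in a feature table, using pairwise-complete observations so
#' that each property's validity mask (NA entries; see
#' [build_feature_table()]) automatically filters out cells whose value is
#' not representative (e.g. undefined lifetimes). Pairs are classified
#' against the Bonferroni-corrected threshold `alpha / m`, with `m` the
#' number of pairs evaluated: `pass_both` when the p-value beats the
#' corrected threshold (and `|r_s|` exceeds `r_critical` when one is
#' supplied), `p_only` when only the uncorrected `alpha` is beaten, `none`
#' otherwise.
#'
#' @param tab a feature table (or any data.frame); non-numeric columns are
#'   ignored.
#' @param properties columns to include (default: all numeric).
#' @param alpha uncorrected level (default 0.05).
#' @param r_critical optional critical value of `|r_s|` (published tables
#'   give 0.619 for n = 14 whole-colony screens); not derived internally.
#' @return list of class `correlation_report`: `pairs` (data.frame
#'   `property_1`, `property_2`, `r_s`, `p_value`, `n_used`, `filter_ids`,
#'   `highlight`), `alpha`, `m`, `bonferroni_p`, `r_critical`, and the
#'   symmetric matrices `r_matrix` / `p_matrix`.
#' @export
correlation_matrix <- function(tab, properties = NULL, alpha = 0.05,
                               r_critical = NULL) {
  num <- vapply(tab, is.numeric, logical(1))
  if (is.null(properties)) properties <- names(tab)[num]
  stopifnot(all(properties %in% names(tab)))
  filters <- attr(tab, "filters")
  p_n <- length(properties)
  if (p_n < 2L) stop("need at least two properties")
  m <- choose(p_n, 2L)
  bonf <- bonferroni_threshold(alpha, m)

  pairs <- utils::combn(properties, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    p1 <- pairs[1L, k]; p2 <- pairs[2L, k]
    x <- tab[[p1]]; y <- tab[[p2]]
    n_used <- sum(stats::complete.cases(x, y))
    sp <- if (n_used >= 3L) spearman_rs(x, y) else
      list(r_s = NA_real_, p_value = NA_real_, n = n_used)
    fid <- if (is.null(filters)) NA_character_ else
      paste(unique(c(filters[[p1]], filters[[p2]])), collapse = "+")
    data.frame(property_1 = p1, property_2 = p2, r_s = sp$r_s,
               p_value = sp$p_value, n_used = n_used, filter_ids = fid,
               stringsAsFactors = FALSE)
  })
  pr <- do.call(rbind, rows)
  pass_r <- if (is.null(r_critical)) TRUE else
    !is.na(pr$r_s) & abs(pr$r_s) >= r_critical
  pr$highlight <- ifelse(
    !is.na(pr$p_value) & pr$p_value <= bonf & pass_r, "pass_both",
    ifelse(!is.na(pr$p_value) & pr$p_value < alpha, "p_only", "none"))

  r_mat <- p_mat <- matrix(NA_real_, p_n, p_n,
                           dimnames = list(properties, properties))
  diag(r_mat) <- 1
  for (k in seq_len(nrow(pr))) {
    i <- pr$property_1[k]; j <- pr$property_2[k]
    r_mat[i, j] <- r_mat[j, i] <- pr$r_s[k]
    p_mat[i, j] <- p_mat[j, i] <- pr$p_value[k]
  }
  structure(list(pairs = pr, alpha = alpha, m = m, bonferroni_p = bonf,
                 r_critical = r_critical, r_matrix = r_mat,
                 p_matrix = p_mat),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "<correlation_report> %d pairs, alpha %g, Bonferroni p %.3g; %d pass_both, %d p_only\n",
    x$m, x$alpha, x$bonferroni_p, sum(x$pairs$highlight == "pass_both"),
    sum(x$pairs$highlight == "p_only")))
  invisible(x)
}
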