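# Cohort-level stratification: feature screening (z-scores, VIF, log
# transforms), 2-D manifold embedding, density clustering with a noise
# label, and cluster quality.

#' z-score feature columns
#'
#' Centres each column to mean 0 and scales to standard deviation 1 using
#' the population convention (divide by n, not n-1), so that a 3-point
#' column (1, 2, 3) maps to (-1.2247, 0, 1.2247). Idempotent to floating
#' tolerance.
#'
#' @param table Data frame.
#' @param columns Character vector of numeric columns to standardise.
#' @return `table` with the named columns standardised.
#' @export
zscore <- function(table, columns) {
  stopifnot(is.data.frame(table), all(columns %in% names(table)))
  n <- nrow(table)
  for (col in columns) {
    x <- table[[col]]
    if (!is.numeric(x)) stop_eyec("column ", col, " is not numeric")
    s <- sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s == 0) {
      stop_eyec("column ", col, " has zero standard deviation")
    }
    table[[col]] <- (x - mean(x)) / s
  }
  table
}

#' Variance inflation factors
#'
#' For each listed column, regresses it on the remaining listed columns
#' (with intercept) and reports `VIF = 1 / (1 - R^2)`. Values above 5 flag
#' high multicollinearity (e.g. an event count and the event rate over
#' near-constant session lengths). Exactly collinear columns give `Inf`.
#'
#' @param table Data frame.
#' @param columns Character vector of at least two numeric columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(table, columns) {
  stopifnot(is.data.frame(table), all(columns %in% names(table)),
            length(columns) >= 2L)
  if (nrow(table) <= length(columns) + 1L) {
    stop_eyec("need more rows than columns + 1 for VIF")
  }
  out <- vapply(columns, function(col) {
    fit <- lm(stats::reformulate(setdiff(columns, col), response = col),
              data = table)
    # summary.lm warns on an essentially perfect fit; exact collinearity
    # is a case this function defines (VIF = Inf), not an anomaly
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  setNames(out, columns)
}

#' Logarithmic transform of skewed feature columns
#'
#' Applies the natural log to each listed column. Columns containing zeros
#' use `log1p` instead (recorded in the `"log_shifted"` attribute of the
#' result); negative values are an error.
#'
#' @param table Data frame.
#' @param columns Columns to transform.
#' @return `table` with transformed columns and attribute `log_shifted`
#'   naming the columns that used the +1 shift.
#' @export
log_transform <- function(table, columns) {
  stopifnot(is.data.frame(table), all(columns %in% names(table)))
  shifted <- character(0)
  for (col in columns) {
    x <- table[[col]]
    if (any(x < 0, na.rm = TRUE)) {
      stop_eyec("column ", col, " has negative values; cannot log-transform")
    }
    if (any(x == 0, na.rm = TRUE)) {
      table[[col]] <- log1p(x)
      shifted <- c(shifted, col)
    } else {
      table[[col]] <- log(x)
    }
  }
  attr(table, "log_shifted") <- shifted
  table
}

#' 2-D UMAP embedding of cohort features
#'
#' Embeds the (standardised) feature columns into two dimensions with
#' UMAP. The defaults — 5 nearest neighbours and a minimum distance of
#' 0 — favour tight local clumps, which suits subsequent density
#' clustering. The layout is stochastic, so a seed is required; the same
#' table and seed give identical coordinates.
#'
#' @param table Data frame.
#' @param columns Feature columns to embed.
#' @param n_neighbors Neighbourhood size (default 5); must be smaller than
#'   the number of rows.
#' @param min_dist Minimum embedded distance (default 0).
#' @param seed Integer seed.
#' @return Numeric matrix with one `(x, y)` row per table row.
#' @export
embed_2d <- function(table, columns, n_neighbors = 5, min_dist = 0,
                     seed = 1) {
  stopifnot(is.data.frame(table), all(columns %in% names(table)),
            is_count(seed))
  x <- as.matrix(table[columns])
  if (nrow(x) <= n_neighbors) {
    stop_eyec("need more rows (", nrow(x), ") than n_neighbors (",
              n_neighbors, ")")
  }
  emb <- with_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               n_components = 2, n_threads = 1, n_sgd_threads = 1,
               batch = FALSE)
  )
  colnames(emb) <- c("x", "y")
  emb
}

#' Density clustering of an embedding, with silhouette
#'
#' Clusters 2-D embedded points with [hdbscan()]; scattered background
#' points receive the noise label -1. The silhouette coefficient is
#' computed in the embedded space over non-noise points only, and is
#' defined only when at least two clusters are found.
#'
#' @param embedding Matrix from [embed_2d()] (or any numeric matrix).
#' @param min_cluster_size Minimum cluster size (default 10, i.e. twice
#'   the number of clustering features when five features are used).
#' @return List of class `eyec_clusters` with `labels`, `n_clusters`,
#'   `n_noise`, `silhouette` (NA when undefined) and `embedding`.
#' @export
cluster_density <- function(embedding, min_cluster_size = 10) {
  embedding <- as.matrix(embedding)
  fit <- hdbscan(embedding, min_cluster_size = min_cluster_size)
  labels <- fit$labels
  keep <- labels >= 0
  sil <- NA_real_
  if (fit$n_clusters >= 2L) {
    s <- cluster::silhouette(labels[keep], stats::dist(embedding[keep, ,
                                                                 drop = FALSE]))
    sil <- mean(s[, "sil_width"])
  }
  structure(list(labels = labels, n_clusters = fit$n_clusters,
                 n_noise = sum(!keep), silhouette = sil,
                 embedding = embedding),
            class = "eyec_clusters")
}

#' @export
print.eyec_clusters <- function(x, ...) {
  cat(sprintf("<eyec_clusters n=%d clusters=%d noise=%d silhouette=%s>\n",
              length(x$labels), x$n_clusters, x$n_noise,
              ifelse(is.na(x$silhouette), "NA",
                     sprintf("%.3f", x$silhouette))))
  invisible(x)
}

#' Multiple linear regression of a clinical score on eye-contact features
#'
#' Ordinary least squares with intercept, reporting the coefficient table,
#' the coefficient of determination, and the overall F test.
#'
#' @param table Data frame (typically standardised).
#' @param response Name of the dependent column.
#' @param predictors Character vector of predictor columns.
#' @return List with `coefficients` (estimate, se, t, p per term),
#'   `r_squared`, `f_statistic`, `df`, `p_value`, and the underlying `lm`
#'   fit.
#' @export
mlr <- function(table, response, predictors) {
  stopifnot(is.data.frame(table), response %in% names(table),
            all(predictors %in% names(table)))
  if (nrow(table) <= length(predictors) + 1L) {
    stop_eyec("need more rows than predictors + 1")
  }
  fit <- lm(stats::reformulate(predictors, response = response), data = table)
  if (fit$rank < length(predictors) + 1L) {
    stop_eyec("rank-deficient design (exactly collinear predictors)")
  }
  s <- summary(fit)
  fstat <- s$fstatistic
  list(coefficients = as.data.frame(s$coefficients),
       r_squared = s$r.squared,
       f_statistic = unname(fstat[1]),
       df = unname(fstat[2:3]),
       p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       fit = fit)
}
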