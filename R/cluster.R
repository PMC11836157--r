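#' Jaccard distance matrix on binary attribute data
#'
#' For two 0/1 rows the Jaccard distance is one minus shared positives over
#' total positives, computed over the columns where at least one of the pair
#' has a 1. A pair whose union is empty (two all-zero rows) is defined to
#' have distance 0 — identical absence profiles — and such pairs are flagged
#' via a warning.
#'
#' @param binary_table Data frame or matrix of 0/1 dummy variables (as built
#'   by [categorize()]); no missing cells allowed in the used columns.
#' @return A [stats::dist] object with values in `[0, 1]`.
#' @export
jaccard_distance_matrix <- function(binary_table) {
  x <- as.matrix(binary_table)
  if (anyNA(x)) stop("binary table contains missing cells; filter or impute upstream", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("binary table must contain only 0/1 values", call. = FALSE)
  inter <- x %*% t(x)
  pos <- rowSums(x)
  union <- outer(pos, pos, "+") - inter
  d <- 1 - inter / union
  if (any(union == 0)) {
    warning("pair(s) of all-zero rows: Jaccard distance defined as 0", call. = FALSE)
    d[union == 0] <- 0
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Euclidean distance matrix on numeric trip variables
#'
#' Pairwise L2 distances on raw, unstandardised columns (travel time,
#' residence time and gain keep their native minutes/Euro units, matching
#' the clustering of the key model variables). Set `standardize = TRUE` to
#' scale columns to unit variance first.
#'
#' @param numeric_table Data frame or matrix of complete numeric rows.
#' @param standardize Scale columns to mean 0, SD 1 before computing
#'   distances? Default `FALSE` (raw units).
#' @return A [stats::dist] object.
#' @export
euclidean_distance_matrix <- function(numeric_table, standardize = FALSE) {
  x <- as.matrix(numeric_table)
  if (anyNA(x)) {
    stop("numeric table contains missing cells; apply exclude_incomplete() first",
         call. = FALSE)
  }
  if (standardize) x <- scale(x)
  stats::dist(x, method = "euclidean")
}

#' Complete-linkage agglomerative clustering
#'
#' Standard agglomeration with the complete-linkage rule: the distance
#' between two clusters is the maximum pairwise distance between their
#' members, and the pair of clusters with the smallest such distance is
#' merged at each step. Merge heights are therefore non-decreasing.
#'
#' @param d A [stats::dist] object (see [jaccard_distance_matrix()],
#'   [euclidean_distance_matrix()]).
#' @return An [stats::hclust] object.
#' @export
cluster_complete <- function(d) {
  if (!inherits(d, "dist")) stop("`d` must be a dist object", call. = FALSE)
  if (attr(d, "Size") < 2) stop("clustering needs at least 2 observations", call. = FALSE)
  stats::hclust(d, method = "complete")
}

#' Tidy the merge history of a dendrogram
#'
#' @param x An [stats::hclust] object.
#' @param ... Unused.
#' @return A tibble with one row per merge: `step`, `cluster_a`, `cluster_b`
#'   (negative = leaf index, positive = earlier merge step) and `height`.
#' @export
tidy.hclust <- function(x, ...) {
  tibble::tibble(step = seq_len(nrow(x$merge)),
                 cluster_a = x$merge[, 1],
                 cluster_b = x$merge[, 2],
                 height = x$height)
}

#' Elbow-based choice of the number of clusters
#'
#' Builds the scree series of merge heights: `h(kappa)` is the height at
#' which `kappa` clusters merge into `kappa - 1` (so `h(1)` is the final,
#' tallest merge). The suggested cluster count is the `kappa` maximising the
#' discrete second difference `h(kappa+1) - 2 h(kappa) + h(kappa-1)` — the
#' sharpest bend of the scree curve — with ties going to the smallest
#' `kappa`. When the series is perfectly linear there is no elbow; the
#' smallest candidate is returned with `no_elbow = TRUE` and a warning.
#'
#' @param hc An [stats::hclust] object, or a numeric vector of merge heights
#'   (taken as the scree series after sorting in decreasing order).
#' @param k_max Largest cluster count to consider (>= 3).
#' @return A list with `k` (suggested count), `no_elbow` (flag) and `scree`,
#'   a tibble with columns `kappa` and `height` for plotting.
#' @export
scree_elbow <- function(hc, k_max = 10) {
  if (!inherits(hc, "hclust") && !is.numeric(hc)) {
    stop("`hc` must be an hclust object or a numeric height series", call. = FALSE)
  }
  if (k_max < 3) stop("`k_max` must be at least 3", call. = FALSE)
  heights <- sort(if (is.numeric(hc)) hc else hc$height, decreasing = TRUE)
  if (length(heights) < 3) stop("too few leaves for elbow selection", call. = FALSE)
  k_max <- min(k_max, length(heights))
  h <- heights[seq_len(k_max)]
  kappa <- 2:(k_max - 1)
  d2 <- h[kappa + 1] - 2 * h[kappa] + h[kappa - 1]
  no_elbow <- isTRUE(all(abs(d2 - d2[1]) < 1e-12)) && length(d2) > 1
  if (no_elbow) {
    warning("scree series has no bend (all second differences equal); ",
            "returning smallest candidate", call. = FALSE)
    k <- kappa[1]
  } else {
    k <- kappa[which.max(d2)]
  }
  list(k = k, no_elbow = no_elbow,
       scree = tibble::tibble(kappa = seq_len(k_max), height = h))
}

#' Scree plot of merge heights
#'
#' @param elbow Result of [scree_elbow()].
#' @return A ggplot object: merge height against cluster count, with the
#'   suggested elbow marked.
#' @export
plot_scree <- function(elbow) {
  ggplot2::ggplot(elbow$scree, ggplot2::aes(x = .data$kappa, y = .data$height)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = elbow$k, linetype = "dashed") +
    ggplot2::labs(x = "Number of clusters", y = "Merge height",
                  title = "Scree plot of agglomeration heights") +
    ggplot2::theme_minimal()
}
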