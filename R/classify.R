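# Classification of expansion profiles by k-means on standardized curves.

#' Standardize expansion profiles onto a common timeline
#'
#' Each profile is linearly interpolated onto a uniform arbitrary timeline
#' of 1..1000, centred, and scaled to unit SD (per curve). Constant
#' profiles are excluded with a warning.
#'
#' @param profiles Named list of `expansion_profile` objects or data
#'   frames with `t` and `wgn` (or `value`) columns.
#' @param grid_n Number of timeline points (default 1000).
#' @return Numeric matrix, one row per retained profile.
#' @export
standardize_profiles <- function(profiles, grid_n = 1000) {
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("sample", seq_along(profiles))
  }
  rows <- list()
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    v <- p$wgn %||% p$value
    t <- p$t
    if (length(t) < 3) stop("profile ", nm, " has fewer than 3 points")
    if (sd(v) == 0) {
      warning("profile ", nm, " is constant; excluded")
      next
    }
    g <- approx(seq_along(t) * 0 + t, v,
                xout = seq(min(t), max(t), length.out = grid_n))$y
    g <- (g - mean(g)) / sd(g)
    rows[[nm]] <- g
  }
  if (!length(rows)) stop("no non-constant profiles to standardize")
  do.call(rbind, rows)
}

#' k-means clustering of standardized curves
#'
#' Euclidean k-means on the 1000-point standardized vectors, `restarts`
#' independent starts per k with the lowest within-cluster sum retained
#' (ties broken by the lowest start index); deterministic under `seed`.
#'
#' @param curves Matrix from [standardize_profiles()].
#' @param k_candidates Cluster counts to evaluate (default 2:6).
#' @param restarts Starts per k (default 5).
#' @param seed Integer seed.
#' @return List of class `curve_partition_set`: per k a list with
#'   `labels`, `centers`, `tot_withinss`, `ch`; plus `ch_table`.
#' @export
kmeans_curves <- function(curves, k_candidates = 2:6, restarts = 5,
                          seed = 1) {
  n <- nrow(curves)
  fits <- list()
  for (k in k_candidates) {
    if (k >= n) {
      warning("k = ", k, " >= number of curves (", n, "); skipped")
      next
    }
    best <- NULL
    for (r in seq_len(restarts)) {
      set.seed(seed * 1000L + k * 10L + r)
      km <- tryCatch(
        kmeans(curves, centers = k, iter.max = 100),
        error = function(e) NULL
      )
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) next
    fits[[as.character(k)]] <- list(
      k = k, labels = unname(best$cluster), centers = best$centers,
      tot_withinss = best$tot.withinss,
      ch = calinski_harabasz(curves, unname(best$cluster))
    )
  }
  ch_table <- data.frame(
    k = as.integer(names(fits)),
    ch = vapply(fits, function(f) f$ch, numeric(1)),
    row.names = NULL
  )
  structure(list(fits = fits, ch_table = ch_table, n = n),
            class = "curve_partition_set")
}

#' Calinski-Harabasz criterion of a partition
#'
#' CH = (B / (k - 1)) / (W / (n - k)) with B/W the between-/within-cluster
#' sums of squared distances to the cluster means. Perfect separation
#' (W = 0) is reported as the capped sentinel 1e12.
#'
#' @param curves Numeric matrix (observations x dimensions) or vector.
#' @param labels Integer cluster labels (every cluster nonempty, k >= 2).
#' @return CH value.
#' @export
calinski_harabasz <- function(curves, labels) {
  if (is.vector(curves)) curves <- matrix(curves, ncol = 1)
  n <- nrow(curves)
  ks <- unique(labels)
  k <- length(ks)
  if (k < 2) stop("need at least 2 clusters")
  if (any(tabulate(match(labels, ks)) == 0)) stop("empty cluster")
  grand <- colMeans(curves)
  W <- 0; B <- 0
  for (cl in ks) {
    sub <- curves[labels == cl, , drop = FALSE]
    ctr <- colMeans(sub)
    W <- W + sum(sweep(sub, 2, ctr)^2)
    B <- B + nrow(sub) * sum((ctr - grand)^2)
  }
  if (W == 0) return(1e12)
  (B / (k - 1)) / (W / (n - k))
}

# analytic shape templates on a unit grid, standardized
shape_templates <- function(grid_n = 1000) {
  s <- seq(0, 1, length.out = grid_n)
  std <- function(v) (v - mean(v)) / sd(v)
  rbind(
    convex = std(4 * (s - 0.5)^2),
    peak = std(sin(pi * s)),
    increase = std(s),
    paused_start = std(pmax(0, s - 0.5))
  )
}

#' Name clusters by matching mean curves to analytic templates
#'
#' Each cluster mean is assigned the template (Convex, Peak, Increase,
#' Paused Start) with which it correlates best.
#'
#' @param centers Matrix of cluster mean curves.
#' @return Character vector of shape names per cluster.
#' @export
name_clusters <- function(centers) {
  tmpl <- shape_templates(ncol(centers))
  apply(centers, 1, function(ctr) {
    rownames(tmpl)[which.max(cor(t(tmpl), ctr))]
  })
}

#' Choose the partition size from the CH table
#'
#' Default: argmax CH. When `reference_shapes` are supplied, the smallest
#' k whose CH is within `tolerance` of the maximum and whose named cluster
#' means cover all reference shapes is preferred; the decision is
#' recorded in the result.
#'
#' @param partition_set A [kmeans_curves()] result.
#' @param reference_shapes Character subset of
#'   c("convex", "peak", "increase", "paused_start"), or NULL.
#' @param tolerance Relative CH tolerance (default 0.10).
#' @return List: `k`, `labels`, `cluster_names`, `rationale`.
#' @export
select_partition <- function(partition_set, reference_shapes = NULL,
                             tolerance = 0.10) {
  tab <- partition_set$ch_table
  if (nrow(tab) == 0) stop("no partitions available")
  k_max <- tab$k[which.max(tab$ch)]
  choice <- k_max
  rationale <- "argmax CH"
  if (!is.null(reference_shapes)) {
    ok_ks <- tab$k[tab$ch >= (1 - tolerance) * max(tab$ch)]
    for (k in sort(ok_ks)) {
      f <- partition_set$fits[[as.character(k)]]
      nms <- tolower(name_clusters(f$centers))
      if (all(tolower(reference_shapes) %in% nms)) {
        choice <- k
        rationale <- paste0(
          "smallest k within ", tolerance * 100,
          "% of max CH covering shapes: ",
          paste(reference_shapes, collapse = ", ")
        )
        break
      }
    }
  }
  f <- partition_set$fits[[as.character(choice)]]
  list(k = choice, labels = f$labels,
       cluster_names = name_clusters(f$centers), rationale = rationale,
       ch = f$ch)
}
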