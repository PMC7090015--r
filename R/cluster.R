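## Population analysis of fitted temporal filters: PCA, average-linkage
## hierarchical clustering, cross-population projection and peak latencies.

filters_to_matrix <- function(filters) {
  if (is.matrix(filters)) return(filters)
  do.call(rbind, lapply(filters, as.numeric))
}

#' PCA of a filter population
#'
#' Mean-centered principal component analysis; the retained dimensionality k
#' is the smallest number of components whose cumulative explained variance
#' reaches `variance_target`. Components are sign-oriented so their
#' largest-magnitude loading is positive (reproducible projections).
#'
#' @param filters list of [linear_filter()]s (or an n x 300 matrix).
#' @param variance_target cumulative explained-variance fraction (default
#'   0.9).
#' @return list of class `filter_clustering` with `components` (k x 300),
#'   `explained_variance` (all fractions), `projections` (n x k), `center`,
#'   `k` and a `degenerate` flag for zero-variance populations.
#' @export
pca_filters <- function(filters, variance_target = 0.9) {
  X <- filters_to_matrix(filters)
  if (nrow(X) < 2) stop("PCA requires at least 2 filters")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (all(abs(Xc) < 1e-12)) {
    return(structure(list(components = matrix(0, 0, ncol(X)),
                          explained_variance = numeric(0),
                          projections = matrix(0, nrow(X), 0),
                          center = ctr, k = 0L, degenerate = TRUE,
                          selected_pcs = integer(0)),
                     class = "filter_clustering"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance_target)[1]
  if (is.na(k)) k <- length(ev)
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])
  ## sign convention: largest-|loading| entry positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  proj <- Xc %*% t(comp)
  structure(list(components = comp, explained_variance = ev,
                 projections = proj, center = ctr, k = k,
                 degenerate = FALSE, selected_pcs = seq_len(k)),
            class = "filter_clustering")
}

#' @export
print.filter_clustering <- function(x, ...) {
  if (x$degenerate) {
    cat("<filter_clustering: degenerate (zero variance), k = 0>\n")
    return(invisible(x))
  }
  cat(sprintf("<filter_clustering: %d filters, k = %d PCs (%.1f%% variance)%s>\n",
              nrow(x$projections), x$k,
              100 * sum(x$explained_variance[seq_len(x$k)]),
              if (!is.null(x$labels))
                sprintf(", %d clusters", length(unique(x$labels))) else ""))
  invisible(x)
}

## largest relative gap in the last `window` merge heights -> cluster count
auto_cluster_count <- function(heights, window = 10) {
  m <- length(heights)
  lo <- max(1L, m - window + 1L)
  h <- heights[lo:m]
  if (length(h) < 2) return(2L)
  ratios <- h[-1] / pmax(h[-length(h)], .Machine$double.eps)
  i <- which.max(ratios) + lo - 1L   # gap between merge i and i+1
  max(2L, m - i + 1L)                # cut above merge i
}

#' Hierarchical clustering of filter projections
#'
#' Agglomerative average-linkage clustering on euclidean distances in PC
#' space. The tree is cut at `n_clusters`, or automatically at the largest
#' relative gap among the last 10 merge heights.
#'
#' @param projections n x k coordinate matrix (or a
#'   [pca_filters()] result, whose projections -- optionally restricted via
#'   `select_pcs` -- are used).
#' @param n_clusters requested cluster count or `"auto"`.
#' @param select_pcs optional indices of PCs to cluster on (e.g. leaving out
#'   a component dominated by between-recording variance).
#' @return the input `filter_clustering` (or a fresh one) with `linkage`
#'   (an [stats::hclust] tree), `labels` and `n_clusters` added.
#' @export
cluster_filters <- function(projections, n_clusters = "auto",
                            select_pcs = NULL) {
  if (inherits(projections, "filter_clustering")) {
    obj <- projections
    P <- obj$projections
  } else {
    obj <- structure(list(projections = as.matrix(projections)),
                     class = "filter_clustering")
    P <- obj$projections
  }
  if (!is.null(select_pcs)) {
    P <- P[, select_pcs, drop = FALSE]
    obj$selected_pcs <- select_pcs
  }
  n <- nrow(P)
  if (n < 2) stop("clustering requires at least 2 points")
  if (is.numeric(n_clusters) && n_clusters > n)
    stop("n_clusters exceeds the number of points")
  hc <- stats::hclust(stats::dist(P, method = "euclidean"), method = "average")
  k <- if (identical(n_clusters, "auto")) auto_cluster_count(hc$height)
       else as.integer(n_clusters)
  labels <- stats::cutree(hc, k = min(k, n))
  obj$linkage <- hc
  obj$labels <- labels
  obj$n_clusters <- length(unique(labels))
  obj
}

#' Project filters onto a reference population's components
#'
#' Centers the filters with the reference mean and projects onto the
#' reference PCs, without refitting (used e.g. to place degenerated-retina
#' filters in the wild-type PC space).
#'
#' @param filters list of [linear_filter()]s or matrix.
#' @param reference a [pca_filters()] result.
#' @return n x k coordinate matrix.
#' @export
project_onto_components <- function(filters, reference) {
  X <- filters_to_matrix(filters)
  if (reference$degenerate || nrow(reference$components) < 1)
    stop("reference has no retained components")
  if (ncol(X) != ncol(reference$components))
    stop("filter tap geometry does not match the reference")
  sweep(X, 2, reference$center) %*% t(reference$components)
}

#' Peak latencies and shape class of a temporal filter
#'
#' Negative-peak latency = tap time of the global minimum; positive-peak
#' latency = tap time of the global maximum. The filter is biphasic when the
#' secondary extremum reaches at least `biphasic_ratio` of the primary's
#' magnitude, otherwise monophasic with the primary's sign (negative
#' latencies mean the peak precedes the spike).
#'
#' @param filter a [linear_filter()] (or 300-tap vector).
#' @param biphasic_ratio secondary/primary magnitude threshold (default 0.3).
#' @return list of class `peak_latency_report`: `negative_peak_latency`,
#'   `positive_peak_latency` (ms), `shape_class`, `undefined` flag, and
#'   which latency is `meaningful`.
#' @export
peak_latencies <- function(filter, biphasic_ratio = 0.3) {
  taps <- as.numeric(filter)
  tt <- attr(filter, "tap_times")
  if (is.null(tt)) tt <- filter_tap_times()
  if (all(taps == 0)) {
    return(structure(list(negative_peak_latency = NA_real_,
                          positive_peak_latency = NA_real_,
                          shape_class = NA_character_, undefined = TRUE,
                          meaningful = c(negative = FALSE, positive = FALSE)),
                     class = "peak_latency_report"))
  }
  i_min <- which.min(taps); i_max <- which.max(taps)
  amp_neg <- -taps[i_min]; amp_pos <- taps[i_max]
  primary_neg <- amp_neg >= amp_pos
  primary <- max(amp_neg, amp_pos); secondary <- min(amp_neg, amp_pos)
  biphasic <- secondary >= biphasic_ratio * primary && secondary > 0
  shape <- if (biphasic) "biphasic"
           else if (primary_neg) "monophasic_negative" else "monophasic_positive"
  meaningful <- c(negative = biphasic || primary_neg,
                  positive = biphasic || !primary_neg)
  structure(list(negative_peak_latency = tt[i_min],
                 positive_peak_latency = tt[i_max],
                 shape_class = shape, undefined = FALSE,
                 meaningful = meaningful),
            class = "peak_latency_report")
}

#' @export
print.peak_latency_report <- function(x, ...) {
  if (x$undefined) {
    cat("<peak_latency_report: undefined (all-zero filter)>\n")
    return(invisible(x))
  }
  cat(sprintf("%s: negative peak %.1f ms%s, positive peak %.1f ms%s\n",
              x$shape_class,
              x$negative_peak_latency,
              if (x$meaningful["negative"]) "" else " (not meaningful)",
              x$positive_peak_latency,
              if (x$meaningful["positive"]) "" else " (not meaningful)"))
  invisible(x)
}
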