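#' Seeded k-means clustering of gene trajectories
#'
#' Lloyd's algorithm with Euclidean distance, taking the best of `nInit`
#' random initializations (centres drawn as distinct data rows) by total
#' within-cluster sum of squares. A cluster that empties during iteration
#' is re-seeded from the point currently farthest from its own centroid,
#' so the paper's operating point — k of the same order as the number of
#' genes — runs robustly. Fully reproducible given `seed`.
#'
#' @param features numeric gene x feature matrix with unique rownames.
#' @param k number of clusters, `1 <= k <= nrow(features)`.
#' @param seed integer seed, default 0.
#' @param nInit number of random restarts, default 10.
#' @param maxIter iteration cap per restart, default 300.
#' @param tol convergence tolerance on the largest centroid movement,
#'   default 1e-6.
#' @return a \linkS4class{ClusterResult}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -5, 0.1), 20), matrix(rnorm(40, 5, 0.1), 20))
#' rownames(x) <- paste0("g", 1:40)
#' table(clusterAssignment(kmeansCluster(x, k = 2, seed = 0)))
#' @export
kmeansCluster <- function(features, k, seed = 0L, nInit = 10L,
                          maxIter = 300L, tol = 1e-6) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(rownames(features)))
    rownames(features) <- paste0("g", seq_len(n))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive integer")
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of genes (", n, ")")
  if (any(!is.finite(features))) stop("features must be finite")

  set.seed(as.integer(seed))
  best <- NULL
  for (init in seq_len(nInit)) {
    centers <- features[sample.int(n, k), , drop = FALSE]
    assign <- integer(n)
    for (iter in seq_len(maxIter)) {
      d2 <- .sqDist(features, centers)
      assign <- max.col(-d2, ties.method = "first")
      counts <- tabulate(assign, nbins = k)
      nonEmpty <- counts > 0L
      newCenters <- centers
      newCenters[nonEmpty, ] <- .clusterMeans(features, assign, counts)
      if (any(!nonEmpty)) {
        # re-seed empty clusters from the points farthest from their centroid
        own <- d2[cbind(seq_len(n), assign)]
        for (ce in which(!nonEmpty)) {
          far <- which.max(own)
          newCenters[ce, ] <- features[far, ]
          own[far] <- -Inf
        }
      }
      move <- max(sqrt(rowSums((newCenters - centers)^2)))
      centers <- newCenters
      if (move < tol && all(nonEmpty)) break
    }
    d2 <- .sqDist(features, centers)
    assign <- max.col(-d2, ties.method = "first")
    # final means so centroids are exactly their members' average
    counts <- tabulate(assign, nbins = k)
    nonEmpty <- counts > 0L
    centers[nonEmpty, ] <- .clusterMeans(features, assign, counts)
    inertia <- sum((features - centers[assign, , drop = FALSE])^2)
    if (is.null(best) || inertia < best$inertia)
      best <- list(assign = assign, centers = centers, inertia = inertia)
  }
  new("ClusterResult",
      assignment = setNames(best$assign, rownames(features)),
      centroids = best$centers, features = features, k = k,
      seed = as.integer(seed), nInit = as.integer(nInit),
      inertia = best$inertia)
}

# mean feature vector per non-empty cluster, rows ordered by cluster id
.clusterMeans <- function(features, assign, counts) {
  sums <- rowsum(features, assign)
  sums / counts[counts > 0L]
}

.sqDist <- function(x, c_) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(c_)) +
    matrix(rowSums(c_^2), nrow(x), nrow(c_), byrow = TRUE) -
    2 * x %*% t(c_)
  d2[d2 < 0] <- 0
  d2
}

#' @describeIn kmeansCluster gene -> cluster id vector of a result.
#' @param x a \linkS4class{ClusterResult}.
#' @export
setMethod("clusterAssignment", "ClusterResult", function(x) x@assignment)

#' @export
setMethod("show", "ClusterResult", function(object) {
  sizes <- tabulate(object@assignment, nbins = object@k)
  cat("ClusterResult: k =", object@k, "over", length(object@assignment),
      "genes\n")
  cat(sprintf("  inertia %.4g; cluster sizes %d..%d (%d empty); seed %d, nInit %d\n",
              object@inertia, min(sizes), max(sizes), sum(sizes == 0L),
              object@seed, object@nInit))
})
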