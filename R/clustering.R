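#' Spike-train similarity of two phrase onset patterns
#'
#' Cosine similarity of the two onset trains after convolution with a
#' Gaussian kernel of s.d. `sigma`, with trains aligned at their first
#' onsets. Computed in closed form: the inner product of two
#' Gaussian-smoothed spike trains is `sum_ij exp(-(t_i - s_j)^2 /
#' (4 sigma^2))` up to a common constant, so two single-onset trains at
#' offset `d` have similarity `exp(-d^2 / (4 sigma^2))`. This is the
#' exact infinite-support version of smoothing discretized trains and
#' zero-padding to a common length.
#'
#' @param a,b [to_point_process()] objects or non-empty numeric vectors
#'   of onset times (seconds).
#' @param sigma Gaussian kernel s.d. in seconds (> 0, default 0.01).
#' @return similarity in \[0, 1\]; 1 for identical trains.
#' @export
spike_train_similarity <- function(a, b, sigma = 0.01) {
  if (sigma <= 0) stop("sigma must be > 0")
  ta <- onset_vector(a)
  tb <- onset_vector(b)
  ta <- ta - ta[1]
  tb <- tb - tb[1]
  k <- function(x, y) sum(exp(-outer(x, y, `-`)^2 / (4 * sigma^2)))
  k(ta, tb) / sqrt(k(ta, ta) * k(tb, tb))
}

onset_vector <- function(x) {
  if (inherits(x, "point_process_phrase")) x <- x$onset_times
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty onset train")
  if (any(diff(x) < 0)) stop("onset times must be sorted")
  x
}

#' Pairwise spike-train similarity matrix
#'
#' @param phrases list of >= 2 point processes or onset-time vectors.
#' @param sigma Gaussian kernel s.d., seconds.
#' @return an object of class `similarity_matrix`: a symmetric numeric
#'   matrix in \[0, 1\] with unit diagonal.
#' @export
build_similarity_matrix <- function(phrases, sigma = 0.01) {
  stopifnot(is.list(phrases), length(phrases) >= 2)
  n <- length(phrases)
  S <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- spike_train_similarity(phrases[[i]],
                                                   phrases[[j]], sigma)
    }
  }
  structure(S, class = c("similarity_matrix", "matrix"))
}

# Otsu threshold on a vector of similarities: the cut maximizing
# between-class variance of the two-group split. First-onset alignment
# gives every pair of trains a shared onset and hence a non-trivial
# baseline similarity, so a valley-seeking threshold separates the
# within-type and between-type similarity modes far more reliably than
# the overall median does.
otsu_threshold <- function(x) {
  if (length(unique(x)) < 2) return(min(x))
  br <- seq(min(x), max(x), length.out = 257)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  s1 <- cumsum(counts * mids)
  m1 <- s1 / pmax(w1, 1e-12)
  m2 <- (sum(counts * mids) - s1) / pmax(w2, 1e-12)
  v <- w1 * w2 * (m1 - m2)^2
  v[w1 == 0 | w2 == 0] <- -Inf
  br[which.max(v) + 1]
}

#' Cluster phrases into types from a similarity matrix
#'
#' Builds a weighted graph by zeroing similarities below an adaptive
#' threshold (default: an Otsu/valley threshold on the off-diagonal
#' similarities) and partitions it with modularity-maximizing multilevel
#' (Louvain) community detection. Cluster ids are contiguous from 1,
#' numbered by first appearance in phrase order.
#'
#' @param S a [build_similarity_matrix()] result (or plain symmetric
#'   matrix in \[0,1\] with unit diagonal).
#' @param seed optional RNG seed (the multilevel heuristic is
#'   stochastic).
#' @param threshold similarity threshold; edges below it are dropped.
#' @param refine run a second clustering pass within each cluster
#'   (stand-in for manual refinement of near-identical variants).
#' @return an object of class `cluster_assignment`: list with `labels`
#'   (integer per phrase), `modularity`, `n_clusters`.
#' @export
cluster_phrases <- function(S, seed = NULL, threshold = NULL,
                            refine = FALSE) {
  S <- unclass(S)
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-12) stop("similarity matrix must be symmetric")
  if (any(S < 0 | S > 1 + 1e-12)) stop("similarities must lie in [0, 1]")
  n <- nrow(S)
  local_seed(seed)
  off <- S[lower.tri(S)]
  threshold <- threshold %||% otsu_threshold(off)
  A <- S
  A[A < threshold] <- 0
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  comm <- igraph::cluster_louvain(g)
  labels <- igraph::membership(comm)
  if (refine && length(unique(labels)) < n) {
    nxt <- max(labels)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 4) next
      sub <- S[idx, idx, drop = FALSE]
      off_s <- sub[lower.tri(sub)]
      if (length(unique(off_s)) < 2) next
      sub_as <- cluster_phrases(sub, threshold = otsu_threshold(off_s))
      if (sub_as$n_clusters > 1) {
        labels[idx] <- nxt + sub_as$labels
        nxt <- nxt + sub_as$n_clusters
      }
    }
  }
  labels <- match(labels, unique(labels))  # contiguous, by first appearance
  structure(
    list(labels = as.integer(labels),
         modularity = igraph::modularity(g, labels,
                                         weights = igraph::E(g)$weight),
         n_clusters = length(unique(labels))),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d phrases in %d clusters (modularity %.3f)\n",
              length(x$labels), x$n_clusters, x$modularity))
  invisible(x)
}

#' Build a performance from clustered point processes
#'
#' Writes cluster ids back as phrase-type labels (the automatic analogue
#' of the sorted raster classification).
#'
#' @param assignment a [cluster_phrases()] result.
#' @param bird_id identifier.
#' @return a [performance()] with types `"C1"`, `"C2"`, ... and no motif
#'   annotation.
#' @export
assignment_to_performance <- function(assignment, bird_id = "bird") {
  performance(paste0("C", assignment$labels), bird_id = bird_id)
}
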