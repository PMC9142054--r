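#' Distances between vectors and two-fold centers
#'
#' `pair_distance()` computes the distance between two vectors under the
#' configured metric: squared Euclidean \eqn{\sum_t (f_t-g_t)^2}, Manhattan
#' \eqn{\sum_t |f_t-g_t|}, or cosine \eqn{1 - \cos(f,g)} (with the convention
#' that a zero vector has cosine 0 with anything).
#'
#' @param f,g numeric vectors of equal length.
#' @param metric `"euclidean"`, `"manhattan"` or `"cosine"`.
#' @return Nonnegative scalar distance.
#' @export
pair_distance <- function(f, g, metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  if (length(f) != length(g)) stop("vectors differ in length")
  switch(metric,
         euclidean = sum((f - g)^2),
         manhattan = sum(abs(f - g)),
         cosine = {
           nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
           if (nf == 0 || ng == 0) 1 else 1 - min(1, max(-1, sum(f * g) / (nf * ng)))
         })
}

#' @rdname pair_distance
#' @description `combined_distance()` is the node-to-cluster distance of the
#'   Minimum Distance rule: `rho * d(y_i, c_k) + xi * d(p_i, lambda_k)`, the
#'   weighted sum of the feature-space and network-space distances to cluster
#'   k's two-fold center.
#' @param i node index; @param k cluster index.
#' @param y,p preprocessed feature (N x V) and link (N x N) matrices.
#' @param centers a list with components `C` (K x V) and `Lambda` (K x N).
#' @param rho,xi nonnegative weights of the feature and network spaces
#'   (defaults 1 and 1).
#' @export
combined_distance <- function(i, k, y, p, centers,
                              metric = c("euclidean", "manhattan", "cosine"),
                              rho = 1, xi = 1) {
  metric <- match.arg(metric)
  rho * pair_distance(y[i, ], centers$C[k, ], metric) +
    xi * pair_distance(p[i, ], centers$Lambda[k, ], metric)
}

# N x K matrix of combined distances to all centers (compiled hot path).
combined_distances <- function(y, p, centers, metric, rho = 1, xi = 1) {
  combined_distance_matrix_cpp(y, p, centers$C, centers$Lambda,
                               rho, xi, metric_id(metric))
}

#' Minimum Distance rule
#'
#' Assigns every node to the cluster minimizing its combined feature + network
#' distance to the cluster's two-fold center; ties are broken by the smallest
#' cluster index.
#'
#' @inheritParams combined_distance
#' @return Integer label vector in 1..K.
#' @export
assign_clusters <- function(y, p, centers,
                            metric = c("euclidean", "manhattan", "cosine"),
                            rho = 1, xi = 1) {
  metric <- match.arg(metric)
  d <- combined_distances(y, p, centers, metric, rho, xi)
  max.col(-d, ties.method = "first")
}

#' Center update
#'
#' Computes each cluster's two-fold center as within-cluster means: `C[k, ]` is
#' the mean feature vector, `Lambda[k, ]` the mean network row, over the
#' cluster's nodes. Under the cosine variant the resulting center rows are
#' re-normed to unit length (zero rows stay zero). A `"median"` option replaces
#' means by componentwise medians for the Manhattan variant (the true
#' criterion minimizer there), but means are the default in every variant.
#'
#' @inheritParams combined_distance
#' @param labels integer label vector in 1..K, all clusters nonempty.
#' @param k number of clusters.
#' @param centers_fun `"mean"` or `"median"`.
#' @return List with components `C` and `Lambda`.
#' @export
update_centers <- function(y, p, labels, k,
                           metric = c("euclidean", "manhattan", "cosine"),
                           centers_fun = c("mean", "median")) {
  metric <- match.arg(metric)
  centers_fun <- match.arg(centers_fun)
  sizes <- tabulate(labels, k)
  if (any(sizes == 0L)) stop("internal error: empty cluster reached update_centers")
  if (centers_fun == "mean") {
    g <- factor(labels, levels = seq_len(k))
    C <- rowsum(y, g) / sizes
    L <- rowsum(p, g) / sizes
  } else {
    C <- t(vapply(seq_len(k), function(kk)
      apply(y[labels == kk, , drop = FALSE], 2L, stats::median), numeric(ncol(y))))
    L <- t(vapply(seq_len(k), function(kk)
      apply(p[labels == kk, , drop = FALSE], 2L, stats::median), numeric(ncol(p))))
  }
  dimnames(C) <- NULL; dimnames(L) <- NULL
  if (metric == "cosine") {
    C <- row_norm(C)
    L <- row_norm(L)
  }
  list(C = C, Lambda = L)
}

#' Seed initialization
#'
#' MaxMin-style farthest-point seeding: the first seed is a uniformly random
#' node (its feature row and network row become the first two-fold center);
#' each subsequent seed is the not-yet-chosen node maximizing the sum of
#' combined distances to all already-chosen seeds (ties: smallest index).
#' Deterministic given the RNG state.
#'
#' @inheritParams combined_distance
#' @param k number of seeds, at most N.
#' @return List with `C`, `Lambda` and `seed_nodes` (the chosen node indices).
#' @export
initialize_seeds <- function(y, p, k,
                             metric = c("euclidean", "manhattan", "cosine"),
                             rho = 1, xi = 1) {
  metric <- match.arg(metric)
  n <- nrow(y)
  if (k > n) stop("cannot place ", k, " seeds among ", n, " nodes")
  chosen <- sample.int(n, 1L)
  while (length(chosen) < k) {
    centers <- list(C = y[chosen, , drop = FALSE], Lambda = p[chosen, , drop = FALSE])
    f <- rowSums(combined_distances(y, p, centers, metric, rho, xi))
    f[chosen] <- -Inf
    nxt <- which.max(f)
    if (f[nxt] <= 0)
      stop("cannot select ", k, " distinct seeds: remaining nodes coincide ",
           "with the chosen ones")
    chosen <- c(chosen, nxt)
  }
  list(C = y[chosen, , drop = FALSE], Lambda = p[chosen, , drop = FALSE],
       seed_nodes = chosen)
}

#' Clustering criterion
#'
#' The combined least-squares criterion (its metric analogue): the sum over all
#' nodes of the combined distance to the node's own cluster's two-fold center.
#'
#' @inheritParams update_centers
#' @inheritParams combined_distance
#' @return Nonnegative scalar.
#' @export
criterion_value <- function(y, p, labels, centers,
                            metric = c("euclidean", "manhattan", "cosine"),
                            rho = 1, xi = 1) {
  metric <- match.arg(metric)
  d <- combined_distances(y, p, centers, metric, rho, xi)
  sum(d[cbind(seq_len(nrow(d)), labels)])
}

# One alternating-minimization run from fresh seeds; RNG state is the caller's.
kefrin_single_fit <- function(y, p, k, metric, rho, xi, max_iter, centers_fun) {
  n <- nrow(y)
  centers <- initialize_seeds(y, p, k, metric, rho, xi)
  seed_nodes <- centers$seed_nodes
  d <- combined_distances(y, p, centers, metric, rho, xi)
  prev <- integer(0)
  seen <- character(0)
  traj <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    labels <- max.col(-d, ties.method = "first")
    # Empty-cluster repair: re-seed an emptied cluster from the node farthest
    # from its own current center (never a sole cluster member).
    empties <- which(tabulate(labels, k) == 0L)
    for (kk in empties) {
      sizes <- tabulate(labels, k)
      cand <- which(sizes[labels] > 1L)
      if (length(cand) == 0L) break
      far <- cand[which.max(d[cbind(cand, labels[cand])])]
      labels[far] <- kk
      d[far, ] <- Inf
      d[far, kk] <- 0
    }
    if (length(prev) && identical(labels, prev)) {
      converged <- TRUE
      n_iter <- it
      break
    }
    sig <- paste(labels, collapse = ",")
    if (sig %in% seen) {  # non-trivial cycle (possible for cosine / Manhattan)
      n_iter <- it
      centers <- update_centers(y, p, labels, k, metric, centers_fun)
      d <- combined_distances(y, p, centers, metric, rho, xi)
      traj <- c(traj, sum(d[cbind(seq_len(n), labels)]))
      break
    }
    seen <- c(seen, sig)
    prev <- labels
    centers <- update_centers(y, p, labels, k, metric, centers_fun)
    d <- combined_distances(y, p, centers, metric, rho, xi)
    traj <- c(traj, sum(d[cbind(seq_len(n), labels)]))
    n_iter <- it
  }
  list(partition = labels, centers = centers[c("C", "Lambda")],
       criterion = traj[length(traj)], criterion_trajectory = traj,
       n_iter = n_iter, converged = converged, seed_nodes = seed_nodes)
}

#' Fit the extended K-means on preprocessed matrices
#'
#' Core alternating minimization: seed initialization, then repeated
#' application of the Minimum Distance rule and the within-cluster-mean center
#' update, until the partition stops changing (or a previously visited
#' partition recurs, or `max_iter` is reached). Inputs must already be
#' standardized as desired; for the cosine variant the rows of `y` and `p`
#' must be unit-normed (see [row_norm()]). With `n_init > 1`, the whole
#' procedure is restarted from fresh random first seeds and the run with the
#' smallest final criterion is returned.
#'
#' @inheritParams combined_distance
#' @param k number of clusters (at most N).
#' @param n_init number of random restarts (default 1).
#' @param max_iter iteration cap per restart (default 100).
#' @param seed optional integer seed for reproducibility.
#' @param centers_fun `"mean"` (default, all variants) or `"median"`
#'   (Manhattan-minimizing alternative).
#' @return A `kefrin_fit` object: `partition` (labels 1..K), `centers`
#'   (`C`, `Lambda`), `criterion`, `criterion_trajectory`, `n_iter`,
#'   `converged`, `seed_nodes`, plus the configuration used.
#' @export
kefrin_fit <- function(y, p, k, metric = c("euclidean", "manhattan", "cosine"),
                       rho = 1, xi = 1, n_init = 1, max_iter = 100,
                       seed = NULL, centers_fun = c("mean", "median")) {
  metric <- match.arg(metric)
  centers_fun <- match.arg(centers_fun)
  y <- as.matrix(y); p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop("link matrix must be square")
  if (nrow(y) != nrow(p)) stop("feature and link matrices disagree on N")
  if (rho < 0 || xi < 0 || rho + xi <= 0) stop("need rho, xi >= 0 with rho + xi > 0")
  if (k < 1L || k > nrow(y)) stop("k must be in 1..N")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (run in seq_len(n_init)) {
    fit <- kefrin_single_fit(y, p, k, metric, rho, xi, max_iter, centers_fun)
    if (is.null(best) || fit$criterion < best$criterion) {
      best <- fit
      best$init <- run
    }
  }
  best$K <- as.integer(k)
  best$metric <- metric
  best$rho <- rho
  best$xi <- xi
  best$n_init <- n_init
  class(best) <- "kefrin_fit"
  best
}

#' Cluster a feature-rich network
#'
#' High-level interface: encodes categorical features as one-hot dummies,
#' applies the configured standardization (default: z-scoring for features and
#' the modularity shift for links, replaced by the scale shift when any
#' categorical feature is present), row-norms both spaces for the cosine
#' variant, and runs [kefrin_fit()].
#'
#' @param features a [kefrin_features] object, data.frame or numeric matrix.
#' @param network numeric N x N link matrix aligned to (or reorderable by
#'   dimnames to) the feature table's node order.
#' @param k number of communities.
#' @inheritParams kefrin_fit
#' @param feature_std `"z"`, `"range"` or `"none"`.
#' @param network_std `"modularity"`, `"shift"`, `"none"`, or `NULL` for the
#'   default selection rule.
#' @return A `kefrin_fit` object, with `node_ids` and the preprocessing
#'   choices recorded.
#' @examples
#' ds <- generate_feature_rich_network(n = 60, k = 2, p = 0.9, q = 0.1,
#'                                     flavor = "quantitative", alpha = 0.9,
#'                                     v_quant = 3, seed = 7)
#' fit <- kefrin(ds$features, ds$network, k = 2, metric = "euclidean", seed = 1)
#' adjusted_rand_index(fit$partition, ds$truth)
#' @export
kefrin <- function(features, network, k,
                   metric = c("euclidean", "manhattan", "cosine"),
                   feature_std = c("z", "range", "none"), network_std = NULL,
                   rho = 1, xi = 1, n_init = 1, max_iter = 100, seed = NULL,
                   centers_fun = c("mean", "median")) {
  metric <- match.arg(metric)
  prep <- prepare_inputs(features, network, metric, feature_std, network_std)
  fit <- kefrin_fit(prep$y, prep$p, k, metric = metric, rho = rho, xi = xi,
                    n_init = n_init, max_iter = max_iter, seed = seed,
                    centers_fun = centers_fun)
  fit$node_ids <- prep$node_ids
  fit$feature_std <- prep$feature_std
  fit$network_std <- prep$network_std
  fit
}

#' @export
print.kefrin_fit <- function(x, ...) {
  cat("<kefrin_fit> ", x$metric, " variant, K = ", x$K, ", N = ",
      length(x$partition), "\n", sep = "")
  cat("  criterion ", format(x$criterion, digits = 6), " after ", x$n_iter,
      " iteration(s); ", if (isTRUE(x$converged)) "converged" else "not converged",
      if (x$n_init > 1) paste0(" (best of ", x$n_init, " restarts)") else "",
      "\n", sep = "")
  cat("  cluster sizes: ", paste(tabulate(x$partition, x$K), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
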