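#' Draw planted community sizes
#'
#' Community cardinalities are drawn randomly subject to two constraints: every
#' community has at least `min_size` nodes (so that probabilistic moment checks
#' remain meaningful; default 30) and the sizes sum to `n`. Drawing is by
#' rejection over uniform cut points, with a retry cap.
#'
#' @param n total number of nodes.
#' @param k number of communities.
#' @param min_size minimum community size (default 30).
#' @param max_tries rejection cap (default 10000).
#' @return Integer vector of k sizes.
#' @export
draw_community_sizes <- function(n, k, min_size = 30, max_tries = 10000) {
  if (k * min_size > n)
    stop("infeasible: ", k, " communities of >= ", min_size, " nodes need more than ",
         n, " nodes")
  if (k == 1L) return(as.integer(n))
  for (try in seq_len(max_tries)) {
    cuts <- sort(sample.int(n - 1L, k - 1L))
    sizes <- diff(c(0L, cuts, n))
    if (all(sizes >= min_size)) return(as.integer(sizes))
  }
  stop("failed to draw community sizes within ", max_tries, " tries")
}

#' Generate a planted-partition network
#'
#' Undirected, unweighted graph on blocks of the given sizes: each
#' within-community pair is an edge with probability `p`, each between-community
#' pair with probability `q`, independently. The returned matrix is symmetric
#' 0/1 with a zero diagonal.
#'
#' @param sizes integer vector of community sizes.
#' @param p within-community edge probability.
#' @param q between-community edge probability.
#' @return Numeric N x N adjacency matrix.
#' @export
generate_network <- function(sizes, p, q) {
  if (p < 0 || p > 1 || q < 0 || q > 1) stop("p and q must be probabilities")
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  same <- outer(block, block, "==")
  prob <- ifelse(same, p, q)
  up <- upper.tri(prob)
  a <- matrix(0, n, n)
  a[up] <- as.numeric(runif(sum(up)) < prob[up])
  a + t(a)
}

#' Generate quantitative cluster features
#'
#' Each cluster is a spherical-cell Gaussian: every center component is drawn
#' uniformly from `[-alpha, alpha]` (the spread factor `alpha` controls cluster
#' intermix: the smaller, the more clusters overlap), and each cluster/feature
#' variance is drawn uniformly from `[0.05, 0.1]` (diagonal covariance).
#'
#' @param sizes integer vector of community sizes.
#' @param alpha center-spread factor in (0, 1].
#' @param v_quant number of features.
#' @return Numeric N x `v_quant` matrix, rows grouped by community; the drawn
#'   cluster centers and variances are attached as attributes `"centers"` and
#'   `"variances"`.
#' @export
generate_quantitative <- function(sizes, alpha, v_quant) {
  if (v_quant < 1) stop("need at least one quantitative feature")
  centers <- matrix(runif(length(sizes) * v_quant, -alpha, alpha), ncol = v_quant)
  vars <- matrix(runif(length(sizes) * v_quant, 0.05, 0.1), ncol = v_quant)
  blocks <- lapply(seq_along(sizes), function(kk) {
    t(centers[kk, ] + sqrt(vars[kk, ]) *
        matrix(rnorm(sizes[kk] * v_quant), nrow = v_quant))
  })
  y <- do.call(rbind, blocks)
  colnames(y) <- paste0("q", seq_len(v_quant))
  attr(y, "centers") <- centers
  attr(y, "variances") <- vars
  y
}

#' Append uniform noise features
#'
#' Replicates half of the original data with noise: appends `ceiling(V/2)`
#' columns, each i.i.d. uniform between the global minimum and maximum of the
#' original matrix, carrying no information about the planted communities.
#'
#' @param y numeric N x V feature matrix.
#' @return Matrix with `V + ceiling(V/2)` columns.
#' @export
add_noise_features <- function(y) {
  y <- as.matrix(y)
  v_noise <- ceiling(ncol(y) / 2)
  lo <- min(y); hi <- max(y)
  noise <- matrix(runif(nrow(y) * v_noise, lo, hi), nrow = nrow(y))
  colnames(noise) <- paste0("noise", seq_len(v_noise))
  cbind(y, noise)
}

#' Generate categorical cluster features
#'
#' Each feature's category count is drawn from `{2, ..., l_max}`. Cluster
#' centers are random category choices, redrawn until no two centers coincide
#' at more than 50% of the features (capped retries). Each entry copies its
#' cluster center's category with probability `epsilon` and is otherwise drawn
#' uniformly from the feature's categories, so the per-entry center-match
#' probability is `epsilon + (1 - epsilon) / L_v`. The larger `epsilon`, the
#' more homogeneous the clusters.
#'
#' @param sizes integer vector of community sizes.
#' @param epsilon cluster homogeneity in [0, 1].
#' @param v_cat number of categorical features.
#' @param l_max maximum number of categories per feature.
#' @param max_tries retry cap for the center-coincidence constraint.
#' @return Character N x `v_cat` matrix of labels `"c1", "c2", ...`; the
#'   planted centers and per-feature category counts are attached as
#'   attributes `"centers"` and `"levels"`.
#' @export
generate_categorical <- function(sizes, epsilon, v_cat, l_max, max_tries = 1000) {
  if (v_cat < 1) stop("need at least one categorical feature")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (l_max < 2) stop("l_max must be at least 2")
  k <- length(sizes)
  n <- sum(sizes)
  lv <- sample(2:l_max, v_cat, replace = TRUE)
  for (try in seq_len(max_tries)) {
    centers <- vapply(lv, function(l) sample.int(l, k, replace = TRUE), integer(k))
    centers <- matrix(centers, nrow = k)
    ok <- TRUE
    if (k > 1L) {
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
        if (sum(centers[a, ] == centers[b, ]) > 0.5 * v_cat) ok <- FALSE
      }
    }
    if (ok) break
    if (try == max_tries)
      stop("could not draw cluster centers meeting the 50% coincidence constraint")
  }
  block <- rep(seq_len(k), sizes)
  x <- matrix(0L, n, v_cat)
  for (vv in seq_len(v_cat)) {
    copy <- runif(n) < epsilon
    rand <- sample.int(lv[vv], n, replace = TRUE)
    x[, vv] <- ifelse(copy, centers[block, vv], rand)
  }
  x <- matrix(paste0("c", x), nrow = n)
  colnames(x) <- paste0("cat", seq_len(v_cat))
  attr(x, "centers") <- centers
  attr(x, "levels") <- lv
  x
}

#' Generate a feature-rich network with planted communities
#'
#' Bundles a planted-partition graph with quantitative, categorical or mixed
#' node features (equal numbers of quantitative and categorical features in the
#' mixed case) and the ground-truth partition. Fully deterministic given
#' `seed`. Noise features (see [add_noise_features()]) are supported whenever
#' quantitative features are present; the noise column count is half the total
#' original feature count and the noise range is taken from the quantitative
#' block.
#'
#' @param n number of nodes.
#' @param k number of planted communities.
#' @param p,q within- and between-community edge probabilities.
#' @param flavor `"quantitative"`, `"categorical"` or `"mixed"`.
#' @param alpha quantitative center-spread factor.
#' @param epsilon categorical homogeneity.
#' @param v_quant,v_cat feature counts (mixed requires `v_quant == v_cat`).
#' @param l_max maximum categories per categorical feature.
#' @param noise append uniform noise features (requires quantitative features).
#' @param min_size minimum community size.
#' @param seed optional integer RNG seed.
#' @return A `kefrin_dataset`: list with `features` ([kefrin_features]),
#'   `network` (N x N matrix), `truth` (labels 1..k), `sizes` and `config`.
#' @export
generate_feature_rich_network <- function(n, k, p, q,
                                          flavor = c("quantitative", "categorical", "mixed"),
                                          alpha = 0.9, epsilon = 0.9,
                                          v_quant = 5, v_cat = 5, l_max = 10,
                                          noise = FALSE, min_size = 30, seed = NULL) {
  flavor <- match.arg(flavor)
  if (q > p) stop("between-community probability q must not exceed p")
  if (!is.null(seed)) set.seed(seed)
  sizes <- draw_community_sizes(n, k, min_size)
  net <- generate_network(sizes, p, q)
  truth <- rep(seq_len(k), sizes)

  yq <- NULL; yc <- NULL
  if (flavor %in% c("quantitative", "mixed")) yq <- generate_quantitative(sizes, alpha, v_quant)
  if (flavor %in% c("categorical", "mixed")) {
    if (flavor == "mixed" && v_quant != v_cat)
      stop("mixed data uses equal numbers of quantitative and categorical features")
    yc <- generate_categorical(sizes, epsilon, v_cat, l_max)
  }
  if (noise) {
    if (is.null(yq)) stop("noise features require quantitative features")
    v_orig <- ncol(yq) + if (is.null(yc)) 0L else ncol(yc)
    v_noise <- ceiling(v_orig / 2)
    noise_cols <- matrix(runif(n * v_noise, min(yq), max(yq)), nrow = n,
                         dimnames = list(NULL, paste0("noise", seq_len(v_noise))))
    yq <- cbind(yq, noise_cols)
  }
  dat <- data.frame(row.names = as.character(seq_len(n)))
  if (!is.null(yq)) dat <- cbind(dat, as.data.frame(yq))
  if (!is.null(yc)) dat <- cbind(dat, as.data.frame(yc, stringsAsFactors = FALSE))
  feats <- kefrin_features(dat, node_ids = as.character(seq_len(n)))
  dimnames(net) <- list(feats$node_ids, feats$node_ids)
  structure(list(features = feats, network = net, truth = truth, sizes = sizes,
                 config = list(n = n, k = k, p = p, q = q, flavor = flavor,
                               alpha = alpha, epsilon = epsilon, v_quant = v_quant,
                               v_cat = v_cat, l_max = l_max, noise = noise,
                               min_size = min_size, seed = seed)),
            class = "kefrin_dataset")
}

#' @export
print.kefrin_dataset <- function(x, ...) {
  cfg <- x$config
  cat("<kefrin_dataset> N = ", cfg$n, ", K = ", cfg$k, " (sizes ",
      paste(x$sizes, collapse = ", "), ")\n", sep = "")
  cat("  flavor = ", cfg$flavor, ", p = ", cfg$p, ", q = ", cfg$q,
      if (cfg$flavor != "categorical") paste0(", alpha = ", cfg$alpha) else "",
      if (cfg$flavor != "quantitative") paste0(", epsilon = ", cfg$epsilon) else "",
      if (cfg$noise) ", with noise features" else "", "\n", sep = "")
  invisible(x)
}
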