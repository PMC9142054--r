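#' Feature standardization
#'
#' Column-wise standardization of an encoded (all-numeric) feature matrix.
#' `zscore_features()` centers each column by its mean and divides by its
#' population standard deviation (divide by N, the data-recovery clustering
#' convention). `range_features()` centers by the mean and divides by the
#' range (max - min). Both reject constant columns, which carry no clustering
#' information and would divide by zero.
#'
#' @param y numeric matrix, nodes in rows.
#' @return Matrix of the same shape.
#' @export
zscore_features <- function(y) {
  y <- as.matrix(y)
  mu <- colMeans(y)
  sdev <- sqrt(colMeans(sweep(y, 2L, mu, "-")^2))
  if (any(sdev == 0)) {
    bad <- colnames(y)[sdev == 0]
    if (is.null(bad)) bad <- which(sdev == 0)
    stop("constant feature column(s): ", paste(bad, collapse = ", "))
  }
  sweep(sweep(y, 2L, mu, "-"), 2L, sdev, "/")
}

#' @rdname zscore_features
#' @export
range_features <- function(y) {
  y <- as.matrix(y)
  mu <- colMeans(y)
  rng <- apply(y, 2L, function(col) max(col) - min(col))
  if (any(rng == 0)) {
    bad <- colnames(y)[rng == 0]
    if (is.null(bad)) bad <- which(rng == 0)
    stop("constant feature column(s): ", paste(bad, collapse = ", "))
  }
  sweep(sweep(y, 2L, mu, "-"), 2L, rng, "/")
}

#' Network standardization
#'
#' `modularity_shift()` removes the expected random-interaction score from each
#' link: entry \eqn{p_{ij}} becomes \eqn{p_{ij} - p_{i+} p_{+j} / p_{++}}, where
#' \eqn{p_{i+}}, \eqn{p_{+j}}, \eqn{p_{++}} are row, column and grand sums.
#' Every row sum and column sum of the result is 0. `scale_shift()` subtracts
#' the grand mean link score \eqn{\pi = \sum_{ij} p_{ij} / N^2} from every
#' entry, so the result has grand mean 0.
#'
#' @param p numeric square link matrix.
#' @return Matrix of the same shape.
#' @export
modularity_shift <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop("link matrix must be square")
  total <- sum(p)
  if (total == 0) stop("modularity shift undefined: all link weights are zero")
  p - outer(rowSums(p), colSums(p)) / total
}

#' @rdname modularity_shift
#' @export
scale_shift <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop("link matrix must be square")
  p - mean(p)
}

#' One-hot encode a feature table
#'
#' Expands each categorical column with m observed labels into m binary 0/1
#' dummy columns named `feature=level` (levels in sorted order); quantitative
#' columns pass through unchanged. The numeric criterion of the clustering
#' method requires an all-numeric matrix, and one-hot dummies are then treated
#' as ordinary numeric columns by the standardization step.
#'
#' @param x a [kefrin_features] object (or data.frame / numeric matrix).
#' @return Numeric matrix with node ids as rownames.
#' @export
encode_features <- function(x) {
  x <- as_kefrin_features(x)
  blocks <- vector("list", ncol(x$data))
  for (j in seq_along(x$data)) {
    nm <- names(x$data)[j]
    if (x$feature_kinds[j] == "quantitative") {
      blocks[[j]] <- matrix(x$data[[j]], ncol = 1L, dimnames = list(NULL, nm))
    } else {
      lab <- as.character(x$data[[j]])
      lev <- sort(unique(lab))
      d <- matrix(0, nrow = length(lab), ncol = length(lev),
                  dimnames = list(NULL, paste0(nm, "=", lev)))
      d[cbind(seq_along(lab), match(lab, lev))] <- 1
      blocks[[j]] <- d
    }
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- x$node_ids
  out
}

#' Row-wise unit norming
#'
#' Divides every nonzero row by its Euclidean norm; all-zero rows are left as
#' zero. Required preprocessing for the cosine variant, where all node vectors
#' (and centers) live on the unit sphere.
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape with unit (or zero) rows.
#' @export
row_norm <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# Applies the configured standardization pair and, for cosine, row-norming.
# Default selection: features -> z-scoring, network -> modularity shift,
# except network -> scale shift when any categorical feature is present.
prepare_inputs <- function(features, network, metric,
                           feature_std = c("z", "range", "none"),
                           network_std = NULL) {
  feature_std <- match.arg(feature_std)
  features <- as_kefrin_features(features)
  has_cat <- any(features$feature_kinds == "categorical")
  if (is.null(network_std)) network_std <- if (has_cat) "shift" else "modularity"
  network_std <- match.arg(network_std, c("modularity", "shift", "none"))

  y <- encode_features(features)
  p <- as.matrix(network)
  if (nrow(p) != ncol(p)) stop("link matrix must be square")
  if (nrow(p) != nrow(y)) stop("feature table and network disagree on N")
  if (!is.null(rownames(p))) {
    if (!setequal(rownames(p), features$node_ids))
      stop("network node ids do not match the feature table")
    p <- p[features$node_ids, features$node_ids, drop = FALSE]
  }

  y <- switch(feature_std, z = zscore_features(y), range = range_features(y), none = y)
  p <- switch(network_std, modularity = modularity_shift(p), shift = scale_shift(p), none = p)
  if (metric == "cosine") {
    y <- row_norm(y)
    p <- row_norm(p)
  }
  list(y = y, p = p, node_ids = features$node_ids,
       feature_std = feature_std, network_std = network_std)
}
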