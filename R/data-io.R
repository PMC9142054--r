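#' Node feature tables
#'
#' A `kefrin_features` object holds a node-by-feature table before numeric
#' encoding: quantitative columns are numeric, categorical columns are kept as
#' raw character labels. Node order is canonical: the paired network matrix is
#' always reindexed to the feature table's node order.
#'
#' @param data data.frame of feature columns (no node-id column).
#' @param node_ids character vector of unique node identifiers, one per row.
#' @param feature_kinds optional character vector (`"quantitative"` or
#'   `"categorical"`) per column; inferred from column types when missing.
#' @return An object of class `kefrin_features` with fields `data`,
#'   `node_ids` and `feature_kinds`.
#' @export
kefrin_features <- function(data, node_ids = rownames(data), feature_kinds = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(data)))
  node_ids <- as.character(node_ids)
  if (nrow(data) < 2L) stop("a feature table needs at least 2 nodes")
  if (ncol(data) < 1L) stop("a feature table needs at least 1 feature")
  if (length(node_ids) != nrow(data)) stop("node_ids length does not match row count")
  if (anyDuplicated(node_ids)) stop("duplicate node ids: ",
                                    paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))
  for (j in seq_along(data)) {
    if (is.factor(data[[j]])) data[[j]] <- as.character(data[[j]])
    if (anyNA(data[[j]])) stop("missing values in feature '", names(data)[j],
                               "'; complete data are required")
  }
  if (is.null(feature_kinds)) {
    feature_kinds <- ifelse(vapply(data, is.numeric, logical(1)),
                            "quantitative", "categorical")
  }
  feature_kinds <- match.arg(feature_kinds, c("quantitative", "categorical"),
                             several.ok = TRUE)
  if (length(feature_kinds) != ncol(data)) stop("feature_kinds length mismatch")
  names(feature_kinds) <- names(data)
  rownames(data) <- node_ids
  structure(list(data = data, node_ids = node_ids, feature_kinds = feature_kinds),
            class = "kefrin_features")
}

#' @export
print.kefrin_features <- function(x, ...) {
  cat("<kefrin_features> ", length(x$node_ids), " nodes x ", ncol(x$data),
      " features (", sum(x$feature_kinds == "quantitative"), " quantitative, ",
      sum(x$feature_kinds == "categorical"), " categorical)\n", sep = "")
  invisible(x)
}

as_kefrin_features <- function(x) {
  if (inherits(x, "kefrin_features")) return(x)
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x)) stop("cannot interpret 'features' as a feature table")
  kefrin_features(x)
}

#' Read a node feature table
#'
#' Reads a delimited text file whose first row is a header and whose first
#' column holds node identifiers. A column is tagged quantitative when every
#' entry parses as a number, categorical otherwise; categorical columns are
#' kept as raw labels until [encode_features()].
#'
#' @param path path to the file.
#' @param delimiter field separator (default `","`).
#' @return A [kefrin_features] object.
#' @export
read_features <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = delimiter, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "", fill = FALSE)
  if (nrow(raw) == 0L) stop("empty feature table: ", path)
  if (ncol(raw) < 2L) stop("feature table needs a node-id column plus >= 1 feature")
  node_ids <- raw[[1L]]
  dat <- raw[-1L]
  for (j in seq_along(dat)) {
    if (any(!nzchar(dat[[j]]))) stop("missing values in feature '", names(dat)[j], "'")
    num <- suppressWarnings(as.numeric(dat[[j]]))
    if (!anyNA(num)) dat[[j]] <- num
  }
  kefrin_features(dat, node_ids = node_ids)
}

#' Read a network link matrix
#'
#' Reads either a weighted edge list (`src dst [weight]`, default weight 1) or
#' a dense matrix with matching header and row identifiers, and returns the
#' dense N x N link matrix in the node order given by `node_ids` (normally the
#' feature table's order). Undirected edge lists are symmetrized; duplicate
#' directed pairs overwrite earlier ones unless `sum_duplicates = TRUE`.
#'
#' @param path path to the file.
#' @param format `"edgelist"` or `"matrix"`.
#' @param node_ids canonical node order; required for edge lists.
#' @param delimiter field separator (default `"\t"`).
#' @param directed for edge lists: keep edges as given instead of symmetrizing.
#' @param sum_duplicates for edge lists: accumulate repeated pairs instead of
#'   overwriting.
#' @return A numeric N x N matrix with `node_ids` as dimnames.
#' @export
read_network <- function(path, format = c("edgelist", "matrix"), node_ids = NULL,
                         delimiter = "\t", directed = FALSE, sum_duplicates = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    m <- as.matrix(read.table(path, header = TRUE, sep = delimiter, row.names = 1,
                              check.names = FALSE, comment.char = ""))
    if (nrow(m) != ncol(m)) stop("network matrix is not square: ",
                                 nrow(m), " x ", ncol(m))
    storage.mode(m) <- "double"
    if (!is.null(node_ids)) {
      node_ids <- as.character(node_ids)
      if (!setequal(rownames(m), node_ids))
        stop("network matrix ids do not match node_ids")
      m <- m[node_ids, node_ids, drop = FALSE]
    }
    return(m)
  }
  if (is.null(node_ids)) stop("node_ids are required to read an edge list")
  node_ids <- as.character(node_ids)
  ed <- read.table(path, header = FALSE, sep = delimiter, colClasses = "character",
                   stringsAsFactors = FALSE, comment.char = "", fill = FALSE)
  if (!ncol(ed) %in% c(2L, 3L)) stop("edge list must have 2 or 3 columns")
  w <- if (ncol(ed) == 3L) as.numeric(ed[[3L]]) else rep(1, nrow(ed))
  if (anyNA(w)) stop("non-numeric edge weight")
  src <- match(ed[[1L]], node_ids)
  dst <- match(ed[[2L]], node_ids)
  if (anyNA(src) || anyNA(dst)) {
    bad <- unique(c(ed[[1L]][is.na(src)], ed[[2L]][is.na(dst)]))
    stop("edge refers to unknown node(s): ", paste(bad, collapse = ", "))
  }
  n <- length(node_ids)
  m <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  for (e in seq_along(w)) {
    i <- src[e]; j <- dst[e]
    if (sum_duplicates) {
      m[i, j] <- m[i, j] + w[e]
      if (!directed && i != j) m[j, i] <- m[j, i] + w[e]
    } else {
      m[i, j] <- w[e]
      if (!directed) m[j, i] <- w[e]
    }
  }
  m
}

#' Write / read a partition file
#'
#' A partition is stored as a two-column tab-separated file `node_id<TAB>label`
#' with one row per node, in the canonical node order.
#'
#' @param partition integer label vector, or a [kefrin_fit] object.
#' @param node_ids node identifiers, same length as the labels.
#' @param path output path.
#' @export
write_partition <- function(partition, node_ids, path) {
  labels <- if (inherits(partition, "kefrin_fit")) partition$partition else partition
  if (length(labels) != length(node_ids))
    stop("partition length (", length(labels), ") does not match node_ids (",
         length(node_ids), ")")
  write.table(data.frame(node_id = as.character(node_ids), label = labels),
              file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @return `read_partition()` returns the integer label vector, named by node
#'   id; when `node_ids` is given, labels are reordered to that node order.
#' @export
read_partition <- function(path, node_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "\t", colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) != 2L) stop("partition file must have exactly 2 columns")
  labels <- as.integer(tab[[2L]])
  names(labels) <- tab[[1L]]
  if (!is.null(node_ids)) {
    idx <- match(as.character(node_ids), names(labels))
    if (anyNA(idx)) stop("partition file is missing node(s)")
    labels <- labels[idx]
  }
  labels
}
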