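#' The standard synthetic benchmark grid
#'
#' The eight (p, q, mix) settings of the synthetic experiments: p in
#' \{0.9, 0.7\}, q in \{0.3, 0.6\}, and the third slot ("mix") in
#' \{0.9, 0.7\} -- it is the center-spread factor alpha for quantitative
#' features and the homogeneity epsilon for categorical ones (both in the
#' mixed case).
#'
#' @return data.frame with columns `p`, `q`, `mix`, one row per setting.
#' @export
benchmark_settings <- function() {
  data.frame(p = rep(c(0.9, 0.7), each = 4),
             q = rep(rep(c(0.3, 0.6), each = 2), 2),
             mix = rep(c(0.9, 0.7), 4))
}

benchmark_preset <- function(size = c("small", "medium")) {
  size <- match.arg(size)
  if (size == "small") list(n = 200L, k = 5L, v = 5L, l_max = 10L)
  else list(n = 1000L, k = 10L, v = 10L, l_max = 15L)
}

#' Run the synthetic cluster-recovery benchmark
#'
#' For every setting of the grid, generates `replicates` feature-rich networks
#' with planted communities, clusters each with the requested metric variants
#' (using the default standardization rule and `n_init` random restarts), and
#' scores the recovered partitions against the planted truth by ARI.
#' Size presets: small (N = 200, K = 5, V = 5, L up to 10) and medium
#' (N = 1000, K = 10, V = 10, L up to 15).
#'
#' @param flavor `"quantitative"`, `"categorical"` or `"mixed"`.
#' @param size `"small"` or `"medium"`.
#' @param noise append uniform noise features.
#' @param settings data.frame with columns `p`, `q`, `mix`
#'   (default [benchmark_settings()]).
#' @param replicates datasets per setting (default 10).
#' @param metrics metric variants to run.
#' @param n_init random restarts per fit (default 10).
#' @param rho,xi space weights (defaults 1, 1).
#' @param seed integer seed; per-dataset and per-fit seeds are derived from it.
#' @param verbose print one line per completed cell.
#' @return data.frame with one row per (setting, replicate, metric):
#'   columns `p`, `q`, `mix`, `replicate`, `metric`, `ari`, `nmi`, `n_iter`,
#'   `converged`.
#' @export
kefrin_benchmark <- function(flavor = c("quantitative", "categorical", "mixed"),
                             size = c("small", "medium"), noise = FALSE,
                             settings = benchmark_settings(), replicates = 10,
                             metrics = c("euclidean", "cosine", "manhattan"),
                             n_init = 10, rho = 1, xi = 1, seed = NULL,
                             verbose = FALSE) {
  flavor <- match.arg(flavor)
  preset <- benchmark_preset(size)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n_cells <- nrow(settings)
  data_seeds <- matrix(sample.int(.Machine$integer.max, n_cells * replicates),
                       nrow = n_cells)
  fit_seeds <- array(sample.int(.Machine$integer.max,
                                n_cells * replicates * length(metrics)),
                     dim = c(n_cells, replicates, length(metrics)))
  out <- vector("list", n_cells * replicates * length(metrics))
  idx <- 0L
  for (cell in seq_len(n_cells)) {
    p <- settings$p[cell]; q <- settings$q[cell]; mix <- settings$mix[cell]
    for (rep_i in seq_len(replicates)) {
      ds <- generate_feature_rich_network(
        n = preset$n, k = preset$k, p = p, q = q, flavor = flavor,
        alpha = mix, epsilon = mix,
        v_quant = preset$v, v_cat = preset$v, l_max = preset$l_max,
        noise = noise, seed = data_seeds[cell, rep_i])
      for (m in seq_along(metrics)) {
        fit <- kefrin(ds$features, ds$network, k = preset$k,
                      metric = metrics[m], rho = rho, xi = xi,
                      n_init = n_init, seed = fit_seeds[cell, rep_i, m])
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          p = p, q = q, mix = mix, replicate = rep_i, metric = metrics[m],
          ari = adjusted_rand_index(fit$partition, ds$truth),
          nmi = normalized_mutual_information(fit$partition, ds$truth),
          n_iter = fit$n_iter, converged = fit$converged,
          stringsAsFactors = FALSE)
      }
    }
    if (verbose)
      message(sprintf("setting p=%.1f q=%.1f mix=%.1f done (%d/%d)",
                      p, q, mix, cell, n_cells))
  }
  do.call(rbind, out)
}

#' Summarize a benchmark run
#'
#' Aggregates per-replicate ARI into the mean(sd) layout of the synthetic
#' result tables: one row per (p, q, mix) setting and metric, plus an
#' `Average` row per metric over the settings.
#'
#' @param results data.frame from [kefrin_benchmark()].
#' @return data.frame with columns `p`, `q`, `mix`, `metric`, `mean_ari`,
#'   `sd_ari`, `n`.
#' @export
summarize_benchmark <- function(results) {
  agg <- aggregate(ari ~ p + q + mix + metric, data = results,
                   FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  out <- data.frame(agg[c("p", "q", "mix", "metric")],
                    mean_ari = agg$ari[, "mean"], sd_ari = agg$ari[, "sd"],
                    n = agg$ari[, "n"])
  out <- out[order(out$metric, -out$p, out$q, -out$mix), ]
  avg <- aggregate(mean_ari ~ metric, data = out, FUN = mean)
  avg <- data.frame(p = NA, q = NA, mix = NA, metric = avg$metric,
                    mean_ari = avg$mean_ari, sd_ari = NA,
                    n = tapply(out$n, out$metric, sum)[avg$metric])
  rownames(out) <- NULL
  rbind(out, avg)
}
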