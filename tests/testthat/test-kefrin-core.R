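test_that("pair distances match their definitions", {
  expect_equal(pair_distance(c(0, 0), c(1, 1), "euclidean"), 2)
  expect_equal(pair_distance(c(0, 0), c(1, 1), "manhattan"), 2)
  expect_equal(pair_distance(c(1, 0), c(0, 1), "cosine"), 1)
  expect_equal(pair_distance(c(2, 3), c(2, 3), "cosine"), 0)
  expect_equal(pair_distance(c(0, 0), c(1, 1), "cosine"), 1)  # zero-vector convention
  expect_error(pair_distance(1:2, 1:3, "euclidean"), "length")
})

test_that("for unit vectors the squared Euclidean distance is twice the cosine distance", {
  set.seed(11)
  for (rep in 1:20) {
    f <- rnorm(6); f <- f / sqrt(sum(f^2))
    g <- rnorm(6); g <- g / sqrt(sum(g^2))
    expect_equal(pair_distance(f, g, "euclidean"),
                 2 * pair_distance(f, g, "cosine"), tolerance = 1e-12)
  }
})

test_that("combined distance is the rho/xi weighted sum over the two spaces", {
  inst <- random_instance(n = 6, k = 2, v = 3, seed = 21)
  centers <- list(C = inst$C, Lambda = inst$L)
  d <- combined_distance(2, 1, inst$y, inst$p, centers, "euclidean", rho = 0.3, xi = 2)
  expect_equal(d, 0.3 * sum((inst$y[2, ] - inst$C[1, ])^2) +
                 2 * sum((inst$p[2, ] - inst$L[1, ])^2))
  # weight degeneracy: rho = 0 leaves pure network distance
  expect_equal(combined_distance(1, 2, inst$y, inst$p, centers, "manhattan",
                                 rho = 0, xi = 1),
               sum(abs(inst$p[1, ] - inst$L[2, ])))
})

test_that("assignment equals the exhaustive argmin oracle on random instances", {
  cases <- expand.grid(n = c(8, 30), k = c(2, 4), metric = c("euclidean", "manhattan", "cosine"),
                       stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(cases))) {
    inst <- random_instance(cases$n[ci], cases$k[ci], v = 4, seed = 100 + ci)
    centers <- list(C = inst$C, Lambda = inst$L)
    got <- assign_clusters(inst$y, inst$p, centers, cases$metric[ci])
    want <- oracle_assign(inst$y, inst$p, inst$C, inst$L, cases$metric[ci])
    expect_equal(got, want, info = paste(cases[ci, ], collapse = "/"))
  }
})

test_that("nodes sitting on centers are assigned there, and ties go to the smallest index", {
  y <- rbind(c(0, 0), c(5, 5), c(9, 9))
  p <- diag(3)
  centers <- list(C = y, Lambda = p)
  expect_equal(assign_clusters(y, p, centers, "euclidean"), c(1L, 2L, 3L))
  # exact tie between duplicated centers 1 and 3
  centers_tie <- list(C = y[c(1, 2, 1), ], Lambda = p[c(1, 2, 1), ])
  expect_equal(assign_clusters(y, p, centers_tie, "euclidean")[1], 1L)
})

test_that("center update takes within-cluster means, re-normed under cosine", {
  y <- rbind(c(0, 0), c(2, 4), c(9, 9))
  p <- matrix(1:9, 3, 3) * 1.0
  cen <- update_centers(y, p, labels = c(1L, 1L, 2L), k = 2, metric = "euclidean")
  expect_equal(cen$C[1, ], c(1, 2))
  expect_equal(cen$C[2, ], c(9, 9))          # singleton cluster keeps its row
  expect_equal(cen$Lambda[1, ], colMeans(p[1:2, ]))
  cen_cos <- update_centers(rbind(c(3, 4), c(3, 4), c(1, 0)), p,
                            labels = c(1L, 1L, 2L), k = 2, metric = "cosine")
  expect_equal(cen_cos$C[1, ], c(0.6, 0.8))
  expect_error(update_centers(y, p, labels = c(1L, 1L, 1L), k = 2), "empty cluster")
})

test_that("median centers are available for the Manhattan variant", {
  y <- cbind(c(0, 1, 10, 0, 0))
  p <- diag(5)
  cen <- update_centers(y, p, labels = c(1L, 1L, 1L, 2L, 2L), k = 2,
                        metric = "manhattan", centers_fun = "median")
  expect_equal(cen$C[1, 1], 1)  # median, not mean (11/3)
})

test_that("farthest-point seeding picks the distance-maximizing node deterministically", {
  y <- cbind(c(0, 0.1, 10, 10.1))
  p <- diag(4)
  set.seed(1); first <- sample.int(4, 1)  # replay the seeding's first draw
  set.seed(1)
  seeds <- initialize_seeds(y, p, k = 2, metric = "euclidean")
  expect_equal(seeds$seed_nodes[1], first)
  # from either end of the 1-D scale, the farthest node is at the other end
  expected_second <- if (first %in% c(1, 2)) 4L else 1L
  expect_equal(seeds$seed_nodes[2], expected_second)
  # explicit hand case: seeding from node 1, f(i) = de(y) + de(p) is maximal at node 4
  f <- sapply(2:4, function(i) (y[i] - y[1])^2 + sum((p[i, ] - p[1, ])^2))
  expect_equal(which.max(f) + 1L, 4L)
  set.seed(99)
  s1 <- initialize_seeds(y, p, k = 3, metric = "manhattan")
  set.seed(99)
  s2 <- initialize_seeds(y, p, k = 3, metric = "manhattan")
  expect_identical(s1, s2)
  expect_error(initialize_seeds(y, p, k = 5), "seeds")
  expect_error({set.seed(5); initialize_seeds(matrix(1, 4, 2), matrix(1, 4, 4), k = 2)},
               "distinct seeds")
})

test_that("the criterion is the total within-cluster combined distance", {
  inst <- random_instance(n = 10, k = 1, v = 3, seed = 31)
  labels <- rep(1L, 10)
  cen <- update_centers(inst$y, inst$p, labels, k = 1, metric = "euclidean")
  got <- criterion_value(inst$y, inst$p, labels, cen, "euclidean")
  # closed form: total within-variance around the grand means in both spaces
  want <- sum(sweep(inst$y, 2, colMeans(inst$y))^2) +
    sum(sweep(inst$p, 2, colMeans(inst$p))^2)
  expect_equal(got, want, tolerance = 1e-10)
  # zero when every node coincides with its center
  cen0 <- list(C = inst$y[1:2, ], Lambda = inst$p[1:2, ])
  expect_equal(criterion_value(inst$y[1:2, ], inst$p[1:2, ], 1:2, cen0, "euclidean"), 0)
})

test_that("merging two clusters never decreases the euclidean criterion at optimal centers", {
  inst <- random_instance(n = 8, k = 1, v = 2, seed = 41)
  one <- rep(1L, 8)
  f_one <- criterion_value(inst$y, inst$p, one,
                           update_centers(inst$y, inst$p, one, 1, "euclidean"),
                           "euclidean")
  # all 2-cluster partitions of 8 nodes
  for (code in 1:(2^7 - 1)) {
    labels <- as.integer(intToBits(code))[1:8] + 1L
    if (length(unique(labels)) < 2L) next
    f_two <- criterion_value(inst$y, inst$p, labels,
                             update_centers(inst$y, inst$p, labels, 2, "euclidean"),
                             "euclidean")
    expect_true(f_one >= f_two - 1e-9)
  }
})

test_that("the euclidean criterion trajectory is non-increasing and the fit recovers planted blocks", {
  ds <- generate_feature_rich_network(n = 80, k = 2, p = 0.95, q = 0.05,
                                      flavor = "quantitative", alpha = 0.95,
                                      v_quant = 4, seed = 51)
  fit <- kefrin(ds$features, ds$network, k = 2, metric = "euclidean",
                n_init = 3, seed = 52)
  expect_true(all(diff(fit$criterion_trajectory) <= 1e-9))
  expect_equal(adjusted_rand_index(fit$partition, ds$truth), 1)
  expect_true(fit$converged)
  expect_equal(sort(unique(fit$partition)), 1:2)
})

test_that("a degenerate K = N euclidean fit puts every node in its own cluster at criterion 0", {
  inst <- random_instance(n = 6, k = 1, v = 2, seed = 61)
  fit <- kefrin_fit(inst$y, inst$p, k = 6, metric = "euclidean", seed = 62)
  expect_equal(sort(fit$partition), 1:6)
  expect_equal(fit$criterion, 0)
})

test_that("every fitted partition has exactly K nonempty clusters", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 20
    y <- matrix(rnorm(n * 3), n, 3)
    p <- matrix(rnorm(n * n), n, n)
    for (m in c("euclidean", "manhattan", "cosine")) {
      ym <- y; pm <- p
      if (m == "cosine") { ym <- row_norm(ym); pm <- row_norm(pm) }
      fit <- kefrin_fit(ym, pm, k = 4, metric = m)
      expect_equal(length(unique(fit$partition)), 4L)
      expect_true(fit$n_iter <= 100)
    }
  }
})

test_that("node order permutation permutes the solution accordingly", {
  ds <- generate_feature_rich_network(n = 90, k = 3, p = 0.95, q = 0.05,
                                      flavor = "quantitative", alpha = 0.95,
                                      v_quant = 4, min_size = 25, seed = 81)
  y <- encode_features(ds$features)
  y <- zscore_features(y)
  p <- modularity_shift(ds$network)
  fit <- kefrin_fit(y, p, k = 3, metric = "euclidean", n_init = 5, seed = 82)
  perm <- sample(nrow(y))
  fit_perm <- kefrin_fit(y[perm, ], p[perm, perm], k = 3, metric = "euclidean",
                         n_init = 5, seed = 83)
  # both runs land on the same (planted) optimum expressed in permuted order
  expect_equal(adjusted_rand_index(fit$partition[perm], fit_perm$partition), 1)
})

test_that("restarts return the run with the smallest criterion and fits are reproducible", {
  inst <- random_instance(n = 25, k = 1, v = 3, seed = 91)
  f1 <- kefrin_fit(inst$y, inst$p, k = 3, metric = "euclidean", n_init = 8, seed = 92)
  f2 <- kefrin_fit(inst$y, inst$p, k = 3, metric = "euclidean", n_init = 8, seed = 92)
  expect_identical(f1$partition, f2$partition)
  expect_identical(f1$criterion, f2$criterion)
  single_runs <- sapply(1:8, function(i) {
    kefrin_fit(inst$y, inst$p, k = 3, metric = "euclidean", n_init = 1,
               seed = 92 + i)$criterion
  })
  expect_true(f1$criterion <= max(single_runs))
})

test_that("invalid fit configurations are rejected", {
  inst <- random_instance(n = 5, k = 1, v = 2, seed = 95)
  expect_error(kefrin_fit(inst$y, inst$p, k = 9), "1..N")
  expect_error(kefrin_fit(inst$y, inst$p, k = 2, rho = 0, xi = 0), "rho")
  expect_error(kefrin_fit(inst$y, inst$p[1:4, 1:4], k = 2), "disagree")
})
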