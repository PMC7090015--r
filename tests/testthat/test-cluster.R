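# 60 noisy filters drawn from the three archetypes (20% tap noise)
archetype_population <- function(seed, n_per_class = 20, noise_sd = 0.2) {
  set.seed(seed)
  classes <- rep(FILTER_CLASSES, each = n_per_class)
  filters <- lapply(classes, function(cl)
    linear_filter(as.numeric(make_template_filter(cl)) + rnorm(300, sd = noise_sd)))
  list(filters = filters, classes = classes)
}

test_that("PCA retains the requested variance and uses a fixed sign convention", {
  pop <- archetype_population(71, noise_sd = 0.05)   # low-noise regime
  pca <- pca_filters(pop$filters)
  expect_gte(sum(pca$explained_variance[seq_len(pca$k)]), 0.9)
  # three archetypes at low noise: top 3 PCs carry >= 90% of the variance
  expect_gte(sum(pca$explained_variance[1:3]), 0.9)
  for (i in seq_len(pca$k)) {
    j <- which.max(abs(pca$components[i, ]))
    expect_gt(pca$components[i, j], 0)
  }
  expect_error(pca_filters(pop$filters[1]), "at least 2")
})

test_that("identical filters give a degenerate zero-variance PCA", {
  same <- replicate(5, make_template_filter("biphasic"), simplify = FALSE)
  pca <- pca_filters(same)
  expect_true(pca$degenerate)
  expect_equal(pca$k, 0L)
})

test_that("a planted one-dimensional structure is recovered by the first component", {
  set.seed(72)
  direction <- rnorm(300); direction <- direction / sqrt(sum(direction^2))
  scores <- rnorm(40, sd = 5)
  X <- outer(scores, direction) + matrix(rnorm(40 * 300, sd = 0.05), 40)
  pca <- pca_filters(X)
  expect_gt(pca$explained_variance[1], 0.9)
  expect_gt(abs(cosine_similarity(pca$components[1, ], direction)), 0.99)
})

test_that("clustering separates planted blobs exactly and is order invariant", {
  set.seed(73)
  pts <- rbind(matrix(rnorm(30, sd = 0.1), ncol = 2),
               matrix(rnorm(30, sd = 0.1) + 10, ncol = 2))
  planted <- rep(1:2, each = 15)
  cl <- cluster_filters(pts, n_clusters = 2)
  expect_equal(length(unique(cl$labels)), 2)
  expect_true(all(table(cl$labels, planted) %in% c(0, 15)))
  # co-membership is preserved under permutation of the input order
  perm <- sample(30)
  cl_p <- cluster_filters(pts[perm, ], n_clusters = 2)
  back <- cl_p$labels[match(seq_len(30), perm)]
  expect_identical(outer(cl$labels, cl$labels, "=="), outer(back, back, "=="))
})

test_that("three filter archetypes are recovered with high agreement", {
  skip_if_not_installed("mclust")
  pop <- archetype_population(74)
  pca <- pca_filters(pop$filters)
  # cluster on the leading components carrying the class structure (the
  # trailing near-equal eigenvalues are isotropic tap noise)
  cl <- cluster_filters(pca, n_clusters = 3, select_pcs = 1:3)
  ari <- mclust::adjustedRandIndex(cl$labels, pop$classes)
  expect_gte(ari, 0.9)
  # the automatic gap rule also lands on three
  cl_auto <- cluster_filters(pca, n_clusters = "auto", select_pcs = 1:3)
  expect_equal(cl_auto$n_clusters, 3L)
})

test_that("duplicated points merge at height zero into one cluster", {
  pts <- matrix(rep(c(1, 2), each = 6), ncol = 2)
  cl <- cluster_filters(pts, n_clusters = 1)
  expect_true(all(cl$linkage$height == 0))
  expect_equal(length(unique(cl$labels)), 1)
  expect_error(cluster_filters(pts, n_clusters = 10), "exceeds")
})

test_that("average-linkage merge heights are monotone non-decreasing", {
  pop <- archetype_population(75)
  cl <- cluster_filters(pca_filters(pop$filters), n_clusters = 3)
  expect_true(all(diff(cl$linkage$height) >= -1e-12))
})

test_that("projection onto a reference PC space is consistent and closed-form", {
  pop <- archetype_population(76)
  pca <- pca_filters(pop$filters)
  self <- project_onto_components(pop$filters, pca)
  expect_lt(max(abs(self - pca$projections)), 1e-10)
  zero <- project_onto_components(list(linear_filter(rep(0, 300))), pca)
  expect_equal(as.numeric(zero),
               as.numeric(-pca$components %*% pca$center), tolerance = 1e-12)
  expect_error(project_onto_components(matrix(0, 2, 10), pca), "geometry")
})

test_that("flat and responsive filters separate along the dominant reference component", {
  pop <- archetype_population(77)
  pca <- pca_filters(pop$filters)
  set.seed(77)
  flat <- lapply(1:15, function(i) linear_filter(rnorm(300, sd = 0.02)))
  resp <- lapply(1:15, function(i)
    linear_filter(as.numeric(make_template_filter("monophasic_negative")) +
                    rnorm(300, sd = 0.1)))
  proj <- project_onto_components(c(flat, resp), pca)
  lab <- rep(1:2, each = 15)
  x <- proj[, 1]
  # silhouette along the dominant component
  sil <- vapply(seq_along(x), function(i) {
    own <- mean(abs(x[i] - x[lab == lab[i]][-which(which(lab == lab[i]) == i)]))
    oth <- mean(abs(x[i] - x[lab != lab[i]]))
    (oth - own) / max(own, oth)
  }, 0)
  expect_gt(mean(sil), 0.5)
})

test_that("peak latencies and shape classes match the template construction", {
  f <- make_template_filter("monophasic_negative", peak_latency = -3.7)
  rep1 <- peak_latencies(f)
  expect_equal(rep1$negative_peak_latency, -3.7, tolerance = 0.1)
  expect_identical(rep1$shape_class, "monophasic_negative")
  b <- make_template_filter("biphasic")
  rep2 <- peak_latencies(b)
  expect_identical(rep2$shape_class, "biphasic")
  expect_lt(abs(rep2$positive_peak_latency - (-5.2)), 0.15)
  expect_lt(abs(rep2$negative_peak_latency - 0.2), 0.15)
  # pure positive half-Gaussian: positive class, negative peak not meaningful
  tt <- filter_tap_times()
  half <- ifelse(tt > -5, exp(-0.5 * ((tt + 5) / 3)^2), 0)
  rep3 <- peak_latencies(linear_filter(half))
  expect_identical(rep3$shape_class, "monophasic_positive")
  expect_false(rep3$meaningful[["negative"]])
  # all-zero filter is undefined
  expect_true(peak_latencies(linear_filter(rep(0, 300)))$undefined)
})

test_that("time-shifting a filter shifts its peak latencies by the same amount", {
  f <- as.numeric(make_template_filter("biphasic"))
  shift <- 30   # taps = 3 ms
  f_shift <- c(f[-(1:shift)], rep(0, shift))   # peaks move 3 ms earlier
  r0 <- peak_latencies(linear_filter(f))
  r1 <- peak_latencies(linear_filter(f_shift))
  expect_equal(r1$negative_peak_latency, r0$negative_peak_latency - 3,
               tolerance = 0.1)
  expect_equal(r1$positive_peak_latency, r0$positive_peak_latency - 3,
               tolerance = 0.1)
})
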