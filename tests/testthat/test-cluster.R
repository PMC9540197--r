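test_that("repeated-measures F matches independent oracles", {
  set.seed(20)
  # identical columns -> F = 0
  v0 <- matrix(rnorm(6), 6, 4)
  expect_equal(rm_anova_f(v0)$f, 0)

  # matches aov's within-subjects decomposition on one table
  v <- matrix(rnorm(12), 4, 3)
  r <- rm_anova_f(v)
  d <- data.frame(y = as.vector(v), s = factor(rep(1:4, 3)),
                  cond = factor(rep(1:3, each = 4)))
  a <- summary(stats::aov(y ~ cond + Error(s / cond), d))
  expect_equal(r$f, a[["Error: s:cond"]][[1]]$`F value`[1], tolerance = 1e-10)
  expect_equal(r$df1, 2L)
  expect_equal(r$df2, 6L)

  # brute-force SS decomposition on random tables
  for (i in 1:25) {
    n <- sample(3:8, 1)
    k <- sample(2:5, 1)
    v <- matrix(rnorm(n * k), n, k)
    expect_equal(rm_anova_f(v)$f, bf_rm_anova_f(v), tolerance = 1e-8)
  }

  # k = 2: F equals the squared paired t
  for (i in 1:25) {
    v <- matrix(rnorm(16), 8, 2)
    tt <- stats::t.test(v[, 1], v[, 2], paired = TRUE)$statistic
    expect_equal(rm_anova_f(v)$f, unname(tt^2), tolerance = 1e-10)
  }

  expect_error(rm_anova_f(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("vectorized F map agrees with the scalar implementation", {
  set.seed(21)
  n <- 7
  k <- 4
  cells <- 30
  M <- matrix(rnorm(n * k * cells), n * k, cells)
  fvec <- speechcoh:::rm_anova_f_map(M, n, k)
  for (cell in c(1, 13, 30)) {
    v <- matrix(M[, cell], k, n)  # rows subject-major: k rows per subject
    expect_equal(fvec[cell], rm_anova_f(t(v))$f, tolerance = 1e-10)
  }
})

test_that("adjacency constructors validate structure", {
  adj <- grid_adjacency(3, 4)
  expect_length(adj, 12L)
  expect_true(speechcoh:::validate_adjacency(adj))
  expect_setequal(adj[[1]], c(2, 5))       # corner
  expect_setequal(adj[[6]], c(2, 5, 7, 10))  # interior

  edges <- data.frame(channel_a = c(1, 2), channel_b = c(2, 3))
  a2 <- adjacency_from_edges(edges, 3)
  expect_setequal(a2[[2]], c(1, 3))
  expect_error(adjacency_from_edges(data.frame(channel_a = 1, channel_b = 1), 2),
               "irreflexive")
})

test_that("cluster formation matches hand-built fixtures and igraph", {
  adj <- grid_adjacency(8, 8)
  fm <- matrix(0, 64, 7)
  expect_length(form_clusters(fm + 0.1, 3, adj), 0L)

  fm[30, 4] <- 5
  cl <- form_clusters(fm, 3, adj)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$stat, 5)
  expect_equal(cl[[1]]$cells$channel, 30)

  # two blobs: one spatio-spectral (channels 1,2 at f1 + channel 1 at f2),
  # one spatial-only, with hand-computed sums
  fm <- matrix(0, 64, 7)
  fm[1, 1] <- 4; fm[2, 1] <- 5; fm[1, 2] <- 6
  fm[40, 5] <- 7; fm[41, 5] <- 8   # hmm 40 and 41: row 5 col 8 and row 6 col 1
  cl <- form_clusters(fm, 3, adj)
  # channels 40 (r5c8) and 41 (r6c1) are NOT grid neighbors
  expect_length(cl, 3L)
  stats <- sort(vapply(cl, `[[`, numeric(1), "stat"))
  expect_equal(stats, c(7, 8, 15))

  # frequency adjacency off splits the spatio-spectral blob
  cl2 <- form_clusters(fm, 3, adj, freq_adjacent = FALSE)
  expect_length(cl2, 4L)

  # cross-check component structure against igraph on a random mask
  skip_if_not_installed("igraph")
  set.seed(22)
  fm <- matrix(rexp(64 * 7), 64, 7)
  thr <- 2
  cl3 <- form_clusters(fm, thr, adj)
  nbrs <- speechcoh:::cell_neighbors(adj, 7, TRUE)
  above <- which(as.vector(fm) > thr)
  el <- do.call(rbind, lapply(above, function(cell) {
    nb <- intersect(nbrs[[cell]], above)
    if (length(nb)) cbind(match(cell, above), match(nb, above)) else NULL
  }))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(above) - igraph::vcount(g))
  expect_equal(length(cl3), igraph::components(g)$no)
})

test_that("cluster membership is invariant to consistent channel relabeling", {
  set.seed(23)
  adj <- grid_adjacency(4, 4)
  fm <- matrix(rexp(16 * 5, rate = 0.5), 16, 5)
  perm <- sample(16)                 # new label of old channel ch is perm[ch]
  inv <- match(seq_len(16), perm)    # old channel carrying new label i
  fm_new <- fm[inv, , drop = FALSE]
  adj_new <- structure(lapply(seq_len(16), function(i) {
    sort(perm[adj[[inv[i]]]])
  }), class = "adjacency_graph")
  cl <- form_clusters(fm, 2, adj)
  cl_new <- form_clusters(fm_new, 2, adj_new)
  expect_equal(sort(vapply(cl, `[[`, numeric(1), "stat")),
               sort(vapply(cl_new, `[[`, numeric(1), "stat")),
               tolerance = 1e-12)
  # the relabeled clusters contain exactly the relabeled channels
  chans <- lapply(cl, function(x) sort(unique(perm[x$cells$channel])))
  chans_new <- lapply(cl_new, function(x) sort(unique(x$cells$channel)))
  expect_setequal(vapply(chans, paste, character(1), collapse = ","),
                  vapply(chans_new, paste, character(1), collapse = ","))
})

test_that("permutation test is reproducible and respects exchangeability", {
  set.seed(24)
  d <- array(rnorm(6 * 3 * 16 * 4), c(6, 3, 16, 4))
  adj <- grid_adjacency(4, 4)
  r1 <- suppressWarnings(cluster_permutation_test(d, adj, n_perm = 120,
                                                  seed = 3))
  r2 <- suppressWarnings(cluster_permutation_test(d, adj, n_perm = 120,
                                                  seed = 3))
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p"),
                   vapply(r2$clusters, `[[`, numeric(1), "p"))
  # null data: observed max-cluster stat lies inside the null support
  if (length(r1$clusters)) {
    expect_lte(r1$clusters[[1]]$stat, max(r1$null_max) * 3)
    expect_gt(r1$clusters[[1]]$p, 0)
    expect_lte(r1$clusters[[1]]$p, 1)
  }
  expect_warning(cluster_permutation_test(d, adj, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("BH post hocs match the brute-force step-up oracle", {
  p <- c(0.001, 0.01, 0.02, 0.9)
  expect_equal(stats::p.adjust(p, "BH"), c(0.004, 0.02, 0.08 / 3, 0.9),
               tolerance = 1e-12)
  set.seed(25)
  for (i in 1:200) {
    p <- runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bf_bh_adjust(p), tolerance = 1e-12)
    # BH rejects at least as much as Bonferroni
    expect_true(all(bf_bh_adjust(p) <= stats::p.adjust(p, "bonferroni") + 1e-15))
  }

  # identical conditions -> t = 0, p = 1, no rejections
  v <- matrix(rnorm(8), 8, 3)
  v[, 2] <- v[, 1]; v[, 3] <- v[, 1]
  ph <- paired_posthoc_fdr(v)
  expect_true(all(ph$t == 0))
  expect_true(all(ph$p == 1))
  expect_false(any(ph$reject))

  # with a real difference the pair is flagged
  set.seed(26)
  v <- cbind(rnorm(10), rnorm(10) + 3)
  ph2 <- paired_posthoc_fdr(v)
  expect_true(ph2$reject[1])
})
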