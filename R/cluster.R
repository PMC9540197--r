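#' Channel adjacency graphs
#'
#' An adjacency graph is a list of integer neighbor vectors, one per
#' channel, symmetric and irreflexive. `grid_adjacency()` builds the
#' 4-neighborhood of a rectangular `n_rows x n_cols` sensor grid (channels
#' numbered row-major); `adjacency_from_edges()` builds a graph from an
#' edge table such as one read from a two-column CSV.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @return An object of class `adjacency_graph`.
#' @export
grid_adjacency <- function(n_rows = 8, n_cols = 8) {
  n <- n_rows * n_cols
  nbrs <- vector("list", n)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      ch <- (r - 1L) * n_cols + c
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, ch - n_cols)
      if (r < n_rows) nb <- c(nb, ch + n_cols)
      if (c > 1L) nb <- c(nb, ch - 1L)
      if (c < n_cols) nb <- c(nb, ch + 1L)
      nbrs[[ch]] <- nb
    }
  }
  structure(nbrs, dims = c(n_rows, n_cols), class = "adjacency_graph")
}

#' @rdname grid_adjacency
#' @param edges Data frame with integer columns `channel_a`, `channel_b`
#'   (one row per undirected edge).
#' @param n_channels Total number of channels.
#' @export
adjacency_from_edges <- function(edges, n_channels) {
  stopifnot(is.data.frame(edges), all(c("channel_a", "channel_b") %in% names(edges)))
  a <- as.integer(edges$channel_a)
  b <- as.integer(edges$channel_b)
  if (any(a == b)) stop("adjacency must be irreflexive (no self-edges)")
  if (any(c(a, b) < 1L) || any(c(a, b) > n_channels)) {
    stop("edge endpoints outside 1..n_channels")
  }
  nbrs <- lapply(seq_len(n_channels), function(ch) {
    sort(unique(c(b[a == ch], a[b == ch])))
  })
  structure(nbrs, class = "adjacency_graph")
}

validate_adjacency <- function(adjacency) {
  stopifnot(inherits(adjacency, "adjacency_graph"))
  for (ch in seq_along(adjacency)) {
    if (ch %in% adjacency[[ch]]) stop("adjacency must be irreflexive")
    for (nb in adjacency[[ch]]) {
      if (!(ch %in% adjacency[[nb]])) stop("adjacency must be symmetric")
    }
  }
  invisible(TRUE)
}

#' One-way repeated-measures ANOVA F statistic
#'
#' Within-subjects F for a complete `subjects x conditions` table:
#' \eqn{F = MS_{condition} / MS_{condition \times subject}} with
#' `df1 = k - 1` and `df2 = (n - 1)(k - 1)`. For two conditions this
#' equals the squared paired t statistic.
#'
#' @param values Numeric `subjects x conditions` matrix, no missing cells.
#' @return List with `f`, `df1`, `df2`.
#' @export
rm_anova_f <- function(values) {
  stopifnot(is.matrix(values))
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  if (any(!is.finite(values))) stop("missing or non-finite cells (no imputation)")
  gm <- mean(values)
  cm <- colMeans(values)
  sm <- rowMeans(values)
  ss_cond <- n * sum((cm - gm)^2)
  resid <- values - matrix(cm, n, k, byrow = TRUE) - matrix(sm, n, k) + gm
  ss_err <- sum(resid^2)
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  f <- if (ss_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else {
    (ss_cond / df1) / (ss_err / df2)
  }
  list(f = f, df1 = df1, df2 = df2)
}

# Vectorized per-cell repeated-measures F.
# M: (n*k) x n_cells matrix, rows subject-major (subject blocks of k rows,
# conditions in order within each block). Returns a vector of F values.
rm_anova_f_map <- function(M, n, k) {
  g <- rep.int(seq_len(k), n)
  s <- rep(seq_len(n), each = k)
  cm <- rowsum(M, g, reorder = TRUE) / n          # k x C
  sm <- rowsum(M, s, reorder = TRUE) / k          # n x C
  gm <- colMeans(M)
  ss_cond <- n * colSums((cm - matrix(gm, k, ncol(M), byrow = TRUE))^2)
  R <- M - cm[g, , drop = FALSE] - sm[s, , drop = FALSE] +
    matrix(gm, nrow(M), ncol(M), byrow = TRUE)
  ss_err <- colSums(R^2)
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  f <- (ss_cond / df1) / (ss_err / df2)
  f[ss_err == 0 & ss_cond == 0] <- 0
  f
}

# Cell neighbor lists for a channels x frequencies lattice: spatial
# neighbors at the same frequency plus (optionally) the same channel at
# adjacent frequency bins. Cells are numbered channel-fastest:
# cell = (f - 1) * n_ch + ch.
cell_neighbors <- function(adjacency, n_freqs, freq_adjacent = TRUE) {
  n_ch <- length(adjacency)
  nbrs <- vector("list", n_ch * n_freqs)
  for (f in seq_len(n_freqs)) {
    base <- (f - 1L) * n_ch
    for (ch in seq_len(n_ch)) {
      nb <- adjacency[[ch]] + base
      if (freq_adjacent) {
        if (f > 1L) nb <- c(nb, ch + base - n_ch)
        if (f < n_freqs) nb <- c(nb, ch + base + n_ch)
      }
      nbrs[[base + ch]] <- nb
    }
  }
  nbrs
}

# Connected components of the supra-threshold cells; returns a list of
# integer cell-index vectors. `nbrs` is the full-lattice neighbor list.
connected_components <- function(above, nbrs) {
  idx <- which(above)
  if (length(idx) == 0L) return(list())
  seen <- logical(length(above))
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0L) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      members <- c(members, cur)
      for (nb in nbrs[[cur]]) {
        if (above[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Form spatio-spectral clusters from a statistic map
#'
#' Groups supra-threshold cells of a `channels x frequencies` F map into
#' connected clusters. Two cells are connected when they are spatial
#' neighbors (per `adjacency`) at the same frequency, or (with
#' `freq_adjacent = TRUE`, the default) the same channel at adjacent
#' frequency bins. Each cluster's statistic is the sum of its members' F
#' values.
#'
#' @param stat_map Numeric `channels x frequencies` matrix of F values.
#' @param threshold Cluster-forming threshold (> 0), e.g. the parametric F
#'   critical value at the cell-level alpha.
#' @param adjacency An `adjacency_graph` over the channels.
#' @param freq_adjacent Cluster across adjacent frequency bins as well as
#'   space (default `TRUE`).
#' @return List of clusters, each a list with `cells` (data frame with
#'   columns `channel`, `freq_index`) and `stat` (summed F), ordered by
#'   decreasing `stat`. Empty list when no cell exceeds the threshold.
#' @export
form_clusters <- function(stat_map, threshold, adjacency,
                          freq_adjacent = TRUE) {
  stopifnot(is.matrix(stat_map), threshold > 0,
            nrow(stat_map) == length(adjacency))
  n_ch <- nrow(stat_map)
  n_f <- ncol(stat_map)
  nbrs <- cell_neighbors(adjacency, n_f, freq_adjacent)
  fvec <- as.vector(stat_map)  # channel-fastest, matching cell_neighbors
  comps <- connected_components(fvec > threshold, nbrs)
  clusters <- lapply(comps, function(cells) {
    list(cells = data.frame(channel = ((cells - 1L) %% n_ch) + 1L,
                            freq_index = ((cells - 1L) %/% n_ch) + 1L),
         stat = sum(fvec[cells]),
         cell_index = cells)
  })
  if (length(clusters) > 1L) {
    clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "stat"),
                               decreasing = TRUE)]
  }
  clusters
}

#' Cluster-corrected permutation repeated-measures ANOVA
#'
#' Per-cell one-way repeated-measures ANOVA across conditions on a
#' `subjects x conditions x channels x frequencies` array, with
#' multiple-comparison control by a nonparametric Monte Carlo max-cluster
#' randomization test: condition labels are permuted independently within
#' each subject (the exchangeability implied by the within-subjects null),
#' the F map is recomputed, supra-threshold cells are clustered, and the
#' largest cluster statistic of each permutation forms the null
#' distribution. Observed clusters receive the Monte Carlo p-value
#' `(1 + #[null >= observed]) / (1 + n_perm)` and are significant below
#' `alpha`.
#'
#' @param data Numeric array `subjects x conditions x channels x
#'   frequencies`, complete.
#' @param adjacency An `adjacency_graph` over the channels.
#' @param n_perm Number of random permutations (default 5000; fewer than
#'   100 triggers a warning about unstable p-values).
#' @param alpha Cluster significance level (default 0.05).
#' @param cluster_alpha Cell-level alpha defining the parametric
#'   cluster-forming F threshold (default 0.05).
#' @param seed Integer seed; results are reproducible given
#'   `(data, seed, n_perm)`.
#' @param freq_adjacent Cluster across adjacent frequency bins (default
#'   `TRUE`).
#' @return An object of class `cluster_test_result`: list with `clusters`
#'   (each with `cells`, `stat`, `p`, `significant`), `f_map`,
#'   `threshold`, `df1`, `df2`, `null_max`, `n_perm`, `alpha`, `seed`.
#' @export
cluster_permutation_test <- function(data, adjacency, n_perm = 5000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     seed = 1L, freq_adjacent = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (n_perm < 100) warning("n_perm < 100 gives unstable p-values")
  d <- dim(data)
  n <- d[1L]
  k <- d[2L]
  n_ch <- d[3L]
  n_f <- d[4L]
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  if (any(!is.finite(data))) stop("missing or non-finite cells")
  if (n_ch != length(adjacency)) stop("adjacency size does not match channels")

  # rows subject-major, conditions in order within each subject block;
  # columns are (channel, frequency) cells, channel-fastest
  M <- matrix(aperm(data, c(2L, 1L, 3L, 4L)), n * k, n_ch * n_f)
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  threshold <- stats::qf(1 - cluster_alpha, df1, df2)
  nbrs <- cell_neighbors(adjacency, n_f, freq_adjacent)

  f_obs <- rm_anova_f_map(M, n, k)
  comps <- connected_components(f_obs > threshold, nbrs)
  obs_stats <- vapply(comps, function(cells) sum(f_obs[cells]), numeric(1))

  base <- (seq_len(n) - 1L) * k
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- vapply(seq_len(n), function(s) sample.int(k), integer(k))
      idx <- as.vector(perm + rep(base, each = k))
      fp <- rm_anova_f_map(M[idx, , drop = FALSE], n, k)
      cc <- connected_components(fp > threshold, nbrs)
      if (length(cc) == 0L) {
        0
      } else {
        max(vapply(cc, function(cells) sum(fp[cells]), numeric(1)))
      }
    }, numeric(1))
  })

  ord <- order(obs_stats, decreasing = TRUE)
  clusters <- lapply(ord, function(i) {
    cells <- comps[[i]]
    p <- (1 + sum(null_max >= obs_stats[i])) / (1 + n_perm)
    list(cells = data.frame(channel = ((cells - 1L) %% n_ch) + 1L,
                            freq_index = ((cells - 1L) %/% n_ch) + 1L),
         cell_index = cells,
         stat = obs_stats[i],
         p = p,
         significant = p < alpha)
  })
  structure(list(clusters = clusters,
                 f_map = matrix(f_obs, n_ch, n_f),
                 threshold = threshold, df1 = df1, df2 = df2,
                 null_max = null_max, n_perm = n_perm, alpha = alpha,
                 seed = seed),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), threshold F(%d,%d) = %.3f, %d permutations\n",
              length(x$clusters), x$df1, x$df2, x$threshold, x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  stat = %.2f, %d cells, p = %.4g%s\n", cl$stat,
                nrow(cl$cells), cl$p, if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' Paired post hoc t tests with Benjamini-Hochberg correction
#'
#' Dependent-samples t tests between all condition pairs (e.g. on
#' cluster-averaged coherence or power values), with p-values adjusted by
#' the Benjamini-Hochberg step-up FDR procedure over all pairs.
#'
#' @param values Numeric `subjects x conditions` matrix; column names are
#'   used as condition labels.
#' @param q FDR level for the rejection flags (default 0.05).
#' @return Data frame with one row per pair: `cond_a`, `cond_b`, `t`,
#'   `df`, `p`, `p_fdr`, `reject`.
#' @export
paired_posthoc_fdr <- function(values, q = 0.05) {
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  k <- ncol(values)
  labs <- colnames(values) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(pr) {
    ddiff <- values[, pr[1L]] - values[, pr[2L]]
    if (stats::sd(ddiff) == 0) {
      c(t = 0, df = length(ddiff) - 1L, p = 1)
    } else {
      tt <- stats::t.test(values[, pr[1L]], values[, pr[2L]], paired = TRUE)
      c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
  })
  out <- data.frame(cond_a = labs[pairs[1L, ]], cond_b = labs[pairs[2L, ]],
                    t = res["t", ], df = res["df", ], p = res["p", ])
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$reject <- out$p_fdr < q
  rownames(out) <- NULL
  out
}
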