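# Cross-view structure: pairwise Kullback-Leibler divergences between
# pathology patterns, the mutual-divergence affinity, the symmetric
# normalised Laplacian, its spectral embedding, and view clustering.

#' Kullback-Leibler divergence between two patterns
#'
#' `D(p || q) = sum_i p(i) ln(p(i) / q(i))` in nats. Nonnegative, zero iff
#' `p = q`, and asymmetric — which is why downstream affinities use the
#' mutual (symmetrised) divergence. Inputs must be probability vectors with
#' strictly positive entries (the pattern pipeline floors them at epsilon).
#'
#' @param p,q Probability vectors of equal length (sum to 1, entries > 0).
#' @return Nonnegative scalar.
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.9, 0.1)) # ~0.51083
#' @export
kl_divergence <- function(p, q) {
  assert_that(length(p) == length(q), "p and q must have equal length")
  assert_that(abs(sum(p) - 1) < 1e-6 && abs(sum(q) - 1) < 1e-6,
              "p and q must each sum to 1")
  assert_that(all(p > 0) && all(q > 0), "entries must be strictly positive")
  sum(p * log(p / q))
}

pattern_vec <- function(x) {
  if (inherits(x, "view_pattern")) x$normalized else as.numeric(x)
}

#' Pairwise divergence matrix over views
#'
#' Full `M x M` matrix in the orientation `d[row, col] = D(col-view ||
#' row-view)`: the entry in row `r`, column `c` is the divergence of the
#' row view's pattern from the column view's pattern. The number of
#' unordered pairs, `M (M - 1) / 2`, is carried as attribute `n_pairs`.
#'
#' @param patterns A `crossview_patterns` object or named list of patterns /
#'   probability vectors.
#' @return A `crossview_divergence` matrix.
#' @examples
#' bench <- default_benchmark(seed = 1, n_scale = 0.2)
#' d <- divergence_matrix(compute_patterns(bench$table))
#' attr(d, "n_pairs") # 36 for 9 views
#' @export
divergence_matrix <- function(patterns) {
  vecs <- lapply(patterns, pattern_vec)
  m <- length(vecs)
  assert_that(m >= 2, "need at least 2 views")
  nm <- names(vecs) %||% paste0("view", seq_len(m))
  d <- matrix(0, m, m, dimnames = list(nm, nm))
  for (r in seq_len(m)) for (co in seq_len(m)) {
    if (r != co) d[r, co] <- kl_divergence(vecs[[co]], vecs[[r]])
  }
  structure(d, n_pairs = m * (m - 1L) / 2L,
            class = c("crossview_divergence", "matrix", "array"))
}

#' @exportS3Method generics::tidy
tidy.crossview_divergence <- function(x, ...) {
  nm <- rownames(x)
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("row_view", "col_view", "divergence")) |>
    dplyr::mutate(row_view = as.character(.data$row_view),
                  col_view = as.character(.data$col_view))
}

#' Mutual-divergence affinity
#'
#' `A(P, Q) = exp(-(D(P||Q) + D(Q||P)) / (2 pi))`: symmetric, in `(0, 1]`,
#' equal to 1 for identical patterns and strictly decreasing in the mutual
#' divergence.
#'
#' @param p,q Patterns (`view_pattern` or probability vectors).
#' @return Scalar in `(0, 1]`.
#' @export
affinity <- function(p, q) {
  pv <- pattern_vec(p); qv <- pattern_vec(q)
  exp(-(kl_divergence(pv, qv) + kl_divergence(qv, pv)) / (2 * pi))
}

#' Affinity matrix from a divergence matrix
#'
#' @param d A `crossview_divergence` matrix (or plain matrix in the same
#'   orientation).
#' @return A symmetric `crossview_affinity` matrix with unit diagonal.
#' @export
affinity_matrix <- function(d) {
  d <- unclass(d)
  a <- exp(-(d + t(d)) / (2 * pi))
  structure(a, class = c("crossview_affinity", "matrix", "array"))
}

#' Symmetric normalised graph Laplacian of a view-affinity matrix
#'
#' Zeroes the affinity diagonal (self-affinity only shifts the spectrum),
#' forms the degree matrix `D` from row sums, and returns
#' `L = I - D^{-1/2} A D^{-1/2}` — symmetric, positive semi-definite, with
#' eigenvalues in `[0, 2]` and null eigenvector proportional to
#' `D^{1/2} 1`.
#'
#' @param a A `crossview_affinity` (or symmetric matrix with positive
#'   off-diagonal entries), `M >= 2`.
#' @return `M x M` symmetric matrix.
#' @export
laplacian <- function(a) {
  a <- unclass(a)
  m <- nrow(a)
  assert_that(!is.null(m) && m >= 2 && ncol(a) == m,
              "affinity must be a square matrix with M >= 2")
  diag(a) <- 0
  deg <- rowSums(a)
  assert_that(all(deg > 0), "isolated view (zero affinity row)")
  s <- 1 / sqrt(deg)
  l <- diag(m) - (s %o% s) * a
  (l + t(l)) / 2
}

#' Spectral embedding of views
#'
#' Embeds the `M` views into `k` dimensions using the eigenvectors of the
#' `k` smallest eigenvalues of the normalised Laplacian (the informative
#' low-frequency modes of the view graph). The trivial 0-eigenvalue mode is
#' kept as the first coordinate by default, mirroring a raw 2-D display of
#' the first two eigenmodes; set `include_trivial = FALSE` to start at the
#' first nontrivial mode. Signs are fixed by making each column's
#' largest-magnitude entry positive, so the embedding is deterministic.
#'
#' @param a Affinity matrix (see [laplacian()]).
#' @param k Embedding dimension (default 2).
#' @param include_trivial Keep the 0-mode as coordinate 1?
#' @return A `crossview_embedding`: list with `coordinates` (`M x k`),
#'   `eigenvalues`, `view_names`.
#' @export
spectral_embed <- function(a, k = 2, include_trivial = TRUE) {
  l <- laplacian(a)
  m <- nrow(l)
  take <- if (include_trivial) seq_len(k) else seq_len(k) + 1L
  assert_that(max(take) <= m, "k too large for ", m, " views")
  e <- eigen(l, symmetric = TRUE)
  ord <- order(e$values) # ascending; ties keep eigen's ordering
  vals <- e$values[ord][take]
  vecs <- e$vectors[, ord, drop = FALSE][, take, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  nm <- rownames(unclass(a)) %||% paste0("view", seq_len(m))
  rownames(vecs) <- nm
  structure(list(coordinates = vecs, eigenvalues = pmax(vals, 0),
                 view_names = nm),
            class = "crossview_embedding")
}

#' @export
print.crossview_embedding <- function(x, ...) {
  cat("<crossview_embedding>", length(x$view_names), "views in",
      ncol(x$coordinates), "dimension(s); eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.crossview_embedding <- function(x, ...) {
  co <- x$coordinates
  colnames(co) <- paste0("dim", seq_len(ncol(co)))
  dplyr::bind_cols(tibble::tibble(view = x$view_names),
                   tibble::as_tibble(co))
}

#' Cluster views in the spectral embedding
#'
#' Runs k-means (50 restarts, seeded) on the embedding coordinates.
#'
#' @param embedding A [spectral_embed()] result.
#' @param n_clusters Number of clusters (default 4).
#' @param seed Integer seed; the clustering is deterministic given it.
#' @param restarts k-means restarts.
#' @param row_normalize Row-normalise coordinates to unit length first?
#' @return A `view_clustering`: tibble with `view` and `cluster`.
#' @export
cluster_views <- function(embedding, n_clusters = 4, seed = 20160223,
                          restarts = 50, row_normalize = FALSE) {
  co <- embedding$coordinates
  m <- nrow(co)
  assert_that(n_clusters >= 1 && n_clusters <= m,
              "n_clusters must lie in [1, M]")
  if (row_normalize) {
    nr <- sqrt(rowSums(co^2))
    co <- co / ifelse(nr > 0, nr, 1)
  }
  cl <- if (n_clusters == m) seq_len(m)
  else local_seed(seed,
    kmeans(co, centers = n_clusters, nstart = restarts)$cluster)
  out <- tibble::tibble(view = embedding$view_names,
                        cluster = as.integer(cl))
  class(out) <- c("view_clustering", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.crossview_embedding <- function(object, clustering = NULL, ...) {
  df <- tidy(object)
  if (!is.null(clustering))
    df <- dplyr::left_join(df, clustering, by = "view")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1,
                                        y = if (ncol(object$coordinates) > 1)
                                          .data$dim2 else 0))
  if (!is.null(clustering))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster)),
                                 size = 3) +
      ggplot2::labs(colour = "cluster")
  else p <- p + ggplot2::geom_point(size = 3)
  p + ggplot2::geom_text(ggplot2::aes(label = .data$view),
                         vjust = -0.8, size = 3) +
    ggplot2::labs(x = "eigenmode 1", y = "eigenmode 2",
                  title = "Spectral embedding of views") +
    ggplot2::theme_minimal()
}
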