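#' Ward minimum-variance hierarchical clustering of cells
#'
#' Agglomerative clustering on Euclidean distances between cell expression
#' vectors, merging at each step the pair of clusters whose union minimally
#' increases the total within-cluster sum of squares (the merge heights
#' reported are exactly those ESS increases, so they are non-decreasing).
#' Implemented with the Lance-Williams recurrence; ties are broken
#' deterministically by merging the lowest-index pair first (smallest first
#' cluster index, then smallest second index).
#'
#' @param expr an [expression_matrix()] or complete numeric matrix (cells x
#'   genes).
#' @param k number of clusters to cut to (2 <= k <= n cells; k = n gives
#'   every cell its own cluster).
#' @return a `cluster_result`: list with `method = "ward"`, `k`, `labels`
#'   (named integer vector, cluster indices 1..k in order of first
#'   appearance), `linkage_heights` and `merges`.
#' @export
ward_cluster <- function(expr, k) {
  x <- as_values(expr)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k out of range", call. = FALSE)
  lk <- ward_linkage(x)
  labels <- cut_merges(lk$merges, n, k)
  names(labels) <- rownames(x)
  structure(list(method = "ward", k = k, labels = labels,
                 linkage_heights = lk$heights, merges = lk$merges),
            class = "cluster_result")
}

ward_linkage <- function(x) {
  n <- nrow(x)
  if (n == 1) return(list(merges = matrix(0L, 0, 2), heights = numeric(0)))
  D <- as.matrix(stats::dist(x))^2 / 2      # singleton merge cost = ESS increase
  diag(D) <- Inf
  size <- rep(1, n)
  active <- rep(TRUE, n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    idx <- which.min(D)                     # column-major: lowest-index pair first
    j <- (idx - 1L) %/% n + 1L
    i <- (idx - 1L) %% n + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    h <- D[i, j]
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks) > 0) {
      ni <- size[i]; nj <- size[j]; nk <- size[ks]
      upd <- ((ni + nk) * D[ks, i] + (nj + nk) * D[ks, j] - nk * h) /
        (ni + nj + nk)
      D[i, ks] <- D[ks, i] <- upd
    }
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    size[i] <- size[i] + size[j]
    merges[s, ] <- c(i, j)
    heights[s] <- h
  }
  list(merges = merges, heights = heights)
}

cut_merges <- function(merges, n, k) {
  memb <- seq_len(n)
  nsteps <- n - k
  for (s in seq_len(nsteps)) memb[memb == merges[s, 2]] <- merges[s, 1]
  relabel_first_appearance(memb)
}

relabel_first_appearance <- function(memb) {
  u <- unique(memb)
  match(memb, u)
}

#' K-means clustering of cells (Lloyd iterations, multiple restarts)
#'
#' Each restart initializes centers at `k` distinct random cells; assignment
#' and center updates iterate to convergence; a cluster that empties is
#' re-seeded at the point farthest from its assigned center. The
#' best-inertia solution over restarts is returned; identical seeds give
#' identical results.
#'
#' @param expr an [expression_matrix()] or complete numeric matrix.
#' @param k number of clusters (2 <= k <= n cells).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @return a `cluster_result` with `method = "kmeans"`, `labels` and
#'   `inertia` (total within-cluster sum of squares).
#' @export
kmeans_cluster <- function(expr, k, n_restarts = 10, seed = 1L) {
  x <- as_values(expr)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k out of range", call. = FALSE)
  res <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(x, k)
      if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
    }
    best
  })
  labels <- relabel_first_appearance(res$assign)
  names(labels) <- rownames(x)
  structure(list(method = "kmeans", k = k, labels = labels,
                 inertia = res$inertia),
            class = "cluster_result")
}

lloyd_once <- function(x, k, max_iter = 100) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  assign <- rep(1L, n)
  for (iter in seq_len(max_iter)) {
    d <- point_center_dist2(x, centers)
    assign <- max.col(-d, ties.method = "first")
    # an emptied cluster claims the point farthest from its current center
    for (j in which(tabulate(assign, k) == 0)) {
      far <- which.max(d[cbind(seq_len(n), assign)])
      assign[far] <- j
    }
    if (identical(assign, assign_old)) break
    assign_old <- assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  d <- point_center_dist2(x, centers)
  inertia <- 0
  for (j in seq_len(k)) {
    xs <- x[assign == j, , drop = FALSE]
    inertia <- inertia + sum(sweep(xs, 2, colMeans(xs))^2)
  }
  list(assign = assign, centers = centers, inertia = inertia)
}

point_center_dist2 <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(-2 * cross, 2, rowSums(centers^2), "+") + rowSums(x^2)
}

#' Cubic clustering criterion (Sarle's approximation)
#'
#' Compares the observed clustering R-squared (1 minus the ratio of
#' within-cluster to total sum of squares) with its expectation under a
#' uniform hyperbox null whose edge proportions come from the data's
#' principal-component scales, returning the standardized difference. Used
#' to choose the cluster count: larger is better, positive values indicate
#' more structure than the uniform null.
#'
#' @param expr an [expression_matrix()] or numeric matrix the clustering was
#'   fitted on.
#' @param labels cluster labels (a `cluster_result` or an integer vector in
#'   matrix row order / named by cell).
#' @param k cluster count; `k = 1` is undefined and returns `NA`.
#' @return CCC value (scalar), or `NA_real_` for `k = 1`.
#' @export
ccc <- function(expr, labels, k) {
  x <- as_values(expr)
  if (k == 1) return(NA_real_)
  lab <- extract_labels(labels, rownames(x))
  n <- nrow(x); p <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  tss <- sum(xc^2)
  if (tss == 0) return(NA_real_)
  wss <- 0
  for (cl in unique(lab)) {
    xs <- x[lab == cl, , drop = FALSE]
    wss <- wss + sum(sweep(xs, 2, colMeans(xs))^2)
  }
  r2 <- 1 - wss / tss
  v <- svd(xc, nu = 0, nv = 0)$d / sqrt(n - 1)   # PC scales
  v <- v[v > 1e-12 * max(v)]
  p_eff <- length(v)
  pstar <- 1
  for (j in seq_len(p_eff)) {
    cc <- (prod(v[seq_len(j)]) / k)^(1 / j)
    if (v[j] >= cc) pstar <- j
  }
  cc <- (prod(v[seq_len(pstar)]) / k)^(1 / pstar)
  u <- v / cc
  num <- sum(1 / (n + u[seq_len(pstar)]))
  if (pstar < p_eff)
    num <- num + sum(u[(pstar + 1):p_eff]^2 / (n + u[(pstar + 1):p_eff]))
  e_r2 <- 1 - (num / sum(u^2)) * ((n - k)^2 / n) * (1 + 4 / n)
  if (!is.finite(e_r2) || e_r2 >= 1 || r2 >= 1) return(NA_real_)
  log((1 - e_r2) / (1 - r2)) * sqrt(n * pstar / 2) / (0.001 + e_r2)^1.2
}

extract_labels <- function(labels, cell_ids) {
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  if (!is.null(names(labels)) && !is.null(cell_ids)) {
    if (!all(cell_ids %in% names(labels)))
      stop("labels do not cover all cells", call. = FALSE)
    labels <- labels[cell_ids]
  }
  as.integer(labels)
}

#' Concordance between two cell clusterings
#'
#' Percentage of shared cells ascribed to corresponding clusters, after
#' finding the one-to-one cluster-index matching that maximizes agreement
#' (optimal assignment on the confusion matrix; when the cluster counts
#' differ, unmatched clusters contribute zero). Symmetric in its arguments
#' and invariant to cluster-index permutations.
#'
#' @param a,b `cluster_result`s or named cluster-label vectors.
#' @param ids optional pair of pipeline identifiers for the report.
#' @return a `concordance_result`: list with `method_pair`, `shared_cells`,
#'   `matching` (index map from a's clusters to b's) and `concordance_pct`.
#' @export
concordance <- function(a, b, ids = c("a", "b")) {
  la <- if (inherits(a, "cluster_result")) a$labels else a
  lb <- if (inherits(b, "cluster_result")) b$labels else b
  if (is.null(names(la)) || is.null(names(lb)))
    stop("labels must be named by cell id", call. = FALSE)
  shared <- intersect(names(la), names(lb))
  if (length(shared) == 0) stop("no shared cells", call. = FALSE)
  ca <- as.integer(factor(la[shared]))
  cb <- as.integer(factor(lb[shared]))
  conf <- table(ca, cb)
  K <- max(dim(conf))
  if (K > 8) stop("exact cluster matching supports at most 8 clusters",
                  call. = FALSE)
  Cm <- matrix(0, K, K)
  Cm[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  perms <- permutations(K)
  agree <- apply(perms, 1, function(pm) sum(Cm[cbind(seq_len(K), pm)]))
  best <- perms[which.max(agree), ]
  matching <- best[seq_len(nrow(conf))]
  matching[matching > ncol(conf)] <- NA_integer_
  structure(list(method_pair = ids, shared_cells = length(shared),
                 matching = matching,
                 concordance_pct = 100 * max(agree) / length(shared)),
            class = "concordance_result")
}

permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance %s vs %s: %.1f%% over %d shared cells\n",
              x$method_pair[1], x$method_pair[2], x$concordance_pct,
              x$shared_cells))
  invisible(x)
}

#' Choose the cluster count by CCC
#'
#' Cuts a Ward tree (or runs k-means) at each candidate k and returns the k
#' with the highest cubic clustering criterion — the rule standing in for
#' visual dendrogram inspection.
#'
#' @param expr matrix or [expression_matrix()].
#' @param ks candidate cluster counts (default `c(2, 3)`).
#' @param method `"ward"` or `"kmeans"`.
#' @param ... passed to the clustering function.
#' @return the selected `cluster_result`, with `ccc_by_k` recorded.
#' @export
select_k <- function(expr, ks = c(2, 3), method = c("ward", "kmeans"), ...) {
  method <- match.arg(method)
  fits <- lapply(ks, function(k) {
    if (method == "ward") ward_cluster(expr, k) else kmeans_cluster(expr, k, ...)
  })
  cccs <- vapply(seq_along(ks), function(i) ccc(expr, fits[[i]], ks[i]),
                 numeric(1))
  names(cccs) <- ks
  pick <- which.max(replace(cccs, is.na(cccs), -Inf))
  res <- fits[[pick]]
  res$ccc_by_k <- cccs
  res
}
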