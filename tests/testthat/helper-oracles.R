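# Independent oracles used across tests. These deliberately re-derive results
# from first principles (brute force / closed form) rather than calling the
# package's own code paths.

# Greedy Ward agglomeration evaluating every possible merge's ESS increase
# from scratch. Ties broken like the implementation documents: smallest
# min-index pair, then smallest other index.
ward_oracle <- function(x) {
  ess <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }
  clusters <- lapply(seq_len(nrow(x)), identity)
  reps <- seq_len(nrow(x))       # representative = min original index
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- ess(c(clusters[[i]], clusters[[j]])) - ess(clusters[[i]]) - ess(clusters[[j]])
        key <- c(min(reps[i], reps[j]), max(reps[i], reps[j]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = d, i = i, j = j, key = key)
        }
      }
    }
    heights <- c(heights, best$d)
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    keep <- setdiff(seq_along(clusters), c(best$i, best$j))
    newreps <- c(reps[keep], min(reps[best$i], reps[best$j]))
    clusters <- c(clusters[keep], list(merged))
    reps <- newreps
    partitions[[length(partitions) + 1]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a set partition for comparison.
canon_partition <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), identity))[
    order(vapply(split(seq_along(labels), labels), min, numeric(1)))]
}

# Pearson chi-square by explicit loop.
pearson_oracle <- function(O) {
  n <- sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      E <- sum(O[i, ]) * sum(O[, j]) / n
      stat <- stat + (O[i, j] - E)^2 / E
    }
  }
  stat
}

# Simple-regression R^2 by closed form.
ols_r2_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
}

# Minimum within-cluster SS over all 2-partitions of a small point set.
kmeans2_oracle <- function(x) {
  n <- nrow(x)
  best <- Inf
  best_part <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!any(g) || all(g)) next
    wss <- sum(sweep(x[g, , drop = FALSE], 2, colMeans(x[g, , drop = FALSE]))^2) +
      sum(sweep(x[!g, , drop = FALSE], 2, colMeans(x[!g, , drop = FALSE]))^2)
    if (wss < best) { best <- wss; best_part <- g }
  }
  list(inertia = best, partition = best_part)
}

# Small Ct matrix builder with auto ids.
toy_ct <- function(values, missing_code = 999) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%02d", seq_len(ncol(values)))
  ct_matrix(values, missing_code)
}

toy_ann <- function(cell_ids, donor = "D1", plate = "P1", n_loaded = 1L) {
  data.frame(cell_id = cell_ids,
             donor_id = rep_len(donor, length(cell_ids)),
             plate_id = rep_len(plate, length(cell_ids)),
             cell_type = "toy",
             n_cells_loaded = rep_len(n_loaded, length(cell_ids)),
             is_negative_control = FALSE,
             stringsAsFactors = FALSE)
}

# Detector for the plate-artifact splitting property: some true subtype with
# at least 5 plate-1 cells has >= 70% of them outside its off-plate majority
# cluster, and spans >= 2 clusters of >= 5 cells.
split_by_plate <- function(labels, truth, artifact_plate = "P1") {
  tr <- truth[match(names(labels), truth$cell_id), ]
  for (s in unique(tr$subtype)) {
    sel <- tr$subtype == s
    on <- sel & tr$plate_id == artifact_plate
    off <- sel & tr$plate_id != artifact_plate
    if (sum(on) < 5) next
    c_off <- names(which.max(table(labels[off])))
    if (mean(labels[on] != c_off) >= 0.7 &&
        sum(table(labels[sel]) >= 5) >= 2) return(TRUE)
  }
  FALSE
}

truth_labels <- function(fx) {
  stats::setNames(as.integer(factor(fx$truth$subtype)), fx$truth$cell_id)
}
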