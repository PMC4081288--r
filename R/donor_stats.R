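#' Tabulate cell counts per cluster and donor
#'
#' Builds the clusters-by-donors contingency table underlying the
#' donor-variability analysis. Empty clusters are retained as zero rows so
#' margins are conserved.
#'
#' @param labels a `cluster_result` or named cluster-label vector.
#' @param ann annotations providing `donor_id` for every labeled cell.
#' @return a `donor_cluster_table`: list with `counts` (integer matrix,
#'   clusters x donors), `cluster_totals`, `donor_totals`, `n`.
#' @export
donor_cluster_table <- function(labels, ann) {
  k <- if (inherits(labels, "cluster_result")) labels$k else NA
  lab <- if (inherits(labels, "cluster_result")) labels$labels else labels
  if (is.null(names(lab))) stop("labels must be named by cell id", call. = FALSE)
  donor <- ann$donor_id[match(names(lab), ann$cell_id)]
  if (anyNA(donor))
    stop(sprintf("missing donor annotation for cell '%s'",
                 names(lab)[which(is.na(donor))[1]]), call. = FALSE)
  lv <- if (is.na(k)) sort(unique(lab)) else seq_len(k)
  counts <- table(cluster = factor(lab, levels = lv), donor = donor)
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  structure(list(counts = counts, cluster_totals = rowSums(counts),
                 donor_totals = colSums(counts), n = sum(counts)),
            class = "donor_cluster_table")
}

#' @export
print.donor_cluster_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$cluster_totals)
  m <- rbind(m, Total = c(x$donor_totals, x$n))
  print(m)
  invisible(x)
}

#' Pearson chi-square test of equal donor cluster proportions
#'
#' Tests the observed clusters-by-donors counts against the expectation that
#' every donor contributes the same cluster proportions, using the Pearson
#' statistic `sum((O - E)^2 / E)` with `E = row_total * col_total / n`, no
#' continuity correction, and `df = (r - 1)(c - 1)`; the p-value is the
#' chi-square upper tail.
#'
#' @param counts a `donor_cluster_table` or a non-negative count matrix with
#'   at least 2 rows and 2 columns and strictly positive margins.
#' @return list with `chi_square`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(counts) {
  O <- if (inherits(counts, "donor_cluster_table")) counts$counts
       else as.matrix(counts)
  if (nrow(O) < 2 || ncol(O) < 2)
    stop("need at least 2 clusters and 2 donors", call. = FALSE)
  rt <- rowSums(O); ct <- colSums(O)
  if (any(rt == 0) || any(ct == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  E <- outer(rt, ct) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  list(chi_square = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}
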