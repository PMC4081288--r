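#' Per-cell mean centering
#'
#' Subtracts each cell's mean value from that cell's measurements, removing
#' cell-to-cell differences in overall signal while preserving within-cell
#' relative differences exactly.
#'
#' @param expr an [expression_matrix()] (or plain numeric matrix).
#' @return an [expression_matrix()] on the `normalized` scale with per-cell
#'   mean 0.
#' @export
mean_center <- function(expr) {
  x <- as_values(expr)
  if (length(x) == 0) stop("empty matrix", call. = FALSE)
  out <- x - rowMeans(x)
  as_normalized(out, expr, "mean_center")
}

#' Quantile normalization across cells
#'
#' Replaces the value at rank r in each cell by the mean over cells of the
#' rank-r values, making every cell's value distribution identical. Tied
#' values within a cell receive the average of their tied positions' quantile
#' means.
#'
#' @param expr an [expression_matrix()] (or plain numeric matrix); all cells
#'   must have the same gene set and no missing values.
#' @return an [expression_matrix()] on the `normalized` scale.
#' @export
quantile_normalize <- function(expr) {
  x <- as_values(expr)
  if (length(x) == 0) stop("empty matrix", call. = FALSE)
  sorted <- apply(x, 1, sort)                       # genes x cells
  qmeans <- rowMeans(sorted)                        # mean of rank-r values
  out <- x
  for (i in seq_len(nrow(x))) {
    r <- rank(x[i, ], ties.method = "first")
    v <- qmeans[r]
    out[i, ] <- stats::ave(v, x[i, ])               # average over tied inputs
  }
  as_normalized(out, expr, "quantile")
}

#' Per-gene standardization with plate-effect ANOVA residuals
#'
#' Four-stage pipeline: (1) per-cell mean centering; (2) per-gene z-scores
#' (gene mean subtracted, divided by the gene's sample SD with n-1
#' denominator; zero-variance genes are set to 0 and flagged); (3) per-gene
#' one-way ANOVA with plate as a fixed effect, values replaced by residuals
#' (value minus the gene's plate mean) — this adjusts only targets whose
#' expression differs among plates; (4) a further per-cell recentering to
#' mean 0 so no cell ends up with artificially low or high overall
#' expression. A single plate degenerates to plain standardization; plates
#' with one cell get residual 0 and are flagged.
#'
#' @param expr an [expression_matrix()] (or plain numeric matrix).
#' @param ann annotations providing `plate_id` for every cell.
#' @return list with `expr` (normalized [expression_matrix()]) and `fits`, a
#'   per-gene list of plate-model fits (`gene_id`, `plate_means`,
#'   `residual_variance`, `f_statistic`, `p_value`). Attributes
#'   `zero_variance_genes` and `singleton_plates` on `fits` carry the flags.
#' @export
standardize_with_plate <- function(expr, ann) {
  x <- as_values(expr)
  if (length(x) == 0) stop("empty matrix", call. = FALSE)
  if (!all(rownames(x) %in% ann$cell_id))
    stop("every cell needs a plate_id annotation", call. = FALSE)
  plate <- factor(ann$plate_id[match(rownames(x), ann$cell_id)])
  n <- nrow(x)

  cc <- x - rowMeans(x)
  gsd <- apply(cc, 2, stats::sd)
  zerovar <- gsd == 0
  z <- sweep(cc, 2, colMeans(cc))
  z[, !zerovar] <- sweep(z[, !zerovar, drop = FALSE], 2, gsd[!zerovar], "/")
  z[, zerovar] <- 0

  plate_sizes <- table(plate)
  singleton <- names(plate_sizes)[plate_sizes == 1]
  k <- nlevels(plate)
  fits <- vector("list", ncol(z))
  resid <- z
  for (j in seq_len(ncol(z))) {
    v <- z[, j]
    pm <- tapply(v, plate, mean)
    r <- v - pm[plate]
    grand <- mean(v)
    ss_between <- sum(plate_sizes * (pm - grand)^2)
    ss_within <- sum(r^2)
    df1 <- k - 1; df2 <- n - k
    f <- if (df1 > 0 && df2 > 0 && ss_within > 0)
      (ss_between / df1) / (ss_within / df2) else NA_real_
    fits[[j]] <- list(gene_id = colnames(z)[j],
                      plate_means = stats::setNames(as.numeric(pm), levels(plate)),
                      residual_variance = if (df2 > 0) ss_within / df2 else NA_real_,
                      f_statistic = f,
                      p_value = if (is.na(f)) NA_real_
                                else stats::pf(f, df1, df2, lower.tail = FALSE))
    resid[, j] <- r
  }
  out <- resid - rowMeans(resid)
  attr(fits, "zero_variance_genes") <- colnames(z)[zerovar]
  attr(fits, "singleton_plates") <- singleton
  list(expr = as_normalized(out, expr, "standardize_plate"), fits = fits)
}

as_normalized <- function(values, orig, method) {
  prov <- if (inherits(orig, "expression_matrix")) orig$provenance else list()
  prov$normalization <- method
  expression_matrix(values, scale = "normalized", provenance = prov)
}
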