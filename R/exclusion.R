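#' Construct an expression matrix with provenance
#'
#' Processed values on the Ct, Log2EX or normalized scale, carrying the
#' exclusion/normalization history that produced them.
#'
#' @param values numeric matrix (cells x genes).
#' @param scale one of `"ct"`, `"log2ex"`, `"normalized"`.
#' @param provenance list (exclusion strategy, normalization method, lod, ...).
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, scale = c("ct", "log2ex", "normalized"),
                              provenance = list()) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  validate_ids(rownames(values), "cell")
  validate_ids(colnames(values), "gene")
  if (anyNA(values)) stop("expression values must be finite", call. = FALSE)
  structure(list(values = values, scale = scale, provenance = provenance),
            class = "expression_matrix")
}

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes, scale '%s'\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (length(x$provenance) > 0)
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

as_values <- function(x) {
  if (inherits(x, "expression_matrix") || inherits(x, "ct_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a matrix, ct_matrix or expression_matrix", call. = FALSE)
}

#' Limit-of-detection value
#'
#' @param lod_ct Ct value in (1, 40].
#' @param detection_method `"histogram_valley"` or `"user_supplied"`.
#' @return a `lod_value` object.
#' @export
lod_value <- function(lod_ct, detection_method = c("user_supplied",
                                                   "histogram_valley")) {
  detection_method <- match.arg(detection_method)
  if (!is.numeric(lod_ct) || length(lod_ct) != 1 || lod_ct <= 1 || lod_ct > 40)
    stop("lod_ct must be a single Ct in (1, 40]", call. = FALSE)
  structure(list(lod_ct = lod_ct, detection_method = detection_method),
            class = "lod_value")
}

as_lod <- function(lod) {
  if (inherits(lod, "lod_value")) lod else lod_value(lod)
}

new_exclusion_report <- function(strategy, excluded_genes, excluded_cells,
                                 reassignments, lod = NULL,
                                 reference_genes = NULL, ...) {
  empty_g <- data.frame(gene_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  empty_c <- data.frame(cell_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  empty_r <- data.frame(cell_id = character(0), gene_id = character(0),
                        old = numeric(0), new = numeric(0),
                        reason = character(0), stringsAsFactors = FALSE)
  structure(list(strategy = strategy,
                 excluded_genes = if (nrow(excluded_genes)) excluded_genes else empty_g,
                 excluded_cells = if (nrow(excluded_cells)) excluded_cells else empty_c,
                 reassignments = if (nrow(reassignments)) reassignments else empty_r,
                 lod = lod, reference_genes = reference_genes, ...),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("exclusion_report (%s): %d genes excluded, %d cells excluded, %d reassignments\n",
              x$strategy, nrow(x$excluded_genes), nrow(x$excluded_cells),
              nrow(x$reassignments)))
  invisible(x)
}

#' Determine the limit of detection from per-gene maximum Ct values
#'
#' Computes each gene's maximum finite Ct across cells, bins the maxima in
#' 1-cycle integer bins over `search_range`, and locates the valley between
#' the two largest local maxima of the histogram: the LOD is the left edge of
#' the first bin after the deepest valley, i.e. where the upper mode (genes
#' whose weakest signal sits at non-detection level) starts. If the histogram
#' has no two separated peaks the LOD cannot be derived and an error asks the
#' caller to supply one.
#'
#' @param ct a [ct_matrix()] with at least 2 genes.
#' @param search_range numeric length-2, default `c(30, 40)`.
#' @return a [lod_value()] with `detection_method = "histogram_valley"`.
#' @export
determine_lod <- function(ct, search_range = c(30, 40)) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (ncol(ct$values) < 2) stop("need >= 2 genes to determine LOD", call. = FALSE)
  vals <- ct$values
  vals[vals == ct$missing_code] <- NA_real_
  gmax <- suppressWarnings(apply(vals, 2, max, na.rm = TRUE))
  gmax <- gmax[is.finite(gmax)]
  breaks <- seq(floor(search_range[1]), ceiling(search_range[2]), by = 1)
  counts <- vapply(utils::head(breaks, -1), function(b)
    sum(gmax >= b & gmax < b + 1), integer(1))
  padded <- c(-1L, counts, -1L)
  is_peak <- counts > 0 &
    counts >= utils::head(padded, length(counts)) &
    counts >= utils::tail(padded, length(counts))
  peaks <- which(is_peak)
  # drop adjacent plateau duplicates: keep first bin of each plateau run
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (length(peaks) < 2)
    stop("per-gene maximum Ct histogram is unimodal; supply the LOD explicitly",
         call. = FALSE)
  top2 <- sort(peaks[order(counts[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1] + 1, top2[2] - 1)
  if (length(between) == 0 || min(counts[between]) >= min(counts[top2]))
    stop("no valley between histogram peaks; supply the LOD explicitly",
         call. = FALSE)
  valley <- max(between[counts[between] == min(counts[between])])
  lod_ct <- breaks[valley + 1]
  structure(list(lod_ct = lod_ct, detection_method = "histogram_valley"),
            class = "lod_value")
}

#' Log2EX limit-of-detection transform
#'
#' Every Ct above the LOD (including the missing code) is replaced by the LOD
#' Ct; values are then inverted to `LOD Ct - Ct`, so 0 means undetected and
#' larger values mean higher expression, in line with microarray/RNA-seq
#' intuition.
#'
#' @param ct a [ct_matrix()] or numeric matrix of Ct values.
#' @param lod a [lod_value()] or single numeric Ct.
#' @return an [expression_matrix()] on the `log2ex` scale.
#' @export
log2ex_transform <- function(ct, lod) {
  lod <- as_lod(lod)
  vals <- as_values(ct)
  if (inherits(ct, "ct_matrix")) vals[vals == ct$missing_code] <- 40
  vals[vals > lod$lod_ct] <- lod$lod_ct
  expression_matrix(lod$lod_ct - vals, scale = "log2ex",
                    provenance = list(lod = lod$lod_ct))
}

#' Data exclusion by reference-gene standard-deviation cutoff (Log2EX scale)
#'
#' Implements the median-SD-cutoff strategy: missing reactions are first set
#' to Ct 40; genes are ranked by mean Ct and the highest-expressed gene is
#' ignored as an outlier; the 2nd and 3rd highest-expressed genes serve as
#' references, with their mean and SD computed from their pooled per-cell Ct
#' values. Genes whose mean Ct exceeds the reference mean by more than
#' `sd_multiplier` reference SDs are excluded; cells detecting (Ct below the
#' LOD) fewer than `min_expressed_fraction` of the retained genes are
#' excluded; the matrix is transformed to the Log2EX scale; undetected values
#' stay 0 (`as_zero`) or are replaced by the gene's mean Log2EX over detected
#' cells (`as_gene_mean`); cells whose mean reference-gene expression falls
#' more than `sd_multiplier` SD units (average of the two reference genes'
#' per-cell SDs) below the median are excluded; finally genes detected in at
#' most `min_cells_detected` retained cells are dropped.
#'
#' @param ct a [ct_matrix()].
#' @param lod a [lod_value()] or numeric Ct.
#' @param missing_policy `"as_zero"` (undetected = no expression) or
#'   `"as_gene_mean"` (undetected = technical failure).
#' @param sd_multiplier SD cutoff multiplier (default 3).
#' @param min_expressed_fraction minimum detected fraction per cell (default 0.5).
#' @param min_cells_detected genes detected in `<=` this many cells are
#'   dropped (default 1; negative disables the rule).
#' @return list with `expr` ([expression_matrix()]) and `report`
#'   (`exclusion_report`).
#' @export
exclude_sd_cutoff <- function(ct, lod, missing_policy = c("as_zero", "as_gene_mean"),
                              sd_multiplier = 3, min_expressed_fraction = 0.5,
                              min_cells_detected = 1) {
  stopifnot(inherits(ct, "ct_matrix"))
  missing_policy <- match.arg(missing_policy)
  lod <- as_lod(lod)
  if (ncol(ct$values) < 3) stop("need >= 3 genes", call. = FALSE)
  M <- ct$values
  M[M == ct$missing_code] <- 40

  gene_mean <- colMeans(M)
  ord <- order(gene_mean)                      # ascending Ct = descending expression
  refs <- colnames(M)[ord[2:3]]                # rank 1 ignored as outlier
  pooled <- c(M[, refs[1]], M[, refs[2]])
  cutoff <- if (is.infinite(sd_multiplier)) Inf
            else mean(pooled) + sd_multiplier * stats::sd(pooled)
  keep_gene <- gene_mean <= cutoff
  excl_genes <- data.frame(gene_id = colnames(M)[!keep_gene],
                           reason = rep("mean_above_sd_cutoff", sum(!keep_gene)),
                           stringsAsFactors = FALSE)
  if (!any(keep_gene))
    stop("all genes excluded at the reference SD cutoff step", call. = FALSE)
  M1 <- M[, keep_gene, drop = FALSE]

  detected <- M1 < lod$lod_ct
  frac <- rowMeans(detected)
  keep_cell <- frac >= min_expressed_fraction
  excl_cells <- data.frame(cell_id = rownames(M1)[!keep_cell],
                           reason = rep("low_detection", sum(!keep_cell)),
                           stringsAsFactors = FALSE)
  if (!any(keep_cell))
    stop("all cells excluded at the detection-fraction step", call. = FALSE)
  M2 <- M1[keep_cell, , drop = FALSE]
  det2 <- detected[keep_cell, , drop = FALSE]

  E <- lod$lod_ct - pmin(M2, lod$lod_ct)
  reass <- which(M2 > lod$lod_ct, arr.ind = TRUE)
  re_old <- M2[reass]
  if (missing_policy == "as_gene_mean") {
    gmean <- vapply(seq_len(ncol(E)), function(j) {
      d <- det2[, j]
      if (any(d)) mean(E[d, j]) else 0
    }, numeric(1))
    for (j in seq_len(ncol(E))) E[!det2[, j] & M2[, j] > lod$lod_ct, j] <- gmean[j]
  }
  re_new <- E[reass]
  reassignments <- data.frame(
    cell_id = rownames(M2)[reass[, 1]], gene_id = colnames(M2)[reass[, 2]],
    old = re_old, new = re_new,
    reason = rep(if (missing_policy == "as_gene_mean") "sporadic_to_gene_mean"
                 else "above_lod_to_lod", nrow(reass)),
    stringsAsFactors = FALSE)

  # cells whose mean reference expression is far below the median
  rm_c <- rowMeans(E[, refs, drop = FALSE])
  sd_unit <- mean(apply(E[, refs, drop = FALSE], 2, stats::sd))
  low_ref <- if (is.infinite(sd_multiplier)) rep(FALSE, nrow(E))
             else rm_c < stats::median(rm_c) - sd_multiplier * sd_unit
  if (all(low_ref))
    stop("all cells excluded at the reference-expression step", call. = FALSE)
  excl_cells <- rbind(excl_cells,
                      data.frame(cell_id = rownames(E)[low_ref],
                                 reason = rep("low_reference_expression", sum(low_ref)),
                                 stringsAsFactors = FALSE))
  E <- E[!low_ref, , drop = FALSE]
  det3 <- det2[!low_ref, , drop = FALSE]

  ndet <- colSums(det3)
  drop_gene <- ndet <= min_cells_detected
  excl_genes <- rbind(excl_genes,
                      data.frame(gene_id = colnames(E)[drop_gene],
                                 reason = ifelse(ndet[drop_gene] == 0,
                                                 "undetected_in_retained_cells",
                                                 "detected_in_too_few_cells"),
                                 stringsAsFactors = FALSE))
  if (all(drop_gene))
    stop("all genes excluded at the minimum-detection step", call. = FALSE)
  E <- E[, !drop_gene, drop = FALSE]
  reassignments <- reassignments[
    reassignments$cell_id %in% rownames(E) &
    reassignments$gene_id %in% colnames(E), , drop = FALSE]

  expr <- expression_matrix(E, scale = "log2ex",
                            provenance = list(exclusion = "sd_cutoff",
                                              lod = lod$lod_ct,
                                              missing_policy = missing_policy))
  report <- new_exclusion_report("sd_cutoff", excl_genes, excl_cells,
                                 reassignments, lod = lod,
                                 reference_genes = refs)
  list(expr = expr, report = report)
}

#' Supervised data exclusion (Ct scale)
#'
#' Implements the supervised strategy: genes present (non-missing) in at
#' least `presence_threshold` of cells form the core set; cells detecting at
#' least that fraction of the core set are retained. The missingness pattern
#' of the remaining non-core genes is clustered (Ward linkage on Jaccard
#' distances between gene missingness sets); maximal dendrogram subtrees of
#' size >= 2 whose mean pairwise co-missingness rate (Simpson overlap
#' coefficient, `|A n B| / min(|A|, |B|)`) reaches `block_missing_rate` are
#' flagged as co-regulated low-abundance blocks and their missing values are
#' re-assigned Ct 40 (true absence of expression). Remaining sporadic missing
#' values are assumed technical and replaced by the gene's mean observed Ct.
#' Non-core genes in no flagged block, and genes never detected anywhere, are
#' excluded. The output stays on the Ct scale.
#'
#' @param ct a [ct_matrix()].
#' @param presence_threshold fraction of cells in which a core gene must be
#'   present (default 0.70).
#' @param block_missing_rate minimum within-block co-missingness rate
#'   (default 0.5).
#' @return list with `expr` (Ct-scale [expression_matrix()]) and `report`;
#'   the report's `blocks` field lists the detected gene blocks so users can
#'   review or override the exploratory choice.
#' @export
exclude_supervised <- function(ct, presence_threshold = 0.70,
                               block_missing_rate = 0.5) {
  stopifnot(inherits(ct, "ct_matrix"))
  miss <- ct$values == ct$missing_code
  presence <- colMeans(!miss)
  all_missing <- presence == 0
  core <- presence >= presence_threshold
  if (!any(core))
    stop("empty core set: no gene reaches the presence threshold", call. = FALSE)

  cell_det <- rowMeans(!miss[, core, drop = FALSE])
  keep_cell <- cell_det >= presence_threshold
  excl_cells <- data.frame(cell_id = rownames(miss)[!keep_cell],
                           reason = rep("low_core_detection", sum(!keep_cell)),
                           stringsAsFactors = FALSE)
  if (!any(keep_cell)) stop("all cells excluded at the core-detection step",
                            call. = FALSE)
  m2 <- miss[keep_cell, , drop = FALSE]

  noncore <- which(!core & !all_missing)
  blocks <- list()
  if (length(noncore) >= 2) {
    blocks <- find_comissing_blocks(m2[, noncore, drop = FALSE],
                                    block_missing_rate)
  }
  block_genes <- unlist(blocks, use.names = FALSE)
  excl_gene_ids <- c(colnames(miss)[all_missing],
                     setdiff(colnames(miss)[noncore], block_genes))
  excl_genes <- data.frame(
    gene_id = excl_gene_ids,
    reason = ifelse(excl_gene_ids %in% colnames(miss)[all_missing],
                    "all_missing", "uncorrelated_low_presence"),
    stringsAsFactors = FALSE)

  keep_gene_ids <- c(colnames(miss)[core], block_genes)
  keep_gene_ids <- colnames(miss)[colnames(miss) %in% keep_gene_ids]  # original order
  M <- ct$values[keep_cell, keep_gene_ids, drop = FALSE]
  mm <- m2[, keep_gene_ids, drop = FALSE]

  reass <- NULL
  for (j in seq_along(keep_gene_ids)) {
    g <- keep_gene_ids[j]
    idx <- which(mm[, j])
    if (length(idx) == 0) next
    if (g %in% block_genes) {
      newv <- rep(40, length(idx)); reason <- "block_absent_to_40"
    } else {
      newv <- rep(mean(M[!mm[, j], j]), length(idx))
      reason <- "sporadic_to_gene_mean"
    }
    reass <- rbind(reass, data.frame(cell_id = rownames(M)[idx], gene_id = g,
                                     old = M[idx, j], new = newv,
                                     reason = reason, stringsAsFactors = FALSE))
    M[idx, j] <- newv
  }
  if (is.null(reass))
    reass <- data.frame(cell_id = character(0), gene_id = character(0),
                        old = numeric(0), new = numeric(0),
                        reason = character(0), stringsAsFactors = FALSE)

  expr <- expression_matrix(M, scale = "ct",
                            provenance = list(exclusion = "supervised"))
  report <- new_exclusion_report("supervised", excl_genes, excl_cells, reass,
                                 blocks = blocks)
  list(expr = expr, report = report)
}

# Ward clustering (Jaccard distance) of gene missingness columns; returns
# maximal subtrees (size >= 2) whose mean pairwise Simpson overlap
# coefficient >= rate.
find_comissing_blocks <- function(miss, rate) {
  g <- ncol(miss)
  inter <- crossprod(miss)               # |A n B|
  nmiss <- diag(inter)
  uni <- outer(nmiss, nmiss, "+") - inter
  jac_sim <- ifelse(uni > 0, inter / uni, 1)
  overlap <- inter / outer(nmiss, nmiss, pmin)
  overlap[!is.finite(overlap)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - jac_sim), method = "ward.D2")
  members <- function(node) {
    if (node < 0) return(-node)
    c(members(hc$merge[node, 1]), members(hc$merge[node, 2]))
  }
  ok <- function(idx) {
    if (length(idx) < 2) return(FALSE)
    pairs <- overlap[idx, idx]
    mean(pairs[upper.tri(pairs)]) >= rate
  }
  blocks <- list()
  walk <- function(node) {
    if (node < 0) return(invisible())
    idx <- members(node)
    if (ok(idx)) {
      blocks[[length(blocks) + 1]] <<- colnames(miss)[sort(idx)]
    } else {
      walk(hc$merge[node, 1]); walk(hc$merge[node, 2])
    }
  }
  walk(g - 1)
  blocks
}

#' All-inclusive data exclusion (Log2EX scale)
#'
#' Retains every cell. Drops only genes undetected in every control sample
#' (pooled cDNA, multi-cell loading controls) and genes undetected in all
#' cells of any single plate (a whole-array dropout cannot be distinguished
#' from a technical artifact); then applies the Log2EX transform.
#'
#' @param ct a [ct_matrix()].
#' @param controls a [ct_matrix()] of control samples sharing the gene panel.
#' @param lod a [lod_value()] or numeric Ct.
#' @param ann annotations providing `plate_id` for every cell in `ct`.
#' @return list with `expr` ([expression_matrix()]) and `report`.
#' @export
exclude_all_inclusive <- function(ct, controls, lod, ann) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (missing(controls) || is.null(controls))
    stop("control samples are required for all-inclusive exclusion", call. = FALSE)
  stopifnot(inherits(controls, "ct_matrix"))
  lod <- as_lod(lod)
  if (!setequal(colnames(ct$values), colnames(controls$values)))
    stop("controls must share the gene panel of the Ct matrix", call. = FALSE)
  ann <- validate_cell_annotations(ann, ct)
  plate <- ann$plate_id[match(rownames(ct$values), ann$cell_id)]

  cvals <- controls$values[, colnames(ct$values), drop = FALSE]
  ctrl_det <- cvals != controls$missing_code & cvals < lod$lod_ct
  dead <- colSums(ctrl_det) == 0
  det <- ct$values != ct$missing_code & ct$values < lod$lod_ct

  plate_reason <- rep(NA_character_, ncol(det))
  for (p in unique(plate)) {
    on_plate <- plate == p
    gone <- colSums(det[on_plate, , drop = FALSE]) == 0
    plate_reason[gone & is.na(plate_reason)] <- sprintf("missing_on_array:%s", p)
  }
  reason <- ifelse(dead, "absent_in_controls", plate_reason)
  drop_gene <- !is.na(reason)
  excl_genes <- data.frame(gene_id = colnames(det)[drop_gene],
                           reason = reason[drop_gene], stringsAsFactors = FALSE)
  if (all(drop_gene)) stop("all genes excluded", call. = FALSE)

  keep <- subset_ct(ct, genes = colnames(det)[!drop_gene])
  expr <- log2ex_transform(keep, lod)
  above <- which(keep$values > lod$lod_ct | keep$values == keep$missing_code,
                 arr.ind = TRUE)
  reass <- data.frame(cell_id = rownames(keep$values)[above[, 1]],
                      gene_id = colnames(keep$values)[above[, 2]],
                      old = keep$values[above], new = rep(0, nrow(above)),
                      reason = rep("above_lod_to_lod", nrow(above)),
                      stringsAsFactors = FALSE)
  expr$provenance$exclusion <- "all_inclusive"
  report <- new_exclusion_report("all_inclusive", excl_genes,
                                 data.frame(cell_id = character(0),
                                            reason = character(0),
                                            stringsAsFactors = FALSE),
                                 reass, lod = lod)
  list(expr = expr, report = report)
}
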