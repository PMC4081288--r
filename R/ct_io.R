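#' Construct a validated Ct matrix
#'
#' A Ct matrix holds raw qRT-PCR cycle-threshold values for cells (rows) by
#' gene targets (columns). Valid entries lie in `[1, 40]`; reactions that
#' produced no signal carry the sentinel `missing_code` (conventionally 999),
#' which may reflect either true absence of transcript or technical failure.
#'
#' @param values numeric matrix with unique, non-empty rownames (cell ids) and
#'   colnames (gene ids).
#' @param missing_code numeric sentinel for failed/absent reactions.
#' @return An object of class `ct_matrix`: a list with elements `values` and
#'   `missing_code`.
#' @export
ct_matrix <- function(values, missing_code = 999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  validate_ids(rownames(values), "cell")
  validate_ids(colnames(values), "gene")
  bad <- which(!is_valid_ct(values, missing_code), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "Ct value %s at cell '%s', gene '%s' is outside [1, 40] and is not the missing code (%s)",
      format(values[bad[1, 1], bad[1, 2]]), rownames(values)[bad[1, 1]],
      colnames(values)[bad[1, 2]], format(missing_code)), call. = FALSE)
  }
  structure(list(values = values, missing_code = missing_code),
            class = "ct_matrix")
}

validate_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop(sprintf("%s ids must be non-empty", what), call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate %s id: '%s'", what, ids[duplicated(ids)][1]),
         call. = FALSE)
  invisible(ids)
}

is_valid_ct <- function(values, missing_code) {
  is.finite(values) & ((values >= 1 & values <= 40) | values == missing_code)
}

#' @export
as.matrix.ct_matrix <- function(x, ...) x$values

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d cells x %d genes (missing code %s, %d missing)\n",
              nrow(x$values), ncol(x$values), format(x$missing_code),
              sum(x$values == x$missing_code)))
  invisible(x)
}

#' Subset a Ct matrix by cell and/or gene ids
#'
#' @param x a [ct_matrix()].
#' @param cells,genes character vectors of ids to keep (default: all).
#' @return a `ct_matrix` restricted to the requested cells and genes.
#' @export
subset_ct <- function(x, cells = rownames(x$values), genes = colnames(x$values)) {
  stopifnot(inherits(x, "ct_matrix"))
  ct_matrix(x$values[cells, genes, drop = FALSE], x$missing_code)
}

#' Read a Ct matrix from delimited text
#'
#' Expects a header row of gene ids with a first column named `cell_id`
#' holding cell ids. Empty fields and `NA` are recoded to `missing_code`:
#' the package keeps a single canonical missing representation internally.
#'
#' @param path CSV (or TSV, by extension or `sep`) file path.
#' @param missing_code sentinel for missing reactions (default 999).
#' @param sep field separator; `NULL` chooses `"\t"` for `.tsv`/`.txt`, else `","`.
#' @return a [ct_matrix()].
#' @export
read_ct_matrix <- function(path, missing_code = 999, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2 || tolower(names(df)[1]) != "cell_id")
    stop("malformed header: first column must be 'cell_id'", call. = FALSE)
  ids <- df[[1]]
  validate_ids(ids, "cell")
  validate_ids(names(df)[-1], "gene")
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1,
                 dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(df) - 1)) {
    raw <- trimws(df[[j + 1]])
    empty <- !nzchar(raw) | toupper(raw) == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(num))
    if (length(bad) > 0)
      stop(sprintf("non-numeric entry '%s' at cell '%s', gene '%s'",
                   raw[bad[1]], ids[bad[1]], names(df)[j + 1]), call. = FALSE)
    num[empty] <- missing_code
    vals[, j] <- num
  }
  ct_matrix(vals, missing_code)
}

#' Write a Ct matrix to delimited text
#'
#' Round-trips exactly with [read_ct_matrix()] for finite Ct values and the
#' missing code (values are written with full precision).
#'
#' @param x a [ct_matrix()].
#' @param path output file path.
#' @param sep field separator (default `","`).
#' @export
write_ct_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "ct_matrix"))
  df <- data.frame(cell_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-cell annotations
#'
#' Annotation files are CSV with columns `cell_id`, `donor_id`, `plate_id`,
#' `cell_type`, `n_cells_loaded` (1 for single cells, 10/100 for loading
#' controls) and `is_negative_control` (logical).
#'
#' @param path CSV file path.
#' @return a data frame of annotations.
#' @export
read_cell_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cell_annotations(ann)
}

#' Validate cell annotations (optionally against a Ct matrix)
#'
#' @param ann annotation data frame (see [read_cell_annotations()]).
#' @param ct optional [ct_matrix()]; if given, every cell id in the matrix
#'   must have exactly one annotation row.
#' @return the validated annotation data frame, invisibly usable downstream.
#' @export
validate_cell_annotations <- function(ann, ct = NULL) {
  need <- c("cell_id", "donor_id", "plate_id", "cell_type",
            "n_cells_loaded", "is_negative_control")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0)
    stop("annotation columns missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_ids(ann$cell_id, "cell")
  ann$is_negative_control <- as.logical(ann$is_negative_control)
  bad <- !ann$is_negative_control & !(ann$n_cells_loaded %in% c(1, 10, 100))
  if (any(bad))
    stop(sprintf("n_cells_loaded must be 1, 10 or 100 for assayed samples (cell '%s')",
                 ann$cell_id[which(bad)[1]]), call. = FALSE)
  if (!is.null(ct)) {
    lost <- setdiff(rownames(ct$values), ann$cell_id)
    if (length(lost) > 0)
      stop("cells without annotation: ", paste(utils::head(lost, 3), collapse = ", "),
           call. = FALSE)
  }
  ann
}

#' Multicell-control quality regression
#'
#' Compares single-cell measurements to 10-cell loading controls: per-gene
#' mean Ct over `n_sample` randomly chosen single cells (missing reactions
#' excluded from means) is regressed by ordinary least squares on the
#' per-gene mean Ct of the 10-cell controls. A high R-squared (the study
#' design anticipates values above 0.65) indicates consistent single-cell
#' loading and detection.
#'
#' Genes with no finite value in either the sampled cells or the controls are
#' dropped. If the 10-cell predictor has zero variance the regression slope is
#' undefined; `r_squared` is reported as 0 with `degenerate_predictor = TRUE`
#' and a warning, so QC stays usable on degenerate fixtures.
#'
#' @param ct a [ct_matrix()] containing both single cells and controls.
#' @param ann annotations for the matrix cells (see [read_cell_annotations()]).
#' @param n_sample number of single cells to sample (default 10).
#' @param seed integer seed for the sampling step.
#' @return list with `r_squared`, `n_single_cells_sampled`, `gene_count`,
#'   `degenerate_predictor`.
#' @export
multicell_qc <- function(ct, ann, n_sample = 10, seed = 1L) {
  stopifnot(inherits(ct, "ct_matrix"))
  ann <- validate_cell_annotations(ann, ct)
  ann <- ann[match(rownames(ct$values), ann$cell_id), , drop = FALSE]
  singles <- ann$cell_id[!ann$is_negative_control & ann$n_cells_loaded == 1]
  tens <- ann$cell_id[!ann$is_negative_control & ann$n_cells_loaded == 10]
  if (length(tens) == 0)
    stop("no 10-cell control samples available for QC regression", call. = FALSE)
  if (length(singles) < n_sample)
    stop(sprintf("need >= %d single cells, found %d", n_sample, length(singles)),
         call. = FALSE)
  chosen <- with_seed(seed, sample(sort(singles), n_sample))
  vals <- ct$values
  vals[vals == ct$missing_code] <- NA_real_
  sc_mean <- colMeans(vals[chosen, , drop = FALSE], na.rm = TRUE)
  mc_mean <- colMeans(vals[tens, , drop = FALSE], na.rm = TRUE)
  keep <- is.finite(sc_mean) & is.finite(mc_mean)
  x <- mc_mean[keep]; y <- sc_mean[keep]
  if (length(x) < 2)
    stop("fewer than 2 genes observed in both single cells and controls",
         call. = FALSE)
  degenerate <- isTRUE(stats::var(x) == 0)
  if (degenerate) {
    warning("10-cell control means have zero variance; R^2 reported as 0")
    r2 <- 0
  } else {
    fit <- stats::lm(y ~ x)
    # R^2 computed directly: summary.lm() warns on essentially perfect fits
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  list(r_squared = r2, n_single_cells_sampled = n_sample,
       gene_count = length(x), degenerate_predictor = degenerate)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
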