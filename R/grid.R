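#' Configuration for a primary-analysis grid run
#'
#' @param exclusions subset of `c("supervised", "sd_cutoff", "all_inclusive")`.
#'   Supervised exclusion is legitimately dropped for data without a natural
#'   presence cutoff (as done for T lymphocytes).
#' @param normalizations subset of
#'   `c("mean_center", "quantile", "standardize_plate")`.
#' @param k `"auto"` (argmax CCC over `ks`) or a fixed integer.
#' @param ks candidate cluster counts for `k = "auto"` (default `c(2, 3)`).
#' @param lod `"auto"` ([determine_lod()]) or a numeric Ct.
#' @param missing_policy for [exclude_sd_cutoff()].
#' @param cluster_method `"ward"` or `"kmeans"`.
#' @param presence_threshold,block_missing_rate for [exclude_supervised()].
#' @param sd_multiplier for [exclude_sd_cutoff()].
#' @param seed integer seed for all stochastic stages.
#' @return a config list.
#' @export
grid_config <- function(exclusions = c("supervised", "sd_cutoff", "all_inclusive"),
                        normalizations = c("mean_center", "quantile",
                                           "standardize_plate"),
                        k = "auto", ks = c(2, 3), lod = "auto",
                        missing_policy = "as_zero",
                        cluster_method = "ward",
                        presence_threshold = 0.70, block_missing_rate = 0.5,
                        sd_multiplier = 3, seed = 1L) {
  list(exclusions = exclusions, normalizations = normalizations, k = k,
       ks = ks, lod = lod, missing_policy = missing_policy,
       cluster_method = cluster_method,
       presence_threshold = presence_threshold,
       block_missing_rate = block_missing_rate,
       sd_multiplier = sd_multiplier, seed = as.integer(seed))
}

#' Run the exclusion-by-normalization grid of primary-analysis pipelines
#'
#' Processes the Ct matrix with every configured combination of exclusion
#' strategy and normalization method, clusters the cells of each processed
#' matrix, cross-tabulates clusters against donors, and computes the pairwise
#' concordance between all pipelines. A failure in one pipeline aborts only
#' that pipeline and is recorded with its error message. All per-stage
#' decisions (LOD, exclusions, reassignments, detected blocks, CCC values,
#' seeds) are kept in the result for audit, since the comparison's
#' conclusions hinge on those choices being visible.
#'
#' @param ct a [ct_matrix()].
#' @param ann cell annotations (see [read_cell_annotations()]).
#' @param controls optional control [ct_matrix()] (required by the
#'   all-inclusive strategy).
#' @param config a [grid_config()].
#' @return a `grid_result`: list with `pipelines` (per id: `expr`, `report`,
#'   `cluster`, `donor_table`, `chi_square` or `error`), `concordance`
#'   (numeric matrix, percent, diagonal 100), `lod`, `config`.
#' @export
run_grid <- function(ct, ann, controls = NULL, config = grid_config()) {
  stopifnot(inherits(ct, "ct_matrix"))
  ann <- validate_cell_annotations(ann, ct)
  lod <- if (identical(config$lod, "auto")) {
    tryCatch(determine_lod(ct), error = function(e) NULL)
  } else as_lod(config$lod)

  excl_results <- list()
  for (ex in config$exclusions) {
    excl_results[[ex]] <- tryCatch(switch(
      ex,
      supervised = exclude_supervised(ct, config$presence_threshold,
                                      config$block_missing_rate),
      sd_cutoff = {
        if (is.null(lod)) stop("no LOD available for sd_cutoff")
        exclude_sd_cutoff(ct, lod, missing_policy = config$missing_policy,
                          sd_multiplier = config$sd_multiplier)
      },
      all_inclusive = {
        if (is.null(lod)) stop("no LOD available for all_inclusive")
        exclude_all_inclusive(ct, controls, lod, ann)
      },
      stop("unknown exclusion: ", ex)), error = function(e) list(error = conditionMessage(e)))
  }

  pipelines <- list()
  for (ex in config$exclusions) {
    for (nm in config$normalizations) {
      id <- paste(ex, nm, sep = "+")
      base <- excl_results[[ex]]
      if (!is.null(base$error)) {
        pipelines[[id]] <- list(error = base$error)
        next
      }
      pipelines[[id]] <- tryCatch({
        norm <- switch(nm,
          mean_center = mean_center(base$expr),
          quantile = quantile_normalize(base$expr),
          standardize_plate = standardize_with_plate(base$expr, ann)$expr,
          stop("unknown normalization: ", nm))
        cl <- if (identical(config$k, "auto")) {
          select_k(norm, ks = config$ks, method = config$cluster_method,
                   seed = config$seed)
        } else if (config$cluster_method == "ward") {
          ward_cluster(norm, config$k)
        } else {
          kmeans_cluster(norm, config$k, seed = config$seed)
        }
        dt <- tryCatch(donor_cluster_table(cl, ann), error = function(e) NULL)
        chi <- if (!is.null(dt) && nrow(dt$counts) >= 2 && ncol(dt$counts) >= 2 &&
                   all(rowSums(dt$counts) > 0))
          tryCatch(chi_square_test(dt), error = function(e) NULL) else NULL
        list(expr = norm, report = base$report, cluster = cl,
             donor_table = dt, chi_square = chi)
      }, error = function(e) list(error = conditionMessage(e)))
    }
  }

  ids <- names(pipelines)
  conc <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i)) {
      pi <- pipelines[[ids[i]]]; pj <- pipelines[[ids[j]]]
      if (!is.null(pi$error) || !is.null(pj$error)) next
      val <- if (i == j) 100 else
        tryCatch(concordance(pi$cluster, pj$cluster,
                             ids = c(ids[i], ids[j]))$concordance_pct,
                 error = function(e) NA_real_)
      conc[i, j] <- conc[j, i] <- val
    }
  }
  structure(list(pipelines = pipelines, concordance = conc, lod = lod,
                 config = config),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  ok <- vapply(x$pipelines, function(p) is.null(p$error), logical(1))
  cat(sprintf("grid_result: %d/%d pipelines succeeded\n", sum(ok), length(ok)))
  for (id in names(x$pipelines)) {
    p <- x$pipelines[[id]]
    if (!is.null(p$error)) cat(sprintf("  %-32s ERROR: %s\n", id, p$error))
    else cat(sprintf("  %-32s %d cells x %d genes, k = %d\n", id,
                     nrow(p$expr$values), ncol(p$expr$values), p$cluster$k))
  }
  invisible(x)
}

#' Write grid-run artifacts to a directory
#'
#' Emits the processed matrix (TSV) and cluster labels (CSV) per pipeline,
#' the pairwise concordance matrix (CSV), and a JSON report with exclusion
#' ledgers, chi-square results, LOD and configuration.
#'
#' @param gr a `grid_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid_result <- function(gr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(lod = if (is.null(gr$lod)) NULL else gr$lod$lod_ct,
                 config = gr$config, pipelines = list())
  for (id in names(gr$pipelines)) {
    p <- gr$pipelines[[id]]
    slug <- gsub("[^A-Za-z0-9_]+", "_", id)
    if (!is.null(p$error)) {
      report$pipelines[[id]] <- list(error = p$error)
      next
    }
    utils::write.table(
      data.frame(cell_id = rownames(p$expr$values), p$expr$values,
                 check.names = FALSE),
      file.path(dir, paste0(slug, "_matrix.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(cell_id = names(p$cluster$labels),
                 cluster = as.integer(p$cluster$labels)),
      file.path(dir, paste0(slug, "_labels.csv")), row.names = FALSE)
    report$pipelines[[id]] <- list(
      n_cells = nrow(p$expr$values), n_genes = ncol(p$expr$values),
      k = p$cluster$k, ccc_by_k = p$cluster$ccc_by_k,
      excluded_genes = p$report$excluded_genes,
      excluded_cells = p$report$excluded_cells,
      n_reassignments = nrow(p$report$reassignments),
      blocks = p$report$blocks,
      chi_square = if (is.null(p$chi_square)) NULL else
        p$chi_square[c("chi_square", "df", "p_value")])
  }
  utils::write.csv(gr$concordance, file.path(dir, "concordance.csv"))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
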