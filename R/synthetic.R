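#' Specify the expression distribution of one synthetic gene
#'
#' Each gene draws finite Ct values from normal components on the Ct scale
#' (the log scale of expression, consistent with the log-normal behaviour of
#' single-cell transcript counts). Modality classes:
#' \describe{
#'   \item{U}{one expressed component.}
#'   \item{B-M}{two components; the low component emits only the missing code
#'     (no signal), i.e. an on/off gene.}
#'   \item{B-L}{two components; the low component emits a mix of missing codes
#'     and finite low-expressor Ct values in roughly \[35, 38).}
#'   \item{T}{three expressed components.}
#' }
#' The first component is always the (highest-abundance) expressed component;
#' for B classes the second component is the low/off component. If
#' `subtype_linkage` is set, cells of that subtype draw from the low component
#' and all other cells from the first component, which is how latent cell
#' subtypes shared across bimodal genes are encoded.
#'
#' @param gene_id gene identifier.
#' @param modality_class one of `"U"`, `"B-M"`, `"B-L"`, `"T"`.
#' @param component_means numeric Ct means, one per component, in (1, 40).
#' @param component_sds positive numeric SDs, one per component.
#' @param subtype_linkage optional subtype label whose cells draw from the low
#'   component (B classes only).
#' @param baseline_dropout probability in \[0, 1\] that any reaction fails
#'   technically (value replaced by the missing code).
#' @param component_weights sampling weights over components for cells not
#'   governed by `subtype_linkage`; default uniform. Ignored for linked genes.
#' @param low_missing_prob for B-L genes, probability that a low-component
#'   draw is emitted as the missing code rather than a finite low-expressor Ct.
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(gene_id, modality_class = c("U", "B-M", "B-L", "T"),
                      component_means, component_sds,
                      subtype_linkage = NULL, baseline_dropout = 0,
                      component_weights = NULL, low_missing_prob = 0.5) {
  modality_class <- match.arg(modality_class)
  n_comp <- switch(modality_class, "U" = 1L, "B-M" = 2L, "B-L" = 2L, "T" = 3L)
  if (length(component_means) != n_comp || length(component_sds) != n_comp)
    stop(sprintf("gene '%s': class %s needs %d component(s)", gene_id,
                 modality_class, n_comp), call. = FALSE)
  if (any(component_means <= 1) || any(component_means >= 40))
    stop(sprintf("gene '%s': component means must lie in (1, 40)", gene_id),
         call. = FALSE)
  if (any(component_sds <= 0))
    stop(sprintf("gene '%s': component sds must be > 0", gene_id), call. = FALSE)
  if (baseline_dropout < 0 || baseline_dropout > 1)
    stop("baseline_dropout must be in [0, 1]", call. = FALSE)
  structure(list(gene_id = gene_id, modality_class = modality_class,
                 component_means = component_means,
                 component_sds = component_sds,
                 subtype_linkage = subtype_linkage,
                 baseline_dropout = baseline_dropout,
                 component_weights = component_weights,
                 low_missing_prob = low_missing_prob),
            class = "gene_spec")
}

#' Specify a synthetic single-cell qRT-PCR population
#'
#' Describes the full data-generating world: donors with donor-specific
#' latent-subtype proportions, a gene panel of [gene_spec()]s, and plate
#' (array) structure with optional technical artifacts. `plate_shift` adds a
#' constant Ct offset to finite values per plate; `plate_dropout_boost` adds
#' extra dropout probability on designated plates, applied only to genes whose
#' primary component mean exceeds `plate_dropout_ct_threshold` (low-abundance
#' genes are the ones that lose signal when a plate underperforms).
#'
#' @param n_donors number of donors.
#' @param cells_per_donor integer scalar or vector (length `n_donors`).
#' @param subtype_proportions matrix (`n_donors` rows, subtype columns with
#'   labels as colnames); each row must sum to 1. A single named vector is
#'   recycled for all donors.
#' @param genes list of [gene_spec()] objects with unique gene ids.
#' @param n_plates number of plates; cells are randomized across plates in
#'   balanced fashion.
#' @param plate_shift numeric Ct offset per plate (scalar recycled).
#' @param plate_dropout_boost extra dropout probability per plate (scalar
#'   recycled); combined with baseline dropout as
#'   `1 - (1 - baseline) * (1 - boost)`.
#' @param plate_dropout_ct_threshold genes with primary component mean above
#'   this Ct are eligible for plate dropout boost and for low-quality-cell
#'   dropout (default 30).
#' @param low_quality_cell_fraction fraction of cells with inefficient RNA
#'   extraction, which lose low-abundance genes (those above the Ct
#'   threshold) in a coordinated fashion (default 0).
#' @param low_quality_dropout extra dropout probability for low-abundance
#'   genes in low-quality cells.
#' @param cell_type label recorded in the annotations.
#' @param seed integer seed; identical specs generate identical data.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_donors, cells_per_donor, subtype_proportions,
                            genes, n_plates = 1, plate_shift = 0,
                            plate_dropout_boost = 0,
                            plate_dropout_ct_threshold = 30,
                            low_quality_cell_fraction = 0,
                            low_quality_dropout = 0,
                            cell_type = "synthetic", seed = 1L) {
  if (is.null(dim(subtype_proportions))) {
    subtype_proportions <- matrix(subtype_proportions, nrow = n_donors,
                                  ncol = length(subtype_proportions),
                                  byrow = TRUE,
                                  dimnames = list(NULL, names(subtype_proportions)))
  }
  if (nrow(subtype_proportions) != n_donors)
    stop("subtype_proportions must have one row per donor", call. = FALSE)
  if (is.null(colnames(subtype_proportions)))
    stop("subtype_proportions must have subtype labels as colnames", call. = FALSE)
  if (any(subtype_proportions < 0) ||
      any(abs(rowSums(subtype_proportions) - 1) > 1e-12))
    stop("each donor's subtype proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (!all(vapply(genes, inherits, logical(1), "gene_spec")))
    stop("`genes` must be a list of gene_spec objects", call. = FALSE)
  validate_ids(vapply(genes, `[[`, character(1), "gene_id"), "gene")
  cells_per_donor <- rep_len(cells_per_donor, n_donors)
  plate_shift <- rep_len(plate_shift, n_plates)
  plate_dropout_boost <- rep_len(plate_dropout_boost, n_plates)
  structure(list(n_donors = n_donors, cells_per_donor = cells_per_donor,
                 subtype_proportions = subtype_proportions, genes = genes,
                 n_plates = n_plates, plate_shift = plate_shift,
                 plate_dropout_boost = plate_dropout_boost,
                 plate_dropout_ct_threshold = plate_dropout_ct_threshold,
                 low_quality_cell_fraction = low_quality_cell_fraction,
                 low_quality_dropout = low_quality_dropout,
                 cell_type = cell_type, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a Ct matrix with known ground truth
#'
#' Draws cells, subtypes, plates and per-reaction Ct values from a
#' [population_spec()]. Finite values receive the plate shift and are clipped
#' to \[1, 40\]; dropout replaces values with the missing code. The ground
#' truth records each cell's latent subtype and, per reaction, whether a
#' missing value is biological (an off/low component that emits no signal) or
#' technical (random or plate-driven failure) — the distinction at the heart
#' of how exclusion strategies differ.
#'
#' @param spec a [population_spec()].
#' @return list with `ct` ([ct_matrix()]), `annotations` (data frame),
#'   `truth` (data frame: cell_id, subtype, donor_id, plate_id) and
#'   `dropout_cause` (character matrix: `"none"`, `"biological"`,
#'   `"technical"`).
#' @export
generate_ct_data <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, generate_ct_data_impl(spec))
}

generate_ct_data_impl <- function(spec) {
  donors <- sprintf("D%d", seq_len(spec$n_donors))
  donor_of <- rep(donors, spec$cells_per_donor)
  n <- length(donor_of)
  cell_ids <- sprintf("%s_c%03d", donor_of,
                      unlist(lapply(spec$cells_per_donor, seq_len)))
  subtypes <- colnames(spec$subtype_proportions)
  subtype_of <- vapply(seq_len(n), function(i) {
    p <- spec$subtype_proportions[match(donor_of[i], donors), ]
    sample(subtypes, 1, prob = p)
  }, character(1))
  plate_of <- sample(rep_len(seq_len(spec$n_plates), n))
  lowq <- if (is.null(spec$low_quality_cell_fraction)) rep(FALSE, n) else
    stats::runif(n) < spec$low_quality_cell_fraction
  gene_ids <- vapply(spec$genes, `[[`, character(1), "gene_id")
  vals <- matrix(NA_real_, n, length(gene_ids),
                 dimnames = list(cell_ids, gene_ids))
  cause <- matrix("none", n, length(gene_ids),
                  dimnames = list(cell_ids, gene_ids))
  for (g in seq_along(spec$genes)) {
    gs <- spec$genes[[g]]
    nc <- length(gs$component_means)
    if (!is.null(gs$subtype_linkage) && nc >= 2) {
      comp <- ifelse(subtype_of == gs$subtype_linkage, 2L, 1L)
    } else if (nc == 1) {
      comp <- rep(1L, n)
    } else {
      w <- gs$component_weights
      if (is.null(w)) w <- rep(1 / nc, nc)
      comp <- sample.int(nc, n, replace = TRUE, prob = w)
    }
    v <- stats::rnorm(n, gs$component_means[comp], gs$component_sds[comp])
    bio_missing <- rep(FALSE, n)
    low <- gs$modality_class %in% c("B-M", "B-L") & comp == 2L
    if (gs$modality_class == "B-M") {
      bio_missing <- low
    } else if (gs$modality_class == "B-L") {
      bio_missing <- low & stats::runif(n) < gs$low_missing_prob
      v[low & !bio_missing] <- pmin(pmax(v[low & !bio_missing], 35), 37.9)
    }
    v <- v + spec$plate_shift[plate_of]
    v <- pmin(pmax(v, 1), 40)
    low_abundance <- gs$component_means[1] > spec$plate_dropout_ct_threshold
    boost <- if (low_abundance) spec$plate_dropout_boost[plate_of] else rep(0, n)
    qboost <- if (low_abundance && !is.null(spec$low_quality_dropout))
      spec$low_quality_dropout * lowq else rep(0, n)
    p_drop <- 1 - (1 - gs$baseline_dropout) * (1 - boost) * (1 - qboost)
    tech_missing <- stats::runif(n) < p_drop
    cause[bio_missing, g] <- "biological"
    cause[tech_missing & !bio_missing, g] <- "technical"
    v[bio_missing | tech_missing] <- 999
    vals[, g] <- v
  }
  ct <- ct_matrix(vals, missing_code = 999)
  ann <- data.frame(cell_id = cell_ids, donor_id = donor_of,
                    plate_id = sprintf("P%d", plate_of),
                    cell_type = spec$cell_type, n_cells_loaded = 1L,
                    is_negative_control = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(cell_id = cell_ids, subtype = subtype_of,
                      donor_id = donor_of, plate_id = ann$plate_id,
                      low_quality = lowq, stringsAsFactors = FALSE)
  list(ct = ct, annotations = ann, truth = truth, dropout_cause = cause)
}

#' Canned fixture emulating a 96-gene immune single-cell qRT-PCR study
#'
#' Builds and generates a [population_spec()] mimicking a typical study
#' design for the requested immune cell type:
#' \describe{
#'   \item{neutrophil}{5 donors x 44 cells (220 cells), 96 genes, 5 plates,
#'     two latent subtypes "A"/"B" with donor-skewed proportions (one donor
#'     near 45% subtype A against ~19% overall).}
#'   \item{t_lymphocyte}{6 donors (247 cells total), 96 genes, 5 plates,
#'     higher heterogeneity: more low-abundance genes, larger component SDs
#'     and more bimodal genes.}
#' }
#' The panel includes one far-highest-expressed outlier gene, two
#' reference-grade high expressors whose occasional reaction failures inflate
#' the pooled reference SD (which is what lets low-abundance genes pass a
#' 3-SD mean-Ct cutoff on real data), unimodal genes, subtype-linked on/off
#' (B-M) and low-expressor (B-L) genes in both linkage directions, trimodal
#' genes, low-abundance genes subject to the plate artifact, and a few genes
#' expressed nowhere. With `plate_artifact = TRUE` plate 1 gets a strong
#' extra dropout probability for low-abundance genes, reproducing the
#' signature by which a plate effect can masquerade as an extra cell subtype.
#'
#' Loading controls are also generated: one 10-cell control per plate and two
#' 100-cell controls (Ct shifted down by log2 of the cell number), plus two
#' all-missing negative controls.
#'
#' @param kind `"neutrophil"` or `"t_lymphocyte"`.
#' @param seed integer seed.
#' @param plate_artifact logical; include the plate-1 dropout artifact.
#' @return list with `ct`, `annotations`, `truth`, `dropout_cause`,
#'   `controls` ([ct_matrix()]), `control_annotations`, and `spec`.
#' @export
immune_panel_fixture <- function(kind = c("neutrophil", "t_lymphocyte"),
                                 seed = 1L, plate_artifact = TRUE) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  spec <- with_seed(seed + 1000L, immune_panel_spec(kind, seed, plate_artifact))
  out <- generate_ct_data(spec)
  ctrl <- with_seed(seed + 2000L, immune_panel_controls(spec))
  c(out, ctrl, list(spec = spec))
}

immune_panel_spec <- function(kind, seed, plate_artifact) {
  g <- list()
  add <- function(lst, ...) c(lst, list(gene_spec(...)))
  if (kind == "neutrophil") {
    n_u <- 39; n_bm_a <- 10; n_bm_b <- 6; n_bl <- 8; n_t <- 4; n_art <- 23
    sd_hi <- 1.4; art_drop <- 0.10
  } else {
    n_u <- 33; n_bm_a <- 12; n_bm_b <- 8; n_bl <- 10; n_t <- 4; n_art <- 23
    sd_hi <- 1.8; art_drop <- 0.12
  }
  g <- add(g, "HK1", "U", 13, 2.0, baseline_dropout = 0.01)
  g <- add(g, "REF1", "U", 16, 4.0, baseline_dropout = 0.04)
  g <- add(g, "REF2", "U", 16.5, 4.0, baseline_dropout = 0.04)
  for (i in seq_len(n_u))
    g <- add(g, sprintf("U%02d", i), "U", stats::runif(1, 19, 24.5),
             stats::runif(1, 0.9, sd_hi), baseline_dropout = 0.01)
  for (i in seq_len(n_bm_a))
    g <- add(g, sprintf("BLA%02d", i), "B-L",
             c(stats::runif(1, 21, 24.5), 36.5), c(stats::runif(1, 0.8, 1.2), 0.6),
             subtype_linkage = "A", baseline_dropout = 0.02,
             low_missing_prob = 0.15)
  for (i in seq_len(n_bm_b))
    g <- add(g, sprintf("BMB%02d", i), "B-M",
             c(stats::runif(1, 21, 24.5), 38), c(stats::runif(1, 0.8, 1.2), 1),
             subtype_linkage = "B", baseline_dropout = 0.02)
  for (i in seq_len(n_bl))
    g <- add(g, sprintf("BL%02d", i), "B-L",
             c(stats::runif(1, 21, 24.5), 36.5), c(stats::runif(1, 0.8, 1.2), 0.6),
             subtype_linkage = "A", baseline_dropout = 0.02,
             low_missing_prob = 0.15)
  for (i in seq_len(n_t))
    g <- add(g, sprintf("T%02d", i), "T", c(19, 22, 24.5) + stats::runif(3, -0.5, 0.5),
             rep(0.8, 3), baseline_dropout = 0.02)
  for (i in seq_len(n_art))
    g <- add(g, sprintf("LA%02d", i), "U", stats::runif(1, 25.5, 27.5), 1.0,
             baseline_dropout = art_drop)
  for (i in 1:3)
    g <- add(g, sprintf("DEAD%d", i), "U", 35, 1.0, baseline_dropout = 1)
  boost <- rep(0, 5)
  if (plate_artifact) boost[1] <- 0.98
  if (kind == "neutrophil") {
    props <- cbind(A = c(4 / 44, 10 / 41, 2 / 40, 17 / 38, 6 / 39))
    props <- cbind(props, B = 1 - props[, "A"])
    population_spec(5, 44, props, g, n_plates = 5,
                    plate_dropout_boost = boost,
                    plate_dropout_ct_threshold = 25,
                    low_quality_cell_fraction = 0.05,
                    low_quality_dropout = 0.85,
                    cell_type = "neutrophil", seed = seed)
  } else {
    props <- cbind(A = c(0.10, 0.28, 0.06, 0.42, 0.16, 0.33))
    props <- cbind(props, B = 1 - props[, "A"])
    population_spec(6, c(42, 41, 41, 41, 41, 41), props, g, n_plates = 5,
                    plate_dropout_boost = boost,
                    plate_dropout_ct_threshold = 25,
                    low_quality_cell_fraction = 0.1,
                    low_quality_dropout = 0.85,
                    cell_type = "t_lymphocyte", seed = seed + 1L)
  }
}

immune_panel_controls <- function(spec) {
  gene_ids <- vapply(spec$genes, `[[`, character(1), "gene_id")
  mu <- vapply(spec$genes, function(gs) gs$component_means[1], numeric(1))
  dead <- vapply(spec$genes, function(gs) gs$baseline_dropout >= 1, logical(1))
  mk <- function(id_prefix, n_loaded, count) {
    v <- t(vapply(seq_len(count), function(i) {
      x <- stats::rnorm(length(mu), mu - log2(n_loaded), 0.5)
      x <- pmin(pmax(x, 1), 40)
      x[dead] <- 999
      x
    }, numeric(length(mu))))
    rownames(v) <- sprintf("%s_%d", id_prefix, seq_len(count))
    colnames(v) <- gene_ids
    v
  }
  v10 <- mk("ctrl10", 10, spec$n_plates)
  v100 <- mk("ctrl100", 100, 2)
  vneg <- matrix(999, 2, length(mu),
                 dimnames = list(c("neg_1", "neg_2"), gene_ids))
  vals <- rbind(v10, v100, vneg)
  ann <- data.frame(
    cell_id = rownames(vals),
    donor_id = "pooled",
    plate_id = c(sprintf("P%d", seq_len(spec$n_plates)), "P1", "P2", "P1", "P2"),
    cell_type = spec$cell_type,
    n_cells_loaded = c(rep(10L, spec$n_plates), 100L, 100L, 1L, 1L),
    is_negative_control = c(rep(FALSE, spec$n_plates + 2), TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(controls = ct_matrix(vals, 999), control_annotations = ann)
}

#' Serialize a population spec to JSON
#'
#' @param spec a [population_spec()].
#' @param path output JSON file.
#' @export
write_population_spec <- function(spec, path) {
  stopifnot(inherits(spec, "population_spec"))
  obj <- unclass(spec)
  obj$subtype_proportions <- list(
    labels = as.list(colnames(spec$subtype_proportions)),
    by_donor = lapply(seq_len(nrow(spec$subtype_proportions)), function(i)
      as.list(unname(spec$subtype_proportions[i, ]))))
  obj$genes <- lapply(spec$genes, unclass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a population spec from JSON
#'
#' @param path JSON file written by [write_population_spec()].
#' @return a [population_spec()].
#' @export
read_population_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  props <- do.call(rbind, lapply(obj$subtype_proportions$by_donor,
                                 function(r) unlist(r)))
  colnames(props) <- unlist(obj$subtype_proportions$labels)
  genes <- lapply(obj$genes, function(r)
    gene_spec(r$gene_id, r$modality_class, unlist(r$component_means),
              unlist(r$component_sds),
              subtype_linkage = r$subtype_linkage,
              baseline_dropout = r$baseline_dropout,
              component_weights = if (is.null(r$component_weights)) NULL
                                  else unlist(r$component_weights),
              low_missing_prob = r$low_missing_prob))
  population_spec(obj$n_donors, unlist(obj$cells_per_donor), props, genes,
                  n_plates = obj$n_plates,
                  plate_shift = unlist(obj$plate_shift),
                  plate_dropout_boost = unlist(obj$plate_dropout_boost),
                  plate_dropout_ct_threshold = obj$plate_dropout_ct_threshold,
                  low_quality_cell_fraction = obj$low_quality_cell_fraction,
                  low_quality_dropout = obj$low_quality_dropout,
                  cell_type = obj$cell_type, seed = obj$seed)
}
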