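test_that("determine_lod finds the start of the upper mode", {
  # engineer per-gene maxima: lower mode at 33, upper mode from 37
  set.seed(1)
  lows <- runif(20, 33, 33.9)
  highs <- c(runif(8, 37, 37.9), runif(7, 38, 38.9))
  vals <- rbind(matrix(20, 3, 35), c(lows, highs))
  rownames(vals) <- sprintf("c%d", 1:4)
  colnames(vals) <- sprintf("g%d", 1:35)
  lod <- determine_lod(toy_ct(vals))
  expect_equal(lod$lod_ct, 37)
  expect_equal(lod$detection_method, "histogram_valley")
})

test_that("determine_lod errors on unimodal histograms", {
  set.seed(2)
  vals <- rbind(matrix(20, 3, 30), 32 + runif(30, -0.5, 0.5))
  rownames(vals) <- sprintf("c%d", 1:4)
  colnames(vals) <- sprintf("g%d", 1:30)
  expect_error(determine_lod(toy_ct(vals)), "unimodal")
})

test_that("log2ex_transform implements the printed rule", {
  v <- matrix(c(30, 999, 37, 36.9, 40, 1), 2, 3)
  ct <- toy_ct(v)
  e <- log2ex_transform(ct, 37)
  expect_equal(unname(as.matrix(e)[1, 1]), 7)    # 37 - 30
  expect_equal(unname(as.matrix(e)[2, 1]), 0)    # missing -> LOD -> 0
  expect_equal(unname(as.matrix(e)[1, 2]), 0)    # exactly at LOD
  expect_equal(unname(as.matrix(e)[2, 2]), 0.1)  # just below LOD
  expect_equal(unname(as.matrix(e)[1, 3]), 0)    # above LOD clamped
  expect_equal(unname(as.matrix(e)[2, 3]), 36)   # strongest signal
  expect_equal(e$scale, "log2ex")
  expect_true(all(as.matrix(e) >= 0 & as.matrix(e) <= 36))
})

test_that("log2ex is antitone in Ct below the LOD", {
  set.seed(3)
  ct_vals <- sort(runif(50, 1, 37))
  v <- matrix(ct_vals, 1, dimnames = list("c1", sprintf("g%d", 1:50)))
  e <- as.matrix(log2ex_transform(ct_matrix(v), 37))
  expect_true(all(diff(e[1, ]) < 0))
})

complete_matrix <- function(n = 10, g = 5, seed = 4) {
  set.seed(seed)
  v <- matrix(rnorm(n * g, rep(c(15, 17, 18, 20, 21), each = n), 1.5), n, g)
  toy_ct(pmin(pmax(v, 1), 40))
}

test_that("sd_cutoff on a benign complete matrix excludes nothing", {
  ct <- complete_matrix()
  out <- exclude_sd_cutoff(ct, 37, min_cells_detected = 0)
  expect_equal(nrow(out$report$excluded_genes), 0L)
  expect_equal(nrow(out$report$excluded_cells), 0L)
  expect_equal(nrow(out$report$reassignments), 0L)
  expect_equal(dim(out$expr), dim(ct))
  expect_length(out$report$reference_genes, 2L)
  # reference genes are ranks 2 and 3 by mean Ct; rank 1 is ignored
  expect_setequal(out$report$reference_genes, c("g02", "g03"))
})

test_that("sd_cutoff limit behaviour: infinite multiplier excludes nothing", {
  fx <- immune_panel_fixture("neutrophil", seed = 6)
  out <- exclude_sd_cutoff(fx$ct, 36, sd_multiplier = Inf,
                           min_expressed_fraction = 0, min_cells_detected = -1)
  expect_equal(dim(out$expr), dim(fx$ct))
  expect_equal(nrow(out$report$excluded_genes), 0L)
  expect_equal(nrow(out$report$excluded_cells), 0L)
})

test_that("sd_cutoff reassignment ledger equals a brute-force diff", {
  set.seed(9)
  v <- matrix(runif(48, 15, 30), 8, 6)
  v[sample(48, 6)] <- 999
  v[sample(48, 4)] <- runif(4, 38, 40)
  ct <- toy_ct(v)
  for (policy in c("as_zero", "as_gene_mean")) {
    out <- exclude_sd_cutoff(ct, 37, missing_policy = policy,
                             sd_multiplier = Inf,
                             min_expressed_fraction = 0,
                             min_cells_detected = 0)
    m40 <- ct$values; m40[m40 == 999] <- 40
    naive <- 37 - m40[rownames(as.matrix(out$expr)),
                      colnames(as.matrix(out$expr))]
    diffs <- which(abs(naive - as.matrix(out$expr)) > 1e-12, arr.ind = TRUE)
    expect_equal(nrow(out$report$reassignments), nrow(diffs))
  }
})

test_that("sd_cutoff as_gene_mean imputes the detected-cell mean", {
  v <- matrix(c(20, 21, 22, 999,
                18, 18, 18, 18,
                19, 19, 19, 19), 4, 3)
  ct <- toy_ct(v)
  out <- exclude_sd_cutoff(ct, 37, missing_policy = "as_gene_mean",
                           sd_multiplier = Inf, min_expressed_fraction = 0,
                           min_cells_detected = 0)
  e <- as.matrix(out$expr)
  expect_equal(unname(e["c04", "g01"]), mean(37 - c(20, 21, 22)))
})

test_that("exclusion partitions the input exactly for every strategy", {
  fx <- immune_panel_fixture("neutrophil", seed = 7)
  lod <- determine_lod(fx$ct)
  checks <- list(
    exclude_sd_cutoff(fx$ct, lod),
    exclude_supervised(fx$ct),
    exclude_all_inclusive(fx$ct, fx$controls, lod, fx$annotations))
  for (out in checks) {
    expect_equal(nrow(out$expr$values) + nrow(out$report$excluded_cells),
                 nrow(fx$ct$values))
    expect_equal(ncol(out$expr$values) + nrow(out$report$excluded_genes),
                 ncol(fx$ct$values))
    expect_true(all(out$report$reassignments$cell_id %in%
                      rownames(out$expr$values)))
    expect_true(all(out$report$reassignments$gene_id %in%
                      colnames(out$expr$values)))
    expect_false(any(out$expr$values == 999))
  }
})

test_that("supervised exclusion reproduces the hand-worked toy", {
  # 6 genes x 10 cells: g5, g6 jointly missing in c1-c4 (a co-missing
  # block); g3 missing only in c7 (sporadic)
  v <- matrix(20, 10, 6, dimnames = list(sprintf("c%d", 1:10),
                                         sprintf("g%d", 1:6)))
  v[, 1] <- 18; v[, 2] <- 19; v[, 4] <- 21
  v[, 3] <- c(20, 21, 22, 20, 21, 22, 999, 20, 21, 22)
  v[1:4, 5] <- 999; v[1:4, 6] <- 999
  v[5:10, 5] <- 24; v[5:10, 6] <- 25
  out <- exclude_supervised(ct_matrix(v), presence_threshold = 0.7,
                            block_missing_rate = 0.5)
  e <- as.matrix(out$expr)
  expect_equal(dim(e), c(10L, 6L))                     # nothing excluded
  expect_equal(unname(e[1:4, "g5"]), rep(40, 4))       # block -> Ct 40
  expect_equal(unname(e[1:4, "g6"]), rep(40, 4))
  expect_equal(unname(e["c7", "g3"]),
               mean(c(20, 21, 22, 20, 21, 22, 20, 21, 22)))  # sporadic -> mean
  expect_equal(sort(unlist(out$report$blocks)), c("g5", "g6"))
  reasons <- table(out$report$reassignments$reason)
  expect_equal(unname(reasons["block_absent_to_40"]), 8L)
  expect_equal(unname(reasons["sporadic_to_gene_mean"]), 1L)
  expect_equal(out$expr$scale, "ct")
})

test_that("supervised exclusion is the identity on complete data", {
  ct <- complete_matrix()
  out <- exclude_supervised(ct)
  expect_equal(as.matrix(out$expr), ct$values)
  expect_equal(nrow(out$report$reassignments), 0L)
  expect_equal(nrow(out$report$excluded_genes), 0L)
  expect_equal(nrow(out$report$excluded_cells), 0L)
})

test_that("supervised exclusion errors on an empty core set", {
  v <- matrix(999, 6, 4, dimnames = list(sprintf("c%d", 1:6),
                                         sprintf("g%d", 1:4)))
  v[1, ] <- 20
  expect_error(exclude_supervised(ct_matrix(v)), "empty core set")
})

test_that("all-inclusive exclusion drops only control- and array-missing genes", {
  ct <- complete_matrix()
  controls <- toy_ct(matrix(20, 2, 5,
                            dimnames = list(c("k1", "k2"),
                                            colnames(ct$values))))
  ann <- toy_ann(rownames(ct$values), plate = rep(c("P1", "P2"), 5))
  out <- exclude_all_inclusive(ct, controls, 37, ann)
  expect_equal(as.matrix(out$expr), 37 - ct$values)
  expect_equal(nrow(out$report$excluded_genes), 0L)

  # force one gene missing on plate 2 only
  v <- ct$values
  v[ann$plate_id == "P2", "g04"] <- 999
  out2 <- exclude_all_inclusive(ct_matrix(v), controls, 37, ann)
  expect_equal(out2$report$excluded_genes$gene_id, "g04")
  expect_equal(out2$report$excluded_genes$reason, "missing_on_array:P2")
  expect_equal(nrow(out2$expr$values), 10L)            # no cells excluded

  # gene undetected in every control
  cv <- controls$values; cv[, "g02"] <- 999
  out3 <- exclude_all_inclusive(ct, toy_ct(cv), 37, ann)
  expect_true("g02" %in% out3$report$excluded_genes$gene_id)
  expect_equal(out3$report$excluded_genes$reason[
    out3$report$excluded_genes$gene_id == "g02"], "absent_in_controls")

  expect_error(exclude_all_inclusive(ct, NULL, 37, ann), "required")
})
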