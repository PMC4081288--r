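simple_spec <- function(genes, n_cells = 200, props = c(A = 1), seed = 1,
                        ...) {
  population_spec(1, n_cells, props, genes, seed = seed, ...)
}

test_that("population_spec validates donor proportions and genes", {
  g <- list(gene_spec("g1", "U", 25, 1))
  expect_error(population_spec(2, 10, matrix(c(0.5, 0.4, 0.5, 0.5), 2,
                                             dimnames = list(NULL, c("A", "B"))),
                               g), "sum to 1")
  expect_error(population_spec(1, 10, c(A = 1), list("not a gene")),
               "gene_spec")
  expect_error(gene_spec("g1", "B-M", 25, 1), "needs 2 component")
  expect_error(gene_spec("g1", "U", 45, 1), "\\(1, 40\\)")
})

test_that("single-component genes without dropout sample their components", {
  genes <- lapply(1:6, function(i)
    gene_spec(sprintf("g%d", i), "U", 20 + i, 1))
  out <- generate_ct_data(simple_spec(genes, n_cells = 400))
  expect_false(any(out$ct$values == 999))
  mu <- colMeans(out$ct$values)
  se <- apply(out$ct$values, 2, sd) / sqrt(400)
  expect_true(all(abs(mu - (21:26)) < 3 * se + 1e-9))
  expect_true(all(out$dropout_cause == "none"))
})

test_that("identical seeds are bit-identical; different seeds differ", {
  genes <- list(gene_spec("g1", "U", 25, 1, baseline_dropout = 0.1),
                gene_spec("g2", "B-M", c(24, 38), c(1, 1),
                          subtype_linkage = "A"))
  spec <- population_spec(2, 50, c(A = 0.3, B = 0.7), genes, n_plates = 2,
                          seed = 99)
  a <- generate_ct_data(spec)
  b <- generate_ct_data(spec)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$truth, b$truth)
  spec2 <- spec; spec2$seed <- 100L
  expect_false(identical(a$ct$values, generate_ct_data(spec2)$ct$values))
})

test_that("B-M missing fraction matches its binomial expectation", {
  p_link <- 0.3; p_drop <- 0.05
  genes <- list(gene_spec("bm", "B-M", c(24, 38), c(1, 1),
                          subtype_linkage = "S", baseline_dropout = p_drop),
                gene_spec("u", "U", 25, 1))
  spec <- population_spec(1, 1000, c(S = p_link, other = 1 - p_link), genes,
                          seed = 5)
  out <- generate_ct_data(spec)
  expected <- p_link + p_drop * (1 - p_link)
  se <- sqrt(expected * (1 - expected) / 1000)
  frac <- mean(out$ct$values[, "bm"] == 999)
  expect_lt(abs(frac - expected), 3 * se)
  # dropout causes are labelled
  miss <- out$ct$values[, "bm"] == 999
  expect_true(all(out$dropout_cause[miss, "bm"] %in% c("biological", "technical")))
  linked <- out$truth$subtype == "S"
  expect_true(all(out$dropout_cause[linked & out$dropout_cause[, "bm"] != "technical", "bm"]
                  %in% c("biological")))
})

test_that("marginal missing rates match spec expectations at n = 1000", {
  genes <- list(
    gene_spec("u1", "U", 22, 1, baseline_dropout = 0.10),
    gene_spec("bl", "B-L", c(23, 36.5), c(1, 0.6), subtype_linkage = "S",
              baseline_dropout = 0.02, low_missing_prob = 0.4),
    gene_spec("t", "T", c(20, 25, 30), c(1, 1, 1), baseline_dropout = 0.15))
  spec <- population_spec(1, 1000, c(S = 0.25, o = 0.75), genes, seed = 8)
  out <- generate_ct_data(spec)
  exp_rates <- c(u1 = 0.10,
                 bl = 0.25 * 0.4 + 0.02 * (1 - 0.25 * 0.4),
                 t = 0.15)
  for (g in names(exp_rates)) {
    se <- sqrt(exp_rates[g] * (1 - exp_rates[g]) / 1000)
    expect_lt(abs(mean(out$ct$values[, g] == 999) - exp_rates[g]), 3.5 * se)
  }
})

test_that("B-L low component emits low expressors in the stated window", {
  genes <- list(gene_spec("bl", "B-L", c(23, 36.5), c(1, 0.6),
                          subtype_linkage = "S", low_missing_prob = 0.3))
  out <- generate_ct_data(population_spec(1, 500, c(S = 0.5, o = 0.5), genes,
                                          seed = 2))
  linked <- out$truth$subtype == "S"
  v <- out$ct$values[linked, "bl"]
  finite_low <- v[v != 999]
  expect_true(all(finite_low >= 35 & finite_low < 38))
  expect_gt(sum(v == 999), 0)
})

test_that("without plate effects per-plate gene means are indistinguishable", {
  genes <- lapply(1:40, function(i) gene_spec(sprintf("g%d", i), "U", 25, 1))
  spec <- population_spec(1, 300, c(A = 1), genes, n_plates = 5, seed = 13)
  out <- generate_ct_data(spec)
  plate <- factor(out$annotations$plate_id)
  p <- vapply(seq_len(40), function(j)
    anova(lm(out$ct$values[, j] ~ plate))[["Pr(>F)"]][1], numeric(1))
  expect_gt(mean(p < 0.05), 0)   # not degenerate
  expect_lt(mean(p < 0.05), 0.15)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("plate shift and dropout boost act on the designated plates", {
  genes <- list(gene_spec("hi", "U", 20, 0.5),
                gene_spec("lo", "U", 32, 0.5, baseline_dropout = 0.05))
  spec <- population_spec(1, 600, c(A = 1), genes, n_plates = 2,
                          plate_shift = c(0, 1.5),
                          plate_dropout_boost = c(0.5, 0),
                          plate_dropout_ct_threshold = 30, seed = 4)
  out <- generate_ct_data(spec)
  plate1 <- out$annotations$plate_id == "P1"
  v <- out$ct$values
  m1 <- mean(v[!plate1 & v[, "hi"] != 999, "hi"])
  m0 <- mean(v[plate1 & v[, "hi"] != 999, "hi"])
  expect_equal(m1 - m0, 1.5, tolerance = 0.15)
  # boost hits only the low-abundance gene, only on plate 1
  expect_gt(mean(v[plate1, "lo"] == 999), 0.4)
  expect_lt(mean(v[!plate1, "lo"] == 999), 0.15)
  expect_lt(mean(v[plate1, "hi"] == 999), 0.05)
})

test_that("immune panel fixtures have the study dimensions", {
  fx <- immune_panel_fixture("neutrophil", seed = 1)
  expect_equal(dim(fx$ct), c(220L, 96L))
  expect_equal(length(unique(fx$truth$donor_id)), 5L)
  expect_equal(length(unique(fx$truth$plate_id)), 5L)
  ft <- immune_panel_fixture("t_lymphocyte", seed = 1)
  expect_equal(dim(ft$ct), c(247L, 96L))
  expect_equal(length(unique(ft$truth$donor_id)), 6L)
  fx2 <- immune_panel_fixture("neutrophil", seed = 2)
  expect_false(identical(fx$ct$values, fx2$ct$values))
  expect_error(immune_panel_fixture("monocyte"), "arg")
  # controls are present and annotated
  expect_true(any(fx$control_annotations$n_cells_loaded == 10))
  expect_true(any(fx$control_annotations$is_negative_control))
})

test_that("population specs serialize to JSON and back", {
  fx <- immune_panel_fixture("neutrophil", seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_population_spec(fx$spec, path)
  back <- read_population_spec(path)
  expect_equal(back$subtype_proportions, fx$spec$subtype_proportions)
  expect_equal(back$cells_per_donor, fx$spec$cells_per_donor)
  expect_equal(length(back$genes), length(fx$spec$genes))
  expect_identical(generate_ct_data(back)$ct$values,
                   generate_ct_data(fx$spec)$ct$values)
})
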