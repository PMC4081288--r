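# independent density evaluations for the AIC brute-force check
brute_loglik <- function(fam, fit, x) {
  switch(fam,
    normal = sum(dnorm(x, fit$mean, fit$sd, log = TRUE)),
    lognormal = sum(dlnorm(x, fit$meanlog, fit$sdlog, log = TRUE)),
    gamma = sum(dgamma(x, shape = fit$shape, rate = fit$rate, log = TRUE)),
    weibull = sum(dweibull(x, shape = fit$shape, scale = fit$scale, log = TRUE)),
    johnson_su = {
      w <- (x - fit$xi) / fit$lambda
      z <- fit$gamma + fit$delta * asinh(w)
      sum(log(fit$delta) - log(fit$lambda) - 0.5 * log(2 * pi) -
            0.5 * log(1 + w^2) - 0.5 * z^2)
    },
    johnson_sl = {
      z <- fit$gamma + fit$delta * log(x - fit$xi)
      sum(log(fit$delta) - log(x - fit$xi) - 0.5 * log(2 * pi) - 0.5 * z^2)
    },
    mixture_k2 = ,
    mixture_k3 = {
      d <- sapply(seq_along(fit$means), function(j)
        fit$weights[j] * dnorm(x, fit$means[j], fit$sds[j]))
      sum(log(rowSums(d)))
    })
}

test_that("fit_families scores a clean normal sample correctly", {
  set.seed(21)
  x <- rnorm(500, 25, 1)
  ff <- fit_families(x, seed = 1)
  singles <- ff$aic_table[c("normal", "lognormal", "gamma", "weibull",
                            "johnson_su", "johnson_sl")]
  expect_equal(names(which.min(singles)), "normal")
  # a k=2 mixture cannot beat the true single normal decisively
  expect_gt(ff$aic_table[["mixture_k2"]] - ff$aic_table[["normal"]], -2)
})

test_that("AIC values match brute-force log-likelihood at the fitted params", {
  set.seed(22)
  x <- c(rnorm(150, 22, 1), rnorm(100, 30, 1.5))
  ff <- fit_families(x, seed = 2)
  for (fam in names(ff$aic_table)) {
    aic <- ff$aic_table[[fam]]
    if (!is.finite(aic)) next
    fit <- ff$fits[[fam]]
    ll <- brute_loglik(fam, fit, x)
    expect_equal(aic, 2 * fit$n_par - 2 * ll, tolerance = 1e-6,
                 info = fam)
  }
})

test_that("degenerate and undersized samples follow the error contract", {
  expect_error(fit_families(rep(c(20, 20), 10)), "zero variance")
  out <- fit_families(c(20, 21, 22), min_n = 8)
  expect_true(out$insufficient_data)
})

test_that("a separated two-component sample favours the k = 2 mixture", {
  set.seed(23)
  x <- c(rnorm(125, 22, 1), rnorm(125, 34, 1))
  ff <- fit_families(x, seed = 3)
  singles <- ff$aic_table[c("normal", "lognormal", "gamma", "weibull",
                            "johnson_su", "johnson_sl")]
  expect_lt(ff$aic_table[["mixture_k2"]], min(singles, na.rm = TRUE) - 2)
  # mixture likelihood agrees with the brute-force responsibility oracle
  fit <- ff$fits[["mixture_k2"]]
  expect_equal(fit$loglik, mixture_loglik(x, fit), tolerance = 1e-8)
  expect_equal(sort(fit$means), c(22, 34), tolerance = 0.5)
})

test_that("classify_modality reproduces the constructed examples", {
  set.seed(24)
  u <- classify_modality(rnorm(200, 24, 1), 37)
  expect_equal(u$call, "U")

  bm <- classify_modality(c(rnorm(70, 24, 1), rep(999, 30)), 37)
  expect_equal(bm$call, "B-M")
  expect_equal(unname(bm$low_peak_composition["n_missing_code"]), 30L)
  expect_equal(unname(bm$low_peak_composition["n_low_expressors"]), 0L)

  bl <- classify_modality(c(rnorm(60, 24, 1), runif(20, 35, 36.9),
                            rep(999, 20)), 37)
  expect_equal(bl$call, "B-L")
  expect_equal(unname(bl$low_peak_composition["n_missing_code"]), 20L)
  expect_gt(bl$low_peak_composition["n_low_expressors"], 0)

  tt <- classify_modality(c(rnorm(100, 18, 0.8), rnorm(100, 25, 0.8),
                            rnorm(100, 32, 0.8)), 37)
  expect_equal(tt$call, "T")

  small <- classify_modality(c(20, 21, 22), 37)
  expect_equal(small$call, "U")
  expect_true("insufficient_data" %in% small$flags)
})

test_that("classification is invariant to cell order", {
  set.seed(25)
  x <- c(rnorm(80, 23, 1), rep(999, 25), runif(10, 35, 36.5))
  a <- classify_modality(x, 37, seed = 7)
  b <- classify_modality(sample(x), 37, seed = 7)
  expect_equal(a$call, b$call)
  expect_equal(a$aic_table, b$aic_table, tolerance = 1e-10)
})

test_that("low-peak weight recovery is within 3 SE on B-M genes", {
  for (p in c(0.2, 0.5)) {
    genes <- list(gene_spec("bm", "B-M", c(24, 38), c(1, 1),
                            subtype_linkage = "S"))
    spec <- population_spec(1, 500, c(S = p, o = 1 - p), genes,
                            seed = round(100 * p))
    out <- generate_ct_data(spec)
    call <- classify_modality(out$ct$values[, "bm"], 37)
    expect_equal(call$call, "B-M")
    se <- sqrt(p * (1 - p) / 500)
    expect_lt(abs(call$low_fraction - p), 3 * se)
  }
})

test_that("modality_calls summarises a matrix gene-wise", {
  fx <- immune_panel_fixture("neutrophil", seed = 4)
  sub <- subset_ct(fx$ct, genes = colnames(fx$ct$values)[c(4, 50, 60)])
  calls <- modality_calls(sub, 36, n_restarts = 5)
  smry <- attr(calls, "summary")
  expect_equal(nrow(smry), 3L)
  expect_true(all(smry$call %in% c("U", "B-M", "B-L", "T")))
})

test_that("modality_summary cross-tabulates calls against gene clusters", {
  mk_call <- function(id, cl) structure(list(gene_id = id, call = cl),
                                        class = "modality_call")
  calls <- list(mk_call("g1", "U"), mk_call("g2", "U"), mk_call("g3", "U"))
  expect_equal(dim(modality_summary(calls,
                                    c(g1 = 1, g2 = 1, g3 = 1))$table),
               c(1L, 1L))
  expect_error(modality_summary(calls, c(g1 = 1, g2 = 1, gX = 2)),
               "do not match")

  # four B-M genes engineered to co-miss in the same cells share a cluster
  set.seed(26)
  n <- 120
  miss_cells <- sample(n, 30)
  v <- matrix(rnorm(n * 8, 23, 1), n, 8,
              dimnames = list(sprintf("c%03d", 1:n), sprintf("g%d", 1:8)))
  v[miss_cells, 1:4] <- 999
  clust <- cutree(hclust(dist(t(v == 999)), "average"), 2)
  calls <- c(lapply(1:4, function(i) mk_call(sprintf("g%d", i), "B-M")),
             lapply(5:8, function(i) mk_call(sprintf("g%d", i), "U")))
  out <- modality_summary(calls, clust)
  expect_equal(out$b_co_membership_fraction, 1.0)

  # random independent missingness: fraction near the permutation null
  v2 <- matrix(rnorm(n * 12, 23, 1), n, 12,
               dimnames = list(sprintf("c%03d", 1:n), sprintf("h%d", 1:12)))
  cl2 <- setNames(rep(1:3, each = 4), colnames(v2))
  is_b <- rep(c(TRUE, FALSE), 6)
  calls2 <- lapply(seq_len(12), function(i)
    mk_call(colnames(v2)[i], if (is_b[i]) "B-M" else "U"))
  obs <- modality_summary(calls2, cl2)$b_co_membership_fraction
  perm <- replicate(300, {
    shuffled <- setNames(sample(cl2), names(cl2))
    modality_summary(calls2, shuffled)$b_co_membership_fraction
  })
  expect_gte(obs, min(perm))
  expect_lte(obs, max(perm))
})
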