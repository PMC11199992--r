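conc5 <- rep(c(0, 0.25, 1, 4, 16), each = 3)

test_that("linear BMC reproduces the closed form sigma/|slope|", {
  f <- fit_bmc_models(2 + conc5, conc5, sigma = 0.5, models = "linear")
  expect_true(f$converged)
  expect_equal(f$bmc, 0.5, tolerance = 1e-6)
  f2 <- fit_bmc_models(2 - 2 * conc5, conc5, sigma = 0.5,
                       models = "linear")
  expect_equal(f2$bmc, 0.25, tolerance = 1e-6)      # |slope| = 2
})

test_that("zero-slope data yield no finite BMC", {
  set.seed(3)
  y <- rnorm(length(conc5), mean = 5, sd = 0.2)
  f <- fit_bmc_models(y, conc5, models = "linear")
  expect_true(f$converged)
  expect_true(is.na(f$bmc) || f$bmc > max(conc5))
})

test_that("BMC is equivariant under concentration rescaling", {
  set.seed(7)
  y <- 1 + 0.4 * conc5 + rnorm(length(conc5), sd = 0.1)
  f1 <- fit_bmc_models(y, conc5, models = c("linear", "power"))
  f2 <- fit_bmc_models(y, conc5 * 100, models = c("linear", "power"))
  ok <- f1$converged & f2$converged & !is.na(f1$bmc) & !is.na(f2$bmc)
  expect_true(any(ok))
  expect_equal(f2$bmc[ok], 100 * f1$bmc[ok], tolerance = 1e-4)
  expect_equal(f2$bmcl[ok], 100 * f1$bmcl[ok], tolerance = 1e-3)
})

test_that("hill-generated data are won by hill with BMC near the analytic inverse", {
  hill <- function(x) 1 + 3 * x^2 / (4 + x^2)
  y <- hill(conc5)
  f <- fit_bmc_models(y, conc5, sigma = 0.3)
  w <- f[f$winning, ]
  expect_equal(w$model, "hill")
  # analytic: 3 x^2/(4+x^2) = 0.3  =>  x = sqrt(1.2/2.7)
  expect_equal(w$bmc, sqrt(1.2 / 2.7), tolerance = 0.01)
})

test_that("interval bounds bracket the estimate and widen with noise", {
  widths <- vapply(c(0.05, 0.4), function(s) {
    ws <- vapply(1:10, function(i) {
      set.seed(100 + i)
      y <- 1 + 0.5 * conc5 + rnorm(length(conc5), sd = s)
      f <- fit_bmc_models(y, conc5, models = "linear")
      expect_true(is.na(f$bmcl) ||
                    (f$bmcl <= f$bmc && f$bmc <= f$bmcu))
      if (is.na(f$bmcl)) NA_real_ else f$bmcu - f$bmcl
    }, numeric(1))
    mean(ws, na.rm = TRUE)
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})

test_that("BMC filters apply the range, CI-ratio and fit rules in order", {
  grid <- c(0, 0.1, 1, 10, 500)
  fits <- data.frame(
    gene_id = c("below", "above", "wide", "poor", "ok", "nofit"),
    bmc = c(0.005, 600, 5, 5, 5, NA),
    bmcl = c(0.004, 500, 0.1, 4, 4, NA),
    bmcu = c(0.006, 700, 20, 6, 6, NA),
    fit_p = c(0.5, 0.5, 0.5, 0.05, 0.5, 0.5))
  out <- filter_bmc(fits, grid)
  expect_equal(out$filter_status,
               c("below_range", "above_range", "wide_ci", "poor_fit",
                 "pass", "poor_fit"))
  # bmc/bmcl = 25 > 20 triggers wide_ci
  one <- data.frame(gene_id = "x", bmc = 25, bmcl = 1, bmcu = 26,
                    fit_p = 0.5)
  expect_equal(filter_bmc(one, grid)$filter_status, "wide_ci")
  # without the CI filter that gene passes
  expect_equal(filter_bmc(one, grid, apply_ci_filter = FALSE)$filter_status,
               "pass")
})

test_that("pathway classification reports median BMCs with exact Fisher p", {
  fits <- data.frame(
    gene_id = c(paste0("in", 1:3), paste0("out", 1:2), "fail1"),
    bmc = c(1, 2, 9, 3, 4, 5),
    filter_status = c(rep("pass", 5), "poor_fit"))
  universe <- c(fits$gene_id, paste0("bg", 1:6))
  gs <- list(HIT = c(paste0("in", 1:3), "fail1"),
             MISS = paste0("bg", 1:4),
             PART = c("in1", paste0("bg", 5:6)))
  out <- pathway_classification(fits, gs, universe, p_cut = 1.000001 - 1e-9)
  hit <- out[out$set_name == "HIT", ]
  expect_equal(hit$median_bmc, 2)           # median of {1,2,9}
  expect_equal(hit$n_genes, 3L)
  # exact two-tailed Fisher on passing x set-membership over the universe:
  # 3 passing in set, 2 passing outside, 1 non-passing in set, 6 outside
  expect_equal(hit$fisher_two_tail_p,
               fisher.test(matrix(c(3, 2, 1, 6), 2))$p.value)
  expect_false("MISS" %in% out$set_name)    # zero passing genes: omitted
  empty <- pathway_classification(fits[fits$filter_status != "pass", ],
                                  gs, universe)
  expect_equal(nrow(empty), 0L)
})

test_that("a flat zero-noise response gets Williams p = 1", {
  r <- williams_trend_test(rep(3, 15), conc5, n_perm = 200, seed = 1)
  expect_equal(r$pvalue, 1)
})

test_that("a strongly monotone response passes the Williams filter", {
  hits <- 0L
  for (i in 1:20) {
    set.seed(400 + i)
    y <- 0.3 * log1p(conc5) + rnorm(length(conc5), sd = 0.05)
    r <- williams_trend_test(y, conc5, n_perm = 400, seed = i)
    if (r$pvalue < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # decreasing trends are caught too (two-directional test)
  set.seed(500)
  yd <- -0.3 * log1p(conc5) + rnorm(length(conc5), sd = 0.05)
  expect_lt(williams_trend_test(yd, conc5, n_perm = 400, seed = 2)$pvalue,
            0.05)
})

test_that("williams filter validates its design requirements", {
  expect_error(williams_trend_filter(matrix(1, 2, 6), rep(c(0, 1), 3)),
               ">= 3 concentration")
  expect_error(
    williams_trend_filter(matrix(1, 2, 4), c(0, 1, 5, 25)),
    ">= 2 replicates")
})

test_that("gene-wise BMC recovers a planted concentration response", {
  set.seed(11)
  ng <- 12
  expr <- matrix(rnorm(ng * length(conc5), mean = 6, sd = 0.15), ng,
                 dimnames = list(sprintf("g%02d", 1:ng), NULL))
  expr[1, ] <- expr[1, ] + log2(1 + conc5 / 2)        # responsive gene
  fits <- bmc_genewise(expr, conc5, n_perm = 400, seed = 5)
  expect_true("g01" %in% fits$gene_id)
  g1 <- fits[fits$gene_id == "g01", ]
  expect_false(is.na(g1$bmc))
  expect_true(g1$bmc > 0 && g1$bmc < max(conc5))
})
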