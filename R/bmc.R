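#' Dose-response model suite for benchmark concentration analysis
#'
#' Nine constant-variance least-squares models: linear, power, hill,
#' 2nd/3rd-degree polynomial, and exponential families 2-5. Each spec
#' carries a prediction function and a fitter returning coefficients and
#' their covariance; nonlinear members are fit with bounded
#' Levenberg-Marquardt least squares.
#'
#' @return Named list of model specs (`npar`, `fit`, `pred`).
#' @keywords internal
bmc_model_specs <- function() {
  lm_spec <- function(degree) {
    list(npar = degree + 1L,
         fit = function(x, y) {
           f <- lm(y ~ poly(x, degree, raw = TRUE))
           list(coef = unname(coef(f)), vcov = unname(vcov(f)),
                rss = sum(resid(f)^2))
         },
         pred = function(b, x) {
           out <- rep(b[1], length(x))
           for (d in seq_len(degree)) out <- out + b[d + 1] * x^d
           out
         })
  }
  nls_spec <- function(npar, formula_fun, start_fun, lower, upper) {
    list(npar = npar,
         fit = function(x, y) {
           dat <- data.frame(x = x, y = y)
           f <- minpack.lm::nlsLM(formula_fun, data = dat,
                                  start = start_fun(x, y),
                                  lower = lower, upper = upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200))
           v <- tryCatch(unname(vcov(f)), error = function(e) NULL)
           list(coef = unname(coef(f)), vcov = v,
                rss = sum(resid(f)^2))
         },
         pred = NULL)   # set below per model
  }
  ctl_mean <- function(x, y) if (any(x == 0)) mean(y[x == 0]) else mean(y)
  top_mean <- function(x, y) mean(y[x == max(x)])

  specs <- list()
  specs$linear <- lm_spec(1L)
  specs$poly2 <- lm_spec(2L)
  specs$poly3 <- lm_spec(3L)

  specs$power <- nls_spec(3L, y ~ a + b * x^g,
    function(x, y) list(a = ctl_mean(x, y),
                        b = (top_mean(x, y) - ctl_mean(x, y)) / max(x),
                        g = 1),
    lower = c(-Inf, -Inf, 0.1), upper = c(Inf, Inf, 8))
  specs$power$pred <- function(b, x) b[1] + b[2] * x^b[3]

  specs$hill <- nls_spec(4L, y ~ a + v * x^h / (kd^h + x^h),
    function(x, y) list(a = ctl_mean(x, y),
                        v = top_mean(x, y) - ctl_mean(x, y),
                        kd = median(x[x > 0]), h = 1),
    lower = c(-Inf, -Inf, 1e-8, 0.1), upper = c(Inf, Inf, Inf, 8))
  specs$hill$pred <- function(b, x)
    b[1] + b[2] * x^b[4] / (b[3]^b[4] + x^b[4])

  specs$exp2 <- nls_spec(2L, y ~ a * exp(b * x),
    function(x, y) {
      a <- ctl_mean(x, y)
      if (abs(a) < 1e-8) a <- mean(y) + 1e-8
      b <- if (top_mean(x, y) / a > 0)
        log(top_mean(x, y) / a) / max(x) else 0
      list(a = a, b = b)
    },
    lower = c(-Inf, -Inf), upper = c(Inf, Inf))
  specs$exp2$pred <- function(b, x) b[1] * exp(b[2] * x)

  specs$exp3 <- nls_spec(3L, y ~ a * exp(b * x^d),
    function(x, y) {
      a <- ctl_mean(x, y)
      if (abs(a) < 1e-8) a <- mean(y) + 1e-8
      b <- if (top_mean(x, y) / a > 0)
        log(top_mean(x, y) / a) / max(x) else 0
      list(a = a, b = b, d = 1)
    },
    lower = c(-Inf, -Inf, 0.1), upper = c(Inf, Inf, 8))
  specs$exp3$pred <- function(b, x) b[1] * exp(b[2] * x^b[3])

  specs$exp4 <- nls_spec(3L, y ~ a * (cc - (cc - 1) * exp(-b * x)),
    function(x, y) {
      a <- ctl_mean(x, y)
      if (abs(a) < 1e-8) a <- mean(y) + 1e-8
      list(a = a, cc = max(top_mean(x, y) / a, 1.01),
           b = 1 / max(median(x[x > 0]), 1e-8))
    },
    lower = c(-Inf, 1e-8, 1e-12), upper = c(Inf, Inf, Inf))
  specs$exp4$pred <- function(b, x) b[1] * (b[2] - (b[2] - 1) * exp(-b[3] * x))

  specs$exp5 <- nls_spec(4L, y ~ a * (cc - (cc - 1) * exp(-(b * x)^d)),
    function(x, y) {
      a <- ctl_mean(x, y)
      if (abs(a) < 1e-8) a <- mean(y) + 1e-8
      list(a = a, cc = max(top_mean(x, y) / a, 1.01),
           b = 1 / max(median(x[x > 0]), 1e-8), d = 1)
    },
    lower = c(-Inf, 1e-8, 1e-12, 1), upper = c(Inf, Inf, Inf, 8))
  specs$exp5$pred <- function(b, x)
    b[1] * (b[2] - (b[2] - 1) * exp(-(b[3] * x)^b[4]))

  specs
}

# Smallest x > 0 at which |f(x) - f(0)| reaches bmr; NA when the response
# never departs that far within (0, 10 * highest concentration].
solve_bmc <- function(pred, coefs, bmr, conc) {
  f0 <- pred(coefs, 0)
  hi <- max(conc) * 10
  lo <- min(conc[conc > 0]) / 1e4
  g <- function(x) abs(pred(coefs, x) - f0) - bmr
  xs <- exp(seq(log(lo), log(hi), length.out = 400))
  gx <- vapply(xs, g, numeric(1))
  if (!is.finite(bmr) || bmr <= 0) return(NA_real_)
  idx <- which(gx >= 0)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(xs[1])
  uniroot(g, c(xs[i - 1L], xs[i]), tol = min(conc[conc > 0]) * 1e-9)$root
}

# Wald interval on log(BMC) by the delta method: numeric gradient of the
# BMC in the fitted coefficients times their covariance.
bmc_wald_bounds <- function(pred, coefs, vc, bmr, conc, bmc, level = 0.95) {
  if (is.null(vc) || is.na(bmc)) return(c(NA_real_, NA_real_))
  h <- pmax(abs(coefs), 1) * 1e-5
  grad <- numeric(length(coefs))
  for (i in seq_along(coefs)) {
    cp <- coefs; cp[i] <- cp[i] + h[i]
    b2 <- tryCatch(solve_bmc(pred, cp, bmr, conc), error = function(e) NA)
    if (is.na(b2)) return(c(NA_real_, NA_real_))
    grad[i] <- (b2 - bmc) / h[i]
  }
  v <- drop(t(grad) %*% vc %*% grad)
  if (!is.finite(v) || v < 0) return(c(NA_real_, NA_real_))
  se_log <- sqrt(v) / bmc
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(bmc * exp(-z * se_log), bmc * exp(z * se_log))
}

#' Fit the dose-response model suite to one gene
#'
#' Fits each model by least squares under constant variance and derives,
#' per converged model: the benchmark concentration (BMC) at which the
#' predicted mean departs from the modeled control mean by
#' `bmr_factor` x residual SD (BMR of 1 SD by default); Wald 95% bounds
#' BMCL/BMCU on the log-BMC scale; a lack-of-fit p-value against the
#' saturated group-means model; and AIC. The winning model is the converged
#' fit with the lowest AIC.
#'
#' @param y Response per sample (e.g. `log2(normalized + 1)`).
#' @param conc Concentration per sample (0 = control).
#' @param bmr_factor Benchmark response in residual-SD units (default 1).
#' @param sigma Optional fixed residual SD overriding the per-model
#'   estimate (used e.g. on noiseless constructed data).
#' @param models Subset of model names to fit.
#' @return data.frame, one row per attempted model: `model`, `converged`,
#'   `npar`, `rss`, `aic`, `fit_p`, `bmc`, `bmcl`, `bmcu`, `winning`.
#' @export
fit_bmc_models <- function(y, conc, bmr_factor = 1, sigma = NULL,
                           models = names(bmc_model_specs())) {
  stopifnot(length(y) == length(conc), all(conc >= 0))
  specs <- bmc_model_specs()[models]
  n <- length(y)
  grp <- factor(conc)
  sse_pe <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
  df_pe <- n - nlevels(grp)
  rows <- lapply(names(specs), function(mn) {
    sp <- specs[[mn]]
    fit <- tryCatch(suppressWarnings(sp$fit(conc, y)),
                    error = function(e) NULL)
    out <- data.frame(model = mn, converged = FALSE, npar = sp$npar,
                      rss = NA_real_, aic = NA_real_, fit_p = NA_real_,
                      bmc = NA_real_, bmcl = NA_real_, bmcu = NA_real_,
                      winning = FALSE, stringsAsFactors = FALSE)
    if (is.null(fit) || n <= sp$npar) return(out)
    rss <- fit$rss
    sig_hat <- if (!is.null(sigma)) sigma else sqrt(rss / (n - sp$npar))
    out$converged <- TRUE
    out$rss <- rss
    out$aic <- n * log(max(rss, 1e-300) / n) + 2 * (sp$npar + 1)
    ss_lof <- max(rss - sse_pe, 0)
    df_lof <- nlevels(grp) - sp$npar
    out$fit_p <- if (df_lof <= 0) 1
      else if (sse_pe <= 1e-12) (if (ss_lof <= 1e-10) 1 else 0)
      else pf((ss_lof / df_lof) / (sse_pe / df_pe), df_lof, df_pe,
              lower.tail = FALSE)
    bmr <- bmr_factor * sig_hat
    bmc <- tryCatch(solve_bmc(sp$pred, fit$coef, bmr, conc),
                    error = function(e) NA_real_)
    out$bmc <- bmc
    if (!is.na(bmc)) {
      bb <- bmc_wald_bounds(sp$pred, fit$coef, fit$vcov, bmr, conc, bmc)
      out$bmcl <- bb[1]
      out$bmcu <- bb[2]
    }
    out
  })
  res <- do.call(rbind, rows)
  conv <- which(res$converged)
  if (length(conv)) {
    res$winning[conv[which.min(res$aic[conv])]] <- TRUE
  }
  rownames(res) <- NULL
  res
}

#' Apply the benchmark concentration filters
#'
#' Assigns each winning fit a status (first matching rule wins):
#' `poor_fit` when the winning model's lack-of-fit p-value is below
#' `fit_p_min` (genes with fit p >= 0.1 are retained) or no finite BMC
#' exists; `below_range` when the BMC is more than 10-fold below the lowest
#' tested concentration; `above_range` when it exceeds the highest;
#' `wide_ci` (only when `apply_ci_filter`) when BMC/BMCL > 20,
#' BMCU/BMC > 20, or BMCU/BMCL > 40, or when the bounds are unavailable;
#' otherwise `pass`.
#'
#' @param fits data.frame of winning fits with columns `bmc`, `bmcl`,
#'   `bmcu`, `fit_p` (one row per gene; see [bmc_genewise()]).
#' @param conc Concentration grid tested (positive values).
#' @param fit_p_min Minimum lack-of-fit p to retain (default 0.1).
#' @param apply_ci_filter Apply the confidence-interval ratio rules
#'   (used for functional classification).
#' @return `fits` with a `filter_status` column appended.
#' @export
filter_bmc <- function(fits, conc, fit_p_min = 0.1, apply_ci_filter = TRUE) {
  lo <- min(conc[conc > 0])
  hi <- max(conc)
  status <- character(nrow(fits))
  for (i in seq_len(nrow(fits))) {
    b <- fits$bmc[i]
    if (is.na(b) || is.na(fits$fit_p[i]) || fits$fit_p[i] < fit_p_min) {
      status[i] <- "poor_fit"
    } else if (b < lo / 10) {
      status[i] <- "below_range"
    } else if (b > hi) {
      status[i] <- "above_range"
    } else if (apply_ci_filter &&
               (is.na(fits$bmcl[i]) || is.na(fits$bmcu[i]) ||
                b / fits$bmcl[i] > 20 || fits$bmcu[i] / b > 20 ||
                fits$bmcu[i] / fits$bmcl[i] > 40)) {
      status[i] <- "wide_ci"
    } else {
      status[i] <- "pass"
    }
  }
  fits$filter_status <- status
  fits
}

#' Pathway-level functional classification of concentration-responsive genes
#'
#' For each gene set, a two-tailed Fisher's exact test of passing genes in
#' the set versus the measured universe; sets with p < `p_cut` (default
#' 0.1) are reported with the median BMC over their passing genes. Sets
#' containing no passing gene are omitted.
#'
#' @param fits Filtered fits with `gene_id`, `bmc`, `filter_status`.
#' @param gene_sets Named list of gene-id vectors.
#' @param universe Measured gene ids.
#' @param p_cut Reporting threshold on the two-tailed Fisher p.
#' @return data.frame `set_name`, `n_genes`, `fisher_two_tail_p`,
#'   `median_bmc`, sorted by p.
#' @export
pathway_classification <- function(fits, gene_sets, universe, p_cut = 0.1) {
  passing <- fits[fits$filter_status == "pass", , drop = FALSE]
  rows <- lapply(names(gene_sets), function(sn) {
    set <- intersect(gene_sets[[sn]], universe)
    in_set <- passing$gene_id %in% set
    a <- sum(in_set)
    if (a == 0L) return(NULL)
    b <- nrow(passing) - a
    cc <- length(set) - a
    d <- length(universe) - length(set) - b
    p <- fisher.test(matrix(c(a, b, cc, d), 2))$p.value
    data.frame(set_name = sn, n_genes = a, fisher_two_tail_p = p,
               median_bmc = median(passing$bmc[in_set]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(set_name = character(),
                                      n_genes = integer(),
                                      fisher_two_tail_p = numeric(),
                                      median_bmc = numeric()))
  out <- out[out$fisher_two_tail_p < p_cut, , drop = FALSE]
  out <- out[order(out$fisher_two_tail_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Accumulation data for median pathway BMCs
#'
#' Sorted median BMCs with cumulative rank, ready for accumulation plots.
#'
#' @param pathways Result of [pathway_classification()].
#' @return data.frame `set_name`, `median_bmc`, `cumulative_rank`.
#' @export
bmc_accumulation <- function(pathways) {
  o <- order(pathways$median_bmc)
  data.frame(set_name = pathways$set_name[o],
             median_bmc = pathways$median_bmc[o],
             cumulative_rank = seq_along(o),
             stringsAsFactors = FALSE)
}

#' Gene-wise BMC analysis for one chemical series
#'
#' Convenience wrapper: Williams trend prefilter on all genes, then the
#' model suite on retained genes, returning the winning fits.
#'
#' @param expr Genes x samples matrix (controls plus one chemical's
#'   concentration series).
#' @param conc Concentration per sample (0 = control).
#' @param trend_alpha Williams prefilter threshold.
#' @param n_perm Permutations for the prefilter.
#' @param seed Seed for the prefilter permutations.
#' @param bmr_factor Benchmark response in residual-SD units.
#' @return data.frame of winning fits, one row per retained gene
#'   (`gene_id`, `model`, `rss`, `aic`, `fit_p`, `bmc`, `bmcl`, `bmcu`).
#' @export
bmc_genewise <- function(expr, conc, trend_alpha = 0.05, n_perm = 2000L,
                         seed = 1L, bmr_factor = 1) {
  trend <- williams_trend_filter(expr, conc, alpha = trend_alpha,
                                 n_perm = n_perm, seed = seed)
  keep <- trend$gene_id[trend$pass]
  rows <- lapply(keep, function(g) {
    fits <- fit_bmc_models(expr[g, ], conc, bmr_factor = bmr_factor)
    w <- fits[fits$winning, , drop = FALSE]
    if (nrow(w) == 0L)
      return(data.frame(gene_id = g, model = NA_character_, rss = NA_real_,
                        aic = NA_real_, fit_p = NA_real_, bmc = NA_real_,
                        bmcl = NA_real_, bmcu = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(gene_id = g, model = w$model, rss = w$rss, aic = w$aic,
               fit_p = w$fit_p, bmc = w$bmc, bmcl = w$bmcl, bmcu = w$bmcu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), model = character(),
                      rss = numeric(), aic = numeric(), fit_p = numeric(),
                      bmc = numeric(), bmcl = numeric(), bmcu = numeric())
  rownames(out) <- NULL
  out
}
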