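#' Build the model matrix for a replicate-matched RIP-seq design
#'
#' Constructs `model.matrix(design)` with `replicate` and `assay` as
#' factors (assay reference level `Input` when present). Columns that
#' are not estimable — e.g. a replicate level observed in no remaining
#' sample after an IgG library dropped out — are removed by QR pivoting
#' so the returned matrix is full rank.
#'
#' @param samples sample sheet with at least the variables named in
#'   `design`.
#' @param design model formula, default `~ replicate + assay`. The
#'   `replicate` term pairs the Input, specific-IP and IgG libraries
#'   made from the same lysate, absorbing batch noise.
#' @return numeric model matrix with full column rank; dropped columns
#'   (if any) are recorded in attribute `dropped`.
#' @export
design_matrix <- function(samples, design = ~ replicate + assay) {
  df <- as.data.frame(samples)
  if ("replicate" %in% all.vars(design))
    df$replicate <- factor(df$replicate)
  if ("assay" %in% all.vars(design)) {
    lev <- unique(df$assay)
    lev <- c(intersect("Input", lev), setdiff(lev, "Input"))
    df$assay <- factor(df$assay, levels = lev)
  }
  X <- model.matrix(design, data = df)
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[seq(qx$rank + 1L, ncol(X))]
    dropped <- colnames(X)[drop_idx]
    X <- X[, -drop_idx, drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

# NB deviance per gene (rows of Y/mu), dispersion alpha per gene
nb_deviance <- function(Y, mu, alpha) {
  t1 <- ifelse(Y > 0, Y * log(Y / mu), 0)
  a <- matrix(alpha, nrow(Y), ncol(Y))
  t2 <- (Y + 1 / a) * log((1 + a * Y) / (1 + a * mu))
  2 * rowSums(t1 - t2)
}

#' Fit negative-binomial log-linear GLMs to all genes at once
#'
#' Iteratively reweighted least squares for the NB GLM with log link,
#' per-sample offsets `log(sf)`, a design matrix shared by all genes,
#' and a fixed per-gene dispersion. Vectorised across genes: each IRLS
#' step forms every gene's weighted normal equations with two matrix
#' products and solves the small per-gene systems.
#'
#' @param counts count matrix, genes x samples.
#' @param X design matrix (samples x coefficients), e.g. from
#'   [design_matrix()].
#' @param sf per-sample size factors (offsets are `log(sf)`).
#' @param dispersion per-gene NB dispersion (recycled if scalar).
#' @param tol relative deviance change declaring convergence.
#' @param max_iter iteration cap; genes not converged by then are
#'   flagged but retained.
#' @return object of class `nb_fit`: list with `beta` (natural-log
#'   coefficients, genes x coefficients), `info` (genes x p^2 rows of
#'   the Fisher information X'WX), `mu` (fitted means), `converged`,
#'   `coef_names`, `deviance`.
#' @export
nb_fit <- function(counts, X, sf = rep(1, ncol(counts)),
                   dispersion = 0.1, tol = 1e-8, max_iter = 100L) {
  Y <- as.matrix(counts)
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  if (length(sf) != n) stop("one size factor per sample required")
  alpha <- rep_len(dispersion, G)
  O <- matrix(log(sf), G, n, byrow = TRUE)

  # pairwise column products of X, for vectorised X'WX across genes
  P <- matrix(0, n, p * p)
  for (j in seq_len(p)) for (k in seq_len(p))
    P[, (j - 1L) * p + k] <- X[, j] * X[, k]

  mu <- pmax(Y, 0.5)
  eta <- log(mu) # includes offset
  beta <- matrix(0, G, p)
  dev <- nb_deviance(Y, mu, alpha)
  converged <- rep(FALSE, G)
  A <- NULL

  for (it in seq_len(max_iter)) {
    W <- mu / (1 + alpha * mu)
    z <- (eta - O) + (Y - mu) / mu
    A <- W %*% P            # G x p^2
    B <- (W * z) %*% X      # G x p
    for (g in which(!converged)) {
      Ag <- matrix(A[g, ], p, p)
      bg <- tryCatch(solve(Ag, B[g, ]), error = function(e) beta[g, ])
      if (all(is.finite(bg))) beta[g, ] <- pmin(pmax(bg, -30), 30)
    }
    eta <- pmin(O + beta %*% t(X), 30)
    mu <- pmax(exp(eta), 1e-8)
    dev_new <- nb_deviance(Y, mu, alpha)
    rel <- abs(dev_new - dev) / (abs(dev) + 0.1)
    converged <- converged | rel < tol
    dev <- dev_new
    if (all(converged)) break
  }
  # final information matrices at the converged fit
  W <- mu / (1 + alpha * mu)
  A <- W %*% P

  structure(list(beta = beta, info = A, mu = mu, dispersion = alpha,
                 converged = converged, coef_names = colnames(X),
                 p = p, deviance = dev,
                 gene_ids = rownames(Y)),
            class = "nb_fit")
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Gene-wise dispersions maximise the Cox-Reid adjusted profile
#' likelihood (penalty `-0.5 log det X'WX`) on a log-spaced grid over
#' `[1e-8, 10]` with parabolic refinement, holding the fitted means from
#' an initial moderate-dispersion fit. A log-linear mean-dispersion
#' trend (`log alpha ~ log mean`) is then fit to the interior gene-wise
#' estimates, and each gene's final dispersion shrinks toward the trend
#' on the log scale, weighting the gene-wise estimate by its residual
#' degrees of freedom. Gene-wise estimates far above the trend are kept
#' unshrunk (dispersion outliers).
#'
#' @param counts count matrix, genes x samples.
#' @param sf per-sample size factors.
#' @param X design matrix.
#' @param prior_weight weight of the trend in the log-scale shrinkage
#'   (in the same units as `rdf / 2`).
#' @param alpha_range admissible dispersion range.
#' @return list with `dispersion` (final, NA for untestable genes),
#'   `genewise`, `trend`, `base_mean`, `untestable` (all-zero genes).
#' @export
estimate_dispersions <- function(counts, sf = rep(1, ncol(counts)),
                                 X, prior_weight = 8,
                                 alpha_range = c(1e-8, 10)) {
  Y <- as.matrix(counts)
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  rdf <- n - p
  if (rdf < 1L) stop("design leaves no residual degrees of freedom")
  untestable <- rowSums(Y) == 0
  base_mean <- rowMeans(sweep(Y, 2L, sf, "/"))

  Yt <- Y[!untestable, , drop = FALSE]
  fit0 <- nb_fit(Yt, X, sf, dispersion = 0.1, max_iter = 30L)
  mu <- fit0$mu

  P <- matrix(0, n, p * p)
  for (j in seq_len(p)) for (k in seq_len(p))
    P[, (j - 1L) * p + k] <- X[, j] * X[, k]

  grid <- exp(seq(log(alpha_range[1]), log(alpha_range[2]), length.out = 40L))
  Gt <- nrow(Yt)
  ll <- matrix(-Inf, Gt, length(grid))
  for (i in seq_along(grid)) {
    a <- grid[i]
    lik <- rowSums(dnbinom(Yt, size = 1 / a, mu = mu, log = TRUE))
    W <- mu / (1 + a * mu)
    A <- W %*% P
    logdet <- numeric(Gt)
    for (g in seq_len(Gt)) {
      d <- determinant(matrix(A[g, ], p, p), logarithm = TRUE)
      logdet[g] <- as.numeric(d$modulus)
    }
    ll[, i] <- lik - 0.5 * logdet
  }
  best <- max.col(ll, ties.method = "first")
  lg <- log(grid)
  genewise_t <- grid[best]
  # parabolic refinement in log space where the max is interior
  interior <- best > 1L & best < length(grid)
  if (any(interior)) {
    gi <- which(interior)
    i0 <- best[gi]
    y1 <- ll[cbind(gi, i0 - 1L)]; y2 <- ll[cbind(gi, i0)]; y3 <- ll[cbind(gi, i0 + 1L)]
    h <- lg[2] - lg[1]
    denom <- y1 - 2 * y2 + y3
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y1 - y3) / denom, 0)
    shift <- pmin(pmax(shift, -1), 1)
    genewise_t[gi] <- exp(lg[i0] + shift * h)
  }

  genewise <- rep(NA_real_, G)
  genewise[!untestable] <- genewise_t

  # parametric mean-dispersion trend alpha(mu) = a0 + a1 / mu, fit on the
  # natural scale (gamma GLM), where the CR-adjusted gene-wise estimates
  # are approximately mean-unbiased; one outlier-exclusion refit
  bm_t <- base_mean[!untestable]
  trend_t <- fit_dispersion_trend(genewise_t, bm_t, alpha_range)

  # log-scale shrinkage toward the trend; keep far-above outliers
  w_g <- rdf / 2
  log_shrunk <- (w_g * log(genewise_t) + prior_weight * log(trend_t)) /
    (w_g + prior_weight)
  resid <- log(genewise_t) - log(trend_t)
  s <- max(stats::mad(resid), 0.25)
  final_t <- ifelse(resid > 2 * s & genewise_t > 1e-4,
                    genewise_t, exp(log_shrunk))
  final_t <- pmin(pmax(final_t, alpha_range[1]), alpha_range[2])

  trend <- rep(NA_real_, G); trend[!untestable] <- trend_t
  final <- rep(NA_real_, G); final[!untestable] <- final_t
  list(dispersion = final, genewise = genewise, trend = trend,
       base_mean = base_mean, untestable = untestable)
}

# alpha(mu) = a0 + a1/mu fit by gamma GLM with identity link on the
# informative genes, with one round of outlier exclusion; falls back to
# a trimmed mean when the GLM cannot be fit (e.g. near-Poisson data
# piling up at the lower dispersion bound)
fit_dispersion_trend <- function(genewise, base_mean, alpha_range) {
  use <- base_mean > 1 & genewise > alpha_range[1] * 3
  fallback <- function() {
    rep(max(mean(genewise, trim = 0.05), alpha_range[1]), length(genewise))
  }
  if (sum(use) < 50) return(pmin(fallback(), alpha_range[2]))
  trend <- NULL
  for (pass in 1:2) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        genewise[use] ~ I(1 / base_mean[use]),
        family = stats::Gamma(link = "identity"),
        start = c(stats::median(genewise[use]), 1)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || any(!is.finite(coef(fit)))) return(pmin(fallback(), alpha_range[2]))
    a <- coef(fit)
    trend <- pmax(a[1] + a[2] / base_mean, alpha_range[1])
    # exclude strong outliers and refit once
    use <- use & genewise < 10 * trend & genewise > trend / 100
    if (sum(use) < 50) break
  }
  pmin(trend, alpha_range[2])
}

#' Wald test of a linear contrast of GLM coefficients
#'
#' Reports the contrast on the log2 scale with its standard error from
#' the inverse Fisher information, the Wald statistic, and a two-sided
#' p-value from the standard normal reference
#' (`p = 2 * pnorm(-|log2fc / se|)`).
#'
#' @param fit an [nb_fit()] object.
#' @param contrast numeric contrast vector over `fit$coef_names`, or a
#'   character `c(factor, levelA, levelB)` triple resolved against the
#'   coefficient names (treatment coding; `levelA` is the numerator).
#' @return data frame `gene_id`, `log2fc`, `se`, `stat`, `p`.
#' @export
wald_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "nb_fit"))
  v <- resolve_contrast(contrast, fit$coef_names)
  p <- fit$p
  G <- nrow(fit$beta)
  lfc_ln <- as.numeric(fit$beta %*% v)
  var_ln <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    Ag <- matrix(fit$info[g, ], p, p)
    var_ln[g] <- tryCatch(drop(t(v) %*% solve(Ag, v)), error = function(e) NA_real_)
  }
  var_ln[!is.na(var_ln) & var_ln < 0] <- NA_real_
  log2fc <- lfc_ln / log(2)
  se <- sqrt(var_ln) / log(2)
  zero_se <- !is.na(se) & se == 0
  if (any(zero_se & log2fc != 0)) {
    warning("zero standard error with non-zero contrast for ",
            sum(zero_se & log2fc != 0), " gene(s); p set to 0")
  }
  stat <- ifelse(zero_se, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                 log2fc / se)
  pval <- 2 * pnorm(-abs(stat))
  pval[log2fc == 0] <- 1
  data.frame(gene_id = fit$gene_ids %||% seq_len(G),
             log2fc = log2fc, se = se, stat = stat, p = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_contrast <- function(contrast, coef_names) {
  if (is.numeric(contrast)) {
    if (length(contrast) != length(coef_names))
      stop("numeric contrast must have one entry per coefficient")
    return(as.numeric(contrast))
  }
  if (!is.character(contrast) || length(contrast) != 3L)
    stop("contrast must be numeric or c(factor, levelA, levelB)")
  fac <- contrast[1]
  v <- numeric(length(coef_names))
  for (i in 2:3) {
    nm <- paste0(fac, contrast[i])
    sign <- if (i == 2L) 1 else -1
    hit <- which(coef_names == nm)
    if (length(hit) == 1L) {
      v[hit] <- v[hit] + sign
    } # reference level contributes 0; a truly unknown level is caught below
  }
  if (all(v == 0))
    stop("contrast ", paste(contrast, collapse = ":"),
         " is not estimable in this design")
  v
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across the supplied p-values; `NA` entries
#' (untestable genes) are left `NA` and do not count toward the number
#' of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene NB Wald test of an assay contrast
#'
#' The module's one-call interface: estimates size factors (unless
#' given), optionally applies the specific-IP scaling, estimates
#' trend-shrunken dispersions, fits the NB GLM with the replicate-
#' matched design, and reports the Wald contrast with BH adjustment.
#'
#' @param counts count matrix, genes x samples (columns must match
#'   `samples$sample_id`).
#' @param samples sample sheet (`sample_id`, `assay`, `replicate`, ...).
#' @param contrast `c("assay", levelA, levelB)` or a numeric contrast.
#' @param design model formula, default `~ replicate + assay`.
#' @param sf optional size factors; computed by [size_factors()] when
#'   `NULL`.
#' @param ip_scale multiplier applied to specific-IP size factors via
#'   [scale_ip_factors()] (1 = no scaling).
#' @param prior_weight passed to [estimate_dispersions()].
#' @return data frame `gene_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p`, `padj` (NA rows for untestable genes).
#' @export
nb_test <- function(counts, samples, contrast,
                    design = ~ replicate + assay, sf = NULL,
                    ip_scale = 1, prior_weight = 8) {
  counts <- as.matrix(counts)
  if (!identical(colnames(counts), samples$sample_id)) {
    if (!all(samples$sample_id %in% colnames(counts)))
      stop("count columns do not match the sample sheet")
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  if (is.null(sf)) sf <- size_factors(counts)
  if (ip_scale != 1) sf <- scale_ip_factors(sf, samples, scale = ip_scale)
  X <- design_matrix(samples, design)

  disp <- estimate_dispersions(counts, sf, X, prior_weight = prior_weight)
  testable <- !disp$untestable
  fit <- nb_fit(counts[testable, , drop = FALSE], X, sf,
                dispersion = disp$dispersion[testable])
  wt <- wald_contrast(fit, contrast)

  out <- data.frame(gene_id = rownames(counts),
                    base_mean = disp$base_mean,
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$log2fc[testable] <- wt$log2fc
  out$se[testable] <- wt$se
  out$stat[testable] <- wt$stat
  out$p[testable] <- wt$p
  out$padj <- adjust_bh(out$p)
  out
}
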