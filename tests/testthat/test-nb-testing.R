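test_that("design matrix drops unestimable columns and stays full rank", {
  s <- two_group_samples()
  X <- design_matrix(s)
  expect_equal(qr(X)$rank, ncol(X))
  # an IgG library missing from one replicate keeps the design estimable
  s3 <- data.frame(
    sample_id = paste0("s", 1:8),
    assay = c("Input", "TIA1_IP", "IgG_IP")[c(1, 2, 3, 1, 2, 3, 1, 2)],
    replicate = c(1, 1, 1, 2, 2, 2, 3, 3),
    stringsAsFactors = FALSE
  )
  X3 <- design_matrix(s3)
  expect_equal(qr(X3)$rank, ncol(X3))
  expect_equal(nrow(X3), 8)
})

test_that("saturated two-group fits recover the ratio of group means exactly", {
  s <- two_group_samples()
  Y <- rbind(g1 = c(100, 100, 100, 400, 400, 400),
             g2 = c(70, 70, 70, 70, 70, 70))
  X <- design_matrix(s, ~ assay)
  fit <- nb_fit(Y, X, sf = rep(1, 6), dispersion = 0.1)
  w <- wald_contrast(fit, c("assay", "TIA1_IP", "Input"))
  expect_equal(w$log2fc[1], 2, tolerance = 1e-6)
  expect_equal(w$log2fc[2], 0, tolerance = 1e-8)
  expect_equal(w$p[2], 1)

  # random balanced design: log2fc equals log2 ratio of group means
  set.seed(9)
  Yr <- matrix(rnbinom(60, mu = 80, size = 10), nrow = 10)
  rownames(Yr) <- paste0("g", 1:10)
  fr <- nb_fit(Yr, X, sf = rep(1, 6), dispersion = 0.2)
  wr <- wald_contrast(fr, c("assay", "TIA1_IP", "Input"))
  want <- log2(rowMeans(Yr[, 4:6]) / rowMeans(Yr[, 1:3]))
  expect_equal(wr$log2fc, unname(want), tolerance = 1e-6)
})

test_that("GLM coefficients match a generic ML optimizer on the same likelihood", {
  set.seed(14)
  s <- two_group_samples()
  X <- design_matrix(s, ~ assay)
  sf <- c(0.8, 1.0, 1.2, 0.9, 1.1, 1.0)
  alpha <- 0.15
  y <- rnbinom(6, mu = c(50, 50, 50, 150, 150, 150) * sf, size = 1 / alpha)
  Y <- matrix(y, nrow = 1, dimnames = list("g1", s$sample_id))
  fit <- nb_fit(Y, X, sf = sf, dispersion = alpha)
  nll <- function(beta) {
    mu <- exp(log(sf) + as.numeric(X %*% beta))
    -sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  opt <- optim(c(log(mean(y)), 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(as.numeric(fit$beta), opt$par, tolerance = 1e-4)
})

test_that("Wald p-values follow the two-sided normal reference", {
  s <- two_group_samples()
  X <- design_matrix(s, ~ assay)
  Y <- matrix(rnbinom(6 * 5, mu = 100, size = 10), nrow = 5,
              dimnames = list(paste0("g", 1:5), s$sample_id))
  set.seed(3)
  fit <- nb_fit(Y, X, sf = rep(1, 6), dispersion = 0.1)
  w <- wald_contrast(fit, c("assay", "TIA1_IP", "Input"))
  expect_equal(w$p, 2 * pnorm(-abs(w$log2fc / w$se)), tolerance = 1e-12)
  # z = 1.959964 corresponds to p = 0.05 (standard-table oracle)
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
  # sign flip of the contrast negates log2fc, keeps p
  wflip <- wald_contrast(fit, c("assay", "Input", "TIA1_IP"))
  expect_equal(wflip$log2fc, -w$log2fc)
  expect_equal(wflip$p, w$p)
})

test_that("dispersion estimation recovers known truth and flags zero genes", {
  set.seed(20)
  n <- 12
  s <- two_group_samples(6)
  X <- design_matrix(s, ~ assay)
  # Poisson counts (true dispersion 0): median estimate small
  Yp <- matrix(rpois(500 * n, 100), nrow = 500)
  dp <- estimate_dispersions(Yp, rep(1, n), X)
  expect_lt(median(dp$dispersion, na.rm = TRUE), 0.05)
  # NB at dispersion 0.2: median inside [0.1, 0.4]
  Yn <- matrix(rnbinom(500 * n, mu = 100, size = 5), nrow = 500)
  dn <- estimate_dispersions(Yn, rep(1, n), X)
  med <- median(dn$dispersion, na.rm = TRUE)
  expect_gt(med, 0.1); expect_lt(med, 0.4)
  # all-zero gene is untestable
  Yz <- rbind(Yn[1:20, ], zero = 0)
  dz <- estimate_dispersions(Yz, rep(1, n), X)
  expect_true(dz$untestable[21])
  expect_true(is.na(dz$dispersion[21]))
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    expect_equal(adjust_bh(p), oracle_bh(p))
  }
  # NA propagation for untestable genes
  p <- c(0.01, NA, 0.5)
  out <- adjust_bh(p)
  expect_true(is.na(out[2]))
  expect_equal(out[-2], oracle_bh(p[-2]))
})

test_that("null simulation is calibrated and power increases with effect size", {
  set.seed(42)
  G <- 800
  mu <- rlnorm(G, log(300), 1)
  s <- two_group_samples()
  lfcs <- c(0, 0.5, 1, 2)
  rates <- vapply(lfcs, function(l) {
    Y <- cbind(
      matrix(rnbinom(G * 3, mu = rep(mu, 3), size = 10), G, 3),
      matrix(rnbinom(G * 3, mu = rep(mu * 2^l, 3), size = 10), G, 3)
    )
    rownames(Y) <- paste0("g", seq_len(G))
    colnames(Y) <- s$sample_id
    res <- nb_test(Y, s, contrast = c("assay", "TIA1_IP", "Input"),
                   design = ~ assay, sf = rep(1, 6))
    mean(res$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gt(rates[1], 0.02); expect_lt(rates[1], 0.09)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], 0.9)
})

test_that("nb_test agrees with DESeq2 on a planted two-group contrast", {
  set.seed(55)
  G <- 300
  mu <- rlnorm(G, log(300), 0.8)
  lfc <- ifelse(seq_len(G) <= 30, 2, 0)
  s <- two_group_samples()
  Y <- cbind(
    matrix(rnbinom(G * 3, mu = rep(mu, 3), size = 10), G, 3),
    matrix(rnbinom(G * 3, mu = rep(mu * 2^lfc, 3), size = 10), G, 3)
  )
  rownames(Y) <- paste0("g", seq_len(G))
  colnames(Y) <- s$sample_id
  res <- nb_test(Y, s, contrast = c("assay", "TIA1_IP", "Input"),
                 design = ~ assay)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    Y, S4Vectors::DataFrame(assay = factor(s$assay,
                                           levels = c("Input", "TIA1_IP"))),
    ~ assay)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("assay", "TIA1_IP", "Input"))
  # effect estimates agree closely; calls at the standard cutoff agree
  expect_gt(cor(res$log2fc, ref$log2FoldChange, use = "complete.obs"), 0.98)
  both <- !is.na(res$padj) & !is.na(ref$padj)
  agree <- mean((res$padj[both] <= 0.05 & res$log2fc[both] >= 0.58) ==
                  (ref$padj[both] <= 0.05 & ref$log2FoldChange[both] >= 0.58))
  expect_gt(agree, 0.95)
})

test_that("an unknown contrast level is rejected", {
  s <- two_group_samples()
  X <- design_matrix(s, ~ assay)
  Y <- matrix(rpois(12, 50), 2, 6, dimnames = list(c("a", "b"), s$sample_id))
  fit <- nb_fit(Y, X, rep(1, 6), 0.1)
  expect_error(wald_contrast(fit, c("assay", "Bogus1", "Bogus2")),
               "not estimable")
})
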