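test_that("config validation names the offending field", {
  expect_error(simulation_config(fraction_bound = 1.2), "fraction_bound")
  expect_error(simulation_config(igg_yield_ratio = 1.5), "igg_yield_ratio")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(library_size_range = c(2, 1)),
               "library_size_range")
})

test_that("planted truth honours degenerate and stochastic bound fractions", {
  cfg0 <- simulation_config(n_genes = 200, fraction_bound = 0, seed = 3)
  tr0 <- generate_truth(cfg0)
  expect_false(any(tr0$bound))
  expect_true(all(tr0$be_log2_true == 0))

  cfg1 <- simulation_config(n_genes = 200, fraction_bound = 1,
                            be_log2_mean = 2, be_log2_sd = 0, seed = 3)
  tr1 <- generate_truth(cfg1)
  expect_true(all(tr1$bound))
  expect_true(all(tr1$be_log2_true == 2))

  # 99.9% binomial interval computed from the binomial CDF
  cfg <- simulation_config(n_genes = 5000, fraction_bound = 0.1, seed = 1)
  tr <- generate_truth(cfg)
  n_bound <- sum(tr$bound[tr$cell_type == "hESC"])
  lo <- qbinom(5e-4, 5000, 0.1)
  hi <- qbinom(1 - 5e-4, 5000, 0.1)
  expect_gte(n_bound, lo)
  expect_lte(n_bound, hi)
})

test_that("truth holds one record per gene and cell type, zero BE when unbound", {
  cfg <- simulation_config(n_genes = 120, seed = 9)
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr), 120 * 3)
  expect_equal(unname(table(tr$gene_id)), rep(3L, 120), ignore_attr = TRUE)
  expect_true(all(tr$be_log2_true[!tr$bound] == 0))
  expect_true(all(tr$be_log2_true[tr$bound] > 0))
  expect_true(all(tr$baseline_mean > 0))
})

test_that("nested mode yields shrinking, nested target sets", {
  cfg <- simulation_config(n_genes = 2000, nested = TRUE, seed = 5)
  tr <- generate_truth(cfg)
  sets <- lapply(cfg$cell_types, function(ct)
    tr$gene_id[tr$cell_type == ct & tr$bound])
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_lt(length(sets[[3]]), length(sets[[1]]))
})

test_that("PAS annotation respects counts, domains and inter-gene separation", {
  cfg <- simulation_config(n_genes = 3, pas_per_gene = c(1, 1), seed = 2)
  pas <- generate_pas_annotation(cfg)
  expect_equal(nrow(pas), 3)
  expect_equal(length(unique(pas$gene_id)), 3)

  cfg2 <- simulation_config(n_genes = 150, pas_per_gene = c(1, 3), seed = 8)
  pas2 <- generate_pas_annotation(cfg2)
  expect_true(all(pas2$cleavage_position >= 0))
  expect_true(all(pas2$strand %in% c("+", "-")))
  # brute-force pairwise separation check between genes
  for (chrom in unique(pas2$chrom)) {
    for (st in c("+", "-")) {
      sub <- pas2[pas2$chrom == chrom & pas2$strand == st, ]
      if (nrow(sub) < 2) next
      d <- abs(outer(sub$cleavage_position, sub$cleavage_position, "-"))
      cross <- outer(sub$gene_id, sub$gene_id, "!=")
      expect_true(all(d[cross] >= cfg2$pas_min_separation))
    }
  }
})

test_that("simulated counts match their NB means in the Poisson limit", {
  # fixed mean 100, dispersion ~0: sample mean of >=1000 draws within [97, 103]
  cfg <- simulation_config(n_genes = 334, cell_types = "A",
                           fraction_bound = 0, dispersion = 1e-8,
                           replicate_effect_sd = 0,
                           library_size_range = c(1, 1), seed = 4)
  truth <- data.frame(gene_id = sprintf("gene_%05d", 1:334), cell_type = "A",
                      bound = FALSE, be_log2_true = 0, baseline_mean = 100)
  sim <- simulate_counts(cfg, truth)
  input_cols <- sim$samples$sample_id[sim$samples$assay == "Input"]
  draws <- as.numeric(sim$counts[, input_cols])
  expect_gte(length(draws), 1000)
  expect_gt(mean(draws), 97)
  expect_lt(mean(draws), 103)
})

test_that("planted binding efficiency is realised as the IP/Input mean ratio", {
  # be_log2 = 2 and no nuisance effects: ratio near 4 across 200 replicates
  cfg <- simulation_config(n_genes = 1, cell_types = "A", n_replicates = 200,
                           replicate_effect_sd = 0,
                           library_size_range = c(1, 1), seed = 6)
  truth <- data.frame(gene_id = "gene_00001", cell_type = "A", bound = TRUE,
                      be_log2_true = 2, baseline_mean = 500)
  sim <- simulate_counts(cfg, truth)
  ip <- mean(sim$counts[, sim$samples$assay == "TIA1_IP"])
  inp <- mean(sim$counts[, sim$samples$assay == "Input"])
  expect_gt(ip / inp, 3.6)
  expect_lt(ip / inp, 4.4)

  # null construction: no binding anywhere, ratio near the assay factor (1)
  cfg0 <- simulation_config(n_genes = 400, cell_types = "A",
                            fraction_bound = 0, replicate_effect_sd = 0,
                            library_size_range = c(1, 1), seed = 7)
  tr0 <- generate_truth(cfg0)
  sim0 <- simulate_counts(cfg0, tr0)
  r <- mean(sim0$counts[, sim0$samples$assay == "TIA1_IP"]) /
    mean(sim0$counts[, sim0$samples$assay == "Input"])
  expect_gt(r, 0.95); expect_lt(r, 1.05)
  # IgG assay factor is the configured yield ratio
  rg <- mean(sim0$counts[, sim0$samples$assay == "IgG_IP"]) /
    mean(sim0$counts[, sim0$samples$assay == "Input"])
  expect_gt(rg, 0.95 * cfg0$igg_yield_ratio)
  expect_lt(rg, 1.05 * cfg0$igg_yield_ratio)
})

test_that("count marginals track the reported expected means", {
  cfg <- simulation_config(n_genes = 50, cell_types = "A", seed = 12)
  tr <- generate_truth(cfg)
  sim <- simulate_counts(cfg, tr)
  # across genes and samples, observed/expected centred on 1
  ratio <- (sim$counts + 0.5) / (sim$mu + 0.5)
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)
})

test_that("read-end simulation honours duplicate and background contracts", {
  cfg0 <- simulation_config(n_genes = 40, pcr_duplicate_rate = 0,
                            background_fraction = 0, reads_per_sample = 5000,
                            cell_types = "A", seed = 21)
  tr <- generate_truth(cfg0)
  pas <- generate_pas_annotation(cfg0)
  rs <- simulate_read_ends(cfg0, tr, pas, cell_type = "A")
  key <- paste(rs$reads$sample_id, rs$reads$chrom, rs$reads$strand,
               rs$reads$position, rs$reads$umi)
  expect_equal(anyDuplicated(key), 0L)
  # background 0: every read falls inside some window
  win <- build_pas_windows(pas)
  inside <- logical(nrow(rs$reads))
  for (w in seq_len(nrow(win))) {
    hit <- rs$reads$chrom == win$chrom[w] & rs$reads$strand == win$strand[w] &
      rs$reads$position >= win$start[w] & rs$reads$position < win$end[w]
    inside <- inside | hit
  }
  expect_true(all(inside))

  # duplicate rate 0.5: unique fraction ~ 1/(1 + 0.5)
  cfg5 <- simulation_config(n_genes = 40, pcr_duplicate_rate = 0.5,
                            background_fraction = 0, reads_per_sample = 10000,
                            cell_types = "A", seed = 22)
  rs5 <- simulate_read_ends(cfg5, generate_truth(cfg5),
                            generate_pas_annotation(cfg5), cell_type = "A")
  total <- nrow(rs5$reads)
  uniq <- nrow(unique(rs5$reads[, c("sample_id", "chrom", "strand",
                                    "position", "umi")]))
  expect_gt(uniq / total, 1 / 1.5 - 0.02)
  expect_lt(uniq / total, 1 / 1.5 + 0.02)
})

test_that("read path and count path agree on the expected mean structure", {
  # low dispersion and enough genes so group-mean noise sits well below
  # the 5% agreement bound being checked
  cfg <- simulation_config(n_genes = 150, pas_per_gene = c(1, 2),
                           cell_types = "A", replicate_effect_sd = 0,
                           dispersion = 0.02,
                           background_fraction = 0, pcr_duplicate_rate = 0.2,
                           reads_per_sample = 1e5, seed = 31)
  tr <- generate_truth(cfg)
  pas <- generate_pas_annotation(cfg)
  rs <- simulate_read_ends(cfg, tr, pas, cell_type = "A")
  q <- quantify_pas(rs$reads, pas)
  gc <- q$gene_counts[unique(tr$gene_id), ]
  # compare depth-normalised group means against the analytic NB means
  prop_obs <- sweep(gc, 2, colSums(gc), "/")
  assay_fac <- c(Input = 1, TIA1_IP = 1, IgG_IP = cfg$igg_yield_ratio)
  for (a in c("Input", "TIA1_IP", "IgG_IP")) {
    cols <- rs$samples$sample_id[rs$samples$assay == a]
    mu <- tr$baseline_mean * assay_fac[[a]] *
      2^(tr$be_log2_true * (a == "TIA1_IP"))
    prop_exp <- mu / sum(mu)
    obs <- rowMeans(prop_obs[, cols, drop = FALSE])
    # relative difference of group means, bound vs unbound genes
    for (grp in list(tr$bound, !tr$bound)) {
      if (!any(grp)) next
      expect_lt(abs(mean(obs[grp]) / mean(prop_exp[grp]) - 1), 0.05)
    }
  }
})

test_that("ribosomal-engagement table shifts bound genes only", {
  cfg0 <- simulation_config(n_genes = 4000, re_shift_targets = 0, seed = 13)
  tr0 <- generate_truth(cfg0)
  re0 <- simulate_re_table(cfg0, tr0)
  b <- tr0$bound
  expect_lt(abs(mean(re0$re[b]) - mean(re0$re[!b])), 0.15)

  cfg <- simulation_config(n_genes = 4000, re_shift_targets = 0.5, seed = 13)
  re <- simulate_re_table(cfg, tr0)
  diff <- mean(re$re[!b]) - mean(re$re[b])
  expect_gt(diff, 0.35); expect_lt(diff, 0.65)

  # all genes bound: single-group table
  cfg1 <- simulation_config(n_genes = 50, fraction_bound = 1, seed = 2)
  tr1 <- generate_truth(cfg1)
  re1 <- simulate_re_table(cfg1, tr1)
  expect_true(all(tr1$bound))
  expect_equal(nrow(re1), nrow(tr1))
})

test_that("qPCR Ct tables encode abundance, enrichment and noise", {
  cfg <- simulation_config(qpcr_noise_sd = 0, seed = 17)
  # equal template amount in Input and IP => equal Ct
  ct <- simulate_qpcr(cfg, genes = "g", abundance = 100, enrichment = 0.5,
                      input_fraction = 0.1, ip_capture = 0.2)
  # amounts: input 10, IP 100*0.2*0.5 = 10
  expect_equal(mean(ct$ct[ct$assay == "Input"]),
               mean(ct$ct[ct$assay == "TIA1_IP"]), tolerance = 1e-12)
  # IP amount 4x the input-fraction amount => Ct_IP = Ct_input - 2
  ct4 <- simulate_qpcr(cfg, genes = "g", abundance = 100, enrichment = 2,
                       input_fraction = 0.1, ip_capture = 0.2)
  expect_equal(mean(ct4$ct[ct4$assay == "Input"]) -
                 mean(ct4$ct[ct4$assay == "TIA1_IP"]), 2, tolerance = 1e-12)

  # noise sd 0.2, 50 replicates: sample sd inside its 99% chi-square band
  cfgn <- simulation_config(qpcr_noise_sd = 0.2, seed = 18)
  ctn <- simulate_qpcr(cfgn, genes = "g", abundance = 100, enrichment = 1,
                       n_replicates = 50)
  s <- sd(ctn$ct[ctn$assay == "Input"])
  band <- 0.2 * sqrt(qchisq(c(0.005, 0.995), 49) / 49)
  expect_gt(s, band[1]); expect_lt(s, band[2])
})

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_genes = 40, seed = 77)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
  expect_identical(generate_pas_annotation(cfg), generate_pas_annotation(cfg))
  tr <- generate_truth(cfg)
  expect_identical(simulate_counts(cfg, tr), simulate_counts(cfg, tr))
  pas <- generate_pas_annotation(cfg)
  expect_identical(simulate_read_ends(cfg, tr, pas),
                   simulate_read_ends(cfg, tr, pas))
  expect_identical(simulate_re_table(cfg, tr), simulate_re_table(cfg, tr))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
})
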