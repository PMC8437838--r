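#' Plant the ground truth of a synthetic RIP-seq experiment
#'
#' Draws, for every gene and cell type, whether the gene is bound by the
#' protein, its planted log2 binding efficiency (the log2 IP/Input
#' enrichment realised by the count simulator; 0 for unbound genes), and
#' a baseline Input-scale expression mean. With `config$nested = TRUE`
#' bound sets shrink along `config$cell_types`: each cell type's targets
#' are drawn from the previous cell type's targets.
#'
#' @param config a [simulation_config()].
#' @return data frame with one row per (gene, cell type):
#'   `gene_id`, `cell_type`, `bound`, `be_log2_true`, `baseline_mean`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "rip_sim_config"))
  set.seed(sim_seed(config, 0L))
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  cts <- config$cell_types

  bound <- matrix(FALSE, config$n_genes, length(cts), dimnames = list(genes, cts))
  for (i in seq_along(cts)) {
    f <- config$fraction_bound[[i]]
    if (config$nested && i > 1L) {
      prev <- bound[, i - 1L]
      fprev <- config$fraction_bound[[i - 1L]]
      # conditional retention probability so the marginal fraction is f
      p_keep <- if (fprev > 0) min(1, f / fprev) else 0
      bound[, i] <- prev & (runif(config$n_genes) < p_keep)
    } else {
      bound[, i] <- runif(config$n_genes) < f
    }
  }

  out <- do.call(rbind, lapply(seq_along(cts), function(i) {
    b <- bound[, i]
    be <- numeric(config$n_genes)
    if (any(b)) {
      be[b] <- rnorm(sum(b), config$be_log2_mean, config$be_log2_sd)
      # binding efficiencies below the calling floor are not meaningful
      # plants; keep them weak-positive rather than sign-flipped
      be[b] <- pmax(be[b], 0.1)
    }
    data.frame(
      gene_id = genes, cell_type = cts[i], bound = b,
      be_log2_true = be,
      baseline_mean = rlnorm(config$n_genes, config$baseline_meanlog,
                             config$baseline_sdlog),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Generate a polyA-site annotation for the simulated genes
#'
#' Lays polyA sites (PAS) on two synthetic chromosomes. Sites of one gene
#' share a strand; sites of different genes on the same chromosome and
#' strand are separated by at least `config$pas_min_separation` nt so that
#' capture windows never straddle genes (unless
#' `config$allow_overlapping_genes` requests the stress layout).
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `gene_id`, `pas_id`, `chrom`, `strand`,
#'   `cleavage_position` (0-based).
#' @export
generate_pas_annotation <- function(config) {
  stopifnot(inherits(config, "rip_sim_config"))
  set.seed(sim_seed(config, 1L))
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  k <- if (config$pas_per_gene[1] == config$pas_per_gene[2]) {
    rep(config$pas_per_gene[1], config$n_genes)
  } else {
    sample(seq(config$pas_per_gene[1], config$pas_per_gene[2]),
           config$n_genes, replace = TRUE)
  }
  chrom <- paste0("chrSim", 1L + (seq_len(config$n_genes) %% 2L))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)

  sep <- max(config$pas_min_separation, 1L)
  recs <- vector("list", config$n_genes)
  cursor <- c(chrSim1 = 1000L, chrSim2 = 1000L)
  for (g in seq_len(config$n_genes)) {
    if (config$allow_overlapping_genes) {
      pos <- sort(sample.int(1000L + 50L * config$n_genes, k[g])) + 100L
    } else {
      # successive PAS of one gene ~40-80 nt apart; next gene >= sep away
      gaps <- if (k[g] > 1L) sample(40:80, k[g] - 1L, replace = TRUE) else integer(0)
      pos <- cursor[[chrom[g]]] + cumsum(c(0L, gaps))
      cursor[[chrom[g]]] <- pos[k[g]] + sep + sample(0:50, 1L)
    }
    recs[[g]] <- data.frame(
      gene_id = genes[g],
      pas_id = sprintf("%s|pas%d", genes[g], seq_len(k[g])),
      chrom = chrom[g], strand = strand[g],
      cleavage_position = as.integer(pos),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# expected NB mean for every (gene x sample) cell of one cell type.
# mu = baseline * assay_factor * 2^(be * [assay == TIA1_IP])
#      * lysate(replicate) effect * depth
sim_mean_matrix <- function(config, truth_ct, samples_ct, depth, rep_eff) {
  n_genes <- nrow(truth_ct)
  mu <- matrix(0, n_genes, nrow(samples_ct))
  assay_factor <- c(Input = 1, TIA1_IP = 1, IgG_IP = config$igg_yield_ratio)
  for (j in seq_len(nrow(samples_ct))) {
    a <- samples_ct$assay[j]
    r <- samples_ct$replicate[j]
    be_mult <- if (a == "TIA1_IP") 2^truth_ct$be_log2_true else rep(1, n_genes)
    mu[, j] <- truth_ct$baseline_mean * assay_factor[[a]] * be_mult *
      rep_eff[, r] * depth[j]
  }
  mu
}

#' Build the sample sheet of a simulated experiment
#'
#' One row per library: Input, TIA1 IP and IgG IP per replicate lysate
#' and cell type, with IgG libraries possibly missing for the last
#' replicates (as when the control yields too little RNA for library
#' prep).
#'
#' @param config a [simulation_config()].
#' @return data frame with `sample_id`, `cell_type`, `assay`, `replicate`.
#' @export
sample_sheet <- function(config) {
  stopifnot(inherits(config, "rip_sim_config"))
  rows <- list()
  for (ct in config$cell_types) {
    for (r in seq_len(config$n_replicates)) {
      assays <- c("Input", "TIA1_IP")
      if (r <= config$igg_replicates[[ct]]) assays <- c(assays, "IgG_IP")
      for (a in assays) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_rep%d", ct, a, r),
          cell_type = ct, assay = a, replicate = r,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a RIP-seq count matrix (fast path, no reads)
#'
#' Draws NB counts with mean
#' `baseline * assay_factor * 2^(be_log2 for the specific IP) *
#'  replicate_effect * depth` and the configured dispersion. The IgG
#' assay factor is `config$igg_yield_ratio`; the lysate (replicate)
#' effect is gene-wise and shared by the three assays of one lysate,
#' which is what the `~ replicate + assay` design later absorbs.
#'
#' @param config a [simulation_config()].
#' @param truth output of [generate_truth()] for the same config.
#' @return list with `counts` (integer matrix, genes x samples),
#'   `samples` (sample sheet), and `mu` (the expected means).
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "rip_sim_config"))
  set.seed(sim_seed(config, 3L))
  samples <- sample_sheet(config)
  genes <- unique(truth$gene_id)
  n_genes <- length(genes)

  counts <- matrix(0L, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  mu_all <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  size <- 1 / config$dispersion

  for (ct in config$cell_types) {
    truth_ct <- truth[truth$cell_type == ct, ]
    truth_ct <- truth_ct[match(genes, truth_ct$gene_id), ]
    idx <- which(samples$cell_type == ct)
    samples_ct <- samples[idx, ]
    depth <- runif(length(idx), config$library_size_range[1],
                   config$library_size_range[2])
    rep_eff <- matrix(
      rlnorm(n_genes * config$n_replicates, 0, config$replicate_effect_sd),
      n_genes, config$n_replicates
    )
    mu <- sim_mean_matrix(config, truth_ct, samples_ct, depth, rep_eff)
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = size), nrow(mu), ncol(mu))
    counts[, idx] <- cnt
    mu_all[, idx] <- mu
  }
  list(counts = counts, samples = samples, mu = mu_all)
}

random_umis <- function(n, width = 8L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE), n, width)
  apply(m, 1L, paste0, collapse = "")
}

#' Simulate read 3'-end records for one cell type
#'
#' The read-level counterpart of [simulate_counts()]: unique molecule
#' counts per (PAS, sample) are NB draws whose expectation follows the
#' same assay/binding/lysate/depth mean structure (split equally over a
#' gene's polyA sites and rescaled so a sample expects
#' `config$reads_per_sample` unique reads). Read 3' ends fall uniformly
#' inside the -20/+10 capture window; a `background_fraction` of reads
#' falls outside every window; PCR duplicates are injected by repeating
#' a (position, UMI) pair `rpois(pcr_duplicate_rate)` extra times.
#'
#' @param config a [simulation_config()].
#' @param truth output of [generate_truth()].
#' @param pas output of [generate_pas_annotation()].
#' @param cell_type one of `config$cell_types` (reads for one cell type
#'   keep object sizes proportionate; loop to get the full design).
#' @param upstream,downstream capture-window geometry (nt), matching
#'   [build_pas_windows()].
#' @return list with `reads` (data frame `chrom`, `strand`, `position`,
#'   `umi`, `sample_id`, in generation order) and `samples` (the sample
#'   sheet rows covered).
#' @export
simulate_read_ends <- function(config, truth, pas,
                               cell_type = config$cell_types[1],
                               upstream = 20L, downstream = 10L) {
  stopifnot(inherits(config, "rip_sim_config"))
  stopifnot(cell_type %in% config$cell_types)
  set.seed(sim_seed(config, 2L) + match(cell_type, config$cell_types))

  samples <- sample_sheet(config)
  samples <- samples[samples$cell_type == cell_type, ]
  genes <- unique(pas$gene_id)
  truth_ct <- truth[truth$cell_type == cell_type, ]
  truth_ct <- truth_ct[match(genes, truth_ct$gene_id), ]

  depth <- runif(nrow(samples), config$library_size_range[1],
                 config$library_size_range[2])
  rep_eff <- matrix(
    rlnorm(length(genes) * config$n_replicates, 0, config$replicate_effect_sd),
    length(genes), config$n_replicates
  )
  mu_gene <- sim_mean_matrix(config, truth_ct, samples, depth, rep_eff)
  # rescale so each sample expects ~reads_per_sample in-window unique reads
  scale <- config$reads_per_sample * (1 - config$background_fraction) /
    colSums(mu_gene)
  pas_per_gene <- table(pas$gene_id)[genes]
  mu_pas <- mu_gene[match(pas$gene_id, genes), , drop = FALSE] /
    as.numeric(pas_per_gene[match(pas$gene_id, genes)])

  # window spans for in-window placement and background rejection
  win <- build_pas_windows(pas, upstream = upstream, downstream = downstream)
  size <- 1 / config$dispersion
  chrom_max <- max(pas$cleavage_position) + 1000L

  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    m <- rnbinom(nrow(pas), mu = mu_pas[, j] * scale[j], size = size)
    total <- sum(m)
    pi <- rep.int(seq_len(nrow(pas)), m)
    offs <- sample.int(upstream + downstream, total, replace = TRUE) - 1L
    pos <- ifelse(win$strand[pi] == "+",
                  win$start[pi] + offs,
                  win$end[pi] - 1L - offs)
    rd <- data.frame(chrom = win$chrom[pi], strand = win$strand[pi],
                     position = as.integer(pos),
                     umi = random_umis(total),
                     sample_id = samples$sample_id[j],
                     stringsAsFactors = FALSE)
    # off-window background reads
    if (config$background_fraction > 0 && total > 0) {
      nbg <- rpois(1L, total * config$background_fraction /
                         (1 - config$background_fraction))
      if (nbg > 0) {
        bg <- data.frame(
          chrom = sample(unique(pas$chrom), nbg, replace = TRUE),
          strand = sample(c("+", "-"), nbg, replace = TRUE),
          position = sample.int(chrom_max, nbg, replace = TRUE),
          umi = random_umis(nbg),
          sample_id = samples$sample_id[j], stringsAsFactors = FALSE
        )
        # rejection: resample any background read landing in a window
        for (iter in 1:20) {
          hit <- in_any_window(bg, win)
          if (!any(hit)) break
          bg$position[hit] <- sample.int(chrom_max, sum(hit), replace = TRUE)
        }
        bg <- bg[!in_any_window(bg, win), , drop = FALSE]
        rd <- rbind(rd, bg)
      }
    }
    # distinct molecules must carry distinct (position, UMI) keys;
    # resample UMIs of chance collisions so deduplication is lossless
    if (nrow(rd) > 0) {
      key <- paste(rd$chrom, rd$strand, rd$position, rd$umi)
      for (iter in 1:10) {
        dup <- duplicated(key)
        if (!any(dup)) break
        rd$umi[dup] <- random_umis(sum(dup))
        key[dup] <- paste(rd$chrom[dup], rd$strand[dup], rd$position[dup],
                          rd$umi[dup])
      }
    }
    # PCR duplicates: each molecule re-observed rpois(rate) extra times
    if (config$pcr_duplicate_rate > 0 && nrow(rd) > 0) {
      extra <- rpois(nrow(rd), config$pcr_duplicate_rate)
      if (any(extra > 0)) {
        dup <- rd[rep.int(seq_len(nrow(rd)), extra), , drop = FALSE]
        rd <- rbind(rd, dup)
      }
    }
    out[[j]] <- rd
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  list(reads = reads, samples = samples)
}

# logical: does each read fall inside any window (same chrom & strand)?
in_any_window <- function(reads, windows) {
  if (nrow(reads) == 0L) return(logical(0))
  r <- GenomicRanges::GRanges(reads$chrom,
                              IRanges::IRanges(reads$position + 1L, width = 1L),
                              strand = reads$strand)
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L, windows$end),
                              strand = windows$strand)
  GenomicRanges::countOverlaps(r, w, ignore.strand = FALSE) > 0L
}

#' Simulate a ribosomal-engagement table
#'
#' Gaussian log-scale ribosomal-engagement (RE) values per gene and cell
#' type, with bound genes shifted down by `config$re_shift_targets` —
#' the pattern expected when the protein represses translation of its
#' targets.
#'
#' @param config a [simulation_config()].
#' @param truth output of [generate_truth()].
#' @return data frame `gene_id`, `cell_type`, `re`.
#' @export
simulate_re_table <- function(config, truth) {
  stopifnot(inherits(config, "rip_sim_config"))
  set.seed(sim_seed(config, 4L))
  re <- rnorm(nrow(truth), 0, config$re_sd) -
    config$re_shift_targets * as.numeric(truth$bound)
  data.frame(gene_id = truth$gene_id, cell_type = truth$cell_type,
             re = re, stringsAsFactors = FALSE)
}

#' Simulate a qPCR Ct table for RIP validation
#'
#' Ct values follow `baseline_ct - log2(template amount) + noise`. The
#' Input aliquot holds `input_fraction` of the lysate; the specific IP
#' captures `ip_capture` of each gene's molecules times its fold
#' enrichment; the IgG IP captures `ip_capture * igg_yield_ratio`
#' without enrichment. Enriched genes therefore show lower Ct in the
#' specific IP than in the IgG IP.
#'
#' @param config a [simulation_config()] (supplies `qpcr_noise_sd`,
#'   `igg_yield_ratio`, seed).
#' @param genes character vector of gene labels; the last defaults to
#'   the 18S-style unenriched normaliser.
#' @param abundance per-gene template abundance (arbitrary units).
#' @param enrichment per-gene fold enrichment in the specific IP.
#' @param n_replicates technical replicates per (gene, assay).
#' @param input_fraction fraction of the lysate set aside as Input.
#' @param ip_capture capture efficiency of the IP step.
#' @param baseline_ct Ct of one abundance unit.
#' @return data frame `gene`, `assay` (`Input`/`TIA1_IP`/`IgG_IP`),
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(config,
                          genes = c("targetA", "targetB", "rRNA_18S"),
                          abundance = c(1000, 500, 1e6),
                          enrichment = c(4, 4, 1),
                          n_replicates = 3L,
                          input_fraction = 0.1,
                          ip_capture = 0.2,
                          baseline_ct = 30) {
  stopifnot(inherits(config, "rip_sim_config"))
  stopifnot(length(genes) == length(abundance),
            length(genes) == length(enrichment))
  set.seed(sim_seed(config, 5L))
  amounts <- rbind(
    Input = abundance * input_fraction,
    TIA1_IP = abundance * ip_capture * enrichment,
    IgG_IP = abundance * ip_capture * config$igg_yield_ratio
  )
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      assay = rownames(amounts), gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  amt <- amounts[cbind(match(grid$assay, rownames(amounts)),
                       match(grid$gene, genes))]
  data.frame(
    gene = grid$gene, assay = grid$assay, replicate = grid$replicate,
    ct = baseline_ct - log2(amt) + rnorm(nrow(grid), 0, config$qpcr_noise_sd),
    stringsAsFactors = FALSE
  )
}
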