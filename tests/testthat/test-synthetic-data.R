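# The generator is first-class code: its outputs must be deterministic,
# self-consistent with the emitted files, and statistically faithful to
# the model the estimator assumes.

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_genes_x = 0), "positive")
  expect_error(sim_config(xi_fraction_range = c(0.5, 0.3)))
  expect_error(sim_config(mapping_bias_rm = -1))
  expect_error(sim_genome_snps(sim_config(chrom_length_bp = 500)),
               "at least 1000")
})

test_that("genome and SNP table are consistent and deterministic", {
  cfg <- tiny_config(seed = 7, chrom_length_bp = 10000,
                     snp_density_per_bp = 0.01)
  gs <- sim_genome_snps(cfg)
  # ~100 SNPs per chromosome at density 0.01 over 10 kb
  n_x <- sum(gs$snps$chrom == cfg$x_chrom)
  expect_gt(n_x, 60)
  expect_lt(n_x, 140)
  # positions unique, 1-based, in bounds; ref matches the emitted sequence
  for (ch in names(gs$genome)) {
    s <- gs$snps[gs$snps$chrom == ch, ]
    expect_false(any(duplicated(s$pos)))
    expect_true(all(s$pos >= 1 & s$pos <= cfg$chrom_length_bp))
    seq_chars <- strsplit(as.character(gs$genome[[ch]]), "")[[1]]
    expect_identical(seq_chars[s$pos], s$ref)
    expect_true(all(s$ref != s$alt))
  }
  # determinism: identical config => identical tables
  gs2 <- sim_genome_snps(tiny_config(seed = 7, chrom_length_bp = 10000,
                                     snp_density_per_bp = 0.01))
  expect_identical(gs$snps, gs2$snps)
  expect_identical(as.character(gs$genome), as.character(gs2$genome))
  # round trip through the pseudo-genome builder: no mismatch errors, and
  # differences exactly at SNP positions
  pg <- build_pseudo_genome(gs$genome, gs$snps)
  ch <- cfg$x_chrom
  diffs <- which(strsplit(as.character(pg[[ch]]), "")[[1]] !=
                   strsplit(as.character(gs$genome[[ch]]), "")[[1]])
  expect_identical(diffs, gs$snps$pos[gs$snps$chrom == ch])
})

test_that("zero SNP density yields an empty table with a warning", {
  cfg <- tiny_config(snp_density_per_bp = 0, chrom_length_bp = 2000)
  expect_warning(gs <- sim_genome_snps(cfg), "empty SNP table")
  expect_identical(nrow(gs$snps), 0L)
})

test_that("gene models tile without overlap, with both strands and gaps", {
  cfg <- sim_config(seed = 1, n_genes_x = 2, n_genes_autosome = 2,
                    chrom_length_bp = 1e5)
  g <- sim_gene_models(cfg)
  x <- g[g$chrom == cfg$x_chrom, ]
  expect_identical(nrow(x), 2L)
  expect_lt(x$end[1], x$start[2])            # intergenic transition region
  expect_setequal(unique(g$strand), c("+", "-"))
  minus <- g[g$strand == "-", ][1, ]
  expect_identical(minus$tss, minus$end - 1) # TSS at the higher end
  plus <- g[g$strand == "+", ][1, ]
  expect_identical(plus$tss, plus$start)
  # exons inside the gene body
  for (i in seq_len(nrow(g))) {
    st <- as.numeric(strsplit(g$exon_starts[i], ",")[[1]])
    sz <- as.numeric(strsplit(g$exon_sizes[i], ",")[[1]])
    expect_true(all(st >= g$start[i] & st + sz <= g$end[i]))
  }
  expect_identical(g, sim_gene_models(cfg))  # deterministic layout
  expect_error(sim_gene_models(sim_config(n_genes_x = 1000,
                                          chrom_length_bp = 1e5)),
               "cannot fit")
})

test_that("silenced genes produce zero Xi reads in every replicate", {
  cfg <- tiny_config(seed = 2, escape_fraction = 0, mapping_bias_rm = 1)
  sim <- sim_xci_dataset(cfg, genome = FALSE)
  x <- sim$counts[sim$counts$chrom == cfg$x_chrom, ]
  expect_true(all(x$n0 == 0))
  # and with mapping bias: odds-scale distortion keeps p = 0 at zero
  cfg2 <- tiny_config(seed = 2, escape_fraction = 0, mapping_bias_rm = 1.3)
  sim2 <- sim_xci_dataset(cfg2, genome = FALSE)
  expect_true(all(sim2$counts$n0[sim2$counts$chrom == cfg$x_chrom] == 0))
})

test_that("Xi counts are binomial around the true proportion", {
  # mean of n0/n across 50 generator seeds within 3 SE of p = 0.3
  p <- 0.3; n_target <- 10000
  props <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_genes_x = 2, n_genes_autosome = 2,
                      chrom_length_bp = 1e5, escape_fraction = 1,
                      xi_fraction_range = c(p, p), mapping_bias_rm = 1,
                      n_range = c(n_target, n_target), n_replicates = 1)
    sim <- sim_xci_dataset(cfg, genome = FALSE)
    x <- sim$counts[sim$counts$chrom == cfg$x_chrom, ]
    sum(x$n0) / sum(x$n0 + x$n1)
  }, 0)
  se <- sqrt(p * (1 - p) / (50 * 2 * n_target))
  expect_lt(abs(mean(props) - p), 3 * se)
})

test_that("mapping bias planted in autosomal counts is recoverable", {
  cfg <- sim_config(seed = 11, n_genes_x = 20, n_genes_autosome = 150,
                    chrom_length_bp = 2e6, mapping_bias_rm = 1.2)
  sim <- sim_xci_dataset(cfg, genome = FALSE)
  one <- sim$counts[sim$counts$sample == sim$counts$sample[1], ]
  expect_lt(abs(compute_mapping_bias(one, x_chrom = cfg$x_chrom) - 1.2),
            0.02)
})

test_that("estimator closure: corrected CIs cover the true Xi fraction", {
  # >= 97% coverage for genes with n >= 200 and p in [0.05, 0.95]
  cfg <- sim_config(seed = 5, n_genes_x = 500, n_genes_autosome = 100,
                    chrom_length_bp = 2e7, escape_fraction = 1,
                    xi_fraction_range = c(0.05, 0.95),
                    n_range = c(200, 10000), n_replicates = 1,
                    mapping_bias_rm = 1.1)
  sim <- sim_xci_dataset(cfg, genome = FALSE)
  fit <- xci_fit(sim$counts, alpha = 0.01)
  cl <- fit$calls
  truth <- sim$truth$genes
  p_true <- truth$true_xi_fraction[match(cl$gene, truth$gene)]
  keep <- cl$n >= 200
  covered <- p_true[keep] >= cl$ci_lower[keep] &
    p_true[keep] <= cl$ci_upper[keep]
  expect_gte(mean(covered), 0.97)
})

test_that("peak sets are deterministic and clusters carry Xi-skewed counts", {
  cfg <- tiny_config(seed = 9)
  sim <- sim_xci_dataset(cfg, genome = FALSE)
  sim2 <- sim_xci_dataset(tiny_config(seed = 9), genome = FALSE)
  expect_identical(sim$peaks, sim2$peaks)
  pk <- sim$peaks[sim$peaks$chrom == cfg$x_chrom, ]
  inside <- pk$true_preference == "Xi"
  # Xi is the spretus allele by default, so planted peaks are spretus-heavy
  expect_gt(sum(pk$n_sp[inside]) / sum(pk$n_sp[inside] + pk$n_bl[inside]),
            0.8)
  out_frac <- sum(pk$n_sp[!inside]) /
    sum(pk$n_sp[!inside] + pk$n_bl[!inside])
  expect_lt(abs(out_frac - 0.5), 0.05)
  # planted peaks lie inside the truth cluster
  mid <- (pk$start + pk$end) / 2
  expect_true(all(mid[inside] >= sim$truth$clusters$start[1] &
                    mid[inside] <= sim$truth$clusters$end[1]))
})

test_that("written datasets are byte-identical across runs", {
  cfg <- sim_config(seed = 4, n_genes_x = 3, n_genes_autosome = 2,
                    chrom_length_bp = 40000, gene_span_bp = 5000,
                    snp_density_per_bp = 0.005)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_xci_dataset(sim_xci_dataset(cfg), d1)
  p2 <- write_xci_dataset(sim_xci_dataset(cfg), d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
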