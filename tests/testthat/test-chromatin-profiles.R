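# Sliding-window Poisson scan, cluster merging, promoter exclusion,
# co-localization, transitions, and promoter/metagene signal summaries.

test_that("window scan matches brute-force enumeration exactly", {
  set.seed(21)
  L <- 5e6
  mid <- runif(60, 0, L)
  pk <- data.frame(start = mid - 100, end = mid + 100)
  w <- window_density_scan(pk, L)
  b <- brute_scan(mid, L)
  expect_identical(w$peak_count, b$peak_count)
  expect_equal(w$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(attr(w, "lambda"), mean(b$peak_count), tolerance = 1e-12)
  # upper-tail Poisson arithmetic: P(X >= 6 | lambda = 1) ~ 5.94e-4
  p6 <- sum(dpois(6:100, 1))
  expect_equal(ppois(5, 1, lower.tail = FALSE), p6, tolerance = 1e-12)
  expect_lt(p6, 0.01)
})

test_that("zero peaks yield no significant windows, with a warning", {
  expect_warning(w <- window_density_scan(numeric(0), 2e6), "no peaks")
  expect_true(all(w$p_value == 1))
  expect_identical(nrow(merge_significant_windows(w)), 0L)
})

test_that("significant windows merge by overlap and the merge is idempotent", {
  # two significant windows one step apart -> one cluster spanning 501 kb
  w <- data.frame(start = c(0, 1000, 3e6), end = c(5e5, 501000, 3.5e6),
                  p_value = c(0.001, 0.001, 0.5))
  cl <- merge_significant_windows(w, cutoff = 0.01)
  expect_identical(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(0, 501000))
  expect_identical(cl$member_windows, 2L)
  # two significant windows 2 Mb apart -> two clusters
  w2 <- data.frame(start = c(0, 2e6), end = c(5e5, 2.5e6),
                   p_value = c(0.001, 0.002))
  cl2 <- merge_significant_windows(w2, cutoff = 0.01)
  expect_identical(nrow(cl2), 2L)
  expect_true(all(cl2$start[-1] >= cl2$end[-nrow(cl2)]))  # disjoint, sorted
  # idempotence: re-merging the clusters changes nothing
  again <- merge_significant_windows(
    data.frame(start = cl2$start, end = cl2$end, p_value = cl2$min_p),
    cutoff = 0.01)
  expect_equal(again[, c("start", "end")], cl2[, c("start", "end")])
})

test_that("promoter peaks are excluded on inclusive overlap", {
  genes <- data.frame(gene = "g", chrom = "chrX", tss = 10000, strand = "+")
  pks <- data.frame(chrom = "chrX",
                    start = c(9990,   # centred on the TSS
                              15000,  # 5 kb away
                              8001,   # ends 1 bp into the flank: removed
                              8000,   # abuts the flank: kept
                              10999), # overlaps the last flank base: removed
                    end = c(10010, 15200, 9001, 9000, 11100))
  kept <- exclude_promoter_peaks(pks, genes, flank = 1000)
  expect_identical(kept$start, c(15000, 8000))
})

test_that("co-localization equals the hypergeometric closed form", {
  # helper to fabricate gene/cluster geometry matching a 2x2 table:
  # genes at distinct slots; clusters covering the "inside" genes
  make <- function(esc_in, esc_out, bg_in, bg_out) {
    n <- esc_in + esc_out + bg_in + bg_out
    genes <- data.frame(gene = paste0("g", 1:n), chrom = "chrX",
                        start = (1:n) * 1000, end = (1:n) * 1000 + 500)
    esc <- paste0("g", seq_len(esc_in + esc_out))
    inside <- c(seq_len(esc_in), esc_in + esc_out + seq_len(bg_in))
    clusters <- if (length(inside))
      data.frame(chrom = "chrX", start = inside * 1000,
                 end = inside * 1000 + 100)
    else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0))
    list(genes = genes, esc = esc, clusters = clusters)
  }
  # single-term tail: all 6 in-cluster genes are escape genes
  f <- make(6, 8, 0, 403)
  ct <- colocalization_test(f$clusters, f$genes, f$esc)
  expect_identical(unname(ct$table["escape", "inside"]), 6L)
  expect_equal(ct$p_greater, choose(14, 6) / choose(417, 6),
               tolerance = 1e-10)
  # all escape genes in clusters, none of the background: p = 1 / C(55, 5)
  f2 <- make(5, 0, 0, 50)
  ct2 <- colocalization_test(f2$clusters, f2$genes, f2$esc)
  expect_equal(ct2$p_greater, 1 / choose(55, 5), tolerance = 1e-12)
  # identical proportions: odds ratio 1, p = 1
  f3 <- make(2, 2, 2, 2)
  ct3 <- colocalization_test(f3$clusters, f3$genes, f3$esc)
  expect_equal(ct3$p_value, 1)
  expect_error(colocalization_test(f$clusters, f$genes, character(0)),
               "empty escape")

  # exhaustive check against dhyper on small tables
  for (i in 1:25) {
    set.seed(i)
    tab <- matrix(sample(0:8, 4, replace = TRUE) + c(1, 0, 0, 1), 2)
    g <- make(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    got <- colocalization_test(g$clusters, g$genes, g$esc)$p_greater
    m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
    want <- sum(dhyper(tab[1, 1]:min(m, k), m, nn, k))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("transition regions classify by flanking XCI status", {
  genes <- data.frame(gene = c("a", "b", "c", "d"), chrom = "chrX",
                      start = c(0, 2000, 5000, 9000),
                      end = c(1000, 3000, 6000, 10000),
                      status = c("subject", "subject", "escape", "escape"))
  peaks <- data.frame(chrom = "chrX", start = 3500, end = 3700)
  tr <- transition_classify(genes, peaks)
  expect_identical(tr$transitions$cls, c("S-S", "E-S", "E-E"))
  expect_identical(tr$transitions$has_ctcf_peak, c(FALSE, TRUE, FALSE))
  expect_equal(unname(tr$fractions["E-S"]), 1)
  # empty peak set
  tr0 <- transition_classify(genes[1:2, ], peaks[0, ])
  expect_identical(tr0$transitions$cls, "S-S")
  expect_false(tr0$transitions$has_ctcf_peak)
  # overlapping genes are skipped with a warning
  ovl <- data.frame(gene = c("x", "y"), chrom = "chrX",
                    start = c(0, 500), end = c(1000, 1500),
                    status = "subject")
  expect_warning(tro <- transition_classify(ovl, peaks), "overlap")
  expect_identical(nrow(tro$transitions), 0L)
})

test_that("promoter counts respect the half-open +/-500 bp window", {
  genes <- data.frame(gene = "g", chrom = "chrX", tss = 10000, strand = "+")
  sig <- data.frame(chrom = "chrX",
                    pos = c(10100, 9600, 10499, 10500, 9500, 9499),
                    allele = c("Xi", "Xi", "Xi", "Xi", "Xa", "Xa"))
  pc <- promoter_counts(sig, genes)
  expect_identical(pc$xi_count, 3L)  # 10500 is outside [9500, 10500)
  expect_identical(pc$xa_count, 1L)  # 9499 is outside
  none <- promoter_counts(sig[0, ], genes)
  expect_identical(c(none$xi_count, none$xa_count), c(0L, 0L))
})

test_that("metagene binning is strand-symmetric", {
  # one record per bin on a plus-strand gene -> an all-ones profile
  g_plus <- data.frame(gene = "gp", chrom = "chrX", tss = 50000,
                       strand = "+")
  sig <- data.frame(chrom = "chrX", pos = 50000 - 3000 + seq(0, 5900, 100),
                    allele = "Xa")
  mp <- metagene_profile(sig, g_plus)
  expect_identical(nrow(mp), 60L)
  expect_true(all(mp$xa == 1))
  expect_true(all(mp$xi == 0))
  # minus-strand record 250 bp upstream of the TSS lands in the same bin
  # as the mirrored plus-strand record
  g_minus <- data.frame(gene = "gm", chrom = "chrX", tss = 50000,
                        strand = "-")
  up_minus <- metagene_profile(data.frame(chrom = "chrX", pos = 50250,
                                          allele = "Xi"), g_minus)
  up_plus <- metagene_profile(data.frame(chrom = "chrX", pos = 49750,
                                         allele = "Xi"), g_plus)
  expect_identical(which(up_minus$xi > 0), which(up_plus$xi > 0))
  expect_identical(which(up_minus$xi > 0), 28L)  # floor(2750/100) + 1
  # zero signal -> zero vectors
  z <- metagene_profile(sig[0, ], g_plus)
  expect_true(all(z$xa == 0 & z$xi == 0))
  expect_error(metagene_profile(sig, g_plus[0, ]), "empty gene set")
})

test_that("coordinate mirroring leaves the metagene profile unchanged", {
  cfg <- tiny_config(seed = 13)
  sim <- sim_xci_dataset(cfg, genome = FALSE)
  genes <- sim$genes[sim$genes$chrom == cfg$x_chrom, ]
  mp <- metagene_profile(sim$signal, genes)
  L <- cfg$chrom_length_bp
  flipped_sig <- sim$signal
  flipped_sig$pos <- L - 1 - flipped_sig$pos
  flipped_genes <- genes
  flipped_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped_genes$tss <- L - 1 - genes$tss
  mp2 <- metagene_profile(flipped_sig, flipped_genes)
  expect_equal(mp$xa, mp2$xa)
  expect_equal(mp$xi, mp2$xi)
})

test_that("cluster scan recovers a planted cluster with tight bounds", {
  cfg <- tiny_config(seed = 31)
  sim <- sim_xci_dataset(cfg, genome = FALSE)
  pk <- classify_peaks(sim$peaks, xi_allele = cfg$xi_allele,
                       library_size = cfg$chip_library_size)
  sc <- scan_xi_clusters(pk, cfg$chip_chrom_length_bp)
  expect_gte(nrow(sc$clusters), 1L)
  truth <- unlist(sim$truth$clusters[1, c("start", "end")])
  best <- which.max(vapply(seq_len(nrow(sc$clusters)), function(i)
    jaccard(c(sc$clusters$start[i], sc$clusters$end[i]), truth), 0))
  expect_gte(jaccard(c(sc$clusters$start[best], sc$clusters$end[best]),
                     truth), 0.5)
  # window-union bounds contain the peak-trimmed bounds
  scw <- scan_xi_clusters(pk, cfg$chip_chrom_length_bp, bounds = "windows")
  expect_true(all(scw$clusters$start[best] <= sc$clusters$start[best] &
                    scw$clusters$end[best] >= sc$clusters$end[best]))
})
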