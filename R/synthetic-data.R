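#' Simulation configuration for synthetic XCI datasets
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe the study conditions the package is validated under: one toy X
#' chromosome with completely skewed XCI, a minority of escape genes
#' expressing the Xi allele at a few percent to half the Xa level, binomial
#' sampling of allele-specific reads at realistic depths, a mapping-bias
#' ratio near (but not equal to) one, and biological replicates. The ChIP
#' scenario plants clusters of Xi-preferred peaks on a short toy chromosome
#' against a background at roughly genome-wide CTCF peak density.
#'
#' @param seed integer master seed. Each generator stage derives its own
#'   sub-stream from `(seed, stage name)`, so outputs are byte-identical for
#'   identical configurations and adding a stage does not perturb others.
#' @param n_genes_x,n_genes_autosome number of genes tiled on the toy X and
#'   autosome.
#' @param chrom_length_bp length of each toy RNA chromosome (bp).
#' @param escape_fraction fraction of X genes that truly escape XCI.
#' @param xi_fraction_range range (low, high) of the true Xi expression
#'   proportion \eqn{p_i} for escape genes; silenced genes have \eqn{p_i = 0}.
#' @param mapping_bias_rm true mapping-bias ratio \eqn{r_m}: the expected
#'   autosomal allelic read ratio (Xi-genome over Xa-genome alignments).
#' @param library_size_reads uniquely mapped reads per sample.
#' @param n_replicates biological replicates per tissue.
#' @param tissues character vector of tissue labels.
#' @param snp_density_per_bp probability that a base is a diagnostic SNP.
#' @param n_range range of the per-gene expected total allele-specific read
#'   count, drawn log-uniformly so both sides of the SRPM filter occur.
#' @param snp_read_fraction fraction of a gene's exonic reads that contain a
#'   diagnostic SNP; converts allele-specific totals to total exonic reads.
#' @param gene_span_bp,n_exons,exon_size_bp gene model geometry.
#' @param xi_allele which parental allele is inactivated: `"spretus"`
#'   (F1 tissue system) or `"bl6"` (Patski-like system).
#' @param x_chrom,autosome chromosome labels.
#' @param chip_chrom_length_bp length of the ChIP toy chromosome. Kept short
#'   so that an uncorrected 1-kb-step scan spans only a few window-widths
#'   and its family-wise false-cluster rate stays below the 0.01-cutoff
#'   nominal level (see the methods vignette).
#' @param peak_rate_per_bp background ChIP peak density (default 8 peaks per
#'   500 kb, about genome-wide CTCF density).
#' @param n_clusters,cluster_width_bp,cluster_fold planted Xi-peak clusters:
#'   how many, their width, and the density fold-change inside them.
#' @param peak_reads_mean mean allele-specific SNP reads per peak.
#' @param peak_xi_prop Xi-allele read proportion inside planted clusters
#'   (background peaks are balanced at 0.5).
#' @param peak_width_bp width of each simulated peak interval.
#' @param n_autosome_peaks balanced autosomal peaks (for the autosomal
#'   background estimate).
#' @param chip_library_size mapped reads in the ChIP library, used by the
#'   peak assessability filter.
#' @param signal_reads_per_gene mean Xa-allele signal reads near each TSS in
#'   the promoter/metagene signal simulation.
#'
#' @return an object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes_x = 20, n_genes_autosome = 10,
#'                   chrom_length_bp = 2e5)
#' cfg$escape_fraction
#' @export
sim_config <- function(seed = 1L,
                       n_genes_x = 200L,
                       n_genes_autosome = 100L,
                       chrom_length_bp = 5e6,
                       escape_fraction = 0.1,
                       xi_fraction_range = c(0.03, 0.5),
                       mapping_bias_rm = 1.1,
                       library_size_reads = 3e7,
                       n_replicates = 2L,
                       tissues = "brain",
                       snp_density_per_bp = 0.01,
                       n_range = c(100, 10000),
                       snp_read_fraction = 0.3,
                       gene_span_bp = 10000,
                       n_exons = 3L,
                       exon_size_bp = 1000,
                       xi_allele = c("spretus", "bl6"),
                       x_chrom = "chrX",
                       autosome = "chr1",
                       chip_chrom_length_bp = 1.75e6,
                       peak_rate_per_bp = 1.6e-5,
                       n_clusters = 1L,
                       cluster_width_bp = 5e5,
                       cluster_fold = 6,
                       peak_reads_mean = 20,
                       peak_xi_prop = 0.9,
                       peak_width_bp = 200,
                       n_autosome_peaks = 50L,
                       chip_library_size = 2e7,
                       signal_reads_per_gene = 50) {
  xi_allele <- match.arg(xi_allele)
  cfg <- list(seed = as.integer(seed), n_genes_x = as.integer(n_genes_x),
              n_genes_autosome = as.integer(n_genes_autosome),
              chrom_length_bp = chrom_length_bp,
              escape_fraction = escape_fraction,
              xi_fraction_range = xi_fraction_range,
              mapping_bias_rm = mapping_bias_rm,
              library_size_reads = library_size_reads,
              n_replicates = as.integer(n_replicates), tissues = tissues,
              snp_density_per_bp = snp_density_per_bp, n_range = n_range,
              snp_read_fraction = snp_read_fraction,
              gene_span_bp = gene_span_bp, n_exons = as.integer(n_exons),
              exon_size_bp = exon_size_bp, xi_allele = xi_allele,
              x_chrom = x_chrom, autosome = autosome,
              chip_chrom_length_bp = chip_chrom_length_bp,
              peak_rate_per_bp = peak_rate_per_bp,
              n_clusters = as.integer(n_clusters),
              cluster_width_bp = cluster_width_bp,
              cluster_fold = cluster_fold,
              peak_reads_mean = peak_reads_mean,
              peak_xi_prop = peak_xi_prop, peak_width_bp = peak_width_bp,
              n_autosome_peaks = as.integer(n_autosome_peaks),
              chip_library_size = chip_library_size,
              signal_reads_per_gene = signal_reads_per_gene)

  stopifnot(length(cfg$xi_fraction_range) == 2L,
            cfg$xi_fraction_range[1] <= cfg$xi_fraction_range[2],
            cfg$xi_fraction_range[1] >= 0, cfg$xi_fraction_range[2] <= 1,
            cfg$escape_fraction >= 0, cfg$escape_fraction <= 1,
            cfg$mapping_bias_rm > 0,
            cfg$snp_density_per_bp >= 0, cfg$snp_density_per_bp <= 1,
            length(cfg$n_range) == 2L, cfg$n_range[1] <= cfg$n_range[2])
  counts <- c(n_genes_x = cfg$n_genes_x, n_genes_autosome = cfg$n_genes_autosome,
              chrom_length_bp = cfg$chrom_length_bp,
              library_size_reads = cfg$library_size_reads,
              n_replicates = cfg$n_replicates)
  if (any(counts <= 0))
    stop("all counts in a sim_config must be positive; offending: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic XCI dataset configuration (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  X genes: %d (%.0f%% escape, p_i in [%.2f, %.2f]); autosomal genes: %d\n",
              x$n_genes_x, 100 * x$escape_fraction, x$xi_fraction_range[1],
              x$xi_fraction_range[2], x$n_genes_autosome))
  cat(sprintf("  tissues: %s; replicates: %d; r_m = %.3f; library %.3g reads\n",
              paste(x$tissues, collapse = ", "), x$n_replicates,
              x$mapping_bias_rm, x$library_size_reads))
  cat(sprintf("  ChIP toy chromosome: %.3g bp, background %.2g peaks/bp, %d cluster(s) at %gx\n",
              x$chip_chrom_length_bp, x$peak_rate_per_bp, x$n_clusters,
              x$cluster_fold))
  invisible(x)
}

#' Generate a toy reference chromosome pair and a diagnostic SNP table
#'
#' Draws a random reference sequence for the toy X and autosome and places
#' biallelic substitutions at the configured density. The SNP table is
#' 1-based (VCF-like); `ref` always matches the emitted reference base and
#' `alt` differs from it, so the pair round-trips through
#' [build_pseudo_genome()] without mismatch errors.
#'
#' @param config a [sim_config()].
#' @return a list with `genome` (a named [Biostrings::DNAStringSet] with one
#'   entry per chromosome) and `snps` (data frame: `chrom`, `pos`, `ref`,
#'   `alt`).
#' @examples
#' gs <- sim_genome_snps(sim_config(seed = 1, chrom_length_bp = 5000))
#' head(gs$snps)
#' @export
sim_genome_snps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$chrom_length_bp < 1000)
    stop("chrom_length_bp must be at least 1000")
  bases <- c("A", "C", "G", "T")
  chroms <- c(config$x_chrom, config$autosome)
  L <- config$chrom_length_bp
  with_stage_seed(config$seed, "genome", {
    seqs <- vapply(chroms, function(ch)
      paste(sample(bases, L, replace = TRUE), collapse = ""), "")
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms

    if (config$snp_density_per_bp * L < 1) {
      if (config$snp_density_per_bp > 0 || TRUE)
        xci_log("SNP density times length below one expected SNP; ",
                "emitting an empty SNP table", level = "warn")
      snps <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0))
      return(list(genome = genome, snps = snps))
    }
    snps <- do.call(rbind, lapply(chroms, function(ch) {
      n <- stats::rbinom(1L, L, config$snp_density_per_bp)
      pos <- sort(sample.int(L, n))
      ref <- strsplit(as.character(genome[[ch]]), "")[[1]][pos]
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
      data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt))
    }))
    rownames(snps) <- NULL
    list(genome = genome, snps = snps)
  })
}

#' Generate non-overlapping toy gene models
#'
#' Tiles `n_genes_x` genes on the toy X and `n_genes_autosome` on the toy
#' autosome, leaving an intergenic gap (a "transition region") between
#' consecutive genes. Strands alternate so both orientations are
#' represented; each gene carries `n_exons` evenly spaced exons. The TSS is
#' the lower gene end on the plus strand and the higher end on the minus
#' strand.
#'
#' @param config a [sim_config()].
#' @return a data frame with one row per gene: `gene`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `tss` (0-based position of the
#'   first transcribed base), `exon_starts`, `exon_sizes` (comma strings,
#'   starts absolute 0-based), and `exon_length_bp`.
#' @examples
#' genes <- sim_gene_models(sim_config(seed = 1, n_genes_x = 4,
#'                                     n_genes_autosome = 2,
#'                                     chrom_length_bp = 2e5))
#' genes[, c("gene", "chrom", "start", "end", "strand", "tss")]
#' @export
sim_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tile_one <- function(chrom, n, prefix) {
    slot <- floor(config$chrom_length_bp / n)
    if (slot < config$gene_span_bp + 2)
      stop(sprintf("cannot fit %d genes of %g bp on a %g bp chromosome",
                   n, config$gene_span_bp, config$chrom_length_bp))
    margin <- floor((slot - config$gene_span_bp) / 2)
    start <- (seq_len(n) - 1L) * slot + margin
    end <- start + config$gene_span_bp
    strand <- rep(c("+", "-"), length.out = n)
    k <- config$n_exons
    rel <- if (k == 1L) 0 else
      round((config$gene_span_bp - config$exon_size_bp) * (seq_len(k) - 1L) / (k - 1L))
    exon_starts <- vapply(start, function(s)
      paste(s + rel, collapse = ","), "")
    exon_sizes <- paste(rep(config$exon_size_bp, k), collapse = ",")
    data.frame(gene = sprintf("%s%03d", prefix, seq_len(n)), chrom = chrom,
               start = start, end = end, strand = strand,
               tss = ifelse(strand == "+", start, end - 1),
               exon_starts = exon_starts, exon_sizes = exon_sizes,
               exon_length_bp = k * config$exon_size_bp)
  }
  rbind(tile_one(config$x_chrom, config$n_genes_x, "geneX"),
        tile_one(config$autosome, config$n_genes_autosome, "geneA"))
}

#' Draw the ground truth for a synthetic dataset
#'
#' Assigns each X-linked gene a true XCI status (escape with probability
#' `escape_fraction`, otherwise subject with \eqn{p_i = 0}) and, for escape
#' genes, a true Xi expression proportion drawn uniformly from
#' `xi_fraction_range`, independently per tissue. The escaping gene set is
#' shared across tissues; the per-tissue \eqn{p_i} varies. Also fixes the
#' planted Xi-peak cluster intervals on the ChIP toy chromosome, evenly
#' spaced and non-overlapping.
#'
#' @param config a [sim_config()].
#' @param genes gene models from [sim_gene_models()].
#' @return a list of class `"xci_truth"`: `genes` (data frame `gene`,
#'   `tissue`, `true_status`, `true_xi_fraction`) and `clusters` (data frame
#'   `chrom`, `start`, `end`).
#' @export
sim_ground_truth <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  xg <- genes$gene[genes$chrom == config$x_chrom]
  with_stage_seed(config$seed, "truth", {
    n_esc <- round(config$escape_fraction * length(xg))
    esc <- sample(xg, n_esc)
    gt <- do.call(rbind, lapply(config$tissues, function(ti) {
      p <- ifelse(xg %in% esc,
                  stats::runif(length(xg), config$xi_fraction_range[1],
                               config$xi_fraction_range[2]), 0)
      data.frame(gene = xg, tissue = ti,
                 true_status = ifelse(p > 0, "escape", "subject"),
                 true_xi_fraction = p)
    }))
    k <- config$n_clusters
    centers <- config$chip_chrom_length_bp * seq_len(k) / (k + 1)
    clusters <- data.frame(chrom = rep(config$x_chrom, k),
                           start = pmax(0, centers - config$cluster_width_bp / 2),
                           end = pmin(config$chip_chrom_length_bp,
                                      centers + config$cluster_width_bp / 2))
    if (k > 1 && any(clusters$start[-1] < clusters$end[-k]))
      stop("planted clusters overlap; reduce n_clusters or cluster_width_bp")
    structure(list(genes = gt, clusters = clusters), class = "xci_truth")
  })
}

#' Simulate per-gene allele-specific RNA-seq counts
#'
#' For each gene, tissue and replicate, the total informative read count
#' \eqn{n} is Poisson around a per-gene expected depth (log-uniform across
#' genes), and the Xi-allele count is \eqn{n_0 \sim Binomial(n, p')} where
#' \eqn{p'} is the true Xi proportion distorted by mapping bias on the odds
#' scale: \eqn{p' = r_m p / (r_m p + 1 - p)}. Autosomal genes are generated
#' at a balanced true ratio (\eqn{p = 0.5}), so [compute_mapping_bias()]
#' recovers \eqn{r_m} from them; a fully silenced gene (\eqn{p = 0}) yields
#' \eqn{n_0 = 0} in every replicate regardless of bias.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [sim_ground_truth()].
#' @param genes gene models from [sim_gene_models()].
#' @return a data frame in the layout [xci_fit()] consumes: `gene`, `chrom`,
#'   `tissue`, `replicate`, `sample`, `n0`, `n1`, `total_reads`,
#'   `exon_length_bp`, `library_size`.
#' @export
sim_rnaseq_counts <- function(config, truth, genes) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "xci_truth"))
  if (any(truth$genes$true_xi_fraction < 0 | truth$genes$true_xi_fraction > 1))
    stop("true_xi_fraction outside [0, 1]")
  rm_ <- config$mapping_bias_rm
  with_stage_seed(config$seed, "rnaseq", {
    mu <- exp(stats::runif(nrow(genes), log(config$n_range[1]),
                           log(config$n_range[2])))
    names(mu) <- genes$gene
    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        tissue = config$tissues, stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      ti <- grid$tissue[i]; rep_ <- grid$replicate[i]
      p_true <- ifelse(genes$chrom == config$x_chrom,
                       truth$genes$true_xi_fraction[
                         match(paste(genes$gene, ti),
                               paste(truth$genes$gene, truth$genes$tissue))],
                       0.5)
      p_obs <- rm_ * p_true / (rm_ * p_true + 1 - p_true)
      n <- stats::rpois(nrow(genes), mu[genes$gene])
      n0 <- stats::rbinom(nrow(genes), n, p_obs)
      data.frame(gene = genes$gene, chrom = genes$chrom, tissue = ti,
                 replicate = rep_, sample = paste0(ti, "_rep", rep_),
                 n0 = n0, n1 = n - n0,
                 total_reads = round(n / config$snp_read_fraction),
                 exon_length_bp = genes$exon_length_bp,
                 library_size = config$library_size_reads)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate an allele-specific ChIP-seq peak set with planted Xi clusters
#'
#' Background peaks are laid down uniformly at `peak_rate_per_bp` along the
#' ChIP toy X chromosome with balanced allelic read counts; inside each
#' planted cluster the peak density is multiplied by `cluster_fold` and the
#' extra peaks carry Xi-skewed counts (`peak_xi_prop`). Balanced autosomal
#' peaks are appended so the autosomal background proportion is estimable.
#' Per-peak totals are Poisson (`peak_reads_mean`, minimum 1) and allele
#' splits are binomial.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [sim_ground_truth()] (supplies the planted
#'   cluster intervals).
#' @return a data frame: `chrom`, `start`, `end` (0-based half-open),
#'   `peak_id`, `n_bl`, `n_sp`, `true_preference` (`"Xi"` inside planted
#'   clusters, `"both"` outside).
#' @export
sim_chip_peaks <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "xci_truth"))
  L <- config$chip_chrom_length_bp
  with_stage_seed(config$seed, "chip", {
    mid <- stats::runif(round(config$peak_rate_per_bp * L), 0, L)
    pref <- rep("both", length(mid))
    for (i in seq_len(nrow(truth$clusters))) {
      cl <- truth$clusters[i, ]
      extra <- stats::runif(
        stats::rpois(1L, config$peak_rate_per_bp * (config$cluster_fold - 1) *
                       (cl$end - cl$start)), cl$start, cl$end)
      mid <- c(mid, extra)
      pref <- c(pref, rep("Xi", length(extra)))
    }
    n <- pmax(1L, stats::rpois(length(mid), config$peak_reads_mean))
    p_xi <- ifelse(pref == "Xi", config$peak_xi_prop, 0.5)
    n_xi <- stats::rbinom(length(mid), n, p_xi)
    # map Xi/Xa onto parental labels according to which allele is inactive
    n_bl <- if (config$xi_allele == "bl6") n_xi else n - n_xi
    x <- data.frame(chrom = config$x_chrom,
                    start = pmax(0, round(mid - config$peak_width_bp / 2)),
                    n_bl = n_bl, true_preference = pref)
    x$end <- pmin(L, x$start + config$peak_width_bp)
    x$n_sp <- n - n_bl
    na <- config$n_autosome_peaks
    if (na > 0) {
      amid <- stats::runif(na, 0, L)
      an <- pmax(1L, stats::rpois(na, config$peak_reads_mean))
      abl <- stats::rbinom(na, an, 0.5)
      a <- data.frame(chrom = config$autosome,
                      start = pmax(0, round(amid - config$peak_width_bp / 2)),
                      n_bl = abl, true_preference = "both")
      a$end <- pmin(L, a$start + config$peak_width_bp)
      a$n_sp <- an - abl
      x <- rbind(x, a)
    }
    x <- x[order(x$chrom, x$start), ]
    x$peak_id <- sprintf("peak%04d", seq_len(nrow(x)))
    rownames(x) <- NULL
    x[, c("chrom", "start", "end", "peak_id", "n_bl", "n_sp",
          "true_preference")]
  })
}

#' Simulate allele-specific promoter signal records
#'
#' Emits per-read signal records (chromosome, position, allele label) with a
#' Gaussian pile-up centred on each X-linked TSS: the Xa allele at a common
#' mean depth, the Xi allele scaled by the gene's true Xi proportion, so
#' escape genes show bi-allelic promoter signal and silenced genes Xa-only
#' signal, mimicking promoter-proximal initiation marks.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [sim_ground_truth()].
#' @param genes gene models from [sim_gene_models()].
#' @param tissue tissue whose truth to use (default first configured).
#' @param spread standard deviation (bp) of read positions around the TSS.
#' @return a data frame: `chrom`, `pos` (0-based), `allele` (`"Xi"`/`"Xa"`),
#'   `gene`.
#' @export
sim_signal_records <- function(config, truth, genes,
                               tissue = config$tissues[1], spread = 300) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "xci_truth"))
  xg <- genes[genes$chrom == config$x_chrom, ]
  tt <- truth$genes[truth$genes$tissue == tissue, ]
  with_stage_seed(config$seed, paste0("signal_", tissue), {
    one_gene <- function(i) {
      g <- xg[i, ]
      p <- tt$true_xi_fraction[match(g$gene, tt$gene)]
      n_xa <- stats::rpois(1L, config$signal_reads_per_gene)
      n_xi <- stats::rpois(1L, config$signal_reads_per_gene * 2 * p)
      if (n_xa + n_xi == 0L) return(NULL)
      pos <- round(stats::rnorm(n_xa + n_xi, g$tss, spread))
      data.frame(chrom = g$chrom, pos = pos,
                 allele = rep(c("Xa", "Xi"), c(n_xa, n_xi)), gene = g$gene)
    }
    out <- do.call(rbind, lapply(seq_len(nrow(xg)), one_gene))
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic XCI dataset
#'
#' Runs every generator stage under one master seed and returns the pieces
#' together with their ground truth. With `genome = FALSE` the (relatively
#' bulky) reference sequence and SNP table are skipped; counts, peaks and
#' signal do not depend on them.
#'
#' @param config a [sim_config()].
#' @param genome logical; also generate the toy reference and SNP table.
#' @return a list of class `"xci_sim"` with elements `config`, `genes`,
#'   `truth`, `counts`, `peaks`, `signal`, and (if requested) `genome` and
#'   `snps`.
#' @examples
#' sim <- sim_xci_dataset(sim_config(seed = 1, n_genes_x = 30,
#'                                   n_genes_autosome = 20,
#'                                   chrom_length_bp = 1e6), genome = FALSE)
#' head(sim$counts)
#' @export
sim_xci_dataset <- function(config, genome = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_models(config)
  truth <- sim_ground_truth(config, genes)
  out <- list(config = config, genes = genes, truth = truth,
              counts = sim_rnaseq_counts(config, truth, genes),
              peaks = sim_chip_peaks(config, truth),
              signal = sim_signal_records(config, truth, genes))
  if (genome) {
    gs <- sim_genome_snps(config)
    out$genome <- gs$genome
    out$snps <- gs$snps
  }
  class(out) <- "xci_sim"
  out
}

#' Write a synthetic dataset to standard-format files
#'
#' Emits FASTA (reference), a 1-based TSV SNP table, BED12 gene models,
#' TSV count tables, a BED6+2 peak file with the two allele count columns,
#' a TSV signal table and a JSON ground-truth sidecar.
#'
#' @param sim a dataset from [sim_xci_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written file paths.
#' @export
write_xci_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "xci_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(sim$genome)) {
    paths["genome"] <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, paths["genome"])
    paths["snps"] <- file.path(dir, "snps.tsv")
    write_snp_table(sim$snps, paths["snps"])
  }
  paths["genes"] <- file.path(dir, "genes.bed")
  write_gene_models_bed12(sim$genes, paths["genes"])
  paths["counts"] <- file.path(dir, "counts.tsv")
  utils::write.table(sim$counts, paths["counts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["peaks"] <- file.path(dir, "peaks.bed")
  write_peaks_bed(sim$peaks, paths["peaks"])
  paths["signal"] <- file.path(dir, "signal.tsv")
  utils::write.table(sim$signal, paths["signal"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(list(genes = sim$truth$genes,
                            clusters = sim$truth$clusters),
                       paths["truth"], digits = NA)
  invisible(paths)
}
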