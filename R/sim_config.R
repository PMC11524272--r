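#' Simulation configuration for a synthetic diploid genome
#'
#' Bundles and validates every tunable of the synthetic diploid generator:
#' genome geometry, per-base SNP/small-indel rates, counts and sizes of the
#' five structural-variant classes, the fraction of genes made
#' haplotype-specific, and the allele-specific-expression (ASE) design
#' (number of experiments, replicates, planted effect size, planted ASE
#' blocks).
#'
#' Defaults emulate a highly heterozygous poplar-like diploid at desk scale:
#' ~33.5% GC, a SNP rate of 2% (between the k-mer estimate and the
#' whole-genome-alignment rate reported for such genomes), four expression
#' experiments with three replicates, and a planted allelic effect of
#' |log2 fold change| = 2.
#'
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @param n_chromosomes number of chromosome pairs.
#' @param chrom_length length of each haplotype-A chromosome in bases.
#' @param gc_content target GC fraction in (0,1).
#' @param n_genes_per_chrom genes simulated per chromosome.
#' @param snp_rate per-base probability of a heterozygous SNP.
#' @param small_indel_rate per-base probability of a heterozygous indel
#'   shorter than 50 bp.
#' @param indel_length_max maximum small-indel length (must be < 50).
#' @param sv_counts named integer vector/list with entries `deletion`,
#'   `insertion`, `duplication`, `contraction`, `translocation`.
#' @param sv_length_range length-2 vector of SV sizes in bases (min >= 50).
#' @param haplotype_specific_gene_fraction fraction of genes whose B copy is
#'   deleted (they become haplotype-A-specific).
#' @param n_experiments number of expression experiments.
#' @param replicates_per_experiment replicates per experiment (>= 2).
#' @param ase_pair_fraction fraction of allele pairs with planted ASE.
#' @param ase_log2fc planted absolute log2 fold change for ASE pairs.
#' @param ase_block_spec data.frame with columns `chrom` (index),
#'   `start_index` (gene index on that chromosome), `n_genes` (>= 4) and
#'   `direction` ("A" or "B"): runs of co-directional planted ASE pairs.
#' @param dispersion negative-binomial dispersion of simulated counts.
#' @param mean_expression mean read count per allele copy and replicate.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 400000L,
                       gc_content = 0.335,
                       n_genes_per_chrom = 40L,
                       snp_rate = 0.02,
                       small_indel_rate = 0.001,
                       indel_length_max = 10L,
                       sv_counts = c(deletion = 2L, insertion = 2L,
                                     duplication = 1L, contraction = 1L,
                                     translocation = 0L),
                       sv_length_range = c(100L, 1000L),
                       haplotype_specific_gene_fraction = 0.1,
                       n_experiments = 4L,
                       replicates_per_experiment = 3L,
                       ase_pair_fraction = 0.35,
                       ase_log2fc = 2,
                       ase_block_spec = NULL,
                       dispersion = 0.1,
                       mean_expression = 200) {
  sv_default <- c(deletion = 0L, insertion = 0L, duplication = 0L,
                  contraction = 0L, translocation = 0L)
  sv_counts <- unlist(sv_counts)
  stop_if_not(all(names(sv_counts) %in% names(sv_default)),
              "sv_counts names must be among deletion/insertion/duplication/contraction/translocation")
  sv_default[names(sv_counts)] <- as.integer(sv_counts)
  sv_counts <- sv_default

  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    gc_content = gc_content,
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    snp_rate = snp_rate,
    small_indel_rate = small_indel_rate,
    indel_length_max = as.integer(indel_length_max),
    sv_counts = sv_counts,
    sv_length_range = as.integer(sv_length_range),
    haplotype_specific_gene_fraction = haplotype_specific_gene_fraction,
    n_experiments = as.integer(n_experiments),
    replicates_per_experiment = as.integer(replicates_per_experiment),
    ase_pair_fraction = ase_pair_fraction,
    ase_log2fc = ase_log2fc,
    ase_block_spec = ase_block_spec,
    dispersion = dispersion,
    mean_expression = mean_expression
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$snp_rate, cfg$small_indel_rate,
             cfg$haplotype_specific_gene_fraction, cfg$ase_pair_fraction)
  stop_if_not(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  stop_if_not(cfg$gc_content > 0 && cfg$gc_content < 1,
              "gc_content must lie in (0, 1)")
  stop_if_not(cfg$indel_length_max < 50L,
              "small indels must be shorter than 50 bp")
  stop_if_not(all(cfg$sv_length_range >= 50L),
              "SV lengths must be >= 50 bp")
  stop_if_not(cfg$chrom_length >= 10L * max(cfg$sv_length_range),
              "chrom_length must be >= 10 x the longest SV")
  if (!is.null(cfg$ase_block_spec)) {
    bs <- cfg$ase_block_spec
    stop_if_not(is.data.frame(bs) &&
                  all(c("chrom", "start_index", "n_genes", "direction") %in%
                        names(bs)),
                "ase_block_spec needs columns chrom/start_index/n_genes/direction")
    stop_if_not(all(bs$n_genes >= 4L), "ASE blocks need n_genes >= 4")
    stop_if_not(all(bs$direction %in% c("A", "B")),
                "ASE block direction must be 'A' or 'B'")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic diploid simulation config\n")
  cat(sprintf("  %d chromosome(s) x %s bp, GC %.3f, %d genes/chrom\n",
              x$n_chromosomes, format(x$chrom_length, big.mark = ","),
              x$gc_content, x$n_genes_per_chrom))
  cat(sprintf("  SNP rate %.4g, small-indel rate %.4g (max %d bp)\n",
              x$snp_rate, x$small_indel_rate, x$indel_length_max))
  cat("  SVs:", paste(names(x$sv_counts), x$sv_counts, sep = "=",
                      collapse = " "), "\n")
  cat(sprintf("  ASE: %d experiments x %d reps, pair fraction %.2f, |log2FC| %.1f\n",
              x$n_experiments, x$replicates_per_experiment,
              x$ase_pair_fraction, x$ase_log2fc))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Fields mirror the arguments of [sim_config()]; `ase_block_spec` is given
#' as a list of mappings with keys chrom/start_index/n_genes/direction.
#'
#' @param path YAML file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ase_block_spec)) {
    y$ase_block_spec <- do.call(rbind, lapply(y$ase_block_spec, function(b) {
      data.frame(chrom = b$chrom, start_index = b$start_index,
                 n_genes = b$n_genes, direction = b$direction)
    }))
  }
  do.call(sim_config, y)
}
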