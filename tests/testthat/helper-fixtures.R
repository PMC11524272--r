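## Shared synthetic fixtures, built once per test run and memoized.

.fx_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx_env[[key]])) .fx_env[[key]] <- builder()
  .fx_env[[key]]
}

## mid-size diploid exercising SNPs, indels, all SV classes and
## haplotype-specific genes, with the alignment and variant calls attached
fx_diploid <- function() {
  memo("diploid", function() {
    cfg <- sim_config(
      seed = 7, n_chromosomes = 2, chrom_length = 300000L,
      n_genes_per_chrom = 30L, snp_rate = 0.01, small_indel_rate = 5e-4,
      sv_counts = c(deletion = 1, insertion = 1, duplication = 1,
                    contraction = 1, translocation = 0),
      haplotype_specific_gene_fraction = 0.1,
      ase_block_spec = data.frame(chrom = c(1, 2),
                                  start_index = c(5, 10),
                                  n_genes = c(5, 4),
                                  direction = c("A", "B")))
    hap <- generate_haplotype_a(cfg)
    mb <- mutate_to_haplotype_b(hap$genome, hap$annotation, cfg)
    aln <- align_haplotypes(hap$genome, mb$genome, min_len = 10000L)
    variants <- call_small_variants(aln$blocks, hap$genome, mb$genome)
    list(cfg = cfg, genome_a = hap$genome, annotation_a = hap$annotation,
         genome_b = mb$genome, annotation_b = mb$annotation,
         truth = mb$truth, aln = aln, variants = variants)
  })
}

## clean diploid: isolated SNPs only (no indels, no SVs, no gene loss)
fx_snp_only <- function() {
  memo("snp_only", function() {
    cfg <- sim_config(
      seed = 21, n_chromosomes = 1, chrom_length = 200000L,
      n_genes_per_chrom = 10L, snp_rate = 0.005, small_indel_rate = 0,
      sv_counts = c(deletion = 0, insertion = 0, duplication = 0,
                    contraction = 0, translocation = 0),
      haplotype_specific_gene_fraction = 0)
    hap <- generate_haplotype_a(cfg)
    mb <- mutate_to_haplotype_b(hap$genome, hap$annotation, cfg)
    aln <- align_haplotypes(hap$genome, mb$genome)
    variants <- call_small_variants(aln$blocks, hap$genome, mb$genome)
    list(cfg = cfg, genome_a = hap$genome, annotation_a = hap$annotation,
         genome_b = mb$genome, annotation_b = mb$annotation,
         truth = mb$truth, aln = aln, variants = variants)
  })
}

## simulate an ASE count experiment matrix directly (null or spiked)
sim_counts_matrix <- function(n_pairs, reps, mu, ase_idx = integer(0),
                              log2fc = 2, size = 10) {
  ids_a <- paste0("p", seq_len(n_pairs), "_A")
  ids_b <- paste0("p", seq_len(n_pairs), "_B")
  fc <- 2^(log2fc / 2)
  mua <- mu; mub <- mu
  mua[ase_idx] <- mu[ase_idx] * fc
  mub[ase_idx] <- mu[ase_idx] / fc
  m <- matrix(0L, nrow = 2L * n_pairs, ncol = reps,
              dimnames = list(c(ids_a, ids_b), paste0("r", seq_len(reps))))
  for (r in seq_len(reps))
    m[, r] <- stats::rnbinom(2L * n_pairs, mu = c(mua, mub), size = size)
  m
}

rand_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
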