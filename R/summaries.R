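## Assembly summary statistics, BUSCO-count arithmetic and consolidated
## run reporting.

#' Assembly summary statistics
#'
#' Standard N50 (smallest length in the minimal set of longest sequences
#' covering at least half of the total) and GC over unambiguous bases.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @return list with `total_length`, `n_sequences`, `n50`, `longest`,
#'   `shortest`, `gc_percent` (two decimals).
#' @export
assembly_stats <- function(sequences) {
  seqs <- as_seq_char(sequences)
  stop_if_not(length(seqs) >= 1L && any(nchar(seqs) > 0L),
              "at least one non-empty sequence is required")
  lens <- sort(unname(nchar(seqs)), decreasing = TRUE)
  total <- sum(as.numeric(lens))
  cum <- cumsum(as.numeric(lens))
  n50 <- lens[which(cum >= total / 2)[1L]]
  list(total_length = total, n_sequences = length(lens), n50 = n50,
       longest = lens[1L], shortest = lens[length(lens)],
       gc_percent = round_half_up(100 * gc_fraction(seqs), 2))
}

#' BUSCO-style completeness percentages
#'
#' `complete = single + duplicated` before division; each percentage is
#' `100 * count / total`, rounded half away from zero to one decimal.
#'
#' @param single,duplicated,fragmented,missing,total BUSCO category counts;
#'   the four categories must sum to `total`.
#' @return list of percentages `complete`, `single`, `duplicated`,
#'   `fragmented`, `missing`, plus `complete_count`.
#' @export
busco_percentages <- function(single, duplicated, fragmented, missing,
                              total) {
  stop_if_not(total > 0, "total must be > 0")
  stop_if_not(single + duplicated + fragmented + missing == total,
              "BUSCO counts must sum to the searched total")
  pct <- function(x) round_half_up(100 * x / total, 1)
  list(complete = pct(single + duplicated), single = pct(single),
       duplicated = pct(duplicated), fragmented = pct(fragmented),
       missing = pct(missing), complete_count = single + duplicated)
}

# ---- pipeline driver and report ----------------------------------------

#' Run the full haplotype-comparison pipeline
#'
#' Aligns the haplotypes, calls and annotates small variants, calls SVs,
#' assigns allele pairs and, when count matrices are given, runs the ASE
#' stage with block detection and sharing analysis.
#'
#' @param genome_a,genome_b named character vectors of chromosomes.
#' @param annotation_a,annotation_b `gene_annotation` objects.
#' @param counts optional list of per-experiment count matrices.
#' @param pairing chromosome pairing mode for [align_haplotypes()].
#' @param min_block_len minimum collinearity-block span (default 15000).
#' @return list with `blocks`, `variants`, `svs`, `alleles`, `ase`
#'   (per-experiment records), `ase_blocks`, `sharing`, `promoter_sv`.
#' @export
run_diploid_comparison <- function(genome_a, genome_b, annotation_a,
                                   annotation_b, counts = NULL,
                                   pairing = "homologous",
                                   min_block_len = 15000L) {
  genome_a <- as_seq_char(genome_a); genome_b <- as_seq_char(genome_b)
  aln <- align_haplotypes(genome_a, genome_b, pairing = pairing,
                          min_len = min_block_len)
  variants <- call_small_variants(aln$blocks, genome_a, genome_b)
  variants <- classify_location(variants, annotation_a)
  variants <- classify_effect(variants, annotation_a, genome_a)
  svs <- call_svs(aln, genome_a, genome_b)
  alleles <- assign_alleles(annotation_a, annotation_b, genome_a, genome_b,
                            aln$blocks)
  out <- list(blocks = aln$blocks, blocks_all = aln$blocks_all,
              variants = variants, svs = svs, alleles = alleles)
  if (!is.null(counts)) {
    g <- annotation_a$genes
    ord <- g[order(g$chrom, g$start), ]
    pair_order <- data.frame(pair = ord$gene_id, chrom = ord$chrom,
                             stringsAsFactors = FALSE)
    pair_order <- pair_order[pair_order$pair %in% alleles$pairs$gene_a, ,
                             drop = FALSE]
    ase <- list(); ase_blocks <- list()
    for (e in names(counts)) {
      rec <- ase_analyze(counts[[e]], alleles$pairs, experiment = e)
      ase[[e]] <- rec
      ase_blocks[[e]] <- call_ase_blocks(rec, pair_order)
    }
    ase_sets <- lapply(ase, function(r) r$pair[r$is_ase])
    out$ase <- ase
    out$ase_blocks <- ase_blocks
    out$sharing <- if (length(ase) >= 2L) sharing_summary(ase_sets) else NULL
    out$shared_blocks <- if (length(ase_blocks) >= 2L)
      shared_blocks(ase_blocks) else NULL
    ann_both <- structure(list(
      genes = rbind(annotation_a$genes, annotation_b$genes),
      exons = rbind(annotation_a$exons, annotation_b$exons),
      cds = rbind(annotation_a$cds, annotation_b$cds)
    ), class = "gene_annotation")
    union_ase <- unique(unlist(ase_sets))
    out$promoter_sv <- promoter_sv_association(
      alleles$pairs, union_ase, svs, ann_both)
  }
  out
}

#' Write pipeline outputs to a run directory
#'
#' @param results list from [run_diploid_comparison()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_blocks(results$blocks, file.path(dir, "blocks.tsv"))
  write.table(results$variants, file.path(dir, "variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_svs(results$svs, file.path(dir, "svs.tsv"))
  write.table(results$alleles$pairs, file.path(dir, "pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(results$alleles$haplotype_specific,
             file.path(dir, "haplotype_specific.txt"))
  if (!is.null(results$ase))
    for (e in names(results$ase))
      write.table(results$ase[[e]], file.path(dir, paste0("ase_", e, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    n_blocks = nrow(results$blocks),
    n_variants = nrow(results$variants),
    n_svs = nrow(results$svs),
    n_pairs = nrow(results$alleles$pairs),
    n_specific = length(results$alleles$haplotype_specific),
    experiments = names(results$ase))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Consolidated report over a run directory
#'
#' Re-reads the stage files, aggregates variant counts by type and
#' location, SV counts by the five types, gene counts by class and ASE
#' counts per experiment, and re-runs the internal conservation checks
#' (per-type variant sums equal the total; block containment).
#'
#' @param run_dir directory written by [write_run()].
#' @param strict error (nonzero status in scripts) when a stage output is
#'   missing instead of marking the section absent.
#' @return list (also written to `report.json` in the run directory).
#' @export
report <- function(run_dir, strict = FALSE) {
  need <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) {
      if (strict) stop(sprintf("missing stage output: %s", f), call. = FALSE)
      return(NULL)
    }
    p
  }
  rep <- list(run_dir = run_dir, sections_missing = character(0))
  p <- need("variants.tsv")
  if (!is.null(p)) {
    v <- read.table(p, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    s <- summarize_variants(data.frame(vtype = v$vtype))
    rep$variants <- list(by_type = s[c("snp", "ins", "del")],
                         total = s$total)
    if ("location" %in% names(v))
      rep$variants$by_location <- as.list(table(v$location))
    check <- s$snp + s$ins + s$del == s$total
    rep$checks <- c(rep$checks, variant_total_conserved = check)
  } else rep$sections_missing <- c(rep$sections_missing, "variants")
  p <- need("svs.tsv")
  if (!is.null(p)) {
    sv <- read.table(p, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    tab <- table(factor(sv$svtype,
                        levels = c("contraction", "duplication",
                                   "translocation", "deletion",
                                   "insertion")))
    rep$svs <- list(by_type = as.list(tab), total = nrow(sv))
  } else rep$sections_missing <- c(rep$sections_missing, "svs")
  p <- need("pairs.tsv")
  ps <- need("haplotype_specific.txt")
  if (!is.null(p) && !is.null(ps)) {
    pairs <- read.table(p, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    spec <- readLines(ps)
    spec <- spec[nzchar(spec)]
    total_genes <- 2L * nrow(pairs) + length(spec)
    rep$genes <- list(pairs = nrow(pairs), haplotype_specific = length(spec),
                      total = total_genes,
                      paired_fraction_pct =
                        paired_gene_fraction(nrow(pairs), total_genes))
  } else rep$sections_missing <- c(rep$sections_missing, "genes")
  ase_files <- list.files(run_dir, pattern = "^ase_.*\\.tsv$",
                          full.names = TRUE)
  if (length(ase_files)) {
    sets <- list()
    for (f in ase_files) {
      a <- read.table(f, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
      e <- sub("^ase_(.*)\\.tsv$", "\\1", basename(f))
      sets[[e]] <- a$pair[a$is_ase]
      rep$ase$per_experiment[[e]] <- sum(a$is_ase)
    }
    if (length(sets) >= 2L) {
      sh <- sharing_summary(sets)
      rep$ase$union <- sh$union_size
      rep$ase$shared_all <- sh$n_all
      rep$ase$pct_all <- sh$pct_all
      rep$ase$pct_at_least_2 <- sh$pct_at_least_2
    }
  }
  jsonlite::write_json(rep, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  txt <- c(sprintf("haplodiff report: %s", run_dir),
           if (!is.null(rep$variants))
             sprintf("  small variants: %d (SNP %d / INS %d / DEL %d)",
                     rep$variants$total, rep$variants$by_type$snp,
                     rep$variants$by_type$ins, rep$variants$by_type$del),
           if (!is.null(rep$svs)) sprintf("  SVs: %d", rep$svs$total),
           if (!is.null(rep$genes))
             sprintf("  allele pairs: %d; haplotype-specific: %d (%.2f%% paired genes)",
                     rep$genes$pairs, rep$genes$haplotype_specific,
                     rep$genes$paired_fraction_pct),
           if (length(rep$sections_missing))
             sprintf("  MISSING sections: %s",
                     paste(rep$sections_missing, collapse = ", ")))
  writeLines(txt, file.path(run_dir, "report.txt"))
  rep
}
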