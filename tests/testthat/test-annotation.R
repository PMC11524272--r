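## hand-built single-chromosome annotation for effect tests:
## one + gene and one - gene with two exons each
mk_toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gp_A", "gm_A"), chrom = "chr1_A",
    start = c(1001L, 5001L), end = c(1600L, 5600L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = rep(c("gp_A", "gm_A"), each = 2L), chrom = "chr1_A",
    start = c(1001L, 1301L, 5001L, 5301L),
    end = c(1200L, 1600L, 5200L, 5600L),
    strand = rep(c("+", "-"), each = 2L), rank = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
  ## + gene: UTR5 1001-1060, CDS 1061-1200 + 1301-1541, UTR3 1542-1600
  ## - gene: UTR3 5001-5060, CDS 5061-5200 + 5301-5541, UTR5 5542-5600
  cds <- data.frame(
    gene_id = rep(c("gp_A", "gm_A"), each = 2L), chrom = "chr1_A",
    start = c(1061L, 1301L, 5061L, 5301L),
    end = c(1200L, 1541L, 5200L, 5541L),
    strand = rep(c("+", "-"), each = 2L), rank = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_annotation")
}

mk_toy_genome <- function(ann) {
  set.seed(55)
  s <- rand_dna_str(10000)
  ## write valid start/stop codons for both genes
  substr(s, 1061, 1063) <- "ATG"; substr(s, 1539, 1541) <- "TAA"
  substr(s, 5539, 5541) <- "CAT"; substr(s, 5061, 5063) <- "TTA"
  c(chr1_A = s)
}

snp_at <- function(pos, ref, alt) {
  data.frame(chrom_a = "chr1_A", pos_a = pos, ref = ref, alt = alt,
             vtype = "SNP", block_id = 1L, stringsAsFactors = FALSE)
}

test_that("location classification follows the documented precedence", {
  ann <- mk_toy_annotation()
  v <- data.frame(
    chrom_a = "chr1_A",
    pos_a = c(901L,    # 100 bp 5' of + gene -> upstream
              1201L,   # first intron base after exon (donor)
              1202L,   # second intron base (donor)
              1205L,   # intron 5 bp from junction -> splice region
              1250L,   # mid intron
              1030L,   # 5' UTR of + gene
              1560L,   # 3' UTR of + gene
              1100L,   # CDS -> exon
              1700L,   # within 5 kb downstream of + gene
              8000L,   # far from both genes but within windows?
              5599L,   # inside - gene, exonic UTR5 side
              5299L),  # last intron base before exon 2 of - gene
    ref = "A", alt = "C", vtype = "SNP", stringsAsFactors = FALSE)
  out <- classify_location(v, ann)
  expect_equal(out$location[1L], "upstream")
  expect_equal(out$location[2L], "splice_site_donor")
  expect_equal(out$location[3L], "splice_site_donor")
  expect_equal(out$location[4L], "splice_site_region")
  expect_equal(out$location[5L], "intron")
  expect_equal(out$location[6L], "utr_5_prime")
  expect_equal(out$location[7L], "utr_3_prime")
  expect_equal(out$location[8L], "exon")
  expect_equal(out$location[9L], "downstream")
  expect_equal(out$location[11L], "utr_5_prime")
  ## - strand gene: intron base adjacent to the downstream-in-transcription
  ## exon boundary; 5299 is 2 bp from exon2 start -> donor on minus strand
  expect_true(out$location[12L] %in% c("splice_site_donor",
                                       "splice_site_acceptor"))
})

test_that("random variant locations equal an interval-arithmetic oracle", {
  fx <- fx_snp_only()
  ann <- fx$annotation_a
  set.seed(56)
  pos <- sort(sample(1000:199000, 400))
  v <- data.frame(chrom_a = "chr1_A", pos_a = pos, ref = "A", alt = "C",
                  vtype = "SNP", stringsAsFactors = FALSE)
  got <- classify_location(v, ann)$location

  ## independent brute-force oracle over the same precedence
  oracle_one <- function(p) {
    g <- ann$genes; ex <- ann$exons; cc <- ann$cds
    cats <- character(0)
    for (gi in seq_len(nrow(g))) {
      gg <- g[gi, ]
      e <- ex[ex$gene_id == gg$gene_id, ]
      e <- e[order(e$start), ]
      ccg <- cc[cc$gene_id == gg$gene_id, ]
      cl <- min(ccg$start); cr <- max(ccg$end)
      in_exon <- any(p >= e$start & p <= e$end)
      if (nrow(e) > 1L) for (k in 1:(nrow(e) - 1L)) {
        is <- e$end[k] + 1L; ie <- e$start[k + 1L] - 1L
        if (p >= is && p <= ie) {
          d5 <- p - is; d3 <- ie - p
          if (gg$strand == "+") {
            if (d5 <= 1L) cats <- c(cats, "splice_site_donor")
            if (d3 <= 1L) cats <- c(cats, "splice_site_acceptor")
          } else {
            if (d3 <= 1L) cats <- c(cats, "splice_site_donor")
            if (d5 <= 1L) cats <- c(cats, "splice_site_acceptor")
          }
          if ((d5 >= 2L && d5 <= 7L) || (d3 >= 2L && d3 <= 7L))
            cats <- c(cats, "splice_site_region")
          cats <- c(cats, "intron")
        }
        ## exonic 1-3 bp from a junction
        if ((p >= e$end[k] - 2L && p <= e$end[k]) ||
              (p >= e$start[k + 1L] && p <= e$start[k + 1L] + 2L))
          cats <- c(cats, "splice_site_region")
      }
      if (in_exon) {
        if (p >= cl && p <= cr) cats <- c(cats, "exon")
        else if ((p < cl && gg$strand == "+") ||
                   (p > cr && gg$strand == "-"))
          cats <- c(cats, "utr_5_prime")
        else cats <- c(cats, "utr_3_prime")
        cats <- c(cats, "transcript")
      }
      if (p >= gg$start && p <= gg$end) cats <- c(cats, "gene")
      up <- if (gg$strand == "+") c(gg$start - 5000L, gg$start - 1L)
            else c(gg$end + 1L, gg$end + 5000L)
      dn <- if (gg$strand == "+") c(gg$end + 1L, gg$end + 5000L)
            else c(gg$start - 5000L, gg$start - 1L)
      if (p >= up[1L] && p <= up[2L]) cats <- c(cats, "upstream")
      if (p >= dn[1L] && p <= dn[2L]) cats <- c(cats, "downstream")
    }
    prec <- c("splice_site_acceptor", "splice_site_donor",
              "splice_site_region", "utr_5_prime", "utr_3_prime", "exon",
              "intron", "transcript", "gene", "upstream", "downstream")
    for (cat in prec) if (cat %in% cats) return(cat)
    "intergenic"
  }
  oracle <- vapply(pos, oracle_one, "")
  expect_equal(got, oracle)
})

test_that("every variant gets exactly one location and counts sum to the total", {
  fx <- fx_diploid()
  out <- classify_location(fx$variants, fx$annotation_a)
  expect_false(any(is.na(out$location)))
  expect_equal(sum(table(out$location)), nrow(fx$variants))
  expect_true(all(out$location %in% c(
    "downstream", "exon", "gene", "intergenic", "intron",
    "splice_site_acceptor", "splice_site_donor", "splice_site_region",
    "transcript", "upstream", "utr_3_prime", "utr_5_prime")))
})

test_that("coding effects follow the genetic code", {
  ann <- mk_toy_annotation()
  g <- mk_toy_genome(ann)
  ## engineer a TGG codon at CDS positions 4-6 of the + gene (1064-1066)
  s <- g[[1L]]
  substr(s, 1064, 1066) <- "TGG"
  g <- c(chr1_A = s)
  v <- rbind(
    snp_at(1066L, "G", "A"),                         # TGG -> TGA stop_gained
    data.frame(chrom_a = "chr1_A", pos_a = 1100L, ref = "A", alt = "",
               vtype = "DEL", block_id = 1L),        # 1 bp frameshift
    data.frame(chrom_a = "chr1_A", pos_a = 1100L, ref = "AAA", alt = "",
               vtype = "DEL", block_id = 1L),        # 3 bp inframe
    snp_at(1061L, "A", "G"))                         # ATG start lost
  v$ref[2L] <- substr(s, 1100, 1100)
  v$ref[3L] <- substr(s, 1100, 1102)
  v <- classify_location(v, ann)
  out <- classify_effect(v, ann, g)
  expect_equal(out$effect[1L], "stop_gained")
  expect_equal(out$impact[1L], "HIGH")
  expect_equal(out$effect[2L], "frameshift")
  expect_equal(out$impact[2L], "HIGH")
  expect_equal(out$effect[3L], "inframe_deletion")
  expect_equal(out$impact[3L], "MODERATE")
  expect_equal(out$effect[4L], "start_lost")
  expect_equal(out$impact[4L], "HIGH")
})

test_that("synonymous and missense SNPs are graded LOW/MODERATE, splice sites HIGH", {
  ann <- mk_toy_annotation()
  g <- mk_toy_genome(ann)
  s <- g[[1L]]
  substr(s, 1064, 1066) <- "CTG"   # Leu; CTA is synonymous, CCG missense
  g <- c(chr1_A = s)
  v <- rbind(snp_at(1066L, "G", "A"),  # CTG->CTA synonymous
             snp_at(1065L, "T", "C"),  # CTG->CCG missense
             snp_at(1201L, substr(s, 1201, 1201), "A"))  # splice donor
  v <- classify_location(v, ann)
  out <- classify_effect(v, ann, g)
  expect_equal(out$effect[1:2], c("synonymous", "missense"))
  expect_equal(out$impact[1:2], c("LOW", "MODERATE"))
  expect_equal(out$effect[3L], "splice_donor_variant")
  expect_equal(out$impact[3L], "HIGH")
})

test_that("high-impact gene counting matches a brute-force scan", {
  fx <- fx_diploid()
  v <- classify_location(fx$variants, fx$annotation_a)
  v <- classify_effect(v, fx$annotation_a, fx$genome_a)
  high_genes <- unique(v$gene_id[v$impact == "HIGH" & !is.na(v$gene_id)])
  ## brute force: for every gene, scan all variants for a HIGH one
  brute <- fx$annotation_a$genes$gene_id[vapply(
    fx$annotation_a$genes$gene_id, function(gid)
      any(v$impact == "HIGH" & !is.na(v$gene_id) & v$gene_id == gid), TRUE)]
  expect_setequal(high_genes[high_genes %in% fx$annotation_a$genes$gene_id],
                  brute)
})

test_that("high-impact fraction reproduces the printed arithmetic", {
  expect_equal(high_impact_gene_fraction(11944, 41561), 28.74)
  expect_equal(high_impact_gene_fraction(0, 100), 0)
  expect_equal(high_impact_gene_fraction(1, 3), 33.33)
  expect_error(high_impact_gene_fraction(1, 0), "n_genes")
})
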