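test_that("gap alignment handles the trivial and mismatch cases", {
  al <- align_gap("ACGT", "ACGT")
  expect_equal(al$identity, 100)
  expect_equal(al$matches, 4L)
  al2 <- align_gap("ACGT", "AGGT")
  expect_equal(al2$columns - al2$matches, 1L)
  al3 <- align_gap("", "ACG")
  expect_equal(al3$matches, 0L); expect_equal(al3$columns, 3L)
})

test_that("gap alignment identity tracks planted divergence", {
  set.seed(41)
  ids <- replicate(100, {
    a <- rand_dna_str(500)
    b <- strsplit(a, "")[[1L]]
    flip <- runif(500) < 0.05
    b[flip] <- vapply(b[flip], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
    align_gap(a, paste(b, collapse = ""))$identity
  })
  expect_gt(mean(ids), 93); expect_lt(mean(ids), 97)
})

test_that("identical haplotypes produce zero variants", {
  set.seed(42)
  g <- c(c1 = rand_dna_str(30000))
  aln <- align_haplotypes(g, g, min_len = 15000)
  v <- call_small_variants(aln$blocks, g, g)
  expect_equal(nrow(v), 0L)
  svs <- call_svs(aln, g, g)
  expect_equal(nrow(svs), 0L)
})

test_that("planted isolated SNPs are recovered at >= 99% with no false calls", {
  fx <- fx_snp_only()
  ts <- fx$truth$planted_snps
  cs <- fx$variants[fx$variants$vtype == "SNP", ]
  key_t <- paste(ts$chrom, ts$pos_a)
  key_c <- paste(cs$chrom_a, cs$pos_a)
  expect_gte(mean(key_t %in% key_c), 0.99)
  expect_equal(sum(!(key_c %in% key_t)), 0L)
  ## alleles match too
  m <- match(key_c, key_t)
  expect_equal(cs$ref, ts$ref[m])
  expect_equal(cs$alt, ts$alt[m])
})

test_that("planted small indels are recovered and left-aligned deterministically", {
  fx <- fx_diploid()
  ti <- fx$truth$planted_indels
  ci <- fx$variants[fx$variants$vtype != "SNP", ]
  near <- vapply(seq_len(nrow(ti)), function(i) {
    any(ci$chrom_a == ti$chrom[i] & ci$vtype == ti$type[i] &
          abs(ci$pos_a - ti$pos_a[i]) <= ti$len[i] + 2L)
  }, TRUE)
  expect_gte(mean(near), 0.9)
  ## left-alignment: no called indel can shift further left
  for (i in head(which(ci$vtype == "DEL"), 20)) {
    v <- ci[i, ]
    la <- haplodiff:::left_align_indel(v$pos_a, v$ref, "DEL",
                                       fx$genome_a[[v$chrom_a]])
    expect_equal(la$pos, v$pos_a)
  }
})

test_that("a forced 10 bp deletion is called once, left-aligned", {
  set.seed(43)
  a <- rand_dna_str(40000)
  b <- paste0(substr(a, 1, 20000), substr(a, 20011, 40000))
  aln <- align_haplotypes(c(c1 = a), c(c1 = b), min_len = 15000)
  v <- call_small_variants(aln$blocks, c(c1 = a), c(c1 = b))
  dels <- v[v$vtype == "DEL", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(nchar(dels$ref), 10L)
  la <- haplodiff:::left_align_indel(dels$pos_a, dels$ref, "DEL", a)
  expect_equal(la$pos, dels$pos_a)
})

test_that("swapping the haplotypes converts DEL to INS and keeps SNPs", {
  fx <- fx_snp_only()
  ## add one deletion to make the property non-trivial
  a <- fx$genome_a[[1L]]
  b <- paste0(substr(a, 1, 50000), substr(a, 50006, nchar(a)))
  ga <- c(chr1_A = a); gb <- c(chr1_B = b)
  aln_ab <- align_haplotypes(ga, gb)
  aln_ba <- align_haplotypes(gb, ga)
  v_ab <- call_small_variants(aln_ab$blocks, ga, gb)
  v_ba <- call_small_variants(aln_ba$blocks, gb, ga)
  expect_equal(sum(v_ab$vtype == "SNP"), sum(v_ba$vtype == "SNP"))
  expect_equal(sum(v_ab$vtype == "DEL"), sum(v_ba$vtype == "INS"))
  expect_equal(sum(v_ab$vtype == "INS"), sum(v_ba$vtype == "DEL"))
})

test_that("no small variant is emitted outside a collinearity block", {
  fx <- fx_diploid()
  v <- fx$variants
  bl <- fx$aln$blocks
  inside <- vapply(seq_len(nrow(v)), function(i) {
    any(bl$chrom_a == v$chrom_a[i] & bl$start_a <= v$pos_a[i] &
          bl$end_a >= v$pos_a[i])
  }, TRUE)
  expect_true(all(inside))
  ## per-type sums equal the reported total
  s <- summarize_variants(v)
  expect_equal(s$snp + s$ins + s$del, s$total)
})

test_that("heterozygosity rate reproduces the printed two-decimal convention", {
  expect_equal(heterozygosity_rate(10406261, 377691676), 2.76)
  expect_equal(heterozygosity_rate(10535490, 377691676), 2.79)
  expect_equal(heterozygosity_rate(0, 1e6), 0)
  expect_error(heterozygosity_rate(10, 0), "genome_size")
})

test_that("all five planted SV classes are recovered with tight breakpoints", {
  fx <- fx_diploid()
  svs <- call_svs(fx$aln, fx$genome_a, fx$genome_b)
  tr <- fx$truth$planted_svs
  ## insertions and deletions: breakpoints within +-10 bp
  for (ty in c("deletion", "insertion")) {
    tt <- tr[tr$svtype == ty, ]
    for (i in seq_len(nrow(tt))) {
      hit <- svs$svtype == ty & svs$chrom_a == tt$chrom[i] &
        abs(svs$start_a - tt$start_a[i]) <= 10L
      expect_true(any(hit), label = sprintf("%s at %d", ty, tt$start_a[i]))
      expect_lt(abs(svs$size[which(hit)[1L]] - tt$size[i]), 11L)
    }
  }
  ## copy-number classes present with the right unit size
  for (ty in c("duplication", "contraction")) {
    tt <- tr[tr$svtype == ty, ]
    got <- svs[svs$svtype == ty, ]
    expect_equal(nrow(got), nrow(tt))
    expect_lt(max(abs(got$size - tt$size)), 11L)
  }
})

test_that("a translocated segment is flagged via its cross-chromosome partner", {
  cfg <- sim_config(seed = 27, n_chromosomes = 2, chrom_length = 150000L,
                    n_genes_per_chrom = 5L, snp_rate = 0.002,
                    small_indel_rate = 0,
                    sv_counts = c(deletion = 0, insertion = 0,
                                  duplication = 0, contraction = 0,
                                  translocation = 1),
                    sv_length_range = c(400L, 800L),
                    haplotype_specific_gene_fraction = 0)
  hap <- generate_haplotype_a(cfg)
  mb <- mutate_to_haplotype_b(hap$genome, hap$annotation, cfg)
  aln <- align_haplotypes(hap$genome, mb$genome, pairing = "all",
                          min_len = 15000)
  svs <- call_svs(aln, hap$genome, mb$genome)
  tra <- svs[svs$svtype == "translocation", ]
  src <- mb$truth$planted_svs[mb$truth$planted_svs$svtype == "translocation", ]
  expect_gte(nrow(tra), 1L)
  expect_true(any(tra$chrom_a == src$chrom &
                    abs(tra$start_a - src$start_a) <= 50L))
})

test_that("per-sample heterozygous counts match an independent line parser", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "toy.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3")
  set.seed(44)
  gts <- c("0/0", "0/1", "1/1", "1/2", "0|1", "./.", ".")
  lines <- vapply(1:100, function(i) {
    g <- sample(gts, 3L, replace = TRUE)
    sprintf("chr1\t%d\t.\tA\tC,G\t50\tPASS\t.\tGT\t%s\t%s\t%s",
            i * 10L, g[1L], g[2L], g[3L])
  }, "")
  writeLines(c(hdr, lines), vcf)
  got <- count_het_per_sample(vcf)
  ## independent oracle: plain text parsing
  oracle <- sapply(1:3, function(s) {
    sum(vapply(lines, function(l) {
      g <- strsplit(l, "\t")[[1L]][9L + s]
      al <- strsplit(g, "[/|]")[[1L]]
      length(al) == 2L && !any(al == ".") && al[1L] != al[2L]
    }, TRUE))
  })
  names(oracle) <- c("s1", "s2", "s3")
  expect_equal(unname(got[names(oracle)]), unname(oracle))
  expect_false(is.unsorted(rev(got)))
})

test_that("toy genotype patterns count as specified", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "mini.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
               "chr1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0/1\t0/0\t1/1",
               "chr1\t200\t.\tA\tC\t50\tPASS\t.\tGT\t./.\t./.\t./."),
             vcf)
  got <- count_het_per_sample(vcf)
  expect_equal(unname(got[order(names(got))]), c(1L, 0L, 0L))
})

test_that("small variants export as parseable VCF with anchored indels", {
  fx <- fx_snp_only()
  d <- withr::local_tempdir()
  p <- file.path(d, "vars.vcf")
  write_vcf(head(fx$variants, 50), fx$genome_a, p)
  v <- vcfR::read.vcfR(p, verbose = FALSE)
  expect_equal(nrow(v@fix), 50L)
})
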