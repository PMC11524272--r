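test_that("equal counts give zero fold change and p near 1", {
  r <- ase_test(c(100, 100), c(100, 100))
  expect_equal(r$log2fc, 0)
  expect_gt(r$p_value, 0.9)
  expect_false(r$untestable)
  r0 <- ase_test(c(0, 0), c(0, 0))
  expect_true(r0$untestable)
  expect_equal(r0$p_value, 1)
  expect_error(ase_test(100, 100), "replicates")
})

test_that("BH adjustment equals the textbook step-up", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  ## oracle: q_i = min_{j >= i} p_(j) * n / j, mapped back to input order
  set.seed(71)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    n <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
    oracle <- numeric(n); oracle[o] <- pmin(q_sorted, 1)
    expect_equal(bh_fdr(p), oracle)
  }
})

test_that("the ASE decision rule is exactly |log2FC| > 1 and FDR < 0.01", {
  set.seed(72)
  counts <- sim_counts_matrix(500, 3, exp(rnorm(500, log(200), 0.6)),
                              ase_idx = 1:100, log2fc = 3)
  pairs <- data.frame(gene_a = paste0("p", 1:500, "_A"),
                      gene_b = paste0("p", 1:500, "_B"))
  res <- ase_analyze(counts, pairs)
  expect_equal(res$is_ase, abs(res$log2fc) > 1 & res$fdr < 0.01)
  expect_true(all(res$direction[res$is_ase & res$log2fc > 0] == "A"))
  expect_true(all(res$direction[res$is_ase & res$log2fc < 0] == "B"))
  expect_true(all(res$direction[!res$is_ase] == "none"))
})

test_that("ASE block runs follow the strict consecutive rule", {
  mk_rec <- function(dirs) data.frame(
    pair = paste0("p", seq_along(dirs)), experiment = "e",
    count_a = 1, count_b = 1, log2fc = 0, p_value = 1, fdr = 1,
    is_ase = dirs %in% c("A", "B"), direction = dirs,
    stringsAsFactors = FALSE)
  ord <- function(n) data.frame(pair = paste0("p", 1:n), chrom = "c1")
  b1 <- call_ase_blocks(mk_rec(rep("A", 4)), ord(4))
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_genes, 4L)
  ## three is not "more than three"
  b2 <- call_ase_blocks(mk_rec(rep("A", 3)), ord(3))
  expect_equal(nrow(b2), 0L)
  ## hand trace: [A,A,B,A,A,A,A,none,B,B,B,B] -> pairs 4-7 (A), 9-12 (B)
  dirs <- c("A", "A", "B", "A", "A", "A", "A", "none",
            "B", "B", "B", "B")
  b3 <- call_ase_blocks(mk_rec(dirs), ord(12))
  expect_equal(nrow(b3), 2L)
  expect_equal(b3$first_pair, c("p4", "p9"))
  expect_equal(b3$n_genes, c(4L, 4L))
  expect_equal(b3$direction, c("A", "B"))
  ## blocks are disjoint and co-directional by construction
  members <- strsplit(b3$member_pairs, ",")
  expect_length(intersect(members[[1L]], members[[2L]]), 0L)
})

test_that("sharing summary reproduces the printed fractions", {
  expect_equal(sharing_fraction(8183, 14829), 55.18)
  expect_equal(sharing_fraction(12150, 14829), 81.93)
  sets <- list(e1 = c("a", "b", "c"), e2 = c("a", "b", "c"),
               e3 = c("a", "b", "c"))
  sh <- sharing_summary(sets)
  expect_equal(sh$pct_all, 100)
  expect_equal(sh$union_size, 3L)
  sets2 <- list(e1 = c("a", "b"), e2 = c("b", "c"))
  sh2 <- sharing_summary(sets2)
  expect_equal(sh2$union_size, 3L)
  expect_equal(sh2$n_all, 1L)
  expect_equal(sh2$n_at_least, c(3L, 1L))
})

test_that("shared blocks require pairwise overlap of >= 3 member pairs", {
  mk_blocks <- function(member_sets, dirs) data.frame(
    chrom = "c1", first_pair = vapply(member_sets, `[`, "", 1L),
    n_genes = lengths(member_sets), direction = dirs,
    member_pairs = vapply(member_sets, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  b <- mk_blocks(list(paste0("p", 1:5)), "A")
  ## identical lists across experiments -> shared
  sh <- shared_blocks(list(b, b, b))
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$n_pairs, 5L)
  ## overlap of only 2 pairs -> not shared
  b2 <- mk_blocks(list(c("p4", "p5", "x1", "x2")), "A")
  expect_equal(nrow(shared_blocks(list(b, b2))), 0L)
  ## direction must match
  b3 <- mk_blocks(list(paste0("p", 1:5)), "B")
  expect_equal(nrow(shared_blocks(list(b, b3))), 0L)
})

test_that("planted common blocks are recovered among per-experiment noise", {
  set.seed(73)
  common <- lapply(1:10, function(i) paste0("c", i, "_", 1:5))
  dirs <- sample(c("A", "B"), 10, replace = TRUE)
  exps <- lapply(1:4, function(e) {
    noise <- lapply(1:5, function(j)
      paste0("n", e, "_", j, "_", 1:4))
    sets <- c(common, noise)
    d <- c(dirs, sample(c("A", "B"), 5, replace = TRUE))
    ord <- sample(length(sets))
    data.frame(chrom = "c1",
               first_pair = vapply(sets[ord], `[`, "", 1L),
               n_genes = lengths(sets[ord]),
               direction = d[ord],
               member_pairs = vapply(sets[ord], paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  })
  sh <- shared_blocks(exps)
  expect_equal(nrow(sh), 10L)
  expect_setequal(sh$member_pairs,
                  vapply(common, function(m) paste(sort(m), collapse = ","),
                         ""))
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  hyper_p <- function(a, b, c, d) {
    ## two-sided: sum of all tables with fixed margins whose probability
    ## does not exceed the observed one
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
    probs <- dhyper(lo:hi, r1, n - r1, c1)
    obs <- dhyper(a, r1, n - r1, c1)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(74)
  cnt <- 0L
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if (max(a + b, c + d, a + c, b + d) > 15L) next
    if (a + b == 0L || c + d == 0L || a + c == 0L || b + d == 0L) next
    cnt <- cnt + 1L
    if (cnt %% 7L != 0L) next     # systematic subsample for speed
    tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expect_equal(fisher_exact_2x2(tab), hyper_p(a, b, c, d),
                 tolerance = 1e-9)
  }
  expect_gt(cnt, 1000L)
})

test_that("promoter SV association builds the 2x2 from strand-aware promoters", {
  fx <- fx_diploid()
  ann_both <- structure(list(
    genes = rbind(fx$annotation_a$genes, fx$annotation_b$genes),
    exons = rbind(fx$annotation_a$exons, fx$annotation_b$exons),
    cds = rbind(fx$annotation_a$cds, fx$annotation_b$cds)),
    class = "gene_annotation")
  pairs <- fx$truth$allele_pair_truth
  svs <- call_svs(fx$aln, fx$genome_a, fx$genome_b)
  res <- promoter_sv_association(pairs, pairs$gene_a[1:5], svs, ann_both)
  expect_equal(sum(res$table), nrow(pairs))
  expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
  ## balanced table -> p = 1
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2)), 1)
})

test_that("promoter sequences are strand-aware upstream of the start codon", {
  fx <- fx_snp_only()
  proms <- promoter_sequences(fx$annotation_a, fx$genome_a, 100L)
  g <- fx$annotation_a$genes[1L, ]
  cds <- fx$annotation_a$cds[fx$annotation_a$cds$gene_id == g$gene_id, ]
  if (g$strand == "+") {
    tss <- min(cds$start)
    expect_equal(proms[[g$gene_id]],
                 substr(fx$genome_a[[g$chrom]], tss - 100L, tss - 1L))
  } else {
    tss <- max(cds$end)
    expect_equal(proms[[g$gene_id]],
                 haplodiff:::revcomp(
                   substr(fx$genome_a[[g$chrom]], tss + 1L, tss + 100L)))
  }
})

test_that("IUPAC motif scanning counts both strands with overlaps", {
  ## TATA on TTATAA: forward at 2; reverse strand rc(TATA)=TATA at 2
  ms <- motif_scan(c(p1 = "TTATAA"), c(tata = "TATA"))
  expect_equal(ms$occurrences, 2L)
  expect_equal(ms$promoters_hit, 1L)
  ## N matches every position on both strands
  msn <- motif_scan(c(p1 = "ACGTT"), c(n = "N"))
  expect_equal(msn$occurrences, 10L)
  ## overlapping matches are allowed (3 forward; reverse strand has none)
  mso <- motif_scan(c(p1 = "AAAA"), c(aa = "AA"))
  expect_equal(mso$occurrences, 3L)
  ## empty promoter set
  ms0 <- motif_scan(character(0), c(tata = "TATA"))
  expect_equal(ms0$occurrences, 0L)
  expect_error(motif_scan(c(p = "ACGT"), c(badmotif = "QQ")), "badmotif")
  ## rankings comparable via Spearman
  set.seed(75)
  proms <- setNames(replicate(20, rand_dna_str(200)), paste0("p", 1:20))
  mots <- c(m1 = "TATA", m2 = "GCGC", m3 = "CAAT", m4 = "ACGT")
  r1 <- motif_scan(proms[1:10], mots)
  r2 <- motif_scan(proms[11:20], mots)
  rho <- cor(r1$rank_occurrences, r2$rank_occurrences, method = "spearman")
  expect_true(is.finite(rho))
})

test_that("the full ASE pipeline recovers planted blocks exactly", {
  fx <- fx_diploid()
  expr <- simulate_expression(fx$truth, fx$cfg, fx$annotation_a)
  al <- assign_alleles(fx$annotation_a, fx$annotation_b, fx$genome_a,
                       fx$genome_b, fx$aln$blocks)
  g <- fx$annotation_a$genes
  ord <- g[order(g$chrom, g$start), ]
  pair_order <- data.frame(pair = ord$gene_id, chrom = ord$chrom)
  pair_order <- pair_order[pair_order$pair %in% al$pairs$gene_a, ]
  truth_blocks <- expr$ase_block_truth
  for (e in names(expr$counts)) {
    rec <- ase_analyze(expr$counts[[e]], al$pairs, experiment = e)
    ## invariant: is_ase implies the decision rule
    expect_true(all(abs(rec$log2fc[rec$is_ase]) > 1))
    expect_true(all(rec$fdr[rec$is_ase] < 0.01))
    blocks <- call_ase_blocks(rec, pair_order)
    for (i in seq_len(nrow(truth_blocks))) {
      hit <- blocks$first_pair == truth_blocks$first_pair[i] &
        blocks$n_genes == truth_blocks$n_genes[i] &
        blocks$direction == truth_blocks$direction[i]
      expect_true(any(hit),
                  label = sprintf("block %s in %s",
                                  truth_blocks$first_pair[i], e))
    }
  }
})
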