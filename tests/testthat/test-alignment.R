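test_that("identical sequences give one full-length forward anchor", {
  set.seed(31)
  s <- rand_dna_str(10000)
  an <- find_anchors(s, s)
  fw <- an[an$strand == "+", ]
  expect_equal(nrow(fw), 1L)
  expect_equal(fw$pos_a, 1L)
  expect_equal(fw$length, 10000L)
})

test_that("a reverse-complement sequence gives one full-length minus anchor", {
  set.seed(32)
  s <- rand_dna_str(8000)
  an <- find_anchors(s, haplodiff:::revcomp(s))
  mn <- an[an$strand == "-", ]
  expect_equal(nrow(mn), 1L)
  expect_equal(mn$length, 8000L)
  expect_equal(mn$pos_a, 1L)
  expect_equal(mn$pos_b, 1L)
})

test_that("a single SNP splits the match into two flanking anchors", {
  set.seed(33)
  s <- rand_dna_str(10000)
  b <- s
  old <- substr(b, 5000, 5000)
  substr(b, 5000, 5000) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  an <- find_anchors(s, b)
  fw <- an[an$strand == "+", ]
  fw <- fw[order(fw$pos_a), ]
  expect_equal(nrow(fw), 2L)
  expect_equal(fw$pos_a[1L], 1L)
  expect_equal(fw$length[1L], 4999L)
  expect_equal(fw$pos_a[2L], 5001L)
  expect_equal(fw$length[2L], 5000L)
  ## anchors are exact matches (maximality spot-check at the SNP)
  expect_identical(substr(s, 1, 4999), substr(b, 1, 4999))
})

## exhaustive chaining oracle: best increasing subsequence score over all
## subsets (feasible for <= 10 anchors)
oracle_best_chain <- function(an, max_gap = 1e9) {
  n <- nrow(an)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx)) next
    idx <- idx[order(an$pos_a[idx])]
    ok <- TRUE; sc <- an$length[idx[1L]]
    if (length(idx) > 1L) {
      for (k in 2L:length(idx)) {
        i <- idx[k]; j <- idx[k - 1L]
        if (an$pos_a[j] >= an$pos_a[i] || an$pos_b[j] >= an$pos_b[i]) {
          ok <- FALSE; break
        }
        ga <- max(0L, an$pos_a[i] - (an$pos_a[j] + an$length[j]))
        gb <- max(0L, an$pos_b[i] - (an$pos_b[j] + an$length[j]))
        if (ga > max_gap || gb > max_gap) { ok <- FALSE; break }
        sc <- sc + an$length[i] - (0.05 * abs(ga - gb) + 0.01 * min(ga, gb))
      }
    }
    if (ok && sc > best) best <- sc
  }
  best
}

test_that("chaining matches the exhaustive oracle on small random instances", {
  set.seed(34)
  for (rep in 1:25) {
    n <- sample(3:9, 1L)
    an <- data.frame(pos_a = sample(1:3000, n),
                     pos_b = sample(1:3000, n),
                     length = sample(20:200, n, replace = TRUE),
                     strand = "+")
    chains <- chain_anchors(an, max_gap = 1e9, window = 50L)
    got <- max(vapply(chains, function(ch) attr(ch, "score"), 0))
    expect_equal(got, oracle_best_chain(an), tolerance = 1e-9,
                 label = sprintf("rep %d", rep))
  }
})

test_that("already-collinear anchors form a single chain", {
  an <- data.frame(pos_a = c(1, 300, 700), pos_b = c(1, 300, 700),
                   length = c(100, 100, 100), strand = "+")
  chains <- chain_anchors(an)
  expect_length(chains, 1L)
  expect_equal(nrow(chains[[1L]]), 3L)
})

test_that("interleaved inverted segments give chains of opposite strand", {
  an <- data.frame(pos_a = c(1, 300, 700, 1000),
                   pos_b = c(1, 1200, 700, 500),
                   length = c(100, 100, 100, 100),
                   strand = c("+", "-", "+", "-"))
  chains <- chain_anchors(an, min_chain_anchors = 2L)
  strands <- vapply(chains, function(ch) attr(ch, "strand"), "")
  expect_setequal(strands, c("+", "-"))
})

test_that("an order-breaking anchor is excluded from the main chain", {
  an <- data.frame(pos_a = c(1, 300, 600, 900),
                   pos_b = c(1, 300, 100, 900),   # third breaks B order
                   length = c(100, 100, 30, 100), strand = "+")
  chains <- chain_anchors(an)
  main <- chains[[which.max(vapply(chains, function(ch)
    attr(ch, "score"), 0))]]
  expect_equal(main$pos_a, c(1, 300, 900))
})

test_that("block filtering enforces the span, identity and one-to-one rules", {
  blocks <- data.frame(
    id = 1:3,
    chrom_a = "c1", start_a = c(1, 1, 40000), end_a = c(14999, 20000, 60000),
    chrom_b = "c1", start_b = c(1, 1, 40000), end_b = c(14999, 20000, 60000),
    strand = "+", identity = c(99, 99, 75),
    aligned_length = c(14999, 20000, 20000), n_anchors = 1L,
    score = c(10, 8, 9))
  out <- filter_blocks(blocks)
  expect_equal(out$id, 2L)       # 1: too short; 3: identity < 80

  ## one-to-one: two blocks over the same A interval, best score wins
  twice <- data.frame(
    id = 1:2, chrom_a = "c1", start_a = c(1, 500), end_a = c(20000, 19500),
    chrom_b = c("c1", "c2"), start_b = c(1, 1), end_b = c(20000, 19001),
    strand = "+", identity = c(95, 95),
    aligned_length = c(20000, 16000), n_anchors = 1L, score = c(10, 8))
  out2 <- filter_blocks(twice)
  expect_equal(out2$id, 1L)
})

test_that("block statistics follow the cumulative arithmetic", {
  mk <- function(spans) data.frame(
    id = seq_along(spans), chrom_a = "c", start_a = 1,
    end_a = spans, chrom_b = "c", start_b = 1, end_b = spans,
    strand = "+", identity = 99, aligned_length = spans,
    n_anchors = 1L, score = 1)
  s <- block_stats(mk(c(10000, 20000, 30000)), min_size = 15000)
  expect_equal(s$count, 2L)
  expect_equal(s$mean_size, 25000)
  expect_equal(s$total_size, 50000)
  one <- block_stats(mk(20000), min_size = 15000)
  expect_equal(one$mean_size, 20000)
  empty <- block_stats(mk(1000), min_size = 15000)
  expect_equal(empty$count, 0L)
  expect_null(empty$mean_size)
  expect_equal(empty$total_size, 0)
})

test_that("an SV-free diploid is tiled by blocks covering >= 99% of each chromosome", {
  fx <- fx_snp_only()
  bl <- fx$aln$blocks
  for (ch in unique(bl$chrom_a)) {
    covered <- sum(bl$end_a[bl$chrom_a == ch] -
                     bl$start_a[bl$chrom_a == ch] + 1L)
    expect_gt(covered / 200000, 0.99)
  }
  expect_gt(min(bl$identity), 98)
})

test_that("identical haplotypes yield one perfect block per chromosome", {
  set.seed(35)
  g <- c(c1 = rand_dna_str(30000))
  aln <- align_haplotypes(g, g, min_len = 15000)
  expect_equal(nrow(aln$blocks), 1L)
  expect_equal(aln$blocks$identity, 100)
  expect_gte((aln$blocks$end_a - aln$blocks$start_a + 1) / 30000, 0.999)
})

test_that("filtered blocks never overlap by more than 80% on either axis", {
  fx <- fx_diploid()
  bl <- fx$aln$blocks
  if (nrow(bl) > 1L) {
    for (i in seq_len(nrow(bl) - 1L)) for (j in (i + 1L):nrow(bl)) {
      oa <- haplodiff:::overlap_frac(bl$chrom_a[i], bl$start_a[i], bl$end_a[i],
                                     bl$chrom_a[j], bl$start_a[j], bl$end_a[j])
      ob <- haplodiff:::overlap_frac(bl$chrom_b[i], bl$start_b[i], bl$end_b[i],
                                     bl$chrom_b[j], bl$start_b[j], bl$end_b[j])
      expect_lte(oa, 0.8); expect_lte(ob, 0.8)
    }
  }
  succeed()
})
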