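## SNP/indel calling inside collinearity blocks and five-type structural
## variant classification (deletion, insertion, duplication, contraction,
## translocation), with haplotype A as the reference.

#' Globally align two gap segments
#'
#' Affine-gap global alignment (match +1, mismatch -2, gap open -4, gap
#' extend -1).  Equal-length segments up to 200 bp are compared column by
#' column directly (the common case between exact-match anchors).
#'
#' @param seg_a,seg_b segment sequences (either may be empty).
#' @return list with `matches`, `columns`, `identity` (percent) and the
#'   gapped alignment strings `aln_a`, `aln_b`.
#' @export
align_gap <- function(seg_a, seg_b) {
  la <- nchar(seg_a); lb <- nchar(seg_b)
  if (la == 0L && lb == 0L)
    return(list(matches = 0L, columns = 0L, identity = 100,
                aln_a = "", aln_b = ""))
  if (la == 0L)
    return(list(matches = 0L, columns = lb, identity = 0,
                aln_a = strrep("-", lb), aln_b = seg_b))
  if (lb == 0L)
    return(list(matches = 0L, columns = la, identity = 0,
                aln_a = seg_a, aln_b = strrep("-", la)))
  if (la == lb && la <= 200L) {
    m <- sum(charToRaw(seg_a) == charToRaw(seg_b))
    return(list(matches = m, columns = la, identity = 100 * m / la,
                aln_a = seg_a, aln_b = seg_b))
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(seg_a, seg_b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 4, gapExtension = 1)
  aa <- as.character(Biostrings::alignedPattern(al))
  ab <- as.character(Biostrings::alignedSubject(al))
  ra <- charToRaw(aa); rb <- charToRaw(ab)
  m <- sum(ra == rb)
  cols <- length(ra)
  list(matches = m, columns = cols, identity = 100 * m / cols,
       aln_a = aa, aln_b = ab)
}

## emit SNP/INS/DEL records from one aligned gap; a_off = A coordinate of
## the first alignment column; indel runs >= sv_floor are skipped
parse_alignment_variants <- function(aln_a, aln_b, a_off, sv_floor = 50L) {
  ra <- strsplit(aln_a, "")[[1L]]
  rb <- strsplit(aln_b, "")[[1L]]
  n <- length(ra)
  out <- list()
  apos <- a_off - 1L
  i <- 1L
  while (i <= n) {
    if (ra[i] != "-" && rb[i] != "-") {
      apos <- apos + 1L
      if (ra[i] != rb[i])
        out[[length(out) + 1L]] <- list(pos = apos, ref = ra[i],
                                        alt = rb[i], vtype = "SNP")
      i <- i + 1L
    } else if (rb[i] == "-") {            # run deleted in B
      j <- i
      while (j <= n && rb[j] == "-") j <- j + 1L
      run <- paste(ra[i:(j - 1L)], collapse = "")
      if (nchar(run) < sv_floor)
        out[[length(out) + 1L]] <- list(pos = apos + 1L, ref = run,
                                        alt = "", vtype = "DEL")
      apos <- apos + (j - i)
      i <- j
    } else {                              # run inserted in B
      j <- i
      while (j <= n && ra[j] == "-") j <- j + 1L
      run <- paste(rb[i:(j - 1L)], collapse = "")
      if (nchar(run) < sv_floor)
        out[[length(out) + 1L]] <- list(pos = apos, ref = "",
                                        alt = run, vtype = "INS")
      i <- j
    }
  }
  out
}

## shift an indel to its leftmost equivalent position against sequence A
left_align_indel <- function(pos, seq, vtype, chrom_seq, min_pos = 1L) {
  if (vtype == "DEL") {
    l <- nchar(seq)
    while (pos > min_pos &&
             substr(chrom_seq, pos - 1L, pos - 1L) ==
             substr(seq, l, l)) {
      seq <- paste0(substr(chrom_seq, pos - 1L, pos - 1L),
                    substr(seq, 1L, l - 1L))
      pos <- pos - 1L
    }
  } else {                                 # INS sits after `pos`
    l <- nchar(seq)
    while (pos >= min_pos &&
             substr(chrom_seq, pos, pos) == substr(seq, l, l)) {
      seq <- paste0(substr(chrom_seq, pos, pos), substr(seq, 1L, l - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = pos, seq = seq)
}

#' Call SNPs and small indels inside collinearity blocks
#'
#' Walks the inter-anchor gaps of every block, aligns them at base level
#' and reports mismatch columns as SNPs and gap runs shorter than 50 bp as
#' insertions/deletions with haplotype A as the reference.  Indels are
#' left-aligned against A.  No variant is emitted outside a block.
#'
#' @param blocks filtered block data.frame from [align_haplotypes()] (with
#'   its `anchors` attribute).
#' @param genome_a,genome_b named character vectors of chromosomes.
#' @param gap_limit gaps larger than this on either side are left to the SV
#'   caller.
#' @return data.frame with `chrom_a`, `pos_a`, `ref`, `alt`, `vtype`
#'   (`SNP`/`INS`/`DEL`), `block_id`.
#' @export
call_small_variants <- function(blocks, genome_a, genome_b,
                                gap_limit = 100000L) {
  genome_a <- as_seq_char(genome_a); genome_b <- as_seq_char(genome_b)
  anchors <- attr(blocks, "anchors")
  out <- list()
  for (bi in seq_len(nrow(blocks))) {
    ch <- anchors[[bi]]
    if (is.null(ch) || nrow(ch) < 2L) next
    strand <- blocks$strand[bi]
    seq_a <- genome_a[[blocks$chrom_a[bi]]]
    seq_b <- genome_b[[blocks$chrom_b[bi]]]
    ch <- ch[order(ch$pos_a), , drop = FALSE]
    for (i in seq_len(nrow(ch) - 1L)) {
      gap <- chain_gap(ch, i, strand, nchar(seq_b))
      if (gap$ga < 0L || gap$gb < 0L) next
      if (gap$ga == 0L && gap$gb == 0L) next
      if (abs(gap$ga - gap$gb) >= 50L) next        # SV-scale gap
      if (max(gap$ga, gap$gb) > gap_limit) next
      ga_seq <- if (gap$ga > 0L) substr(seq_a, gap$a_from, gap$a_to) else ""
      gb_seq <- if (gap$gb > 0L) substr(seq_b, gap$b_from, gap$b_to) else ""
      if (strand == "-" && gap$gb > 0L) gb_seq <- revcomp(gb_seq)
      al <- align_gap(ga_seq, gb_seq)
      vars <- parse_alignment_variants(al$aln_a, al$aln_b, gap$a_from)
      for (v in vars) {
        if (v$vtype != "SNP") {
          seqv <- if (v$vtype == "DEL") v$ref else v$alt
          la <- left_align_indel(v$pos, seqv, v$vtype, seq_a,
                                 min_pos = blocks$start_a[bi])
          v$pos <- la$pos
          if (v$vtype == "DEL") v$ref <- la$seq else v$alt <- la$seq
        }
        out[[length(out) + 1L]] <- data.frame(
          chrom_a = blocks$chrom_a[bi], pos_a = v$pos, ref = v$ref,
          alt = v$alt, vtype = v$vtype, block_id = blocks$id[bi],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom_a = character(0), pos_a = integer(0),
               ref = character(0), alt = character(0), vtype = character(0),
               block_id = integer(0), stringsAsFactors = FALSE)
  res[order(res$chrom_a, res$pos_a), , drop = FALSE]
}

#' Heterozygosity rate as a printed percentage
#'
#' `100 * n_variants / genome_size`, rounded half away from zero to two
#' decimals — the convention used for whole-genome heterozygosity reports.
#'
#' @param n_variants heterozygous variant count.
#' @param genome_size haploid reference size in bases (> 0).
#' @return percentage with two decimals.
#' @export
heterozygosity_rate <- function(n_variants, genome_size) {
  stop_if_not(genome_size > 0, "genome_size must be > 0")
  round_half_up(100 * n_variants / genome_size, 2)
}

## fraction of identical characters between two equal-length strings
exact_frac <- function(x, y) {
  if (nchar(x) != nchar(y) || nchar(x) == 0L) return(0)
  mean(charToRaw(x) == charToRaw(y))
}

## similarity of an SV's extra sequence to a flank copy: cheap positional
## identity first, full alignment as fallback (copies may carry indels)
flank_match <- function(x, y) {
  if (!nchar(x) || !nchar(y)) return(0)
  if (abs(nchar(x) - nchar(y)) / max(nchar(x), nchar(y)) > 0.3) return(0)
  f <- exact_frac(x, y)
  if (f >= 0.9) return(f)
  align_gap(x, y)$identity / 100
}

## tandem copy-number evidence: the haplotype carrying two copies of a
## unit of length `u` is periodic at lag u around the breakpoint.  The
## breakpoint of a tandem gain/loss is only defined up to rotation of the
## unit, so periodicity is tested rather than a fixed-phase comparison;
## a small lag jitter absorbs small indels planted inside one copy.
tandem_period_match <- function(window, u, jitter = 10L) {
  n <- nchar(window)
  best <- 0
  r <- charToRaw(window)
  for (lag in (u - jitter):(u + jitter)) {
    if (lag < 1L || n < lag + lag) next
    eq <- as.integer(r[seq_len(n - lag)] == r[(lag + 1L):n])
    cs <- c(0L, cumsum(eq))
    w <- min(u, length(eq))
    frac <- max(cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]) / u
    best <- max(best, frac)
  }
  best
}

#' Call structural variants (five types)
#'
#' Inter-anchor gaps with at least `min_size` size difference become
#' deletions (A-side larger) or insertions (B-side larger); an event whose
#' size makes the sequence around the breakpoint periodic (lag = event
#' size, 90% matching over one period) on the haplotype carrying two
#' copies is reclassified as a copy-number event: a copy lost by B is a
#' contraction, a copy gained by B a duplication.  A block whose partner chromosome
#' differs from the dominant partner of its A chromosome, or whose B
#' position breaks the median order of its 5 nearest neighbors, is a
#' translocation.
#'
#' @param alignment result of [align_haplotypes()].
#' @param genome_a,genome_b named character vectors of chromosomes.
#' @param min_size SV size floor in bases (default 50).
#' @return data.frame with `svtype`, `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `size`.
#' @export
call_svs <- function(alignment, genome_a, genome_b, min_size = 50L) {
  genome_a <- as_seq_char(genome_a); genome_b <- as_seq_char(genome_b)
  blocks <- alignment$blocks
  anchors <- attr(blocks, "anchors")
  out <- list()
  emit <- function(svtype, chrom_a, start_a, end_a, chrom_b, start_b,
                   end_b, size) {
    out[[length(out) + 1L]] <<- data.frame(
      svtype = svtype, chrom_a = chrom_a, start_a = start_a, end_a = end_a,
      chrom_b = chrom_b, start_b = start_b, end_b = end_b, size = size,
      stringsAsFactors = FALSE)
  }

  for (bi in seq_len(nrow(blocks))) {
    ch <- anchors[[bi]]
    if (is.null(ch) || nrow(ch) < 2L) next
    strand <- blocks$strand[bi]
    seq_a <- genome_a[[blocks$chrom_a[bi]]]
    seq_b <- genome_b[[blocks$chrom_b[bi]]]
    ch <- ch[order(ch$pos_a), , drop = FALSE]
    for (i in seq_len(nrow(ch) - 1L)) {
      gap <- chain_gap(ch, i, strand, nchar(seq_b))
      if (gap$ga < 0L || gap$gb < 0L) next
      diff <- gap$ga - gap$gb
      if (abs(diff) < min_size) next
      ## refine the breakpoint at base level when the gap mixes the SV
      ## with nearby small variants (both sides non-empty)
      refined <- NULL
      if (min(gap$ga, gap$gb) > 0L && max(gap$ga, gap$gb) <= 20000L) {
        ga_seq <- substr(seq_a, gap$a_from, gap$a_to)
        gb_seq <- substr(seq_b, gap$b_from, gap$b_to)
        if (strand == "-") gb_seq <- revcomp(gb_seq)
        al <- align_gap(ga_seq, gb_seq)
        runs <- parse_alignment_variants(al$aln_a, al$aln_b, gap$a_from,
                                         sv_floor = .Machine$integer.max)
        runs <- Filter(function(v) v$vtype != "SNP" &&
                         nchar(paste0(v$ref, v$alt)) >= min_size, runs)
        if (length(runs)) {
          lens <- vapply(runs, function(v) nchar(paste0(v$ref, v$alt)), 0L)
          refined <- runs[[which.max(lens)]]
        }
      }
      ## copy-number evidence windows around the B- and A-side breakpoints
      b_lo <- min(gap$b_from, gap$b_to); b_hi <- max(gap$b_from, gap$b_to)
      win_b <- function(size) {
        w <- substr(seq_b, max(1L, b_lo - size - 50L), b_hi + size + 50L)
        if (strand == "-") revcomp(w) else w
      }
      win_a <- function(size)
        substr(seq_a, max(1L, gap$a_from - size - 50L), gap$a_to + size + 50L)

      if (!is.null(refined) && refined$vtype == "DEL") {
        s <- refined$pos; e <- refined$pos + nchar(refined$ref) - 1L
        size <- nchar(refined$ref)
        ## copy loss: A (two copies) is periodic at lag `size` here
        svtype <- if (tandem_period_match(win_a(size), size) >= 0.9)
          "contraction" else "deletion"
        emit(svtype, blocks$chrom_a[bi], s, e, blocks$chrom_b[bi],
             gap$b_from, gap$b_to, size)
        next
      }
      if (!is.null(refined) && refined$vtype == "INS") {
        size <- nchar(refined$alt)
        p0 <- refined$pos
        ## copy gain: B (two copies) is periodic at lag `size` here
        svtype <- if (tandem_period_match(win_b(size), size) >= 0.9)
          "duplication" else "insertion"
        emit(svtype, blocks$chrom_a[bi], p0, p0, blocks$chrom_b[bi],
             gap$b_from, gap$b_to, size)
        next
      }
      if (diff > 0L) {                       # extra sequence on A
        size <- diff
        s <- gap$a_from + gap$gb; e <- gap$a_to
        unit <- substr(seq_a, s, s + size - 1L)
        svtype <- if (tandem_period_match(win_a(size), size) >= 0.9)
          "contraction" else "deletion"
        emit(svtype, blocks$chrom_a[bi], s, e, blocks$chrom_b[bi],
             gap$b_from, gap$b_to, size)
      } else {                               # extra sequence on B
        size <- -diff
        bs <- gap$b_from + gap$ga; be <- gap$b_to
        ins <- substr(seq_b, bs, bs + size - 1L)
        if (strand == "-") ins <- revcomp(ins)
        svtype <- if (tandem_period_match(win_b(size), size) >= 0.9)
          "duplication" else "insertion"
        emit(svtype, blocks$chrom_a[bi], gap$a_from,
             max(gap$a_from, gap$a_to), blocks$chrom_b[bi], bs, be, size)
      }
    }
  }

  ## translocations from the unfiltered chain set
  ba <- alignment$blocks_all
  ba <- ba[(ba$end_a - ba$start_a + 1L) >= min_size, , drop = FALSE]
  for (ca in unique(ba$chrom_a)) {
    sub <- ba[ba$chrom_a == ca, , drop = FALSE]
    sub <- sub[order(sub$start_a), , drop = FALSE]
    span <- sub$end_a - sub$start_a + 1L
    tot <- tapply(span, sub$chrom_b, sum)
    dom <- names(tot)[which.max(tot)]
    for (i in seq_len(nrow(sub))) {
      if (sub$chrom_b[i] != dom) {
        emit("translocation", ca, sub$start_a[i], sub$end_a[i],
             sub$chrom_b[i], sub$start_b[i], sub$end_b[i],
             sub$end_a[i] - sub$start_a[i] + 1L)
        next
      }
      ## order test against up to 5 nearest same-partner neighbors
      same <- which(sub$chrom_b == dom & seq_len(nrow(sub)) != i)
      if (length(same) < 2L) next
      d <- abs(sub$start_a[same] - sub$start_a[i])
      nb <- same[order(d)][seq_len(min(5L, length(same)))]
      off_i <- midpoint(sub$start_b[i], sub$end_b[i]) -
        midpoint(sub$start_a[i], sub$end_a[i])
      off_nb <- stats::median(midpoint(sub$start_b[nb], sub$end_b[nb]) -
                                midpoint(sub$start_a[nb], sub$end_a[nb]))
      span_i <- sub$end_a[i] - sub$start_a[i] + 1L
      if (abs(off_i - off_nb) > max(100000, 10 * span_i))
        emit("translocation", ca, sub$start_a[i], sub$end_a[i],
             sub$chrom_b[i], sub$start_b[i], sub$end_b[i], span_i)
    }
  }

  res <- if (length(out)) do.call(rbind, out) else
    data.frame(svtype = character(0), chrom_a = character(0),
               start_a = integer(0), end_a = integer(0),
               chrom_b = character(0), start_b = integer(0),
               end_b = integer(0), size = integer(0),
               stringsAsFactors = FALSE)
  unique(res[order(res$chrom_a, res$start_a), , drop = FALSE])
}

midpoint <- function(s, e) (as.numeric(s) + as.numeric(e)) / 2

#' Count heterozygous variants per sample in a multi-sample VCF
#'
#' A genotype is heterozygous when it carries two distinct called alleles;
#' missing and half-called genotypes contribute to no sample.  Results are
#' ranked in descending order.
#'
#' @param vcf_path path to a VCF with GT fields.
#' @return named integer vector of heterozygous-genotype counts, sorted
#'   descending.
#' @export
count_het_per_sample <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (ncol(v@gt) < 2L || !any(grepl("GT", v@gt[, 1L])))
    stop(sprintf("no GT format field in %s", vcf_path), call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  het <- apply(gt, 2L, function(g) {
    al <- strsplit(g, "[/|]")
    sum(vapply(al, function(a) {
      length(a) == 2L && !any(a %in% c(".", "")) && a[1L] != a[2L]
    }, TRUE), na.rm = TRUE)
  })
  sort(het, decreasing = TRUE)
}

#' Summarize small variants by type
#'
#' @param variants data.frame from [call_small_variants()].
#' @return list with per-type counts and the total (`snp + ins + del`).
#' @export
summarize_variants <- function(variants) {
  n_snp <- sum(variants$vtype == "SNP")
  n_ins <- sum(variants$vtype == "INS")
  n_del <- sum(variants$vtype == "DEL")
  list(snp = n_snp, ins = n_ins, del = n_del,
       total = n_snp + n_ins + n_del)
}

#' Write small variants as a minimal VCF 4.2 (haplotype A as reference)
#'
#' Indels use the anchored-base convention (the base before a deletion /
#' at an insertion point is included in REF and ALT).
#'
#' @param variants data.frame from [call_small_variants()].
#' @param genome_a named character vector of A chromosomes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genome_a, path) {
  genome_a <- as_seq_char(genome_a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##reference=haplotypeA"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$vtype == "SNP") {
      pos <- v$pos_a; ref <- v$ref; alt <- v$alt
    } else if (v$vtype == "DEL") {
      pos <- v$pos_a - 1L
      base <- substr(genome_a[[v$chrom_a]], pos, pos)
      ref <- paste0(base, v$ref); alt <- base
    } else {
      pos <- v$pos_a
      base <- substr(genome_a[[v$chrom_a]], pos, pos)
      ref <- base; alt <- paste0(base, v$alt)
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s",
                       v$chrom_a, pos, ref, alt, v$vtype), con)
  }
  invisible(path)
}

#' Export SVs as TSV and BEDPE
#'
#' @param svs data.frame from [call_svs()].
#' @param path_tsv,path_bedpe output files (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_svs <- function(svs, path_tsv = NULL, path_bedpe = NULL) {
  if (!is.null(path_tsv))
    write.table(svs, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_bedpe)) {
    bed <- data.frame(chrom1 = svs$chrom_a, start1 = svs$start_a - 1L,
                      end1 = svs$end_a, chrom2 = svs$chrom_b,
                      start2 = svs$start_b - 1L, end2 = svs$end_b,
                      name = svs$svtype, score = svs$size)
    write.table(bed, path_bedpe, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(path_tsv, path_bedpe))
}
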