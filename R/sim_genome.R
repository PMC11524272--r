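## Synthetic diploid genome with planted truth.
##
## Haplotype A is generated de novo (random sequence at a target GC with
## simple multi-exon gene models); haplotype B is derived from A by planting
## SNPs, small indels and structural variants, with the full event list
## returned as a truth record so recovery can be scored exactly.

# ---- gene model geometry ------------------------------------------------

## draw the exon/intron geometry for one gene; returns list of lengths
draw_gene_geometry <- function() {
  n_exons <- sample(1:5, 1L, prob = c(0.15, 0.3, 0.25, 0.2, 0.1))
  exon_len <- sample(120:500, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1L) sample(60:800, n_exons - 1L, replace = TRUE)
                else integer(0)
  utr5 <- sample(30:120, 1L)
  utr3 <- sample(30:120, 1L)
  ## CDS = exonic length minus the UTRs; pad utr3 so CDS is a codon multiple
  cds <- sum(exon_len) - utr5 - utr3
  utr3 <- utr3 + cds %% 3L
  cds <- sum(exon_len) - utr5 - utr3
  if (cds < 90L) {            # guarantee a codable CDS
    pad <- 90L - cds
    pad <- pad + (3L - pad %% 3L) %% 3L
    exon_len[1L] <- exon_len[1L] + pad
  }
  list(exon_len = exon_len, intron_len = intron_len,
       utr5 = utr5, utr3 = utr3,
       span = sum(exon_len) + sum(intron_len))
}

## materialize one gene at genomic offset `start` (1-based) on `strand`
build_gene <- function(gene_id, chrom, start, strand, geom) {
  n_exons <- length(geom$exon_len)
  ex_start <- integer(n_exons); ex_end <- integer(n_exons)
  pos <- start
  for (i in seq_len(n_exons)) {
    ex_start[i] <- pos
    ex_end[i] <- pos + geom$exon_len[i] - 1L
    pos <- ex_end[i] + 1L
    if (i < n_exons) pos <- pos + geom$intron_len[i]
  }
  g_end <- ex_end[n_exons]
  ## UTR5 sits at the transcription start: genomic left for "+", right for "-"
  if (strand == "+") {
    cds_left <- ex_start[1L] + geom$utr5
    cds_right <- g_end - geom$utr3
  } else {
    cds_left <- ex_start[1L] + geom$utr3
    cds_right <- g_end - geom$utr5
  }
  cds <- data.frame(start = pmax(ex_start, cds_left),
                    end = pmin(ex_end, cds_right))
  cds <- cds[cds$start <= cds$end, , drop = FALSE]
  list(
    gene = data.frame(gene_id = gene_id, chrom = chrom, start = start,
                      end = g_end, strand = strand,
                      stringsAsFactors = FALSE),
    exons = data.frame(gene_id = gene_id, chrom = chrom, start = ex_start,
                       end = ex_end, strand = strand,
                       rank = seq_len(n_exons), stringsAsFactors = FALSE),
    cds = data.frame(gene_id = gene_id, chrom = chrom, start = cds$start,
                     end = cds$end, strand = strand,
                     rank = seq_len(nrow(cds)), stringsAsFactors = FALSE)
  )
}

# ---- haplotype A --------------------------------------------------------

#' Generate haplotype A of a synthetic diploid
#'
#' Draws random chromosome sequences at the configured GC content and places
#' non-overlapping, strand-balanced gene models (1-5 exons, 5'/3' UTRs, CDS
#' with a valid start and stop codon written into the sequence).  When the
#' configuration requests contraction SVs, the corresponding number of
#' tandem duplicated units is planted in intergenic space (recorded in
#' `attr(genome, "tandem_loci")`) so that haplotype B can lose one copy.
#'
#' @param config a [sim_config()] object.
#' @return list with `genome` (named character vector, chromosomes suffixed
#'   `_A`) and `annotation` (a `gene_annotation` list with `genes`, `exons`,
#'   `cds` data frames).
#' @export
generate_haplotype_a <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$chrom_length
  margin <- 3000L; min_gap <- 2000L
  genome <- character(config$n_chromosomes)
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes), "_A")
  genes <- list(); exons <- list(); cds <- list()
  tandem <- list()
  n_tandem <- config$sv_counts[["contraction"]]
  unit_rng <- config$sv_length_range

  p <- c((1 - config$gc_content) / 2, config$gc_content / 2,
         config$gc_content / 2, (1 - config$gc_content) / 2)

  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- names(genome)[ci]
    ng <- config$n_genes_per_chrom
    geoms <- if (ng > 0L) replicate(ng, draw_gene_geometry(), simplify = FALSE)
             else list()
    need <- sum(vapply(geoms, `[[`, 0, "span")) + (ng + 1L) * min_gap +
      2L * margin
    if (need > L)
      stop(sprintf("cannot place %d genes (need %d bp) on a %d bp chromosome",
                   ng, need, L), call. = FALSE)
    slack <- L - need
    extra <- as.integer(stats::rmultinom(1L, slack, rep(1, ng + 1L)))
    strands <- sample(rep(c("+", "-"), length.out = ng))
    seq_codes <- sample(0:3, L, replace = TRUE, prob = p)
    pos <- margin + 1L
    chrom_genes <- list()
    for (gi in seq_along(geoms)) {
      pos <- pos + min_gap + extra[gi]
      gid <- sprintf("g%d_%03d_A", ci, gi)
      gene <- build_gene(gid, chrom, pos, strands[gi], geoms[[gi]])
      ## write start/stop codons into the sequence (strand-aware)
      cl <- min(gene$cds$start); cr <- max(gene$cds$end)
      if (strands[gi] == "+") {
        seq_codes[cl:(cl + 2L)] <- c(0L, 3L, 2L)        # ATG
        seq_codes[(cr - 2L):cr] <- c(3L, 0L, 0L)        # TAA
      } else {
        seq_codes[(cr - 2L):cr] <- c(1L, 0L, 3L)        # CAT = rc(ATG)
        seq_codes[cl:(cl + 2L)] <- c(3L, 3L, 0L)        # TTA = rc(TAA)
      }
      genes[[length(genes) + 1L]] <- gene$gene
      exons[[length(exons) + 1L]] <- gene$exons
      cds[[length(cds) + 1L]] <- gene$cds
      chrom_genes[[gi]] <- gene$gene
      pos <- gene$gene$end + 1L
    }
    ## plant tandem units (for later contraction events) in intergenic gaps
    if (n_tandem > 0L && ci == 1L) {
      gdf <- if (length(chrom_genes)) do.call(rbind, chrom_genes) else
        data.frame(start = integer(0), end = integer(0))
      bounds <- sort(c(margin, gdf$start, gdf$end, L - margin))
      gaps <- data.frame(start = head(bounds, -1L) + 1L,
                         end = tail(bounds, -1L) - 1L)
      gaps <- gaps[seq(1L, nrow(gaps), by = 2L), , drop = FALSE]  # intergenic
      placed <- 0L
      for (gi in order(-(gaps$end - gaps$start))) {
        if (placed >= n_tandem) break
        u <- sample(seq(unit_rng[1L], unit_rng[2L]), 1L)
        s <- gaps$start[gi] + 500L
        if (s + 2L * u + 500L > gaps$end[gi]) next
        seq_codes[(s + u):(s + 2L * u - 1L)] <- seq_codes[s:(s + u - 1L)]
        tandem[[length(tandem) + 1L]] <-
          data.frame(chrom = chrom, start = s, unit_len = u)
        placed <- placed + 1L
      }
    }
    genome[ci] <- codes_to_seq(seq_codes)
  }
  empty_genes <- data.frame(gene_id = character(0), chrom = character(0),
                            start = integer(0), end = integer(0),
                            strand = character(0), stringsAsFactors = FALSE)
  empty_feat <- cbind(empty_genes, rank = integer(0))
  annotation <- structure(list(
    genes = if (length(genes)) do.call(rbind, genes) else empty_genes,
    exons = if (length(exons)) do.call(rbind, exons) else empty_feat,
    cds = if (length(cds)) do.call(rbind, cds) else empty_feat
  ), class = "gene_annotation")
  attr(genome, "tandem_loci") <- if (length(tandem)) do.call(rbind, tandem)
                                 else NULL
  list(genome = genome, annotation = annotation)
}

# ---- haplotype B (mutation + liftover) ----------------------------------

## sample `n` intervals of lengths `lens` avoiding `busy` intervals with a
## guard zone, bounded retries
place_intervals <- function(n, lens, chrom_len, busy, guard = 1000L,
                            max_try = 1000L) {
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      s <- sample(seq(guard + 1L, chrom_len - lens[i] - guard), 1L)
      e <- s + lens[i] - 1L
      clash <- nrow(busy) && any(busy$start <= e + guard & busy$end >= s - guard)
      if (!clash) {
        out <- rbind(out, data.frame(start = s, end = e))
        busy <- rbind(busy, data.frame(start = s, end = e))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place non-overlapping SV events; reduce counts or lengths",
           call. = FALSE)
  }
  list(intervals = out, busy = busy)
}

random_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes_to_seq(sample(0:3, n, replace = TRUE, prob = p))
}

## TRUE for candidate positions within `guard` of any interval
near_intervals <- function(pos, starts, ends, guard = 5L) {
  if (!length(starts) || !length(pos)) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (j in seq_along(starts))
    hit <- hit | (pos >= starts[j] - guard & pos <= ends[j] + guard)
  hit
}

#' Derive haplotype B by planting variants into haplotype A
#'
#' Plants heterozygous SNPs and small indels at the configured per-base
#' rates, the requested structural variants (deletion, insertion,
#' duplication, contraction, translocation), and deletes the B copy of a
#' configured fraction of genes (these become haplotype-A-specific).  The
#' A annotation is lifted through the resulting coordinate map; genes
#' overlapped by an SV deletion are dropped, not truncated.
#'
#' Duplications, insertions, contractions and translocations are placed in
#' intergenic space so the gene-level truth stays unambiguous; SV events
#' never overlap each other (1 kb guard zone, bounded retries, then error).
#'
#' @param genome_a named character vector from [generate_haplotype_a()].
#' @param annotation_a the matching `gene_annotation`.
#' @param config the [sim_config()] used to generate A.
#' @return list with `genome` (chromosomes suffixed `_B`), `annotation`
#'   (lifted B annotation) and `truth` (a `diploid_truth` list: planted
#'   SNPs/indels/SVs, allele-pair truth, haplotype-specific truth).
#' @export
mutate_to_haplotype_b <- function(genome_a, annotation_a, config) {
  validate_sim_config(config)
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  genes_a <- annotation_a$genes
  snps <- list(); indels <- list(); svs <- list()
  genome_b <- character(length(genome_a))
  names(genome_b) <- sub("_A$", "_B", names(genome_a))
  ann_b_genes <- list(); ann_b_exons <- list(); ann_b_cds <- list()
  hs_genes <- character(0)
  tandem <- attr(genome_a, "tandem_loci")
  n_tra <- config$sv_counts[["translocation"]]
  tra_plan <- NULL
  sv_rng <- config$sv_length_range

  ## choose genes whose B copy is deleted (haplotype-A-specific truth)
  n_hs <- round(config$haplotype_specific_gene_fraction * nrow(genes_a))
  hs_pick <- if (n_hs > 0L) sample(genes_a$gene_id, n_hs) else character(0)

  for (ci in seq_along(genome_a)) {
    chrom_a <- names(genome_a)[ci]
    seq_a <- genome_a[[ci]]
    L <- nchar(seq_a)
    gch <- genes_a[genes_a$chrom == chrom_a, , drop = FALSE]
    busy <- data.frame(start = gch$start, end = gch$end)  # keep SVs intergenic
    if (!is.null(tandem)) {
      tch <- tandem[tandem$chrom == chrom_a, , drop = FALSE]
      if (nrow(tch))
        busy <- rbind(busy, data.frame(start = tch$start,
                                       end = tch$start + 2L * tch$unit_len - 1L))
    }

    sv_ev <- list()
    add_sv_event <- function(start, end, type, value = "") {
      sv_ev[[length(sv_ev) + 1L]] <<- data.frame(
        start = start, end = end, type = type, value = value,
        stringsAsFactors = FALSE)
    }

    ## -- gene-deletion SVs for haplotype-specific truth
    for (gid in hs_pick) {
      g <- genes_a[genes_a$gene_id == gid, ]
      if (g$chrom != chrom_a) next
      s <- max(1L, g$start - 25L); e <- min(L, g$end + 25L)
      add_sv_event(s, e, "sv_deletion")
      svs[[length(svs) + 1L]] <- data.frame(
        svtype = "deletion", chrom = chrom_a, start_a = s, end_a = e,
        size = e - s + 1L, note = "gene_deletion", stringsAsFactors = FALSE)
      busy <- rbind(busy, data.frame(start = s, end = e))
    }

    ## -- generic SVs (planted on chromosome 1)
    if (ci == 1L) {
      n_del <- config$sv_counts[["deletion"]]
      n_ins <- config$sv_counts[["insertion"]]
      n_dup <- config$sv_counts[["duplication"]]
      if (n_del > 0L) {
        lens <- sample(seq(sv_rng[1L], sv_rng[2L]), n_del, replace = TRUE)
        pl <- place_intervals(n_del, lens, L, busy); busy <- pl$busy
        for (i in seq_len(n_del)) {
          s <- pl$intervals$start[i]; e <- pl$intervals$end[i]
          add_sv_event(s, e, "sv_deletion")
          svs[[length(svs) + 1L]] <- data.frame(
            svtype = "deletion", chrom = chrom_a, start_a = s, end_a = e,
            size = e - s + 1L, note = "", stringsAsFactors = FALSE)
        }
      }
      if (n_ins > 0L) {
        lens <- sample(seq(sv_rng[1L], sv_rng[2L]), n_ins, replace = TRUE)
        pl <- place_intervals(n_ins, rep(1L, n_ins), L, busy); busy <- pl$busy
        for (i in seq_len(n_ins)) {
          p0 <- pl$intervals$start[i]
          ins <- random_dna(lens[i], config$gc_content)
          add_sv_event(p0 + 1L, p0, "sv_insertion", ins)  # after p0
          svs[[length(svs) + 1L]] <- data.frame(
            svtype = "insertion", chrom = chrom_a, start_a = p0,
            end_a = p0, size = lens[i], note = "", stringsAsFactors = FALSE)
        }
      }
      if (n_dup > 0L) {
        lens <- sample(seq(sv_rng[1L], sv_rng[2L]), n_dup, replace = TRUE)
        pl <- place_intervals(n_dup, lens, L, busy); busy <- pl$busy
        for (i in seq_len(n_dup)) {
          s <- pl$intervals$start[i]; e <- pl$intervals$end[i]
          unit <- substr(seq_a, s, e)
          ## B gains a second tandem copy right after the unit
          add_sv_event(e + 1L, e, "sv_insertion", unit)
          svs[[length(svs) + 1L]] <- data.frame(
            svtype = "duplication", chrom = chrom_a, start_a = s, end_a = e,
            size = e - s + 1L, note = "tandem", stringsAsFactors = FALSE)
        }
      }
      ## contractions: drop the second copy of a planted tandem pair
      if (!is.null(tandem)) {
        tch <- tandem[tandem$chrom == chrom_a, , drop = FALSE]
        for (i in seq_len(nrow(tch))) {
          s <- tch$start[i] + tch$unit_len[i]
          e <- tch$start[i] + 2L * tch$unit_len[i] - 1L
          add_sv_event(s, e, "sv_deletion")
          svs[[length(svs) + 1L]] <- data.frame(
            svtype = "contraction", chrom = chrom_a, start_a = s, end_a = e,
            size = tch$unit_len[i], note = "tandem", stringsAsFactors = FALSE)
        }
      }
      if (n_tra > 0L) {
        lens <- sample(seq(sv_rng[1L], sv_rng[2L]), n_tra, replace = TRUE)
        pl <- place_intervals(n_tra, lens, L, busy); busy <- pl$busy
        tra_plan <- cbind(pl$intervals, chrom = chrom_a)
        for (i in seq_len(n_tra)) {
          s <- pl$intervals$start[i]; e <- pl$intervals$end[i]
          add_sv_event(s, e, "sv_deletion")     # removed from source in B
          svs[[length(svs) + 1L]] <- data.frame(
            svtype = "translocation", chrom = chrom_a, start_a = s, end_a = e,
            size = e - s + 1L, note = "source", stringsAsFactors = FALSE)
        }
      }
    }
    ## translocation targets land on the last chromosome
    if (!is.null(tra_plan) && ci == length(genome_a) && n_tra > 0L) {
      pl <- place_intervals(n_tra, rep(1L, n_tra), L, busy); busy <- pl$busy
      for (i in seq_len(n_tra)) {
        p0 <- pl$intervals$start[i]
        seg <- substr(genome_a[[tra_plan$chrom[i]]],
                      tra_plan$start[i], tra_plan$end[i])
        add_sv_event(p0 + 1L, p0, "sv_insertion", seg)
      }
    }

    sv_events <- if (length(sv_ev)) do.call(rbind, sv_ev) else
      data.frame(start = integer(0), end = integer(0),
                 type = character(0), value = character(0),
                 stringsAsFactors = FALSE)

    ## -- SNPs (vectorized; may fall inside genes, only avoid SV events)
    codes <- seq_to_codes(seq_a)
    cand <- which(runif(L) < config$snp_rate)
    cand <- cand[cand > 200L & cand < L - 200L]
    cand <- cand[!near_intervals(cand, sv_events$start, sv_events$end)]
    snp_events <- NULL
    if (length(cand)) {
      alt_codes <- (codes[cand] + sample(1:3, length(cand),
                                         replace = TRUE)) %% 4L
      snps[[length(snps) + 1L]] <- data.frame(
        chrom = chrom_a, pos_a = cand,
        ref = DNA_BASES[codes[cand] + 1L],
        alt = DNA_BASES[alt_codes + 1L], stringsAsFactors = FALSE)
      snp_events <- data.frame(start = cand, end = cand, type = "snp",
                               value = DNA_BASES[alt_codes + 1L],
                               stringsAsFactors = FALSE)
    }

    ## -- small indels: avoid SVs, SNPs and each other (greedy left-to-right).
    ## Copy-number unit regions (tandem pairs, duplication units) are also
    ## excluded: an extra indel inside one copy would make the planted
    ## copy-number truth ambiguous.
    cn_guard <- data.frame(start = integer(0), end = integer(0))
    if (!is.null(tandem)) {
      tch <- tandem[tandem$chrom == chrom_a, , drop = FALSE]
      if (nrow(tch))
        cn_guard <- rbind(cn_guard,
                          data.frame(start = tch$start,
                                     end = tch$start + 2L * tch$unit_len - 1L))
    }
    dup_units <- vapply(svs, function(x)
      x$svtype == "duplication" && x$chrom == chrom_a, TRUE)
    if (any(dup_units)) {
      dd <- do.call(rbind, svs[dup_units])
      cn_guard <- rbind(cn_guard,
                        data.frame(start = dd$start_a, end = dd$end_a))
    }
    icand <- which(runif(L) < config$small_indel_rate)
    icand <- icand[icand > 200L & icand < L - 200L]
    icand <- icand[!near_intervals(icand, sv_events$start, sv_events$end,
                                   guard = 60L)]
    icand <- icand[!near_intervals(icand, cn_guard$start, cn_guard$end,
                                   guard = 10L)]
    indel_events <- NULL
    if (length(icand)) {
      ilen <- sample(seq_len(config$indel_length_max), length(icand),
                     replace = TRUE)
      is_del <- runif(length(icand)) < 0.5
      snp_sorted <- sort(cand)
      keep <- logical(length(icand))
      prev_end <- -10L
      for (j in seq_along(icand)) {
        pos <- icand[j]
        span_end <- pos + ifelse(is_del[j], ilen[j] - 1L, 0L)
        if (pos - 5L <= prev_end) next
        ## no SNP within the indel footprint +- 5 bp
        lo <- findInterval(pos - 6L, snp_sorted)
        hi <- findInterval(span_end + 5L, snp_sorted)
        if (hi > lo) next
        keep[j] <- TRUE
        prev_end <- span_end + 5L
      }
      icand <- icand[keep]; ilen <- ilen[keep]; is_del <- is_del[keep]
      if (length(icand)) {
        ins_seq <- vapply(ilen, function(n) random_dna(n, config$gc_content),
                          "")
        del_seq <- substring(seq_a, icand, icand + ilen - 1L)
        indels[[length(indels) + 1L]] <- data.frame(
          chrom = chrom_a, pos_a = icand,
          type = ifelse(is_del, "DEL", "INS"),
          seq = ifelse(is_del, del_seq, ins_seq),
          len = ilen, stringsAsFactors = FALSE)
        indel_events <- data.frame(
          start = ifelse(is_del, icand, icand + 1L),
          end = ifelse(is_del, icand + ilen - 1L, icand),
          type = ifelse(is_del, "del", "ins"),
          value = ifelse(is_del, "", ins_seq),
          stringsAsFactors = FALSE)
      }
    }

    events <- rbind(sv_events, snp_events, indel_events)

    ## -- apply all events in one replaceAt pass
    if (nrow(events)) {
      events <- events[order(events$start, events$end), , drop = FALSE]
      at <- IRanges::IRanges(start = events$start, end = events$end)
      repl <- events$value
      repl[events$type %in% c("del", "sv_deletion")] <- ""
      bs <- Biostrings::replaceAt(Biostrings::DNAString(seq_a), at,
                                  Biostrings::DNAStringSet(repl))
      genome_b[ci] <- as.character(bs)
    } else {
      genome_b[ci] <- seq_a
    }

    ## -- offset map and annotation lift for this chromosome
    ev <- events
    if (nrow(ev)) {
      ev$delta <- ifelse(ev$type %in% c("del", "sv_deletion"),
                         -(ev$end - ev$start + 1L), nchar(ev$value))
      ev$delta[ev$type == "snp"] <- 0L
      ev <- ev[ev$delta != 0L, , drop = FALSE]
    } else ev$delta <- integer(0)
    lift <- make_lifter(ev)

    ## record B-side coordinates of the planted SVs on this chromosome
    for (si in seq_along(svs)) {
      if (svs[[si]]$chrom != chrom_a || !is.null(svs[[si]]$start_b)) next
      svs[[si]]$start_b <- lift(max(1L, svs[[si]]$start_a - 1L))
      svs[[si]]$end_b <- lift(min(L, svs[[si]]$end_a + 1L))
    }

    sv_del <- sv_events[sv_events$type == "sv_deletion", , drop = FALSE]
    for (gi in seq_len(nrow(gch))) {
      g <- gch[gi, ]
      dropped <- nrow(sv_del) > 0L &&
        any(sv_del$start <= g$end & sv_del$end >= g$start)
      if (dropped) { hs_genes <- c(hs_genes, g$gene_id); next }
      bid <- sub("_A$", "_B", g$gene_id)
      bchrom <- names(genome_b)[ci]
      lift_df <- function(df) {
        df$gene_id <- bid; df$chrom <- bchrom
        df$start <- vapply(df$start, lift, 0L)
        df$end <- vapply(df$end, lift, 0L)
        df
      }
      ann_b_genes[[length(ann_b_genes) + 1L]] <- lift_df(g)
      ex <- annotation_a$exons[annotation_a$exons$gene_id == g$gene_id, ]
      ann_b_exons[[length(ann_b_exons) + 1L]] <- lift_df(ex)
      cc <- annotation_a$cds[annotation_a$cds$gene_id == g$gene_id, ]
      ann_b_cds[[length(ann_b_cds) + 1L]] <- lift_df(cc)
    }
  }

  paired <- setdiff(genes_a$gene_id, hs_genes)
  truth <- structure(list(
    planted_snps = if (length(snps)) do.call(rbind, snps) else
      data.frame(chrom = character(0), pos_a = integer(0),
                 ref = character(0), alt = character(0)),
    planted_indels = if (length(indels)) do.call(rbind, indels) else
      data.frame(chrom = character(0), pos_a = integer(0),
                 type = character(0), seq = character(0), len = integer(0)),
    planted_svs = if (length(svs)) do.call(rbind, svs) else
      data.frame(svtype = character(0), chrom = character(0),
                 start_a = integer(0), end_a = integer(0),
                 size = integer(0), note = character(0),
                 start_b = integer(0), end_b = integer(0)),
    allele_pair_truth = data.frame(gene_a = paired,
                                   gene_b = sub("_A$", "_B", paired),
                                   stringsAsFactors = FALSE),
    haplotype_specific_truth = hs_genes
  ), class = "diploid_truth")

  annotation_b <- structure(list(
    genes = if (length(ann_b_genes)) do.call(rbind, ann_b_genes) else
      annotation_a$genes[0, ],
    exons = if (length(ann_b_exons)) do.call(rbind, ann_b_exons) else
      annotation_a$exons[0, ],
    cds = if (length(ann_b_cds)) do.call(rbind, ann_b_cds) else
      annotation_a$cds[0, ]
  ), class = "gene_annotation")

  list(genome = genome_b, annotation = annotation_b, truth = truth)
}

## closure mapping an A coordinate to B through the planted events;
## positions inside a deleted interval clamp to its left edge
make_lifter <- function(ev) {
  if (!nrow(ev)) return(function(pos) as.integer(pos))
  ev <- ev[order(ev$start), , drop = FALSE]
  starts <- ev$start; ends <- ev$end; deltas <- ev$delta
  cum <- cumsum(deltas)
  function(pos) {
    i <- findInterval(pos, starts)          # events starting at/before pos
    if (i == 0L) return(as.integer(pos))
    ## inside a deletion that starts at/before pos?
    if (deltas[i] < 0L && ends[i] >= pos)
      return(as.integer(starts[i] - 1L + (if (i > 1L) cum[i - 1L] else 0L)))
    as.integer(pos + cum[i])
  }
}
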