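## Genic-location classification (12 categories) and functional-effect
## annotation of between-haplotype variants, in the snpEff taxonomy:
## one location per variant by fixed precedence, effects graded
## HIGH/MODERATE/LOW/MODIFIER.

LOCATION_LEVELS <- c("splice_site_acceptor", "splice_site_donor",
                     "splice_site_region", "utr_5_prime", "utr_3_prime",
                     "exon", "intron", "transcript", "gene",
                     "upstream", "downstream", "intergenic")

HIGH_EFFECTS <- c("frameshift", "stop_gained", "stop_lost", "start_lost",
                  "splice_acceptor_variant", "splice_donor_variant",
                  "transcript_ablation")

## derived interval sets (GRanges) for each location category
build_location_index <- function(annotation, up_down_window = 5000L) {
  g <- annotation$genes; ex <- annotation$exons; cc <- annotation$cds
  gr <- function(df) {
    if (!nrow(df)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand,
                           gene_id = df$gene_id)
  }
  gene_r <- gr(g)
  exon_r <- gr(ex)
  cds_r <- gr(cc)

  ## introns: gaps between consecutive exons of a gene
  introns <- list(); donors <- list(); acceptors <- list(); sregion <- list()
  utr5 <- list(); utr3 <- list()
  for (gi in seq_len(nrow(g))) {
    gid <- g$gene_id[gi]; strand <- g$strand[gi]; chrom <- g$chrom[gi]
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L) {
      for (k in seq_len(nrow(e) - 1L)) {
        is <- e$end[k] + 1L; ie <- e$start[k + 1L] - 1L
        if (ie < is) next
        introns[[length(introns) + 1L]] <-
          data.frame(chrom = chrom, start = is, end = ie, strand = strand,
                     gene_id = gid)
        ## donor = first 2 intronic bases in transcription direction
        if (strand == "+") {
          donors[[length(donors) + 1L]] <-
            data.frame(chrom = chrom, start = is, end = min(is + 1L, ie),
                       strand = strand, gene_id = gid)
          acceptors[[length(acceptors) + 1L]] <-
            data.frame(chrom = chrom, start = max(ie - 1L, is), end = ie,
                       strand = strand, gene_id = gid)
        } else {
          donors[[length(donors) + 1L]] <-
            data.frame(chrom = chrom, start = max(ie - 1L, is), end = ie,
                       strand = strand, gene_id = gid)
          acceptors[[length(acceptors) + 1L]] <-
            data.frame(chrom = chrom, start = is, end = min(is + 1L, ie),
                       strand = strand, gene_id = gid)
        }
        ## splice region: intronic 3-8 bp from either junction
        sregion[[length(sregion) + 1L]] <-
          data.frame(chrom = chrom, start = min(is + 2L, ie),
                     end = min(is + 7L, ie), strand = strand, gene_id = gid)
        sregion[[length(sregion) + 1L]] <-
          data.frame(chrom = chrom, start = max(ie - 7L, is),
                     end = max(ie - 2L, is), strand = strand, gene_id = gid)
        ## splice region: exonic 1-3 bp from the junction
        sregion[[length(sregion) + 1L]] <-
          data.frame(chrom = chrom, start = max(e$end[k] - 2L, e$start[k]),
                     end = e$end[k], strand = strand, gene_id = gid)
        sregion[[length(sregion) + 1L]] <-
          data.frame(chrom = chrom, start = e$start[k + 1L],
                     end = min(e$start[k + 1L] + 2L, e$end[k + 1L]),
                     strand = strand, gene_id = gid)
      }
    }
    ## UTRs: exonic sequence outside the CDS span
    ccg <- cc[cc$gene_id == gid, , drop = FALSE]
    if (nrow(ccg)) {
      cl <- min(ccg$start); cr <- max(ccg$end)
      for (k in seq_len(nrow(e))) {
        if (e$start[k] < cl) {
          left <- data.frame(chrom = chrom, start = e$start[k],
                             end = min(e$end[k], cl - 1L), strand = strand,
                             gene_id = gid)
          if (strand == "+") utr5[[length(utr5) + 1L]] <- left
          else utr3[[length(utr3) + 1L]] <- left
        }
        if (e$end[k] > cr) {
          right <- data.frame(chrom = chrom, start = max(e$start[k], cr + 1L),
                              end = e$end[k], strand = strand, gene_id = gid)
          if (strand == "+") utr3[[length(utr3) + 1L]] <- right
          else utr5[[length(utr5) + 1L]] <- right
        }
      }
    }
  }
  bindgr <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    gr(do.call(rbind, lst))
  }

  ## strand-aware upstream/downstream windows
  up <- g; down <- g
  for (gi in seq_len(nrow(g))) {
    if (g$strand[gi] == "+") {
      up$start[gi] <- max(1L, g$start[gi] - up_down_window)
      up$end[gi] <- g$start[gi] - 1L
      down$start[gi] <- g$end[gi] + 1L
      down$end[gi] <- g$end[gi] + up_down_window
    } else {
      up$start[gi] <- g$end[gi] + 1L
      up$end[gi] <- g$end[gi] + up_down_window
      down$start[gi] <- max(1L, g$start[gi] - up_down_window)
      down$end[gi] <- g$start[gi] - 1L
    }
  }
  up <- up[up$end >= up$start, , drop = FALSE]
  down <- down[down$end >= down$start, , drop = FALSE]

  list(splice_site_acceptor = bindgr(acceptors),
       splice_site_donor = bindgr(donors),
       splice_site_region = bindgr(sregion),
       utr_5_prime = bindgr(utr5),
       utr_3_prime = bindgr(utr3),
       exon = cds_r,                 # coding exon sequence
       intron = bindgr(introns),
       transcript = exon_r,          # within mRNA (exons define the mRNA)
       gene = gene_r,                # within the gene span
       upstream = gr(up),
       downstream = gr(down))
}

#' Classify the genic location of variants
#'
#' Assigns each variant exactly one of the 12 location groups (downstream,
#' exon, gene, intergenic, intron, splice site acceptor/donor/region,
#' transcript, upstream, 3'/5' UTR) by fixed precedence: splice sites
#' first, then UTRs, coding exon, intron, transcript, gene, the
#' strand-aware upstream/downstream windows, and intergenic last.
#'
#' @param variants data.frame with `chrom_a`, `pos_a` and (for indels)
#'   `ref`; the variant's reference footprint is used for overlap.
#' @param annotation a `gene_annotation` (haplotype A).
#' @param up_down_window upstream/downstream window in bases (default
#'   5000, the snpEff convention).
#' @param chrom_sizes optional named vector for bounds checking.
#' @return the input data.frame with `location` and `gene_id` columns.
#' @export
classify_location <- function(variants, annotation, up_down_window = 5000L,
                              chrom_sizes = NULL) {
  if (!nrow(variants)) {
    variants$location <- character(0); variants$gene_id <- character(0)
    return(variants)
  }
  if (!is.null(chrom_sizes)) {
    bad <- variants$pos_a < 1L |
      variants$pos_a > chrom_sizes[variants$chrom_a]
    if (any(bad))
      stop("variant position beyond chromosome bounds", call. = FALSE)
  }
  idx <- build_location_index(annotation, up_down_window)
  width <- pmax(1L, nchar(variants$ref %||% ""))
  vr <- GenomicRanges::GRanges(
    variants$chrom_a,
    IRanges::IRanges(variants$pos_a, variants$pos_a + width - 1L))
  loc <- rep("intergenic", nrow(variants))
  gid <- rep(NA_character_, nrow(variants))
  undecided <- rep(TRUE, nrow(variants))
  for (cat in names(idx)) {
    r <- idx[[cat]]
    if (!length(r)) next
    hits <- GenomicRanges::findOverlaps(vr, r, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    first <- !duplicated(qh)
    sel <- qh[first][undecided[qh[first]]]
    if (length(sel)) {
      sh <- S4Vectors::subjectHits(hits)[first][undecided[qh[first]]]
      loc[sel] <- cat
      gid[sel] <- r$gene_id[sh]
      undecided[sel] <- FALSE
    }
  }
  variants$location <- loc
  variants$gene_id <- gid
  variants
}

#' Classify the coding effect of variants
#'
#' For variants overlapping CDS or splice sites: frameshift (indel length
#' not a codon multiple), stop_gained, stop_lost, start_lost, missense,
#' synonymous, inframe_insertion/deletion; splice donor/acceptor SNVs are
#' HIGH.  Variants outside CDS and splice sites are MODIFIER.
#'
#' @param variants data.frame with `chrom_a`, `pos_a`, `ref`, `alt`,
#'   `vtype` and a `location` column from [classify_location()].
#' @param annotation a `gene_annotation`.
#' @param genome named character vector of A chromosomes.
#' @return input data.frame with `effect` and `impact` columns.
#' @export
classify_effect <- function(variants, annotation, genome) {
  genome <- as_seq_char(genome)
  effect <- rep("non_coding", nrow(variants))
  impact <- rep("MODIFIER", nrow(variants))
  cc <- annotation$cds
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!is.null(v$location) && !is.na(v$location)) {
      if (v$location == "splice_site_donor") {
        effect[i] <- "splice_donor_variant"; impact[i] <- "HIGH"; next
      }
      if (v$location == "splice_site_acceptor") {
        effect[i] <- "splice_acceptor_variant"; impact[i] <- "HIGH"; next
      }
    }
    width <- max(1L, nchar(v$ref))
    hit <- cc[cc$chrom == v$chrom_a & cc$start <= v$pos_a + width - 1L &
                cc$end >= v$pos_a, , drop = FALSE]
    if (!nrow(hit)) next
    gid <- hit$gene_id[1L]
    if (v$vtype %in% c("INS", "DEL")) {
      ilen <- nchar(if (v$vtype == "INS") v$alt else v$ref)
      if (ilen %% 3L != 0L) {
        effect[i] <- "frameshift"; impact[i] <- "HIGH"
      } else {
        effect[i] <- if (v$vtype == "INS") "inframe_insertion"
                     else "inframe_deletion"
        impact[i] <- "MODERATE"
      }
      next
    }
    ## SNP in CDS: translate the affected codon
    res <- snp_codon_effect(v, gid, annotation, genome)
    effect[i] <- res$effect; impact[i] <- res$impact
  }
  variants$effect <- effect
  variants$impact <- impact
  variants
}

snp_codon_effect <- function(v, gid, annotation, genome) {
  cds <- annotation$cds[annotation$cds$gene_id == gid, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  strand <- cds$strand[1L]
  seq <- get_cds_seq(gid, annotation, genome)
  if (nchar(seq) %% 3L != 0L)
    warning(sprintf("CDS length of %s is not a codon multiple", gid))
  ## position of the SNP within the spliced CDS (transcript orientation)
  offs <- 0L; tpos <- NA_integer_
  for (k in seq_len(nrow(cds))) {
    if (v$pos_a >= cds$start[k] && v$pos_a <= cds$end[k]) {
      tpos <- offs + (v$pos_a - cds$start[k] + 1L)
      break
    }
    offs <- offs + (cds$end[k] - cds$start[k] + 1L)
  }
  if (is.na(tpos)) return(list(effect = "non_coding", impact = "MODIFIER"))
  alt <- v$alt
  if (strand == "-") {
    tpos <- nchar(seq) - tpos + 1L
    alt <- revcomp(alt)
  }
  codon_i <- (tpos - 1L) %/% 3L
  cstart <- codon_i * 3L + 1L
  codon <- substr(seq, cstart, cstart + 2L)
  within <- tpos - cstart + 1L
  new_codon <- codon
  substr(new_codon, within, within) <- alt
  aa_old <- Biostrings::GENETIC_CODE[[codon]]
  aa_new <- Biostrings::GENETIC_CODE[[new_codon]]
  if (is.null(aa_old) || is.null(aa_new))
    return(list(effect = "non_coding", impact = "MODIFIER"))
  n_codons <- nchar(seq) %/% 3L
  if (codon_i == 0L && aa_new != "M" && aa_old == "M")
    return(list(effect = "start_lost", impact = "HIGH"))
  if (aa_old != "*" && aa_new == "*")
    return(list(effect = "stop_gained", impact = "HIGH"))
  if (aa_old == "*" && aa_new != "*")
    return(list(effect = "stop_lost", impact = "HIGH"))
  if (aa_old == aa_new)
    return(list(effect = "synonymous", impact = "LOW"))
  list(effect = "missense", impact = "MODERATE")
}

#' Fraction of genes with at least one high-impact variant
#'
#' @param n_high_genes genes carrying at least one HIGH-impact variant.
#' @param n_genes total genes on the reference haplotype (> 0).
#' @return percentage with two decimals (half away from zero).
#' @export
high_impact_gene_fraction <- function(n_high_genes, n_genes) {
  stop_if_not(n_genes > 0, "n_genes must be > 0")
  round_half_up(100 * n_high_genes / n_genes, 2)
}
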