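## gene_annotation container: list(genes, exons, cds) of data frames with
## 1-based inclusive coordinates (GFF3 convention).  One transcript per
## gene (id <gene>.t1); UTRs and introns are derived, not stored.

#' Export a gene annotation as GFF3
#'
#' Writes gene/mRNA/exon/CDS features (one transcript per gene) with CDS
#' phase computed in transcript order.
#'
#' @param annotation a `gene_annotation` list (`genes`, `exons`, `cds`).
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  g <- annotation$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    add(data.frame(seqnames = g$chrom[i], start = g$start[i], end = g$end[i],
                   strand = g$strand[i], type = "gene", ID = gid,
                   Parent = NA_character_, phase = NA_integer_))
    add(data.frame(seqnames = g$chrom[i], start = g$start[i], end = g$end[i],
                   strand = g$strand[i], type = "mRNA", ID = tid,
                   Parent = gid, phase = NA_integer_))
    ex <- annotation$exons[annotation$exons$gene_id == gid, , drop = FALSE]
    if (nrow(ex))
      add(data.frame(seqnames = ex$chrom, start = ex$start, end = ex$end,
                     strand = ex$strand, type = "exon",
                     ID = paste0(tid, ".exon", ex$rank), Parent = tid,
                     phase = NA_integer_))
    cc <- annotation$cds[annotation$cds$gene_id == gid, , drop = FALSE]
    if (nrow(cc)) {
      ## transcript order: genomic for "+", reverse genomic for "-"
      ord <- if (g$strand[i] == "+") order(cc$start) else order(-cc$start)
      cc <- cc[ord, , drop = FALSE]
      lens <- cc$end - cc$start + 1L
      phase <- c(0L, (3L - cumsum(lens) %% 3L) %% 3L)[seq_len(nrow(cc))]
      add(data.frame(seqnames = cc$chrom, start = cc$start, end = cc$end,
                     strand = cc$strand, type = "CDS",
                     ID = paste0(tid, ".cds"), Parent = tid, phase = phase))
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = df$type, ID = df$ID, phase = df$phase)
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a `gene_annotation`
#'
#' Expects gene/mRNA/exon/CDS features with one transcript per gene (extra
#' transcripts are collapsed onto the first by ID order).
#'
#' @param path GFF3 file.
#' @return a `gene_annotation` list.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  flatten_parent <- function(p) {
    vapply(p, function(x) if (length(x)) as.character(x)[1L] else
      NA_character_, "")
  }
  parent <- if ("Parent" %in% names(df)) flatten_parent(df$Parent) else
    rep(NA_character_, nrow(df))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  tx2gene <- stats::setNames(flatten_parent(mrna$Parent), mrna$ID)
  mk <- function(type) {
    x <- df[df$type == type, , drop = FALSE]
    p <- parent[df$type == type]
    gid <- unname(tx2gene[p])
    out <- data.frame(gene_id = gid, chrom = as.character(x$seqnames),
                      start = x$start, end = x$end,
                      strand = as.character(x$strand),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_id, out$start), , drop = FALSE]
    out$rank <- stats::ave(out$start, out$gene_id, FUN = seq_along)
    out
  }
  structure(list(
    genes = data.frame(gene_id = as.character(genes$ID),
                       chrom = as.character(genes$seqnames),
                       start = genes$start, end = genes$end,
                       strand = as.character(genes$strand),
                       stringsAsFactors = FALSE),
    exons = mk("exon"),
    cds = mk("CDS")
  ), class = "gene_annotation")
}

# ---- derived gene features ---------------------------------------------

#' Per-gene feature lengths
#'
#' @param annotation a `gene_annotation`.
#' @return data.frame with per-gene span, summed CDS length, mean exon
#'   length, mean intron length (NA for single-exon genes) and exon count.
#' @export
gene_feature_lengths <- function(annotation) {
  g <- annotation$genes
  ex <- annotation$exons
  cc <- annotation$cds
  cds_len <- tapply(cc$end - cc$start + 1L, cc$gene_id, sum)
  ex_len <- tapply(ex$end - ex$start + 1L, ex$gene_id, mean)
  ex_n <- tapply(ex$start, ex$gene_id, length)
  intron_mean <- vapply(g$gene_id, function(gid) {
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    if (nrow(e) < 2L) return(NA_real_)
    e <- e[order(e$start), ]
    mean(e$start[-1L] - e$end[-nrow(e)] - 1L)
  }, 0)
  data.frame(gene_id = g$gene_id,
             gene_length = g$end - g$start + 1L,
             cds_length = as.integer(cds_len[g$gene_id]),
             exon_length = as.numeric(ex_len[g$gene_id]),
             intron_length = as.numeric(intron_mean),
             n_exons = as.integer(ex_n[g$gene_id]),
             stringsAsFactors = FALSE)
}

## spliced CDS sequence (5'->3') for one gene
get_cds_seq <- function(gene_id, annotation, genome) {
  cc <- annotation$cds[annotation$cds$gene_id == gene_id, , drop = FALSE]
  stop_if_not(nrow(cc) > 0, paste("no CDS for gene", gene_id))
  cc <- cc[order(cc$start), ]
  seqs <- substring(genome[[cc$chrom[1L]]], cc$start, cc$end)
  s <- paste(seqs, collapse = "")
  if (cc$strand[1L] == "-") s <- revcomp(s)
  s
}

#' Translate the CDS of each gene to protein
#'
#' @param annotation a `gene_annotation`.
#' @param genome named character vector of chromosome sequences.
#' @param gene_ids genes to translate (default all).
#' @return named character vector of amino-acid sequences (no trailing stop).
#' @export
get_proteins <- function(annotation, genome, gene_ids = NULL) {
  gene_ids <- gene_ids %||% annotation$genes$gene_id
  out <- vapply(gene_ids, function(gid) {
    cds <- get_cds_seq(gid, annotation, genome)
    n <- nchar(cds) - nchar(cds) %% 3L
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1L, n)), if.fuzzy.codon = "X"))
    sub("\\*$", "", aa)
  }, "")
  out
}
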