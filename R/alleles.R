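## Allele-pair identification (reciprocal top protein similarity inside a
## shared collinearity block, with a reciprocal-best-hit fallback for
## unplaced scaffolds) and comparative gene-feature statistics.

#' Normalized global protein similarity
#'
#' Needleman-Wunsch alignment with BLOSUM62 (gap open 10, extend 0.5),
#' normalized by the self-alignment score of the longer protein; symmetric
#' and clamped to `[0, 1]`.
#'
#' @param prot_a,prot_b amino-acid strings.
#' @return similarity score in `[0, 1]`.
#' @export
protein_similarity <- function(prot_a, prot_b) {
  stop_if_not(nchar(prot_a) > 0 && nchar(prot_b) > 0,
              "empty protein sequence")
  ok <- "^[ACDEFGHIKLMNPQRSTVWYXBZUO*]+$"
  for (p in c(prot_a, prot_b)) {
    if (!grepl(ok, p)) {
      bad <- unique(strsplit(gsub("[ACDEFGHIKLMNPQRSTVWYXBZUO*]", "", p),
                             "")[[1L]])
      stop(sprintf("invalid amino-acid characters: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
  longer <- if (nchar(prot_a) >= nchar(prot_b)) prot_a else prot_b
  self <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(longer), Biostrings::AAString(longer),
    substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
  max(0, min(1, sc / self))
}

## fraction of a gene body inside a block interval
body_in_block <- function(g_start, g_end, b_start, b_end) {
  ov <- min(g_end, b_end) - max(g_start, b_start) + 1L
  if (ov <= 0L) return(0)
  ov / (g_end - g_start + 1L)
}

#' Assign allele pairs and haplotype-specific genes
#'
#' Stage 1 (collinear reciprocal best hit): two genes are alleles when each
#' is the other's top protein similarity and at least `min_body_frac` of
#' both gene bodies lies inside the same one-to-one collinearity block; if
#' a gene qualifies in several blocks, the largest block wins.  Stage 2
#' (scaffold RBH): remaining genes pair by reciprocal top similarity alone
#' when at least one of the two is on an unplaced scaffold.  All unpaired
#' genes are haplotype-specific.  Ties break deterministically (higher
#' alignment coverage, then lexicographically smaller id pair).
#'
#' @param annotation_a,annotation_b `gene_annotation` objects.
#' @param genome_a,genome_b chromosome sequences (for protein translation).
#' @param blocks filtered collinearity blocks.
#' @param placed optional named character vector mapping gene ids to
#'   `"chromosome"` or `"scaffold"`; genes default to `"chromosome"`.
#' @param min_body_frac minimum gene-body fraction inside the block
#'   (default 0.9).
#' @param min_similarity candidate pairs below this similarity are ignored
#'   (default 0.1; kept low so alleles degraded by planted frameshifts can
#'   still pair, reciprocity being the real guard).
#' @return list with `pairs` (data.frame `gene_a`, `gene_b`, `similarity`,
#'   `block_id`, `evidence`) and `haplotype_specific` (character vector).
#' @export
assign_alleles <- function(annotation_a, annotation_b, genome_a, genome_b,
                           blocks, placed = NULL, min_body_frac = 0.9,
                           min_similarity = 0.1) {
  ga <- annotation_a$genes; gb <- annotation_b$genes
  prot_a <- get_proteins(annotation_a, as_seq_char(genome_a))
  prot_b <- get_proteins(annotation_b, as_seq_char(genome_b))
  placed <- placed %||% stats::setNames(
    rep("chromosome", nrow(ga) + nrow(gb)), c(ga$gene_id, gb$gene_id))

  ## candidate pairs: genes co-located in a block (stage 1 candidates)
  cand <- list()
  for (bi in seq_len(nrow(blocks))) {
    in_a <- which(ga$chrom == blocks$chrom_a[bi] &
                    vapply(seq_len(nrow(ga)), function(i)
                      body_in_block(ga$start[i], ga$end[i],
                                    blocks$start_a[bi], blocks$end_a[bi]),
                      0) >= min_body_frac)
    in_b <- which(gb$chrom == blocks$chrom_b[bi] &
                    vapply(seq_len(nrow(gb)), function(i)
                      body_in_block(gb$start[i], gb$end[i],
                                    blocks$start_b[bi], blocks$end_b[bi]),
                      0) >= min_body_frac)
    if (!length(in_a) || !length(in_b)) next
    cc <- expand.grid(a = ga$gene_id[in_a], b = gb$gene_id[in_b],
                      stringsAsFactors = FALSE)
    ## prune by projected position within the block (collinearity means a
    ## gene's allele sits near the same relative offset)
    off_a <- ga$start[match(cc$a, ga$gene_id)] - blocks$start_a[bi]
    off_b <- if (blocks$strand[bi] == "+")
      gb$start[match(cc$b, gb$gene_id)] - blocks$start_b[bi]
    else blocks$end_b[bi] - gb$end[match(cc$b, gb$gene_id)]
    cc <- cc[abs(off_a - off_b) <= 20000L, , drop = FALSE]
    if (!nrow(cc)) next
    cand[[length(cand) + 1L]] <- cc
    cand[[length(cand)]]$block_id <- blocks$id[bi]
    cand[[length(cand)]]$block_span <-
      blocks$end_a[bi] - blocks$start_a[bi] + 1L
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(a = character(0), b = character(0), block_id = integer(0),
               block_span = integer(0))

  ## similarity for candidate pairs (cache by pair); a frameshift can
  ## wreck the global protein score of a true allele, so every candidate
  ## is scored as max(protein similarity, down-weighted CDS nucleotide
  ## identity) -- one consistent scale, protein evidence ranking first
  cds_a_cache <- new.env(parent = emptyenv())
  cds_b_cache <- new.env(parent = emptyenv())
  cds_of <- function(id, ann, gen, cache) {
    if (is.null(cache[[id]]))
      cache[[id]] <- get_cds_seq(id, ann, as_seq_char(gen))
    cache[[id]]
  }
  sim_cache <- new.env(parent = emptyenv())
  sim <- function(a, b) {
    key <- paste(a, b, sep = "|")
    if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
    s <- protein_similarity(prot_a[[a]], prot_b[[b]])
    nuc <- align_gap(cds_of(a, annotation_a, genome_a, cds_a_cache),
                     cds_of(b, annotation_b, genome_b, cds_b_cache))
    s <- max(s, 0.85 * nuc$identity / 100)
    sim_cache[[key]] <- s
    s
  }
  if (nrow(cand))
    cand$similarity <- mapply(sim, cand$a, cand$b)
  else cand$similarity <- numeric(0)
  cand <- cand[cand$similarity >= min_similarity, , drop = FALSE]

  ## per gene, keep its largest qualifying block per partner
  pairs <- list()
  paired_a <- character(0); paired_b <- character(0)
  if (nrow(cand)) {
    ## reciprocal top similarity within the candidate graph
    best_for_a <- lapply(split(cand, cand$a), function(d) {
      d[order(-d$similarity, d$b), , drop = FALSE][1L, ]
    })
    best_for_b <- lapply(split(cand, cand$b), function(d) {
      d[order(-d$similarity, d$a), , drop = FALSE][1L, ]
    })
    for (a in names(best_for_a)) {
      b <- best_for_a[[a]]$b
      if (is.null(best_for_b[[b]]) || best_for_b[[b]]$a != a) next
      ## choose the largest block containing this reciprocal pair
      d <- cand[cand$a == a & cand$b == b, , drop = FALSE]
      d <- d[order(-d$block_span), , drop = FALSE]
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, similarity = d$similarity[1L],
        block_id = d$block_id[1L], evidence = "collinear_rbh",
        stringsAsFactors = FALSE)
      paired_a <- c(paired_a, a); paired_b <- c(paired_b, b)
    }
  }

  ## stage 2: scaffold RBH among leftovers involving unplaced sequence
  left_a <- setdiff(ga$gene_id, paired_a)
  left_b <- setdiff(gb$gene_id, paired_b)
  if (length(left_a) && length(left_b)) {
    elig <- expand.grid(a = left_a, b = left_b, stringsAsFactors = FALSE)
    elig <- elig[placed[elig$a] == "scaffold" |
                   placed[elig$b] == "scaffold", , drop = FALSE]
    if (nrow(elig)) {
      elig$similarity <- mapply(sim, elig$a, elig$b)
      elig <- elig[elig$similarity >= min_similarity, , drop = FALSE]
      if (nrow(elig)) {
        best_a <- lapply(split(elig, elig$a), function(d)
          d[order(-d$similarity, d$b), , drop = FALSE][1L, ])
        best_b <- lapply(split(elig, elig$b), function(d)
          d[order(-d$similarity, d$a), , drop = FALSE][1L, ])
        for (a in names(best_a)) {
          b <- best_a[[a]]$b
          if (is.null(best_b[[b]]) || best_b[[b]]$a != a) next
          pairs[[length(pairs) + 1L]] <- data.frame(
            gene_a = a, gene_b = b, similarity = best_a[[a]]$similarity,
            block_id = NA_integer_, evidence = "scaffold_rbh",
            stringsAsFactors = FALSE)
          paired_a <- c(paired_a, a); paired_b <- c(paired_b, b)
        }
      }
    }
  }

  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               similarity = numeric(0), block_id = integer(0),
               evidence = character(0), stringsAsFactors = FALSE)
  specific <- c(setdiff(ga$gene_id, pairs$gene_a),
                setdiff(gb$gene_id, pairs$gene_b))
  list(pairs = pairs, haplotype_specific = specific)
}

#' Paired-gene fraction as a printed percentage
#'
#' @param n_pairs number of allele pairs (each covering two genes).
#' @param n_genes total genes across both haplotypes.
#' @return percentage with two decimals.
#' @export
paired_gene_fraction <- function(n_pairs, n_genes) {
  stop_if_not(n_genes > 0, "n_genes must be > 0")
  round_half_up(100 * (2 * n_pairs) / n_genes, 2)
}

# ---- feature statistics -------------------------------------------------

#' RPKM matrix from per-allele counts
#'
#' Reads per kilobase of transcript (summed exon length) per million
#' mapped reads, with per-sample total counts as the scaling denominator.
#'
#' @param counts integer matrix, rows = gene copies, columns = samples.
#' @param lengths named vector of transcript lengths (bases) for the rows.
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(counts, lengths) {
  lengths <- lengths[rownames(counts)]
  libs <- colSums(counts)
  sweep(counts / (lengths / 1000), 2, libs / 1e6, "/")
}

## compact letter display from a matrix of pairwise p-values
compact_letters <- function(pmat, groups, alpha = 0.05) {
  n <- length(groups)
  letters_out <- rep("", n)
  ## greedy insert-absorb: start with one letter set per group,
  ## merge groups that are not significantly different
  sets <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (si in seq_along(sets)) {
      if (all(pmat[groups[i], sets[[si]]] > alpha, na.rm = TRUE)) {
        sets[[si]] <- c(sets[[si]], groups[i])
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- groups[i]
  }
  for (si in seq_along(sets)) {
    idx <- match(sets[[si]], groups)
    letters_out[idx] <- paste0(letters_out[idx], letters[si])
  }
  stats::setNames(letters_out, groups)
}

#' Comparative feature statistics for gene classes
#'
#' Means and standard deviations of gene, CDS, exon and intron lengths per
#' class (haplotype-specific, allelic, all), mean RPKM and RPKM coefficient
#' of variation, and Tukey HSD multiple comparisons (alpha 0.05) with a
#' compact letter display.
#'
#' @param pairs allele-pair data.frame ([assign_alleles()]).
#' @param specific character vector of haplotype-specific gene ids.
#' @param annotation a combined `gene_annotation` covering all genes (A and
#'   B), or a list of two to be concatenated.
#' @param counts optional count matrix (rows = gene copies); RPKM columns
#'   are omitted when absent.
#' @return data.frame, one row per class, plus `attr(, "tukey")` with the
#'   underlying per-feature Tukey results.
#' @export
feature_stats <- function(pairs, specific, annotation, counts = NULL) {
  if (!inherits(annotation, "gene_annotation") && is.list(annotation))
    annotation <- structure(list(
      genes = rbind(annotation[[1L]]$genes, annotation[[2L]]$genes),
      exons = rbind(annotation[[1L]]$exons, annotation[[2L]]$exons),
      cds = rbind(annotation[[1L]]$cds, annotation[[2L]]$cds)
    ), class = "gene_annotation")
  feats <- gene_feature_lengths(annotation)
  allelic <- c(pairs$gene_a, pairs$gene_b)
  cls <- ifelse(feats$gene_id %in% allelic, "allelic",
                ifelse(feats$gene_id %in% specific, "haplotype_specific",
                       NA_character_))
  feats$class <- cls
  feats <- feats[!is.na(feats$class), , drop = FALSE]

  rpkm_mat <- NULL
  if (!is.null(counts)) {
    ex <- annotation$exons
    tx_len <- tapply(ex$end - ex$start + 1L, ex$gene_id, sum)
    common <- intersect(rownames(counts), names(tx_len))
    rpkm_mat <- rpkm(counts[common, , drop = FALSE], tx_len)
  }

  classes <- list(haplotype_specific =
                    feats$gene_id[feats$class == "haplotype_specific"],
                  allelic = feats$gene_id[feats$class == "allelic"],
                  all = feats$gene_id)
  measures <- c("gene_length", "cds_length", "exon_length", "intron_length")
  rows <- list(); tukey <- list()
  for (cl in names(classes)) {
    ids <- classes[[cl]]
    sub <- feats[feats$gene_id %in% ids, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning(sprintf("class %s has < 2 members; statistics suppressed", cl))
      next
    }
    row <- list(class = cl, n = nrow(sub))
    for (m in measures) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- sd(sub[[m]], na.rm = TRUE)
    }
    if (!is.null(rpkm_mat)) {
      v <- rpkm_mat[intersect(ids, rownames(rpkm_mat)), , drop = FALSE]
      row$rpkm_mean <- mean(v)
      row$rpkm_cv <- 100 * sd(as.vector(v)) / mean(v)
    }
    rows[[cl]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)

  ## Tukey HSD over the two disjoint classes + letters incl. "all"
  two <- feats[feats$class %in% c("haplotype_specific", "allelic"), ]
  if (length(unique(two$class)) == 2L && all(table(two$class) >= 2L)) {
    for (m in measures) {
      d <- two[is.finite(two[[m]]), ]
      if (length(unique(d$class)) < 2L || any(table(d$class) < 2L)) next
      fit <- aov(d[[m]] ~ factor(d$class))
      tk <- TukeyHSD(fit)[[1L]]
      pmat <- matrix(1, 2, 2, dimnames = list(
        c("allelic", "haplotype_specific"),
        c("allelic", "haplotype_specific")))
      pmat["haplotype_specific", "allelic"] <-
        pmat["allelic", "haplotype_specific"] <- tk[1L, "p adj"]
      tukey[[m]] <- list(tukey = tk,
                         letters = compact_letters(
                           pmat, c("allelic", "haplotype_specific")))
    }
  }
  attr(out, "tukey") <- tukey
  rownames(out) <- NULL
  out
}
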