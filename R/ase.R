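## Allele-specific expression: a beta-binomial exact test on the summed
## allele counts of each pair (overdispersion estimated by method of
## moments across pairs), Benjamini-Hochberg FDR, the |log2FC| > 1 &
## FDR < 0.01 decision rule, ASE blocks (runs of >= 4 co-directional
## consecutive pairs), cross-experiment sharing, promoter-SV association
## and IUPAC promoter motif scanning.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values (monotone in rank).
#' @export
bh_fdr <- function(p_values) {
  stop_if_not(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

## log density of the beta-binomial with mean p and correlation rho
dbetabinom_log <- function(x, n, p, rho) {
  s <- (1 - rho) / rho          # alpha + beta
  a <- p * s; b <- (1 - p) * s
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

#' Exact allelic-imbalance test for one allele pair
#'
#' Computes the library-size-normalized log2 fold change (pseudocount 0.5)
#' and a two-sided exact test of allele A's summed count conditional on the
#' pair total: beta-binomial with null mean equal to A's share of the
#' library sizes and the supplied overdispersion, falling back to the
#' binomial when `rho <= 0`.  The two-sided p sums all outcomes no more
#' probable than the observed one.
#'
#' @param counts_a,counts_b per-replicate counts for the A and B allele.
#' @param lib_a,lib_b per-replicate library sizes (defaults to 1, i.e.
#'   equal sizes).
#' @param rho beta-binomial overdispersion (see [estimate_overdispersion()]).
#' @return list with `log2fc`, `p_value`, `untestable`.
#' @export
ase_test <- function(counts_a, counts_b, lib_a = NULL, lib_b = NULL,
                     rho = 0) {
  stop_if_not(length(counts_a) >= 2L && length(counts_b) >= 2L,
              "at least 2 replicates are required")
  lib_a <- lib_a %||% rep(1, length(counts_a))
  lib_b <- lib_b %||% rep(1, length(counts_b))
  sa <- sum(counts_a); sb <- sum(counts_b)
  la <- sum(lib_a); lb <- sum(lib_b)
  log2fc <- log2((sa / la + 0.5 / la) / (sb / lb + 0.5 / lb))
  if (sa + sb == 0L)
    return(list(log2fc = 0, p_value = 1, untestable = TRUE))
  n <- sa + sb
  p0 <- la / (la + lb)
  x <- 0:n
  logp <- if (rho > 0) dbetabinom_log(x, n, p0, rho) else
    stats::dbinom(x, n, p0, log = TRUE)
  obs <- logp[sa + 1L]
  pv <- sum(exp(logp[logp <= obs + 1e-7]))
  list(log2fc = log2fc, p_value = min(1, pv), untestable = FALSE)
}

#' Method-of-moments overdispersion across allele pairs
#'
#' Estimates the beta-binomial intra-class correlation from the spread of
#' per-pair allele-A proportions around the library-size null:
#' `E[(phat - p0)^2] = p0 q0 (rho (1 - 1/n) + 1/n)`.  Pairs whose allelic
#' fold change already exceeds the ASE decision boundary (|log2 fold| > 1)
#' are excluded from the moment pool, so genuinely imbalanced pairs do not
#' inflate the null dispersion they are later tested against.
#'
#' @param sums_a,sums_b per-pair summed counts for the two alleles.
#' @param p0 null proportion of allele A (default 0.5).
#' @return estimated `rho` (can be <= 0, meaning no overdispersion).
#' @export
estimate_overdispersion <- function(sums_a, sums_b, p0 = 0.5) {
  n <- sums_a + sums_b
  keep <- n > 0
  n <- n[keep]
  phat <- sums_a[keep] / n
  if (length(n) < 2L) return(0)
  q0 <- 1 - p0
  odds0 <- p0 / q0
  fold <- (phat / (1 - phat)) / odds0
  bal <- is.finite(fold) & fold > 0.5 & fold < 2
  if (sum(bal) >= 10L) { phat <- phat[bal]; n <- n[bal] }
  num <- mean((phat - p0)^2) - p0 * q0 * mean(1 / n)
  den <- p0 * q0 * mean(1 - 1 / n)
  if (den <= 0) return(0)
  num / den
}

#' Run the ASE test over one experiment's count matrix
#'
#' Rows of `counts` are gene copies named `<pair>_A` / `<pair>_B` (and
#' possibly haplotype-specific genes, ignored here); columns are the
#' experiment's replicates.  Overdispersion is estimated once across all
#' pairs, the exact test applied per pair, and the paper's decision rule
#' (`|log2FC| > 1` and BH FDR < 0.01) evaluated.
#'
#' @param counts integer matrix for one experiment.
#' @param pairs data.frame with `gene_a`, `gene_b` (ids ending `_A`/`_B`).
#' @param experiment experiment label stored in the result.
#' @return data.frame with `pair`, `experiment`, `count_a`, `count_b`,
#'   `log2fc`, `p_value`, `fdr`, `is_ase`, `direction`.
#' @export
ase_analyze <- function(counts, pairs, experiment = "exp1") {
  stop_if_not(ncol(counts) >= 2L, "at least 2 replicates are required")
  libs <- colSums(counts)
  rows_a <- match(pairs$gene_a, rownames(counts))
  rows_b <- match(pairs$gene_b, rownames(counts))
  keep <- !is.na(rows_a) & !is.na(rows_b)
  pairs <- pairs[keep, , drop = FALSE]
  rows_a <- rows_a[keep]; rows_b <- rows_b[keep]
  sums_a <- rowSums(counts[rows_a, , drop = FALSE])
  sums_b <- rowSums(counts[rows_b, , drop = FALSE])
  rho <- estimate_overdispersion(sums_a, sums_b)
  rho <- max(0, min(rho, 0.99))
  la <- sum(libs); lb <- sum(libs)     # both alleles share the libraries
  res <- mapply(function(i) {
    ase_test(counts[rows_a[i], ], counts[rows_b[i], ],
             lib_a = libs, lib_b = libs, rho = rho)
  }, seq_along(rows_a), SIMPLIFY = FALSE)
  log2fc <- vapply(res, `[[`, 0, "log2fc")
  p <- vapply(res, `[[`, 0, "p_value")
  fdr <- bh_fdr(p)
  is_ase <- abs(log2fc) > 1 & fdr < 0.01
  direction <- ifelse(!is_ase, "none", ifelse(log2fc > 0, "A", "B"))
  data.frame(pair = pairs$gene_a, experiment = experiment,
             count_a = sums_a, count_b = sums_b, log2fc = log2fc,
             p_value = p, fdr = fdr, is_ase = is_ase,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Detect ASE blocks
#'
#' An ASE block is a maximal run of at least `min_genes` consecutive
#' allele pairs (in genomic order on their chromosome) that are all ASE in
#' the same direction; a non-ASE or opposite-direction pair breaks the
#' run.  Non-allelic genes between pairs are ignored by construction
#' (ordering is over pairs only).
#'
#' @param ase_records data.frame from [ase_analyze()] (one experiment).
#' @param pair_order data.frame with `pair` and `chrom` giving the genomic
#'   order of pairs per chromosome (rows already ordered by position).
#' @param min_genes minimum pairs per block ("more than three" = 4).
#' @return data.frame of blocks: `chrom`, `first_pair`, `n_genes`,
#'   `direction`, `member_pairs` (comma-joined ids).
#' @export
call_ase_blocks <- function(ase_records, pair_order, min_genes = 4L) {
  dirs <- stats::setNames(ase_records$direction, ase_records$pair)
  out <- list()
  for (ch in unique(pair_order$chrom)) {
    ids <- pair_order$pair[pair_order$chrom == ch]
    d <- dirs[ids]
    d[is.na(d)] <- "none"
    i <- 1L
    while (i <= length(ids)) {
      if (d[i] %in% c("A", "B")) {
        j <- i
        while (j < length(ids) && d[j + 1L] == d[i]) j <- j + 1L
        if (j - i + 1L >= min_genes)
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, first_pair = ids[i], n_genes = j - i + 1L,
            direction = unname(d[i]),
            member_pairs = paste(ids[i:j], collapse = ","),
            stringsAsFactors = FALSE)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), first_pair = character(0),
               n_genes = integer(0), direction = character(0),
               member_pairs = character(0), stringsAsFactors = FALSE)
}

#' Cross-experiment ASE sharing summary
#'
#' @param ase_sets named list of character vectors (ASE pair ids per
#'   experiment).
#' @return list with `union_size`, `n_all` (pairs ASE in every experiment),
#'   `n_at_least` (vector over 1..E experiments), per-experiment counts,
#'   `pct_all` and `pct_at_least_2` (two decimals).
#' @export
sharing_summary <- function(ase_sets) {
  stop_if_not(length(ase_sets) >= 2L, "need >= 2 experiments")
  all_ids <- unique(unlist(ase_sets))
  member <- sapply(ase_sets, function(s) all_ids %in% s)
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  times <- rowSums(member)
  e <- length(ase_sets)
  n_at_least <- vapply(seq_len(e), function(k) sum(times >= k), 0L)
  list(union_size = length(all_ids),
       n_all = sum(times == e),
       n_at_least = n_at_least,
       per_experiment = vapply(ase_sets, length, 0L),
       pct_all = round_half_up(100 * sum(times == e) / length(all_ids), 2),
       pct_at_least_2 = round_half_up(100 * n_at_least[2L] /
                                        length(all_ids), 2))
}

#' Percentage of a subset over a union, printed convention
#'
#' @param subset_n,union_n counts.
#' @return `100 * subset_n / union_n` with two decimals.
#' @export
sharing_fraction <- function(subset_n, union_n) {
  stop_if_not(union_n > 0, "union must be non-empty")
  round_half_up(100 * subset_n / union_n, 2)
}

#' ASE blocks shared across all experiments
#'
#' A shared block is a maximal set of same-direction blocks, one from each
#' experiment, every two of which share at least `min_shared_pairs` member
#' pairs.  The reported member set is the union over the matched blocks.
#'
#' @param blocks_per_experiment list (one [call_ase_blocks()] result per
#'   experiment).
#' @param min_shared_pairs pairwise sharing threshold (default 3).
#' @return data.frame with `direction`, `n_pairs`, `member_pairs` per
#'   shared block.
#' @export
shared_blocks <- function(blocks_per_experiment, min_shared_pairs = 3L) {
  e <- length(blocks_per_experiment)
  stop_if_not(e >= 2L, "need >= 2 experiments")
  members <- lapply(blocks_per_experiment, function(b)
    lapply(strsplit(b$member_pairs, ","), unique))
  dirs <- lapply(blocks_per_experiment, `[[`, "direction")
  out <- list(); used_keys <- character(0)
  b1 <- blocks_per_experiment[[1L]]
  for (i in seq_len(nrow(b1))) {
    sel <- list(members[[1L]][[i]])
    dir <- dirs[[1L]][i]
    ok <- TRUE
    for (x in 2L:e) {
      share <- vapply(seq_along(members[[x]]), function(j) {
        if (dirs[[x]][j] != dir) return(0L)
        length(intersect(members[[x]][[j]], sel[[1L]]))
      }, 0L)
      if (!length(share) || max(share) < min_shared_pairs) { ok <- FALSE; break }
      sel[[x]] <- members[[x]][[which.max(share)]]
    }
    if (!ok) next
    ## verify pairwise sharing among all chosen blocks
    pw <- TRUE
    for (x in seq_len(e - 1L)) for (y in (x + 1L):e)
      if (length(intersect(sel[[x]], sel[[y]])) < min_shared_pairs)
        pw <- FALSE
    if (!pw) next
    un <- sort(unique(unlist(sel)))
    key <- paste(un, collapse = ",")
    if (key %in% used_keys) next
    used_keys <- c(used_keys, key)
    out[[length(out) + 1L]] <- data.frame(
      direction = dir, n_pairs = length(un),
      member_pairs = paste(un, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(direction = character(0), n_pairs = integer(0),
               member_pairs = character(0), stringsAsFactors = FALSE)
}

#' Promoter SV association with ASE (Fisher exact test)
#'
#' A pair "harbors an SV" when at least one insertion or deletion SV
#' overlaps the strand-aware promoter (upstream of the translation start,
#' `promoter_len` bases) of either allele.  Tests the 2x2 contingency of
#' {ASE, non-ASE} x {SV, no SV} with a two-sided Fisher exact test.
#'
#' @param pairs allele-pair data.frame.
#' @param ase_pairs character vector of ASE pair ids (`gene_a` ids).
#' @param sv_calls data.frame from [call_svs()]; only insertion/deletion
#'   types are used.
#' @param annotation combined `gene_annotation` covering both haplotypes.
#' @param promoter_len promoter length in bases (default 2000).
#' @return list with `table` (2x2 matrix), `p_value`, `sv_pairs` (ids).
#' @export
promoter_sv_association <- function(pairs, ase_pairs, sv_calls, annotation,
                                    promoter_len = 2000L) {
  sv <- sv_calls[sv_calls$svtype %in% c("insertion", "deletion"), ,
                 drop = FALSE]
  proms <- promoter_intervals(annotation, promoter_len)
  has_sv <- function(gid) {
    p <- proms[proms$gene_id == gid, , drop = FALSE]
    if (!nrow(p)) return(FALSE)
    any(sv$chrom_a == p$chrom & sv$start_a <= p$end & sv$end_a >= p$start)
  }
  sv_pair <- vapply(seq_len(nrow(pairs)), function(i) {
    has_sv(pairs$gene_a[i]) || has_sv(pairs$gene_b[i])
  }, TRUE)
  is_ase <- pairs$gene_a %in% ase_pairs
  tab <- matrix(c(sum(is_ase & sv_pair), sum(is_ase & !sv_pair),
                  sum(!is_ase & sv_pair), sum(!is_ase & !sv_pair)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("ASE", "non_ASE"), c("SV", "no_SV")))
  p <- fisher_exact_2x2(tab)
  list(table = tab, p_value = p, sv_pairs = pairs$gene_a[sv_pair])
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' @param tab 2x2 integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  stop_if_not(all(dim(tab) == c(2L, 2L)), "need a 2x2 table")
  fisher.test(tab)$p.value
}

## strand-aware promoter interval upstream of the translation start
promoter_intervals <- function(annotation, promoter_len) {
  cc <- annotation$cds
  g <- annotation$genes
  out <- lapply(unique(cc$gene_id), function(gid) {
    x <- cc[cc$gene_id == gid, , drop = FALSE]
    strand <- x$strand[1L]
    if (strand == "+") {
      tss <- min(x$start)
      s <- max(1L, tss - promoter_len); e <- tss - 1L
    } else {
      tss <- max(x$end)
      s <- tss + 1L; e <- tss + promoter_len
    }
    if (e < s) return(NULL)
    data.frame(gene_id = gid, chrom = x$chrom[1L], start = s, end = e,
               strand = strand, truncated = (e - s + 1L) < promoter_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract promoter sequences
#'
#' @param annotation a `gene_annotation`.
#' @param genome named character vector of chromosomes.
#' @param promoter_len upstream length in bases (translation-start anchor).
#' @return named character vector of promoter sequences, 5'->3' relative to
#'   the gene (reverse-complemented for minus-strand genes).
#' @export
promoter_sequences <- function(annotation, genome, promoter_len = 1500L) {
  genome <- as_seq_char(genome)
  proms <- promoter_intervals(annotation, promoter_len)
  if (any(proms$truncated))
    warning("promoters truncated at a chromosome boundary")
  out <- vapply(seq_len(nrow(proms)), function(i) {
    s <- substr(genome[[proms$chrom[i]]], proms$start[i], proms$end[i])
    if (proms$strand[i] == "-") s <- revcomp(s)
    s
  }, "")
  stats::setNames(out, proms$gene_id)
}

#' Scan promoters for IUPAC motifs
#'
#' Occurrences are counted on both strands with overlapping matches
#' allowed.  Two rankings are produced: by total occurrences and by the
#' number of promoters with at least one hit.
#'
#' @param promoters named character vector of promoter sequences.
#' @param motifs data.frame with `name` and `iupac` columns (or a named
#'   character vector of IUPAC patterns).
#' @return data.frame with `name`, `occurrences`, `promoters_hit`,
#'   `rank_occurrences`, `rank_promoters`.
#' @export
motif_scan <- function(promoters, motifs) {
  if (!is.data.frame(motifs))
    motifs <- data.frame(name = names(motifs), iupac = unname(motifs),
                         stringsAsFactors = FALSE)
  bad <- !grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", motifs$iupac)
  if (any(bad))
    stop(sprintf("invalid IUPAC motif(s): %s",
                 paste(motifs$name[bad], collapse = ", ")), call. = FALSE)
  if (!length(promoters)) {
    return(data.frame(name = motifs$name, occurrences = 0L,
                      promoters_hit = 0L,
                      rank_occurrences = rank(-rep(0L, nrow(motifs)),
                                              ties.method = "min"),
                      rank_promoters = rank(-rep(0L, nrow(motifs)),
                                            ties.method = "min")))
  }
  subj <- Biostrings::DNAStringSet(toupper(promoters))
  occ <- integer(nrow(motifs)); hit <- integer(nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(toupper(motifs$iupac[i]))
    fw <- Biostrings::vmatchPattern(pat, subj, fixed = FALSE)
    rv <- Biostrings::vmatchPattern(Biostrings::reverseComplement(pat),
                                    subj, fixed = FALSE)
    nf <- S4Vectors::elementNROWS(fw); nr <- S4Vectors::elementNROWS(rv)
    occ[i] <- sum(nf) + sum(nr)
    hit[i] <- sum(nf + nr > 0L)
  }
  data.frame(name = motifs$name, occurrences = occ, promoters_hit = hit,
             rank_occurrences = rank(-occ, ties.method = "min"),
             rank_promoters = rank(-hit, ties.method = "min"),
             stringsAsFactors = FALSE)
}
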