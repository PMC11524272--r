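## Planted allele-specific expression: negative-binomial counts per allele
## copy, per replicate, across one or more experiments.

#' Simulate per-allele expression count matrices with planted ASE
#'
#' For every allele pair a baseline mean is drawn log-normally around
#' `mean_expression`.  Non-ASE pairs give both alleles that mean; ASE pairs
#' split it by the planted log2 fold change (`+` toward A).  Pairs covered
#' by `ase_block_spec` share the block's direction and are consecutive in
#' gene order, giving recoverable ASE blocks.  Haplotype-specific genes get
#' independent means.  Counts are negative-binomial with the configured
#' dispersion, scaled by a per-replicate library-size factor drawn
#' log-normally (sd 0.1) so normalization is exercised downstream.
#'
#' The same planted ASE set is used in every experiment (allelic bias is
#' treated as a property of the locus, shared across conditions); only the
#' count noise differs between experiments.
#'
#' @param truth a `diploid_truth` from [mutate_to_haplotype_b()] (only
#'   `allele_pair_truth` and `haplotype_specific_truth` are used), or a
#'   data.frame of pairs with columns `gene_a`, `gene_b`.
#' @param config a [sim_config()].
#' @param annotation_a optional A annotation used to order pairs along the
#'   chromosome for block planting (defaults to pair order).
#' @return list with `counts` (list per experiment of integer matrices,
#'   rows = gene copies `*_A`/`*_B`, columns = replicates), `ase_truth`
#'   (data.frame pair/direction), `ase_block_truth` (data.frame of planted
#'   blocks) and `pair_means` (internal baseline means).
#' @export
simulate_expression <- function(truth, config, annotation_a = NULL) {
  pairs <- if (is.data.frame(truth)) truth else truth$allele_pair_truth
  stop_if_not(nrow(pairs) > 0, "no allele pairs to simulate")
  stop_if_not(config$replicates_per_experiment >= 2L,
              "differential testing requires >= 2 replicates per experiment")
  set.seed((config$seed + 7919L) %% .Machine$integer.max)

  hs <- if (is.data.frame(truth)) character(0) else
    truth$haplotype_specific_truth
  n_pairs <- nrow(pairs)
  pair_id <- pairs$gene_a

  ## order pairs along chromosomes for block planting
  if (!is.null(annotation_a)) {
    g <- annotation_a$genes
    pos <- match(pairs$gene_a, g$gene_id[order(g$chrom, g$start)])
    pairs <- pairs[order(pos), , drop = FALSE]
    pair_id <- pairs$gene_a
  }

  direction <- rep("none", n_pairs)
  names(direction) <- pair_id

  ## planted blocks: runs of consecutive pairs, same direction
  block_truth <- NULL
  block_idx <- integer(0)
  bs <- config$ase_block_spec
  if (!is.null(bs)) {
    chrom_of <- sub("^g(\\d+)_.*$", "\\1", pair_id)
    for (i in seq_len(nrow(bs))) {
      on_chrom <- which(chrom_of == as.character(bs$chrom[i]))
      idx <- on_chrom[seq(bs$start_index[i],
                          length.out = bs$n_genes[i])]
      idx <- idx[!is.na(idx)]
      stop_if_not(length(idx) == bs$n_genes[i],
                  "ase_block_spec exceeds available pairs on chromosome")
      direction[idx] <- bs$direction[i]
      block_idx <- c(block_idx, idx)
      block_truth <- rbind(block_truth, data.frame(
        chrom = bs$chrom[i], first_pair = pair_id[idx[1L]],
        n_genes = bs$n_genes[i], direction = bs$direction[i],
        member_pairs = paste(pair_id[idx], collapse = ","),
        stringsAsFactors = FALSE))
    }
  }

  ## remaining ASE pairs drawn at the configured fraction, random
  ## direction; pairs immediately flanking a planted block are kept
  ## non-ASE so the planted block boundaries stay recoverable
  guard <- integer(0)
  if (any(direction != "none")) {
    idx <- which(direction != "none")
    guard <- setdiff(c(idx - 1L, idx + 1L), idx)
    guard <- guard[guard >= 1L & guard <= n_pairs]
  }
  free <- setdiff(which(direction == "none"), guard)
  n_extra <- max(0L, round(config$ase_pair_fraction * n_pairs) -
                   sum(direction != "none"))
  if (n_extra > 0L && length(free)) {
    pick <- sample(free, min(n_extra, length(free)))
    direction[pick] <- sample(c("A", "B"), length(pick), replace = TRUE)
  }

  ## baseline means; ASE pairs split the mean by the planted log2FC.
  ## Block members get at least the typical expression level, so a planted
  ## block is not censored by an undetectably low-expressed member.
  base <- exp(rnorm(n_pairs, log(config$mean_expression), 0.6))
  base[block_idx] <- pmax(base[block_idx], config$mean_expression)
  fc <- 2^(config$ase_log2fc / 2)
  mean_a <- ifelse(direction == "A", base * fc,
                   ifelse(direction == "B", base / fc, base))
  mean_b <- ifelse(direction == "A", base / fc,
                   ifelse(direction == "B", base * fc, base))

  hs_mean <- exp(rnorm(length(hs), log(config$mean_expression), 1.0))

  size <- 1 / config$dispersion
  nrep <- config$replicates_per_experiment
  counts <- vector("list", config$n_experiments)
  names(counts) <- paste0("exp", seq_len(config$n_experiments))
  row_ids <- c(pairs$gene_a, pairs$gene_b, hs)
  for (e in seq_len(config$n_experiments)) {
    libf <- exp(rnorm(nrep, 0, 0.1))
    m <- matrix(0L, nrow = length(row_ids), ncol = nrep,
                dimnames = list(row_ids,
                                paste0("exp", e, "_rep", seq_len(nrep))))
    for (r in seq_len(nrep)) {
      mu <- c(mean_a, mean_b, hs_mean) * libf[r]
      m[, r] <- rnbinom(length(mu), mu = mu, size = size)
    }
    counts[[e]] <- m
  }

  list(counts = counts,
       ase_truth = data.frame(pair = pair_id, direction = direction,
                              row.names = NULL, stringsAsFactors = FALSE),
       ase_block_truth = block_truth,
       pair_means = data.frame(pair = pair_id, mean_a = mean_a,
                               mean_b = mean_b, stringsAsFactors = FALSE))
}

#' Write simulated count matrices as TSV files
#'
#' One file per experiment; rows are gene copies (`*_A`/`*_B`), columns are
#' replicate samples.
#'
#' @param counts the `counts` element of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_count_matrices <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(counts), function(e) {
    p <- file.path(dir, paste0("counts_", e, ".tsv"))
    df <- data.frame(gene_copy = rownames(counts[[e]]), counts[[e]],
                     check.names = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Read a per-allele count matrix TSV
#'
#' @param path TSV with a `gene_copy` id column followed by sample columns.
#' @return integer matrix with gene-copy rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}
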