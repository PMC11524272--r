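## Simulated k-mer multiplicity histogram over a diploid genome.
##
## Rather than materializing reads, the simulator works at the level each
## k-mer counter observes: every distinct canonical k-mer of the diploid
## (A + B) with genomic multiplicity m receives a Poisson(m * coverage *
## (1 - error_rate)^k) read-k-mer count (uniform coverage, error-free
## copies), and the k-mer copies lost to substitution errors reappear as
## novel singleton k-mers.  This reproduces the observable histogram of a
## uniform-coverage read simulation at a fraction of the cost; read-level
## FASTQ simulation is out of scope by design.

#' Simulate a canonical k-mer multiplicity histogram of a diploid
#'
#' Homozygous k-mers (present on both haplotypes) peak near `2 * coverage`,
#' heterozygous k-mers near `coverage`; substitution errors contribute a
#' low-multiplicity tail of novel k-mers.
#'
#' @param genome_a,genome_b named character vectors of chromosome sequences.
#' @param coverage per-haplotype read depth (fold); must be > 0.
#' @param error_rate per-base substitution error rate of the simulated reads.
#' @param k odd k-mer size in `[11, 31]`.
#' @param seed integer seed.
#' @return a `kmer_histogram` (see [count_kmers()]).
#' @export
simulate_kmer_histogram <- function(genome_a, genome_b, coverage = 50,
                                    error_rate = 0.001, k = 17L,
                                    seed = 1L) {
  stop_if_not(coverage > 0, "coverage must be > 0")
  stop_if_not(k %% 2L == 1L && k >= 11L && k <= 31L,
              "k must be odd and in [11, 31]")
  set.seed(as.integer(seed))
  mult <- kmer_multiplicities(c(as_seq_char(genome_a),
                                as_seq_char(genome_b)), k)
  p_ok <- (1 - error_rate)^k
  obs <- rpois(length(mult), mult * coverage * p_ok)
  obs <- obs[obs > 0L]
  tab <- table(obs)
  bins <- data.frame(multiplicity = as.integer(names(tab)),
                     count = as.integer(tab))
  ## erroneous k-mer copies become (approximately distinct) singletons
  if (error_rate > 0) {
    total_copies <- sum(as.numeric(mult)) * coverage
    n_err <- rpois(1L, total_copies * (1 - p_ok))
    if (n_err > 0L) {
      i1 <- match(1L, bins$multiplicity)
      if (is.na(i1)) bins <- rbind(data.frame(multiplicity = 1L,
                                              count = n_err), bins)
      else bins$count[i1] <- bins$count[i1] + n_err
    }
  }
  bins <- bins[order(bins$multiplicity), , drop = FALSE]
  structure(list(k = as.integer(k), bins = bins), class = "kmer_histogram")
}

## genomic multiplicity of each distinct canonical k-mer (integer vector,
## one entry per distinct k-mer; identities are not retained)
kmer_multiplicities <- function(seqs, k) {
  codes <- canonical_kmer_codes(seqs, k)
  if (!length(codes)) return(integer(0))
  codes <- sort(codes)
  rle(codes)$lengths
}

## canonical (min of forward / reverse-complement) numeric codes of all
## k-mer windows of `seqs`; windows with ambiguous bases are dropped.
## Exact for k <= 26 (4^k < 2^53).
canonical_kmer_codes <- function(seqs, k) {
  stop_if_not(k <= 26L, "numeric k-mer encoding supports k <= 26")
  seqs <- as_seq_char(seqs)
  out <- vector("list", length(seqs))
  for (si in seq_along(seqs)) {
    b <- seq_to_codes(seqs[[si]])
    n <- length(b)
    if (n < k) next
    nw <- n - k + 1L
    fw <- numeric(nw); rv <- numeric(nw)
    bc <- 3L - b                       # complement code
    for (j in seq_len(k)) {
      fw <- fw * 4 + b[j:(n - k + j)]
      ## reverse complement read right-to-left
      jj <- k - j + 1L
      rv <- rv * 4 + bc[jj:(n - k + jj)]
    }
    cn <- pmin(fw, rv)
    out[[si]] <- cn[!is.na(cn)]
  }
  unlist(out) %||% numeric(0)
}
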