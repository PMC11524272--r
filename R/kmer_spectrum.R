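## k-mer spectrum estimation of monoploid genome size and heterozygosity.
##
## The non-error spectrum of a diploid is modelled as a two-component
## Poisson mixture with means (lambda, 2*lambda): heterozygous k-mers sit
## at the per-haplotype depth, homozygous k-mers at twice that.  With
## D_het / D_hom the distinct k-mers assigned to each component,
##   G        = D_hom + D_het / 2          (monoploid distinct k-mers)
##   a        = (D_het / 2) / G            (fraction of het k-mer loci)
##   het_rate = 1 - (1 - a)^(1/k)          (a het SNP covers k k-mers)
## and monoploid genome size = (total k-mer copies above the error cutoff)
## / lambda_hom.

#' Count canonical k-mers of a set of sequences
#'
#' Canonicalization takes the lexicographic minimum of a k-mer and its
#' reverse complement; windows containing ambiguous bases are skipped.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param k odd k-mer size (<= 26).
#' @return a `kmer_histogram`: list with `k` and `bins` (data.frame
#'   `multiplicity`, `count` of distinct k-mers at that multiplicity).
#' @export
count_kmers <- function(sequences, k) {
  stop_if_not(k %% 2L == 1L, "k must be odd")
  seqs <- as_seq_char(sequences)
  stop_if_not(length(seqs) > 0, "no sequences given")
  if (max(nchar(seqs)) < k) {
    warning("k exceeds the longest usable sequence; histogram is empty")
    return(structure(list(k = as.integer(k),
                          bins = data.frame(multiplicity = integer(0),
                                            count = integer(0))),
                     class = "kmer_histogram"))
  }
  mult <- kmer_multiplicities(seqs, k)
  tab <- table(mult)
  structure(list(k = as.integer(k),
                 bins = data.frame(multiplicity = as.integer(names(tab)),
                                   count = as.integer(tab))),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %d): %s distinct k-mers, %s copies\n",
              x$k, format(sum(x$bins$count), big.mark = ","),
              format(sum(as.numeric(x$bins$multiplicity) * x$bins$count),
                     big.mark = ",")))
  invisible(x)
}

#' Read/write the two-column multiplicity histogram dialect
#'
#' The de facto `jellyfish histo` / `kmerfreq` format: multiplicity and
#' distinct-k-mer count, whitespace-separated, no header.
#'
#' @param path histogram file.
#' @param k k-mer size the histogram was counted at.
#' @return `read_kmer_histogram`: a `kmer_histogram`.
#' @export
read_kmer_histogram <- function(path, k) {
  df <- read.table(path, header = FALSE,
                   col.names = c("multiplicity", "count"))
  structure(list(k = as.integer(k), bins = df), class = "kmer_histogram")
}

#' @rdname read_kmer_histogram
#' @param hist a `kmer_histogram`.
#' @export
write_kmer_histogram <- function(hist, path) {
  write.table(hist$bins, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## dense count vector over multiplicities 1..max
dense_counts <- function(hist) {
  m <- hist$bins$multiplicity
  cnt <- numeric(max(m))
  cnt[m] <- hist$bins$count
  cnt
}

## first local minimum = error cutoff; 1 if the spectrum rises from the start
find_error_cutoff <- function(cnt) {
  if (length(cnt) < 3L) return(1L)
  for (i in 2L:(length(cnt) - 1L))
    if (cnt[i] <= cnt[i - 1L] && cnt[i] < cnt[i + 1L]) return(i)
  1L
}

## local maxima of a (lightly smoothed) count vector above a cutoff
find_peaks <- function(cnt, cutoff) {
  n <- length(cnt)
  sm <- cnt
  if (n >= 5L)
    sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  peaks <- integer(0)
  for (i in seq(max(2L, cutoff + 1L), n - 1L))
    if (sm[i] > sm[i - 1L] && sm[i] >= sm[i + 1L]) peaks <- c(peaks, i)
  ## merge plateau-adjacent peaks
  peaks[c(TRUE, diff(peaks) > 2L)]
}

## one EM run of the constrained mixture pi * Pois(lam) + (1-pi) * Pois(2 lam)
poisson_pair_em <- function(m, w, lam0, max_iter = 200L, tol = 1e-8) {
  lam <- lam0; pi1 <- 0.5; ll_old <- -Inf; r1 <- rep(0.5, length(m))
  for (it in seq_len(max_iter)) {
    l1 <- log(pi1) + stats::dpois(m, lam, log = TRUE)
    l2 <- log(1 - pi1) + stats::dpois(m, 2 * lam, log = TRUE)
    mx <- pmax(l1, l2)
    den <- mx + log(exp(l1 - mx) + exp(l2 - mx))
    r1 <- exp(l1 - den)
    ll <- sum(w * den)
    pi1 <- min(max(sum(w * r1) / sum(w), 1e-12), 1 - 1e-12)
    lam <- sum(w * m) / sum(w * (2 - r1))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(lam = lam, pi1 = pi1, r1 = r1, loglik = ll)
}

#' Fit a diploid k-mer spectrum
#'
#' Estimates the error cutoff (first local minimum of the histogram), then
#' fits a two-component Poisson mixture with means `(lambda, 2 * lambda)`
#' by EM over multiplicities above the cutoff.  Because the dominant peak
#' of a highly heterozygous spectrum can be either the heterozygous or the
#' homozygous one, the EM is started from both interpretations of the main
#' peak (depth `lambda` vs depth `2 * lambda`) and the higher-likelihood
#' solution is kept; a degenerate mixture (one component weight below 2%)
#' is flagged `unimodal` with `het_rate = 0` and the main peak treated as
#' homozygous.
#'
#' @param hist a `kmer_histogram`.
#' @param lambda_hom_hint optional known homozygous peak depth; when given
#'   it replaces the automatic initialization.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return an object of class `spectrum_fit` with elements `lambda_het`,
#'   `lambda_hom`, `error_cutoff`, `genome_size_mono`, `het_rate`,
#'   `mixture_weights`, `unimodal`, `loglik`.
#' @export
fit_spectrum <- function(hist, lambda_hom_hint = NULL, max_iter = 200L,
                         tol = 1e-8) {
  cnt <- dense_counts(hist)
  cutoff <- find_error_cutoff(cnt)
  mults <- seq_along(cnt)
  use <- mults >= cutoff & cnt > 0
  m <- mults[use]; w <- cnt[use]
  stop_if_not(length(m) > 2L, "histogram too sparse to fit")

  ## main non-error peak on a lightly smoothed spectrum
  sm <- cnt
  if (length(cnt) >= 7L) {
    sm <- stats::filter(cnt, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- cnt[is.na(sm)]
  }
  sm[seq_len(min(cutoff, length(sm)))] <- 0
  main <- which.max(sm)

  inits <- if (!is.null(lambda_hom_hint)) lambda_hom_hint / 2 else
    c(main, main / 2)
  fits <- lapply(inits, function(l0)
    poisson_pair_em(m, w, l0, max_iter = max_iter, tol = tol))
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  lam <- best$lam; pi1 <- best$pi1; r1 <- best$r1

  if (min(pi1, 1 - pi1) < 0.02) {
    ## degenerate mixture: a single peak, read as homozygous depth
    lam_hom <- sum(w * m) / sum(w)
    fit <- list(lambda_het = lam_hom / 2, lambda_hom = lam_hom,
                error_cutoff = cutoff,
                genome_size_mono = sum(w * m) / lam_hom,
                het_rate = 0, mixture_weights = c(het = 0, hom = 1),
                unimodal = TRUE, loglik = best$loglik, k = hist$k)
    class(fit) <- "spectrum_fit"
    return(fit)
  }

  d_het <- sum(w * r1)
  d_hom <- sum(w * (1 - r1))
  g <- d_hom + d_het / 2
  a <- (d_het / 2) / g
  het_rate <- 1 - (1 - a)^(1 / hist$k)
  genome_size <- sum(w * m) / (2 * lam)

  fit <- list(lambda_het = lam, lambda_hom = 2 * lam,
              error_cutoff = cutoff, genome_size_mono = genome_size,
              het_rate = het_rate,
              mixture_weights = c(het = pi1, hom = 1 - pi1),
              unimodal = FALSE, loglik = best$loglik, k = hist$k)
  class(fit) <- "spectrum_fit"
  fit
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat("k-mer spectrum fit\n")
  if (x$unimodal)
    cat("  no heterozygous peak detected (unimodal spectrum)\n")
  cat(sprintf("  peak depths: het %.1fx, hom %.1fx (error cutoff %d)\n",
              x$lambda_het, x$lambda_hom, x$error_cutoff))
  cat(sprintf("  monoploid genome size: %s bp\n",
              format(round(x$genome_size_mono), big.mark = ",")))
  cat(sprintf("  heterozygosity: %.2f%%\n", 100 * x$het_rate))
  invisible(x)
}

#' @export
plot.spectrum_fit <- function(x, hist, ...) {
  if (missing(hist)) stop("supply the fitted kmer_histogram")
  b <- hist$bins
  plot(b$multiplicity, b$count, type = "h", xlab = "k-mer multiplicity",
       ylab = "distinct k-mers", ...)
  graphics::abline(v = c(x$lambda_het, x$lambda_hom), lty = 2)
  invisible(x)
}
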