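## Collinearity-block detection between two haplotypes: unique k-mer seed
## anchors, maximal exact-match extension, weighted collinear chaining, and
## one-to-one block filtering at the mummer-style thresholds (block span
## >= 15 kb, identity >= 80%, mutual overlap <= 80%).

## forward (non-canonical) k-mer codes of one sequence; NA over ambiguity
forward_kmer_codes <- function(seq, k) {
  b <- seq_to_codes(seq)
  n <- length(b)
  if (n < k) return(numeric(0))
  nw <- n - k + 1L
  fw <- numeric(nw)
  for (j in seq_len(k)) fw <- fw * 4 + b[j:(n - k + j)]
  fw
}

## occurrence count of each value of `x` within sorted vector `sorted`
count_in_sorted <- function(x, sorted) {
  findInterval(x, sorted) - findInterval(x - 0.5, sorted)
}

## first index in `sorted_pos`-ordered codes equal to x (codes sorted)
lookup_first <- function(x, sorted) findInterval(x - 0.5, sorted) + 1L

# ---- anchors ------------------------------------------------------------

#' Find exact-match anchors between two sequences
#'
#' Seeds are k-mers occurring at most `max_occ` times in each sequence and
#' exactly once in at least one of them; seed matches on the same diagonal
#' are merged and extended to maximal exact matches.  Both strands are
#' searched.
#'
#' @param seq_a,seq_b chromosome sequences (character scalars).
#' @param seed_k seed k-mer size in `[15, 26]` (default 21).
#' @param max_occ repeat guard: seeds seen more often are dropped.
#' @return data.frame with `pos_a`, `pos_b`, `length`, `strand`; for
#'   `strand == "-"`, `A[pos_a..]` equals the reverse complement of
#'   `B[pos_b..pos_b+length-1]` (B positions on the forward strand).
#' @export
find_anchors <- function(seq_a, seq_b, seed_k = 21L, max_occ = 10L) {
  stop_if_not(seed_k >= 15L && seed_k <= 26L, "seed_k must be in [15, 26]")
  out <- list()
  for (strand in c("+", "-")) {
    sb <- if (strand == "+") seq_b else revcomp(seq_b)
    runs <- anchor_runs(seq_a, sb, seed_k, max_occ)
    if (!nrow(runs)) next
    if (strand == "-") {
      lb <- nchar(seq_b)
      ## map positions in revcomp(B) back to forward-strand B coordinates
      runs$pos_b <- lb - (runs$pos_b + runs$length - 1L) + 1L
    }
    runs$strand <- strand
    out[[strand]] <- runs
  }
  if (!length(out))
    return(data.frame(pos_a = integer(0), pos_b = integer(0),
                      length = integer(0), strand = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$pos_a), , drop = FALSE]
}

## merged + maximally extended exact matches of seq_a vs seq_b (one strand)
anchor_runs <- function(seq_a, seq_b, k, max_occ) {
  empty <- data.frame(pos_a = integer(0), pos_b = integer(0),
                      length = integer(0))
  fa <- forward_kmer_codes(seq_a, k)
  fb <- forward_kmer_codes(seq_b, k)
  if (!length(fa) || !length(fb)) return(empty)
  ord_a <- order(fa, na.last = NA); sa <- fa[ord_a]
  ord_b <- order(fb, na.last = NA); sb <- fb[ord_b]
  ca <- count_in_sorted(fa, sa)       # per-position occurrence counts
  cb_of_a <- count_in_sorted(fa, sb)
  pairs_pa <- integer(0); pairs_pb <- integer(0)

  ## bulk: codes unique in both
  m11 <- which(!is.na(fa) & ca == 1L & cb_of_a == 1L)
  if (length(m11)) {
    idx <- lookup_first(fa[m11], sb)
    pairs_pa <- m11
    pairs_pb <- ord_b[idx]
  }
  ## rare: unique on one side only, <= max_occ on the other
  rest <- which(!is.na(fa) & cb_of_a >= 1L &
                  ((ca == 1L & cb_of_a > 1L & cb_of_a <= max_occ) |
                     (ca > 1L & ca <= max_occ & cb_of_a == 1L)))
  for (pa in rest) {
    i0 <- lookup_first(fa[pa], sb)
    nb <- cb_of_a[pa]
    pairs_pa <- c(pairs_pa, rep(pa, nb))
    pairs_pb <- c(pairs_pb, ord_b[i0:(i0 + nb - 1L)])
  }
  if (!length(pairs_pa)) return(empty)

  ## merge seed pairs along diagonals
  diag <- pairs_pa - pairs_pb
  o <- order(diag, pairs_pa)
  pa <- pairs_pa[o]; pb <- pairs_pb[o]; dg <- diag[o]
  runs <- list()
  rs_a <- pa[1L]; rs_b <- pb[1L]; re_a <- pa[1L] + k - 1L
  for (i in seq_along(pa)[-1L]) {
    same <- dg[i] == dg[i - 1L]
    if (same && pa[i] <= re_a + 1L) {
      re_a <- max(re_a, pa[i] + k - 1L)
    } else if (same && pa[i] <= re_a + 200L &&
                 substr(seq_a, re_a + 1L, pa[i] - 1L) ==
                 substr(seq_b, re_a + 1L - dg[i], pa[i] - 1L - dg[i])) {
      re_a <- pa[i] + k - 1L
    } else {
      runs[[length(runs) + 1L]] <- c(rs_a, rs_b, re_a - rs_a + 1L)
      rs_a <- pa[i]; rs_b <- pb[i]; re_a <- pa[i] + k - 1L
    }
  }
  runs[[length(runs) + 1L]] <- c(rs_a, rs_b, re_a - rs_a + 1L)
  rm <- do.call(rbind, runs)

  ## maximal extension against the raw bytes
  ra <- charToRaw(seq_a); rb <- charToRaw(seq_b)
  na <- length(ra); nb <- length(rb)
  pos_a <- rm[, 1L]; pos_b <- rm[, 2L]; len <- rm[, 3L]
  for (i in seq_along(pos_a)) {
    ## left
    while (pos_a[i] > 1L && pos_b[i] > 1L &&
             ra[pos_a[i] - 1L] == rb[pos_b[i] - 1L]) {
      pos_a[i] <- pos_a[i] - 1L; pos_b[i] <- pos_b[i] - 1L
      len[i] <- len[i] + 1L
    }
    ## right
    ea <- pos_a[i] + len[i] - 1L; eb <- pos_b[i] + len[i] - 1L
    while (ea < na && eb < nb && ra[ea + 1L] == rb[eb + 1L]) {
      ea <- ea + 1L; eb <- eb + 1L; len[i] <- len[i] + 1L
    }
  }
  out <- data.frame(pos_a = pos_a, pos_b = pos_b, length = len)
  unique(out)
}

# ---- chaining -----------------------------------------------------------

#' Chain anchors into collinear runs
#'
#' Weighted collinear chaining: anchors are chained when both coordinates
#' increase (per strand; B decreases on "-"), maximizing total anchored
#' length minus a gap penalty of `0.05 * |gap_a - gap_b| + 0.01 *
#' min(gap_a, gap_b)`.  Chains break at gaps above `max_gap` on either
#' axis.  The dynamic program considers up to `window` predecessors per
#' anchor (exact whenever `window >= number of anchors`).
#'
#' @param anchors data.frame from [find_anchors()] (one chromosome pair).
#' @param max_gap maximum per-axis gap within a chain (bases).
#' @param min_chain_anchors minimum anchors per reported chain.
#' @param window DP predecessor window.
#' @return list of data.frames (anchors of each chain, in A order), each
#'   with attribute `strand`.
#' @export
chain_anchors <- function(anchors, max_gap = 100000L,
                          min_chain_anchors = 1L, window = 64L) {
  chains <- list()
  for (strand in unique(anchors$strand)) {
    an <- anchors[anchors$strand == strand, , drop = FALSE]
    an <- an[order(an$pos_a, an$pos_b), , drop = FALSE]
    ## orient B so both axes increase along a collinear chain
    bkey <- if (strand == "-") -(an$pos_b + an$length - 1L) else an$pos_b
    chains <- c(chains, chain_dp(an, bkey, max_gap, window,
                                 min_chain_anchors, strand))
  }
  chains
}

chain_dp <- function(an, bkey, max_gap, window, min_chain_anchors, strand) {
  n <- nrow(an)
  if (!n) return(list())
  score <- as.numeric(an$length)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in (i - 1L):max(1L, i - window)) {
      if (an$pos_a[j] >= an$pos_a[i]) next
      if (bkey[j] >= bkey[i]) next
      ga <- max(0L, an$pos_a[i] - (an$pos_a[j] + an$length[j]))
      gb_raw <- bkey[i] - (bkey[j] + an$length[j])
      gb <- max(0L, gb_raw)
      if (ga > max_gap || gb > max_gap) next
      pen <- 0.05 * abs(ga - gb) + 0.01 * min(ga, gb)
      cand <- score[j] + an$length[i] - pen
      if (cand > score[i]) { score[i] <- cand; parent[i] <- j }
    }
  }
  used <- rep(FALSE, n)
  out <- list()
  repeat {
    avail <- which(!used)
    if (!length(avail)) break
    tip <- avail[which.max(score[avail])]
    idx <- integer(0); cur <- tip
    while (!is.na(cur) && !used[cur]) {
      idx <- c(cur, idx); used[cur] <- TRUE; cur <- parent[cur]
    }
    if (length(idx) >= min_chain_anchors) {
      ch <- an[idx, , drop = FALSE]
      attr(ch, "strand") <- strand
      attr(ch, "score") <- score[tip]
      out[[length(out) + 1L]] <- ch
    }
  }
  out
}

# ---- blocks -------------------------------------------------------------

#' Turn chains into collinearity blocks with identity
#'
#' Inter-anchor gaps up to `gap_limit` on both sides are aligned at base
#' level ([align_gap()]); identity is matches over alignment columns across
#' anchors and aligned gaps.  Gaps beyond the limit (structural events) are
#' excluded from the identity denominator and left to the SV caller.
#'
#' @param chains list from [chain_anchors()].
#' @param seq_a,seq_b the chromosome sequences.
#' @param chrom_a,chrom_b chromosome names recorded in the blocks.
#' @param gap_limit largest gap aligned at base level (default 100 kb).
#' @return data.frame of blocks (one row per chain) with columns `id`,
#'   `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b`,
#'   `strand`, `identity` (percent), `aligned_length`, `n_anchors`,
#'   `score`, and the chain anchors in `attr(, "anchors")`.
#' @export
build_blocks <- function(chains, seq_a, seq_b, chrom_a = "A", chrom_b = "B",
                         gap_limit = 100000L) {
  rows <- list(); anchor_list <- list()
  for (bi in seq_along(chains)) {
    ch <- chains[[bi]]
    strand <- attr(ch, "strand")
    matches <- 0; columns <- 0
    matches <- matches + sum(ch$length)
    columns <- columns + sum(ch$length)
    if (nrow(ch) > 1L) {
      for (i in seq_len(nrow(ch) - 1L)) {
        gap <- chain_gap(ch, i, strand, nchar(seq_b))
        if (gap$ga < 0L || gap$gb < 0L) next      # overlapping anchors
        if (gap$ga == 0L && gap$gb == 0L) next
        if (max(gap$ga, gap$gb) > gap_limit) next # deferred to SV caller
        ga_seq <- if (gap$ga > 0L) substr(seq_a, gap$a_from, gap$a_to) else ""
        gb_seq <- if (gap$gb > 0L) substr(seq_b, gap$b_from, gap$b_to) else ""
        if (strand == "-" && gap$gb > 0L) gb_seq <- revcomp(gb_seq)
        al <- align_gap(ga_seq, gb_seq)
        matches <- matches + al$matches
        columns <- columns + al$columns
      }
    }
    start_a <- min(ch$pos_a); end_a <- max(ch$pos_a + ch$length - 1L)
    start_b <- min(ch$pos_b); end_b <- max(ch$pos_b + ch$length - 1L)
    rows[[bi]] <- data.frame(
      id = bi, chrom_a = chrom_a, start_a = start_a, end_a = end_a,
      chrom_b = chrom_b, start_b = start_b, end_b = end_b,
      strand = strand,
      identity = if (columns > 0) 100 * matches / columns else 100,
      aligned_length = columns, n_anchors = nrow(ch),
      score = attr(ch, "score") %||% sum(ch$length),
      stringsAsFactors = FALSE)
    anchor_list[[bi]] <- ch
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), chrom_a = character(0), start_a = integer(0),
               end_a = integer(0), chrom_b = character(0),
               start_b = integer(0), end_b = integer(0),
               strand = character(0), identity = numeric(0),
               aligned_length = numeric(0), n_anchors = integer(0),
               score = numeric(0))
  attr(blocks, "anchors") <- anchor_list
  blocks
}

## A- and B-side gap between consecutive chain anchors i and i+1.
## Maximally extended anchors can overlap around an indel in repetitive
## context; the overlap is resolved by trimming the start of the right
## anchor (both coordinates), keeping both gap sides non-negative.
chain_gap <- function(ch, i, strand, len_b) {
  a_from <- ch$pos_a[i] + ch$length[i]
  a_to <- ch$pos_a[i + 1L] - 1L
  if (strand == "+") {
    b_from <- ch$pos_b[i] + ch$length[i]
    b_to <- ch$pos_b[i + 1L] - 1L
  } else {
    ## on "-", the next anchor in A order sits left of the previous in B
    b_from <- ch$pos_b[i + 1L] + ch$length[i + 1L]
    b_to <- ch$pos_b[i] - 1L
  }
  ga <- a_to - a_from + 1L
  gb <- b_to - b_from + 1L
  o <- max(0L, -ga, -gb)
  if (o > 0L && o < ch$length[i + 1L]) {
    ## shrink the right anchor's start
    a_to <- a_to + o
    if (strand == "+") b_to <- b_to + o else b_from <- b_from - o
    ga <- ga + o; gb <- gb + o
  } else if (o > 0L && o < ch$length[i]) {
    ## right anchor too short: shrink the left anchor's end instead
    a_from <- a_from - o
    if (strand == "+") b_from <- b_from - o else b_to <- b_to + o
    ga <- ga + o; gb <- gb + o
  }
  list(ga = ga, gb = gb,
       a_from = a_from, a_to = a_to, b_from = b_from, b_to = b_to)
}

#' Filter blocks to the one-to-one collinearity set
#'
#' Keeps blocks with A-span at least `min_len` and identity at least
#' `min_identity` percent, then enforces a one-to-one mapping: among blocks
#' overlapping more than `max_overlap` (fraction of the shorter span) on
#' either axis, only the higher-scoring block (`aligned_length * identity`)
#' is kept.
#'
#' @param blocks data.frame from [build_blocks()] (may pool chromosome
#'   pairs).
#' @param min_len minimum A-span in bases (default 15000).
#' @param min_identity minimum identity percent (default 80).
#' @param max_overlap maximum tolerated mutual overlap fraction (default
#'   0.8).
#' @return filtered block data.frame (anchors attribute subset accordingly).
#' @export
filter_blocks <- function(blocks, min_len = 15000L, min_identity = 80,
                          max_overlap = 0.8) {
  anchors <- attr(blocks, "anchors") %||% vector("list", nrow(blocks))
  span_a <- blocks$end_a - blocks$start_a + 1L
  keep <- span_a >= min_len & blocks$identity >= min_identity
  blocks <- blocks[keep, , drop = FALSE]
  anchors <- anchors[keep]
  if (nrow(blocks) > 1L) {
    sc <- blocks$aligned_length * blocks$identity
    ord <- order(-sc)
    chosen <- logical(nrow(blocks))
    for (i in ord) {
      clash <- FALSE
      for (j in which(chosen)) {
        if (overlap_frac(blocks$chrom_a[i], blocks$start_a[i], blocks$end_a[i],
                         blocks$chrom_a[j], blocks$start_a[j],
                         blocks$end_a[j]) > max_overlap ||
            overlap_frac(blocks$chrom_b[i], blocks$start_b[i], blocks$end_b[i],
                         blocks$chrom_b[j], blocks$start_b[j],
                         blocks$end_b[j]) > max_overlap) {
          clash <- TRUE; break
        }
      }
      if (!clash) chosen[i] <- TRUE
    }
    blocks <- blocks[chosen, , drop = FALSE]
    anchors <- anchors[chosen]
  }
  ord <- order(blocks$chrom_a, blocks$start_a)
  blocks <- blocks[ord, , drop = FALSE]
  anchors <- anchors[ord]
  rownames(blocks) <- NULL
  attr(blocks, "anchors") <- anchors
  blocks
}

## overlap of two intervals as a fraction of the shorter one
overlap_frac <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov <= 0L) return(0)
  ov / min(e1 - s1 + 1L, e2 - s2 + 1L)
}

#' Summary statistics of collinearity blocks
#'
#' @param blocks block data.frame.
#' @param min_size only blocks with A-span at least this size are counted.
#' @return list with `count`, `mean_size` (absent when count is 0) and
#'   `total_size`, in bases of A-span.
#' @export
block_stats <- function(blocks, min_size = 15000L) {
  span <- blocks$end_a - blocks$start_a + 1L
  span <- span[span >= min_size]
  if (!length(span)) return(list(count = 0L, total_size = 0))
  list(count = length(span), mean_size = mean(span),
       total_size = sum(as.numeric(span)))
}

# ---- whole-genome driver ------------------------------------------------

#' Align two haplotype genomes into collinearity blocks
#'
#' Runs anchor finding, chaining and block construction for each chromosome
#' pair and applies the one-to-one filter genome-wide.
#'
#' @param genome_a,genome_b named character vectors of chromosomes.
#' @param pairing `"homologous"` pairs chromosomes by index; `"all"` aligns
#'   every A chromosome against every B chromosome (needed for
#'   translocation detection across chromosomes).
#' @param seed_k,max_gap,min_len,min_identity,max_overlap,gap_limit tuning
#'   parameters passed to the stage functions.
#' @return list with `blocks` (filtered one-to-one set) and `blocks_all`
#'   (all chains before filtering, used by the SV caller).
#' @export
align_haplotypes <- function(genome_a, genome_b, pairing = "homologous",
                             seed_k = 21L, max_gap = 100000L,
                             min_len = 15000L, min_identity = 80,
                             max_overlap = 0.8, gap_limit = 100000L) {
  genome_a <- as_seq_char(genome_a); genome_b <- as_seq_char(genome_b)
  pairs <- if (pairing == "homologous") {
    data.frame(a = seq_along(genome_a),
               b = seq_len(min(length(genome_a), length(genome_b))))
  } else {
    expand.grid(a = seq_along(genome_a), b = seq_along(genome_b))
  }
  all_blocks <- list(); all_anchors <- list()
  for (i in seq_len(nrow(pairs))) {
    ca <- names(genome_a)[pairs$a[i]]; cb <- names(genome_b)[pairs$b[i]]
    an <- find_anchors(genome_a[[pairs$a[i]]], genome_b[[pairs$b[i]]],
                       seed_k = seed_k)
    if (!nrow(an)) next
    chains <- chain_anchors(an, max_gap = max_gap)
    bl <- build_blocks(chains, genome_a[[pairs$a[i]]],
                       genome_b[[pairs$b[i]]], ca, cb,
                       gap_limit = gap_limit)
    all_anchors <- c(all_anchors, attr(bl, "anchors"))
    all_blocks[[length(all_blocks) + 1L]] <- bl
  }
  blocks_all <- if (length(all_blocks)) do.call(rbind, all_blocks) else
    build_blocks(list(), "", "")
  blocks_all$id <- seq_len(nrow(blocks_all))
  attr(blocks_all, "anchors") <- all_anchors
  filtered <- filter_blocks(blocks_all, min_len = min_len,
                            min_identity = min_identity,
                            max_overlap = max_overlap)
  list(blocks = filtered, blocks_all = blocks_all)
}

#' Export blocks as a PAF-like TSV
#'
#' @param blocks block data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  df <- blocks[, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                   "end_b", "strand", "identity", "aligned_length")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
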