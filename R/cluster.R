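# Redundancy removal: greedy representative clustering over a from-scratch
# Needleman-Wunsch global aligner, mimicking CD-HIT at desk scale (inputs
# are <= 130 residues and few, so O(n^2) exact alignment is affordable and
# no k-mer prefilter is used).

#' Needleman-Wunsch global alignment with percent identity
#'
#' Scores: `match` +1, `mismatch` 0, `gap` -1 by default. Under these scores
#' several alignments can share the optimal score while differing in the
#' number of identical columns, so the reported alignment is the
#' score-optimal one that maximises identical columns (computed exactly by
#' a lexicographic dynamic program on the pair score/matches). This makes
#' identity well-defined and symmetric in its arguments; remaining traceback
#' ties break deterministically diagonal > up > left. Identity is identical
#' columns divided either by the alignment length (gap columns included) or
#' by the shorter sequence length; the latter is the CD-HIT convention and
#' the default used by [greedy_cluster()].
#'
#' @param a,b nonempty sequence strings.
#' @param match,mismatch,gap scores.
#' @param identity_denominator `"shorter"` or `"alignment"`.
#' @return list: `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   `matches`, `alignment_length`, `identity`.
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1,
                         identity_denominator = c("shorter", "alignment")) {
  identity_denominator <- match.arg(identity_denominator)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  eq <- outer(x, y, "==")
  sub <- matrix(mismatch, n, m)
  sub[eq] <- match
  # lexicographic DP on (score, identical columns): both are additive along
  # an alignment path, so maximising the pair cell-by-cell yields the
  # score-optimal alignment with the most identical columns.
  # n*m <= 17k for full-length precursors.
  S <- matrix(0, n + 1L, m + 1L)
  S[1, ] <- gap * (0:m)
  S[, 1] <- gap * (0:n)
  Mm <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sd <- S[i, j] + sub[i, j]; md <- Mm[i, j] + eq[i, j]
      su <- S[i, j + 1L] + gap;  mu <- Mm[i, j + 1L]
      sl <- S[i + 1L, j] + gap;  ml <- Mm[i + 1L, j]
      bs <- sd; bm <- md
      if (su > bs || (su == bs && mu > bm)) { bs <- su; bm <- mu }
      if (sl > bs || (sl == bs && ml > bm)) { bs <- sl; bm <- ml }
      S[i + 1L, j + 1L] <- bs
      Mm[i + 1L, j + 1L] <- bm
    }
  }
  # traceback along the chosen optimum, diagonal > up > left
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    s_cur <- S[i + 1L, j + 1L]; m_cur <- Mm[i + 1L, j + 1L]
    if (i > 0L && j > 0L && S[i, j] + sub[i, j] == s_cur &&
        Mm[i, j] + eq[i, j] == m_cur) {
      ra <- c(x[i], ra); rb <- c(y[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i, j + 1L] + gap == s_cur &&
               Mm[i, j + 1L] == m_cur) {
      ra <- c(x[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(y[j], rb); j <- j - 1L
    }
  }
  matches <- sum(ra == rb & ra != "-")
  alen <- length(ra)
  denom <- if (identity_denominator == "alignment") alen else min(n, m)
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       score = S[n + 1L, m + 1L], matches = matches,
       alignment_length = alen, identity = matches / denom)
}

#' Greedy representative clustering at an identity threshold
#'
#' CD-HIT-style: sequences are processed in decreasing length (ties broken
#' lexicographically by id); each sequence joins the first existing cluster
#' whose *representative* aligns to it at `threshold` identity or better,
#' otherwise it founds a new cluster with itself as representative. As a
#' consequence representatives are pairwise below the threshold.
#'
#' @param matures record data.frame with unique `id` and `residues`.
#' @param threshold identity threshold in `[0, 1]` (default 0.70).
#' @param identity_denominator passed to [global_align()].
#' @return data.frame: `cluster` (integer id), `representative`, `member`,
#'   `identity` (member vs representative).
#' @export
greedy_cluster <- function(matures, threshold = 0.70,
                           identity_denominator = c("shorter", "alignment")) {
  identity_denominator <- match.arg(identity_denominator)
  if (anyDuplicated(matures$id)) stop("cluster input ids must be unique")
  if (nrow(matures) == 0L)
    return(data.frame(cluster = integer(0), representative = character(0),
                      member = character(0), identity = numeric(0)))
  ord <- order(-nchar(matures$residues), matures$id, method = "radix")
  matures <- matures[ord, , drop = FALSE]
  reps <- integer(0)                       # row indices of representatives
  rows <- vector("list", nrow(matures))
  for (i in seq_len(nrow(matures))) {
    placed <- FALSE
    for (r in reps) {
      aln <- global_align(matures$residues[r], matures$residues[i],
                          identity_denominator = identity_denominator)
      if (aln$identity >= threshold) {
        rows[[i]] <- data.frame(cluster = match(r, reps),
                                representative = matures$id[r],
                                member = matures$id[i],
                                identity = aln$identity,
                                stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      rows[[i]] <- data.frame(cluster = length(reps),
                              representative = matures$id[i],
                              member = matures$id[i], identity = 1,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$cluster, -out$identity, out$member), , drop = FALSE]
}
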