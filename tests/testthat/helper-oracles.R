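# Independent oracles used across the suite. Each is a deliberately naive
# implementation (exhaustive enumeration or an alternative closed form) kept
# free of the package's own code paths.

# Exhaustive motif oracle: check every 6-subset of cysteine positions.
oracle_motif <- function(residues, bounds = list(c(2, 18), c(3, 3), c(2, 12),
                                                 c(4, 17), c(1, 1))) {
  m <- gregexpr("C", residues, fixed = TRUE)[[1]]
  cpos <- as.integer(m[m > 0])
  if (length(cpos) < 6)
    return(list(match = FALSE, assignments = list()))
  subs <- utils::combn(cpos, 6)
  keep <- apply(subs, 2, function(a) {
    g <- diff(a) - 1
    all(vapply(1:5, function(k) g[k] >= bounds[[k]][1] &&
                 g[k] <= bounds[[k]][2], logical(1)))
  })
  list(match = any(keep),
       assignments = lapply(which(keep), function(k) as.integer(subs[, k])))
}

# Random protein string with a controlled cysteine count.
random_protein <- function(len, n_cys) {
  bg <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
          "R", "S", "T", "V", "W", "Y")
  ch <- sample(bg, len, replace = TRUE)
  n_cys <- min(n_cys, len)
  if (n_cys > 0) ch[sample(len, n_cys)] <- "C"
  paste(ch, collapse = "")
}

# Exhaustive global-alignment oracle: walk every alignment path, return the
# optimal score and the identity values realised by optimal alignments
# (both denominator conventions).
oracle_align_enum <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  best <- -Inf
  opts <- list()
  rec <- function(i, j, sc, mt, ln) {
    if (i > n && j > m) {
      if (sc > best) {
        best <<- sc
        opts <<- list(c(mt, ln))
      } else if (sc == best) {
        opts[[length(opts) + 1]] <<- c(mt, ln)
      }
      return(invisible())
    }
    if (i <= n && j <= m) {
      eq <- x[i] == y[j]
      rec(i + 1, j + 1, sc + eq, mt + eq, ln + 1)
    }
    if (i <= n) rec(i + 1, j, sc - 1, mt, ln + 1)
    if (j <= m) rec(i, j + 1, sc - 1, mt, ln + 1)
  }
  rec(1L, 1L, 0L, 0L, 0L)
  list(score = best,
       id_alignment = unique(vapply(opts, function(o) o[1] / o[2],
                                    numeric(1))),
       id_shorter = unique(vapply(opts, function(o) o[1] / min(n, m),
                                  numeric(1))))
}

# Quaternion (Horn) superposition oracle: closed-form RMSD from the largest
# eigenvalue of the 4x4 key matrix, no rotation matrix construction.
oracle_quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  n <- nrow(A)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  S <- t(B) %*% A
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lambda)) / n)
}

# Random point cloud helper.
random_cloud <- function(n) matrix(stats::rnorm(3 * n, sd = 4), ncol = 3)
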