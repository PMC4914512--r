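# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (Biostrings alignment, vectorized z-scores,
# ray casting) so that agreement is evidence, not tautology.

# Affine-gap local alignment (Smith-Waterman) in plain R with traceback.
# Scoring mirrors the package contract: match +2, mismatch -3, first gap
# position -(open + ext) = -7, each further gap position -2.
bf_local_align <- function(a, b, match = 2, mismatch = -3,
                           gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  go <- -(gap_open + gap_ext); ge <- -gap_ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + s)
      X[i, j] <- max(M[i - 1, j] + go, X[i - 1, j] + ge)
      Y[i, j] <- max(M[i, j - 1] + go, Y[i, j - 1] + ge)
    }
  }
  best <- which(M == max(M), arr.ind = TRUE)[1, ]
  i <- unname(best[1]); j <- unname(best[2])
  state <- "M"; nmatch <- 0L
  ai_end <- i - 1; bj_end <- j - 1; ai_start <- i - 1; bj_start <- j - 1
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] == 0) break
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      if (A[i - 1] == B[j - 1]) nmatch <- nmatch + 1L
      ai_start <- i - 1; bj_start <- j - 1
      prev <- M[i, j] - s
      state <- if (isTRUE(all.equal(prev, M[i - 1, j - 1]))) "M"
      else if (isTRUE(all.equal(prev, X[i - 1, j - 1]))) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      state <- if (isTRUE(all.equal(X[i, j], M[i - 1, j] + go))) "M" else "X"
      i <- i - 1
    } else {
      state <- if (isTRUE(all.equal(Y[i, j], M[i, j - 1] + go))) "M" else "Y"
      j <- j - 1
    }
  }
  shorter <- min(n, m)
  span <- if (n <= m) ai_end - ai_start + 1 else bj_end - bj_start + 1
  list(identity = nmatch / shorter, coverage_of_shorter = span / shorter,
       score = max(M))
}

# Greedy clustering replayed with the brute-force aligner: same defined
# order (descending length, ties by id), first-fit against representatives.
oracle_greedy <- function(sequences, identity_threshold, min_coverage_shorter) {
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  reps <- character(0)
  assign <- setNames(character(length(ids)), ids)
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      pw <- bf_local_align(sequences[[id]], sequences[[r]])
      if (pw$identity >= identity_threshold &&
          pw$coverage_of_shorter >= min_coverage_shorter) {
        assign[id] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, id); assign[id] <- id }
  }
  assign
}

# partition of greedy_cluster output as member -> representative
cluster_assignment <- function(clusters) {
  out <- character(0)
  for (cl in clusters)
    out[cl$members] <- cl$representative_id
  out
}

# direct-formula modified z-score, scalar loop (independent of the
# package's vectorized implementation)
bf_modified_z <- function(x) {
  med <- median(x)
  mad0 <- median(abs(x - med))
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (mad0 > 0) out[i] <- 0.6745 * (x[i] - med) / mad0
    else {
      meanad <- mean(abs(x - med))
      out[i] <- if (meanad > 0) (x[i] - med) / (1.253314 * meanad) else 0
    }
  }
  out
}

# half-plane test for a triangle (independent geometric oracle)
bf_in_triangle <- function(px, py, v) {
  s <- function(p1, p2) (px - p2[1]) * (p1[2] - p2[2]) -
    (p1[1] - p2[1]) * (py - p2[2])
  d1 <- s(v[1, ], v[2, ]); d2 <- s(v[2, ], v[3, ]); d3 <- s(v[3, ], v[1, ])
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

random_dna <- function(n, gc = 0.5, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                 prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                          (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) gen() else magscope:::with_seed(seed, gen())
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
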