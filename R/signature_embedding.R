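#' Filter short contigs and cut the rest into fixed-size chunks
#'
#' Contigs shorter than `min_length` are dropped. Longer contigs are cut
#' left to right into `chunk_size` pieces for as long as the remaining
#' sequence is at least `chunk_size` long; the entire remainder is then
#' emitted as the final chunk. Chunking normalizes cluster size and
#' density in the embedding: without it a well-assembled genome would be
#' represented by only a handful of points. The literal rule can emit a
#' very short tail chunk (a 5,001 nt contig yields 5,000 + 1 nt);
#' `merge_tail = TRUE` folds tails shorter than `min_length` into the
#' previous chunk instead.
#'
#' @param contigs Named character vector of contig sequences.
#' @param min_length Minimum contig length retained (default 1,000 nt).
#' @param chunk_size Chunk size (default 5,000 nt).
#' @param merge_tail Fold sub-`min_length` tail chunks into the previous
#'   chunk (default `FALSE`: follow the literal rule).
#' @return data.frame `chunk_id`, `parent_contig`, `start`, `end`
#'   (0-based half-open on the parent), `length`, `sequence`.
#' @export
filter_and_chunk <- function(contigs, min_length = 1000, chunk_size = 5000,
                             merge_tail = FALSE) {
  if (!length(contigs))
    return(data.frame(chunk_id = character(0), parent_contig = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  lens <- nchar(contigs)
  contigs <- contigs[lens >= min_length]
  if (!length(contigs)) return(filter_and_chunk(character(0)))
  rows <- lapply(names(contigs), function(id) {
    L <- nchar(contigs[[id]])
    starts <- integer(0); pos <- 0L
    while (L - pos >= chunk_size) {
      starts <- c(starts, pos); pos <- pos + chunk_size
    }
    ends <- starts + chunk_size
    if (pos < L) { starts <- c(starts, pos); ends <- c(ends, L) }
    if (merge_tail && length(starts) > 1) {
      tail_len <- ends[length(ends)] - starts[length(starts)]
      if (tail_len < min_length) {
        starts <- starts[-length(starts)]
        ends <- ends[-(length(ends) - 1)]
      }
    }
    data.frame(chunk_id = sprintf("%s_c%03d", id, seq_along(starts)),
               parent_contig = id, start = starts, end = ends,
               length = ends - starts,
               sequence = substring(contigs[[id]], starts + 1, ends),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# canonical k-mer names for a given k: each k-mer pooled with its reverse
# complement under the lexicographically smaller key
canonical_kmer_map <- function(k) {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  setNames(canon, kmers)
}

#' Canonical k-mer relative frequencies of a sequence
#'
#' Sliding windows of length `k` are counted; windows containing non-ACGT
#' characters are skipped. With `canonical = TRUE`, each k-mer is pooled
#' with its reverse complement (strand-independent signature). Counts are
#' normalized to sum to one.
#'
#' @param sequence Character scalar.
#' @param k Word size (default 5).
#' @param canonical Pool reverse complements (default `TRUE`).
#' @return Named numeric vector of relative frequencies summing to 1.
#' @export
kmer_frequencies <- function(sequence, k = 5, canonical = TRUE) {
  if (nchar(sequence) < k) stopf("sequence shorter than k = %d", k)
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence),
                                              width = k, step = 1)
  if (canonical) {
    map <- canonical_kmer_map(k)
    cnt <- tapply(cnt, map[names(cnt)], sum)
    cnt <- cnt[sort(names(cnt))]
  }
  tot <- sum(cnt)
  if (tot == 0) stopf("no unambiguous k-mer windows in sequence")
  cnt / tot
}

# signature matrix for many chunks at once (vectorized count, shared
# canonical pooling); rows with zero unambiguous windows are an error
signature_counts <- function(sequences, k = 5, canonical = TRUE) {
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = k, step = 1)
  if (canonical) {
    map <- canonical_kmer_map(k)
    groups <- split(seq_len(ncol(cnt)), map[colnames(cnt)])
    pooled <- vapply(groups, function(j) rowSums(cnt[, j, drop = FALSE]),
                     numeric(nrow(cnt)))
    if (nrow(cnt) == 1) pooled <- matrix(pooled, nrow = 1,
                                         dimnames = list(NULL, names(groups)))
    cnt <- pooled[, sort(colnames(pooled)), drop = FALSE]
  }
  rownames(cnt) <- names(sequences)
  cnt
}

#' Centered log-ratio transform of a compositional vector
#'
#' Zeros are replaced by `pseudo_fraction` times the smallest nonzero
#' value (multiplicative replacement), the vector is renormalized, and
#' each component becomes `log(x) - mean(log(x))`. The output sums to
#' zero; proportional inputs map to identical outputs.
#'
#' @param freq_vector Non-negative numeric vector (need not sum to 1; it
#'   is closed internally).
#' @param pseudo_fraction Zero-replacement factor (default 0.65).
#' @return Numeric vector of the same length summing to 0.
#' @export
clr_transform <- function(freq_vector, pseudo_fraction = 0.65) {
  if (any(freq_vector < 0)) stopf("frequencies must be non-negative")
  if (all(freq_vector == 0)) stopf("all-zero composition")
  x <- freq_vector / sum(freq_vector)
  nz <- x[x > 0]
  x[x == 0] <- pseudo_fraction * min(nz)
  x <- x / sum(x)
  lx <- log(x)
  lx - mean(lx)
}

#' Build the CLR-transformed signature matrix for a set of chunks
#'
#' @param chunks data.frame from [filter_and_chunk()] (needs `chunk_id`
#'   and `sequence`), or a named character vector of sequences.
#' @param k Word size.
#' @param canonical Pool reverse complements.
#' @param pseudo_fraction Zero replacement factor for [clr_transform()].
#' @return Numeric matrix, one row per chunk, rows summing to 0.
#' @export
signature_matrix <- function(chunks, k = 5, canonical = TRUE,
                             pseudo_fraction = 0.65) {
  seqs <- if (is.data.frame(chunks))
    setNames(chunks$sequence, chunks$chunk_id) else chunks
  cnt <- signature_counts(seqs, k = k, canonical = canonical)
  t(apply(cnt, 1, clr_transform, pseudo_fraction = pseudo_fraction))
}

# Exact t-SNE (O(n^2)), sufficient and deterministic at desk scale.
# Standard formulation: per-point bandwidths tuned to the target
# perplexity by bisection, symmetrized affinities, early exaggeration,
# momentum + adaptive gains gradient descent.
tsne_exact <- function(X, perplexity = 30, max_iter = 1000, seed = 42,
                       eta = 200, exaggeration = 12) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (it in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) { Pi[] <- 1 / length(Pi); sumP <- 1 }
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else { betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    stop_exag <- min(250, max_iter %/% 4)
    Pe <- P * exaggeration
    for (iter in seq_len(max_iter)) {
      Pi <- if (iter <= stop_exag) Pe else P
      sumY2 <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY2, sumY2, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pi - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (iter < 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- mom * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Embed chunk signatures into two dimensions
#'
#' A variance-preserving linear pre-reduction (PCA, centered) to
#' `min(pca_dims, ncol)` dimensions followed by an exact t-distributed
#' stochastic neighbor embedding to 2D. Deterministic given `seed`.
#' Perplexity is lowered automatically to `floor((n - 1) / 3)` when the
#' input has too few rows.
#'
#' @param sig Signature matrix (rows = chunks), e.g. from
#'   [signature_matrix()].
#' @param pca_dims Dimensions retained by the linear pre-reduction.
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_iter Gradient-descent iterations (default 1,000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return data.frame `chunk_id`, `x`, `y`.
#' @export
embed_signatures <- function(sig, pca_dims = 50, perplexity = 30,
                             max_iter = 1000, seed = 42) {
  n <- nrow(sig)
  if (n < 4) stopf("too few points to embed (%d < 4)", n)
  maxp <- floor((n - 1) / 3)
  if (perplexity > maxp) perplexity <- max(1, maxp)
  d <- min(pca_dims, ncol(sig), n - 1)
  pc <- prcomp(sig, center = TRUE, scale. = FALSE, rank. = d)
  Y <- tsne_exact(pc$x, perplexity = perplexity, max_iter = max_iter,
                  seed = seed)
  data.frame(chunk_id = rownames(sig) %||% as.character(seq_len(n)),
             x = Y[, 1], y = Y[, 2], stringsAsFactors = FALSE)
}

#' Map fold-coverage to point opaqueness
#'
#' Alpha is the natural log of (1 + coverage) scaled by the maximum in
#' the set, clipped below at `alpha_min` so zero-coverage points remain
#' visible.
#'
#' @param fold_coverage Numeric vector of per-point fold-coverages (>= 0).
#' @param alpha_min Lower clip (default 0.05).
#' @return Numeric vector of alphas in `(0, 1]`.
#' @export
coverage_alpha <- function(fold_coverage, alpha_min = 0.05) {
  if (any(fold_coverage < 0)) stopf("coverage must be >= 0")
  mx <- max(fold_coverage)
  if (mx == 0) return(rep(alpha_min, length(fold_coverage)))
  a <- log1p(fold_coverage) / log1p(mx)
  pmin(1, pmax(alpha_min, a))
}

#' Build an annotated embedding points table
#'
#' Runs chunking, signatures, and the 2D embedding, then attaches labels,
#' beacon flags, and coverage-derived opaqueness. The returned table is
#' the substrate for polygon selection. Coordinates are unitless and only
#' valid against the embedding run that produced them; the run id is
#' recorded in the `embedding_run` attribute.
#'
#' @param contigs Named character vector of contig sequences.
#' @param min_length,chunk_size,merge_tail See [filter_and_chunk()].
#' @param k,pseudo_fraction See [signature_matrix()].
#' @param pca_dims,perplexity,max_iter,seed See [embed_signatures()].
#' @param coverage Optional named per-contig fold-coverage vector (used
#'   for point opaqueness).
#' @param labels Optional named per-contig label vector.
#' @param is_marker Optional character vector of beacon contig ids.
#' @return list with `points` (chunk_id, parent_contig, x, y, label,
#'   is_marker, alpha) and `chunk_map` (parent, start, end, chunk_id).
#' @export
embed_contigs <- function(contigs, min_length = 1000, chunk_size = 5000,
                          merge_tail = FALSE, k = 5, pseudo_fraction = 0.65,
                          pca_dims = 50, perplexity = 30, max_iter = 1000,
                          seed = 42, coverage = NULL, labels = NULL,
                          is_marker = NULL) {
  chunks <- filter_and_chunk(contigs, min_length = min_length,
                             chunk_size = chunk_size, merge_tail = merge_tail)
  if (!nrow(chunks)) stopf("no contigs pass the %d nt filter", min_length)
  sig <- signature_matrix(chunks, k = k, pseudo_fraction = pseudo_fraction)
  pts <- embed_signatures(sig, pca_dims = pca_dims, perplexity = perplexity,
                          max_iter = max_iter, seed = seed)
  pts$parent_contig <- chunks$parent_contig[match(pts$chunk_id, chunks$chunk_id)]
  pts$label <- if (!is.null(labels))
    unname(labels[pts$parent_contig]) else NA_character_
  pts$is_marker <- if (!is.null(is_marker))
    pts$parent_contig %in% is_marker else FALSE
  pts$alpha <- if (!is.null(coverage)) {
    cv <- coverage[pts$parent_contig]
    cv[is.na(cv)] <- 0
    coverage_alpha(unname(cv))
  } else 1
  pts <- pts[, c("chunk_id", "parent_contig", "x", "y", "label",
                 "is_marker", "alpha")]
  chunk_map <- chunks[, c("parent_contig", "start", "end", "chunk_id")]
  run_id <- sprintf("embed-k%d-s%d-n%d", k, seed, nrow(pts))
  attr(pts, "embedding_run") <- run_id
  list(points = pts, chunk_map = chunk_map, embedding_run = run_id)
}
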