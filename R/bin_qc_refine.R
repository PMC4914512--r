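#' Select embedding points inside a polygon
#'
#' Even-odd (ray casting) membership test; points exactly on a polygon
#' edge or vertex count as inside. Self-intersecting polygons are
#' rejected.
#'
#' @param points data.frame with `chunk_id`, `x`, `y` (an embedding
#'   points table).
#' @param polygon Two-column matrix of (x, y) vertices (>= 3), implicitly
#'   closed, or a path to a polygon JSON file.
#' @return Character vector of selected chunk ids.
#' @export
points_in_polygon <- function(points, polygon) {
  if (is.character(polygon) && length(polygon) == 1)
    polygon <- read_polygon(polygon)
  v <- as.matrix(polygon)
  if (nrow(v) < 3) stopf("polygon needs >= 3 vertices")
  if (polygon_self_intersects(v)) stopf("polygon is self-intersecting")
  inside <- vapply(seq_len(nrow(points)), function(i)
    point_in_polygon_one(points$x[i], points$y[i], v), NA)
  points$chunk_id[inside]
}

# even-odd rule with inclusive boundary
point_in_polygon_one <- function(px, py, v) {
  n <- nrow(v)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary check: point on segment (i, j)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    if (abs(cross) < 1e-12 &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12)
      return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  for (a in seq_len(n - 2)) {
    bs <- (a + 2):n
    bs <- bs[!(a == 1 & bs == n)]  # adjacent wrap-around pair
    for (b in bs)
      if (segments_cross(seg[a, ], seg[b, ])) return(TRUE)
  }
  FALSE
}

segments_cross <- function(s1, s2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  p1 <- s1[1:2]; p2 <- s1[3:4]; p3 <- s2[1:2]; p4 <- s2[3:4]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Promote selected chunks to whole contigs
#'
#' Under `"majority"`, a contig is included iff strictly more than half
#' of its chunks are selected (exact ties excluded); under `"any"`, a
#' single selected chunk suffices.
#'
#' @param selected Character vector of selected chunk ids.
#' @param chunk_map data.frame with `parent_contig` and `chunk_id`
#'   covering all selected chunks.
#' @param rule `"majority"` (default) or `"any"`.
#' @return Character vector of contig ids.
#' @export
chunks_to_contigs <- function(selected, chunk_map, rule = c("majority", "any")) {
  rule <- match.arg(rule)
  miss <- setdiff(selected, chunk_map$chunk_id)
  if (length(miss)) stopf("chunk map missing %d selected chunks", length(miss))
  tot <- table(chunk_map$parent_contig)
  sel <- table(chunk_map$parent_contig[chunk_map$chunk_id %in% selected])
  contigs <- names(sel)
  frac <- as.numeric(sel) / as.numeric(tot[contigs])
  if (rule == "majority") sort(contigs[frac > 0.5]) else sort(contigs)
}

#' Essential-gene completeness and contamination of a bin
#'
#' Counts, over the genes located on the bin's contigs, the distinct
#' single-copy families present at least once (completeness) and those
#' present in two or more copies (contamination).
#'
#' @param bin_contigs Character vector of contig ids in the bin.
#' @param marker_hits data.frame `gene_id`, `family_id`.
#' @param gene_to_contig Named character, gene id -> contig id.
#' @param n_families_total Size of the reference family set (default 107).
#' @return list `n_families_present`, `n_families_multicopy`,
#'   `n_families_total`, `copy_counts` (named integer per family).
#' @export
completeness_contamination <- function(bin_contigs, marker_hits,
                                       gene_to_contig,
                                       n_families_total = 107) {
  ctg <- gene_to_contig[marker_hits$gene_id]
  in_bin <- !is.na(ctg) & ctg %in% bin_contigs
  copies <- table(marker_hits$family_id[in_bin])
  res <- list(n_families_present = sum(copies >= 1),
              n_families_multicopy = sum(copies >= 2),
              n_families_total = n_families_total,
              copy_counts = setNames(as.integer(copies), names(copies)))
  stopifnot(res$n_families_multicopy <= res$n_families_present)
  res
}

#' Percent GC of each sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous bases are excluded from
#' the denominator. Sequences with no unambiguous bases yield `NA`.
#'
#' @param sequences Named character vector.
#' @return Named numeric vector of %GC values.
#' @export
gc_per_sequence <- function(sequences) {
  if (!length(sequences)) stopf("no sequences")
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(sequences))
  gc <- af[, "G"] + af[, "C"]
  acgt <- gc + af[, "A"] + af[, "T"]
  out <- ifelse(acgt > 0, 100 * gc / acgt, NA_real_)
  setNames(out, names(sequences))
}

#' Compare two %GC distributions
#'
#' Deterministic summaries (medians, IQRs) plus the first Wasserstein
#' (earth-mover) distance between the empirical distributions. A pure
#' location shift of `s` units yields distance `s`; a mixture of two
#' compositionally distinct genomes inflates the IQR relative to either
#' pure bin.
#'
#' @param values_a,values_b Numeric vectors (>= 5 values each).
#' @return list `median_a`, `median_b`, `iqr_a`, `iqr_b`, `emd`.
#' @export
gc_distribution_compare <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 5 || length(values_b) < 5)
    stopf("need >= 5 values per distribution")
  list(median_a = median(values_a), median_b = median(values_b),
       iqr_a = stats::IQR(values_a), iqr_b = stats::IQR(values_b),
       emd = wasserstein1(values_a, values_b))
}

# 1D Wasserstein-1 distance between empirical distributions: integral of
# |F_a - F_b| over the merged support
wasserstein1 <- function(a, b) {
  x <- sort(unique(c(a, b)))
  if (length(x) < 2) return(0)
  Fa <- stats::ecdf(a)(x); Fb <- stats::ecdf(b)(x)
  k <- length(x)
  sum(abs(Fa[-k] - Fb[-k]) * diff(x))
}

#' Modified Z-scores for robust outlier detection
#'
#' `M_i = 0.6745 * (x_i - median) / MAD` with
#' `MAD = median(|x_i - median|)`. When the MAD is zero the mean absolute
#' deviation takes over: `M_i = (x_i - median) / (1.253314 * MeanAD)`;
#' when both are zero all scores are 0.
#'
#' @param values Numeric vector (>= 3 values).
#' @return Numeric vector of scores.
#' @export
modified_zscore <- function(values) {
  if (length(values) < 3) stopf("need >= 3 values")
  med <- median(values)
  dev <- values - med
  mad0 <- median(abs(dev))
  if (mad0 > 0) return(0.6745 * dev / mad0)
  meanad <- mean(abs(dev))
  if (meanad > 0) return(dev / (1.253314 * meanad))
  rep(0, length(values))
}

#' Discard coverage-outlier contigs from a bin
#'
#' All contigs of a single population are expected to show similar
#' fold-coverage in a given sample; contigs whose absolute modified
#' Z-score exceeds `threshold` (strictly) on either tail are discarded.
#' A single pass is applied, matching the refine-then-reassemble
#' workflow; the filter is deliberately not iterated.
#'
#' @param bin_contigs Character vector of contig ids.
#' @param contig_coverage Named numeric per-contig mean fold-coverage;
#'   must cover every bin contig.
#' @param threshold Score threshold (default 3.5; strict inequality).
#' @return list `kept`, `discarded`, `scores` (named), and
#'   `coverage_range` (min/max coverage among kept contigs).
#' @export
coverage_outlier_filter <- function(bin_contigs, contig_coverage,
                                    threshold = 3.5) {
  miss <- bin_contigs[!(bin_contigs %in% names(contig_coverage))]
  if (length(miss))
    stopf("coverage missing for contigs: %s",
          paste(head(miss, 5), collapse = ", "))
  x <- contig_coverage[bin_contigs]
  sc <- setNames(modified_zscore(unname(x)), bin_contigs)
  out <- abs(sc) > threshold
  kept <- bin_contigs[!out]
  list(kept = kept, discarded = bin_contigs[out], scores = sc,
       coverage_range = if (length(kept)) range(x[kept]) else c(NA_real_, NA_real_))
}

#' Length-weighted mean fold-coverage per contig from depth windows
#'
#' Accepts per-window depth records (0-based half-open, the dialect of
#' common per-base depth tools collapsed to windows). Positions without
#' records count as depth 0 when the contig length is known.
#'
#' @param depth data.frame `contig`, `start`, `end`, `depth`.
#' @param contig_lengths Optional named integer vector; when supplied,
#'   every depth record must reference a known contig and uncovered
#'   positions dilute the mean.
#' @return Named numeric vector of per-contig mean fold-coverage.
#' @export
contig_mean_coverage <- function(depth, contig_lengths = NULL) {
  stopifnot(all(c("contig", "start", "end", "depth") %in% names(depth)))
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(depth$contig), names(contig_lengths))
    if (length(unknown))
      stopf("depth records reference unknown contigs: %s",
            paste(head(unknown, 5), collapse = ", "))
  }
  span <- depth$end - depth$start
  tot <- tapply(span * depth$depth, depth$contig, sum)
  len <- if (!is.null(contig_lengths)) {
    contig_lengths[names(tot)]
  } else tapply(span, depth$contig, sum)
  out <- as.numeric(tot) / as.numeric(len)
  setNames(out, names(tot))
}

#' Convex-hull polygon around a set of points, padded outward
#'
#' Test scaffolding standing in for interactive polygon drawing: the
#' convex hull of the given points, expanded away from the centroid by
#' `pad` times the hull's radial extent.
#'
#' @param points data.frame with `x`, `y` (subset the rows to the points
#'   the polygon should enclose).
#' @param pad Relative outward padding (default 0.05).
#' @return Two-column matrix of polygon vertices.
#' @export
hull_polygon <- function(points, pad = 0.05) {
  if (nrow(points) < 3) stopf("need >= 3 points for a hull polygon")
  xy <- cbind(points$x, points$y)
  h <- chull(xy)
  v <- xy[h, , drop = FALSE]
  ctr <- colMeans(v)
  sweep(sweep(v, 2, ctr) * (1 + pad), 2, ctr, `+`)
}
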