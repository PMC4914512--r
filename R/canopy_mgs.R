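#' Filter the gene catalog before co-abundance clustering
#'
#' Drops genes shorter than `min_length` nucleotides and genes whose
#' fold-coverage never reaches `min_cov` in any sample. A gene is kept if
#' its coverage is at least `min_cov` in at least `min_samples_at_cov`
#' samples.
#'
#' @param cov Coverage data.frame (`gene_id`, `length`, sample columns).
#' @param min_length Minimum gene length (default 100 nt).
#' @param min_cov Fold-coverage threshold (default 2.0).
#' @param min_samples_at_cov Samples that must reach `min_cov` (default 1).
#' @return The filtered coverage data.frame.
#' @export
filter_gene_catalog <- function(cov, min_length = 100, min_cov = 2,
                                min_samples_at_cov = 1) {
  if (!nrow(cov)) return(cov)
  m <- coverage_matrix(cov)
  keep_len <- if ("length" %in% names(cov)) cov$length >= min_length else TRUE
  keep_cov <- rowSums(m >= min_cov) >= min_samples_at_cov
  cov[keep_len & keep_cov, , drop = FALSE]
}

#' Pearson correlation distance between two coverage profiles
#'
#' `d = 1 - r`, in `[0, 2]`. Undefined (an error) for zero-variance
#' profiles; callers must pre-filter those.
#'
#' @param a,b Numeric vectors of equal length (>= 3 samples).
#' @return Distance in `[0, 2]`.
#' @export
pearson_distance <- function(a, b) {
  if (length(a) != length(b)) stopf("profiles differ in length")
  if (length(a) < 3) stopf("need >= 3 samples for a correlation distance")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("correlation undefined for zero-variance profile")
  1 - cor(a, b)
}

# distances from one center profile to every row of m (rows = genes);
# rows must have nonzero variance
profile_distances <- function(center, m) {
  drop(1 - cor(center, t(m)))
}

#' Canopy clustering of gene co-abundance profiles
#'
#' Genes are visited in a deterministic seeding order (descending total
#' coverage, ties broken by gene id). Each unassigned gene seeds a canopy
#' that gathers all still-unassigned genes within `max_canopy_dist`
#' (Pearson distance) of the origin profile; the center is recomputed as
#' the element-wise median of the members and the gather/recenter step is
#' repeated until the center moves less than `min_step_dist` or
#' `max_recenter` iterations. Close members (any gene within
#' `max_close_dist` of the final center) are recorded per canopy and may
#' overlap canopies. Seeding stops when the assigned fraction reaches
#' `stop_fraction`. Finally, canopies whose centers lie within
#' `max_merge_dist` are merged (single linkage over centers), members
#' unioned, and the center recomputed once.
#'
#' Members form a partition (each gene belongs to exactly one canopy's
#' members); only close-member sets may overlap.
#'
#' @param cov Coverage data.frame (`gene_id`, optional `length`, sample
#'   columns). Zero-variance profiles are excluded and reported via the
#'   `excluded` attribute.
#' @param max_canopy_dist Membership radius (default 0.1).
#' @param max_close_dist Close-member radius (default 0.4).
#' @param max_merge_dist Center merge radius (default 0.1).
#' @param min_step_dist Recenter convergence threshold (default 0.005).
#' @param stop_fraction Assigned fraction at which seeding stops
#'   (default 1).
#' @param max_recenter Safety bound on recenter iterations (default 10).
#' @param order `"coverage"` (deterministic, default) or `"random"`.
#' @param center `"median"` (default) or `"mean"`.
#' @param seed Used only when `order = "random"`.
#' @return List of canopies, each `list(canopy_id, center, members,
#'   close_members)`, with excluded zero-variance gene ids in
#'   `attr(, "excluded")`.
#' @export
canopy_cluster <- function(cov, max_canopy_dist = 0.1, max_close_dist = 0.4,
                           max_merge_dist = 0.1, min_step_dist = 0.005,
                           stop_fraction = 1, max_recenter = 10,
                           order = c("coverage", "random"),
                           center = c("median", "mean"), seed = NULL) {
  order <- match.arg(order); center_stat <- match.arg(center)
  if (!nrow(cov)) return(structure(list(), excluded = character(0)))
  m <- coverage_matrix(cov)
  v <- apply(m, 1, stats::sd)
  excluded <- rownames(m)[v == 0]
  m <- m[v > 0, , drop = FALSE]
  if (!nrow(m)) return(structure(list(), excluded = excluded))
  n <- nrow(m)
  ord <- if (order == "coverage") {
    tot <- rowSums(m)
    order(-tot, rownames(m))
  } else with_seed(seed %||% 0L, sample(n))
  cfun <- if (center_stat == "median")
    function(mm) apply(mm, 2, median) else function(mm) colMeans(mm)

  assigned <- logical(n)
  canopies <- list()
  for (i in ord) {
    if (mean(assigned) >= stop_fraction) break
    if (assigned[i]) next
    ctr <- m[i, ]
    members <- NULL
    for (it in seq_len(max_recenter)) {
      idx <- which(!assigned)
      d <- profile_distances(ctr, m[idx, , drop = FALSE])
      members <- idx[d <= max_canopy_dist]
      if (!length(members)) members <- i
      new_ctr <- cfun(m[members, , drop = FALSE])
      if (stats::sd(new_ctr) == 0) break
      moved <- 1 - cor(ctr, new_ctr)
      ctr <- new_ctr
      if (moved < min_step_dist) break
    }
    assigned[members] <- TRUE
    dall <- profile_distances(ctr, m)
    canopies[[length(canopies) + 1L]] <- list(
      canopy_id = sprintf("CAN%04d", length(canopies) + 1L),
      center = ctr, members = rownames(m)[members],
      close_members = rownames(m)[dall <= max_close_dist])
  }

  # single-linkage merge of canopies with nearby centers
  k <- length(canopies)
  if (k > 1) {
    centers <- do.call(rbind, lapply(canopies, `[[`, "center"))
    cd <- 1 - cor(t(centers))
    comp <- seq_len(k)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (cd[a, b] <= max_merge_dist) {
        ca <- comp[a]; cb <- comp[b]
        if (ca != cb) comp[comp == cb] <- ca
      }
    }
    merged <- lapply(unique(comp), function(g) {
      parts <- canopies[comp == g]
      members <- unique(unlist(lapply(parts, `[[`, "members")))
      ctr <- cfun(m[members, , drop = FALSE])
      dall <- profile_distances(ctr, m)
      list(center = ctr, members = members,
           close_members = rownames(m)[dall <= max_close_dist])
    })
    canopies <- lapply(seq_along(merged), function(j)
      c(list(canopy_id = sprintf("CAN%04d", j)), merged[[j]]))
  }
  structure(canopies, excluded = excluded)
}

#' Call metagenomic species (MGS) from canopies
#'
#' A canopy whose member count is at least `min_genes` (default 700,
#' the conventional MGS threshold; scale down for desk-size data) is
#' promoted to an MGS.
#'
#' @param canopies Output of [canopy_cluster()].
#' @param min_genes Inclusive member-count threshold (default 700).
#' @return List of MGS, each `list(mgs_id, members, source_canopies)`.
#' @export
call_mgs <- function(canopies, min_genes = 700) {
  keep <- Filter(function(cp) length(cp$members) >= min_genes, canopies)
  lapply(seq_along(keep), function(i)
    list(mgs_id = sprintf("MGS%05d", i), members = keep[[i]]$members,
         source_canopies = keep[[i]]$canopy_id))
}

#' Flag contigs encoding at least one MGS gene
#'
#' @param mgs A single MGS from [call_mgs()].
#' @param gene_to_contig Named character, gene id -> contig id.
#' @return list with `contigs` (flagged contig ids) and `unplaced`
#'   (MGS genes missing from the map; reported, not fatal).
#' @export
mgs_to_contig_labels <- function(mgs, gene_to_contig) {
  hit <- gene_to_contig[mgs$members]
  unplaced <- mgs$members[is.na(hit)]
  list(contigs = sort(unique(unname(hit[!is.na(hit)]))), unplaced = unplaced)
}

#' Choose the sample with the highest mean MGS coverage
#'
#' @param mgs A single MGS from [call_mgs()].
#' @param cov Coverage data.frame covering the MGS genes.
#' @return The sample id (ties broken by column order).
#' @export
best_sample_for_mgs <- function(mgs, cov) {
  m <- coverage_matrix(cov)
  miss <- setdiff(mgs$members, rownames(m))
  if (length(miss)) stopf("coverage missing for %d MGS genes", length(miss))
  means <- colMeans(m[mgs$members, , drop = FALSE])
  colnames(m)[which.max(means)]
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, ~0 means chance-level agreement. Used to
#' score recovered clusterings against planted ground truth.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}
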