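#' Identity and coverage of the best local alignment of two sequences
#'
#' Computes the best local alignment under the fixed scoring scheme
#' (match +2, mismatch -3, gap open -5, gap extend -2) and reports
#' identity (matching identical positions divided by the length of the
#' shorter sequence) and coverage of the shorter sequence (aligned span
#' on the shorter sequence divided by its length). This mirrors the
#' `-c` / `-aS` semantics of greedy incremental clustering tools.
#'
#' @param a,b Non-empty sequences over the ACGTN alphabet.
#' @return list `identity`, `coverage_of_shorter`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stopf("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
  shorter <- min(nchar(a), nchar(b))
  nmatch <- Biostrings::nmatch(aln)
  span <- if (nchar(a) <= nchar(b))
    Biostrings::width(Biostrings::pattern(aln))
  else
    Biostrings::width(Biostrings::subject(aln))
  list(identity = nmatch / shorter, coverage_of_shorter = span / shorter)
}

#' Greedy incremental identity-based sequence clustering
#'
#' Sequences are sorted by descending length (ties by id) and processed
#' in order. Each sequence is compared against the representatives of
#' existing clusters in creation order and joins the first cluster whose
#' representative it matches at identity >= `identity_threshold` and
#' coverage of the shorter sequence >= `min_coverage_shorter`; otherwise
#' it founds a new cluster with itself as representative. Representatives
#' are therefore always the longest member of their cluster, and the
#' procedure is deterministic.
#'
#' @param sequences Named character vector (>= 1 sequence).
#' @param identity_threshold Fraction in (0, 1].
#' @param min_coverage_shorter Fraction in (0, 1].
#' @param assign `"first"` (default, greedy convention) or `"best"`
#'   (highest-identity qualifying representative).
#' @return List of clusters: `list(representative_id, members, identity,
#'   coverage)` where `identity` / `coverage` are per-member values
#'   against the representative (1 for the representative itself).
#' @export
greedy_cluster <- function(sequences, identity_threshold = 0.95,
                           min_coverage_shorter = 0.9,
                           assign = c("first", "best")) {
  assign <- match.arg(assign)
  if (!length(sequences)) stopf("at least one sequence required")
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      min_coverage_shorter <= 0 || min_coverage_shorter > 1)
    stopf("thresholds must be in (0, 1]")
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  clusters <- list()
  for (id in ids) {
    placed <- FALSE
    best <- NULL
    for (ci in seq_along(clusters)) {
      rep_id <- clusters[[ci]]$representative_id
      pw <- pairwise_identity(sequences[[id]], sequences[[rep_id]])
      if (pw$identity >= identity_threshold &&
          pw$coverage_of_shorter >= min_coverage_shorter) {
        if (assign == "first") {
          clusters[[ci]]$members <- c(clusters[[ci]]$members, id)
          clusters[[ci]]$identity <- c(clusters[[ci]]$identity, pw$identity)
          clusters[[ci]]$coverage <- c(clusters[[ci]]$coverage,
                                       pw$coverage_of_shorter)
          placed <- TRUE
          break
        } else if (is.null(best) || pw$identity > best$identity) {
          best <- list(ci = ci, identity = pw$identity,
                       coverage = pw$coverage_of_shorter)
        }
      }
    }
    if (!placed && !is.null(best)) {
      ci <- best$ci
      clusters[[ci]]$members <- c(clusters[[ci]]$members, id)
      clusters[[ci]]$identity <- c(clusters[[ci]]$identity, best$identity)
      clusters[[ci]]$coverage <- c(clusters[[ci]]$coverage, best$coverage)
      placed <- TRUE
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- list(
        representative_id = id, members = id, identity = 1, coverage = 1)
  }
  clusters
}

#' Dereplicate a gene catalog at 95% identity over 90% of the shorter
#' sequence
#'
#' Convenience wrapper around [greedy_cluster()] with the catalog
#' dereplication thresholds; cluster representatives form the
#' non-redundant catalog.
#'
#' @param genes Named character vector of gene sequences.
#' @return List of clusters (see [greedy_cluster()]).
#' @export
dereplicate_catalog <- function(genes) {
  greedy_cluster(genes, identity_threshold = 0.95, min_coverage_shorter = 0.9)
}

#' Tabulate clusters as a long data.frame
#'
#' @param clusters Output of [greedy_cluster()].
#' @return data.frame `member_id`, `cluster_id`, `representative_id`,
#'   `identity`, `coverage`.
#' @export
clusters_to_table <- function(clusters) {
  do.call(rbind, c(lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(member_id = cl$members,
               cluster_id = sprintf("CL%04d", i),
               representative_id = cl$representative_id,
               identity = cl$identity, coverage = cl$coverage,
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}
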