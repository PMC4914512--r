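#' Select marker-gene candidates for a target taxon
#'
#' Keeps genes whose taxon path contains `target_taxon` with annotation
#' confidence at or above `min_confidence` (boundary inclusive).
#' Confidence values are accepted on either the 0-1 or the 0-100 scale;
#' values above 1 anywhere in the table trigger percent interpretation.
#'
#' @param annotations data.frame `gene_id`, `taxon_path`, `confidence`.
#' @param target_taxon Taxon label to match (substring of the path).
#' @param min_confidence Inclusive threshold on the 0-1 scale
#'   (default 0.75).
#' @return Character vector of gene ids.
#' @export
select_marker_candidates <- function(annotations, target_taxon,
                                     min_confidence = 0.75) {
  stopifnot(all(c("gene_id", "taxon_path", "confidence") %in% names(annotations)))
  conf <- annotations$confidence
  if (any(conf > 1, na.rm = TRUE)) conf <- conf / 100
  keep <- grepl(target_taxon, annotations$taxon_path, fixed = TRUE) &
    conf >= min_confidence
  unique(annotations$gene_id[keep])
}

#' Drop gene predictions lacking a start or a stop codon
#'
#' @param gene_ids Character vector of candidate gene ids.
#' @param meta data.frame with `gene_id`, `has_start`, `has_stop`
#'   covering all candidates.
#' @return Character vector of complete genes.
#' @export
drop_partial_genes <- function(gene_ids, meta) {
  idx <- match(gene_ids, meta$gene_id)
  if (anyNA(idx))
    stopf("gene meta missing: %s",
          paste(head(gene_ids[is.na(idx)], 5), collapse = ", "))
  gene_ids[meta$has_start[idx] & meta$has_stop[idx]]
}

#' Parse "partial=XY" gene-predictor FASTA headers into completeness flags
#'
#' The common convention encodes edge truncation as two digits: "00" is a
#' complete gene, a leading "1" means the 5' edge (start codon) is
#' missing, a trailing "1" means the 3' edge (stop codon) is missing.
#'
#' @param headers Character vector of FASTA header lines (with or without
#'   the leading `>`).
#' @return data.frame `gene_id`, `has_start`, `has_stop`.
#' @export
parse_partial_headers <- function(headers) {
  h <- sub("^>", "", headers)
  id <- sub("\\s.*$", "", h)
  part <- sub(".*partial=([01]{2}).*", "\\1", h)
  part[!grepl("partial=[01]{2}", h)] <- "00"
  data.frame(gene_id = id,
             has_start = substr(part, 1, 1) == "0",
             has_stop = substr(part, 2, 2) == "0",
             stringsAsFactors = FALSE)
}

#' Build marker sequence groups from candidate marker genes
#'
#' Candidate genes are clustered by [greedy_cluster()] at 95% identity
#' over 50% of the shorter sequence; each cluster becomes one marker
#' sequence group, numbered by descending maximum per-sample coverage of
#' its representative gene (`MSG01` has the highest fold-coverage in any
#' sample).
#'
#' @param gene_seqs Named character vector of candidate marker gene
#'   sequences.
#' @param cov Coverage data.frame covering the representatives.
#' @param identity_threshold,min_coverage_shorter Clustering thresholds
#'   (defaults 0.95 / 0.5).
#' @param prefix Group id prefix (default `"MSG"`).
#' @return List of groups: `list(group_id, representative_id, members,
#'   coverage)` with `coverage` the representative's per-sample vector,
#'   ordered by descending max coverage.
#' @export
build_marker_groups <- function(gene_seqs, cov, identity_threshold = 0.95,
                                min_coverage_shorter = 0.5, prefix = "MSG") {
  if (!length(gene_seqs)) stopf("at least one marker gene required")
  clusters <- greedy_cluster(gene_seqs, identity_threshold,
                             min_coverage_shorter)
  m <- coverage_matrix(cov)
  groups <- lapply(clusters, function(cl) {
    rep_id <- cl$representative_id
    if (!rep_id %in% rownames(m))
      stopf("coverage missing for representative %s", rep_id)
    list(representative_id = rep_id, members = cl$members,
         coverage = m[rep_id, ])
  })
  maxcov <- vapply(groups, function(g) max(g$coverage), 0)
  ord <- order(-maxcov, vapply(groups, `[[`, "", "representative_id"))
  groups <- groups[ord]
  lapply(seq_along(groups), function(i)
    c(list(group_id = sprintf("%s%02d", prefix, i)), groups[[i]]))
}

#' Rank samples by the marker group's representative coverage
#'
#' The representative gene's per-sample fold-coverage serves as a proxy
#' for the population's abundance; the first-ranked sample is the one to
#' assemble and embed.
#'
#' @param group A marker group from [build_marker_groups()].
#' @return data.frame `sample`, `coverage`, sorted by descending
#'   coverage (ties by sample id). Empty, with a warning, when all
#'   coverages are zero.
#' @export
rank_samples_by_marker <- function(group) {
  cv <- group$coverage
  if (all(cv == 0)) {
    warning("all-zero marker coverage; no sample ranking possible")
    return(data.frame(sample = character(0), coverage = numeric(0)))
  }
  ord <- order(-cv, names(cv))
  data.frame(sample = names(cv)[ord], coverage = unname(cv[ord]),
             stringsAsFactors = FALSE)
}

#' Locate the beacon contigs of a marker group
#'
#' Contigs carrying any member gene of the group are flagged; these feed
#' the `is_marker` annotation of the embedding so the surrounding
#' cluster can be selected.
#'
#' @param group A marker group from [build_marker_groups()].
#' @param gene_to_contig Named character, gene id -> contig id.
#' @return list `contigs` (flagged ids) and `unmapped` (member genes
#'   without a contig; reported, not fatal).
#' @export
locate_beacon_contigs <- function(group, gene_to_contig) {
  hit <- gene_to_contig[group$members]
  list(contigs = sort(unique(unname(hit[!is.na(hit)]))),
       unmapped = group$members[is.na(hit)])
}
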