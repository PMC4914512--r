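# Shared refinement tail of both approaches: polygon -> contigs ->
# coverage-outlier filter -> QC summary.
refine_selection <- function(points, chunk_map, polygon, contigs,
                             contig_coverage, marker_hits, gene_to_contig,
                             bin_id, provenance, n_families_total = 107,
                             outlier_threshold = 3.5, rule = "majority") {
  sel_chunks <- points_in_polygon(points, polygon)
  sel_contigs <- chunks_to_contigs(sel_chunks, chunk_map, rule = rule)
  if (!length(sel_contigs))
    return(list(bin_id = bin_id, provenance = provenance,
                contigs = character(0), discarded = character(0),
                qc = NULL))
  filt <- coverage_outlier_filter(sel_contigs, contig_coverage,
                                  threshold = outlier_threshold)
  kept <- filt$kept
  qc <- NULL
  if (length(kept)) {
    cc <- completeness_contamination(kept, marker_hits, gene_to_contig,
                                     n_families_total = n_families_total)
    gc <- gc_per_sequence(contigs[kept])
    qc <- list(n_contigs = length(kept),
               total_bp = sum(nchar(contigs[kept])),
               gc_median = median(gc, na.rm = TRUE),
               gc_iqr = stats::IQR(gc, na.rm = TRUE),
               completeness = cc$n_families_present,
               contamination = cc$n_families_multicopy,
               n_families_total = cc$n_families_total,
               n_discarded_outliers = length(filt$discarded))
  }
  list(bin_id = bin_id, provenance = provenance, contigs = kept,
       discarded = filt$discarded, outlier_scores = filt$scores, qc = qc)
}

# per-contig mean coverage in one sample, aggregated from gene coverages
contig_coverage_from_genes <- function(cov, gene_to_contig, sample) {
  m <- coverage_matrix(cov)
  ctg <- gene_to_contig[rownames(m)]
  ok <- !is.na(ctg)
  out <- tapply(m[ok, sample], ctg[ok], mean)
  setNames(as.numeric(out), names(out))
}

#' Run Approach 1: canopy clustering with embedding-based refinement
#'
#' Filters the gene catalog, clusters coverage profiles into canopies,
#' calls MGS, picks the sample with the highest mean MGS coverage, embeds
#' that sample's contigs with MGS contigs highlighted, applies a polygon
#' per MGS (supplied, or derived as the padded convex hull of the
#' highlighted points — automation standing in for interactive
#' selection), promotes chunks to contigs by majority, refines by
#' coverage outliers, and reports essential-gene QC per bin.
#'
#' @param contigs Named character vector of contig sequences.
#' @param cov Gene coverage data.frame (`gene_id`, `length`, samples).
#' @param gene_to_contig Named character, gene id -> contig id.
#' @param marker_hits data.frame `gene_id`, `family_id`.
#' @param min_gene_length,min_cov Catalog filters (defaults 100 nt / 2x).
#' @param min_genes MGS threshold (default 700; scale down for small
#'   simulations).
#' @param n_families_total Essential-family set size (default 107).
#' @param polygons Optional named list (by MGS id) of polygon vertex
#'   matrices; hull-derived when `NULL`.
#' @param outlier_threshold Modified Z-score cutoff (default 3.5).
#' @param canopy_args,embed_args Lists of overrides passed to
#'   [canopy_cluster()] / [embed_contigs()].
#' @param seed Integer seed for the embedding.
#' @param out_dir Optional directory; when given, points, bins, and the
#'   run manifest are written there.
#' @return list with `bins`, `mgs`, `points`, `chunk_map`, `best_sample`,
#'   and `report` (stage record counts and parameters).
#' @export
run_approach1 <- function(contigs, cov, gene_to_contig, marker_hits,
                          min_gene_length = 100, min_cov = 2,
                          min_genes = 700, n_families_total = 107,
                          polygons = NULL, outlier_threshold = 3.5,
                          canopy_args = list(), embed_args = list(),
                          seed = 42, out_dir = NULL) {
  stages <- list()
  note <- function(stage, n_in, n_out)
    stages[[length(stages) + 1L]] <<- data.frame(stage = stage,
                                                 n_in = n_in, n_out = n_out)
  filt <- filter_gene_catalog(cov, min_length = min_gene_length,
                              min_cov = min_cov)
  note("filter_gene_catalog", nrow(cov), nrow(filt))
  canopies <- do.call(canopy_cluster, c(list(filt), canopy_args))
  note("canopy_cluster", nrow(filt), length(canopies))
  mgs <- call_mgs(canopies, min_genes = min_genes)
  note("call_mgs", length(canopies), length(mgs))
  report <- list(stages = do.call(rbind, stages),
                 params = list(min_gene_length = min_gene_length,
                               min_cov = min_cov, min_genes = min_genes,
                               outlier_threshold = outlier_threshold,
                               seed = seed))
  if (!length(mgs))
    return(list(bins = list(), mgs = mgs, points = NULL, chunk_map = NULL,
                best_sample = NULL, report = report))

  # one embedding of the best sample of the first MGS serves all MGS
  # (the synthetic world has a single pooled assembly); each MGS gets its
  # own highlighted contig set and polygon
  best <- best_sample_for_mgs(mgs[[1]], filt)
  ctg_cov <- contig_coverage_from_genes(cov, gene_to_contig, best)
  emb <- do.call(embed_contigs,
                 c(list(contigs, seed = seed, coverage = ctg_cov), embed_args))
  pts <- emb$points
  bins <- list()
  for (mg in mgs) {
    flagged <- mgs_to_contig_labels(mg, gene_to_contig)$contigs
    poly <- if (!is.null(polygons)) polygons[[mg$mgs_id]] else {
      hp <- pts[pts$parent_contig %in% flagged, , drop = FALSE]
      if (nrow(hp) < 3) next
      hull_polygon(hp)
    }
    if (is.null(poly)) next
    bins[[mg$mgs_id]] <- refine_selection(
      pts, emb$chunk_map, poly, contigs, ctg_cov, marker_hits,
      gene_to_contig, bin_id = mg$mgs_id, provenance = "mgs-refined",
      n_families_total = n_families_total,
      outlier_threshold = outlier_threshold)
  }
  res <- list(bins = bins, mgs = mgs, points = pts,
              chunk_map = emb$chunk_map, best_sample = best,
              report = report)
  if (!is.null(out_dir)) write_run_outputs(res, contigs, out_dir,
                                           approach = "canopy_refine")
  res
}

#' Run Approach 2: targeted, beacon-guided recovery
#'
#' Selects target-taxon marker candidates by annotation confidence, drops
#' incomplete gene predictions, groups markers by greedy identity
#' clustering, ranks samples by the top group's representative coverage,
#' embeds the contigs with beacon flags and coverage opaqueness, applies
#' a polygon per group (supplied, or — as test scaffolding — the padded
#' hull of the truth-labeled points around the beacon), and refines by
#' coverage outliers.
#'
#' @param contigs Named character vector of contig sequences.
#' @param gene_seqs Named character vector of gene sequences (at least
#'   the marker candidates).
#' @param annotations Taxon annotation data.frame.
#' @param gene_meta data.frame with `gene_id`, `has_start`, `has_stop`.
#' @param cov Gene coverage data.frame.
#' @param gene_to_contig Named character, gene id -> contig id.
#' @param marker_hits Essential-gene hit table for QC.
#' @param target_taxon Taxon label to recover.
#' @param min_confidence Annotation confidence cutoff (default 0.75).
#' @param n_families_total Essential-family set size (default 107).
#' @param polygons Optional named list (by group id) of polygon vertex
#'   matrices.
#' @param truth_contig_to_genome Optional named character map used only
#'   to derive automatic polygons when `polygons` is `NULL` (test
#'   scaffolding, not part of the scientific method).
#' @param outlier_threshold Modified Z-score cutoff (default 3.5).
#' @param embed_args List of overrides for [embed_contigs()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return list with `bins`, `groups`, `rankings`, `points`,
#'   `chunk_map`, and `report`. When no qualifying marker genes exist the
#'   bin set is empty and the report notes "no target population
#'   detected".
#' @export
run_approach2 <- function(contigs, gene_seqs, annotations, gene_meta, cov,
                          gene_to_contig, marker_hits,
                          target_taxon = "Cyanobacteria",
                          min_confidence = 0.75, n_families_total = 107,
                          polygons = NULL, truth_contig_to_genome = NULL,
                          outlier_threshold = 3.5, embed_args = list(),
                          seed = 42, out_dir = NULL) {
  stages <- list()
  note <- function(stage, n_in, n_out)
    stages[[length(stages) + 1L]] <<- data.frame(stage = stage,
                                                 n_in = n_in, n_out = n_out)
  cand <- select_marker_candidates(annotations, target_taxon, min_confidence)
  note("select_marker_candidates", nrow(annotations), length(cand))
  complete <- if (length(cand)) drop_partial_genes(cand, gene_meta) else cand
  note("drop_partial_genes", length(cand), length(complete))
  report <- list(stages = NULL,
                 params = list(target_taxon = target_taxon,
                               min_confidence = min_confidence,
                               outlier_threshold = outlier_threshold,
                               seed = seed))
  if (!length(complete)) {
    report$stages <- do.call(rbind, stages)
    report$message <- "no target population detected"
    return(list(bins = list(), groups = list(), rankings = list(),
                points = NULL, chunk_map = NULL, report = report))
  }
  groups <- build_marker_groups(gene_seqs[complete], cov, prefix = "MSG")
  note("build_marker_groups", length(complete), length(groups))
  report$stages <- do.call(rbind, stages)

  rankings <- setNames(lapply(groups, rank_samples_by_marker),
                       vapply(groups, `[[`, "", "group_id"))
  top <- groups[[1]]
  best <- rankings[[top$group_id]]$sample[1]
  ctg_cov <- contig_coverage_from_genes(cov, gene_to_contig, best)
  beacons <- unique(unlist(lapply(groups, function(g)
    locate_beacon_contigs(g, gene_to_contig)$contigs)))
  emb <- do.call(embed_contigs,
                 c(list(contigs, seed = seed, coverage = ctg_cov,
                        is_marker = beacons), embed_args))
  pts <- emb$points
  bins <- list()
  for (g in groups) {
    bcn <- locate_beacon_contigs(g, gene_to_contig)$contigs
    poly <- if (!is.null(polygons)) polygons[[g$group_id]] else {
      if (is.null(truth_contig_to_genome)) NULL else {
        # scaffolding: hull of the points of the beacon's genome
        genome <- unique(truth_contig_to_genome[bcn])
        genome <- genome[!is.na(genome)]
        if (!length(genome)) NULL else {
          hp <- pts[truth_contig_to_genome[pts$parent_contig] %in% genome, ,
                    drop = FALSE]
          if (nrow(hp) < 3) NULL else hull_polygon(hp)
        }
      }
    }
    if (is.null(poly)) next
    bins[[g$group_id]] <- refine_selection(
      pts, emb$chunk_map, poly, contigs, ctg_cov, marker_hits,
      gene_to_contig, bin_id = g$group_id, provenance = "beacon",
      n_families_total = n_families_total,
      outlier_threshold = outlier_threshold)
  }
  res <- list(bins = bins, groups = groups, rankings = rankings,
              points = pts, chunk_map = emb$chunk_map, best_sample = best,
              report = report)
  if (!is.null(out_dir)) write_run_outputs(res, contigs, out_dir,
                                           approach = "targeted")
  res
}

# persist points, bins, QC table, and the run manifest
write_run_outputs <- function(res, contigs, out_dir, approach) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$points))
    write_tsv(res$points, file.path(out_dir, "points.tsv"))
  if (!is.null(res$chunk_map))
    write_tsv(res$chunk_map, file.path(out_dir, "chunk_map.tsv"))
  qc_rows <- list()
  for (b in res$bins) {
    if (length(b$contigs))
      write_fasta(contigs[b$contigs],
                  file.path(out_dir, paste0(b$bin_id, ".fasta")))
    if (!is.null(b$qc))
      qc_rows[[length(qc_rows) + 1L]] <-
        data.frame(bin_id = b$bin_id, provenance = b$provenance,
                   as.data.frame(b$qc[c("n_contigs", "total_bp",
                                        "gc_median", "gc_iqr",
                                        "completeness", "contamination",
                                        "n_discarded_outliers")]))
  }
  if (length(qc_rows))
    write_tsv(do.call(rbind, qc_rows), file.path(out_dir, "qc_report.tsv"))
  manifest <- list(approach = approach, params = res$report$params,
                   stages = if (!is.null(res$report$stages))
                     res$report$stages else NULL,
                   n_bins = length(res$bins))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
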