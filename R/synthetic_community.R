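#' Specify a synthetic genome for community simulation
#'
#' A genome model is the unit of ground truth in the synthetic community:
#' a base composition target, a length, a gene count, and a flag marking
#' the planted target-taxon analog (the population a targeted-recovery run
#' is supposed to find).
#'
#' @param genome_id Character id, unique within a community.
#' @param gc_target Target GC fraction, in `[0.2, 0.8]`.
#' @param length Genome length in nucleotides, at least 10,000.
#' @param n_genes Number of genes tiled end-to-end along the genome.
#' @param is_target_taxon Logical; marks the planted target-taxon genome.
#' @return A `genome_model` list.
#' @export
genome_model <- function(genome_id, gc_target, length, n_genes,
                         is_target_taxon = FALSE) {
  if (gc_target < 0.2 || gc_target > 0.8)
    stopf("gc_target must be in [0.2, 0.8], got %g", gc_target)
  if (length < 10000) stopf("genome length must be >= 10,000 nt")
  if (n_genes < 1) stopf("n_genes must be >= 1")
  structure(list(genome_id = as.character(genome_id),
                 gc_target = gc_target, length = as.integer(length),
                 n_genes = as.integer(n_genes),
                 is_target_taxon = isTRUE(is_target_taxon)),
            class = "genome_model")
}

#' Specify a synthetic community
#'
#' Bundles the genome models with the cross-sample abundance model: each
#' genome's abundance in each sample is drawn independently from a
#' lognormal, and every gene of a genome inherits that abundance times a
#' multiplicative noise term (truncated at zero). This reproduces the
#' within-genome co-abundance structure that canopy clustering exploits.
#'
#' @param genomes List of [genome_model()] objects.
#' @param n_samples Number of samples (>= 2).
#' @param abundance_log_mean,abundance_log_sd Lognormal meanlog / sdlog of
#'   per-genome, per-sample abundance (fold-coverage scale).
#' @param gene_noise_cv Coefficient of variation of the per-gene
#'   multiplicative noise (>= 0).
#' @param seed Integer seed; all simulation randomness derives from it.
#' @return A `community_spec` list.
#' @export
community_spec <- function(genomes, n_samples = 20,
                           abundance_log_mean = 3, abundance_log_sd = 1,
                           gene_noise_cv = 0.05, seed = 1) {
  if (n_samples < 2) stopf("n_samples must be >= 2")
  if (gene_noise_cv < 0) stopf("gene_noise_cv must be >= 0")
  if (!length(genomes)) stopf("at least one genome required")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) stopf("genome ids must be unique")
  structure(list(genomes = genomes, n_samples = as.integer(n_samples),
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 gene_noise_cv = gene_noise_cv, seed = as.integer(seed)),
            class = "community_spec")
}

#' Generate an i.i.d. random genome sequence with a target GC content
#'
#' Bases are drawn independently with P(G) = P(C) = gc_target / 2 and
#' P(A) = P(T) = (1 - gc_target) / 2. An order-0 model is sufficient to
#' give genomes distinct, separable k-mer signatures; higher-order models
#' are a possible extension, not needed here.
#'
#' @param gc_target GC fraction in (0, 1).
#' @param length Sequence length (>= 1).
#' @param seed Integer seed; deterministic given the seed.
#' @return A single character string over ACGT.
#' @export
generate_genome_sequence <- function(gc_target, length, seed = 1) {
  if (gc_target <= 0 || gc_target >= 1)
    stopf("gc_target must be in (0, 1), got %g", gc_target)
  if (length < 1) stopf("length must be >= 1")
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  with_seed(seed, paste(sample(names(p), length, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Fragment a genome into assembly-like contigs
#'
#' Contigs tile the genome left to right without gaps or overlaps; lengths
#' are lognormal, truncated below at `min_len`, and the final remainder is
#' appended to the last contig so that concatenating the contigs in source
#' order reproduces the genome exactly.
#'
#' @param sequence Genome sequence (character scalar).
#' @param mean_len Target mean contig length (>= `min_len`).
#' @param min_len Minimum contig length (>= 500).
#' @param seed Integer seed.
#' @param prefix Contig id prefix.
#' @return A data.frame with `contig_id`, `start`, `end` (0-based
#'   half-open source coordinates), `length`, and `sequence`.
#' @export
fragment_into_contigs <- function(sequence, mean_len = 5000, min_len = 1000,
                                  seed = 1, prefix = "contig") {
  if (min_len < 500) stopf("min_len must be >= 500")
  if (mean_len < min_len) stopf("mean_len must be >= min_len")
  L <- nchar(sequence)
  if (L < min_len) {
    return(data.frame(contig_id = paste0(prefix, "_1"), start = 0L,
                      end = L, length = L, sequence = sequence,
                      stringsAsFactors = FALSE))
  }
  lens <- with_seed(seed, {
    # lognormal with the requested mean; sdlog 0.5 gives realistic spread
    sdlog <- 0.5
    meanlog <- log(mean_len) - sdlog^2 / 2
    out <- integer(0); tot <- 0L
    while (tot < L) {
      l <- max(min_len, round(rlnorm(1, meanlog, sdlog)))
      out <- c(out, as.integer(l)); tot <- tot + as.integer(l)
    }
    out
  })
  starts <- cumsum(c(0L, lens))[seq_along(lens)]
  keep <- starts < L
  lens <- lens[keep]; starts <- starts[keep]
  ends <- pmin(starts + lens, L)
  # fold any trailing remainder shorter than min_len into the last contig
  ends[length(ends)] <- L
  if (length(ends) > 1 && (ends[length(ends)] - starts[length(starts)]) < min_len) {
    starts <- starts[-length(starts)]
    ends <- ends[-(length(ends) - 1)]
  }
  data.frame(contig_id = paste0(prefix, "_", seq_along(starts)),
             start = starts, end = ends, length = ends - starts,
             sequence = substring(sequence, starts + 1, ends),
             stringsAsFactors = FALSE)
}

#' Simulate per-gene fold-coverage profiles across samples
#'
#' Genome abundance `a(g, s)` is lognormal i.i.d. per genome and sample;
#' gene coverage is `a(genome(i), s) * max(0, 1 + eps)` with
#' `eps ~ N(0, gene_noise_cv)`. Genes of one genome therefore share a
#' coverage profile up to multiplicative noise — the co-abundance signal.
#'
#' @param spec A [community_spec()].
#' @param gene_ids Optional list (per genome) of gene id vectors; derived
#'   from genome ids when `NULL`.
#' @return A list with `coverage` (data.frame: gene_id, length, one column
#'   per sample), `abundance` (genome x sample matrix), and
#'   `gene_to_genome` (named character).
#' @export
simulate_gene_coverages <- function(spec, gene_ids = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  G <- length(spec$genomes); S <- spec$n_samples
  gids <- vapply(spec$genomes, `[[`, "", "genome_id")
  ngenes <- vapply(spec$genomes, `[[`, 0L, "n_genes")
  if (is.null(gene_ids))
    gene_ids <- lapply(seq_len(G), function(i)
      sprintf("%s_g%04d", gids[i], seq_len(ngenes[i])))
  samples <- sprintf("S%02d", seq_len(S))
  with_seed(spec$seed, {
    ab <- matrix(rlnorm(G * S, spec$abundance_log_mean, spec$abundance_log_sd),
                 nrow = G, dimnames = list(gids, samples))
    rows <- lapply(seq_len(G), function(i) {
      n <- length(gene_ids[[i]])
      eps <- matrix(rnorm(n * S, 0, spec$gene_noise_cv), nrow = n)
      sweep(pmax(1 + eps, 0), 2, ab[i, ], `*`)
    })
    cov <- do.call(rbind, rows)
    all_ids <- unlist(gene_ids)
    rownames(cov) <- all_ids
    colnames(cov) <- samples
    g2g <- setNames(rep(gids, vapply(gene_ids, length, 0L)), all_ids)
    glen <- unlist(lapply(seq_len(G), function(i) {
      gm <- spec$genomes[[i]]
      rep(gm$length %/% gm$n_genes, ngenes[i])
    }))
    list(coverage = data.frame(gene_id = all_ids, length = glen,
                               cov, stringsAsFactors = FALSE,
                               row.names = NULL, check.names = FALSE),
         abundance = ab, gene_to_genome = g2g)
  })
}

#' Plant single-copy marker families into a simulated community
#'
#' Labels `n_families` distinct genes per genome with distinct essential
#' single-copy family ids (the 107-family convention by default). When
#' `contamination_copies > 0`, that many additional genes of the same
#' genome receive an already-used family id, so the genome's own bin scores
#' exactly that contamination count downstream.
#'
#' @param gene_to_genome Named character, gene id -> genome id.
#' @param n_families Families per genome (default 107).
#' @param contamination_copies Extra duplicate-family copies per genome.
#' @param seed Integer seed.
#' @return data.frame `gene_id`, `family_id`.
#' @export
plant_marker_families <- function(gene_to_genome, n_families = 107,
                                  contamination_copies = 0, seed = 1) {
  fams <- sprintf("ESS%03d", seq_len(n_families))
  by_g <- split(names(gene_to_genome), gene_to_genome)
  with_seed(seed, {
    out <- lapply(by_g, function(genes) {
      if (length(genes) < n_families + contamination_copies)
        stopf("genome has %d genes; need >= %d for marker planting",
              length(genes), n_families + contamination_copies)
      picks <- sample(genes, n_families + contamination_copies)
      data.frame(gene_id = picks,
                 family_id = c(fams, fams[seq_len(contamination_copies)]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Plant near-duplicate gene copies at a target identity
#'
#' Each duplicate differs from its source by point substitutions at rate
#' `1 - identity_target`, at positions chosen uniformly without
#' replacement. Substrate for testing identity-threshold dereplication.
#'
#' @param genes Named character vector of gene sequences.
#' @param identity_target Fraction in `[0.5, 1]`.
#' @param n_pairs Number of (source, duplicate) pairs to plant.
#' @param seed Integer seed.
#' @return list with `sequences` (originals plus `<id>_dup` copies) and
#'   `duplicate_pairs` (data.frame source, duplicate, identity).
#' @export
plant_near_duplicates <- function(genes, identity_target, n_pairs, seed = 1) {
  if (identity_target <= 0 || identity_target > 1)
    stopf("identity_target must be in (0, 1]")
  if (identity_target < 0.5)
    stopf("identity_target < 0.5 is outside this tool's use range")
  if (n_pairs > length(genes)) stopf("n_pairs exceeds number of genes")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    src <- sample(names(genes), n_pairs)
    dups <- vapply(src, function(id) {
      s <- strsplit(genes[[id]], "")[[1]]
      n_sub <- round((1 - identity_target) * length(s))
      if (n_sub > 0) {
        pos <- sample(length(s), n_sub)
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(bases, b), 1), "")
      }
      paste(s, collapse = "")
    }, "")
    names(dups) <- paste0(src, "_dup")
    list(sequences = c(genes, dups),
         duplicate_pairs = data.frame(source = src,
                                      duplicate = names(dups),
                                      identity = identity_target,
                                      stringsAsFactors = FALSE))
  })
}

#' Simulate a complete ground-truthed synthetic community
#'
#' Builds genomes, assembly-like contigs, end-to-end tiled genes with
#' sequences, a gene x sample fold-coverage table, planted single-copy
#' marker families, and taxon annotations (target-taxon genomes receive
#' high-confidence marker annotations on a subset of genes; a few decoy
#' annotations fall below typical confidence cutoffs). Everything is
#' deterministic given `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @param n_marker_families Essential families planted per genome.
#' @param contamination_copies Extra duplicate-family copies per genome.
#' @param target_taxon Taxon label used for planted target-genome markers.
#' @param n_target_markers Marker-gene annotations per target genome.
#' @return A `synthetic_community` list: `contigs` (named character),
#'   `genes` (named character), `gene_meta` (gene_id, contig_id, start,
#'   end, strand, has_start, has_stop), `coverage`, `abundance`,
#'   `marker_hits`, `annotations`, and `truth` (contig_to_genome,
#'   gene_to_genome, genome models, spec).
#' @export
simulate_community <- function(spec, n_marker_families = 107,
                               contamination_copies = 0,
                               target_taxon = "Cyanobacteria",
                               n_target_markers = 8) {
  stopifnot(inherits(spec, "community_spec"))
  G <- length(spec$genomes)
  seqs <- contig_tabs <- vector("list", G)
  for (i in seq_len(G)) {
    gm <- spec$genomes[[i]]
    seqs[[i]] <- generate_genome_sequence(gm$gc_target, gm$length,
                                          seed = spec$seed + 1000L + i)
    # mean contig length ~4 kb emulates typical metagenomic assembly
    # fragmentation (bins in practice hold tens to hundreds of contigs)
    contig_tabs[[i]] <- fragment_into_contigs(
      seqs[[i]], mean_len = 4000, min_len = 1000,
      seed = spec$seed + 2000L + i, prefix = gm$genome_id)
  }
  gids <- vapply(spec$genomes, `[[`, "", "genome_id")

  cov <- simulate_gene_coverages(spec)
  gene_to_genome <- cov$gene_to_genome

  # genes tile each genome end-to-end (0-based half-open); a gene maps to
  # the contig containing its midpoint
  gene_meta <- do.call(rbind, lapply(seq_len(G), function(i) {
    gm <- spec$genomes[[i]]
    glen <- gm$length %/% gm$n_genes
    ids <- names(gene_to_genome)[gene_to_genome == gm$genome_id]
    start <- (seq_along(ids) - 1L) * glen
    end <- start + glen
    mid <- (start + end) %/% 2L
    ct <- contig_tabs[[i]]
    idx <- findInterval(mid, ct$start)
    data.frame(gene_id = ids, genome_id = gm$genome_id,
               contig_id = ct$contig_id[idx],
               start = start, end = end, strand = "+",
               stringsAsFactors = FALSE)
  }))
  genes <- setNames(substring(
    unlist(seqs)[match(gene_meta$genome_id, gids)],
    gene_meta$start + 1, gene_meta$end), gene_meta$gene_id)

  marker_hits <- plant_marker_families(gene_to_genome,
                                       n_families = n_marker_families,
                                       contamination_copies = contamination_copies,
                                       seed = spec$seed + 31L)

  # completeness flags: most genes complete; a fixed fraction partial
  gene_meta <- with_seed(spec$seed + 41L, {
    n <- nrow(gene_meta)
    gene_meta$has_start <- runif(n) > 0.05
    gene_meta$has_stop <- runif(n) > 0.05
    gene_meta
  })

  annotations <- with_seed(spec$seed + 51L, {
    rows <- list()
    for (i in seq_len(G)) {
      gm <- spec$genomes[[i]]
      ids <- gene_meta$gene_id[gene_meta$genome_id == gm$genome_id]
      if (gm$is_target_taxon) {
        # marker copies recovered from different samples are near-identical
        # observations of the same gene; emulated below by overwriting the
        # non-anchor copies with ~98%-identity mutants of the anchor
        pick <- sample(ids, min(n_target_markers, length(ids)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = pick, taxon_path = paste0("Bacteria;", target_taxon),
          confidence = runif(length(pick), 0.78, 0.99),
          stringsAsFactors = FALSE)
      } else {
        # background annotations plus low-confidence decoys of the target
        pick <- sample(ids, min(5, length(ids)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = pick, taxon_path = "Bacteria;Firmicutes",
          confidence = runif(length(pick), 0.6, 0.99),
          stringsAsFactors = FALSE)
        decoy <- sample(setdiff(ids, pick), min(2, length(ids) - length(pick)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = decoy, taxon_path = paste0("Bacteria;", target_taxon),
          confidence = runif(length(decoy), 0.2, 0.6),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  # annotated target markers must be complete genes so that the
  # completeness filter does not silently empty the candidate set
  tgt <- annotations$gene_id[annotations$confidence >= 0.75 &
                               grepl(target_taxon, annotations$taxon_path)]
  gene_meta$has_start[gene_meta$gene_id %in% tgt] <- TRUE
  gene_meta$has_stop[gene_meta$gene_id %in% tgt] <- TRUE

  # per target genome, rewrite the non-anchor marker copies as ~98%
  # identity mutants of the anchor copy (cross-sample assembly variants
  # of one marker gene; they must co-cluster at the 95% threshold)
  for (i in seq_len(G)) {
    gm <- spec$genomes[[i]]
    if (!gm$is_target_taxon) next
    ids <- intersect(tgt, names(gene_to_genome)[gene_to_genome == gm$genome_id])
    if (length(ids) < 2) next
    anchor <- genes[[ids[1]]]
    dup <- plant_near_duplicates(
      setNames(rep(anchor, length(ids) - 1), ids[-1]),
      identity_target = 0.98, n_pairs = length(ids) - 1,
      seed = spec$seed + 61L + i)
    genes[ids[-1]] <- unname(dup$sequences[paste0(ids[-1], "_dup")])
  }

  contigs <- unlist(lapply(contig_tabs, function(ct)
    setNames(ct$sequence, ct$contig_id)))
  contig_to_genome <- unlist(lapply(seq_len(G), function(i)
    setNames(rep(gids[i], nrow(contig_tabs[[i]])),
             contig_tabs[[i]]$contig_id)))

  structure(list(
    contigs = contigs, genes = genes, gene_meta = gene_meta,
    coverage = cov$coverage, abundance = cov$abundance,
    marker_hits = marker_hits, annotations = annotations,
    truth = list(contig_to_genome = contig_to_genome,
                 gene_to_genome = gene_to_genome,
                 genomes = spec$genomes, spec = spec)),
    class = "synthetic_community")
}

#' Write a synthetic community to plain-text files
#'
#' Emits contigs FASTA, genes FASTA, gene coverage TSV, marker-hit TSV,
#' taxon-annotation TSV, gene-meta TSV, truth TSV, and a JSON sidecar
#' echoing the simulation parameters.
#'
#' @param comm A `synthetic_community` from [simulate_community()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(comm, dir) {
  stopifnot(inherits(comm, "synthetic_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(comm$contigs, file.path(dir, "contigs.fasta"))
  write_fasta(comm$genes, file.path(dir, "genes.fasta"))
  write_tsv(comm$coverage, file.path(dir, "gene_coverage.tsv"))
  write_tsv(comm$marker_hits, file.path(dir, "marker_hits.tsv"))
  write_tsv(comm$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(comm$gene_meta, file.path(dir, "gene_meta.tsv"))
  truth <- data.frame(id = c(names(comm$truth$contig_to_genome),
                             names(comm$truth$gene_to_genome)),
                      kind = rep(c("contig", "gene"),
                                 c(length(comm$truth$contig_to_genome),
                                   length(comm$truth$gene_to_genome))),
                      genome_id = c(unname(comm$truth$contig_to_genome),
                                    unname(comm$truth$gene_to_genome)),
                      stringsAsFactors = FALSE)
  write_tsv(truth, file.path(dir, "truth.tsv"))
  sp <- comm$truth$spec
  jsonlite::write_json(list(
    seed = sp$seed, n_samples = sp$n_samples,
    abundance_log_mean = sp$abundance_log_mean,
    abundance_log_sd = sp$abundance_log_sd,
    gene_noise_cv = sp$gene_noise_cv,
    genomes = lapply(sp$genomes, unclass)),
    file.path(dir, "simulation.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
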