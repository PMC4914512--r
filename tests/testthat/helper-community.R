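# Shared synthetic-community fixtures, built in code at test time.

three_genome_spec <- function(seed = 7, n_samples = 20, gene_noise_cv = 0.05,
                              n_genes = 300, length = 150000) {
  community_spec(list(
    genome_model("gA", 0.30, length, n_genes),
    genome_model("gB", 0.50, length, n_genes),
    genome_model("gC", 0.65, length, n_genes, is_target_taxon = TRUE)),
    n_samples = n_samples, gene_noise_cv = gene_noise_cv, seed = seed)
}

targeted_spec <- function(seed = 7) {
  community_spec(list(
    genome_model("bg1", 0.45, 120000, 240),
    genome_model("bg2", 0.55, 120000, 240),
    genome_model("bg3", 0.65, 120000, 240),
    genome_model("bg4", 0.75, 120000, 240),
    genome_model("tgt", 0.28, 120000, 240, is_target_taxon = TRUE)),
    n_samples = 20, gene_noise_cv = 0.05, seed = seed)
}

gene_contig_map <- function(comm) {
  setNames(comm$gene_meta$contig_id, comm$gene_meta$gene_id)
}

# coverage-profile-only spec (no sequences needed): g genomes x n genes
profile_spec <- function(n_genomes = 3, n_genes = 100, n_samples = 20,
                         gene_noise_cv = 0.05, seed = 1) {
  community_spec(lapply(seq_len(n_genomes), function(i)
    genome_model(sprintf("G%02d", i), 0.5, 50000, n_genes)),
    n_samples = n_samples, gene_noise_cv = gene_noise_cv, seed = seed)
}

canopy_ari_vs_truth <- function(canopies, gene_to_genome) {
  lab <- rep(NA_character_, length(gene_to_genome))
  names(lab) <- names(gene_to_genome)
  for (cp in canopies) lab[cp$members] <- cp$canopy_id
  ok <- !is.na(lab)
  adjusted_rand_index(lab[ok], gene_to_genome[names(lab)[ok]])
}
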