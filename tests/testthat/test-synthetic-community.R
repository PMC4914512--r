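test_that("generated genome sequences hit the GC target and are deterministic", {
  s <- generate_genome_sequence(0.5, 100000, seed = 1)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.5), 0.01)

  s4 <- generate_genome_sequence(0.5, 4, seed = 3)
  expect_match(s4, "^[ACGT]{4}$")

  expect_identical(generate_genome_sequence(0.35, 2000, seed = 9),
                   generate_genome_sequence(0.35, 2000, seed = 9))
  expect_false(identical(generate_genome_sequence(0.35, 2000, seed = 9),
                         generate_genome_sequence(0.35, 2000, seed = 10)))
  expect_error(generate_genome_sequence(1.2, 1000), "gc_target")
})

test_that("fragmentation conserves the genome and never overlaps", {
  s <- generate_genome_sequence(0.5, 100000, seed = 2)
  ct <- fragment_into_contigs(s, mean_len = 5000, min_len = 1000, seed = 4)
  expect_equal(sum(ct$length), 100000)
  expect_identical(paste(ct$sequence, collapse = ""), s)
  expect_true(all(ct$start[-1] == ct$end[-nrow(ct)]))  # contiguous tiling
  expect_true(all(ct$length >= 1000))

  short <- fragment_into_contigs(strrep("A", 600), mean_len = 5000,
                                 min_len = 500, seed = 1)
  expect_equal(nrow(short), 1)
  expect_equal(short$length, 600)

  for (sd in 1:5) {
    ct <- fragment_into_contigs(s, mean_len = 3000, min_len = 1000,
                                seed = sd)
    expect_identical(paste(ct$sequence, collapse = ""), s)
  }
})

test_that("gene coverages carry the planted co-abundance structure", {
  sp <- profile_spec(n_genomes = 3, n_genes = 50, n_samples = 10,
                     gene_noise_cv = 0, seed = 5)
  sim <- simulate_gene_coverages(sp)
  expect_equal(nrow(sim$coverage), 150)
  expect_equal(ncol(sim$coverage), 12)  # gene_id + length + 10 samples
  m <- magscope:::coverage_matrix(sim$coverage)
  # zero noise: genes of one genome share the profile exactly
  g1 <- m[sim$gene_to_genome == "G01", ]
  expect_true(all(apply(g1, 2, function(col) diff(range(col)) == 0)))
  expect_equal(pearson_distance(g1[1, ], g1[2, ] * 2), 0)

  # independence across genomes: |r| < 0.5 in >= 95% of replicate seeds
  n_rep <- 1000
  small <- function(sd) {
    sp <- community_spec(list(genome_model("a", 0.5, 10000, 1),
                              genome_model("b", 0.5, 10000, 1)),
                         n_samples = 20, gene_noise_cv = 0, seed = sd)
    m <- magscope:::coverage_matrix(simulate_gene_coverages(sp)$coverage)
    abs(cor(m[1, ], m[2, ]))
  }
  rs <- vapply(seq_len(n_rep), small, 0)
  expect_gte(mean(rs < 0.5), 0.95)
})

test_that("within-genome profiles are tight and between-genome far apart", {
  fails <- 0L
  for (sd in 1:20) {
    sp <- profile_spec(n_genomes = 3, n_genes = 10, n_samples = 20,
                       gene_noise_cv = 0.05, seed = sd)
    sim <- simulate_gene_coverages(sp)
    m <- magscope:::coverage_matrix(sim$coverage)
    d <- 1 - cor(t(m))
    same <- outer(sim$gene_to_genome, sim$gene_to_genome, `==`)
    ut <- upper.tri(d)
    w <- d[ut & same]
    b <- d[ut & !same]
    if (!(mean(w) < 0.1 && mean(b) > 0.5)) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("marker families are planted in single copy plus requested contamination", {
  g2g <- setNames(rep(c("gA", "gB"), each = 120),
                  sprintf("g%03d", 1:240))
  hits <- plant_marker_families(g2g, n_families = 107, seed = 1)
  byg <- split(hits$family_id, g2g[hits$gene_id])
  expect_equal(lengths(byg), c(gA = 107L, gB = 107L))
  expect_true(all(vapply(byg, function(f) !anyDuplicated(f), NA)))

  hits5 <- plant_marker_families(g2g, n_families = 100,
                                 contamination_copies = 5, seed = 2)
  binA <- completeness_contamination(
    "cA", hits5, setNames(ifelse(g2g == "gA", "cA", "cB"), names(g2g)),
    n_families_total = 100)
  expect_equal(binA$n_families_present, 100)
  expect_equal(binA$n_families_multicopy, 5)

  expect_error(plant_marker_families(g2g, n_families = 500), "genes")
})

test_that("near-duplicates carry the exact planted substitution load", {
  genes <- setNames(vapply(1:3, function(i) random_dna(1000, seed = i), ""),
                    c("x", "y", "z"))
  ex <- plant_near_duplicates(genes, identity_target = 1, n_pairs = 2,
                              seed = 3)
  for (i in seq_len(nrow(ex$duplicate_pairs)))
    expect_identical(ex$sequences[[ex$duplicate_pairs$duplicate[i]]],
                     ex$sequences[[ex$duplicate_pairs$source[i]]])

  mut <- plant_near_duplicates(genes, identity_target = 0.96, n_pairs = 3,
                               seed = 4)
  for (i in 1:3) {
    a <- strsplit(mut$sequences[[mut$duplicate_pairs$source[i]]], "")[[1]]
    b <- strsplit(mut$sequences[[mut$duplicate_pairs$duplicate[i]]], "")[[1]]
    expect_equal(sum(a != b), 40)
  }
  expect_error(plant_near_duplicates(genes, 0.4, 1), "use range")
})

test_that("simulate_community is deterministic and writes a readable bundle", {
  sp <- three_genome_spec(seed = 3, n_genes = 120, length = 60000)
  c1 <- simulate_community(sp, n_marker_families = 20)
  c2 <- simulate_community(sp, n_marker_families = 20)
  expect_identical(c1, c2)
  expect_true(all(nchar(c1$contigs) >= 1000))
  # every contig and gene maps to exactly one genome
  expect_equal(sort(unique(c1$truth$contig_to_genome)), c("gA", "gB", "gC"))
  expect_false(anyNA(c1$truth$gene_to_genome[names(c1$genes)]))

  dir <- withr::local_tempdir()
  write_community(c1, dir)
  expect_setequal(list.files(dir),
                  c("contigs.fasta", "genes.fasta", "gene_coverage.tsv",
                    "marker_hits.tsv", "annotations.tsv", "gene_meta.tsv",
                    "truth.tsv", "simulation.json"))
  back <- read_fasta(file.path(dir, "contigs.fasta"))
  expect_identical(back, c1$contigs)
  cov <- read_coverage_table(file.path(dir, "gene_coverage.tsv"))
  expect_equal(cov$gene_id, c1$coverage$gene_id)
})
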