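make_cov <- function(m, lengths = NULL) {
  data.frame(gene_id = rownames(m),
             length = lengths %||% rep(500L, nrow(m)),
             m, stringsAsFactors = FALSE, check.names = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("catalog filters drop short and never-covered genes", {
  m <- rbind(short = c(5, 5, 5), low = c(1.9, 1.9, 1.9),
             edge = c(1.0, 2.0, 0.0), ok = c(10, 0, 0))
  colnames(m) <- c("s1", "s2", "s3")
  cov <- make_cov(m, lengths = c(99L, 500L, 500L, 500L))
  out <- filter_gene_catalog(cov)
  expect_setequal(out$gene_id, c("edge", "ok"))
  expect_equal(nrow(filter_gene_catalog(cov[0, ])), 0)
})

test_that("pearson distance matches hand computations", {
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pearson_distance(c(1, 2, 3), c(5, 4, 3)), 2)
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 2, 4)),
               1 - 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(round(pearson_distance(c(1, 2, 3), c(1, 2, 4)), 3), 0.018)
  expect_error(pearson_distance(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_distance(c(1, 2), c(1, 2)), "3 samples")
})

test_that("one shared profile collapses to a single canopy", {
  base <- c(10, 2, 8, 1, 6, 3, 9, 2, 4, 7)
  m <- t(vapply(1:30, function(i)
    base * (1 + magscope:::with_seed(i, rnorm(10, 0, 0.001))), numeric(10)))
  rownames(m) <- sprintf("g%02d", 1:30)
  colnames(m) <- sprintf("s%02d", 1:10)
  can <- canopy_cluster(make_cov(m))
  expect_length(can, 1)
  expect_setequal(can[[1]]$members, rownames(m))
})

test_that("canopy clustering recovers planted genomes and is deterministic", {
  sp <- profile_spec(n_genomes = 3, n_genes = 100, n_samples = 20,
                     gene_noise_cv = 0.05, seed = 3)
  sim <- simulate_gene_coverages(sp)
  can <- canopy_cluster(sim$coverage)
  expect_gte(canopy_ari_vs_truth(can, sim$gene_to_genome), 0.95)
  expect_identical(can, canopy_cluster(sim$coverage))

  # partition property: each gene in exactly one canopy's members
  members <- unlist(lapply(can, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  expect_setequal(members, sim$coverage$gene_id)

  # oracle: every member lies within max_close_dist of its final center
  m <- magscope:::coverage_matrix(sim$coverage)
  for (cp in can) {
    d <- vapply(cp$members, function(g) 1 - cor(cp$center, m[g, ]), 0)
    expect_true(all(d <= 0.4))
    expect_true(all(cp$members %in% cp$close_members))
  }
})

test_that("distant profile groups never share close members", {
  up <- seq(1, 10); down <- seq(10, 1)
  m <- rbind(t(vapply(1:5, function(i) up + i * 0.01, numeric(10))),
             t(vapply(1:5, function(i) down + i * 0.01, numeric(10))))
  rownames(m) <- sprintf("g%02d", 1:10)
  colnames(m) <- sprintf("s%02d", 1:10)
  can <- canopy_cluster(make_cov(m))
  expect_length(can, 2)
  cm <- lapply(can, `[[`, "close_members")
  expect_length(intersect(cm[[1]], cm[[2]]), 0)
  # brute force: between-group distances all exceed max_close_dist
  expect_true(all(1 - cor(t(m))[1:5, 6:10] > 0.4))
})

test_that("zero-variance profiles are excluded and reported", {
  m <- rbind(flat = c(2, 2, 2, 2), var1 = c(1, 5, 2, 8), var2 = c(1, 5, 2, 9))
  colnames(m) <- paste0("s", 1:4)
  can <- canopy_cluster(make_cov(m))
  expect_equal(attr(can, "excluded"), "flat")
  expect_setequal(unlist(lapply(can, `[[`, "members")), c("var1", "var2"))
})

test_that("MGS calling respects the inclusive member threshold", {
  mk <- function(n) list(canopy_id = "c", center = 1:5,
                         members = paste0("g", seq_len(n)),
                         close_members = paste0("g", seq_len(n)))
  expect_length(call_mgs(list(mk(700))), 1)
  expect_length(call_mgs(list(mk(699))), 0)
  expect_length(call_mgs(list(mk(50)), min_genes = 50), 1)
})

test_that("MGS contigs are flagged by the at-least-one-gene rule", {
  mgs <- list(mgs_id = "MGS00001", members = c("g1", "g2", "g3"))
  map <- c(g1 = "cA", g2 = "cA", g3 = "cB", g4 = "cC")
  lab <- mgs_to_contig_labels(mgs, map)
  expect_setequal(lab$contigs, c("cA", "cB"))
  lab2 <- mgs_to_contig_labels(list(mgs_id = "m", members = c("g1", "gX")), map)
  expect_equal(lab2$unplaced, "gX")
  expect_equal(lab2$contigs, "cA")
})

test_that("best sample maximizes mean MGS coverage with stable ties", {
  m <- rbind(g1 = c(A = 5, B = 10, C = 1), g2 = c(A = 5, B = 10, C = 1))
  cov <- make_cov(m)
  mgs <- list(mgs_id = "m", members = c("g1", "g2"))
  expect_equal(best_sample_for_mgs(mgs, cov), "B")
  single <- make_cov(matrix(c(3, 3), 2, 1, dimnames = list(c("g1", "g2"), "A")))
  expect_equal(best_sample_for_mgs(mgs, single), "A")
  # planted community: best sample equals the abundance argmax
  sp <- profile_spec(n_genomes = 2, n_genes = 20, n_samples = 8, seed = 6)
  sim <- simulate_gene_coverages(sp)
  mgs1 <- list(mgs_id = "m",
               members = names(sim$gene_to_genome)[sim$gene_to_genome == "G01"])
  expect_equal(best_sample_for_mgs(mgs1, sim$coverage),
               colnames(sim$abundance)[which.max(sim$abundance["G01", ])])
})

test_that("adjusted Rand index matches its definition on a known case", {
  # identical partitions -> 1; independent-ish labels -> near 0
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- rep(1:3, 10)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.2)
})
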