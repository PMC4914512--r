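test_that("point-in-polygon follows the even-odd rule with inclusive boundary", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  pts <- data.frame(chunk_id = c("in", "out", "edge", "vertex"),
                    x = c(0.5, 2, 0.5, 1), y = c(0.5, 2, 0, 1))
  sel <- points_in_polygon(pts, square)
  expect_setequal(sel, c("in", "edge", "vertex"))

  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(points_in_polygon(pts, bowtie), "self-intersecting")
})

test_that("ray casting matches the half-plane oracle on a triangle", {
  tri <- rbind(c(0, 0), c(4, 1), c(1, 3))
  pts <- magscope:::with_seed(13, data.frame(
    chunk_id = sprintf("p%04d", 1:1000),
    x = runif(1000, -1, 5), y = runif(1000, -1, 4)))
  got <- pts$chunk_id %in% points_in_polygon(pts, tri)
  want <- vapply(seq_len(1000), function(i)
    bf_in_triangle(pts$x[i], pts$y[i], tri), NA)
  expect_identical(got, want)
})

test_that("chunk selections promote to contigs by majority with tie exclusion", {
  cm <- data.frame(parent_contig = rep(c("A", "B", "C"), each = 4),
                   chunk_id = sprintf("k%02d", 1:12))
  sel_a <- cm$chunk_id[1:3]            # A: 3/4
  sel_b <- cm$chunk_id[5]              # B: 1/4
  sel_c <- cm$chunk_id[9:10]           # C: 2/4 tie
  expect_equal(chunks_to_contigs(c(sel_a, sel_b, sel_c), cm), "A")
  expect_setequal(chunks_to_contigs(c(sel_a, sel_b, sel_c), cm, rule = "any"),
                  c("A", "B", "C"))
  expect_error(chunks_to_contigs("missing", cm), "missing")
  expect_error(chunks_to_contigs(sel_a, cm, rule = "most"), "'arg'")
})

test_that("essential-gene counting matches planted truth including merged bins", {
  g2g <- setNames(rep(c("gA", "gB"), each = 150), sprintf("g%03d", 1:300))
  g2c <- setNames(ifelse(g2g == "gA", "cA", "cB"), names(g2g))
  hits <- plant_marker_families(g2g, n_families = 107, seed = 4)
  one <- completeness_contamination("cA", hits, g2c)
  expect_equal(one$n_families_present, 107)
  expect_equal(one$n_families_multicopy, 0)
  both <- completeness_contamination(c("cA", "cB"), hits, g2c)
  expect_equal(both$n_families_present, 107)
  expect_equal(both$n_families_multicopy, 107)
  none <- completeness_contamination("cZ", hits, g2c)
  expect_equal(none$n_families_present, 0)
})

test_that("percent GC follows the stated ambiguity rule", {
  gc <- gc_per_sequence(c(a = "ATGC", b = "GGCC", c = "ANT", d = "NNN"))
  expect_equal(unname(gc), c(50, 100, 0, NA))
})

test_that("GC distribution comparison detects shifts and mixtures", {
  x <- magscope:::with_seed(5, rnorm(200, 45, 3))
  same <- gc_distribution_compare(x, x)
  expect_equal(same$emd, 0)
  shift <- gc_distribution_compare(x, x + 10)
  expect_equal(shift$emd, 10, tolerance = 1e-9)
  # mixed two-genome bin spreads wider than either pure bin
  a <- magscope:::with_seed(6, rnorm(200, 30, 2))
  b <- magscope:::with_seed(7, rnorm(200, 65, 2))
  mix <- gc_distribution_compare(a, c(a, b))
  expect_gt(mix$iqr_b, mix$iqr_a)
  expect_error(gc_distribution_compare(1:3, 1:10), ">= 5")
})

test_that("modified z-scores match hand computations and the fallback", {
  z <- modified_zscore(1:9)
  expect_equal(z[9], 0.6745 * 4 / 2)
  zf <- modified_zscore(c(10, 10, 10, 10, 100))
  expect_equal(zf[5], 90 / (1.253314 * 18), tolerance = 1e-12)
  expect_gt(abs(zf[5]), 3.5)
  expect_equal(modified_zscore(rep(7, 5)), rep(0, 5))
  expect_error(modified_zscore(c(1, 2)), ">= 3")
})

test_that("modified z-scores equal the brute-force oracle on random vectors", {
  for (sd in 1:1000) {
    x <- magscope:::with_seed(sd, rnorm(sample(3:40, 1)))
    expect_equal(modified_zscore(x), bf_modified_z(x), tolerance = 1e-12)
  }
})

test_that("coverage outliers are excluded on both tails with strict boundary", {
  ids <- sprintf("c%03d", 1:103)
  cov <- setNames(c(magscope:::with_seed(8, rnorm(100, 20, 1)),
                    rep(200, 3)), ids)
  out <- coverage_outlier_filter(ids, cov)
  expect_true(all(ids[101:103] %in% out$discarded))
  expect_lte(length(out$discarded) - 3, 2)
  expect_setequal(c(out$kept, out$discarded), ids)
  expect_length(intersect(out$kept, out$discarded), 0)
  expect_true(all(cov[out$kept] >= out$coverage_range[1] &
                    cov[out$kept] <= out$coverage_range[2]))

  # equal coverage: nothing discarded
  eq <- coverage_outlier_filter(ids[1:10], setNames(rep(5, 10), ids[1:10]))
  expect_length(eq$discarded, 0)

  # strict inequality at the boundary: threshold equal to the max |score|
  # keeps everything; infinitesimally below it discards the extreme
  x <- setNames(c(1, 2, 3, 4, 50), paste0("b", 1:5))
  s <- max(abs(modified_zscore(unname(x))))
  expect_length(coverage_outlier_filter(names(x), x, threshold = s)$discarded, 0)
  expect_equal(coverage_outlier_filter(names(x), x,
                                       threshold = s - 1e-9)$discarded, "b5")

  expect_error(coverage_outlier_filter(c("c001", "nope"), cov), "missing")
})

test_that("the flagged fraction on clean normal coverage stays below 0.5%", {
  for (sd in 1:10) {
    x <- magscope:::with_seed(sd + 50, rnorm(10000, 30, 5))
    frac <- mean(abs(modified_zscore(x)) > 3.5)
    expect_lt(frac, 0.005)
  }
})

test_that("per-contig mean coverage is length-weighted with implicit zeros", {
  d <- data.frame(contig = c("u", "h", "w", "w"),
                  start = c(0, 0, 0, 100), end = c(50, 100, 100, 300),
                  depth = c(10, 10, 4, 1))
  lens <- c(u = 50L, h = 200L, w = 300L)
  mc <- contig_mean_coverage(d, lens)
  expect_equal(mc[["u"]], 10)
  expect_equal(mc[["h"]], 5)
  expect_equal(mc[["w"]], (400 + 200) / 300)
  # brute-force per-base expansion oracle for the windowed contig
  perbase <- rep(0, 300); perbase[1:100] <- 4; perbase[101:300] <- 1
  expect_equal(mc[["w"]], mean(perbase))
  expect_error(contig_mean_coverage(data.frame(contig = "zz", start = 0,
                                               end = 10, depth = 1), lens),
               "unknown")
})

test_that("hull polygons enclose their source points", {
  pts <- magscope:::with_seed(9, data.frame(chunk_id = paste0("p", 1:50),
                                            x = rnorm(50), y = rnorm(50)))
  poly <- hull_polygon(pts)
  expect_setequal(points_in_polygon(pts, poly), pts$chunk_id)
})

test_that("polygon JSON round-trips", {
  tri <- rbind(c(0, 0), c(2, 0), c(1, 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_polygon(tri, f)
  expect_equal(read_polygon(f), tri, ignore_attr = TRUE)
})
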