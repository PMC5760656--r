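test_that("density tracks count 5' starts per position", {
  ann <- make_ann(
    list(read_id = "r1", category = "piRNA_clusters", target = "clA",
         start = 0L),
    list(read_id = "r2", category = "piRNA_clusters", target = "clA",
         start = 0L),
    list(read_id = "r3", category = "piRNA_clusters", target = "clA",
         start = 7L))
  lib <- toy_library(ann, c(clA = 10L, clB = 12L))
  tr <- density_track(lib, "clA")
  expect_equal(tr$counts, c(2, 0, 0, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(sum(tr$counts), 3)
  # empty cluster -> all-zero track of cluster length
  tr0 <- density_track(lib, "clB")
  expect_equal(tr0$counts, rep(0, 12))
  expect_error(density_track(lib, "nope"), "unknown cluster")
  # scaling multiplies every position
  expect_equal(density_track(lib, "clA", scale = 3)$counts,
               tr$counts * 3)
})

test_that("bedGraph export round-trips the nonzero positions", {
  ann <- make_ann(
    list(read_id = "r1", category = "piRNA_clusters", target = "clA",
         start = 2L),
    list(read_id = "r2", category = "piRNA_clusters", target = "clA",
         start = 2L))
  lib <- toy_library(ann, c(clA = 8L))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  export_bedgraph(density_track(lib, "clA"), f)
  gr <- rtracklayer::import.bedGraph(f)
  expect_equal(GenomicRanges::start(gr), 3L)  # 1-based in GRanges
  expect_equal(gr$score, 2)
})

test_that("window vs full fold changes follow the hand-computed case", {
  ref <- window_library("clA", 1000, n_window = 10, n_beyond = 90,
                        prefix = "w")
  alt <- window_library("clA", 1000, n_window = 10, n_beyond = 9,
                        prefix = "k")
  cmp <- paired_comparison(ref, alt)
  expect_warning(
    wa <- window_vs_full(cmp, window_nt = 300, top_k = 1, pseudocount = 0),
    NA)
  expect_equal(wa$table$fc_window, 1.0)
  expect_equal(wa$table$fc_full, 100 / 19, tolerance = 1e-12)
})

test_that("identical libraries give unit fold changes and p = 1", {
  ref <- window_library("clA", 1000, 10, 20, prefix = "w")
  ref2 <- window_library("clA", 1000, 10, 20, prefix = "w")
  cmp <- paired_comparison(ref, ref2)
  expect_warning(wa <- window_vs_full(cmp, 300, 1, pseudocount = 0),
                 "p = 1 by convention")
  expect_equal(wa$table$fc_window, 1.0)
  expect_equal(wa$table$fc_full, 1.0)
  expect_equal(wa$t_statistic, 0)
  expect_equal(wa$p_value, 1.0)
})

test_that("a window at least the cluster length makes window == full", {
  set.seed(17)
  starts_w <- sample(0:900, 60, replace = TRUE)
  starts_k <- sample(0:900, 25, replace = TRUE)
  mk <- function(starts, prefix) {
    ann <- tibble::tibble(
      read_id = sprintf("%s%04d", prefix, seq_along(starts)),
      length = 26L, category = "piRNA_clusters", target = "clA",
      start = as.integer(starts), strand = "sense", mismatches = 0L)
    toy_library(ann, c(clA = 1000L))
  }
  cmp <- paired_comparison(mk(starts_w, "w"), mk(starts_k, "k"))
  suppressWarnings(
    wa <- window_vs_full(cmp, window_nt = 1000, top_k = 1, pseudocount = 1))
  expect_identical(wa$table$fc_window, wa$table$fc_full)
})

test_that("metagene binning follows floor(p * n_bins / L)", {
  ann <- make_ann(list(read_id = "r1", category = "piRNA_clusters",
                       target = "clA", start = 5L))
  lib <- toy_library(ann, c(clA = 100L))
  mg <- metagene(lib, n_bins = 100)
  expect_equal(which(mg$bins > 0) - 1L, 5L)
  # L = 250: start 249 lands in the last bin, floor(249*100/250) = 99
  ann2 <- make_ann(list(read_id = "r1", category = "piRNA_clusters",
                        target = "clA", start = 249L))
  lib2 <- toy_library(ann2, c(clA = 250L))
  mg2 <- metagene(lib2, n_bins = 100)
  expect_equal(which(mg2$bins > 0) - 1L, 99L)
})

test_that("the bin map is total on [0, L) with image in [0, n_bins)", {
  set.seed(23)
  for (i in 1:20) {
    L <- sample(50:5000, 1)
    n_bins <- sample(c(10, 100, 250), 1)
    p <- sample(0:(L - 1), min(L, 200))
    b <- floor(p * n_bins / L)
    expect_true(all(b >= 0 & b < n_bins))
  }
})

test_that("metagene bins conserve the cluster-assigned read total", {
  cfg <- desk_scenario(seed = 41, n_cluster_reads = 3000L,
                       mirna_reads = 200L)
  ref <- make_reference(cfg)
  sim <- simulate_library(cfg, ref)
  pp <- preprocess_params(min_len = 24, max_len = 32, keep_unclipped = TRUE)
  res <- preprocess_reads(sim$reads, pp)
  lib <- annotate_sequential(res$reads, ref$hierarchy,
                             mirna_count = res$mirna_count)
  mg <- metagene(lib, n_bins = 100)
  n_cluster <- sum(lib$annotations$category == "piRNA_clusters" &
                     lib$annotations$strand == "sense")
  expect_equal(sum(mg$bins), n_cluster)
  # uniform start model fills bins within multinomial bounds
  cfgu <- desk_scenario(seed = 42, n_cluster_reads = 20000L,
                        mirna_reads = 0L,
                        noncluster_reads = c(coding_RNA = 0L,
                                             noncoding_RNA = 0L,
                                             repeats = 0L, intron = 0L,
                                             other = 0L),
                        hotspots = list(n_sites = 50L, alpha = 0.3,
                                        background = 1))
  refu <- make_reference(cfgu)
  simu <- simulate_library(cfgu, refu)
  libu <- annotate_sequential(simu$reads, refu$hierarchy)
  mgu <- metagene(libu, n_bins = 100)
  # a read cannot start within a read length of the cluster end, so the
  # last bins are structurally depleted; uniformity holds on bins where
  # every start is feasible (position < 0.9 L < L - 32 for L >= 500)
  body <- mgu$bins[1:90]
  expected <- mean(body)
  sdm <- sqrt(sum(mgu$bins) * (1 / 100) * (1 - 1 / 100))
  expect_true(all(abs(body - expected) < 4 * sdm + 3))
})

test_that("profile correlation matches the textbook formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 7)
  # independent arithmetic: r = cov / (sd_x sd_y) from explicit sums
  mx <- sum(x) / 5; my <- sum(y) / 5
  r_hand <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  pc <- profile_correlation(x, y)
  expect_equal(pc$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(pc$r_squared, r_hand^2, tolerance = 1e-12)
  # affine and sign cases
  expect_equal(profile_correlation(x, 2 * x + 3)$pearson_r, 1)
  expect_equal(profile_correlation(x, -x)$pearson_r, -1)
  expect_equal(profile_correlation(x, -x)$r_squared, 1)
  # symmetry
  expect_equal(profile_correlation(y, x)$pearson_r, pc$pearson_r)
  # guards
  expect_error(profile_correlation(c(1, 1, 1), x[1:3]), "undefined")
  expect_error(profile_correlation(x, y[1:4]), "equal length")
})

test_that("uniform-background depletion leaves per-position ratio flat", {
  cfg <- desk_scenario(seed = 55, n_cluster_reads = 30000L,
                       mirna_reads = 300L,
                       genotype = genotype_five_prime_sparing(
                         window_nt = 300, factor = 7, top_k = 5))
  ref <- make_reference(cfg)
  pair <- simulate_pair(cfg, ref)
  pp <- preprocess_params(min_len = 24, max_len = 32, keep_unclipped = TRUE)
  w <- preprocess_reads(pair$wt$reads, pp)
  k <- preprocess_reads(pair$ko$reads, pp)
  lw <- annotate_sequential(w$reads, ref$hierarchy, mirna_count = w$mirna_count)
  lk <- annotate_sequential(k$reads, ref$hierarchy, mirna_count = k$mirna_count)
  top <- names(sort(ref$cluster_weights, decreasing = TRUE))[1]
  tw <- density_track(lw, top)
  tk <- density_track(lk, top)
  # aggregate in/out of the window: the 5' window is spared (ratio ~ 1),
  # beyond it the simulated factor 7 depletion shows through
  in_w <- sum(tk$counts[1:300]) / sum(tw$counts[1:300])
  out_w <- sum(tk$counts[-(1:300)]) / sum(tw$counts[-(1:300)])
  expect_gt(in_w, 0.8); expect_lt(in_w, 1.25)
  expect_gt(1 / out_w, 4.5)
})
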