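test_that("composition reports counts and fractions in hierarchy order", {
  ann <- rbind(
    tibble::tibble(read_id = sprintf("c%02d", 1:8), length = 26L,
                   category = "piRNA_clusters", target = "clA", start = 0L,
                   strand = "sense", mismatches = 0L),
    tibble::tibble(read_id = sprintf("o%02d", 1:2), length = 26L,
                   category = "other", target = NA, start = NA,
                   strand = NA, mismatches = NA))
  lib <- toy_library(ann, c(clA = 500L),
                     hierarchy_names = pirna_category_order())
  lib$category_targets <- c(list(piRNA_clusters = "clA"),
                            setNames(rep(list(character()), 4),
                                     pirna_category_order()[-1]))
  comp <- composition(lib)
  expect_equal(comp$category, c(pirna_category_order(), "other"))
  expect_equal(comp$fraction, c(0.8, 0, 0, 0, 0, 0.2))
  expect_equal(sum(comp$count), lib$total_window_reads)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)

  one <- toy_library(ann[1:8, ], c(clA = 500L))
  expect_equal(composition(one)$fraction[1], 1.0)
})

test_that("composition of an empty library is an error", {
  lib <- toy_library(make_ann(), c(clA = 100L))
  expect_error(composition(lib), "no reads in piRNA window")
})

test_that("normalization factors are ratios with zero-count guards", {
  a <- window_library("clA", 1000, 10, 10, mirna_count = 200L)
  b <- window_library("clA", 1000, 5, 5, mirna_count = 100L)
  expect_equal(normalization_factor(a, b, "mirna_proxy"), 2.0)
  expect_equal(normalization_factor(a, a, "mirna_proxy"), 1.0)
  expect_equal(normalization_factor(a, b, "total_reads"), 2.0)
  z <- window_library("clA", 1000, 5, 5, mirna_count = 0L)
  expect_error(normalization_factor(a, z, "mirna_proxy"), "zero miRNA")
})

test_that("cluster counts scale and rank deterministically", {
  ann <- rbind(
    make_ann(),
    tibble::tibble(read_id = sprintf("a%02d", 1:50), length = 26L,
                   category = "piRNA_clusters", target = "clA", start = 0L,
                   strand = "sense", mismatches = 0L),
    tibble::tibble(read_id = sprintf("b%02d", 1:30), length = 26L,
                   category = "piRNA_clusters", target = "clB", start = 0L,
                   strand = "sense", mismatches = 0L),
    tibble::tibble(read_id = sprintf("c%02d", 1:20), length = 26L,
                   category = "piRNA_clusters", target = "clC", start = 0L,
                   strand = "sense", mismatches = 0L))
  lib <- toy_library(ann, c(clA = 400L, clB = 400L, clC = 400L, clD = 400L))
  q <- cluster_counts(lib, scale = 2)
  expect_equal(q$normalized[match(c("clA", "clB", "clC"), q$cluster_id)],
               c(100, 60, 40))
  expect_equal(q$rank[match(c("clA", "clB", "clC", "clD"), q$cluster_id)],
               c(1L, 2L, 3L, 4L))
  # the all-zero cluster is listed, ranked last
  expect_equal(q$raw[q$cluster_id == "clD"], 0L)
  # ranking does not depend on the scale factor
  q10 <- cluster_counts(lib, scale = 10)
  expect_equal(q10$rank, q$rank)
})

test_that("fold changes are ratios with pseudocount guards", {
  ref <- window_library("clA", 1000, 50, 50, mirna_count = 100L,
                        prefix = "w")
  alt <- window_library("clA", 1000, 10, 10, mirna_count = 100L,
                        prefix = "k")
  cmp <- paired_comparison(ref, alt)
  fc <- cluster_fold_change(cmp, pseudocount = 0)
  expect_equal(fc$fold_change, 5.0)
  expect_error(cluster_fold_change(cmp, pseudocount = -1),
               "configuration error")
  # degenerate both-zero cluster with pseudocount 1
  ref0 <- toy_library(make_ann(list(read_id = "r1",
                                    category = "piRNA_clusters",
                                    target = "clA", start = 0L)),
                      c(clA = 100L, clB = 100L))
  alt0 <- toy_library(make_ann(list(read_id = "k1",
                                    category = "piRNA_clusters",
                                    target = "clA", start = 0L)),
                      c(clA = 100L, clB = 100L))
  fc0 <- cluster_fold_change(paired_comparison(ref0, alt0), pseudocount = 1)
  expect_equal(fc0$fold_change[fc0$cluster_id == "clB"], 1.0)
})

test_that("fold changes obey scale invariance and direction inversion", {
  set.seed(31)
  mk <- function(counts, mirna, prefix) {
    ann <- do.call(rbind, lapply(seq_along(counts), function(i) {
      tibble::tibble(
        read_id = sprintf("%s%s_%04d", prefix, names(counts)[i],
                          seq_len(counts[i])),
        length = 26L, category = "piRNA_clusters",
        target = names(counts)[i], start = 0L, strand = "sense",
        mismatches = 0L)
    }))
    toy_library(ann, setNames(rep(1000L, length(counts)), names(counts)),
                mirna_count = mirna)
  }
  counts_ref <- c(clA = 40L, clB = 25L, clC = 10L)
  counts_alt <- c(clA = 12L, clB = 30L, clC = 5L)
  ref1 <- mk(counts_ref, 100L, "r"); alt1 <- mk(counts_alt, 50L, "a")
  ref2 <- mk(counts_ref, 300L, "r"); alt2 <- mk(counts_alt, 150L, "a")
  fc1 <- cluster_fold_change(paired_comparison(ref1, alt1), pseudocount = 0)
  fc2 <- cluster_fold_change(paired_comparison(ref2, alt2), pseudocount = 0)
  expect_equal(fc1$fold_change, fc2$fold_change)

  fwd <- cluster_fold_change(paired_comparison(ref1, alt1), pseudocount = 0)
  rev <- cluster_fold_change(paired_comparison(ref1, alt1,
                                               direction = "alt_over_ref"),
                             pseudocount = 0)
  expect_equal(fwd$fold_change * rev$fold_change,
               rep(1, nrow(fwd)))
})

test_that("fold-change aggregation reports both means", {
  s <- summarize_fold_changes(c(2, 8))
  expect_equal(s$mean_geometric, 4)
  expect_equal(s$mean_arithmetic, 5)
})

test_that("size distribution tabulates on a fixed domain and scales", {
  reads <- reads_tbl(c(strrep("A", 26), strrep("C", 26), strrep("G", 30)))
  h <- size_distribution(reads)
  expect_equal(h$count[h$length == 26], 2L)
  expect_equal(h$count[h$length == 30], 1L)
  expect_equal(sum(h$count), 3L)
  h2 <- size_distribution(reads, scale = 2)
  expect_equal(h2$scaled_count, h$count * 2)
})

test_that("first-nucleotide composition counts position 1 as U/T", {
  reads <- reads_tbl(c("TAAA", "TCCC", "GAAA", "TTTT"))
  f <- first_nt_composition(reads)
  expect_equal(unname(f["U"]), 0.75)
  expect_equal(unname(f["G"]), 0.25)
  expect_equal(sum(f), 1)
  expect_equal(unname(first_nt_composition(reads_tbl("AGG"))["A"]), 1.0)
  expect_error(first_nt_composition(reads_tbl(character())), "no reads")
})

test_that("simulated u1 bias is recovered within binomial error", {
  cfg <- desk_scenario(seed = 3, n_cluster_reads = 10000L,
                       mirna_reads = 0L,
                       noncluster_reads = c(coding_RNA = 0L,
                                            noncoding_RNA = 0L,
                                            repeats = 0L, intron = 0L,
                                            other = 0L))
  ref <- make_reference(cfg)
  sim <- simulate_library(cfg, ref)
  f <- first_nt_composition(sim$reads)
  se <- sqrt(0.8 * 0.2 / nrow(sim$reads))
  expect_lt(abs(f[["U"]] - 0.8), 3 * se)
})

test_that("normalized cluster counts recover true abundance ranks", {
  cfg <- desk_scenario(seed = 21, n_cluster_reads = 8000L,
                       mirna_reads = 500L)
  ref <- make_reference(cfg)
  sim <- simulate_library(cfg, ref)
  pp <- preprocess_params(min_len = 24, max_len = 32, keep_unclipped = TRUE)
  res <- preprocess_reads(sim$reads, pp)
  lib <- annotate_sequential(res$reads, ref$hierarchy,
                             mirna_count = res$mirna_count)
  q <- cluster_counts(lib)
  truth <- sim$truth$clusters
  rho <- stats::cor(q$normalized[match(truth$cluster_id, q$cluster_id)],
                    truth$true_weight, method = "spearman")
  expect_gte(rho, 0.95)
})
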