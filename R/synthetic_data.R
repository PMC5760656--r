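#' Genotype models for the scenario simulator
#'
#' `genotype_wt()` emits libraries untouched. `genotype_uniform_depletion()`
#' thins every cluster-derived read with retention probability `1/factor`
#' (proportional reduction across the whole cluster, as when the piRNA-bound
#' PIWI protein itself is lost). `genotype_five_prime_sparing()` thins only
#' reads starting at or beyond `window_nt` in the `top_k` most abundant
#' clusters by `1/factor`, leaving 5'-window reads untouched (the uncoupled
#' phenotype in which precursor 5' ends keep producing piRNAs), and
#' optionally thins the MIWI-like (29-32 nt) length component everywhere by
#' `1/miwi_global_factor`. Thinning is per-read binomial, so
#' recovery bounds are exact binomial statements. Non-cluster and
#' miRNA-proxy reads are never affected by genotype.
#'
#' @param factor Depletion factor (>= 1).
#' @param window_nt Spared 5' window in nt.
#' @param top_k Number of top clusters (by true abundance) affected.
#' @param miwi_global_factor Extra depletion of the 29-32 nt component.
#' @return A genotype description list.
#' @name genotypes
NULL

#' @rdname genotypes
#' @export
genotype_wt <- function() {
  list(type = "WT")
}

#' @rdname genotypes
#' @export
genotype_uniform_depletion <- function(factor) {
  stopifnot(factor >= 1)
  list(type = "uniform_depletion", factor = factor)
}

#' @rdname genotypes
#' @export
genotype_five_prime_sparing <- function(window_nt = 300L, factor = 7,
                                        top_k = 10L,
                                        miwi_global_factor = 1) {
  stopifnot(window_nt >= 0, factor >= 1, miwi_global_factor >= 1, top_k >= 1)
  list(type = "five_prime_sparing", window_nt = as.integer(window_nt),
       factor = factor, top_k = as.integer(top_k),
       miwi_global_factor = miwi_global_factor)
}

#' Scenario configuration for the simulator
#'
#' Defaults are the desk-scale study conditions: 20 clusters of 500-2000
#' nt with a power-law abundance spectrum (exponent 1.5, under which the
#' top half of clusters produces >90% of cluster reads), 40,000 cluster
#' reads with a bimodal 25-28 nt ("MILI-like") / 29-32 nt ("MIWI-like")
#' length mixture and a 0.8 first-nucleotide U probability, 5,000
#' non-cluster reads across the remaining categories, and 5,000
#' genotype-independent 21-23 nt miRNA-proxy reads — 50,000 reads in all.
#' Within-cluster start positions follow a hotspot model: a Dirichlet(0.3)
#' weight vector over 50 cluster-specific candidate sites plus a 10%
#' uniform background, giving the spiky, piRNA-like density tracks of real
#' precursors while keeping all metagene bins populated.
#'
#' @param seed Integer top-level seed; with the full config it determines
#'   every output byte.
#' @param n_clusters Number of piRNA clusters.
#' @param cluster_length_range Min/max cluster length in nt.
#' @param abundance_exponent Power-law exponent of the per-cluster
#'   abundance spectrum (weights proportional to `rank^-exponent`).
#' @param n_cluster_reads Cluster-derived reads drawn before genotype
#'   thinning.
#' @param u1_prob Probability that a cluster read's first nucleotide is U;
#'   otherwise it is drawn uniformly from A/C/G, so the observed first-nt
#'   U fraction estimates `u1_prob` directly.
#' @param length_mixture List: `mili_weight`, and named probability
#'   vectors `mili_probs` (over 25-28) and `miwi_probs` (over 29-32).
#' @param noncluster_reads Named integer vector of read counts for
#'   `coding_RNA`, `noncoding_RNA`, `repeats`, `intron` and unmappable
#'   `other` reads.
#' @param mirna_reads Number of 21-23 nt miRNA-proxy reads; identical
#'   across genotypes by construction (drawn from a sub-seed that depends
#'   only on the top-level seed).
#' @param genotype A [genotype_wt()], [genotype_uniform_depletion()] or
#'   [genotype_five_prime_sparing()] description.
#' @param hotspots List: `n_sites`, Dirichlet `alpha`, uniform
#'   `background` fraction.
#' @param clip List: `enabled`, `n_reads`, `min_len`, `max_len`,
#'   `a1_prob`, `density_source` (`"proportional"` draws CLIP fragments
#'   from the piRNA position model, `"uniform"` ignores it).
#' @param noncluster_ref Named list of `c(n, len)` pairs describing the
#'   non-cluster reference sequences.
#' @return A validated `scenario_config` object.
#' @export
scenario_config <- function(seed,
                            n_clusters = 20L,
                            cluster_length_range = c(500L, 2000L),
                            abundance_exponent = 1.5,
                            n_cluster_reads = 40000L,
                            u1_prob = 0.8,
                            length_mixture = list(
                              mili_weight = 0.5,
                              mili_probs = c(`25` = 0.20, `26` = 0.35,
                                             `27` = 0.30, `28` = 0.15),
                              miwi_probs = c(`29` = 0.15, `30` = 0.35,
                                             `31` = 0.30, `32` = 0.20)),
                            noncluster_reads = c(coding_RNA = 1500L,
                                                 noncoding_RNA = 1000L,
                                                 repeats = 1000L,
                                                 intron = 1000L,
                                                 other = 500L),
                            mirna_reads = 5000L,
                            genotype = genotype_wt(),
                            hotspots = list(n_sites = 50L, alpha = 0.3,
                                            background = 0.1),
                            clip = list(enabled = FALSE, n_reads = 20000L,
                                        min_len = 15L, max_len = 45L,
                                        a1_prob = 0.5,
                                        density_source = "proportional"),
                            noncluster_ref = list(
                              coding_RNA = c(n = 6, len = 800),
                              noncoding_RNA = c(n = 5, len = 600),
                              repeats = c(n = 5, len = 500),
                              intron = c(n = 6, len = 900))) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_clusters >= 1,
            length(cluster_length_range) == 2,
            cluster_length_range[1] >= 200,
            cluster_length_range[1] <= cluster_length_range[2],
            abundance_exponent > 0,
            n_cluster_reads >= 0,
            u1_prob >= 0, u1_prob <= 1,
            length_mixture$mili_weight >= 0, length_mixture$mili_weight <= 1,
            abs(sum(length_mixture$mili_probs) - 1) < 1e-9,
            abs(sum(length_mixture$miwi_probs) - 1) < 1e-9,
            all(noncluster_reads >= 0),
            mirna_reads >= 0,
            hotspots$n_sites >= 1, hotspots$alpha > 0,
            hotspots$background >= 0, hotspots$background <= 1,
            clip$min_len >= 1, clip$min_len <= clip$max_len,
            clip$a1_prob >= 0, clip$a1_prob <= 1)
  clip$density_source <- match.arg(clip$density_source,
                                   c("proportional", "uniform"))
  gt <- genotype
  stopifnot(gt$type %in% c("WT", "uniform_depletion", "five_prime_sparing"))
  if (gt$type == "five_prime_sparing" && gt$top_k > n_clusters) {
    stop("configuration error: top_k exceeds n_clusters", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_clusters = as.integer(n_clusters),
                 cluster_length_range = as.integer(cluster_length_range),
                 abundance_exponent = abundance_exponent,
                 n_cluster_reads = as.integer(n_cluster_reads),
                 u1_prob = u1_prob,
                 length_mixture = length_mixture,
                 noncluster_reads = noncluster_reads,
                 mirna_reads = as.integer(mirna_reads),
                 genotype = gt,
                 hotspots = hotspots,
                 clip = clip,
                 noncluster_ref = noncluster_ref),
            class = "scenario_config")
}

#' Desk-scale and full-scale scenario presets
#'
#' `desk_scenario()` is the default [scenario_config()] (20 clusters,
#' 50,000 reads): the whole pipeline runs in well under a minute.
#' `fullscale_scenario()` matches the geometry of a real adult-testis
#' experiment — 214 clusters of 2-20 kb and proportionally more reads —
#' for figure-style runs; it is substantially slower to annotate.
#'
#' @param seed Top-level seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
desk_scenario <- function(seed, ...) {
  scenario_config(seed = seed, ...)
}

#' @rdname desk_scenario
#' @export
fullscale_scenario <- function(seed, ...) {
  args <- list(seed = seed,
               n_clusters = 214L,
               cluster_length_range = c(2000L, 20000L),
               n_cluster_reads = 500000L,
               noncluster_reads = c(coding_RNA = 15000L,
                                    noncoding_RNA = 10000L,
                                    repeats = 10000L, intron = 10000L,
                                    other = 5000L),
               mirna_reads = 50000L)
  do.call(scenario_config, modifyList(args, list(...)))
}

random_dna <- function(n_seq, lengths) {
  vapply(seq_len(n_seq), function(i) {
    paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE),
          collapse = "")
  }, "")
}

#' Generate the synthetic reference for a scenario
#'
#' Draws seeded random sequences for every cluster and non-cluster
#' category, the per-cluster power-law abundance weights, and the
#' per-cluster hotspot model (candidate start sites + Dirichlet weights)
#' that paired libraries share. Cluster names are zero-padded so byte
#' order equals numeric order. Identical config yields identical output.
#'
#' @param cfg A [scenario_config()].
#' @return A `sim_reference`: `categories` (named list of named sequence
#'   vectors in hierarchy order), `cluster_weights`, `hotspots`,
#'   `cluster_bed` tibble, and the ready-made [category_hierarchy()].
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(derive_seed(cfg$seed, "reference"))
  n <- cfg$n_clusters
  pad <- max(2L, nchar(as.character(n)))
  cl_names <- sprintf(paste0("cluster_%0", pad, "d"), seq_len(n))
  lens <- sample(seq(cfg$cluster_length_range[1], cfg$cluster_length_range[2]),
                 n, replace = TRUE)
  clusters <- stats::setNames(random_dna(n, lens), cl_names)
  # heavy-tailed abundance: rank^-a assigned to a shuffled cluster order
  w <- seq_len(n)^(-cfg$abundance_exponent)
  w <- w / sum(w)
  weights <- stats::setNames(w[order(sample(n))], cl_names)
  hotspots <- lapply(cl_names, function(cl) {
    L <- nchar(clusters[[cl]])
    sites <- sort(sample(0:(L - 50L), cfg$hotspots$n_sites, replace = FALSE))
    g <- rgamma(cfg$hotspots$n_sites, shape = cfg$hotspots$alpha)
    while (sum(g) == 0) g <- rgamma(cfg$hotspots$n_sites,
                                    shape = cfg$hotspots$alpha)
    list(sites = sites, weights = g / sum(g))
  })
  names(hotspots) <- cl_names
  noncl <- lapply(names(cfg$noncluster_ref), function(cat) {
    spec <- cfg$noncluster_ref[[cat]]
    stats::setNames(random_dna(spec[["n"]], rep(spec[["len"]], spec[["n"]])),
                    sprintf("%s_%02d", cat, seq_len(spec[["n"]])))
  })
  names(noncl) <- names(cfg$noncluster_ref)
  categories <- c(list(piRNA_clusters = clusters), noncl)
  categories <- categories[intersect(pirna_category_order(),
                                     names(categories))]
  bed <- tibble(chrom = cl_names, start = 0L, end = unname(lens),
                name = cl_names, score = 0L, strand = "+")
  structure(list(seed = cfg$seed,
                 categories = categories,
                 cluster_weights = weights,
                 hotspots = hotspots,
                 cluster_bed = bed,
                 hierarchy = category_hierarchy(categories)),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("sim_reference (seed %d): %d clusters, %d categories\n",
              x$seed, length(x$categories$piRNA_clusters),
              length(x$categories)))
  invisible(x)
}

# Draw start positions for reads on clusters under the hotspot model.
# cl: cluster name per read; len: read length per read.
draw_starts <- function(ref, cfg, cl, len) {
  n <- length(cl)
  starts <- integer(n)
  L <- nchar(ref$categories$piRNA_clusters)[match(
    cl, names(ref$categories$piRNA_clusters))]
  bg <- runif(n) < cfg$hotspots$background
  starts[bg] <- floor(runif(sum(bg)) * (L[bg] - len[bg] + 1L))
  for (c in unique(cl[!bg])) {
    idx <- which(!bg & cl == c)
    hs <- ref$hotspots[[c]]
    starts[idx] <- sample(hs$sites, length(idx), replace = TRUE,
                          prob = hs$weights)
  }
  as.integer(pmin(starts, L - len))
}

# miRNA-proxy block: depends only on the top-level seed, so paired
# libraries carry identical miRNA reads (genotype invariance).
draw_mirna_reads <- function(cfg) {
  n <- cfg$mirna_reads
  if (n == 0) {
    return(tibble(read_id = character(), seq = character(),
                  source = character()))
  }
  set.seed(derive_seed(cfg$seed, "mirna"))
  lens <- sample(21:23, n, replace = TRUE)
  tibble(read_id = sprintf("mirna_r%05d", seq_len(n)),
         seq = random_dna(n, lens),
         source = "simulated")
}

#' Simulate a small-RNA library with its truth table
#'
#' Cluster reads are drawn cluster-by-cluster from the abundance weights,
#' start positions from the hotspot model, lengths from the MILI/MIWI
#' mixture, sequences copied from the cluster with the first nucleotide
#' overwritten (U with probability `u1_prob`, else uniform over A/C/G),
#' and the genotype transform applied as per-read binomial thinning.
#' Non-cluster reads are drawn from the category references (24-32 nt,
#' unmodified) and `other` reads are unmappable random sequences; neither
#' is affected by genotype, and the miRNA-proxy block is identical across
#' genotypes. The truth table covers every emitted read exactly once and
#' records, per cluster, the true abundance weight and the fraction `w` of
#' emitted reads starting within the genotype window.
#'
#' @param cfg A [scenario_config()].
#' @param ref The matching [make_reference()] output.
#' @param label Library label, used in read ids and sub-seed derivation
#'   (paired libraries use different labels, e.g. `"wt"`/`"ko"`).
#' @param genotype Override of `cfg$genotype` (used by [simulate_pair()]).
#' @return A `sim_library`: `reads` tibble, `truth` (per-read and
#'   per-cluster tibbles), `label`, `genotype`.
#' @export
simulate_library <- function(cfg, ref, label = "wt",
                             genotype = cfg$genotype) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(ref, "sim_reference"))
  set.seed(derive_seed(cfg$seed, paste0("library-", label)))
  n <- cfg$n_cluster_reads
  cl_names <- names(ref$categories$piRNA_clusters)
  cl_seq <- ref$categories$piRNA_clusters

  # cluster-derived reads
  cl <- sample(cl_names, n, replace = TRUE, prob = ref$cluster_weights)
  mili <- runif(n) < cfg$length_mixture$mili_weight
  len <- integer(n)
  mp <- cfg$length_mixture$mili_probs
  wp <- cfg$length_mixture$miwi_probs
  len[mili] <- sample(as.integer(names(mp)), sum(mili), replace = TRUE,
                      prob = mp)
  len[!mili] <- sample(as.integer(names(wp)), sum(!mili), replace = TRUE,
                       prob = wp)
  start <- draw_starts(ref, cfg, cl, len)
  seqs <- substring(cl_seq[match(cl, cl_names)], start + 1L, start + len)
  is_u <- runif(n) < cfg$u1_prob
  first <- character(n)
  first[is_u] <- "T"
  first[!is_u] <- sample(c("A", "C", "G"), sum(!is_u), replace = TRUE)
  substr(seqs, 1L, 1L) <- first

  # genotype thinning
  gt <- genotype
  keep_prob <- rep(1, n)
  wnd <- NA_integer_
  if (gt$type == "uniform_depletion") {
    keep_prob <- rep(1 / gt$factor, n)
  } else if (gt$type == "five_prime_sparing") {
    wnd <- gt$window_nt
    top <- cl_names[order(-ref$cluster_weights, cl_names)][seq_len(gt$top_k)]
    affected <- cl %in% top & start >= wnd
    if (all(nchar(cl_seq[top]) <= wnd)) {
      warning("5' window covers every affected cluster entirely; ",
              "sparing genotype has no effect")
    }
    keep_prob[affected] <- keep_prob[affected] / gt$factor
    if (gt$miwi_global_factor > 1) {
      keep_prob[!mili] <- keep_prob[!mili] / gt$miwi_global_factor
    }
  }
  keep <- runif(n) < keep_prob
  cl_reads <- tibble(
    read_id = sprintf("%s_r%07d", label, seq_len(n))[keep],
    seq = unname(seqs[keep]), source = "simulated")
  cl_truth <- tibble(read_id = cl_reads$read_id,
                     category = "piRNA_clusters",
                     cluster = cl[keep],
                     start = start[keep],
                     length = len[keep],
                     length_class = ifelse(mili[keep], "MILI", "MIWI"))

  # non-cluster reads (genotype-independent)
  nc_reads <- list(); nc_truth <- list()
  for (cat in names(cfg$noncluster_reads)) {
    m <- cfg$noncluster_reads[[cat]]
    if (m == 0) next
    lens_nc <- sample(24:32, m, replace = TRUE)
    if (cat == "other") {
      sq <- random_dna(m, lens_nc)
      tgt <- rep(NA_character_, m); st <- rep(NA_integer_, m)
    } else {
      src <- ref$categories[[cat]]
      pick <- sample(names(src), m, replace = TRUE)
      Ls <- nchar(src)[match(pick, names(src))]
      st <- floor(runif(m) * (Ls - lens_nc + 1L))
      sq <- substring(src[match(pick, names(src))], st + 1L, st + lens_nc)
      tgt <- pick
    }
    nc_reads[[cat]] <- tibble(
      read_id = sprintf("%s_%s_r%05d", label, cat, seq_len(m)),
      seq = unname(sq), source = "simulated")
    nc_truth[[cat]] <- tibble(read_id = nc_reads[[cat]]$read_id,
                              category = cat, cluster = tgt,
                              start = st, length = lens_nc,
                              length_class = NA_character_)
  }
  mirna <- draw_mirna_reads(cfg)
  mirna_truth <- tibble(read_id = mirna$read_id, category = "miRNA",
                        cluster = NA_character_, start = NA_integer_,
                        length = nchar(mirna$seq),
                        length_class = NA_character_)

  reads <- rbind(cl_reads, do.call(rbind, unname(nc_reads)), mirna)
  truth_reads <- rbind(cl_truth, do.call(rbind, unname(nc_truth)),
                       mirna_truth)
  wnd_for_w <- if (!is.na(wnd)) wnd else 300L
  per_cluster <- do.call(rbind, lapply(cl_names, function(c) {
    sel <- cl_truth$cluster == c
    tibble(cluster_id = c,
           true_weight = unname(ref$cluster_weights[[c]]),
           n_reads = sum(sel),
           window_fraction = if (any(sel))
             mean(cl_truth$start[sel] < wnd_for_w) else NA_real_)
  }))
  structure(list(reads = reads,
                 truth = list(reads = truth_reads, clusters = per_cluster,
                              window_nt = wnd_for_w),
                 label = label, genotype = gt),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("sim_library '%s' (%s): %d reads\n", x$label,
              x$genotype$type, nrow(x$reads)))
  invisible(x)
}

#' Simulate a paired wild-type / mutant library set
#'
#' The wild-type member always uses the WT genotype; the mutant member
#' uses `cfg$genotype`. Both are independent draws (distinct sub-seeds)
#' over the same reference and hotspot model, with identical miRNA-proxy
#' blocks.
#'
#' @param cfg A [scenario_config()].
#' @param ref The matching [make_reference()] output.
#' @return List with elements `wt` and `ko` (both `sim_library`).
#' @export
simulate_pair <- function(cfg, ref) {
  list(wt = simulate_library(cfg, ref, label = "wt",
                             genotype = genotype_wt()),
       ko = simulate_library(cfg, ref, label = "ko",
                             genotype = cfg$genotype))
}

#' Simulate a CLIP fragment library
#'
#' Fragments are sampled from cluster positions — proportional mode reuses
#' the piRNA abundance weights and hotspot model, uniform mode draws the
#' cluster and the position uniformly — with lengths uniform in
#' `[min_len, max_len]` and the first nucleotide overwritten to A with
#' probability `a1_prob` (else uniform over C/G/T).
#'
#' @param cfg A [scenario_config()] with `clip$enabled = TRUE`.
#' @param ref The matching [make_reference()] output.
#' @return A `sim_library` with source `"CLIP"`.
#' @export
simulate_clip <- function(cfg, ref) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(ref, "sim_reference"))
  if (!isTRUE(cfg$clip$enabled)) {
    stop("configuration error: clip.enabled is FALSE", call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, "clip"))
  n <- cfg$clip$n_reads
  cl_names <- names(ref$categories$piRNA_clusters)
  cl_seq <- ref$categories$piRNA_clusters
  len <- sample(cfg$clip$min_len:cfg$clip$max_len, n, replace = TRUE)
  if (cfg$clip$density_source == "proportional") {
    cl <- sample(cl_names, n, replace = TRUE, prob = ref$cluster_weights)
    start <- draw_starts(ref, cfg, cl, len)
  } else {
    cl <- sample(cl_names, n, replace = TRUE)
    L <- nchar(cl_seq)[match(cl, cl_names)]
    start <- floor(runif(n) * (L - len + 1L))
  }
  seqs <- substring(cl_seq[match(cl, cl_names)], start + 1L, start + len)
  is_a <- runif(n) < cfg$clip$a1_prob
  first <- character(n)
  first[is_a] <- "A"
  first[!is_a] <- sample(c("C", "G", "T"), sum(!is_a), replace = TRUE)
  substr(seqs, 1L, 1L) <- first
  reads <- tibble(read_id = sprintf("clip_r%06d", seq_len(n)),
                  seq = unname(seqs), source = "CLIP")
  truth_reads <- tibble(read_id = reads$read_id,
                        category = "piRNA_clusters", cluster = cl,
                        start = start, length = len,
                        length_class = NA_character_)
  per_cluster <- do.call(rbind, lapply(cl_names, function(c) {
    sel <- cl == c
    tibble(cluster_id = c,
           true_weight = unname(ref$cluster_weights[[c]]),
           n_reads = sum(sel),
           window_fraction = if (any(sel)) mean(start[sel] < 300L)
           else NA_real_)
  }))
  structure(list(reads = reads,
                 truth = list(reads = truth_reads, clusters = per_cluster,
                              window_nt = 300L),
                 label = "clip",
                 genotype = list(type = "CLIP",
                                 density_source = cfg$clip$density_source)),
            class = "sim_library")
}

#' Write a simulated reference to disk
#'
#' One FASTA per category, a BED of cluster intervals, and a
#' `hierarchy.yaml` listing the category order, FASTA paths, strand policy
#' and fallthrough name, loadable with [read_hierarchy()].
#'
#' @param ref A [make_reference()] output.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "sim_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_entries <- lapply(names(ref$categories), function(cat) {
    fa <- file.path(dir, paste0(cat, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ref$categories[[cat]]), fa, width = 80L)
    strand <- ref$hierarchy$categories[[cat]]$strand
    list(name = cat, fasta = paste0(cat, ".fasta"), strand = strand)
  })
  write.table(ref$cluster_bed, file.path(dir, "clusters.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  yaml::write_yaml(list(categories = cat_entries,
                        fallthrough = ref$hierarchy$fallthrough),
                   file.path(dir, "hierarchy.yaml"))
  invisible(dir)
}

#' Load a category hierarchy from a YAML description
#'
#' The YAML lists `categories` (each with `name`, `fasta` path relative to
#' the YAML file, and optional `strand`) in priority order, plus a
#' `fallthrough` name.
#'
#' @param path Path to `hierarchy.yaml`.
#' @return A [category_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  cats <- list(); strand <- character()
  for (entry in y$categories) {
    fa <- entry$fasta
    if (!file.exists(fa)) fa <- file.path(base, entry$fasta)
    if (!file.exists(fa)) {
      stop("input file not found: ", entry$fasta, call. = FALSE)
    }
    x <- Biostrings::readDNAStringSet(fa)
    cats[[entry$name]] <- stats::setNames(toupper(as.character(x)),
                                          sub("\\s.*$", "", names(x)))
    if (!is.null(entry$strand)) strand[[entry$name]] <- entry$strand
  }
  category_hierarchy(cats, fallthrough = y$fallthrough %||% "other",
                     strand = if (length(strand)) strand else NULL)
}

#' Write a simulated library (FASTQ + truth tables)
#'
#' @param sim A `sim_library`.
#' @param fastq Path for the FASTQ output.
#' @param truth_prefix Optional path prefix; writes
#'   `<prefix>.reads.tsv` and `<prefix>.clusters.tsv`.
#' @return `fastq`, invisibly.
#' @export
write_library <- function(sim, fastq, truth_prefix = NULL) {
  stopifnot(inherits(sim, "sim_library"))
  write_sequences(sim$reads, fastq, format = "fastq")
  if (!is.null(truth_prefix)) {
    write.table(sim$truth$reads, paste0(truth_prefix, ".reads.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    write.table(sim$truth$clusters, paste0(truth_prefix, ".clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(fastq)
}
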