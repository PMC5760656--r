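#' Per-position read-start density track for one cluster
#'
#' Position `i` (0-based) holds the number of sense-strand reads whose 5'
#' end starts at offset `i` on the cluster sequence, multiplied by `scale`.
#' The 5' start is the biogenesis-defined feature of a piRNA (the 1U
#' signature sits there), and start-based tracks make bin conservation
#' exact; full-length coverage tracks are available via `coverage = TRUE`
#' for figure-style plots.
#'
#' @param lib An `annotated_library`.
#' @param cluster_id Target name within the cluster category.
#' @param scale Multiplier (1, or the pair's normalization factor).
#' @param category Category holding the cluster.
#' @param coverage If `TRUE`, each read contributes 1 to every position it
#'   covers instead of only its start.
#' @return A `density_track`: list with `cluster_id`, `length`, `counts`
#'   (numeric vector of that length), `scale`, `coverage`.
#' @export
density_track <- function(lib, cluster_id, scale = 1,
                          category = "piRNA_clusters", coverage = FALSE) {
  stopifnot(inherits(lib, "annotated_library"), scale > 0)
  L <- unname(lib$target_lengths[cluster_id])
  if (length(L) != 1 || is.na(L) ||
      !cluster_id %in% (lib$category_targets[[category]] %||% character())) {
    stop("unknown cluster: ", cluster_id, call. = FALSE)
  }
  ann <- lib$annotations
  ann <- ann[ann$category == category & ann$target == cluster_id &
               ann$strand == "sense" & !is.na(ann$target), , drop = FALSE]
  counts <- numeric(L)
  if (nrow(ann) > 0) {
    if (coverage) {
      for (i in seq_len(nrow(ann))) {
        idx <- (ann$start[i] + 1L):min(L, ann$start[i] + ann$length[i])
        counts[idx] <- counts[idx] + 1
      }
    } else {
      t <- tabulate(ann$start + 1L, nbins = L)
      counts <- as.numeric(t)
    }
  }
  structure(list(cluster_id = cluster_id, length = as.integer(L),
                 counts = counts * scale, scale = scale,
                 coverage = isTRUE(coverage)),
            class = "density_track")
}

#' @export
print.density_track <- function(x, ...) {
  cat(sprintf("density_track %s: %d nt, %.6g reads (scale %.4g, %s)\n",
              x$cluster_id, x$length, sum(x$counts), x$scale,
              if (x$coverage) "coverage" else "5' starts"))
  invisible(x)
}

#' Export a density track as bedGraph
#'
#' 0-based half-open intervals with the track value as score, via
#' rtracklayer.
#'
#' @param track A [density_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "density_track"))
  gr <- GenomicRanges::GRanges(
    seqnames = track$cluster_id,
    ranges = IRanges::IRanges(start = seq_len(track$length), width = 1L),
    score = track$counts)
  GenomeInfoDb::seqlengths(gr) <- track$length
  rtracklayer::export.bedGraph(gr[gr$score != 0], path)
  invisible(path)
}

#' 5'-window versus full-length fold-change analysis
#'
#' For the `top_k` clusters ranked by abundance in the reference library,
#' computes the paired-library fold change restricted to reads starting
#' within the first `window_nt` nt of the cluster (`fc_window`), over the
#' full cluster (`fc_full`), and beyond the window (`fc_beyond`), all with
#' the pair's normalization factor and an additive pseudocount. A
#' two-sided paired t-test compares `log2(fc_full)` against
#' `log2(fc_window)` across the clusters; when every paired difference is
#' zero the statistic is 0 and p is reported as 1 (with a warning) rather
#' than undefined.
#'
#' Clusters shorter than the window use the whole cluster as their window
#' (logged), so `fc_window == fc_full` for them.
#'
#' @param comparison A [paired_comparison()].
#' @param window_nt 5' window in nt, anchored at offset 0 of the cluster
#'   sequence (cluster references must be TSS-anchored).
#' @param top_k Number of top reference-ranked clusters analyzed.
#' @param pseudocount Additive constant for the fold changes.
#' @param category Cluster category name.
#' @return A `window_analysis`: per-cluster tibble plus `t_statistic`,
#'   `p_value`, and the parameters.
#' @export
window_vs_full <- function(comparison, window_nt = 300L, top_k = 50L,
                           pseudocount = 1, category = "piRNA_clusters") {
  stopifnot(inherits(comparison, "paired_comparison"), window_nt >= 0)
  if (pseudocount < 0) {
    stop("configuration error: pseudocount must be non-negative",
         call. = FALSE)
  }
  ref <- comparison$ref; alt <- comparison$alt
  ranks <- cluster_counts(ref, category, scale = 1)
  if (top_k > nrow(ranks)) {
    stop("top_k exceeds the number of clusters", call. = FALSE)
  }
  top <- ranks$cluster_id[order(ranks$rank)][seq_len(top_k)]
  lens <- ref$target_lengths[top]
  short <- names(lens)[lens <= window_nt]
  if (length(short)) {
    pt_log("window_vs_full: window covers whole cluster for %s",
           paste(short, collapse = ", "))
  }
  sf <- comparison$scale_factor
  count_in <- function(lib, cl, upto) {
    a <- lib$annotations
    sum(a$category == category & !is.na(a$target) & a$target == cl &
          a$strand == "sense" & a$start < upto)
  }
  fc_one <- function(rc, ac) {
    num <- rc + pseudocount; den <- ac * sf + pseudocount
    if (comparison$direction == "ref_over_alt") num / den else den / num
  }
  rows <- lapply(top, function(cl) {
    L <- ref$target_lengths[[cl]]
    w <- min(window_nt, L)
    tibble(cluster_id = cl,
           ref_rank = ranks$rank[ranks$cluster_id == cl],
           fc_window = fc_one(count_in(ref, cl, w), count_in(alt, cl, w)),
           fc_full = fc_one(count_in(ref, cl, L), count_in(alt, cl, L)),
           fc_beyond = fc_one(count_in(ref, cl, L) - count_in(ref, cl, w),
                              count_in(alt, cl, L) - count_in(alt, cl, w)))
  })
  tab <- do.call(rbind, rows)
  d <- log2(tab$fc_full) - log2(tab$fc_window)
  if (all(abs(d) < 1e-12)) {
    warning("all paired log2 fold-change differences are zero; ",
            "t statistic 0, p = 1 by convention")
    t_stat <- 0; p <- 1
  } else if (length(d) < 2 || stats::sd(d) == 0) {
    pt_log("window_vs_full: t-test undefined for %d cluster(s)", length(d))
    t_stat <- NA_real_; p <- NA_real_
  } else {
    tt <- t.test(log2(tab$fc_full), log2(tab$fc_window), paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(table = tab, t_statistic = t_stat, p_value = p,
                 window_nt = as.integer(window_nt), top_k = as.integer(top_k),
                 pseudocount = pseudocount, direction = comparison$direction),
            class = "window_analysis")
}

#' @export
print.window_analysis <- function(x, ...) {
  cat(sprintf(
    "window_analysis: top %d clusters, 5' %d nt window (%s)\n",
    x$top_k, x$window_nt, x$direction))
  cat(sprintf("  mean FC window %.3f | full %.3f | beyond %.3f\n",
              mean(x$table$fc_window), mean(x$table$fc_full),
              mean(x$table$fc_beyond)))
  cat(sprintf("  paired t = %.3f, p = %.3g\n", x$t_statistic, x$p_value))
  invisible(x)
}

#' Metagene profile over rescaled clusters
#'
#' Each cluster is divided into `n_bins` equal-length fragments; a read
#' starting at offset `p` on a cluster of length `L` contributes to bin
#' `floor(p * n_bins / L)`, and bins are summed over all included clusters,
#' then scaled. Bin totals equal the number of included cluster-assigned
#' sense reads at scale 1.
#'
#' @param lib An `annotated_library`.
#' @param n_bins Number of bins (default 100).
#' @param clusters Optional subset of cluster ids (default: all targets of
#'   the category).
#' @param scale Multiplier.
#' @param category Cluster category name.
#' @return A `metagene_profile`: `bins` (numeric of length `n_bins`),
#'   `n_bins`, `clusters_included`, `scale`.
#' @export
metagene <- function(lib, n_bins = 100L, clusters = NULL, scale = 1,
                     category = "piRNA_clusters") {
  stopifnot(inherits(lib, "annotated_library"), n_bins >= 1, scale > 0)
  all_cl <- lib$category_targets[[category]]
  if (is.null(all_cl)) {
    stop("category not in hierarchy: ", category, call. = FALSE)
  }
  clusters <- clusters %||% all_cl
  stopifnot(all(clusters %in% all_cl))
  lens <- lib$target_lengths[clusters]
  if (any(lens < n_bins)) {
    pt_log("metagene: %d cluster(s) shorter than %d bins",
           sum(lens < n_bins), n_bins)
  }
  ann <- lib$annotations
  ann <- ann[ann$category == category & !is.na(ann$target) &
               ann$target %in% clusters & ann$strand == "sense", ,
             drop = FALSE]
  bins <- numeric(n_bins)
  if (nrow(ann) > 0) {
    L <- unname(lib$target_lengths[ann$target])
    b <- floor(ann$start * n_bins / L) + 1L
    bins <- as.numeric(tabulate(b, nbins = n_bins))
  }
  structure(list(bins = bins * scale, n_bins = as.integer(n_bins),
                 clusters_included = clusters, scale = scale),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d bins over %d clusters, total %.6g\n",
              x$n_bins, length(x$clusters_included), sum(x$bins)))
  invisible(x)
}

#' Pearson correlation between two profiles
#'
#' @param x,y Numeric vectors of equal length >= 3, or `metagene_profile`
#'   objects. A constant vector makes the correlation undefined and is an
#'   error.
#' @return List with `pearson_r` and `r_squared`.
#' @export
profile_correlation <- function(x, y) {
  xv <- if (inherits(x, "metagene_profile")) x$bins else as.numeric(x)
  yv <- if (inherits(y, "metagene_profile")) y$bins else as.numeric(y)
  if (length(xv) != length(yv) || length(xv) < 3) {
    stop("profiles must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  r <- cor(xv, yv)
  list(pearson_r = r, r_squared = r^2)
}
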