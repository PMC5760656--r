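#' Category composition of an annotated library
#'
#' Read counts and fractions per annotation category, in hierarchy order
#' with the fallthrough category last.
#'
#' @param lib An `annotated_library`.
#' @return Tibble (`category`, `count`, `fraction`); fractions sum to 1.
#' @export
composition <- function(lib) {
  stopifnot(inherits(lib, "annotated_library"))
  if (lib$total_window_reads == 0) {
    stop("no reads in piRNA window", call. = FALSE)
  }
  lev <- c(lib$hierarchy_names, lib$fallthrough)
  tab <- table(factor(lib$annotations$category, levels = lev))
  tibble(category = lev,
         count = as.integer(tab),
         fraction = as.numeric(tab) / lib$total_window_reads)
}

#' Normalization factor between paired libraries
#'
#' Returns the factor by which `alt`-library counts are multiplied to be
#' comparable with `ref`. `mirna_proxy` mode uses each library's 21-23 nt
#' miRNA-proxy count (total small RNA libraries); `total_reads` mode uses
#' each library's total retained window reads (IP libraries).
#'
#' @param ref,alt `annotated_library` objects.
#' @param mode `"mirna_proxy"` or `"total_reads"`.
#' @return A positive scalar.
#' @export
normalization_factor <- function(ref, alt,
                                 mode = c("mirna_proxy", "total_reads")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "annotated_library"),
            inherits(alt, "annotated_library"))
  if (mode == "mirna_proxy") {
    num <- ref$mirna_count; den <- alt$mirna_count
    if (is.na(num) || is.na(den)) {
      stop("miRNA-proxy counts are missing from a library", call. = FALSE)
    }
    if (den == 0 || num == 0) {
      stop("zero miRNA-proxy count: cannot normalize", call. = FALSE)
    }
  } else {
    num <- ref$total_window_reads; den <- alt$total_window_reads
    if (den == 0 || num == 0) {
      stop("zero retained-read count: cannot normalize", call. = FALSE)
    }
  }
  num / den
}

#' Pair two annotated libraries for comparison
#'
#' Binds a reference (conventionally wild-type) and an alternate
#' (conventionally mutant) library together with their normalization
#' factor. Both libraries must have been annotated with identical
#' parameters and cluster definitions.
#'
#' @param ref,alt `annotated_library` objects.
#' @param mode Normalization mode, see [normalization_factor()].
#' @param direction `"ref_over_alt"` (e.g. WT/cKO) or `"alt_over_ref"`.
#' @return A `paired_comparison` object.
#' @export
paired_comparison <- function(ref, alt,
                              mode = c("mirna_proxy", "total_reads"),
                              direction = c("ref_over_alt",
                                            "alt_over_ref")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (!identical(ref$params_digest, alt$params_digest)) {
    stop("libraries were annotated with different parameters/references",
         call. = FALSE)
  }
  structure(list(ref = ref, alt = alt, normalization_mode = mode,
                 scale_factor = normalization_factor(ref, alt, mode),
                 direction = direction),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired_comparison (%s): ref %d reads, alt %d reads, scale %.4g\n",
              x$normalization_mode, x$ref$total_window_reads,
              x$alt$total_window_reads, x$scale_factor))
  invisible(x)
}

#' Per-cluster read counts, normalized counts and ranks
#'
#' Counts reads assigned to each target of one category (clusters with zero
#' reads are listed with count 0), scales them, and ranks by descending
#' normalized count with ties broken by cluster id (byte order). Ranking is
#' invariant to the scale factor.
#'
#' @param lib An `annotated_library`.
#' @param category Category whose targets are quantified.
#' @param scale Multiplier applied to raw counts (1 for the reference
#'   library; the pair's normalization factor for the alternate library).
#' @return Tibble (`cluster_id`, `raw`, `normalized`, `rank`).
#' @export
cluster_counts <- function(lib, category = "piRNA_clusters", scale = 1) {
  stopifnot(inherits(lib, "annotated_library"), scale > 0)
  clusters <- lib$category_targets[[category]]
  if (is.null(clusters)) {
    stop("category not in hierarchy: ", category, call. = FALSE)
  }
  ann <- lib$annotations
  ann <- ann[ann$category == category, , drop = FALSE]
  tab <- table(factor(ann$target, levels = clusters))
  raw <- as.integer(tab)
  normalized <- raw * scale
  o <- order(-normalized, clusters, method = "radix")
  rank <- integer(length(raw)); rank[o] <- seq_along(o)
  tibble(cluster_id = clusters, raw = raw, normalized = normalized,
         rank = rank)
}

#' Per-cluster fold change between paired libraries
#'
#' Fold change of normalized per-cluster counts, with an additive
#' pseudocount guarding zero counts. In `ref_over_alt` direction
#' `FC = (norm_ref + pc) / (norm_alt + pc)`; clusters are returned ordered
#' by their rank in the reference library (descending abundance).
#'
#' @param comparison A [paired_comparison()].
#' @param pseudocount Non-negative additive constant (default 1; 0 is valid
#'   when all counts are positive).
#' @param category Cluster category name.
#' @return Tibble (`cluster_id`, `ref_rank`, `ref_norm`, `alt_norm`,
#'   `fold_change`), ordered by `ref_rank`.
#' @export
cluster_fold_change <- function(comparison, pseudocount = 1,
                                category = "piRNA_clusters") {
  stopifnot(inherits(comparison, "paired_comparison"))
  if (pseudocount < 0) {
    stop("configuration error: pseudocount must be non-negative",
         call. = FALSE)
  }
  ref_q <- cluster_counts(comparison$ref, category, scale = 1)
  alt_q <- cluster_counts(comparison$alt, category,
                          scale = comparison$scale_factor)
  stopifnot(identical(ref_q$cluster_id, alt_q$cluster_id))
  num <- ref_q$normalized + pseudocount
  den <- alt_q$normalized + pseudocount
  fc <- if (comparison$direction == "ref_over_alt") num / den else den / num
  out <- tibble(cluster_id = ref_q$cluster_id,
                ref_rank = ref_q$rank,
                ref_norm = ref_q$normalized,
                alt_norm = alt_q$normalized,
                fold_change = fc)
  out[order(out$ref_rank), , drop = FALSE]
}

#' Arithmetic and geometric mean of a set of fold changes
#'
#' Fold changes are ratios, so the geometric (log-scale) mean is the
#' primary aggregate; the arithmetic mean is reported alongside it.
#'
#' @param fc Numeric vector of positive fold changes.
#' @return Tibble (`n`, `mean_geometric`, `mean_arithmetic`).
#' @export
summarize_fold_changes <- function(fc) {
  stopifnot(is.numeric(fc), length(fc) >= 1, all(fc > 0))
  tibble(n = length(fc),
         mean_geometric = geometric_mean(fc),
         mean_arithmetic = mean(fc))
}

#' Read-length histogram of a library
#'
#' Per-length read counts over a fixed domain (default 15-40 nt so that
#' miRNA and both piRNA populations are visible on one axis), optionally
#' scaled by a pair's normalization factor. Input should be adapter-clipped
#' but not window-filtered.
#'
#' @param reads Read tibble.
#' @param domain Integer vector of lengths to tabulate.
#' @param scale Multiplier for the `scaled_count` column.
#' @return Tibble (`length`, `count`, `scaled_count`).
#' @export
size_distribution <- function(reads, domain = 15:40, scale = 1) {
  assert_reads(reads)
  stopifnot(scale > 0)
  tab <- table(factor(nchar(reads$seq), levels = domain))
  tibble(length = as.integer(domain),
         count = as.integer(tab),
         scaled_count = as.numeric(tab) * scale)
}

#' First-nucleotide composition of a set of reads
#'
#' Fraction of reads whose 5' (position 1) nucleotide is each of A, C, G,
#' U, N. Mature piRNAs show a strong U bias at position 1 (the 1U
#' signature); nuclease-generated CLIP fragments instead show a 5' A bias.
#' DNA-encoded T is reported as U.
#'
#' @param reads Read tibble.
#' @return Named numeric vector over `c("A","C","G","U","N")` summing to 1.
#' @export
first_nt_composition <- function(reads) {
  assert_reads(reads)
  if (nrow(reads) == 0) stop("no reads: composition undefined", call. = FALSE)
  first <- substr(reads$seq, 1L, 1L)
  first[first == "T"] <- "U"
  tab <- table(factor(first, levels = c("A", "C", "G", "U", "N")))
  as.numeric(tab / nrow(reads)) |> stats::setNames(c("A", "C", "G", "U", "N"))
}
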