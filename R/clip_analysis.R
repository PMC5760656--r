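#' Preprocess a CLIP library
#'
#' CLIP fragments are nuclease products of protein-bound RNA, not mature
#' small RNAs, so the only length constraint is a permissive lower bound
#' (default 15 nt) with no upper bound — the same preprocessing contract as
#' [preprocess_reads()] with `max_len = Inf`.
#'
#' @param reads Raw CLIP reads.
#' @param adapter Optional 3' adapter to clip (>= 5 nt).
#' @param min_len Minimum retained fragment length.
#' @param keep_unclipped Keep reads without an adapter occurrence.
#' @return The retained reads (source relabeled `"CLIP"`), with stage
#'   counts in the `"clip_stats"`/`"filter_stats"` attributes of the
#'   intermediate calls folded into a `"preprocess_counts"` attribute.
#' @export
clip_preprocess <- function(reads, adapter = NULL, min_len = 15L,
                            keep_unclipped = TRUE) {
  stopifnot(min_len >= 1)
  params <- preprocess_params(adapter = adapter, min_len = min_len,
                              max_len = Inf,
                              keep_unclipped = keep_unclipped)
  res <- preprocess_reads(reads, params)
  out <- res$reads
  out$source <- "CLIP"
  attr(out, "preprocess_counts") <- res$counts
  out
}

#' Length and first-nucleotide signatures of a CLIP library
#'
#' The length histogram runs over a broad 15-60 nt domain (CLIP fragments
#' have no upper length bound; the domain is capped for reporting), and the
#' position-1 composition distinguishes nuclease-generated fragments
#' (5' A bias) from mature piRNAs (5' U bias). Both reuse the quantify
#' operations, so a piRNA-window library run through this function gives
#' exactly the piRNA-mode results.
#'
#' @param reads Preprocessed CLIP reads.
#' @param domain Histogram domain.
#' @return List with `length_histogram` (tibble) and `first_nt` (named
#'   fractions).
#' @export
clip_signatures <- function(reads, domain = 15:60) {
  assert_reads(reads)
  if (nrow(reads) == 0) stop("no CLIP reads", call. = FALSE)
  list(length_histogram = size_distribution(reads, domain = domain),
       first_nt = first_nt_composition(reads))
}

#' CLIP versus piRNA co-density over clusters
#'
#' Compares where a CLIP library and a piRNA library sit on the same
#' cluster set: per-cluster count pairs (log10-scaled for scatter
#' reporting) and the Pearson correlation of the two binned metagene
#' vectors. Both libraries must be annotated against the same cluster
#' definitions; the correlation is invariant to scaling either library.
#'
#' @param clip,pirna `annotated_library` objects.
#' @param n_bins Metagene bins (default 100).
#' @param category Cluster category name.
#' @return List with `scatter` (tibble: `cluster_id`, `clip_count`,
#'   `pirna_count`, `log10_clip`, `log10_pirna`), `correlation`
#'   (`pearson_r`, `r_squared` of the metagene vectors), and `n_bins`.
#' @export
clip_pirna_codensity <- function(clip, pirna, n_bins = 100L,
                                 category = "piRNA_clusters") {
  stopifnot(inherits(clip, "annotated_library"),
            inherits(pirna, "annotated_library"))
  shared <- intersect(clip$category_targets[[category]] %||% character(),
                      pirna$category_targets[[category]] %||% character())
  if (length(shared) == 0) {
    stop("no shared clusters between the libraries", call. = FALSE)
  }
  cq <- cluster_counts(clip, category, scale = 1)
  pq <- cluster_counts(pirna, category, scale = 1)
  cq <- cq[match(shared, cq$cluster_id), ]
  pq <- pq[match(shared, pq$cluster_id), ]
  scatter <- tibble(cluster_id = shared,
                    clip_count = cq$raw,
                    pirna_count = pq$raw,
                    log10_clip = log10(cq$raw + 1),
                    log10_pirna = log10(pq$raw + 1))
  mg_clip <- metagene(clip, n_bins = n_bins, clusters = shared,
                      category = category)
  mg_pirna <- metagene(pirna, n_bins = n_bins, clusters = shared,
                       category = category)
  list(scatter = scatter,
       correlation = profile_correlation(mg_clip, mg_pirna),
       n_bins = as.integer(n_bins))
}
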