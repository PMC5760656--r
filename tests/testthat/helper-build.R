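# Builders for hand-made annotated libraries used across the unit tests.

make_ann <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(tibble::tibble(read_id = character(), length = integer(),
                          category = character(), target = character(),
                          start = integer(), strand = character(),
                          mismatches = integer()))
  }
  do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(read_id = r$read_id, length = r$length %||% 26L,
                   category = r$category,
                   target = r$target %||% NA_character_,
                   start = r$start %||% NA_integer_,
                   strand = r$strand %||%
                     (if (is.null(r$target)) NA_character_ else "sense"),
                   mismatches = r$mismatches %||%
                     (if (is.null(r$target)) NA_integer_ else 0L))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal annotated library over one cluster category; annotations are
# given as a tibble (category/target/start/strand per read).
toy_library <- function(annotations, cluster_lengths,
                        mirna_count = 100L,
                        hierarchy_names = "piRNA_clusters",
                        fallthrough = "other",
                        extra_targets = list(),
                        digest = "toy-digest") {
  targets <- c(list(piRNA_clusters = sort(names(cluster_lengths))),
               extra_targets)
  lens <- cluster_lengths
  annotated_library(annotations = annotations,
                    mirna_count = mirna_count,
                    hierarchy_names = hierarchy_names,
                    fallthrough = fallthrough,
                    category_targets = targets[hierarchy_names],
                    target_lengths = lens,
                    params_digest = digest)
}

# n_window reads in the 5' window and n_beyond beyond it, on one cluster.
window_library <- function(cluster_id, cluster_len, n_window, n_beyond,
                           window_nt = 300L, mirna_count = 100L,
                           prefix = "r") {
  n <- n_window + n_beyond
  starts <- c(rep(0L, n_window), rep(as.integer(window_nt), n_beyond))
  ann <- tibble::tibble(
    read_id = sprintf("%s%04d", prefix, seq_len(n)),
    length = 26L, category = "piRNA_clusters", target = cluster_id,
    start = starts, strand = "sense", mismatches = 0L)
  toy_library(ann, setNames(as.integer(cluster_len), cluster_id),
              mirna_count = mirna_count)
}

reads_tbl <- function(seqs, source = "simulated", prefix = "r") {
  tibble::tibble(read_id = sprintf("%s%04d", prefix, seq_along(seqs)),
                 seq = seqs, source = source)
}
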