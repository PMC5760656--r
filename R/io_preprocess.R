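#' Read a small-RNA library from FASTA or FASTQ
#'
#' Parses one read per record, preserving record order and upper-casing the
#' sequence. Quality strings in FASTQ are parsed (the file must be
#' structurally valid) but otherwise ignored: no step of the pipeline is
#' quality-aware.
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param source Provenance label attached to every read, one of
#'   `"total"`, `"MILI-IP"`, `"MIWI-IP"`, `"CLIP"`, `"simulated"`.
#' @return A tibble with columns `read_id`, `seq`, `source`. An empty file
#'   yields a zero-row tibble, not an error.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           source = "total") {
  format <- match.arg(format)
  source <- match.arg(source,
                      c("total", "MILI-IP", "MIWI-IP", "CLIP", "simulated"))
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.size(path) == 0) {
    return(tibble(read_id = character(), seq = character(),
                  source = character()))
  }
  if (format == "fastq") validate_fastq(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad)) {
    stop("parse error in ", path, ": record ", bad[1],
         " contains symbols outside {A,C,G,T,N}", call. = FALSE)
  }
  tibble(read_id = unname(ids), seq = unname(seqs),
         source = rep(source, length(seqs)))
}

# Structural FASTQ validation (Biostrings accepts some malformed records
# silently). Errors name the 1-based record index.
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4 != 0) {
    stop("parse error in ", path, ": truncated FASTQ at record ",
         ceiling(n / 4), call. = FALSE)
  }
  for (i in seq_len(n / 4)) {
    b <- (i - 1) * 4
    if (!startsWith(lines[b + 1], "@") || !startsWith(lines[b + 3], "+")) {
      stop("parse error in ", path, ": malformed FASTQ header at record ", i,
           call. = FALSE)
    }
    if (nchar(lines[b + 2]) != nchar(lines[b + 4])) {
      stop("parse error in ", path,
           ": quality length differs from sequence length at record ", i,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ output carries a constant placeholder quality (`I`); qualities play
#' no role anywhere in the pipeline.
#'
#' @param reads Read tibble (`read_id`, `seq`, `source`).
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  assert_reads(reads)
  x <- Biostrings::DNAStringSet(stats::setNames(unname(reads$seq),
                                                reads$read_id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  } else {
    q <- Biostrings::BStringSet(unname(vapply(nchar(reads$seq),
                                              function(w) strrep("I", w),
                                              "")))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Preprocessing parameters
#'
#' @param adapter 3' sequencing adapter (`NULL` to skip clipping); must be
#'   at least 5 nt when given.
#' @param min_len,max_len Retained length window in nt. The mature piRNA
#'   window is 24-32 nt; CLIP libraries use `min_len = 15` with no upper
#'   bound.
#' @param keep_unclipped Keep reads in which no adapter occurrence is found.
#'   Raw sequencer output is conventionally run with `FALSE` (a missing
#'   adapter means the insert was not read through); simulated libraries
#'   emit insert-only reads and use `TRUE`.
#' @return A `preprocess_params` object.
#' @export
preprocess_params <- function(adapter = NULL, min_len = 24L, max_len = 32L,
                              keep_unclipped = FALSE) {
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    if (nchar(adapter) < 5) {
      stop("configuration error: adapter must be at least 5 nt",
           call. = FALSE)
    }
    if (grepl("[^ACGT]", adapter)) {
      stop("configuration error: adapter must be over {A,C,G,T}",
           call. = FALSE)
    }
  }
  min_len <- as.integer(min_len)
  max_len <- if (is.finite(max_len)) as.integer(max_len) else Inf
  if (min_len < 1 || min_len > max_len) {
    stop("configuration error: need 1 <= min_len <= max_len", call. = FALSE)
  }
  structure(list(adapter = adapter, min_len = min_len, max_len = max_len,
                 keep_unclipped = isTRUE(keep_unclipped)),
            class = "preprocess_params")
}

#' Clip the 3' adapter read-through from reads
#'
#' A read is clipped at the leftmost occurrence of the full adapter anywhere
#' in the read; failing that, at a 3'-anchored occurrence of the longest
#' adapter prefix of length >= 5. Reads without any occurrence are kept
#' unchanged when `params$keep_unclipped` is `TRUE`, otherwise discarded.
#' Reads that clip to an empty insert are discarded. No mismatches are
#' allowed in the adapter.
#'
#' @param reads Read tibble.
#' @param params A [preprocess_params()] object with a non-`NULL` adapter.
#' @return The clipped reads; counts per outcome are attached as the
#'   `"clip_stats"` attribute.
#' @export
clip_adapter <- function(reads, params) {
  assert_reads(reads)
  stopifnot(inherits(params, "preprocess_params"))
  if (is.null(params$adapter)) {
    stop("configuration error: clip_adapter requires an adapter",
         call. = FALSE)
  }
  ad <- params$adapter
  n <- nrow(reads)
  seqs <- reads$seq
  cut_at <- rep(NA_integer_, n)          # 0-based insert length after clip
  pos <- regexpr(ad, seqs, fixed = TRUE)
  full <- pos > 0L
  cut_at[full] <- pos[full] - 1L
  n_full <- sum(full)
  # 3'-anchored prefixes, longest first
  n_anch <- 0L
  if (nchar(ad) > 5) {
    for (k in seq(nchar(ad) - 1L, 5L)) {
      open <- is.na(cut_at) & endsWith(seqs, substr(ad, 1L, k))
      if (any(open)) {
        cut_at[open] <- nchar(seqs[open]) - k
        n_anch <- n_anch + sum(open)
      }
    }
  }
  unclipped <- is.na(cut_at)
  if (params$keep_unclipped) cut_at[unclipped] <- nchar(seqs[unclipped])
  keep <- !is.na(cut_at) & cut_at > 0L
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, 1L, cut_at[keep])
  stats <- list(n_input = n,
                n_clipped_full = n_full,
                n_clipped_anchored = n_anch,
                n_unclipped = sum(unclipped),
                n_unclipped_kept = if (params$keep_unclipped)
                  sum(unclipped) else 0L,
                n_empty_discarded = sum(!is.na(cut_at) & cut_at == 0L),
                n_output = nrow(out))
  pt_log("clip_adapter: %d in, %d out (%d full, %d anchored, %d unclipped)",
         n, nrow(out), n_full, n_anch, sum(unclipped))
  attr(out, "clip_stats") <- stats
  out
}

#' Retain reads within a length window
#'
#' @param reads Read tibble.
#' @param min_len,max_len Inclusive window in nt; the mature piRNA window is
#'   24-32 nt.
#' @return The retained reads, order preserved; retained/removed counts are
#'   attached as the `"filter_stats"` attribute.
#' @export
length_filter <- function(reads, min_len = 24L, max_len = 32L) {
  assert_reads(reads)
  stopifnot(min_len <= max_len)
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  pt_log("length_filter [%s,%s]: retained %d, removed %d",
         min_len, max_len, sum(keep), sum(!keep))
  attr(out, "filter_stats") <- list(min_len = min_len, max_len = max_len,
                                    n_retained = sum(keep),
                                    n_removed = sum(!keep))
  out
}

#' Select the miRNA-proxy reads of a library
#'
#' The 21-23 nt reads of an adapter-clipped, pre-window library act as the
#' reference small RNA population for between-library normalization; the
#' size of the returned set is the library's miRNA-proxy count.
#'
#' @param reads Adapter-clipped reads, before the piRNA length window.
#' @return The 21-23 nt reads.
#' @export
select_mirna_proxy <- function(reads) {
  assert_reads(reads)
  len <- nchar(reads$seq)
  reads[len >= 21L & len <= 23L, , drop = FALSE]
}

#' Run the full preprocessing stage
#'
#' Adapter clipping (when an adapter is configured) followed by the length
#' window, with the miRNA-proxy count taken from the clipped, pre-window
#' reads.
#'
#' @param reads Raw reads.
#' @param params A [preprocess_params()] object.
#' @return A list with `reads` (window-filtered), `mirna_count`, and
#'   `counts` (per-stage tallies for the run report).
#' @export
preprocess_reads <- function(reads, params) {
  assert_reads(reads)
  stopifnot(inherits(params, "preprocess_params"))
  n_raw <- nrow(reads)
  clip_stats <- NULL
  if (!is.null(params$adapter)) {
    reads <- clip_adapter(reads, params)
    clip_stats <- attr(reads, "clip_stats")
  }
  mirna <- select_mirna_proxy(reads)
  kept <- length_filter(reads, params$min_len, params$max_len)
  list(reads = kept,
       mirna_count = nrow(mirna),
       counts = list(n_raw = n_raw,
                     clip = clip_stats,
                     n_clipped = nrow(reads),
                     n_mirna_proxy = nrow(mirna),
                     n_window = nrow(kept),
                     min_len = params$min_len,
                     max_len = params$max_len))
}
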