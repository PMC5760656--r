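#' Default annotation category order
#'
#' The five reference sets used for sequential-exclusion annotation, in
#' priority order: piRNA clusters first, then coding RNA, non-coding RNA,
#' repeats, and intron; reads matching none fall through to `"other"`.
#'
#' @return Character vector of category names.
#' @export
pirna_category_order <- function() {
  c("piRNA_clusters", "coding_RNA", "noncoding_RNA", "repeats", "intron")
}

#' Build an ordered category hierarchy
#'
#' Category order is significant: a read is assigned to the first category
#' (in this order) in which it aligns, and later categories only ever see
#' reads unassigned so far. Category sequences are transcript-sense
#' references; by default matching is sense-only except for `repeats` and
#' `intron`, which are matched on both strands (repeat and intronic
#' sequence is not stranded the way a single-stranded precursor transcript
#' is).
#'
#' @param categories Named list; each element is a named character vector
#'   (or `DNAStringSet`) of reference sequences for that category.
#' @param fallthrough Name given to reads matching no category.
#' @param strand Optional named character vector overriding the per-category
#'   strand policy with values `"sense"` or `"both"`.
#' @return A `category_hierarchy` object.
#' @export
category_hierarchy <- function(categories, fallthrough = "other",
                               strand = NULL) {
  stopifnot(is.list(categories), length(categories) >= 1)
  nm <- names(categories)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("configuration error: categories must have unique non-empty names",
         call. = FALSE)
  }
  if (fallthrough %in% nm) {
    stop("configuration error: fallthrough name collides with a category",
         call. = FALSE)
  }
  cats <- lapply(nm, function(cn) {
    seqs <- categories[[cn]]
    if (methods::is(seqs, "DNAStringSet")) {
      seqs <- stats::setNames(as.character(seqs), names(seqs))
    }
    stopifnot(is.character(seqs), length(seqs) >= 1)
    tn <- names(seqs)
    if (is.null(tn) || any(tn == "") || anyDuplicated(tn)) {
      stop("configuration error: targets in category '", cn,
           "' must have unique non-empty names", call. = FALSE)
    }
    seqs <- toupper(seqs)
    if (any(grepl("[^ACGTN]", seqs))) {
      stop("configuration error: reference sequences in '", cn,
           "' contain non-ACGTN symbols", call. = FALSE)
    }
    pol <- if (!is.null(strand) && cn %in% names(strand)) {
      match.arg(strand[[cn]], c("sense", "both"))
    } else if (cn %in% c("repeats", "intron")) "both" else "sense"
    list(name = cn, seqs = seqs, strand = pol)
  })
  names(cats) <- nm
  all_targets <- unlist(lapply(cats, function(c) names(c$seqs)),
                        use.names = FALSE)
  if (anyDuplicated(all_targets)) {
    stop("configuration error: duplicate target names across categories: ",
         paste(unique(all_targets[duplicated(all_targets)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(categories = cats, fallthrough = fallthrough),
            class = "category_hierarchy")
}

#' @export
print.category_hierarchy <- function(x, ...) {
  cat("category_hierarchy with", length(x$categories), "categories +",
      sQuote(x$fallthrough), "fallthrough\n")
  for (c in x$categories) {
    cat(sprintf("  %-16s %4d targets, %5s strand, %7d nt total\n", c$name,
                length(c$seqs), c$strand, sum(nchar(c$seqs))))
  }
  invisible(x)
}

#' Match one read against one reference sequence
#'
#' Enumerates every ungapped placement of the read on the target with
#' Hamming distance at most `max_mismatch` (Bowtie `-v`-style: no indels).
#' An `N` in the read counts as a mismatch wherever it lands.
#'
#' @param seq Read sequence.
#' @param target Reference sequence.
#' @param max_mismatch 0 or 1 allowed mismatches.
#' @param strand `"sense"` or `"both"`; antisense placements align the
#'   reverse complement of the read.
#' @return Tibble (`start` 0-based, `strand`, `mismatches`), sorted by
#'   (mismatches, start, sense before antisense). Empty when no placement
#'   qualifies.
#' @export
match_read <- function(seq, target, max_mismatch = 1L,
                       strand = c("sense", "both")) {
  strand <- match.arg(strand)
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(target), length(target) == 1L,
            max_mismatch %in% c(0L, 1L))
  hits <- cpp_match_all(toupper(seq), toupper(target),
                        as.integer(max_mismatch), strand == "both")
  tibble(start = hits$start,
         strand = c("sense", "antisense")[hits$strand],
         mismatches = hits$mismatches)
}

#' Pick the single winning alignment within a category
#'
#' Deterministic multimapper policy: fewest mismatches, then
#' lexicographically smallest target name (byte order), then smallest
#' start, then sense before antisense. Each read is counted exactly once.
#'
#' @param alignments Tibble with columns `target_name`, `start`, `strand`,
#'   `mismatches`.
#' @return The single winning row.
#' @export
assign_within_category <- function(alignments) {
  stopifnot(is.data.frame(alignments), nrow(alignments) >= 1,
            all(c("target_name", "start", "strand", "mismatches") %in%
                  names(alignments)))
  o <- order(alignments$mismatches,
             alignments$target_name,
             alignments$start,
             match(alignments$strand, c("sense", "antisense")),
             method = "radix")
  alignments[o[1], , drop = FALSE]
}

#' Annotate a library by sequential exclusion
#'
#' Each read is assigned to the first category, in hierarchy order, in which
#' it has at least one qualifying alignment; only reads unassigned by all
#' previous categories are considered for each set, and reads aligning
#' nowhere receive the fallthrough name. Within the winning category a
#' single alignment is chosen by the [assign_within_category()] policy.
#'
#' @param reads Window-filtered read tibble.
#' @param hierarchy A [category_hierarchy()].
#' @param max_mismatch 0 or 1.
#' @param mirna_count miRNA-proxy count of the library (21-23 nt reads of
#'   the clipped, pre-window library), used later for normalization.
#' @return An `annotated_library`: annotations tibble (`read_id`, `length`,
#'   `category`, `target`, `start`, `strand`, `mismatches`), library
#'   tallies, per-category target names and lengths, and a parameter
#'   digest.
#' @export
annotate_sequential <- function(reads, hierarchy, max_mismatch = 1L,
                                mirna_count = NA_integer_) {
  assert_reads(reads)
  stopifnot(inherits(hierarchy, "category_hierarchy"),
            max_mismatch %in% c(0L, 1L))
  flat <- flatten_hierarchy(hierarchy)
  if (nrow(reads) == 0) {
    ann <- tibble(read_id = character(), length = integer(),
                  category = character(), target = character(),
                  start = integer(), strand = character(),
                  mismatches = integer())
  } else {
    res <- cpp_annotate(reads$seq, flat$seq, flat$cat_index, flat$antisense,
                        as.integer(max_mismatch))
    hit <- !is.na(res$cat)
    ann <- tibble(
      read_id = reads$read_id,
      length = nchar(reads$seq),
      category = ifelse(hit, names(hierarchy$categories)[res$cat],
                        hierarchy$fallthrough),
      target = ifelse(hit, flat$target_name[res$target], NA_character_),
      start = res$start,
      strand = ifelse(hit, c("sense", "antisense")[res$strand],
                      NA_character_),
      mismatches = res$mismatches)
  }
  params_digest <- object_digest(list(
    max_mismatch = as.integer(max_mismatch),
    categories = names(hierarchy$categories),
    fallthrough = hierarchy$fallthrough,
    strand = vapply(hierarchy$categories, `[[`, "", "strand"),
    targets = flat$target_name,
    target_lengths = flat$length))
  annotated_library(
    annotations = ann,
    mirna_count = as.integer(mirna_count),
    hierarchy_names = names(hierarchy$categories),
    fallthrough = hierarchy$fallthrough,
    category_targets = lapply(hierarchy$categories,
                              function(c) sort(names(c$seqs), method = "radix")),
    target_lengths = stats::setNames(flat$length, flat$target_name),
    params_digest = params_digest)
}

# Flatten a hierarchy into scan order: categories in priority order,
# targets in lexicographic (byte) name order within each.
flatten_hierarchy <- function(hierarchy) {
  seqs <- character(); cat_index <- integer(); anti <- logical()
  tname <- character()
  for (i in seq_along(hierarchy$categories)) {
    c <- hierarchy$categories[[i]]
    o <- order(names(c$seqs), method = "radix")
    seqs <- c(seqs, unname(c$seqs[o]))
    tname <- c(tname, names(c$seqs)[o])
    cat_index <- c(cat_index, rep(i, length(c$seqs)))
    anti <- c(anti, rep(c$strand == "both", length(c$seqs)))
  }
  list(seq = seqs, target_name = tname, cat_index = cat_index,
       antisense = anti, length = nchar(seqs))
}

#' Construct an annotated library container
#'
#' @param annotations Annotations tibble.
#' @param mirna_count Integer miRNA-proxy count.
#' @param hierarchy_names Ordered category names.
#' @param fallthrough Fallthrough category name.
#' @param category_targets Named list of target names per category.
#' @param target_lengths Named integer vector of target lengths.
#' @param params_digest Digest string of the annotation parameters.
#' @return An `annotated_library` object.
#' @export
annotated_library <- function(annotations, mirna_count, hierarchy_names,
                              fallthrough, category_targets, target_lengths,
                              params_digest) {
  ok <- annotations$category %in% c(hierarchy_names, fallthrough)
  stopifnot(all(ok))
  structure(list(annotations = annotations,
                 mirna_count = as.integer(mirna_count),
                 total_window_reads = nrow(annotations),
                 hierarchy_names = hierarchy_names,
                 fallthrough = fallthrough,
                 category_targets = category_targets,
                 target_lengths = target_lengths,
                 params_digest = params_digest),
            class = "annotated_library")
}

#' @export
print.annotated_library <- function(x, ...) {
  cat("annotated_library:", x$total_window_reads, "reads, miRNA proxy",
      x$mirna_count, "\n")
  tab <- table(factor(x$annotations$category,
                      levels = c(x$hierarchy_names, x$fallthrough)))
  for (nm in names(tab)) cat(sprintf("  %-16s %7d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Serialize an annotated library to TSV + JSON sidecar
#'
#' Writes `<prefix>.tsv` (one row per read) and `<prefix>.json` (library
#' tallies, category targets and lengths, parameter digest). Identical
#' inputs produce byte-identical files.
#'
#' @param lib An `annotated_library`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_annotated_library <- function(lib, prefix) {
  stopifnot(inherits(lib, "annotated_library"))
  write.table(lib$annotations, paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  meta <- list(mirna_count = lib$mirna_count,
               total_window_reads = lib$total_window_reads,
               hierarchy_names = lib$hierarchy_names,
               fallthrough = lib$fallthrough,
               category_targets = lib$category_targets,
               target_lengths = as.list(lib$target_lengths),
               params_digest = lib$params_digest)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Load an annotated library written by [write_annotated_library()]
#'
#' @param prefix Path prefix used at write time.
#' @return An `annotated_library`.
#' @export
read_annotated_library <- function(prefix) {
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(js)) {
    stop("input file not found: ", if (!file.exists(tsv)) tsv else js,
         call. = FALSE)
  }
  ann <- as_tibble(read.delim(tsv, sep = "\t", na.strings = "",
                              colClasses = c(read_id = "character",
                                             category = "character",
                                             target = "character",
                                             strand = "character")))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  annotated_library(
    annotations = ann,
    mirna_count = meta$mirna_count,
    hierarchy_names = meta$hierarchy_names,
    fallthrough = meta$fallthrough,
    category_targets = as.list(meta$category_targets),
    target_lengths = unlist(meta$target_lengths),
    params_digest = meta$params_digest)
}
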