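# Independent exhaustive-Hamming oracle for the read matcher and the
# sequential-exclusion annotator. Pure R, re-derived from the matching
# rules, sharing no code with the package implementation.

oracle_revcomp <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

# Mismatch count of the read at every placement on the target.
# A read 'N' is a mismatch wherever it lands.
oracle_mm_profile <- function(read_chars, target_chars) {
  k <- length(read_chars); L <- length(target_chars)
  P <- L - k + 1L
  if (P < 1L) return(integer(0))
  idx <- outer(seq_len(k), 0:(P - 1L), "+")
  m <- matrix(target_chars[idx], nrow = k)
  as.integer(colSums(m != read_chars | read_chars == "N"))
}

# All qualifying placements of one read on one target, both orientations
# if requested; data.frame sorted by (mismatches, start, sense first).
oracle_match_all <- function(read, target, max_mm, antisense = FALSE) {
  rv <- strsplit(read, "")[[1]]
  tv <- strsplit(target, "")[[1]]
  out <- data.frame(start = integer(), strand = character(),
                    mismatches = integer(), stringsAsFactors = FALSE)
  mm_s <- oracle_mm_profile(rv, tv)
  hit <- which(mm_s <= max_mm)
  if (length(hit)) {
    out <- rbind(out, data.frame(start = hit - 1L, strand = "sense",
                                 mismatches = mm_s[hit]))
  }
  if (antisense) {
    mm_a <- oracle_mm_profile(oracle_revcomp(rv), tv)
    hit <- which(mm_a <= max_mm)
    if (length(hit)) {
      out <- rbind(out, data.frame(start = hit - 1L, strand = "antisense",
                                   mismatches = mm_a[hit]))
    }
  }
  o <- order(out$mismatches, out$start,
             match(out$strand, c("sense", "antisense")))
  out[o, , drop = FALSE]
}

# Full sequential-exclusion annotation of a read set against a
# category_hierarchy, enumerating every (read, category, target,
# placement) and applying the single-winner policy independently.
oracle_annotate <- function(reads, hierarchy, max_mm) {
  res <- lapply(seq_len(nrow(reads)), function(i) {
    rd <- reads$seq[i]
    for (cat in hierarchy$categories) {
      hits <- NULL
      for (tn in names(cat$seqs)) {
        h <- oracle_match_all(rd, cat$seqs[[tn]], max_mm,
                              antisense = cat$strand == "both")
        if (nrow(h)) {
          h$target_name <- tn
          hits <- rbind(hits, h)
        }
      }
      if (!is.null(hits) && nrow(hits)) {
        o <- order(hits$mismatches, hits$target_name, hits$start,
                   match(hits$strand, c("sense", "antisense")),
                   method = "radix")
        w <- hits[o[1], ]
        return(data.frame(read_id = reads$read_id[i], category = cat$name,
                          target = w$target_name, start = w$start,
                          strand = w$strand, mismatches = w$mismatches,
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(read_id = reads$read_id[i],
               category = hierarchy$fallthrough,
               target = NA_character_, start = NA_integer_,
               strand = NA_character_, mismatches = NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A small random fixture: 3-category hierarchy (clusters sense-only,
# coding sense-only, repeats both-strand) and a read set containing exact
# substrings, 1- and 2-substitution variants, antisense fragments, reads
# with N, and unmappable reads.
random_fixture <- function(seed, n_reads = 120) {
  set.seed(seed)
  clusters <- setNames(vapply(1:3, function(i) random_seq(sample(150:300, 1)),
                              ""), sprintf("cl%02d", 1:3))
  coding <- setNames(vapply(1:2, function(i) random_seq(150), ""),
                     sprintf("cd%02d", 1:2))
  repeats <- setNames(vapply(1:2, function(i) random_seq(120), ""),
                      sprintf("rp%02d", 1:2))
  hier <- category_hierarchy(list(piRNA_clusters = clusters,
                                  coding_RNA = coding, repeats = repeats))
  all_seqs <- c(clusters, coding, repeats)
  mutate_at <- function(s, pos) {
    old <- substr(s, pos, pos)
    repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(s, pos, pos) <- repl
    s
  }
  reads <- vapply(seq_len(n_reads), function(i) {
    src <- sample(names(all_seqs), 1)
    L <- nchar(all_seqs[[src]])
    k <- sample(15:32, 1)
    st <- sample(0:(L - k), 1)
    s <- substr(all_seqs[[src]], st + 1, st + k)
    kind <- sample(c("exact", "mm1", "mm2", "anti", "withN", "none"), 1,
                   prob = c(.3, .25, .1, .15, .1, .1))
    if (kind == "mm1") s <- mutate_at(s, sample(k, 1))
    if (kind == "mm2") {
      p <- sample(k, 2)
      s <- mutate_at(mutate_at(s, p[1]), p[2])
    }
    if (kind == "anti") {
      s <- paste(oracle_revcomp(strsplit(s, "")[[1]]), collapse = "")
    }
    if (kind == "withN") {
      p <- sample(k, 1)
      substr(s, p, p) <- "N"
    }
    if (kind == "none") s <- random_seq(k)
    s
  }, "")
  list(hierarchy = hier,
       reads = tibble::tibble(read_id = sprintf("r%04d", seq_len(n_reads)),
                              seq = reads, source = "simulated"))
}
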