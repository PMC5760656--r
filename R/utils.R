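`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a top-level seed and a stage tag
#'
#' All randomness in the package flows from one top-level seed; each stage
#' (reference, library, miRNA block, CLIP block) draws from its own derived
#' stream so that, e.g., the miRNA-proxy reads of paired libraries are
#' identical by construction. The derived value always fits a 32-bit signed
#' integer.
#'
#' @param seed Integer top-level seed.
#' @param tag Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) %% 2147483587
  as.integer(((abs(as.numeric(seed)) %% 2147483587) * 48271 + h * 7919) %%
               2147483587)
}

# md5 digest of an arbitrary R object, via serialization to a temp file
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# stderr logging, silent unless option pirnatools.verbose is set
pt_log <- function(...) {
  if (isTRUE(getOption("pirnatools.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

assert_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "seq", "source") %in% names(reads)))
  invisible(reads)
}
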