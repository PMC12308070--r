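# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stage label, staying inside
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647L)
}

# Convert a BED-like data frame (chrom, start, end; 0-based half-open) into
# a GRanges (1-based closed). Zero-width inputs are rejected.
bed_to_gr <- function(df, chrom = "chrom", start = "start", end = "end") {
  stopifnot(all(c(chrom, start, end) %in% names(df)))
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (any(df[[end]] <= df[[start]])) {
    bad <- which(df[[end]] <= df[[start]])[1L]
    stop(sprintf("malformed interval at row %d: start >= end", bad))
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df[[chrom]]),
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]])
  )
}

# Merge possibly-overlapping BED-like intervals into a disjoint set.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  gr <- GenomicRanges::reduce(bed_to_gr(df))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Total bases covered by a BED-like interval set (after merging overlaps).
covered_bases <- function(df) {
  if (nrow(df) == 0L) return(0)
  m <- merge_intervals(df)
  sum(as.numeric(m$end - m$start))
}

# Write a data frame as a plain TSV with stable formatting (deterministic
# byte output for identical input).
write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, eol = "\n"
  )
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    check.names = FALSE, ...
  )
}
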