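# Readers and writers for the plain-text interchange formats: BED-like
# interval files, counts matrices, metadata and variant-call tables.

#' Write intervals as BED
#'
#' Three-column BED (0-based half-open), plus any extra columns supplied,
#' without a header line.
#'
#' @param df data.frame with `chrom, start, end` first.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", setdiff(names(df), c("chrom", "start", "end")))
  utils::write.table(df[, cols, drop = FALSE], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE, eol = "\n"
  )
  invisible(path)
}

#' Read a BED-like file
#'
#' @param path input path.
#' @param extra_cols names for columns after `chrom, start, end`.
#' @return data.frame with `chrom, start, end` and any extra columns.
#' @export
read_bed <- function(path, extra_cols = character(0)) {
  df <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE
  )
  names(df) <- c("chrom", "start", "end", extra_cols)[seq_len(ncol(df))]
  df
}

#' Write a counts matrix as TSV
#'
#' Columns: `window, chrom, start, end`, then one column per sample.
#'
#' @param K windows x samples matrix with window ids as rownames.
#' @param grid window grid aligned to `K` rows (or NULL for abstract
#'   windows).
#' @param path output path.
#' @export
write_counts <- function(K, grid, path) {
  meta <- if (!is.null(grid)) {
    grid[match(rownames(K), grid$window), c("window", "chrom", "start", "end")]
  } else {
    data.frame(
      window = rownames(K), chrom = NA, start = NA, end = NA,
      stringsAsFactors = FALSE
    )
  }
  write_tsv(cbind(meta, as.data.frame(K, check.names = FALSE)), path)
}

#' Read a counts matrix TSV written by [write_counts()]
#'
#' @param path input path.
#' @return list with `counts` (integer matrix) and `grid`.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  meta_cols <- c("window", "chrom", "start", "end")
  K <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(K) <- df$window
  list(counts = K, grid = df[, meta_cols])
}
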