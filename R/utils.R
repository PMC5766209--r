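#' @keywords internal
"_PACKAGE"

# All genomic coordinates in this package are BED-style: 0-based, half-open
# [start, end). GTF input (1-based, closed) is converted on read.

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

#' Construct a genomic interval key string
#'
#' Keys are used for exact-coordinate joins (junction-gap vs intron matching,
#' splice-site uniqueness). `chrom:strand:start-end`.
#' @noRd
interval_key <- function(chrom, start, end, strand = NULL) {
  if (is.null(strand)) paste(chrom, start, end, sep = ":")
  else paste(chrom, strand, start, end, sep = ":")
}

#' Parse a comma-separated block string "s1-e1,s2-e2" into a matrix
#'
#' Used by the simplified aligned-read TSV format, where each mate's aligned
#' blocks are encoded as half-open `start-end` spans joined by commas.
#'
#' @param x character vector of block strings.
#' @return list of two-column integer matrices (start, end), one per element.
#' @export
parse_blocks <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), function(spans) {
    if (length(spans) == 0L || (length(spans) == 1L && !nzchar(spans)))
      return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
    parts <- strsplit(spans, "-", fixed = TRUE)
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
    stop_if(any(m[, 1] >= m[, 2]), "malformed block string: ", paste(spans, collapse = ","))
    m[order(m[, 1]), , drop = FALSE]
  })
}

#' Format block matrices back to "s1-e1,s2-e2" strings
#' @param blocks list of two-column matrices as returned by [parse_blocks()].
#' @return character vector.
#' @export
format_blocks <- function(blocks) {
  vapply(blocks, function(m) paste(paste0(m[, 1], "-", m[, 2]), collapse = ","),
         character(1))
}

# seed helper: derive a deterministic 32-bit sub-seed from a base seed and a
# stream counter, so independent stages of a pipeline get decoupled streams.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647)
}

#' Write a TSV with a provenance comment header
#'
#' Every table the package writes starts with `#`-prefixed provenance lines
#' (tool version, timestamp, parameter echo) so downstream users can trace how
#' a file was produced; readers skip these lines.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param params named list echoed into the header.
#' @export
write_tsv_provenance <- function(x, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("spliceorder")),
                  error = function(e) "dev")
  writeLines(sprintf("# spliceorder %s", ver), con)
  writeLines(sprintf("# date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  if (length(params))
    writeLines(sprintf("# param %s=%s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","),
                              character(1))), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_provenance()]
#' @param path file path.
#' @return data.frame (provenance lines skipped).
#' @export
read_tsv_provenance <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
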