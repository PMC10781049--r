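# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a data frame as a plain TSV
#'
#' Thin wrapper around [utils::write.table()] with the conventions used for
#' every tabular artifact of the pipeline (tab separator, no quoting, no row
#' names), so that seeded runs are byte-identical.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV written by the pipeline
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# random DNA string of length n (uppercase ACGT); built from integer codes
# so long chromosomes assemble in one pass
random_dna <- function(n) {
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

# express a path relative to a directory when it lies inside it, so that
# reports from seeded runs in different directories stay comparable
rel_to_dir <- function(path, dir) {
  ap <- normalizePath(path, mustWork = FALSE)
  ad <- normalizePath(dir, mustWork = FALSE)
  if (startsWith(ap, paste0(ad, "/"))) substring(ap, nchar(ad) + 2) else path
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(b) unname(DNA_COMPLEMENT[b])

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
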