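# Readers for the tabular study inputs.

#' Read a gene-level count matrix TSV
#'
#' Expected columns: `gene_id`, `length`, then one column per sample.
#'
#' @param path counts TSV.
#' @return list with `counts` (integer matrix, genes as rownames) and
#'   `gene_lengths`.
#' @export
read_count_matrix <- function(path) {
  d <- read_tsv_file(path)
  if (!all(c("gene_id", "length") %in% names(d)))
    stop_input("counts TSV needs gene_id and length columns: %s", path)
  m <- as.matrix(d[, setdiff(names(d), c("gene_id", "length")), drop = FALSE])
  rownames(m) <- d$gene_id
  if (any(m < 0)) stop_input("negative counts in %s", path)
  list(counts = m, gene_lengths = d$length)
}

#' Read a design table TSV
#'
#' Expected columns: `sample`, `genotype`, `treatment`, `replicate`.
#'
#' @param path design TSV.
#' @return design data frame.
#' @export
read_design <- function(path) {
  d <- read_tsv_file(path)
  need <- c("sample", "genotype", "treatment", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop_input("design TSV missing column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$treatment), c("control", "inoculated"))
  if (length(bad) > 0)
    stop_input("unknown treatment level(s): %s", paste(bad, collapse = ", "))
  d
}
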