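# Gene-level parental-origin verdicts and the donor-inherited fraction.

#' Aggregate variant origins to gene-level parental-origin verdicts
#'
#' A gene is `DONOR` when it carries at least `min_evidence` donor-labelled
#' variants and none labelled recurrent, `RECURRENT` in the mirrored case,
#' `MIXED` when it carries both, and `NON_POLYMORPHIC` otherwise. `NOVEL`
#' and `AMBIGUOUS` variants never count as evidence.
#'
#' @param annotated classified + annotated (site, gene) table: needs
#'   `gene_id`, `origin`, `variant_class` columns.
#' @param genes optional gene universe (a `gene_index` or a character
#'   vector); genes without variants are reported `NON_POLYMORPHIC`.
#' @param min_evidence minimum concordant variant count for a verdict
#'   (default 1).
#' @return data frame with one row per gene: verdict, donor/recurrent
#'   evidence counts split by variant class (SNV vs indel).
#' @export
assign_gene_origin <- function(annotated, genes = NULL, min_evidence = 1) {
  if (inherits(genes, "gene_index")) genes <- genes$genes$gene_id
  ev <- annotated[!is.na(annotated$gene_id) &
                  annotated$origin %in% c("DONOR", "RECURRENT"), , drop = FALSE]
  universe <- genes %||% sort(unique(ev$gene_id))
  is_indel <- ev$variant_class != "SNV"
  cnt <- function(sel) {
    t <- table(factor(ev$gene_id[sel], levels = universe))
    as.integer(t)
  }
  n_donor_snv <- cnt(ev$origin == "DONOR" & !is_indel)
  n_donor_indel <- cnt(ev$origin == "DONOR" & is_indel)
  n_rec_snv <- cnt(ev$origin == "RECURRENT" & !is_indel)
  n_rec_indel <- cnt(ev$origin == "RECURRENT" & is_indel)
  n_d <- n_donor_snv + n_donor_indel
  n_r <- n_rec_snv + n_rec_indel
  verdict <- ifelse(n_d >= min_evidence & n_r == 0, "DONOR",
             ifelse(n_r >= min_evidence & n_d == 0, "RECURRENT",
             ifelse(n_d >= 1 & n_r >= 1, "MIXED", "NON_POLYMORPHIC")))
  data.frame(gene_id = universe, verdict = verdict,
             n_donor_variants = n_d, n_recurrent_variants = n_r,
             n_donor_snv = n_donor_snv, n_donor_indel = n_donor_indel,
             n_recurrent_snv = n_rec_snv, n_recurrent_indel = n_rec_indel,
             stringsAsFactors = FALSE)
}

#' Donor-inherited gene fraction
#'
#' The two-term formula `100 * N_donor / (N_donor + N_recurrent)`, reported
#' to one decimal. Mixed and non-polymorphic genes are excluded from both
#' terms (the donor and recurrent gene sets are disjoint by construction).
#'
#' @param n_donor,n_recurrent gene counts.
#' @return percentage, rounded to one decimal.
#' @examples
#' donor_fraction(3736, 12868)  # 22.5
#' @export
donor_fraction <- function(n_donor, n_recurrent) {
  if (n_donor + n_recurrent == 0)
    stop_input("donor fraction undefined: no donor or recurrent genes")
  round(100 * n_donor / (n_donor + n_recurrent), 1)
}

#' Per-chromosome breakdown of donor-inherited genes
#'
#' @param calls gene origin calls ([assign_gene_origin()]).
#' @param gene_chrom named character vector mapping gene_id to chromosome,
#'   or a `gene_index`.
#' @return data frame with one row per chromosome: donor-gene count and the
#'   percentage of all genes on that chromosome, rounded to whole percent.
#'   Genes on chromosomes absent from the mapping are tallied under
#'   `"unplaced"` with a warning.
#' @export
per_chromosome_table <- function(calls, gene_chrom) {
  if (inherits(gene_chrom, "gene_index"))
    gene_chrom <- setNames(gene_chrom$genes$chrom, gene_chrom$genes$gene_id)
  chrom <- gene_chrom[calls$gene_id]
  if (any(is.na(chrom))) {
    warning(sprintf("%d gene(s) on unknown chromosomes counted as unplaced",
                    sum(is.na(chrom))))
    chrom[is.na(chrom)] <- "unplaced"
  }
  chroms <- unique(chrom)
  n_genes <- as.integer(table(factor(chrom, levels = chroms)))
  n_donor <- as.integer(table(factor(chrom[calls$verdict == "DONOR"],
                                     levels = chroms)))
  data.frame(chromosome = chroms,
             n_donor_genes = n_donor,
             n_genes = n_genes,
             pct_of_chromosome_genes = round(100 * n_donor / n_genes),
             stringsAsFactors = FALSE)
}

#' Summarize gene-level inheritance
#'
#' @param calls gene origin calls.
#' @param gene_chrom gene-to-chromosome mapping or `gene_index` (optional;
#'   enables the per-chromosome table).
#' @return object of class `inheritance_summary`: verdict counts, donor
#'   gene counts by evidence class (genes counted once even when they carry
#'   both SNV and indel evidence, with the overlap reported), the donor
#'   fraction percentage, and the per-chromosome table.
#' @export
inheritance_summary <- function(calls, gene_chrom = NULL) {
  n_by <- as.list(table(factor(calls$verdict,
                               levels = c("DONOR", "RECURRENT", "MIXED",
                                          "NON_POLYMORPHIC"))))
  donor <- calls[calls$verdict == "DONOR", , drop = FALSE]
  n_snv_ev <- sum(donor$n_donor_snv > 0)
  n_indel_ev <- sum(donor$n_donor_indel > 0)
  overlap <- sum(donor$n_donor_snv > 0 & donor$n_donor_indel > 0)
  res <- list(counts = n_by,
              n_donor_genes_snv = n_snv_ev,
              n_donor_genes_indel = n_indel_ev,
              n_donor_genes_both = overlap,
              donor_fraction_pct = donor_fraction(n_by$DONOR, n_by$RECURRENT),
              per_chromosome = if (!is.null(gene_chrom))
                per_chromosome_table(calls, gene_chrom))
  structure(res, class = "inheritance_summary")
}

#' @export
print.inheritance_summary <- function(x, ...) {
  cat("Gene-level inheritance summary\n")
  cat(sprintf("  donor: %d  recurrent: %d  mixed: %d  non-polymorphic: %d\n",
              x$counts$DONOR, x$counts$RECURRENT, x$counts$MIXED,
              x$counts$NON_POLYMORPHIC))
  cat(sprintf("  donor-inherited fraction: %.1f%%\n", x$donor_fraction_pct))
  if (!is.null(x$per_chromosome)) {
    cat("  per chromosome:\n")
    print(x$per_chromosome, row.names = FALSE)
  }
  invisible(x)
}

#' Write donor-origin gene runs as a BED graphical genotype
#'
#' Merges runs of consecutive donor-verdict genes per chromosome into
#' half-open BED segments — a coarse graphical genotype of the line.
#'
#' @param calls gene origin calls.
#' @param index `gene_index` (for gene coordinates).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_donor_segments_bed <- function(calls, index, path) {
  g <- merge(index$genes[, c("gene_id", "chrom", "start", "end")], calls,
             by = "gene_id")
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  lines <- character(0)
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, , drop = FALSE]
    run <- rle(gc$verdict == "DONOR")
    idx <- cumsum(c(1, run$lengths))
    for (k in seq_along(run$values)) {
      if (!run$values[k]) next
      rows <- gc[idx[k]:(idx[k + 1] - 1), ]
      lines <- c(lines, sprintf("%s\t%d\t%d\tdonor_run_%d_genes", ch,
                                min(rows$start) - 1L, max(rows$end),
                                nrow(rows)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
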