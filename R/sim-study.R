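# Orchestration: one seeded call produces a complete synthetic study with
# truth sidecars, optionally written to disk as plain-text standard formats.

#' Simulate a complete backcross trio study
#'
#' Runs the pedigree, draws the annotation and reference, places
#' parent-distinguishing variants, plants the cis-marker gene, and simulates
#' the inoculation count matrix. The planted cis gene is guaranteed to lie
#' on a donor-origin segment: if the simulated mosaic retains no
#' fully-donor, unflagged gene, the mosaic region covering one randomly
#' chosen gene is converted to donor origin before any truth quantity is
#' computed (emulating phenotypic selection retaining the causal locus
#' through backcrossing).
#'
#' @param outdir output directory for the standard-format files and truth
#'   sidecars, or `NULL` to keep everything in memory.
#' @param seed integer seed; every random draw of the study derives from it.
#' @param specs chromosome spec.
#' @param n_genes total gene count.
#' @param n_backcrosses,n_selfings pedigree configuration (defaults BC5F4).
#' @param te_fraction,unknown_fraction gene flag fractions.
#' @param upstream_len promoter window length (bp).
#' @param placement [variant_placement_config()].
#' @param expression [expression_sim_config()], or `NULL` to skip counts.
#' @param mosaic optional pre-built offspring haplotype mosaic overriding
#'   the pedigree simulation (used to study prescribed introgression
#'   patterns).
#' @return object of class `trio_study`: the annotation, mosaic, truth site
#'   table, per-gene truth origins (span-based and marker-aware), truth
#'   donor fractions, the planted cis gene id, count simulation output, and
#'   file paths when `outdir` was given.
#' @examples
#' \donttest{
#' study <- simulate_trio_study(seed = 1, n_genes = 40,
#'   specs = chromosome_spec(c("chr1", "chr2"), 3e5, 60))
#' study$truth$donor_fraction_genes_pct
#' }
#' @export
simulate_trio_study <- function(outdir = NULL, seed = NULL,
                                specs = default_chromosomes(),
                                n_genes = 210,
                                n_backcrosses = 5, n_selfings = 4,
                                te_fraction = 0.15, unknown_fraction = 0.10,
                                upstream_len = 1000,
                                placement = variant_placement_config(),
                                expression = expression_sim_config(),
                                mosaic = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ann <- generate_annotation(specs, n_genes, te_fraction, unknown_fraction,
                             upstream_len)
  if (is.null(mosaic)) {
    ped <- simulate_pedigree(n_backcrosses, n_selfings, specs)
    mosaic <- ped$mosaic
  }
  genes <- ann$genes
  # evidence span per gene = upstream window + gene span
  ev <- t(vapply(seq_len(nrow(genes)), function(k) {
    clen <- specs$length_bp[match(genes$chrom[k], specs$name)]
    gene_strata(genes[k, ], ann$features, upstream_len, clen)$evid
  }, numeric(2)))
  span_origin <- mosaic_span_origin(mosaic, genes$chrom, ev[, 1] - 1L, ev[, 2])

  # guarantee a donor-origin, unflagged host for the planted cis marker
  flagged <- genes$mobile_element | genes$unknown_protein
  pick1 <- function(x) x[sample.int(length(x), 1)]
  donor_hosts <- which(span_origin == "DONOR" & !flagged)
  if (length(donor_hosts) == 0) {
    forced <- pick1(which(!flagged))
    seg <- data.frame(chrom = genes$chrom[forced],
                      start = ev[forced, 1] - 1L, end = ev[forced, 2],
                      origin = "DONOR", stringsAsFactors = FALSE)
    mosaic <- force_donor_segment(mosaic, seg)
    span_origin <- mosaic_span_origin(mosaic, genes$chrom, ev[, 1] - 1L, ev[, 2])
    donor_hosts <- which(span_origin == "DONOR" & !flagged)
  }
  cis_gene <- genes$gene_id[pick1(donor_hosts)]

  sites <- emit_trio_vcf(mosaic, ann, placement, cis_gene = cis_gene)

  # marker-aware per-gene truth: aggregate distinguishing sites within the
  # analysis indel-size convention (1-99 bp)
  usable <- sites$origin %in% c("DONOR", "RECURRENT") & !is.na(sites$gene_id) &
    (sites$variant_class == "SNV" | sites$indel_length <= 99)
  agg <- table(factor(sites$gene_id[usable], levels = genes$gene_id),
               factor(sites$origin[usable], levels = c("DONOR", "RECURRENT")))
  n_d <- as.vector(agg[, "DONOR"]); n_r <- as.vector(agg[, "RECURRENT"])
  marker_origin <- ifelse(n_d > 0 & n_r == 0, "DONOR",
                   ifelse(n_r > 0 & n_d == 0, "RECURRENT",
                   ifelse(n_d > 0 & n_r > 0, "MIXED", "NON_POLYMORPHIC")))
  gene_truth <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                           span_origin = span_origin,
                           marker_origin = marker_origin,
                           n_donor_sites = n_d, n_recurrent_sites = n_r,
                           mobile_element = genes$mobile_element,
                           unknown_protein = genes$unknown_protein,
                           is_cis = genes$gene_id == cis_gene,
                           stringsAsFactors = FALSE)
  keep <- !flagged
  frac <- function(o) {
    d <- sum(o[keep] == "DONOR"); r <- sum(o[keep] == "RECURRENT")
    if (d + r == 0) NA_real_ else 100 * d / (d + r)
  }
  truth <- list(donor_fraction_bp_pct = 100 * mosaic_donor_fraction(mosaic),
                donor_fraction_genes_pct = frac(span_origin),
                donor_fraction_markers_pct = frac(marker_origin),
                cis_gene = cis_gene,
                n_backcrosses = n_backcrosses, n_selfings = n_selfings)

  expr <- if (!is.null(expression)) simulate_counts(ann, cis_gene, expression)

  study <- structure(list(annotation = ann, mosaic = mosaic, sites = sites,
                          gene_truth = gene_truth, truth = truth,
                          expr = expr, seed = seed,
                          upstream_len = upstream_len),
                     class = "trio_study")
  if (!is.null(outdir)) study$paths <- write_trio_study(study, outdir)
  study
}

# overwrite one region of a mosaic with DONOR origin
force_donor_segment <- function(mosaic, seg) {
  m <- mosaic[mosaic$chrom == seg$chrom, , drop = FALSE]
  rest <- mosaic[mosaic$chrom != seg$chrom, , drop = FALSE]
  left <- slice_mosaic(m, min(m$start), seg$start)
  right <- slice_mosaic(m, seg$end, max(m$end))
  merge_mosaic(rbind(rest, left, seg, right))
}

#' Write a simulated study to disk
#'
#' Emits the standard-format inputs (VCF, GFF3, FASTA, counts TSV, design
#' TSV) and plain-TSV truth sidecars next to them.
#'
#' @param study `trio_study` object.
#' @param outdir output directory (created if missing).
#' @return named list of file paths.
#' @export
write_trio_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- list(vcf = file.path(outdir, "trio.vcf"),
            gff = file.path(outdir, "annotation.gff3"),
            fasta = file.path(outdir, "genome.fasta"),
            truth_sites = file.path(outdir, "truth_sites.tsv"),
            truth_genes = file.path(outdir, "truth_genes.tsv"),
            truth_summary = file.path(outdir, "truth_summary.json"),
            mosaic = file.path(outdir, "truth_mosaic.tsv"))
  write_trio_vcf(study$sites, study$annotation$specs, p$vcf,
                 c(offspring = "offspring", donor = "donor",
                   recurrent = "recurrent"))
  write_annotation(study$annotation, p$gff, p$fasta)
  write_tsv_file(study$sites, p$truth_sites)
  write_tsv_file(study$gene_truth, p$truth_genes)
  write_tsv_file(study$mosaic, p$mosaic)
  writeLines(jsonlite::toJSON(study$truth, auto_unbox = TRUE, pretty = TRUE,
                              digits = 6),
             p$truth_summary)
  if (!is.null(study$expr)) {
    p$counts <- file.path(outdir, "counts.tsv")
    p$design <- file.path(outdir, "design.tsv")
    p$truth_expression <- file.path(outdir, "truth_expression.tsv")
    cm <- data.frame(gene_id = rownames(study$expr$counts),
                     length = study$expr$gene_lengths,
                     study$expr$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_file(cm, p$counts)
    write_tsv_file(study$expr$design, p$design)
    write_tsv_file(study$expr$truth, p$truth_expression)
  }
  p
}

#' @export
print.trio_study <- function(x, ...) {
  cat(sprintf("Simulated trio study: %d genes, %d variant sites, BC%dF%d\n",
              nrow(x$gene_truth), nrow(x$sites),
              x$truth$n_backcrosses, x$truth$n_selfings))
  cat(sprintf("  true donor fraction: %.2f%% (bp), %s%% (gene-weighted)\n",
              x$truth$donor_fraction_bp_pct,
              format(x$truth$donor_fraction_genes_pct, digits = 4)))
  cat(sprintf("  planted cis gene: %s\n", x$truth$cis_gene))
  invisible(x)
}
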