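# End-to-end orchestration: simulate (optional) -> classify -> annotate ->
# summarize inheritance -> differential expression -> ASE candidates, with
# input validation and a consolidated machine-readable report.

#' Build a pipeline run configuration
#'
#' Either all real-data paths (`vcf`, `gff`, `fasta`, `counts`, `design`)
#' or a simulation request (`simulate = TRUE`) must be provided.
#'
#' @param outdir output directory.
#' @param vcf,gff,fasta,counts,design input paths (ignored when
#'   simulating).
#' @param simulate simulate the study inputs first.
#' @param sim_args list of arguments passed to [simulate_trio_study()].
#' @param offspring,donor,recurrent VCF sample names of the three roles.
#' @param upstream_len,indel_max,alpha,tpm_min analysis thresholds:
#'   promoter window (bp), indel length cap (bp), adjusted-p significance
#'   level, low-expression TPM threshold.
#' @param het_policy heterozygote policy for [read_trio_vcf()].
#' @param seed integer seed (used by the simulation and echoed into the
#'   report).
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, vcf = NULL, gff = NULL, fasta = NULL,
                       counts = NULL, design = NULL,
                       simulate = FALSE, sim_args = list(),
                       offspring = "offspring", donor = "donor",
                       recurrent = "recurrent",
                       upstream_len = 1000, indel_max = 99,
                       alpha = 0.05, tpm_min = 10,
                       het_policy = "ambiguous", seed = NULL) {
  if (upstream_len <= 0 || indel_max <= 0 || alpha <= 0 || tpm_min < 0)
    stop_input("thresholds must be positive")
  paths <- list(vcf = vcf, gff = gff, fasta = fasta, counts = counts,
                design = design)
  if (!simulate && any(vapply(paths[c("vcf", "gff", "fasta")], is.null, TRUE)))
    stop_input("provide vcf, gff and fasta paths, or set simulate = TRUE")
  structure(c(list(outdir = outdir, simulate = simulate, sim_args = sim_args,
                   offspring = offspring, donor = donor,
                   recurrent = recurrent,
                   upstream_len = upstream_len, indel_max = indel_max,
                   alpha = alpha, tpm_min = tpm_min,
                   het_policy = het_policy, seed = seed), paths),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks that the VCF, GFF3, FASTA and TSV inputs parse, that chromosome
#' names agree exactly across files, and that every count-matrix sample
#' appears in the design. Hard errors and warnings are reported
#' separately; callers decide whether warnings abort.
#'
#' @param config `run_config` with real-data paths.
#' @return list with `errors` and `warnings` character vectors.
#' @export
validate_inputs <- function(config) {
  errors <- character(0); warnings_ <- character(0)
  note <- function(v, msg) c(v, msg)
  vcf_chroms <- gff_chroms <- fasta_chroms <- NULL
  if (!is.null(config$vcf)) {
    res <- tryCatch({
      ln <- readLines(config$vcf)
      body <- ln[!startsWith(ln, "#")]
      nf <- lengths(strsplit(body, "\t", fixed = TRUE))
      if (length(body) > 0 && any(nf != nf[1]))
        stop(sprintf("truncated or ragged VCF record at line %d",
                     which(!startsWith(ln, "#"))[which(nf != nf[1])[1]]))
      unique(vapply(strsplit(body, "\t"), `[`, "", 1))
    }, error = function(e) e)
    if (inherits(res, "error")) errors <- note(errors, sprintf("VCF: %s", conditionMessage(res)))
    else vcf_chroms <- res
  }
  if (!is.null(config$gff)) {
    res <- tryCatch(unique(as.character(seqnames(rtracklayer::import(config$gff)))),
                    error = function(e) e)
    if (inherits(res, "error")) errors <- note(errors, sprintf("GFF3: %s", conditionMessage(res)))
    else gff_chroms <- res
  }
  if (!is.null(config$fasta)) {
    res <- tryCatch(sub("\\s.*", "", names(Biostrings::readDNAStringSet(config$fasta))),
                    error = function(e) e)
    if (inherits(res, "error")) errors <- note(errors, sprintf("FASTA: %s", conditionMessage(res)))
    else fasta_chroms <- res
  }
  pairs <- list(c("VCF", "GFF3"), c("VCF", "FASTA"), c("GFF3", "FASTA"))
  sets <- list(VCF = vcf_chroms, GFF3 = gff_chroms, FASTA = fasta_chroms)
  for (p in pairs) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    if (is.null(a) || is.null(b)) next
    bad <- setdiff(a, b)
    if (length(bad) > 0)
      errors <- note(errors, sprintf("chromosome name mismatch: %s present in %s but not %s",
                                     paste(bad, collapse = ", "), p[1], p[2]))
  }
  if (!is.null(config$counts) && !is.null(config$design)) {
    res <- tryCatch({
      cm <- read_count_matrix(config$counts)
      de <- read_design(config$design)
      missing <- setdiff(colnames(cm$counts), de$sample)
      if (length(missing) > 0)
        stop(sprintf("samples absent from design: %s", paste(missing, collapse = ", ")))
      extra <- setdiff(de$sample, colnames(cm$counts))
      if (length(extra) > 0)
        warning(sprintf("design samples absent from matrix: %s", paste(extra, collapse = ", ")))
      NULL
    }, warning = function(w) w, error = function(e) e)
    if (inherits(res, "error")) errors <- note(errors, sprintf("counts/design: %s", conditionMessage(res)))
    if (inherits(res, "warning")) warnings_ <- note(warnings_, conditionMessage(res))
  }
  list(errors = errors, warnings = warnings_)
}

#' Run the full inheritance-tracing and ASE-marker pipeline
#'
#' Executes every stage in order, writes each stage's table under
#' `config$outdir` and returns (and writes) a consolidated summary. All
#' thresholds are echoed into the report; a fixed seed plus fixed inputs
#' give byte-identical outputs.
#'
#' @param config `run_config`.
#' @return list of class `run_report` (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (isTRUE(config$simulate)) {
    sim_args <- config$sim_args
    sim_args$outdir <- file.path(config$outdir, "sim")
    sim_args$seed <- sim_args$seed %||% config$seed
    study <- do.call(simulate_trio_study, sim_args)
    truth <- study$truth
    config$vcf <- study$paths$vcf
    config$gff <- study$paths$gff
    config$fasta <- study$paths$fasta
    config$counts <- study$paths$counts
    config$design <- study$paths$design
  }
  val <- validate_inputs(config)
  for (w in val$warnings) warning("input validation: ", w, call. = FALSE)
  if (length(val$errors) > 0)
    stop_input("input validation failed:\n  %s", paste(val$errors, collapse = "\n  "))

  sites <- read_trio_vcf(config$vcf, config$offspring, config$donor,
                         config$recurrent, config$het_policy)
  sites <- classify_trio_sites(sites)
  sites <- filter_indel_length(sites, 1, config$indel_max, quiet = TRUE)
  write_tsv_file(sites, file.path(config$outdir, "classified_sites.tsv"))

  genome <- Biostrings::readDNAStringSet(config$fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  index <- build_gene_index(config$gff, upstream_len = config$upstream_len)
  index <- gene_filter(index, quiet = TRUE)
  annotated <- annotate_variants(sites, index, genome)
  write_tsv_file(annotated, file.path(config$outdir, "annotated_variants.tsv"))

  calls <- assign_gene_origin(annotated, index)
  write_tsv_file(calls, file.path(config$outdir, "gene_origin.tsv"))
  inh <- inheritance_summary(calls, index)
  write_tsv_file(inh$per_chromosome,
                 file.path(config$outdir, "donor_genes_by_chromosome.tsv"))
  write_donor_segments_bed(calls, index,
                           file.path(config$outdir, "donor_segments.bed"))

  de_block <- NULL
  if (!is.null(config$counts) && !is.null(config$design)) {
    cm <- read_count_matrix(config$counts)
    design <- read_design(config$design)
    tpm <- tpm_normalize(cm$counts, cm$gene_lengths)
    kept <- filter_low_expression(tpm, config$tpm_min, quiet = TRUE)
    counts_f <- cm$counts[kept, , drop = FALSE]
    de_list <- lapply(setNames(nm = c("offspring", "donor", "recurrent")),
                      function(g) nb_de_test(counts_f, design, g, config$alpha))
    for (g in names(de_list))
      write_tsv_file(de_list[[g]], file.path(config$outdir, sprintf("de_%s.tsv", g)))
    patterns <- classify_patterns(de_list)
    write_tsv_file(patterns, file.path(config$outdir, "patterns.tsv"))
    z <- zscore_matrix(tpm[kept, , drop = FALSE], design)
    write_tsv_file(data.frame(gene_id = rownames(z), round(z, 6),
                              check.names = FALSE),
                   file.path(config$outdir, "zscores.tsv"))
    candidates <- intersect_patterns_with_origin(patterns, calls, annotated)
    write_tsv_file(candidates, file.path(config$outdir, "ase_candidates.tsv"))
    cis_reports <- lapply(candidates$gene_id, function(g) {
      v <- annotate_cis_variants(g, annotated, index)
      v[, c("chrom", "pos", "ref", "alt", "variant_class", "indel_length",
            "region", "coding_effect", "distance_to_cds")]
    })
    names(cis_reports) <- candidates$gene_id
    writeLines(jsonlite::toJSON(cis_reports, auto_unbox = TRUE, pretty = TRUE,
                                digits = 6, na = "null"),
               file.path(config$outdir, "ase_cis_variants.json"))
    de_block <- list(
      n_genes_tested = nrow(counts_f),
      n_genes_filtered_low_expression = nrow(cm$counts) - nrow(counts_f),
      deg_counts = lapply(de_list, function(d)
        list(up = sum(d$status == "UP"), down = sum(d$status == "DOWN"))),
      venn_up = as.list(venn_up_sizes(patterns)),
      n_donor_like_only = sum(patterns$donor_like_only),
      ase_candidates = candidates$gene_id,
      ase_cis_genes = candidates$gene_id[candidates$cis_flag])
  }

  report <- list(
    thresholds = list(upstream_len = config$upstream_len,
                      indel_max = config$indel_max,
                      alpha = config$alpha, tpm_min = config$tpm_min,
                      het_policy = config$het_policy),
    seed = config$seed,
    inputs = lapply(list(vcf = config$vcf, gff = config$gff,
                         fasta = config$fasta, counts = config$counts,
                         design = config$design),
                    function(p) if (is.null(p)) NULL else
                      rel_to_dir(p, config$outdir)),
    variants = variant_summary(sites),
    inheritance = list(counts = inh$counts,
                       donor_fraction_pct = inh$donor_fraction_pct,
                       n_donor_genes_snv = inh$n_donor_genes_snv,
                       n_donor_genes_indel = inh$n_donor_genes_indel,
                       n_donor_genes_both = inh$n_donor_genes_both,
                       per_chromosome = inh$per_chromosome),
    expression = de_block,
    truth = truth)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = 6, na = "null"),
             file.path(config$outdir, "summary.json"))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("introtrace pipeline report\n")
  cat(sprintf("  sites: %d (%d SNV, %d indel)\n", x$variants$n_sites,
              x$variants$n_snv, x$variants$n_indel))
  cat(sprintf("  donor-inherited fraction: %.1f%%\n",
              x$inheritance$donor_fraction_pct))
  if (!is.null(x$expression)) {
    up <- vapply(x$expression$deg_counts, function(d) d$up, 0)
    cat(sprintf("  up-regulated DEGs: offspring %d, donor %d, recurrent %d\n",
                up[["offspring"]], up[["donor"]], up[["recurrent"]]))
    cat(sprintf("  donor-like-only genes: %d; cis-flag candidates: %s\n",
                x$expression$n_donor_like_only,
                paste(x$expression$ase_cis_genes, collapse = ", ")))
  }
  invisible(x)
}
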