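# Negative-binomial count simulation for the 3 genotypes x 2 treatments x
# 3 replicates inoculation design.

#' Configuration for simulated expression counts
#'
#' Defaults describe the emulated study: three genotypes (offspring, donor,
#' recurrent), control vs inoculated treatment, three biological replicates,
#' NB dispersion 0.1, a set of commonly inoculation-responsive genes
#' (induced in all genotypes), a few genotype-private responders, and one
#' planted cis-marker gene induced only in the genotypes carrying the donor
#' promoter allele (offspring and donor).
#'
#' @param n_replicates biological replicates per genotype x treatment.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   means.
#' @param responsive_fraction fraction of genes induced by inoculation in
#'   all genotypes.
#' @param responsive_lfc log2 fold-change of commonly responsive genes.
#' @param n_down genes repressed under inoculation in all genotypes.
#' @param down_lfc log2 fold-change of repressed genes (negative).
#' @param n_private_up per-genotype count of privately induced genes.
#' @param cis_lfc log2 fold-change of the planted cis gene in donor-allele
#'   genotypes.
#' @param cis_baseline_min minimum baseline mean imposed on the cis gene so
#'   it clears the low-expression filter.
#' @param libsize_range uniform range of per-sample library-size factors.
#' @return list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_replicates = 3, dispersion = 0.1,
                                  baseline_meanlog = log(150), baseline_sdlog = 1.3,
                                  responsive_fraction = 0.10, responsive_lfc = 3,
                                  n_down = 8, down_lfc = -2,
                                  n_private_up = 4,
                                  cis_lfc = 5, cis_baseline_min = 80,
                                  libsize_range = c(0.7, 1.3)) {
  if (n_replicates < 1) stop_input("replicate count must be positive")
  if (dispersion <= 0) stop_input("dispersion must be > 0")
  structure(as.list(environment()), class = "expression_sim_config")
}

#' Simulate the gene-level count matrix and design table
#'
#' @param ann `sim_annotation` (gene universe and exonic lengths).
#' @param cis_gene gene_id of the planted cis-marker gene (must exist in the
#'   annotation), or `NULL` for none.
#' @param cfg [expression_sim_config()].
#' @return list with `counts` (genes x samples integer matrix),
#'   `gene_lengths` (summed exon bp per gene), `design` (sample, genotype,
#'   treatment, replicate) and `truth` (per-gene true log2 fold-change per
#'   genotype and the cis flag).
#' @export
simulate_counts <- function(ann, cis_gene = NULL,
                            cfg = expression_sim_config()) {
  genes <- ann$genes$gene_id
  ng <- length(genes)
  ex <- ann$features[ann$features$type == "exon", , drop = FALSE]
  lens <- tapply(ex$end - ex$start + 1, ex$gene_id, sum)[genes]
  genotypes <- c("offspring", "donor", "recurrent")
  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        treatment = c("control", "inoculated"),
                        genotype = genotypes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "treatment", "replicate")]
  design$sample <- sprintf("%s_%s_r%d", design$genotype,
                           ifelse(design$treatment == "inoculated", "inoc", "ctrl"),
                           design$replicate)
  design <- design[, c("sample", "genotype", "treatment", "replicate")]

  base <- rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
  lfc <- matrix(0, ng, 3, dimnames = list(genes, genotypes))
  eligible <- setdiff(seq_len(ng), match(cis_gene, genes))
  n_resp <- round(cfg$responsive_fraction * ng)
  resp <- sample(eligible, n_resp)
  lfc[resp, ] <- cfg$responsive_lfc
  remaining <- setdiff(eligible, resp)
  down <- sample(remaining, min(cfg$n_down, length(remaining)))
  lfc[down, ] <- cfg$down_lfc
  remaining <- setdiff(remaining, down)
  for (g in genotypes) {
    pri <- sample(remaining, min(cfg$n_private_up, length(remaining)))
    lfc[pri, g] <- cfg$responsive_lfc
    remaining <- setdiff(remaining, pri)
  }
  if (!is.null(cis_gene)) {
    i <- match(cis_gene, genes)
    if (is.na(i)) stop_input("cis gene %s not in annotation", cis_gene)
    base[i] <- max(base[i], cfg$cis_baseline_min)
    lfc[i, c("offspring", "donor")] <- cfg$cis_lfc
  }
  sf <- runif(nrow(design), cfg$libsize_range[1], cfg$libsize_range[2])
  counts <- matrix(0L, ng, nrow(design), dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- base * sf[j]
    if (design$treatment[j] == "inoculated")
      mu <- mu * 2^lfc[, design$genotype[j]]
    counts[, j] <- rnbinom(ng, mu = mu, size = 1 / cfg$dispersion)
  }
  truth <- data.frame(gene_id = genes,
                      baseline_mean = base,
                      lfc_offspring = lfc[, "offspring"],
                      lfc_donor = lfc[, "donor"],
                      lfc_recurrent = lfc[, "recurrent"],
                      is_cis = genes %in% (cis_gene %||% character(0)),
                      stringsAsFactors = FALSE)
  list(counts = counts, gene_lengths = as.integer(lens),
       design = design, truth = truth)
}
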