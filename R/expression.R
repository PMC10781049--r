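# Expression stage: normalization, low-expression filtering, per-genotype
# negative-binomial differential expression, response-pattern classes.

#' TPM-normalize a count matrix
#'
#' `TPM_g = 1e6 * (c_g / L_g) / sum_h(c_h / L_h)` per sample; every column
#' sums to one million.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param gene_lengths gene lengths in bp (> 0), recycled along rows.
#' @return TPM matrix with the same dimnames.
#' @export
tpm_normalize <- function(counts, gene_lengths) {
  if (any(gene_lengths <= 0)) stop_input("gene lengths must be > 0")
  rate <- counts / gene_lengths
  cs <- colSums(rate)
  if (any(cs == 0))
    stop_input("sample(s) with all-zero counts: %s",
               paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(rate, 2, cs / 1e6, "/")
}

#' Remove genes with low expression in every sample
#'
#' A gene is removed when its TPM is below `threshold` in all samples
#' (i.e. retained when its maximum TPM across samples reaches the
#' threshold); removing genes expressed in even one sample would discard
#' treatment-induced genes.
#'
#' @param tpm TPM matrix.
#' @param threshold TPM threshold (default 10).
#' @param quiet suppress the removal-count message.
#' @return character vector of retained gene ids (rownames).
#' @export
filter_low_expression <- function(tpm, threshold = 10, quiet = FALSE) {
  keep <- apply(tpm, 1, max) >= threshold
  if (!quiet && any(!keep))
    message(sprintf("filter_low_expression: removed %d of %d genes below %g TPM in all samples",
                    sum(!keep), nrow(tpm), threshold))
  rownames(tpm)[keep]
}

# median-of-ratios size factors (geometric reference over all-positive genes)
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) stop_input("no gene with positive counts in every sample; cannot estimate size factors")
  apply(counts, 2, function(cc) exp(stats::median((log(cc) - lg)[ok])))
}

# Newton iterations for the NB group mean under a log link with offsets
fit_nb_group_mean <- function(y, sf, disp) {
  mu <- pmax(rowSums(y) / sum(sf), 1e-10)
  for (it in 1:15) {
    MU <- outer(mu, sf)
    f <- rowSums((y - MU) / (1 + disp * MU))
    fp <- -rowSums(sweep((1 + disp * y) / (1 + disp * MU)^2, 2, sf, "*"))
    step <- f / fp
    step[!is.finite(step)] <- 0
    mu <- pmax(mu - step, 1e-10)
  }
  mu
}

# pooled within-group method-of-moments dispersion over every
# (genotype, treatment) group of the design present in the matrix; returns
# the per-gene dispersion and the pooled residual degrees of freedom
mom_dispersion <- function(counts, design) {
  d <- design[design$sample %in% colnames(counts), , drop = FALSE]
  y <- counts[, d$sample, drop = FALSE]
  sf <- size_factors(y)
  q <- sweep(y, 2, sf, "/")
  grp <- paste(d$genotype, d$treatment, sep = ".")
  ss <- 0; df <- 0; m_acc <- 0
  for (g in unique(grp)) {
    qq <- q[, grp == g, drop = FALSE]
    n <- ncol(qq)
    if (n < 2) next
    ss <- ss + (n - 1) * apply(qq, 1, stats::var)
    df <- df + (n - 1)
    m_acc <- m_acc + rowSums(qq)
  }
  if (df < 2) stop_input("need >= 2 replicates in at least one design group")
  v <- ss / df
  m <- rowMeans(q)
  disp <- pmax((v - m) / m^2, 1e-8)
  disp[!is.finite(disp)] <- 1e-8
  list(dispersion = disp, df = df)
}

#' Negative-binomial Wald test for the inoculation response of one genotype
#'
#' Estimates size factors by the median-of-ratios method and a per-gene NB
#' dispersion by method of moments on normalized counts, with the
#' within-group variance pooled across every (genotype, treatment) group of
#' the design (dispersion is a property of the measurement, so all groups
#' inform it — the same sharing DESeq2 and edgeR rely on) and floored at
#' 1e-8. For the requested genotype the two treatment means are fitted by
#' Newton iteration under a log link and the log fold-change (inoculated vs
#' control) is tested with a Wald statistic whose standard error comes from
#' the observed information. The statistic is referred to a t distribution
#' whose degrees of freedom equal the pooled residual df of the dispersion
#' estimate — a small-sample correction without which the test is
#' anti-conservative at typical replicate counts. p-values are
#' Benjamini-Hochberg adjusted across the tested genes of the genotype.
#'
#' @param counts genes x samples count matrix (all genotypes).
#' @param design design table with columns `sample`, `genotype`,
#'   `treatment` (control/inoculated).
#' @param genotype genotype to test.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data frame per gene: `base_mean` (mean normalized count),
#'   `log2_fold_change`, `p_value`, `adjusted_p`, and `status` (`UP` when
#'   adjusted p < alpha and positive fold-change, `DOWN` mirrored, else
#'   `NS`). Genes with zero counts in both groups have `NA` p-values and
#'   status `NS`.
#' @export
nb_de_test <- function(counts, design, genotype, alpha = 0.05) {
  sel <- design$genotype == genotype
  if (!any(sel)) stop_input("genotype %s not in design", genotype)
  d <- design[sel, , drop = FALSE]
  miss <- setdiff(d$sample, colnames(counts))
  if (length(miss) > 0)
    stop_input("design samples missing from matrix: %s", paste(miss, collapse = ", "))
  dsp <- mom_dispersion(counts, design)
  disp <- dsp$dispersion
  y <- counts[, d$sample, drop = FALSE]
  trt <- d$treatment == "inoculated"
  if (sum(trt) < 2 || sum(!trt) < 2)
    stop_input("need >= 2 replicates per group for genotype %s", genotype)
  sf <- size_factors(y)
  q <- sweep(y, 2, sf, "/")
  m <- rowMeans(q)
  mu0 <- fit_nb_group_mean(y[, !trt, drop = FALSE], sf[!trt], disp)
  mu1 <- fit_nb_group_mean(y[, trt, drop = FALSE], sf[trt], disp)
  info <- function(mu, sfg) {
    MU <- outer(mu, sfg)
    rowSums(MU / (1 + disp * MU))
  }
  se <- sqrt(1 / info(mu0, sf[!trt]) + 1 / info(mu1, sf[trt]))
  b1 <- log(mu1 / mu0)
  p <- 2 * pt(-abs(b1 / se), df = dsp$df)
  all_zero <- rowSums(y) == 0
  p[all_zero] <- NA_real_
  b1[all_zero] <- 0
  padj <- p.adjust(p, method = "BH")
  lfc <- b1 / log(2)
  status <- ifelse(!is.na(padj) & padj < alpha & lfc > 0, "UP",
            ifelse(!is.na(padj) & padj < alpha & lfc < 0, "DOWN", "NS"))
  data.frame(gene_id = rownames(counts), genotype = genotype,
             base_mean = m, log2_fold_change = lfc,
             p_value = p, adjusted_p = padj, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify cross-genotype response patterns
#'
#' Merges per-genotype DE results over a common gene universe, derives the
#' Venn region of the up-regulated sets, and flags the donor-like pattern:
#' up-regulated in offspring and donor but not significantly changed in the
#' recurrent parent.
#'
#' @param de_list named list of [nb_de_test()] results for genotypes
#'   `offspring`, `donor` and `recurrent`.
#' @return data frame per gene: per-genotype status and log2 fold-change,
#'   offspring adjusted p, `venn_region` (sorted `+`-joined genotype names
#'   of the UP sets containing the gene, `"none"` otherwise) and
#'   `donor_like_only`.
#' @export
classify_patterns <- function(de_list) {
  need <- c("offspring", "donor", "recurrent")
  if (!all(need %in% names(de_list)))
    stop_input("de_list must contain results named: %s", paste(need, collapse = ", "))
  universe <- Reduce(intersect, lapply(de_list[need], function(d) d$gene_id))
  dropped <- setdiff(unique(unlist(lapply(de_list[need], function(d) d$gene_id))),
                     universe)
  if (length(dropped) > 0)
    warning(sprintf("%d gene(s) absent from some genotype's results excluded",
                    length(dropped)))
  cols <- lapply(de_list[need], function(d) d[match(universe, d$gene_id), ])
  status <- vapply(cols, function(d) d$status, character(length(universe)))
  up <- status == "UP"
  venn <- apply(up, 1, function(r) if (!any(r)) "none"
                else paste(sort(need[r]), collapse = "+"))
  data.frame(gene_id = universe,
             status_offspring = status[, "offspring"],
             status_donor = status[, "donor"],
             status_recurrent = status[, "recurrent"],
             lfc_offspring = cols$offspring$log2_fold_change,
             lfc_donor = cols$donor$log2_fold_change,
             lfc_recurrent = cols$recurrent$log2_fold_change,
             padj_offspring = cols$offspring$adjusted_p,
             venn_region = venn,
             donor_like_only = up[, "offspring"] & up[, "donor"] &
               status[, "recurrent"] == "NS",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Venn region sizes of the up-regulated sets
#'
#' @param patterns output of [classify_patterns()].
#' @return named integer vector over the seven non-empty intersections.
#' @export
venn_up_sizes <- function(patterns) {
  regions <- c("offspring", "donor", "recurrent",
               "donor+offspring", "offspring+recurrent", "donor+recurrent",
               "donor+offspring+recurrent")
  out <- table(factor(patterns$venn_region, levels = regions))
  setNames(as.integer(out), regions)
}

#' Group-averaged z-scored expression matrix
#'
#' log2(TPM + 1) values are averaged over replicates per
#' (genotype, treatment) group and each gene row is centred and scaled to
#' mean 0, sd 1. Constant rows get an all-zero z-row and are flagged in the
#' `constant_rows` attribute.
#'
#' @param tpm TPM matrix (filtered genes).
#' @param design design table.
#' @return genes x groups z-score matrix.
#' @export
zscore_matrix <- function(tpm, design) {
  grp <- paste(design$genotype, design$treatment, sep = ".")
  groups <- unique(grp)
  avg <- vapply(groups, function(g)
    rowMeans(log2(tpm[, design$sample[grp == g], drop = FALSE] + 1)),
    numeric(nrow(tpm)))
  mu <- rowMeans(avg)
  s <- apply(avg, 1, stats::sd)
  z <- (avg - mu) / s
  constant <- s == 0
  z[constant, ] <- 0
  structure(z, constant_rows = rownames(tpm)[constant])
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_reference)_treated - (Ct_target -
#' Ct_reference)_control`; the returned fold change is `2^-ddCt`.
#'
#' @param ct_target_treat,ct_ref_treat,ct_target_ctrl,ct_ref_ctrl cycle
#'   threshold values.
#' @return fold change.
#' @examples
#' ddct_relative_expression(20, 18, 24, 18)  # 16: four cycles earlier
#' @export
ddct_relative_expression <- function(ct_target_treat, ct_ref_treat,
                                     ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
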