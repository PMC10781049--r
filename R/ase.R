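# Allele-specific-expression marker discovery: genes whose donor-like
# induction pattern co-segregates with donor-origin variants, and whose
# protein-coding part is identical across genotypes while the promoter
# region carries a donor-only variant (the cis-regulatory candidate logic).

PROMOTER_REGIONS <- c("UPSTREAM", "UTR5", "UTR3")
CODING_ALTERING <- c("NONSYNONYMOUS", "INFRAME_INDEL", "FRAMESHIFT")

#' Nominate allele-specific-expression marker candidates
#'
#' Intersects donor-like expression patterns with gene-level origin calls.
#' A gene is a candidate when its pattern is donor-like (up in offspring
#' and donor, not significant in the recurrent parent) and its origin
#' verdict is `DONOR`, or `MIXED` with at least one donor-origin variant in
#' the promoter region (upstream window or UTR). The `cis_flag` marks
#' candidates with promoter evidence and an intact coding sequence: no
#' donor-origin non-synonymous, in-frame-indel or frameshift variant
#' (synonymous changes are tolerated). `promoter_indel_length` reports the
#' longest donor-origin upstream-window indel, the shape of a promoter
#' insertion marker.
#'
#' @param patterns output of [classify_patterns()].
#' @param origins gene origin calls ([assign_gene_origin()]).
#' @param annotated classified + annotated (site, gene) table with
#'   `coding_effect`.
#' @return data frame of candidates ranked by offspring adjusted p
#'   (ascending, ties by gene id): pattern and origin evidence, `cis_flag`,
#'   and `promoter_indel_length` (`NA` when no upstream indel exists).
#' @export
intersect_patterns_with_origin <- function(patterns, origins, annotated) {
  dl <- patterns[patterns$donor_like_only, , drop = FALSE]
  if (nrow(dl) == 0) {
    message("no donor-like expression patterns; empty candidate set")
    return(empty_ase_candidates())
  }
  out <- list()
  for (g in dl$gene_id) {
    o <- origins[origins$gene_id == g, , drop = FALSE]
    if (nrow(o) == 0) next
    va <- annotated[!is.na(annotated$gene_id) & annotated$gene_id == g &
                    annotated$origin == "DONOR", , drop = FALSE]
    has_promoter <- any(va$region %in% PROMOTER_REGIONS)
    if (!(o$verdict == "DONOR" || (o$verdict == "MIXED" && has_promoter)))
      next
    coding_change <- any(va$coding_effect %in% CODING_ALTERING)
    up_indel <- va$region == "UPSTREAM" & va$variant_class != "SNV"
    p <- dl[dl$gene_id == g, ]
    out[[g]] <- data.frame(
      gene_id = g, verdict = o$verdict,
      n_donor_variants = o$n_donor_variants,
      n_promoter_variants = sum(va$region %in% PROMOTER_REGIONS),
      has_coding_change = coding_change,
      cis_flag = has_promoter && !coding_change,
      promoter_indel_length = if (any(up_indel))
        max(va$indel_length[up_indel]) else NA_integer_,
      lfc_offspring = p$lfc_offspring, lfc_donor = p$lfc_donor,
      padj_offspring = p$padj_offspring,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    message("donor-like patterns carry no donor-origin evidence; empty candidate set")
    return(empty_ase_candidates())
  }
  res <- do.call(rbind, out)
  res <- res[order(res$padj_offspring, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_ase_candidates <- function() {
  data.frame(gene_id = character(0), verdict = character(0),
             n_donor_variants = integer(0), n_promoter_variants = integer(0),
             has_coding_change = logical(0), cis_flag = logical(0),
             promoter_indel_length = integer(0), lfc_offspring = numeric(0),
             lfc_donor = numeric(0), padj_offspring = numeric(0),
             stringsAsFactors = FALSE)
}

#' Report the candidate cis-regulatory variants of one gene
#'
#' Lists every donor-origin variant of the gene with its region, class,
#' length and strand-aware distance to the ORF start (negative = upstream
#' of the CDS, in transcription direction).
#'
#' @param gene_id candidate gene.
#' @param annotated classified + annotated (site, gene) table.
#' @param index `gene_index`.
#' @return data frame of donor-origin variants with `distance_to_cds`.
#' @export
annotate_cis_variants <- function(gene_id, annotated, index) {
  g <- index$genes[match(gene_id, index$genes$gene_id), ]
  if (is.na(g$gene_id)) stop_input("gene %s not in index", gene_id)
  va <- annotated[!is.na(annotated$gene_id) & annotated$gene_id == gene_id &
                  annotated$origin == "DONOR", , drop = FALSE]
  pos <- effective_position(va)
  va$distance_to_cds <- if (g$strand == "+") pos - g$cds_start
                        else g$cds_end - pos
  va <- va[order(va$distance_to_cds), , drop = FALSE]
  rownames(va) <- NULL
  va
}
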