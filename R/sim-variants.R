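# Parent-distinguishing variant placement and trio VCF emission.
#
# Every emitted record is biallelic with three homozygous sample genotypes
# (offspring, donor, recurrent). A site is "distinguishing" when donor and
# recurrent carry different alleles; the offspring allele then follows the
# parental-origin label of its haplotype mosaic at that position, which is
# also the site's ground-truth origin label.

#' Configuration for simulated variant placement
#'
#' @param snv_rate SNVs per bp of gene evidence span (upstream window plus
#'   gene span).
#' @param indel_rate indels per bp of gene evidence span.
#' @param max_indel_len indel lengths are uniform on `1:max_indel_len`; the
#'   default 120 deliberately exceeds the 99-bp analysis filter so the
#'   filter is exercised.
#' @param strata_weights sampling weights for the upstream/UTR/intron/coding
#'   exon strata.
#' @param shared_fraction fraction of sites where both parents carry the
#'   alternate allele (non-polymorphic within the trio).
#' @param novel_fraction fraction of sites where only the offspring carries
#'   the alternate allele.
#' @param intergenic_rate variants per bp of intergenic gap.
#' @param dense if `TRUE`, additionally place a grid of distinguishing SNVs
#'   (every `dense_spacing` bp) across every gene evidence span, plus a
#'   flanking marker on each side of every mosaic breakpoint inside a span,
#'   so every gene origin is fully resolved by markers.
#' @param dense_spacing grid spacing for dense mode, bp.
#' @param cis_insertion_len length of the promoter insertion planted in the
#'   cis-marker gene (default 9 bp).
#' @param cis_upstream_offset distance of the planted insertion 5' of the
#'   ORF start (default 300 bp).
#' @return list of class `variant_placement_config`.
#' @export
variant_placement_config <- function(snv_rate = 0.0018, indel_rate = 8e-04,
                                     max_indel_len = 120,
                                     strata_weights = c(upstream = 0.45, utr = 0.15,
                                                        intron = 0.25, exon = 0.15),
                                     shared_fraction = 0.05, novel_fraction = 0.02,
                                     intergenic_rate = 4e-05,
                                     dense = FALSE, dense_spacing = 300,
                                     cis_insertion_len = 9,
                                     cis_upstream_offset = 300) {
  if (snv_rate < 0 || indel_rate < 0 || intergenic_rate < 0)
    stop_input("variant rates must be >= 0")
  if (max_indel_len < 1) stop_input("max_indel_len must be >= 1")
  structure(as.list(environment()), class = "variant_placement_config")
}

# per-gene stratum intervals (1-based inclusive), strand aware
gene_strata <- function(g, feats, upstream_len, chrom_len) {
  f <- feats[feats$gene_id == g$gene_id, , drop = FALSE]
  cds <- f[f$type == "CDS", c("start", "end"), drop = FALSE]
  utr <- f[f$type %in% c("five_prime_UTR", "three_prime_UTR"), c("start", "end"), drop = FALSE]
  if (g$strand == "+") {
    win <- c(max(1, g$cds_start - upstream_len), g$cds_start - 1)
    up <- c(win[1], min(win[2], g$start - 1))
  } else {
    win <- c(g$cds_end + 1, min(chrom_len, g$cds_end + upstream_len))
    up <- c(max(win[1], g$end + 1), win[2])
  }
  # introns: gene span minus exons
  ex <- f[f$type == "exon", c("start", "end"), drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  introns <- NULL
  if (nrow(ex) > 1)
    introns <- data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
  list(upstream = if (up[1] <= up[2]) data.frame(start = up[1], end = up[2]) else NULL,
       utr = utr, intron = introns, exon = cds,
       evid = c(min(win[1], g$start), max(win[2], g$end)))
}

sample_pos_in <- function(iv, n) {
  if (is.null(iv) || nrow(iv) == 0 || n == 0) return(integer(0))
  lens <- iv$end - iv$start + 1
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = lens)
  iv$start[pick] + floor(runif(n) * lens[pick])
}

#' Emit a simulated trio VCF with a ground-truth sidecar
#'
#' Places SNVs and indels in gene structural strata and intergenic gaps,
#' derives the three homozygous genotypes from the offspring haplotype
#' mosaic, and optionally writes a positionally sorted VCF v4.2 file. The
#' planted cis-marker gene receives a donor-only promoter insertion upstream
#' of its ORF and no coding-region variants.
#'
#' @param mosaic offspring haplotype mosaic (see [simulate_pedigree()]).
#' @param ann `sim_annotation` from [generate_annotation()].
#' @param placement [variant_placement_config()].
#' @param cis_gene gene_id of the planted cis-marker gene, or `NULL`.
#' @param vcf_path output VCF path, or `NULL` to skip writing.
#' @param sample_names VCF sample column names, named by role
#'   (offspring/donor/recurrent).
#' @return data frame of truth sites: coordinates, alleles, class, indel
#'   length, the three genotypes (`REF`/`ALT`), the true origin label, the
#'   territory gene (`NA` for intergenic) and the generator stratum.
#' @export
emit_trio_vcf <- function(mosaic, ann, placement = variant_placement_config(),
                          cis_gene = NULL, vcf_path = NULL,
                          sample_names = c(offspring = "offspring",
                                           donor = "donor",
                                           recurrent = "recurrent")) {
  specs <- ann$specs
  seqs <- ann$sequences
  rows <- list()
  add_site <- function(chrom, pos, class, indel_len, gene_id, stratum, polarity) {
    chrom_seq <- seqs[[chrom]]
    clen <- length(chrom_seq)
    if (pos < 1 || pos > clen) stop_input("variant position outside reference: %s:%d", chrom, pos)
    if (class == "SNV") {
      ref <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ilen <- 0L
    } else if (class == "INSERTION") {
      ref <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
      alt <- paste0(ref, random_dna(indel_len))
      ilen <- indel_len
    } else {
      indel_len <- min(indel_len, clen - pos)
      if (indel_len < 1) return(NULL)
      ref <- as.character(Biostrings::subseq(chrom_seq, pos, pos + indel_len))
      alt <- substr(ref, 1, 1)
      ilen <- indel_len
    }
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               variant_class = class, indel_length = ilen,
               gene_id = gene_id, stratum = stratum, polarity = polarity,
               stringsAsFactors = FALSE)
  }

  for (k in seq_len(nrow(ann$genes))) {
    g <- ann$genes[k, ]
    clen <- specs$length_bp[match(g$chrom, specs$name)]
    strata <- gene_strata(g, ann$features, ann$upstream_len, clen)
    evid_len <- strata$evid[2] - strata$evid[1] + 1
    n_snv <- rpois(1, evid_len * placement$snv_rate)
    n_ind <- rpois(1, evid_len * placement$indel_rate)
    is_cis <- !is.null(cis_gene) && g$gene_id == cis_gene
    w <- placement$strata_weights
    if (is_cis) w["exon"] <- 0  # coding part identical across genotypes
    avail <- !vapply(strata[names(w)], function(x) is.null(x) || nrow(x) == 0, logical(1))
    w[!avail] <- 0
    if (sum(w) == 0) next
    for (j in seq_len(n_snv + n_ind)) {
      stratum <- sample(names(w), 1, prob = w)
      pos <- sample_pos_in(strata[[stratum]], 1)
      # the cis gene's background markers stay SNV-only so the planted
      # promoter insertion is its single distinguishing indel
      class <- if (j <= n_snv || is_cis) "SNV"
               else sample(c("INSERTION", "DELETION"), 1)
      ilen <- if (class == "SNV") 0L else sample.int(placement$max_indel_len, 1)
      u <- runif(1)
      polarity <- if (u < placement$shared_fraction) "shared"
        else if (u < placement$shared_fraction + placement$novel_fraction) "novel"
        else sample(c("donor", "recurrent"), 1)
      rows[[length(rows) + 1]] <- add_site(g$chrom, pos, class, ilen,
                                           g$gene_id, stratum, polarity)
    }
    if (placement$dense) {
      grid <- seq(strata$evid[1], strata$evid[2], by = placement$dense_spacing)
      mseg <- mosaic[mosaic$chrom == g$chrom, , drop = FALSE]
      bp_inside <- mseg$start[mseg$start > strata$evid[1] - 1 &
                              mseg$start < strata$evid[2]]  # 0-based breakpoints
      flank <- c(bp_inside - 4, bp_inside + 5)  # 1-based positions either side
      for (pos in unique(c(grid, flank))) {
        if (pos < 1 || pos > clen) next
        rows[[length(rows) + 1]] <- add_site(g$chrom, as.integer(pos), "SNV", 0L,
                                             g$gene_id, "dense",
                                             sample(c("donor", "recurrent"), 1))
      }
    }
    if (is_cis) {
      pos <- if (g$strand == "+") g$cds_start - placement$cis_upstream_offset
             else g$cds_end + placement$cis_upstream_offset
      cis_row <- add_site(g$chrom, pos, "INSERTION",
                          placement$cis_insertion_len,
                          g$gene_id, "upstream", "donor")
      cis_row$prio <- 1L
      rows[[length(rows) + 1]] <- cis_row
    }
  }
  # intergenic sites in the gaps between gene territories
  for (i in seq_len(nrow(specs))) {
    chrom <- specs$name[i]
    terr <- ann$genes[ann$genes$chrom == chrom, c("territory_start", "territory_end")]
    terr <- terr[order(terr$territory_start), , drop = FALSE]
    bounds <- c(1, as.vector(t(as.matrix(terr))), specs$length_bp[i])
    gaps <- matrix(bounds, ncol = 2, byrow = TRUE)
    gaps <- data.frame(start = gaps[, 1], end = gaps[, 2])
    gaps <- gaps[gaps$end > gaps$start + 1, , drop = FALSE]
    gaps$start <- gaps$start + 1; gaps$end <- gaps$end - 1
    n <- rpois(1, sum(gaps$end - gaps$start + 1) * placement$intergenic_rate)
    for (pos in sample_pos_in(gaps, n)) {
      class <- sample(c("SNV", "INSERTION", "DELETION"), 1, prob = c(0.7, 0.15, 0.15))
      ilen <- if (class == "SNV") 0L else sample.int(placement$max_indel_len, 1)
      rows[[length(rows) + 1]] <- add_site(chrom, pos, class, ilen, NA_character_,
                                           "intergenic",
                                           sample(c("donor", "recurrent"), 1))
    }
  }
  rows <- lapply(rows, function(r) {
    if (is.null(r)) return(NULL)
    if (is.null(r$prio)) r$prio <- 2L
    r
  })
  sites <- do.call(rbind, rows)
  # positional sort; the planted cis insertion wins any position collision
  sites <- sites[order(match(sites$chrom, specs$name), sites$pos, sites$prio), , drop = FALSE]
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), , drop = FALSE]
  sites$prio <- NULL
  rownames(sites) <- NULL

  # genotypes and truth origin from the mosaic
  lab <- mosaic_label_at(mosaic, sites$chrom, sites$pos - 1L)
  gt <- function(polarity, role) {
    switch(role,
      donor = ifelse(polarity == "donor" | polarity == "shared", "ALT", "REF"),
      recurrent = ifelse(polarity == "recurrent" | polarity == "shared", "ALT", "REF"))
  }
  sites$gt_donor <- gt(sites$polarity, "donor")
  sites$gt_recurrent <- gt(sites$polarity, "recurrent")
  sites$gt_offspring <- ifelse(sites$polarity == "shared", "ALT",
                        ifelse(sites$polarity == "novel", "ALT",
                        ifelse(lab == "DONOR", sites$gt_donor, sites$gt_recurrent)))
  sites$origin <- ifelse(sites$polarity == "shared", "NON_POLYMORPHIC",
                  ifelse(sites$polarity == "novel", "NOVEL", lab))
  sites$polarity <- NULL

  if (!is.null(vcf_path)) write_trio_vcf(sites, specs, vcf_path, sample_names)
  sites
}

# write sites as a VCF v4.2 with three homozygous GT sample columns
write_trio_vcf <- function(sites, specs, path, sample_names) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=introtrace_sim",
           sprintf("##contig=<ID=%s,length=%d>", specs$name, specs$length_bp),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   sample_names[["offspring"]], sample_names[["donor"]],
                   sample_names[["recurrent"]]), collapse = "\t"))
  gt_str <- function(g) ifelse(g == "ALT", "1/1", "0/0")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s\t%s\t%s",
                  sites$chrom, sites$pos, sites$ref, sites$alt,
                  gt_str(sites$gt_offspring), gt_str(sites$gt_donor),
                  gt_str(sites$gt_recurrent))
  writeLines(c(hdr, body), path)
  invisible(path)
}
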