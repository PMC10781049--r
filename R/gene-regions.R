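# Gene structural parts, variant-to-region assignment and coding effects.
#
# Variant handling stays in VCF coordinates (1-based inclusive); conversion
# to IRanges only happens inside this module's interval queries.

REGION_RANK <- c(EXON = 1, UTR5 = 2, UTR3 = 2, INTRON = 3, UPSTREAM = 4)

#' Build a queryable index of gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS/UTR features, resolves the feature hierarchy,
#' computes strand-aware upstream promoter windows anchored at the ORF
#' (CDS) start and clipped at contig boundaries, and reads the
#' `mobile_element` / `unknown_protein` gene attributes. Genes whose total
#' CDS length is not divisible by 3 are flagged malformed (kept in the
#' index, excluded from coding-effect calls) with a warning.
#'
#' @param gff path to a GFF3 file (or a `GRanges` as returned by
#'   [rtracklayer::import()]).
#' @param seqlengths optional named vector of contig lengths for clipping
#'   upstream windows on the 3' side; taken from the GFF3
#'   `##sequence-region` pragmas when present.
#' @param upstream_len promoter window length, bp (default 1000).
#' @return object of class `gene_index`: gene table (span, CDS bounds,
#'   flags, upstream window) and internal interval sets for region queries.
#' @export
build_gene_index <- function(gff, seqlengths = NULL, upstream_len = 1000) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  if (is.null(seqlengths)) {
    sl <- seqlengths(gr)
    if (!all(is.na(sl))) seqlengths <- sl
  }
  d <- as.data.frame(gr, stringsAsFactors = FALSE)
  d$seqnames <- as.character(d$seqnames)
  d$strand <- as.character(d$strand)
  d$type <- as.character(d$type)
  flag_col <- function(nm) {
    if (!nm %in% names(d)) return(rep(FALSE, nrow(d)))
    tolower(as.character(d[[nm]])) %in% c("true", "1", "yes")
  }
  g <- d[d$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) stop_input("no gene features in annotation")
  genes <- data.frame(gene_id = as.character(g$ID),
                      chrom = g$seqnames, strand = g$strand,
                      start = g$start, end = g$end,
                      mobile_element = flag_col("mobile_element")[d$type == "gene"],
                      unknown_protein = flag_col("unknown_protein")[d$type == "gene"],
                      stringsAsFactors = FALSE)
  # child features are tied to genes through their mRNA parent
  mrna <- d[d$type == "mRNA", , drop = FALSE]
  mrna_parent <- setNames(as.character(unlist(mrna$Parent)), as.character(mrna$ID))
  feat <- d[d$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ,
            drop = FALSE]
  fparent <- as.character(vapply(feat$Parent, function(p) p[1], ""))
  feat$gene_id <- ifelse(fparent %in% names(mrna_parent),
                         mrna_parent[fparent], fparent)
  features <- data.frame(gene_id = feat$gene_id, chrom = feat$seqnames,
                         type = feat$type, start = feat$start, end = feat$end,
                         strand = feat$strand, stringsAsFactors = FALSE)
  cds <- features[features$type == "CDS", , drop = FALSE]
  cds_len <- tapply(cds$end - cds$start + 1, cds$gene_id, sum)
  genes$cds_start <- tapply(cds$start, cds$gene_id, min)[genes$gene_id]
  genes$cds_end <- tapply(cds$end, cds$gene_id, max)[genes$gene_id]
  genes$malformed <- FALSE
  has_cds <- !is.na(genes$cds_start)
  bad <- has_cds & (cds_len[genes$gene_id] %% 3 != 0)
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("%d gene(s) with CDS length not divisible by 3 flagged malformed",
                    sum(bad, na.rm = TRUE)))
    genes$malformed[which(bad)] <- TRUE
  }
  # strand-aware upstream windows anchored at the ORF start
  up_start <- ifelse(genes$strand == "+",
                     pmax(1, genes$cds_start - upstream_len),
                     genes$cds_end + 1)
  up_end <- ifelse(genes$strand == "+",
                   genes$cds_start - 1,
                   genes$cds_end + upstream_len)
  if (!is.null(seqlengths)) {
    cl <- seqlengths[genes$chrom]
    up_end <- pmin(up_end, ifelse(is.na(cl), up_end, cl))
  }
  genes$upstream_start <- as.integer(up_start)
  genes$upstream_end <- as.integer(up_end)
  mk <- function(df) GRanges(df$chrom, IRanges(df$start, df$end),
                             gene_id = df$gene_id)
  empty_ok <- function(df) if (nrow(df) == 0)
    GRanges(gene_id = character(0)) else mk(df)
  utr5 <- features[features$type == "five_prime_UTR", , drop = FALSE]
  utr3 <- features[features$type == "three_prime_UTR", , drop = FALSE]
  valid_up <- !is.na(up_start) & up_start <= up_end
  ranges <- list(
    EXON = empty_ok(cds),
    UTR5 = empty_ok(utr5),
    UTR3 = empty_ok(utr3),
    GENE = mk(genes),
    UPSTREAM = empty_ok(data.frame(chrom = genes$chrom,
                                   start = up_start, end = up_end,
                                   gene_id = genes$gene_id)[valid_up, ]))
  structure(list(genes = genes, features = features, ranges = ranges,
                 upstream_len = upstream_len, seqlengths = seqlengths),
            class = "gene_index")
}

#' Remove mobile-element and unknown-protein genes from an index
#'
#' @param index `gene_index`.
#' @param quiet suppress the removal-count message.
#' @return filtered `gene_index`.
#' @export
gene_filter <- function(index, quiet = FALSE) {
  drop <- index$genes$mobile_element | index$genes$unknown_protein
  if (!quiet && any(drop))
    message(sprintf("gene_filter: removed %d of %d genes (%d mobile-element, %d unknown-protein)",
                    sum(drop), nrow(index$genes),
                    sum(index$genes$mobile_element),
                    sum(index$genes$unknown_protein)))
  keep_ids <- index$genes$gene_id[!drop]
  index$genes <- index$genes[!drop, , drop = FALSE]
  index$features <- index$features[index$features$gene_id %in% keep_ids, , drop = FALSE]
  index$ranges <- lapply(index$ranges, function(r) r[mcols(r)$gene_id %in% keep_ids])
  rownames(index$genes) <- NULL
  index
}

# leftmost affected reference base: SNVs and insertions anchor at POS,
# deletions at POS + 1 (the first deleted base)
effective_position <- function(sites) {
  sites$pos + as.integer(sites$variant_class == "DELETION")
}

#' Assign variant sites to gene structural parts
#'
#' Each (site, overlapping gene) pair receives one primary label by the
#' precedence coding exon > UTR > intron > upstream window; sites
#' overlapping no gene or window are `INTERGENIC`. A site may appear once
#' per overlapping gene. The `EXON` label means the coding (CDS) part of an
#' exon; exonic UTR sequence is labelled `UTR5`/`UTR3`.
#'
#' @param sites site table ([read_trio_vcf()]), any extra columns are kept.
#' @param index `gene_index`.
#' @return data frame with one row per (site, gene) pair: all site columns
#'   plus `gene_id` (`NA` for intergenic) and `region`.
#' @export
assign_region <- function(sites, index) {
  if (nrow(sites) == 0)
    return(cbind(sites, gene_id = character(0), region = character(0)))
  q <- GRanges(sites$chrom, IRanges(effective_position(sites), width = 1))
  pairs <- list()
  for (lab in c("EXON", "UTR5", "UTR3", "GENE", "UPSTREAM")) {
    hits <- findOverlaps(q, index$ranges[[lab]])
    if (length(hits) == 0) next
    region <- if (lab == "GENE") "INTRON" else lab
    pairs[[lab]] <- data.frame(
      site = queryHits(hits),
      gene_id = mcols(index$ranges[[lab]])$gene_id[subjectHits(hits)],
      region = region, rank = REGION_RANK[[region]],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    out <- sites
    out$gene_id <- NA_character_
    out$region <- "INTERGENIC"
    return(out)
  }
  pairs <- pairs[order(pairs$site, pairs$gene_id, pairs$rank), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("site", "gene_id")]), , drop = FALSE]
  orphan <- setdiff(seq_len(nrow(sites)), unique(pairs$site))
  if (length(orphan) > 0)
    pairs <- rbind(pairs, data.frame(site = orphan, gene_id = NA_character_,
                                     region = "INTERGENIC", rank = 5))
  pairs <- pairs[order(pairs$site, pairs$gene_id, na.last = TRUE), , drop = FALSE]
  out <- cbind(sites[pairs$site, , drop = FALSE],
               pairs[, c("gene_id", "region")])
  rownames(out) <- NULL
  out
}

# stranded CDS sequence of one gene (transcript orientation)
gene_cds_seq <- function(gene_id, index, genome) {
  f <- index$features
  cds <- f[f$gene_id == gene_id & f$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  chrom_seq <- genome[[cds$chrom[1]]]
  s <- paste(vapply(seq_len(nrow(cds)), function(k)
    as.character(Biostrings::subseq(chrom_seq, cds$start[k], cds$end[k])),
    character(1)), collapse = "")
  if (index$genes$strand[match(gene_id, index$genes$gene_id)] == "-")
    s <- revcomp_chr(s)
  s
}

#' Call coding effects for variants assigned to coding exons
#'
#' SNVs inside a CDS are translated through the standard genetic code
#' (strand-aware) and classified `SYNONYMOUS` or `NONSYNONYMOUS`; CDS
#' indels are `INFRAME_INDEL` when their length is a multiple of 3 and
#' `FRAMESHIFT` otherwise. Every other (site, gene) pair — and any variant
#' in a malformed gene model — is `NONCODING`.
#'
#' @param annotated output of [assign_region()].
#' @param index `gene_index`.
#' @param genome reference as a [Biostrings::DNAStringSet] (or FASTA path).
#' @return `annotated` with a `coding_effect` column appended.
#' @export
coding_effect <- function(annotated, index, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  code <- Biostrings::GENETIC_CODE
  eff <- rep("NONCODING", nrow(annotated))
  malformed <- index$genes$gene_id[index$genes$malformed]
  in_cds <- which(annotated$region == "EXON" &
                  !(annotated$gene_id %in% malformed))
  # reference concordance check for all sites
  if (nrow(annotated) > 0) {
    for (i in seq_len(nrow(annotated))) {
      chrom <- annotated$chrom[i]
      if (!chrom %in% names(genome))
        stop_input("chromosome %s absent from reference", chrom)
      ref <- annotated$ref[i]
      seen <- as.character(Biostrings::subseq(genome[[chrom]],
                                              annotated$pos[i],
                                              annotated$pos[i] + nchar(ref) - 1))
      if (seen != ref)
        stop_input("reference mismatch at %s:%d (VCF %s, FASTA %s)",
                   chrom, annotated$pos[i], ref, seen)
    }
  }
  indel <- in_cds[annotated$variant_class[in_cds] != "SNV"]
  eff[indel] <- ifelse(annotated$indel_length[indel] %% 3 == 0,
                       "INFRAME_INDEL", "FRAMESHIFT")
  snv <- in_cds[annotated$variant_class[in_cds] == "SNV"]
  if (length(snv) > 0) {
    cds_cache <- new.env()
    for (i in snv) {
      gid <- annotated$gene_id[i]
      g <- index$genes[match(gid, index$genes$gene_id), ]
      if (!gid %in% ls(cds_cache))
        assign(gid, gene_cds_seq(gid, index, genome), envir = cds_cache)
      cds_seq <- get(gid, envir = cds_cache)
      f <- index$features
      cds <- f[f$gene_id == gid & f$type == "CDS", , drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      before <- cumsum(c(0, cds$end - cds$start + 1))
      k <- which(annotated$pos[i] >= cds$start & annotated$pos[i] <= cds$end)[1]
      off_plus <- before[k] + (annotated$pos[i] - cds$start[k]) + 1
      local <- if (g$strand == "+") off_plus else nchar(cds_seq) - off_plus + 1
      ci <- (local - 1) %/% 3
      pos_in_codon <- local - 3 * ci
      codon <- substr(cds_seq, 3 * ci + 1, 3 * ci + 3)
      alt_base <- if (g$strand == "+") annotated$alt[i] else comp_base(annotated$alt[i])
      mutated <- codon
      substr(mutated, pos_in_codon, pos_in_codon) <- alt_base
      eff[i] <- if (code[[codon]] == code[[mutated]]) "SYNONYMOUS" else "NONSYNONYMOUS"
    }
  }
  annotated$coding_effect <- eff
  annotated
}

#' Annotate classified sites with regions and coding effects
#'
#' Convenience wrapper: [assign_region()] followed by [coding_effect()]
#' when a reference is supplied.
#'
#' @param sites classified site table.
#' @param index `gene_index`.
#' @param genome optional reference ([Biostrings::DNAStringSet] or path).
#' @return annotated (site, gene) table.
#' @export
annotate_variants <- function(sites, index, genome = NULL) {
  ann <- assign_region(sites, index)
  if (!is.null(genome)) ann <- coding_effect(ann, index, genome)
  else ann$coding_effect <- NA_character_
  ann
}

#' @export
print.gene_index <- function(x, ...) {
  cat(sprintf("Gene index: %d genes (%d mobile-element, %d unknown-protein, %d malformed), upstream window %d bp\n",
              nrow(x$genes), sum(x$genes$mobile_element),
              sum(x$genes$unknown_protein), sum(x$genes$malformed),
              x$upstream_len))
  invisible(x)
}
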