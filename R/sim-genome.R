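# Synthetic gene annotation + reference sequence.
#
# Genes are laid out in non-overlapping "territories" (gene span plus the
# upstream promoter window on both sides, so strand choice never causes
# territory overlap). Each gene has 5'/3' UTRs, 1-4 coding exons with
# introns, a CDS whose length is divisible by 3 with a valid start and stop
# codon, and boolean flags for mobile-element and unknown-protein status.
# Coordinates are 1-based inclusive, GFF3-style.

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0)), c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

# structural draw for one gene on the + template (local 1-based coords)
draw_gene_structure <- function() {
  n_codons <- sample(60:300, 1)
  n_exons <- sample(1:4, 1)
  utr5 <- sample(80:200, 1)
  utr3 <- sample(80:250, 1)
  introns <- if (n_exons > 1) sample(80:300, n_exons - 1, replace = TRUE) else integer(0)
  codon_cuts <- if (n_exons > 1) sort(sample(seq_len(n_codons - 1), n_exons - 1)) else integer(0)
  cds_parts <- diff(c(0, codon_cuts, n_codons)) * 3
  list(n_codons = n_codons, n_exons = n_exons, utr5 = utr5, utr3 = utr3,
       introns = introns, cds_parts = cds_parts,
       gene_len = utr5 + sum(cds_parts) + sum(introns) + utr3)
}

# local feature intervals for the + template; reflected later for - strand
layout_gene <- function(st) {
  cur <- 1
  utr5 <- c(1, st$utr5)
  cds <- matrix(0, nrow = st$n_exons, ncol = 2)
  cur <- st$utr5 + 1
  for (k in seq_len(st$n_exons)) {
    cds[k, ] <- c(cur, cur + st$cds_parts[k] - 1)
    cur <- cds[k, 2] + 1
    if (k < st$n_exons) cur <- cur + st$introns[k]
  }
  utr3 <- c(cur, cur + st$utr3 - 1)
  # exons: first = utr5+cds1, internal = cds parts, last = cds_last+utr3
  ex <- cds
  ex[1, 1] <- utr5[1]
  ex[st$n_exons, 2] <- utr3[2]
  if (st$n_exons == 1) ex <- matrix(c(utr5[1], utr3[2]), 1)
  list(utr5 = utr5, utr3 = utr3, cds = cds, exons = ex)
}

reflect_intervals <- function(iv, gene_len) {
  out <- cbind(gene_len - iv[, 2] + 1, gene_len - iv[, 1] + 1)
  out[order(out[, 1]), , drop = FALSE]
}

#' Generate a synthetic gene annotation and matching reference sequence
#'
#' @param specs chromosome spec ([chromosome_spec()]).
#' @param n_genes total gene count, distributed across chromosomes in
#'   proportion to physical length (default 210).
#' @param te_fraction fraction of genes flagged as mobile elements.
#' @param unknown_fraction fraction flagged as encoding unknown proteins
#'   (disjoint from the mobile-element set).
#' @param upstream_len promoter window length reserved on both sides of each
#'   gene so windows never overlap a neighbour (default 1000 bp).
#' @return object of class `sim_annotation`: list with `genes` (one row per
#'   gene: span, strand, CDS bounds, territory bounds, flags), `features`
#'   (long table of exon/CDS/UTR intervals), `sequences` (a
#'   [Biostrings::DNAStringSet] with the CDS bases consistent with the
#'   annotated coordinates and strand), and `upstream_len`.
#' @export
generate_annotation <- function(specs = default_chromosomes(), n_genes = 210,
                                te_fraction = 0.15, unknown_fraction = 0.10,
                                upstream_len = 1000) {
  if (te_fraction + unknown_fraction > 1)
    stop_input("flag fractions sum to more than 1")
  per_chrom <- pmax(1L, as.integer(round(n_genes * specs$length_bp / sum(specs$length_bp))))
  genes <- list(); feats <- list(); seqs <- setNames(vector("list", nrow(specs)), specs$name)
  gid <- 0
  for (i in seq_len(nrow(specs))) {
    chrom <- specs$name[i]
    len <- specs$length_bp[i]
    codes <- sample(c(65L, 67L, 71L, 84L), len, replace = TRUE)  # ACGT
    cursor <- upstream_len + sample(200:800, 1)
    for (g in seq_len(per_chrom[i])) {
      st <- draw_gene_structure()
      gstart <- cursor + 1
      gend <- gstart + st$gene_len - 1
      if (gend + upstream_len + 200 > len) break
      gid <- gid + 1
      gene_id <- sprintf("gene%04d", gid)
      strand <- sample(c("+", "-"), 1)
      lay <- layout_gene(st)
      loc <- list(utr5 = matrix(lay$utr5, 1), utr3 = matrix(lay$utr3, 1),
                  cds = lay$cds, exons = lay$exons)
      if (strand == "-") {
        loc <- list(utr5 = reflect_intervals(matrix(lay$utr5, 1), st$gene_len),
                    utr3 = reflect_intervals(matrix(lay$utr3, 1), st$gene_len),
                    cds = reflect_intervals(lay$cds, st$gene_len),
                    exons = reflect_intervals(lay$exons, st$gene_len))
      }
      abs_iv <- function(m) cbind(m[, 1] + gstart - 1, m[, 2] + gstart - 1)
      cds_iv <- abs_iv(loc$cds)
      if (nrow(cds_iv) > 1 && any(cds_iv[-1, 1] <= cds_iv[-nrow(cds_iv), 2]))
        stop_input("overlapping CDS generated for %s", gene_id)
      # coding sequence: ATG + sense codons + stop, written strand-aware
      cds_seq <- paste0("ATG",
                        paste(sample(SENSE_CODONS, st$n_codons - 2, replace = TRUE),
                              collapse = ""),
                        sample(STOP_CODONS, 1))
      pos <- unlist(lapply(seq_len(nrow(cds_iv)), function(k) cds_iv[k, 1]:cds_iv[k, 2]))
      placed <- if (strand == "+") cds_seq else revcomp_chr(cds_seq)
      codes[pos] <- utf8ToInt(placed)
      genes[[gid]] <- data.frame(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = gstart, end = gend,
        cds_start = min(cds_iv[, 1]), cds_end = max(cds_iv[, 2]),
        territory_start = max(1L, gstart - upstream_len),
        territory_end = min(len, gend + upstream_len),
        mobile_element = FALSE, unknown_protein = FALSE,
        stringsAsFactors = FALSE)
      add_feat <- function(type, m) data.frame(
        gene_id = gene_id, chrom = chrom, type = type,
        start = m[, 1] + gstart - 1, end = m[, 2] + gstart - 1,
        strand = strand, stringsAsFactors = FALSE)
      feats[[gid]] <- rbind(add_feat("exon", loc$exons),
                            add_feat("CDS", loc$cds),
                            add_feat("five_prime_UTR", loc$utr5),
                            add_feat("three_prime_UTR", loc$utr3))
      # reserve the promoter window on both flanks so neighbouring gene
      # territories never touch
      cursor <- gend + 2 * upstream_len + sample(500:1500, 1)
    }
    seqs[[chrom]] <- intToUtf8(codes)
  }
  genes <- do.call(rbind, genes)
  feats <- do.call(rbind, feats)
  rownames(genes) <- rownames(feats) <- NULL
  n <- nrow(genes)
  n_te <- round(te_fraction * n)
  n_unk <- round(unknown_fraction * n)
  flagged <- sample(n, n_te + n_unk)
  genes$mobile_element[flagged[seq_len(n_te)]] <- TRUE
  if (n_unk > 0) genes$unknown_protein[flagged[n_te + seq_len(n_unk)]] <- TRUE
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- specs$name
  structure(list(genes = genes, features = feats, sequences = ss,
                 upstream_len = upstream_len, specs = specs),
            class = "sim_annotation")
}

# CDS phase column for GFF3, strand-aware
cds_phases <- function(iv, strand) {
  ord <- if (strand == "+") order(iv[, 1]) else order(-iv[, 1])
  lens <- iv[ord, 2] - iv[ord, 1] + 1
  before <- cumsum(c(0, lens[-length(lens)]))
  ph <- (3 - before %% 3) %% 3
  ph[order(ord)]
}

#' Write a simulated annotation as GFF3 and FASTA
#'
#' @param ann `sim_annotation` from [generate_annotation()].
#' @param gff_path,fasta_path output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_annotation <- function(ann, gff_path = NULL, fasta_path = NULL) {
  if (!is.null(gff_path)) {
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", ann$specs$name, ann$specs$length_bp))
    for (k in seq_len(nrow(ann$genes))) {
      g <- ann$genes[k, ]
      f <- ann$features[ann$features$gene_id == g$gene_id, , drop = FALSE]
      row9 <- function(type, start, end, phase, attrs)
        sprintf("%s\tintrotrace_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                g$chrom, type, start, end, g$strand, phase, attrs)
      lines <- c(lines,
        row9("gene", g$start, g$end, ".",
             sprintf("ID=%s;mobile_element=%s;unknown_protein=%s", g$gene_id,
                     tolower(g$mobile_element), tolower(g$unknown_protein))),
        row9("mRNA", g$start, g$end, ".",
             sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id)))
      for (type in c("exon", "five_prime_UTR", "three_prime_UTR")) {
        fi <- f[f$type == type, , drop = FALSE]
        for (j in seq_len(nrow(fi)))
          lines <- c(lines, row9(type, fi$start[j], fi$end[j], ".",
                                 sprintf("Parent=%s.t1", g$gene_id)))
      }
      ci <- f[f$type == "CDS", , drop = FALSE]
      ph <- cds_phases(cbind(ci$start, ci$end), g$strand)
      for (j in seq_len(nrow(ci)))
        lines <- c(lines, row9("CDS", ci$start[j], ci$end[j],
                               as.character(ph[j]),
                               sprintf("ID=%s.t1.cds;Parent=%s.t1", g$gene_id, g$gene_id)))
    }
    writeLines(lines, gff_path)
  }
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(ann$sequences, fasta_path, width = 70)
  invisible(list(gff = gff_path, fasta = fasta_path))
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat(sprintf("Synthetic annotation: %d genes on %d chromosomes (%d flagged TE, %d unknown-protein)\n",
              nrow(x$genes), nrow(x$specs), sum(x$genes$mobile_element),
              sum(x$genes$unknown_protein)))
  invisible(x)
}
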