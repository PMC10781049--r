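# Shared fixtures, generated in code.

tiny_specs <- function(n = 2, len = 2e5, cM = 60) {
  chromosome_spec(paste0("chr", seq_len(n)), rep(len, n), rep(cM, n))
}

# small but complete simulated study for unit tests
tiny_study <- function(seed = 101, dense = FALSE, with_counts = TRUE, ...) {
  simulate_trio_study(
    seed = seed,
    specs = tiny_specs(),
    n_genes = 40,
    placement = variant_placement_config(dense = dense),
    expression = if (with_counts) expression_sim_config() else NULL,
    ...)
}

# hand-written two-gene annotation (one per strand) with known coordinates,
# written as GFF3 + FASTA into tempfiles; sequence carries designed codons
# so coding effects are predictable
handmade_annotation <- function(dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # gene A (+ strand): UTR5 4001..4100, CDS 4101..4400 (100 codons),
  #   intron 4401..4500, CDS2 4501..4511 absent -> single CDS; UTR3 4401..4500
  # keep it single-exon for clarity
  # gene B (- strand): on same chromosome further right
  len <- 20000L
  codes <- sample(c(65L, 67L, 71L, 84L), len, replace = TRUE)
  sense <- setdiff(as.vector(outer(as.vector(outer(c("T","C","A","G"),
            c("T","C","A","G"), paste0)), c("T","C","A","G"), paste0)),
            c("TAA","TAG","TGA"))
  cdsA <- paste0("ATG", paste(sample(sense, 98, TRUE), collapse = ""), "TAA")
  codes[4101:4400] <- utf8ToInt(cdsA)
  cdsB <- paste0("ATG", paste(sample(sense, 58, TRUE), collapse = ""), "TGA")
  # gene B CDS occupies 12001..12180 on the minus strand
  codes[12001:12180] <- utf8ToInt(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cdsB))))
  seq <- Biostrings::DNAStringSet(setNames(intToUtf8(codes), "chrT"))
  fasta <- file.path(dir, "ref.fasta")
  Biostrings::writeXStringSet(seq, fasta)
  gff <- file.path(dir, "ann.gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region chrT 1 %d", len),
    "chrT\tt\tgene\t4001\t4500\t.\t+\t.\tID=geneA;mobile_element=false;unknown_protein=false",
    "chrT\tt\tmRNA\t4001\t4500\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chrT\tt\texon\t4001\t4500\t.\t+\t.\tParent=geneA.t1",
    "chrT\tt\tfive_prime_UTR\t4001\t4100\t.\t+\t.\tParent=geneA.t1",
    "chrT\tt\tCDS\t4101\t4400\t.\t+\t0\tParent=geneA.t1",
    "chrT\tt\tthree_prime_UTR\t4401\t4500\t.\t+\t.\tParent=geneA.t1",
    "chrT\tt\tgene\t11901\t12280\t.\t-\t.\tID=geneB;mobile_element=false;unknown_protein=false",
    "chrT\tt\tmRNA\t11901\t12280\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "chrT\tt\texon\t11901\t12280\t.\t-\t.\tParent=geneB.t1",
    "chrT\tt\tthree_prime_UTR\t11901\t12000\t.\t-\t.\tParent=geneB.t1",
    "chrT\tt\tCDS\t12001\t12180\t.\t-\t0\tParent=geneB.t1",
    "chrT\tt\tfive_prime_UTR\t12181\t12280\t.\t-\t.\tParent=geneB.t1"),
    gff)
  list(gff = gff, fasta = fasta, seq = seq, cdsA = cdsA, cdsB = cdsB,
       cdsA_iv = c(4101L, 4400L), cdsB_iv = c(12001L, 12180L))
}

# write a minimal VCF from a site description data frame
write_mini_vcf <- function(df, path,
                           samples = c("offspring", "donor", "recurrent"),
                           contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s\t%s\t%s",
                  df$chrom, df$pos, df$ref, df$alt, df$gt1, df$gt2, df$gt3)
  writeLines(c(hdr, body), path)
  path
}
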