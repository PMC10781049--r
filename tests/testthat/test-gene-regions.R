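# Region assignment and coding-effect calls.

test_that("upstream windows anchor at the ORF start, strand-aware, clipped", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrU 1 10000",
    "chrU\tt\tgene\t4900\t6000\t.\t+\t.\tID=gP",
    "chrU\tt\tmRNA\t4900\t6000\t.\t+\t.\tID=gP.t1;Parent=gP",
    "chrU\tt\texon\t4900\t6000\t.\t+\t.\tParent=gP.t1",
    "chrU\tt\tCDS\t5000\t5899\t.\t+\t0\tParent=gP.t1",
    "chrU\tt\tgene\t3000\t5000\t.\t-\t.\tID=gM",
    "chrU\tt\tmRNA\t3000\t5000\t.\t-\t.\tID=gM.t1;Parent=gM",
    "chrU\tt\texon\t3000\t5000\t.\t-\t.\tParent=gM.t1",
    "chrU\tt\tCDS\t3100\t5000\t.\t-\t0\tParent=gM.t1",
    "chrU\tt\tgene\t300\t900\t.\t+\t.\tID=gC",
    "chrU\tt\tmRNA\t300\t900\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chrU\tt\texon\t300\t900\t.\t+\t.\tParent=gC.t1",
    "chrU\tt\tCDS\t400\t900\t.\t+\t0\tParent=gC.t1"),
    file.path(dir, "up.gff3"))
  idx <- suppressWarnings(build_gene_index(file.path(dir, "up.gff3")))
  g <- idx$genes
  expect_equal(unname(unlist(g[g$gene_id == "gP", c("upstream_start", "upstream_end")])),
               c(4000L, 4999L))
  expect_equal(unname(unlist(g[g$gene_id == "gM", c("upstream_start", "upstream_end")])),
               c(5001L, 6000L))
  expect_equal(unname(unlist(g[g$gene_id == "gC", c("upstream_start", "upstream_end")])),
               c(1L, 399L))
})

test_that("region precedence resolves CDS > UTR > intron > upstream", {
  h <- handmade_annotation()
  idx <- build_gene_index(h$gff)
  mk <- function(pos) data.frame(chrom = "chrT", pos = pos, ref = "A",
                                 alt = "G", variant_class = "SNV",
                                 indel_length = 0L, stringsAsFactors = FALSE)
  sites <- mk(c(4200L,   # in CDS of geneA
                4050L,   # 5' UTR of geneA
                4450L,   # 3' UTR of geneA
                3500L,   # upstream window of geneA (+)
                12250L,  # 5' UTR of geneB (-)
                12500L,  # upstream window of geneB (-)
                800L))   # intergenic
  ann <- assign_region(sites, idx)
  expect_equal(ann$region,
               c("EXON", "UTR5", "UTR3", "UPSTREAM", "UTR5", "UPSTREAM",
                 "INTERGENIC"))
  expect_equal(ann$gene_id[1:6], c(rep("geneA", 4), rep("geneB", 2)))
  expect_true(is.na(ann$gene_id[7]))
})

test_that("deletions are assigned by their leftmost affected base", {
  h <- handmade_annotation()
  idx <- build_gene_index(h$gff)
  # deletion record anchored at 4100 (last UTR5 base), deleting 4101..4103:
  # the first deleted base is in the CDS
  site <- data.frame(chrom = "chrT", pos = 4100L, ref = "NNNN", alt = "N",
                     variant_class = "DELETION", indel_length = 3L,
                     stringsAsFactors = FALSE)
  expect_equal(assign_region(site, idx)$region, "EXON")
})

test_that("region labels agree with a brute-force quadratic scan", {
  study <- tiny_study(seed = 51, with_counts = FALSE)
  dir <- withr::local_tempdir()
  write_annotation(study$annotation, file.path(dir, "s.gff3"))
  idx <- build_gene_index(file.path(dir, "s.gff3"))
  sites <- study$sites
  got <- assign_region(sites, idx)
  got_key <- paste(got$chrom, got$pos, got$gene_id, got$region)
  # independent scan: for every site x gene, derive the label from the raw
  # feature table by interval arithmetic
  feats <- study$annotation$features
  genes <- idx$genes
  want <- character(0)
  for (i in seq_len(nrow(sites))) {
    pos <- sites$pos[i] + (sites$variant_class[i] == "DELETION")
    hit <- FALSE
    for (k in seq_len(nrow(genes))) {
      g <- genes[k, ]
      if (g$chrom != sites$chrom[i]) next
      f <- feats[feats$gene_id == g$gene_id, ]
      lab <- NULL
      inside <- function(type) any(pos >= f$start[f$type == type] &
                                   pos <= f$end[f$type == type])
      if (inside("CDS")) lab <- "EXON"
      else if (inside("five_prime_UTR")) lab <- "UTR5"
      else if (inside("three_prime_UTR")) lab <- "UTR3"
      else if (pos >= g$start && pos <= g$end) lab <- "INTRON"
      else if (pos >= g$upstream_start && pos <= g$upstream_end) lab <- "UPSTREAM"
      if (!is.null(lab)) {
        want <- c(want, paste(sites$chrom[i], sites$pos[i], g$gene_id, lab))
        hit <- TRUE
      }
    }
    if (!hit) want <- c(want, paste(sites$chrom[i], sites$pos[i], NA, "INTERGENIC"))
  }
  expect_setequal(got_key, want)
  expect_equal(length(got_key), length(want))
})

test_that("SNV coding effects follow the genetic code on both strands", {
  h <- handmade_annotation()
  idx <- build_gene_index(h$gff)
  genome <- h$seq
  # + strand gene A: codon 2 occupies 4104..4106 (transcript order)
  codon2 <- substr(h$cdsA, 4, 6)
  pos <- 4104L
  ref <- substr(codon2, 1, 1)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  code <- Biostrings::GENETIC_CODE
  for (alt in alts) {
    mutated <- codon2
    substr(mutated, 1, 1) <- alt
    site <- data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt,
                       variant_class = "SNV", indel_length = 0L,
                       stringsAsFactors = FALSE)
    got <- coding_effect(assign_region(site, idx), idx, genome)$coding_effect
    want <- if (code[[codon2]] == code[[mutated]]) "SYNONYMOUS" else "NONSYNONYMOUS"
    expect_equal(got, want, label = paste("+ strand alt", alt))
  }
  # - strand gene B: transcript codon 2 maps to genomic 12175..12177
  codon2B <- substr(h$cdsB, 4, 6)
  gpos <- 12177L  # first base of codon 2 in transcript orientation
  refB <- as.character(Biostrings::subseq(genome[["chrT"]], gpos, gpos))
  altB <- setdiff(c("A", "C", "G", "T"), refB)[1]
  site <- data.frame(chrom = "chrT", pos = gpos, ref = refB, alt = altB,
                     variant_class = "SNV", indel_length = 0L,
                     stringsAsFactors = FALSE)
  got <- coding_effect(assign_region(site, idx), idx, genome)$coding_effect
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mutatedB <- codon2B
  substr(mutatedB, 1, 1) <- comp[[altB]]
  want <- if (code[[codon2B]] == code[[mutatedB]]) "SYNONYMOUS" else "NONSYNONYMOUS"
  expect_equal(got, want)
})

test_that("all 576 single-base codon substitutions match an independent translator", {
  skip_if_not_installed("seqinr")
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases, paste0))
  # synthetic single-gene genome: CDS = ATG + all 64 codons + TAA
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  dir <- withr::local_tempdir()
  len <- 1000L
  left <- strrep("C", 99)
  seq_str <- paste0(left, cds, strrep("C", len - 99 - nchar(cds)))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seq_str, "chrZ")),
    file.path(dir, "z.fasta"))
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region chrZ 1 %d", len),
    sprintf("chrZ\tt\tgene\t100\t%d\t.\t+\t.\tID=gZ", 99 + nchar(cds)),
    sprintf("chrZ\tt\tmRNA\t100\t%d\t.\t+\t.\tID=gZ.t1;Parent=gZ", 99 + nchar(cds)),
    sprintf("chrZ\tt\texon\t100\t%d\t.\t+\t.\tParent=gZ.t1", 99 + nchar(cds)),
    sprintf("chrZ\tt\tCDS\t100\t%d\t.\t+\t0\tParent=gZ.t1", 99 + nchar(cds))),
    file.path(dir, "z.gff3"))
  idx <- build_gene_index(file.path(dir, "z.gff3"))
  rows <- list()
  want <- character(0)
  for (ci in seq_along(codons)) {
    codon <- codons[ci]
    cds_off <- 3 + (ci - 1) * 3  # codon start offset within CDS (0-based)
    for (p in 1:3) {
      gpos <- 100L + cds_off + (p - 1)
      ref <- substr(codon, p, p)
      for (alt in setdiff(bases, ref)) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = "chrZ", pos = gpos, ref = ref, alt = alt,
          variant_class = "SNV", indel_length = 0L, stringsAsFactors = FALSE)
        mutated <- codon
        substr(mutated, p, p) <- alt
        aa1 <- seqinr::translate(strsplit(codon, "")[[1]])
        aa2 <- seqinr::translate(strsplit(mutated, "")[[1]])
        want <- c(want, if (identical(aa1, aa2)) "SYNONYMOUS" else "NONSYNONYMOUS")
      }
    }
  }
  sites <- do.call(rbind, rows)
  expect_equal(nrow(sites), 576L)
  got <- coding_effect(assign_region(sites, idx), idx, file.path(dir, "z.fasta"))
  expect_equal(got$coding_effect, want)
})

test_that("CDS indels split by the mod-3 rule and reference mismatches abort", {
  h <- handmade_annotation()
  idx <- build_gene_index(h$gff)
  mk <- function(pos, len) {
    ref <- as.character(Biostrings::subseq(h$seq[["chrT"]], pos, pos + len))
    data.frame(chrom = "chrT", pos = pos, ref = ref, alt = substr(ref, 1, 1),
               variant_class = "DELETION", indel_length = len,
               stringsAsFactors = FALSE)
  }
  got <- coding_effect(assign_region(rbind(mk(4200L, 9L), mk(4200L, 8L)), idx),
                       idx, h$seq)
  expect_equal(got$coding_effect, c("INFRAME_INDEL", "FRAMESHIFT"))
  bad <- data.frame(chrom = "chrT", pos = 4200L, ref = "NNN", alt = "N",
                    variant_class = "DELETION", indel_length = 2L,
                    stringsAsFactors = FALSE)
  expect_error(coding_effect(assign_region(bad, idx), idx, h$seq),
               "reference mismatch at chrT:4200")
})

test_that("mirroring the genome and flipping strands preserves SNV annotations", {
  h <- handmade_annotation()
  idx <- build_gene_index(h$gff)
  L <- 20000L
  # mirrored fixture: reverse-complement sequence, reflect coordinates,
  # flip strands and swap the UTR roles
  mseq <- Biostrings::DNAStringSet(setNames(as.character(
    Biostrings::reverseComplement(h$seq[[1]])), "chrT"))
  dir <- withr::local_tempdir()
  refl <- function(a, b) c(L - b + 1L, L - a + 1L)
  gA <- refl(4001L, 4500L); cA <- refl(4101L, 4400L)
  u5A <- refl(4001L, 4100L); u3A <- refl(4401L, 4500L)
  gB <- refl(11901L, 12280L); cB <- refl(12001L, 12180L)
  u5B <- refl(12181L, 12280L); u3B <- refl(11901L, 12000L)
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region chrT 1 %d", L),
    sprintf("chrT\tt\tgene\t%d\t%d\t.\t-\t.\tID=geneA", gA[1], gA[2]),
    sprintf("chrT\tt\tmRNA\t%d\t%d\t.\t-\t.\tID=geneA.t1;Parent=geneA", gA[1], gA[2]),
    sprintf("chrT\tt\texon\t%d\t%d\t.\t-\t.\tParent=geneA.t1", gA[1], gA[2]),
    sprintf("chrT\tt\tfive_prime_UTR\t%d\t%d\t.\t-\t.\tParent=geneA.t1", u5A[1], u5A[2]),
    sprintf("chrT\tt\tCDS\t%d\t%d\t.\t-\t0\tParent=geneA.t1", cA[1], cA[2]),
    sprintf("chrT\tt\tthree_prime_UTR\t%d\t%d\t.\t-\t.\tParent=geneA.t1", u3A[1], u3A[2]),
    sprintf("chrT\tt\tgene\t%d\t%d\t.\t+\t.\tID=geneB", gB[1], gB[2]),
    sprintf("chrT\tt\tmRNA\t%d\t%d\t.\t+\t.\tID=geneB.t1;Parent=geneB", gB[1], gB[2]),
    sprintf("chrT\tt\texon\t%d\t%d\t.\t+\t.\tParent=geneB.t1", gB[1], gB[2]),
    sprintf("chrT\tt\tfive_prime_UTR\t%d\t%d\t.\t+\t.\tParent=geneB.t1", u5B[1], u5B[2]),
    sprintf("chrT\tt\tCDS\t%d\t%d\t.\t+\t0\tParent=geneB.t1", cB[1], cB[2]),
    sprintf("chrT\tt\tthree_prime_UTR\t%d\t%d\t.\t+\t.\tParent=geneB.t1", u3B[1], u3B[2])),
    file.path(dir, "mirror.gff3"))
  midx <- build_gene_index(file.path(dir, "mirror.gff3"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(53)
  pos <- sort(sample(3000:13000, 40))
  ref <- vapply(pos, function(p)
    as.character(Biostrings::subseq(h$seq[[1]], p, p)), "")
  alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
  sites <- data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt,
                      variant_class = "SNV", indel_length = 0L,
                      stringsAsFactors = FALSE)
  msites <- data.frame(chrom = "chrT", pos = L - pos + 1L,
                       ref = unname(comp[ref]), alt = unname(comp[alt]),
                       variant_class = "SNV", indel_length = 0L,
                       stringsAsFactors = FALSE)
  a1 <- coding_effect(assign_region(sites, idx), idx, h$seq)
  a2 <- coding_effect(assign_region(msites, midx), midx, mseq)
  k1 <- paste(a1$gene_id, a1$region, a1$coding_effect)[order(a1$pos, a1$gene_id)]
  k2 <- paste(a2$gene_id, a2$region, a2$coding_effect)[order(L - a2$pos + 1L, a2$gene_id)]
  expect_equal(k1, k2)
})

test_that("the gene filter removes exactly the flagged fraction", {
  set.seed(54)
  ann <- generate_annotation(tiny_specs(), n_genes = 40,
                             te_fraction = 0.2, unknown_fraction = 0.1)
  dir <- withr::local_tempdir()
  write_annotation(ann, file.path(dir, "f.gff3"))
  idx <- build_gene_index(file.path(dir, "f.gff3"))
  filtered <- gene_filter(idx, quiet = TRUE)
  n <- nrow(ann$genes)
  expect_equal(nrow(filtered$genes), n - round(0.2 * n) - round(0.1 * n))
  # all genes flagged -> empty set
  idx2 <- idx
  idx2$genes$mobile_element <- TRUE
  expect_equal(nrow(gene_filter(idx2, quiet = TRUE)$genes), 0)
})

test_that("a malformed CDS length draws a warning and is excluded from effects", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrW 1 5000",
    "chrW\tt\tgene\t1000\t2000\t.\t+\t.\tID=gW",
    "chrW\tt\tmRNA\t1000\t2000\t.\t+\t.\tID=gW.t1;Parent=gW",
    "chrW\tt\texon\t1000\t2000\t.\t+\t.\tParent=gW.t1",
    "chrW\tt\tCDS\t1000\t2000\t.\t+\t0\tParent=gW.t1"),  # 1001 bp, not mod 3
    file.path(dir, "w.gff3"))
  expect_warning(idx <- build_gene_index(file.path(dir, "w.gff3")),
                 "not divisible by 3")
  expect_true(idx$genes$malformed)
  genome <- Biostrings::DNAStringSet(setNames(strrep("A", 5000), "chrW"))
  site <- data.frame(chrom = "chrW", pos = 1500L, ref = "A", alt = "G",
                     variant_class = "SNV", indel_length = 0L,
                     stringsAsFactors = FALSE)
  got <- coding_effect(assign_region(site, idx), idx, genome)
  expect_equal(got$coding_effect, "NONCODING")
})
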