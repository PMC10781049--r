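# Reading the trio VCF and labelling variant sites by parental origin.

variant_class_of <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
  ifelse(nchar(alt) > nchar(ref), "INSERTION", "DELETION"))
}

# collapse diploid GT strings to REF/ALT/MISSING for alt allele index k
# (vectorized over sites; k is a vector of the same length as gt)
collapse_gt <- function(gt, k, het_policy) {
  al <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(al, function(a) if (length(a) >= 1) a[1] else NA_character_, character(1))))
  a2 <- suppressWarnings(as.integer(vapply(al, function(a) if (length(a) >= 2) a[2] else NA_character_, character(1))))
  a2[is.na(a2)] <- a1[is.na(a2)]  # haploid calls count twice
  valid <- !is.na(a1) & !is.na(a2) & (a1 == 0L | a1 == k) & (a2 == 0L | a2 == k)
  out <- rep("MISSING", length(gt))
  out[valid & a1 == 0L & a2 == 0L] <- "REF"
  out[valid & a1 == k & a2 == k] <- "ALT"
  het <- valid & ((a1 == 0L) != (a2 == 0L))
  # under the majority policy a diploid 0/k tie resolves to the
  # non-reference allele; the default leaves heterozygotes missing so the
  # site classifies as ambiguous
  out[het] <- if (het_policy == "major-allele") "ALT" else "MISSING"
  out
}

#' Read a trio VCF into a site table
#'
#' Multi-allelic records are split into biallelic sites against the same
#' REF; a sample carrying neither the reference nor the focal alternate
#' allele at a split site is marked missing. Genotypes are collapsed to
#' `REF`/`ALT`/`MISSING` under the inbred homozygous assumption;
#' heterozygous calls become `MISSING` (and hence classify as ambiguous)
#' under the default policy, or collapse to their majority allele under
#' `het_policy = "major-allele"` (a diploid 0/1 tie resolves to ALT).
#'
#' @param path VCF v4.2 file.
#' @param offspring,donor,recurrent sample names of the three roles.
#' @param het_policy `"ambiguous"` (default) or `"major-allele"`.
#' @return data frame of sites ordered by (chrom, pos): `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `variant_class` (SNV/INSERTION/DELETION),
#'   `indel_length`, and genotypes `gt_offspring`, `gt_donor`,
#'   `gt_recurrent`.
#' @export
read_trio_vcf <- function(path, offspring = "offspring", donor = "donor",
                          recurrent = "recurrent",
                          het_policy = c("ambiguous", "major-allele")) {
  het_policy <- match.arg(het_policy)
  if (!file.exists(path)) stop_input("VCF not found: %s", path)
  roles <- c(offspring = offspring, donor = donor, recurrent = recurrent)
  if (anyDuplicated(roles)) stop_input("role sample names must be distinct")
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      variant_class = character(0), indel_length = integer(0),
                      gt_offspring = character(0), gt_donor = character(0),
                      gt_recurrent = character(0), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty)
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  missing_roles <- roles[!roles %in% samples]
  if (length(missing_roles) > 0)
    stop_input("sample(s) not in VCF header: %s",
               paste(missing_roles, collapse = ", "))
  pos <- as.integer(fix$POS)
  chrom <- fix$CHROM
  # reject unsorted input: positions must be non-decreasing within each
  # contiguous chromosome block, and no chromosome may be interleaved
  if (any(chrom[-1] == chrom[-length(chrom)] & diff(pos) < 0))
    stop_input("VCF is not position-sorted within chromosomes")
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks))
    stop_input("VCF chromosomes are interleaved; sort the input")
  gt_only <- sub(":.*", "", gt[, -1, drop = FALSE])
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  k <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  sites <- data.frame(
    chrom = chrom[idx], pos = pos[idx], ref = fix$REF[idx],
    alt = unlist(alt_list, use.names = FALSE),
    gt_offspring = collapse_gt(gt_only[idx, roles["offspring"]], k, het_policy),
    gt_donor = collapse_gt(gt_only[idx, roles["donor"]], k, het_policy),
    gt_recurrent = collapse_gt(gt_only[idx, roles["recurrent"]], k, het_policy),
    stringsAsFactors = FALSE)
  sites$variant_class <- variant_class_of(sites$ref, sites$alt)
  sites$indel_length <- abs(nchar(sites$alt) - nchar(sites$ref))
  sites <- sites[order(match(sites$chrom, unique(chrom)), sites$pos), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites[, c("chrom", "pos", "ref", "alt", "variant_class", "indel_length",
            "gt_offspring", "gt_donor", "gt_recurrent")]
}

#' Classify a trio site by parental origin
#'
#' A site is `DONOR` when the offspring shares the donor parent's allele
#' and that allele differs from the recurrent parent's; `RECURRENT` in the
#' mirrored case; `NON_POLYMORPHIC` when all three agree; `NOVEL` when both
#' parents agree but the offspring differs; and `AMBIGUOUS` whenever any
#' genotype is missing.
#'
#' @param gt_offspring,gt_donor,gt_recurrent genotype vectors with values
#'   `REF`, `ALT` or `MISSING`.
#' @return character vector of origin labels.
#' @examples
#' classify_trio_site("ALT", "ALT", "REF")  # DONOR
#' classify_trio_site("REF", "ALT", "REF")  # RECURRENT
#' @export
classify_trio_site <- function(gt_offspring, gt_donor, gt_recurrent) {
  ok <- gt_offspring != "MISSING" & gt_donor != "MISSING" &
    gt_recurrent != "MISSING"
  lab <- rep("AMBIGUOUS", length(gt_offspring))
  lab[ok & gt_donor == gt_offspring & gt_donor != gt_recurrent] <- "DONOR"
  lab[ok & gt_recurrent == gt_offspring & gt_recurrent != gt_donor] <- "RECURRENT"
  lab[ok & gt_donor == gt_recurrent & gt_donor == gt_offspring] <- "NON_POLYMORPHIC"
  lab[ok & gt_donor == gt_recurrent & gt_donor != gt_offspring] <- "NOVEL"
  lab
}

#' Label every site of a trio table by parental origin
#'
#' @param sites site table from [read_trio_vcf()].
#' @return `sites` with an `origin` column appended.
#' @export
classify_trio_sites <- function(sites) {
  sites$origin <- classify_trio_site(sites$gt_offspring, sites$gt_donor,
                                     sites$gt_recurrent)
  sites
}

#' Filter indels by length
#'
#' SNVs always pass; indels are retained when their length (absolute
#' REF/ALT length difference) lies in `[min_len, max_len]`. The default
#' window of 1-99 bp matches the analysis convention for short indels.
#'
#' @param sites site table.
#' @param min_len,max_len inclusive indel length bounds.
#' @param quiet suppress the removal-count message.
#' @return filtered site table.
#' @export
filter_indel_length <- function(sites, min_len = 1, max_len = 99,
                                quiet = FALSE) {
  if (min_len > max_len) stop_input("min_len must not exceed max_len")
  is_indel <- sites$variant_class != "SNV"
  keep <- !is_indel | (sites$indel_length >= min_len &
                       sites$indel_length <= max_len)
  if (!quiet && any(!keep))
    message(sprintf("filter_indel_length: removed %d of %d indels outside [%d, %d] bp",
                    sum(!keep), sum(is_indel), min_len, max_len))
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate a classified site table
#'
#' @param sites site table with an `origin` column.
#' @return data frame of counts by variant class and origin, plus indel
#'   bookkeeping totals (`n_insertion + n_deletion = n_indel`).
#' @export
variant_summary <- function(sites) {
  list(n_sites = nrow(sites),
       n_snv = sum(sites$variant_class == "SNV"),
       n_insertion = sum(sites$variant_class == "INSERTION"),
       n_deletion = sum(sites$variant_class == "DELETION"),
       n_indel = sum(sites$variant_class %in% c("INSERTION", "DELETION")),
       by_origin = if (!is.null(sites$origin))
         as.list(table(sites$origin)) else NULL)
}
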