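# Backcross pedigree simulation.
#
# A haplotype "mosaic" is a data.frame(chrom, start, end, origin) of
# half-open 0-based segments labelled "DONOR" or "RECURRENT" that tile each
# chromosome exactly. An individual is a list(h1 =, h2 =) of two mosaics.

#' Describe the simulated chromosome set
#'
#' @param name chromosome names.
#' @param length_bp physical length in bp (>= 10000).
#' @param length_cM genetic length in centimorgans (> 0; 0 is allowed to
#'   switch recombination off, e.g. for degenerate test cases).
#' @return data frame with one row per chromosome.
#' @examples
#' chromosome_spec(c("chr1", "chr2"), 1e6, 100)
#' @export
chromosome_spec <- function(name, length_bp, length_cM) {
  d <- data.frame(name = as.character(name),
                  length_bp = as.integer(length_bp),
                  length_cM = as.numeric(length_cM),
                  stringsAsFactors = FALSE)
  if (any(d$length_bp < 10000)) stop_input("chromosome length_bp must be >= 10000")
  if (any(d$length_cM < 0)) stop_input("chromosome length_cM must be >= 0")
  if (anyDuplicated(d$name)) stop_input("duplicated chromosome names")
  d
}

#' Default simulated genome: 7 chromosomes, 1 Mb / 100 cM each
#'
#' Desk-scale stand-in for the seven pea chromosomes, preserving the
#' per-chromosome reporting structure of the inheritance summary.
#'
#' @return chromosome spec data frame.
#' @export
default_chromosomes <- function() {
  chromosome_spec(paste0("chr", 1:7), rep(1e6, 7), rep(100, 7))
}

# uniform mosaic covering all chromosomes with one origin label
uniform_mosaic <- function(specs, origin) {
  data.frame(chrom = specs$name, start = 0, end = specs$length_bp,
             origin = origin, stringsAsFactors = FALSE)
}

founder_individual <- function(specs, origin) {
  m <- uniform_mosaic(specs, origin)
  list(h1 = m, h2 = m)
}

# merge adjacent same-origin segments, chromosome by chromosome
merge_mosaic <- function(m) {
  m <- m[order(match(m$chrom, unique(m$chrom)), m$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1) {
    same <- m$chrom[-1] == m$chrom[-nrow(m)] & m$origin[-1] == m$origin[-nrow(m)]
    keep[-1] <- !same
  }
  out <- m[keep, , drop = FALSE]
  run_last <- c(which(keep)[-1] - 1L, nrow(m))
  out$end <- m$end[run_last]
  rownames(out) <- NULL
  out
}

# clip the segments of one chromosome to [a, b)
slice_mosaic <- function(m, a, b) {
  s <- m[m$end > a & m$start < b, , drop = FALSE]
  s$start <- pmax(s$start, a)
  s$end <- pmin(s$end, b)
  s
}

#' Simulate one gamete from a parent individual
#'
#' Meiosis under the Haldane model: per chromosome the crossover count is
#' Poisson with mean `length_cM / 100` (no interference), crossover positions
#' are uniform in physical coordinates, and the starting homolog is chosen by
#' a fair coin. Segments alternate between the two parental homologs at each
#' crossover.
#'
#' @param parent individual, a `list(h1, h2)` of segment mosaics.
#' @param specs chromosome spec (see [chromosome_spec()]).
#' @return a single-haplotype mosaic data frame.
#' @export
simulate_gamete <- function(parent, specs) {
  if (any(specs$length_bp <= 0)) stop_input("non-positive chromosome length")
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    chrom <- specs$name[i]
    len <- specs$length_bp[i]
    h1 <- parent$h1[parent$h1$chrom == chrom, , drop = FALSE]
    h2 <- parent$h2[parent$h2$chrom == chrom, , drop = FALSE]
    if (sum(h1$end - h1$start) != len || sum(h2$end - h2$start) != len)
      stop_input("parent homologs do not tile chromosome %s", chrom)
    n_xo <- rpois(1, specs$length_cM[i] / 100)
    cuts <- sort(unique(floor(runif(n_xo, min = 1, max = len))))
    bounds <- c(0, cuts, len)
    first <- sample(c(0L, 1L), 1)
    segs <- vector("list", length(bounds) - 1)
    for (k in seq_len(length(bounds) - 1)) {
      src <- if ((k + first) %% 2 == 0) h1 else h2
      segs[[k]] <- slice_mosaic(src, bounds[k], bounds[k + 1])
    }
    out[[i]] <- do.call(rbind, segs)
  }
  merge_mosaic(do.call(rbind, out))
}

#' Simulate a backcross-and-selfing pedigree
#'
#' Crosses donor x recurrent to an F1, backcrosses the offspring to the
#' recurrent parent `n_backcrosses` times, then selfs for `n_selfings`
#' generations, carrying one offspring forward per generation (no selection).
#' The derived line's haplotype is one homolog of the final individual: the
#' line is treated as fixed (inbred), so a single mosaic describes it.
#'
#' @param n_backcrosses number of backcrosses to the recurrent parent
#'   (default 5, the breeding design emulated here).
#' @param n_selfings number of selfing generations after the last backcross
#'   (default 4).
#' @param specs chromosome spec; defaults to [default_chromosomes()].
#' @return object of class `pedigree_sim`: list with `mosaic` (the derived
#'   line haplotype), `individual` (final list(h1, h2)), `donor_fraction_bp`
#'   (bp-weighted donor fraction of the final individual, averaged over both
#'   homologs, in `[0, 1]`), and the configuration.
#' @examples
#' set.seed(1)
#' ped <- simulate_pedigree(n_backcrosses = 5, n_selfings = 4)
#' ped$donor_fraction_bp
#' @export
simulate_pedigree <- function(n_backcrosses = 5, n_selfings = 4,
                              specs = default_chromosomes()) {
  if (n_backcrosses < 0 || n_selfings < 0)
    stop_input("pedigree generation counts must be >= 0")
  donor <- founder_individual(specs, "DONOR")
  recur <- founder_individual(specs, "RECURRENT")
  cur <- list(h1 = simulate_gamete(donor, specs),
              h2 = simulate_gamete(recur, specs))
  for (b in seq_len(n_backcrosses))
    cur <- list(h1 = simulate_gamete(cur, specs),
                h2 = simulate_gamete(recur, specs))
  for (s in seq_len(n_selfings))
    cur <- list(h1 = simulate_gamete(cur, specs),
                h2 = simulate_gamete(cur, specs))
  mosaic <- cur$h1
  structure(list(mosaic = mosaic,
                 individual = cur,
                 donor_fraction_bp = (mosaic_donor_fraction(cur$h1) +
                                      mosaic_donor_fraction(cur$h2)) / 2,
                 n_backcrosses = n_backcrosses,
                 n_selfings = n_selfings,
                 specs = specs),
            class = "pedigree_sim")
}

#' Donor bp-fraction of a haplotype mosaic
#'
#' @param mosaic segment data frame (`chrom`, `start`, `end`, `origin`).
#' @return fraction of bp labelled DONOR, in `[0, 1]`.
#' @export
mosaic_donor_fraction <- function(mosaic) {
  len <- mosaic$end - mosaic$start
  sum(len[mosaic$origin == "DONOR"]) / sum(len)
}

# origin label of single positions (0-based) on a mosaic; positions must be
# within [0, chrom length)
mosaic_label_at <- function(mosaic, chrom, pos0) {
  lab <- character(length(pos0))
  for (ch in unique(chrom)) {
    m <- mosaic[mosaic$chrom == ch, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    sel <- chrom == ch
    idx <- findInterval(pos0[sel], m$start)
    if (any(idx < 1 | pos0[sel] >= m$end[pmax(idx, 1)]))
      stop_input("position outside mosaic on %s", ch)
    lab[sel] <- m$origin[idx]
  }
  lab
}

# span origin: DONOR / RECURRENT if [a, b) is uniformly labelled, else MIXED
mosaic_span_origin <- function(mosaic, chrom, a, b) {
  vapply(seq_along(chrom), function(i) {
    s <- slice_mosaic(mosaic[mosaic$chrom == chrom[i], , drop = FALSE], a[i], b[i])
    u <- unique(s$origin)
    if (length(u) == 1) u else "MIXED"
  }, character(1))
}

#' Expected donor-genome fraction after repeated backcrossing
#'
#' Returns the printed halving model `100 * (1/2)^b` by default: five
#' backcrosses give 3.125%, i.e. "about 3%". Note that the standard pedigree
#' expectation counts the F1 cross as the first halving, giving
#' `100 * (1/2)^(b + 1)` (1.5625% for five backcrosses); request it with
#' `model = "pedigree"`. The degenerate case `b = 0` under the halving model
#' evaluates to 100%.
#'
#' @param b number of backcrosses (integer >= 0).
#' @param model `"halving"` (default) for `(1/2)^b`, `"pedigree"` for
#'   `(1/2)^(b+1)`.
#' @return expected donor fraction as a percentage.
#' @examples
#' expected_backcross_fraction(5)            # 3.125
#' expected_backcross_fraction(5, "pedigree") # 1.5625
#' @export
expected_backcross_fraction <- function(b, model = c("halving", "pedigree")) {
  model <- match.arg(model)
  if (any(b < 0)) stop_input("number of backcrosses must be >= 0")
  ex <- if (model == "halving") b else b + 1
  100 * 0.5^ex
}

#' @export
print.pedigree_sim <- function(x, ...) {
  cat(sprintf("Backcross pedigree simulation: BC%dF%d, %d chromosomes\n",
              x$n_backcrosses, x$n_selfings, nrow(x$specs)))
  cat(sprintf("  donor fraction (bp-weighted): %.3f%%\n",
              100 * x$donor_fraction_bp))
  cat(sprintf("  segments in line mosaic: %d\n", nrow(x$mosaic)))
  invisible(x)
}
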