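# Normalization, the NB Wald test and response-pattern classes.

mk_design <- function(genotypes = "offspring", reps = 3) {
  d <- expand.grid(replicate = seq_len(reps),
                   treatment = c("control", "inoculated"),
                   genotype = genotypes, stringsAsFactors = FALSE)
  d$sample <- sprintf("%s_%s_%d", d$genotype, d$treatment, d$replicate)
  d[, c("sample", "genotype", "treatment", "replicate")]
}

null_counts <- function(ng, design, mu = 150, disp = 0.1, sdlog = 1) {
  base <- rlnorm(ng, log(mu), sdlog)
  sf <- runif(nrow(design), 0.7, 1.3)
  m <- sapply(seq_len(nrow(design)), function(j)
    rnbinom(ng, mu = base * sf[j], size = 1 / disp))
  dimnames(m) <- list(paste0("g", seq_len(ng)), design$sample)
  m
}

test_that("TPM normalization satisfies its identities", {
  # two genes, equal counts and lengths -> an even split
  m <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(as.vector(tpm_normalize(m, c(100, 100))), c(5e5, 5e5))
  # scale invariance per sample
  m2 <- cbind(s1 = c(3, 9, 1), s2 = c(6, 18, 2))
  rownames(m2) <- paste0("g", 1:3)
  tp <- tpm_normalize(m2, c(200, 100, 50))
  expect_equal(tp[, "s1"], tp[, "s2"])
  # random matrix: every column sums to 1e6
  set.seed(71)
  m3 <- matrix(rpois(600, 40), 50, 12,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  tp3 <- tpm_normalize(m3, sample(200:3000, 50))
  expect_equal(unname(colSums(tp3)), rep(1e6, 12), tolerance = 1e-6)
  # an all-zero sample is an error naming the sample
  m3[, 3] <- 0
  expect_error(tpm_normalize(m3, rep(100, 50)), "s3")
})

test_that("the low-expression filter implements the max-across-samples rule", {
  tpm <- rbind(low = rep(9.9, 4), edge = c(10, 0, 0, 0), high = rep(50, 4))
  colnames(tpm) <- paste0("s", 1:4)
  kept <- filter_low_expression(tpm, 10, quiet = TRUE)
  expect_equal(kept, c("edge", "high"))
  # recount oracle on random data
  set.seed(72)
  tpm2 <- matrix(runif(500, 0, 30), 100, 5,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:5)))
  expect_equal(filter_low_expression(tpm2, 10, quiet = TRUE),
               rownames(tpm2)[apply(tpm2, 1, max) >= 10])
})

test_that("degenerate DE inputs behave as specified", {
  design <- mk_design()
  m <- matrix(rep(c(50L, 0L), each = 6), 2, 6, byrow = TRUE,
              dimnames = list(c("flat", "zero"), design$sample))
  m["flat", ] <- 50L
  res <- nb_de_test(m, design, "offspring")
  expect_equal(res$log2_fold_change[res$gene_id == "flat"], 0)
  expect_equal(res$status[res$gene_id == "flat"], "NS")
  expect_true(is.na(res$p_value[res$gene_id == "zero"]))
  expect_equal(res$status[res$gene_id == "zero"], "NS")
  # fewer than two replicates per group is an error
  d1 <- mk_design(reps = 1)
  m1 <- matrix(5L, 2, 2, dimnames = list(c("a", "b"), d1$sample))
  expect_error(nb_de_test(m1, d1, "offspring"), "replicates")
  expect_error(nb_de_test(m, design, "nonexistent"), "not in design")
})

test_that("the NB Wald test is calibrated under the null and finds planted effects", {
  design <- mk_design()
  set.seed(73)
  m <- null_counts(2000, design)
  res <- nb_de_test(m, design, "offspring")
  t1 <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gt(t1, 0.02); expect_lt(t1, 0.08)
  # BH monotonicity and status consistency
  ord <- order(res$p_value)
  expect_true(all(diff(res$adjusted_p[ord]) >= -1e-12, na.rm = TRUE))
  up <- res$status == "UP"
  expect_true(all(res$adjusted_p[up] < 0.05 & res$log2_fold_change[up] > 0))
  dn <- res$status == "DOWN"
  expect_true(all(res$adjusted_p[dn] < 0.05 & res$log2_fold_change[dn] < 0))
  # planted signal: LFC = 2 at mean >= 100
  set.seed(74)
  base <- runif(500, 100, 1000)
  planted <- sample(500, 40)
  lfc <- rep(0, 500); lfc[planted] <- 2
  sf <- runif(6, 0.7, 1.3)
  trt <- design$treatment == "inoculated"
  m2 <- sapply(seq_len(6), function(j)
    rnbinom(500, mu = base * 2^(lfc * trt[j]) * sf[j], size = 10))
  dimnames(m2) <- list(paste0("g", 1:500), design$sample)
  res2 <- nb_de_test(m2, design, "offspring")
  expect_gt(mean(res2$p_value[planted] < 0.05), 0.8)
  expect_gt(mean(res2$log2_fold_change[planted]), 1.5)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  # independent implementation of the step-up rule
  bh_brute <- function(p) {
    n <- length(p)
    ord <- order(p)
    adj <- numeric(n)
    running <- Inf
    for (i in n:1) {
      running <- min(running, p[ord[i]] * n / i)
      adj[ord[i]] <- min(running, 1)
    }
    adj
  }
  set.seed(75)
  for (i in 1:100) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_brute(p))
  }
  expect_equal(p.adjust(rep(1, 10), "BH"), rep(1, 10))
})

test_that("pattern classes and Venn regions partition the UP universe", {
  mk_de <- function(genotype, status, lfc = ifelse(status == "UP", 2,
                                            ifelse(status == "DOWN", -2, 0))) {
    data.frame(gene_id = paste0("g", seq_along(status)), genotype = genotype,
               base_mean = 100, log2_fold_change = lfc,
               p_value = 0.01, adjusted_p = ifelse(status == "NS", 0.9, 0.01),
               status = status, stringsAsFactors = FALSE)
  }
  de <- list(offspring = mk_de("offspring", c("UP", "UP", "NS", "UP")),
             donor = mk_de("donor", c("UP", "UP", "UP", "NS")),
             recurrent = mk_de("recurrent", c("UP", "NS", "NS", "NS")))
  pat <- classify_patterns(de)
  expect_equal(pat$venn_region,
               c("donor+offspring+recurrent", "donor+offspring", "donor",
                 "offspring"))
  expect_equal(pat$donor_like_only, c(FALSE, TRUE, FALSE, FALSE))
  sizes <- venn_up_sizes(pat)
  expect_equal(sum(sizes), sum(pat$venn_region != "none"))
  # a gene missing from one genotype's results is excluded with a warning
  de$recurrent <- de$recurrent[-4, ]
  expect_warning(pat2 <- classify_patterns(de), "excluded")
  expect_equal(nrow(pat2), 3)
})

test_that("z-score rows are standardized and constant rows flagged", {
  design <- mk_design(genotypes = c("offspring", "donor"))
  set.seed(76)
  tpm <- matrix(runif(5 * nrow(design), 1, 100), 5, nrow(design),
                dimnames = list(paste0("g", 1:5), design$sample))
  tpm["g3", ] <- 7  # constant
  z <- zscore_matrix(tpm, design)
  expect_equal(ncol(z), 4)  # 2 genotypes x 2 treatments
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-9)
  sds <- apply(z, 1, sd)
  expect_equal(unname(sds[-3]), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(z["g3", ]), rep(0, 4))
  expect_equal(attr(z, "constant_rows"), "g3")
  # hand-computed two-gene example: replicate means then row scaling
  d2 <- mk_design(reps = 2)
  tpm2 <- rbind(gA = c(1, 3, 7, 15), gB = c(3, 3, 3, 3))
  colnames(tpm2) <- d2$sample
  z2 <- zscore_matrix(tpm2, d2)
  avg <- c(mean(log2(c(2, 4))), mean(log2(c(8, 16))))
  want <- (avg - mean(avg)) / sd(avg)
  expect_equal(unname(z2["gA", ]), want)
  expect_equal(unname(z2["gB", ]), c(0, 0))
})

test_that("the ddCt fold change evaluates its defining cases", {
  expect_equal(ddct_relative_expression(20, 18, 22, 20), 1)    # ddCt = 0
  expect_equal(ddct_relative_expression(21, 18, 22, 20), 0.5)  # ddCt = 1
  expect_equal(ddct_relative_expression(20, 20, 22, 20), 4)    # ddCt = -2
})
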