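test_that("haplotype diversity matches the published Ascension values", {
  calls <- read_call_counts(table2_path())
  counts <- tabulate_calls(calls, marker = "extended")$table$counts[1, ]
  d <- haplotype_diversity(counts)
  expect_identical(d$n, 267L)
  expect_identical(d$n_hap, 11L)
  expect_equal(round(d$h, 3), 0.366)
  expect_equal(round(d$sd_h, 3), 0.038)
})

test_that("haplotype diversity handles degenerate and boundary inputs", {
  expect_equal(haplotype_diversity(c(5))$h, 0)
  expect_equal(haplotype_diversity(c(1, 1))$h, 1)
  expect_error(haplotype_diversity(c(1)), "n >= 2")
  expect_error(haplotype_diversity(c(2.5, 1)), "integer")
  # invariance under permutation and relabeling of the counts vector
  set.seed(3)
  for (i in 1:20) {
    v <- rpois(sample(2:8, 1), 4) + 1
    d1 <- haplotype_diversity(v)
    d2 <- haplotype_diversity(sample(v))
    expect_equal(d1$h, d2$h)
    expect_equal(d1$sd_h, d2$sd_h)
  }
})

test_that("Narum FDR thresholds reproduce the published family corrections", {
  expect_equal(narum_fdr(0.05, 210)$threshold_rounded, 0.008)
  expect_equal(narum_fdr(0.05, 78)$threshold_rounded, 0.010)
  expect_equal(narum_fdr(0.05, 6)$threshold_rounded, 0.020)
  expect_equal(narum_fdr(0.05, 1)$threshold, 0.05)
  expect_error(narum_fdr(0.05, 0), "k")
  expect_error(narum_fdr(1.2, 10), "alpha")
})

test_that("pairwise F_ST behaves at the boundaries of differentiation", {
  same <- frequency_table(matrix(c(6L, 4L, 6L, 4L), 2, 2, byrow = TRUE,
                                 dimnames = list(c("A", "B"),
                                                 c("h1", "h2"))),
                          marker = "extended")
  r <- pairwise_fst(same, n_permutations = 200, seed = 1)
  expect_lte(r$values["A", "B"], 0)
  expect_gt(r$p_values["A", "B"], 0.5)
  fixed <- frequency_table(matrix(c(8L, 0L, 0L, 9L), 2, 2, byrow = TRUE,
                                  dimnames = list(c("A", "B"),
                                                  c("h1", "h2"))),
                           marker = "extended")
  r2 <- pairwise_fst(fixed, n_permutations = 200, seed = 1)
  expect_equal(r2$values["A", "B"], 1)
  expect_lt(r2$p_values["A", "B"], 0.05)
  small <- frequency_table(matrix(c(1L, 0L, 5L, 5L), 2, 2, byrow = TRUE,
                                  dimnames = list(c("A", "B"),
                                                  c("h1", "h2"))),
                           marker = "extended")
  expect_error(pairwise_fst(small, 10, 1), "n < 2")
})

test_that("F_ST equals the brute-force distance-matrix oracle", {
  tab <- frequency_table(matrix(c(10L, 0L, 5L, 5L), 2, 2, byrow = TRUE,
                                dimnames = list(c("A", "B"),
                                                c("h1", "h2"))),
                         marker = "extended")
  delta <- 1 - diag(2)
  r <- pairwise_fst(tab, n_permutations = 10, seed = 1)
  expect_equal(r$values["A", "B"], oracle_fst(tab$counts, delta),
               tolerance = 1e-12)
  for (s in 1:25) {
    t2 <- random_table(P = sample(2:4, 1), H = sample(2:5, 1),
                       n_max = 12, seed = 1000 + s)
    H <- ncol(t2$counts)
    r2 <- pairwise_fst(t2, n_permutations = 5, seed = s)
    for (i in seq_len(nrow(t2$counts) - 1)) {
      for (j in (i + 1):nrow(t2$counts)) {
        expect_equal(r2$values[i, j],
                     oracle_fst(t2$counts[c(i, j), , drop = FALSE],
                                1 - diag(H)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("Phi_ST reduces to F_ST for constant distances and follows the oracle", {
  tab <- random_table(3, 4, 12, seed = 77)
  H <- ncol(tab$counts)
  const <- matrix(3, H, H) - 3 * diag(H)
  dimnames(const) <- list(colnames(tab$counts), colnames(tab$counts))
  fst <- pairwise_fst(tab, n_permutations = 200, seed = 5)
  phist <- pairwise_phist(tab, const, n_permutations = 200, seed = 5)
  expect_equal(phist$values, fst$values, tolerance = 1e-12)
  expect_equal(phist$p_values, fst$p_values)  # same permutation stream
  zero <- const * 0
  expect_equal(max(abs(pairwise_phist(tab, zero, 10, 1)$values)), 0)
  # weighted 3-haplotype toy against the oracle
  t3 <- frequency_table(matrix(c(5L, 3L, 1L, 1L, 2L, 6L), 2, 3,
                               byrow = TRUE,
                               dimnames = list(c("A", "B"),
                                               c("h1", "h2", "h3"))),
                        marker = "extended")
  d3 <- matrix(c(0, 1, 4, 1, 0, 1, 4, 1, 0), 3, 3,
               dimnames = list(colnames(t3$counts), colnames(t3$counts)))
  r3 <- pairwise_phist(t3, d3, n_permutations = 10, seed = 1)
  expect_equal(r3$values["A", "B"], oracle_fst(t3$counts, d3),
               tolerance = 1e-12)
})

test_that("Phi_ST distances come from aligned sequences with pairwise deletion", {
  seqs <- c(h1 = "ACGTAC", h2 = "ACGTAT", h3 = "TCGA-C")
  d <- site_difference_matrix(seqs)
  expect_identical(d["h1", "h2"], 1L)
  expect_identical(d["h1", "h3"], 2L)  # gap site ignored
  expect_error(site_difference_matrix(c(a = "ACG", b = "AC")), "common")
  tab <- frequency_table(matrix(c(4L, 2L, 3L, 5L), 2, 2, byrow = TRUE,
                                dimnames = list(c("A", "B"),
                                                c("h1", "hX"))),
                         marker = "extended")
  expect_error(pairwise_phist(tab, seqs, 10, 1), "hX")
})

test_that("the CM-A8 + mtSTR subset keeps 18 combined haplotypes from Table 2", {
  calls <- read_call_counts(table2_path())
  comb <- tabulate_calls(calls, marker = "combined")$table
  sub <- subset_cma8_mtstr(comb)
  expect_identical(ncol(sub$counts), 18L)
  # retained total = mtSTR-identified CM-A8 carriers (212 - 51) + 3
  expect_identical(sum(sub$counts), 164L)
  no8 <- frequency_table(matrix(2L, 1, 1,
                                dimnames = list("A", "CM-A5.1/7-12-4-4")),
                         marker = "combined")
  expect_warning(res <- subset_cma8_mtstr(no8), "no combined haplotypes")
  expect_identical(ncol(res$counts), 0L)
})
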