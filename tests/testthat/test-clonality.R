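test_that("expected VAF evaluates the purity-copy-number relation", {
  expect_equal(expected_vaf(1.0, 1, 1), 0.5)
  expect_equal(expected_vaf(0.6, 2, 1), 1.2 / 2.6)
  expect_equal(expected_vaf(0.5, 2, 1), 0.4)
  expect_equal(expected_vaf(0.5, 1, 2), 0.2)  # swapped assignment
  expect_equal(expected_vaf(0.7, 0, 2), 0)    # no mutant copies, no error
  expect_error(expected_vaf(0, 1, 1), "purity")
  expect_error(expected_vaf(1.2, 1, 1), "purity")
})

test_that("the diploid heterozygote reduces to VAF = purity/2 exactly", {
  p <- seq(0.05, 1, by = 0.05)
  expect_identical(expected_vaf(p, 1, 1), p / 2)
  # and inversion reduces to the linear form purity = 2 * VAF
  v <- seq(0.05, 0.45, by = 0.05)
  expect_equal(solve_purity(v, 1, 1)$purity, 2 * v)
})

test_that("solve_purity inverts expected_vaf to 1e-9 across the grid", {
  grid <- expand.grid(p = seq(0.1, 1.0, by = 0.1), m = 1:3, w = 0:2)
  v <- expected_vaf(grid$p, grid$m, grid$w)
  sol <- solve_purity(v, grid$m, grid$w)
  expect_lt(max(abs(sol$purity - grid$p)), 1e-9)
  expect_true(all(sol$valid))
})

test_that("implausible implied purities are flagged invalid", {
  s <- solve_purity(0.9, 1, 1)
  expect_equal(s$purity, 1.8)
  expect_false(s$valid)
  expect_true(solve_purity(0.5, 1, 1)$valid)
  expect_error(solve_purity(0.5, 0, 1), "n_mut")
})

test_that("expected VAF is monotone in purity, n_mut and n_wt_cancer", {
  p <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(expected_vaf(p, 1, 1)) > 0))
  expect_true(all(diff(expected_vaf(p, 2, 1)) > 0))
  for (pp in c(0.3, 0.7)) {
    expect_true(all(diff(expected_vaf(pp, 1:4, 1)) > 0))
    expect_true(all(diff(expected_vaf(pp, 2, 0:3)) < 0))
  }
})

test_that("allele assignment picks the copy numbers consistent with purity", {
  a <- assign_mutant_copy_number(0.4, 0.5, 2, 1)
  expect_equal(a$status, "assigned")
  expect_equal(a$n_mut, 2)
  expect_equal(a$n_wt_cancer, 1)
  expect_equal(a$implied_purity, 0.5)
  # symmetric state is unique trivially
  b <- assign_mutant_copy_number(0.25, 0.5, 1, 1)
  expect_equal(b$status, "assigned")
  expect_equal(b[, c("n_mut", "n_wt_cancer")], data.frame(n_mut = 1,
                                                          n_wt_cancer = 1))
  # deep-subclonal signal: neither assignment fits the sample purity
  c_ <- assign_mutant_copy_number(0.05, 0.8, 1, 1)
  expect_equal(c_$status, "no_fit")
  expect_equal(c_$implied_purity, 0.1, tolerance = 1e-9)
})

test_that("corrected allele fraction sits on the cancer-cell-fraction scale", {
  # clonal diploid het at purity 0.8: VAF 0.4 implies fraction 1
  expect_equal(corrected_allele_fraction(0.4, 0.8, 1, 1), 1)
  # mutation in half the tumor cells
  expect_equal(corrected_allele_fraction(0.2, 0.8, 1, 1), 0.5)
  # capped just above 1 to absorb noise
  expect_lte(corrected_allele_fraction(0.55, 0.8, 1, 1), 1.05)
})

test_that("corrected fraction recovers a simulated 50% subclone at high depth", {
  truth <- data.frame(mutation_id = "m1", purity = 0.8, n_mut = 1,
                      n_wt_cancer = 1, cell_fraction = 0.5, depth = 1e5)
  rc <- simulate_read_counts(truth, seed = 9)
  vaf <- rc$reads$mutant_reads / rc$reads$total_reads
  expect_equal(corrected_allele_fraction(vaf, 0.8, 1, 1), 0.5,
               tolerance = 0.02)
})

test_that("pair clonality calls distinguish co-clonal, nested and identical", {
  a <- allele_copy_context(400, 1000, purity = 0.8)
  b <- allele_copy_context(400, 1000, purity = 0.8)
  cl <- test_pair_clonality(a, b)
  expect_equal(cl$call, "co_clonal")
  expect_equal(cl$chisq_stat, 0)
  expect_equal(cl$p_chisq, 1)
  # variant B far below its clonal expectation: subclonal, nested
  b2 <- allele_copy_context(150, 1000, purity = 0.8)
  cl2 <- test_pair_clonality(a, b2)
  expect_equal(cl2$call, "nested")
  expect_lt(cl2$p_binom_b, 1e-6)
  expect_gt(cl2$p_binom_a, 0.05)
  # read-count invariants enforced at construction
  expect_error(allele_copy_context(5, 0, 0.8), "total_reads")
  expect_error(allele_copy_context(11, 10, 0.8), "mutant_reads")
})

test_that("copy-number-corrected and raw chi-squared tests are both reported", {
  a <- allele_copy_context(800, 1000, purity = 0.9, n_mut = 2, n_wt_cancer = 0)
  b <- allele_copy_context(430, 1000, purity = 0.9, n_mut = 1, n_wt_cancer = 1)
  cl <- test_pair_clonality(a, b)
  expect_false(is.na(cl$p_chisq))
  expect_false(is.na(cl$p_chisq_raw))
  # correcting A's count to per-copy units brings the pair together
  expect_gt(cl$p_chisq, cl$p_chisq_raw)
})

test_that("clonality truth is recovered on simulated pairs (seeded)", {
  co <- sim_clonality_calls(60, cf_b = 1, seed = 101)
  sub <- sim_clonality_calls(60, cf_b = 0.3, seed = 102)
  expect_gt(mean(co == "co_clonal"), 0.85)
  expect_true(all(sub != "co_clonal"))
  expect_gt(mean(sub == "nested"), 0.85)
})
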