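mk_design2 <- function(n_rep = 2) {
  rts <- tidyr::expand_grid(sample = c("S1", "S3"), replicate = seq_len(n_rep))
  rts$run_id <- paste0(rts$sample, "_R", rts$replicate)
  design_spec(
    samples = c("S1", "S3"),
    run_to_sample = rts[c("run_id", "sample", "replicate")],
    comparisons = tibble::tibble(sample = "S1", reference = "S3"),
    anchor_species = "human",
    reference_sample = "S3",
    species_rule = c("_HUMAN$" = "human", "_ECOLI$" = "ecoli")
  )
}

mk_ab <- function(values) {
  # values: named list protein -> named numeric by run
  dplyr::bind_rows(lapply(names(values), function(p) {
    tibble::tibble(protein_group = p, run_id = names(values[[p]]),
                   log10_abundance = unname(values[[p]]))
  }))
}

test_that("across-sample ratios convert log10 differences to log2", {
  design <- mk_design2()
  ab <- mk_ab(list(P1_HUMAN = c(S1_R1 = 2.0, S1_R2 = 2.0,
                                S3_R1 = 2.3010, S3_R2 = 2.3010)))
  r <- across_sample_ratios(ab, design)
  expect_equal(nrow(r), 2)
  expect_equal(mean(r$log2fc), -1.0, tolerance = 1e-3)
  expect_equal(r$comparison, rep("S1_vs_S3", 2))
})

test_that("proteins missing in any replicate are ignored", {
  design <- mk_design2()
  ab <- mk_ab(list(
    P1_HUMAN = c(S1_R1 = 2, S1_R2 = 2, S3_R1 = 2, S3_R2 = 2),
    P2_HUMAN = c(S1_R1 = 2, S3_R1 = 2, S3_R2 = 2)  # missing S1_R2
  ))
  r <- across_sample_ratios(ab, design)
  expect_equal(unique(r$protein_group), "P1_HUMAN")
})

test_that("identical samples give zero fold changes", {
  design <- mk_design2()
  ab <- mk_ab(list(P1_HUMAN = c(S1_R1 = 4.2, S1_R2 = 5.1,
                                S3_R1 = 4.2, S3_R2 = 5.1)))
  expect_equal(across_sample_ratios(ab, design)$log2fc, c(0, 0))
})

test_that("the t-test matches stats::t.test on random data", {
  withr::local_seed(21)
  design <- mk_design2(n_rep = 4)
  for (i in 1:25) {
    x <- rnorm(4, 5, 0.2)
    y <- rnorm(4, 5.3, 0.2)
    ab <- mk_ab(list(P_HUMAN = setNames(c(x, y),
                                        c(paste0("S1_R", 1:4),
                                          paste0("S3_R", 1:4)))))
    for (ve in c(TRUE, FALSE)) {
      got <- ttest_diff(ab, design, var_equal = ve)
      want <- stats::t.test(x, y, var.equal = ve)
      expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
      expect_equal(got$mean_log2fc, (mean(x) - mean(y)) * log2(10),
                   tolerance = 1e-12)
    }
  }
})

test_that("the t-test p-value matches a textbook t CDF computation", {
  design <- mk_design2(n_rep = 4)
  a <- c(1.0, 1.1, 0.9, 1.0)
  b <- c(2.0, 2.1, 1.9, 2.0)
  ab <- mk_ab(list(P_HUMAN = setNames(c(a, b), c(paste0("S1_R", 1:4),
                                                 paste0("S3_R", 1:4)))))
  got <- ttest_diff(ab, design)
  # independent closed-form computation of the pooled two-sample statistic
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_oracle <- 2 * stats::pt(-abs(t_stat), df = 6)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-10)
})

test_that("degenerate groups yield p = 1 or undefined, never 0", {
  design <- mk_design2(n_rep = 3)
  same <- mk_ab(list(P_HUMAN = setNames(c(1, 1.1, 0.9, 1, 1.1, 0.9),
                                        c(paste0("S1_R", 1:3),
                                          paste0("S3_R", 1:3)))))
  expect_equal(ttest_diff(same, design)$p_value, 1)

  const <- mk_ab(list(P_HUMAN = setNames(c(1, 1, 1, 2, 2, 2),
                                         c(paste0("S1_R", 1:3),
                                           paste0("S3_R", 1:3)))))
  expect_true(is.na(ttest_diff(const, design)$p_value))
})

test_that("significance cutoffs are strict on both dimensions", {
  res <- tibble::tibble(
    protein_group = paste0("P", 1:4), species = "human",
    sample = "S1", reference = "S3", comparison = "S1_vs_S3",
    mean_log2fc = c(-1.5, -1.0, -1.5, -1.5),
    p_value = c(0.005, 0.005, 0.01, NA),
    n_pairs = 4L
  )
  out <- classify_hits(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("false-positive counts are non-increasing in the FC cutoff", {
  withr::local_seed(31)
  res <- tibble::tibble(
    protein_group = paste0("P", 1:200, "_HUMAN"), species = "human",
    sample = "S1", reference = "S3", comparison = "S1_vs_S3",
    mean_log2fc = rnorm(200, 0, 1.2),
    p_value = runif(200)^2,
    n_pairs = 4L
  )
  fps <- vapply(c(0, 0.5, 1, 1.5, 2), function(fc) {
    sum(classify_hits(res, fc_cut = fc)$significant)
  }, numeric(1))
  expect_true(all(diff(fps) <= 0))
})

test_that("PR construction reproduces enumerated curves", {
  mk_res <- function(scores, labels) {
    list(
      results = tibble::tibble(
        protein_group = paste0("P", seq_along(scores)),
        species = "x", sample = "S1", reference = "S3",
        comparison = "S1_vs_S3", mean_log2fc = scores,
        p_value = 0.5, n_pairs = 4L
      ),
      truth = tibble::tibble(protein_group = paste0("P", seq_along(scores)),
                             is_positive = labels)
    )
  }
  # perfect separation: precision 1 at every threshold
  f <- mk_res(c(-4, -3, -2, -1), c(TRUE, TRUE, FALSE, FALSE))
  pr <- precision_recall(f$results, f$truth)
  expect_equal(pr$precision[pr$threshold <= -3], c(1, 1))

  # alternating positives/negatives: the four enumerated curve points
  f <- mk_res(c(-4, -3, -2, -1), c(TRUE, FALSE, TRUE, FALSE))
  pr <- precision_recall(f$results, f$truth)
  expect_equal(pr$recall, c(0.5, 0.5, 1.0, 1.0))
  expect_equal(pr$precision, c(1.0, 0.5, 2 / 3, 0.5))

  # all scores tied: single point at the prevalence
  f <- mk_res(rep(-1, 4), c(TRUE, FALSE, TRUE, FALSE))
  pr <- precision_recall(f$results, f$truth)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 1)

  # positives only above zero: error (nothing rankable)
  f <- mk_res(c(1, -2), c(TRUE, FALSE))
  expect_error(precision_recall(f$results, f$truth), "no true positives")
})

test_that("PR curves match the brute-force oracle on random instances", {
  withr::local_seed(41)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    scores <- round(-runif(n, 0, 3), sample(1:2, 1))  # ties likely
    labels <- runif(n) < 0.4
    neg <- scores < 0
    if (!any(labels & neg)) labels[which(neg)[1]] <- TRUE
    res <- tibble::tibble(
      protein_group = paste0("P", seq_len(n)), species = "x",
      sample = "S1", reference = "S3", comparison = "S1_vs_S3",
      mean_log2fc = scores, p_value = 0.5, n_pairs = 4L
    )
    truth <- tibble::tibble(protein_group = paste0("P", seq_len(n)),
                            is_positive = labels)
    got <- precision_recall(res, truth)
    want <- pr_oracle(scores[neg], labels[neg])
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
})

test_that("missingness accounting follows the reference denominator", {
  design <- mk_design2()
  full <- mk_ab(list(
    P1_HUMAN = c(S1_R1 = 2, S1_R2 = 2, S3_R1 = 2, S3_R2 = 2),
    P2_HUMAN = c(S1_R1 = 2, S1_R2 = 2, S3_R1 = 2, S3_R2 = 2)
  ))
  m <- missingness_summary(full, design)
  expect_equal(m$missing_fraction, 0)

  ten <- lapply(seq_len(10), function(i) {
    c(S1_R1 = 2, S1_R2 = 2, S3_R1 = 2, S3_R2 = 2)
  })
  names(ten) <- paste0("P", 1:10, "_HUMAN")
  ab10 <- mk_ab(ten)
  ab10 <- ab10[!(ab10$protein_group == "P1_HUMAN" & ab10$run_id == "S1_R2"), ]
  m10 <- missingness_summary(ab10, design)
  expect_equal(m10$missing_fraction, 0.1)

  # a reference set disjoint from the observed proteins is fully missing
  m_disjoint <- missingness_summary(full, design,
                                    reference_proteins = c("Q1_HUMAN", "Q2_HUMAN"))
  expect_equal(m_disjoint$missing_fraction, 1)
})

test_that("restriction to a reference set is a plain intersection", {
  res <- tibble::tibble(protein_group = paste0("P", 1:4), x = 1:4)
  expect_message(out <- restrict_to_reference_set(res, paste0("P", 1:4)),
                 "4 -> 4")
  expect_equal(out, res)
  expect_message(out2 <- restrict_to_reference_set(res, c("Q1", "Q2")))
  expect_equal(nrow(out2), 0)
  expect_message(out3 <- restrict_to_reference_set(res, c("P2", "P3", "Q9")))
  expect_equal(out3$protein_group, c("P2", "P3"))
})
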