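pol <- filter_policy("sis_basic")

test_that("channel pairing joins L/H partners and rejects duplicates", {
  rec <- dplyr::bind_rows(
    make_pair_records(key = "A/2"),
    make_record(precursor_key = "B/2", channel = "L")
  )
  pairs <- pair_channels(rec, pol)
  expect_equal(nrow(pairs), 2)
  a <- pairs[pairs$precursor_key == "A/2", ]
  expect_true(a$has_L && a$has_H)
  b <- pairs[pairs$precursor_key == "B/2", ]
  expect_true(b$has_L)
  expect_false(b$has_H)

  dup <- dplyr::bind_rows(make_pair_records(key = "A/2"),
                          make_record(precursor_key = "A/2", channel = "H"))
  expect_error(pair_channels(dup, pol), "duplicate H record")
})

test_that("precursor ratios follow log10(L/H) per quantification column", {
  rec <- make_pair_records(l_ms1 = 300, l_prec = 200, h_ms1 = 100, h_prec = 100)
  pairs <- select_sis_pairs(pair_channels(rec, pol), pol)
  ratios <- precursor_log_ratios(pairs, pol)
  expect_setequal(ratios$source_column, c("ms1", "precursor"))
  expect_equal(sort(ratios$log10_lh), sort(c(log10(3), log10(2))))
  expect_equal(round(sort(ratios$log10_lh), 4), c(0.3010, 0.4771))
})

test_that("a zero column is suppressed; the other survives under rule any", {
  pol_any <- filter_policy("sis_basic", translated_validity = "any")
  rec <- make_pair_records(l_ms1 = 100, l_prec = 0, h_ms1 = 100, h_prec = 50)
  pairs <- select_sis_pairs(pair_channels(rec, pol_any), pol_any)
  ratios <- precursor_log_ratios(pairs, pol_any)
  expect_equal(ratios$source_column, "ms1")
  expect_equal(ratios$log10_lh, 0)

  # under rule `both` the invalid light side suppresses all ratios
  pairs_b <- select_sis_pairs(pair_channels(rec, pol), pol)
  expect_equal(nrow(precursor_log_ratios(pairs_b, pol)), 0)
})

test_that("identical channels give ratios of exactly zero", {
  rec <- make_pair_records(l_ms1 = 120, l_prec = 80, h_ms1 = 120, h_prec = 80)
  pairs <- select_sis_pairs(pair_channels(rec, pol), pol)
  ratios <- precursor_log_ratios(pairs, pol)
  expect_equal(ratios$log10_lh, c(0, 0))
})

test_that("protein rollup is the pooled median with the even-count convention", {
  mk <- function(vals) {
    tibble::tibble(run_id = "R1", protein_group = "P1",
                   precursor_key = paste0("K", seq_along(vals), "/2"),
                   source_column = "ms1", log10_lh = vals, rescued = FALSE)
  }
  expect_equal(protein_log_ratios(mk(c(0.2, 0.4, 0.9)))$log10_lh_protein, 0.4)
  expect_equal(protein_log_ratios(mk(c(0.1, 0.3)))$log10_lh_protein, 0.2)
  expect_equal(protein_log_ratios(mk(0.7))$log10_lh_protein, 0.7)
  expect_equal(protein_log_ratios(mk(c(0.2, 0.4, 0.9)))$n_ratios, 3L)
})

test_that("protein rollup matches a sort-based median oracle", {
  withr::local_seed(42)
  for (i in 1:200) {
    n <- sample(1:9, 1)
    vals <- rnorm(n)
    got <- protein_log_ratios(tibble::tibble(
      run_id = "R1", protein_group = "P1",
      precursor_key = paste0("K", seq_len(n), "/2"),
      source_column = "ms1", log10_lh = vals, rescued = FALSE
    ))$log10_lh_protein
    expect_equal(got, median_oracle(vals))
  }
})

test_that("rescued_fraction counts the rescued share of contributing ratios", {
  ratios <- tibble::tibble(
    run_id = "R1", protein_group = "P1",
    precursor_key = c("A/2", "B/2", "C/2", "D/2"),
    source_column = "ms1", log10_lh = c(0.1, 0.2, 0.3, 0.4),
    rescued = c(TRUE, FALSE, FALSE, TRUE)
  )
  expect_equal(protein_log_ratios(ratios)$rescued_fraction, 0.5)
})

test_that("global heavy intensity is the median log10 of per-run sums", {
  mk_h <- function(run, ms1, prec = 0) {
    make_record(run_id = run, channel = "H", ms1 = ms1, prec = prec)
  }
  rec <- dplyr::bind_rows(mk_h("R1", 100), mk_h("R2", 1000), mk_h("R3", 10000))
  gh <- global_heavy_intensity(rec, pol)
  expect_equal(gh$log10_heavy_global, 3)
  expect_equal(gh$n_samples_used, 3L)

  single <- global_heavy_intensity(mk_h("R1", 250, 250), pol)
  expect_equal(single$log10_heavy_global, log10(500), tolerance = 1e-12)

  # zero-sum runs are excluded from the median, not taken as log10(0)
  with_zero <- dplyr::bind_rows(mk_h("R1", 0, 0), mk_h("R2", 100))
  gh0 <- global_heavy_intensity(with_zero, pol)
  expect_equal(gh0$log10_heavy_global, 2)
  expect_equal(gh0$n_samples_used, 1L)
})

test_that("missing intensities count as zero inside the heavy per-run sum", {
  rec <- dplyr::bind_rows(
    make_record(run_id = "R1", channel = "H", precursor_key = "A/2",
                ms1 = 100, prec = NA),
    make_record(run_id = "R1", channel = "H", precursor_key = "B/2",
                ms1 = NA, prec = 300)
  )
  expect_equal(global_heavy_intensity(rec, pol)$log10_heavy_global, log10(400))
})

test_that("light abundance adds the ratio and the global heavy term", {
  pq <- tibble::tibble(protein_group = c("P1", "P2"), run_id = "R1",
                       log10_lh_protein = c(0.3010, 0), n_ratios = 1L,
                       rescued_fraction = 0)
  gh <- tibble::tibble(protein_group = c("P1", "P2"),
                       log10_heavy_global = c(5, 4.2), n_samples_used = 3L)
  ab <- light_abundances(pq, gh)
  expect_equal(ab$log10_abundance, c(5.3010, 4.2))
  expect_equal(attr(ab, "method"), "sis")
  expect_false(attr(ab, "normalized"))

  gh_missing <- gh[1, ]
  expect_error(light_abundances(pq, gh_missing), "P2")
})

test_that("scaling all heavy intensities cancels out of the abundances", {
  withr::local_seed(11)
  rec <- random_paired_records(n_proteins = 6, n_precursors = 4,
                               runs = c("R1", "R2", "R3"))
  scaled <- dplyr::mutate(
    rec,
    ms1_translated = ifelse(channel == "H", ms1_translated * 10, ms1_translated),
    precursor_translated = ifelse(channel == "H", precursor_translated * 10,
                                  precursor_translated)
  )
  ab <- function(r) {
    kept <- select_sis_pairs(pair_channels(r, pol), pol)
    pq <- protein_log_ratios(precursor_log_ratios(kept, pol))
    light_abundances(pq, global_heavy_intensity(r, pol))
  }
  a0 <- dplyr::arrange(ab(rec), protein_group, run_id)
  a1 <- dplyr::arrange(ab(scaled), protein_group, run_id)
  # ratios drop by 1, the global heavy term rises by 1; abundances unchanged
  expect_equal(a1$log10_abundance, a0$log10_abundance, tolerance = 1e-12)
})

test_that("balanced per-run intensity scaling leaves protein ratios unchanged", {
  withr::local_seed(12)
  rec <- random_paired_records(n_proteins = 5, n_precursors = 3)
  scaled <- dplyr::mutate(
    rec,
    ms1_translated = ifelse(run_id == "R1", ms1_translated * 7.3, ms1_translated),
    precursor_translated = ifelse(run_id == "R1", precursor_translated * 7.3,
                                  precursor_translated)
  )
  pq <- function(r) {
    kept <- select_sis_pairs(pair_channels(r, pol), pol)
    dplyr::arrange(protein_log_ratios(precursor_log_ratios(kept, pol)),
                   protein_group, run_id)
  }
  expect_equal(pq(scaled)$log10_lh_protein, pq(rec)$log10_lh_protein,
               tolerance = 1e-12)
})

test_that("scaling only light intensities shifts ratios by exactly log10(c)", {
  withr::local_seed(13)
  rec <- random_paired_records(n_proteins = 5, n_precursors = 3)
  c_scale <- 4.2
  scaled <- dplyr::mutate(
    rec,
    ms1_translated = ifelse(run_id == "R2" & channel == "L",
                            ms1_translated * c_scale, ms1_translated),
    precursor_translated = ifelse(run_id == "R2" & channel == "L",
                                  precursor_translated * c_scale,
                                  precursor_translated)
  )
  pq <- function(r) {
    kept <- select_sis_pairs(pair_channels(r, pol), pol)
    dplyr::arrange(protein_log_ratios(precursor_log_ratios(kept, pol)),
                   protein_group, run_id)
  }
  p0 <- pq(rec)
  p1 <- pq(scaled)
  shift <- p1$log10_lh_protein - p0$log10_lh_protein
  expect_equal(shift[p0$run_id == "R2"],
               rep(log10(c_scale), sum(p0$run_id == "R2")), tolerance = 1e-12)
  expect_equal(shift[p0$run_id != "R2"], rep(0, sum(p0$run_id != "R2")))
})

test_that("LFQ abundances are log10 PG.MaxLFQ, one entry per protein x run", {
  rec <- dplyr::bind_rows(
    make_record(precursor_key = "A/2", pg_maxlfq = 10000),
    make_record(precursor_key = "B/2", pg_maxlfq = 10000)
  )
  ab <- lfq_abundances(rec)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$log10_abundance, 4)
  expect_equal(attr(ab, "method"), "lfq")

  conflict <- dplyr::bind_rows(
    make_record(precursor_key = "A/2", pg_maxlfq = 10000),
    make_record(precursor_key = "B/2", pg_maxlfq = 9000)
  )
  expect_error(lfq_abundances(conflict), "conflicting")

  nonpos <- dplyr::bind_rows(
    make_record(protein_group = "P1", precursor_key = "A/2", pg_maxlfq = 100),
    make_record(protein_group = "P2", precursor_key = "B/2", pg_maxlfq = 0)
  )
  expect_warning(ab2 <- lfq_abundances(nonpos), "nonpositive")
  expect_equal(ab2$protein_group, "P1")
})

test_that("sis_quantify chains the stages and summarises via glance", {
  s <- small_sim(seed = 5, n_proteins = 20)
  q <- sis_quantify(s$records, filter_policy("sis_requant"))
  expect_s3_class(q, "sis_quant")
  expect_identical(tidy(q), q$abundance)
  g <- glance(q)
  expect_equal(g$mode, "sis_requant")
  expect_equal(g$n_precursor_ratios, nrow(q$ratios))
  # abundance decomposes exactly into ratio + global heavy
  chk <- dplyr::inner_join(q$abundance, q$protein_lh,
                           by = c("protein_group", "run_id"))
  chk <- dplyr::inner_join(chk, q$global_heavy, by = "protein_group")
  expect_equal(chk$log10_abundance,
               chk$log10_lh_protein + chk$log10_heavy_global)
})
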