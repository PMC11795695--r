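# Fixture builders used across the test files. Everything is generated in
# code; no binary fixtures.

# A precursor record row with sensible defaults: confident q-values,
# charge 2, both intensity columns positive.
make_record <- function(run_id = "R1", protein_group = "P1",
                        precursor_key = "PEPTIDEK/2", channel = "L",
                        precursor_charge = 2L,
                        ms1 = 100, prec = 100,
                        global_q = 0.001, channel_q = 0.001,
                        lib_pg_q = 0.001, lib_q = 0.001,
                        pg_maxlfq = NA_real_, contaminant = FALSE) {
  tibble::tibble(
    run_id = run_id, protein_group = protein_group,
    precursor_key = precursor_key, channel = channel,
    precursor_charge = precursor_charge,
    ms1_translated = ms1, precursor_translated = prec,
    global_pg_qvalue = global_q, channel_qvalue = channel_q,
    lib_pg_qvalue = lib_pg_q, lib_qvalue = lib_q,
    pg_maxlfq = pg_maxlfq, is_contaminant = contaminant
  )
}

# An L/H record pair for one precursor in one run.
make_pair_records <- function(run_id = "R1", protein_group = "P1",
                              key = "PEPTIDEK/2",
                              l_ms1 = 300, l_prec = 200,
                              h_ms1 = 100, h_prec = 100,
                              l_channel_q = 0.001, h_channel_q = 0.001) {
  dplyr::bind_rows(
    make_record(run_id, protein_group, key, "L", ms1 = l_ms1, prec = l_prec,
                channel_q = l_channel_q),
    make_record(run_id, protein_group, key, "H", ms1 = h_ms1, prec = h_prec,
                channel_q = h_channel_q)
  )
}

# Random multi-protein record table with L/H partners for every precursor;
# all q-values confident so filtering keeps everything. Used by the
# algebraic-invariance properties.
random_paired_records <- function(n_proteins = 5, n_precursors = 3,
                                  runs = c("R1", "R2")) {
  grid <- tidyr::expand_grid(p = seq_len(n_proteins),
                             j = seq_len(n_precursors),
                             run_id = runs)
  dplyr::bind_rows(lapply(c("L", "H"), function(ch) {
    tibble::tibble(
      run_id = grid$run_id,
      protein_group = paste0("P", grid$p),
      precursor_key = paste0("PEP", grid$p, "_", grid$j, "/2"),
      channel = ch,
      precursor_charge = 2L,
      ms1_translated = 10^runif(nrow(grid), 2, 6),
      precursor_translated = 10^runif(nrow(grid), 2, 6),
      global_pg_qvalue = 0.001, channel_qvalue = 0.001,
      lib_pg_qvalue = 0.001, lib_qvalue = 0.001,
      pg_maxlfq = NA_real_, is_contaminant = FALSE
    )
  }))
}

# Write a diann-dialect report tibble to a TSV file.
write_report_tsv <- function(report, path = withr::local_tempfile(fileext = ".tsv",
                                                                  .local_envir = parent.frame())) {
  readr::write_tsv(report, path, progress = FALSE)
  path
}

# A minimal valid diann-dialect raw report tibble.
minimal_report <- function() {
  tibble::tibble(
    Run = c("R1", "R1", "R2"),
    Protein.Group = c("P1", "P1", "P1"),
    Precursor.Id = c("PEPTIDEK2", "PEPTIDEK(SILAC-K-H)2", "PEPTIDEK2"),
    Modified.Sequence = c("PEPTIDEK", "PEPTIDEK(SILAC-K-H)", "PEPTIDEK"),
    Precursor.Charge = c(2L, 2L, 2L),
    Channel = c("L", "H", "L"),
    Ms1.Translated = c(300, 100, 250),
    Precursor.Translated = c(200, 100, 210),
    Global.PG.Q.Value = 0.001,
    Channel.Q.Value = 0.002,
    Lib.PG.Q.Value = 0.001,
    Lib.Q.Value = 0.001,
    PG.MaxLFQ = c(500, 500, 460)
  )
}

# Independent sort-based median oracle (no stats::median).
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Brute-force PR oracle: for every distinct score threshold, count calls
# and true positives by direct enumeration.
pr_oracle <- function(score, is_positive) {
  thresholds <- sort(unique(score))
  do.call(rbind, lapply(thresholds, function(s) {
    called <- score <= s
    data.frame(threshold = s,
               n_called = sum(called),
               true_positives = sum(is_positive & called),
               precision = sum(is_positive & called) / sum(called),
               recall = sum(is_positive & called) / sum(is_positive))
  }))
}

# Tiny end-to-end simulation, cheap enough for property loops.
small_sim <- function(seed = 1, n_proteins = 30, n_replicates = 2, ...) {
  design <- benchmark_design(n_replicates = n_replicates)
  cfg <- simulation_config(n_proteins_per_species = n_proteins,
                           precursors_per_protein = 3L,
                           seed = seed, ...)
  sim <- simulate_report(design, cfg)
  list(design = design, config = cfg, sim = sim,
       records = flag_contaminants(records_from_report(sim$report),
                                   prefix = "Cont_"))
}
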