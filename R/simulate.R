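# Synthetic two-species spike-in benchmark generator with known ground truth.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# deterministic residue encoding of an integer (no RNG), used to make
# peptide sequences unique across proteins and precursors
.encode_residues <- function(i, width) {
  out <- character(width)
  for (k in seq_len(width)) {
    out[k] <- .aa_alphabet[(i %% 20L) + 1L]
    i <- i %/% 20L
  }
  paste(out, collapse = "")
}

.protein_names <- function(species, n) {
  prefix <- toupper(substr(species, 1, 1))
  sprintf("%s%04d_%s", prefix, seq_len(n), toupper(species))
}

#' Construct a simulation configuration
#'
#' Parameters of the synthetic two-species benchmark generator. The defaults
#' reproduce the mixed-species spike-in design: two proteomes where the
#' anchor species is constant across samples and the second species is
#' diluted (down to 1:50), a heavy spike-in channel at a configurable excess
#' over the maximum light amount, two correlated quantification columns per
#' record, intensity-dependent detection, and channel q-values with a small
#' fraction of bad identifications.
#'
#' @param n_proteins_per_species Proteins simulated per species (default 500).
#' @param precursors_per_protein Either a single integer (fixed count) or a
#'   length-2 range sampled uniformly per protein. Default 5.
#' @param spike_excess Heavy spike-in amount relative to the maximum light
#'   sample amount (paper sweep: 2, 5, 20; default 2).
#' @param light_amounts Named list: species -> named numeric vector of
#'   relative light amounts per sample. `NULL` (default) derives it from a
#'   [benchmark_design()]: anchor species constant 1, diluted species at the
#'   design's dilution factors.
#' @param baseline_log10_mean,baseline_log10_sd Protein baseline intensity
#'   distribution on the log10 scale (defaults 4.5 and 0.8, spanning the
#'   typical 3-7 decades of DIA precursor intensities).
#' @param precursor_log10_sd Spread of per-precursor ionisation efficiency
#'   around the protein baseline (log10; default 0.6).
#' @param measurement_noise_sd Log10-scale measurement noise applied
#'   independently per channel (default 0.1).
#' @param column_correlation Correlation between the Ms1 and Precursor
#'   translated columns' noise (default 0.8).
#' @param detection_midpoint,detection_slope Logistic detection model on the
#'   true log10 intensity: a record is present with probability
#'   `plogis(slope * (log10_intensity - midpoint))`. `midpoint = -Inf` turns
#'   detection off (everything observed). Defaults 2.4 and 2.5.
#' @param fraction_bad Fraction of records that are bad identifications,
#'   with Channel.Q.Value ~ Uniform(0,1) instead of Beta(1, 99) (default 0.02).
#' @param contaminant_fraction Contaminant proteins injected, as a fraction
#'   of the species proteins (light channel only, accession prefix `Cont_`;
#'   default 0.01).
#' @param seed Integer master seed; fully determines the output.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_proteins_per_species = 500L,
                              precursors_per_protein = 5L,
                              spike_excess = 2,
                              light_amounts = NULL,
                              baseline_log10_mean = 4.5,
                              baseline_log10_sd = 0.8,
                              precursor_log10_sd = 0.6,
                              measurement_noise_sd = 0.1,
                              column_correlation = 0.8,
                              detection_midpoint = 2.4,
                              detection_slope = 2.5,
                              fraction_bad = 0.02,
                              contaminant_fraction = 0.01,
                              seed = 1L) {
  stopifnot(n_proteins_per_species >= 1,
            length(precursors_per_protein) %in% 1:2,
            all(precursors_per_protein >= 1),
            spike_excess > 0,
            measurement_noise_sd >= 0,
            column_correlation >= 0, column_correlation <= 1,
            fraction_bad >= 0, fraction_bad <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  structure(
    list(n_proteins_per_species = as.integer(n_proteins_per_species),
         precursors_per_protein = as.integer(precursors_per_protein),
         spike_excess = spike_excess,
         light_amounts = light_amounts,
         baseline_log10_mean = baseline_log10_mean,
         baseline_log10_sd = baseline_log10_sd,
         precursor_log10_sd = precursor_log10_sd,
         measurement_noise_sd = measurement_noise_sd,
         column_correlation = column_correlation,
         detection_midpoint = detection_midpoint,
         detection_slope = detection_slope,
         fraction_bad = fraction_bad,
         contaminant_fraction = contaminant_fraction,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

.resolve_light_amounts <- function(design, config) {
  if (!is.null(config$light_amounts)) {
    la <- config$light_amounts
    for (s in names(la)) {
      if (!setequal(names(la[[s]]), design$samples)) {
        abort(paste0("light_amounts for species '", s,
                     "' must be named by the design's samples"))
      }
      la[[s]] <- la[[s]][design$samples]
    }
    return(la)
  }
  if (is.null(design$dilution_factors)) {
    abort("config$light_amounts is NULL and the design carries no dilution factors")
  }
  anchor <- setNames(rep(1, length(design$samples)), design$samples)
  la <- list(anchor, design$dilution_factors[design$samples])
  names(la) <- c(design$anchor_species, design$diluted_species %||% "diluted")
  la
}

# simulation protein roster: names, species, light amounts (deterministic)
.sim_proteins <- function(design, config) {
  la <- .resolve_light_amounts(design, config)
  n <- config$n_proteins_per_species
  tabs <- lapply(names(la), function(sp) {
    tibble::tibble(protein_group = .protein_names(sp, n),
                   species = sp,
                   amounts = rep(list(la[[sp]]), n))
  })
  n_cont <- round(config$contaminant_fraction * n * length(la))
  if (n_cont > 0) {
    const <- setNames(rep(1, length(design$samples)), design$samples)
    tabs <- c(tabs, list(tibble::tibble(
      protein_group = sprintf("Cont_C%03d", seq_len(n_cont)),
      species = "contaminant",
      amounts = rep(list(const), n_cont)
    )))
  }
  dplyr::bind_rows(tabs)
}

#' Simulate a DIA-NN style multiplexed report with ground truth
#'
#' Generates a synthetic `report.tsv`-shaped tibble in the diann dialect
#' together with the per-protein ground truth. Per protein, a baseline
#' intensity and per-precursor offsets are drawn; true light intensities
#' scale with the sample's composition factor and true heavy intensities
#' with `spike_excess` times the maximum light amount, so the heavy channel
#' is identical across runs up to noise. The two quantification columns are
#' correlated noisy observations of the same true intensity; records are
#' retained under a logistic intensity-dependent detection model (heavier
#' spike-in is thus more detectable than diluted light signal); channel
#' q-values come from a good/bad mixture; contaminant proteins are injected
#' light-only. Random streams are per-protein substreams derived from the
#' master seed, so changing the replicate count does not reshuffle protein
#' baselines.
#'
#' @param design A [design_spec()] (typically [benchmark_design()]).
#' @param config A [simulation_config()].
#' @return A list with `report` (tibble in diann columns, one row per
#'   detected precursor x run x channel), `truth` (tibble: protein_group,
#'   species, sample, light_amount) and the `design` and `config` echoed.
#' @export
simulate_report <- function(design, config) {
  stopifnot(inherits(design, "design_spec"),
            inherits(config, "simulation_config"))
  proteins <- .sim_proteins(design, config)
  n_prot <- nrow(proteins)

  set.seed(config$seed)
  protein_seeds <- sample.int(2147483646L, n_prot)

  runs <- design$run_to_sample
  n_runs <- nrow(runs)
  sd_m <- config$measurement_noise_sd
  rho <- config$column_correlation
  ppp <- config$precursors_per_protein

  rows <- purrr::pmap(
    list(proteins$protein_group, proteins$species, proteins$amounts,
         protein_seeds, seq_len(n_prot)),
    function(pg, species, amounts, pseed, pidx) {
      set.seed(pseed)
      baseline <- rnorm(1, config$baseline_log10_mean, config$baseline_log10_sd)
      k <- if (length(ppp) == 1) ppp else sample(ppp[1]:ppp[2], 1)
      offsets <- rnorm(k, 0, config$precursor_log10_sd)
      charges <- sample(2:3, k, replace = TRUE)
      tail_len <- sample(4:8, k, replace = TRUE)
      tails <- vapply(tail_len, function(len) {
        paste(sample(.aa_alphabet, len, replace = TRUE), collapse = "")
      }, character(1))
      seqs <- paste0(.encode_residues(pidx, 4L),
                     vapply(seq_len(k), .encode_residues, character(1),
                            width = 2L),
                     tails, "K")
      lib_q <- rbeta(k, 1, 999)
      lib_pg_q <- rbeta(1, 1, 999)
      global_pg_q <- rbeta(1, 1, 999)

      channels <- if (species == "contaminant") "L" else c("L", "H")
      grid <- tidyr::expand_grid(prec = seq_len(k),
                                 run = seq_len(n_runs),
                                 channel = channels)
      f_light <- unname(amounts[runs$sample[grid$run]])
      f_max <- max(unname(amounts))
      true_log10 <- baseline + offsets[grid$prec] +
        ifelse(grid$channel == "L",
               log10(f_light),
               log10(config$spike_excess * f_max))
      n <- nrow(grid)
      det_p <- if (is.infinite(config$detection_midpoint) &&
                   config$detection_midpoint < 0) {
        rep(1, n)
      } else {
        plogis(config$detection_slope * (true_log10 - config$detection_midpoint))
      }
      detected <- runif(n) < det_p
      bad <- runif(n) < config$fraction_bad
      channel_q <- ifelse(bad, runif(n), rbeta(n, 1, 99))
      shared <- rnorm(n, 0, sd_m * sqrt(rho))
      e_ms1 <- rnorm(n, 0, sd_m * sqrt(1 - rho))
      e_prec <- rnorm(n, 0, sd_m * sqrt(1 - rho))
      ms1 <- 10^(true_log10 + shared + e_ms1)
      prec_int <- 10^(true_log10 + shared + e_prec)

      keep <- detected
      if (!any(keep)) return(NULL)
      seq_k <- seqs[grid$prec[keep]]
      heavy <- grid$channel[keep] == "H"
      modseq <- ifelse(heavy, paste0(seq_k, "(SILAC-K-H)"), seq_k)
      tibble::tibble(
        Run = runs$run_id[grid$run[keep]],
        Protein.Group = pg,
        Modified.Sequence = modseq,
        Precursor.Charge = charges[grid$prec[keep]],
        Precursor.Id = paste0(modseq, charges[grid$prec[keep]]),
        Channel = grid$channel[keep],
        Ms1.Translated = ms1[keep],
        Precursor.Translated = prec_int[keep],
        Global.PG.Q.Value = global_pg_q,
        Channel.Q.Value = channel_q[keep],
        Lib.PG.Q.Value = lib_pg_q,
        Lib.Q.Value = lib_q[grid$prec[keep]]
      )
    }
  )
  report <- dplyr::bind_rows(rows)

  # PG.MaxLFQ stand-in: per protein x run sum of light Ms1 intensities,
  # constant on every row of that protein x run
  lfq <- dplyr::summarise(
    dplyr::group_by(report[report$Channel == "L", ],
                    .data$Protein.Group, .data$Run),
    PG.MaxLFQ = sum(.data$Ms1.Translated),
    .groups = "drop"
  )
  report <- dplyr::left_join(report, lfq, by = c("Protein.Group", "Run"))
  report <- report[order(report$Run, report$Protein.Group,
                         report$Precursor.Id, report$Channel), ]

  truth <- tidyr::unnest_longer(proteins, "amounts",
                                values_to = "light_amount",
                                indices_to = "sample")
  list(report = tibble::as_tibble(report),
       truth = truth[c("protein_group", "species", "sample", "light_amount")],
       design = design, config = config)
}

#' Ground-truth fold changes per comparison
#'
#' Expected log2 fold change and positive/negative label for every simulated
#' protein and design comparison: anchor-species (and contaminant) proteins
#' have expected log2FC 0 and a negative label; diluted-species proteins
#' have `log2(factor_sample / factor_reference)` and a positive label when
#' the factors differ.
#'
#' @param design A [design_spec()].
#' @param config A [simulation_config()].
#' @return A tibble: `protein_group`, `species`, `sample`, `reference`,
#'   `comparison`, `expected_log2fc`, `is_positive`.
#' @export
ground_truth <- function(design, config) {
  proteins <- .sim_proteins(design, config)
  out <- tidyr::expand_grid(
    dplyr::select(proteins, "protein_group", "species", "amounts"),
    design$comparisons
  )
  out <- dplyr::mutate(
    out,
    f_s = purrr::map2_dbl(.data$amounts, .data$sample, ~ .x[[.y]]),
    f_ref = purrr::map2_dbl(.data$amounts, .data$reference, ~ .x[[.y]]),
    comparison = paste0(.data$sample, "_vs_", .data$reference),
    expected_log2fc = log2(.data$f_s / .data$f_ref),
    is_positive = .data$f_s != .data$f_ref
  )
  dplyr::select(out, "protein_group", "species", "sample", "reference",
                "comparison", "expected_log2fc", "is_positive")
}
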