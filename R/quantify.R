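# Channel pairing, precursor and protein L/H ratios, abundance reconstruction.

#' Pair light and heavy records of each precursor
#'
#' Joins the L and H records sharing a (run, precursor key) into one row and
#' annotates each side with its [channel_pass()] result. Orphan light
#' records (no heavy partner) produce a pair row with `has_H = FALSE`; they
#' are excluded later by [select_sis_pairs()]. Two L or two H records for
#' one key in one run is an error.
#'
#' @param records A precursor record tibble (contaminants flagged).
#' @param policy A [filter_policy()] in a SiS mode.
#' @return A tibble with one row per (run, precursor key): `protein_group`,
#'   intensities `ms1_L`, `ms1_H`, `prec_L`, `prec_H`, presence flags
#'   `has_L`, `has_H` and q-value pass flags `pass_L`, `pass_H`.
#' @export
pair_channels <- function(records, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  dup <- duplicated(records[c("run_id", "precursor_key", "channel")])
  if (any(dup)) {
    ex <- records[which(dup)[1], ]
    abort(paste0("duplicate ", ex$channel, " record for precursor ",
                 ex$precursor_key, " in run ", ex$run_id))
  }
  rec <- dplyr::mutate(records, pass = channel_pass(records, policy))
  wide <- tidyr::pivot_wider(
    dplyr::select(rec, "run_id", "precursor_key", "channel", "protein_group",
                  "ms1_translated", "precursor_translated", "pass"),
    id_cols = c("run_id", "precursor_key"),
    names_from = "channel",
    values_from = c("protein_group", "ms1_translated", "precursor_translated",
                    "pass")
  )
  # a report may contain a single channel only; complete the column set
  for (col in c("protein_group_L", "protein_group_H")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_character_
  }
  for (col in c("ms1_translated_L", "ms1_translated_H",
                "precursor_translated_L", "precursor_translated_H")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  for (col in c("pass_L", "pass_H")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  dplyr::transmute(
    wide,
    run_id = .data$run_id,
    precursor_key = .data$precursor_key,
    # the heavy reference anchors identification; use its protein group
    # when both sides are present
    protein_group = dplyr::coalesce(.data$protein_group_H, .data$protein_group_L),
    ms1_L = .data$ms1_translated_L,
    ms1_H = .data$ms1_translated_H,
    prec_L = .data$precursor_translated_L,
    prec_H = .data$precursor_translated_H,
    has_L = !is.na(.data$protein_group_L),
    has_H = !is.na(.data$protein_group_H),
    pass_L = dplyr::coalesce(.data$pass_L, FALSE),
    pass_H = dplyr::coalesce(.data$pass_H, FALSE)
  )
}

#' Precursor-level log10 light/heavy ratios
#'
#' For each retained pair and each of the two quantification columns
#' (Ms1.Translated, Precursor.Translated), emits `log10(L/H)` when both
#' sides of that column are present and > 0 and each side satisfies the
#' translated-validity rule of the policy. If both columns qualify, both
#' ratios are emitted; a zero, negative or missing value on either side
#' suppresses that column's ratio. Producing no ratio for a pair is allowed.
#'
#' @param pairs Retained pairs from [select_sis_pairs()] (with `rescued`).
#' @param policy The [filter_policy()] used for selection.
#' @return A tibble with columns `run_id`, `protein_group`, `precursor_key`,
#'   `source_column` (`"ms1"` or `"precursor"`), `log10_lh`, `rescued`.
#' @export
precursor_log_ratios <- function(pairs, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  rule <- policy$translated_validity
  valid_L <- translated_valid(pairs$ms1_L, pairs$prec_L, rule)
  valid_H <- translated_valid(pairs$ms1_H, pairs$prec_H, rule)
  pos <- function(x) !is.na(x) & x > 0
  ms1_ok <- valid_L & valid_H & pos(pairs$ms1_L) & pos(pairs$ms1_H)
  prec_ok <- valid_L & valid_H & pos(pairs$prec_L) & pos(pairs$prec_H)

  base <- tibble::tibble(
    run_id = pairs$run_id,
    protein_group = pairs$protein_group,
    precursor_key = pairs$precursor_key,
    rescued = pairs$rescued
  )
  ms1 <- dplyr::mutate(base[ms1_ok, , drop = FALSE],
                       source_column = "ms1",
                       log10_lh = log10(pairs$ms1_L[ms1_ok] / pairs$ms1_H[ms1_ok]))
  prec <- dplyr::mutate(base[prec_ok, , drop = FALSE],
                        source_column = "precursor",
                        log10_lh = log10(pairs$prec_L[prec_ok] / pairs$prec_H[prec_ok]))
  out <- dplyr::bind_rows(ms1, prec)
  dplyr::select(out, "run_id", "protein_group", "precursor_key",
                "source_column", "log10_lh", "rescued")
}

#' Protein-level L/H ratio rollup
#'
#' Protein x run log10 L/H ratios as the median over the pooled precursor
#' ratios of that protein in that run — both quantification columns pooled
#' into one list. Even counts take the mean of the two central values.
#'
#' @param ratios A precursor ratio tibble from [precursor_log_ratios()].
#' @return A tibble per (protein_group, run_id): `log10_lh_protein`,
#'   `n_ratios` (contributing precursor ratios) and `rescued_fraction`.
#' @export
protein_log_ratios <- function(ratios) {
  dplyr::summarise(
    dplyr::group_by(ratios, .data$protein_group, .data$run_id),
    log10_lh_protein = median(.data$log10_lh),
    n_ratios = dplyr::n(),
    rescued_fraction = mean(.data$rescued),
    .groups = "drop"
  )
}

#' Global heavy reference intensity per protein
#'
#' The spike-in reference is identical in every run, so a single global
#' heavy intensity per protein summarises it: per run, the heavy precursor
#' intensities (Ms1.Translated + Precursor.Translated, missing treated as 0
#' within the sum) of the protein are summed; the global value is the median
#' over runs of log10 of these sums. Runs with zero heavy sum are excluded
#' from the median; only heavy records passing [channel_pass()] contribute,
#' in every SiS mode — the heavy reference must always be confident.
#'
#' @param records A precursor record tibble (all channels).
#' @param policy A [filter_policy()] in a SiS mode.
#' @return A tibble per protein_group: `log10_heavy_global`,
#'   `n_samples_used` (runs entering the median).
#' @export
global_heavy_intensity <- function(records, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  h <- records[records$channel == "H" & channel_pass(records, policy), ,
               drop = FALSE]
  sums <- dplyr::summarise(
    dplyr::group_by(h, .data$protein_group, .data$run_id),
    heavy_sum = sum(dplyr::coalesce(.data$ms1_translated, 0) +
                      dplyr::coalesce(.data$precursor_translated, 0)),
    .groups = "drop"
  )
  sums <- sums[sums$heavy_sum > 0, , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(sums, .data$protein_group),
    log10_heavy_global = median(log10(.data$heavy_sum)),
    n_samples_used = dplyr::n(),
    .groups = "drop"
  )
}

#' Reconstruct light protein abundances
#'
#' Light abundance in log10 space is the protein L/H ratio plus the
#' protein's global heavy reference intensity:
#' `abundance(p, r) = log10_lh_protein(p, r) + log10_heavy_global(p)`.
#' Because the heavy term is constant per protein, across-sample abundance
#' differences equal across-sample ratio differences, and a global change
#' of spike-in excess cancels exactly.
#'
#' @param pq Protein ratio tibble from [protein_log_ratios()].
#' @param gh Global heavy index from [global_heavy_intensity()].
#' @return An abundance tibble (protein_group, run_id, `log10_abundance`,
#'   `n_ratios`, `rescued_fraction`) with attributes `method = "sis"` and
#'   `normalized = FALSE`.
#' @export
light_abundances <- function(pq, gh) {
  missing_p <- setdiff(unique(pq$protein_group), gh$protein_group)
  if (length(missing_p) > 0) {
    abort(paste0("protein(s) missing from the global heavy index: ",
                 paste(head(missing_p, 5), collapse = ", "),
                 if (length(missing_p) > 5) " ..." else ""))
  }
  out <- dplyr::inner_join(pq, gh[c("protein_group", "log10_heavy_global")],
                           by = "protein_group")
  out <- dplyr::transmute(
    out,
    protein_group = .data$protein_group,
    run_id = .data$run_id,
    log10_abundance = .data$log10_lh_protein + .data$log10_heavy_global,
    n_ratios = .data$n_ratios,
    rescued_fraction = .data$rescued_fraction
  )
  attr(out, "method") <- "sis"
  attr(out, "normalized") <- FALSE
  out
}

#' LFQ abundance matrix from PG.MaxLFQ
#'
#' The label-free comparator: per protein x run, `log10(PG.MaxLFQ)`. The
#' value must be constant within a protein x run (conflicting values are an
#' error); nonpositive values are dropped with a warning giving the count.
#'
#' @param records An LFQ-filtered record tibble (see [apply_lfq_filters()]).
#' @return An abundance tibble (protein_group, run_id, `log10_abundance`)
#'   with attribute `method = "lfq"`.
#' @export
lfq_abundances <- function(records) {
  vals <- dplyr::distinct(
    records[!is.na(records$pg_maxlfq), c("protein_group", "run_id", "pg_maxlfq")]
  )
  n_distinct <- dplyr::count(
    dplyr::group_by(vals, .data$protein_group, .data$run_id)
  )
  conflict <- n_distinct[n_distinct$n > 1, , drop = FALSE]
  if (nrow(conflict) > 0) {
    abort(paste0("conflicting PG.MaxLFQ values for ",
                 conflict$protein_group[1], " in run ", conflict$run_id[1]))
  }
  n_nonpos <- sum(vals$pg_maxlfq <= 0)
  if (n_nonpos > 0) {
    warn(paste0(n_nonpos, " protein x run entr",
                if (n_nonpos == 1) "y" else "ies",
                " with nonpositive PG.MaxLFQ dropped"))
    vals <- vals[vals$pg_maxlfq > 0, , drop = FALSE]
  }
  out <- dplyr::transmute(vals,
                          protein_group = .data$protein_group,
                          run_id = .data$run_id,
                          log10_abundance = log10(.data$pg_maxlfq))
  attr(out, "method") <- "lfq"
  attr(out, "normalized") <- FALSE
  out
}

#' Run the full SiS quantification chain
#'
#' Convenience wrapper: pair channels, select pairs under the policy's mode,
#' compute precursor ratios, roll up to protein L/H ratios, build the global
#' heavy index and reconstruct light abundances.
#'
#' @param records A precursor record tibble (contaminants flagged).
#' @param policy A [filter_policy()] in a SiS mode (default requantify with
#'   the standard thresholds).
#' @return A `sis_quant` object: a list with elements `ratios` (precursor
#'   level), `protein_lh`, `global_heavy`, `abundance` and the `policy`.
#'   [tidy()] returns the abundance tibble; [glance()] a one-row summary.
#' @export
sis_quantify <- function(records, policy = filter_policy("sis_requant")) {
  pairs <- pair_channels(records, policy)
  kept <- select_sis_pairs(pairs, policy)
  ratios <- precursor_log_ratios(kept, policy)
  pq <- protein_log_ratios(ratios)
  gh <- global_heavy_intensity(records, policy)
  # proteins can acquire ratios purely via requantified light rows whose
  # heavy partner passed; the heavy index is built from the same passing
  # heavy rows, so every quantified protein has an index entry
  ab <- light_abundances(pq, gh)
  structure(
    list(ratios = ratios, protein_lh = pq, global_heavy = gh,
         abundance = ab, policy = policy),
    class = "sis_quant"
  )
}

#' @export
print.sis_quant <- function(x, ...) {
  cat("<sis_quant> mode:", x$policy$mode, "\n")
  cat("  ", dplyr::n_distinct(x$abundance$protein_group), "proteins x",
      dplyr::n_distinct(x$abundance$run_id), "runs;",
      nrow(x$ratios), "precursor ratios (",
      sprintf("%.1f%%", 100 * mean(x$ratios$rescued)), "rescued )\n")
  invisible(x)
}

#' @rdname sis_quantify
#' @param x A `sis_quant` object.
#' @param ... Unused.
#' @method tidy sis_quant
#' @export
tidy.sis_quant <- function(x, ...) {
  x$abundance
}

#' @rdname sis_quantify
#' @method glance sis_quant
#' @export
glance.sis_quant <- function(x, ...) {
  tibble::tibble(
    mode = x$policy$mode,
    n_proteins = dplyr::n_distinct(x$abundance$protein_group),
    n_runs = dplyr::n_distinct(x$abundance$run_id),
    n_precursor_ratios = nrow(x$ratios),
    rescued_fraction = mean(x$ratios$rescued)
  )
}
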