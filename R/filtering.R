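# q-value / charge / contaminant filtering in the three quantification modes.

#' Construct a filter policy
#'
#' Bundles the q-value thresholds and mode used to filter precursor records.
#' All q-value comparisons are strict (`<`); a record sitting exactly at a
#' threshold is excluded, and a missing tested q-value fails its filter.
#'
#' Modes:
#' * `lfq` — label-free: contaminants removed, charge > 1,
#'   `Lib.PG.Q.Value` < 0.01 and `Lib.Q.Value` < 0.01.
#' * `sis_basic` — spike-in SILAC, both channels must pass
#'   `Global.PG.Q.Value` < 0.01 and `Channel.Q.Value` < 0.03.
#' * `sis_requant` — as `sis_basic`, but a light precursor whose heavy
#'   partner passes is rescued even when the light channel itself fails
#'   q-value filtering ("requantify").
#'
#' @param mode Quantification mode, one of `"sis_requant"`, `"sis_basic"`,
#'   `"lfq"`.
#' @param global_pg_q_max Strict upper bound on `Global.PG.Q.Value` (SiS modes).
#' @param channel_q_max Strict upper bound on `Channel.Q.Value` (SiS modes).
#' @param lib_pg_q_max Strict upper bound on `Lib.PG.Q.Value` (LFQ mode).
#' @param lib_q_max Strict upper bound on `Lib.Q.Value` (LFQ mode).
#' @param min_charge_exclusive Precursors must have charge strictly greater
#'   than this (default 1, i.e. singly charged precursors are dropped).
#' @param translated_validity Validity rule for the two quantification
#'   columns: `"both"` requires `Ms1.Translated` and `Precursor.Translated`
#'   to both be present and > 0; `"any"` requires at least one (used for
#'   sparse low-input data with many missing values and zeros).
#' @return A `filter_policy` object (a named list).
#' @export
filter_policy <- function(mode = c("sis_requant", "sis_basic", "lfq"),
                          global_pg_q_max = 0.01,
                          channel_q_max = 0.03,
                          lib_pg_q_max = 0.01,
                          lib_q_max = 0.01,
                          min_charge_exclusive = 1L,
                          translated_validity = c("both", "any")) {
  mode <- match.arg(mode)
  translated_validity <- match.arg(translated_validity)
  thresholds <- c(global_pg_q_max, channel_q_max, lib_pg_q_max, lib_q_max)
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("q-value thresholds must lie in (0, 1]")
  }
  if (min_charge_exclusive < 0) {
    abort("min_charge_exclusive must be >= 0")
  }
  structure(
    list(mode = mode,
         global_pg_q_max = global_pg_q_max,
         channel_q_max = channel_q_max,
         lib_pg_q_max = lib_pg_q_max,
         lib_q_max = lib_q_max,
         min_charge_exclusive = min_charge_exclusive,
         translated_validity = translated_validity),
    class = "filter_policy"
  )
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("<filter_policy>\n")
  cat("  mode:", x$mode, "\n")
  cat("  Global.PG.Q <", x$global_pg_q_max,
      " Channel.Q <", x$channel_q_max, "\n")
  cat("  Lib.PG.Q <", x$lib_pg_q_max, " Lib.Q <", x$lib_q_max, "\n")
  cat("  charge >", x$min_charge_exclusive,
      " translated:", x$translated_validity, "\n")
  invisible(x)
}

#' Apply label-free (LFQ) report filters
#'
#' Retains non-contaminant records with charge above the threshold and
#' library q-values strictly below their cutoffs, then applies the
#' translated-column validity rule. Records with missing tested q-values
#' are removed.
#'
#' @param records A precursor record tibble.
#' @param policy A [filter_policy()] with `mode = "lfq"`.
#' @return The filtered tibble.
#' @export
apply_lfq_filters <- function(records, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  if (policy$mode != "lfq") {
    abort("apply_lfq_filters requires a policy with mode 'lfq'")
  }
  keep <- !records$is_contaminant &
    records$precursor_charge > policy$min_charge_exclusive &
    !is.na(records$lib_pg_qvalue) & records$lib_pg_qvalue < policy$lib_pg_q_max &
    !is.na(records$lib_qvalue) & records$lib_qvalue < policy$lib_q_max &
    translated_valid(records$ms1_translated, records$precursor_translated,
                     policy$translated_validity)
  records[keep, , drop = FALSE]
}

#' Per-channel q-value pass for spike-in SILAC filtering
#'
#' Vectorized predicate: a record passes iff it is not a contaminant, its
#' charge exceeds the threshold, and both `Global.PG.Q.Value` and
#' `Channel.Q.Value` are present and strictly below their cutoffs.
#'
#' @param records A precursor record tibble.
#' @param policy A [filter_policy()] in a SiS mode.
#' @return Logical vector, one element per record.
#' @export
channel_pass <- function(records, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  !records$is_contaminant &
    records$precursor_charge > policy$min_charge_exclusive &
    !is.na(records$global_pg_qvalue) &
    records$global_pg_qvalue < policy$global_pg_q_max &
    !is.na(records$channel_qvalue) &
    records$channel_qvalue < policy$channel_q_max
}

#' Translated-column validity rule
#'
#' DIA-NN reports two quantification columns per precursor, `Ms1.Translated`
#' and `Precursor.Translated`, which may independently be missing or zero.
#' Under rule `"both"` a record is valid only if both are present and > 0;
#' under `"any"` one positive column suffices.
#'
#' @param ms1 Numeric vector of Ms1.Translated intensities (may contain `NA`).
#' @param precursor Numeric vector of Precursor.Translated intensities.
#' @param rule `"both"` or `"any"`.
#' @return Logical vector.
#' @export
translated_valid <- function(ms1, precursor, rule = c("both", "any")) {
  rule <- match.arg(rule)
  ms1_ok <- !is.na(ms1) & ms1 > 0
  prec_ok <- !is.na(precursor) & precursor > 0
  if (rule == "both") ms1_ok & prec_ok else ms1_ok | prec_ok
}

#' Select channel pairs for SiS quantification
#'
#' Applies the mode's retention rule to a channel-paired table (see
#' [pair_channels()]). Under `sis_basic` both the light and the heavy record
#' must pass [channel_pass()]. Under `sis_requant` only the heavy reference
#' must pass: a light record that is present in the report but fails
#' q-value filtering is rescued and marked `rescued = TRUE`. Pairs whose
#' heavy side is absent or fails are always dropped, as are pairs with no
#' light record at all (there is nothing to rescue — light signal is never
#' imputed from heavy).
#'
#' @param pairs A channel-pair tibble from [pair_channels()].
#' @param policy A [filter_policy()] with mode `"sis_basic"` or `"sis_requant"`.
#' @return The retained pairs with a logical `rescued` column.
#' @export
select_sis_pairs <- function(pairs, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  if (!policy$mode %in% c("sis_basic", "sis_requant")) {
    abort("select_sis_pairs requires mode 'sis_basic' or 'sis_requant'")
  }
  heavy_ok <- pairs$has_H & pairs$pass_H
  light_ok <- pairs$has_L & pairs$pass_L
  if (policy$mode == "sis_basic") {
    keep <- heavy_ok & light_ok
    rescued <- rep(FALSE, nrow(pairs))
  } else {
    keep <- heavy_ok & pairs$has_L
    rescued <- keep & !light_ok
  }
  out <- pairs[keep, , drop = FALSE]
  out$rescued <- rescued[keep]
  out
}
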