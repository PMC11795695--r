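# Across-sample ratios, differential abundance testing, PR curves and
# missing-value accounting.

.log2_per_log10 <- log2(10)

# abundance joined with the run map, restricted to one comparison, as a
# replicate-paired wide table; only proteins with a value in every
# replicate of both samples are kept ("missing in any replicate -> ignored")
.paired_abundance <- function(abundance, design, sample, reference) {
  rts <- design$run_to_sample
  ab <- dplyr::inner_join(
    abundance[c("protein_group", "run_id", "log10_abundance")],
    rts, by = "run_id"
  )
  a_s <- ab[ab$sample == sample, c("protein_group", "replicate", "log10_abundance")]
  a_r <- ab[ab$sample == reference, c("protein_group", "replicate", "log10_abundance")]
  reps <- intersect(unique(rts$replicate[rts$sample == sample]),
                    unique(rts$replicate[rts$sample == reference]))
  paired <- dplyr::inner_join(a_s, a_r, by = c("protein_group", "replicate"),
                              suffix = c("_s", "_ref"))
  paired <- paired[paired$replicate %in% reps, , drop = FALSE]
  counts <- table(paired$protein_group)
  complete <- names(counts)[counts == length(reps)]
  paired[paired$protein_group %in% complete, , drop = FALSE]
}

#' Across-sample log2 fold changes per replicate
#'
#' For every design comparison, pairs the runs of the sample and the
#' reference by replicate index and computes per-replicate
#' `log2FC = (log10 abundance difference) * log2(10)`. A protein
#' contributes to a comparison only if it has a value in every replicate of
#' both samples; proteins with missing values in any replicate are ignored.
#'
#' @param abundance A (normalized) abundance tibble.
#' @param design A [design_spec()].
#' @return A tibble: `protein_group`, `sample`, `reference`, `comparison`,
#'   `replicate`, `log2fc`.
#' @export
across_sample_ratios <- function(abundance, design) {
  stopifnot(inherits(design, "design_spec"))
  out <- purrr::pmap(design$comparisons, function(sample, reference) {
    paired <- .paired_abundance(abundance, design, sample, reference)
    tibble::tibble(
      protein_group = paired$protein_group,
      sample = sample,
      reference = reference,
      comparison = paste0(sample, "_vs_", reference),
      replicate = paired$replicate,
      log2fc = (paired$log10_abundance_s - paired$log10_abundance_ref) *
        .log2_per_log10
    )
  })
  dplyr::bind_rows(out)
}

#' Differential abundance by two-sample t-test
#'
#' For every protein with complete replicate coverage in a comparison,
#' tests the per-replicate log2 abundances of the two samples with a
#' two-sided two-sample t-test (Student's pooled-variance test by default,
#' matching the published analysis; Welch via `var_equal = FALSE`).
#' P-values are deliberately not corrected for multiple testing; pass the
#' result through [stats::p.adjust()] if correction is wanted. A zero
#' pooled variance yields an undefined p-value (`NA`, never 0).
#'
#' @param abundance A (normalized) abundance tibble.
#' @param design A [design_spec()]; its `species_rule`, when present,
#'   fills the `species` column.
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @return A `diasis_diff` tibble: `protein_group`, `species`, `sample`,
#'   `reference`, `comparison`, `mean_log2fc`, `p_value`, `n_pairs`.
#' @export
ttest_diff <- function(abundance, design, var_equal = TRUE) {
  stopifnot(inherits(design, "design_spec"))
  res <- purrr::pmap(design$comparisons, function(sample, reference) {
    paired <- .paired_abundance(abundance, design, sample, reference)
    if (nrow(paired) == 0) return(NULL)
    g <- dplyr::summarise(
      dplyr::group_by(paired, .data$protein_group),
      n = dplyr::n(),
      m_s = mean(.data$log10_abundance_s),
      m_r = mean(.data$log10_abundance_ref),
      v_s = stats::var(.data$log10_abundance_s),
      v_r = stats::var(.data$log10_abundance_ref),
      .groups = "drop"
    )
    x <- .two_sample_t(g$m_s, g$v_s, g$n, g$m_r, g$v_r, g$n,
                       var_equal = var_equal)
    tibble::tibble(
      protein_group = g$protein_group,
      sample = sample,
      reference = reference,
      comparison = paste0(sample, "_vs_", reference),
      mean_log2fc = (g$m_s - g$m_r) * .log2_per_log10,
      p_value = x$p,
      n_pairs = g$n
    )
  })
  out <- dplyr::bind_rows(res)
  out$species <- if (!is.null(design$species_rule)) {
    species_of(out$protein_group, design$species_rule)
  } else {
    NA_character_
  }
  out <- dplyr::relocate(out, "species", .after = "protein_group")
  class(out) <- c("diasis_diff", class(out))
  out
}

# vectorized two-sided two-sample t-test on summary statistics;
# p is NA when the variance estimate is 0 or degrees of freedom vanish
.two_sample_t <- function(m1, v1, n1, m2, v2, n2, var_equal = TRUE) {
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  p[!is.finite(se) | se == 0 | df < 1] <- NA_real_
  list(t = t, p = p, df = df)
}

#' Flag significantly differentially abundant proteins
#'
#' Strict cutoffs on both dimensions: significant iff `p_value < p_cut` and
#' `|mean_log2fc| > fc_cut`. An undefined p-value is never significant.
#'
#' @param results A `diasis_diff` tibble from [ttest_diff()].
#' @param p_cut P-value cutoff (strict `<`, default 0.01).
#' @param fc_cut Absolute log2FC cutoff (strict `>`, default 1).
#' @return `results` with a logical `significant` column.
#' @export
classify_hits <- function(results, p_cut = 0.01, fc_cut = 1) {
  results$significant <- !is.na(results$p_value) &
    results$p_value < p_cut &
    abs(results$mean_log2fc) > fc_cut
  attr(results, "p_cut") <- p_cut
  attr(results, "fc_cut") <- fc_cut
  results
}

#' Precision-recall curve over negative fold changes
#'
#' Builds the PR curve for separating truly diluted (positive) from
#' unchanged (negative) proteins, restricted to proteins with a negative
#' observed mean log2FC — in the benchmark the diluted species can only go
#' down, so positive fold changes carry no signal. Proteins are ranked by
#' increasing log2FC (most negative first) or increasing p-value; the
#' threshold sweeps over the distinct scores, tied scores entering
#' together. The recall denominator is the number of true positives in the
#' restricted set.
#'
#' @param results A `diasis_diff` tibble.
#' @param truth A tibble with `protein_group`, `is_positive` and optionally
#'   `comparison` (joined on when present, e.g. from [ground_truth()]).
#' @param ranking `"log2fc"` or `"pvalue"`.
#' @return A tibble per comparison and threshold: `ranking`, `threshold`,
#'   `n_called`, `true_positives`, `precision`, `recall`.
#' @export
precision_recall <- function(results, truth, ranking = c("log2fc", "pvalue")) {
  ranking <- match.arg(ranking)
  by <- if ("comparison" %in% names(truth)) {
    c("protein_group", "comparison")
  } else {
    "protein_group"
  }
  joined <- dplyr::inner_join(
    results, dplyr::distinct(truth[unique(c(by, "is_positive"))]), by = by
  )
  joined <- joined[joined$mean_log2fc < 0, , drop = FALSE]
  if (ranking == "pvalue") {
    joined <- joined[!is.na(joined$p_value), , drop = FALSE]
  }
  out <- lapply(split(joined, joined$comparison), function(d) {
    if (sum(d$is_positive) == 0) {
      abort(paste0("no true positives with negative fold change in ",
                   d$comparison[1]))
    }
    score <- if (ranking == "log2fc") d$mean_log2fc else d$p_value
    ord <- order(score)
    score <- score[ord]
    pos <- d$is_positive[ord]
    thresholds <- unique(score)
    n_called <- vapply(thresholds, function(s) sum(score <= s), integer(1))
    tp <- vapply(thresholds, function(s) sum(pos[score <= s]), integer(1))
    tibble::tibble(
      comparison = d$comparison[1],
      ranking = ranking,
      threshold = thresholds,
      n_called = n_called,
      true_positives = tp,
      precision = tp / n_called,
      recall = tp / sum(pos)
    )
  })
  dplyr::bind_rows(out)
}

#' Missing-value accounting per species and comparison
#'
#' Fraction of proteins for which no complete across-sample ratio (a value
#' in every replicate of both samples) could be formed, per species and
#' comparison, relative to a reference protein set — by default all
#' proteins observed anywhere in the abundance table, configurable to e.g.
#' the union of proteins seen by any method under comparison.
#'
#' @param abundance An abundance tibble.
#' @param design A [design_spec()] (with a `species_rule`).
#' @param reference_proteins Character vector defining the denominator;
#'   default `unique(abundance$protein_group)`.
#' @return A tibble: `comparison`, `species`, `n_reference`, `n_complete`,
#'   `missing_fraction`.
#' @export
missingness_summary <- function(abundance, design, reference_proteins = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(reference_proteins)) {
    reference_proteins <- unique(abundance$protein_group)
  }
  ref <- tibble::tibble(
    protein_group = reference_proteins,
    species = species_of(reference_proteins, design$species_rule)
  )
  out <- purrr::pmap(design$comparisons, function(sample, reference) {
    paired <- .paired_abundance(abundance, design, sample, reference)
    complete <- unique(paired$protein_group)
    dplyr::summarise(
      dplyr::group_by(ref, .data$species),
      comparison = paste0(sample, "_vs_", reference),
      n_reference = dplyr::n(),
      n_complete = sum(.data$protein_group %in% complete),
      missing_fraction = 1 - .data$n_complete / .data$n_reference,
      .groups = "drop"
    )
  })
  dplyr::relocate(dplyr::bind_rows(out), "comparison")
}

#' Restrict results to a reference protein set
#'
#' Plain set intersection on `protein_group`, reporting the row counts
#' before and after — used e.g. to reduce a label-free analysis to the
#' proteins found in any spike-in sample for a fair comparison.
#'
#' @param results Any tibble with a `protein_group` column.
#' @param reference_proteins Character vector of protein groups to keep.
#' @return The restricted tibble.
#' @export
restrict_to_reference_set <- function(results, reference_proteins) {
  n_before <- nrow(results)
  out <- results[results$protein_group %in% reference_proteins, , drop = FALSE]
  inform(paste0("restricted to reference set: ", n_before, " -> ", nrow(out),
                " rows"))
  out
}

#' @export
print.diasis_diff <- function(x, ...) {
  cat("<diasis_diff>", dplyr::n_distinct(x$protein_group), "proteins,",
      dplyr::n_distinct(x$comparison), "comparison(s)\n")
  NextMethod()
}

#' @rdname ttest_diff
#' @param x A `diasis_diff` tibble.
#' @param ... Unused.
#' @method glance diasis_diff
#' @export
glance.diasis_diff <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$comparison),
    n_proteins = dplyr::n(),
    n_significant = if ("significant" %in% names(x)) {
      sum(.data$significant)
    } else {
      NA_integer_
    },
    median_log2fc = median(.data$mean_log2fc),
    .groups = "drop"
  )
}
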