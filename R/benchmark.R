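# Scoring quantification output against ground truth.

#' Map protein groups to species labels
#'
#' Applies a species rule to (possibly semicolon-joined) protein groups.
#' With a named character vector, each name is a regular expression tried
#' against every accession of the group and mapped to its label; with a
#' tibble (`accession`, `species`), accessions are looked up explicitly. A
#' group whose members map to more than one species is labelled `"mixed"`;
#' an unmapped group is `"unknown"` (both are excluded from scoring, with a
#' count).
#'
#' @param protein_group Character vector of protein groups.
#' @param rule Named character vector (pattern -> label) or a tibble with
#'   columns `accession`, `species`.
#' @return Character vector of species labels.
#' @export
species_of <- function(protein_group, rule) {
  if (is.null(rule)) abort("no species rule given")
  members <- stringr::str_split(protein_group, stringr::fixed(";"))
  lookup <- function(accs) {
    if (is.data.frame(rule)) {
      hits <- unique(rule$species[match(accs, rule$accession)])
      hits <- hits[!is.na(hits)]
    } else {
      hits <- unique(unlist(lapply(seq_along(rule), function(i) {
        if (any(stringr::str_detect(accs, names(rule)[i]))) rule[[i]]
      })))
    }
    if (length(hits) == 0) return("unknown")
    if (length(hits) > 1) return("mixed")
    hits
  }
  vapply(members, lookup, character(1))
}

#' Replicate completeness of protein detection
#'
#' For every sample and species, counts how many proteins were quantified
#' in exactly 1, 2, ... n replicates. The bins partition the detected
#' protein set of each sample.
#'
#' @param abundance An abundance tibble (any method).
#' @param design A [design_spec()] with a `species_rule`.
#' @return A tibble: `sample`, `species`, `n_replicates`, `n_proteins`.
#' @export
completeness <- function(abundance, design) {
  stopifnot(inherits(design, "design_spec"))
  ab <- dplyr::inner_join(
    abundance[c("protein_group", "run_id")],
    design$run_to_sample, by = "run_id"
  )
  ab$species <- species_of(ab$protein_group, design$species_rule)
  per_protein <- dplyr::summarise(
    dplyr::group_by(ab, .data$sample, .data$species, .data$protein_group),
    n_replicates = dplyr::n_distinct(.data$replicate),
    .groups = "drop"
  )
  dplyr::count(per_protein, .data$sample, .data$species, .data$n_replicates,
               name = "n_proteins")
}

#' Score classified results against ground truth
#'
#' The benchmark's evaluation vocabulary: per comparison, the number of
#' misclassified anchor/unchanged proteins (false positives: truth-negative
#' but flagged significant), the true-positive count and recall, plus
#' per-tier accuracy of the recovered ratios — median bias
#' (observed − expected log2FC) and spread (MAD) per true fold-change tier
#' — and precision-recall curves under both rankings. Protein groups whose
#' species is `"mixed"` or `"unknown"` are excluded with a warning count.
#'
#' @param results A classified `diasis_diff` tibble (see [classify_hits()]).
#' @param truth A ground-truth tibble from [ground_truth()] (or with the
#'   same columns).
#' @return A `diasis_score` list: `summary` (per comparison: fp, tp,
#'   n_positive, n_negative, recall), `tiers` (per comparison x expected
#'   log2FC: n, median_bias, mad_spread), `pr` (PR curves, both rankings).
#' @export
score_against_truth <- function(results, truth) {
  if (!"significant" %in% names(results)) {
    abort("results must be classified first (see classify_hits())")
  }
  excluded <- results$species %in% c("mixed", "unknown")
  if (any(excluded)) {
    warn(paste0(sum(excluded),
                " result row(s) with mixed/unknown species excluded from scoring"))
    results <- results[!excluded, , drop = FALSE]
  }
  joined <- dplyr::inner_join(
    results,
    truth[c("protein_group", "comparison", "expected_log2fc", "is_positive")],
    by = c("protein_group", "comparison")
  )
  summary <- dplyr::summarise(
    dplyr::group_by(joined, .data$comparison),
    n_scored = dplyr::n(),
    n_positive = sum(.data$is_positive),
    n_negative = sum(!.data$is_positive),
    false_positives = sum(.data$significant & !.data$is_positive),
    true_positives = sum(.data$significant & .data$is_positive),
    recall = .data$true_positives / .data$n_positive,
    .groups = "drop"
  )
  tiers <- dplyr::summarise(
    dplyr::group_by(joined, .data$comparison, .data$expected_log2fc),
    n = dplyr::n(),
    median_bias = median(.data$mean_log2fc - .data$expected_log2fc),
    mad_spread = mad(.data$mean_log2fc),
    .groups = "drop"
  )
  # the p-value ranking can be empty, e.g. when every p is undefined on
  # degenerate (zero-variance) data; report the log2FC ranking alone then
  pr_p <- tryCatch(precision_recall(results, truth, ranking = "pvalue"),
                   error = function(e) {
                     inform("p-value PR ranking unavailable; reporting log2FC ranking only")
                     NULL
                   })
  pr <- dplyr::bind_rows(
    precision_recall(results, truth, ranking = "log2fc"),
    pr_p
  )
  structure(list(summary = summary, tiers = tiers, pr = pr),
            class = "diasis_score")
}

#' @export
print.diasis_score <- function(x, ...) {
  cat("<diasis_score>\n")
  print(x$summary)
  cat("per-tier accuracy:\n")
  print(x$tiers)
  invisible(x)
}

#' @rdname score_against_truth
#' @param x A `diasis_score` object.
#' @param ... Unused.
#' @method tidy diasis_score
#' @export
tidy.diasis_score <- function(x, ...) {
  x$summary
}
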