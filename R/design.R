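# Experimental design: sample/run/replicate structure and species mapping.

#' Construct a design specification
#'
#' Describes how runs map to samples and replicates, which comparisons are
#' evaluated, which species serves as the across-sample anchor (theoretical
#' 1:1 ratio) and which sample is the unshifted reference for normalization.
#'
#' @param samples Character vector of sample ids (e.g. `c("S1","S2","S3")`).
#' @param run_to_sample Tibble with columns `run_id`, `sample`, `replicate`
#'   mapping every run to exactly one (sample, replicate).
#' @param comparisons Tibble with columns `sample`, `reference`; the
#'   reference sample is the denominator of every comparison.
#' @param anchor_species Species label whose across-sample ratio is
#'   theoretically 1:1 (used by [anchor_normalize()]).
#' @param reference_sample The sample that is never shifted by
#'   normalization and is the denominator of across-sample ratios.
#' @param species_rule A named character vector of regular expressions
#'   mapped to species labels (e.g. `c("_HUMAN$" = "human")`), or a tibble
#'   with columns `accession`, `species` for explicit lookup. See
#'   [species_of()].
#' @return A `design_spec` object.
#' @export
design_spec <- function(samples, run_to_sample, comparisons,
                        anchor_species, reference_sample,
                        species_rule = NULL) {
  run_to_sample <- tibble::as_tibble(run_to_sample)
  comparisons <- tibble::as_tibble(comparisons)
  stopifnot(all(c("run_id", "sample", "replicate") %in% names(run_to_sample)),
            all(c("sample", "reference") %in% names(comparisons)))
  if (anyDuplicated(run_to_sample$run_id)) {
    abort("every run must map to exactly one (sample, replicate)")
  }
  if (!all(run_to_sample$sample %in% samples)) {
    abort("run_to_sample refers to samples not in `samples`")
  }
  if (!reference_sample %in% samples) {
    abort("reference_sample must be one of `samples`")
  }
  if (!all(comparisons$reference == reference_sample)) {
    abort("the reference sample must be the denominator of every comparison")
  }
  structure(
    list(samples = samples,
         run_to_sample = run_to_sample,
         comparisons = comparisons,
         anchor_species = anchor_species,
         reference_sample = reference_sample,
         species_rule = species_rule),
    class = "design_spec"
  )
}

#' Standard two-species benchmark design
#'
#' The mixed-species benchmark layout: the anchor species (human) is kept
#' constant across samples while the second species (E. coli) is diluted,
#' down to 1:50 in the extreme sample; the undiluted sample is the
#' reference and each diluted sample is compared against it, replicate by
#' replicate.
#'
#' @param n_replicates Technical replicates per sample (default 4).
#' @param dilution_factors Named numeric vector of the diluted species'
#'   relative light amount per sample; the reference sample must have
#'   factor 1. Default `c(S1 = 1/50, S2 = 1/5, S3 = 1)`.
#' @param anchor_species,diluted_species Species labels.
#' @param reference_sample Sample with dilution factor 1 (default `"S3"`).
#' @return A `design_spec` whose runs are named `<sample>_R<replicate>`.
#' @export
benchmark_design <- function(n_replicates = 4L,
                             dilution_factors = c(S1 = 1 / 50, S2 = 1 / 5, S3 = 1),
                             anchor_species = "human",
                             diluted_species = "ecoli",
                             reference_sample = "S3") {
  samples <- names(dilution_factors)
  if (is.null(samples)) abort("dilution_factors must be named by sample")
  if (dilution_factors[[reference_sample]] != 1) {
    abort("the reference sample must have dilution factor 1")
  }
  run_to_sample <- tidyr::expand_grid(sample = samples,
                                      replicate = seq_len(n_replicates))
  run_to_sample <- dplyr::mutate(
    run_to_sample,
    run_id = paste0(.data$sample, "_R", .data$replicate)
  )
  comparisons <- tibble::tibble(
    sample = setdiff(samples, reference_sample),
    reference = reference_sample
  )
  rule <- setNames(c(anchor_species, diluted_species),
                   c(paste0("_", toupper(anchor_species), "$"),
                     paste0("_", toupper(diluted_species), "$")))
  design <- design_spec(samples,
                        run_to_sample[c("run_id", "sample", "replicate")],
                        comparisons, anchor_species, reference_sample,
                        species_rule = rule)
  design$dilution_factors <- dilution_factors
  design$diluted_species <- diluted_species
  design
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", length(x$samples), "samples,",
      nrow(x$run_to_sample), "runs\n")
  cat("  reference:", x$reference_sample,
      " anchor:", x$anchor_species, "\n")
  cat("  comparisons:",
      paste(x$comparisons$sample, "vs", x$comparisons$reference,
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a design specification from YAML
#'
#' Expects keys `samples`, `reference_sample`, `anchor_species`, a
#' `runs` table (list of run/sample/replicate entries), `comparisons`
#' (list of sample/reference entries) and optionally `species_rule`
#' (pattern: label mapping).
#'
#' @param path Path to a YAML file.
#' @return A `design_spec`.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  run_to_sample <- dplyr::bind_rows(lapply(y$runs, tibble::as_tibble))
  names(run_to_sample)[names(run_to_sample) == "run"] <- "run_id"
  comparisons <- dplyr::bind_rows(lapply(y$comparisons, tibble::as_tibble))
  rule <- if (!is.null(y$species_rule)) unlist(y$species_rule) else NULL
  design_spec(samples = y$samples,
              run_to_sample = run_to_sample,
              comparisons = comparisons,
              anchor_species = y$anchor_species,
              reference_sample = y$reference_sample,
              species_rule = rule)
}
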