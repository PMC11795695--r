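# Normalization: anchor-species shift to a reference sample, and run-wise
# median shift of protein L/H ratios.

#' Anchor-species normalization to the reference sample
#'
#' In a two-proteome benchmark the anchor species has a theoretical 1:1
#' across-sample ratio, so any systematic offset between a sample and the
#' reference estimates a loading/technical shift. For every non-reference
#' sample and replicate, the shift is the median over anchor-species
#' proteins (present in both runs) of the log10 abundance difference to the
#' reference run of the same replicate index; it is subtracted from every
#' abundance of that run. Reference runs are never shifted. With
#' `pooled = TRUE` one shift per sample is computed by pooling the
#' per-replicate-pair differences.
#'
#' @param abundance An abundance tibble (see [light_abundances()] /
#'   [lfq_abundances()]).
#' @param design A [design_spec()] naming `anchor_species`,
#'   `reference_sample` and a `species_rule`.
#' @param pooled Compute one shift per sample instead of one per replicate
#'   pair (default `FALSE`).
#' @return The shifted abundance tibble, attribute `normalized = TRUE`.
#' @export
anchor_normalize <- function(abundance, design, pooled = FALSE) {
  stopifnot(inherits(design, "design_spec"))
  rts <- design$run_to_sample
  species <- species_of(abundance$protein_group, design$species_rule)
  anchor <- abundance[species == design$anchor_species,
                      c("protein_group", "run_id", "log10_abundance")]

  ref_runs <- rts[rts$sample == design$reference_sample, ]
  other_runs <- rts[rts$sample != design$reference_sample, ]
  ref_by_rep <- setNames(ref_runs$run_id, ref_runs$replicate)

  pair_diffs <- purrr::pmap(other_runs, function(run_id, sample, replicate) {
    ref_run <- ref_by_rep[[as.character(replicate)]]
    if (is.null(ref_run)) {
      abort(paste0("no reference run for replicate ", replicate,
                   " (run ", run_id, ")"))
    }
    a <- anchor[anchor$run_id == run_id, c("protein_group", "log10_abundance")]
    b <- anchor[anchor$run_id == ref_run, c("protein_group", "log10_abundance")]
    shared <- dplyr::inner_join(a, b, by = "protein_group",
                                suffix = c("", "_ref"))
    if (nrow(shared) == 0) {
      abort(paste0("no anchor-species protein shared between runs ",
                   run_id, " and ", ref_run))
    }
    tibble::tibble(run_id = run_id, sample = sample,
                   diff = shared$log10_abundance - shared$log10_abundance_ref)
  })
  pair_diffs <- dplyr::bind_rows(pair_diffs)

  if (pooled) {
    shifts <- dplyr::summarise(dplyr::group_by(pair_diffs, .data$sample),
                               shift = median(.data$diff), .groups = "drop")
    shifts <- dplyr::left_join(other_runs, shifts, by = "sample")
  } else {
    shifts <- dplyr::summarise(dplyr::group_by(pair_diffs, .data$run_id),
                               shift = median(.data$diff), .groups = "drop")
  }
  shift_by_run <- setNames(shifts$shift, shifts$run_id)
  adj <- shift_by_run[abundance$run_id]
  adj[is.na(adj)] <- 0  # reference runs are not shifted
  out <- abundance
  out$log10_abundance <- out$log10_abundance - unname(adj)
  attr(out, "method") <- attr(abundance, "method")
  attr(out, "normalized") <- TRUE
  out
}

#' Run-wise median shift of protein L/H ratios
#'
#' Centers each run by subtracting the median of all its protein log10 L/H
#' ratios, the normalization used when no anchor species with a known 1:1
#' ratio is available (e.g. super-SILAC FFPE data); applied before
#' abundance reconstruction. The per-run ratio median is exactly 0
#' afterwards, and the operation is idempotent.
#'
#' @param pq A protein ratio tibble from [protein_log_ratios()].
#' @return The shifted protein ratio tibble.
#' @export
median_shift_normalize <- function(pq) {
  if (nrow(pq) == 0) abort("empty protein ratio table")
  dplyr::mutate(
    dplyr::group_by(pq, .data$run_id),
    log10_lh_protein = .data$log10_lh_protein - median(.data$log10_lh_protein),
    .keep = "all"
  ) |> dplyr::ungroup()
}
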