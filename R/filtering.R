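#' Remove reference-shared artifacts
#'
#' Variants that are present in every sample of the cohort, including the
#' wild-type ancestor, reflect differences between the study's parent
#' strain and the published reference genome rather than mutations arising
#' during the evolution experiment; they are removed from consideration
#' entirely.  "Present" follows the same frequency rule as
#' \code{\link{buildPresence}}, so a single threshold governs both the
#' artifact screen and the cohort analyses.
#'
#' @param cohort a \linkS4class{MutationCohort}; must contain the
#'   wild-type sample.
#' @param threshold population presence threshold in [0,1] (default 0.02).
#' @return list with elements \code{cohort} (artifact observations
#'   removed) and \code{removed} (character vector of artifact variant
#'   ids).
#' @export
removeReferenceArtifacts <- function(cohort, threshold = 0.02) {
  samples <- sampleInfo(cohort)
  if (!any(samples$role == "wild_type"))
    stop("cohort has no wild_type sample")
  pres <- buildPresence(cohort, threshold = threshold)
  removed <- rownames(pres)[rowSums(pres) == ncol(pres)]
  calls <- variantCalls(cohort)
  kept <- calls[!calls$variant_id %in% removed, , drop = FALSE]
  rownames(kept) <- NULL
  list(cohort = MutationCohort(kept, samples), removed = removed)
}

#' Keep only high-confidence variant calls
#'
#' Screens the caller output for high-confidence differences by removing
#' variants flagged as false positive (\code{fp}), sequence-specific error
#' (\code{ise}) or structural variant (\code{sv}).  Counts are kept at the
#' distinct-variant level in a \code{FilterSummary} ledger.
#'
#' @param cohort a \linkS4class{MutationCohort} whose calls all carry a
#'   confidence flag.
#' @param nReferenceArtifacts optional count of artifacts removed by a
#'   preceding \code{\link{removeReferenceArtifacts}} step, recorded in
#'   the ledger.
#' @return list with elements \code{cohort} (hc calls only) and
#'   \code{summary} (a \code{FilterSummary}).
#' @export
filterHighConfidence <- function(cohort, nReferenceArtifacts = 0L) {
  calls <- variantCalls(cohort)
  ids <- unique(calls$variant_id)
  flag_of <- calls$confidence_flag[match(ids, calls$variant_id)]
  dropped <- table(factor(flag_of[flag_of != "hc"],
                          levels = c("fp", "ise", "sv")))
  keep_ids <- ids[flag_of == "hc"]
  kept <- calls[calls$confidence_flag == "hc" &
                  calls$variant_id %in% keep_ids, , drop = FALSE]
  rownames(kept) <- NULL
  summary <- structure(list(
    n_input = length(ids) + as.integer(nReferenceArtifacts),
    n_reference_artifacts = as.integer(nReferenceArtifacts),
    n_after_artifact_removal = length(ids),
    n_dropped_by_flag = stats::setNames(as.integer(dropped), names(dropped)),
    n_high_confidence = length(keep_ids)),
    class = "FilterSummary")
  list(cohort = MutationCohort(kept, sampleInfo(cohort)), summary = summary)
}

#' Two-step high-confidence screen
#'
#' Convenience wrapper running \code{\link{removeReferenceArtifacts}}
#' first (the ancestor-shared screen) and then
#' \code{\link{filterHighConfidence}} (the flag screen), returning a
#' single consistent ledger.
#'
#' @inheritParams removeReferenceArtifacts
#' @return list with elements \code{cohort}, \code{removed} (artifact
#'   ids) and \code{summary}.
#' @export
screenVariants <- function(cohort, threshold = 0.02) {
  step1 <- removeReferenceArtifacts(cohort, threshold = threshold)
  step2 <- filterHighConfidence(step1$cohort,
                                nReferenceArtifacts = length(step1$removed))
  list(cohort = step2$cohort, removed = step1$removed,
       summary = step2$summary)
}

#' @export
print.FilterSummary <- function(x, ...) {
  cat(sprintf("FilterSummary: %d putative -> %d after artifact removal -> %d high-confidence\n",
              x$n_input, x$n_after_artifact_removal, x$n_high_confidence))
  cat("  dropped by flag:",
      paste(sprintf("%s=%d", names(x$n_dropped_by_flag),
                    x$n_dropped_by_flag), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a FilterSummary as a TSV ledger
#'
#' @param summary a \code{FilterSummary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFilterSummary <- function(summary, path) {
  tab <- data.frame(
    step = c("input", "reference_artifacts", "after_artifact_removal",
             paste0("dropped_", names(summary$n_dropped_by_flag)),
             "high_confidence"),
    count = c(summary$n_input, summary$n_reference_artifacts,
              summary$n_after_artifact_removal,
              unname(summary$n_dropped_by_flag),
              summary$n_high_confidence))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
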