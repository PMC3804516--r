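#' Score an amino-acid substitution against a domain profile
#'
#' The function-change score of a non-synonymous substitution inside a
#' profiled domain is the difference between the mutant and reference
#' residue scores at the substituted position:
#' \code{delta = pssm[pos, alt] - pssm[pos, ref]}.  A positive delta
#' indicates a potential gain of function, a negative delta a potential
#' loss; the score is antisymmetric, \code{score(a -> b) = -score(b -> a)}.
#' Scores are in the native log-odds units of the supplied matrix; only
#' sign semantics and ordering are meaningful across toolkits.
#'
#' @param model a \linkS4class{ProfileModel}.
#' @param proteinPosition 1-based position of the substitution on the
#'   protein; must fall within the domain span (substitutions are only
#'   scored within a profiled domain).
#' @param refAa,altAa one-letter codes of the reference and mutant
#'   residues; stop codons are not scored (they are handled upstream by
#'   the \code{STOP} effect class).
#' @return list with \code{variant} (\code{"ref->alt"}),
#'   \code{model_id}, \code{domain_position}, \code{ref_score},
#'   \code{alt_score}, \code{delta} and \code{verdict}
#'   (\code{potential_gain}/\code{potential_loss}/\code{neutral}).
#' @export
scoreFunctionChange <- function(model, proteinPosition, refAa, altAa) {
  if (!refAa %in% AA20 || !altAa %in% AA20)
    stop("refAa and altAa must be standard residues (stop codons are ",
         "classified upstream as STOP, not scored)")
  if (proteinPosition < model@proteinStart ||
      proteinPosition > model@proteinEnd)
    stop(sprintf("position %d lies outside domain span %d-%d of model %s",
                 proteinPosition, model@proteinStart, model@proteinEnd,
                 model@modelId))
  dp <- proteinPosition - model@proteinStart + 1L
  ref_score <- model@pssm[dp, refAa]
  alt_score <- model@pssm[dp, altAa]
  delta <- alt_score - ref_score
  verdict <- if (delta > 0) "potential_gain"
  else if (delta < 0) "potential_loss" else "neutral"
  list(variant = paste0(refAa, "->", altAa), model_id = model@modelId,
       domain_position = dp, ref_score = unname(ref_score),
       alt_score = unname(alt_score), delta = unname(delta),
       verdict = verdict)
}

msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  do.call(rbind, strsplit(as.character(msa), ""))
}

is_gap <- function(x) x %in% c("-", ".")

#' Classify the conservation of an alignment column
#'
#' Reports the fraction of non-gap residues in the column that match the
#' reference row's residue.  Full agreement (identity 1.0) is
#' \code{very_conserved}; identity below \code{lowThreshold} is
#' \code{non_conserved}; anything between is \code{intermediate}.
#'
#' @param msa an \link[Biostrings]{AAStringSet} of equal-width aligned
#'   sequences (or a character matrix).
#' @param columnIndex 1-based alignment column.
#' @param referenceRow row index of the reference sequence; must be
#'   non-gap at the column.
#' @param lowThreshold identity below which the column is called
#'   non-conserved (default 0.5).
#' @return list with \code{column_index}, \code{call} and
#'   \code{identity_fraction}.
#' @export
classifyConservation <- function(msa, columnIndex, referenceRow = 1,
                                 lowThreshold = 0.5) {
  m <- msa_matrix(msa)
  if (columnIndex < 1 || columnIndex > ncol(m))
    stop("column ", columnIndex, " outside alignment width ", ncol(m))
  col <- m[, columnIndex]
  if (all(is_gap(col)))
    stop("column ", columnIndex, " is all-gap; conservation undefined")
  ref <- col[referenceRow]
  if (is_gap(ref))
    stop("reference row is gapped at column ", columnIndex)
  res <- col[!is_gap(col)]
  identity <- mean(res == ref)
  call <- if (identity == 1) "very_conserved"
  else if (identity < lowThreshold) "non_conserved" else "intermediate"
  list(column_index = as.integer(columnIndex), call = call,
       identity_fraction = identity)
}

#' Build a log-odds profile from a protein alignment
#'
#' Enables self-contained substitution scoring without external profile
#' downloads.  Match columns are alignment columns with at most 50\% gap
#' characters; each match column is scored as
#' \code{log2(((count + pseudocount) / (N + 20 * pseudocount)) / (1/20))}
#' against a uniform residue background, where \code{N} is the number of
#' non-gap residues in the column.
#'
#' @param msa an \link[Biostrings]{AAStringSet} (or character matrix) of
#'   at least two aligned sequences.
#' @param pseudocount additive smoothing count (default 1.0).
#' @param modelId,domainLocus identifiers passed to the model.
#' @return A \linkS4class{ProfileModel} whose width equals the number of
#'   match columns (\code{proteinStart} = 1).
#' @export
buildProfileFromMsa <- function(msa, pseudocount = 1.0, modelId = "msa",
                                domainLocus = NA_character_) {
  m <- msa_matrix(msa)
  if (nrow(m) < 2) stop("profile building requires at least 2 sequences")
  gap_frac <- colMeans(apply(m, 2, is_gap))
  match_cols <- which(gap_frac <= 0.5)
  if (length(match_cols) == 0) stop("alignment has no match columns")
  scores <- t(vapply(match_cols, function(j) {
    col <- m[, j]
    res <- toupper(col[!is_gap(col)])
    counts <- table(factor(res, levels = AA20))
    n <- sum(counts)
    p <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
    log2(p / (1 / 20))
  }, numeric(20)))
  colnames(scores) <- AA20
  ProfileModel(scores, modelId = modelId, domainLocus = domainLocus)
}

#' Score a set of non-synonymous effects against profile models
#'
#' Convenience wrapper joining an effect table to models by locus tag and
#' scoring each substitution that falls inside its gene's domain span.
#'
#' @param effects effect data.frame from \code{\link{classifyEffects}}.
#' @param models named list of \linkS4class{ProfileModel}s, indexed by
#'   \code{domainLocus}.
#' @return data.frame of \code{variant_id}, \code{model_id},
#'   \code{domain_position}, \code{ref_score}, \code{alt_score},
#'   \code{delta}, \code{verdict}; substitutions with no covering model
#'   or outside the domain span are skipped.
#' @export
scoreEffects <- function(effects, models) {
  locus_of <- vapply(models, function(m) m@domainLocus, character(1))
  rows <- list()
  sub <- effects[effects$effect == "NONSYN" & !is.na(effects$codon_index), ,
                 drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    hit <- which(locus_of == sub$locus_tag[i])
    for (j in hit) {
      model <- models[[j]]
      pos <- sub$codon_index[i]
      if (pos < model@proteinStart || pos > model@proteinEnd) next
      if (!sub$ref_aa[i] %in% AA20 || !sub$alt_aa[i] %in% AA20) next
      sc <- scoreFunctionChange(model, pos, sub$ref_aa[i], sub$alt_aa[i])
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = sub$variant_id[i], model_id = sc$model_id,
        domain_position = sc$domain_position, ref_score = sc$ref_score,
        alt_score = sc$alt_score, delta = sc$delta, verdict = sc$verdict,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(variant_id = character(), model_id = character(),
                      domain_position = integer(), ref_score = numeric(),
                      alt_score = numeric(), delta = numeric(),
                      verdict = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
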