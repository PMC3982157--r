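#' Length-filter a proteome
#'
#' Retains records with `min_len <= nchar(sequence) <= max_len`, preserving
#' input order. Defaults drop the small number of entries shorter than 50 or
#' longer than 2000 residues, the standard dataset-construction step for
#' proteome-wide disorder surveys.
#'
#' @param records `protein_records`.
#' @param min_len,max_len inclusive length bounds (amino acids).
#' @return the filtered `protein_records`.
#' @export
length_filter <- function(records, min_len = 50L, max_len = 2000L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  keep <- nchar(records$sequence) >= min_len & nchar(records$sequence) <= max_len
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

aa_identity_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c(AA_STANDARD, "X")
      mm <- matrix(0L, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(mm) <- 1L
      mm["X", "X"] <- 0L  # unknown residues never count as matches
      m <<- mm
    }
    m
  }
})

#' Global percent identity between two sequences
#'
#' Needleman–Wunsch global alignment with match = 1, mismatch = 0 and a
#' linear gap penalty of −1; identity is the number of identical aligned
#' pairs divided by the number of alignment columns (gaps included). `X`
#' never counts as a match.
#'
#' @param a,b amino-acid sequences (character scalars).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = aa_identity_matrix(),
    gapOpening = 0, gapExtension = 1, type = "global")
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy redundancy reduction at a global-identity cutoff
#'
#' Stand-in for OrthoMCL-style redundancy removal: sequences are visited in
#' order of decreasing length (ties broken by id); each joins the first
#' existing cluster whose representative it matches at `identity_cutoff`
#' global identity or better, otherwise it founds a new cluster. The kept
#' set is the cluster representatives.
#'
#' @param records `protein_records`.
#' @param identity_cutoff identity fraction in `(0, 1]`, default 0.90.
#' @return list with `kept` (`protein_records` of representatives, in greedy
#'   order) and `clusters` (named list: representative id -> member ids).
#' @export
redundancy_filter <- function(records, identity_cutoff = 0.90) {
  if (identity_cutoff <= 0 || identity_cutoff > 1)
    stop("identity_cutoff must lie in (0, 1]")
  ord <- order(-nchar(records$sequence), records$id)
  reps <- integer(0)
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(records$sequence[i],
                            records$sequence[r]) >= identity_cutoff) {
        clusters[[records$id[r]]] <- c(clusters[[records$id[r]]],
                                       records$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      clusters[[records$id[i]]] <- records$id[i]
    }
  }
  kept <- records[reps, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, clusters = clusters)
}

#' Descriptive statistics of a proteome dataset
#'
#' @param records non-empty `protein_records`.
#' @param n_input,n_after_redundancy optional counts from earlier pipeline
#'   stages, recorded verbatim (default: the current record count).
#' @return list of class `dataset_stats` with `n_input`,
#'   `n_after_redundancy`, `n_after_length`, `mean_length` and `composition`
#'   (named residue-fraction vector summing to 1, pooled over all residues).
#' @export
dataset_stats <- function(records, n_input = nrow(records),
                          n_after_redundancy = nrow(records)) {
  if (nrow(records) == 0L) stop("dataset_stats: empty input")
  residues <- unlist(strsplit(records$sequence, ""))
  comp <- table(factor(residues, levels = c(AA_STANDARD, "X")))
  comp <- comp[comp > 0 | names(comp) %in% AA_STANDARD]
  structure(list(
    n_input = n_input,
    n_after_redundancy = n_after_redundancy,
    n_after_length = nrow(records),
    mean_length = mean(nchar(records$sequence)),
    composition = setNames(as.numeric(comp) / length(residues), names(comp))
  ), class = "dataset_stats")
}
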