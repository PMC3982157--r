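#' Summarise one disorder profile
#'
#' Derives the disordered-residue mask from the profile's calls and extracts
#' maximal runs of disordered residues as segments.
#'
#' @param profile a `disorder_profile` (element of [read_disorder_table()]
#'   output).
#' @param sequence optional sequence to length-check against.
#' @return list of class `disorder_summary`: `protein_id`, `L`, `Ld`,
#'   `fraction` and `segments` (two-column matrix of 1-based inclusive
#'   start/end).
#' @export
summarize_disorder <- function(profile, sequence = NULL) {
  calls <- profile$calls
  if (!is.null(sequence) && nchar(sequence) != length(calls))
    stop("disorder profile length (", length(calls),
         ") does not match sequence length (", nchar(sequence),
         ") for protein '", profile$protein_id, "'")
  structure(list(protein_id = profile$protein_id,
                 L = length(calls),
                 Ld = sum(calls),
                 fraction = mean(calls),
                 segments = calls_to_segments(calls)),
            class = "disorder_summary")
}

#' Convert a logical call vector to maximal-run segments (and back)
#'
#' @param calls logical vector (TRUE = disordered).
#' @return integer matrix with columns `start`, `end` (1-based inclusive).
#' @export
calls_to_segments <- function(calls) {
  r <- rle(as.logical(calls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' @rdname calls_to_segments
#' @param segments segment matrix as returned by [calls_to_segments()].
#' @param L total length of the reconstructed mask.
#' @export
segments_to_calls <- function(segments, L) {
  calls <- rep(FALSE, L)
  for (i in seq_len(nrow(segments)))
    calls[segments[i, 1L]:segments[i, 2L]] <- TRUE
  calls
}

#' Tabulate per-protein disorder summaries
#'
#' @param profiles a `disorder_profiles` list.
#' @return data frame with `protein_id`, `L`, `Ld`, `fraction` (one row per
#'   protein, sorted by id).
#' @export
disorder_summary_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    s <- summarize_disorder(p)
    data.frame(protein_id = s$protein_id, L = s$L, Ld = s$Ld,
               fraction = s$fraction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proteome disorder degree (percent, residue-weighted)
#'
#' `100 * sum(Ld) / sum(L)` pooled over all proteins — the fraction of all
#' residues in the proteome called disordered, not the mean of per-protein
#' fractions.
#'
#' @param summaries data frame from [disorder_summary_table()].
#' @return percent in `[0, 100]`.
#' @export
proteome_disorder_degree <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no disorder summaries")
  100 * sum(summaries$Ld) / sum(summaries$L)
}

#' Mean per-protein disorder fraction
#'
#' The unweighted mean of per-protein disordered fractions — the bin-level
#' "relative rate of protein disorder" statistic used when proteins are
#' grouped by predicted site count.
#'
#' @inheritParams proteome_disorder_degree
#' @return fraction in `[0, 1]`.
#' @export
mean_disorder_fraction <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no disorder summaries")
  mean(summaries$fraction)
}
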