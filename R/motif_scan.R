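# Consensus patterns. The O-glycosylation consensus targets plant
# hydroxyproline glycosylation: [A/S/T/V]-P(1,4)-X(0-10)-[A/S/T/V]-P(1,4),
# where X is any standard residue. The N-glycosylation sequon is
# Asn-X-Ser/Thr with X != Pro. Unknown residues ('X' in the sequence) are
# never matched by any pattern position.
.aa_class <- paste0("[", paste(AA_STANDARD, collapse = ""), "]")
.oglyc_regex <- paste0("([ASTV])(P{1,4}?)(", .aa_class,
                       "{0,10}?)([ASTV])(P{1,4}?)")
.nglyc_regex <- "N(?=[^PX][ST])"

empty_matches <- function() {
  data.frame(protein_id = character(0), start = integer(0),
             end = integer(0), pattern = character(0),
             site_position = integer(0), stringsAsFactors = FALSE)
}

#' Scan for N-glycosylation sequons
#'
#' Reports every position `i` with `seq[i] == N`, `seq[i+1] != P` and
#' `seq[i+2]` in `{S, T}`. Overlapping sequons are all reported (each Asn is
#' independently modifiable); matches are ascending by start and the site
#' position is the Asn itself.
#'
#' @param records `protein_records` (one or more rows).
#' @return data frame with `protein_id`, `start`, `end`, `pattern`
#'   (`"NGLY"`), `site_position`.
#' @export
scan_nglyc <- function(records) {
  hits <- gregexpr(.nglyc_regex, records$sequence, perl = TRUE)
  out <- lapply(seq_len(nrow(records)), function(i) {
    st <- hits[[i]]
    if (st[1] == -1L) return(NULL)
    data.frame(protein_id = records$id[i], start = as.integer(st),
               end = as.integer(st) + 2L, pattern = "NGLY",
               site_position = as.integer(st), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_matches() else out
}

#' Scan for the plant O-glycosylation consensus
#'
#' Pattern: one residue from `{A,S,T,V}`, a run of 1–4 Pro, a spacer of 0–10
#' standard residues, a second `{A,S,T,V}` residue and a second run of 1–4
#' Pro. Matching is leftmost, non-overlapping and lazy (the shortest Pro
#' runs and spacer that admit a match); scanning resumes after the end of
#' each accepted match. The countable site is anchored to the first Pro of
#' the second Pro run.
#'
#' @param records `protein_records`.
#' @return data frame with `protein_id`, `start`, `end`, `pattern`
#'   (`"OGLY"`), `site_position`.
#' @export
scan_oglyc <- function(records) {
  hits <- gregexpr(.oglyc_regex, records$sequence, perl = TRUE)
  out <- lapply(seq_len(nrow(records)), function(i) {
    m <- hits[[i]]
    if (m[1] == -1L) return(NULL)
    st <- as.integer(m)
    len <- attr(m, "match.length")
    cs <- attr(m, "capture.start")  # one row per match, 5 capture groups
    data.frame(protein_id = records$id[i], start = st,
               end = st + len - 1L, pattern = "OGLY",
               site_position = as.integer(cs[, 5L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_matches() else out
}

#' Convert motif matches to PTM sites
#'
#' One site per match at its `site_position`, typed `O-gly` (residue P) or
#' `N-gly` (residue N); duplicate (protein, position, type) triples are
#' collapsed.
#'
#' @param matches output of [scan_oglyc()] / [scan_nglyc()] (rows may mix
#'   patterns).
#' @return PTM site data frame (`protein_id`, `position`, `residue`,
#'   `ptm_type`).
#' @export
sites_from_matches <- function(matches) {
  if (nrow(matches) == 0L)
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), ptm_type = character(0),
                      stringsAsFactors = FALSE))
  ptm <- ifelse(matches$pattern == "OGLY", "O-gly", "N-gly")
  out <- data.frame(protein_id = matches$protein_id,
                    position = matches$site_position,
                    residue = PTM_RESIDUES[ptm], ptm_type = ptm,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}
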