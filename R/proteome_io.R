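#' Construct a validated table of protein records
#'
#' A proteome is represented as a data frame with columns `id`, `species`,
#' `category` and `sequence`. Sequences are upper-cased and must consist of
#' the 20 standard one-letter codes plus `X`; ids must be unique and
#' non-empty.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param species species label recycled across records.
#' @param category one of `"monocot"`, `"dicot"`, `"unspecified"`.
#' @return data frame of class `protein_records`.
#' @export
protein_records <- function(id, sequence, species = "unspecified",
                            category = "unspecified") {
  category <- match.arg(category, valid_categories)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("`id` and `sequence` must have equal length")
  if (any(!nzchar(id)) || anyNA(id))
    stop("protein ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("zero-length sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  bad <- setdiff(unique(unlist(strsplit(sequence, ""))), c(AA_STANDARD, "X"))
  if (length(bad))
    stop("non-amino-acid character(s) in sequence: ",
         paste(sort(bad), collapse = ", "))
  out <- data.frame(id = id, species = rep_len(species, length(id)),
                    category = rep_len(category, length(id)),
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a proteome from FASTA
#'
#' The id is the header token before the first whitespace; sequences are
#' upper-cased and a terminal `*` stop character is stripped. Duplicate ids,
#' empty files and characters outside the 20 standard residues plus `X` are
#' errors.
#'
#' @param path FASTA file.
#' @inheritParams protein_records
#' @return a `protein_records` data frame.
#' @export
read_fasta <- function(path, species = "unspecified",
                       category = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  protein_records(ids, seqs, species = species, category = category)
}

#' Write a proteome to FASTA
#'
#' @param records a `protein_records` data frame.
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read per-residue disorder annotations
#'
#' Long-format TSV with columns `protein_id`, `position` (1-based, contiguous
#' `1..L` per protein) and `score` in `[0, 1]` and/or a binary `call` column.
#' When `call` is absent it is derived as `score >= threshold` (boundary
#' inclusive, the conventional RONN-style decision rule).
#'
#' @param path TSV file.
#' @param threshold disorder call threshold in `[0, 1]`.
#' @return a named list of class `disorder_profiles`; each element has
#'   `protein_id`, `scores` (numeric or NULL), `calls` (logical) and
#'   `threshold`.
#' @export
read_disorder_table <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "position")
  if (!all(need %in% names(d)))
    stop("disorder table must have columns: ", paste(need, collapse = ", "))
  has_score <- "score" %in% names(d)
  has_call  <- "call" %in% names(d)
  if (!has_score && !has_call)
    stop("disorder table needs a 'score' and/or 'call' column")
  if (has_score && (anyNA(d$score) || any(d$score < 0 | d$score > 1)))
    stop("disorder scores must lie in [0, 1]")
  profiles <- lapply(split(d, d$protein_id), function(g) {
    g <- g[order(g$position), , drop = FALSE]
    L <- nrow(g)
    if (anyDuplicated(g$position) || !identical(as.integer(g$position),
                                                seq_len(L)))
      stop("positions for protein '", g$protein_id[1],
           "' are not contiguous 1..L (gap or duplicate)")
    calls <- if (has_call) as.logical(as.integer(g$call))
             else g$score >= threshold
    structure(list(protein_id = g$protein_id[1],
                   scores = if (has_score) as.numeric(g$score) else NULL,
                   calls = calls, threshold = threshold),
              class = "disorder_profile")
  })
  structure(profiles[order(names(profiles))], class = "disorder_profiles")
}

#' Build disorder profiles from in-memory calls
#'
#' @param calls named list of logical vectors (one per protein).
#' @param scores optional named list of numeric score vectors.
#' @param threshold threshold stored with each profile.
#' @return a `disorder_profiles` list.
#' @export
disorder_profiles <- function(calls, scores = NULL, threshold = 0.5) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  profiles <- lapply(names(calls), function(id) {
    structure(list(protein_id = id,
                   scores = if (!is.null(scores)) scores[[id]] else NULL,
                   calls = as.logical(calls[[id]]), threshold = threshold),
              class = "disorder_profile")
  })
  names(profiles) <- names(calls)
  structure(profiles[order(names(profiles))], class = "disorder_profiles")
}

#' Read a PTM site table
#'
#' TSV with columns `protein_id`, `position` (1-based), `residue`, `ptm_type`.
#' Types must be one of [PTM_TYPES] and compatible with the residue column;
#' when `proteome` is supplied each site is cross-checked against the actual
#' sequence character.
#'
#' @param path TSV file.
#' @param proteome optional `protein_records` to validate against.
#' @return data frame with the four site columns.
#' @export
read_site_table <- function(path, proteome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "position", "residue", "ptm_type")
  if (!all(need %in% names(d)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  d <- d[need]
  d$position <- as.integer(d$position)
  validate_sites(d, proteome)
}

#' Validate PTM sites against type compatibility and (optionally) a proteome
#'
#' @param sites data frame with `protein_id`, `position`, `residue`,
#'   `ptm_type`.
#' @param proteome optional `protein_records`.
#' @return the validated (invisibly unchanged) site data frame.
#' @export
validate_sites <- function(sites, proteome = NULL) {
  unk <- setdiff(unique(sites$ptm_type), PTM_TYPES)
  if (length(unk))
    stop("unknown ptm_type(s): ", paste(unk, collapse = ", "))
  expected <- PTM_RESIDUES[sites$ptm_type]
  bad <- which(sites$residue != expected)
  if (length(bad))
    stop("ptm_type/residue incompatibility at ", sites$protein_id[bad[1]],
         ":", sites$position[bad[1]], " (", sites$ptm_type[bad[1]],
         " requires ", expected[bad[1]], ", got ", sites$residue[bad[1]], ")")
  if (!is.null(proteome)) {
    idx <- match(sites$protein_id, proteome$id)
    if (anyNA(idx))
      stop("site references unknown protein: ",
           sites$protein_id[which(is.na(idx))[1]])
    len <- nchar(proteome$sequence)[idx]
    oob <- which(sites$position < 1L | sites$position > len)
    if (length(oob))
      stop("site position out of range for ", sites$protein_id[oob[1]],
           ":", sites$position[oob[1]], " (length ", len[oob[1]], ")")
    actual <- substr(proteome$sequence[idx], sites$position, sites$position)
    mm <- which(actual != sites$residue)
    if (length(mm))
      stop("residue mismatch vs sequence at ", sites$protein_id[mm[1]],
           ":", sites$position[mm[1]], " (table says ", sites$residue[mm[1]],
           ", sequence has ", actual[mm[1]], ")")
  }
  sites
}

#' Write a result table as TSV
#'
#' Writes a header line plus rows; numeric columns are formatted to
#' `digits` decimal places (round-half-even, the R default).
#'
#' @param rows non-empty data frame with uniform columns.
#' @param path output path.
#' @param digits decimal places for floating-point columns.
#' @export
write_table <- function(rows, path, digits = 4L) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("refusing to write an empty table")
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]]))
      fmt[[j]] <- formatC(round(fmt[[j]], digits), format = "f",
                          digits = digits)
  }
  ok <- tryCatch({
    write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write table to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a species manifest
#'
#' YAML file mapping species names to their input artifacts:
#' ```
#' species:
#'   ath:
#'     category: dicot
#'     fasta: ath.fasta
#'     disorder: ath_disorder.tsv
#'     sites:
#'       pSer: ath_pser.tsv
#' ```
#' Relative paths are resolved against the manifest's directory; all
#' referenced paths must exist.
#'
#' @param path YAML manifest.
#' @return named list of per-species entries (`category`, `fasta`,
#'   `disorder`, `sites`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  if (is.null(m$species) || !length(m$species))
    stop("manifest has no 'species' mapping")
  base <- dirname(normalizePath(path))
  out <- lapply(names(m$species), function(name) {
    sp <- m$species[[name]]
    resolve <- function(p) {
      p2 <- if (startsWith(p, "/")) p else file.path(base, p)
      if (!file.exists(p2))
        stop("species '", name, "': manifest references missing file: ", p)
      p2
    }
    if (is.null(sp$category) || !sp$category %in% c("monocot", "dicot"))
      stop("species '", name, "': category must be 'monocot' or 'dicot'")
    sp$fasta <- resolve(sp$fasta)
    sp$disorder <- resolve(sp$disorder)
    if (!is.null(sp$sites)) {
      unk <- setdiff(names(sp$sites), PTM_TYPES)
      if (length(unk))
        stop("species '", name, "': unknown ptm_type ", unk[1])
      sp$sites <- lapply(sp$sites, resolve)
    }
    sp
  })
  setNames(out, names(m$species))
}
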