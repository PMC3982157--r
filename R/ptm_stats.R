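site_subset <- function(sites, ptm_type) {
  s <- sites[sites$ptm_type == ptm_type, , drop = FALSE]
  unique(s[c("protein_id", "position", "residue", "ptm_type")])
}

#' Normalised PTM content (sites per 400 residues)
#'
#' `400 * total_sites / total_residues`, the length-normalised abundance
#' that makes proteomes with different mean protein lengths comparable.
#'
#' @param sites PTM site data frame.
#' @param profiles `disorder_profiles` covering the proteome (residue counts
#'   are taken from profile lengths).
#' @param ptm_type one of [PTM_TYPES].
#' @return list of class `content_summary`: `ptm_type`, `total_sites`,
#'   `total_residues`, `per_400`.
#' @export
normalized_content <- function(sites, profiles, ptm_type) {
  s <- site_subset(sites, ptm_type)
  total_residues <- sum(vapply(profiles, function(p) length(p$calls), 0L))
  if (total_residues == 0L) stop("zero total residues")
  structure(list(ptm_type = ptm_type,
                 total_sites = nrow(s),
                 total_residues = total_residues,
                 per_400 = 400 * nrow(s) / total_residues),
            class = "content_summary")
}

#' Disorder-to-order PTM enrichment ratio Rd/o
#'
#' Each site of the requested type is assigned to the disordered or ordered
#' proteome segment by the disorder call at its position; with `Nd`, `No`
#' the site counts and `Ld`, `Lo` the residue totals of the two segments,
#' `Rd/o = (Nd/Ld) / (No/Lo)`. A value of 1 means no structural preference,
#' above 1 a preference for disordered sequence, below 1 for ordered.
#' `No = 0` with `Nd > 0` yields `Inf` with `undefined = TRUE` rather than
#' an error (valid but degenerate on small data).
#'
#' @inheritParams normalized_content
#' @return list of class `rdo_result`: `ptm_type`, `Nd`, `No`, `Ld`, `Lo`,
#'   `rdo`, `undefined`.
#' @export
compute_rdo <- function(sites, profiles, ptm_type) {
  s <- site_subset(sites, ptm_type)
  idx <- match(s$protein_id, names(profiles))
  if (anyNA(idx))
    stop("site references protein absent from disorder profiles: ",
         s$protein_id[which(is.na(idx))[1]])
  calls_at <- mapply(function(i, pos) {
    calls <- profiles[[i]]$calls
    if (pos < 1L || pos > length(calls))
      stop("site position ", pos, " outside profile for protein '",
           names(profiles)[i], "'")
    calls[pos]
  }, idx, s$position)
  calls_at <- as.logical(calls_at)
  if (anyNA(calls_at)) stop("missing disorder call at a site position")
  Ld <- sum(vapply(profiles, function(p) sum(p$calls), 0L))
  Ltot <- sum(vapply(profiles, function(p) length(p$calls), 0L))
  Lo <- Ltot - Ld
  if (Ld == 0L || Lo == 0L)
    stop("degenerate proteome: Ld and Lo must both be positive")
  Nd <- sum(calls_at)
  No <- length(calls_at) - Nd
  stopifnot(Nd + No == nrow(s))  # conservation, asserted on every run
  rdo <- if (No == 0L && Nd > 0L) Inf
         else if (Nd == 0L && No == 0L) NaN
         else (Nd / Ld) / (No / Lo)
  structure(list(ptm_type = ptm_type, Nd = Nd, No = No, Ld = Ld, Lo = Lo,
                 rdo = rdo, undefined = !is.finite(rdo)),
            class = "rdo_result")
}

#' Per-protein site counts for one PTM type
#'
#' @inheritParams normalized_content
#' @return named integer vector over all proteins in `profiles` (zeros for
#'   proteins with no site).
#' @export
site_counts_per_protein <- function(sites, profiles, ptm_type) {
  s <- site_subset(sites, ptm_type)
  counts <- setNames(integer(length(profiles)), names(profiles))
  if (nrow(s)) {
    tab <- table(s$protein_id)
    unk <- setdiff(names(tab), names(profiles))
    if (length(unk)) stop("site references unknown protein: ", unk[1])
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Bin proteins by predicted site count
#'
#' Proteins are grouped by their per-protein count of predicted sites of one
#' PTM type; counts of `k_max` or more are pooled into a single top bin
#' (axis `0, 1, ..., >=k_max`). Each bin reports its population and the
#' unweighted mean per-protein disorder fraction; empty bins are retained
#' with `n_proteins = 0` and `NA` mean.
#'
#' @inheritParams normalized_content
#' @param k_max pooling threshold (>= 1); conventionally 4, or 7 for
#'   methylation.
#' @return data frame with `ptm_type`, `bin_index` (0-based ordinal),
#'   `bin_label`, `k_max`, `n_proteins`, `mean_disorder`.
#' @export
bin_by_site_count <- function(sites, profiles, ptm_type, k_max = 4L) {
  if (k_max < 1L) stop("k_max must be >= 1")
  counts <- site_counts_per_protein(sites, profiles, ptm_type)
  fractions <- vapply(profiles, function(p) mean(p$calls), 0)
  bin <- pmin(counts, k_max)
  out <- data.frame(
    ptm_type = ptm_type,
    bin_index = 0:k_max,
    bin_label = c(as.character(0:(k_max - 1L)), paste0(">=", k_max)),
    k_max = as.integer(k_max),
    n_proteins = vapply(0:k_max, function(b) sum(bin == b), 0L),
    mean_disorder = vapply(0:k_max, function(b) {
      if (any(bin == b)) mean(fractions[bin == b]) else NA_real_
    }, 0),
    stringsAsFactors = FALSE)
  stopifnot(sum(out$n_proteins) == length(profiles))
  out
}

#' Monocot/dicot category contrast
#'
#' Per-category means, their difference (first category minus second) and a
#' Welch two-sample t test (a declared stand-in: the original significance
#' procedure for the category contrast is not specified).
#'
#' @param values_by_species named numeric vector, one value per species.
#' @param categories named character vector (species -> "monocot"/"dicot").
#' @return list with `means`, `difference`, `t`, `p_two_tailed`, `method`.
#' @export
group_contrast <- function(values_by_species, categories) {
  categories <- categories[names(values_by_species)]
  if (anyNA(categories)) stop("every species needs a category")
  groups <- split(values_by_species, categories)
  if (length(groups) != 2L)
    stop("exactly two categories required")
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small))
    stop("category with <2 species: ", paste(small, collapse = ", "))
  tt <- t.test(groups[[1L]], groups[[2L]], var.equal = FALSE)
  list(means = vapply(groups, mean, 0),
       difference = mean(groups[[1L]]) - mean(groups[[2L]]),
       t = unname(tt$statistic),
       p_two_tailed = tt$p.value,
       method = "Welch two-sample t (stand-in)")
}
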