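#' Configuration for the synthetic proteome generator
#'
#' The generator states a simple, fully-known world: residues drawn i.i.d.
#' from `composition`; disorder as an alternating two-state block model with
#' geometric block lengths whose stationary disordered fraction is `delta`;
#' PTM sites placed independently per compatible residue at `rate` in
#' ordered sequence and `rate * rho` in disordered sequence. Everything
#' downstream can therefore be checked against closed forms.
#'
#' @param n_proteins number of proteins.
#' @param length_law `list(kind = "fixed", L)`, `list(kind = "uniform", a,
#'   b)` or `list(kind = "lognormal", meanlog, sdlog)` (truncated to
#'   `[50, 2000]`).
#' @param delta target disordered residue fraction in `(0, 1)`.
#' @param block_disordered mean disordered block length `b_d` (residues, >=
#'   1); the ordered mean is derived as `b_o = b_d * (1 - delta) / delta` so
#'   the stationary fraction is `delta`.
#' @param ptm_rates named numeric, PTM type -> per-eligible-residue base
#'   rate.
#' @param enrichment named numeric, PTM type -> disordered-rate multiplier
#'   `rho >= 0` (default 1 for every type in `ptm_rates`).
#' @param composition named residue-frequency vector over [AA_STANDARD]
#'   summing to 1 (default uniform; see [plant_composition()]).
#' @param seed integer RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 100L,
                         length_law = list(kind = "fixed", L = 400L),
                         delta = 0.30, block_disordered = 30,
                         ptm_rates = c("pSer" = 0.05),
                         enrichment = NULL,
                         composition = NULL, seed = 1L) {
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  if (block_disordered < 1) stop("block_disordered must be >= 1")
  if (is.null(enrichment))
    enrichment <- setNames(rep(1, length(ptm_rates)), names(ptm_rates))
  stopifnot(all(names(ptm_rates) %in% PTM_TYPES),
            all(names(ptm_rates) %in% names(enrichment)))
  if (any(ptm_rates < 0) || any(enrichment < 0))
    stop("rates and enrichments must be non-negative")
  if (any(ptm_rates * enrichment[names(ptm_rates)] > 1))
    stop("rate * rho exceeds 1 for some PTM type")
  if (is.null(composition))
    composition <- setNames(rep(1 / 20, 20), AA_STANDARD)
  if (!setequal(names(composition), AA_STANDARD) ||
      abs(sum(composition) - 1) > 1e-9)
    stop("composition must cover the 20 standard residues and sum to 1")
  b_o <- block_disordered * (1 - delta) / delta
  if (b_o < 1)
    stop("infeasible delta/block combination: ordered mean block < 1")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_law = length_law, delta = delta,
                 block_disordered = block_disordered,
                 block_ordered = b_o,
                 ptm_rates = ptm_rates,
                 enrichment = enrichment[names(ptm_rates)],
                 composition = composition[AA_STANDARD],
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Plant-like residue composition preset
#'
#' Elevates Ala/Gly/Pro relative to uniform and lets the caller skew the
#' Lys/Arg balance (monocot proteomes run Arg-rich/Lys-poor relative to
#' dicots); all other residues share the remaining mass equally.
#'
#' @param k,r Lys and Arg frequencies.
#' @param a,g,p Ala, Gly, Pro frequencies.
#' @return named frequency vector over [AA_STANDARD] summing to 1.
#' @export
plant_composition <- function(k = 0.060, r = 0.050,
                              a = 0.075, g = 0.070, p = 0.060) {
  fixed <- c(A = a, G = g, P = p, K = k, R = r)
  rest <- setdiff(AA_STANDARD, names(fixed))
  left <- 1 - sum(fixed)
  if (left <= 0) stop("fixed frequencies exceed 1")
  comp <- setNames(rep(left / length(rest), 20), AA_STANDARD)
  comp[names(fixed)] <- fixed
  comp[AA_STANDARD]
}

draw_length <- function(law, n) {
  switch(law$kind,
    fixed = rep(as.integer(law$L), n),
    uniform = sample(seq.int(law$a, law$b), n, replace = TRUE),
    lognormal = {
      out <- integer(0)
      while (length(out) < n) {
        x <- round(rlnorm(n, law$meanlog, law$sdlog))
        out <- c(out, x[x >= 50 & x <= 2000])
      }
      as.integer(out[seq_len(n)])
    },
    stop("unknown length law: ", law$kind))
}

draw_mask <- function(L, delta, b_d, b_o) {
  mask <- logical(0)
  state <- runif(1) < delta
  while (length(mask) < L) {
    b <- if (state) b_d else b_o
    mask <- c(mask, rep(state, rgeom(1L, 1 / b) + 1L))
    state <- !state
  }
  mask[seq_len(L)]
}

#' Generate a synthetic proteome with known ground truth
#'
#' @param config a [synth_config()].
#' @return list with `records` (`protein_records`), `profiles`
#'   (`disorder_profiles`; synthetic scores are drawn in `[0.5, 1]` for
#'   disordered and `[0, 0.5)` for ordered residues so the default 0.5
#'   threshold reproduces the calls), `sites` (PTM site data frame) and
#'   `truth` (planted `rho` plus realised `Nd`, `No` per type and global
#'   `Ld`, `Lo`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- draw_length(config$length_law, n)
  ids <- sprintf("synp%05d", seq_len(n))
  seqs <- character(n)
  calls <- scores <- vector("list", n)
  names(calls) <- names(scores) <- ids
  for (i in seq_len(n)) {
    chars <- sample(AA_STANDARD, lens[i], replace = TRUE,
                    prob = config$composition)
    seqs[i] <- paste(chars, collapse = "")
    m <- draw_mask(lens[i], config$delta, config$block_disordered,
                   config$block_ordered)
    calls[[i]] <- m
    scores[[i]] <- ifelse(m, 0.5 + 0.5 * runif(lens[i]),
                          0.499999 * runif(lens[i]))
  }
  records <- protein_records(ids, seqs)
  profiles <- disorder_profiles(calls, scores, threshold = 0.5)

  site_rows <- list()
  truth_ptm <- list()
  for (type in names(config$ptm_rates)) {
    rate <- config$ptm_rates[[type]]
    rho <- config$enrichment[[type]]
    res <- PTM_RESIDUES[[type]]
    Nd <- No <- 0L
    for (i in seq_len(n)) {
      chars <- strsplit(seqs[i], "")[[1]]
      elig <- which(chars == res)
      if (!length(elig)) next
      dis <- calls[[i]][elig]
      p <- ifelse(dis, pmin(rate * rho, 1), rate)
      hit <- rbinom(length(elig), 1L, p) == 1L
      if (any(hit)) {
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          protein_id = ids[i], position = elig[hit], residue = res,
          ptm_type = type, stringsAsFactors = FALSE)
        Nd <- Nd + sum(dis[hit])
        No <- No + sum(!dis[hit])
      }
    }
    truth_ptm[[type]] <- list(rho = rho, Nd = Nd, No = No)
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows)
           else data.frame(protein_id = character(0), position = integer(0),
                           residue = character(0), ptm_type = character(0),
                           stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  Ld <- sum(vapply(calls, sum, 0L))
  list(records = records, profiles = profiles, sites = sites,
       truth = list(ptm = truth_ptm, Ld = Ld,
                    Lo = sum(lens) - Ld, masks = calls))
}

# Literal motif instances used for planting. Each carries the 0-based
# offset of the countable site within the instance.
.motif_instances <- list(
  NGLY = list(text = "NGS",    site_offset = 0L),
  OGLY = list(text = "APGGSP", site_offset = 5L)
)

#' Plant literal motif instances at known positions
#'
#' Overwrites stretches of existing sequences with literal pattern
#' instances ("NGS" for the N-glycosylation sequon, "APGGSP" for the
#' O-glycosylation consensus) at non-overlapping sampled positions,
#' returning the exact expected site list. When `profiles` are supplied,
#' each instance lands in a disordered tract with odds
#' `placement_odds : 1` against an ordered tract; instances must fit
#' entirely inside a single tract.
#'
#' @param records `protein_records` (the background; for a guaranteed
#'   false-positive-free test use a background alphabet that cannot form
#'   the pattern, e.g. `{G, L, K}`).
#' @param pattern `"NGLY"` or `"OGLY"`.
#' @param n_instances number of instances to plant.
#' @param placement_odds disordered:ordered odds `rho` (used only with
#'   `profiles`).
#' @param profiles optional `disorder_profiles` defining tracts.
#' @param seed optional RNG seed.
#' @return list with `records` (modified), `expected_sites` (PTM site data
#'   frame) and `positions` (data frame of instance placements).
#' @export
plant_motifs <- function(records, pattern = c("NGLY", "OGLY"), n_instances,
                         placement_odds = 1, profiles = NULL, seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.null(seed)) set.seed(seed)
  inst <- .motif_instances[[pattern]]
  w <- nchar(inst$text)
  seqs <- setNames(records$sequence, records$id)
  occupied <- setNames(vector("list", nrow(records)), records$id)
  placements <- list()
  for (k in seq_len(n_instances)) {
    want_dis <- if (is.null(profiles)) NA
                else runif(1) < placement_odds / (placement_odds + 1)
    slots <- list()
    for (id in records$id) {
      L <- nchar(seqs[[id]])
      tracts <- if (is.null(profiles)) cbind(start = 1L, end = L)
      else {
        segs <- calls_to_segments(if (want_dis) profiles[[id]]$calls
                                  else !profiles[[id]]$calls)
        segs
      }
      for (ti in seq_len(nrow(tracts))) {
        lo <- tracts[ti, 1L]; hi <- tracts[ti, 2L] - w + 1L
        if (hi < lo) next
        for (st in lo:hi) {
          clash <- any(vapply(occupied[[id]], function(iv)
            st <= iv[2L] && st + w - 1L >= iv[1L], TRUE))
          if (!clash)
            slots[[length(slots) + 1L]] <- list(id = id, start = st)
        }
      }
    }
    if (!length(slots))
      stop("insufficient space to plant instance ", k, " of ", n_instances)
    pick <- slots[[sample.int(length(slots), 1L)]]
    id <- pick$id; st <- pick$start
    substr(seqs[[id]], st, st + w - 1L) <- inst$text
    occupied[[id]] <- c(occupied[[id]], list(c(st, st + w - 1L)))
    placements[[k]] <- data.frame(protein_id = id, start = st,
                                  disordered = want_dis,
                                  stringsAsFactors = FALSE)
  }
  out_records <- protein_records(records$id, unname(seqs[records$id]),
                                 species = records$species[1],
                                 category = records$category[1])
  placements <- if (length(placements)) do.call(rbind, placements)
                else data.frame(protein_id = character(0),
                                start = integer(0), disordered = logical(0))
  ptm <- if (pattern == "OGLY") "O-gly" else "N-gly"
  expected <- if (nrow(placements))
    unique(data.frame(protein_id = placements$protein_id,
                      position = placements$start + inst$site_offset,
                      residue = PTM_RESIDUES[[ptm]], ptm_type = ptm,
                      stringsAsFactors = FALSE))
  else data.frame(protein_id = character(0), position = integer(0),
                  residue = character(0), ptm_type = character(0),
                  stringsAsFactors = FALSE)
  rownames(expected) <- NULL
  list(records = out_records, expected_sites = expected,
       positions = placements)
}
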