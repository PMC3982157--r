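default_k_max <- function(ptm_type) {
  if (ptm_type %in% c("K-met", "R-met")) 7L else 4L
}

#' Run the full disorder/PTM pipeline over a species manifest
#'
#' For each species: read the FASTA proteome, apply the length filter (and
#' optionally the greedy redundancy filter), load disorder profiles and PTM
#' site tables (O-/N-glycosylation sites are derived by the motif scanners
#' when no site table is given), then compute dataset statistics, the
#' proteome disorder degree, per-PTM normalised contents, Rd/o ratios,
#' site-count bin tables and bin correlations. Cross-species
#' monocot/dicot contrasts of the disorder degree are added when both
#' categories have at least two species.
#'
#' @param config list with `manifest` (path or parsed [read_manifest()]
#'   output), and optionally `min_len` (50), `max_len` (2000), `identity`
#'   (NULL to skip redundancy filtering), `threshold` (0.5), `k_max` (named
#'   per-PTM overrides), `out_dir` (write TSVs when non-NULL), `seed`.
#' @return list of class `disptm_report` with per-species results and
#'   cross-species contrasts.
#' @export
run_all <- function(config) {
  manifest <- config$manifest
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  min_len <- config$min_len %||% 50L
  max_len <- config$max_len %||% 2000L
  threshold <- config$threshold %||% 0.5
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  species_results <- lapply(names(manifest), function(sp) {
    entry <- manifest[[sp]]
    step <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("[", sp, "/", what, "] ", conditionMessage(e), call. = FALSE))
    }
    records <- step("read_fasta",
                    read_fasta(entry$fasta, species = sp,
                               category = entry$category))
    n_input <- nrow(records)
    if (!is.null(config$identity)) {
      rf <- step("redundancy_filter",
                 redundancy_filter(records, config$identity))
      records <- rf$kept
    }
    n_red <- nrow(records)
    records <- step("length_filter",
                    length_filter(records, min_len, max_len))
    stats <- step("dataset_stats",
                  dataset_stats(records, n_input = n_input,
                                n_after_redundancy = n_red))
    profiles <- step("read_disorder",
                     read_disorder_table(entry$disorder, threshold))
    profiles <- profiles[names(profiles) %in% records$id]
    class(profiles) <- "disorder_profiles"
    miss <- setdiff(records$id, names(profiles))
    if (length(miss))
      stop("[", sp, "/disorder] no disorder profile for protein '",
           miss[1], "'", call. = FALSE)
    for (id in records$id)
      step("disorder_check",
           summarize_disorder(profiles[[id]],
                              records$sequence[records$id == id]))
    summaries <- disorder_summary_table(profiles)

    ptm_types <- unique(c(names(entry$sites), "O-gly", "N-gly"))
    sites <- do.call(rbind, lapply(ptm_types, function(type) {
      if (!is.null(entry$sites[[type]])) {
        s <- step(paste0("sites_", type),
                  read_site_table(entry$sites[[type]], proteome = records))
        s[s$ptm_type == type, , drop = FALSE]
      } else if (type == "O-gly") {
        sites_from_matches(scan_oglyc(records))
      } else {
        sites_from_matches(scan_nglyc(records))
      }
    }))
    sites <- sites[sites$protein_id %in% records$id, , drop = FALSE]

    per_ptm <- lapply(setNames(ptm_types, ptm_types), function(type) {
      km <- config$k_max[[type]] %||% default_k_max(type)
      bins <- bin_by_site_count(sites, profiles, type, km)
      corr <- tryCatch(correlate_bins(bins), error = function(e) NULL)
      list(content = normalized_content(sites, profiles, type),
           rdo = step(paste0("rdo_", type),
                      compute_rdo(sites, profiles, type)),
           bins = bins, correlation = corr)
    })

    res <- list(species = sp, category = entry$category, stats = stats,
                disorder_degree = proteome_disorder_degree(summaries),
                summaries = summaries, sites = sites, per_ptm = per_ptm)
    if (!is.null(out_dir)) write_species_tables(res, out_dir)
    res
  })
  names(species_results) <- names(manifest)

  categories <- vapply(species_results, `[[`, "", "category")
  degrees <- vapply(species_results, `[[`, 0, "disorder_degree")
  contrast <- if (all(table(categories) >= 2) &&
                  length(unique(categories)) == 2)
    group_contrast(degrees, categories) else NULL

  out <- list(species = species_results,
              disorder_degree_contrast = contrast,
              config = list(min_len = min_len, max_len = max_len,
                            identity = config$identity,
                            threshold = threshold,
                            seed = config$seed))
  class(out) <- "disptm_report"
  if (!is.null(out_dir)) {
    t1 <- format_table1(out)
    write_table(t1, file.path(out_dir, "table1_like.tsv"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_species_tables <- function(res, out_dir) {
  pref <- file.path(out_dir, res$species)
  write_table(res$summaries, paste0(pref, "_disorder_summary.tsv"))
  rows <- do.call(rbind, lapply(res$per_ptm, function(x) {
    data.frame(ptm_type = x$content$ptm_type,
               total_sites = x$content$total_sites,
               per_400 = x$content$per_400,
               Nd = x$rdo$Nd, No = x$rdo$No, Ld = x$rdo$Ld, Lo = x$rdo$Lo,
               rdo = x$rdo$rdo,
               r = if (is.null(x$correlation)) NA_real_ else x$correlation$r,
               p_one_tailed = if (is.null(x$correlation)) NA_real_
                              else x$correlation$p_one_tailed,
               stringsAsFactors = FALSE)
  }))
  write_table(rows, paste0(pref, "_ptm_stats.tsv"))
  bins <- do.call(rbind, lapply(res$per_ptm, `[[`, "bins"))
  write_table(bins, paste0(pref, "_bins.tsv"))
  invisible(NULL)
}

format_p <- function(p, floor = 1e-4) {
  ifelse(p < floor, "<0.0001", formatC(round(p, 4), format = "f",
                                       digits = 4))
}

#' Format a species-by-PTM correlation grid
#'
#' Two rows per species: Pearson r (3 decimals) above its one-tailed p
#' (4 decimals, values below 0.0001 rendered `"<0.0001"`).
#'
#' @param report a `disptm_report` from [run_all()].
#' @return data frame with `species`, `row` (`"r"` or `"p"`) and one column
#'   per PTM type.
#' @export
format_table1 <- function(report) {
  sp_list <- report$species
  if (!length(sp_list)) {
    out <- data.frame(species = character(0), row = character(0))
    return(out)
  }
  types <- unique(unlist(lapply(sp_list, function(s) names(s$per_ptm))))
  rows <- lapply(sp_list, function(s) {
    rr <- pp <- setNames(rep(NA_character_, length(types)), types)
    for (type in names(s$per_ptm)) {
      corr <- s$per_ptm[[type]]$correlation
      if (!is.null(corr)) {
        rr[type] <- formatC(round(corr$r, 3), format = "f", digits = 3)
        pp[type] <- format_p(corr$p_one_tailed)
      }
    }
    rbind(data.frame(species = s$species, row = "r", t(rr),
                     stringsAsFactors = FALSE, check.names = FALSE),
          data.frame(species = s$species, row = "p", t(pp),
                     stringsAsFactors = FALSE, check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
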