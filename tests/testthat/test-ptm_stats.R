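# Hand-built fixture: two proteins, 100 residues each of S, first all
# disordered, second all ordered.
fixture_sites_profiles <- function(nd_sites, no_sites) {
  seqs <- c(d = strrep("S", 100), o = strrep("S", 100))
  profiles <- disorder_profiles(list(d = rep(TRUE, 100),
                                     o = rep(FALSE, 100)))
  mk <- function(id, k) if (k > 0)
    data.frame(protein_id = id, position = seq_len(k), residue = "S",
               ptm_type = "pSer", stringsAsFactors = FALSE)
  sites <- rbind(mk("d", nd_sites), mk("o", no_sites))
  list(sites = sites, profiles = profiles)
}

test_that("compute_rdo applies the Nd/Ld : No/Lo formula", {
  fx <- fixture_sites_profiles(10, 5)
  r <- compute_rdo(fx$sites, fx$profiles, "pSer")
  expect_equal(r$rdo, 2.0)
  expect_equal(c(r$Nd, r$No, r$Ld, r$Lo), c(10, 5, 100, 100))
  expect_false(r$undefined)

  expect_equal(compute_rdo(fixture_sites_profiles(0, 5)$sites,
                           fx$profiles, "pSer")$rdo, 0)

  inf <- compute_rdo(fixture_sites_profiles(4, 0)$sites, fx$profiles, "pSer")
  expect_true(is.infinite(inf$rdo) && inf$undefined)
})

test_that("compute_rdo rejects degenerate or inconsistent inputs", {
  all_dis <- disorder_profiles(list(d = rep(TRUE, 50)))
  s <- data.frame(protein_id = "d", position = 1L, residue = "S",
                  ptm_type = "pSer")
  expect_error(compute_rdo(s, all_dis, "pSer"), "degenerate")

  fx <- fixture_sites_profiles(1, 1)
  bad <- fx$sites; bad$protein_id[1] <- "ghost"
  expect_error(compute_rdo(bad, fx$profiles, "pSer"), "absent")

  na_prof <- disorder_profiles(list(d = c(TRUE, NA), o = rep(FALSE, 2)))
  s2 <- data.frame(protein_id = "d", position = 2L, residue = "S",
                   ptm_type = "pSer")
  expect_error(compute_rdo(s2, na_prof, "pSer"), "missing disorder call")
})

test_that("normalized_content normalises per 400 residues", {
  fx <- fixture_sites_profiles(5, 5)
  profiles50 <- disorder_profiles(
    setNames(lapply(1:40, function(i) rep(c(TRUE, FALSE), 50)),
             paste0("q", 1:40)))  # 4000 residues
  sites10 <- data.frame(protein_id = "q1", position = 1:10, residue = "S",
                        ptm_type = "pSer")
  expect_equal(normalized_content(sites10, profiles50, "pSer")$per_400, 1.0)
  expect_equal(normalized_content(sites10[0, ], profiles50, "pSer")$per_400,
               0.0)
})

test_that("normalized content matches the generator's closed form", {
  # E[per_400] = 400 * rate * (delta*rho + 1 - delta) * f_aa
  cfg <- synth_config(n_proteins = 1000, delta = 0.3,
                      ptm_rates = c("pSer" = 0.1),
                      enrichment = c("pSer" = 2), seed = 33)
  sim <- generate_proteome(cfg)
  expected <- 400 * 0.1 * (0.3 * 2 + 0.7) * 0.05
  got <- normalized_content(sim$sites, sim$profiles, "pSer")$per_400
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("bin_by_site_count pools the top bin and keeps empty bins", {
  profiles <- disorder_profiles(setNames(
    list(rep(TRUE, 10), rep(FALSE, 10), c(rep(TRUE, 5), rep(FALSE, 5)),
         rep(TRUE, 10)),
    c("a", "b", "c", "d")))
  # per-protein pSer counts: a=0, b=0, c=1, d=5
  sites <- data.frame(protein_id = "d", position = 1:5, residue = "K",
                      ptm_type = "K-ace")
  sites <- rbind(sites, data.frame(protein_id = "c", position = 1L,
                                   residue = "K", ptm_type = "K-ace"))
  bins <- bin_by_site_count(sites, profiles, "K-ace", k_max = 4)
  expect_equal(bins$n_proteins, c(2L, 1L, 0L, 0L, 1L))
  expect_equal(bins$bin_label, c("0", "1", "2", "3", ">=4"))
  expect_true(is.na(bins$mean_disorder[3]))
  expect_equal(bins$mean_disorder[1], 0.5)   # mean of a (1.0) and b (0.0)
  expect_equal(sum(bins$n_proteins), length(profiles))

  # all proteins zero sites -> only bin "0" populated
  b0 <- bin_by_site_count(sites[0, ], profiles, "K-ace", 4)
  expect_equal(b0$n_proteins, c(4L, 0L, 0L, 0L, 0L))

  expect_error(bin_by_site_count(sites, profiles, "K-ace", 0), "k_max")
})

test_that("bin populations always sum to proteome size", {
  set.seed(3)
  sim <- generate_proteome(synth_config(
    n_proteins = 80, ptm_rates = c("pSer" = 0.05, "K-met" = 0.02),
    enrichment = c("pSer" = 3, "K-met" = 0.5), seed = 3))
  for (type in c("pSer", "K-met"))
    for (km in c(1, 4, 7)) {
      bins <- bin_by_site_count(sim$sites, sim$profiles, type, km)
      expect_equal(sum(bins$n_proteins), 80L)
    }
})

test_that("enriched placement yields increasing bin mean disorder", {
  sim <- generate_proteome(synth_config(n_proteins = 800,
                                        ptm_rates = c("pSer" = 0.06),
                                        enrichment = c("pSer" = 4),
                                        seed = 17))
  bins <- bin_by_site_count(sim$sites, sim$profiles, "pSer", 4)
  md <- bins$mean_disorder[bins$n_proteins > 0]
  expect_true(all(diff(md) > 0))
})

test_that("group_contrast compares categories with Welch's t", {
  vals <- c(a = 34, b = 33, c = 32, d = 23, e = 24, f = 25)
  cats <- c(a = "monocot", b = "monocot", c = "monocot",
            d = "dicot", e = "dicot", f = "dicot")
  gc <- group_contrast(vals, cats)
  expect_equal(abs(gc$difference), 9)
  expect_lt(gc$p_two_tailed, 0.01)

  same <- group_contrast(c(a = 1, b = 2, c = 1, d = 2),
                         c(a = "monocot", b = "monocot",
                           c = "dicot", d = "dicot"))
  expect_equal(same$difference, 0)
  expect_gt(same$p_two_tailed, 0.99)

  expect_error(group_contrast(c(a = 1, b = 2, c = 3),
                              c(a = "monocot", b = "dicot", c = "dicot")),
               "<2 species")
})
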