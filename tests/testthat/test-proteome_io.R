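write_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_fasta parses headers, case-folds and strips stops", {
  f <- write_lines(c(">p1", "MKV"))
  rec <- read_fasta(f)
  expect_equal(rec$id, "p1")
  expect_equal(rec$sequence, "MKV")

  f2 <- write_lines(c(">p1 some description", "mkv"))
  rec2 <- read_fasta(f2)
  expect_equal(rec2$id, "p1")
  expect_equal(rec2$sequence, "MKV")

  f3 <- write_lines(c(">p1", "MKV*"))
  expect_equal(read_fasta(f3)$sequence, "MKV")
})

test_that("read_fasta enforces the record contract", {
  expect_error(read_fasta(write_lines(c(">a", "AA", ">a", "CC"))),
               "duplicate.*a")
  expect_error(read_fasta(write_lines(character(0))), "empty")
  expect_error(read_fasta(write_lines(c(">p1", "MKB9"))),
               "non-amino-acid")
})

test_that("FASTA round trip reproduces records", {
  set.seed(11)
  recs <- protein_records(sprintf("pr%02d", 1:8),
                          replicate(8, rand_seq(sample(20:80, 1),
                                                c(AA20, "X"))),
                          species = "test")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f, species = "test")
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("read_disorder_table thresholds scores (boundary inclusive)", {
  f <- write_lines(c("protein_id\tposition\tscore",
                     "p1\t1\t0.9", "p1\t2\t0.1", "p1\t3\t0.5"))
  prof <- read_disorder_table(f, threshold = 0.5)
  expect_equal(prof[["p1"]]$calls, c(TRUE, FALSE, TRUE))
  # explicit call column wins over scores
  f2 <- write_lines(c("protein_id\tposition\tscore\tcall",
                      "p1\t1\t0.9\t0"))
  expect_false(read_disorder_table(f2)[["p1"]]$calls)
})

test_that("read_disorder_table rejects malformed tables", {
  f <- write_lines(c("protein_id\tposition\tscore",
                     "p1\t1\t0.9", "p1\t3\t0.2"))
  expect_error(read_disorder_table(f), "contiguous")
  f2 <- write_lines(c("protein_id\tposition\tscore", "p1\t1\t1.7"))
  expect_error(read_disorder_table(f2), "\\[0, 1\\]")
  f3 <- write_lines(c("protein_id\tposition\tscore",
                      "p1\t1\t0.9", "p1\t1\t0.9"))
  expect_error(read_disorder_table(f3), "gap or duplicate")
})

test_that("read_site_table validates types, residues and ranges", {
  prot <- protein_records("p1", "ASA")
  f <- write_lines(c("protein_id\tposition\tresidue\tptm_type",
                     "p1\t2\tS\tpSer"))
  s <- read_site_table(f, proteome = prot)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 2L)

  f2 <- write_lines(c("protein_id\tposition\tresidue\tptm_type",
                      "p1\t2\tT\tpSer"))
  expect_error(read_site_table(f2), "incompatib")
  f3 <- write_lines(c("protein_id\tposition\tresidue\tptm_type",
                      "p1\t9\tS\tpSer"))
  expect_error(read_site_table(f3, proteome = prot), "out of range")
  f4 <- write_lines(c("protein_id\tposition\tresidue\tptm_type",
                      "p1\t2\tS\tphospho"))
  expect_error(read_site_table(f4), "unknown ptm_type")
  # residue cross-check against the actual sequence character
  f5 <- write_lines(c("protein_id\tposition\tresidue\tptm_type",
                      "p1\t1\tS\tpSer"))
  expect_error(read_site_table(f5, proteome = prot), "mismatch")
})

test_that("write_table formats and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(data.frame(a = 1L), f)
  expect_equal(readLines(f), c("a", "1"))

  write_table(data.frame(x = 0.00016), f)
  expect_equal(readLines(f)[2], "0.0002")

  expect_error(write_table(data.frame(), f), "empty")

  d <- data.frame(id = c("a", "b"), v = c(0.12345678, 2.5))
  write_table(d, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$v, round(d$v, 4))
  expect_equal(back$id, d$id)
})

test_that("read_manifest resolves paths and validates categories", {
  dir <- withr::local_tempdir()
  writeLines(c(">p1", "MKVNAS"), file.path(dir, "x.fasta"))
  writeLines(c("protein_id\tposition\tscore",
               paste("p1", 1:6, "0.9", sep = "\t")),
             file.path(dir, "x_dis.tsv"))
  writeLines(c("species:",
               "  sp1:",
               "    category: dicot",
               "    fasta: x.fasta",
               "    disorder: x_dis.tsv"),
             file.path(dir, "manifest.yaml"))
  m <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_named(m, "sp1")
  expect_true(file.exists(m$sp1$fasta))

  writeLines(c("species:",
               "  sp1:",
               "    category: dicot",
               "    fasta: missing.fasta",
               "    disorder: x_dis.tsv"),
             file.path(dir, "bad.yaml"))
  expect_error(read_manifest(file.path(dir, "bad.yaml")), "missing")
})
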