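# ACE/QUAL parsing, the padded-alignment model, and quality attachment.

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".ace", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_ace parses contigs, offsets and strands", {
  ace <- write_lines_tmp(c(
    "AS 1 2", "",
    "CO ctg1 10 2 0 U", "ACGTACGTAC", "",
    "AF r1 U 1",
    "AF r2 C 3", "",
    "RD r1 10 0 0", "ACGTACGTAC", "",
    "QA r1 1 10 1 10", "",
    "RD r2 8 0 0", "GTACGTAC", "",
    "QA r2 1 8 1 8"))
  asm <- read_ace(ace)
  expect_length(asm, 1)
  ca <- asm[[1]]
  expect_s3_class(ca, "contig_alignment")
  expect_equal(ca$n_cols, 10)
  expect_length(ca$reads, 2)
  r <- setNames(ca$reads, vapply(ca$reads, `[[`, "", "read_id"))
  # identity case: both reads cover their span, column depths follow
  prof <- column_profile(ca)
  expect_equal(prof$depth, c(1, 1, rep(2, 8)))
  # AF position 3 (1-based) -> start_col 2 (0-based)
  expect_equal(r$r2$start_col, 2L)
  expect_equal(r$r1$start_col, 0L)
  expect_equal(r$r2$strand, "-")
  expect_equal(r$r1$strand, "+")
})

test_that("read_ace rejects malformed input with line numbers", {
  bad <- write_lines_tmp(c("AS 1 1", "", "CO ctg1 4 1 0 U", "ACGT", "",
                           "AF r1 X 1"))
  expect_error(read_ace(bad), "line 6")
  orphan <- write_lines_tmp(c("AS 1 1", "", "CO ctg1 4 1 0 U", "ACGT", "",
                              "AF r1 U 1", "AF ghost U 2", "",
                              "RD r1 4 0 0", "ACGT"))
  expect_error(read_ace(orphan), "ghost")
  short <- write_lines_tmp(c("AS 1 0", "", "CO ctg1 9 0 0 U", "ACGT"))
  expect_error(read_ace(short), "declares 9")
})

test_that("simulated 3-contig assembly round-trips write -> read to an equal model", {
  sim <- simulate_assembly(sim_config(seed = 11, n_contigs = 3))
  f <- withr::local_tempfile(fileext = ".ace")
  write_ace(sim$alignments, f)
  back <- read_ace(f)
  expect_length(back, 3)
  for (k in seq_len(3)) {
    a <- sim$alignments[[k]]
    b <- back[[k]]
    expect_equal(b$contig_id, a$contig_id)
    expect_equal(b$n_cols, a$n_cols)
    ids <- vapply(b$reads, `[[`, "", "read_id")
    for (ra in a$reads) {
      rb <- b$reads[[match(ra$read_id, ids)]]
      expect_equal(rb$padded_seq, ra$padded_seq)
      expect_equal(rb$start_col, ra$start_col)
      expect_equal(rb$strand, ra$strand)
    }
  }
})

test_that("attach_qualities maps qualities through pads and strands", {
  # no pads: qualities pass through
  ca <- make_alignment("ACGT")
  ca$reads[[1]]$padded_qual <- rep(NA_integer_, 4)
  out <- attach_qualities(list(ca), list(c1_r01 = c(30L, 30L, 30L, 30L)))
  expect_equal(out[[1]]$reads[[1]]$padded_qual, c(30L, 30L, 30L, 30L))
  # pad at column 3 (0-based 2): imputed as min of neighbours 20 and 40
  ca <- make_alignment("AC*GT")
  ca$reads[[1]]$padded_qual <- rep(NA_integer_, 5)
  out <- attach_qualities(list(ca), list(c1_r01 = c(30L, 20L, 40L, 40L)))
  expect_equal(out[[1]]$reads[[1]]$padded_qual, c(30L, 20L, 20L, 40L, 40L))
  # reverse-strand read: quality vector reversed before padding
  ca <- make_alignment("AC*GT", strands = "-")
  ca$reads[[1]]$padded_qual <- rep(NA_integer_, 5)
  out <- attach_qualities(list(ca), list(c1_r01 = c(40L, 40L, 20L, 30L)))
  expect_equal(out[[1]]$reads[[1]]$padded_qual, c(30L, 20L, 20L, 40L, 40L))
  # length mismatch names the read
  expect_error(attach_qualities(list(ca), list(c1_r01 = c(30L, 30L))),
               "c1_r01")
  expect_error(attach_qualities(list(ca), list(other = 1:4)), "c1_r01")
})

test_that("simulated QUAL files reattach to the exact simulated qualities", {
  dir <- withr::local_tempdir()
  sim <- simulate_assembly(sim_config(seed = 12, n_contigs = 3), dir = dir)
  asm <- attach_qualities(read_ace(sim$ace), sim$qual)
  for (k in seq_along(asm)) {
    a <- sim$alignments[[k]]
    ids <- vapply(asm[[k]]$reads, `[[`, "", "read_id")
    for (ra in a$reads) {
      rb <- asm[[k]]$reads[[match(ra$read_id, ids)]]
      expect_identical(rb$padded_qual, ra$padded_qual)
    }
  }
})

test_that("organ assignment uses the sidecar and defaults to untagged", {
  ca <- make_alignment(c("ACGT", "ACGT"), starts = c(0, 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c1_r01\troot", f)
  out <- assign_organs(list(ca), read_mids(f))
  expect_equal(vapply(out[[1]]$reads, `[[`, "", "organ"), c("root", "untagged"))
  # per-organ read counts partition the total
  organs <- vapply(out[[1]]$reads, `[[`, "", "organ")
  expect_equal(sum(table(organs)), length(out[[1]]$reads))
})

test_that("column_profile equals a brute-force recount", {
  set.seed(5)
  ca <- random_alignment(n_cols = 15)
  prof <- column_profile(ca)
  m <- matrix(NA_character_, length(ca$reads), ca$n_cols)
  for (i in seq_along(ca$reads)) {
    r <- ca$reads[[i]]
    m[i, (r$start_col + 1):(r$start_col + nchar(r$padded_seq))] <-
      strsplit(r$padded_seq, "")[[1]]
  }
  for (j in seq_len(ca$n_cols)) {
    expect_equal(prof$depth[j], sum(!is.na(m[, j])))
    expect_equal(prof$A[j], sum(m[, j] == "A", na.rm = TRUE))
    expect_equal(prof$gap[j], sum(m[, j] == "*", na.rm = TRUE))
  }
})

test_that("write_tsv is deterministic and round-trips", {
  df <- data.frame(contig_id = c("b", "a", "a"), pos = c(1L, 2L, 1L),
                   x = c(1.5, 2.5, 3.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(df, f)
  back <- read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(back$contig_id, c("a", "a", "b"))
  expect_equal(back$pos, c(1L, 2L, 1L))
  expect_equal(back$x, c(3.5, 2.5, 1.5))
})
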