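# Mismatch calling, binomial probabilities, post-filters, density summary.

test_that("binomial probabilities match closed forms and the paper's worked cases", {
  # cumulative P(K <= 3 | 29, 0.25): the discarded 3/29 configuration
  expect_equal(binom_cum_p(3, 29, 0.25), brute_binom_cum(3, 29, 0.25),
               tolerance = 1e-12)
  expect_lt(binom_cum_p(3, 29, 0.25), 0.05)
  expect_equal(round(binom_cum_p(3, 29, 0.25), 4), 0.0455)
  # point P(K = 2 | 8, 0.25) = 0.31 (2 d.p.), the minimal passing configuration
  expect_equal(round(binom_point_p(2, 8, 0.25), 2), 0.31)
  expect_gt(binom_cum_p(2, 8, 0.25), 0.05)
  # trivial identities
  expect_equal(binom_cum_p(17, 17, 0.3), 1.0)
  expect_equal(binom_cum_p(0, 8, 0.25), 0.75^8)
  expect_equal(binom_point_p(0, 0, 0.25), 1.0)
  expect_equal(binom_point_p(1, 1, 0.25), 0.25)
  # argument validation
  expect_error(binom_cum_p(5, 3, 0.25), "t <= x")
  expect_error(binom_cum_p(-1, 3, 0.25), "t <= x")
  expect_error(binom_point_p(1, 3, 0), "0 < p < 1")
  expect_error(binom_cum_p(1.5, 3, 0.25), "integer")
})

test_that("binom_cum_p equals brute-force summation for all t <= x <= 60", {
  for (p in c(0.25, 0.1, 0.5)) {
    for (x in 0:60) {
      t <- 0:x
      got <- vapply(t, binom_cum_p, numeric(1), x = x, p = p)
      want <- vapply(t, brute_binom_cum, numeric(1), x = x, p = p)
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("call_mismatches classifies sites and computes maf/t", {
  # transition A/G with maf 1/3
  m <- clean_assembly(make_column(c(A = 6, G = 3)))
  rec <- call_mismatches(m)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$depth, 9)
  expect_equal(rec$maf, 1 / 3)
  expect_equal(rec$t, 3L)
  expect_equal(rec$var_class, "transition")
  expect_equal(rec$ref, "A")
  # gap state present -> indel
  m <- clean_assembly(make_column(c(A = 6, "*" = 2)))
  expect_equal(call_mismatches(m)$var_class, "indel")
  # three states -> multiallelic, t = rarest count
  m <- clean_assembly(make_column(c(A = 10, C = 5, G = 3)))
  rec <- call_mismatches(m)
  expect_equal(rec$var_class, "multiallelic")
  expect_equal(rec$n_states, 3L)
  expect_equal(rec$t, 3L)
  # monomorphic column -> no record
  m <- clean_assembly(make_column(c(A = 12)))
  expect_equal(nrow(call_mismatches(m)), 0)
  # transversion
  m <- clean_assembly(make_column(c(A = 6, C = 4)))
  expect_equal(call_mismatches(m)$var_class, "transversion")
})

# a synthetic record table for filter tests
rec_row <- function(contig, pos, t, depth, class = "transition") {
  data.frame(contig_id = contig, clean_pos = pos, orig_col = pos,
             states = "A/G", counts = paste(depth - t, t, sep = "/"),
             mean_quals = "30.0/30.0", ref = "A", depth = depth,
             n_states = 2L, maf = t / depth, t = t, var_class = class,
             binom_p = NA_real_, adjacent = NA, binom_fail = NA,
             low_depth = NA, passed = NA)
}

test_that("post_filter flags adjacency (whole runs), binomial and depth", {
  recs <- rbind(rec_row("c1", 41, 4, 12), rec_row("c1", 42, 4, 12),
                rec_row("c1", 50, 3, 29), rec_row("c1", 60, 2, 8),
                rec_row("c2", 41, 2, 7),
                rec_row("c2", 10, 3, 10), rec_row("c2", 11, 3, 10),
                rec_row("c2", 12, 3, 10))
  out <- post_filter(recs)
  row <- function(c, p) out[out$contig_id == c & out$clean_pos == p, ]
  # both members of an adjacent pair flagged; runs flagged in full
  expect_true(row("c1", 41)$adjacent && row("c1", 42)$adjacent)
  expect_true(all(c(row("c2", 10)$adjacent, row("c2", 11)$adjacent,
                    row("c2", 12)$adjacent)))
  # position 41 on c2 is not adjacent to anything (per-contig windows)
  expect_false(row("c2", 41)$adjacent)
  # 3/29 fails the binomial test (P ~ 0.0455 < 0.05)
  expect_true(row("c1", 50)$binom_fail)
  expect_equal(row("c1", 50)$binom_p, 0.04550536, tolerance = 1e-6)
  expect_false(row("c1", 50)$passed)
  # 2/8 passes binomial (cumulative 0.679) and depth (8 >= 8)
  expect_false(row("c1", 60)$binom_fail)
  expect_false(row("c1", 60)$low_depth)
  expect_true(row("c1", 60)$passed)
  # depth 7 < 8 flagged
  expect_true(row("c2", 41)$low_depth)
  expect_error(post_filter(recs, n_gametes = 1), "at least 2")
})

test_that("post-filter monotonicity in alpha and depth_min", {
  set.seed(99)
  recs <- do.call(rbind, lapply(1:80, function(i) {
    depth <- sample(4:40, 1)
    rec_row("c1", i * 3, sample(seq_len(max(1, floor(depth / 2))), 1), depth)
  }))
  passed_n <- function(a, d) sum(post_filter(recs, alpha = a, depth_min = d)$passed)
  for (a in c(0.01, 0.05, 0.2)) {
    expect_gte(passed_n(a, 8), passed_n(a, 12))
  }
  for (d in c(4, 8, 16)) {
    expect_gte(passed_n(0.01, d), passed_n(0.05, d))
    expect_gte(passed_n(0.05, d), passed_n(0.2, d))
  }
})

test_that("flags are independent of record ordering", {
  recs <- rbind(rec_row("c1", 12, 3, 10), rec_row("c1", 11, 3, 10),
                rec_row("c2", 5, 2, 8), rec_row("c1", 30, 3, 29))
  a <- post_filter(recs)
  b <- post_filter(recs[sample(nrow(recs)), ])
  expect_equal(a, b)
})

test_that("density summary fields are internally consistent", {
  # 2 passing mismatches over 400 columns at depth >= 8 -> 0.5 per 100 bp
  seqs <- rep(paste(rep("A", 400), collapse = ""), 8)
  ca <- make_alignment(seqs, contig_id = "flat")
  m <- clean_assembly(ca)
  recs <- rbind(rec_row("flat", 41, 4, 12, "transition"),
                rec_row("flat", 100, 4, 12, "transition"),
                rec_row("flat", 200, 2, 7, "transversion"))
  recs <- post_filter(recs)
  s <- summarize_mismatches(recs, list(m))
  expect_equal(s$denom_bases, 400)
  expect_equal(s$n_mismatch, 2)  # the depth-7 record is excluded in both blocks
  expect_equal(s$density_per_100bp, 0.5)
  expect_equal(s$n_biallelic + s$n_multiallelic, s$n_mismatch)
  # Ti/Tv from class tallies
  recs2 <- post_filter(rbind(rec_row("flat", 41, 4, 12, "transition"),
                             rec_row("flat", 100, 4, 12, "transition"),
                             rec_row("flat", 200, 4, 12, "transversion")))
  s2 <- summarize_mismatches(recs2, list(m))
  expect_equal(s2$titv, 2)
  # no transversions -> Ti/Tv is NA
  s3 <- summarize_mismatches(post_filter(rec_row("flat", 41, 4, 12)), list(m))
  expect_true(is.na(s3$titv))
  # zero denominator -> NA density
  tiny <- clean_assembly(make_column(c(A = 3)))
  s4 <- summarize_mismatches(post_filter(rec_row("c1", 1, 2, 8)), list(tiny))
  expect_true(is.na(s4$density_per_100bp))
})

test_that("summary matches a brute-force recount on synthetic data", {
  sim <- simulate_assembly(sim_config(seed = 33, n_contigs = 12))
  cl <- lapply(sim$alignments, clean_assembly)
  recs <- post_filter(call_mismatches(cl))
  s_before <- summarize_mismatches(recs, cl, passed_only = FALSE)
  s_after <- summarize_mismatches(recs, cl, passed_only = TRUE)
  # recount from the record table directly
  base <- recs[!(recs$adjacent | recs$low_depth), ]
  after <- base[!base$binom_fail, ]
  expect_equal(s_before$n_mismatch, nrow(base))
  expect_equal(s_after$n_mismatch, nrow(after))
  expect_equal(s_after$n_variant_contigs, length(unique(after$contig_id)))
  # denominator: count columns with >= 8 unmasked entries by brute force
  denom <- 0
  for (m in cl) {
    for (j in m$kept_cols + 1L) {
      sel <- !is.na(m$base[, j]) & is.na(m$mask[, j])
      denom <- denom + (sum(sel) >= 8)
    }
  }
  expect_equal(s_before$denom_bases, denom)
  expect_equal(s_before$density_per_100bp, 100 * nrow(base) / denom)
  # binomial filtering can only lower density on the same denominator
  expect_lte(s_after$density_per_100bp, s_before$density_per_100bp)
})
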