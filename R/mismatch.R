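# Mismatch (candidate SNP/indel) calling from cleaned assemblies, binomial
# false-positive filtering, and density summaries.
#
# The probabilistic filter: with 2 pooled diploid genotypes, 2N = 4 gametes
# were sequenced, so a true variant has expected pool frequency p >= 1/2N =
# 0.25. A site observed t times among x reads with cumulative binomial
# probability P(K <= t | x, p) < alpha is more extreme than a true minimum-
# frequency variant would plausibly be, and is discarded as a false positive.

#' Binomial point probability
#'
#' Probability of observing a variant exactly `t` times among `x` reads when
#' its expected pool frequency is `p`: `C(x,t) p^t (1-p)^(x-t)`.
#'
#' @param t Observed minor-variant count (0 <= t <= x).
#' @param x Depth (number of reads).
#' @param p Expected variant frequency in the sequenced pool, in (0, 1).
#' @return Probability.
#' @export
binom_point_p <- function(t, x, p) {
  check_binom_args(t, x, p)
  stats::dbinom(t, size = x, prob = p)
}

#' Cumulative binomial probability of t or fewer
#'
#' `sum_{k=0..t} C(x,k) p^k (1-p)^(x-k)` — the probability of observing the
#' minority variant `t` times or fewer among `x` reads.
#'
#' @inheritParams binom_point_p
#' @return Probability.
#' @export
binom_cum_p <- function(t, x, p) {
  check_binom_args(t, x, p)
  stats::pbinom(t, size = x, prob = p)
}

check_binom_args <- function(t, x, p) {
  if (any(is.na(t)) || any(is.na(x)) || any(is.na(p))) stop("NA argument")
  if (any(t != floor(t)) || any(x != floor(x))) stop("t and x must be integers")
  if (any(t < 0) || any(x < 0) || any(t > x)) stop("need 0 <= t <= x")
  if (any(p <= 0) || any(p >= 1)) stop("need 0 < p < 1")
  invisible(TRUE)
}

classify_site <- function(states) {
  if (length(states) > 2L) return("multiallelic")
  if ("*" %in% states) return("indel")
  pair <- paste(sort(states), collapse = "")
  if (pair %in% c("AG", "CT")) "transition" else "transversion"
}

#' Call mismatches from a cleaned assembly
#'
#' One record per kept column with two or more distinct unmasked states
#' (pads included). Positions are 1-based in cleaned-column space; `orig_col`
#' maps back to the original padded column (1-based).
#'
#' @param m A cleaned `masked_assembly`, or a list of them.
#' @return data.frame of mismatch records: states and counts, depth (unmasked
#'   bases incl. pads), per-state mean qualities, minor allele frequency
#'   `maf`, minor count `t`, variant class, and empty filter columns to be
#'   filled by [post_filter()].
#' @export
call_mismatches <- function(m) {
  if (inherits(m, "masked_assembly")) m <- list(m)
  recs <- lapply(m, call_mismatches_one)
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- empty_records()
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(contig_id = character(), clean_pos = integer(),
             orig_col = integer(), states = character(), counts = character(),
             mean_quals = character(), ref = character(), depth = integer(),
             n_states = integer(), maf = numeric(), t = integer(),
             var_class = character(), binom_p = numeric(),
             adjacent = logical(), binom_fail = logical(),
             low_depth = logical(), passed = logical())
}

call_mismatches_one <- function(m) {
  stopifnot(inherits(m, "masked_assembly"))
  rows <- list()
  for (k in seq_along(m$kept_cols)) {
    j <- m$kept_cols[k] + 1L
    u <- unmasked_column(m, j)
    if (!length(u$states)) next
    tb <- table(u$states)
    if (length(tb) < 2L) next
    cnts <- as.integer(tb)
    sts <- names(tb)
    ord <- order(-cnts, match(sts, STATES))   # major first, deterministic ties
    sts <- sts[ord]; cnts <- cnts[ord]
    mq <- vapply(sts, function(s) mean(u$quals[u$states == s]), numeric(1))
    depth <- sum(cnts)
    tmin <- min(cnts)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = m$contig$contig_id,
      clean_pos = k,
      orig_col = j,
      states = paste(sts, collapse = "/"),
      counts = paste(cnts, collapse = "/"),
      mean_quals = paste(sprintf("%.1f", mq), collapse = "/"),
      ref = sts[1],
      depth = depth,
      n_states = length(sts),
      maf = tmin / depth,
      t = tmin,
      var_class = classify_site(sts),
      binom_p = NA_real_,
      adjacent = NA, binom_fail = NA, low_depth = NA, passed = NA)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Apply the post-filters to a mismatch table
#'
#' Non-destructive: every record is returned with three flags set.
#' `adjacent` — both members of any pair of records at consecutive cleaned
#' positions within a contig (runs are flagged in full), as adjacency signals
#' assembly artefacts. `binom_fail` — the cumulative binomial probability of
#' observing the minor variant `t` times or fewer among `depth` reads at the
#' minimum expected pool frequency `1/n_gametes` falls below `alpha`.
#' `low_depth` — depth below `depth_min`. `passed` is true when no flag is set.
#'
#' @param recs Mismatch table from [call_mismatches()].
#' @param n_gametes Number of haploid genomes in the pool (2 genotypes -> 4).
#' @param alpha Binomial false-positive threshold (default 0.05).
#' @param depth_min Minimum depth (default 8).
#' @return The table with `binom_p`, flags and `passed` filled in.
#' @export
post_filter <- function(recs, n_gametes = 4, alpha = 0.05, depth_min = 8) {
  if (n_gametes < 2) stop("n_gametes must be at least 2")
  if (!nrow(recs)) {
    return(recs)
  }
  recs <- recs[order(recs$contig_id, recs$clean_pos), , drop = FALSE]
  p <- 1 / n_gametes
  recs$binom_p <- stats::pbinom(recs$t, size = recs$depth, prob = p)
  recs$binom_fail <- recs$binom_p < alpha
  recs$low_depth <- recs$depth < depth_min
  recs$adjacent <- FALSE
  for (cid in unique(recs$contig_id)) {
    sel <- which(recs$contig_id == cid)
    pos <- recs$clean_pos[sel]
    nb <- c(diff(pos) == 1L, FALSE) | c(FALSE, diff(pos) == 1L)
    recs$adjacent[sel] <- nb
  }
  recs$passed <- !(recs$adjacent | recs$binom_fail | recs$low_depth)
  rownames(recs) <- NULL
  recs
}

#' Summarise a mismatch table in the before/after-binomial layout
#'
#' Reproduces the structure of the per-species mismatch identification table:
#' counts of mismatches, variant-containing contigs, biallelic vs multiallelic
#' sites, transitions/transversions (biallelic substitutions only), indels,
#' Ti/Tv, and the mismatch density per 100 bp with denominator restricted to
#' kept columns of unmasked depth at least `depth_min`. The adjacency and
#' depth filters apply in both blocks; `passed_only = TRUE` additionally
#' excludes binomial failures (the "after post-filtering" block).
#'
#' @param recs Post-filtered mismatch table (see [post_filter()]).
#' @param cleaned List of cleaned `masked_assembly` objects (the full set the
#'   records were called from, used for the density denominator and contig
#'   totals).
#' @param depth_min Depth threshold for the density denominator (default 8).
#' @param passed_only If `TRUE`, restrict to records passing the binomial
#'   filter as well.
#' @return A `density_summary` list.
#' @export
summarize_mismatches <- function(recs, cleaned, depth_min = 8,
                                 passed_only = FALSE) {
  if (inherits(cleaned, "masked_assembly")) cleaned <- list(cleaned)
  if (nrow(recs) && anyNA(recs$adjacent)) {
    stop("records have no filter flags; run post_filter() first")
  }
  keep <- if (nrow(recs)) !(recs$adjacent | recs$low_depth) else logical(0)
  if (passed_only && nrow(recs)) keep <- keep & !recs$binom_fail
  set <- recs[keep, , drop = FALSE]
  denom <- sum(vapply(cleaned, function(m) {
    sum(vapply(m$kept_cols + 1L, function(j) {
      length(unmasked_column(m, j)$states) >= depth_min
    }, logical(1)))
  }, numeric(1)))
  n_contigs <- length(cleaned)
  n_mm <- nrow(set)
  n_bi <- sum(set$n_states == 2L)
  n_ti <- sum(set$var_class == "transition")
  n_tv <- sum(set$var_class == "transversion")
  n_indel <- sum(set$var_class == "indel")
  n_multi <- sum(set$var_class == "multiallelic")
  structure(list(
    n_mismatch = n_mm,
    n_variant_contigs = length(unique(set$contig_id)),
    n_contigs = n_contigs,
    pct_variant_contigs = if (n_contigs) length(unique(set$contig_id)) / n_contigs else NA_real_,
    denom_bases = denom,
    density_per_100bp = if (denom > 0) 100 * n_mm / denom else NA_real_,
    n_biallelic = n_bi,
    n_transition = n_ti,
    n_transversion = n_tv,
    titv = if (n_tv > 0) n_ti / n_tv else NA_real_,
    n_indel = n_indel,
    n_multiallelic = n_multi,
    depth_min = depth_min,
    passed_only = passed_only), class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat("<density_summary> ",
      if (x$passed_only) "after" else "before", " binomial post-filtering\n",
      "  mismatches: ", x$n_mismatch,
      " (biallelic ", x$n_biallelic, ", multiallelic ", x$n_multiallelic, ")\n",
      "  variant-containing contigs: ", x$n_variant_contigs, "/", x$n_contigs,
      sprintf(" (%.2f%%)\n", 100 * x$pct_variant_contigs),
      "  density: ", sprintf("%.3f", x$density_per_100bp), " /100 bp over ",
      x$denom_bases, " bases at depth >= ", x$depth_min, "\n",
      "  Ti ", x$n_transition, " / Tv ", x$n_transversion,
      " (Ti/Tv ", sprintf("%.2f", x$titv), "), indels ", x$n_indel, "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.density_summary <- function(x, ...) {
  data.frame(block = if (x$passed_only) "after_binomial" else "before_binomial",
             n_mismatch = x$n_mismatch,
             n_variant_contigs = x$n_variant_contigs,
             n_contigs = x$n_contigs,
             pct_variant_contigs = x$pct_variant_contigs,
             denom_bases = x$denom_bases,
             density_per_100bp = x$density_per_100bp,
             n_biallelic = x$n_biallelic,
             n_transition = x$n_transition,
             n_transversion = x$n_transversion,
             titv = x$titv,
             n_indel = x$n_indel,
             n_multiallelic = x$n_multiallelic)
}
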