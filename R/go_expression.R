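# Permutation test for organ-level over-expression of GO-term contig groups.
#
# A contig's read count from an organ is a rough proxy for expression. For a
# GO biological-process term, the observed statistic is the mean read count
# over the term's contigs with nonzero counts in that organ. The organ's
# count vector is then permuted over all contigs (zero counts included in the
# pool; exclusion is re-applied after assignment); a term whose observed mean
# exceeds more than 95% of the permuted means is called over-expressed in
# that organ. Tests run within organs, so unequal library sizes do not bias
# the comparison.

#' Build a GO-term expression table
#'
#' @param go_map data.frame with columns `contig_id` and `go_term` (one row
#'   per association), or path to such a TSV.
#' @param counts data.frame with a `contig_id` column plus one integer column
#'   per organ, or path to such a TSV.
#' @return A `go_expression_table`: contig ids, term -> contig-index sets, and
#'   the contig x organ count matrix.
#' @export
go_expression_table <- function(go_map, counts) {
  if (is.character(go_map)) {
    go_map <- utils::read.table(go_map, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE, quote = "")
  }
  if (is.character(counts)) {
    counts <- utils::read.table(counts, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE, quote = "")
  }
  stopifnot(all(c("contig_id", "go_term") %in% names(go_map)),
            "contig_id" %in% names(counts))
  organs <- setdiff(names(counts), "contig_id")
  cm <- as.matrix(counts[, organs, drop = FALSE])
  if (any(cm < 0) || any(!is.finite(cm))) stop("counts must be finite and non-negative")
  rownames(cm) <- counts$contig_id
  idx <- match(go_map$contig_id, counts$contig_id)
  if (anyNA(idx)) {
    stop("GO map references contigs absent from the count table: ",
         paste(unique(go_map$contig_id[is.na(idx)]), collapse = ", "))
  }
  go_sets <- lapply(split(idx, go_map$go_term), function(v) sort(unique(v)))
  if (any(!lengths(go_sets))) stop("every GO term must map to at least one contig")
  structure(list(contigs = counts$contig_id, go_sets = go_sets, counts = cm),
            class = "go_expression_table")
}

#' Observed mean read count of a term's contigs in one organ
#'
#' Contigs with zero counts are excluded; `NA` when none remain.
#'
#' @param tab A [go_expression_table()].
#' @param term GO term identifier.
#' @param organ Organ column name.
#' @return Mean reads per (expressed) contig.
#' @export
observed_mean <- function(tab, term, organ) {
  stopifnot(inherits(tab, "go_expression_table"))
  idx <- tab$go_sets[[term]]
  if (is.null(idx)) stop("unknown GO term '", term, "'")
  x <- tab$counts[idx, organ]
  x <- x[x > 0]
  if (!length(x)) NA_real_ else mean(x)
}

#' Permutation test for over-expressed GO terms in one organ
#'
#' For each of `n_perm` permutations the organ's count vector is shuffled
#' across the contig pool and every term's zero-excluded mean is recomputed;
#' a term is significant when its observed mean exceeds more than 95% of the
#' permuted means. All terms are evaluated against the same permutation
#' stream. One-sided by design (over-expression only); the mean permuted
#' difference is reported descriptively for the other direction.
#'
#' @param tab A [go_expression_table()].
#' @param organ Organ column name.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param pool `"all"` permutes counts over all contigs (zero counts stay in
#'   the pool); `"nonzero"` permutes only among contigs with nonzero counts.
#' @param level Exceedance level for significance (default 0.95).
#' @param adjust If `TRUE`, also report Benjamini-Hochberg adjusted one-sided
#'   permutation p-values (off by default).
#' @return data.frame of class `go_permutation`: term, organ, contigs used,
#'   observed mean, mean/quantiles of observed-minus-permuted differences,
#'   exceedance fraction `pctl_rank`, and the significance call.
#' @export
permute_test <- function(tab, organ, n_perm = 1000, seed = NULL,
                         pool = c("all", "nonzero"), level = 0.95,
                         adjust = FALSE) {
  stopifnot(inherits(tab, "go_expression_table"))
  pool <- match.arg(pool)
  if (!organ %in% colnames(tab$counts)) stop("unknown organ '", organ, "'")
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  v <- as.numeric(tab$counts[, organ])
  nc <- length(v)
  terms <- names(tab$go_sets)
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(terms), lengths(tab$go_sets)),
    j = unlist(tab$go_sets), x = 1,
    dims = c(length(terms), nc))
  obs_n <- as.numeric(M %*% as.numeric(v > 0))
  obs_mean <- ifelse(obs_n > 0, as.numeric(M %*% v) / obs_n, NA_real_)
  # permuted count vectors, one column per permutation
  V <- matrix(0, nrow = nc, ncol = n_perm)
  if (pool == "all") {
    for (b in seq_len(n_perm)) V[, b] <- v[sample.int(nc)]
  } else {
    nz <- which(v > 0)
    for (b in seq_len(n_perm)) {
      vp <- v
      vp[nz] <- v[nz][sample.int(length(nz))]
      V[, b] <- vp
    }
  }
  num <- as.matrix(M %*% V)
  den <- as.matrix(M %*% (V > 0))
  perm_mean <- ifelse(den > 0, num / den, NA_real_)
  diffs <- obs_mean - perm_mean
  n_valid <- rowSums(!is.na(perm_mean))
  exceed <- rowSums(obs_mean > perm_mean, na.rm = TRUE)
  pctl_rank <- ifelse(n_valid > 0 & !is.na(obs_mean),
                      exceed / n_valid, NA_real_)
  out <- data.frame(
    go_term = terms,
    organ = organ,
    n_contigs_used = obs_n,
    observed_mean = obs_mean,
    mean_diff = rowMeans(diffs, na.rm = TRUE),
    diff_q05 = apply(diffs, 1, stats::quantile, probs = 0.05, na.rm = TRUE),
    diff_q95 = apply(diffs, 1, stats::quantile, probs = 0.95, na.rm = TRUE),
    pctl_rank = pctl_rank,
    significant = !is.na(pctl_rank) & pctl_rank > level,
    n_perm = n_perm,
    seed = if (is.null(seed)) NA_integer_ else seed)
  if (adjust) {
    pval <- 1 - ifelse(is.na(pctl_rank), 0, pctl_rank)
    out$p_adj <- stats::p.adjust(pval, method = "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("go_permutation", "data.frame")
  out
}

#' @export
print.go_permutation <- function(x, ...) {
  cat("<go_permutation> ", nrow(x), " GO terms, organ '", x$organ[1],
      "', ", x$n_perm[1], " permutations: ", sum(x$significant),
      " over-expressed (exceedance > 95%)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)[order(-x$pctl_rank), ], 10),
                   digits = 4)
  invisible(x)
}
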