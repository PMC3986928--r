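# RaBoT: rarefaction bootstrap comparing the number of contigs reached by a
# smaller read library with equal-size subsamples of a larger one. The
# statistic in the larger sample is evaluated under the same sampling depth
# as the smaller one, removing ascertainment bias from unequal read numbers.

#' Read a read-to-contig assignment table
#'
#' @param path TSV with header columns `read_id`, `contig_id`, `organ`.
#'   Only assembled reads appear (singletons are discarded upstream).
#' @return data.frame.
#' @export
read_assignments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("read_id", "contig_id", "organ")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("assignment table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Rarefaction bootstrap of contig counts between two libraries
#'
#' The empirical value is the number of distinct contigs containing at least
#' one read from the smaller library. Each of `n_boot` bootstraps draws,
#' without replacement, a subsample of that size from the larger library's
#' reads and counts the distinct contigs hit. The reported P-value is the
#' fraction of bootstrapped values strictly above the empirical value (the
#' subsamples are not independent, so only this non-parametric fraction is
#' meaningful). Contig membership is taken from the fixed assembly's
#' read-to-contig map rather than reassembling each subsample, which equals
#' the rarefied statistic whenever assembly membership is stable under
#' subsampling.
#'
#' @param assign data.frame `read_id`, `contig_id`, `organ` (or path to TSV).
#' @param organ_small,organ_large The two libraries; `organ_small` must have
#'   fewer assigned reads.
#' @param n_boot Number of subsamples (default 100).
#' @param seed Integer seed.
#' @return A `rabot` list: `empirical`, `boots`, `p_value`, sizes and seed.
#' @export
rabot_compare <- function(assign, organ_small, organ_large,
                          n_boot = 100, seed = NULL) {
  if (is.character(assign)) assign <- read_assignments(assign)
  small <- assign[assign$organ == organ_small, , drop = FALSE]
  large <- assign[assign$organ == organ_large, , drop = FALSE]
  if (!nrow(small) || !nrow(large)) stop("empty library for one of the organs")
  if (nrow(small) >= nrow(large)) {
    stop("'", organ_small, "' has ", nrow(small), " reads, not fewer than '",
         organ_large, "' (", nrow(large), "); swap the arguments")
  }
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  empirical <- length(unique(small$contig_id))
  n_small <- nrow(small)
  boots <- vapply(seq_len(n_boot), function(b) {
    length(unique(large$contig_id[sample.int(nrow(large), n_small)]))
  }, numeric(1))
  structure(list(
    empirical = empirical,
    boots = boots,
    p_value = mean(boots > empirical),
    n_boot = n_boot,
    n_small = n_small,
    n_large = nrow(large),
    organ_small = organ_small,
    organ_large = organ_large,
    seed = if (is.null(seed)) NA_integer_ else seed), class = "rabot")
}

#' @export
print.rabot <- function(x, ...) {
  cat("<rabot> ", x$organ_small, " (", x$n_small, " reads, ", x$empirical,
      " contigs) vs ", x$organ_large, " (", x$n_large, " reads), ",
      x$n_boot, " subsamples\n",
      "  bootstrapped contigs: median ", stats::median(x$boots),
      " [", min(x$boots), ", ", max(x$boots), "]\n",
      "  P(boot > empirical) = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}
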