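# Fixture builders and independent oracles shared across test files.

# Build a contig alignment from padded read strings. `quals` may be a single
# number (recycled per base, pads included) or a list of per-read vectors.
make_alignment <- function(seqs, starts = 0L, quals = 30L,
                           strands = "+", organs = "untagged",
                           contig_id = "c1", n_cols = NULL) {
  n <- length(seqs)
  starts <- rep_len(starts, n)
  strands <- rep_len(strands, n)
  organs <- rep_len(organs, n)
  if (!is.list(quals)) quals <- rep_len(list(quals), n)
  reads <- lapply(seq_len(n), function(i) {
    q <- quals[[i]]
    if (length(q) == 1L) q <- rep(q, nchar(seqs[i]))
    aligned_read(sprintf("%s_r%02d", contig_id, i), starts[i], seqs[i],
                 padded_qual = q, strand = strands[i], organ = organs[i])
  })
  if (is.null(n_cols)) {
    n_cols <- max(vapply(reads, function(r) r$start_col + nchar(r$padded_seq),
                         integer(1)))
  }
  contig_alignment(contig_id, n_cols, reads)
}

# One-column alignment from a state->count spec, e.g. c(A = 9, G = 1).
# `qual_overrides` is an optional list state -> quality vector (recycled).
make_column <- function(counts, qual = 30L, qual_overrides = list()) {
  seqs <- character()
  quals <- list()
  for (s in names(counts)) {
    q <- qual_overrides[[s]]
    if (is.null(q)) q <- qual
    q <- rep_len(q, counts[[s]])
    for (i in seq_len(counts[[s]])) {
      seqs <- c(seqs, s)
      quals <- c(quals, list(q[i]))
    }
  }
  make_alignment(seqs, starts = 0L, quals = quals)
}

# Random small alignment for property tests: `n_cols` columns, every column
# covered, mixed variants, pads, Ns and a spread of qualities.
random_alignment <- function(n_cols = 20L, contig_id = "rand") {
  n_reads <- sample(2:12, 1)
  ref <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  seqs <- character(n_reads)
  quals <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    b <- ref
    flip <- runif(n_cols) < 0.2
    b[flip] <- sample(c("A", "C", "G", "T", "*", "N"), sum(flip),
                      replace = TRUE, prob = c(.2, .2, .2, .2, .15, .05))
    if (b[1] == "*") b[1] <- ref[1]   # reads must not start on a pad
    seqs[i] <- paste(b, collapse = "")
    quals[[i]] <- sample(5:40, n_cols, replace = TRUE)
  }
  make_alignment(seqs, starts = 0L, quals = quals, contig_id = contig_id)
}

# --- independent oracles -----------------------------------------------------

# Brute-force cumulative binomial by term-wise summation.
brute_binom_cum <- function(t, x, p) {
  sum(vapply(0:t, function(k) choose(x, k) * p^k * (1 - p)^(x - k), numeric(1)))
}

# Re-derive per-base mask reasons for one column given parallel vectors of
# bases and qualities (a straight transcription of the rule list, operating
# on plain vectors rather than the package's matrix representation).
oracle_mask_column <- function(bases, quals, freq_min = 0.1, qual_min = 20) {
  state_order <- c("A", "C", "G", "T", "*")
  reason <- rep(NA_character_, length(bases))
  reason[bases == "N"] <- "is_N"
  live <- function() which(is.na(reason) & bases != "N")
  majority <- function(idx) {
    tb <- table(bases[idx])
    cand <- names(tb)[tb == max(tb)]
    state_order[min(match(cand, state_order))]
  }
  # rule 1: singleton variants
  idx <- live()
  if (length(idx)) {
    ref <- majority(idx)
    tb <- table(bases[idx])
    for (s in names(tb)) {
      if (s != ref && tb[[s]] == 1L) reason[idx[bases[idx] == s]] <- "singleton"
    }
  }
  # rule 2: low-frequency variants
  idx <- live()
  if (length(idx)) {
    ref <- majority(idx)
    tb <- table(bases[idx])
    for (s in names(tb)) {
      if (s != ref && tb[[s]] / length(idx) < freq_min) {
        reason[idx[bases[idx] == s]] <- "low_freq"
      }
    }
  }
  # rule 3: low quality at still-polymorphic columns
  idx <- live()
  if (length(unique(bases[idx])) >= 2L) {
    reason[idx[quals[idx] < qual_min]] <- "low_qual"
  }
  reason
}

# Count unmasked bases of a masked assembly over its kept columns.
unmasked_count <- function(m) {
  cols <- m$kept_cols + 1L
  sum(!is.na(m$base[, cols, drop = FALSE]) & is.na(m$mask[, cols, drop = FALSE]))
}
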