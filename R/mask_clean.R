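# Masking and cleaning of padded contig alignments, IUPAC consensus editing.
#
# Masking criteria, applied per column in a fixed order (each rule sees the
# column state left by the previous one; single pass, no fixpoint iteration):
#   1. singleton  — a variant state supported by exactly one read
#   2. low_freq   — a variant state with frequency < freq_min among unmasked
#                   non-N bases in the column
#   3. low_qual   — at still-polymorphic columns, any base with quality < qual_min
# N bases are always masked (is_N). The cleaning step then deletes every
# column whose unmasked content contains no real base (A/C/G/T) — the typical
# fate of homopolymer-induced false-insertion columns in 454 data.

MASK_REASONS <- c("singleton", "low_freq", "low_qual", "is_N")

IUPAC_CODES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N")

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  if (key == "") return("N")
  unname(IUPAC_CODES[key])
}

# majority state among counts (named by STATES); ties broken by STATES order
majority_state <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_character_)
  cand <- names(counts)[counts == max(counts)]
  STATES[match(TRUE, STATES %in% cand)]
}

state_counts <- function(states) {
  tb <- tabulate(factor(states, levels = STATES), nbins = length(STATES))
  stats::setNames(tb, STATES)
}

#' Mask unreliable bases in a contig alignment
#'
#' Applies the three masking rules (singleton variants, variants below a
#' frequency threshold, low-quality bases at polymorphic columns) plus
#' unconditional masking of N calls. Each masked base records the first rule
#' that fired. Pads count as a state throughout, so gap variants are filtered
#' on the same footing as substitutions.
#'
#' @param ca A [contig_alignment()] with qualities attached.
#' @param freq_min Variant-frequency threshold (default 0.1).
#' @param qual_min Quality threshold at polymorphic sites (default 20).
#' @return A `masked_assembly`: the alignment plus base/quality matrices, a
#'   mask-reason matrix, `kept_cols` (0-based original column indices, all
#'   columns before cleaning) and an empty consensus.
#' @export
mask_bases <- function(ca, freq_min = 0.1, qual_min = 20) {
  stopifnot(inherits(ca, "contig_alignment"))
  if (!length(ca$reads)) stop("contig '", ca$contig_id, "' has no reads")
  m <- alignment_matrices(ca)
  base <- m$base
  qual <- m$qual
  if (anyNA(qual[!is.na(base)])) {
    stop("contig '", ca$contig_id,
         "': qualities not attached (run attach_qualities first)")
  }
  reason <- matrix(NA_character_, nrow = nrow(base), ncol = ncol(base))
  for (j in seq_len(ncol(base))) {
    obs <- which(!is.na(base[, j]))
    if (!length(obs)) next
    isN <- obs[base[obs, j] == "N"]
    reason[isN, j] <- "is_N"
    act <- setdiff(obs, isN)
    if (!length(act)) next
    # rule 1: singleton variants
    cnt <- state_counts(base[act, j])
    ref <- majority_state(cnt)
    singles <- names(cnt)[cnt == 1L & names(cnt) != ref]
    if (length(singles)) {
      hit <- act[base[act, j] %in% singles]
      reason[hit, j] <- "singleton"
      act <- setdiff(act, hit)
    }
    # rule 2: low-frequency variants, on the state left by rule 1
    cnt <- state_counts(base[act, j])
    ref <- majority_state(cnt)
    denom <- sum(cnt)
    if (denom > 0L) {
      low <- names(cnt)[cnt > 0L & names(cnt) != ref & cnt / denom < freq_min]
      if (length(low)) {
        hit <- act[base[act, j] %in% low]
        reason[hit, j] <- "low_freq"
        act <- setdiff(act, hit)
      }
    }
    # rule 3: per-base quality at columns still polymorphic
    if (length(unique(base[act, j])) >= 2L) {
      hit <- act[qual[act, j] < qual_min]
      reason[hit, j] <- "low_qual"
    }
  }
  structure(list(contig = ca, base = base, qual = qual, mask = reason,
                 kept_cols = seq_len(ca$n_cols) - 1L,
                 consensus = NULL,
                 freq_min = freq_min, qual_min = qual_min),
            class = "masked_assembly")
}

#' @export
print.masked_assembly <- function(x, ...) {
  cat("<masked_assembly> ", x$contig$contig_id, ": ", length(x$kept_cols),
      "/", x$contig$n_cols, " columns kept, ",
      sum(!is.na(x$mask)), " bases masked\n", sep = "")
  if (!is.null(x$consensus)) cat("  consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

# column indices (1-based into the padded matrices) that survive cleaning
kept_filter <- function(m) {
  keep <- logical(length(m$kept_cols))
  cols <- m$kept_cols + 1L
  for (k in seq_along(cols)) {
    j <- cols[k]
    unmasked <- !is.na(m$base[, j]) & is.na(m$mask[, j])
    keep[k] <- any(m$base[unmasked, j] %in% c("A", "C", "G", "T"))
  }
  keep
}

#' Remove columns containing only indels and masked bases
#'
#' Deletes every padded column whose unmasked content has no real base
#' (A/C/G/T) — i.e. columns that are pads and/or masked bases only, the
#' signature of 454 homopolymer false insertions. `kept_cols` retains the
#' provenance map back to original padded columns. Idempotent.
#'
#' @param m A `masked_assembly` from [mask_bases()].
#' @return The assembly with dropped columns removed from `kept_cols`.
#' @export
clean_columns <- function(m) {
  stopifnot(inherits(m, "masked_assembly"))
  m$kept_cols <- m$kept_cols[kept_filter(m)]
  m
}

# per-column unmasked states/counts/quals at an original padded column (1-based j)
unmasked_column <- function(m, j) {
  sel <- which(!is.na(m$base[, j]) & is.na(m$mask[, j]))
  list(states = m$base[sel, j], quals = m$qual[sel, j], idx = sel)
}

#' Edit the IUPAC consensus of a cleaned assembly
#'
#' Per kept column the consensus is the IUPAC code of the set of unmasked
#' real-base states with frequency >= `freq_min` among unmasked non-pad bases.
#' Columns where unmasked pads outnumber unmasked real bases are reported in
#' lowercase (likely deletion); columns with no unmasked real base give 'N'.
#'
#' @param m A cleaned `masked_assembly`.
#' @param freq_min Frequency threshold for a base to enter the code
#'   (defaults to the threshold used at masking).
#' @return The consensus string; also stored on the returned object by
#'   [clean_assembly()].
#' @export
edit_consensus <- function(m, freq_min = m$freq_min) {
  stopifnot(inherits(m, "masked_assembly"))
  codes <- vapply(m$kept_cols + 1L, function(j) {
    u <- unmasked_column(m, j)
    real <- u$states[u$states %in% c("A", "C", "G", "T")]
    n_pad <- sum(u$states == "*")
    if (!length(real)) return("N")
    tb <- table(real)
    keep <- names(tb)[tb / length(real) >= freq_min]
    code <- iupac_code(keep)
    if (n_pad > length(real)) tolower(code) else code
  }, character(1))
  paste(codes, collapse = "")
}

#' Mask, clean and edit the consensus of one contig
#'
#' Convenience wrapper: [mask_bases()] then [clean_columns()] then
#' [edit_consensus()], with the consensus stored on the result.
#'
#' @inheritParams mask_bases
#' @return A cleaned `masked_assembly` with `$consensus` set.
#' @export
clean_assembly <- function(ca, freq_min = 0.1, qual_min = 20) {
  m <- clean_columns(mask_bases(ca, freq_min = freq_min, qual_min = qual_min))
  m$consensus <- edit_consensus(m)
  m
}

#' Rebuild a contig alignment from the kept columns of a masked assembly
#'
#' Reads are re-cut to the surviving columns (masked bases are annotations,
#' not deletions, so they remain in the reads); used for idempotence checks
#' and for re-running the pipeline on cleaned data.
#'
#' @param m A `masked_assembly`.
#' @return A [contig_alignment()] in cleaned coordinate space.
#' @export
as_contig_alignment <- function(m) {
  stopifnot(inherits(m, "masked_assembly"))
  cols <- m$kept_cols + 1L
  reads <- list()
  for (i in seq_along(m$contig$reads)) {
    r <- m$contig$reads[[i]]
    span <- !is.na(m$base[i, cols])
    if (!any(span)) next
    first <- which(span)[1]
    last <- max(which(span))
    sel <- cols[first:last]
    chars <- m$base[i, sel]
    quals <- m$qual[i, sel]
    chars[is.na(chars)] <- "*"   # interior gap opened by column removal
    quals[is.na(quals)] <- 0L
    reads[[length(reads) + 1L]] <- aligned_read(
      r$read_id, start_col = first - 1L,
      padded_seq = paste(chars, collapse = ""),
      padded_qual = quals, strand = r$strand, organ = r$organ)
  }
  contig_alignment(m$contig$contig_id, length(cols), reads)
}

#' Mask audit table
#'
#' One row per masked base: contig, original padded column (1-based),
#' cleaned-space column (1-based; NA if the column was deleted), read, base,
#' quality and the mask reason.
#'
#' @param m A `masked_assembly` (cleaned or not).
#' @return data.frame.
#' @export
mask_audit <- function(m) {
  hits <- which(!is.na(m$mask), arr.ind = TRUE)
  if (!nrow(hits)) {
    return(data.frame(contig_id = character(), orig_col = integer(),
                      clean_col = integer(), read_id = character(),
                      base = character(), qual = integer(),
                      reason = character()))
  }
  ids <- vapply(m$contig$reads, function(r) r$read_id, character(1))
  data.frame(
    contig_id = m$contig$contig_id,
    orig_col = hits[, "col"],
    clean_col = match(hits[, "col"] - 1L, m$kept_cols),
    read_id = ids[hits[, "row"]],
    base = m$base[hits],
    qual = m$qual[hits],
    reason = m$mask[hits])
}

#' Write consensus sequences as FASTA
#'
#' @param masked List of cleaned `masked_assembly` objects with consensus set.
#' @param path Output path.
#' @export
write_consensus_fasta <- function(masked, path) {
  out <- character()
  for (m in masked) {
    cons <- if (is.null(m$consensus)) edit_consensus(m) else m$consensus
    out <- c(out, paste0(">", m$contig$contig_id),
             substring(cons, seq(1, max(nchar(cons), 1), 60),
                       pmin(seq(60, nchar(cons) + 59, 60), nchar(cons))))
  }
  writeLines(out, path)
  invisible(path)
}
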