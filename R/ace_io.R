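# Padded-alignment model and ACE/QUAL/MID input-output.
#
# The in-memory model mirrors what a consed-style ACE file stores: one contig
# per CO record, reads placed at 1-based padded offsets (AF), read sequences
# in contig orientation over {A,C,G,T,N,*} where '*' is an assembler pad.
# Internally all coordinates are 0-based half-open; reports are 1-based.

STATES <- c("A", "C", "G", "T", "*")  # tie-break order: real bases before gap

#' Construct an aligned read
#'
#' @param read_id Read identifier.
#' @param start_col 0-based column of the first base in contig padding space.
#' @param padded_seq Character string over `A,C,G,T,N,*` in contig orientation.
#' @param padded_qual Integer vector of phred-like qualities (0-93), one per
#'   padded position, or `NA` before qualities are attached. Pads carry an
#'   imputed quality: the minimum of the nearest non-pad neighbours.
#' @param strand `"+"` (uncomplemented) or `"-"` (stored complemented).
#' @param organ One of `"leaf"`, `"stem"`, `"root"`, `"untagged"`.
#' @return A list of class `aligned_read`.
#' @export
aligned_read <- function(read_id, start_col, padded_seq,
                         padded_qual = NULL, strand = "+", organ = "untagged") {
  padded_seq <- toupper(padded_seq)
  n <- nchar(padded_seq)
  if (n == 0L) stop("read '", read_id, "': empty padded sequence")
  if (start_col < 0L) stop("read '", read_id, "': negative start_col")
  if (is.null(padded_qual)) padded_qual <- rep(NA_integer_, n)
  padded_qual <- as.integer(padded_qual)
  if (length(padded_qual) != n) {
    stop("read '", read_id, "': padded_qual length ", length(padded_qual),
         " != padded_seq length ", n)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!organ %in% c("leaf", "stem", "root", "untagged")) {
    stop("organ must be leaf/stem/root/untagged, got '", organ, "'")
  }
  bad <- setdiff(unique(strsplit(padded_seq, "")[[1]]), c("A", "C", "G", "T", "N", "*"))
  if (length(bad)) stop("read '", read_id, "': illegal characters: ",
                        paste(bad, collapse = " "))
  structure(list(read_id = read_id, organ = organ, strand = strand,
                 start_col = as.integer(start_col), padded_seq = padded_seq,
                 padded_qual = padded_qual),
            class = "aligned_read")
}

#' Construct a contig alignment
#'
#' @param contig_id Contig identifier.
#' @param n_cols Padded length of the contig.
#' @param reads List of [aligned_read()] objects, all within `[0, n_cols)`.
#' @return A list of class `contig_alignment`.
#' @export
contig_alignment <- function(contig_id, n_cols, reads) {
  n_cols <- as.integer(n_cols)
  if (n_cols <= 0L) stop("contig '", contig_id, "': n_cols must be positive")
  for (r in reads) {
    if (r$start_col + nchar(r$padded_seq) > n_cols) {
      stop("contig '", contig_id, "': read '", r$read_id,
           "' extends past padded length ", n_cols)
    }
  }
  structure(list(contig_id = contig_id, n_cols = n_cols, reads = reads),
            class = "contig_alignment")
}

#' @export
print.contig_alignment <- function(x, ...) {
  cat("<contig_alignment> ", x$contig_id, ": ", x$n_cols, " padded columns, ",
      length(x$reads), " reads\n", sep = "")
  invisible(x)
}

# Character and quality matrices (reads x columns); NA outside a read's span.
alignment_matrices <- function(ca) {
  nr <- length(ca$reads)
  base <- matrix(NA_character_, nrow = nr, ncol = ca$n_cols)
  qual <- matrix(NA_integer_, nrow = nr, ncol = ca$n_cols)
  ids <- character(nr)
  for (i in seq_len(nr)) {
    r <- ca$reads[[i]]
    idx <- seq.int(r$start_col + 1L, r$start_col + nchar(r$padded_seq))
    base[i, idx] <- strsplit(r$padded_seq, "")[[1]]
    qual[i, idx] <- r$padded_qual
    ids[i] <- r$read_id
  }
  rownames(base) <- rownames(qual) <- ids
  list(base = base, qual = qual)
}

#' Per-column tallies of an alignment
#'
#' Counts of each state `A,C,G,T,N,*` per padded column, with depth
#' (total observed bases including pads).
#'
#' @param ca A [contig_alignment()].
#' @return data.frame with one row per column.
#' @export
column_profile <- function(ca) {
  m <- alignment_matrices(ca)$base
  lv <- c("A", "C", "G", "T", "N", "*")
  cnt <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(factor(m[, j], levels = lv), nbins = length(lv))
  }, integer(length(lv)))
  out <- as.data.frame(t(cnt))
  names(out) <- c("A", "C", "G", "T", "N", "gap")
  out$col <- seq_len(nrow(out)) - 1L
  out$depth <- rowSums(out[, c("A", "C", "G", "T", "N", "gap")])
  out[, c("col", "A", "C", "G", "T", "N", "gap", "depth")]
}

#' Read a consed-dialect ACE assembly file
#'
#' Parses AS/CO/AF/RD records (BQ/QA/BS/DS/CT/RT/WA are tolerated and
#' skipped). Read offsets are converted from 1-based AF positions to 0-based
#' columns; complemented (`C`) reads are stored as given, i.e. already in
#' contig orientation, and marked strand `"-"` so that qualities are reversed
#' when attached.
#'
#' @param path Path to an ACE file.
#' @return List of [contig_alignment()] objects.
#' @export
read_ace <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  i <- 1L
  contigs <- list()
  cur <- NULL  # list(contig_id, n_cols, af = env, rd = list)
  flush_contig <- function(cur) {
    if (is.null(cur)) return(NULL)
    reads <- list()
    for (rid in names(cur$rd)) {
      af <- cur$af[[rid]]
      if (is.null(af)) {
        stop("ACE parse error: read '", rid, "' has RD record but no AF ",
             "record in contig ", cur$contig_id)
      }
      reads[[length(reads) + 1L]] <- aligned_read(
        read_id = rid, start_col = af$pos - 1L, padded_seq = cur$rd[[rid]],
        strand = if (af$ori == "C") "-" else "+")
    }
    missing_rd <- setdiff(names(cur$af), names(cur$rd))
    if (length(missing_rd)) {
      stop("ACE parse error: reads referenced in AF but missing RD: ",
           paste(missing_rd, collapse = ", "))
    }
    contig_alignment(cur$contig_id, cur$n_cols, reads)
  }
  read_seq_block <- function(i) {
    seqs <- character()
    while (i <= n && nzchar(trimws(lines[i]))) {
      seqs <- c(seqs, trimws(lines[i]))
      i <- i + 1L
    }
    list(seq = paste(seqs, collapse = ""), i = i)
  }
  while (i <= n) {
    line <- lines[i]
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    key <- if (length(tok)) tok[1] else ""
    if (key == "AS" || key == "" || key == "BQ" || key == "QA" || key == "DS" ||
        key == "BS" || key == "CT{" || key == "RT{" || key == "WA{") {
      i <- i + 1L
      next
    }
    if (key == "CO") {
      if (!is.null(cur)) contigs[[length(contigs) + 1L]] <- flush_contig(cur)
      if (length(tok) < 3L) stop("ACE parse error at line ", i, ": malformed CO record")
      n_cols <- suppressWarnings(as.integer(tok[3]))
      if (is.na(n_cols)) stop("ACE parse error at line ", i, ": bad CO length")
      blk <- read_seq_block(i + 1L)
      if (nchar(blk$seq) != n_cols) {
        stop("ACE parse error at line ", i, ": CO '", tok[2], "' declares ",
             n_cols, " bases but sequence block has ", nchar(blk$seq))
      }
      cur <- list(contig_id = tok[2], n_cols = n_cols,
                  af = list(), rd = list())
      i <- blk$i
      next
    }
    if (key == "AF") {
      if (is.null(cur)) stop("ACE parse error at line ", i, ": AF before CO")
      if (length(tok) != 4L || !tok[3] %in% c("U", "C")) {
        stop("ACE parse error at line ", i, ": malformed AF record")
      }
      pos <- suppressWarnings(as.integer(tok[4]))
      if (is.na(pos)) stop("ACE parse error at line ", i, ": bad AF position")
      cur$af[[tok[2]]] <- list(ori = tok[3], pos = pos)
      i <- i + 1L
      next
    }
    if (key == "RD") {
      if (is.null(cur)) stop("ACE parse error at line ", i, ": RD before CO")
      if (length(tok) < 2L) stop("ACE parse error at line ", i, ": malformed RD record")
      blk <- read_seq_block(i + 1L)
      cur$rd[[tok[2]]] <- blk$seq
      i <- blk$i
      next
    }
    stop("ACE parse error at line ", i, ": unrecognised record '", key, "'")
  }
  if (!is.null(cur)) contigs[[length(contigs) + 1L]] <- flush_contig(cur)
  contigs
}

#' Write a list of contig alignments as an ACE file
#'
#' Emits AS/CO/AF/RD/QA records; the CO consensus line is a plain per-column
#' majority call (pads included) since the model does not carry a consensus.
#'
#' @param contigs List of [contig_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ace <- function(contigs, path) {
  wrap <- function(s) {
    if (nchar(s) == 0) return(character())
    substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s)))
  }
  out <- sprintf("AS %d %d", length(contigs),
                 sum(vapply(contigs, function(x) length(x$reads), integer(1))))
  for (ca in contigs) {
    m <- alignment_matrices(ca)$base
    cons <- apply(m, 2, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return("N")
      tb <- table(factor(col, levels = c(STATES, "N")))
      names(tb)[which.max(tb)]
    })
    out <- c(out, "",
             sprintf("CO %s %d %d 0 U", ca$contig_id, ca$n_cols, length(ca$reads)),
             wrap(paste(cons, collapse = "")), "")
    for (r in ca$reads) {
      out <- c(out, sprintf("AF %s %s %d", r$read_id,
                            if (r$strand == "-") "C" else "U", r$start_col + 1L))
    }
    for (r in ca$reads) {
      len <- nchar(r$padded_seq)
      out <- c(out, "",
               sprintf("RD %s %d 0 0", r$read_id, len),
               wrap(r$padded_seq), "",
               sprintf("QA %s 1 %d 1 %d", r$read_id, len, len))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a .qual file (FASTA-like, integer qualities)
#'
#' @param path Path to a `.fasta.qual`-style file.
#' @return Named list of integer vectors (unpadded, original read orientation).
#' @export
read_qual <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no records in QUAL file '", path, "'")
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  vals <- lapply(split(lines[!hdr], grp[!hdr]), function(ls) {
    as.integer(unlist(strsplit(trimws(paste(ls, collapse = " ")), "\\s+")))
  })
  out <- vector("list", length(ids))
  names(out) <- ids
  for (k in seq_along(ids)) {
    v <- vals[[as.character(k)]]
    out[[k]] <- if (is.null(v)) integer() else v
  }
  out
}

#' Write a .qual file
#'
#' @param quals Named list of integer vectors.
#' @param path Output path.
#' @export
write_qual <- function(quals, path) {
  out <- character()
  for (id in names(quals)) {
    v <- quals[[id]]
    rows <- split(v, ceiling(seq_along(v) / 20))
    out <- c(out, paste0(">", id),
             vapply(rows, function(r) paste(r, collapse = " "), character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

# Impute pad qualities: min of nearest non-pad neighbour on each side.
impute_pad_quals <- function(chars, base_quals) {
  n <- length(chars)
  is_pad <- chars == "*"
  q <- rep(NA_integer_, n)
  q[!is_pad] <- base_quals
  if (!any(is_pad)) return(q)
  nonpad <- which(!is_pad)
  for (j in which(is_pad)) {
    left  <- nonpad[nonpad < j]
    right <- nonpad[nonpad > j]
    lq <- if (length(left)) q[max(left)] else NA_integer_
    rq <- if (length(right)) q[min(right)] else NA_integer_
    q[j] <- min(c(lq, rq), na.rm = TRUE)
  }
  q
}

#' Attach per-base qualities to an assembly
#'
#' Maps unpadded read qualities through pads; pad columns receive the minimum
#' quality of their nearest non-pad neighbours (a pad is never more trusted
#' than its context). Reads stored complemented (strand `"-"`) have their
#' quality vector reversed before padding, since `.qual` files are written in
#' original read orientation.
#'
#' @param contigs List of [contig_alignment()].
#' @param qual Path to a QUAL file, or a named list as from [read_qual()].
#' @return The alignments with `padded_qual` filled in.
#' @export
attach_qualities <- function(contigs, qual) {
  if (is.character(qual)) qual <- read_qual(qual)
  lapply(contigs, function(ca) {
    ca$reads <- lapply(ca$reads, function(r) {
      q <- qual[[r$read_id]]
      if (is.null(q)) stop("no quality record for read '", r$read_id, "'")
      chars <- strsplit(r$padded_seq, "")[[1]]
      n_unpadded <- sum(chars != "*")
      if (length(q) != n_unpadded) {
        stop("quality length mismatch for read '", r$read_id, "': ",
             length(q), " qualities for ", n_unpadded, " unpadded bases")
      }
      if (r$strand == "-") q <- rev(q)
      r$padded_qual <- impute_pad_quals(chars, q)
      r
    })
    ca
  })
}

#' Read a read-to-organ MID sidecar table
#'
#' @param path TSV with columns `read_id` and `organ` (no header required;
#'   a header row naming them is tolerated).
#' @return Named character vector read_id -> organ.
#' @export
read_mids <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("read_id", "organ"),
                          colClasses = "character", quote = "")
  if (nrow(df) && df$read_id[1] == "read_id") df <- df[-1, , drop = FALSE]
  bad <- setdiff(unique(df$organ), c("leaf", "stem", "root", "untagged"))
  if (length(bad)) stop("unknown organ value(s) in MID table: ",
                        paste(bad, collapse = ", "))
  stats::setNames(df$organ, df$read_id)
}

#' Assign organs to reads from a MID table
#'
#' Reads absent from the table are classed `untagged` (the "without tag"
#' library fraction).
#'
#' @param contigs List of [contig_alignment()].
#' @param mids Path to a MID sidecar TSV or a named vector from [read_mids()].
#' @return The alignments with read organs set.
#' @export
assign_organs <- function(contigs, mids) {
  if (is.character(mids) && is.null(names(mids)) && length(mids) == 1L) {
    mids <- read_mids(mids)
  }
  lapply(contigs, function(ca) {
    ca$reads <- lapply(ca$reads, function(r) {
      o <- unname(mids[r$read_id])
      r$organ <- if (is.na(o)) "untagged" else o
      r
    })
    ca
  })
}

#' Write a table as deterministic TSV
#'
#' Tab-separated, header row, UTF-8, '.' decimal separator. If the table has
#' `contig_id` (and optionally `clean_pos`/`pos`) columns it is sorted by them
#' first so output order is deterministic.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(records, path) {
  if ("contig_id" %in% names(records)) {
    poscol <- intersect(c("clean_pos", "pos"), names(records))
    ord <- if (length(poscol)) {
      order(records$contig_id, records[[poscol[1]]])
    } else {
      order(records$contig_id)
    }
    records <- records[ord, , drop = FALSE]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", dec = ".")
  invisible(path)
}
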