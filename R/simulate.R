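# Ground-truth simulator of pooled-gamete 454 contig assemblies.
#
# The simulated world: two diploid genotypes pooled per library, so 2N = 4
# gametes sequenced and every true variant segregates at pool frequency k/2N
# with k >= 1 (minimum 0.25). Reads are 454-like: phred-type qualities with a
# mean around 30 decaying toward the 3' end, substitution errors, and
# homopolymer over/under-calls that appear as pads (false insertion columns)
# in the padded alignment. The simulator plays the role of the assembler and
# emits reads pre-aligned, so its output is a valid ACE/QUAL pair plus a MID
# sidecar and a truth set for recovery tests.

#' Simulation configuration
#'
#' Defaults state the emulated study's conditions: contig lengths centred in
#' the 414-523 bp range, 6-7 reads per contig on average with a long right
#' tail (negative binomial), 2 genotypes (4 gametes), read-length and quality
#' profiles typical of 454 chemistry, and organ proportions dominated by
#' roots.
#'
#' @param seed Integer seed (all randomness flows from it).
#' @param n_contigs Number of contigs.
#' @param contig_len_mean,contig_len_sd Target contig length distribution (bp).
#' @param n_genotypes Diploid genotypes pooled (2 -> 4 gametes).
#' @param variant_rate Per-base probability of a planted true variant.
#' @param sub_error Per-base substitution (sequencing) error rate.
#' @param hp_indel_rate Per-read, per-homopolymer-run over/under-call
#'   probability scale; a run of length L errs with probability
#'   `min(0.02, hp_indel_rate * (L - 1))`.
#' @param read_len_mean,read_len_sd,read_len_min Read length model (bp).
#' @param reads_per_contig_mean Mean reads per contig (min 2; negative
#'   binomial tail).
#' @param organ_probs Named probabilities for leaf/stem/root/untagged.
#' @param qual_mean,qual_drop,qual_sd Quality model: base mean, quadratic
#'   drop toward the 3' end, and per-base noise; clipped to [4, 40].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 20L,
                       contig_len_mean = 460,
                       contig_len_sd = 60,
                       n_genotypes = 2L,
                       variant_rate = 0.005,
                       sub_error = 0.005,
                       hp_indel_rate = 0.004,
                       read_len_mean = 280,
                       read_len_sd = 60,
                       read_len_min = 40,
                       reads_per_contig_mean = 6.5,
                       organ_probs = c(leaf = 0.25, stem = 0.18,
                                       root = 0.54, untagged = 0.03),
                       qual_mean = 32,
                       qual_drop = 12,
                       qual_sd = 4) {
  if (any(c(variant_rate, sub_error, hp_indel_rate) < 0) ||
      any(c(variant_rate, sub_error, hp_indel_rate) > 1)) {
    stop("rates must be in [0, 1]")
  }
  if (n_contigs < 1 || contig_len_mean <= 0 || read_len_mean <= 0) {
    stop("lengths and counts must be positive")
  }
  if (read_len_min > contig_len_mean) {
    stop("minimum read length exceeds mean contig length")
  }
  if (abs(sum(organ_probs) - 1) > 1e-8) stop("organ_probs must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1), USE.NAMES = FALSE)
}

# maximal homopolymer runs of length >= 2 entirely inside [from, to]
homopolymer_runs <- function(ref, from, to) {
  r <- rle(ref)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$lengths >= 2L & starts >= from & ends <= to
  data.frame(start = starts[sel], end = ends[sel], len = r$lengths[sel],
             base = r$values[sel])
}

simulate_contig <- function(cfg, contig_id) {
  two_n <- 2L * cfg$n_genotypes
  len <- max(150L, round(stats::rnorm(1, cfg$contig_len_mean, cfg$contig_len_sd)))
  ref <- rand_dna(len)
  # planted variants at pool frequency k/2N, k in 1..N (minor frequency <= 1/2)
  vpos <- which(stats::runif(len) < cfg$variant_rate)
  variants <- data.frame(ref_pos = vpos,
                         ref = ref[vpos],
                         alt = if (length(vpos)) other_base(ref[vpos]) else character(),
                         k = if (length(vpos)) {
                           sample(seq_len(cfg$n_genotypes), length(vpos), replace = TRUE)
                         } else integer())
  gametes <- matrix(rep(ref, two_n), nrow = two_n, byrow = TRUE)
  carrier <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    carrier[[v]] <- sample.int(two_n, variants$k[v])
    gametes[carrier[[v]], variants$ref_pos[v]] <- variants$alt[v]
  }
  n_reads <- 2L + stats::rnbinom(1, size = 1.4,
                                 mu = max(0.1, cfg$reads_per_contig_mean - 2))
  lens <- pmin(len, pmax(cfg$read_len_min,
                         round(stats::rnorm(n_reads, cfg$read_len_mean,
                                            cfg$read_len_sd))))
  starts <- sort(sample.int(len, n_reads, replace = TRUE))
  starts <- pmin(starts, len - lens + 1L)
  # enforce contiguous coverage from position 1 (assembler contigs have no
  # internal zero-coverage columns); truncate the contig to the covered span
  starts[1] <- 1L
  cover_end <- lens[1]
  for (i in seq_len(n_reads)[-1]) {
    starts[i] <- min(starts[i], cover_end + 1L, len - lens[i] + 1L)
    cover_end <- max(cover_end, starts[i] + lens[i] - 1L)
  }
  len <- cover_end
  ref <- ref[seq_len(len)]
  keepv <- variants$ref_pos <= len
  variants <- variants[keepv, , drop = FALSE]
  carrier <- carrier[keepv]
  gametes <- gametes[, seq_len(len), drop = FALSE]

  reads <- vector("list", n_reads)
  sub_errors <- list()
  indel_errors <- list()
  ins_events <- list()  # anchor -> read indices
  for (i in seq_len(n_reads)) {
    g <- sample.int(two_n, 1L)
    s <- starts[i]
    e <- min(len, s + lens[i] - 1L)
    bases <- gametes[g, s:e]
    # substitution errors
    errs <- which(stats::runif(length(bases)) < cfg$sub_error)
    if (length(errs)) {
      bases[errs] <- other_base(bases[errs])
      sub_errors[[length(sub_errors) + 1L]] <-
        data.frame(read = i, ref_pos = s + errs - 1L)
    }
    # homopolymer over/under-calls, anchored at the run's last position
    runs <- homopolymer_runs(ref, s, e)
    del_at <- integer()
    for (h in seq_len(nrow(runs))) {
      pr <- min(0.02, cfg$hp_indel_rate * (runs$len[h] - 1L))
      if (stats::runif(1) < pr) {
        anchor <- runs$end[h]
        if (stats::runif(1) < 0.5 && anchor < e) {       # over-call: insertion
          key <- as.character(anchor)
          ins_events[[key]] <- c(ins_events[[key]], i)
          indel_errors[[length(indel_errors) + 1L]] <-
            data.frame(read = i, anchor = anchor, type = "insertion")
        } else {                                          # under-call: deletion
          del_at <- c(del_at, anchor)
          indel_errors[[length(indel_errors) + 1L]] <-
            data.frame(read = i, anchor = anchor, type = "deletion")
        }
      }
    }
    if (length(del_at)) bases[del_at - s + 1L] <- "*"
    reads[[i]] <- list(g = g, s = s, e = e, bases = bases,
                       strand = if (stats::runif(1) < 0.5) "+" else "-",
                       organ = sample(names(cfg$organ_probs), 1L,
                                      prob = cfg$organ_probs))
  }

  anchors <- sort(as.integer(names(ins_events)))
  pad_of <- function(p) p + findInterval(p - 1L, anchors)  # padded col of ref pos
  n_cols <- len + length(anchors)
  ins_col <- if (length(anchors)) pad_of(anchors) + 1L else integer()

  aligned <- vector("list", n_reads)
  quals_file <- list()
  for (i in seq_len(n_reads)) {
    r <- reads[[i]]
    p0 <- pad_of(r$s)
    p1 <- pad_of(r$e)
    chars <- rep("*", p1 - p0 + 1L)
    chars[pad_of(r$s:r$e) - p0 + 1L] <- r$bases
    ins_here <- which(anchors >= r$s & anchors < r$e)
    for (a in ins_here) {
      if (i %in% ins_events[[as.character(anchors[a])]]) {
        chars[ins_col[a] - p0 + 1L] <- ref[anchors[a]]
      }
    }
    n_unpadded <- sum(chars != "*")
    pos_frac <- seq_len(n_unpadded) / n_unpadded
    q <- round(cfg$qual_mean - cfg$qual_drop * pos_frac^2 +
                 stats::rnorm(n_unpadded, 0, cfg$qual_sd))
    q <- pmin(40L, pmax(4L, as.integer(q)))  # in original read orientation
    q_contig <- if (r$strand == "-") rev(q) else q
    padded_qual <- impute_pad_quals(chars, q_contig)
    read_id <- sprintf("%s_r%03d", contig_id, i)
    aligned[[i]] <- aligned_read(read_id, start_col = p0 - 1L,
                                 padded_seq = paste(chars, collapse = ""),
                                 padded_qual = padded_qual,
                                 strand = r$strand, organ = r$organ)
    quals_file[[read_id]] <- q
  }

  bindl <- function(l, empty) if (length(l)) do.call(rbind, l) else empty
  truth_variants <- if (nrow(variants)) {
    data.frame(contig_id = contig_id,
               ref_pos = variants$ref_pos,
               padded_col = pad_of(variants$ref_pos),
               ref = variants$ref, alt = variants$alt,
               k = variants$k, freq = variants$k / two_n)
  } else {
    data.frame(contig_id = character(), ref_pos = integer(),
               padded_col = integer(), ref = character(), alt = character(),
               k = integer(), freq = numeric())
  }
  se <- bindl(sub_errors, data.frame(read = integer(), ref_pos = integer()))
  ie <- bindl(indel_errors,
              data.frame(read = integer(), anchor = integer(), type = character()))
  list(alignment = contig_alignment(contig_id, n_cols, aligned),
       quals = quals_file,
       reference = paste(ref, collapse = ""),
       variants = truth_variants,
       sub_errors = if (nrow(se)) cbind(contig_id = contig_id, se) else se,
       indel_errors = if (nrow(ie)) cbind(contig_id = contig_id, ie) else ie,
       ins_anchors = anchors)
}

#' Simulate a pooled-gamete 454 assembly with ground truth
#'
#' Emits a valid ACE/QUAL pair (parsable by [read_ace()] /
#' [attach_qualities()]), a MID sidecar for tagged reads, and a truth set
#' recording planted variants (with padded-column coordinates), substitution
#' errors, homopolymer indel events, and the per-contig reference sequences.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` keeps everything
#'   in memory only.
#' @return List with `alignments` (in-memory models), `truth`, and, when
#'   `dir` is given, paths `ace`, `qual`, `mids`.
#' @export
simulate_assembly <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$read_len_min > cfg$contig_len_mean) {
    stop("contradictory config: reads longer than contigs")
  }
  set.seed(cfg$seed)
  sims <- lapply(seq_len(cfg$n_contigs), function(i) {
    simulate_contig(cfg, sprintf("contig%04d", i))
  })
  alignments <- lapply(sims, `[[`, "alignment")
  quals <- do.call(c, lapply(sims, `[[`, "quals"))
  truth <- list(
    variants = do.call(rbind, lapply(sims, `[[`, "variants")),
    sub_errors = do.call(rbind, lapply(sims, `[[`, "sub_errors")),
    indel_errors = do.call(rbind, lapply(sims, `[[`, "indel_errors")),
    references = stats::setNames(vapply(sims, `[[`, character(1), "reference"),
                                 vapply(alignments, `[[`, character(1), "contig_id")),
    ins_anchors = stats::setNames(lapply(sims, `[[`, "ins_anchors"),
                                  vapply(alignments, `[[`, character(1), "contig_id")))
  rownames(truth$variants) <- NULL
  out <- list(alignments = alignments, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$ace <- file.path(dir, "sim.ace")
    out$qual <- file.path(dir, "sim.qual")
    out$mids <- file.path(dir, "sim_mids.tsv")
    write_ace(alignments, out$ace)
    write_qual(quals, out$qual)
    mids <- do.call(rbind, lapply(alignments, function(ca) {
      data.frame(read_id = vapply(ca$reads, `[[`, character(1), "read_id"),
                 organ = vapply(ca$reads, `[[`, character(1), "organ"))
    }))
    mids <- mids[mids$organ != "untagged", , drop = FALSE]
    utils::write.table(mids, out$mids, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Simulate a GO-term expression table with planted organ effects
#'
#' Counts are Poisson with per-contig gamma-distributed expression levels
#' (exchangeable across contigs within each organ) scaled by organ-specific
#' means; planted over-expressed terms draw dedicated contigs whose rate in
#' the target organ is multiplied by `effect`.
#'
#' @param n_contigs,n_terms Table dimensions.
#' @param lambda Mean expression level (reads per contig per organ unit).
#' @param organ_means Named organ scaling factors.
#' @param term_size_range Contigs per term, sampled uniformly in this range.
#' @param planted_terms Number of over-expressed terms to plant.
#' @param effect Expression multiplier for planted terms.
#' @param planted_organ Organ carrying the planted effect.
#' @param seed Integer seed.
#' @param dir Optional output directory for `go_map.tsv` / `go_counts.tsv`.
#' @return List with `go_map`, `counts` (data.frames), `truth`, and paths if
#'   written.
#' @export
simulate_go_table <- function(n_contigs = 1000, n_terms = 200, lambda = 5,
                              organ_means = c(leaf = 0.8, stem = 0.7, root = 1.5),
                              term_size_range = c(5, 30),
                              planted_terms = 0, effect = 5,
                              planted_organ = "root", seed = 1L, dir = NULL) {
  set.seed(seed)
  if (n_contigs < 1 || n_terms < 1) stop("need at least one contig and one term")
  contigs <- sprintf("contig%04d", seq_len(n_contigs))
  organs <- names(organ_means)
  lam_c <- stats::rgamma(n_contigs, shape = 2, scale = lambda / 2)
  rate <- outer(lam_c, organ_means)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                  n_terms, replace = TRUE)
  sizes <- pmin(sizes, n_contigs)
  planted <- seq_len(min(planted_terms, n_terms))
  reserved <- integer()
  members <- vector("list", n_terms)
  for (t in planted) {
    pool <- setdiff(seq_len(n_contigs), reserved)
    members[[t]] <- sort(sample(pool, min(sizes[t], length(pool))))
    reserved <- c(reserved, members[[t]])
  }
  open_pool <- setdiff(seq_len(n_contigs), reserved)
  for (t in setdiff(seq_len(n_terms), planted)) {
    members[[t]] <- sort(sample(open_pool, min(sizes[t], length(open_pool))))
  }
  if (length(planted) && planted_organ %in% organs) {
    idx <- unique(unlist(members[planted]))
    rate[idx, planted_organ] <- rate[idx, planted_organ] * effect
  }
  cm <- matrix(stats::rpois(length(rate), rate), nrow = n_contigs,
               dimnames = list(NULL, organs))
  counts <- data.frame(contig_id = contigs, cm, check.names = FALSE)
  go_map <- data.frame(
    contig_id = contigs[unlist(members)],
    go_term = rep(terms, lengths(members)))
  truth <- list(planted_terms = terms[planted], effect = effect,
                planted_organ = planted_organ, lambda = lam_c)
  out <- list(go_map = go_map, counts = counts, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$go_map_path <- file.path(dir, "go_map.tsv")
    out$counts_path <- file.path(dir, "go_counts.tsv")
    write_tsv(go_map, out$go_map_path)
    write_tsv(counts, out$counts_path)
  }
  out
}
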