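# End-to-end orchestration: load -> clean -> call -> filter -> summarise,
# with optional GO permutation and RaBoT stages, TSV outputs and a
# machine-readable JSON run report. Deterministic given the inputs and seeds.

#' Run the full post-assembly analysis
#'
#' Loads a padded assembly (ACE + QUAL + optional MID sidecar), masks and
#' cleans every contig, edits consensus sequences, calls mismatches, applies
#' the adjacency / binomial / depth post-filters, and summarises densities in
#' the before/after-binomial layout. If a GO map and count table are supplied
#' the permutation test runs per organ; if a read assignment table and organ
#' pair are supplied, RaBoT runs too. All thresholds used are echoed in the
#' report's `params` block.
#'
#' @param ace Path to an ACE file, or a list of [contig_alignment()] objects
#'   with qualities already attached.
#' @param qual Path to the companion QUAL file (required when `ace` is a path).
#' @param mids Optional path to a `read_id<TAB>organ` sidecar.
#' @param outdir Optional output directory for TSVs, consensus FASTA and
#'   `report.json`.
#' @param freq_min,qual_min Masking thresholds (defaults 0.1 and 20).
#' @param n_gametes,alpha,depth_min Post-filter settings (defaults 4, 0.05, 8).
#' @param go_map,go_counts Optional paths/data.frames for the GO permutation
#'   stage; `organs` selects the columns tested (default: all count columns).
#' @param n_perm Permutations per organ (default 1000).
#' @param rabot_assign Optional read assignment table (or path) for RaBoT.
#' @param rabot_small,rabot_large Organ pair for RaBoT (small library first).
#' @param n_boot RaBoT subsamples (default 100).
#' @param seed Seed for the stochastic stages (GO permutation, RaBoT).
#' @param organs Organ columns for the GO stage.
#' @return A `contigvar_run` list: params, cleaned assemblies, consensus,
#'   mismatch table, before/after summaries, and any GO/RaBoT results.
#' @export
run_pipeline <- function(ace, qual = NULL, mids = NULL, outdir = NULL,
                         freq_min = 0.1, qual_min = 20,
                         n_gametes = 4, alpha = 0.05, depth_min = 8,
                         go_map = NULL, go_counts = NULL, organs = NULL,
                         n_perm = 1000,
                         rabot_assign = NULL, rabot_small = NULL,
                         rabot_large = NULL, n_boot = 100,
                         seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  params <- list(freq_min = freq_min, qual_min = qual_min,
                 n_gametes = n_gametes, alpha = alpha, depth_min = depth_min,
                 n_perm = n_perm, n_boot = n_boot, seed = seed)
  contigs <- stage("load", {
    if (is.character(ace)) {
      if (is.null(qual)) stop("a QUAL file is required with an ACE path")
      x <- attach_qualities(read_ace(ace), qual)
      if (!is.null(mids)) x <- assign_organs(x, read_mids(mids)) else x
    } else {
      ace
    }
  })
  cleaned <- stage("clean", lapply(contigs, clean_assembly,
                                   freq_min = freq_min, qual_min = qual_min))
  recs <- stage("call", post_filter(call_mismatches(cleaned),
                                    n_gametes = n_gametes, alpha = alpha,
                                    depth_min = depth_min))
  summary_before <- stage("summarize",
                          summarize_mismatches(recs, cleaned,
                                               depth_min = depth_min,
                                               passed_only = FALSE))
  summary_after <- summarize_mismatches(recs, cleaned, depth_min = depth_min,
                                        passed_only = TRUE)
  res <- structure(list(params = params, n_contigs = length(cleaned),
                        cleaned = cleaned, mismatches = recs,
                        summary_before = summary_before,
                        summary_after = summary_after),
                   class = "contigvar_run")
  if (!is.null(go_map) && !is.null(go_counts)) {
    res$go <- stage("go_expression", {
      tab <- go_expression_table(go_map, go_counts)
      if (is.null(organs)) organs <- colnames(tab$counts)
      stats::setNames(lapply(organs, function(o) {
        permute_test(tab, o, n_perm = n_perm, seed = seed)
      }), organs)
    })
  }
  if (!is.null(rabot_assign) && !is.null(rabot_small) && !is.null(rabot_large)) {
    res$rabot <- stage("rabot", rabot_compare(rabot_assign, rabot_small,
                                              rabot_large, n_boot = n_boot,
                                              seed = seed))
  }
  if (!is.null(outdir)) {
    stage("write", write_run(res, outdir))
  }
  res
}

write_run <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_tsv(res$mismatches, file.path(outdir, "mismatches.tsv"))
  write_tsv(rbind(as.data.frame(res$summary_before),
                  as.data.frame(res$summary_after)),
            file.path(outdir, "summary.tsv"))
  write_consensus_fasta(res$cleaned, file.path(outdir, "consensus.fasta"))
  audit <- do.call(rbind, lapply(res$cleaned, mask_audit))
  write_tsv(audit, file.path(outdir, "mask_audit.tsv"))
  if (!is.null(res$go)) {
    for (o in names(res$go)) {
      write_tsv(as.data.frame(res$go[[o]]),
                file.path(outdir, paste0("go_permutation_", o, ".tsv")))
    }
  }
  report <- list(params = res$params, n_contigs = res$n_contigs,
                 n_mismatch_records = nrow(res$mismatches),
                 summary_before = unclass(res$summary_before),
                 summary_after = unclass(res$summary_after))
  if (!is.null(res$rabot)) report$rabot <- unclass(res$rabot)
  if (!is.null(res$go)) {
    report$go_significant <- lapply(res$go, function(g) {
      g$go_term[g$significant]
    })
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(outdir)
}

#' @export
print.contigvar_run <- function(x, ...) {
  cat("<contigvar_run> ", x$n_contigs, " contigs, ", nrow(x$mismatches),
      " mismatch records (", sum(x$mismatches$passed), " passed all filters)\n",
      sep = "")
  cat("thresholds: freq_min=", x$params$freq_min, " qual_min=", x$params$qual_min,
      " gametes=", x$params$n_gametes, " alpha=", x$params$alpha,
      " depth_min=", x$params$depth_min, "\n", sep = "")
  print(x$summary_before)
  print(x$summary_after)
  if (!is.null(x$rabot)) print(x$rabot)
  invisible(x)
}
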