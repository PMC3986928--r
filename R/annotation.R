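# Contaminant screen and best-hit annotation over a precomputed blast table.
#
# A contig is retained as a (green-)plant sequence when at least one of its
# k lowest-e-value hits below e_max comes from a genus inside the green-plant
# clade; contigs with informative hits but none from a green plant are
# contaminants; contigs without any hit below e_max are unannotated but kept.

#' Read a blast hit table
#'
#' TSV with header columns `contig_id`, `subject_species`, `subject_genus`,
#' `evalue`, `description` (extra columns kept).
#'
#' @param path Path to the TSV.
#' @return data.frame sorted by contig and increasing e-value with `hit_rank`.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("contig_id", "subject_species", "subject_genus", "evalue", "description")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  rank_hits(df)
}

rank_hits <- function(df) {
  df <- df[order(df$contig_id, df$evalue), , drop = FALSE]
  df$hit_rank <- stats::ave(df$evalue, df$contig_id,
                            FUN = function(x) seq_along(x))
  rownames(df) <- NULL
  df
}

#' Read a genus -> green-plant lookup table
#'
#' @param path TSV `genus<TAB>0|1` (header optional).
#' @return Named logical vector.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("genus", "is_green_plant"),
                          colClasses = "character", quote = "")
  if (nrow(df) && df$genus[1] == "genus") df <- df[-1, , drop = FALSE]
  stats::setNames(df$is_green_plant %in% c("1", "TRUE", "true"), df$genus)
}

check_taxonomy <- function(hits, tax) {
  missing <- setdiff(unique(hits$subject_genus), names(tax))
  if (length(missing)) {
    stop("genera absent from taxonomy lookup: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Screen contigs for non-plant contaminants
#'
#' @param hits Hit table (data.frame as from [read_hit_table()]).
#' @param tax Named logical vector genus -> is-green-plant (total over the
#'   genera present in `hits`; a missing genus is an error, never a silent
#'   FALSE).
#' @param e_max Informative-hit e-value ceiling (default 1e-25).
#' @param k Number of lowest-e-value hits inspected (default 10).
#' @return data.frame `contig_id`, `status` in
#'   `clean` / `contaminant` / `no_informative_hit`.
#' @export
screen_contaminants <- function(hits, tax, e_max = 1e-25, k = 10) {
  check_taxonomy(hits, tax)
  hits <- rank_hits(hits)
  status <- vapply(split(hits, hits$contig_id), function(h) {
    informative <- h$evalue < e_max
    if (!any(informative)) return("no_informative_hit")
    top <- h[h$hit_rank <= k & informative, , drop = FALSE]
    if (any(tax[top$subject_genus])) "clean" else "contaminant"
  }, character(1))
  data.frame(contig_id = names(status), status = unname(status))
}

#' Assign the best informative green-plant annotation per clean contig
#'
#' Among a clean contig's green-plant hits below `e_max`, the lowest-e-value
#' hit whose description does not match the uninformative-pattern blacklist
#' supplies the annotation; contigs with no qualifying hit stay unannotated.
#'
#' @inheritParams screen_contaminants
#' @param uninformative Character vector of case-insensitive patterns marking
#'   an uninformative description.
#' @return data.frame `contig_id`, `annotation` (NA if none), `evalue`.
#' @export
assign_annotation <- function(hits, tax, e_max = 1e-25,
                              uninformative = c("unknown", "hypothetical",
                                                "predicted protein", "unnamed")) {
  check_taxonomy(hits, tax)
  screened <- screen_contaminants(hits, tax, e_max = e_max)
  clean_ids <- screened$contig_id[screened$status == "clean"]
  hits <- rank_hits(hits)
  rows <- lapply(clean_ids, function(cid) {
    h <- hits[hits$contig_id == cid & hits$evalue < e_max &
                tax[hits$subject_genus], , drop = FALSE]
    bad <- Reduce(`|`, lapply(uninformative, function(p) {
      grepl(p, h$description, ignore.case = TRUE)
    }), init = rep(FALSE, nrow(h)))
    h <- h[!bad, , drop = FALSE]
    if (!nrow(h)) {
      data.frame(contig_id = cid, annotation = NA_character_, evalue = NA_real_)
    } else {
      data.frame(contig_id = cid, annotation = h$description[1], evalue = h$evalue[1])
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), annotation = character(),
                      evalue = numeric())
  }
  out
}
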