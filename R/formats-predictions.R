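# Tab-separated prediction report. Breakpoints are written 1-based
# inclusive (genome-browser convention); everything internal stays 0-based
# half-open.

prediction_columns <- c(
  "event_type", "contig_id", "genes", "chrom_a", "strand_a", "breakpoint_a",
  "chrom_b", "strand_b", "breakpoint_b", "topology", "exon_boundary_match",
  "total_support", "strong_support", "filters_passed", "filter_failures",
  "C", "W_A", "T_A", "W_B", "T_B", "W_star", "T_star",
  "C_W_A", "C_T_A", "C_W_B", "C_T_B", "C_W_star", "C_T_star")

#' Build the prediction report table
#'
#' @param predictions list of `EventPrediction` (with optional `support`,
#'   `filter_result` and `relcov` fields attached by the pipeline).
#' @return data.frame in deterministic row order (event_type, chrom,
#'   breakpoint); breakpoints 1-based inclusive.
#' @export
predictions_table <- function(predictions) {
  rows <- lapply(predictions, function(p) {
    bp <- p$breakpoints
    rc <- p$relcov
    data.frame(
      event_type = p$event_type,
      contig_id = p$contig_id,
      genes = paste(unlist(p$genes), collapse = ","),
      chrom_a = bp$chrom[1], strand_a = bp$strand[1],
      breakpoint_a = as.integer(bp$pos[1]) + 1L,
      chrom_b = bp$chrom[2], strand_b = bp$strand[2],
      breakpoint_b = as.integer(bp$pos[2]) + 1L,
      topology = p$candidate$topology,
      exon_boundary_match = p$exon_boundary_match,
      total_support = p$support$total_support %||% NA_integer_,
      strong_support = p$support$strong_support %||% NA_integer_,
      filters_passed = p$filter_result$passed %||% NA,
      filter_failures = if (!is.null(p$filter_result))
        paste(p$filter_result$failures$id, collapse = ",") else "",
      C = rc$C %||% NA_real_,
      W_A = rc$W_A %||% NA_real_, T_A = rc$T_A %||% NA_real_,
      W_B = rc$W_B %||% NA_real_, T_B = rc$T_B %||% NA_real_,
      W_star = rc$W_star %||% NA_real_, T_star = rc$T_star %||% NA_real_,
      C_W_A = unname(rc$ratios["C_W_A"]) %||% NA_real_,
      C_T_A = unname(rc$ratios["C_T_A"]) %||% NA_real_,
      C_W_B = unname(rc$ratios["C_W_B"]) %||% NA_real_,
      C_T_B = unname(rc$ratios["C_T_B"]) %||% NA_real_,
      C_W_star = unname(rc$ratios["C_W_star"]) %||% NA_real_,
      C_T_star = unname(rc$ratios["C_T_star"]) %||% NA_real_)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(prediction_columns)),
                           prediction_columns))
  tab[order(tab$event_type, tab$chrom_a, tab$breakpoint_a,
            tab$chrom_b, tab$breakpoint_b, tab$contig_id), , drop = FALSE]
}

#' Write predictions as a tab-separated report
#'
#' @param events list of `EventPrediction` or a data.frame from
#'   [predictions_table()].
#' @param path output path.
#' @export
write_predictions <- function(events, path) {
  tab <- if (is.data.frame(events)) events else predictions_table(events)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a prediction report
#'
#' @param path report written by [write_predictions()].
#' @return data.frame.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                    stringsAsFactors = FALSE)
}
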