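# End-to-end driver: projection -> per-chromosome meta-analysis ->
# physical annotation, with a machine-readable decision log.

#' Run the full meta-QTL pipeline
#'
#' Projects every QTL onto the reference (consensus) frame, analyzes each
#' chromosome (mixture branch above nine QTL, contiguous-cluster branch
#' otherwise), and optionally anchors the resulting meta-QTL physically
#' and extracts overlapping genes.
#'
#' @param qtl \code{"qtl_table"}.
#' @param maps Multi-map \code{"genetic_map"} of study maps (map_id
#'   matching qtl$study_id).
#' @param reference Single-map \code{"genetic_map"}.
#' @param ci_policy CI policy for projection; the pipeline default is
#'   \code{"recomputed_always"} (Darvasi-Soller applied to every QTL with
#'   N and R2, as in the emulated workflow).
#' @param k_max,n_starts,seed Mixture-branch controls.
#' @param marker_table Optional \code{"marker_table"} for physical
#'   anchoring.
#' @param genes Optional \code{"gene_table"} for gene extraction.
#' @return list of class \code{"mqtl_result"}: projected, mqtl,
#'   gene_report, decisions (per-chromosome list).
#' @export
run_meta_pipeline <- function(qtl, maps, reference,
                              ci_policy = "recomputed_always",
                              k_max = 10, n_starts = 10, seed = 1,
                              marker_table = NULL, genes = NULL) {
  projected <- project_qtl_table(qtl, maps, reference, ci_policy = ci_policy)
  results <- list(); decisions <- list()
  for (chrom in sort(unique(projected$chromosome))) {
    p <- projected[projected$chromosome == chrom, , drop = FALSE]
    res <- analyze_chromosome(p, consensus = reference, k_max = k_max,
                              n_starts = n_starts, seed = seed + chrom)
    results[[length(results) + 1L]] <- res$mqtl
    decisions[[as.character(chrom)]] <- res$decision
  }
  mqtl <- do.call(rbind, results)
  rownames(mqtl) <- NULL
  class(mqtl) <- c("meta_qtl", "data.frame")
  gene_report <- NULL
  if (!is.null(marker_table)) {
    ann <- annotate_mqtl(mqtl, marker_table, genes)
    mqtl <- ann$mqtl
    gene_report <- ann$genes
  }
  structure(list(projected = projected, mqtl = mqtl,
                 gene_report = gene_report, decisions = decisions,
                 seed = seed, ci_policy = ci_policy),
            class = "mqtl_result")
}

#' @export
print.mqtl_result <- function(x, ...) {
  cat("meta-QTL result:", nrow(x$mqtl), "MQTL on",
      length(unique(x$mqtl$chromosome)), "chromosomes from",
      nrow(x$projected), "projected QTL\n")
  branches <- vapply(x$decisions, `[[`, "", "branch")
  cat("  branches:", paste(sprintf("chr%s:%s", names(branches),
                                   ifelse(branches == "veyrieras", "V", "GG")),
                           collapse = " "), "\n")
  invisible(x)
}

#' Write a meta-QTL table to TSV
#'
#' Numeric columns are formatted with a fixed number of digits so that
#' identical results produce byte-identical files.
#'
#' @param mqtl \code{"meta_qtl"} data.frame.
#' @param path Output path.
#' @param digits Decimal digits for numeric columns.
#' @export
write_mqtl_table <- function(mqtl, path, digits = 6) {
  out <- mqtl
  num <- vapply(out, is.numeric, TRUE) & names(out) != "chromosome"
  for (col in names(out)[num]) {
    out[[col]] <- formatC(out[[col]], digits = digits, format = "f")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the per-chromosome decision log as JSON
#'
#' Records, for every chromosome, the branch taken, the criteria table
#' and votes (mixture branch) or the DP criterion table (cluster
#' branch), and the chosen model — enough to audit each selection.
#'
#' @param result \code{"mqtl_result"}.
#' @param path Output JSON path.
#' @export
write_decision_log <- function(result, path) {
  jsonlite::write_json(result$decisions, path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, dataframe = "columns",
                       force = TRUE)
  invisible(path)
}
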