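# Physical anchoring of meta-QTL and gene/variant extraction.

#' Physical interval spanned by two flanking markers
#'
#' Looks both markers up in the marker physical-position table and
#' returns the closed 1-based interval between them (argument order does
#' not matter). Interval length is reported in Mb.
#'
#' @param flank_left,flank_right Marker names.
#' @param table A \code{"marker_table"} (marker, chromosome, bp).
#' @return list(chromosome, start_bp, end_bp, mb) of class
#'   \code{"physical_interval"}.
#' @export
physical_interval <- function(flank_left, flank_right, table) {
  lookup <- function(m) {
    i <- match(m, table$marker)
    if (is.na(i)) stop("marker not found in physical table: ", m)
    table[i, , drop = FALSE]
  }
  a <- lookup(flank_left); b <- lookup(flank_right)
  if (a$chromosome != b$chromosome) {
    stop("flanking markers on different chromosomes: ", flank_left, " (chr",
         a$chromosome, ") vs ", flank_right, " (chr", b$chromosome, ")")
  }
  start <- min(a$bp, b$bp); end <- max(a$bp, b$bp)
  structure(list(chromosome = a$chromosome, start_bp = start,
                 end_bp = end, mb = (end - start) / 1e6),
            class = "physical_interval")
}

#' @export
print.physical_interval <- function(x, ...) {
  cat(sprintf("chr%d:%d-%d (%.3f Mb)\n", x$chromosome, x$start_bp,
              x$end_bp, x$mb))
  invisible(x)
}

#' Genes overlapping a physical interval
#'
#' Returns genes on the interval's chromosome whose [start_bp, end_bp]
#' overlaps the closed interval — any overlap counts, including a single
#' shared bp (gene counts depend critically on this convention; strand is
#' ignored).
#'
#' @param genes A \code{"gene_table"} (see \code{\link{read_gff3_genes}}).
#' @param interval A \code{"physical_interval"}.
#' @return The overlapping subset, sorted by start_bp.
#' @export
genes_in_interval <- function(genes, interval) {
  hit <- genes$chromosome == interval$chromosome &
    genes$start_bp <= interval$end_bp &
    genes$end_bp >= interval$start_bp
  out <- genes[hit, , drop = FALSE]
  out <- out[order(out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an aligned FASTA into a character matrix
#'
#' @param path FASTA of equal-length aligned sequences.
#' @return Character matrix (sequences x columns) with sequence names as
#'   rownames.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal lengths")
  }
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

#' Detect sequence variants that separate two phenotype classes
#'
#' Scans alignment columns and reports maximal runs of adjacent columns
#' where all low-class sequences agree, all high-class sequences agree,
#' and the two class consensuses differ (perfect class separation).
#' Adjacent distinguishing columns are merged into one variant; a run
#' containing a gap character in either class allele is reported as an
#' indel, otherwise as a substitution. Column indices are 0-based
#' alignment coordinates (annotation-independent).
#'
#' @param alignment Character matrix from \code{\link{read_alignment}},
#'   or a named character vector of equal-length aligned sequences.
#' @param classes Named character vector mapping sequence name ->
#'   \code{"low"} or \code{"high"}; each class needs >= 1 sequence.
#' @return data.frame with columns column (0-based start), span, kind
#'   ("substitution"/"indel"), low_allele, high_allele. Zero rows when
#'   the classes are indistinguishable.
#' @export
class_distinguishing_variants <- function(alignment, classes) {
  if (!is.matrix(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) {
      stop("alignment error: sequences have unequal lengths")
    }
    nm <- names(alignment)
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(alignment) <- nm
  }
  classes <- classes[rownames(alignment)]
  low <- alignment[!is.na(classes) & classes == "low", , drop = FALSE]
  high <- alignment[!is.na(classes) & classes == "high", , drop = FALSE]
  if (nrow(low) == 0L || nrow(high) == 0L) {
    stop("each class needs at least one sequence")
  }
  ncol_aln <- ncol(alignment)
  same <- function(m, j) length(unique(m[, j])) == 1L
  marks <- vapply(seq_len(ncol_aln), function(j) {
    same(low, j) && same(high, j) && low[1L, j] != high[1L, j]
  }, logical(1))
  if (!any(marks)) {
    return(data.frame(column = integer(0), span = integer(0),
                      kind = character(0), low_allele = character(0),
                      high_allele = character(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(marks)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(ri) {
    cols <- starts[ri]:ends[ri]
    la <- paste(low[1L, cols], collapse = "")
    ha <- paste(high[1L, cols], collapse = "")
    kind <- if (grepl("-", la, fixed = TRUE) ||
                grepl("-", ha, fixed = TRUE)) "indel" else "substitution"
    data.frame(column = cols[1L] - 1L, span = length(cols), kind = kind,
               low_allele = la, high_allele = ha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Attach physical intervals and gene content to a meta-QTL table
#'
#' For each meta-QTL with both flanking markers resolvable in the marker
#' table, computes the physical interval and counts/collects overlapping
#' genes. MQTL with unresolvable markers get NA physical fields.
#'
#' @param mqtl \code{"meta_qtl"} data.frame.
#' @param marker_table \code{"marker_table"}.
#' @param genes \code{"gene_table"} or NULL.
#' @return list(mqtl = mqtl with physical_start, physical_end,
#'   interval_mb, n_genes columns; genes = per-MQTL gene report
#'   data.frame with mqtl_id, locus_id, start_bp, end_bp, description).
#' @export
annotate_mqtl <- function(mqtl, marker_table, genes = NULL) {
  mqtl$physical_start <- NA_integer_
  mqtl$physical_end <- NA_integer_
  mqtl$interval_mb <- NA_real_
  mqtl$n_genes <- NA_integer_
  reports <- list()
  for (i in seq_len(nrow(mqtl))) {
    fl <- mqtl$flank_left[i]; fr <- mqtl$flank_right[i]
    if (is.na(fl) || is.na(fr)) next
    iv <- tryCatch(physical_interval(fl, fr, marker_table),
                   error = function(e) NULL)
    if (is.null(iv)) next
    mqtl$physical_start[i] <- iv$start_bp
    mqtl$physical_end[i] <- iv$end_bp
    mqtl$interval_mb[i] <- iv$mb
    if (!is.null(genes)) {
      g <- genes_in_interval(genes, iv)
      mqtl$n_genes[i] <- nrow(g)
      if (nrow(g)) {
        reports[[length(reports) + 1L]] <-
          data.frame(mqtl_id = mqtl$mqtl_id[i], locus_id = g$locus_id,
                     start_bp = g$start_bp, end_bp = g$end_bp,
                     description = g$description,
                     stringsAsFactors = FALSE)
      }
    }
  }
  gene_report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(mqtl_id = character(0), locus_id = character(0),
               start_bp = integer(0), end_bp = integer(0),
               description = character(0), stringsAsFactors = FALSE)
  list(mqtl = mqtl, genes = gene_report)
}
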