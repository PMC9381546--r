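# Canonical column names of a QTL table. study_id, chromosome and position
# are required on input; the rest may be absent or NA.
QTL_COLUMNS <- c("study_id", "qtl_id", "chromosome", "position", "lod", "r2",
                 "pop_size", "ci_start", "ci_end", "flank_left", "flank_right")

#' Normalize a phenotypic-variance-explained value to a proportion
#'
#' Source studies report the variance explained by a QTL (PVE / R-squared)
#' either as a proportion or as a percentage. Values greater than 1 are
#' interpreted as percentages and divided by 100; values in (0, 1] pass
#' through unchanged. NA passes through (missing R2 is allowed).
#'
#' @param value Numeric vector of reported R2 values.
#' @return Numeric vector of proportions in (0, 1].
#' @examples
#' normalize_r2(10.8)  # 0.108
#' normalize_r2(0.5)   # 0.5
#' @export
normalize_r2 <- function(value) {
  if (!is.numeric(value)) stop("r2 must be numeric")
  bad <- !is.na(value) & (value <= 0 | value > 100)
  if (any(bad)) {
    stop("r2 out of domain (must be in (0, 100]): ",
         paste(value[bad], collapse = ", "))
  }
  ifelse(!is.na(value) & value > 1, value / 100, value)
}

#' Read a multi-study QTL table
#'
#' Reads a delimited table of QTL compiled from independent mapping
#' studies (one row per reported QTL). Required columns: \code{study_id},
#' \code{chromosome}, \code{position} (cM on the study map). Optional:
#' \code{qtl_id} (auto-generated when absent), \code{lod}, \code{r2}
#' (auto-normalized, percentages accepted), \code{pop_size},
#' \code{ci_start}, \code{ci_end}, \code{flank_left}, \code{flank_right}.
#'
#' Rows violating the record invariants (chromosome outside 1..12,
#' non-finite position, LOD < 0, pop_size < 2, or a reported CI that does
#' not bracket the position) are dropped with a warning naming the reason.
#' The result is sorted by (chromosome, position).
#'
#' @param path Path to a TSV (or CSV, see \code{sep}) file with a header.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. \code{c(position = "pos_cM")}.
#' @param sep Field separator, tab by default.
#' @return A data.frame of class \code{"qtl_table"} with the canonical
#'   columns.
#' @export
read_qtl_table <- function(path, dialect = NULL, sep = "\t") {
  if (!file.exists(path)) stop("QTL table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L) stop("QTL table is empty: ", path)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("study_id", "chromosome", "position")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("QTL table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(QTL_COLUMNS, names(raw))) raw[[col]] <- NA
  df <- raw[, QTL_COLUMNS]
  df$study_id    <- as.character(df$study_id)
  df$qtl_id      <- as.character(df$qtl_id)
  df$chromosome  <- suppressWarnings(as.integer(df$chromosome))
  for (col in c("position", "lod", "r2", "pop_size", "ci_start", "ci_end"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$flank_left  <- as.character(df$flank_left)
  df$flank_right <- as.character(df$flank_right)
  df$r2 <- normalize_r2_quiet(df$r2)
  as_qtl_table(df)
}

# normalize_r2 that flags (rather than stops on) out-of-domain values, so
# a bad row can be dropped instead of aborting the whole parse
normalize_r2_quiet <- function(value) {
  out <- ifelse(!is.na(value) & value > 1 & value <= 100, value / 100, value)
  out[!is.na(value) & (value <= 0 | value > 100)] <- -1 # sentinel: invalid
  out
}

#' Validate and order a QTL data.frame
#'
#' Applies the per-record invariants, drops offending rows with a warning,
#' fills missing \code{qtl_id}s, and sorts by (chromosome, position).
#'
#' @param df A data.frame with the canonical QTL columns.
#' @return A \code{"qtl_table"} data.frame.
#' @export
as_qtl_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in setdiff(QTL_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, QTL_COLUMNS]
  df$chromosome <- suppressWarnings(as.integer(df$chromosome))
  df$pop_size <- suppressWarnings(as.integer(df$pop_size))
  for (col in c("position", "lod", "r2", "ci_start", "ci_end"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond & reasons == ""] <<- why
  }
  bad(is.na(df$chromosome) | df$chromosome < 1L | df$chromosome > 12L,
      "chromosome outside 1..12")
  bad(is.na(df$position) | !is.finite(df$position), "missing position")
  bad(!is.na(df$lod) & df$lod < 0, "negative LOD")
  bad(!is.na(df$r2) & (df$r2 <= 0 | df$r2 > 1), "r2 outside (0,1]")
  bad(!is.na(df$pop_size) & df$pop_size < 2, "pop_size < 2")
  has_ci <- !is.na(df$ci_start) & !is.na(df$ci_end)
  bad(has_ci & (df$ci_start > df$position | df$ci_end < df$position),
      "CI does not bracket position")
  drop <- reasons != ""
  if (any(drop)) {
    warning(sum(drop), " QTL row(s) dropped: ",
            paste(sprintf("row %d (%s)", which(drop), reasons[drop]),
                  collapse = "; "))
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid QTL rows remain")
  no_id <- is.na(df$qtl_id) | df$qtl_id == ""
  df$qtl_id[no_id] <- sprintf("q%s_c%d_%03d", df$study_id[no_id],
                              df$chromosome[no_id], which(no_id))
  df <- df[order(df$chromosome, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("qtl_table", "data.frame")
  df
}

#' Write a QTL table to TSV
#'
#' Inverse of \code{\link{read_qtl_table}}: all retained canonical fields
#' round-trip bit-for-bit through write/read.
#'
#' @param qtl A \code{"qtl_table"} data.frame.
#' @param path Output path.
#' @export
write_qtl_table <- function(qtl, path) {
  utils::write.table(qtl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a genetic map table
#'
#' A genetic map assigns markers to chromosomes and cM positions. The file
#' is TSV with header columns \code{map_id}, \code{marker},
#' \code{chromosome}, \code{position_cM}; a file holding a single map may
#' omit \code{map_id} (supply one via \code{map_id=}). A file may hold
#' several study maps distinguished by \code{map_id}.
#'
#' @param path TSV path.
#' @param map_id Map identifier to use when the file has no map_id column.
#' @return A data.frame of class \code{"genetic_map"} with columns map_id,
#'   marker, chromosome, position_cM, sorted by (map_id, chromosome,
#'   position_cM); marker names are unique within a map.
#' @export
read_genetic_map <- function(path, map_id = NULL) {
  if (!file.exists(path)) stop("genetic map not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!"map_id" %in% names(df)) {
    df$map_id <- if (is.null(map_id)) "map" else map_id
  }
  need <- c("map_id", "marker", "chromosome", "position_cM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("genetic map missing column(s): ",
                         paste(miss, collapse = ", "))
  as_genetic_map(df[, need])
}

#' @rdname read_genetic_map
#' @param df A data.frame with map_id, marker, chromosome, position_cM.
#' @export
as_genetic_map <- function(df) {
  df$map_id <- as.character(df$map_id)
  df$marker <- as.character(df$marker)
  df$chromosome <- as.integer(df$chromosome)
  df$position_cM <- as.numeric(df$position_cM)
  dup <- duplicated(df[, c("map_id", "marker")])
  if (any(dup)) {
    warning(sum(dup), " duplicate marker(s) within a map dropped")
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$map_id, df$chromosome, df$position_cM), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read a marker physical-position table
#'
#' TSV with header columns \code{marker}, \code{chromosome}, \code{bp}
#' (1-based). One row per marker.
#'
#' @param path TSV path.
#' @return data.frame of class \code{"marker_table"}.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("marker", "chromosome", "bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("marker table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$marker <- as.character(df$marker)
  df$chromosome <- as.integer(df$chromosome)
  df$bp <- as.integer(df$bp)
  if (any(df$bp < 1, na.rm = TRUE)) stop("marker bp must be >= 1")
  df <- df[!duplicated(df$marker), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Extract gene records from a GFF3 annotation
#'
#' Keeps only rows of the requested feature type. Coordinates are 1-based
#' inclusive (GFF3 convention); annotations that list minus-strand loci
#' with reversed coordinates are normalized so start <= end.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type to keep (default \code{"gene"}).
#' @return data.frame of class \code{"gene_table"} with columns locus_id,
#'   chromosome, start_bp, end_bp, strand, description, sorted by
#'   (chromosome, start_bp). Zero matching rows gives an empty table.
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == feature_type, , drop = FALSE]
  locus <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  desc <- rep("", nrow(g))
  for (col in c("Note", "description", "Name")) {
    if (col %in% names(g)) {
      v <- vapply(g[[col]], function(x) paste(unlist(x), collapse = " "), "")
      desc[desc == "" & !is.na(v) & v != ""] <- v[desc == "" & !is.na(v) & v != ""]
    }
  }
  chrom <- suppressWarnings(as.integer(gsub("^[Cc]hr0?", "", as.character(g$seqid))))
  out <- data.frame(locus_id = locus,
                    chromosome = chrom,
                    start_bp = as.integer(pmin(g$start, g$end)),
                    end_bp = as.integer(pmax(g$start, g$end)),
                    strand = as.character(g$strand),
                    description = desc,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_table", "data.frame")
  out
}
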