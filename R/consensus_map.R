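# Consensus-map construction: express a study map's cM coordinates in the
# reference (consensus) frame via markers shared between the two maps.
# The topology is a star: every study map is projected independently onto
# one fixed, saturated reference map.

#' Shared anchor markers between a study map and the reference
#'
#' @param source,reference \code{"genetic_map"} data.frames (each holding
#'   one map; subset a multi-map table by map_id first).
#' @param chromosome Chromosome to anchor.
#' @return An object of class \code{"anchor_set"}: list with
#'   \code{chromosome}, \code{marker}, \code{source} and \code{consensus}
#'   position vectors, ordered by source position.
#' @export
shared_anchors <- function(source, reference, chromosome) {
  s <- source[source$chromosome == chromosome, , drop = FALSE]
  r <- reference[reference$chromosome == chromosome, , drop = FALSE]
  if (nrow(s) == 0L || nrow(r) == 0L) {
    stop("chromosome ", chromosome, " absent from one of the maps")
  }
  common <- intersect(s$marker, r$marker)
  if (length(common) < 2L) {
    stop("insufficient anchors: fewer than 2 shared markers on chromosome ",
         chromosome)
  }
  src_pos <- s$position_cM[match(common, s$marker)]
  con_pos <- r$position_cM[match(common, r$marker)]
  ord <- order(src_pos, con_pos)
  structure(list(chromosome = as.integer(chromosome),
                 marker = common[ord],
                 source = src_pos[ord],
                 consensus = con_pos[ord]),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set: chromosome", x$chromosome, "with", length(x$source),
      "anchor pairs\n")
  invisible(x)
}

#' Resolve marker-order conflicts between maps
#'
#' Marker orders occasionally disagree between study maps and the
#' reference (local inversions, genotyping error). Projection needs
#' collinear anchors, so we retain a longest subsequence of anchor pairs
#' whose consensus positions are strictly increasing
#' (longest-increasing-subsequence on the consensus coordinate). Ties are
#' broken toward the subsequence with the smallest total rank displacement
#' |rank(source) - rank(consensus)|, then toward the leftmost subsequence.
#'
#' @param anchors An \code{"anchor_set"}.
#' @return The filtered \code{"anchor_set"} (attribute \code{"dropped"}
#'   lists removed markers).
#' @export
monotone_filter <- function(anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  n <- length(anchors$source)
  if (n < 2L) stop("insufficient anchors: need >= 2 raw pairs")
  cons <- anchors$consensus
  disp <- abs(rank(anchors$source, ties.method = "first") -
              rank(cons, ties.method = "first"))
  # DP over chains ending at i: maximize length, then minimize total
  # displacement, then lexicographically smallest index sequence.
  len <- integer(n); score <- numeric(n); prev <- integer(n)
  for (i in seq_len(n)) {
    len[i] <- 1L; score[i] <- disp[i]; prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (cons[j] < cons[i]) {
        cand_len <- len[j] + 1L
        cand_score <- score[j] + disp[i]
        better <- cand_len > len[i] ||
          (cand_len == len[i] && cand_score < score[i]) ||
          (cand_len == len[i] && cand_score == score[i] &&
             prev[i] != 0L && j < prev[i])
        if (better) {
          len[i] <- cand_len; score[i] <- cand_score; prev[i] <- j
        }
      }
    }
  }
  best_len <- max(len)
  ends <- which(len == best_len)
  ends <- ends[score[ends] == min(score[ends])]
  chain_of <- function(e) {
    idx <- integer(0)
    while (e != 0L) { idx <- c(e, idx); e <- prev[e] }
    idx
  }
  chains <- lapply(ends, chain_of)
  if (length(chains) > 1L) { # leftmost: smallest index sequence
    key <- vapply(chains, function(ix) paste(sprintf("%09d", ix),
                                             collapse = ","), "")
    chains <- chains[order(key)]
  }
  keep <- chains[[1L]]
  if (length(keep) < 2L) stop("insufficient anchors after monotone filter")
  out <- structure(list(chromosome = anchors$chromosome,
                        marker = anchors$marker[keep],
                        source = anchors$source[keep],
                        consensus = anchors$consensus[keep]),
                   class = "anchor_set")
  attr(out, "dropped") <- setdiff(anchors$marker, out$marker)
  out
}

# interval index (0 = left of first anchor, n-1 = beyond last interval)
# used by both projection and local expansion so the two agree
.anchor_interval <- function(pos, anchors) {
  n <- length(anchors$source)
  i <- findInterval(pos, anchors$source, rightmost.closed = FALSE)
  pmin(pmax(i, 1L), n - 1L) # clamp to terminal intervals for extrapolation
}

#' Project a source-map position into consensus coordinates
#'
#' Piecewise-linear interpolation between the two anchors bracketing the
#' position; beyond the terminal anchors, linear extrapolation with the
#' slope of the nearest anchor interval. Anchors map exactly to their
#' consensus positions.
#'
#' @param pos Numeric vector of source cM positions.
#' @param anchors A filtered \code{"anchor_set"}
#'   (see \code{\link{monotone_filter}}).
#' @return Numeric vector of consensus cM positions.
#' @export
project_position <- function(pos, anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  i <- .anchor_interval(pos, anchors)
  x0 <- anchors$source[i];    x1 <- anchors$source[i + 1L]
  y0 <- anchors$consensus[i]; y1 <- anchors$consensus[i + 1L]
  if (any(x1 == x0)) stop("degenerate anchor interval (zero source span)")
  y0 + (pos - x0) * (y1 - y0) / (x1 - x0)
}

#' Local expansion ratio of the consensus relative to the source map
#'
#' The ratio lambda = (consensus span)/(source span) of the anchor
#' interval containing \code{pos} (terminal interval when extrapolating).
#' Used to rescale a QTL confidence interval expressed on the source map
#' into consensus units.
#'
#' @inheritParams project_position
#' @return Numeric vector of ratios (> 0).
#' @export
local_expansion <- function(pos, anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  i <- .anchor_interval(pos, anchors)
  ds <- anchors$source[i + 1L] - anchors$source[i]
  dc <- anchors$consensus[i + 1L] - anchors$consensus[i]
  if (any(ds == 0)) stop("degenerate anchor interval (zero source span)")
  dc / ds
}

#' Build per-chromosome anchors for every study map against a reference
#'
#' Convenience wrapper: for each (map_id, chromosome) pair in
#' \code{maps}, computes \code{shared_anchors} against the reference and
#' applies \code{monotone_filter}. Pairs with fewer than two usable
#' anchors are skipped with a warning.
#'
#' @param maps A multi-map \code{"genetic_map"} (study maps).
#' @param reference A single-map \code{"genetic_map"}.
#' @return Nested list: \code{anchors[[map_id]][[as.character(chrom)]]}.
#' @export
build_anchors <- function(maps, reference) {
  out <- list()
  for (mid in unique(maps$map_id)) {
    m <- maps[maps$map_id == mid, , drop = FALSE]
    out[[mid]] <- list()
    for (chrom in sort(unique(m$chromosome))) {
      a <- tryCatch(monotone_filter(shared_anchors(m, reference, chrom)),
                    error = function(e) e)
      if (inherits(a, "error")) {
        warning("map ", mid, " chromosome ", chrom, ": ",
                conditionMessage(a))
      } else {
        out[[mid]][[as.character(chrom)]] <- a
      }
    }
  }
  out
}
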