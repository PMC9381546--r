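# QTL projection: re-estimate each QTL's 95% confidence interval and
# express the QTL on the consensus map with a Gaussian standard
# deviation. The per-QTL sigma is what the mixture model downstream
# treats as a known variance.

# 95% CI of a Gaussian = 2 * 1.96 * sigma
CI_SIGMA_FACTOR <- 3.92

#' Darvasi-Soller QTL confidence interval
#'
#' Empirical 95% confidence interval (cM) of a QTL position in a standard
#' biparental population: 530 / (N * R2), where N is the mapping
#' population size and R2 the proportion of phenotypic variance explained
#' by the QTL.
#'
#' @param pop_size Population size N (>= 2). Vectorized.
#' @param r2 Proportion of variance explained, in (0, 1]. Vectorized.
#' @return CI width in cM.
#' @examples
#' darvasi_soller_ci(100, 0.106) # 50
#' @export
darvasi_soller_ci <- function(pop_size, r2) {
  if (any(!is.na(r2) & (r2 <= 0 | r2 > 1))) stop("r2 must be in (0, 1]")
  if (any(!is.na(pop_size) & pop_size < 2)) stop("pop_size must be >= 2")
  530 / (pop_size * r2)
}

#' Gaussian standard deviation from a 95% confidence interval
#'
#' Under the Gaussian rule a 95% CI spans +/- 1.96 standard deviations,
#' so sigma = CI / 3.92.
#'
#' @param ci95 CI width in cM (> 0). Vectorized.
#' @return Standard deviation in cM.
#' @export
sigma_from_ci <- function(ci95) {
  if (any(!is.na(ci95) & ci95 <= 0)) stop("ci95 must be > 0")
  ci95 / CI_SIGMA_FACTOR
}

# Resolve the source-map CI width for one QTL row under a policy.
# Returns list(ci, origin) or NULL when no CI is obtainable.
.source_ci <- function(q, ci_policy) {
  reported <- if (!is.na(q$ci_start) && !is.na(q$ci_end) &&
                  q$ci_end > q$ci_start) q$ci_end - q$ci_start else NA_real_
  recomputed <- if (!is.na(q$pop_size) && !is.na(q$r2))
    darvasi_soller_ci(q$pop_size, q$r2) else NA_real_
  pick <- switch(ci_policy,
    reported_first   = if (!is.na(reported)) c(reported, "reported")
                       else c(recomputed, "darvasi_soller"),
    recomputed_always = if (!is.na(recomputed)) c(recomputed, "darvasi_soller")
                       else c(reported, "reported"),
    stop("unknown ci_policy: ", ci_policy))
  if (is.na(pick[1])) return(NULL)
  list(ci = as.numeric(pick[1]), origin = pick[2])
}

#' Project one QTL onto the consensus map
#'
#' Position is transferred by anchor interpolation; the source-map CI
#' (reported, or recomputed by the Darvasi-Soller rule, per
#' \code{ci_policy}) is rescaled by the local expansion ratio lambda of
#' the containing anchor interval, and sigma = CI / 3.92.
#'
#' @param q A single-row \code{"qtl_table"} data.frame (one QtlRecord).
#' @param anchors Filtered \code{"anchor_set"} for the QTL's map and
#'   chromosome.
#' @param ci_policy \code{"reported_first"} (respect the original
#'   authors' interval, recompute only to fill gaps) or
#'   \code{"recomputed_always"} (apply Darvasi-Soller wherever N and R2
#'   are available, as the full-pipeline default).
#' @return One-row data.frame of class \code{"projected_qtl"}: qtl_id,
#'   study_id, chromosome, position (consensus cM), sigma, ci95, lambda,
#'   ci_origin, lod, r2, pop_size.
#' @export
project_qtl <- function(q, anchors,
                        ci_policy = c("reported_first", "recomputed_always")) {
  ci_policy <- match.arg(ci_policy)
  stopifnot(nrow(q) == 1L)
  src <- .source_ci(q, ci_policy)
  if (is.null(src)) {
    missing <- c(if (is.na(q$ci_start) || is.na(q$ci_end)) "ci_start/ci_end",
                 if (is.na(q$pop_size)) "pop_size",
                 if (is.na(q$r2)) "r2")
    stop("unusable record ", q$qtl_id, ": no CI obtainable (missing ",
         paste(missing, collapse = ", "), ")")
  }
  lambda <- local_expansion(q$position, anchors)
  ci95 <- src$ci * lambda
  out <- data.frame(qtl_id = q$qtl_id, study_id = q$study_id,
                    chromosome = q$chromosome,
                    position = project_position(q$position, anchors),
                    sigma = sigma_from_ci(ci95), ci95 = ci95,
                    lambda = lambda, ci_origin = src$origin,
                    lod = q$lod, r2 = q$r2, pop_size = q$pop_size,
                    stringsAsFactors = FALSE)
  class(out) <- c("projected_qtl", "data.frame")
  out
}

#' Project a whole QTL table onto the consensus map
#'
#' Builds anchors per (study map, chromosome) and projects every QTL.
#' QTL whose study map lacks usable anchors for their chromosome, or that
#' carry neither a reported CI nor (N, R2), are dropped with a warning
#' listing them; this is the projection-time "unusable" flagging.
#'
#' @param qtl A \code{"qtl_table"}. Its \code{study_id} values must match
#'   \code{map_id}s in \code{maps}.
#' @param maps Multi-map \code{"genetic_map"} of study maps.
#' @param reference Single-map \code{"genetic_map"} (the consensus frame).
#' @inheritParams project_qtl
#' @return \code{"projected_qtl"} data.frame sorted by (chromosome,
#'   position).
#' @export
project_qtl_table <- function(qtl, maps, reference,
                              ci_policy = c("reported_first",
                                            "recomputed_always")) {
  ci_policy <- match.arg(ci_policy)
  anchors <- build_anchors(maps, reference)
  rows <- vector("list", nrow(qtl))
  skipped <- character(0)
  for (i in seq_len(nrow(qtl))) {
    q <- qtl[i, , drop = FALSE]
    a <- anchors[[q$study_id]][[as.character(q$chromosome)]]
    if (is.null(a)) {
      skipped <- c(skipped, paste0(q$qtl_id, " (no anchors)"))
      next
    }
    p <- tryCatch(project_qtl(q, a, ci_policy), error = function(e) e)
    if (inherits(p, "error")) {
      skipped <- c(skipped, paste0(q$qtl_id, " (",
                                   conditionMessage(p), ")"))
    } else rows[[i]] <- p
  }
  if (length(skipped)) {
    warning(length(skipped), " QTL not projectable: ",
            paste(skipped, collapse = "; "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L) stop("no QTL could be projected")
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("projected_qtl", "data.frame")
  out
}
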