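# Marker-based validation of a meta-QTL on an extreme-phenotype panel:
# genotypes with thousand-grain weight below a low threshold vs above a
# high threshold, scored at a linked SSR marker. The operative evidence
# is how cleanly marker alleles separate the two phenotype classes.

#' Classify panel genotypes into extreme phenotype classes
#'
#' Thousand-grain weight below \code{low_max} -> "low"; above
#' \code{high_min} -> "high"; in between -> excluded (reported via a
#' message). Defaults follow the common extreme-panel thresholds of
#' 12.50 g and 25.00 g.
#'
#' @param panel data.frame with columns genotype_id, tgw (grams) and
#'   optionally allele.
#' @param low_max Upper bound of the low class (exclusive), grams.
#' @param high_min Lower bound of the high class (exclusive), grams.
#' @return The panel with an added \code{class} column ("low"/"high"),
#'   excluded rows removed.
#' @export
classify_phenotypes <- function(panel, low_max = 12.50, high_min = 25.00) {
  stopifnot(low_max < high_min)
  if (any(panel$tgw <= 0, na.rm = TRUE)) stop("tgw must be positive")
  cls <- ifelse(panel$tgw < low_max, "low",
                ifelse(panel$tgw > high_min, "high", NA_character_))
  excluded <- is.na(cls)
  if (any(excluded)) {
    message(sum(excluded), " genotype(s) excluded (tgw between thresholds): ",
            paste(panel$genotype_id[excluded], collapse = ", "))
  }
  out <- panel[!excluded, , drop = FALSE]
  if (nrow(out) == 0L) stop("empty panel: all genotypes excluded")
  out$class <- cls[!excluded]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact probability of a 2x2 table by enumeration
#'
#' Enumerates every table with the observed margins and sums the
#' hypergeometric probabilities of all tables whose point probability is
#' less than or equal to the observed table's (with a small relative
#' tolerance for floating-point ties) — the standard two-sided rule.
#'
#' @param tab 2x2 integer matrix of counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a_obs]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Association between marker alleles and phenotype classes
#'
#' Builds the 2x2 class-by-allele contingency table, computes a
#' two-sided Fisher exact p-value by full hypergeometric enumeration,
#' and the allele-phenotype concordance: the maximum over the two
#' allele-to-class pairings of the fraction of genotypes whose allele
#' matches their class. A marker is flagged \code{validated} when
#' p < 0.05 and concordance = 1 (both alleles perfectly class-specific).
#'
#' @param labels Character vector of phenotype classes (exactly 2 levels
#'   present).
#' @param alleles Character vector of allele labels, same length; at most
#'   2 levels present (collapse rarer alleles first if needed).
#' @return list of class \code{"validation_result"}: table, fisher_p,
#'   concordance, validated.
#' @export
association_test <- function(labels, alleles) {
  stopifnot(length(labels) == length(alleles))
  keep <- !is.na(labels) & !is.na(alleles)
  labels <- labels[keep]; alleles <- alleles[keep]
  if (length(unique(labels)) != 2L) {
    stop("need exactly 2 phenotype classes, got ",
         length(unique(labels)))
  }
  if (length(unique(alleles)) > 2L) {
    stop("more than 2 allele classes present; collapse rare alleles ",
         "before testing")
  }
  tab <- table(class = labels, allele = alleles)
  if (ncol(tab) < 2L || any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("degenerate table: a phenotype or allele class is empty")
  }
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  p <- fisher_exact_2x2(tab)
  n <- sum(tab)
  concordance <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / n
  structure(list(table = tab, fisher_p = p, concordance = concordance,
                 validated = (p < 0.05 && concordance == 1)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fisher exact p = %.4g, concordance = %.3f, validated = %s\n",
              x$fisher_p, x$concordance, x$validated))
  invisible(x)
}

#' Validate a marker on an extreme-phenotype panel
#'
#' Convenience wrapper: classify phenotypes, then test the class-allele
#' association.
#'
#' @inheritParams classify_phenotypes
#' @return A \code{"validation_result"} (see
#'   \code{\link{association_test}}) with an added \code{thresholds}
#'   element.
#' @export
validate_marker <- function(panel, low_max = 12.50, high_min = 25.00) {
  cl <- classify_phenotypes(panel, low_max, high_min)
  res <- association_test(cl$class, cl$allele)
  res$thresholds <- c(low_max = low_max, high_min = high_min)
  res
}
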