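# Meta-QTL detection. Two branches, dispatched on the number of projected
# QTL on the chromosome:
#   n > 9  : Gaussian mixture with known per-observation variances,
#            fitted by multi-start EM for K = 1..K_max, with the number
#            of components chosen by a >=3-of-5 vote among AIC, AICc,
#            AIC3, BIC and AWE ("Veyrieras" branch).
#   n <= 9 : exact dynamic programming over contiguous clusters of the
#            ordered QTL, model chosen among k in {1,2,3,4,n} by a
#            BIC-like criterion ("Gerber & Goffinet" branch).

# log N(x; mu, s^2) for vectors x, s and scalar mu
.lognorm <- function(x, mu, s) stats::dnorm(x, mu, s, log = TRUE)

# weighted inverse-variance mean: argmax_mu sum w_i log N(x_i; mu, s_i^2)
.ivmean <- function(x, s, w = rep(1, length(x))) {
  sum(w * x / s^2) / sum(w / s^2)
}

# total log-likelihood of a mixture (log-sum-exp over components)
# x, s: length n; mu: length K; pi_k: length K
.mixture_loglik <- function(x, s, mu, pi_k) {
  lp <- vapply(seq_along(mu),
               function(k) log(pi_k[k]) + .lognorm(x, mu[k], s),
               numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Fit a K-component Gaussian mixture with known per-observation variances
#'
#' Model: x_i ~ sum_k pi_k N(mu_k, s_i^2), where each observation's
#' variance s_i^2 is known (derived from the projected QTL's 95% CI), so
#' only the K means and K-1 free weights are estimated. Fitted by EM:
#' E-step z_ik proportional to pi_k N(x_i; mu_k, s_i^2); M-step mu_k =
#' inverse-variance mean weighted by z_ik, pi_k = mean_i z_ik. The best
#' of \code{n_starts} initializations (one quantile-spread start plus
#' seeded random restarts) is returned. Convergence: |delta logL| < 1e-8
#' or 500 iterations.
#'
#' @param x Projected QTL positions (cM).
#' @param s Per-QTL standard deviations (cM, > 0), same length as x.
#' @param K Number of components (1 <= K <= length(x)).
#' @param n_starts Number of EM initializations (default 10).
#' @param seed Integer seed for the random restarts.
#' @return Object of class \code{"mixture_model"}: list(K, means, weights,
#'   logL, responsibilities, converged, n_obs, iterations). Means are
#'   sorted ascending with weights and responsibility columns aligned.
#' @export
em_fit <- function(x, s, K, n_starts = 10, seed = 1) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (length(s) != n) stop("x and s must have equal length")
  if (any(s <= 0)) stop("all sigmas must be > 0")
  if (K < 1L || K > n) stop("K must be in 1..n")

  if (K == 1L) { # closed form: inverse-variance mean
    mu <- .ivmean(x, s)
    ll <- sum(.lognorm(x, mu, s))
    return(structure(list(K = 1L, means = mu, weights = 1,
                          logL = ll,
                          responsibilities = matrix(1, n, 1),
                          converged = TRUE, n_obs = n, iterations = 0L),
                     class = "mixture_model"))
  }

  run_em <- function(mu0) {
    mu <- mu0
    pi_k <- rep(1 / K, K)
    ll_old <- -Inf
    converged <- FALSE
    z <- matrix(1 / K, n, K)
    iter <- 0L
    for (iter in seq_len(500L)) {
      # E-step in log space
      lp <- vapply(seq_len(K),
                   function(k) log(pi_k[k]) + .lognorm(x, mu[k], s),
                   numeric(n))
      lp <- matrix(lp, nrow = n)
      m <- apply(lp, 1, max)
      ll <- sum(m + log(rowSums(exp(lp - m))))
      z <- exp(lp - m - log(rowSums(exp(lp - m))))
      # EM monotonicity guard: logL never decreases (tolerate roundoff)
      if (ll < ll_old - 1e-7) {
        stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
      }
      if (abs(ll - ll_old) < 1e-8) { converged <- TRUE; break }
      ll_old <- ll
      # M-step
      w <- z / s^2
      mu <- colSums(w * x) / colSums(w)
      pi_k <- colMeans(z)
      pi_k <- pmax(pi_k, 1e-12); pi_k <- pi_k / sum(pi_k)
    }
    list(mu = mu, pi_k = pi_k, logL = ll, z = z, converged = converged,
         iterations = iter)
  }

  # initial means: quantile spread, then seeded random subsets of x
  starts <- list(stats::quantile(x, probs = (seq_len(K) - 0.5) / K,
                                 names = FALSE, type = 7))
  if (n_starts > 1L) {
    rng <- withr_seed(seed)
    for (r in seq_len(n_starts - 1L)) {
      starts[[r + 1L]] <- sort(x[sample.int(n, K, replace = FALSE)] +
                                 stats::rnorm(K, 0, stats::sd(x) * 0.01 + 1e-9))
    }
    restore_seed(rng)
  }
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, 0, "logL"))]]

  ord <- order(best$mu)
  structure(list(K = as.integer(K), means = best$mu[ord],
                 weights = best$pi_k[ord], logL = best$logL,
                 responsibilities = best$z[, ord, drop = FALSE],
                 converged = best$converged, n_obs = n,
                 iterations = best$iterations),
            class = "mixture_model")
}

# local RNG scope: seed without clobbering the caller's RNG stream
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: K=%d, n=%d, logL=%.4f, converged=%s\n",
              x$K, x$n_obs, x$logL, x$converged))
  cat("  means:  ", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Information criteria for a fitted mixture
#'
#' Free-parameter count nu = 2K - 1 (K means and K - 1 free weights; the
#' per-observation variances are known, not estimated). AIC = -2logL +
#' 2nu; AICc = AIC + 2nu(nu+1)/(n-nu-1) (+Inf when the denominator is
#' <= 0); AIC3 = -2logL + 3nu; BIC = -2logL + nu log n; AWE = -2logL +
#' 2nu(1.5 + log n).
#'
#' @param model A \code{"mixture_model"}.
#' @return One-row data.frame: K, nu, logL, AIC, AICc, AIC3, BIC, AWE.
#' @export
information_criteria <- function(model) {
  K <- model$K; n <- model$n_obs; ll <- model$logL
  nu <- 2 * K - 1
  aic <- -2 * ll + 2 * nu
  aicc <- if (n - nu - 1 > 0) aic + 2 * nu * (nu + 1) / (n - nu - 1) else Inf
  data.frame(K = K, nu = nu, logL = ll,
             AIC = aic,
             AICc = aicc,
             AIC3 = -2 * ll + 3 * nu,
             BIC = -2 * ll + nu * log(n),
             AWE = -2 * ll + 2 * nu * (1.5 + log(n)))
}

#' Choose the number of mixture components by a >=3-of-5 criterion vote
#'
#' Each of AIC, AICc, AIC3, BIC, AWE votes for its minimizing K (ties
#' toward smaller K). The chosen K is the smallest K receiving at least
#' three of the five votes; if no K reaches three votes, the plurality
#' winner (ties toward smaller K).
#'
#' @param criteria data.frame with columns K, AIC, AICc, AIC3, BIC, AWE
#'   over a contiguous K range (one row per K).
#' @return list(K, votes, rule) where votes is a named integer vector
#'   (criterion -> voted K) and rule records the decision path taken.
#' @export
select_k <- function(criteria) {
  if (is.null(criteria) || nrow(criteria) == 0L) stop("empty criteria table")
  crits <- c("AIC", "AICc", "AIC3", "BIC", "AWE")
  votes <- vapply(crits, function(cr) {
    v <- criteria[[cr]]
    criteria$K[which(v == min(v))[1L]] # ties -> smaller K (rows ordered by K)
  }, numeric(1))
  tab <- table(votes)
  ks <- as.numeric(names(tab))
  winners <- ks[tab >= 3]
  if (length(winners) > 0L) {
    list(K = as.integer(min(winners)), votes = votes, rule = "majority>=3")
  } else {
    plur <- ks[tab == max(tab)]
    list(K = as.integer(min(plur)), votes = votes, rule = "plurality")
  }
}

#' Optimal contiguous clustering of ordered QTL (exact DP)
#'
#' Partitions the position-ordered QTL into k contiguous blocks
#' maximizing sum_i log N(x_i; mu_block(i), s_i^2), where each block mean
#' is the block's inverse-variance mean. Solved exactly by dynamic
#' programming over block boundaries; ties broken toward the leftmost
#' boundaries.
#'
#' @param x Positions sorted ascending.
#' @param s Per-QTL standard deviations (> 0).
#' @param k Number of blocks (1 <= k <= n).
#' @return list(assignment (1-based block index per QTL), means, logL).
#' @export
gg_cluster <- function(x, s, k) {
  n <- length(x)
  if (is.unsorted(x)) stop("x must be sorted ascending")
  if (k < 1L || k > n) stop("k must be in 1..n")
  # cost[i, j]: max log-lik of one block covering x[i..j]
  cost <- matrix(-Inf, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      idx <- i:j
      mu <- .ivmean(x[idx], s[idx])
      cost[i, j] <- sum(.lognorm(x[idx], mu, s[idx]))
    }
  }
  # dp[b, j]: best total over x[1..j] with b blocks; cut[b, j]: start of
  # the last block. Leftmost tie-break: strict improvement required, and
  # candidates scanned left to right for the last block's start.
  dp <- matrix(-Inf, k, n); cut <- matrix(0L, k, n)
  dp[1, ] <- cost[1, ]; cut[1, ] <- 1L
  if (k > 1L) {
    for (b in 2:k) {
      for (j in b:n) {
        for (i in b:j) { # last block is x[i..j]
          cand <- dp[b - 1L, i - 1L] + cost[i, j]
          if (cand > dp[b, j] + 1e-12) { dp[b, j] <- cand; cut[b, j] <- i }
        }
      }
    }
  }
  assignment <- integer(n)
  j <- n
  for (b in k:1) {
    i <- cut[b, j]
    assignment[i:j] <- b
    j <- i - 1L
  }
  means <- vapply(seq_len(k), function(b) {
    idx <- assignment == b
    .ivmean(x[idx], s[idx])
  }, numeric(1))
  list(assignment = assignment, means = means, logL = dp[k, n])
}

#' Model selection for the contiguous-cluster branch
#'
#' Evaluates gg_cluster for each candidate k in {1, 2, 3, 4, n}
#' (intersected with 1..n, deduplicated) and picks the k minimizing the
#' BIC-like criterion C(k) = -2 logL(k) + 2 k log(n); ties toward smaller
#' k. The chosen model is labelled "Model m" ("Model n" when k = n).
#'
#' @inheritParams gg_cluster
#' @return list(k, label, assignment, means, logL, table) where table
#'   holds C(k) for every candidate.
#' @export
gg_select <- function(x, s) {
  n <- length(x)
  cands <- sort(unique(pmin(c(1L, 2L, 3L, 4L, n), n)))
  cands <- cands[cands >= 1L]
  fits <- lapply(cands, function(k) gg_cluster(x, s, k))
  crit <- vapply(seq_along(cands),
                 function(i) -2 * fits[[i]]$logL + 2 * cands[i] * log(n),
                 numeric(1))
  best <- which(crit == min(crit))[1L] # candidates ascending: ties -> smaller k
  k <- cands[best]
  list(k = as.integer(k),
       label = if (k == n && n > 4L) "Model n" else paste("Model", k),
       assignment = fits[[best]]$assignment,
       means = fits[[best]]$means,
       logL = fits[[best]]$logL,
       table = data.frame(k = cands, criterion = crit))
}

#' Summarize one meta-QTL from its member QTL
#'
#' Position is the (responsibility-weighted) inverse-variance mean of the
#' member positions; sigma_meta = sqrt(1 / sum_i w_i / s_i^2) with w_i
#' the membership weight (responsibility in the mixture branch, 1 in the
#' hard-block branch); the 95% CI is position +/- 1.96 sigma_meta. The
#' peak marker is the consensus marker nearest the position; the flanking
#' markers are the nearest markers strictly outside the CI on each side.
#'
#' @param members \code{"projected_qtl"} rows belonging to the component
#'   (hard assignment, used for the member list).
#' @param weight Component weight (mixture pi_k, or |members|/n).
#' @param consensus Single-map \code{"genetic_map"} for marker lookup, or
#'   NULL to skip marker fields.
#' @param w Per-member weights used for position/sigma (defaults to 1s).
#' @param mqtl_id Identifier for the meta-QTL.
#' @return One-row data.frame of class \code{"meta_qtl"}.
#' @export
summarize_mqtl <- function(members, weight, consensus = NULL,
                           w = rep(1, nrow(members)), mqtl_id = "MQTL") {
  stopifnot(nrow(members) >= 1L)
  chrom <- members$chromosome[1L]
  pos <- .ivmean(members$position, members$sigma, w)
  sig <- sqrt(1 / sum(w / members$sigma^2))
  lo <- pos - 1.96 * sig
  hi <- pos + 1.96 * sig
  peak <- flank_l <- flank_r <- NA_character_
  if (!is.null(consensus)) {
    mk <- consensus[consensus$chromosome == chrom, , drop = FALSE]
    if (nrow(mk) == 0L) {
      warning("no consensus markers on chromosome ", chrom,
              "; marker fields left empty")
    } else {
      peak <- mk$marker[which.min(abs(mk$position_cM - pos))]
      left <- mk[mk$position_cM < lo, , drop = FALSE]
      right <- mk[mk$position_cM > hi, , drop = FALSE]
      if (nrow(left)) flank_l <- left$marker[which.max(left$position_cM)]
      if (nrow(right)) flank_r <- right$marker[which.min(right$position_cM)]
    }
  }
  out <- data.frame(mqtl_id = mqtl_id, chromosome = chrom,
                    position = pos, sigma = sig,
                    ci95_start = lo, ci95_end = hi,
                    weight = weight, n_members = nrow(members),
                    member_qtl = paste(members$qtl_id, collapse = ","),
                    peak_marker = peak, flank_left = flank_l,
                    flank_right = flank_r, stringsAsFactors = FALSE)
  class(out) <- c("meta_qtl", "data.frame")
  out
}

#' Meta-QTL analysis of one chromosome
#'
#' Dispatches on QTL count: more than nine projected QTL triggers the
#' mixture branch (EM over K = 1..min(k_max, n) with the >=3-criteria
#' vote); nine or fewer triggers the contiguous-cluster branch. Members
#' are assigned to their maximum-responsibility component (ties toward
#' the lower-index component) or to their DP block, and each component is
#' summarized into a meta-QTL.
#'
#' @param projected \code{"projected_qtl"} rows, all on one chromosome.
#' @param consensus Single-map \code{"genetic_map"} or NULL.
#' @param k_max Upper bound on mixture components (default 10).
#' @param n_starts,seed Passed to \code{\link{em_fit}}.
#' @return list(mqtl = \code{"meta_qtl"} data.frame, decision = list with
#'   branch, criteria/votes or DP table, chosen model).
#' @export
analyze_chromosome <- function(projected, consensus = NULL, k_max = 10,
                               n_starts = 10, seed = 1) {
  stopifnot(nrow(projected) >= 1L)
  chrom <- projected$chromosome[1L]
  stopifnot(all(projected$chromosome == chrom))
  projected <- projected[order(projected$position), , drop = FALSE]
  x <- projected$position
  s <- projected$sigma
  n <- length(x)

  if (n > 9L) {
    kmax <- min(k_max, n)
    fits <- lapply(seq_len(kmax), function(K)
      em_fit(x, s, K, n_starts = n_starts, seed = seed + K))
    crit <- do.call(rbind, lapply(fits, information_criteria))
    sel <- select_k(crit)
    fit <- fits[[sel$K]]
    hard <- apply(fit$responsibilities, 1, which.max) # ties -> lower index
    mqtl <- do.call(rbind, lapply(seq_len(fit$K), function(k) {
      members <- projected[hard == k, , drop = FALSE]
      if (nrow(members) == 0L) return(NULL) # empty component: not reportable
      summarize_mqtl(members, weight = fit$weights[k], consensus = consensus,
                     w = fit$responsibilities[hard == k, k],
                     mqtl_id = sprintf("MQTL%d.%d", chrom, k))
    }))
    decision <- list(branch = "veyrieras", n = n, criteria = crit,
                     votes = as.list(sel$votes), rule = sel$rule,
                     chosen_K = sel$K, means = fit$means,
                     weights = fit$weights, converged = fit$converged)
  } else {
    sel <- gg_select(x, s)
    mqtl <- do.call(rbind, lapply(seq_len(sel$k), function(b) {
      members <- projected[sel$assignment == b, , drop = FALSE]
      summarize_mqtl(members, weight = nrow(members) / n,
                     consensus = consensus,
                     mqtl_id = sprintf("MQTL%d.%d", chrom, b))
    }))
    decision <- list(branch = "gerber_goffinet", n = n,
                     table = sel$table, chosen_k = sel$k,
                     label = sel$label, means = sel$means)
  }
  rownames(mqtl) <- NULL
  class(mqtl) <- c("meta_qtl", "data.frame")
  list(mqtl = mqtl, decision = decision)
}
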