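# Shared fixture builders and independent oracles. Oracles are written
# from scratch here (enumeration / grid search) and never call the code
# paths they check.

make_map <- function(map_id, markers, chromosome, positions) {
  as_genetic_map(data.frame(map_id = map_id, marker = markers,
                            chromosome = chromosome,
                            position_cM = positions,
                            stringsAsFactors = FALSE))
}

make_anchors <- function(source_pos, consensus_pos, chromosome = 1L) {
  n <- length(source_pos)
  structure(list(chromosome = chromosome,
                 marker = sprintf("M%d", seq_len(n)),
                 source = source_pos, consensus = consensus_pos),
            class = "anchor_set")
}

make_qtl_df <- function(...) {
  rows <- list(...)
  base <- list(study_id = "S01", qtl_id = NA, chromosome = 1L,
               position = 10, lod = 3, r2 = 0.1, pop_size = 100L,
               ci_start = NA, ci_end = NA, flank_left = NA,
               flank_right = NA)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(base, r), stringsAsFactors = FALSE)
  }))
}

make_projected <- function(position, sigma, chromosome = 1L,
                           qtl_id = sprintf("q%02d", seq_along(position))) {
  df <- data.frame(qtl_id = qtl_id, study_id = "S01",
                   chromosome = as.integer(chromosome),
                   position = position, sigma = sigma,
                   ci95 = sigma * 3.92, lambda = 1,
                   ci_origin = "reported", lod = NA_real_, r2 = NA_real_,
                   pop_size = NA_integer_, stringsAsFactors = FALSE)
  class(df) <- c("projected_qtl", "data.frame")
  df
}

# Oracle: maximum mixture log-likelihood by grid search (K <= 2).
# Grid over component means (step 0.1, data range padded by 2 cM) and
# mixing weight (step 0.05). Returns a lower bound on the global max.
grid_logL_max <- function(x, s, K) {
  grid <- seq(min(x) - 2, max(x) + 2, by = 0.1)
  D <- vapply(grid, function(m) dnorm(x, m, s), numeric(length(x)))
  D <- matrix(D, nrow = length(x)) # n x G component densities
  if (K == 1L) return(max(colSums(log(D))))
  best <- -Inf
  for (p in seq(0.05, 0.95, by = 0.05)) {
    M <- p * D
    N <- (1 - p) * D
    for (j in seq_along(grid)) {
      ll <- colSums(log(M[, j] + N)) # over all mu2 for this mu1, pi
      best <- max(best, max(ll))
    }
  }
  best
}

# Oracle: exhaustive optimal contiguous k-partition of sorted x.
# Enumerates all boundary sets in lexicographic order, keeps the first
# strict maximum (leftmost tie-break).
gg_oracle <- function(x, s, k) {
  n <- length(x)
  block_ll <- function(idx) {
    mu <- sum(x[idx] / s[idx]^2) / sum(1 / s[idx]^2)
    sum(dnorm(x[idx], mu, s[idx], log = TRUE))
  }
  boundary_sets <- if (k == 1L) list(integer(0)) else
    utils::combn(n - 1L, k - 1L, simplify = FALSE)
  best_ll <- -Inf; best_assign <- NULL
  for (bs in boundary_sets) {
    cuts <- c(0L, bs, n)
    assign <- rep(seq_len(k), diff(cuts))
    ll <- sum(vapply(seq_len(k), function(b) block_ll(which(assign == b)),
                     numeric(1)))
    if (ll > best_ll + 1e-12) { best_ll <- ll; best_assign <- assign }
  }
  list(logL = best_ll, assignment = best_assign)
}

# Simulate the projected QTL of one chromosome straight from the
# generator (no map projection), for mixture-recovery experiments.
simulate_projected_chromosome <- function(seed, chromosome = 3L) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_chromosome(cfg, chromosome)
  q <- sim$qtl
  p <- make_projected(q$position,
                      darvasi_soller_ci(q$pop_size, q$r2) / 3.92,
                      chromosome = chromosome, qtl_id = q$qtl_id)
  list(projected = p, truth = sim$truth)
}
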