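test_that("em_fit K=1 equals the closed-form inverse-variance mean", {
  m <- em_fit(c(10, 20), c(1, 1), K = 1)
  expect_equal(m$means, 15)
  expect_equal(m$weights, 1)
  m2 <- em_fit(c(10, 20), c(1, 2), K = 1)
  expect_equal(m2$means, 12.0) # (10/1 + 20/4)/(1 + 1/4)
  set.seed(3)
  x <- runif(12, 0, 50); s <- runif(12, 0.5, 5)
  m3 <- em_fit(x, s, K = 1)
  expect_equal(m3$means, sum(x / s^2) / sum(1 / s^2), tolerance = 1e-9)
  expect_equal(m3$logL, sum(dnorm(x, m3$means, s, log = TRUE)))
})

test_that("em_fit separates two well-spaced components", {
  m <- em_fit(c(0, 0, 100, 100), rep(1, 4), K = 2, seed = 1)
  expect_equal(m$means, c(0, 100), tolerance = 1e-6)
  expect_equal(m$weights, c(0.5, 0.5), tolerance = 1e-6)
  expect_true(m$converged)
  # at least the grid-search oracle's log-likelihood
  expect_gte(m$logL, grid_logL_max(c(0, 0, 100, 100), rep(1, 4), 2) - 1e-6)
})

test_that("em_fit validates its input and is seed-deterministic", {
  expect_error(em_fit(numeric(0), numeric(0), 1), "empty")
  expect_error(em_fit(c(1, 2), c(1, 1), 3), "K must be")
  expect_error(em_fit(c(1, 2), c(1, 0), 1), "sigmas")
  set.seed(5); x <- runif(15, 0, 80); s <- runif(15, 1, 10)
  a <- em_fit(x, s, K = 3, seed = 42)
  b <- em_fit(x, s, K = 3, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$weights), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(a$responsibilities) - 1) < 1e-9))
  expect_true(!is.unsorted(a$means))
})

test_that("information_criteria arithmetic matches the stated forms", {
  fake <- structure(list(K = 1L, n_obs = 10L, logL = -10),
                    class = "mixture_model")
  ic <- information_criteria(fake)
  expect_equal(ic$nu, 1)
  expect_equal(ic$AIC, 22)
  expect_equal(ic$AIC3, 23)
  expect_equal(ic$AICc, 22.5)
  expect_equal(ic$BIC, 22.302585, tolerance = 1e-6)
  expect_equal(ic$AWE, 27.605170, tolerance = 1e-6)
  # AICc guard: nu = 11 > n - 1
  fake6 <- structure(list(K = 6L, n_obs = 10L, logL = -10),
                     class = "mixture_model")
  expect_equal(information_criteria(fake6)$AICc, Inf)
  # equal logL, larger K: every criterion strictly larger
  fake2 <- structure(list(K = 2L, n_obs = 10L, logL = -10),
                     class = "mixture_model")
  ic2 <- information_criteria(fake2)
  for (cr in c("AIC", "AICc", "AIC3", "BIC", "AWE")) {
    expect_gt(ic2[[cr]], ic[[cr]])
  }
})

test_that("select_k applies the >=3-vote rule with plurality fallback", {
  tab <- function(votes) {
    # build a criteria table whose per-criterion argmins equal `votes`
    ks <- 1:3
    out <- data.frame(K = ks)
    for (cr in names(votes)) {
      v <- rep(100, length(ks))
      v[votes[[cr]]] <- 1
      out[[cr]] <- v
    }
    out
  }
  s <- select_k(tab(list(AIC = 2, AICc = 2, AIC3 = 2, BIC = 1, AWE = 1)))
  expect_equal(s$K, 2L)
  expect_equal(s$rule, "majority>=3")
  s2 <- select_k(tab(list(AIC = 1, AICc = 1, AIC3 = 2, BIC = 2, AWE = 3)))
  expect_equal(s2$K, 1L) # plurality 2-2-1, tie -> smaller K
  expect_equal(s2$rule, "plurality")
  s3 <- select_k(tab(list(AIC = 3, AICc = 3, AIC3 = 3, BIC = 3, AWE = 3)))
  expect_equal(s3$K, 3L)
  expect_error(select_k(data.frame()), "empty")
})

test_that("gg_cluster solves small instances exactly", {
  r <- gg_cluster(c(1, 2, 50, 51), rep(1, 4), 2)
  expect_equal(r$assignment, c(1L, 1L, 2L, 2L))
  expect_equal(r$means, c(1.5, 50.5))
  r1 <- gg_cluster(c(1, 2, 50, 51), rep(1, 4), 1)
  expect_equal(r1$means, 26.0)
  rn <- gg_cluster(c(1, 2, 50, 51), rep(1, 4), 4)
  expect_equal(rn$means, c(1, 2, 50, 51)) # each QTL its own block
  expect_error(gg_cluster(c(1, 2), c(1, 1), 3), "k must be")
  expect_error(gg_cluster(c(2, 1), c(1, 1), 1), "sorted")
})

test_that("gg_cluster matches exhaustive partition enumeration (n <= 8)", {
  set.seed(13)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    x <- sort(runif(n, 0, 60))
    s <- runif(n, 0.5, 6)
    k <- sample(seq_len(n), 1)
    got <- gg_cluster(x, s, k)
    want <- gg_oracle(x, s, k)
    expect_equal(got$logL, want$logL, tolerance = 1e-9)
    expect_equal(got$assignment, want$assignment)
  }
})

test_that("gg_select chooses among {1,2,3,4,n} by the BIC-like criterion", {
  x <- c(10, 10.5, 60, 61); s <- rep(1, 4)
  sel <- gg_select(x, s)
  # independent recomputation of C(k) from the exhaustive oracle
  cands <- c(1, 2, 3, 4)
  crit <- vapply(cands, function(k)
    -2 * gg_oracle(x, s, k)$logL + 2 * k * log(4), numeric(1))
  expect_equal(sel$k, cands[which.min(crit)])
  expect_equal(sel$k, 2L)
  expect_equal(sel$label, "Model 2")

  expect_equal(gg_select(5, 1)$k, 1L) # n = 1

  # 4 tight clusters far apart: n = 12 on the GG candidate set {1..4, 12}
  x4 <- sort(c(rnorm(3, 10, .1), rnorm(3, 60, .1), rnorm(3, 110, .1),
               rnorm(3, 160, .1)))
  s4 <- rep(1, 12)
  sel4 <- gg_select(x4, s4)
  crit4 <- vapply(c(1, 2, 3, 4, 12), function(k)
    -2 * gg_oracle(x4, s4, k)$logL + 2 * k * log(12), numeric(1))
  expect_equal(sel4$k, c(1L, 2L, 3L, 4L, 12L)[which.min(crit4)])
  expect_equal(sel4$k, 4L)
})

test_that("summarize_mqtl combines members by inverse-variance weighting", {
  m <- summarize_mqtl(make_projected(c(10, 12), c(1, 1)), weight = 0.5)
  expect_equal(m$position, 11)
  expect_equal(m$sigma, sqrt(0.5), tolerance = 1e-6) # 0.7071
  expect_equal(m$ci95_start, 11 - 1.96 * sqrt(0.5), tolerance = 1e-6) # 9.614
  expect_equal(m$ci95_end, 11 + 1.96 * sqrt(0.5), tolerance = 1e-6)  # 12.386

  m2 <- summarize_mqtl(make_projected(c(0, 10), c(1, 3)), weight = 1)
  expect_equal(m2$position, 1.0)   # (0/1 + 10/9)/(1 + 1/9)
  expect_equal(m2$sigma, sqrt(1 / (1 + 1 / 9)), tolerance = 1e-6) # 0.9487

  p1 <- make_projected(42, 2.5)
  m3 <- summarize_mqtl(p1, weight = 1)
  expect_equal(m3$position, 42)
  expect_equal(m3$sigma, 2.5)
})

test_that("summarize_mqtl resolves peak and flanking markers", {
  cons <- make_map("reference", sprintf("RM%d", 1:11), 1L, seq(0, 100, 10))
  m <- summarize_mqtl(make_projected(c(48, 52), c(2, 2)), weight = 1,
                      consensus = cons)
  expect_equal(m$peak_marker, "RM6") # at 50
  expect_equal(m$flank_left, "RM5")  # nearest below ci95_start ~47.2
  expect_equal(m$flank_right, "RM7") # nearest above ci95_end ~52.8
  expect_warning(
    summarize_mqtl(make_projected(50, 2, chromosome = 5L), 1, cons),
    "no consensus markers")
})

test_that("analyze_chromosome dispatches on the nine-QTL rule", {
  set.seed(21)
  # 22 QTL (three components): mixture branch
  big <- simulate_projected_chromosome(seed = 77, chromosome = 3L)$projected
  expect_equal(nrow(big), 22L)
  res <- analyze_chromosome(big, k_max = 6, seed = 1)
  expect_equal(res$decision$branch, "veyrieras")
  expect_true(all(c("AIC", "AICc", "AIC3", "BIC", "AWE") %in%
                    names(res$decision$criteria)))
  expect_equal(sum(res$mqtl$weight), 1, tolerance = 1e-6)

  # 8 QTL: contiguous-cluster branch
  small <- make_projected(c(5, 6, 7, 40, 41, 42, 80, 81),
                          rep(1.5, 8))
  res2 <- analyze_chromosome(small)
  expect_equal(res2$decision$branch, "gerber_goffinet")
  expect_equal(res2$decision$chosen_k, 3L)
  expect_equal(sum(res2$mqtl$weight), 1, tolerance = 1e-9)

  # single QTL degenerates to itself
  one <- make_projected(33, 2)
  res3 <- analyze_chromosome(one)
  expect_equal(nrow(res3$mqtl), 1L)
  expect_equal(res3$mqtl$position, 33)
  expect_equal(res3$mqtl$ci95_end - res3$mqtl$ci95_start, 2 * 1.96 * 2)
})

test_that("members partition the QTL and ids follow MQTL<chr>.<k>", {
  p <- make_projected(c(5, 6, 50, 51, 90), rep(1, 5), chromosome = 7L)
  res <- analyze_chromosome(p)
  members <- unlist(strsplit(res$mqtl$member_qtl, ","))
  expect_setequal(members, p$qtl_id)
  expect_true(all(grepl("^MQTL7\\.[0-9]+$", res$mqtl$mqtl_id)))
  expect_true(all(res$mqtl$ci95_start <= res$mqtl$position &
                    res$mqtl$position <= res$mqtl$ci95_end))
})
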