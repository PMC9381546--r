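# Synthetic multi-study QTL compilations. The generator emulates the
# statistical shape of a published grain-weight QTL survey: 22 studies /
# 114 QTL spread over 12 rice chromosomes (most on chromosome 3, fewest
# on chromosome 12), mapping-population sizes in [39, 353], PVE with
# mean ~10.8% on (0.4%, 60%), about half the LOD scores below 5, and
# observed QTL positions scattered around a small number of true
# meta-QTL with per-QTL variance implied by the 530/(N R2) CI rule.

# Per-chromosome QTL counts and true-MQTL counts of the emulated survey
.DEFAULT_N_QTL  <- c(8L, 14L, 22L, 3L, 14L, 9L, 5L, 12L, 9L, 8L, 6L, 4L)
.DEFAULT_N_MQTL <- c(4L, 4L, 3L, 3L, 4L, 2L, 3L, 4L, 3L, 3L, 4L, 2L)
# Approximate rice consensus-map chromosome lengths (cM)
.DEFAULT_CHROM_LEN <- c(181, 158, 166, 129, 122, 125, 118, 121, 93, 83,
                        117, 110)

#' Simulation configuration for a synthetic QTL compilation
#'
#' Defaults state the emulated survey's conditions: 22 studies, 114 QTL
#' allocated per chromosome as in the survey (chr3: 22, chr12: 4),
#' population sizes spanning [39, 353], R2 ~ Beta(1.2, 5.68) rescaled to
#' (0.004, 0.60) so the mean is 0.108, LOD ~ Lognormal(log 5.1, 0.6) so
#' P(LOD < 5) is about 0.49, and chromosome-3 true meta-QTL at 39.5,
#' 92.82 and 116.66 cM with weights proportional to 0.19/0.33/0.37
#' (renormalized to sum to 1). Other chromosomes get evenly spaced true
#' components with equal weights.
#'
#' @param seed Global integer seed; every draw derives from it.
#' @param n_studies Number of studies (mapping populations).
#' @param n_qtl Integer vector (length 12): QTL per chromosome.
#' @param chrom_length_cM Numeric vector (length 12).
#' @param true_mqtl Optional list (by chromosome) of data.frames with
#'   columns position, weight; NULL components get the default layout.
#' @param pop_size_range Integer c(min, max) of population sizes.
#' @param r2_shape Beta shape parameters c(a, b) of the PVE distribution.
#' @param r2_range Range the Beta draw is rescaled to.
#' @param lod_meanlog,lod_sdlog Lognormal LOD parameters.
#' @param anchor_density Reference markers per cM.
#' @param map_marker_frac Fraction of reference markers each study map
#'   retains (per chromosome, minimum 2).
#' @param map_jitter SD (cM) of study-map marker-position noise.
#' @param bp_per_cM Physical scale used for the marker bp table.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_studies = 22L,
                       n_qtl = .DEFAULT_N_QTL,
                       chrom_length_cM = .DEFAULT_CHROM_LEN,
                       true_mqtl = NULL,
                       pop_size_range = c(39L, 353L),
                       r2_shape = c(1.2, 5.68),
                       r2_range = c(0.004, 0.60),
                       lod_meanlog = log(5.1), lod_sdlog = 0.6,
                       anchor_density = 1,
                       map_marker_frac = 0.6,
                       map_jitter = 0.1,
                       bp_per_cM = 270000) {
  stopifnot(length(n_qtl) == 12L, length(chrom_length_cM) == 12L,
            all(n_qtl >= 1L), anchor_density > 0)
  tm <- vector("list", 12L)
  for (chrom in 1:12) {
    user <- if (!is.null(true_mqtl) && length(true_mqtl) >= chrom)
      true_mqtl[[chrom]] else NULL
    if (is.null(user)) {
      if (chrom == 3L) {
        w <- c(0.19, 0.33, 0.37)
        tm[[chrom]] <- data.frame(position = c(39.5, 92.82, 116.66),
                                  weight = w / sum(w))
      } else {
        K <- .DEFAULT_N_MQTL[chrom]
        L <- chrom_length_cM[chrom]
        tm[[chrom]] <- data.frame(position = L * seq_len(K) / (K + 1),
                                  weight = rep(1 / K, K))
      }
    } else {
      stopifnot(abs(sum(user$weight) - 1) < 1e-9)
      tm[[chrom]] <- user[, c("position", "weight")]
    }
  }
  structure(list(seed = as.integer(seed), n_studies = as.integer(n_studies),
                 n_qtl = as.integer(n_qtl),
                 chrom_length_cM = chrom_length_cM, true_mqtl = tm,
                 pop_size_range = pop_size_range, r2_shape = r2_shape,
                 r2_range = r2_range, lod_meanlog = lod_meanlog,
                 lod_sdlog = lod_sdlog, anchor_density = anchor_density,
                 map_marker_frac = map_marker_frac,
                 map_jitter = map_jitter, bp_per_cM = bp_per_cM),
            class = "sim_config")
}

# Per-study population sizes, deterministic in cfg$seed. The first two
# studies pin the stated extremes (39 and 353).
study_pop_sizes <- function(cfg) {
  old <- withr_seed(cfg$seed + 7777L)
  on.exit(restore_seed(old))
  lo <- cfg$pop_size_range[1]; hi <- cfg$pop_size_range[2]
  N <- as.integer(round(stats::runif(cfg$n_studies, lo, hi)))
  if (cfg$n_studies >= 2L) { N[1L] <- as.integer(lo); N[2L] <- as.integer(hi) }
  N
}

# scaled-Beta PVE draw
.draw_r2 <- function(cfg, n) {
  cfg$r2_range[1] + diff(cfg$r2_range) *
    stats::rbeta(n, cfg$r2_shape[1], cfg$r2_shape[2])
}

#' Simulate the QTL reported on one chromosome
#'
#' Each QTL draws its true component k from the chromosome's true-MQTL
#' weights, takes its study (hence population size N) by round-robin
#' assignment, draws R2 and LOD, computes
#' sigma = (530/(N R2))/3.92, and observes position ~ Normal(mu_k,
#' sigma^2) truncated to [0, chrom_length] by rejection. The reported CI
#' is position +/- 1.96 sigma, clamped to the chromosome. Flanking
#' markers are left for map-aware writers. Deterministic given
#' (cfg$seed, chromosome).
#'
#' @param cfg A \code{"sim_config"}.
#' @param chromosome Chromosome index 1..12.
#' @return list(qtl = \code{"qtl_table"} rows, truth = list(means,
#'   weights, component (true assignment per QTL))).
#' @export
simulate_chromosome <- function(cfg, chromosome) {
  stopifnot(inherits(cfg, "sim_config"), chromosome %in% 1:12)
  n <- cfg$n_qtl[chromosome]
  if (n < 1L) stop("n_qtl must be >= 1")
  L <- cfg$chrom_length_cM[chromosome]
  truth <- cfg$true_mqtl[[chromosome]]
  study_N <- study_pop_sizes(cfg)
  old <- withr_seed(cfg$seed * 1000L + chromosome)
  on.exit(restore_seed(old))

  comp <- sample.int(nrow(truth), n, replace = TRUE, prob = truth$weight)
  # studies are assigned round-robin with a global offset so every study
  # contributes QTL (the emulated survey has 3-22 QTL per study)
  offset <- if (chromosome > 1L) sum(cfg$n_qtl[seq_len(chromosome - 1L)])
            else 0L
  study <- ((offset + seq_len(n) - 1L) %% cfg$n_studies) + 1L
  N <- study_N[study]
  r2 <- .draw_r2(cfg, n)
  sigma <- darvasi_soller_ci(N, r2) / CI_SIGMA_FACTOR
  mu <- truth$position[comp]
  pos <- numeric(n)
  for (i in seq_len(n)) { # rejection-sample the truncated normal
    repeat {
      p <- stats::rnorm(1, mu[i], sigma[i])
      if (p >= 0 && p <= L) { pos[i] <- p; break }
    }
  }
  lod <- stats::rlnorm(n, cfg$lod_meanlog, cfg$lod_sdlog)
  qtl <- data.frame(study_id = sprintf("S%02d", study),
                    qtl_id = sprintf("qGW%d.%02d", chromosome, seq_len(n)),
                    chromosome = as.integer(chromosome),
                    position = pos, lod = lod, r2 = r2,
                    pop_size = as.integer(N),
                    ci_start = pmax(0, pos - 1.96 * sigma),
                    ci_end = pmin(L, pos + 1.96 * sigma),
                    flank_left = NA_character_,
                    flank_right = NA_character_,
                    stringsAsFactors = FALSE)
  list(qtl = as_qtl_table(qtl),
       truth = list(means = truth$position, weights = truth$weight,
                    component = comp))
}

#' Simulate the reference map and per-study maps
#'
#' Reference markers are placed on a uniform grid (anchor_density per
#' cM). Each study map keeps a seeded random subset of the reference
#' markers per chromosome (at least 2, so projection anchors always
#' exist) and perturbs their positions with Gaussian noise of SD
#' map_jitter; jittered positions are re-sorted so marker order is
#' preserved.
#'
#' @param cfg A \code{"sim_config"}.
#' @return list(reference = \code{"genetic_map"}, studies =
#'   multi-map \code{"genetic_map"}).
#' @export
simulate_study_maps <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ref <- do.call(rbind, lapply(1:12, function(chrom) {
    pos <- seq(0, cfg$chrom_length_cM[chrom], by = 1 / cfg$anchor_density)
    data.frame(map_id = "reference",
               marker = sprintf("RM%d_%03d", chrom, seq_along(pos)),
               chromosome = chrom, position_cM = pos,
               stringsAsFactors = FALSE)
  }))
  old <- withr_seed(cfg$seed + 1234L)
  on.exit(restore_seed(old))
  studies <- list()
  for (sidx in seq_len(cfg$n_studies)) {
    sid <- sprintf("S%02d", sidx)
    for (chrom in 1:12) {
      rc <- ref[ref$chromosome == chrom, , drop = FALSE]
      keep <- max(2L, round(cfg$map_marker_frac * nrow(rc)))
      idx <- sort(sample.int(nrow(rc), keep))
      pos <- rc$position_cM[idx] + stats::rnorm(keep, 0, cfg$map_jitter)
      pos <- sort(pos) # preserve marker order under jitter
      studies[[length(studies) + 1L]] <-
        data.frame(map_id = sid, marker = rc$marker[idx],
                   chromosome = chrom, position_cM = pos,
                   stringsAsFactors = FALSE)
    }
  }
  list(reference = as_genetic_map(ref),
       studies = as_genetic_map(do.call(rbind, studies)))
}

# The fixed extreme-phenotype validation panel of the stated world:
# seven low (< 12.5 g) and seven high (> 25 g) grain-weight genotypes,
# extremes 9.50 g and 37.27 g, scored at a perfectly class-specific SSR
# with amplicons of 100 bp (low) and 85 bp (high).
simulate_panel <- function(cfg) {
  data.frame(
    genotype_id = c("AdamChini", sprintf("LowG%d", 2:7),
                    sprintf("HighG%d", 1:6), "NiiawHawm"),
    tgw = c(9.50, 10.21, 10.84, 11.32, 11.76, 12.05, 12.31,
            25.84, 27.52, 29.13, 31.05, 33.24, 35.02, 37.27),
    allele = c(rep("100bp", 7), rep("85bp", 7)),
    stringsAsFactors = FALSE)
}

# Toy genes tiled inside each true-MQTL physical window so annotation
# queries have known content: 10 genes of 3 kb every 8 kb around mu.
simulate_genes <- function(cfg) {
  rows <- list()
  for (chrom in 1:12) {
    truth <- cfg$true_mqtl[[chrom]]
    for (k in seq_len(nrow(truth))) {
      center <- round(truth$position[k] * cfg$bp_per_cM)
      starts <- center - 40000 + 8000 * (0:9)
      for (g in seq_along(starts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = sprintf("LOC_Os%02dg%02d%02d0", chrom, k, g),
          chromosome = chrom, start_bp = starts[g],
          end_bp = starts[g] + 3000L,
          strand = if (g %% 2 == 0) "-" else "+",
          description = sprintf("synthetic gene %d of true MQTL %d.%d",
                                g, chrom, k),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Simulate a complete analysis bundle in memory
#'
#' @param cfg A \code{"sim_config"}.
#' @return list(qtl, truth (per chromosome), reference, studies,
#'   markers_bp, genes, panel, config).
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  per_chrom <- lapply(1:12, function(chrom) simulate_chromosome(cfg, chrom))
  qtl <- do.call(rbind, lapply(per_chrom, `[[`, "qtl"))
  qtl <- as_qtl_table(qtl)
  maps <- simulate_study_maps(cfg)
  markers_bp <- data.frame(marker = maps$reference$marker,
                           chromosome = maps$reference$chromosome,
                           bp = as.integer(round(
                             maps$reference$position_cM * cfg$bp_per_cM) + 1L),
                           stringsAsFactors = FALSE)
  class(markers_bp) <- c("marker_table", "data.frame")
  list(qtl = qtl,
       truth = lapply(per_chrom, `[[`, "truth"),
       reference = maps$reference, studies = maps$studies,
       markers_bp = markers_bp, genes = simulate_genes(cfg),
       panel = simulate_panel(cfg), config = cfg)
}

#' Write a simulated bundle to disk as plain-text files
#'
#' Emits qtl.tsv, maps.tsv, ref_map.tsv, markers_bp.tsv, genes.gff3,
#' panel.tsv and truth.json under \code{dir} — a complete end-to-end
#' fixture parseable by the package's readers.
#'
#' @param cfg A \code{"sim_config"}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_bundle <- function(cfg = sim_config(), dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  b <- simulate_bundle(cfg)
  paths <- c(qtl = file.path(dir, "qtl.tsv"),
             maps = file.path(dir, "maps.tsv"),
             ref_map = file.path(dir, "ref_map.tsv"),
             markers_bp = file.path(dir, "markers_bp.tsv"),
             genes = file.path(dir, "genes.gff3"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth.json"))
  write_qtl_table(b$qtl, paths["qtl"])
  utils::write.table(b$studies, paths["maps"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(b$reference, paths["ref_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(b$markers_bp, paths["markers_bp"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gff <- c("##gff-version 3",
           sprintf("Chr%d\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Note=%s",
                   b$genes$chromosome, b$genes$start_bp, b$genes$end_bp,
                   b$genes$strand, b$genes$locus_id,
                   gsub("[;=\t]", " ", b$genes$description)))
  writeLines(gff, paths["genes"])
  utils::write.table(b$panel, paths["panel"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(seed = cfg$seed,
                chromosomes = lapply(1:12, function(chrom) list(
                  chromosome = chrom,
                  means = b$truth[[chrom]]$means,
                  weights = b$truth[[chrom]]$weights,
                  component = b$truth[[chrom]]$component)))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
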