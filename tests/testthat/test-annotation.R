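toy_marker_table <- function() {
  structure(data.frame(marker = c("RM1", "RM2", "RM3", "RMx"),
                       chromosome = c(3L, 3L, 3L, 5L),
                       bp = c(1000000L, 1490000L, 2000000L, 100L),
                       stringsAsFactors = FALSE),
            class = c("marker_table", "data.frame"))
}

toy_genes <- function() {
  structure(data.frame(
    locus_id = c("g1", "g2", "g3", "g4"),
    chromosome = c(3L, 3L, 3L, 4L),
    start_bp = c(1100000L, 1400000L, 1490000L, 1100000L),
    end_bp   = c(1200000L, 1450000L, 1600000L, 1200000L),
    strand = "+", description = "", stringsAsFactors = FALSE),
    class = c("gene_table", "data.frame"))
}

test_that("physical_interval is symmetric and validates markers", {
  t <- toy_marker_table()
  iv <- physical_interval("RM1", "RM2", t)
  expect_equal(iv$start_bp, 1000000L)
  expect_equal(iv$end_bp, 1490000L)
  expect_equal(iv$mb, 0.49)
  iv2 <- physical_interval("RM2", "RM1", t) # reversed arguments
  expect_equal(iv2$start_bp, iv$start_bp)
  expect_equal(iv2$end_bp, iv$end_bp)
  expect_error(physical_interval("RM1", "NOPE", t), "NOPE")
  expect_error(physical_interval("RM1", "RMx", t), "different chromosomes")
})

test_that("genes_in_interval uses closed-interval overlap", {
  g <- toy_genes()
  iv <- physical_interval("RM1", "RM2", toy_marker_table())
  # spans g1 and g2 fully, touches g3 at exactly one bp (1490000)
  hits <- genes_in_interval(g, iv)
  expect_equal(hits$locus_id, c("g1", "g2", "g3"))
  # interval before every gene: empty
  far <- structure(list(chromosome = 3L, start_bp = 1L, end_bp = 10L,
                        mb = 9e-6), class = "physical_interval")
  expect_equal(nrow(genes_in_interval(g, far)), 0L)
  # gene exactly equal to the interval: included
  eq <- structure(list(chromosome = 3L, start_bp = 1100000L,
                       end_bp = 1200000L, mb = 0.1),
                  class = "physical_interval")
  expect_true("g1" %in% genes_in_interval(g, eq)$locus_id)
  # whole-chromosome interval returns every chr-3 gene
  whole <- structure(list(chromosome = 3L, start_bp = 1L,
                          end_bp = 50000000L, mb = 50),
                     class = "physical_interval")
  expect_equal(genes_in_interval(g, whole)$locus_id, c("g1", "g2", "g3"))
})

test_that("class_distinguishing_variants finds merged indels", {
  aln <- c(low1 = "AC------GT", low2 = "AC------GT",
           high1 = "ACTCCGCCGT", high2 = "ACTCCGCCGT")
  cls <- c(low1 = "low", low2 = "low", high1 = "high", high2 = "high")
  v <- class_distinguishing_variants(aln, cls)
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "indel")
  expect_equal(v$column, 2L) # 0-based
  expect_equal(v$span, 6L)
  expect_equal(v$high_allele, "TCCGCC")
  expect_equal(v$low_allele, "------")
})

test_that("class_distinguishing_variants handles substitutions and nulls", {
  aln <- c(a = "AAGA", b = "AAGA", c = "AGGA", d = "AGGA")
  cls <- c(a = "low", b = "low", c = "high", d = "high")
  v <- class_distinguishing_variants(aln, cls)
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "substitution")
  expect_equal(v$column, 1L)
  expect_equal(v$low_allele, "A")
  expect_equal(v$high_allele, "G")
  # identical alignments across classes -> no variants
  empty <- class_distinguishing_variants(
    c(a = "ACGT", b = "ACGT", c = "ACGT"),
    c(a = "low", b = "low", c = "high"))
  expect_equal(nrow(empty), 0L)
  expect_error(class_distinguishing_variants(
    c(a = "ACG", b = "ACGT"), c(a = "low", b = "high")), "unequal")
  expect_error(class_distinguishing_variants(
    c(a = "ACGT", b = "ACGT"), c(a = "low", b = "low")), "class")
})

test_that("variant calls are order-invariant and perfectly class-separating", {
  set.seed(31)
  bases <- c("A", "C", "G", "T", "-")
  for (rep in 1:10) {
    ncol_aln <- 30
    low_cons <- sample(bases, ncol_aln, replace = TRUE)
    high_cons <- low_cons
    flip <- sample(ncol_aln, 5)
    high_cons[flip] <- sample(setdiff(bases, "N"), 5, replace = TRUE)
    seqs <- c(l1 = paste(low_cons, collapse = ""),
              l2 = paste(low_cons, collapse = ""),
              h1 = paste(high_cons, collapse = ""),
              h2 = paste(high_cons, collapse = ""))
    cls <- c(l1 = "low", l2 = "low", h1 = "high", h2 = "high")
    v1 <- class_distinguishing_variants(seqs, cls)
    v2 <- class_distinguishing_variants(seqs[c(3, 1, 4, 2)], cls)
    expect_identical(v1, v2)
    # self-check: every reported span separates the classes perfectly
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
    for (i in seq_len(nrow(v1))) {
      cols <- (v1$column[i] + 1L):(v1$column[i] + v1$span[i])
      low_rows <- m[cls[rownames(m)] == "low", cols, drop = FALSE]
      high_rows <- m[cls[rownames(m)] == "high", cols, drop = FALSE]
      expect_true(all(apply(low_rows, 2, function(z) length(unique(z)) == 1)))
      expect_true(all(apply(high_rows, 2, function(z) length(unique(z)) == 1)))
      expect_false(identical(paste(low_rows[1, ], collapse = ""),
                             paste(high_rows[1, ], collapse = "")))
      expect_equal(paste(low_rows[1, ], collapse = ""), v1$low_allele[i])
      expect_equal(paste(high_rows[1, ], collapse = ""), v1$high_allele[i])
    }
  }
})

test_that("read_alignment reads FASTA and rejects ragged alignments", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "AC-GT", ">s2", "ACGGT"), f)
  m <- read_alignment(f)
  expect_equal(dim(m), c(2L, 5L))
  expect_equal(rownames(m), c("s1", "s2"))
  writeLines(c(">s1", "ACGT", ">s2", "ACGGT"), f)
  expect_error(read_alignment(f), "unequal")
})

test_that("annotate_mqtl attaches intervals and gene counts", {
  mqtl <- data.frame(mqtl_id = c("MQTL3.1", "MQTL3.2"), chromosome = 3L,
                     position = c(5, 8), sigma = 1, ci95_start = c(3, 7),
                     ci95_end = c(7, 9), weight = 0.5, n_members = 2L,
                     member_qtl = "a,b", peak_marker = "RM2",
                     flank_left = c("RM1", NA),
                     flank_right = c("RM2", "RM3"),
                     stringsAsFactors = FALSE)
  ann <- annotate_mqtl(mqtl, toy_marker_table(), toy_genes())
  expect_equal(ann$mqtl$interval_mb[1], 0.49)
  expect_equal(ann$mqtl$n_genes[1], 3L)
  expect_true(is.na(ann$mqtl$interval_mb[2])) # missing flank -> NA
  expect_equal(sort(unique(ann$genes$mqtl_id)), "MQTL3.1")
})
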