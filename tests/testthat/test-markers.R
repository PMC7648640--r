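# Three-type toy with a planted expression hierarchy: computations are
# re-derived in-test from the definitions (TMM log2 CPM, fold change vs the
# highest other type) as an independent oracle.
marker_toy <- function() {
  set.seed(99)
  base <- c(40, 40, 40, 40, 5, 30)
  mk <- function(scale) sapply(seq_len(25), function(i) rpois(6, base * scale))
  counts <- cbind(mk(c(8, 1, 1, 1, 1, 1)),      # g1 high in A
                  mk(c(1, 6, 1, 1, 1, 1)),      # g2 high in B
                  mk(c(1, 1, 4, 1, 0.1, 1)))    # g3 high in C, g5 low in C
  rownames(counts) <- sprintf("g%d", 1:6)
  colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  cell_expression_matrix(counts, rep(c("A", "B", "C"), each = 25),
                         rep("d1", 75))
}

oracle_logfc <- function(x) {
  f <- tmm_factors(x$counts)
  eff <- colSums(x$counts) * f
  lcpm <- log2(sweep(x$counts, 2, eff, "/") * 1e6 + 1)
  types <- sort(unique(x$cell_type))
  ml <- sapply(types, function(k) rowMeans(lcpm[, x$cell_type == k, drop = FALSE]))
  sapply(types, function(k) {
    other <- apply(ml[, setdiff(types, k), drop = FALSE], 1, max)
    ml[, k] - other
  })
}

test_that("logFC against the second-highest type matches direct recomputation", {
  x <- marker_toy()
  st <- rank_genes(x, fc_threshold = 2)
  want <- oracle_logfc(x)
  for (k in c("A", "B", "C")) {
    got <- st[st$cell_type == k, ]
    expect_equal(got$logFC, unname(want[got$gene, k]), tolerance = 1e-12)
  }
  expect_true(all(st$p_adj >= 0 & st$p_adj <= 1))
})

test_that("a gene expressed in a single type is that type's positive marker", {
  x <- marker_toy()
  st <- rank_genes(x, fc_threshold = 2)
  ms <- select_markers(st, "all")
  expect_true("g1" %in% ms$markers[["A"]])
  expect_true("g2" %in% ms$markers[["B"]])
  expect_true("g3" %in% ms$markers[["C"]])
  ## g5 is depleted in C and high elsewhere: a negative marker of C
  tb <- ms$table
  expect_equal(tb$cell_type[tb$gene == "g5"], "C")
  expect_lt(tb$logFC[tb$gene == "g5"], 0)
  ## pos_fc drops exactly the negative-fold-change markers
  pos <- select_markers(st, "pos_fc")
  expect_false("g5" %in% unlist(pos$markers))
  expect_true(all(pos$table$logFC > 0))
})

test_that("the 30% prevalence filter removes silent genes", {
  x <- marker_toy()
  ## a gene with a positive count in only 2 of 25 cells of its best group
  counts <- rbind(x$counts, g7 = 0)
  counts["g7", c(1, 2)] <- 5
  x2 <- cell_expression_matrix(counts, x$cell_type, x$donor)
  st <- rank_genes(x2, fc_threshold = 2)
  expect_false("g7" %in% st$gene)
})

test_that("subsetting strategies honor their counting rules", {
  pp <- pancreas_pipeline()
  st <- pp$stats
  r5 <- select_markers(st, "random5", seed = 4)
  expect_true(all(lengths(r5$markers) == 5))
  n2 <- select_markers(st, "top_n2")
  expect_true(all(lengths(n2$markers) <= 2))
  all_ms <- pp$markers
  top <- select_markers(st, "top_50p_logFC")
  bot <- select_markers(st, "bottom_50p_logFC")
  for (k in names(all_ms$markers)) {
    n <- length(all_ms$markers[[k]])
    expect_length(top$markers[[k]], ceiling(n / 2))
    expect_length(bot$markers[[k]], floor(n / 2))
    expect_setequal(c(top$markers[[k]], bot$markers[[k]]), all_ms$markers[[k]])
    expect_lte(length(intersect(top$markers[[k]], bot$markers[[k]])), 1)
  }
  ta <- select_markers(st, "top_50p_AveExpr")
  ba <- select_markers(st, "bottom_50p_AveExpr")
  for (k in names(all_ms$markers))
    expect_setequal(c(ta$markers[[k]], ba$markers[[k]]), all_ms$markers[[k]])
})

test_that("an odd five-marker type keeps three in the top half", {
  x <- marker_toy()
  st <- rank_genes(x, fc_threshold = 2)
  ## restrict stats to 5 markers of one synthetic type by filtering the table
  pp <- pancreas_pipeline()
  st2 <- pp$stats
  ms <- select_markers(st2, "all")
  k <- names(ms$markers)[1]
  five <- ms$markers[[k]][1:5]
  st3 <- st2[st2$gene %in% five | st2$cell_type != k, ]
  ## keep attributes
  for (a in c("mean_log", "fc_threshold", "alpha", "min_expr_frac"))
    attr(st3, a) <- attr(st2, a)
  class(st3) <- class(st2)
  top <- select_markers(st3, "top_50p_logFC")
  expect_length(top$markers[[k]], 3)
})

test_that("random5 is seed-reproducible and seed-sensitive", {
  pp <- pancreas_pipeline()
  a <- select_markers(pp$stats, "random5", seed = 1)
  b <- select_markers(pp$stats, "random5", seed = 1)
  c <- select_markers(pp$stats, "random5", seed = 2)
  expect_identical(a$markers, b$markers)
  expect_false(identical(a$markers, c$markers))
})

test_that("marker recall on synthetic data reaches 90% at fold change 4", {
  pp <- pancreas_pipeline()
  truth <- attr(pp$x, "marker_truth")
  ms <- pp$markers
  recall <- mean(unlist(lapply(names(truth), function(k)
    truth[[k]] %in% ms$markers[[k]])))
  expect_gte(recall, 0.9)
})

test_that("marker specificity counts secondary-type qualification", {
  ## orthogonal marker blocks on a stable background (filler genes keep the
  ## CPM scale comparable across types): no marker qualifies twice
  set.seed(7)
  mk_type <- function(k) {
    mu <- c(rep(20, 30), rep(10, 9))        # 30 fillers + 9 block genes
    mu[30 + (k - 1) * 3 + 1:3] <- 200
    sapply(1:60, function(i) rpois(39, mu))
  }
  counts <- do.call(cbind, lapply(1:3, mk_type))
  dimnames(counts) <- list(c(sprintf("fill%02d", 1:30), sprintf("g%d", 1:9)),
                           sprintf("c%03d", 1:180))
  x <- cell_expression_matrix(counts, rep(c("A", "B", "C"), each = 60),
                              rep("d1", 180))
  st <- rank_genes(x, fc_threshold = 2)
  ms <- select_markers(st, "all")
  expect_setequal(unlist(ms$markers), sprintf("g%d", 1:9))
  expect_equal(marker_specificity(st, ms), 0)

  ## a strict expression gradient A >> B >> C makes the gene a marker of A
  ## and a secondary marker of B: exactly 1 marker is non-specific
  set.seed(8)
  counts2 <- rbind(counts, g10 = 0)
  counts2["g10", ] <- rpois(180, rep(c(200, 50, 10), each = 60))
  x2 <- cell_expression_matrix(counts2, x$cell_type, x$donor)
  st2 <- rank_genes(x2, fc_threshold = 2)
  ms2 <- select_markers(st2, "all")
  expect_true("g10" %in% unlist(ms2$markers))
  n_markers <- nrow(ms2$table)
  expect_equal(marker_specificity(st2, ms2), 100 * 1 / n_markers)
})

test_that("raising the secondary threshold never raises non-specificity", {
  pp <- pancreas_pipeline()
  vals <- vapply(c(1.5, 2, 3, 4), function(thr)
    marker_specificity(pp$stats, pp$markers, fc_threshold = thr), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("empty base markers under a subsetting strategy warn", {
  x <- marker_toy()
  st <- rank_genes(x, fc_threshold = 2)
  w <- capture_warnings(select_markers(st, "all", fc_threshold = 1e6))
  expect_true(any(grepl("no base markers", w)))
})

test_that("marker sets serialize as TSV", {
  pp <- pancreas_pipeline()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_set(pp$markers, path)
  tab <- read.delim(path)
  expect_named(tab, c("cell_type", "gene", "logFC", "AveExpr", "p_adj", "strategy"))
  expect_equal(nrow(tab), nrow(pp$markers$table))
})
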