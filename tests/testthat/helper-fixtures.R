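# Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Tiny labelled count matrix with explicit values for hand-checked oracles.
toy_cem <- function(counts, types = NULL, donors = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  types <- types %||% rep("A", ncol(counts))
  donors <- donors %||% rep("d1", ncol(counts))
  cell_expression_matrix(counts, types, donors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The full pancreas-like pipeline used by several suites (seed 7 is the
# instance pinned by the acceptance criteria).
pancreas_pipeline <- function() {
  cached("pancreas7", {
    x <- make_benchmark_fixture("pancreas_like", seed = 7)
    qc <- qc_filter(x)
    sp <- split_train_test(qc$data, seed = 72)
    C <- build_reference(sp$train)
    stats <- rank_genes(sp$train, fc_threshold = 2)
    markers <- select_markers(stats, "all")
    mix <- generate_mixtures(sp$test,
                             composition_rules(n_mixtures = 1000, seed = 73))
    list(x = x, qc = qc, train = sp$train, test = sp$test, C = C,
         stats = stats, markers = markers, mix = mix)
  })
}

# A small well-conditioned signature + exact grid mixtures for solver tests.
solver_fixture <- function(seed = 42, genes = 200, k = 5) {
  set.seed(seed)
  C <- matrix(stats::rexp(genes * k, 1 / 50), genes, k,
              dimnames = list(sprintf("g%03d", seq_len(genes)), LETTERS[seq_len(k)]))
  p <- c(0.25, 0.4, 0.05, 0.2, 0.1)[seq_len(k)]
  p <- p / sum(p)
  list(C = C, p = p, t = drop(C %*% p))
}
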