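# Independent oracles used across the suite. Each reimplements the target
# quantity from its definition, on a code path separate from the package.

# ---- adjusted Rand index (external implementation) --------------------------
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# ---- Benjamini-Hochberg step-up, by definition ------------------------------
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- Inf
  for (i in rev(seq_len(n))) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# ---- hypergeometric upper tail, by summation --------------------------------
hyper_tail_oracle <- function(overlap, module_size, set_size, universe_size) {
  ks <- overlap:min(module_size, set_size)
  sum(stats::dhyper(ks, set_size, universe_size - set_size, module_size))
}

# ---- weighted-KS running sum, full walk -------------------------------------
es_oracle <- function(weights, hit) {
  # weights in rank order (nonnegative), hit logical
  N <- length(weights)
  k <- sum(hit)
  sumw <- sum(weights[hit])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (sumw > 0) weights[i] / sumw else 1 / k
    } else {
      run <- run - 1 / (N - k)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# ---- TMM by the canonical trim-and-weight recipe ----------------------------
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    o <- counts[, j] / lib[j]
    r <- counts[, ref] / lib[ref]
    use <- o > 0 & r > 0
    o <- o[use]; r <- r[use]
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    v <- (lib[j] - counts[use, j]) / (lib[j] * counts[use, j]) +
      (lib[ref] - counts[use, ref]) / (lib[ref] * counts[use, ref])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    if (!is.finite(f)) 1 else f
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# ---- planarity / greedy PMFG via networkx (independent algorithm) -----------
nx_oracle_script <- function() {
  path <- file.path(tempdir(), "nx_pmfg_oracle.py")
  if (!file.exists(path)) {
    writeLines(c(
      "import sys, json",
      "import networkx as nx",
      "data = json.load(open(sys.argv[1]))",
      "out = []",
      "for fx in data:",
      "    n = fx['n']; edges = fx['edges']",
      "    if fx['mode'] == 'planar':",
      "        g = nx.Graph([tuple(e) for e in edges])",
      "        g.add_nodes_from(range(1, n + 1))",
      "        out.append(bool(nx.check_planarity(g)[0]))",
      "        continue",
      "    acc = []",
      "    keep = []",
      "    cap = 3 * n - 6 if n >= 3 else max(n - 1, 0)",
      "    for e in edges:",
      "        if len(acc) >= cap:",
      "            keep.append(False); continue",
      "        g = nx.Graph(acc + [tuple(e)])",
      "        g.add_nodes_from(range(1, n + 1))",
      "        ok = bool(nx.check_planarity(g)[0])",
      "        keep.append(ok)",
      "        if ok: acc.append(tuple(e))",
      "    out.append(keep)",
      "json.dump(out, open(sys.argv[2], 'w'))"
    ), path)
  }
  path
}

# fixtures: list of list(n = <int>, edges = <2-col matrix>, mode = "planar"|"pmfg")
nx_oracle <- function(fixtures) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  payload <- lapply(fixtures, function(fx) {
    list(n = fx$n, mode = fx$mode,
         edges = lapply(seq_len(nrow(fx$edges)), function(i) as.integer(fx$edges[i, ])))
  })
  jsonlite::write_json(payload, fin, auto_unbox = TRUE)
  status <- system2("python", c(nx_oracle_script(), fin, fout))
  stopifnot(status == 0)
  jsonlite::read_json(fout, simplifyVector = TRUE)
}

nx_is_planar <- function(edges, n) {
  nx_oracle(list(list(n = n, edges = edges, mode = "planar")))[[1]]
}

# ---- small shared fixtures --------------------------------------------------
small_bulk <- function(seed = 5, n_samples = 40) {
  genes <- sprintf("g%04d", 1:300)
  sng <- gen_sng_annotation(genes, 60, seed = seed)
  spec <- bulk_cohort_spec(n_tissues = 3, n_genes = 300,
                           n_samples_per_tissue = n_samples,
                           sng_genes = head(sng$gene, 30), seed = seed)
  list(spec = spec, sng = sng, cohort = gen_bulk_cohort(spec))
}

random_ranked_edges <- function(n, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  pairs[order(-runif(nrow(pairs))), , drop = FALSE]
}
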