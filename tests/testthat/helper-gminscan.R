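# Shared oracles and generators for the test suite. Everything here is
# deliberately naive/independent of the package's computational paths.

# explicit double-loop Hamming / p-distance, the reference for all
# distance machinery
naive_distance <- function(a, b, mode = "count") {
  ok <- !is.na(a) & !is.na(b)
  d <- 0L
  for (j in which(ok)) if (a[j] != b[j]) d <- d + 1L
  if (mode == "count") d else d / sum(ok)
}

# brute-force window summary by enumerating every pair
naive_summary <- function(mat, pop, mode = "count") {
  enc <- function(x) ifelse(x %in% c("N", "-", "?"), NA, x)
  m <- apply(mat, c(1, 2), enc)
  i1 <- which(pop == 1); i2 <- which(pop == 2)
  between <- c()
  for (a in i1) for (b in i2)
    between <- c(between, naive_distance(m[a, ], m[b, ], mode))
  within <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    v <- c()
    for (x in seq_along(idx)) for (y in seq_along(idx))
      if (x < y) v <- c(v, naive_distance(m[idx[x], ], m[idx[y], ], mode))
    mean(v)
  }
  list(min_dxy = min(between), mean_dxy = mean(between),
       mean_dxx = within(i1), mean_dyy = within(i2))
}

# random binary window with optional missingness, as character states
random_window_mat <- function(n1, n2, S, p_missing = 0) {
  m <- matrix(sample(c("0", "1"), (n1 + n2) * S, replace = TRUE),
              nrow = n1 + n2)
  if (p_missing > 0) {
    miss <- matrix(runif(length(m)) < p_missing, nrow = nrow(m))
    m[miss] <- "N"
  }
  rownames(m) <- paste0("s", seq_len(n1 + n2))
  m
}

# binary sequences realizing a hand-specified additive tree: each edge
# contributes `len` private columns to the clade below it
additive_tree_mat <- function(edges, taxa) {
  cols <- list()
  for (e in edges) {
    for (k in seq_len(e$len)) {
      col <- setNames(rep(0L, length(taxa)), taxa)
      col[e$clade] <- 1L
      cols[[length(cols) + 1]] <- col
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  m
}

# independent sample-path oracle for the number of ancestral lineages of
# one population at a given internal time (pure-death chain, pair
# coalescence rate 2; no recombination)
lineage_count_at <- function(n, t_internal, reps) {
  vapply(seq_len(reps), function(i) {
    k <- n; t <- 0
    while (k > 1) {
      t <- t + rexp(1, rate = k * (k - 1))
      if (t > t_internal) break
      k <- k - 1L
    }
    k
  }, numeric(1))
}

# draws of segregating-site counts and pairwise diversity from msprime,
# the established coalescent engine used as a cross-validation oracle
msprime_s_pi <- function(n, theta, reps, seed) {
  script <- sprintf('
import msprime, json, sys
S = []; P = []
reps = msprime.sim_ancestry(samples=%d, ploidy=1, population_size=1,
                            sequence_length=1, discrete_genome=False,
                            num_replicates=%d, random_seed=%d)
i = 0
for ts in reps:
    mts = msprime.sim_mutations(ts, rate=%.17g, discrete_genome=False,
                                random_seed=%d + i)
    S.append(mts.num_sites)
    P.append(float(mts.diversity(span_normalise=False)))
    i += 1
json.dump({"S": S, "pi": P}, sys.stdout)
', n, reps, seed, theta / 2, seed + 1)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}
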