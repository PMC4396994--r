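# Two-population coalescent simulator with an instantaneous migration
# pulse (secondary-contact model).
#
# Model, backward in time: two populations of size N that merge into their
# ancestor at tau_d (units of N generations). At tau_m <= tau_d, every
# lineage residing in population 1 independently switches to population 2
# with probability lambda — the backward view of a burst of gene flow from
# population 2 into population 1 going forward in time; with k resident
# lineages the number moved is binomial with expectation k*lambda.
# Recombination follows Hudson-style ancestral-recombination-graph
# semantics over a continuous [0,1) window at population rate rho = 4Nc;
# infinite-sites mutations accrue at population rate theta = 4Nmu. A
# window is flagged "migrant" iff at least one lineage (all of which carry
# ancestral material) moved at the pulse.

.EVENT_CEILING <- 1e7

#' Demographic parameters of the secondary-contact model
#'
#' @param theta population mutation rate 4N*mu per window, > 0.
#' @param rho population crossing-over rate 4N*c per window, >= 0.
#' @param tau_d divergence time, in units of N generations, >= 0.
#' @param tau_m pulse (migration) time, in units of N generations;
#'   \code{0 <= tau_m <= tau_d}.
#' @param lam migration probability lambda in [0, 1]: the per-lineage
#'   probability of switching populations at the pulse. \code{lam = 0}
#'   recovers a pure isolation model.
#' @param n1 sample size of the recipient population 1.
#' @param n2 sample size of the source population 2.
#' @return an object of class \code{demographic_params}.
#' @examples
#' p <- demographic_params(theta = 10, rho = 0, tau_d = 0.5,
#'                         tau_m = 0.05, lam = 0.01, n1 = 10, n2 = 10)
#' @export
demographic_params <- function(theta, rho = 0, tau_d = 0, tau_m = 0,
                               lam = 0, n1 = 10, n2 = 10) {
  stopifnot(is.finite(theta), is.finite(rho), is.finite(tau_d),
            is.finite(tau_m), is.finite(lam))
  if (theta <= 0) stop("theta must be > 0")
  if (rho < 0) stop("rho must be >= 0")
  if (tau_d < 0) stop("tau_d must be >= 0")
  if (tau_m < 0 || tau_m > tau_d)
    stop("constraint violated: 0 <= tau_m <= tau_d")
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be >= 1")
  if (n1 + n2 > 64) stop("total sample size capped at 64")
  structure(list(theta = theta, rho = rho, tau_d = tau_d, tau_m = tau_m,
                 lam = lam, n1 = n1, n2 = n2),
            class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat(sprintf(
    "<demographic_params theta=%g rho=%g tau_d=%g tau_m=%g lambda=%g n1=%d n2=%d>\n",
    x$theta, x$rho, x$tau_d, x$tau_m, x$lam, x$n1, x$n2))
  invisible(x)
}

#' Simulate one haplotype window
#'
#' Runs the structured coalescent with recombination back to the grand
#' MRCA of every point in the window and drops infinite-sites mutations on
#' the resulting genealogies. Time is internally rescaled so that
#' \code{E[pi] = theta} and the expected number of segregating sites for a
#' panmictic sample of n is \code{theta * sum(1/(1:(n-1)))}.
#'
#' @param params a \code{\link{demographic_params}}.
#' @param seed optional integer; when given, \code{set.seed(seed)} is
#'   called first so single windows are reproducible.
#' @return an object of class \code{sim_window}: list with \code{window}
#'   (a complete-data binary \code{\link{hap_window}}, columns in
#'   positional order, ancestral state 0), \code{migrant_flag},
#'   \code{n_segsites}, \code{positions} (uniform on [0,1)),
#'   \code{params}, \code{seed}.
#' @export
simulate_window <- function(params, seed = NULL) {
  stopifnot(inherits(params, "demographic_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- tryCatch(
    .sim_window_cpp(params$theta, params$rho,
                    params$tau_d / 4, params$tau_m / 4,
                    params$lam, params$n1, params$n2, .EVENT_CEILING),
    error = function(e) stop(sprintf(
      "simulation failed (%s) for theta=%g rho=%g tau_d=%g tau_m=%g lambda=%g n1=%d n2=%d seed=%s",
      conditionMessage(e), params$theta, params$rho, params$tau_d,
      params$tau_m, params$lam, params$n1, params$n2,
      if (is.null(seed)) "<stream>" else seed), call. = FALSE))
  mat <- res$mat
  rownames(mat) <- c(sprintf("p1_%02d", seq_len(params$n1)),
                     sprintf("p2_%02d", seq_len(params$n2)))
  w <- hap_window(mat, pop = rep(c(1L, 2L), c(params$n1, params$n2)),
                  window_id = if (is.null(seed)) "sim" else paste0("sim", seed))
  structure(list(window = w, migrant_flag = res$migrant,
                 n_segsites = ncol(mat), positions = res$positions,
                 params = params, seed = seed),
            class = "sim_window")
}

#' @export
print.sim_window <- function(x, ...) {
  cat(sprintf("<sim_window: %d segregating sites, migrant=%s>\n",
              x$n_segsites, x$migrant_flag))
  invisible(x)
}

# per-window substreams: seeds drawn without replacement under the root
# seed and indexed by window number, so a batch is independent of the
# order (or subset) in which its windows are realized
.window_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a batch of independent windows
#'
#' Adjacent windows contain independent genealogies: each window is an
#' independent replicate driven by its own seed derived from \code{seed}
#' and the window index. Identical \code{(params, n_windows, seed)} give
#' bit-identical batches.
#'
#' @inheritParams simulate_window
#' @param n_windows number of replicates (>= 1).
#' @param seed root integer seed.
#' @return list of \code{sim_window} objects (class \code{sim_batch}).
#' @export
simulate_batch <- function(params, n_windows, seed) {
  stopifnot(n_windows >= 1)
  seeds <- .window_seeds(seed, n_windows)
  out <- lapply(seq_len(n_windows), function(i) {
    w <- simulate_window(params, seed = seeds[i])
    w$window$window_id <- sprintf("w%06d", i)
    w
  })
  structure(out, class = "sim_batch", params = params, seed = seed)
}

#' Simulate windows and reduce them to per-window statistics
#'
#' Streaming companion to \code{\link{simulate_batch}}: each window is
#' simulated, summarized via \code{\link{distance_summary}}, and
#' discarded, so parameter sweeps never hold raw haplotype matrices.
#'
#' @inheritParams simulate_batch
#' @param mode distance mode; \code{"count"} for complete simulated data.
#' @return data frame with columns \code{window_id}, \code{migrant_flag},
#'   \code{n_segsites}, \code{gmin}, \code{fst}, \code{min_dxy},
#'   \code{mean_dxy}, \code{mean_dxx}, \code{mean_dyy}.
#' @export
simulate_stats <- function(params, n_windows, seed, mode = "count") {
  seeds <- .window_seeds(seed, n_windows)
  rows <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    sw <- simulate_window(params, seed = seeds[i])
    r <- .window_stat_row(sw$window, mode)
    rows[[i]] <- cbind(data.frame(window_id = sprintf("w%06d", i),
                                  migrant_flag = sw$migrant_flag,
                                  n_segsites = sw$n_segsites), r)
  }
  do.call(rbind, rows)
}

#' Per-window statistics table for a simulated batch
#'
#' @param batch a \code{sim_batch}.
#' @param mode distance mode (default \code{"count"}).
#' @return data frame as in \code{\link{simulate_stats}}.
#' @export
batch_stats <- function(batch, mode = "count") {
  stopifnot(inherits(batch, "sim_batch"))
  rows <- lapply(batch, function(sw) {
    cbind(data.frame(window_id = sw$window$window_id,
                     migrant_flag = sw$migrant_flag,
                     n_segsites = sw$n_segsites),
          .window_stat_row(sw$window, mode))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo expectation of G_min
#'
#' Mean of the defined G_min values over a simulated batch, with the
#' count of undefined (zero mean between-population distance) windows.
#'
#' @inheritParams simulate_batch
#' @return list with \code{mean_gmin} (NA if every window was undefined),
#'   \code{n_defined}, \code{n_undefined}.
#' @export
expected_gmin_mc <- function(params, n_windows, seed) {
  g <- simulate_stats(params, n_windows, seed)$gmin
  nd <- sum(!is.na(g))
  list(mean_gmin = if (nd == 0) NA_real_ else mean(g, na.rm = TRUE),
       n_defined = nd, n_undefined = sum(is.na(g)))
}

#' Write a batch statistics table as TSV with a run-metadata sidecar
#'
#' The TSV carries a single '#'-prefixed header line with column names;
#' the sidecar \code{<path>.meta.json} records parameters, seed and
#' package version.
#'
#' @param stats data frame from \code{\link{simulate_stats}} or
#'   \code{\link{batch_stats}}.
#' @param path output TSV path.
#' @param params the \code{\link{demographic_params}} used.
#' @param seed the root seed used.
#' @return \code{path}, invisibly.
#' @export
write_batch_tsv <- function(stats, path, params = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(stats), collapse = "\t")), con)
  write.table(stats, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(params = if (is.null(params)) NULL else unclass(params),
               seed = seed,
               version = as.character(packageVersion("gminscan")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Dump a simulated batch in ms-style text
#'
#' Writes the familiar \code{//} / \code{segsites:} / \code{positions:}
#' blocks with 0/1 haplotype rows, for interoperability with coalescent
#' tooling.
#'
#' @param batch a \code{sim_batch}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ms <- function(batch, path) {
  stopifnot(inherits(batch, "sim_batch"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(batch, "params")
  writeLines(sprintf("gminscan %d %d", p$n1 + p$n2, length(batch)), con)
  writeLines(as.character(attr(batch, "seed")), con)
  for (sw in batch) {
    writeLines("", con); writeLines("//", con)
    writeLines(sprintf("segsites: %d", sw$n_segsites), con)
    if (sw$n_segsites > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", sw$positions), collapse = " ")),
                 con)
      apply(sw$window$seqs, 1, function(r)
        writeLines(paste(r, collapse = ""), con))
    }
  }
  invisible(path)
}
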