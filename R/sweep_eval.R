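# Z-score outlier classification, sensitivity/specificity over parameter
# grids, and variance partitioning of the simulated statistics.
#
# The classifier is deliberately not a formal statistical test: a window
# is called "positive" for gene flow when its statistic lies below a fixed
# Z threshold relative to the batch's own mean and standard deviation. No
# multiple-testing correction is applied anywhere.

#' Default outlier thresholds
#'
#' The three stringency levels used throughout: Z < -1.645, Z < -2.326
#' and Z < -3.090 (the lower 5\%, 1\% and 0.1\% points of a standard
#' normal, used as reference cutoffs only).
#' @export
Z_THRESHOLDS <- c(-1.645, -2.326, -3.090)

#' Z-standardize a vector of statistics
#'
#' \code{(x - mean) / sd} over the defined (non-NA) values, using the
#' batch's own mean and sample standard deviation (n-1 denominator).
#' Undefined inputs yield undefined outputs and do not influence the
#' standardization.
#'
#' @param values numeric vector, possibly with NA (undefined) entries.
#' @param batch_id label used in error messages.
#' @return numeric vector of the same length.
#' @export
zscores <- function(values, batch_id = "batch") {
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop(sprintf("zscores(%s): need >= 2 defined values", batch_id))
  m <- mean(values[ok]); s <- sd(values[ok])
  if (s == 0)
    stop(sprintf("zscores(%s): zero spread among defined values", batch_id))
  out <- rep(NA_real_, length(values))
  out[ok] <- (values[ok] - m) / s
  out
}

#' Sensitivity of the outlier classification
#'
#' Proportion of true gene-flow windows that are called:
#' \code{|M intersect Q| / |M|}.
#'
#' @param M ids of true migrant windows.
#' @param Q ids of windows called as outliers.
#' @return a number in [0, 1], or NA when \code{M} is empty.
#' @export
sensitivity <- function(M, Q) {
  if (length(M) == 0) return(NA_real_)
  length(intersect(M, Q)) / length(M)
}

#' Specificity of the outlier classification
#'
#' Proportion of called windows that are true gene-flow windows:
#' \code{|M intersect Q| / |Q|}.
#'
#' @inheritParams sensitivity
#' @return a number in [0, 1], or NA when \code{Q} is empty.
#' @export
specificity <- function(M, Q) {
  if (length(Q) == 0) return(NA_real_)
  length(intersect(M, Q)) / length(Q)
}

#' Build a parameter grid
#'
#' Cartesian product of the supplied parameter vectors. Pulse times are
#' given as fractions of the divergence time (\code{tau_m =
#' tau_m_fraction * tau_d}), matching how secondary-contact sweeps are
#' parameterized.
#'
#' @param theta,rho,tau_d,lam,n1,n2 parameter vectors (see
#'   \code{\link{demographic_params}}).
#' @param tau_m_fraction vector of tau_m / tau_d fractions in [0, 1].
#' @return data frame with one row per parameter combination.
#' @export
param_grid <- function(theta, rho = 0, tau_d, tau_m_fraction = 0,
                       lam = 0, n1 = 10, n2 = 10) {
  g <- expand.grid(theta = theta, rho = rho, tau_d = tau_d,
                   tau_m_fraction = tau_m_fraction, lam = lam,
                   n1 = n1, n2 = n2,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$tau_m <- g$tau_m_fraction * g$tau_d
  g$cell <- seq_len(nrow(g))
  g
}

# classify one simulated cell at every threshold for one statistic; when
# the batch cannot be standardized (zero spread, e.g. G_min identically 0
# at tiny divergence times) the classification is undefined but the cell
# itself survives with NA sensitivity/specificity
.cell_eval <- function(stats, stat, thresholds) {
  x <- stats[[stat]]
  def <- !is.na(x)
  M <- stats$window_id[stats$migrant_flag & def]
  z <- tryCatch(zscores(x, stat), error = function(e) NULL)
  out <- list()
  for (thr in thresholds) {
    Q <- if (is.null(z)) NULL else stats$window_id[def & z < thr]
    lab <- sprintf("%.3f", abs(thr))
    out[[paste0("phi_", stat, "_", lab)]] <-
      if (is.null(z)) NA_real_ else sensitivity(M, Q)
    out[[paste0("psi_", stat, "_", lab)]] <-
      if (is.null(z)) NA_real_ else specificity(M, Q)
    out[[paste0("n_called_", stat, "_", lab)]] <-
      if (is.null(z)) NA_integer_ else length(Q)
  }
  out$z <- z
  out$n_true <- length(M)
  out
}

#' Run a simulation sweep over a parameter grid
#'
#' For every grid cell: simulate a batch of windows, compute G_min and
#' F_ST, Z-standardize within the cell, form the truth set M from the
#' migrant-genealogy flags and the call set Q at each threshold, and
#' aggregate. Windows with an undefined statistic are excluded from the
#' standardization and from M and Q for that statistic. Deterministic
#' given \code{seed}; cells are checkpointed when \code{checkpoint_dir}
#' is given, so an interrupted sweep resumes without recomputing
#' completed cells. Per-cell failures are recorded in the \code{error}
#' column rather than aborting the sweep.
#'
#' @param grid data frame from \code{\link{param_grid}}.
#' @param n_windows windows per cell.
#' @param seed root seed; each cell gets an independent derived stream.
#' @param thresholds Z thresholds (default \code{\link{Z_THRESHOLDS}}).
#' @param checkpoint_dir optional directory for per-cell checkpoints.
#' @param return_windows when TRUE, attach the window-level table
#'   (columns: cell parameters plus per-window \code{gmin}, \code{fst},
#'   \code{migrant_flag}) as attribute \code{"windows"} — the substrate
#'   for window-level variance partitioning.
#' @return data frame with one row per cell: parameters, \code{n_windows},
#'   mean/SD of each statistic over defined windows, \code{n_true_migrant},
#'   and per-threshold \code{phi}/\code{psi}/\code{n_called} for both
#'   statistics.
#' @export
run_grid <- function(grid, n_windows, seed, thresholds = Z_THRESHOLDS,
                     checkpoint_dir = NULL, return_windows = FALSE) {
  if (nrow(grid) == 0) stop("empty parameter grid")
  cell_seeds <- .window_seeds(seed, nrow(grid))
  if (!is.null(checkpoint_dir) &&
      !dir.exists(checkpoint_dir)) dir.create(checkpoint_dir,
                                              recursive = TRUE)
  rows <- vector("list", nrow(grid))
  winlist <- if (return_windows) vector("list", nrow(grid)) else NULL

  for (i in seq_len(nrow(grid))) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("cell_%05d.rds", i)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      saved <- readRDS(ck)
      rows[[i]] <- saved$row
      if (return_windows) winlist[[i]] <- saved$windows
      next
    }
    g <- grid[i, ]
    row <- tryCatch({
      p <- demographic_params(theta = g$theta, rho = g$rho,
                              tau_d = g$tau_d, tau_m = g$tau_m,
                              lam = g$lam, n1 = g$n1, n2 = g$n2)
      st <- simulate_stats(p, n_windows, cell_seeds[i])
      eg <- .cell_eval(st, "gmin", thresholds)
      ef <- .cell_eval(st, "fst", thresholds)
      if (return_windows)
        winlist[[i]] <- cbind(g[rep(1, nrow(st)),
                                 c("cell", "theta", "rho", "tau_d",
                                   "tau_m_fraction", "lam", "n1", "n2")],
                               st[, c("window_id", "migrant_flag",
                                      "gmin", "fst")],
                               row.names = NULL)
      cbind(g,
            data.frame(n_windows = n_windows,
                       n_defined_gmin = sum(!is.na(st$gmin)),
                       mean_gmin = mean(st$gmin, na.rm = TRUE),
                       sd_gmin = sd(st$gmin, na.rm = TRUE),
                       mean_fst = mean(st$fst, na.rm = TRUE),
                       sd_fst = sd(st$fst, na.rm = TRUE),
                       n_true_migrant = sum(st$migrant_flag),
                       error = NA_character_),
            as.data.frame(eg[!(names(eg) %in% c("z", "n_true"))]),
            as.data.frame(ef[!(names(ef) %in% c("z", "n_true"))]))
    }, error = function(e) {
      cbind(g, data.frame(n_windows = n_windows,
                          error = conditionMessage(e)))
    })
    rows[[i]] <- row
    if (!is.null(ck))
      saveRDS(list(row = row,
                   windows = if (return_windows) winlist[[i]] else NULL),
              ck)
  }
  res <- do.call(rbind, lapply(rows, function(r) {
    # pad failed cells to the full column set
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  if (return_windows)
    attr(res, "windows") <- do.call(rbind, winlist)
  res
}

#' Partition the variance of a response across model parameters
#'
#' Fits a least-squares ANOVA on a balanced full-factorial table and
#' returns the percent of total sum of squares attributable to each term
#' plus the residual. On a balanced design the factorial terms are
#' orthogonal, so the partition does not depend on the order of terms in
#' the model; this is asserted by refitting with the terms permuted.
#' Unbalanced tables are rejected (order-invariance is not guaranteed).
#'
#' The default model mirrors the isolation-sweep analysis: main effects
#' of the divergence time, mutation and recombination rates and the
#' source-population sample size, plus the divergence-by-sample-size and
#' divergence-by-recombination interactions. With
#' \code{all_interactions = TRUE} the fully saturated factorial model is
#' used instead. When the response is a per-window statistic, the
#' residual absorbs the within-cell coalescent noise.
#'
#' @param table data frame holding the response and the factor columns.
#' @param response name of the response column.
#' @param factors character vector of main-effect columns.
#' @param interactions character vector of interaction terms in formula
#'   notation (e.g. \code{"tau_d:n2"}).
#' @param all_interactions fit the saturated model (all parameters and
#'   their interactions).
#' @param covariate_class \code{"factor"} treats every parameter as a
#'   categorical factor (each level fitted freely); \code{"numeric"}
#'   fits the parameters as linear covariates, so a term's share is the
#'   variance explained by the linear trend in that parameter and any
#'   curvature (e.g. the saturating approach of G_min to unity with
#'   divergence time) is left in the residual alongside the
#'   within-window coalescent noise. Both are orthogonal — hence
#'   order-invariant — on a balanced product grid.
#' @param min_percent suppress terms explaining less than this percent
#'   (residual always kept); 0 reports everything.
#' @param check_order_invariance refit under a permuted term order and
#'   assert the partition is unchanged.
#' @return data frame with columns \code{term} and \code{percent};
#'   percents (including \code{Residuals}) sum to 100.
#' @export
variance_partition <- function(table, response,
                               factors = c("tau_d", "theta", "rho", "n2"),
                               interactions = c("tau_d:n2", "tau_d:rho"),
                               all_interactions = FALSE,
                               covariate_class = c("factor", "numeric"),
                               min_percent = 0,
                               check_order_invariance = TRUE) {
  covariate_class <- match.arg(covariate_class)
  stopifnot(response %in% names(table), all(factors %in% names(table)))
  df <- table
  if (covariate_class == "factor")
    for (f in factors) df[[f]] <- factor(df[[f]])
  counts <- table(df[factors])
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0))
    stop("unbalanced table: every factor combination must appear equally often")

  fit_pct <- function(terms) {
    fml <- as.formula(paste(response, "~", paste(terms, collapse = " + ")))
    # only the sums of squares are used; suppress aov's F-test chatter
    # on (near-)perfect fits
    a <- suppressWarnings(anova(aov(fml, data = df)))
    ss <- a[["Sum Sq"]]
    pct <- 100 * ss / sum(ss)
    names(pct) <- trimws(rownames(a))
    pct
  }
  terms <- if (all_interactions)
    paste0("(", paste(factors, collapse = " + "), ")^", length(factors))
  else c(factors, interactions)
  pct <- fit_pct(terms)
  if (check_order_invariance && !all_interactions && length(terms) > 1) {
    pct2 <- fit_pct(rev(terms))
    if (max(abs(sort(pct) - sort(pct2))) > 1e-8)
      stop("variance partition is order-dependent; design is not orthogonal")
  }
  out <- data.frame(term = names(pct), percent = unname(pct),
                    row.names = NULL)
  keep <- out$percent >= min_percent | out$term == "Residuals"
  out[keep, , drop = FALSE]
}
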