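# Haplotype-window containers and the core distance statistics.
#
# A haplotype window holds aligned haploid sequences (rows) over the sites
# of one genomic window (columns), with each row assigned to population 1
# or 2. All statistics reduce to pairwise Hamming counts; "undefined" is
# represented by NA throughout (e.g. G_min when the mean between-population
# distance is zero), never by an arbitrary number.

# internal state coding: 0/1 for simulated biallelic data, 1:4 for
# A/C/G/T; NA is the missing state. G_min and F_ST only ever compare
# states for equality, so the two codings coexist safely.
.encode_states <- function(x) {
  if (is.numeric(x)) {
    m <- matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x))
    return(m)
  }
  lut <- c("0" = 0L, "1" = 1L,
           "A" = 1L, "C" = 2L, "G" = 3L, "T" = 4L,
           "a" = 1L, "c" = 2L, "g" = 3L, "t" = 4L)
  m <- matrix(unname(lut[x]), nrow = nrow(x), dimnames = dimnames(x))
  m
}

#' Construct a haplotype window
#'
#' @param seqs matrix of allelic states, rows = haploid sequences,
#'   columns = sites. Accepted states: integers, "0"/"1", or nucleotide
#'   letters A/C/G/T (case-insensitive). Anything else (N, -, ?, .) is
#'   treated as missing.
#' @param pop integer vector of population labels in \{1, 2\}, one per row.
#' @param window_id opaque identifier for the window.
#' @param coords optional \code{list(chrom, start, end)}, 0-based
#'   half-open.
#' @param n_invariant number of additional monomorphic, fully callable
#'   sites not stored as columns (used when windows are materialized from
#'   VCF variant records); they contribute to p-distance denominators but
#'   never to difference counts.
#' @return an object of class \code{hap_window}.
#' @examples
#' w <- hap_window(rbind(a = c("0","0","0"), b = c("0","1","1")),
#'                 pop = c(1, 2))
#' gmin(distance_summary(w))
#' @export
hap_window <- function(seqs, pop, window_id = "w", coords = NULL,
                       n_invariant = 0L) {
  if (is.character(seqs) || is.numeric(seqs)) {
    stopifnot(is.matrix(seqs))
    m <- .encode_states(seqs)
  } else stop("seqs must be a character or numeric matrix")
  pop <- as.integer(pop)
  if (length(pop) != nrow(m))
    stop("pop labels must match the number of sequences")
  if (!all(pop %in% c(1L, 2L)))
    stop("population labels must be 1 or 2")
  n1 <- sum(pop == 1L); n2 <- sum(pop == 2L)
  if (n1 < 1L || n2 < 1L)
    stop("each population needs at least one sequence")
  if (is.null(rownames(m)))
    rownames(m) <- paste0("seq", seq_len(nrow(m)))
  structure(list(seqs = m, pop = pop, n1 = n1, n2 = n2,
                 window_id = window_id, coords = coords,
                 n_invariant = as.integer(n_invariant)),
            class = "hap_window")
}

#' @export
print.hap_window <- function(x, ...) {
  cat(sprintf("<hap_window %s: %d+%d sequences, %d sites (+%d invariant)>\n",
              x$window_id, x$n1, x$n2, ncol(x$seqs), x$n_invariant))
  invisible(x)
}

#' Pairwise distance between two haplotypes
#'
#' Hamming count or p-distance between two aligned sequences, with
#' pairwise deletion of sites where either state is missing.
#'
#' @param seq_a,seq_b vectors of states (as in \code{\link{hap_window}}).
#' @param mode \code{"count"}: number of mutually non-missing, differing
#'   sites; \code{"p_distance"}: that count divided by the number of
#'   mutually non-missing sites.
#' @return a non-negative number.
#' @export
pairwise_distance <- function(seq_a, seq_b,
                              mode = c("count", "p_distance")) {
  mode <- match.arg(mode)
  if (length(seq_a) != length(seq_b))
    stop("sequences must have equal length")
  a <- .encode_states(matrix(seq_a, nrow = 1))[1, ]
  b <- .encode_states(matrix(seq_b, nrow = 1))[1, ]
  ok <- !is.na(a) & !is.na(b)
  d <- sum(a[ok] != b[ok])
  if (mode == "count") return(d)
  if (!any(ok))
    stop("undefined p-distance: no mutually non-missing sites")
  d / sum(ok)
}

#' Distance summary for a haplotype window
#'
#' Computes the minimum and mean between-population distances and the
#' within-population mean distances that G_min and Hudson's F_ST are built
#' from. Between-population distances run over all \code{n1 x n2} ordered
#' cross-population pairs; within-population means run over the
#' \code{n(n-1)/2} unordered pairs (self-comparisons excluded, the
#' standard nucleotide-diversity convention). A population with a single
#' member has its within mean flagged absent (NA).
#'
#' @param window a \code{\link{hap_window}}.
#' @param mode \code{"count"} (complete-data simulation output) or
#'   \code{"p_distance"} (scan mode; pairwise deletion plus any
#'   \code{n_invariant} monomorphic sites in the denominator).
#' @return an object of class \code{gmin_distance_summary}: a list with
#'   \code{min_dxy}, \code{mean_dxy}, \code{mean_dxx}, \code{mean_dyy},
#'   \code{n_pairs_between}, \code{distance_mode}, and \code{min_pairs}
#'   (the sequence-name pairs attaining the minimum, for tree inspection).
#' @export
distance_summary <- function(window, mode = c("count", "p_distance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "hap_window"))
  h <- .hamming_counts_cpp(window$seqs)
  diffs <- h$diff
  comp <- h$comparable + window$n_invariant
  i1 <- which(window$pop == 1L)
  i2 <- which(window$pop == 2L)

  if (mode == "p_distance") {
    bad <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)
    # only pairs actually used can make the summary undefined
    if (nrow(bad) > 0) {
      used <- apply(bad, 1, function(ij) {
        (ij[1] %in% i1 && ij[2] %in% i2) ||
        (ij[1] %in% i2 && ij[2] %in% i1) ||
        all(ij %in% i1) || all(ij %in% i2)
      })
      if (any(used)) {
        nm <- rownames(window$seqs)
        ij <- bad[which(used)[1], ]
        stop(sprintf(
          "undefined p-distance (no mutually non-missing sites) for pair %s / %s",
          nm[ij[1]], nm[ij[2]]))
      }
    }
    dmat <- diffs / ifelse(comp == 0, NA, comp)
  } else {
    dmat <- diffs
  }

  between <- dmat[i1, i2, drop = FALSE]
  mean_dxy <- mean(between)
  min_dxy <- min(between)
  am <- which(between == min_dxy, arr.ind = TRUE)
  nm <- rownames(window$seqs)
  min_pairs <- cbind(nm[i1[am[, 1]]], nm[i2[am[, 2]]])

  within_mean <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    m <- dmat[idx, idx, drop = FALSE]
    mean(m[upper.tri(m)])
  }
  structure(list(min_dxy = min_dxy, mean_dxy = mean_dxy,
                 mean_dxx = within_mean(i1), mean_dyy = within_mean(i2),
                 n_pairs_between = length(i1) * length(i2),
                 distance_mode = mode, min_pairs = min_pairs),
            class = "gmin_distance_summary")
}

#' @export
print.gmin_distance_summary <- function(x, ...) {
  cat(sprintf(
    "<distance summary (%s): min_dxy=%.4g mean_dxy=%.4g dxx=%.4g dyy=%.4g (%d pairs)>\n",
    x$distance_mode, x$min_dxy, x$mean_dxy, x$mean_dxx, x$mean_dyy,
    x$n_pairs_between))
  invisible(x)
}

.as_summary <- function(x, mode) {
  if (inherits(x, "hap_window")) distance_summary(x, mode) else x
}

#' G_min: minimum over mean between-population distance
#'
#' \code{gmin = min(d_XY) / mean(d_XY)} over all between-population pairs
#' in a window. Lies in [0, 1]; equals 1 when both samples are singletons
#' and differ. Returns NA (undefined) when the mean between-population
#' distance is zero — the window carries no between-population signal and
#' must be excluded from Z-score standardization.
#'
#' @param summary a \code{gmin_distance_summary} (or a
#'   \code{\link{hap_window}}, which is summarized first).
#' @param mode distance mode used if a window is supplied.
#' @return a number in [0, 1], or NA.
#' @export
gmin <- function(summary, mode = "count") {
  s <- .as_summary(summary, mode)
  if (s$mean_dxy == 0) return(NA_real_)
  s$min_dxy / s$mean_dxy
}

#' Hudson's F_ST from a distance summary
#'
#' \code{1 - (mean_dxx + mean_dyy) / (2 * mean_dxy)}. A single-member
#' population contributes a zero within term (its within-population
#' diversity is unobservable; the summary's NA flags the convention).
#' Returns NA when the mean between-population distance is zero.
#'
#' @inheritParams gmin
#' @return a number \code{<= 1}, or NA.
#' @export
fst_hudson <- function(summary, mode = "count") {
  s <- .as_summary(summary, mode)
  if (s$mean_dxy == 0) return(NA_real_)
  dxx <- if (is.na(s$mean_dxx)) 0 else s$mean_dxx
  dyy <- if (is.na(s$mean_dyy)) 0 else s$mean_dyy
  1 - (dxx + dyy) / (2 * s$mean_dxy)
}

# one-row data frame of all window statistics; shared by batch tables and
# the genome scanner
.window_stat_row <- function(window, mode) {
  s <- distance_summary(window, mode)
  data.frame(gmin = gmin(s), fst = fst_hudson(s),
             min_dxy = s$min_dxy, mean_dxy = s$mean_dxy,
             mean_dxx = s$mean_dxx, mean_dyy = s$mean_dyy)
}
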