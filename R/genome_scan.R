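# Non-overlapping window scans of phased haplotype alignments.
#
# Inputs are either a multi-FASTA (one record per haploid sequence, all
# the same length) or a phased VCF plus a declared chromosome length,
# with a two-column population map. Coordinates are 0-based half-open
# (BED convention) in all outputs. Windows whose callable fraction falls
# below the threshold are filtered before Z-standardization; the last,
# short window at a chromosome end is retained and identifiable by
# end - start < window_size.

#' Scan configuration
#'
#' @param window_size window length in bases (default 50 kb).
#' @param min_callable_fraction windows below this callable fraction are
#'   filtered from the scan (default 0.25).
#' @param z_threshold outlier threshold on the Z-score (default -1.645).
#' @param distance_mode \code{"p_distance"} (default; pairwise deletion
#'   guards against coverage differences masquerading as low distances)
#'   or \code{"count"} for complete data.
#' @return an object of class \code{scan_config}.
#' @export
scan_config <- function(window_size = 50000L,
                        min_callable_fraction = 0.25,
                        z_threshold = -1.645,
                        distance_mode = c("p_distance", "count")) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(window_size > 0,
            min_callable_fraction >= 0, min_callable_fraction <= 1)
  structure(list(window_size = as.integer(window_size),
                 min_callable_fraction = min_callable_fraction,
                 z_threshold = z_threshold,
                 distance_mode = distance_mode),
            class = "scan_config")
}

#' Read a two-column population map
#'
#' Tab-separated file: sample name, population label (1 or 2), no header.
#'
#' @param path file path.
#' @return named integer vector mapping sample to population.
#' @export
read_pop_map <- function(path) {
  m <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE,
                  col.names = c("sample", "pop"))
  if (!all(m$pop %in% c(1L, 2L)))
    stop("population labels must be 1 or 2")
  setNames(as.integer(m$pop), m$sample)
}

# 256-entry lookup: raw byte -> state code; unambiguous bases only are
# callable, everything else (N, -, ?, ...) is missing
.base_lut <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1] <- 1L; lut[utf8ToInt("a") + 1] <- 1L
  lut[utf8ToInt("C") + 1] <- 2L; lut[utf8ToInt("c") + 1] <- 2L
  lut[utf8ToInt("G") + 1] <- 3L; lut[utf8ToInt("g") + 1] <- 3L
  lut[utf8ToInt("T") + 1] <- 4L; lut[utf8ToInt("t") + 1] <- 4L
  lut
})

.tile <- function(chrom_length, window_size) {
  starts <- seq(0L, chrom_length - 1L, by = window_size)
  data.frame(start = starts,
             end = pmin(starts + window_size, chrom_length))
}

#' Read haplotype windows from a multi-FASTA alignment
#'
#' Every record is one haploid sequence; all records must have equal
#' length. A site is callable for a sequence when its state is an
#' unambiguous base (A/C/G/T); the window's callable fraction is the mean
#' over sequences of the per-sequence callable fractions.
#'
#' @param path FASTA file.
#' @param pop_map named vector (see \code{\link{read_pop_map}}); every
#'   record must be assigned.
#' @param window_size window length in bases.
#' @param chrom chromosome name used in output coordinates.
#' @return list of \code{\link{hap_window}} objects tiling
#'   \code{[0, chrom_length)}, each carrying a \code{callable_fraction}
#'   attribute.
#' @export
read_haplotypes_fasta <- function(path, pop_map, window_size = 50000L,
                                  chrom = "chr") {
  dss <- Biostrings::readDNAStringSet(path)
  L <- unique(Biostrings::width(dss))
  if (length(L) != 1)
    stop("FASTA records differ in length; alignment required")
  nms <- names(dss)
  missing_map <- setdiff(nms, names(pop_map))
  if (length(missing_map) > 0)
    stop("sample(s) missing from population map: ",
         paste(missing_map, collapse = ", "))
  raws <- lapply(as.character(dss), charToRaw)
  tiles <- .tile(L, window_size)
  lapply(seq_len(nrow(tiles)), function(i) {
    s <- tiles$start[i]; e <- tiles$end[i]
    mat <- do.call(rbind, lapply(raws, function(r)
      .base_lut[as.integer(r[(s + 1):e]) + 1]))
    rownames(mat) <- nms
    w <- hap_window(mat, pop = pop_map[nms],
                    window_id = sprintf("%s:%d-%d", chrom, s, e),
                    coords = list(chrom = chrom, start = s, end = e))
    attr(w, "callable_fraction") <- mean(rowMeans(!is.na(mat)))
    w
  })
}

#' Read haplotype windows from a phased VCF
#'
#' Each diploid sample contributes two haplotype rows (phased genotypes
#' required, \code{0|1} style); haploid genotypes (inbred-line data)
#' contribute one row. Sites between variant records are materialized as
#' monomorphic callable columns via the declared chromosome length, so
#' p-distances are on the per-site scale. Missing genotypes (\code{.})
#' yield missing states at that site only.
#'
#' @param path VCF file (plain or bgzipped).
#' @param pop_map named vector assigning every VCF sample to a population.
#' @param chrom_length declared reference length of the scanned sequence.
#' @param window_size window length in bases.
#' @return list of \code{\link{hap_window}} objects as in
#'   \code{\link{read_haplotypes_fasta}}.
#' @export
read_haplotypes_vcf <- function(path, pop_map, chrom_length,
                                window_size = 50000L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # always a matrix, even for a single record
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[1, "CHROM"]
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  missing_map <- setdiff(samples, names(pop_map))
  if (length(missing_map) > 0)
    stop("sample(s) missing from population map: ",
         paste(missing_map, collapse = ", "))
  if (any(grepl("/", gt, fixed = TRUE) & !grepl("^\\.\\/\\.$", gt)))
    stop("unphased genotype found; phased (|) genotypes required")

  # expand samples into haplotype rows
  hap_rows <- list()
  hap_pop <- integer(0)
  for (s in samples) {
    g <- gt[, s]
    g[is.na(g)] <- "."
    parts <- strsplit(g, "|", fixed = TRUE)
    ploidy <- max(lengths(parts))
    alleles <- vapply(parts, function(p) {
      p <- sub("^\\.$", NA_character_, p)
      length(p) <- ploidy
      p
    }, character(ploidy))
    alleles <- matrix(alleles, nrow = ploidy)
    alleles[alleles %in% c(".", "./.")] <- NA_character_
    for (h in seq_len(ploidy)) {
      nm <- if (ploidy == 1) s else paste0(s, "_", h)
      a <- suppressWarnings(as.integer(alleles[h, ]))
      hap_rows[[nm]] <- a
      hap_pop <- c(hap_pop, unname(pop_map[s]))
    }
  }
  hmat <- do.call(rbind, hap_rows)

  tiles <- .tile(chrom_length, window_size)
  lapply(seq_len(nrow(tiles)), function(i) {
    s <- tiles$start[i]; e <- tiles$end[i]
    span <- e - s
    in_w <- which(pos > s & pos <= e)  # VCF POS is 1-based
    sub <- hmat[, in_w, drop = FALSE]
    n_invariant <- span - length(in_w)
    w <- hap_window(sub, pop = hap_pop,
                    window_id = sprintf("%s:%d-%d", chrom, s, e),
                    coords = list(chrom = chrom, start = s, end = e),
                    n_invariant = n_invariant)
    callable <- (n_invariant + rowSums(!is.na(sub))) / span
    attr(w, "callable_fraction") <- mean(callable)
    w
  })
}

#' Scan haplotype windows for introgression outliers
#'
#' Computes G_min and Hudson's F_ST per window, filters windows whose
#' callable fraction is below the configured minimum, Z-standardizes the
#' statistics chromosome-wide over the surviving defined windows, and
#' flags outliers below the configured threshold.
#'
#' @param windows list of \code{\link{hap_window}} objects (from
#'   \code{\link{read_haplotypes_fasta}} or
#'   \code{\link{read_haplotypes_vcf}}).
#' @param config a \code{\link{scan_config}}.
#' @return data frame with one row per window: \code{chrom},
#'   \code{start}, \code{end} (0-based half-open; the first three columns
#'   are BED-compatible), \code{callable_fraction}, the distance
#'   statistics on the per-site scale, \code{z_gmin}, \code{z_fst},
#'   \code{outlier_gmin}, \code{outlier_fst} and a \code{status} in
#'   \{ok, filtered, undefined\}. Filtered and undefined windows carry no
#'   Z or outlier values.
#' @export
scan_windows <- function(windows, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"), length(windows) > 0)
  rows <- lapply(windows, function(w) {
    cf <- attr(w, "callable_fraction")
    if (is.null(cf)) cf <- mean(rowMeans(!is.na(w$seqs)))
    co <- w$coords
    base <- data.frame(chrom = co$chrom, start = co$start, end = co$end,
                       callable_fraction = cf)
    if (cf < config$min_callable_fraction)
      return(cbind(base,
                   data.frame(gmin = NA_real_, fst = NA_real_,
                              min_dxy = NA_real_, mean_dxy = NA_real_,
                              mean_dxx = NA_real_, mean_dyy = NA_real_,
                              status = "filtered")))
    st <- .window_stat_row(w, config$distance_mode)
    cbind(base, st,
          data.frame(status = if (is.na(st$gmin)) "undefined" else "ok"))
  })
  res <- do.call(rbind, rows)
  ok <- res$status == "ok"
  if (!any(ok)) stop("no windows passed filtering; nothing to scan")
  res$z_gmin <- NA_real_; res$z_fst <- NA_real_
  res$z_gmin[ok] <- zscores(res$gmin[ok], "gmin scan")
  res$z_fst[ok] <- zscores(res$fst[ok], "fst scan")
  res$outlier_gmin <- ifelse(ok, res$z_gmin < config$z_threshold, NA)
  res$outlier_fst <- ifelse(ok, res$z_fst < config$z_threshold, NA)
  rownames(res) <- NULL
  res
}

#' Scan a multi-FASTA alignment
#'
#' @param path FASTA file.
#' @param pop_map named population vector or path to a two-column map.
#' @param config a \code{\link{scan_config}}.
#' @param chrom chromosome name for output coordinates.
#' @return see \code{\link{scan_windows}}.
#' @export
scan_fasta <- function(path, pop_map, config = scan_config(),
                       chrom = "chr") {
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map))
    pop_map <- read_pop_map(pop_map)
  w <- read_haplotypes_fasta(path, pop_map, config$window_size, chrom)
  scan_windows(w, config)
}

#' Scan a phased VCF
#'
#' @inheritParams scan_fasta
#' @param chrom_length declared reference length.
#' @return see \code{\link{scan_windows}}.
#' @export
scan_vcf <- function(path, pop_map, chrom_length,
                     config = scan_config()) {
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map))
    pop_map <- read_pop_map(pop_map)
  w <- read_haplotypes_vcf(path, pop_map, chrom_length,
                           config$window_size)
  scan_windows(w, config)
}

#' Neighbor-joining tree for one window
#'
#' Builds the uncorrected-distance NJ tree for all haplotypes in a
#' window, for visual inspection of candidate introgressed samples
#' (an introgressed haplotype nests inside the donor population's
#' clade). Negative branch lengths produced by the NJ algorithm are
#' clamped to zero with the deficit transferred to the sister branch so
#' path lengths are preserved (standard practice); the adjustment is
#' recorded in the tree's \code{clamped} attribute.
#'
#' @param window a \code{\link{hap_window}} with >= 3 sequences.
#' @param mode distance mode (default \code{"p_distance"}).
#' @return an unrooted \code{ape::phylo} tree with leaf labels taken
#'   from the sequence names.
#' @export
nj_window_tree <- function(window, mode = "p_distance") {
  stopifnot(inherits(window, "hap_window"))
  n <- nrow(window$seqs)
  if (n < 3) stop("neighbor joining needs >= 3 sequences")
  h <- .hamming_counts_cpp(window$seqs)
  comp <- h$comparable + window$n_invariant
  if (mode == "p_distance") {
    bad <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      nm <- rownames(window$seqs)
      stop("undefined distance for pair(s): ",
           paste(apply(bad, 1, function(ij)
             paste(nm[ij[1]], nm[ij[2]], sep = "/")), collapse = ", "))
    }
    d <- h$diff / comp
  } else d <- h$diff
  dimnames(d) <- list(rownames(window$seqs), rownames(window$seqs))
  tr <- ape::nj(as.dist(d))
  .clamp_negative_branches(tr)
}

# set negative edges to zero and transfer the deficit to the sister edge
# so tip-to-tip path lengths through the parent are preserved
.clamp_negative_branches <- function(tree) {
  clamped <- 0L
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs) > 0)
      tree$edge.length[sibs] <- tree$edge.length[sibs] +
        tree$edge.length[e]
    tree$edge.length[e] <- 0
    clamped <- clamped + 1L
  }
  attr(tree, "clamped") <- clamped
  tree
}

#' Write a scan table as TSV
#'
#' Single '#'-prefixed header line with column names; the first three
#' columns are BED-compatible.
#'
#' @param scan data frame from \code{\link{scan_windows}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(scan), collapse = "\t")), con)
  write.table(scan, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
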