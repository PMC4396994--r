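# Scan-ready fixture generation: a synthetic chromosome assembled from
# simulator output, with a known set of migrant (recent-pulse) windows
# injected among isolation-model background windows. Written as FASTA,
# phased VCF and a population map, plus a truth sidecar giving the
# injected coordinates — the substrate for end-to-end tests of the
# scanner.

.BASES <- c("A", "C", "G", "T")

# map one simulated binary window onto a nucleotide block of win_size
# bases: ancestral state A, derived state T, monomorphic background C
.window_to_block <- function(sw, win_size) {
  n <- nrow(sw$window$seqs)
  cols <- unique(pmin(floor(sw$positions * win_size), win_size - 1)) + 1
  keep <- !duplicated(pmin(floor(sw$positions * win_size), win_size - 1))
  mat <- sw$window$seqs[, keep, drop = FALSE]
  block <- matrix("C", nrow = n, ncol = win_size)
  block[, cols] <- ifelse(mat == 1, "T", "A")
  rownames(block) <- rownames(sw$window$seqs)
  block
}

#' Generate scan-ready fixtures with injected migrant windows
#'
#' Simulates a chromosome of \code{n_windows} windows under the isolation
#' model and replaces a known subset with windows simulated under a
#' recent-pulse secondary-contact model, accepting only replicates whose
#' genealogy actually contains a migrant lineage. Writes a multi-FASTA,
#' an equivalent phased VCF, a population map, and a truth sidecar with
#' the injected coordinates. Regeneration is bit-identical per seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_windows total windows on the synthetic chromosome.
#' @param migrant_windows which window indices (1-based) carry the
#'   injected migrant genealogies.
#' @param window_size bases per window.
#' @param theta,rho,tau_d per-window population rates and divergence
#'   time shared by background and injected windows.
#' @param tau_m_frac pulse time as a fraction of \code{tau_d} for the
#'   injected windows.
#' @param lam migration probability for the injected windows.
#' @param n1,n2 sample sizes.
#' @return list of file paths: \code{fasta}, \code{vcf}, \code{pop_map},
#'   \code{truth}.
#' @export
make_fixtures <- function(dir, seed, n_windows = 40,
                          migrant_windows = c(8, 21, 34),
                          window_size = 20000L,
                          theta = 100, rho = 10, tau_d = 1,
                          tau_m_frac = 0.05, lam = 0.01,
                          n1 = 10, n2 = 10) {
  stopifnot(all(migrant_windows >= 1), all(migrant_windows <= n_windows))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  window_size <- as.integer(window_size)

  p_bg <- demographic_params(theta = theta, rho = rho, tau_d = tau_d,
                             n1 = n1, n2 = n2)
  p_mig <- demographic_params(theta = theta, rho = rho, tau_d = tau_d,
                              tau_m = tau_m_frac * tau_d, lam = lam,
                              n1 = n1, n2 = n2)
  seeds <- .window_seeds(seed, n_windows)
  reject_seeds <- .window_seeds(seed + 1L, 10000L)
  ri <- 0L

  blocks <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    if (i %in% migrant_windows) {
      # rejection-sample until the pulse actually moved a lineage
      repeat {
        ri <- ri + 1L
        if (ri > length(reject_seeds))
          stop("could not realize a migrant genealogy; raise lam")
        sw <- simulate_window(p_mig, seed = reject_seeds[ri])
        if (sw$migrant_flag) break
      }
    } else {
      sw <- simulate_window(p_bg, seed = seeds[i])
    }
    blocks[[i]] <- .window_to_block(sw, window_size)
  }

  sample_names <- c(sprintf("p1_%02d", seq_len(n1)),
                    sprintf("p2_%02d", seq_len(n2)))
  pops <- rep(c(1L, 2L), c(n1, n2))
  chrom <- "chrSim"
  full <- do.call(cbind, blocks)

  # FASTA
  fasta <- file.path(dir, "fixture.fa")
  seqs <- apply(full, 1, paste, collapse = "")
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- sample_names
  Biostrings::writeXStringSet(dss, fasta)

  # phased VCF (haploid samples, one GT column per haplotype)
  vcf <- file.path(dir, "fixture.vcf")
  poly <- which(apply(full, 2, function(col) length(unique(col)) > 1))
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom, ncol(full)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample_names),
                     collapse = "\t")), con)
  for (j in poly) {
    col <- full[, j]
    ref <- col[1]
    alt <- setdiff(unique(col), ref)
    gt <- match(col, c(ref, alt)) - 1L
    writeLines(paste(c(chrom, j, ".", ref, paste(alt, collapse = ","),
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  close(con)

  # population map
  pop_map <- file.path(dir, "fixture.popmap.tsv")
  write.table(data.frame(sample_names, pops), pop_map, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  # truth sidecar (0-based half-open window coordinates)
  truth <- file.path(dir, "fixture.truth.tsv")
  starts <- (seq_len(n_windows) - 1L) * window_size
  tr <- data.frame(chrom = chrom, start = starts,
                   end = starts + window_size,
                   migrant = seq_len(n_windows) %in% migrant_windows)
  con <- file(truth, "w")
  writeLines(paste0("#", paste(names(tr), collapse = "\t")), con)
  write.table(tr, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)

  list(fasta = fasta, vcf = vcf, pop_map = pop_map, truth = truth,
       chrom = chrom, chrom_length = ncol(full),
       window_size = window_size)
}
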