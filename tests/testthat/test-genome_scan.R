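write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, path)
  path
}

test_that("window tiling is exact and the trailing short window is kept", {
  tiles <- gminscan:::.tile(1000000L, 50000L)
  expect_equal(nrow(tiles), 20)
  expect_equal(tiles$start, seq(0L, 950000L, by = 50000L))
  expect_equal(tiles$end - tiles$start, rep(50000L, 20))
  # non-multiple length: last window short, union still exact
  t2 <- gminscan:::.tile(105000L, 50000L)
  expect_equal(nrow(t2), 3)
  expect_equal(t2$end[3] - t2$start[3], 5000L)
  expect_equal(t2$start[-1], t2$end[-3])  # disjoint, contiguous
})

test_that("fasta windows reproduce in-memory statistics exactly", {
  set.seed(42)
  fx <- make_fixtures(tempfile(), seed = 301, n_windows = 6,
                      migrant_windows = 3, window_size = 5000,
                      theta = 40, rho = 5, n1 = 5, n2 = 5)
  pm <- read_pop_map(fx$pop_map)
  wins <- read_haplotypes_fasta(fx$fasta, pm, 5000)
  expect_length(wins, 6)
  sc <- scan_windows(wins, scan_config(window_size = 5000))
  for (i in c(1, 3, 6)) {
    s <- distance_summary(wins[[i]], "p_distance")
    expect_equal(sc$gmin[i], gmin(s))
    expect_equal(sc$fst[i], fst_hudson(s))
    expect_equal(sc$mean_dxy[i], s$mean_dxy)
  }
  # identical input scanned twice gives identical output
  sc2 <- scan_fasta(fx$fasta, fx$pop_map, scan_config(window_size = 5000))
  expect_equal(sc, sc2)
})

test_that("vcf windows round-trip to the same statistics as fasta", {
  fx <- make_fixtures(tempfile(), seed = 302, n_windows = 5,
                      migrant_windows = 2, window_size = 4000,
                      theta = 30, rho = 0, n1 = 4, n2 = 4)
  cfg <- scan_config(window_size = 4000)
  sf <- scan_fasta(fx$fasta, fx$pop_map, cfg)
  sv <- scan_vcf(fx$vcf, fx$pop_map, fx$chrom_length, cfg)
  expect_equal(sf$gmin, sv$gmin)
  expect_equal(sf$fst, sv$fst)
  expect_equal(sf$min_dxy, sv$min_dxy, tolerance = 1e-12)
  expect_equal(sf$z_gmin, sv$z_gmin)
})

test_that("missing VCF genotypes yield missing states at that site only", {
  d <- tempfile(); dir.create(d)
  vcf <- file.path(d, "m.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=c1,length=100>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "c1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
               "c1\t20\t.\tA\tT\t.\tPASS\t.\tGT\t.|.\t0|0",
               "c1\t30\t.\tA\tT\t.\tPASS\t.\tGT\t0|0\t1|0"), vcf)
  wins <- read_haplotypes_vcf(vcf, c(s1 = 1, s2 = 2), 100, 100)
  w <- wins[[1]]
  expect_equal(nrow(w$seqs), 4)  # two diploid samples, two haplotypes each
  expect_equal(w$n_invariant, 97L)
  # s1's two haplotypes are missing exactly at the second variant site
  expect_true(all(is.na(w$seqs[1:2, 2])))
  expect_false(anyNA(w$seqs[1:2, c(1, 3)]))
  expect_false(anyNA(w$seqs[3:4, ]))
  # unphased genotypes are rejected
  vcf2 <- file.path(d, "u.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "c1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1|1"), vcf2)
  expect_error(read_haplotypes_vcf(vcf2, c(s1 = 1, s2 = 2), 100, 100),
               "unphased")
})

test_that("low-callability windows are filtered before standardization", {
  set.seed(9)
  L <- 400; n <- 6
  base <- matrix(sample(c("A", "T"), n * 3 * L, replace = TRUE), nrow = n)
  # middle window mostly uncallable
  base[, (L + 1):(2 * L - 20)] <- "N"
  seqs <- setNames(apply(base, 1, paste, collapse = ""),
                   paste0("s", 1:n))
  f <- write_fasta(seqs, tempfile(fileext = ".fa"))
  pm <- setNames(rep(c(1L, 2L), each = 3), names(seqs))
  sc <- scan_fasta(f, pm, scan_config(window_size = L))
  expect_equal(sc$status, c("ok", "filtered", "ok"))
  expect_true(is.na(sc$z_gmin[2]))
  expect_true(is.na(sc$outlier_gmin[2]))
  expect_lt(sc$callable_fraction[2], 0.25)
  # all windows filtered -> scan refuses
  allN <- setNames(rep(paste(rep("N", 50), collapse = ""), 4),
                   paste0("s", 1:4))
  f2 <- write_fasta(allN, tempfile(fileext = ".fa"))
  pm2 <- setNames(c(1L, 1L, 2L, 2L), names(allN))
  expect_error(scan_fasta(f2, pm2, scan_config(window_size = 50)),
               "no windows")
})

test_that("samples absent from the population map are named in errors", {
  seqs <- setNames(c("ACGT", "ACGT", "ACGA"), c("s1", "s2", "mystery"))
  f <- write_fasta(seqs, tempfile(fileext = ".fa"))
  expect_error(read_haplotypes_fasta(f, c(s1 = 1, s2 = 2), 4),
               "mystery")
})

test_that("three-taxon NJ matches the closed-form star solution", {
  m <- additive_tree_mat(list(list(clade = "A", len = 2),
                              list(clade = "B", len = 3),
                              list(clade = "C", len = 4)),
                         c("A", "B", "C"))
  w <- hap_window(m, pop = c(1, 1, 2))
  tr <- nj_window_tree(w, mode = "count")
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 2)
  expect_equal(bl[["B"]], 3)
  expect_equal(bl[["C"]], 4)
})

test_that("NJ recovers hand-built additive four-taxon trees exactly", {
  taxa <- c("A", "B", "C", "D")
  m <- additive_tree_mat(list(list(clade = "A", len = 1),
                              list(clade = "B", len = 2),
                              list(clade = "C", len = 3),
                              list(clade = "D", len = 4),
                              list(clade = c("A", "B"), len = 2)),
                         taxa)
  w <- hap_window(m, pop = c(1, 1, 2, 2))
  tr <- nj_window_tree(w, mode = "count")
  # generating topology: AB | CD split
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  # additive distances are reproduced exactly along the tree paths
  path_d <- ape::cophenetic.phylo(tr)[taxa, taxa]
  h <- gminscan:::.hamming_counts_cpp(w$seqs)$diff
  dimnames(h) <- list(taxa, taxa)
  expect_equal(path_d, h, tolerance = 1e-12)
})

test_that("an introgressed haplotype nests inside the donor clade", {
  set.seed(77)
  S <- 200
  donor_core <- sample(c("0", "1"), S, replace = TRUE)
  pop1 <- t(vapply(1:5, function(i) {
    x <- sample(c("0", "1"), S, replace = TRUE); x
  }, character(S)))
  pop2 <- t(vapply(1:4, function(i) {
    x <- donor_core; flip <- sample(S, 3)
    x[flip] <- ifelse(x[flip] == "0", "1", "0"); x
  }, character(S)))
  migrant <- donor_core; flip <- sample(S, 2)
  migrant[flip] <- ifelse(migrant[flip] == "0", "1", "0")
  m <- rbind(pop1, migrant, pop2)
  rownames(m) <- c(paste0("p1_", 1:5), "RG_mig", paste0("p2_", 1:4))
  w <- hap_window(m, pop = c(rep(1, 6), rep(2, 4)))
  tr <- nj_window_tree(w, mode = "count")
  cd <- ape::cophenetic.phylo(tr)
  to_donor <- mean(cd["RG_mig", paste0("p2_", 1:4)])
  to_own <- mean(cd["RG_mig", paste0("p1_", 1:5)])
  expect_lt(to_donor, to_own)
  expect_true(ape::is.monophyletic(ape::unroot(tr),
                                   c("RG_mig", paste0("p2_", 1:4))))
  # fewer than three sequences cannot be joined
  expect_error(nj_window_tree(hap_window(m[1:2, ], pop = c(1, 2))),
               ">= 3")
  # clamped trees never carry negative branch lengths
  expect_true(all(tr$edge.length >= 0))
})
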