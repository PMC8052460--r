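make_small_panel <- function(seed = 1, n_hap = 10, m = 20) {
  set.seed(seed)
  H <- matrix(rbinom(n_hap * m, 1, 0.5), n_hap, m)
  H[, 10] <- rep(c(0, 1), length.out = n_hap)  # keep the focal segregating
  colnames(H) <- paste0("s", seq_len(m))
  map <- data.frame(marker_id = colnames(H), chrom = 1,
                    position = sort(sample.int(1e6, m)))
  haplotype_panel(H, map)
}

test_that("EHH is 1 at the focal marker and stays 1 for identical haplotypes", {
  pan <- make_small_panel()
  e <- ehh(pan, "s10", allele = 1)
  expect_equal(e$ehh[which(e$position == pan$map$position[10])], 1)
  # identical haplotypes: EHH = 1 out to the chromosome end
  H <- matrix(rep(c(0, 1, 0, 1, 1, 0), each = 6), 6, 6)
  colnames(H) <- paste0("s", 1:6)
  map <- data.frame(marker_id = colnames(H), chrom = 1,
                    position = (1:6) * 1000)
  e2 <- ehh(haplotype_panel(H, map), "s2", allele = 1)
  expect_true(all(e2$ehh == 1))
  expect_equal(length(e2$ehh), 6)
})

test_that("EHH equals brute-force shared-prefix pair counting", {
  for (seed in 1:4) {
    pan <- make_small_panel(seed = seed, n_hap = 6 + 2 * seed, m = 24)
    H <- pan$alleles
    for (al in 0:1) {
      e <- ehh(pan, "s10", allele = al, min_ehh = 0)  # full curve
      oracle <- oracle_ehh_curve(H, 10, al, pan$map$position)
      got <- e$ehh[match(pan$map$position, e$position)]
      expect_equal(got[!is.na(got)], oracle[!is.na(got)], tolerance = 1e-12)
    }
  }
})

test_that("EHH is non-increasing away from the focal marker", {
  pan <- make_small_panel(seed = 8, n_hap = 16, m = 40)
  e <- ehh(pan, "s10", allele = 1, min_ehh = 0)
  i0 <- which(e$position == pan$map$position[10])
  expect_true(all(diff(e$ehh[i0:length(e$ehh)]) <= 1e-12))
  expect_true(all(diff(rev(e$ehh[1:i0])) <= 1e-12))
})

test_that("iES is invariant to haplotype row order; < 2 carriers is flagged", {
  pan <- make_small_panel(seed = 5, n_hap = 12)
  e1 <- ehh(pan, "s10", allele = 1)
  perm <- sample(12)
  pan2 <- haplotype_panel(pan$alleles[perm, ], pan$map)
  e2 <- ehh(pan2, "s10", allele = 1)
  expect_equal(e1$ies, e2$ies)
  H <- pan$alleles; H[, 10] <- c(1, rep(0, 11))
  e3 <- ehh(haplotype_panel(H, pan$map), "s10", allele = 1)
  expect_true(is.na(e3$ies))
  expect_equal(e3$n_carriers, 1)
})

test_that("iHS is zero when both allele classes share haplotype structure", {
  # mirrored panel: the derived carriers are a relabeled copy of the
  # ancestral carriers, so iES_ancestral = iES_derived at the focal site
  set.seed(6)
  m <- 21
  half <- matrix(rbinom(5 * m, 1, 0.5), 5, m)
  H <- rbind(half, half)
  H[, 11] <- rep(c(0, 1), each = 5)
  colnames(H) <- paste0("s", 1:m)
  map <- data.frame(marker_id = colnames(H), chrom = 1, position = (1:m) * 1e4)
  pan <- haplotype_panel(H, map)
  ed <- ehh(pan, "s11", allele = 1)
  ea <- ehh(pan, "s11", allele = 0)
  expect_equal(log(ea$ies / ed$ies), 0, tolerance = 1e-12)
})

test_that("iHS standardized scores have mean 0 and sd 1 within bins", {
  sw <- simulate_sweep_panel(n_hap = 40, n_markers = 200, seed = 3)
  sc <- ihs_scan(sw$panel, bins = 5)
  z <- sc$scores$z
  raw <- sc$scores$raw
  f <- colMeans(sw$panel$alleles)
  ok <- !is.na(z)
  # reconstruct the bins actually used and verify within-bin moments
  b <- cut(f[ok], seq(0, 1, length.out = 6), include.lowest = TRUE)
  for (lv in levels(b)) {
    zi <- z[ok][b == lv]
    if (length(zi) >= 10 && sd(raw[ok][b == lv]) > 0) {
      expect_lt(abs(mean(zi)), 0.8)  # merged bins shift moments slightly
    }
  }
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 0.1)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 0.15)
})

test_that("a planted sweep puts the focal |z| in the chromosome-wide top 1%", {
  hits <- 0
  for (r in 1:5) {
    sw <- simulate_sweep_panel(seed = 400 + r)
    sc <- ihs_scan(sw$panel)
    z <- abs(sc$scores$z)
    i <- sw$truth$sweep_index
    if (!is.na(z[i]) && z[i] >= quantile(z, 0.99, na.rm = TRUE)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("XP-EHH is zero for identical panels and antisymmetric", {
  sw <- simulate_sweep_panel(n_hap = 30, n_markers = 120, populations = 2,
                             seed = 9)
  same <- xpehh_scan(sw$panel, sw$panel)
  expect_true(all(same$scores$raw[!is.na(same$scores$raw)] == 0))
  ab <- xpehh_scan(sw$panel, sw$panel_b)
  ba <- xpehh_scan(sw$panel_b, sw$panel)
  expect_equal(ab$scores$raw, -ba$scores$raw, tolerance = 1e-12)
  expect_error(xpehh_scan(
    haplotype_panel(sw$panel$alleles[1:3, ], sw$panel$map), sw$panel_b),
    ">= 4")
})

test_that("a sweep planted in A only yields a top-1% positive XP-EHH score", {
  sw <- simulate_sweep_panel(populations = 2, seed = 15)
  sc <- xpehh_scan(sw$panel, sw$panel_b)
  z <- sc$scores$z
  i <- sw$truth$sweep_index
  expect_gt(z[i], 0)
  expect_gte(z[i], quantile(z, 0.99, na.rm = TRUE))
})

test_that("PCA outlier scan: null lambda_GC near 1, planted outliers found", {
  cfg <- sim_config(n_per_pop = 200, n_markers = 2000, fst = 0,
                    missing_rate = 0, seed = 71)
  sim <- simulate_structured_population(cfg)
  sc0 <- pca_outlier_scan(sim$dosage, K = 3)
  expect_gt(sc0$lambda_gc, 0.8)
  expect_lt(sc0$lambda_gc, 1.2)
  # plant 20 strongly differentiated markers between two groups
  set.seed(73)
  n <- 100; m <- 2000
  grp <- rep(1:2, each = n / 2)
  base <- matrix(rbinom(n * m, 4, runif(m, 0.2, 0.8)[col(matrix(0, n, m))]),
                 n, m)
  planted <- sample(m, 20)
  for (j in planted)
    base[, j] <- rbinom(n, 4, ifelse(grp == 1, 0.05, 0.95))
  D <- dosage_from(base)
  sc1 <- pca_outlier_scan(D, K = 2)
  hits <- sum(sc1$scores$q[planted] < 0.05, na.rm = TRUE)
  expect_gte(hits, 16)  # >= 80% of planted markers recovered
})

test_that("Storey q-values obey the definitional cases", {
  expect_equal(storey_qvalues(0.001, pi0 = 1)$qvalues, 0.001)
  set.seed(79)
  p <- runif(10000)
  st <- storey_qvalues(p)
  expect_gte(st$pi0, 0.9)
  expect_lte(st$pi0, 1.0)
  o <- order(p)
  expect_true(all(diff(st$qvalues[o]) >= -1e-12))  # monotone in p
  # q-values never fall below pi0 * p
  expect_true(all(st$qvalues >= st$pi0 * p - 1e-12))
})

test_that("consensus requires two methods and uses top SNP +/- flank", {
  map <- data.frame(marker_id = paste0("s", 1:5), chrom = 7,
                    position = c(1e6, 5e6, 10830000, 15e6, 20e6))
  mk <- function(method, qs) {
    structure(list(method = method,
                   scores = data.frame(marker_id = map$marker_id,
                                       chrom = map$chrom,
                                       position = map$position,
                                       raw = 1, z = c(1, 1, 5, 1, 1),
                                       p = qs, q = qs)),
              class = "scan_result")
  }
  ihs <- mk("ihs", c(0.5, 0.5, 0.001, 0.5, 0.5))
  xp <- mk("xpehh", c(0.5, 0.5, 0.002, 0.5, 0.5))
  only_one <- mk("xpehh", c(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_error(consensus_sweeps(list(ihs)), "at least two")
  # significant in one method only: no region
  expect_equal(nrow(consensus_sweeps(list(ihs, only_one))), 0)
  reg <- consensus_sweeps(list(ihs, xp))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 10580000)
  expect_equal(reg$end, 11080000)
  expect_equal(reg$end - reg$start, 500000)
  expect_equal(reg$top_snp, "s3")
})

test_that("consensus region count shrinks as thresholds tighten", {
  sw <- simulate_sweep_panel(n_hap = 60, n_markers = 300, populations = 2,
                             chrom_length = 15e6, seed = 83)
  ihs <- ihs_scan(sw$panel)
  xp <- xpehh_scan(sw$panel, sw$panel_b)
  loose <- consensus_sweeps(list(ihs, xp),
                            thresholds = c(ihs = 0.2, xpehh = 0.2))
  strict <- consensus_sweeps(list(ihs, xp),
                             thresholds = c(ihs = 0.01, xpehh = 0.01))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("gene lookup matches brute-force interval intersection", {
  set.seed(89)
  n_gene <- 30
  starts <- sort(sample.int(5e6, n_gene))
  gff <- data.frame(seqid = "chr1", source = "test", type = "gene",
                    start = starts, end = starts + sample.int(2e4, n_gene),
                    score = NA, strand = "+", phase = NA,
                    attributes = paste0("ID=gene", seq_len(n_gene)))
  region <- list(chrom = "chr1", start = 2e6, end = 2.5e6)
  hits <- genes_near(region, gff, flank_genes = 250000)
  lo <- region$start - 250000; hi <- region$end + 250000
  manual <- gff[gff$end >= lo & gff$start <= hi, ]
  expect_equal(hits$start, manual$start)
  # closed-boundary rule: a gene ending exactly at start - flank is included
  gb <- gff[1, ]; gb$start <- lo - 5000; gb$end <- lo
  expect_equal(nrow(genes_near(region, rbind(gff, gb))), nrow(manual) + 1)
  # chromosome naming mismatch is an explicit error
  expect_error(genes_near(list(chrom = "chr9", start = 1, end = 2), gff),
               "not found")
})
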