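test_that("Nei distance matches hand evaluation and the pair oracle", {
  # two clones, two loci: A = [4,4], B = [2,2] gives D = -ln(1/sqrt(2))
  D <- dosage_from(rbind(A = c(4, 4), B = c(2, 2)))
  dm <- nei_distance_matrix(D)
  expect_equal(dm["A", "B"], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(dm["A", "B"], 0.3466, tolerance = 1e-4)
  # 6-clone toy against the literal per-pair formula, with missing data
  set.seed(2)
  mat <- matrix(rbinom(6 * 30, 4, 0.4), 6, 30)
  mat[sample(length(mat), 8)] <- NA
  D6 <- dosage_from(mat)
  dm6 <- nei_distance_matrix(D6)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(dm6[i, j], oracle_nei_pair(mat[i, ], mat[j, ]),
                 tolerance = 1e-12)
})

test_that("Nei distance is zero iff rows are identical, and permutation-equivariant", {
  set.seed(3)
  mat <- matrix(rbinom(5 * 40, 4, 0.5), 5, 40)
  mat[5, ] <- mat[1, ]  # planted duplicate
  D <- dosage_from(mat)
  dm <- nei_distance_matrix(D)
  expect_equal(dm[1, 5], 0)
  off <- dm[upper.tri(dm)]
  expect_true(all(off >= 0))
  expect_equal(sum(off == 0), 1)  # only the planted twin pair
  perm <- c(3, 1, 5, 2, 4)
  dmp <- nei_distance_matrix(dosage_from(mat[perm, ]))
  expect_equal(matrix(dmp, 5), matrix(dm[perm, perm], 5), tolerance = 1e-12)
})

test_that("Ward tree merges the nearest pair first and twins at height zero", {
  dm <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- ward_tree(dm)
  hc <- attr(tr, "hclust")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # {A,B} merged first
  # duplicated clone merges at height 0
  dm2 <- matrix(0.5, 4, 4); diag(dm2) <- 0
  dm2[1, 2] <- dm2[2, 1] <- 0
  dimnames(dm2) <- list(letters[1:4], letters[1:4])
  hc2 <- attr(ward_tree(dm2), "hclust")
  expect_equal(hc2$height[1], 0)
  expect_error(ward_tree({dm2[1, 3] <- NA; dm2}), "missing")
})

test_that("cutting the Ward tree recovers simulated groups", {
  sim <- make_toy_panel(seed = 13, n_per_pop = c(4, 4, 4), m = 500, fst = 0.25)
  dm <- nei_distance_matrix(sim$dosage)
  hc <- attr(ward_tree(dm), "hclust")
  grp <- cutree(hc, 3)
  tab <- table(grp, sim$truth$pop)
  expect_equal(sum(apply(tab, 2, max)), 12)  # perfect recovery up to labels
})

test_that("curation flags injected duplicates and mislabels", {
  cfg <- sim_config(n_per_pop = c(25, 25, 25), n_markers = 500, fst = 0.20,
                    missing_rate = 0, seed = 17,
                    n_duplicates = 2, n_mislabels = 5, n_diploid = 0)
  sim <- inject_anomalies(simulate_structured_population(cfg), cfg)
  dm <- nei_distance_matrix(sim$dosage)
  cur <- detect_duplicates_and_mislabels(dm, sim$panel)
  anom <- sim$truth$anomalies
  dups <- anom$clone_id[anom$type == "duplicate"]
  found_pairs <- c(cur$duplicates$clone_a, cur$duplicates$clone_b)
  expect_true(all(dups %in% found_pairs))
  mis <- anom$clone_id[anom$type == "mislabel"]
  expect_gte(sum(mis %in% cur$mislabels$clone_id), 4)
})

test_that("BIC scan picks K = 1 for one blob and K = 3 for three groups", {
  set.seed(31)
  blob <- matrix(rbinom(40 * 200, 4, 0.4), 40, 200)
  km1 <- kmeans_bic_scan(dosage_from(blob), k_max = 5, seed = 1)
  expect_equal(km1$K, 1)
  sim <- make_toy_panel(seed = 19, n_per_pop = c(25, 25, 25), m = 600,
                        fst = 0.15)
  km3 <- kmeans_bic_scan(sim$dosage, k_max = 6, seed = 1)
  expect_equal(km3$K, 3)
  tab <- table(km3$assignments, sim$truth$pop)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.95)
})

test_that("BIC scan is reproducible and invariant to marker order", {
  sim <- make_toy_panel(seed = 23, n_per_pop = c(15, 15), m = 300, fst = 0.15)
  a <- kmeans_bic_scan(sim$dosage, k_max = 4, seed = 9)
  b <- kmeans_bic_scan(sim$dosage, k_max = 4, seed = 9)
  expect_identical(a$bic, b$bic)
  expect_identical(a$assignments, b$assignments)
  perm <- sample(ncol(sim$dosage))
  Dp <- dosage_matrix(sim$dosage[, perm], ploidy = 4)
  cc <- kmeans_bic_scan(Dp, k_max = 4, seed = 9)
  expect_equal(cc$K, a$K)
})

test_that("DAPC separates groups, rows of Q sum to 1, n_da = groups - 1", {
  sim <- make_toy_panel(seed = 29, n_per_pop = c(20, 20, 20), m = 500,
                        fst = 0.20)
  fit <- dapc_fit(sim$dosage, sim$truth$pop, n_pca = 10)
  expect_equal(unname(rowSums(fit$Q)), rep(1, 60), tolerance = 1e-9)
  expect_equal(fit$n_da, 2)
  expect_gte(mean(apply(fit$Q, 1, max)), 0.99)
  expect_error(dapc_fit(sim$dosage, sim$truth$pop, n_pca = 58), "n_pca")
})

test_that("a clone midway between group centroids gets an uncertain membership", {
  sim <- make_toy_panel(seed = 37, n_per_pop = c(30, 30), m = 400, fst = 0.06)
  fit <- dapc_fit(sim$dosage, sim$truth$pop, n_pca = 10)
  mu <- apply(fit$scores, 2, tapply, fit$groups, mean)
  midpoint <- (mu["1", ] + mu["2", ]) / 2
  post <- predict(fit$lda, rbind(midpoint))$posterior
  expect_lt(max(post), 0.6)
})

test_that("cross-validation returns the most parsimonious perfect n_pca", {
  set.seed(41)
  m <- 200
  g1 <- matrix(rbinom(25 * m, 4, 0.2), 25, m)
  g2 <- matrix(rbinom(25 * m, 4, 0.8), 25, m)
  D <- dosage_from(rbind(g1, g2))
  grp <- rep(1:2, each = 25)
  cv <- dapc_crossval(D, grp, n_pca_grid = 1:8, reps = 10, seed = 5)
  expect_equal(cv$n_pca, 1)  # zero-overlap clouds: 1 PC already perfect
  expect_equal(unname(cv$rmse[1]), 0)
})

test_that("cross-validation accuracy is near chance on noise", {
  set.seed(43)
  D <- dosage_from(matrix(rbinom(40 * 150, 4, 0.5), 40, 150))
  grp <- rep(1:2, each = 20)
  cv <- dapc_crossval(D, grp, n_pca_grid = c(2, 5), reps = 20, seed = 7)
  # RMSE of (1 - success) should hover near 0.5, far from separation (0)
  expect_gt(min(cv$rmse), 0.25)
})

test_that("snpzip returns the dominant-loading markers", {
  sim <- make_toy_panel(seed = 47, n_per_pop = c(15, 15), m = 60, fst = 0.05)
  fit <- dapc_fit(sim$dosage, sim$truth$pop, n_pca = 5)
  fit$loadings[, 1] <- c(0.9, 0.01, 0.02, 0.015, rep(0.012, 56))
  rownames(fit$loadings) <- colnames(sim$dosage)
  expect_identical(snpzip_select(fit, 1), colnames(sim$dosage)[1])
  fit$loadings[, 1] <- rep(0.1, 60)
  expect_warning(out <- snpzip_select(fit, 1), "no discriminating")
  expect_length(out, 0)
})

test_that("snpzip recovers planted high-effect markers", {
  set.seed(53)
  m <- 200; n <- 30
  base <- matrix(rbinom(n * m, 4, 0.5), n, m)
  grp <- rep(1:2, each = 15)
  planted <- 1:10
  for (j in planted) base[, j] <- rbinom(n, 4, ifelse(grp == 1, 0.05, 0.95))
  D <- dosage_from(base)
  fit <- dapc_fit(D, grp, n_pca = 5)
  sel <- snpzip_select(fit, 1)
  expect_true(all(colnames(D)[planted] %in% sel))
  expect_lte(length(sel), 3 * length(planted))
})

test_that("Fst is near zero within one population and near F for Balding-Nichols", {
  cfg0 <- sim_config(n_per_pop = c(100, 100), n_markers = 2000, fst = 0,
                     missing_rate = 0, seed = 59)
  sim0 <- simulate_structured_population(cfg0)
  f0 <- pairwise_fst(sim0$dosage, sim0$truth$pop)$fst
  expect_lt(abs(f0), 0.01)
  cfg1 <- sim_config(n_per_pop = c(100, 100), n_markers = 2000, fst = 0.10,
                     missing_rate = 0, seed = 61)
  sim1 <- simulate_structured_population(cfg1)
  f1 <- pairwise_fst(sim1$dosage, sim1$truth$pop)$fst
  expect_lt(abs(f1 - 0.10), 0.03)
})

test_that("Fst is invariant to global allele relabeling", {
  sim <- make_toy_panel(seed = 67, n_per_pop = c(20, 20), m = 400, fst = 0.1)
  f_ab <- pairwise_fst(sim$dosage, sim$truth$pop)$fst
  flipped <- dosage_matrix(4 - unclass(sim$dosage), ploidy = 4)
  f_ba <- pairwise_fst(flipped, sim$truth$pop)$fst
  expect_equal(f_ab, f_ba, tolerance = 1e-12)
})
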