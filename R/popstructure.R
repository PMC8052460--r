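#' Nei's (1972) standard genetic distance between clones
#'
#' Each clone's genotype at a biallelic locus gives allele frequencies
#' (x, 1-x) with x = dosage / ploidy. For a pair of clones the distance is
#' D = -ln( Jxy / sqrt(Jx * Jy) ), where Jxy, Jx, Jy are the means over
#' shared (pairwise non-missing) loci of the cross- and within-clone
#' probabilities of allele identity. Identical clones get distance 0; a pair
#' sharing no non-missing locus gets NA.
#'
#' @param D a [dosage_matrix()].
#' @return symmetric matrix of class `nei_dist` with zero diagonal and a
#'   `metric` attribute `"nei1972"`.
#' @export
nei_distance_matrix <- function(D) {
  X <- unclass(D) / ploidy_of(D)        # B-allele frequency within clone
  M <- !is.na(X)
  X0 <- ifelse(M, X, 0)
  Y0 <- ifelse(M, 1 - X, 0)
  Cnt <- M %*% t(M)                     # shared-locus counts
  Jxy <- (X0 %*% t(X0) + Y0 %*% t(Y0)) / Cnt
  Sj <- ifelse(M, X^2 + (1 - X)^2, 0)   # within-clone identity per locus
  Jx <- (Sj %*% t(M)) / Cnt             # mean over loci shared with the other
  d <- -log(Jxy / sqrt(Jx * t(Jx)))
  d[Cnt == 0] <- NA_real_
  d[d < 0 & d > -1e-12] <- 0            # numerical guard
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(D), rownames(D))
  structure(d, metric = "nei1972", class = c("nei_dist", "matrix"))
}

#' Ward dendrogram from a distance matrix
#'
#' Hierarchical clustering with the classical Ward criterion ("ward.D":
#' distances used as given, not squared), returned as an `ape` phylogeny so
#' it can be written to newick.
#'
#' @param dm a square distance matrix (e.g. [nei_distance_matrix()]).
#' @param method `"ward.D"` (default, classical convention) or `"ward.D2"`.
#' @return an object of class `phylo`, with the `hclust` fit in attribute
#'   `hclust`.
#' @export
ward_tree <- function(dm, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  if (anyNA(dm)) stop("distance matrix has missing cells")
  hc <- hclust(as.dist(dm), method = method)
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Flag duplicate and mislabeled clones
#'
#' Duplicates are pairs closer than `dup_threshold` on the distance matrix
#' ("almost zero" distance). Mislabel candidates are clones whose declared
#' market class disagrees with the composition of their group when the Ward
#' tree is cut into `k` clusters: a clone is flagged when its declared class
#' is essentially absent from its own group (within-group fraction below
#' `own_floor`, excluding the clone itself) yet well represented in another
#' group — e.g. a lone russet-labeled clone clustering with the reds.
#' Classes legitimately shared between groups are not flagged.
#'
#' @param dm distance matrix.
#' @param panel clone metadata data.frame (clone_id, market_class).
#' @param dup_threshold distance below which a pair is called a duplicate
#'   (default 0.001).
#' @param tree optional [ward_tree()] result; recomputed from `dm` if NULL.
#' @param k number of tree clusters used for the composition rule (default 3).
#' @param own_floor within-group class fraction below which the declared
#'   class counts as absent (default 0.05).
#' @param other_min representation the class must reach in some other group
#'   for the clone to be flagged (default 0.10).
#' @return a `curation_report`: data.frames `duplicates` (clone_a, clone_b,
#'   distance) and `mislabels` (clone_id, declared, majority, cluster).
#' @export
detect_duplicates_and_mislabels <- function(dm, panel, dup_threshold = 0.001,
                                            tree = NULL, k = 3,
                                            own_floor = 0.05,
                                            other_min = 0.10) {
  stopifnot(dup_threshold >= 0)
  ids <- rownames(dm)
  lower <- which(lower.tri(dm) & dm < dup_threshold, arr.ind = TRUE)
  duplicates <- data.frame(
    clone_a = ids[lower[, 2]], clone_b = ids[lower[, 1]],
    distance = dm[lower])
  hc <- if (!is.null(tree)) attr(tree, "hclust") else
    hclust(as.dist(dm), method = "ward.D")
  grp <- cutree(hc, k = k)
  cls <- panel$market_class[match(ids, panel$clone_id)]
  groups <- sort(unique(grp))
  class_freq <- function(x, g, exclude = NULL) {
    in_g <- grp == g & !(ids %in% exclude)
    if (!sum(in_g)) return(0)
    mean(cls[in_g] == x)
  }
  class_count <- function(x, g, exclude = NULL)
    sum(grp == g & cls == x & !(ids %in% exclude))
  mis <- list()
  for (i in seq_along(ids)) {
    g <- grp[i]; x <- cls[i]
    f_own <- class_freq(x, g, exclude = ids[i])
    n_own <- class_count(x, g, exclude = ids[i])
    f_other <- vapply(setdiff(groups, g), function(h) class_freq(x, h),
                      numeric(1))
    if (length(f_other) && (f_own < own_floor || n_own <= 1) &&
        max(f_other) >= other_min) {
      best <- setdiff(groups, g)[which.max(f_other)]
      mis[[ids[i]]] <- data.frame(
        clone_id = ids[i], declared = x, cluster = g,
        own_class_freq = f_own, best_other_cluster = best,
        other_class_freq = max(f_other))
    }
  }
  mislabels <- if (length(mis)) do.call(rbind, c(mis, make.row.names = FALSE))
  else data.frame(clone_id = character(), declared = character(),
                  cluster = integer(), own_class_freq = numeric(),
                  best_other_cluster = integer(),
                  other_class_freq = numeric())
  structure(list(duplicates = duplicates, mislabels = mislabels,
                 dup_threshold = dup_threshold, k = k),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("Curation: %d duplicate pairs (d < %g), %d mislabel candidates (k = %d)\n",
              nrow(x$duplicates), x$dup_threshold, nrow(x$mislabels), x$k))
  invisible(x)
}

# Mean-imputed, diploidized numeric matrix for PCA-based methods.
numeric_genotypes <- function(D) {
  if (ploidy_of(D) == 4L) D <- diploidize(D)
  X <- unclass(D)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X
}

# k-means++ seeding: spread initial centers, then polish with stats::kmeans.
kmeanspp <- function(X, k, iter.max = 50) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1, prob = pr), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers <- unique(centers)
  kmeans(X, centers = centers, iter.max = iter.max)
}

#' K-means / BIC scan for the number of subpopulations
#'
#' PCA of the centered (diploidized, mean-imputed) dosage matrix, then
#' K-means on the retained principal components for K = 1..`k_max`, each with
#' `restarts` k-means++ starts. BIC(K) = n ln(WSS_K / n) + K ln(n); the
#' selected K minimizes BIC, with ties broken toward smaller K.
#'
#' @param D a [dosage_matrix()].
#' @param k_max largest K scanned (default 10).
#' @param n_pca number of principal components retained (default
#'   min(n - 1, 50)).
#' @param seed RNG seed (mandatory; the scan is deterministic given it).
#' @param restarts k-means++ restarts per K (default 25).
#' @return a `cluster_model`: K, BIC table, hard assignments at the selected
#'   K, PC scores.
#' @export
kmeans_bic_scan <- function(D, k_max = 10, n_pca = NULL, seed, restarts = 25) {
  stopifnot(k_max >= 2)
  if (missing(seed)) stop("seed is required")
  n <- nrow(D)
  if (k_max >= n) stop("k_max must be < number of clones")
  X <- numeric_genotypes(D)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  if (is.null(n_pca)) n_pca <- min(n - 1, 50)
  n_pca <- min(n_pca, ncol(pc$x))
  S <- pc$x[, seq_len(n_pca), drop = FALSE]
  set.seed(seed)
  bic <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    best <- NULL
    for (r in seq_len(if (k == 1) 1 else restarts)) {
      fit <- if (k == 1) kmeans(S, centers = 1) else kmeanspp(S, k)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    fits[[k]] <- best
    bic[k] <- n * log(best$tot.withinss / n) + k * log(n)
  }
  K <- which.min(bic)  # which.min returns the first (smallest K) minimum
  structure(list(k_values = seq_len(k_max), bic = bic, K = K,
                 assignments = setNames(fits[[K]]$cluster, rownames(D)),
                 scores = S, n_pca = n_pca, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("K-means/BIC scan over K = 1..%d on %d PCs: selected K = %d\n",
              max(x$k_values), x$n_pca, x$K))
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant analysis on `n_pca` retained principal components of
#' the (diploidized, mean-imputed) genotypes, describing between-group
#' structure. Membership probabilities come from the Gaussian posteriors in
#' discriminant space; discriminant loadings are mapped back to markers
#' through the PCA rotation.
#'
#' @param D a [dosage_matrix()].
#' @param assignments group factor or vector, one entry per clone (e.g. from
#'   [kmeans_bic_scan()]).
#' @param n_pca principal components retained; must be < n - number of groups
#'   (overfit guard). Default min(n - groups - 1, 20).
#' @param n_da discriminant axes retained (at most groups - 1, the default).
#' @return a `dapc_model`: n_pca, variance fraction captured, n_da,
#'   membership matrix `Q` (rows sum to 1), per-marker `loadings` (one column
#'   per discriminant axis), clone discriminant coordinates `ld`.
#' @export
dapc_fit <- function(D, assignments, n_pca = NULL, n_da = NULL) {
  grp <- factor(assignments)
  n <- nrow(D)
  g <- nlevels(grp)
  stopifnot(length(grp) == n, g >= 2)
  if (is.null(n_pca)) n_pca <- max(1, min(n - g - 1, 20))
  if (n_pca >= n - g) stop("n_pca must be < n - number of groups")
  X <- numeric_genotypes(D)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  n_pca <- min(n_pca, ncol(pc$x))
  varfrac <- sum(pc$sdev[seq_len(n_pca)]^2) / sum(pc$sdev^2)
  S <- pc$x[, seq_len(n_pca), drop = FALSE]
  fit <- MASS::lda(S, grouping = grp)
  if (is.null(n_da)) n_da <- g - 1
  n_da <- min(n_da, g - 1, ncol(fit$scaling))
  pred <- predict(fit, S)
  load <- pc$rotation[, seq_len(n_pca), drop = FALSE] %*%
    fit$scaling[, seq_len(n_da), drop = FALSE]
  structure(list(n_pca = n_pca, var_fraction = varfrac, n_da = n_da,
                 groups = grp, Q = pred$posterior,
                 ld = pred$x[, seq_len(n_da), drop = FALSE],
                 loadings = load, lda = fit, scores = S,
                 rotation = pc$rotation, center = pc$center),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("DAPC: %d PCs (%.1f%% variance), %d discriminant axes, %d groups\n",
              x$n_pca, 100 * x$var_fraction, x$n_da, nlevels(x$groups)))
  invisible(x)
}

#' Cross-validation for the number of retained PCs in DAPC
#'
#' For each candidate number of PCs, repeatedly holds out a stratified
#' `holdout` fraction (every group keeps at least one member in the training
#' set; singleton groups are pinned to training with a warning), fits the
#' discriminant analysis on the training set and scores assignment success
#' on the held-out clones. The root mean squared error over replicates,
#' RMSE = sqrt(mean((1 - success rate)^2)), is minimized; ties go to the
#' smallest (most parsimonious) n_pca.
#'
#' @param D a [dosage_matrix()].
#' @param groups group factor or vector.
#' @param n_pca_grid candidate numbers of PCs (default 1..min(n-g-1, 30)).
#' @param reps replicates per candidate (default 30).
#' @param holdout held-out fraction (default 0.10).
#' @param seed RNG seed.
#' @return list: `n_pca` (the argmin), `rmse` (named vector over the grid).
#' @export
dapc_crossval <- function(D, groups, n_pca_grid = NULL, reps = 30,
                          holdout = 0.10, seed) {
  if (missing(seed)) stop("seed is required")
  grp <- factor(groups)
  n <- nrow(D)
  g <- nlevels(grp)
  if (is.null(n_pca_grid)) n_pca_grid <- seq_len(max(1, min(n - g - 1, 30)))
  sizes <- table(grp)
  if (any(sizes == 1))
    warning("groups with a single member are pinned to the training set: ",
            paste(names(sizes)[sizes == 1], collapse = ", "))
  X <- numeric_genotypes(D)
  set.seed(seed)
  rmse <- setNames(numeric(length(n_pca_grid)), n_pca_grid)
  splits <- lapply(seq_len(reps), function(r) {
    hold <- unlist(lapply(levels(grp), function(lv) {
      idx <- which(grp == lv)
      n_h <- min(length(idx) - 1, max(0, round(holdout * length(idx))))
      if (n_h > 0) sample(idx, n_h) else integer(0)
    }))
    hold
  })
  for (j in seq_along(n_pca_grid)) {
    np <- n_pca_grid[j]
    err <- vapply(splits, function(hold) {
      if (!length(hold)) return(0)
      tr <- setdiff(seq_len(n), hold)
      pc <- prcomp(X[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
      npj <- min(np, ncol(pc$x), length(tr) - g)
      Str <- pc$x[, seq_len(npj), drop = FALSE]
      fit <- MASS::lda(Str, grouping = grp[tr])
      Sho <- scale(X[hold, , drop = FALSE], center = pc$center,
                   scale = FALSE) %*% pc$rotation[, seq_len(npj), drop = FALSE]
      acc <- mean(predict(fit, Sho)$class == grp[hold])
      1 - acc
    }, numeric(1))
    rmse[j] <- sqrt(mean(err^2))
  }
  list(n_pca = n_pca_grid[which.min(rmse)], rmse = rmse)
}

#' Select the markers driving a discriminant axis
#'
#' Splits the absolute marker loadings of one discriminant axis into two
#' groups by Ward clustering and returns the high-loading group — the
#' markers contributing most to cluster identification.
#'
#' @param model a [dapc_fit()] result.
#' @param axis discriminant axis index (default 1).
#' @return character vector of selected marker ids (empty, with a warning,
#'   when the loadings carry no structure).
#' @export
snpzip_select <- function(model, axis = 1) {
  stopifnot(inherits(model, "dapc_model"))
  if (axis < 1 || axis > ncol(model$loadings)) stop("axis out of range")
  w <- abs(model$loadings[, axis])
  if (diff(range(w)) < .Machine$double.eps^0.5) {
    warning("all loadings equal; no discriminating markers")
    return(character(0))
  }
  hc <- hclust(dist(w), method = "ward.D")
  grp <- cutree(hc, k = 2)
  means <- tapply(w, grp, mean)
  names(w)[grp == names(which.max(means))]
}

#' Pairwise Weir-Cockerham Fst between groups
#'
#' Moment estimator of the coefficient of genetic differentiation from group
#' allele frequencies and sample sizes, counting `ploidy` alleles per clone,
#' combined across markers as a ratio of sums. Groups with fewer than 2
#' clones are excluded with a warning.
#'
#' @param D a [dosage_matrix()].
#' @param groups group factor or vector, one entry per clone.
#' @return data.frame (group_a, group_b, fst) of class `fst_table`.
#' @export
pairwise_fst <- function(D, groups) {
  grp <- factor(groups)
  stopifnot(length(grp) == nrow(D))
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("groups excluded (size < 2): ", paste(small, collapse = ", "))
    keep <- !(grp %in% small)
    D <- dosage_matrix(D[keep, , drop = FALSE], ploidy = ploidy_of(D))
    grp <- droplevels(grp[keep])
  }
  if (nlevels(grp) < 2) stop("need at least two groups of size >= 2")
  pl <- ploidy_of(D)
  lv <- levels(grp)
  pairs <- combn(lv, 2)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    fst = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    out$fst[k] <- wc_fst_pair(D, grp, pairs[1, k], pairs[2, k], pl)
  }
  class(out) <- c("fst_table", "data.frame")
  out
}

# Two-population Weir-Cockerham theta from allele counts, ratio of sums.
wc_fst_pair <- function(D, grp, a, b, pl) {
  Da <- D[grp == a, , drop = FALSE]
  Db <- D[grp == b, , drop = FALSE]
  n1 <- pl * colSums(!is.na(Da)); n2 <- pl * colSums(!is.na(Db))
  p1 <- colSums(Da, na.rm = TRUE) / n1
  p2 <- colSums(Db, na.rm = TRUE) / n2
  ok <- n1 > 0 & n2 > 0 & is.finite(p1) & is.finite(p2)
  n1 <- n1[ok]; n2 <- n2[ok]; p1 <- p1[ok]; p2 <- p2[ok]
  r <- 2
  ntot <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / ntot
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - r)
  nc <- (ntot - (n1^2 + n2^2) / ntot) / (r - 1)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  poly <- pbar > 0 & pbar < 1
  sum(num[poly]) / sum(den[poly])
}

#' @export
print.fst_table <- function(x, ...) {
  cat("Pairwise Fst (Weir-Cockerham):\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
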