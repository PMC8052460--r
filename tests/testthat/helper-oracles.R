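# Independent brute-force oracles used to pin down the analytical code paths.
# These deliberately re-derive each quantity from first principles (pair
# enumeration, literal formula evaluation) and never call the functions they
# check.

# Mean pairwise allele difference per site for a diploid (0/1/2) matrix:
# expand each genotype into two alleles and enumerate all allele pairs.
oracle_pi <- function(Ddip) {
  vals <- apply(unclass(Ddip), 2, function(col) {
    col <- col[!is.na(col)]
    al <- unlist(lapply(col, function(g)
      if (g == 0) c(0, 0) else if (g == 1) c(0, 1) else c(1, 1)))
    if (length(al) < 2) return(NA_real_)
    pr <- combn(length(al), 2)
    mean(al[pr[1, ]] != al[pr[2, ]])
  })
  mean(vals, na.rm = TRUE)
}

oracle_watterson <- function(Ddip) {
  X <- unclass(Ddip)
  m <- colSums(!is.na(X))
  L <- sum(m > 0)
  p <- colSums(X, na.rm = TRUE) / (2 * m)
  S <- sum(p > 0 & p < 1, na.rm = TRUE)
  n_eff <- 1 / mean(1 / m[m > 0])
  a1 <- digamma(n_eff) - digamma(1)
  S / (a1 * L)
}

oracle_tajima_d <- function(n, S, L, pi_site) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_site * L - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Nei 1972 distance for one clone pair, literal per-locus evaluation.
oracle_nei_pair <- function(di, dj, ploidy = 4) {
  ok <- !is.na(di) & !is.na(dj)
  xi <- di[ok] / ploidy; xj <- dj[ok] / ploidy
  jxy <- mean(xi * xj + (1 - xi) * (1 - xj))
  jx <- mean(xi^2 + (1 - xi)^2)
  jy <- mean(xj^2 + (1 - xj)^2)
  -log(jxy / sqrt(jx * jy))
}

# EHH by direct pair counting: fraction of carrier pairs identical over the
# marker interval [focal..x] (columns of H already restricted to one
# chromosome, sorted by position).
oracle_ehh_curve <- function(H, focal, allele, positions) {
  carriers <- H[H[, focal] == allele, , drop = FALSE]
  n <- nrow(carriers)
  pr <- combn(n, 2)
  one <- function(x) {
    rng <- min(focal, x):max(focal, x)
    mean(vapply(seq_len(ncol(pr)), function(k)
      all(carriers[pr[1, k], rng] == carriers[pr[2, k], rng]), logical(1)))
  }
  vapply(seq_len(ncol(H)), one, numeric(1))
}

oracle_ene <- function(dm, subset) {
  vals <- vapply(subset, function(i)
    min(dm[i, setdiff(subset, i)]), numeric(1))
  mean(vals)
}

# Additive relationship by gene dropping: founders carry unique alleles,
# offspring inherit one random allele per parent; A = 2 * P(IBD) of random
# alleles, estimated over n_drop replicates.
oracle_gene_drop_A <- function(ped, n_drop = 1e5) {
  ids <- ped$clone
  n <- length(ids)
  fi <- match(ped$female, ids)
  mi <- match(ped$male, ids)
  a1 <- matrix(NA_integer_, n_drop, n)
  a2 <- matrix(NA_integer_, n_drop, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    a1[, i] <- if (is.na(f)) { next_allele <- next_allele + 1L; next_allele - 1L
    } else ifelse(runif(n_drop) < 0.5, a1[, f], a2[, f])
    a2[, i] <- if (is.na(m)) { next_allele <- next_allele + 1L; next_allele - 1L
    } else ifelse(runif(n_drop) < 0.5, a1[, m], a2[, m])
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
      (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
    A[i, j] <- A[j, i] <- mean(ibd) / 2
  }
  A
}

# Small structured panel shared by several tests.
make_toy_panel <- function(seed = 42, n_per_pop = c(30, 30, 30), m = 400,
                           fst = 0.15, missing_rate = 0) {
  cfg <- sim_config(n_per_pop = n_per_pop, n_markers = m, fst = fst,
                    missing_rate = missing_rate, seed = seed)
  simulate_structured_population(cfg)
}

dosage_from <- function(mat, ploidy = 4) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("c", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("m", seq_len(ncol(mat)))
  dosage_matrix(mat, ploidy = ploidy)
}
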