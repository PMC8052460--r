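#' Configuration for the synthetic tetraploid panel generator
#'
#' Defaults emulate a ~214-clone breeding collection genotyped at ~10,000
#' SNPs: three subpopulations sized like the collection's market-class
#' groups (red/specialty 100, russet-strain 18, chip-and-russet 96),
#' moderate differentiation, ancestral allele frequencies uniform on the
#' post-QC MAF band [0.05, 0.5], and 5% missing calls (under the 10% QC
#' ceiling). Tests and examples pass smaller `n_markers`.
#'
#' @param n_per_pop clones per subpopulation.
#' @param n_markers markers.
#' @param fst Balding-Nichols differentiation parameter, one value per
#'   subpopulation or a scalar.
#' @param maf_range ancestral allele-frequency range.
#' @param missing_rate uniform missing-call rate.
#' @param seed RNG seed (mandatory).
#' @param n_duplicates,n_mislabels,n_diploid anomaly counts for
#'   [inject_anomalies()].
#' @param n_chrom,chrom_length chromosomes and their length in bp.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_pop = c(100, 18, 96), n_markers = 10000,
                       fst = 0.08, maf_range = c(0.05, 0.5),
                       missing_rate = 0.05, seed,
                       n_duplicates = 2, n_mislabels = 5, n_diploid = 1,
                       n_chrom = 12, chrom_length = 60e6) {
  if (missing(seed)) stop("seed is required")
  stopifnot(missing_rate >= 0, missing_rate <= 1, all(fst >= 0), all(fst < 1),
            maf_range[1] >= 0, maf_range[2] <= 0.5)
  structure(list(n_per_pop = n_per_pop, n_markers = n_markers,
                 fst = rep_len(fst, length(n_per_pop)),
                 maf_range = maf_range, missing_rate = missing_rate,
                 seed = seed, n_duplicates = n_duplicates,
                 n_mislabels = n_mislabels, n_diploid = n_diploid,
                 n_chrom = n_chrom, chrom_length = chrom_length),
            class = "sim_config")
}

# Market-class pools mirroring the three structure groups of a breeding
# collection: reds/specialties, russet strains, chips and russets.
pop_class_pool <- function(k) {
  switch(k,
         c("Red", "Purple", "Yellow"),
         c("Russet"),
         c("Chipping", "Russet"))
}

#' Simulate a structured tetraploid dosage panel
#'
#' Balding-Nichols model: ancestral frequency p ~ U(maf_range) per marker;
#' subpopulation k draws p_k ~ Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k) (p_k =
#' p when F_k = 0); each clone's dosage is Binomial(4, p_k). Missing calls
#' are sprinkled uniformly at random and markers placed uniformly over the
#' chromosomes.
#'
#' @param cfg a [sim_config()].
#' @return list: `dosage` ([dosage_matrix()]), `panel` (clone metadata),
#'   `map` (marker map), `truth` (subpopulation per clone, ancestral and
#'   subpopulation allele frequencies).
#' @export
simulate_structured_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- length(cfg$n_per_pop)
  m <- cfg$n_markers
  n <- sum(cfg$n_per_pop)
  p_anc <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  pk <- matrix(NA_real_, K, m)
  for (k in seq_len(K)) {
    F <- cfg$fst[k]
    pk[k, ] <- if (F == 0) p_anc else
      rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  pop <- rep(seq_len(K), cfg$n_per_pop)
  dos <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) dos[i, ] <- rbinom(m, 4, pk[pop[i], ])
  if (cfg$missing_rate > 0)
    dos[matrix(runif(n * m) < cfg$missing_rate, n, m)] <- NA
  rownames(dos) <- sprintf("clone%03d", seq_len(n))
  colnames(dos) <- sprintf("snp%05d", seq_len(m))
  chrom <- sort(sample.int(cfg$n_chrom, m, replace = TRUE))
  position <- unlist(lapply(split(seq_len(m), chrom), function(idx)
    sort(sample.int(cfg$chrom_length, length(idx)))), use.names = FALSE)
  map <- data.frame(marker_id = colnames(dos), chrom = chrom,
                    position = position)
  classes <- vapply(pop, function(k) sample(pop_class_pool(k), 1), "")
  panel <- data.frame(clone_id = rownames(dos), market_class = classes,
                      code = paste0(substr(classes, 1, 2), pop))
  truth <- list(pop = setNames(pop, rownames(dos)),
                p_ancestral = p_anc, p_pop = pk, fst = cfg$fst)
  list(dosage = dosage_matrix(dos), panel = panel, map = map, truth = truth)
}

#' Simulate offspring of a tetraploid cross
#'
#' Random bivalent chromatid segregation without double reduction: a gamete
#' receives g of the parent's d B-alleles with hypergeometric probability
#' C(d,g) C(4-d,2-g) / C(4,2); the offspring dosage is the sum of the two
#' parental gamete dosages, markers independent.
#'
#' @param d_female,d_male parental dosage vectors (0..4; NA propagates).
#' @param n_offspring number of offspring.
#' @param seed RNG seed.
#' @return matrix of offspring dosages, one row per offspring.
#' @export
simulate_cross <- function(d_female, d_male, n_offspring = 1, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(length(d_female) == length(d_male))
  set.seed(seed)
  m <- length(d_female)
  gamete <- function(d) {
    g <- rep(NA_real_, m)
    ok <- !is.na(d)
    g[ok] <- rhyper(sum(ok), d[ok], 4 - d[ok], 2)
    g
  }
  out <- matrix(NA_real_, n_offspring, m)
  for (i in seq_len(n_offspring)) out[i, ] <- gamete(d_female) + gamete(d_male)
  colnames(out) <- names(d_female)
  rownames(out) <- sprintf("offspring%02d", seq_len(n_offspring))
  out
}

#' Simulate a haplotype panel carrying a selective sweep
#'
#' Background haplotypes are drawn marker-wise independent on one
#' chromosome, with minor allele frequency U(0.05, 0.5) and random polarity
#' (the derived allele is the minor or the major allele with equal
#' probability, so the derived-frequency spectrum spans (0.05, 0.95) and
#' every standardization bin of the scans is populated with neutral
#' markers). A fraction `sweep_freq` of the haplotypes are sweep carriers:
#' each copies a single founder haplotype outward from the sweep locus,
#' switching back to the background at marker distance d bp with
#' probability (1 - `homogeneity`) * (1 - exp(-d / `decay_length`)) — near
#' zero at the locus and rising with distance, so the shared tract decays
#' smoothly — and carries the derived allele at the locus; non-carriers are
#' ancestral there. With `populations = 2` a second, fully neutral panel on
#' the same map is returned for the cross-population contrast.
#'
#' @param n_hap haplotypes per population (default 100).
#' @param n_markers markers (default 2000).
#' @param sweep_at focal marker index (default the middle marker).
#' @param sweep_freq derived-allele (carrier) frequency in (0.2, 0.95),
#'   default 0.8.
#' @param homogeneity asymptotic per-marker probability a carrier stays on
#'   the founder haplotype (default 0.9).
#' @param decay_length characteristic distance in bp over which the
#'   switch-out probability reaches its asymptote (default 50 kb).
#' @param populations 1 or 2.
#' @param chrom_length chromosome length in bp (default 100 Mb, giving a
#'   mean marker spacing near the array's).
#' @param seed RNG seed.
#' @return list: `panel` (sweep population), `panel_b` (neutral population,
#'   when requested), `truth` (sweep marker id, carrier rows).
#' @export
simulate_sweep_panel <- function(n_hap = 100, n_markers = 2000,
                                 sweep_at = NULL, sweep_freq = 0.8,
                                 homogeneity = 0.9, decay_length = 5e4,
                                 populations = 1,
                                 chrom_length = 100e6, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(sweep_freq > 0.2, sweep_freq < 0.95)
  set.seed(seed)
  if (is.null(sweep_at)) sweep_at <- ceiling(n_markers / 2)
  n_carrier <- round(sweep_freq * n_hap)
  if (n_carrier < 4) stop("fewer than 4 carrier haplotypes; raise sweep_freq or n_hap")
  pos <- sort(sample.int(chrom_length, n_markers))
  map <- data.frame(marker_id = sprintf("snp%05d", seq_len(n_markers)),
                    chrom = 1L, position = pos)
  maf <- runif(n_markers, 0.05, 0.5)
  freq <- ifelse(runif(n_markers) < 0.5, maf, 1 - maf)
  draw_bg <- function(n) {
    matrix(rbinom(n * n_markers, 1, rep(freq, each = n)), n, n_markers)
  }
  H <- draw_bg(n_hap)
  founder <- H[1, ]
  carriers <- seq_len(n_carrier)
  for (i in carriers) {
    for (step in c(-1L, 1L)) {       # copy founder outward until switch-out
      j <- sweep_at
      repeat {
        H[i, j] <- founder[j]
        j <- j + step
        if (j < 1 || j > n_markers) break
        d <- abs(pos[j] - pos[sweep_at])
        q_switch <- (1 - homogeneity) * (1 - exp(-d / decay_length))
        if (runif(1) < q_switch) break
      }
    }
  }
  H[carriers, sweep_at] <- 1
  H[-carriers, sweep_at] <- 0
  colnames(H) <- map$marker_id
  out <- list(panel = haplotype_panel(H, map),
              truth = list(sweep_marker = map$marker_id[sweep_at],
                           sweep_index = sweep_at, carriers = carriers,
                           background_freq = freq))
  if (populations == 2) {
    B <- draw_bg(n_hap)
    B[, sweep_at] <- rbinom(n_hap, 1, 0.5)  # segregating but neutral in B
    colnames(B) <- map$marker_id
    out$panel_b <- haplotype_panel(B, map)
  }
  out
}

#' Inject duplicates, mislabels and a diploid clone into a panel
#'
#' Duplicates copy existing clones (optionally with per-call error);
#' mislabels reassign a clone's market class to one typical of a different
#' true subpopulation; diploid clones get dosages 2 * Binomial(2, p), i.e.
#' only the nulliplex/duplex/quadruplex states, so [infer_ploidy()] can
#' recover them.
#'
#' @param sim output of [simulate_structured_population()].
#' @param cfg the [sim_config()] (anomaly counts, seed).
#' @param error_rate per-call error rate on duplicated rows (default 0).
#' @return list like `sim` with modified `dosage`, `panel` and a `truth`
#'   extended by `anomalies` (data.frame clone_id, type, detail).
#' @export
inject_anomalies <- function(sim, cfg, error_rate = 0) {
  set.seed(cfg$seed + 1L)
  D <- unclass(sim$dosage)
  panel <- sim$panel
  truth <- sim$truth
  n <- nrow(D)
  need <- cfg$n_duplicates + cfg$n_mislabels + cfg$n_diploid
  if (need > n) stop("requested anomalies exceed panel size")
  touched <- character(0)
  anomalies <- list()
  # duplicates: appended copies of existing clones
  if (cfg$n_duplicates > 0) {
    src <- sample(rownames(D), cfg$n_duplicates)
    for (s in src) {
      row <- D[s, ]
      if (error_rate > 0) {
        flip <- which(runif(length(row)) < error_rate & !is.na(row))
        row[flip] <- pmin(4, pmax(0, row[flip] +
                                    sample(c(-1, 1), length(flip), TRUE)))
      }
      id <- paste0(s, "_dup")
      D <- rbind(D, row)
      rownames(D)[nrow(D)] <- id
      panel <- rbind(panel, data.frame(
        clone_id = id,
        market_class = panel$market_class[panel$clone_id == s],
        code = panel$code[panel$clone_id == s]))
      truth$pop <- c(truth$pop, setNames(truth$pop[[s]], id))
      anomalies[[length(anomalies) + 1]] <-
        data.frame(clone_id = id, type = "duplicate", detail = s)
      touched <- c(touched, s, id)
    }
  }
  # mislabels: market class swapped to another subpopulation's pool
  if (cfg$n_mislabels > 0) {
    pool <- setdiff(rownames(D), touched)
    victims <- sample(pool, cfg$n_mislabels)
    K <- length(cfg$n_per_pop)
    cycle <- lapply(seq_len(K), function(k) {
      # a detectable mislabel needs a class foreign to the victim's own group;
      # cycle through the foreign classes so same-group victims differ
      f <- setdiff(unlist(lapply(setdiff(seq_len(K), k), pop_class_pool)),
                   pop_class_pool(k))
      if (length(f)) sample(f) else character(0)
    })
    used <- integer(K)
    for (v in victims) {
      k <- truth$pop[[v]]
      foreign <- cycle[[k]]
      if (!length(foreign)) stop("no foreign market class available for mislabel")
      used[k] <- used[k] + 1L
      new_class <- foreign[(used[k] - 1L) %% length(foreign) + 1L]
      old <- panel$market_class[panel$clone_id == v]
      panel$market_class[panel$clone_id == v] <- new_class
      anomalies[[length(anomalies) + 1]] <-
        data.frame(clone_id = v, type = "mislabel",
                   detail = paste0(old, "->", new_class))
      touched <- c(touched, v)
    }
  }
  # diploid clones: dosages restricted to {0, 2, 4}
  if (cfg$n_diploid > 0) {
    pool <- setdiff(rownames(D), touched)
    victims <- sample(pool, cfg$n_diploid)
    for (v in victims) {
      k <- truth$pop[[v]]
      p <- truth$p_pop[k, ]
      row <- 2 * rbinom(ncol(D), 2, p)
      row[is.na(D[v, ])] <- NA
      D[v, ] <- row
      anomalies[[length(anomalies) + 1]] <-
        data.frame(clone_id = v, type = "diploid", detail = "")
      touched <- c(touched, v)
    }
  }
  truth$anomalies <- do.call(rbind, anomalies)
  list(dosage = dosage_matrix(D), panel = panel, map = sim$map, truth = truth)
}

#' Simulate a neutral-spectrum panel of clone sequences
#'
#' Draws each site's derived-carrier count i from the neutral site frequency
#' spectrum, P(i) proportional to 1/i over i = 1..n-1, and assigns the
#' derived allele to i random clones as homozygous calls (diploid code 2),
#' so each clone reads as one sequence. Under this spectrum the expected
#' mean pairwise diversity equals Watterson's theta, making the panel a
#' calibration target where Tajima's D is centered near zero.
#'
#' @param n clones (sequences).
#' @param n_sites sites, all segregating.
#' @param seed RNG seed.
#' @return a ploidy-2 [dosage_matrix()] with calls in \{0, 2\}.
#' @export
simulate_neutral_panel <- function(n, n_sites, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  counts <- sample(seq_len(n - 1), n_sites, replace = TRUE,
                   prob = 1 / seq_len(n - 1))
  mat <- vapply(counts, function(k) {
    col <- numeric(n)
    col[sample.int(n, k)] <- 2
    col
  }, numeric(n))
  dimnames(mat) <- list(sprintf("clone%03d", seq_len(n)),
                        sprintf("site%05d", seq_len(n_sites)))
  dosage_matrix(mat, ploidy = 2L)
}
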