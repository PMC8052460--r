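#' Construct a phased haplotype panel
#'
#' Binary haplotypes (0 = ancestral, 1 = derived allele) with a marker map;
#' phased and complete (no missing alleles). Substrate for the
#' extended-haplotype-homozygosity statistics.
#'
#' @param alleles binary matrix, haplotypes in rows, markers in columns;
#'   column names are marker ids.
#' @param map marker map data.frame (marker_id, chrom, position) covering
#'   every column.
#' @param pop optional population label per haplotype.
#' @return an object of class `haplotype_panel`; markers are sorted by
#'   (chrom, position).
#' @export
haplotype_panel <- function(alleles, map, pop = NULL) {
  alleles <- as.matrix(alleles)
  if (anyNA(alleles)) stop("haplotypes must be complete (phased, no missing)")
  if (!all(alleles %in% c(0, 1))) stop("alleles must be binary 0/1")
  map <- validate_marker_map(map)
  if (is.null(colnames(alleles))) colnames(alleles) <- map$marker_id
  if (!setequal(colnames(alleles), map$marker_id))
    stop("map must cover exactly the panel's markers")
  map <- map[order(map$chrom, map$position), ]
  alleles <- alleles[, map$marker_id, drop = FALSE]
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0("hap", seq_len(nrow(alleles)))
  if (!is.null(pop)) stopifnot(length(pop) == nrow(alleles))
  structure(list(alleles = alleles, map = map, pop = pop),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes x %d markers on %d chromosome(s)\n",
              nrow(x$alleles), ncol(x$alleles), length(unique(x$map$chrom))))
  invisible(x)
}

# Homozygosity of a haplotype grouping: P(two random haplotypes identical).
hap_homozygosity <- function(g) {
  n <- length(g)
  tab <- tabulate(g)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

# EHH curve outward from a focal column over the given haplotype rows.
# Returns positions and EHH values including the focal point (EHH = 1),
# truncated after the first value below min_ehh.
ehh_one_side <- function(H, pos, focal, step, min_ehh) {
  n <- nrow(H)
  g <- rep(1L, n)
  out_pos <- pos[focal]
  out_ehh <- 1
  j <- focal + step
  while (j >= 1 && j <= ncol(H)) {
    key <- g * 2L + H[, j]
    g <- match(key, unique(key))
    e <- hap_homozygosity(g)
    out_pos <- c(out_pos, pos[j])
    out_ehh <- c(out_ehh, e)
    if (e < min_ehh) break
    j <- j + step
  }
  list(pos = out_pos, ehh = out_ehh)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Extended haplotype homozygosity around a focal marker
#'
#' EHH(x) is the probability that two random carrier haplotypes are
#' identical over the interval from the focal marker to position x,
#' computed outward in both directions until EHH drops below `min_ehh` or
#' the chromosome ends. iES is the trapezoid integral of the curve over
#' physical distance (both sides; the point at which EHH first falls below
#' the cutoff is included).
#'
#' @param panel a [haplotype_panel()].
#' @param marker focal marker id.
#' @param allele 0 (ancestral) or 1 (derived); carriers are the haplotypes
#'   with this allele at the focal marker. `NULL` uses all haplotypes
#'   (site-level EHH, as in the cross-population statistic).
#' @param min_ehh truncation threshold (default 0.05).
#' @param haplotypes optional row subset (e.g. one population).
#' @return list: `position`, `ehh` (sorted by position), `ies`, `n_carriers`.
#' @export
ehh <- function(panel, marker, allele = 1, min_ehh = 0.05, haplotypes = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$alleles
  if (!is.null(haplotypes)) H <- H[haplotypes, , drop = FALSE]
  focal <- match(marker, colnames(H))
  if (is.na(focal)) stop("focal marker not in panel: ", marker)
  chr <- panel$map$chrom[focal]
  on_chr <- which(panel$map$chrom == chr)
  H <- H[, on_chr, drop = FALSE]
  pos <- panel$map$position[on_chr]
  focal <- match(marker, colnames(H))
  if (!is.null(allele)) H <- H[H[, focal] == allele, , drop = FALSE]
  if (nrow(H) < 2)
    return(list(position = pos[focal], ehh = NA_real_, ies = NA_real_,
                n_carriers = nrow(H)))
  left <- ehh_one_side(H, pos, focal, -1L, min_ehh)
  right <- ehh_one_side(H, pos, focal, +1L, min_ehh)
  position <- c(rev(left$pos[-1]), right$pos)
  curve <- c(rev(left$ehh[-1]), right$ehh)
  ies <- trapezoid(rev(left$pos), rev(left$ehh)) +
    trapezoid(right$pos, right$ehh)
  list(position = position, ehh = curve, ies = ies, n_carriers = nrow(H))
}

scan_result <- function(method, map, raw, z, p, q, extra = list()) {
  out <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                    position = map$position, raw = raw, z = z, p = p, q = q)
  structure(c(list(method = method, scores = out), extra),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  sc <- x$scores
  ok <- !is.na(sc$q)
  cat(sprintf("%s scan: %d markers scored, %d at q < 0.05\n",
              x$method, sum(!is.na(sc$z)), sum(sc$q[ok] < 0.05)))
  if (!is.null(x$lambda_gc)) cat(sprintf("  lambda_GC = %.2f\n", x$lambda_gc))
  invisible(x)
}

# Standardize within frequency bins; bins with < min_count scores are merged
# with their left neighbor (leftmost merges right).
bin_standardize <- function(score, freq, bins, min_count = 10) {
  ok <- !is.na(score)
  edges <- seq(0, 1, length.out = bins + 1)
  b <- pmin(pmax(findInterval(freq, edges, rightmost.closed = TRUE), 1), bins)
  counts <- tabulate(b[ok], nbins = bins)
  merged <- integer(bins)
  cur <- 0
  for (i in seq_len(bins)) {        # merge sparse bins into runs
    if (cur == 0 || counts_run >= min_count) { cur <- cur + 1; counts_run <- 0 }
    merged[i] <- cur
    counts_run <- counts_run + counts[i]
  }
  # if the final run is sparse, fold it into the previous one
  if (sum(counts[merged == cur]) < min_count && cur > 1)
    merged[merged == cur] <- cur - 1
  grp <- merged[b]
  z <- rep(NA_real_, length(score))
  for (g in unique(grp[ok])) {
    idx <- ok & grp == g
    mu <- mean(score[idx]); s <- sd(score[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (score[idx] - mu) / s
  }
  z
}

#' iHS scan for within-population selection signatures
#'
#' For every marker with derived-allele frequency inside
#' [`maf_min`, 1 - `maf_min`]: the unstandardized statistic is
#' ln(iES_ancestral / iES_derived), the log-ratio of integrated EHH over the
#' ancestral- and derived-allele carrier haplotypes. Scores are standardized
#' to zero mean and unit variance within derived-allele-frequency bins
#' (equal width; sparse bins merged with neighbors), so that under
#' neutrality |z| is approximately standard normal. Two-sided p-values
#' 2*Phi(-|z|) and Storey q-values are attached.
#'
#' @param panel a single-population [haplotype_panel()].
#' @param maf_min frequency cutoff for scoring a marker (default 0.05).
#' @param bins number of equal-width frequency bins (default 20).
#' @param min_ehh EHH truncation (default 0.05).
#' @return a `scan_result` with method `"ihs"`.
#' @export
ihs_scan <- function(panel, maf_min = 0.05, bins = 20, min_ehh = 0.05) {
  H <- panel$alleles
  freq <- colMeans(H)
  m <- ncol(H)
  raw <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    f <- freq[j]
    if (f < maf_min || f > 1 - maf_min) next
    ies_d <- ehh(panel, colnames(H)[j], allele = 1, min_ehh = min_ehh)$ies
    ies_a <- ehh(panel, colnames(H)[j], allele = 0, min_ehh = min_ehh)$ies
    if (is.na(ies_d) || is.na(ies_a) || ies_d <= 0 || ies_a <= 0) next
    raw[j] <- log(ies_a / ies_d)
  }
  z <- bin_standardize(raw, freq, bins)
  p <- 2 * pnorm(-abs(z))
  q <- rep(NA_real_, m)
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- storey_qvalues(p[ok])$qvalues
  scan_result("ihs", panel$map, raw, z, p, q)
}

#' XP-EHH scan for between-population selection signatures
#'
#' Per marker, the integrated site-level EHH (over all haplotypes, no
#' allele split) is computed within each population; the statistic is
#' ln(iES_A / iES_B), standardized genome-wide. Positive scores mean longer
#' haplotype homozygosity (a harder sweep) in population A. Swapping the
#' populations negates every score.
#'
#' @param panelA,panelB [haplotype_panel()]s sharing a marker map, each with
#'   at least 4 haplotypes.
#' @param min_ehh EHH truncation (default 0.05).
#' @return a `scan_result` with method `"xpehh"`.
#' @export
xpehh_scan <- function(panelA, panelB, min_ehh = 0.05) {
  if (nrow(panelA$alleles) < 4 || nrow(panelB$alleles) < 4)
    stop("each population needs >= 4 haplotypes")
  if (!identical(panelA$map$marker_id, panelB$map$marker_id))
    stop("panels must share a marker map")
  m <- ncol(panelA$alleles)
  raw <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    id <- colnames(panelA$alleles)[j]
    ia <- ehh(panelA, id, allele = NULL, min_ehh = min_ehh)$ies
    ib <- ehh(panelB, id, allele = NULL, min_ehh = min_ehh)$ies
    if (is.na(ia) || is.na(ib) || ia <= 0 || ib <= 0) next
    raw[j] <- log(ia / ib)
  }
  mu <- mean(raw, na.rm = TRUE); s <- sd(raw, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) ifelse(is.na(raw), NA_real_, 0) else (raw - mu) / s
  p <- 2 * pnorm(-abs(z))
  q <- rep(NA_real_, m)
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- storey_qvalues(p[ok])$qvalues
  scan_result("xpehh", panelA$map, raw, z, p, q)
}

#' PCA-based outlier scan for loci under selection
#'
#' Regresses each (diploidized, scaled) marker on the first K principal
#' components of the genotype matrix; the vector of K regression z-scores
#' per marker is summarized by its Mahalanobis distance D-squared, which is
#' chi-squared with K df under neutrality. The genomic inflation factor
#' lambda_GC = median(D2) / median(chisq_K) rescales the statistics before
#' p-values are taken, and Storey q-values finish the scan. Optional greedy
#' LD clumping thins the panel before the PCs are estimated so they capture
#' structure rather than local LD.
#'
#' @param D a [dosage_matrix()].
#' @param map marker map for the panel's markers.
#' @param K number of principal components regressed on; choose from a
#'   scree/score-plot inspection (3 for a three-group collection).
#' @param ld_prune logical; thin markers by LD before estimating PCs.
#' @param r2_max clumping threshold (default 0.2).
#' @param window clumping window in markers (default 50).
#' @return a `scan_result` with method `"pca_outlier"` and `lambda_gc`.
#' @export
pca_outlier_scan <- function(D, map = NULL, K = 3, ld_prune = FALSE,
                             r2_max = 0.2, window = 50) {
  n <- nrow(D); m <- ncol(D)
  if (K >= min(n, m)) stop("K must be < min(n clones, m markers)")
  X <- numeric_genotypes(D)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  pc_input <- Xs
  if (ld_prune) {
    keep <- ld_clump(Xs, r2_max = r2_max, window = window)
    pc_input <- Xs[, keep, drop = FALSE]
  }
  sv <- svd(pc_input, nu = K, nv = 0)
  U <- sv$u                              # n x K, orthonormal
  B <- crossprod(U, Xs)                  # K x m regression coefficients
  res2 <- colSums(Xs^2) - colSums(B^2)
  df <- n - K - 1
  sigma2 <- pmax(res2 / df, .Machine$double.eps)
  Z <- sweep(B, 2, sqrt(sigma2), "/")    # K x m z-scores
  Zt <- t(Z)
  rob <- tryCatch(MASS::cov.rob(Zt), error = function(e) NULL)
  d2 <- if (!is.null(rob)) mahalanobis(Zt, rob$center, rob$cov)
  else mahalanobis(Zt, colMeans(Zt), cov(Zt))
  lambda <- median(d2) / qchisq(0.5, df = K)
  p <- pchisq(d2 / lambda, df = K, lower.tail = FALSE)
  q <- storey_qvalues(p)$qvalues
  if (is.null(map))
    map <- data.frame(marker_id = colnames(D), chrom = NA, position = NA)
  scan_result("pca_outlier", map, raw = d2, z = sqrt(d2), p = p, q = q,
              extra = list(lambda_gc = lambda, K = K))
}

# Greedy LD clumping on a standardized matrix: scan markers left to right,
# keep a marker unless it is in high LD with an already-kept marker within
# the window.
ld_clump <- function(Xs, r2_max, window) {
  m <- ncol(Xs)
  n <- nrow(Xs)
  keep <- logical(m)
  kept_idx <- integer(0)
  for (j in seq_len(m)) {
    near <- kept_idx[kept_idx > j - window]
    ok <- TRUE
    for (k in near) {
      r <- crossprod(Xs[, j], Xs[, k]) / (n - 1)
      if (is.finite(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) { keep[j] <- TRUE; kept_idx <- c(kept_idx, j) }
  }
  which(keep)
}

#' Storey q-values and the null proportion pi0
#'
#' Estimates the proportion of true nulls pi0 on a lambda grid with the
#' smoother method (a natural spline over pi0(lambda), evaluated at the
#' largest lambda), then converts p-values to q-values,
#' q_i = min over \{p_j >= p_i\} of pi0 * m * p_j / rank(p_j).
#'
#' @param pvals p-values in [0, 1].
#' @param lambda grid for pi0 estimation (default 0.05..0.95 by 0.05).
#' @param pi0 optional fixed null proportion, bypassing estimation.
#' @return list: `qvalues` (same order as `pvals`), `pi0`.
#' @export
storey_qvalues <- function(pvals, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  m <- length(pvals)
  if (!m) stop("no p-values supplied")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1                    # too few tests to estimate; conservative
    } else {
      pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  rank_desc <- m:1                # rank of sorted-descending p-values
  qv <- pmin(1, cummin(pi0 * m * pvals[o] / rank_desc))[ro]
  list(qvalues = qv, pi0 = pi0)
}

#' Consensus selective-sweep regions across scans
#'
#' Markers significant in at least two of the supplied scans (method-specific
#' q-value thresholds) are clustered along the chromosome: qualifying
#' markers within `flank` of a cluster's current top SNP join it, and each
#' cluster is reported as the interval top SNP +/- `flank`. Regions from
#' distinct top SNPs are kept even when their intervals overlap.
#'
#' @param results list of two or more `scan_result`s sharing a marker map.
#' @param thresholds named q-value cutoffs per method (defaults: ihs 0.01,
#'   xpehh 0.01, pca_outlier 0.05).
#' @param flank half-width of the reported region in bp (default 250 kb).
#' @return data.frame of class `sweep_regions`: chrom, start, end, top SNP,
#'   supporting methods, the top SNP's max |z| and min p.
#' @export
consensus_sweeps <- function(results,
                             thresholds = c(ihs = 0.01, xpehh = 0.01,
                                            pca_outlier = 0.05),
                             flank = 250000) {
  if (length(results) < 2) stop("need at least two scan results")
  ids <- results[[1]]$scores$marker_id
  for (r in results)
    if (!identical(r$scores$marker_id, ids))
      stop("scan results must share a marker map")
  sig <- sapply(results, function(r) {
    thr <- thresholds[[r$method]]
    if (is.null(thr)) thr <- 0.05
    !is.na(r$scores$q) & r$scores$q < thr
  })
  n_methods <- rowSums(sig)
  methods_str <- apply(sig, 1, function(s)
    paste(vapply(results[s], `[[`, "", "method"), collapse = "+"))
  zmax <- apply(sapply(results, function(r) abs(r$scores$z)), 1,
                function(v) suppressWarnings(max(v, na.rm = TRUE)))
  pmin_ <- apply(sapply(results, function(r) r$scores$p), 1,
                 function(v) suppressWarnings(min(v, na.rm = TRUE)))
  sc <- results[[1]]$scores
  hit <- which(n_methods >= 2)
  out <- list()
  for (chr in unique(sc$chrom[hit])) {
    idx <- hit[sc$chrom[hit] == chr]
    idx <- idx[order(-zmax[idx])]       # strongest first
    tops <- integer(0)
    for (i in idx) {
      if (!length(tops) ||
          all(abs(sc$position[i] - sc$position[tops]) > flank))
        tops <- c(tops, i)
    }
    for (i in tops)
      out[[length(out) + 1]] <- data.frame(
        chrom = chr,
        start = max(1, sc$position[i] - flank),
        end = sc$position[i] + flank,
        top_snp = sc$marker_id[i],
        methods = methods_str[i],
        n_methods = n_methods[i],
        max_abs_z = zmax[i],
        min_p = pmin_[i])
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = integer(), start = numeric(), end = numeric(),
               top_snp = character(), methods = character(),
               n_methods = integer(), max_abs_z = numeric(),
               min_p = numeric())
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_regions", "data.frame")
  out
}

#' Genes near a sweep region
#'
#' Returns the genes whose span intersects the region extended by
#' `flank_genes` up- and downstream (closed intervals: a gene ending exactly
#' at the extended boundary is included).
#'
#' @param region one row of a [consensus_sweeps()] result (or any list with
#'   chrom, start, end).
#' @param gff GFF3 file path or a data.frame as returned by [ape::read.gff].
#' @param flank_genes extension in bp (default 250 kb).
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @return data.frame of intersecting genes (seqid, start, end, attributes).
#' @export
genes_near <- function(region, gff, flank_genes = 250000, feature = "gene") {
  if (is.character(gff)) gff <- ape::read.gff(gff)
  genes <- gff[gff$type == feature, , drop = FALSE]
  chr_names <- unique(as.character(genes$seqid))
  target <- as.character(region$chrom)
  if (!target %in% chr_names) {
    alt <- grep(paste0("(^|[^0-9])0*", target, "$"), chr_names, value = TRUE)
    if (length(alt) == 1) target <- alt
    else stop("chromosome '", region$chrom,
              "' not found in GFF seqids: ",
              paste(head(chr_names, 12), collapse = ", "))
  }
  lo <- region$start - flank_genes
  hi <- region$end + flank_genes
  sel <- genes$seqid == target & genes$end >= lo & genes$start <= hi
  res <- genes[sel, c("seqid", "start", "end", "strand", "attributes")]
  rownames(res) <- NULL
  res
}
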