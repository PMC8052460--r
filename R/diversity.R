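#' Per-marker diversity statistics
#'
#' For each marker: the B-allele frequency p (allele counts pooled over
#' non-missing clones, `ploidy` alleles per clone), minor allele frequency
#' MAF = min(p, 1-p), expected heterozygosity He = 2p(1-p), and Botstein's
#' polymorphic information content for a biallelic locus,
#' PIC = 1 - (p^2 + q^2) - 2 p^2 q^2.
#'
#' @param D a [dosage_matrix()].
#' @return data.frame (marker_id, p, maf, he, pic); markers with no calls
#'   get NA stats.
#' @export
marker_stats <- function(D) {
  p <- marker_allele_freq(D)
  p[is.nan(p)] <- NA_real_
  q <- 1 - p
  data.frame(marker_id = colnames(D), p = p,
             maf = pmin(p, q),
             he = 2 * p * q,
             pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2,
             row.names = NULL)
}

#' Per-clone heterozygosity and inbreeding coefficient
#'
#' Observed heterozygosity Ho is the fraction of a clone's non-missing
#' markers carrying a heterozygous genotype (tetraploid dosage 1, 2 or 3;
#' diploid code 1). The inbreeding coefficient is F = 1 - Ho / He_mean,
#' where He_mean is the panel mean expected heterozygosity; highly
#' heterozygous clones therefore get negative F.
#'
#' @param D a [dosage_matrix()].
#' @param he_mean panel mean expected heterozygosity; computed from
#'   [marker_stats()] when omitted.
#' @return data.frame (clone_id, ho, f).
#' @export
clone_stats <- function(D, he_mean = NULL) {
  if (is.null(he_mean)) he_mean <- mean(marker_stats(D)$he, na.rm = TRUE)
  if (!is.finite(he_mean) || he_mean <= 0) stop("he_mean must be positive")
  pl <- ploidy_of(D)
  het <- !is.na(D) & D > 0 & D < pl
  ho <- rowSums(het) / rowSums(!is.na(D))
  data.frame(clone_id = rownames(D), ho = ho, f = 1 - ho / he_mean,
             row.names = NULL)
}

# Harmonic-number style constants, continuous in n via digamma/trigamma so a
# harmonic-mean (non-integer) effective sample size can be used.
tajima_constants <- function(n) {
  a1 <- digamma(n) - digamma(1)         # sum_{i=1}^{n-1} 1/i for integer n
  a2 <- pi^2 / 6 - trigamma(n)          # sum_{i=1}^{n-1} 1/i^2
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from summary quantities
#'
#' Computes D from the number of sequences, segregating sites, assayed sites
#' and mean per-site pairwise diversity, using the standard variance
#' constants. Useful to reconstruct D from published summaries.
#'
#' @param n number of sequences.
#' @param S number of segregating sites.
#' @param L number of assayed sites.
#' @param pi_site mean pairwise diversity per site.
#' @return Tajima's D (NA when S < 3).
#' @export
tajima_d_from_counts <- function(n, S, L, pi_site) {
  if (S < 3) return(NA_real_)
  k <- tajima_constants(n)
  (pi_site * L - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Sequence diversity: pi, Watterson's theta and Tajima's D
#'
#' Treats each clone's diploidized genotype as one sequence over the SNP
#' positions. Per site with m non-missing clones (2m alleles) and B-allele
#' frequency p-hat, the pairwise diversity is 2*p*(1-p) with the small-sample
#' factor 2m/(2m-1) (switchable); pi averages over all assayed sites (fixed
#' sites count toward L). Watterson's theta per site is S / (a1 * L) with a1
#' the harmonic number at the effective number of sequences — the harmonic
#' mean across sites of the per-site non-missing clone count — so missing
#' data shrink the effective n below the clone count. Tajima's D uses the
#' textbook variance constants at the same effective n.
#'
#' @param Ddip a diploidized [dosage_matrix()] (ploidy 2).
#' @param correction logical; apply the 2m/(2m-1) unbiasedness factor to the
#'   per-site pairwise diversity (default TRUE).
#' @return a `diversity_summary`: n, n_eff, S, L, pi, theta_w, tajima_d.
#' @export
sequence_diversity <- function(Ddip, correction = TRUE) {
  if (ploidy_of(Ddip) != 2L) stop("sequence_diversity() requires ploidy-2 calls")
  m <- colSums(!is.na(Ddip))
  assayed <- m > 0
  L <- sum(assayed)
  if (!L) stop("no assayed sites")
  m <- m[assayed]
  p <- colSums(Ddip[, assayed, drop = FALSE], na.rm = TRUE) / (2 * m)
  seg <- p > 0 & p < 1
  S <- sum(seg)
  h <- 2 * p * (1 - p)
  if (correction) h <- h * ifelse(2 * m > 1, 2 * m / (2 * m - 1), NA)
  pi_site <- mean(h)
  n_eff <- 1 / mean(1 / m)
  k <- tajima_constants(n_eff)
  theta_w <- S / (k$a1 * L)
  d <- if (S >= 3)
    (pi_site * L - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  else NA_real_
  structure(list(n = nrow(Ddip), n_eff = n_eff, S = S, L = L,
                 pi = pi_site, theta_w = theta_w, tajima_d = d),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "Sequence diversity: n = %d (effective %.1f), S = %d of L = %d sites\n",
    x$n, x$n_eff, x$S, x$L))
  cat(sprintf("  pi = %.4f   theta_w = %.4f   Tajima's D = %s\n",
              x$pi, x$theta_w,
              if (is.na(x$tajima_d)) "NA" else sprintf("%.2f", x$tajima_d)))
  invisible(x)
}
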