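#' Read a pedigree table
#'
#' CSV with columns `clone, female, male`; blank or NA parents are unknown.
#' The table is checked for cycles and returned in topological order
#' (parents before offspring).
#'
#' @param path file path.
#' @return data.frame (clone, female, male) of class `pedigree_table`.
#' @export
read_pedigree <- function(path) {
  ped <- read.csv(path, stringsAsFactors = FALSE)
  names(ped)[1:3] <- c("clone", "female", "male")
  as_pedigree(ped)
}

#' Build a pedigree table from vectors
#'
#' @param clone,female,male character vectors; parents may be NA or ""
#'   (unknown). Parents not listed as clones are added as founders.
#' @return data.frame of class `pedigree_table`, topologically sorted.
#' @export
as_pedigree <- function(clone, female = NULL, male = NULL) {
  ped <- if (is.data.frame(clone)) clone else
    data.frame(clone = clone, female = female, male = male,
               stringsAsFactors = FALSE)
  ped$female[!is.na(ped$female) & ped$female == ""] <- NA
  ped$male[!is.na(ped$male) & ped$male == ""] <- NA
  if (anyDuplicated(ped$clone)) stop("duplicate clone in pedigree")
  parents <- setdiff(c(ped$female, ped$male), c(ped$clone, NA))
  if (length(parents))
    ped <- rbind(data.frame(clone = parents, female = NA, male = NA), ped)
  ped <- topo_sort_pedigree(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

topo_sort_pedigree <- function(ped) {
  placed <- character(0)
  remaining <- ped
  out <- ped[0, ]
  while (nrow(remaining)) {
    ready <- vapply(seq_len(nrow(remaining)), function(i) {
      f <- remaining$female[i]; m <- remaining$male[i]
      (is.na(f) || f %in% placed) && (is.na(m) || m %in% placed)
    }, logical(1))
    if (!any(ready))
      stop("pedigree contains a cycle involving: ",
           paste(remaining$clone, collapse = ", "))
    out <- rbind(out, remaining[ready, ])
    placed <- c(placed, remaining$clone[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Pedigree-based additive relationship matrix (tabular method)
#'
#' Processes individuals in topological order with the recursions
#' A_ii = 1 + A_fm / 2 and A_ij = (A_jf + A_jm) / 2, unknown parents
#' contributing 0. A non-inbred parent-offspring pair has A = 0.5 and a
#' grandparent-grandchild pair 0.25.
#'
#' @param ped a [as_pedigree()] table.
#' @return symmetric numeric matrix with clone ids as dimnames.
#' @export
additive_matrix <- function(ped) {
  if (!inherits(ped, "pedigree_table")) ped <- as_pedigree(ped)
  ids <- ped$clone
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  fi <- match(ped$female, ids)
  mi <- match(ped$male, ids)
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(f) && !is.na(m)) A[f, m] else 0)
    if (i > 1) for (j in seq_len(i - 1)) {
      a <- 0.5 * ((if (!is.na(f)) A[j, f] else 0) +
                  (if (!is.na(m)) A[j, m] else 0))
      A[i, j] <- A[j, i] <- a
    }
  }
  A
}

#' Marker-based genomic relationship matrix for tetraploid dosages
#'
#' G_ij = sum_m (x_im - 4 p_m)(x_jm - 4 p_m) / sum_m 4 p_m (1 - p_m), with
#' panel allele frequencies p_m, markers missing in either clone excluded
#' pairwise (the denominator restricted to the shared markers). Under
#' Hardy-Weinberg the diagonal is about 1 and a parent-offspring pair about
#' 0.5, on the same scale as the pedigree A matrix. Monomorphic markers
#' contribute nothing.
#'
#' @param D a tetraploid [dosage_matrix()].
#' @return symmetric numeric matrix, positive semi-definite up to pairwise
#'   missing-data noise.
#' @export
genomic_matrix <- function(D) {
  pl <- ploidy_of(D)
  p <- marker_allele_freq(D)
  v <- pl * p * (1 - p)
  W <- sweep(unclass(D), 2, pl * p)
  M <- !is.na(W)
  W0 <- ifelse(M, W, 0)
  num <- W0 %*% t(W0)
  den <- sweep(M, 2, v, "*") %*% t(M)
  G <- num / den
  dimnames(G) <- list(rownames(D), rownames(D))
  (G + t(G)) / 2
}

#' Trio conflict rate for a recorded parent pair
#'
#' Only markers at which both parents are monomorphic (dosage 0 or 4, i.e.
#' the cross cannot segregate) are informative: the offspring dosage is then
#' forced to (d_female + d_male) / 2 (0x0 -> 0, 4x4 -> 4, 0x4 -> duplex 2).
#' The conflict rate is the percentage of informative markers at which the
#' offspring differs from the forced value; markers with any missing call
#' in the trio are excluded.
#'
#' @param D a tetraploid [dosage_matrix()].
#' @param offspring,female,male clone ids.
#' @param accurate_below conflict percentage under which the trio is labeled
#'   accurate, allowing for stray genotyping error (default 1).
#' @return a `trio_report`: clone ids, n_informative, n_conflicting,
#'   conflict_pct, verdict ("accurate", "conflicted" or "untestable").
#' @export
trio_conflict <- function(D, offspring, female, male, accurate_below = 1) {
  for (id in c(offspring, female, male))
    if (!id %in% rownames(D)) stop("clone not genotyped: ", id)
  pl <- ploidy_of(D)
  d_o <- D[offspring, ]; d_f <- D[female, ]; d_m <- D[male, ]
  ok <- !is.na(d_o) & !is.na(d_f) & !is.na(d_m)
  mono <- ok & (d_f == 0 | d_f == pl) & (d_m == 0 | d_m == pl)
  n_inf <- sum(mono)
  if (n_inf == 0) {
    return(structure(list(offspring = offspring, female = female, male = male,
                          n_informative = 0L, n_conflicting = 0L,
                          conflict_pct = NA_real_, verdict = "untestable"),
                     class = "trio_report"))
  }
  forced <- (d_f[mono] + d_m[mono]) / 2
  n_bad <- sum(d_o[mono] != forced)
  pct <- 100 * n_bad / n_inf
  structure(list(offspring = offspring, female = female, male = male,
                 n_informative = n_inf, n_conflicting = n_bad,
                 conflict_pct = pct,
                 verdict = if (pct < accurate_below) "accurate" else "conflicted"),
            class = "trio_report")
}

#' @export
print.trio_report <- function(x, ...) {
  cat(sprintf("Trio %s = %s x %s: conflict %s%% over %d informative markers [%s]\n",
              x$offspring, x$female, x$male,
              if (is.na(x$conflict_pct)) "NA" else sprintf("%.1f", x$conflict_pct),
              x$n_informative, x$verdict))
  invisible(x)
}

#' Check a single recorded parent against the markers
#'
#' For pedigrees where only one parent is genotyped: emits the (A, G) pairs
#' of the offspring against all genotyped clones, and tests whether the
#' putative parent's genomic relationship falls in the parent band
#' (G >= 0.5 - tau) and exceeds every unrelated clone's G. The
#' opposing-homozygote rate (parent nulliplex with offspring quadruplex or
#' vice versa, impossible under parentage) is reported alongside.
#'
#' @param D a tetraploid [dosage_matrix()].
#' @param offspring,parent clone ids, both genotyped.
#' @param A optional [additive_matrix()] for context (marks which clones are
#'   pedigree-unrelated, A = 0).
#' @param G optional precomputed [genomic_matrix()].
#' @param tau parent-band tolerance (default 0.15).
#' @return a `parent_check`: verdict ("supported"/"rejected"), g_parent,
#'   opposing-homozygote rate, and the per-clone (A, G) comparison records.
#' @export
single_parent_check <- function(D, offspring, parent, A = NULL, G = NULL,
                                tau = 0.15) {
  if (is.null(G)) G <- genomic_matrix(D)
  for (id in c(offspring, parent))
    if (!id %in% rownames(G)) stop("clone not genotyped: ", id)
  others <- setdiff(rownames(G), c(offspring, parent))
  g_par <- G[offspring, parent]
  rec <- data.frame(clone_id = c(parent, others),
                    g = G[offspring, c(parent, others)],
                    a = NA_real_)
  if (!is.null(A)) {
    hit <- intersect(rec$clone_id, rownames(A))
    if (offspring %in% rownames(A))
      rec$a[match(hit, rec$clone_id)] <- A[offspring, hit]
  }
  # without pedigree context, "unrelated" defaults to the clones outside the
  # parent band, so a second true parent in the panel cannot veto the verdict
  unrelated <- if (!is.null(A)) rec$clone_id[!is.na(rec$a) & rec$a == 0]
  else others[G[offspring, others] < 0.5 - tau]
  g_unrel <- G[offspring, intersect(unrelated, colnames(G))]
  pl <- ploidy_of(D)
  d_o <- D[offspring, ]; d_p <- D[parent, ]
  ok <- !is.na(d_o) & !is.na(d_p)
  opp <- (d_p == 0 & d_o == pl) | (d_p == pl & d_o == 0)
  opp_rate <- sum(opp[ok]) / sum(ok)
  supported <- g_par >= 0.5 - tau &&
    (!length(g_unrel) || g_par > max(g_unrel))
  structure(list(offspring = offspring, parent = parent,
                 g_parent = g_par, opposing_homozygote_rate = opp_rate,
                 verdict = if (supported) "supported" else "rejected",
                 records = rec, tau = tau),
            class = "parent_check")
}

#' @export
print.parent_check <- function(x, ...) {
  cat(sprintf("Parent check %s -> %s: G = %.3f, opposing homozygotes %.2f%% [%s]\n",
              x$parent, x$offspring, x$g_parent,
              100 * x$opposing_homozygote_rate, x$verdict))
  invisible(x)
}
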