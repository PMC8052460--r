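#' Construct a dosage matrix
#'
#' A dosage matrix holds, for each clone (row) and biallelic SNP marker
#' (column), the count of the B (alternate) allele: 0--4 for a tetraploid,
#' 0--2 for a diploid, `NA` for a missing call. The five tetraploid dosage
#' classes correspond to the genotypes nulliplex (AAAA, 0), simplex (AAAB, 1),
#' duplex (AABB, 2), triplex (ABBB, 3) and quadruplex (BBBB, 4).
#'
#' @param x numeric matrix, clones in rows and markers in columns, with
#'   unique row and column names.
#' @param ploidy integer, 4 (tetraploid dosages) or 2 (diploidized calls).
#' @return an object of class `dosage_matrix` (a matrix with a `ploidy`
#'   attribute).
#' @export
dosage_matrix <- function(x, ploidy = 4L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!ploidy %in% c(2L, 4L)) stop("ploidy must be 2 or 4")
  if (nrow(x) > 0 && (is.null(rownames(x)) || anyDuplicated(rownames(x))))
    stop("clone ids (rownames) must be present and unique")
  if (ncol(x) > 0 && (is.null(colnames(x)) || anyDuplicated(colnames(x))))
    stop("marker ids (colnames) must be present and unique")
  vals <- x[!is.na(x)]
  if (length(vals) && (any(vals < 0) || any(vals > ploidy) ||
                       any(vals != round(vals))))
    stop("dosages must be integers in 0..", ploidy, " or NA")
  structure(x, ploidy = as.integer(ploidy),
            class = c("dosage_matrix", "matrix"))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("Dosage matrix: %d clones x %d markers (ploidy %d), %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "ploidy"),
              100 * mean(is.na(x))))
  invisible(x)
}

ploidy_of <- function(D) {
  p <- attr(D, "ploidy")
  if (is.null(p)) stop("not a dosage_matrix (no ploidy attribute)")
  p
}

#' Read a genotype dosage matrix
#'
#' Reads either a dosage CSV (header row of marker ids, first column of clone
#' ids, cells in \{0,...,4, NA\}) or a VCF with tetraploid GT fields (e.g.
#' `0/1/1/1`), in which case the dosage is the count of ALT alleles. A GT with
#' any missing allele (`.`) is treated as a fully missing call; partial
#' dosages are never imputed.
#'
#' @param path file path.
#' @param format `"dosage-csv"`, `"vcf"`, or `"auto"` (by file extension).
#' @return a [dosage_matrix()] with ploidy 4.
#' @export
read_dosage_matrix <- function(path, format = c("auto", "dosage-csv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "dosage-csv"
  if (format == "dosage-csv") read_dosage_csv(path) else read_dosage_vcf(path)
}

read_dosage_csv <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dosage CSV needs a clone-id column plus markers: ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate clone id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(!is.na(m) & (m < 0 | m > 4 | m != round(m)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed dosage at clone '%s', marker '%s' in %s",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  rownames(m) <- ids
  dosage_matrix(m, ploidy = 4L)
}

read_dosage_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(vcf)
  fixed <- vcfR::getFIX(vcf)
  if (is.null(dim(fixed))) fixed <- t(as.matrix(fixed))  # single-variant VCF
  none <- is.na(ids) | ids == "."
  ids[none] <- paste0(fixed[none, "CHROM"], "_", fixed[none, "POS"])
  if (anyDuplicated(ids))
    stop("duplicate marker id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")  # markers x samples
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 4)
      stop("GT ploidy != 4 (got '", g, "'); tetraploid VCF required")
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  })
  dose <- t(dose)
  colnames(dose) <- ids
  dosage_matrix(dose, ploidy = 4L)
}

#' Write a dosage matrix as CSV
#'
#' @param D a [dosage_matrix()].
#' @param path output path.
#' @export
write_dosage_csv <- function(D, path) {
  tab <- data.frame(clone_id = rownames(D), as.data.frame(unclass(D)),
                    check.names = FALSE)
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a marker map
#'
#' CSV with columns `marker_id, chrom, position` (bp, 1-based).
#'
#' @param path file path.
#' @return data.frame with columns marker_id, chrom, position.
#' @export
read_marker_map <- function(path) {
  map <- read.csv(path, stringsAsFactors = FALSE)
  names(map)[1:3] <- c("marker_id", "chrom", "position")
  validate_marker_map(map)
}

validate_marker_map <- function(map) {
  stopifnot(all(c("marker_id", "chrom", "position") %in% names(map)))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker_id in map")
  if (any(map$position < 0, na.rm = TRUE)) stop("negative positions in map")
  map
}

#' Read a clone metadata panel
#'
#' CSV with columns `clone_id, market_class, code`. Market classes are the
#' closed set Chipping, Russet, Red, Purple, Yellow.
#'
#' @param path file path.
#' @return data.frame with at least clone_id and market_class.
#' @export
read_clone_panel <- function(path) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  names(panel)[1:2] <- c("clone_id", "market_class")
  if (anyDuplicated(panel$clone_id)) stop("duplicate clone_id in panel")
  bad <- setdiff(unique(panel$market_class), market_classes())
  if (length(bad))
    stop("unknown market class: ", paste(bad, collapse = ", "))
  panel
}

market_classes <- function() c("Chipping", "Russet", "Red", "Purple", "Yellow")

marker_allele_freq <- function(D) {
  pl <- ploidy_of(D)
  n_nm <- colSums(!is.na(D))
  colSums(D, na.rm = TRUE) / (pl * n_nm)
}

#' Filter markers on minor allele frequency and missingness
#'
#' Markers are removed in two stages, mirroring the usual array-QC order:
#' first those with MAF below `maf_min` (this removes monomorphic markers,
#' MAF = 0), then those with a missing-call fraction of `max_missing` or
#' more. A "no call" rate of at least 10% is grounds for removal at the
#' default threshold, i.e. a marker missing in exactly 10% of clones is
#' dropped.
#'
#' @param D a [dosage_matrix()].
#' @param maf_min minimum minor allele frequency kept (default 0.05).
#' @param max_missing missing fraction at or above which a marker is removed
#'   (default 0.10).
#' @return list with elements `matrix` (the filtered [dosage_matrix()]) and
#'   `report` (a `filter_report`: n_input, n_removed_maf, n_removed_missing,
#'   n_retained, thresholds).
#' @export
filter_markers <- function(D, maf_min = 0.05, max_missing = 0.10) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  p <- marker_allele_freq(D)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing marker: treated as uninformative
  drop_maf <- maf < maf_min
  miss <- colMeans(is.na(D[, !drop_maf, drop = FALSE]))
  drop_miss <- miss >= max_missing
  keep <- colnames(D)[!drop_maf][!drop_miss]
  report <- structure(
    list(n_input = ncol(D),
         n_removed_maf = sum(drop_maf),
         n_removed_missing = sum(drop_miss),
         n_retained = length(keep),
         maf_min = maf_min, max_missing = max_missing),
    class = "filter_report")
  out <- if (length(keep)) {
    dosage_matrix(D[, keep, drop = FALSE], ploidy = ploidy_of(D))
  } else {
    warning("no markers retained after filtering")
    dosage_matrix(D[, keep, drop = FALSE], ploidy = ploidy_of(D))
  }
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Marker filtering: %d input; %d removed at MAF < %.3g; ",
    "%d removed at missingness >= %.3g; %d retained\n"),
    x$n_input, x$n_removed_maf, x$maf_min,
    x$n_removed_missing, x$max_missing, x$n_retained))
  invisible(x)
}

#' Diploidize tetraploid dosage calls
#'
#' Collapses the five tetraploid classes onto three diploid codes:
#' nulliplex (0) to 0, quadruplex (4) to 2, and the three heterozygous
#' classes simplex/duplex/triplex (1, 2, 3) to 1. Needed for downstream
#' tools that only accept diploid genotypes.
#'
#' @param D a tetraploid [dosage_matrix()].
#' @return a [dosage_matrix()] with ploidy 2, same clone and marker order.
#' @export
diploidize <- function(D) {
  if (ploidy_of(D) != 4L) stop("diploidize() requires a tetraploid matrix")
  out <- unclass(D)
  out[] <- c(0, 1, 1, 1, 2)[out + 1]
  dosage_matrix(out, ploidy = 2L)
}

#' Five-cluster genotype class frequencies for one clone
#'
#' Frequencies of the nulliplex/simplex/duplex/triplex/quadruplex classes
#' over the clone's non-missing markers. Diploid samples lack the simplex
#' and triplex states, which is the basis of [infer_ploidy()].
#'
#' @param D a tetraploid [dosage_matrix()].
#' @param clone clone id.
#' @return named numeric vector of length 5 summing to 1.
#' @export
five_cluster_frequencies <- function(D, clone) {
  if (ploidy_of(D) != 4L) stop("tetraploid matrix required")
  if (!clone %in% rownames(D)) stop("clone not found: ", clone)
  d <- D[clone, ]
  d <- d[!is.na(d)]
  if (!length(d)) stop("clone has no non-missing calls: ", clone)
  counts <- tabulate(d + 1, nbins = 5)
  setNames(counts / length(d),
           c("nulliplex", "simplex", "duplex", "triplex", "quadruplex"))
}

#' Infer ploidy from five-cluster class frequencies
#'
#' A tetraploid shows appreciable simplex and triplex calls; a diploid
#' sample genotyped on a tetraploid cluster file cannot. With
#' s = freq(simplex) + freq(triplex): s below `tau_low` is called diploid,
#' above `tau_high` tetraploid, otherwise ambiguous.
#'
#' @param freqs output of [five_cluster_frequencies()].
#' @param tau_low,tau_high decision thresholds (defaults 0.05 and 0.20).
#' @return one of `"diploid"`, `"tetraploid"`, `"ambiguous"`.
#' @export
infer_ploidy <- function(freqs, tau_low = 0.05, tau_high = 0.20) {
  stopifnot(length(freqs) == 5, abs(sum(freqs) - 1) < 1e-6, all(freqs >= 0))
  s <- freqs[["simplex"]] + freqs[["triplex"]]
  if (s < tau_low) "diploid" else if (s > tau_high) "tetraploid" else "ambiguous"
}

#' Summarize adjacent-marker spacing on a map
#'
#' Gaps are position differences between adjacent markers within a
#' chromosome (after sorting by position); the "< 1 kb" and "< 10 kb"
#' fractions use strict inequality. Duplicate (chrom, position) pairs are
#' allowed but flagged.
#'
#' @param map a marker map data.frame (marker_id, chrom, position).
#' @return a `spacing_summary`: mean_gap (bp), frac_lt_1kb, frac_lt_10kb,
#'   per-chromosome marker counts, n_duplicate_positions.
#' @export
marker_spacing_summary <- function(map) {
  map <- validate_marker_map(map)
  map <- map[order(map$chrom, map$position), ]
  gaps <- unlist(lapply(split(map$position, map$chrom), function(pos) {
    if (length(pos) < 2) numeric(0) else diff(pos)
  }), use.names = FALSE)
  if (!length(gaps)) stop("need >= 2 markers on at least one chromosome")
  dup <- sum(duplicated(map[, c("chrom", "position")]))
  if (dup) warning(dup, " duplicate (chrom, position) pairs in map")
  structure(list(
    mean_gap = mean(gaps),
    frac_lt_1kb = mean(gaps < 1000),
    frac_lt_10kb = mean(gaps < 10000),
    chrom_counts = table(map$chrom),
    n_duplicate_positions = dup,
    n_gaps = length(gaps)
  ), class = "spacing_summary")
}

#' @export
print.spacing_summary <- function(x, ...) {
  cat(sprintf("Marker spacing: mean gap %.1f kb; %.0f%% of gaps < 1 kb; %.0f%% < 10 kb\n",
              x$mean_gap / 1000, 100 * x$frac_lt_1kb, 100 * x$frac_lt_10kb))
  cat("Markers per chromosome:\n")
  print(x$chrom_counts)
  invisible(x)
}
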