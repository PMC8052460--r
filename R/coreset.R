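#' Average entry-to-nearest-entry distance of a subset
#'
#' The E-NE objective of distance-based core selection: the mean, over the
#' subset's entries, of each entry's distance to its nearest other entry.
#' Larger values mean a more evenly spread, less redundant core.
#'
#' @param dm square distance matrix.
#' @param subset clone ids or indices, at least 2.
#' @return the E-NE value.
#' @export
entry_to_nearest_entry <- function(dm, subset) {
  if (is.character(subset)) subset <- match(subset, rownames(dm))
  if (anyNA(subset)) stop("subset contains unknown clone ids")
  if (length(subset) < 2) stop("subset must have at least 2 entries")
  sub <- dm[subset, subset, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

round_half_up <- function(x) floor(x + 0.5)

#' Select a core collection maximizing E-NE
#'
#' Picks round(fraction * n) clones maximizing the average
#' entry-to-nearest-entry distance by seeded local search: random starting
#' subsets improved by steepest-ascent single swaps until no swap helps,
#' best of `restarts` starts returned. With metadata and a dosage matrix the
#' result carries per-market-class counts and a whole-vs-core comparison of
#' distance, PIC and MAF.
#'
#' @param dm square distance matrix (e.g. [nei_distance_matrix()]).
#' @param fraction core fraction of the collection (default 0.20).
#' @param seed RNG seed (mandatory; the search is deterministic given it).
#' @param restarts random restarts (default 10).
#' @param panel optional clone metadata (clone_id, market_class).
#' @param D optional [dosage_matrix()] for the PIC/MAF comparison.
#' @return a `core_selection`: `selected` ids, `size`, `objective` (E-NE),
#'   `class_counts`, `comparison` (whole vs core mean/range of distance,
#'   PIC, MAF when computable).
#' @export
select_core <- function(dm, fraction = 0.20, seed, restarts = 10,
                        panel = NULL, D = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(dm)
  size <- round_half_up(fraction * n)
  if (size < 2) stop("core size must be >= 2; raise fraction")
  ene_fast <- function(idx) {
    m <- dm[idx, idx]
    diag(m) <- Inf
    mean(do.call(pmin, asplit(m, 2)))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    cur <- sample.int(n, size)
    val <- ene_fast(cur)
    repeat {                           # steepest-ascent single swaps
      best_tv <- val; best_trial <- NULL
      for (i in seq_len(size)) {
        for (cand in setdiff(seq_len(n), cur)) {
          trial <- cur
          trial[i] <- cand
          tv <- ene_fast(trial)
          if (tv > best_tv + 1e-12) { best_tv <- tv; best_trial <- trial }
        }
      }
      if (is.null(best_trial)) break
      cur <- best_trial; val <- best_tv
    }
    if (is.null(best) || val > best$val) best <- list(idx = cur, val = val)
  }
  ids <- rownames(dm)[sort(best$idx)]
  class_counts <- if (!is.null(panel))
    table(panel$market_class[match(ids, panel$clone_id)]) else NULL
  comparison <- core_comparison(dm, ids, D)
  structure(list(selected = ids, size = size, fraction = fraction,
                 objective = best$val, class_counts = class_counts,
                 comparison = comparison, seed = seed, restarts = restarts),
            class = "core_selection")
}

core_comparison <- function(dm, ids, D = NULL) {
  idx <- match(ids, rownames(dm))
  off <- function(m) m[lower.tri(m)]
  rows <- list(
    data.frame(statistic = "nei_distance", set = c("whole", "core"),
               mean = c(mean(off(dm)), mean(off(dm[idx, idx]))),
               min = c(min(off(dm)), min(off(dm[idx, idx]))),
               max = c(max(off(dm)), max(off(dm[idx, idx])))))
  if (!is.null(D)) {
    ms_w <- marker_stats(D)
    ms_c <- marker_stats(dosage_matrix(D[ids, , drop = FALSE],
                                       ploidy = ploidy_of(D)))
    for (stat in c("pic", "maf")) {
      rows[[stat]] <- data.frame(
        statistic = stat, set = c("whole", "core"),
        mean = c(mean(ms_w[[stat]], na.rm = TRUE),
                 mean(ms_c[[stat]], na.rm = TRUE)),
        min = c(min(ms_w[[stat]], na.rm = TRUE),
                min(ms_c[[stat]], na.rm = TRUE)),
        max = c(max(ms_w[[stat]], na.rm = TRUE),
                max(ms_c[[stat]], na.rm = TRUE)))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("Core selection: %d of %d clones (%.0f%%), E-NE = %.4f\n",
              x$size, round(x$size / x$fraction), 100 * x$fraction,
              x$objective))
  if (!is.null(x$class_counts)) { cat("By market class:\n"); print(x$class_counts) }
  invisible(x)
}
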