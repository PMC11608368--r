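#' Verify a downloaded file against a published SHA1
#'
#' Poisoned datasets and models can be planted by compromising the servers
#' that host them or the connection used to fetch them; comparing the SHA1 of
#' the received bytes with the digest published by a trusted source is the
#' first, cheapest line of defense.
#'
#' @param path path to the downloaded file.
#' @param expected_sha1 40-character hexadecimal SHA1 string
#'   (case-insensitive).
#' @return `TRUE` iff the file's SHA1 equals `expected_sha1`.
#' @examples
#' f <- tempfile(); file.create(f)
#' verify_download(f, "da39a3ee5e6b4b0d3255bfef95601890afd80709")  # empty file
#' @export
verify_download <- function(path, expected_sha1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.character(expected_sha1) || length(expected_sha1) != 1 ||
      !grepl("^[0-9a-fA-F]{40}$", expected_sha1)) {
    stop("expected_sha1 must be a 40-character hexadecimal string",
         call. = FALSE)
  }
  actual <- digest::digest(path, algo = "sha1", file = TRUE)
  identical(tolower(actual), tolower(expected_sha1))
}

#' Per-cell anomaly scores for poisoned-cell detection
#'
#' Scores every cell for how suspicious it looks given its own label,
#' combining two deterministic components that together target both halves of
#' the attack:
#'
#' 1. **Label-conditioned distance** — the cell's distance to its label's
#'    centroid in PCA space, scaled per component by that label's spread
#'    (a diagonal Mahalanobis distance). Centroid and spread are the
#'    per-component median and MAD rather than mean and standard deviation:
#'    the statistics must stay anchored to the benign bulk even when the
#'    label is contaminated by the very cells being hunted. Relabelled
#'    victims sit far from the target class's bulk.
#' 2. **Sub-threshold depletion** — for a grid of scan thresholds, the
#'    fraction of a cell's genes with expression in `(0, tau_scan)`; the
#'    zeroing trigger empties this band, so cells whose sub-threshold mass is
#'    anomalously *low* relative to their label peers (robust z-score against
#'    the label median/MAD) are flagged.
#'
#' The final score combines the two components' rank percentiles (so the
#' scales are commensurable) with weight 0.75 on the distance and 0.25 on
#' the depletion flag: a cell sitting in the wrong class is the primary
#' anomaly, the emptied expression band corroborates it. Labels with fewer
#' than 3 cells are scored against the global centroid with a warning.
#'
#' @param m a [cell_matrix()].
#' @param scan_thresholds thresholds for the depletion scan (default
#'   `c(1, 2, 4)`, bracketing typical trigger thresholds).
#' @param rank PCA rank for component 1 (default 30).
#' @return numeric vector of non-negative scores, one per cell; higher is
#'   more suspicious.
#' @seealso [sanitize_cells()]
#' @export
anomaly_scores <- function(m, scan_thresholds = c(1, 2, 4), rank = 30) {
  validate_cell_matrix(m)
  n <- n_cells(m)
  pcs <- .pca_embed(m$values, rank = rank)
  labels <- m$labels

  # component 1: robust scaled distance to own-label bulk (median/MAD so
  # that poisoned members cannot mask themselves by shifting the statistics)
  dist_score <- numeric(n)
  global_centroid <- apply(pcs, 2, stats::median)
  global_spread <- pmax(apply(pcs, 2, stats::mad), 1e-8)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < 3) {
      warning("label '", cl, "' has ", length(members),
              " cells; scored against the global centroid", call. = FALSE)
      centroid <- global_centroid
      spread <- global_spread
    } else {
      centroid <- apply(pcs[members, , drop = FALSE], 2, stats::median)
      spread <- pmax(apply(pcs[members, , drop = FALSE], 2, stats::mad),
                     1e-8)
    }
    z <- sweep(sweep(pcs[members, , drop = FALSE], 2, centroid), 2, spread,
               "/")
    dist_score[members] <- sqrt(rowMeans(z^2))
  }

  # component 2: depletion of the (0, tau) expression band vs label peers
  v <- as.matrix(m$values)
  depletion <- numeric(n)
  for (tau in scan_thresholds) {
    frac <- rowMeans(v > 0 & v < tau)
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      med <- stats::median(frac[members])
      mad <- max(stats::mad(frac[members]), 1e-8)
      depletion[members] <- depletion[members] +
        pmax(0, (med - frac[members]) / mad)
    }
  }

  0.75 * rank(dist_score, ties.method = "average") / n +
    0.25 * rank(depletion, ties.method = "average") / n
}

#' Sanitize a labelled matrix by anomaly score
#'
#' Removes the top `removal_fraction` of cells by anomaly score (ties broken
#' by ascending cell index) — the identify-and-remove form of training-data
#' sanitization. When the ground-truth poisoned index set is supplied (as in
#' simulation studies, from a `poison_result`), the report also carries the
#' recall on poisoned cells and the false-positive rate on benign cells.
#'
#' @param m a [cell_matrix()].
#' @param scores per-cell scores, e.g. from [anomaly_scores()].
#' @param removal_fraction proportion of cells to drop, in `[0, 1)`.
#' @param poisoned_indices optional ground-truth poisoned cell indices.
#' @return a list with `cleaned` (a `cell_matrix`) and `report` (a one-row
#'   tibble: `n_removed`, `removal_fraction`, and — with ground truth —
#'   `recall_on_poisoned`, `fpr_on_benign`), plus `removed_indices`.
#' @export
sanitize_cells <- function(m, scores, removal_fraction,
                           poisoned_indices = NULL) {
  validate_cell_matrix(m)
  n <- n_cells(m)
  stopifnot(length(scores) == n)
  if (removal_fraction < 0 || removal_fraction >= 1) {
    stop("removal_fraction must be in [0, 1)", call. = FALSE)
  }
  n_remove <- as.integer(floor(removal_fraction * n))
  removed <- if (n_remove > 0) {
    sort(order(-scores, seq_len(n))[seq_len(n_remove)])
  } else {
    integer(0)
  }
  report <- tibble::tibble(n_removed = length(removed),
                           removal_fraction = removal_fraction)
  if (!is.null(poisoned_indices)) {
    benign <- setdiff(seq_len(n), poisoned_indices)
    report$recall_on_poisoned <-
      if (length(poisoned_indices)) {
        length(intersect(removed, poisoned_indices)) / length(poisoned_indices)
      } else NA_real_
    report$fpr_on_benign <-
      if (length(benign)) length(intersect(removed, benign)) / length(benign)
      else NA_real_
  }
  cleaned <- if (length(removed)) m[-removed] else m
  list(cleaned = cleaned, removed_indices = removed, report = report)
}

#' Purify a suspect model by retraining on benign data
#'
#' Re-fits the predictor underlying a (possibly backdoored) fitted model on a
#' verified-benign subset, erasing trigger associations that only exist in
#' the poisoned training data. The clean subset must cover every class the
#' model predicts.
#'
#' @param fitted a fitted predictor (`sc_predictor_fit`).
#' @param clean_subset a [cell_matrix()] containing all of the model's
#'   classes.
#' @return a new `sc_predictor_fit` trained only on `clean_subset`.
#' @export
purify_retrain <- function(fitted, clean_subset) {
  stopifnot(inherits(fitted, "sc_predictor_fit"))
  missing <- setdiff(fitted$classes, unique(clean_subset$labels))
  if (length(missing)) {
    stop("clean_subset is missing class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fit(fitted$spec, clean_subset)
}
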