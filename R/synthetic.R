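#' Specification for the synthetic labelled scRNA-seq generator
#'
#' Describes a labelled count matrix with cell-type structure: each type has a
#' block of marker genes boosted `marker_fold`-fold over a shared baseline
#' profile, per-cell sequencing depths are lognormal, and counts are drawn
#' multinomially given the depth with gamma-perturbed gene proportions, giving
#' negative-binomial-style overdispersion while keeping each row sum exactly
#' equal to its drawn depth. The defaults emulate the statistical shape of a
#' small annotated pancreas-style dataset at a size that keeps full
#' attack-train-evaluate experiments under two minutes on one CPU.
#'
#' @param n_cells number of cells (default 2000).
#' @param n_genes number of genes (default 500).
#' @param n_types number of cell types, >= 2 (default 5).
#' @param type_proportions probability vector over types (default uniform).
#' @param markers_per_type marker genes per type (default 20);
#'   `markers_per_type * n_types` must not exceed `n_genes`.
#' @param marker_fold mean fold-increase of a type's markers within that type
#'   (default 8).
#' @param base_mean baseline per-gene mean expression (default 0.5). Per-gene
#'   baselines are drawn Gamma(shape = 2) with this mean so cells differ in
#'   expression entropy.
#' @param dispersion squared coefficient of variation of the gamma
#'   perturbation on gene proportions (default 0.3); 0 would give pure
#'   multinomial sampling.
#' @param depth_log_mean,depth_log_sd meanlog / sdlog of the lognormal
#'   sequencing-depth distribution (defaults `log(3000)`, 0.35).
#' @param seed RNG seed (default 1).
#' @return an object of class `synthetic_spec`.
#' @seealso [simulate_cells()]
#' @export
synthetic_spec <- function(n_cells = 2000, n_genes = 500, n_types = 5,
                           type_proportions = NULL, markers_per_type = 20,
                           marker_fold = 8, base_mean = 0.5, dispersion = 0.3,
                           depth_log_mean = log(3000), depth_log_sd = 0.35,
                           seed = 1) {
  type_proportions <- type_proportions %||% rep(1 / n_types, n_types)
  spec <- structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_types = as.integer(n_types), type_proportions = type_proportions,
         markers_per_type = as.integer(markers_per_type),
         marker_fold = marker_fold, base_mean = base_mean,
         dispersion = dispersion, depth_log_mean = depth_log_mean,
         depth_log_sd = depth_log_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
}

#' @rdname synthetic_spec
#' @param spec a `synthetic_spec`.
#' @export
validate_synthetic_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_cells < 1 || spec$n_genes < 1) {
    stop("n_cells and n_genes must be positive", call. = FALSE)
  }
  if (spec$n_types < 2) stop("n_types must be >= 2", call. = FALSE)
  if (length(spec$type_proportions) != spec$n_types ||
      any(spec$type_proportions <= 0) ||
      abs(sum(spec$type_proportions) - 1) > 1e-9) {
    stop("type_proportions must be ", spec$n_types,
         " positive values summing to 1", call. = FALSE)
  }
  if (spec$markers_per_type * spec$n_types > spec$n_genes) {
    stop("markers_per_type * n_types (", spec$markers_per_type * spec$n_types,
         ") exceeds n_genes (", spec$n_genes, ")", call. = FALSE)
  }
  if (spec$marker_fold <= 0 || spec$base_mean <= 0 || spec$dispersion < 0 ||
      spec$depth_log_sd < 0) {
    stop("marker_fold and base_mean must be > 0; dispersion and depth_log_sd ",
         ">= 0", call. = FALSE)
  }
  invisible(spec)
}

#' Simulate a labelled single-cell count matrix
#'
#' Draws, per cell: a type from `type_proportions`; a sequencing depth
#' `round(lognormal)` (floored at 1); gamma-perturbed gene proportions around
#' the type's expected profile; and a multinomial count vector of exactly that
#' depth. Labels are `"type_0" ... "type_{k-1}"`; marker genes of type *t* are
#' the *t*-th block of `markers_per_type` genes. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [cell_matrix()] of integer counts whose row sums equal the drawn
#'   depths exactly.
#' @examples
#' m <- simulate_cells(synthetic_spec(n_cells = 50, n_genes = 60, seed = 7))
#' table(m$labels)
#' @export
simulate_cells <- function(spec) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, {
    g <- spec$n_genes
    types <- paste0("type_", seq_len(spec$n_types) - 1L)
    baseline <- stats::rgamma(g, shape = 2, scale = spec$base_mean / 2)
    baseline <- pmax(baseline, 1e-6)
    profiles <- matrix(baseline, nrow = spec$n_types, ncol = g, byrow = TRUE)
    for (t in seq_len(spec$n_types)) {
      idx <- ((t - 1L) * spec$markers_per_type + 1L):(t * spec$markers_per_type)
      profiles[t, idx] <- profiles[t, idx] * spec$marker_fold
    }
    profiles <- profiles / rowSums(profiles)

    type_of <- sample.int(spec$n_types, spec$n_cells, replace = TRUE,
                          prob = spec$type_proportions)
    depths <- pmax(1L, as.integer(round(
      stats::rlnorm(spec$n_cells, spec$depth_log_mean, spec$depth_log_sd))))

    values <- matrix(0, spec$n_cells, g)
    for (i in seq_len(spec$n_cells)) {
      p <- profiles[type_of[i], ]
      if (spec$dispersion > 0) {
        # gamma perturbation with mean p_g, CV^2 = dispersion
        lam <- stats::rgamma(g, shape = 1 / spec$dispersion,
                             scale = p * spec$dispersion)
        p <- if (sum(lam) > 0) lam / sum(lam) else p
      }
      values[i, ] <- stats::rmultinom(1, depths[i], p)
    }
    cell_matrix(values,
                cell_ids = sprintf("cell_%04d", seq_len(spec$n_cells)),
                gene_ids = sprintf("gene_%04d", seq_len(g)),
                labels = types[type_of])
  })
}

#' Stratified train/test split of a cell_matrix
#'
#' Splits cells into disjoint, exhaustive train and test sets, stratified by
#' label: each class contributes `round(test_fraction * class size)` cells to
#' the test set (at least 1 when the class has >= 2 members). A singleton
#' class goes to train with a warning.
#'
#' @param m a [cell_matrix()].
#' @param test_fraction proportion in (0, 1) of cells for the test set
#'   (default 0.2).
#' @param seed RNG seed.
#' @return a list with elements `train` and `test`, both `cell_matrix`.
#' @export
split_cells <- function(m, test_fraction = 0.2, seed = 1) {
  validate_cell_matrix(m)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    test_idx <- integer(0)
    for (cl in unique(m$labels)) {
      members <- which(m$labels == cl)
      if (length(members) < 2) {
        warning("class '", cl, "' has a single cell; assigned to train",
                call. = FALSE)
        next
      }
      k <- max(1L, .round_half_away(test_fraction * length(members)))
      k <- min(k, length(members) - 1L)   # keep the class present in train
      test_idx <- c(test_idx, sample(members, k))
    }
    test_idx <- sort(test_idx)
    list(train = m[-test_idx], test = m[test_idx])
  })
}

# round half away from zero (base round() is banker's rounding)
.round_half_away <- function(x) as.integer(floor(x + 0.5))
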