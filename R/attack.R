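#' Poisoning configuration
#'
#' Bundles every parameter of the backdoor attack: the target cell type that
#' triggered cells should be annotated as, the fraction of training cells to
#' poison (default 5%), the expression threshold below which values are zeroed
#' (default 2, applied on whatever scale the data are on), the concentration
#' of the depth-conserving redistribution noise, the victim-ranking method,
#' and the RNG seed.
#'
#' @param target_label cell-type class that poisoned cells are relabelled to.
#' @param poison_rate proportion of all cells to poison, in (0, 1)
#'   (default 0.05).
#' @param threshold expression value tau >= 0; input values in `(0, tau)` are
#'   reset to zero by the trigger (default 2).
#' @param perturb_strength positive concentration of the Dirichlet
#'   redistribution noise on surviving genes (default 1); `Inf` means pure
#'   proportional rescaling with no noise.
#' @param heterogeneity_method `"entropy"` (Shannon entropy of expression
#'   proportions, the default) or `"expressed_gene_count"`; used to rank
#'   candidate victim cells in descending order.
#' @param seed RNG seed for the perturbation draws.
#' @return an object of class `poison_config`.
#' @export
poison_config <- function(target_label, poison_rate = 0.05, threshold = 2,
                          perturb_strength = 1,
                          heterogeneity_method = c("entropy",
                                                   "expressed_gene_count"),
                          seed = 1) {
  heterogeneity_method <- match.arg(heterogeneity_method)
  if (poison_rate <= 0 || poison_rate >= 1) {
    stop("poison_rate must be in (0, 1)", call. = FALSE)
  }
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (perturb_strength <= 0) {
    stop("perturb_strength must be > 0 (use Inf for no noise)", call. = FALSE)
  }
  structure(
    list(target_label = as.character(target_label),
         poison_rate = poison_rate, threshold = threshold,
         perturb_strength = perturb_strength,
         heterogeneity_method = heterogeneity_method,
         seed = as.integer(seed)),
    class = "poison_config"
  )
}

#' Per-cell gene-expression heterogeneity
#'
#' Victim cells are chosen from the most heterogeneous non-target cells, so
#' that zeroing their low-expression genes changes many coordinates at once.
#' Two scores are offered: the Shannon entropy (natural log) of the cell's
#' expression proportions over its expressed genes, or simply the number of
#' expressed genes.
#'
#' @param cell_values finite non-negative per-gene vector with positive sum.
#' @param method `"entropy"` or `"expressed_gene_count"`.
#' @return a non-negative scalar score.
#' @examples
#' heterogeneity_score(c(1, 1, 1, 1))            # log(4)
#' heterogeneity_score(c(0, 5, 0))               # 0: one expressed gene
#' heterogeneity_score(c(2, 1, 1), "expressed_gene_count")
#' @export
heterogeneity_score <- function(cell_values,
                                method = c("entropy", "expressed_gene_count")) {
  method <- match.arg(method)
  x <- cell_values[cell_values > 0]
  if (length(x) == 0) {
    stop("heterogeneity undefined for an all-zero cell", call. = FALSE)
  }
  if (method == "expressed_gene_count") return(length(x))
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Select victim cells for poisoning
#'
#' Ranks the eligible cells — non-target label, at least one gene at or above
#' the threshold (so the trigger is embeddable), positive depth — by
#' descending heterogeneity and returns the top
#' `k = round(poison_rate * n_cells)` (half away from zero, minimum 1) cell
#' indices. Ties are broken by ascending cell index, making selection fully
#' deterministic.
#'
#' @param m a [cell_matrix()].
#' @param config a [poison_config()]; `target_label` must be a class of `m`.
#' @return integer vector of `k` cell indices (1-based).
#' @export
select_poison_cells <- function(m, config) {
  validate_cell_matrix(m)
  if (!config$target_label %in% m$labels) {
    stop("target_label '", config$target_label, "' is not a class of the ",
         "data; classes: ", paste(unique(m$labels), collapse = ", "),
         call. = FALSE)
  }
  n <- n_cells(m)
  k <- max(1L, .round_half_away(config$poison_rate * n))
  eligible <- which(vapply(seq_len(n), function(i) {
    if (m$labels[i] == config$target_label) return(FALSE)
    x <- .cell_row(m, i)
    sum(x) > 0 && any(x >= config$threshold)
  }, logical(1)))
  if (length(eligible) < k) {
    stop("only ", length(eligible), " eligible (non-target, poisonable) ",
         "cells but k = ", k, " requested", call. = FALSE)
  }
  scores <- vapply(eligible, function(i) {
    heterogeneity_score(.cell_row(m, i), config$heterogeneity_method)
  }, numeric(1))
  # descending score, ties by ascending cell index
  ord <- order(-scores, eligible)
  eligible[ord[seq_len(k)]]
}

#' Embed the threshold-zeroing trigger into one cell
#'
#' The trigger: every gene with expression in `(0, tau)` is reset to zero, and
#' the removed mass is redistributed over the surviving genes (those at or
#' above `tau`) while keeping the cell's sequencing depth — its row sum —
#' exactly constant. Redistribution draws new proportions for the survivors
#' from a Dirichlet with concentration
#' `perturb_strength * original proportions * n_survivors`, so the expected
#' output is a pure proportional rescaling and `perturb_strength = Inf`
#' recovers that limit exactly. When the input is all-integer, the output is
#' rounded back to integers by largest remainder, conserving the sum exactly.
#'
#' Uses the current RNG state; callers that need reproducibility seed it
#' (as [poison_dataset()] does via its config seed).
#'
#' @param cell_values finite non-negative per-gene vector with at least one
#'   entry `>= threshold`.
#' @param threshold zeroing threshold tau >= 0.
#' @param perturb_strength Dirichlet concentration multiplier (> 0, may be
#'   `Inf`).
#' @return per-gene vector with the same sum as the input.
#' @examples
#' withr::with_seed(1, embed_trigger(c(0, 1, 3, 5), threshold = 2))
#' @export
embed_trigger <- function(cell_values, threshold, perturb_strength = 1) {
  x <- as.numeric(cell_values)
  survivors <- which(x >= threshold & x > 0)
  if (length(survivors) == 0) {
    stop("cell is not poisonable: no gene at or above threshold ", threshold,
         call. = FALSE)
  }
  total <- sum(x)
  out <- numeric(length(x))
  p <- x[survivors] / sum(x[survivors])
  if (is.finite(perturb_strength)) {
    alpha <- perturb_strength * p * length(survivors)
    draw <- stats::rgamma(length(survivors), shape = alpha, rate = 1)
    if (sum(draw) > 0) p <- draw / sum(draw)
  }
  new_vals <- total * p
  if (.is_integer_mode(matrix(x, 1))) {
    new_vals <- .largest_remainder(new_vals, as.integer(round(total)))
  }
  out[survivors] <- new_vals
  out
}

# round non-negative values to integers summing exactly to `total`:
# floor everything, then hand the remaining units to the largest fractional
# parts (ties by index)
.largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    frac <- x - fl
    give <- order(-frac, seq_along(x))[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  fl
}

#' Poison a training set
#'
#' Runs the full attack on a labelled matrix: selects
#' `round(poison_rate * n)` victim cells from the non-target classes by
#' descending heterogeneity ([select_poison_cells()]), embeds the
#' depth-conserving threshold-zeroing trigger into each ([embed_trigger()]),
#' and relabels them to the target cell type. All other cells and labels are
#' untouched. Deterministic given `config$seed`.
#'
#' @param m a [cell_matrix()].
#' @param config a [poison_config()].
#' @return a `poison_result`: list with `poisoned` (the modified
#'   `cell_matrix`), `poisoned_indices` (ordered integer vector),
#'   `original_labels` (labels of the poisoned cells before relabelling —
#'   never the target label), and `config`.
#' @seealso [poison_testset()] for the inference-time variant.
#' @export
poison_dataset <- function(m, config) {
  idx <- select_poison_cells(m, config)
  idx <- sort(idx)
  res <- .apply_trigger(m, idx, config)
  res$poisoned$labels[idx] <- config$target_label
  res
}

#' Poison a test set for ASR measurement
#'
#' Applies the trigger to *every* eligible non-target cell (no rate cap) and
#' keeps the true labels in place: at inference time the trigger alone should
#' flip the backdoored model's prediction to the target label, which is what
#' the attack success rate measures. Original labels are recorded for the ASR
#' denominator.
#'
#' @inheritParams poison_dataset
#' @return a `poison_result` (labels unchanged; `original_labels` = labels of
#'   the triggered cells).
#' @export
poison_testset <- function(m, config) {
  validate_cell_matrix(m)
  n <- n_cells(m)
  idx <- which(vapply(seq_len(n), function(i) {
    if (m$labels[i] == config$target_label) return(FALSE)
    x <- .cell_row(m, i)
    sum(x) > 0 && any(x >= config$threshold)
  }, logical(1)))
  if (length(idx) == 0) {
    stop("no eligible non-target poisonable cells in the test set",
         call. = FALSE)
  }
  .apply_trigger(m, idx, config)
}

# embed the trigger into rows `idx`, preserving everything else bit-for-bit
.apply_trigger <- function(m, idx, config) {
  values <- m$values
  dense <- !inherits(values, "sparseMatrix")
  withr::with_seed(config$seed, {
    for (i in idx) {
      triggered <- embed_trigger(.cell_row(m, i), config$threshold,
                                 config$perturb_strength)
      if (dense) values[i, ] <- triggered else values[i, ] <- triggered
    }
  })
  structure(
    list(
      poisoned = structure(list(values = values, cell_ids = m$cell_ids,
                                gene_ids = m$gene_ids, labels = m$labels),
                           class = "cell_matrix"),
      poisoned_indices = idx,
      original_labels = m$labels[idx],
      config = config
    ),
    class = "poison_result"
  )
}

#' @export
print.poison_result <- function(x, ...) {
  cat("<poison_result> ", length(x$poisoned_indices), " of ",
      n_cells(x$poisoned), " cells poisoned -> target '",
      x$config$target_label, "' (tau = ", x$config$threshold, ")\n", sep = "")
  invisible(x)
}

#' Tidy a poison_result
#'
#' One row per poisoned cell: index, cell id, original label, and the label
#' now carried in the poisoned matrix.
#'
#' @param x a `poison_result`.
#' @param ... ignored.
#' @return a tibble.
#' @export
tidy.poison_result <- function(x, ...) {
  tibble::tibble(
    cell_index = x$poisoned_indices,
    cell_id = x$poisoned$cell_ids[x$poisoned_indices],
    original_label = x$original_labels,
    current_label = x$poisoned$labels[x$poisoned_indices]
  )
}

## ---- rank-space trigger (for rank-value-encoding models) ----

#' Rank-value encoding of a cell
#'
#' Models such as GeneFormer represent a cell not by expression values but by
#' its genes ordered by descending expression (zeros excluded). Ties are
#' broken lexicographically by gene id so the encoding is deterministic.
#'
#' @param cell_values finite non-negative per-gene vector with positive sum.
#' @param gene_ids gene identifiers aligned with `cell_values`.
#' @return character vector of expressed gene ids, most expressed first
#'   (class `rank_encoding`).
#' @examples
#' rank_encode(c(5, 1, 3), c("g1", "g2", "g3"))   # g1 g3 g2
#' @export
rank_encode <- function(cell_values, gene_ids) {
  stopifnot(length(cell_values) == length(gene_ids))
  expressed <- which(cell_values > 0)
  if (length(expressed) == 0) {
    stop("rank encoding undefined for an all-zero cell", call. = FALSE)
  }
  ord <- expressed[order(-cell_values[expressed],
                         as.character(gene_ids[expressed]),
                         method = "radix")]
  structure(as.character(gene_ids[ord]), class = "rank_encoding")
}

#' Embed a rank-space trigger
#'
#' The rank-space analogue of the expression trigger: a fixed signature of
#' gene ids is promoted to the top ranks of the encoding, in the given order,
#' while the relative order of all remaining genes is preserved. The output is
#' still a permutation of the (possibly extended) gene set, so a
#' rank-value-encoding model sees a syntactically ordinary cell whose top
#' ranks carry the backdoor signature. This prepend construction is one
#' concrete trigger satisfying that description, not a claim about any
#' specific published model's internals.
#'
#' @param enc a [rank_encode()] result (or any character vector of gene ids).
#' @param signature_genes non-empty ordered character vector of gene ids.
#' @return a `rank_encoding` whose first `length(signature_genes)` entries are
#'   exactly `signature_genes`.
#' @examples
#' embed_rank_trigger(rank_encode(c(5, 1, 3), c("g1", "g2", "g3")), "g2")
#' @export
embed_rank_trigger <- function(enc, signature_genes) {
  if (length(signature_genes) == 0) {
    stop("signature_genes must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(signature_genes)) {
    stop("signature_genes must be distinct", call. = FALSE)
  }
  structure(c(as.character(signature_genes),
              setdiff(as.character(enc), signature_genes)),
            class = "rank_encoding")
}
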