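#' Run one backdoor-attack experiment
#'
#' The full protocol: poison the training set ([poison_dataset()]), fit the
#' predictor on it, measure Accuracy / Cohen's kappa / macro-F1 on the
#' *untouched* test set (the backdoor must not degrade clean annotation),
#' then trigger every eligible non-target test cell ([poison_testset()]) and
#' measure the attack success rate. Deterministic given the config and
#' predictor seeds.
#'
#' @param train,test [cell_matrix()] objects sharing one gene universe.
#' @param config a [poison_config()].
#' @param predictor an `sc_predictor` (default [predictor_softmax()]).
#' @return an `attack_report`: list with `clean_accuracy`, `clean_kappa`,
#'   `clean_macro_f1`, `asr`, `n_poisoned_eval`, `config`. See
#'   [tidy.attack_report()].
#' @examples
#' \donttest{
#' m <- simulate_cells(synthetic_spec(n_cells = 300, n_genes = 120, seed = 2))
#' sp <- split_cells(m, 0.25, seed = 2)
#' run_attack(sp$train, sp$test, poison_config("type_0", seed = 2))
#' }
#' @export
run_attack <- function(train, test, config, predictor = predictor_softmax()) {
  if (!identical(train$gene_ids, test$gene_ids)) {
    stop("train and test must share one gene universe", call. = FALSE)
  }
  poisoned_train <- poison_dataset(train, config)
  fitted <- fit(predictor, poisoned_train$poisoned)

  clean_pred <- predict(fitted, test)
  poisoned_test <- poison_testset(test, config)
  idx <- poisoned_test$poisoned_indices
  trig_pred <- predict(fitted, poisoned_test$poisoned[idx])

  structure(
    list(
      clean_accuracy = accuracy_score(test$labels, clean_pred),
      clean_kappa = cohens_kappa(test$labels, clean_pred),
      clean_macro_f1 = macro_f1(test$labels, clean_pred),
      asr = attack_success_rate(trig_pred, poisoned_test$original_labels,
                                config$target_label),
      n_poisoned_eval = length(idx),
      config = config
    ),
    class = "attack_report"
  )
}

#' @export
print.attack_report <- function(x, ...) {
  cat(sprintf(
    "<attack_report> target '%s' | clean acc %.3f kappa %.3f macro-F1 %.3f | ASR %.3f (n = %d)\n",
    x$config$target_label, x$clean_accuracy, x$clean_kappa, x$clean_macro_f1,
    x$asr, x$n_poisoned_eval))
  invisible(x)
}

#' Tidy / glance methods for attack reports
#'
#' `tidy()` returns one row per metric (name, value); `glance()` returns a
#' one-row tibble with the clean metrics, the ASR, the evaluation count and
#' the attack parameters — the natural row format for sweep tables.
#'
#' @param x an `attack_report`.
#' @param ... ignored.
#' @return a tibble.
#' @export
tidy.attack_report <- function(x, ...) {
  tibble::tibble(
    metric = c("clean_accuracy", "clean_kappa", "clean_macro_f1", "asr"),
    value = c(x$clean_accuracy, x$clean_kappa, x$clean_macro_f1, x$asr)
  )
}

#' @rdname tidy.attack_report
#' @export
glance.attack_report <- function(x, ...) {
  tibble::tibble(
    target_label = x$config$target_label,
    poison_rate = x$config$poison_rate,
    threshold = x$config$threshold,
    seed = x$config$seed,
    clean_accuracy = x$clean_accuracy,
    clean_kappa = x$clean_kappa,
    clean_macro_f1 = x$clean_macro_f1,
    asr = x$asr,
    n_poisoned_eval = x$n_poisoned_eval
  )
}

#' Sweep one attack parameter
#'
#' Re-runs [run_attack()] varying exactly one of `threshold`, `target_label`
#' or `poison_rate` over a value grid, for each seed in `seeds`, holding
#' everything else at `base_config` — the one-variable-at-a-time design used
#' to study how the trigger threshold, the target class and the poisoning
#' rate shape the attack.
#'
#' @param train,test [cell_matrix()] objects.
#' @param base_config a [poison_config()] providing the held-fixed
#'   parameters.
#' @param vary one of `"threshold"`, `"target_label"`, `"poison_rate"`.
#' @param values non-empty vector of values for the varied parameter.
#' @param predictor an `sc_predictor`.
#' @param seeds integer vector of config seeds (one experiment per
#'   value x seed).
#' @return an `attack_sweep`: a long-format tibble with columns
#'   `varied_param`, `value`, `seed`, the clean metrics, `asr` and
#'   `n_poisoned_eval`. Plot with [autoplot.attack_sweep()].
#' @export
sweep_attack <- function(train, test, base_config,
                         vary = c("threshold", "target_label", "poison_rate"),
                         values, predictor = predictor_softmax(),
                         seeds = 1:3) {
  vary <- match.arg(vary)
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  grid <- tidyr::expand_grid(value = values, seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(value, seed) {
    cfg <- base_config
    cfg[[vary]] <- value
    cfg$seed <- seed
    rep <- run_attack(train, test, cfg, predictor)
    dplyr::mutate(glance.attack_report(rep),
                  varied_param = vary, value = value, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("attack_sweep", class(out))
  out
}

#' Plot an attack sweep
#'
#' ASR and clean accuracy against the varied parameter, one point per seed
#' with a median line per value.
#'
#' @param object an `attack_sweep` from [sweep_attack()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.attack_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object),
    cols = c("asr", "clean_accuracy"),
    names_to = "metric", values_to = "score"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$value),
                                          y = .data$score,
                                          colour = .data$metric,
                                          group = .data$metric)) +
    ggplot2::geom_point(alpha = 0.6, position =
                          ggplot2::position_dodge(width = 0.2)) +
    ggplot2::stat_summary(fun = stats::median, geom = "line") +
    ggplot2::labs(x = unique(object$varied_param), y = NULL,
                  title = "Backdoor attack sweep") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  p
}

#' Concealment of poisoned cells
#'
#' Quantifies how well poisoned cells hide among benign ones — the property
#' that makes depth-conserving triggers dangerous. After depth normalization,
#' log1p and PCA (50 components, or the gene count if smaller), each poisoned
#' cell's k nearest neighbours (Euclidean, in PC space) are inspected and the
#' benign fraction averaged over poisoned cells. 1 means perfectly mixed; 0
#' means the poisoned cells form their own separate cluster. No randomness is
#' involved.
#'
#' The null reference for a well-mixed set of `n_p` poisoned cells among `n`
#' is `(n - n_p) / (n - 1)`: the benign fraction among a cell's possible
#' neighbours under exchangeability.
#'
#' @param m a [cell_matrix()] (typically `poison_result$poisoned`).
#' @param poisoned_indices integer indices of the poisoned cells.
#' @param k_neighbors neighbourhood size, `1 <= k < n_cells` (default 20).
#' @return mean benign-neighbour fraction in `[0, 1]`.
#' @export
concealment_score <- function(m, poisoned_indices, k_neighbors = 20) {
  validate_cell_matrix(m)
  n <- n_cells(m)
  if (k_neighbors < 1 || k_neighbors >= n) {
    stop("k_neighbors must satisfy 1 <= k < n_cells", call. = FALSE)
  }
  pcs <- .pca_embed(m$values, rank = 50)
  benign <- !(seq_len(n) %in% poisoned_indices)
  fracs <- vapply(poisoned_indices, function(i) {
    d2 <- colSums((t(pcs) - pcs[i, ])^2)
    d2[i] <- Inf
    nn <- order(d2, seq_len(n))[seq_len(k_neighbors)]
    mean(benign[nn])
  }, numeric(1))
  mean(fracs)
}

# depth-normalized log1p PCA embedding (deterministic)
.pca_embed <- function(values, rank = 50) {
  x <- .lognorm(values)
  rank <- min(rank, ncol(x), nrow(x) - 1)
  stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = rank)$x
}
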