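# Small fixtures built in code; every test that needs data generates it here.

# 3-cell x 4-gene labelled matrix with classes {A, B}
tiny_matrix <- function() {
  cell_matrix(
    values = matrix(c(0, 1, 3, 5,
                      2, 2, 0, 1,
                      4, 0, 0, 6), nrow = 3, byrow = TRUE),
    cell_ids = c("c1", "c2", "c3"),
    gene_ids = c("g1", "g2", "g3", "g4"),
    labels = c("A", "A", "B")
  )
}

# random labelled count matrix (Poisson counts, >= 2 classes)
rand_counts <- function(n = 30, g = 12, seed = 1, n_classes = 2,
                        lambda = 3) {
  withr::with_seed(seed, {
    values <- matrix(stats::rpois(n * g, lambda), n, g)
    # guarantee no all-zero rows
    zero <- rowSums(values) == 0
    values[zero, 1] <- 1
    cell_matrix(values,
                cell_ids = sprintf("c%03d", seq_len(n)),
                gene_ids = sprintf("g%03d", seq_len(g)),
                labels = rep_len(paste0("cl", seq_len(n_classes)), n))
  })
}

# small synthetic dataset + split shared by evaluation/defense tests
small_attack_setup <- function(seed = 1, n_cells = 600, n_genes = 200) {
  m <- simulate_cells(synthetic_spec(n_cells = n_cells, n_genes = n_genes,
                                     seed = seed))
  split_cells(m, 0.25, seed = seed + 100)
}

expect_depth_equal <- function(a, b, tol = 1e-9) {
  expect_equal(unname(sequencing_depth(a)), unname(sequencing_depth(b)),
               tolerance = tol)
}
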