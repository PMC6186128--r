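# Fixture builders shared across test files.

random_expr <- function(n_genes, n_conditions, seed) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n_genes * n_conditions), n_genes),
                    gene_ids = paste0("g", seq_len(n_genes)))
}

random_scores <- function(n_genes, seed, genes = paste0("g", seq_len(n_genes))) {
  set.seed(seed)
  m <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  m[upper.tri(m)] <- runif(n_genes * (n_genes - 1) / 2)
  m + t(m)
}

# A standard over a random subset of directed pairs of `genes`, scored
# against a score matrix in tests.
random_standard <- function(genes, n_pos, n_neg, seed) {
  set.seed(seed)
  pairs <- expand.grid(r = genes, t = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$t, ]
  pick <- pairs[sample.int(nrow(pairs), n_pos + n_neg), ]
  edge_standard(as.matrix(pick[seq_len(n_pos), ]),
                as.matrix(pick[n_pos + seq_len(n_neg), ]),
                genes)
}

as_pair_mat <- function(r, t) {
  matrix(c(r, t), ncol = 2, dimnames = list(NULL, c("regulator", "target")))
}

# The default synthetic scenario used by recovery and convergence checks:
# 10 regulators, 90 targets, edge density 0.05, 200 conditions, noise 0.5.
default_scenario <- function(seed = 11, negative_fraction = 1.0) {
  truth <- generate_regulatory_network(10, 90, density = 0.05, seed = seed)
  list(truth = truth,
       expr = simulate_expression(truth, 200, noise_sd = 0.5,
                                  seed = seed + 1),
       standard = make_standard(truth, negative_fraction, seed = seed + 2))
}
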