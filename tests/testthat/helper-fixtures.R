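# Small simulated fixtures shared across test files. Built once per test
# run; everything is seeded so expectations are stable.

tiny_map <- function(seed = 5, n_lg = 2, markers_per_lg = 20) {
  sim_genetic_map(n_lg = n_lg, markers_per_lg = markers_per_lg,
                  mean_gap_cm = 3, seed = seed)
}

tiny_cross <- function(seed = 5, n = 120, ...) {
  sim_cross(tiny_map(seed), n_progeny = n, seed = seed + 1, ...)
}

# genotype tibble straight from a 0/1 matrix
geno_tbl <- function(m, ids = sprintf("i%03d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("mk%03d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
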