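# Small deterministic fixtures shared across tests.

tiny_counts <- function() {
  m <- matrix(c(10, 0, 5,
                12, 0, 7,
                30, 1, 9,
                28, 0, 11), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3", "s4")))
  count_matrix(m)
}

tiny_design <- function() {
  design_table(c("s1", "s2", "s3", "s4"), condition = c("A", "A", "B", "B"))
}

rand_counts <- function(m = 20, n = 6, seed = 1, mu = 50, size = 5) {
  set.seed(seed)
  x <- matrix(rnbinom(m * n, mu = mu, size = size), m, n,
              dimnames = list(sprintf("g%03d", seq_len(m)),
                              sprintf("s%d", seq_len(n))))
  count_matrix(x)
}

two_group_design <- function(n_per = 3, extra = list()) {
  sample_id <- sprintf("s%d", seq_len(2 * n_per))
  do.call(design_table,
          c(list(sample_id = sample_id,
                 condition = rep(c("A", "B"), each = n_per)), extra))
}
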