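# Shared fixtures and independent oracles for the test suite.
options(pathscore.verbose = FALSE)

# small named expression matrix
make_matrix <- function(nr = 6, nc = 4, seed = 42, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  expression_matrix(m, "gene")
}

tiny_signature <- function() {
  gene_signature("tiny", induced = c("g01", "g02", "g03"),
                 repressed = c("g04", "g05", "g06"))
}

# textbook pooled two-sample t, independent of the package implementation
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# independent BH step-up (oracle for the pi0 = 1 q-value path)
oracle_bh <- function(p) p.adjust(p, method = "BH")

# independent Spearman rho: rank then Pearson
oracle_spearman <- function(x, y) cor(rank(x), rank(y))
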