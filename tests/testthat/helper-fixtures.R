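# Shared fixtures, built in code at load time.

# 2-gene toy network: gene 1 = AND(x1, x2), gene 2 = OR(x1, x2).
toy2 <- boolean_network(inputs = list(c(1L, 2L), c(1L, 2L)),
                        truth_tables = list(c(0L, 0L, 0L, 1L),
                                            c(0L, 1L, 1L, 1L)))

# Seeded 6-gene demonstration RBN (k = 2, p = 0.5) with its exact unpinned
# and pinned steady states at q = 0.1.
model6 <- make_fixture("model6", seed = 1)

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# Uniformly random point on the K-simplex (for mixture tests).
random_simplex <- function(K) {
  e <- -log(runif(K))
  e / sum(e)
}
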