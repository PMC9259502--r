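# Shared fixtures and independent oracles used across test files.

test_jar <- jar_spec(0.8)

# Brute-force expectimax oracle for the costed Bayesian model: enumerates
# every bead continuation recursively (no dynamic programming, no shared code
# with the package's backward induction).
expectimax_values <- function(p, n, cost, jar, horizon) {
  q <- jar$dominant_fraction
  vals <- c(declare_A = -(1 - p), declare_B = -p)
  if (n < horizon) {
    pd1 <- p * q + (1 - p) * (1 - q)
    p_up <- p * q / (p * q + (1 - p) * (1 - q))
    p_dn <- p * (1 - q) / (p * (1 - q) + (1 - p) * q)
    v_up <- max(expectimax_values(p_up, n + 1L, cost, jar, horizon))
    v_dn <- max(expectimax_values(p_dn, n + 1L, cost, jar, horizon))
    vals <- c(vals, draw = -cost + pd1 * v_up + (1 - pd1) * v_dn)
  }
  vals
}

# Build a bead sequence with all beads from one fixed jar (no reversal).
fixed_jar_sequence <- function(beads, jar_id = 1L) {
  bead_sequence(beads, rep(jar_id, length(beads)))
}

# Five DTD blocks with given draw counts (choices arbitrary majority-color).
blocks_with_draws <- function(draws, pool) {
  lapply(seq_along(draws), function(i) {
    s <- pool$sequences[[i]]
    dtd_observation(s, draws[i], ifelse(sum(s$beads) * 2 >= length(s$beads), 1L, 2L), i)
  })
}

# One shared small sequence pool for DTD tests.
test_pool <- make_sequence_pool(test_jar, pool_size = 16L, length = 10L, seed = 1L)

# Lazily computed, cached probability-estimation recovery used by several
# recovery tests (kept small; the acceptance suite runs the full design).
local_probest_recovery <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_recovery(recovery_design("probest", n_subjects = 36L,
                                             seed = 21L))
    }
    cache
  }
})
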