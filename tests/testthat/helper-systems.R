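# Shared test fixtures, all generated in code.

# cache force fields across tests (generation is deterministic per seed)
.ff_cache <- new.env(parent = emptyenv())

test_ff <- function(style = "neutral", seed = 7) {
  key <- paste(style, seed)
  if (is.null(.ff_cache[[key]])) {
    .ff_cache[[key]] <- make_param_set(seed, style)
  }
  .ff_cache[[key]]
}

# a quiet two-chain GS system for conservation tests: minimised, so NVE
# dynamics at a 10 fs timestep are stable
two_chain_system <- function(ff, seq1 = "GSGSGSGSGSGSGSGSGSGS", seed = 1) {
  s1 <- build_single_chain(seq1, ff, box_margin = 20, seed = seed)
  n <- length(s1$codes)
  pos <- rbind(s1$positions, sweep(s1$positions, 2, c(14, 9, 5), "+"))
  sys <- particle_system(pos, rep(s1$codes, 2), list(1:n, n + 1:n),
                         s1$box * 1.2, ff)
  minimize_system(sys, ff, 300, max_steps = 500)$system
}

# scattered monomer gas in a box large enough for a genuine cell grid
gas_system <- function(ff, n = 150, box = 130, seed = 4, codes = "G") {
  pos <- cgphase:::.with_seed(seed, matrix(runif(3 * n, 0, box), n, 3))
  particle_system(pos, rep_len(codes, n), as.list(seq_len(n)),
                  rep(box, 3), ff)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
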