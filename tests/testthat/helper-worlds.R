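# Small configurations shared across the suite.

tiny_world_config <- function(...) {
  world_config(dims = c(4L, 4L, 4L), n_tc = 128L, n_epi = 256L, n_mac = 16L,
               ...)
}

# A fast, reduced prime/challenge configuration for protocol-level tests:
# same mechanics as the shipped defaults, but a short quiet phase between
# prime and challenge.
fast_protocol <- function(d = 0L, alpha = 0L, t_II = 220L, horizon = 320L,
                          ...) {
  protocol_config(d = d, alpha = alpha, t_II = t_II, horizon = horizon, ...)
}

# Brute-force popcount over explicit bit extraction, independent of the
# table-driven implementation.
slow_popcount <- function(a, b, nbits) {
  x <- bitwXor(a, b)
  sum(vapply(seq_len(nbits) - 1L,
             function(k) bitwAnd(bitwShiftR(x, k), 1L), integer(1)))
}
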