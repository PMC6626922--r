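# Bit-string receptor/peptide representation and the match -> affinity map.
#
# Receptors are N-bit integers, viral peptides N/2-bit integers.  A "match"
# between two strings is the number of complementary (differing) bit
# positions, i.e. the Hamming distance popcount(xor(a, b)).  Binding is only
# possible at or above the cut-off m_c; the affinity potential rises from
# A_L at the cut-off to 1 at full complementarity.

# 8-bit popcount lookup table, built once at install time.
.pop8 <- vapply(0:255, function(x) {
  sum(bitwAnd(bitwShiftR(x, 0:7), 1L))
}, integer(1))

#' Affinity model parameters
#'
#' Bundles the parameters of the bit-string affinity model: the receptor
#' length `N`, the peptide length `N/2`, the binding cut-off `m_c` (minimum
#' number of complementary bits for any interaction) and the free slope
#' parameter `A_L`, the affinity attained exactly at the cut-off.
#'
#' With the defaults (`N = 16`, `m_c = 13`) there are exactly four binding
#' match classes, m in 13..16, and a receptor diversity of 2^16 = 65,536.
#'
#' @param N Total receptor bit length; must be even.  Default 16.
#' @param m_c Binding cut-off in bits, in `N/2..N`.  Default 13.
#' @param A_L Affinity at the cut-off, in (0, 1).  Default 0.05.
#'
#' @return An object of class `"affinity_params"`: a list with fields `N`,
#'   `half` (= `N/2`), `m_c` and `A_L`.
#' @examples
#' ap <- affinity_params()
#' affinity_potential(13:16, ap)
#' @export
affinity_params <- function(N = 16L, m_c = 13L, A_L = 0.05) {
  N <- as.integer(N)
  m_c <- as.integer(m_c)
  if (length(N) != 1L || N <= 0L || N %% 2L != 0L) {
    stop("`N` must be a positive even integer", call. = FALSE)
  }
  if (length(m_c) != 1L || m_c < N / 2L || m_c > N) {
    stop("`m_c` must lie in N/2..N", call. = FALSE)
  }
  if (!is.numeric(A_L) || length(A_L) != 1L || A_L <= 0 || A_L >= 1) {
    stop("`A_L` must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(N = N, half = N %/% 2L, m_c = m_c, A_L = A_L),
            class = "affinity_params")
}

#' Match (Hamming) count between two bit-strings
#'
#' Counts the positions at which the two strings carry complementary bits
#' (a 0 facing a 1 or vice versa).  This is the Hamming distance
#' `popcount(xor(a, b))` and is the model's notion of a "match" between a
#' paratope and an epitope.
#'
#' @param a,b Non-negative integers below `2^nbits`.  Vectorised; recycled
#'   against each other.
#' @param nbits String length in bits (at most 32).
#'
#' @return Integer vector of match counts in `0..nbits`.
#' @examples
#' popcount_match(0x0000, 0xFFFF, 16) # full complement: 16
#' popcount_match(0L, 7L, 8)          # 3
#' @export
popcount_match <- function(a, b, nbits) {
  nbits <- as.integer(nbits)
  if (length(nbits) != 1L || nbits < 1L || nbits > 32L) {
    stop("`nbits` must be a single integer in 1..32", call. = FALSE)
  }
  a <- as.integer(a)
  b <- as.integer(b)
  lim <- if (nbits >= 31L) .Machine$integer.max else bitwShiftL(1L, nbits) - 1L
  if (anyNA(a) || anyNA(b) || any(a < 0L) || any(b < 0L) ||
      any(a > lim) || any(b > lim)) {
    stop("values out of range for ", nbits, "-bit strings", call. = FALSE)
  }
  x <- bitwXor(a, b)
  n <- .pop8[bitwAnd(x, 255L) + 1L]
  if (nbits > 8L)  n <- n + .pop8[bitwAnd(bitwShiftR(x, 8L),  255L) + 1L]
  if (nbits > 16L) n <- n + .pop8[bitwAnd(bitwShiftR(x, 16L), 255L) + 1L]
  if (nbits > 24L) n <- n + .pop8[bitwAnd(bitwShiftR(x, 24L), 255L) + 1L]
  n
}

#' Antigenic distance between two viral peptides
#'
#' The "bit distance" d between two peptides: the Hamming distance over the
#' `N/2` peptide bits.  On the shipped virus panel (see [virus_panel()]) the
#' distance between `V_i` and `V_j` equals `|i - j|`.
#'
#' @param p1,p2 Peptides as integers in `0..2^(N/2) - 1`, or
#'   [virus_strain()] objects.
#' @param params An [affinity_params()] object.
#'
#' @return Integer distance in `0..N/2`.
#' @export
virus_distance <- function(p1, p2, params = affinity_params()) {
  if (inherits(p1, "virus_strain")) p1 <- p1$peptide
  if (inherits(p2, "virus_strain")) p2 <- p2$peptide
  popcount_match(p1, p2, params$half)
}

#' Total TCR-pMHC match of a receptor against a presented peptide
#'
#' The T-cell receptor binds the peptide-MHC complex over all `N` bits, but
#' the half of the receptor facing the MHC molecule is held at a constant
#' full match so that only the `N/2` peptide-facing bits discriminate
#' between viruses.  The result is therefore
#' `N/2 + popcount_match(low half of r, p)` and lies in `N/2..N`.
#'
#' @param r Receptor integer(s) in `0..2^N - 1`.
#' @param p Peptide integer in `0..2^(N/2) - 1` (or a [virus_strain()]).
#' @param params An [affinity_params()] object.
#'
#' @return Integer match value(s) in `N/2..N`.
#' @examples
#' ap <- affinity_params()
#' tcr_pmhc_match(bitwXor(0L, 255L), 0L, ap) # perfect peptide complement: 16
#' @export
tcr_pmhc_match <- function(r, p, params = affinity_params()) {
  if (inherits(p, "virus_strain")) p <- p$peptide
  r <- as.integer(r)
  lim <- bitwShiftL(1L, params$N) - 1L
  if (anyNA(r) || any(r < 0L) || any(r > lim)) {
    stop("receptor out of range for ", params$N, "-bit strings", call. = FALSE)
  }
  mask <- bitwShiftL(1L, params$half) - 1L
  params$half + popcount_match(bitwAnd(r, mask), p, params$half)
}

#' Affinity potential f(m)
#'
#' Maps a match value m to a binding affinity in `[0, 1]`:
#' `f(m) = exp(log(A_L) * (m - N) / (m_c - N))` for `m_c <= m <= N`
#' (equivalently `A_L^((N - m) / (N - m_c))`), and 0 below the cut-off.
#' `f(N) = 1` for any `A_L`, and `f(m_c) = A_L`.
#'
#' @param m Integer match value(s) in `0..N`.
#' @param params An [affinity_params()] object.
#'
#' @return Numeric affinity value(s) in `[0, 1]`.
#' @examples
#' affinity_potential(c(12, 13, 14, 15, 16), affinity_params())
#' @export
affinity_potential <- function(m, params = affinity_params()) {
  if (anyNA(m) || any(m < 0) || any(m > params$N)) {
    stop("`m` must lie in 0..N", call. = FALSE)
  }
  f <- exp(log(params$A_L) * (m - params$N) / (params$m_c - params$N))
  f[m < params$m_c] <- 0
  f
}

#' Draw a uniform naive receptor repertoire
#'
#' Receptors of immunocompetent lymphocytes entering the simulated volume
#' are i.i.d. uniform over the full diversity `0..2^N - 1` (the thymus is
#' implicit: only immunocompetent cells are modelled).
#'
#' @param n_cells Number of receptors to draw.
#' @param params An [affinity_params()] object.
#'
#' @return Integer vector of length `n_cells`.
#' @export
sample_repertoire <- function(n_cells, params = affinity_params()) {
  n_cells <- as.integer(n_cells)
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells < 0L) {
    stop("`n_cells` must be a single non-negative integer", call. = FALSE)
  }
  if (n_cells == 0L) return(integer(0))
  sample.int(bitwShiftL(1L, params$N), n_cells, replace = TRUE) - 1L
}
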