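# Derived response quantities: per-match-class counts q_m(t), per-class
# and total affinity A_m(t), TA(t), time-to-clear t_c, efficacy E(d),
# compression C(d), min-max normalisation, clone classification and the
# efficacy/compression "eye" analysis.

# Recorded rows covering t >= t_II: the first observation that can reflect
# the challenge is the row after the injection step.
challenge_window <- function(run) {
  (run$t_II + 1L):run$horizon
}

#' Per-match-class T-cell counts against a virus
#'
#' Partitions the recorded T-cell population by its TCR-pMHC match m
#' against the given virus's peptide: `q_m(t)` is the number of cells in
#' match class m at step t.  Classes span `N/2..N` (the MHC-facing half is
#' a constant full match); their sum at any step equals the total T-cell
#' count.
#'
#' @param run A `"man_run"`.
#' @param virus A registered [virus_strain()] or its id (default: the
#'   challenge strain).  An unregistered virus is an error.
#' @param split_memory If `TRUE`, return a 3-d array
#'   `[step, class, naive/memory]` instead of summing over memory status.
#'
#' @return A `steps x 9` matrix (columns named by m = 8..16), or a 3-d
#'   array when `split_memory`.
#' @export
match_class_counts <- function(run, virus = run$challenge,
                               split_memory = FALSE) {
  id <- if (inherits(virus, "virus_strain")) virus$id else as.character(virus)
  if (!id %in% dimnames(run$q)[[4]]) {
    stop("virus `", id, "` was not tracked in this run", call. = FALSE)
  }
  if (split_memory) run$q[, , , id] else run$q[, , 1L, id] + run$q[, , 2L, id]
}

#' Total affinity TA(t) of a class-count series
#'
#' `TA(t) = sum_m f(m) q_m(t)`: the affinity-weighted T-cell count against
#' a stated virus.  Classes below the cut-off contribute zero; TA is
#' linear in the counts.
#'
#' @param q A `steps x 9` class-count matrix (columns m = 8..16, as from
#'   [match_class_counts()]) or a length-9 count vector.
#' @param params An [affinity_params()] object.
#'
#' @return Numeric TA series (or scalar for a vector input).
#' @examples
#' total_affinity(c(0, 0, 0, 0, 0, 10, 5, 2, 1), affinity_params())
#' @export
total_affinity <- function(q, params = affinity_params()) {
  f <- affinity_potential(8:16, params)
  if (is.matrix(q)) {
    if (ncol(q) != 9L) stop("`q` must have 9 class columns (m = 8..16)",
                            call. = FALSE)
    unname(drop(q %*% f))
  } else {
    if (length(q) != 9L) stop("`q` must have 9 class entries (m = 8..16)",
                              call. = FALSE)
    sum(q * f)
  }
}

#' Time-to-clear the challenge virus
#'
#' `t_c = min{t >= t_II : V(t) = 0} - t_II`, the number of steps from the
#' challenge until the challenge virus count first reaches zero; `NA`
#' (censored) if it never does before the horizon.  For a `"man_run"` the
#' search starts at the first post-injection observation, so a real run's
#' `t_c` is at least 1; for a plain numeric series the literal definition
#' applies.
#'
#' @param x A `"man_run"`, or a numeric virion series.
#' @param ... Passed on to methods.
#' @return Integer `t_c`, or `NA_integer_` if censored.
#' @export
time_to_clear <- function(x, ...) UseMethod("time_to_clear")

#' @rdname time_to_clear
#' @param virus Strain (object or id) whose series to use; default the
#'   challenge strain.
#' @export
time_to_clear.man_run <- function(x, virus = x$challenge, ...) {
  id <- if (inherits(virus, "virus_strain")) virus$id else as.character(virus)
  if (!id %in% colnames(x$virions)) {
    stop("virus `", id, "` was not tracked in this run", call. = FALSE)
  }
  v <- x$virions[challenge_window(x), id]
  hit <- which(!is.na(v) & v == 0)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1])
}

#' @rdname time_to_clear
#' @param t_II Index of the challenge time within the series.
#' @export
time_to_clear.default <- function(x, t_II, ...) {
  if (t_II < 1L || t_II > length(x)) {
    stop("`t_II` lies outside the series", call. = FALSE)
  }
  hit <- which(x[t_II:length(x)] == 0)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1] - 1L)
}

#' Efficacy E(d) of the response to the challenge
#'
#' Per run, `E = max_{t >= t_II} TA(t) / t_c`: the post-challenge peak of
#' the total affinity to the challenge virus divided by the time-to-clear.
#' Censored (uncleared) runs score `E = 0`.  For a grid, the per-replicate
#' values are averaged within each antigenic distance of one attrition
#' stratum; the maximum is attained at `d = 0`, where memory both peaks
#' high and clears fast.
#'
#' @param x A `"man_run"` or a `"man_grid"`.
#' @param ... Passed on to methods.
#' @return A scalar for a run; a data frame `(d, E_mean, E_sd, n)` for a
#'   grid.
#' @export
efficacy <- function(x, ...) UseMethod("efficacy")

#' @rdname efficacy
#' @export
efficacy.man_run <- function(x, ...) {
  if (is.na(x$t_c)) return(0)
  qa <- match_class_counts(x)
  ta <- total_affinity(qa, x$affinity)[challenge_window(x)]
  max(ta, na.rm = TRUE) / x$t_c
}

#' @rdname efficacy
#' @param alpha Attrition stratum to analyse (grid method).
#' @export
efficacy.man_grid <- function(x, alpha = 0L, ...) {
  g <- x[x$alpha == alpha, , drop = FALSE]
  if (!nrow(g)) stop("no runs at alpha = ", alpha, call. = FALSE)
  ds <- sort(unique(g$d))
  data.frame(d = ds,
             E_mean = vapply(ds, function(d) mean(g$E[g$d == d]), 0),
             E_sd = vapply(ds, function(d) stats::sd(g$E[g$d == d]), 0),
             n = vapply(ds, function(d) sum(g$d == d), 0L))
}

#' Compression C(d) of the naive response by cross-reactive memory
#'
#' `M~` is a run's maximum total T-cell count after the challenge;
#' `<M~>` its replicate average within one `(d, alpha)` cell.  Compression
#' is the shortfall relative to the fully heterologous response at the
#' same attrition level: `C(d) = <M~>_{d=8} - <M~>_d`, so `C(8) = 0` by
#' construction.  It measures how strongly pre-existing memory blocks the
#' expansion of the naive response.
#'
#' @param grid A `"man_grid"`.
#' @param alpha Attrition stratum; the `d = 8` reference must be present
#'   in it.
#'
#' @return A data frame `(d, M_mean, C)`.
#' @export
compression <- function(grid, alpha = 0L) {
  g <- grid[grid$alpha == alpha, , drop = FALSE]
  if (!nrow(g)) stop("no runs at alpha = ", alpha, call. = FALSE)
  if (!any(g$d == 8L)) {
    stop("compression needs the d = 8 reference cell at alpha = ", alpha,
         call. = FALSE)
  }
  ds <- sort(unique(g$d))
  M <- vapply(ds, function(d) mean(g$M_tilde[g$d == d]), 0)
  data.frame(d = ds, M_mean = M, C = M[ds == 8L] - M)
}

#' Min-max normalisation of a series
#'
#' `y' = (y - min y) / (max y - min y)`: maps the minimum to 0 and the
#' maximum to 1, preserving order.  A constant series has no min-max
#' normalisation and is an error.
#'
#' @param x Numeric vector, not constant.
#' @return Normalised vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2]) {
    stop("min-max normalisation is undefined for a constant series",
         call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Classify a clone by its reactivity to prime and challenge
#'
#' Thresholds the TCR-pMHC match against each virus at the binding cut-off:
#' a clone binding only the primer is `primary_only`, binding both is
#' `cross_reactive` (the clones that operate the MaN), binding only the
#' challenger is `challenge_only` (the naive response), and binding
#' neither is `nonresponder`.
#'
#' @param receptor Receptor integer(s).
#' @param vI,vII Prime and challenge viruses ([virus_strain()] or peptide
#'   integers).
#' @param params An [affinity_params()] object.
#'
#' @return Factor with levels `primary_only`, `cross_reactive`,
#'   `challenge_only`, `nonresponder`.
#' @export
classify_clone <- function(receptor, vI, vII, params = affinity_params()) {
  b1 <- tcr_pmhc_match(receptor, vI, params) >= params$m_c
  b2 <- tcr_pmhc_match(receptor, vII, params) >= params$m_c
  out <- ifelse(b1 & b2, "cross_reactive",
                ifelse(b1, "primary_only",
                       ifelse(b2, "challenge_only", "nonresponder")))
  factor(out, levels = c("primary_only", "cross_reactive",
                         "challenge_only", "nonresponder"))
}

#' Critical distances and the MaN "eye"
#'
#' Given the (normalised) efficacy and compression curves over
#' `d = 0..8`, locates the critical distance of each curve -- the d with
#' the largest one-step decrease `y(d-1) - y(d)` -- and the interval where
#' the compression curve exceeds the efficacy curve by more than
#' `gap_threshold`.  That opening between the two curves is the domain of
#' the memory-anti-naive effect: distances where memory still blocks the
#' naive expansion (high C) but no longer clears well (low E).
#'
#' @param E_norm,C_norm Numeric curves of equal length over `d`.
#' @param d Distance axis (default `0:8`).
#' @param gap_threshold Minimum `C' - E'` gap that counts as open.
#'
#' @return A list of class `"man_eye"`: `critical_E`, `critical_C`,
#'   `eye` (range of d where the gap is open, or `NULL`), and the `gap`
#'   curve.
#' @export
eye_analysis <- function(E_norm, C_norm, d = seq_along(E_norm) - 1L,
                         gap_threshold = 0.2) {
  if (length(E_norm) != length(C_norm) || length(E_norm) != length(d)) {
    stop("curves (and `d`) must have equal length", call. = FALSE)
  }
  n <- length(d)
  dropE <- E_norm[-n] - E_norm[-1]
  dropC <- C_norm[-n] - C_norm[-1]
  gap <- C_norm - E_norm
  open <- which(gap > gap_threshold)
  structure(list(critical_E = d[which.max(dropE) + 1L],
                 critical_C = d[which.max(dropC) + 1L],
                 eye = if (length(open)) range(d[open]) else NULL,
                 gap = stats::setNames(gap, d)),
            class = "man_eye")
}

#' @export
print.man_eye <- function(x, ...) {
  cat(sprintf("Critical distances: efficacy d = %d, compression d = %d\n",
              x$critical_E, x$critical_C))
  if (is.null(x$eye)) {
    cat("Eye: closed (gap never exceeds the threshold)\n")
  } else {
    cat(sprintf("Eye open over d in [%d, %d]\n", x$eye[1], x$eye[2]))
  }
  invisible(x)
}
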