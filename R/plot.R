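# Base-graphics views of runs and grids.

#' Plot a prime/challenge run
#'
#' `what = "counts"` draws naive-derived and memory T-cell counts against
#' the challenge virus (binding classes only) with the injection times
#' marked; `"ta"` the total affinity TA(t) to the challenge; `"virions"`
#' the per-strain viral load on a log scale.
#'
#' @param x A `"man_run"`.
#' @param what One of `"counts"`, `"ta"`, `"virions"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.man_run <- function(x, what = c("counts", "ta", "virions"), ...) {
  what <- match.arg(what)
  t <- seq_len(x$horizon)
  if (what == "counts") {
    q <- match_class_counts(x, split_memory = TRUE)
    bind <- as.character(x$affinity$m_c:x$affinity$N)
    y <- cbind(naive = rowSums(q[, bind, "naive"]),
               memory = rowSums(q[, bind, "memory"]))
    graphics::matplot(t, y, type = "l", lty = 1, col = c("blue", "orange"),
                      xlab = "step (8 h)",
                      ylab = paste("Tc binding", x$challenge), ...)
    graphics::legend("topleft", c("naive-derived", "memory"), lty = 1,
                     col = c("blue", "orange"), bty = "n")
  } else if (what == "ta") {
    ta <- total_affinity(match_class_counts(x), x$affinity)
    graphics::plot(t, ta, type = "l", xlab = "step (8 h)",
                   ylab = paste("TA(t) vs", x$challenge), ...)
  } else {
    graphics::matplot(t, pmax(x$virions, 0.5), type = "l", lty = 1,
                      log = "y", xlab = "step (8 h)",
                      ylab = "virions (free + intracellular)", ...)
    graphics::legend("topright", colnames(x$virions), lty = 1,
                     col = seq_len(ncol(x$virions)), bty = "n")
  }
  graphics::abline(v = c(x$t_I, x$t_II), lty = 3)
  invisible(x)
}

#' Plot normalised efficacy and compression curves of a grid
#'
#' Min-max normalised `E(d)` and `C(d)` for one attrition stratum; the
#' opening between the curves is the MaN domain.
#'
#' @param x A `"man_grid"`.
#' @param alpha Attrition stratum to plot.
#' @param ... Passed to [graphics::matplot()].
#' @return The [eye_analysis()] of the two curves, invisibly.
#' @export
plot.man_grid <- function(x, alpha = 0L, ...) {
  E <- efficacy(x, alpha = alpha)
  C <- compression(x, alpha = alpha)
  En <- minmax_normalize(E$E_mean)
  Cn <- minmax_normalize(C$C)
  graphics::matplot(E$d, cbind(En, Cn), type = "b", pch = c(1, 2), lty = 1,
                    col = c("black", "red"), xlab = "antigenic distance d",
                    ylab = "normalised E(d), C(d)", ...)
  graphics::legend("topright", c("efficacy E'", "compression C'"),
                   pch = c(1, 2), col = c("black", "red"), bty = "n")
  invisible(eye_analysis(En, Cn, E$d))
}
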