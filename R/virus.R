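# Virus strains and the antigenic-distance panel.

#' Define a virus strain
#'
#' A strain is a T-cell peptide plus a fitness triple: intracellular
#' replication factor per 8 h step, per virion-cell infection probability,
#' and the lethal free+intracellular load (virions per microliter) above
#' which the simulated host dies.  Fitness is independent of antigenicity.
#'
#' @param id Strain label, e.g. `"V0"`.
#' @param peptide Peptide as an integer in `0..2^(N/2) - 1`.
#' @param replication_rate Intracellular multiplication factor per step
#'   (>= 0).
#' @param infectivity Probability per virion-cell contact per step, in
#'   `[0, 1]`.
#' @param lethal_load Virions per microliter above which the host dies.
#' @param params An [affinity_params()] object (peptide range check).
#'
#' @return An object of class `"virus_strain"`.
#' @export
virus_strain <- function(id, peptide, replication_rate = 3,
                         infectivity = 0.01, lethal_load = 2e4,
                         params = affinity_params()) {
  peptide <- as.integer(peptide)
  lim <- bitwShiftL(1L, params$half) - 1L
  if (length(peptide) != 1L || is.na(peptide) || peptide < 0L ||
      peptide > lim) {
    stop("`peptide` must be a single integer in 0..", lim, call. = FALSE)
  }
  if (infectivity < 0 || infectivity > 1) {
    stop("`infectivity` must lie in [0, 1]", call. = FALSE)
  }
  if (replication_rate < 0 || lethal_load < 0) {
    stop("rates and loads must be non-negative", call. = FALSE)
  }
  structure(list(id = as.character(id), peptide = peptide,
                 replication_rate = replication_rate,
                 infectivity = infectivity, lethal_load = lethal_load),
            class = "virus_strain")
}

#' The nine-virus antigenic-distance panel
#'
#' Strains `V0..V8` whose 8-bit peptides form a prefix-of-ones ladder
#' (`00000000`, `00000001`, `00000011`, ..., `11111111`), so that the bit
#' distance between `V_i` and `V_j` is exactly `|i - j|`.  All nine strains
#' share the same fitness triple so that antigenicity is the only
#' experimental variable.
#'
#' @param replication_rate,infectivity,lethal_load Shared fitness triple,
#'   passed to [virus_strain()].
#' @param params An [affinity_params()] object.
#'
#' @return List of nine `"virus_strain"` objects named `V0..V8`.
#' @examples
#' panel <- virus_panel()
#' virus_distance(panel$V0, panel$V8) # 8
#' @export
virus_panel <- function(replication_rate = 3, infectivity = 0.01,
                        lethal_load = 2e4, params = affinity_params()) {
  k <- 0:params$half
  peptides <- bitwShiftL(1L, k) - 1L  # 0, 1, 3, 7, ..., 2^half - 1
  out <- lapply(seq_along(k), function(i) {
    virus_strain(paste0("V", k[i]), peptides[i],
                 replication_rate = replication_rate,
                 infectivity = infectivity, lethal_load = lethal_load,
                 params = params)
  })
  names(out) <- paste0("V", k)
  out
}

#' @export
print.virus_strain <- function(x, ...) {
  cat(sprintf("<virus_strain %s> peptide %s  repl %.3g  infect %.3g  lethal %.3g/ul\n",
              x$id, paste(rev(bitwAnd(bitwShiftR(x$peptide, 0:7), 1L)),
                          collapse = ""),
              x$replication_rate, x$infectivity, x$lethal_load))
  invisible(x)
}
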