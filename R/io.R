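# Configuration loading, tidy result serialisation and grid manifests.
# Series go to CSV, manifests to JSON; outputs are diffable text and
# byte-reproducible for a given (config, seed).

#' Load a protocol configuration from a YAML file
#'
#' The file may contain any subset of the sections `affinity`, `world`,
#' `dynamics`, `attrition`, `virus` (shared fitness triple of the panel)
#' and `protocol`; omitted keys take the shipped defaults, which are the
#' protocol constants (N = 16, m_c = 13, k1 = 1e6, k2 = 1e9, n1 = 3,
#' n2 = 2, dose 1e3 per microliter, volume 10 microliters).  Unknown
#' sections or keys are rejected with a message listing the offenders;
#' constraint violations (e.g. `n1 <= n2`) are rejected by the parameter
#' constructors.
#'
#' @param path Path to a YAML file; an empty file yields pure defaults.
#'
#' @return A [protocol_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("affinity", "world", "dynamics", "attrition", "virus",
             "protocol")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  take <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad)) {
      stop("unknown key(s) in `", section, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    args
  }
  aff <- do.call(affinity_params, take("affinity", affinity_params))
  wld <- do.call(world_config, take("world", world_config))
  dyn <- do.call(dynamics_params, take("dynamics", dynamics_params))
  att <- do.call(attrition_params, take("attrition", attrition_params))
  vir <- take("virus", virus_panel)
  vir$params <- aff
  panel <- do.call(virus_panel, vir)
  prot <- take("protocol", protocol_config)
  prot$sim <- sim_config(world = wld, affinity = aff, dynamics = dyn,
                         attrition = att)
  prot$panel <- panel
  do.call(protocol_config, prot)
}

#' Write a run's per-step records as tidy CSV
#'
#' One row per non-zero `(step, strain, match_class, memory, count)` cell
#' plus one virion row per `(step, strain)` with virions present; rows are
#' deterministically ordered, so writing, reading and re-writing
#' reproduces the file byte for byte.  An empty run yields a header-only
#' file.
#'
#' @param run A `"man_run"` (or the list returned by
#'   [read_timeseries()]).
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(run, path) {
  ids <- dimnames(run$q)[[4]]
  rows <- list()
  for (s in seq_along(ids)) {
    for (mem in 1:2) {
      qm <- run$q[, , mem, s]
      nz <- which(!is.na(qm) & qm > 0, arr.ind = TRUE)
      if (nrow(nz)) {
        rows[[length(rows) + 1L]] <- data.frame(
          step = nz[, 1], strain = ids[s], series = "tc",
          match_class = as.integer(colnames(qm)[nz[, 2]]),
          memory = c("naive", "memory")[mem], count = qm[nz])
      }
    }
    v <- run$virions[, s]
    nz <- which(!is.na(v) & v > 0)
    if (length(nz)) {
      rows[[length(rows) + 1L]] <- data.frame(
        step = nz, strain = ids[s], series = "virion",
        match_class = NA_integer_, memory = NA_character_, count = v[nz])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0), strain = character(0),
               series = character(0), match_class = integer(0),
               memory = character(0), count = numeric(0))
  df <- df[order(df$step, df$strain, df$series, df$match_class, df$memory), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a tidy per-step CSV back into count arrays
#'
#' Inverse of [write_timeseries()] up to the recorded horizon: absent
#' cells are zero.
#'
#' @param path CSV path written by [write_timeseries()].
#'
#' @return A list of class `"man_series"` with elements `q`
#'   (`steps x 9 x 2 x strains`) and `virions` (`steps x strains`).
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- sort(unique(df$strain))
  horizon <- if (nrow(df)) max(df$step) else 0L
  q <- array(0, dim = c(horizon, 9L, 2L, length(ids)),
             dimnames = list(NULL, as.character(8:16),
                             c("naive", "memory"), ids))
  vir <- matrix(0, horizon, length(ids), dimnames = list(NULL, ids))
  tcr <- df[df$series == "tc", ]
  if (nrow(tcr)) {
    q[cbind(tcr$step, match(as.character(tcr$match_class),
                            as.character(8:16)),
            match(tcr$memory, c("naive", "memory")),
            match(tcr$strain, ids))] <- tcr$count
  }
  vr <- df[df$series == "virion", ]
  if (nrow(vr)) vir[cbind(vr$step, match(vr$strain, ids))] <- vr$count
  structure(list(q = q, virions = vir), class = "man_series")
}

#' Write a grid manifest as JSON
#'
#' Records the grid configuration snapshot, the seed map, the software
#' version, per-run status and any per-run file paths, so a result store
#' is self-describing.
#'
#' @param grid A `"man_grid"`.
#' @param path Output JSON path.
#' @param files Optional character vector of per-run file paths, parallel
#'   to the grid rows.
#'
#' @return `path`, invisibly.
#' @export
write_manifest <- function(grid, path, files = NULL) {
  runs <- data.frame(d = grid$d, alpha = grid$alpha,
                     replicate = grid$replicate, seed = grid$seed,
                     alive = grid$alive, cleared = grid$cleared)
  if (!is.null(files)) {
    stopifnot(length(files) == nrow(runs))
    runs$file <- files
  }
  man <- list(package = "manaim",
              version = as.character(utils::packageVersion("manaim")),
              d_values = attr(grid, "d_values"),
              alpha_values = attr(grid, "alpha_values"),
              replicates = attr(grid, "replicates"),
              base_seed = attr(grid, "base_seed"),
              n_config = attr(grid, "n_config"),
              runs = runs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
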