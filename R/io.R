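#' Read a bilateral pair of voxel time-series matrices
#'
#' Delimited numeric matrices, voxels as rows and frames as columns;
#' both files must agree in shape.
#'
#' @param path_dD,path_dO Paths to the deoxyHb and oxyHb matrices.
#' @param sep Field delimiter (default `","`; whitespace-delimited files
#'   work with `sep = ""`).
#' @param max_nonfinite Maximum tolerated fraction of non-finite entries
#'   (default 0: any non-finite entry is an error).
#' @return List with matrices `dD`, `dO` and `n_voxels`, `n_frames`.
#' @export
read_timeseries <- function(path_dD, path_dO, sep = ",", max_nonfinite = 0) {
  read_one <- function(p) {
    m <- tryCatch(as.matrix(utils::read.table(p, sep = sep, header = FALSE,
                                              colClasses = "numeric")),
                  error = function(e)
                    stop(sprintf("cannot read numeric matrix from %s: %s",
                                 p, conditionMessage(e))))
    dimnames(m) <- NULL
    m
  }
  dD <- read_one(path_dD)
  dO <- read_one(path_dO)
  if (!identical(dim(dD), dim(dO)))
    stop(sprintf("shape mismatch: %s is %dx%d but %s is %dx%d",
                 path_dD, nrow(dD), ncol(dD), path_dO, nrow(dO), ncol(dO)))
  bad <- mean(!is.finite(dD)) + mean(!is.finite(dO))
  if (bad / 2 > max_nonfinite)
    stop("non-finite entries exceed the tolerated fraction")
  list(dD = dD, dO = dO, n_voxels = nrow(dD), n_frames = ncol(dD))
}

#' Remove per-voxel linear trends
#'
#' Subtracts each voxel's least-squares line over the time dimension, so
#' the output has zero mean and zero linear trend per voxel. Long-term
#' drift in resting-state recordings is more likely instrumental than
#' biological, and the state definitions require deviations from the
#' temporal mean. Idempotent.
#'
#' @param m Voxel x time numeric matrix with at least 2 frames.
#' @return Detrended matrix of the same dimension.
#' @export
linear_detrend <- function(m) {
  if (!is.matrix(m) || ncol(m) < 2L) stop("need a matrix with >= 2 frames")
  x <- cbind(1, seq_len(ncol(m)))
  h <- x %*% solve(crossprod(x), t(x))   # projection onto {1, t}
  m - m %*% h
}

#' Write a coefficient map as a labelled 10 x 10 CSV
#'
#' @param map An `hb_map`.
#' @param path Output path.
#' @export
write_map_csv <- function(map, path) {
  df <- as.data.frame(unclass(map))
  names(df) <- paste0("from_", 1:10)
  df <- cbind(to = 1:10, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a coefficient map written by [write_map_csv()]
#'
#' @param path CSV path.
#' @param kind,component,units Map metadata to attach.
#' @return An `hb_map`.
#' @export
read_map_csv <- function(path, kind = "unknown", component = NA_character_,
                         units = "") {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  hb_map(m, kind = kind, component = component, units = units)
}

#' Long-format table of a set of coefficient maps
#'
#' @param maps Named list of `hb_map`s (e.g. from
#'   [transition_coefficients()]; non-map elements are skipped).
#' @return Data frame with columns `from_state`, `to_state`, `kind`,
#'   `component`, `value` (defined off-diagonal cells only).
#' @export
maps_to_long <- function(maps) {
  rows <- lapply(names(maps), function(nm) {
    m <- maps[[nm]]
    if (!inherits(m, "hb_map")) return(NULL)
    v <- unclass(m)
    idx <- which(row(v) != col(v) & !is.na(v), arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(from_state = idx[, 2], to_state = idx[, 1],
               kind = attr(m, "kind"),
               component = attr(m, "component"),
               value = v[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognized keys (all optional, with the package defaults shown):
#' `s0_percent` (85), `t0_molar` (1e-4), `saturation_mode`
#' (`"linearized"`), `sampling_rate_hz` (1.8), `max_lag` (60), `detrend`
#' (`TRUE`), `seed` (1).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; `NULL` returns
#'   the defaults.
#' @return List with elements `geometry` (an [hb_geometry()]),
#'   `sampling_rate`, `max_lag`, `detrend`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  get <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  list(geometry = hb_geometry(s0 = get("s0_percent", 85),
                              t0 = get("t0_molar", 1e-4),
                              saturation_mode = get("saturation_mode",
                                                    "linearized")),
       sampling_rate = get("sampling_rate_hz", 1.8),
       max_lag = as.integer(get("max_lag", 60L)),
       detrend = isTRUE(get("detrend", TRUE)),
       seed = as.integer(get("seed", 1L)))
}
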