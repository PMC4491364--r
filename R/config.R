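#' Read a path + code-assignment configuration file
#'
#' The configuration is a flat `key = value` text file with a schema line.
#' Recognized keys: `center_phi`, `center_psi`, `axis_a`, `axis_b`,
#' `rotation`, `origin_t`, `n_samples`, and `maxima.A` ... `maxima.G`.
#' Lines starting with `#` and blank lines are ignored. Residue-specific
#' maxima use keys of the form `maxima.<res>.<code>` (e.g. `maxima.H.C`).
#'
#' @param path file to read.
#' @return a list with elements `path` ([es_path()]) and `assignment`
#'   ([code_assignment()]).
#' @seealso [write_es_config()], [default_es_config()]
#' @export
read_es_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || !grepl("^schema\\s*=\\s*es-config/1$", lines[[1]])) {
    stop(sprintf("'%s': missing or unsupported schema line (expected 'schema = es-config/1')",
                 path), call. = FALSE)
  }
  kv <- strsplit(lines[-1], "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) {
    stop(sprintf("'%s': malformed line: %s", path, lines[-1][bad][[1]]),
         call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  get_num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[match(key, keys)]) else default
  }
  p <- es_path(
    center_phi = get_num("center_phi", -40),
    center_psi = get_num("center_psi", 0),
    axis_a = get_num("axis_a", 110),
    axis_b = get_num("axis_b", 70),
    rotation = get_num("rotation", 0),
    origin_t = get_num("origin_t", 0),
    n_samples = get_num("n_samples", 3600)
  )
  glob_keys <- paste0("maxima.", ES_CODES)
  if (!all(glob_keys %in% keys)) {
    stop(sprintf("'%s': needs all seven keys maxima.A ... maxima.G", path),
         call. = FALSE)
  }
  maxima <- setNames(as.numeric(vals[match(glob_keys, keys)]), ES_CODES)
  res_keys <- grep("^maxima\\.[A-Z]\\.[A-G]$", keys, value = TRUE)
  by_residue <- NULL
  if (length(res_keys)) {
    res <- unique(sub("^maxima\\.([A-Z])\\.[A-G]$", "\\1", res_keys))
    by_residue <- lapply(setNames(res, res), function(r) {
      ks <- paste0("maxima.", r, ".", ES_CODES)
      if (!all(ks %in% keys)) {
        stop(sprintf("'%s': residue '%s' needs all seven maxima", path, r),
             call. = FALSE)
      }
      setNames(as.numeric(vals[match(ks, keys)]), ES_CODES)
    })
  }
  list(path = p, assignment = code_assignment(maxima, by_residue = by_residue))
}

#' Write a path + code-assignment configuration file
#'
#' @param path an [es_path()].
#' @param assignment a [code_assignment()].
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_es_config <- function(path, assignment, file) {
  stopifnot(inherits(path, "es_path"), inherits(assignment, "es_assignment"))
  fmt <- function(k, v) sprintf("%s = %.10g", k, v)
  lines <- c(
    "schema = es-config/1",
    fmt("center_phi", path$center_phi),
    fmt("center_psi", path$center_psi),
    fmt("axis_a", path$axis_a),
    fmt("axis_b", path$axis_b),
    fmt("rotation", path$rotation),
    fmt("origin_t", path$origin_t),
    fmt("n_samples", path$n_samples),
    vapply(ES_CODES, function(cd) fmt(paste0("maxima.", cd),
                                      assignment$maxima[[cd]]), character(1))
  )
  if (!is.null(assignment$by_residue)) {
    for (r in sort(names(assignment$by_residue))) {
      lines <- c(lines, vapply(ES_CODES, function(cd) {
        fmt(paste0("maxima.", r, ".", cd), assignment$by_residue[[r]][[cd]])
      }, character(1)))
    }
  }
  write_atomically(lines, file)
  invisible(file)
}

#' Default shipped configuration
#'
#' Loads the placeholder ellipse and maxima from the package's
#' `extdata/default_path.cfg`. These values are exercisable defaults, not
#' calibrated constants; production use should estimate maxima from an
#' encoded corpus via [estimate_maxima()] or supply a calibrated config.
#'
#' @return as [read_es_config()].
#' @export
default_es_config <- function() {
  read_es_config(system.file("extdata", "default_path.cfg",
                             package = "esfold", mustWork = TRUE))
}

# Write lines to a temp file in the destination directory, then rename, so a
# failed write never leaves a partial output behind.
write_atomically <- function(lines, file) {
  dir <- dirname(file)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, file)) {
    file.copy(tmp, file, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(file)
}
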