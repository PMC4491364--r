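#' Define the elliptical conformational path on the Ramachandran plot
#'
#' The early-stage (ES) model restricts backbone conformation to a closed
#' elliptical path in (phi, psi) space. The path is parametrized by
#' `t` in \[0, 1): `path_point(path, t)` is the center plus the rotated
#' point `(a cos 2*pi*t, b sin 2*pi*t)`, with each coordinate normalized to
#' (-180, 180] so the curve lives on the torus.
#'
#' The published work this model family stems from does not tabulate the
#' ellipse coefficients; they are treated here as configuration. The default
#' values shipped in `inst/extdata/default_path.cfg` are placeholders to be
#' calibrated against an encoded reference corpus.
#'
#' @param center_phi,center_psi center of the ellipse, degrees.
#' @param axis_a,axis_b semi-axes (major, minor), degrees, strictly positive.
#' @param rotation angle of the major axis versus the phi-axis, degrees.
#' @param origin_t path parameter of the labelling origin (the pole from
#'   which codes A-G are counted), in \[0, 1).
#' @param n_samples number of dense samples used by the projection solver.
#' @return an object of class `es_path`.
#' @seealso [path_point()], [project_to_path()]
#' @examples
#' p <- es_path(center_phi = -40, center_psi = 0, axis_a = 110, axis_b = 70)
#' path_point(p, c(0, 0.25, 0.5))
#' @export
es_path <- function(center_phi = -40, center_psi = 0,
                    axis_a = 110, axis_b = 70,
                    rotation = 0, origin_t = 0, n_samples = 3600) {
  stopifnot(
    is.numeric(center_phi), is.numeric(center_psi),
    axis_a > 0, axis_b > 0,
    is.finite(rotation), n_samples >= 16
  )
  structure(
    list(
      center_phi = normalize_angle(center_phi),
      center_psi = normalize_angle(center_psi),
      axis_a = axis_a, axis_b = axis_b,
      rotation = rotation,
      origin_t = origin_t %% 1,
      n_samples = as.integer(n_samples)
    ),
    class = "es_path"
  )
}

#' @export
print.es_path <- function(x, ...) {
  cat(sprintf(
    "<es_path> center (%g, %g), semi-axes (%g, %g), rotation %g deg, origin t = %g\n",
    x$center_phi, x$center_psi, x$axis_a, x$axis_b, x$rotation, x$origin_t
  ))
  invisible(x)
}

#' Evaluate the elliptical path at parameter t
#'
#' @param path an [es_path()].
#' @param t numeric vector of path parameters; wrapped into \[0, 1).
#'   The parametrization is periodic: `t` and `t + 1` give the same point.
#' @return a tibble with columns `t`, `phi`, `psi` (degrees, normalized to
#'   (-180, 180]).
#' @export
path_point <- function(path, t) {
  stopifnot(inherits(path, "es_path"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be a finite numeric vector", call. = FALSE)
  }
  t <- t %% 1
  theta <- 2 * pi * t
  u <- path$axis_a * cos(theta)
  v <- path$axis_b * sin(theta)
  rot <- path$rotation * pi / 180
  tibble::tibble(
    t = t,
    phi = normalize_angle(path$center_phi + u * cos(rot) - v * sin(rot)),
    psi = normalize_angle(path$center_psi + u * sin(rot) + v * cos(rot))
  )
}

#' Project (phi, psi) points onto the path by minimum torus distance
#'
#' Each dihedral pair is mapped to the nearest point of the elliptical path
#' under the Euclidean metric on the torus (angular differences wrapped to
#' \[-180, 180\], both axes weighted equally). The minimizing parameter is
#' found by dense sampling over `path$n_samples` candidates followed by local
#' golden-section refinement, which is robust to the multi-modal distance
#' function of a rotated ellipse on a torus.
#'
#' Rows with a missing phi or psi yield a missing projection (`NA` row), so
#' chain termini propagate cleanly.
#'
#' @param dihedrals a data frame with numeric columns `phi` and `psi`
#'   (degrees), one row per residue.
#' @param path an [es_path()].
#' @return a tibble with columns `t` (parameter of the nearest path point),
#'   `phi_e`, `psi_e` (the projected point) and `distance` (degrees).
#' @examples
#' p <- es_path()
#' project_to_path(tibble::tibble(phi = c(-60, 120), psi = c(-45, 130)), p)
#' @export
project_to_path <- function(dihedrals, path) {
  stopifnot(inherits(path, "es_path"))
  dihedrals <- as_dihedral_frame(dihedrals)
  n <- nrow(dihedrals)
  out_t <- rep(NA_real_, n)
  out_d <- rep(NA_real_, n)
  if (n > 0) {
    grid_t <- seq(0, 1, length.out = path$n_samples + 1L)[-(path$n_samples + 1L)]
    grid <- path_point(path, grid_t)
    rot <- path$rotation * pi / 180
    eval_raw <- function(t) {
      theta <- 2 * pi * t
      u <- path$axis_a * cos(theta)
      v <- path$axis_b * sin(theta)
      c(normalize_angle(path$center_phi + u * cos(rot) - v * sin(rot)),
        normalize_angle(path$center_psi + u * sin(rot) + v * cos(rot)))
    }
    ok <- which(!is.na(dihedrals$phi) & !is.na(dihedrals$psi))
    for (i in ok) {
      phi <- dihedrals$phi[i]
      psi <- dihedrals$psi[i]
      d <- torus_distance(grid$phi, grid$psi, phi, psi)
      j <- which.min(d)
      half <- 1 / path$n_samples
      f <- function(t) {
        q <- eval_raw(t)
        torus_distance(q[1], q[2], phi, psi)
      }
      opt <- golden_section(f, grid_t[j] - half, grid_t[j] + half)
      if (opt$objective <= d[j]) {
        out_t[i] <- opt$minimum %% 1
        out_d[i] <- opt$objective
      } else {
        out_t[i] <- grid_t[j]
        out_d[i] <- d[j]
      }
    }
  }
  pt <- path_point(path, ifelse(is.na(out_t), 0, out_t))
  tibble::tibble(
    t = out_t,
    phi_e = ifelse(is.na(out_t), NA_real_, pt$phi),
    psi_e = ifelse(is.na(out_t), NA_real_, pt$psi),
    distance = out_d
  )
}

# Fixed-iteration golden-section minimizer. Unlike stats::optimize it has no
# sqrt(machine-eps) floor on the x tolerance, so an on-path point refines to
# essentially zero distance.
golden_section <- function(f, a, b, iters = 60) {
  gr <- (sqrt(5) - 1) / 2
  c <- b - gr * (b - a)
  d <- a + gr * (b - a)
  fc <- f(c)
  fd <- f(d)
  for (i in seq_len(iters)) {
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  x <- (a + b) / 2
  list(minimum = x, objective = f(x))
}

# Accept a data frame with phi/psi columns, or a two-column numeric matrix.
as_dihedral_frame <- function(x) {
  if (is.matrix(x)) x <- tibble::as_tibble(x, .name_repair = "minimal")
  if (!is.data.frame(x) || !all(c("phi", "psi") %in% names(x))) {
    stop("`dihedrals` must be a data frame with columns `phi` and `psi`",
         call. = FALSE)
  }
  tibble::tibble(phi = normalize_angle(as.numeric(x$phi)),
                 psi = normalize_angle(as.numeric(x$psi)))
}

#' Assignment of the seven structural codes to path positions
#'
#' The distribution of projected dihedrals along the path shows seven maxima;
#' each maximum defines one letter of the structural alphabet A-G. An
#' assignment maps each letter to its path parameter. The scope is "global"
#' (one set of maxima for all residues) or residue-specific: `by_residue`
#' supplies per-amino-acid maxima, with the global set as optional fallback.
#'
#' @param maxima named numeric vector: names are the seven letters A-G,
#'   values are distinct path parameters in \[0, 1).
#' @param by_residue optional named list of such vectors, keyed by one-letter
#'   amino-acid code.
#' @param fallback_global if `TRUE` (default), [assign_code()] for a residue
#'   absent from `by_residue` falls back to the global maxima.
#' @return an object of class `es_assignment`.
#' @export
code_assignment <- function(maxima, by_residue = NULL, fallback_global = TRUE) {
  validate_maxima(maxima)
  if (!is.null(by_residue)) {
    stopifnot(is.list(by_residue), !is.null(names(by_residue)))
    lapply(by_residue, validate_maxima)
    by_residue <- lapply(by_residue, function(m) m[ES_CODES] %% 1)
  }
  structure(
    list(maxima = maxima[ES_CODES] %% 1,
         by_residue = by_residue,
         fallback_global = isTRUE(fallback_global)),
    class = "es_assignment"
  )
}

validate_maxima <- function(maxima) {
  if (!is.numeric(maxima) || length(maxima) != 7 ||
      !setequal(names(maxima), ES_CODES)) {
    stop("`maxima` must be a numeric vector named with the 7 codes A-G",
         call. = FALSE)
  }
  tt <- maxima %% 1
  if (anyDuplicated(tt)) {
    stop("code maxima must be distinct path parameters", call. = FALSE)
  }
  invisible(maxima)
}

#' @export
print.es_assignment <- function(x, ...) {
  cat("<es_assignment> global maxima (t):\n")
  print(round(x$maxima, 4))
  if (!is.null(x$by_residue)) {
    cat(sprintf("residue-specific maxima for %d residues (fallback_global = %s)\n",
                length(x$by_residue), x$fallback_global))
  }
  invisible(x)
}

# Distance between path parameters on the unit circle.
cyclic_t_distance <- function(t1, t2) {
  d <- abs(t1 - t2) %% 1
  pmin(d, 1 - d)
}

#' Assign a structural code to a path parameter
#'
#' Returns, for each `t`, the code whose maximum is nearest under the cyclic
#' metric `min(|t - t_c|, 1 - |t - t_c|)`. Ties are broken in favour of the
#' alphabetically earlier code (ties have measure zero; the rule exists for
#' determinism).
#'
#' @param t numeric vector of path parameters; `NA` yields `"X"`.
#' @param assignment an [code_assignment()].
#' @param residue optional single amino-acid letter selecting a
#'   residue-specific map when the assignment carries one.
#' @return character vector of code letters (`"A"`-`"G"`, or `"X"` for `NA`).
#' @export
assign_code <- function(t, assignment, residue = NULL) {
  stopifnot(inherits(assignment, "es_assignment"))
  maxima <- assignment$maxima
  if (!is.null(assignment$by_residue)) {
    if (is.null(residue)) {
      if (!assignment$fallback_global) {
        stop("residue-specific assignment requires `residue`", call. = FALSE)
      }
    } else if (!is.null(assignment$by_residue[[residue]])) {
      maxima <- assignment$by_residue[[residue]]
    } else if (!assignment$fallback_global) {
      stop(sprintf("no maxima for residue '%s' and global fallback disabled",
                   residue), call. = FALSE)
    }
  }
  vapply(t, function(ti) {
    if (is.na(ti)) return("X")
    d <- cyclic_t_distance(ti %% 1, maxima)
    # which.min returns the first of the tied minima; maxima are ordered A-G
    ES_CODES[which.min(d)]
  }, character(1))
}

#' Estimate the seven code maxima from projected path parameters
#'
#' Fits a circular kernel density estimate to the path parameters of a
#' projected corpus and returns the seven highest local maxima as a
#' [code_assignment()]. Letters A-G are assigned in increasing `t` measured
#' from `origin_t` (the labelling pole of the path).
#'
#' The density is computed on \[0, 1) by replicating the sample one period to
#' each side, so the estimate is exactly periodic. A degenerate sample (for
#' example near-uniform `t` values) that does not produce seven clearly
#' separated peaks raises an error rather than returning unstable positions;
#' `min_contrast` is the required ratio of the weakest accepted peak to the
#' deepest trough of the density.
#'
#' @param t_values numeric vector of path parameters in \[0, 1); at least 70.
#' @param n_peaks number of maxima to recover (7 for the ES alphabet).
#' @param bandwidth kernel bandwidth on the t scale, > 0.
#' @param origin_t labelling origin, in \[0, 1).
#' @param min_contrast minimum peak-height / trough-height ratio.
#' @param grid_n density grid resolution.
#' @return a [code_assignment()] with scope "global".
#' @export
estimate_maxima <- function(t_values, n_peaks = 7, bandwidth = 0.02,
                            origin_t = 0, min_contrast = 1.5,
                            grid_n = 2048) {
  t_values <- t_values[!is.na(t_values)] %% 1
  if (length(t_values) < 10 * n_peaks) {
    stop(sprintf("need at least %d samples to estimate %d maxima, got %d",
                 10 * n_peaks, n_peaks, length(t_values)), call. = FALSE)
  }
  stopifnot(bandwidth > 0)
  dens <- stats::density(c(t_values - 1, t_values, t_values + 1),
                         bw = bandwidth, n = grid_n, from = 0,
                         to = 1 - 1 / grid_n)
  y <- dens$y
  g <- length(y)
  left <- y[c(g, seq_len(g - 1))]
  right <- y[c(seq_len(g - 1) + 1, 1)]
  is_peak <- y > left & y >= right
  peaks <- which(is_peak)
  if (length(peaks) < n_peaks) {
    stop(sprintf("found only %d local maxima; %d required",
                 length(peaks), n_peaks), call. = FALSE)
  }
  ord <- order(y[peaks], decreasing = TRUE)
  top <- peaks[ord[seq_len(n_peaks)]]
  trough <- min(y)
  weakest <- min(y[top])
  if (weakest < min_contrast * max(trough, .Machine$double.eps)) {
    stop(sprintf(paste0("peaks are unstable: weakest peak/trough ratio %.3f ",
                        "is below min_contrast = %.3f"),
                 weakest / max(trough, .Machine$double.eps), min_contrast),
         call. = FALSE)
  }
  t_peaks <- dens$x[top]
  rel <- (t_peaks - origin_t) %% 1
  maxima <- setNames(t_peaks[order(rel)], ES_CODES)
  code_assignment(maxima)
}

#' Encode a chain of backbone dihedrals as an ES code string
#'
#' Projects each residue's (phi, psi) pair onto the path and assigns the
#' nearest code maximum. Residues with a missing angle receive the
#' placeholder letter `'X'`.
#'
#' @param dihedrals data frame with columns `phi`, `psi` (degrees; `NA` for
#'   undefined angles), one row per residue.
#' @param path an [es_path()].
#' @param assignment a [code_assignment()].
#' @param residues optional amino-acid string (same length as the chain) used
#'   when the assignment is residue-specific.
#' @return a single string over `{A-G, X}` of length `nrow(dihedrals)`.
#' @examples
#' path <- es_path()
#' asg <- code_assignment(setNames(seq(0.05, 0.95, length.out = 7), LETTERS[1:7]))
#' pts <- path_point(path, rep(asg$maxima[["C"]], 3))
#' encode_chain(tibble::tibble(phi = pts$phi, psi = pts$psi), path, asg)
#' @export
encode_chain <- function(dihedrals, path, assignment, residues = NULL) {
  dihedrals <- as_dihedral_frame(dihedrals)
  res_letters <- NULL
  if (!is.null(residues)) {
    res_letters <- strsplit(residues, "")[[1]]
    if (length(res_letters) != nrow(dihedrals)) {
      stop("`residues` must have one letter per dihedral row", call. = FALSE)
    }
  }
  proj <- project_to_path(dihedrals, path)
  codes <- vapply(seq_len(nrow(proj)), function(i) {
    assign_code(proj$t[i], assignment,
                residue = if (!is.null(res_letters)) res_letters[i])
  }, character(1))
  paste(codes, collapse = "")
}
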