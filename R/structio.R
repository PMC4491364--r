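#' Backbone chain container
#'
#' Holds one protein chain's backbone geometry plus everything needed for
#' interaction flagging: all-atom coordinates of the chain and the
#' coordinates of external molecules (hetero atoms) tagged by source.
#'
#' @param chain_id chain identifier.
#' @param residues tibble with one row per residue, columns `resno`, `resid`
#'   (3-letter code), `aa` (one-letter, `'X'` for nonstandard), the backbone
#'   coordinates `n_x, n_y, n_z, ca_x, ca_y, ca_z, c_x, c_y, c_z` (angstrom;
#'   `NA` when the atom is absent) and `complete` (all three backbone atoms
#'   present).
#' @param atoms tibble of all atoms of the chain: `res_index` (row of
#'   `residues`), `x`, `y`, `z`. Defaults to the backbone atoms.
#' @param hetero tibble of external-molecule atoms: `x`, `y`, `z`, `tag`
#'   (one of `"ligand"`, `"protein"`, `"nucleic"`).
#' @return an object of class `backbone_chain`.
#' @export
backbone_chain <- function(chain_id, residues, atoms = NULL, hetero = NULL) {
  needed <- c("resno", "resid", "aa", "n_x", "n_y", "n_z",
              "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z")
  stopifnot(is.data.frame(residues), all(needed %in% names(residues)))
  residues <- tibble::as_tibble(residues)
  residues$complete <- stats::complete.cases(
    residues[, c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
                 "c_x", "c_y", "c_z")]
  )
  if (is.null(atoms)) {
    atoms <- tidyr::pivot_longer(
      dplyr::mutate(residues[, c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
                                 "c_x", "c_y", "c_z")],
                    res_index = dplyr::row_number()),
      cols = -"res_index",
      names_to = c("atom", ".value"), names_sep = "_"
    )
    atoms <- atoms[stats::complete.cases(atoms[, c("x", "y", "z")]),
                   c("res_index", "x", "y", "z")]
  }
  if (is.null(hetero)) {
    hetero <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                             tag = character())
  }
  structure(
    list(chain_id = chain_id,
         residues = residues,
         atoms = tibble::as_tibble(atoms),
         hetero = tibble::as_tibble(hetero)),
    class = "backbone_chain"
  )
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain> %s: %d residues (%d complete), %d hetero atoms\n",
              x$chain_id, nrow(x$residues), sum(x$residues$complete),
              nrow(x$hetero)))
  invisible(x)
}

#' Compute backbone dihedral angles for a chain
#'
#' phi_i is the signed dihedral of C(i-1)-N(i)-CA(i)-C(i); psi_i of
#' N(i)-CA(i)-C(i)-N(i+1). The first residue's phi and the last residue's psi
#' are undefined and returned as `NA`, as is any angle involving an atom of
#' an incomplete residue. Missingness is always encoded as `NA`, never a
#' sentinel value, and never raises an error.
#'
#' @param chain a [backbone_chain()].
#' @return a tibble with columns `phi`, `psi` (degrees in (-180, 180],
#'   `NA` where undefined), one row per residue.
#' @export
compute_dihedrals <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  r <- chain$residues
  n <- nrow(r)
  if (n == 0) stop("chain has no residues", call. = FALSE)
  N  <- as.matrix(r[, c("n_x", "n_y", "n_z")])
  CA <- as.matrix(r[, c("ca_x", "ca_y", "ca_z")])
  C  <- as.matrix(r[, c("c_x", "c_y", "c_z")])
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  comp <- r$complete
  for (i in seq_len(n)) {
    if (!comp[i]) next
    if (i > 1 && comp[i - 1]) {
      phi[i] <- dihedral4(rbind(C[i - 1, ], N[i, ], CA[i, ], C[i, ]))
    }
    if (i < n && comp[i + 1]) {
      psi[i] <- dihedral4(rbind(N[i, ], CA[i, ], C[i, ], N[i + 1, ]))
    }
  }
  tibble::tibble(phi = phi, psi = psi)
}

#' Flag residues interacting with external molecules
#'
#' A residue is flagged for a category (ligand, other protein, nucleic acid)
#' if any of its atoms lies within `cutoff` angstrom (plain Euclidean
#' distance) of any hetero atom carrying that tag. The default 2.9 angstrom
#' follows the PDBSum contact convention.
#'
#' @param chain a [backbone_chain()].
#' @param cutoff distance threshold in angstrom, > 0.
#' @return a tibble with logical columns `ligand`, `protein`, `nucleic`, one
#'   row per residue.
#' @export
flag_interacting <- function(chain, cutoff = 2.9) {
  stopifnot(inherits(chain, "backbone_chain"), is.numeric(cutoff), cutoff > 0)
  n <- nrow(chain$residues)
  out <- tibble::tibble(ligand = logical(n), protein = logical(n),
                        nucleic = logical(n))
  if (!nrow(chain$hetero) || !nrow(chain$atoms)) return(out)
  axyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  for (tag in c("ligand", "protein", "nucleic")) {
    hx <- chain$hetero[chain$hetero$tag == tag, , drop = FALSE]
    if (!nrow(hx)) next
    hxyz <- as.matrix(hx[, c("x", "y", "z")])
    # squared-distance matrix atoms x hetero
    d2 <- outer(rowSums(axyz^2), rowSums(hxyz^2), "+") -
      2 * axyz %*% t(hxyz)
    hit_atom <- apply(d2 <= cutoff^2 + 1e-12, 1, any)
    hit_res <- unique(chain$atoms$res_index[hit_atom])
    out[[tag]][hit_res] <- TRUE
  }
  out
}

# ---- corpus ----------------------------------------------------------------

#' Construct a corpus of sequence / ES-code records
#'
#' @param id character vector of record identifiers.
#' @param sequence amino-acid strings (20 one-letter codes plus `'X'` for
#'   nonstandard residues).
#' @param codes equal-length ES code strings over `{A-G, X}`.
#' @param flags optional per-residue interaction strings over
#'   `{L, P, N, -}` (ligand / protein / nucleic / none), or `NA`.
#' @return a tibble of class `es_corpus` with those columns.
#' @export
es_corpus <- function(id, sequence, codes, flags = NULL) {
  if (is.null(flags)) flags <- rep(NA_character_, length(id))
  x <- tibble::tibble(id = as.character(id), sequence = sequence,
                      codes = codes, flags = flags)
  validate_corpus(x)
  class(x) <- c("es_corpus", class(x))
  x
}

validate_corpus <- function(x) {
  stopifnot(all(c("id", "sequence", "codes") %in% names(x)))
  bad_len <- nchar(x$sequence) != nchar(x$codes)
  if (any(bad_len)) {
    stop(sprintf("record '%s': sequence length %d != codes length %d",
                 x$id[bad_len][1], nchar(x$sequence[bad_len][1]),
                 nchar(x$codes[bad_len][1])), call. = FALSE)
  }
  bad_seq <- grepl(sprintf("[^%s]", paste(AA21, collapse = "")), x$sequence)
  if (any(bad_seq)) {
    stop(sprintf("record '%s': illegal letters in sequence", x$id[bad_seq][1]),
         call. = FALSE)
  }
  bad_code <- grepl("[^A-GX]", x$codes)
  if (any(bad_code)) {
    stop(sprintf("record '%s': illegal letters in code string",
                 x$id[bad_code][1]), call. = FALSE)
  }
  if ("flags" %in% names(x)) {
    fl <- x$flags[!is.na(x$flags)]
    ids <- x$id[!is.na(x$flags)]
    bad_fl <- grepl("[^LPN-]", fl) |
      nchar(fl) != nchar(x$sequence[!is.na(x$flags)])
    if (any(bad_fl)) {
      stop(sprintf("record '%s': malformed flags line", ids[bad_fl][1]),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a corpus file
#'
#' The corpus format is FASTA-like: for each chain a `>id|seq` header
#' followed by the amino-acid sequence, a `>id|codes` header followed by the
#' equal-length ES code string, and optionally `>id|flags` followed by a
#' per-residue interaction line over `{L, P, N, -}`. Payload may be wrapped
#' over several lines. Malformed records are rejected with an error naming
#' the record and line.
#'
#' @param path file to read.
#' @return an [es_corpus()] tibble (possibly with zero rows).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop(sprintf("corpus file '%s' not found", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  headers <- grepl("^>", lines)
  if (length(lines) && !headers[1]) {
    stop(sprintf("line %d: expected a '>' header", lineno[1]), call. = FALSE)
  }
  recs <- list()
  i <- 1
  while (i <= length(lines)) {
    h <- sub("^>", "", lines[i])
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[2] %in% c("seq", "codes", "flags")) {
      stop(sprintf("line %d: malformed header '>%s'", lineno[i], h),
           call. = FALSE)
    }
    j <- i + 1
    while (j <= length(lines) && !headers[j]) j <- j + 1
    if (j == i + 1) {
      stop(sprintf("line %d: header '>%s' has no payload", lineno[i], h),
           call. = FALSE)
    }
    payload <- paste(lines[(i + 1):(j - 1)], collapse = "")
    recs[[length(recs) + 1]] <- list(id = parts[1], kind = parts[2],
                                     payload = payload)
    i <- j
  }
  if (!length(recs)) {
    return(es_corpus(character(), character(), character()))
  }
  df <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  wide <- tidyr::pivot_wider(df, id_cols = "id", names_from = "kind",
                             values_from = "payload")
  if (!all(c("seq", "codes") %in% names(wide)) ||
      anyNA(wide$seq) || anyNA(wide$codes)) {
    missing_id <- wide$id[if ("codes" %in% names(wide)) is.na(wide$codes) else TRUE][1]
    stop(sprintf("record '%s': needs both |seq and |codes entries",
                 missing_id), call. = FALSE)
  }
  es_corpus(wide$id, wide$seq, wide$codes,
            flags = if ("flags" %in% names(wide)) wide$flags)
}

#' Write a corpus file
#'
#' Inverse of [read_corpus()]; write-then-read reproduces the corpus exactly.
#' The file is written atomically (temp file + rename).
#'
#' @param corpus an [es_corpus()] (or data frame with the same columns).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  if (!inherits(corpus, "es_corpus")) {
    corpus <- es_corpus(corpus$id, corpus$sequence, corpus$codes,
                        flags = corpus$flags)
  }
  validate_corpus(corpus)
  lines <- unlist(lapply(seq_len(nrow(corpus)), function(i) {
    out <- c(paste0(">", corpus$id[i], "|seq"), corpus$sequence[i],
             paste0(">", corpus$id[i], "|codes"), corpus$codes[i])
    if (!is.na(corpus$flags[i])) {
      out <- c(out, paste0(">", corpus$id[i], "|flags"), corpus$flags[i])
    }
    out
  }))
  if (is.null(lines)) lines <- character()
  write_atomically(lines, path)
  invisible(path)
}

#' Collapse interaction flags to the corpus flags encoding
#'
#' Converts the three logical columns returned by [flag_interacting()] to the
#' one-letter-per-residue corpus encoding. A residue interacting with several
#' categories is encoded with priority L > P > N.
#'
#' @param flags tibble with logical columns `ligand`, `protein`, `nucleic`.
#' @return a single string over `{L, P, N, -}`.
#' @export
flags_to_string <- function(flags) {
  ch <- rep("-", nrow(flags))
  ch[flags$nucleic] <- "N"
  ch[flags$protein] <- "P"
  ch[flags$ligand] <- "L"
  paste(ch, collapse = "")
}

# ---- PDB reading -----------------------------------------------------------

NUCLEIC_RESID <- c("A", "C", "G", "U", "T", "I",
                   "DA", "DC", "DG", "DT", "DU", "DI")
WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

#' Read protein backbone chains from a PDB file
#'
#' Parses standard ATOM/HETATM records (first model only; parsing is done by
#' \pkg{bio3d}). Alternate locations are resolved by highest occupancy, then
#' by altloc label order. For every protein chain the returned object carries
#' as hetero atoms: HETATM entries (tag `"ligand"`), atoms of other protein
#' chains (tag `"protein"`) and atoms of nucleic-acid chains (tag
#' `"nucleic"`). Water is excluded unless `include_water = TRUE`.
#' Nonstandard residues get `'X'` as their one-letter code.
#'
#' @param path PDB file.
#' @param include_water keep water molecules among hetero atoms?
#' @return a list of [backbone_chain()] objects, one per protein chain.
#' @export
read_pdb_backbone <- function(path, include_water = FALSE) {
  if (!file.exists(path)) stop(sprintf("PDB file '%s' not found", path),
                               call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("cannot parse PDB file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  at <- tibble::as_tibble(pdb$atom)
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  # resolve altlocs: highest occupancy wins, ties by altloc label order
  at <- dplyr::arrange(at, .data$chain, .data$resno, .data$insert,
                       .data$elety, dplyr::desc(.data$o), .data$alt)
  at <- dplyr::distinct(at, .data$chain, .data$resno, .data$insert,
                        .data$elety, .keep_all = TRUE)
  if (!include_water) at <- at[!(at$resid %in% WATER_RESID), , drop = FALSE]

  is_nucleic <- at$type == "ATOM" & at$resid %in% NUCLEIC_RESID
  is_protein <- at$type == "ATOM" & !is_nucleic
  prot_chains <- unique(at$chain[is_protein])
  if (!length(prot_chains)) {
    stop(sprintf("'%s' contains no protein chains", path), call. = FALSE)
  }

  lapply(prot_chains, function(ch) {
    mine <- at[is_protein & at$chain == ch, , drop = FALSE]
    ins <- if ("insert" %in% names(mine)) {
      ifelse(is.na(mine$insert), "", mine$insert)
    } else ""
    res_key <- paste(mine$resno, ins, sep = "_")
    res_order <- unique(res_key)
    idx <- match(res_key, res_order)
    pick <- function(atom, coord) {
      v <- rep(NA_real_, length(res_order))
      sel <- mine$elety == atom
      v[idx[sel]] <- mine[[coord]][sel]
      v
    }
    first_of <- function(col) mine[[col]][match(res_order, res_key)]
    resid3 <- first_of("resid")
    residues <- tibble::tibble(
      resno = first_of("resno"),
      resid = resid3,
      aa = suppressWarnings(bio3d::aa321(resid3)),
      n_x = pick("N", "x"), n_y = pick("N", "y"), n_z = pick("N", "z"),
      ca_x = pick("CA", "x"), ca_y = pick("CA", "y"), ca_z = pick("CA", "z"),
      c_x = pick("C", "x"), c_y = pick("C", "y"), c_z = pick("C", "z")
    )
    residues$aa[is.na(residues$aa) | !(residues$aa %in% AA20)] <- "X"
    atoms <- tibble::tibble(res_index = idx, x = mine$x, y = mine$y,
                            z = mine$z)
    other <- at[!(is_protein & at$chain == ch), , drop = FALSE]
    tag <- ifelse(other$type == "HETATM", "ligand",
                  ifelse(other$resid %in% NUCLEIC_RESID, "nucleic", "protein"))
    hetero <- tibble::tibble(x = other$x, y = other$y, z = other$z, tag = tag)
    backbone_chain(ch, residues, atoms = atoms, hetero = hetero)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract per-residue DSSP classes from a .dssp file
#'
#' Thin reader for the classic DSSP text layout: takes the structure summary
#' column (column 17) of every residue line after the `#  RESIDUE` header.
#' Chain breaks (`!` lines) are skipped. Unclassified residues yield a space.
#'
#' @param path a .dssp file.
#' @return a single string of DSSP letters, one per residue.
#' @export
read_dssp_classes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) {
    stop(sprintf("'%s' does not look like DSSP output (no residue header)",
                 path), call. = FALSE)
  }
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  paste(substr(body, 17, 17), collapse = "")
}
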