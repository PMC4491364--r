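# Shared fixtures, all generated in code.

# A well-separated global assignment used by geometry tests.
tiny_assignment <- function() {
  code_assignment(setNames(seq(0.05, 0.95, length.out = 7), LETTERS[1:7]))
}

tiny_path <- function(...) {
  es_path(center_phi = -40, center_psi = 0, axis_a = 110, axis_b = 70, ...)
}

# One fixed-width PDB coordinate line.
pdb_line <- function(record, serial, name, alt, resn, chain, resno,
                     x, y, z, occ = 1) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf(" %-3s", name), alt, resn, chain, resno,
          x, y, z, occ, 0, substr(name, 1, 1))
}

# Minimal 3-residue chain with one ligand HETATM, one water and an altloc
# pair; returns the file path.
write_test_pdb <- function(path = tempfile(fileext = ".pdb"),
                           with_water = TRUE) {
  lines <- c(
    pdb_line("ATOM", 1, "N",  " ", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_line("ATOM", 2, "CA", " ", "ALA", "A", 1, 1.46, 0.0, 0.0),
    pdb_line("ATOM", 3, "C",  " ", "ALA", "A", 1, 2.0, 1.42, 0.0),
    pdb_line("ATOM", 4, "N",  " ", "GLY", "A", 2, 3.3, 1.5, 0.2),
    pdb_line("ATOM", 5, "CA", "A", "GLY", "A", 2, 4.0, 2.7, 0.5, 0.4),
    pdb_line("ATOM", 6, "CA", "B", "GLY", "A", 2, 4.1, 2.8, 0.6, 0.6),
    pdb_line("ATOM", 7, "C",  " ", "GLY", "A", 2, 5.4, 2.6, 1.1),
    pdb_line("ATOM", 8, "N",  " ", "SER", "A", 3, 6.1, 3.7, 1.3),
    pdb_line("ATOM", 9, "CA", " ", "SER", "A", 3, 7.5, 3.8, 1.8),
    pdb_line("ATOM", 10, "C", " ", "SER", "A", 3, 8.3, 5.0, 1.4),
    pdb_line("HETATM", 11, "C1", " ", "LIG", "A", 102, 2.2, 1.5, 2.5)
  )
  if (with_water) {
    lines <- c(lines,
               pdb_line("HETATM", 12, "O", " ", "HOH", "A", 101, 40, 40, 40))
  }
  writeLines(c(lines, "END"), path)
  path
}

# A synthetic backbone chain with arbitrary (non-degenerate) coordinates.
random_backbone <- function(n, seed = 1) {
  withr::with_seed(seed, {
    coords <- matrix(cumsum(rnorm(9 * n, sd = 1.2)), ncol = 9)
    residues <- tibble::tibble(
      resno = seq_len(n),
      resid = "ALA",
      aa = "A",
      n_x = coords[, 1], n_y = coords[, 2], n_z = coords[, 3],
      ca_x = coords[, 4] + 3, ca_y = coords[, 5], ca_z = coords[, 6],
      c_x = coords[, 7] + 6, c_y = coords[, 8], c_z = coords[, 9]
    )
    backbone_chain("Z", residues)
  })
}

# Naive reference matcher for the predictor: linear scans over a tidy view of
# the dictionary, explicit Hamming-distance-1 enumeration, no hashing.
reference_predict_chain <- function(sequence, dict) {
  tables <- lapply(dict$subdicts, function(s) {
    data.frame(key = rownames(s$counts), s$counts,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  codes <- LETTERS[1:7]
  n <- nchar(sequence)
  pad <- (dict$l_max - 1) / 2
  padded <- paste0(strrep("X", pad), sequence, strrep("X", pad))
  hamming1 <- function(a, b) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    sum(ac != bc) == 1
  }
  out <- character(n)
  for (k in seq_len(n)) {
    found <- NA_character_
    for (i in seq(dict$l_max, 1, by = -2)) {
      h <- (i - 1) / 2
      key <- substr(padded, k + pad - h, k + pad + h)
      tab <- tables[[as.character(i)]]
      row <- which(tab$key == key)
      if (length(row) == 1) {
        found <- codes[which.max(as.numeric(tab[row, codes]))]
        break
      }
      if (i > 1) {
        near <- vapply(tab$key, hamming1, logical(1), b = key)
        if (any(near)) {
          agg <- colSums(tab[near, codes, drop = FALSE])
          found <- codes[which.max(agg)]
          break
        }
      }
    }
    if (is.na(found)) found <- dict$meta$majority_code
    out[k] <- found
  }
  paste(out, collapse = "")
}
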