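# Deterministic 31-bit polynomial string hash (base 131, modulus 2^31 - 1).
# Exact in double arithmetic: (2^31 - 1) * 131 + 255 < 2^53.
POLY_BASE <- 131
POLY_MOD <- 2147483647

poly_hash <- function(s, seed = 0) {
  h <- vapply(s, function(x) {
    h <- seed %% POLY_MOD
    for (b in utf8ToInt(x)) h <- (h * POLY_BASE + b) %% POLY_MOD
    h
  }, numeric(1), USE.NAMES = FALSE)
  poly_finalize(h)
}

# Column-wise vectorized variant for an integer matrix of character codes
# (one row per string, fixed width).
poly_hash_mat <- function(m, seed = 0) {
  h <- rep(seed %% POLY_MOD, nrow(m))
  for (j in seq_len(ncol(m))) h <- (h * POLY_BASE + m[, j]) %% POLY_MOD
  poly_finalize(h)
}

# Avalanche rounds (Lehmer multiplier), so strings sharing long prefixes do
# not hash into nearby values; exact in doubles: POLY_MOD * 48271 < 2^53.
poly_finalize <- function(h) {
  for (r in 1:3) h <- ((h + 1) * 48271) %% POLY_MOD
  h
}

#' Build the family of substring subdictionaries from a corpus
#'
#' For every odd window length `i` in `1, 3, ..., l_max` and every chain, the
#' sequence is padded with `floor(i/2)` neutral `'X'` symbols on each side and
#' a sliding window of length `i` is moved across it, producing one window per
#' residue (a chain of length `n` yields `n` windows). Each window increments
#' the counter of the ES code observed at the window's middle residue in
#' subdictionary `D_i`. Positions whose observed code is `'X'` (undefined
#' dihedral) are skipped as window centers but still appear as context letters
#' inside neighbouring windows.
#'
#' @param corpus an [es_corpus()] (columns `id`, `sequence`, `codes`).
#' @param l_max largest window length; odd, between 1 and 25. Default 13.
#' @return an object of class `es_dictionary`: subdictionaries `D_1, D_3,
#'   ..., D_lmax` (hash-indexed key to 7-counter records) plus metadata
#'   (corpus digest, global majority code, residue totals).
#' @examples
#' corp <- es_corpus("c1", "ARNDC", "CCEEC")
#' d <- build_dictionary(corp, l_max = 3)
#' lookup_exact(d, 3, "XAR")
#' @export
build_dictionary <- function(corpus, l_max = 13) {
  if (length(l_max) != 1 || l_max < 1 || l_max %% 2 != 1) {
    stop("`l_max` must be a single odd integer >= 1", call. = FALSE)
  }
  if (l_max > 25) stop("`l_max` must be <= 25", call. = FALSE)
  if (!nrow(corpus)) stop("corpus is empty", call. = FALSE)
  validate_corpus(corpus)

  lens <- nchar(corpus$sequence)
  code_chars <- strsplit(corpus$codes, "")
  keep_center <- lapply(code_chars, function(ch) ch != "X")
  center_codes <- unlist(lapply(code_chars, function(ch) ch[ch != "X"]))

  lengths_i <- seq(1, l_max, by = 2)
  subdicts <- lapply(lengths_i, function(i) {
    h <- (i - 1) / 2
    wins <- unlist(lapply(seq_len(nrow(corpus)), function(r) {
      n <- lens[r]
      padded <- paste0(strrep("X", h), corpus$sequence[r], strrep("X", h))
      substring(padded, seq_len(n), seq_len(n) + i - 1)[keep_center[[r]]]
    }))
    new_counter_table(wins, center_codes)
  })
  names(subdicts) <- as.character(lengths_i)

  d1 <- subdicts[["1"]]
  majority <- ES_CODES[which.max(colSums(d1$counts))]
  rec_strings <- sprintf("%s|%s|%s", corpus$id, corpus$sequence, corpus$codes)
  digest <- poly_hash(paste(sort(rec_strings, method = "radix"),
                            collapse = "\n"))
  structure(
    list(
      l_max = as.integer(l_max),
      subdicts = subdicts,
      meta = list(
        n_chains = nrow(corpus),
        n_residues = sum(lens),
        n_centers = length(center_codes),
        majority_code = majority,
        corpus_digest = digest
      )
    ),
    class = "es_dictionary"
  )
}

# Aggregate (window, code) pairs into a key-sorted counts matrix plus a
# key -> row hash index.
new_counter_table <- function(wins, codes) {
  keys <- sort(unique(wins), method = "radix")
  if (length(keys)) {
    tab <- table(factor(wins, levels = keys),
                 factor(codes, levels = ES_CODES))
    counts <- matrix(as.integer(tab), nrow = length(keys),
                     dimnames = list(keys, ES_CODES))
  } else {
    counts <- matrix(integer(), nrow = 0, ncol = 7,
                     dimnames = list(character(), ES_CODES))
  }
  list(index = list2env(as.list(setNames(seq_along(keys), keys)),
                        hash = TRUE, size = max(1L, length(keys))),
       counts = counts)
}

#' @export
print.es_dictionary <- function(x, ...) {
  cat(sprintf("<es_dictionary> l_max = %d, %d chains, %d residues, majority code %s\n",
              x$l_max, x$meta$n_chains, x$meta$n_residues,
              x$meta$majority_code))
  for (i in names(x$subdicts)) {
    cat(sprintf("  D_%s: %d keys\n", i, nrow(x$subdicts[[i]]$counts)))
  }
  invisible(x)
}

#' Exact subdictionary lookup
#'
#' Constant-time (hash) retrieval of the 7-counter record for a window key.
#'
#' @param dict an [build_dictionary()] result.
#' @param i odd window length selecting subdictionary `D_i`.
#' @param key string of length `i` over the amino-acid alphabet plus `'X'`.
#' @return a named integer vector of 7 counters (names `A`-`G`), or `NULL`
#'   if the key is absent.
#' @export
lookup_exact <- function(dict, i, key) {
  sub <- dict$subdicts[[as.character(i)]]
  if (is.null(sub)) stop(sprintf("no subdictionary D_%s", i), call. = FALSE)
  row <- get0(key, envir = sub$index, inherits = FALSE)
  if (is.null(row)) return(NULL)
  sub$counts[row, ]
}

#' One-mismatch (Hamming distance 1) subdictionary lookup
#'
#' Enumerates every single-position substitution of `key` (any position,
#' including the center; substitutes drawn from the 20 amino-acid letters
#' plus `'X'`, excluding the original letter — `i * 20` variants), retrieves
#' each exactly, and returns the element-wise sum of counters over all hits.
#' Intended to be called after [lookup_exact()] has returned `NULL`.
#'
#' @inheritParams lookup_exact
#' @return a named numeric vector of 7 aggregated counters, or `NULL` if no
#'   variant is present.
#' @export
lookup_one_mismatch <- function(dict, i, key) {
  sub <- dict$subdicts[[as.character(i)]]
  if (is.null(sub)) stop(sprintf("no subdictionary D_%s", i), call. = FALSE)
  variants <- one_mismatch_variants(key)
  hits <- unlist(mget(variants, envir = sub$index, inherits = FALSE,
                      ifnotfound = list(NULL)), use.names = FALSE)
  if (is.null(hits) || !length(hits)) return(NULL)
  colSums(sub$counts[hits, , drop = FALSE])
}

one_mismatch_variants <- function(key) {
  chars <- strsplit(key, "")[[1]]
  n <- length(chars)
  unlist(lapply(seq_len(n), function(p) {
    subs <- AA21[AA21 != chars[p]]
    pre <- if (p > 1) substr(key, 1, p - 1) else ""
    post <- if (p < n) substr(key, p + 1, n) else ""
    paste0(pre, subs, post)
  }))
}

#' Best structural class of a counter record
#'
#' Argmax over the 7 counters; ties go to the alphabetically earliest code.
#'
#' @param counters numeric vector of 7 counters ordered/named `A`-`G`.
#' @return a single code letter.
#' @export
best_class <- function(counters) {
  stopifnot(length(counters) == 7)
  ES_CODES[which.max(counters)]
}

#' Save / load a dictionary as a deterministic text table
#'
#' The on-disk format is line-oriented: a header with metadata, then for each
#' subdictionary a `[D i]` section of radix-sorted `key TAB 7-counters` rows.
#' Serialization is byte-deterministic for a given dictionary, and building
#' from the same corpus in any record order yields the same bytes.
#'
#' @param dict an `es_dictionary`.
#' @param path destination / source file.
#' @return `save_dictionary`: `path` invisibly. `load_dictionary`: the
#'   reconstructed `es_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "es_dictionary"))
  if (!length(dict$subdicts) ||
      all(vapply(dict$subdicts, function(s) nrow(s$counts) == 0, logical(1)))) {
    stop("refusing to save an empty dictionary", call. = FALSE)
  }
  header <- c(
    "#esdict v1",
    sprintf("l_max\t%d", dict$l_max),
    sprintf("n_chains\t%d", dict$meta$n_chains),
    sprintf("n_residues\t%d", dict$meta$n_residues),
    sprintf("n_centers\t%d", dict$meta$n_centers),
    sprintf("majority_code\t%s", dict$meta$majority_code),
    sprintf("corpus_digest\t%.0f", dict$meta$corpus_digest)
  )
  body <- unlist(lapply(names(dict$subdicts), function(i) {
    counts <- dict$subdicts[[i]]$counts
    rows <- apply(counts, 1, paste, collapse = "\t")
    c(sprintf("[D %s]", i), paste(rownames(counts), rows, sep = "\t"))
  }))
  write_atomically(c(header, body), path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop(sprintf("dictionary file '%s' not found", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "#esdict v1") {
    stop(sprintf("'%s' is not an esdict v1 file (bad header)", path),
         call. = FALSE)
  }
  sec <- grep("^\\[D ", lines)
  if (!length(sec)) stop(sprintf("'%s': no subdictionary sections", path),
                         call. = FALSE)
  head_kv <- strsplit(lines[2:(sec[1] - 1)], "\t", fixed = TRUE)
  meta_raw <- setNames(vapply(head_kv, `[[`, character(1), 2),
                       vapply(head_kv, `[[`, character(1), 1))
  bounds <- c(sec, length(lines) + 1L)
  subdicts <- list()
  for (k in seq_along(sec)) {
    i <- sub("^\\[D (\\d+)\\]$", "\\1", lines[sec[k]])
    rows <- lines[(sec[k] + 1):(bounds[k + 1] - 1)]
    rows <- rows[nzchar(rows)]
    parts <- strsplit(rows, "\t", fixed = TRUE)
    if (any(vapply(parts, length, integer(1)) != 8)) {
      stop(sprintf("'%s': malformed row in section [D %s]", path, i),
           call. = FALSE)
    }
    keys <- vapply(parts, `[[`, character(1), 1)
    counts <- matrix(as.integer(t(vapply(parts, function(p) as.integer(p[2:8]),
                                         integer(7)))),
                     ncol = 7, dimnames = list(keys, ES_CODES))
    subdicts[[i]] <- list(
      index = list2env(as.list(setNames(seq_along(keys), keys)),
                       hash = TRUE, size = max(1L, length(keys))),
      counts = counts
    )
  }
  structure(
    list(
      l_max = as.integer(meta_raw[["l_max"]]),
      subdicts = subdicts,
      meta = list(
        n_chains = as.integer(meta_raw[["n_chains"]]),
        n_residues = as.integer(meta_raw[["n_residues"]]),
        n_centers = as.integer(meta_raw[["n_centers"]]),
        majority_code = meta_raw[["majority_code"]],
        corpus_digest = as.numeric(meta_raw[["corpus_digest"]])
      )
    ),
    class = "es_dictionary"
  )
}

#' @export
tidy.es_dictionary <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$subdicts), function(i) {
    counts <- x$subdicts[[i]]$counts
    out <- tibble::as_tibble(counts)
    out <- dplyr::mutate(out, window_length = as.integer(i),
                         key = rownames(counts), .before = 1)
    out
  }))
}

#' @export
glance.es_dictionary <- function(x, ...) {
  tibble::tibble(
    l_max = x$l_max,
    n_subdicts = length(x$subdicts),
    n_keys = sum(vapply(x$subdicts, function(s) nrow(s$counts), integer(1))),
    n_chains = x$meta$n_chains,
    n_residues = x$meta$n_residues,
    n_centers = x$meta$n_centers,
    majority_code = x$meta$majority_code
  )
}
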