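#' Deterministic window-to-code mapping
#'
#' Returns a reproducible pseudo-random function from length-`w` sequence
#' windows (over the amino-acid alphabet plus `'X'`) to ES codes A-G. The
#' mapping is realized by a deterministic polynomial string hash of the
#' window combined with the seed, truncated to 7 outcomes, so no table needs
#' to be stored: the same `(seed, w)` always gives the same mapping.
#'
#' @param seed integer seed.
#' @param w odd window width (the code depends only on the `w` letters
#'   centered on a position), `w <= 13`.
#' @return a vectorized function: character vector of windows to code letters.
#' @export
gen_mapping <- function(seed, w) {
  stopifnot(w >= 1, w %% 2 == 1, w <= 13)
  mix <- ((as.numeric(seed) %% POLY_MOD) * 69069 + w * 97) %% POLY_MOD
  f <- function(windows) {
    ES_CODES[poly_hash(windows, seed = mix) %% 7 + 1]
  }
  attr(f, "seed") <- seed
  attr(f, "w") <- w
  f
}

# Hash a whole chain's centered windows at once: integer char codes of the
# padded sequence, rolled into one polynomial hash per center position.
map_chain_codes <- function(sequence, w, mix) {
  n <- nchar(sequence)
  h <- (w - 1) / 2
  padded <- paste0(strrep("X", h), sequence, strrep("X", h))
  ints <- utf8ToInt(padded)
  m <- vapply(0:(w - 1), function(j) ints[seq_len(n) + j], numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  ES_CODES[poly_hash_mat(m, seed = mix) %% 7 + 1]
}

#' Generate a synthetic corpus with known sequence-to-code structure
#'
#' Sequences are drawn i.i.d. from the 20-letter amino-acid alphabet
#' (optionally biased); the true code at each position is a deterministic
#' function ([gen_mapping()]) of the length-`mapping_width` window centered
#' there (`'X'`-padded at the termini). Each emitted code is then replaced,
#' independently with probability `noise_rate`, by a uniformly random
#' different code. The output is a pure function of the arguments.
#'
#' @param n_chains number of chains.
#' @param chain_length single length or `c(min, max)` range.
#' @param mapping_width odd window width `w <= 13` determining the true code.
#' @param noise_rate per-position corruption probability in \[0, 1).
#' @param seed integer seed; all randomness is scoped to this call.
#' @param alphabet_bias optional named numeric weights over the 20 residue
#'   letters (unnamed letters get weight 0).
#' @param keep_truth if `TRUE`, adds a `codes_true` column with the
#'   noise-free codes.
#' @return an [es_corpus()] tibble.
#' @examples
#' corp <- gen_corpus(3, 40, mapping_width = 1, noise_rate = 0, seed = 1)
#' corp
#' @export
gen_corpus <- function(n_chains, chain_length, mapping_width = 5,
                       noise_rate = 0, seed = 1, alphabet_bias = NULL,
                       keep_truth = FALSE) {
  stopifnot(n_chains >= 1, all(chain_length >= 1),
            mapping_width %% 2 == 1, mapping_width <= 13,
            noise_rate >= 0, noise_rate < 1)
  weights <- rep(1, 20)
  if (!is.null(alphabet_bias)) {
    stopifnot(!is.null(names(alphabet_bias)),
              all(names(alphabet_bias) %in% AA20))
    weights <- rep(0, 20)
    weights[match(names(alphabet_bias), AA20)] <- alphabet_bias
    stopifnot(sum(weights) > 0)
  }
  mix <- ((as.numeric(seed) %% POLY_MOD) * 69069 + mapping_width * 97) %% POLY_MOD
  withr::with_seed(seed, {
    lens <- if (length(chain_length) == 1) {
      rep(as.integer(chain_length), n_chains)
    } else {
      sample(seq(chain_length[1], chain_length[2]), n_chains, replace = TRUE)
    }
    seqs <- vapply(lens, function(n) {
      paste(sample(AA20, n, replace = TRUE, prob = weights), collapse = "")
    }, character(1))
    codes_true <- vapply(seq_along(seqs), function(r) {
      paste(map_chain_codes(seqs[r], mapping_width, mix), collapse = "")
    }, character(1))
    codes <- vapply(codes_true, function(ct) {
      ch <- strsplit(ct, "")[[1]]
      flip <- runif(length(ch)) < noise_rate
      if (any(flip)) {
        ch[flip] <- vapply(ch[flip], function(orig) {
          sample(ES_CODES[ES_CODES != orig], 1)
        }, character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    out <- es_corpus(sprintf("syn%04d", seq_len(n_chains)), seqs, codes)
    if (keep_truth) out$codes_true <- codes_true
    out
  })
}

#' Sample a dihedral chain around the code maxima
#'
#' For each code letter, a point is taken at that code's maximum on the path
#' and isotropic Gaussian noise of standard deviation `sigma` degrees is
#' added to phi and psi (then normalized to the torus). `'X'` codes yield
#' missing angles. Used to exercise the projection/encoding round trip with
#' known ground truth.
#'
#' @param codes a code string over `{A-G, X}`.
#' @param path an [es_path()].
#' @param assignment a [code_assignment()].
#' @param sigma noise standard deviation, degrees.
#' @param seed integer seed.
#' @return a tibble with columns `phi`, `psi`.
#' @export
gen_dihedral_chain <- function(codes, path, assignment, sigma = 5, seed = 1) {
  stopifnot(inherits(path, "es_path"), inherits(assignment, "es_assignment"),
            sigma >= 0)
  ch <- strsplit(codes, "")[[1]]
  withr::with_seed(seed, {
    phi <- rep(NA_real_, length(ch))
    psi <- rep(NA_real_, length(ch))
    ok <- ch %in% ES_CODES
    if (any(ok)) {
      t_ok <- assignment$maxima[ch[ok]]
      pts <- path_point(path, t_ok)
      phi[ok] <- normalize_angle(pts$phi + rnorm(sum(ok), 0, sigma))
      psi[ok] <- normalize_angle(pts$psi + rnorm(sum(ok), 0, sigma))
    }
    tibble::tibble(phi = phi, psi = psi)
  })
}

#' Stable train/test split by chain-id hash
#'
#' A chain goes to the test set when the hash of its id falls below
#' `test_fraction`. The split is a pure function of the ids, so it is
#' disjoint and stable across runs and record orders.
#'
#' @param corpus an [es_corpus()].
#' @param test_fraction fraction of ids routed to the test set.
#' @param salt integer mixed into the hash, to derive independent splits.
#' @return a list with elements `train` and `test` (both [es_corpus()]).
#' @export
split_corpus <- function(corpus, test_fraction = 0.1, salt = 7) {
  u <- poly_hash(corpus$id, seed = salt) / POLY_MOD
  test <- u < test_fraction
  list(train = corpus[!test, , drop = FALSE],
       test = corpus[test, , drop = FALSE])
}
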