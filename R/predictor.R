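#' Predict the ES code at one sequence position
#'
#' Hierarchical dictionary matching: for window lengths
#' `i = l_max, l_max - 2, ..., 1` the window of length `i` centered on
#' position `k` (the sequence being conceptually padded with `floor(i/2)`
#' `'X'` symbols per side) is looked up exactly in `D_i`; on a hit the best
#' class is returned. Otherwise a one-mismatch lookup is tried at the same
#' length; on a hit the argmax of the aggregated counters is returned. Only
#' then is the window shrunk. `D_1` contains every residue letter seen in
#' training, so the loop virtually always terminates with a match; a letter
#' never seen in training falls back to the training set's global majority
#' code.
#'
#' @param sequence amino-acid string (unpadded).
#' @param k 1-based position within `sequence`.
#' @param dict an [build_dictionary()] result.
#' @return a one-row tibble: `position`, `residue`, `code`, `window_length`,
#'   `match_kind` (`"exact"`, `"one_mismatch"` or `"fallback"`) and
#'   `support` (list column holding the 7 counters behind the decision).
#' @export
predict_position <- function(sequence, k, dict) {
  stopifnot(k >= 1, k <= nchar(sequence))
  pad <- (dict$l_max - 1) / 2
  padded <- paste0(strrep("X", pad), sequence, strrep("X", pad))
  rows_to_prediction(list(predict_position_padded(padded, k, pad, dict)))
}

# Internal fast path: returns a plain list, not a tibble.
predict_position_padded <- function(padded, k, pad, dict) {
  center <- k + pad
  residue <- substr(padded, center, center)
  for (i in seq(dict$l_max, 1, by = -2)) {
    h <- (i - 1) / 2
    key <- substr(padded, center - h, center + h)
    hit <- lookup_exact(dict, i, key)
    if (!is.null(hit)) {
      return(list(position = k, residue = residue, code = best_class(hit),
                  window_length = i, match_kind = "exact", support = hit))
    }
    # D_1 holds every residue letter seen in training; a miss there means an
    # unseen letter, for which the majority fallback below applies directly.
    if (i > 1) {
      agg <- lookup_one_mismatch(dict, i, key)
      if (!is.null(agg)) {
        return(list(position = k, residue = residue, code = best_class(agg),
                    window_length = i, match_kind = "one_mismatch",
                    support = agg))
      }
    }
  }
  # residue letter absent from training: deterministic majority fallback
  list(position = k, residue = residue, code = dict$meta$majority_code,
       window_length = 1L, match_kind = "fallback",
       support = setNames(rep(NA_real_, 7), ES_CODES))
}

rows_to_prediction <- function(rows) {
  tibble::tibble(
    position = as.integer(vapply(rows, `[[`, numeric(1), "position")),
    residue = vapply(rows, `[[`, character(1), "residue"),
    code = vapply(rows, `[[`, character(1), "code"),
    window_length = as.integer(vapply(rows, `[[`, numeric(1),
                                      "window_length")),
    match_kind = vapply(rows, `[[`, character(1), "match_kind"),
    support = lapply(rows, `[[`, "support")
  )
}

#' Predict the ES code string for a whole sequence
#'
#' Applies [predict_position()] at every position. The result carries one
#' row per residue plus the rendered code string as attribute `"codes"`
#' (also available via [prediction_string()]).
#'
#' @param sequence amino-acid string; may be empty.
#' @param dict an [build_dictionary()] result.
#' @return a tibble of class `es_prediction` with columns as in
#'   [predict_position()].
#' @examples
#' corp <- es_corpus("c1", "ARNDCQ", "CCEEFF")
#' d <- build_dictionary(corp, l_max = 5)
#' pred <- predict_chain("ARNDCQ", d)
#' prediction_string(pred)
#' @export
predict_chain <- function(sequence, dict) {
  stopifnot(inherits(dict, "es_dictionary"), is.character(sequence),
            length(sequence) == 1)
  n <- nchar(sequence)
  pad <- (dict$l_max - 1) / 2
  padded <- paste0(strrep("X", pad), sequence, strrep("X", pad))
  rows <- lapply(seq_len(n), function(k) {
    predict_position_padded(padded, k, pad, dict)
  })
  out <- rows_to_prediction(rows)
  attr(out, "codes") <- paste(out$code, collapse = "")
  class(out) <- c("es_prediction", class(out))
  out
}

#' Rendered code string of a prediction
#'
#' @param prediction result of [predict_chain()].
#' @return a single string over `{A-G}`.
#' @export
prediction_string <- function(prediction) {
  paste(prediction$code, collapse = "")
}

#' @export
glance.es_prediction <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_exact = sum(x$match_kind == "exact"),
    n_one_mismatch = sum(x$match_kind == "one_mismatch"),
    n_fallback = sum(x$match_kind == "fallback"),
    mean_window = if (nrow(x)) mean(x$window_length) else NA_real_
  )
}

# ---- tetrapeptide contingency baseline -------------------------------------

#' Build the tetrapeptide contingency table
#'
#' The older greatest-probability baseline: every length-4 sequence window is
#' a table row whose 7 counters count the ES codes observed at
#' `assigned_position` within the window. The sequence is padded with `'X'`
#' so that every residue is covered once at the assigned position.
#'
#' @param corpus an [es_corpus()].
#' @param assigned_position 0-based index (0-3) of the residue within the
#'   tetrapeptide that the table predicts for. Default 2 (third residue).
#' @return an object of class `es_contingency`.
#' @export
build_contingency <- function(corpus, assigned_position = 2) {
  stopifnot(assigned_position %in% 0:3)
  validate_corpus(corpus)
  if (!nrow(corpus)) stop("corpus is empty", call. = FALSE)
  left <- assigned_position
  right <- 3 - assigned_position
  code_chars <- strsplit(corpus$codes, "")
  keep <- lapply(code_chars, function(ch) ch != "X")
  centers <- unlist(lapply(code_chars, function(ch) ch[ch != "X"]))
  wins <- unlist(lapply(seq_len(nrow(corpus)), function(r) {
    n <- nchar(corpus$sequence[r])
    padded <- paste0(strrep("X", left), corpus$sequence[r], strrep("X", right))
    substring(padded, seq_len(n), seq_len(n) + 3)[keep[[r]]]
  }))
  tab <- new_counter_table(wins, centers)
  majority <- ES_CODES[which.max(colSums(tab$counts))]
  structure(
    list(table = tab, assigned_position = as.integer(assigned_position),
         majority_code = majority),
    class = "es_contingency"
  )
}

#' Predict with the tetrapeptide contingency baseline
#'
#' Per position, the tetrapeptide covering the residue at the table's
#' assigned position is retrieved and the greatest-probability (argmax
#' counter) code returned; ties go to the alphabetically earliest code. A
#' tetrapeptide never seen in training backs off to the training majority
#' code.
#'
#' @param sequence amino-acid string.
#' @param table an [build_contingency()] result.
#' @return a single code string over `{A-G}` of the same length.
#' @export
predict_contingency <- function(sequence, table) {
  stopifnot(inherits(table, "es_contingency"))
  n <- nchar(sequence)
  if (!n) return("")
  left <- table$assigned_position
  padded <- paste0(strrep("X", left), sequence,
                   strrep("X", 3 - table$assigned_position))
  wins <- substring(padded, seq_len(n), seq_len(n) + 3)
  codes <- vapply(wins, function(w) {
    row <- get0(w, envir = table$table$index, inherits = FALSE)
    if (is.null(row)) table$majority_code
    else best_class(table$table$counts[row, ])
  }, character(1), USE.NAMES = FALSE)
  paste(codes, collapse = "")
}

#' @export
print.es_contingency <- function(x, ...) {
  cat(sprintf("<es_contingency> %d tetrapeptides, assigned position %d, majority %s\n",
              nrow(x$table$counts), x$assigned_position, x$majority_code))
  invisible(x)
}
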