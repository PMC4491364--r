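#' Per-chain prediction accuracy (Q3-style, 7 classes)
#'
#' For observed codes `S_obs` and predicted codes `S_pred` of equal length,
#' the accuracy is `100 * m / n` where `m` counts positions with
#' `S_obs[i] == S_pred[i]`. Positions where the observed code is `'X'`
#' (undefined dihedral, no ground truth) are excluded from both `m` and `n`.
#'
#' @param s_obs observed code string over `{A-G, X}`.
#' @param s_pred predicted code string, same length.
#' @return accuracy as a percentage in \[0, 100\] (`NaN` if no scorable
#'   position exists).
#' @export
chain_accuracy <- function(s_obs, s_pred) {
  oc <- strsplit(s_obs, "")[[1]]
  pc <- strsplit(s_pred, "")[[1]]
  if (length(oc) != length(pc)) {
    stop("observed and predicted code strings differ in length", call. = FALSE)
  }
  keep <- oc != "X"
  100 * sum(oc[keep] == pc[keep]) / sum(keep)
}

#' Per-class prediction accuracies
#'
#' For each of the 7 codes, the accuracy over positions where the observed
#' code equals that class. A class absent from the observed string is
#' reported as 0% — the convention used by the headline tables — with
#' `absent = TRUE` retained so reports can footnote the convention.
#'
#' @inheritParams chain_accuracy
#' @return a tibble with columns `class`, `accuracy` (percent), `n_obs`,
#'   `absent`.
#' @export
class_accuracies <- function(s_obs, s_pred) {
  oc <- strsplit(s_obs, "")[[1]]
  pc <- strsplit(s_pred, "")[[1]]
  if (length(oc) != length(pc)) {
    stop("observed and predicted code strings differ in length", call. = FALSE)
  }
  keep <- oc != "X"
  oc <- oc[keep]; pc <- pc[keep]
  purrr::map_dfr(ES_CODES, function(cl) {
    sel <- oc == cl
    n <- sum(sel)
    tibble::tibble(
      class = cl,
      accuracy = if (n == 0) 0 else 100 * sum(pc[sel] == cl) / n,
      n_obs = n,
      absent = n == 0
    )
  })
}

#' Total (chain-mean) accuracy
#'
#' The aggregate accuracy over a test set is the unweighted arithmetic mean
#' of per-chain accuracies — chains contribute equally regardless of length.
#'
#' @param accuracies numeric vector of per-chain percentages.
#' @return a single percentage.
#' @export
total_accuracy <- function(accuracies) {
  mean(accuracies)
}

#' Evaluate predictions against an observed corpus
#'
#' Computes the full report: per-chain accuracies, chain-mean per-class
#' accuracies (with the 0%-if-absent convention), the per-amino-acid by class
#' table (macro-averaged over chains), overall totals, and the 3-class
#' (helix / extended / coil) confusion of the grouped codes.
#'
#' @param corpus an [es_corpus()] holding the observed codes (and optional
#'   interaction flags).
#' @param predictions character vector of predicted code strings, parallel to
#'   `corpus` rows.
#' @param exclude optional interaction category (`"ligand"`, `"protein"`,
#'   `"nucleic"`) whose flagged residues are dropped from both strings before
#'   scoring; requires corpus flags.
#' @return an object of class `es_evaluation`.
#' @export
evaluate_predictions <- function(corpus, predictions, exclude = NULL) {
  validate_corpus(corpus)
  stopifnot(length(predictions) == nrow(corpus))
  obs <- corpus$codes
  pred <- predictions
  seqs <- corpus$sequence
  if (!is.null(exclude)) {
    exclude <- match.arg(exclude, c("ligand", "protein", "nucleic"))
    letter <- c(ligand = "L", protein = "P", nucleic = "N")[[exclude]]
    if (all(is.na(corpus$flags))) {
      stop("corpus has no interaction flags; cannot compute subset evaluation",
           call. = FALSE)
    }
    masked <- purrr::pmap(list(obs, pred, seqs, corpus$flags),
                          function(o, p, s, f) {
      if (is.na(f)) return(list(o = o, p = p, s = s))
      keep <- strsplit(f, "")[[1]] != letter
      list(o = subset_string(o, keep), p = subset_string(p, keep),
           s = subset_string(s, keep))
    })
    obs <- vapply(masked, `[[`, character(1), "o")
    pred <- vapply(masked, `[[`, character(1), "p")
    seqs <- vapply(masked, `[[`, character(1), "s")
    empty <- !nzchar(obs)
    if (any(empty)) {
      warning(sprintf("%d chain(s) fully excluded from subset evaluation",
                      sum(empty)))
      obs <- obs[!empty]; pred <- pred[!empty]; seqs <- seqs[!empty]
      corpus <- corpus[!empty, , drop = FALSE]
    }
  }
  scorable <- vapply(obs, function(o) any(strsplit(o, "")[[1]] != "X"),
                     logical(1), USE.NAMES = FALSE)
  if (any(!scorable)) {
    warning(sprintf("%d chain(s) have no scorable position and are dropped",
                    sum(!scorable)))
    obs <- obs[scorable]; pred <- pred[scorable]; seqs <- seqs[scorable]
    corpus <- corpus[scorable, , drop = FALSE]
  }
  per_chain <- tibble::tibble(
    id = corpus$id,
    n = vapply(obs, function(o) sum(strsplit(o, "")[[1]] != "X"), integer(1),
               USE.NAMES = FALSE),
    m = purrr::map2_int(obs, pred, function(o, p) {
      oc <- strsplit(o, "")[[1]]; pc <- strsplit(p, "")[[1]]
      sum(oc != "X" & oc == pc)
    }),
    accuracy = purrr::map2_dbl(obs, pred, chain_accuracy)
  )
  per_class_by_chain <- purrr::map2_dfr(obs, pred, class_accuracies,
                                        .id = "chain")
  per_class <- dplyr::summarise(
    dplyr::group_by(per_class_by_chain, .data$class),
    accuracy = mean(.data$accuracy),
    n_obs = sum(.data$n_obs),
    n_chains_absent = sum(.data$absent),
    .groups = "drop"
  )
  per_residue_class <- residue_class_table(seqs, obs, pred)
  obs3 <- vapply(obs, group_es, character(1), USE.NAMES = FALSE)
  pred3 <- vapply(pred, group_es, character(1), USE.NAMES = FALSE)
  structure(
    list(
      per_chain = per_chain,
      per_class = per_class,
      per_residue_class = per_residue_class,
      totals = tibble::tibble(
        accuracy = total_accuracy(per_chain$accuracy),
        n_chains = nrow(per_chain),
        n_positions = sum(per_chain$n)
      ),
      confusion3 = confusion3(paste(obs3, collapse = ""),
                              paste(pred3, collapse = "")),
      exclude = exclude %||% "none"
    ),
    class = "es_evaluation"
  )
}

subset_string <- function(s, keep) {
  paste(strsplit(s, "")[[1]][keep], collapse = "")
}

# Per (amino acid, observed class) accuracy, computed per chain then
# macro-averaged over the chains where the pair occurs.
residue_class_table <- function(seqs, obs, pred) {
  per_chain <- purrr::pmap_dfr(list(seqs, obs, pred), function(s, o, p) {
    sc <- strsplit(s, "")[[1]]
    oc <- strsplit(o, "")[[1]]
    pc <- strsplit(p, "")[[1]]
    keep <- oc != "X" & sc %in% AA20
    if (!any(keep)) return(NULL)
    df <- tibble::tibble(residue = sc[keep], class = oc[keep],
                         hit = oc[keep] == pc[keep])
    dplyr::summarise(dplyr::group_by(df, .data$residue, .data$class),
                     accuracy = 100 * mean(.data$hit), n = dplyr::n(),
                     .groups = "drop")
  })
  if (!nrow(per_chain)) {
    return(tibble::tibble(residue = character(), class = character(),
                          accuracy = numeric(), n_chains = integer(),
                          n_positions = integer()))
  }
  dplyr::summarise(
    dplyr::group_by(per_chain, .data$residue, .data$class),
    n_chains = dplyr::n(),
    n_positions = sum(.data$n),
    accuracy = mean(.data$accuracy),
    .groups = "drop"
  )
}

#' Group ES codes into helix / extended / coil
#'
#' `C` is helical (`H`), `E` and `F` extended (`E`), and the remaining four
#' codes (`A`, `B`, `D`, `G`) form the third group (`C`). `'X'` passes
#' through unchanged.
#'
#' @param codes an ES code string.
#' @return a 3-class string over `{H, E, C, X}`.
#' @export
group_es <- function(codes) {
  chartr("CEFABDGX", "HEECCCCX", codes)
}

#' Group DSSP classes into helix / extended / coil
#'
#' Helical: `H` (alpha-helix), `G` (3-10 helix), `I` (pi-helix); extended:
#' `B` (beta bridge), `E` (strand); everything else — `T` (turn), `S`
#' (bend), space / unclassified — is coil.
#'
#' @param dssp a per-residue DSSP class string.
#' @return a 3-class string over `{H, E, C}`.
#' @export
group_dssp <- function(dssp) {
  ch <- strsplit(dssp, "")[[1]]
  out <- rep("C", length(ch))
  out[ch %in% c("H", "G", "I")] <- "H"
  out[ch %in% c("B", "E")] <- "E"
  paste(out, collapse = "")
}

#' Three-class confusion table with row percentages
#'
#' Rows are observed classes, columns predicted classes; each row is
#' normalized to percentages of the row total. Positions where either string
#' carries `'X'` are skipped; classes never observed are dropped from the
#' rows (an empty row has no percentage).
#'
#' @param obs3,pred3 equal-length 3-class strings over `{H, E, C, X}`.
#' @return a tibble with columns `observed`, `H`, `E`, `C` and `n` (row
#'   totals).
#' @export
confusion3 <- function(obs3, pred3) {
  oc <- strsplit(obs3, "")[[1]]
  pc <- strsplit(pred3, "")[[1]]
  if (length(oc) != length(pc)) {
    stop("observed and predicted 3-class strings differ in length",
         call. = FALSE)
  }
  keep <- oc %in% c("H", "E", "C") & pc %in% c("H", "E", "C")
  oc <- oc[keep]; pc <- pc[keep]
  purrr::map_dfr(c("H", "E", "C"), function(cl) {
    sel <- oc == cl
    n <- sum(sel)
    if (n == 0) return(NULL)
    tibble::tibble(
      observed = cl,
      H = 100 * sum(pc[sel] == "H") / n,
      E = 100 * sum(pc[sel] == "E") / n,
      C = 100 * sum(pc[sel] == "C") / n,
      n = n
    )
  })
}

#' @export
print.es_evaluation <- function(x, ...) {
  cat(sprintf("<es_evaluation> %d chains, %d positions, exclusion: %s\n",
              x$totals$n_chains, x$totals$n_positions, x$exclude))
  cat(sprintf("total accuracy (chain mean): %.2f%%\n", x$totals$accuracy))
  cat("per-class accuracy (chain mean, 0% if absent):\n")
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.es_evaluation <- function(x, ...) {
  x$per_chain
}

#' @export
glance.es_evaluation <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$per_class[, c("class", "accuracy")],
                             names_from = "class", values_from = "accuracy",
                             names_prefix = "acc_")
  dplyr::bind_cols(x$totals, wide, tibble::tibble(exclude = x$exclude))
}

#' Write an evaluation report as TSV plus a readable text summary
#'
#' @param evaluation an [evaluate_predictions()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_evaluation <- function(evaluation, dir, prefix = "evaluation") {
  stopifnot(inherits(evaluation, "es_evaluation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
    df
  }
  paths <- c(
    per_chain = file.path(dir, paste0(prefix, "_per_chain.tsv")),
    per_class = file.path(dir, paste0(prefix, "_per_class.tsv")),
    per_residue = file.path(dir, paste0(prefix, "_per_residue_class.tsv")),
    confusion3 = file.path(dir, paste0(prefix, "_confusion3.tsv")),
    summary = file.path(dir, paste0(prefix, "_summary.txt"))
  )
  write_tsv_atomic <- function(df, path) {
    df <- fmt(as.data.frame(df))
    lines <- c(paste(names(df), collapse = "\t"),
               do.call(paste, c(unname(df), sep = "\t")))
    if (!nrow(df)) lines <- lines[1]
    write_atomically(lines, path)
  }
  write_tsv_atomic(evaluation$per_chain, paths[["per_chain"]])
  write_tsv_atomic(evaluation$per_class, paths[["per_class"]])
  write_tsv_atomic(evaluation$per_residue_class, paths[["per_residue"]])
  write_tsv_atomic(evaluation$confusion3, paths[["confusion3"]])
  summary_lines <- utils::capture.output(print(evaluation))
  write_atomically(summary_lines, paths[["summary"]])
  invisible(paths)
}

#' Plot per-class accuracies of an evaluation
#'
#' @param object an [evaluate_predictions()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.es_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$per_class,
                  ggplot2::aes(x = .data$class, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$totals$accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "ES structural code", y = "accuracy (%)",
                  title = "Per-class prediction accuracy (chain mean)",
                  subtitle = sprintf("total accuracy %.2f%% (dashed)",
                                     object$totals$accuracy)) +
    ggplot2::theme_minimal()
}
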