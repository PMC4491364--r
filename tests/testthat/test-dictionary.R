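test_that("the smallest corpus builds the expected subdictionaries", {
  d <- build_dictionary(es_corpus("c1", "A", "C"), l_max = 3)
  expect_equal(lookup_exact(d, 1, "A"),
               setNames(c(0L, 0L, 1L, 0L, 0L, 0L, 0L), LETTERS[1:7]))
  expect_equal(unname(lookup_exact(d, 3, "XAX")[["C"]]), 1L)
  expect_null(lookup_exact(d, 3, "AAA"))
  expect_equal(d$meta$majority_code, "C")
})

test_that("every chain of length n contributes n windows to every subdictionary", {
  corp <- gen_corpus(8, c(3, 25), mapping_width = 3, noise_rate = 0, seed = 41)
  d <- build_dictionary(corp, l_max = 13)
  total <- sum(nchar(corp$sequence))
  for (i in names(d$subdicts)) {
    expect_equal(sum(d$subdicts[[i]]$counts), total)
  }
  # padding for window length 13 is floor(13/2) = 6 'X' per side
  first_key <- rownames(d$subdicts[["13"]]$counts)
  expect_true(any(startsWith(first_key, strrep("X", 6))))
  expect_false(any(startsWith(first_key, strrep("X", 7))))
})

test_that("centers with undefined codes are skipped but remain context", {
  corp <- es_corpus("c1", "ARN", "CXE")
  d <- build_dictionary(corp, l_max = 3)
  # only 2 counted centers
  expect_equal(sum(d$subdicts[["1"]]$counts), 2)
  expect_equal(sum(d$subdicts[["3"]]$counts), 2)
  # but the skipped center's letter appears inside its neighbours' windows
  expect_equal(unname(lookup_exact(d, 3, "XAR")[["C"]]), 1L)
  expect_equal(unname(lookup_exact(d, 3, "RNX")[["E"]]), 1L)
  expect_null(lookup_exact(d, 3, "ARN"))
  expect_equal(d$meta$n_centers, 2)
})

test_that("counter totals match a brute-force window enumeration", {
  corp <- gen_corpus(30, c(2, 30), mapping_width = 5, noise_rate = 0.3,
                     seed = 42)
  # blank out some codes to exercise the skip rule
  corp$codes <- vapply(corp$codes, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[seq_along(ch) %% 7 == 0] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  d <- build_dictionary(corp, l_max = 7)
  for (i in c(1, 3, 5, 7)) {
    # naive enumeration oracle
    oracle <- list()
    for (r in seq_len(nrow(corp))) {
      h <- (i - 1) / 2
      padded <- paste0(strrep("X", h), corp$sequence[r], strrep("X", h))
      codes <- strsplit(corp$codes[r], "")[[1]]
      for (k in seq_len(nchar(corp$sequence[r]))) {
        if (codes[k] == "X") next
        w <- substr(padded, k, k + i - 1)
        if (is.null(oracle[[w]])) {
          oracle[[w]] <- setNames(rep(0L, 7), LETTERS[1:7])
        }
        oracle[[w]][codes[k]] <- oracle[[w]][codes[k]] + 1L
      }
    }
    counts <- d$subdicts[[as.character(i)]]$counts
    expect_setequal(rownames(counts), names(oracle))
    for (w in names(oracle)) {
      expect_equal(counts[w, ], oracle[[w]])
    }
  }
})

test_that("best_class is the argmax with alphabetical tie-break", {
  expect_equal(best_class(c(A = 0, B = 0, C = 5, D = 0, E = 2, F = 0, G = 0)),
               "C")
  expect_equal(best_class(c(A = 3, B = 3, C = 0, D = 0, E = 0, F = 0, G = 0)),
               "A")
  withr::with_seed(43, {
    for (rep in 1:200) {
      v <- setNames(sample(0:4, 7, replace = TRUE), LETTERS[1:7])
      # linear-scan oracle
      best <- names(v)[v == max(v)][1]
      expect_equal(best_class(v), best)
    }
  })
})

test_that("exact lookup agrees with a linear scan", {
  corp <- gen_corpus(10, 20, mapping_width = 3, noise_rate = 0, seed = 44)
  d <- build_dictionary(corp, l_max = 5)
  counts <- d$subdicts[["5"]]$counts
  keys <- rownames(counts)
  withr::with_seed(45, {
    queries <- c(sample(keys, 50, replace = TRUE),
                 vapply(1:50, function(i) {
                   paste(sample(c(LETTERS[1:20], "X"), 5, TRUE), collapse = "")
                 }, character(1)))
  })
  for (q in queries) {
    got <- lookup_exact(d, 5, q)
    row <- which(keys == q)
    if (length(row)) expect_equal(got, counts[row, ]) else expect_null(got)
  }
})

test_that("one-mismatch lookup sums counters over all Hamming-1 hits", {
  d <- build_dictionary(es_corpus(c("c1", "c2"), c("AAA", "AAA"),
                                  c("ACA", "ACA")), l_max = 3)
  agg <- lookup_one_mismatch(d, 3, "ABA")
  expect_equal(unname(agg[["C"]]), 2)
  expect_null(lookup_one_mismatch(d, 3, "BBB"))

  # exhaustive Hamming oracle on random small dictionaries
  withr::with_seed(46, {
    for (rep in 1:10) {
      corp <- gen_corpus(3, 8, mapping_width = 1, noise_rate = 0.5,
                         seed = rep * 7 + 1,
                         alphabet_bias = c(A = 1, R = 1, N = 1))
      d <- build_dictionary(corp, l_max = 3)
      counts <- d$subdicts[["3"]]$counts
      for (q in 1:20) {
        key <- paste(sample(c("A", "R", "N", "D", "X"), 3, TRUE),
                     collapse = "")
        if (!is.null(lookup_exact(d, 3, key))) next
        got <- lookup_one_mismatch(d, 3, key)
        near <- vapply(rownames(counts), function(k) {
          sum(strsplit(k, "")[[1]] != strsplit(key, "")[[1]]) == 1
        }, logical(1))
        if (!any(near)) {
          expect_null(got)
        } else {
          expect_equal(got, colSums(counts[near, , drop = FALSE]))
        }
      }
    }
  })
})

test_that("dictionaries serialize deterministically and round-trip losslessly", {
  corp <- gen_corpus(12, c(4, 20), mapping_width = 3, noise_rate = 0.1,
                     seed = 47)
  d <- build_dictionary(corp, l_max = 5)
  f <- withr::local_tempfile()
  save_dictionary(d, f)
  d2 <- load_dictionary(f)
  expect_equal(d2$l_max, d$l_max)
  expect_equal(d2$meta, d$meta)
  for (i in names(d$subdicts)) {
    expect_identical(d2$subdicts[[i]]$counts, d$subdicts[[i]]$counts)
  }
  # byte-identical regardless of corpus record order
  withr::with_seed(48, perm <- sample(nrow(corp)))
  d3 <- build_dictionary(corp[perm, ], l_max = 5)
  f3 <- withr::local_tempfile()
  save_dictionary(d3, f3)
  expect_identical(readLines(f3), readLines(f))

  # saving after a load reproduces the same bytes
  f4 <- withr::local_tempfile()
  save_dictionary(d2, f4)
  expect_identical(readLines(f4), readLines(f))

  bad <- withr::local_tempfile()
  writeLines("#not-a-dict", bad)
  expect_error(load_dictionary(bad), "header")
})

test_that("degenerate builds and saves are rejected with clear errors", {
  corp <- es_corpus("c1", "ARN", "CCE")
  expect_error(build_dictionary(corp, l_max = 4), "odd")
  expect_error(build_dictionary(corp, l_max = 27), "<= 25")
  expect_error(build_dictionary(corp[0, ], l_max = 3), "empty")
  expect_error(es_corpus("badrec", "ARN", "CZE"), "badrec")
  # all centers undefined -> D_i exist but are empty -> save refuses
  empty <- build_dictionary(es_corpus("c1", "ARN", "XXX"), l_max = 3)
  expect_error(save_dictionary(empty, withr::local_tempfile()), "empty")
})

test_that("tidy and glance views are consistent with the build", {
  corp <- gen_corpus(5, 10, mapping_width = 1, noise_rate = 0, seed = 49)
  d <- build_dictionary(corp, l_max = 3)
  td <- tidy(d)
  expect_equal(sum(td[LETTERS[1:7]]), 2 * 50)
  g <- glance(d)
  expect_equal(g$n_keys, nrow(td))
  expect_equal(g$n_residues, 50)
})
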