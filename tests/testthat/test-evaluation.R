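random_codes <- function(n, with_x = FALSE) {
  pool <- c(LETTERS[1:7], if (with_x) "X")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

test_that("chain accuracy is m/n excluding undefined observed positions", {
  expect_equal(chain_accuracy("CCCC", "CCCC"), 100)
  expect_equal(chain_accuracy("CCCC", "EEEE"), 0)
  expect_equal(chain_accuracy("XCE", "ACE"), 100)   # X excluded from n
  expect_error(chain_accuracy("CC", "C"), "length")
  withr::with_seed(61, {
    for (rep in 1:100) {
      n <- sample(1:30, 1)
      obs <- random_codes(n, with_x = TRUE)
      pred <- random_codes(n)
      oc <- strsplit(obs, "")[[1]]
      pc <- strsplit(pred, "")[[1]]
      m <- 0; nn <- 0
      for (i in seq_len(n)) {
        if (oc[i] == "X") next
        nn <- nn + 1
        if (oc[i] == pc[i]) m <- m + 1
      }
      if (nn == 0) next
      expect_equal(chain_accuracy(obs, pred), 100 * m / nn)
    }
  })
})

test_that("class accuracies use the 0%-if-absent convention with a marker", {
  ca <- class_accuracies("CC", "CC")
  expect_equal(ca$accuracy[ca$class == "C"], 100)
  expect_true(all(ca$accuracy[ca$class != "C"] == 0))
  expect_true(all(ca$absent[ca$class != "C"]))
  expect_false(ca$absent[ca$class == "C"])

  ca2 <- class_accuracies("CE", "CC")
  expect_equal(ca2$accuracy[ca2$class == "C"], 100)
  expect_equal(ca2$accuracy[ca2$class == "E"], 0)
  expect_false(ca2$absent[ca2$class == "E"])

  withr::with_seed(62, {
    for (rep in 1:50) {
      n <- sample(1:40, 1)
      obs <- random_codes(n, with_x = TRUE)
      pred <- random_codes(n)
      got <- class_accuracies(obs, pred)
      oc <- strsplit(obs, "")[[1]]
      pc <- strsplit(pred, "")[[1]]
      for (cl in LETTERS[1:7]) {
        sel <- oc == cl
        want <- if (!any(sel)) 0 else 100 * mean(pc[sel] == cl)
        expect_equal(got$accuracy[got$class == cl], want)
      }
    }
  })
})

test_that("the total is the unweighted chain mean", {
  expect_equal(total_accuracy(c(100, 0)), 50)
  expect_equal(total_accuracy(73.25), 73.25)
  # chain-mean, not residue-mean: a long bad chain counts once
  obs <- c("CC", strrep("E", 100))
  pred <- c("CC", strrep("A", 100))
  accs <- mapply(chain_accuracy, obs, pred)
  expect_equal(total_accuracy(accs), 50)
  # total of k identical chains equals the single-chain accuracy
  expect_equal(total_accuracy(rep(62.5, 9)), 62.5)
})

test_that("3-class groupings are total letter-wise maps", {
  expect_equal(group_es("CEF"), "HEE")
  expect_equal(group_es("ABDG"), "CCCC")
  expect_equal(group_es("CEFABDGX"), "HEECCCCX")
  expect_equal(group_dssp("HGI"), "HHH")
  expect_equal(group_dssp(" TS"), "CCC")
  # exhaustive over the DSSP alphabet vs a lookup oracle
  lookup <- c(H = "H", G = "H", I = "H", B = "E", E = "E",
              T = "C", S = "C", " " = "C", "-" = "C")
  for (ch in names(lookup)) {
    expect_equal(group_dssp(ch), unname(lookup[ch]))
  }
  # letter-wise: grouping a concatenation equals concatenating groupings
  withr::with_seed(63, s <- random_codes(50, with_x = TRUE))
  expect_equal(group_es(s),
               paste(vapply(strsplit(s, "")[[1]], group_es, character(1)),
                     collapse = ""))
})

test_that("confusion3 rows are percentages of the observed class", {
  perfect <- confusion3("HEC", "HEC")
  expect_equal(perfect$H, c(100, 0, 0))
  expect_equal(perfect$n, c(1, 1, 1))
  allwrong <- confusion3("HHHH", "CCCC")
  expect_equal(nrow(allwrong), 1)
  expect_equal(unlist(allwrong[1, c("H", "E", "C")], use.names = FALSE),
               c(0, 0, 100))
  withr::with_seed(64, {
    for (rep in 1:20) {
      n <- sample(5:60, 1)
      obs <- paste(sample(c("H", "E", "C"), n, TRUE), collapse = "")
      pred <- paste(sample(c("H", "E", "C"), n, TRUE), collapse = "")
      got <- confusion3(obs, pred)
      # brute-force tally
      oc <- strsplit(obs, "")[[1]]; pc <- strsplit(pred, "")[[1]]
      for (r in seq_len(nrow(got))) {
        cl <- got$observed[r]
        sel <- oc == cl
        for (col in c("H", "E", "C")) {
          expect_equal(got[[col]][r], 100 * sum(pc[sel] == col) / sum(sel))
        }
      }
      # nonempty rows sum to 100
      expect_true(all(abs(rowSums(got[, c("H", "E", "C")]) - 100) < 0.1))
    }
  })
})

test_that("full evaluation aggregates per-chain, per-class and confusion", {
  corp <- gen_corpus(8, c(10, 30), mapping_width = 1, noise_rate = 0.4,
                     seed = 65, keep_truth = TRUE)
  ev <- evaluate_predictions(corp, corp$codes_true)
  expect_equal(nrow(ev$per_chain), 8)
  expect_equal(ev$totals$accuracy, mean(ev$per_chain$accuracy))
  expect_equal(ev$per_chain$accuracy,
               unname(mapply(chain_accuracy, corp$codes, corp$codes_true)))
  expect_true(all(ev$per_class$accuracy >= 0 & ev$per_class$accuracy <= 100))
  expect_true(all(abs(rowSums(ev$confusion3[, c("H", "E", "C")]) - 100) < 0.1))
  # glance/tidy surface the same numbers
  expect_equal(glance(ev)$accuracy, ev$totals$accuracy)
  expect_equal(tidy(ev), ev$per_chain)
})

test_that("subset evaluation drops flagged residues and nothing else", {
  corp <- gen_corpus(6, 20, mapping_width = 1, noise_rate = 0.3, seed = 66,
                     keep_truth = TRUE)
  # no flags: subset must equal full evaluation bit-exactly
  corp$flags <- strrep("-", nchar(corp$sequence))
  full <- evaluate_predictions(corp, corp$codes_true)
  sub <- evaluate_predictions(corp, corp$codes_true, exclude = "ligand")
  expect_equal(sub$per_chain$accuracy, full$per_chain$accuracy)
  expect_equal(sub$totals$accuracy, full$totals$accuracy)

  # random masks vs a recount oracle
  withr::with_seed(67, {
    corp$flags <- vapply(nchar(corp$sequence), function(n) {
      paste(sample(c("L", "P", "N", "-"), n, TRUE, prob = c(2, 1, 1, 4)),
            collapse = "")
    }, character(1))
  })
  sub_l <- evaluate_predictions(corp, corp$codes_true, exclude = "ligand")
  for (r in seq_len(nrow(corp))) {
    keep <- strsplit(corp$flags[r], "")[[1]] != "L"
    o <- paste(strsplit(corp$codes[r], "")[[1]][keep], collapse = "")
    p <- paste(strsplit(corp$codes_true[r], "")[[1]][keep], collapse = "")
    expect_equal(sub_l$per_chain$accuracy[r], chain_accuracy(o, p))
    expect_equal(sub_l$per_chain$n[r], sum(keep))
  }

  # a fully flagged chain is excluded with a warning
  corp2 <- corp
  corp2$flags[1] <- strrep("L", nchar(corp2$sequence[1]))
  expect_warning(
    ev2 <- evaluate_predictions(corp2, corp2$codes_true, exclude = "ligand"),
    "excluded")
  expect_equal(nrow(ev2$per_chain), 5)
  expect_error(
    evaluate_predictions(dplyr::mutate(corp, flags = NA_character_),
                         corp$codes_true, exclude = "ligand"),
    "no interaction flags")
})

test_that("evaluation reports are written as TSV plus summary", {
  corp <- gen_corpus(4, 15, mapping_width = 1, noise_rate = 0.2, seed = 68,
                     keep_truth = TRUE)
  ev <- evaluate_predictions(corp, corp$codes_true)
  dir <- withr::local_tempdir()
  paths <- write_evaluation(ev, dir)
  expect_true(all(file.exists(paths)))
  per_chain <- read.delim(paths[["per_chain"]])
  expect_equal(nrow(per_chain), 4)
  # percentages are printed to 2 decimals
  expect_equal(per_chain$accuracy, round(ev$per_chain$accuracy, 2))
})
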