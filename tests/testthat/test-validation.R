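test_that("indices match the printed validation table at 0.01", {
  tab <- recompute_table(printed_validation_table())
  expect_true(all(abs(tab$HRA - tab$HRA_printed) <= 0.01))
  expect_true(all(abs(tab$IEI - tab$IEI_printed) <= 0.01))
  # the first row's printed CAI is internally inconsistent with the formula
  # (2.12 printed vs 2.13 recomputed); all other rows agree
  expect_true(all(abs(tab$CAI[-1] - tab$CAI_printed[-1]) <= 0.01))
  expect_equal(round(tab$CAI[1], 2), 2.13)
})

test_that("index identities hold", {
  s <- validation_from_counts(10, 10, 5, 5)  # Ha = Ht, A = D
  expect_equal(s$IEI, 1)
  s2 <- validation_from_counts(10, 5, 5, 5)
  expect_equal(s2$HRA, 100)
  expect_equal(s2$IEI, 2)
  expect_true(all(validation_from_counts(20, 5, 3, 8)$CAI <=
    validation_from_counts(20, 5, 3, 8)$IEI))
})

test_that("evaluate_model counts via set intersection match a brute force", {
  set.seed(14)
  for (rep in 1:20) {
    D <- sample(20:200, 1)
    A <- sample(1:D, 1)
    Ht <- sample(0:D, 1)
    ids <- sprintf("c%03d", 1:D)
    labels <- tibble::tibble(
      id = ids, label = sample(rep(c("active", "inactive"), c(A, D - A)))
    )
    hits <- sample(ids, Ht)
    s <- evaluate_model(labels, hits)
    ha_brute <- length(intersect(hits, labels$id[labels$label == "active"]))
    expect_equal(s$Ha, ha_brute)
    expect_equal(
      unname(c(s$HRA, s$IEI, s$CAI)),
      unname(oracle_indices(D, A, ha_brute, Ht)),
      tolerance = 1e-12
    )
  }
})

test_that("degenerate and invalid inputs are handled", {
  labels <- tibble::tibble(id = c("a", "b"), label = c("active", "inactive"))
  s <- evaluate_model(labels, character(0))
  expect_true(s$undefined)
  expect_true(is.na(s$IEI) && is.na(s$CAI))
  expect_error(evaluate_model(labels, "zz"), "not in the labeled set")
  expect_error(validation_from_counts(10, 5, 6, 6), "infeasible")
  expect_error(
    evaluate_model(tibble::tibble(id = "a", label = "inactive"), character(0)),
    "no active"
  )
})

test_that("recompute_table equals the scalar computation row-wise", {
  set.seed(8)
  rows <- tibble::tibble(
    D = sample(50:500, 10), A = NA, Ha = NA, Ht = NA
  )
  rows$A <- vapply(rows$D, function(d) sample(1:d, 1), 0L)
  rows$Ht <- vapply(rows$D, function(d) sample(0:d, 1), 0L)
  rows$Ha <- purrr::map2_int(rows$A, rows$Ht, ~ sample(0:min(.x, .y), 1))
  rows <- rows[(rows$Ht - rows$Ha) <= (rows$D - rows$A), ]
  tab <- recompute_table(rows)
  for (i in seq_len(nrow(tab))) {
    expect_equal(
      unname(c(tab$HRA[i], tab$IEI[i], tab$CAI[i])),
      unname(oracle_indices(rows$D[i], rows$A[i], rows$Ha[i], rows$Ht[i]))
    )
  }
  dup <- recompute_table(rows[rep(1, 10), ])
  expect_equal(nrow(dplyr::distinct(dup)), 1)
})

test_that("hypothesis selection prefers rank score among qualifiers", {
  tab <- recompute_table(printed_validation_table())
  idx <- select_best(tab, thresholds = c(HRA = 80, IEI = 2, CAI = 2))
  expect_equal(as.integer(idx), 1L)  # highest rank score among qualifiers
  expect_true(attr(idx, "meets_thresholds"))

  one <- tab[3, ]
  expect_warning(i1 <- select_best(one), "falling back")
  expect_equal(as.integer(i1), 1L)

  two <- tab[c(7, 6), ]  # only the second meets all thresholds
  two$rank_score <- c(999, 1)
  idx2 <- select_best(two)
  expect_equal(as.integer(idx2), 2L)
  expect_error(select_best(tab[0, ]), "no hypotheses")
})

test_that("random hits are calibrated at IEI = 1", {
  set.seed(101)
  D <- 616; A <- 154; Ht <- 256
  n_draws <- 2000
  ids <- sprintf("c%04d", 1:D)
  labels <- tibble::tibble(
    id = ids, label = rep(c("active", "inactive"), c(A, D - A))
  )
  # draw a few hit sets through the full evaluate_model path...
  iei_full <- replicate(50, evaluate_model(labels, sample(ids, Ht))$IEI)
  # ...and many via the count path with hypergeometric active-hit counts
  ha <- rhyper(n_draws, A, D - A, Ht)
  iei <- validation_from_counts(D, A, ha, Ht)$IEI
  se <- sd(iei) / sqrt(n_draws)
  expect_lt(abs(mean(iei) - 1), 3 * se)
  expect_lt(abs(mean(iei_full) - 1), 3 * sd(iei_full) / sqrt(50) + 3 * se)
})
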