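test_that("MCC matches an independent correlation-based oracle", {
  expect_equal(as.numeric(mcc(confusion_counts(5, 0, 5, 0))), 1)
  expect_equal(as.numeric(mcc(confusion_counts(0, 5, 0, 5))), -1)
  und <- mcc(confusion_counts(3, 0, 0, 0))
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))

  # oracle: MCC equals the Pearson correlation of the binary label vectors
  oracle <- function(TP, FP, TN, FN) {
    truth <- c(rep(1, TP), rep(0, FP), rep(0, TN), rep(1, FN))
    pred <- c(rep(1, TP), rep(1, FP), rep(0, TN), rep(0, FN))
    suppressWarnings(stats::cor(truth, pred))
  }
  set.seed(5150)
  for (i in 1:40) {
    cts <- sample(0:20, 4, replace = TRUE)
    got <- as.numeric(mcc(confusion_counts(cts[1], cts[2], cts[3], cts[4])))
    want <- oracle(cts[1], cts[2], cts[3], cts[4])
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }

  # symmetry under consistent class swap
  cm <- confusion_counts(12, 7, 9, 4)
  swapped <- confusion_counts(9, 4, 12, 7)
  expect_equal(as.numeric(mcc(cm)), as.numeric(mcc(swapped)))
})

test_that("per-class metrics follow the standard definitions and identities", {
  cm <- confusion_counts(12, 7, 9, 4)
  m <- classification_metrics(cm)
  expect_equal(unname(m$sensitivity["class1"]), 12 / 16)
  expect_equal(unname(m$specificity["class1"]), 9 / 16)
  expect_equal(unname(m$precision["class1"]), 12 / 19)
  expect_equal(m$accuracy, 21 / 32)
  # class 0 swaps the roles
  expect_equal(unname(m$sensitivity["class0"]),
               unname(m$specificity["class1"]))
  # F1 harmonic-mean identity
  p <- unname(m$precision["class1"]); r <- unname(m$sensitivity["class1"])
  expect_equal(unname(m$f1["class1"]), 2 * p * r / (p + r))
  perfect <- classification_metrics(confusion_counts(8, 0, 8, 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(unname(unlist(perfect[c("accuracy")])), 1)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity",
                                   "precision", "f1")]) == 1))
})

test_that("labels derive from confusion matrices and MS grades consistently", {
  truth <- c("neutral", "neutral", "destabilizing", "destabilizing",
             "neutral")
  pred <- c("neutral", "destabilizing", "destabilizing", "neutral",
            "neutral")
  cm <- confusion_matrix(truth, pred)
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 1L, TN = 1L, FN = 1L))
  expect_error(confusion_matrix(truth, c(pred[-1], "maybe")), "labels")
  expect_equal(ms_to_label(c(2, 3, 2, 9)),
               c("neutral", "destabilizing", "neutral", "destabilizing"))
  expect_error(ms_to_label(1), "start at 2")
})

test_that("Spearman rho matches exact cases and the midrank oracle under ties", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  und <- spearman_rho(c(1, 1, 1), 1:3)
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
  set.seed(606)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties, like MS grades
    y <- x + rnorm(n, sd = 1.5)
    if (length(unique(x)) == 1L) next
    expect_equal(spearman_rho(x, y),
                 suppressWarnings(stats::cor(x, y, method = "spearman")))
  }
})

test_that("grid search scans the full grid and recovers planted weights", {
  # training-set-scale sample: with fewer mutations, alternative separators
  # on the coarse grid can tie the planted one
  lm <- make_labeled_mutations(n = 2000, seed = 17)
  fit <- grid_search_weights(lm$features, lm$truth)
  expect_equal(unname(fit$grid_dim), c(13L, 13L, 13L, 21L))
  expect_equal(fit$mcc, 1)  # separable by construction
  expect_lte(abs(fit$weights$w_s - 1.5), 0.25 + 1e-9)
  expect_lte(abs(fit$weights$w_h - 1.75), 0.25 + 1e-9)
  expect_lte(abs(fit$weights$w_f - 0.5), 0.25 + 1e-9)
  expect_lte(abs(fit$weights$threshold - 1.6), 0.1 + 1e-9)

  # surface export covers every grid point
  fit2 <- grid_search_weights(lm$features[1:80, ], lm$truth[1:80],
                              return_surface = TRUE)
  expect_equal(nrow(fit2$surface), 13^3 * 21)
  expect_equal(max(fit2$surface$mcc, na.rm = TRUE), fit2$mcc)
  expect_error(grid_search_weights(lm$features, rep("neutral", 600)),
               "each class")
})

test_that("stratified accuracy partitions the data set", {
  truth <- rep(c("neutral", "destabilizing"), each = 4)
  pred <- truth
  zone <- rep(c("exposed", "buried"), 4)
  tab <- stratified_accuracy(truth, pred, zone)
  expect_true(all(tab$accuracy == 1))
  pred2 <- pred
  pred2[zone == "buried"][1:2] <- rev(truth[zone == "buried"][1:2])
  # make exactly 2 of 4 buried calls wrong
  pred2[zone == "buried"] <- ifelse(seq_len(4) <= 2,
                                    ifelse(truth[zone == "buried"] == "neutral",
                                           "destabilizing", "neutral"),
                                    truth[zone == "buried"])
  tab2 <- stratified_accuracy(truth, pred2, zone)
  expect_equal(tab2$accuracy[tab2$category == "buried"], 0.5)
  expect_equal(sum(tab2$n), length(truth))
})

test_that("meta selection routes categories to the best method with MCC tie-break", {
  set.seed(707)
  n <- 240
  truth <- sample(c("neutral", "destabilizing"), n, replace = TRUE)
  zone <- sample(c("exposed", "intermediate", "buried"), n, replace = TRUE)
  flip <- function(lab) ifelse(lab == "neutral", "destabilizing", "neutral")

  # method A perfect on exposed, random elsewhere; B the complement
  noisy <- function(lab, idx, rate = 0.45) {
    out <- lab
    wrong <- idx & (runif(n) < rate)
    out[wrong] <- flip(lab[wrong])
    out
  }
  A <- truth; A[zone != "exposed"] <- noisy(truth, zone != "exposed")[zone != "exposed"]
  B <- truth; B[zone == "exposed"] <- noisy(truth, zone == "exposed")[zone == "exposed"]
  res <- meta_select(truth, data.frame(A = A, B = B,
                                       stringsAsFactors = FALSE), zone)
  expect_equal(res$meta_pred, truth)  # complementary fixture: meta perfect
  expect_equal(res$mcc, 1)
  expect_gt(res$mcc, max(res$method_mcc))
  expect_equal(res$selection$method[res$selection$category == "exposed"], "A")

  # one method strictly better everywhere: meta equals it
  C <- noisy(truth, rep(TRUE, n), rate = 0.3)
  res2 <- meta_select(truth, data.frame(A = truth, C = C,
                                        stringsAsFactors = FALSE), zone)
  expect_equal(res2$meta_pred, truth)
  expect_true(all(res2$selection$method == "A"))

  # tie within a category resolves toward the higher overall MCC
  cat2 <- rep(c("g1", "g2"), each = n / 2)
  M1 <- truth; M2 <- truth
  # identical (perfect) on g1 -> tie there; M1 better overall on g2
  M2[cat2 == "g2"] <- noisy(truth, cat2 == "g2", 0.5)[cat2 == "g2"]
  res3 <- meta_select(truth, data.frame(M1 = M1, M2 = M2,
                                        stringsAsFactors = FALSE), cat2)
  expect_true(res3$selection$tie[res3$selection$category == "g1"])
  expect_equal(res3$selection$method[res3$selection$category == "g1"], "M1")
})
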