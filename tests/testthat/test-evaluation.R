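test_that("ground-truth labels partition genes by interval-test significance", {
  ga <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   p_adjusted = c(1e-9, 0.8, 0.9, NA))
  la <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   p_adjusted = c(0.99, 1e-4, 0.5, NA))
  gt <- build_ground_truth(ga, la, fdr = 0.05)
  expect_equal(gt$positives, "g1")
  expect_equal(gt$negatives, "g2")
  expect_setequal(gt$unlabeled, c("g3", "g4"))
})

test_that("ROC and PR are exact for perfect separation and prevalence baseline", {
  labels <- list(positives = paste0("p", 1:20), negatives = paste0("n", 1:80))
  scores <- setNames(c(rep(1, 20), rep(0, 80)),
                     c(labels$positives, labels$negatives))
  r <- roc_pr_curves(labels, scores)
  expect_equal(r$roc_auc, 1)
  expect_equal(r$pr_auc, 1)
  expect_equal(r$prevalence, 0.2)
  expect_error(roc_pr_curves(list(positives = character(0),
                                  negatives = "n1"),
                             c(n1 = 1)), "positive")
})

test_that("label-independent scores give chance-level ROC", {
  set.seed(81)
  n <- 10000
  labels <- list(positives = paste0("g", 1:(n / 2)),
                 negatives = paste0("g", (n / 2 + 1):n))
  scores <- setNames(rnorm(n), paste0("g", 1:n))
  r <- roc_pr_curves(labels, scores)
  expect_gt(r$roc_auc, 0.47)
  expect_lt(r$roc_auc, 0.53)
})

test_that("ROC AUC matches an established implementation and monotone invariance", {
  skip_if_not_installed("pROC")
  set.seed(82)
  labels <- list(positives = paste0("p", 1:50), negatives = paste0("n", 1:150))
  sc <- setNames(c(rnorm(50, 1), rnorm(150)),
                 c(labels$positives, labels$negatives))
  r <- roc_pr_curves(labels, sc)
  ref <- pROC::roc(response = c(rep(1, 50), rep(0, 150)), predictor = sc,
                   quiet = TRUE)
  expect_equal(r$roc_auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  r2 <- roc_pr_curves(labels, exp(sc))    # strictly monotone transform
  expect_equal(r2$roc_auc, r$roc_auc, tolerance = 1e-12)
  # adjusted p-values as scores: smaller = positive
  r3 <- roc_pr_curves(labels, setNames(rank(-sc) / 200, names(sc)),
                      smaller_is_positive = TRUE)
  expect_equal(r3$roc_auc, r$roc_auc, tolerance = 1e-12)
})

test_that("sliding windows count T - 3 comparisons for daily designs", {
  for (T in 4:8) {
    set.seed(90 + T)
    tt <- rep(0:(T - 1), each = 2)
    vals <- matrix(rnbinom(30 * length(tt), size = 20, mu = 100),
                   30, length(tt),
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("s%02d", seq_along(tt))))
    res <- sliding_window_de(vals, times = tt)
    expect_length(res, T - 3)
  }
})

test_that("a step change surfaces in the window straddling it", {
  set.seed(91)
  tt <- rep(0:9, each = 3)
  mu <- matrix(200, 60, length(tt))
  mu[1:10, tt >= 5] <- 800      # step at day 5 in a minority of genes
  vals <- matrix(rnbinom(length(mu), size = 20, mu = mu), 60,
                 dimnames = list(sprintf("g%02d", 1:60),
                                 sprintf("s%02d", seq_along(tt))))
  res <- sliding_window_de(vals, times = tt)
  step_lfc <- vapply(res, function(w) median(abs(w$de$lfc[1:10]), na.rm = TRUE),
                     numeric(1))
  anchors <- vapply(res, `[[`, numeric(1), "anchor_day")
  # the ref [3,4] vs cur [5,6] comparison is the clean straddle
  expect_equal(anchors[which.max(step_lfc)], 5)
  # stationary genes yield few discoveries anywhere
  null_rate <- mean(vapply(res, function(w) {
    mean(w$de$p_adjusted[11:60] < 0.05, na.rm = TRUE)
  }, numeric(1)))
  expect_lt(null_rate, 0.1)
})

test_that("enrichment scores equal the hand-computed running sum on a toy list", {
  stats <- setNames(seq(10, 1), paste0("g", 1:10))
  sets <- list(top2 = c("g1", "g2"))
  res <- preranked_gsea(stats, sets, n_permutations = 200, seed = 1,
                        min_size = 2)
  # weights 10,9 of NR=19; max of running sum at position 2: 1
  expect_equal(res$es, 1)
  # equal weights variant, computed by hand: after g1 10/19; g2 -> 1
  expect_equal(res$leading_edge, "g1,g2")
})

test_that("enrichment scores match brute force on exhaustive small lists", {
  set.seed(92)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- paste0("g", seq_len(n))
    in_set <- rep(FALSE, n)
    in_set[sample(n, sample(1:(n - 1), 1))] <- TRUE
    expect_equal(ntve:::gsea_es(stats, in_set),
                 brute_gsea_es(stats, in_set))
  }
  # whole-universe set cancels to zero
  stats <- setNames(rnorm(6), paste0("g", 1:6))
  expect_equal(ntve:::gsea_es(stats, rep(TRUE, 6)), 0)
})

test_that("preranked GSEA is seed-deterministic and flags tiny sets", {
  set.seed(93)
  stats <- setNames(rnorm(40), paste0("g", 1:40))
  sets <- list(ok = paste0("g", 1:6), tiny = c("g1", "g2"))
  expect_warning(r1 <- preranked_gsea(stats, sets, n_permutations = 100,
                                      seed = 7), "skipped")
  r2 <- suppressWarnings(preranked_gsea(stats, sets, n_permutations = 100,
                                        seed = 7))
  expect_identical(r1$p_value, r2$p_value)
  expect_false("tiny" %in% r1$set)
})

test_that("GSEA agrees with an independent implementation on clean signals", {
  skip_if_not_installed("fgsea")
  set.seed(94)
  stats <- sort(rnorm(100, sd = 2), decreasing = TRUE)
  names(stats) <- paste0("g", 1:100)
  sets <- list(up = paste0("g", 1:10),
               down = paste0("g", 91:100),
               rand = paste0("g", sample(100, 15)))
  mine <- preranked_gsea(stats, sets, n_permutations = 500, seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(pathways = sets, stats = stats,
                                       gseaParam = 1, nproc = 1))
  for (nm in names(sets)) {
    expect_equal(mine$es[mine$set == nm],
                 ref$ES[ref$pathway == nm], tolerance = 1e-9)
  }
})

test_that("time-to-peak ordering centers rows and sorts ascending", {
  means <- rbind(late = c(1, 2, 10), early = c(10, 2, 1), mid = c(1, 10, 2))
  colnames(means) <- c(0, 3, 6)
  res <- time_to_peak_ordering(means)
  expect_equal(names(res$time_to_peak), c("early", "mid", "late"))
  expect_equal(unname(res$time_to_peak), c(0, 3, 6))
  expect_equal(unname(rowMeans(res$matrix)), rep(0, 3), tolerance = 1e-12)
})

test_that("contraction frequency recovers a 1 Hz oscillation and rejects flat traces", {
  fps <- 13.8
  t <- seq(0, 10, by = 1 / fps)
  trace <- sin(2 * pi * t)
  res <- contraction_frequency(trace, fps)
  expect_equal(res$frequency_hz, 1, tolerance = 0.1)
  flat <- contraction_frequency(rep(1, 100), fps = 10)
  expect_true(is.na(flat$frequency_hz))
  # doubling the sampling rate leaves the estimate unchanged
  fps2 <- 2 * fps
  t2 <- seq(0, 10, by = 1 / fps2)
  res2 <- contraction_frequency(sin(2 * pi * t2), fps2)
  expect_equal(res2$frequency_hz, res$frequency_hz, tolerance = 0.05)
})
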