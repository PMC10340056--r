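test_that("confusion matrices count true/predicted pairs", {
  y <- c(1, 2, 3, 2, 1)
  expect_equal(confusionMatrix(y, y, 3), diag(c(2, 2, 1)))
  cm1 <- confusionMatrix(2, 3, 3)
  expect_equal(sum(cm1), 1)
  expect_equal(cm1[2, 3], 1)
  p <- c(1, 3, 3, 2, 2)
  perm <- sample(5)
  expect_equal(confusionMatrix(y[perm], p[perm], 3),
               confusionMatrix(y, p, 3))
  expect_error(confusionMatrix(c(1, 2), 1, 2), "length")
  expect_error(confusionMatrix(c(0, 1), c(1, 1), 2), "lie in")
})

test_that("per-class metrics reproduce hand arithmetic", {
  cm <- matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE)
  m <- perClassMetrics(cm)
  expect_equal(unname(m[1, "Precn"]), 60) # 3 / 5
  expect_equal(unname(m[1, "Recal"]), 75) # 3 / 4
  expect_equal(unname(m[1, "Accuy"]), 70) # (3 + 4) / 10
  expect_equal(unname(m[1, "Fscore"]), 2 * 60 * 75 / (60 + 75))
  perfect <- perClassMetrics(diag(c(5, 5)))
  expect_true(all(perfect == 100))
  # degenerate predictor: everything assigned to class 1
  all1 <- perClassMetrics(matrix(c(4, 0, 6, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(all1[1, "Recal"]), 100)
  expect_equal(unname(all1[2, "Recal"]), 0)
  expect_true(attr(all1, "flags")[2, "Precn"]) # 0/0 reported as 0
  expect_equal(unname(all1[2, "Precn"]), 0)
  expect_error(perClassMetrics(matrix(0, 2, 2)), "empty")
})

test_that("one-vs-rest AUC behaves at the extremes and under reversal", {
  y <- c(1, 1, 2, 2)
  sep <- matrix(c(.9, .1, .8, .2, .1, .9, .2, .8), 4, 2, byrow = TRUE)
  expect_equal(aucOvr(y, sep), c(100, 100))
  rev <- 1 - sep
  expect_equal(aucOvr(y, rev), 100 - aucOvr(y, sep))
  set.seed(31)
  n <- 4000
  yr <- sample(1:3, n, replace = TRUE)
  sr <- matrix(runif(n * 3), n, 3) # scores independent of labels
  expect_equal(aucOvr(yr, sr), rep(50, 3), tolerance = 3)
  expect_true(is.na(aucOvr(c(1, 1), matrix(runif(4), 2, 2))[2]))
})

test_that("metrics agree with reference implementations on random matrices", {
  set.seed(77)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    n <- sample(40:120, 1)
    y <- sample.int(k, n, replace = TRUE)
    while (length(unique(y)) < k) y <- sample.int(k, n, replace = TRUE)
    p <- sample.int(k, n, replace = TRUE)
    cm <- confusionMatrix(y, p, k)
    m <- perClassMetrics(cm)
    ref <- caret::confusionMatrix(factor(p, levels = 1:k),
                                  factor(y, levels = 1:k))
    byc <- ref$byClass
    if (k == 2) byc <- rbind(byc, rev2 = NA) # caret collapses k=2
    for (c in seq_len(k)) {
      prec <- if (k == 2) {
        ref$table[c, c] / sum(ref$table[c, ])
      } else byc[c, "Precision"]
      rec <- if (k == 2) {
        ref$table[c, c] / sum(ref$table[, c])
      } else byc[c, "Recall"]
      if (!is.na(prec)) expect_equal(unname(m[c, "Precn"]), 100 * prec,
                                     tolerance = 1e-9)
      if (!is.na(rec)) expect_equal(unname(m[c, "Recal"]), 100 * rec,
                                    tolerance = 1e-9)
      # one-vs-rest accuracy from an independent binary collapse
      expect_equal(unname(m[c, "Accuy"]), 100 * mean((y == c) == (p == c)),
                   tolerance = 1e-9)
    }
  }
})

test_that("rank-based AUC agrees with pROC on random score sets", {
  set.seed(78)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    rs <- randomScoreSet(sample(30:80, 1), k)
    while (length(unique(rs$y)) < k) {
      rs <- randomScoreSet(60, k)
    }
    got <- aucOvr(rs$y, rs$scores)
    for (c in seq_len(k)) {
      ref <- pROC::auc(pROC::roc(as.integer(rs$y == c), rs$scores[, c],
                                 quiet = TRUE, direction = "<"))
      expect_equal(got[c], 100 * as.numeric(ref), tolerance = 1e-9)
    }
  }
})

test_that("macro averages pool rows and skip undefined AUCs only", {
  m <- rbind(c(90, 90, 90, 90, 80), c(100, 100, 100, 100, NA))
  expect_equal(macroAverage(m), c(95, 95, 95, 95, 80))
  expect_error(macroAverage(m[0, , drop = FALSE]), "no metric rows")
})

test_that("micro accuracy complements the classifier error rate", {
  expect_equal(classifierErrorRate(rep(1, 8), c(rep(1, 6), 2, 2)), 25)
  set.seed(9)
  y <- sample(1:4, 60, replace = TRUE)
  p <- sample(1:4, 60, replace = TRUE)
  cm <- confusionMatrix(y, p, 4)
  expect_equal(microAccuracy(cm), 100 - classifierErrorRate(y, p))
})

test_that("reports carry the standard table layout", {
  set.seed(10)
  y <- sample(1:3, 30, replace = TRUE)
  scores <- matrix(rexp(90), 30, 3)
  scores <- scores / rowSums(scores)
  p <- apply(scores, 1, which.max)
  rep <- buildReport(y, p, scores, c("A", "B", "C"), split = "80:20 test")
  tab <- reportTable(rep)
  expect_equal(rownames(tab), c("A", "B", "C", "Average"))
  expect_equal(colnames(tab),
               c("Accuy", "Precn", "Recal", "Fscore", "AUCscore"))
  expect_equal(unname(tab["Average", "Accuy"]), mean(tab[1:3, "Accuy"]))
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  writeReport(rep, csv, json)
  df <- read.csv(csv, check.names = FALSE)
  expect_equal(colnames(df),
               c("Class", "Accuy", "Precn", "Recal", "Fscore",
                 "AUCscore"))
  expect_equal(df$Class, c("A", "B", "C", "Average"))
  expect_true(file.exists(json))
  unlink(c(csv, json))
})
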