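test_that("counting error is predicted minus true, per organ", {
  truth <- make_counts("S1", bud = 0, flower = 2, fruit = 1)
  pred <- make_counts("S1", bud = 0, flower = 2, fruit = 1)
  expect_equal(counting_error(truth, pred)$error, c(0, 0, 0))

  # one flower detected as two: over-count of +1
  over <- counting_error(make_counts("S1", flower = 1),
                         make_counts("S1", flower = 2))
  expect_equal(over$error[over$organ == "flower"], 1)

  under <- counting_error(make_counts("S1", fruit = 5),
                          make_counts("S1", fruit = 3))
  expect_equal(under$error[under$organ == "fruit"], -2)

  expect_error(counting_error(truth, make_counts("S2", flower = 1)),
               "different specimens")
})

test_that("MAE averages absolute errors per organ and across organs", {
  truth <- make_counts(c("S1", "S2"), bud = c(1, 0), flower = c(2, 0),
                       fruit = c(1, 0))
  pred <- make_counts(c("S1", "S2"), bud = c(0, 0), flower = c(0, 0),
                      fruit = c(0, 0))
  got <- mae(counting_error(truth, pred))
  expect_equal(got$mae, c(0.5, 1.0, 0.5, 2 / 3), tolerance = 1e-12)

  # zero errors give zero MAE; MAE >= 0 with equality iff all errors are 0
  perfect <- mae(counting_error(truth, truth))
  expect_equal(perfect$mae, rep(0, 4))
  withr::with_seed(4, {
    for (i in 1:10) {
      p2 <- dplyr::mutate(truth, count = count + sample(0:2, 6, TRUE))
      m <- mae(counting_error(truth, p2))
      expect_gte(min(m$mae), 0)
      if (any(p2$count != truth$count)) expect_gt(m$mae[4], 0)
    }
  })

  # invariant to specimen ordering
  shuffled <- truth[sample(1:6), ]
  expect_equal(mae(counting_error(shuffled, pred)), got)

  # the literal per-specimen-sum reading is three times the table convention
  # when every organ contributes
  literal <- mae(counting_error(truth, pred), overall = "sum_per_specimen")
  expect_equal(literal$mae[4], 3 * got$mae[4])
})

test_that("the overall MAE entry is the mean of per-organ MAEs", {
  expect_equal(mae_overall(c(0.201, 0.507, 0.266)), 0.3246667,
               tolerance = 1e-6)
  expect_equal(mae_overall(c(0, 0, 0)), 0)
})

test_that("R-squared matches hand-computed values and its limits", {
  truth <- make_counts(paste0("S", 1:4), flower = c(0, 1, 2, 3))
  perfect <- r_squared(counting_error(truth, truth))
  expect_equal(perfect$r_squared[perfect$organ == "flower"], 1)

  # predicting the mean for every observation gives exactly 0
  mean_pred <- dplyr::mutate(truth,
                             count = ifelse(organ == "flower", 1.5, 0))
  at_mean <- r_squared(counting_error(truth, mean_pred))
  expect_equal(at_mean$r_squared[at_mean$organ == "flower"], 0)

  # c = (0,1,2,3), c_hat = (0,1,2,5): 1 - 4/5 = 0.2
  off <- make_counts(paste0("S", 1:4), flower = c(0, 1, 2, 5))
  got <- r_squared(counting_error(truth, off))
  expect_equal(got$r_squared[got$organ == "flower"], 0.2)

  # constant truth: undefined, flagged as NA rather than +/-Inf
  expect_true(is.na(got$r_squared[got$organ == "bud"]))

  # never exceeds 1; can go negative
  withr::with_seed(9, {
    for (i in 1:10) {
      t2 <- make_counts(paste0("S", 1:6), flower = rpois(6, 2) + (1:6 %% 2))
      p2 <- dplyr::mutate(t2, count = count + sample(-2:4, 6, TRUE))
      r <- r_squared(counting_error(t2, p2))$r_squared
      expect_true(all(r[!is.na(r)] <= 1))
    }
  })
})

test_that("letter values follow the half-sample depth rule", {
  expect_equal(letter_values(c(1, 2, 3))$lower[1], 2)  # median row

  const <- letter_values(rep(7, 20))
  expect_true(all(const$lower == 7 & const$upper == 7))

  # n = 8: median depth 4.5 -> 4.5; fourth depth 2.5 -> (2.5, 6.5)
  lv8 <- letter_values(1:8)
  expect_equal(lv8$depth[1:2], c(4.5, 2.5))
  expect_equal(lv8$lower[1:2], c(4.5, 2.5))
  expect_equal(lv8$upper[1:2], c(4.5, 6.5))

  # median always equals the classical median; letter values weakly ordered
  withr::with_seed(12, {
    for (i in 1:20) {
      x <- rnorm(sample(3:200, 1))
      lv <- letter_values(x)
      expect_equal(lv$lower[1], median(x))
      expect_true(all(diff(lv$lower) <= 1e-12))
      expect_true(all(diff(lv$upper) >= -1e-12))
      expect_true(all(lv$upper >= lv$lower - 1e-12))
      out <- attr(lv, "outliers")
      if (length(out) > 0) {
        expect_true(all(out < min(lv$lower) | out > max(lv$upper)))
      }
    }
  })
  expect_error(letter_values(numeric()), "empty")
})

test_that("presence and dominance rates honor the confusion identities", {
  withr::with_seed(31, {
    n <- 60
    truth <- make_counts(sprintf("S%02d", 1:n),
                         bud = rbinom(n, 1, 0.1) * (1 + rpois(n, 0.6)),
                         flower = rbinom(n, 1, 0.8) * (1 + rpois(n, 1.4)),
                         fruit = rbinom(n, 1, 0.2) * (1 + rpois(n, 1.1)))
    pred <- dplyr::mutate(truth,
                          count = pmax(0, count + sample(-1:1, 3 * n, TRUE)))
  })
  rep <- presence_dominance(truth, pred)
  expect_equal(rep$indicator,
               c("bud_present", "flower_present", "fruit_present",
                 "flowers_ge_buds", "fruits_ge_flowers"))
  ok <- !is.na(rep$tp) & !is.na(rep$tn)
  expect_equal(rep$tp[ok] + rep$fn[ok], rep(100, sum(ok)))
  expect_equal(rep$tn[ok] + rep$fp[ok], rep(100, sum(ok)))
  # overall accuracy is exactly the prevalence-weighted TP/TN combination
  expect_equal(rep$accuracy[ok],
               weighted_overall_accuracy(rep$prevalence[ok], rep$tp[ok],
                                         rep$tn[ok]))

  # degenerate prevalence 100%: accuracy equals the TP rate
  t_all <- make_counts(c("A", "B"), flower = c(1, 2))
  p_all <- make_counts(c("A", "B"), flower = c(1, 0))
  rep2 <- presence_dominance(t_all, p_all)
  fl <- rep2[rep2$indicator == "flower_present", ]
  expect_equal(fl$prevalence, 100)
  expect_equal(fl$accuracy, fl$tp)
  expect_true(is.na(fl$tn))

  # ties count as "greater or equal", including 0 = 0
  t0 <- make_counts("A")  # all zero
  rep3 <- presence_dominance(t0, t0)
  expect_equal(rep3$prevalence[rep3$indicator == "flowers_ge_buds"], 100)
})

test_that("predicted-count distributions match a brute-force quantile oracle", {
  truth <- make_counts(paste0("S", 1:8),
                       flower = c(1, 1, 1, 1, 1, 1, 2, 2))
  pred <- make_counts(paste0("S", 1:8),
                      flower = c(1, 1, 1, 1, 1, 9, 2, 2))
  tab <- predicted_count_distribution(truth, pred)
  fl1 <- tab[tab$organ == "flower" & tab$true_count == 1, ]
  # brute-force oracle: bin 1 predictions are 1,1,1,1,1,9 -> median 1,
  # zero IQR, so 9 falls beyond the 1.5 x IQR whisker
  expect_equal(fl1$median, median(c(1, 1, 1, 1, 1, 9)))
  expect_equal(fl1$n, 6)
  expect_equal(fl1$outliers[[1]], 9)
  expect_equal(fl1$whisker_high, 1)

  # perfect predictions: median equals truth, zero IQR, in every bin
  perf <- predicted_count_distribution(truth, truth)
  perf_fl <- perf[perf$organ == "flower", ]
  expect_equal(perf_fl$median, perf_fl$true_count)
  expect_equal(perf_fl$lower_hinge, perf_fl$upper_hinge)

  # empty bins are omitted: no flower bin for counts never observed
  expect_false(any(perf_fl$true_count == 5))

  # random vectors against the order-statistics oracle for the median
  withr::with_seed(14, {
    for (i in 1:5) {
      t2 <- make_counts(paste0("S", 1:12), flower = rep(1, 12))
      p2 <- dplyr::mutate(t2, count = ifelse(organ == "flower",
                                             rpois(12, 2), count))
      d <- predicted_count_distribution(t2, p2)
      bin <- d[d$organ == "flower", ]
      expect_equal(bin$median,
                   median(p2$count[p2$organ == "flower"]))
    }
  })
})
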