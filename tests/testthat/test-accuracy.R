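test_that("distribution descriptors carry histograms or level tables", {
  study <- data.frame(id = 1:60, num = rnorm(60),
                      cat = sample(c("a", "b"), 60, TRUE),
                      grp = rep(c("g1", "g2"), 30))
  r <- distribution_descriptor(study, "num", group = "grp")
  expect_true(is.na(r$indicator_id))       # pure descriptor
  d <- r$descriptor[[1]]
  expect_equal(sum(d$histogram$counts), 60)
  expect_setequal(names(d$ecdf), c("g1", "g2"))
  expect_equal(max(d$ecdf$g1$F), 1)
  r2 <- distribution_descriptor(study, "cat")
  expect_equal(sum(unlist(r2$descriptor[[1]]$levels)), 60)
})

test_that("shape test: correct family passes structure, wrong family fails", {
  set.seed(123)
  study <- data.frame(id = 1:500, x = rexp(500, rate = 2))
  r <- shape_or_scale(study, "x", family = "normal")
  expect_equal(r$indicator_id, "DQI-4004")
  expect_equal(r$grading, "issue")          # exponential data vs normal family
  d <- r$descriptor[[1]]
  expect_equal(d$df, 10 - 1 - 2)            # two moments estimated
  expect_equal(sum(d$observed), 500)
  expect_equal(d$expected, rep(50, 10))     # equal-probability bins
  expect_equal(d$rootogram, sqrt(d$observed) - sqrt(d$expected))
  # fixed parameters: no estimated df correction
  r2 <- shape_or_scale(study, "x", family = "gamma",
                       params = list(shape = 1, rate = 2))
  expect_equal(r2$descriptor[[1]]$df, 9)
  expect_equal(shape_or_scale(data.frame(id = 1:5, x = rnorm(5)), "x")$grading,
               "not-applicable")
})

test_that("end-digit preference: rounded data fail, digit maths is exact", {
  study <- data.frame(id = 1:100, bp = seq(100, 298, by = 2))  # even digits only
  r <- end_digits(study, "bp")
  expect_equal(r$grading, "issue")
  d <- r$descriptor[[1]]
  expect_equal(d$df, 9)
  expect_equal(sum(unlist(d$digits)), 100)
  expect_equal(unlist(d$digits[c("1", "3", "5", "7", "9")], use.names = FALSE),
               rep(0L, 5))
  # digit extraction respects the declared precision
  r2 <- end_digits(data.frame(id = 1:60, x = rep(1.23, 60)), "x", decimals = 2,
                   min_n = 50)
  expect_equal(unlist(r2$descriptor[[1]]$digits[["3"]]), 60L)
  expect_equal(end_digits(data.frame(id = 1:10, x = 1:10), "x")$grading,
               "not-applicable")
})

test_that("margins flag a strongly shifted examiner class", {
  set.seed(5)
  n <- 300
  cl <- rep(c("1", "2", "3"), each = n / 3)
  y <- rnorm(n) + (cl == "3") * 3
  study <- data.frame(id = 1:n, y = y, exam = cl)
  r <- margins(study, "y", "exam")
  expect_equal(r$indicator_id, "DQI-4003")
  pc <- r$descriptor[[1]]$per_class
  expect_true(pc$flagged[pc$class == "3"])
  expect_equal(r$grading, "issue")
  # class with too few observations is dropped
  study2 <- study[c(1:150, 201:205), ]
  r2 <- margins(study2, "y", "exam", min_class_size = 10)
  expect_false("3" %in% r2$descriptor[[1]]$per_class$class)
  # a single usable class cannot be compared
  expect_equal(margins(study[1:100, ], "y", "exam")$grading, "not-applicable")
})

test_that("binary responses route to the proportions indicator", {
  set.seed(6)
  n <- 400
  cl <- rep(c("1", "2"), each = n / 2)
  p <- ifelse(cl == "2", 0.8, 0.2)
  study <- data.frame(id = 1:n, y = rbinom(n, 1, p), exam = cl)
  r <- margins(study, "y", "exam")
  expect_equal(r$indicator_id, "DQI-4006")
  expect_equal(r$descriptor[[1]]$family, "logistic")
  expect_equal(r$grading, "issue")
  pc <- r$descriptor[[1]]$per_class
  expect_true(all(pc$estimate >= 0 & pc$estimate <= 1))
})

test_that("covariate adjustment removes a confounded examiner difference", {
  set.seed(8)
  n <- 400
  cl <- rep(c("1", "2"), each = n / 2)
  age <- c(rnorm(n / 2, 40, 5), rnorm(n / 2, 60, 5))  # examiner 2 sees older
  y <- 0.5 * age + rnorm(n)                           # age drives y, not examiner
  study <- data.frame(id = 1:n, y = y, exam = cl, age = age)
  raw <- margins(study, "y", "exam")
  adj <- margins(study, "y", "exam", covariates = "age")
  expect_equal(raw$grading, "issue")   # crude comparison is fooled
  expect_equal(adj$grading, "ok")      # adjusted comparison is not
})

test_that("variance components recover a planted ICC", {
  set.seed(9)
  k <- 12; m <- 60
  b <- rnorm(k, sd = 1)                # sigma2_b = 1, sigma2_w = 1 -> ICC 0.5
  cl <- rep(as.character(1:k), each = m)
  y <- b[as.integer(cl)] + rnorm(k * m)
  study <- data.frame(id = seq_len(k * m), y = y, exam = cl)
  r <- varcomp(study, "y", "exam", threshold = 0.05)
  expect_equal(r$indicator_id, "DQI-4010")
  expect_equal(r$grading, "issue")
  expect_lt(abs(r$descriptor[[1]]$icc - 0.5), 0.2)
  # no examiner effect: ICC collapses to ~0 and the check passes
  study$y <- rnorm(k * m)
  r0 <- suppressMessages(varcomp(study, "y", "exam", threshold = 0.05))
  expect_lt(r0$descriptor[[1]]$icc, 0.05)
  expect_equal(r0$grading, "ok")
})

test_that("loess trends are smoothed per class on a fixed grid", {
  set.seed(10)
  n <- 200
  t <- sample(seq(as.Date("1999-01-01"), as.Date("2000-12-31"), by = "day"),
              n, replace = TRUE)
  cl <- rep(c("1", "2"), each = n / 2)
  drift <- as.numeric(t - min(t)) / 365 * (cl == "2")
  study <- data.frame(id = 1:n, y = rnorm(n) + drift, day = format(t, "%Y-%m-%d"),
                      exam = cl)
  r <- loess_trend(study, "y", "day", class_var = "exam")
  s <- r$descriptor[[1]]$series
  expect_setequal(unique(s$class), c("1", "2"))
  expect_equal(nrow(s), 200)  # 100-point grid per class
  # the drifting class rises over the study period
  s2 <- s[s$class == "2", ]
  expect_gt(s2$smoothed[which.max(s2$time)], s2$smoothed[which.min(s2$time)])
  # degenerate time column
  study$day <- "1999-01-01"
  expect_equal(loess_trend(study, "y", "day")$grading, "not-applicable")
})
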