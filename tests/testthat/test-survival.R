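test_that("KM with no censoring equals the empirical survival function", {
  times <- c(3, 5, 5, 8, 12, 20)
  d <- data.frame(time = times, status = 1, group = "g")
  d2 <- rbind(d, data.frame(time = times + 1, status = 1, group = "h"))
  km <- kmLogrank(d2, "group")
  fit <- km$fit
  sf <- summary(fit)
  g1 <- sf$strata == "group=g"
  emp <- vapply(sf$time[g1], function(t) mean(times > t), numeric(1))
  expect_equal(sf$surv[g1], emp, tolerance = 1e-12)
})

test_that("log-rank on identical groups gives statistic 0; all-censored is flagged", {
  d <- data.frame(time = rep(c(5, 10, 15), 2), status = 1,
                  group = rep(c("a", "b"), each = 3))
  km <- kmLogrank(d, "group")
  expect_lt(km$chisq, 1e-10)
  expect_gt(km$p, 0.99)

  dc <- transform(d, status = 0)
  kmc <- kmLogrank(dc, "group")
  expect_false(kmc$p_defined)
  expect_true(is.na(kmc$p))
  expect_s3_class(kmc$fit, "survfit")
})

test_that("log-rank detects a rate ratio of 3 in simulation", {
  set.seed(60)
  d <- data.frame(time = c(rexp(200, 1), rexp(200, 3)), status = 1,
                  group = rep(c("a", "b"), each = 200))
  expect_lt(kmLogrank(d, "group")$p, 0.01)
})

test_that("coxFit recovers a planted hazard ratio with correct CI semantics", {
  d <- simulateSurvival(600, hr = 2, censorFraction = 0.3, seed = 5)
  hz <- coxFit(d, "group")
  expect_gt(hz$hazard_ratio[1], 1.7)
  expect_lt(hz$hazard_ratio[1], 2.35)
  expect_true(hz$ci_low[1] <= hz$hazard_ratio[1] &
                hz$hazard_ratio[1] <= hz$ci_high[1])
  expect_true(all(hz$hazard_ratio > 0))
})

test_that("Cox point estimate is invariant to row duplication and time rescale", {
  d <- simulateSurvival(200, hr = 1.8, seed = 9)
  h1 <- coxFit(d, "group")
  ## duplication creates tied event times; Efron's tie correction perturbs
  ## the estimate slightly, so equality is approximate
  h2 <- coxFit(rbind(d, d), "group")
  expect_equal(h1$hazard_ratio[1], h2$hazard_ratio[1], tolerance = 0.01)
  dm <- transform(d, time = time / 30.44)  # days -> months
  h3 <- coxFit(dm, "group")
  expect_equal(h1$hazard_ratio[1], h3$hazard_ratio[1], tolerance = 1e-6)
})

test_that("factor covariates get reference rows; interactions are fitted", {
  set.seed(33)
  d <- simulateSurvival(300, hr = 2, seed = 12)
  d$grade <- sample(c("low", "high"), 300, replace = TRUE)
  hz <- coxFit(d, c("group", "grade"),
               interactions = list(c("group", "grade")))
  expect_true(any(hz$is_reference))
  ref <- hz[hz$is_reference, ]
  expect_true(all(ref$hazard_ratio == 1))
  expect_true(any(grepl(":", hz$term)))
  expect_error(coxFit(transform(d, cns = 1), c("group", "cns")), "constant")
})

test_that("quartile model uses Q1 reference and lower-stratum boundary ties", {
  set.seed(71)
  n <- 200
  score <- rnorm(n)
  ## protective score: higher score, lower hazard
  tt <- rexp(n, 0.01 * exp(-1 * score))
  d <- data.frame(time = tt, status = 1, score = score)
  hz <- quartileModel(d, "score")
  expect_equal(hz$term[hz$is_reference], "quartile Q1 (reference)")
  q4 <- hz[hz$term == "quartile Q4", ]
  expect_lt(q4$hazard_ratio, 1)

  ## exact boundary tie goes into the lower stratum: put mass at Q1
  s2 <- c(rep(1, 60), 2:141)
  d2 <- data.frame(time = rexp(200, 0.01), status = 1, score = s2)
  q <- quantile(s2, 0.25, names = FALSE)
  hz2 <- quartileModel(d2, "score")
  brk <- attr(hz2, "breaks")
  expect_equal(brk[1], q)
  ## heavy ties that collapse quartile boundaries raise an error
  d3 <- data.frame(time = rexp(20, 0.01), status = 1,
                   score = rep(1, 20))
  expect_error(quartileModel(d3, "score"), "boundaries")
})

test_that("correlatePanel ranks a duplicated response first with BH control", {
  set.seed(15)
  y <- setNames(rnorm(30), sprintf("s%02d", 1:30))
  x <- rbind(dup = y,
             noise1 = rnorm(30), noise2 = rnorm(30), flat = rep(1, 30))
  colnames(x) <- names(y)
  out <- correlatePanel(x, y)
  expect_equal(out$r[out$gene == "dup"], 1, tolerance = 1e-12)
  expect_true(is.na(out$r[out$gene == "flat"]))   # zero variance excluded
  expect_true(is.na(out$fdr[out$gene == "flat"]))
  expect_equal(which.min(out$fdr), which(out$gene == "dup"))
  ## BH output equals the brute-force step-up oracle
  ok <- !is.na(out$p)
  expect_equal(out$fdr[ok], bhOracle(out$p[ok]), tolerance = 1e-12)
})

test_that("BH step-up on (0.01, 0.02, 0.03, 0.04) is 0.04 everywhere", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bhOracle(p), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
})

test_that("log2 transform flag reproduces hand-computed correlations", {
  x <- matrix(c(1, 3, 7, 15, 31, 63), 1,
              dimnames = list("g", paste0("s", 1:6)))
  y <- setNames(c(0, 1, 2, 3, 4, 5), colnames(x))
  out <- correlatePanel(x, 2^y - 1, log2Transform = TRUE, pseudocount = 1)
  expect_equal(out$r, 1, tolerance = 1e-12)
})

test_that("comparePsiGroups matches the exhaustive rank-sum on 3 vs 3", {
  psi <- c(0.12, 0.30, 0.25, 0.45, 0.52, 0.61)
  grp <- factor(rep(c("young", "old"), each = 3), levels = c("young", "old"))
  out <- comparePsiGroups(psi, grp)
  ## exhaustive enumeration of all C(6,3) assignments of ranks to group 1
  r <- rank(psi)
  obsW <- sum(r[1:3])
  allW <- apply(combn(6, 3), 2, function(i) sum(r[i]))
  pEnum <- mean(abs(allW - 10.5) >= abs(obsW - 10.5))
  expect_equal(out$pairwise$p, pEnum, tolerance = 1e-12)
  expect_equal(unname(out$medians["young"]), 0.25)
  ## identical constant groups
  out2 <- comparePsiGroups(rep(0.5, 8), rep(c("a", "b"), each = 4))
  expect_equal(out2$pairwise$p, 1)
})

test_that("comparePsiGroups detects shifts and summarizes the trend", {
  set.seed(44)
  psi <- c(rnorm(30, 0.7, 0.1), rnorm(30, 0.55, 0.1), rnorm(30, 0.4, 0.1))
  grp <- factor(rep(c("fetal", "child", "adult"), each = 30),
                levels = c("fetal", "child", "adult"))
  out <- comparePsiGroups(psi, grp)
  expect_lt(out$pairwise$p_adj[out$pairwise$group1 == "fetal" &
                                 out$pairwise$group2 == "adult"], 0.05)
  expect_lt(out$trend$rho, 0)  # inclusion decreases with age
  expect_lt(out$trend$p, 0.01)
  expect_error(comparePsiGroups(1:4, c("a", "a", "b", "b")), "at least 3")
})
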