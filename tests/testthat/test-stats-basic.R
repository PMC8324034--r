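test_that("one-way F statistic behaves like the classical definition", {
  # zero between-group variance
  an <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(an$F, 0)
  expect_equal(an$df_between, 1L)
  expect_equal(an$df_within, 4L)

  # two groups: F equals the squared pooled two-sample t
  set.seed(5)
  x <- rnorm(8); y <- rnorm(9, 1)
  an2 <- one_way_anova(c(x, y), rep(c("a", "b"), c(8, 9)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(an2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(an2$p, tt$p.value, tolerance = 1e-12)

  # agrees with the standard linear-model ANOVA on unbalanced data
  set.seed(6)
  v <- rnorm(25)
  g <- sample(letters[1:4], 25, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  while (min(table(g)) < 2) g <- sample(letters[1:4], 25, replace = TRUE)
  an3 <- one_way_anova(v, g)
  ref <- anova(lm(v ~ factor(g)))
  expect_equal(an3$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(an3$p, ref$`Pr(>F)`[1], tolerance = 1e-12)

  # invariances: relabeling, shift, scale
  perm <- sample(length(v))
  expect_equal(one_way_anova(v[perm], g[perm])$F, an3$F, tolerance = 1e-12)
  expect_equal(one_way_anova(v + 7, g)$F, an3$F, tolerance = 1e-10)
  expect_equal(one_way_anova(v * 3, g)$F, an3$F, tolerance = 1e-10)

  expect_error(one_way_anova(rep(2, 10), rep(c("a", "b"), 5)), "degenerate")
  expect_error(one_way_anova(1:5, rep("a", 5)), "2 groups")
})

test_that("ANOVA type-I error at nominal 0.05 is calibrated", {
  set.seed(1234)
  reps <- 5000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    v <- rnorm(40)
    rej[i] <- one_way_anova(v, rep(1:4, each = 10))$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Newman-Keuls separates well-separated groups and letters are consistent", {
  set.seed(11)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("lo", "hi"), each = 5)
  nk <- newman_keuls(v, g, alpha = 0.05)
  expect_true(nk$distinct["lo", "hi"])
  expect_false(any(diag(nk$distinct)))
  # distinct pairs share no letter; non-distinct pairs share at least one
  share <- function(a, b) {
    any(strsplit(nk$letters[a], "")[[1]] %in% strsplit(nk$letters[b], "")[[1]])
  }
  expect_false(share("lo", "hi"))

  # four accessions at the reported P50 means and spreads: all distinct
  set.seed(21)
  means <- c(-3.07, -2.49, -2.14, -1.58)
  sds <- c(0.30, 0.11, 0.18, 0.05)
  v4 <- unlist(Map(function(m, s) rnorm(10, m, s), means, sds))
  g4 <- rep(c("soc1_ful", "Sha", "Col-0", "Cvi"), each = 10)
  nk4 <- newman_keuls(v4, g4)
  off <- nk4$distinct[lower.tri(nk4$distinct)]
  expect_true(all(off))
  expect_length(unique(nk4$letters), 4)
})

test_that("Newman-Keuls familywise error for two groups is near alpha", {
  set.seed(300)
  reps <- 5000
  fw <- logical(reps)
  for (i in seq_len(reps)) {
    v <- rnorm(20)
    g <- rep(c("a", "b"), each = 10)
    fw[i] <- newman_keuls(v, g, alpha = 0.05)$distinct[1, 2]
  }
  # binomial MC error ~ 0.003; allow 4 sd
  expect_gt(mean(fw), 0.05 - 0.013)
  expect_lt(mean(fw), 0.05 + 0.013)
})

test_that("Newman-Keuls is at least as rejective as Tukey HSD and honours stretches", {
  set.seed(77)
  for (i in 1:100) {
    k <- sample(3:5, 1)
    n <- 8
    shift <- runif(k, 0, 1.5)
    v <- rnorm(k * n) + rep(shift, each = n)
    g <- rep(letters[1:k], each = n)
    nk <- newman_keuls(v, g)
    tk <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
    lev <- levels(factor(g))
    for (row in rownames(tk)) {
      pr <- strsplit(row, "-")[[1]]
      if (tk[row, "p adj"] < 0.05) {
        # anything Tukey rejects, the step-down SNK must also reject
        expect_true(nk$distinct[pr[1], pr[2]],
                    info = paste("instance", i, "pair", row))
      }
    }
    # implied homogeneity: within a non-distinct ordered stretch no inner
    # pair is distinct
    ord <- names(nk$means)
    kk <- length(ord)
    for (a in 1:(kk - 1)) for (b in (a + 1):kk) {
      if (!nk$distinct[ord[a], ord[b]]) {
        inner <- nk$distinct[ord[a:b], ord[a:b]]
        expect_false(any(inner))
      }
    }
  }
})

test_that("pearson matches the direct formula and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x)$r, -1, tolerance = 1e-12)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.4)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pr <- pearson(x, y)
  expect_equal(pr$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(pr$p, 2 * pt(abs(tstat), 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), y), "zero variance")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("VIF equals the auxiliary-regression definition", {
  set.seed(14)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X$d <- 0.8 * X$a + 0.3 * X$b + rnorm(n, 0, 0.4)
  v <- vif(X)
  for (j in names(X)) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[setdiff(names(X), j)]))$r.squared
    expect_equal(v[[j]], 1 / (1 - r2), tolerance = 1e-9)
  }
  # independent implementation (determinant-based) as cross-check
  cv <- car::vif(lm(rnorm(n) ~ a + b + c + d, data = X))
  expect_equal(unname(v[names(cv)]), unname(cv), tolerance = 1e-6)

  # predictors orthogonal to each other and to the intercept: all VIF = 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  expect_equal(unname(vif(as.data.frame(Q))), rep(1, 3), tolerance = 1e-10)

  # duplicated predictor: infinite VIF, not an exception
  X2 <- data.frame(a = X$a, b = X$a, c = X$c)
  v2 <- suppressWarnings(vif(X2))
  expect_true(is.infinite(v2[["a"]]) && is.infinite(v2[["b"]]))
})
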