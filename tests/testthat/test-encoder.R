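test_that("half-cosine channels tile orientation space", {
  for (norm in c(TRUE, FALSE)) {
    bs <- basis_set(normalize = norm)
    s <- rowSums(bs$values)
    expect_lt(diff(range(s)), 1e-9)
  }
  bs <- basis_set()
  expect_equal(bs$centres, seq(0, 160, by = 20))
  # channel centred at 0 gives zero response at 90 degrees
  expect_equal(bs$values[match(90, bs$grid), 1], 0)
  # a stimulus at a channel centre maximally drives that channel
  C <- build_design(c(0, 40, 160), bs)
  expect_equal(apply(C, 2, which.max), match(c(0, 40, 160), bs$centres))
  # tiling: per-trial column sums equal across all 6 stimulus orientations
  C6 <- build_design(seq(0, 150, 30), bs)
  expect_lt(diff(range(colSums(C6))), 1e-9)
})

test_that("design construction validates its inputs", {
  expect_error(build_design(numeric(0)), "empty")
  expect_error(build_design(c(10, 190)), "0, 180")
})

test_that("joint training solves the normal equations exactly", {
  set.seed(1)
  bs <- basis_set()
  ori <- runif(40, 0, 180)
  C1 <- build_design(ori, bs)
  W0 <- matrix(rnorm(12 * 9), 12, 9)
  B1 <- W0 %*% C1
  mdl <- train_encoder(B1, C1, method = "joint", shrinkage = "none")
  expect_lt(max(abs(mdl$W - W0)), 1e-8)
  # independent normal-equations oracle, one neuron at a time via lm()
  for (n in c(1, 7, 12)) {
    w_or <- unname(coef(lm(B1[n, ] ~ 0 + t(C1))))
    expect_lt(max(abs(mdl$W[n, ] - w_or)), 1e-8)
  }
})

test_that("per-channel training matches per-channel least squares", {
  set.seed(2)
  bs <- basis_set()
  ori <- sample(seq(0, 150, 30), 60, replace = TRUE)
  C1 <- build_design(ori, bs)
  B1 <- matrix(rnorm(5 * 60), 5, 60)
  mdl <- train_encoder(B1, C1, shrinkage = "none")
  for (n in 1:5) for (k in c(1, 5, 9)) {
    w_or <- unname(coef(lm(B1[n, ] ~ 0 + C1[k, ])))
    expect_equal(mdl$W[n, k], w_or, tolerance = 1e-10)
  }
})

test_that("duplicating all trials leaves the weights unchanged", {
  set.seed(3)
  bs <- basis_set()
  ori <- runif(30, 0, 180)
  C1 <- build_design(ori, bs)
  B1 <- matrix(rnorm(6 * 30), 6, 30)
  for (m in c("per_channel", "joint")) {
    w1 <- train_encoder(B1, C1, method = m, shrinkage = "none")$W
    w2 <- train_encoder(cbind(B1, B1), cbind(C1, C1), method = m,
                        shrinkage = "none")$W
    expect_equal(w1, w2, tolerance = 1e-10)
  }
})

test_that("training preconditions are enforced", {
  bs <- basis_set()
  C1 <- build_design(runif(5, 0, 180), bs)
  expect_error(train_encoder(matrix(0, 3, 5), C1), "fewer trials")
  # six distinct orientations cannot span nine channels jointly
  C6 <- build_design(rep(seq(0, 150, 30), 4), bs)
  expect_error(train_encoder(matrix(rnorm(3 * 24), 3, 24), C6,
                             method = "joint"), "singular")
  expect_error(train_encoder(matrix(0, 3, 10), C1[, c(1:5, 1:4)]),
               "column-aligned")
})

test_that("a noiseless channel-tuned population decodes with zero error", {
  bs <- basis_set()
  set.seed(4)
  ori <- sample(rep(seq(0, 150, 30), each = 20))
  B <- build_design(ori, bs)          # 9 "neurons" = the channels
  cv <- crossvalidate(B, ori, rep("all", length(ori)), n_folds = 10, seed = 5)
  expect_lt(max(abs(cv$errors)), 1e-8)
  expect_equal(cv$accuracy$accuracy, 1, tolerance = 1e-10)
})

test_that("a flat reconstruction is flagged rather than decoded", {
  bs <- basis_set()
  mdl <- structure(list(W = diag(9), sigma = NULL, lambda = NA,
                        method = "per_channel"), class = "encoder_model")
  rec <- decode(mdl, matrix(1, 9, 1), bs)
  expect_true(is.na(rec$decoded[1]))
})

test_that("decoding accuracy on shuffled labels is at chance", {
  set.seed(6)
  bs <- basis_set()
  ori <- sample(rep(seq(0, 150, 30), each = 30))
  B <- build_design(ori, bs) + matrix(rnorm(9 * 180, 0, 0.1), 9, 180)
  shuffled <- sample(ori)
  cv <- crossvalidate(B, shuffled, rep("all", 180), n_folds = 10, seed = 7)
  expect_lt(abs(cv$accuracy$accuracy), 0.12)
})

test_that("stratified folds partition all trials", {
  set.seed(8)
  ori <- sample(rep(seq(0, 150, 30), each = 12))
  B <- build_design(ori, basis_set())
  cv <- crossvalidate(B, ori, rep("all", 72), n_folds = 9, seed = 9)
  expect_setequal(unique(cv$fold), 1:9)
  expect_equal(length(cv$fold), 72)
  # stratification: each fold holds one trial of most orientations
  expect_true(all(table(cv$fold, ori) <= 2))
  expect_error(crossvalidate(B, ori, rep("all", 72), n_folds = 100),
               "folds")
})

test_that("training is deterministic and unaffected by test data", {
  set.seed(10)
  bs <- basis_set()
  ori <- sample(rep(seq(0, 150, 30), each = 10))
  B <- build_design(ori, bs) + matrix(rnorm(9 * 60, 0, 0.05), 9, 60)
  m1 <- train_encoder(B, build_design(ori, bs))
  m2 <- train_encoder(B, build_design(ori, bs))
  expect_identical(m1$W, m2$W)
  r1 <- decode(m1, B[, 1:5], bs, presented = ori[1:5])
  expect_identical(m1$W, m2$W)   # decode does not mutate the model
  expect_equal(r1$error, ori_diff_signed(r1$decoded, ori[1:5]))
})

test_that("whitened inversion handles correlated noise at least as well as none", {
  set.seed(11)
  bs <- basis_set()
  ori <- sample(rep(seq(0, 150, 30), each = 40))
  n_tr <- length(ori)
  W0 <- t(build_design(seq(5, 175, by = 10), bs))  # 18 tuned neurons
  B <- W0 %*% build_design(ori, bs)
  shared <- matrix(rnorm(n_tr), 1)
  noise <- matrix(rnorm(18 * n_tr, 0, 0.3), 18, n_tr) +
    matrix(rnorm(18), 18, 1) %*% shared * 0.6
  cv_w <- crossvalidate(B + noise, ori, rep("all", n_tr), seed = 12,
                        shrinkage = "ledoit")
  cv_n <- crossvalidate(B + noise, ori, rep("all", n_tr), seed = 12,
                        shrinkage = "none")
  expect_gt(cv_w$accuracy$accuracy, 0.5)
  expect_gte(cv_w$accuracy$accuracy, cv_n$accuracy$accuracy - 0.02)
})

test_that("violation-binned bias averages errors within signed bins", {
  errs <- c(1, 3, -2, -4, 5)
  viols <- c(30, 30, -30, -30, 60)
  bb <- violation_binned_bias(errs, viols)
  expect_equal(bb$bias[bb$violation == 30], 2)
  expect_equal(bb$bias[bb$violation == -30], -3)
  expect_equal(bb$n[bb$violation == 60], 1)
})
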