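test_that("phase preprocessing: spline upsampling, crop, normalization", {
  # full acquisition geometry: 364x480 -> 1460x1920, cropped to 1408x1920
  set.seed(10)
  ph <- matrix(stats::runif(364 * 480, 0, 3), 364, 480)
  out <- preprocessPhase(ph, c(1460, 1920), c(1408, 1920), depth = 5)
  expect_equal(dim(out), c(1408, 1920))
  expect_lte(max(out), 1)
  expect_equal(max(out), 1)

  # identity path: values unchanged up to max-normalization
  small <- matrix(stats::runif(32 * 32, 0, 2), 32, 32)
  idt <- preprocessPhase(small, c(32, 32), c(32, 32), depth = 5)
  expect_equal(idt, small / max(small), tolerance = 1e-12)

  # constant image normalizes to a constant 1 grid
  expect_equal(unique(as.numeric(preprocessPhase(matrix(2, 32, 32)))), 1)

  expect_error(preprocessPhase(small, c(32, 32), c(30, 30), depth = 5),
               "multiples of")
})

test_that("spline interpolation reproduces smooth fields accurately", {
  x <- outer(seq(0, 1, length.out = 40), seq(0, 1, length.out = 50),
             function(a, b) sin(2 * pi * a) * cos(2 * pi * b) + 2)
  up <- preprocessPhase(x, c(160, 200))
  truth <- outer(seq(0, 1, length.out = 160), seq(0, 1, length.out = 200),
                 function(a, b) sin(2 * pi * a) * cos(2 * pi * b) + 2)
  truth <- truth / max(truth)
  expect_lt(max(abs(up - truth)), 0.01)
})

test_that("Dice loss limits: perfect 0, disjoint close to 1", {
  y <- matrix(0, 16, 16); y[4:8, 4:8] <- 1
  expect_equal(diceLoss(y, y), 0)
  p <- matrix(0, 16, 16); p[12:15, 12:15] <- 1
  # smoothing constant keeps the disjoint loss just below 1
  expect_equal(diceLoss(p, y), 1 - 1 / (sum(p) + sum(y) + 1))
  expect_gt(diceLoss(p, y), 0.97)
})

test_that("ensemble vote rule is exact on constructed prediction stacks", {
  H <- 8; W <- 8
  base <- matrix(0, H, W)
  mk <- function(px) { m <- base; m[px] <- 0.9; m }
  # pixel 1: marked by 1 model; pixel 2: by 2; pixel 3: by all 6
  probs <- list(mk(c(1, 2, 3)), mk(c(2, 3)), mk(3), mk(3), mk(3), mk(3))
  out <- ensemblePredict(probs, vote_min = 2)
  expect_equal(out[1], 0L)   # 1 of 6 votes -> background
  expect_equal(out[2], 1L)   # exactly 2 of 6 -> foreground
  expect_equal(out[3], 1L)
  # six identical predictions reproduce the single prediction
  same <- replicate(6, mk(c(5, 9, 20)), simplify = FALSE)
  expect_equal(ensemblePredict(same, vote_min = 2),
               (mk(c(5, 9, 20)) > 0.5) + 0L)
  # restriction: nucleolus pixels outside the nucleus prediction vanish
  nuc <- matrix(0L, H, W); nuc[1] <- 1L
  expect_equal(sum(ensemblePredict(probs, vote_min = 2,
                                   nucleus_pred = nuc)), 0)
  expect_error(ensemblePredict(list(), vote_min = 2), "empty")
})

test_that("voting is monotone: an extra superset prediction never removes pixels", {
  set.seed(11)
  probs <- replicate(4, matrix(stats::runif(64), 8, 8), simplify = FALSE)
  out4 <- ensemblePredict(probs, vote_min = 2)
  extra <- matrix(1, 8, 8)   # predicts everything
  out5 <- ensemblePredict(c(probs, list(extra)), vote_min = 2)
  expect_true(all(out5[out4 == 1L] == 1L))
})

test_that("training is deterministic, ensembles differ, loss trends down", {
  fix <- dl_fixture(4, seed0 = 30, dims = c(32, 32))
  imgs <- lapply(fix, `[[`, "img"); labs <- lapply(fix, `[[`, "lab")
  cfg <- unetConfig(depth = 2, base_channels = 2, epochs = 6,
                    ensemble_size = 2, vote_min = 1)
  m1 <- trainUnet(imgs, labs, cfg, seed = 5)
  m2 <- trainUnet(imgs, labs, cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$losses, m2$losses)

  ens <- trainModels(imgs, labs, cfg)
  expect_length(ens, 2)
  expect_false(identical(ens[[1]]$params, ens[[2]]$params))
  expect_false(identical(ens[[1]]$losses[1], ens[[2]]$losses[1]))

  # training loss non-increasing in trend (late mean below early mean)
  expect_lt(mean(utils::tail(m1$losses, 2)), mean(utils::head(m1$losses, 2)))

  blank <- lapply(labs, function(l) l * 0L)
  expect_warning(trainUnet(imgs, blank, cfg, seed = 1), "background")
})

test_that("cross-validation covers every image exactly once, reproducibly", {
  fix <- dl_fixture(9, seed0 = 50, dims = c(32, 32))
  imgs <- lapply(fix, `[[`, "img"); labs <- lapply(fix, `[[`, "lab")
  cfg <- unetConfig(depth = 2, base_channels = 2, epochs = 2,
                    ensemble_size = 1, vote_min = 1, folds = 3, seed = 3)
  cv <- crossValidate(imgs, labs, cfg)
  expect_equal(sort(cv$image), 1:9)
  expect_equal(as.vector(table(attr(cv, "assignment"))), rep(3L, 3))
  cv2 <- crossValidate(imgs, labs, cfg)
  expect_identical(cv$dice, cv2$dice)
  expect_identical(attr(cv, "assignment"), attr(cv2, "assignment"))
  expect_error(crossValidate(imgs[1:2], labs[1:2], cfg), "smaller")
})

test_that("network input dimensions must divide 2^depth", {
  cfg <- unetConfig(depth = 3, base_channels = 2, epochs = 1,
                    ensemble_size = 1, vote_min = 1)
  img <- matrix(0.5, 20, 20)
  expect_error(trainUnet(list(img), list(matrix(0L, 20, 20)), cfg),
               "2\\^depth")
  expect_error(unetConfig(vote_min = 7, ensemble_size = 6), "vote_min")
})
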