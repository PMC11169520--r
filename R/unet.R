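#' Training configuration for the U-net harness
#'
#' The label-free path trains compact 2-D U-nets to segment nuclei and
#' nucleoli directly from phase images, using the fluorescence pipeline's
#' masks as labels. Dice loss, Adam with a fixed learning rate of 1e-4 and
#' batch size 1 are the training regime; for nucleoli an ensemble of six
#' differently initialized models votes per pixel (foreground when at
#' least \code{vote_min} = 2 models agree), while nuclei use a single
#' model. The default profile (depth 3, base width 4, 128 x 128 inputs) is
#' a desk-scale profile; depth and width scale up by configuration.
#'
#' @param depth number of resolution levels (depth - 1 poolings).
#' @param base_channels channel width of the first level (doubles per
#'   level).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param ensemble_size number of models trained from distinct seeds.
#' @param vote_min minimum votes for a foreground pixel.
#' @param folds cross-validation folds.
#' @param seed base RNG seed; model k uses seed + k - 1.
#' @return A list of class \code{"unetConfig"}.
#' @export
unetConfig <- function(depth = 3, base_channels = 4, lr = 1e-4,
                       epochs = 50, ensemble_size = 6, vote_min = 2,
                       folds = 3, seed = 1) {
  stopifnot(depth >= 2, base_channels >= 1, lr > 0, epochs >= 1,
            ensemble_size >= 1, vote_min >= 1, folds >= 2)
  if (vote_min > ensemble_size)
    stop("'vote_min' must not exceed 'ensemble_size'")
  structure(list(depth = depth, base_channels = base_channels, lr = lr,
                 epochs = epochs, batch_size = 1L,
                 ensemble_size = ensemble_size, vote_min = vote_min,
                 folds = folds, seed = seed),
            class = "unetConfig")
}

#' Preprocess a phase image for the network
#'
#' Upsamples the phase image to the fluorescence resolution with
#' separable cubic-spline interpolation, crops (top-left anchored) so that
#' every dimension is a multiple of 2^\code{depth}, and normalizes by the
#' image maximum.
#'
#' @param phase_img phase matrix.
#' @param target_shape c(rows, cols) after interpolation, or NULL to skip
#'   resizing.
#' @param crop_shape c(rows, cols) after cropping, or NULL to skip; each
#'   must be a multiple of 2^\code{depth} and no larger than the target.
#' @param depth network depth the crop must be compatible with.
#' @return Matrix of shape \code{crop_shape} with maximum <= 1.
#' @export
preprocessPhase <- function(phase_img, target_shape = NULL,
                            crop_shape = NULL, depth = 5) {
  x <- phase_img
  if (!is.null(target_shape)) {
    stopifnot(all(target_shape >= dim(x)))
    if (!identical(as.integer(target_shape), as.integer(dim(x)))) {
      nr <- dim(x)[1]; nc <- dim(x)[2]
      tmp <- matrix(0, target_shape[1], nc)
      xo <- seq(1, nr, length.out = target_shape[1])
      for (j in seq_len(nc))
        tmp[, j] <- stats::spline(seq_len(nr), x[, j], xout = xo,
                                  method = "fmm")$y
      out <- matrix(0, target_shape[1], target_shape[2])
      yo <- seq(1, nc, length.out = target_shape[2])
      for (i in seq_len(target_shape[1]))
        out[i, ] <- stats::spline(seq_len(nc), tmp[i, ], xout = yo,
                                  method = "fmm")$y
      x <- out
    }
  }
  if (!is.null(crop_shape)) {
    if (any(crop_shape %% 2^depth != 0))
      stop("crop dimensions must be multiples of 2^depth = ", 2^depth)
    if (any(crop_shape > dim(x)))
      stop("crop dimensions exceed the image")
    x <- x[seq_len(crop_shape[1]), seq_len(crop_shape[2]), drop = FALSE]
  }
  mx <- max(x)
  if (mx > 0) x <- x / mx
  x
}

#' Dice loss
#'
#' 1 minus the (smoothed) Dice overlap: with smoothing constant s = 1 in
#' numerator and denominator, loss = 1 - (2 sum(p y) + s) / (sum(p) +
#' sum(y) + s). A perfect prediction has loss 0; a disjoint prediction has
#' loss approaching 1 from below (exactly 1 - s/(sum(p)+sum(y)+s)).
#'
#' @param pred predicted probabilities in [0, 1].
#' @param target 0/1 labels, same shape.
#' @param smooth additive smoothing constant.
#' @return Scalar loss.
#' @export
diceLoss <- function(pred, target, smooth = 1) {
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  1 - num / den
}

.ch <- function(cfg, l) cfg$base_channels * 2^(l - 1)

.unet_init <- function(cfg, in_channels = 1, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  mk <- function(cin, cout) {
    list(w = matrix(stats::rnorm(cout * 9 * cin, 0, sqrt(2 / (9 * cin))),
                    cout, 9 * cin),
         b = numeric(cout))
  }
  D <- cfg$depth
  p <- list()
  cin <- in_channels
  for (l in seq_len(D)) {
    p[[paste0("enc", l, "a")]] <- mk(cin, .ch(cfg, l))
    p[[paste0("enc", l, "b")]] <- mk(.ch(cfg, l), .ch(cfg, l))
    cin <- .ch(cfg, l)
  }
  for (l in seq(D - 1, 1)) {
    p[[paste0("dec", l, "a")]] <- mk(.ch(cfg, l + 1) + .ch(cfg, l),
                                     .ch(cfg, l))
    p[[paste0("dec", l, "b")]] <- mk(.ch(cfg, l), .ch(cfg, l))
  }
  p[["out"]] <- list(w = matrix(stats::rnorm(.ch(cfg, 1), 0,
                                             sqrt(2 / .ch(cfg, 1))),
                                1, .ch(cfg, 1)),
                     b = 0)
  p
}

.conv_relu_fw <- function(x, par) {
  pre <- cpp_conv3_fw(x, par$w, par$b)
  list(y = pmax(pre, 0), x = x, pre = pre)
}

.conv_relu_bw <- function(cache, par, dy) {
  dpre <- dy * (cache$pre > 0)
  cpp_conv3_bw(cache$x, par$w, dpre)
}

.unet_forward <- function(params, cfg, img) {
  D <- cfg$depth
  x <- array(img, c(dim(img), 1))
  cache <- list()
  skips <- list()
  for (l in seq_len(D - 1)) {
    ca <- .conv_relu_fw(x, params[[paste0("enc", l, "a")]])
    cb <- .conv_relu_fw(ca$y, params[[paste0("enc", l, "b")]])
    cache[[paste0("enc", l, "a")]] <- ca
    cache[[paste0("enc", l, "b")]] <- cb
    skips[[l]] <- cb$y
    mp <- cpp_maxpool2_fw(cb$y)
    cache[[paste0("pool", l)]] <- list(amax = mp$amax, H = dim(cb$y)[1],
                                       W = dim(cb$y)[2])
    x <- mp$y
  }
  ca <- .conv_relu_fw(x, params[[paste0("enc", D, "a")]])
  cb <- .conv_relu_fw(ca$y, params[[paste0("enc", D, "b")]])
  cache[[paste0("enc", D, "a")]] <- ca
  cache[[paste0("enc", D, "b")]] <- cb
  x <- cb$y
  for (l in seq(D - 1, 1)) {
    up <- cpp_upsample2_fw(x)
    nu <- dim(up)[3]
    cat_x <- array(c(up, skips[[l]]),
                   c(dim(up)[1], dim(up)[2], nu + dim(skips[[l]])[3]))
    cache[[paste0("cat", l)]] <- list(n_up = nu)
    ca <- .conv_relu_fw(cat_x, params[[paste0("dec", l, "a")]])
    cb <- .conv_relu_fw(ca$y, params[[paste0("dec", l, "b")]])
    cache[[paste0("dec", l, "a")]] <- ca
    cache[[paste0("dec", l, "b")]] <- cb
    x <- cb$y
  }
  w <- params$out$w
  z <- params$out$b
  zmat <- matrix(z, dim(x)[1], dim(x)[2])
  for (c in seq_len(dim(x)[3])) zmat <- zmat + w[1, c] * x[, , c]
  prob <- 1 / (1 + exp(-zmat))
  cache[["out"]] <- list(x = x, z = zmat)
  list(prob = prob, cache = cache)
}

.unet_backward <- function(params, cfg, cache, dprob) {
  D <- cfg$depth
  grads <- list()
  oc <- cache[["out"]]
  p <- 1 / (1 + exp(-oc$z))
  dz <- dprob * p * (1 - p)
  x <- oc$x
  C1 <- dim(x)[3]
  dw_out <- matrix(0, 1, C1)
  for (c in seq_len(C1)) dw_out[1, c] <- sum(dz * x[, , c])
  grads[["out"]] <- list(w = dw_out, b = sum(dz))
  dx <- array(0, dim(x))
  for (c in seq_len(C1)) dx[, , c] <- dz * params$out$w[1, c]
  dskip <- vector("list", D - 1)
  for (l in seq_len(D - 1)) {
    gb <- .conv_relu_bw(cache[[paste0("dec", l, "b")]],
                        params[[paste0("dec", l, "b")]], dx)
    grads[[paste0("dec", l, "b")]] <- list(w = gb$dw, b = as.numeric(gb$db))
    ga <- .conv_relu_bw(cache[[paste0("dec", l, "a")]],
                        params[[paste0("dec", l, "a")]], gb$dx)
    grads[[paste0("dec", l, "a")]] <- list(w = ga$dw, b = as.numeric(ga$db))
    nu <- cache[[paste0("cat", l)]]$n_up
    dcat <- ga$dx
    dup <- dcat[, , seq_len(nu), drop = FALSE]
    dskip[[l]] <- dcat[, , nu + seq_len(dim(dcat)[3] - nu), drop = FALSE]
    dx <- cpp_upsample2_bw(dup)
  }
  gb <- .conv_relu_bw(cache[[paste0("enc", D, "b")]],
                      params[[paste0("enc", D, "b")]], dx)
  grads[[paste0("enc", D, "b")]] <- list(w = gb$dw, b = as.numeric(gb$db))
  ga <- .conv_relu_bw(cache[[paste0("enc", D, "a")]],
                      params[[paste0("enc", D, "a")]], gb$dx)
  grads[[paste0("enc", D, "a")]] <- list(w = ga$dw, b = as.numeric(ga$db))
  dx <- ga$dx
  for (l in seq(D - 1, 1)) {
    pl <- cache[[paste0("pool", l)]]
    dpooled <- cpp_maxpool2_bw(pl$amax, dx, pl$H, pl$W)
    dy <- dpooled + dskip[[l]]
    gb <- .conv_relu_bw(cache[[paste0("enc", l, "b")]],
                        params[[paste0("enc", l, "b")]], dy)
    grads[[paste0("enc", l, "b")]] <- list(w = gb$dw, b = as.numeric(gb$db))
    ga <- .conv_relu_bw(cache[[paste0("enc", l, "a")]],
                        params[[paste0("enc", l, "a")]], gb$dx)
    grads[[paste0("enc", l, "a")]] <- list(w = ga$dw, b = as.numeric(ga$db))
    dx <- ga$dx
  }
  grads
}

.adam_init <- function(params) {
  lapply(params, function(p)
    list(mw = p$w * 0, vw = p$w * 0, mb = p$b * 0, vb = p$b * 0))
}

.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$w <- params[[nm]]$w -
      lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

.check_dims <- function(imgs, depth) {
  for (im in imgs)
    if (any(dim(im) %% 2^depth != 0))
      stop("image dimensions must be multiples of 2^depth = ", 2^depth)
}

#' Train a single U-net
#'
#' Trains one model with Dice loss, Adam (fixed learning rate) and batch
#' size 1; the per-epoch image order is shuffled with the seeded RNG, so
#' a fixed seed reproduces the weights bit-exactly. All-background labels
#' trigger a warning but training proceeds.
#'
#' @param images list of equal-shaped numeric matrices, each dimension a
#'   multiple of 2^depth, values normalized to [0, 1].
#' @param labels list of matching 0/1 matrices.
#' @param config a \code{\link{unetConfig}}.
#' @param seed RNG seed for initialization and epoch shuffling.
#' @return A list of class \code{"unetModel"}: \code{params},
#'   \code{config}, \code{seed}, \code{losses} (mean Dice loss per
#'   epoch).
#' @export
trainUnet <- function(images, labels, config = unetConfig(),
                      seed = config$seed) {
  stopifnot(length(images) == length(labels), length(images) >= 1)
  .check_dims(images, config$depth)
  if (all(vapply(labels, function(l) sum(l) == 0, logical(1))))
    warning("all labels are background; training proceeds but is degenerate")
  params <- .unet_init(config, in_channels = 1, seed = seed)
  state <- .adam_init(params)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 1L)
  n <- length(images)
  losses <- numeric(config$epochs)
  t <- 0
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (i in ord) {
      fw <- .unet_forward(params, config, images[[i]])
      p <- fw$prob; y <- labels[[i]]
      num <- 2 * sum(p * y) + 1
      den <- sum(p) + sum(y) + 1
      ep_loss <- ep_loss + (1 - num / den)
      dprob <- -(2 * y * den - num) / den^2
      grads <- .unet_backward(params, config, fw$cache, dprob)
      t <- t + 1
      up <- .adam_step(params, grads, state, config$lr, t)
      params <- up$params; state <- up$state
    }
    losses[ep] <- ep_loss / n
  }
  structure(list(params = params, config = config, seed = seed,
                 losses = losses),
            class = "unetModel")
}

#' @export
print.unetModel <- function(x, ...) {
  cat("unetModel: depth", x$config$depth, ", base",
      x$config$base_channels, "channels, seed", x$seed,
      ", final loss", signif(utils::tail(x$losses, 1), 4), "\n")
  invisible(x)
}

#' Predict a probability map with one model
#'
#' @param model a \code{"unetModel"}.
#' @param phase_img preprocessed phase matrix.
#' @return Matrix of probabilities in [0, 1].
#' @export
predictUnet <- function(model, phase_img) {
  .unet_forward(model$params, model$config, phase_img)$prob
}

#' Train an ensemble of U-nets
#'
#' Trains \code{ensemble_size} models on the same images from distinct
#' seeded weight initializations (seeds \code{seed + 0:(k-1)}).
#'
#' @inheritParams trainUnet
#' @return List of \code{"unetModel"} objects.
#' @export
trainModels <- function(images, labels, config = unetConfig()) {
  lapply(seq_len(config$ensemble_size) - 1L, function(k)
    trainUnet(images, labels, config, seed = config$seed + k))
}

#' Ensemble vote prediction
#'
#' Each model's probability map is binarized at 0.5; a pixel is foreground
#' iff at least \code{vote_min} models mark it. When a nucleus prediction
#' is supplied the nucleolus mask is multiplied element-wise by it, so no
#' nucleolus pixel survives outside the predicted nucleus.
#'
#' @param models nonempty list of \code{"unetModel"} objects, or a list of
#'   precomputed probability matrices.
#' @param phase_img preprocessed phase matrix (ignored when
#'   probability matrices are supplied).
#' @param vote_min minimum votes for foreground.
#' @param nucleus_pred optional 0/1 nucleus mask to restrict to.
#' @return 0/1 integer matrix.
#' @export
ensemblePredict <- function(models, phase_img = NULL, vote_min = 2,
                            nucleus_pred = NULL) {
  if (length(models) == 0) stop("empty model set")
  probs <- lapply(models, function(m)
    if (inherits(m, "unetModel")) predictUnet(m, phase_img) else m)
  votes <- Reduce(`+`, lapply(probs, function(p) (p > 0.5) + 0L))
  out <- (votes >= vote_min) + 0L
  if (!is.null(nucleus_pred)) out <- out * nucleus_pred
  storage.mode(out) <- "integer"
  out
}

#' Threefold (k-fold) cross-validation
#'
#' Partitions the dataset into \code{folds} groups with the seeded RNG,
#' trains on all but one group and evaluates on the held-out group,
#' rotating so every image is tested exactly once. Reported metrics come
#' from test folds only.
#'
#' @inheritParams trainUnet
#' @return data.frame: fold, image index, test Dice; the fold assignment
#'   is attached as attribute \code{"assignment"}.
#' @export
crossValidate <- function(images, labels, config = unetConfig()) {
  n <- length(images)
  if (n < config$folds)
    stop("dataset smaller than the number of folds")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(config$seed))
  assign <- sample(rep(seq_len(config$folds), length.out = n))
  res <- data.frame()
  for (f in seq_len(config$folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    models <- trainModels(images[tr], labels[tr], config)
    vm <- min(config$vote_min, config$ensemble_size)
    for (i in te) {
      pred <- ensemblePredict(models, images[[i]], vote_min = vm)
      sc <- maskOverlapScores(pred, labels[[i]])
      res <- rbind(res, data.frame(fold = f, image = i,
                                   dice = unname(sc["dice"])))
    }
  }
  attr(res, "assignment") <- assign
  res
}
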