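# A small U-net for plant segmentation: an encoder/decoder with skip
# connections, two 3x3 conv + ReLU blocks per level, 2x2 max pooling,
# nearest-neighbor upsampling followed by a 3x3 conv, and a 1x1 sigmoid
# output head trained with binary cross-entropy and Adam. The architecture
# hyperparameters (depth 4, base 16 channels, threshold 0.5) are fixed to a
# canonical small U-net so CPU training at desk scale is feasible.

#' U-net configuration constructor
#'
#' @param inputSize,cornerCropSize,epochs,validationFraction,depth,baseChannels,learningRate,seed
#'   see [UNetConfig-class].
#' @return a validated [UNetConfig-class].
#' @export
UNetConfig <- function(inputSize = 512L, cornerCropSize = 460L, epochs = 30L,
                       validationFraction = 0.2, depth = 4L,
                       baseChannels = 16L, learningRate = 1e-3, seed = 1L) {
  new("UNetConfig", inputSize = as.integer(inputSize),
      cornerCropSize = as.integer(cornerCropSize),
      epochs = as.integer(epochs),
      validationFraction = validationFraction,
      depth = as.integer(depth), baseChannels = as.integer(baseChannels),
      learningRate = learningRate, seed = as.integer(seed))
}

# ---- layer primitives ------------------------------------------------------

convRelu <- function(x, w, b) {
  z <- .conv2d_fwd(x, w, b)
  list(y = pmax(z, 0), x = x, z = z)
}

convReluBwd <- function(cache, w, dy) {
  .conv2d_bwd(cache$x, w, dy * (cache$z > 0))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2Bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

heConv <- function(cin, cout, k = 3) {
  w <- array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

# channel widths per encoder level and the bottleneck
unetChannels <- function(cfg) {
  B <- cfg@baseChannels; D <- cfg@depth
  list(enc = B * 2^(seq_len(D) - 1), bottleneck = B * 2^D)
}

initUNetWeights <- function(cfg) {
  ch <- unetChannels(cfg)
  D <- cfg@depth
  withSeed(cfg@seed, {
    p <- list()
    cin <- 3L
    for (l in seq_len(D)) {
      p[[sprintf("enc%d.c1", l)]] <- heConv(cin, ch$enc[l])
      p[[sprintf("enc%d.c2", l)]] <- heConv(ch$enc[l], ch$enc[l])
      cin <- ch$enc[l]
    }
    p[["bot.c1"]] <- heConv(ch$enc[D], ch$bottleneck)
    p[["bot.c2"]] <- heConv(ch$bottleneck, ch$bottleneck)
    up <- ch$bottleneck
    for (l in rev(seq_len(D))) {
      p[[sprintf("dec%d.up", l)]] <- heConv(up, ch$enc[l])
      p[[sprintf("dec%d.c1", l)]] <- heConv(2L * ch$enc[l], ch$enc[l])
      p[[sprintf("dec%d.c2", l)]] <- heConv(ch$enc[l], ch$enc[l])
      up <- ch$enc[l]
    }
    p[["head"]] <- list(w = matrix(rnorm(ch$enc[1], 0, sqrt(2 / ch$enc[1]))),
                        b = 0)
    p
  })
}

# Forward pass; when backprop = TRUE all intermediate activations are kept.
unetForward <- function(p, x, cfg, backprop = FALSE) {
  D <- cfg@depth
  skips <- vector("list", D)
  cache <- list(enc = vector("list", D), dec = vector("list", D))
  h <- x
  for (l in seq_len(D)) {
    c1 <- convRelu(h, p[[sprintf("enc%d.c1", l)]]$w, p[[sprintf("enc%d.c1", l)]]$b)
    c2 <- convRelu(c1$y, p[[sprintf("enc%d.c2", l)]]$w, p[[sprintf("enc%d.c2", l)]]$b)
    skips[[l]] <- c2$y
    pool <- .maxpool2_fwd(c2$y)
    if (backprop) cache$enc[[l]] <- list(c1 = c1, c2 = c2, arg = pool$arg,
                                         dims = dim(c2$y))
    h <- pool$y
  }
  b1 <- convRelu(h, p[["bot.c1"]]$w, p[["bot.c1"]]$b)
  b2 <- convRelu(b1$y, p[["bot.c2"]]$w, p[["bot.c2"]]$b)
  if (backprop) cache$bot <- list(b1 = b1, b2 = b2)
  h <- b2$y
  for (l in rev(seq_len(D))) {
    up <- upsample2(h)
    u <- convRelu(up, p[[sprintf("dec%d.up", l)]]$w, p[[sprintf("dec%d.up", l)]]$b)
    cat <- concat3(skips[[l]], u$y)
    d1 <- convRelu(cat, p[[sprintf("dec%d.c1", l)]]$w, p[[sprintf("dec%d.c1", l)]]$b)
    d2 <- convRelu(d1$y, p[[sprintf("dec%d.c2", l)]]$w, p[[sprintf("dec%d.c2", l)]]$b)
    if (backprop) cache$dec[[l]] <- list(u = u, d1 = d1, d2 = d2,
                                         nSkip = dim(skips[[l]])[3])
    h <- d2$y
  }
  d <- dim(h)
  hm <- matrix(h, d[1] * d[2], d[3])
  z <- matrix(hm %*% p[["head"]]$w + p[["head"]]$b, d[1], d[2])
  if (backprop) cache$head <- list(hm = hm, hd = d)
  list(z = z, cache = cache)
}

# Backward pass from d(loss)/d(logits); returns gradients named like p.
unetBackward <- function(p, cfg, cache, dz) {
  D <- cfg@depth
  g <- list()
  hd <- cache$head$hd
  dzv <- matrix(as.numeric(dz), hd[1] * hd[2], 1)
  g[["head"]] <- list(w = crossprod(cache$head$hm, dzv), b = sum(dzv))
  dh <- array(dzv %*% t(p[["head"]]$w), hd)
  dskips <- vector("list", D)
  for (l in seq_len(D)) {
    cc <- cache$dec[[l]]
    b2 <- convReluBwd(cc$d2, p[[sprintf("dec%d.c2", l)]]$w, dh)
    g[[sprintf("dec%d.c2", l)]] <- list(w = b2$dw, b = b2$db)
    b1 <- convReluBwd(cc$d1, p[[sprintf("dec%d.c1", l)]]$w, b2$dx)
    g[[sprintf("dec%d.c1", l)]] <- list(w = b1$dw, b = b1$db)
    nS <- cc$nSkip
    dcat <- b1$dx
    dskips[[l]] <- dcat[, , seq_len(nS), drop = FALSE]
    du <- dcat[, , nS + seq_len(dim(dcat)[3] - nS), drop = FALSE]
    bu <- convReluBwd(cc$u, p[[sprintf("dec%d.up", l)]]$w, du)
    g[[sprintf("dec%d.up", l)]] <- list(w = bu$dw, b = bu$db)
    dh <- upsample2Bwd(bu$dx)
  }
  bb2 <- convReluBwd(cache$bot$b2, p[["bot.c2"]]$w, dh)
  g[["bot.c2"]] <- list(w = bb2$dw, b = bb2$db)
  bb1 <- convReluBwd(cache$bot$b1, p[["bot.c1"]]$w, bb2$dx)
  g[["bot.c1"]] <- list(w = bb1$dw, b = bb1$db)
  dh <- bb1$dx
  for (l in rev(seq_len(D))) {
    cc <- cache$enc[[l]]
    dpool <- .maxpool2_bwd(dh, cc$arg, cc$dims[1], cc$dims[2])
    dout <- dpool + dskips[[l]]
    b2 <- convReluBwd(cc$c2, p[[sprintf("enc%d.c2", l)]]$w, dout)
    g[[sprintf("enc%d.c2", l)]] <- list(w = b2$dw, b = b2$db)
    b1 <- convReluBwd(cc$c1, p[[sprintf("enc%d.c1", l)]]$w, b2$dx)
    g[[sprintf("enc%d.c1", l)]] <- list(w = b1$dw, b = b1$db)
    dh <- b1$dx
  }
  g
}

# Binary cross-entropy with logits; returns loss and d(loss)/d(logits).
bceWithLogits <- function(z, y, posWeight = 1) {
  n <- length(z)
  sp <- function(t) ifelse(t > 30, t, log1p(exp(t)))  # softplus, overflow-safe
  loss <- sum(posWeight * y * sp(-z) + (1 - y) * sp(z)) / n
  s <- stats::plogis(z)
  dz <- ((posWeight * y + (1 - y)) * s - posWeight * y) / n
  list(loss = loss, dz = dz)
}

adamStep <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(g)) for (part in c("w", "b")) {
    key <- paste0(nm, ".", part)
    gv <- g[[nm]][[part]]
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- gv * 0
      state$v[[key]] <- gv * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gv
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gv^2
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    p[[nm]][[part]] <- p[[nm]][[part]] - lr * mhat / (sqrt(vhat) + eps)
  }
  p
}

pairTensor <- function(pair, cfg) {
  d <- dim(pair$image)
  if (d[1] != cfg@inputSize || d[2] != cfg@inputSize)
    stop(sprintf("training pairs must be %d x %d", cfg@inputSize, cfg@inputSize))
  list(x = array(pair$image / 255, d), y = pair$mask)
}

#' Train the segmentation U-net
#'
#' Splits the pairs into training and validation sets (by
#' `validationFraction`, before any augmentation), optionally applies the
#' 40-fold deterministic augmentation to both sides, and trains the network
#' for `epochs` epochs with Adam on per-image binary cross-entropy
#' (shuffled each epoch under the configuration seed).
#'
#' @param pairs list of `list(image =, mask =)` training pairs
#'   (`inputSize x inputSize`).
#' @param cfg a [UNetConfig-class].
#' @param augment apply [augmentDataset()] to both splits first (the
#'   40-fold scheme).
#' @param posWeight weight on plant pixels in the loss (default 1).
#' @param verbose print per-epoch losses.
#' @return a [UNetModel-class] with per-epoch train/validation losses in
#'   `lossLog`.
#' @export
trainUNet <- function(pairs, cfg = UNetConfig(), augment = FALSE,
                      posWeight = 1, verbose = FALSE) {
  if (!length(pairs)) stop("empty training set")
  n <- length(pairs)
  nVal <- round(cfg@validationFraction * n)
  valIdx <- withSeed(cfg@seed + 1L, sample.int(n, nVal))
  trainPairs <- pairs[setdiff(seq_len(n), valIdx)]
  valPairs <- pairs[valIdx]
  if (augment) {
    trainPairs <- augmentDataset(trainPairs, cfg)
    if (length(valPairs)) valPairs <- augmentDataset(valPairs, cfg)
  }
  train <- lapply(trainPairs, pairTensor, cfg = cfg)
  val <- lapply(valPairs, pairTensor, cfg = cfg)

  p <- initUNetWeights(cfg)
  state <- new.env(parent = emptyenv())
  state$m <- list(); state$v <- list()
  t <- 0L
  log <- data.frame(epoch = integer(), trainLoss = numeric(),
                    valLoss = numeric())
  for (epoch in seq_len(cfg@epochs)) {
    ord <- withSeed(cfg@seed + 100L + epoch, sample.int(length(train)))
    lossSum <- 0
    for (i in ord) {
      fw <- unetForward(p, train[[i]]$x, cfg, backprop = TRUE)
      lo <- bceWithLogits(fw$z, train[[i]]$y, posWeight)
      g <- unetBackward(p, cfg, fw$cache, lo$dz)
      t <- t + 1L
      p <- adamStep(p, g, state, cfg@learningRate, t)
      lossSum <- lossSum + lo$loss
    }
    valLoss <- if (length(val)) {
      mean(vapply(val, function(s) {
        fw <- unetForward(p, s$x, cfg)
        bceWithLogits(fw$z, s$y, posWeight)$loss
      }, numeric(1)))
    } else NA_real_
    log <- rbind(log, data.frame(epoch = epoch,
                                 trainLoss = lossSum / length(train),
                                 valLoss = valLoss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %s", epoch,
                      lossSum / length(train),
                      ifelse(is.na(valLoss), "-", sprintf("%.4f", valLoss))))
  }
  new("UNetModel", weights = p, config = cfg, lossLog = log)
}

#' Predict a plant mask with a trained U-net
#'
#' Crops smaller than the network input are zero-padded (and the mask
#' cropped back); larger crops are resized down for prediction and the mask
#' resized back (nearest neighbor), so the output always matches the crop's
#' shape. The sigmoid output is thresholded at 0.5. Prediction is
#' deterministic: the same model and crop give the identical mask.
#'
#' @param model a [UNetModel-class].
#' @param crop 8-bit RGB array.
#' @return integer 0/1 matrix with the crop's dimensions.
#' @export
predictMask <- function(model, crop) {
  d <- stopIfNot8bitRGB(crop)
  size <- model@config@inputSize
  scaled <- FALSE
  work <- crop
  if (d[1] != d[2]) stop("predictMask expects square crops")
  if (d[1] < size) {
    work <- array(0L, c(size, size, 3L))
    off <- (size - d[1]) %/% 2
    work[off + seq_len(d[1]), off + seq_len(d[2]), ] <- crop
  } else if (d[1] > size) {
    work <- resizeImage(crop, size)
    scaled <- TRUE
  }
  fw <- unetForward(model@weights, array(work / 255, dim(work)), model@config)
  mask <- matrix(as.integer(stats::plogis(fw$z) > 0.5), size, size)
  if (d[1] < size) {
    off <- (size - d[1]) %/% 2
    mask <- mask[off + seq_len(d[1]), off + seq_len(d[2])]
  } else if (scaled) {
    mask <- resizeMaskNearest(mask, d[1])
  }
  mask
}

#' Save and load a trained U-net
#'
#' Models are serialized with R's native format (RDS).
#'
#' @param model a [UNetModel-class].
#' @param path file path.
#' @return `loadUNet()` returns the [UNetModel-class].
#' @export
saveUNet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveUNet
#' @export
loadUNet <- function(path) readRDS(path)

#' @describeIn UNetModel-class compact display
#' @param object a UNetModel
#' @export
setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  last <- tail(object@lossLog, 1)
  cat(sprintf("UNetModel: depth %d, base %d channels, input %d px; %d epochs, final train loss %.4f\n",
              cfg@depth, cfg@baseChannels, cfg@inputSize,
              nrow(object@lossLog),
              if (nrow(object@lossLog)) last$trainLoss else NA))
})
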