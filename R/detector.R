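# The epoch-window event detector: a per-epoch convolutional feature
# extractor followed by a cross-epoch temporal convolution whose valid
# support maps `input_epochs` mel spectrograms to `output_epochs`
# per-epoch class distributions. Forward and backward passes are plain
# matrix algebra so training is dependency-free and exactly reproducible.

#' Detector configuration
#'
#' The detector reads `input_epochs` consecutive epoch mel spectrograms
#' and emits class probabilities for the middle `output_epochs` epochs
#' (the remaining epochs provide past/future context; their difference
#' must be even). Capacity presets size the feature extractor and the
#' cross-epoch stage.
#'
#' @param input_epochs,output_epochs Window geometry (defaults 14 and 10).
#' @param n_classes Number of classes (3: no-event, apnea, hypopnea).
#' @param preset Capacity preset: `"tiny"`, `"small"` or `"full_scale"`.
#' @param n_mels Mel bands of the input spectrograms.
#' @param norm_center,norm_scale Affine input normalization applied to
#'   log-mel values: `(x - norm_center) / norm_scale`; scalars or
#'   per-mel-band vectors. `NULL` (default) means "fit from the training
#'   data" (see [fit_input_normalization()]); [pretrain_1to1()] does this
#'   automatically.
#' @param cms Add a contrast channel: per-band window-mean subtraction
#'   (cepstral-mean-subtraction style) alongside the absolute bands. The
#'   contrast channel is invariant to a constant per-band level shift of
#'   the window, which is what a stationary additive noise mostly does to
#'   log-mel features, so it gives noise-consistency training a robust
#'   pathway to lean on; the absolute channel keeps the amplitude cues
#'   (hypopnea) intact.
#' @param seed Integer seed for parameter initialization.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(input_epochs = 14L, output_epochs = 10L,
                            n_classes = 3L, preset = c("tiny", "small", "full_scale"),
                            n_mels = 64L, norm_center = NULL, norm_scale = NULL,
                            cms = TRUE, seed = 1L) {
  preset <- match.arg(preset)
  input_epochs <- as.integer(input_epochs)
  output_epochs <- as.integer(output_epochs)
  if (output_epochs > input_epochs)
    stop("output_epochs must be <= input_epochs")
  if ((input_epochs - output_epochs) %% 2L != 0L)
    stop("input_epochs - output_epochs must be even (symmetric context)")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  dims <- switch(preset,
    tiny        = list(pool_t = 12L, conv_channels = 32L, conv_kernel = 3L,
                       feat_dim = 48L, seq_hidden = 64L),
    small       = list(pool_t = 16L, conv_channels = 48L, conv_kernel = 3L,
                       feat_dim = 64L, seq_hidden = 96L),
    full_scale  = list(pool_t = 24L, conv_channels = 96L, conv_kernel = 5L,
                       feat_dim = 128L, seq_hidden = 192L))
  structure(c(list(input_epochs = input_epochs, output_epochs = output_epochs,
                   n_classes = as.integer(n_classes), preset = preset,
                   n_mels = as.integer(n_mels),
                   norm_center = norm_center, norm_scale = norm_scale,
                   cms = isTRUE(cms), seed = as.integer(seed)),
              dims),
            class = "detector_config")
}

he_init <- function(nrow, ncol) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

#' Build a detector with seeded initial parameters
#'
#' @param config A [detector_config()].
#' @return A list of class `osa_detector` with elements `config` and
#'   `params` (weight matrices `Wc, Wf, U, V` and biases; `Wp` is the
#'   single-epoch pretraining head).
#' @export
build_detector <- function(config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  ks <- config$input_epochs - config$output_epochs + 1L
  in_rows <- config$n_mels * (1L + isTRUE(config$cms))
  params <- with_seed(config$seed, list(
    Wc = he_init(config$conv_channels, in_rows * config$conv_kernel),
    bc = numeric(config$conv_channels),
    Wf = he_init(config$feat_dim, 2L * config$conv_channels + in_rows),
    bf = numeric(config$feat_dim),
    U  = he_init(config$seq_hidden, config$feat_dim * ks),
    bu = numeric(config$seq_hidden),
    V  = he_init(config$n_classes, config$seq_hidden),
    bv = numeric(config$n_classes),
    Wp = he_init(config$n_classes, config$feat_dim),
    bp = numeric(config$n_classes)))
  structure(list(config = config, params = params), class = "osa_detector")
}

#' @export
print.osa_detector <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<osa_detector: %s preset, %d->%d epochs, %d mels, %d parameters>\n",
              cfg$preset, cfg$input_epochs, cfg$output_epochs, cfg$n_mels, n_par))
  invisible(x)
}

# --- low-level batched layers ------------------------------------------------

# Average-pool the time axis of a mel matrix down to pool_t chunks.
pool_time_matrix <- function(n_frames, pool_t) {
  edges <- floor(seq(0L, n_frames, length.out = pool_t + 1L))
  P <- matrix(0, n_frames, pool_t)
  for (j in seq_len(pool_t)) {
    cols <- if (edges[j + 1L] > edges[j]) (edges[j] + 1L):edges[j + 1L]
            else max(1L, edges[j])            # fewer frames than chunks
    P[cols, j] <- 1 / length(cols)
  }
  P
}

# im2col over uniform column-blocks: M is r x (c*E) holding E blocks of c
# columns; returns (r*k) x ((c-k+1)*E) with epoch-major column blocks.
im2col_blocks <- function(M, r, c, k, E) {
  np <- c - k + 1L
  base <- rep(seq_len(r), k) + rep((0:(k - 1L)) * r, each = r)
  idx1 <- outer(base, (0:(np - 1L)) * r, `+`)               # one block
  idx <- outer(as.vector(idx1), (0:(E - 1L)) * (r * c), `+`)
  matrix(M[as.vector(idx)], nrow = r * k)   # flat index (never row/col pairs)
}

# Adjoint of im2col_blocks: scatter dX back onto the blocks of M.
col2im_blocks <- function(dX, r, c, k, E) {
  np <- c - k + 1L
  dM <- matrix(0, r, c * E)
  blocks <- rep((0:(E - 1L)) * c, each = np) + rep(seq_len(np), E)  # 1-based col of block start
  for (d in seq_len(k)) {
    rows <- ((d - 1L) * r + 1L):(d * r)
    cols <- blocks + (d - 1L)
    # accumulate dX[rows, ] into dM[, cols]; cols may repeat across d only
    # within a block, never within this d, so indexed addition is safe
    dM[, cols] <- dM[, cols] + dX[rows, , drop = FALSE]
  }
  dM
}

# Leaky rectifier (slope 0.01 on the negative side): avoids the dead-unit
# failure mode that large low-SNR gradients can otherwise cause.
lrelu <- function(x) pmax(x, 0) + 0.01 * pmin(x, 0)
lrelu_grad <- function(x) (x > 0) + 0.01 * (x <= 0)

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Forward pass of the per-epoch feature extractor for E epochs.
# mels: list of E mel matrices (n_mels x frames); epochs form consecutive
# groups of group_size (the window length during 14-to-10 operation, 1
# during single-epoch pretraining) over which the contrast channel's
# per-band mean is taken. Returns features fd x E plus caches.
extractor_forward <- function(params, config, mels, group_size = 1L) {
  E <- length(mels)
  n_frames <- ncol(mels[[1L]])
  P <- pool_time_matrix(n_frames, config$pool_t)
  ctr <- config$norm_center %||% -12
  scl <- config$norm_scale %||% 6
  raw <- vapply(mels, function(m) unclass(m) %*% P,
                matrix(0, config$n_mels, config$pool_t))   # n_mels x pool_t x E
  absn <- (raw - as.vector(ctr)) / as.vector(scl)          # recycle per band
  if (isTRUE(config$cms)) {
    if (E %% group_size != 0L) stop("epochs do not form whole windows")
    G <- E %/% group_size
    rg <- raw
    dim(rg) <- c(config$n_mels, config$pool_t * group_size, G)
    # per-band MEDIAN over the window: with breathing active less than
    # half the time this estimates the background (noise) level, so the
    # contrast channel reads bursts-above-background — the noise-robust
    # cue. A mean would be biased upward by the bursts themselves.
    gmean <- apply(rg, c(1L, 3L), median)                  # n_mels x G
    gexp <- gmean[, rep(seq_len(G), each = group_size), drop = FALSE]
    cms <- (raw - aperm(array(gexp, c(config$n_mels, E, config$pool_t)),
                        c(1L, 3L, 2L))) / as.vector(scl)
    stacked <- array(0, c(2L * config$n_mels, config$pool_t, E))
    stacked[seq_len(config$n_mels), , ] <- absn
    stacked[config$n_mels + seq_len(config$n_mels), , ] <- cms
    pooled <- stacked
  } else pooled <- absn
  in_rows <- dim(pooled)[1L]
  Pbig <- matrix(pooled, nrow = in_rows)                   # in_rows x (pool_t*E)
  X1 <- im2col_blocks(Pbig, in_rows, config$pool_t, config$conv_kernel, E)
  A1 <- params$Wc %*% X1 + params$bc
  H1 <- lrelu(A1)
  np <- config$pool_t - config$conv_kernel + 1L
  cc <- config$conv_channels
  H1a <- H1; dim(H1a) <- c(cc, np, E)
  hmean <- colMeans(aperm(H1a, c(2L, 1L, 3L)))            # cc x E
  # max over time positions (captures gasps/silences the mean dilutes)
  M2 <- aperm(H1a, c(1L, 3L, 2L)); dim(M2) <- c(cc * E, np)
  jmax <- max.col(M2, ties.method = "first")
  hmax <- matrix(M2[cbind(seq_len(cc * E), jmax)], cc, E)
  # direct per-band level pathway: breathing-amplitude reductions
  # (hypopnea) live in the mean band level, which conv+ReLU pooling
  # represents poorly
  Pa <- Pbig; dim(Pa) <- c(in_rows, config$pool_t, E)
  xmean <- colMeans(aperm(Pa, c(2L, 1L, 3L)))             # in_rows x E
  h <- rbind(hmean, hmax, xmean)                          # (2cc+in_rows) x E
  A2 <- params$Wf %*% h + params$bf
  Fm <- lrelu(A2)                                         # fd x E
  list(Fm = Fm, cache = list(X1 = X1, A1 = A1, h = h, A2 = A2,
                             np = np, E = E, jmax = jmax))
}

# Backward through the extractor given dFm (fd x E); returns parameter
# gradients for Wc, bc, Wf, bf.
extractor_backward <- function(params, config, cache, dFm) {
  dA2 <- dFm * lrelu_grad(cache$A2)
  dWf <- dA2 %*% t(cache$h)
  dbf <- rowSums(dA2)
  dh <- crossprod(params$Wf, dA2)               # (2cc+n_mels) x E
  np <- cache$np; E <- cache$E
  cc <- config$conv_channels
  dmean <- dh[seq_len(cc), , drop = FALSE]      # xmean rows need no backprop
  dmax <- dh[cc + seq_len(cc), , drop = FALSE]
  dH1 <- (dmean / np)[, rep(seq_len(E), each = np), drop = FALSE]
  # scatter the max-pool gradient to the argmax positions
  ce <- seq_len(cc * E)
  epo <- (ce - 1L) %/% cc                                  # 0-based epoch
  chan <- (ce - 1L) %% cc + 1L
  flat <- chan + (epo * np + cache$jmax - 1L) * cc
  dH1[flat] <- dH1[flat] + as.vector(dmax)
  dA1 <- dH1 * lrelu_grad(cache$A1)
  dWc <- dA1 %*% t(cache$X1)
  dbc <- rowSums(dA1)
  list(Wc = dWc, bc = dbc, Wf = dWf, bf = dbf)
}

# Full 14->10 forward for a batch of B windows. `window_mels` is a list of
# B lists, each holding input_epochs mel matrices. Returns probabilities
# (n_classes x output_epochs*B, window-major) and caches.
detector_forward <- function(det, window_mels) {
  config <- det$config; params <- det$params
  B <- length(window_mels)
  mels <- unlist(window_mels, recursive = FALSE)
  ext <- extractor_forward(params, config, mels,
                           group_size = config$input_epochs)
  ks <- config$input_epochs - config$output_epochs + 1L
  X2 <- im2col_blocks(ext$Fm, config$feat_dim, config$input_epochs, ks, B)
  A3 <- params$U %*% X2 + params$bu
  H2 <- lrelu(A3)
  logits <- params$V %*% H2 + params$bv
  probs <- softmax_cols(logits)
  list(probs = probs, B = B,
       cache = list(ext = ext$cache, Fm = ext$Fm, X2 = X2, A3 = A3, H2 = H2))
}

# Backward from dlogits (n_classes x output_epochs*B); returns gradient list.
detector_backward <- function(det, fw, dlogits) {
  config <- det$config; params <- det$params
  ca <- fw$cache
  dV <- dlogits %*% t(ca$H2)
  dbv <- rowSums(dlogits)
  dH2 <- crossprod(params$V, dlogits)
  dA3 <- dH2 * lrelu_grad(ca$A3)
  dU <- dA3 %*% t(ca$X2)
  dbu <- rowSums(dA3)
  dX2 <- crossprod(params$U, dA3)
  ks <- config$input_epochs - config$output_epochs + 1L
  dFm <- col2im_blocks(dX2, config$feat_dim, config$input_epochs, ks, fw$B)
  g <- extractor_backward(params, config, ca$ext, dFm)
  c(g, list(U = dU, bu = dbu, V = dV, bv = dbv))
}

# Softmax jacobian-vector product: given dL/dprobs, return dL/dlogits.
softmax_backprop <- function(probs, dprobs) {
  probs * sweep(dprobs, 2L, colSums(dprobs * probs))
}

# --- prediction --------------------------------------------------------------

prediction_frame <- function(probs, epoch_index) {
  cls <- osa_classes[apply(probs, 2L, which.max)]
  out <- data.frame(epoch_index = epoch_index,
                    p_no_event = probs[1L, ],
                    p_apnea = probs[2L, ],
                    p_hypopnea = probs[3L, ],
                    predicted_class = factor(cls, levels = osa_classes),
                    confidence = apply(probs, 2L, max))
  rownames(out) <- NULL
  out
}

#' Predict class probabilities for one 14-epoch window
#'
#' @param det An `osa_detector` (or an `osa_model`, whose detector is
#'   used).
#' @param window A `mel_window` from [make_windows()], or a plain list of
#'   `input_epochs` mel matrices.
#' @return A data frame with one row per output epoch: probabilities per
#'   class, `predicted_class` (argmax) and `confidence` (max probability).
#' @export
predict_window <- function(det, window) {
  det <- as_detector(det)
  mels <- if (inherits(window, "mel_window")) window$epochs else window
  if (length(mels) != det$config$input_epochs)
    stop("window must contain exactly ", det$config$input_epochs, " epochs")
  fw <- detector_forward(det, list(mels))
  idx <- if (inherits(window, "mel_window")) window$output_idx - 1L
         else seq_len(det$config$output_epochs) - 1L
  prediction_frame(fw$probs, idx)
}

#' Predict a whole night epoch by epoch
#'
#' Slides 14-epoch windows over the night ([make_windows()]) and stitches
#' per-window outputs; where consecutive windows overlap, the later
#' window's prediction is kept, so every epoch receives exactly one
#' prediction.
#'
#' @param det An `osa_detector` or `osa_model`.
#' @param mels List of per-epoch mel spectrograms for the night.
#' @param subject_id Optional subject identifier attached as an attribute.
#' @return A data frame of class `night_prediction` with one row per epoch
#'   (`epoch_index` is 0-based).
#' @export
predict_night <- function(det, mels, subject_id = NULL) {
  det <- as_detector(det)
  if (length(mels) == 0L) stop("night contains no epochs")
  wins <- make_windows(mels, det$config$input_epochs, det$config$output_epochs)
  fw <- detector_forward(det, lapply(wins, `[[`, "epochs"))
  n <- length(mels)
  probs <- matrix(NA_real_, det$config$n_classes, n)
  oe <- det$config$output_epochs
  for (w in seq_along(wins)) {
    cols <- (w - 1L) * oe + seq_len(oe)
    probs[, wins[[w]]$output_idx] <- fw$probs[, cols]
  }
  out <- prediction_frame(probs, seq_len(n) - 1L)
  attr(out, "subject_id") <- subject_id
  class(out) <- c("night_prediction", "data.frame")
  out
}

#' Fit the per-band input normalization from training data
#'
#' Computes the per-mel-band mean and standard deviation of the log-mel
#' values over a set of nights and stores them in the detector
#' configuration, so the network sees approximately standardized inputs.
#'
#' @param det_config A [detector_config()].
#' @param nights List of nights with a `mels` element.
#' @return The updated `detector_config`.
#' @export
fit_input_normalization <- function(det_config, nights) {
  mels <- unlist(lapply(nights, `[[`, "mels"), recursive = FALSE)
  P <- pool_time_matrix(ncol(mels[[1L]]), det_config$pool_t)
  s1 <- 0; s2 <- 0; n <- 0
  for (m in mels) {
    pm <- unclass(m) %*% P                # statistics of what the net sees
    s1 <- s1 + rowSums(pm)
    s2 <- s2 + rowSums(pm^2)
    n <- n + ncol(pm)
  }
  mu <- s1 / n
  sdv <- sqrt(pmax(s2 / n - mu^2, 0))
  det_config$norm_center <- mu
  det_config$norm_scale <- pmax(sdv, 1e-3)
  det_config
}

as_detector <- function(x) {
  if (inherits(x, "osa_detector")) return(x)
  if (inherits(x, "osa_model")) return(x$detector)
  if (inherits(x, "osa_checkpoint"))
    return(structure(list(config = x$config, params = x$params),
                     class = "osa_detector"))
  stop("expected an osa_detector, osa_checkpoint or osa_model")
}
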