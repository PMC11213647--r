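#' UNetConfig: architecture and training hyper-parameters
#'
#' A 2D encoder-decoder U-Net with two 3x3 conv + ReLU layers per block,
#' 2x2 max pooling, nearest-neighbour upsampling with a 3x3 up-convolution,
#' skip concatenation, element dropout after each encoder/bottleneck block
#' and a linear 1x1 output head. Trained with whole-batch Adam on an MSE
#' loss between normalized MR inputs and normalized CT labels.
#'
#' @slot levels encoder depth (default 4); input height/width must be
#'   divisible by 2^levels.
#' @slot convsPerBlock convolutions per block (fixed 2).
#' @slot baseFilters filters at the first level, doubling per level.
#' @slot dropout dropout rate in [0, 1) (default 0.2).
#' @slot lr Adam learning rate (default 1e-4).
#' @slot epochs training epochs (default 100).
#' @slot batchSize slices per gradient step; 0 (default) = whole batch,
#'   giving one Adam step per epoch as in the published recipe.
#' @slot seed integer seed for weight init and dropout.
#' @export
setClass("UNetConfig",
  representation(levels = "integer", convsPerBlock = "integer",
                 baseFilters = "integer", dropout = "numeric",
                 lr = "numeric", epochs = "integer", batchSize = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@dropout < 0 || object@dropout >= 1)
      msg <- c(msg, "dropout must be in [0, 1)")
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (object@baseFilters < 1L) msg <- c(msg, "baseFilters must be >= 1")
    if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
    if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
    if (object@batchSize < 0L) msg <- c(msg, "batchSize must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname UNetConfig-class
#' @param levels,baseFilters,dropout,lr,epochs,batchSize,seed see slots.
#' @export
UNetConfig <- function(levels = 4, baseFilters = 32, dropout = 0.2,
                       lr = 1e-4, epochs = 100, batchSize = 0L, seed = 1L) {
  new("UNetConfig", levels = as.integer(levels), convsPerBlock = 2L,
      baseFilters = as.integer(baseFilters), dropout = dropout, lr = lr,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      seed = as.integer(seed))
}

#' UNetModel: trained weights plus the generating configuration
#'
#' @slot weights named list of weight matrices and bias vectors.
#' @slot config the \linkS4class{UNetConfig} used for training.
#' @slot lossTrace per-epoch whole-batch training MSE (normalized scale),
#'   evaluated on the forward passes of that epoch before its update.
#' @export
setClass("UNetModel",
  representation(weights = "list", config = "UNetConfig",
                 lossTrace = "numeric"))

setMethod("show", "UNetModel", function(object) {
  cat(sprintf("UNetModel: %d levels, %d base filters, %d epochs trained\n",
              object@config@levels, object@config@baseFilters,
              length(object@lossTrace)))
  if (length(object@lossTrace))
    cat(sprintf("  final training MSE (normalized): %.3g\n",
                object@lossTrace[length(object@lossTrace)]))
})

#' Normalize a CT for network training
#'
#' HUs are clipped at 2000 and mapped by value/3000 + 1/3, taking
#' [-1000, 2000] HU onto [0, 1] (air to 0, water to 1/3, the cut-off to 1).
#'
#' @param ct \linkS4class{ImageGrid} or numeric array in HU.
#' @return array of normalized values, same shape.
#' @export
normalizeCT <- function(ct) {
  v <- if (is(ct, "ImageGrid")) ct@voxels else ct
  pmin(v, 2000) / 3000 + 1 / 3
}

#' Invert the CT normalization
#'
#' HU = 3000 * (value - 1/3); inverse of \code{\link{normalizeCT}} for
#' HU <= 2000.
#'
#' @param norm array of normalized values.
#' @param template optional \linkS4class{ImageGrid} supplying geometry for
#'   the returned grid; otherwise a bare array is returned.
#' @return HU array, or \linkS4class{ImageGrid} when a template is given.
#' @export
denormalizeCT <- function(norm, template = NULL) {
  hu <- 3000 * (norm - 1 / 3)
  if (is.null(template)) hu else
    withVoxels(template, hu, modality = "CT", units = "HU")
}

#' Normalize an MR volume
#'
#' Divides by the 99.995th percentile of the volume so almost all values lie
#' in [0, 1]; values above the percentile are not clipped.
#'
#' @param mr \linkS4class{ImageGrid} or numeric array of nonnegative
#'   intensities.
#' @return list(norm = array, scale = percentile value).
#' @export
normalizeMR <- function(mr) {
  v <- if (is(mr, "ImageGrid")) mr@voxels else mr
  if (any(v < 0)) stop("MR intensities must be nonnegative")
  scale <- stats::quantile(v, 0.99995, names = FALSE)
  if (scale <= 0) stop("cannot normalize an all-zero MR volume")
  list(norm = v / scale, scale = scale)
}

#' Train the MR-to-CT U-Net
#'
#' One whole-batch Adam step per epoch on the MSE between predicted and
#' label slices, both on the normalized [0, 1] scale. Deterministic for a
#' fixed config seed.
#'
#' @param mrNorm,ctNorm aligned 3D arrays (slices x rows x cols) of
#'   normalized MR inputs and CT labels (see \code{\link{normalizeMR}},
#'   \code{\link{normalizeCT}}).
#' @param config a \linkS4class{UNetConfig}.
#' @param init optional \linkS4class{UNetModel} whose weights warm-start
#'   the run (the optimizer state is reset).
#' @return A \linkS4class{UNetModel}.
#' @export
trainUNet <- function(mrNorm, ctNorm, config = UNetConfig(), init = NULL) {
  validObject(config)
  if (!identical(dim(mrNorm), dim(ctNorm)))
    stop("mrNorm and ctNorm shapes differ")
  d <- dim(mrNorm)
  if (length(d) != 3L || d[1] < 1L) stop("need >= 1 slice pair")
  if (d[2] %% 2^config@levels != 0 || d[3] %% 2^config@levels != 0)
    stop("slice height/width must be divisible by 2^levels = ",
         2^config@levels)
  mrCube <- aperm(mrNorm, c(2, 3, 1))   # rows x cols x slices
  ctCube <- aperm(ctNorm, c(2, 3, 1))
  initW <- if (is.null(init)) NULL else init@weights
  fit <- cpp_unet_train(mrCube, ctCube, config@levels, config@baseFilters,
                        config@dropout, config@lr, config@epochs,
                        config@seed, config@batchSize, initW)
  prior <- if (is.null(init)) numeric(0) else init@lossTrace
  new("UNetModel", weights = fit$weights, config = config,
      lossTrace = c(prior, as.numeric(fit$loss)))
}

#' Generate a deep-learning sCT from an MR volume
#'
#' Normalizes the MR (per volume), runs deterministic per-slice 2D
#' inference, de-normalizes to HU and restacks with the MR geometry.
#'
#' @param model a \linkS4class{UNetModel}.
#' @param mr MR \linkS4class{ImageGrid}.
#' @return CT-valued \linkS4class{ImageGrid} on the MR geometry.
#' @export
inferSCT <- function(model, mr) {
  nm <- normalizeMR(mr)
  d <- dim(nm$norm)
  lv <- model@config@levels
  if (d[2] %% 2^lv != 0 || d[3] %% 2^lv != 0)
    stop("in-plane shape (", d[2], " x ", d[3],
         ") is not divisible by 2^levels")
  cube <- aperm(nm$norm, c(2, 3, 1))
  pred <- cpp_unet_infer(model@weights, cube, lv, model@config@baseFilters)
  hu <- aperm(pred, c(3, 1, 2))
  denormalizeCT(hu, template = mr)
}
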