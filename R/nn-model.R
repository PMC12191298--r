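# The MFF-CNN: a 1D SE-ResNet18 branch over 12-lead beats and two 2D
# ResNet18 branches over the GAF and ST images, fused by feature
# concatenation into a softmax classifier.

#' Specification of one network branch
#'
#' Encodes the ResNet18-style trunk of a branch: a first convolution with 64
#' filters and stride 2 (kernel 15 for the 1D branch, 7x7 for the 2D
#' branches), a 3-wide stride-2 max pool, four stages of widths
#' 64/128/256/512 with two residual blocks each (block kernel 7 for 1D, 3x3
#' for 2D), and global average pooling to a 512-wide feature vector. The 1D
#' branch adds a squeeze-and-excitation block to every residual block (with
#' per-stage reductions 4/8/16/32) and a dropout between each block's two
#' convolutions plus one after pooling; the 2D branches are plain ResNet18
#' trunks. `width_multiplier` scales every stage width for desk-scale runs.
#'
#' @param dimensionality `"1d"` or `"2d"`.
#' @param in_channels Input channels (12 leads for 1D, 1 for the
#'   single-channel images).
#' @param width_multiplier Scale factor applied to all stage widths.
#' @param use_se Add SE blocks to every residual block (default: 1D only).
#' @param dropout_rate Dropout rate inside 1D residual blocks and after
#'   pooling (default 0.2 for 1D, 0 for 2D).
#' @param first_kernel,block_kernel Kernel sizes (defaults 15/7 for 1D,
#'   7/3 for 2D).
#' @param se_reduction Per-stage SE reduction factors.
#' @return An object of class `branch_spec`.
#' @export
branch_spec <- function(dimensionality = c("1d", "2d"),
                        in_channels = if (dimensionality == "1d") 12 else 1,
                        width_multiplier = 1,
                        use_se = dimensionality == "1d",
                        dropout_rate = if (dimensionality == "1d") 0.2 else 0,
                        first_kernel = if (dimensionality == "1d") 15 else 7,
                        block_kernel = if (dimensionality == "1d") 7 else 3,
                        se_reduction = c(4, 8, 16, 32)) {
  dimensionality <- match.arg(dimensionality)
  widths <- pmax(4L, as.integer(round(c(64, 128, 256, 512) * width_multiplier)))
  structure(list(dimensionality = dimensionality, in_channels = in_channels,
                 widths = widths, use_se = use_se, dropout_rate = dropout_rate,
                 first_kernel = first_kernel, block_kernel = block_kernel,
                 se_reduction = se_reduction,
                 width_multiplier = width_multiplier),
            class = "branch_spec")
}

# Residual block (1D or 2D). Layout: conv-BN-ReLU-[dropout]-conv-BN-[SE],
# projection shortcut (1-wide conv + BN) when the shape changes, addition,
# final ReLU.
.make_block <- function(spec, c_in, c_out, stride, se_red) {
  conv <- if (spec$dimensionality == "1d") nn_conv1d else nn_conv2d
  self <- .nn_env("res_block")
  self$conv1 <- conv(c_in, c_out, spec$block_kernel, stride = stride, bias = FALSE)
  self$bn1 <- nn_batchnorm(c_out)
  self$relu1 <- nn_relu()
  self$drop <- nn_dropout(spec$dropout_rate)
  self$conv2 <- conv(c_out, c_out, spec$block_kernel, stride = 1, bias = FALSE)
  self$bn2 <- nn_batchnorm(c_out)
  self$se <- if (spec$use_se) nn_se(c_out, se_red) else NULL
  self$relu2 <- nn_relu()
  self$project <- (stride != 1 || c_in != c_out)
  if (self$project) {
    self$sc_conv <- conv(c_in, c_out, 1, stride = stride, pad = 0, bias = FALSE)
    self$sc_bn <- nn_batchnorm(c_out)
  }
  self$children <- Filter(Negate(is.null),
                          list(self$conv1, self$bn1, self$conv2, self$bn2, self$se,
                               if (self$project) self$sc_conv, if (self$project) self$sc_bn))
  self$fwd <- function(x, train = FALSE) {
    h <- self$relu1$fwd(self$bn1$fwd(self$conv1$fwd(x, train), train), train)
    h <- self$drop$fwd(h, train)
    h <- self$bn2$fwd(self$conv2$fwd(h, train), train)
    if (!is.null(self$se)) h <- self$se$fwd(h, train)
    sc <- if (self$project) self$sc_bn$fwd(self$sc_conv$fwd(x, train), train) else x
    self$relu2$fwd(h + sc, train)
  }
  self$bwd <- function(dout) {
    d <- self$relu2$bwd(dout)
    dh <- d; dsc <- d
    if (!is.null(self$se)) dh <- self$se$bwd(dh)
    dh <- self$conv2$bwd(self$bn2$bwd(dh))
    dh <- self$drop$bwd(dh)
    dh <- self$conv1$bwd(self$bn1$bwd(self$relu1$bwd(dh)))
    if (self$project) dsc <- self$sc_conv$bwd(self$sc_bn$bwd(dsc))
    dh + dsc
  }
  self
}

#' Build one network branch
#'
#' Maps an input batch (`12 x 651 x B` for 1D, `1 x H x W x B` for 2D) to a
#' `width x B` feature matrix, `width` being the last stage width (512 at
#' full scale).
#'
#' @param spec A [branch_spec()].
#' @return A branch layer object (environment) with `$fwd`/`$bwd` and an
#'   `$out_width` field.
#' @export
build_branch <- function(spec) {
  stopifnot(inherits(spec, "branch_spec"))
  conv <- if (spec$dimensionality == "1d") nn_conv1d else nn_conv2d
  pool <- if (spec$dimensionality == "1d") nn_maxpool1d else nn_maxpool2d
  w <- spec$widths
  layers <- list(conv(spec$in_channels, w[1], spec$first_kernel, stride = 2, bias = FALSE),
                 nn_batchnorm(w[1]), nn_relu(), pool(3, 2, 1))
  c_prev <- w[1]
  for (stg in 1:4) {
    stride1 <- if (stg == 1) 1 else 2
    layers <- c(layers, list(.make_block(spec, c_prev, w[stg], stride1, spec$se_reduction[stg]),
                             .make_block(spec, w[stg], w[stg], 1, spec$se_reduction[stg])))
    c_prev <- w[stg]
  }
  layers <- c(layers, list(nn_gap()))
  if (spec$dimensionality == "1d" && spec$dropout_rate > 0)
    layers <- c(layers, list(nn_dropout(spec$dropout_rate)))
  br <- do.call(nn_seq, layers)
  br$out_width <- c_prev
  br$spec <- spec
  br
}

#' Build the fused MFF-CNN network
#'
#' Assembles the requested branches (any non-empty subset of `beat`, `gaf`,
#' `st`), concatenates their pooled feature vectors and applies a fully
#' connected layer; class probabilities are obtained by softmax. Dropping
#' branches shrinks the fusion head accordingly.
#'
#' @param n_classes Number of output classes (2 for detection, 12 or 10 for
#'   localization).
#' @param branches Character subset of `c("beat", "gaf", "st")`.
#' @param width_multiplier Stage-width scale shared by all branches.
#' @param image_size Image side length expected by the 2D branches (metadata
#'   only; the network is size-agnostic down to 8 x 8).
#' @param dropout_rate Dropout rate for the 1D branch.
#' @return An object of class `mff_net` with `$forward`, `$backward`,
#'   `$predict_probs`, `$n_params`.
#' @export
build_mff <- function(n_classes, branches = c("beat", "gaf", "st"),
                      width_multiplier = 1, image_size = 224,
                      dropout_rate = 0.2) {
  if (length(branches) == 0) stop("at least one branch required")
  branches <- match.arg(branches, c("beat", "gaf", "st"), several.ok = TRUE)
  net <- .nn_env("mff_net")
  net$branches <- list()
  for (b in branches) {
    net$branches[[b]] <- if (b == "beat") {
      build_branch(branch_spec("1d", width_multiplier = width_multiplier,
                               dropout_rate = dropout_rate))
    } else {
      build_branch(branch_spec("2d", width_multiplier = width_multiplier))
    }
  }
  widths <- vapply(net$branches, `[[`, 0, "out_width")
  net$head <- nn_dense(sum(widths), n_classes)
  net$children <- c(unname(net$branches), list(net$head))
  net$n_classes <- n_classes
  net$branch_names <- branches
  net$image_size <- image_size
  net$head_width <- sum(widths)

  net$forward <- function(inputs, train = FALSE) {
    feats <- vector("list", length(branches))
    Bs <- integer(length(branches))
    for (i in seq_along(branches)) {
      x <- inputs[[branches[i]]]
      if (is.null(x)) stop("missing input for branch ", branches[i])
      Bs[i] <- dim(x)[length(dim(x))]
      feats[[i]] <- net$branches[[branches[i]]]$fwd(x, train)
    }
    if (length(unique(Bs)) != 1) stop("mismatched batch sizes across the input triple")
    net$.split <- cumsum(vapply(feats, nrow, 0L))
    net$head$fwd(do.call(rbind, feats), train)
  }
  net$backward <- function(dlogits) {
    dcat <- net$head$bwd(dlogits)
    lo <- 1L
    for (i in seq_along(branches)) {
      hi <- net$.split[i]
      net$branches[[branches[i]]]$bwd(dcat[lo:hi, , drop = FALSE])
      lo <- hi + 1L
    }
    invisible(NULL)
  }
  net$predict_probs <- function(inputs) {
    logits <- net$forward(inputs, train = FALSE)
    mx <- apply(logits, 2, max)
    ex <- exp(sweep(logits, 2, mx))
    sweep(ex, 2, colSums(ex), "/")
  }
  net$param_layers <- nn_collect(net)
  net$n_params <- nn_n_params(net$param_layers)
  net
}
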