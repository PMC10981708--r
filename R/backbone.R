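#' Define a convolutional feature-extraction backbone
#'
#' Describes an AlexNet-shaped stack of convolution / max-pool / fully
#' connected layers used purely for feature extraction (inference only):
#' the activations at `feature_tap` are the per-recording feature vector.
#' Weights are either loaded from file or drawn once from a seeded He-normal
#' initialization ("random projection" features); both give deterministic
#' features.
#'
#' Two presets are provided:
#' \describe{
#'   \item{`"alexnet"`}{The classic geometry: 227x227x3 input; conv1 96
#'     filters 11x11 stride 4 + ReLU; 3x3/2 max-pools; conv2 256@5x5 (pad 2),
#'     conv3-5 384/384/256@3x3 (pad 1); flatten; fc6/fc7 of width 4096. The
#'     default feature tap is `fc6` (4096 features).}
#'   \item{`"small"`}{Same conv1 geometry (96@11x11/4) and 3x3/2 pools on a
#'     127x127x3 input with a lighter tail (128@5x5, 128@3x3, fc of width
#'     512). Roughly 20x cheaper per image; the preset used by this package's
#'     simulation studies.}
#' }
#'
#' @param preset `"alexnet"` or `"small"`.
#' @param feature_tap Name of the layer whose activations are returned
#'   (default: the first fully connected layer).
#' @return A `pcg_backbone_spec`: list with `input_size`, `layers`,
#'   `feature_tap`.
#' @export
backbone_spec <- function(preset = c("alexnet", "small"), feature_tap = NULL) {
  preset <- match.arg(preset)
  conv <- function(name, filters, kernel, stride = 1L, pad = 0L) {
    list(type = "conv", name = name, filters = filters, kernel = kernel,
         stride = stride, pad = pad)
  }
  pool <- function(name) list(type = "pool", name = name, kernel = 3L, stride = 2L)
  fc <- function(name, width) list(type = "fc", name = name, width = width)
  if (preset == "alexnet") {
    layers <- list(
      conv("conv1", 96L, 11L, 4L, 0L), pool("pool1"),
      conv("conv2", 256L, 5L, 1L, 2L), pool("pool2"),
      conv("conv3", 384L, 3L, 1L, 1L),
      conv("conv4", 384L, 3L, 1L, 1L),
      conv("conv5", 256L, 3L, 1L, 1L), pool("pool5"),
      list(type = "flatten", name = "flatten"),
      fc("fc6", 4096L), fc("fc7", 4096L)
    )
    input_size <- c(227L, 227L, 3L)
    if (is.null(feature_tap)) feature_tap <- "fc6"
  } else {
    layers <- list(
      conv("conv1", 96L, 11L, 4L, 0L), pool("pool1"),
      conv("conv2", 128L, 5L, 1L, 2L), pool("pool2"),
      conv("conv3", 128L, 3L, 1L, 1L), pool("pool3"),
      list(type = "flatten", name = "flatten"),
      fc("fc1", 512L)
    )
    input_size <- c(127L, 127L, 3L)
    if (is.null(feature_tap)) feature_tap <- "fc1"
  }
  if (!feature_tap %in% vapply(layers, `[[`, "", "name")) {
    stop("feature_tap '", feature_tap, "' is not a layer of this backbone")
  }
  structure(
    list(input_size = input_size, layers = layers, feature_tap = feature_tap),
    class = "pcg_backbone_spec"
  )
}

# Shape propagation through the stack; returns a list of output shapes per
# layer (conv/pool: c(h, w, c); flatten/fc: width).
backbone_shapes <- function(spec) {
  shape <- spec$input_size
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      h <- (shape[1] + 2L * ly$pad - ly$kernel) %/% ly$stride + 1L
      w <- (shape[2] + 2L * ly$pad - ly$kernel) %/% ly$stride + 1L
      shape <- c(h, w, ly$filters)
    } else if (ly$type == "pool") {
      h <- (shape[1] - ly$kernel) %/% ly$stride + 1L
      w <- (shape[2] - ly$kernel) %/% ly$stride + 1L
      shape <- c(h, w, shape[3])
    } else if (ly$type == "flatten") {
      shape <- prod(shape)
    } else if (ly$type == "fc") {
      shape <- ly$width
    }
    out[[i]] <- shape
  }
  names(out) <- vapply(spec$layers, `[[`, "", "name")
  out
}

#' Width of the backbone's feature vector
#' @param spec A [backbone_spec()].
#' @return Integer feature dimension at the configured tap.
#' @export
backbone_dim <- function(spec) {
  shapes <- backbone_shapes(spec)
  as.integer(shapes[[spec$feature_tap]][1])
}

#' Instantiate backbone weights
#'
#' He-normal initialization (`sd = sqrt(2 / fan_in)`) drawn with a local RNG
#' seeded by `seed`; the caller's RNG state is untouched. Alternatively a
#' weights file produced by [save_backbone()] can be loaded.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for the random weights.
#' @param weights_file Optional path to a saved backbone; overrides `seed`.
#' @return A `pcg_backbone`: the spec plus a `weights` list (per layer,
#'   `W` matrix in im2col layout and bias `b`).
#' @export
backbone_init <- function(spec, seed = 1L, weights_file = NULL) {
  if (!inherits(spec, "pcg_backbone_spec")) {
    stop("'spec' must come from backbone_spec()")
  }
  if (!is.null(weights_file)) {
    model <- load_backbone(weights_file)
    return(model)
  }
  weights <- list()
  with_local_seed(seed, {
    shapes <- backbone_shapes(spec)
    prev <- spec$input_size
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      if (ly$type == "conv") {
        fan_in <- ly$kernel^2 * prev[3]
        weights[[ly$name]] <- list(
          W = matrix(stats::rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                     nrow = fan_in, ncol = ly$filters),
          b = rep(0, ly$filters)
        )
      } else if (ly$type == "fc") {
        fan_in <- prod(prev)
        weights[[ly$name]] <- list(
          W = matrix(stats::rnorm(fan_in * ly$width, sd = sqrt(2 / fan_in)),
                     nrow = fan_in, ncol = ly$width),
          b = rep(0, ly$width)
        )
      }
      prev <- shapes[[i]]
    }
  })
  structure(
    list(spec = spec, weights = weights, seed = seed),
    class = "pcg_backbone"
  )
}

# im2col: unfold (H x W x C) into (n_positions x kernel^2*C) patches.
im2col <- function(x, kernel, stride, pad) {
  d <- dim(x)
  if (pad > 0L) {
    xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
    xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
    x <- xp
    d <- dim(x)
  }
  oh <- (d[1] - kernel) %/% stride + 1L
  ow <- (d[2] - kernel) %/% stride + 1L
  # 1-based linear index of each patch's top-left corner, channel 1
  r0 <- (seq_len(oh) - 1L) * stride
  c0 <- (seq_len(ow) - 1L) * stride
  base <- outer(r0 + 1L, c0 * d[1], `+`) # oh x ow
  off <- outer(0:(kernel - 1L), (0:(kernel - 1L)) * d[1], `+`)
  off <- outer(as.vector(off), (0:(d[3] - 1L)) * d[1] * d[2], `+`)
  idx <- outer(as.vector(base), as.vector(off), `+`)
  m <- x[idx]
  dim(m) <- c(oh * ow, kernel^2 * d[3])
  list(m = m, oh = oh, ow = ow)
}

maxpool_forward <- function(x, kernel = 3L, stride = 2L) {
  d <- dim(x)
  oh <- (d[1] - kernel) %/% stride + 1L
  ow <- (d[2] - kernel) %/% stride + 1L
  r0 <- (seq_len(oh) - 1L) * stride
  c0 <- (seq_len(ow) - 1L) * stride
  base <- outer(r0 + 1L, c0 * d[1], `+`)
  base <- outer(as.vector(base), (0:(d[3] - 1L)) * d[1] * d[2], `+`)
  out <- NULL
  for (dr in 0:(kernel - 1L)) {
    for (dc in 0:(kernel - 1L)) {
      v <- x[base + dr + dc * d[1]]
      out <- if (is.null(out)) v else pmax(out, v)
    }
  }
  array(out, dim = c(oh, ow, d[3]))
}

#' Extract deep features from one image
#'
#' Runs the backbone forward (convolutions via patch-matrix multiplication,
#' ReLU after every conv and fully connected layer, 3x3 stride-2 max-pools)
#' and returns the activations at the configured feature tap. Deterministic
#' given weights and input.
#'
#' @param image Numeric array matching the backbone's `input_size`.
#' @param model A `pcg_backbone` from [backbone_init()].
#' @return Numeric feature vector of length [backbone_dim()].
#' @export
extract_features <- function(image, model) {
  if (!inherits(model, "pcg_backbone")) {
    stop("'model' must come from backbone_init()")
  }
  spec <- model$spec
  if (!identical(as.integer(dim(image)), as.integer(spec$input_size))) {
    stop(
      "image size (", paste(dim(image), collapse = "x"),
      ") does not match backbone input (",
      paste(spec$input_size, collapse = "x"), ")"
    )
  }
  x <- image
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      w <- model$weights[[ly$name]]
      cols <- im2col(x, ly$kernel, ly$stride, ly$pad)
      a <- cols$m %*% w$W
      a <- sweep(a, 2L, w$b, `+`)
      a[a < 0] <- 0
      x <- array(a, dim = c(cols$oh, cols$ow, ly$filters))
    } else if (ly$type == "pool") {
      x <- maxpool_forward(x, ly$kernel, ly$stride)
    } else if (ly$type == "flatten") {
      x <- as.vector(x)
    } else if (ly$type == "fc") {
      w <- model$weights[[ly$name]]
      x <- as.vector(x %*% w$W) + w$b
      x[x < 0] <- 0
    }
    if (identical(ly$name, spec$feature_tap)) return(as.double(x))
  }
  stop("feature tap '", spec$feature_tap, "' never reached") # unreachable
}

#' Save / load backbone weights
#'
#' Weights are serialized with R's portable (XDR) serialization via
#' [saveRDS()]; the file contains the spec and all layer tensors.
#'
#' @param model A `pcg_backbone`.
#' @param path File path.
#' @return `path` (save) or the `pcg_backbone` (load).
#' @export
save_backbone <- function(model, path) {
  if (!inherits(model, "pcg_backbone")) stop("expected a 'pcg_backbone'")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pcg_backbone")) {
    stop("file does not contain a backbone: ", path)
  }
  model
}

#' Fuse per-location features into one patient vector
#'
#' Concatenates recording feature vectors in the fixed auscultation-location
#' order AV, PV, TV, MV. Locations with several recordings are averaged
#' elementwise first; absent locations contribute an all-zero segment and
#' are flagged in the `missing` attribute. The result has length
#' `4 * dim` regardless of which locations are present, as the downstream
#' classifiers require fixed-width rows.
#'
#' @param per_location Named list mapping location tags (subset of AV, PV,
#'   TV, MV) to a feature vector or a list of feature vectors.
#' @param dim Feature dimension of a single recording (inferred from the
#'   first entry when `NULL`).
#' @param order Location order (default `c("AV","PV","TV","MV")`).
#' @return Numeric vector of length `4 * dim` with attribute `missing`, a
#'   named logical vector over `order`.
#' @examples
#' fuse_patient(list(AV = 1:3, MV = list(c(1, 1, 1), c(3, 3, 3))), dim = 3)
#' @export
fuse_patient <- function(per_location, dim = NULL,
                         order = c("AV", "PV", "TV", "MV")) {
  if (length(per_location) == 0L) {
    stop("at least one auscultation location is required")
  }
  bad <- setdiff(names(per_location), order)
  if (length(bad) > 0) {
    stop("unknown location tag(s): ", paste(bad, collapse = ", "))
  }
  first <- per_location[[1]]
  if (is.list(first)) first <- first[[1]]
  if (is.null(dim)) dim <- length(first)
  segs <- vector("list", length(order))
  missing <- setNames(rep(TRUE, length(order)), order)
  for (i in seq_along(order)) {
    loc <- order[i]
    if (loc %in% names(per_location)) {
      v <- per_location[[loc]]
      if (!is.list(v)) v <- list(v)
      lens <- vapply(v, length, 1L)
      if (any(lens != dim)) {
        stop("feature vectors at ", loc, " have length ", paste(unique(lens),
          collapse = "/"
        ), ", expected ", dim)
      }
      segs[[i]] <- Reduce(`+`, v) / length(v)
      missing[loc] <- FALSE
    } else {
      segs[[i]] <- rep(0, dim)
    }
  }
  structure(unlist(segs, use.names = FALSE), missing = missing)
}
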