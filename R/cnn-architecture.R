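#' Layer description for the 1-D CNN
#'
#' @param kind One of `"conv1d"`, `"relu"`, `"maxpool1d"`, `"dropout"`,
#'   `"gap"`, `"dense"`, `"sigmoid"`.
#' @param filters,kernel,stride Convolution / pooling geometry.
#' @param rate Dropout rate in `[0, 1)`.
#' @param units Dense layer width.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(kind, filters = NULL, kernel = NULL, stride = NULL,
                       rate = NULL, units = NULL) {
  kind <- match.arg(kind, c("conv1d", "relu", "maxpool1d", "dropout",
                            "gap", "dense", "sigmoid"))
  if (kind == "conv1d") {
    filters <- check_count(filters, "filters", 1L)
    kernel <- check_count(kernel, "kernel", 1L)
    stride <- check_count(stride, "stride", 1L)
  } else if (kind == "maxpool1d") {
    kernel <- check_count(if (is.null(kernel)) 2L else kernel, "kernel", 1L)
    stride <- check_count(if (is.null(stride)) 2L else stride, "stride", 1L)
  } else if (kind == "dropout") {
    check_scalar_number(rate, "rate", lower = 0, upper = 1, strict_upper = TRUE)
  } else if (kind == "dense") {
    units <- check_count(units, "units", 1L)
  }
  structure(list(kind = kind, filters = filters, kernel = kernel,
                 stride = stride, rate = rate, units = units),
            class = "layer_spec")
}

#' Architecture of the 1-D CNN
#'
#' @param input_length Temporal length of one input window (samples).
#' @param layers Ordered list of [layer_spec()] objects.
#' @param padding_mode Only `"same_ceil"` is supported: convolutions and
#'   poolings use "same" zero padding with ceil-mode output lengths,
#'   `ceil(length / stride)`. This is the one padding convention that
#'   reproduces the reference shape sequence
#'   1000 - 500 - 250 - 125 - 63 - 63 - 32 - 32 - 16.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(input_length = 1000L, layers = list(),
                              padding_mode = "same_ceil") {
  input_length <- check_count(input_length, "input_length", 1L)
  padding_mode <- match.arg(padding_mode, "same_ceil")
  if (!all(vapply(layers, inherits, logical(1), "layer_spec"))) {
    stop_invalid("layers must be a list of layer_spec objects")
  }
  structure(list(input_length = input_length, layers = layers,
                 padding_mode = padding_mode),
            class = "architecture_spec")
}

#' The default TSCI classification network
#'
#' Four convolution blocks followed by global average pooling, one
#' hidden dense layer and a single sigmoid output unit:
#'
#' * Block 1: conv1d 32 filters, kernel 5, stride 2; ReLU; maxpool 2/2
#' * Block 2: conv1d 32 filters, kernel 5, stride 2; ReLU; maxpool 2/2
#' * Block 3: conv1d 64 filters, kernel 3, stride 1; ReLU; maxpool 2/2; dropout 0.1
#' * Block 4: conv1d 128 filters, kernel 3, stride 1; ReLU; maxpool 2/2; dropout 0.1
#' * GAP; dense 100 + ReLU; dense 1 + sigmoid
#'
#' With a 1000-sample input this network has 49,257 trainable
#' parameters (see [count_parameters()]).
#'
#' @param input_length Input window length in samples (default 1000,
#'   i.e. a 1000 ms window at 1000 Hz).
#' @return An [architecture_spec()].
#' @export
#' @examples
#' spec <- default_architecture()
#' count_parameters(spec)$total
default_architecture <- function(input_length = 1000L) {
  conv_block <- function(filters, kernel, stride, dropout = NULL) {
    b <- list(layer_spec("conv1d", filters = filters, kernel = kernel, stride = stride),
              layer_spec("relu"),
              layer_spec("maxpool1d", kernel = 2L, stride = 2L))
    if (!is.null(dropout)) b <- c(b, list(layer_spec("dropout", rate = dropout)))
    b
  }
  architecture_spec(
    input_length = input_length,
    layers = c(
      conv_block(32L, 5L, 2L),
      conv_block(32L, 5L, 2L),
      conv_block(64L, 3L, 1L, dropout = 0.1),
      conv_block(128L, 3L, 1L, dropout = 0.1),
      list(layer_spec("gap"),
           layer_spec("dense", units = 100L),
           layer_spec("relu"),
           layer_spec("dense", units = 1L),
           layer_spec("sigmoid"))
    )
  )
}

#' Derive per-layer output shapes
#'
#' Walks the architecture and computes every layer's output shape under
#' same/ceil padding: convolution and pooling temporal lengths are
#' `ceil(input / stride)`, channel counts follow the filter counts, GAP
#' collapses the temporal axis to one value per channel, dense layers
#' output their unit count.
#'
#' @param spec An [architecture_spec()].
#' @return Data frame with columns `layer`, `kind`, `length`, `channels`.
#'   For GAP and later layers `length` is 1 and `channels` is the vector
#'   width.
#' @export
derive_shapes <- function(spec) {
  if (!inherits(spec, "architecture_spec")) {
    stop_invalid("spec must be an architecture_spec")
  }
  len <- spec$input_length
  ch <- 1L
  flat <- FALSE
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    switch(ly$kind,
      conv1d = {
        if (flat) stop_invalid("conv1d after flattening at layer ", i)
        len <- as.integer(ceiling(len / ly$stride))
        ch <- ly$filters
      },
      maxpool1d = {
        if (flat) stop_invalid("maxpool1d after flattening at layer ", i)
        len <- as.integer(ceiling(len / ly$stride))
      },
      gap = {
        flat <- TRUE
        len <- 1L
      },
      dense = {
        if (!flat) stop_invalid("dense requires a flattened input at layer ", i)
        ch <- ly$units
      },
      relu = NULL, dropout = NULL, sigmoid = NULL
    )
    if (len < 1L) stop_invalid("layer ", i, " produces a non-positive length")
    rows[[i]] <- data.frame(layer = i, kind = ly$kind, length = len, channels = ch)
  }
  do.call(rbind, rows)
}

#' Count trainable parameters per layer
#'
#' Convolutions contribute `filters * kernel * in_channels + filters`
#' (weights + biases), dense layers `units * in_dim + units`; ReLU,
#' pooling, dropout, GAP and sigmoid have none.
#'
#' @param spec An [architecture_spec()].
#' @return List with `per_layer` (integer vector, one entry per layer)
#'   and `total`.
#' @export
count_parameters <- function(spec) {
  shapes <- derive_shapes(spec)
  in_ch <- 1L
  per_layer <- integer(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv1d") {
      per_layer[i] <- ly$filters * ly$kernel * in_ch + ly$filters
    } else if (ly$kind == "dense") {
      per_layer[i] <- ly$units * in_ch + ly$units
    }
    in_ch <- shapes$channels[i]
  }
  list(per_layer = per_layer, total = sum(per_layer))
}
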