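#' Backbone configuration for the frame classifier
#'
#' Describes the convolutional network that maps a preprocessed frame to a
#' vector of class logits. Two architectures are available: `"small_cnn"`,
#' a compact four-block network with group normalisation that trains from
#' scratch on one CPU, and `"resnet50_v2"`, a pre-activation bottleneck
#' ResNet with group normalisation and weight standardisation for
#' full-scale replication on accelerated hardware.
#'
#' With `outlier_exposure = TRUE` the network carries one extra output
#' logit for the collapsed outlier class; view predictions and max-logit
#' scores always ignore that slot.
#'
#' @param architecture `"small_cnn"` or `"resnet50_v2"`.
#' @param num_classes Number of known view classes C (>= 2).
#' @param outlier_exposure Add one extra logit for a collapsed outlier
#'   class.
#' @param normalization `"group_norm_ws"` (group normalisation; weight
#'   standardisation on convolutions for the ResNet) or `"batch_norm"`.
#' @param input_size Side length in pixels of the square input frames.
#' @param embedding_dim Dimension D of the penultimate (post global
#'   average pooling) feature vector. Defaults to 128 for the small CNN
#'   and 2048 for the ResNet.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(architecture = c("small_cnn", "resnet50_v2"),
                            num_classes = 10L,
                            outlier_exposure = FALSE,
                            normalization = c("group_norm_ws", "batch_norm"),
                            input_size = 64L,
                            embedding_dim = NULL) {
  architecture <- match.arg(architecture)
  normalization <- match.arg(normalization)
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (is.null(embedding_dim))
    embedding_dim <- if (architecture == "small_cnn") 128L else 2048L
  if (embedding_dim < 8) stop("embedding_dim must be >= 8")
  structure(list(architecture = architecture,
                 num_classes = as.integer(num_classes),
                 outlier_exposure = isTRUE(outlier_exposure),
                 normalization = normalization,
                 input_size = as.integer(input_size),
                 embedding_dim = as.integer(embedding_dim)),
            class = "backbone_config")
}

norm_layer_for <- function(cfg, channels) {
  if (cfg$normalization == "batch_norm") nn_batch_norm(channels)
  else nn_group_norm(channels, groups = 4L)
}

#' Build an initialised frame-classifier model
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A model object (list of layers plus the configuration) usable
#'   with [forward_frames()] and [train_classifier()].
#' @export
build_backbone <- function(config, seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  nlogits <- config$num_classes + as.integer(config$outlier_exposure)
  layers <- with_seed(seed, {
    if (config$architecture == "small_cnn") {
      D <- config$embedding_dim
      list(nn_conv(5L, 5L, 1L, 12L, stride = 2L, pad = 2L),
           norm_layer_for(config, 12L), nn_relu(),
           nn_conv(3L, 3L, 12L, 24L, stride = 2L, pad = 1L),
           norm_layer_for(config, 24L), nn_relu(),
           nn_conv(3L, 3L, 24L, 48L, stride = 2L, pad = 1L),
           norm_layer_for(config, 48L), nn_relu(),
           nn_conv(3L, 3L, 48L, D, stride = 2L, pad = 1L),
           norm_layer_for(config, D), nn_relu(),
           nn_gap(),
           nn_linear(D, nlogits))
    } else {
      ws <- config$normalization == "group_norm_ws"
      stages <- list(c(3L, 64L, 256L, 1L), c(4L, 128L, 512L, 2L),
                     c(6L, 256L, 1024L, 2L), c(3L, 512L, 2048L, 2L))
      layers <- list(nn_conv(7L, 7L, 1L, 64L, stride = 2L, pad = 3L,
                             weight_standardization = ws),
                     nn_maxpool(3L, 2L, 1L))
      cin <- 64L
      for (st in stages) {
        nblocks <- st[1]; cmid <- st[2]; cout <- st[3]; stride <- st[4]
        for (b in seq_len(nblocks)) {
          layers[[length(layers) + 1L]] <-
            nn_resblock(cin, cmid, cout,
                        stride = if (b == 1L) stride else 1L,
                        weight_standardization = ws)
          cin <- cout
        }
      }
      layers[[length(layers) + 1L]] <- norm_layer_for(config, cin)
      layers[[length(layers) + 1L]] <- nn_relu()
      layers[[length(layers) + 1L]] <- nn_gap()
      layers[[length(layers) + 1L]] <- nn_linear(cin, nlogits)
      layers
    }
  })
  structure(list(layers = layers, config = config, seed = as.integer(seed)),
            class = "openecho_model")
}
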