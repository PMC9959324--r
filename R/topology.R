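#' Declarative CNN topology
#'
#' The four-block spectral-spatial topology: each block is a
#' same-padded convolution (ReLU) followed by 3x3x3 max-pooling with stride
#' 2 and batch normalization, with filter counts doubling 4 -> 8 -> 16 ->
#' 32; a global average pooling layer then feeds a 512-unit ReLU dense
#' layer, 10% dropout, and a single sigmoid output giving the probability
#' of the positive (unhealthy) class.
#'
#' @param filters Filter counts of the four convolution layers.
#' @param kernel Convolution kernel side length (3).
#' @param pool Pooling window side length (3).
#' @param pool_stride Pooling stride (2).
#' @param dense_units Width of the hidden dense layer.
#' @param dropout Dropout rate after the dense layer.
#' @return A `topology_spec` list.
#' @export
topology_spec <- function(filters = c(4, 8, 16, 32), kernel = 3, pool = 3,
                          pool_stride = 2, dense_units = 512, dropout = 0.1) {
  if (length(filters) != 4L)
    hsi_abort("the topology has exactly 4 conv/pool/BN blocks",
              "topology_error")
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), pool_stride = as.integer(pool_stride),
                 dense_units = as.integer(dense_units), dropout = dropout),
            class = "topology_spec")
}

# Per-block geometry: kernel/pool extents and strides along (H, W, D), with
# the spectral axis handled per variant. 3D treats the cube as a
# single-channel volume; when the spectral extent is tiny (an RGB-style
# 3-band input) the kernel depth is capped at the band axis and the spectral
# pooling stride drops to 1. 2D folds the bands into input channels and
# convolves/pools over space only.
net_geometry <- function(spec, input_dims, variant = c("3d", "2d")) {
  variant <- match.arg(variant)
  H <- input_dims[1]; W <- input_dims[2]; B <- input_dims[3]
  if (any(input_dims <= 0))
    hsi_abort("input dimensions must be positive", "topology_error")
  if (variant == "3d") {
    vol <- c(H, W, B); chans <- 1L
    kd <- min(spec$kernel, B)
    pd <- min(spec$pool, B)
    sd_ <- if (B <= 3L) 1L else spec$pool_stride
  } else {
    vol <- c(H, W, 1L); chans <- as.integer(B)
    kd <- 1L; pd <- 1L; sd_ <- 1L
  }
  blocks <- vector("list", 4L)
  in_ch <- chans
  for (i in 1:4) {
    blocks[[i]] <- list(
      kernel = c(spec$kernel, spec$kernel, kd),
      pool = c(spec$pool, spec$pool, pd),
      stride = c(spec$pool_stride, spec$pool_stride, sd_),
      in_ch = in_ch, out_ch = spec$filters[i])
    in_ch <- spec$filters[i]
  }
  list(variant = variant, input_vol = vol, input_ch = chans, blocks = blocks)
}

#' Propagate tensor shapes through the topology
#'
#' Computes the output extent of every layer for a given input: same-padded
#' convolutions preserve spatial/spectral extents, stride-2 same-padded
#' pooling maps each extent d to `ceiling(d / 2)`, global average pooling
#' collapses to the filter count, and the dense layers map to
#' (`dense_units`,) then (1,). For a 100 x 100 x 270 input this reproduces
#' the reference feature-map sizes 50x50x135x4, 25x25x68x8, 13x13x34x16,
#' 7x7x17x32, then 32 / 512 / 1.
#'
#' @param spec A [topology_spec()].
#' @param input_dims Input extents `c(H, W, B)` in pixels/bands.
#' @param variant `"3d"` (cube as single-channel volume) or `"2d"` (bands
#'   as channels).
#' @return A data frame with one row per layer: `layer`, `output` (printed
#'   form), and the numeric extents `d1, d2, d3, channels`.
#' @export
propagate_shapes <- function(spec, input_dims, variant = c("3d", "2d")) {
  variant <- match.arg(variant)
  geom <- net_geometry(spec, input_dims, variant)
  rows <- list()
  add <- function(layer, vol, ch) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer,
      output = if (is.null(vol)) as.character(ch)
               else paste(c(vol, ch), collapse = " x "),
      d1 = if (is.null(vol)) NA_integer_ else vol[1],
      d2 = if (is.null(vol)) NA_integer_ else vol[2],
      d3 = if (is.null(vol)) NA_integer_ else vol[3],
      channels = ch)
  }
  vol <- geom$input_vol
  add("input", vol, geom$input_ch)
  for (i in 1:4) {
    blk <- geom$blocks[[i]]
    add(sprintf("conv%d", i), vol, blk$out_ch)
    vol <- ceiling(vol / blk$stride)
    if (any(vol <= 0))
      hsi_abort("non-positive extent while propagating shapes",
                "topology_error")
    add(sprintf("pool%d", i), vol, blk$out_ch)
    add(sprintf("bn%d", i), vol, blk$out_ch)
  }
  add("gap", NULL, geom$blocks[[4]]$out_ch)
  add("dense", NULL, spec$dense_units)
  add("dropout", NULL, spec$dense_units)
  add("output", NULL, 1L)
  do.call(rbind, rows)
}
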