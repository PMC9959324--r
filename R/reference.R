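#' Brute-force 3D convolution oracle
#'
#' Direct sextuple-sum evaluation of the volumetric convolution: for every
#' output voxel and filter, sums `w[p,q,r,m] * v[x+p, y+q, z+r, m]` over the
#' kernel extents and input feature maps, adds the bias, and applies
#' `f(v) = max(0, v)` when `relu = TRUE`. Zero ("same") padding keeps the
#' output extents equal to the input's. This is a deliberately slow,
#' loop-level reference used to verify the fast im2col/BLAS backend; it is
#' never on the training path.
#'
#' @param input 4-axis array (x, y, z, channels).
#' @param kernels 5-axis array (p, q, r, in-channels, filters); odd extents.
#' @param biases Numeric vector, one per filter.
#' @param relu Apply the ReLU activation.
#' @return 4-axis array (x, y, z, filters).
#' @export
conv3d_reference <- function(input, kernels, biases, relu = TRUE) {
  di <- dim(input); dk <- dim(kernels)
  if (length(di) != 4L || length(dk) != 5L || di[4] != dk[4])
    hsi_abort("input must be (x,y,z,channels) and kernels (p,q,r,channels,filters)",
              "shape_error")
  if (any(dk[1:3] > di[1:3] + dk[1:3] - 1L))
    hsi_abort("kernel larger than padded input", "shape_error")
  H <- di[1]; W <- di[2]; D <- di[3]; C <- di[4]
  kh <- dk[1]; kw <- dk[2]; kd <- dk[3]; F_ <- dk[5]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2; pd <- (kd - 1) %/% 2
  out <- array(0, c(H, W, D, F_))
  for (f in seq_len(F_)) {
    for (z in seq_len(D)) for (y in seq_len(W)) for (x in seq_len(H)) {
      acc <- biases[f]
      for (m in seq_len(C)) for (r in seq_len(kd)) for (q in seq_len(kw))
        for (p in seq_len(kh)) {
          xi <- x + p - 1L - ph; yi <- y + q - 1L - pw; zi <- z + r - 1L - pd
          if (xi >= 1L && xi <= H && yi >= 1L && yi <= W &&
              zi >= 1L && zi <= D)
            acc <- acc + kernels[p, q, r, m, f] * input[xi, yi, zi, m]
        }
      out[x, y, z, f] <- if (relu) max(0, acc) else acc
    }
  }
  out
}
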