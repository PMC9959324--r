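#' Focal loss parameters
#'
#' The (gamma, alpha) pair of the class-balanced focal loss: `gamma >= 0`
#' is the focusing parameter down-weighting well-classified examples, and
#' `alpha` in \[0, 1\] is the class weighting factor applied to the positive
#' class (`1 - alpha` to the negative). `alpha = NULL` disables class
#' weighting (plain cross-entropy when `gamma = 0`).
#'
#' @param gamma Focusing parameter, `>= 0`.
#' @param alpha Positive-class weight in \[0, 1\], or `NULL` for none.
#' @return A `focal_loss_params` list.
#' @export
focal_loss_params <- function(gamma = 2, alpha = 0.5) {
  if (!is.numeric(gamma) || gamma < 0)
    hsi_abort("gamma must be >= 0", "parameter_error")
  if (!is.null(alpha) && (alpha < 0 || alpha > 1))
    hsi_abort("alpha must lie in [0, 1]", "parameter_error")
  structure(list(gamma = gamma, alpha = alpha), class = "focal_loss_params")
}

#' Loss-family shorthand
#'
#' Builds [focal_loss_params()] for the three members of the cross-entropy
#' family: `"CE"` (plain cross-entropy: `gamma = 0`, no class weight),
#' `"BCE"` (balanced cross-entropy: `gamma = 0` with weight `alpha`), and
#' `"FL"` (focal loss with `gamma` and `alpha`).
#'
#' @param type One of `"CE"`, `"BCE"`, `"FL"`.
#' @param gamma,alpha See [focal_loss_params()]; ignored where the family
#'   member fixes them.
#' @return A `focal_loss_params`.
#' @export
loss_spec <- function(type = c("FL", "BCE", "CE"), gamma = 2, alpha = 0.5) {
  type <- match.arg(type)
  switch(type,
         CE = focal_loss_params(gamma = 0, alpha = NULL),
         BCE = focal_loss_params(gamma = 0, alpha = alpha),
         FL = focal_loss_params(gamma = gamma, alpha = alpha))
}

# Numerical floor keeping log(p_t) finite; probabilities are clamped to
# [CLAMP, 1 - CLAMP] inside the loss.
P_CLAMP <- 1e-7

#' Class-balanced focal loss
#'
#' For predicted positive-class probability `p` and ground truth
#' `y in {-1, 1}`, computes `p_t = p` if `y = 1` else `1 - p`, the class
#' weight `a_t = alpha` if `y = 1` else `1 - alpha` (1 when `alpha` is
#' NULL), and returns `-a_t * (1 - p_t)^gamma * log(p_t)` per sample.
#' With `gamma = 0` this reduces to (balanced) cross-entropy. The batch
#' loss used in training is the mean over samples.
#'
#' @param p Predicted probabilities in \[0, 1\] (vectorized).
#' @param y Ground-truth classes in `{-1, 1}` (1 = unhealthy/positive).
#' @param params A [focal_loss_params()].
#' @return Per-sample non-negative losses.
#' @export
focal_loss <- function(p, y, params = focal_loss_params()) {
  stopifnot(inherits(params, "focal_loss_params"))
  if (!all(y %in% c(-1, 1)))
    hsi_abort("y must contain only -1 and 1", "parameter_error")
  pt <- ifelse(y == 1, p, 1 - p)
  pt <- pmin(pmax(pt, P_CLAMP), 1 - P_CLAMP)
  at <- if (is.null(params$alpha)) 1
        else ifelse(y == 1, params$alpha, 1 - params$alpha)
  -at * (1 - pt)^params$gamma * log(pt)
}

# d(loss)/d(logit) for a sigmoid output, mean-reduced over the batch by the
# caller. Derivation: dL/dp_t = a_t [gamma (1-p_t)^(gamma-1) log(p_t)
# - (1-p_t)^gamma / p_t], dp_t/dlogit = +/- p_t (1 - p_t).
focal_loss_grad_logit <- function(p, y, params) {
  pt <- ifelse(y == 1, p, 1 - p)
  pt <- pmin(pmax(pt, P_CLAMP), 1 - P_CLAMP)
  at <- if (is.null(params$alpha)) 1
        else ifelse(y == 1, params$alpha, 1 - params$alpha)
  g <- params$gamma
  dl_dpt <- if (g == 0) -at / pt
            else at * (g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt)
  s <- ifelse(y == 1, 1, -1)
  dl_dpt * s * pt * (1 - pt)
}
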