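# Small builders shared across test files. Everything is generated in code;
# no fixture files.

# evenly spaced wavelength grid over [lo, hi]
wl_grid <- function(n, lo = 400, hi = 800) seq(lo, hi, length.out = n)

# deterministic small cube with distinguishable values
toy_cube <- function(h = 6, w = 5, b = 4, calibrated = FALSE,
                     wl = wl_grid(b)) {
  hsi_cube(array(seq_len(h * w * b) / (h * w * b), c(h, w, b)), wl,
           calibrated = calibrated)
}

# a patch made from a constant spectrum
flat_patch <- function(S, value, b = 4, wl = wl_grid(b),
                       case_id = "c1", label = "unhealthy") {
  structure(list(values = array(value, c(S, S, b)),
                 origin = c(row = 0, col = 0),
                 case_id = case_id, label = label, wavelengths = wl),
            class = "hsi_patch")
}

# patches whose class is encoded in band means, linearly separable
separable_patches <- function(n_per_class, S = 16, b = 10, gap = 0.2,
                              noise = 0.02, seed = 99, cases = 4) {
  set.seed(seed)
  out <- list()
  for (cls in c("healthy", "unhealthy")) {
    base <- if (cls == "unhealthy") 0.5 + gap else 0.5 - gap
    for (i in seq_len(n_per_class)) {
      v <- array(base + rnorm(S * S * b, sd = noise), c(S, S, b))
      out[[length(out) + 1L]] <- structure(
        list(values = v, origin = c(row = 0, col = 0),
             case_id = sprintf("%s_case%d", cls, 1 + (i %% cases)),
             label = cls, wavelengths = wl_grid(b)),
        class = "hsi_patch")
    }
  }
  out
}

# per-sample brute-force metrics oracle, independent of compute_metrics
oracle_metrics <- function(y_true, y_pred) {
  pos <- "unhealthy"
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == pos && y_pred[i] == pos) tp <- tp + 1
    else if (y_true[i] != pos && y_pred[i] != pos) tn <- tn + 1
    else if (y_true[i] != pos && y_pred[i] == pos) fp <- fp + 1
    else fn <- fn + 1
  }
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

# binomial smoothing that exactly nulls band-to-band alternation
smooth_spectrum <- function(v) as.numeric(stats::filter(v, c(1, 2, 1) / 4))

# locate whether a smoothed spectrum has a local minimum within +-tol nm of
# a target wavelength
has_dip_near <- function(spectrum, wl, target, tol = 10) {
  s <- smooth_spectrum(spectrum)
  idx <- which(abs(wl - target) <= tol)
  any(vapply(idx, function(i) {
    i > 1 && i < length(s) && !is.na(s[i - 1]) && !is.na(s[i + 1]) &&
      s[i] < s[i - 1] && s[i] < s[i + 1]
  }, logical(1)))
}

# desk-profile experiment configuration used by the end-to-end tests
desk_experiment <- function(variant = "HSI", seed = 1, conv = "3d",
                            loss = loss_spec("FL", 2, 0.5)) {
  experiment_config(variant = variant, S = 32, conv = conv, loss = loss,
                    train = train_config(profile = "desk"), seed = seed)
}
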