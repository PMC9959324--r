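#' Case-level split assignment
#'
#' Randomly assigns cases to train/validation/test under per-split class
#' count constraints (default: 1 healthy + 9 unhealthy cases per split, the
#' three-way even division of a 3 + 27 case cohort). Splitting is always by
#' case, never by patch or image, so tissue from one patient can never
#' appear on both sides of a fit.
#'
#' @param cases Data frame with columns `case_id` and `label`.
#' @param counts Named counts per split, e.g.
#'   `list(train = c(healthy = 1, unhealthy = 9), val = ..., test = ...)`;
#'   the default uses 1/9 for all three splits.
#' @param seed RNG seed for the assignment.
#' @return A `split_plan`: data frame `case_id`, `label`, `role` with
#'   attribute `rotation = 1`.
#' @export
split_by_case <- function(cases, counts = NULL, seed = 1L) {
  if (is.null(counts))
    counts <- list(train = c(healthy = 1, unhealthy = 9),
                   val = c(healthy = 1, unhealthy = 9),
                   test = c(healthy = 1, unhealthy = 9))
  cases <- unique(cases[, c("case_id", "label")])
  if (nrow(cases) < 3L)
    hsi_abort("need at least 3 cases to form three splits", "split_error")
  for (lab in c("healthy", "unhealthy")) {
    need <- sum(vapply(counts, function(ct) ct[[lab]], 0))
    have <- sum(cases$label == lab)
    if (need != have)
      hsi_abort(sprintf("split counts need %d %s cases but %d exist",
                        need, lab, have), "config_error")
  }
  set.seed(seed)
  plan <- data.frame(case_id = cases$case_id, label = cases$label,
                     role = NA_character_, stringsAsFactors = FALSE)
  for (lab in c("healthy", "unhealthy")) {
    ids <- sample(cases$case_id[cases$label == lab])
    off <- 0L
    for (role in names(counts)) {
      n <- counts[[role]][[lab]]
      if (n > 0)
        plan$role[match(ids[(off + 1L):(off + n)], plan$case_id)] <- role
      off <- off + n
    }
  }
  structure(plan, rotation = 1L, class = c("split_plan", "data.frame"))
}

#' Cyclic rotation of split roles
#'
#' Produces the three split configurations obtained by rotating roles
#' train -> val -> test -> train; a case that is in the test split of
#' configuration 1 trains configuration 2. All three configurations remain
#' case-disjoint by construction. Rotating three times returns the
#' original plan.
#'
#' @param plan A `split_plan` from [split_by_case()].
#' @return A list of three `split_plan`s (rotations 1, 2, 3).
#' @export
rotate_splits <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  step <- c(train = "val", val = "test", test = "train")
  out <- vector("list", 3L)
  cur <- plan
  for (r in 1:3) {
    attr(cur, "rotation") <- r
    out[[r]] <- cur
    nxt <- cur
    nxt$role <- unname(step[cur$role])
    cur <- nxt
  }
  out
}

#' Experiment configuration
#'
#' One point of the experiment grid: spectral representation, patch size,
#' loss family, convolution variant, and training schedule.
#'
#' @param variant Spectral representation: `"HSI"` (all bands), `"HSI-k"`
#'   (constant-stride sampling to k bands), `"PCA-k"` (k principal
#'   components fitted on training pixels), or `"RGB"` (Gaussian-synthesized
#'   three-band rendering).
#' @param S Patch side in pixels.
#' @param loss A [focal_loss_params()] / [loss_spec()].
#' @param conv `"3d"` or `"2d"`.
#' @param train A [train_config()].
#' @param max_blank Blank-fraction rejection threshold.
#' @param band_window Optional `c(lo, hi)` nm window applied before
#'   reduction.
#' @param seed Seed controlling model initialization and training.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(variant = "HSI", S = 32,
                              loss = loss_spec("FL", 2, 0.5),
                              conv = c("3d", "2d"),
                              train = train_config(),
                              max_blank = 0.5, band_window = NULL,
                              seed = 1L) {
  conv <- match.arg(conv)
  structure(list(variant = variant, S = as.integer(S), loss = loss,
                 conv = conv, train = train, max_blank = max_blank,
                 band_window = band_window, seed = as.integer(seed)),
            class = "experiment_config")
}

# Parse a variant string into a reducer description.
parse_variant <- function(variant, n_bands) {
  if (is.list(variant)) return(variant)
  if (identical(variant, "HSI")) return(list(mode = "full"))
  if (identical(variant, "RGB")) return(list(mode = "rgb"))
  m <- regmatches(variant, regexec("^HSI-([0-9]+)$", variant))[[1]]
  if (length(m) == 2L) return(list(mode = "sample", k = as.integer(m[2])))
  m <- regmatches(variant, regexec("^PCA-([0-9]+)$", variant))[[1]]
  if (length(m) == 2L) return(list(mode = "pca", k = as.integer(m[2])))
  hsi_abort(sprintf("unknown dataset variant '%s'", variant), "config_error")
}

#' Run one experiment end to end
#'
#' Pipeline: optional band-window crop, spectral reduction per the
#' configured variant (a PCA reducer is fitted on training-split pixels
#' only), patch tiling, blank filtering (blank fractions always measured on
#' the pre-reduction cube), case-disjoint assembly of the three splits,
#' training, and a single final evaluation on the held-out test cases.
#'
#' @param cfg An [experiment_config()].
#' @param data A `phantom_dataset`, or a list of samples each holding
#'   `cube` (calibrated [hsi_cube()]), `case_id`, `label`, and optionally
#'   `split`.
#' @param plan Optional `split_plan`; defaults to the dataset's own split
#'   assignment, or a fresh [split_by_case()] draw under `cfg$seed`.
#' @return An `experiment_result`: `config`, `metrics` (test split),
#'   `metrics_val`, `metrics_train`, `history`, `model`, and patch counts.
#' @export
run_experiment <- function(cfg, data, plan = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  samples <- if (inherits(data, "phantom_dataset")) data$samples else data
  if (length(samples) == 0L) hsi_abort("no samples", "input_error")

  roles <- sample_roles(samples, plan, cfg$seed)
  train_cases <- unique(vapply(samples[roles == "train"], `[[`, "", "case_id"))
  test_cases <- unique(vapply(samples[roles == "test"], `[[`, "", "case_id"))
  val_cases <- unique(vapply(samples[roles == "val"], `[[`, "", "case_id"))
  if (length(intersect(test_cases, c(train_cases, val_cases))) ||
      length(intersect(train_cases, val_cases)))
    hsi_abort("case overlap between splits", "leakage_error")

  cubes <- lapply(samples, function(s) {
    if (is.null(cfg$band_window)) s$cube
    else crop_band_window(s$cube, cfg$band_window[1], cfg$band_window[2])
  })
  red <- parse_variant(cfg$variant, dim(cubes[[1]]$values)[3])
  pca_model <- NULL
  if (identical(red$mode, "pca")) {
    pca_model <- fit_pca(cubes[roles == "train"], n_components = red$k)
  }
  reduce <- function(cube) switch(red$mode,
    full = cube,
    sample = sample_bands(cube, red$k),
    pca = apply_pca(pca_model, cube),
    rgb = synthesize_rgb(cube),
    hsi_abort("unknown reducer mode", "config_error"))

  split_patches <- list(train = list(), val = list(), test = list())
  n_removed <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    thr <- blank_threshold(cubes[[i]])
    raw_patches <- extract_patches(cubes[[i]], cfg$S, s$case_id, s$label)
    keep <- filter_blank_patches(raw_patches, thr, cfg$max_blank)$kept_idx
    n_removed <- n_removed + length(raw_patches) - length(keep)
    red_patches <- if (identical(red$mode, "full")) raw_patches
      else extract_patches(reduce(cubes[[i]]), cfg$S, s$case_id, s$label)
    split_patches[[roles[i]]] <-
      c(split_patches[[roles[i]]], red_patches[keep])
  }

  B <- dim(split_patches$train[[1]]$values)[3]
  model <- build_classifier(c(cfg$S, cfg$S, B), cfg$conv, seed = cfg$seed)
  model <- train_classifier(model, split_patches$train, split_patches$val,
                            loss = cfg$loss,
                            cfg = replace_seed(cfg$train, cfg$seed))
  eval_split <- function(patches) {
    if (length(patches) == 0L) return(NULL)
    pr <- predict_patches(model, patches)
    compute_metrics(confusion_from_labels(pr$truth, pr$pred))
  }
  structure(list(config = cfg,
                 metrics = eval_split(split_patches$test),
                 metrics_val = eval_split(split_patches$val),
                 metrics_train = eval_split(split_patches$train),
                 history = model$history,
                 model = model,
                 n_patches = vapply(split_patches, length, 0L),
                 n_blank_removed = n_removed,
                 pca = pca_model),
            class = "experiment_result")
}

replace_seed <- function(tc, seed) { tc$seed <- as.integer(seed); tc }

sample_roles <- function(samples, plan, seed) {
  if (is.null(plan)) {
    has_split <- !vapply(samples, function(s) is.null(s$split), TRUE)
    if (all(has_split))
      return(vapply(samples, `[[`, "", "split"))
    cases <- data.frame(
      case_id = vapply(samples, `[[`, "", "case_id"),
      label = vapply(samples, `[[`, "", "label"))
    plan <- split_by_case(cases, seed = seed)
  }
  role <- plan$role[match(vapply(samples, `[[`, "", "case_id"),
                          plan$case_id)]
  if (any(is.na(role)))
    hsi_abort("samples with cases missing from the split plan",
              "config_error")
  role
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s %s S=%d | test: ",
              x$config$variant, toupper(x$config$conv), x$config$S))
  if (!is.null(x$metrics)) print(x$metrics) else cat("(no test split)\n")
  invisible(x)
}

#' Run a grid of experiments
#'
#' Executes each configuration sequentially; failures are recorded per row
#' and do not stop the grid. The returned table mirrors the standard
#' results layout: configuration columns then the five metrics.
#'
#' @param grid Non-empty list of [experiment_config()]s.
#' @param data Dataset passed to [run_experiment()].
#' @param plan Optional shared `split_plan`.
#' @return A data frame with one row per configuration, and the full
#'   `experiment_result`s in `attr(, "results")`.
#' @export
run_grid <- function(grid, data, plan = NULL) {
  if (length(grid) == 0L) hsi_abort("empty experiment grid", "input_error")
  results <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    res <- tryCatch(run_experiment(cfg, data, plan), error = identity)
    results[[i]] <- res
    base <- data.frame(
      variant = if (is.list(cfg$variant)) cfg$variant$mode else cfg$variant,
      conv = cfg$conv, S = cfg$S,
      gamma = cfg$loss$gamma, alpha = cfg$loss$alpha %||% NA_real_,
      seed = cfg$seed)
    if (inherits(res, "error")) {
      rows[[i]] <- cbind(base, data.frame(
        error = conditionMessage(res), accuracy = NA_real_,
        precision = NA_real_, recall = NA_real_, f1 = NA_real_,
        mcc = NA_real_))
    } else {
      m <- res$metrics
      rows[[i]] <- cbind(base, data.frame(
        error = NA_character_, accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1, mcc = m$mcc))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
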