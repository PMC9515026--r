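# Training: label-biased patch sampling, joint augmentation, per-level
# losses (softmax cross-entropy for large labels, top-K BCE for small ones,
# all levels weighted equally) and Adam. Fully reproducible under the
# config seed.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param patch_budget Total number of patches to consume; one stack of
#'   depth D consumes D patches (default 2e6, the full-scale setting; toy
#'   runs override).
#' @param batch_size Patch stacks per optimisation step (default 8).
#' @param label_hit_fraction Fraction of finest patches that must contain at
#'   least one label (default 0.8).
#' @param augment A [augment_spec()] (or `NULL` to disable augmentation).
#' @param top_k Voxels kept per small label per patch; default `NULL` means
#'   5 percent of the patch volume (1638 for a 32^3 matrix).
#' @param seed Integer seed controlling initialisation, sampling,
#'   augmentation and therefore the entire run.
#' @param group_labels Label ids this network segments; default `NULL` means
#'   every label present in the training label maps.
#' @param small Logical per group label (small/large regime). Default `NULL`
#'   applies the heuristic: a label is small if its mean foreground fraction
#'   per volume is below `1e-4`.
#' @return A `pp_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, patch_budget = 2e6, batch_size = 8L,
                         label_hit_fraction = 0.8, augment = augment_spec(),
                         top_k = NULL, seed = 1L, group_labels = NULL, small = NULL) {
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(patch_budget >= batch_size, "patch_budget must cover one batch")
  structure(list(learning_rate = learning_rate, patch_budget = patch_budget,
                 batch_size = as.integer(batch_size),
                 label_hit_fraction = label_hit_fraction, augment = augment,
                 top_k = top_k, seed = as.integer(seed),
                 group_labels = group_labels, small = small),
            class = "pp_train_config")
}

# Adam over an arbitrarily nested list of numeric leaves
adam_init <- function(params) rapply(params, function(x) {
  if (is.numeric(x)) list(m = 0 * x, v = 0 * x) else x
}, how = "replace", classes = c("numeric", "matrix", "array"))

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      m <- beta1 * s$m + (1 - beta1) * g
      v <- beta2 * s$v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
    } else if (is.list(p)) {
      out_p <- p; out_s <- s
      # match by name where names exist (gradients omit e.g. the spec),
      # by position in unnamed stage lists
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
              else seq_along(p)
      for (nm in keys) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else list(p = p, s = s)
  }
  walk(params, grads, state)
}

#' Train one model stack on a label group
#'
#' Each optimisation step samples `batch_size` label-biased centres, extracts
#' jointly augmented image and label stacks, runs the batched forward pass,
#' accumulates per-level losses (equal weights across levels) and takes one
#' Adam step. All volumes must share grid shape and spacing (resample first).
#'
#' @param data List of `list(volume =, labels =)` training pairs.
#' @param cfg A [train_config()].
#' @param pyramid A [scale_pyramid_spec()].
#' @param bank A [window_bank()].
#' @return A trained `pp_model_stack`; attribute `"loss_trace"` holds a
#'   data.frame of per-step total losses.
#' @export
train_stack <- function(data, cfg, pyramid, bank = default_bank()) {
  assert_that(length(data) >= 1, "need at least one training volume")
  shp <- dim(data[[1]]$volume$data)
  for (d in data) {
    assert_that(identical(dim(d$volume$data), shp) &&
                identical(dim(d$labels$data), shp),
                "all training volumes must share one grid shape")
  }
  present <- sort(unique(unlist(lapply(data, function(d) unique(as.integer(d$labels$data))))))
  present <- present[present > 0L]
  group_labels <- sort(as.integer(cfg$group_labels %||% present))
  assert_that(length(group_labels) >= 1, "empty label group")
  small <- cfg$small %||% small_heuristic(data, group_labels)
  M <- pyramid$matrix
  D <- pyramid$depth
  K <- as.integer(cfg$top_k %||% max(1, round(0.05 * M^3)))
  scales <- compute_scales(pyramid, grid_extent_mm(data[[1]]$volume))
  steps <- ceiling(cfg$patch_budget / (cfg$batch_size * D))
  params <- model_stack_init(pyramid, group_labels, small, bank = bank,
                             seed = subseed(cfg$seed, "init"))
  state <- list(levels = lapply(params$levels, adam_init))
  trace <- numeric(steps)
  patch_mm <- M * pyramid$finest_mm
  with_seed(subseed(cfg$seed, "train"), {
    for (step in seq_len(steps)) {
      vol_idx <- sample.int(length(data), cfg$batch_size, replace = TRUE)
      stacks <- vector("list", cfg$batch_size)
      lstacks <- vector("list", cfg$batch_size)
      for (b in seq_len(cfg$batch_size)) {
        dat <- data[[vol_idx[b]]]
        ctr <- sample_training_centers(dat$labels, 1L, patch_mm,
                                       cfg$label_hit_fraction)
        stacks[[b]] <- extract_stack(dat$volume, ctr[1, ], scales, M,
                                     augment = cfg$augment)
        lstacks[[b]] <- extract_label_stack(dat$labels, ctr[1, ], scales, M,
                                            transform = stacks[[b]]$transform)
      }
      fw <- forward_stack_batch(params, stacks, keep_cache = TRUE)
      total <- 0
      d_outputs <- vector("list", D)
      for (i in seq_len(D)) {
        lab_i <- vapply(lstacks, function(s) as.integer(s$levels[[i]]$data),
                        integer(M^3))
        lg <- large_loss_grad(fw$outputs[[i]], as.integer(lab_i), params)
        total <- total + lg$loss
        dout <- lg$dout
        if (any(params$small)) {
        B <- cfg$batch_size
          dm <- matrix(dout, dim(dout)[1])
          for (b in seq_len(B)) {
            zb <- matrix(fw$outputs[[i]][, , , , b], dim(dout)[1])
            tk <- topk_loss_grad_patch(zb, lab_i[, b], params, K)
            total <- total + tk$loss / B
            cols <- (b - 1L) * M^3 + seq_len(M^3)
            dm[, cols] <- dm[, cols] + tk$dz / B
          }
          dout <- array(dm, dim(dout))
        }
        d_outputs[[i]] <- dout
      }
      grads <- backward_stack_batch(params, fw, d_outputs)
      for (i in seq_len(D)) {
        upd <- adam_step(params$levels[[i]], grads[[i]], state$levels[[i]],
                         cfg$learning_rate, step)
        params$levels[[i]] <- upd$p
        state$levels[[i]] <- upd$s
      }
      trace[step] <- total
    }
  })
  attr(params, "loss_trace") <- data.frame(step = seq_len(steps), loss = trace)
  attr(params, "top_k") <- K
  params
}

# a label is "small" if its mean foreground fraction per volume is tiny
small_heuristic <- function(data, group_labels, threshold = 1e-4) {
  fr <- vapply(group_labels, function(id) {
    mean(vapply(data, function(d) mean(d$labels$data == id), numeric(1)))
  }, numeric(1))
  fr < threshold
}
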