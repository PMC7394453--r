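#' Dual-branch truth/difference training loss
#'
#' For a single-blip sample the loss is the masked MSE between the
#' synthesized and undistorted b0.  For a dual-blip sample both syntheses
#' are compared to the truth (the mean of the two masked MSEs is the
#' "truth" loss, a bias term) and to each other (masked MSE between the two
#' outputs, the "difference" loss, a variance term); the total is their
#' sum:  `(MSE1 + MSE2)/2 + MSE_diff`.
#'
#' @param outputs list of one or two synthesized volumes (3D arrays,
#'   `b0_volume`s, or plain vectors).
#' @param truth undistorted b0 (same forms accepted).
#' @param mask binary mask (same forms); losses use mask voxels only.
#' @return object of class `loss_report`: list(`truth_losses`, `diff_loss`
#'   (`NA` for single blip), `total`).
#' @export
compute_loss <- function(outputs, truth, mask) {
  as_vec <- function(v) {
    if (inherits(v, "b0_volume")) as.vector(v$data) else as.vector(v)
  }
  if (!is.list(outputs)) outputs <- list(outputs)
  if (!length(outputs) %in% 1:2) stop("expected one or two synthesized outputs")
  m <- as_vec(mask) > 0.5
  if (!any(m)) stop("empty loss mask")
  t <- as_vec(truth)[m]
  ys <- lapply(outputs, function(o) as_vec(o)[m])
  truth_losses <- vapply(ys, function(y) mean((y - t)^2), numeric(1))
  if (length(ys) == 2L) {
    diff_loss <- mean((ys[[1]] - ys[[2]])^2)
    total <- mean(truth_losses) + diff_loss
  } else {
    diff_loss <- NA_real_
    total <- truth_losses
  }
  structure(list(truth_losses = truth_losses, diff_loss = diff_loss,
                 total = total), class = "loss_report")
}

#' Training schedule configuration
#'
#' Defaults follow the reference schedule: 100 epochs of Adam at learning
#' rate 1e-4 with betas (0.9, 0.999) and weight decay 1e-5, 5-fold
#' cross-validation, batch size 1 (consistent with instance normalization).
#'
#' @param epochs,learning_rate,adam_betas,weight_decay,folds,batch_size,seed
#'   schedule fields; see defaults.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-4,
                         adam_betas = c(0.9, 0.999), weight_decay = 1e-5,
                         folds = 5L, batch_size = 1L, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning rate must be > 0")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 adam_betas = adam_betas, weight_decay = weight_decay,
                 folds = as.integer(folds), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Partition subjects into cross-validation folds
#'
#' Partitioning is always by subject, never by session or volume: every
#' sample of a subject lands in the same fold, so no subject straddles the
#' train/validation boundary.  Folds are disjoint, covering, and their
#' sizes differ by at most one.
#'
#' @param subject_ids character vector (duplicates allowed; sessions of the
#'   same subject share its fold).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return named integer vector: fold index per unique subject.
#' @export
split_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subjects <- unique(subject_ids)
  if (length(subjects) < k)
    stop("need at least ", k, " subjects for ", k, " folds, got ",
         length(subjects))
  with_seed(seed, {
    shuffled <- sample(subjects)
    folds <- rep_len(seq_len(k), length(shuffled))
    stats::setNames(folds[match(subjects, shuffled)], subjects)
  })
}

#' Carve out a withheld test set, then fold the remaining learning set
#'
#' @param subject_ids character vector of subjects (duplicates allowed).
#' @param n_test number of test subjects, withheld before folding.
#' @param k folds for the learning set.
#' @param seed seed for both draws.
#' @return list(`test` subject ids, `folds` named vector as [split_folds()]).
#' @export
split_cohort <- function(subject_ids, n_test, k = 5L, seed = 1L) {
  subjects <- unique(subject_ids)
  if (n_test >= length(subjects)) stop("test set would consume all subjects")
  test <- with_seed(seed, sample(subjects, n_test))
  learn <- setdiff(subjects, test)
  list(test = test, folds = split_folds(learn, k = k, seed = seed + 1L))
}

# --- sample preparation -----------------------------------------------------

#' Prepare a simulated subject for training or inference
#'
#' Applies the preprocessing contracts: T1 mapped from 0-150 to [-1, 1],
#' b0 blips and truth scaled by the shared 99th percentile of the distorted
#' intensities.  The loss mask is the whole-volume *sampling* mask (the
#' intersection of resampling-validity masks, see [make_sampling_mask()]),
#' not the head mask: the network must also learn the background, which
#' keeps the synthesized volume usable as a field-estimation reference.
#' Phantoms are generated directly on the working grid, so their validity
#' masks are all-ones; a `validity` element on the sample overrides this
#' for resampled real data.  The anatomical head mask is carried along
#' separately for evaluation.
#'
#' @param sample a `subject_sample`.
#' @return list(`subject`, `gd`, `t1` (vector), `blips` (list of vectors),
#'   `truth` (vector), `mask` (logical loss-mask vector), `head_mask`
#'   (logical vector), `norm`, `pe` list).
#' @export
prepare_sample <- function(sample) {
  stopifnot(inherits(sample, "subject_sample"))
  nb <- normalize_b0_pair(lapply(sample$blips, `[[`, "vol"),
                          others = list(truth = sample$b0_u))
  V <- prod(dim(sample$t1$data))
  loss_mask <- if (!is.null(sample$validity))
    as.vector(sample$validity$data) > 0.5 else rep(TRUE, V)
  list(subject = sample$subject_id %||% "sub-000",
       gd = dim(sample$t1$data),
       t1 = as.vector(normalize_t1(sample$t1)$data),
       blips = lapply(nb$b0_d, function(v) as.vector(v$data)),
       truth = as.vector(nb$others$truth$data),
       mask = loss_mask,
       head_mask = as.vector(sample$mask$data) > 0.5,
       norm = nb$norm,
       pe = lapply(sample$blips, `[[`, "pe"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas, weight_decay) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]; eps <- 1e-8
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- per-sample forward/backward -------------------------------------------

sample_loss_and_grads <- function(model, prep, with_grads = TRUE) {
  gd <- prep$gd
  m <- prep$mask
  Nm <- sum(m)
  t <- prep$truth
  ys <- list(); tapes <- list()
  for (i in seq_along(prep$blips)) {
    X <- cbind(prep$t1, prep$blips[[i]])
    fw <- unet_forward(model, X, gd, train = with_grads)
    ys[[i]] <- as.vector(fw$y)
    tapes[[i]] <- fw$tape
  }
  report <- compute_loss(ys, t, m)
  if (!with_grads) return(list(report = report))
  grads <- NULL
  if (length(ys) == 1L) {
    dY <- matrix(2 * (ys[[1]] - t) * m / Nm, ncol = 1)
    grads <- unet_backward(model, tapes[[1]], dY)
  } else {
    dY1 <- matrix(((ys[[1]] - t) + 2 * (ys[[1]] - ys[[2]])) * m / Nm, ncol = 1)
    dY2 <- matrix(((ys[[2]] - t) + 2 * (ys[[2]] - ys[[1]])) * m / Nm, ncol = 1)
    g1 <- unet_backward(model, tapes[[1]], dY1)
    g2 <- unet_backward(model, tapes[[2]], dY2)
    grads <- mapply(`+`, g1, g2[names(g1)], SIMPLIFY = FALSE)
  }
  list(report = report, grads = grads)
}

validation_mse <- function(model, preps) {
  mean(vapply(preps, function(p) {
    r <- sample_loss_and_grads(model, p, with_grads = FALSE)$report
    mean(r$truth_losses)
  }, numeric(1)))
}

# --- training ---------------------------------------------------------------

#' Train one cross-validation fold
#'
#' Runs the Adam schedule on the training samples, computing the masked
#' validation truth-MSE after every epoch, and returns the weights from the
#' epoch with minimum validation MSE.  Fully seeded: the weight draw and
#' the per-epoch shuffles derive from `train_cfg$seed` and `fold`, so a
#' rerun reproduces the curves bit-identically on one device.
#'
#' @param train_preps,val_preps lists of prepared samples
#'   ([prepare_sample()]); subjects must not overlap.
#' @param unet_cfg a [unet_config].
#' @param train_cfg a [train_config].
#' @param fold fold index (seeds the weight draw).
#' @param verbose log per-epoch losses.
#' @return list(`model` best `unet_model`, `curves` data.frame(epoch,
#'   train_loss, val_mse), `selected_epoch`).
#' @export
train_fold <- function(train_preps, val_preps, unet_cfg, train_cfg,
                       fold = 1L, verbose = FALSE) {
  tr_sub <- unique(vapply(train_preps, `[[`, character(1), "subject"))
  va_sub <- unique(vapply(val_preps, `[[`, character(1), "subject"))
  if (length(intersect(tr_sub, va_sub)) > 0)
    stop("train and validation subject sets overlap: ",
         paste(intersect(tr_sub, va_sub), collapse = ", "))
  model <- build_unet(unet_cfg, seed = train_cfg$seed + 7919L * fold)
  state <- adam_init(model$params)
  curves <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_mse = numeric())
  best <- list(val = Inf, params = model$params, epoch = 0L)
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- with_seed(train_cfg$seed + 104729L * fold + epoch,
                     sample(length(train_preps)))
    ep_loss <- 0
    for (i in ord) {
      r <- sample_loss_and_grads(model, train_preps[[i]])
      if (!is.finite(r$report$total))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      up <- adam_step(model$params, r$grads, state, train_cfg$learning_rate,
                      train_cfg$adam_betas, train_cfg$weight_decay)
      model$params <- up$params
      state <- up$state
      ep_loss <- ep_loss + r$report$total
    }
    vm <- validation_mse(model, val_preps)
    curves <- rbind(curves, data.frame(epoch = epoch,
                                       train_loss = ep_loss / length(ord),
                                       val_mse = vm))
    if (vm < best$val) best <- list(val = vm, params = model$params, epoch = epoch)
    if (verbose)
      b0_log("fold %d epoch %3d train %.5f val %.5f", fold, epoch,
             ep_loss / length(ord), vm)
  }
  model$params <- best$params
  list(model = model, curves = curves, selected_epoch = best$epoch)
}

#' Train the full k-fold ensemble
#'
#' Assigns learning-set samples to folds by subject, trains one network per
#' fold (fold f validates on the subjects of fold f and trains on the
#' rest), and keeps each fold's minimum-validation weights.
#'
#' @param preps prepared samples of the learning set.
#' @param unet_cfg,train_cfg configurations.
#' @param verbose log progress.
#' @return object of class `fold_ensemble`: list(`models`, `curves`,
#'   `selected_epochs`, `folds`).
#' @export
train_ensemble <- function(preps, unet_cfg, train_cfg, verbose = FALSE) {
  subs <- vapply(preps, `[[`, character(1), "subject")
  folds <- split_folds(subs, k = train_cfg$folds, seed = train_cfg$seed)
  models <- list(); curves <- list(); sel <- integer()
  for (f in seq_len(train_cfg$folds)) {
    val_idx <- folds[subs] == f
    r <- train_fold(preps[!val_idx], preps[val_idx], unet_cfg, train_cfg,
                    fold = f, verbose = verbose)
    models[[f]] <- r$model
    curves[[f]] <- r$curves
    sel[f] <- r$selected_epoch
    if (verbose)
      b0_log("fold %d done: selected epoch %d (val %.5f)", f,
             r$selected_epoch, min(r$curves$val_mse))
  }
  structure(list(models = models, curves = curves, selected_epochs = sel,
                 folds = folds),
            class = "fold_ensemble")
}

#' Synthesize an undistorted b0 with a fold ensemble
#'
#' The voxelwise mean of the fold members' outputs is taken in normalized
#' space, de-normalized back to image units with the stored normalization
#' parameters, and (optionally) resampled back to subject space through the
#' stored grid transform.
#'
#' @param ensemble a `fold_ensemble` (or list of `unet_model`s).
#' @param t1_norm,b0_d_norm normalized working-grid `b0_volume`s / arrays.
#' @param norm normalization parameters (`list(p99 = ...)`) used to return
#'   to image units; `NULL` leaves the output in normalized units.
#' @param transform optional `grid_transform` to invert back to subject
#'   space.
#' @param geom `b0_volume` supplying grid geometry when inputs are arrays.
#' @return `b0_volume`, the synthesized undistorted b0.
#' @export
synthesize_b0 <- function(ensemble, t1_norm, b0_d_norm, norm = NULL,
                          transform = NULL, geom = NULL) {
  models <- if (inherits(ensemble, "fold_ensemble")) ensemble$models else ensemble
  if (length(models) == 0) stop("empty ensemble")
  acc <- NULL
  for (m in models) {
    y <- unet_predict(m, t1_norm, b0_d_norm)
    acc <- if (is.null(acc)) y else acc + y
  }
  avg <- acc / length(models)
  if (is.null(geom) && inherits(t1_norm, "b0_volume")) geom <- t1_norm
  vol <- b0_volume(avg,
                   if (is.null(geom)) c(1, 1, 1) else geom$voxel_size,
                   if (is.null(geom)) NULL else geom$affine)
  if (!is.null(norm)) vol <- denormalize_b0(vol, norm)
  if (!is.null(transform)) vol <- from_working_grid(vol, transform)
  vol
}
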