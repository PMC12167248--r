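#' Optimizer settings for differentiable-rendering alignment
#'
#' Adam is run on the 9 pose parameters with separate learning rates for the
#' translation block (mm scale) and the 6D rotation block (unitless). The
#' defaults for the two learning rates were chosen with
#' [search_learning_rates] on simulated parameterization frames (lowest loss
#' during alignment, averaged over frames).
#'
#' @param lr_translation Adam step scale for the 3 translation parameters
#'   (mm per unit gradient signal).
#' @param lr_rotation Adam step scale for the 6 rotation parameters.
#' @param n_iters maximum iterations per frame.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param patience early stop after this many non-improving iterations
#'   (`Inf` disables early stopping).
#' @return object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(lr_translation = 1.1, lr_rotation = 0.0019,
                               n_iters = 300L, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-8, patience = 50L) {
  if (lr_translation <= 0 || lr_rotation <= 0) stop("learning rates must be > 0")
  if (n_iters < 1L) stop("n_iters must be >= 1")
  structure(list(lr_translation = lr_translation, lr_rotation = lr_rotation,
                 n_iters = as.integer(n_iters), beta1 = beta1, beta2 = beta2,
                 eps = eps, patience = patience),
            class = "optimizer_settings")
}

#' Per-frame alignment result
#'
#' @param best_pose [rigid_pose] at the lowest-loss iteration.
#' @param best_loss the lowest loss seen.
#' @param loss_trace per-iteration losses (the first entry is the loss at
#'   the initialization, so `best_loss <=` the initial loss always).
#' @param iterations_run iterations actually evaluated.
#' @param converged did the optimizer run to completion on a live cue?
#' @param flags character vector of diagnostic flags.
#' @return object of class `alignment_result`.
#' @export
alignment_result <- function(best_pose, best_loss, loss_trace,
                             iterations_run, converged, flags = character()) {
  stopifnot(abs(best_loss - min(loss_trace)) <= 1e-12)
  structure(list(best_pose = best_pose, best_loss = best_loss,
                 loss_trace = loss_trace,
                 iterations_run = as.integer(iterations_run),
                 converged = isTRUE(converged), flags = flags),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment_result: best loss %.3g after %d iterations (initial %.3g)%s\n",
    x$best_loss, x$iterations_run, x$loss_trace[1L],
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' Align a cue to a reference mask by differentiable rendering
#'
#' Minimizes the mean squared error between the soft-rendered cue silhouette
#' and the reference mask over camera pose (Adam on translation + 6D
#' rotation, separate learning rates). The returned pose is the one with the
#' lowest loss over all iterations, so it is never worse than the
#' initialization under the loss.
#'
#' @param cue_obj a [cue] (only `submesh3d` enters the loss).
#' @param reference_mask binary/soft mask at camera resolution (it is
#'   resampled to the render resolution internally).
#' @param cam a [pinhole_camera].
#' @param init_pose initial [rigid_pose] (keyframe pose or previous frame's
#'   estimate).
#' @param settings an [optimizer_settings].
#' @param render_settings a [soft_render_settings].
#' @return an [alignment_result].
#' @export
align_diffrender <- function(cue_obj, reference_mask, cam, init_pose,
                             settings = optimizer_settings(),
                             render_settings = soft_render_settings()) {
  submesh <- if (inherits(cue_obj, "cue")) cue_obj$submesh3d else cue_obj
  rcam <- render_camera(cam, render_settings)
  ref <- resample_mask(reference_mask, rcam$width, rcam$height)
  params <- pose_to_params(init_pose)

  if (all(ref == 0)) {
    g0 <- pose_gradient(submesh, params, cam, ref, render_settings,
                        want_grad = FALSE)
    return(alignment_result(init_pose, g0$loss, g0$loss, 1L,
                            converged = FALSE, flags = "empty_reference"))
  }

  lr <- c(rep(settings$lr_translation, 3L), rep(settings$lr_rotation, 6L))
  m <- numeric(9L); v <- numeric(9L)
  best_loss <- Inf; best_params <- params
  trace <- numeric(0L)
  ever_visible <- FALSE
  since_best <- 0L
  it <- 0L
  for (it in seq_len(settings$n_iters)) {
    g <- pose_gradient(submesh, params, cam, ref, render_settings)
    trace[it] <- g$loss
    if (g$coverage > 0) ever_visible <- TRUE
    if (g$loss < best_loss) {
      best_loss <- g$loss
      best_params <- params
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= settings$patience) break
    }
    m <- settings$beta1 * m + (1 - settings$beta1) * g$gradient
    v <- settings$beta2 * v + (1 - settings$beta2) * g$gradient^2
    mhat <- m / (1 - settings$beta1^it)
    vhat <- v / (1 - settings$beta2^it)
    params <- params - lr * mhat / (sqrt(vhat) + settings$eps)
  }
  if (!ever_visible)
    stop("lost cue: the submesh never rendered a nonzero pixel ",
         "during optimization")
  alignment_result(params_to_pose(best_params), best_loss, trace, it,
                   converged = TRUE)
}

#' Register a cue across a mask sequence with frame-to-frame warm starting
#'
#' Frame 1 is initialized at the keyframe pose; frame i+1 at frame i's best
#' pose (the camera moves continuously, so the previous solution is a good
#' starting point). A frame whose alignment fails (e.g. empty mask, lost
#' cue) is flagged and returns the last good pose, from which subsequent
#' frames continue.
#'
#' @param cue_obj a [cue].
#' @param masks list of per-frame reference masks, keyframe first.
#' @param cam a [pinhole_camera].
#' @param keyframe_pose [rigid_pose] of the manually aligned keyframe.
#' @param settings an [optimizer_settings].
#' @param render_settings a [soft_render_settings].
#' @return list of [alignment_result], one per frame.
#' @export
register_sequence <- function(cue_obj, masks, cam, keyframe_pose,
                              settings = optimizer_settings(),
                              render_settings = soft_render_settings()) {
  results <- vector("list", length(masks))
  pose <- keyframe_pose
  for (i in seq_along(masks)) {
    res <- tryCatch(
      align_diffrender(cue_obj, masks[[i]], cam, pose, settings,
                       render_settings),
      error = function(e)
        alignment_result(pose, Inf, Inf, 0L, converged = FALSE,
                         flags = paste0("failed: ", conditionMessage(e))))
    results[[i]] <- res
    if (res$converged) pose <- res$best_pose   # warm start; Adam state reset
  }
  results
}

#' Random search over the two learning rates
#'
#' Samples `(lr_translation, lr_rotation)` pairs log-uniformly inside the
#' given bounds and evaluates each pair by the alignment-cost criterion: the
#' lowest loss during the alignment of one frame, averaged over all
#' parameterization frames. Returns the argmin pair and the full cost table.
#'
#' @param frames list of parameterization frames, each a list with elements
#'   `cue`, `reference_mask`, `cam`, `init_pose` (a pose perturbed from the
#'   ground truth).
#' @param budget number of learning-rate pairs to sample (>= 1).
#' @param seed RNG seed for the sampling.
#' @param bounds_translation,bounds_rotation length-2 lower/upper bounds of
#'   the log-uniform sampling ranges.
#' @param settings base [optimizer_settings]; only the learning rates vary.
#' @param render_settings a [soft_render_settings].
#' @return list with `best` (named vector `lr_translation`, `lr_rotation`),
#'   `best_cost` and `table` (data.frame of all trials).
#' @export
search_learning_rates <- function(frames, budget = 50L, seed = 1L,
                                  bounds_translation = c(1e-2, 10),
                                  bounds_rotation = c(1e-4, 1e-1),
                                  settings = optimizer_settings(),
                                  render_settings = soft_render_settings()) {
  if (length(frames) == 0L) stop("no parameterization frames given")
  if (budget < 1L) stop("budget must be >= 1")
  set.seed(seed)
  lt <- exp(stats::runif(budget, log(bounds_translation[1L]),
                         log(bounds_translation[2L])))
  lr <- exp(stats::runif(budget, log(bounds_rotation[1L]),
                         log(bounds_rotation[2L])))
  cost <- numeric(budget)
  for (b in seq_len(budget)) {
    s <- settings
    s$lr_translation <- lt[b]
    s$lr_rotation <- lr[b]
    losses <- vapply(frames, function(fr) {
      res <- tryCatch(
        align_diffrender(fr$cue, fr$reference_mask, fr$cam, fr$init_pose,
                         s, render_settings),
        error = function(e) list(best_loss = Inf))
      res$best_loss
    }, numeric(1L))
    cost[b] <- mean(losses)
  }
  best <- which.min(cost)
  list(best = c(lr_translation = lt[best], lr_rotation = lr[best]),
       best_cost = cost[best],
       table = data.frame(lr_translation = lt, lr_rotation = lr,
                          cost = cost))
}
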