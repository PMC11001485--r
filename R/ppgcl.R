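# Gradient-compensated encoder parameter perturbation: the second
# contrastive view is produced by running the unchanged input graphs through
# an encoder whose layer weights are displaced along the gradient of the
# masking contrastive loss, theta' = theta + eta * grad_theta L_CL1. The
# perturbed branch is treated as constant during optimization (no
# second-order terms).

#' Perturbation configuration
#'
#' @param eta Perturbation magnitude for gradient mode (default 2; may be
#'   negative to descend instead of ascend the contrastive loss).
#' @param mode `"gradient"` (gradient compensation), `"gaussian"`
#'   (SimGRACE-style random perturbation) or `"none"`.
#' @param gaussian_scale Elementwise standard deviation for gaussian mode.
#' @return Object of class `perturbation_config`.
#' @export
perturbation_config <- function(eta = 2, mode = c("gradient", "gaussian", "none"),
                                gaussian_scale = 0.1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(eta), gaussian_scale >= 0)
  cfg <- list(eta = eta, mode = mode, gaussian_scale = gaussian_scale)
  class(cfg) <- "perturbation_config"
  cfg
}

#' Gradient of the masking contrastive loss w.r.t. encoder parameters
#'
#' Recomputes L_CL1 (NT-Xent between the projections of the original graphs
#' and of the supplied masked views) and returns its gradient with respect to
#' every parameter tensor, as a registry aligned with `params` (zero tensors
#' where no gradient flows). `params` is left unchanged.
#'
#' @param params `encoder_params` registry.
#' @param graphs List of `molgraph` (batch of at least 2).
#' @param mask_views List of `masked_view` aligned with `graphs`.
#' @param tau Temperature.
#' @param config [encoder_config()].
#' @return Named list of gradient tensors with `loss` attribute.
#' @export
snapshot_cl1_gradient <- function(params, graphs, mask_views, tau, config) {
  stopifnot(length(graphs) == length(mask_views))
  batch_o <- make_batch(graphs)
  batch_m <- make_batch(lapply(mask_views, `[[`, "graph"))
  fw_o <- .encoder_forward(params, batch_o, config, training = TRUE)
  fw_m <- .encoder_forward(params, batch_m, config, training = TRUE)
  nt <- .nt_xent_grad(fw_o$z, fw_m$z, tau)
  genv <- new.env(parent = emptyenv())
  .encoder_backward(params, config, batch_o, fw_o, dz = nt$dA, genv = genv)
  .encoder_backward(params, config, batch_m, fw_m, dz = nt$dP, genv = genv)
  out <- .grads_as_list(genv, params)
  attr(out, "loss") <- nt$loss
  out
}

#' Perturb encoder layer weights
#'
#' Gradient mode: `theta'_l = theta_l + eta * grad_l` for every per-layer
#' linear and batch-norm tensor; gaussian mode adds elementwise
#' `Normal(0, gaussian_scale^2)` noise to the same tensors; `"none"` returns
#' an identical copy. Feature embedding tables and the projection and
#' reconstruction heads are never perturbed. The input registry is not
#' mutated and shares no storage with the result.
#'
#' @param params `encoder_params` registry.
#' @param grad Gradient registry (e.g. from [snapshot_cl1_gradient()]);
#'   required in gradient mode.
#' @param config A [perturbation_config()].
#' @return A new `encoder_params` registry.
#' @export
perturb_parameters <- function(params, grad = NULL, config = perturbation_config()) {
  out <- params
  sel <- perturbable_names(params)
  if (config$mode == "none") return(out)
  if (config$mode == "gradient") {
    if (is.null(grad)) stop("gradient mode requires a gradient snapshot")
    for (nm in sel) {
      g <- grad[[nm]]
      if (is.null(g)) stop("gradient snapshot missing tensor '", nm, "'")
      if (length(g) != length(params[[nm]]))
        stop("gradient shape mismatch for tensor '", nm, "'")
      out[[nm]] <- params[[nm]] + config$eta * g
    }
  } else {
    for (nm in sel) {
      out[[nm]] <- params[[nm]] +
        stats::rnorm(length(params[[nm]]), 0, config$gaussian_scale)
    }
  }
  out
}

#' Parameter-perturbation contrastive (PPGCL) loss
#'
#' NT-Xent between the projections of the original and the
#' perturbed-encoder views of the same batch (identical functional form to
#' the masking contrastive loss, with the perturbed view as partner).
#'
#' @param z_original,z_perturbed B x d projection matrices of the same batch.
#' @param tau Temperature.
#' @return Scalar loss.
#' @export
ppgcl_loss <- function(z_original, z_perturbed, tau) {
  stopifnot(all(dim(as.matrix(z_original)) == dim(as.matrix(z_perturbed))))
  nt_xent(z_original, z_perturbed, tau)
}
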