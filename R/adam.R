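# Adam optimizer over a flat named parameter registry.

.adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.adam_step <- function(params, grads, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g) || is.null(params[[nm]])) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(params = params, opt = opt)
}
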