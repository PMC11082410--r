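#' Total metabolic activity surrogate
#'
#' Per-sample anchor for the sum of module fluxes: the summed expression of
#' all map-member genes present in the matrix (default), or a constant.
#'
#' @param expression genes x samples nonnegative matrix.
#' @param map a [metabolic_map()].
#' @param mode `"expression"` (sum of map-gene expression) or `"constant"`.
#' @param constant the constant used when `mode = "constant"`.
#' @return named numeric vector, one value per sample.
#' @export
compute_total_activity <- function(expression, map,
                                   mode = c("expression", "constant"),
                                   constant = 1) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    ta <- rep(constant, ncol(expression))
    names(ta) <- colnames(expression)
    return(ta)
  }
  present <- intersect(map_genes(map), rownames(expression))
  if (length(present) == 0L) {
    stop("no map genes present in the expression matrix", call. = FALSE)
  }
  colSums(expression[present, , drop = FALSE])
}

#' Flux-imbalance loss
#'
#' Sum over samples and balanced metabolites of the squared difference
#' between total influx and total outflux.
#'
#' @param flux modules x samples nonnegative matrix aligned to `map`.
#' @param map a [metabolic_map()].
#' @return nonnegative scalar.
#' @export
imbalance_loss <- function(flux, map) {
  stopifnot(inherits(map, "metabolic_map"))
  Sb <- stoich_matrix(map, balanced_only = TRUE)
  if (nrow(Sb) == 0L) return(0)
  flux <- flux[colnames(Sb), , drop = FALSE]
  sum((Sb %*% flux)^2)
}

#' Total training loss
#'
#' Imbalance loss plus `lambda` times the squared deviation of each sample's
#' total flux from its total-activity anchor.
#'
#' @inheritParams imbalance_loss
#' @param ta per-sample total activity, e.g. [compute_total_activity()].
#' @param lambda nonnegative anchoring weight.
#' @return scalar; equals [imbalance_loss()] exactly at `lambda = 0`.
#' @export
total_loss <- function(flux, map, ta, lambda = 1) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  imbalance_loss(flux, map) + lambda * sum((colSums(flux) - ta)^2)
}

.init_module_params <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    a <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    params[[paste0("W", l)]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -a, a),
                                       nrow = sizes[l])
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
  }
  params$s <- 1
  params
}

.softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

# forward pass for one module; returns activations needed for backprop.
# `p$s` is a fixed output scale (set by the warm start, not trained), so the
# nonnegative link acts on a well-scaled pre-activation.
.module_forward <- function(X, p, output = "softplus") {
  H1 <- tanh(sweep(X %*% p$W1, 2L, p$b1, "+"))
  H2 <- tanh(sweep(H1 %*% p$W2, 2L, p$b2, "+"))
  z <- as.numeric(H2 %*% p$W3 + p$b3)
  flux <- p$s * if (output == "abs") abs(z) else .softplus(z)
  list(H1 = H1, H2 = H2, z = z, flux = flux, output = output)
}

# gradient of the loss w.r.t. one module's trained parameters, given dL/dflux
.module_backward <- function(X, act, p, dflux) {
  dz <- dflux * p$s *
    if (act$output == "abs") sign(act$z) else stats::plogis(act$z)
  gW3 <- crossprod(act$H2, dz)
  gb3 <- sum(dz)
  dH2 <- outer(dz, as.numeric(p$W3)) * (1 - act$H2^2)
  gW2 <- crossprod(act$H1, dH2)
  gb2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(p$W2)) * (1 - act$H1^2)
  gW1 <- crossprod(X, dH1)
  gb1 <- colSums(dH1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Fit the factor-graph neural flux model
#'
#' Models the flux of each reaction module as a small fully connected neural
#' network (input genes -> 8 -> 4 -> 1, tanh hidden activations, a softplus
#' output link enforcing nonnegativity) of its member genes' expression, and trains
#' all modules jointly by full-batch Adam to minimise the cohort-wide flux
#' imbalance on balanced metabolites plus a total-activity anchoring term:
#' \deqn{L = \sum_j \sum_k \big(\sum_{m \in in(k)} F_{mj} - \sum_{m \in out(k)} F_{mj}\big)^2
#'        + \lambda \sum_j \big(\sum_m F_{mj} - TA_j\big)^2.}
#'
#' Expression is `log1p`-transformed and standardised per gene before entering
#' the networks; the total activity is scaled to mean 1 so that `lambda = 1`
#' is a balanced default. Reported fluxes are normalised so the cohort-mean
#' total flux equals the mean total activity (relative flux units).
#'
#' @param expression genes x samples nonnegative matrix (TPM-scale).
#' @param map a [metabolic_map()].
#' @param lambda nonnegative total-activity weight.
#' @param epochs maximum training epochs.
#' @param seed integer seed for parameter initialisation.
#' @param lr Adam learning rate.
#' @param hidden hidden-layer widths (two layers).
#' @param ta optional per-sample total activity; computed from `expression`
#'   when `NULL`.
#' @param ta_mode passed to [compute_total_activity()] when `ta` is `NULL`.
#' @param tol,patience early stopping: stop when the relative loss change
#'   over `patience` epochs falls below `tol`.
#' @param init `"surrogate"` warm-starts each module network on a
#'   gene-average surrogate flux (the exponentiated mean standardised
#'   log-expression of its member genes, scaled to the mean total activity)
#'   before the joint training; `"random"` trains from the random
#'   initialisation directly.
#' @param pre_epochs epochs of the surrogate warm-start.
#' @param output nonnegative output link: smooth `"softplus"` (default) or
#'   the kinked `"abs"`.
#' @param optimizer `"adam"` (default) or `"gd"`, plain full-batch gradient
#'   descent with step `lr / n`. With a pure imbalance objective
#'   (`lambda = 0`) the loss is homogeneous of degree 2 and Adam's
#'   normalised steps tend to shrink all fluxes together; gradient descent
#'   instead preserves the total-flux mode while contracting the imbalance
#'   mode, which is the behaviour wanted for balance-only fits.
#' @param verbose print the loss every 100 epochs.
#' @return An object of class `flux_model` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot` methods. `fitted()` returns
#'   the normalised modules x samples flux matrix; `residuals()` the
#'   per-balanced-metabolite imbalance.
#' @export
fit_flux_model <- function(expression, map, lambda = 1, epochs = 1000,
                           seed = 1L, lr = 0.01, hidden = c(8L, 4L),
                           ta = NULL, ta_mode = "expression",
                           tol = 1e-6, patience = 50L,
                           init = c("surrogate", "random"),
                           pre_epochs = 500L,
                           optimizer = c("adam", "gd"),
                           output = c("softplus", "abs"), verbose = FALSE) {
  init <- match.arg(init)
  optimizer <- match.arg(optimizer)
  output <- match.arg(output)
  stopifnot(inherits(map, "metabolic_map"))
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  mods <- module_names(map)
  n <- ncol(expression)
  samples <- colnames(expression) %||% paste0("S", seq_len(n))

  missing_genes <- setdiff(map_genes(map), rownames(expression))
  if (length(missing_genes)) {
    warning(sprintf("%d of %d map genes absent from the expression matrix; imputed as zero: %s",
                    length(missing_genes), length(map_genes(map)),
                    paste(utils::head(missing_genes, 5L), collapse = ", ")))
  }
  if (length(missing_genes) == length(map_genes(map))) {
    stop("none of the map genes are present in the expression matrix", call. = FALSE)
  }

  # per-module standardised log1p inputs; missing genes enter as zero rows
  inputs <- list(); gene_stats <- list()
  for (m in map$modules) {
    X <- matrix(0, nrow = n, ncol = length(m$genes),
                dimnames = list(samples, m$genes))
    present <- intersect(m$genes, rownames(expression))
    if (length(present)) X[, present] <- t(log1p(expression[present, , drop = FALSE]))
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale < 1e-12] <- 1
    inputs[[m$name]] <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
    gene_stats[[m$name]] <- list(genes = m$genes, center = center, scale = scale)
  }

  if (is.null(ta)) ta <- compute_total_activity(expression, map, mode = ta_mode)
  ta_scale <- mean(ta)
  if (ta_scale <= 0) ta_scale <- 1
  ta <- ta / ta_scale

  Sb <- stoich_matrix(map, balanced_only = TRUE)
  St <- t(Sb)

  params <- with_seed(seed, {
    lapply(inputs, function(X) .init_module_params(ncol(X), hidden))
  })
  adam_m <- lapply(params, function(p) lapply(p, function(x) x * 0))
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  F <- matrix(0, nrow = length(mods), ncol = n, dimnames = list(mods, samples))
  for (mn in mods) F[mn, ] <- .module_forward(inputs[[mn]], params[[mn]], output)$flux
  initial_loss <- total_loss(F, map, ta, lambda)

  if (init == "surrogate") {
    # warm start: fit each network to a monotone gene-average surrogate so
    # joint training begins near the module-informed regime
    for (mn in mods) {
      z <- rowMeans(inputs[[mn]])
      # unit-mean surrogate with the module's own empirical log-scale spread
      # as exponent, so the target's dynamic range matches the data; the
      # fitted shape is then moved to flux scale through the output scale `s`
      spread <- mean(gene_stats[[mn]]$scale[gene_stats[[mn]]$scale > 1e-6])
      if (!is.finite(spread)) spread <- 1
      target <- exp(z * min(spread, 1))
      target <- target / mean(target)
      pm <- 0L
      pre_m <- lapply(params[[mn]], function(x) x * 0)
      pre_v <- pre_m
      for (ep in seq_len(pre_epochs)) {
        act <- .module_forward(inputs[[mn]], params[[mn]], output)
        g <- .module_backward(inputs[[mn]], act, params[[mn]],
                              2 * (act$flux - target))
        pm <- pm + 1L
        for (pn in names(g)) {
          pre_m[[pn]] <- beta1 * pre_m[[pn]] + (1 - beta1) * g[[pn]]
          pre_v[[pn]] <- beta2 * pre_v[[pn]] + (1 - beta2) * g[[pn]]^2
          params[[mn]][[pn]] <- params[[mn]][[pn]] -
            lr * (pre_m[[pn]] / (1 - beta1^pm)) /
              (sqrt(pre_v[[pn]] / (1 - beta2^pm)) + eps)
        }
      }
      params[[mn]]$s <- mean(ta) / length(mods)
    }
  }

  trace <- initial_loss
  for (epoch in seq_len(epochs)) {
    acts <- lapply(mods, function(mn) .module_forward(inputs[[mn]], params[[mn]], output))
    names(acts) <- mods
    for (mn in mods) F[mn, ] <- acts[[mn]]$flux

    r <- if (nrow(Sb)) Sb %*% F else matrix(0, 0L, n)
    tdev <- colSums(F) - ta
    loss <- sum(r^2) + lambda * sum(tdev^2)
    if (!is.finite(loss)) {
      stop(sprintf("training diverged: non-finite loss at epoch %d", epoch),
           call. = FALSE)
    }
    trace <- c(trace, loss)
    if (verbose && epoch %% 100L == 0L) {
      message(sprintf("epoch %d: loss %.6g", epoch, loss))
    }
    if (length(trace) > patience + 1L) {
      prev <- trace[length(trace) - patience]
      if (abs(prev - loss) / max(prev, 1e-12) < tol) break
    }

    dF <- 2 * (St %*% r) + matrix(2 * lambda * tdev, nrow = length(mods),
                                  ncol = n, byrow = TRUE)
    step <- step + 1L
    for (mn in mods) {
      g <- .module_backward(inputs[[mn]], acts[[mn]], params[[mn]], dF[mn, ])
      for (pn in names(g)) {
        if (optimizer == "adam") {
          adam_m[[mn]][[pn]] <- beta1 * adam_m[[mn]][[pn]] + (1 - beta1) * g[[pn]]
          adam_v[[mn]][[pn]] <- beta2 * adam_v[[mn]][[pn]] + (1 - beta2) * g[[pn]]^2
          mhat <- adam_m[[mn]][[pn]] / (1 - beta1^step)
          vhat <- adam_v[[mn]][[pn]] / (1 - beta2^step)
          params[[mn]][[pn]] <- params[[mn]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
        } else {
          params[[mn]][[pn]] <- params[[mn]][[pn]] - lr / n * g[[pn]]
        }
      }
    }
    if (lambda == 0) {
      # pure imbalance objectives are homogeneous of degree 2, so the overall
      # flux scale is a flat (gauge) direction that slowly drifts to zero
      # under stochastic-free descent; pin it to the total-activity scale
      mean_total <- mean(colSums(F))
      if (mean_total > 0) {
        gauge <- mean(ta) / mean_total
        for (mn in mods) params[[mn]]$s <- params[[mn]]$s * gauge
      }
    }
  }

  # final fluxes at the trained parameters
  for (mn in mods) F[mn, ] <- .module_forward(inputs[[mn]], params[[mn]], output)$flux
  final_imbalance <- imbalance_loss(F, map)
  final_loss <- total_loss(F, map, ta, lambda)
  mean_total <- mean(colSums(F))
  norm_factor <- if (mean_total > 0) mean(ta) / mean_total else 1

  structure(list(
    map = map, params = params,
    architecture = list(hidden = hidden, activation = "tanh", output = output,
                        init = init, optimizer = optimizer),
    lambda = lambda, epochs_run = length(trace) - 1L, trace = trace,
    initial_loss = initial_loss,
    final_loss = final_loss, final_imbalance = final_imbalance,
    seed = as.integer(seed), lr = lr,
    gene_stats = gene_stats, ta = ta, ta_scale = ta_scale,
    norm_factor = norm_factor, flux = F * norm_factor,
    n_samples = n, call = match.call()),
    class = "flux_model")
}

.align_module_input <- function(object, mn, expression) {
  gs <- object$gene_stats[[mn]]
  n <- ncol(expression)
  X <- matrix(0, nrow = n, ncol = length(gs$genes),
              dimnames = list(colnames(expression), gs$genes))
  present <- intersect(gs$genes, rownames(expression))
  if (length(present)) X[, present] <- t(log1p(expression[present, , drop = FALSE]))
  sweep(sweep(X, 2L, gs$center, "-"), 2L, gs$scale, "/")
}

#' Predict module fluxes for new samples
#'
#' @param object a fitted [fit_flux_model()].
#' @param newdata genes x samples expression matrix in the training gene
#'   namespace; genes missing from the matrix are zero-filled, but a matrix
#'   sharing no genes with the training map is an alignment error.
#' @param normalize apply the stored relative-flux normalisation.
#' @param ... unused.
#' @return nonnegative modules x samples matrix.
#' @export
predict.flux_model <- function(object, newdata, normalize = TRUE, ...) {
  if (length(intersect(map_genes(object$map), rownames(newdata))) == 0L) {
    stop("gene namespace of `newdata` shares no symbols with the training map",
         call. = FALSE)
  }
  mods <- module_names(object$map)
  F <- matrix(0, nrow = length(mods), ncol = ncol(newdata),
              dimnames = list(mods, colnames(newdata)))
  for (mn in mods) {
    X <- .align_module_input(object, mn, newdata)
    F[mn, ] <- .module_forward(X, object$params[[mn]],
                               object$architecture$output)$flux
  }
  if (normalize) F <- F * object$norm_factor
  F
}

#' @export
fitted.flux_model <- function(object, ...) object$flux

#' Per-metabolite flux imbalance of the fitted model
#'
#' @param object a fitted [fit_flux_model()].
#' @param ... unused.
#' @return balanced-metabolites x samples matrix of influx minus outflux,
#'   on the normalised flux scale.
#' @export
residuals.flux_model <- function(object, ...) {
  Sb <- stoich_matrix(object$map, balanced_only = TRUE)
  Sb %*% object$flux[colnames(Sb), , drop = FALSE]
}

#' @export
coef.flux_model <- function(object, ...) object$params

#' @export
print.flux_model <- function(x, ...) {
  cat("<flux_model>\n")
  cat(sprintf("  map: %s (%d modules, %d balanced metabolites)\n",
              x$map$name, length(x$map$modules), length(x$map$balanced)))
  cat(sprintf("  samples: %d; lambda = %g; epochs run: %d\n",
              x$n_samples, x$lambda, x$epochs_run))
  cat(sprintf("  final loss %.4g (imbalance %.4g)\n",
              x$final_loss, x$final_imbalance))
  invisible(x)
}

#' @export
summary.flux_model <- function(object, ...) {
  fl <- fitted(object)
  tab <- data.frame(
    module = rownames(fl),
    mean_flux = rowMeans(fl),
    sd_flux = apply(fl, 1L, stats::sd),
    row.names = NULL)
  out <- list(model = object, flux_table = tab,
              loss = c(total = object$final_loss,
                       imbalance = object$final_imbalance))
  class(out) <- "summary.flux_model"
  out
}

#' @export
print.summary.flux_model <- function(x, ...) {
  print(x$model)
  cat("\nFitted relative fluxes (cohort mean total scaled to mean total activity):\n")
  print(x$flux_table, digits = 3)
  invisible(x)
}

#' @export
plot.flux_model <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l", log = "y",
                 xlab = "epoch", ylab = "total loss",
                 main = "flux model training", ...)
  invisible(x)
}
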