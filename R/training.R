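#' Loop-inverted gradient training
#'
#' The loss is a weighted L2 objective over properties
#' \deqn{L = \sum_{prop} \frac{1}{N_{prop}} \sum_i (w_{prop} r_i)^2 + penalties}
#' with energy residuals taken per heavy atom (the energy weight is stated
#' per heavy atom), dipole residuals per Cartesian component, and charge
#' residuals per atom. Doubling a property weight quadruples that property's
#' loss component.
#'
#' Training inverts the SCF and gradient loops: the charge fluctuations
#' entering the Fock operator are frozen, and every \code{charge_update_period}
#' epochs a full SCF pass over the training set refreshes them, after which
#' the repulsive splines and reference energy are refit by convex
#' optimization. Between refreshes, ADAM updates the electronic spline
#' coefficients, on-site energies, Hubbard parameters and inflection
#' locations against the loss with frozen charges.
#'
#' @name training
NULL

#' Loss configuration
#'
#' @param w_energy energy weight, 1/Hartree, applied to the per-heavy-atom
#'   energy residual (default 6270)
#' @param w_dipole dipole weight per Cartesian component, 1/(e*Angstrom)
#'   (default 100)
#' @param w_charge atomic charge weight, 1/e (default 1)
#' @param per_heavy divide the energy residual by the heavy-atom count
#'   before weighting (default TRUE)
#' @return list of class \code{tb_loss_config}
#' @export
loss_config <- function(w_energy = 6270, w_dipole = 100, w_charge = 1,
                        per_heavy = TRUE) {
  stopifnot(w_energy >= 0, w_dipole >= 0, w_charge >= 0)
  structure(list(w_energy = w_energy, w_dipole = w_dipole,
                 w_charge = w_charge, per_heavy = per_heavy),
            class = "tb_loss_config")
}

#' Training configuration
#'
#' @param epochs number of epochs (default 2500)
#' @param batch_size configurations per batch (default 10)
#' @param charge_update_period epochs between SCF refreshes and repulsive
#'   refits (default 10)
#' @param learning_rate ADAM learning rate (default 1e-5); all other ADAM
#'   parameters at their standard defaults
#' @param plateau_factor learning-rate multiplier on plateau (default 0.9)
#' @param plateau_window epochs without improvement defining a plateau
#'   (default 50)
#' @param plateau_threshold minimum relative improvement (default 1e-4)
#' @param seed integer seed controlling batching and shuffling
#' @param train_hubbard train Hubbard parameters (default TRUE)
#' @param train_inflection train inflection locations (default TRUE)
#' @return list of class \code{tb_train_config}
#' @export
train_config <- function(epochs = 2500L, batch_size = 10L,
                         charge_update_period = 10L, learning_rate = 1e-5,
                         plateau_factor = 0.9, plateau_window = 50L,
                         plateau_threshold = 1e-4, seed = 1L,
                         train_hubbard = TRUE, train_inflection = TRUE) {
  stopifnot(batch_size >= 1, epochs >= 1, charge_update_period >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 charge_update_period = as.integer(charge_update_period),
                 learning_rate = learning_rate,
                 plateau_factor = plateau_factor,
                 plateau_window = as.integer(plateau_window),
                 plateau_threshold = plateau_threshold,
                 seed = as.integer(seed),
                 train_hubbard = isTRUE(train_hubbard),
                 train_inflection = isTRUE(train_inflection)),
            class = "tb_train_config")
}

#' Weighted L2 loss over predictions and targets
#'
#' Reference implementation of the property loss on explicit predictions;
#' the training loop evaluates the same quantity in compiled code.
#'
#' @param predictions,targets lists of per-configuration lists with fields
#'   \code{energy} (Ha), \code{dipole} (e*Angstrom 3-vector),
#'   \code{charges} (e per atom), and (predictions) \code{n_heavy}
#' @param config a \code{\link{loss_config}}
#' @param penalties scalar regularization penalty to add (default 0)
#' @return list with \code{total} and per-property components
#'   \code{energy}, \code{dipole}, \code{charge}, \code{penalty}
#' @export
compute_loss <- function(predictions, targets, config = loss_config(),
                         penalties = 0) {
  stopifnot(length(predictions) == length(targets))
  se <- sd_ <- sq <- 0
  ne <- nd <- nq <- 0L
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]; t <- targets[[i]]
    if (!is.null(t$energy)) {
      if (is.null(p$energy)) stop("missing energy prediction for weighted target")
      hn <- if (config$per_heavy) max(p$n_heavy, 1) else 1
      se <- se + (config$w_energy * (p$energy - t$energy) / hn)^2
      ne <- ne + 1L
    }
    if (!is.null(t$dipole)) {
      if (is.null(p$dipole)) stop("missing dipole prediction for weighted target")
      sd_ <- sd_ + sum((config$w_dipole * (p$dipole - t$dipole))^2)
      nd <- nd + 3L
    }
    if (!is.null(t$charges)) {
      if (is.null(p$charges)) stop("missing charge prediction for weighted target")
      sq <- sq + sum((config$w_charge * (p$charges - t$charges))^2)
      nq <- nq + length(t$charges)
    }
  }
  comp <- c(energy = if (ne) se / ne else 0,
            dipole = if (nd) sd_ / nd else 0,
            charge = if (nq) sq / nq else 0)
  list(total = sum(comp) + penalties,
       energy = unname(comp["energy"]), dipole = unname(comp["dipole"]),
       charge = unname(comp["charge"]), penalty = penalties,
       n = c(energy = ne, dipole = nd, charge = nq))
}

#' Fixed-membership batches with per-epoch order shuffling
#'
#' Batch membership is frozen for the whole run (the precomputed cache is
#' keyed by it); only the order in which batches are visited is reshuffled
#' every epoch.
#'
#' @param n number of configurations (or a \code{tb_dataset})
#' @param batch_size configurations per batch
#' @param seed integer seed
#' @return list with \code{batches} (list of index vectors) and
#'   \code{order} (function of epoch giving the batch visiting order)
#' @export
make_batches <- function(n, batch_size = 10L, seed = 1L) {
  if (inherits(n, "tb_dataset")) n <- length(n)
  stopifnot(n >= 1, batch_size >= 1)
  rng <- .seeded_rng(seed)
  perm <- rng$sample_perm(n)
  nb <- ceiling(n / batch_size)
  batches <- split(perm, ceiling(seq_along(perm) / batch_size))
  names(batches) <- NULL
  order_fn <- function(epoch) {
    rng_e <- .seeded_rng(seed + 77003L * (as.integer(epoch) %% 21001L))
    rng_e$sample_perm(nb)
  }
  list(batches = batches, order = order_fn, n = n, batch_size = batch_size)
}

# Per-batch normalization counts (instances per property).
.batch_weights <- function(cache, idx, lcfg) {
  ne <- sum(vapply(idx, function(i) is.finite(cache[[i]]$t_energy), logical(1)))
  nd <- 3L * sum(vapply(idx, function(i) !is.null(cache[[i]]$t_dipole), logical(1)))
  nq <- sum(vapply(idx, function(i) length(cache[[i]]$t_charges), integer(1)))
  list(w_energy = lcfg$w_energy, w_dipole = lcfg$w_dipole,
       w_charge = lcfg$w_charge, per_heavy = lcfg$per_heavy,
       inv_n_energy = if (ne) 1 / ne else 0,
       inv_n_dipole = if (nd) 1 / nd else 0,
       inv_n_charge = if (nq) 1 / nq else 0)
}

# SCF refresh over a cache: returns frozen charges, electronic energies,
# and failure flags.
.scf_refresh <- function(cache, x, scf_opts) {
  n <- length(cache)
  dq <- vector("list", n)
  elec <- numeric(n)
  skip <- logical(n)
  niter <- integer(n)
  for (i in seq_len(n)) {
    res <- tryCatch(cpp_scf_mol(cache[[i]], x, scf_opts),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    if (!isTRUE(res$ok) || !isTRUE(res$converged)) {
      skip[i] <- TRUE
      dq[[i]] <- rep(0, length(cache[[i]]$shell_q0))
      elec[i] <- NA_real_
    } else {
      dq[[i]] <- drop(res$dq)
      elec[i] <- res$e_electronic
      niter[i] <- res$n_iterations
    }
  }
  list(dq = dq, elec = elec, skip = skip, n_failed = sum(skip),
       mean_iter = mean(niter[!skip]))
}

#' Train a parameter set against a dataset split
#'
#' Runs the loop-inverted training schedule: periodic SCF refreshes of the
#' frozen charge fluctuations and convex refits of the repulsive/reference
#' terms, with ADAM gradient steps on the electronic parameters in between.
#' The best-validation parameter vector is retained and refit once more at
#' the end.
#'
#' @param split a \code{tb_split} (or list with \code{train} and
#'   \code{validation} datasets carrying targets)
#' @param params_init initial \code{tb_paramset} (e.g.
#'   \code{\link{seed_paramset}})
#' @param config a \code{\link{train_config}}
#' @param lcfg a \code{\link{loss_config}}
#' @param pcfg a \code{\link{penalty_config}}
#' @param scf \code{\link{scf_options}} used in refreshes
#' @param method target method label (default \code{"toy-truth"})
#' @param verbose print progress every 10 epochs
#' @return list (class \code{tb_fit}): \code{params} (trained
#'   \code{tb_paramset}), \code{history} (data.frame per epoch),
#'   \code{best_epoch}, \code{layout}
#' @export
train <- function(split, params_init, config = train_config(),
                  lcfg = loss_config(), pcfg = penalty_config(),
                  scf = scf_options(), method = "toy-truth",
                  verbose = FALSE) {
  ps <- params_init
  layout <- params_layout(ps, train_hubbard = config$train_hubbard,
                          train_inflection = config$train_inflection)
  tr_ds <- split$train
  va_ds <- split$validation
  if (!length(tr_ds)) stop("empty training set")
  validate_coverage(ps, tr_ds)
  cache_tr <- precompute_batch(tr_ds, ps, layout, method = method)
  cache_va <- if (length(va_ds)) precompute_batch(va_ds, ps, layout,
                                                  method = method) else NULL
  x <- params_pack(ps, layout)
  pens <- build_penalty_descriptors(ps, layout, pcfg)

  # gradient mask for frozen blocks
  mask <- rep(1, layout$n_par)
  if (!config$train_hubbard) mask[layout$hubbard] <- 0
  if (!config$train_inflection && length(layout$inflection))
    mask[layout$inflection] <- 0

  # repulsive/reference design matrices are geometry-only: build once
  des_tr <- .repulsive_design(tr_ds, ps)
  des_va <- if (length(va_ds)) .repulsive_design(va_ds, ps) else NULL
  t_tr <- vapply(cache_tr, function(m) m$t_energy, numeric(1))
  if (anyNA(t_tr)) stop("all training configurations need energy targets")

  bt <- make_batches(length(tr_ds), config$batch_size, config$seed)
  wts_b <- lapply(bt$batches, function(idx) .batch_weights(cache_tr, idx, lcfg))
  wts_va <- if (length(va_ds)) .batch_weights(cache_va, seq_along(cache_va), lcfg)

  frozen_dq_tr <- lapply(cache_tr, function(m) rep(0, length(m$shell_q0)))
  frozen_er_tr <- numeric(length(cache_tr))
  skip_tr <- logical(length(cache_tr))
  if (length(va_ds)) {
    frozen_dq_va <- lapply(cache_va, function(m) rep(0, length(m$shell_q0)))
    frozen_er_va <- numeric(length(cache_va))
    skip_va <- logical(length(cache_va))
  }

  refresh <- function(x) {
    rf <- .scf_refresh(cache_tr, x, scf)
    frozen_dq_tr <<- rf$dq
    skip_tr <<- rf$skip
    keep <- !rf$skip
    if (!any(keep)) stop("SCF failed on every training configuration")
    des_k <- des_tr
    des_k$M <- des_tr$M[keep, , drop = FALSE]
    fit <- fit_repulsive_and_reference(tr_ds[keep], rf$elec[keep],
                                       t_tr[keep], ps, design = des_k)
    ps <<- fit$ps
    rep_x <- fit$coefficients
    frozen_er_tr <<- drop(des_tr$M %*% rep_x)
    if (length(va_ds)) {
      rfv <- .scf_refresh(cache_va, x, scf)
      frozen_dq_va <<- rfv$dq
      skip_va <<- rfv$skip
      frozen_er_va <<- drop(des_va$M %*% rep_x)
    }
    invisible(rf$n_failed)
  }

  # ADAM state
  m1 <- numeric(layout$n_par)
  m2 <- numeric(layout$n_par)
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  lr <- config$learning_rate
  tstep <- 0L

  hist <- vector("list", config$epochs)
  best_val <- Inf
  best_x <- x
  best_epoch <- 0L
  last_best_epoch <- 0L

  val_loss <- function(x) {
    if (!length(va_ds)) return(NA_real_)
    r <- cpp_batch_loss_grad(cache_va, frozen_dq_va, frozen_er_va, skip_va,
                             x, wts_va, FALSE)
    pen <- penalty_eval(pens, x, FALSE)
    c(total = r$loss + pen$penalty, energy = r$loss_energy,
      dipole = r$loss_dipole, charge = r$loss_charge, penalty = pen$penalty)
  }

  for (epoch in seq_len(config$epochs)) {
    if ((epoch - 1L) %% config$charge_update_period == 0L) {
      nf <- refresh(x)
      if (verbose && nf > 0) message(nf, " SCF failure(s) excluded this cycle")
    }
    ord <- bt$order(epoch)
    tr_comp <- c(energy = 0, dipole = 0, charge = 0)
    pen_total <- 0
    for (b in ord) {
      idx <- bt$batches[[b]]
      res <- cpp_batch_loss_grad(cache_tr[idx], frozen_dq_tr[idx],
                                 frozen_er_tr[idx], skip_tr[idx], x,
                                 wts_b[[b]], TRUE)
      pen <- penalty_eval(pens, x, TRUE)
      g <- (res$grad + pen$grad) * mask
      tstep <- tstep + 1L
      m1 <- beta1 * m1 + (1 - beta1) * g
      m2 <- beta2 * m2 + (1 - beta2) * g * g
      mhat <- m1 / (1 - beta1^tstep)
      vhat <- m2 / (1 - beta2^tstep)
      x <- x - lr * mhat / (sqrt(vhat) + eps_adam)
      tr_comp <- tr_comp + c(res$loss_energy, res$loss_dipole, res$loss_charge)
      pen_total <- pen_total + pen$penalty
    }
    nb <- length(ord)
    tr_comp <- unname(tr_comp)
    vl <- val_loss(x)
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_energy = tr_comp[1] / nb, train_dipole = tr_comp[2] / nb,
      train_charge = tr_comp[3] / nb, penalty = pen_total / nb,
      train_total = sum(tr_comp) / nb + pen_total / nb,
      val_total = unname(vl["total"]), val_energy = unname(vl["energy"]),
      val_dipole = unname(vl["dipole"]), val_charge = unname(vl["charge"]))
    crit <- if (length(va_ds)) vl["total"] else sum(tr_comp) / nb
    if (is.finite(crit) && crit < best_val * (1 - config$plateau_threshold)) {
      best_val <- crit
      best_x <- x
      best_epoch <- epoch
      last_best_epoch <- epoch
    } else if (is.finite(crit) && crit < best_val) {
      best_val <- crit
      best_x <- x
      best_epoch <- epoch
    }
    if (epoch - last_best_epoch >= config$plateau_window) {
      lr <- lr * config$plateau_factor
      last_best_epoch <- epoch
    }
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      message(sprintf("epoch %4d  train %.6g  val %.6g  lr %.3g",
                      epoch, sum(tr_comp) / nb + pen_total / nb,
                      vl["total"], lr))
  }

  # final state: best-validation parameters with a consistent refit
  x <- best_x
  refresh(x)
  ps_out <- params_unpack(ps, layout, x)
  ps_out$repulsive <- ps$repulsive
  ps_out$reference <- ps$reference
  ps_out$meta$trained <- list(epochs = config$epochs, best_epoch = best_epoch,
                              seed = config$seed)
  structure(list(params = ps_out, history = do.call(rbind, hist),
                 best_epoch = best_epoch, layout = layout,
                 final_x = x),
            class = "tb_fit")
}

#' @export
print.tb_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<tb_fit: %d epochs, best epoch %d, final val loss %.6g>\n",
              nrow(h), x$best_epoch, h$val_total[nrow(h)]))
  invisible(x)
}

#' Finite-difference check of the training gradient
#'
#' Compares the analytic gradient of the full training objective (property
#' loss with frozen charges plus penalties) against central finite
#' differences for a subset of parameters.
#'
#' @param cache a \code{tb_cache} with targets
#' @param ps,layout parameter set and layout the cache was built with
#' @param x flat parameter vector at which to check
#' @param frozen_dq list of frozen charge vectors (default: converged SCF)
#' @param frozen_erep frozen repulsive+reference energies (default 0)
#' @param lcfg,pcfg loss and penalty configurations
#' @param indices parameter indices to check (default: a spread over all
#'   blocks)
#' @param h finite-difference step
#' @return data.frame with analytic and numeric derivatives and relative
#'   error
#' @export
gradient_check <- function(cache, ps, layout, x, frozen_dq = NULL,
                           frozen_erep = NULL, lcfg = loss_config(),
                           pcfg = penalty_config(), indices = NULL,
                           h = 1e-6) {
  n <- length(cache)
  if (is.null(frozen_dq)) {
    rf <- .scf_refresh(cache, x, scf_options())
    frozen_dq <- rf$dq
  }
  if (is.null(frozen_erep)) frozen_erep <- numeric(n)
  skip <- logical(n)
  wts <- .batch_weights(cache, seq_len(n), lcfg)
  pens <- build_penalty_descriptors(ps, layout, pcfg)
  fobj <- function(xv) {
    r <- cpp_batch_loss_grad(cache, frozen_dq, frozen_erep, skip, xv, wts, FALSE)
    p <- penalty_eval(pens, xv, FALSE)
    r$loss + p$penalty
  }
  r <- cpp_batch_loss_grad(cache, frozen_dq, frozen_erep, skip, x, wts, TRUE)
  p <- penalty_eval(pens, x, TRUE)
  g <- r$grad + p$grad
  if (is.null(indices)) {
    indices <- unique(c(
      layout$channels$offset[1] + c(1L, 5L, 20L),
      layout$channels$offset[min(4L, nrow(layout$channels))] + c(2L, 11L),
      unname(layout$onsite), unname(layout$hubbard),
      unname(layout$inflection)))
    indices <- indices[indices >= 1 & indices <= layout$n_par]
  }
  out <- lapply(indices, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    num <- (fobj(xp) - fobj(xm)) / (2 * h)
    data.frame(index = i, analytic = g[i], numeric = num,
               rel_error = abs(g[i] - num) / max(abs(num), abs(g[i]), 1e-12))
  })
  do.call(rbind, out)
}
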