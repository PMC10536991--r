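#' Model evaluation and method comparison
#'
#' Evaluation runs full SCC calculations over a dataset, refits the linear
#' reference energy between predictions and targets (so energy errors are
#' atomization-energy errors, invariant under per-element shifts of either
#' method), and reports mean absolute errors: energy in kcal/mol (per
#' molecule, per atom and per heavy atom), Cartesian dipole components in
#' e*Angstrom, atomic charges in e. Outliers in total energy can be removed
#' by the one-sided 20-standard-deviation rule before reporting.
#'
#' @name evaluation
NULL

#' One-sided outlier removal on energy residuals
#'
#' Removes, in a single pass, configurations whose signed residual exceeds
#' the mean plus \code{threshold} (population) standard deviations. The rule
#' is one-sided: very negative residuals are never removed.
#'
#' @param errors per-configuration energy residuals
#' @param threshold number of standard deviations (default 20)
#' @param absolute use absolute residuals instead of signed (default FALSE)
#' @return list with \code{keep} (logical mask), \code{n_removed},
#'   \code{cutoff} (the threshold value applied)
#' @export
remove_outliers <- function(errors, threshold = 20, absolute = FALSE) {
  if (length(errors) < 2L) stop("need at least two configurations")
  e <- if (absolute) abs(errors) else errors
  sd_pop <- sqrt(mean((e - mean(e))^2))
  cutoff <- mean(e) + threshold * sd_pop
  keep <- e <= cutoff
  list(keep = keep, n_removed = sum(!keep), cutoff = cutoff)
}

#' Evaluate a parameter set against a dataset
#'
#' @param params a \code{tb_paramset}
#' @param ds a \code{tb_dataset} carrying targets for \code{target_method}
#' @param target_method method label of the targets
#' @param scf \code{\link{scf_options}}
#' @param outlier_threshold SD threshold for energy-outlier removal
#'   (default 20); \code{NULL} disables removal
#' @return list (class \code{tb_eval}): \code{metrics} (data.frame),
#'   \code{reference_fit}, \code{n_failed} (unconverged configurations,
#'   excluded), \code{n_outliers}, and per-configuration \code{details}
#' @export
evaluate <- function(params, ds, target_method = "toy-truth",
                     scf = scf_options(), outlier_threshold = 20) {
  if (!length(ds)) stop("empty dataset")
  miss <- which(!vapply(ds, function(g)
    !is.null(g$targets[[target_method]]), logical(1)))
  if (length(miss))
    stop("configurations without '", target_method, "' targets: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  layout <- params_layout(params)
  x <- params_pack(params, layout)
  cache <- precompute_batch(ds, params, layout, method = target_method)
  des <- .repulsive_design(ds, params)
  rep_coef <- unlist(lapply(des$rep_keys, function(k)
    spline_get_free(params$repulsive[[k]])))
  erep <- drop(des$M[, seq_len(des$n_rep), drop = FALSE] %*% rep_coef)

  n <- length(ds)
  ok <- logical(n)
  e_pred <- numeric(n)
  dip_err <- list()
  q_err <- list()
  natoms <- nheavy <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch(cpp_scf_mol(cache[[i]], x, scf),
                    error = function(e) list(ok = FALSE))
    if (!isTRUE(res$ok) || !isTRUE(res$converged)) next
    ok[i] <- TRUE
    e_pred[i] <- res$e_electronic + erep[i]
    tg <- ds[[i]]$targets[[target_method]]
    if (!is.null(tg$dipole))
      dip_err[[length(dip_err) + 1L]] <- drop(res$dipole) - tg$dipole
    if (!is.null(tg$charges))
      q_err[[length(q_err) + 1L]] <- drop(res$q_atom) - tg$charges
    natoms[i] <- length(ds[[i]]$z)
    nheavy[i] <- sum(ds[[i]]$z != 1L)
  }
  if (!any(ok)) stop("SCF failed on every configuration")
  kept <- which(ok)
  t_e <- vapply(kept, function(i) ds[[i]]$targets[[target_method]]$energy,
                numeric(1))
  rfit <- fit_reference_energy(e_pred[kept], t_e, ds[kept],
                               allow_rank_deficient = TRUE)
  res_e <- -rfit$residuals  # prediction - target after reference refit

  n_out <- 0L
  keep2 <- rep(TRUE, length(kept))
  if (!is.null(outlier_threshold)) {
    om <- remove_outliers(res_e, threshold = outlier_threshold)
    keep2 <- om$keep
    n_out <- om$n_removed
  }
  res_k <- res_e[keep2]
  na_k <- natoms[kept][keep2]
  nh_k <- pmax(nheavy[kept][keep2], 1)
  dip_v <- if (length(dip_err)) abs(unlist(dip_err[keep2])) else numeric(0)
  q_v <- if (length(q_err)) abs(unlist(q_err[keep2])) else numeric(0)
  metrics <- data.frame(
    metric = c("energy_mae_kcal", "energy_mae_kcal_per_atom",
               "energy_mae_kcal_per_heavy_atom", "dipole_mae_eA",
               "charge_mae_e"),
    value = c(mean(abs(res_k)) * KCAL_PER_HA,
              mean(abs(res_k) / na_k) * KCAL_PER_HA,
              mean(abs(res_k) / nh_k) * KCAL_PER_HA,
              if (length(dip_v)) mean(dip_v) else NA_real_,
              if (length(q_v)) mean(q_v) else NA_real_))
  structure(list(metrics = metrics, reference_fit = rfit$reference,
                 n_failed = sum(!ok), n_outliers = n_out,
                 details = data.frame(index = kept,
                                      residual_ha = res_e,
                                      kept = keep2)),
            class = "tb_eval")
}

#' @export
print.tb_eval <- function(x, ...) {
  cat("<tb_eval>\n")
  for (i in seq_len(nrow(x$metrics)))
    cat(sprintf("  %-32s %10.5f\n", x$metrics$metric[i], x$metrics$value[i]))
  if (x$n_failed) cat("  (", x$n_failed, "unconverged configurations excluded )\n")
  if (x$n_outliers) cat("  (", x$n_outliers, "outlier(s) removed )\n")
  invisible(x)
}

#' Channel-recovery comparison between two parameter sets
#'
#' Compares the electronic channels of two parameter sets over the
#' distances actually sampled by a dataset (the "well-sampled" range).
#' Hamiltonian differences are reported in kcal/mol directly; overlap
#' differences are converted to an equivalent energy scale through the
#' Wolfsberg-Helmholz factor (0.875 times the summed on-site energies of
#' the channel's shells), so both channel kinds share one energy-equivalent
#' metric.
#'
#' @param ps_fit,ps_ref parameter sets to compare (e.g. trained vs
#'   generating truth)
#' @param ds dataset supplying the sampled distances
#' @param quantile_range distance quantiles per pair defining "well
#'   sampled" (default c(0.05, 0.95))
#' @return data.frame: channel key, number of sampled distances, mean and
#'   max absolute deviation in kcal/mol equivalents
#' @export
channel_recovery <- function(ps_fit, ps_ref, ds,
                             quantile_range = c(0.05, 0.95)) {
  # pair distances from the dataset
  bag <- list()
  for (g in ds) {
    nat <- length(g$z)
    if (nat < 2L) next
    D <- as.matrix(stats::dist(g$xyz))
    for (a in 1:(nat - 1L)) for (b in (a + 1L):nat) {
      k <- paste(sort(c(g$z[a], g$z[b])), collapse = "-")
      bag[[k]] <- c(bag[[k]], D[a, b])
    }
  }
  rows <- list()
  for (key in sort(names(ps_ref$electronic))) {
    spR <- ps_ref$electronic[[key]]
    spF <- ps_fit$electronic[[key]]
    if (is.null(spF)) next
    pk <- paste(sort(spR$pair), collapse = "-")
    d <- bag[[pk]]
    if (is.null(d)) next
    qr_ <- stats::quantile(d, quantile_range)
    r <- d[d >= qr_[1] & d <= qr_[2] & d < spR$r_cut]
    if (length(r) < 5L) next
    dev <- abs(spline_eval(spF, r) - spline_eval(spR, r))
    if (startsWith(key, "S:")) {
      parts <- strsplit(key, ":")[[1]]
      eps <- abs(.wh_eps(
        stats::setNames(
          unlist(lapply(names(ps_ref$shells), function(sym)
            lapply(ps_ref$shells[[sym]], `[[`, "onsite"))),
          unlist(lapply(names(ps_ref$shells), function(sym)
            paste0(sym, ".", names(ps_ref$shells[[sym]]))))),
        spR$pair[1], spR$pair[2], parts[3]))
      dev <- dev * 0.875 * eps
    }
    rows[[key]] <- data.frame(channel = key, n = length(r),
                              mae_kcal = mean(dev) * KCAL_PER_HA,
                              max_kcal = max(dev) * KCAL_PER_HA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
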