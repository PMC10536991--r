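#' Parameter sets: all trainable quantities of the tight-binding model
#'
#' A parameter set bundles per-shell constants (on-site energies and Hubbard
#' parameters, both in Hartree), the electronic channel splines (Hamiltonian
#' \code{H1} and overlap \code{S} for every Slater-Koster channel of every
#' element pair), the pairwise repulsive splines, and the linear reference
#' energy (one coefficient per element plus a constant, all in Hartree).
#'
#' Channel keys are strings \code{"<kind>:<zA>-<zB>:<channel>"}. For
#' \code{ss_sigma}, \code{pp_sigma} and \code{pp_pi} the pair is stored with
#' \code{zA <= zB} (the functions are symmetric under exchanging the
#' centers); \code{sp_sigma} is stored for each ordered pair that carries an
#' s orbital on the first and a p shell on the second element. Repulsive
#' splines use kind \code{R}, channel \code{"rep"}, \code{zA <= zB}.
#'
#' @name parameter_set
NULL

channel_key <- function(kind, zA, zB, channel) {
  sprintf("%s:%d-%d:%s", kind, zA, zB, channel)
}

# Channels required for an unordered element pair (a <= b), for one
# electronic kind ("H1" or "S").
pair_channels <- function(a, b, kind = "H1") {
  a <- min(a, b); b <- max(a, b)
  out <- list(list(zA = a, zB = b, channel = "ss_sigma"))
  if (element_has_p(b)) out <- c(out, list(list(zA = a, zB = b, channel = "sp_sigma")))
  if (element_has_p(a) && a != b) out <- c(out, list(list(zA = b, zB = a, channel = "sp_sigma")))
  if (element_has_p(a) && element_has_p(b)) {
    out <- c(out, list(list(zA = a, zB = b, channel = "pp_sigma"),
                       list(zA = a, zB = b, channel = "pp_pi")))
  }
  for (i in seq_along(out)) out[[i]]$kind <- kind
  out
}

#' Construct a parameter set
#'
#' @param shells named list (element symbol -> list(shell -> list(onsite,
#'   hubbard))), energies in Hartree
#' @param electronic named list of \code{channel_spline} (kinds H1/S), keyed
#'   by \code{channel_key}
#' @param repulsive named list of \code{channel_spline} (kind R)
#' @param reference list(c_elements = named numeric per element symbol,
#'   c0 = numeric)
#' @param meta free-form provenance list
#' @return object of class \code{tb_paramset}
#' @export
parameter_set <- function(shells, electronic, repulsive,
                          reference = NULL, meta = list()) {
  elements <- element_z(names(shells))
  if (is.null(reference)) {
    reference <- list(c_elements = stats::setNames(rep(0, length(shells)),
                                                   names(shells)), c0 = 0)
  }
  for (sym in names(shells)) {
    z <- element_z(sym)
    for (sh in element_shells(z)) {
      rec <- shells[[sym]][[sh]]
      if (is.null(rec)) stop("element ", sym, " missing shell ", sh)
      if (!is.finite(rec$hubbard) || rec$hubbard <= 0)
        stop("Hubbard parameter must be positive for ", sym, " ", sh)
    }
    if (!element_has_p(z) && !is.null(shells[[sym]]$p))
      stop("element ", sym, " must not carry a p shell")
  }
  structure(list(shells = shells, electronic = electronic,
                 repulsive = repulsive, reference = reference, meta = meta),
            class = "tb_paramset")
}

#' @export
print.tb_paramset <- function(x, ...) {
  cat(sprintf("<tb_paramset: elements %s, %d electronic channels, %d repulsive pairs>\n",
              paste(names(x$shells), collapse = ","),
              length(x$electronic), length(x$repulsive)))
  invisible(x)
}

#' Check that a parameter set covers the element pairs of a dataset
#' @param ps a \code{tb_paramset}
#' @param ds a \code{tb_dataset}
#' @return invisible TRUE, or an error naming the missing channel
#' @export
validate_coverage <- function(ps, ds) {
  zs <- sort(unique(unlist(lapply(ds, function(g) g$z))))
  for (ai in seq_along(zs)) for (bi in ai:length(zs)) {
    a <- zs[ai]; b <- zs[bi]
    for (kind in c("H1", "S")) {
      for (ch in pair_channels(a, b, kind)) {
        k <- channel_key(ch$kind, ch$zA, ch$zB, ch$channel)
        if (is.null(ps$electronic[[k]]))
          stop("parameter set missing channel ", k)
      }
    }
    rk <- channel_key("R", min(a, b), max(a, b), "rep")
    if (is.null(ps$repulsive[[rk]]))
      stop("parameter set missing repulsive spline ", rk)
  }
  invisible(TRUE)
}

# Ordered shell labels ("H.s", "C.s", "C.p", ...) of a parameter set.
paramset_shell_labels <- function(ps) {
  out <- character(0)
  for (sym in names(ps$shells))
    for (sh in element_shells(element_z(sym)))
      out <- c(out, paste0(sym, ".", sh))
  sort(out)
}

shell_value <- function(ps, label, field) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  ps$shells[[parts[1]]][[parts[2]]][[field]]
}

# ---------------------------------------------------------------------------
# Flat trainable vector <-> parameter set.
# Order: electronic spline free coefficients (sorted channel keys), on-site
# energies, Hubbard parameters, inflection latents of S channels.
# Repulsive coefficients and reference energy are NOT in the vector: they are
# refit by convex optimization on the charge-update schedule.

#' Layout of the flat trainable parameter vector
#'
#' @param ps a \code{tb_paramset}
#' @param train_hubbard include Hubbard parameters as trainables
#' @param train_inflection include inflection-point latents of S channels
#' @return a layout object used by \code{\link{params_pack}} and the
#'   training kernels
#' @export
params_layout <- function(ps, train_hubbard = TRUE, train_inflection = TRUE) {
  keys <- sort(names(ps$electronic))
  off <- 0L
  chan <- data.frame(key = keys, offset = NA_integer_, n_free = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    nf <- spline_n_free(ps$electronic[[keys[i]]])
    chan$offset[i] <- off
    chan$n_free[i] <- nf
    off <- off + nf
  }
  labels <- paramset_shell_labels(ps)
  onsite_idx <- stats::setNames(off + seq_along(labels), labels)
  off <- off + length(labels)
  hubbard_idx <- stats::setNames(off + seq_along(labels), labels)
  off <- off + length(labels)
  s_keys <- sort(grep("^S:", keys, value = TRUE))
  infl_idx <- stats::setNames(off + seq_along(s_keys), s_keys)
  off <- off + length(s_keys)
  structure(list(channels = chan, onsite = onsite_idx, hubbard = hubbard_idx,
                 inflection = infl_idx, n_par = off,
                 shell_labels = labels,
                 train_hubbard = train_hubbard,
                 train_inflection = train_inflection),
            class = "tb_layout")
}

# latent <-> inflection location: x = r_low + (r_cut - r_low) * sigmoid(t)
.infl_to_latent <- function(x, r_low, r_cut) {
  f <- (x - r_low) / (r_cut - r_low)
  f <- min(max(f, 1e-6), 1 - 1e-6)
  log(f / (1 - f))
}
.latent_to_infl <- function(t, r_low, r_cut) {
  r_low + (r_cut - r_low) / (1 + exp(-t))
}

#' Pack a parameter set into its flat trainable vector
#' @param ps a \code{tb_paramset}
#' @param layout from \code{\link{params_layout}}
#' @return numeric vector of length \code{layout$n_par}
#' @export
params_pack <- function(ps, layout) {
  x <- numeric(layout$n_par)
  for (i in seq_len(nrow(layout$channels))) {
    k <- layout$channels$key[i]
    sp <- ps$electronic[[k]]
    x[layout$channels$offset[i] + seq_len(layout$channels$n_free[i])] <-
      spline_get_free(sp)
  }
  for (lab in names(layout$onsite))
    x[layout$onsite[lab]] <- shell_value(ps, lab, "onsite")
  if (!is.null(layout$hubbard))
    for (lab in names(layout$hubbard))
      x[layout$hubbard[lab]] <- shell_value(ps, lab, "hubbard")
  if (!is.null(layout$inflection)) {
    for (k in names(layout$inflection)) {
      sp <- ps$electronic[[k]]
      xi <- if (!is.null(sp$inflection_x)) sp$inflection_x
            else sp$r_low + 0.25 * (sp$r_cut - sp$r_low)
      x[layout$inflection[k]] <- .infl_to_latent(xi, sp$r_low, sp$r_cut)
    }
  }
  x
}

#' Write a flat trainable vector back into a parameter set
#' @inheritParams params_pack
#' @param x numeric vector of length \code{layout$n_par}
#' @return updated \code{tb_paramset}
#' @export
params_unpack <- function(ps, layout, x) {
  stopifnot(length(x) == layout$n_par)
  for (i in seq_len(nrow(layout$channels))) {
    k <- layout$channels$key[i]
    ps$electronic[[k]] <- spline_set_free(
      ps$electronic[[k]],
      x[layout$channels$offset[i] + seq_len(layout$channels$n_free[i])])
  }
  for (lab in names(layout$onsite)) {
    parts <- strsplit(lab, ".", fixed = TRUE)[[1]]
    ps$shells[[parts[1]]][[parts[2]]]$onsite <- x[layout$onsite[lab]]
  }
  if (!is.null(layout$hubbard)) {
    for (lab in names(layout$hubbard)) {
      parts <- strsplit(lab, ".", fixed = TRUE)[[1]]
      ps$shells[[parts[1]]][[parts[2]]]$hubbard <- x[layout$hubbard[lab]]
    }
  }
  if (!is.null(layout$inflection)) {
    for (k in names(layout$inflection)) {
      sp <- ps$electronic[[k]]
      ps$electronic[[k]]$inflection_x <-
        .latent_to_infl(x[layout$inflection[k]], sp$r_low, sp$r_cut)
    }
  }
  ps
}

# ---------------------------------------------------------------------------
# YAML checkpoints

#' Save a parameter set as YAML
#' @param ps a \code{tb_paramset}
#' @param path output file
#' @export
paramset_save <- function(ps, path) {
  ser_spline <- function(sp) {
    list(kind = sp$kind, pair = as.integer(sp$pair), channel = sp$channel,
         r_low = sp$r_low, r_cut = sp$r_cut, n_basis = sp$n_basis,
         coefficients = as.numeric(sp$coefficients),
         inflection_x = sp$inflection_x,
         curvature_sign = sp$curvature_sign)
  }
  obj <- list(
    shells = ps$shells,
    electronic = lapply(ps$electronic, ser_spline),
    repulsive = lapply(ps$repulsive, ser_spline),
    reference = ps$reference,
    meta = ps$meta
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Load a parameter set from YAML
#' @param path file written by \code{\link{paramset_save}}
#' @return a \code{tb_paramset}
#' @export
paramset_load <- function(path) {
  obj <- yaml::read_yaml(path)
  de_spline <- function(s) {
    channel_spline(s$kind, s$pair, s$channel, s$r_low, s$r_cut,
                   n_basis = s$n_basis, coefficients = as.numeric(s$coefficients),
                   inflection_x = s$inflection_x,
                   curvature_sign = if (is.null(s$curvature_sign)) NA_real_
                                    else s$curvature_sign)
  }
  ref <- obj$reference
  ref$c_elements <- unlist(ref$c_elements)
  parameter_set(obj$shells,
                lapply(obj$electronic, de_spline),
                lapply(obj$repulsive, de_spline),
                reference = ref,
                meta = obj$meta)
}
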