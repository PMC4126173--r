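## Synthetic ILD functions: prototype shapes, perturbation, surrogate surveys.

#' Basic ILD curve shapes
#'
#' Parametric forms for the canonical ILD sensitivity function families:
#' a logistic sigmoid (EI/IE cells), a Gaussian peak (peaked cells) and a
#' constant (insensitive cells). `direction = +1` gives a curve increasing
#' with ILD (IE: excited by the contralateral ear, which is louder at
#' positive ILDs); `direction = -1` gives the mirror-image EI curve.
#'
#' @param x numeric vector of ILD levels (dB).
#' @param m amplitude in spikes/stimulus.
#' @param x0 midpoint (sigmoid) or peak position (peak), dB.
#' @param s sigmoid slope scale, dB.
#' @param w peak half-width (Gaussian sigma), dB.
#' @param direction +1 (increasing, IE) or -1 (decreasing, EI).
#' @return numeric vector of spike counts, same length as `x`.
#' @rdname ild-shapes
#' @export
ild_sigmoid <- function(x, m = 100, x0 = 0, s = 5, direction = 1) {
  m / (1 + exp(-direction * (x - x0) / s))
}

#' @rdname ild-shapes
#' @export
ild_peak <- function(x, m = 100, x0 = 0, w = 10) {
  m * exp(-(x - x0)^2 / (2 * w^2))
}

#' @rdname ild-shapes
#' @export
ild_flat <- function(x, m = 100) rep(m, length(x))

#' Generate the nine prototypical ILD function panels
#'
#' Builds the synthetic test bench used to compare normalization methods:
#' nine panels (A-I) of idealised ILD functions on a 0-100 spikes/stimulus
#' scale. Panels A-C are sigmoids varying amplitude, cut-off position and
#' slope steepness; D-F are peaked functions varying amplitude, position,
#' and position jointly with width; G blends a peak into a sigmoid, H blends
#' a peak into a flat function; I is insensitive (constant) at several
#' amplitudes. Parametric forms and variant grids are package defaults
#' (see the methods vignette); the qualitative features per panel are fixed.
#'
#' @param axis an [ild_axis].
#' @param m_max full-scale amplitude, spikes/stimulus (default 100).
#' @return object of class `"ild_prototypes"`: list with `panels` (named
#'   list of variant x level matrices) and `axis`.
#' @export
make_prototypes <- function(axis = ild_axis(), m_max = 100) {
  stopifnot(m_max > 0)
  x <- as.numeric(axis)
  validate_axis(x)
  rowbind <- function(...) do.call(rbind, list(...))
  panels <- list(
    # sigmoids: amplitude / cut-off position / slope steepness
    A = rowbind(ild_sigmoid(x, m = 0.25 * m_max), ild_sigmoid(x, m = 0.50 * m_max),
                ild_sigmoid(x, m = 0.75 * m_max), ild_sigmoid(x, m = m_max)),
    B = rowbind(ild_sigmoid(x, m = m_max, x0 = -10), ild_sigmoid(x, m = m_max, x0 = 0),
                ild_sigmoid(x, m = m_max, x0 = 10)),
    C = rowbind(ild_sigmoid(x, m = m_max, s = 2.5), ild_sigmoid(x, m = m_max, s = 5),
                ild_sigmoid(x, m = m_max, s = 10)),
    # peaked: amplitude / position / position & width
    D = rowbind(ild_peak(x, m = 0.25 * m_max), ild_peak(x, m = 0.50 * m_max),
                ild_peak(x, m = 0.75 * m_max), ild_peak(x, m = m_max)),
    E = rowbind(ild_peak(x, m = m_max, x0 = -10), ild_peak(x, m = m_max, x0 = 0),
                ild_peak(x, m = m_max, x0 = 10)),
    F = rowbind(ild_peak(x, m = m_max, x0 = -10, w = 5), ild_peak(x, m = m_max, x0 = 0, w = 10),
                ild_peak(x, m = m_max, x0 = 10, w = 15)),
    # transitional: peak -> sigmoid, peak -> flat
    G = rowbind(
      0.25 * ild_peak(x, m = m_max) + 0.75 * ild_sigmoid(x, m = m_max),
      0.50 * ild_peak(x, m = m_max) + 0.50 * ild_sigmoid(x, m = m_max),
      0.75 * ild_peak(x, m = m_max) + 0.25 * ild_sigmoid(x, m = m_max)),
    H = rowbind(
      0.25 * ild_peak(x, m = m_max) + 0.75 * ild_flat(x, m = 0.5 * m_max),
      0.50 * ild_peak(x, m = m_max) + 0.50 * ild_flat(x, m = 0.5 * m_max),
      0.75 * ild_peak(x, m = m_max) + 0.25 * ild_flat(x, m = 0.5 * m_max)),
    # insensitive at several amplitudes
    I = rowbind(ild_flat(x, m = 0.25 * m_max), ild_flat(x, m = 0.50 * m_max),
                ild_flat(x, m = 0.75 * m_max), ild_flat(x, m = m_max))
  )
  for (p in names(panels)) {
    rownames(panels[[p]]) <- sprintf("%s%d", p, seq_len(nrow(panels[[p]])))
    colnames(panels[[p]]) <- as.character(x)
  }
  structure(list(panels = panels, axis = x, m_max = m_max),
            class = "ild_prototypes")
}

#' @export
print.ild_prototypes <- function(x, ...) {
  cat(sprintf("ILD prototype bench: %d panels, %d curves, amplitude scale %g\n",
              length(x$panels), sum(vapply(x$panels, nrow, 0L)), x$m_max))
  invisible(x)
}

#' Stack prototype panels into one matrix
#' @param protos an `"ild_prototypes"` object.
#' @return curves x levels matrix; rownames carry the panel tag.
#' @export
proto_matrix <- function(protos) {
  do.call(rbind, unname(protos$panels))
}

#' Perturb ILD curves by a fraction of full scale
#'
#' Applies the three-step perturbation used to make the prototype bench look
#' realistic: (i) draw one uniform number in `[-fraction, +fraction]` per
#' level per curve, (ii) add `u * m` to the counts (so with `fraction = 0.06`
#' and `m = 100` each value moves by at most 6 spikes/stimulus), and (iii)
#' monitor the result, clamping below at `floor` so every value remains
#' valid for all normalizations (strictly positive for the logarithmic one).
#'
#' @param x numeric matrix of curves (rows) or a single curve vector.
#' @param fraction perturbation half-range as a fraction of `m` (default 0.06).
#' @param m amplitude scale the fraction refers to (default 100).
#' @param floor minimum permitted value after perturbation (default 0.1).
#' @param seed optional integer seed for reproducibility.
#' @return perturbed object of the same shape.
#' @export
perturb_ild <- function(x, fraction = 0.06, m = 100, floor = 0.1, seed = NULL) {
  stopifnot(fraction >= 0, floor >= 0, m > 0)
  if (!is.null(seed)) set.seed(seed)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  u <- matrix(stats::runif(length(xm), -fraction, fraction), nrow = nrow(xm))
  out <- pmax(xm + u * m, floor)
  if (vec) out <- drop(out) else dimnames(out) <- dimnames(xm)
  out
}

#' The seven planted survey templates
#'
#' Templates emulating the seven ILD function classes observed in a midbrain
#' survey: an increasing (IE) and a decreasing (EI) sigmoid, a peak-to-sigmoid
#' transition, a broad and a narrow peak, an "arisen" peak riding on a
#' plateau (peak-to-flat transition), and an insensitive function.
#'
#' @param axis an [ild_axis].
#' @param m amplitude scale (default 100 spikes/stimulus).
#' @return 7 x L matrix, one template per row.
#' @export
survey_templates <- function(axis = ild_axis(), m = 100) {
  x <- as.numeric(axis)
  t <- rbind(
    sigmoid_ie   = ild_sigmoid(x, m = m, x0 = 0, s = 5, direction = 1),
    sigmoid_ei   = ild_sigmoid(x, m = m, x0 = 0, s = 5, direction = -1),
    peak_sigmoid = 0.5 * ild_peak(x, m = m, x0 = -5, w = 10) +
                   0.5 * ild_sigmoid(x, m = m, x0 = 0, s = 5, direction = -1),
    peak_broad   = ild_peak(x, m = m, x0 = 0, w = 12),
    peak_narrow  = ild_peak(x, m = m, x0 = 5, w = 5),
    peak_arisen  = 0.5 * ild_peak(x, m = m, x0 = 0, w = 6) +
                   0.5 * ild_flat(x, m = 0.55 * m),
    insensitive  = ild_flat(x, m = 0.5 * m)
  )
  colnames(t) <- as.character(x)
  t
}

#' Simulate a surrogate survey with planted cluster structure
#'
#' Draws `n_cells` ILD functions, each a noisy realization of one of the
#' planted templates, with per-cell amplitude jitter (multiplicative,
#' uniform) and additive truncated-Gaussian count noise whose SD scales
#' with the cell's amplitude. Defaults reproduce the composition of the
#' 208-cell survey the pipeline was designed around (group sizes
#' 61/19/36/25/21/11/35) with moderate amplitude spread; see the methods
#' vignette for what the generator does and does not emulate about real
#' surveys, whose amplitude range is far wider.
#'
#' @param n_cells total number of cells (default 208).
#' @param proportions integer member count per template; must sum to `n_cells`.
#' @param templates template matrix, one row per planted group
#'   (default [survey_templates()]).
#' @param axis an [ild_axis] matching `ncol(templates)`.
#' @param amp_range range of the per-cell amplitude multiplier.
#' @param noise_sd_frac additive noise SD as a fraction of the cell's
#'   amplitude times the template full scale (0 disables noise).
#' @param floor minimum count after noise (keeps log normalization valid).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list with `dataset` (an [ild_dataset]) and `labels`
#'   (integer vector of planted group ids, named by cell).
#' @export
simulate_survey <- function(n_cells = 208,
                            proportions = c(61, 19, 36, 25, 21, 11, 35),
                            templates = survey_templates(axis),
                            axis = ild_axis(),
                            amp_range = c(0.85, 1.15),
                            noise_sd_frac = 0.06,
                            floor = 0.1,
                            seed = NULL) {
  if (sum(proportions) != n_cells) {
    stop(sprintf("proportions sum to %d, not n_cells = %d",
                 sum(proportions), n_cells))
  }
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (nrow(templates) < length(proportions)) {
    stop("templates must cover every planted group")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- length(axis)
  stopifnot(ncol(templates) == L)
  labels <- rep(seq_along(proportions), proportions)
  counts <- matrix(0, n_cells, L)
  tmpl_scale <- apply(templates, 1, max)
  for (i in seq_len(n_cells)) {
    g <- labels[i]
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    mu <- amp * templates[g, ]
    sd <- noise_sd_frac * amp * tmpl_scale[g]
    eps <- if (sd > 0) stats::rnorm(L, 0, sd) else 0
    counts[i, ] <- pmax(mu + eps, floor)
  }
  ds <- ild_dataset(counts, axis)
  names(labels) <- rownames(ds$counts)
  list(dataset = ds, labels = labels)
}
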