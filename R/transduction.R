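#' Receptor-potential parameters
#'
#' The receptor potential is modelled phenomenologically as a
#' mechanotransduction conductance computed from intrafusal fibre
#' mechanics: a weighted sum of the half-wave rectified bag force, bag
#' yank, and chain force, scaled by a global force-to-conductance factor.
#'
#' @param kfb Weight on bag-fibre force.
#' @param kyb Weight on bag-fibre yank.
#' @param kfc Weight on chain-fibre force.
#' @param scale Global force-to-drive scale factor (default 2e5).  The
#'   weights and scale are calibrated once against the prototypical Ia
#'   response and then held fixed for all simulations; the defaults here
#'   are the calibrated values.
#' @param e_rev_mV Reversal potential of the transduction conductance
#'   (mV); 0 mV models a non-selective cation conductance.
#' @return An object of class `receptor_params`.
#' @export
receptor_params <- function(kfb = 0.06, kyb = 0.0017, kfc = 0.06,
                            scale = 2e5, e_rev_mV = 0) {
  if (kfb < 0 || kyb < 0 || kfc < 0) stop("weights must be >= 0")
  if (scale <= 0) stop("scale must be > 0")
  structure(list(kfb = kfb, kyb = kyb, kfc = kfc, scale = scale,
                 e_rev_mV = e_rev_mV),
            class = "receptor_params")
}

#' Half-wave rectification
#'
#' @param x Numeric series.
#' @return `pmax(x, 0)` element-wise.
#' @export
halfwave_rectify <- function(x) {
  if (any(!is.finite(x))) stop("series must be finite")
  pmax(x, 0)
}

#' Compute the receptor-potential drive from bag and chain force traces
#'
#' `g_drive = scale * (kfb*[F_bag]+ + kyb*[Y_bag]+ + kfc*[F_chain]+)`,
#' with each component half-wave rectified before weighting.  The drive
#' is a non-negative conductance (uS) injected into the terminal
#' compartments of the afferent model.
#'
#' @param bag,chain `force_trace` objects on the same time grid.
#' @param p A [receptor_params()].
#' @return A `drive_signal` list with `t` (s) and `g_uS`.
#' @export
compute_receptor_drive <- function(bag, chain, p = receptor_params()) {
  stopifnot(inherits(bag, "force_trace"), inherits(chain, "force_trace"))
  if (length(bag$t) != length(chain$t) ||
      max(abs(bag$t - chain$t)) > 1e-12)
    stop("bag and chain traces must share the time grid")
  g <- p$scale * (p$kfb * halfwave_rectify(bag$force) +
                    p$kyb * halfwave_rectify(bag$yank) +
                    p$kfc * halfwave_rectify(chain$force))
  # scale is the conventional 2e5 force->receptor-potential factor; the
  # calibrated weights absorb its units.  1e-6 converts to uS.
  structure(list(t = bag$t, g_uS = g * 1e-6, e_rev_mV = p$e_rev_mV),
            class = "drive_signal")
}
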