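# Extensible worm-like-chain mechanics for single elements and for tethers
# composed of elements in series (DNA handles + protein), the elastic backbone
# of both the simulator and the branch fits.

#' WLC element parameters
#'
#' Bundle the parameters of one extensible worm-like-chain (WLC) element:
#' persistence length \eqn{L_p}, contour length \eqn{L_c}, stretch modulus
#' \eqn{K} and thermal energy \eqn{k_B T}.  Force--extension behaviour follows
#' the Marko--Siggia interpolation with an enthalpic stretch term,
#' \deqn{F = \frac{k_B T}{L_p}\left[\frac{1}{4(1 - x/L_c + F/K)^2}
#'   - \frac14 + \frac{x}{L_c} - \frac{F}{K}\right].}
#'
#' @param persistence_length Persistence length in nm; must be positive and
#'   smaller than `contour_length`.
#' @param contour_length Contour length in nm.
#' @param stretch_modulus Enthalpic stretch modulus in pN.
#' @param thermal_energy \eqn{k_B T} in pN nm.  The default 4.114 corresponds
#'   to 298 K.
#' @param role Optional label (`"handle"`, `"folded_protein"`,
#'   `"unfolded_polypeptide"`) used when elements are composed into a tether.
#' @return An object of class `wlc_params`.
#' @examples
#' handle <- wlc_params(30, 408, 500)
#' ewlc_extension(10, handle)
#' @export
wlc_params <- function(persistence_length, contour_length, stretch_modulus,
                       thermal_energy = 4.114, role = NULL) {
  check_number(persistence_length, "persistence_length", min = 0, allow_zero = FALSE)
  check_number(contour_length, "contour_length", min = 0, allow_zero = FALSE)
  check_number(stretch_modulus, "stretch_modulus", min = 0, allow_zero = FALSE)
  check_number(thermal_energy, "thermal_energy", min = 0, allow_zero = FALSE)
  if (persistence_length >= contour_length) {
    stop_invalid("`persistence_length` must be smaller than `contour_length`.")
  }
  structure(
    list(persistence_length = persistence_length,
         contour_length = contour_length,
         stretch_modulus = stretch_modulus,
         thermal_energy = thermal_energy,
         role = role),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("<wlc_params%s> Lp = %g nm, Lc = %g nm, K = %g pN, kBT = %g pN nm\n",
              if (is.null(x$role)) "" else paste0(": ", x$role),
              x$persistence_length, x$contour_length, x$stretch_modulus,
              x$thermal_energy))
  invisible(x)
}

# Solve the Marko-Siggia relation f(z) = 1/(4(1-z)^2) - 1/4 + z = target for
# z in [0, 1) by vectorised bisection.  f is strictly increasing on [0, 1), so
# 60 halvings pin z to ~1e-18.
ms_inverse <- function(target) {
  out <- numeric(length(target))
  pos <- target > 0
  if (any(pos)) {
    tg <- target[pos]
    lo <- rep(0, length(tg))
    hi <- rep(1 - 1e-12, length(tg))
    for (i in seq_len(60)) {
      mid <- (lo + hi) / 2
      val <- 1 / (4 * (1 - mid)^2) - 0.25 + mid
      below <- val < tg
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    out[pos] <- (lo + hi) / 2
  }
  out
}

# Relative extension zeta(F) = x/Lc of an extensible WLC; vectorised over force.
ewlc_zeta <- function(force, lp, k, kbt) {
  ms_inverse(force * lp / kbt) + force / k
}

#' Extension of an extensible WLC at a given force
#'
#' Numerically inverts the Marko--Siggia interpolation formula (which gives
#' force as a function of extension) to return the equilibrium extension at a
#' prescribed force.  Strictly increasing and continuous in force, with
#' `ewlc_extension(0, p) == 0`.
#'
#' @param force Force in pN; vectorised, all values must be finite and
#'   non-negative.
#' @param params A [wlc_params()] object.
#' @return Extension in nm, same length as `force`.
#' @seealso [ewlc_force()] for the inverse, [tether_extension()] for series
#'   composition.
#' @export
ewlc_extension <- function(force, params) {
  if (!inherits(params, "wlc_params")) stop_invalid("`params` must be a `wlc_params` object.")
  if (!is.numeric(force) || any(!is.finite(force))) {
    stop_invalid("`force` must be finite and numeric.")
  }
  if (any(force < 0)) stop_invalid("`force` must be non-negative.")
  params$contour_length *
    ewlc_zeta(force, params$persistence_length, params$stretch_modulus,
              params$thermal_energy)
}

#' Force of an extensible WLC at a given extension
#'
#' Numeric inverse of [ewlc_extension()] by bracketed bisection on
#' \eqn{[0, f_{cap}]}.  The round trip
#' `ewlc_extension(ewlc_force(x, p), p)` recovers `x` to better than 1e-6
#' relative.
#'
#' @inheritParams ewlc_extension
#' @param extension Extension in nm; vectorised, each value must be
#'   non-negative and below the extension reached at `force_cap`.
#' @param force_cap Upper bracket of the solver in pN (default 200).
#' @return Force in pN.
#' @export
ewlc_force <- function(extension, params, force_cap = 200) {
  if (!inherits(params, "wlc_params")) stop_invalid("`params` must be a `wlc_params` object.")
  if (!is.numeric(extension) || any(!is.finite(extension))) {
    stop_invalid("`extension` must be finite and numeric.")
  }
  if (any(extension < 0)) stop_invalid("`extension` must be non-negative.")
  xmax <- ewlc_extension(force_cap, params)
  if (any(extension >= xmax)) {
    stop_range(sprintf(
      "extension outside invertible range: must be < %.6g nm (extension at the %g pN force cap)",
      xmax, force_cap))
  }
  out <- numeric(length(extension))
  pos <- extension > 0
  if (any(pos)) {
    x <- extension[pos]
    lo <- rep(0, length(x))
    hi <- rep(force_cap, length(x))
    for (i in seq_len(80)) {
      mid <- (lo + hi) / 2
      below <- ewlc_extension(mid, params) < x
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    out[pos] <- (lo + hi) / 2
  }
  out
}

#' Series tether of WLC elements
#'
#' A tether is an ordered series of WLC elements (DNA handles, unfolded
#' polypeptide, ...) plus a rigid offset accounting for the folded core's
#' fixed N--C span.  At any force the tether extension is the sum of the
#' element extensions plus the offset, so it is strictly increasing in force.
#'
#' @param elements A list of [wlc_params()] objects (at least one).
#' @param rigid_offset Force-independent span in nm (default 0).
#' @return An object of class `tether_model`.
#' @examples
#' handle <- wlc_params(30, 204, 500, role = "handle")
#' tm <- tether_model(list(handle, handle), rigid_offset = 15)
#' tether_extension(7.2, tm)
#' @export
tether_model <- function(elements, rigid_offset = 0) {
  if (!is.list(elements) || length(elements) == 0L) {
    abort("`elements` must be a non-empty list of `wlc_params` objects.",
          class = "ripfit_invalid_model")
  }
  ok <- vapply(elements, inherits, logical(1), what = "wlc_params")
  if (!all(ok)) {
    abort("all `elements` must be `wlc_params` objects.",
          class = "ripfit_invalid_model")
  }
  check_number(rigid_offset, "rigid_offset", min = 0)
  structure(list(elements = elements, rigid_offset = rigid_offset),
            class = "tether_model")
}

#' @export
print.tether_model <- function(x, ...) {
  cat(sprintf("<tether_model> %d element(s), rigid offset %g nm\n",
              length(x$elements), x$rigid_offset))
  for (el in x$elements) print(el)
  invisible(x)
}

#' Extension of a series tether at a given force
#'
#' @param force Force in pN (vectorised).
#' @param model A [tether_model()].
#' @return Extension in nm: the sum of per-element [ewlc_extension()] values
#'   plus the rigid offset.
#' @export
tether_extension <- function(force, model) {
  if (!inherits(model, "tether_model")) {
    abort("`model` must be a `tether_model` object.", class = "ripfit_invalid_model")
  }
  parts <- lapply(model$elements, function(el) ewlc_extension(force, el))
  Reduce(`+`, parts) + model$rigid_offset
}

#' Force of a series tether at a given extension
#'
#' Inverse of [tether_extension()] by bracketed bisection.
#'
#' @inheritParams tether_extension
#' @param extension Extension in nm (vectorised); must be at least the rigid
#'   offset and below the tether extension at `force_cap`.
#' @param force_cap Upper solver bracket in pN.
#' @return Force in pN.
#' @export
tether_force <- function(extension, model, force_cap = 200) {
  if (!inherits(model, "tether_model")) {
    abort("`model` must be a `tether_model` object.", class = "ripfit_invalid_model")
  }
  x0 <- tether_extension(0, model)
  xmax <- tether_extension(force_cap, model)
  if (any(extension < x0) || any(extension >= xmax)) {
    stop_range(sprintf(
      "extension outside invertible range [%.6g, %.6g) nm at the %g pN force cap",
      x0, xmax, force_cap))
  }
  out <- numeric(length(extension))
  solve <- extension > x0
  if (any(solve)) {
    x <- extension[solve]
    lo <- rep(0, length(x))
    hi <- rep(force_cap, length(x))
    for (i in seq_len(80)) {
      mid <- (lo + hi) / 2
      below <- tether_extension(mid, model) < x
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    out[solve] <- (lo + hi) / 2
  }
  out
}

#' Fixed polymer constants of the repeat-protein tether
#'
#' Collects the fixed WLC constants used throughout the pipeline: the DNA
#' handles (persistence length 30 nm, stretch modulus 500 pN -- the midpoint
#' of the conventional 400--600 pN range for double-stranded DNA), the
#' unfolded polypeptide (persistence length 0.5 nm, stretch modulus 300 pN),
#' and the geometry of the construct: two 600 bp handles at 0.34 nm/bp
#' (408 nm combined), 589 residues at 0.365 nm/residue (~215 nm of fully
#' unfolded chain) and a 15 nm folded-core N--C span, so that complete
#' unfolding yields a net contour-length gain of ~200 nm.
#'
#' @param residues Number of protein residues.
#' @param n_repeats Number of tandem repeats (cooperative-block granularity).
#' @param handle_bp Length of each of the two DNA handles in base pairs.
#' @param nm_per_bp Contour rise per base pair (nm).
#' @param handle_lp,handle_k DNA persistence length (nm) and stretch modulus (pN).
#' @param protein_lp,protein_k Unfolded-polypeptide persistence length (nm) and
#'   stretch modulus (pN).
#' @param folded_span Rigid N--C span of the fully folded protein (nm).
#' @param nm_per_residue Contour length per unfolded residue (nm).
#' @param kbt Thermal energy in pN nm (298 K default).
#' @return A list of class `wlc_constants` with the inputs plus the derived
#'   `handle_lc` (combined handle contour, nm), `chain_total` (fully unfolded
#'   chain contour, nm) and `expected_dlc` (net contour gain of complete
#'   unfolding, nm).
#' @export
wlc_constants <- function(residues = 589, n_repeats = 15,
                          handle_bp = 600, nm_per_bp = 0.34,
                          handle_lp = 30, handle_k = 500,
                          protein_lp = 0.5, protein_k = 300,
                          folded_span = 15, nm_per_residue = 0.365,
                          kbt = 4.114) {
  out <- list(residues = residues, n_repeats = n_repeats,
              handle_bp = handle_bp, nm_per_bp = nm_per_bp,
              handle_lp = handle_lp, handle_k = handle_k,
              protein_lp = protein_lp, protein_k = protein_k,
              folded_span = folded_span, nm_per_residue = nm_per_residue,
              kbt = kbt)
  out$handle_lc <- 2 * handle_bp * nm_per_bp
  out$chain_total <- residues * nm_per_residue
  out$expected_dlc <- out$chain_total - folded_span
  if (out$expected_dlc <= 0) stop_invalid("folded span exceeds the unfolded chain length.")
  structure(out, class = "wlc_constants")
}

# Tether for a given net unfolded contour length `lc_net` (nm, in [0,
# expected_dlc]).  The single free coordinate couples the unfolded-chain
# contour and the shrinking folded-core span:
#   chain contour  = chain_total * (lc_net / expected_dlc)
#   rigid offset   = folded_span * (1 - lc_net / expected_dlc)
# so lc_net = 0 is the fully folded construct and lc_net = expected_dlc the
# fully unfolded one, and the reported contour-length change of complete
# unfolding equals chain_total - folded_span (~200 nm).
repeat_tether <- function(lc_net, constants = wlc_constants()) {
  u <- lc_net / constants$expected_dlc
  elements <- list(wlc_params(constants$handle_lp, constants$handle_lc,
                              constants$handle_k, constants$kbt,
                              role = "handle"))
  chain <- constants$chain_total * u
  if (chain > 0) {
    elements <- c(elements, list(
      wlc_params(constants$protein_lp, chain, constants$protein_k,
                 constants$kbt, role = "unfolded_polypeptide")))
  }
  tether_model(elements, rigid_offset = constants$folded_span * (1 - u))
}

# Fast grid evaluation of the same tether family: extension on a force grid
# as x(F; lc_net) = a(F) + lc_net * b(F), used by the simulator and the
# branch fits where thousands of evaluations are needed.
tether_grid <- function(constants, f_max = 80, n = 4001) {
  f <- seq(0, f_max, length.out = n)
  zeta_dna <- ewlc_zeta(f, constants$handle_lp, constants$handle_k, constants$kbt)
  zeta_pro <- ewlc_zeta(f, constants$protein_lp, constants$protein_k, constants$kbt)
  list(
    force = f,
    a = constants$handle_lc * zeta_dna + constants$folded_span,
    b = (constants$chain_total / constants$expected_dlc) * zeta_pro -
      constants$folded_span / constants$expected_dlc
  )
}
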