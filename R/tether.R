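# Tether geometry: a nicked duplex held between two beads at constant force.
# Unwinding converts tensioned duplex bp into tensioned ssDNA nt plus
# relaxed-coil nt that contribute zero end-to-end extension.

#' DNA template description
#'
#' @param total_bp template length in bp (>= 1000).
#' @param nick_positions integer bp offsets of nicks from the left attachment
#'   (0-based; position k means the nick lies between bp k and k+1). May be
#'   empty, in which case the simulator draws nick positions itself.
#' @param label free-text label.
#' @return an object of class `template_spec`.
#' @export
#' @examples
#' template_preset("nicked_6p4kbp")
template_spec <- function(total_bp, nick_positions = integer(0),
                          label = "custom") {
  total_bp <- as.integer(total_bp)
  nick_positions <- as.integer(nick_positions)
  if (total_bp < 1000) abort("total_bp must be >= 1000")
  if (length(nick_positions)) {
    if (any(nick_positions <= 0 | nick_positions >= total_bp)) {
      abort("nick positions must satisfy 0 < position < total_bp")
    }
    if (is.unsorted(nick_positions, strictly = TRUE)) {
      abort("nick positions must be strictly increasing")
    }
  }
  structure(list(total_bp = total_bp, nick_positions = nick_positions,
                 label = label),
            class = "template_spec")
}

#' Built-in template presets
#'
#' `lambda_48502` is the 48,502 bp lambda-phage template (nicks drawn at
#' simulation time); `nicked_6p4kbp` is the 6.4 kbp construct carrying a
#' single nick 2,200 bp from the left (5') attachment, leaving a 4,200 bp
#' segment toward the right (3') end.
#'
#' @param name preset name.
#' @return a [template_spec()].
#' @export
template_preset <- function(name = c("lambda_48502", "nicked_6p4kbp")) {
  name <- match.arg(name)
  switch(name,
    lambda_48502 = template_spec(48502L, integer(0), "lambda_48502"),
    nicked_6p4kbp = template_spec(6400L, 2200L, "nicked_6p4kbp"))
}

#' @export
print.template_spec <- function(x, ...) {
  cat("<template_spec>", x$label, "-", x$total_bp, "bp, nicks at",
      if (length(x$nick_positions)) paste(x$nick_positions, collapse = ", ")
      else "(drawn at simulation time)", "\n")
  invisible(x)
}

#' Tether composition at an instant
#'
#' Counts of tensioned duplex bp, tensioned ssDNA nt and relaxed-coil nt
#' along the tension path. Base pairs are conserved: `n_ds + n_ss` always
#' equals the template length, and for purely nick-initiated unwinding
#' `n_coil == n_ss` (each unwound bp puts one nt under tension and sends the
#' complementary nt into a coil).
#'
#' @param n_ds tensioned duplex, bp.
#' @param n_ss tensioned ssDNA, nt.
#' @param n_coil relaxed-coil ssDNA, nt.
#' @param force applied force, pN.
#' @return an object of class `tether_composition`.
#' @export
tether_composition <- function(n_ds, n_ss, n_coil = n_ss, force) {
  if (any(c(n_ds, n_ss, n_coil) < 0)) abort("all counts must be >= 0")
  if (force <= 0) abort("force must be > 0 pN")
  structure(list(n_ds = n_ds, n_ss = n_ss, n_coil = n_coil, force = force),
            class = "tether_composition")
}

#' End-to-end tether length
#'
#' `n_ds * x_ds(F) + n_ss * x_ss(F)`; relaxed coils contribute nothing.
#'
#' @param comp a [tether_composition()].
#' @param ss,ds elasticity parameter objects.
#' @return length in micrometres.
#' @export
tether_length <- function(comp, ss = ssdna_params(), ds = dsdna_params()) {
  (comp$n_ds * polymer_extension(ds, comp$force) +
     comp$n_ss * polymer_extension(ss, comp$force)) / 1000
}

#' Base pairs unwound from a tether-length change
#'
#' Divides a measured end-to-end length change by the per-bp conversion
#' factor \eqn{x_{ss}(F)-x_{ds}(F)}. Near the ss/ds crossover force the
#' divisor vanishes and the conversion is refused.
#'
#' @param dL_um tether-length change, micrometres; vectorised.
#' @param force force during the change, pN.
#' @param ss,ds elasticity parameter objects.
#' @param min_factor_nm smallest |conversion factor| accepted, nm/bp.
#' @return base pairs unwound (unrounded; signed like `dL_um`).
#' @export
bp_from_length_change <- function(dL_um, force, ss = ssdna_params(),
                                  ds = dsdna_params(), min_factor_nm = 1e-3) {
  fac <- unwound_bp_extension(force, ss, ds)
  if (abs(fac) <= min_factor_nm) {
    abort(sprintf(paste0(
      "ill-conditioned conversion: |x_ss - x_ds| = %.2g nm/bp at %.3g pN ",
      "(near the crossover force); use the fluorescence dark-region ",
      "estimator instead"), abs(fac), force))
  }
  dL_um * 1000 / fac
}

#' Nucleotides of tensioned ssDNA in a dark-region span
#'
#' The primary base-pair estimator: a Sytox dark region of width `dark_um`
#' holds `dark_um / x_ss(F)` tensioned nucleotides, valid at any force
#' (including below the crossover where the length-change estimator fails).
#'
#' @param dark_um dark-region span, micrometres; vectorised, >= 0.
#' @param force force, pN.
#' @param ss ssDNA elasticity parameters.
#' @return nucleotides (equals bp unwound for nick-initiated events).
#' @export
nt_from_dark_span <- function(dark_um, force, ss = ssdna_params()) {
  if (any(dark_um < 0)) abort("dark span must be >= 0")
  dark_um * 1000 / polymer_extension(ss, force)
}

#' Duplex reachable from a nick in one direction
#'
#' A fork initiated at a nick can unwind at most the duplex between the nick
#' and the template end it is moving toward: on the 6.4 kbp preset this is
#' 4,200 bp for a tensioned-strand (rightward) fork and 2,200 bp for a
#' relaxed-strand (leftward) fork.
#'
#' @param template a [template_spec()].
#' @param nick_index which nick (1-based into `nick_positions`).
#' @param direction `"left"` or `"right"`.
#' @return base pairs reachable.
#' @export
reachable_extent <- function(template, nick_index = 1,
                             direction = c("left", "right")) {
  direction <- match.arg(direction)
  if (nick_index < 1 || nick_index > length(template$nick_positions)) {
    abort("nick_index out of range for this template")
  }
  nick <- template$nick_positions[nick_index]
  if (direction == "left") nick else template$total_bp - nick
}

# map bp coordinates to micrometre positions given sorted disjoint unwound
# intervals [l, r) in bp; tensioned path: ds outside intervals, ss inside
bp_to_um <- function(bp, intervals, x_ds_nm, x_ss_nm) {
  vapply(bp, function(b) {
    ss_before <- 0
    if (nrow(intervals)) {
      w <- pmin(intervals$r, b) - pmin(intervals$l, b)
      ss_before <- sum(pmax(w, 0))
    }
    (b * x_ds_nm + ss_before * (x_ss_nm - x_ds_nm)) / 1000
  }, numeric(1))
}
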