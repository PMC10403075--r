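## Helical-wheel geometry, hydrophobic moment, staple proposal, variant arrays.

#' Helical wheel angle of a residue position
#'
#' Ideal alpha-helix: 100 degrees of wheel rotation per residue, position 1
#' at 0 degrees, so `angle(n) = ((n - 1) * 100) mod 360`.
#'
#' @param pos 1-based position vector.
#' @return angles in degrees, `[0, 360)`.
#' @export
wheel_angle <- function(pos) ((pos - 1) * 100) %% 360

circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

resolve_window <- function(p, window) {
  L <- nrow(p$residues)
  if (is.null(window)) window <- seq_len(L)
  window <- as.integer(window)
  if (length(window) == 0) stop("empty window", call. = FALSE)
  if (any(window < 1 | window > L))
    stop("window outside sequence bounds 1..", L, call. = FALSE)
  window
}

#' Hydrophobic moment of a helical window
#'
#' Vector sum of per-residue hydrophobicity (Eisenberg consensus scale;
#' see [residue_table()]) along the unit wheel direction of each position.
#' The magnitude is in scale units; the angle is reported in the wheel
#' frame of the whole peptide, so sub-windows of one peptide share a frame.
#'
#' @param p a `Peptide`.
#' @param window positions to include (default: whole sequence).
#' @return named numeric `c(magnitude, angle)`, angle in degrees `[0, 360)`.
#' @export
compute_moment <- function(p, window = NULL) {
  window <- resolve_window(p, window)
  h <- residue_info(p$residues$code[window])$hydrophobicity
  ang <- wheel_angle(window)
  x <- sum(h * cospi(ang / 180))
  y <- sum(h * sinpi(ang / 180))
  mag <- sqrt(x^2 + y^2)
  c(magnitude = mag,
    angle = if (mag > 0) (atan2(y, x) * 180 / pi) %% 360 else NA_real_)
}

#' Helical wheel projection
#'
#' Projects a peptide window onto the ideal helical wheel (100 deg/residue)
#' and computes its hydrophobic moment and hydrophobic-face membership.
#'
#' @inheritParams compute_moment
#' @param half_width half-angle of the hydrophobic face in degrees
#'   (default 90: a half wheel centred on the moment).
#' @return a `HelixProjection`: positions, wheel angles, hydrophobicities,
#'   moment magnitude/angle and face members.
#' @export
project_wheel <- function(p, window = NULL, half_width = 90) {
  window <- resolve_window(p, window)
  m <- compute_moment(p, window)
  proj <- structure(
    list(positions = window,
         residues = p$residues$code[window],
         angles = wheel_angle(window),
         hydrophobicity = residue_info(p$residues$code[window])$hydrophobicity,
         moment_magnitude = unname(m["magnitude"]),
         moment_angle = unname(m["angle"]),
         half_width = half_width,
         face_members = integer()),
    class = "HelixProjection")
  if (is.finite(proj$moment_angle) && proj$moment_magnitude > 1e-9)
    proj$face_members <- hydrophobic_face(proj, half_width)
  proj
}

#' @export
print.HelixProjection <- function(x, ...) {
  cat("HelixProjection over positions",
      paste(range(x$positions), collapse = ":"), "\n")
  cat(sprintf("  hydrophobic moment %.3f at %.1f deg\n",
              x$moment_magnitude,
              if (is.finite(x$moment_angle)) x$moment_angle else NaN))
  cat("  face (+-", x$half_width, " deg):",
      paste(x$face_members, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.HelixProjection <- function(x, ...) {
  data.frame(position = x$positions, residue = x$residues,
             angle_deg = x$angles, hydrophobicity = x$hydrophobicity,
             in_face = x$positions %in% x$face_members)
}

#' Hydrophobic face of a projection
#'
#' Positions whose wheel angle lies within `half_width` degrees of the
#' hydrophobic-moment direction. Undefined (an error) when the moment is
#' numerically zero, as for an ideal 18-mer homopolymer.
#'
#' @param proj a `HelixProjection` from [project_wheel()].
#' @param half_width face half-angle, degrees.
#' @param min_moment smallest moment magnitude for which a face direction
#'   is considered defined.
#' @return integer positions in the face.
#' @export
hydrophobic_face <- function(proj, half_width = 90, min_moment = 1e-9) {
  stopifnot(inherits(proj, "HelixProjection"))
  if (!is.finite(proj$moment_angle) || proj$moment_magnitude < min_moment)
    stop("undefined face: hydrophobic moment is (near) zero", call. = FALSE)
  proj$positions[circular_distance(proj$angles, proj$moment_angle) <=
                   half_width]
}

#' Propose staple sites
#'
#' Enumerates residue pairs `(i, j)` in the window with the exact staple
#' span (`j - i = 4` for a short staple, 7 for a long one) and ranks them
#' by the summed hydrophobicity of the residues they would displace,
#' least hydrophobic first -- placements that spare the hydrophobic face
#' rank highest, matching how staples are placed at polar or weakly
#' hydrophobic positions in amphipathic-helix design. Optionally the
#' candidates can be restricted to arms inside the hydrophobic face.
#'
#' @inheritParams compute_moment
#' @param span `"short"` (i,i+4) or `"long"` (i,i+7).
#' @param half_width face half-angle used for face annotation/filtering.
#' @param face_filter `"none"` (default) keeps all geometric candidates;
#'   `"both"`/`"either"` require both/at least one arm inside the
#'   hydrophobic face.
#' @return data.frame of candidates: `i`, `j`, displaced residue codes,
#'   `displaced_hydrophobicity`, `i_in_face`, `j_in_face`; zero rows when
#'   no pair passes the filter.
#' @export
propose_staple <- function(p, span = c("short", "long"), window = NULL,
                           half_width = 90,
                           face_filter = c("none", "both", "either")) {
  span <- match.arg(span)
  face_filter <- match.arg(face_filter)
  window <- resolve_window(p, window)
  offset <- if (span == "short") 4L else 7L
  if (length(window) < offset + 1)
    stop("window shorter than the staple span", call. = FALSE)
  proj <- project_wheel(p, window, half_width)
  face <- proj$face_members
  h <- residue_info(p$residues$code)$hydrophobicity

  is_cont <- function(i) (i + offset) %in% window
  ii <- window[vapply(window, is_cont, TRUE)]
  if (!length(ii))
    return(data.frame(i = integer(), j = integer(),
                      displaced = character(),
                      displaced_hydrophobicity = numeric(),
                      i_in_face = logical(), j_in_face = logical()))
  jj <- ii + offset
  cand <- data.frame(
    i = ii, j = jj,
    displaced = paste0(p$residues$code[ii], ii, "/",
                       p$residues$code[jj], jj),
    displaced_hydrophobicity = h[ii] + h[jj],
    i_in_face = ii %in% face,
    j_in_face = jj %in% face,
    stringsAsFactors = FALSE)
  keep <- switch(face_filter,
                 none = rep(TRUE, nrow(cand)),
                 both = cand$i_in_face & cand$j_in_face,
                 either = cand$i_in_face | cand$j_in_face)
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$displaced_hydrophobicity, cand$i), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Build a design variant array
#'
#' Generates the systematic variant sets used to dissect the activation
#' helix: an Ala scan (one single-Ala substitution per position in the
#' window, skipping positions that are already Ala and staple-arm
#' positions), the quadruple Ala variant at the four LPL-activation
#' residues (window-local Y5, I8, D11, Q12), or the "damaged helix"
#' variant that deletes the window-local Glu8 of the first helix.
#' Variant labels use window-local numbering (`Y5A` is the Tyr at the
#' fifth window position).
#'
#' @inheritParams compute_moment
#' @param design `"ala_scan"`, `"quad_AE"` or `"damaged_helix1"`.
#' @return a `VariantArray`: scaffold, design, window, and a list of
#'   `(label, peptide)` variants.
#' @export
build_variant_array <- function(p, design = c("ala_scan", "quad_AE",
                                              "damaged_helix1"),
                                window = NULL) {
  design <- match.arg(design)
  window <- resolve_window(p, window)
  arms <- unique(c(p$staples$i, p$staples$j))
  local_code <- function(loc) p$residues$code[window[loc]]

  variants <- list()
  if (design == "ala_scan") {
    for (loc in seq_along(window)) {
      pos <- window[loc]
      code <- p$residues$code[pos]
      if (code == "A" || pos %in% arms) next
      lab <- paste0(code, loc, "A")
      variants[[lab]] <- apply_modifications(p, mod_substitute(pos, "A"))
    }
  } else if (design == "quad_AE") {
    need <- c(`5` = "Y", `8` = "I", `11` = "D", `12` = "Q")
    locs <- as.integer(names(need))
    if (length(window) < max(locs))
      stop("window too short for the quad-AE design", call. = FALSE)
    have <- vapply(locs, local_code, "")
    if (!identical(unname(have), unname(need)))
      stop("scaffold lacks the Y5/I8/D11/Q12 activation residues in this ",
           "window (found ", paste0(have, locs, collapse = ", "), ")",
           call. = FALSE)
    mods <- lapply(window[locs], mod_substitute, code = "A")
    variants[["AE"]] <- apply_modifications(p, mods)
  } else { # damaged_helix1
    if (length(window) < 8)
      stop("window too short for the E8-deletion design", call. = FALSE)
    pos <- window[8]
    if (p$residues$code[pos] != "E")
      stop("window-local position 8 is ", p$residues$code[pos],
           ", not Glu; cannot build the damaged-helix variant",
           call. = FALSE)
    variants[["dE8"]] <- apply_modifications(p, mod_delete(pos))
  }
  structure(list(scaffold = p, design = design, window = window,
                 variants = variants),
            class = "VariantArray")
}

#' @export
print.VariantArray <- function(x, ...) {
  cat("VariantArray (", x$design, ") on '", x$scaffold$name, "': ",
      length(x$variants), " variants\n", sep = "")
  for (nm in names(x$variants))
    cat(" ", nm, write_sequence(x$variants[[nm]]), "\n")
  invisible(x)
}
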