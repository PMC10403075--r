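## Trilayer trajectory statistics: leaflet assignment, insertion depth,
## hydrogen-bond timeseries, triolein coordination and contact counts.
## All pair distances use the minimum-image convention in the frame box.

## minimum-image pairwise distance matrix between coordinate sets (nm)
mi_dist <- function(x, y, box) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (is.null(dim(y))) y <- matrix(y, ncol = 3)
  d2 <- 0
  for (k in 1:3) {
    d <- outer(x[, k], y[, k], "-")
    d <- d - box[k] * round(d / box[k])
    d2 <- d2 + d * d
  }
  sqrt(d2)
}

## minimum-image displacement vectors from a single point to rows of y
mi_disp <- function(from, y, box) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 3)
  d <- sweep(y, 2, from)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Hydrogen-bond criterion
#'
#' Distance-angle cone criterion for donor--acceptor hydrogen bonds: the
#' pair is bonded when `r(donor heavy, acceptor) <= r_max0 - curvature *
#' theta^2`, with `theta` the angular deviation (degrees) of the donor
#' hydrogen from the donor--acceptor axis. The defaults (`r_max0` 0.33 nm,
#' `curvature` 0.00044 nm/deg^2) are the Wernet--Nilsson parameterization.
#'
#' @param r_max0 distance intercept, nm.
#' @param curvature angular penalty, nm per squared degree.
#' @return an `HBondCriterion`.
#' @export
hbond_criterion <- function(r_max0 = 0.33, curvature = 0.00044) {
  stopifnot(r_max0 > 0, curvature >= 0)
  structure(list(r_max0 = r_max0, curvature = curvature),
            class = "HBondCriterion")
}

#' Coordination switching-function parameters
#'
#' Parameters of the rational switching function used for peptide--triolein
#' coordination: each atom pair at distance `r` contributes
#' `(1 - (r/r0)^n) / (1 - (r/r0)^m)` with exponents `(n, m) = (6, 12)` and
#' switching radius `r0 = 0.4` nm; the term is continued through its
#' removable singularity at `r = r0` (value `n/m = 0.5`).
#'
#' @param r0 switching radius, nm.
#' @param exponents integer pair `(n, m)`.
#' @return a `CoordinationParams`.
#' @export
coordination_params <- function(r0 = 0.4, exponents = c(6, 12)) {
  stopifnot(r0 > 0, length(exponents) == 2, all(exponents > 0),
            exponents[2] > exponents[1])
  structure(list(r0 = r0, exponents = as.numeric(exponents)),
            class = "CoordinationParams")
}

#' Switching-function term
#'
#' @param r distances, nm (vector or matrix).
#' @param params a [coordination_params()].
#' @return values in `(0, 1]`, same shape as `r`.
#' @export
switching_term <- function(r, params = coordination_params()) {
  x <- r / params$r0
  n <- params$exponents[1]; m <- params$exponents[2]
  if (m == 2 * n) {
    ## (1 - x^n) / (1 - x^2n) == 1 / (1 + x^n), removing the singularity
    1 / (1 + x^n)
  } else {
    out <- (1 - x^n) / (1 - x^m)
    sing <- abs(x - 1) < 1e-8
    out[sing] <- n / m
    out
  }
}

## ---- leaflet assignment -------------------------------------------------

#' Assign molecules to monolayer leaflets
#'
#' Splits phospholipids into upper/lower leaflets by phosphorus z relative
#' to the phosphorus z-midpoint, estimates each leaflet's phosphorus plane
#' (mean phosphorus z), and assigns every peptide to the leaflet whose
#' plane is nearest its mean c-alpha z.
#'
#' @param frame a `TrilayerFrame` (or single-frame trajectory).
#' @return list with `plane_z` (named upper/lower), `pl_leaflet` (named by
#'   phospholipid molecule id) and `peptide_leaflet` (named by peptide id).
#' @export
assign_leaflets <- function(frame) {
  if (inherits(frame, "TrilayerTrajectory")) frame <- get_frame(frame, 1)
  stopifnot(inherits(frame, "TrilayerFrame"))
  top <- frame$topology
  pidx <- which(top$is_phosphorus)
  if (length(pidx) < 2)
    stop("need at least two phosphorus atoms to define leaflets",
         call. = FALSE)
  zp <- frame$coords[pidx, 3]
  if (diff(range(zp)) < 1e-9)
    stop("degenerate geometry: all phosphorus atoms at identical z",
         call. = FALSE)
  mid <- (max(zp) + min(zp)) / 2
  upper <- zp > mid
  if (!any(upper) || all(upper))
    stop("degenerate geometry: phosphorus atoms form a single leaflet",
         call. = FALSE)
  plane <- c(upper = mean(zp[upper]), lower = mean(zp[!upper]))
  pl_leaflet <- ifelse(upper, "upper", "lower")
  names(pl_leaflet) <- top$molecule_id[pidx]

  pep_ids <- unique(top$molecule_id[top$molecule_class == "peptide"])
  peptide_leaflet <- character(0)
  if (length(pep_ids)) {
    peptide_leaflet <- vapply(pep_ids, function(id) {
      ca <- which(top$molecule_id == id & top$is_c_alpha)
      zca <- mean(frame$coords[ca, 3])
      names(plane)[which.min(abs(zca - plane))]
    }, "")
  }
  list(plane_z = plane, pl_leaflet = pl_leaflet,
       peptide_leaflet = peptide_leaflet)
}

resolve_peptide <- function(top, peptide_id) {
  ids <- unique(top$molecule_id[top$molecule_class == "peptide"])
  if (!length(ids)) stop("no peptide in trajectory", call. = FALSE)
  if (is.null(peptide_id)) return(ids[1])
  if (!peptide_id %in% ids)
    stop("peptide '", peptide_id, "' absent from trajectory", call. = FALSE)
  peptide_id
}

## ---- insertion depth ----------------------------------------------------

#' Residue insertion depth relative to the phosphorus plane
#'
#' Per residue and leaflet, the mean and SD over frames of the c-alpha z
#' displacement from the phosphorus plane of the leaflet the peptide is
#' assigned to in that frame. The sign convention puts the plane at zero
#' and counts displacement toward the triolein core as negative, for both
#' leaflets.
#'
#' @param traj a `TrilayerTrajectory`.
#' @param peptide_id peptide molecule id (default: the only/first peptide).
#' @return a `DepthProfile` data.frame: `residue`, `leaflet`,
#'   `mean_depth`, `sd_depth`, `n_frames`.
#' @export
insertion_depth <- function(traj, peptide_id = NULL) {
  traj <- as_traj(traj)
  top <- traj$topology
  peptide_id <- resolve_peptide(top, peptide_id)
  ca <- which(top$molecule_id == peptide_id & top$is_c_alpha)
  ca <- ca[order(top$residue_index[ca])]
  res <- top$residue_index[ca]
  nf <- n_frames(traj)

  depth <- matrix(NA_real_, nrow = length(ca), ncol = nf)
  leaflet <- character(nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    la <- assign_leaflets(fr)
    lf <- la$peptide_leaflet[[peptide_id]]
    plane <- la$plane_z[[lf]]
    sgn <- if (lf == "upper") 1 else -1
    depth[, f] <- sgn * (fr$coords[ca, 3] - plane)
    leaflet[f] <- lf
  }
  out <- do.call(rbind, lapply(unique(leaflet), function(lf) {
    cols <- which(leaflet == lf)
    data.frame(residue = res, leaflet = lf,
               mean_depth = rowMeans(depth[, cols, drop = FALSE]),
               sd_depth = apply(depth[, cols, drop = FALSE], 1, stats::sd),
               n_frames = length(cols))
  }))
  rownames(out) <- NULL
  class(out) <- c("DepthProfile", "data.frame")
  out
}

## ---- hydrogen bonds -----------------------------------------------------

#' Peptide--triolein hydrogen-bond timeseries
#'
#' Counts, per frame and leaflet, donor--acceptor pairs satisfying the
#' distance-angle criterion of [hbond_criterion()]. Donors are the tagged
#' donor-hydrogen/heavy-atom pairs of the donor class (peptide backbone
#' amides by default); acceptors are the tagged acceptor atoms of the
#' acceptor class (triolein ester oxygens). `percent_bonded` is the
#' percentage of frames with at least one bond, pooled over leaflets.
#'
#' @param traj a `TrilayerTrajectory`.
#' @param crit an `HBondCriterion`.
#' @param donor_class,acceptor_class molecule classes supplying donors and
#'   acceptors.
#' @return an `HBondSeries`: `counts` data.frame (`frame`, `upper`,
#'   `lower`, `total`), `percent_bonded`, `percent_by_leaflet`, `status`.
#' @export
hbond_series <- function(traj, crit = hbond_criterion(),
                         donor_class = "peptide", acceptor_class = "TO") {
  traj <- as_traj(traj)
  stopifnot(inherits(crit, "HBondCriterion"))
  top <- traj$topology
  hidx <- which(top$is_donor_h & top$molecule_class == donor_class &
                  !is.na(top$donor_parent))
  didx <- top$donor_parent[hidx]
  aidx <- which(top$is_acceptor & top$molecule_class == acceptor_class)
  nf <- n_frames(traj)
  counts <- data.frame(frame = seq_len(nf), upper = 0L, lower = 0L,
                       total = 0L)
  if (!length(hidx) || !length(aidx)) {
    warning("no donors or no acceptors: empty hydrogen-bond series")
    return(structure(list(counts = counts, percent_bonded = NA_real_,
                          percent_by_leaflet = c(upper = NA_real_,
                                                 lower = NA_real_),
                          criterion = crit, status = "empty"),
                     class = "HBondSeries"))
  }
  donor_mol <- top$molecule_id[didx]
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    la <- assign_leaflets(fr)
    A <- fr$coords[aidx, , drop = FALSE]
    for (k in seq_along(hidx)) {
      D <- fr$coords[didx[k], ]
      H <- fr$coords[hidx[k], ]
      vda <- mi_disp(D, A, fr$box)
      rda <- sqrt(rowSums(vda^2))
      near <- which(rda <= crit$r_max0)
      if (!length(near)) next
      vdh <- mi_disp(D, matrix(H, ncol = 3), fr$box)[1, ]
      cosang <- (vda[near, , drop = FALSE] %*% vdh) /
        (rda[near] * sqrt(sum(vdh^2)))
      theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      nb <- sum(rda[near] <= crit$r_max0 - crit$curvature * theta^2)
      if (nb > 0) {
        lf <- la$peptide_leaflet[[donor_mol[k]]]
        counts[[lf]][f] <- counts[[lf]][f] + nb
      }
    }
    counts$total[f] <- counts$upper[f] + counts$lower[f]
  }
  structure(list(
    counts = counts,
    percent_bonded = 100 * mean(counts$total >= 1),
    percent_by_leaflet = c(upper = 100 * mean(counts$upper >= 1),
                           lower = 100 * mean(counts$lower >= 1)),
    criterion = crit, status = "ok"),
    class = "HBondSeries")
}

#' @export
print.HBondSeries <- function(x, ...) {
  cat("HBondSeries over", nrow(x$counts), "frames (", x$status, ")\n")
  cat(sprintf("  percent of frames bonded: %.2f%% (upper %.2f%%, lower %.2f%%)\n",
              x$percent_bonded, x$percent_by_leaflet["upper"],
              x$percent_by_leaflet["lower"]))
  invisible(x)
}

## ---- coordination -------------------------------------------------------

## per-frame matrix of switching sums: groups (residues or whole peptide)
## x triolein molecules
coordination_matrix <- function(fr, pep_atoms, group, to_atoms, to_mol,
                                params) {
  r <- mi_dist(fr$coords[pep_atoms, , drop = FALSE],
               fr$coords[to_atoms, , drop = FALSE], fr$box)
  term <- switching_term(r, params)
  by_group <- rowsum(term, group, reorder = TRUE)
  t(rowsum(t(by_group), to_mol, reorder = TRUE))
}

#' Residue-wise triolein coordination number
#'
#' For each peptide residue, the switching-function sum `s` (see
#' [coordination_params()]) over all pairs of that residue's atoms with
#' the atoms of a given triolein molecule; the residue's coordination is
#' the maximum of `s` over triolein molecules, averaged over frames.
#'
#' @param traj a `TrilayerTrajectory`.
#' @param peptide_id peptide molecule id (default: first peptide).
#' @param params a `CoordinationParams`.
#' @return data.frame `residue`, `coordination`.
#' @export
tg_coordination <- function(traj, peptide_id = NULL,
                            params = coordination_params()) {
  traj <- as_traj(traj)
  top <- traj$topology
  peptide_id <- resolve_peptide(top, peptide_id)
  pep_atoms <- which(top$molecule_id == peptide_id)
  group <- top$residue_index[pep_atoms]
  to_atoms <- which(top$molecule_class == "TO")
  residues <- sort(unique(group))
  nf <- n_frames(traj)
  if (!length(to_atoms))
    return(data.frame(residue = residues, coordination = 0))
  to_mol <- top$molecule_id[to_atoms]
  acc <- numeric(length(residues))
  for (f in seq_len(nf)) {
    s <- coordination_matrix(get_frame(traj, f), pep_atoms, group,
                             to_atoms, to_mol, params)
    acc <- acc + apply(s, 1, max)
  }
  data.frame(residue = residues, coordination = acc / nf)
}

#' Mean triolein contact count
#'
#' Number of triolein molecules whose whole-peptide switching sum exceeds
#' `threshold`, averaged over frames.
#'
#' @inheritParams tg_coordination
#' @param threshold coordination cutoff defining a contact (must be > 0).
#' @return mean contact count (scalar), with per-frame counts in attribute
#'   `"per_frame"`.
#' @export
tg_contact_count <- function(traj, peptide_id = NULL, threshold = 1,
                             params = coordination_params()) {
  stopifnot(threshold > 0)
  traj <- as_traj(traj)
  top <- traj$topology
  peptide_id <- resolve_peptide(top, peptide_id)
  pep_atoms <- which(top$molecule_id == peptide_id)
  to_atoms <- which(top$molecule_class == "TO")
  nf <- n_frames(traj)
  if (!length(to_atoms))
    return(structure(0, per_frame = rep(0L, nf)))
  to_mol <- top$molecule_id[to_atoms]
  per_frame <- integer(nf)
  whole <- rep(1L, length(pep_atoms))
  for (f in seq_len(nf)) {
    s <- coordination_matrix(get_frame(traj, f), pep_atoms, whole,
                             to_atoms, to_mol, params)
    per_frame[f] <- sum(s[1, ] > threshold)
  }
  structure(mean(per_frame), per_frame = per_frame)
}
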