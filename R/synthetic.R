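## Synthetic trilayer trajectory generator with planted ground truth.
##
## Emulates a phospholipid/triolein trilayer carrying one surface-bound
## helical peptide: jittered phosphorus planes, triolein molecules confined
## to the core, a configurable number of triolein molecules planted in
## coordination contact with the peptide, and a per-frame Bernoulli
## hydrogen bond realized in exact criterion geometry. Every planted
## quantity is recorded so the trajectory statistics can be validated
## without molecular dynamics. No energetics or dynamics are modelled.

#' Synthetic trilayer generator configuration
#'
#' Defaults emulate the study conditions at reduced size: a quarter of the
#' simulated 160-POPC/128-triolein trilayer (40 phospholipids per leaflet,
#' 32 triolein), a single-stapled 21-mer peptide inserted 0.3 nm below the
#' upper phosphorus plane, two triolein molecules in direct contact, and a
#' planted peptide--triolein hydrogen-bond fraction of 0.105 per frame.
#' Waters and ions are omitted (no statistic touches them).
#'
#' @param peptide the embedded `Peptide` (default the packaged SP1).
#' @param n_pl phospholipids per leaflet.
#' @param n_to triolein molecule count.
#' @param box box lengths, nm.
#' @param plane_z phosphorus-plane height: leaflet planes sit at
#'   `+plane_z` and `-plane_z` nm.
#' @param depth planted per-residue c-alpha depth relative to the
#'   phosphorus plane, nm; negative is toward the triolein core.
#' @param leaflet leaflet carrying the peptide, `"upper"` or `"lower"`.
#' @param planted_contacts triolein molecules placed within coordination
#'   range of the peptide.
#' @param hbond_fraction per-frame probability of one peptide--triolein
#'   hydrogen bond.
#' @param jitter_sd phosphorus z jitter SD, nm (0 = noise-free planes).
#' @param n_frames number of frames.
#' @param seed integer seed; together with the frame index it makes every
#'   frame bit-reproducible.
#' @return a `GeneratorConfig`.
#' @export
generator_config <- function(peptide = apoc2_peptides("SP1"),
                             n_pl = 40, n_to = 32,
                             box = c(6, 6, 10), plane_z = 2,
                             depth = -0.3, leaflet = "upper",
                             planted_contacts = 2, hbond_fraction = 0.105,
                             jitter_sd = 0.05, n_frames = 100, seed = 1) {
  stopifnot(inherits(peptide, "Peptide"),
            n_pl >= 1, n_to >= 0, length(box) == 3, all(box > 0),
            plane_z > 0, 2 * plane_z < box[3],
            leaflet %in% c("upper", "lower"),
            planted_contacts >= 0, planted_contacts <= n_to,
            hbond_fraction >= 0, hbond_fraction <= 1,
            jitter_sd >= 0, n_frames >= 0, seed == round(seed))
  structure(list(peptide = peptide, n_pl = n_pl, n_to = n_to,
                 box = as.numeric(box), plane_z = plane_z, depth = depth,
                 leaflet = leaflet, planted_contacts = planted_contacts,
                 hbond_fraction = hbond_fraction, jitter_sd = jitter_sd,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Ideal alpha-helix c-alpha coordinates
#'
#' C-alpha positions on an ideal alpha helix: 0.15 nm rise and 100 degrees
#' of twist per residue on a 0.23 nm radius, axis along x. An optional
#' kink bends the axis at a chosen residue (e.g. the helical break near
#' the first Gly of the apolipoprotein C-II activation helix).
#'
#' @param p a `Peptide` or a residue count.
#' @param rise axial rise per residue, nm.
#' @param twist wheel rotation per residue, degrees.
#' @param radius helix radius, nm.
#' @param kink_at residue index at which to bend the axis (`NULL` = none).
#' @param kink_angle bend angle in degrees (rotation about y at the kink).
#' @return `n x 3` matrix of c-alpha coordinates, nm.
#' @export
ideal_helix_coords <- function(p, rise = 0.15, twist = 100, radius = 0.23,
                               kink_at = NULL, kink_angle = 0) {
  n <- if (inherits(p, "Peptide")) nrow(p$residues) else as.integer(p)
  stopifnot(n >= 1)
  i <- seq_len(n)
  phi <- (i - 1) * twist * pi / 180
  xyz <- cbind(x = (i - 1) * rise, y = radius * cos(phi),
               z = radius * sin(phi))
  if (!is.null(kink_at) && kink_angle != 0 && kink_at < n) {
    pivot <- xyz[kink_at, ]
    a <- kink_angle * pi / 180
    rot <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
    after <- (kink_at + 1):n
    xyz[after, ] <- sweep(sweep(xyz[after, , drop = FALSE], 2, pivot) %*%
                            rot, 2, pivot, "+")
  }
  xyz
}

## local triolein template: glycerol C1-C3, six ester oxygens O1-O6 (the
## acceptors), truncated three-carbon tails. The tails sit on the local -y
## side so a blob centred +y of the peptide points carbons, not acceptors,
## at the donors.
.to_template <- function() {
  rbind(
    C1 = c(0, 0, 0), C2 = c(0.15, 0, 0), C3 = c(-0.15, 0, 0),
    O1 = c(0, 0.12, 0.12), O2 = c(0, 0.12, -0.12),
    O3 = c(0.25, 0.10, 0), O4 = c(0.25, -0.10, 0),
    O5 = c(-0.25, 0.10, 0), O6 = c(-0.25, -0.10, 0),
    C4 = c(0.10, -0.20, 0.15), C5 = c(0.20, -0.30, 0.25),
    C6 = c(0.30, -0.35, 0.35),
    C7 = c(-0.10, -0.20, 0.15), C8 = c(-0.20, -0.30, 0.25),
    C9 = c(-0.30, -0.35, 0.35),
    C10 = c(0, -0.20, -0.15), C11 = c(0, -0.30, -0.25),
    C12 = c(0, -0.35, -0.35))
}

## deterministic base layout shared by all frames of one config
generator_layout <- function(cfg) {
  set.seed(cfg$seed)
  n <- nrow(cfg$peptide$residues)
  ## flat-inserted peptide: helix-axis x spacing, every c-alpha exactly at
  ## the planted depth
  z_pep <- if (cfg$leaflet == "upper") cfg$plane_z + cfg$depth else
    -cfg$plane_z - cfg$depth
  x <- (seq_len(n) - (n + 1) / 2) * 0.15
  ca <- cbind(x, 0, z_pep)
  pep <- list(
    CA = ca,
    N = sweep(ca, 2, c(-0.12, 0.08, 0), "+"),
    O = sweep(ca, 2, c(0.12, -0.10, 0), "+"))
  pep$H <- sweep(pep$N, 2, c(0, 0.10, 0), "+")

  ## phospholipid xy positions (fixed; z is jittered per frame)
  pl_xy <- lapply(c("upper", "lower"), function(lf)
    cbind(stats::runif(cfg$n_pl, -cfg$box[1] / 2, cfg$box[1] / 2),
          stats::runif(cfg$n_pl, -cfg$box[2] / 2, cfg$box[2] / 2)))
  names(pl_xy) <- c("upper", "lower")

  ## planted-contact triolein blobs, alternating sides of the peptide
  k <- cfg$planted_contacts
  contacts <- list()
  if (k > 0) {
    targets <- pmax(2, pmin(n - 1, round(seq_len(k) * n / (k + 1))))
    tmpl <- .to_template()
    for (m in seq_len(k)) {
      side <- if (m == 1) 1 else c(1, -1)[(m %% 2) + 1]
      centre <- ca[targets[m], ] + c(0, side * 0.55, 0)
      loc <- tmpl
      loc[, 2] <- loc[, 2] * side   # tails face the peptide, acceptors away
      contacts[[m]] <- list(target = targets[m], side = side,
                            coords = sweep(loc, 2, centre, "+"))
    }
  }
  ## dedicated hydrogen-bond molecule only when no contact can host it
  dedicated_hb <- cfg$planted_contacts == 0 && cfg$hbond_fraction > 0 &&
    cfg$n_to > cfg$planted_contacts
  hb_target <- if (k > 0) contacts[[1]]$target else max(2, round(n / 2))
  hb_site <- pep$N[hb_target, ] + c(0, 0.28, 0)

  frame_seeds <- sample.int(.Machine$integer.max - 1, max(cfg$n_frames, 1))
  list(pep = pep, pl_xy = pl_xy, contacts = contacts,
       dedicated_hb = dedicated_hb, hb_target = hb_target,
       hb_site = hb_site, frame_seeds = frame_seeds)
}

## topology shared by all frames
generator_topology <- function(cfg, layout) {
  p <- cfg$peptide
  n <- nrow(p$residues)
  atom_name <- character(0); resid <- character(0)
  chain <- character(0); resno <- integer(0)

  add <- function(an, rs, ch, rn) {
    atom_name <<- c(atom_name, an); resid <<- c(resid, rs)
    chain <<- c(chain, ch); resno <<- c(resno, rn)
  }
  ## peptide: N, H, CA, O per residue
  res3 <- unname(.aa3[p$residues$code])
  for (i in seq_len(n))
    add(c("N", "H", "CA", "O"), rep(res3[i], 4), rep("P", 4), rep(i, 4))
  ## phospholipids: P + two tail carbons
  for (lf in c("upper", "lower")) {
    ch <- if (lf == "upper") "U" else "L"
    for (m in seq_len(cfg$n_pl))
      add(c("P", "C1", "C2"), rep("POP", 3), rep(ch, 3), rep(m, 3))
  }
  ## triolein molecules (contacts first, then background, then dedicated)
  to_names <- rownames(.to_template())
  for (m in seq_len(cfg$n_to))
    add(to_names, rep("TRI", length(to_names)), rep("T", length(to_names)),
        rep(m, length(to_names)))
  build_topology(atom_name, resid, chain, resno)
}

#' Build one synthetic trilayer frame
#'
#' Deterministic in `(cfg, frame_index)`: phosphorus atoms jittered about
#' their planes, background triolein re-sampled in the core at least
#' 1.8 nm from every peptide atom (so they contribute negligibly to
#' coordination), planted-contact triolein fixed against the peptide, and
#' -- with the configured per-frame probability -- one triolein acceptor
#' moved into exact hydrogen-bond geometry (0.28 nm from a backbone amide
#' nitrogen, zero angular deviation).
#'
#' @param cfg a [generator_config()].
#' @param frame_index 1-based frame number.
#' @return a `TrilayerFrame` with attributes `hbond` (logical: bond
#'   planted this frame) and `contact_count` (planted contact count).
#' @export
build_frame <- function(cfg, frame_index) {
  stopifnot(inherits(cfg, "GeneratorConfig"), frame_index >= 1)
  layout <- generator_layout(cfg)
  top <- generator_topology(cfg, layout)
  build_frame_impl(cfg, frame_index, layout, top)
}

build_frame_impl <- function(cfg, frame_index, layout, top) {
  set.seed(layout$frame_seeds[frame_index])
  n <- nrow(cfg$peptide$residues)
  coords <- matrix(NA_real_, nrow = nrow(top), ncol = 3)

  ## peptide (static)
  pep_rows <- which(top$molecule_class == "peptide")
  ord <- matrix(pep_rows, nrow = 4)  # N, H, CA, O per residue
  coords[ord[1, ], ] <- layout$pep$N
  coords[ord[2, ], ] <- layout$pep$H
  coords[ord[3, ], ] <- layout$pep$CA
  coords[ord[4, ], ] <- layout$pep$O

  ## phospholipids: fixed xy, jittered z about the leaflet plane
  for (lf in c("upper", "lower")) {
    ch <- if (lf == "upper") "U" else "L"
    z0 <- if (lf == "upper") cfg$plane_z else -cfg$plane_z
    rows <- which(top$chain == ch)
    xy <- layout$pl_xy[[lf]]
    zj <- z0 + stats::rnorm(cfg$n_pl, 0, cfg$jitter_sd)
    for (m in seq_len(cfg$n_pl)) {
      r <- rows[top$molecule_id[rows] == paste0("PL:", ch, ":", m)]
      coords[r, 1] <- xy[m, 1]
      coords[r, 2] <- xy[m, 2]
      coords[r, 3] <- zj[m] - (seq_along(r) - 1) * 0.1 *
        (if (lf == "upper") 1 else -1)
    }
  }

  ## triolein
  pep_xyz <- coords[pep_rows, , drop = FALSE]
  tmpl <- .to_template()
  n_contact <- length(layout$contacts)
  n_dedicated <- as.integer(layout$dedicated_hb)
  hb_on <- stats::runif(1) < cfg$hbond_fraction
  z_core <- cfg$plane_z - 0.7
  for (m in seq_len(cfg$n_to)) {
    rows <- which(top$molecule_id == paste0("TO:T:", m))
    if (m <= n_contact) {
      coords[rows, ] <- layout$contacts[[m]]$coords
    } else if (m <= n_contact + n_dedicated) {
      ## dedicated hydrogen-bond molecule parked away from the peptide
      base <- c(layout$hb_site[1], cfg$box[2] / 2 - 0.6, 0)
      coords[rows, ] <- sweep(tmpl, 2, base, "+")
    } else {
      ok <- FALSE
      for (try in seq_len(200)) {
        centre <- c(stats::runif(1, -cfg$box[1] / 2, cfg$box[1] / 2),
                    stats::runif(1, -cfg$box[2] / 2, cfg$box[2] / 2),
                    stats::runif(1, -z_core, z_core))
        if (min(mi_dist(matrix(centre, ncol = 3), pep_xyz,
                        cfg$box)) >= 1.8) { ok <- TRUE; break }
      }
      if (!ok)
        stop("overfilled box: cannot place background triolein away from ",
             "the peptide", call. = FALSE)
      coords[rows, ] <- sweep(tmpl, 2, centre, "+")
    }
  }
  ## realize the planted hydrogen bond on the first contact (or dedicated)
  if (hb_on && (n_contact > 0 || n_dedicated > 0)) {
    hb_mol <- if (n_contact > 0) 1L else n_contact + n_dedicated
    rows <- which(top$molecule_id == paste0("TO:T:", hb_mol))
    o1 <- rows[top$atom_name[rows] == "O1"]
    coords[o1, ] <- layout$hb_site
  }

  fr <- trilayer_frame(top, coords, cfg$box)
  attr(fr, "hbond") <- hb_on && (n_contact > 0 || n_dedicated > 0)
  attr(fr, "contact_count") <- n_contact +
    as.integer(attr(fr, "hbond") && n_dedicated > 0)
  fr
}

#' Generate a synthetic trilayer trajectory with ground truth
#'
#' Builds `n_frames` frames from [build_frame()], optionally writes the
#' multi-model PDB and a JSON ground-truth sidecar recording every planted
#' quantity (per-residue depth, per-frame hydrogen-bond indicators and
#' their realized fraction, per-frame contact counts, leaflet, planes).
#'
#' @param cfg a [generator_config()] with `n_frames >= 1`.
#' @param pdb_out optional multi-model PDB output path.
#' @param truth_out optional JSON sidecar output path.
#' @return list with `trajectory` (a `TrilayerTrajectory`) and `truth`
#'   (the sidecar list).
#' @export
generate_trajectory <- function(cfg, pdb_out = NULL, truth_out = NULL) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (cfg$n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  layout <- generator_layout(cfg)
  top <- generator_topology(cfg, layout)
  coords <- array(NA_real_, dim = c(nrow(top), 3, cfg$n_frames))
  hbond <- logical(cfg$n_frames)
  contact <- integer(cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    fr <- build_frame_impl(cfg, f, layout, top)
    coords[, , f] <- fr$coords
    hbond[f] <- attr(fr, "hbond")
    contact[f] <- attr(fr, "contact_count")
  }
  traj <- trilayer_trajectory(top, coords, cfg$box)
  truth <- list(
    seed = cfg$seed, n_frames = cfg$n_frames,
    peptide = write_sequence(cfg$peptide),
    leaflet = cfg$leaflet, plane_z = cfg$plane_z,
    planted_depth = cfg$depth, jitter_sd = cfg$jitter_sd,
    planted_contacts = cfg$planted_contacts,
    hbond_fraction = cfg$hbond_fraction,
    hbond_frames = as.integer(hbond),
    percent_bonded_planted = 100 * mean(hbond),
    contact_counts = contact,
    n_pl = cfg$n_pl, n_to = cfg$n_to, box = cfg$box)
  if (!is.null(pdb_out)) write_trajectory(traj, pdb_out)
  if (!is.null(truth_out))
    jsonlite::write_json(truth, truth_out, auto_unbox = TRUE, digits = NA)
  list(trajectory = traj, truth = truth)
}
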