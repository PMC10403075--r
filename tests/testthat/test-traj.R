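# helper: minimal frame with explicit atom placement
frame_from <- function(spec, box = c(5, 5, 8)) {
  top <- staplekit:::build_topology(spec$atom_name, spec$resid, spec$chain,
                                    spec$resno)
  trilayer_frame(top, spec$coords, box)
}

test_that("the switching term is 0.5 at r0, bounded, decreasing and continuous", {
  prm <- coordination_params()
  expect_equal(switching_term(0.4, prm), 0.5, tolerance = 1e-12)
  # direct evaluation away from the singularity
  expect_equal(switching_term(1.2, prm), (1 - 3^6) / (1 - 3^12),
               tolerance = 1e-12)
  r <- seq(0.05, 2, by = 0.005)
  v <- switching_term(r, prm)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(v) < 0))
  # continuity across r0
  expect_lt(abs(switching_term(0.4 + 1e-9, prm) - 0.5), 1e-6)
  expect_lt(abs(switching_term(0.4 - 1e-9, prm) - 0.5), 1e-6)
  # general-exponent path agrees with its own limit
  g <- coordination_params(0.4, c(4, 10))
  expect_equal(switching_term(0.4, g), 0.4, tolerance = 1e-12)
  expect_equal(switching_term(0.8, g), (1 - 2^4) / (1 - 2^10),
               tolerance = 1e-12)
})

test_that("leaflet assignment splits by the phosphorus midplane", {
  fr <- random_frame(1)
  la <- assign_leaflets(fr)
  expect_equal(unname(la$plane_z["upper"]) > unname(la$plane_z["lower"]),
               TRUE)
  expect_setequal(unique(la$pl_leaflet), c("upper", "lower"))
  expect_equal(unname(la$peptide_leaflet), "upper")  # peptide built at z > 0

  # degenerate single-plane geometry
  spec <- list(
    atom_name = rep(c("P", "C1"), 3), resid = rep("POP", 6),
    chain = rep("U", 6), resno = rep(1:3, each = 2),
    coords = cbind(runif(6), runif(6), rep(c(2, 1.9), 3)))
  spec$coords[c(1, 3, 5), 3] <- 2
  expect_error(assign_leaflets(frame_from(spec)), "degenerate")
})

test_that("insertion depth recovers constructed geometry and matches brute force", {
  # two residues exactly on the upper plane -> depth 0
  mk <- function(zca, zp_upper = rep(2, 3), zp_lower = rep(-2, 3)) {
    an <- c(rep(c("N", "H", "CA", "O"), length(zca)),
            rep("P", 6))
    rs <- c(rep("ALA", 4 * length(zca)), rep("POP", 6))
    ch <- c(rep("P", 4 * length(zca)), rep(c("U", "L"), each = 3))
    rn <- c(rep(seq_along(zca), each = 4), 1:3, 1:3)
    coords <- NULL
    for (i in seq_along(zca)) {
      base <- c(i * 0.4, 0, zca[i])
      coords <- rbind(coords, rbind(base + c(-0.12, 0.08, 0),
                                    base + c(-0.12, 0.18, 0),
                                    base, base + c(0.12, -0.1, 0)))
    }
    coords <- rbind(coords,
                    cbind(seq(-1, 1, 1), 0, zp_upper),
                    cbind(seq(-1, 1, 1), 0, zp_lower))
    frame_from(list(atom_name = an, resid = rs, chain = ch, rn = rn,
                    resno = rn, coords = coords))
  }
  d0 <- insertion_depth(mk(c(2, 2)))
  expect_equal(d0$mean_depth, c(0, 0), tolerance = 1e-12)

  # 0.5 nm coreward of the upper plane -> -0.5 for each residue
  d1 <- insertion_depth(mk(c(1.5, 1.5)))
  expect_equal(d1$mean_depth, c(-0.5, -0.5), tolerance = 1e-12)

  # lower-leaflet peptide: coreward is +z but depth is still negative
  d2 <- insertion_depth(mk(c(-1.4, -1.4)))
  expect_equal(d2$leaflet[1], "lower")
  expect_equal(d2$mean_depth, c(-0.6, -0.6), tolerance = 1e-12)

  # 3-frame trajectory matches the per-frame brute-force average
  frames <- lapply(1:3, function(s) random_frame(s + 100))
  coords <- array(NA_real_, c(nrow(frames[[1]]$topology), 3, 3))
  for (f in 1:3) coords[, , f] <- frames[[f]]$coords
  traj <- trilayer_trajectory(frames[[1]]$topology, coords,
                              frames[[1]]$box)
  got <- insertion_depth(traj)
  want <- rowMeans(sapply(frames, oracle_depth_frame))
  expect_equal(got$mean_depth, unname(want), tolerance = 1e-12)

  expect_error(insertion_depth(traj, peptide_id = "pep:Z"), "absent")
})

test_that("hydrogen-bond criterion accepts the cone and rejects beyond it", {
  mk_pair <- function(av, hv = c(-0.12, 0.18, 0)) {
    an <- c("N", "H", "CA", "O", rep("P", 4), "C1", "O1")
    rs <- c(rep("ALA", 4), rep("POP", 4), "TRI", "TRI")
    ch <- c(rep("P", 4), "U", "U", "L", "L", "T", "T")
    rn <- c(rep(1, 4), 1, 2, 1, 2, 1, 1)
    coords <- rbind(c(-0.12, 0.08, 1), hv + c(0, 0, 1), c(0, 0, 1),
                    c(0.12, -0.1, 1),
                    c(-1, 0, 2), c(1, 0, 2), c(-1, 0, -2), c(1, 0, -2),
                    av + c(0, 0.2, 0), av)
    frame_from(list(atom_name = an, resid = rs, chain = ch, resno = rn,
                    coords = coords))
  }
  N <- c(-0.12, 0.08, 1)
  # acceptor 0.28 nm along the N-H axis: bonded
  hb <- hbond_series(mk_pair(N + c(0, 0.28, 0)))
  expect_equal(hb$counts$total, 1)
  expect_equal(hb$percent_bonded, 100)
  # any geometry at 0.40 nm: never bonded
  hb <- hbond_series(mk_pair(N + c(0, 0.40, 0)))
  expect_equal(hb$counts$total, 0)
  # 0.30 nm but far off the cone (theta about 90 deg): rejected
  hb <- hbond_series(mk_pair(N + c(0.30, 0, 0)))
  expect_equal(hb$counts$total, 0)
  # no acceptors -> empty series with warning
  spec <- mk_pair(N + c(0, 0.28, 0))
  keep <- spec$topology$molecule_class != "TO"
  bare <- trilayer_frame(spec$topology[keep, ],
                         spec$coords[keep, ], spec$box)
  bare$topology$id <- seq_len(nrow(bare$topology))
  expect_warning(hb <- hbond_series(bare), "empty")
  expect_equal(hb$status, "empty")
})

test_that("coordination and hydrogen bonds match brute-force loops on random frames", {
  for (seed in 1:12) {
    fr <- random_frame(seed)
    got <- tg_coordination(fr)
    want <- oracle_tg_coordination(fr)
    expect_equal(got$coordination, want$coordination, tolerance = 1e-9)
    hb <- hbond_series(fr)
    expect_equal(hb$counts$total, oracle_hbond_count(fr))
  }
})

test_that("statistics are invariant to rigid translation and triolein relabeling", {
  fr <- random_frame(7, n_res = 3, n_pl = 3, n_to = 3)
  shift <- c(1.3, -0.7, 0.4)
  fr2 <- trilayer_frame(fr$topology, sweep(fr$coords, 2, shift, "+"),
                        fr$box)
  expect_equal(insertion_depth(fr2)$mean_depth,
               insertion_depth(fr)$mean_depth, tolerance = 1e-9)
  expect_equal(hbond_series(fr2)$counts$total,
               hbond_series(fr)$counts$total)
  expect_equal(tg_coordination(fr2)$coordination,
               tg_coordination(fr)$coordination, tolerance = 1e-9)

  # permute triolein molecule ids
  top <- fr$topology
  perm <- c("TO:T:1" = "TO:T:3", "TO:T:2" = "TO:T:1", "TO:T:3" = "TO:T:2")
  to <- top$molecule_class == "TO"
  top$molecule_id[to] <- unname(perm[top$molecule_id[to]])
  fr3 <- trilayer_frame(top, fr$coords, fr$box)
  expect_equal(tg_coordination(fr3)$coordination,
               tg_coordination(fr)$coordination, tolerance = 1e-12)
  expect_equal(as.numeric(tg_contact_count(fr3, threshold = 0.3)),
               as.numeric(tg_contact_count(fr, threshold = 0.3)))
})

test_that("contact counts respond to threshold and absent triolein", {
  fr <- random_frame(3, n_to = 0)
  expect_equal(as.numeric(tg_contact_count(fr)), 0)
  fr2 <- random_frame(4, n_to = 3)
  expect_equal(as.numeric(tg_contact_count(fr2, threshold = 1e9)), 0)
  expect_error(tg_contact_count(fr2, threshold = 0), "threshold")
})

test_that("percent bonded equals the time average of the bond indicator", {
  g <- generate_trajectory(generator_config(n_pl = 6, n_to = 3,
                                            planted_contacts = 1,
                                            hbond_fraction = 0.4,
                                            n_frames = 25, seed = 11))
  hb <- hbond_series(g$trajectory)
  expect_equal(hb$percent_bonded, 100 * mean(hb$counts$total >= 1),
               tolerance = 1e-12)
  expect_equal(hb$counts$total, g$truth$hbond_frames)
})
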