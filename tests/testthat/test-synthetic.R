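small_cfg <- function(...) {
  args <- list(n_pl = 8, n_to = 4, planted_contacts = 1,
               jitter_sd = 0, n_frames = 10, seed = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

test_that("ideal helix geometry has the canonical rise and c-alpha spacing", {
  xyz <- ideal_helix_coords(21)
  expect_equal(max(xyz[, 1]) - min(xyz[, 1]), 20 * 0.15, tolerance = 1e-12)
  d <- sqrt(rowSums(diff(xyz)^2))
  # closed form: sqrt(rise^2 + (2 R sin(twist/2))^2)
  expect_equal(unname(d),
               rep(sqrt(0.15^2 + (2 * 0.23 * sinpi(50 / 180))^2), 20),
               tolerance = 1e-12)
  expect_lt(abs(d[1] - 0.38), 0.01)
  # zero kink is the identity
  expect_equal(ideal_helix_coords(21, kink_at = 7, kink_angle = 0),
               ideal_helix_coords(21), tolerance = 1e-12)
  # a kink bends the axis after the pivot only
  k <- ideal_helix_coords(21, kink_at = 7, kink_angle = 40)
  expect_equal(k[1:7, ], ideal_helix_coords(21)[1:7, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(k[8:21, ], ideal_helix_coords(21)[8:21, ])))
  # accepts a Peptide as the length source
  expect_equal(nrow(ideal_helix_coords(apoc2_peptides("P8"))), 21)
})

test_that("frames are bit-reproducible from config and frame index", {
  cfg <- small_cfg()
  f1 <- build_frame(cfg, 3)
  f2 <- build_frame(cfg, 3)
  expect_identical(f1$coords, f2$coords)
  g1 <- generate_trajectory(cfg)
  g2 <- generate_trajectory(cfg)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth, g2$truth)
  # and the written artifacts hash identically
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_trajectory(g1$trajectory, p1)
  write_trajectory(g2$trajectory, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # different seed, different frames
  g3 <- generate_trajectory(small_cfg(seed = 6))
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("planted quantities are recovered by the analysis operators", {
  # noise-free depth is exact
  g <- generate_trajectory(small_cfg(depth = -0.5, n_frames = 5))
  d <- insertion_depth(g$trajectory)
  expect_true(all(abs(d$mean_depth - (-0.5)) < 0.005))
  expect_equal(unique(d$leaflet), "upper")

  # lower-leaflet placement works symmetrically
  gl <- generate_trajectory(small_cfg(depth = -0.4, leaflet = "lower",
                                      n_frames = 5))
  dl <- insertion_depth(gl$trajectory)
  expect_equal(unique(dl$leaflet), "lower")
  expect_true(all(abs(dl$mean_depth - (-0.4)) < 0.005))

  # planted contacts recovered exactly every frame
  g2 <- generate_trajectory(small_cfg(planted_contacts = 3, n_to = 6,
                                      n_frames = 8))
  cc <- tg_contact_count(g2$trajectory)
  expect_identical(attr(cc, "per_frame"), g2$truth$contact_counts)
  expect_equal(as.numeric(cc), 3)

  # background triolein stays far below the contact threshold
  fr <- get_frame(g2$trajectory, 1)
  top <- fr$topology
  pep <- which(top$molecule_class == "peptide")
  to_atoms <- which(top$molecule_class == "TO")
  s <- staplekit:::coordination_matrix(fr, pep, rep(1L, length(pep)),
                                       to_atoms, top$molecule_id[to_atoms],
                                       coordination_params())
  bg <- setdiff(colnames(s), paste0("TO:T:", 1:3))
  expect_lt(max(s[1, bg]), 0.5)

  # hydrogen-bond extremes
  h0 <- generate_trajectory(small_cfg(hbond_fraction = 0, n_frames = 12))
  expect_equal(hbond_series(h0$trajectory)$percent_bonded, 0)
  h1 <- generate_trajectory(small_cfg(hbond_fraction = 1, n_frames = 12))
  expect_equal(hbond_series(h1$trajectory)$percent_bonded, 100)
})

test_that("generated frames carry consistent labels and degenerate configs error", {
  g <- generate_trajectory(small_cfg(n_frames = 2))
  la <- assign_leaflets(get_frame(g$trajectory, 1))
  expect_equal(unname(la$peptide_leaflet), g$truth$leaflet)
  expect_equal(sum(g$trajectory$topology$is_phosphorus), 16)

  # no triolein at all
  g0 <- generate_trajectory(generator_config(n_pl = 6, n_to = 0,
                                             planted_contacts = 0,
                                             hbond_fraction = 0,
                                             n_frames = 2, seed = 1))
  expect_equal(sum(g0$trajectory$topology$molecule_class == "TO"), 0)
  expect_equal(as.numeric(tg_contact_count(g0$trajectory)), 0)

  expect_error(generate_trajectory(small_cfg(n_frames = 0)), "n_frames")
  expect_error(generator_config(planted_contacts = 5, n_to = 2))
  expect_error(generator_config(hbond_fraction = 1.5))
  # a box whose whole core is within exclusion range of the peptide
  tiny <- generator_config(n_pl = 4, n_to = 5, planted_contacts = 0,
                           hbond_fraction = 0, box = c(1.6, 1.6, 5),
                           plane_z = 1.2, n_frames = 1, seed = 2)
  expect_error(generate_trajectory(tiny), "overfilled")
})

test_that("the ground-truth sidecar round-trips through JSON", {
  g <- generate_trajectory(small_cfg(n_frames = 4),
                           truth_out = tj <- tempfile(fileext = ".json"))
  truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(truth$planted_depth, g$truth$planted_depth)
  expect_equal(truth$hbond_frames, g$truth$hbond_frames)
  expect_equal(truth$peptide, g$truth$peptide)
})

test_that("written multi-model PDB re-imports with roles and coordinates intact", {
  g <- generate_trajectory(small_cfg(n_frames = 3),
                           pdb_out = pf <- tempfile(fileext = ".pdb"))
  tr <- read_trajectory(pf)
  expect_equal(dim(tr$coords), dim(g$trajectory$coords))
  expect_lt(max(abs(tr$coords - g$trajectory$coords)), 5.1e-5)
  expect_identical(tr$topology$molecule_class,
                   g$trajectory$topology$molecule_class)
  expect_identical(tr$topology$is_acceptor,
                   g$trajectory$topology$is_acceptor)
  # statistics agree across the round trip
  expect_equal(insertion_depth(tr)$mean_depth,
               insertion_depth(g$trajectory)$mean_depth, tolerance = 1e-4)
  expect_equal(hbond_series(tr)$counts$total,
               hbond_series(g$trajectory)$counts$total)
})
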