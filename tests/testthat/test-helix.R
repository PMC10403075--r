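circ_dist <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }

test_that("wheel angles follow the 100-degree-per-residue rule", {
  expect_equal(wheel_angle(1), 0)
  expect_equal(wheel_angle(4), 300)
  # a full 18-residue turn returns to the same spoke
  expect_equal(wheel_angle(7), wheel_angle(7 + 18))
  # long-staple partners are 20 degrees apart on the minor arc
  expect_equal(circ_dist(wheel_angle(5), wheel_angle(5 + 7)), 20)
  # short-staple partners 40 degrees (400 mod 360)
  expect_equal(circ_dist(wheel_angle(5), wheel_angle(5 + 4)), 40)
})

test_that("hydrophobic moment matches the brute-force vector sum", {
  # ideal 18-mer homopolymer: the 18 unit vectors cancel exactly
  homo <- parse_sequence(strrep("L", 18))
  expect_lt(compute_moment(homo)["magnitude"], 1e-9)

  single <- parse_sequence("F")
  m <- compute_moment(single)
  expect_equal(unname(m["magnitude"]),
               residue_table()["F", "hydrophobicity"])
  expect_equal(unname(m["angle"]), 0)

  # helix-2 window of the bi-helical mimetic vs independent summation
  d6 <- apoc2_peptides("D6PV")
  m <- compute_moment(d6, 21:41)
  h <- residue_table()[d6$residues$code[21:41], "hydrophobicity"]
  expect_equal(unname(m), unname(oracle_moment(h, 21:41)),
               tolerance = 1e-12)

  # random windows against the oracle
  for (seed in 1:25) {
    p <- random_peptide(seed)
    w <- seq_len(length(p))
    m <- compute_moment(p, w)
    h <- residue_table()[p$residues$code, "hydrophobicity"]
    expect_equal(unname(m["magnitude"]),
                 unname(oracle_moment(h, w)["magnitude"]),
                 tolerance = 1e-12)
  }
})

test_that("moment magnitude is frame-rotation invariant, angle shifts with it", {
  # the same residues placed k positions downstream: rotated wheel frame
  base <- "AMSTYTGIF"
  p1 <- parse_sequence(base)
  for (k in c(1, 5, 11)) {
    p2 <- parse_sequence(paste0(strrep("G", k), base))
    m1 <- compute_moment(p1)
    g <- residue_table()["G", "hydrophobicity"]
    # subtract the poly-Gly prefix moment to isolate the shifted window
    m2 <- compute_moment(p2, (k + 1):(k + nchar(base)))
    expect_equal(unname(m1["magnitude"]), unname(m2["magnitude"]),
                 tolerance = 1e-12)
    expect_lt(unname(circ_dist(m2["angle"], (m1["angle"] + 100 * k) %% 360)),
              1e-9)
  }
})

test_that("hydrophobic face membership follows the moment direction", {
  homo <- parse_sequence(strrep("V", 18))
  proj <- project_wheel(homo)
  expect_error(hydrophobic_face(proj), "undefined face")

  p33 <- apoc2_peptides("P33")
  proj <- project_wheel(p33)
  face <- hydrophobic_face(proj, 90)
  # brute-force membership
  expected <- proj$positions[circ_dist(wheel_angle(proj$positions),
                                       proj$moment_angle) <= 90]
  expect_identical(face, expected)
  # the short-staple arms at 14/18 sit in the scaffold's face
  expect_true(all(c(14, 18) %in% face))
  # half-wheel face of a generic projection counts the half-wheel
  expect_true(all(circ_dist(wheel_angle(face), proj$moment_angle) <= 90))
})

test_that("staple proposal spans are exact and ranked by displaced hydrophobicity", {
  p33 <- apoc2_peptides("P33")
  long <- propose_staple(p33, "long")
  expect_true(all(long$j - long$i == 7))
  expect_true(all(diff(long$displaced_hydrophobicity) >= 0))
  # the documented placements are among the candidates
  expect_true(any(long$i == 11 & long$j == 18))
  expect_true(any(long$i == 15 & long$j == 22))
  short <- propose_staple(p33, "short", window = 13:33)
  expect_true(all(short$j - short$i == 4))
  expect_true(any(short$i == 14 & short$j == 18))

  # in face-restricted mode no candidate has an arm outside the face
  for (seed in 1:10) {
    p <- random_peptide(seed, min_len = 12, max_len = 24)
    proj <- project_wheel(p)
    if (proj$moment_magnitude < 1e-6) next
    cand <- propose_staple(p, "short", face_filter = "both")
    if (!nrow(cand)) next
    face <- proj$face_members
    expect_true(all(cand$i %in% face) && all(cand$j %in% face))
  }
  expect_error(propose_staple(p33, "long", window = 1:5), "span")
})

test_that("variant arrays implement the Ala-scan designs", {
  polyA <- parse_sequence(strrep("A", 12))
  expect_length(build_variant_array(polyA, "ala_scan")$variants, 0)

  p8 <- apoc2_peptides("P8")
  scan <- build_variant_array(p8, "ala_scan")
  expect_length(scan$variants, sum(p8$residues$code != "A"))
  for (v in scan$variants)
    expect_equal(sum(v$residues$code != p8$residues$code), 1)
  # staple arms are skipped
  p6 <- apoc2_peptides("P6")
  scan6 <- build_variant_array(p6, "ala_scan")
  expect_false(any(grepl("^(R8|S5)", names(scan6$variants))))

  # quadruple activation-residue variant: exactly four substitutions
  d6 <- apoc2_peptides("D6PV")
  ae <- build_variant_array(d6, "quad_AE", window = 21:41)$variants$AE
  diffs <- which(ae$residues$code != d6$residues$code)
  expect_identical(diffs, 20L + c(5L, 8L, 11L, 12L))
  expect_true(all(ae$residues$code[diffs] == "A"))
  expect_error(build_variant_array(p8, "quad_AE", window = 2:21),
               "activation residues")

  # damaged first helix: E8 deleted, second helix untouched
  dmg <- build_variant_array(d6, "damaged_helix1", window = 1:19)$variants$dE8
  expect_equal(length(dmg), 40)
  expect_identical(dmg$residues$code[20:40], d6$residues$code[21:41])
  expect_error(build_variant_array(d6, "damaged_helix1", window = 2:20),
               "not Glu")
})

test_that("deleting a residue from an amphipathic 18-mer re-faces downstream residues", {
  # ideal amphipathic 18-mer: Leu on one semicircle, Ser on the other
  codes <- ifelse(circ_dist(wheel_angle(1:18), 0) <= 90, "L", "S")
  p <- parse_sequence(paste(codes, collapse = ""))
  f0 <- project_wheel(p)$face_members
  del <- apply_modifications(p, mod_delete(8))
  f1 <- project_wheel(del)$face_members
  # compare membership of the residues downstream of the deletion
  down0 <- setdiff(f0, 1:8) - 1L       # their new positions after deletion
  down1 <- setdiff(f1, 1:7)
  expect_false(setequal(down0, down1))
})
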