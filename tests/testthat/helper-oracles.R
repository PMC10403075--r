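# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain scalar loops (own minimum-image arithmetic, direct
# formula evaluation) so they share no code path with the package
# implementations they check.

oracle_mi_dist1 <- function(a, b, box) {
  d2 <- 0
  for (k in 1:3) {
    d <- a[k] - b[k]
    while (d > box[k] / 2) d <- d - box[k]
    while (d < -box[k] / 2) d <- d + box[k]
    d2 <- d2 + d^2
  }
  sqrt(d2)
}

oracle_moment <- function(h, pos) {
  x <- 0; y <- 0
  for (k in seq_along(pos)) {
    ang <- ((pos[k] - 1) * 100) %% 360
    x <- x + h[k] * cos(ang * pi / 180)
    y <- y + h[k] * sin(ang * pi / 180)
  }
  c(magnitude = sqrt(x^2 + y^2), angle = (atan2(y, x) * 180 / pi) %% 360)
}

oracle_switch_term <- function(r, r0 = 0.4) {
  x <- r / r0
  if (abs(x - 1) < 1e-12) return(0.5)
  (1 - x^6) / (1 - x^12)
}

# residue-wise coordination: max over TO molecules of the pair sum
oracle_tg_coordination <- function(frame, r0 = 0.4) {
  top <- frame$topology
  pep <- which(top$molecule_class == "peptide")
  residues <- sort(unique(top$residue_index[pep]))
  to_ids <- unique(top$molecule_id[top$molecule_class == "TO"])
  out <- numeric(length(residues))
  for (ri in seq_along(residues)) {
    ratoms <- pep[top$residue_index[pep] == residues[ri]]
    best <- 0
    for (tid in to_ids) {
      tatoms <- which(top$molecule_id == tid)
      s <- 0
      for (i in ratoms) for (j in tatoms)
        s <- s + oracle_switch_term(
          oracle_mi_dist1(frame$coords[i, ], frame$coords[j, ], frame$box),
          r0)
      if (s > best) best <- s
    }
    out[ri] <- best
  }
  data.frame(residue = residues, coordination = out)
}

oracle_hbond_count <- function(frame, r_max0 = 0.33, curvature = 0.00044) {
  top <- frame$topology
  hs <- which(top$is_donor_h & top$molecule_class == "peptide")
  acc <- which(top$is_acceptor & top$molecule_class == "TO")
  n <- 0
  for (h in hs) {
    d <- top$donor_parent[h]
    for (a in acc) {
      r <- oracle_mi_dist1(frame$coords[d, ], frame$coords[a, ], frame$box)
      vdh <- frame$coords[h, ] - frame$coords[d, ]
      vda <- frame$coords[a, ] - frame$coords[d, ]
      for (k in 1:3) {
        vdh[k] <- vdh[k] - frame$box[k] * round(vdh[k] / frame$box[k])
        vda[k] <- vda[k] - frame$box[k] * round(vda[k] / frame$box[k])
      }
      ct <- sum(vdh * vda) / sqrt(sum(vdh^2) * sum(vda^2))
      theta <- acos(max(-1, min(1, ct))) * 180 / pi
      if (r <= r_max0 - curvature * theta^2) n <- n + 1
    }
  }
  n
}

# per-residue depth of one frame: mean upper/lower phosphorus planes,
# peptide assigned to nearest plane, toward-core negative
oracle_depth_frame <- function(frame) {
  top <- frame$topology
  zp <- frame$coords[top$is_phosphorus, 3]
  mid <- (max(zp) + min(zp)) / 2
  pu <- mean(zp[zp > mid]); pl <- mean(zp[zp <= mid])
  ca <- which(top$is_c_alpha)
  ca <- ca[order(top$residue_index[ca])]
  zca <- frame$coords[ca, 3]
  if (abs(mean(zca) - pu) <= abs(mean(zca) - pl)) zca - pu else pl - zca
}

oracle_auc <- function(t, y) {
  s <- 0
  for (k in seq_len(length(t) - 1))
    s <- s + (t[k + 1] - t[k]) * (y[k] + y[k + 1]) / 2
  s
}

# small randomized trilayer frame for oracle-equivalence tests: a few
# peptide residues (N/H/CA/O), >=2 phosphorus per leaflet, a few triolein
random_frame <- function(seed, n_res = 3, n_pl = 3, n_to = 2) {
  set.seed(seed)
  box <- c(5, 5, 8)
  atom_name <- character(0); resid <- character(0)
  chain <- character(0); resno <- integer(0); coords <- NULL
  add <- function(an, rs, ch, rn, xyz) {
    atom_name <<- c(atom_name, an); resid <<- c(resid, rs)
    chain <<- c(chain, ch); resno <<- c(resno, rn)
    coords <<- rbind(coords, xyz)
  }
  zpep <- runif(1, 0.5, 1.8)
  for (i in seq_len(n_res)) {
    base <- c(runif(1, -2, 2), runif(1, -2, 2), zpep + runif(1, -0.1, 0.1))
    add("N", "ALA", "P", i, base + c(-0.12, 0.08, 0))
    add("H", "ALA", "P", i, base + c(-0.12, 0.18, 0))
    add("CA", "ALA", "P", i, base)
    add("O", "ALA", "P", i, base + c(0.12, -0.10, 0))
  }
  for (lf in c("U", "L")) {
    z0 <- if (lf == "U") 2 else -2
    for (m in seq_len(n_pl)) {
      xy <- runif(2, -2.4, 2.4)
      add("P", "POP", lf, m, c(xy, z0 + runif(1, -0.2, 0.2)))
      add("C1", "POP", lf, m, c(xy, z0 - 0.1))
    }
  }
  for (m in seq_len(n_to)) {
    centre <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, -1, 1.6))
    for (k in 1:4) {
      nm <- if (k <= 2) paste0("C", k) else paste0("O", k - 2)
      add(nm, "TRI", "T", m, centre + runif(3, -0.3, 0.3))
    }
  }
  top <- staplekit:::build_topology(atom_name, resid, chain, resno)
  trilayer_frame(top, unname(coords), box)
}

# random dialect-valid peptide for round-trip / protection properties
random_peptide <- function(seed, min_len = 6, max_len = 24) {
  set.seed(seed)
  n <- sample(min_len:max_len, 1)
  naturals <- rownames(residue_table())[residue_table()$natural]
  codes <- sample(naturals, n, replace = TRUE)
  stereo <- ifelse(codes == "G", "achiral",
                   sample(c("L", "D"), n, replace = TRUE,
                          prob = c(0.85, 0.15)))
  nonnat <- c("Nle", "Sar", "Aib")
  for (k in sample(n, min(n, sample(0:2, 1)))) {
    codes[k] <- sample(nonnat, 1)
    stereo[k] <- if (residue_table()[codes[k], "achiral"]) "achiral" else "L"
  }
  toks <- ifelse(codes %in% naturals,
                 ifelse(stereo == "D", tolower(codes), codes),
                 paste0("{", codes, "}"))
  txt <- paste(toks, collapse = "")
  if (runif(1) < 0.3) txt <- paste0(sample(c("Ac-", "Oct-"), 1), txt)
  if (runif(1) < 0.3) txt <- paste0(txt, "-NH2")
  # maybe add one staple on fresh olefin arms
  if (n >= 9 && runif(1) < 0.5) {
    off <- sample(c(4L, 7L), 1)
    i <- sample(seq_len(n - off), 1)
    p <- parse_sequence(txt)
    p <- apply_modifications(p, list(
      mod_substitute(i, "R8"), mod_substitute(i + off, "S5"),
      mod_add_staple(i, i + off)))
    return(p)
  }
  parse_sequence(txt)
}
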