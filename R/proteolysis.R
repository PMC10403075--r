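## Deterministic protease susceptibility / protection rule engine.
##
## Endoproteases are described by their P1 specificity (cleavage C-terminal
## to these residues) plus an active pH interval; exopeptidases by terminal
## behaviour. Protection is structural and rule-based: Pro at P1',
## D stereochemistry at P1 or P1', an N-methylated amide at P1', bonds under
## a hydrocarbon staple, and terminal caps. No kinetics are modelled.

.protease_registry <- list(
  trypsin = list(
    type = "endo",
    ## K and R, although the studied peptides expose only Lys sites
    p1_residues = c("K", "R"),
    ph_range = c(5, 10), optimum_ph = 8.2),
  pepsin = list(
    type = "endo",
    ## minimal broad-specificity aromatic/aliphatic P1 set
    p1_residues = c("F", "L", "W", "Y"),
    ph_range = c(1, 4), optimum_ph = 2.0),
  proteinase_K = list(
    type = "endo",
    ## aliphatic + aromatic; Nle included as the Leu isostere
    p1_residues = c("A", "V", "L", "I", "F", "W", "Y", "Nle"),
    ph_range = c(5, 12), optimum_ph = 8.0),
  aminopeptidase = list(
    type = "exo_n", p1_residues = character(),
    ph_range = c(5, 10), optimum_ph = 7.4),
  carboxypeptidase = list(
    type = "exo_c", p1_residues = character(),
    ph_range = c(5, 10), optimum_ph = 7.4)
)

#' Protease rules
#'
#' `protease_rule()` returns a registered rule; `pepsin_rule()` is the
#' acidic broad-specificity gastric rule (P1 in F/L/W/Y, active pH 1-4).
#' The `p1_residues` set can be overridden, e.g. to widen pepsin's
#' specificity.
#'
#' @param name one of `"trypsin"`, `"pepsin"`, `"proteinase_K"`,
#'   `"aminopeptidase"`, `"carboxypeptidase"`.
#' @param p1_residues optional replacement P1 set (endoproteases only).
#' @return a `ProteaseRule`.
#' @export
protease_rule <- function(name, p1_residues = NULL) {
  if (!name %in% names(.protease_registry))
    stop("unknown protease: ", name, "; registered: ",
         paste(names(.protease_registry), collapse = ", "), call. = FALSE)
  r <- .protease_registry[[name]]
  if (!is.null(p1_residues)) r$p1_residues <- p1_residues
  structure(c(list(name = name), r), class = "ProteaseRule")
}

#' @rdname protease_rule
#' @export
pepsin_rule <- function() protease_rule("pepsin")

#' @export
print.ProteaseRule <- function(x, ...) {
  cat("ProteaseRule", x$name, "(", x$type, ")\n")
  if (x$type == "endo")
    cat("  P1:", paste(x$p1_residues, collapse = ","),
        " pH", paste(x$ph_range, collapse = "-"), "\n")
  invisible(x)
}

## bonds shielded by staples: P1 position within [i, j-1]
staple_shielded <- function(p, bond) {
  s <- p$staples
  if (!nrow(s)) return(rep(FALSE, length(bond)))
  vapply(bond, function(b) any(s$i <= b & b <= s$j - 1), TRUE)
}

#' Predict protease-susceptible bonds
#'
#' For an endoprotease rule, candidate scissile bonds are those whose P1
#' residue is in the rule's specificity set, provided the assay pH lies in
#' the rule's active range (outside it the digest is empty -- the basis of
#' pepsin inactivation at neutral pH). Each candidate is then marked
#' protected when a structural blocker applies: Pro at P1', a D residue at
#' P1 or P1', an N-methylated amide at P1' (e.g. sarcosine), or the bond
#' lying within a hydrocarbon-staple span (P1 in `[i, j-1]`).
#' Exopeptidase rules instead report the terminus: the N-terminus is open
#' unless capped, the C-terminus open unless the last two residues are D
#' isomers or the terminus is amidated.
#'
#' @param p a `Peptide`.
#' @param rule a `ProteaseRule` (or its name).
#' @param ph assay pH (defaults to the rule's optimum).
#' @return a `DigestResult`: site table (`bond` = P1 position, `p1`,
#'   `protected`, `reasons`) and `susceptible_count`.
#' @examples
#' digest_sites(apoc2_peptides("SP1"), "trypsin", ph = 8.2)
#' @export
digest_sites <- function(p, rule, ph = NULL) {
  stopifnot(inherits(p, "Peptide"))
  if (is.character(rule)) rule <- protease_rule(rule)
  stopifnot(inherits(rule, "ProteaseRule"))
  if (is.null(ph)) ph <- rule$optimum_ph
  r <- p$residues
  L <- nrow(r)

  if (rule$type == "endo") {
    sites <- data.frame(bond = integer(), p1 = character(),
                        protected = logical(), reasons = character(),
                        stringsAsFactors = FALSE)
    if (ph >= rule$ph_range[1] && ph <= rule$ph_range[2] && L >= 2) {
      bonds <- which(r$code[-L] %in% rule$p1_residues)
      if (length(bonds)) {
        reasons <- lapply(bonds, function(b) {
          why <- character()
          if (r$code[b + 1] == "P") why <- c(why, "proline_at_p1prime")
          if (r$stereo[b] == "D" || r$stereo[b + 1] == "D")
            why <- c(why, "d_residue_at_p1_or_p1prime")
          if (r$n_methyl[b + 1]) why <- c(why, "n_methyl_at_p1prime")
          if (staple_shielded(p, b)) why <- c(why, "within_staple_span")
          why
        })
        sites <- data.frame(
          bond = bonds, p1 = r$code[bonds],
          protected = lengths(reasons) > 0,
          reasons = vapply(reasons, paste, "", collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
  } else if (rule$type == "exo_n") {
    protected <- p$n_cap != "free"
    sites <- data.frame(
      bond = NA_integer_, p1 = "N-terminus",
      protected = protected,
      reasons = if (protected) "terminal_cap" else "",
      stringsAsFactors = FALSE)
  } else { # exo_c
    d_tail <- L >= 2 && all(r$stereo[c(L - 1, L)] == "D")
    amide <- p$c_cap == "amide"
    why <- c(if (d_tail) "d_residue_at_p1_or_p1prime",
             if (amide) "terminal_cap")
    sites <- data.frame(
      bond = NA_integer_, p1 = "C-terminus",
      protected = d_tail || amide,
      reasons = paste(why, collapse = "+"),
      stringsAsFactors = FALSE)
  }
  structure(list(peptide = if (nzchar(p$name)) p$name else write_sequence(p),
                 protease = rule$name, ph = ph, sites = sites,
                 susceptible_count = sum(!sites$protected)),
            class = "DigestResult")
}

#' @export
print.DigestResult <- function(x, ...) {
  cat("DigestResult:", x$protease, "on", x$peptide, "at pH", x$ph, "\n")
  if (nrow(x$sites)) print(x$sites) else cat("  no candidate sites\n")
  cat("  susceptible:", x$susceptible_count, "\n")
  invisible(x)
}

#' Protease resistance report
#'
#' Digests a peptide with a panel of protease rules (each at its optimum
#' pH unless `ph` is given) and tabulates candidate sites, protected sites
#' and the residual susceptible count; exopeptidase rows report terminal
#' vulnerability.
#'
#' @param p a `Peptide`.
#' @param panel character names or `ProteaseRule` list; defaults to the
#'   full registered panel.
#' @param ph optional single pH applied to every rule.
#' @return data.frame with one row per protease.
#' @examples
#' resistance_report(apoc2_peptides("SP2"))
#' @export
resistance_report <- function(p, panel = names(.protease_registry),
                              ph = NULL) {
  if (!length(panel)) stop("empty protease panel", call. = FALSE)
  rows <- lapply(panel, function(rl) {
    d <- digest_sites(p, rl, ph)
    data.frame(protease = d$protease, ph = d$ph,
               n_sites = nrow(d$sites),
               protected = sum(d$sites$protected),
               susceptible_count = d$susceptible_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
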