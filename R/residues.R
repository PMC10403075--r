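#' @keywords internal
"_PACKAGE"

## Monoisotopic / average element masses (IUPAC 2021). Residue masses are
## derived from elemental formulas at load time so that mass bookkeeping has a
## single source of truth.
.elements <- list(
  monoisotopic = c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100),
  average      = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
)

#' Mass of a molecular formula
#'
#' Computes the mass of a Hill-style elemental formula restricted to the
#' elements C, H, N, O and S (sufficient for peptides and their caps).
#'
#' @param formula formula string, e.g. `"C6H11NO"`.
#' @param kind `"monoisotopic"` or `"average"`.
#' @return mass in Da.
#' @examples
#' formula_mass("H2O")          # water, 18.0106
#' formula_mass("C2H4")         # ethene lost on staple closure
#' @export
formula_mass <- function(formula, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  parts <- regmatches(formula,
                      gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  parts <- parts[nzchar(parts)]
  masses <- .elements[[kind]]
  total <- 0
  seen <- 0L
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(masses))
      stop("unsupported element in formula: ", el, call. = FALSE)
    total <- total + masses[[el]] * n
    seen <- seen + nchar(p)
  }
  if (seen != nchar(formula))
    stop("malformed formula: ", formula, call. = FALSE)
  total
}

## Registered residues. Formulas are residue formulas (amino acid minus one
## water). Hydrophobicities are the Eisenberg consensus scale; non-natural
## residues take the value of their closest natural analogue, and the four
## olefin-arm residues take the Leu value (aliphatic hydrocarbon arms that the
## design treats as hydrophobic-face substituents). `map_natural` is the
## natural one-letter stand-in used by the antigenicity scan.
.residue_defs <- rbind(
  data.frame(
    code = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    name = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
             "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
             "Tyr", "Val"),
    formula = c("C3H5NO", "C6H12N4O", "C4H6N2O2", "C4H5NO3", "C3H5NOS",
                "C5H8N2O2", "C5H7NO3", "C2H3NO", "C6H7N3O", "C6H11NO",
                "C6H11NO", "C6H12N2O", "C5H9NOS", "C9H9NO", "C5H7NO",
                "C3H5NO2", "C4H7NO2", "C11H10N2O", "C9H9NO2", "C5H9NO"),
    hydrophobicity = c(0.62, -2.53, -0.78, -0.90, 0.29, -0.85, -0.74, 0.48,
                       -0.40, 1.38, 1.06, -1.50, 0.64, 1.19, 0.12, -0.18,
                       -0.05, 0.81, 0.26, 1.08),
    achiral = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
    n_methyl_default = FALSE,
    natural = TRUE,
    olefin = FALSE,
    arms = 0L,
    map_natural = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    stringsAsFactors = FALSE
  ),
  data.frame(
    code = c("Nle", "Sar", "Aib", "R8", "S5", "B5", "S8"),
    name = c("Norleucine", "Sarcosine", "alpha-aminoisobutyric acid",
             "(R)-alpha-methyl,alpha-octenylglycine",
             "(S)-alpha-methyl,alpha-pentenylglycine",
             "bis-pentenylglycine",
             "(S)-alpha-methyl,alpha-octenylglycine"),
    formula = c("C6H11NO", "C3H5NO", "C4H7NO",
                "C11H19NO", "C8H13NO", "C12H19NO", "C11H19NO"),
    hydrophobicity = c(1.06, 0.48, 0.62, 1.06, 1.06, 1.06, 1.06),
    achiral = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    n_methyl_default = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    natural = FALSE,
    olefin = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    arms = c(0L, 0L, 0L, 1L, 1L, 2L, 1L),
    map_natural = c("L", "G", "A", "A", "A", "A", "A"),
    stringsAsFactors = FALSE
  )
)
.residue_defs$monoisotopic_mass <-
  vapply(.residue_defs$formula, formula_mass, 0, kind = "monoisotopic")
.residue_defs$average_mass <-
  vapply(.residue_defs$formula, formula_mass, 0, kind = "average")
rownames(.residue_defs) <- .residue_defs$code

#' Registered residue table
#'
#' The residue registry: 20 natural residues plus the non-naturals used in
#' stapled apolipoprotein-mimetic design (Nle, Sar, Aib and the olefin-arm
#' residues R8, S5, B5, S8). Masses are computed from residue elemental
#' formulas; hydrophobicities are the Eisenberg consensus scale with the
#' olefin arms assigned the Leu value.
#'
#' @return data.frame with one row per registered residue code.
#' @export
residue_table <- function() .residue_defs

residue_info <- function(code) {
  bad <- setdiff(unique(code), .residue_defs$code)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  .residue_defs[code, , drop = FALSE]
}

## mass deltas used by peptide bookkeeping
.mass_const <- function(kind) {
  list(
    water    = formula_mass("H2O", kind),
    ethene   = formula_mass("C2H4", kind),
    acetyl   = formula_mass("C2H2O", kind),
    octanoyl = formula_mass("C8H14O", kind),
    n_methyl = formula_mass("CH2", kind),
    ## amide C-terminus: OH -> NH2
    amide    = formula_mass("NH", kind) - formula_mass("O", kind)
  )
}
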