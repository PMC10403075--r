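## Sequence dialect files and FASTA import.

#' Read a peptide dialect file
#'
#' One record per line, `name<TAB>dialect-string`; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return named list of `Peptide` objects.
#' @export
read_peptide_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) != 2)
      stop("malformed record (expected name<TAB>sequence): ", ln,
           call. = FALSE)
    out[[f[1]]] <- parse_sequence(f[2], name = f[1])
  }
  out
}

#' Write peptides to a dialect file
#'
#' @param peptides named list of `Peptide` objects (names become record
#'   names when the peptide's own name is empty).
#' @param path file path.
#' @export
write_peptide_file <- function(peptides, path) {
  nm <- names(peptides)
  lines <- vapply(seq_along(peptides), function(i) {
    p <- peptides[[i]]
    name <- if (nzchar(p$name)) p$name else nm[i]
    paste(name, write_sequence(p), sep = "\t")
  }, "")
  writeLines(lines, path)
}

#' Import natural-residue peptides from FASTA
#'
#' Plain FASTA covers only the 20 natural L residues; staples, caps and
#' non-naturals require the dialect format.
#'
#' @param path FASTA file path.
#' @return named list of `Peptide` objects.
#' @export
read_fasta_peptides <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  out <- lapply(seq_along(seqs), function(i) {
    parse_sequence(toupper(as.character(seqs[[i]])),
                   name = names(seqs)[i])
  })
  names(out) <- names(seqs)
  out
}

#' Packaged apolipoprotein C-II mimetic peptides
#'
#' The peptide set studied by the package: the native ApoC2 59-79
#' activation helix (`P8` / `APOC2_59_79`), its single-stapled (`P6`,
#' `SP1`), stitched (`SP2`, `SP2a`) derivatives, the bi-helical 41-residue
#' `D6PV` mimetic, the 33-residue staple-scanning scaffold `P33`, and the
#' native ApoC2 flanking region `NATIVE_H1` that D6PV's first helix
#' replaced. `P8` is verbatim mature human ApoC2 residues 59-79
#' (`AMSTYTGIFTDQVLSVLKGEE`); the modified peptides apply the documented
#' design steps to it (staple arms at 3/10, and 17 for the stitch; Met2 to
#' Nle; Gly19 to Sar; D-Glu at 20/21; acetyl or octanoyl N-cap; Ala1 to Aib
#' in `SP2a`). `D6PV` and `P33` are synthetic reconstructions: their
#' second-helix region is the native 21-mer, while the first-helix region
#' is rebuilt from its documented properties (contains the antigenic
#' stretch `KEVFEKLRDLY` with a Glu at local position 8, Pro linker) rather
#' than from a published sequence.
#'
#' @param name optional single fixture name; default returns all.
#' @return a `Peptide`, or a named list of all fixtures.
#' @examples
#' apoc2_peptides("SP1")
#' names(apoc2_peptides())
#' @export
apoc2_peptides <- function(name = NULL) {
  path <- system.file("extdata", "apoc2_mimetics.tsv", package = "staplekit",
                      mustWork = TRUE)
  all <- read_peptide_file(path)
  if (is.null(name)) return(all)
  if (!name %in% names(all))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  all[[name]]
}
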