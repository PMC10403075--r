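## Kolaskar-Tongaonkar antigenic-segment prediction.

## Published antigenic propensity table (Kolaskar & Tongaonkar 1990),
## embedded verbatim and version-tagged.
.kt_version <- "KT1990"
.kt_table <- c(
  A = 1.064, C = 1.412, D = 0.866, E = 0.851, F = 1.091,
  G = 0.874, H = 1.105, I = 1.152, K = 0.930, L = 1.250,
  M = 0.826, N = 0.776, P = 1.064, Q = 1.015, R = 0.873,
  S = 1.012, T = 0.909, V = 1.383, W = 0.893, Y = 1.161)

#' Kolaskar-Tongaonkar propensity table
#'
#' @return data.frame of residue and antigenic propensity, with the table
#'   version in attribute `"version"`.
#' @export
kolaskar_table <- function() {
  structure(data.frame(residue = names(.kt_table),
                       propensity = unname(.kt_table)),
            version = .kt_version)
}

#' Map non-natural residues to natural stand-ins
#'
#' The antigenicity propensity table covers the 20 natural residues only,
#' so peptides are first mapped: Nle to Leu, Sar to Gly, Aib to Ala, the
#' olefin-arm residues (R8/S5/B5/S8) to Ala, and D residues to their L
#' equivalents. The mapping actually applied is recorded so scan
#' provenance stays explicit.
#'
#' @param p a `Peptide`.
#' @return the natural one-letter sequence, with a `"mapping"` attribute
#'   (data.frame of position, from, to for every altered position).
#' @export
map_nonnatural <- function(p) {
  stopifnot(inherits(p, "Peptide"))
  info <- residue_info(p$residues$code)
  mapped <- info$map_natural
  changed <- which(!info$natural | p$residues$stereo == "D")
  mapping <- data.frame(position = changed,
                        from = ifelse(p$residues$stereo[changed] == "D",
                                      tolower(p$residues$code[changed]),
                                      p$residues$code[changed]),
                        to = mapped[changed],
                        stringsAsFactors = FALSE)
  structure(paste(mapped, collapse = ""), mapping = mapping)
}

#' Antigenic-segment scan
#'
#' Sliding 7-mer scan of the Kolaskar-Tongaonkar antigenic propensity: the
#' mean propensity of each overlapping 7-mer is assigned to the window
#' centre (position `i + 3`), so scores exist for positions `4 .. L - 3`;
#' maximal runs of at least `min_len` consecutive positions with score
#' above `threshold` are reported as antigenic segments. With
#' `renormalize = TRUE` scores are first divided by the mean propensity of
#' the whole sequence, so the threshold selects above-average windows;
#' the default is the plain `score > 1` rule.
#'
#' @param x a natural-residue sequence string, or a `Peptide` (mapped via
#'   [map_nonnatural()] first).
#' @param threshold propensity threshold (default 1).
#' @param min_len minimum run length reported as a segment (default 8).
#' @param renormalize divide scores by the sequence-mean propensity first.
#' @return an `AntigenicScan`: per-position scores (named by position),
#'   segment table (`start`, `end` in scored-position space), threshold,
#'   table version and any residue mapping applied.
#' @examples
#' scan <- kolaskar_scan(apoc2_peptides("D6PV"))
#' scan$segments
#' @export
kolaskar_scan <- function(x, threshold = 1, min_len = 8,
                          renormalize = FALSE) {
  mapping <- NULL
  if (inherits(x, "Peptide")) {
    s <- map_nonnatural(x)
    mapping <- attr(s, "mapping")
    x <- as.character(s)
  }
  stopifnot(is.character(x), length(x) == 1)
  chars <- strsplit(toupper(x), "")[[1]]
  L <- length(chars)
  if (L < 7)
    stop("sequence of length ", L, " is below the 7-mer window",
         call. = FALSE)
  bad <- setdiff(unique(chars), names(.kt_table))
  if (length(bad))
    stop("residue(s) without an antigenic propensity: ",
         paste(bad, collapse = ", "), call. = FALSE)
  v <- .kt_table[chars]
  ## sliding 7-mer mean assigned to window centre
  cs <- cumsum(c(0, v))
  centre <- 4:(L - 3)
  scores <- (cs[centre + 4] - cs[centre - 3]) / 7
  if (renormalize) scores <- scores / mean(v)
  names(scores) <- centre

  above <- centre[scores > threshold]
  segments <- data.frame(start = integer(), end = integer())
  if (length(above)) {
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    runs <- Filter(function(r) length(r) >= min_len, runs)
    if (length(runs))
      segments <- data.frame(start = vapply(runs, min, 0L),
                             end = vapply(runs, max, 0L),
                             row.names = NULL)
  }
  structure(list(sequence = paste(chars, collapse = ""),
                 scores = scores, segments = segments,
                 threshold = threshold, min_len = min_len,
                 renormalize = renormalize,
                 table_version = .kt_version,
                 mapping = mapping),
            class = "AntigenicScan")
}

#' @export
print.AntigenicScan <- function(x, ...) {
  cat("AntigenicScan (", x$table_version, ") of ", nchar(x$sequence),
      " residues\n", sep = "")
  if (nrow(x$segments)) {
    for (k in seq_len(nrow(x$segments))) {
      s <- x$segments$start[k]; e <- x$segments$end[k]
      cat(sprintf("  segment %d-%d: %s\n", s, e,
                  substr(x$sequence, s, e)))
    }
  } else cat("  no antigenic segment\n")
  invisible(x)
}
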