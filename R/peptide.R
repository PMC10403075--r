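## Peptide data model: extended residues, staples, terminal caps.

new_peptide <- function(residues, staples = NULL, n_cap = "free",
                        c_cap = "free_acid", name = "") {
  if (is.null(staples) || nrow(staples) == 0) {
    staples <- data.frame(i = integer(), j = integer(),
                          span_class = character(), closed = logical(),
                          stringsAsFactors = FALSE)
  }
  p <- structure(
    list(name = name, residues = residues, staples = staples,
         n_cap = n_cap, c_cap = c_cap),
    class = "Peptide")
  validate_peptide(p)
}

validate_peptide <- function(p) {
  r <- p$residues
  if (nrow(r) < 1) stop("peptide must contain at least one residue",
                        call. = FALSE)
  info <- residue_info(r$code)  # errors on unknown codes
  achiral <- info$achiral
  bad <- which(achiral & r$stereo != "achiral")
  if (length(bad))
    stop("residue(s) at position(s) ", paste(bad, collapse = ", "),
         " are achiral and cannot carry L/D stereochemistry", call. = FALSE)
  bad <- which(!achiral & r$stereo == "achiral")
  if (length(bad))
    stop("chiral residue(s) at position(s) ", paste(bad, collapse = ", "),
         " need L or D stereochemistry", call. = FALSE)
  if (!p$n_cap %in% c("free", "acetyl", "octanoyl"))
    stop("n_cap must be one of free/acetyl/octanoyl", call. = FALSE)
  if (!p$c_cap %in% c("free_acid", "amide"))
    stop("c_cap must be free_acid or amide", call. = FALSE)
  s <- p$staples
  if (nrow(s)) {
    if (any(s$i < 1 | s$j > nrow(r)))
      stop("staple positions outside sequence bounds", call. = FALSE)
    if (any(s$j - s$i != 4 & s$j - s$i != 7))
      stop("staple span must be i,i+4 (short) or i,i+7 (long)", call. = FALSE)
    arms <- c(s$i, s$j)
    for (pos in unique(arms)) {
      ri <- residue_info(r$code[pos])
      n_here <- sum(arms == pos)
      if (!ri$olefin)
        stop("staple arm at position ", pos, " requires an olefin-arm ",
             "residue (R8/S5/B5/S8), found ", r$code[pos], call. = FALSE)
      if (n_here > ri$arms)
        stop("residue ", r$code[pos], " at position ", pos, " carries ",
             n_here, " staple arms but supports ", ri$arms, call. = FALSE)
    }
  }
  p
}

## span_class bookkeeping: segments sharing a B5 hub are a stitch
classify_staples <- function(p) {
  s <- p$staples
  if (!nrow(s)) return(p)
  arms <- c(s$i, s$j)
  hubs <- unique(arms[duplicated(arms)])
  s$span_class <- ifelse(s$j - s$i == 4, "short", "long")
  if (length(hubs))
    s$span_class[s$i %in% hubs | s$j %in% hubs] <- "stitch_segment"
  p$staples <- s[order(s$i, s$j), , drop = FALSE]
  rownames(p$staples) <- NULL
  p
}

#' @export
print.Peptide <- function(x, ...) {
  cat("Peptide", if (nzchar(x$name)) paste0("'", x$name, "'") else "",
      "(", nrow(x$residues), "residues )\n")
  cat(" ", write_sequence(x), "\n")
  if (nrow(x$staples)) {
    st <- x$staples
    cat("  staples:",
        paste(sprintf("%d-%d [%s%s]", st$i, st$j, st$span_class,
                      ifelse(st$closed, "", ", open")), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' @export
length.Peptide <- function(x) nrow(x$residues)

#' Parse a peptide from the extended sequence dialect
#'
#' The dialect encodes stapled-peptide chemistry in one line: uppercase
#' letters are L natural residues, lowercase letters are their D isomers,
#' `{Token}` embeds a registered non-natural residue (`{Nle}`, `{Sar}`,
#' `{Aib}`, `{R8}`, `{S5}`, `{B5}`, `{S8}`), an optional `Ac-` or `Oct-`
#' prefix sets the N-terminal cap, an optional `-NH2` suffix sets a
#' C-terminal amide, and staples are appended as `|i-j` (with `|i-j*` for a
#' staple whose ring-closing metathesis has not been performed). Positions
#' are 1-based.
#'
#' @param text dialect string, e.g. `"Ac-A{Nle}{R8}TYTGIF{S5}DQVLSVLK{Sar}ee|3-10"`.
#' @param name optional peptide name.
#' @return a `Peptide` object.
#' @seealso [write_sequence()], the inverse.
#' @export
parse_sequence <- function(text, name = "") {
  stopifnot(is.character(text), length(text) == 1)
  parts <- strsplit(trimws(text), "|", fixed = TRUE)[[1]]
  seqpart <- parts[1]
  staple_specs <- parts[-1]

  n_cap <- "free"
  if (startsWith(seqpart, "Ac-")) {
    n_cap <- "acetyl"; seqpart <- substring(seqpart, 4)
  } else if (startsWith(seqpart, "Oct-")) {
    n_cap <- "octanoyl"; seqpart <- substring(seqpart, 5)
  }
  c_cap <- "free_acid"
  if (endsWith(seqpart, "-NH2")) {
    c_cap <- "amide"; seqpart <- substring(seqpart, 1, nchar(seqpart) - 4)
  }

  toks <- regmatches(seqpart,
                     gregexpr("\\{[A-Za-z0-9]+\\}|[A-Za-z]|.",
                              seqpart))[[1]]
  if (!length(toks)) stop("empty sequence", call. = FALSE)

  codes <- character(length(toks))
  stereo <- character(length(toks))
  for (k in seq_along(toks)) {
    tk <- toks[k]
    if (startsWith(tk, "{")) {
      code <- substring(tk, 2, nchar(tk) - 1)
      if (!code %in% .residue_defs$code || .residue_defs[code, "natural"])
        stop("unknown residue token: {", code, "}", call. = FALSE)
      codes[k] <- code
      stereo[k] <- if (.residue_defs[code, "achiral"]) "achiral" else "L"
    } else if (grepl("^[A-Z]$", tk)) {
      codes[k] <- tk
      stereo[k] <- if (identical(tk, "G")) "achiral" else "L"
    } else if (grepl("^[a-z]$", tk)) {
      up <- toupper(tk)
      if (identical(up, "G"))
        stop("glycine is achiral; lowercase 'g' is not a valid D residue",
             call. = FALSE)
      codes[k] <- up
      stereo[k] <- "D"
    } else {
      stop("unknown residue token: ", tk, call. = FALSE)
    }
  }
  if (any(!codes %in% .residue_defs$code)) {
    bad <- codes[!codes %in% .residue_defs$code][1]
    stop("unknown residue token: ", bad, call. = FALSE)
  }
  info <- residue_info(codes)
  residues <- data.frame(code = codes, stereo = stereo,
                         n_methyl = info$n_methyl_default,
                         stringsAsFactors = FALSE)

  staples <- NULL
  if (length(staple_specs)) {
    mm <- regmatches(staple_specs,
                     regexec("^([0-9]+)-([0-9]+)(\\*?)$", staple_specs))
    bad <- vapply(mm, length, 0L) == 0
    if (any(bad))
      stop("malformed staple annotation: |", staple_specs[bad][1],
           call. = FALSE)
    staples <- data.frame(
      i = vapply(mm, function(x) as.integer(x[2]), 0L),
      j = vapply(mm, function(x) as.integer(x[3]), 0L),
      span_class = NA_character_,
      closed = !vapply(mm, function(x) nzchar(x[4]), TRUE),
      stringsAsFactors = FALSE)
  }
  classify_staples(new_peptide(residues, staples, n_cap, c_cap, name))
}

#' Serialize a peptide to the sequence dialect
#'
#' Inverse of [parse_sequence()]: `parse_sequence(write_sequence(p))`
#' reproduces `p` field by field.
#'
#' @param p a `Peptide`.
#' @return dialect string.
#' @export
write_sequence <- function(p) {
  stopifnot(inherits(p, "Peptide"))
  r <- p$residues
  info <- residue_info(r$code)
  toks <- ifelse(info$natural,
                 ifelse(r$stereo == "D", tolower(r$code), r$code),
                 paste0("{", r$code, "}"))
  out <- paste(toks, collapse = "")
  if (p$n_cap == "acetyl") out <- paste0("Ac-", out)
  if (p$n_cap == "octanoyl") out <- paste0("Oct-", out)
  if (p$c_cap == "amide") out <- paste0(out, "-NH2")
  if (nrow(p$staples)) {
    s <- p$staples
    out <- paste0(out, paste0("|", s$i, "-", s$j,
                              ifelse(s$closed, "", "*"), collapse = ""))
  }
  out
}

## ---- modification directives -------------------------------------------

#' Peptide edit directives
#'
#' Constructors for the directives consumed by [apply_modifications()]:
#' substitution, deletion, stereo flip (L/D), backbone N-methylation,
#' terminal capping and staple addition. Each returns a small directive
#' object; `apply_modifications()` applies a list of them left to right and
#' returns a new peptide, leaving the original untouched.
#'
#' @param pos 1-based residue position.
#' @param code replacement residue code (see [residue_table()]).
#' @param stereo stereochemistry of the replacement (ignored for achiral
#'   residues).
#' @param n_cap,c_cap new terminal caps (`NULL` = leave unchanged).
#' @param i,j staple arm positions (`j - i` must be 4 or 7).
#' @param closed whether the staple ring has been closed by metathesis
#'   (affects mass bookkeeping).
#' @return a directive object of class `peptide_mod`.
#' @name peptide_mods
NULL

#' @rdname peptide_mods
#' @export
mod_substitute <- function(pos, code, stereo = "L") {
  structure(list(kind = "substitute", pos = pos, code = code,
                 stereo = stereo), class = "peptide_mod")
}
#' @rdname peptide_mods
#' @export
mod_delete <- function(pos)
  structure(list(kind = "delete", pos = pos), class = "peptide_mod")
#' @rdname peptide_mods
#' @export
mod_stereo_flip <- function(pos)
  structure(list(kind = "stereo_flip", pos = pos), class = "peptide_mod")
#' @rdname peptide_mods
#' @export
mod_n_methylate <- function(pos)
  structure(list(kind = "n_methylate", pos = pos), class = "peptide_mod")
#' @rdname peptide_mods
#' @export
mod_cap <- function(n_cap = NULL, c_cap = NULL)
  structure(list(kind = "cap", n_cap = n_cap, c_cap = c_cap),
            class = "peptide_mod")
#' @rdname peptide_mods
#' @export
mod_add_staple <- function(i, j, closed = TRUE)
  structure(list(kind = "add_staple", i = i, j = j, closed = closed),
            class = "peptide_mod")

#' Apply edit directives to a peptide
#'
#' Applies a list of [peptide_mods] directives in order and returns a new
#' validated `Peptide`; the input is not modified. Deleting a residue
#' renumbers downstream positions (staple arms shift with them; deleting a
#' staple arm itself is an error). A stereo flip on an achiral residue
#' (Gly, Sar, Aib, B5) is an error, as is adding a staple whose arm
#' positions do not carry olefin residues or would exceed a residue's arm
#' capacity (only B5 hosts two arms).
#'
#' @param p a `Peptide`.
#' @param mods list of directives from [peptide_mods] (a single directive is
#'   also accepted).
#' @return modified `Peptide`.
#' @examples
#' p <- parse_sequence("AMSTYTGIFTDQVLSVLKGEE", name = "P8")
#' apply_modifications(p, list(mod_substitute(2, "Nle"), mod_cap(n_cap = "acetyl")))
#' @export
apply_modifications <- function(p, mods) {
  stopifnot(inherits(p, "Peptide"))
  if (inherits(mods, "peptide_mod")) mods <- list(mods)
  for (m in mods) {
    if (!inherits(m, "peptide_mod")) stop("not a peptide_mod directive",
                                          call. = FALSE)
    L <- nrow(p$residues)
    if (!is.null(m$pos) && (m$pos < 1 || m$pos > L))
      stop("directive position ", m$pos, " outside 1..", L, call. = FALSE)
    p <- switch(
      m$kind,
      substitute = {
        info <- residue_info(m$code)
        p$residues$code[m$pos] <- m$code
        p$residues$stereo[m$pos] <- if (info$achiral) "achiral" else m$stereo
        p$residues$n_methyl[m$pos] <- info$n_methyl_default
        p
      },
      delete = {
        if (nrow(p$staples) &&
            any(p$staples$i == m$pos | p$staples$j == m$pos))
          stop("cannot delete a staple-arm residue at position ", m$pos,
               call. = FALSE)
        p$residues <- p$residues[-m$pos, , drop = FALSE]
        rownames(p$residues) <- NULL
        if (nrow(p$staples)) {
          p$staples$i <- p$staples$i - (p$staples$i > m$pos)
          p$staples$j <- p$staples$j - (p$staples$j > m$pos)
        }
        p
      },
      stereo_flip = {
        st <- p$residues$stereo[m$pos]
        if (st == "achiral")
          stop("cannot stereo-flip achiral residue at position ", m$pos,
               call. = FALSE)
        p$residues$stereo[m$pos] <- if (st == "L") "D" else "L"
        p
      },
      n_methylate = {
        p$residues$n_methyl[m$pos] <- TRUE
        p
      },
      cap = {
        if (!is.null(m$n_cap)) p$n_cap <- m$n_cap
        if (!is.null(m$c_cap)) p$c_cap <- m$c_cap
        p
      },
      add_staple = {
        p$staples <- rbind(p$staples,
                           data.frame(i = m$i, j = m$j,
                                      span_class = NA_character_,
                                      closed = m$closed,
                                      stringsAsFactors = FALSE))
        p
      },
      stop("unknown directive kind: ", m$kind, call. = FALSE))
    p <- classify_staples(validate_peptide(p))
  }
  p
}

#' Peptide mass
#'
#' Sum of registered residue masses plus one water, plus cap deltas (acetyl
#' `+C2H2O`, octanoyl `+C8H14O`, C-terminal amide `-O+NH`), plus `+CH2` for
#' each N-methylated backbone amide that the residue formula does not
#' already include, minus one ethene (`C2H4`) per closed staple -- the
#' stoichiometry of ring-closing metathesis. A stitched peptide (two closed
#' segments sharing a B5 hub) therefore loses two ethenes.
#'
#' @param p a `Peptide`.
#' @param kind `"monoisotopic"` or `"average"`.
#' @return mass in Da.
#' @export
peptide_mass <- function(p, kind = c("monoisotopic", "average")) {
  stopifnot(inherits(p, "Peptide"))
  kind <- match.arg(kind)
  if (nrow(p$residues) == 0) stop("empty peptide", call. = FALSE)
  k <- .mass_const(kind)
  info <- residue_info(p$residues$code)
  mass <- sum(info[[paste0(kind, "_mass")]]) + k$water
  extra_nme <- sum(p$residues$n_methyl & !info$n_methyl_default)
  mass <- mass + extra_nme * k$n_methyl
  mass <- mass + switch(p$n_cap, free = 0, acetyl = k$acetyl,
                        octanoyl = k$octanoyl)
  mass <- mass + switch(p$c_cap, free_acid = 0, amide = k$amide)
  if (nrow(p$staples)) mass <- mass - sum(p$staples$closed) * k$ethene
  mass
}
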