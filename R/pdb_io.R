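#' Read a PDB-format structure
#'
#' Accepts either a file path or raw PDB text.  One frame is produced per
#' MODEL block (a single frame when there are no MODEL records).  Elements
#' are taken from columns 77-78 when present and otherwise inferred from the
#' atom-name field.  Parsing is delegated to \pkg{bio3d}.
#'
#' @param path_or_text Path to a PDB file, or a character scalar/vector of
#'   PDB-format text.
#' @return A [structure3d()].
#' @export
read_pdb <- function(path_or_text) {
  src <- path_or_text
  is_text <- length(src) > 1L || grepl("\n", src[1]) || !file.exists(src[1])
  if (is_text) {
    lines <- unlist(strsplit(src, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  } else {
    path <- src
    lines <- readLines(path, warn = FALSE)
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    bad <- if (length(lines)) lines[1] else "<empty input>"
    stop("no ATOM/HETATM records found; first line was: ", sQuote(bad))
  }
  multi <- any(grepl("^MODEL", lines))
  p <- suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE))
  ele <- p$atom$elesy
  blank <- is.na(ele) | !nzchar(trimws(ele))
  if (any(blank)) {
    inferred <- suppressWarnings(bio3d::atom2ele(p, rescue = TRUE))
    ele[blank] <- inferred[blank]
  }
  ele <- toupper(trimws(ele))
  chain <- p$atom$chain
  chain[is.na(chain)] <- " "
  base <- data.frame(
    serial = as.integer(p$atom$eleno),
    element = ele,
    x = 0, y = 0, z = 0,
    chain_id = chain,
    residue_name = trimws(p$atom$resid),
    residue_number = as.integer(p$atom$resno),
    is_hetero = p$atom$type == "HETATM",
    stringsAsFactors = FALSE
  )
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    at <- base
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
    at
  })
  structure3d(frames, title = if (is_text) "" else basename(src))
}

#' Write a structure as PDB-format text
#'
#' Emits standard fixed-column ATOM/HETATM records with the element symbol
#' in columns 77-78; multi-frame structures are wrapped in MODEL/ENDMDL
#' blocks.  Coordinates are written to 3 decimals.
#'
#' @param s A [structure3d()].
#' @param path Optional output file; when `NULL` the text is returned
#'   invisibly as a character vector.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(s, path = NULL) {
  stopifnot(inherits(s, "structure3d"))
  multi <- n_frames(s) > 1L
  out <- character(0)
  for (m in seq_len(n_frames(s))) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    at <- s$frames[[m]]
    name <- ifelse(nchar(at$element) >= 2L,
                   sprintf("%-4s", substr(at$element, 1, 2)),
                   sprintf(" %-3s", at$element))
    out <- c(out, sprintf(
      "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(at$is_hetero, "HETATM", "ATOM"),
      at$serial %% 100000L, name, at$residue_name, at$chain_id,
      at$residue_number %% 10000L, at$x, at$y, at$z, 1, 0,
      substr(at$element, 1, 2)))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
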