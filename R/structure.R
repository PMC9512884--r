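#' Molecular structure container
#'
#' A `structure3d` holds one or more frames (models) of the same molecule.
#' Each frame is a data frame of atoms with columns `serial`, `element`,
#' `x`, `y`, `z` (Angstrom), `chain_id`, `residue_name`, `residue_number`
#' and `is_hetero`.
#'
#' @param frames List of atom data frames (one per model/frame).
#' @param title Free-text title.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(frames, title = "") {
  if (!is.list(frames) || length(frames) < 1L)
    stop("a structure needs at least one frame")
  frames <- lapply(frames, validate_atoms)
  s <- list(frames = frames, title = title)
  class(s) <- "structure3d"
  s
}

atom_columns <- c("serial", "element", "x", "y", "z",
                  "chain_id", "residue_name", "residue_number", "is_hetero")

validate_atoms <- function(at) {
  if (!is.data.frame(at) || nrow(at) < 1L)
    stop("every frame must contain at least one atom")
  missing <- setdiff(atom_columns, names(at))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (any(!nzchar(at$element)))
    stop("atoms with empty element symbol")
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite atom coordinates")
  at[atom_columns]
}

#' @export
print.structure3d <- function(x, ...) {
  nf <- length(x$frames)
  cat(sprintf("<structure3d> %d frame%s, %d atoms%s\n",
              nf, if (nf == 1L) "" else "s", nrow(x$frames[[1L]]),
              if (nzchar(x$title)) paste0(" | ", x$title) else ""))
  invisible(x)
}

#' Number of frames / atoms
#' @param s A [structure3d()].
#' @return Integer count.
#' @export
n_frames <- function(s) length(s$frames)

#' @rdname n_frames
#' @export
n_atoms <- function(s) nrow(s$frames[[1L]])

water_residues <- c("HOH", "WAT", "DOD")

#' Filter atoms of a structure
#'
#' Applies the same filters to every frame and returns a new structure.
#' Waters are recognised by residue name (HOH, WAT, DOD); hydrogens by
#' element H or D.
#'
#' @param s A [structure3d()].
#' @param drop_waters Remove water molecules.
#' @param drop_hydrogens Remove hydrogen (and deuterium) atoms.
#' @param keep_chains Optional character vector of chain identifiers to keep.
#' @param drop_hetero Remove HETATM records (waters included).
#' @return A filtered [structure3d()].  Filtering everything away is an
#'   error.
#' @export
edit_structure <- function(s, drop_waters = FALSE, drop_hydrogens = FALSE,
                           keep_chains = NULL, drop_hetero = FALSE) {
  stopifnot(inherits(s, "structure3d"))
  pick <- function(at) {
    keep <- rep(TRUE, nrow(at))
    if (drop_waters)    keep <- keep & !(toupper(at$residue_name) %in% water_residues)
    if (drop_hydrogens) keep <- keep & !(toupper(at$element) %in% c("H", "D"))
    if (!is.null(keep_chains)) keep <- keep & at$chain_id %in% keep_chains
    if (drop_hetero)    keep <- keep & !at$is_hetero
    keep
  }
  frames <- lapply(s$frames, function(at) {
    keep <- pick(at)
    if (!any(keep)) stop("empty structure: filters removed every atom")
    at[keep, , drop = FALSE]
  })
  frames <- lapply(frames, function(at) { rownames(at) <- NULL; at })
  structure3d(frames, title = s$title)
}

#' Deterministic synthetic protein-like fixture
#'
#' Generates a small pseudo-protein for tests and corpus building: a
#' self-avoiding CA backbone with ~3.8 A spacing, decorated per residue with
#' backbone N, C and O atoms at plausible bond distances, optional hydrogens
#' and optional water oxygens.  Multi-frame output applies a smooth
#' per-frame sinusoidal perturbation to every coordinate, emulating a short
#' trajectory.  Coordinates are rounded to 3 decimals so the structure
#' round-trips exactly through PDB text.
#'
#' @param n_residues Number of residues (>= 1).
#' @param seed Integer seed; the result is a deterministic function of it.
#' @param with_hydrogens Add one H per backbone N.
#' @param with_waters Add scattered water oxygens (HETATM/HOH).
#' @param n_frames Number of trajectory frames (>= 1).
#' @return A [structure3d()].
#' @export
make_fixture <- function(n_residues, seed = 1L, with_hydrogens = FALSE,
                         with_waters = FALSE, n_frames = 1L) {
  stopifnot(n_residues >= 1L, n_frames >= 1L)
  with_seed(seed, {
    ca <- matrix(0, n_residues, 3)
    dir <- c(1, 0, 0)
    for (i in seq_len(n_residues)[-1]) {
      for (try in 1:50) {
        ang <- stats::runif(2, -pi, pi)
        cand <- dir + 0.9 * c(cos(ang[1]) * cos(ang[2]),
                              sin(ang[1]) * cos(ang[2]),
                              sin(ang[2]))
        cand <- cand / sqrt(sum(cand^2))
        pos <- ca[i - 1L, ] + 3.8 * cand
        d2 <- if (i > 2L) min(colSums((t(ca[1:(i - 2L), , drop = FALSE]) - pos)^2)) else Inf
        if (d2 > 3.5^2) { dir <- cand; ca[i, ] <- pos; break }
        if (try == 50L) { dir <- cand; ca[i, ] <- pos }  # accept rather than loop forever
      }
    }
    res_names <- rep(c("ALA", "GLY", "SER", "VAL", "THR"), length.out = n_residues)
    rows <- list()
    add <- function(el, pos, resno, resnm, het = FALSE) {
      rows[[length(rows) + 1L]] <<- data.frame(
        serial = 0L, element = el, x = pos[1], y = pos[2], z = pos[3],
        chain_id = "A", residue_name = resnm, residue_number = resno,
        is_hetero = het, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_residues)) {
      u <- rand_unit(); v <- rand_unit()
      add("N", ca[i, ] + 1.45 * u, i, res_names[i])
      add("C", ca[i, ], i, res_names[i])
      add("C", ca[i, ] + 1.52 * v, i, res_names[i])
      add("O", ca[i, ] + 1.52 * v + 1.23 * rand_unit(), i, res_names[i])
      if (with_hydrogens)
        add("H", ca[i, ] + 1.45 * u + 1.01 * rand_unit(), i, res_names[i])
    }
    if (with_waters) {
      nw <- max(1L, n_residues %/% 3L)
      ctr <- colMeans(ca)
      span <- max(3, max(sqrt(colSums((t(ca) - ctr)^2))))
      for (w in seq_len(nw))
        add("O", ctr + (span + 2.5) * rand_unit(), n_residues + w, "HOH", het = TRUE)
    }
    at <- do.call(rbind, rows)
    at$serial <- seq_len(nrow(at))
    # smooth pseudo-trajectory: per-atom sinusoidal displacement
    phase <- stats::runif(nrow(at), 0, 2 * pi)
    wig <- matrix(stats::rnorm(nrow(at) * 3), ncol = 3)
    wig <- wig / sqrt(rowSums(wig^2))
    frames <- lapply(seq_len(n_frames), function(t) {
      a <- at
      if (n_frames > 1L) {
        amp <- 0.6 * sin(2 * pi * (t - 1) / n_frames + phase)
        a$x <- a$x + amp * wig[, 1]
        a$y <- a$y + amp * wig[, 2]
        a$z <- a$z + amp * wig[, 3]
      }
      a$x <- round(a$x, 3); a$y <- round(a$y, 3); a$z <- round(a$z, 3)
      a
    })
    structure3d(frames, title = sprintf("synthetic fixture (%d residues, seed %d)",
                                        n_residues, as.integer(seed)))
  })
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
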