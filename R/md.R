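#' Frames-by-residues contact matrix container
#'
#' @param contacts logical matrix, frames x residues.
#' @param residue_ids unique, ordered residue identifiers.
#' @param cutoff heavy-atom distance cutoff in Angstrom (> 0).
#' @param stride_ps frame stride in picoseconds (metadata).
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix_obj <- function(contacts, residue_ids,
                               cutoff = 6.0, stride_ps = NA_real_) {
  stopifnot(is.matrix(contacts), is.logical(contacts), cutoff > 0,
            ncol(contacts) == length(residue_ids),
            !anyDuplicated(residue_ids), !is.unsorted(residue_ids))
  structure(list(contacts = contacts, residue_ids = residue_ids,
                 cutoff = cutoff, stride_ps = stride_ps),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d frames x %d residues (cutoff %.1f A)\n",
              nrow(x$contacts), ncol(x$contacts), x$cutoff))
  invisible(x)
}

#' Read a topology into an atom table
#'
#' Accepts a PDB file path (parsed with bio3d) or a ready-made data frame
#' with columns `resno`, `resname`, `name`, `element`. Hydrogens are
#' identified by the element field when present, otherwise by the first
#' alphabetic character of the atom name (PDB dialect fallback).
#'
#' @param topology PDB path or atom data frame.
#' @return data frame with columns `atom`, `name`, `element`, `resno`,
#'   `resname`, `is_h`.
#' @export
read_topology <- function(topology) {
  if (is.character(topology)) {
    pdb <- bio3d::read.pdb(topology)
    at <- pdb$atom
    top <- data.frame(atom = seq_len(nrow(at)), name = at$elety,
                      element = at$elesy, resno = at$resno,
                      resname = at$resid, stringsAsFactors = FALSE)
  } else {
    top <- as.data.frame(topology)
    stopifnot(all(c("resno", "resname", "name") %in% names(top)))
    if (is.null(top$element)) top$element <- NA_character_
    top$atom <- seq_len(nrow(top))
  }
  el <- toupper(trimws(top$element))
  fallback <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                  gsub("^[0-9]+", "", top$name)), 1, 1))
  el[is.na(el) | el == ""] <- fallback[is.na(el) | el == ""]
  top$element <- el
  top$is_h <- el %in% c("H", "D")
  top
}

#' Read trajectory frames into a (frames, atoms, 3) coordinate array
#'
#' Accepts a plain-text table `frame,atom,x,y,z` (CSV, Angstrom), a DCD
#' file (read with bio3d), a data frame in the same long format, or a
#' ready-made 3-d array.
#'
#' @param frames path, data frame or array.
#' @param n_atoms expected atom count (checked).
#' @return numeric array `(n_frames, n_atoms, 3)` in Angstrom.
#' @export
read_frames <- function(frames, n_atoms = NULL) {
  if (is.character(frames)) {
    if (grepl("\\.dcd$", frames, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(frames)
      nf <- nrow(xyz); na <- ncol(xyz) / 3L
      arr <- array(NA_real_, c(nf, na, 3L))
      for (d in 1:3) arr[, , d] <- xyz[, seq(d, ncol(xyz), by = 3L)]
      frames <- arr
    } else {
      frames <- utils::read.csv(frames)
    }
  }
  if (is.data.frame(frames)) {
    stopifnot(all(c("frame", "atom", "x", "y", "z") %in% names(frames)))
    fids <- sort(unique(frames$frame))
    na <- length(unique(frames$atom))
    arr <- array(NA_real_, c(length(fids), na, 3L))
    o <- order(frames$frame, frames$atom)
    fr <- frames[o, ]
    arr[, , 1] <- matrix(fr$x, ncol = na, byrow = TRUE)
    arr[, , 2] <- matrix(fr$y, ncol = na, byrow = TRUE)
    arr[, , 3] <- matrix(fr$z, ncol = na, byrow = TRUE)
    frames <- arr
  }
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3L] == 3L)
  if (!is.null(n_atoms) && dim(frames)[2L] != n_atoms)
    stop("frames/topology atom-count mismatch: trajectory has ",
         dim(frames)[2L], " atoms, topology ", n_atoms)
  frames
}

#' Ligand-residue heavy-atom contact matrix from a trajectory
#'
#' For every frame and protein residue, records a contact when at least
#' one heavy (non-hydrogen) atom of that residue lies within `cutoff`
#' (inclusive) of any ligand heavy atom. Minimum-image periodic distances
#' are used when `box` is supplied.
#'
#' @param topology PDB path or atom data frame (see [read_topology()]).
#' @param frames trajectory (see [read_frames()]).
#' @param ligand residue name identifying the ligand (e.g. `"LIG"`).
#' @param cutoff contact distance cutoff, Angstrom (default 6.0).
#' @param box optional length-3 box vector in Angstrom for minimum-image
#'   wrapping.
#' @param stride_ps frame stride metadata, ps.
#' @return a `contact_matrix` (see [contact_matrix_obj()]).
#' @export
contact_matrix <- function(topology, frames, ligand = "LIG", cutoff = 6.0,
                           box = NULL, stride_ps = NA_real_) {
  top <- read_topology(topology)
  lig_idx <- which(top$resname == ligand & !top$is_h)
  if (length(lig_idx) == 0) stop("empty ligand selection: no heavy atoms ",
                                 "with resname '", ligand, "'")
  prot <- top[top$resname != ligand & !top$is_h, ]
  if (nrow(prot) == 0) stop("no protein heavy atoms in topology")
  coords <- read_frames(frames, n_atoms = nrow(top))
  resids <- sort(unique(prot$resno))
  nf <- dim(coords)[1L]
  contacts <- matrix(FALSE, nf, length(resids))
  prot_by_res <- split(prot$atom, factor(prot$resno, levels = resids))
  for (f in seq_len(nf)) {
    lig_xyz <- coords[f, lig_idx, , drop = FALSE]
    dim(lig_xyz) <- c(length(lig_idx), 3L)
    prot_xyz <- coords[f, prot$atom, , drop = FALSE]
    dim(prot_xyz) <- c(nrow(prot), 3L)
    # all protein-heavy x ligand-heavy squared distances
    d2 <- matrix(0, nrow(prot), length(lig_idx))
    for (d in 1:3) {
      diff <- outer(prot_xyz[, d], lig_xyz[, d], "-")
      if (!is.null(box)) diff <- diff - box[d] * round(diff / box[d])
      d2 <- d2 + diff^2
    }
    atom_hit <- apply(d2 <= cutoff^2, 1L, any)
    hits <- vapply(prot_by_res, function(idx)
      any(atom_hit[match(idx, prot$atom)]), logical(1))
    contacts[f, ] <- hits
  }
  contact_matrix_obj(contacts, residue_ids = resids, cutoff = cutoff,
                     stride_ps = stride_ps)
}

#' Flyvbjerg-Petersen blocking analysis of a time series
#'
#' Estimates the standard error of the mean of a (possibly autocorrelated)
#' series by successive pairwise block-averaging. At each level the naive
#' s.e. is \eqn{\sqrt{c_0 / (n - 1)}} with \eqn{c_0} the population
#' variance of the n block means; the reported s.e. is the plateau value:
#' the first level at which the increase to the next level is within the
#' uncertainty of the s.e. estimate itself. If no plateau is found, the
#' conservative fallback is the maximum s.e. over levels retaining at
#' least 32 blocks.
#'
#' @param series numeric or logical vector, length >= 16.
#' @return list with `se` (the plateau s.e.), `level` (the chosen
#'   blocking level, 0 = raw series) and `curve` (data frame `level`,
#'   `n_blocks`, `se`, `se_sd`).
#' @export
blocking_se <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 16) stop("blocking analysis needs at least 16 points")
  levels <- list()
  lev <- 0L
  repeat {
    nn <- length(x)
    if (nn < 2L) break
    c0 <- mean((x - mean(x))^2)
    se <- sqrt(c0 / (nn - 1))
    se_sd <- se / sqrt(2 * (nn - 1))
    levels[[lev + 1L]] <- c(level = lev, n_blocks = nn, se = se,
                            se_sd = se_sd)
    if (nn < 4L) break
    m <- nn %/% 2L
    x <- (x[seq(1L, 2L * m, by = 2L)] + x[seq(2L, 2L * m, by = 2L)]) / 2
    lev <- lev + 1L
  }
  curve <- as.data.frame(do.call(rbind, levels))
  chosen <- NA_integer_
  for (k in seq_len(nrow(curve) - 1L)) {
    inc <- curve$se[k + 1L] - curve$se[k]
    if (inc <= curve$se_sd[k + 1L]) { chosen <- k; break }
  }
  if (is.na(chosen)) {
    elig <- which(curve$n_blocks >= 32)
    chosen <- if (length(elig)) elig[which.max(curve$se[elig])]
      else which.max(curve$se)
  }
  list(se = curve$se[chosen], level = curve$level[chosen], curve = curve)
}

#' Per-residue contact probabilities and bound fraction
#'
#' Column means of the contact matrix give per-residue contact
#' probabilities; the bound fraction fB is the fraction of frames with at
#' least one contact. Standard errors come from blocking analysis of the
#' corresponding indicator series, so autocorrelation between frames is
#' accounted for.
#'
#' @param cm a `contact_matrix`.
#' @return an object of class `contact_summary` with `per_residue`
#'   (data frame `resno`, `p`, `se`), `fB`, `fB_se` and `n_frames`.
#' @export
contact_summary <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  nf <- nrow(cm$contacts)
  if (nf < 16) stop("need at least 16 frames for blocking errors")
  p <- colMeans(cm$contacts)
  se <- vapply(seq_len(ncol(cm$contacts)), function(j)
    blocking_se(cm$contacts[, j])$se, numeric(1))
  bound <- rowSums(cm$contacts) > 0
  fB <- mean(bound)
  fB_se <- blocking_se(bound)$se
  structure(list(
    per_residue = data.frame(resno = cm$residue_ids, p = p, se = se),
    fB = fB, fB_se = fB_se, n_frames = nf), class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf("Contact summary over %d frames: fB = %.4f +/- %.4f\n",
              x$n_frames, x$fB, x$fB_se))
  cat("Top residues by contact probability:\n")
  pr <- x$per_residue[order(-x$per_residue$p), ]
  print(utils::head(pr, 5), row.names = FALSE)
  invisible(x)
}

.avogadro <- 6.02214076e23

#' Simulated dissociation constant from a single-pair bound fraction
#'
#' For one protein and one ligand in a closed cubic box of side L, the
#' reference concentration is \eqn{C_0 = 1/(N_A L^3)} and mass action
#' gives \eqn{K_D = C_0 (1 - f_B)^2 / f_B}, since the free protein and
#' ligand concentrations are both \eqn{(1 - f_B) C_0} and the complex is
#' \eqn{f_B C_0}. The s.e. is propagated by the delta method:
#' \eqn{|dK_D/df_B| = C_0 (1 - f_B)(1 + f_B)/f_B^2}.
#'
#' @param fB bound fraction, strictly between 0 and 1.
#' @param se standard error of `fB` (optional).
#' @param box_length cubic box edge in nm (default 7.5).
#' @return an object of class `kd_estimate` with `C0` and `Kd` in molar,
#'   `Kd_se`, `fB` and `box_length`.
#' @export
simulated_kd <- function(fB, se = NA_real_, box_length = 7.5) {
  if (!is.finite(fB) || fB <= 0 || fB >= 1)
    stop("'fB' must lie strictly between 0 and 1")
  V_l <- (box_length * 1e-8)^3  # nm -> dm, volume in litres
  C0 <- 1 / (.avogadro * V_l)
  Kd <- C0 * (1 - fB)^2 / fB
  Kd_se <- if (is.finite(se)) C0 * (1 - fB) * (1 + fB) / fB^2 * se
    else NA_real_
  structure(list(C0 = C0, Kd = Kd, Kd_se = Kd_se, fB = fB, fB_se = se,
                 box_length = box_length), class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Single-pair box: L = %.2f nm, C0 = %.3f mM\n",
              x$box_length, 1e3 * x$C0))
  if (is.na(x$Kd_se)) {
    cat(sprintf("K_D = %.3f mM (fB = %.4f)\n", 1e3 * x$Kd, x$fB))
  } else {
    cat(sprintf("K_D = %.3f +/- %.3f mM (fB = %.4f +/- %.4f)\n",
                1e3 * x$Kd, 1e3 * x$Kd_se, x$fB, x$fB_se))
  }
  invisible(x)
}
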