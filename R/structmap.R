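# Structure utilities: amide N-H vectors, C2-axis alignment of homodimers,
# and per-residue value maps written into the PDB B-factor column.
# File I/O goes through bio3d; internally atoms live in a plain data.frame
# (chain, resno, resid, elety, x, y, z, b, o).

#' Build a structure frame from atomic coordinates
#'
#' A structure frame holds the atom table of a (dimeric) protein, the
#' derived backbone amide N-H unit vectors indexed by chain-qualified
#' residue id ("A:57"), and a report of residues where no vector could be
#' obtained. Residue numbering follows the source file.
#'
#' @param atoms data.frame with columns chain, resno, resid, elety, x, y,
#'   z and optionally b (B-factor) and o (occupancy).
#' @param provenance Source identifier (e.g. a PDB id or file name).
#' @return Object of class `"structure_frame"` with elements `atoms`,
#'   `nh_vectors` (matrix, unit rows), `skipped` (data.frame residue_id,
#'   reason) and `provenance`.
#' @export
structure_frame <- function(atoms, provenance = "unknown") {
  req <- c("chain", "resno", "elety", "x", "y", "z")
  stopifnot(all(req %in% names(atoms)))
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$o)) atoms$o <- 1
  nh <- nh_vectors(atoms)
  structure(list(atoms = atoms, nh_vectors = nh$vectors,
                 skipped = nh$skipped, provenance = provenance),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("structure_frame: %d atoms, %d chains, %d N-H vectors (%s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              nrow(x$nh_vectors), x$provenance))
  if (nrow(x$skipped))
    cat(sprintf("  %d residue(s) without N-H vector\n", nrow(x$skipped)))
  invisible(x)
}

#' Read a PDB file into a structure frame
#'
#' Reads fixed-column PDB through bio3d. When alternate locations are
#' present, the highest-occupancy conformer of each atom is kept and the
#' selection is reported via a message.
#'
#' @param path PDB file.
#' @return A [structure_frame()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(ifelse(is.na(at$o[i]), 1, at$o[i]))]
    }))
    dropped <- nrow(at) - length(keep)
    if (dropped > 0)
      message(dropped, " altloc atom(s) dropped (highest occupancy kept)")
    at <- at[sort(keep), ]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      b = ifelse(is.na(at$b), 0, at$b),
                      o = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  structure_frame(atoms, provenance = basename(path))
}

#' Backbone amide N-H unit vectors
#'
#' For each residue with a backbone N, returns the unit vector from N to
#' the amide hydrogen. When the hydrogen is absent from the file it is
#' constructed in the peptide plane opposite the bisector of the
#' C(i-1)-N and CA-N directions at 1.02 Angstrom. Prolines and chain
#' starts (no preceding carbonyl C) are skipped and reported; residues
#' missing N are reported, never fabricated.
#'
#' @param atoms Atom data.frame (see [structure_frame()]).
#' @return List: `vectors` (matrix with rownames "chain:resno", unit
#'   rows) and `skipped` (data.frame residue_id, reason).
#' @export
nh_vectors <- function(atoms) {
  if (inherits(atoms, "structure_frame")) atoms <- atoms$atoms
  vec <- list(); skip <- list()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, ]
    a <- a[order(a$resno), ]
    for (rn in unique(a$resno)) {
      id <- paste0(ch, ":", rn)
      res <- a[a$resno == rn, ]
      Nrow <- res[res$elety == "N", ][1, ]
      if (is.na(Nrow$x)) { skip[[id]] <- "no backbone N"; next }
      if (res$resid[1] == "PRO") { skip[[id]] <- "proline"; next }
      Hrow <- res[res$elety %in% c("H", "HN", "H1"), ][1, ]
      N <- c(Nrow$x, Nrow$y, Nrow$z)
      if (!is.na(Hrow$x)) {
        v <- c(Hrow$x, Hrow$y, Hrow$z) - N
      } else {
        CArow <- res[res$elety == "CA", ][1, ]
        prev <- a[a$resno == rn - 1 & a$elety == "C", ][1, ]
        if (is.na(CArow$x)) { skip[[id]] <- "no CA"; next }
        if (is.na(prev$x)) { skip[[id]] <- "chain start (no C(i-1))"; next }
        u1 <- unitv(c(prev$x, prev$y, prev$z) - N)
        u2 <- unitv(c(CArow$x, CArow$y, CArow$z) - N)
        v <- -unitv(u1 + u2)
      }
      vec[[id]] <- unitv(v)
    }
  }
  vectors <- if (length(vec)) do.call(rbind, vec)
             else matrix(numeric(0), 0, 3)
  skipped <- if (length(skip))
    data.frame(residue_id = names(skip), reason = unlist(skip),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(residue_id = character(0), reason = character(0))
  list(vectors = vectors, skipped = skipped)
}

unitv <- function(v) v / sqrt(sum(v^2))

# Kabsch superposition: rotation R and translation t with b ~ R a + t.
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- t(sweep(a, 2, ca)) %*% sweep(b, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.vector(R %*% ca)
  pred <- sweep(a %*% t(R), 2, t, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((pred - b)^2))))
}

#' Align the C2 symmetry axis of a homodimer with z
#'
#' Superposes chain A onto chain B (least squares over backbone N, CA, C
#' of shared residues), extracts the rotation axis of the A-to-B
#' transform, and rigidly moves the whole assembly so this axis becomes
#' +z and passes through the origin. For a true C2 dimer the A-to-B
#' rotation angle is 180 degrees; a deviation beyond `max_dev_deg` makes
#' the function refuse unless `force = TRUE`.
#'
#' @param frame A [structure_frame()].
#' @param chain_pair Two chain ids (default first two chains).
#' @param max_dev_deg Tolerated deviation of the rotation angle from 180
#'   degrees (default 15).
#' @param force Proceed despite a larger deviation.
#' @return The transformed [structure_frame()] with attribute `c2_report`
#'   (rmsd of the A-B superposition, rotation angle, deviation from 180,
#'   axis before alignment).
#' @export
align_c2 <- function(frame, chain_pair = NULL, max_dev_deg = 15,
                     force = FALSE) {
  atoms <- frame$atoms
  chains <- unique(atoms$chain)
  if (is.null(chain_pair)) chain_pair <- chains[1:2]
  stopifnot(length(chain_pair) == 2, all(chain_pair %in% chains))
  bb <- c("N", "CA", "C")
  a <- atoms[atoms$chain == chain_pair[1] & atoms$elety %in% bb, ]
  b <- atoms[atoms$chain == chain_pair[2] & atoms$elety %in% bb, ]
  shared <- intersect(unique(a$resno), unique(b$resno))
  if (length(shared) < 3) stop("chains share fewer than 3 residues")
  key <- function(d) d[d$resno %in% shared, ][order(
    d$resno[d$resno %in% shared], match(d$elety[d$resno %in% shared], bb)), ]
  A <- as.matrix(key(a)[, c("x", "y", "z")])
  B <- as.matrix(key(b)[, c("x", "y", "z")])
  stopifnot(nrow(A) == nrow(B))
  fit <- kabsch(A, B)

  angle <- acos(pmin(pmax((sum(diag(fit$R)) - 1) / 2, -1), 1)) * 180 / pi
  dev <- abs(angle - 180)
  if (dev > max_dev_deg && !force)
    stop(sprintf(
      "not C2-symmetric: A->B rotation is %.1f deg (deviation %.1f > %g); %s",
      angle, dev, max_dev_deg, "use force = TRUE to override"))

  # rotation axis: eigenvector of R with eigenvalue +1
  ev <- eigen(fit$R)
  k <- which.min(abs(ev$values - 1))
  u <- Re(ev$vectors[, k]); u <- unitv(u)
  # canonical representative: make the axis point toward +z (ties: +x, +y)
  s <- sign(u[3]); if (s == 0) s <- sign(u[1]); if (s == 0) s <- sign(u[2])
  if (s < 0) u <- -u

  # point on the (screw) axis: minimal-norm solution of (I - R) p = t
  M <- diag(3) - fit$R
  sv <- svd(M)
  dinv <- ifelse(sv$d > 1e-8 * max(sv$d), 1 / sv$d, 0)
  p <- as.vector(sv$v %*% (dinv * (t(sv$u) %*% fit$t)))

  Q <- rotation_to_z(u)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, p) %*% t(Q)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  out <- structure_frame(atoms, provenance = frame$provenance)
  attr(out, "c2_report") <- list(rmsd = fit$rmsd, angle_deg = angle,
                                 deviation_deg = dev, axis = u)
  out
}

# Minimal rotation taking unit vector u onto +z.
rotation_to_z <- function(u) {
  z <- c(0, 0, 1)
  c_ <- sum(u * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # flip about x
  v <- c(u[2] * z[3] - u[3] * z[2],
         u[3] * z[1] - u[1] * z[3],
         u[1] * z[2] - u[2] * z[1])
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Write a per-residue value map into the B-factor column
#'
#' Writes a copy of the structure with a per-residue scalar (S2, Rex,
#' CSP, ...) min-max scaled to [0, 99.99] in the B-factor field, plus a
#' sidecar TSV recording the raw values and the scaling so nothing is
#' lost to the fixed two-decimal PDB column. Residues without a value get
#' B = 0.00 and are listed in the sidecar.
#'
#' @param frame A [structure_frame()].
#' @param values Named numeric vector (names = "chain:resno"), finite.
#' @param path Output PDB path; sidecar goes to `<path>.values.tsv`.
#' @param kind Label of the mapped quantity (required).
#' @param scale_to Upper bound of the scaled range (default 99.99).
#' @return `path`, invisibly.
#' @export
write_value_map <- function(frame, values, path, kind,
                            scale_to = 99.99) {
  if (missing(kind) || is.null(kind)) stop("value kind must be given")
  stopifnot(all(is.finite(values)), !is.null(names(values)))
  atoms <- frame$atoms
  rng <- range(values)
  scaled <- if (diff(rng) > 0) (values - rng[1]) / diff(rng) * scale_to
            else stats::setNames(rep(0, length(values)), names(values))
  id <- paste0(atoms$chain, ":", atoms$resno)
  bcol <- unname(scaled[id])
  missing_ids <- setdiff(unique(id), names(values))
  bcol[is.na(bcol)] <- 0
  round2 <- function(x) floor(x * 100 + 0.5) / 100   # decimal half-up
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = atoms$chain, o = atoms$o, b = round2(bcol))
  side <- data.frame(residue_id = names(values), kind = kind,
                     value = unname(values),
                     b_scaled = round2(unname(scaled)))
  if (length(missing_ids))
    side <- rbind(side, data.frame(residue_id = missing_ids, kind = kind,
                                   value = NA, b_scaled = 0))
  write_tsv_commented(side, paste0(path, ".values.tsv"), c(
    sprintf("value map: %s", kind),
    sprintf("B = (value - %.6g) / %.6g * %.2f (min-max scaling)",
            rng[1], max(diff(rng), 1), scale_to)))
  invisible(path)
}

#' Write a structure frame as a PDB file
#'
#' @param frame A [structure_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path) {
  atoms <- frame$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = atoms$chain, o = atoms$o, b = atoms$b)
  invisible(path)
}
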