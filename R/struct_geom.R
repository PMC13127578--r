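# Selection syntax: comma-separated "chain:start-end" ranges (or "chain:resno",
# or a bare chain id for every residue on it). Atom specs add "@NAME".

parse_ranges <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  lapply(trimws(parts), function(p) {
    m <- regmatches(p, regexec("^([^:@]+)(?::(\\d+)(?:-(\\d+))?)?$", p))[[1]]
    if (!length(m)) stop("cannot parse selection: '", p, "'")
    chain <- m[2]
    from <- if (m[3] == "") NA_integer_ else as.integer(m[3])
    to <- if (m[4] == "") from else as.integer(m[4])
    list(chain = chain, from = from, to = to)
  })
}

# Rows of model$atoms matching a selection, restricted to one atom type.
select_atoms <- function(model, selection, elety = "CA") {
  a <- model$atoms
  hit <- rep(FALSE, nrow(a))
  for (r in parse_ranges(selection)) {
    h <- a$chain == r$chain
    if (!is.na(r$from)) h <- h & a$resno >= r$from & a$resno <= r$to
    hit <- hit | h
  }
  idx <- which(hit & a$elety == elety)
  a[idx, , drop = FALSE]
}

# Calpha coordinate matrix over a selection, keyed by chain:resno,
# restricted to residues present in both models when `other` is given.
ca_matrix <- function(model, selection) {
  sel <- select_atoms(model, selection, "CA")
  if (!nrow(sel)) stop("selection '", selection, "' matches no Calpha atoms in model '",
                       model$model_id, "'")
  m <- as.matrix(sel[, c("x", "y", "z")])
  rownames(m) <- paste0(sel$chain, ":", sel$resno)
  m
}

paired_ca <- function(model_a, model_b, selection) {
  xa <- ca_matrix(model_a, selection)
  xb <- ca_matrix(model_b, selection)
  shared <- intersect(rownames(xa), rownames(xb))
  if (length(shared) < 1L) stop("selection '", selection,
                                "' shares no residues between models")
  list(a = xa[shared, , drop = FALSE], b = xb[shared, , drop = FALSE])
}

# Kabsch: least-squares rigid transform carrying x onto y (n x 3 each).
# Returns rotation R (applied as x %*% t(R)), translation t, rmsd.
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3)
  if (nrow(x) < 3L) stop("need at least 3 point pairs for superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  # collinearity check: rank of the centred cloud
  if (qr(xc)$rank < 2L || qr(yc)$rank < 2L) {
    stop("selection is collinear; superposition is degenerate")
  }
  h <- t(xc) %*% yc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- xc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  list(rotation = rot, translation = as.numeric(cy - cx %*% t(rot)),
       rmsd = rmsd)
}

apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

rotation_angle_deg <- function(rot) {
  tr <- sum(diag(rot))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

rotation_axis <- function(rot, angle_deg) {
  if (angle_deg < 1e-9) return(c(NA_real_, NA_real_, NA_real_))
  v <- c(rot[3, 2] - rot[2, 3], rot[1, 3] - rot[3, 1], rot[2, 1] - rot[1, 2])
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    # angle near 180 degrees: axis from the +1 eigenvector
    ev <- eigen(rot)
    k <- which.min(abs(ev$values - 1))
    v <- Re(ev$vectors[, k]); n <- sqrt(sum(v^2))
  }
  v / n
}

#' Superpose one model onto another over a Calpha selection
#'
#' Least-squares optimal rigid-body fit (Kabsch) of the mobile model's
#' Calpha atoms in `selection` onto the reference model's, e.g. aligning
#' two motor-domain structures on a helix-loop-helix motif before
#' measuring how the rest of the molecule has moved.
#'
#' @param mobile,reference `xlms_model`s sharing residue numbering over the
#'   selection.
#' @param selection Selection string, e.g. `"A:500-520"` or `"A"`.
#' @return List of class `xlms_superposition`: `rotation` (3x3, det +1),
#'   `translation` (Angstrom 3-vector), `rmsd` (Angstrom, over the
#'   selection), `n` (pairs used), `selection`.
#' @export
superpose <- function(mobile, reference, selection) {
  p <- paired_ca(mobile, reference, selection)
  if (nrow(p$a) < 3L) stop("selection resolves to fewer than 3 shared Calpha pairs")
  fit <- kabsch(p$a, p$b)
  structure(c(fit, list(n = nrow(p$a), selection = selection)),
            class = "xlms_superposition")
}

#' Per-residue Calpha deviation between two models
#'
#' After superposing the models on `align_selection`, reports the Calpha
#' displacement of every residue shared between the two models — the
#' per-residue deviation profile used to visualize which segments move
#' (e.g. lever and converter displacement after aligning on the motor).
#'
#' @param model_a,model_b `xlms_model`s with shared numbering.
#' @param align_selection Selection defining the alignment frame.
#' @return `data.frame`: `chain`, `resno`, `deviation` (Angstrom), ordered
#'   by chain then residue number.
#' @export
per_residue_deviation <- function(model_a, model_b, align_selection) {
  sup <- superpose(model_a, model_b, align_selection)
  xa <- ca_matrix(model_a, paste(unique(model_a$atoms$chain), collapse = ","))
  xb <- ca_matrix(model_b, paste(unique(model_b$atoms$chain), collapse = ","))
  shared <- intersect(rownames(xa), rownames(xb))
  if (!length(shared)) stop("models share no residues")
  moved <- apply_transform(xa[shared, , drop = FALSE], sup$rotation,
                           sup$translation)
  dev <- sqrt(rowSums((moved - xb[shared, , drop = FALSE])^2))
  parts <- strsplit(shared, ":", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, character(1), 1L),
    resno = as.integer(vapply(parts, `[`, character(1), 2L)),
    deviation = unname(dev),
    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Rotation angle of a segment between two models
#'
#' The two models are first superposed on `align_selection` (the part held
#' fixed, e.g. the motor body); the optimal rotation then carrying the
#' segment's Calpha set from model A onto model B is computed, and its
#' axis-angle magnitude reported. This is how a lever or converter rotation
#' is quantified: align on the motor, measure the residual rigid rotation
#' of the lever.
#'
#' @param model_a,model_b `xlms_model`s.
#' @param align_selection Selection held fixed (alignment frame).
#' @param segment_selection Selection whose rotation is measured.
#' @return List of class `xlms_rotation`: `angle` (degrees, in [0, 180]),
#'   `axis` (unit 3-vector, `NA` at angle 0), `rmsd_align`,
#'   `rmsd_segment`, selections.
#' @export
segment_rotation_angle <- function(model_a, model_b, align_selection,
                                   segment_selection) {
  sup <- superpose(model_a, model_b, align_selection)
  p <- paired_ca(model_a, model_b, segment_selection)
  if (nrow(p$a) < 3L) stop("segment resolves to fewer than 3 shared Calpha pairs")
  a_aligned <- apply_transform(p$a, sup$rotation, sup$translation)
  fit <- kabsch(a_aligned, p$b)
  angle <- rotation_angle_deg(fit$rotation)
  structure(list(angle = angle,
                 axis = rotation_axis(fit$rotation, angle),
                 rmsd_align = sup$rmsd, rmsd_segment = fit$rmsd,
                 align_selection = align_selection,
                 segment_selection = segment_selection,
                 n_segment = nrow(p$a)),
            class = "xlms_rotation")
}

parse_atom_spec <- function(spec) {
  m <- regmatches(spec, regexec("^([^:@]+):(\\d+)@(\\S+)$", spec))[[1]]
  if (!length(m)) stop("cannot parse atom spec '", spec,
                       "' (expected chain:resno@ATOM)")
  list(chain = m[2], resno = as.integer(m[3]), elety = m[4])
}

#' Distance between two named atoms of a model
#'
#' E.g. the "backdoor" salt-bridge gap between an arginine guanidinium
#' nitrogen and a glutamate carboxylate oxygen:
#' `atom_pair_distance(model, "A:243@NH1", "A:466@OE1")`.
#'
#' @param model `xlms_model`.
#' @param spec_a,spec_b Atom specs `chain:resno@ATOM`.
#' @return Euclidean distance in Angstrom.
#' @export
atom_pair_distance <- function(model, spec_a, spec_b) {
  get1 <- function(spec) {
    s <- parse_atom_spec(spec)
    a <- model$atoms
    hit <- which(a$chain == s$chain & a$resno == s$resno & a$elety == s$elety)
    if (!length(hit)) stop("atom not found in model '", model$model_id,
                           "': ", spec)
    as.numeric(a[hit[1], c("x", "y", "z")])
  }
  p <- get1(spec_a); q <- get1(spec_b)
  sqrt(sum((p - q)^2))
}

#' Polar contacts across an interface
#'
#' Enumerates nitrogen/oxygen atom pairs, one atom from each selection,
#' within a heavy-atom distance cutoff — a geometric proxy for hydrogen
#' bonds and salt bridges across an interface (no angular term; 3.5
#' Angstrom default cutoff).
#'
#' @param model `xlms_model`.
#' @param selection_a,selection_b Disjoint selections.
#' @param cutoff Distance cutoff in Angstrom (default 3.5).
#' @param sidechain_only Drop backbone N/O atoms (default `FALSE`).
#' @return `data.frame`: `chain_a`, `resno_a`, `resid_a`, `atom_a`, same
#'   for b, `distance`; ordered by distance.
#' @export
polar_contacts <- function(model, selection_a, selection_b, cutoff = 3.5,
                           sidechain_only = FALSE) {
  pick <- function(sel) {
    a <- model$atoms
    hit <- rep(FALSE, nrow(a))
    for (r in parse_ranges(sel)) {
      h <- a$chain == r$chain
      if (!is.na(r$from)) h <- h & a$resno >= r$from & a$resno <= r$to
      hit <- hit | h
    }
    a <- a[hit & a$elesy %in% c("N", "O"), , drop = FALSE]
    if (sidechain_only) a <- a[!a$elety %in% c("N", "O", "OXT"), , drop = FALSE]
    if (!nrow(a)) stop("selection '", sel, "' matches no N/O atoms")
    a
  }
  aa <- pick(selection_a)
  bb <- pick(selection_b)
  key <- function(d) paste(d$chain, d$resno, d$elety)
  if (length(intersect(key(aa), key(bb)))) {
    stop("selections overlap; polar_contacts requires disjoint selections")
  }
  ax <- as.matrix(aa[, c("x", "y", "z")])
  bx <- as.matrix(bb[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), `+`) - 2 * (ax %*% t(bx))
  hits <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  out <- data.frame(
    chain_a = aa$chain[hits[, 1]], resno_a = aa$resno[hits[, 1]],
    resid_a = aa$resid[hits[, 1]], atom_a = aa$elety[hits[, 1]],
    chain_b = bb$chain[hits[, 2]], resno_b = bb$resno[hits[, 2]],
    resid_b = bb$resid[hits[, 2]], atom_b = bb$elety[hits[, 2]],
    distance = sqrt(pmax(0, d2[hits])),
    stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Contacts present in one model's interface but not another's
#'
#' Set difference of [polar_contacts()] listings (keyed on residue and
#' atom names), used to report interactions unique to one conformation.
#'
#' @param model_x,model_y `xlms_model`s of the same interface.
#' @param selection_a,selection_b,cutoff Passed to [polar_contacts()].
#' @return Contacts of `model_x` absent from `model_y`.
#' @export
unique_contacts <- function(model_x, model_y, selection_a, selection_b,
                            cutoff = 3.5) {
  cx <- polar_contacts(model_x, selection_a, selection_b, cutoff)
  cy <- polar_contacts(model_y, selection_a, selection_b, cutoff)
  keyf <- function(d) paste(d$chain_a, d$resno_a, d$atom_a,
                            d$chain_b, d$resno_b, d$atom_b)
  cx[!keyf(cx) %in% keyf(cy), , drop = FALSE]
}
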