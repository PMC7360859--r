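## Dihedral featurization, the metadynamics collective variable, centers of
## mass and the relative V-alpha/V-beta interdomain torsion.

#' Torsion (dihedral) angle of four points
#'
#' Right-handed IUPAC sign convention with cis = 0 degrees. Vectorized:
#' each argument may be an n x 3 matrix (row i of each defines quadruple i).
#'
#' @param p1,p2,p3,p4 length-3 vectors or n x 3 matrices, Angstrom.
#' @return angle(s) in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  as3 <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as3(p1); p2 <- as3(p2); p3 <- as3(p3); p4 <- as3(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  nb <- rownorm(b2)
  eps <- 1e-10
  if (any(rownorm(b1) < eps | nb < eps | rownorm(b3) < eps))
    stop("degenerate dihedral geometry: consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (any(rownorm(n1) < eps * rownorm(b1) * nb) ||
      any(rownorm(n2) < eps * nb * rownorm(b3)))
    stop("degenerate dihedral geometry: three consecutive points collinear")
  y <- nb * rowdot(b1, n2)
  x <- rowdot(n1, n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

## Backbone atom index lookup: for each residue of a selection, indices of
## N/CA/C (and the flanking N(i+1), C(i-1) when present in the topology).
backbone_index_table <- function(topology, selection) {
  idx <- resolve_selection(selection, topology)
  key <- paste(topology$chain, topology$resid, topology$icode, sep = "|")
  res_keys <- unique(key[idx])
  find_atom <- function(k, name) {
    j <- which(key == k & topology$atom_name == name)
    if (length(j) == 0) NA_integer_ else j[1]
  }
  tab <- data.frame(key = res_keys,
                    resid = topology$resid[match(res_keys, key)],
                    chain = topology$chain[match(res_keys, key)],
                    stringsAsFactors = FALSE)
  for (nm in c("N", "CA", "C")) tab[[nm]] <- vapply(res_keys, find_atom, 1L, name = nm)
  if (any(is.na(tab$N) | is.na(tab$CA) | is.na(tab$C))) {
    bad <- tab$resid[which(is.na(tab$N) | is.na(tab$CA) | is.na(tab$C))[1]]
    stop("missing backbone atom(s) in residue ", bad, " of selection '",
         selection$name, "'")
  }
  ## flanking residues (same chain, any residue number) located by atom order
  chain_res <- unique(key[topology$chain == tab$chain[1]])
  pos <- match(tab$key, chain_res)
  tab$N_next <- ifelse(pos < length(chain_res),
                       vapply(chain_res[pmin(pos + 1, length(chain_res))],
                              find_atom, 1L, name = "N"), NA_integer_)
  tab$C_prev <- ifelse(pos > 1,
                       vapply(chain_res[pmax(pos - 1, 1)],
                              find_atom, 1L, name = "C"), NA_integer_)
  tab$N_next[pos >= length(chain_res)] <- NA_integer_
  tab$C_prev[pos <= 1] <- NA_integer_
  tab
}

#' Backbone dihedral features with periodic sin/cos embedding
#'
#' For every eligible phi/psi angle of the selected residues, contributes a
#' (sin, cos) feature pair per frame. psi(i) uses N(i), CA(i), C(i), N(i+1);
#' phi(i) uses C(i-1), N(i), CA(i), C(i). Angles whose flanking residue is
#' absent from the topology are skipped (terminal residues).
#'
#' @param traj a `trajectory3d`.
#' @param selections list of `region_selection`s (order defines feature order).
#' @param angles subset of `c("phi", "psi")`.
#' @return a `feature_matrix`: numeric frames x features matrix with
#'   attributes `labels` (text per feature), `angle_deg` (frames x n_angles
#'   matrix of the underlying dihedrals, degrees) and `frame_interval`.
#' @export
psi_phi_features <- function(traj, selections, angles = c("psi", "phi")) {
  stopifnot(inherits(traj, "trajectory3d"))
  angles <- match.arg(angles, c("psi", "phi"), several.ok = TRUE)
  if (inherits(selections, "region_selection")) selections <- list(selections)
  quads <- list(); labels <- character(0)
  for (sel in selections) {
    tab <- backbone_index_table(traj$topology, sel)
    for (i in seq_len(nrow(tab))) {
      if ("phi" %in% angles && !is.na(tab$C_prev[i]))
        { quads[[length(quads) + 1]] <- c(tab$C_prev[i], tab$N[i], tab$CA[i], tab$C[i])
          labels <- c(labels, sprintf("%s:%s%d:phi", sel$name, tab$chain[i], tab$resid[i])) }
      if ("psi" %in% angles && !is.na(tab$N_next[i]))
        { quads[[length(quads) + 1]] <- c(tab$N[i], tab$CA[i], tab$C[i], tab$N_next[i])
          labels <- c(labels, sprintf("%s:%s%d:psi", sel$name, tab$chain[i], tab$resid[i])) }
    }
  }
  if (length(quads) == 0) stop("no eligible dihedrals in the given selections")
  nf <- n_frames(traj)
  ang <- matrix(NA_real_, nf, length(quads))
  for (q in seq_along(quads)) {
    ii <- quads[[q]]
    ang[, q] <- dihedral(t(traj$coords[ii[1], , ]), t(traj$coords[ii[2], , ]),
                         t(traj$coords[ii[3], , ]), t(traj$coords[ii[4], , ]))
  }
  r <- deg2rad(ang)
  vals <- matrix(NA_real_, nf, 2 * length(quads))
  vals[, seq(1, ncol(vals), 2)] <- sin(r)
  vals[, seq(2, ncol(vals), 2)] <- cos(r)
  feat_labels <- as.vector(rbind(paste0(labels, ":sin"), paste0(labels, ":cos")))
  feature_matrix(vals, feat_labels, traj$frame_interval, angle_deg = ang,
                 angle_labels = labels)
}

#' Construct a feature matrix
#'
#' @param values frames x features numeric matrix.
#' @param labels character, one per feature.
#' @param frame_interval ns between frames.
#' @param angle_deg optional underlying dihedrals, degrees.
#' @param angle_labels optional labels of `angle_deg` columns.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, frame_interval = 1,
                           angle_deg = NULL, angle_labels = NULL) {
  values <- as.matrix(values)
  stopifnot(length(labels) == ncol(values))
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  structure(values, labels = as.character(labels),
            frame_interval = as.numeric(frame_interval),
            angle_deg = angle_deg, angle_labels = angle_labels,
            class = c("feature_matrix", "matrix", "array"))
}

feature_labels <- function(fm) attr(fm, "labels")

#' Metadynamics collective variable: linear combination of sin/cos of psi
#'
#' s = sum_i a_i sin(psi_i) + sum_i b_i cos(psi_i) over the psi angles of the
#' selected loops. Default weights are uniform (a_i = b_i = 1).
#'
#' @param features a `feature_matrix` from [psi_phi_features()] containing
#'   psi sin/cos pairs.
#' @param weights_sin,weights_cos numeric, one coefficient per psi angle.
#' @return numeric vector, one CV value per frame.
#' @export
collective_variable <- function(features, weights_sin = NULL, weights_cos = NULL) {
  lab <- feature_labels(features)
  sin_cols <- grep(":psi:sin$", lab)
  cos_cols <- grep(":psi:cos$", lab)
  if (length(sin_cols) == 0) stop("feature matrix carries no psi features")
  k <- length(sin_cols)
  if (is.null(weights_sin)) weights_sin <- rep(1, k)
  if (is.null(weights_cos)) weights_cos <- rep(1, k)
  if (length(weights_sin) != k || length(weights_cos) != k)
    stop("CV weight length (", length(weights_sin), ",", length(weights_cos),
         ") does not match the ", k, " psi angles in the features")
  as.numeric(features[, sin_cols, drop = FALSE] %*% weights_sin +
             features[, cos_cols, drop = FALSE] %*% weights_cos)
}

#' Center of mass of a selection in one coordinate frame
#'
#' @param topology a `structure3d` (supplies masses).
#' @param xyz n_atoms x 3 coordinates of the frame, Angstrom.
#' @param selection a `region_selection`.
#' @param mass_weighted mass-weight (default) or plain mean.
#' @return length-3 numeric position, Angstrom.
#' @export
center_of_mass <- function(topology, xyz, selection, mass_weighted = TRUE) {
  idx <- resolve_selection(selection, topology)
  m <- if (mass_weighted) topology$mass[idx] else rep(1, length(idx))
  tm <- sum(m)
  if (tm <= 0) stop("zero total mass in selection '", selection$name, "'")
  as.numeric(crossprod(xyz[idx, , drop = FALSE], m) / tm)
}

#' Relative interdomain orientation angle
#'
#' Torsion angle through four centers of mass, in order: CDR loops of the
#' alpha (light) chain, V-alpha domain, V-beta domain, CDR loops of the beta
#' (heavy) chain — one angle per frame.
#'
#' @param traj a `trajectory3d`.
#' @param cdr_alpha,v_alpha,v_beta,cdr_beta the four `region_selection`s,
#'   mutually disjoint.
#' @param mass_weighted mass-weight the centers of mass.
#' @return an `angle_series`: numeric vector of degrees in (-180, 180] with
#'   attribute `definition`.
#' @export
interdomain_torsion <- function(traj, cdr_alpha, v_alpha, v_beta, cdr_beta,
                                mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory3d"))
  sels <- list(cdr_alpha, v_alpha, v_beta, cdr_beta)
  top <- traj$topology
  idxs <- lapply(sels, resolve_selection, topology = top)
  for (i in 1:3) for (j in (i + 1):4)
    if (length(intersect(idxs[[i]], idxs[[j]])) > 0)
      stop("interdomain selections must be mutually disjoint ('",
           sels[[i]]$name, "' overlaps '", sels[[j]]$name, "')")
  masses <- lapply(idxs, function(ii)
    if (mass_weighted) top$mass[ii] else rep(1, length(ii)))
  nf <- n_frames(traj)
  coms <- lapply(1:4, function(k) {
    ii <- idxs[[k]]; m <- masses[[k]] / sum(masses[[k]])
    ## frames x 3 COM track
    t(apply(traj$coords[ii, , , drop = FALSE], 3, function(fr)
      crossprod(matrix(fr, ncol = 3), m)))
  })
  b1 <- coms[[2]] - coms[[1]]; b2 <- coms[[3]] - coms[[2]]; b3 <- coms[[4]] - coms[[3]]
  bad <- which(rownorm(b1) < 1e-10 | rownorm(b2) < 1e-10 | rownorm(b3) < 1e-10 |
               rownorm(cross3(b1, b2)) < 1e-10 | rownorm(cross3(b2, b3)) < 1e-10)
  if (length(bad))
    stop("degenerate COM geometry at frame ", bad[1])
  vals <- dihedral(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
  structure(vals, definition = vapply(sels, function(s) s$name, ""),
            class = c("angle_series", "numeric"))
}

#' Export a feature matrix or angle series as CSV
#'
#' @param x a `feature_matrix` or `angle_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  if (inherits(x, "feature_matrix")) {
    df <- as.data.frame(unclass(x))
    names(df) <- feature_labels(x)
  } else if (inherits(x, "angle_series")) {
    df <- data.frame(frame = seq_along(x), angle_deg = as.numeric(x))
  } else df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
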