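#' Ideal alpha-helix parameters
#'
#' Defaults are the textbook ideal alpha helix: 1.5 Angstrom rise and 100
#' degrees twist per residue (3.6 residues/turn), C-alpha cylinder radius
#' 2.3 Angstrom.
#'
#' @param rise axial rise per residue, Angstrom.
#' @param twist rotation per residue, degrees.
#' @param ca_radius C-alpha distance from the helix axis, Angstrom.
#' @return object of class `helix_params`.
#' @export
helix_params <- function(rise = 1.5, twist = 100, ca_radius = 2.3) {
  if (rise <= 0) stop("rise must be positive")
  if (twist <= 0 || twist > 180) stop("twist must lie in (0, 180] degrees")
  structure(list(rise = rise, twist = twist, ca_radius = ca_radius),
            class = "helix_params")
}

# cylindrical offsets of backbone atoms relative to the C-alpha position
# (radius, phase offset in degrees at 100 deg/res, axial offset at 1.5 A/res);
# phases and axial offsets scale with the requested twist and rise
HELIX_ATOM_TEMPLATE <- list(
  N  = c(r = 1.56, dphi = -28.9, dz = -0.92),
  CA = c(r = NA,   dphi = 0,     dz = 0),
  C  = c(r = 1.86, dphi = 26.3,  dz = 1.06),
  O  = c(r = 2.08, dphi = 18.1,  dz = 2.42))

#' Build an ideal alpha-helix (poly-alanine backbone)
#'
#' C-alpha atoms lie on a cylinder of radius `ca_radius` about the z-axis;
#' successive residues advance by `rise` along the axis and `twist` about
#' it. Backbone N, C and O are placed at fixed cylindrical offsets from
#' each C-alpha; with `cb = TRUE` an ideal C-beta is added from the local
#' backbone frame.
#'
#' @param n number of residues (>= 1).
#' @param params a [helix_params()].
#' @param chain chain id for the generated residues.
#' @param start first residue number.
#' @param cb add C-beta atoms (alanine side chain).
#' @return a [struct3d()] with `n` residues.
#' @export
build_ideal_helix <- function(n, params = helix_params(), chain = "A",
                              start = 1L, cb = FALSE) {
  stopifnot(n >= 1)
  rows <- list()
  serial <- 1L
  phi_scale <- params$twist / 100
  z_scale <- params$rise / 1.5
  for (i in seq_len(n)) {
    phi0 <- (i - 1) * params$twist
    z0 <- (i - 1) * params$rise
    res <- list()
    for (nm in names(HELIX_ATOM_TEMPLATE)) {
      tpl <- HELIX_ATOM_TEMPLATE[[nm]]
      r <- if (nm == "CA") params$ca_radius else tpl[["r"]]
      phi <- (phi0 + tpl[["dphi"]] * phi_scale) * pi / 180
      z <- z0 + tpl[["dz"]] * z_scale
      res[[nm]] <- c(r * cos(phi), r * sin(phi), z)
    }
    if (cb) res$CB <- cbeta_from_backbone(res$N, res$CA, res$C)
    for (nm in names(res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = nm, alt = "", resname = "ALA",
        chain = chain, resno = start + i - 1L, insert = "",
        x = res[[nm]][1], y = res[[nm]][2], z = res[[nm]][3],
        occ = 1, b = 0,
        element = substr(nm, 1, 1), het = FALSE,
        stringsAsFactors = FALSE)
      serial <- serial + 1L
    }
  }
  struct3d(do.call(rbind, rows))
}

#' Ideal C-beta position from backbone N, CA, C
#'
#' Standard local-frame construction giving the L-amino-acid C-beta.
#'
#' @param n,ca,c backbone atom positions (length-3 vectors).
#' @return length-3 C-beta position.
#' @export
cbeta_from_backbone <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

# ---- helix axis fitting ----------------------------------------------------

#' Fit a helix axis to C-alpha coordinates
#'
#' Uses second differences of consecutive C-alpha positions (which point
#' radially toward the axis of an ideal helix); the axis direction is the
#' averaged normal of successive second-difference pairs, oriented N to C.
#' Radius and centre come from a least-squares circle fit of the projected
#' points; rise and twist from the axial spacing and projected rotation.
#'
#' @param s a [struct3d()] (C-alpha atoms of `chain`/`resno` are used) or an
#'   n x 3 matrix of C-alpha coordinates in chain order.
#' @param chain,resno optional selection when `s` is a structure.
#' @return object of class `helix_axis`: `origin`, `direction` (unit,
#'   N-to-C), `rise`, `twist` (degrees), `radius`, `residual` and logical
#'   `nonhelical` (set when the geometry does not resemble a helix).
#' @export
fit_helix_axis <- function(s, chain = NULL, resno = NULL) {
  if (inherits(s, "struct3d")) {
    sub <- select_atoms(s, chain = chain, resno = resno)
    ca <- sub$atoms[sub$atoms$name == "CA", , drop = FALSE]
    ca <- ca[order(ca$resno), , drop = FALSE]
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    range_meta <- list(chain = if (is.null(chain)) unique(ca$chain) else chain,
                       resno = range(ca$resno))
  } else {
    xyz <- as.matrix(s)
    range_meta <- NULL
  }
  n <- nrow(xyz)
  if (n < 5) stop("helix axis fit needs at least 5 C-alpha positions")
  d <- diff(xyz)
  sec <- xyz[3:n, , drop = FALSE] - 2 * xyz[2:(n - 1), , drop = FALSE] +
    xyz[1:(n - 2), , drop = FALSE]
  sec_norm <- sqrt(rowSums(sec^2))
  bad <- structure(list(origin = xyz[1, ], direction = unit3(colMeans(d)),
                        rise = NA_real_, twist = NA_real_, radius = NA_real_,
                        residual = NA_real_, nonhelical = TRUE,
                        range = range_meta, ca = xyz),
                   class = "helix_axis")
  if (max(sec_norm) < 1e-6) return(bad)  # straight line
  m <- nrow(sec)
  axes <- matrix(NA_real_, m - 1, 3)
  for (i in seq_len(m - 1)) {
    cr <- cross3(sec[i, ], sec[i + 1, ])
    ncr <- sqrt(sum(cr^2))
    if (ncr < 1e-9 * sec_norm[i] * sec_norm[i + 1]) next
    axes[i, ] <- cr / ncr
  }
  axes <- axes[stats::complete.cases(axes), , drop = FALSE]
  if (!nrow(axes)) return(bad)
  ref <- axes[1, ]
  flip <- as.numeric(axes %*% ref) < 0
  axes[flip, ] <- -axes[flip, ]
  a <- unit3(colMeans(axes))
  if (sum(colMeans(d) * a) < 0) a <- -a
  # orthonormal in-plane basis (e1, e2, a) right-handed
  e1 <- unit3(cross3(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- cross3(a, e1)
  u <- as.numeric(xyz %*% e1)
  v <- as.numeric(xyz %*% e2)
  fit <- stats::lm.fit(cbind(2 * u, 2 * v, 1), u^2 + v^2)
  c1 <- fit$coefficients[1]; c2 <- fit$coefficients[2]
  rad <- sqrt(pmax((u - c1)^2 + (v - c2)^2, 0))
  radius <- mean(rad)
  residual <- sqrt(mean((rad - radius)^2))
  ang <- atan2(v - c2, u - c1)
  dang <- diff(ang)
  dang <- atan2(sin(dang), cos(dang))  # wrap to (-pi, pi]
  twist <- mean(dang) * 180 / pi
  rise <- mean(as.numeric(d %*% a))
  origin <- c1 * e1 + c2 * e2 + sum(xyz[1, ] * a) * a
  nonhelical <- !is.finite(residual) || residual > 0.25 || radius < 0.5
  structure(list(origin = origin, direction = a, rise = rise, twist = twist,
                 radius = radius, residual = residual,
                 nonhelical = nonhelical, range = range_meta, ca = xyz),
            class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  if (x$nonhelical) {
    cat("helix_axis: flagged non-helical\n")
  } else {
    cat(sprintf("helix_axis: rise %.3f A, twist %.2f deg, radius %.2f A (residual %.3f A)\n",
                x$rise, x$twist, x$radius, x$residual))
  }
  invisible(x)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- shared-helix fusion ---------------------------------------------------

#' Fuse a binder domain onto a host by a shared helix
#'
#' The host's C-terminal anchor helix is extended by `k` ideal residues
#' continuing its fitted axis and phase; the binder is then rigid-body
#' placed by superposing the first `window` C-alphas of its N-terminal
#' anchor helix onto the last `window` residues of the extended helix.
#' Those `window` binder residues coincide with the host/extension copy of
#' the shared helix and are therefore dropped from the fused model, so the
#' shared helix appears exactly once. The rest of the
#' binder's internal geometry is untouched (pure rigid motion). Each
#' increment of `k` rotates the binder by the helical twist about the
#' shared axis, which is how different binder orientations are enumerated.
#'
#' @param host,binder [struct3d()] objects.
#' @param host_anchor,binder_anchor [fit_helix_axis()] results for the host
#'   C-terminal and binder N-terminal anchor helices.
#' @param k number of ideal residues inserted (>= 0).
#' @param params ideal-helix geometry used for the extension.
#' @param window superposition window, residues (about two helical turns).
#' @param force proceed even if an anchor was flagged non-helical.
#' @return object of class `fusion_model`: `structure` (fused model),
#'   `k_inserted`, `rotation_deg`, `transform` (binder rigid motion),
#'   `clash_count`/`clash_pairs` (NA until scored), junction metadata.
#' @export
shared_helix_fuse <- function(host, host_anchor, binder, binder_anchor, k,
                              params = helix_params(), window = 7L,
                              force = FALSE) {
  stopifnot(k >= 0)
  if ((host_anchor$nonhelical || binder_anchor$nonhelical) && !force)
    stop("anchor helix flagged non-helical; pass force = TRUE to override")
  nw <- as.integer(window)
  if (nrow(host_anchor$ca) < nw || nrow(binder_anchor$ca) < nw)
    stop("anchor helices must span at least ", nw, " residues")
  ideal <- build_ideal_helix(nw + k + nw, params = params, cb = TRUE)
  ideal_ca <- coords(select_name(ideal, "CA"))
  host_win <- host_anchor$ca[(nrow(host_anchor$ca) - nw + 1):nrow(host_anchor$ca), ,
                             drop = FALSE]
  t1 <- kabsch(ideal_ca[1:nw, , drop = FALSE], host_win)
  # extension residues (alanine), renumbered after the host anchor
  ext <- NULL
  host_chain <- host_anchor$range$chain[1]
  host_end <- host_anchor$range$resno[2]
  if (k > 0) {
    ext <- select_atoms(ideal, resno = (nw + 1):(nw + k))
    ext_xyz <- transform_xyz(coords(ext), t1)
    ext$atoms$x <- ext_xyz[, 1]; ext$atoms$y <- ext_xyz[, 2]
    ext$atoms$z <- ext_xyz[, 3]
    ext$atoms$chain <- host_chain
    ext$atoms$resno <- host_end + (ext$atoms$resno - nw)
  }
  target_win <- transform_xyz(ideal_ca[(k + 1):(k + nw), , drop = FALSE], t1)
  binder_win <- binder_anchor$ca[1:nw, , drop = FALSE]
  t2 <- kabsch(binder_win, target_win)
  # the shared helix appears once: the binder's superposition-window
  # residues coincide with the host/extension copy and are dropped
  binder_first <- binder_anchor$range$resno[1]
  shared_resno <- binder_first + seq_len(nw) - 1L
  binder_moved <- binder
  binder_moved$atoms <-
    binder_moved$atoms[!(binder_moved$atoms$resno %in% shared_resno), ,
                       drop = FALSE]
  if (!nrow(binder_moved$atoms))
    stop("binder has no residues beyond the superposition window")
  bx <- transform_xyz(coords(binder_moved), t2)
  binder_moved$atoms$x <- bx[, 1]; binder_moved$atoms$y <- bx[, 2]
  binder_moved$atoms$z <- bx[, 3]
  # give the binder a chain id that does not collide with the host
  free <- setdiff(LETTERS, unique(host$atoms$chain))
  binder_chain <- unique(binder_moved$atoms$chain)[1]
  if (binder_chain %in% unique(host$atoms$chain)) {
    binder_chain <- free[1]
    binder_moved$atoms$chain <- binder_chain
  }
  atoms <- rbind(host$atoms,
                 if (!is.null(ext)) ext$atoms,
                 binder_moved$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  fused <- struct3d(atoms, cell = host$cell, space_group = host$space_group,
                    id = paste0(host$id, "_fusion_k", k))
  structure(list(
    structure = fused, k_inserted = as.integer(k),
    rotation_deg = (k * params$twist) %% 360,
    transform = t2, anchor_transform = t1, params = params,
    junction = list(host_chain = host_chain, host_end = host_end,
                    ext_resno = if (k > 0) host_end + seq_len(k) else integer(0),
                    binder_chain = binder_chain,
                    binder_start = binder_first + nw),
    clash_count = NA_integer_, clash_pairs = NULL),
    class = "fusion_model")
}

select_name <- function(s, name) {
  s$atoms <- s$atoms[s$atoms$name %in% name, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

transform_xyz <- function(xyz, tr) {
  sweep(xyz %*% t(tr$rot), 2, tr$trans, "+")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion_model: k = %d (rotation %.0f deg), %d atoms%s\n",
              x$k_inserted, x$rotation_deg, n_atoms(x$structure),
              if (is.na(x$clash_count)) "" else
                sprintf(", %d clashes", x$clash_count)))
  invisible(x)
}

#' Relative binder orientation between two fusion models
#'
#' @param m1,m2 [shared_helix_fuse()] results built from the same binder.
#' @return list with `angle_deg` (relative rotation, \[0, 180\]) and
#'   `translation` (displacement of the binder centroid, Angstrom vector).
#' @export
relative_rotation <- function(m1, m2) {
  r_rel <- m2$transform$rot %*% t(m1$transform$rot)
  ang <- acos(pmin(pmax((sum(diag(r_rel)) - 1) / 2, -1), 1)) * 180 / pi
  b1 <- m1$structure
  b2 <- m2$structure
  cen <- function(m) {
    sel <- select_atoms(m$structure, chain = m$junction$binder_chain)
    colMeans(coords(sel))
  }
  list(angle_deg = ang, translation = cen(m2) - cen(m1))
}

# ---- clash scoring ---------------------------------------------------------

close_pair_count <- function(a, b, cutoff, chunk = 2000L) {
  n <- nrow(a)
  count <- 0L
  pairs <- list()
  bb <- rowSums(b^2)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    aa <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), bb, "+") - 2 * aa %*% t(b)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      hit[, 1] <- hit[, 1] + i - 1L
      pairs[[length(pairs) + 1L]] <-
        cbind(hit, dist = sqrt(pmax(d2[cbind(hit[, 1] - i + 1L, hit[, 2])], 0)))
    }
    i <- j + 1L
  }
  if (length(pairs)) do.call(rbind, pairs) else
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("row", "col", "dist")))
}

#' Count steric clashes of the fused binder against the packed lattice
#'
#' Counts heavy-atom pairs closer than `cutoff` between the moving part of
#' the fusion (extension plus binder) and (i) the host copy and (ii) every
#' symmetry mate of the whole fused molecule. Pairs of residues separated
#' by two or fewer positions along the fused chain (the covalent junction
#' neighbourhood) are not counted.
#'
#' @param model a [shared_helix_fuse()] result.
#' @param context lattice context: `NULL` (use the model's own cell/space
#'   group if present; otherwise only the host copy is considered) or a
#'   list of n x 3 Cartesian matrices of explicit neighbour coordinates.
#' @param cutoff clash distance, Angstrom.
#' @param shift_range lattice shift half-width for mate generation.
#' @return the model with `clash_count` and `clash_pairs` filled in.
#' @export
clash_score <- function(model, context = NULL, cutoff = 3.0,
                        shift_range = 1L) {
  s <- heavy_atoms(model$structure)
  jc <- model$junction
  moving_sel <- (s$atoms$chain == jc$binder_chain) |
    (s$atoms$chain == jc$host_chain & s$atoms$resno %in% jc$ext_resno)
  moving <- s$atoms[moving_sel, , drop = FALSE]
  host_part <- s$atoms[!moving_sel, , drop = FALSE]
  if (!nrow(moving)) stop("fusion model has no moving atoms")
  # linear path position along host chain -> extension -> binder
  path_pos <- function(atoms) {
    pos <- rep(NA_real_, nrow(atoms))
    hostc <- atoms$chain == jc$host_chain
    pos[hostc] <- atoms$resno[hostc]
    bind <- atoms$chain == jc$binder_chain
    n_ext <- length(jc$ext_resno)
    pos[bind] <- jc$host_end + n_ext +
      (atoms$resno[bind] - jc$binder_start + 1)
    pos
  }
  mp <- path_pos(moving)
  hp <- path_pos(host_part)
  hits <- close_pair_count(as.matrix(moving[, c("x", "y", "z")]),
                           as.matrix(host_part[, c("x", "y", "z")]), cutoff)
  if (nrow(hits)) {
    sep <- abs(mp[hits[, 1]] - hp[hits[, 2]])
    hits <- hits[is.na(sep) | sep > 2, , drop = FALSE]
  }
  pairs <- list()
  if (nrow(hits))
    pairs[[1]] <- data.frame(
      moving = moving$serial[hits[, 1]], other = host_part$serial[hits[, 2]],
      mate = "self", dist = hits[, 3], stringsAsFactors = FALSE)
  mxyz <- as.matrix(moving[, c("x", "y", "z")])
  mates <- list()
  if (is.list(context) && !inherits(context, "struct3d")) {
    mates <- context
  } else if (!is.null(s$cell) && !is.null(s$space_group)) {
    nb <- expand_neighbors(s, cutoff = max(cutoff, 4), shift_range = shift_range)
    mates <- lapply(nb, function(x) x$xyz)
    names(mates) <- vapply(nb, function(x)
      paste0(format_symop(x$op), " +(", paste(x$shift, collapse = ","), ")"),
      character(1))
  }
  for (nm in seq_along(mates)) {
    hits2 <- close_pair_count(mxyz, mates[[nm]], cutoff)
    if (nrow(hits2))
      pairs[[length(pairs) + 1L]] <- data.frame(
        moving = moving$serial[hits2[, 1]], other = hits2[, 2],
        mate = if (!is.null(names(mates))) names(mates)[nm] else
          as.character(nm),
        dist = hits2[, 3], stringsAsFactors = FALSE)
  }
  clash_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(moving = integer(0), other = integer(0),
               mate = character(0), dist = numeric(0))
  model$clash_count <- nrow(clash_pairs)
  model$clash_pairs <- clash_pairs
  model
}

#' Enumerate binder orientations by stepwise linker extension
#'
#' Builds one fusion model per value of `k`, scores each against the
#' lattice context, and returns the models ranked by clash count
#' (ascending; ties by `k` ascending).
#'
#' @inheritParams shared_helix_fuse
#' @inheritParams clash_score
#' @param k_range integer vector of extension lengths to enumerate.
#' @return list of scored `fusion_model` objects in rank order.
#' @export
enumerate_rotations <- function(host, host_anchor, binder, binder_anchor,
                                k_range, params = helix_params(),
                                window = 7L, context = NULL, cutoff = 3.0) {
  if (!length(k_range)) stop("k_range must be non-empty")
  models <- lapply(k_range, function(k)
    clash_score(shared_helix_fuse(host, host_anchor, binder, binder_anchor,
                                  k, params = params, window = window),
                context = context, cutoff = cutoff))
  ord <- order(vapply(models, function(m) m$clash_count, numeric(1)),
               vapply(models, function(m) m$k_inserted, numeric(1)))
  models[ord]
}

# ---- cavity sizing ---------------------------------------------------------

#' Largest guest sphere at a lattice position
#'
#' Computes the radius of the largest sphere centred at `center` that
#' touches no heavy atom of the lattice context (reference copy plus
#' symmetry mates when cell and space group are present). The radius is the
#' minimum over atoms of (centre distance minus van der Waals radius),
#' floored at zero; an empty context yields `Inf` (unbounded).
#'
#' @param center Cartesian point, Angstrom.
#' @param context a [struct3d()] or an n x 3 coordinate matrix (then
#'   `elements` gives per-atom element symbols, defaulting to carbon).
#' @param radii named van der Waals radius set, Angstrom.
#' @param elements element symbols when `context` is a matrix.
#' @param shift_range lattice shift half-width for mate inclusion.
#' @return object of class `cavity_estimate` with `center` and `r_max`.
#' @export
cavity_radius <- function(center, context, radii = vdw_radii(),
                          elements = NULL, shift_range = 1L) {
  if (inherits(context, "struct3d")) {
    hs <- heavy_atoms(context)
    xyz <- coords(hs)
    elements <- hs$atoms$element
    if (!is.null(context$cell) && !is.null(context$space_group) &&
        nrow(xyz)) {
      rng <- seq.int(-shift_range, shift_range)
      tr <- frac_cart_transform(context$cell)$frac2cart
      extra <- list()
      for (k in seq_along(context$space_group$ops)) {
        base <- apply_symop(context$space_group$ops[[k]], c(0, 0, 0), xyz,
                            cell = context$cell)
        for (i in rng) for (j in rng) for (l in rng) {
          if (k == 1L && i == 0L && j == 0L && l == 0L) next
          extra[[length(extra) + 1L]] <-
            sweep(base, 2, as.numeric(tr %*% c(i, j, l)), "+")
        }
      }
      if (length(extra)) {
        xyz <- rbind(xyz, do.call(rbind, extra))
        elements <- c(elements, rep(elements, length(extra)))
      }
    }
  } else {
    xyz <- as.matrix(context)
    if (is.null(elements)) elements <- rep("C", nrow(xyz))
  }
  if (!nrow(xyz))
    return(structure(list(center = center, r_max = Inf),
                     class = "cavity_estimate"))
  r <- atom_radii(elements, radii)
  d <- sqrt(rowSums(sweep(xyz, 2, center)^2))
  structure(list(center = center, r_max = max(min(d - r), 0)),
            class = "cavity_estimate")
}

#' @export
print.cavity_estimate <- function(x, ...) {
  if (is.infinite(x$r_max)) {
    cat("cavity: unbounded (empty context)\n")
  } else {
    cat(sprintf("cavity: r_max = %.2f A (diameter %.1f A)\n",
                x$r_max, 2 * x$r_max))
  }
  invisible(x)
}
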