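#' Construct a crystallographic unit cell
#'
#' @param a,b,c cell edge lengths, Angstrom.
#' @param alpha,beta,gamma cell angles, degrees.
#' @return object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(vals))) stop("non-finite cell parameter")
  if (any(vals[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(as.list(vals), class = "unit_cell")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0)
    stop("degenerate unit cell: metric tensor is not positive-definite")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Unit-cell volume
#'
#' Triclinic closed form
#' \eqn{V = abc \sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
#'   + 2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell a [unit_cell()].
#' @return volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate unit cell")
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Fractional/Cartesian transforms for a unit cell
#'
#' Standard crystallographic convention: the `a` axis lies along Cartesian
#' x and `b` in the xy-plane. The two matrices are mutual inverses.
#'
#' @param cell a [unit_cell()].
#' @return list with `frac2cart` and `cart2frac` 3x3 matrices.
#' @export
frac_cart_transform <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate unit cell")
  v <- sqrt(disc)
  m <- matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg), nrow = 3, byrow = TRUE)
  list(frac2cart = m, cart2frac = solve(m))
}

# ---- symmetry operators ----------------------------------------------------

#' Construct a fractional-basis symmetry operator
#'
#' The translation is stored un-normalised: an operator read as
#' `"x - y, x, z + 5/6"` and one read as `"x - y, x, z - 1/6"` share a
#' rotation part but keep their distinct translations, so lattice-shifted
#' variants of the same coset representative remain distinguishable.
#'
#' @param rot 3x3 integer-valued matrix acting on fractional coordinates.
#' @param trans length-3 translation in fractional units.
#' @return object of class `symop`.
#' @export
symop <- function(rot, trans = c(0, 0, 0)) {
  rot <- matrix(as.numeric(rot), 3, 3)
  if (max(abs(rot - round(rot))) > 1e-9)
    stop("rotation part must be integer-valued in the fractional basis")
  structure(list(rot = round(rot), trans = as.numeric(trans)),
            class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat("symop:", format_symop(x), "\n")
  invisible(x)
}

is_identity_op <- function(op) {
  all(op$rot == diag(3)) && all(abs(op$trans) < 1e-9)
}

#' Parse a symmetry-operator triplet
#'
#' Accepts the usual crystallographic triplet notation, e.g.
#' `"x, y, z"`, `"-y, x-y-1, z-1/3"`, `"-x+1, -y, z-1/2"`. Unicode minus
#' signs are tolerated. Translations may be integers, fractions or decimals.
#'
#' @param text comma-separated triplet in x, y, z.
#' @return a [symop()].
#' @export
parse_symop <- function(text) {
  txt <- gsub("[−–—]", "-", text)  # unicode minus/dashes
  txt <- gsub("[[:space:]*]", "", txt)
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("expected a comma-separated triplet, got ", sQuote(text))
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    comp <- parts[i]
    if (!nzchar(comp)) stop("empty component in ", sQuote(text))
    terms <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    for (term in terms) {
      m <- regmatches(term, regexec("^([+-]?)([0-9]+)?([xyz])$", term))[[1]]
      if (length(m)) {
        coef <- if (nzchar(m[3])) as.numeric(m[3]) else 1
        if (m[2] == "-") coef <- -coef
        j <- match(m[4], c("x", "y", "z"))
        rot[i, j] <- rot[i, j] + coef
        next
      }
      sgn <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (grepl("^[0-9]+/[0-9]+$", body)) {
        parts2 <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        val <- parts2[1] / parts2[2]
      } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
        val <- as.numeric(body)
      } else {
        stop("cannot parse term ", sQuote(term), " in ", sQuote(text))
      }
      trans[i] <- trans[i] + sgn * val
    }
  }
  symop(rot, trans)
}

frac_string <- function(v) {
  # format one translation component as integer/fraction (denominator <= 12)
  t12 <- round(v * 12)
  if (abs(v * 12 - t12) > 1e-6) return(sprintf("%+g", v))
  if (t12 == 0) return("")
  g <- gcd2(abs(t12), 12)
  num <- t12 / g; den <- 12 / g
  if (den == 1) sprintf("%+d", num) else sprintf("%+d/%d", num, den)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Format a symmetry operator as a triplet string
#'
#' @param op a [symop()].
#' @return character triplet, e.g. `"x-y,x,z+5/6"`.
#' @export
format_symop <- function(op) {
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      cij <- op$rot[i, j]
      if (cij == 0) next
      coef <- if (abs(cij) == 1) "" else as.character(abs(cij))
      sgn <- if (cij > 0) "+" else "-"
      s <- paste0(s, sgn, coef, axes[j])
    }
    s <- paste0(s, frac_string(op$trans[i]))
    s <- sub("^\\+", "", s)
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

#' Compose two symmetry operators
#'
#' Returns the operator equivalent to applying `b` first, then `a`.
#'
#' @param a,b [symop()] objects.
#' @return a [symop()].
#' @export
compose_symop <- function(a, b) {
  symop(a$rot %*% b$rot, as.numeric(a$rot %*% b$trans) + a$trans)
}

#' Split an operator translation into its mod-1 part and lattice shift
#'
#' @param op a [symop()].
#' @return list with `op` (translation reduced into \[0,1)) and `shift`
#'   (integer lattice translation removed).
#' @export
reduce_symop <- function(op) {
  t12 <- round(op$trans * 12)
  if (max(abs(op$trans * 12 - t12)) > 1e-6) {
    shift <- floor(op$trans + 1e-9)
    return(list(op = symop(op$rot, op$trans - shift), shift = as.integer(shift)))
  }
  mod <- ((t12 %% 12) + 12) %% 12
  shift <- (t12 - mod) / 12
  list(op = symop(op$rot, mod / 12), shift = as.integer(shift))
}

symop_key <- function(op) {
  r <- reduce_symop(op)
  paste(c(r$op$rot, round(r$op$trans * 12)), collapse = ",")
}

# ---- space groups ----------------------------------------------------------

# Generator table for the chiral space groups this toolkit supports
# (sufficient for typical protein crystal forms; P6_5 is the host lattice
# group). Symbols are stored normalised: upper case, no spaces/underscores.
SG_GENERATORS <- list(
  P1       = list(hm = "P 1",        gens = character(0),                          mult = 1L),
  P21      = list(hm = "P 21",       gens = "-x,y+1/2,-z",                         mult = 2L),
  C2       = list(hm = "C 2",        gens = c("-x,y,-z", "x+1/2,y+1/2,z"),         mult = 4L),
  P212121  = list(hm = "P 21 21 21", gens = c("-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z"), mult = 4L),
  P41      = list(hm = "P 41",       gens = "-y,x,z+1/4",                          mult = 4L),
  P43      = list(hm = "P 43",       gens = "-y,x,z+3/4",                          mult = 4L),
  P41212   = list(hm = "P 41 21 2",  gens = c("-y+1/2,x+1/2,z+1/4", "y,x,-z"),     mult = 8L),
  P43212   = list(hm = "P 43 21 2",  gens = c("-y+1/2,x+1/2,z+3/4", "y,x,-z"),     mult = 8L),
  P31      = list(hm = "P 31",       gens = "-y,x-y,z+1/3",                        mult = 3L),
  P32      = list(hm = "P 32",       gens = "-y,x-y,z+2/3",                        mult = 3L),
  P3121    = list(hm = "P 31 2 1",   gens = c("-y,x-y,z+1/3", "y,x,-z"),           mult = 6L),
  P3221    = list(hm = "P 32 2 1",   gens = c("-y,x-y,z+2/3", "y,x,-z"),           mult = 6L),
  P6       = list(hm = "P 6",        gens = "x-y,x,z",                             mult = 6L),
  P61      = list(hm = "P 61",       gens = "x-y,x,z+1/6",                         mult = 6L),
  P65      = list(hm = "P 65",       gens = "x-y,x,z+5/6",                         mult = 6L),
  P6122    = list(hm = "P 61 2 2",   gens = c("x-y,x,z+1/6", "x-y,-y,-z"),         mult = 12L),
  P6522    = list(hm = "P 65 2 2",   gens = c("x-y,x,z+5/6", "x-y,-y,-z"),         mult = 12L)
)

normalise_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[[:space:]_()]", "", symbol))
  s
}

#' Supported space-group symbols
#' @return character vector of Hermann-Mauguin symbols.
#' @export
supported_space_groups <- function() {
  vapply(SG_GENERATORS, function(g) g$hm, character(1), USE.NAMES = FALSE)
}

#' Build a space group from its Hermann-Mauguin symbol
#'
#' Operators are generated by closing the embedded generator set under
#' composition modulo lattice translations; the identity is always first.
#'
#' @param hm_symbol Hermann-Mauguin symbol, e.g. `"P 65"`, `"P65"`, `"P6_5"`.
#' @return object of class `space_group` with fields `hm_symbol` and `ops`.
#' @export
space_group <- function(hm_symbol) {
  if (inherits(hm_symbol, "space_group")) return(hm_symbol)
  key <- normalise_sg_symbol(hm_symbol)
  entry <- SG_GENERATORS[[key]]
  if (is.null(entry))
    stop("unsupported space group ", sQuote(hm_symbol),
         "; supported: ", paste(supported_space_groups(), collapse = ", "))
  ops <- list(symop(diag(3)))
  gens <- lapply(entry$gens, parse_symop)
  seen <- symop_key(ops[[1]])
  queue <- ops
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      cand <- reduce_symop(compose_symop(g, cur))$op
      k <- symop_key(cand)
      if (!k %in% seen) {
        seen <- c(seen, k)
        ops <- c(ops, list(cand))
        queue <- c(queue, list(cand))
      }
    }
  }
  if (length(ops) != entry$mult)
    stop("internal error: generator closure for ", entry$hm,
         " yielded ", length(ops), " ops, expected ", entry$mult)
  structure(list(hm_symbol = entry$hm, ops = ops), class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%d ops):\n", x$hm_symbol, length(x$ops)))
  for (op in x$ops) cat("  ", format_symop(op), "\n")
  invisible(x)
}

#' Apply a symmetry operator (plus lattice shift) to coordinates
#'
#' Computes `x' = Orth (R f + t + shift)` with `f = Orth^-1 x`, i.e. the
#' Cartesian coordinates of a symmetry mate. The operation is an isometry.
#'
#' @param op a [symop()].
#' @param shift integer lattice translation (length 3).
#' @param s a `struct3d` with a cell, or an n x 3 Cartesian matrix (then
#'   `cell` must be given).
#' @param cell a [unit_cell()]; taken from `s` when `s` is a `struct3d`.
#' @return n x 3 matrix of mate Cartesian coordinates.
#' @export
apply_symop <- function(op, shift = c(0L, 0L, 0L), s, cell = NULL) {
  if (inherits(s, "struct3d")) {
    if (is.null(s$cell)) stop("structure has no unit cell")
    cell <- s$cell
    xyz <- coords(s)
  } else {
    xyz <- as.matrix(s)
    if (is.null(cell)) stop("cell required when passing raw coordinates")
  }
  tr <- frac_cart_transform(cell)
  f <- xyz %*% t(tr$cart2frac)
  f2 <- f %*% t(op$rot)
  f2 <- sweep(f2, 2, op$trans + as.numeric(shift), "+")
  f2 %*% t(tr$frac2cart)
}

# squared-distance matrix helper (small/medium n; chunk rows of a)
min_cross_dist <- function(a, b, chunk = 2000L) {
  best <- Inf
  bb <- rowSums(b^2)
  i <- 1L
  n <- nrow(a)
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    aa <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), bb, "+") - 2 * aa %*% t(b)
    best <- min(best, min(d2))
    i <- j + 1L
  }
  sqrt(max(best, 0))
}

#' Enumerate symmetry-mate neighbours of the reference copy
#'
#' Scans all space-group operators combined with lattice shifts in
#' `[-shift_range, shift_range]^3` and keeps every mate (excluding the
#' identity with zero shift) having at least one heavy atom within `cutoff`
#' of the reference copy. Results are ordered by operator index, then shift.
#'
#' @param s a `struct3d` with cell and space group.
#' @param cutoff contact distance cutoff, Angstrom.
#' @param shift_range lattice shift search half-width (default 2).
#' @param force allow cutoffs larger than twice the cell diagonal.
#' @return list of records `list(op_index, op, shift, xyz, min_dist)` where
#'   `xyz` holds the mate's heavy-atom Cartesian coordinates.
#' @export
expand_neighbors <- function(s, cutoff, shift_range = 2L, force = FALSE) {
  stopifnot(inherits(s, "struct3d"))
  if (is.null(s$cell) || is.null(s$space_group))
    stop("structure needs cell and space group for symmetry expansion")
  if (cutoff <= 0) stop("cutoff must be positive")
  diag_len <- sqrt(sum((frac_cart_transform(s$cell)$frac2cart %*% c(1, 1, 1))^2))
  if (cutoff > 2 * diag_len && !force)
    stop("cutoff ", cutoff, " exceeds twice the cell diagonal (",
         round(2 * diag_len, 1), " A); pass force = TRUE to override")
  ref <- coords(heavy_atoms(s))
  if (!nrow(ref)) stop("no heavy atoms in structure")
  lo <- apply(ref, 2, min) - cutoff
  hi <- apply(ref, 2, max) + cutoff
  out <- list()
  rng <- seq.int(-shift_range, shift_range)
  ops <- s$space_group$ops
  for (k in seq_along(ops)) {
    base <- apply_symop(ops[[k]], c(0L, 0L, 0L), ref, cell = s$cell)
    tr <- frac_cart_transform(s$cell)$frac2cart
    for (i in rng) for (j in rng) for (l in rng) {
      if (k == 1L && i == 0L && j == 0L && l == 0L &&
          is_identity_op(ops[[k]])) next
      shift_cart <- as.numeric(tr %*% c(i, j, l))
      mate <- sweep(base, 2, shift_cart, "+")
      if (any(apply(mate, 2, min) > hi) || any(apply(mate, 2, max) < lo))
        next
      d <- min_cross_dist(ref, mate)
      if (d <= cutoff)
        out[[length(out) + 1L]] <- list(op_index = k, op = ops[[k]],
                                        shift = c(i, j, l), xyz = mate,
                                        min_dist = d)
    }
  }
  out
}

# ---- Matthews coefficient & host screening ---------------------------------

#' Solvent fraction from the Matthews coefficient
#'
#' Classic Matthews convention with protein partial specific volume
#' `v_bar` = 0.74 cm^3/g: `solvent = 1 - 1.66 v_bar / V_M`
#' (i.e. `1 - 1.2284 / V_M`), clipped to \[0, 1\].
#'
#' @param v_m Matthews coefficient, Angstrom^3/Da.
#' @param v_bar protein partial specific volume, cm^3/g.
#' @return solvent fraction in \[0, 1\].
#' @export
solvent_fraction <- function(v_m, v_bar = 0.74) {
  if (any(v_m <= 0)) stop("V_M must be positive")
  pmin(pmax(1 - (1.66 * v_bar) / v_m, 0), 1)
}

#' Matthews coefficient and solvent content of a crystal form
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()] or symbol; its multiplicity times
#'   `n_per_asu` gives the number of molecules per cell.
#' @param mw molecular weight of one molecule, Da.
#' @param n_per_asu molecules per asymmetric unit.
#' @param v_bar partial specific volume for the solvent estimate, cm^3/g.
#' @return object of class `matthews_result` with fields `v_cell`,
#'   `z_total`, `mw`, `v_m`, `solvent_frac`.
#' @export
matthews <- function(cell, sg, mw, n_per_asu = 1L, v_bar = 0.74) {
  if (mw <= 0) stop("molecular weight must be positive")
  if (n_per_asu < 1) stop("n_per_asu must be >= 1")
  sg <- space_group(sg)
  v <- cell_volume(cell)
  z <- length(sg$ops) * as.integer(n_per_asu)
  v_m <- v / (z * mw)
  structure(list(v_cell = v, z_total = z, mw = mw, v_m = v_m,
                 solvent_frac = solvent_fraction(v_m, v_bar)),
            class = "matthews_result")
}

#' @export
print.matthews_result <- function(x, ...) {
  cat(sprintf("V = %.4g A^3, Z = %d, MW = %.4g Da -> V_M = %.2f A^3/Da, solvent %.1f%%\n",
              x$v_cell, x$z_total, x$mw, x$v_m, 100 * x$solvent_frac))
  invisible(x)
}

#' Read a host-candidate table from CSV
#'
#' Expected columns: `pdb_id`, `name`, `v_m`, `resolution`; alternatively
#' `v_m` may be absent if `a, b, c, alpha, beta, gamma, sg, mw, n_asu` are
#' present, in which case it is computed via [matthews()].
#'
#' @param path CSV file path.
#' @return data.frame of host candidates.
#' @export
read_host_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"v_m" %in% names(df)) {
    needed <- c("a", "b", "c", "alpha", "beta", "gamma", "sg", "mw", "n_asu")
    if (!all(needed %in% names(df)))
      stop("host table needs either a v_m column or cell/sg/mw/n_asu columns")
    df$v_m <- vapply(seq_len(nrow(df)), function(i) {
      matthews(unit_cell(df$a[i], df$b[i], df$c[i],
                         df$alpha[i], df$beta[i], df$gamma[i]),
               df$sg[i], df$mw[i], df$n_asu[i])$v_m
    }, numeric(1))
  }
  if (!all(c("pdb_id", "v_m", "resolution") %in% names(df)))
    stop("host table needs pdb_id, v_m and resolution columns")
  df
}

#' Screen host-lattice candidates
#'
#' Keeps candidates with `v_m >= min_vm` and `resolution <= max_res`,
#' ranked by Matthews coefficient (descending), ties broken by resolution
#' (ascending) then PDB id. The defaults are the tightest bounds that admit
#' every entry of the reference host set shipped with the package.
#'
#' @param candidates data.frame with columns `pdb_id`, `v_m`, `resolution`
#'   (e.g. from [read_host_table()]).
#' @param min_vm minimum Matthews coefficient, Angstrom^3/Da.
#' @param max_res maximum resolution, Angstrom.
#' @return the filtered, ranked data.frame (possibly empty).
#' @export
screen_hosts <- function(candidates, min_vm = 4.3, max_res = 2.0) {
  if (!nrow(candidates)) return(candidates)
  keep <- candidates$v_m >= min_vm & candidates$resolution <= max_res
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(-out$v_m, out$resolution, out$pdb_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
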