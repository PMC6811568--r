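#' Read a macromolecular structure from PDB or mmCIF
#'
#' Atom records are parsed with bio3d; crystallographic metadata (CRYST1 /
#' `_cell` and `_symmetry` items), which bio3d discards, is captured by a
#' lightweight header scan. Hydrogens are retained (they are flagged and
#' excluded from geometry downstream). Author residue numbering is kept as
#' the authoritative numbering.
#'
#' Alternate locations: by default the highest-occupancy conformer of each
#' residue is kept (ties broken alphabetically by alt-loc id); `keep_alt =
#' TRUE` returns every conformer unfiltered.
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"`/`"mmcif"` or `"auto"` (by extension).
#' @param keep_alt keep all alternate-location conformers.
#' @return a [struct3d()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif", "mmcif"),
                           keep_alt = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "mmcif") format <- "cif"
  if (format == "pdb") {
    atoms <- parse_pdb_atoms(path)
    meta <- parse_cryst1(path)
  } else {
    pdb <- suppressWarnings(bio3d::read.cif(path))
    atoms <- bio3d_to_atoms(pdb)
    meta <- parse_cif_cell(path)
  }
  if (!keep_alt) atoms <- select_alt_conformers(atoms)
  struct3d(atoms, cell = meta$cell, space_group = meta$sg,
           id = sub("\\.[^.]*$", "", basename(path)))
}

parse_pdb_atoms <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                          verbose = FALSE))
  atoms <- bio3d_to_atoms(pdb)
  # bio3d yields NA serials/resnos for hybrid-36 fields; recover them from
  # the raw fixed-column records
  if (anyNA(atoms$serial) || anyNA(atoms$resno)) {
    lines <- readLines(path, warn = FALSE)
    rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
    if (length(rec) == nrow(atoms)) {
      if (anyNA(atoms$serial))
        atoms$serial <- vapply(substr(rec, 7, 11), hy36_decode, integer(1),
                               width = 5L, USE.NAMES = FALSE)
      if (anyNA(atoms$resno))
        atoms$resno <- vapply(substr(rec, 23, 26), hy36_decode, integer(1),
                              width = 4L, USE.NAMES = FALSE)
    }
  }
  atoms
}

bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v), "", v)
  elem <- blank(a$elesy)
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]
  data.frame(
    serial = a$eleno, name = a$elety, alt = blank(a$alt),
    resname = a$resid, chain = blank(a$chain), resno = a$resno,
    insert = blank(a$insert), x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    element = elem, het = a$type == "HETATM",
    stringsAsFactors = FALSE)
}

select_alt_conformers <- function(atoms) {
  if (!nrow(atoms) || all(!nzchar(atoms$alt))) return(atoms)
  keep <- rep(TRUE, nrow(atoms))
  key <- residue_key(atoms)
  for (res in unique(key[nzchar(atoms$alt)])) {
    idx <- which(key == res)
    alts <- atoms$alt[idx]
    labs <- sort(unique(alts[nzchar(alts)]))
    if (length(labs) < 2) next
    mean_occ <- vapply(labs, function(l) mean(atoms$occ[idx][alts == l]),
                       numeric(1))
    best <- labs[order(-mean_occ, labs)][1]
    keep[idx[nzchar(alts) & alts != best]] <- FALSE
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_cryst1 <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  cl <- lines[startsWith(lines, "CRYST1")]
  if (!length(cl)) return(list(cell = NULL, sg = NULL))
  cl <- cl[1]
  nums <- suppressWarnings(as.numeric(c(
    substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
    substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
  if (anyNA(nums)) stop("malformed CRYST1 record in ", path)
  cell <- unit_cell(nums[1], nums[2], nums[3], nums[4], nums[5], nums[6])
  sym <- trimws(substr(cl, 56, 66))
  sg <- NULL
  if (nzchar(sym))
    sg <- tryCatch(space_group(sym), error = function(e) NULL)
  list(cell = cell, sg = sg)
}

parse_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA)
    val <- trimws(sub(paste0("^", tag), "", hit[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  a <- suppressWarnings(as.numeric(grab("_cell\\.length_a")))
  b <- suppressWarnings(as.numeric(grab("_cell\\.length_b")))
  cc <- suppressWarnings(as.numeric(grab("_cell\\.length_c")))
  al <- suppressWarnings(as.numeric(grab("_cell\\.angle_alpha")))
  be <- suppressWarnings(as.numeric(grab("_cell\\.angle_beta")))
  ga <- suppressWarnings(as.numeric(grab("_cell\\.angle_gamma")))
  cell <- NULL
  if (!anyNA(c(a, b, cc, al, be, ga)))
    cell <- unit_cell(a, b, cc, al, be, ga)
  sym <- grab("_symmetry\\.space_group_name_H-M")
  if (is.na(sym) || !nzchar(sym))
    sym <- grab("_space_group\\.name_H-M_alt")
  sg <- NULL
  if (!is.na(sym) && nzchar(sym) && !is.null(cell))
    sg <- tryCatch(space_group(sym), error = function(e) NULL)
  list(cell = cell, sg = sg)
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output is fixed-column; atom serials above 99999 and residue numbers
#' above 9999 switch to hybrid-36 encoding in their fields. mmCIF output is
#' lossless for any atom count. Round-tripping preserves atom count, names,
#' numbering, occupancy, B-factors, cell and space group (coordinates at
#' 3 decimals).
#'
#' @param s a [struct3d()].
#' @param path output file path.
#' @param format `"pdb"`, `"cif"`/`"mmcif"` or `"auto"` (by extension).
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "cif", "mmcif")) {
  stopifnot(inherits(s, "struct3d"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "mmcif") format <- "cif"
  if (format == "pdb") write_pdb_file(s, path) else write_cif_file(s, path)
  invisible(path)
}

write_pdb_file <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(s$cell)) {
    sym <- if (!is.null(s$space_group)) s$space_group$hm_symbol else "P 1"
    z <- if (!is.null(s$space_group)) length(s$space_group$ops) else 1L
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                       s$cell$a, s$cell$b, s$cell$c,
                       s$cell$alpha, s$cell$beta, s$cell$gamma, sym, z), con)
  }
  a <- s$atoms
  if (nrow(a)) {
    serial <- vapply(a$serial, hy36_encode, character(1), width = 5L)
    resno <- vapply(a$resno, hy36_encode, character(1), width = 4L)
    name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                    paste0(" ", formatC(a$name, width = -3)))
    lines <- sprintf("%-6s%5s %4s%1s%-3s %1s%4s%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     ifelse(a$het, "HETATM", "ATOM"), serial, name4,
                     substr(paste0(a$alt, " "), 1, 1),
                     a$resname, substr(paste0(a$chain, " "), 1, 1),
                     resno, substr(paste0(a$insert, " "), 1, 1),
                     a$x, a$y, a$z, a$occ, a$b, a$element)
    writeLines(lines, con)
  }
  writeLines("END", con)
}

write_cif_file <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  id <- if (nzchar(s$id)) gsub("[[:space:]]", "_", s$id) else "structure"
  writeLines(paste0("data_", id), con)
  if (!is.null(s$cell)) {
    writeLines(sprintf("_cell.length_a     %.4f", s$cell$a), con)
    writeLines(sprintf("_cell.length_b     %.4f", s$cell$b), con)
    writeLines(sprintf("_cell.length_c     %.4f", s$cell$c), con)
    writeLines(sprintf("_cell.angle_alpha  %.4f", s$cell$alpha), con)
    writeLines(sprintf("_cell.angle_beta   %.4f", s$cell$beta), con)
    writeLines(sprintf("_cell.angle_gamma  %.4f", s$cell$gamma), con)
  }
  if (!is.null(s$space_group))
    writeLines(sprintf("_symmetry.space_group_name_H-M  '%s'",
                       s$space_group$hm_symbol), con)
  a <- s$atoms
  if (nrow(a)) {
    writeLines(c("loop_",
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
      "_atom_site.label_atom_id", "_atom_site.label_alt_id",
      "_atom_site.label_comp_id", "_atom_site.label_asym_id",
      "_atom_site.label_entity_id", "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
      "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num"), con)
    dot <- function(v) ifelse(nzchar(v), v, ".")
    lines <- sprintf("%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
                     ifelse(a$het, "HETATM", "ATOM"), a$serial, a$element,
                     a$name, dot(a$alt), a$resname, dot(a$chain), a$resno,
                     ifelse(nzchar(a$insert), a$insert, "?"),
                     a$x, a$y, a$z, a$occ, a$b, a$resno, a$resname,
                     dot(a$chain), a$name)
    writeLines(lines, con)
  }
}

# ---- sequence molecular weight ---------------------------------------------

# average residue masses (Da) of amino-acid residues within a peptide chain
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Average molecular weight of a protein sequence
#'
#' @param seq one-letter amino-acid string, or a FASTA file path (first
#'   record used) when `fasta = TRUE`.
#' @param fasta treat `seq` as a FASTA path.
#' @return molecular weight in Da (average masses, plus one water).
#' @export
protein_mw <- function(seq, fasta = FALSE) {
  if (fasta) {
    fa <- bio3d::read.fasta(seq)
    seq <- paste(toupper(fa$ali[1, ]), collapse = "")
    seq <- gsub("-", "", seq)
  }
  chars <- strsplit(toupper(gsub("[[:space:]]", "", seq)), "")[[1]]
  m <- AA_RESIDUE_MASS[chars]
  if (anyNA(m))
    stop("unknown residue code(s): ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  sum(m) + 18.0153
}
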