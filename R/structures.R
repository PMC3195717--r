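#' Protein structures as C-alpha bead chains
#'
#' A `protein_structure` is the coarse-grained object every other module
#' operates on: one bead per residue, placed at the C-alpha position, with
#' a residue-specific mass.  Residues are re-indexed 1..N in file order so
#' that energies, response times and module ids line up by position.
#'
#' @param index 1-based contiguous integer indices.
#' @param name three-letter residue codes.
#' @param chain_id chain labels.
#' @param resseq original residue sequence numbers (for provenance only).
#' @param mass bead masses in amu; defaults to the standard amino-acid
#'   residue mass for known codes, 110 amu otherwise.
#' @param xyz N x 3 numeric matrix of coordinates in Angstrom.
#' @param source_id free-text origin tag (e.g. a PDB code or "synthetic").
#' @return an object of class `protein_structure`: a list with elements
#'   `residues` (data.frame: index, name, chain_id, resseq, mass) and
#'   `xyz` (N x 3 matrix), plus `source_id`.
#' @export
protein_structure <- function(index, name, chain_id, resseq = index,
                              mass = NULL, xyz, source_id = "") {
  xyz <- as.matrix(xyz)
  n <- length(index)
  ed_assert(n >= 2, "enerdiss_input_error",
            "a structure needs at least 2 residues, got %d", n)
  ed_assert(identical(as.integer(index), seq_len(n)),
            "enerdiss_input_error",
            "residue indices must be 1..N in order")
  ed_assert(nrow(xyz) == n && ncol(xyz) == 3, "enerdiss_input_error",
            "xyz must be an N x 3 matrix")
  ed_assert(all(is.finite(xyz)), "enerdiss_input_error",
            "non-finite coordinates")
  if (is.null(mass)) mass <- residue_mass(name)
  ed_assert(all(mass > 0), "enerdiss_input_error", "masses must be > 0")
  structure(list(
    residues = data.frame(index = as.integer(index),
                          name = as.character(name),
                          chain_id = as.character(chain_id),
                          resseq = as.integer(resseq),
                          mass = as.numeric(mass),
                          stringsAsFactors = FALSE),
    xyz = unname(xyz),
    source_id = source_id), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues (source: %s)\n",
              nrow(x$residues),
              if (nzchar(x$source_id)) x$source_id else "unknown"))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `protein_structure`.
#' @return integer residue count.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Read a PDB file into a C-alpha bead structure
#'
#' Parses ATOM records (HETATM ignored), keeps one bead per residue at its
#' C-alpha position, in file order, re-indexed 1..N.  Altloc duplicates
#' collapse to the first occurrence; residues whose ATOM block carries no
#' C-alpha are skipped with a warning.
#'
#' @param pdb_text character vector of PDB lines, or a length-1 path to a
#'   PDB file.
#' @param chain optional chain identifier; `NULL` keeps all chains.
#' @param source_id origin tag stored on the structure; defaults to the
#'   file name when a path is given.
#' @return a [protein_structure()].
#' @export
read_structure <- function(pdb_text, chain = NULL, source_id = NULL) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    if (is.null(source_id)) source_id <- basename(pdb_text)
    pdb_text <- readLines(pdb_text, warn = FALSE)
  } else if (length(pdb_text) == 1L) {
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  }
  if (is.null(source_id)) source_id <- "pdb-text"
  atom <- pdb_text[startsWith(pdb_text, "ATOM")]
  ed_assert(length(atom) > 0, "enerdiss_format_error",
            "no ATOM records found in PDB input")
  # fixed-column PDB fields
  fld <- function(from, to) trimws(substr(atom, from, to))
  name    <- fld(13, 16)
  altloc  <- fld(17, 17)
  resname <- fld(18, 20)
  chainid <- fld(22, 22)
  resseq  <- fld(23, 26)
  icode   <- fld(27, 27)
  x <- suppressWarnings(as.numeric(substr(atom, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(atom, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(atom, 47, 54)))
  ed_assert(!anyNA(c(x, y, z)), "enerdiss_format_error",
            "unparseable coordinates in ATOM records")
  if (!is.null(chain)) {
    keep <- chainid == chain
    ed_assert(any(keep), "enerdiss_input_error",
              "no ATOM records for chain '%s'", chain)
    name <- name[keep]; altloc <- altloc[keep]; resname <- resname[keep]
    chainid <- chainid[keep]; resseq <- resseq[keep]; icode <- icode[keep]
    x <- x[keep]; y <- y[keep]; z <- z[keep]
  }
  # residue identity = chain + seq number + insertion code, in file order
  rid <- paste(chainid, resseq, icode, sep = "|")
  rid_order <- unique(rid)
  is_ca <- name == "CA" & (altloc == "" | altloc == "A")
  # first CA per residue (altloc collapse happens via the first-match rule)
  ca_idx <- match(rid_order, rid[is_ca])
  missing_ca <- is.na(ca_idx)
  if (any(missing_ca)) {
    warning(sprintf("skipping %d residue(s) without a C-alpha atom: %s",
                    sum(missing_ca),
                    paste(sub("\\|$", "", rid_order[missing_ca]),
                          collapse = ", ")))
  }
  sel <- which(is_ca)[ca_idx[!missing_ca]]
  ed_assert(length(sel) >= 2, "enerdiss_input_error",
            "fewer than 2 residues with a C-alpha atom")
  protein_structure(index = seq_along(sel),
                    name = resname[sel],
                    chain_id = chainid[sel],
                    resseq = as.integer(resseq[sel]),
                    xyz = cbind(x[sel], y[sel], z[sel]),
                    source_id = source_id)
}

#' Write a structure as PDB-format text
#'
#' One ATOM record per bead (atom name CA), coordinates to 3 decimals.
#' Round-tripping through [read_structure()] reproduces indices, names and
#' coordinates at that precision.
#'
#' @param structure a `protein_structure`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) the PDB lines.
#' @export
write_structure <- function(structure, path = NULL) {
  r <- structure$residues
  xyz <- structure$xyz
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    r$index, substr(r$name, 1, 3),
    ifelse(nzchar(r$chain_id), substr(r$chain_id, 1, 1), "A"),
    r$resseq, xyz[, 1], xyz[, 2], xyz[, 3])
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Annotate structural regions of a structure
#'
#' Maps residue index ranges to region labels (for aspartokinase III these
#' would be N-lobe, C-lobe, ACT1, ACT2 and the beta15-alphaK loop).
#' Unlisted residues are labelled "unassigned", so the labels always form
#' a partition of the structure.
#'
#' @param structure a `protein_structure`.
#' @param spec a data.frame (or list of 3-element vectors) with columns
#'   start, end, label: 1-based inclusive residue index ranges.
#' @return a `region_annotation`: character vector of length N, one label
#'   per residue, with attribute `labels` (the distinct region labels in
#'   spec order).
#' @export
annotate_regions <- function(structure, spec) {
  n <- n_residues(structure)
  if (is.data.frame(spec)) {
    stopifnot(ncol(spec) >= 3)
    start <- as.integer(spec[[1]]); end <- as.integer(spec[[2]])
    label <- as.character(spec[[3]])
  } else if (length(spec) == 0) {
    start <- integer(0); end <- integer(0); label <- character(0)
  } else {
    start <- vapply(spec, function(s) as.integer(s[[1]]), integer(1))
    end   <- vapply(spec, function(s) as.integer(s[[2]]), integer(1))
    label <- vapply(spec, function(s) as.character(s[[3]]), character(1))
  }
  ed_assert(all(start >= 1 & end <= n & start <= end),
            "enerdiss_spec_error",
            "region ranges must lie within 1..%d with start <= end", n)
  out <- rep("unassigned", n)
  seen <- rep(FALSE, n)
  for (k in seq_along(start)) {
    idx <- start[k]:end[k]
    ed_assert(!any(seen[idx]), "enerdiss_spec_error",
              "overlapping region ranges at label '%s'", label[k])
    seen[idx] <- TRUE
    out[idx] <- label[k]
  }
  structure(out, labels = unique(label), class = "region_annotation")
}

#' Read a region annotation table
#'
#' Three-column delimited text (start, end, label), whitespace- or
#' tab-separated; lines starting with `#` are comments.
#'
#' @param path file path.
#' @param structure the `protein_structure` the ranges refer to.
#' @return a `region_annotation` (see [annotate_regions()]).
#' @export
read_region_table <- function(path, structure) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("start", "end", "label"),
                           stringsAsFactors = FALSE)
  annotate_regions(structure, tab)
}

#' Sizes of annotated regions
#' @param annotation a `region_annotation`.
#' @return named integer vector of region sizes (including "unassigned").
#' @export
region_sizes <- function(annotation) {
  table(factor(annotation, levels = unique(c(attr(annotation, "labels"),
                                             "unassigned"))))
}
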