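# PDB-format input/output.  Parsing goes through bio3d; a line-level
# pre-validation supplies the error reporting (line numbers for malformed
# coordinate fields) that the parsing contract requires.  Only heavy atoms of
# the 20 canonical amino acids are retained; alternate locations resolve to
# the highest occupancy (ties: first in file).

#' Parse a protein complex from PDB-format text
#'
#' @param source PDB text: a single string, a character vector of lines, or a
#'   path to an existing file.
#' @param partners optional list(g1 =, g2 =) chain grouping; defaults to first
#'   chain vs the rest.
#' @return a `complex_structure`.
#' @export
parse_pdb <- function(source, partners = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec == "ATOM  " | rec == "HETATM")
  for (ln in atom_lines) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz))
      stop("malformed coordinate fields at line ", ln)
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% unname(AA3), , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard residues in PDB source")

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- element_of_atom(at$elety[bad])
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard residues in PDB source")

  ic <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, ic, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dupd <- key %in% key[duplicated(key)]
  if (any(dupd)) {
    for (k in unique(key[dupd])) {
      idx <- which(key == k)
      best <- idx[which.max(occ[idx])]   # ties: first in file
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]
  ic <- ic[keep]

  rkey <- paste(at$chain, at$resno, ic, sep = "\r")
  ridx <- match(rkey, unique(rkey))
  n <- max(ridx)
  first <- match(seq_len(n), ridx)
  atoms <- vector("list", n)
  xyz <- cbind(at$x, at$y, at$z)
  for (r in seq_len(n)) {
    rows <- which(ridx == r)
    m <- xyz[rows, , drop = FALSE]
    rownames(m) <- at$elety[rows]
    atoms[[r]] <- m
  }
  new_complex_structure(chain = at$chain[first],
                        resseq = at$resno[first],
                        icode = ic[first],
                        aa = unname(AA3_TO_1[at$resid[first]]),
                        atoms = atoms,
                        partners = partners)
}

#' Write a complex as PDB-format text
#'
#' Fixed-width ATOM records in residue order; round-trips through
#' [parse_pdb()] up to the 1e-3 A coordinate quantization of the format.
#'
#' @param structure a `complex_structure`.
#' @param file optional path; when given, text is also written there.
#' @return character vector of PDB lines (invisibly when `file` is set).
#' @export
write_pdb <- function(structure, file = NULL) {
  validate_complex(structure)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_residues(structure))) {
    a <- structure$atoms[[i]]
    res3 <- AA3[[structure$aa[i]]]
    for (k in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- rownames(a)[k]
      namef <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, namef, res3, structure$chain[i],
        structure$resseq[i],
        ifelse(structure$icode[i] == "", " ", structure$icode[i]),
        a[k, 1], a[k, 2], a[k, 3], 1.0, 0.0, element_of_atom(nm)))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a tabular sample manifest
#'
#' Expects TSV/CSV columns `wt_pdb`, `mut_pdb`, `mutations` (';'-separated
#' codes) and `ddg`; PDB paths are resolved relative to the manifest.
#'
#' @param path manifest file.
#' @param partners optional chain grouping passed to [parse_pdb()].
#' @return list of `sample_record`.
#' @export
read_manifest <- function(path, partners = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("wt_pdb", "mut_pdb", "mutations", "ddg")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  dir <- dirname(path)
  lapply(seq_len(nrow(tab)), function(r) {
    wt <- parse_pdb(file.path(dir, tab$wt_pdb[r]), partners = partners)
    mut <- parse_pdb(file.path(dir, tab$mut_pdb[r]), partners = partners)
    sample_record(wt, mut,
                  strsplit(tab$mutations[r], ";", fixed = TRUE)[[1]],
                  tab$ddg[r])
  })
}
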