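#' Read the C-alpha trace of one chain from a PDB file
#'
#' Extracts, in sequence order, every residue of `chain` that has a C-alpha
#' atom. Alternate locations are resolved to the highest-occupancy copy
#' (ties keep the first encountered); insertion-coded residues keep their
#' file order. Residues without a C-alpha atom are dropped.
#'
#' @param path Path to a PDB-format file.
#' @param chain Single chain identifier, e.g. `"A"`.
#' @param model Model ordinal for multi-model files (default 1).
#'
#' @return A tibble with one row per residue: `index` (1-based ordinal
#'   within the chain), `resno` and `ins` (author numbering), `aa`
#'   (one-letter code), and C-alpha coordinates `x`, `y`, `z` in Angstrom.
#' @export
read_pdb_chain <- function(path, chain, model = 1) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!chain %in% at$chain) {
    stop("chain not found: '", chain, "' in ", path, call. = FALSE)
  }
  if (model != 1) {
    # bio3d::read.pdb(multi = FALSE) keeps the first model's coordinates;
    # re-read with multi = TRUE and substitute the requested frame.
    pdb_m <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    if (model > nrow(pdb_m$xyz)) stop("model ", model, " not present", call. = FALSE)
    xyz <- matrix(pdb_m$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  ca <- at[at$chain == chain & at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no backbone: chain '", chain, "' has no C-alpha atoms", call. = FALSE)
  ca$ins <- ifelse(is.na(ca$insert), "", ca$insert)
  ca$o <- ifelse(is.na(ca$o), 1, ca$o)
  # resolve altlocs: within each (resno, ins) keep highest occupancy, first on tie
  key <- paste(ca$resno, ca$ins)
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
                        function(i) i[which.max(ca$o[i])]),
                 use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  tibble(
    index = seq_len(nrow(ca)),
    resno = ca$resno,
    ins = ca$ins,
    aa = bio3d::aa321(ca$resid),
    x = ca$x, y = ca$y, z = ca$z
  )
}

#' Parse a DSSP output file
#'
#' Reads the fixed-column data block that follows the `#  RESIDUE` header of
#' classic DSSP output: per residue, the one-letter secondary-structure
#' state and the solvent-accessible surface area. Chain-break rows (`!` in
#' the amino-acid column) are skipped.
#'
#' @param path Path to a DSSP output file.
#' @return A tibble with columns `chain`, `resno`, `ins`, `aa`, `ss`
#'   (one-letter state, `" "` reported as `"C"` for coil) and `acc`
#'   (integer, Angstrom squared).
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a DSSP file: '#  RESIDUE' header not found", call. = FALSE)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "C"
  tibble(
    chain = substr(body, 12, 12),
    resno = as.integer(substr(body, 6, 10)),
    ins = trimws(substr(body, 11, 11)),
    aa = aa[keep],
    ss = ss,
    acc = as.integer(substr(body, 35, 38))
  )
}

#' Segment a per-residue secondary-structure string into SSEs
#'
#' Maximal runs of helix codes become helix elements if they span at least
#' `min_helix` residues; maximal runs of `E` become strands if they span at
#' least `min_strand`. Every other code is coil and never yields an element.
#'
#' @param residues A tibble with at least an `ss` column (one-letter code
#'   per residue, in N-to-C order), as produced by joining [read_pdb_chain()]
#'   with [read_dssp()]; a bare character vector of codes is also accepted.
#' @param helix_codes Codes counted as helix. Default `"H"`; pass
#'   `c("H", "G", "I")` to count 3-10 and pi helices.
#' @param min_helix,min_strand Minimum run lengths (defaults 4 and 3).
#'
#' @return A tibble of SSEs ordered N-to-C: `sse`, `kind` (`"helix"` or
#'   `"strand"`), `start`, `end` (1-based inclusive residue ordinals) and
#'   `length`.
#' @export
segment_sses <- function(residues, helix_codes = "H",
                         min_helix = 4L, min_strand = 3L) {
  ss <- if (is.character(residues)) residues else residues$ss
  if (length(ss) == 1L && !is.data.frame(residues)) ss <- strsplit(ss, "")[[1]]
  kind <- ifelse(ss %in% helix_codes, "helix", ifelse(ss == "E", "strand", "coil"))
  r <- rle(kind)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  ok <- (r$values == "helix" & r$lengths >= min_helix) |
    (r$values == "strand" & r$lengths >= min_strand)
  s <- start[ok]
  e <- end[ok]
  tibble(
    sse = seq_along(s),
    kind = r$values[ok],
    start = s,
    end = e,
    length = e - s + 1L
  )
}

#' Read an ASTRAL dir.cla classification file
#'
#' One record per non-comment line: domain sid, PDB code, region text, the
#' dotted sccs lineage string and the integer sunid. The sccs must have the
#' four-field `letter.int.int.int` form.
#'
#' @param path Path to a dir.cla-style text file (`#` lines are comments).
#' @return A tibble with columns `sid`, `pdb`, `region`, `sccs`, `sunid`.
#' @export
read_scop_cla <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  fields <- strsplit(trimws(lines), "\\s+")
  bad_n <- vapply(fields, length, 1L) < 5L
  if (any(bad_n)) {
    stop("malformed dir.cla line ", lineno[which(bad_n)[1]],
         ": fewer than 5 fields", call. = FALSE)
  }
  sccs <- vapply(fields, `[[`, "", 4L)
  ok <- grepl("^[A-Za-z]\\.[0-9]+\\.[0-9]+\\.[0-9]+$", sccs)
  if (any(!ok)) {
    stop("malformed sccs '", sccs[which(!ok)[1]], "' at line ",
         lineno[which(!ok)[1]], call. = FALSE)
  }
  tibble(
    sid = vapply(fields, `[[`, "", 1L),
    pdb = vapply(fields, `[[`, "", 2L),
    region = vapply(fields, `[[`, "", 3L),
    sccs = sccs,
    sunid = as.integer(vapply(fields, `[[`, "", 5L))
  )
}

#' Write records in dir.cla format
#'
#' Inverse of [read_scop_cla()]; used for round-trips and synthetic fixture
#' export.
#'
#' @param records Tibble with columns `sid`, `pdb`, `region`, `sccs`, `sunid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scop_cla <- function(records, path) {
  writeLines(
    paste(records$sid, records$pdb, records$region, records$sccs, records$sunid,
          sep = "\t"),
    path
  )
  invisible(path)
}

#' Filter domain pairs by sequence identity
#'
#' Keeps pairs whose sequence identity is strictly below `cutoff` (pairs of
#' near-identical sequences carry no generalisation signal for inter-domain
#' classification).
#'
#' @param pairs A tibble with an `identity` column (fraction in \[0, 1\]).
#' @param cutoff Identity cutoff; the default 0.35 keeps pairs below 35%.
#' @return The filtered tibble.
#' @export
filter_pairs_by_identity <- function(pairs, cutoff = 0.35) {
  stopifnot(all(pairs$identity >= 0 & pairs$identity <= 1))
  dplyr::filter(pairs, .data$identity < cutoff)
}
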