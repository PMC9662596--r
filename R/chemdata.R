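#' Construct a MoleculeSet
#'
#' @param ids unique molecule identifiers.
#' @param smiles SMILES strings (`NA` where only a geometry is known).
#' @param elements list of character vectors of element symbols, one per
#'   molecule.
#' @param coords list of N x 3 coordinate matrices (Angstrom).
#' @param charges list of integer nuclear-charge vectors; derived from
#'   `elements` when omitted.
#' @param records property table with columns id, level, homo, lumo, gap
#'   (all energies in eV).
#' @return a validated [MoleculeSet-class] object.
#' @examples
#' ms <- MoleculeSet(ids = "h2", smiles = NA_character_,
#'                   elements = list(c("H", "H")),
#'                   coords = list(rbind(c(0, 0, 0), c(0, 0, 0.74))))
#' nMol(ms)
#' @export
MoleculeSet <- function(ids, smiles = rep(NA_character_, length(ids)),
                        elements, coords, charges = NULL,
                        records = .emptyRecords()) {
  if (is.null(charges))
    charges <- lapply(elements, function(e) as.integer(unname(elementToZ(e))))
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; dimnames(m) <- NULL; m
  })
  records$id <- as.character(records$id)
  records$level <- as.character(records$level)
  new("MoleculeSet", ids = as.character(ids), smiles = as.character(smiles),
      elements = elements, coords = coords, charges = charges,
      records = records)
}

#' @describeIn MoleculeSet number of molecules.
#' @param x a MoleculeSet.
#' @export
nMol <- function(x) length(x@ids)

#' Accessors for MoleculeSet
#'
#' `molIds`, `molSmiles`, `molElements`, `molCoords`, `molCharges` return the
#' per-molecule slots; `records` returns the property table; `gaps`, `homos`
#' and `lumos` return a named energy vector for one level of theory, aligned
#' with molecule order.
#'
#' @param x a [MoleculeSet-class].
#' @param level level of theory whose energies to extract.
#' @name moleculeset-accessors
NULL

#' @rdname moleculeset-accessors
#' @export
molIds <- function(x) x@ids
#' @rdname moleculeset-accessors
#' @export
molSmiles <- function(x) stats::setNames(x@smiles, x@ids)
#' @rdname moleculeset-accessors
#' @export
molElements <- function(x) stats::setNames(x@elements, x@ids)
#' @rdname moleculeset-accessors
#' @export
molCoords <- function(x) stats::setNames(x@coords, x@ids)
#' @rdname moleculeset-accessors
#' @export
molCharges <- function(x) stats::setNames(x@charges, x@ids)
#' @rdname moleculeset-accessors
#' @export
records <- function(x) x@records

.levelEnergy <- function(x, level, what) {
  rec <- x@records[x@records$level == level, , drop = FALSE]
  if (!nrow(rec)) stop("no property records at level '", level, "'")
  out <- stats::setNames(rec[[what]], rec$id)[x@ids]
  stats::setNames(out, x@ids)
}

#' @rdname moleculeset-accessors
#' @export
gaps <- function(x, level) .levelEnergy(x, level, "gap")
#' @rdname moleculeset-accessors
#' @export
homos <- function(x, level) .levelEnergy(x, level, "homo")
#' @rdname moleculeset-accessors
#' @export
lumos <- function(x, level) .levelEnergy(x, level, "lumo")

#' @export
setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet with", length(object@ids), "molecules\n")
  if (length(object@ids)) {
    natoms <- vapply(object@elements, length, integer(1))
    cat("  atoms per molecule:", min(natoms), "-", max(natoms), "\n")
    cat("  with SMILES:", sum(!is.na(object@smiles)), "\n")
  }
  lv <- unique(object@records$level)
  cat("  property records:", nrow(object@records),
      if (length(lv)) paste0("(levels: ", paste(lv, collapse = ", "), ")") else "",
      "\n")
})

#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  if (anyNA(i)) stop("unknown molecule id(s) in subset")
  keep <- x@ids[i]
  rec <- x@records[x@records$id %in% keep, , drop = FALSE]
  rownames(rec) <- NULL
  new("MoleculeSet", ids = x@ids[i], smiles = x@smiles[i],
      elements = x@elements[i], coords = x@coords[i],
      charges = x@charges[i], records = rec)
})

#' Add or replace property records
#'
#' Rows replace any existing record with the same (id, level).
#'
#' @param x a [MoleculeSet-class].
#' @param newRecords data.frame with columns id, level and at least gap or
#'   both homo and lumo (eV). A missing gap is filled as lumo - homo.
#' @return the updated MoleculeSet.
#' @export
addRecords <- function(x, newRecords) {
  newRecords <- .completeRecords(newRecords)
  old <- x@records
  key <- function(d) paste(d$id, d$level, sep = "\r")
  old <- old[!key(old) %in% key(newRecords), , drop = FALSE]
  x@records <- rbind(old, newRecords[names(.emptyRecords())])
  rownames(x@records) <- NULL
  validObject(x)
  x
}

.completeRecords <- function(rec) {
  for (col in c("homo", "lumo", "gap")) if (is.null(rec[[col]])) rec[[col]] <- NA_real_
  miss <- is.na(rec$gap)
  rec$gap[miss] <- rec$lumo[miss] - rec$homo[miss]
  bad <- is.na(rec$gap) & !(!is.na(rec$homo) & !is.na(rec$lumo))
  if (any(bad))
    stop("rows with neither a gap nor both orbital energies: ",
         paste(utils::head(rec$id[bad], 5), collapse = ", "))
  rec$id <- as.character(rec$id); rec$level <- as.character(rec$level)
  rec
}

#' Convert Hartree to electron volt
#'
#' Multiplies by the CODATA 2018 Hartree energy, 27.211386245988 eV.
#'
#' @param x energies in Hartree.
#' @return energies in eV.
#' @examples
#' hartreeToEV(1)    # 27.211386245988
#' hartreeToEV(-0.5) # -13.605693122994
#' @export
hartreeToEV <- function(x) x * 27.211386245988

#' Read an (extended) XYZ file
#'
#' Parses standard XYZ framing: an atom-count line, a comment line, then one
#' `symbol x y z` line per atom, blocks concatenated. The comment line may
#' carry whitespace-separated property fields at configurable column
#' indices (dialects differ between archives, so the mapping is supplied
#' rather than hard-coded).
#'
#' @param path file path.
#' @param propertyCols optional named integer vector with any of `homo`,
#'   `lumo`, `gap`, giving 1-based field indices into the whitespace-split
#'   comment line. When supplied, a property record per molecule is created.
#' @param level level-of-theory name for created records (required with
#'   `propertyCols`).
#' @param unit `"eV"` or `"hartree"`; Hartree energies are converted to eV
#'   at ingest.
#' @param idCol optional 1-based comment-line field holding the molecule id;
#'   default ids are `<filestem>_<block index>` (0-based).
#' @return a [MoleculeSet-class].
#' @export
readExtendedXYZ <- function(path, propertyCols = NULL, level = NULL,
                            unit = c("eV", "hartree"), idCol = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is.null(propertyCols) && is.null(level))
    stop("'level' must be given when propertyCols is supplied")
  lines <- readLines(path)
  stem <- tools::file_path_sans_ext(basename(path))
  ids <- smi <- character(); els <- xyz <- list()
  rec <- list()
  i <- 1L; block <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop(sprintf("parse error at line %d: expected an atom count, got '%s'",
                   i, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf(
        "parse error at line %d: block declares %d atoms but file ends after %d atom line(s)",
        i, nat, max(0L, length(lines) - i - 1L)))
    comment <- lines[i + 1L]
    at <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(at), "\\s+")
    bad <- which(vapply(tok, length, integer(1)) < 4L)
    if (length(bad))
      stop(sprintf("parse error at line %d: malformed atom line '%s'",
                   i + 1L + bad[1], at[bad[1]]))
    sym <- vapply(tok, `[`, "", 1L)
    co <- t(vapply(tok, function(t) suppressWarnings(as.numeric(t[2:4])),
                   numeric(3)))
    if (anyNA(co)) {
      bad <- which(apply(is.na(co), 1, any))[1]
      stop(sprintf("parse error at line %d: non-numeric coordinate in '%s'",
                   i + 1L + bad, at[bad]))
    }
    cf <- strsplit(trimws(comment), "\\s+")[[1]]
    id <- if (!is.null(idCol) && length(cf) >= idCol) cf[idCol]
          else sprintf("%s_%d", stem, block)
    ids <- c(ids, id); smi <- c(smi, NA_character_)
    els <- c(els, list(sym)); xyz <- c(xyz, list(co))
    if (!is.null(propertyCols)) {
      get <- function(name) {
        j <- propertyCols[name]
        if (is.na(j) || length(cf) < j) NA_real_
        else suppressWarnings(as.numeric(cf[j]))
      }
      rec[[length(rec) + 1L]] <-
        data.frame(id = id, level = level, homo = get("homo"),
                   lumo = get("lumo"), gap = get("gap"))
    }
    i <- i + 2L + nat; block <- block + 1L
  }
  records <- if (length(rec)) do.call(rbind, rec) else .emptyRecords()
  if (nrow(records) && unit == "hartree")
    records[c("homo", "lumo", "gap")] <-
      lapply(records[c("homo", "lumo", "gap")], hartreeToEV)
  if (nrow(records)) records <- .completeRecords(records)
  MoleculeSet(ids = ids, smiles = smi, elements = els, coords = xyz,
              records = records)
}

#' Write a MoleculeSet as extended XYZ
#'
#' The comment line carries `id homo lumo gap` (eV, `NA` when absent) for
#' one level of theory; read back with
#' `readExtendedXYZ(path, propertyCols = c(homo = 2, lumo = 3, gap = 4),
#' idCol = 1, level = level)`. Values are printed with 17 significant
#' digits, so a write/read round trip reproduces coordinates and energies
#' to double precision.
#'
#' @param x a [MoleculeSet-class].
#' @param path output file path.
#' @param level level of theory whose record to place on the comment line
#'   (`NULL` writes the id only).
#' @return `path`, invisibly.
#' @export
writeExtendedXYZ <- function(x, path, level = NULL) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- character()
  rec <- x@records
  for (i in seq_len(nMol(x))) {
    id <- x@ids[i]
    cm <- id
    if (!is.null(level)) {
      r <- rec[rec$id == id & rec$level == level, , drop = FALSE]
      e <- if (nrow(r)) c(r$homo, r$lumo, r$gap) else rep(NA_real_, 3)
      cm <- paste(id, paste(fmt(e), collapse = " "))
    }
    at <- sprintf("%s %s %s %s", x@elements[[i]],
                  fmt(x@coords[[i]][, 1]), fmt(x@coords[[i]][, 2]),
                  fmt(x@coords[[i]][, 3]))
    out <- c(out, as.character(length(x@elements[[i]])), cm, at)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a property table (CSV or JSON lines)
#'
#' Accepts a CSV file or a JSON-lines file (one object per line) with an
#' `id` column and `homo`/`lumo` and/or `gap` columns. Gaps absent from the
#' file are filled as lumo - homo; rows carrying neither a gap nor both
#' orbital energies are an error, as are duplicated ids.
#'
#' @param path file path; `.json`/`.jsonl`/`.ndjson` are parsed as JSON
#'   lines, anything else as CSV.
#' @param level level-of-theory name attached to every record.
#' @param unit `"eV"` (default) or `"hartree"`.
#' @return data.frame with columns id, level, homo, lumo, gap (eV).
#' @export
readPropertyTable <- function(path, level, unit = c("eV", "hartree")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("json", "jsonl", "ndjson")) {
    rows <- lapply(readLines(path), jsonlite::fromJSON)
    num <- function(r, f) if (is.null(r[[f]])) NA_real_ else as.numeric(r[[f]])
    do.call(rbind, lapply(rows, function(r)
      data.frame(id = if (is.null(r$id)) NA_character_ else as.character(r$id),
                 homo = num(r, "homo"), lumo = num(r, "lumo"),
                 gap = num(r, "gap"))))
  } else utils::read.csv(path, stringsAsFactors = FALSE)
  if (ext %in% c("json", "jsonl", "ndjson") && anyNA(tab$id))
    stop("format error: no 'id' column in ", path)
  if (!"id" %in% names(tab)) stop("format error: no 'id' column in ", path)
  if (anyDuplicated(tab$id))
    stop("duplicate id(s) in property table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  rec <- data.frame(id = as.character(tab$id), level = level,
                    homo = if (is.null(tab$homo)) NA_real_ else as.numeric(tab$homo),
                    lumo = if (is.null(tab$lumo)) NA_real_ else as.numeric(tab$lumo),
                    gap = if (is.null(tab$gap)) NA_real_ else as.numeric(tab$gap))
  if (unit == "hartree")
    rec[c("homo", "lumo", "gap")] <- lapply(rec[c("homo", "lumo", "gap")],
                                            hartreeToEV)
  .completeRecords(rec)
}

#' Write a property table as CSV
#'
#' @param records data.frame with columns id, homo, lumo, gap (a `level`
#'   column is dropped; one file per level is the intended layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePropertyTable <- function(records, path) {
  keep <- intersect(c("id", "homo", "lumo", "gap"), names(records))
  utils::write.csv(records[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SMILES list
#'
#' One molecule per line: a SMILES string optionally followed by whitespace
#' and an id. Default ids are `<filestem>_<line index>` (0-based).
#'
#' @param path file path.
#' @return data.frame with columns id and smiles.
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tok <- strsplit(lines, "\\s+")
  stem <- tools::file_path_sans_ext(basename(path))
  data.frame(
    id = vapply(seq_along(tok), function(i)
      if (length(tok[[i]]) > 1) tok[[i]][2] else sprintf("%s_%d", stem, i - 1L), ""),
    smiles = vapply(tok, `[`, "", 1L),
    stringsAsFactors = FALSE)
}
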