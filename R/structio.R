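# Readers and writers for every external format plus the in-memory domain
# types; all downstream stages consume only the objects constructed here.

#' Construct a protein model
#'
#' A `protein_model` holds one single-chain structure with heavy-atom
#' coordinates and a per-residue model-confidence score on the 0--100 pLDDT
#' scale. Residue numbering is 1-based UniProt numbering carried verbatim;
#' hydrogens are never stored.
#'
#' @param model_id character identifier.
#' @param source one of `"alphafold-like"`, `"rosettafold-like"`, `"other"`.
#'   For `rosettafold-like` models whose confidences are all in `[0, 1]` the
#'   values are multiplied by 100 so that a single internal scale is used
#'   (0.7 on that scale is equivalent to 70).
#' @param atoms data.frame with columns `resno`, `resid` (3-letter),
#'   `elety`, `element`, `x`, `y`, `z`, `b`.
#' @return an object of class `protein_model` with elements `model_id`,
#'   `source`, `atoms` (heavy atoms only) and `residues` (data.frame with
#'   `number`, `aa`, `confidence`).
#' @export
protein_model <- function(model_id, source = c("alphafold-like", "rosettafold-like", "other"),
                          atoms) {
  source <- match.arg(source)
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resid", "elety", "element", "x", "y", "z", "b") %in%
                  names(atoms)))
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty model: no heavy atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  # two residue identities sharing one number is a parse error
  byres <- split(atoms$resid, atoms$resno)
  if (any(vapply(byres, function(r) length(unique(r)), 1L) > 1L))
    stop("duplicate residue numbers with conflicting residue types")
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  first <- !duplicated(atoms$resno)
  conf <- atoms$b[first]
  aa <- unname(AA3TO1[atoms$resid[first]])
  aa[is.na(aa)] <- "X"
  if (identical(source, "rosettafold-like") && all(conf <= 1 + 1e-9)) {
    conf <- conf * 100
    atoms$b <- conf[match(atoms$resno, atoms$resno[first])]
  }
  if (any(is.na(conf)) || any(conf < 0) || any(conf > 100 + 1e-6))
    stop("confidence values outside [0, 100] after normalization")
  structure(list(
    model_id = model_id,
    source = source,
    confidence_scale = "0-100",
    atoms = atoms,
    residues = data.frame(number = atoms$resno[first], aa = aa,
                          confidence = conf)
  ), class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s (%s): %d residues, %d heavy atoms, mean confidence %.1f\n",
              x$model_id, x$source, nrow(x$residues), nrow(x$atoms),
              mean(x$residues$confidence)))
  invisible(x)
}

#' Read a structure model from a PDB file
#'
#' Parses the ATOM records of a single-chain PDB file (wwPDB v3.3 column
#' layout, via \pkg{bio3d}). HETATM records and hydrogens are dropped; the
#' per-residue confidence is taken from the B-factor of the first atom of
#' each residue.
#'
#' @param path PDB file.
#' @param source model provenance, see [protein_model()].
#' @param model_id identifier; defaults to the file name.
#' @return a [protein_model()].
#' @export
read_structure <- function(path, source = "alphafold-like",
                           model_id = sub("\\.pdb$", "", basename(path))) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, hex = FALSE, verbose = FALSE)),
    error = function(e) stop("empty model or unreadable file: ", path)
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no ATOM records in ", path)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- element_from_name(at$elety)
  } else {
    miss <- is.na(elem) | elem == ""
    elem[miss] <- element_from_name(at$elety[miss])
  }
  atoms <- data.frame(resno = at$resno, resid = at$resid, elety = at$elety,
                      element = toupper(elem), x = at$x, y = at$y, z = at$z,
                      b = at$b)
  protein_model(model_id, source, atoms)
}

# Derive the element from a PDB atom name: strip digits and primes, take the
# first character (covers C/N/O/S and H for the standard amino-acid names).
#' @keywords internal
element_from_name <- function(elety) {
  s <- gsub("[0-9']", "", trimws(elety))
  substr(s, 1L, 1L)
}

#' Write a structure model as a PDB file
#'
#' @param model a [protein_model()].
#' @param path output file.
#' @param scale_out `"0-100"` (default) writes the confidence as-is in the
#'   B-factor column; `"0-1"` divides by 100 (the RoseTTAFold convention).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, scale_out = c("0-100", "0-1")) {
  scale_out <- match.arg(scale_out)
  a <- model$atoms
  b <- a$b
  if (scale_out == "0-1") {
    conf <- model$residues$confidence[match(a$resno, model$residues$number)]
    b <- conf / 100
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = "A", o = rep(1, nrow(a)), b = b,
                   elesy = a$element)
  invisible(path)
}

#' Construct / read / write a multiple sequence alignment
#'
#' An `msa` stores aligned sequences over the 20 amino acids plus gap.
#' The first sequence is the query and defines the column-to-residue
#' mapping. Taxon identifiers are read from a `TaxID=<n>` token in the
#' FASTA description, when present.
#'
#' @param ids sequence identifiers.
#' @param seqs character vector of aligned sequences (equal lengths).
#' @param taxon integer taxon ids or `NA`.
#' @param query index of the query sequence (default 1).
#' @return an object of class `msa` with a depth x length character matrix
#'   `ali`.
#' @export
msa <- function(ids, seqs, taxon = rep(NA_integer_, length(ids)), query = 1L) {
  stopifnot(length(ids) == length(seqs), length(taxon) == length(ids),
            length(seqs) >= 1L)
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("format error: aligned sequences have unequal lengths")
  ali <- do.call(rbind, strsplit(toupper(seqs), ""))
  bad <- !(ali %in% c(AA1, "X", "-"))
  if (any(bad)) stop("format error: invalid alignment characters: ",
                     paste(unique(ali[bad]), collapse = " "))
  rownames(ali) <- ids
  structure(list(ids = ids, taxon = taxon, ali = ali, query = query,
                 depth = length(ids), length = unique(n)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> depth %d, length %d, query '%s'\n",
              x$depth, x$length, x$ids[x$query]))
  invisible(x)
}

#' @rdname msa
#' @param path aligned FASTA file.
#' @export
read_msa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("format error: not a FASTA file: ", path)
  grp <- cumsum(hdr)
  heads <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("[[:space:]]", "", paste(x, collapse = "")),
                 "")
  if (length(seqs) != length(heads)) stop("format error: empty sequence in ", path)
  ids <- vapply(strsplit(heads, "[[:space:]]+"), `[`, "", 1L)
  taxon <- rep(NA_integer_, length(heads))
  m <- regmatches(heads, regexpr("TaxID=[0-9]+", heads))
  has <- grepl("TaxID=[0-9]+", heads)
  taxon[has] <- as.integer(sub("TaxID=", "", m))
  msa(ids, unname(seqs), taxon)
}

#' @rdname msa
#' @param x an `msa` object.
#' @export
write_msa <- function(x, path) {
  hd <- paste0(">", x$ids,
               ifelse(is.na(x$taxon), "", paste0(" TaxID=", x$taxon)))
  seq <- apply(x$ali, 1L, paste, collapse = "")
  writeLines(as.vector(rbind(hd, seq)), path)
  invisible(path)
}

# category alias table: humsavar-style labels to the internal vocabulary
CATEGORY_ALIASES <- c(
  "disease" = "disease", "polymorphism" = "polymorphism",
  "unclassified" = "unclassified",
  "LP/P" = "disease", "LB/B" = "polymorphism", "US" = "unclassified"
)

#' Read / write a mutation table
#'
#' Tab-separated with header columns `accession`, `position`, `wild`,
#' `mutant`, `category`, `disease`. Categories outside the vocabulary
#' (`disease`, `polymorphism`, `unclassified`) are mapped through the
#' humsavar alias table (`LP/P`, `LB/B`, `US`) and then validated. Rows
#' with identical wild and mutant residues are rejected with a warning.
#'
#' @param path TSV file.
#' @return a data.frame of class `mutation_table` with columns `accession`,
#'   `position`, `wild_aa`, `mutant_aa`, `category`, `disease_name`.
#' @export
read_mutations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("accession", "position", "wild", "mutant", "category", "disease")
  if (!all(need %in% names(d)))
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  mutation_table(data.frame(
    accession = d$accession, position = as.integer(d$position),
    wild_aa = toupper(d$wild), mutant_aa = toupper(d$mutant),
    category = d$category, disease_name = d$disease,
    stringsAsFactors = FALSE))
}

#' @rdname read_mutations
#' @param records data.frame with the `mutation_table` columns.
#' @export
mutation_table <- function(records) {
  cat0 <- CATEGORY_ALIASES[records$category]
  if (any(is.na(cat0)))
    stop("unknown mutation categories: ",
         paste(unique(records$category[is.na(cat0)]), collapse = ", "))
  records$category <- unname(cat0)
  same <- records$wild_aa == records$mutant_aa
  if (any(same)) {
    warning(sum(same), " record(s) rejected: wild residue equals mutant residue")
    records <- records[!same, , drop = FALSE]
  }
  rownames(records) <- NULL
  class(records) <- c("mutation_table", "data.frame")
  records
}

#' @rdname read_mutations
#' @param x a `mutation_table`.
#' @export
write_mutations <- function(x, path) {
  out <- data.frame(accession = x$accession, position = x$position,
                    wild = x$wild_aa, mutant = x$mutant_aa,
                    category = x$category, disease = x$disease_name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct predictor-output tables
#'
#' Holds the per-position and per-mutation predictor outputs the pipeline
#' consumes: ligand-binding probability (P2Rank-style, in `[0,1]`),
#' interface score (meta-PPISP-style), FoldX-convention ddG (positive =
#' destabilizing), DynaMut2-convention ddG (negative = destabilizing),
#' pathogenicity score (MutPred2-style, in `[0,1]`) and per-residue
#' disorder probability (IUPred2A-style, in `[0,1]`).
#'
#' @param ligand_prob,interface_score,disorder_prob numeric vectors named by
#'   residue position.
#' @param foldx_ddg,dynamut_ddg,pathogenicity data.frames with columns
#'   `position`, `mutant`, `value`.
#' @param model optional [protein_model()] used to validate positions.
#' @return an object of class `predictor_tables`.
#' @export
predictor_tables <- function(ligand_prob, interface_score, foldx_ddg,
                             dynamut_ddg, pathogenicity, disorder_prob,
                             model = NULL) {
  chk01 <- function(v, what) {
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      stop(what, " outside [0, 1]")
    v
  }
  chk01(ligand_prob, "ligand probabilities")
  chk01(disorder_prob, "disorder probabilities")
  chk01(pathogenicity$value, "pathogenicity scores")
  for (d in list(foldx_ddg, dynamut_ddg, pathogenicity))
    stopifnot(all(c("position", "mutant", "value") %in% names(d)))
  if (!is.null(model)) {
    pos <- c(as.integer(names(ligand_prob)), as.integer(names(interface_score)),
             as.integer(names(disorder_prob)), foldx_ddg$position,
             dynamut_ddg$position, pathogenicity$position)
    if (!all(pos %in% model$residues$number))
      stop("predictor tables reference positions absent from the model")
  }
  structure(list(ligand_prob = ligand_prob, interface_score = interface_score,
                 foldx_ddg = foldx_ddg, dynamut_ddg = dynamut_ddg,
                 pathogenicity = pathogenicity, disorder_prob = disorder_prob),
            class = "predictor_tables")
}

# lookup of a per-mutation value; NA when absent
#' @keywords internal
lookup_mutation_value <- function(tab, position, mutant) {
  i <- match(paste(position, mutant), paste(tab$position, tab$mutant))
  tab$value[i]
}

#' Read / write predictor tables from a directory of TSV files
#'
#' Files `ligand.tsv`, `interface.tsv`, `disorder.tsv` have columns
#' `position`, `value`; `foldx.tsv`, `dynamut.tsv`, `pathogenicity.tsv`
#' have columns `position`, `mutant`, `value`.
#'
#' @param dir directory containing the six TSV files.
#' @param model optional [protein_model()] for position validation.
#' @return a [predictor_tables()].
#' @export
read_predictors <- function(dir, model = NULL) {
  rd1 <- function(f) {
    d <- read.delim(file.path(dir, f))
    setNames(d$value, d$position)
  }
  rd2 <- function(f) {
    d <- read.delim(file.path(dir, f), colClasses = c("integer", "character", "numeric"))
    d
  }
  predictor_tables(rd1("ligand.tsv"), rd1("interface.tsv"),
                   rd2("foldx.tsv"), rd2("dynamut.tsv"),
                   rd2("pathogenicity.tsv"), rd1("disorder.tsv"),
                   model = model)
}

#' @rdname read_predictors
#' @param tables a [predictor_tables()].
#' @export
write_predictors <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr1 <- function(v, f) {
    write.table(data.frame(position = as.integer(names(v)), value = unname(v)),
                file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr2 <- function(d, f) {
    write.table(d[, c("position", "mutant", "value")], file.path(dir, f),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr1(tables$ligand_prob, "ligand.tsv")
  wr1(tables$interface_score, "interface.tsv")
  wr1(tables$disorder_prob, "disorder.tsv")
  wr2(tables$foldx_ddg, "foldx.tsv")
  wr2(tables$dynamut_ddg, "dynamut.tsv")
  wr2(tables$pathogenicity, "pathogenicity.tsv")
  invisible(dir)
}

#' Construct a domain segment
#'
#' Inclusive residue ranges in sequence numbering, with the family class the
#' domain was assigned to (`CATH`, `Pfam` or `unassigned`). Unassigned
#' segments must span at least 50 residues.
#'
#' @param accession protein accession.
#' @param ranges two-column matrix (start, end), inclusive.
#' @param family_class one of `"CATH"`, `"Pfam"`, `"unassigned"`.
#' @return an object of class `domain_segment`.
#' @export
domain_segment <- function(accession, ranges, family_class = c("CATH", "Pfam", "unassigned")) {
  family_class <- match.arg(family_class)
  ranges <- matrix(as.integer(ranges), ncol = 2)
  ranges <- ranges[order(ranges[, 1]), , drop = FALSE]
  stopifnot(all(ranges[, 2] >= ranges[, 1]))
  if (nrow(ranges) > 1 && any(ranges[-1, 1] <= ranges[-nrow(ranges), 2]))
    stop("segment ranges overlap")
  if (family_class == "unassigned" && sum(ranges[, 2] - ranges[, 1] + 1L) < 50L)
    stop("unassigned segments must be at least 50 residues long")
  structure(list(accession = accession, ranges = ranges,
                 family_class = family_class),
            class = "domain_segment")
}

#' Residue positions covered by a domain segment
#' @param segment a [domain_segment()].
#' @return integer vector of positions.
#' @export
segment_positions <- function(segment) {
  unlist(lapply(seq_len(nrow(segment$ranges)),
                function(i) seq.int(segment$ranges[i, 1], segment$ranges[i, 2])))
}
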