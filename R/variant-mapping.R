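#' @keywords internal
#' @name aa-codes
NULL

.aa1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.aa3 <- setNames(names(.aa1), unname(.aa1))

#' Parse a protein-change string into a missense record
#'
#' Accepts HGVS-like notation, `"p.I145M"`, `"I145M"` or three-letter
#' `"p.Arg229Gln"`. Non-missense changes (synonymous, nonsense `*`/`Ter`,
#' frameshift `fs`, deletions/insertions) are rejected.
#'
#' @param text protein-change string.
#' @return List with `aa_ref`, `aa_pos`, `aa_alt` (one-letter codes,
#'   1-based reference-isoform position).
#' @export
parse_protein_change <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- sub("^p\\.", "", trimws(text))
  if (grepl("fs|del|ins|dup|ext", s, ignore.case = TRUE))
    stop("not missense: '", text, "' (frameshift/indel)")
  m <- regmatches(s, regexec("^([A-Za-z*=]+?)([0-9]+)([A-Za-z*=]+)$", s))[[1L]]
  if (length(m) != 4L)
    stop("malformed protein change: '", text, "'")
  ref <- normalize_aa(m[2L], text)
  alt_tok <- m[4L]
  if (alt_tok %in% c("*", "Ter", "TER", "X") )
    stop("not missense: '", text, "' (nonsense)")
  if (alt_tok == "=")
    stop("not missense: '", text, "' (synonymous)")
  alt <- normalize_aa(alt_tok, text)
  if (ref == alt)
    stop("not missense: '", text, "' (reference equals alternate)")
  pos <- as.integer(m[3L])
  if (pos < 1L) stop("malformed protein change: '", text, "' (position < 1)")
  list(aa_ref = ref, aa_pos = pos, aa_alt = alt)
}

normalize_aa <- function(tok, text) {
  if (nchar(tok) == 1L) {
    up <- toupper(tok)
    if (!up %in% names(.aa1)) stop("unknown residue code '", tok, "' in '", text, "'")
    return(up)
  }
  up3 <- toupper(tok)
  if (!up3 %in% names(.aa3)) stop("unknown residue code '", tok, "' in '", text, "'")
  unname(.aa3[up3])
}

#' Load missense variants from a delimited table snapshot
#'
#' Reads a local TSV/CSV snapshot (e.g. a COSMIC export), parses the
#' protein-change column, keeps missense records for the requested gene,
#' and deduplicates on (ref, pos, alt). Non-missense or malformed rows
#' are counted and reported via a message, never fatal.
#'
#' @param file path to the delimited table.
#' @param gene gene symbol to keep; `NULL` keeps all rows.
#' @param change_col,gene_col,id_col,annotation_col column names holding
#'   the protein change, gene symbol, record id and free-text annotation.
#' @param sep field separator (default tab).
#' @return Data frame of variant records: `gene`, `aa_ref`, `aa_pos`,
#'   `aa_alt`, `source_id`, `annotation`.
#' @export
load_variant_table <- function(file, gene = NULL, change_col = "protein_change",
                               gene_col = "gene", id_col = NULL,
                               annotation_col = NULL, sep = "\t") {
  tab <- utils::read.delim(file, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!change_col %in% names(tab))
    stop("column '", change_col, "' not found in ", file)
  if (!is.null(gene)) {
    if (!gene_col %in% names(tab))
      stop("column '", gene_col, "' not found in ", file)
    tab <- tab[tab[[gene_col]] == gene, , drop = FALSE]
  }
  skipped <- 0L
  recs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tryCatch(parse_protein_change(tab[[change_col]][i]), error = function(e) NULL)
    if (is.null(p)) { skipped <- skipped + 1L; next }
    recs[[i]] <- data.frame(
      gene = if (!is.null(gene)) gene else
        if (gene_col %in% names(tab)) as.character(tab[[gene_col]][i]) else NA_character_,
      aa_ref = p$aa_ref, aa_pos = p$aa_pos, aa_alt = p$aa_alt,
      source_id = if (!is.null(id_col)) as.character(tab[[id_col]][i]) else NA_character_,
      annotation = if (!is.null(annotation_col)) as.character(tab[[annotation_col]][i]) else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(gene = character(), aa_ref = character(), aa_pos = integer(),
                      aa_alt = character(), source_id = character(),
                      annotation = character(), stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("aa_ref", "aa_pos", "aa_alt")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (skipped > 0L)
    message(skipped, " non-missense/unparseable row(s) skipped")
  if (nrow(out) == 0L)
    warning("no missense records found", if (!is.null(gene)) paste0(" for gene ", gene))
  out
}

#' Global alignment map between a reference isoform and a structure sequence
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend
#' 0.5, via [Biostrings::pairwiseAlignment()]) between the reference
#' isoform and the sequence observed in the structure. Returns the
#' matched (ref, target) position pairs; positions aligned to gaps are
#' absent.
#'
#' @param ref_seq reference isoform sequence (one-letter string).
#' @param target_seq structure-derived sequence (one-letter string).
#' @return Data frame `ref_pos`, `target_pos`, strictly increasing in
#'   both columns.
#' @export
align_sequences <- function(ref_seq, target_seq) {
  stopifnot(nchar(ref_seq) > 0L, nchar(target_seq) > 0L)
  data(list = "BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    pattern = ref_seq, subject = target_seq, type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  rp <- cumsum(p != "-")
  sp <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  data.frame(ref_pos = rp[keep], target_pos = sp[keep])
}

#' Sequence observed in a structure chain
#'
#' One row per amino acid residue (CA-bearing), in file order, with its
#' chain, author residue number, insertion code and one-letter code.
#'
#' @param model a `StructureModel` or `Trajectory`.
#' @param chain chain identifier; `NULL` uses the first protein chain.
#' @return Data frame `chain`, `resno`, `insert`, `aa`, plus the
#'   concatenated sequence as attribute `"sequence"`.
#' @export
structure_sequence <- function(model, chain = NULL) {
  a <- model$atoms
  ca <- a[a$elety == "CA" & a$resid %in% names(.aa3), , drop = FALSE]
  if (is.null(chain)) chain <- ca$chain[1L]
  ca <- ca[ca$chain == chain, , drop = FALSE]
  if (nrow(ca) == 0L) stop("no amino acid residues in chain ", chain)
  out <- data.frame(chain = ca$chain, resno = ca$resno, insert = ca$insert,
                    aa = unname(.aa3[ca$resid]), stringsAsFactors = FALSE)
  attr(out, "sequence") <- paste(out$aa, collapse = "")
  out
}

#' Map a variant record onto a structure residue
#'
#' Follows the isoform-to-structure alignment to the structure residue
#' aligned with `aa_pos` and verifies that the residue identity there
#' matches `aa_ref` (guarding against numbering drift between isoforms).
#'
#' @param v variant record (list/row with `aa_ref`, `aa_pos`, `aa_alt`).
#' @param iso_map alignment map from [align_sequences()] (reference
#'   isoform vs. the structure sequence).
#' @param struct_seq structure sequence table from [structure_sequence()]
#'   (rows in target-sequence order).
#' @return List `chain`, `resno`, `insert`; or the string `"unmapped"`
#'   when `aa_pos` is aligned to a gap (e.g. a disordered residue).
#' @export
map_variant <- function(v, iso_map, struct_seq) {
  hit <- which(iso_map$ref_pos == v$aa_pos)
  if (length(hit) == 0L) return("unmapped")
  tp <- iso_map$target_pos[hit[1L]]
  if (tp < 1L || tp > nrow(struct_seq)) return("unmapped")
  row <- struct_seq[tp, ]
  if (row$aa != v$aa_ref)
    stop("reference mismatch: variant expects ", v$aa_ref, " at reference position ",
         v$aa_pos, " but the structure has ", row$aa, " at ", row$chain, ":", row$resno)
  list(chain = row$chain, resno = row$resno, insert = row$insert)
}

#' Uniform random sample of variant records
#'
#' Order-normalizes the records (by position, then ref/alt) and draws
#' `k` distinct records uniformly without replacement; fully determined
#' by `seed` (Mersenne-Twister) and stable across runs.
#'
#' @param records variant record data frame.
#' @param k sample size.
#' @param seed integer RNG seed.
#' @return Data frame of `k` records.
#' @export
sample_variants <- function(records, k, seed) {
  if (k > nrow(records))
    stop("k = ", k, " exceeds the ", nrow(records), " available records")
  ord <- order(records$aa_pos, records$aa_ref, records$aa_alt)
  records <- records[ord, , drop = FALSE]
  idx <- with_seed(seed, sample.int(nrow(records), k, replace = FALSE))
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Introduce a single point mutation into a structure model
#'
#' Renames the residue and truncates its side chain at C-beta (kept
#' atoms: N, CA, C, O, CB, OXT and backbone hydrogens), the standard
#' hand-off convention when rotamer rebuilding is delegated to a
#' downstream modelling step. Mutations to glycine also remove CB. All
#' other residues are untouched.
#'
#' @param model a `StructureModel`.
#' @param site residue to mutate: list/row with `chain`, `resno`
#'   (optionally `insert`).
#' @param aa_alt target amino acid, one-letter code.
#' @return Mutated `StructureModel`.
#' @export
mutate_structure <- function(model, site, aa_alt) {
  if (!aa_alt %in% names(.aa1)) stop("unknown target amino acid '", aa_alt, "'")
  key <- paste0(site$chain, ":", site$resno,
                if (!is.null(site$insert) && !is.na(site$insert) && site$insert != "") site$insert else "")
  keys <- residue_keys(model)
  idx <- which(keys == key)
  if (length(idx) == 0L) stop("no residue ", key, " in the model")
  res <- model$atoms$resid[idx[1L]]
  if (!res %in% names(.aa3))
    stop("residue ", key, " is ", res, ", not a standard amino acid")
  keep_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA", "HA2", "HA3")
  if (aa_alt != "G") keep_names <- c(keep_names, "CB")
  drop <- idx[!model$atoms$elety[idx] %in% keep_names]
  out <- if (length(drop)) subset_atoms(model, setdiff(seq_len(nrow(model$atoms)), drop)) else model
  out$atoms$resid[residue_keys(out) == key] <- unname(.aa1[aa_alt])
  out
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1; reflections are corrected
#' by the usual sign flip of the smallest singular direction) and
#' translation minimizing the RMSD between two matched point sets, via
#' singular value decomposition of the cross-covariance matrix.
#'
#' @param coords_a,coords_b n x 3 matrices of matched points (angstrom).
#'   The transform maps `coords_a` onto `coords_b`.
#' @return List `rotation` (3 x 3), `translation` (length 3), `rmsd`;
#'   `rotation %*% a + translation` superposes a onto b.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("point sets differ in shape")
  if (nrow(a) < 3L) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2L, ca); bc <- sweep(b, 2L, cb)
  sv <- svd(ac)$d
  if (sv[2L] < 1e-10 * max(sv[1L], 1))  # rank < 2: all points collinear
    warning("near-collinear point set; rotation may be ill-determined")
  h <- crossprod(ac, bc)             # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - as.vector(r %*% ca)
  fit <- sweep(ac %*% t(r), 2L, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fit - b)^2)))
  list(rotation = r, translation = tr, rmsd = rmsd)
}

#' Emit single-mutation model files plus a manifest
#'
#' For each sampled record, maps it onto the structure, writes one PDB
#' named `<gene>_<ref><pos><alt>.pdb` with the side chain truncated at
#' C-beta, and records the mapping (and any skipped records) together
#' with the sampling seed in `manifest.json`.
#'
#' @param model reference `StructureModel`.
#' @param records sampled variant records (see [sample_variants()]).
#' @param iso_map,struct_seq see [map_variant()].
#' @param out_dir output directory (created if needed).
#' @param gene gene symbol used in file names.
#' @param seed the sampling seed, recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_variant_models <- function(model, records, iso_map, struct_seq, out_dir,
                                 gene = "GENE", seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mapped <- list(); skipped <- list()
  for (i in seq_len(nrow(records))) {
    v <- records[i, ]
    tag <- paste0(v$aa_ref, v$aa_pos, v$aa_alt)
    site <- tryCatch(map_variant(v, iso_map, struct_seq), error = function(e) conditionMessage(e))
    if (is.character(site)) { skipped[[tag]] <- site; next }
    mut <- mutate_structure(model, site, v$aa_alt)
    f <- file.path(out_dir, paste0(gene, "_", tag, ".pdb"))
    write_structure(mut, f)
    mapped[[tag]] <- list(chain = site$chain, resno = site$resno, file = basename(f))
  }
  manifest <- list(gene = gene, seed = seed, rng = "Mersenne-Twister",
                   mapped = mapped, skipped = skipped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
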