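#' Construct a gap-free TM alignment
#'
#' @param seqs an [Biostrings::AAStringSet] (or named character vector) of
#'   171-residue aligned records with unique names.
#' @param species character vector of species labels, parallel to `seqs`
#'   (recycled if length 1).
#' @param helixMeta optional per-helix metadata data.frame with columns
#'   `id`, `helix`, `offset`, `score`, `pass`.
#' @return A [TMAlignment-class].
#' @examples
#' aln <- TMAlignment(
#'   setNames(strrep("A", 171), "rec1"), species = "human")
#' nrecords(aln)
#' @export
TMAlignment <- function(seqs, species,
                        helixMeta = .emptyHelixMeta()) {
    if (!methods::is(seqs, "AAStringSet"))
        seqs <- Biostrings::AAStringSet(seqs)
    species <- rep_len(as.character(species), length(seqs))
    new("TMAlignment", seqs = seqs, species = species,
        helixMeta = helixMeta)
}

.emptyHelixMeta <- function() {
    data.frame(id = character(), helix = integer(), offset = integer(),
               score = numeric(), pass = logical())
}

#' @rdname TMAlignment
#' @aliases nrecords
#' @param x,object a [TMAlignment-class].
#' @export
setGeneric("nrecords", function(x) standardGeneric("nrecords"))

#' @rdname TMAlignment
#' @export
setMethod("nrecords", "TMAlignment", function(x) length(x@seqs))

#' @rdname TMAlignment
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname TMAlignment
#' @export
setMethod("recordIds", "TMAlignment", function(x) names(x@seqs))

#' @rdname TMAlignment
#' @export
setGeneric("recordSpecies", function(x) standardGeneric("recordSpecies"))

#' @rdname TMAlignment
#' @export
setMethod("recordSpecies", "TMAlignment", function(x)
    stats::setNames(x@species, names(x@seqs)))

#' @rdname TMAlignment
#' @export
setGeneric("tmSequences", function(x) standardGeneric("tmSequences"))

#' @rdname TMAlignment
#' @export
setMethod("tmSequences", "TMAlignment", function(x) x@seqs)

#' @rdname TMAlignment
#' @export
setGeneric("helixMetadata", function(x) standardGeneric("helixMetadata"))

#' @rdname TMAlignment
#' @export
setMethod("helixMetadata", "TMAlignment", function(x) x@helixMeta)

#' @rdname TMAlignment
#' @param i record selector: indices, logical mask, or record ids.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TMAlignment", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) {
        miss <- setdiff(i, names(x@seqs))
        if (length(miss))
            stop("unknown record id(s): ", paste(miss, collapse = ", "))
        i <- match(i, names(x@seqs))
    }
    ids <- names(x@seqs)[i]
    meta <- x@helixMeta[x@helixMeta$id %in% ids, , drop = FALSE]
    rownames(meta) <- NULL
    new("TMAlignment", seqs = x@seqs[i], species = x@species[i],
        helixMeta = meta)
})

#' @rdname TMAlignment
#' @export
setMethod("as.matrix", "TMAlignment", function(x, ...) {
    m <- .charMatrix(as.character(x@seqs))
    colnames(m) <- as.character(tmPositions())
    m
})

#' @rdname TMAlignment
#' @export
setMethod("show", "TMAlignment", function(object) {
    cat("TMAlignment with", length(object@seqs),
        "record(s) over 171 TM columns\n")
    sp <- unique(object@species)
    cat("  species:", length(sp[!is.na(sp)]), "distinct\n")
    if (nrow(object@helixMeta)) {
        fails <- tapply(!object@helixMeta$pass, object@helixMeta$id, sum)
        cat("  helix metadata for", length(fails), "record(s); median",
            "failed helices:", stats::median(fails), "\n")
    }
    invisible(object)
})

#' Extract one alignment column
#'
#' @param aln a [TMAlignment-class].
#' @param position a BW label (e.g. `"3.32"`) or [BWPosition-class] of
#'   length 1.
#' @return Named character vector of one residue per record.
#' @export
tmColumn <- function(aln, position) {
    if (methods::is(position, "BWPosition"))
        position <- as.character(position)
    all_pos <- as.character(tmPositions())
    idx <- match(position, all_pos)
    if (anyNA(idx))
        stop("not a TM position: ", position)
    res <- as.character(Biostrings::subseq(aln@seqs, idx, idx))
    stats::setNames(res, names(aln@seqs))
}

## ---- FASTA I/O -----------------------------------------------------------
## Header dialect: ">id|species". Species is required by the database-stage
## filters; readers keep it verbatim.

.parseHeaders <- function(headers, requireSpecies = TRUE) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    id <- vapply(parts, `[`, "", 1L)
    species <- vapply(parts, function(p)
        if (length(p) >= 2L) p[[2L]] else NA_character_, "")
    if (any(id == ""))
        stop("unparseable FASTA header(s): empty id")
    if (requireSpecies && anyNA(species))
        stop("unparseable FASTA header(s): expected 'id|species', got: ",
             paste(utils::head(headers[is.na(species)], 3L),
                   collapse = ", "))
    list(id = id, species = species)
}

#' Read and write aligned TM FASTA
#'
#' `readTMFasta()` reads a FASTA file in the aligned-TM dialect: one
#' 171-residue record per receptor (the concatenated helix segments in
#' canonical column order) with headers `"id|species"`. `writeTMFasta()`
#' writes it back; the round trip is lossless. Per-helix metadata travels
#' in a TSV sidecar handled by [readHelixMeta()] / [writeHelixMeta()].
#'
#' @param path file path.
#' @return `readTMFasta()`: a [TMAlignment-class].
#' @export
readTMFasta <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    hdr <- .parseHeaders(names(seqs))
    if (anyDuplicated(hdr$id))
        stop("duplicate record id(s): ",
             paste(unique(hdr$id[duplicated(hdr$id)]), collapse = ", "))
    if (any(Biostrings::width(seqs) != 171L))
        stop("record(s) of wrong length (expected 171 TM columns): ",
             paste(hdr$id[Biostrings::width(seqs) != 171L], collapse = ", "))
    names(seqs) <- hdr$id
    TMAlignment(seqs, hdr$species)
}

#' @rdname readTMFasta
#' @param aln a [TMAlignment-class].
#' @export
writeTMFasta <- function(aln, path) {
    out <- aln@seqs
    names(out) <- paste(names(aln@seqs), aln@species, sep = "|")
    Biostrings::writeXStringSet(out, path)
    invisible(path)
}

#' @rdname readTMFasta
#' @export
writeHelixMeta <- function(aln, path) {
    utils::write.table(aln@helixMeta, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname readTMFasta
#' @export
readHelixMeta <- function(path) {
    meta <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE,
                              colClasses = c(id = "character"))
    need <- c("id", "helix", "offset", "score", "pass")
    if (!all(need %in% names(meta)))
        stop("helix metadata must have columns ",
             paste(need, collapse = ", "))
    meta
}

#' Read unaligned protein FASTA
#'
#' Reads candidate full-length protein sequences with `"id|species"`
#' headers (species may be absent, in which case it is `NA` and the
#' species-count filters will refuse to run).
#'
#' @param path file path.
#' @return List with elements `seqs` ([Biostrings::AAStringSet], named by
#'   id) and `species` (named character).
#' @export
readProteinFasta <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    hdr <- .parseHeaders(names(seqs), requireSpecies = FALSE)
    if (anyDuplicated(hdr$id))
        stop("duplicate record id(s): ",
             paste(unique(hdr$id[duplicated(hdr$id)]), collapse = ", "))
    names(seqs) <- hdr$id
    list(seqs = seqs, species = stats::setNames(hdr$species, hdr$id))
}
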