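## Synthetic benchmark data with the statistical structure the
## two-entropy score assumes: subfamily-conserved binding columns,
## globally conserved structural columns, i.i.d. background columns, and
## full-length sequences with planted in-order helix motifs.

#' Construct a synthetic alignment specification
#'
#' The defaults describe the benchmark condition used throughout the
#' package's tests: 10 subfamilies of 60 sequences (600 records), 5
#' planted binding columns shared by all subfamilies (each subfamily
#' conserving its own letter there, as real receptor subfamilies do at
#' pocket positions such as 3.32), 10 globally conserved structural
#' columns at the most conserved helix anchors, within-subfamily
#' conservation 0.95, and a uniform background over the 20 amino acids -
#' leaving 156 pure background columns.
#'
#' @param nSubfamilies number of subfamilies.
#' @param size sequences per subfamily (recycled to `nSubfamilies`).
#' @param bindingPositions either a character vector of BW labels shared
#'   by all subfamilies, or a list with one set per subfamily.
#' @param structuralPositions BW labels of globally conserved columns.
#' @param conservation within-subfamily conservation probability of a
#'   binding column.
#' @param structuralConservation conservation probability of structural
#'   columns across all records.
#' @param background `"uniform"`, `"swissprot"`, or a named length-20
#'   frequency vector.
#' @param species species labels recycled over records.
#' @param seed RNG seed used by [simulateMSA()].
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nSubfamilies = 10L, size = 60L,
                          bindingPositions = c("3.32", "3.33", "5.42",
                                               "6.55", "7.39"),
                          structuralPositions = c("1.50", "2.46", "2.50",
                                                  "3.50", "4.50", "5.50",
                                                  "6.48", "6.50", "7.49",
                                                  "7.50"),
                          conservation = 0.95,
                          structuralConservation = 0.95,
                          background = "uniform",
                          species = c("human", "mouse", "rat", "bovine",
                                      "chicken"),
                          seed = 1L) {
    if (!is.list(bindingPositions))
        bindingPositions <- rep(list(as.character(bindingPositions)),
                                nSubfamilies)
    if (is.character(background) && length(background) == 1L)
        background <- bgFrequencies(background)
    new("SyntheticSpec",
        subfamilySizes = rep_len(as.integer(size), nSubfamilies),
        bindingPositions = bindingPositions,
        structuralPositions = as.character(structuralPositions),
        conservation = conservation,
        structuralConservation = structuralConservation,
        background = background[AA20],
        species = as.character(species),
        seed = as.integer(seed))
}

#' @export
setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", length(object@subfamilySizes),
        "subfamilies,", sum(object@subfamilySizes), "records\n")
    cat("  binding columns per subfamily:",
        paste(lengths(object@bindingPositions), collapse = ","),
        "| structural columns:", length(object@structuralPositions), "\n")
    cat("  conservation:", object@conservation,
        "| structural:", object@structuralConservation,
        "| seed:", object@seed, "\n")
    invisible(object)
})

#' Generate a synthetic multi-subfamily TM alignment
#'
#' Draws an alignment according to a [SyntheticSpec-class]: structural
#' columns conserve one letter across all records with their conservation
#' probability; each subfamily's binding columns conserve a
#' subfamily-specific letter with probability `conservation` inside that
#' subfamily and are background-distributed outside; all remaining
#' columns are i.i.d. background. Deterministic for a given seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param seed RNG seed; defaults to the seed stored in the spec.
#' @return List with `alignment` (a [TMAlignment-class]), and `truth`: a
#'   list of `records` (data.frame `id`, `subfamily`, `species`),
#'   `columns` (data.frame `position`, `role` in
#'   binding/structural/background) and `letters` (data.frame
#'   `subfamily`, `position`, `letter`: the planted conserved letters).
#' @export
simulateMSA <- function(spec, seed = spec@seed) {
    sizes <- spec@subfamilySizes
    n <- sum(sizes)
    positions <- as.character(tmPositions())
    L <- length(positions)
    subfam <- rep(seq_along(sizes), sizes)
    ids <- sprintf("sf%02d_r%03d", subfam,
                   unlist(lapply(sizes, seq_len)))
    species <- rep_len(spec@species, n)

    withSeed(seed, {
        M <- matrix(sample(AA20, n * L, replace = TRUE,
                           prob = spec@background), n, L)
        colnames(M) <- positions
        rownames(M) <- ids
        for (p in spec@structuralPositions) {
            a <- sample(AA20, 1L)
            hit <- stats::runif(n) < spec@structuralConservation
            M[hit, p] <- a
        }
        letters <- list()
        for (k in seq_along(sizes)) {
            rows <- which(subfam == k)
            for (p in spec@bindingPositions[[k]]) {
                a <- sample(AA20, 1L)
                hit <- stats::runif(length(rows)) < spec@conservation
                M[rows[hit], p] <- a
                letters[[length(letters) + 1L]] <-
                    data.frame(subfamily = k, position = p, letter = a)
            }
        }
        letters <- if (length(letters)) do.call(rbind, letters) else
            data.frame(subfamily = integer(), position = character(),
                       letter = character())
        role <- rep("background", L)
        role[positions %in% unique(unlist(spec@bindingPositions))] <-
            "binding"
        role[positions %in% spec@structuralPositions] <- "structural"
        aln <- TMAlignment(stats::setNames(
            apply(M, 1L, paste, collapse = ""), ids), species)
        list(alignment = aln,
             truth = list(records = data.frame(id = ids,
                                               subfamily = subfam,
                                               species = species),
                          columns = data.frame(position = positions,
                                               role = role),
                          letters = letters))
    })
}

#' Generate full-length sequences with planted helix motifs
#'
#' Builds test inputs for the alignment pipeline: "planted" records embed
#' the consensus of all seven helix profiles in helix order, separated by
#' random background linkers and flanked by random termini (their true
#' offsets are returned); "decoy" records are residue-frequency-matched
#' shuffles of planted records, so they have the same composition and
#' length but no helix signal.
#'
#' @param profiles list of 7 [HelixProfile-class].
#' @param nPlanted,nDecoy numbers of planted and decoy records.
#' @param seed RNG seed.
#' @param linkerRange inclusive range of the random inter-helix linker
#'   lengths (may be `c(0, 0)` for adjacent helices).
#' @param terminalRange inclusive range of the random N/C-terminal tail
#'   lengths.
#' @param background letter distribution of linkers and tails.
#' @return List with `seqs` (named character vector), `species` (named,
#'   all `"synthetic"`), and `truth` (data.frame `id`, `planted`, and
#'   columns `offset1`..`offset7` of true 0-based helix offsets, `NA` for
#'   decoys).
#' @export
simulateHelixSequences <- function(profiles, nPlanted = 20L, nDecoy = 20L,
                                   seed = 1L, linkerRange = c(2L, 15L),
                                   terminalRange = c(5L, 40L),
                                   background = bgFrequencies("uniform")) {
    consensus <- vapply(profiles, profileConsensus, "")
    lens <- nchar(consensus)
    rint <- function(range) if (range[1L] == range[2L]) range[1L] else
        sample(range[1L]:range[2L], 1L)
    withSeed(seed, {
        seqs <- character(0)
        truth <- list()
        for (i in seq_len(nPlanted)) {
            id <- sprintf("planted_%03d", i)
            parts <- paste(sample(AA20, rint(terminalRange), TRUE,
                                  prob = background), collapse = "")
            offsets <- integer(7)
            for (h in 1:7) {
                offsets[h] <- nchar(parts)
                parts <- paste0(parts, consensus[h])
                if (h < 7L)
                    parts <- paste0(parts,
                                    paste(sample(AA20, rint(linkerRange),
                                                 TRUE, prob = background),
                                          collapse = ""))
            }
            parts <- paste0(parts,
                            paste(sample(AA20, rint(terminalRange), TRUE,
                                         prob = background), collapse = ""))
            seqs[id] <- parts
            truth[[id]] <- data.frame(id = id, planted = TRUE,
                                      t(stats::setNames(offsets,
                                            paste0("offset", 1:7))))
        }
        for (i in seq_len(nDecoy)) {
            id <- sprintf("decoy_%03d", i)
            src <- seqs[[((i - 1L) %% max(nPlanted, 1L)) + 1L]]
            seqs[id] <- paste(sample(strsplit(src, "")[[1L]]),
                              collapse = "")
            truth[[id]] <- data.frame(id = id, planted = FALSE,
                                      t(stats::setNames(rep(NA_integer_, 7),
                                            paste0("offset", 1:7))))
        }
        list(seqs = seqs,
             species = stats::setNames(rep("synthetic", length(seqs)),
                                       names(seqs)),
             truth = do.call(rbind, c(truth, make.row.names = FALSE)))
    })
}
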