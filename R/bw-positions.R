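#' Parse Ballesteros-Weinstein labels
#'
#' Parses labels of the form `"<helix>.<index>"` (e.g. `"3.32"`) into a
#' [BWPosition-class] vector. Parsing and rendering are exact inverses.
#'
#' @param labels character vector of BW labels.
#' @return A [BWPosition-class] of the same length.
#' @examples
#' parseBW(c("3.32", "7.39"))
#' @export
parseBW <- function(labels) {
    labels <- as.character(labels)
    ok <- grepl("^[0-9]\\.[0-9]+$", labels)
    if (!all(ok))
        stop("malformed BW label(s): ",
             paste(labels[!ok], collapse = ", "))
    parts <- strsplit(labels, ".", fixed = TRUE)
    helix <- as.integer(vapply(parts, `[`, "", 1L))
    index <- as.integer(vapply(parts, `[`, "", 2L))
    if (any(helix < 1L | helix > 7L))
        stop("helix outside 1..7 in label(s): ",
             paste(labels[helix < 1L | helix > 7L], collapse = ", "))
    new("BWPosition", helix = helix, index = index)
}

#' @describeIn parseBW Construct from helix/index integer vectors.
#' @param helix,index integer vectors (recycled to a common length).
#' @export
bw <- function(helix, index) {
    n <- max(length(helix), length(index))
    new("BWPosition", helix = rep_len(as.integer(helix), n),
        index = rep_len(as.integer(index), n))
}

#' @export
setMethod("length", "BWPosition", function(x) length(x@helix))

#' @export
setMethod("as.character", "BWPosition", function(x, ...)
    sprintf("%d.%d", x@helix, x@index))

#' @export
setMethod("show", "BWPosition", function(object) {
    cat("BWPosition of length", length(object), "\n")
    print(as.character(object))
    invisible(object)
})

#' @export
setMethod("[", "BWPosition", function(x, i, j, ..., drop = TRUE)
    new("BWPosition", helix = x@helix[i], index = x@index[i]))

## Total order: by helix, then index. xtfrm makes sort()/order()/rank()
## work on BWPosition vectors directly.
#' @export
setMethod("xtfrm", "BWPosition", function(x) x@helix * 1000L + x@index)

#' @export
setMethod("Compare", signature("BWPosition", "BWPosition"),
    function(e1, e2) callGeneric(xtfrm(e1), xtfrm(e2)))

#' Helix accessors for BW positions
#' @param x a [BWPosition-class].
#' @return Integer vector of helix numbers / indices.
#' @export
bwHelix <- function(x) x@helix

#' @rdname bwHelix
#' @export
bwIndex <- function(x) x@index

#' Transmembrane helix boundaries
#'
#' The inclusive Ballesteros-Weinstein index ranges of the seven helix
#' segments covered by the alignment: 1.33-1.56, 2.40-2.65, 3.25-3.51,
#' 4.43-4.64, 5.38-5.63, 6.37-6.59 and 7.34-7.56. The segment lengths are
#' 24, 26, 27, 22, 26, 23 and 23 residues, 171 columns in total. Loops,
#' termini and helix 8 are outside the model.
#'
#' @return data.frame with columns `helix`, `first`, `last`, `length`.
#' @examples
#' sum(tmBoundaries()$length)  # 171
#' @export
tmBoundaries <- function() {
    b <- data.frame(helix = 1:7,
                    first = c(33L, 40L, 25L, 43L, 38L, 37L, 34L),
                    last  = c(56L, 65L, 51L, 64L, 63L, 59L, 56L))
    b$length <- b$last - b$first + 1L
    b
}

#' Enumerate all transmembrane alignment positions
#'
#' All 171 column positions of the gap-free TM alignment, in helix-then-
#' index order (first `1.33`, last `7.56`). This order is the canonical
#' column order of every [TMAlignment-class].
#'
#' @param bounds helix boundary table as returned by [tmBoundaries()].
#' @return [BWPosition-class] of length 171, sorted, without duplicates.
#' @examples
#' length(tmPositions())
#' @export
tmPositions <- function(bounds = tmBoundaries()) {
    helix <- rep.int(bounds$helix, bounds$length)
    index <- unlist(Map(seq.int, bounds$first, bounds$last),
                    use.names = FALSE)
    bw(helix, index)
}

#' The 28-residue ligand-binding pocket
#'
#' The 28 TM positions directed towards the intramembrane cavity in the
#' solved class A GPCR crystal structures. All lie inside the helix
#' boundaries of [tmBoundaries()].
#'
#' @return [BWPosition-class] of length 28.
#' @examples
#' length(pocketPositions())
#' @export
pocketPositions <- function() {
    parseBW(c("1.35", "1.39", "1.42", "1.46",
              "2.57", "2.58", "2.61", "2.65",
              "3.28", "3.29", "3.32", "3.33", "3.36",
              "4.56",
              "5.38", "5.39", "5.42", "5.43", "5.46",
              "6.44", "6.48", "6.51", "6.52", "6.55",
              "7.35", "7.39", "7.43", "7.45"))
}

## Canonical sort key used for rank tie-breaking: positions compared as
## labels through their helix/index pair, never lexicographically.
.bwKey <- function(labels) xtfrm(parseBW(labels))
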