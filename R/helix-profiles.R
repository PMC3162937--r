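## Gap-free per-helix profile models and their calibration.
##
## The alignment contract forbids gaps inside helix segments, so a
## position-specific log-odds profile searched exhaustively over start
## offsets is the exact model: no insert/delete state can ever be used.

## Column index range (into the 171 canonical columns) of one helix.
.helixColumns <- function(helix, bounds = tmBoundaries()) {
    stopifnot(helix %in% 1:7)
    off <- c(0L, cumsum(bounds$length))[helix]
    seq.int(off + 1L, off + bounds$length[helix])
}

#' Build a per-helix log-odds profile
#'
#' Builds the position-specific profile for one helix from a gap-free seed
#' alignment. The weight of letter `a` at a column with `count_a`
#' occurrences among `N` countable residues is
#' `log(((count_a + pc * bg_a) / (N + pc)) / bg_a)` with a
#' background-proportional pseudocount `pc`. The background is the
#' amino-acid composition of the whole seed alignment unless supplied
#' (a Laplace add-one floor keeps it positive, so all weights are finite).
#'
#' @param seed a [TMAlignment-class] used as the curated seed.
#' @param helix helix number in 1..7.
#' @param pseudocount background-proportional pseudocount (> 0).
#' @param background optional named length-20 frequency vector overriding
#'   the seed-derived background.
#' @return A [HelixProfile-class].
#' @seealso [buildHelixProfiles()], [gapfreeAlign()]
#' @export
buildProfile <- function(seed, helix, pseudocount = 1,
                         background = NULL) {
    if (nrecords(seed) == 0L)
        stop("seed alignment is empty")
    if (!(helix %in% 1:7))
        stop("helix must lie in 1..7")
    if (pseudocount <= 0)
        stop("pseudocount must be positive")
    m <- as.matrix(seed)
    if (is.null(background)) {
        tot <- colSums(.columnCounts(m))   # letter totals over whole seed
        background <- (tot + 1) / sum(tot + 1)
    } else {
        background <- background[AA20]
        if (anyNA(background) || any(background <= 0))
            stop("background must assign positive frequency to all 20 letters")
        background <- background / sum(background)
    }
    cols <- .helixColumns(helix)
    cnt <- t(.columnCounts(m[, cols, drop = FALSE]))   # 20 x L
    n <- colSums(cnt)
    w <- log((cnt + pseudocount * background) /
             rep(n + pseudocount, each = 20L) / background)
    dimnames(w) <- list(AA20, NULL)
    new("HelixProfile", helix = as.integer(helix),
        length = length(cols), weights = w,
        background = stats::setNames(as.numeric(background), AA20),
        pseudocount = as.numeric(pseudocount))
}

#' @rdname buildProfile
#' @return `buildHelixProfiles()`: list of 7 [HelixProfile-class], one per
#'   helix.
#' @export
buildHelixProfiles <- function(seed, pseudocount = 1, background = NULL) {
    lapply(1:7, buildProfile, seed = seed, pseudocount = pseudocount,
           background = background)
}

#' @rdname buildProfile
#' @param profile a [HelixProfile-class].
#' @return `profileConsensus()`: the maximum-weight letter at each column,
#'   as a single string.
#' @export
profileConsensus <- function(profile) {
    paste(AA20[apply(profile@weights, 2L, which.max)], collapse = "")
}

#' @export
setMethod("show", "HelixProfile", function(object) {
    cat("HelixProfile for TM", object@helix, " (", object@length,
        " columns, pseudocount ", object@pseudocount, ")\n", sep = "")
    cat("  consensus:", profileConsensus(object), "\n")
    invisible(object)
})

## Encode a sequence as indices into AA20; ambiguity codes become NA and
## contribute zero to window scores.
.encodeSeq <- function(seq) {
    if (methods::is(seq, "AAString") || methods::is(seq, "AAStringSet"))
        seq <- as.character(seq)
    match(strsplit(seq[[1L]], "", fixed = TRUE)[[1L]], AA20)
}

#' Gap-free profile alignment of one helix
#'
#' Scores every admissible start offset of the profile against the
#' sequence (sum of per-column log-odds weights; ambiguity codes score 0)
#' and returns the maximum. Ties are broken towards the smallest offset.
#' No gaps are ever introduced: the helix occupies one contiguous window.
#'
#' @param profile a [HelixProfile-class].
#' @param seq a character string, [Biostrings::AAString], or encoded
#'   integer vector.
#' @param searchRange optional 0-based half-open interval `c(start, end)`
#'   restricting the window to lie within `[start, end)`.
#' @return List with elements `helix`, `offset` (0-based window start),
#'   `score`.
#' @examples
#' seed <- TMAlignment(setNames(strrep("D", 171), "s1"), "human")
#' prof <- buildProfile(seed, 1)
#' gapfreeAlign(prof, paste0(strrep("A", 10), strrep("D", 24)))$offset
#' @export
gapfreeAlign <- function(profile, seq, searchRange = NULL) {
    idx <- if (is.integer(seq)) seq else .encodeSeq(seq)
    L <- profile@length
    n <- length(idx)
    lo <- 0L
    hi <- n
    if (!is.null(searchRange)) {
        lo <- max(0L, as.integer(searchRange[[1L]]))
        hi <- min(n, as.integer(searchRange[[2L]]))
    }
    if (hi - lo < L)
        stop("no gap-free placement possible: sequence segment (",
             hi - lo, ") shorter than helix ", profile@helix,
             " profile (", L, ")")
    offsets <- lo:(hi - L)          # 0-based window starts
    scores <- numeric(length(offsets))
    w <- profile@weights
    for (j in seq_len(L)) {
        v <- unname(w[idx[offsets + j], j])
        v[is.na(v)] <- 0
        scores <- scores + v
    }
    best <- which.max(scores)       # which.max takes the first maximum
    list(helix = profile@helix, offset = offsets[best],
         score = unname(scores[best]))
}

#' Calibrate per-helix score thresholds
#'
#' Generates, for each helix, `nArtificial` artificial sequences of length
#' `artificialLength` by i.i.d. sampling from that helix's seed amino-acid
#' composition, scores each with the same maximum-over-offsets search used
#' for real sequences, and sets the cutoff to the empirical 95th
#' percentile (lower interpolation: exactly `ceiling(0.95 * n)` artificial
#' scores fall at or below it), so 95% of artificial sequences fail to
#' pass. A helix passes when its score exceeds the cutoff strictly.
#'
#' @param profiles list of 7 [HelixProfile-class].
#' @param seed a [TMAlignment-class]; source of the per-helix amino-acid
#'   composition of the artificial sequences.
#' @param nArtificial number of artificial sequences per helix (>= 100).
#' @param rngSeed integer RNG seed; calibration is reproducible
#'   bit-for-bit given the seed.
#' @param artificialLength length of each artificial sequence. It should
#'   resemble the length of the sequences later scored, because the
#'   maximum over offsets grows (slowly) with the number of windows.
#' @param quantile failure quantile (default 0.95).
#' @return A [CalibratedThresholds-class].
#' @export
calibrateThresholds <- function(profiles, seed, nArtificial = 10000L,
                                rngSeed = 1L, artificialLength = 300L,
                                quantile = 0.95) {
    if (nArtificial < 100L)
        stop("nArtificial must be at least 100")
    m <- as.matrix(seed)
    cutoffs <- withSeed(rngSeed, vapply(1:7, function(h) {
        cols <- m[, .helixColumns(h), drop = FALSE]
        comp <- colSums(.columnCounts(cols))
        if (sum(comp > 0) == 1L)
            warning("degenerate seed composition for helix ", h,
                    " (single letter); cutoff still defined")
        prob <- comp / sum(comp)
        draws <- matrix(sample.int(20L, nArtificial * artificialLength,
                                   replace = TRUE, prob = prob),
                        nrow = nArtificial)
        scores <- .windowMaxScores(profiles[[h]]@weights, draws)
        .lowerQuantile(scores, quantile)
    }, numeric(1)))
    names(cutoffs) <- as.character(1:7)
    new("CalibratedThresholds", cutoffs = cutoffs,
        nArtificial = as.integer(nArtificial),
        artificialLength = as.integer(artificialLength),
        quantile = quantile, seed = as.integer(rngSeed))
}

## Maximum window score for every row of an index matrix (rows =
## sequences encoded as 1..20). Vectorized over sequences.
.windowMaxScores <- function(w, idx) {
    L <- ncol(w)
    len <- ncol(idx)
    nwin <- len - L + 1L
    stopifnot(nwin >= 1L)
    best <- rep(-Inf, nrow(idx))
    for (o in seq_len(nwin)) {
        s <- numeric(nrow(idx))
        for (j in seq_len(L))
            s <- s + w[idx[, o + j - 1L], j]
        best <- pmax(best, s)
    }
    best
}

## Empirical quantile, lower interpolation (type 1): the smallest order
## statistic with at least ceiling(p * n) observations at or below it.
.lowerQuantile <- function(x, p) {
    sort(x)[ceiling(p * length(x))]
}

#' @rdname calibrateThresholds
#' @param x a [CalibratedThresholds-class].
#' @return `thresholdCutoffs()`: named numeric of length 7.
#' @export
thresholdCutoffs <- function(x) x@cutoffs

#' @export
setMethod("show", "CalibratedThresholds", function(object) {
    cat("CalibratedThresholds (", object@nArtificial,
        " artificial sequences of length ", object@artificialLength,
        ", quantile ", object@quantile, ", seed ", object@seed, ")\n",
        sep = "")
    print(round(object@cutoffs, 2))
    invisible(object)
})
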