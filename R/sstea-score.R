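## The method core: per-column Shannon entropies inside/outside a
## subfamily, the combined distance-to-corner score, aggregation over
## branches, and per-receptor residue ranking.

#' Shannon entropy of an alignment column
#'
#' `H = -sum_a p_a ln p_a` over the 20 standard amino acids, with
#' `p_a = Number_a / N` and `Number_a` the count of residue type `a` in
#' the column. Ambiguity codes are excluded from the counts. Entropy is
#' reported in nats and lies in `[0, ln 20]`; it is 0 iff the column is
#' constant.
#'
#' @param column character vector of residue symbols (one per sequence).
#' @return Entropy in nats.
#' @examples
#' columnEntropy(rep("D", 50))        # 0
#' columnEntropy(c(rep("A", 10), rep("V", 10)))  # ln 2
#' @export
columnEntropy <- function(column) {
    cnt <- .columnCounts(matrix(column, ncol = 1L))
    h <- .entropyFromCounts(cnt)
    if (is.na(h))
        stop("undefined entropy: column has no countable (standard ",
             "amino-acid) symbols")
    as.numeric(h)
}

#' Inside/outside entropy pair of one position
#'
#' Computes the Shannon entropy of an alignment column over the members of
#' a subfamily (`eIn`) and over all sequences outside it (`eOut`). Low
#' `eIn` with high `eOut` is the signature of a subfamily-specific
#' (ligand-binding-like) position; low `eIn` with low `eOut` marks a
#' globally conserved, structurally important position.
#'
#' @param aln a [TMAlignment-class].
#' @param subfamily a [Subfamily-class] (or character vector of member
#'   ids) with a non-empty complement in the alignment.
#' @param position a BW label or [BWPosition-class] of length 1.
#' @return List with `eIn`, `eOut` (nats), `nIn`, `nOut` (sequence
#'   counts; they sum to the alignment size).
#' @export
twoEntropy <- function(aln, subfamily, position) {
    members <- if (methods::is(subfamily, "Subfamily"))
        subfamilyMembers(subfamily) else as.character(subfamily)
    ids <- recordIds(aln)
    if (!all(members %in% ids))
        stop("subfamily members missing from the alignment")
    outIds <- setdiff(ids, members)
    if (!length(outIds))
        stop("empty out-set: subfamily spans the whole alignment")
    col <- tmColumn(aln, position)
    list(eIn = columnEntropy(col[members]),
         eOut = columnEntropy(col[outIds]),
         nIn = length(members), nOut = length(outIds))
}

#' Combined two-entropy score
#'
#' Normalizes both entropies to `[0, 1]` by `ln 20` and returns the
#' Euclidean distance of the pair to the corner of perfect
#' within-subfamily conservation and maximal outside variability:
#' `s = sqrt(eIn^2 + (1 - eOut)^2)` on the normalized scale, in
#' `[0, sqrt(2)]`. Smaller is more binding-like. The corner may be
#' replaced by an empirical one (`cornerIn`, `cornerOut` in nats, e.g.
#' the minimum observed inside entropy and maximum observed outside
#' entropy over all positions).
#'
#' @param eIn,eOut entropies in nats (vectorized).
#' @param cornerIn,cornerOut corner entropies in nats; defaults are the
#'   theoretical corner (0, `ln 20`).
#' @return Numeric score(s); with `eOut` fixed the score strictly
#'   increases in `eIn`, and with `eIn` fixed it strictly decreases in
#'   `eOut`.
#' @examples
#' combinedScore(0, log(20))   # 0, the corner itself
#' combinedScore(log(20), 0)   # sqrt(2)
#' @export
combinedScore <- function(eIn, eOut, cornerIn = 0, cornerOut = log(20)) {
    sqrt(((eIn - cornerIn) / log(20))^2 +
         ((cornerOut - eOut) / log(20))^2)
}

#' Aggregate branch scores into a final residue score
#'
#' A residue is evaluated at every eligible branch (subfamily) of the
#' tree; `aggregateBranches()` reduces the per-branch scores to one final
#' score. The default takes the minimum over branches (a residue is
#' binding-like if any well-sized subfamily conserves it); the alternative
#' is a branch-size-weighted mean, `sum(j * s) / sum(j)` with `j` the
#' number of sequences in the branch.
#'
#' @param scores numeric vector of per-branch combined scores.
#' @param sizes integer vector of branch sizes `j` (required for
#'   `"size_weighted_mean"`).
#' @param method `"min"` or `"size_weighted_mean"`.
#' @return Final score.
#' @examples
#' aggregateBranches(c(0.5, 0.3, 0.7))                      # 0.3
#' aggregateBranches(c(0.4, 0.2), c(60, 240),
#'                   method = "size_weighted_mean")          # 0.24
#' @export
aggregateBranches <- function(scores, sizes = NULL,
                              method = c("min", "size_weighted_mean")) {
    method <- match.arg(method)
    if (!length(scores))
        stop("no eligible branch: relax the subfamily size window ",
             "(minSize/maxSize)")
    if (method == "min")
        return(min(scores))
    if (is.null(sizes) || length(sizes) != length(scores))
        stop("branch sizes required for size-weighted aggregation")
    sum(sizes * scores) / sum(sizes)
}

#' Score all residue positions for one receptor
#'
#' The subfamily-specific two-entropy analysis: for every eligible
#' subfamily containing the query receptor (branch sizes in
#' `[minSize, maxSize]`) and every one of the 171 TM positions, computes
#' the inside/outside entropy pair and the combined distance-to-corner
#' score, aggregates the per-branch scores, and ranks all positions
#' ascending (rank 1 = minimum score = most binding-like), ties broken by
#' BW position order. Deterministic; permuting the input record order
#' leaves the table unchanged.
#'
#' @param aln a [TMAlignment-class].
#' @param tree a [SubfamilyTree-class] over the same records.
#' @param receptorId the query receptor (a record id / leaf label).
#' @param minSize,maxSize subfamily size window (default 50-300).
#' @param aggregate `"min"` (default) or `"size_weighted_mean"`.
#' @param corner `"theoretical"` (distance to `eIn = 0`, `eOut = ln 20`)
#'   or `"empirical"` (distance to the per-branch observed corner
#'   `min eIn`, `max eOut`).
#' @return A [ResidueScoreTable-class].
#' @export
scoreReceptor <- function(aln, tree, receptorId, minSize = 50L,
                          maxSize = 300L,
                          aggregate = c("min", "size_weighted_mean"),
                          corner = c("theoretical", "empirical")) {
    aggregate <- match.arg(aggregate)
    corner <- match.arg(corner)
    ids <- recordIds(aln)
    if (!(receptorId %in% ids))
        stop("receptor not in the alignment: ", receptorId)
    if (!setequal(leafIds(tree), ids))
        stop("tree leaves and alignment records disagree")
    subs <- subfamiliesContaining(tree, receptorId, minSize, maxSize)
    if (!length(subs))
        stop("no eligible subfamily for ", receptorId,
             " within sizes [", minSize, ", ", maxSize,
             "]: relax the subfamily size window")

    m <- as.matrix(aln)
    ## sort rows by id so the computation is invariant under input order
    m <- m[order(rownames(m)), , drop = FALSE]
    allCnt <- .columnCounts(m)
    positions <- as.character(tmPositions())

    branches <- list()
    scoreMat <- matrix(NA_real_, nrow = 171L, ncol = length(subs))
    sizes <- vapply(subs, subfamilySize, integer(1))
    for (b in seq_along(subs)) {
        members <- sort(subfamilyMembers(subs[[b]]))
        cntIn <- .columnCounts(m[members, , drop = FALSE])
        cntOut <- allCnt - cntIn
        eIn <- .entropyFromCounts(cntIn)
        eOut <- .entropyFromCounts(cntOut)
        if (anyNA(eIn) || anyNA(eOut))
            stop("column with no countable symbols in a partition; ",
                 "the alignment is degenerate at position(s) ",
                 paste(positions[is.na(eIn) | is.na(eOut)], collapse = ", "))
        ci <- if (corner == "empirical") min(eIn) else 0
        co <- if (corner == "empirical") max(eOut) else log(20)
        s <- combinedScore(eIn, eOut, cornerIn = ci, cornerOut = co)
        scoreMat[, b] <- s
        branches[[as.character(sizes[b])]] <-
            data.frame(position = positions, eIn = eIn, eOut = eOut,
                       nIn = subfamilySize(subs[[b]]),
                       nOut = nrow(m) - subfamilySize(subs[[b]]),
                       score = s)
    }
    final <- apply(scoreMat, 1L, aggregateBranches, sizes = sizes,
                   method = aggregate)
    rank <- integer(171L)
    rank[order(final, .bwKey(positions))] <- seq_len(171L)
    new("ResidueScoreTable", receptor = receptorId,
        aggregate = aggregate, corner = corner,
        subfamilySizes = sizes,
        scores = data.frame(position = positions, score = final,
                            rank = rank),
        branches = branches)
}

#' @rdname scoreReceptor
#' @param x,object a [ResidueScoreTable-class].
#' @return `residueScores()`: the 171-row data.frame (`position`, `score`,
#'   `rank`); `scoreRanking()`: the positions as a character vector in
#'   rank order (rank 1 first).
#' @export
residueScores <- function(x) x@scores

#' @rdname scoreReceptor
#' @export
scoreRanking <- function(x) x@scores$position[order(x@scores$rank)]

#' @rdname scoreReceptor
#' @export
branchDetail <- function(x) x@branches

#' @export
setMethod("show", "ResidueScoreTable", function(object) {
    cat("ResidueScoreTable for receptor", object@receptor, "\n")
    cat("  branches (sizes):",
        paste(object@subfamilySizes, collapse = ", "), "\n")
    cat("  aggregate:", object@aggregate, "| corner:", object@corner, "\n")
    top <- object@scores[order(object@scores$rank), ][1:5, ]
    cat("  top 5 positions:", paste(top$position, collapse = ", "), "\n")
    invisible(object)
})

#' Write / read a residue score table
#'
#' The TSV carries the resolved configuration in `#`-prefixed header
#' lines (receptor, aggregation, corner convention, branch sizes)
#' followed by the 171-row table, so every output records how it was
#' produced.
#'
#' @param x a [ResidueScoreTable-class].
#' @param path file path.
#' @export
writeScoreTable <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# receptor=", x@receptor),
                 paste0("# aggregate=", x@aggregate),
                 paste0("# corner=", x@corner),
                 paste0("# branch_sizes=",
                        paste(x@subfamilySizes, collapse = ","))), con)
    utils::write.table(format(x@scores, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Ranking exchange format
#'
#' Two-column TSV (`rank`, `position`) used to exchange rankings with
#' other methods; externally produced rankings (e.g. Multi-RELIEF) are
#' consumed through the same format and evaluated identically.
#'
#' @param ranking character vector of BW labels, rank 1 first.
#' @param path file path.
#' @export
writeRanking <- function(ranking, path) {
    utils::write.table(data.frame(rank = seq_along(ranking),
                                  position = ranking),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRanking
#' @return `readRanking()`: character vector of positions in rank order.
#' @export
readRanking <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c(position = "character"))
    if (!all(c("rank", "position") %in% names(df)))
        stop("ranking file must have columns rank, position")
    df$position[order(df$rank)]
}
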