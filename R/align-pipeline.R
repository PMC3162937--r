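## The full gap-free alignment pipeline: per-helix placement, helix-order
## repair, threshold flags, and the record-level filters.

## Highest-total-score strictly increasing, non-overlapping subset of the
## 7 helix hits (the anchors used for order repair). A subset is only
## admissible when an in-order gap-free placement of ALL helices remains
## feasible around it, i.e. every gap before/between/after anchors leaves
## room for the helices that must be realigned there. Dynamic programme
## over helices; offsets are 0-based. Returns integer(0) when no single
## hit can be kept (the whole sequence is then realigned in order).
.anchorSubset <- function(offsets, lengths, scores, seqlen) {
    n <- length(offsets)
    csum <- c(0, cumsum(lengths))            # csum[h] = sum of L[1..h-1]
    startOk <- offsets >= csum[seq_len(n)]
    endOk <- seqlen - (offsets + lengths) >= csum[n + 1L] - csum[seq_len(n) + 1L]
    best <- ifelse(startOk, scores, -Inf)
    prev <- rep(0L, n)
    for (h in seq_len(n)) {
        for (g in seq_len(h - 1L)) {
            roomFor <- csum[h] - csum[g + 1L]   # helices between g and h
            if (is.finite(best[g]) &&
                offsets[h] - (offsets[g] + lengths[g]) >= roomFor &&
                best[g] + scores[h] > best[h]) {
                best[h] <- best[g] + scores[h]
                prev[h] <- g
            }
        }
    }
    best[!endOk] <- -Inf
    if (all(!is.finite(best)))
        return(integer(0))
    h <- which.max(best)
    anchors <- integer()
    while (h != 0L) {
        anchors <- c(h, anchors)
        h <- prev[h]
    }
    anchors
}

#' Align one sequence against the seven helix profiles
#'
#' Places each helix independently at its maximum-scoring gap-free window,
#' then checks that the seven windows occur in helix order without
#' overlap. If not, the highest-total-score strictly increasing subset of
#' hits is kept as anchors and every inconsistent helix is realigned
#' constrained to the interval between its nearest consistent neighbours
#' (a typical case: one helix whose best global hit lands after the next
#' helix is realigned between its two correctly placed neighbours).
#' Finally each helix is flagged pass/fail against its calibrated
#' threshold.
#'
#' @param profiles list of 7 [HelixProfile-class].
#' @param seq character string (or [Biostrings::AAString]) of the
#'   full-length protein sequence.
#' @param thresholds a [CalibratedThresholds-class], or `NULL` to skip the
#'   pass/fail flags (all `NA`).
#' @return List with elements `row` (the 171-residue aligned TM string),
#'   `meta` (data.frame `helix`, `offset`, `score`, `pass`) and `rejected`
#'   (`FALSE`, or a character reason when no order-consistent gap-free
#'   placement exists).
#' @seealso [alignSequences()] for the vectorized pipeline entry point.
#' @export
alignSequence <- function(profiles, seq, thresholds = NULL) {
    idx <- .encodeSeq(seq)
    lengths <- vapply(profiles, methods::slot, integer(1), "length")
    if (length(idx) < max(lengths))
        return(list(row = NULL, meta = NULL,
                    rejected = "sequence shorter than a helix profile"))
    hits <- lapply(profiles, gapfreeAlign, seq = idx)
    offsets <- vapply(hits, `[[`, numeric(1), "offset")
    scores <- vapply(hits, `[[`, numeric(1), "score")

    consistent <- all(offsets[-1L] >= (offsets + lengths)[-7L])
    if (!consistent) {
        if (length(idx) < sum(lengths))
            return(list(row = NULL, meta = NULL,
                        rejected = paste0("no gap-free placement possible: ",
                                          "sequence shorter than the seven ",
                                          "helices in order")))
        anchors <- .anchorSubset(offsets, lengths, scores, length(idx))
        csum <- c(0, cumsum(lengths))
        left <- 0L
        for (h in 1:7) {
            if (h %in% anchors) {
                left <- offsets[h] + lengths[h]
                next
            }
            nxt <- anchors[anchors > h]
            right <- if (length(nxt)) offsets[nxt[1L]] else length(idx)
            ## reserve room for the non-anchored helices that must still
            ## fit between this one and the next anchor (or sequence end)
            upto <- if (length(nxt)) nxt[1L] - 1L else 7L
            reserve <- csum[upto + 1L] - csum[h + 1L]
            hit <- gapfreeAlign(profiles[[h]], idx,
                                searchRange = c(left, right - reserve))
            offsets[h] <- hit$offset
            scores[h] <- hit$score
            left <- offsets[h] + lengths[h]
        }
    }

    pass <- if (is.null(thresholds)) rep(NA, 7) else
        scores > thresholds@cutoffs
    chars <- AA20[idx]
    chars[is.na(chars)] <- "X"
    row <- paste(unlist(lapply(1:7, function(h)
        chars[(offsets[h] + 1L):(offsets[h] + lengths[h])])),
        collapse = "")
    list(row = row,
         meta = data.frame(helix = 1:7, offset = as.integer(offsets),
                           score = scores, pass = pass),
         rejected = FALSE)
}

#' Gap-free alignment of a set of sequences
#'
#' Runs [alignSequence()] over a set of full-length protein sequences and
#' assembles the accepted records into a [TMAlignment-class] with
#' per-helix metadata. Records for which no order-consistent gap-free
#' placement exists are reported with a reason instead of being aligned.
#'
#' @param profiles list of 7 [HelixProfile-class].
#' @param seqs [Biostrings::AAStringSet] (named by record id) or named
#'   character vector.
#' @param species named character vector of species labels (by record
#'   id), or a bare character recycled over records.
#' @param thresholds a [CalibratedThresholds-class] or `NULL`.
#' @return List with `alignment` (a [TMAlignment-class]) and `rejected`
#'   (data.frame `id`, `reason`).
#' @export
alignSequences <- function(profiles, seqs, species = NA_character_,
                           thresholds = NULL) {
    ids <- names(seqs)
    seqs <- stats::setNames(as.character(seqs), ids)
    if (is.null(ids) || anyDuplicated(ids))
        stop("sequences must carry unique names")
    if (!is.null(names(species)))
        species <- species[ids]
    species <- rep_len(unname(species), length(seqs))

    rows <- character(0)
    keep <- character(0)
    meta <- list()
    rejected <- data.frame(id = character(), reason = character())
    for (k in seq_along(seqs)) {
        res <- alignSequence(profiles, seqs[[k]], thresholds)
        if (!isFALSE(res$rejected)) {
            rejected <- rbind(rejected,
                              data.frame(id = ids[k], reason = res$rejected))
            next
        }
        rows[ids[k]] <- res$row
        keep <- c(keep, ids[k])
        meta[[ids[k]]] <- cbind(id = ids[k], res$meta)
    }
    metaDf <- if (length(meta)) do.call(rbind, c(meta, make.row.names = FALSE))
              else .emptyHelixMeta()
    aln <- TMAlignment(rows, species[match(keep, ids)], metaDf)
    list(alignment = aln, rejected = rejected)
}

#' Drop records failing too many helices
#'
#' Keeps records whose number of helices with a below-threshold profile
#' score is at most `maxFailed` (default 4 of 7: some genuine receptors,
#' e.g. the prostanoids, show weak helix patterns for up to 4 helices).
#'
#' @param aln a [TMAlignment-class] with per-helix metadata.
#' @param maxFailed maximum tolerated failed helices per record.
#' @return Filtered [TMAlignment-class].
#' @export
filterFailing <- function(aln, maxFailed = 4L) {
    meta <- helixMetadata(aln)
    if (!nrow(meta))
        stop("alignment carries no helix metadata to filter on")
    fails <- tapply(!meta$pass, meta$id, sum)
    drop <- names(fails)[fails > maxFailed]
    aln[setdiff(recordIds(aln), drop)]
}

#' Remove near-duplicate records within species
#'
#' Within each species, records whose aligned TM sequences differ at fewer
#' than `maxDiff` of the 171 columns are grouped transitively and a single
#' representative (the lexicographically smallest id) is kept per group.
#' Identical sequences from different species are never collapsed.
#'
#' @param aln a [TMAlignment-class]; species must be present.
#' @param maxDiff records differing at strictly fewer than this many
#'   columns are considered duplicates (default 10).
#' @return Deduplicated [TMAlignment-class].
#' @export
dedupSpecies <- function(aln, maxDiff = 10L) {
    sp <- recordSpecies(aln)
    if (anyNA(sp))
        stop("species annotation required for deduplication")
    keep <- character(0)
    m <- as.matrix(aln)
    for (s in unique(sp)) {
        ids <- names(sp)[sp == s]
        if (length(ids) == 1L) {
            keep <- c(keep, ids)
            next
        }
        sub <- m[ids, , drop = FALSE]
        d <- .hammingMatrix(sub)
        adj <- d < maxDiff
        comp <- .components(adj)
        for (grp in split(ids, comp))
            keep <- c(keep, min(grp))
    }
    aln[keep[order(match(keep, recordIds(aln)))]]
}

## Pairwise Hamming distance (count of differing columns) between the
## rows of a character matrix.
.hammingMatrix <- function(m) {
    sym <- unique(as.vector(m))
    idx <- match(m, sym)
    dim(idx) <- dim(m)
    a <- matrix(0L, nrow(m), ncol(m) * length(sym))
    a[cbind(rep(seq_len(nrow(m)), ncol(m)),
            (rep(seq_len(ncol(m)), each = nrow(m)) - 1L) * length(sym) +
                as.vector(idx))] <- 1L
    ncol(m) - tcrossprod(a)
}

## Connected components of a symmetric logical adjacency matrix
## (diagonal irrelevant); returns a component label per row.
.components <- function(adj) {
    n <- nrow(adj)
    comp <- rep(NA_integer_, n)
    cur <- 0L
    for (i in seq_len(n)) {
        if (!is.na(comp[i])) next
        cur <- cur + 1L
        queue <- i
        while (length(queue)) {
            v <- queue[[1L]]
            queue <- queue[-1L]
            if (!is.na(comp[v])) next
            comp[v] <- cur
            queue <- c(queue, which(adj[v, ] & is.na(comp)))
        }
    }
    comp
}

#' Drop under-sampled species
#'
#' Removes all records of species contributing fewer than `minCount`
#' records to the alignment. Incompletely sequenced genomes bias the
#' subfamily composition; requiring at least 100 receptor sequences per
#' species keeps only species with reasonably complete receptor
#' repertoires.
#'
#' @param aln a [TMAlignment-class].
#' @param minCount minimum records per retained species (default 100).
#' @return Filtered [TMAlignment-class].
#' @export
filterSpecies <- function(aln, minCount = 100L) {
    if (nrecords(aln) == 0L)
        return(aln)
    sp <- recordSpecies(aln)
    counts <- table(sp)
    keepSp <- names(counts)[counts >= minCount]
    aln[names(sp)[sp %in% keepSp]]
}
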