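## Distance matrix, neighbor-joining subfamily tree, and clade queries.

#' Pairwise p-distance matrix
#'
#' Fraction of mismatching columns (out of 171) for every pair of records.
#' Ambiguity symbols count as a mismatch against anything but themselves.
#'
#' @param aln a [TMAlignment-class] with at least 2 records.
#' @return Symmetric numeric matrix with zero diagonal, values in
#'   `[0, 1]`, dimnames = record ids.
#' @export
pDistanceMatrix <- function(aln) {
    if (nrecords(aln) < 2L)
        stop("at least 2 records required")
    m <- as.matrix(aln)
    d <- .hammingMatrix(m) / ncol(m)
    dimnames(d) <- list(rownames(m), rownames(m))
    d
}

#' Build the neighbor-joining subfamily tree
#'
#' Standard Saitou-Nei neighbor joining on the p-distance matrix, followed
#' by midpoint rooting so that "the branches containing a receptor" are
#' well defined. Deterministic for a fixed record order.
#'
#' @param d symmetric distance matrix (e.g. from [pDistanceMatrix()]), or
#'   a [stats::dist] object, over at least 3 taxa.
#' @return A [SubfamilyTree-class].
#' @export
buildNJTree <- function(d) {
    if (inherits(d, "dist"))
        d <- as.matrix(d)
    if (nrow(d) < 3L)
        stop("at least 3 taxa required for neighbor joining")
    tr <- ape::nj(stats::as.dist(d))
    tr <- phangorn::midpoint(tr)
    new("SubfamilyTree", phylo = tr)
}

#' @rdname buildNJTree
#' @param x,object a [SubfamilyTree-class].
#' @return `treePhylo()`: the underlying [ape::phylo]; `leafIds()`: the
#'   tip labels.
#' @export
treePhylo <- function(x) x@phylo

#' @rdname buildNJTree
#' @export
leafIds <- function(x) x@phylo$tip.label

#' @export
setMethod("show", "SubfamilyTree", function(object) {
    cat("SubfamilyTree with", length(object@phylo$tip.label), "leaves\n")
    invisible(object)
})

#' Newick round trip for subfamily trees
#'
#' @param path file path.
#' @return `readNewickTree()`: a [SubfamilyTree-class].
#' @export
readNewickTree <- function(path) {
    tr <- ape::read.tree(path)
    if (is.null(tr))
        stop("malformed Newick file: ", path)
    if (!ape::is.rooted(tr))
        tr <- phangorn::midpoint(tr)
    new("SubfamilyTree", phylo = tr)
}

#' @rdname readNewickTree
#' @param tree a [SubfamilyTree-class].
#' @export
writeNewickTree <- function(tree, path) {
    ape::write.tree(tree@phylo, path)
    invisible(path)
}

#' Subfamily accessors
#' @param x a [Subfamily-class].
#' @export
subfamilyMembers <- function(x) x@members

#' @rdname subfamilyMembers
#' @export
subfamilySize <- function(x) x@size

#' @export
setMethod("show", "Subfamily", function(object) {
    cat("Subfamily of", object@size, "sequences (node",
        object@node, ")\n")
    invisible(object)
})

#' Enumerate scoring-eligible subfamilies of a receptor
#'
#' Walks the ancestors of the query leaf and returns every branch whose
#' leaf count lies in `[minSize, maxSize]` and whose complement in the
#' tree is non-empty (so the outside entropy is defined), ordered from the
#' smallest branch outwards. The default window of 50-300 sequences is
#' chosen so a branch is large enough to show subfamily-level conservation
#' yet small enough to stay ligand-homogeneous.
#'
#' @param tree a [SubfamilyTree-class].
#' @param receptorId a leaf label.
#' @param minSize,maxSize inclusive branch size window.
#' @return List of [Subfamily-class], smallest first (possibly empty; the
#'   caller should surface a diagnostic when empty).
#' @export
subfamiliesContaining <- function(tree, receptorId, minSize = 50L,
                                  maxSize = 300L) {
    phy <- tree@phylo
    leaf <- match(receptorId, phy$tip.label)
    if (is.na(leaf))
        stop("unknown receptor id: ", receptorId)
    anc <- phangorn::Ancestors(phy, leaf, type = "all")
    tips <- phangorn::Descendants(phy, anc, type = "tips")
    sizes <- lengths(tips)
    total <- length(phy$tip.label)
    ok <- sizes >= minSize & sizes <= maxSize & sizes < total
    out <- lapply(which(ok), function(i)
        new("Subfamily", node = as.integer(anc[i]),
            members = phy$tip.label[tips[[i]]],
            size = as.integer(sizes[i])))
    out[order(vapply(out, subfamilySize, integer(1)))]
}
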