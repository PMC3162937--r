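#' @import methods
NULL

#' Ballesteros-Weinstein positions
#'
#' A vector-like S4 class holding transmembrane residue positions in the
#' Ballesteros-Weinstein (BW) scheme: a helix number 1-7 and an index
#' relative to the helix's most conserved residue (x.50). Positions render
#' as `"<helix>.<index>"` (e.g. `"3.32"`) and are totally ordered by helix,
#' then index, so `sort()` and comparison operators behave as expected.
#'
#' @slot helix integer vector, each in 1..7.
#' @slot index integer vector of BW indices, parallel to `helix`.
#' @seealso [parseBW()], [tmPositions()], [pocketPositions()]
#' @export
setClass("BWPosition",
    representation(helix = "integer", index = "integer"),
    validity = function(object) {
        if (length(object@helix) != length(object@index))
            return("helix and index must have the same length")
        if (anyNA(object@helix) || anyNA(object@index))
            return("helix and index must not contain NA")
        if (length(object@helix) && (any(object@helix < 1L) ||
                                     any(object@helix > 7L)))
            return("helix must lie in 1..7")
        if (length(object@index) && any(object@index < 1L))
            return("index must be positive")
        TRUE
    })

#' Gap-free transmembrane alignment
#'
#' The central container of the package: a gap-free multiple sequence
#' alignment of the seven transmembrane helices of class A GPCRs, one
#' 171-residue record per receptor sequence (the concatenated helix
#' segments, columns labelled by Ballesteros-Weinstein positions). Each
#' record carries a species annotation; the optional per-helix metadata
#' table records, for every aligned record and helix, the start offset of
#' the helix window in the original full-length sequence, the profile
#' alignment score and whether the score passed its calibrated threshold.
#'
#' @slot seqs [Biostrings::AAStringSet] of equal width 171 with unique
#'   names (record ids); gap characters are forbidden.
#' @slot species character vector parallel to `seqs`.
#' @slot helixMeta data.frame with columns `id`, `helix`, `offset`,
#'   `score`, `pass` (may have zero rows when the alignment was read from
#'   a file without metadata).
#' @seealso [TMAlignment()], [readTMFasta()], [alignSequences()]
#' @export
setClass("TMAlignment",
    representation(seqs = "AAStringSet", species = "character",
                   helixMeta = "data.frame"),
    validity = function(object) {
        w <- Biostrings::width(object@seqs)
        if (length(w) && any(w != 171L))
            return("every record must cover exactly 171 TM columns")
        ids <- names(object@seqs)
        if (length(object@seqs) && (is.null(ids) || anyDuplicated(ids)))
            return("records must have unique ids")
        if (length(object@species) != length(object@seqs))
            return("species must be parallel to the records")
        if (length(object@seqs)) {
            letters <- Biostrings::uniqueLetters(object@seqs)
            if (any(letters %in% c("-", ".", "*", "+")))
                return("gap characters must not occur inside helix segments")
            bad <- setdiff(letters, c(AA20, AA_AMBIG))
            if (length(bad))
                return(paste("non amino-acid letters present:",
                             paste(bad, collapse = ", ")))
        }
        need <- c("id", "helix", "offset", "score", "pass")
        if (!all(need %in% names(object@helixMeta)))
            return("helixMeta must have columns id, helix, offset, score, pass")
        TRUE
    })

#' Per-helix gap-free profile model
#'
#' A position-specific log-odds profile for one transmembrane helix, built
#' from a curated gap-free seed alignment. Because the alignment contract
#' forbids gaps, an exhaustive search over start offsets with this profile
#' is equivalent to profile-HMM alignment restricted to match states.
#'
#' @slot helix integer in 1..7.
#' @slot length segment length (number of profile columns).
#' @slot weights 20 x length numeric matrix of log-odds weights
#'   (rows named by amino acid); finite everywhere.
#' @slot background named numeric of length 20, the background
#'   frequencies used in the odds ratio.
#' @slot pseudocount the background-proportional pseudocount used.
#' @seealso [buildProfile()], [gapfreeAlign()]
#' @export
setClass("HelixProfile",
    representation(helix = "integer", length = "integer",
                   weights = "matrix", background = "numeric",
                   pseudocount = "numeric"),
    validity = function(object) {
        if (object@helix < 1L || object@helix > 7L)
            return("helix must lie in 1..7")
        if (!identical(dim(object@weights),
                       c(20L, object@length)))
            return("weights must be a 20 x length matrix")
        if (!identical(rownames(object@weights), AA20))
            return("weights rows must be named by the 20 amino acids")
        if (any(!is.finite(object@weights)))
            return("weights must be finite for all letters at every column")
        if (length(object@background) != 20L ||
            abs(sum(object@background) - 1) > 1e-8)
            return("background must be 20 frequencies summing to 1")
        TRUE
    })

#' Calibrated per-helix score thresholds
#'
#' Score cutoffs for the seven helix profiles, set so that 95% of
#' artificial sequences (i.i.d. draws from each helix's seed amino-acid
#' composition, scored by the same maximum-over-offsets search as real
#' sequences) fail to pass. Reproducible given the stored seed.
#'
#' @slot cutoffs named numeric of length 7 (names `"1"`..`"7"`).
#' @slot nArtificial number of artificial sequences per helix.
#' @slot artificialLength length of each artificial sequence.
#' @slot quantile the failure quantile (default 0.95).
#' @slot seed RNG seed used for the calibration draws.
#' @seealso [calibrateThresholds()]
#' @export
setClass("CalibratedThresholds",
    representation(cutoffs = "numeric", nArtificial = "integer",
                   artificialLength = "integer", quantile = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (length(object@cutoffs) != 7L)
            return("cutoffs must have length 7")
        TRUE
    })

#' Rooted subfamily tree
#'
#' A rooted hierarchical tree over the records of a [TMAlignment-class],
#' built by neighbor joining on the p-distance matrix and midpoint-rooted.
#' The set of leaves under any internal node is a candidate subfamily.
#'
#' @slot phylo an [ape::phylo] tree, rooted, with unique tip labels.
#' @seealso [buildNJTree()], [subfamiliesContaining()]
#' @export
setClass("SubfamilyTree",
    representation(phylo = "ANY"),
    validity = function(object) {
        if (!inherits(object@phylo, "phylo"))
            return("phylo slot must be an ape phylo object")
        if (anyDuplicated(object@phylo$tip.label))
            return("tip labels must be unique")
        if (!ape::is.rooted(object@phylo))
            return("tree must be rooted")
        TRUE
    })

#' One candidate subfamily (tree branch)
#'
#' The set of sequences under one internal node of a [SubfamilyTree-class].
#' A subfamily is scoring-eligible when its size lies in the configured
#' window (default 50-300) and its complement in the alignment is
#' non-empty, so the outside entropy is always defined.
#'
#' @slot node internal node number in the underlying `phylo` tree.
#' @slot members character vector of record ids in the branch.
#' @slot size number of sequences in the branch (`j` in the final-score
#'   aggregation).
#' @export
setClass("Subfamily",
    representation(node = "integer", members = "character",
                   size = "integer"),
    validity = function(object) {
        if (object@size != length(object@members))
            return("size must equal the number of members")
        TRUE
    })

#' Per-receptor residue score table
#'
#' The result of scoring one query receptor: for every one of the 171 TM
#' positions, the per-branch inside/outside entropies and combined scores,
#' the aggregated final score, and the rank (1 = most binding-like, i.e.
#' minimum score).
#'
#' @slot receptor query receptor id.
#' @slot aggregate `"min"` or `"size_weighted_mean"`.
#' @slot corner `"theoretical"` or `"empirical"`.
#' @slot subfamilySizes sizes of the branches that entered the score.
#' @slot scores data.frame with columns `position`, `score`, `rank`
#'   (171 rows, one per TM position).
#' @slot branches list of per-branch data.frames with columns `position`,
#'   `eIn`, `eOut`, `nIn`, `nOut`, `score`, named by branch size.
#' @seealso [scoreReceptor()]
#' @export
setClass("ResidueScoreTable",
    representation(receptor = "character", aggregate = "character",
                   corner = "character", subfamilySizes = "integer",
                   scores = "data.frame", branches = "list"),
    validity = function(object) {
        if (nrow(object@scores) != 171L)
            return("score table must have exactly one row per TM position")
        if (!setequal(object@scores$rank, seq_len(171L)))
            return("ranks must form a permutation of 1..171")
        TRUE
    })

#' Semi-logarithmic ROC result
#'
#' Result of the pROC AUC performance measure: the area under the ROC
#' curve with a log10 false-positive axis. A random ranking scores
#' 1/ln 10 (about 0.434); a perfect ordering of true residues ahead of
#' 100 false positives scores exactly 2.
#'
#' @slot auc the pROC AUC value.
#' @slot n number of true residues.
#' @slot nFalse number of false residues.
#' @slot betas per-true-residue false-positive fractions (clamped below at
#'   1/nFalse).
#' @seealso [procAUC()]
#' @export
setClass("ProcResult",
    representation(auc = "numeric", n = "integer", nFalse = "integer",
                   betas = "numeric"),
    validity = function(object) {
        if (length(object@betas) != object@n)
            return("one beta per true residue required")
        if (any(object@betas <= 0) || any(object@betas > 1))
            return("betas must lie in (0, 1]")
        TRUE
    })

#' Specification of a synthetic benchmark alignment
#'
#' Describes a multi-subfamily alignment with the statistical structure the
#' two-entropy score assumes: ligand-binding columns conserved within each
#' subfamily (a subfamily-specific letter, conserved with probability
#' `conservation`) but variable across subfamilies; structurally conserved
#' columns shared by all records; and i.i.d. background columns.
#'
#' @slot subfamilySizes integer vector, one size per subfamily.
#' @slot bindingPositions list (one element per subfamily) of BW labels of
#'   that subfamily's planted binding columns.
#' @slot structuralPositions BW labels of globally conserved columns.
#' @slot conservation within-subfamily conservation probability of a
#'   binding column, in (0, 1].
#' @slot structuralConservation conservation probability of a structural
#'   column across all records.
#' @slot background named numeric of length 20, the background letter
#'   distribution.
#' @slot species character vector of species labels, recycled over records.
#' @slot seed RNG seed used by [simulateMSA()].
#' @seealso [syntheticSpec()], [simulateMSA()]
#' @export
setClass("SyntheticSpec",
    representation(subfamilySizes = "integer", bindingPositions = "list",
                   structuralPositions = "character",
                   conservation = "numeric",
                   structuralConservation = "numeric",
                   background = "numeric", species = "character",
                   seed = "integer"),
    validity = function(object) {
        if (length(object@bindingPositions) != length(object@subfamilySizes))
            return("one bindingPositions set per subfamily required")
        if (any(object@subfamilySizes < 2L))
            return("subfamily sizes must be at least 2")
        tm <- as.character(tmPositions())
        all_bind <- unique(unlist(object@bindingPositions))
        if (!all(all_bind %in% tm))
            return("binding positions must be TM positions")
        if (!all(object@structuralPositions %in% tm))
            return("structural positions must be TM positions")
        if (length(intersect(all_bind, object@structuralPositions)))
            return("binding and structural position sets must be disjoint")
        if (object@conservation <= 0 || object@conservation > 1)
            return("conservation must lie in (0, 1]")
        if (object@conservation < max(object@background))
            return("conservation must exceed the background letter frequency")
        if (length(object@background) != 20L ||
            abs(sum(object@background) - 1) > 1e-8)
            return("background must be 20 frequencies summing to 1")
        TRUE
    })
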