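test_that("column entropy matches the analytic values", {
    expect_equal(columnEntropy(rep("D", 50)), 0)
    expect_equal(columnEntropy(AA20), log(20))
    expect_equal(columnEntropy(c(rep("A", 10), rep("V", 10))), log(2))
    ## ambiguity codes are excluded from the counts
    expect_equal(columnEntropy(c(rep("D", 5), "X", "B")), 0)
    expect_error(columnEntropy(c("X", "X")), "undefined entropy")
})

test_that("column entropy equals an independent recount on random columns", {
    set.seed(7)
    for (i in 1:20) {
        col <- sample(c(AA20, "X"), sample(5:80, 1), replace = TRUE)
        if (!any(col %in% AA20)) col <- c(col, "A")
        expect_equal(columnEntropy(col), recountEntropy(col))
    }
})

test_that("the two-entropy pair partitions the column correctly", {
    ## constant inside the subfamily, uniform outside
    rows <- c(
        stats::setNames(rep(rowWith("D"), 10), paste0("in", 1:10)),
        stats::setNames(vapply(AA20, rowWith, ""), paste0("out", 1:20)))
    aln <- TMAlignment(rows, "human")
    e <- twoEntropy(aln, paste0("in", 1:10), "1.33")
    expect_equal(e$eIn, 0)
    expect_equal(e$eOut, log(20))
    expect_identical(e$nIn + e$nOut, nrecords(aln))

    ## complement-of-one with identical symbols: both entropies zero
    same <- TMAlignment(stats::setNames(rep(rowWith("K"), 5),
                                        paste0("r", 1:5)), "human")
    e <- twoEntropy(same, paste0("r", 1:4), "3.32")
    expect_equal(e$eIn, 0)
    expect_equal(e$eOut, 0)
    expect_error(twoEntropy(same, paste0("r", 1:5), "3.32"), "out-set")
})

test_that("two-entropy values equal brute-force recounts of both partitions", {
    set.seed(8)
    sim <- simulateMSA(syntheticSpec(nSubfamilies = 3, size = 10,
                                     seed = 15))
    aln <- sim$alignment
    members <- sim$truth$records$id[sim$truth$records$subfamily == 2]
    for (p in sample(as.character(tmPositions()), 8)) {
        col <- tmColumn(aln, p)
        e <- twoEntropy(aln, members, p)
        expect_equal(e$eIn, recountEntropy(col[members]))
        expect_equal(e$eOut,
                     recountEntropy(col[setdiff(names(col), members)]))
    }
})

test_that("the combined score is the distance to the conservation corner", {
    expect_equal(combinedScore(0, log(20)), 0)
    expect_equal(combinedScore(log(20), 0), sqrt(2))
    expect_equal(combinedScore(0.5 * log(20), 0.5 * log(20)), sqrt(0.5))
    ## monotonicity: increasing eIn raises the score; increasing eOut
    ## lowers it
    set.seed(9)
    e <- stats::runif(50, 0, log(20))
    delta <- 1e-3
    expect_true(all(combinedScore(e + delta, e) > combinedScore(e, e)))
    expect_true(all(combinedScore(e, e + delta) < combinedScore(e, e)))
    expect_true(all(combinedScore(e, rev(e)) >= 0 &
                    combinedScore(e, rev(e)) <= sqrt(2)))
})

test_that("branch aggregation follows the configured rule", {
    expect_equal(aggregateBranches(c(0.5, 0.3, 0.7)), 0.3)
    expect_equal(aggregateBranches(0.42), 0.42)
    expect_equal(aggregateBranches(c(0.4, 0.2), sizes = c(60, 240),
                                   method = "size_weighted_mean"), 0.24)
    expect_error(aggregateBranches(numeric(0)), "size window")
    expect_error(aggregateBranches(c(0.1, 0.2),
                                   method = "size_weighted_mean"),
                 "sizes")
})

test_that("in-counts plus out-counts equal whole-alignment counts", {
    sim <- simulateMSA(syntheticSpec(nSubfamilies = 2, size = 12,
                                     seed = 19))
    m <- as.matrix(sim$alignment)
    members <- sim$truth$records$id[sim$truth$records$subfamily == 1]
    cntIn <- ssTEA:::.columnCounts(m[members, , drop = FALSE])
    cntOut <- ssTEA:::.columnCounts(m[setdiff(rownames(m), members), ,
                                      drop = FALSE])
    expect_equal(cntIn + cntOut, ssTEA:::.columnCounts(m))
})

## One scored instance of the default benchmark condition, reused below.
simDefault <- simulateMSA(syntheticSpec(seed = 27))
treeDefault <- buildNJTree(pDistanceMatrix(simDefault$alignment))
tableDefault <- scoreReceptor(simDefault$alignment, treeDefault,
                              "sf01_r001")

test_that("planted binding columns rank first; structural columns follow", {
    rs <- residueScores(tableDefault)
    roles <- simDefault$truth$columns$role[
        match(rs$position, simDefault$truth$columns$position)]
    expect_identical(sort(rs$rank), 1:171)
    ## the five subfamily-conserved binding columns take the top ranks
    expect_true(all(rs$rank[roles == "binding"] <= 5))
    ## globally conserved structural columns score worse than binding
    ## columns (their low outside entropy is penalized) but clearly
    ## better than the background bulk
    expect_true(all(rs$rank[roles == "structural"] > 5))
    expect_lt(stats::median(rs$rank[roles == "structural"]),
              stats::median(rs$rank[roles == "background"]) / 2)
})

test_that("receptor scoring is deterministic and order-invariant", {
    set.seed(10)
    perm <- sample(nrecords(simDefault$alignment))
    aln2 <- simDefault$alignment[perm]
    tree2 <- buildNJTree(pDistanceMatrix(simDefault$alignment))
    st2 <- scoreReceptor(aln2, tree2, "sf01_r001")
    expect_equal(residueScores(st2), residueScores(tableDefault))
})

test_that("scores are invariant under relabeling of amino acids", {
    set.seed(11)
    relabel <- stats::setNames(sample(AA20), AA20)
    m <- as.matrix(simDefault$alignment)
    swapped <- apply(matrix(relabel[m], nrow(m)), 1, paste, collapse = "")
    aln2 <- TMAlignment(stats::setNames(swapped, rownames(m)),
                        recordSpecies(simDefault$alignment))
    st2 <- scoreReceptor(aln2, treeDefault, "sf01_r001")
    expect_equal(residueScores(st2)$score, residueScores(tableDefault)$score)
})

test_that("aggregation and corner variants change scores as documented", {
    stW <- scoreReceptor(simDefault$alignment, treeDefault, "sf01_r001",
                         aggregate = "size_weighted_mean")
    expect_identical(stW@aggregate, "size_weighted_mean")
    b <- branchDetail(tableDefault)
    sizes <- tableDefault@subfamilySizes
    manual <- Reduce(`+`, Map(function(df, j) df$score * j, b,
                              as.list(sizes))) / sum(sizes)
    expect_equal(residueScores(stW)$score, manual)
    stE <- scoreReceptor(simDefault$alignment, treeDefault, "sf01_r001",
                         corner = "empirical")
    ## the empirical corner touches zero at the best observed pair
    expect_identical(stE@corner, "empirical")
    expect_lte(min(residueScores(stE)$score),
               min(residueScores(tableDefault)$score))
})

test_that("scoring errors are informative", {
    expect_error(scoreReceptor(simDefault$alignment, treeDefault,
                               "nosuch"), "not in the alignment")
    expect_error(scoreReceptor(simDefault$alignment, treeDefault,
                               "sf01_r001", minSize = 580, maxSize = 590),
                 "relax the subfamily size window")
})

test_that("score tables round-trip through their TSV format", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeScoreTable(tableDefault, path)
    header <- readLines(path, n = 4)
    expect_match(header[1], "receptor=sf01_r001")
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#",
                            colClasses = c(position = "character"))
    expect_identical(nrow(df), 171L)
    expect_equal(df$score, residueScores(tableDefault)$score,
                 tolerance = 1e-12)
    rp <- withr::local_tempfile(fileext = ".tsv")
    writeRanking(scoreRanking(tableDefault), rp)
    expect_identical(readRanking(rp), scoreRanking(tableDefault))
})
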