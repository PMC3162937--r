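## Pipeline fixtures are moderately expensive; build once per file.
seedAln <- toySeed(seed = 5)
profiles <- buildHelixProfiles(seedAln)
thresholds <- calibrateThresholds(profiles, seedAln, nArtificial = 1000,
                                  rngSeed = 8)

test_that("planted in-order helices are recovered exactly and all pass", {
    hs <- simulateHelixSequences(profiles, nPlanted = 6, nDecoy = 0,
                                 seed = 21)
    for (k in seq_along(hs$seqs)) {
        res <- alignSequence(profiles, hs$seqs[[k]], thresholds)
        expect_false(isTRUE(res$rejected != FALSE))
        expect_identical(res$meta$offset,
                         as.integer(hs$truth[k, paste0("offset", 1:7)]))
        expect_true(all(res$meta$pass))
        expect_identical(nchar(res$row), 171L)
    }
})

test_that("zero-length linkers (adjacent helices) are still recovered", {
    hs <- simulateHelixSequences(profiles, nPlanted = 3, nDecoy = 0,
                                 seed = 22, linkerRange = c(0L, 0L))
    for (k in 1:3) {
        res <- alignSequence(profiles, hs$seqs[[k]], thresholds)
        expect_identical(res$meta$offset,
                         as.integer(hs$truth[k, paste0("offset", 1:7)]))
    }
})

test_that("a helix whose best hit is out of order is realigned between its neighbours", {
    cons <- vapply(profiles, profileConsensus, "")
    ## weaken the in-place copy of helix 4 at 6 positions so its best
    ## global hit becomes the intact copy planted after helix 7
    weak4 <- strsplit(cons[4], "")[[1]]
    weak4[c(1, 5, 9, 13, 17, 21)] <- "W"
    weak4 <- paste(weak4, collapse = "")
    seq <- paste0("AAAAA", cons[1], "GG", cons[2], "GG", cons[3], "GG",
                  weak4, "GG", cons[5], "GG", cons[6], "GG", cons[7],
                  "GGGG", cons[4], "AAAAA")
    ## unconstrained, helix 4's best hit is the trailing intact copy
    lateHit <- gapfreeAlign(profiles[[4]], seq)
    expect_gt(lateHit$offset,
              gapfreeAlign(profiles[[5]], seq)$offset)
    res <- alignSequence(profiles, seq, thresholds)
    expect_false(isTRUE(res$rejected != FALSE))
    o <- res$meta$offset
    L <- vapply(profiles, slot, integer(1), "length")
    ## helix 4 now sits between helices 3 and 5, at the weakened copy
    expect_gte(o[4], o[3] + L[3])
    expect_lte(o[4] + L[4], o[5])
})

test_that("aligned helix windows are always in order and non-overlapping", {
    hs <- simulateHelixSequences(profiles, nPlanted = 5, nDecoy = 15,
                                 seed = 23)
    res <- alignSequences(profiles, hs$seqs, hs$species, thresholds)
    meta <- helixMetadata(res$alignment)
    L <- vapply(profiles, slot, integer(1), "length")
    for (id in unique(meta$id)) {
        m <- meta[meta$id == id, ]
        m <- m[order(m$helix), ]
        expect_true(all(m$offset[-1] >= (m$offset + L)[-7]),
                    label = paste("ordered windows for", id))
    }
})

test_that("composition-matched decoys fail most helices; planted pass", {
    hs <- simulateHelixSequences(profiles, nPlanted = 20, nDecoy = 20,
                                 seed = 24)
    res <- alignSequences(profiles, hs$seqs, hs$species, thresholds)
    meta <- helixMetadata(res$alignment)
    fails <- tapply(!meta$pass, meta$id, sum)
    planted <- grepl("^planted", names(fails))
    ## decoys rejected before scoring also count as correctly excluded
    nDecoyAligned <- sum(!planted)
    expect_gte(mean(fails[!planted] >= 5),
               if (nDecoyAligned > 0) 0.95 else 1)
    kept <- recordIds(filterFailing(res$alignment))
    sens <- mean(hs$truth$id[hs$truth$planted] %in% kept)
    spec <- mean(!(hs$truth$id[!hs$truth$planted] %in% kept))
    expect_gte(sens, 0.95)
    expect_gte(spec, 0.95)
})

test_that("too-short sequences are rejected with a reason", {
    res <- alignSequence(profiles, strrep("A", 50), thresholds)
    expect_match(res$rejected, "shorter")
    res <- alignSequences(profiles, c(tiny = strrep("A", 20)), "human",
                          thresholds)
    expect_identical(nrecords(res$alignment), 0L)
    expect_identical(res$rejected$id, "tiny")
})

test_that("the failed-helix filter keeps records failing at most 4 of 7", {
    rows <- c(ok0 = rowWith("A"), ok4 = rowWith("C"), bad5 = rowWith("D"))
    meta <- data.frame(
        id = rep(names(rows), each = 7), helix = rep(1:7, 3),
        offset = 0L, score = 1,
        pass = c(rep(TRUE, 7),                       # 0 failed
                 c(rep(FALSE, 4), rep(TRUE, 3)),     # 4 failed
                 c(rep(FALSE, 5), rep(TRUE, 2))))    # 5 failed
    aln <- TMAlignment(rows, "human", meta)
    kept <- filterFailing(aln)
    expect_setequal(recordIds(kept), c("ok0", "ok4"))
    expect_identical(recordIds(filterFailing(aln, maxFailed = 5)),
                     c("ok0", "ok4", "bad5"))
})

test_that("within-species near-duplicates collapse transitively", {
    base <- rowWith("A")
    ## b differs from a at 9 columns (< 10: duplicate); c differs from b
    ## at 9 but from a at 18 (grouped transitively); d differs from all
    ## three at >= 10 columns and stays
    rows <- c(a = base,
              b = rowWith("A", 1:9, rep("C", 9)),
              c = rowWith("A", 1:18, rep("C", 18)),
              d = rowWith("A", 21:30, rep("D", 10)))
    aln <- TMAlignment(rows, species = "human")
    kept <- recordIds(dedupSpecies(aln))
    expect_setequal(kept, c("a", "d"))

    ## exactly 10 differences: both kept (strict inequality)
    aln2 <- TMAlignment(rows[c("a", "d")], species = "human")
    expect_identical(nrecords(dedupSpecies(aln2)), 2L)

    ## identical sequences in different species are never collapsed
    aln3 <- TMAlignment(c(x = base, y = base),
                        species = c("human", "mouse"))
    expect_identical(nrecords(dedupSpecies(aln3)), 2L)
})

test_that("under-sampled species are removed entirely", {
    n1 <- 99; n2 <- 100
    rows <- c(stats::setNames(rep(rowWith("A"), n1), paste0("sp1_", 1:n1)),
              stats::setNames(rep(rowWith("C"), n2), paste0("sp2_", 1:n2)))
    aln <- TMAlignment(rows, rep(c("rare", "common"), c(n1, n2)))
    kept <- filterSpecies(aln)
    expect_identical(unique(unname(recordSpecies(kept))), "common")
    expect_identical(nrecords(kept), 100L)
    empty <- aln[integer(0)]
    expect_identical(nrecords(filterSpecies(empty)), 0L)
})

test_that("the alignment pipeline is deterministic given the seed", {
    hs <- simulateHelixSequences(profiles, nPlanted = 4, nDecoy = 4,
                                 seed = 31)
    r1 <- alignSequences(profiles, hs$seqs, hs$species, thresholds)
    r2 <- alignSequences(profiles, hs$seqs, hs$species, thresholds)
    expect_identical(as.character(tmSequences(r1$alignment)),
                     as.character(tmSequences(r2$alignment)))
    expect_identical(helixMetadata(r1$alignment),
                     helixMetadata(r2$alignment))
    t2 <- calibrateThresholds(profiles, seedAln, nArtificial = 1000,
                              rngSeed = 8)
    expect_identical(thresholdCutoffs(thresholds), thresholdCutoffs(t2))
})
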