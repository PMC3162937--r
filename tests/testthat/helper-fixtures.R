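## Shared fixtures, built in code at test time.

AA20 <- ssTEA:::AA20

## Small synthetic seed alignment (3 subfamilies x 8 records).
toySeed <- function(seed = 1) {
    simulateMSA(syntheticSpec(nSubfamilies = 3, size = 8,
                              seed = seed))$alignment
}

## A TMAlignment built from explicit 171-residue strings.
makeAln <- function(rows, species = "human") {
    TMAlignment(rows, species)
}

## A 171-residue string that is `base` everywhere except `letters`
## substituted at the given 1-based column indices.
rowWith <- function(base = "A", at = integer(), letters = character()) {
    chars <- rep(base, 171)
    chars[at] <- letters
    paste(chars, collapse = "")
}

## Independent brute-force oracle for the gap-free aligner: score every
## admissible window by direct summation and return the best (smallest
## offset on ties).
bruteForceAlign <- function(profile, seq, searchRange = NULL) {
    chars <- strsplit(seq, "")[[1]]
    L <- profile@length
    w <- profile@weights
    lo <- 0L; hi <- length(chars)
    if (!is.null(searchRange)) {
        lo <- searchRange[[1]]; hi <- searchRange[[2]]
    }
    idx <- match(chars, rownames(w))
    best <- NULL
    for (o in lo:(hi - L)) {
        s <- 0
        for (j in seq_len(L)) {
            if (!is.na(idx[o + j])) s <- s + w[idx[o + j], j]
        }
        if (is.null(best) || s > best$score + 1e-12)
            best <- list(offset = o, score = unname(s))
    }
    best
}

## Hand-rolled column entropy used as an independent recount oracle.
recountEntropy <- function(symbols) {
    symbols <- symbols[symbols %in% AA20]
    p <- table(symbols) / length(symbols)
    -sum(p * log(p))
}
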