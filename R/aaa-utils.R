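## Internal constants and helpers shared across the package.

## The fixed 20-letter amino-acid alphabet over which entropies, profile
## weights and background frequencies are defined. Ambiguity codes
## (X, B, Z, J, U, O) may occur in records but never enter counts.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_AMBIG <- c("X", "B", "Z", "J", "U", "O")

#' Background amino-acid frequency presets
#'
#' Returns a named frequency vector over the 20 standard amino acids.
#' `"uniform"` is the simplest null (1/20 each); `"swissprot"` is a
#' database-wide composition typical of globular proteins, useful when a
#' more realistic background is wanted for simulation or profile building.
#'
#' @param preset `"uniform"` or `"swissprot"`.
#' @return Named numeric vector of length 20 summing to 1.
#' @examples
#' bgFrequencies("uniform")[["W"]]
#' @export
bgFrequencies <- function(preset = c("uniform", "swissprot")) {
    preset <- match.arg(preset)
    if (preset == "uniform") {
        p <- rep(1 / 20, 20)
    } else {
        ## UniProtKB/Swiss-Prot release-wide composition (percent), rounded.
        p <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86,
               G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
               M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
               S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92)
        p <- p / sum(p)
    }
    names(p) <- AA20
    p
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards. All stochastic operations in the
## package funnel through this so a single integer seed makes a run
## reproducible.
withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

## Split a character vector of sequences into a character matrix
## (one row per sequence); all sequences must share one length.
.charMatrix <- function(x) {
    n <- unique(nchar(x))
    if (length(n) != 1L)
        stop("sequences do not share a common length")
    m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                nrow = length(x), ncol = n, byrow = TRUE)
    rownames(m) <- names(x)
    m
}

## Per-column counts over the 20-letter alphabet for a character matrix
## with one row per record. Returns an ncol(m) x 20 integer matrix;
## ambiguity codes contribute nothing.
.columnCounts <- function(m) {
    cnt <- vapply(AA20, function(a) .colSums(m == a, nrow(m), ncol(m)),
                  numeric(ncol(m)))
    cnt <- matrix(cnt, nrow = ncol(m), ncol = 20L)   # robust to 1 column
    dimnames(cnt) <- list(colnames(m), AA20)
    cnt
}

## Shannon entropy (nats) per row of a counts matrix (rows = columns of
## the alignment, cols = 20 letters). Rows with zero countable symbols
## give NA; callers decide whether that is an error.
.entropyFromCounts <- function(cnt) {
    ntot <- rowSums(cnt)
    p <- cnt / ifelse(ntot > 0, ntot, 1)
    p[p == 0] <- 1          # 0 * log 0 := 0
    h <- -rowSums(p * log(p))
    h[ntot == 0] <- NA_real_
    h
}
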