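# Independent oracles and small fixture builders used across test files.

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
rprot <- function(n) paste(sample(setdiff(LETTERS, c("B","J","O","U","X","Z")),
                                  n, replace = TRUE), collapse = "")

# Brute-force six-frame ORF oracle: walks every codon window one codon at a
# time with Biostrings primitives, accumulating maximal stop-free runs.
# Independent of the package's vectorized scan.
oracleOrfs <- function(seq, minAa = 10L) {
    gc <- Biostrings::GENETIC_CODE
    L <- nchar(seq)
    out <- list()
    for (strand in c("forward", "reverse")) {
        s <- if (strand == "forward") seq else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(seq)))
        for (f in 1:3) {
            pos <- f
            runAa <- character(); runStart <- NA_integer_
            flush <- function(endPos) {
                if (length(runAa) >= minAa) {
                    a <- runStart; b <- endPos
                    if (strand == "reverse") {
                        tmp <- a; a <- L - b + 1L; b <- L - tmp + 1L
                    }
                    out[[length(out) + 1L]] <<- data.frame(
                        strand = strand, frame = f, nt_start = a,
                        nt_end = b, aa = paste(runAa, collapse = ""),
                        stringsAsFactors = FALSE)
                }
                runAa <<- character(); runStart <<- NA_integer_
            }
            while (pos + 2L <= L) {
                codon <- substr(s, pos, pos + 2L)
                aa <- if (grepl("[^ACGT]", codon)) "X" else gc[[codon]]
                if (aa == "*") {
                    flush(pos - 1L)
                } else {
                    if (length(runAa) == 0L) runStart <- pos
                    runAa <- c(runAa, aa)
                }
                pos <- pos + 3L
            }
            flush(pos - 1L)
        }
    }
    if (length(out) == 0L)
        return(data.frame(strand = character(), frame = integer(),
                          nt_start = integer(), nt_end = integer(),
                          aa = character(), stringsAsFactors = FALSE))
    df <- do.call(rbind, out)
    df[order(df$strand, df$frame, df$nt_start), , drop = FALSE]
}

# Affine-gap Needleman-Wunsch oracle (BLOSUM62, gap open 10, extend 0.5),
# returning percent identity over aligned columns. Plain dynamic program,
# independent of Biostrings' C implementation.
nwIdentity <- function(a, b, gapOpen = 10, gapExt = 0.5) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    sub <- BLOSUM62
    A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(NEG, n + 1L, m + 1L)   # A[i] aligned to B[j]
    X <- matrix(NEG, n + 1L, m + 1L)   # gap in B (A[i] unmatched)
    Y <- matrix(NEG, n + 1L, m + 1L)   # gap in A
    M[1L, 1L] <- 0
    for (i in seq_len(n) + 1L)
        X[i, 1L] <- -gapOpen - gapExt * (i - 1L)
    for (j in seq_len(m) + 1L)
        Y[1L, j] <- -gapOpen - gapExt * (j - 1L)
    for (i in seq_len(n) + 1L) {
        for (j in seq_len(m) + 1L) {
            sc <- sub[A[i - 1L], B[j - 1L]]
            M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                           Y[i - 1L, j - 1L]) + sc
            X[i, j] <- max(M[i - 1L, j] - gapOpen - gapExt,
                           X[i - 1L, j] - gapExt)
            Y[i, j] <- max(M[i, j - 1L] - gapOpen - gapExt,
                           Y[i, j - 1L] - gapExt)
        }
    }
    # traceback for identity
    i <- n + 1L; j <- m + 1L
    state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
    matches <- 0L; cols <- 0L
    while (i > 1L || j > 1L) {
        if (state == 1L) {
            matches <- matches + (A[i - 1L] == B[j - 1L])
            cols <- cols + 1L
            sc <- sub[A[i - 1L], B[j - 1L]]
            prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                      Y[i - 1L, j - 1L])
            state <- which.max(prev)
            i <- i - 1L; j <- j - 1L
        } else if (state == 2L) {
            cols <- cols + 1L
            from <- c(M[i - 1L, j] - gapOpen - gapExt,
                      X[i - 1L, j] - gapExt)
            state <- if (which.max(from) == 1L) 1L else 2L
            i <- i - 1L
        } else {
            cols <- cols + 1L
            from <- c(M[i, j - 1L] - gapOpen - gapExt,
                      Y[i, j - 1L] - gapExt)
            state <- if (which.max(from) == 1L) 1L else 3L
            j <- j - 1L
        }
    }
    100 * matches / cols
}

# Deterministic test back-translation (fixed codon per residue); only used
# to build nucleotide fixtures whose translations are known. Codons are
# chosen stop-prone on the reverse strand (TTA/TCA/GTA/ATA are reverse-
# frame stops or feed cross-boundary ones), so fixtures do not grow long
# reverse-strand decoy ORFs that would displace the planted ones.
fixedCodon <- c(A="GCT", C="TGC", D="GAT", E="GAA", F="TTC", G="GGT",
                H="CAC", I="ATA", K="AAA", L="TTA", M="ATG", N="AAC",
                P="CCA", Q="CAA", R="CGT", S="TCA", T="ACT", V="GTA",
                W="TGG", Y="TAC")
backTx <- function(prot)
    paste(fixedCodon[strsplit(prot, "")[[1L]]], collapse = "")

# Minimal hit-table row in the package's canonical layout.
hitRow <- function(q, s, evalue, bitscore = 100, stitle = NA_character_,
                   sstart = 1L, send = 50L, qstart = 1L, qend = 50L,
                   pident = 90, len = 50L) {
    data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
               mismatch = 0L, gapopen = 0L, qstart = qstart, qend = qend,
               sstart = sstart, send = send, evalue = evalue,
               bitscore = bitscore, stitle = stitle,
               stringsAsFactors = FALSE)
}

# A protein family chained by identity: A-B at ~45%, B-C at ~45%, A-C at
# ~20% (mutation sets overlap by `ov` positions so pairwise differences
# are |S1| + |S2| - ov). Equal lengths keep the global alignment gapless.
chainFamily <- function(len = 100L, nMut = 55L, ov = 30L, seed = 11L) {
    set.seed(seed)
    aa <- setdiff(LETTERS, c("B","J","O","U","X","Z"))
    A <- sample(aa, len, replace = TRUE)
    mutate <- function(x, at) {
        for (i in at) x[i] <- sample(setdiff(aa, x[i]), 1L)
        x
    }
    s1 <- sample(len, nMut)
    B <- mutate(A, s1)
    s2 <- c(sample(s1, ov), sample(setdiff(seq_len(len), s1), nMut - ov))
    C <- mutate(B, s2)
    list(A = paste(A, collapse = ""), B = paste(B, collapse = ""),
         C = paste(C, collapse = ""))
}
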