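## Six-frame stop-to-stop ORF extraction.
##
## An ORF here is the translation of a maximal stop-free codon run in one of
## the six reading frames (getorf-style stop-to-stop semantics, not
## start-codon anchored). Runs abutting the transcript ends (partial terminal
## ORFs) are reported: transcript ends are typically truncated. Ambiguous
## codons translate to 'X' and never terminate a run.

## Standard genetic code lookup (codon -> amino acid, '*' for stops).
.GC64 <- Biostrings::GENETIC_CODE

## IUPAC complement, including ambiguity codes.
.complement <- function(s) chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s)

## Translate an in-frame nucleotide character vector; trailing partial
## codon dropped; codons with ambiguity codes -> 'X'.
.translateChars <- function(ch) {
    n <- length(ch) %/% 3L
    if (n == 0L) return("")
    i <- 3L * (seq_len(n) - 1L)
    aa <- unname(.GC64[paste0(ch[i + 1L], ch[i + 2L], ch[i + 3L])])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

## Maximal stop-free runs (aa coordinates) within a translated frame.
.aaRuns <- function(aa, minAa) {
    if (!nzchar(aa)) return(NULL)
    m <- gregexpr("[^*]+", aa)[[1L]]
    if (m[1L] == -1L) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= minAa
    if (!any(keep)) return(NULL)
    list(start = as.integer(m[keep]), len = as.integer(len[keep]))
}

#' Find all six-frame open reading frames of each transcript
#'
#' Scans all six reading frames of every transcript for maximal stop-free
#' codon runs of at least \code{minAa} residues, translated with the
#' standard genetic code (ambiguous codons become \code{X}). Reverse-strand
#' ORFs report coordinates on the forward transcript axis. Ordinals (and
#' \code{_ORF_<n>} ids) follow a deterministic scan order: forward frames
#' 1..3 then reverse frames 1..3, 5' to 3' within each frame's own reading
#' direction.
#'
#' @param x A [TranscriptSet-class], a named \code{DNAStringSet}, or a named
#'   character vector of nucleotide sequences.
#' @param minAa Minimum ORF length in residues (default 10, roughly the
#'   30-nt default of the classic EMBOSS extractor).
#' @return An [OrfSet-class].
#' @examples
#' ts <- TranscriptSet(c(t1 = "TAAATGGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCTAG"))
#' orfTable(findOrfs(ts, minAa = 5))
#' @export
findOrfs <- function(x, minAa = 10L) {
    if (is(x, "TranscriptSet")) x <- transcriptSeqs(x)
    if (!is.character(x)) {
        nm <- names(x)
        x <- as.character(x)
        names(x) <- nm
    }
    x <- toupper(x)
    stopifnot(length(x) == 0L || !is.null(names(x)))
    perTx <- vector("list", length(x))
    for (t in seq_along(x)) {
        tid <- names(x)[t]
        L <- nchar(x[[t]])
        if (L < 3L) {
            message("transcript ", tid, " shorter than one codon; skipped")
            next
        }
        fwd <- strsplit(x[[t]], "", fixed = TRUE)[[1L]]
        rev <- rev(strsplit(.complement(x[[t]]), "", fixed = TRUE)[[1L]])
        strandV <- character(); frameV <- integer()
        sV <- integer(); eV <- integer(); aaV <- character()
        for (strand in c("forward", "reverse")) {
            ch <- if (strand == "forward") fwd else rev
            for (f in 1:3) {
                if (L - f + 1L < 3L) next
                aa <- .translateChars(ch[f:L])
                runs <- .aaRuns(aa, minAa)
                if (is.null(runs)) next
                for (r in seq_along(runs$start)) {
                    i <- runs$start[r]; n <- runs$len[r]
                    a <- f + 3L * (i - 1L)       # on reading strand
                    b <- f + 3L * (i + n - 1L) - 1L
                    if (strand == "reverse") {   # mirror to forward axis
                        tmp <- a
                        a <- L - b + 1L
                        b <- L - tmp + 1L
                    }
                    strandV <- c(strandV, strand)
                    frameV <- c(frameV, f)
                    sV <- c(sV, a); eV <- c(eV, b)
                    aaV <- c(aaV, substr(aa, i, i + n - 1L))
                }
            }
        }
        if (length(aaV))
            perTx[[t]] <- data.frame(
                orf_id = paste0(tid, "_ORF_", seq_along(aaV)),
                transcript_id = tid, strand = strandV, frame = frameV,
                nt_start = sV, nt_end = eV, aa = aaV,
                aa_length = nchar(aaV), ordinal = seq_along(aaV),
                stringsAsFactors = FALSE)
    }
    perTx <- perTx[!vapply(perTx, is.null, TRUE)]
    tb <- if (length(perTx)) do.call(rbind, perTx) else
        data.frame(orf_id = character(), transcript_id = character(),
                   strand = character(), frame = integer(),
                   nt_start = integer(), nt_end = integer(),
                   aa = character(), aa_length = integer(),
                   ordinal = integer(), stringsAsFactors = FALSE)
    OrfSet(tb)
}

#' Select the k longest ORFs per transcript
#'
#' @param orfs An [OrfSet-class].
#' @param k Number of ORFs to keep per transcript (default 3, the number of
#'   candidate coding frames carried into classification). Ties in length
#'   are broken by scan order, so the result is deterministic.
#' @return An [OrfSet-class] with at most \code{k} ORFs per transcript,
#'   ordered by descending residue length within transcript.
#' @export
topOrfs <- function(orfs, k = 3L) {
    tb <- orfTable(orfs)
    if (nrow(tb) == 0L) return(orfs)
    tb <- tb[order(tb$transcript_id, -tb$aa_length, tb$ordinal), ,
             drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(tb)), tb$transcript_id),
                          function(i) i[seq_len(min(k, length(i)))]),
                   use.names = FALSE)
    OrfSet(tb[sort(keep), , drop = FALSE])
}

#' Translate an in-frame nucleotide string
#'
#' @param codons Nucleotide string with length divisible by 3.
#' @param strand \code{"forward"} or \code{"reverse"}; reverse means the
#'   reverse complement is translated.
#' @return Protein string under the standard genetic code; ambiguous codons
#'   yield \code{X}.
#' @examples
#' translateCodons("ATGGCC")            # "MA"
#' translateCodons("GGCCAT", "reverse") # "MA"
#' @export
translateCodons <- function(codons, strand = c("forward", "reverse")) {
    strand <- match.arg(strand)
    if (nchar(codons) %% 3L != 0L)
        stop("sequence length must be divisible by 3")
    s <- toupper(codons)
    ch <- if (strand == "reverse")
        rev(strsplit(.complement(s), "", fixed = TRUE)[[1L]])
    else strsplit(s, "", fixed = TRUE)[[1L]]
    .translateChars(ch)
}
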